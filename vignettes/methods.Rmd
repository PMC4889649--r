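---
title: "Methods: masked-haplotype PCA, Mendelian checks and the synthetic cohort"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: masked-haplotype PCA, Mendelian checks and the synthetic cohort}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(laikit)
```

# The problem

Local ancestry inference assigns a continental origin to each of an
admixed individual's two chromosomes at every genomic position. Once
such calls exist, three downstream questions recur: *how accurate are
they* (no truth is available for real cohorts), *what structure exists
within one ancestral component* (confounded, in ordinary PCA, by
genome-wide admixture proportions), and *how should the X chromosome be
coded* for diploid-only callers when males are haploid. This package
implements the post-processing machinery for all three, plus the
synthetic data needed to validate it.

# Ancestry-specific PCA by masked-haplotype MDS

## Model and procedure

For a target ancestry, every allele on a haplotype segment *not* called
as that ancestry is set to missing ("masking"). The masking pattern is
haplotype-level, so the analysis is per haplotype: each sample
contributes two rows. The pipeline is

1. drop samples on an externally supplied exclusion list (e.g. close
   relatives — kinship estimation is out of scope here and treated as
   an input);
2. keep samples with at least 50% global target ancestry, computed from
   the local calls themselves (individuals below that retain too little
   data after masking and produce noisy coordinates; the comparison is
   inclusive, `>=`);
3. thin markers (default 10,000) to tame linkage disequilibrium and
   distance cost;
4. mask;
5. compute pairwise haplotype distances under pairwise deletion;
6. classical (Torgerson) MDS.

With alleles coded 0/1 and no missingness, Euclidean-distance MDS is
exactly PCA of the centred allele matrix, which is why the output is
called PCs. The MDS route exists because of the missingness: distances
need only the sites both haplotypes retain.

## The distance and its numerical choices

For haplotypes $x, y$ sharing $s > 0$ non-missing sites of $M$,

$$ d(x,y) = \sqrt{\frac{M}{s} \sum_{m \in \text{shared}} (x_m - y_m)^2 }, $$

the proportional up-scaling convention of R's `dist()`. The scaling
matters: masked/unmasked haplotype pairs share systematically fewer
sites, and without rescaling their distances would shrink, separating
masked haplotypes artifactually. A `scaled = FALSE` flag exposes the
unscaled $\sqrt{\sum}$ alternative for sensitivity analysis. Pairs
sharing *no* site get the mean of all defined off-diagonal distances,
computed once after all defined pairs (no iteration); they are flagged
in the result. A panel where no pair shares a site is an error.

MDS double-centres the squared distances, $B = -\tfrac12 J D^{(2)} J$,
and eigendecomposes $B$. Coordinates use only positive eigenvalues
(columns beyond them are zero and `n_positive` reports the shortfall);
eigen-sign is fixed by making each column's largest-magnitude entry
positive, so results are deterministic across linear-algebra backends.
Non-Euclidean inputs (possible after mean imputation) simply yield
negative trailing eigenvalues, which are reported, not used.

Reference haplotypes, when supplied, pass through unmasked alongside
the masked admixed haplotypes, so admixed clusters can be anchored to
reference populations in the same embedding.

## Marker thinning

Thinning is deterministic: the target count is allocated to
chromosomes by largest-remainder rounding of their site-count shares,
then evenly spaced site indices are taken within each chromosome.
Deterministic spacing was chosen over random or LD-based pruning
because it is reproducible without an RNG and close to uniform
coverage; LD-aware pruning would need genotype-level LD estimates that
masking has partly destroyed.

# Mendelian inconsistency of ancestry calls

A child receives exactly one chromosome from each parent. At a site,
write the child's unordered call pair $\{c_1, c_2\}$:

* **trio**: consistent iff some ordering has $c_1$ in the mother's pair
  and $c_2$ in the father's (the ordering form is multiset-aware —
  child $\{A,A\}$ needs $A$ in both parents);
* **pair** (one parent observed): consistent iff either child code
  appears in the observed parent's pair — the missing parent is
  unconstrained, which is why pair rates are systematically *lower*
  than trio rates at equal call error: fewer errors are detectable;
* **X**: a son's single X is maternal (code must be in the mother's
  pair); a daughter carries the father's X unchanged plus one maternal
  recombinant (father's code in the daughter's pair, and the remaining
  daughter code — after multiset removal of one instance of the
  father's — in the mother's pair).

Predicates operate on unordered calls even though calls are phased:
statistical phase is unreliable across individuals, and transmission
logic does not need it. Rates pool all (family, site) cells equally
within a configuration rather than averaging per-family rates; with
balanced site counts the two coincide, and pooling matches the
single-number-per-configuration reporting convention. Any missing call
among a family's members removes that cell from numerator and
denominator. Sites are assumed restricted to non-pseudoautosomal X in
X mode.

# X-chromosome codings

Coding reference males as homozygous diploids makes each male
haplotype appear twice in the reference, inflating its apparent
frequency; pairing two real male haplotypes into one phased
pseudodiploid avoids this without losing phase (reference phase is
never re-estimated downstream). Pairing is by input order within each
reference group, with an optional seeded shuffle (the pairing rule is
arbitrary; input order is the reproducible default), and an odd
trailing male is dropped and reported. Option 1 analyses admixed males
(haploid, known phase) separately from admixed females (statistically
phased); Option 2 codes admixed males homozygous and analyses everyone
together; Option 3 codes *all* males homozygous. Options 2 and 3
encode admixed individuals identically — they differ only in the
reference — which the tests assert.

# The synthetic cohort generator

## What it emulates

* **Hierarchical allele frequencies** (Balding–Nichols): ancestral
  frequency per site $\sim$ Uniform(0.05, 0.95); continental
  frequencies Beta-distributed around it with drift $F_{\text{cont}}$;
  optional nested subpopulations drawn the same way around their
  continent with $F_{\text{sub}}$. A continent declared with one
  subpopulation reuses the continental vector unchanged.
* **Admixture tracts**: ancestry switch points form a Poisson process
  of intensity $g$ per Morgan along a uniform genetic map; tract
  ancestries are i.i.d. from the admixture proportions $\pi$ (so
  adjacent tracts may share an ancestry; the realised switch rate is
  thinned by the collision probability).
* **Families**: children are built by meiosis — crossovers Poisson at
  rate 1 per Morgan — copying alleles *and* true ancestry labels from
  the active parental haplotype, so the truth is Mendelian-consistent
  by construction at both the allele and the ancestry level.
* **X chromosome**: mothers/daughters diploid, fathers/sons haploid;
  sons receive a maternal recombinant, daughters the paternal X
  unchanged plus a maternal recombinant.
* **Call errors**: `corrupt_calls` flips each cell to a uniformly
  chosen different ancestry with probability $\varepsilon$.

## Defaults and why

$K = 3$ ancestries (African, Amerindian, European — the classic
three-way admixture of the Americas); $F_{\text{cont}} = 0.15$, the
scale of continental-level divergence; $F_{\text{sub}} = 0.05$ for
within-continent structure; $g = 8$ generations, a typical
post-colonial admixture depth giving realistic tract lengths; map
length 3 Morgans and $M = 2000$ sites — one long chromosome's worth,
large enough for stable distances yet fast; uniform $\pi$ unless a
scenario needs otherwise. Reference individuals are unadmixed draws
from their continental frequencies. All generators are seeded from the
config; a fixed seed reproduces every byte.

## What it does not emulate

Sites are independent given frequencies — there is no within-population
LD, no mutation/selection, no coalescent genealogy, and tract
ancestries have no Markov dependence beyond forced switching. Passing
tests therefore demonstrate the *contracts* (masking, distances,
transmission logic, rate bookkeeping) on data with realistic marginal
structure, not performance on LD-rich real genomes. Similarly,
posterior arrays are synthetic: the package summarises posteriors, it
does not calibrate them.

# Validation experiment sizes

The shipped tests and the acceptance script run, among others: exact
enumeration oracles for all 36 pair, 216 trio and all X predicate
combinations; corruption response on 50 trios × 2000 sites across 10
seeds and $\varepsilon \in \{0, 0.005, 0.01, 0.02, 0.05\}$ (trio rate
exceeds pair rate at every seed; mean rates monotone); MDS/PCA duality
on 200 haplotypes × 2000 sites (per-component $|r| > 0.999$ against
`prcomp`); masking robustness with 50% random masking in half of 200
haplotypes over 5 seeds (logistic classifier on PCs 1–2 stays below
0.60 accuracy; PC1 group-mean shift below 0.5 pooled SD); and
subpopulation recovery — two subpopulations at $F_{\text{sub}} = 0.05$
inside the target continent, 100 admixed diploids with ≥ 50% target
ancestry — where 2-means on PC1 of the masked embedding recovers the
subpopulation of origin for ≥ 95% of haplotypes over 3 seeds. These
sizes give stable statistics at interactive runtimes.

# Known limitations

* No kinship estimation: relative removal is an input list.
* No LD-aware thinning; no projection of new samples onto existing PCs;
  no subspace-decomposition variant of masked PCA.
* Viterbi text is consumed positionally: columns must follow sample
  order (copy 1 before copy 2), as no index file accompanies the
  format.
* Pair rates on autosomes treat either single parent as equivalent;
  sex-specific transmission only enters on X.
* The `0` code is reserved for missing calls in the Viterbi dialect,
  so ancestry codes must start at 1.
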