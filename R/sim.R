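# Synthetic admixed-genome simulator.
#
# Populations follow the Balding-Nichols construction: an ancestral allele
# frequency per site, continental frequencies drawn Beta around it with a
# drift parameter F_cont, and optional nested subpopulations drawn the
# same way around each continent with F_sub.  Admixed haplotypes are
# mosaics of ancestry tracts: switch points form a Poisson process of
# intensity g per Morgan along a genetic map, each tract's ancestry drawn
# independently from the admixture proportions pi.  Sites are independent
# given frequencies (no LD within populations).

#' Simulation configuration
#'
#' @param K Number of continental ancestries.
#' @param labels Ancestry names, length `K`.
#' @param F_cont Balding-Nichols drift parameter for continents vs the
#'   ancestral population, in (0, 1).
#' @param subpops Integer vector, length `K`: number of nested
#'   subpopulations per continent.  A continent with one subpopulation
#'   uses its continental frequencies directly.
#' @param F_sub Drift parameter for subpopulations around their continent.
#' @param pi Admixture proportions, length `K`, summing to 1.
#' @param g Generations since admixture: ancestry-switch intensity per
#'   Morgan along each haplotype.
#' @param M Number of sites.
#' @param map_length_morgans Total genetic map length.  The default map is
#'   uniform (genetic position proportional to site index).
#' @param n_ref Reference diploids simulated per continent.
#' @param n_admixed Number of admixed diploids.
#' @param n_trios Number of mother-father-child trios.
#' @param error_rate Ancestry-call corruption probability applied by
#'   [corrupt_calls()] when requested.
#' @param chrom Chromosome label written into the site map.
#' @param seed Integer seed; a fixed seed makes every simulated object
#'   reproducible.
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(K = 3, labels = DEFAULT_ANCESTRIES[seq_len(K)],
                       F_cont = 0.15, subpops = rep(1L, K), F_sub = 0.05,
                       pi = rep(1 / K, K), g = 8, M = 2000,
                       map_length_morgans = 3, n_ref = 30, n_admixed = 50,
                       n_trios = 0, error_rate = 0, chrom = "1",
                       seed = 1L) {
  if (length(labels) != K) stop("labels must have length K")
  if (length(pi) != K || abs(sum(pi) - 1) > 1e-9) {
    stop("pi must have length K and sum to 1")
  }
  if (F_cont <= 0 || F_cont >= 1 || F_sub <= 0 || F_sub >= 1) {
    stop("drift parameters must lie in (0, 1)")
  }
  if (g <= 0) stop("g must be positive")
  cfg <- list(K = as.integer(K), labels = labels, F_cont = F_cont,
              subpops = as.integer(rep_len(subpops, K)), F_sub = F_sub,
              pi = pi, g = g, M = as.integer(M),
              map_length_morgans = map_length_morgans,
              n_ref = as.integer(n_ref), n_admixed = as.integer(n_admixed),
              n_trios = as.integer(n_trios), error_rate = error_rate,
              chrom = as.character(chrom), seed = as.integer(seed))
  class(cfg) <- "sim_config"
  cfg
}

# Uniform genetic map: M sites evenly spaced over the map length.
sim_sites <- function(cfg) {
  cm <- seq(0, cfg$map_length_morgans * 100, length.out = cfg$M)
  site_map(chrom = rep(cfg$chrom, cfg$M),
           pos_bp = as.integer(round(seq(1e4, 1e4 + (cfg$M - 1) * 1e4,
                                         length.out = cfg$M))),
           site_id = paste0("s", seq_len(cfg$M)),
           pos_cm = cm)
}

# One Balding-Nichols draw of daughter frequencies around a parent vector.
bn_draw <- function(p, F) {
  a <- p * (1 - F) / F
  b <- (1 - p) * (1 - F) / F
  q <- rbeta(length(p), a, b)
  pmin(pmax(q, 1e-6), 1 - 1e-6)
}

#' Draw hierarchical allele frequencies
#'
#' Ancestral frequencies are Uniform(0.05, 0.95) per site; each continent
#' is a Balding-Nichols draw around the ancestral vector with `F_cont`;
#' each subpopulation is a draw around its continent with `F_sub`
#' (continents with a single subpopulation reuse the continental vector).
#'
#' @param cfg A [sim_config()].  The caller controls the RNG state;
#'   top-level simulators seed from `cfg$seed`.
#' @return List with `ancestral` (length M), `continent` (K x M matrix)
#'   and `subpop` (list of per-continent matrices, rows = subpopulations).
#' @export
draw_allele_frequencies <- function(cfg) {
  p0 <- runif(cfg$M, 0.05, 0.95)
  cont <- t(vapply(seq_len(cfg$K), function(k) bn_draw(p0, cfg$F_cont),
                   numeric(cfg$M)))
  sub <- lapply(seq_len(cfg$K), function(k) {
    ns <- cfg$subpops[k]
    if (ns == 1L) {
      matrix(cont[k, ], nrow = 1)
    } else {
      t(vapply(seq_len(ns), function(s) bn_draw(cont[k, ], cfg$F_sub),
               numeric(cfg$M)))
    }
  })
  list(ancestral = p0, continent = cont, subpop = sub)
}

# Per-site ancestry of one haplotype: Poisson switch points on the map,
# tract ancestries i.i.d. from pi.  Returns integer vector length M.
draw_tract_ancestry <- function(cfg, pos_cm) {
  L <- cfg$map_length_morgans
  n_switch <- rpois(1, cfg$g * L)
  breaks <- sort(runif(n_switch, 0, L)) * 100   # cM
  n_tracts <- n_switch + 1L
  anc <- sample.int(cfg$K, n_tracts, replace = TRUE, prob = cfg$pi)
  anc[findInterval(pos_cm, breaks) + 1L]
}

#' Simulate one admixed haplotype
#'
#' @param cfg A [sim_config()].
#' @param freqs Frequencies from [draw_allele_frequencies()].
#' @param sub_assign Integer vector length `K`: which subpopulation of each
#'   continent this individual's tracts of that ancestry come from.
#' @param pos_cm Genetic positions of the sites (centimorgans).
#' @return List with `alleles` (0/1, length M) and `ancestry` (1..K).
#' @export
simulate_admixed_haplotype <- function(cfg, freqs, sub_assign, pos_cm) {
  anc <- draw_tract_ancestry(cfg, pos_cm)
  p <- numeric(cfg$M)
  for (k in unique(anc)) {
    idx <- anc == k
    p[idx] <- freqs$subpop[[k]][sub_assign[k], idx]
  }
  list(alleles = rbinom(cfg$M, 1L, p), ancestry = anc)
}

# One unadmixed haplotype from a fixed frequency vector.
draw_pop_haplotype <- function(freq) rbinom(length(freq), 1L, freq)

# Meiosis: recombine the two haplotypes of a parent (alleles + ancestry),
# crossovers Poisson(rate 1 per Morgan), starting haplotype uniform.
meiose <- function(hapA, hapB, ancA, ancB, pos_cm, map_length) {
  n_x <- rpois(1, map_length)
  breaks <- sort(runif(n_x, 0, map_length)) * 100
  seg <- findInterval(pos_cm, breaks)                 # 0-based segment index
  from_a <- (seg + sample.int(2L, 1L)) %% 2L == 0L    # alternate parents
  list(alleles = ifelse(from_a, hapA, hapB),
       ancestry = ifelse(from_a, ancA, ancB))
}

#' Simulate a full autosomal cohort
#'
#' Generates (i) a reference panel of `n_ref` unadmixed diploids per
#' continent, (ii) `n_admixed` admixed diploids with known tract-level
#' ancestry, and (iii) `n_trios` mother-father-child trios in which child
#' haplotypes are formed by meiosis, copying alleles and true ancestry
#' labels jointly so that the truth is Mendelian-consistent by
#' construction.
#'
#' @param cfg A [sim_config()]; the RNG is seeded from `cfg$seed`.
#' @return List with elements `panel` ([hap_panel()]), `truth`
#'   ([la_calls()] of true tract ancestries), `ped` (pedigree
#'   data frame), `subpop_of` (per admixed sample, its subpopulation of
#'   origin in each continent), `freqs` and `config`.
#' @export
simulate_cohort <- function(cfg) {
  set.seed(cfg$seed)
  sites <- sim_sites(cfg)
  freqs <- draw_allele_frequencies(cfg)
  pos_cm <- sites$pos_cm

  alleles <- list(); calls <- list()
  sample_id <- character(); copy <- integer()
  sex <- character(); group <- character()

  add_hap <- function(id, cp, sx, grp, al, an) {
    alleles[[length(alleles) + 1L]] <<- al
    calls[[length(calls) + 1L]] <<- an
    sample_id <<- c(sample_id, id); copy <<- c(copy, cp)
    sex <<- c(sex, sx); group <<- c(group, grp)
  }

  # reference diploids, unadmixed, drawn from continental frequencies
  for (k in seq_len(cfg$K)) {
    for (i in seq_len(cfg$n_ref)) {
      id <- sprintf("ref_%s_%03d", cfg$labels[k], i)
      sx <- if (i %% 2L == 0L) "female" else "male"
      for (cp in 1:2) {
        add_hap(id, cp, sx, cfg$labels[k],
                draw_pop_haplotype(freqs$continent[k, ]),
                rep(k, cfg$M))
      }
    }
  }

  # admixed diploids with per-continent subpopulation assignment
  subpop_of <- matrix(1L, nrow = 0, ncol = cfg$K)
  adm_ids <- character()
  sim_admixed_diploid <- function(id, sx) {
    sa <- vapply(cfg$subpops, function(ns) sample.int(ns, 1L), integer(1))
    subpop_of <<- rbind(subpop_of, sa)
    adm_ids <<- c(adm_ids, id)
    for (cp in 1:2) {
      h <- simulate_admixed_haplotype(cfg, freqs, sa, pos_cm)
      add_hap(id, cp, sx, "admixed", h$alleles, h$ancestry)
    }
  }
  for (i in seq_len(cfg$n_admixed)) {
    sim_admixed_diploid(sprintf("adm_%04d", i),
                        if (i %% 2L == 0L) "female" else "male")
  }

  # trios: parents admixed, child via meiosis of alleles + ancestry
  ped <- data.frame(child = character(), mother = character(),
                    father = character(), sex = character(),
                    stringsAsFactors = FALSE)
  for (t in seq_len(cfg$n_trios)) {
    mo <- sprintf("trio%03d_mo", t); fa <- sprintf("trio%03d_fa", t)
    ch <- sprintf("trio%03d_ch", t)
    sim_admixed_diploid(mo, "female")
    sim_admixed_diploid(fa, "male")
    n <- length(alleles)
    gm <- meiose(alleles[[n - 3L]], alleles[[n - 2L]],
                 calls[[n - 3L]], calls[[n - 2L]],
                 pos_cm, cfg$map_length_morgans)
    gf <- meiose(alleles[[n - 1L]], alleles[[n]],
                 calls[[n - 1L]], calls[[n]],
                 pos_cm, cfg$map_length_morgans)
    ch_sex <- if (t %% 2L == 0L) "female" else "male"
    add_hap(ch, 1L, ch_sex, "admixed", gm$alleles, gm$ancestry)
    add_hap(ch, 2L, ch_sex, "admixed", gf$alleles, gf$ancestry)
    ped <- rbind(ped, data.frame(child = ch, mother = mo, father = fa,
                                 sex = ch_sex, stringsAsFactors = FALSE))
  }

  meta <- hap_meta(sample_id, copy, sex, group)
  panel <- hap_panel(do.call(rbind, alleles), meta, sites)
  truth <- la_calls(do.call(rbind, calls), cfg$labels, meta, sites)
  if (length(adm_ids)) rownames(subpop_of) <- adm_ids
  colnames(subpop_of) <- cfg$labels
  list(panel = panel, truth = truth, ped = classify_pedigree(ped),
       subpop_of = subpop_of, freqs = freqs, config = cfg)
}

#' Simulate an X-chromosome cohort of trios
#'
#' Mothers and daughters are diploid on X; fathers and sons are haploid.
#' A son receives one maternal recombinant X; a daughter receives the
#' paternal X unchanged plus one maternal recombinant.  True ancestry
#' labels travel with the alleles, so the truth is consistent under the
#' X-specific transmission rules.
#'
#' @param cfg A [sim_config()] (`n_trios` families; `chrom` is forced to
#'   `"X"`).
#' @return List with `panel`, `truth`, `ped`, `freqs`, `config` as in
#'   [simulate_cohort()].  Haploid individuals carry a single row.
#' @export
simulate_x_cohort <- function(cfg) {
  cfg$chrom <- "X"
  set.seed(cfg$seed + 1L)  # distinct stream from the autosomal cohort
  sites <- sim_sites(cfg)
  freqs <- draw_allele_frequencies(cfg)
  pos_cm <- sites$pos_cm

  alleles <- list(); calls <- list()
  sample_id <- character(); copy <- integer()
  sex <- character(); group <- character()
  add_hap <- function(id, cp, sx, grp, al, an) {
    alleles[[length(alleles) + 1L]] <<- al
    calls[[length(calls) + 1L]] <<- an
    sample_id <<- c(sample_id, id); copy <<- c(copy, cp)
    sex <<- c(sex, sx); group <<- c(group, grp)
  }
  new_hap <- function() {
    sa <- vapply(cfg$subpops, function(ns) sample.int(ns, 1L), integer(1))
    simulate_admixed_haplotype(cfg, freqs, sa, pos_cm)
  }
  ped <- data.frame(child = character(), mother = character(),
                    father = character(), sex = character(),
                    stringsAsFactors = FALSE)
  for (t in seq_len(cfg$n_trios)) {
    mo <- sprintf("xtrio%03d_mo", t); fa <- sprintf("xtrio%03d_fa", t)
    ch <- sprintf("xtrio%03d_ch", t)
    m1 <- new_hap(); m2 <- new_hap(); fx <- new_hap()
    add_hap(mo, 1L, "female", "admixed", m1$alleles, m1$ancestry)
    add_hap(mo, 2L, "female", "admixed", m2$alleles, m2$ancestry)
    add_hap(fa, 1L, "male", "admixed", fx$alleles, fx$ancestry)
    mat <- meiose(m1$alleles, m2$alleles, m1$ancestry, m2$ancestry,
                  pos_cm, cfg$map_length_morgans)
    ch_sex <- if (t %% 2L == 0L) "female" else "male"
    if (ch_sex == "male") {
      add_hap(ch, 1L, "male", "admixed", mat$alleles, mat$ancestry)
    } else {
      add_hap(ch, 1L, "female", "admixed", fx$alleles, fx$ancestry)
      add_hap(ch, 2L, "female", "admixed", mat$alleles, mat$ancestry)
    }
    ped <- rbind(ped, data.frame(child = ch, mother = mo, father = fa,
                                 sex = ch_sex, stringsAsFactors = FALSE))
  }
  meta <- hap_meta(sample_id, copy, sex, group)
  panel <- hap_panel(do.call(rbind, alleles), meta, sites)
  truth <- la_calls(do.call(rbind, calls), cfg$labels, meta, sites)
  list(panel = panel, truth = truth, ped = classify_pedigree(ped),
       freqs = freqs, config = cfg)
}

#' Randomly corrupt ancestry calls
#'
#' Each non-missing call is independently replaced, with probability
#' `epsilon`, by a uniformly chosen *different* ancestry code.  Used to
#' study how Mendelian-inconsistency rates respond to call error.
#'
#' @param calls An [la_calls()] object.
#' @param epsilon Per-cell corruption probability in `[0, 1]`.
#' @param seed Optional integer seed.
#' @return A new `la_calls` with corrupted entries.
#' @export
corrupt_calls <- function(calls, epsilon, seed = NULL) {
  if (epsilon < 0 || epsilon > 1) stop("epsilon must be in [0, 1]")
  if (!is.null(seed)) set.seed(seed)
  cm <- calls$calls
  K <- length(calls$labels)
  if (epsilon > 0) {
    flip <- !is.na(cm) & matrix(runif(length(cm)) < epsilon,
                                nrow(cm), ncol(cm))
    n <- sum(flip)
    if (n > 0) {
      # add a nonzero offset mod K: guaranteed different code
      off <- sample.int(K - 1L, n, replace = TRUE)
      cm[flip] <- ((cm[flip] - 1L + off) %% K) + 1L
    }
  }
  la_calls(cm, calls$labels, calls$meta, calls$sites)
}
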