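# Operations on local ancestry calls: masking, global proportions,
# inclusion filters, marker thinning, reference-panel filtering, site
# intersection, call-set concordance and posterior summaries.

#' Mask alleles by called ancestry
#'
#' Sets to missing every allele whose haplotype is not called as the
#' target ancestry at that position, leaving only the genomic material
#' attributed to one ancestral component.  Alleles that are already
#' missing stay missing.
#'
#' @param panel A [hap_panel()].
#' @param calls A dimension-aligned [la_calls()].
#' @param target Ancestry name (one of `calls$labels`).
#' @return A new [hap_panel()] with non-target alleles set to `NA`.
#' @export
mask_by_ancestry <- function(panel, calls, target) {
  code <- match(target, calls$labels)
  if (is.na(code)) {
    stop("unknown ancestry '", target, "'; expected one of: ",
         paste(calls$labels, collapse = ", "))
  }
  if (!all(dim(panel$alleles) == dim(calls$calls))) {
    stop("panel and calls dimensions differ")
  }
  a <- panel$alleles
  a[is.na(calls$calls) | calls$calls != code] <- NA_integer_
  hap_panel(a, panel$meta, panel$sites)
}

#' Global ancestry proportions from local calls
#'
#' For each sample, the proportion of each ancestry among the non-missing
#' (haplotype, site) cells of its haplotypes — the genome-wide average
#' ancestry implied by the local calls.
#'
#' @param calls An [la_calls()] with haplotype metadata.
#' @return A `data.frame` with `sample_id`, one proportion column per
#'   ancestry label, `n_obs` (non-missing cells) and `defined` (FALSE for
#'   samples whose cells are all missing; their proportions are `NA`).
#' @export
global_proportions <- function(calls) {
  if (is.null(calls$meta)) stop("calls carry no haplotype metadata")
  K <- length(calls$labels)
  by_sample <- rows_by_sample(calls$meta)
  res <- t(vapply(by_sample, function(r) {
    x <- calls$calls[r, , drop = FALSE]
    x <- x[!is.na(x)]
    n <- length(x)
    if (n == 0L) return(c(rep(NA_real_, K), 0))
    c(tabulate(x, K) / n, n)
  }, numeric(K + 1)))
  out <- data.frame(sample_id = names(by_sample), res,
                    stringsAsFactors = FALSE, row.names = NULL)
  names(out) <- c("sample_id", calls$labels, "n_obs")
  out$n_obs <- as.integer(out$n_obs)
  out$defined <- out$n_obs > 0L
  out
}

#' Select samples by minimum ancestry proportion
#'
#' Retains samples whose proportion of the target ancestry is at least
#' the threshold (inclusive), the standard inclusion rule for
#' ancestry-specific analyses: individuals with little target ancestry
#' retain too few alleles after masking to place reliably.
#'
#' @param props Output of [global_proportions()].
#' @param target Ancestry name (a column of `props`).
#' @param threshold Minimum proportion, default 0.5.
#' @return Character vector of retained sample ids.
#' @export
filter_by_ancestry_threshold <- function(props, target, threshold = 0.5) {
  if (!target %in% names(props)) stop("no proportion column '", target, "'")
  p <- props[[target]]
  props$sample_id[!is.na(p) & p >= threshold]
}

#' Deterministic site indices for marker thinning
#'
#' Allocates the target count to chromosomes proportionally to their site
#' counts (largest-remainder rounding), then picks evenly spaced site
#' indices within each chromosome.
#'
#' @param sites A [site_map()].
#' @param n_target Total number of sites to retain.
#' @return Sorted integer vector of column indices into the site map.
#' @export
thin_indices <- function(sites, n_target = 10000) {
  M <- nrow(sites)
  if (n_target <= 0) stop("n_target must be positive")
  if (n_target > M) stop("n_target (", n_target, ") exceeds site count (",
                         M, ")")
  if (n_target == M) return(seq_len(M))
  chroms <- unique(sites$chrom)
  n_c <- vapply(chroms, function(cc) sum(sites$chrom == cc), integer(1))
  quota <- n_target * n_c / M
  alloc <- floor(quota)
  rem <- n_target - sum(alloc)
  if (rem > 0) {
    frac <- quota - alloc
    room <- n_c - alloc
    # award remainders largest-first, never exceeding a chromosome's sites
    ord <- order(frac, n_c, decreasing = TRUE)
    for (i in ord) {
      if (rem == 0L) break
      add <- min(1L, room[i], rem)
      alloc[i] <- alloc[i] + add
      rem <- rem - add
    }
  }
  idx <- integer(0)
  for (i in seq_along(chroms)) {
    if (alloc[i] == 0L) next
    where <- which(sites$chrom == chroms[i])
    pick <- unique(round(seq(1, n_c[i], length.out = alloc[i])))
    idx <- c(idx, where[pick])
  }
  sort(idx)
}

#' Thin a panel to a target number of markers
#'
#' @param panel A [hap_panel()].
#' @param n_target Number of sites to retain (default 10,000, the usual
#'   scale for interhaplotype distance work on autosomes).
#' @return The thinned [hap_panel()].
#' @seealso [thin_indices()] to apply the identical thinning to a paired
#'   call set.
#' @export
thin_markers <- function(panel, n_target = 10000) {
  subset_panel(panel, cols = thin_indices(panel$sites, n_target))
}

#' Filter reference individuals by modeled ancestry fraction
#'
#' Given a Q-matrix of per-individual ancestry fractions over J clusters
#' (e.g. from an unsupervised ADMIXTURE run), retains individuals whose
#' largest non-excluded cluster fraction is at least `min_fraction` and
#' whose overall best cluster is not excluded, and assigns each retained
#' individual to that cluster.
#'
#' @param q Numeric matrix (individuals x clusters) with rows summing to
#'   1; row names are individual ids, column names cluster labels.
#' @param min_fraction Minimum ancestry fraction, default 0.9
#'   (inclusive).
#' @param exclude Character vector of cluster labels to exclude (e.g. an
#'   out-of-model continent).
#' @return `data.frame` with `individual` and assigned `cluster`.
#' @export
filter_reference_panel <- function(q, min_fraction = 0.9,
                                   exclude = character()) {
  q <- as.matrix(q)
  if (is.null(colnames(q))) colnames(q) <- paste0("K", seq_len(ncol(q)))
  if (is.null(rownames(q))) rownames(q) <- paste0("ind", seq_len(nrow(q)))
  if (any(abs(rowSums(q) - 1) > 1e-6)) stop("Q-matrix rows must sum to 1")
  keep_cl <- setdiff(colnames(q), exclude)
  if (!length(keep_cl)) stop("exclusion covers every cluster")
  sub <- q[, keep_cl, drop = FALSE]
  best <- max.col(sub, ties.method = "first")
  best_frac <- sub[cbind(seq_len(nrow(sub)), best)]
  best_overall <- colnames(q)[max.col(q, ties.method = "first")]
  ok <- best_frac >= min_fraction & !(best_overall %in% exclude)
  data.frame(individual = rownames(q)[ok],
             cluster = keep_cl[best[ok]],
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Intersect two site maps on (chromosome, position)
#'
#' @param a,b [site_map()] objects, each without duplicate positions.
#' @return List with integer vectors `idx_a`, `idx_b` (order-preserving
#'   indices into each map) such that `a[idx_a, ]` and `b[idx_b, ]` are
#'   the shared sites.
#' @export
intersect_sites <- function(a, b) {
  key_a <- paste(a$chrom, a$pos_bp)
  key_b <- paste(b$chrom, b$pos_bp)
  if (anyDuplicated(key_a)) stop("duplicate positions in first site map")
  if (anyDuplicated(key_b)) stop("duplicate positions in second site map")
  idx_b <- match(key_a, key_b)
  idx_a <- which(!is.na(idx_b))
  list(idx_a = idx_a, idx_b = idx_b[idx_a])
}

#' Match two unordered diploid ancestry calls
#'
#' Two call sets phase haplotypes arbitrarily, so per-site diploid calls
#' are compared as unordered pairs: of the two ways to align the
#' haplotypes of `a` with those of `b`, the one with maximal agreement is
#' used (ties broken toward the identity alignment).
#'
#' @param a,b Length-2 integer vectors of ancestry codes.
#' @return List with `agreement` (0, 1 or 2), `alignment` (`c(1, 2)` for
#'   identity or `c(2, 1)` for the swap, indexing `b`), and `pairs`
#'   (2 x 2 matrix of matched `(code_a, code_b)` rows).
#' @export
match_diploid_calls <- function(a, b) {
  ident <- sum(a == b)
  swap <- (a[1] == b[2]) + (a[2] == b[1])
  if (swap > ident) {
    list(agreement = swap, alignment = c(2L, 1L),
         pairs = rbind(c(a[1], b[2]), c(a[2], b[1])))
  } else {
    list(agreement = ident, alignment = c(1L, 2L),
         pairs = rbind(c(a[1], b[1]), c(a[2], b[2])))
  }
}

#' Concordance between two local ancestry call sets
#'
#' For every (sample, site) the two unordered diploid calls are aligned
#' by [match_diploid_calls()] and the matched haplotype-level label pairs
#' are accumulated into a K x K proportion table; the overall agreement
#' is the diagonal sum.  Cells with any missing call are excluded.
#'
#' @param calls_a,calls_b [la_calls()] over the same samples, sites and
#'   ancestry alphabet.
#' @return List of class `concordance`: `table` (K x K proportions, rows
#'   = first call set), `agreement` (diagonal sum), `n_cells` (matched
#'   haplotype pairs counted).
#' @export
concordance_table <- function(calls_a, calls_b) {
  if (!all(dim(calls_a$calls) == dim(calls_b$calls))) {
    stop("call sets have different dimensions")
  }
  if (!identical(calls_a$labels, calls_b$labels)) {
    stop("call sets use different ancestry alphabets")
  }
  K <- length(calls_a$labels)
  meta <- calls_a$meta
  if (is.null(meta)) stop("calls carry no haplotype metadata")
  counts <- matrix(0, K, K)
  for (r in rows_by_sample(meta)) {
    if (length(r) != 2L) next   # diploid matching only
    a1 <- calls_a$calls[r[1], ]; a2 <- calls_a$calls[r[2], ]
    b1 <- calls_b$calls[r[1], ]; b2 <- calls_b$calls[r[2], ]
    ok <- !(is.na(a1) | is.na(a2) | is.na(b1) | is.na(b2))
    if (!any(ok)) next
    a1 <- a1[ok]; a2 <- a2[ok]; b1 <- b1[ok]; b2 <- b2[ok]
    use_swap <- ((a1 == b2) + (a2 == b1)) > ((a1 == b1) + (a2 == b2))
    m1 <- ifelse(use_swap, b2, b1)
    m2 <- ifelse(use_swap, b1, b2)
    counts <- counts +
      matrix(tabulate(a1 + K * (m1 - 1L), K * K), K, K) +
      matrix(tabulate(a2 + K * (m2 - 1L), K * K), K, K)
  }
  n <- sum(counts)
  if (n == 0) stop("no comparable cells between the call sets")
  tab <- counts / n
  dimnames(tab) <- list(calls_a$labels, calls_b$labels)
  structure(list(table = tab, agreement = sum(diag(tab)),
                 n_cells = n), class = "concordance")
}

#' @export
print.concordance <- function(x, ...) {
  cat("Call-set concordance over", x$n_cells, "haplotype cells\n")
  print(round(x$table, 4))
  cat("overall agreement:", formatC(x$agreement, digits = 4,
                                    format = "f"), "\n")
  invisible(x)
}

#' Average highest posterior probability per call
#'
#' For each haplotype at each position, the maximum posterior probability
#' and its ancestry are recorded; means of these maxima are reported per
#' winning ancestry and overall.  Ties in the argmax are broken toward
#' the lowest ancestry index and their count reported in a message.
#'
#' @param post An [la_posterior()].
#' @return `data.frame` with rows for each ancestry label plus
#'   `"overall"`: columns `ancestry`, `mean_max_posterior`, `n_cells`.
#' @export
avg_max_posterior <- function(post) {
  d <- dim(post$probs)
  if (any(d == 0)) stop("empty posterior array")
  K <- d[3]
  flat <- matrix(post$probs, nrow = d[1] * d[2], ncol = K)
  win <- max.col(flat, ties.method = "first")
  mx <- flat[cbind(seq_len(nrow(flat)), win)]
  n_tie <- sum(rowSums(flat == mx) > 1L)
  if (n_tie > 0) {
    message("avg_max_posterior: ", n_tie,
            " tie(s) broken toward the lowest ancestry index")
  }
  by_lab <- vapply(seq_len(K), function(k) {
    i <- win == k
    c(if (any(i)) mean(mx[i]) else NA_real_, sum(i))
  }, numeric(2))
  data.frame(ancestry = c(post$labels, "overall"),
             mean_max_posterior = c(by_lab[1, ], mean(mx)),
             n_cells = as.integer(c(by_lab[2, ], length(mx))),
             stringsAsFactors = FALSE)
}
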