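# Ancestry-specific PCA via masked-haplotype multidimensional scaling.
#
# Masking sets non-target alleles to missing, so distances must handle
# heavy, structured missingness.  Only positions where both haplotypes
# are non-missing enter a pair's distance; the summed squared difference
# is scaled up by M / n_shared (pairwise-deletion proportional scaling,
# the convention of R's dist()).  Pairs with no shared site get the mean
# of all defined distances, computed once.  Classical (Torgerson) MDS of
# the resulting matrix yields PCs; with complete data this is exactly
# PCA of the centred allele matrix.

#' Pairwise haplotype distances under missing data
#'
#' Euclidean distance over 0/1 alleles with pairwise deletion: for
#' haplotypes `x`, `y` sharing `s > 0` non-missing sites,
#' `d = sqrt((M / s) * sum((x - y)^2))` over the shared sites (or
#' `sqrt(sum)` with `scaled = FALSE`).  Pairs sharing no site are set,
#' after all defined pairs are computed, to the mean of the defined
#' off-diagonal distances (single pass, no iteration) and flagged.
#'
#' @param panel A [hap_panel()]; rows are haplotypes.
#' @param scaled Use the proportional `M / s` up-scaling (default TRUE).
#' @return Object of class `hap_dist`: `d` (symmetric H x H matrix, zero
#'   diagonal), `imputed` (logical matrix marking zero-overlap pairs),
#'   `n_shared` (integer matrix of shared non-missing site counts).
#' @export
pairwise_distance <- function(panel, scaled = TRUE) {
  X <- panel$alleles
  H <- nrow(X); M <- ncol(X)
  if (M < 1) stop("panel has no sites")
  W <- !is.na(X)
  storage.mode(W) <- "double"
  X0 <- X
  X0[is.na(X0)] <- 0L
  storage.mode(X0) <- "double"
  # alleles are 0/1 so x^2 = x; sum over shared sites of x^2 is X0 W^T
  XW <- X0 %*% t(W)
  D2 <- XW + t(XW) - 2 * (X0 %*% t(X0))
  D2[D2 < 0] <- 0          # numerical guard
  S <- W %*% t(W)
  diag(D2) <- 0
  defined <- S > 0
  d <- matrix(0, H, H)
  if (scaled) {
    d[defined] <- sqrt(D2[defined] * (M / S[defined]))
  } else {
    d[defined] <- sqrt(D2[defined])
  }
  imputed <- !defined
  diag(imputed) <- FALSE
  off_defined <- defined & upper.tri(defined)
  if (!any(off_defined) && H > 1) stop("panel too sparse: no haplotype pair shares a non-missing site")
  if (any(imputed)) {
    d[imputed] <- mean(d[upper.tri(d)][off_defined[upper.tri(off_defined)]])
  }
  diag(d) <- 0
  rownames(d) <- colnames(d) <- rownames(X)
  structure(list(d = d, imputed = imputed,
                 n_shared = matrix(as.integer(S), H, H),
                 scaled = scaled, M = M),
            class = "hap_dist")
}

#' @export
print.hap_dist <- function(x, ...) {
  cat("hap_dist:", nrow(x$d), "haplotypes;",
      sum(x$imputed) / 2, "zero-overlap pair(s) mean-imputed;",
      if (x$scaled) "proportionally scaled" else "unscaled", "\n")
  invisible(x)
}

#' Classical (Torgerson) multidimensional scaling
#'
#' Double-centres the squared distance matrix, `B = -1/2 J D^2 J`,
#' eigendecomposes `B`, and returns coordinates `v_j * sqrt(lambda_j)`
#' for the top `k` positive eigenvalues.  If fewer than `k` eigenvalues
#' are positive the remaining columns are zero.  For determinism across
#' linear-algebra backends, each column's largest-magnitude entry is made
#' positive.
#'
#' @param D A `hap_dist` from [pairwise_distance()] or a symmetric
#'   distance matrix.
#' @param k Number of components.
#' @return Object of class `mds_pc`: `coords` (H x k), `eigenvalues`
#'   (the k leading eigenvalues, descending), `n_positive` (number of
#'   positive eigenvalues of `B`).
#' @export
classical_mds <- function(D, k = 4) {
  if (k <= 0) stop("k must be positive")
  dm <- if (inherits(D, "hap_dist")) D$d else as.matrix(D)
  H <- nrow(dm)
  if (H < k + 1) stop("need at least k + 1 = ", k + 1, " haplotypes")
  D2 <- dm^2
  rm <- rowMeans(D2); gm <- mean(D2)
  B <- -0.5 * (sweep(sweep(D2, 1, rm), 2, rm) + gm)
  e <- eigen(B, symmetric = TRUE)
  tol <- max(abs(e$values)) * 1e-9
  n_pos <- sum(e$values > tol)
  coords <- matrix(0, H, k)
  use <- seq_len(min(k, n_pos))
  for (j in use) {
    v <- e$vectors[, j] * sqrt(e$values[j])
    if (v[which.max(abs(v))] < 0) v <- -v
    coords[, j] <- v
  }
  colnames(coords) <- paste0("PC", seq_len(k))
  rownames(coords) <- rownames(dm)
  structure(list(coords = coords,
                 eigenvalues = e$values[seq_len(k)],
                 n_positive = n_pos),
            class = "mds_pc")
}

#' @export
print.mds_pc <- function(x, ...) {
  cat("mds_pc:", nrow(x$coords), "rows x", ncol(x$coords),
      "components; leading eigenvalues:",
      paste(signif(x$eigenvalues, 4), collapse = ", "), "\n")
  invisible(x)
}

#' Ancestry-specific PCA of masked haplotypes
#'
#' End-to-end driver: drop excluded samples, keep samples with at least
#' `threshold` global target ancestry, thin markers to `n_sites`, mask
#' non-target alleles, optionally append unmasked reference haplotypes,
#' compute pairwise-deletion distances and classical MDS.  Both
#' haplotypes of each retained sample enter as separate rows, since the
#' masking pattern is haplotype-level.
#'
#' @param panel A [hap_panel()] of admixed samples.
#' @param calls The aligned [la_calls()].
#' @param target Ancestry to analyse.
#' @param threshold Minimum global target-ancestry proportion (default
#'   0.5).
#' @param n_sites Marker count after thinning (default 10,000; capped at
#'   the available site count).
#' @param exclude Character vector of sample ids to drop first (e.g. an
#'   externally computed list of close relatives).
#' @param k Number of components (default 4).
#' @param ref_panel Optional [hap_panel()] of reference haplotypes on the
#'   same site map; they pass through unmasked alongside the masked
#'   admixed haplotypes.
#' @param scaled Distance scaling flag, see [pairwise_distance()].
#' @return Object of class `aspca`: `pc` (an `mds_pc`), `meta`
#'   (haplotype metadata of the analysed rows, with `role` =
#'   `"admixed"`/`"reference"`), `dist` (the `hap_dist`), `target`,
#'   `n_sites_used`, `retained_samples`.
#' @export
ancestry_specific_pca <- function(panel, calls, target, threshold = 0.5,
                                  n_sites = 10000, exclude = NULL, k = 4,
                                  ref_panel = NULL, scaled = TRUE) {
  if (!all(dim(panel$alleles) == dim(calls$calls))) {
    stop("panel and calls dimensions differ")
  }
  if (!is.null(exclude) && length(exclude)) {
    keep_rows <- !(panel$meta$sample_id %in% exclude)
    panel <- subset_panel(panel, rows = keep_rows)
    calls <- subset_calls(calls, rows = keep_rows)
  }
  props <- global_proportions(calls)
  retained <- filter_by_ancestry_threshold(props, target, threshold)
  if (!length(retained)) {
    stop("no samples reach ", threshold, " ", target, " ancestry")
  }
  rows <- panel$meta$sample_id %in% retained
  panel <- subset_panel(panel, rows = rows)
  calls <- subset_calls(calls, rows = rows)

  n_sites <- min(n_sites, ncol(panel$alleles))
  idx <- thin_indices(panel$sites, n_sites)
  panel <- subset_panel(panel, cols = idx)
  calls <- subset_calls(calls, cols = idx)

  masked <- mask_by_ancestry(panel, calls, target)
  meta <- masked$meta
  meta$role <- "admixed"
  alleles <- masked$alleles
  if (!is.null(ref_panel)) {
    if (ncol(ref_panel$alleles) == ncol(panel$alleles)) {
      ref_idx <- seq_len(ncol(ref_panel$alleles))
    } else {
      ref_idx <- idx
    }
    ra <- ref_panel$alleles[, ref_idx, drop = FALSE]
    if (ncol(ra) != ncol(alleles)) {
      stop("reference panel is not on the same site map")
    }
    rmeta <- ref_panel$meta
    rmeta$role <- "reference"
    alleles <- rbind(alleles, ra)
    meta <- rbind(meta, rmeta)
  }
  if (nrow(alleles) < k + 1) {
    stop("only ", nrow(alleles), " haplotypes retained; need k + 1 = ",
         k + 1)
  }
  combined <- hap_panel(alleles,
                        hap_meta(meta$sample_id, meta$copy, meta$sex,
                                 meta$group),
                        masked$sites)
  D <- pairwise_distance(combined, scaled = scaled)
  pc <- classical_mds(D, k)
  structure(list(pc = pc, meta = meta, dist = D, target = target,
                 n_sites_used = length(idx),
                 retained_samples = retained),
            class = "aspca")
}

#' @export
print.aspca <- function(x, ...) {
  cat("Ancestry-specific PCA (", x$target, "): ",
      nrow(x$pc$coords), " haplotypes from ",
      length(x$retained_samples), " retained samples, ",
      x$n_sites_used, " sites\n", sep = "")
  invisible(x)
}

#' Coordinates of an ancestry-specific PCA as a table
#'
#' @param x An `aspca` object.
#' @return `data.frame` with `haplotype_id`, `sample_id`, `copy`, `role`
#'   and one column per component.
#' @export
aspca_coords <- function(x) {
  data.frame(haplotype_id = paste(x$meta$sample_id, x$meta$copy,
                                  sep = "."),
             sample_id = x$meta$sample_id,
             copy = x$meta$copy,
             role = x$meta$role,
             x$pc$coords,
             stringsAsFactors = FALSE, row.names = NULL)
}
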