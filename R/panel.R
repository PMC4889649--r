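# Core containers: haplotype panels, local ancestry call sets, posterior
# arrays, site maps.  All are light S3 wrappers around base matrices and
# data frames; missing alleles and missing ancestry calls are NA.

#' Construct a site map
#'
#' A site map annotates the M columns of a haplotype panel or call matrix
#' with genomic coordinates.  Positions are 1-based base pairs, following
#' VCF convention; genetic positions, when absent, default to a uniform
#' map (proportional to site index) when needed by the simulator.
#'
#' @param chrom Character or integer vector of chromosome labels.
#' @param pos_bp Integer vector of 1-based physical positions, strictly
#'   increasing within each chromosome.
#' @param site_id Optional character vector of site identifiers; defaults
#'   to `"chrom:pos"`.
#' @param pos_cm Optional numeric vector of genetic positions in
#'   centimorgans.
#' @return A `data.frame` of class `site_map` with columns `chrom`,
#'   `pos_bp`, `site_id` and optionally `pos_cm`.
#' @export
site_map <- function(chrom, pos_bp, site_id = NULL, pos_cm = NULL) {
  chrom <- as.character(chrom)
  pos_bp <- as.integer(pos_bp)
  if (length(chrom) != length(pos_bp)) {
    stop("chrom and pos_bp must have equal length")
  }
  if (is.null(site_id)) site_id <- paste0(chrom, ":", pos_bp)
  sm <- data.frame(chrom = chrom, pos_bp = pos_bp,
                   site_id = as.character(site_id),
                   stringsAsFactors = FALSE)
  if (!is.null(pos_cm)) sm$pos_cm <- as.numeric(pos_cm)
  for (cc in unique(chrom)) {
    p <- sm$pos_bp[sm$chrom == cc]
    if (any(diff(p) <= 0)) {
      stop("positions must be strictly increasing within chromosome ", cc)
    }
  }
  class(sm) <- c("site_map", "data.frame")
  sm
}

#' Construct per-haplotype metadata
#'
#' @param sample_id Character vector, one entry per haplotype row.
#' @param copy Integer vector in `{1, 2}`; haploid samples (male X) carry a
#'   single row with copy 1.
#' @param sex Character vector in `{"male", "female", "unknown"}`.
#' @param group Optional character grouping label (e.g. reference
#'   population or `"admixed"`).
#' @return A `data.frame` with one row per haplotype.
#' @export
hap_meta <- function(sample_id, copy, sex = "unknown", group = NA_character_) {
  n <- length(sample_id)
  data.frame(sample_id = as.character(sample_id),
             copy = as.integer(copy),
             sex = rep_len(as.character(sex), n),
             group = rep_len(as.character(group), n),
             stringsAsFactors = FALSE)
}

#' Construct a haplotype panel
#'
#' A haplotype panel holds an H x M matrix of alleles coded 0/1 with `NA`
#' for missing, per-haplotype metadata (sample, copy, sex, group) and a
#' site map.  Each diploid sample contributes exactly two consecutive
#' rows; a haploid male X sample contributes one.
#'
#' @param alleles Integer (or numeric) H x M matrix over `{0, 1, NA}`.
#' @param meta Haplotype metadata as built by [hap_meta()].
#' @param sites A [site_map()] with M rows.
#' @return An object of class `hap_panel`.
#' @export
hap_panel <- function(alleles, meta, sites) {
  alleles <- as.matrix(alleles)
  storage.mode(alleles) <- "integer"
  if (nrow(alleles) != nrow(meta)) {
    stop("alleles has ", nrow(alleles), " rows but meta describes ",
         nrow(meta), " haplotypes")
  }
  if (ncol(alleles) != nrow(sites)) {
    stop("alleles has ", ncol(alleles), " sites but site map has ",
         nrow(sites))
  }
  bad <- alleles[!is.na(alleles)]
  if (length(bad) && !all(bad %in% c(0L, 1L))) {
    stop("alleles must be 0, 1 or NA")
  }
  check_copy_structure(meta)
  rownames(alleles) <- hap_ids(meta)
  obj <- list(alleles = alleles, meta = meta, sites = sites)
  class(obj) <- "hap_panel"
  obj
}

# Each sample must contribute rows (copy 1[, copy 2]) consecutively.
check_copy_structure <- function(meta) {
  r <- rle(meta$sample_id)
  if (any(r$lengths > 2)) {
    stop("sample ", r$values[which(r$lengths > 2)[1]],
         " contributes more than two haplotype rows")
  }
  if (anyDuplicated(r$values)) {
    stop("haplotype rows of sample ",
         r$values[duplicated(r$values)][1], " are not consecutive")
  }
  idx <- 1L
  for (i in seq_along(r$values)) {
    cp <- meta$copy[idx:(idx + r$lengths[i] - 1L)]
    if (!identical(as.integer(cp), seq_len(r$lengths[i]))) {
      stop("sample ", r$values[i], " has copy labels (",
           paste(cp, collapse = ","), "); expected 1",
           if (r$lengths[i] == 2L) ",2" else "")
    }
    idx <- idx + r$lengths[i]
  }
  invisible(TRUE)
}

#' Haplotype row identifiers
#'
#' @param x A `hap_panel`, `la_calls` or haplotype metadata data frame.
#' @return Character vector `"<sample_id>.<copy>"`, one per haplotype row.
#' @export
hap_ids <- function(x) {
  m <- if (is.data.frame(x)) x else x$meta
  paste(m$sample_id, m$copy, sep = ".")
}

#' Samples represented in a panel or call set
#' @param x A `hap_panel` or `la_calls`.
#' @return Character vector of unique sample ids, in row order.
#' @export
panel_samples <- function(x) unique(x$meta$sample_id)

#' Construct a local ancestry call set
#'
#' Holds an H x M matrix of integer ancestry codes in `1..K` (with `NA`
#' for missing calls), the ordered ancestry labels, and the same
#' haplotype metadata / site map as a companion [hap_panel()].
#'
#' @param calls Integer H x M matrix with entries in `1..K` or `NA`.
#' @param labels Ordered character vector of K unique ancestry names.
#' @param meta,sites As in [hap_panel()].
#' @return An object of class `la_calls`.
#' @export
la_calls <- function(calls, labels = DEFAULT_ANCESTRIES, meta = NULL,
                     sites = NULL) {
  calls <- as.matrix(calls)
  storage.mode(calls) <- "integer"
  K <- length(labels)
  if (K < 2) stop("need at least two ancestry labels")
  if (anyDuplicated(labels)) stop("ancestry labels must be unique")
  obs <- calls[!is.na(calls)]
  if (length(obs) && (min(obs) < 1L || max(obs) > K)) {
    stop("ancestry codes must lie in 1..", K)
  }
  if (!is.null(meta)) {
    if (nrow(meta) != nrow(calls)) stop("meta does not match call rows")
    check_copy_structure(meta)
    rownames(calls) <- hap_ids(meta)
  }
  if (!is.null(sites) && nrow(sites) != ncol(calls)) {
    stop("site map does not match call columns")
  }
  obj <- list(calls = calls, labels = as.character(labels),
              meta = meta, sites = sites)
  class(obj) <- "la_calls"
  obj
}

#' Construct a local ancestry posterior array
#'
#' @param probs Numeric H x M x K array; each `(h, m)` slice must sum to 1
#'   within 1e-6.
#' @param labels Ordered ancestry names, length K.
#' @return An object of class `la_posterior`.
#' @export
la_posterior <- function(probs, labels = DEFAULT_ANCESTRIES) {
  probs <- as.array(probs)
  if (length(dim(probs)) != 3L) stop("probs must be an H x M x K array")
  if (dim(probs)[3] != length(labels)) {
    stop("third dimension must match number of ancestry labels")
  }
  if (any(probs < 0)) stop("posterior probabilities must be nonnegative")
  tot <- apply(probs, c(1, 2), sum)
  if (any(abs(tot - 1) > 1e-6)) {
    stop("posterior slices must sum to 1 (max deviation ",
         format(max(abs(tot - 1))), ")")
  }
  obj <- list(probs = probs, labels = as.character(labels))
  class(obj) <- "la_posterior"
  obj
}

#' Subset a panel (and optionally paired calls) by haplotype rows or sites
#'
#' @param panel A `hap_panel`.
#' @param rows Integer or logical index of haplotype rows to keep.
#' @param cols Integer or logical index of sites to keep.
#' @return A new `hap_panel`.
#' @export
subset_panel <- function(panel, rows = NULL, cols = NULL) {
  a <- panel$alleles
  m <- panel$meta
  s <- panel$sites
  if (!is.null(rows)) {
    a <- a[rows, , drop = FALSE]
    m <- m[rows, , drop = FALSE]
    rownames(m) <- NULL
  }
  if (!is.null(cols)) {
    a <- a[, cols, drop = FALSE]
    s <- s[cols, , drop = FALSE]
    rownames(s) <- NULL
    class(s) <- c("site_map", "data.frame")
  }
  hap_panel(a, m, s)
}

#' @rdname subset_panel
#' @param calls An `la_calls` object.
#' @export
subset_calls <- function(calls, rows = NULL, cols = NULL) {
  cm <- calls$calls
  m <- calls$meta
  s <- calls$sites
  if (!is.null(rows)) {
    cm <- cm[rows, , drop = FALSE]
    if (!is.null(m)) { m <- m[rows, , drop = FALSE]; rownames(m) <- NULL }
  }
  if (!is.null(cols)) {
    cm <- cm[, cols, drop = FALSE]
    if (!is.null(s)) {
      s <- s[cols, , drop = FALSE]
      rownames(s) <- NULL
      class(s) <- c("site_map", "data.frame")
    }
  }
  la_calls(cm, calls$labels, m, s)
}

#' @export
print.hap_panel <- function(x, ...) {
  n_miss <- sum(is.na(x$alleles))
  cat("hap_panel:", nrow(x$alleles), "haplotypes x", ncol(x$alleles),
      "sites;", length(unique(x$meta$sample_id)), "samples;",
      n_miss, "missing alleles\n")
  invisible(x)
}

#' @export
print.la_calls <- function(x, ...) {
  cat("la_calls:", nrow(x$calls), "haplotypes x", ncol(x$calls),
      "sites; ancestries:", paste(x$labels, collapse = ", "), "\n")
  invisible(x)
}

# Map rows of haplotypes to samples: returns list(sample_id -> row indices)
rows_by_sample <- function(meta) {
  split(seq_len(nrow(meta)), factor(meta$sample_id,
                                    levels = unique(meta$sample_id)))
}
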