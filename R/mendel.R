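# Mendelian consistency of local ancestry calls.
#
# A child receives exactly one chromosome from each parent, so at any
# locus the child's unordered pair of ancestry calls must be explainable
# by one code drawn from each parent's pair.  Inconsistency rates across
# families and sites act as a proxy for call accuracy when truth is
# unavailable.  All predicates work on unordered calls: statistical
# phasing is unreliable across individuals, so haplotype order carries
# no information here.

#' Parent-offspring ancestry consistency (one parent observed)
#'
#' With one parent missing, the child's other chromosome is
#' unconstrained, so the calls are consistent iff at least one of the
#' child's two codes appears in the observed parent's pair.
#'
#' @param parent,child Length-2 integer vectors of ancestry codes
#'   (unordered).
#' @return Logical.
#' @export
consistent_pair <- function(parent, child) {
  stopifnot(length(parent) == 2L, length(child) == 2L)
  child[1] %in% parent || child[2] %in% parent
}

#' Mother-father-child ancestry consistency
#'
#' Consistent iff some ordering `(c1, c2)` of the child's codes has
#' `c1` in the mother's pair and `c2` in the father's pair.  The
#' ordering formulation is multiset-aware: a child called `{A, A}`
#' requires `A` in both parents.
#'
#' @param mother,father,child Length-2 integer vectors of ancestry codes.
#' @return Logical.
#' @export
consistent_trio <- function(mother, father, child) {
  stopifnot(length(mother) == 2L, length(father) == 2L,
            length(child) == 2L)
  (child[1] %in% mother && child[2] %in% father) ||
    (child[2] %in% mother && child[1] %in% father)
}

#' X-chromosome ancestry consistency
#'
#' Transmission on X differs by configuration: a son receives his single
#' X from his mother; a daughter receives her father's X unchanged plus
#' one maternal recombinant.
#'
#' * `mother-son`: the son's single code must appear in the mother's
#'   pair.
#' * `mother-daughter`: as [consistent_pair()] (the paternal X is
#'   unconstrained).
#' * `mother-father-daughter`: the father's single code must appear in
#'   the daughter's pair, and the daughter's remaining code (after
#'   removing one instance of the father's) must appear in the mother's
#'   pair.
#'
#' @param config One of `"mother-daughter"`, `"mother-son"`,
#'   `"mother-father-daughter"`.
#' @param mother Length-2 vector (diploid).
#' @param father Length-1 vector (haploid), for the trio configuration.
#' @param child Length-2 for daughters, length-1 for sons.
#' @return Logical.
#' @export
consistent_x <- function(config = c("mother-daughter", "mother-son",
                                    "mother-father-daughter"),
                         mother, child, father = NULL) {
  config <- match.arg(config)
  if (length(mother) != 2L) stop("mother must carry a diploid (size-2) call")
  switch(config,
    "mother-son" = {
      if (length(child) != 1L) stop("a son carries a haploid (size-1) call")
      child %in% mother
    },
    "mother-daughter" = {
      if (length(child) != 2L) stop("a daughter carries a diploid call")
      child[1] %in% mother || child[2] %in% mother
    },
    "mother-father-daughter" = {
      if (length(child) != 2L) stop("a daughter carries a diploid call")
      if (is.null(father) || length(father) != 1L) {
        stop("father must carry a haploid (size-1) call")
      }
      (child[1] == father && child[2] %in% mother) ||
        (child[2] == father && child[1] %in% mother)
    })
}

# Site-vectorised predicate kernels (NA-safe: callers mask NA cells).
.pair_ok <- function(p1, p2, c1, c2) {
  (c1 == p1) | (c1 == p2) | (c2 == p1) | (c2 == p2)
}
.trio_ok <- function(m1, m2, f1, f2, c1, c2) {
  in_m <- function(x) (x == m1) | (x == m2)
  in_f <- function(x) (x == f1) | (x == f2)
  (in_m(c1) & in_f(c2)) | (in_m(c2) & in_f(c1))
}
.x_mfd_ok <- function(m1, m2, f, d1, d2) {
  in_m <- function(x) (x == m1) | (x == m2)
  ((d1 == f) & in_m(d2)) | ((d2 == f) & in_m(d1))
}

#' Genome-wide Mendelian inconsistency rates of ancestry calls
#'
#' Evaluates the appropriate consistency predicate at every site for
#' every pedigree record and pools inconsistent cells over (family,
#' site) within each configuration.  Sites at which any involved call is
#' missing are removed from both numerator and denominator.  Families
#' with members absent from the call set are skipped with a message.
#'
#' On autosomes, configurations are `pair` (one parent observed; either
#' parent qualifies) and `trio`.  On X they are `mother-daughter`,
#' `mother-son` and `mother-father-daughter`; a trio record with a male
#' child is evaluated as `mother-son` since the father does not transmit
#' an X to a son.
#'
#' @param calls An [la_calls()] with haplotype metadata.
#' @param ped A `pedigree` data frame ([read_pedigree()] /
#'   [classify_pedigree()]).
#' @param chrom_mode `"autosome"` or `"X"`.
#' @return Object of class `mendel_report`: `summary` (data frame:
#'   `config`, `n_families`, `n_inconsistent`, `n_evaluated`, `rate`)
#'   and `per_family` (data frame of per-family counts).
#' @export
inconsistency_rates <- function(calls, ped,
                                chrom_mode = c("autosome", "X")) {
  chrom_mode <- match.arg(chrom_mode)
  if (is.null(calls$meta)) stop("calls carry no haplotype metadata")
  by_sample <- rows_by_sample(calls$meta)
  cm <- calls$calls
  get_rows <- function(id) by_sample[[id]]

  fam_rows <- list()
  for (i in seq_len(nrow(ped))) {
    ch <- ped$child[i]; mo <- ped$mother[i]; fa <- ped$father[i]
    members <- c(ch, mo, fa)
    members <- members[!is.na(members)]
    if (!all(members %in% names(by_sample))) {
      message("inconsistency_rates: skipping family of ", ch,
              " (member absent from calls)")
      next
    }
    crow <- get_rows(ch)
    if (chrom_mode == "autosome") {
      if (length(crow) != 2L) {
        message("inconsistency_rates: skipping ", ch,
                " (child not diploid on autosomes)")
        next
      }
      c1 <- cm[crow[1], ]; c2 <- cm[crow[2], ]
      if (ped$type[i] == "trio") {
        mrow <- get_rows(mo); frow <- get_rows(fa)
        ok_obs <- !(is.na(c1) | is.na(c2) |
                      is.na(cm[mrow[1], ]) | is.na(cm[mrow[2], ]) |
                      is.na(cm[frow[1], ]) | is.na(cm[frow[2], ]))
        cons <- .trio_ok(cm[mrow[1], ], cm[mrow[2], ],
                         cm[frow[1], ], cm[frow[2], ], c1, c2)
        cfg <- "trio"
      } else {
        par <- if (!is.na(mo)) mo else fa
        prow <- get_rows(par)
        if (length(prow) != 2L) {
          message("inconsistency_rates: skipping ", ch,
                  " (parent not diploid)")
          next
        }
        ok_obs <- !(is.na(c1) | is.na(c2) |
                      is.na(cm[prow[1], ]) | is.na(cm[prow[2], ]))
        cons <- .pair_ok(cm[prow[1], ], cm[prow[2], ], c1, c2)
        cfg <- "pair"
      }
    } else {                       # chromosome X
      if (is.na(mo)) {
        message("inconsistency_rates: skipping ", ch,
                " (X configurations require the mother)")
        next
      }
      mrow <- get_rows(mo)
      if (length(mrow) != 2L) {
        message("inconsistency_rates: skipping ", ch,
                " (mother not diploid on X)")
        next
      }
      m1 <- cm[mrow[1], ]; m2 <- cm[mrow[2], ]
      child_sex <- calls$meta$sex[crow[1]]
      if (child_sex == "male") {
        if (length(crow) != 1L) {
          message("inconsistency_rates: skipping ", ch,
                  " (son not haploid on X)")
          next
        }
        s <- cm[crow[1], ]
        ok_obs <- !(is.na(s) | is.na(m1) | is.na(m2))
        cons <- (s == m1) | (s == m2)
        cfg <- "mother-son"
      } else {
        if (length(crow) != 2L) {
          message("inconsistency_rates: skipping ", ch,
                  " (daughter not diploid on X)")
          next
        }
        d1 <- cm[crow[1], ]; d2 <- cm[crow[2], ]
        if (ped$type[i] == "trio" && !is.na(fa)) {
          frow <- get_rows(fa)
          if (length(frow) != 1L) {
            message("inconsistency_rates: skipping ", ch,
                    " (father not haploid on X)")
            next
          }
          f <- cm[frow[1], ]
          ok_obs <- !(is.na(d1) | is.na(d2) | is.na(m1) | is.na(m2) |
                        is.na(f))
          cons <- .x_mfd_ok(m1, m2, f, d1, d2)
          cfg <- "mother-father-daughter"
        } else {
          ok_obs <- !(is.na(d1) | is.na(d2) | is.na(m1) | is.na(m2))
          cons <- .pair_ok(m1, m2, d1, d2)
          cfg <- "mother-daughter"
        }
      }
    }
    fam_rows[[length(fam_rows) + 1L]] <- data.frame(
      family = ch, config = cfg,
      n_inconsistent = sum(!cons[ok_obs]),
      n_evaluated = sum(ok_obs),
      stringsAsFactors = FALSE)
  }
  if (!length(fam_rows)) stop("no evaluable families")
  per_family <- do.call(rbind, fam_rows)
  per_family$rate <- ifelse(per_family$n_evaluated > 0,
                            per_family$n_inconsistent /
                              per_family$n_evaluated, NA_real_)
  agg_inc <- tapply(per_family$n_inconsistent, per_family$config, sum)
  agg_eval <- tapply(per_family$n_evaluated, per_family$config, sum)
  agg_fam <- tapply(per_family$family, per_family$config, length)
  cfgs <- names(agg_inc)
  summary <- data.frame(config = cfgs,
                        n_families = as.integer(agg_fam[cfgs]),
                        n_inconsistent = as.integer(agg_inc[cfgs]),
                        n_evaluated = as.integer(agg_eval[cfgs]),
                        rate = as.numeric(agg_inc[cfgs] / agg_eval[cfgs]),
                        stringsAsFactors = FALSE, row.names = NULL)
  structure(list(summary = summary, per_family = per_family,
                 chrom_mode = chrom_mode),
            class = "mendel_report")
}

#' @export
print.mendel_report <- function(x, ...) {
  cat("Mendelian inconsistency of ancestry calls (", x$chrom_mode,
      ")\n", sep = "")
  s <- x$summary
  s$rate <- formatC(s$rate, digits = 4, format = "f")
  print(s, row.names = FALSE)
  invisible(x)
}

#' Reduce trio pedigree records to single-parent pairs
#'
#' Useful for evaluating the same families under the pair configuration
#' (as when one parent's data are unavailable).
#'
#' @param ped A `pedigree` data frame.
#' @param keep Which parent to keep: `"mother"` or `"father"`.
#' @return A `pedigree` of pair records.
#' @export
as_pairs <- function(ped, keep = c("mother", "father")) {
  keep <- match.arg(keep)
  df <- as.data.frame(ped)[, c("child", "mother", "father", "sex")]
  if (keep == "mother") df$father <- NA_character_
  else df$mother <- NA_character_
  classify_pedigree(df)
}
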