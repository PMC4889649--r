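# X-chromosome male coding schemes for diploid-only downstream callers.
#
# Males are haploid on non-pseudoautosomal X.  Coding reference males as
# homozygous diploid inflates the apparent frequency of their
# haplotypes, so reference males are instead paired into phased
# pseudodiploids within each reference group.  Admixed males may be
# analysed haploid (separately from females), coded homozygous, or all
# males coded homozygous; these are Options 1-3 below.

#' Pair haploid reference males into pseudodiploids
#'
#' Within each group, males are paired in input order (first with
#' second, and so on); each pair becomes one pseudodiploid sample whose
#' two haplotype rows are the two males' X haplotypes.  A trailing
#' unpaired male is dropped and reported.  Pairing never crosses group
#' boundaries.
#'
#' @param panel A [hap_panel()] whose rows are haploid male X haplotypes
#'   (one row per sample) with group labels.
#' @param shuffle_seed Optional integer: shuffle male order within each
#'   group (seeded) before pairing instead of using input order.
#' @return List: `panel` (pseudodiploid [hap_panel()]), `dropped`
#'   (character vector of dropped sample ids), `pairing` (data frame:
#'   pseudodiploid id, member ids, group).
#' @export
pair_reference_males <- function(panel, shuffle_seed = NULL) {
  meta <- panel$meta
  if (any(meta$sex != "male")) stop("panel must contain only males")
  if (any(duplicated(meta$sample_id))) {
    stop("panel must be haploid: one row per male")
  }
  groups <- unique(meta$group)
  alleles <- list(); ids <- character(); cps <- integer()
  grs <- character()
  dropped <- character()
  pairing <- data.frame(pseudodiploid = character(),
                        member1 = character(), member2 = character(),
                        group = character(), stringsAsFactors = FALSE)
  for (g in groups) {
    rows <- which(meta$group == g)
    if (!is.null(shuffle_seed)) {
      set.seed(shuffle_seed)
      rows <- rows[sample.int(length(rows))]
    }
    n <- length(rows)
    if (n < 2L) {
      warning("group '", g, "' has ", n,
              " male(s); no pseudodiploid formed")
      if (n == 1L) dropped <- c(dropped, meta$sample_id[rows])
      next
    }
    if (n %% 2L == 1L) {
      dropped <- c(dropped, meta$sample_id[rows[n]])
      rows <- rows[-n]
      n <- n - 1L
    }
    for (p in seq_len(n / 2L)) {
      r1 <- rows[2L * p - 1L]; r2 <- rows[2L * p]
      pid <- paste0("pd_", g, "_", p)
      alleles[[length(alleles) + 1L]] <- panel$alleles[r1, ]
      alleles[[length(alleles) + 1L]] <- panel$alleles[r2, ]
      ids <- c(ids, pid, pid); cps <- c(cps, 1L, 2L)
      grs <- c(grs, g, g)
      pairing <- rbind(pairing, data.frame(
        pseudodiploid = pid, member1 = meta$sample_id[r1],
        member2 = meta$sample_id[r2], group = g,
        stringsAsFactors = FALSE))
    }
  }
  out <- if (length(alleles)) {
    hap_panel(do.call(rbind, alleles),
              hap_meta(ids, cps, "male", grs), panel$sites)
  } else {
    NULL
  }
  list(panel = out, dropped = dropped, pairing = pairing)
}

#' Code haploid males as homozygous diploids
#'
#' Duplicates each targeted male's single haplotype row into a two-row
#' homozygous diploid.  Females pass through unchanged (with a message).
#' Applying the coding to males that are already diploid is an error, as
#' a guard against double application.
#'
#' @param panel A [hap_panel()] on X.
#' @param which Which males to code: `"admixed"` (group label
#'   `"admixed"`), `"reference"` (any other group) or `"both"`.
#' @return List: `panel` (recoded [hap_panel()]), `duplicated_samples`
#'   (ids of males whose rows were duplicated).
#' @export
code_males_homozygous <- function(panel, which = c("admixed",
                                                   "reference", "both")) {
  which <- match.arg(which)
  meta <- panel$meta
  is_adm <- !is.na(meta$group) & meta$group == "admixed"
  targeted_sample <- function(i) {
    meta$sex[i] == "male" &&
      (which == "both" || (which == "admixed") == is_adm[i])
  }
  alleles <- list(); ids <- character(); cps <- integer()
  sxs <- character(); grs <- character()
  duplicated_samples <- character()
  n_female <- 0L
  for (r in rows_by_sample(meta)) {
    i <- r[1]
    if (meta$sex[i] == "female") n_female <- n_female + 1L
    if (targeted_sample(i)) {
      if (length(r) != 1L) {
        stop("male ", meta$sample_id[i],
             " is already diploid; refusing to re-code")
      }
      alleles[[length(alleles) + 1L]] <- panel$alleles[r, ]
      alleles[[length(alleles) + 1L]] <- panel$alleles[r, ]
      ids <- c(ids, meta$sample_id[i], meta$sample_id[i])
      cps <- c(cps, 1L, 2L)
      sxs <- c(sxs, "male", "male")
      grs <- c(grs, meta$group[i], meta$group[i])
      duplicated_samples <- c(duplicated_samples, meta$sample_id[i])
    } else {
      for (j in r) {
        alleles[[length(alleles) + 1L]] <- panel$alleles[j, ]
        ids <- c(ids, meta$sample_id[j]); cps <- c(cps, meta$copy[j])
        sxs <- c(sxs, meta$sex[j]); grs <- c(grs, meta$group[j])
      }
    }
  }
  if (n_female > 0L) {
    message("code_males_homozygous: ", n_female,
            " female sample(s) passed through unchanged")
  }
  list(panel = hap_panel(do.call(rbind, alleles),
                         hap_meta(ids, cps, sxs, grs), panel$sites),
       duplicated_samples = duplicated_samples)
}

#' Stack two haplotype panels on the same site map
#'
#' @param a,b [hap_panel()] objects sharing a site map; either may be
#'   `NULL`, in which case the other is returned.
#' @return The row-bound [hap_panel()].
#' @export
bind_panels <- function(a, b) {
  if (is.null(a)) return(b)
  if (is.null(b)) return(a)
  if (!identical(a$sites$pos_bp, b$sites$pos_bp)) {
    stop("panels are not on the same site map")
  }
  m <- rbind(a$meta, b$meta)
  hap_panel(rbind(a$alleles, b$alleles),
            hap_meta(m$sample_id, m$copy, m$sex, m$group), a$sites)
}

#' Build analysis-ready X-chromosome input sets (Options 1-3)
#'
#' * Option 1: two sets — admixed haploid males plus pseudodiploid
#'   reference (phase known), and admixed females plus pseudodiploid
#'   reference (statistically phased).  Reference females, if present,
#'   accompany both sets unchanged.
#' * Option 2: one set — admixed males coded homozygous diploid,
#'   reference males paired into pseudodiploids.
#' * Option 3: one set — all males (admixed and reference) coded
#'   homozygous; no pseudodiploid pairing.
#'
#' Admixed samples are identified by group label `"admixed"`; all other
#' groups are treated as reference.
#'
#' @param panel A [hap_panel()] on X: haploid male rows, diploid female
#'   rows, complete sex metadata.
#' @param option 1, 2 or 3.
#' @param shuffle_seed Optional seed forwarded to
#'   [pair_reference_males()].
#' @return Object of class `x_option_inputs`: `option`, `sets` (named
#'   list of `list(panel, phase)`), `dropped_males`, `manifest` (data
#'   frame: sample, role, sex, coding, set).
#' @export
build_x_option_inputs <- function(panel, option, shuffle_seed = NULL) {
  option <- as.integer(option)
  if (!option %in% 1:3) stop("option must be 1, 2 or 3")
  meta <- panel$meta
  unknown <- unique(meta$sample_id[!meta$sex %in% c("male", "female")])
  if (length(unknown)) {
    stop("samples with unknown sex: ", paste(unknown, collapse = ", "))
  }
  is_adm <- !is.na(meta$group) & meta$group == "admixed"
  pick <- function(keep) if (any(keep)) subset_panel(panel, rows = keep)
  adm_m <- pick(is_adm & meta$sex == "male")
  adm_f <- pick(is_adm & meta$sex == "female")
  ref_m <- pick(!is_adm & meta$sex == "male")
  ref_f <- pick(!is_adm & meta$sex == "female")

  dropped <- character()
  sets <- list()
  manifest <- data.frame(sample = character(), role = character(),
                         sex = character(), coding = character(),
                         set = character(), stringsAsFactors = FALSE)
  add_manifest <- function(p, role, coding, set_name) {
    if (is.null(p)) return()
    m <- p$meta[!duplicated(p$meta$sample_id), ]
    manifest <<- rbind(manifest, data.frame(
      sample = m$sample_id, role = role, sex = m$sex, coding = coding,
      set = set_name, stringsAsFactors = FALSE))
  }

  make_ref <- function(set_name) {
    # pseudodiploid reference males + unchanged reference females
    pd <- NULL
    if (!is.null(ref_m)) {
      pr <- pair_reference_males(ref_m, shuffle_seed = shuffle_seed)
      dropped <<- unique(c(dropped, pr$dropped))
      pd <- pr$panel
      add_manifest(pd, "reference", "pseudodiploid", set_name)
    }
    add_manifest(ref_f, "reference", "diploid", set_name)
    bind_panels(pd, ref_f)
  }

  if (option == 1L) {
    ref1 <- make_ref("males")
    add_manifest(adm_m, "admixed", "haploid", "males")
    sets$males <- list(panel = bind_panels(adm_m, ref1),
                       phase = "known")
    ref2 <- make_ref("females")
    add_manifest(adm_f, "admixed", "diploid", "females")
    sets$females <- list(panel = bind_panels(adm_f, ref2),
                         phase = "statistical")
  } else if (option == 2L) {
    adm_m2 <- if (!is.null(adm_m)) {
      code_males_homozygous(adm_m, "admixed")$panel
    }
    add_manifest(adm_m2, "admixed", "homozygous-diploid", "all")
    add_manifest(adm_f, "admixed", "diploid", "all")
    ref <- make_ref("all")
    sets$all <- list(panel = bind_panels(bind_panels(adm_m2, adm_f), ref),
                     phase = "statistical")
  } else {
    adm_m3 <- if (!is.null(adm_m)) {
      code_males_homozygous(adm_m, "admixed")$panel
    }
    ref_m3 <- if (!is.null(ref_m)) {
      code_males_homozygous(ref_m, "reference")$panel
    }
    add_manifest(adm_m3, "admixed", "homozygous-diploid", "all")
    add_manifest(adm_f, "admixed", "diploid", "all")
    add_manifest(ref_m3, "reference", "homozygous-diploid", "all")
    add_manifest(ref_f, "reference", "diploid", "all")
    sets$all <- list(panel = bind_panels(bind_panels(adm_m3, adm_f),
                                         bind_panels(ref_m3, ref_f)),
                     phase = "statistical")
  }
  structure(list(option = option, sets = sets, dropped_males = dropped,
                 manifest = manifest),
            class = "x_option_inputs")
}

#' @export
print.x_option_inputs <- function(x, ...) {
  cat("X-chromosome inputs, Option ", x$option, ": ",
      length(x$sets), " set(s); ", length(x$dropped_males),
      " unpaired male(s) dropped\n", sep = "")
  for (nm in names(x$sets)) {
    p <- x$sets[[nm]]$panel
    cat("  ", nm, ": ", nrow(p$alleles), " haplotype rows (phase ",
        x$sets[[nm]]$phase, ")\n", sep = "")
  }
  invisible(x)
}
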