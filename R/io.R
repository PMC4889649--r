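# On-disk formats: phased VCF (GT only, via vcfR), RFMix v1-style
# site-major Viterbi and posterior text, pedigree TSV, site-map TSV and
# generic TSV result tables.  All file coordinates are 1-based bp; the
# in-memory matrices are addressed with ordinary R (1-based) indices.

#' Read a phased VCF into a haplotype panel
#'
#' Biallelic sites with phased (`|`-separated) GT fields are transcribed
#' into an H x M allele matrix with two consecutive rows per diploid
#' sample, in VCF header order (copy 1 before copy 2).  Multiallelic
#' records are skipped with a message reporting the count.  `.` alleles
#' become missing.  A sample whose GT fields are all single-allele is
#' haploid and yields one row; this is accepted only for males on
#' chromosome X (per the `sex` lookup), since autosomes are diploid.
#'
#' @param path Path to a VCF (plain text or gzipped).
#' @param region Optional chromosome label; only records on that
#'   chromosome are read.
#' @param sex Optional named character vector mapping sample id to
#'   `"male"`/`"female"`; defaults to `"unknown"`.
#' @param group Optional named character vector of group labels.
#' @return A [hap_panel()].
#' @export
read_phased_vcf <- function(path, region = NULL, sex = NULL, group = NULL) {
  if (!file.exists(path)) stop("no such file: ", path)
  v <- tryCatch(vcfR::read.vcfR(path, verbose = FALSE),
                error = function(e) stop("cannot parse VCF ", path, ": ",
                                         conditionMessage(e)))
  fix <- vcfR::getFIX(v)
  if (is.null(fix) || nrow(v@gt) == 0) stop("empty VCF: ", path)
  if (is.null(dim(fix))) fix <- matrix(fix, nrow = 1,
                                       dimnames = list(NULL, names(fix)))
  fix <- as.data.frame(fix, stringsAsFactors = FALSE)
  keep <- rep(TRUE, nrow(fix))
  if (!is.null(region)) keep <- keep & fix$CHROM == as.character(region)
  multi <- grepl(",", fix$ALT %||% "")
  n_multi <- sum(multi & keep)
  if (n_multi > 0) {
    message("read_phased_vcf: skipped ", n_multi, " multiallelic site(s)")
  }
  keep <- keep & !multi
  if (!any(keep)) stop("no usable biallelic records in ", path)
  fix <- fix[keep, , drop = FALSE]
  gt_all <- v@gt
  if (is.null(dim(gt_all))) {
    gt_all <- matrix(gt_all, nrow = 1, dimnames = list(NULL, names(gt_all)))
  }
  gt <- gt_all[keep, -1, drop = FALSE]   # drop FORMAT column
  fmt <- gt_all[keep, 1]
  gt_idx <- vapply(strsplit(fmt, ":", fixed = TRUE),
                   function(f) match("GT", f), integer(1))
  if (anyNA(gt_idx)) stop("record without GT field in ", path)
  samples <- colnames(gt)
  M <- nrow(fix)

  get_sex <- function(s) {
    if (!is.null(sex) && s %in% names(sex)) sex[[s]] else "unknown"
  }
  get_group <- function(s) {
    if (!is.null(group) && s %in% names(group)) group[[s]] else NA_character_
  }

  rows <- list(); ids <- character(); cps <- integer()
  sxs <- character(); grps <- character()
  for (s in samples) {
    raw <- gt[, s]
    gt_str <- vapply(seq_len(M), function(i) {
      strsplit(raw[i], ":", fixed = TRUE)[[1]][gt_idx[i]]
    }, character(1))
    slash <- grepl("/", gt_str, fixed = TRUE)
    if (any(slash)) {
      i <- which(slash)[1]
      stop("unphased genotype '", gt_str[i], "' for sample ", s,
           " at ", fix$CHROM[i], ":", fix$POS[i])
    }
    parts <- strsplit(gt_str, "|", fixed = TRUE)
    ploidy <- lengths(parts)
    parse_allele <- function(x) {
      a <- suppressWarnings(as.integer(x))
      a[x == "." | x == ""] <- NA_integer_
      a
    }
    if (all(ploidy == 1L)) {
      sx <- get_sex(s)
      if (!is.null(region) && toupper(region) == "X" && sx == "male") {
        rows[[length(rows) + 1L]] <- parse_allele(unlist(parts))
        ids <- c(ids, s); cps <- c(cps, 1L)
        sxs <- c(sxs, sx); grps <- c(grps, get_group(s))
        next
      }
      stop("sample ", s, " has haploid genotypes but is not a male ",
           "on chromosome X")
    }
    if (any(ploidy != 2L)) {
      i <- which(ploidy != 2L)[1]
      stop("sample ", s, " has ploidy ", ploidy[i], " at ",
           fix$CHROM[i], ":", fix$POS[i])
    }
    am <- matrix(parse_allele(unlist(parts)), nrow = 2)
    for (cp in 1:2) {
      rows[[length(rows) + 1L]] <- am[cp, ]
      ids <- c(ids, s); cps <- c(cps, cp)
      sxs <- c(sxs, get_sex(s)); grps <- c(grps, get_group(s))
    }
  }
  sm <- site_map(fix$CHROM, as.integer(fix$POS),
                 site_id = ifelse(fix$ID == "." | is.na(fix$ID),
                                  paste0(fix$CHROM, ":", fix$POS), fix$ID))
  hap_panel(do.call(rbind, rows), hap_meta(ids, cps, sxs, grps), sm)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Write a haplotype panel as a phased VCF
#'
#' Alleles are written as GT-only records with REF `A` / ALT `T`
#' placeholders; haploid rows produce single-allele GTs.  Missing alleles
#' are written as `.`.
#'
#' @param panel A [hap_panel()].
#' @param path Output path.
#' @export
write_phased_vcf <- function(panel, path) {
  meta <- panel$meta
  sm <- panel$sites
  by_sample <- rows_by_sample(meta)
  samples <- names(by_sample)
  hdr <- c("##fileformat=VCFv4.2",
           '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
           paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                   "INFO", "FORMAT", samples), collapse = "\t"))
  al <- panel$alleles
  fmt_allele <- function(a) ifelse(is.na(a), ".", as.character(a))
  cols <- lapply(by_sample, function(r) {
    if (length(r) == 1L) {
      fmt_allele(al[r, ])
    } else {
      paste(fmt_allele(al[r[1], ]), fmt_allele(al[r[2], ]), sep = "|")
    }
  })
  body <- do.call(paste, c(list(sm$chrom, sm$pos_bp, sm$site_id, "A", "T",
                                ".", "PASS", ".", "GT"), cols,
                           list(sep = "\t")))
  writeLines(c(hdr, body), path)
  invisible(path)
}

#' Write / read a panel with sidecar metadata
#'
#' The VCF format does not carry sex, group or genetic-map information, so
#' [write_panel()] emits three files under a common prefix:
#' `<prefix>.vcf`, `<prefix>.samples.tsv` (sample, sex, group) and
#' `<prefix>.sites.tsv`.  [read_panel()] reassembles the identical panel.
#'
#' @param panel A [hap_panel()].
#' @param prefix Path prefix for the three output files.
#' @return `read_panel` returns the reconstructed [hap_panel()];
#'   `write_panel` returns the prefix invisibly.
#' @export
write_panel <- function(panel, prefix) {
  write_phased_vcf(panel, paste0(prefix, ".vcf"))
  meta <- panel$meta
  samp <- meta[!duplicated(meta$sample_id),
               c("sample_id", "sex", "group")]
  write.table(samp, paste0(prefix, ".samples.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  write_site_map(panel$sites, paste0(prefix, ".sites.tsv"))
  invisible(prefix)
}

#' @rdname write_panel
#' @param prefix Path prefix used by [write_panel()].
#' @export
read_panel <- function(prefix) {
  samp <- read.table(paste0(prefix, ".samples.tsv"), sep = "\t",
                     header = TRUE, stringsAsFactors = FALSE,
                     na.strings = "NA")
  sm <- read_site_map(paste0(prefix, ".sites.tsv"))
  region <- if (all(toupper(sm$chrom) == "X")) "X" else NULL
  p <- read_phased_vcf(paste0(prefix, ".vcf"), region = region,
                       sex = setNames(samp$sex, samp$sample_id),
                       group = setNames(samp$group, samp$sample_id))
  if (!identical(p$sites$pos_bp, sm$pos_bp)) {
    stop("site map sidecar disagrees with VCF positions")
  }
  hap_panel(p$alleles, p$meta, sm)
}

#' Read RFMix-style Viterbi calls
#'
#' Site-major whitespace-delimited text: one row per site, one integer
#' column per haplotype, codes `1..K`.  The code `0` denotes a missing
#' call.  Columns are taken in haplotype order (sample order, copy 1
#' before copy 2) so no index file is needed.
#'
#' @param path Path to the Viterbi text file.
#' @param labels Ordered ancestry names (length K).
#' @param sites A [site_map()]; the file must have exactly `nrow(sites)`
#'   rows.
#' @param meta Optional haplotype metadata matching the columns.
#' @return An [la_calls()] object (haplotypes x sites).
#' @export
read_rfmix_viterbi <- function(path, labels = DEFAULT_ANCESTRIES,
                               sites = NULL, meta = NULL) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  if (!length(lines)) stop("empty Viterbi file: ", path)
  rows <- strsplit(trimws(lines), "[ \t]+")
  ncols <- lengths(rows)
  if (length(unique(ncols)) != 1L) {
    stop("ragged Viterbi file: line ",
         which(ncols != ncols[1])[1], " has ", ncols[ncols != ncols[1]][1],
         " columns, expected ", ncols[1])
  }
  m <- suppressWarnings(
    matrix(as.integer(unlist(rows)), nrow = length(lines), byrow = TRUE))
  if (anyNA(m)) {
    stop("non-integer token in Viterbi file at line ",
         which(apply(is.na(m), 1, any))[1])
  }
  K <- length(labels)
  bad <- m < 0L | m > K
  if (any(bad)) {
    stop("ancestry code outside 0..", K, " in Viterbi file at line ",
         which(apply(bad, 1, any))[1])
  }
  m[m == 0L] <- NA_integer_
  if (!is.null(sites) && nrow(m) != nrow(sites)) {
    stop("Viterbi file has ", nrow(m), " rows but site map has ",
         nrow(sites), " sites")
  }
  la_calls(t(m), labels, meta, sites)
}

#' Write RFMix-style Viterbi calls
#'
#' @param calls An [la_calls()] object.
#' @param path Output path.  Missing calls are written as `0`.
#' @export
write_rfmix_viterbi <- function(calls, path) {
  m <- t(calls$calls)            # site-major on disk
  m[is.na(m)] <- 0L
  writeLines(apply(m, 1, paste, collapse = " "), path)
  invisible(path)
}

#' Read RFMix-style posterior probabilities
#'
#' Site-major text with K columns per haplotype: row m holds
#' `hap1_p1..hap1_pK hap2_p1..` for site m.
#'
#' @param path Path to the posterior text file.
#' @param labels Ordered ancestry names (length K).
#' @param n_hap Number of haplotypes expected.
#' @return An [la_posterior()].
#' @export
read_rfmix_posterior <- function(path, labels = DEFAULT_ANCESTRIES, n_hap) {
  K <- length(labels)
  m <- as.matrix(read.table(path, header = FALSE))
  if (ncol(m) != n_hap * K) {
    stop("posterior file has ", ncol(m), " columns; expected n_hap * K = ",
         n_hap * K)
  }
  M <- nrow(m)
  probs <- array(0, dim = c(n_hap, M, K))
  for (h in seq_len(n_hap)) {
    probs[h, , ] <- m[, ((h - 1L) * K + 1L):(h * K), drop = FALSE]
  }
  la_posterior(probs, labels)
}

#' @rdname read_rfmix_posterior
#' @param post An [la_posterior()] to write.
#' @export
write_rfmix_posterior <- function(post, path) {
  d <- dim(post$probs)
  out <- matrix(0, nrow = d[2], ncol = d[1] * d[3])
  for (h in seq_len(d[1])) {
    out[, ((h - 1L) * d[3] + 1L):(h * d[3])] <- post$probs[h, , ]
  }
  write.table(format(out, digits = 10, trim = TRUE), path, sep = " ",
              quote = FALSE, row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read a pedigree table
#'
#' TSV with header columns `child`, `mother`, `father`, `sex`; `0`, `NA`
#' or an empty field mark an absent parent.  Records are classified into
#' trios (both parents), pairs (one parent) or dropped (neither, with a
#' message reporting the count).
#'
#' @param path Path to the pedigree TSV.
#' @return A `data.frame` of class `pedigree` with a `type` column in
#'   `{"trio", "pair"}` .
#' @export
read_pedigree <- function(path) {
  df <- read.table(path, sep = "\t", header = TRUE,
                   stringsAsFactors = FALSE,
                   colClasses = "character", na.strings = c("NA", ""))
  need <- c("child", "mother", "father", "sex")
  if (!all(need %in% names(df))) {
    stop("pedigree file must have columns: ", paste(need, collapse = ", "))
  }
  df$mother[df$mother %in% "0"] <- NA_character_
  df$father[df$father %in% "0"] <- NA_character_
  classify_pedigree(df)
}

#' Classify pedigree records into pairs and trios
#'
#' @param df Data frame with columns `child`, `mother`, `father`, `sex`
#'   (absent parents as `NA`).
#' @return The classified `pedigree` data frame; founder-only records
#'   (no parents) are dropped with a message.
#' @export
classify_pedigree <- function(df) {
  if (nrow(df)) {
    self <- !is.na(df$mother) & df$mother == df$child |
      !is.na(df$father) & df$father == df$child
    if (any(self)) {
      stop("child ", df$child[which(self)[1]], " is listed as its own parent")
    }
    n_par <- (!is.na(df$mother)) + (!is.na(df$father))
    dropped <- sum(n_par == 0L)
    if (dropped > 0) {
      message("classify_pedigree: dropped ", dropped,
              " record(s) with no parents")
    }
    df <- df[n_par > 0L, , drop = FALSE]
    df$type <- ifelse((!is.na(df$mother)) + (!is.na(df$father)) == 2L,
                      "trio", "pair")
  } else {
    df$type <- character(0)
  }
  rownames(df) <- NULL
  class(df) <- c("pedigree", "data.frame")
  df
}

#' Write / read a site map as TSV
#'
#' Columns: `chrom`, `pos_bp`, `site_id`, optionally `pos_cm`.
#'
#' @param sm A [site_map()].
#' @param path File path.
#' @export
write_site_map <- function(sm, path) {
  write.table(as.data.frame(sm), path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}

#' @rdname write_site_map
#' @export
read_site_map <- function(path) {
  df <- read.table(path, sep = "\t", header = TRUE,
                   stringsAsFactors = FALSE)
  site_map(df$chrom, df$pos_bp, df$site_id,
           if ("pos_cm" %in% names(df)) df$pos_cm else NULL)
}

#' Write a pedigree table as TSV
#' @param ped A `pedigree` data frame.
#' @param path File path.
#' @export
write_pedigree <- function(ped, path) {
  out <- as.data.frame(ped)[, c("child", "mother", "father", "sex")]
  out$mother[is.na(out$mother)] <- "0"
  out$father[is.na(out$father)] <- "0"
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

# Uniform TSV writer for result tables: 4-decimal rates, header row.
write_result_tsv <- function(df, path, digits = 4) {
  num <- vapply(df, is.numeric, logical(1)) &
    !vapply(df, is.integer, logical(1))
  df[num] <- lapply(df[num], function(x) formatC(x, digits = digits,
                                                 format = "f"))
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
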