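# Masking, proportions, thinning, reference filtering, site
# intersection, diploid matching, concordance and posterior summaries.

test_that("masking keeps target-ancestry alleles and nothing else", {
  a <- rbind(c(0L, 1L, 0L, 1L), c(1L, 1L, 0L, 0L))
  p <- diploid_panel(a)
  all_target <- diploid_calls(matrix(1L, 2, 4))
  expect_identical(mask_by_ancestry(p, all_target, "African")$alleles,
                   p$alleles)
  none <- diploid_calls(matrix(2L, 2, 4))
  expect_true(all(is.na(mask_by_ancestry(p, none, "African")$alleles)))
  # mixed rows: row1 (A,A,E,E), row2 (E,E,E,E): 6 of 8 cells masked
  cm <- rbind(c(1L, 1L, 3L, 3L), c(3L, 3L, 3L, 3L))
  m <- mask_by_ancestry(p, diploid_calls(cm), "African")
  expect_equal(unname(m$alleles[1, ]), c(0L, 1L, NA, NA))
  expect_true(all(is.na(m$alleles[2, ])))
  expect_equal(sum(is.na(m$alleles)), 6L)
  expect_error(mask_by_ancestry(p, none, "Oceanian"), "unknown ancestry")
})

test_that("masks over all ancestries partition the non-missing cells", {
  set.seed(21)
  a <- matrix(sample(c(0:1, NA), 8 * 50, replace = TRUE,
                     prob = c(0.45, 0.45, 0.1)), 8, 50)
  cm <- matrix(sample(1:3, 8 * 50, replace = TRUE), 8, 50)
  p <- diploid_panel(a); calls <- diploid_calls(cm)
  counts <- vapply(ANC, function(t) {
    sum(!is.na(mask_by_ancestry(p, calls, t)$alleles))
  }, numeric(1))
  expect_equal(sum(counts), sum(!is.na(a)))
})

test_that("global proportions count cells per sample", {
  cm <- rbind(rep(3L, 10), rep(3L, 10))      # all European
  pr <- global_proportions(diploid_calls(cm))
  expect_equal(unname(unlist(pr[1, ANC])), c(0, 0, 1))
  cm <- rbind(rep(1L, 7), rep(3L, 7))        # hap1 African, hap2 European
  pr <- global_proportions(diploid_calls(cm))
  expect_equal(unname(unlist(pr[1, ANC])), c(0.5, 0, 0.5))
  # 10-site diploid: 5 African cells, 15 European
  cm <- rbind(c(rep(1L, 5), rep(3L, 5)), rep(3L, 10))
  pr <- global_proportions(diploid_calls(cm))
  expect_equal(unname(unlist(pr[1, ANC])), c(0.25, 0, 0.75))
  # all-missing sample is flagged undefined
  cm <- rbind(rep(NA_integer_, 4), rep(NA_integer_, 4),
              rep(1L, 4), rep(1L, 4))
  pr <- global_proportions(diploid_calls(cm))
  expect_false(pr$defined[1])
  expect_true(is.na(pr$African[1]))
  expect_true(pr$defined[2])
})

test_that("ancestry threshold is inclusive and matches a brute-force filter", {
  mk <- function(p) data.frame(sample_id = paste0("s", seq_along(p)),
                               African = p, Amerindian = 0.2,
                               European = 1 - p - 0.2)
  expect_equal(filter_by_ancestry_threshold(mk(0.5), "African"), "s1")
  expect_equal(filter_by_ancestry_threshold(mk(0.49), "African"),
               character(0))
  set.seed(22)
  p <- rbeta(100, 2, 2)
  props <- mk(p)
  got <- filter_by_ancestry_threshold(props, "African", 0.5)
  want <- props$sample_id[vapply(seq_len(100),
                                 function(i) p[i] >= 0.5, logical(1))]
  expect_identical(got, want)
})

test_that("thinning is even within chromosomes with largest-remainder allocation", {
  p <- tiny_panel(matrix(0L, 2, 100))
  expect_identical(thin_markers(p, 100)$sites$pos_bp, p$sites$pos_bp)
  idx <- thin_indices(p$sites, 10)
  expect_length(idx, 10)
  expect_equal(idx[1], 1L); expect_equal(idx[10], 100L)
  gaps <- diff(idx)
  expect_lte(max(gaps) - min(gaps), 1L)
  # two chromosomes of 300 and 100 sites
  sm <- site_map(c(rep("1", 300), rep("2", 100)),
                 c(1:300, 1:100))
  idx <- thin_indices(sm, 100)
  expect_equal(sum(sm$chrom[idx] == "1"), 75L)
  expect_equal(sum(sm$chrom[idx] == "2"), 25L)
  expect_error(thin_indices(sm, 0), "positive")
  expect_error(thin_indices(sm, 500), "exceeds")
})

test_that("reference filtering keeps >=90% single-cluster individuals outside exclusions", {
  q <- rbind(a = c(0.92, 0.05, 0.02, 0.01),
             b = c(0.02, 0.95, 0.02, 0.01),
             c = c(0.89, 0.11, 0.00, 0.00))
  colnames(q) <- c("Africa", "EastAsia", "Europe", "America")
  res <- filter_reference_panel(q)
  expect_equal(res$individual, c("a", "b"))
  expect_equal(res$cluster, c("Africa", "EastAsia"))
  # an individual assigned to an excluded cluster is dropped even at 0.95
  res <- filter_reference_panel(q, exclude = "EastAsia")
  expect_equal(res$individual, "a")
  # boundary: 0.89 is strictly below the default 0.9
  expect_false("c" %in% res$individual)
  expect_error(filter_reference_panel(q, exclude = colnames(q)),
               "every cluster")
})

test_that("site intersection matches a set-based oracle", {
  a <- site_map(rep("1", 4), c(10, 20, 30, 40))
  expect_equal(intersect_sites(a, a),
               list(idx_a = 1:4, idx_b = 1:4))
  b <- site_map(rep("1", 3), c(11, 21, 31))
  expect_equal(lengths(intersect_sites(a, b)),
               c(idx_a = 0L, idx_b = 0L))
  set.seed(23)
  pa <- sort(sample(1:1000, 10)); pb <- sort(sample(1:1000, 8))
  pb[1:5] <- pa[c(2, 4, 6, 8, 10)]; pb <- sort(unique(pb))[1:8]
  ma <- site_map(rep("1", 10), pa); mb <- site_map(rep("1", 8), pb)
  r <- intersect_sites(ma, mb)
  shared <- intersect(pa, pb)
  expect_equal(ma$pos_bp[r$idx_a], sort(shared))
  expect_equal(mb$pos_bp[r$idx_b], sort(shared))
  dup <- site_map(c("1", "1"), c(5, 6)); dup$pos_bp <- c(5L, 5L)
  expect_error(intersect_sites(dup, a), "duplicate")
})

test_that("diploid call matching maximises agreement over the two alignments", {
  # African/European vs Amerindian/African: one haplotype agrees (African)
  r <- match_diploid_calls(c(1L, 3L), c(2L, 1L))
  expect_equal(r$agreement, 1)
  expect_equal(r$alignment, c(2L, 1L))
  expect_true(any(r$pairs[, 1] == 1L & r$pairs[, 2] == 1L))
  expect_equal(match_diploid_calls(c(2L, 3L), c(2L, 3L))$agreement, 2)
  # exhaustive grid vs brute-force maximum over the two alignments
  up <- unordered_pairs(3)
  for (a in up) for (b in up) {
    brute <- max(sum(a == b), (a[1] == b[2]) + (a[2] == b[1]))
    expect_equal(match_diploid_calls(a, b)$agreement, brute)
  }
})

test_that("concordance of identical call sets is a diagonal table", {
  set.seed(24)
  cm <- matrix(sample(1:3, 20 * 30, replace = TRUE), 20, 30)
  ca <- diploid_calls(cm)
  conc <- concordance_table(ca, ca)
  expect_equal(conc$agreement, 1.0)
  expect_equal(sum(conc$table), 1.0)
  expect_equal(conc$table[upper.tri(conc$table)], rep(0, 3))
  expect_equal(conc$table[lower.tri(conc$table)], rep(0, 3))
})

test_that("concordance is invariant to within-sample phase swaps", {
  set.seed(25)
  cm <- matrix(sample(1:3, 20 * 30, replace = TRUE), 20, 30)
  swap <- cm
  for (s in seq_len(10)) {
    r <- c(2 * s - 1, 2 * s)
    swap[r, ] <- cm[rev(r), ]
  }
  conc <- concordance_table(diploid_calls(cm), diploid_calls(swap))
  expect_equal(conc$agreement, 1.0)
})

test_that("concordance with corrupted calls matches a per-cell enumeration oracle", {
  set.seed(26)
  n_s <- 20; M <- 50; K <- 3
  cm <- matrix(sample(1:K, 2 * n_s * M, replace = TRUE), 2 * n_s, M)
  cb <- cm
  relabel <- matrix(runif(length(cb)) < 0.05, nrow(cb), ncol(cb))
  cb[relabel] <- ((cb[relabel] + sample(1:(K - 1), sum(relabel),
                                        replace = TRUE) - 1L) %% K) + 1L
  conc <- concordance_table(diploid_calls(cm), diploid_calls(cb))
  # oracle: loop every (sample, site), align by brute force, recount
  counts <- matrix(0, K, K)
  for (s in seq_len(n_s)) for (m in seq_len(M)) {
    a <- cm[c(2 * s - 1, 2 * s), m]; b <- cb[c(2 * s - 1, 2 * s), m]
    ident <- sum(a == b); sw <- (a[1] == b[2]) + (a[2] == b[1])
    bb <- if (sw > ident) rev(b) else b
    counts[a[1], bb[1]] <- counts[a[1], bb[1]] + 1
    counts[a[2], bb[2]] <- counts[a[2], bb[2]] + 1
  }
  expect_equal(unname(conc$table), counts / sum(counts))
  # transpose symmetry under swapping the inputs
  conc_ba <- concordance_table(diploid_calls(cb), diploid_calls(cm))
  expect_equal(unname(conc_ba$table), t(unname(conc$table)))
})

test_that("highest-posterior summaries match a loop-based oracle", {
  probs <- array(0, dim = c(1, 1, 3))
  probs[1, 1, ] <- c(0.99, 0.009, 0.001)
  s <- avg_max_posterior(la_posterior(probs, ANC))
  expect_equal(s$mean_max_posterior[s$ancestry == "African"], 0.99)
  expect_equal(s$n_cells[s$ancestry == "African"], 1L)

  uni <- array(1 / 3, dim = c(2, 4, 3))
  expect_message(s <- avg_max_posterior(la_posterior(uni, ANC)), "tie")
  expect_equal(s$mean_max_posterior[s$ancestry == "overall"], 1 / 3)

  set.seed(27)
  raw <- array(runif(4 * 3 * 3), dim = c(4, 3, 3))
  tot <- apply(raw, c(1, 2), sum)
  probs <- raw / array(rep(tot, 3), dim = dim(raw))
  s <- avg_max_posterior(la_posterior(probs, ANC))
  # oracle: explicit loops
  mx <- c(); arg <- c()
  for (h in 1:4) for (m in 1:3) {
    v <- probs[h, m, ]
    mx <- c(mx, max(v)); arg <- c(arg, which.max(v))
  }
  for (k in 1:3) {
    got <- s$mean_max_posterior[s$ancestry == ANC[k]]
    if (any(arg == k)) expect_equal(got, mean(mx[arg == k]))
    else expect_true(is.na(got))
  }
  expect_equal(s$mean_max_posterior[s$ancestry == "overall"], mean(mx))
})
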