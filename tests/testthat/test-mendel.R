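# Mendelian consistency predicates and genome-wide inconsistency rates.

test_that("pair consistency matches the transmission-enumeration oracle (36 cases)", {
  # mother African/European with a two-Amerindian child is inconsistent
  expect_false(consistent_pair(c(1L, 3L), c(2L, 2L)))
  expect_true(consistent_pair(c(3L, 3L), c(3L, 1L)))
  for (p in unordered_pairs(3)) for (ch in unordered_pairs(3)) {
    expect_equal(consistent_pair(p, ch), oracle_pair(p, ch),
                 info = paste("parent", paste(p, collapse = "/"),
                              "child", paste(ch, collapse = "/")))
  }
})

test_that("trio consistency matches the enumeration oracle (216 cases)", {
  expect_true(consistent_trio(c(1L, 3L), c(3L, 3L), c(1L, 3L)))
  expect_false(consistent_trio(c(1L, 1L), c(1L, 1L), c(1L, 3L)))
  up <- unordered_pairs(3)
  for (mo in up) for (fa in up) for (ch in up) {
    expect_equal(consistent_trio(mo, fa, ch), oracle_trio(mo, fa, ch))
  }
})

test_that("X-chromosome predicates match transmission enumeration", {
  expect_true(consistent_x("mother-son", c(1L, 3L), 3L))
  expect_false(consistent_x("mother-son", c(1L, 3L), 2L))
  # father African, mother European/European, daughter African/African:
  # the daughter's remaining African cannot come from the mother
  expect_false(consistent_x("mother-father-daughter", c(3L, 3L),
                            c(1L, 1L), father = 1L))
  up <- unordered_pairs(3)
  for (mo in up) {
    for (s in 1:3) {
      expect_equal(consistent_x("mother-son", mo, s),
                   oracle_x_ms(mo, s))
    }
    for (d in up) {
      expect_equal(consistent_x("mother-daughter", mo, d),
                   oracle_x_md(mo, d))
      for (f in 1:3) {
        expect_equal(consistent_x("mother-father-daughter", mo, d,
                                  father = f),
                     oracle_x_mfd(mo, f, d))
      }
    }
  }
  expect_error(consistent_x("mother-son", c(1L, 2L), c(1L, 2L)),
               "haploid")
  expect_error(consistent_x("mother-father-daughter", c(1L, 2L),
                            c(1L, 2L), father = c(1L, 2L)), "haploid")
})

test_that("predicates are phase-invariant (unordered multisets)", {
  set.seed(41)
  for (i in 1:200) {
    mo <- sample(1:3, 2, replace = TRUE)
    fa <- sample(1:3, 2, replace = TRUE)
    ch <- sample(1:3, 2, replace = TRUE)
    expect_equal(consistent_trio(mo, fa, ch),
                 consistent_trio(rev(mo), rev(fa), rev(ch)))
    expect_equal(consistent_pair(mo, ch),
                 consistent_pair(rev(mo), rev(ch)))
  }
})

test_that("every pair-consistent combination is trio-consistent for some father", {
  up <- unordered_pairs(3)
  for (p in up) for (ch in up) {
    if (consistent_pair(p, ch)) {
      some_father <- any(vapply(up, function(f) {
        consistent_trio(p, f, ch)
      }, logical(1)))
      expect_true(some_father)
    }
  }
})

test_that("a hand-written trio with one bad site in four has rate 0.25", {
  # sites: consistent, consistent, inconsistent, consistent
  mo <- rbind(c(1L, 1L, 1L, 1L), c(3L, 3L, 3L, 3L))   # {A,E} everywhere
  fa <- rbind(c(3L, 3L, 3L, 3L), c(3L, 3L, 3L, 3L))   # {E,E}
  ch <- rbind(c(1L, 3L, 2L, 3L), c(3L, 3L, 2L, 3L))   # site 3: {Amr,Amr}
  cm <- rbind(mo, fa, ch)
  meta <- hap_meta(rep(c("mo", "fa", "ch"), each = 2), rep(1:2, 3),
                   c("female", "female", "male", "male", "male", "male"))
  calls <- la_calls(cm, ANC, meta, site_map(rep("1", 4), 1:4))
  ped <- classify_pedigree(data.frame(child = "ch", mother = "mo",
                                      father = "fa", sex = "M"))
  rep <- inconsistency_rates(calls, ped, "autosome")
  expect_equal(rep$summary$rate, 0.25)
  expect_equal(rep$summary$n_evaluated, 4L)
})

test_that("missing calls drop cells from numerator and denominator", {
  mo <- rbind(c(1L, NA, 1L), c(3L, 3L, 3L))
  fa <- rbind(c(3L, 3L, 3L), c(3L, 3L, 3L))
  ch <- rbind(c(2L, 2L, 1L), c(2L, 2L, 3L))  # sites 1,2 inconsistent
  cm <- rbind(mo, fa, ch)
  meta <- hap_meta(rep(c("mo", "fa", "ch"), each = 2), rep(1:2, 3),
                   "female")
  calls <- la_calls(cm, ANC, meta, site_map(rep("1", 3), 1:3))
  ped <- classify_pedigree(data.frame(child = "ch", mother = "mo",
                                      father = "fa", sex = "F"))
  rep <- inconsistency_rates(calls, ped, "autosome")
  # site 2 excluded (mother missing): 1 inconsistent of 2 evaluated
  expect_equal(rep$summary$n_evaluated, 2L)
  expect_equal(rep$summary$rate, 0.5)
})

test_that("true transmitted ancestries are consistent; families missing from calls are skipped", {
  cfg <- sim_config(n_ref = 0, n_admixed = 0, n_trios = 8, M = 300,
                    seed = 42)
  sim <- simulate_cohort(cfg)
  rep <- inconsistency_rates(sim$truth, sim$ped, "autosome")
  expect_equal(rep$summary$rate[rep$summary$config == "trio"], 0)
  # evaluating mothers only gives the pair configuration, still 0
  rep_pair <- inconsistency_rates(sim$truth, as_pairs(sim$ped), "autosome")
  expect_equal(rep_pair$summary$rate[rep_pair$summary$config == "pair"], 0)
  # a family referencing an absent sample is skipped with a message
  bad <- sim$ped
  bad$mother[1] <- "nobody"
  expect_message(rep2 <- inconsistency_rates(sim$truth, bad, "autosome"),
                 "skipping")
  expect_equal(sum(rep2$summary$n_families), nrow(sim$ped) - 1L)
})

test_that("corruption raises the trio rate above the pair rate", {
  cfg <- sim_config(n_ref = 0, n_admixed = 0, n_trios = 20, M = 500,
                    seed = 43)
  sim <- simulate_cohort(cfg)
  noisy <- corrupt_calls(sim$truth, 0.02, seed = 43)
  trio <- inconsistency_rates(noisy, sim$ped, "autosome")$summary
  pair <- inconsistency_rates(noisy, as_pairs(sim$ped),
                              "autosome")$summary
  expect_gt(trio$rate[trio$config == "trio"],
            pair$rate[pair$config == "pair"])
})

test_that("X rates are zero on truth for all three configurations", {
  cfg <- sim_config(n_trios = 10, M = 300, seed = 44)
  sim <- simulate_x_cohort(cfg)
  rep <- inconsistency_rates(sim$truth, sim$ped, "X")
  expect_true(all(rep$summary$rate == 0))
  expect_setequal(rep$summary$config,
                  c("mother-son", "mother-father-daughter"))
  # dropping fathers turns daughters into mother-daughter pairs
  rep_md <- inconsistency_rates(sim$truth, as_pairs(sim$ped), "X")
  expect_true("mother-daughter" %in% rep_md$summary$config)
  expect_true(all(rep_md$summary$rate == 0))
})
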