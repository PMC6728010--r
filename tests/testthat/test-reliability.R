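test_that("one-way ANOVA matches the sum-of-squares oracle", {
  m <- matrix(c(1, 2, 3, 4, 5, 6), nrow = 3, byrow = TRUE)
  a <- anova_oneway(m)
  o <- aov_oracle(m)
  expect_equal(a$ms_between, o$ms_between, tolerance = 1e-12)
  expect_equal(a$ms_within, o$ms_within, tolerance = 1e-12)
  icc <- icc_oneway_average(m)
  expect_equal(icc$icc, (o$ms_between - o$ms_within) / o$ms_between,
               tolerance = 1e-12)
})

test_that("ANOVA is symmetric in rater slots and flags degenerate inputs", {
  set.seed(12)
  m <- matrix(rnorm(24), nrow = 6)
  mp <- m[, sample(ncol(m))]
  # permuting rater slots within each subject leaves both mean squares alone
  for (i in seq_len(nrow(m))) mp[i, ] <- sample(m[i, ])
  expect_equal(anova_oneway(m)$ms_between, anova_oneway(mp)$ms_between)
  expect_equal(anova_oneway(m)$ms_within, anova_oneway(mp)$ms_within)
  const <- matrix(2, 4, 3)
  expect_equal(anova_oneway(const)$ms_between, 0)
  expect_equal(anova_oneway(const)$ms_within, 0)
  expect_equal(icc_oneway_average(const)$status, "degenerate")
  expect_error(anova_oneway(matrix(c(1, NA, 2, 3), 2)), "missing")
  expect_error(anova_oneway(matrix(1:2, 1)), "at least 2")
})

test_that("perfect agreement gives ICC exactly 1, pure noise gives ICC < 0", {
  m <- cbind(1:6, 1:6, 1:6)
  expect_identical(icc_oneway_average(m)$icc, 1)
  # near-identical subject means, large within-subject spread
  m2 <- rbind(c(1, 3), c(3, 1.1), c(2, 2))
  expect_warning(r <- icc_oneway_average(m2), "negative")
  expect_lt(r$icc, 0)
})

test_that("ICC is invariant to location shifts and positive rescaling", {
  set.seed(8)
  m <- matrix(rnorm(30, sd = 0.5) + rep(rnorm(10, sd = 2), 3), nrow = 10)
  base <- icc_oneway_average(m)$icc
  expect_equal(icc_oneway_average(m + 100)$icc, base, tolerance = 1e-12)
  expect_equal(icc_oneway_average(m * 3.7)$icc, base, tolerance = 1e-12)
})

test_that("average-measures reliability grows with the panel size", {
  # Spearman-Brown direction: same per-rater reliability, more raters
  sim_icc <- function(k, seed) {
    set.seed(seed)
    truth <- rnorm(200)
    m <- matrix(rnorm(200 * k, mean = truth), nrow = 200)
    icc_oneway_average(m)$icc
  }
  m2 <- mean(sapply(1:10, function(s) sim_icc(2, s)))
  m6 <- mean(sapply(1:10, function(s) sim_icc(6, s + 100)))
  expect_gt(m6, m2)
})

test_that("guarding ICC on default cohorts sits in the good range", {
  iccs <- sapply(c(5, 17, 29, 41), function(s) {
    co <- small_cohort(seed = s)
    it <- icc_table(co$instances, co$ratings)
    it$icc[it$measure == "guarding" & it$exercise == "all"]
  })
  expect_true(all(iccs >= 0.6 & iccs <= 0.85))
})

test_that("grouped ICC is reported per exercise type", {
  co <- small_cohort(seed = 11)
  it <- icc_table(co$instances, co$ratings)
  expect_setequal(unique(it$exercise),
                  c("all", "sit_to_stand", "forward_flexion", "full_flexion"))
  expect_setequal(unique(it$measure), c("guarding", "self_efficacy"))
  # grouped values are computed from that exercise's instances only
  sts <- co$instances$instance_id[co$instances$exercise == "sit_to_stand"]
  sub <- co$ratings[co$ratings$instance_id %in% sts, ]
  m <- matrix(sub$guarding[order(sub$instance_id, sub$rater_id)],
              ncol = 4, byrow = TRUE)
  expect_equal(it$icc[it$measure == "guarding" & it$exercise == "sit_to_stand"],
               suppressWarnings(icc_oneway_average(m)$icc))
})
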