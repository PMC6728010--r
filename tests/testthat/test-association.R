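test_that("spearman handles monotone, reversed and tied inputs", {
  expect_equal(spearman(c(1, 2, 3), c(10, 20, 30))$rho, 1)
  expect_equal(spearman(c(1, 2, 3), c(3, 2, 1))$rho, -1)
  x <- c(1, 2, 2, 4); y <- c(1, 3, 2, 4)
  expect_equal(spearman(x, y)$rho, spearman_oracle(x, y), tolerance = 1e-14)
  # cross-check against the stats implementation
  expect_equal(spearman(x, y)$rho, stats::cor(x, y, method = "spearman"),
               tolerance = 1e-14)
  expect_equal(spearman(c(2, 2, 2), c(1, 2, 3))$status, "constant")
  expect_error(spearman(c(1, 2), c(1, 2)), "at least 3")
})

test_that("spearman is invariant under strictly monotone transforms", {
  set.seed(21)
  for (i in 1:20) {
    x <- rnorm(30); y <- rnorm(30) + 0.5 * x
    base <- spearman(x, y)$rho
    expect_equal(spearman(exp(x), y)$rho, base, tolerance = 1e-12)
    expect_equal(spearman(x, y^3 + 2 * y)$rho, base, tolerance = 1e-12)
  }
})

test_that("the p-value matches the t approximation", {
  set.seed(4)
  x <- rnorm(40); y <- rnorm(40) + 0.4 * x
  s <- spearman(x, y)
  tstat <- s$rho * sqrt((s$n - 2) / (1 - s$rho^2))
  expect_equal(s$p_value, 2 * pt(-abs(tstat), s$n - 2))
  expect_gte(s$p_value, 0)
  expect_lte(s$p_value, 1)
})

test_that("correlation matrix is symmetric with unit diagonal", {
  rec <- small_records(seed = 19)
  cm <- correlation_matrix(rec)
  expect_equal(cm$rho, t(cm$rho))
  expect_equal(unname(diag(cm$rho)), rep(1, 5))
  expect_true(all(abs(cm$rho) <= 1))
  expect_equal(nrow(cm$table), 10)
  # pairwise-complete sample sizes
  rec2 <- rec
  rec2$pain[1:5] <- NA
  cm2 <- correlation_matrix(rec2)
  expect_equal(cm2$n["pain", "anxiety"],
               sum(!is.na(rec2$pain) & !is.na(rec2$anxiety)))
})

test_that("a constant variable is flagged, not propagated as NaN", {
  rec <- small_records(seed = 19)
  rec$distress <- 12
  cm <- correlation_matrix(rec)
  expect_true(all(is.na(cm$rho["distress", -5])))
  expect_true(all(cm$table$status[cm$table$var2 == "distress" |
                                    cm$table$var1 == "distress"] ==
                    "constant"))
})

test_that("dichotomization cuts match the lower/higher rules", {
  rec <- data.frame(instance_id = as.character(1:7), guarding = 0:6 %% 5,
                    self_efficacy = c(1, 2, 2.5, 3, 2, 1.5, 2),
                    pain = c(4, 5, 0, 10, NA, 3, 7),
                    anxiety = c(4, 5, 2, 9, 1, NA, 6),
                    distress = c(19, 20, 0, 39, 18, 25, NA))
  d <- dichotomize(rec)
  expect_equal(d$pain_level[1:4], c("lower", "higher", "lower", "higher"))
  expect_true(is.na(d$pain_level[5]))
  expect_equal(d$anxiety_level[1:2], c("lower", "higher"))
  expect_equal(d$distress_level[1:2], c("lower", "higher"))
  expect_equal(d$self_efficacy_level[1:4],
               c("lower", "lower", "higher", "higher"))
  bad <- rec; bad$distress[1] <- 40
  expect_error(dichotomize(bad), "out of range")
})

test_that("frequency table conserves counts", {
  rec <- dichotomize(small_records(seed = 23))
  ft <- guarding_frequency_table(rec)
  for (v in c("pain", "anxiety", "distress", "self_efficacy")) {
    expect_equal(sum(ft$count[ft$variable == v]),
                 sum(!is.na(rec[[paste0(v, "_level")]])))
  }
  # degenerate single-cell case
  one <- data.frame(instance_id = "a", guarding = 0L, self_efficacy = 3,
                    pain = 1, anxiety = 1, distress = 5)
  ft1 <- guarding_frequency_table(dichotomize(one))
  expect_equal(sum(ft1$count), 4)  # one record per variable panel
  expect_equal(sum(ft1$count[ft1$count > 0 & ft1$variable == "pain"]), 1)
})

test_that("unguarded instances are predominantly low-anxiety", {
  # generator property: anxiety raises guarding, so score-0 instances skew
  # toward the lower anxiety stratum
  lower <- higher <- 0
  for (s in c(2, 12, 22, 32, 42)) {
    rec <- dichotomize(small_records(seed = s))
    ft <- guarding_frequency_table(rec)
    g0 <- ft[ft$variable == "anxiety" & ft$guarding == 0, ]
    lower <- lower + g0$count[g0$level == "lower"]
    higher <- higher + g0$count[g0$level == "higher"]
  }
  expect_gt(lower, higher)
})
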