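test_that("an isolated node predicts its fitted mean", {
  set.seed(33)
  m <- cbind(a = rnorm(100, mean = 7), b = rnorm(100))
  fit <- bic_score(m, dag(c("a", "b")))
  pred <- predict_conditional_mean(fit, as.data.frame(m), "a")
  expect_equal(pred, rep(mean(m[, "a"]), 100), tolerance = 1e-10)
})

test_that("noiseless chains are predicted exactly", {
  a <- rnorm(200)
  m <- cbind(a = a, b = 2 * a + 1, c = -1.5 * (2 * a + 1))
  g <- dag(c("a", "b", "c"), rbind(c("a", "b"), c("b", "c")))
  fit <- bic_score(m, g)
  for (mode in c("full", "parents")) {
    pred <- predict_conditional_mean(fit, as.data.frame(m), "b", mode = mode)
    expect_lt(mean((pred - m[, "b"])^2), 1e-12)
  }
})

test_that("full-conditional prediction matches the joint-covariance oracle", {
  d <- sem_draws(600, seed = 41)
  g <- hill_climb(d, seed = 1, n_restarts = 3)$dag
  fit <- bic_score(d, g)
  jm <- implied_joint(fit)
  target <- "guarding"
  rest <- setdiff(colnames(d), target)
  # oracle: conditional-normal formula assembled by hand
  w <- solve(jm$cov[rest, rest]) %*% jm$cov[rest, target]
  oracle <- jm$mean[target] +
    as.matrix(sweep(as.data.frame(d)[rest], 2, jm$mean[rest])) %*% w
  pred <- predict_conditional_mean(fit, as.data.frame(d), target)
  expect_equal(pred, drop(oracle), tolerance = 1e-8)
  # and the implied joint reproduces the SEM moments when the truth is fitted
  tfit <- bic_score(d, truth_analysis_dag(default_truth()))
  jm2 <- implied_joint(tfit)
  expect_equal(unname(jm2$mean), unname(colMeans(d)), tolerance = 1e-6)
})

test_that("parents-only mode is the child regression", {
  d <- sem_draws(400, seed = 43)
  g <- truth_analysis_dag(default_truth())
  fit <- bic_score(d, g)
  pred <- predict_conditional_mean(fit, as.data.frame(d), "anxiety",
                                   mode = "parents")
  ref <- lm(anxiety ~ pain + distress, data = as.data.frame(d))
  expect_equal(pred, unname(fitted(ref)), tolerance = 1e-8)
})

test_that("the empty-graph learner reproduces the mean-predictor baseline", {
  d <- sem_draws(300, seed = 51)
  r <- cross_validated_mse(d, learner = "empty", target = "guarding",
                           seed = 4)
  v <- var(d[, "guarding"])
  expect_lt(abs(r$mean_mse - v) / v, 0.15)
})

test_that("cross-validation partitions records and is seed-deterministic", {
  d <- sem_draws(120, seed = 52)
  r1 <- cross_validated_mse(d, learner = "hill_climb", seed = 11)
  r2 <- cross_validated_mse(d, learner = "hill_climb", seed = 11)
  expect_identical(r1$fold_assignment, r2$fold_assignment)
  expect_identical(r1$mean_mse, r2$mean_mse)
  expect_equal(sort(unique(r1$fold_assignment)), 1:5)
  expect_equal(sum(r1$fold_n), nrow(d))
  # weighted fold mean equals the overall mean squared error
  expect_equal(r1$mean_mse,
               sum(r1$fold_mse * r1$fold_n) / sum(r1$fold_n))
})

test_that("patient-level folds keep a patient's instances together", {
  co <- small_cohort(seed = 61)
  rec <- assemble_records(co$instances, co$ratings)
  m <- records_matrix(rec)
  grp <- rec$patient_id[stats::complete.cases(
    rec[c("guarding", "self_efficacy", "pain", "anxiety", "distress")])]
  r <- cross_validated_mse(m, learner = "empty", seed = 2, group_by = grp)
  folds_per_patient <- tapply(r$fold_assignment, grp,
                              function(f) length(unique(f)))
  expect_true(all(folds_per_patient == 1))
})

test_that("network prediction beats the baseline on cohort data", {
  wins <- 0
  for (s in c(3, 13, 23, 33, 43)) {
    co <- small_cohort(seed = s)
    m <- records_matrix(assemble_records(co$instances, co$ratings))
    hc <- cross_validated_mse(m, "hill_climb", seed = s, n_restarts = 3)
    base <- cross_validated_mse(m, "empty", seed = s)
    if (hc$mean_mse < base$mean_mse) wins <- wins + 1
  }
  expect_gte(wins, 4)
})
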