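test_that("same seed gives bit-identical cohorts", {
  c1 <- simulate_cohort(generator_config(seed = 42))
  c2 <- simulate_cohort(generator_config(seed = 42))
  expect_identical(c1$instances, c2$instances)
  expect_identical(c1$ratings, c2$ratings)
})

test_that("cohort dimensions respect the instance-count support", {
  co <- simulate_cohort(generator_config(n_patients = 17, seed = 9))
  n <- nrow(co$instances)
  expect_gte(n, 17)
  expect_lte(n, 153)
  # every instance carries exactly one label per rater
  cnt <- table(co$ratings$instance_id)
  expect_true(all(cnt == 4))
  expect_setequal(names(cnt), co$instances$instance_id)
})

test_that("distress is constant within patient", {
  co <- simulate_cohort(generator_config(seed = 3))
  per_patient <- tapply(co$instances$distress, co$instances$patient_id,
                        function(x) length(unique(x)))
  expect_true(all(per_patient == 1))
})

test_that("invalid generator settings are rejected", {
  expect_error(generator_config(instances_per_patient =
                                  list(min = 0, max = 9, mean = 6)),
               "support")
  expect_error(generator_config(instances_per_patient =
                                  list(min = 1, max = 12, mean = 6)),
               "support")
  expect_error(rater_model(selfeff_thresholds = c(1, 1)), "increasing")
  expect_error(generator_config(exercise_mix = c(sit_to_stand = 0.5,
                                                 forward_flexion = 0.5,
                                                 full_flexion = 0.5)),
               "sum to 1")
})

test_that("degenerate noise collapses a patient's instances to one record", {
  tr <- default_truth()
  tr$residual_sd[] <- 1e-9
  tr$residual_sd[["distress"]] <- 1e-9
  tr$patient_intercept_sd[] <- 0
  # deterministic raters: no impression/noise, no bias, saturating slope
  tr$raters <- rater_model(guarding_intercept = 5, guarding_slope = 10,
                           rater_bias = rep(0, 4), impression_sd = 0,
                           selfeff_noise_sd = 0)
  co <- simulate_cohort(generator_config(n_patients = 5, seed = 8), tr)
  rec <- assemble_records(co$instances, co$ratings)
  vars <- c("guarding", "self_efficacy", "pain", "anxiety", "distress")
  for (p in unique(rec$patient_id))
    expect_equal(nrow(unique(rec[rec$patient_id == p, vars])), 1)
})

test_that("SEM draws match the closed-form covariance", {
  tr <- default_truth()
  mom <- truth_moments(tr)
  x <- simulate_truth(tr, 2e5, seed = 77)
  expect_equal(colMeans(x), mom$mean, tolerance = 0.02)
  # element-wise agreement of the covariance, scaled by its magnitude
  expect_lt(max(abs(stats::cov(x) - mom$cov)) / max(abs(mom$cov)), 0.02)
})

test_that("guarding/self-efficacy and pain/anxiety are the strongest pairs", {
  # latent level: the guarding/self-efficacy link dominates
  mom <- truth_moments(default_truth())
  r <- stats::cov2cor(mom$cov)
  expect_equal(max(abs(r[upper.tri(r)])),
               abs(r["guarding_latent", "selfeff_latent"]))
  # observed level (the Table-1 analogue): rater observation attenuates the
  # pairs unevenly, and the top two are guarding/self-efficacy then
  # pain/anxiety
  co <- simulate_cohort(generator_config(n_patients = 1000, seed = 314))
  rec <- assemble_records(co$instances, co$ratings)
  rho <- correlation_matrix(rec)$rho
  off <- abs(rho[upper.tri(rho)])
  top2 <- sort(off, decreasing = TRUE)[2]
  expect_gte(abs(rho["guarding", "self_efficacy"]), top2)
  expect_gte(abs(rho["pain", "anxiety"]), top2)
})

test_that("cohort Spearman(pain, anxiety) matches a Monte-Carlo oracle", {
  # oracle: a large iid draw from the same SEM with the same integer
  # clipping, correlated by the same rank statistic
  tr <- default_truth()
  xo <- simulate_truth(tr, 1e6, seed = 1234)
  po <- pmin(pmax(round(xo[, "pain"]), 0), 10)
  ao <- pmin(pmax(round(xo[, "anxiety"]), 0), 10)
  oracle <- stats::cor(rank(po), rank(ao))
  co <- simulate_cohort(generator_config(n_patients = 500, seed = 55), tr)
  rec <- assemble_records(co$instances, co$ratings)
  got <- spearman(rec$pain, rec$anxiety)$rho
  expect_lt(abs(got - oracle), 0.05)
})

test_that("cohort round-trips through CSV", {
  co <- simulate_cohort(generator_config(n_patients = 4, seed = 2))
  dir <- withr::local_tempdir()
  write_cohort(co, dir)
  back <- read_cohort(dir)
  expect_equal(back$instances, co$instances)
  expect_equal(back$ratings, co$ratings)
  expect_true(file.exists(file.path(dir, "truth.json")))
})
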