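# Shared fixtures and independent oracles used across the test files.

# Independent sum-of-squares oracle for the one-way ANOVA decomposition:
# builds the long-format data and uses stats::aov, a route entirely separate
# from the package's closed-form computation.
aov_oracle <- function(m) {
  long <- data.frame(y = as.vector(t(m)),
                     subject = factor(rep(seq_len(nrow(m)), each = ncol(m))))
  tab <- summary(stats::aov(y ~ subject, data = long))[[1]]
  list(ms_between = tab["subject", "Mean Sq"],
       ms_within = tab["Residuals", "Mean Sq"])
}

# Brute-force Spearman oracle: average ranks built by hand (no rank()),
# Pearson formula applied directly.
spearman_oracle <- function(x, y) {
  avg_rank <- function(v) {
    r <- numeric(length(v))
    for (i in seq_along(v))
      r[i] <- sum(v < v[i]) + (sum(v == v[i]) + 1) / 2
    r
  }
  rx <- avg_rank(x); ry <- avg_rank(y)
  num <- sum((rx - mean(rx)) * (ry - mean(ry)))
  den <- sqrt(sum((rx - mean(rx))^2) * sum((ry - mean(ry))^2))
  num / den
}

# Small deterministic cohort for pipeline-level tests.
small_cohort <- function(seed = 101, n_patients = 17) {
  simulate_cohort(generator_config(n_patients = n_patients, seed = seed))
}

# Records and the complete-case analysis matrix for a seed.
small_records <- function(seed = 101) {
  co <- small_cohort(seed)
  assemble_records(co$instances, co$ratings)
}

# Hand-built toy instance/rating tables exercising the inclusion rule.
toy_tables <- function() {
  instances <- data.frame(
    patient_id = c("P1", "P1", "P2", "P3"),
    instance_id = c("i1", "i2", "i3", "i4"),
    exercise = c("sit_to_stand", "forward_flexion", "sit_to_stand",
                 "full_flexion"),
    challenge = c("low", "high", "low", "high"),
    pain = c(4, NA, NA, NA),
    anxiety = c(2, NA, NA, NA),
    distress = c(10, 10, NA, 25),
    stringsAsFactors = FALSE)
  ratings <- data.frame(
    instance_id = rep(c("i1", "i2", "i3", "i4"), each = 4),
    rater_id = rep(paste0("R", 1:4), times = 4),
    guarding = c(1, 1, 1, 0,  0, 0, 0, 0,  1, 1, 1, 1,  1, 0, 1, 0),
    self_efficacy = c("medium", "medium", "high", "high",
                      "low", "low", "low", "low",
                      "low", "medium", "high", "medium",
                      "high", "high", "high", "high"),
    stringsAsFactors = FALSE)
  list(instances = instances, ratings = ratings)
}

# Data simulated from a named 3-node structure, used by search tests.
chain_data <- function(n, seed, b1 = 0.8, b2 = 0.7) {
  set.seed(seed)
  a <- stats::rnorm(n)
  b <- b1 * a + stats::rnorm(n)
  c_ <- b2 * b + stats::rnorm(n)
  cbind(a = a, b = b, c = c_)
}

collider_data <- function(n, seed, noise = 0.5) {
  set.seed(seed)
  x <- stats::rnorm(n); y <- stats::rnorm(n)
  cbind(x = x, y = y, z = x + y + noise * stats::rnorm(n))
}

analysis_names <- c("pain", "anxiety", "distress", "guarding",
                    "self_efficacy")

# SEM draws renamed to the analysis variables.
sem_draws <- function(n, seed, truth = default_truth()) {
  x <- simulate_truth(truth, n, seed = seed)
  colnames(x) <- analysis_names
  x
}
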