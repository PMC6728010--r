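test_that("empty-graph BIC equals the univariate Gaussian closed form", {
  set.seed(42)
  m <- matrix(rnorm(3000), ncol = 3, dimnames = list(NULL, c("x", "y", "z")))
  f <- bic_score(m, dag(colnames(m)))
  n <- nrow(m)
  closed <- sum(apply(m, 2, function(v) {
    s2 <- mean((v - mean(v))^2)
    -n / 2 * (log(2 * pi * s2) + 1) - (2 / 2) * log(n)
  }))
  expect_equal(f$total_bic, closed, tolerance = 1e-10)
  expect_equal(f$total_bic,
               f$total_loglik - sum(sapply(f$families, `[[`, "param_count")) /
                 2 * log(n))
})

test_that("family fits agree with lm and param counts with |parents| + 2", {
  d <- chain_data(400, seed = 5)
  g <- dag(c("a", "b", "c"), rbind(c("a", "b"), c("b", "c")))
  f <- bic_score(d, g)
  ref <- lm(b ~ a, data = as.data.frame(d))
  expect_equal(unname(f$families$b$coef), unname(coef(ref)),
               tolerance = 1e-10)
  expect_equal(f$families$b$sigma2,
               sum(resid(ref)^2) / nrow(d), tolerance = 1e-10)
  expect_equal(sapply(f$families, `[[`, "param_count"),
               c(a = 2, b = 3, c = 3))
})

test_that("adding an edge changes only the child's family score", {
  d <- sem_draws(300, seed = 8)
  g0 <- dag(colnames(d), rbind(c("pain", "anxiety")))
  g1 <- dag(colnames(d), rbind(c("pain", "anxiety"),
                               c("anxiety", "guarding")))
  f0 <- bic_score(d, g0); f1 <- bic_score(d, g1)
  for (v in colnames(d)) {
    if (v == "guarding") next
    expect_equal(f0$families[[v]]$score, f1$families[[v]]$score,
                 tolerance = 1e-12)
  }
  expect_false(isTRUE(all.equal(f0$families$guarding$score,
                                f1$families$guarding$score)))
})

test_that("Markov-equivalent two-node DAGs score identically", {
  set.seed(14)
  m <- cbind(a = rnorm(500))
  m <- cbind(m, b = 0.6 * m[, "a"] + rnorm(500))
  s1 <- bic_score(m, dag(c("a", "b"), rbind(c("a", "b"))))$total_bic
  s2 <- bic_score(m, dag(c("a", "b"), rbind(c("b", "a"))))$total_bic
  expect_equal(s1, s2, tolerance = 1e-8)
})

test_that("collinear parents are flagged with -Inf score", {
  set.seed(3)
  a <- rnorm(100)
  m <- cbind(a = a, b = 2 * a, c = rnorm(100))
  g <- dag(c("a", "b", "c"), rbind(c("a", "c"), c("b", "c")))
  f <- bic_score(m, g)
  expect_true(f$families$c$singular)
  expect_identical(f$families$c$score, -Inf)
  expect_identical(f$total_bic, -Inf)
})

test_that("arc strengths follow the deletion definition", {
  d <- chain_data(500, seed = 77)
  g <- dag(c("a", "b", "c"), rbind(c("a", "b")))
  s <- arc_strengths(d, g)
  f_full <- bic_score(d, g)$total_bic
  f_empty <- bic_score(d, dag(c("a", "b", "c")))$total_bic
  expect_equal(s$strength, f_full - f_empty, tolerance = 1e-8)

  # strength of x -> y equals the change in y's family score alone
  g2 <- dag(c("a", "b", "c"), rbind(c("a", "b"), c("b", "c")))
  s2 <- arc_strengths(d, g2)
  fit_ab <- bic_score(d, g2)
  fit_drop <- bic_score(d, dag(c("a", "b", "c"), rbind(c("a", "b"))))
  expect_equal(s2$strength[s2$tail == "b" & s2$head == "c"],
               fit_ab$families$c$score - fit_drop$families$c$score,
               tolerance = 1e-8)

  # at a hill-climb optimum every arc survives deletion scrutiny
  hc <- hill_climb(sem_draws(800, seed = 10))
  st <- arc_strengths(sem_draws(800, seed = 10), hc)
  expect_true(all(st$strength >= -1e-9))
})
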