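# Fisher-z test of conditional independence for Gaussian data: the
# constraint-based primitive behind Grow-Shrink and IAMB.

# Partial correlation of x and y given Z from the inverse covariance of the
# involved block; falls back to correlating OLS residuals if the block is
# numerically singular.
partial_correlation <- function(data, x, y, Z = character(0)) {
  cols <- c(x, y, Z)
  S <- stats::cov(data[, cols, drop = FALSE])
  P <- tryCatch(solve(S), error = function(e) NULL)
  if (!is.null(P)) return(-P[1, 2] / sqrt(P[1, 1] * P[2, 2]))
  if (length(Z) == 0) return(stats::cor(data[, x], data[, y]))
  XZ <- cbind(1, data[, Z, drop = FALSE])
  rx <- stats::lm.fit(XZ, data[, x])$residuals
  ry <- stats::lm.fit(XZ, data[, y])$residuals
  stats::cor(rx, ry)
}

#' Fisher-z conditional-independence test
#'
#' Tests x independent of y given the conditioning set Z under a Gaussian
#' model: the partial correlation r is mapped to
#' `z = sqrt(n - |Z| - 3) * atanh(r)`, two-sided p from the standard normal.
#'
#' @param data complete numeric matrix/data.frame.
#' @param x,y column names.
#' @param Z character vector of conditioning column names (may be empty).
#' @param alpha significance level for the `independent` verdict.
#' @return list of class `"ci_test"` with `x`, `y`, `conditioning_set`,
#'   `partial_correlation`, `z_statistic`, `p_value`, `independent`, and
#'   `degenerate` (TRUE when |r| = 1 makes the statistic infinite).
#' @examples
#' d <- cbind(a = rnorm(200), b = rnorm(200))
#' fisher_z_ci_test(d, "a", "b")$p_value
#' @export
fisher_z_ci_test <- function(data, x, y, Z = character(0), alpha = 0.05) {
  data <- as.matrix(data)
  n <- nrow(data)
  if (n - length(Z) - 3 <= 0)
    stop("need n - |Z| - 3 > 0 observations for the Fisher-z test")
  r <- partial_correlation(data, x, y, Z)
  r <- max(min(r, 1), -1)
  degenerate <- abs(r) >= 1
  if (degenerate) {
    z <- sign(r) * Inf
    p <- 0
  } else {
    z <- sqrt(n - length(Z) - 3) * atanh(r)
    p <- 2 * stats::pnorm(-abs(z))
  }
  structure(list(x = x, y = y, conditioning_set = Z,
                 partial_correlation = r, z_statistic = z, p_value = p,
                 independent = p > alpha, degenerate = degenerate,
                 alpha = alpha, n = n),
            class = "ci_test")
}

#' @export
print.ci_test <- function(x, ...) {
  cond <- if (length(x$conditioning_set))
    paste(x$conditioning_set, collapse = ", ") else "{}"
  cat(sprintf("%s _||_ %s | %s : r = %.4f, z = %.3f, p = %.4g -> %s\n",
              x$x, x$y, cond, x$partial_correlation, x$z_statistic,
              x$p_value,
              if (x$independent) "independent" else "dependent"))
  invisible(x)
}
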