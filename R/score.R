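# Decomposable BIC scoring of linear-Gaussian networks.
#
# The score of a DAG factorizes over node families (child + its parents):
#   BIC(G) = sum_j [ logL_j - (p_j / 2) * log n ],  p_j = |parents_j| + 2,
# higher is better, natural log, residual variance with the MLE divisor n.
# Family fits are ordinary least squares computed from the moment matrix
# M = crossprod(cbind(1, X)), so scoring a family costs a small solve()
# regardless of n — this is what makes exhaustive search and repeated
# hill-climb scoring cheap.

score_stats <- function(data) {
  data <- as.matrix(data)
  if (!is.numeric(data)) stop("data must be numeric")
  if (anyNA(data) || any(!is.finite(data)))
    stop("data must be complete and finite")
  X <- cbind(`(Intercept)` = 1, data)
  list(M = crossprod(X), n = nrow(data), vars = colnames(data),
       cache = new.env(parent = emptyenv()))
}

# OLS fit of `child` on `parents` (names) from moment matrix; returns
# coefficients, residual variance (MLE), and the family log-likelihood.
family_fit <- function(st, child, parents) {
  idx <- c("(Intercept)", parents)
  A <- st$M[idx, idx, drop = FALSE]
  b <- st$M[idx, child]
  beta <- tryCatch(solve(A, b), error = function(e) NULL)
  if (is.null(beta))
    return(list(singular = TRUE, loglik = -Inf, score = -Inf))
  rss <- max(st$M[child, child] - sum(beta * b), 0)
  n <- st$n
  sigma2 <- max(rss / n, .Machine$double.xmin)
  loglik <- -n / 2 * (log(2 * pi * sigma2) + rss / (n * sigma2))
  p <- length(parents) + 2
  list(singular = FALSE, coef = beta, sigma2 = sigma2, loglik = loglik,
       param_count = p, score = loglik - p / 2 * log(n))
}

family_score <- function(st, child, parents) {
  key <- paste(child, paste(sort(parents), collapse = ","), sep = "|")
  hit <- st$cache[[key]]
  if (!is.null(hit)) return(hit)
  s <- family_fit(st, child, parents)$score
  st$cache[[key]] <- s
  s
}

#' BIC score and parameter fit of a linear-Gaussian network
#'
#' Fits each node on its parents by ordinary least squares (residual variance
#' with the maximum-likelihood divisor n) and returns the decomposable BIC in
#' the higher-is-better convention `logL - (p/2) log n`.
#'
#' @param data complete numeric matrix or data.frame, columns named after the
#'   DAG's nodes.
#' @param g a `guardnet_dag` whose nodes are columns of `data`.
#' @return object of class `"gaussian_fit"`: list with `dag`, per-node
#'   `families` (coef, sigma2, loglik, param_count, score), `total_loglik`,
#'   `total_bic`, `n`.
#' @examples
#' x <- cbind(a = rnorm(100))
#' x <- cbind(x, b = 2 * x[, "a"] + rnorm(100))
#' bic_score(x, dag(c("a", "b"), rbind(c("a", "b"))))$total_bic
#' @export
bic_score <- function(data, g) {
  st <- if (inherits(data, "score_stats")) data else score_stats(data)
  fit_from_stats(st, g)
}

fit_from_stats <- function(st, g) {
  if (!all(g$nodes %in% st$vars))
    stop("DAG nodes missing from data: ",
         paste(setdiff(g$nodes, st$vars), collapse = ", "))
  if (st$n <= max(colSums(g$amat)) + 2)
    stop("too few rows for the largest family")
  fams <- lapply(g$nodes, function(v) family_fit(st, v, dag_parents(g, v)))
  names(fams) <- g$nodes
  structure(list(dag = g,
                 families = fams,
                 total_loglik = sum(vapply(fams, `[[`, 0, "loglik")),
                 total_bic = sum(vapply(fams, `[[`, 0, "score")),
                 n = st$n),
            class = "gaussian_fit")
}

#' @export
print.gaussian_fit <- function(x, ...) {
  cat(sprintf("Linear-Gaussian network fit: %d nodes, %d edges, n = %d\n",
              length(x$dag$nodes), nrow(dag_edges(x$dag)), x$n))
  cat(sprintf("  total log-likelihood %.3f,  BIC (higher is better) %.3f\n",
              x$total_loglik, x$total_bic))
  invisible(x)
}

dag_total_score <- function(st, g) {
  sum(vapply(g$nodes, function(v) family_score(st, v, dag_parents(g, v)), 0))
}

#' Arc strengths of a fitted network
#'
#' For each edge, the decrease in the network's BIC if that edge alone were
#' removed: `strength = BIC(G) - BIC(G minus edge)`. At a deletion-local
#' optimum all strengths are non-negative. Strengths above 10 are flagged as
#' highly meaningful, the conventional reading of large score differences.
#'
#' @param data the data the network was fitted on.
#' @param fit a `gaussian_fit` (or a `guardnet_dag`, which is fitted first).
#' @return data.frame with tail, head, strength, highly_meaningful, sorted by
#'   decreasing strength.
#' @export
arc_strengths <- function(data, fit) {
  g <- if (inherits(fit, "gaussian_fit")) fit$dag else fit
  st <- score_stats(as.matrix(data)[, g$nodes, drop = FALSE])
  total <- dag_total_score(st, g)
  e <- dag_edges(g)
  if (nrow(e) == 0)
    return(data.frame(tail = character(0), head = character(0),
                      strength = numeric(0), highly_meaningful = logical(0)))
  strength <- vapply(seq_len(nrow(e)), function(i) {
    pa <- setdiff(dag_parents(g, e[i, "head"]), e[i, "tail"])
    delta_head <- family_score(st, e[i, "head"], pa) -
      family_score(st, e[i, "head"], dag_parents(g, e[i, "head"]))
    -delta_head  # only the head family changes (decomposability)
  }, 0)
  out <- data.frame(tail = e[, "tail"], head = e[, "head"],
                    strength = strength,
                    highly_meaningful = strength > 10)
  out[order(-out$strength), , drop = FALSE]
}
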