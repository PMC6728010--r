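# Prediction from a fitted linear-Gaussian network: either the child
# regression on its parents, or the exact conditional mean under the joint
# multivariate normal the network implies.

#' Joint normal implied by a fitted network
#'
#' Solves the structural equations for the mean vector and covariance matrix:
#' with coefficient matrix B (B[i, j] the coefficient of parent i in child
#' j's regression), `mu = (I - B')^{-1} a` and
#' `Sigma = (I - B')^{-1} D (I - B')^{-T}` with D the residual variances.
#'
#' @param fit a `gaussian_fit` from [bic_score()] or [hill_climb()].
#' @return list with `mean` and `cov` over the fit's nodes.
#' @export
implied_joint <- function(fit) {
  nodes <- fit$dag$nodes
  k <- length(nodes)
  B <- matrix(0, k, k, dimnames = list(nodes, nodes))
  a <- numeric(k); names(a) <- nodes
  d <- numeric(k); names(d) <- nodes
  for (v in nodes) {
    fam <- fit$families[[v]]
    if (isTRUE(fam$singular))
      stop("family for node '", v, "' is singular; cannot form the joint")
    pa <- dag_parents(fit$dag, v)
    a[v] <- fam$coef[["(Intercept)"]]
    if (length(pa)) B[pa, v] <- fam$coef[pa]
    d[v] <- fam$sigma2
  }
  Ainv <- solve(diag(k) - t(B))
  mu <- drop(Ainv %*% a)
  S <- Ainv %*% diag(d, k) %*% t(Ainv)
  dimnames(S) <- list(nodes, nodes)
  if (any(!is.finite(S)))
    stop("implied covariance is not finite")
  list(mean = stats::setNames(mu, nodes), cov = S)
}

#' Predict a node from a fitted network
#'
#' `mode = "full"` returns the exact conditional mean
#' `E[target | all other variables]` under the implied joint normal (using a
#' Moore-Penrose pseudo-inverse when the conditioning block is singular, as
#' with near-noiseless nodes); `mode = "parents"` returns the child
#' regression on the target's parents only.
#'
#' @param fit a `gaussian_fit`.
#' @param records data.frame/matrix containing all non-target node columns.
#' @param target node name to predict.
#' @param mode `"full"` or `"parents"`.
#' @return numeric vector of predictions, one per record.
#' @export
predict_conditional_mean <- function(fit, records, target,
                                     mode = c("full", "parents")) {
  mode <- match.arg(mode)
  nodes <- fit$dag$nodes
  if (!(target %in% nodes)) stop("unknown target node: ", target)
  records <- as.data.frame(records)
  if (mode == "parents") {
    fam <- fit$families[[target]]
    pa <- dag_parents(fit$dag, target)
    if (isTRUE(fam$singular)) stop("singular family for ", target)
    pred <- rep(fam$coef[["(Intercept)"]], nrow(records))
    if (length(pa))
      pred <- pred + drop(as.matrix(records[pa]) %*% fam$coef[pa])
    return(pred)
  }
  jm <- implied_joint(fit)
  rest <- setdiff(nodes, target)
  if (!all(rest %in% names(records)))
    stop("records are missing columns: ",
         paste(setdiff(rest, names(records)), collapse = ", "))
  Srr <- jm$cov[rest, rest, drop = FALSE]
  Str <- jm$cov[target, rest, drop = FALSE]
  Sinv <- tryCatch(solve(Srr), error = function(e) MASS::ginv(Srr))
  w <- drop(Str %*% Sinv)
  X <- sweep(as.matrix(records[rest]), 2, jm$mean[rest])
  drop(jm$mean[target] + X %*% w)
}
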