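# Interrater agreement: one-way random, absolute-agreement, average-measures
# intraclass correlation, ICC(1,k) = (MSB - MSW) / MSB.

#' One-way ANOVA decomposition of a ratings matrix
#'
#' Subjects are rows, rater slots are columns; under the one-way random model
#' rater identity is not a crossed factor, so columns are interchangeable.
#' Between-subject sum of squares uses k * sum((row mean - grand mean)^2) on
#' n - 1 degrees of freedom; within-subject uses the residuals around row
#' means on n (k - 1) degrees of freedom.
#'
#' @param m numeric matrix, n subjects x k raters, complete.
#' @return list with `ms_between`, `ms_within`, `n_subjects`, `k_raters`.
#' @export
anova_oneway <- function(m) {
  m <- as.matrix(m)
  if (anyNA(m))
    stop("ratings matrix has missing cells; reduce to complete cases first")
  n <- nrow(m); k <- ncol(m)
  if (n < 2 || k < 2) stop("need at least 2 subjects and 2 raters")
  row_means <- rowMeans(m)
  ssb <- k * sum((row_means - mean(m))^2)
  ssw <- sum((m - row_means)^2)
  list(ms_between = ssb / (n - 1), ms_within = ssw / (n * (k - 1)),
       n_subjects = n, k_raters = k)
}

#' One-way random, average-measures intraclass correlation
#'
#' ICC(1,k) = (MSB - MSW) / MSB: the reliability of the mean of k
#' interchangeable raters under the one-way random-effects model. Values can
#' be negative when subjects agree less than raters do; a degenerate status is
#' returned instead of NaN when there is no between-subject variance.
#'
#' @param m numeric matrix, subjects x raters.
#' @param conf.level if non-NULL, an F-based confidence interval is attached.
#' @return list of class `"icc_result"` with `icc`, `ms_between`, `ms_within`,
#'   `n_subjects`, `k_raters`, `status` (`"ok"`, `"degenerate"` or
#'   `"negative"`), and optionally `conf_int`.
#' @examples
#' icc_oneway_average(matrix(c(1, 2, 3, 4, 5, 6), 3, byrow = TRUE))
#' @export
icc_oneway_average <- function(m, conf.level = NULL) {
  a <- anova_oneway(m)
  if (a$ms_between <= 0) {
    res <- c(a, list(icc = NA_real_, status = "degenerate"))
  } else {
    icc <- (a$ms_between - a$ms_within) / a$ms_between
    status <- "ok"
    if (icc < 0) {
      status <- "negative"
      warning("ICC is negative: within-subject variance exceeds ",
              "between-subject variance")
    }
    res <- c(a, list(icc = icc, status = status))
  }
  if (!is.null(conf.level) && res$status != "degenerate") {
    # F = MSB/MSW ~ F(n-1, n(k-1)) under the one-way model
    alpha <- 1 - conf.level
    f <- a$ms_between / a$ms_within
    df1 <- a$n_subjects - 1
    df2 <- a$n_subjects * (a$k_raters - 1)
    fl <- f / stats::qf(1 - alpha / 2, df1, df2)
    fu <- f * stats::qf(1 - alpha / 2, df2, df1)
    res$conf_int <- c(lower = 1 - 1 / fl, upper = 1 - 1 / fu)
  }
  structure(res, class = "icc_result")
}

#' @export
print.icc_result <- function(x, ...) {
  cat(sprintf("ICC(1,%d): %s  [n = %d subjects, MSB = %.4g, MSW = %.4g]\n",
              x$k_raters,
              if (is.na(x$icc)) paste0("undefined (", x$status, ")")
              else sprintf("%.3f", x$icc),
              x$n_subjects, x$ms_between, x$ms_within))
  invisible(x)
}

#' Per-exercise ICC table from rater labels
#'
#' Builds the instance x rater matrix for each measure (guarding coded 0/1,
#' self-efficacy coded 1-3) and computes ICC(1,k) overall and within each
#' exercise type.
#'
#' @param instances,ratings cohort data.frames as produced by
#'   [simulate_cohort()] / [read_cohort()].
#' @param measures which measures to include.
#' @return data.frame with measure, exercise ("all" plus each type),
#'   n_subjects, k_raters, icc, status.
#' @export
icc_table <- function(instances, ratings,
                      measures = c("guarding", "self_efficacy")) {
  groups <- c(list(all = instances$instance_id),
              split(instances$instance_id, instances$exercise))
  rows <- list()
  for (ms in measures) {
    val <- if (ms == "guarding") as.numeric(ratings$guarding)
           else se_to_code(ratings$self_efficacy)
    for (g in names(groups)) {
      sub <- ratings[ratings$instance_id %in% groups[[g]], , drop = FALSE]
      v <- val[ratings$instance_id %in% groups[[g]]]
      cnt <- table(sub$instance_id)
      k <- as.integer(max(cnt))
      ok <- names(cnt)[cnt == k]          # complete panels only
      if (length(ok) < 2 || k < 2) {
        rows[[length(rows) + 1]] <- data.frame(
          measure = ms, exercise = g, n_subjects = length(ok), k_raters = k,
          icc = NA_real_, status = "insufficient")
        next
      }
      sub2 <- sub[sub$instance_id %in% ok, , drop = FALSE]
      v2 <- v[sub$instance_id %in% ok]
      ord <- order(sub2$instance_id, sub2$rater_id)
      mat <- matrix(v2[ord], nrow = length(ok), ncol = k, byrow = TRUE,
                    dimnames = list(sort(ok), NULL))
      r <- suppressWarnings(icc_oneway_average(mat))
      rows[[length(rows) + 1]] <- data.frame(
        measure = ms, exercise = g, n_subjects = r$n_subjects,
        k_raters = r$k_raters, icc = r$icc, status = r$status)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
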