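# Spearman rank correlation, the lower/higher dichotomizations, and the
# guarding-score frequency distributions.

.ANALYSIS_VARS <- c("guarding", "self_efficacy", "pain", "anxiety", "distress")

#' Spearman rank-order correlation
#'
#' Average ranks are assigned to ties, rho is the Pearson correlation of the
#' two rank vectors, and the two-sided p-value uses the t approximation with
#' n - 2 degrees of freedom. Pairs with a missing value in either vector are
#' dropped first.
#'
#' @param x,y numeric vectors of equal length.
#' @return list with `rho`, `p_value`, `n`, and `status` (`"ok"` or
#'   `"constant"` when either vector has zero rank variance, in which case
#'   `rho` is NA).
#' @examples
#' spearman(c(1, 2, 2, 4), c(1, 3, 2, 4))
#' @export
spearman <- function(x, y) {
  stopifnot(length(x) == length(y))
  ok <- !is.na(x) & !is.na(y)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  if (n < 3) stop("need at least 3 complete pairs")
  rx <- rank(x); ry <- rank(y)
  if (stats::var(rx) == 0 || stats::var(ry) == 0)
    return(list(rho = NA_real_, p_value = NA_real_, n = n,
                status = "constant"))
  rho <- stats::cor(rx, ry)
  if (abs(rho) >= 1) {
    p <- 0
  } else {
    tstat <- rho * sqrt((n - 2) / (1 - rho^2))
    p <- 2 * stats::pt(-abs(tstat), df = n - 2)
  }
  list(rho = rho, p_value = p, n = n, status = "ok")
}

#' Pairwise Spearman correlation matrix of the analysis variables
#'
#' All ten unordered pairs of (guarding, self_efficacy, pain, anxiety,
#' distress), each on its pairwise-complete observations.
#'
#' @param records analysis records from [assemble_records()].
#' @return list of class `"correlation_matrix"` with 5x5 matrices `rho`, `n`,
#'   `p_value` and a long-form data.frame `table` (var1, var2, rho, n, p).
#' @export
correlation_matrix <- function(records) {
  if (nrow(records) < 3) stop("need at least 3 records")
  v <- .ANALYSIS_VARS
  rho <- matrix(1, 5, 5, dimnames = list(v, v))
  nmat <- matrix(NA_integer_, 5, 5, dimnames = list(v, v))
  pmat <- matrix(NA_real_, 5, 5, dimnames = list(v, v))
  diag(nmat) <- colSums(!is.na(records[v]))
  tab <- list()
  for (i in 1:4) for (j in (i + 1):5) {
    s <- spearman(records[[v[i]]], records[[v[j]]])
    rho[i, j] <- rho[j, i] <- s$rho
    nmat[i, j] <- nmat[j, i] <- s$n
    pmat[i, j] <- pmat[j, i] <- s$p_value
    tab[[length(tab) + 1]] <- data.frame(var1 = v[i], var2 = v[j],
                                         rho = s$rho, n = s$n,
                                         p = s$p_value, status = s$status)
  }
  structure(list(rho = rho, n = nmat, p_value = pmat,
                 table = do.call(rbind, tab)),
            class = "correlation_matrix")
}

#' @export
print.correlation_matrix <- function(x, ...) {
  cat("Pairwise Spearman correlations (pairwise-complete):\n")
  print(round(x$rho, 3))
  invisible(x)
}

#' Dichotomization configuration
#'
#' Cut points for the lower/higher split: pain and anxiety are higher when
#' `>= pain_cut` (default 5 of 10), distress when `> distress_cut` (default
#' 19 of 39), and self-efficacy when better than medium (`> selfeff_cut`,
#' default 2).
#'
#' @param pain_cut,anxiety_cut,distress_cut,selfeff_cut numeric cuts.
#' @return named list of class `"dichotomy_config"`.
#' @export
dichotomy_config <- function(pain_cut = 5, anxiety_cut = 5,
                             distress_cut = 19, selfeff_cut = 2) {
  if (pain_cut < 0 || pain_cut > 10 || anxiety_cut < 0 || anxiety_cut > 10)
    stop("pain/anxiety cuts must lie in [0, 10]")
  if (distress_cut < 0 || distress_cut > 39)
    stop("distress cut must lie in [0, 39]")
  if (selfeff_cut < 1 || selfeff_cut > 3)
    stop("self-efficacy cut must lie in [1, 3]")
  structure(list(pain_cut = pain_cut, anxiety_cut = anxiety_cut,
                 distress_cut = distress_cut, selfeff_cut = selfeff_cut),
            class = "dichotomy_config")
}

#' Dichotomize the analysis variables
#'
#' Adds `pain_level`, `anxiety_level`, `distress_level`, `self_efficacy_level`
#' columns with values `"lower"`/`"higher"`; missing values stay missing.
#'
#' @param records analysis records.
#' @param config a [dichotomy_config()].
#' @return the records with the four level columns appended.
#' @export
dichotomize <- function(records, config = dichotomy_config()) {
  chk <- function(x, lo, hi, what) {
    if (any(!is.na(x) & (x < lo | x > hi)))
      stop(what, " values out of range [", lo, ", ", hi, "]")
  }
  chk(records$pain, 0, 10, "pain")
  chk(records$anxiety, 0, 10, "anxiety")
  chk(records$distress, 0, 39, "distress")
  chk(records$self_efficacy, 1, 3, "self_efficacy")
  lev <- function(x, higher) ifelse(is.na(x), NA_character_,
                                    ifelse(higher, "higher", "lower"))
  records$pain_level <- lev(records$pain, records$pain >= config$pain_cut)
  records$anxiety_level <- lev(records$anxiety,
                               records$anxiety >= config$anxiety_cut)
  records$distress_level <- lev(records$distress,
                                records$distress > config$distress_cut)
  records$self_efficacy_level <- lev(records$self_efficacy,
                                     records$self_efficacy > config$selfeff_cut)
  records
}

#' Guarding-score frequency table
#'
#' Counts of exercise instances by guarding score (0-4) and lower/higher
#' level of each dichotomized variable, mirroring the frequency-distribution
#' panels of the analysis.
#'
#' @param records dichotomized records (see [dichotomize()]).
#' @return data.frame with variable, level, guarding, count; for each
#'   variable the counts sum to the number of records where it is non-missing.
#' @export
guarding_frequency_table <- function(records) {
  vars <- c("pain", "anxiety", "distress", "self_efficacy")
  lev_cols <- paste0(vars, "_level")
  if (!all(lev_cols %in% names(records)))
    stop("records are not dichotomized; call dichotomize() first")
  scores <- 0:max(4, records$guarding)
  rows <- list()
  for (i in seq_along(vars)) {
    lv <- records[[lev_cols[i]]]
    for (l in c("lower", "higher")) {
      cnt <- table(factor(records$guarding[!is.na(lv) & lv == l],
                          levels = scores))
      rows[[length(rows) + 1]] <- data.frame(
        variable = vars[i], level = l, guarding = as.integer(names(cnt)),
        count = as.integer(cnt))
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
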