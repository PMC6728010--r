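# Aggregation of per-rater labels and per-instance self-reports into the
# five-variable analysis records (guarding score, self-efficacy median, pain,
# anxiety, distress).

.SE_CODES <- c(low = 1, medium = 2, high = 3)

se_to_code <- function(x) {
  if (is.numeric(x)) {
    if (!all(x %in% 1:3)) stop("numeric self-efficacy codes must be 1, 2 or 3")
    return(as.numeric(x))
  }
  if (!all(x %in% names(.SE_CODES)))
    stop("self-efficacy labels must be low/medium/high")
  unname(.SE_CODES[x])
}

#' Guarding score for one instance
#'
#' The count of raters who marked guarding present (0 to the panel size).
#' With fewer labels than the nominal panel size, the raw sum over available
#' raters is returned by default; `rescale_to` rescales `sum * (rescale_to/k)`
#' to the nominal panel and rounds to the nearest integer.
#'
#' @param guarding vector of 0/1 per-rater guarding codes for one instance.
#' @param rescale_to optional nominal panel size for rescaling.
#' @return integer score.
#' @examples
#' guarding_score(c(1, 1, 1, 0))
#' @export
guarding_score <- function(guarding, rescale_to = NULL) {
  if (length(guarding) == 0) stop("no ratings: guarding score undefined")
  if (!all(guarding %in% c(0, 1))) stop("guarding codes must be 0 or 1")
  s <- sum(guarding)
  if (!is.null(rescale_to) && length(guarding) != rescale_to)
    s <- round(s * rescale_to / length(guarding))
  as.integer(s)
}

#' Median self-efficacy for one instance
#'
#' Median of the ordinal codes (low = 1, medium = 2, high = 3) across raters.
#' With an even panel and distinct middle values the half-integer midpoint is
#' retained; `rounding` can force it down or up for sensitivity analysis.
#'
#' @param self_efficacy per-rater codes (1/2/3) or labels (low/medium/high).
#' @param rounding `"none"` (default), `"floor"` or `"ceiling"`, applied only
#'   to half-integer medians.
#' @return value in {1, 1.5, 2, 2.5, 3}.
#' @examples
#' self_efficacy_median(c("medium", "medium", "high", "high"))
#' @export
self_efficacy_median <- function(self_efficacy,
                                 rounding = c("none", "floor", "ceiling")) {
  rounding <- match.arg(rounding)
  if (length(self_efficacy) == 0) stop("no ratings: median undefined")
  m <- stats::median(se_to_code(self_efficacy))
  switch(rounding, none = m, floor = floor(m), ceiling = ceiling(m))
}

#' Assemble analysis records
#'
#' Joins instances with their rater labels, applies the inclusion rule (an
#' instance is kept only if at least one of pain, anxiety or distress is
#' present, and it has at least one rater label), and attaches the guarding
#' score and the self-efficacy median.
#'
#' @param instances data.frame with columns patient_id, instance_id, exercise,
#'   challenge, pain, anxiety, distress (NA allowed in the self-reports).
#' @param ratings data.frame with columns instance_id, rater_id, guarding,
#'   self_efficacy.
#' @param se_rounding passed to [self_efficacy_median()].
#' @param rescale_guarding if TRUE, rescale incomplete panels to the modal
#'   panel size (see [guarding_score()]).
#' @return data.frame of analysis records: instance_id, patient_id, exercise,
#'   challenge, guarding, n_raters, self_efficacy, pain, anxiety, distress.
#' @export
assemble_records <- function(instances, ratings, se_rounding = "none",
                             rescale_guarding = FALSE) {
  need_i <- c("patient_id", "instance_id", "exercise", "challenge",
              "pain", "anxiety", "distress")
  need_r <- c("instance_id", "rater_id", "guarding", "self_efficacy")
  if (!all(need_i %in% names(instances)))
    stop("instances is missing columns: ",
         paste(setdiff(need_i, names(instances)), collapse = ", "))
  if (!all(need_r %in% names(ratings)))
    stop("ratings is missing columns: ",
         paste(setdiff(need_r, names(ratings)), collapse = ", "))
  dangling <- setdiff(ratings$instance_id, instances$instance_id)
  if (length(dangling))
    stop("ratings reference unknown instance_id(s): ",
         paste(utils::head(dangling, 5), collapse = ", "))
  rng_bad <- with(instances,
                  (!is.na(pain) & (pain < 0 | pain > 10)) |
                  (!is.na(anxiety) & (anxiety < 0 | anxiety > 10)) |
                  (!is.na(distress) & (distress < 0 | distress > 39)))
  if (any(rng_bad))
    stop("self-report values out of range in instance(s): ",
         paste(utils::head(instances$instance_id[rng_bad], 5), collapse = ", "))

  by_inst <- split(ratings, ratings$instance_id)
  panel <- if (rescale_guarding)
    as.integer(names(which.max(table(lengths(lapply(by_inst, `[[`,
                                                    "guarding")))))) else NULL
  keep <- instances$instance_id %in% names(by_inst) &
    (!is.na(instances$pain) | !is.na(instances$anxiety) |
       !is.na(instances$distress))
  kept <- instances[keep, , drop = FALSE]
  if (nrow(kept) == 0)
    return(data.frame(instance_id = character(0), patient_id = character(0),
                      exercise = character(0), challenge = character(0),
                      guarding = integer(0), n_raters = integer(0),
                      self_efficacy = numeric(0), pain = numeric(0),
                      anxiety = numeric(0), distress = numeric(0)))
  agg <- t(vapply(kept$instance_id, function(id) {
    r <- by_inst[[id]]
    c(guarding_score(r$guarding, rescale_to = panel),
      length(r$guarding),
      self_efficacy_median(r$self_efficacy, rounding = se_rounding))
  }, numeric(3)))
  out <- data.frame(instance_id = kept$instance_id,
                    patient_id = kept$patient_id,
                    exercise = kept$exercise,
                    challenge = kept$challenge,
                    guarding = as.integer(agg[, 1]),
                    n_raters = as.integer(agg[, 2]),
                    self_efficacy = agg[, 3],
                    pain = as.numeric(kept$pain),
                    anxiety = as.numeric(kept$anxiety),
                    distress = as.numeric(kept$distress),
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

#' Read a cohort from instances.csv / ratings.csv
#'
#' @param dir directory containing `instances.csv` and `ratings.csv`.
#' @return list with `instances` and `ratings` data.frames.
#' @export
read_cohort <- function(dir) {
  pi <- file.path(dir, "instances.csv")
  pr <- file.path(dir, "ratings.csv")
  if (!file.exists(pi)) stop("missing ", pi)
  if (!file.exists(pr)) stop("missing ", pr)
  list(instances = utils::read.csv(pi, stringsAsFactors = FALSE),
       ratings = utils::read.csv(pr, stringsAsFactors = FALSE))
}
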