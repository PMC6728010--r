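# Synthetic cohort generator: a linear-Gaussian structural equation model over
# {pain, anxiety, distress, guarding_latent, selfeff_latent} plus an
# observation layer (integer clipping of self-reports, Bernoulli guarding
# judgements and thresholded ordinal self-efficacy from a panel of raters).

.SEM_NODES <- c("pain", "anxiety", "distress", "guarding_latent",
                "selfeff_latent")

#' Default ground-truth network structure
#'
#' The data-generating DAG used by the synthetic cohort: pain and overall
#' distress feed anxiety; anxiety drives latent guarding; guarding and anxiety
#' jointly drive latent movement self-efficacy. Guarding has no direct edge
#' from pain or distress, so the pain-guarding association is mediated
#' entirely by anxiety.
#'
#' @return a `guardnet_dag` over the five structural nodes.
#' @examples
#' default_structure()
#' @export
default_structure <- function() {
  dag(.SEM_NODES, rbind(
    c("pain", "anxiety"),
    c("distress", "anxiety"),
    c("anxiety", "guarding_latent"),
    c("anxiety", "selfeff_latent"),
    c("guarding_latent", "selfeff_latent")
  ))
}

#' Rater observation model
#'
#' Describes how a panel of raters turns the latent guarding and self-efficacy
#' values of an exercise instance into labels. Each rater marks guarding
#' present with probability `plogis(guarding_intercept + guarding_slope *
#' guarding_latent + rater_bias[r])`, and rates self-efficacy by cutting
#' `selfeff_latent + rater_bias[r] + noise` at `selfeff_thresholds` into
#' low/medium/high (coded 1/2/3).
#'
#' Raters are not independent channels: each rater forms one overall
#' impression of the clip (a shared latent perturbation `impression_sd`) that
#' raises their guarding judgement and lowers their self-efficacy judgement
#' together, emulating the correlated-observer effect of having the same
#' person rate both constructs.
#'
#' @param n_raters number of raters per instance.
#' @param guarding_intercept baseline guarding log-odds at zero latent score.
#' @param guarding_slope log-odds increase per unit of latent guarding.
#' @param rater_bias per-rater shift, recycled/checked to length `n_raters`.
#' @param impression_sd SD of the per-rater, per-instance shared impression
#'   that couples the guarding and self-efficacy judgements.
#' @param selfeff_noise_sd SD of each rater's private noise on the latent
#'   self-efficacy scale (drives interrater disagreement).
#' @param selfeff_thresholds two strictly increasing cut points.
#' @return a list of class `"rater_model"`.
#' @export
rater_model <- function(n_raters = 4,
                        guarding_intercept = 1.5,
                        guarding_slope = 1.8,
                        rater_bias = c(-0.2, -0.07, 0.07, 0.2),
                        impression_sd = 0.5,
                        selfeff_noise_sd = 0.9,
                        selfeff_thresholds = c(-0.85, 0.85)) {
  if (n_raters < 1) stop("n_raters must be >= 1")
  if (length(rater_bias) != n_raters)
    stop("rater_bias must have one entry per rater")
  if (length(selfeff_thresholds) != 2 || diff(selfeff_thresholds) <= 0)
    stop("selfeff_thresholds must be two strictly increasing values")
  structure(list(n_raters = n_raters,
                 guarding_intercept = guarding_intercept,
                 guarding_slope = guarding_slope,
                 rater_bias = rater_bias,
                 impression_sd = impression_sd,
                 selfeff_noise_sd = selfeff_noise_sd,
                 selfeff_thresholds = selfeff_thresholds),
            class = "rater_model")
}

#' Ground-truth structural model
#'
#' Bundles a DAG with linear-Gaussian structural parameters and the rater
#' observation model. Node `j` is generated as
#' `intercept[j] + patient_effect[j] + sum(coef * parents) + N(0, residual_sd[j])`.
#' Nodes listed in `patient_level_nodes` draw their residual once per patient
#' and replicate it across that patient's instances (used for HADS distress).
#'
#' @param structure a `guardnet_dag` over the five structural nodes.
#' @param intercepts,residual_sd,patient_intercept_sd named numeric vectors
#'   over the nodes; all `residual_sd` must be positive,
#'   `patient_intercept_sd` non-negative.
#' @param coefficients named numeric vector, names `"tail->head"`, one per
#'   edge of `structure`.
#' @param patient_level_nodes nodes whose residual is a per-patient constant.
#' @param raters a `rater_model`.
#' @return a list of class `"ground_truth"`.
#' @export
ground_truth <- function(structure, intercepts, coefficients, residual_sd,
                         patient_intercept_sd = NULL,
                         patient_level_nodes = "distress",
                         raters = rater_model()) {
  nodes <- structure$nodes
  if (is.null(patient_intercept_sd))
    patient_intercept_sd <- stats::setNames(numeric(length(nodes)), nodes)
  for (v in list(intercepts, residual_sd, patient_intercept_sd))
    if (!all(nodes %in% names(v)))
      stop("intercepts, residual_sd and patient_intercept_sd must be named ",
           "over all nodes")
  if (any(residual_sd[nodes] <= 0)) stop("all residual_sd must be > 0")
  if (any(patient_intercept_sd[nodes] < 0))
    stop("patient_intercept_sd must be >= 0")
  e <- dag_edges(structure)
  want <- paste0(e[, "tail"], "->", e[, "head"])
  if (!setequal(names(coefficients), want))
    stop("coefficients must be named 'tail->head', exactly one per edge")
  structure(list(structure = structure,
                 intercepts = intercepts[nodes],
                 coefficients = coefficients,
                 residual_sd = residual_sd[nodes],
                 patient_intercept_sd = patient_intercept_sd[nodes],
                 patient_level_nodes = patient_level_nodes,
                 raters = raters),
            class = "ground_truth")
}

#' Default ground truth for the synthetic cohort
#'
#' Effect sizes are chosen so that, at cohort scale (about 99 instances), the
#' observed variables reproduce the descriptive profile of the chronic-pain
#' analysis set: pain near mean 5 (SD 3) on 0-10, anxiety near mean 1 with a
#' long upper tail, HADS distress near mean 18 (SD 7) on 0-39, guarding score
#' near mean 3, self-efficacy near mean 2; guarding/self-efficacy and
#' pain/anxiety are the two strongest pairwise associations.
#'
#' @return a `ground_truth` object.
#' @export
default_truth <- function() {
  nodes <- .SEM_NODES
  ground_truth(
    structure = default_structure(),
    intercepts = c(pain = 5, anxiety = -4.45, distress = 18,
                   guarding_latent = -0.5, selfeff_latent = 0.1),
    coefficients = c("pain->anxiety" = 0.55,
                     "distress->anxiety" = 0.15,
                     "anxiety->guarding_latent" = 0.5,
                     "anxiety->selfeff_latent" = -0.1,
                     "guarding_latent->selfeff_latent" = -0.8),
    residual_sd = c(pain = 2.0, anxiety = 1.0, distress = 7,
                    guarding_latent = 1.0, selfeff_latent = 0.45),
    patient_intercept_sd = c(pain = 2.2, anxiety = 0, distress = 0,
                             guarding_latent = 0, selfeff_latent = 0),
    patient_level_nodes = "distress",
    raters = rater_model()
  )
}

#' Generator configuration
#'
#' @param n_patients number of patients in the cohort.
#' @param instances_per_patient list with `min`, `max`, `mean`: counts are
#'   drawn as `min + Binomial(max - min, (mean - min)/(max - min))`, a
#'   discrete distribution on `[min, max]` with the requested mean.
#' @param seed integer seed for the whole simulation.
#' @param exercise_mix named proportions over the three exercise types.
#' @return a list of class `"generator_config"`.
#' @export
generator_config <- function(n_patients = 17,
                             instances_per_patient = list(min = 1, max = 9,
                                                          mean = 6),
                             seed = 1,
                             exercise_mix = c(sit_to_stand = 0.73,
                                              forward_flexion = 0.19,
                                              full_flexion = 0.08)) {
  ip <- instances_per_patient
  if (n_patients < 1) stop("n_patients must be >= 1")
  if (ip$min < 1 || ip$max > 9 || ip$min > ip$max)
    stop("instances_per_patient support must lie within [1, 9]")
  if (ip$mean < ip$min || ip$mean > ip$max)
    stop("instances_per_patient mean must lie within its support")
  if (!setequal(names(exercise_mix),
                c("sit_to_stand", "forward_flexion", "full_flexion")))
    stop("exercise_mix must cover the three exercise types")
  if (abs(sum(exercise_mix) - 1) > 1e-8)
    stop("exercise_mix proportions must sum to 1")
  structure(list(n_patients = n_patients,
                 instances_per_patient = ip,
                 seed = as.integer(seed),
                 exercise_mix = exercise_mix),
            class = "generator_config")
}

# coefficient matrix B with B[i, j] = coefficient of parent i in child j
sem_coef_matrix <- function(truth) {
  nodes <- truth$structure$nodes
  B <- matrix(0, length(nodes), length(nodes), dimnames = list(nodes, nodes))
  for (nm in names(truth$coefficients)) {
    th <- strsplit(nm, "->", fixed = TRUE)[[1]]
    B[th[1], th[2]] <- truth$coefficients[[nm]]
  }
  B
}

#' Closed-form moments of the structural model
#'
#' The mean vector and covariance matrix of one independent draw from the
#' linear-Gaussian SEM, with per-patient intercept variance folded into each
#' node's innovation variance (each draw is its own patient).
#'
#' @param truth a `ground_truth`.
#' @return list with `mean` and `cov` over the structural nodes.
#' @export
truth_moments <- function(truth) {
  nodes <- truth$structure$nodes
  B <- sem_coef_matrix(truth)
  A <- solve(diag(length(nodes)) - t(B))  # x = a + B'x + e  =>  x = A (a + e)
  d <- truth$residual_sd^2 + truth$patient_intercept_sd^2
  mu <- drop(A %*% truth$intercepts)
  S <- A %*% diag(d) %*% t(A)
  dimnames(S) <- list(nodes, nodes)
  list(mean = stats::setNames(mu, nodes), cov = S)
}

#' Draw iid rows from the structural model
#'
#' Exact draws of the latent five-variable vector, before any integer
#' clipping or rater observation; used for structure-recovery experiments and
#' for checking the generator against its closed-form covariance.
#'
#' @param truth a `ground_truth`.
#' @param n number of rows.
#' @param seed optional integer seed.
#' @return numeric matrix `n x 5` with structural node columns.
#' @export
simulate_truth <- function(truth, n, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  nodes <- truth$structure$nodes
  B <- sem_coef_matrix(truth)
  sd_tot <- sqrt(truth$residual_sd^2 + truth$patient_intercept_sd^2)
  x <- matrix(0, n, length(nodes), dimnames = list(NULL, nodes))
  for (v in topological_order(truth$structure)) {
    pa <- dag_parents(truth$structure, v)
    eta <- truth$intercepts[[v]] + stats::rnorm(n, 0, sd_tot[[v]])
    if (length(pa))
      eta <- eta + drop(x[, pa, drop = FALSE] %*% B[pa, v])
    x[, v] <- eta
  }
  x
}

clip_int <- function(x, lo, hi) pmin(pmax(round(x), lo), hi)

#' Simulate a synthetic cohort with rater annotations
#'
#' Samples per-patient random intercepts and instance counts, generates the
#' latent structural variables in topological order, maps pain/anxiety to
#' clipped integers on 0-10 and distress to a per-patient constant integer on
#' 0-39, and emits one guarding/self-efficacy label per rater per instance
#' through the rater observation model.
#'
#' @param config a `generator_config`.
#' @param truth a `ground_truth` (default [default_truth()]).
#' @return list of class `"cohort"` with data.frames `instances` (patient_id,
#'   instance_id, exercise, challenge, pain, anxiety, distress) and `ratings`
#'   (instance_id, rater_id, guarding, self_efficacy in low/medium/high), plus
#'   the unchanged `truth` for downstream recovery checks.
#' @examples
#' co <- simulate_cohort(generator_config(seed = 7))
#' head(co$instances)
#' @export
simulate_cohort <- function(config = generator_config(),
                            truth = default_truth()) {
  stopifnot(inherits(config, "generator_config"),
            inherits(truth, "ground_truth"))
  set.seed(config$seed)
  nodes <- truth$structure$nodes
  B <- sem_coef_matrix(truth)
  topo <- topological_order(truth$structure)
  rm_ <- truth$raters
  ip <- config$instances_per_patient
  p_bin <- if (ip$max > ip$min) (ip$mean - ip$min) / (ip$max - ip$min) else 0

  inst <- list(); rat <- list()
  for (p in seq_len(config$n_patients)) {
    pid <- sprintf("P%03d", p)
    m <- ip$min + stats::rbinom(1, ip$max - ip$min, p_bin)
    u <- stats::rnorm(length(nodes), 0, truth$patient_intercept_sd)
    names(u) <- nodes
    e_pat <- stats::setNames(stats::rnorm(length(truth$patient_level_nodes),
                                          0, truth$residual_sd[truth$patient_level_nodes]),
                             truth$patient_level_nodes)
    ex <- sample(names(config$exercise_mix), m, replace = TRUE,
                 prob = config$exercise_mix)
    ch <- sample(c("low", "high"), m, replace = TRUE)
    x <- matrix(0, m, length(nodes), dimnames = list(NULL, nodes))
    for (v in topo) {
      pa <- dag_parents(truth$structure, v)
      e <- if (v %in% truth$patient_level_nodes)
        rep(e_pat[[v]], m) else stats::rnorm(m, 0, truth$residual_sd[[v]])
      eta <- truth$intercepts[[v]] + u[[v]] + e
      if (length(pa)) eta <- eta + drop(x[, pa, drop = FALSE] %*% B[pa, v])
      x[, v] <- eta
    }
    iid <- sprintf("%s_I%02d", pid, seq_len(m))
    inst[[p]] <- data.frame(
      patient_id = pid, instance_id = iid, exercise = ex, challenge = ch,
      pain = clip_int(x[, "pain"], 0, 10),
      anxiety = clip_int(x[, "anxiety"], 0, 10),
      distress = clip_int(x[, "distress"], 0, 39),
      stringsAsFactors = FALSE)
    # rater panel: one Bernoulli guarding call and one thresholded
    # self-efficacy call per rater per instance
    g_lat <- rep(x[, "guarding_latent"], each = rm_$n_raters)
    s_lat <- rep(x[, "selfeff_latent"], each = rm_$n_raters)
    bias <- rep(rm_$rater_bias, times = m)
    impression <- stats::rnorm(length(g_lat), 0, rm_$impression_sd)
    pg <- stats::plogis(rm_$guarding_intercept +
                          rm_$guarding_slope * (g_lat + impression) + bias)
    guard <- stats::rbinom(length(pg), 1, pg)
    s_obs <- s_lat + bias - impression +
      stats::rnorm(length(s_lat), 0, rm_$selfeff_noise_sd)
    se <- cut(s_obs, c(-Inf, rm_$selfeff_thresholds, Inf),
              labels = c("low", "medium", "high"))
    rat[[p]] <- data.frame(
      instance_id = rep(iid, each = rm_$n_raters),
      rater_id = rep(sprintf("R%02d", seq_len(rm_$n_raters)), times = m),
      guarding = guard,
      self_efficacy = as.character(se),
      stringsAsFactors = FALSE)
  }
  structure(list(instances = do.call(rbind, inst),
                 ratings = do.call(rbind, rat),
                 truth = truth),
            class = "cohort")
}

#' The ground-truth DAG on the analysis variable names
#'
#' Renames the structural nodes to the names used by the aggregated analysis
#' records (`guarding`, `self_efficacy`) so learned structures can be compared
#' with the truth via [cpdag()] and [shd()].
#'
#' @param truth a `ground_truth`.
#' @return a `guardnet_dag`.
#' @export
truth_analysis_dag <- function(truth) {
  map <- c(pain = "pain", anxiety = "anxiety", distress = "distress",
           guarding_latent = "guarding", selfeff_latent = "self_efficacy")
  e <- dag_edges(truth$structure)
  dag(unname(map[truth$structure$nodes]),
      cbind(unname(map[e[, "tail"]]), unname(map[e[, "head"]])))
}

#' Write a cohort to disk
#'
#' Writes `instances.csv`, `ratings.csv` and the ground truth as
#' `truth.json`.
#'
#' @param cohort a `cohort`.
#' @param dir output directory (created if needed).
#' @return invisibly, the paths written.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  pi <- file.path(dir, "instances.csv")
  pr <- file.path(dir, "ratings.csv")
  pt <- file.path(dir, "truth.json")
  utils::write.csv(cohort$instances, pi, row.names = FALSE)
  utils::write.csv(cohort$ratings, pr, row.names = FALSE)
  tr <- cohort$truth
  jsonlite::write_json(list(
    nodes = tr$structure$nodes,
    edges = as.data.frame(dag_edges(tr$structure)),
    intercepts = as.list(tr$intercepts),
    coefficients = as.list(tr$coefficients),
    residual_sd = as.list(tr$residual_sd),
    patient_intercept_sd = as.list(tr$patient_intercept_sd),
    patient_level_nodes = tr$patient_level_nodes,
    raters = unclass(tr$raters)), pt, auto_unbox = TRUE, digits = NA,
    pretty = TRUE)
  invisible(c(instances = pi, ratings = pr, truth = pt))
}
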