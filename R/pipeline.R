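# End-to-end pipeline: simulate (or read) -> aggregate -> ICC ->
# correlations/dichotomies -> network learning -> cross-validation -> report.

#' Analysis-variable matrix from records
#'
#' Complete-case numeric matrix of (guarding, self_efficacy, pain, anxiety,
#' distress) in the fixed analysis order, as consumed by the network
#' machinery.
#'
#' @param records analysis records from [assemble_records()].
#' @return numeric matrix.
#' @export
records_matrix <- function(records) {
  m <- as.matrix(records[.ANALYSIS_VARS])
  m[stats::complete.cases(m), , drop = FALSE]
}

#' Pipeline configuration
#'
#' Exactly one of `generator` (a [generator_config()], with optional `truth`)
#' or `input_dir` (a directory holding `instances.csv` and `ratings.csv`)
#' must be supplied.
#'
#' @param generator a `generator_config` or NULL.
#' @param truth a `ground_truth` used with `generator`.
#' @param input_dir directory of cohort CSVs, or NULL.
#' @param dichotomy a [dichotomy_config()].
#' @param learners learners compared by cross-validation.
#' @param cv_k number of CV folds.
#' @param alpha CI-test level.
#' @param n_restarts hill-climb restarts.
#' @param prediction_mode `"full"` or `"parents"`.
#' @param group_by_patient if TRUE, CV folds are assigned at patient level.
#' @param seed master seed; per-stage seeds are derived from it.
#' @return list of class `"pipeline_config"`.
#' @export
pipeline_config <- function(generator = generator_config(),
                            truth = default_truth(),
                            input_dir = NULL,
                            dichotomy = dichotomy_config(),
                            learners = c("hill_climb", "grow_shrink", "iamb"),
                            cv_k = 5, alpha = 0.05, n_restarts = 5,
                            prediction_mode = "full",
                            group_by_patient = FALSE,
                            seed = 1) {
  if (!is.null(input_dir)) generator <- NULL
  if (is.null(generator) == is.null(input_dir))
    stop("exactly one of generator config or input_dir must be active")
  if (!is.null(input_dir)) {
    for (f in c("instances.csv", "ratings.csv"))
      if (!file.exists(file.path(input_dir, f)))
        stop("input_dir is missing ", f)
  }
  structure(list(generator = generator, truth = truth, input_dir = input_dir,
                 dichotomy = dichotomy, learners = learners, cv_k = cv_k,
                 alpha = alpha, n_restarts = n_restarts,
                 prediction_mode = prediction_mode,
                 group_by_patient = group_by_patient,
                 seed = as.integer(seed)),
            class = "pipeline_config")
}

# Per-stage seeds derived from the master seed, kept under 2^31.
derive_seed <- function(master, stage) {
  (as.numeric(master) * 1009 + stage * 9973) %% 2147483647
}

#' Run the full analysis pipeline
#'
#' Executes simulate/read -> aggregate -> ICC -> correlations and
#' dichotomized frequency table -> hill-climb network with arc strengths ->
#' cross-validated guarding prediction for every configured learner plus the
#' mean-predictor baseline, all on the same record set. Fully reproducible
#' from (config, seed).
#'
#' @param config a [pipeline_config()].
#' @param quiet suppress stage logging.
#' @return list of class `"report_bundle"`: `records`, `icc`, `correlations`,
#'   `fig1_counts`, `network` (a `gaussian_fit`), `strengths`, `cv` (named
#'   list of `cv_report`s incl. `empty` baseline), `provenance`.
#' @export
run_pipeline <- function(config = pipeline_config(), quiet = FALSE) {
  say <- function(...) if (!quiet) message(...)
  stage <- function(what, expr) {
    tryCatch(expr, error = function(e)
      stop("pipeline stage '", what, "' failed: ", conditionMessage(e),
           call. = FALSE))
  }
  if (!is.null(config$generator)) {
    gen <- config$generator
    gen$seed <- as.integer(derive_seed(config$seed, 1))
    cohort <- stage("simulate", simulate_cohort(gen, config$truth))
    say("simulate: ", nrow(cohort$instances), " instances, ",
        nrow(cohort$ratings), " ratings")
  } else {
    cohort <- stage("read", read_cohort(config$input_dir))
    say("read: ", nrow(cohort$instances), " instances")
  }
  records <- stage("aggregate",
                   assemble_records(cohort$instances, cohort$ratings))
  say("aggregate: ", nrow(records), " records pass the inclusion rule")
  icc <- stage("icc", icc_table(cohort$instances, cohort$ratings))
  corr <- stage("correlations", correlation_matrix(records))
  lab <- stage("dichotomize", dichotomize(records, config$dichotomy))
  fig1 <- stage("frequencies", guarding_frequency_table(lab))
  mat <- records_matrix(records)
  say("network: ", nrow(mat), " complete records")
  net <- stage("network",
               hill_climb(mat, seed = as.integer(derive_seed(config$seed, 2)),
                          n_restarts = config$n_restarts))
  strengths <- stage("strengths", arc_strengths(mat, net))
  grp <- if (config$group_by_patient)
    records$patient_id[stats::complete.cases(records[.ANALYSIS_VARS])]
  else NULL
  cv <- list()
  for (ln in unique(c(config$learners, "empty"))) {
    cv[[ln]] <- stage(paste0("cv_", ln), cross_validated_mse(
      mat, learner = ln, target = "guarding", k = config$cv_k,
      seed = as.integer(derive_seed(config$seed, 3)),
      mode = config$prediction_mode, alpha = config$alpha,
      n_restarts = config$n_restarts, group_by = grp))
    say("cv ", ln, ": mean MSE ", sprintf("%.3f", cv[[ln]]$mean_mse))
  }
  prov <- list(seed = config$seed, config_hash = config_hash(config),
               package_version = as.character(utils::packageVersion("guardnet")))
  structure(list(records = records, icc = icc, correlations = corr,
                 fig1_counts = fig1, network = net, strengths = strengths,
                 cv = cv, provenance = prov),
            class = "report_bundle")
}

config_hash <- function(config) {
  tmp <- tempfile(fileext = ".json")
  on.exit(unlink(tmp))
  cfg <- config
  cfg$truth <- if (!is.null(cfg$truth))
    list(edges = as.data.frame(dag_edges(cfg$truth$structure)),
         coefficients = as.list(cfg$truth$coefficients),
         intercepts = as.list(cfg$truth$intercepts),
         residual_sd = as.list(cfg$truth$residual_sd))
  jsonlite::write_json(lapply(cfg, unclass), tmp, auto_unbox = TRUE,
                       digits = NA, force = TRUE)
  unname(tools::md5sum(tmp))
}

#' Write a report bundle to disk
#'
#' Writes the tables as CSV, the learned network as a Graphviz DOT file and
#' an edge CSV, the CV reports, and a provenance JSON; returns a manifest of
#' files with MD5 checksums.
#'
#' @param bundle a `report_bundle`.
#' @param out_dir output directory (created if needed).
#' @return data.frame manifest (file, md5), invisibly also written as
#'   `manifest.csv`.
#' @export
write_report <- function(bundle, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  if (file.access(out_dir, 2) != 0) stop("output directory is not writable")
  w <- function(df, name) {
    utils::write.csv(df, file.path(out_dir, name), row.names = FALSE)
    name
  }
  files <- c(
    w(bundle$records, "records.csv"),
    w(bundle$icc, "icc.csv"),
    w(bundle$correlations$table, "correlations.csv"),
    w(bundle$fig1_counts, "fig1_counts.csv"),
    w(bundle$strengths, "network_edges.csv"))
  cvdf <- do.call(rbind, lapply(bundle$cv, function(r)
    data.frame(learner = r$learner, fold = seq_len(r$k), mse = r$fold_mse,
               n = r$fold_n, mean_mse = r$mean_mse, mode = r$mode)))
  files <- c(files, w(cvdf, "cv_report.csv"))
  dot <- file.path(out_dir, "network.dot")
  writeLines(dag_to_dot(bundle$network$dag, bundle$strengths), dot)
  files <- c(files, "network.dot")
  prov <- file.path(out_dir, "provenance.json")
  jsonlite::write_json(bundle$provenance, prov, auto_unbox = TRUE,
                       digits = NA)
  files <- c(files, "provenance.json")
  manifest <- data.frame(
    file = files,
    md5 = unname(tools::md5sum(file.path(out_dir, files))))
  utils::write.csv(manifest, file.path(out_dir, "manifest.csv"),
                   row.names = FALSE)
  manifest
}

#' Graphviz DOT rendering of a DAG
#' @param g a `guardnet_dag`.
#' @param strengths optional arc-strength table used as edge labels.
#' @return character vector of DOT lines.
#' @export
dag_to_dot <- function(g, strengths = NULL) {
  e <- dag_edges(g)
  lab <- ""
  lines <- c("digraph network {", paste0("  \"", g$nodes, "\";"))
  if (nrow(e) > 0) {
    lab <- rep("", nrow(e))
    if (!is.null(strengths)) {
      key <- paste(strengths$tail, strengths$head)
      idx <- match(paste(e[, 1], e[, 2]), key)
      lab <- ifelse(is.na(idx), "",
                    sprintf(" [label=\"%.1f\"]", strengths$strength[idx]))
    }
    lines <- c(lines,
               paste0("  \"", e[, 1], "\" -> \"", e[, 2], "\"", lab, ";"))
  }
  c(lines, "}")
}
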