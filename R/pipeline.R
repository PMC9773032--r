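# End-to-end orchestration: simulate/load -> match -> select features ->
# bicluster -> replicate -> classify -> risk table -> annotate -> predict ->
# compare -> report. Every stage reads its inputs from and writes its
# outputs to the run directory, so stages are independently re-runnable and
# the full pipeline is just their composition.

#' Build a validated pipeline configuration
#'
#' @param seed Master seed (mandatory); per-stage seeds are derived from it
#'   deterministically and logged, so each stage is independently
#'   reproducible.
#' @param out_dir Run directory for all artifacts.
#' @param cohort_csv Path to an existing cohort CSV (schema of
#'   [write_cohort()]); mutually exclusive with `synthetic`.
#' @param synthetic Named list of [cohort_spec()] arguments for the built-in
#'   generator.
#' @param alpha Feature-selection significance level before Bonferroni
#'   correction.
#' @param prevalence_threshold Prevalence filter threshold.
#' @param matching_keys Demographic fields for 1:1 exact matching.
#' @param restarts Optimizer restarts for the observed partitions.
#' @param perm_restarts Reduced restart budget for permutation nulls.
#' @param n_perm Permutations for modularity significance and replication.
#' @param n_splits Repeated splits for classifier internal validation.
#' @param visual_split Training fraction of the visual-analytical split.
#' @param model_split Training fraction of the classifier/prediction splits.
#' @param nri_cutpoints Categorical NRI cutpoints (`NULL` = tertiles).
#' @param null_model Permutation null: `"swap"` or `"shuffle"`.
#' @return Object of class `run_config`.
#' @export
run_config <- function(seed, out_dir, cohort_csv = NULL, synthetic = NULL,
                       alpha = 0.05, prevalence_threshold = 0.01,
                       matching_keys = c("age_band", "sex", "race",
                                         "medicaid"),
                       restarts = 20, perm_restarts = 5, n_perm = 1000,
                       n_splits = 1000, visual_split = 0.5,
                       model_split = 0.75, nri_cutpoints = NULL,
                       null_model = "swap") {
  if (missing(seed) || is.null(seed))
    stop("a master seed is mandatory for every stochastic stage")
  stopifnot(visual_split > 0, visual_split < 1,
            model_split > 0, model_split < 1)
  if (is.null(cohort_csv) && is.null(synthetic))
    stop("config needs either cohort_csv or a synthetic cohort spec")
  if (!is.null(cohort_csv) && !file.exists(cohort_csv))
    stop("input cohort not found: ", cohort_csv)
  structure(list(
    seed = as.integer(seed), out_dir = out_dir, cohort_csv = cohort_csv,
    synthetic = synthetic, alpha = alpha,
    prevalence_threshold = prevalence_threshold,
    matching_keys = matching_keys, restarts = restarts,
    perm_restarts = perm_restarts, n_perm = n_perm, n_splits = n_splits,
    visual_split = visual_split, model_split = model_split,
    nri_cutpoints = nri_cutpoints, null_model = null_model),
    class = "run_config")
}

#' Load a pipeline configuration from a YAML or JSON file
#'
#' @param path Config file (`.yaml`/`.yml` or `.json`).
#' @param ... Overrides passed to [run_config()].
#' @return A `run_config`.
#' @export
load_run_config <- function(path, ...) {
  ext <- tolower(tools::file_ext(path))
  raw <- if (ext %in% c("yaml", "yml")) yaml::read_yaml(path) else
    jsonlite::read_json(path, simplifyVector = TRUE)
  over <- list(...)
  raw[names(over)] <- over
  do.call(run_config, raw)
}

# --- run-directory bookkeeping ----------------------------------------------

manifest_path <- function(config) file.path(config$out_dir, "manifest.json")

read_manifest <- function(config) {
  p <- manifest_path(config)
  if (file.exists(p)) jsonlite::read_json(p, simplifyVector = TRUE) else list()
}

record_stage <- function(config, stage, files, seed = NULL) {
  man <- read_manifest(config)
  man[[stage]] <- list(files = files, seed = seed)
  jsonlite::write_json(man, manifest_path(config), auto_unbox = TRUE,
                       digits = NA)
  invisible(man)
}

require_stage <- function(config, stage) {
  man <- read_manifest(config)
  if (is.null(man[[stage]]))
    stop("stage-order violation: run '", stage, "' first")
  invisible(man[[stage]])
}

log_line <- function(config, stage, msg) {
  line <- sprintf("[%s] %s: %s", format(Sys.time(), "%Y-%m-%d %H:%M:%S"),
                  stage, msg)
  cat(line, "\n", sep = "", file = file.path(config$out_dir, "run.log"),
      append = TRUE)
  invisible(line)
}

init_run_dir <- function(config) {
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  # echo the config verbatim into the log so the run is auditable
  log_line(config, "config",
           jsonlite::toJSON(unclass(config), auto_unbox = TRUE, null = "null"))
}

# --- stages -----------------------------------------------------------------

#' Pipeline stages
#'
#' Each stage consumes the previous stage's declared files from
#' `config$out_dir` and writes its own, so stages can be run independently
#' (and from the command line); [run_pipeline()] is their composition.
#'
#' @param config A [run_config()].
#' @return Each stage returns its main result invisibly.
#' @name pipeline_stages
NULL

#' @rdname pipeline_stages
#' @export
stage_simulate <- function(config) {
  init_run_dir(config)
  if (!is.null(config$cohort_csv)) {
    cohort <- read_cohort(config$cohort_csv)
    write_cohort(cohort, file.path(config$out_dir, "cohort.csv"))
    log_line(config, "simulate",
             sprintf("loaded %d patients from %s", nrow(cohort),
                     config$cohort_csv))
  } else {
    sp <- config$synthetic
    sp$seed <- sp$seed %||% stage_seed(config$seed, "simulate")
    spec <- do.call(cohort_spec, sp)
    cohort <- generate_cohort(spec)
    write_cohort(cohort, file.path(config$out_dir, "cohort.csv"))
    log_line(config, "simulate",
             sprintf("generated %d cases / %d controls (seed %d)",
                     sum(cohort$is_case), sum(!cohort$is_case), spec$seed))
  }
  record_stage(config, "simulate", "cohort.csv",
               stage_seed(config$seed, "simulate"))
  invisible(cohort)
}

#' @rdname pipeline_stages
#' @export
stage_select_features <- function(config) {
  require_stage(config, "simulate")
  cohort <- read_cohort(file.path(config$out_dir, "cohort.csv"))
  halves <- split_halves(cohort, seed = stage_seed(config$seed, "split"))
  splits <- rbind(
    data.frame(patient_id = halves$train$patient_id, half = "train"),
    data.frame(patient_id = halves$replication$patient_id,
               half = "replication"))
  write.csv(splits, file.path(config$out_dir, "splits.csv"),
            row.names = FALSE)
  match_seed <- stage_seed(config$seed, "match")
  matched <- lapply(halves, function(h) {
    m <- match_controls(h[h$is_case, ], h[!h$is_case, ],
                        keys = config$matching_keys, seed = match_seed)
    log_line(config, "match",
             sprintf("%d pairs, %d unmatched cases", nrow(m$pairs),
                     length(m$unmatched_cases)))
    matched_cohort(m, h[h$is_case, ], h[!h$is_case, ])
  })
  report <- select_features(matched$train, matched$replication,
                            alpha = config$alpha,
                            prevalence_threshold = config$prevalence_threshold)
  write.csv(as.data.frame(report),
            file.path(config$out_dir, "feature_report.csv"),
            row.names = FALSE)
  log_line(config, "select-features",
           sprintf("%d tested, %d survived (alpha_bonf = %.3g)",
                   attr(report, "d_tested"), sum(report$survived),
                   attr(report, "alpha_bonf")))
  record_stage(config, "select-features",
               c("splits.csv", "feature_report.csv"), match_seed)
  invisible(report)
}

#' @rdname pipeline_stages
#' @export
stage_bicluster <- function(config) {
  require_stage(config, "select-features")
  cohort <- read_cohort(file.path(config$out_dir, "cohort.csv"))
  splits <- read.csv(file.path(config$out_dir, "splits.csv"),
                     stringsAsFactors = FALSE)
  report <- read.csv(file.path(config$out_dir, "feature_report.csv"),
                     stringsAsFactors = FALSE)
  selected <- report$comorbidity[report$survived]
  if (length(selected) < 2)
    stop("only ", length(selected), " comorbidity survived feature ",
         "selection; biclustering and replication need at least 2")
  half_of <- setNames(splits$half, splits$patient_id)
  parts <- list()
  graphs <- list()
  for (h in c("train", "replication")) {
    cases <- cohort[cohort$is_case & half_of[cohort$patient_id] == h, ]
    cases <- drop_empty_patients(cases, selected)
    log_line(config, "bicluster",
             sprintf("%s half: %d cases after dropping %d empty", h,
                     nrow(cases), attr(cases, "n_dropped")))
    graphs[[h]] <- build_graph(cases, selected)
    parts[[h]] <- maximize_modularity(
      graphs[[h]], restarts = config$restarts,
      seed = stage_seed(config$seed, paste0("bicluster-", h)))
  }
  sig <- modularity_significance(
    graphs$train, partition = parts$train, n_perm = config$n_perm,
    seed = stage_seed(config$seed, "permutation"),
    restarts = config$perm_restarts, null = config$null_model)
  repl <- replication_test(parts$train, parts$replication,
                           n_perm = config$n_perm,
                           seed = stage_seed(config$seed, "replication"))
  write.csv(partition_table(parts$train),
            file.path(config$out_dir, "partition_train.csv"),
            row.names = FALSE)
  write.csv(partition_table(parts$replication),
            file.path(config$out_dir, "partition_replication.csv"),
            row.names = FALSE)
  export_graphml(graphs$train, parts$train,
                 file.path(config$out_dir, "network.graphml"),
                 significance = sig)
  stats <- list(K = parts$train$K, Q = parts$train$Q, z = sig$z,
                p_empirical = sig$p_empirical, p_normal = sig$p_normal,
                n_perm = sig$n_perm, null_model = sig$null_model,
                perm_restarts = config$perm_restarts,
                ri = repl$ri, ri_z = repl$z, ri_p = repl$p,
                K_replication = parts$replication$K,
                Q_replication = parts$replication$Q)
  jsonlite::write_json(stats, file.path(config$out_dir,
                                        "bicluster_stats.json"),
                       auto_unbox = TRUE, digits = NA)
  log_line(config, "bicluster",
           sprintf("K = %d, Q = %.3f, z = %.2f, P = %.4g; RI = %.3f (P = %.4g)",
                   parts$train$K, parts$train$Q, sig$z, sig$p_empirical,
                   repl$ri, repl$p))
  record_stage(config, "bicluster",
               c("partition_train.csv", "partition_replication.csv",
                 "network.graphml", "bicluster_stats.json"),
               stage_seed(config$seed, "bicluster-train"))
  invisible(list(partitions = parts, significance = sig,
                 replication = repl))
}

#' @rdname pipeline_stages
#' @export
stage_classify <- function(config) {
  require_stage(config, "bicluster")
  cohort <- read_cohort(file.path(config$out_dir, "cohort.csv"))
  report <- read.csv(file.path(config$out_dir, "feature_report.csv"),
                     stringsAsFactors = FALSE)
  selected <- report$comorbidity[report$survived]
  ptab <- read.csv(file.path(config$out_dir, "partition_train.csv"),
                   stringsAsFactors = FALSE)
  plab <- ptab[ptab$type == "patient", ]
  train_cases <- cohort[match(plab$node_id, cohort$patient_id), ]
  train_cases$subgroup <- plab$cluster
  fit_seed <- stage_seed(config$seed, "classifier")
  model <- fit_subgroup_model(train_cases, selected, seed = fit_seed)
  vs <- internal_validation(train_cases, selected,
                            n_splits = config$n_splits,
                            train_frac = config$model_split,
                            seed = stage_seed(config$seed, "validation"))
  memberships <- classify_all(model, cohort[cohort$is_case, ],
                              cohort[!cohort$is_case, ])
  risks <- subgroup_risk(memberships)
  write.csv(memberships, file.path(config$out_dir, "memberships.csv"),
            row.names = FALSE)
  vs_df <- data.frame(fold = c("training", "testing"),
                      rbind(vs$training, vs$testing))
  write.csv(vs_df, file.path(config$out_dir, "validation_summary.csv"),
            row.names = FALSE)
  write.csv(as.data.frame(risks),
            file.path(config$out_dir, "subgroup_risks.csv"),
            row.names = FALSE)
  # annotated network figure for clinical interpretation
  cases_sel <- drop_empty_patients(train_cases, selected)
  graph <- build_graph(cases_sel, selected)
  part <- bicluster_partition(
    graph,
    patient_labels = cases_sel$subgroup,
    comorbidity_labels = ptab$cluster[match(graph$comorbidities,
                                            ptab$node_id)])
  lay <- layout_network(graph, part,
                        seed = stage_seed(config$seed, "layout"))
  report_df <- report
  class(report_df) <- c("feature_report", "data.frame")
  fig <- file.path(config$out_dir,
                   if (capabilities("cairo")) "network.svg" else "network.png")
  ann <- annotate_network(lay, report_df, risks, file = fig, graph = graph)
  write.csv(ann, file.path(config$out_dir, "annotation.csv"),
            row.names = FALSE)
  log_line(config, "classify",
           sprintf("training accuracy %.2f%%; median testing accuracy %.2f%%",
                   100 * model$training_accuracy, vs$testing["q50"]))
  record_stage(config, "classify",
               c("memberships.csv", "validation_summary.csv",
                 "subgroup_risks.csv", "annotation.csv", basename(fig)),
               fit_seed)
  invisible(list(model = model, validation = vs, memberships = memberships,
                 risks = risks))
}

#' @rdname pipeline_stages
#' @export
stage_predict <- function(config) {
  require_stage(config, "classify")
  cohort <- read_cohort(file.path(config$out_dir, "cohort.csv"))
  report <- read.csv(file.path(config$out_dir, "feature_report.csv"),
                     stringsAsFactors = FALSE)
  selected <- report$comorbidity[report$survived]
  memberships <- read.csv(file.path(config$out_dir, "memberships.csv"),
                          stringsAsFactors = FALSE)
  dat <- cohort
  dat$assigned_subgroup <- memberships$assigned_subgroup[
    match(dat$patient_id, memberships$patient_id)]
  n <- nrow(dat)
  idx <- withr::with_seed(stage_seed(config$seed, "predict-split"),
                          sample(n, round(config$model_split * n)))
  train <- dat[idx, ]
  valid <- dat[-idx, ]
  demo <- intersect(c("age_band", "sex", "race", "medicaid"), names(dat))
  standard <- fit_prediction_model(train, "standard", selected, demo)
  hierarchical <- fit_prediction_model(train, "hierarchical", selected, demo)
  cmp <- compare_models(standard, hierarchical, valid,
                        memberships = memberships,
                        cutpoints = config$nri_cutpoints)
  out <- list(
    n_train = nrow(train), n_validation = nrow(valid),
    c_standard = cmp$c_standard[c("c_statistic", "ci95")],
    c_hierarchical = cmp$c_hierarchical[c("c_statistic", "ci95")],
    c_test = cmp$c_test[c("chi2", "df", "p", "z")],
    calibration_standard = cmp$calibration_standard[
      c("slope", "slope_ci", "citl", "citl_ci")],
    calibration_hierarchical = cmp$calibration_hierarchical[
      c("slope", "slope_ci", "citl", "citl_ci")],
    per_subgroup_c = cmp$per_subgroup,
    nri_continuous = cmp$nri$continuous[c("estimate", "ci95", "z", "p")],
    nri_categorical = if (!is.null(cmp$nri$categorical))
      cmp$nri$categorical[c("estimate", "ci95", "z", "p")],
    idi = cmp$idi[c("estimate", "ci95", "z", "p")],
    cutpoints = cmp$cutpoints,
    separation = c(standard = standard$separation,
                   hierarchical = hierarchical$separation))
  jsonlite::write_json(out, file.path(config$out_dir,
                                      "model_comparison.json"),
                       auto_unbox = TRUE, digits = NA)
  coefs <- function(m) data.frame(term = names(coef(m$fit)),
                                  estimate = unname(coef(m$fit)))
  write.csv(coefs(standard),
            file.path(config$out_dir, "model_standard.csv"),
            row.names = FALSE)
  write.csv(coefs(hierarchical),
            file.path(config$out_dir, "model_hierarchical.csv"),
            row.names = FALSE)
  log_line(config, "predict",
           sprintf("C %.3f vs %.3f, P = %.3g; NRI cont %.3f; IDI %.4f",
                   cmp$c_standard$c_statistic,
                   cmp$c_hierarchical$c_statistic, cmp$c_test$p,
                   cmp$nri$continuous$estimate, cmp$idi$estimate))
  record_stage(config, "predict",
               c("model_comparison.json", "model_standard.csv",
                 "model_hierarchical.csv"),
               stage_seed(config$seed, "predict-split"))
  invisible(cmp)
}

#' @rdname pipeline_stages
#' @export
stage_report <- function(config) {
  for (s in c("simulate", "select-features", "bicluster", "classify",
              "predict"))
    require_stage(config, s)
  # the reporter only collates stage outputs; it recomputes nothing
  stats <- jsonlite::read_json(file.path(config$out_dir,
                                         "bicluster_stats.json"),
                               simplifyVector = TRUE)
  vs <- read.csv(file.path(config$out_dir, "validation_summary.csv"),
                 stringsAsFactors = FALSE)
  risks <- read.csv(file.path(config$out_dir, "subgroup_risks.csv"),
                    stringsAsFactors = FALSE)
  mc <- jsonlite::read_json(file.path(config$out_dir,
                                      "model_comparison.json"),
                            simplifyVector = TRUE)
  report <- read.csv(file.path(config$out_dir, "feature_report.csv"),
                     stringsAsFactors = FALSE)
  summary <- list(
    seed = config$seed,
    n_features_tested = sum(report$retained),
    n_features_survived = sum(report$survived),
    biclustering = stats,
    classifier = list(
      median_testing_accuracy = vs$q50[vs$fold == "testing"],
      mean_testing_accuracy = vs$mean[vs$fold == "testing"],
      mean_training_accuracy = vs$mean[vs$fold == "training"]),
    subgroup_risks = risks,
    prediction = mc)
  jsonlite::write_json(summary, file.path(config$out_dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  record_stage(config, "report", "summary.json")
  invisible(summary)
}

#' Run the full pipeline
#'
#' Composition of [stage_simulate()], [stage_select_features()],
#' [stage_bicluster()], [stage_classify()], [stage_predict()] and
#' [stage_report()]; any stage failure aborts with the stage name. All
#' artifacts (CSV tables, GraphML network, figure, JSON summaries, run log)
#' are written to `config$out_dir`.
#'
#' @param config A [run_config()].
#' @return The summary list, invisibly.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  stage_simulate(config)
  stage_select_features(config)
  stage_bicluster(config)
  stage_classify(config)
  stage_predict(config)
  out <- stage_report(config)
  log_line(config, "pipeline", "completed")
  invisible(out)
}
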