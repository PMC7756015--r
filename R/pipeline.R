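#' Pipeline run configuration
#'
#' Everything needed to reproduce a full experiment: the sweep protocol,
#' fluid properties, cohort priors, cross-validation controls, and the
#' master seed.
#'
#' @param seed master seed; the cohort and the fold assignment derive their
#'   seeds from it
#' @param cohort a [cohort_config()]; its own seed is overridden by `seed`
#' @param sweep a [sweep_config()]
#' @param fluid a [fluid_properties()]
#' @param k number of cross-validation folds (default 5)
#' @param threshold_rule operating-point rule, `"youden"` or `"fixed"`
#' @param fixed_threshold probability threshold for `"fixed"`
#' @return an object of class `run_config`
#' @export
run_config <- function(seed = 42L, cohort = cohort_config(seed = seed),
                       sweep = sweep_config(), fluid = fluid_properties(),
                       k = 5L, threshold_rule = "youden",
                       fixed_threshold = 0.5) {
  stopifnot(inherits(cohort, "cohort_config"),
            inherits(sweep, "sweep_config"),
            inherits(fluid, "fluid_properties"), k >= 2L)
  cohort$seed <- as.integer(seed)
  structure(list(seed = as.integer(seed), cohort = cohort, sweep = sweep,
                 fluid = fluid, k = as.integer(k),
                 threshold_rule = threshold_rule,
                 fixed_threshold = fixed_threshold),
            class = "run_config")
}

#' Read a run configuration from JSON or YAML
#'
#' Accepts a document whose top-level keys mirror the [run_config()]
#' arguments (`seed`, `k`, `threshold_rule`, `fixed_threshold`, and nested
#' `cohort`, `sweep`, `fluid` objects whose keys mirror the corresponding
#' constructors); missing keys take the package defaults.
#'
#' @param path path to a `.json`, `.yml` or `.yaml` file
#' @return a `run_config`
#' @export
read_run_config <- function(path) {
  doc <- if (grepl("\\.ya?ml$", path, ignore.case = TRUE))
    yaml::read_yaml(path)
  else jsonlite::read_json(path, simplifyVector = TRUE)
  if (!is.null(doc$cohort)) {
    # YAML 1.1 resolves a bare key `n` to boolean FALSE; map it back
    names(doc$cohort)[names(doc$cohort) == "FALSE"] <- "n"
  }
  take <- function(ctor, args) {
    args <- args[names(args) %in% names(formals(ctor))]
    do.call(ctor, lapply(args, function(a) unlist(a, use.names = FALSE)))
  }
  seed <- doc$seed %||% 42L
  run_config(
    seed = as.integer(seed),
    cohort = take(cohort_config, c(doc$cohort, list(seed = seed))),
    sweep = take(sweep_config, doc$sweep %||% list()),
    fluid = take(fluid_properties, doc$fluid %||% list()),
    k = as.integer(doc$k %||% 5L),
    threshold_rule = doc$threshold_rule %||% "youden",
    fixed_threshold = doc$fixed_threshold %||% 0.5)
}

#' Run the full diagnostic pipeline
#'
#' End-to-end experiment: generate the virtual cohort, characterize every
#' patient by the resistance sweep, cross-validate the combined `(f, s)`
#' logistic model alongside the single-feature and ESC comparators, and
#' compute the Spearman correlation matrix of (PSPG, f, s).  With an
#' `output_dir` the cohort table, feature table, sweep points, fold
#' assignment, metric summary (CSV) and the full report (JSON) are written
#' out; every file round-trips through the package readers.
#'
#' @param config a [run_config()]
#' @param output_dir optional directory for the report files
#' @return an object of class `pipeline_report`: `cohort_summary`,
#'   `features`, `cv` (the `cv_report`), `spearman`, `config`, plus the
#'   written `files` when `output_dir` is given
#' @export
run_pipeline <- function(config = run_config(), output_dir = NULL) {
  stopifnot(inherits(config, "run_config"))
  cohort <- generate_cohort(config$cohort, config$fluid)
  features <- characterize_cohort(cohort, config$fluid, config$sweep,
                                  keep_sweeps = !is.null(output_dir))
  cv <- cross_validate(features, k = config$k, seed = config$seed,
                       threshold_rule = config$threshold_rule,
                       fixed_threshold = config$fixed_threshold)
  sp <- spearman_matrix(data.frame(pspg = features$pspg_measured,
                                   f = features$f, s = features$s))
  report <- structure(
    list(schema = "coaflow-report/1.0",
         config = config,
         cohort_summary = list(
           n = length(cohort$patients),
           n_positive = cohort$n_positive,
           n_negative = length(cohort$patients) - cohort$n_positive,
           severity_location = cohort$severity_location),
         features = features, cv = cv,
         spearman = sp),
    class = "pipeline_report")
  if (!is.null(output_dir)) {
    dir.create(output_dir, recursive = TRUE, showWarnings = FALSE)
    files <- c(
      cohort = file.path(output_dir, "cohort.csv"),
      features = file.path(output_dir, "features.csv"),
      sweeps = file.path(output_dir, "sweeps.csv"),
      folds = file.path(output_dir, "folds.csv"),
      summary = file.path(output_dir, "cv_summary.csv"),
      report = file.path(output_dir, "report.json"))
    write_cohort_csv(cohort, files[["cohort"]])
    utils::write.csv(features, files[["features"]], row.names = FALSE)
    sw <- attr(features, "sweeps")
    utils::write.csv(data.frame(patient_id = sw$patient_id,
                                scale = sw$scale,
                                total_resistance = sw$total_resistance,
                                Q_bar_cm3_s = sw$Q_bar,
                                dp_bar_mmHg = sw$dp_bar),
                     files[["sweeps"]], row.names = FALSE)
    utils::write.csv(data.frame(patient_id = features$patient_id,
                                fold = cv$folds),
                     files[["folds"]], row.names = FALSE)
    utils::write.csv(cv$summary, files[["summary"]], row.names = FALSE)
    jsonlite::write_json(
      list(schema = "coaflow-report/1.0",
           seed = config$seed,
           cohort_summary = report$cohort_summary,
           averages = cv$averages,
           per_fold = cv$summary,
           spearman_rho = as.data.frame(sp$rho),
           spearman_p = as.data.frame(sp$p)),
      files[["report"]], auto_unbox = TRUE, digits = NA)
    report$files <- files
  }
  report
}

#' @export
print.pipeline_report <- function(x, ...) {
  cs <- x$cohort_summary
  cat(sprintf("coaflow pipeline report (seed %d)\n", x$config$seed))
  cat(sprintf("  cohort: %d patients (%d CoA / %d non-CoA)\n",
              cs$n, cs$n_positive, cs$n_negative))
  cat("  cross-validated averages:\n")
  print(x$cv$averages, digits = 3)
  cat("  Spearman rho (PSPG, f, s):\n")
  print(round(x$spearman$rho, 3))
  invisible(x)
}
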