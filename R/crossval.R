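## Evaluate code with a locally seeded RNG, restoring the caller's RNG state.
with_local_seed <- function(seed, code) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_seed) get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

#' Stratified fold assignment
#'
#' Partitions patients into `k` folds of near-equal size (exactly equal when
#' `n` is divisible by `k`).  Stratification is exact on the CoA label --
#' per-fold positive counts differ by at most one -- and approximate on the
#' covariates: within each label the patients are shuffled (seeded), stably
#' sorted by sex and age, and dealt round-robin, so consecutive deals land in
#' different folds while sex/age composition stays balanced.
#'
#' @param labels binary CoA labels
#' @param sex optional covariate used for secondary balancing
#' @param age optional covariate used for secondary balancing
#' @param k number of folds (default 5)
#' @param seed integer seed of the shuffle
#' @return integer vector of fold indices in `1..k`, one per patient
#' @export
stratified_partition <- function(labels, sex = NULL, age = NULL, k = 5L,
                                 seed = 1L) {
  y <- as.numeric(labels)
  n <- length(y)
  if (n < k) stop("invalid parameter: need n >= k", call. = FALSE)
  if (!all(y %in% c(0, 1)) || length(unique(y)) < 2L)
    stop("both classes must be present", call. = FALSE)
  if (is.null(sex)) sex <- rep(0L, n)
  if (is.null(age)) age <- rep(0, n)
  fold <- integer(n)
  offset <- 0L
  with_local_seed(seed, {
    for (lab in c(1, 0)) {
      idx <- which(y == lab)
      idx <- idx[sample.int(length(idx))]
      idx <- idx[order(sex[idx], rank(age)[idx])]  # stable: shuffle survives ties
      fold[idx] <- ((offset + seq_along(idx) - 1L) %% k) + 1L
      offset <- offset + length(idx)
    }
  })
  fold
}

## Metric row for one model on one data split.
split_metrics <- function(scores, labels, threshold) {
  roc <- roc_auc(scores, labels)
  cm <- classification_metrics(scores, labels, threshold)
  data.frame(auc = roc$auc, ci_low = roc$ci_low, ci_high = roc$ci_high,
             sensitivity = cm$sensitivity, specificity = cm$specificity,
             accuracy = cm$accuracy, threshold = threshold)
}

#' Stratified k-fold cross-validation of the diagnosis models
#'
#' Reproduces the evaluation design of the pipeline: for each fold a
#' logistic model is fit per feature set on the remaining `k - 1` folds,
#' scored on both the training split and the held-out test split, and
#' summarized by AUC (with DeLong CI), sensitivity, specificity and accuracy
#' at an operating threshold chosen on the training split (Youden-optimal by
#' default, or a fixed probability).  The anatomic ESC narrowing-rate rule
#' is evaluated alongside as a fixed comparator.  Averages over folds are
#' unweighted; folds whose test split contains a single class are reported
#' as degenerate and excluded from the averages with a warning.
#'
#' @param features feature table from [characterize_cohort()] (needs columns
#'   `label`, the feature columns, and `narrowing_rate` for the ESC
#'   comparator; `sex`/`age_months` are used for stratification when present)
#' @param k number of folds (default 5)
#' @param seed partition seed
#' @param feature_sets named list of feature-column subsets to fit
#' @param threshold_rule `"youden"` or `"fixed"`
#' @param fixed_threshold probability threshold when `threshold_rule =
#'   "fixed"`
#' @param esc_column column holding the narrowing rate, or `NULL` to skip
#'   the comparator
#' @return an object of class `cv_report`: `folds` (assignment), `summary`
#'   (per fold x model x split metrics), `averages` (unweighted fold means),
#'   `models` (per-fold fitted models), `degenerate_folds`
#' @export
cross_validate <- function(features, k = 5L, seed = 1L,
                           feature_sets = list(combined = c("f", "s"),
                                               f_only = "f", s_only = "s"),
                           threshold_rule = c("youden", "fixed"),
                           fixed_threshold = 0.5,
                           esc_column = "narrowing_rate") {
  threshold_rule <- match.arg(threshold_rule)
  stopifnot(is.data.frame(features), "label" %in% names(features))
  y <- as.numeric(features$label)
  fold <- stratified_partition(y, features$sex, features$age_months, k, seed)
  degenerate <- integer(0)
  rows <- list()
  models <- vector("list", k)
  for (i in seq_len(k)) {
    train <- which(fold != i)
    test <- which(fold == i)
    if (length(unique(y[test])) < 2L || length(unique(y[train])) < 2L ||
        min(table(y[train])) < 2L) {
      degenerate <- c(degenerate, i)
      next
    }
    models[[i]] <- list()
    for (mn in names(feature_sets)) {
      cols <- feature_sets[[mn]]
      mod <- fit_logistic_model(features[train, cols, drop = FALSE], y[train])
      sc_train <- predict_coa_probability(
        mod, newdata = features[train, cols, drop = FALSE])
      sc_test <- predict_coa_probability(
        mod, newdata = features[test, cols, drop = FALSE])
      thr <- if (threshold_rule == "youden")
        youden_threshold(sc_train, y[train]) else fixed_threshold
      rows[[length(rows) + 1L]] <- cbind(
        data.frame(model = mn, fold = i, set = "train"),
        split_metrics(sc_train, y[train], thr))
      rows[[length(rows) + 1L]] <- cbind(
        data.frame(model = mn, fold = i, set = "test"),
        split_metrics(sc_test, y[test], thr))
      models[[i]][[mn]] <- mod
    }
    if (!is.null(esc_column) && esc_column %in% names(features)) {
      esc <- esc_classifier(features[[esc_column]])
      rows[[length(rows) + 1L]] <- cbind(
        data.frame(model = "esc", fold = i, set = "train"),
        split_metrics(esc[train], y[train], 0.5))
      rows[[length(rows) + 1L]] <- cbind(
        data.frame(model = "esc", fold = i, set = "test"),
        split_metrics(esc[test], y[test], 0.5))
    }
  }
  if (length(degenerate))
    warning("fold(s) ", paste(degenerate, collapse = ", "),
            " have a single-class (or unfittable) split; excluded from averages",
            call. = FALSE)
  metric_cols <- c("auc", "sensitivity", "specificity", "accuracy")
  if (length(rows)) {
    summary <- do.call(rbind, rows)
    averages <- do.call(rbind, lapply(
      split(summary, list(summary$model, summary$set), drop = TRUE),
      function(d) cbind(data.frame(model = d$model[1L], set = d$set[1L],
                                   n_folds = nrow(d)),
                        as.data.frame(as.list(colMeans(d[metric_cols]))))))
    rownames(averages) <- NULL
  } else {
    summary <- averages <- data.frame()
  }
  structure(list(folds = fold, summary = summary, averages = averages,
                 models = models, degenerate_folds = degenerate,
                 k = k, seed = seed),
            class = "cv_report")
}

#' @export
print.cv_report <- function(x, ...) {
  cat(sprintf("%d-fold stratified cross-validation (seed %s)\n", x$k, x$seed))
  print(x$averages, digits = 3)
  invisible(x)
}
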