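#' Fit the combined logistic diagnosis model
#'
#' Maximum-likelihood logistic regression of the CoA label on the stenosis
#' features, `P = 1 / (1 + exp(-(a f + b s + c)))`.  Fitting is by
#' iteratively reweighted least squares on internally standardized features
#' (for conditioning; coefficients are reported on the original scale), with
#' convergence declared when the log-likelihood changes by less than `tol`.
#' Complete separation is detected -- the iteration is stopped with capped
#' coefficients and the `separated` flag set -- rather than left to diverge.
#'
#' @param features data frame or matrix of numeric predictors (zero columns
#'   give an intercept-only model); for the canonical model the columns are
#'   `f` and `s`
#' @param labels binary vector (0/1 or logical), one per row of `features`
#' @param decision_threshold probability threshold stored with the model
#' @param max_iter,tol IRLS iteration controls
#' @return an object of class `diagnostic_model`: `coefficients` (named,
#'   `(intercept)` last), `decision_threshold`, `converged`, `separated`,
#'   `log_likelihood`, `iterations`; for the two-feature `(f, s)` model the
#'   aliases `a`, `b`, `c` are also set
#' @export
#' @examples
#' fit_logistic_model(data.frame(x = numeric(10))[, 0],
#'                    rep(c(1, 0), c(3, 7)))$coefficients  # log(3/7)
fit_logistic_model <- function(features, labels, decision_threshold = 0.5,
                               max_iter = 100L, tol = 1e-10) {
  y <- as.numeric(labels)
  if (!all(y %in% c(0, 1))) stop("labels must be binary", call. = FALSE)
  if (length(unique(y)) < 2L)
    stop("invalid labels: both classes must be present", call. = FALSE)
  xraw <- as.matrix(as.data.frame(features))
  if (nrow(xraw) == 0L) xraw <- matrix(0, length(y), 0L)
  if (nrow(xraw) != length(y))
    stop("features and labels must have equal length", call. = FALSE)
  if (ncol(xraw) > 0L && !all(is.finite(xraw)))
    stop("features must be finite", call. = FALSE)
  if (min(table(y)) < 2L)
    stop("need at least two patients per class", call. = FALSE)
  nm <- colnames(xraw)
  if (is.null(nm) && ncol(xraw) > 0L) nm <- paste0("x", seq_len(ncol(xraw)))

  # standardize for conditioning (f and s live on very different scales)
  ctr <- if (ncol(xraw)) colMeans(xraw) else numeric(0)
  scl <- if (ncol(xraw)) apply(xraw, 2L, stats::sd) else numeric(0)
  scl[!is.finite(scl) | scl == 0] <- 1
  x <- cbind(sweep(sweep(xraw, 2L, ctr), 2L, scl, "/"), 1)

  beta <- numeric(ncol(x))
  beta[ncol(x)] <- stats::qlogis(mean(y))
  loglik <- function(b) {
    eta <- drop(x %*% b)
    sum(y * eta - log1p(exp(pmin(eta, 700))) - pmax(eta - 700, 0))
  }
  ll <- loglik(beta)
  converged <- FALSE
  separated <- FALSE
  it <- 0L
  cap <- 30
  while (it < max_iter) {
    it <- it + 1L
    eta <- drop(x %*% beta)
    p <- stats::plogis(eta)
    w <- pmax(p * (1 - p), 1e-12)
    z <- eta + (y - p) / w
    beta_new <- tryCatch(
      solve(crossprod(x, x * w), crossprod(x, w * z)),
      error = function(e) NULL)
    if (is.null(beta_new)) break
    beta_new <- drop(beta_new)
    if (max(abs(beta_new)) > cap) {
      # complete (or quasi-complete) separation: slopes diverge; cap the
      # standardized coefficients and stop
      beta <- beta_new * (cap / max(abs(beta_new)))
      separated <- TRUE
      ll <- loglik(beta)
      break
    }
    beta <- beta_new
    ll_new <- loglik(beta)
    if (abs(ll_new - ll) < tol) {
      converged <- TRUE
      ll <- ll_new
      break
    }
    ll <- ll_new
  }
  # back-transform to the original feature scale
  k <- length(ctr)
  coefs <- numeric(k + 1L)
  if (k) {
    coefs[seq_len(k)] <- beta[seq_len(k)] / scl
    coefs[k + 1L] <- beta[k + 1L] - sum(beta[seq_len(k)] * ctr / scl)
  } else coefs[1L] <- beta[1L]
  names(coefs) <- c(nm, "(intercept)")

  model <- structure(list(coefficients = coefs,
                          decision_threshold = decision_threshold,
                          converged = converged, separated = separated,
                          log_likelihood = ll, iterations = it),
                     class = "diagnostic_model")
  if (identical(nm, c("f", "s"))) {
    model$a <- coefs[["f"]]
    model$b <- coefs[["s"]]
    model$c <- coefs[["(intercept)"]]
  }
  model
}

#' @export
print.diagnostic_model <- function(x, ...) {
  cat("logistic diagnosis model\n  coefficients:\n")
  print(x$coefficients)
  cat(sprintf("  threshold %.3g | converged %s | separated %s\n",
              x$decision_threshold, x$converged, x$separated))
  invisible(x)
}

#' Predicted CoA probability
#'
#' Evaluates the logistic model `P = 1/(1 + exp(-(a f + b s + c)))`,
#' numerically stable for arbitrarily large linear predictors.  For models
#' fit on other feature sets pass the features as a data frame via
#' `newdata`.
#'
#' @param model a `diagnostic_model`
#' @param f,s stenosis coefficients (vectors), used when the model was fit
#'   on `(f, s)`
#' @param newdata data frame with the model's feature columns (alternative
#'   to `f`/`s`)
#' @return probabilities in `[0, 1]`
#' @export
predict_coa_probability <- function(model, f = NULL, s = NULL,
                                    newdata = NULL) {
  stopifnot(inherits(model, "diagnostic_model"))
  nm <- setdiff(names(model$coefficients), "(intercept)")
  if (is.null(newdata)) {
    newdata <- data.frame(row.names = seq_along(if (length(nm)) f else 1))
    if ("f" %in% nm) newdata$f <- f
    if ("s" %in% nm) newdata$s <- s
    if (!all(nm %in% names(newdata)))
      stop("supply `newdata` with columns: ", paste(nm, collapse = ", "),
           call. = FALSE)
  }
  eta <- rep(model$coefficients[["(intercept)"]],
             max(1L, nrow(newdata)))
  for (v in nm) eta <- eta + model$coefficients[[v]] * newdata[[v]]
  stats::plogis(eta)
}

## Placement values of the DeLong construction: for each positive score the
## fraction of negatives it beats (ties count 1/2), and vice versa.
delong_placements <- function(scores, labels) {
  y <- as.numeric(labels)
  xs <- scores[y == 1]
  ys <- scores[y == 0]
  cmp <- outer(xs, ys, function(a, b) (a > b) + 0.5 * (a == b))
  list(v10 = rowMeans(cmp), v01 = colMeans(cmp),
       auc = mean(cmp), m = length(xs), n = length(ys))
}

#' ROC curve with AUC and DeLong confidence interval
#'
#' Computes the empirical ROC curve of a score against a binary label.  The
#' AUC is the Mann-Whitney statistic (ties counted 1/2) and its variance is
#' estimated by the DeLong placement-value method; the confidence interval is
#' the normal approximation truncated to `[0, 1]`.
#'
#' @param scores numeric scores (higher = more CoA-like)
#' @param labels binary reference labels
#' @param conf_level confidence level of the AUC interval
#' @return an object of class `roc_result`: `auc`, `ci_low`, `ci_high`,
#'   `variance`, `thresholds`, `sensitivities`, `specificities`, `n_pos`,
#'   `n_neg`
#' @export
#' @examples
#' roc_auc(c(0.1, 0.4, 0.35, 0.8), c(0, 0, 1, 1))$auc  # 0.75
roc_auc <- function(scores, labels, conf_level = 0.95) {
  y <- as.numeric(labels)
  if (!all(y %in% c(0, 1)) || length(unique(y)) < 2L)
    stop("invalid labels: both classes must be present", call. = FALSE)
  if (length(scores) != length(y))
    stop("`scores` and `labels` must have equal length", call. = FALSE)
  pl <- delong_placements(scores, y)
  v <- 0
  if (pl$m > 1L) v <- v + stats::var(pl$v10) / pl$m
  if (pl$n > 1L) v <- v + stats::var(pl$v01) / pl$n
  zq <- stats::qnorm(1 - (1 - conf_level) / 2)
  thr <- c(Inf, sort(unique(scores), decreasing = TRUE))
  sens <- vapply(thr, function(t) mean(scores[y == 1] >= t), 0)
  spec <- vapply(thr, function(t) mean(scores[y == 0] < t), 0)
  structure(list(auc = pl$auc,
                 ci_low = max(0, pl$auc - zq * sqrt(v)),
                 ci_high = min(1, pl$auc + zq * sqrt(v)),
                 variance = v, thresholds = thr, sensitivities = sens,
                 specificities = spec, n_pos = pl$m, n_neg = pl$n),
            class = "roc_result")
}

#' @export
print.roc_result <- function(x, ...) {
  cat(sprintf("AUC %.3f (%.3f-%.3f), %d positives / %d negatives\n",
              x$auc, x$ci_low, x$ci_high, x$n_pos, x$n_neg))
  invisible(x)
}

#' DeLong paired comparison of two correlated AUCs
#'
#' Paired DeLong test of the AUCs of two scores measured on the same
#' patients against the same labels: the difference of the Mann-Whitney
#' AUCs is studentized by the placement-value covariance.
#'
#' @param scores_a,scores_b paired score vectors
#' @param labels binary reference labels
#' @return list with `auc_a`, `auc_b`, `z`, `p_value` (two-sided)
#' @export
delong_compare <- function(scores_a, scores_b, labels) {
  if (length(scores_a) != length(scores_b) ||
      length(scores_a) != length(labels))
    stop("invalid input: paired scores and labels must have equal length",
         call. = FALSE)
  y <- as.numeric(labels)
  if (!all(y %in% c(0, 1)) || length(unique(y)) < 2L)
    stop("invalid labels: both classes must be present", call. = FALSE)
  pa <- delong_placements(scores_a, y)
  pb <- delong_placements(scores_b, y)
  s10 <- stats::cov(cbind(pa$v10, pb$v10))
  s01 <- stats::cov(cbind(pa$v01, pb$v01))
  vd <- (s10[1, 1] + s10[2, 2] - 2 * s10[1, 2]) / pa$m +
    (s01[1, 1] + s01[2, 2] - 2 * s01[1, 2]) / pa$n
  d <- pa$auc - pb$auc
  if (vd <= 1e-16) {
    z <- if (abs(d) < 1e-12) 0 else sign(d) * Inf
  } else z <- d / sqrt(vd)
  list(auc_a = pa$auc, auc_b = pb$auc, z = z,
       p_value = 2 * stats::pnorm(-abs(z)))
}

#' Confusion-matrix metrics at a threshold
#'
#' Calls `score >= threshold` positive and reports the confusion counts,
#' sensitivity, specificity and accuracy.
#'
#' @param scores numeric scores
#' @param labels binary reference labels
#' @param threshold decision threshold
#' @return an object of class `classification_report`: `tp`, `fp`, `tn`,
#'   `fn`, `sensitivity`, `specificity`, `accuracy`, `threshold`
#' @export
classification_metrics <- function(scores, labels, threshold) {
  y <- as.numeric(labels)
  if (!all(y %in% c(0, 1)) || length(unique(y)) < 2L)
    stop("invalid labels: both classes must be present", call. = FALSE)
  call_pos <- scores >= threshold
  tp <- sum(call_pos & y == 1)
  fp <- sum(call_pos & y == 0)
  tn <- sum(!call_pos & y == 0)
  fn <- sum(!call_pos & y == 1)
  structure(list(tp = tp, fp = fp, tn = tn, fn = fn,
                 sensitivity = tp / (tp + fn),
                 specificity = tn / (tn + fp),
                 accuracy = (tp + tn) / length(y),
                 threshold = threshold),
            class = "classification_report")
}

#' Youden-optimal operating threshold
#'
#' Returns the threshold maximizing the Youden index
#' (sensitivity + specificity - 1).  Candidate thresholds are the midpoints
#' between consecutive distinct score values (so a separable training set
#' yields a cut placed between the two classes, not on a patient); ties are
#' broken toward the lowest (most sensitive) threshold.
#'
#' @param scores numeric scores
#' @param labels binary reference labels
#' @return a single threshold value
#' @export
youden_threshold <- function(scores, labels) {
  y <- as.numeric(labels)
  u <- sort(unique(scores))
  cand <- if (length(u) > 1L) (u[-1L] + u[-length(u)]) / 2 else u
  j <- vapply(cand, function(t) {
    mean(scores[y == 1] >= t) + mean(scores[y == 0] < t) - 1
  }, 0)
  cand[which(j >= max(j) - 1e-12)[1L]]
}

#' ESC guideline narrowing-rate classifier
#'
#' Anatomic comparator of the diagnosis model: positive if and only if the
#' narrowing rate reaches 50% of the diaphragm-level aortic diameter (the
#' boundary is inclusive, per the ">= 50%" guideline wording).
#'
#' @param narrowing narrowing fraction(s) in `[0, 1)`
#' @return integer vector of 0/1 calls
#' @export
#' @examples
#' esc_classifier(c(0.49, 0.50, 0.60))  # 0 1 1
esc_classifier <- function(narrowing) {
  if (any(!is.finite(narrowing) | narrowing < 0 | narrowing >= 1))
    stop("invalid input: narrowing must lie in [0, 1)", call. = FALSE)
  as.integer(narrowing >= 0.5)
}

#' Spearman rank-correlation matrix with p-values
#'
#' Rank correlation (average ranks for ties, then Pearson on the ranks)
#' between every pair of columns, with two-sided p-values from the
#' t-approximation `t = rho sqrt((n-2)/(1-rho^2))`.  Constant columns give
#' `NA` correlations with a warning rather than a silent zero.
#'
#' @param columns data frame (or named list) of equal-length numeric vectors
#' @return an object of class `spearman_matrix`: `rho` and `p` matrices and
#'   the sample size `n`
#' @export
spearman_matrix <- function(columns) {
  d <- as.data.frame(columns)
  n <- nrow(d)
  if (n < 3L) stop("need at least 3 observations", call. = FALSE)
  const <- vapply(d, function(v) length(unique(v)) < 2L, TRUE)
  if (any(const))
    warning("constant column(s): ", paste(names(d)[const], collapse = ", "),
            "; correlations undefined (NA)", call. = FALSE)
  k <- ncol(d)
  rho <- p <- matrix(NA_real_, k, k, dimnames = list(names(d), names(d)))
  for (i in seq_len(k)) for (j in seq_len(k)) {
    if (const[i] || const[j]) next
    r <- stats::cor(rank(d[[i]]), rank(d[[j]]))
    rho[i, j] <- r
    if (i == j) p[i, j] <- 0
    else {
      tt <- r * sqrt((n - 2) / max(1 - r^2, 1e-300))
      p[i, j] <- 2 * stats::pt(-abs(tt), n - 2)
    }
  }
  structure(list(rho = rho, p = p, n = n), class = "spearman_matrix")
}

#' @export
print.spearman_matrix <- function(x, ...) {
  cat(sprintf("Spearman rank correlations (n = %d)\n", x$n))
  print(round(x$rho, 3))
  invisible(x)
}
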