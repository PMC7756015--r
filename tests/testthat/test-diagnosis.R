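test_that("intercept-only logistic MLE equals the log-odds of the prevalence", {
  y <- rep(c(1, 0), c(3, 7))
  m <- fit_logistic_model(data.frame(row.names = seq_along(y)), y)
  expect_equal(unname(m$coefficients["(intercept)"]), log(3 / 7),
               tolerance = 1e-8)
})

test_that("IRLS agrees with glm on a well-behaved dataset", {
  set.seed(5)
  n <- 200
  x <- data.frame(f = rnorm(n, 1, 0.4), s = rnorm(n, 0.02, 0.01))
  eta <- 2 * x$f + 50 * x$s - 3
  y <- rbinom(n, 1, plogis(eta))
  m <- fit_logistic_model(x, y)
  g <- stats::glm(y ~ f + s, data = cbind(x, y = y), family = binomial())
  expect_equal(unname(m$coefficients[c("f", "s", "(intercept)")]),
               unname(coef(g)[c("f", "s", "(Intercept)")]), tolerance = 1e-6)
  expect_true(m$converged)
  expect_false(m$separated)
  # aliases for the canonical two-feature model
  expect_equal(m$a, unname(m$coefficients["f"]))
})

test_that("known coefficients are recovered within sampling error", {
  set.seed(99)
  n <- 5000
  x <- data.frame(f = rnorm(n, 1, 0.5), s = rnorm(n, 0.03, 0.012))
  y <- rbinom(n, 1, plogis(2 * x$f + 50 * x$s - 3))
  m <- fit_logistic_model(x, y)
  g <- stats::glm(y ~ f + s, data = cbind(x, y = y), family = binomial())
  se <- sqrt(diag(stats::vcov(g)))[c("f", "s", "(Intercept)")]
  est <- m$coefficients[c("f", "s", "(intercept)")]
  expect_true(all(abs(est - c(2, 50, -3)) < 3 * se))
})

test_that("complete separation is detected and probabilities stay monotone", {
  x <- data.frame(f = c(1, 2, 3, 4, 10, 11, 12, 13))
  y <- c(0, 0, 0, 0, 1, 1, 1, 1)
  m <- fit_logistic_model(x, y)
  expect_true(m$separated)
  p <- predict_coa_probability(m, newdata = x)
  expect_true(all(diff(p) >= 0))
  expect_true(all(p[y == 1] > 0.5) && all(p[y == 0] < 0.5))
})

test_that("predicted probability is the stable logistic of the linear predictor", {
  m <- structure(list(coefficients = c(f = 1, s = 1, "(intercept)" = -2),
                      decision_threshold = 0.5),
                 class = "diagnostic_model")
  expect_equal(predict_coa_probability(m, f = 1, s = 1), 0.5)
  expect_equal(predict_coa_probability(m, f = 1000, s = 2), 1, tolerance = 1e-12)
  expect_equal(predict_coa_probability(m, f = -1000, s = 2), 0, tolerance = 1e-12)
  # strictly increasing in each feature for positive slopes
  expect_true(all(diff(predict_coa_probability(m, f = 1:5, s = rep(1, 5))) > 0))
})

test_that("invalid label vectors are rejected", {
  expect_error(fit_logistic_model(data.frame(f = 1:4), c(1, 1, 1, 1)),
               "classes")
  expect_error(roc_auc(1:4, c(0, 0, 0, 0)), "classes")
  expect_error(classification_metrics(1:4, c(2, 0, 1, 1), 0.5), "label|classes")
})

test_that("AUC equals exhaustive pair counting", {
  expect_equal(roc_auc(c(0.1, 0.4, 0.35, 0.8), c(0, 0, 1, 1))$auc, 0.75)
  expect_equal(roc_auc(c(1, 2, 3, 4), c(0, 0, 1, 1))$auc, 1)
  expect_equal(roc_auc(rep(0.3, 6), c(0, 1, 0, 1, 0, 1))$auc, 0.5)
  # random small instances against brute-force concordance counting
  set.seed(17)
  for (i in 1:30) {
    n <- sample(4:12, 1)
    y <- c(0, 1, sample(0:1, n - 2, replace = TRUE))
    sc <- sample(seq(0, 1, 0.1), n, replace = TRUE)   # plenty of ties
    pos <- sc[y == 1]; neg <- sc[y == 0]
    brute <- mean(outer(pos, neg, ">") + 0.5 * outer(pos, neg, "=="))
    expect_equal(roc_auc(sc, y)$auc, brute)
  }
})

test_that("the ROC curve integrates back to the AUC", {
  set.seed(3)
  y <- rbinom(40, 1, 0.5)
  y[1:2] <- c(0, 1)
  sc <- rnorm(40) + y
  r <- roc_auc(sc, y)
  xs <- 1 - r$specificities
  ys <- r$sensitivities
  auc_trap <- sum(diff(xs) * (head(ys, -1) + tail(ys, -1)) / 2)
  expect_equal(auc_trap, r$auc, tolerance = 1e-12)
  expect_true(all(diff(ys) >= 0) && all(diff(xs) >= 0))
  expect_true(r$ci_low <= r$auc && r$auc <= r$ci_high)
})

test_that("DeLong AUC inference matches pROC", {
  skip_if_not_installed("pROC")
  set.seed(21)
  y <- rep(c(0, 1), each = 30)
  sc <- rnorm(60) + 1.2 * y
  r <- roc_auc(sc, y)
  pr <- pROC::roc(y, sc, quiet = TRUE, direction = "<")
  expect_equal(r$auc, as.numeric(pROC::auc(pr)), tolerance = 1e-12)
  expect_equal(r$variance, as.numeric(pROC::var(pr)), tolerance = 1e-10)
  sc2 <- rnorm(60) + 0.8 * y
  cmp <- delong_compare(sc, sc2, y)
  pt <- pROC::roc.test(pr, pROC::roc(y, sc2, quiet = TRUE, direction = "<"),
                       method = "delong")
  expect_equal(cmp$p_value, as.numeric(pt$p.value), tolerance = 1e-10)
})

test_that("DeLong variance is close to a stratified bootstrap", {
  set.seed(8)
  y <- rep(c(0, 1), each = 30)
  sc <- rnorm(60) + 1.0 * y
  v_delong <- roc_auc(sc, y)$variance
  reps <- 2000
  aucs <- numeric(reps)
  pos <- which(y == 1); neg <- which(y == 0)
  for (b in seq_len(reps)) {
    i <- c(sample(pos, replace = TRUE), sample(neg, replace = TRUE))
    aucs[b] <- roc_auc(sc[i], y[i])$auc
  }
  expect_lt(abs(v_delong / var(aucs) - 1), 0.15)
})

test_that("delong_compare is antisymmetric and null on identical scores", {
  set.seed(13)
  y <- rep(c(0, 1), each = 15)
  a <- rnorm(30) + y
  b <- rnorm(30) + 0.5 * y
  expect_equal(delong_compare(a, a, y)$z, 0)
  expect_equal(delong_compare(a, a, y)$p_value, 1)
  ab <- delong_compare(a, b, y)
  ba <- delong_compare(b, a, y)
  expect_equal(ab$z, -ba$z, tolerance = 1e-12)
  expect_error(delong_compare(a, b[-1], y), "length")
})

test_that("classification metrics reproduce definitional arithmetic", {
  sc <- c(rep(0.9, 3), 0.8, rep(0.1, 6), rep(0.2, 3))
  y <- c(rep(1, 3), 0, rep(0, 6), rep(1, 3))
  cm <- classification_metrics(sc, y, 0.5)
  expect_identical(c(cm$tp, cm$fp, cm$tn, cm$fn), c(3L, 1L, 6L, 3L))
  expect_equal(cm$sensitivity, 0.5)
  expect_equal(cm$specificity, 6 / 7)
  expect_equal(cm$accuracy, 9 / 13)
  # extreme thresholds
  all_pos <- classification_metrics(sc, y, min(sc))
  expect_equal(c(all_pos$sensitivity, all_pos$specificity), c(1, 0))
  all_neg <- classification_metrics(sc, y, max(sc) + 1)
  expect_equal(c(all_neg$sensitivity, all_neg$specificity), c(0, 1))
})

test_that("the Youden threshold maximizes sensitivity + specificity", {
  set.seed(4)
  y <- rbinom(50, 1, 0.5); y[1:2] <- 0:1
  sc <- rnorm(50) + y
  thr <- youden_threshold(sc, y)
  j_at <- function(t) mean(sc[y == 1] >= t) + mean(sc[y == 0] < t) - 1
  expect_equal(j_at(thr), max(vapply(sort(unique(sc)), j_at, 0)))
})

test_that("the ESC rule is >= 50% inclusive", {
  expect_identical(esc_classifier(c(0.6, 0.49, 0.5)), c(1L, 0L, 1L))
  expect_error(esc_classifier(1.2), "\\[0, 1\\)")
  expect_error(esc_classifier(-0.1), "\\[0, 1\\)")
})

test_that("Spearman matrix equals brute-force average ranks, including ties", {
  x <- c(1, 5, 3, 3, 7, 2, 2, 2)
  y <- c(2, 9, 4, 6, 8, 1, 3, 3)
  avg_rank <- function(v) vapply(v, function(a)
    sum(v < a) + (1 + sum(v == a)) / 2, 0)
  rx <- avg_rank(x); ry <- avg_rank(y)
  brute <- sum((rx - mean(rx)) * (ry - mean(ry))) /
    sqrt(sum((rx - mean(rx))^2) * sum((ry - mean(ry))^2))
  sm <- spearman_matrix(data.frame(x = x, y = y))
  expect_equal(sm$rho["x", "y"], brute, tolerance = 1e-12)
  # monotone and reversed pairs
  expect_equal(spearman_matrix(data.frame(a = 1:5, b = exp(1:5)))$rho["a", "b"], 1)
  expect_equal(spearman_matrix(data.frame(a = 1:5, b = -(1:5)))$rho["a", "b"], -1)
  # constant column flagged, not silently zero
  expect_warning(sm2 <- spearman_matrix(data.frame(a = 1:5, b = rep(2, 5))),
                 "constant")
  expect_true(is.na(sm2$rho["a", "b"]))
})
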