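#' Fit the stenosis pressure-flow curve
#'
#' Least-squares fit of `dp = f Q + s Q^2` to sweep points.  The model is
#' linear in `(f, s)`, so the default path solves the normal equations on the
#' design `[Q, Q^2]` exactly, with active-set handling of the non-negativity
#' constraints: if the unconstrained optimum leaves the quadrant, the best of
#' the boundary solutions (`s = 0`, `f = 0`, or both) is returned.  A
#' Levenberg-Marquardt iterative path (`method = "gauss_newton"`) is provided
#' for fidelity with iterative nonlinear least-squares workflows and agrees
#' with the direct solution to high precision.
#'
#' @param q flows at the lesion, cm^3/s (or a 2-column data frame of
#'   `(Q, dp)` points, in which case `dp` is ignored)
#' @param dp pressure drops, mmHg
#' @param constrain_nonnegative enforce `f >= 0`, `s >= 0` (default TRUE)
#' @param method `"normal"` (exact, default) or `"gauss_newton"`
#' @return an object of class `curve_fit_report`: `coefficients`
#'   (a [stenosis_coefficients()]), `residual_sum_squares`, `n_points`,
#'   `converged`, `method`
#' @export
#' @examples
#' q <- 1:6
#' fit_pressure_flow_curve(q, 2 * q + 0.5 * q^2)
fit_pressure_flow_curve <- function(q, dp = NULL, constrain_nonnegative = TRUE,
                                    method = c("normal", "gauss_newton")) {
  method <- match.arg(method)
  if (is.data.frame(q) || is.matrix(q)) {
    pts <- as.data.frame(q)
    dp <- pts[[2L]]
    q <- pts[[1L]]
  }
  if (length(q) != length(dp))
    stop("`q` and `dp` must have equal length", call. = FALSE)
  keep <- is.finite(q) & is.finite(dp)
  q <- q[keep]
  dp <- dp[keep]
  if (length(unique(q)) < 2L)
    stop("insufficient data: need at least two distinct flow values",
         call. = FALSE)
  if (any(q <= 0))
    stop("flows must be strictly positive", call. = FALSE)

  x <- cbind(q, q^2)
  rss_of <- function(beta) sum((dp - x %*% beta)^2)
  beta_ls <- function(cols) {
    # exact least squares on a column subset via QR
    b <- numeric(2)
    fitq <- qr(x[, cols, drop = FALSE])
    if (fitq$rank < length(cols))
      stop("degenerate design: flow values do not identify (f, s)",
           call. = FALSE)
    b[cols] <- qr.coef(fitq, dp)
    b
  }
  beta <- beta_ls(1:2)
  if (constrain_nonnegative && any(beta < 0)) {
    cand <- list(pmax(beta, 0))
    b1 <- beta_ls(1L)
    if (b1[1L] >= 0) cand <- c(cand, list(b1))
    b2 <- beta_ls(2L)
    if (b2[2L] >= 0) cand <- c(cand, list(b2))
    cand <- c(cand, list(c(0, 0)))
    # keep only quadrant-feasible candidates and take the lowest RSS
    cand <- Filter(function(b) all(b >= 0), cand)
    beta <- cand[[which.min(vapply(cand, rss_of, 0))]]
  }
  converged <- TRUE

  if (method == "gauss_newton") {
    start <- list(f = max(beta[1L], 1e-8), s = max(beta[2L], 1e-8))
    lower <- if (constrain_nonnegative) c(0, 0) else c(-Inf, -Inf)
    fit <- minpack.lm::nlsLM(dp ~ f * q + s * q^2, start = start,
                             lower = lower,
                             control = minpack.lm::nls.lm.control(
                               maxiter = 200, ftol = 1e-15, ptol = 1e-15))
    beta <- as.numeric(stats::coef(fit))
    converged <- fit$convInfo$isConv %||% TRUE
    if (constrain_nonnegative) beta <- pmax(beta, 0)
  }

  cf <- if (constrain_nonnegative)
    stenosis_coefficients(beta[1L], beta[2L])
  else structure(list(f = beta[1L], s = beta[2L]),
                 class = "stenosis_coefficients")
  structure(list(coefficients = cf, residual_sum_squares = rss_of(beta),
                 n_points = length(q), converged = converged,
                 method = method),
            class = "curve_fit_report")
}

#' @export
print.curve_fit_report <- function(x, ...) {
  cat(sprintf("pressure-flow fit (%s, n = %d): f = %.6g, s = %.6g, RSS = %.3g mmHg^2\n",
              x$method, x$n_points, x$coefficients$f, x$coefficients$s,
              x$residual_sum_squares))
  invisible(x)
}

#' Sweep protocol configuration
#'
#' Bundles the boundary-condition protocol of the resistance sweep: inlet
#' static pressure, base total outlet resistance, the resistance scale
#' factors, the diameter exponent of the outlet allocation, and the
#' downstream reference pressure.
#'
#' @param inlet_pressure mmHg (default 80)
#' @param base_total_resistance mmHg.s/cm^3 (default 9.6)
#' @param scales resistance scale factors (default 1, 1/2, ..., 1/6)
#' @param exponent outlet-allocation diameter exponent (default 1)
#' @param reference_pressure mmHg (default 0)
#' @return an object of class `sweep_config`
#' @export
sweep_config <- function(inlet_pressure = 80, base_total_resistance = 9.6,
                         scales = 1 / (1:6), exponent = 1,
                         reference_pressure = 0) {
  if (inlet_pressure <= reference_pressure || base_total_resistance <= 0)
    stop("invalid sweep configuration", call. = FALSE)
  if (any(scales <= 0 | scales > 1) || anyDuplicated(scales) ||
      length(scales) < 2L)
    stop("`scales` must be >= 2 distinct values in (0, 1]", call. = FALSE)
  structure(list(inlet_pressure = inlet_pressure,
                 base_total_resistance = base_total_resistance,
                 scales = scales, exponent = exponent,
                 reference_pressure = reference_pressure),
            class = "sweep_config")
}

#' Characterize one patient by the resistance sweep
#'
#' Full feature-extraction chain for a single geometry: run the outlet
#' resistance sweep, then fit the stenosis pressure-flow curve to the
#' resulting `(Q, dp)` pairs.
#'
#' @param network an [aorta_network()]
#' @param fluid a [fluid_properties()]
#' @param sweep a [sweep_config()]
#' @param ... passed to [fit_pressure_flow_curve()]
#' @return list with `coefficients` (a [stenosis_coefficients()]), `fit`
#'   (the `curve_fit_report`) and `sweep` (the `sweep_result`)
#' @export
characterize_patient <- function(network, fluid = fluid_properties(),
                                 sweep = sweep_config(), ...) {
  stopifnot(inherits(sweep, "sweep_config"))
  sw <- run_resistance_sweep(network, fluid,
                             inlet_pressure = sweep$inlet_pressure,
                             base_total_resistance = sweep$base_total_resistance,
                             scales = sweep$scales,
                             exponent = sweep$exponent,
                             reference_pressure = sweep$reference_pressure)
  fit <- fit_pressure_flow_curve(sw$Q_bar, sw$dp_bar, ...)
  list(coefficients = fit$coefficients, fit = fit, sweep = sw)
}

#' Characterize a whole cohort
#'
#' Runs [characterize_patient()] on every patient of a cohort and assembles
#' the per-patient feature table used by the diagnostic model.
#'
#' @param cohort a `coa_cohort` from [generate_cohort()]
#' @param fluid a [fluid_properties()]
#' @param sweep a [sweep_config()]
#' @param keep_sweeps also return the raw sweep points (default FALSE)
#' @return data frame with columns `patient_id`, `f`, `s`,
#'   `residual_sum_squares`, `narrowing_rate`, `pspg_measured`, `label`,
#'   plus covariates `age_months`, `sex`, `bsa`; with `keep_sweeps = TRUE`
#'   the sweep table is attached as attribute `"sweeps"`.
#' @export
characterize_cohort <- function(cohort, fluid = fluid_properties(),
                                sweep = sweep_config(), keep_sweeps = FALSE) {
  stopifnot(inherits(cohort, "coa_cohort"))
  rows <- vector("list", length(cohort$patients))
  sweeps <- if (keep_sweeps) vector("list", length(cohort$patients))
  for (i in seq_along(cohort$patients)) {
    p <- cohort$patients[[i]]
    ch <- tryCatch(characterize_patient(p$network, fluid, sweep),
                   error = function(e)
                     stop(sprintf("patient %s: %s", p$id,
                                  conditionMessage(e)), call. = FALSE))
    rows[[i]] <- data.frame(
      patient_id = p$id, f = ch$coefficients$f, s = ch$coefficients$s,
      residual_sum_squares = ch$fit$residual_sum_squares,
      narrowing_rate = narrowing_rate(p$network),
      pspg_measured = p$pspg_measured, label = p$coa_label,
      age_months = p$age_months, sex = p$sex, bsa = p$bsa)
    if (keep_sweeps)
      sweeps[[i]] <- data.frame(patient_id = p$id, as.data.frame(ch$sweep))
  }
  tab <- do.call(rbind, rows)
  rownames(tab) <- NULL
  if (keep_sweeps) attr(tab, "sweeps") <- do.call(rbind, sweeps)
  tab
}
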