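#' Virtual cohort configuration
#'
#' Priors and controls of the synthetic pediatric cohort generator.  The
#' defaults emulate the study conditions the pipeline is designed for: 65
#' patients with a target CoA prevalence of 38/65, ages from 1 month to 14
#' years, body-surface-area-scaled arch dimensions, an isthmus stenosis
#' whose severity prior is calibrated so the induced peak systolic pressure
#' gradient (PSPG) distribution straddles the 20 mmHg diagnostic cut-off,
#' and a catheterization-style PSPG measurement with 2 mmHg Gaussian noise.
#'
#' @param n cohort size
#' @param target_prevalence target CoA fraction (default 38/65)
#' @param seed integer seed; every random draw of the generator flows from it
#' @param pspg_sigma PSPG measurement noise SD, mmHg (truncated at 0)
#' @param lesion_jitter SD (cm) of the jitter applied to the lesion start and
#'   end planes, emulating observer placement (default 0 = exact planes)
#' @param k_e_range range of the lesion expansion-loss factor; `c(1, 1)`
#'   (pure Borda-Carnot) keeps the generator matched to the fitted model
#' @param reynolds_friction add a transitional `t Q^1.5` loss term to the
#'   lesion law (model-mismatch mode, default off)
#' @param peak_flow_per_bsa median peak-systolic isthmus flow per unit BSA,
#'   cm^3/s/m^2
#' @param peak_flow_sdlog log-SD of the lognormal peak-flow variability
#' @param severity_range narrowing-fraction range spanned by the stenosis
#'   severity prior (mild to severe)
#' @param severity_sdlog SD of the latent severity variable on the logit
#'   scale
#' @param male_fraction probability of male sex
#' @return an object of class `cohort_config`
#' @export
cohort_config <- function(n = 65L, target_prevalence = 38 / 65, seed = 42L,
                          pspg_sigma = 2, lesion_jitter = 0,
                          k_e_range = c(1, 1), reynolds_friction = FALSE,
                          peak_flow_per_bsa = 160, peak_flow_sdlog = 0.25,
                          severity_range = c(0.05, 0.80),
                          severity_sdlog = 1.2, male_fraction = 35 / 65) {
  if (n < 1L) stop("`n` must be positive", call. = FALSE)
  if (target_prevalence <= 0 || target_prevalence >= 1)
    stop("`target_prevalence` must lie in (0, 1)", call. = FALSE)
  if (pspg_sigma < 0 || lesion_jitter < 0)
    stop("noise magnitudes must be non-negative", call. = FALSE)
  if (length(k_e_range) != 2L || any(k_e_range <= 0) ||
      k_e_range[1L] > k_e_range[2L])
    stop("`k_e_range` must be an increasing positive pair", call. = FALSE)
  if (severity_range[1L] <= 0 || severity_range[2L] >= 1 ||
      severity_range[1L] >= severity_range[2L])
    stop("`severity_range` must be increasing within (0, 1)", call. = FALSE)
  structure(list(n = as.integer(n), target_prevalence = target_prevalence,
                 seed = as.integer(seed), pspg_sigma = pspg_sigma,
                 lesion_jitter = lesion_jitter, k_e_range = k_e_range,
                 reynolds_friction = isTRUE(reynolds_friction),
                 peak_flow_per_bsa = peak_flow_per_bsa,
                 peak_flow_sdlog = peak_flow_sdlog,
                 severity_range = severity_range,
                 severity_sdlog = severity_sdlog,
                 male_fraction = male_fraction),
            class = "cohort_config")
}

## One patient's bundle of random draws, taken in a fixed order so that the
## whole cohort is a deterministic function of the seed.  Severity is kept as
## a latent standard normal so the calibration can move its location without
## redrawing.
draw_patient_bundle <- function(config) {
  list(z_severity = stats::rnorm(1),
       u_shape = stats::runif(1),
       u_sex = stats::runif(1),
       z_age = stats::rnorm(1),
       z_bsa = stats::rnorm(1),
       z_dref = stats::rnorm(1),
       z_diaph = stats::rnorm(1),
       z_dasc = stats::rnorm(1),
       u_branch = stats::runif(3, 0.9, 1.1),
       z_isthmus_len = stats::rnorm(1),
       u_post = stats::runif(1, 0.95, 1.10),
       u_ke = stats::runif(1),
       z_qpeak = stats::rnorm(1),
       z_jitter = stats::rnorm(2),
       z_pspg_noise = stats::rnorm(1))
}

## Deterministically build one virtual patient from a draw bundle and the
## severity location parameter.  `build_network = FALSE` skips the (cheap but
## unneeded) network construction during calibration.
build_patient <- function(bundle, loc, config, id,
                          fluid = fluid_properties(),
                          build_network = TRUE) {
  age_months <- min(168, max(1, exp(log(12) + 1.1 * bundle$z_age)))
  sex <- as.integer(bundle$u_sex < config$male_fraction)  # 1 = male
  bsa <- (0.2 + 0.09 * sqrt(age_months)) * exp(0.08 * bundle$z_bsa)
  scale <- sqrt(bsa)

  d_ref <- 1.0 * scale * exp(0.06 * bundle$z_dref)
  # distal descending aorta tapers slightly below the pre-lesion reference
  diaphragm_d <- 0.95 * d_ref * exp(0.04 * bundle$z_diaph)
  d_asc <- 1.6 * d_ref * exp(0.05 * bundle$z_dasc)
  d_arch <- 1.3 * d_ref

  sev <- config$severity_range[1L] +
    diff(config$severity_range) *
    stats::plogis(config$severity_sdlog * bundle$z_severity + loc)
  r_ref <- d_ref / 2
  r_min <- r_ref * (1 - sev)
  r_post <- r_ref * bundle$u_post

  len_isthmus <- 2.0 * scale * exp(0.45 * bundle$z_isthmus_len)
  # lesion morphology spans discrete (V-shaped throat) to tubular
  # (long plateau at the minimal radius), decoupling the viscous
  # coefficient from the expansion loss at fixed anatomic severity
  throat_half <- 0.18 * len_isthmus * bundle$u_shape
  l_start <- 0.3 * len_isthmus
  l_end <- 0.7 * len_isthmus
  if (config$lesion_jitter > 0) {
    l_start <- min(max(l_start + config$lesion_jitter * bundle$z_jitter[1L],
                       0.05 * len_isthmus), 0.45 * len_isthmus)
    l_end <- min(max(l_end + config$lesion_jitter * bundle$z_jitter[2L],
                     0.55 * len_isthmus), 0.95 * len_isthmus)
  }

  k_e <- config$k_e_range[1L] + diff(config$k_e_range) * bundle$u_ke
  peak_flow <- config$peak_flow_per_bsa * bsa *
    exp(config$peak_flow_sdlog * bundle$z_qpeak)

  make_network <- function(transitional = 0) {
    segs <- list(
      vessel_segment("ascending", 3.5 * scale,
                     data.frame(pos = c(0, 3.5 * scale),
                                radius = rep(d_asc / 2, 2))),
      vessel_segment("arch_a", 1.2 * scale,
                     data.frame(pos = c(0, 1.2 * scale),
                                radius = c(0.95 * d_asc / 2, d_arch / 2))),
      vessel_segment("arch_b", 1.2 * scale,
                     data.frame(pos = c(0, 1.2 * scale),
                                radius = c(d_arch / 2, r_ref))),
      vessel_segment("isthmus", len_isthmus,
                     data.frame(pos = c(0, 0.3 * len_isthmus,
                                        0.5 * len_isthmus - throat_half,
                                        0.5 * len_isthmus + throat_half,
                                        0.7 * len_isthmus, len_isthmus),
                                radius = c(r_ref, r_ref, r_min, r_min,
                                           r_post, r_post))[
                       c(TRUE, TRUE, TRUE, throat_half > 0, TRUE, TRUE), ],
                     is_lesion = TRUE, lesion_start = l_start,
                     lesion_end = l_end),
      vessel_segment("descending", 5 * scale,
                     data.frame(pos = c(0, 5 * scale),
                                radius = c(r_post, diaphragm_d / 2))))
    con <- data.frame(
      segment = c("ascending", "arch_a", "arch_b", "isthmus", "descending"),
      from = c("inlet", "n1", "n2", "n3", "n4"),
      to = c("n1", "n2", "n3", "n4", "n5"))
    outs <- data.frame(
      id = c("brachiocephalic", "left_carotid", "left_subclavian",
             "descending_aorta"),
      node = c("n1", "n2", "n3", "n5"),
      diameter = c(0.45 * d_asc * bundle$u_branch[1L],
                   0.30 * d_asc * bundle$u_branch[2L],
                   0.35 * d_asc * bundle$u_branch[3L],
                   diaphragm_d))
    aorta_network(segs, con, "inlet", outs, diaphragm_d, lesion_k_e = k_e,
                  lesion_transitional = transitional)
  }

  net <- make_network(0)
  if (config$reynolds_friction) {
    cf <- stenosis_true_coefficients(net, fluid)
    net <- make_network(0.3 * sqrt(cf$f * cf$s))
  }
  pspg_ref <- reference_pspg(net, fluid, peak_flow)
  pspg_meas <- max(0, pspg_ref + config$pspg_sigma * bundle$z_pspg_noise)

  p <- list(id = id, age_months = age_months, sex = sex, bsa = bsa,
            severity = sev, peak_flow = peak_flow,
            pspg_reference = pspg_ref, pspg_measured = pspg_meas,
            coa_label = as.integer(pspg_meas >= 20))
  if (build_network) p$network <- net
  structure(p, class = "virtual_patient")
}

#' Sample one virtual arch geometry
#'
#' Draws a single [aorta_network()] from the geometry priors of a
#' [cohort_config()], using the session RNG (seed it with `set.seed()` for
#' reproducibility).  `severity_location` plays the role the prevalence
#' calibration of [generate_cohort()] normally fills.
#'
#' @param config a [cohort_config()]
#' @param severity_location location shift of the latent severity variable
#' @return an [aorta_network()]
#' @export
sample_patient_geometry <- function(config = cohort_config(),
                                    severity_location = 0) {
  b <- draw_patient_bundle(config)
  build_patient(b, severity_location, config, id = "sample")$network
}

#' Reference (catheterization-style) PSPG of a network
#'
#' Evaluates the lesion's generative pressure-flow law at the peak-systolic
#' flow, giving the ground-truth peak systolic pressure gradient the
#' catheter would read: `f_true Q + s_true Q^2` (plus the transitional term
#' when the network carries one).
#'
#' @param network an [aorta_network()]
#' @param fluid a [fluid_properties()]
#' @param peak_flow peak-systolic flow through the coarctation, cm^3/s
#' @return PSPG, mmHg
#' @export
#' @examples
#' # f = 0.5, s = 0.1 at Q = 20 gives 0.5*20 + 0.1*400 = 50 mmHg
reference_pspg <- function(network, fluid = fluid_properties(), peak_flow) {
  stopifnot(inherits(network, "aorta_network"), peak_flow > 0)
  cf <- stenosis_true_coefficients(network, fluid)
  cf$f * peak_flow + network$lesion_transitional * peak_flow^1.5 +
    cf$s * peak_flow^2
}

#' Generate a virtual pediatric cohort
#'
#' Draws `n` patients from the configured priors.  The location of the
#' latent stenosis-severity prior is calibrated by bisection so that the
#' realized number of CoA-positive patients (measured PSPG >= 20 mmHg) falls
#' within +/-10% of the target prevalence; all other randomness is fixed
#' before calibration, so the cohort is a deterministic function of
#' `(config, seed)`.
#'
#' @param config a [cohort_config()]
#' @param fluid a [fluid_properties()]
#' @return an object of class `coa_cohort`: `patients` (list of
#'   `virtual_patient`), `config`, `severity_location`, `n_positive`
#' @export
#' @examples
#' \donttest{
#' coh <- generate_cohort(cohort_config(n = 20, seed = 7))
#' table(cohort_table(coh)$label)
#' }
generate_cohort <- function(config = cohort_config(),
                            fluid = fluid_properties()) {
  stopifnot(inherits(config, "cohort_config"))
  bundles <- with_local_seed(config$seed,
                             lapply(seq_len(config$n),
                                    function(i) draw_patient_bundle(config)))
  ids <- sprintf("P%03d", seq_len(config$n))
  count_pos <- function(loc) {
    sum(vapply(seq_len(config$n), function(i) {
      build_patient(bundles[[i]], loc, config, ids[i], fluid,
                    build_network = FALSE)$coa_label
    }, 0L))
  }
  target <- config$target_prevalence * config$n
  lo_n <- ceiling(0.9 * target)
  hi_n <- floor(1.1 * target)
  lo <- -8
  hi <- 8
  if (count_pos(hi) < lo_n || count_pos(lo) > hi_n)
    stop("calibration failure: target prevalence unreachable under priors",
         call. = FALSE)
  loc <- NA_real_
  a <- lo
  b <- hi
  for (iter in 1:80) {
    mid <- 0.5 * (a + b)
    np <- count_pos(mid)
    if (np < lo_n) a <- mid
    else if (np > hi_n) b <- mid
    else {
      loc <- mid
      break
    }
    if (b - a < 1e-10)
      stop("calibration failure: no severity location hits the target band",
           call. = FALSE)
  }
  patients <- lapply(seq_len(config$n), function(i) {
    build_patient(bundles[[i]], loc, config, ids[i], fluid,
                  build_network = TRUE)
  })
  structure(list(patients = patients, config = config,
                 severity_location = loc,
                 n_positive = sum(vapply(patients, `[[`, 0L, "coa_label"))),
            class = "coa_cohort")
}

#' @export
print.coa_cohort <- function(x, ...) {
  cat(sprintf("virtual cohort: %d patients (%d CoA / %d non-CoA), seed %d\n",
              length(x$patients), x$n_positive,
              length(x$patients) - x$n_positive, x$config$seed))
  invisible(x)
}

#' Flat covariate table of a cohort
#'
#' @param cohort a `coa_cohort`
#' @return data frame with one row per patient: id, covariates, peak flow,
#'   reference and measured PSPG, CoA label, and the anatomic narrowing rate
#' @export
cohort_table <- function(cohort) {
  stopifnot(inherits(cohort, "coa_cohort"))
  do.call(rbind, lapply(cohort$patients, function(p) {
    data.frame(patient_id = p$id, age_months = p$age_months, sex = p$sex,
               bsa = p$bsa, severity = p$severity, peak_flow = p$peak_flow,
               pspg_reference = p$pspg_reference,
               pspg_measured = p$pspg_measured, label = p$coa_label,
               narrowing_rate = narrowing_rate(p$network))
  }))
}

#' Write / read a cohort
#'
#' `write_cohort_json()` stores the full cohort (including every network) as
#' a versioned JSON document; `write_cohort_csv()` stores the flat covariate
#' table.  Both round-trip through their readers.
#'
#' @param cohort a `coa_cohort`
#' @param path file path
#' @return the path, invisibly (writers); a `coa_cohort` or data frame
#'   (readers)
#' @export
write_cohort_json <- function(cohort, path) {
  stopifnot(inherits(cohort, "coa_cohort"))
  tmp <- tempfile(fileext = ".json")
  on.exit(unlink(tmp))
  pats <- lapply(cohort$patients, function(p) {
    write_aorta_network(p$network, tmp)
    net <- jsonlite::read_json(tmp, simplifyVector = FALSE)
    list(id = p$id, age_months = p$age_months, sex = p$sex, bsa = p$bsa,
         severity = p$severity, peak_flow = p$peak_flow,
         pspg_reference = p$pspg_reference,
         pspg_measured = p$pspg_measured, coa_label = p$coa_label,
         network = net)
  })
  doc <- list(schema = "coaflow-cohort/1.0",
              config = unclass(cohort$config),
              severity_location = cohort$severity_location,
              patients = pats)
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_cohort_json
#' @export
read_cohort_json <- function(path) {
  doc <- jsonlite::read_json(path, simplifyVector = FALSE)
  if (!identical(doc$schema, "coaflow-cohort/1.0"))
    stop("unsupported cohort schema: ", doc$schema, call. = FALSE)
  keep <- intersect(names(formals(cohort_config)), names(doc$config))
  cfg <- do.call(cohort_config,
                 lapply(doc$config[keep], unlist, use.names = FALSE))
  tmp <- tempfile(fileext = ".json")
  on.exit(unlink(tmp))
  patients <- lapply(doc$patients, function(p) {
    jsonlite::write_json(p$network, tmp, auto_unbox = TRUE, digits = NA)
    structure(list(id = p$id, age_months = p$age_months, sex = p$sex,
                   bsa = p$bsa, severity = p$severity,
                   peak_flow = p$peak_flow,
                   pspg_reference = p$pspg_reference,
                   pspg_measured = p$pspg_measured,
                   coa_label = p$coa_label,
                   network = read_aorta_network(tmp)),
              class = "virtual_patient")
  })
  structure(list(patients = patients, config = cfg,
                 severity_location = doc$severity_location,
                 n_positive = sum(vapply(patients, `[[`, 0L, "coa_label"))),
            class = "coa_cohort")
}

#' @rdname write_cohort_json
#' @export
write_cohort_csv <- function(cohort, path) {
  utils::write.csv(cohort_table(cohort), path, row.names = FALSE)
  invisible(path)
}
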