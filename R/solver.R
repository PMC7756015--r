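#' Outlet resistance set
#'
#' Bundle of the four single-resistance lumped parameter outlet boundary
#' conditions: one resistance per outlet, draining to a common reference
#' (venous) pressure.  The total resistance is the parallel combination
#' `1/R_tot = sum(1/R_i)`.
#'
#' @param resistances named numeric vector of outlet resistances,
#'   mmHg.s/cm^3, names are outlet ids
#' @param reference_pressure downstream reference pressure, mmHg (default 0)
#' @return an object of class `outlet_resistance_set` with elements
#'   `resistances`, `total_resistance`, `reference_pressure`
#' @export
outlet_resistance_set <- function(resistances, reference_pressure = 0) {
  if (!is.numeric(resistances) || any(resistances <= 0))
    stop("invalid parameter: resistances must be positive", call. = FALSE)
  if (is.null(names(resistances)) || any(!nzchar(names(resistances))))
    stop("resistances must be named by outlet id", call. = FALSE)
  structure(list(resistances = resistances,
                 total_resistance = 1 / sum(1 / resistances),
                 reference_pressure = as.numeric(reference_pressure)),
            class = "outlet_resistance_set")
}

#' Allocate a total resistance over the outlets
#'
#' Splits a prescribed total (parallel-combination) resistance over the
#' outlets in proportion to a power of their reference diameters: the
#' conductance of outlet i is proportional to `d_i^exponent`.  With the
#' default `exponent = 1` larger outlets receive proportionally lower
#' resistance ("inverse diameters"); `exponent = 3` gives the Murray-law
#' alternative in which flow scales with the diameter cubed.
#'
#' @param outlet_diameters named positive numeric vector of outlet reference
#'   diameters, cm (names become outlet ids; unnamed vectors are given
#'   `outlet_1..outlet_n`)
#' @param total_resistance target parallel combination, mmHg.s/cm^3
#' @param exponent positive diameter exponent of the conductance weights
#' @param reference_pressure reference pressure of the set, mmHg
#' @return an [outlet_resistance_set()] whose parallel combination equals
#'   `total_resistance`
#' @export
#' @examples
#' allocate_outlet_resistances(c(a = 2, b = 1), 9.6)  # 14.4 and 28.8
allocate_outlet_resistances <- function(outlet_diameters, total_resistance,
                                        exponent = 1, reference_pressure = 0) {
  if (!is.numeric(outlet_diameters) || any(outlet_diameters <= 0))
    stop("invalid parameter: diameters must be positive", call. = FALSE)
  if (!is.numeric(total_resistance) || total_resistance <= 0)
    stop("invalid parameter: total_resistance must be positive", call. = FALSE)
  if (!is.numeric(exponent) || exponent <= 0)
    stop("invalid parameter: exponent must be positive", call. = FALSE)
  if (is.null(names(outlet_diameters)))
    names(outlet_diameters) <- paste0("outlet_", seq_along(outlet_diameters))
  w <- outlet_diameters^exponent
  g <- (1 / total_resistance) * w / sum(w)
  outlet_resistance_set(1 / g, reference_pressure)
}

#' Flow through a quadratic pressure-loss element
#'
#' Inverts the stenosis pressure-flow law `dp = f Q + s Q^2` (optionally with
#' a transitional term `t Q^1.5`) for the unique non-negative flow at a given
#' non-negative pressure drop.  The quadratic root is evaluated in the
#' cancellation-free form `Q = 2 dp / (f + sqrt(f^2 + 4 s dp))`.
#'
#' @param f viscous coefficient, mmHg.s/cm^3 (>= 0)
#' @param s expansion-loss coefficient, mmHg.s^2/cm^6 (>= 0)
#' @param dp pressure drop, mmHg (>= 0)
#' @param t transitional coefficient, mmHg.s^1.5/cm^4.5 (>= 0, default 0)
#' @return flow, cm^3/s
#' @export
#' @examples
#' segment_flow_from_dp(1, 1, 2)  # 1
#' segment_flow_from_dp(2, 0, 4)  # 2
segment_flow_from_dp <- function(f, s, dp, t = 0) {
  if (f < 0 || s < 0 || t < 0) stop("coefficients must be non-negative",
                                    call. = FALSE)
  if (dp < 0) stop("`dp` must be non-negative", call. = FALSE)
  if (dp == 0) return(0)
  if (f == 0 && s == 0 && t == 0)
    stop("degenerate segment: f = s = 0 with dp > 0", call. = FALSE)
  if (t == 0) return(2 * dp / (f + sqrt(f * f + 4 * s * dp)))
  # monotone scalar law with a Q^1.5 term: bracketed root find
  law <- function(q) f * q + t * q^1.5 + s * q * q - dp
  hi <- (dp / t)^(2 / 3)
  if (f > 0 || s > 0)
    hi <- max(hi, 2 * dp / (f + sqrt(f * f + 4 * s * dp)))
  hi <- max(hi, 1)
  while (law(hi) < 0) hi <- hi * 2
  stats::uniroot(law, c(0, hi), tol = 1e-14 * max(1, hi))$root
}

## Signed flow law inversion used inside the Newton iteration: odd extension
## of segment_flow_from_dp so intermediate iterates with locally reversed
## gradients remain well defined.
qflow_signed <- function(f, s, t, dp) {
  sg <- sign(dp)
  ad <- abs(dp)
  if (ad == 0) return(0)
  if (t == 0) return(sg * 2 * ad / (f + sqrt(f * f + 4 * s * ad)))
  sg * segment_flow_from_dp(f, s, ad, t)
}

## d flow / d dp of the (odd-extended) law at flow magnitude q.
qflow_deriv <- function(f, s, t, q) {
  1 / (f + 1.5 * t * sqrt(abs(q)) + 2 * s * abs(q))
}

#' Steady solution of a coefficient network
#'
#' Low-level steady solver: every segment obeys the pressure-loss law
#' `dp = f Q + t Q^1.5 + s Q^2`, every outlet obeys `dp = R Q` to the
#' reference pressure, and mass is conserved at each node.  The nodal system
#' is solved by damped Newton iteration on the junction pressures with an
#' analytic Jacobian, started from the linearized (all `s = t = 0`) network
#' solution; on the rare Newton failure a nonlinear Gauss-Seidel bisection
#' fallback is run before a final Newton polish.
#'
#' @param segments data frame with columns `segment`, `from`, `to`, `f`, `s`
#'   and optionally `t` (per-segment coefficients)
#' @param outlets data frame with columns `id`, `node`, `resistance`
#' @param inlet_node name of the fixed-pressure inlet node
#' @param inlet_pressure inlet static pressure, mmHg
#' @param reference_pressure outlet reference pressure, mmHg
#' @param tol relative mass-balance tolerance
#' @param max_iter maximum Newton iterations
#' @return list with `segment_flows`, `node_pressures`, `outlet_flows`
#'   (named numeric vectors), `inlet_flow`, `iterations`, `residual`
#' @export
solve_segment_network <- function(segments, outlets, inlet_node,
                                  inlet_pressure, reference_pressure = 0,
                                  tol = 1e-12, max_iter = 200) {
  seg <- as.data.frame(segments, stringsAsFactors = FALSE)
  if (is.null(seg[["t"]])) seg[["t"]] <- 0
  out <- as.data.frame(outlets, stringsAsFactors = FALSE)
  if (inlet_pressure <= reference_pressure)
    stop("inlet pressure must exceed the reference pressure", call. = FALSE)
  nodes <- unique(c(inlet_node, seg$from, seg$to))
  free <- setdiff(nodes, inlet_node)
  nf <- length(free)
  # integer node indexing: 0 = inlet (fixed pressure), 1..nf = free nodes
  ifrom <- match(seg$from, free, nomatch = 0L)
  ito <- match(seg$to, free, nomatch = 0L)
  ns <- nrow(seg)
  sf <- seg$f
  ss <- seg$s
  st <- seg[["t"]]
  has_t <- any(st > 0)
  out_g <- numeric(nf)
  oi <- match(out$node, free, nomatch = 0L)
  if (any(oi == 0L))
    stop("outlets cannot sit on the inlet node", call. = FALSE)
  for (i in seq_along(oi)) out_g[oi[i]] <- out_g[oi[i]] + 1 / out$resistance[i]

  press <- function(p) c(inlet_pressure, p)  # index with i + 1
  flows_at <- function(p) {
    pp <- press(p)
    dp <- pp[ifrom + 1L] - pp[ito + 1L]
    q <- sign(dp) * 2 * abs(dp) / (sf + sqrt(sf * sf + 4 * ss * abs(dp)))
    if (has_t) {
      for (j in which(st > 0)) q[j] <- qflow_signed(sf[j], ss[j], st[j], dp[j])
    }
    q
  }
  residual_at <- function(p, q) {
    r <- -out_g * (p - reference_pressure)
    for (j in seq_len(ns)) {
      if (ito[j] > 0L) r[ito[j]] <- r[ito[j]] + q[j]
      if (ifrom[j] > 0L) r[ifrom[j]] <- r[ifrom[j]] - q[j]
    }
    r
  }
  jacobian_at <- function(q) {
    jmat <- diag(-out_g, nf)
    cj <- 1 / (sf + 1.5 * st * sqrt(abs(q)) + 2 * ss * abs(q))
    for (j in seq_len(ns)) {
      fi <- ifrom[j]
      ti <- ito[j]
      if (ti > 0L) {
        jmat[ti, ti] <- jmat[ti, ti] - cj[j]
        if (fi > 0L) jmat[ti, fi] <- jmat[ti, fi] + cj[j]
      }
      if (fi > 0L) {
        jmat[fi, fi] <- jmat[fi, fi] - cj[j]
        if (ti > 0L) jmat[fi, ti] <- jmat[fi, ti] + cj[j]
      }
    }
    jmat
  }

  # linearized initial guess: conductance Laplacian with g = 1/f
  glin <- 1 / pmax(sf, 1e-12)
  a <- diag(out_g, nf)
  b <- out_g * reference_pressure
  for (j in seq_len(ns)) {
    fi <- ifrom[j]
    ti <- ito[j]
    if (ti > 0L) {
      a[ti, ti] <- a[ti, ti] + glin[j]
      if (fi > 0L) a[ti, fi] <- a[ti, fi] - glin[j]
      else b[ti] <- b[ti] + glin[j] * inlet_pressure
    }
    if (fi > 0L) {
      a[fi, fi] <- a[fi, fi] + glin[j]
      if (ti > 0L) a[fi, ti] <- a[fi, ti] - glin[j]
      else b[fi] <- b[fi] + glin[j] * inlet_pressure
    }
  }
  p <- as.numeric(solve(a, b))
  p <- pmin(pmax(p, reference_pressure), inlet_pressure)

  # characteristic flow: what the outlet bank would pass at full driving
  # pressure; residual tolerances are relative to this
  scale_q <- max(1e-6, (inlet_pressure - reference_pressure) * sum(out_g))

  newton <- function(p, iters) {
    q <- flows_at(p)
    r <- residual_at(p, q)
    it <- 0L
    while (max(abs(r)) > tol * scale_q && it < iters) {
      step <- tryCatch(solve(jacobian_at(q), -r), error = function(e) NULL)
      if (is.null(step)) break
      lambda <- 1
      stalled <- FALSE
      repeat {
        p_new <- p + lambda * step
        q_new <- flows_at(p_new)
        r_new <- residual_at(p_new, q_new)
        if (max(abs(r_new)) < max(abs(r))) break
        lambda <- lambda / 2
        if (lambda < 1e-12) {  # at the numerical floor; cannot improve
          stalled <- TRUE
          break
        }
      }
      if (stalled) break
      p <- p_new
      q <- q_new
      r <- r_new
      it <- it + 1L
    }
    list(p = p, q = q, r = r, it = it)
  }

  res <- newton(p, max_iter)
  # accept a stall at the attainable floor well inside the physical tolerance
  floor_tol <- max(tol * scale_q,
                   64 * .Machine$double.eps * inlet_pressure *
                     (max(glin) + max(out_g)))
  if (max(abs(res$r)) > floor_tol) {
    # Gauss-Seidel bisection fallback: solve each node balance in its own
    # pressure (monotone decreasing), then polish with Newton
    p <- res$p
    for (sweep in 1:500) {
      delta <- 0
      for (i in seq_len(nf)) {
        bal <- function(pi) {
          pp <- p
          pp[i] <- pi
          residual_at(pp, flows_at(pp))[i]
        }
        lo <- reference_pressure
        hi <- inlet_pressure
        if (bal(lo) < 0 || bal(hi) > 0) next
        for (k in 1:80) {
          mid <- 0.5 * (lo + hi)
          if (bal(mid) > 0) lo <- mid else hi <- mid
        }
        delta <- max(delta, abs(p[i] - 0.5 * (lo + hi)))
        p[i] <- 0.5 * (lo + hi)
      }
      if (delta < 1e-13 * inlet_pressure) break
    }
    res <- newton(p, max_iter)
    if (max(abs(res$r)) > 1e-8 * scale_q)
      stop(sprintf("solver failed to converge (max residual %.3e cm^3/s)",
                   max(abs(res$r))), call. = FALSE)
  }

  q <- res$q
  if (any(q < -1e-9 * scale_q))
    stop("backflow detected: negative segment flow is unsupported",
         call. = FALSE)
  q[q < 0] <- 0
  node_p <- stats::setNames(c(inlet_pressure, res$p), c(inlet_node, free))
  outlet_q <- stats::setNames(
    (node_p[out$node] - reference_pressure) / out$resistance, out$id)
  inlet_q <- sum(q[seg$from == inlet_node])
  list(segment_flows = stats::setNames(q, seg$segment),
       node_pressures = node_p, outlet_flows = outlet_q,
       inlet_flow = inlet_q, iterations = res$it, residual = max(abs(res$r)))
}

## Per-segment pressure-loss coefficients of a network: full-length Poiseuille
## viscous coefficient everywhere, plus the expansion and transitional terms
## on the lesion segment.  Also records the lesion-plane viscous coefficient
## used to read off the trans-stenotic pressure drop.
network_coefficients <- function(network, fluid) {
  les <- lesion_segment(network)
  true_cf <- stenosis_true_coefficients(network, fluid)
  seg <- network$connections
  seg$f <- vapply(network$segments[seg$segment],
                  segment_viscous_coefficient, 0, fluid = fluid)
  seg$s <- ifelse(seg$segment == les$id, true_cf$s, 0)
  seg$t <- ifelse(seg$segment == les$id, network$lesion_transitional, 0)
  list(segments = seg, lesion_id = les$id,
       lesion_f = true_cf$f, lesion_s = true_cf$s,
       lesion_t = network$lesion_transitional)
}

#' Steady flow solution of an aortic network
#'
#' Solves an [aorta_network()] for steady flow with a fixed inlet static
#' pressure and single-resistance lumped outlets.  Every segment obeys the
#' quadratic loss law with its geometric Poiseuille coefficient (expansion
#' loss only on the lesion segment), and the trans-stenotic pair
#' `(lesion_flow, lesion_dp)` is read between the lesion start and end
#' planes.
#'
#' @param network an [aorta_network()]
#' @param fluid a [fluid_properties()]
#' @param inlet_pressure inlet static pressure, mmHg (default 80)
#' @param outlets an [outlet_resistance_set()] covering the network's outlet
#'   ids
#' @return an object of class `flow_solution`: `segment_flows`,
#'   `node_pressures`, `outlet_flows`, `inlet_flow`, `lesion_flow`,
#'   `lesion_dp`, plus solver diagnostics
#' @export
solve_steady_network <- function(network, fluid = fluid_properties(),
                                 inlet_pressure = 80, outlets) {
  stopifnot(inherits(network, "aorta_network"),
            inherits(outlets, "outlet_resistance_set"))
  if (!all(network$outlets$id %in% names(outlets$resistances)))
    stop("resistance set does not cover all outlet ids", call. = FALSE)
  cf <- network_coefficients(network, fluid)
  out <- data.frame(id = network$outlets$id, node = network$outlets$node,
                    resistance = as.numeric(
                      outlets$resistances[network$outlets$id]))
  sol <- solve_segment_network(cf$segments, out, network$inlet_node,
                               inlet_pressure, outlets$reference_pressure)
  q_les <- as.numeric(sol$segment_flows[cf$lesion_id])
  sol$lesion_flow <- q_les
  sol$lesion_dp <- cf$lesion_f * q_les + cf$lesion_t * q_les^1.5 +
    cf$lesion_s * q_les^2
  class(sol) <- "flow_solution"
  sol
}

#' Six-level outlet-resistance sweep
#'
#' Traces the stenosis pressure-flow curve of a patient: the outlet
#' resistances are allocated once at the base total resistance and then
#' scaled by each factor in `scales` (default 1, 1/2, ..., 1/6), preserving
#' the allocation ratios; one steady solution is run per level and the
#' trans-stenotic `(Q, dp)` pair is recorded.
#'
#' @param network an [aorta_network()]
#' @param fluid a [fluid_properties()]
#' @param inlet_pressure inlet static pressure, mmHg (default 80)
#' @param base_total_resistance total outlet resistance at scale 1,
#'   mmHg.s/cm^3 (default 9.6)
#' @param scales resistance scale factors, each in (0, 1]
#' @param exponent diameter exponent of [allocate_outlet_resistances()]
#' @param reference_pressure outlet reference pressure, mmHg
#' @return an object of class `sweep_result`: a data frame with columns
#'   `scale`, `total_resistance`, `Q_bar`, `dp_bar` ordered as `scales`
#' @export
run_resistance_sweep <- function(network, fluid = fluid_properties(),
                                 inlet_pressure = 80,
                                 base_total_resistance = 9.6,
                                 scales = 1 / (1:6), exponent = 1,
                                 reference_pressure = 0) {
  stopifnot(inherits(network, "aorta_network"))
  if (any(scales <= 0 | scales > 1) || anyDuplicated(scales))
    stop("`scales` must be distinct values in (0, 1]", call. = FALSE)
  d <- stats::setNames(network$outlets$diameter, network$outlets$id)
  base <- allocate_outlet_resistances(d, base_total_resistance, exponent,
                                      reference_pressure)
  rows <- lapply(scales, function(sc) {
    set <- outlet_resistance_set(base$resistances * sc, reference_pressure)
    sol <- tryCatch(
      solve_steady_network(network, fluid, inlet_pressure, set),
      error = function(e) stop(sprintf("sweep failed at scale %.4g: %s",
                                       sc, conditionMessage(e)), call. = FALSE))
    data.frame(scale = sc, total_resistance = set$total_resistance,
               Q_bar = sol$lesion_flow, dp_bar = sol$lesion_dp)
  })
  res <- do.call(rbind, rows)
  class(res) <- c("sweep_result", "data.frame")
  res
}

#' Write / read sweep results as CSV
#'
#' @param sweeps a `sweep_result` or named list of them (names are patient
#'   ids), or a data frame already carrying a `patient_id` column
#' @param path file path
#' @return `write_sweep_csv()` returns `path` invisibly; `read_sweep_csv()`
#'   returns a data frame with columns `patient_id`, `scale`,
#'   `total_resistance`, `Q_bar_cm3_s`, `dp_bar_mmHg`.
#' @export
write_sweep_csv <- function(sweeps, path) {
  if (inherits(sweeps, "sweep_result")) sweeps <- list(patient = sweeps)
  if (is.data.frame(sweeps) && "patient_id" %in% names(sweeps)) {
    tab <- sweeps
  } else {
    tab <- do.call(rbind, lapply(names(sweeps), function(id) {
      s <- as.data.frame(sweeps[[id]])
      data.frame(patient_id = id, scale = s$scale,
                 total_resistance = s$total_resistance,
                 Q_bar_cm3_s = s$Q_bar, dp_bar_mmHg = s$dp_bar)
    }))
  }
  utils::write.csv(tab, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_sweep_csv
#' @export
read_sweep_csv <- function(path) {
  utils::read.csv(path, stringsAsFactors = FALSE)
}
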