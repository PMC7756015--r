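#' Blood properties in pressure-flow units
#'
#' Constructs the fluid-property record used throughout the package.  All
#' hemodynamic quantities are kept in the clinical unit system: pressures in
#' mmHg, flows in cm^3/s, lengths in cm.  In these units standard blood has a
#' dynamic viscosity of 0.004 Pa.s = 3.0e-5 mmHg.s and a density of
#' 1060 kg/m^3 = 7.95e-4 mmHg.s^2/cm^2.
#'
#' @param viscosity dynamic viscosity, mmHg.s
#' @param density mass density, mmHg.s^2/cm^2
#' @return an object of class `fluid_properties`
#' @export
#' @examples
#' fluid_properties()
fluid_properties <- function(viscosity = 3.0e-5, density = 7.95e-4) {
  if (!is.numeric(viscosity) || length(viscosity) != 1L || viscosity <= 0)
    stop("`viscosity` must be a single positive number", call. = FALSE)
  if (!is.numeric(density) || length(density) != 1L || density <= 0)
    stop("`density` must be a single positive number", call. = FALSE)
  structure(list(viscosity = viscosity, density = density),
            class = "fluid_properties")
}

#' Vessel segment with an axial radius profile
#'
#' A segment is a straight reduced-order vessel described by a piecewise
#' linear lumen radius profile along its axis.  At most one segment of a
#' network is flagged as the lesion (the coarctation); for that segment the
#' axial positions of the lesion start and end planes must be given, mirroring
#' the cross-sections between which the trans-stenotic pressure drop is read.
#'
#' @param id segment identifier (single string)
#' @param length segment length, cm
#' @param radius_profile two-column object (`pos`, `radius`), cm: axial knot
#'   positions (strictly increasing from 0 to `length`) and lumen radii
#' @param is_lesion logical flag marking the coarctation segment
#' @param lesion_start,lesion_end axial positions (cm) of the lesion planes,
#'   required when `is_lesion = TRUE`
#' @return an object of class `vessel_segment`
#' @export
#' @examples
#' vessel_segment("isthmus", 2,
#'   data.frame(pos = c(0, 0.6, 1, 1.4, 2),
#'              radius = c(0.5, 0.5, 0.25, 0.5, 0.5)),
#'   is_lesion = TRUE, lesion_start = 0.6, lesion_end = 1.4)
vessel_segment <- function(id, length, radius_profile, is_lesion = FALSE,
                           lesion_start = NULL, lesion_end = NULL) {
  if (!is.character(id) || length(id) != 1L || !nzchar(id))
    stop("`id` must be a non-empty string", call. = FALSE)
  if (!is.numeric(length) || base::length(length) != 1L || length <= 0)
    stop("segment `length` must be a single positive number", call. = FALSE)
  rp <- as.data.frame(radius_profile)
  if (ncol(rp) < 2L) stop("`radius_profile` needs columns pos and radius",
                          call. = FALSE)
  names(rp)[1:2] <- c("pos", "radius")
  rp <- rp[, c("pos", "radius")]
  if (nrow(rp) < 2L)
    stop("`radius_profile` needs at least two knots", call. = FALSE)
  if (any(diff(rp$pos) <= 0))
    stop("radius profile positions must be strictly increasing", call. = FALSE)
  tol <- 1e-9 * max(1, length)
  if (abs(rp$pos[1L]) > tol || abs(rp$pos[nrow(rp)] - length) > tol)
    stop("radius profile must span [0, length]", call. = FALSE)
  rp$pos[1L] <- 0
  rp$pos[nrow(rp)] <- length
  if (any(rp$radius <= 0))
    stop("all radii must be strictly positive", call. = FALSE)
  if (isTRUE(is_lesion)) {
    if (is.null(lesion_start) || is.null(lesion_end))
      stop("lesion segments require `lesion_start` and `lesion_end`",
           call. = FALSE)
    if (!(lesion_start >= 0 && lesion_end <= length &&
          lesion_start < lesion_end))
      stop("need 0 <= lesion_start < lesion_end <= length", call. = FALSE)
  } else {
    lesion_start <- lesion_end <- NULL
  }
  structure(list(id = id, length = as.numeric(length), radius_profile = rp,
                 is_lesion = isTRUE(is_lesion),
                 lesion_start = lesion_start, lesion_end = lesion_end),
            class = "vessel_segment")
}

## Linear interpolation of the lumen radius at axial position x.
segment_radius_at <- function(segment, x) {
  rp <- segment$radius_profile
  stats::approx(rp$pos, rp$radius, xout = x, rule = 2)$y
}

## Minimum lumen radius over [from, to]; the profile is piecewise linear so
## the minimum is attained at a knot or at an interval endpoint.
segment_min_radius <- function(segment, from = 0, to = segment$length) {
  rp <- segment$radius_profile
  inside <- rp$pos > from & rp$pos < to
  min(c(segment_radius_at(segment, c(from, to)), rp$radius[inside]))
}

## Closed-form integral of dx / r(x)^4 over [from, to] for the piecewise
## linear radius profile.  On an interval where r goes linearly r0 -> r1 over
## length h the antiderivative gives h * (r0^-3 - r1^-3) / (3 (r1 - r0)).
integral_inv_r4 <- function(segment, from = 0, to = segment$length) {
  stopifnot(from >= -1e-12, to <= segment$length + 1e-12, from <= to)
  rp <- segment$radius_profile
  total <- 0
  for (i in seq_len(nrow(rp) - 1L)) {
    a <- max(rp$pos[i], from)
    b <- min(rp$pos[i + 1L], to)
    if (b <= a) next
    ra <- segment_radius_at(segment, a)
    rb <- segment_radius_at(segment, b)
    if (abs(rb - ra) < 1e-12 * max(ra, rb)) {
      total <- total + (b - a) / ((0.5 * (ra + rb))^4)
    } else {
      total <- total + (b - a) * (ra^-3 - rb^-3) / (3 * (rb - ra))
    }
  }
  total
}

#' Poiseuille viscous coefficient of a segment
#'
#' Integrates the local Poiseuille resistance `8 mu / (pi r(x)^4)` along the
#' segment axis, giving the linear coefficient of the segment pressure-flow
#' law `dp = f Q` for fully developed laminar flow.  The coefficient is
#' additive over sub-segments and linear in segment length.
#'
#' @param segment a [vessel_segment()]
#' @param fluid a [fluid_properties()]
#' @param from,to axial bounds of the integral, cm (default: whole segment)
#' @return viscous coefficient, mmHg.s/cm^3
#' @export
#' @examples
#' seg <- vessel_segment("a", 1, data.frame(pos = c(0, 1), radius = 0.25))
#' segment_viscous_coefficient(seg, fluid_properties())  # ~0.01956
segment_viscous_coefficient <- function(segment, fluid = fluid_properties(),
                                        from = 0, to = segment$length) {
  stopifnot(inherits(segment, "vessel_segment"))
  8 * fluid$viscosity / pi * integral_inv_r4(segment, from, to)
}

#' Stenosis coefficient pair (f, s)
#'
#' Container for the two coefficients of the stenosis pressure-flow curve
#' `dp = f Q + s Q^2`: `f` the viscous friction (mmHg.s/cm^3) and `s` the
#' expansion loss (mmHg.s^2/cm^6).  Both are non-negative.
#'
#' @param f viscous friction coefficient, mmHg.s/cm^3
#' @param s expansion loss coefficient, mmHg.s^2/cm^6
#' @return an object of class `stenosis_coefficients`
#' @export
stenosis_coefficients <- function(f, s) {
  if (!is.numeric(f) || length(f) != 1L || !is.finite(f) || f < 0)
    stop("`f` must be a single finite non-negative number", call. = FALSE)
  if (!is.numeric(s) || length(s) != 1L || !is.finite(s) || s < 0)
    stop("`s` must be a single finite non-negative number", call. = FALSE)
  structure(list(f = as.numeric(f), s = as.numeric(s)),
            class = "stenosis_coefficients")
}

#' @export
print.stenosis_coefficients <- function(x, ...) {
  cat(sprintf("stenosis coefficients: f = %.6g mmHg.s/cm^3, s = %.6g mmHg.s^2/cm^6\n",
              x$f, x$s))
  invisible(x)
}

#' Aortic-arch vessel network
#'
#' A rooted tree of [vessel_segment()]s standing in for a segmented
#' aortic-arch reconstruction.  Nodes are named junction points; every
#' segment connects a `from` node to a `to` node, the tree is rooted at the
#' single inlet node, and exactly four outlets (supra-aortic branches plus
#' the distal descending aorta) attach lumped resistance boundary conditions
#' at nodes.  Exactly one segment carries the coarctation lesion.
#'
#' @param segments list of [vessel_segment()]s
#' @param connections data frame with columns `segment`, `from`, `to` giving
#'   the node attachment of every segment
#' @param inlet_node name of the root (inlet) node
#' @param outlets data frame with columns `id`, `node`, `diameter` (cm):
#'   the four outlet boundaries and their reference diameters
#' @param diaphragm_diameter aortic diameter at the diaphragm level, cm
#'   (denominator of the ESC narrowing rate)
#' @param lesion_k_e expansion-loss factor of the lesion (1 = Borda-Carnot)
#' @param lesion_transitional optional transitional-loss coefficient of the
#'   lesion (mmHg.s^1.5/cm^4.5); adds a `t Q^1.5` term to the lesion law and
#'   is used to inject model mismatch (default 0)
#' @return an object of class `aorta_network`
#' @export
aorta_network <- function(segments, connections, inlet_node, outlets,
                          diaphragm_diameter, lesion_k_e = 1,
                          lesion_transitional = 0) {
  if (!is.list(segments) || !all(vapply(segments, inherits, TRUE,
                                        "vessel_segment")))
    stop("`segments` must be a list of vessel_segment objects", call. = FALSE)
  seg_ids <- vapply(segments, `[[`, "", "id")
  if (anyDuplicated(seg_ids)) stop("duplicated segment ids", call. = FALSE)
  names(segments) <- seg_ids
  con <- as.data.frame(connections, stringsAsFactors = FALSE)
  if (!all(c("segment", "from", "to") %in% names(con)))
    stop("`connections` needs columns segment, from, to", call. = FALSE)
  if (!setequal(con$segment, seg_ids) || nrow(con) != length(seg_ids))
    stop("`connections` must list every segment exactly once", call. = FALSE)
  con <- con[match(seg_ids, con$segment), , drop = FALSE]
  out <- as.data.frame(outlets, stringsAsFactors = FALSE)
  if (!all(c("id", "node", "diameter") %in% names(out)))
    stop("`outlets` needs columns id, node, diameter", call. = FALSE)
  if (nrow(out) != 4L)
    stop("an aorta network has exactly four outlet boundaries", call. = FALSE)
  if (anyDuplicated(out$id)) stop("duplicated outlet ids", call. = FALSE)
  if (any(out$diameter <= 0))
    stop("outlet reference diameters must be positive", call. = FALSE)
  if (!is.numeric(diaphragm_diameter) || diaphragm_diameter <= 0)
    stop("`diaphragm_diameter` must be positive", call. = FALSE)
  nodes <- unique(c(inlet_node, con$from, con$to))
  if (!all(out$node %in% nodes))
    stop("outlet nodes must be network nodes", call. = FALSE)
  # tree rooted at the inlet: every non-inlet node has exactly one parent
  # segment and every node is reachable from the inlet
  non_inlet <- setdiff(nodes, inlet_node)
  indeg <- table(factor(con$to, levels = non_inlet))
  if (any(con$to == inlet_node) || any(indeg != 1L))
    stop("network must be a tree rooted at the inlet node", call. = FALSE)
  reach <- inlet_node
  repeat {
    nxt <- con$to[con$from %in% reach & !(con$to %in% reach)]
    if (!length(nxt)) break
    reach <- c(reach, nxt)
  }
  if (!setequal(reach, nodes))
    stop("network is not connected to the inlet", call. = FALSE)
  leaves <- setdiff(nodes, con$from)
  if (!all(leaves %in% out$node))
    stop("every terminal node must carry an outlet boundary", call. = FALSE)
  n_lesion <- sum(vapply(segments, `[[`, TRUE, "is_lesion"))
  if (n_lesion != 1L)
    stop("network must contain exactly one lesion segment", call. = FALSE)
  if (!is.numeric(lesion_k_e) || lesion_k_e <= 0)
    stop("`lesion_k_e` must be positive", call. = FALSE)
  if (!is.numeric(lesion_transitional) || lesion_transitional < 0)
    stop("`lesion_transitional` must be non-negative", call. = FALSE)
  structure(list(segments = segments, connections = con,
                 inlet_node = inlet_node, outlets = out,
                 diaphragm_diameter = as.numeric(diaphragm_diameter),
                 lesion_k_e = as.numeric(lesion_k_e),
                 lesion_transitional = as.numeric(lesion_transitional)),
            class = "aorta_network")
}

#' @export
print.aorta_network <- function(x, ...) {
  cat(sprintf("aorta network: %d segments, inlet '%s', 4 outlets, lesion '%s'\n",
              length(x$segments), x$inlet_node, lesion_segment(x)$id))
  cat(sprintf("  narrowing rate %.1f%% (diaphragm diameter %.3f cm)\n",
              100 * narrowing_rate(x), x$diaphragm_diameter))
  invisible(x)
}

## The unique lesion segment of a network.
lesion_segment <- function(network) {
  i <- which(vapply(network$segments, `[[`, TRUE, "is_lesion"))
  network$segments[[i]]
}

#' ESC narrowing rate of the coarctation
#'
#' Anatomic severity measure of the ESC guideline criterion: one minus the
#' ratio of the minimum lesion diameter to the aortic diameter at the
#' diaphragm level, clipped below at zero.
#'
#' @param network an [aorta_network()]
#' @return narrowing fraction in `[0, 1)`
#' @export
#' @seealso [esc_classifier()] for the >= 50% decision rule
narrowing_rate <- function(network) {
  stopifnot(inherits(network, "aorta_network"))
  les <- lesion_segment(network)
  if (is.null(les$lesion_start))
    stop("invalid geometry: lesion planes missing", call. = FALSE)
  d_min <- 2 * segment_min_radius(les, les$lesion_start, les$lesion_end)
  max(0, 1 - d_min / network$diaphragm_diameter)
}

#' Ground-truth stenosis coefficients of a network
#'
#' Evaluates the generative physics of the lesion: the viscous friction is
#' the Poiseuille integral between the lesion planes, and the expansion loss
#' follows the sudden-expansion (Borda-Carnot) form
#' `s = K_e (rho/2) (1/A_min - 1/A_ref)^2` with `A_min` the minimal lesion
#' lumen area and `A_ref` the lumen area at the lesion start plane.  These
#' are the coefficients the resistance-sweep characterization is expected to
#' recover, and they depend only on geometry and fluid properties, not on any
#' flow or pressure level.
#'
#' @param network an [aorta_network()]
#' @param fluid a [fluid_properties()]
#' @param k_e expansion-loss factor; defaults to the network's own
#'   `lesion_k_e`
#' @return a [stenosis_coefficients()] pair
#' @export
stenosis_true_coefficients <- function(network, fluid = fluid_properties(),
                                       k_e = network$lesion_k_e) {
  stopifnot(inherits(network, "aorta_network"))
  les <- lesion_segment(network)
  if (is.null(les$lesion_start))
    stop("invalid geometry: lesion planes missing", call. = FALSE)
  f <- segment_viscous_coefficient(les, fluid, les$lesion_start,
                                   les$lesion_end)
  r_min <- segment_min_radius(les, les$lesion_start, les$lesion_end)
  r_ref <- segment_radius_at(les, les$lesion_start)
  a_min <- pi * r_min^2
  a_ref <- pi * r_ref^2
  s <- k_e * (fluid$density / 2) * (1 / a_min - 1 / a_ref)^2
  stenosis_coefficients(f, s)
}
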