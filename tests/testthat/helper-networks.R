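# Shared fixtures: small hand-built networks, a random-network generator,
# and an independent brute-force steady-flow oracle.

uniform_segment <- function(id, r, len, ...) {
  vessel_segment(id, len, data.frame(pos = c(0, len), radius = c(r, r)), ...)
}

# Three-segment arch stand-in with a V-shaped isthmus lesion.
toy_lesion_network <- function(r_ref = 0.35, r_min = 0.15,
                               diaphragm = 2 * r_ref) {
  les <- vessel_segment(
    "isthmus", 2,
    data.frame(pos = c(0, 0.5, 1, 1.5, 2),
               radius = c(r_ref, r_ref, r_min, r_ref, r_ref)),
    is_lesion = TRUE, lesion_start = 0.5, lesion_end = 1.5)
  aorta_network(
    list(uniform_segment("asc", 0.5, 3), les,
         uniform_segment("desc", 0.4, 4)),
    data.frame(segment = c("asc", "isthmus", "desc"),
               from = c("inlet", "n1", "n2"), to = c("n1", "n2", "n3")),
    "inlet",
    data.frame(id = c("bc", "lc", "ls", "da"),
               node = c("n1", "n1", "n2", "n3"),
               diameter = c(0.5, 0.35, 0.4, 0.8)),
    diaphragm_diameter = diaphragm)
}

# Symmetric fork: common lesion trunk, then two identical branches with two
# equal outlets each.
symmetric_fork_network <- function() {
  les <- vessel_segment(
    "trunk", 2,
    data.frame(pos = c(0, 0.8, 1, 1.2, 2),
               radius = c(0.4, 0.4, 0.2, 0.4, 0.4)),
    is_lesion = TRUE, lesion_start = 0.8, lesion_end = 1.2)
  aorta_network(
    list(les, uniform_segment("left", 0.3, 3),
         uniform_segment("right", 0.3, 3)),
    data.frame(segment = c("trunk", "left", "right"),
               from = c("inlet", "n1", "n1"), to = c("n1", "n2", "n3")),
    "inlet",
    data.frame(id = c("l1", "l2", "r1", "r2"),
               node = c("n2", "n2", "n3", "n3"),
               diameter = c(0.5, 0.4, 0.5, 0.4)),
    diaphragm_diameter = 0.8)
}

# Random valid aorta network: a chain of 2-5 segments with one lesion,
# optionally one side branch, outlets distributed over non-inlet nodes so
# that every leaf carries one.
random_network <- function() {
  n_chain <- sample(2:5, 1)
  radii <- runif(n_chain, 0.25, 0.6)
  lens <- runif(n_chain, 1, 4)
  lesion_at <- sample(n_chain, 1)
  segs <- vector("list", n_chain)
  for (j in seq_len(n_chain)) {
    if (j == lesion_at) {
      r <- radii[j]
      rmin <- r * runif(1, 0.3, 0.8)
      segs[[j]] <- vessel_segment(
        paste0("seg", j), lens[j],
        data.frame(pos = c(0, 0.3, 0.5, 0.7, 1) * lens[j],
                   radius = c(r, r, rmin, r, r)),
        is_lesion = TRUE, lesion_start = 0.3 * lens[j],
        lesion_end = 0.7 * lens[j])
    } else {
      segs[[j]] <- uniform_segment(paste0("seg", j), radii[j], lens[j])
    }
  }
  nodes <- c("inlet", paste0("n", seq_len(n_chain)))
  con <- data.frame(segment = paste0("seg", seq_len(n_chain)),
                    from = nodes[seq_len(n_chain)],
                    to = nodes[seq_len(n_chain) + 1L])
  out_nodes <- nodes[length(nodes)]          # chain leaf always has one
  with_branch <- n_chain >= 3 && runif(1) < 0.5
  if (with_branch) {
    host <- paste0("n", sample(n_chain - 1L, 1))
    segs <- c(segs, list(uniform_segment("branch", runif(1, 0.2, 0.4),
                                         runif(1, 1, 3))))
    con <- rbind(con, data.frame(segment = "branch", from = host,
                                 to = "nb"))
    out_nodes <- c(out_nodes, "nb")
  }
  # remaining outlets on random non-inlet, non-leaf chain nodes
  pool <- paste0("n", seq_len(n_chain))
  out_nodes <- c(out_nodes,
                 sample(pool, 4L - length(out_nodes), replace = TRUE))
  outs <- data.frame(id = paste0("o", 1:4), node = out_nodes,
                     diameter = runif(4, 0.3, 0.9))
  aorta_network(segs, con, "inlet", outs,
                diaphragm_diameter = 2 * radii[n_chain])
}

# ---------------------------------------------------------------------------
# Independent steady-flow oracle: shooting with bisection.  Flow is
# propagated down the tree from a guessed inlet flow; at every branch
# junction the flow of each child but the last is found by bisection on the
# (monotone) subtree imbalance, and the terminal imbalance is driven to zero
# by an outer bisection on the inlet flow.  No Jacobians, no Newton steps.

oracle_law <- function(f, s, t, q) f * q + t * q^1.5 + s * q * q

oracle_solve <- function(seg, out, inlet_node, inlet_pressure,
                         reference_pressure = 0, iters = 55L) {
  if (is.null(seg[["t"]])) seg[["t"]] <- 0
  flows <- numeric(nrow(seg))
  pressures <- list()
  g_out <- tapply(1 / out$resistance, out$node, sum)

  # imbalance left over after pushing flow q through segment j at upstream
  # pressure p_from; fills `flows` / `pressures` as a side effect
  descend <- function(j, p_from, q) {
    flows[j] <<- q
    p_to <- p_from - oracle_law(seg$f[j], seg$s[j], seg[["t"]][j],
                                max(q, 0)) * sign(q)
    pressures[[seg$to[j]]] <<- p_to
    avail <- q
    if (!is.na(g_out[seg$to[j]]))
      avail <- avail - g_out[[seg$to[j]]] * (p_to - reference_pressure)
    kids <- which(seg$from == seg$to[j])
    if (!length(kids)) return(avail)
    if (length(kids) > 1L) {
      for (k in kids[-length(kids)]) {
        lo <- 0
        hi <- max(abs(avail), 1e-6)
        while (descend(k, p_to, hi) < 0) hi <- hi * 2
        for (i in seq_len(iters)) {
          mid <- 0.5 * (lo + hi)
          if (descend(k, p_to, mid) < 0) lo <- mid else hi <- mid
        }
        qk <- 0.5 * (lo + hi)
        descend(k, p_to, qk)
        avail <- avail - qk
      }
    }
    descend(kids[length(kids)], p_to, avail)
  }

  roots <- which(seg$from == inlet_node)
  stopifnot(length(roots) == 1L)  # fixtures use a single inlet segment
  lo <- 0
  hi <- 1
  while (descend(roots, inlet_pressure, hi) < 0) hi <- hi * 2
  for (i in seq_len(iters)) {
    mid <- 0.5 * (lo + hi)
    if (descend(roots, inlet_pressure, mid) < 0) lo <- mid else hi <- mid
  }
  descend(roots, inlet_pressure, 0.5 * (lo + hi))
  pressures[[inlet_node]] <- inlet_pressure
  list(segment_flows = stats::setNames(flows, seg$segment),
       node_pressures = unlist(pressures))
}

# oracle on an aorta_network + resistance set, via the package's coefficient
# table (the geometry -> coefficient mapping is tested separately against
# closed forms)
oracle_solve_network <- function(network, fluid, inlet_pressure, outlets) {
  cf <- coaflow:::network_coefficients(network, fluid)
  out <- data.frame(id = network$outlets$id, node = network$outlets$node,
                    resistance = as.numeric(
                      outlets$resistances[network$outlets$id]))
  oracle_solve(cf$segments, out, network$inlet_node, inlet_pressure,
               outlets$reference_pressure)
}

random_resistance_set <- function(network) {
  d <- stats::setNames(network$outlets$diameter, network$outlets$id)
  allocate_outlet_resistances(d, runif(1, 3, 15),
                              exponent = sample(c(1, 3), 1))
}
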