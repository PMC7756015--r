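test_that("resistance allocation honours the diameter weighting", {
  # symmetry: equal diameters, equal shares
  rs <- allocate_outlet_resistances(c(a = 1, b = 1, c = 1, d = 1), 9.6)
  expect_equal(unname(rs$resistances), rep(38.4, 4))
  # hand-computed two-outlet allocation, G_i = G_tot d_i / sum(d)
  rs2 <- allocate_outlet_resistances(c(a = 2, b = 1), 9.6)
  expect_equal(unname(rs2$resistances), c(14.4, 28.8))
  # parallel recombination returns the total for arbitrary allocations
  for (expo in c(1, 3)) {
    rs3 <- allocate_outlet_resistances(c(a = 0.51, b = 0.34, c = 0.4,
                                         d = 0.8), 9.6, exponent = expo)
    expect_equal(1 / sum(1 / rs3$resistances), 9.6, tolerance = 1e-10)
  }
  expect_error(allocate_outlet_resistances(c(a = -1, b = 1), 9.6),
               "positive")
})

test_that("pressure-flow law inversion is exact and stable", {
  expect_equal(segment_flow_from_dp(1, 1, 2), 1)
  expect_equal(segment_flow_from_dp(2, 0, 4), 2)
  expect_equal(segment_flow_from_dp(3, 0.7, 0), 0)
  # cancellation-prone regime: tiny s against large f
  f <- 10; s <- 1e-12; dp <- 5
  q <- segment_flow_from_dp(f, s, dp)
  expect_equal(f * q + s * q^2, dp, tolerance = 1e-14)
  # transitional term round-trip
  q <- segment_flow_from_dp(0.5, 0.2, 7, t = 0.1)
  expect_equal(0.5 * q + 0.1 * q^1.5 + 0.2 * q^2, 7, tolerance = 1e-10)
  expect_error(segment_flow_from_dp(0, 0, 1), "degenerate")
  expect_error(segment_flow_from_dp(1, 1, -1), "non-negative")
})

test_that("single-path solutions match closed forms", {
  # Ohm-law analog: near-lossless conduit into R = 9.6 at 80 mmHg
  sol <- solve_segment_network(
    data.frame(segment = "a", from = "inlet", to = "n1", f = 1e-6, s = 0),
    data.frame(id = "o", node = "n1", resistance = 9.6), "inlet", 80)
  expect_equal(unname(sol$inlet_flow), 80 / 9.6, tolerance = 1e-6)
  # quadratic lesion: Q^2 + 4 Q = 80
  sol2 <- solve_segment_network(
    data.frame(segment = "l", from = "inlet", to = "n1", f = 1, s = 1),
    data.frame(id = "o", node = "n1", resistance = 3), "inlet", 80)
  expect_equal(unname(sol2$segment_flows["l"]), (-4 + sqrt(336)) / 2,
               tolerance = 1e-10)
})

test_that("linear networks match the closed-form circuit solution exactly", {
  # chain of three resistive segments with two outlet nodes: solve the
  # 2x2 linear nodal system by hand and compare
  f1 <- 0.8; f2 <- 1.7; r1 <- 6; r2 <- 4; pin <- 80
  a <- matrix(c(1 / f1 + 1 / f2 + 1 / r1, -1 / f2,
                -1 / f2, 1 / f2 + 1 / r2), 2, byrow = TRUE)
  p <- solve(a, c(pin / f1, 0))
  sol <- solve_segment_network(
    data.frame(segment = c("s1", "s2"), from = c("inlet", "n1"),
               to = c("n1", "n2"), f = c(f1, f2), s = 0),
    data.frame(id = c("o1", "o2"), node = c("n1", "n2"),
               resistance = c(r1, r2)), "inlet", pin)
  expect_equal(unname(sol$node_pressures[c("n1", "n2")]), as.numeric(p),
               tolerance = 1e-12)
  expect_equal(unname(sol$segment_flows), c((pin - p[1]) / f1,
                                            (p[1] - p[2]) / f2),
               tolerance = 1e-12)
})

test_that("symmetric fork splits flow equally", {
  net <- symmetric_fork_network()
  rs <- allocate_outlet_resistances(
    stats::setNames(net$outlets$diameter, net$outlets$id), 9.6)
  sol <- solve_steady_network(net, outlets = rs)
  expect_equal(unname(sol$segment_flows["left"]),
               unname(sol$segment_flows["right"]), tolerance = 1e-10)
  expect_equal(unname(sol$segment_flows["trunk"]),
               unname(sol$segment_flows["left"] + sol$segment_flows["right"]),
               tolerance = 1e-10)
})

test_that("solver agrees with the bisection oracle on random networks", {
  set.seed(2024)
  fl <- fluid_properties()
  for (i in 1:25) {
    net <- random_network()
    rs <- random_resistance_set(net)
    sol <- solve_steady_network(net, fl, 80, rs)
    ora <- oracle_solve_network(net, fl, 80, rs)
    expect_equal(sol$segment_flows[names(ora$segment_flows)],
                 ora$segment_flows,
                 tolerance = 1e-8)
  }
})

test_that("mass is conserved and lesion dp is consistent at every node", {
  set.seed(11)
  fl <- fluid_properties()
  for (i in 1:10) {
    net <- random_network()
    rs <- random_resistance_set(net)
    sol <- solve_steady_network(net, fl, 80, rs)
    # global balance: inlet flow equals summed outlet flows
    expect_equal(sol$inlet_flow, sum(sol$outlet_flows),
                 tolerance = 1e-8 * sol$inlet_flow)
    # solver-reported worst junction residual is tiny relative to the flow
    expect_lt(sol$residual, 1e-8 * max(sol$inlet_flow, 1))
    expect_gte(sol$lesion_dp, 0)
  }
})

test_that("the resistance sweep is ordered and scale-consistent", {
  net <- toy_lesion_network()
  sw <- run_resistance_sweep(net)
  expect_s3_class(sw, "sweep_result")
  expect_identical(nrow(as.data.frame(sw)), 6L)
  # flows strictly increase as the total resistance drops 1 -> 1/6
  expect_true(all(diff(sw$Q_bar) > 0))
  expect_true(all(diff(sw$dp_bar) > 0))
  # halving the base resistance reproduces the scale-1/2 point at scale 1
  sw_half <- run_resistance_sweep(net, base_total_resistance = 4.8,
                                  scales = c(1, 0.5))
  expect_equal(sw_half$Q_bar[1], sw$Q_bar[2], tolerance = 1e-10)
  expect_equal(sw_half$dp_bar[1], sw$dp_bar[2], tolerance = 1e-10)
})

test_that("a lossless lesion produces zero pressure drop across the sweep", {
  net <- toy_lesion_network(r_ref = 0.8, r_min = 0.8)
  sw <- run_resistance_sweep(net)
  # the wide-open 'lesion' still has a (tiny) viscous drop; the expansion
  # part must be exactly zero and the drop negligible
  expect_equal(stenosis_true_coefficients(net)$s, 0)
  expect_lt(max(sw$dp_bar), 0.05)
})

test_that("sweep CSV round-trips losslessly", {
  net <- toy_lesion_network()
  sw <- run_resistance_sweep(net)
  path <- withr::local_tempfile(fileext = ".csv")
  write_sweep_csv(list(P001 = sw), path)
  back <- read_sweep_csv(path)
  expect_equal(back$Q_bar_cm3_s, sw$Q_bar, tolerance = 1e-12)
  expect_equal(back$dp_bar_mmHg, sw$dp_bar, tolerance = 1e-12)
  expect_identical(unique(back$patient_id), "P001")
})

test_that("backflow and non-physical inputs are rejected loudly", {
  expect_error(solve_segment_network(
    data.frame(segment = "a", from = "inlet", to = "n1", f = 1, s = 0),
    data.frame(id = "o", node = "n1", resistance = 5), "inlet",
    inlet_pressure = 0, reference_pressure = 0),
    "exceed")
  expect_error(run_resistance_sweep(toy_lesion_network(),
                                    scales = c(1, 1, 0.5)),
               "distinct")
})
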