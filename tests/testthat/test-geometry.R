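test_that("segment constructor enforces the radius-profile invariants", {
  expect_s3_class(uniform_segment("a", 0.3, 2), "vessel_segment")
  expect_error(vessel_segment("a", 2, data.frame(pos = c(0, 1, 1, 2),
                                                 radius = 0.3)),
               "strictly increasing")
  expect_error(vessel_segment("a", 2, data.frame(pos = c(0, 2),
                                                 radius = c(0.3, -0.1))),
               "positive")
  expect_error(vessel_segment("a", 2, data.frame(pos = c(0.5, 2),
                                                 radius = 0.3)),
               "span")
  expect_error(vessel_segment("a", 2, data.frame(pos = c(0, 2), radius = 0.3),
                              is_lesion = TRUE, lesion_start = 1.5,
                              lesion_end = 1.0),
               "lesion")
})

test_that("viscous coefficient matches the closed-form Poiseuille integral", {
  fl <- fluid_properties()
  seg <- uniform_segment("a", 0.25, 1)
  expect_equal(segment_viscous_coefficient(seg, fl),
               8 * 3.0e-5 * 1 / (pi * 0.25^4), tolerance = 1e-12)
  # linear in length
  expect_equal(segment_viscous_coefficient(uniform_segment("b", 0.25, 2), fl),
               2 * segment_viscous_coefficient(seg, fl), tolerance = 1e-12)
  # additive over sub-segments
  expect_equal(segment_viscous_coefficient(seg, fl, 0, 0.5) +
                 segment_viscous_coefficient(seg, fl, 0.5, 1),
               segment_viscous_coefficient(seg, fl), tolerance = 1e-12)
  # tapered segment against numerical quadrature of 8 mu / (pi r(x)^4)
  tap <- vessel_segment("t", 2, data.frame(pos = c(0, 2),
                                           radius = c(0.5, 0.2)))
  r_of <- function(x) 0.5 + (0.2 - 0.5) * x / 2
  num <- stats::integrate(function(x) 8 * fl$viscosity / (pi * r_of(x)^4),
                          0, 2, rel.tol = 1e-12)$value
  expect_equal(segment_viscous_coefficient(tap, fl), num, tolerance = 1e-9)
})

test_that("narrowing rate is the diaphragm-relative diameter deficit", {
  net <- toy_lesion_network(r_ref = 0.5, r_min = 0.2, diaphragm = 1.0)
  expect_equal(narrowing_rate(net), 1 - 0.4 / 1.0, tolerance = 1e-12)
  # identity case: no caliber loss
  net0 <- toy_lesion_network(r_ref = 0.5, r_min = 0.5, diaphragm = 1.0)
  expect_equal(narrowing_rate(net0), 0)
  # scale invariance
  net_a <- toy_lesion_network(r_ref = 0.35, r_min = 0.15, diaphragm = 0.7)
  net_b <- toy_lesion_network(r_ref = 0.70, r_min = 0.30, diaphragm = 1.4)
  expect_equal(narrowing_rate(net_a), narrowing_rate(net_b),
               tolerance = 1e-12)
})

test_that("ground-truth expansion loss follows the Borda-Carnot form", {
  fl <- fluid_properties()
  net <- toy_lesion_network(r_ref = 0.7, r_min = 0.25)
  cf <- stenosis_true_coefficients(net, fl)
  expect_equal(cf$s,
               (7.95e-4 / 2) * (1 / (pi * 0.25^2) - 1 / (pi * 0.7^2))^2,
               tolerance = 1e-12)
  # no caliber change, no expansion loss
  expect_equal(stenosis_true_coefficients(
    toy_lesion_network(r_ref = 0.4, r_min = 0.4), fl)$s, 0)
  # viscous part equals the Poiseuille integral between the lesion planes
  les <- toy_lesion_network(r_ref = 0.7, r_min = 0.25)$segments$isthmus
  expect_equal(cf$f,
               segment_viscous_coefficient(les, fl, 0.5, 1.5),
               tolerance = 1e-12)
  # monotone in severity, independent of any flow or pressure argument
  s_of <- vapply(c(0.35, 0.3, 0.25, 0.2, 0.15), function(rm)
    stenosis_true_coefficients(toy_lesion_network(r_min = rm, r_ref = 0.4),
                               fl)$s, 0)
  expect_true(all(diff(s_of) > 0))
})

test_that("network constructor rejects malformed topologies", {
  good <- toy_lesion_network()
  expect_s3_class(good, "aorta_network")
  # three outlets only
  expect_error(aorta_network(good$segments, good$connections, "inlet",
                             good$outlets[1:3, ], 0.7),
               "four outlet")
  # two lesions
  segs <- good$segments
  segs$asc <- vessel_segment("asc", 3, data.frame(pos = c(0, 3), radius = 0.5),
                             is_lesion = TRUE, lesion_start = 1,
                             lesion_end = 2)
  expect_error(aorta_network(segs, good$connections, "inlet", good$outlets,
                             0.7),
               "exactly one lesion")
  # disconnected segment
  con <- good$connections
  con$from[3] <- "nowhere"
  expect_error(aorta_network(good$segments, con, "inlet", good$outlets, 0.7),
               "tree|connected")
})

test_that("geometry JSON round-trips through the reader", {
  net <- toy_lesion_network()
  path <- withr::local_tempfile(fileext = ".json")
  write_aorta_network(net, path)
  back <- read_aorta_network(path)
  expect_equal(back$connections, net$connections)
  expect_equal(back$outlets$diameter, net$outlets$diameter)
  expect_equal(narrowing_rate(back), narrowing_rate(net), tolerance = 1e-12)
  expect_equal(stenosis_true_coefficients(back)$s,
               stenosis_true_coefficients(net)$s, tolerance = 1e-12)
  # schema is checked
  writeLines('{"schema":"something-else/9"}', path)
  expect_error(read_aorta_network(path), "schema")
})
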