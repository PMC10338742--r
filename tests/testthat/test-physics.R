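test_that("stopping-power transcription reproduces the published reference-depth values", {
  # gate: the two-variable rational fit, evaluated along the reference
  # depth z_ref = 0.6 R50 - 0.1, must agree with the independently
  # published closed-form fit of s_w,air(z_ref) to better than 0.25%
  r50 <- seq(2.40, 8.82, length.out = 20)
  got <- vapply(r50, function(r)
    stopping_power_ratio(reference_depth(r), r), numeric(1))
  want <- oracle_sp_at_zref(r50)
  expect_lt(max(abs(got / want - 1)), 0.0025)
})

test_that("stopping-power ratio rises with depth and enforces its validity window", {
  r50 <- 4.0
  z <- seq(0.02, 1.2, length.out = 60) * r50
  s <- stopping_power_ratio(z, r50)
  expect_true(all(diff(s) > 0))
  expect_gt(stopping_power_ratio(3.0, r50),
            stopping_power_ratio(1.0, r50))
  expect_error(stopping_power_ratio(1.3 * r50, r50), "1.2")
  expect_error(stopping_power_ratio(0.01 * r50, r50), "0.02")
  # agreement with the independently typed formula over a 2-D grid
  for (r in c(2.4, 5, 8.82)) {
    zz <- seq(0.05, 1.15, by = 0.1) * r
    expect_equal(stopping_power_ratio(zz, r), oracle_sp(zz, r),
                 tolerance = 1e-12)
  }
})

test_that("I50 to R50 protocol conversion", {
  expect_equal(i50_to_r50(5.0), 1.029 * 5.0 - 0.06)
  expect_equal(i50_to_r50(5.0), 5.085)
  # the two branches at the 10 cm boundary differ by a known small jump
  jump <- (1.059 * 10 - 0.37) - (1.029 * 10 - 0.06)
  expect_equal(jump, -0.01, tolerance = 1e-12)
  i <- seq(1, 15, by = 0.5)
  expect_true(all(diff(i50_to_r50(i)) > 0))
  expect_error(i50_to_r50(-1), "positive")
})

test_that("R50 extraction: linear crossing, scale invariance, dense-grid oracle", {
  z <- seq(0, 6, by = 0.1)
  v <- ifelse(z <= 2, 100, 100 * (6 - z) / 4)   # plateau, then linear to 0
  cv <- depth_curve(z, v, "dose")
  expect_equal(compute_r50(cv), 4.0, tolerance = 1e-9)
  cv$values <- 0.37 * cv$values
  expect_equal(compute_r50(cv), 4.0, tolerance = 1e-9)

  beam <- demo_beam()
  pdd <- epomfit:::.pdd_fun(beam)
  z2 <- seq(0, round(1.3 * beam$rp, 2), by = 0.1)
  sampled <- depth_curve(z2, pdd(z2), "dose")
  dense <- seq(beam$zmax, beam$rp, by = 0.001)
  oracle <- dense[which.min(abs(pdd(dense) - 50))]
  expect_lt(abs(compute_r50(sampled) - oracle), 0.005)

  expect_error(compute_r50(depth_curve(1:4, c(90, 100, 95, 80), "dose")),
               "crossing")
  expect_error(compute_r50(depth_curve(1:4, c(90, 100, 95, 80),
                                       "ionization")), "dose")
})

test_that("PDI to PDD conversion: stub identity, hand arithmetic, monotone-ratio property", {
  z <- seq(0.5, 4.5, by = 1)
  pdi <- depth_curve(z, c(80, 100, 90, 50, 20), "ionization")
  unit <- pdi_to_pdd(pdi, r50 = 4.0, sp_fun = function(z, r50) rep(1, length(z)))
  expect_identical(unit$quantity, "dose")
  expect_equal(unit$values, 100 * pdi$values / max(pdi$values),
               tolerance = 1e-12)

  # end-to-end equals pointwise hand multiplication on the 5-point toy
  s <- stopping_power_ratio(z, 4.0)
  hand <- c(80, 100, 90, 50, 20) * s
  hand <- 100 * hand / max(hand)
  expect_equal(pdi_to_pdd(pdi, 4.0)$values, hand, tolerance = 1e-12)

  # since s increases with depth, the dose maximum cannot move shallower
  pdd <- pdi_to_pdd(pdi, 4.0)
  expect_gte(pdd$depths[which.max(pdd$values)],
             pdi$depths[which.max(pdi$values)])

  # prescaling the ionization curve changes nothing after renormalization
  pdi2 <- pdi; pdi2$values <- 42 * pdi$values
  expect_equal(pdi_to_pdd(pdi2, 4.0)$values, pdd$values, tolerance = 1e-12)

  deep <- depth_curve(c(0.5, 1, 2, 5.2), c(100, 90, 70, 5), "ionization")
  expect_error(pdi_to_pdd(deep, 4.0), "5.2")
})

test_that("reference depth is the protocol affine map of R50", {
  expect_equal(reference_depth(4.0), 2.3)
  expect_equal(reference_depth(2.40), 1.34)
  r <- c(2, 5, 8)
  expect_equal(reference_depth(r), 0.6 * r - 0.1)
  expect_error(reference_depth(0.1), "nonpositive")
})

test_that("beam-quality extraction is self-consistent under R50 perturbation", {
  beam <- demo_beam()
  ref <- demo_ref(beam)
  truth <- synthetic_truth(0, noise_sigma = 0, seed = 1,
                           sp_convention = "nominal")
  pdi <- correct_scan(make_chamber_scan(ref, truth, beam))$curve
  # trim so the depths stay inside the validity window for every
  # perturbed R50 below
  keep <- pdi$depths >= 0.03 * beam$r50 & pdi$depths <= 1.17 * beam$r50
  pdi <- depth_curve(pdi$depths[keep], pdi$values[keep], "ionization")
  r50_hat <- compute_r50(pdi_to_pdd(pdi, beam$r50))
  for (f in c(0.98, 1.02)) {
    r50_f <- compute_r50(pdi_to_pdd(pdi, beam$r50 * f))
    expect_lt(abs(r50_f / r50_hat - 1), 0.005)
  }
  # fixed-point route lands near the true beam quality
  expect_lt(abs(r50_from_ionization(pdi) - beam$r50), 0.02)
})

test_that("beam spec warns outside the validated R50 range", {
  expect_silent(beam_spec("12 MeV", 4.97))
  expect_warning(beam_spec("4 MeV", 1.6), "2.4")
  expect_error(beam_spec("x", -1), "positive")
})
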