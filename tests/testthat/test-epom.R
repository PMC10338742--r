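test_that("objective vanishes for an exactly matching construction", {
  beam <- demo_beam()
  ref <- demo_ref(beam)
  z <- ref$depths[ref$depths >= 0.3 & ref$depths <= 1.1 * beam$r50]
  det <- depth_curve(z, resample_curve(ref, z) /
                          stopping_power_ratio(z, beam$r50), "ionization")
  o <- epom_rms(ref, det, dz = 0, r50 = beam$r50)
  expect_lt(o$rms, 1e-8)
  expect_gte(o$n, 10)
})

test_that("hand-computed toy objective", {
  # residuals (2, 0, 2, 0) over four points -> rms = sqrt(8/4)
  ref <- depth_curve(1:4, c(90, 100, 60, 30), "dose")
  det <- depth_curve(1:4, c(92, 100, 58, 30), "dose")
  cfg <- epom_config(min_points = 2)
  o <- epom_rms(ref, det, dz = 0, r50 = 4.0, config = cfg)
  expect_equal(o$rms^2, (4 + 0 + 4 + 0) / 4, tolerance = 1e-12)
  expect_equal(o$n, 4L)
  # too few usable points is an error under the default minimum
  expect_error(epom_rms(ref, det, dz = 0, r50 = 4.0), "usable")
})

test_that("grid argmin equals an independent brute-force enumeration", {
  for (seed in 1:10) {
    case <- random_case(seed)
    fit <- fit_epom(case$ref, case$det, r50 = case$r50)
    bf <- brute_epom(case$ref, case$det, case$r50)
    expect_equal(fit$dz_opt, bf$dz_opt,
                 info = sprintf("seed %d (r50 %.2f)", seed, case$r50))
    expect_equal(fit$n_points, bf$n)
  }
})

test_that("zero-shift and on-grid truths are recovered exactly", {
  beam <- demo_beam()
  ref <- demo_ref(beam)
  z <- ref$depths[ref$depths >= 0.3 & ref$depths <= 1.1 * beam$r50]
  det0 <- depth_curve(z, resample_curve(ref, z) /
                           stopping_power_ratio(z, beam$r50), "ionization")
  expect_equal(fit_epom(ref, det0, beam$r50)$dz_opt, 0)

  truth <- synthetic_truth(0.07, noise_sigma = 0, seed = 3)
  det <- correct_scan(make_chamber_scan(ref, truth, beam))$curve
  fit <- fit_epom(ref, det)
  expect_equal(fit$dz_opt, 0.07)
  expect_true(fit$unimodal)
  expect_equal(fit$rms_min, min(fit$grid$rms, na.rm = TRUE))
  expect_true(fit$dz_opt %in% fit$grid$dz)
})

test_that("shift equivariance and scale invariance", {
  beam <- demo_beam()
  ref <- demo_ref(beam)
  truth <- synthetic_truth(0.04, noise_sigma = 0, seed = 5)
  det <- correct_scan(make_chamber_scan(ref, truth, beam))$curve
  base <- fit_epom(ref, det)$dz_opt

  # displacing the chamber depth axis by +delta moves the optimum by -delta
  delta <- 0.03
  shifted <- depth_curve(det$depths + delta, det$values, "ionization")
  moved <- fit_epom(ref, shifted)$dz_opt
  expect_lte(abs((moved - base) + delta), 0.01 + 1e-9)

  # multiplying the readings by a constant changes nothing
  scaled <- depth_curve(det$depths, 13.7 * det$values, "ionization")
  expect_equal(fit_epom(ref, scaled)$dz_opt, base)
})

test_that("exact ties break toward the smallest shift", {
  z <- seq(0.1, 5, by = 0.1)
  flat_ref <- depth_curve(z, rep(100, length(z)), "dose")
  flat_det <- depth_curve(z, rep(70, length(z)), "dose")
  fit <- fit_epom(flat_ref, flat_det, r50 = 4.0)
  expect_equal(fit$dz_opt, 0)
  expect_equal(fit$rms_min, 0)
})

test_that("energy table is sorted by beam quality and reports the spread", {
  beams <- lapply(c(`6` = 2.40, `18` = 7.37), synthetic_beam)
  fits <- lapply(list(`18` = list(b = beams[["18"]], dz = 0.12),
                      `6` = list(b = beams[["6"]], dz = 0.09)),
                 function(x) {
    ref <- demo_ref(x$b)
    truth <- synthetic_truth(x$dz, noise_sigma = 0, seed = 2)
    fit_epom(ref, correct_scan(make_chamber_scan(ref, truth, x$b))$curve)
  })
  tab <- epom_vs_energy(fits)
  expect_equal(tab$energy, c("6", "18"))      # sorted by r50, not insertion
  expect_true(all(diff(tab$r50) > 0))
  expect_equal(attr(tab, "spread"), 0.03, tolerance = 1e-9)

  # plain arithmetic on sub-grid shifts: min at 6 MeV, max at 18 MeV
  hand <- list(`6` = list(dz_opt = 0.09, r50_used = 2.40),
               `18` = list(dz_opt = 0.116, r50_used = 7.37))
  expect_equal(attr(epom_vs_energy(hand), "spread"), 0.026,
               tolerance = 1e-12)

  same <- epom_vs_energy(list(a = fits[[1]], b = fits[[1]]))
  expect_equal(attr(same, "spread"), 0)
  expect_error(epom_vs_energy(fits[1]), "2")
})

test_that("fit object methods report the estimate coherently", {
  beam <- demo_beam()
  ref <- demo_ref(beam)
  truth <- synthetic_truth(0.10, noise_sigma = 0, seed = 9)
  fit <- fit_epom(ref, correct_scan(make_chamber_scan(ref, truth, beam))$curve)
  expect_equal(unname(coef(fit)), fit$dz_opt)
  expect_length(residuals(fit), fit$n_points)
  expect_equal(sqrt(mean(residuals(fit)^2)), fit$rms_min, tolerance = 1e-12)
  expect_output(print(fit), "dz_opt")
  expect_output(print(summary(fit)), "unimodal")
})
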