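# Shared fixtures and independent oracles.

demo_beam <- function(r50 = 4.97) synthetic_beam(r50)

demo_ref <- function(beam = demo_beam(), step = 0.02) {
  make_reference_pdd(beam, seq(0, round(1.3 * beam$rp, 2), by = step))
}

# Independently re-typed rational stopping-power fit (same published
# coefficients, written out separately from the package source).
oracle_sp <- function(z, r50) {
  x <- log(r50); y <- z / r50
  num <- 1.0752 - 0.50867 * x + 0.08867 * x^2 - 0.08402 * y
  den <- 1 - 0.42806 * x + 0.064627 * x^2 + 0.003085 * x^3 - 0.12460 * y
  num / den
}

# Published closed-form value of s_w,air at the electron reference depth
# z_ref = 0.6 R50 - 0.1, fitted independently of the two-variable rational
# fit; serves as the transcription (anti-typo) gate.
oracle_sp_at_zref <- function(r50) 1.2534 - 0.1487 * r50^0.2144

# Plain-loop brute-force enumeration of the RMS objective and its argmin,
# written independently of the package internals.  `det` is an ionization
# curve; the stopping-power ratio is applied at z + dz (shifted convention).
brute_epom <- function(ref, det, r50, dz_min = -0.10, dz_max = 0.20,
                       dz_step = 0.01, eval_z_min = 0.1,
                       eval_zr_max = 1.2) {
  grid <- round(seq(dz_min, dz_max, by = dz_step), 10)
  lo <- max(eval_z_min, 0.02 * r50 - dz_min, min(ref$depths) - dz_min)
  hi <- min(eval_zr_max * r50, 1.2 * r50 - dz_max,
            max(ref$depths) - dz_max)
  pts <- det$depths[det$depths >= lo - 1e-9 & det$depths <= hi + 1e-9]
  refv <- 100 * ref$values / max(ref$values)
  rf <- stats::splinefun(ref$depths, refv, method = "monoH.FC")
  dv <- stats::splinefun(det$depths, det$values, method = "monoH.FC")(pts)
  rms <- numeric(length(grid))
  for (j in seq_along(grid)) {
    dz <- grid[j]
    conv <- oracle_sp(pts + dz, r50) * dv
    conv <- 100 * conv / max(conv)
    acc <- 0
    for (i in seq_along(pts)) acc <- acc + (rf(pts[i] + dz) - conv[i])^2
    rms[j] <- sqrt(acc / length(pts))
  }
  cand <- which(rms == min(rms))
  list(dz_opt = grid[cand[which.min(abs(grid[cand]))]], rms = rms,
       grid = grid, n = length(pts))
}

# one random synthetic case: beam, reference, noise-free or noisy scan
random_case <- function(seed) {
  set.seed(seed)
  r50 <- runif(1, 2.4, 8.82)
  dz_true <- round(runif(1, -0.05, 0.15), 2)
  beam <- synthetic_beam(r50)
  ref <- make_reference_pdd(beam, seq(0, round(1.3 * beam$rp, 2),
                                      by = 0.02))
  truth <- synthetic_truth(dz_true, noise_sigma = sample(c(0, 0.003), 1),
                           seed = seed + 1000L)
  det <- suppressWarnings(
    correct_scan(make_chamber_scan(ref, truth, beam))$curve)
  list(beam = beam, ref = ref, det = det, dz_true = dz_true, r50 = r50)
}
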