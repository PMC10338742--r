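# Synthetic electron-beam depth-dose curves and raw chamber scans with
# known ground truth.  The generator inverts the analysis chain: the ideal
# chamber signal is the reference dose at the shifted (effective) depth
# divided by the stopping-power ratio, and the raw electrometer channels
# are constructed so that the two-voltage and polarity corrections invert
# them exactly.

.with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit(if (had) assign(".Random.seed", old, envir = globalenv())
          else if (exists(".Random.seed", envir = globalenv(),
                          inherits = FALSE))
            rm(".Random.seed", envir = globalenv()))
  set.seed(seed)
  expr
}

#' Synthetic electron beam
#'
#' Parameterizes the analytic depth-dose family used by
#' [make_reference_pdd()]: a smooth build-up from `surface_frac` of the
#' maximum at the surface to 100 at `zmax`, a gently rounded shoulder, a
#' logistic distal falloff calibrated to cross exactly 50 at `r50`, and a
#' low bremsstrahlung tail of relative amplitude `tail_frac` beyond the
#' practical range `rp`.
#'
#' Defaults scale with beam quality the way clinical beams do:
#' `rp = 1.271 r50 - 0.23` cm, `zmax = min(0.55 r50, 3)` cm,
#' `surface_frac = min(0.74 + 0.025 r50, 0.97)`,
#' `tail_frac = min(0.005 r50, 0.09)`.
#'
#' @param r50 Half-value depth, cm.
#' @param rp Practical range, cm (`> r50`).
#' @param zmax Depth of dose maximum, cm (`0 < zmax < r50`).
#' @param surface_frac Surface dose as a fraction of the maximum, in (0,1).
#' @param tail_frac Bremsstrahlung-tail fraction, in [0, 0.1).
#' @param shoulder_frac Quadratic shoulder decline between `zmax` and the
#'   falloff, as a fraction of the maximum per `(z/r50)^2` (default 0.25).
#' @return A `synthetic_beam` list.
#' @export
synthetic_beam <- function(r50, rp = NULL, zmax = NULL,
                           surface_frac = NULL, tail_frac = NULL,
                           shoulder_frac = 0.25) {
  if (is.null(rp)) rp <- 1.271 * r50 - 0.23
  if (is.null(zmax)) zmax <- min(0.55 * r50, 3.0)
  if (is.null(surface_frac)) surface_frac <- min(0.74 + 0.025 * r50, 0.97)
  if (is.null(tail_frac)) tail_frac <- min(0.005 * r50, 0.09)
  if (!(zmax > 0 && zmax < r50 && r50 < rp))
    stop("need 0 < zmax < r50 < rp", call. = FALSE)
  if (!(surface_frac > 0 && surface_frac < 1))
    stop("`surface_frac` must be in (0, 1)", call. = FALSE)
  if (!(tail_frac >= 0 && tail_frac < 0.1))
    stop("`tail_frac` must be in [0, 0.1)", call. = FALSE)
  structure(list(r50 = r50, rp = rp, zmax = zmax,
                 surface_frac = surface_frac, tail_frac = tail_frac,
                 shoulder_frac = shoulder_frac),
            class = "synthetic_beam")
}

#' Default study beams
#'
#' The four clinical electron energies of a modern linac, with typical
#' beam qualities: 6, 12, 18, 22 MeV at R50 = 2.40, 4.97, 7.37, 8.82 cm.
#' The lowest and highest anchor the validated R50 range of the shipped
#' chamber-shift results.
#'
#' @return Named list of [synthetic_beam()] objects.
#' @export
electron_beams <- function() {
  r50 <- c(`6` = 2.40, `12` = 4.97, `18` = 7.37, `22` = 8.82)
  lapply(r50, synthetic_beam)
}

# analytic PDD evaluator for a synthetic beam; exact properties:
# value 100*surface_frac at z = 0, maximum 100 at zmax, crosses 50 at r50
.pdd_fun <- function(beam) {
  r50 <- beam$r50; rp <- beam$rp; zmax <- beam$zmax
  sf <- beam$surface_frac; tf <- beam$tail_frac; q <- beam$shoulder_frac
  k <- 6 / (rp - r50)

  shoulder <- function(z) 1 - q * (pmax(z - zmax, 0) / r50)^2
  # calibrate the logistic center so the total crosses exactly 50 at r50
  cc <- 0.5 / shoulder(r50)
  arg <- cc - exp(-k * (r50 - zmax))
  if (arg <= 0)
    stop("falloff too shallow to place the 50% level at r50", call. = FALSE)
  z0 <- (k * r50 + log(arg) - log(1 - cc)) / k
  l0 <- stats::plogis(-k * (zmax - z0))
  fall <- function(z) stats::plogis(-k * (z - z0)) / l0

  tail_amp <- 100 * tf
  tail <- function(z) {
    t <- pmin(pmax((z - r50) / (rp - r50), 0), 1)
    ramp <- t * t * (3 - 2 * t)
    ifelse(z <= rp, tail_amp * ramp,
           tail_amp * pmax(1 - 0.05 * (z - rp), 0))
  }

  function(z) {
    up <- pmin(pmax(z / zmax, 0), 1)
    build <- sf + (1 - sf) * up * up * (3 - 2 * up)
    ifelse(z < zmax,
           100 * build,
           100 * fall(z) * shoulder(z) + tail(z))
  }
}

#' Generate a synthetic reference depth-dose curve
#'
#' Evaluates the analytic PDD of a [synthetic_beam()] on the given depths.
#' Stands in for an energy-independent reference detector: by construction
#' the curve is 100 at `zmax`, `100 * surface_frac` at the surface, and
#' crosses 50 exactly at `r50` (so [compute_r50()] recovers `beam$r50` on
#' a dense grid).
#'
#' @param beam A [synthetic_beam()].
#' @param depths Depths in cm; must span at least `[0.05, 1.25 * r50]`.
#' @return A [depth_curve()] with `quantity = "dose"`.
#' @export
make_reference_pdd <- function(beam, depths) {
  if (!inherits(beam, "synthetic_beam"))
    stop("`beam` must be a `synthetic_beam`", call. = FALSE)
  if (min(depths) > 0.05 || max(depths) < 1.25 * beam$r50)
    stop(sprintf("depths must span at least [0.05, %.3g] cm",
                 1.25 * beam$r50), call. = FALSE)
  depth_curve(depths, .pdd_fun(beam)(depths), "dose",
              meta = list(detector = "synthetic-reference",
                          r50_true = beam$r50))
}

#' Ground truth for a synthetic chamber scan
#'
#' @param dz_true True EPOM shift, cm (positive: toward the cavity).
#' @param noise_sigma Relative (multiplicative Gaussian) noise per raw
#'   channel; default 0.3%, the repeatability of a scanning system.
#' @param seed Integer seed; identical seeds give identical datasets.
#' @param ks_profile,kpol_profile Slowly varying depth profiles of the
#'   recombination and polarity corrections, as functions of depth (cm).
#' @param v1,v2 Polarizing voltages of the two-voltage method, volts.
#'   The default ratio V1/V2 = 2 is an assumption, not a measured setting.
#' @param sp_convention Depth convention the generator uses for the
#'   stopping-power division: `"shifted"` (at `z + dz_true`) or
#'   `"nominal"` (at `z`).  Match it to the analysis convention for exact
#'   round trips.
#' @return A `synthetic_truth` list.
#' @export
synthetic_truth <- function(dz_true, noise_sigma = 0.003, seed = 1L,
                            ks_profile = function(z) 1.002 + 4e-4 * z,
                            kpol_profile = function(z) 0.997 + 6e-4 * z,
                            v1 = 400, v2 = 200,
                            sp_convention = c("shifted", "nominal")) {
  sp_convention <- match.arg(sp_convention)
  if (noise_sigma < 0) stop("`noise_sigma` must be >= 0", call. = FALSE)
  structure(list(dz_true = dz_true, noise_sigma = noise_sigma,
                 seed = as.integer(seed), ks_profile = ks_profile,
                 kpol_profile = kpol_profile, v1 = v1, v2 = v2,
                 sp_convention = sp_convention),
            class = "synthetic_truth")
}

# invert the pulsed-beam quadratic: reading ratio r = m1/m2 giving ks
.ks_to_ratio <- function(ks, v1, v2) {
  tab <- ks_coefficients()
  i <- which(abs(v1 / v2 - tab$ratio) / tab$ratio < 1e-3)
  if (length(i) != 1L) stop("unsupported voltage ratio", call. = FALSE)
  disc <- tab$a1[i]^2 - 4 * tab$a2[i] * (tab$a0[i] - ks)
  if (any(disc < 0)) stop("ks not reachable for this voltage ratio",
                          call. = FALSE)
  (-tab$a1[i] + sqrt(disc)) / (2 * tab$a2[i])
}

#' Generate a raw synthetic chamber scan
#'
#' The ideal chamber signal at nominal depth `z` is
#' `M(z) = D_ref(z + dz_true) / s_w,air(z*, r50)` with `z* = z + dz_true`
#' under the shifted convention (`z` under nominal).  Raw channels are
#' built so the corrections invert exactly: `m_v1 = M / (ks(z) kpol(z))`,
#' `m_v2` from the two-voltage quadratic consistent with `ks(z)`, and the
#' polarity pair consistent with `kpol(z)` (with `m_pos = m_v1`, the
#' routine polarity).  Multiplicative Gaussian noise of relative width
#' `noise_sigma` is then applied independently per channel under the
#' truth's seed.
#'
#' Nominal depths run on a regular grid of `grid_step`, restricted so that
#' `z + dz_true` stays inside both the reference support and the
#' stopping-power validity window.
#'
#' @param ref Reference [depth_curve()] (`"dose"`).
#' @param truth A [synthetic_truth()].
#' @param beam The [synthetic_beam()] the reference was generated from
#'   (supplies `r50`).
#' @param grid_step Scan step, cm (>= 0.01; default 0.1, the usual
#'   water-tank step).
#' @return A [raw_depth_readings()] object.
#' @export
make_chamber_scan <- function(ref, truth, beam, grid_step = 0.1) {
  stopifnot_quantity(ref, "dose")
  if (!inherits(truth, "synthetic_truth"))
    stop("`truth` must be a `synthetic_truth`", call. = FALSE)
  if (grid_step < 0.01) stop("`grid_step` must be >= 0.01 cm", call. = FALSE)
  r50 <- beam$r50
  dz <- truth$dz_true
  w <- burns_coefficients()$zr_window
  # the stopping-power argument (z + dz under the shifted convention, z
  # under nominal) and the sampled reference depth z + dz must both stay
  # inside their supports
  sp_off <- if (truth$sp_convention == "shifted") dz else 0
  z_lo <- max(0.1, w[1L] * r50 - sp_off + 1e-9, min(ref$depths) - dz)
  z_hi <- min(w[2L] * r50 - sp_off - 1e-9, max(ref$depths) - dz)
  grid <- seq(ceiling(z_lo / grid_step) * grid_step,
              floor(z_hi / grid_step) * grid_step, by = grid_step)
  grid <- round(grid, 10)
  if (length(grid) < 4L)
    stop("reference support / validity window leave too few scan depths",
         call. = FALSE)
  zs <- if (truth$sp_convention == "shifted") grid + dz else grid
  M <- resample_curve(ref, grid + dz) / stopping_power_ratio(zs, r50)
  ks <- truth$ks_profile(grid)
  kpol <- truth$kpol_profile(grid)
  m_v1 <- M / (ks * kpol)
  m_v2 <- m_v1 / .ks_to_ratio(ks, truth$v1, truth$v2)
  m_pos <- m_v1
  m_neg <- -m_v1 * (2 * kpol - 1)
  if (truth$noise_sigma > 0) {
    n <- length(grid)
    .with_seed(truth$seed, {
      m_v1 <- m_v1 * (1 + stats::rnorm(n, 0, truth$noise_sigma))
      m_v2 <- m_v2 * (1 + stats::rnorm(n, 0, truth$noise_sigma))
      m_pos <- m_pos * (1 + stats::rnorm(n, 0, truth$noise_sigma))
      m_neg <- m_neg * (1 + stats::rnorm(n, 0, truth$noise_sigma))
    })
  }
  raw_depth_readings(grid, m_v1, m_v2, m_pos, m_neg,
                     v1 = truth$v1, v2 = truth$v2)
}

#' Configuration of a synthetic chamber study
#'
#' Defaults mirror a full experimental campaign: three chamber types with
#' three serial numbers each, four energies, three repeat sessions per
#' scan, 0.1 cm chamber scan step, 0.3% channel noise.  The type-level
#' true shifts default to the established experimental values for NACP-02,
#' Roos and Advanced Markus (0.104, 0.040, 0.012 cm), with per-type
#' energy spreads 0.026, 0.020, 0.021 cm distributed as minimum at 6 MeV
#' and maximum at 18 MeV, and serial-to-serial variation of SD 0.005 cm.
#'
#' @param chambers Chamber type names.
#' @param type_means True type-level mean shifts, cm (one per chamber).
#' @param energy_spreads Max-minus-min of the per-energy true shifts, cm.
#' @param serial_sd SD of the serial-level offsets, cm.
#' @param n_serials,n_sessions Serial numbers per type, sessions per scan.
#' @param energies Data frame `label`, `r50` of the beams.
#' @param noise_sigma Relative channel noise per session.
#' @param grid_step,ref_step Chamber and reference scan steps, cm.
#' @param v1,v2 Polarizing voltages, volts.
#' @param seed Master seed; every scan derives its own sub-seed from it.
#' @return A `study_config` list.
#' @export
study_config <- function(chambers = c("NACP-02", "Roos", "Advanced Markus"),
                         type_means = c(0.104, 0.040, 0.012),
                         energy_spreads = c(0.026, 0.020, 0.021),
                         serial_sd = 0.005,
                         n_serials = 3L, n_sessions = 3L,
                         energies = data.frame(
                           label = c("6", "12", "18", "22"),
                           r50 = c(2.40, 4.97, 7.37, 8.82)),
                         noise_sigma = 0.003,
                         grid_step = 0.1, ref_step = 0.02,
                         v1 = 400, v2 = 200, seed = 1L) {
  if (length(type_means) != length(chambers) ||
      length(energy_spreads) != length(chambers))
    stop("`type_means` and `energy_spreads` must match `chambers`",
         call. = FALSE)
  structure(list(chambers = chambers, type_means = type_means,
                 energy_spreads = energy_spreads, serial_sd = serial_sd,
                 n_serials = as.integer(n_serials),
                 n_sessions = as.integer(n_sessions), energies = energies,
                 noise_sigma = noise_sigma, grid_step = grid_step,
                 ref_step = ref_step, v1 = v1, v2 = v2,
                 seed = as.integer(seed)),
            class = "study_config")
}

# energy-offset pattern: zero mean, unit max-minus-min, minimum at the
# first (lowest) energy and maximum at the third, as observed for all
# chamber types
.energy_pattern <- function(n) {
  base <- c(-0.55, -0.05, 0.45, 0.15)
  if (n == 4L) base else {
    p <- base[seq_len(min(n, 4L))]
    if (n > 4L) p <- c(p, rep(0.1, n - 4L))
    p - mean(p)
  }
}

.sub_seed <- function(seed, k) as.integer((as.numeric(seed) * 7919 + k) %%
                                            2147483647)

#' Write a full synthetic study to disk
#'
#' Generates a complete measurement campaign under a [study_config()]:
#' one dense reference PDD per energy, `n_sessions` raw chamber scans per
#' (chamber type, serial, energy), a `manifest.json` describing the inputs
#' (files, voltages, energies) for [run_study()], and a `truth.json`
#' recording every true shift for validation.  All files are plain CSV
#' with JSON sidecars; regeneration with the same config is byte-identical.
#'
#' @param dir Output directory (created if needed).
#' @param config A [study_config()].
#' @return `dir`, invisibly.  Side effect: files written.
#' @export
make_study_fixture <- function(dir, config = study_config()) {
  cfg <- config
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  beams <- lapply(cfg$energies$r50, synthetic_beam)
  names(beams) <- cfg$energies$label

  refs <- character(0)
  for (i in seq_along(beams)) {
    b <- beams[[i]]
    depths <- seq(0, round(1.3 * b$rp, 2), by = cfg$ref_step)
    ref <- make_reference_pdd(b, depths)
    f <- sprintf("ref_%s.csv", cfg$energies$label[i])
    write_scan(ref, file.path(dir, f))
    refs[cfg$energies$label[i]] <- f
  }

  n_e <- nrow(cfg$energies)
  pattern <- .energy_pattern(n_e)
  serial_off <- .with_seed(cfg$seed,
    matrix(stats::rnorm(length(cfg$chambers) * cfg$n_serials,
                        0, cfg$serial_sd),
           nrow = length(cfg$chambers)))

  scans <- list(); truths <- list(); k <- 0L
  for (ci in seq_along(cfg$chambers)) {
    for (si in seq_len(cfg$n_serials)) {
      for (ei in seq_len(n_e)) {
        dz_true <- cfg$type_means[ci] + serial_off[ci, si] +
          pattern[ei] * cfg$energy_spreads[ci]
        b <- beams[[ei]]
        depths <- seq(0, round(1.3 * b$rp, 2), by = cfg$ref_step)
        ref <- make_reference_pdd(b, depths)
        slug <- gsub("[^A-Za-z0-9]+", "-", tolower(cfg$chambers[ci]))
        for (sess in seq_len(cfg$n_sessions)) {
          k <- k + 1L
          tr <- synthetic_truth(dz_true, cfg$noise_sigma,
                                seed = .sub_seed(cfg$seed, k),
                                v1 = cfg$v1, v2 = cfg$v2)
          raw <- make_chamber_scan(ref, tr, b, cfg$grid_step)
          f <- sprintf("scan_%s_S%d_%s_sess%d.csv", slug, si,
                       cfg$energies$label[ei], sess)
          write_scan(raw, file.path(dir, f))
          scans[[length(scans) + 1L]] <- list(
            file = f, chamber = cfg$chambers[ci],
            serial = sprintf("S%d", si),
            energy = cfg$energies$label[ei], session = sess)
        }
        truths[[length(truths) + 1L]] <- list(
          chamber = cfg$chambers[ci], serial = sprintf("S%d", si),
          energy = cfg$energies$label[ei], dz_true = dz_true)
      }
    }
  }

  manifest <- list(
    energies = data.frame(label = cfg$energies$label,
                          r50_nominal = cfg$energies$r50,
                          ref = unname(refs[cfg$energies$label])),
    scans = do.call(rbind, lapply(scans, as.data.frame)),
    v1 = cfg$v1, v2 = cfg$v2)
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, dataframe = "rows")
  truth <- list(seed = cfg$seed, noise_sigma = cfg$noise_sigma,
                type_means = stats::setNames(as.list(cfg$type_means),
                                             cfg$chambers),
                shifts = do.call(rbind, lapply(truths, as.data.frame)))
  jsonlite::write_json(truth, file.path(dir, "truth.json"),
                       auto_unbox = TRUE, digits = NA, dataframe = "rows")
  invisible(dir)
}
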