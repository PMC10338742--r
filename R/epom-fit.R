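# Core estimator: grid search for the effective-point-of-measurement shift
# dz that minimizes the RMS deviation between the reference depth-dose
# curve sampled at z + dz and the stopping-power-converted chamber curve
# at the nominal scan depths z.

#' Fit configuration for the EPOM grid search
#'
#' @param dz_min,dz_max Search interval for the shift, cm.  The default
#'   -0.10 to +0.20 cm brackets every published plane-parallel EPOM shift
#'   with margin.
#' @param dz_step Grid step, cm (default 0.01 cm, the resolution at which
#'   shifts are conventionally reported).
#' @param eval_z_min Shallow end of the evaluation window on the nominal
#'   chamber depths, cm (default 0.1 cm below the phantom surface).
#' @param eval_zr_max Deep end of the window as a fraction of R50 (default
#'   1.2; beyond it the bremsstrahlung tail dominates and the
#'   stopping-power fit is no longer valid).
#' @param sp_convention Depth at which the stopping-power ratio is
#'   evaluated: `"shifted"` (at `z + dz`, the effective depth -- the
#'   default, since the ratio should reflect the electron spectrum at the
#'   point the reading represents) or `"nominal"` (at the scan depth `z`,
#'   equivalent to converting the PDI once before fitting).
#' @param amplitude `"normalize_max"` (both curves normalized to 100 at
#'   their maximum, the standard relative-dosimetry convention) or
#'   `"fit_scale"` (a per-shift least-squares scale factor, which avoids
#'   pinning the comparison to a single point).
#' @param min_points Minimum number of evaluation points (default 10).
#' @param sp_fun Stopping-power-ratio function `f(z, r50)`; defaults to
#'   [stopping_power_ratio()].
#' @return An `epom_config` list.
#' @export
epom_config <- function(dz_min = -0.10, dz_max = 0.20, dz_step = 0.01,
                        eval_z_min = 0.1, eval_zr_max = 1.2,
                        sp_convention = c("shifted", "nominal"),
                        amplitude = c("normalize_max", "fit_scale"),
                        min_points = 10L,
                        sp_fun = stopping_power_ratio) {
  sp_convention <- match.arg(sp_convention)
  amplitude <- match.arg(amplitude)
  if (dz_step <= 0) stop("`dz_step` must be positive", call. = FALSE)
  if (dz_min >= dz_max) stop("need dz_min < dz_max", call. = FALSE)
  if (eval_z_min < 0) stop("`eval_z_min` must be >= 0", call. = FALSE)
  if (eval_zr_max > 1.2)
    stop("`eval_zr_max` cannot exceed the stopping-power validity limit 1.2",
         call. = FALSE)
  structure(list(dz_min = dz_min, dz_max = dz_max, dz_step = dz_step,
                 eval_z_min = eval_z_min, eval_zr_max = eval_zr_max,
                 sp_convention = sp_convention, amplitude = amplitude,
                 min_points = as.integer(min_points), sp_fun = sp_fun),
            class = "epom_config")
}

# Nominal chamber depths usable for every dz in [dz_lo, dz_hi]:
# inside the evaluation window, with the stopping-power argument valid
# under the chosen convention and z + dz inside the reference support.
.epom_points <- function(det_depths, ref_range, r50, cfg, dz_lo, dz_hi,
                         need_sp) {
  lo <- cfg$eval_z_min
  hi <- cfg$eval_zr_max * r50
  if (need_sp) {
    w <- burns_coefficients()$zr_window
    if (cfg$sp_convention == "shifted") {
      lo <- max(lo, w[1L] * r50 - dz_lo)
      hi <- min(hi, w[2L] * r50 - dz_hi)
    } else {
      lo <- max(lo, w[1L] * r50)
      hi <- min(hi, w[2L] * r50)
    }
  }
  lo <- max(lo, ref_range[1L] - dz_lo)
  hi <- min(hi, ref_range[2L] - dz_hi)
  tol <- 1e-9
  det_depths[det_depths >= lo - tol & det_depths <= hi + tol]
}

# rms at one dz over a fixed set of nominal depths `pts`
.epom_rms_at <- function(ref_fun, det_map, pts, dz, r50, cfg, need_sp) {
  s <- if (need_sp) {
    zs <- if (cfg$sp_convention == "shifted") pts + dz else pts
    cfg$sp_fun(zs, r50)
  } else 1
  conv <- s * det_map(pts)
  refv <- ref_fun(pts + dz)
  if (cfg$amplitude == "normalize_max") {
    conv <- 100 * conv / max(conv)
    k <- 1
  } else {
    k <- sum(refv * conv) / sum(conv^2)
    conv <- k * conv
  }
  d <- refv - conv
  list(rms = sqrt(mean(d * d)), n = length(pts), scale = k,
       residuals = d, fitted = conv)
}

#' RMS deviation between reference and chamber curve at a given shift
#'
#' The objective of the EPOM search:
#' \deqn{\mathrm{rms}(\Delta z)^2 = \frac{1}{n} \sum_i
#'   \left[ D_w(z_i + \Delta z) -
#'          \bar s_{w,air}(z^*, R_{50})\, \bar D_{det}(z_i) \right]^2,}
#' where the \eqn{z_i} are the chamber's nominal scan depths inside the
#' evaluation window, \eqn{D_w} is the reference PDD interpolated at the
#' shifted depths, and \eqn{z^* = z_i + \Delta z} (shifted convention) or
#' \eqn{z_i} (nominal).  Curves are amplitude-matched per
#' `config$amplitude` before differencing.
#'
#' @param ref Reference [depth_curve()] with `quantity = "dose"`.
#' @param det Chamber [depth_curve()]; `"ionization"` curves are converted
#'   through the stopping-power ratio inside the objective, `"dose"` curves
#'   are compared as-is.
#' @param dz Shift to evaluate, cm.
#' @param r50 Beam quality R50, cm.
#' @param config An [epom_config()].
#' @return List with `rms`, `n` (number of points used) and `scale`.
#' @export
epom_rms <- function(ref, det, dz, r50, config = epom_config()) {
  stopifnot_quantity(ref, "dose")
  if (!inherits(det, "depth_curve"))
    stop("`det` must be a `depth_curve`", call. = FALSE)
  need_sp <- det$quantity == "ionization"
  pts <- .epom_points(det$depths, range(ref$depths), r50, config,
                      dz, dz, need_sp)
  if (length(pts) < config$min_points)
    stop(sprintf("only %d usable evaluation points at dz = %g (need >= %d)",
                 length(pts), dz, config$min_points), call. = FALSE)
  refn <- normalize_curve(ref)
  ref_fun <- stats::splinefun(refn$depths, refn$values, method = "monoH.FC")
  det_map <- stats::splinefun(det$depths, det$values, method = "monoH.FC")
  out <- .epom_rms_at(ref_fun, det_map, pts, dz, r50, config, need_sp)
  out[c("rms", "n", "scale")]
}

#' Fit the effective point of measurement of a chamber scan
#'
#' Grid search for the shift \eqn{\Delta z} of the chamber's effective
#' point of measurement relative to its nominal reference point (the inner
#' surface of the entrance window), by minimizing the RMS deviation of
#' [epom_rms()] over a regular grid of candidate shifts.  A positive shift
#' moves the EPOM from the entrance window toward (into) the air cavity,
#' i.e. deeper in water.
#'
#' One fixed set of evaluation points -- valid for every shift on the grid
#' -- is used throughout, so the `n` of the objective is constant and the
#' grid values are comparable.  Shifts for which the reference curve cannot
#' cover `z + dz` are dropped with a warning.  Ties in the minimum are
#' broken toward the smallest `|dz|`.
#'
#' @param ref Reference [depth_curve()] (`"dose"`), e.g. a microDiamond or
#'   Monte Carlo PDD needing no stopping-power conversion.
#' @param det Chamber [depth_curve()], normally `"ionization"` after
#'   [correct_scan()] / [average_curves()].
#' @param r50 Beam quality R50 in cm; computed from `ref` when `NULL`.
#' @param config An [epom_config()].
#' @return An object of class `epom_fit` with elements `dz_opt`, `rms_min`,
#'   `grid` (data frame `dz`, `rms`), `n_points`, `eval_window`,
#'   `r50_used`, `scale_factor`, `config`, `dropped_dz`, `unimodal`, and
#'   the residuals/fitted values at the optimum.  Methods: `print`,
#'   `summary`, `coef`, `plot`, `residuals`, `fitted`.
#' @examples
#' beam <- synthetic_beam(r50 = 4.0)
#' ref  <- make_reference_pdd(beam, seq(0, 6.5, by = 0.02))
#' tr   <- synthetic_truth(dz_true = 0.07, noise_sigma = 0, seed = 1)
#' raw  <- make_chamber_scan(ref, tr, beam)
#' det  <- correct_scan(raw)$curve
#' fit  <- fit_epom(ref, det)
#' coef(fit)
#' @export
fit_epom <- function(ref, det, r50 = NULL, config = epom_config()) {
  cl <- match.call()
  stopifnot_quantity(ref, "dose")
  if (!inherits(det, "depth_curve"))
    stop("`det` must be a `depth_curve`", call. = FALSE)
  if (inherits(r50, "epom_config"))
    stop("`r50` got an `epom_config`; pass it as `config =`", call. = FALSE)
  if (is.null(r50)) r50 <- compute_r50(ref)
  if (!is.numeric(r50) || length(r50) != 1L || r50 <= 0)
    stop("`r50` must be a positive scalar (cm)", call. = FALSE)
  need_sp <- det$quantity == "ionization"
  cfg <- config

  grid <- seq(cfg$dz_min, cfg$dz_max, by = cfg$dz_step)
  grid <- round(grid, 10)

  # fixed evaluation set, valid across the whole grid
  pts <- .epom_points(det$depths, range(ref$depths), r50, cfg,
                      min(grid), max(grid), need_sp)
  if (length(pts) < cfg$min_points) {
    # ref support may be the binding constraint for extreme dz only:
    # retry per-dz below with the window/validity constraints alone
    pts <- .epom_points(det$depths, c(-Inf, Inf), r50, cfg,
                        min(grid), max(grid), need_sp)
    ok_dz <- vapply(grid, function(dz)
      all(pts + dz >= min(ref$depths) - 1e-9 &
          pts + dz <= max(ref$depths) + 1e-9), logical(1))
    if (!any(ok_dz) || length(pts) < cfg$min_points)
      stop("no feasible shift: evaluation window leaves fewer than ",
           cfg$min_points, " points", call. = FALSE)
    warning(sprintf("%d infeasible shift(s) dropped (reference support)",
                    sum(!ok_dz)), call. = FALSE)
  } else {
    ok_dz <- rep(TRUE, length(grid))
  }

  refn <- normalize_curve(ref)
  ref_fun <- stats::splinefun(refn$depths, refn$values, method = "monoH.FC")
  det_map <- stats::splinefun(det$depths, det$values, method = "monoH.FC")

  rms <- rep(NA_real_, length(grid))
  scales <- rep(NA_real_, length(grid))
  for (j in which(ok_dz)) {
    o <- .epom_rms_at(ref_fun, det_map, pts, grid[j], r50, cfg, need_sp)
    rms[j] <- o$rms
    scales[j] <- o$scale
  }
  if (all(is.na(rms))) stop("all grid shifts infeasible", call. = FALSE)

  m <- min(rms, na.rm = TRUE)
  cand <- which(rms == m)
  best <- cand[which.min(abs(grid[cand]))]   # tie-break toward |dz| smallest
  opt <- .epom_rms_at(ref_fun, det_map, pts, grid[best], r50, cfg, need_sp)

  finite <- rms[!is.na(rms)]
  sgn <- sign(diff(finite))
  unimodal <- sum(diff(sgn[sgn != 0]) != 0) <= 1

  structure(list(
    dz_opt = grid[best], rms_min = rms[best],
    grid = data.frame(dz = grid, rms = rms),
    n_points = length(pts), eval_points = pts,
    eval_window = range(pts), r50_used = r50,
    scale_factor = scales[best],
    residuals = opt$residuals, fitted = opt$fitted,
    dropped_dz = grid[!ok_dz], unimodal = unimodal,
    config = cfg, call = cl), class = "epom_fit")
}

#' @export
print.epom_fit <- function(x, ...) {
  cat("Effective point of measurement fit\n")
  cat(sprintf("  dz_opt  = %+.3f cm (positive: toward the cavity)\n",
              x$dz_opt))
  cat(sprintf("  rms_min = %.4f (relative dose), n = %d points\n",
              x$rms_min, x$n_points))
  cat(sprintf("  R50 = %.3f cm, window = [%.2f, %.2f] cm, s_w,air at %s depth\n",
              x$r50_used, x$eval_window[1L], x$eval_window[2L],
              x$config$sp_convention))
  invisible(x)
}

#' @export
summary.epom_fit <- function(object, ...) {
  structure(list(fit = object), class = "summary.epom_fit")
}

#' @export
print.summary.epom_fit <- function(x, ...) {
  f <- x$fit
  print(f)
  cat(sprintf("  grid: %d shifts in [%+.2f, %+.2f] cm, step %.2f cm\n",
              nrow(f$grid), min(f$grid$dz), max(f$grid$dz),
              f$config$dz_step))
  if (length(f$dropped_dz))
    cat("  dropped (infeasible):", paste(sprintf("%+.2f", f$dropped_dz),
                                         collapse = " "), "\n")
  cat(sprintf("  amplitude: %s (scale %.5f); grid %s\n",
              f$config$amplitude, f$scale_factor,
              if (f$unimodal) "unimodal" else "NOT unimodal"))
  q <- stats::quantile(abs(f$residuals), c(0.5, 1))
  cat(sprintf("  |residual| median %.3f, max %.3f (dose %% points)\n",
              q[1L], q[2L]))
  invisible(x)
}

#' @export
coef.epom_fit <- function(object, ...) c(dz = object$dz_opt)

#' @export
residuals.epom_fit <- function(object, ...) {
  stats::setNames(object$residuals, format(object$eval_points))
}

#' @export
fitted.epom_fit <- function(object, ...) {
  stats::setNames(object$fitted, format(object$eval_points))
}

#' Plot an EPOM fit
#'
#' RMS deviation against the candidate shift, with the optimum marked.
#'
#' @param x An `epom_fit`.
#' @param ... Passed to [graphics::plot()].
#' @export
plot.epom_fit <- function(x, ...) {
  graphics::plot(x$grid$dz, x$grid$rms, type = "b", pch = 16, cex = 0.6,
                 xlab = expression(Delta * z ~ "(cm)"),
                 ylab = "rms deviation (relative dose)", ...)
  graphics::abline(v = x$dz_opt, lty = 2)
  graphics::mtext(sprintf("dz_opt = %+.3f cm", x$dz_opt), side = 3,
                  line = 0.2, cex = 0.8)
  invisible(x)
}

#' Tabulate fitted shifts against beam quality
#'
#' @param results Named list of `epom_fit` objects (names are energy
#'   labels), at least two.
#' @return Data frame `energy`, `r50`, `dz_opt` sorted by `r50`, with the
#'   max-minus-min spread of the shifts in attribute `"spread"`.
#' @export
epom_vs_energy <- function(results) {
  if (length(results) < 2L) stop("need >= 2 energies", call. = FALSE)
  tab <- data.frame(
    energy = names(results),
    r50 = vapply(results, `[[`, numeric(1), "r50_used"),
    dz_opt = vapply(results, `[[`, numeric(1), "dz_opt"),
    row.names = NULL)
  tab <- tab[order(tab$r50), ]
  rownames(tab) <- NULL
  attr(tab, "spread") <- max(tab$dz_opt) - min(tab$dz_opt)
  tab
}
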