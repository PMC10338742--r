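# Beam-quality extraction and ionization -> dose conversion through the
# water/air stopping-power ratio parameterized in R50.

#' Electron beam specification
#'
#' @param nominal_energy Energy label (e.g. `"12 MeV"` or `12`).
#' @param r50 Beam quality: depth of the 50% dose level, cm.  Values
#'   outside the validated 2.40--8.82 cm range trigger a warning (the
#'   chamber-shift results shipped with this package were established
#'   inside that range), not an error.
#' @param ssd Source-to-surface distance, cm.
#' @param field_size Field size at the surface, cm (length-2).
#' @return A `beam_spec` list.
#' @export
beam_spec <- function(nominal_energy, r50, ssd = 100,
                      field_size = c(20, 20)) {
  if (!is.numeric(r50) || length(r50) != 1L || r50 <= 0)
    stop("`r50` must be a positive scalar (cm)", call. = FALSE)
  if (r50 < 2.40 || r50 > 8.82)
    warning(sprintf(
      "R50 = %.3g cm is outside the validated range 2.40-8.82 cm", r50),
      call. = FALSE)
  structure(list(nominal_energy = nominal_energy, r50 = r50, ssd = ssd,
                 field_size = field_size), class = "beam_spec")
}

#' Burns stopping-power-ratio fit coefficients
#'
#' Coefficients of the published rational-function fit of the Spencer-Attix
#' water/air mean restricted mass collision stopping-power ratio
#' \eqn{\bar s_{w,air}(z, R_{50})} for clinical electron beams,
#' \deqn{s(x, y) = \frac{a + b x + c x^2 + d y}{1 + e x + f x^2 + g x^3 + h y},}
#' with \eqn{x = \ln R_{50}} and \eqn{y = z / R_{50}}.  Valid for
#' \eqn{0.02 \le z/R_{50} \le 1.2}.
#'
#' @return Named list of numerator coefficients `a..d`, denominator
#'   coefficients `e..h`, and the validity window `zr_window`.
#' @export
burns_coefficients <- function() {
  list(a = 1.0752, b = -0.50867, c = 0.08867, d = -0.08402,
       e = -0.42806, f = 0.064627, g = 0.003085, h = -0.12460,
       zr_window = c(0.02, 1.2))
}

#' Water/air stopping-power ratio at depth
#'
#' Evaluates \eqn{\bar s_{w,air}(z, R_{50})} from the rational fit in
#' [burns_coefficients()].  Strictly enforced validity window
#' `0.02 <= z/R50 <= 1.2`; requests outside it are an error, never an
#' extrapolation.
#'
#' @param z Depth(s) in cm.
#' @param r50 Beam quality R50 in cm (scalar).
#' @param coef Fit coefficients, by default [burns_coefficients()].  An
#'   alternative fit of the same functional form may be supplied.
#' @return Dimensionless ratio(s), same length as `z`.
#' @export
stopping_power_ratio <- function(z, r50, coef = burns_coefficients()) {
  if (!is.numeric(r50) || length(r50) != 1L || r50 <= 0)
    stop("`r50` must be a positive scalar", call. = FALSE)
  y <- z / r50
  w <- coef$zr_window
  tol <- 1e-9
  bad <- y < w[1L] - tol | y > w[2L] + tol
  if (any(bad))
    stop(sprintf(
      "z/R50 = %s outside the stopping-power validity window [%g, %g]",
      paste(signif(y[bad], 4), collapse = ", "), w[1L], w[2L]),
      call. = FALSE)
  x <- log(r50)
  (coef$a + coef$b * x + coef$c * x^2 + coef$d * y) /
    (1 + coef$e * x + coef$f * x^2 + coef$g * x^3 + coef$h * y)
}

#' Beam quality R50 from a dose curve
#'
#' Depth on the distal side of the maximum where the interpolated curve
#' falls to 50% of its maximum.  The curve is interpolated with the same
#' monotone piecewise cubic used by [resample_curve()] and the crossing is
#' located by root finding, so the result is not limited to the scan step.
#'
#' @param curve A [depth_curve()] with `quantity = "dose"`.
#' @return R50 in cm.
#' @export
compute_r50 <- function(curve) {
  stopifnot_quantity(curve, "dose")
  v <- 100 * curve$values / max(curve$values)
  z <- curve$depths
  imax <- which.max(v)
  distal <- seq(imax, length(v))
  below <- distal[v[distal] < 50]
  if (!length(below))
    stop("curve has no distal 50% crossing", call. = FALSE)
  i2 <- below[1L]            # first point under 50% beyond the maximum
  above <- distal[distal < i2 & v[distal] >= 50]
  if (!length(above))
    stop("curve has no distal 50% crossing", call. = FALSE)
  i1 <- max(above)
  f <- stats::splinefun(z, v, method = "monoH.FC")
  stats::uniroot(function(x) f(x) - 50, lower = z[i1], upper = z[i2],
                 tol = 1e-10)$root
}

#' Convert I50 to R50
#'
#' Standard dosimetry-protocol linear conversion from the 50% ionization
#' depth to the 50% dose depth: `1.029 * i50 - 0.06` for `i50 <= 10` cm,
#' `1.059 * i50 - 0.37` above.
#'
#' @param i50 Depth of the 50% ionization level, cm (> 0).
#' @return R50 in cm.
#' @export
i50_to_r50 <- function(i50) {
  if (any(i50 <= 0)) stop("`i50` must be positive", call. = FALSE)
  ifelse(i50 <= 10, 1.029 * i50 - 0.06, 1.059 * i50 - 0.37)
}

#' Convert a depth-ionization curve to depth dose
#'
#' Multiplies the ionization values pointwise by the stopping-power ratio
#' at the (nominal) scan depth and renormalizes to 100 at the maximum.
#' All depths must lie inside the stopping-power validity window for the
#' given beam quality; offending depths are reported.
#'
#' @param curve A [depth_curve()] with `quantity = "ionization"`.
#' @param r50 Beam quality R50, cm.
#' @param sp_fun Stopping-power-ratio function `f(z, r50)`; defaults to
#'   [stopping_power_ratio()].
#' @return A `depth_curve` with `quantity = "dose"`, normalized to 100.
#' @export
pdi_to_pdd <- function(curve, r50, sp_fun = stopping_power_ratio) {
  stopifnot_quantity(curve, "ionization")
  w <- burns_coefficients()$zr_window
  y <- curve$depths / r50
  bad <- y < w[1L] - 1e-9 | y > w[2L] + 1e-9
  if (any(bad))
    stop("depths outside the stopping-power validity window: ",
         paste(signif(curve$depths[bad], 4), collapse = ", "), " cm",
         call. = FALSE)
  out <- curve
  out$values <- curve$values * sp_fun(curve$depths, r50)
  out$quantity <- "dose"
  normalize_curve(out)
}

#' Protocol reference depth for electron beams
#'
#' `z_ref = 0.6 * R50 - 0.1` cm.
#'
#' @param r50 Beam quality R50, cm (> 0.17 so the result is positive).
#' @return Reference depth in cm.
#' @export
reference_depth <- function(r50) {
  z <- 0.6 * r50 - 0.1
  if (any(z <= 0))
    stop("reference depth is nonpositive for r50 <= 1/6 cm", call. = FALSE)
  z
}

#' Beam quality from an ionization-only dataset
#'
#' When no reference dose curve is available, R50 is obtained by fixed-point
#' iteration: start from the I50-based protocol estimate, convert the PDI to
#' a PDD with the current R50, recompute R50 from the converted curve, and
#' repeat until the change is below `tol` (default 0.001 cm, at most
#' `max_iter` rounds).  Depths outside the stopping-power validity window
#' for the current R50 are excluded from the conversion step.
#'
#' @param curve A [depth_curve()] with `quantity = "ionization"`.
#' @param tol Convergence tolerance on R50, cm.
#' @param max_iter Iteration cap.
#' @return R50 in cm.
#' @export
r50_from_ionization <- function(curve, tol = 0.001, max_iter = 20L) {
  stopifnot_quantity(curve, "ionization")
  as_dose <- curve; as_dose$quantity <- "dose"
  i50 <- compute_r50(as_dose)        # 50% level of the ionization curve
  r50 <- i50_to_r50(i50)
  w <- burns_coefficients()$zr_window
  for (it in seq_len(max_iter)) {
    keep <- curve$depths / r50 >= w[1L] & curve$depths / r50 <= w[2L]
    if (sum(keep) < 4L)
      stop("too few depths inside the validity window", call. = FALSE)
    sub <- depth_curve(curve$depths[keep], curve$values[keep], "ionization")
    r50_new <- compute_r50(pdi_to_pdd(sub, r50))
    if (abs(r50_new - r50) < tol) return(r50_new)
    r50 <- r50_new
  }
  warning("R50 fixed-point iteration did not converge to ", tol,
          " cm in ", max_iter, " iterations", call. = FALSE)
  r50
}
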