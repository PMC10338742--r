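# Depth-wise ion-recombination and polarity corrections of raw chamber
# readings, following the standard dosimetry-protocol prescriptions for
# pulsed beams.

.ks_pulsed <- data.frame(
  ratio = c(2.0, 2.5, 3.0, 3.5, 4.0, 5.0),
  a0 = c(2.337, 1.474, 1.198, 1.080, 1.022, 0.975),
  a1 = c(-3.636, -1.587, -0.875, -0.542, -0.363, -0.188),
  a2 = c(2.299, 1.114, 0.677, 0.463, 0.341, 0.214))

#' Two-voltage recombination coefficients (pulsed beams)
#'
#' Quadratic-fit coefficients `(a0, a1, a2)` of the pulsed-beam two-voltage
#' method, `ks = a0 + a1 (M1/M2) + a2 (M1/M2)^2`, tabulated per supported
#' voltage ratio `V1/V2`.  Each row satisfies `a0 + a1 + a2 = 1` to within
#' 0.001 (no recombination at equal readings), which the test suite uses as
#' a transcription gate.
#'
#' @return Data frame with columns `ratio`, `a0`, `a1`, `a2`.
#' @export
ks_coefficients <- function() .ks_pulsed

#' Polarity correction factor
#'
#' `kpol = (|M+| + |M-|) / (2 |M|)` where `M` is the reading at the
#' routinely used polarity.
#'
#' @param m_pos,m_neg Readings at positive and negative polarity (signs are
#'   ignored).
#' @param m Reading at the routine polarity (nonzero).
#' @return Dimensionless correction factor.
#' @export
k_pol <- function(m_pos, m_neg, m) {
  if (any(m == 0)) stop("routine-polarity reading must be nonzero",
                        call. = FALSE)
  (abs(m_pos) + abs(m_neg)) / (2 * abs(m))
}

#' Ion-recombination correction by the two-voltage method
#'
#' Pulsed-beam quadratic in the reading ratio `m1/m2`, with coefficients
#' from [ks_coefficients()] for the voltage ratio `v1/v2`.  Only tabulated
#' voltage ratios are supported (matched to 0.1%); other ratios are an
#' error.  A reading ratio below 1 is nonphysical (more charge at lower
#' voltage) and triggers a warning, but the fitted value is still returned.
#'
#' @param m1,m2 Readings at voltages `v1` and `v2` (positive).
#' @param v1,v2 Polarizing voltages, `v1 > v2 > 0`.
#' @return Dimensionless correction factor ks (vectorized over readings).
#' @export
k_s_two_voltage <- function(m1, m2, v1, v2) {
  if (!(v1 > v2 && v2 > 0)) stop("need v1 > v2 > 0", call. = FALSE)
  if (any(m1 <= 0) || any(m2 <= 0))
    stop("readings must be positive", call. = FALSE)
  tab <- ks_coefficients()
  i <- which(abs(v1 / v2 - tab$ratio) / tab$ratio < 1e-3)
  if (length(i) != 1L)
    stop(sprintf(
      "unsupported voltage ratio V1/V2 = %.4g; supported: %s",
      v1 / v2, paste(tab$ratio, collapse = ", ")), call. = FALSE)
  r <- m1 / m2
  if (any(r < 1))
    warning("reading ratio m1/m2 < 1 is nonphysical", call. = FALSE)
  tab$a0[i] + tab$a1[i] * r + tab$a2[i] * r^2
}

#' Correct a raw chamber scan for recombination and polarity
#'
#' Applies `ks` and `kpol` depth by depth: the corrected relative
#' ionization is `m_v1 * ks(z) * kpol(z)`, renormalized to 100 at its
#' maximum.  The per-depth correction profile is returned alongside for
#' reporting; a depth-independent correction leaves the normalized curve
#' unchanged.
#'
#' @param readings A [raw_depth_readings()] object with at least 4 depths.
#' @return A list with `curve` (a `depth_curve` of quantity
#'   `"ionization"`) and `profile` (data frame `depth`, `ks`, `kpol`).
#' @export
correct_scan <- function(readings) {
  if (!inherits(readings, "raw_depth_readings"))
    stop("expected `raw_depth_readings`", call. = FALSE)
  if (nrow(readings) < 4L) stop("need at least 4 depths", call. = FALSE)
  ks <- k_s_two_voltage(readings$m_v1, readings$m_v2,
                        attr(readings, "v1"), attr(readings, "v2"))
  kpol <- k_pol(readings$m_pos, readings$m_neg, readings$m_v1)
  if (any(kpol < 0.95 | kpol > 1.05))
    warning("kpol outside the sanity band [0.95, 1.05]", call. = FALSE)
  if (any(ks < 1 - 0.005))
    warning("ks below 1 by more than 0.5%; recombination should lose charge",
            call. = FALSE)
  corrected <- abs(readings$m_v1) * ks * kpol
  curve <- normalize_curve(depth_curve(readings$depth, corrected,
                                       "ionization"))
  list(curve = curve,
       profile = data.frame(depth = readings$depth, ks = ks, kpol = kpol))
}
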