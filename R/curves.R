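# Depth-scan curve container and plumbing: construction, reading/writing,
# multi-session averaging and shape-preserving resampling.

#' Depth-value curve
#'
#' The basic container for a water-tank depth scan: a strictly increasing
#' vector of depths (cm, water) and the corresponding relative detector
#' values.  Every curve carries a declared physical quantity -- `"dose"`
#' (a PDD, e.g. from the reference detector) or `"ionization"` (a PDI, a
#' chamber reading not yet corrected for the stopping-power ratio) -- so
#' that operations requiring one cannot silently receive the other.
#'
#' @param depths Numeric vector of depths in cm, strictly increasing,
#'   length >= 4.
#' @param values Numeric vector of relative detector values, same length
#'   as `depths`, finite and non-negative with at least one positive value.
#' @param quantity Either `"dose"` or `"ionization"`.
#' @param meta Optional named list of free-form metadata (detector, energy
#'   label, serial, session id, ...).
#' @return An object of class `depth_curve`: a list with elements
#'   `depths`, `values`, `quantity`, `meta`.
#' @examples
#' dc <- depth_curve(seq(0, 5, by = 0.5), 100 * exp(-seq(0, 5, by = 0.5)/3),
#'                   "dose")
#' dc
#' @export
depth_curve <- function(depths, values, quantity = c("dose", "ionization"),
                        meta = list()) {
  quantity <- match.arg(quantity)
  depths <- as.numeric(depths)
  values <- as.numeric(values)
  if (length(depths) != length(values))
    stop("`depths` and `values` must have the same length", call. = FALSE)
  if (length(depths) < 4L)
    stop("a depth curve needs at least 4 points", call. = FALSE)
  if (anyNA(depths) || any(!is.finite(depths)))
    stop("depths must be finite", call. = FALSE)
  if (any(diff(depths) <= 0))
    stop("depths must be strictly increasing", call. = FALSE)
  if (anyNA(values) || any(!is.finite(values)))
    stop("values must be finite", call. = FALSE)
  if (any(values < 0) || max(values) <= 0)
    stop("values must be non-negative with a positive maximum", call. = FALSE)
  structure(list(depths = depths, values = values,
                 quantity = quantity, meta = as.list(meta)),
            class = "depth_curve")
}

#' @export
print.depth_curve <- function(x, ...) {
  cat(sprintf("<depth_curve: %s, %d points, z = [%.3g, %.3g] cm>\n",
              x$quantity, length(x$depths), min(x$depths), max(x$depths)))
  if (length(x$meta))
    cat("  meta:", paste(names(x$meta), unlist(lapply(x$meta, format)),
                         sep = "=", collapse = ", "), "\n")
  invisible(x)
}

#' @export
range.depth_curve <- function(..., na.rm = FALSE) {
  range(..1$depths)
}

stopifnot_quantity <- function(curve, quantity) {
  if (!inherits(curve, "depth_curve"))
    stop("expected a `depth_curve`", call. = FALSE)
  if (curve$quantity != quantity)
    stop(sprintf("expected a %s curve, got a %s curve", quantity,
                 curve$quantity), call. = FALSE)
  invisible(curve)
}

#' Raw per-depth chamber readings
#'
#' Electrometer readings before recombination/polarity correction: at each
#' depth the reading at the operating voltage `v1`, at the reduced voltage
#' `v2` (two-voltage method), and at both polarities.  `m_v1` is taken at
#' the routinely used polarity.
#'
#' @param depth Depths in cm, strictly increasing.
#' @param m_v1,m_v2 Readings at polarizing voltages `v1` > `v2`.
#' @param m_pos,m_neg Readings at positive and negative polarity.
#' @param v1,v2 Polarizing voltages in volts, `v1 > v2 > 0`.
#' @return A `raw_depth_readings` data frame with the voltages stored as
#'   attributes `v1`, `v2`.
#' @export
raw_depth_readings <- function(depth, m_v1, m_v2, m_pos, m_neg, v1, v2) {
  if (!(is.numeric(v1) && is.numeric(v2) && length(v1) == 1L &&
        length(v2) == 1L && v1 > v2 && v2 > 0))
    stop("voltages must satisfy v1 > v2 > 0", call. = FALSE)
  n <- length(depth)
  if (any(lengths(list(m_v1, m_v2, m_pos, m_neg)) != n))
    stop("all reading columns must match `depth` in length", call. = FALSE)
  if (any(diff(depth) <= 0))
    stop("depths must be strictly increasing", call. = FALSE)
  if (any(c(m_v1, m_v2, m_pos, m_neg) == 0))
    stop("readings must be nonzero", call. = FALSE)
  structure(
    data.frame(depth = as.numeric(depth), m_v1 = as.numeric(m_v1),
               m_v2 = as.numeric(m_v2), m_pos = as.numeric(m_pos),
               m_neg = as.numeric(m_neg)),
    v1 = v1, v2 = v2,
    class = c("raw_depth_readings", "data.frame"))
}

#' Read a depth scan from disk
#'
#' Two concrete dialects are supported.  `"two_column"` is whitespace- or
#' comma-separated `depth_cm value` ASCII (no header, `#` comments allowed)
#' and yields a [depth_curve()].  `"raw_csv"` is a headered CSV with columns
#' `depth_cm,m_v1,m_v2,m_pos,m_neg` and yields [raw_depth_readings()]
#' (voltages via `v1`/`v2` arguments, or from a JSON sidecar `<path>.json`
#' written by [write_scan()]).  `"auto"` inspects the first non-comment line.
#'
#' @param path File to read.
#' @param dialect One of `"auto"`, `"two_column"`, `"raw_csv"`.
#' @param quantity Declared quantity for two-column scans.
#' @param v1,v2 Voltages for raw readings when no sidecar is present.
#' @return A `depth_curve` or a `raw_depth_readings` object.
#' @export
read_scan <- function(path, dialect = c("auto", "two_column", "raw_csv"),
                      quantity = c("dose", "ionization"),
                      v1 = NULL, v2 = NULL) {
  dialect <- match.arg(dialect)
  quantity <- match.arg(quantity)
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  keep <- !grepl("^\\s*(#|$)", lines)
  if (!any(keep)) stop("empty scan file: ", path, call. = FALSE)
  first <- lines[keep][1L]
  if (dialect == "auto")
    dialect <- if (grepl("m_v1", first, fixed = TRUE)) "raw_csv"
               else "two_column"

  sidecar <- paste0(path, ".json")
  meta <- if (file.exists(sidecar))
    jsonlite::read_json(sidecar, simplifyVector = TRUE) else list()

  if (dialect == "two_column") {
    rows <- which(keep)
    if (grepl("depth", first)) rows <- rows[-1L]  # tolerate a header line
    parsed <- lapply(rows, function(i) {
      flds <- strsplit(trimws(lines[i]), "[, \t]+")[[1L]]
      x <- suppressWarnings(as.numeric(flds))
      if (length(x) != 2L || anyNA(x))
        stop(sprintf("malformed row at line %d of %s: '%s'", i, path,
                     lines[i]), call. = FALSE)
      x
    })
    m <- do.call(rbind, parsed)
    q <- if (!is.null(meta$quantity)) meta$quantity else quantity
    mm <- meta[setdiff(names(meta), "quantity")]
    return(depth_curve(m[, 1L], m[, 2L], q, meta = mm))
  }

  df <- utils::read.csv(path, comment.char = "#")
  need <- c("depth_cm", "m_v1", "m_v2", "m_pos", "m_neg")
  if (!all(need %in% names(df)))
    stop("raw_csv dialect needs columns ", paste(need, collapse = ","),
         call. = FALSE)
  if (is.null(v1)) v1 <- meta$v1
  if (is.null(v2)) v2 <- meta$v2
  if (is.null(v1) || is.null(v2))
    stop("voltages v1/v2 required (argument or JSON sidecar)", call. = FALSE)
  raw_depth_readings(df$depth_cm, df$m_v1, df$m_v2, df$m_pos, df$m_neg,
                     v1 = as.numeric(v1), v2 = as.numeric(v2))
}

#' Write a depth scan to disk
#'
#' Curves are written as two-column CSV `depth_cm,value`; raw readings as
#' the five-column CSV dialect.  Metadata (quantity, free-form meta,
#' voltages) goes into a JSON sidecar `<path>.json` so a round trip through
#' [read_scan()] restores the object.
#'
#' @param x A `depth_curve` or `raw_depth_readings`.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_scan <- function(x, path) {
  if (inherits(x, "depth_curve")) {
    df <- data.frame(depth_cm = x$depths, value = x$values)
    utils::write.csv(format(df, digits = 15, trim = TRUE), path,
                     row.names = FALSE, quote = FALSE)
    jsonlite::write_json(c(list(quantity = x$quantity), x$meta),
                         paste0(path, ".json"), auto_unbox = TRUE,
                         digits = NA)
  } else if (inherits(x, "raw_depth_readings")) {
    df <- data.frame(depth_cm = x$depth, m_v1 = x$m_v1, m_v2 = x$m_v2,
                     m_pos = x$m_pos, m_neg = x$m_neg)
    utils::write.csv(format(df, digits = 15, trim = TRUE), path,
                     row.names = FALSE, quote = FALSE)
    jsonlite::write_json(list(v1 = attr(x, "v1"), v2 = attr(x, "v2")),
                         paste0(path, ".json"), auto_unbox = TRUE,
                         digits = NA)
  } else stop("don't know how to write a ", class(x)[1L], call. = FALSE)
  invisible(path)
}

#' Resample a curve onto new depths
#'
#' Monotone shape-preserving piecewise-cubic (Fritsch--Carlson Hermite)
#' interpolation: exact at the original knots and free of overshoot on
#' monotone segments, which matters on the steep distal falloff where an
#' ordinary cubic spline rings.  Extrapolation is refused.
#'
#' @param curve A [depth_curve()].
#' @param new_depths Depths (cm) at which to evaluate; all must lie within
#'   the curve's depth range.
#' @return Numeric vector of interpolated values.
#' @export
resample_curve <- function(curve, new_depths) {
  if (!inherits(curve, "depth_curve"))
    stop("expected a `depth_curve`", call. = FALSE)
  rng <- range(curve$depths)
  tol <- 1e-9
  if (any(new_depths < rng[1L] - tol) || any(new_depths > rng[2L] + tol))
    stop(sprintf(
      "refusing to extrapolate: requested depths outside [%.4g, %.4g] cm",
      rng[1L], rng[2L]), call. = FALSE)
  new_depths <- pmin(pmax(new_depths, rng[1L]), rng[2L])
  f <- stats::splinefun(curve$depths, curve$values, method = "monoH.FC")
  f(new_depths)
}

#' Average several depth scans
#'
#' Pointwise mean of the curves after resampling each onto the union of
#' their depth grids, restricted to the depth interval common to all
#' sessions (measured data are never extrapolated).  All curves must carry
#' the same quantity.
#'
#' @param curves List of [depth_curve()] objects (>= 1), typically repeat
#'   sessions of the same scan.
#' @return A `depth_curve` on the common union grid; `meta$sessions`
#'   records how many curves were averaged.
#' @export
average_curves <- function(curves) {
  if (!length(curves)) stop("need at least one curve", call. = FALSE)
  if (!all(vapply(curves, inherits, logical(1), "depth_curve")))
    stop("all elements must be `depth_curve` objects", call. = FALSE)
  qs <- unique(vapply(curves, `[[`, character(1), "quantity"))
  if (length(qs) != 1L)
    stop("cannot average curves of mixed quantities: ",
         paste(qs, collapse = " vs "), call. = FALSE)
  lo <- max(vapply(curves, function(c) min(c$depths), numeric(1)))
  hi <- min(vapply(curves, function(c) max(c$depths), numeric(1)))
  if (lo >= hi) stop("curves share no common depth interval", call. = FALSE)
  grid <- sort(unique(unlist(lapply(curves, `[[`, "depths"))))
  grid <- grid[grid >= lo - 1e-12 & grid <= hi + 1e-12]
  vals <- rowMeans(vapply(curves, resample_curve, numeric(length(grid)),
                          new_depths = grid))
  meta <- curves[[1L]]$meta
  meta$sessions <- length(curves)
  depth_curve(grid, vals, qs, meta = meta)
}

#' Normalize a curve to 100 at its maximum
#'
#' Standard relative-dosimetry convention for PDD/PDI curves.
#'
#' @param curve A [depth_curve()].
#' @return The curve with values scaled so the sampled maximum is 100.
#' @export
normalize_curve <- function(curve) {
  curve$values <- 100 * curve$values / max(curve$values)
  curve
}
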