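# Chamber geometry registry.  Nominal dimensions of the three plane-parallel
# chambers commonly used for low-energy electron dosimetry, plus the
# published NACP-02 entrance-window model variants (the window build of this
# chamber is known to deviate from its specification sheet).

.chamber_table <- data.frame(
  name = c("NACP-02", "Roos", "Advanced Markus"),
  sensitive_volume = c(0.160, 0.350, 0.020),   # cm^3
  cavity_radius    = c(0.500, 0.800, 0.250),   # cm
  window_thickness = c(0.060, 0.112, 0.130),   # cm
  water_equiv_scaling = c(0.104, 0.118, 0.106),# g/cm^2
  guard            = c(0.300, 0.400, 0.200),   # cm
  stringsAsFactors = FALSE)

.nacp02_models <- data.frame(
  model = c("specification", "thick-window", "dense-graphite",
            "measured-teardown"),
  entrance_window  = c(0.060, 0.090, 0.060, 0.067),  # cm
  graphite_layer   = c(0.050, 0.075, 0.050, 0.050),  # cm
  graphite_density = c(1.75, 1.75, 2.25, 2.25),      # g/cm^3
  mylar_layer      = c(0.010, 0.015, 0.010, 0.017),  # cm
  stringsAsFactors = FALSE)

#' Plane-parallel chamber geometry registry
#'
#' Nominal air-cavity dimensions and physical characteristics of the
#' NACP-02, Roos (PTW 34001) and Advanced Markus (PTW 34045) chambers.
#'
#' @param name Optional chamber name; if given, the matching single row is
#'   returned as a one-row data frame (error if unknown).
#' @return A data frame with columns `name`, `sensitive_volume` (cm^3),
#'   `cavity_radius` (cm), `window_thickness` (cm), `water_equiv_scaling`
#'   (g/cm^2) and `guard` (cm).
#' @export
chamber_specs <- function(name = NULL) {
  if (is.null(name)) return(.chamber_table)
  i <- match(name, .chamber_table$name)
  if (is.na(i))
    stop("unknown chamber '", name, "'; known: ",
         paste(.chamber_table$name, collapse = ", "), call. = FALSE)
  .chamber_table[i, , drop = FALSE]
}

#' NACP-02 entrance-window model variants
#'
#' Published geometry variants of the NACP-02 entrance window (specification
#' sheet, two literature re-creations with thicker window or denser
#' graphite, and a destructive-teardown measurement).  Shipped for
#' documentation and reporting; the package does not simulate them.
#'
#' @return A data frame of the four window models (cm, g/cm^3).
#' @export
nacp02_window_models <- function() .nacp02_models
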