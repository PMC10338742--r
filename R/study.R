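# Study-level aggregation: chamber-type mean shifts, energy dependence,
# reference-depth dose impact, and the end-to-end pipeline over a study
# directory (average -> correct -> convert -> fit -> summarize).

#' Summarize fitted shifts for one chamber type
#'
#' Aggregates a per-serial, per-energy table of fitted shifts: serial
#' means over energies, the type mean (mean of the serial means), the
#' energy means over serials with their max-minus-min spread, and two
#' labelled 1-sigma standard deviations -- over the serial means and over
#' all contributing (serial, energy) values (sample SD, n-1).
#'
#' @param shifts Data frame with columns `serial`, `energy`, `dz` (cm);
#'   optionally `r50`.
#' @param chamber_type Optional label carried into the summary.
#' @return A `shift_summary` list with `per_serial`, `type_mean`,
#'   `sd_serial_means`, `sd_all_values`, `energy_means`, `energy_spread`.
#' @export
summarize_shifts <- function(shifts, chamber_type = NULL) {
  if (!is.data.frame(shifts) || !nrow(shifts))
    stop("`shifts` must be a nonempty data frame", call. = FALSE)
  if (!all(c("serial", "energy", "dz") %in% names(shifts)))
    stop("`shifts` needs columns serial, energy, dz", call. = FALSE)
  serial_means <- tapply(shifts$dz, shifts$serial, mean)
  energy_means <- tapply(shifts$dz, shifts$energy, mean)
  # keep energies in the order first seen (typically ascending energy)
  energy_means <- energy_means[unique(as.character(shifts$energy))]
  per_serial <- data.frame(serial = names(serial_means),
                           dz_mean = as.numeric(serial_means),
                           row.names = NULL)
  structure(list(
    chamber_type = chamber_type,
    per_serial = per_serial,
    type_mean = mean(serial_means),
    sd_serial_means = if (length(serial_means) > 1L)
      stats::sd(serial_means) else NA_real_,
    sd_all_values = if (nrow(shifts) > 1L) stats::sd(shifts$dz)
      else NA_real_,
    energy_means = data.frame(energy = names(energy_means),
                              dz_mean = as.numeric(energy_means),
                              row.names = NULL),
    energy_spread = max(energy_means) - min(energy_means),
    n_values = nrow(shifts)), class = "shift_summary")
}

#' @export
print.shift_summary <- function(x, ...) {
  if (!is.null(x$chamber_type)) cat(x$chamber_type, "\n")
  cat(sprintf("  type mean dz = %.3f cm (SD over serial means %.3f, over all %d values %.3f)\n",
              x$type_mean, x$sd_serial_means, x$n_values, x$sd_all_values))
  cat(sprintf("  energy spread (max - min of energy means) = %.3f cm\n",
              x$energy_spread))
  invisible(x)
}

#' Dose impact of the EPOM shift at the reference depth
#'
#' The change in relative dose that applying the fitted shift makes at the
#' protocol reference depth `z_ref = 0.6 R50 - 0.1`:
#' `|PDD(z_ref + dz) - PDD(z_ref)|` in percentage points of the curve
#' normalized to 100 at its maximum.
#'
#' @param pdd A [depth_curve()] (`"dose"`).
#' @param dz_opt Fitted shift, cm.
#' @param r50 Beam quality, cm.
#' @return Dose difference in percentage points.
#' @export
dose_difference_at_reference_depth <- function(pdd, dz_opt, r50) {
  stopifnot_quantity(pdd, "dose")
  zref <- reference_depth(r50)
  pdd <- normalize_curve(pdd)
  v <- resample_curve(pdd, c(zref, zref + dz_opt))
  abs(v[2L] - v[1L])
}

#' Run a full EPOM study from a directory of scans
#'
#' Executes the whole analysis chain over a study directory laid out as by
#' [make_study_fixture()] (or assembled by hand with the same
#' `manifest.json` schema): per energy, the reference PDD is read and its
#' R50 extracted; each session scan is corrected for recombination and
#' polarity, sessions are averaged, and the EPOM shift is fitted; shifts
#' are then aggregated per chamber type, and the reference-depth dose
#' impact of each type's per-energy mean shift is evaluated.
#'
#' Individual scan failures are collected in the report rather than
#' aborting; a missing reference curve for an energy is fatal and names
#' the energy.
#'
#' @param input_dir Directory containing `manifest.json` and the scans.
#' @param out_dir Optional output directory; when given, writes
#'   `report.json`, `shifts.csv`, `corrections.csv`, and the figure-ready
#'   tables `energy_dependence.csv` and `serial_means.csv`.
#' @param config An [epom_config()] applied to every fit.
#' @param verbose Emit one log line per scan.
#' @return An `epom_study` list: `shifts` (data frame: chamber, serial,
#'   energy, r50, dz, rms_min, n), `summaries` (one [summarize_shifts()]
#'   result per chamber), `dose_diff` (per chamber and energy),
#'   `r50` (per energy), `failures`, and the conventions used.
#' @export
run_study <- function(input_dir, out_dir = NULL, config = epom_config(),
                      verbose = FALSE) {
  mf_path <- file.path(input_dir, "manifest.json")
  if (!file.exists(mf_path))
    stop("no manifest.json in ", input_dir, call. = FALSE)
  mf <- jsonlite::read_json(mf_path, simplifyVector = TRUE)
  energies <- mf$energies
  scans <- mf$scans

  refs <- list(); r50s <- numeric(0)
  for (i in seq_len(nrow(energies))) {
    lab <- as.character(energies$label[i])
    f <- file.path(input_dir, energies$ref[i])
    if (is.na(energies$ref[i]) || !file.exists(f))
      stop("missing reference curve for energy ", lab, call. = FALSE)
    refs[[lab]] <- read_scan(f)
    r50s[lab] <- compute_r50(refs[[lab]])
  }
  miss <- setdiff(unique(as.character(scans$energy)), names(refs))
  if (length(miss))
    stop("missing reference curve for energy ",
         paste(miss, collapse = ", "), call. = FALSE)

  key <- interaction(scans$chamber, scans$serial, scans$energy, drop = TRUE)
  rows <- list(); failures <- list(); corr <- list()
  for (g in levels(key)) {
    sub <- scans[key == g, , drop = FALSE]
    lab <- as.character(sub$energy[1L])
    res <- tryCatch({
      sessions <- lapply(file.path(input_dir, sub$file), read_scan,
                         v1 = mf$v1, v2 = mf$v2)
      corrected <- lapply(sessions, correct_scan)
      for (j in seq_along(corrected))
        corr[[length(corr) + 1L]] <- cbind(file = sub$file[j],
                                           corrected[[j]]$profile)
      avg <- average_curves(lapply(corrected, `[[`, "curve"))
      fit <- fit_epom(refs[[lab]], avg, r50 = r50s[lab], config = config)
      if (verbose)
        message(sprintf("%s %s %s MeV: dz = %+.3f cm (rms %.4f, n %d)",
                        sub$chamber[1L], sub$serial[1L], lab,
                        fit$dz_opt, fit$rms_min, fit$n_points))
      data.frame(chamber = sub$chamber[1L], serial = sub$serial[1L],
                 energy = lab, r50 = unname(r50s[lab]), dz = fit$dz_opt,
                 rms_min = fit$rms_min, n = fit$n_points)
    }, error = function(e) {
      failures[[length(failures) + 1L]] <<- list(group = g,
                                                 error = conditionMessage(e))
      NULL
    })
    if (!is.null(res)) rows[[length(rows) + 1L]] <- res
  }
  if (!length(rows)) stop("no scan group could be analyzed", call. = FALSE)
  shifts <- do.call(rbind, rows)
  shifts <- shifts[order(shifts$chamber, shifts$serial, shifts$r50), ]
  rownames(shifts) <- NULL

  summaries <- lapply(split(shifts, shifts$chamber), function(s)
    summarize_shifts(s[c("serial", "energy", "dz")], s$chamber[1L]))

  dd <- list()
  for (ch in names(summaries)) {
    em <- summaries[[ch]]$energy_means
    for (i in seq_len(nrow(em))) {
      lab <- as.character(em$energy[i])
      dd[[length(dd) + 1L]] <- data.frame(
        chamber = ch, energy = lab, r50 = unname(r50s[lab]),
        dz_mean = em$dz_mean[i],
        dose_diff_pct = dose_difference_at_reference_depth(
          refs[[lab]], em$dz_mean[i], r50s[lab]))
    }
  }
  dose_diff <- do.call(rbind, dd)

  report <- structure(list(
    shifts = shifts, summaries = summaries, dose_diff = dose_diff,
    r50 = r50s, failures = failures,
    conventions = list(sp_convention = config$sp_convention,
                       amplitude = config$amplitude,
                       dz_grid = c(config$dz_min, config$dz_max,
                                   config$dz_step),
                       eval_window = c(config$eval_z_min,
                                       config$eval_zr_max),
                       sd_definition = "sample (n-1)")),
    class = "epom_study")

  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    utils::write.csv(shifts, file.path(out_dir, "shifts.csv"),
                     row.names = FALSE)
    utils::write.csv(do.call(rbind, corr),
                     file.path(out_dir, "corrections.csv"),
                     row.names = FALSE)
    edep <- do.call(rbind, lapply(names(summaries), function(ch) {
      s <- shifts[shifts$chamber == ch, ]
      agg <- do.call(rbind, lapply(split(s, s$energy), function(e)
        data.frame(chamber = ch, energy = e$energy[1L], r50 = e$r50[1L],
                   dz_mean = mean(e$dz), dz_sd = stats::sd(e$dz))))
      agg[order(agg$r50), ]
    }))
    utils::write.csv(edep, file.path(out_dir, "energy_dependence.csv"),
                     row.names = FALSE)
    smean <- do.call(rbind, lapply(names(summaries), function(ch) {
      s <- shifts[shifts$chamber == ch, ]
      do.call(rbind, lapply(split(s, s$serial), function(e)
        data.frame(chamber = ch, serial = e$serial[1L],
                   dz_mean = mean(e$dz), dz_sd = stats::sd(e$dz))))
    }))
    utils::write.csv(smean, file.path(out_dir, "serial_means.csv"),
                     row.names = FALSE)
    jsonlite::write_json(
      list(shifts = shifts, dose_diff = dose_diff,
           r50 = as.list(r50s),
           summaries = lapply(summaries, unclass),
           conventions = report$conventions,
           failures = failures),
      file.path(out_dir, "report.json"), auto_unbox = TRUE, digits = NA,
      dataframe = "rows")
  }
  report
}

#' @export
print.epom_study <- function(x, ...) {
  cat("EPOM study:", nrow(x$shifts), "scan groups,",
      length(x$summaries), "chamber types\n")
  for (s in x$summaries) print(s)
  if (length(x$failures))
    cat("  failures:", length(x$failures), "\n")
  invisible(x)
}
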