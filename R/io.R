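# CSV input/output and the end-to-end pipeline driver.
#
# File schemas (header mandatory, SI conversion at the boundary):
#   progress curves: curve_id, time_s, a410, inhibitor_nM
#   ITC heats:       injection, volume_uL, heat_uJ [, blank_heat_uJ]
#   DSF melts:       temperature_C, fluorescence, replicate_id

require_columns <- function(df, cols, path) {
  missing <- setdiff(cols, names(df))
  if (length(missing) > 0)
    stop(sprintf("%s: missing required column(s): %s",
                 path, paste(missing, collapse = ", ")))
}

#' Read an inhibition series from CSV
#'
#' Expects columns `curve_id`, `time_s`, `a410`, `inhibitor_nM`. Rows are
#' grouped by `curve_id`, sorted by time within each curve, converted to SI
#' and validated against the progress-curve invariants. Duplicate
#' (curve_id, time) rows and non-finite values are structured errors naming
#' the offending rows.
#'
#' @param path CSV file path.
#' @return List of `progress_curve` objects, ordered by inhibitor
#'   concentration.
#' @export
read_progress_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  require_columns(df, c("curve_id", "time_s", "a410", "inhibitor_nM"), path)
  bad <- which(!is.finite(df$time_s) | !is.finite(df$a410) |
                 !is.finite(df$inhibitor_nM))
  if (length(bad) > 0)
    stop(sprintf("%s: non-finite values at data row(s) %s", path,
                 paste(utils::head(bad, 5), collapse = ", ")))
  dup <- duplicated(df[, c("curve_id", "time_s")])
  if (any(dup))
    stop(sprintf("%s: duplicate (curve_id, time) at data row(s) %s", path,
                 paste(utils::head(which(dup), 5), collapse = ", ")))
  curves <- lapply(split(df, df$curve_id), function(g) {
    g <- g[order(g$time_s), ]
    it <- unique(g$inhibitor_nM)
    if (length(it) != 1)
      stop(sprintf("%s: curve %s has inconsistent inhibitor_nM", path,
                   g$curve_id[1]))
    progress_curve(g$curve_id[1], it * 1e-9, g$time_s, g$a410)
  })
  curves[order(vapply(curves, function(cv) cv$inhibitor_conc, numeric(1)))]
}

#' Write an inhibition series to CSV
#'
#' @param curves list of `progress_curve` objects.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_progress_csv <- function(curves, path) {
  df <- do.call(rbind, lapply(curves, function(cv)
    data.frame(curve_id = cv$curve_id, time_s = cv$times, a410 = cv$signal,
               inhibitor_nM = cv$inhibitor_conc * 1e9)))
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Read integrated ITC heats from CSV
#'
#' Expects columns `injection`, `volume_uL`, `heat_uJ` and optionally
#' `blank_heat_uJ`; converts to SI (L, J).
#'
#' @param path CSV file path.
#' @return List with `heats` (an `injection_heats`) and `injection_volumes`
#'   (L), ordered by injection index.
#' @export
read_itc_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  require_columns(df, c("injection", "volume_uL", "heat_uJ"), path)
  df <- df[order(df$injection), ]
  blank <- if ("blank_heat_uJ" %in% names(df)) df$blank_heat_uJ * 1e-6 else NULL
  list(heats = injection_heats(df$heat_uJ * 1e-6, blank),
       injection_volumes = df$volume_uL * 1e-6)
}

#' Write integrated ITC heats to CSV
#' @param heats an `injection_heats`.
#' @param injection_volumes per-injection volumes (L).
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_itc_csv <- function(heats, injection_volumes, path) {
  df <- data.frame(injection = seq_len(heats$n_injections),
                   volume_uL = injection_volumes * 1e6,
                   heat_uJ = heats$heats * 1e6)
  if (!is.null(heats$blank_heats)) df$blank_heat_uJ <- heats$blank_heats * 1e6
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Read DSF melt curves from CSV
#'
#' Expects columns `temperature_C`, `fluorescence`, `replicate_id`; one
#' `melt_curve` per replicate, sorted by temperature.
#'
#' @param path CSV file path.
#' @return List of `melt_curve` objects.
#' @export
read_melt_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  require_columns(df, c("temperature_C", "fluorescence", "replicate_id"), path)
  lapply(split(df, df$replicate_id), function(g) {
    g <- g[order(g$temperature_C), ]
    melt_curve(g$temperature_C, g$fluorescence, g$replicate_id[1])
  })
}

#' Write DSF melt curves to CSV
#' @param curves list of `melt_curve` objects.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_melt_csv <- function(curves, path) {
  df <- do.call(rbind, lapply(curves, function(cv)
    data.frame(temperature_C = cv$temperatures, fluorescence = cv$fluorescence,
               replicate_id = cv$replicate_id)))
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Run a simulate-fit-report pipeline on a named fixture
#'
#' Chains the synthetic-data generator for the fixture to the matching
#' fitting stage and returns a machine-readable report (fitted constants
#' with the fixture truths alongside). With `out_dir` set, the report is
#' also written as JSON.
#'
#' @param fixture_name one of the [propkin_fixture()] names.
#' @param seed integer seed for the noise stream (mandatory).
#' @param noise a `sim_noise` template; its seed field is overridden.
#' @param out_dir optional directory for `report_<fixture>.json`.
#' @return The report, a named list.
#' @export
run_pipeline <- function(fixture_name, seed, noise = sim_noise(),
                         out_dir = NULL) {
  if (missing(seed) || !is.finite(seed)) stop("a seed is mandatory")
  fx <- propkin_fixture(fixture_name)
  noise$seed <- as.integer(seed)
  report <- switch(fx$kind,
    progress = {
      curves <- simulate_inhibition_series(fx, noise)
      res <- fit_inhibition_series(curves, fx$design$Et, fx$design)
      list(fixture = fx$name, kind = fx$kind, seed = as.integer(seed),
           ki_app_nM = res$henderson$ki_app * 1e9,
           ki_app_truth_nM = fx$truth$ki_app * 1e9,
           intercept_nM = res$henderson$intercept * 1e9,
           Et_nM = fx$design$Et * 1e9,
           r_squared = res$henderson$r_squared,
           n_curves = res$henderson$n_curves,
           converged = all(vapply(res$fits, function(f) f$converged,
                                  logical(1))))
    },
    itc = {
      heats <- simulate_itc(fx, noise)
      fit <- fit_itc(heats, fx$design)
      list(fixture = fx$name, kind = fx$kind, seed = as.integer(seed),
           n_sites = fit$n_sites, n_truth = fx$truth$n,
           kd_nM = fit$kd * 1e9, kd_truth_nM = fx$truth$kd * 1e9,
           delta_h_kJ_mol = fit$delta_h / 1000,
           delta_h_truth_kJ_mol = fx$truth$delta_h / 1000,
           c_value = fit$c_value,
           conditioning_warning = fit$conditioning_warning,
           converged = fit$converged)
    },
    dsf = {
      cv <- truncate_quench(simulate_melt(fx, noise))
      fit <- fit_melt_sigmoid(cv)
      list(fixture = fx$name, kind = fx$kind, seed = as.integer(seed),
           tm_C = fit$tm, tm_truth_C = fx$truth$tm,
           width_C = fit$a, method = fit$method,
           converged = fit$converged)
    })
  if (!is.null(out_dir)) {
    if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
    jsonlite::write_json(report,
                         file.path(out_dir,
                                   sprintf("report_%s.json", fx$name)),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  report
}
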