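#' Assay design for a chromogenic progress-curve experiment
#'
#' Describes one inhibition-series experiment: a protease acting on a
#' chromogenic peptide substrate (p-nitroaniline release followed at 410 nm)
#' in the presence of a tight, slow-binding inhibitor. All concentrations are
#' molar (SI); times are seconds.
#'
#' @param Et total enzyme concentration (M).
#' @param S0 substrate concentration (M).
#' @param temperature assay temperature (degrees C); metadata only.
#' @param duration length of the recorded window (s).
#' @param sampling_interval time between absorbance readings (s).
#' @param product_extinction molar extinction coefficient of the released
#'   chromophore at 410 nm (M^-1 cm^-1). Default 8800, the accepted value for
#'   free p-nitroaniline.
#' @param path_length optical path (cm).
#' @param A0 baseline absorbance at t = 0 (AU).
#' @param v0_abs uninhibited product-formation velocity on the absorbance
#'   scale (AU/s); the slope of the inhibitor-free trace.
#' @return An object of class `assay_design`.
#' @export
assay_design <- function(Et, S0, temperature = 25, duration = 1800,
                         sampling_interval = 2, product_extinction = 8800,
                         path_length = 1, A0 = 0.02, v0_abs = 2e-4) {
  stopifnot(
    "Et must be a single positive number" = is.numeric(Et) && length(Et) == 1 && Et > 0,
    "S0 must be positive" = is.numeric(S0) && S0 > 0,
    "duration must be positive" = duration > 0,
    "sampling_interval must be positive" = sampling_interval > 0,
    "product_extinction must be positive" = product_extinction > 0,
    "path_length must be positive" = path_length > 0,
    "v0_abs must be positive" = v0_abs > 0
  )
  structure(
    list(Et = Et, S0 = S0, temperature = temperature, duration = duration,
         sampling_interval = sampling_interval,
         product_extinction = product_extinction, path_length = path_length,
         A0 = A0, v0_abs = v0_abs),
    class = "assay_design"
  )
}

#' One chromogenic progress curve at a fixed inhibitor concentration
#'
#' @param curve_id character label.
#' @param inhibitor_conc total inhibitor concentration It (M); 0 for the
#'   uninhibited reference.
#' @param times sampling times (s), strictly increasing, first >= 0.
#' @param signal absorbance at 410 nm (AU), finite.
#' @return An object of class `progress_curve`.
#' @export
progress_curve <- function(curve_id, inhibitor_conc, times, signal) {
  stopifnot(
    "inhibitor_conc must be a single non-negative number" =
      is.numeric(inhibitor_conc) && length(inhibitor_conc) == 1 && inhibitor_conc >= 0,
    "times and signal must have equal length" = length(times) == length(signal),
    "all signal values must be finite" = all(is.finite(signal)),
    "all times must be finite" = all(is.finite(times)),
    "first time must be >= 0" = times[1] >= 0
  )
  if (any(diff(times) <= 0)) stop("times must be strictly increasing")
  structure(
    list(curve_id = as.character(curve_id), inhibitor_conc = inhibitor_conc,
         times = as.numeric(times), signal = as.numeric(signal)),
    class = "progress_curve"
  )
}

#' @export
print.progress_curve <- function(x, ...) {
  cat(sprintf("<progress_curve> %s: It = %.3g nM, %d points over %.0f s\n",
              x$curve_id, x$inhibitor_conc * 1e9, length(x$times),
              max(x$times) - min(x$times)))
  invisible(x)
}

#' Mechanistic ground truth for slow, tight binding
#'
#' Parameterizes one-step association E + I <-> EI under competing substrate:
#' an apparent association rate constant `kon_app` (already reduced by the
#' substrate competition factor) and dissociation rate `koff`. The apparent
#' inhibition constant is their ratio. The progress-curve model fits only
#' (v0, vs, k); these rate constants are the simulator's ground truth.
#'
#' @param kon_app apparent association rate constant (M^-1 s^-1), > 0.
#' @param koff dissociation rate constant (s^-1), >= 0.
#' @return An object of class `slow_binding_params` with derived `ki_app`.
#' @export
slow_binding_params <- function(kon_app, koff) {
  stopifnot("kon_app must be positive" = kon_app > 0,
            "koff must be non-negative" = koff >= 0)
  structure(list(kon_app = kon_app, koff = koff, ki_app = koff / kon_app),
            class = "slow_binding_params")
}

#' ITC titration geometry
#'
#' @param cell_volume active cell volume V0 (L).
#' @param cell_conc concentration of the species in the cell (M).
#' @param syringe_conc titrant concentration in the syringe (M).
#' @param injection_volumes per-injection volumes (L).
#' @param temperature temperature (degrees C); metadata only.
#' @return An object of class `titration_design`.
#' @export
titration_design <- function(cell_volume, cell_conc, syringe_conc,
                             injection_volumes, temperature = 25) {
  stopifnot(
    "cell_volume must be positive" = cell_volume > 0,
    "cell_conc must be positive" = cell_conc > 0,
    "syringe_conc must be positive" = syringe_conc > 0,
    "all injection volumes must be positive" = all(injection_volumes > 0)
  )
  if (sum(injection_volumes) >= cell_volume)
    stop("cumulative injected volume must be smaller than the cell volume")
  structure(
    list(cell_volume = cell_volume, cell_conc = cell_conc,
         syringe_conc = syringe_conc,
         injection_volumes = as.numeric(injection_volumes),
         n_injections = length(injection_volumes),
         temperature = temperature),
    class = "titration_design"
  )
}

#' Integrated per-injection heats
#'
#' Holds the output of peak integration: one signed heat per injection
#' (exothermic negative), optionally paired with blank (titrant-into-buffer)
#' heats for subtraction.
#'
#' @param heats per-injection heats (J), signed.
#' @param blank_heats optional blank heats (J), same length.
#' @return An object of class `injection_heats`.
#' @export
injection_heats <- function(heats, blank_heats = NULL) {
  stopifnot("heats must be finite" = all(is.finite(heats)))
  if (!is.null(blank_heats) && length(blank_heats) != length(heats))
    stop("blank_heats must match heats in length")
  structure(list(heats = as.numeric(heats),
                 blank_heats = if (is.null(blank_heats)) NULL else as.numeric(blank_heats),
                 n_injections = length(heats)),
            class = "injection_heats")
}

#' A DSF fluorescence melting ramp
#'
#' @param temperatures temperatures (degrees C), strictly increasing,
#'   at least 20 points spanning at least 20 degrees.
#' @param fluorescence dye fluorescence (arbitrary units), finite.
#' @param replicate_id character label.
#' @return An object of class `melt_curve`.
#' @export
melt_curve <- function(temperatures, fluorescence, replicate_id = "rep1") {
  stopifnot(
    "temperatures and fluorescence must have equal length" =
      length(temperatures) == length(fluorescence),
    "fluorescence must be finite" = all(is.finite(fluorescence)),
    "need at least 20 points" = length(temperatures) >= 20
  )
  if (any(diff(temperatures) <= 0)) stop("temperatures must be strictly increasing")
  if (diff(range(temperatures)) < 20)
    stop("ramp must span at least 20 degrees C")
  structure(list(temperatures = as.numeric(temperatures),
                 fluorescence = as.numeric(fluorescence),
                 replicate_id = as.character(replicate_id)),
            class = "melt_curve")
}

#' Noise model for the synthetic-data generators
#'
#' Absorbance and fluorescence traces carry multiplicative Gaussian noise;
#' injection heats carry additive Gaussian noise (instrument-limited rather
#' than signal-limited).
#'
#' @param progress_rel_sigma fractional sd on absorbance (default 0.01).
#' @param itc_abs_sigma additive sd on heats in J (default 0.2e-6, i.e. 0.2 uJ).
#' @param dsf_rel_sigma fractional sd on fluorescence (default 0.02).
#' @param seed integer seed, or NULL to draw from the current RNG stream.
#' @return An object of class `sim_noise`.
#' @export
sim_noise <- function(progress_rel_sigma = 0.01, itc_abs_sigma = 0.2e-6,
                      dsf_rel_sigma = 0.02, seed = NULL) {
  stopifnot(progress_rel_sigma >= 0, itc_abs_sigma >= 0, dsf_rel_sigma >= 0)
  structure(list(progress_rel_sigma = progress_rel_sigma,
                 itc_abs_sigma = itc_abs_sigma,
                 dsf_rel_sigma = dsf_rel_sigma, seed = seed),
            class = "sim_noise")
}

#' Zero-noise convenience constructor
#' @return A `sim_noise` object with all sigmas 0.
#' @export
no_noise <- function() sim_noise(0, 0, 0, seed = NULL)

# Run fn with the RNG seeded (and the caller's RNG state restored afterwards)
# when seed is non-NULL; otherwise consume the current stream.
with_seed <- function(seed, fn) {
  if (is.null(seed)) return(fn())
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  fn()
}
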