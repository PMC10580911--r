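# Small published-formula spectroscopy utilities used around the main
# analyses: CD unit conversion, chromogenic activity blank subtraction and
# Beer-Lambert concentration determination.

#' Mean-residue molar ellipticity from observed CD signal
#'
#' `[theta] = theta_obs * MRW / (10 * path * conc)` with `theta_obs` in
#' millidegrees, concentration in g/L (mg/mL) and path in cm; the result is
#' in deg cm^2 dmol^-1.
#'
#' @param theta_obs observed ellipticity (millidegrees); vectorized.
#' @param mean_residue_weight mean residue weight (g/mol).
#' @param concentration protein concentration (g/L).
#' @param path_length optical path (cm).
#' @return Mean-residue molar ellipticity (deg cm^2 dmol^-1).
#' @export
molar_ellipticity <- function(theta_obs, mean_residue_weight,
                              concentration, path_length) {
  if (!is.finite(concentration) || concentration <= 0)
    stop("concentration must be positive")
  if (!is.finite(path_length) || path_length <= 0)
    stop("path_length must be positive")
  if (mean_residue_weight <= 0) stop("mean_residue_weight must be positive")
  theta_obs * mean_residue_weight / (10 * path_length * concentration)
}

#' Control-subtracted chromogenic activity
#'
#' Subtracts the control absorbance (active protease without the test
#' species) from the sample absorbance. Negative results are meaningful:
#' they indicate inhibition relative to the control.
#'
#' @param sample_a440 sample absorbance; vectorized.
#' @param control_a440 matched control absorbance.
#' @return Signed difference, negatives preserved.
#' @export
azocasein_activity <- function(sample_a440, control_a440) {
  if (!all(is.finite(sample_a440)) || !all(is.finite(control_a440)))
    stop("absorbances must be finite")
  sample_a440 - control_a440
}

#' Replicate summary of control-subtracted activities
#'
#' @param sample_reps replicate sample absorbances.
#' @param control_reps replicate control absorbances (same length).
#' @return List with per-replicate differences, `mean` and `sd` (sd of the
#'   differences for paired replicates).
#' @export
azocasein_replicates <- function(sample_reps, control_reps) {
  if (length(sample_reps) != length(control_reps))
    stop("replicate vectors must match in length")
  d <- azocasein_activity(sample_reps, control_reps)
  list(differences = d, mean = mean(d), sd = stats::sd(d))
}

#' Protein concentration from A280 (Beer-Lambert)
#'
#' @param a280 absorbance at 280 nm; vectorized.
#' @param extinction molar extinction coefficient (M^-1 cm^-1), > 0.
#' @param path_length optical path (cm), > 0.
#' @return Concentration (M).
#' @export
conc_from_a280 <- function(a280, extinction, path_length = 1) {
  if (!is.finite(extinction) || extinction <= 0)
    stop("extinction must be positive")
  if (!is.finite(path_length) || path_length <= 0)
    stop("path_length must be positive")
  a280 / (extinction * path_length)
}
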