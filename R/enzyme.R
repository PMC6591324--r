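#' Specific GST activity from CDNB assay kinetics
#'
#' Converts the absorbance slope of the glutathione-CDNB conjugation assay
#' (followed at 344 nm) into specific activity. The product formation rate
#' in mM/min is `delta_a_per_min / (epsilon * path)` with the product's
#' extinction coefficient epsilon = 9.6 mM^-1 cm^-1 by default; 1 mM/min
#' equals 1000 nmol per mL per minute, so
#' `activity = rate * volume_ml * 1000 / protein_mg` in
#' nmol CDNB conjugated / min / mg total protein.
#'
#' @param delta_a_per_min absorbance change per minute at 344 nm (>= 0).
#' @param reaction_volume_ml reaction volume in mL (no default in the
#'   assay protocol; must be supplied).
#' @param protein_mg total protein in the reaction, mg (> 0).
#' @param path_cm cuvette path length in cm.
#' @param epsilon_mm_cm extinction coefficient in mM^-1 cm^-1.
#' @return specific activity, nmol/min/mg.
#' @examples
#' specific_activity(0.0096, reaction_volume_ml = 1, protein_mg = 0.5)  # 2
#' @export
specific_activity <- function(delta_a_per_min, reaction_volume_ml,
                              protein_mg, path_cm = 1,
                              epsilon_mm_cm = 9.6) {
  if (protein_mg <= 0) stop("protein mass must be positive")
  stopifnot(path_cm > 0, epsilon_mm_cm > 0, reaction_volume_ml > 0,
            delta_a_per_min >= 0)
  rate_mm_per_min <- delta_a_per_min / (epsilon_mm_cm * path_cm)
  nmol_per_min <- rate_mm_per_min * reaction_volume_ml * 1000
  nmol_per_min / protein_mg
}
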