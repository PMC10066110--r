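#' Enlarged-vestibular-aqueduct classification thresholds
#'
#' Cincinnati: enlarged if operculum width > 1.9 mm and/or midpoint width
#' > 0.9 mm. Valvassori: enlarged if midpoint width > 1.5 mm. Volumetric:
#' enlarged if VA volume > 15.4 mm^3 (the ROC-derived cutoff). All
#' comparisons are strict, so boundary values classify as normal.
#'
#' @param cincinnati_operculum,cincinnati_midpoint,valvassori_midpoint
#'   diameter thresholds, mm.
#' @param volumetric volume threshold, mm^3.
#' @return A `criteria_thresholds` object.
#' @export
criteria_thresholds <- function(cincinnati_operculum = 1.9,
                                cincinnati_midpoint = 0.9,
                                valvassori_midpoint = 1.5,
                                volumetric = 15.4) {
  vals <- c(cincinnati_operculum, cincinnati_midpoint, valvassori_midpoint,
            volumetric)
  if (any(!is.finite(vals)) || any(vals <= 0))
    stop_vamorph("all thresholds must be positive", class = "vamorph_parameter_error")
  structure(list(cincinnati_operculum = cincinnati_operculum,
                 cincinnati_midpoint = cincinnati_midpoint,
                 valvassori_midpoint = valvassori_midpoint,
                 volumetric = volumetric),
            class = "criteria_thresholds")
}

check_measurement <- function(x, what) {
  if (any(!is.finite(x)) || any(x < 0))
    stop_vamorph("invalid %s: must be finite and >= 0", what,
                 class = "vamorph_measurement_error")
}

#' Classify by the Cincinnati criteria
#'
#' @param midpoint,operculum axial widths in mm (vectorized).
#' @param thresholds a [criteria_thresholds()].
#' @return A data.frame with logical `enlarged` and a `trigger` tag naming
#'   the clause(s) that fired (`"operculum"`, `"midpoint"`,
#'   `"operculum+midpoint"`, or `""`).
#' @export
classify_cincinnati <- function(midpoint, operculum,
                                thresholds = criteria_thresholds()) {
  check_measurement(midpoint, "midpoint width")
  check_measurement(operculum, "operculum width")
  op <- operculum > thresholds$cincinnati_operculum
  mi <- midpoint > thresholds$cincinnati_midpoint
  trigger <- ifelse(op & mi, "operculum+midpoint",
                    ifelse(op, "operculum", ifelse(mi, "midpoint", "")))
  data.frame(enlarged = op | mi, trigger = trigger, stringsAsFactors = FALSE)
}

#' Classify by the Valvassori criterion
#'
#' @param midpoint axial midpoint width in mm (vectorized).
#' @param thresholds a [criteria_thresholds()].
#' @return Logical vector: enlarged iff midpoint > 1.5 mm (strict).
#' @export
classify_valvassori <- function(midpoint, thresholds = criteria_thresholds()) {
  check_measurement(midpoint, "midpoint width")
  midpoint > thresholds$valvassori_midpoint
}

#' Classify by the volumetric criterion
#'
#' @param volume VA volume in mm^3 (vectorized).
#' @param thresholds a [criteria_thresholds()].
#' @return Logical vector: enlarged iff volume > 15.4 mm^3 (strict).
#' @export
classify_volumetric <- function(volume, thresholds = criteria_thresholds()) {
  check_measurement(volume, "volume")
  volume > thresholds$volumetric
}
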