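# Treatment-technique classification.
#
# The DICOM Beam Type carries the static/dynamic distinction: STATIC beams
# are 3D-CRT. DYNAMIC beams are split by whether the gantry rotates during
# delivery — constant gantry angle across the control points means
# intensity modulation at a fixed port (IMRT), a varying angle means an arc
# (VMAT). Rotation during delivery is the defining property of VMAT.

TECHNIQUES <- c("3D-CRT", "IMRT", "VMAT")

# angular span threshold (degrees) below which a dynamic beam counts as
# fixed-gantry
.GANTRY_SPAN_TOL <- 1e-6

#' Classify a treatment beam by technique
#'
#' @param beam a `beam_record` passing [is_treatment_beam()].
#' @return `"3D-CRT"`, `"IMRT"` or `"VMAT"` (never `"MIXED"`).
#' @export
classify_beam <- function(beam) {
  cp <- beam$control_points
  if (nrow(cp) < 2) {
    stop_validation(sprintf("beam %d has fewer than 2 control points",
                            beam$beam_number))
  }
  if (identical(beam$beam_type, "STATIC")) return("3D-CRT")
  ang <- cp$gantry_angle_deg
  # span on the circle: pointwise distance from the first angle
  d <- (ang - ang[1]) %% 360
  d <- pmin(d, 360 - d)
  if (max(d) < .GANTRY_SPAN_TOL) "IMRT" else "VMAT"
}

#' Classify a plan by technique
#'
#' A plan whose treatment beams all share one technique gets that label;
#' otherwise `"MIXED"`. When aggregating, MIXED plans still contribute each
#' beam to its own technique stratum — stratification is per beam.
#'
#' @param plan an `rtplan` with at least one treatment beam.
#' @return `"3D-CRT"`, `"IMRT"`, `"VMAT"` or `"MIXED"`.
#' @export
classify_plan <- function(plan) {
  tb <- Filter(function(b) suppressMessages(is_treatment_beam(b)), plan$beams)
  if (!length(tb)) stop_empty("plan has no treatment beams")
  techs <- unique(vapply(tb, classify_beam, character(1)))
  if (length(techs) == 1L) techs else "MIXED"
}
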