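#' Blind-spot distance from fixation
#'
#' Euclidean distance (degrees of visual angle) between a blind-spot
#' centre and fixation.
#'
#' @param h_deg,v_deg Numeric vectors of field coordinates, degrees.
#' @return Numeric vector of distances in degrees.
#' @examples
#' nbsl_distance(14, -3)   # sqrt(205)
#' @export
nbsl_distance <- function(h_deg, v_deg) {
  sqrt(h_deg^2 + v_deg^2)
}

#' Blind-spot angle relative to the horizontal meridian
#'
#' Polar angle `atan2(v, h)` in degrees, in (-180, 180]. Negative values
#' lie inferior to the horizontal meridian; for a blind spot in the
#' temporal field (h > 0) the angle is small in magnitude.
#'
#' @param h_deg,v_deg Numeric vectors of field coordinates, degrees.
#' @return Numeric vector of angles in degrees.
#' @examples
#' nbsl_angle(14, -2)   # -8.13
#' @export
nbsl_angle <- function(h_deg, v_deg) {
  if (any(h_deg == 0 & v_deg == 0)) {
    stop("nbsl_angle() is undefined at the origin (0, 0)")
  }
  atan2(v_deg, h_deg) * 180 / pi
}

#' Is a blind-spot location the instrument default?
#'
#' The perimeter reports (15, -1) (right-eye format) when the blind-spot
#' test failed or was switched off; a reported (15, -1) is
#' indistinguishable from a true result and is treated as missing
#' downstream.
#'
#' @param h_deg,v_deg Field coordinates in right-eye format, degrees.
#' @return Logical vector.
#' @export
is_default_nbsl <- function(h_deg, v_deg) {
  h_deg == 15 & v_deg == -1
}

#' Transpose left-eye records to right-eye format
#'
#' Mirrors left-eye records about the vertical meridian so that all
#' records share the right-eye field convention (blind spot temporal at
#' positive h). Pattern-deviation columns are always stored on the
#' right-eye location template: for a left-eye record, column `pd_<h>_<v>`
#' holds the value measured at (-h, v) in that eye's true field (the
#' anatomically mirrored location), so only the blind-spot coordinate --
#' which is recorded in true field coordinates, e.g. (-15, -1) for a
#' left-eye default -- needs negating here. Right-eye records pass
#' through unchanged. The `eye` column is set to `"R"`; the original
#' laterality is retained in `eye_original`. The operation is idempotent.
#'
#' @param records A record data frame (see [read_records()]).
#' @return The transposed record data frame.
#' @export
transpose_to_right_eye <- function(records) {
  stopifnot(is.data.frame(records))
  if (is.null(records$eye_original)) records$eye_original <- records$eye
  left <- which(records$eye == "L")
  if (length(left)) {
    records$nbsl_h[left] <- -records$nbsl_h[left]
    records$eye[left] <- "R"
  }
  records
}
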