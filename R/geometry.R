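# Fan-beam acquisition geometry ----------------------------------------

#' Flat-detector fan-beam geometry
#'
#' Source on a circle of radius `sad` around the isocenter, flat
#' detector at `aid` beyond it, uniform view angles over a full 360
#' degree rotation.
#'
#' @param sad Source-to-axis distance in mm.
#' @param aid Axis-to-image-receptor distance in mm.
#' @param n_views Number of views over 360 degrees.
#' @param n_det Number of detector pixels.
#' @param det_pitch Detector pixel pitch in mm.
#' @return Object of class `fan_geometry` with derived fields `sdd`
#'   (source-to-detector distance), `angles` (radians) and `det_u`
#'   (centered detector coordinates, mm).
#' @export
#' @examples
#' fan_beam_geometry(600, 400, 360, 256, 1)
fan_beam_geometry <- function(sad, aid, n_views, n_det, det_pitch) {
  stopifnot(sad > 0, aid > 0, n_views >= 2, n_det >= 2, det_pitch > 0)
  structure(list(
    sad = sad, aid = aid, sdd = sad + aid,
    n_views = as.integer(n_views), n_det = as.integer(n_det),
    det_pitch = det_pitch,
    angles = seq(0, 2 * pi, length.out = n_views + 1)[seq_len(n_views)],
    det_u = (seq_len(n_det) - (n_det + 1) / 2) * det_pitch
  ), class = "fan_geometry")
}

#' @export
print.fan_geometry <- function(x, ...) {
  cat(sprintf(paste0("<fan_geometry> SAD %g mm, AID %g mm (mag %.3g), ",
                     "%d views, %d det px @ %g mm\n"),
              x$sad, x$aid, x$sdd / x$sad, x$n_views, x$n_det, x$det_pitch))
  invisible(x)
}

#' Geometry presets
#'
#' `dental` (SAD 400 mm, AID 200 mm, 0.5-mm detector pitch) and
#' `conventional` (SAD 600 mm, AID 400 mm, 1-mm pitch) presets at either
#' `full` scale (1080 views, 1024 detector pixels) or the faster `test`
#' scale (360 views, 256 detector pixels at four times the pitch, so
#' the detector span and hence the scan field of view are preserved).
#'
#' @param preset "dental" or "conventional".
#' @param scale "full" or "test".
#' @return A `fan_geometry`.
#' @export
geometry_preset <- function(preset = c("conventional", "dental"),
                            scale = c("test", "full")) {
  preset <- match.arg(preset)
  scale <- match.arg(scale)
  p <- switch(preset,
              dental = list(sad = 400, aid = 200, pitch = 0.5),
              conventional = list(sad = 600, aid = 400, pitch = 1.0))
  if (scale == "full") {
    fan_beam_geometry(p$sad, p$aid, 1080, 1024, p$pitch)
  } else {
    fan_beam_geometry(p$sad, p$aid, 360, 256, p$pitch * 4)
  }
}

# field of view diameter (mm) covered by the detector at the isocenter
fov_diameter <- function(geometry) {
  geometry$n_det * geometry$det_pitch * geometry$sad / geometry$sdd
}
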