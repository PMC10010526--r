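# Flat-detector fan-beam filtered backprojection ------------------------

# band-limited ramp convolution kernel (spatial domain), sample pitch du
ramp_kernel <- function(n, du) {
  idx <- c(0:(n / 2), -(n / 2 - 1):-1)
  h <- numeric(n)
  h[idx == 0] <- 1 / (4 * du^2)
  odd <- idx %% 2 != 0
  h[odd] <- -1 / (pi * idx[odd] * du)^2
  h
}

# filter projections (n_det x n_views) sampled at pitch du:
# q = 0.5 * du * conv(p, ramp), linear convolution via padded FFT
filter_projections <- function(p, du, apodization = c("ramp", "hann")) {
  apodization <- match.arg(apodization)
  nd <- nrow(p)
  nfft <- 2^ceiling(log2(2 * nd))
  H <- fft(ramp_kernel(nfft, du))
  if (apodization == "hann") {
    f <- c(seq(0, nfft / 2), seq(nfft / 2 - 1, 1)) / (nfft / 2)
    H <- H * 0.5 * (1 + cos(pi * f))
  }
  pad <- rbind(p, matrix(0, nfft - nd, ncol(p)))
  q <- Re(mvfft(mvfft(pad) * H, inverse = TRUE)) / nfft
  0.5 * du * q[seq_len(nd), , drop = FALSE]
}

#' Fan-beam filtered backprojection (flat detector)
#'
#' Cosine pre-weighting, band-limited ramp filtering (optionally Hann
#' apodized) on the virtual detector at the isocenter, then
#' distance-weighted backprojection over the full 360-degree scan.
#'
#' @param logp Matrix (n_det, n_views) of log projections
#'   (dimensionless line integrals with lengths in cm).
#' @param geometry The `fan_geometry` of the acquisition.
#' @param out_pixel_size Reconstruction pixel size in mm.
#' @param out_n Reconstruction matrix size (default 512).
#' @param apodization "ramp" (default) or "hann".
#' @return Object of class `recon_image`: `values` (out_n x out_n
#'   matrix, 1/cm), `pixel_size` (mm), `units`, and provenance `meta`.
#' @export
fbp_fan <- function(logp, geometry, out_pixel_size, out_n = 512L,
                    apodization = c("ramp", "hann")) {
  apodization <- match.arg(apodization)
  stopifnot(nrow(logp) == geometry$n_det, ncol(logp) == geometry$n_views)
  mag <- geometry$sdd / geometry$sad
  u <- geometry$det_u / mag            # virtual detector at isocenter
  du <- geometry$det_pitch / mag
  w <- geometry$sad / sqrt(geometry$sad^2 + u^2)
  q <- filter_projections(logp * w, du, apodization)
  img <- cpp_backproject_fan(q, geometry$angles, u[1], du, geometry$sad,
                             as.integer(out_n), out_pixel_size)
  dbeta <- 2 * pi / geometry$n_views
  # spatial variables are in mm, so the raw result is mm^-1
  values <- img * dbeta * 10
  structure(list(values = values, pixel_size = out_pixel_size,
                 units = "cm^-1",
                 meta = list(apodization = apodization,
                             n_views = geometry$n_views,
                             n_det = geometry$n_det)),
            class = "recon_image")
}

#' @export
print.recon_image <- function(x, ...) {
  cat(sprintf("<recon_image> %dx%d px at %.3g mm [%s], range [%.4g, %.4g]\n",
              nrow(x$values), ncol(x$values), x$pixel_size, x$units,
              min(x$values), max(x$values)))
  invisible(x)
}

#' Convert a reconstruction from 1/cm to Hounsfield units
#'
#' `HU = 1000 * (mu - mu_water) / mu_water`.  The water reference must
#' match the energy scale of the image: for virtual monochromatic
#' images use `mu_water` at the synthesis energy, for polychromatic
#' uncorrected images the spectrum's mean detected energy.
#'
#' @param image A `recon_image` in 1/cm.
#' @param mu_water Water linear attenuation reference in 1/cm.
#' @return The image with `values` in HU.
#' @export
to_hu <- function(image, mu_water) {
  stopifnot(mu_water > 0)
  image$values <- 1000 * (image$values - mu_water) / mu_water
  image$units <- "HU"
  image$meta$mu_water <- mu_water
  image
}

#' Save / load a reconstruction as 32-bit float TIFF with a JSON side-car
#'
#' Values are min-max normalized into `[0, 1]` for storage (the TIFF
#' writer's domain); the original range is recorded in the side-car and
#' restored on load.
#'
#' @param image A `recon_image`.
#' @param path TIFF path to write.
#' @export
save_recon <- function(image, path) {
  rng <- range(image$values)
  span <- if (diff(rng) > 0) diff(rng) else 1
  tiff::writeTIFF((image$values - rng[1]) / span, path,
                  bits.per.sample = 32L, reduce = FALSE)
  jsonlite::write_json(list(pixel_size_mm = image$pixel_size,
                            units = image$units, range = rng,
                            meta = image$meta),
                       paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname save_recon
#' @export
load_recon <- function(path) {
  vals <- tiff::readTIFF(path)
  meta <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  span <- if (diff(meta$range) > 0) diff(meta$range) else 1
  structure(list(values = vals * span + meta$range[1],
                 pixel_size = meta$pixel_size_mm,
                 units = meta$units, meta = meta$meta),
            class = "recon_image")
}
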