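# End-to-end pipeline ----------------------------------------------------
#
# run_pipeline() reproduces the full comparison on one phantom: simulate
# the two-bin PCD acquisition once, then derive every requested
# correction from that same raw sinogram (paired comparison), alongside
# a monochromatic reference reconstruction.

#' Assemble a run configuration
#'
#' @param phantom A `phantom_image` to scan.
#' @param geometry A `fan_geometry` (default: conventional preset at
#'   test scale).
#' @param kvp Tube potential in kV (default 140).
#' @param extra_al_mm Additional aluminium filtration in mm (default 2).
#' @param thresholds PCD thresholds in keV (default c(20, 90)).
#' @param n0 Blank-scan photons per detector pixel per view.
#' @param seed Integer seed for the Poisson noise, or NULL for a
#'   noise-free run.
#' @param methods Methods to run; subset of
#'   `c("uncorrected", "lmar", "nmar", "vmi_poly", "vmi_atable")`.
#' @param e_vmi Virtual monochromatic energy in keV (default 100; also
#'   the reference energy).
#' @param calib_design A `calibration_design` (default: the 10x10
#'   PMMA 0-50 cm / Al 0-10 cm factorial).
#' @param out_n Reconstruction matrix size.
#' @param out_pixel_size Reconstruction pixel size in mm (default: the
#'   phantom extent divided by `out_n`).
#' @param metal_threshold_hu Metal segmentation threshold (default 3000).
#' @param apodization FBP filter apodization ("ramp" or "hann").
#' @param rois Named list of metric ROIs `c(row0, row1, col0, col1)`.
#' @param profiles Named list of line profiles
#'   `list(p0 = c(x, y), p1 = c(x, y), n = samples)` in mm.
#' @return A `run_config` list.
#' @export
pipeline_config <- function(phantom,
                            geometry = geometry_preset("conventional", "test"),
                            kvp = 140, extra_al_mm = 2,
                            thresholds = c(20, 90),
                            n0 = 1e5, seed = 1L,
                            methods = c("uncorrected", "lmar", "nmar",
                                        "vmi_poly", "vmi_atable"),
                            e_vmi = 100,
                            calib_design = make_calibration_design(),
                            out_n = 256L, out_pixel_size = NULL,
                            metal_threshold_hu = 3000,
                            apodization = "ramp",
                            rois = list(), profiles = list()) {
  methods <- match.arg(methods, several.ok = TRUE)
  if (is.null(out_pixel_size)) {
    out_pixel_size <- nrow(phantom$label_map) * phantom$pixel_size / out_n
  }
  structure(list(phantom = phantom, geometry = geometry, kvp = kvp,
                 extra_al_mm = extra_al_mm, thresholds = thresholds,
                 n0 = n0, seed = seed, methods = methods, e_vmi = e_vmi,
                 calib_design = calib_design, out_n = as.integer(out_n),
                 out_pixel_size = out_pixel_size,
                 metal_threshold_hu = metal_threshold_hu,
                 apodization = apodization, rois = rois,
                 profiles = profiles),
            class = "run_config")
}

#' Run the full simulate / decompose / correct / evaluate pipeline
#'
#' Simulates the two-bin acquisition of the configured phantom, then
#' produces (per requested method) the uncorrected polychromatic
#' reconstruction, LMAR- and NMAR-inpainted reconstructions, and the
#' virtual monochromatic reconstructions from both decomposition
#' algorithms, plus the monochromatic reference at the same energy.
#' All methods consume the identical (optionally noisy) raw sinogram.
#'
#' @param config A `run_config` from [pipeline_config()].
#' @return Object of class `pipeline_result`: list with `reference`
#'   and per-method `images` (HU `recon_image`s), `metrics` (data
#'   frame), `profiles`, `models`, and a `manifest` recording the
#'   configuration, seed, timings and warnings.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  t0 <- Sys.time()
  timings <- numeric()
  tick <- function(stage) {
    dt <- as.numeric(Sys.time() - t0, units = "secs")
    timings[[stage]] <<- dt - sum(timings)
  }

  spectrum <- generate_spectrum(config$kvp)
  if (config$extra_al_mm > 0) {
    spectrum <- apply_filtration(spectrum, "al", config$extra_al_mm / 10)
  }
  detector <- detector_model(config$thresholds[1], config$thresholds[2])
  paths <- trace_paths(config$phantom, config$geometry)
  sino0 <- expected_counts(paths, spectrum, detector, config$n0)
  sino <- if (!is.null(config$seed)) {
    add_poisson_noise(sino0, config$seed)
  } else sino0
  tick("simulate")

  # reference: monochromatic projection at the VMI energy, noise-free
  mu_water_ref <- linear_attenuation("water", config$e_vmi)
  ref <- to_hu(fbp_fan(mono_projection(paths, config$e_vmi),
                       config$geometry, config$out_pixel_size,
                       config$out_n, config$apodization), mu_water_ref)
  tick("reference")

  images <- list()
  models <- list()
  p_total <- total_log_projection(sino)
  needs_uncorr <- any(c("uncorrected", "lmar", "nmar") %in% config$methods)
  if (needs_uncorr) {
    mu_water_poly <- linear_attenuation(
      "water", mean_energy(spectrum, above = config$thresholds[1]))
    uncorr <- to_hu(fbp_fan(p_total, config$geometry,
                            config$out_pixel_size, config$out_n,
                            config$apodization), mu_water_poly)
    if ("uncorrected" %in% config$methods) images$uncorrected <- uncorr
  }
  tick("uncorrected")

  if (any(c("lmar", "nmar") %in% config$methods)) {
    mask <- withCallingHandlers(
      segment_metal(uncorr, config$metal_threshold_hu),
      warning = function(w) invokeRestart("muffleWarning"))
    trace <- if (any(mask$mask)) {
      metal_trace(mask, config$geometry)
    } else matrix(FALSE, config$geometry$n_det, config$geometry$n_views)
    p_lmar <- lmar(p_total, trace)
    lmar_img <- to_hu(fbp_fan(p_lmar, config$geometry,
                              config$out_pixel_size, config$out_n,
                              config$apodization), mu_water_poly)
    if ("lmar" %in% config$methods) {
      images$lmar <- reinsert_metal(lmar_img, mask, uncorr)
    }
    if ("nmar" %in% config$methods) {
      prior <- build_prior(lmar_img)
      p_nmar <- nmar(p_total, trace, prior, config$geometry)
      nmar_img <- to_hu(fbp_fan(p_nmar, config$geometry,
                                config$out_pixel_size, config$out_n,
                                config$apodization), mu_water_poly)
      images$nmar <- reinsert_metal(nmar_img, mask, uncorr)
    }
  }
  tick("mar")

  if (any(c("vmi_poly", "vmi_atable") %in% config$methods)) {
    calib <- simulate_calibration(config$calib_design, spectrum, detector,
                                  config$n0)
    if ("vmi_poly" %in% config$methods) {
      models$poly <- fit_poly(calib)
      thick <- decompose_sinogram(models$poly, sino)
      images$vmi_poly <- to_hu(
        fbp_fan(synthesize_vmi(thick, config$e_vmi), config$geometry,
                config$out_pixel_size, config$out_n, config$apodization),
        mu_water_ref)
    }
    if ("vmi_atable" %in% config$methods) {
      models$atable <- fit_atable(calib)
      thick <- decompose_sinogram(models$atable, sino)
      images$vmi_atable <- to_hu(
        fbp_fan(synthesize_vmi(thick, config$e_vmi), config$geometry,
                config$out_pixel_size, config$out_n, config$apodization),
        mu_water_ref)
    }
  }
  tick("vmi")

  metrics <- metrics_report(ref, images, config$rois)
  profiles <- lapply(config$profiles, function(pr) {
    out <- lapply(c(reference = list(ref), images), function(img) {
      extract_line_profile(img, pr$p0, pr$p1, pr$n)
    })
    out
  })
  tick("evaluate")

  structure(list(reference = ref, images = images, metrics = metrics,
                 profiles = profiles, models = models,
                 manifest = list(
                   seed = config$seed, n0 = config$n0, kvp = config$kvp,
                   e_vmi = config$e_vmi, methods = config$methods,
                   thresholds = config$thresholds,
                   geometry = config$geometry[c("sad", "aid", "n_views",
                                                "n_det", "det_pitch")],
                   timings_s = as.list(round(timings, 3)),
                   version = as.character(utils::packageVersion("pcdct")))),
            class = "pipeline_result")
}

#' @export
print.pipeline_result <- function(x, ...) {
  cat("<pipeline_result>", paste(names(x$images), collapse = ", "), "\n")
  print(x$metrics)
  invisible(x)
}

#' Sample an image along a line segment
#'
#' Bilinear interpolation at `n` uniformly spaced points from `p0` to
#' `p1` (mm coordinates, image center = origin, y up).
#'
#' @param image A `recon_image`.
#' @param p0,p1 Endpoints `c(x, y)` in mm; must lie inside the image.
#' @param n Number of samples (default 200).
#' @return Data frame with columns `s` (distance along the line, mm)
#'   and `value`.
#' @export
extract_line_profile <- function(image, p0, p1, n = 200) {
  v <- as_values(image)
  nn <- nrow(v)
  px <- image$pixel_size
  half <- nn * px / 2
  if (any(abs(c(p0, p1)) > half)) stop("profile endpoint outside the image")
  t <- if (n == 1) 0.5 else seq(0, 1, length.out = n)
  x <- p0[1] + t * (p1[1] - p0[1])
  y <- p0[2] + t * (p1[2] - p0[2])
  # fractional array indices (row from top, col from left)
  ci <- (nn + 1) / 2 + x / px
  ri <- (nn + 1) / 2 - y / px
  ci <- pmin(pmax(ci, 1), nn)
  ri <- pmin(pmax(ri, 1), nn)
  r0 <- pmin(floor(ri), nn - 1)
  c0 <- pmin(floor(ci), nn - 1)
  fr <- ri - r0
  fc <- ci - c0
  val <- (1 - fr) * (1 - fc) * v[cbind(r0, c0)] +
    (1 - fr) * fc * v[cbind(r0, c0 + 1)] +
    fr * (1 - fc) * v[cbind(r0 + 1, c0)] +
    fr * fc * v[cbind(r0 + 1, c0 + 1)]
  data.frame(s = t * sqrt(sum((p1 - p0)^2)), value = val)
}
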