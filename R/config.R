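# YAML run configuration -------------------------------------------------

#' Build a run configuration from a YAML file
#'
#' The YAML mirrors [pipeline_config()] fields; the phantom is declared
#' inline.  Example:
#'
#' ```yaml
#' phantom:
#'   type: anatomy          # disk | mae | anatomy
#'   region: head
#'   pixel_size_mm: 1
#'   metal: default         # default | none, or a list of shapes
#' geometry: {preset: dental, scale: test}
#' kvp: 140
#' n0: 1.0e5
#' seed: 1
#' methods: [uncorrected, lmar, nmar, vmi_poly, vmi_atable]
#' e_vmi: 100
#' out_n: 256
#' ```
#'
#' @param path YAML file path.
#' @return A `run_config`.
#' @export
read_run_config <- function(path) {
  y <- yaml::read_yaml(path)
  ph <- y$phantom
  phantom <- switch(ph$type,
    disk = make_disk_phantom(ph$material %||% "water",
                             ph$radius_mm %||% 50,
                             ph$pixel_size_mm %||% 0.5),
    mae = make_mae_phantom(ph$pixel_size_mm %||% 0.1),
    anatomy = {
      metal <- ph$metal %||% "default"
      ms <- if (identical(metal, "none")) NULL
            else if (identical(metal, "default")) default_metal_spec(ph$region)
            else metal_spec(metal$shapes, metal$material %||% "ti")
      make_anatomy_surrogate(ph$region, ms, ph$pixel_size_mm %||% 1)
    },
    stop("unknown phantom type: ", ph$type))
  geom <- if (!is.null(y$geometry$preset)) {
    geometry_preset(y$geometry$preset, y$geometry$scale %||% "test")
  } else {
    fan_beam_geometry(y$geometry$sad, y$geometry$aid, y$geometry$n_views,
                      y$geometry$n_det, y$geometry$det_pitch)
  }
  args <- list(phantom = phantom, geometry = geom)
  for (f in c("kvp", "extra_al_mm", "n0", "seed", "methods", "e_vmi",
              "out_n", "out_pixel_size", "metal_threshold_hu",
              "apodization")) {
    if (!is.null(y[[f]])) args[[f]] <- y[[f]]
  }
  if (!is.null(y$thresholds)) args$thresholds <- unlist(y$thresholds)
  if (!is.null(y$rois)) args$rois <- lapply(y$rois, unlist)
  if (!is.null(y$profiles)) {
    args$profiles <- lapply(y$profiles, function(p) {
      list(p0 = unlist(p$p0), p1 = unlist(p$p1), n = p$n %||% 200)
    })
  }
  do.call(pipeline_config, args)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Write pipeline outputs to a directory
#'
#' Saves the reference and corrected images as float TIFFs, the metrics
#' table as CSV, the fitted models as JSON, the line profiles as CSV,
#' and the run manifest as JSON.
#'
#' @param result A `pipeline_result`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_pipeline_outputs <- function(result, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  save_recon(result$reference, file.path(dir, "reference.tif"))
  for (nm in names(result$images)) {
    save_recon(result$images[[nm]], file.path(dir, paste0(nm, ".tif")))
  }
  write.csv(result$metrics, file.path(dir, "metrics.csv"), row.names = FALSE)
  for (nm in names(result$models)) {
    save_model(result$models[[nm]], file.path(dir, paste0("model_", nm, ".json")))
  }
  for (nm in names(result$profiles)) {
    prof <- result$profiles[[nm]]
    df <- data.frame(s = prof[[1]]$s)
    for (m in names(prof)) df[[m]] <- prof[[m]]$value
    write.csv(df, file.path(dir, paste0("profile_", nm, ".csv")),
              row.names = FALSE)
  }
  jsonlite::write_json(result$manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}
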