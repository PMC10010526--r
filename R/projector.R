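# Spectral forward projection ------------------------------------------
#
# trace_paths() ray-traces a label map into per-material intersection
# lengths; expected_counts() turns those into per-bin mean photon
# counts via the polychromatic Beer-Lambert model; add_poisson_noise()
# draws the measurement; log_projections() forms the per-bin log
# projections used by reconstruction and decomposition.

#' Per-material path lengths through a phantom
#'
#' Exact Siddon-style grid traversal: each ray's intersection length
#' with every pixel is attributed to that pixel's material.
#'
#' @param phantom A `phantom_image`.
#' @param geometry A `fan_geometry`; the phantom must fit inside its
#'   field of view.
#' @return Object of class `path_sinogram`: `lengths` is an array
#'   (n_det, n_views, n_material) of lengths in cm; `materials` and
#'   `geometry` are carried along.
#' @export
trace_paths <- function(phantom, geometry) {
  extent <- nrow(phantom$label_map) * phantom$pixel_size
  if (extent > fov_diameter(geometry)) {
    stop("phantom extent (", extent, " mm) exceeds the scan field of view (",
         round(fov_diameter(geometry), 1), " mm)")
  }
  lengths <- cpp_trace_paths(phantom$label_map, length(phantom$materials),
                             phantom$pixel_size, geometry$angles,
                             geometry$det_u, geometry$sad, geometry$sdd)
  dimnames(lengths) <- list(NULL, NULL, phantom$materials)
  structure(list(lengths = lengths, materials = phantom$materials,
                 geometry = geometry),
            class = "path_sinogram")
}

#' Expected per-bin photon counts (noise-free)
#'
#' Mean counts `N_k = n0 * sum_E w_k(E) exp(-sum_m mu_m(E) L_m)` with
#' unit-sum spectrum weights `w_k(E)`; blank counts are
#' `N_0k = n0 * sum_E w_k(E)`.  The energy sum runs over the 1-keV
#' spectrum grid.
#'
#' @param paths A `path_sinogram`.
#' @param spectrum A `spectrum`.
#' @param detector A `detector_model`.
#' @param n0 Expected blank-scan photons per detector pixel per view
#'   (total across the spectrum).
#' @return Object of class `binned_sinogram`: `counts` is an array
#'   (n_det, n_views, n_bin) of expected counts, `blank` the per-bin
#'   blank counts; spectrum/detector/geometry are carried along.
#' @export
expected_counts <- function(paths, spectrum, detector, n0 = 1e7) {
  stopifnot(n0 > 0)
  w <- bin_weights(spectrum, detector)
  keep <- which(rowSums(w) > 0)
  mu <- material_mu_matrix(paths$materials, spectrum$energies[keep])
  dm <- dim(paths$lengths)
  L <- matrix(paths$lengths, dm[1] * dm[2], dm[3])
  counts <- matrix(0, dm[1] * dm[2], ncol(w))
  for (i in seq_along(keep)) {
    atten <- exp(-drop(L %*% mu[i, ]))
    for (k in seq_len(ncol(w))) {
      wk <- w[keep[i], k]
      if (wk > 0) counts[, k] <- counts[, k] + wk * atten
    }
  }
  counts <- counts * n0
  dim(counts) <- c(dm[1], dm[2], ncol(w))
  structure(list(counts = counts, blank = unname(n0 * colSums(w)),
                 spectrum = spectrum, detector = detector,
                 geometry = paths$geometry, noisy = FALSE),
            class = "binned_sinogram")
}

#' Replace expected counts by Poisson draws
#'
#' @param sino A `binned_sinogram` of expected counts.
#' @param seed Integer seed; the same seed reproduces the same draw.
#'   The caller's RNG state is left untouched.
#' @return The sinogram with Poisson-distributed integer counts.
#' @export
add_poisson_noise <- function(sino, seed) {
  old <- if (exists(".Random.seed", globalenv())) {
    get(".Random.seed", globalenv())
  }
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  sino$counts[] <- rpois(length(sino$counts), sino$counts)
  sino$noisy <- TRUE
  sino
}

#' Per-bin log projections
#'
#' `P_k = -ln(N_k / N_0k)`; counts are floored (default 0.5 photons)
#' before the log so that photon-starved rays stay finite.
#'
#' @param sino A `binned_sinogram`.
#' @param floor_counts Count floor (default 0.5).
#' @return Array (n_det, n_views, n_bin) of log projections.
#' @export
log_projections <- function(sino, floor_counts = 0.5) {
  p <- sino$counts
  for (k in seq_len(dim(p)[3])) {
    p[, , k] <- -log(pmax(sino$counts[, , k], floor_counts) / sino$blank[k])
  }
  p
}

#' Log projection of the summed (energy-integrated count) signal
#'
#' The conventional single-energy sinogram: all bins pooled before the
#' log, as an energy-blind CT would measure.
#'
#' @inheritParams log_projections
#' @return Matrix (n_det, n_views).
#' @export
total_log_projection <- function(sino, floor_counts = 0.5) {
  tot <- sino$counts[, , 1]
  for (k in seq_len(dim(sino$counts)[3])[-1]) tot <- tot + sino$counts[, , k]
  -log(pmax(tot, floor_counts) / sum(sino$blank))
}

#' Monoenergetic line-integral projection
#'
#' The ideal artifact-free projection `sum_m mu_m(E) L_m` used for
#' reference images and for validating the VMI chain.
#'
#' @param paths A `path_sinogram`.
#' @param energy Photon energy in keV.
#' @return Matrix (n_det, n_views) of dimensionless line integrals.
#' @export
mono_projection <- function(paths, energy) {
  mu <- vapply(paths$materials, function(m) linear_attenuation(m, energy), 1.0)
  dm <- dim(paths$lengths)
  out <- matrix(0, dm[1], dm[2])
  for (m in seq_len(dm[3])) out <- out + mu[m] * paths$lengths[, , m]
  out
}
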