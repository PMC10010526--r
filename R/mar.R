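# Sinogram-inpainting metal artifact reduction --------------------------
#
# The conventional baselines operate on the summed-bin (energy-blind)
# log projection: segment metal in an initial reconstruction, forward
# project the mask to find the metal trace, replace trace samples by
# per-view linear interpolation (LMAR), or interpolate a prior-
# normalized sinogram and denormalize (NMAR).  Outside the trace both
# methods leave the sinogram bit-identical.

#' Segment metal from a reconstructed image
#'
#' @param image A `recon_image` in HU.
#' @param threshold_hu Threshold (default 3000 HU).
#' @return Object of class `metal_mask`: logical matrix `mask` aligned
#'   with the image plus the threshold used.  An empty mask triggers a
#'   warning (MAR then degenerates to the identity).
#' @export
segment_metal <- function(image, threshold_hu = 3000) {
  stopifnot(identical(image$units, "HU"))
  mask <- image$values >= threshold_hu
  if (!any(mask)) warning("no pixels above ", threshold_hu, " HU; empty mask")
  structure(list(mask = mask, threshold_hu = threshold_hu,
                 pixel_size = image$pixel_size),
            class = "metal_mask")
}

#' Metal trace: sinogram support of the metal mask
#'
#' Forward projects the binary mask and marks every ray with a positive
#' metal path length.
#'
#' @param mask A `metal_mask` (or logical matrix).
#' @param geometry A `fan_geometry`.
#' @param pixel_size Pixel size of the mask grid in mm (taken from the
#'   `metal_mask` if available).
#' @param tol Path-length tolerance in cm (default 1e-6).
#' @return Logical matrix (n_det, n_views).
#' @export
metal_trace <- function(mask, geometry, pixel_size = NULL, tol = 1e-6) {
  if (inherits(mask, "metal_mask")) {
    pixel_size <- mask$pixel_size
    mask <- mask$mask
  }
  stopifnot(!is.null(pixel_size))
  lens <- cpp_forward_image(mask + 0, pixel_size, geometry$angles,
                            geometry$det_u, geometry$sad, geometry$sdd)
  lens > tol
}

# per-view linear fill of TRUE runs in `bad`, given values y
fill_runs <- function(y, bad) {
  if (!any(bad)) return(y)
  good <- which(!bad)
  if (!length(good)) return(rep(mean(y), length(y)))  # whole row flagged
  r <- rle(bad)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1
  for (k in which(r$values)) {
    i0 <- starts[k]
    i1 <- ends[k]
    left <- if (i0 > 1) i0 - 1 else NA
    right <- if (i1 < length(y)) i1 + 1 else NA
    if (is.na(left) && is.na(right)) {
      y[i0:i1] <- mean(y[good])
    } else if (is.na(left)) {
      y[i0:i1] <- y[right]
    } else if (is.na(right)) {
      y[i0:i1] <- y[left]
    } else {
      y[i0:i1] <- approx(c(left, right), y[c(left, right)], xout = i0:i1)$y
    }
  }
  y
}

#' Linear-interpolation MAR (LMAR)
#'
#' Within each view, samples inside the metal trace are replaced by 1-D
#' linear interpolation between the nearest non-trace neighbours;
#' everything outside the trace is returned unchanged.
#'
#' @param logp Matrix (n_det, n_views) of log projections.
#' @param trace Logical matrix of the same shape.
#' @return Corrected log projection matrix.
#' @export
lmar <- function(logp, trace) {
  stopifnot(identical(dim(logp), dim(trace)))
  out <- logp
  for (v in seq_len(ncol(logp))) {
    if (any(trace[, v])) out[, v] <- fill_runs(logp[, v], trace[, v])
  }
  out
}

#' Three-class prior image for NMAR
#'
#' Pixels below `thresholds[1]` become air (-1000 HU), pixels between
#' the thresholds become flat soft tissue (`soft_hu`), pixels above
#' retain their original (bone) values.
#'
#' @param image A `recon_image` in HU (typically the LMAR result).
#' @param thresholds Air/soft and soft/bone HU cuts (default -500, 500).
#' @param soft_hu Flat soft-tissue value (default 0 HU).
#' @return A `recon_image` prior in HU.
#' @export
build_prior <- function(image, thresholds = c(-500, 500), soft_hu = 0) {
  stopifnot(identical(image$units, "HU"))
  v <- image$values
  out <- v
  out[v < thresholds[1]] <- -1000
  out[v >= thresholds[1] & v <= thresholds[2]] <- soft_hu
  image$values <- out
  image$meta$prior_thresholds <- thresholds
  image
}

#' Normalized MAR (NMAR)
#'
#' The sinogram is divided by the forward projection of a prior image,
#' linearly interpolated across the metal trace in the normalized
#' domain, and multiplied back.  A +1000 HU offset keeps the prior
#' positive before projection; the offset cancels in the ratio.  Where
#' the prior sinogram vanishes across a trace interval the method falls
#' back to plain LMAR.  Outside the trace the input is restored exactly.
#'
#' @param logp Matrix (n_det, n_views) of log projections.
#' @param trace Logical metal trace of the same shape.
#' @param prior A `recon_image` prior in HU (see [build_prior()]).
#' @param geometry The acquisition `fan_geometry`.
#' @return Corrected log projection matrix.
#' @export
nmar <- function(logp, trace, prior, geometry) {
  stopifnot(identical(prior$units, "HU"))
  pvals <- prior$values + 1000
  psino <- cpp_forward_image(pvals, prior$pixel_size, geometry$angles,
                             geometry$det_u, geometry$sad, geometry$sdd)
  eps <- 1e-6 * max(psino)
  ok <- psino > eps
  norm <- ifelse(ok, logp / pmax(psino, eps), logp)
  filled <- lmar(norm, trace)
  out <- ifelse(ok, filled * psino, filled)
  out[!trace] <- logp[!trace]
  out
}

#' Reinsert metal pixels into a corrected image
#'
#' @param corrected,original `recon_image`s on the same grid.
#' @param mask A `metal_mask` (or logical matrix).
#' @return `corrected` with mask pixels replaced by `original` values.
#' @export
reinsert_metal <- function(corrected, mask, original) {
  if (inherits(mask, "metal_mask")) mask <- mask$mask
  stopifnot(identical(dim(corrected$values), dim(original$values)),
            identical(dim(corrected$values), dim(mask)))
  corrected$values[mask] <- original$values[mask]
  corrected
}
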