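# Image-quality and shape metrics ---------------------------------------

as_values <- function(x) if (inherits(x, "recon_image")) x$values else x

#' Peak signal-to-noise ratio
#'
#' `PSNR = 10 log10(max(f)^2 / MSE(f, g))` with `f` the reference
#' image.  Identical images yield `Inf`.
#'
#' @param f Reference image (matrix or `recon_image`).
#' @param g Test image of the same dimensions.
#' @return PSNR value (dB-like).
#' @export
psnr <- function(f, g) {
  f <- as_values(f)
  g <- as_values(g)
  stopifnot(identical(dim(f), dim(g)))
  mse <- mean((f - g)^2)
  if (mse == 0) return(Inf)
  10 * log10(max(f)^2 / mse)
}

#' Normalized root-mean-square error
#'
#' `sqrt(sum((f - g)^2)) / sqrt(sum(g^2))` - the normalization is by
#' the test (corrected) image `g`.  Set `normalize = "reference"` for
#' the more common reference-normalized variant.
#'
#' @inheritParams psnr
#' @param normalize "test" (default) or "reference".
#' @return NRMSE value (>= 0).
#' @export
nrmse <- function(f, g, normalize = c("test", "reference")) {
  normalize <- match.arg(normalize)
  f <- as_values(f)
  g <- as_values(g)
  stopifnot(identical(dim(f), dim(g)))
  denom <- if (normalize == "test") sum(g^2) else sum(f^2)
  if (denom == 0) stop("normalization image is identically zero")
  sqrt(sum((f - g)^2) / denom)
}

#' Structural similarity (global)
#'
#' Single image-wide moments (means, population variances, covariance):
#' `SSIM = (2 mu_f mu_g + C1)(2 cov + C2) /
#' ((mu_f^2 + mu_g^2 + C1)(var_f + var_g + C2))`.  By default
#' `C1 = (0.01 L)^2`, `C2 = (0.03 L)^2` with `L` the reference dynamic
#' range.
#'
#' @inheritParams psnr
#' @param c1,c2 Stabilization constants; NULL (default) derives them
#'   from the reference dynamic range.
#' @return SSIM value (<= 1).
#' @export
ssim <- function(f, g, c1 = NULL, c2 = NULL) {
  f <- as_values(f)
  g <- as_values(g)
  stopifnot(identical(dim(f), dim(g)))
  L <- diff(range(f))
  if (is.null(c1)) c1 <- (0.01 * L)^2
  if (is.null(c2)) c2 <- (0.03 * L)^2
  mf <- mean(f)
  mg <- mean(g)
  vf <- mean((f - mf)^2)
  vg <- mean((g - mg)^2)
  cfg <- mean((f - mf) * (g - mg))
  (2 * mf * mg + c1) * (2 * cfg + c2) /
    ((mf^2 + mg^2 + c1) * (vf + vg + c2))
}

#' Segment the largest bright component inside a region of interest
#'
#' Thresholds the ROI and returns the largest 4-connected component,
#' e.g. one metal rod for a circularity measurement.
#'
#' @param image A `recon_image` (any units).
#' @param roi Integer vector `c(row0, row1, col0, col1)` (inclusive),
#'   or NULL for the whole image.
#' @param threshold Segmentation threshold in image units.
#' @return Logical matrix over the full image grid with only the
#'   selected component TRUE.
#' @export
segment_rod <- function(image, roi = NULL, threshold) {
  v <- as_values(image)
  if (is.null(roi)) roi <- c(1, nrow(v), 1, ncol(v))
  sub <- v[roi[1]:roi[2], roi[3]:roi[4], drop = FALSE]
  bw <- sub >= threshold
  if (!any(bw)) stop("no pixels above threshold in the ROI")
  lab <- cpp_label_components(bw)
  sizes <- tabulate(lab[lab > 0])
  keep <- lab == which.max(sizes)
  out <- matrix(FALSE, nrow(v), ncol(v))
  out[roi[1]:roi[2], roi[3]:roi[4]] <- keep
  out
}

# marching-squares length of the 0.5-level contour of field z
contour_length <- function(z) {
  nr <- nrow(z)
  nc <- ncol(z)
  total <- 0
  # corner values per cell: a=(i,j) b=(i,j+1) c=(i+1,j+1) d=(i+1,j)
  a <- z[-nr, -nc]
  b <- z[-nr, -1]
  cc <- z[-1, -1]
  d <- z[-1, -nc]
  lev <- 0.5
  # interpolated crossing offsets along each edge (NA if no crossing)
  cross <- function(v1, v2) (lev - v1) / (v2 - v1)
  top <- cross(a, b)     # along +col at row i
  right <- cross(b, cc)  # along +row at col j+1
  bottom <- cross(d, cc) # along +col at row i+1
  left <- cross(a, d)    # along +row at col j
  case <- (a >= lev) + 2 * (b >= lev) + 4 * (cc >= lev) + 8 * (d >= lev)
  seg <- function(x1, y1, x2, y2) sqrt((x2 - x1)^2 + (y2 - y1)^2)
  # segment endpoints per case in cell-local (x=col offset, y=row offset)
  len <- matrix(0, nr - 1, nc - 1)
  add <- function(m, cases, x1, y1, x2, y2) {
    sel <- case %in% cases
    m[sel] <- m[sel] + seg(x1[sel], y1[sel], x2[sel], y2[sel])
    m
  }
  zx <- matrix(0, nr - 1, nc - 1)
  one <- zx + 1
  # single-corner and complementary cases
  len <- add(len, c(1, 14), top, zx, zx, left)
  len <- add(len, c(2, 13), top, zx, one, right)
  len <- add(len, c(4, 11), one, right, bottom, one)
  len <- add(len, c(8, 7), zx, left, bottom, one)
  # edge-pair cases
  len <- add(len, c(3, 12), zx, left, one, right)
  len <- add(len, c(6, 9), top, zx, bottom, one)
  # ambiguous saddles: resolve by the cell-center average
  center <- (a + b + cc + d) / 4
  for (cs in c(5, 10)) {
    sel <- which(case == cs)
    if (!length(sel)) next
    hi <- center[sel] >= lev
    if (cs == 5) {
      l1 <- ifelse(hi,
                   seg(top[sel], 0, 1, right[sel]) +
                     seg(0, left[sel], bottom[sel], 1),
                   seg(top[sel], 0, 0, left[sel]) +
                     seg(bottom[sel], 1, 1, right[sel]))
    } else {
      l1 <- ifelse(hi,
                   seg(top[sel], 0, 0, left[sel]) +
                     seg(bottom[sel], 1, 1, right[sel]),
                   seg(top[sel], 0, 1, right[sel]) +
                     seg(0, left[sel], bottom[sel], 1))
    }
    len[sel] <- len[sel] + l1
  }
  sum(len)
}

#' Circularity from area and perimeter
#'
#' The shape-roundness score `4 pi Area / Perimeter^2`, which is 1 for
#' an ideal circle and `pi/4` for an ideal square (`4 pi a^2 / (4a)^2`).
#'
#' @param area Region area (any consistent units).
#' @param perimeter Region perimeter.
#' @return Circularity value.
#' @export
shape_circularity <- function(area, perimeter) {
  stopifnot(area > 0, perimeter > 0)
  4 * pi * area / perimeter^2
}

#' Circularity of a segmented region
#'
#' [shape_circularity()] of the rasterized region.  Area is the pixel
#' count times the pixel area; the perimeter is the marching-squares
#' length of the 0.5-level contour of the lightly smoothed (3x3 box,
#' applied twice) binary mask, which tracks the underlying shape at
#' sub-pixel accuracy instead of the staircase boundary (accurate for
#' smooth convex regions such as rod cross-sections; sharp corners are
#' slightly rounded).  Values marginally above 1 from discretization
#' are clipped; the raw value is kept in the `"raw"` attribute.
#'
#' @param region Logical matrix (e.g. from [segment_rod()]).
#' @param pixel_size Pixel size in mm (default 1; circularity is scale
#'   free).
#' @return Circularity in (0, 1].
#' @export
circularity <- function(region, pixel_size = 1) {
  stopifnot(any(region))
  area <- sum(region) * pixel_size^2
  z <- region + 0
  # pad so contours of boundary-touching regions close
  z <- rbind(0, cbind(0, z, 0), 0)
  for (pass in 1:2) {
    zp <- rbind(0, cbind(0, z, 0), 0)
    n <- nrow(zp)
    m <- ncol(zp)
    z <- (zp[2:(n - 1), 2:(m - 1)] + zp[1:(n - 2), 2:(m - 1)] +
            zp[3:n, 2:(m - 1)] + zp[2:(n - 1), 1:(m - 2)] +
            zp[2:(n - 1), 3:m] + zp[1:(n - 2), 1:(m - 2)] +
            zp[1:(n - 2), 3:m] + zp[3:n, 1:(m - 2)] + zp[3:n, 3:m]) / 9
  }
  per <- contour_length(z) * pixel_size
  raw <- shape_circularity(area, per)
  structure(min(raw, 1), raw = raw)
}

#' Tabulate PSNR / NRMSE / SSIM for corrected images against a reference
#'
#' One row per method and region of interest, mirroring a standard
#' MAR-comparison table.
#'
#' @param reference A `recon_image` (the artifact-free standard).
#' @param images Named list of corrected `recon_image`s.
#' @param rois Named list of ROIs `c(row0, row1, col0, col1)`; the
#'   whole image is always included as roi "whole".
#' @return Data frame with columns method, roi, psnr, nrmse, ssim.
#' @export
metrics_report <- function(reference, images, rois = list()) {
  ref <- as_values(reference)
  rois <- c(list(whole = c(1, nrow(ref), 1, ncol(ref))), rois)
  rows <- list()
  for (mn in names(images)) {
    g <- as_values(images[[mn]])
    for (rn in names(rois)) {
      r <- rois[[rn]]
      fs <- ref[r[1]:r[2], r[3]:r[4], drop = FALSE]
      gs <- g[r[1]:r[2], r[3]:r[4], drop = FALSE]
      rows[[length(rows) + 1]] <- data.frame(
        method = mn, roi = rn, psnr = psnr(fs, gs),
        nrmse = nrmse(fs, gs), ssim = ssim(fs, gs))
    }
  }
  do.call(rbind, rows)
}
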