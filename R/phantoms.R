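# Digital phantoms ------------------------------------------------------
#
# A phantom is a square label map on a pixel grid whose center is the
# rotation isocenter.  Pixel centers sit at half-integer offsets from
# the center; the row index increases downward (y decreases), the
# column index increases with x.  Label l indexes materials[l].

phantom_image <- function(label_map, materials, pixel_size_mm) {
  stopifnot(nrow(label_map) == ncol(label_map), pixel_size_mm > 0,
            max(label_map) <= length(materials), min(label_map) >= 1)
  structure(list(label_map = label_map, materials = materials,
                 pixel_size = pixel_size_mm),
            class = "phantom_image")
}

#' @export
print.phantom_image <- function(x, ...) {
  cat(sprintf("<phantom_image> %dx%d px at %.3g mm; materials: %s\n",
              nrow(x$label_map), ncol(x$label_map), x$pixel_size,
              paste(x$materials, collapse = ", ")))
  invisible(x)
}

# pixel-center coordinate grids (mm), isocenter at (0, 0), y up
pixel_grids <- function(n, pixel_size) {
  cx <- (seq_len(n) - (n + 1) / 2) * pixel_size
  list(x = matrix(cx, n, n, byrow = TRUE),
       y = matrix(rev(cx), n, n, byrow = FALSE))
}

in_ellipse <- function(g, cx, cy, rx, ry) {
  ((g$x - cx) / rx)^2 + ((g$y - cy) / ry)^2 <= 1
}

#' Geometric metal insert specification
#'
#' @param shapes List of shapes; each shape is a list with `type`
#'   ("disk" or "rect"), `center` (x, y in mm, y up), and `radius` (mm)
#'   for disks or `width`/`height` (mm) for rectangles.
#' @param material Metal material name (e.g. "ti", "cu").
#' @return Object of class `metal_spec`.
#' @export
#' @examples
#' metal_spec(list(list(type = "disk", center = c(-25, -60), radius = 4),
#'                 list(type = "disk", center = c(25, -60), radius = 4)), "ti")
metal_spec <- function(shapes, material = "ti") {
  structure(list(shapes = shapes, material = material), class = "metal_spec")
}

rasterize_metal <- function(spec, g) {
  mask <- matrix(FALSE, nrow(g$x), ncol(g$x))
  for (s in spec$shapes) {
    if (s$type == "disk") {
      mask <- mask | in_ellipse(g, s$center[1], s$center[2], s$radius, s$radius)
    } else if (s$type == "rect") {
      mask <- mask | (abs(g$x - s$center[1]) <= s$width / 2 &
                        abs(g$y - s$center[2]) <= s$height / 2)
    } else stop("unknown shape type: ", s$type)
  }
  mask
}

#' Single disk in air (analytic test fixture)
#'
#' @param material Disk material name.
#' @param radius_mm Disk radius in mm.
#' @param pixel_size_mm Pixel size in mm.
#' @param fov_mm Field of view (grid extent); default `2 * radius + 10`.
#' @return A `phantom_image` with materials `air` and `material`.
#' @export
make_disk_phantom <- function(material, radius_mm, pixel_size_mm,
                              fov_mm = 2 * radius_mm + 10) {
  stopifnot(radius_mm > 0)
  n <- ceiling(fov_mm / pixel_size_mm)
  g <- pixel_grids(n, pixel_size_mm)
  map <- matrix(1L, n, n)
  map[in_ellipse(g, 0, 0, radius_mm, radius_mm)] <- 2L
  phantom_image(map, c("air", material), pixel_size_mm)
}

#' Metal-artifact evaluation phantom: three Cu rods in a PMMA cylinder
#'
#' A 30-mm diameter PMMA disk holding three 5-mm diameter copper rods
#' whose centers sit on a 9-mm radius circle at 90, 210 and 330 degrees.
#'
#' @param pixel_size_mm Pixel size in mm; must be <= 0.2 to resolve the
#'   5-mm rods.
#' @return A `phantom_image` with materials air, pmma, cu.
#' @export
make_mae_phantom <- function(pixel_size_mm = 0.1) {
  if (pixel_size_mm > 0.2) stop("pixel size must be <= 0.2 mm")
  n <- ceiling(40 / pixel_size_mm)
  g <- pixel_grids(n, pixel_size_mm)
  map <- matrix(1L, n, n)
  map[in_ellipse(g, 0, 0, 15, 15)] <- 2L
  for (ang in c(90, 210, 330) * pi / 180) {
    map[in_ellipse(g, 9 * cos(ang), 9 * sin(ang), 2.5, 2.5)] <- 3L
  }
  phantom_image(map, c("air", "pmma", "cu"), pixel_size_mm)
}

#' Anatomical surrogate slices with metal inserts
#'
#' Parameterized geometric stand-ins for head, abdomen and hip CT
#' slices: an elliptical soft-tissue body with bone structures (skull
#' ring, vertebral body, femoral heads and sacrum) and the metal shapes
#' burned in last.  Field of view follows the per-region phantom
#' dimensions (head 256 mm, abdomen 409.6 mm, hip 512 mm).
#'
#' @param region One of "head", "abdomen", "hip".
#' @param metal A `metal_spec`, or NULL for no insert.
#' @param pixel_size_mm Pixel size in mm.
#' @return A `phantom_image` with materials air, soft_tissue, bone and
#'   (when inserted) the metal.
#' @export
make_anatomy_surrogate <- function(region = c("head", "abdomen", "hip"),
                                   metal = NULL, pixel_size_mm = 1) {
  region <- match.arg(region)
  fov <- switch(region, head = 256, abdomen = 409.6, hip = 512)
  n <- ceiling(fov / pixel_size_mm)
  g <- pixel_grids(n, pixel_size_mm)
  map <- matrix(1L, n, n)
  if (region == "head") {
    map[in_ellipse(g, 0, 0, 78, 98)] <- 3L                 # skull
    map[in_ellipse(g, 0, 2, 70, 90)] <- 2L                 # brain
    map[in_ellipse(g, 0, -70, 30, 16)] <- 3L               # jaw / maxilla
    map[in_ellipse(g, 0, -72, 14, 7)] <- 2L
  } else if (region == "abdomen") {
    map[in_ellipse(g, 0, 0, 170, 120)] <- 2L               # body
    map[in_ellipse(g, 0, -70, 22, 18)] <- 3L               # vertebral body
    map[in_ellipse(g, -120, 30, 28, 45)] <- 3L             # rib/iliac hint
    map[in_ellipse(g, 120, 30, 28, 45)] <- 3L
  } else {
    map[in_ellipse(g, 0, 0, 200, 135)] <- 2L               # pelvis body
    map[in_ellipse(g, 0, -50, 45, 35)] <- 3L               # sacrum
    map[in_ellipse(g, -100, 0, 28, 28)] <- 3L              # femoral heads
    map[in_ellipse(g, 100, 0, 28, 28)] <- 3L
  }
  materials <- c("air", "soft_tissue", "bone")
  if (!is.null(metal)) {
    mask <- rasterize_metal(metal, g)
    materials <- c(materials, metal$material)
    map[mask] <- length(materials)
  }
  phantom_image(map, materials, pixel_size_mm)
}

#' Default titanium implant layouts for the anatomy surrogates
#'
#' Two dental-position disks for the head, bilateral prosthesis-sized
#' disks at the femoral heads for the hip, and paired spinal rods for
#' the abdomen.
#'
#' @param region One of "head", "abdomen", "hip".
#' @return A `metal_spec` of titanium shapes.
#' @export
default_metal_spec <- function(region = c("head", "abdomen", "hip")) {
  region <- match.arg(region)
  shapes <- switch(region,
    head = list(list(type = "disk", center = c(-16, -70), radius = 4),
                list(type = "disk", center = c(16, -70), radius = 4)),
    abdomen = list(list(type = "disk", center = c(-14, -70), radius = 4),
                   list(type = "disk", center = c(14, -70), radius = 4)),
    hip = list(list(type = "disk", center = c(-100, 0), radius = 14),
               list(type = "disk", center = c(100, 0), radius = 14)))
  metal_spec(shapes, "ti")
}

#' Full-factorial thickness design for decomposition calibration
#'
#' Equally spaced thickness pairs (including zero) of the two basis
#' materials, emulating a step-wedge calibration phantom measured in
#' slab geometry.
#'
#' @param n1,n2 Number of steps per material (>= 3).
#' @param max1,max2 Maximum thicknesses in cm.
#' @param basis A `basis_pair` (default pmma/al).
#' @return Object of class `calibration_design`: a data frame with
#'   columns `A1`, `A2` (cm) and attributes `n1`, `n2`, `basis`.
#' @export
#' @examples
#' d <- make_calibration_design(10, 10, 50, 10)
#' nrow(d)  # 100
make_calibration_design <- function(n1 = 10, n2 = 10, max1 = 50, max2 = 10,
                                    basis = basis_pair("pmma", "al")) {
  stopifnot(n1 >= 3, n2 >= 3, max1 > 0, max2 > 0)
  t1 <- seq(0, max1, length.out = n1)
  t2 <- seq(0, max2, length.out = n2)
  df <- expand.grid(A1 = t1, A2 = t2, KEEP.OUT.ATTRS = FALSE)
  structure(df, n1 = n1, n2 = n2, basis = basis,
            class = c("calibration_design", "data.frame"))
}

#' Save / load a phantom (16-bit TIFF label map + JSON side-car)
#'
#' The label map round-trips bit-exactly; materials and pixel size are
#' stored in `<path>.json`.
#'
#' @param phantom A `phantom_image`.
#' @param path Path of the TIFF file to write.
#' @export
save_phantom <- function(phantom, path) {
  tiff::writeTIFF((phantom$label_map - 1L) / 65535, path,
                  bits.per.sample = 16L)
  jsonlite::write_json(list(materials = phantom$materials,
                            pixel_size_mm = phantom$pixel_size),
                       paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname save_phantom
#' @export
load_phantom <- function(path) {
  map <- tiff::readTIFF(path)
  meta <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  phantom_image(matrix(as.integer(round(map * 65535)) + 1L,
                       nrow(map), ncol(map)),
                meta$materials, meta$pixel_size_mm)
}
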