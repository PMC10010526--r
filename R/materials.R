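# Embedded linear attenuation tables -----------------------------------
#
# Tables live in inst/extdata/materials/<name>.csv on a 1-150 keV,
# 1 keV grid (columns energy_keV, mu_per_cm).  They were derived from
# published mass attenuation coefficients times standard densities; see
# data-raw/build_material_tables.R for provenance.  Between grid nodes
# attenuation is interpolated linearly in log(mu) vs log(E), because
# away from absorption edges the cross sections are close to power laws
# in energy.

.materials_env <- new.env(parent = emptyenv())

materials_dir <- function() {
  system.file("extdata", "materials", package = "pcdct", mustWork = TRUE)
}

#' List the materials with embedded attenuation tables
#'
#' @return Character vector of material names understood by
#'   [material_table()] (water, soft_tissue, bone, pmma, al, ti, cu, air).
#' @export
#' @examples
#' list_materials()
list_materials <- function() {
  files <- list.files(materials_dir(), pattern = "\\.csv$")
  sort(setdiff(sub("\\.csv$", "", files), "densities"))
}

material_densities <- function() {
  if (is.null(.materials_env$densities)) {
    df <- read.csv(file.path(materials_dir(), "densities.csv"))
    .materials_env$densities <- stats::setNames(df$density_g_cm3, df$material)
  }
  .materials_env$densities
}

#' Load the attenuation table of one material
#'
#' @param name Material name; one of [list_materials()].
#' @return An object of class `material_table` with fields `name`,
#'   `energies` (keV), `mu` (linear attenuation, 1/cm) and `density`
#'   (g/cm^3).
#' @export
#' @examples
#' w <- material_table("water")
#' range(w$energies)
material_table <- function(name) {
  name <- match.arg(name, list_materials())
  key <- paste0("tab_", name)
  if (is.null(.materials_env[[key]])) {
    df <- read.csv(file.path(materials_dir(), paste0(name, ".csv")))
    stopifnot(all(diff(df$energy_keV) > 0), all(df$mu_per_cm > 0))
    .materials_env[[key]] <- structure(
      list(name = name, energies = df$energy_keV, mu = df$mu_per_cm,
           density = unname(material_densities()[name])),
      class = "material_table")
  }
  .materials_env[[key]]
}

#' @export
print.material_table <- function(x, ...) {
  cat(sprintf("<material_table %s> density %.4g g/cm^3, %d energies %g-%g keV\n",
              x$name, x$density, length(x$energies),
              min(x$energies), max(x$energies)))
  invisible(x)
}

as_material <- function(x) {
  if (inherits(x, "material_table")) x else material_table(x)
}

#' Linear attenuation coefficient at arbitrary energies
#'
#' Log-log interpolation of the embedded table; exact at table nodes.
#'
#' @param material A `material_table` or a material name.
#' @param energy Photon energy in keV (vectorized); must lie inside the
#'   table range (1-150 keV).
#' @return Linear attenuation in 1/cm.
#' @export
#' @examples
#' linear_attenuation("water", 100)   # ~0.171 cm^-1
linear_attenuation <- function(material, energy) {
  m <- as_material(material)
  if (any(energy < min(m$energies) | energy > max(m$energies))) {
    stop("energy outside the table range [", min(m$energies), ", ",
         max(m$energies), "] keV")
  }
  exp(approx(log(m$energies), log(m$mu), xout = log(energy))$y)
}

#' Pair of basis materials for two-material decomposition
#'
#' @param m1,m2 Materials (names or `material_table`s); must differ.
#' @return Object of class `basis_pair`.
#' @export
#' @examples
#' basis_pair("pmma", "al")
basis_pair <- function(m1, m2) {
  m1 <- as_material(m1)
  m2 <- as_material(m2)
  if (identical(m1$name, m2$name)) stop("basis materials must differ")
  structure(list(m1 = m1, m2 = m2), class = "basis_pair")
}

#' @export
print.basis_pair <- function(x, ...) {
  cat(sprintf("<basis_pair %s / %s>\n", x$m1$name, x$m2$name))
  invisible(x)
}

# mu values of every material in `names` at the energies of the common
# 1-keV grid, as a matrix (n_energy x n_material)
material_mu_matrix <- function(names, energies) {
  m <- vapply(names, function(nm) linear_attenuation(nm, energies),
              numeric(length(energies)))
  matrix(m, nrow = length(energies), ncol = length(names),
         dimnames = list(NULL, names))
}
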