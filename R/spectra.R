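# Polychromatic tube spectrum and PCD energy binning --------------------

#' Generate a filtered tungsten-anode tube spectrum
#'
#' Kramers bremsstrahlung continuum (relative fluence proportional to
#' `(kvp - E)/E`) with tungsten K characteristic lines at 59.3, 67.2 and
#' 69.1 keV (added when `kvp` exceeds the K edge at 69.5 keV, jointly
#' about 7% of the filtered fluence), hardened by anode self-absorption
#' (modelled as an aluminium-equivalent filter) plus the tube's inherent
#' aluminium filtration, and normalized to unit total fluence.  The bare
#' Kramers law badly overestimates low-energy output because photons
#' generated at depth are absorbed in the target itself; the default
#' 5 mm Al-equivalent self-filtration brings the 140 kV beam to the
#' quality of published tabulated spectra (mean detected energy around
#' 65 keV).  This is a parameterized stand-in with the qualitative shape
#' of a measured spectrum; an externally tabulated spectrum can be
#' supplied via [read_spectrum_csv()] instead.
#'
#' @param kvp Tube potential in kV (40-150).
#' @param grid_step Energy grid step in keV (default 1).
#' @param inherent_al_mm Inherent aluminium filtration in mm (default 1.6).
#' @param anode_self_mm_al Anode self-filtration in mm Al-equivalent
#'   (default 5).
#' @return Object of class `spectrum` with fields `energies` (keV),
#'   `fluence` (unit-sum weights) and `kvp`.
#' @export
#' @examples
#' s <- generate_spectrum(140)
#' sum(s$fluence)
generate_spectrum <- function(kvp, grid_step = 1, inherent_al_mm = 1.6,
                              anode_self_mm_al = 5) {
  if (kvp < 40 || kvp > 150) stop("kvp must lie in [40, 150] kV")
  energies <- seq(1, 150, by = grid_step)
  fluence <- pmax(kvp - energies, 0) / energies
  s <- structure(list(energies = energies, fluence = fluence, kvp = kvp),
                 class = "spectrum")
  if (anode_self_mm_al + inherent_al_mm > 0) {
    s <- apply_filtration(s, "al", (anode_self_mm_al + inherent_al_mm) / 10)
  }
  if (kvp > 69.5) {
    # K-shell fluorescence: K-alpha1 / K-beta1 / K-beta2 with roughly
    # the relative yields of tungsten
    lines <- c(59.3, 67.2, 69.1)
    fracs <- c(0.045, 0.018, 0.007)
    idx <- vapply(lines, function(e) which.min(abs(energies - e)), 1L)
    s$fluence[idx] <- s$fluence[idx] + fracs * sum(s$fluence)
  }
  s$fluence <- s$fluence / sum(s$fluence)
  s
}

#' @export
print.spectrum <- function(x, ...) {
  cat(sprintf("<spectrum %g kVp> mean energy %.1f keV, %d grid points\n",
              x$kvp, mean_energy(x), length(x$energies)))
  invisible(x)
}

#' Monoenergetic spectrum (single delta line)
#'
#' @param energy Line energy in keV.
#' @param grid_step Grid step in keV.
#' @return A `spectrum` whose fluence is 1 at the grid point nearest
#'   `energy` and 0 elsewhere.
#' @export
monoenergetic_spectrum <- function(energy, grid_step = 1) {
  energies <- seq(1, 150, by = grid_step)
  fluence <- numeric(length(energies))
  fluence[which.min(abs(energies - energy))] <- 1
  structure(list(energies = energies, fluence = fluence, kvp = energy),
            class = "spectrum")
}

#' Attenuate a spectrum by a slab of material (Beer-Lambert)
#'
#' @param spectrum A `spectrum`.
#' @param material Material name or `material_table`.
#' @param thickness_cm Slab thickness in cm (>= 0).
#' @param renormalize Rescale to unit sum afterwards (default TRUE;
#'   absolute intensity enters the simulation only through the blank
#'   count `n0`).
#' @return Filtered `spectrum`.
#' @export
apply_filtration <- function(spectrum, material, thickness_cm,
                             renormalize = TRUE) {
  if (thickness_cm < 0) stop("thickness must be >= 0")
  mu <- linear_attenuation(material, spectrum$energies)
  spectrum$fluence <- spectrum$fluence * exp(-mu * thickness_cm)
  if (renormalize && sum(spectrum$fluence) > 0) {
    spectrum$fluence <- spectrum$fluence / sum(spectrum$fluence)
  }
  spectrum
}

#' Mean energy of a spectrum (optionally above a threshold)
#'
#' @param spectrum A `spectrum`.
#' @param above Lower energy cut in keV (default 0).
#' @return Fluence-weighted mean energy in keV.
#' @export
mean_energy <- function(spectrum, above = 0) {
  keep <- spectrum$energies >= above
  sum(spectrum$energies[keep] * spectrum$fluence[keep]) /
    sum(spectrum$fluence[keep])
}

#' Ideal two-bin PCD energy response
#'
#' The detector sorts photons into two bins by comparator thresholds:
#' bin 1 covers `[low, high)` and bin 2 covers `[high, kvp]`.  Energy
#' resolution and detection efficiency are ideal.
#'
#' @param low,high Threshold energies in keV, `low < high`.
#' @return Object of class `detector_model`.
#' @export
#' @examples
#' detector_model(20, 90)
detector_model <- function(low = 20, high = 90) {
  if (!(low < high)) stop("thresholds must satisfy low < high")
  structure(list(thresholds = c(low = low, high = high), n_bins = 2L),
            class = "detector_model")
}

#' @export
print.detector_model <- function(x, ...) {
  cat(sprintf("<detector_model> bins [%g, %g) and [%g, kvp] keV\n",
              x$thresholds[1], x$thresholds[2], x$thresholds[2]))
  invisible(x)
}

#' Per-bin spectral weights
#'
#' Multiplies the spectrum fluence by each bin's indicator response.
#' Columns are a partition: no energy contributes to both bins, and
#' energies below the low threshold contribute to neither.
#'
#' @param spectrum A `spectrum`.
#' @param detector A `detector_model`.
#' @return Matrix (n_energy x 2) of fluence weights per bin.
#' @export
bin_weights <- function(spectrum, detector) {
  e <- spectrum$energies
  low <- detector$thresholds[[1]]
  high <- detector$thresholds[[2]]
  w <- cbind(bin1 = spectrum$fluence * (e >= low & e < high),
             bin2 = spectrum$fluence * (e >= high))
  rownames(w) <- NULL
  w
}

#' Read / write a spectrum as two-column CSV
#'
#' Columns `energy_keV` and `relative_fluence`; the import hook lets an
#' externally generated tabulated spectrum replace the parameterized
#' model.
#'
#' @param path File path.
#' @param kvp Tube potential to record (default: max energy with
#'   nonzero fluence).
#' @return A `spectrum`.
#' @export
read_spectrum_csv <- function(path, kvp = NULL) {
  df <- read.csv(path)
  stopifnot(all(c("energy_keV", "relative_fluence") %in% names(df)))
  fl <- df$relative_fluence / sum(df$relative_fluence)
  if (is.null(kvp)) kvp <- max(df$energy_keV[fl > 0])
  structure(list(energies = df$energy_keV, fluence = fl, kvp = kvp),
            class = "spectrum")
}

#' @rdname read_spectrum_csv
#' @param spectrum A `spectrum` to write.
#' @export
write_spectrum_csv <- function(spectrum, path) {
  write.csv(data.frame(energy_keV = spectrum$energies,
                       relative_fluence = spectrum$fluence),
            path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
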