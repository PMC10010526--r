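# Shared fixtures, memoized so expensive pieces are built once per run.

.fixtures <- new.env(parent = emptyenv())

fixture <- function(name, builder) {
  if (is.null(.fixtures[[name]])) .fixtures[[name]] <- builder()
  .fixtures[[name]]
}

# the study beam: 140 kVp + 2 mm added Al
beam140 <- function() {
  fixture("beam140", function() {
    apply_filtration(generate_spectrum(140), "al", 0.2)
  })
}

pcd2 <- function() detector_model(20, 90)

# noise-free 10x10 PMMA/Al calibration at n0 = 1e7
calib10 <- function() {
  fixture("calib10", function() {
    simulate_calibration(make_calibration_design(10, 10, 50, 10),
                         beam140(), pcd2(), 1e7)
  })
}

poly10 <- function() fixture("poly10", function() fit_poly(calib10()))
atable10 <- function() fixture("atable10", function() fit_atable(calib10()))

geom_test <- function() geometry_preset("dental", "test")

# interior disk mask on an n x n grid with pixel size px
disk_mask <- function(n, px, radius_mm) {
  cx <- (seq_len(n) - (n + 1) / 2) * px
  outer(cx, cx, function(y, x) x^2 + y^2) <= radius_mm^2
}
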