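test_that("metal segmentation thresholds in HU", {
  img <- structure(list(values = matrix(0, 8, 8), pixel_size = 1,
                        units = "HU", meta = list()), class = "recon_image")
  expect_warning(m0 <- segment_metal(img), "empty")
  expect_false(any(m0$mask))
  img$values[3:4, 5] <- 4000
  m <- segment_metal(img)
  expect_equal(sum(m$mask), 2)
  expect_warning(segment_metal(img, 5000), "empty")
})

test_that("metal trace is the sinogram support of the mask", {
  g <- geom_test()
  # empty mask -> empty trace
  empty <- metal_trace(matrix(FALSE, 64, 64), g, pixel_size = 1)
  expect_false(any(empty))
  # centered disk -> constant-width band across views
  n <- 128
  mask <- disk_mask(n, 0.5, 6)
  tr <- metal_trace(mask, g, pixel_size = 0.5)
  widths <- colSums(tr)
  expect_true(all(widths > 0))
  expect_lte(diff(range(widths)), 2)
  # off-center disk -> band center follows the projected center
  cx <- (seq_len(n) - (n + 1) / 2) * 0.5
  mask2 <- outer(rev(cx), cx, function(y, x) (x - 10)^2 + (y - 5)^2 <= 6^2)
  tr2 <- metal_trace(mask2, g, pixel_size = 0.5)
  centers <- apply(tr2, 2, function(col) mean(which(col)))
  # analytic detector coordinate of the projected disk center
  beta <- g$angles
  xr <- 10 * cos(beta) + 5 * sin(beta)
  yr <- -10 * sin(beta) + 5 * cos(beta)
  u <- xr * g$sdd / (g$sad - yr)
  pred <- (u - g$det_u[1]) / g$det_pitch + 1
  expect_lt(max(abs(centers - pred)), 1.5)
})

test_that("LMAR is exact outside the trace and on affine data", {
  set.seed(7)
  p <- matrix(runif(100 * 40), 100, 40)
  none <- matrix(FALSE, 100, 40)
  expect_identical(lmar(p, none), p)
  tr <- none
  tr[30:45, ] <- TRUE
  out <- lmar(p, tr)
  expect_identical(out[!tr], p[!tr])
  # constant and affine sinograms are reproduced exactly inside the trace
  const <- matrix(5, 100, 40)
  expect_equal(lmar(const, tr), const)
  ramp <- matrix(seq_len(100) * 0.2, 100, 40)
  expect_equal(lmar(ramp, tr), ramp, tolerance = 1e-12)
})

test_that("whole-row traces fall back to a mean fill", {
  p <- matrix(rep(c(1, 3), each = 5), 10, 2)
  tr <- matrix(c(rep(TRUE, 10), rep(FALSE, 10)), 10, 2)
  out <- lmar(p, tr)
  expect_equal(out[, 1], rep(mean(p[, 1]), 10))
  expect_identical(out[, 2], p[, 2])
})

test_that("the NMAR prior classifies air, soft tissue and bone", {
  img <- structure(list(values = matrix(c(-900, -100, 200, 900), 2, 2),
                        pixel_size = 1, units = "HU", meta = list()),
                   class = "recon_image")
  pr <- build_prior(img)
  expect_equal(pr$values, matrix(c(-1000, 0, 0, 900), 2, 2))
  air <- img
  air$values[] <- -950
  expect_true(all(build_prior(air)$values == -1000))
})

test_that("NMAR reduces to LMAR under a flat prior and is exact outside", {
  g <- geom_test()
  set.seed(11)
  p <- matrix(runif(g$n_det * g$n_views), g$n_det, g$n_views)
  tr <- matrix(FALSE, g$n_det, g$n_views)
  tr[100:110, ] <- TRUE
  # uniform soft-tissue prior: its sinogram is smooth; outside-trace
  # samples must be untouched bit-exactly
  prior <- structure(list(values = matrix(0, 128, 128), pixel_size = 2,
                          units = "HU", meta = list()),
                     class = "recon_image")
  out <- nmar(p, tr, prior, g)
  expect_identical(out[!tr], p[!tr])
  expect_identical(nmar(p, matrix(FALSE, g$n_det, g$n_views), prior, g), p)
})

test_that("NMAR with a perfect prior beats LMAR on structured data", {
  n <- 160
  gr <- pcdct:::pixel_grids(n, 1)
  map <- matrix(1L, n, n)
  map[(gr$x / 70)^2 + (gr$y / 55)^2 <= 1] <- 2L
  map[((gr$x - 25)^2 + (gr$y - 10)^2) <= 15^2] <- 3L
  ph <- pcdct:::phantom_image(map, c("air", "soft_tissue", "bone"), 1)
  g <- geom_test()
  logp <- mono_projection(trace_paths(ph, g), 70)
  muw <- linear_attenuation("water", 70)
  mus <- c(0, linear_attenuation("soft_tissue", 70),
           linear_attenuation("bone", 70))
  prior <- structure(list(values = 1000 * (matrix(mus[map], n, n) - muw) / muw,
                          pixel_size = 1, units = "HU", meta = list()),
                     class = "recon_image")
  tr <- matrix(FALSE, g$n_det, g$n_views)
  tr[120:140, ] <- TRUE
  e_nmar <- sqrt(mean((nmar(logp, tr, prior, g)[tr] - logp[tr])^2))
  e_lmar <- sqrt(mean((lmar(logp, tr)[tr] - logp[tr])^2))
  expect_lt(e_nmar, e_lmar)
  scale <- sqrt(mean(logp[tr]^2))
  expect_lt(e_nmar / scale, 0.01)
})

test_that("metal reinsertion replaces only mask pixels", {
  a <- structure(list(values = matrix(1, 4, 4), pixel_size = 1,
                      units = "HU", meta = list()), class = "recon_image")
  b <- structure(list(values = matrix(9, 4, 4), pixel_size = 1,
                      units = "HU", meta = list()), class = "recon_image")
  mask <- matrix(FALSE, 4, 4)
  expect_equal(reinsert_metal(a, mask, b)$values, a$values)
  mask[2, 3] <- TRUE
  out <- reinsert_metal(a, mask, b)
  expect_equal(out$values[2, 3], 9)
  expect_equal(sum(out$values), 16 - 1 + 9)
  expect_equal(reinsert_metal(a, matrix(TRUE, 4, 4), b)$values, b$values)
})
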