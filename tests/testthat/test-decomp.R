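test_that("calibration measurements behave physically", {
  cal <- calib10()
  # blank pair
  blank <- cal$A1 == 0 & cal$A2 == 0
  expect_equal(cal$P1[blank], 0, tolerance = 1e-12)
  expect_equal(cal$P2[blank], 0, tolerance = 1e-12)
  # noise-free projections strictly increase in each thickness
  p1 <- matrix(cal$P1, 10, 10)
  p2 <- matrix(cal$P2, 10, 10)
  expect_true(all(apply(p1, 2, diff) > 0))
  expect_true(all(apply(t(p1), 2, diff) > 0))
  expect_true(all(apply(p2, 2, diff) > 0))
  expect_true(all(apply(t(p2), 2, diff) > 0))
})

test_that("monoenergetic bins make the calibration exactly linear", {
  # two delta-line spectrum: fluence at 50 and 100 keV
  s <- monoenergetic_spectrum(50)
  s$fluence[s$energies == 100] <- 1
  s$fluence <- s$fluence / sum(s$fluence)
  s$kvp <- 140
  det <- detector_model(20, 90)
  cal <- simulate_calibration(make_calibration_design(6, 6, 20, 4),
                              s, det, 1e7)
  pm <- fit_poly(cal)
  # quadratic terms vanish and the residual is ~ 0
  expect_lt(max(abs(pm$d1[4:6])), 1e-6)
  expect_lt(max(abs(pm$d2[4:6])), 1e-6)
  expect_lt(max(pm$fit_residual), 1e-8)
  am <- fit_atable(cal)
  expect_lt(max(abs(am$values)), 1e-8)   # dA ~ 0 everywhere
  # apply_atable == mle_estimate in the linear regime
  est1 <- apply_atable(am, cal$P1, cal$P2)
  est2 <- mle_estimate(am, cal$P1, cal$P2)
  expect_equal(est1$A1, est2$A1, tolerance = 1e-7)
  expect_equal(est1$A2, est2$A2, tolerance = 1e-7)
})

test_that("the reverse polynomial recovers a planted quadratic exactly", {
  d1 <- c(0.3, 2.0, -1.1, 0.05, -0.02, 0.01)
  d2 <- c(-0.1, 0.4, 1.7, -0.03, 0.015, -0.005)
  g <- expand.grid(P1 = seq(0, 4, length.out = 8),
                   P2 = seq(0, 3, length.out = 8))
  X <- pcdct:::poly_basis(g$P1, g$P2)
  cal <- data.frame(A1 = drop(X %*% d1), A2 = drop(X %*% d2),
                    P1 = g$P1, P2 = g$P2, N1 = 1, N2 = 1)
  attr(cal, "basis") <- basis_pair("pmma", "al")
  pm <- fit_poly(cal)
  expect_equal(pm$d1, d1, tolerance = 1e-6)
  expect_equal(pm$d2, d2, tolerance = 1e-6)
  expect_lt(max(pm$fit_residual), 1e-9)
})

test_that("polynomial fit on the 10x10 design meets the residual budget", {
  pm <- poly10()
  expect_lt(pm$fit_residual[1], 0.02 * 50)
  expect_lt(pm$fit_residual[2], 0.02 * 10)
  # evaluation at calibration points agrees within a few residuals
  cal <- calib10()
  est <- apply_poly(pm, cal$P1, cal$P2)
  # worst node within a small multiple of the RMS residual
  expect_lt(max(abs(est$A1 - cal$A1)), 10 * pm$fit_residual[1])
  expect_lt(max(abs(est$A2 - cal$A2)), 10 * pm$fit_residual[2])
})

test_that("apply_poly degenerate coefficient cases", {
  b <- basis_pair("pmma", "al")
  zero <- structure(list(d1 = numeric(6), d2 = numeric(6),
                         fit_residual = c(0, 0), basis = b),
                    class = "poly_model")
  expect_equal(apply_poly(zero, 1.3, 2.1), list(A1 = 0, A2 = 0))
  ident <- zero
  ident$d1 <- c(0, 1, 0, 0, 0, 0)
  expect_equal(apply_poly(ident, c(0.5, 2), c(9, 9))$A1, c(0.5, 2))
})

test_that("MLE solves the square linear system independent of weights", {
  am <- atable10()
  A <- c(12, 3.3)
  p <- drop(am$M %*% A)
  est <- mle_estimate(am, p[1], p[2])
  expect_equal(c(est$A1, est$A2), A, tolerance = 1e-10)
  est_w <- mle_estimate(am, p[1], p[2], n1 = 17, n2 = 4200)
  expect_equal(est_w, est)
  ident <- am
  ident$M <- diag(2)
  expect_equal(mle_estimate(ident, 1.2, 0.7), list(A1 = 1.2, A2 = 0.7))
})

test_that("Atable decomposition is exact at every calibration node", {
  cal <- calib10()
  am <- atable10()
  est <- apply_atable(am, cal$P1, cal$P2)
  expect_lt(max(abs(est$A1 - cal$A1)), 1e-9)
  expect_lt(max(abs(est$A2 - cal$A2)), 1e-9)
  # blank node maps to (0, 0)
  blank <- which(cal$A1 == 0 & cal$A2 == 0)
  expect_equal(est$A1[blank], 0, tolerance = 1e-10)
  expect_equal(est$A2[blank], 0, tolerance = 1e-10)
})

test_that("the correction grows toward the deep end of the design", {
  am <- atable10()
  dn <- sqrt(am$values[, 1]^2 + am$values[, 2]^2)
  diag_idx <- (0:9) * 10 + (1:10)
  d <- dn[diag_idx]
  expect_equal(d[1], 0, tolerance = 1e-10)
  # beam hardening accumulates: the deepest node needs the largest
  # correction along the diagonal (the trend is not monotone because
  # the globally fitted M crosses the local slope mid-design)
  expect_equal(which.max(d), 10L)
  expect_gt(d[10], d[2])
})

test_that("decompose_sinogram recovers a basis-material object", {
  ph <- make_disk_phantom("pmma", 40, 0.5)
  g <- geom_test()
  sino <- expected_counts(trace_paths(ph, g), beam140(), pcd2(), 1e7)
  for (model in list(poly10(), atable10())) {
    th <- decompose_sinogram(model, sino)
    expect_equal(dim(th$A1), c(g$n_det, g$n_views))
    # Al channel near zero: the object is pure PMMA (plus air)
    expect_lt(mean(abs(th$A2)), 0.05 * mean(th$A1[th$A1 > 0.1]))
    # PMMA channel tracks the traced path length through the disk
    # (off-disk rays carry the fit's intercept error, which for the
    # global polynomial is of the order of its residual)
    L <- trace_paths(ph, g)$lengths[, , "pmma"]
    hit <- L > 0.5
    expect_lt(median(abs(th$A1 - L)[hit]), 0.1)
    expect_lt(max(abs(th$A1 - L)[hit]), 0.6)
  }
})

test_that("VMI synthesis is the stated linear combination", {
  b <- basis_pair("pmma", "al")
  th <- structure(list(A1 = matrix(c(1, 2, 0, 4), 2),
                       A2 = matrix(c(0.5, 0, 1, 2), 2),
                       basis = b, outside_frac = 0),
                  class = "thickness_sinogram")
  v <- synthesize_vmi(th, 100)
  mu1 <- linear_attenuation("pmma", 100)
  mu2 <- linear_attenuation("al", 100)
  expect_equal(v, mu1 * th$A1 + mu2 * th$A2)
  # single-material limit and linearity in thickness
  th0 <- th
  th0$A2[] <- 0
  expect_equal(synthesize_vmi(th0, 80), linear_attenuation("pmma", 80) * th$A1)
  th2 <- th
  th2$A1 <- 2 * th$A1
  th2$A2 <- 2 * th$A2
  expect_equal(synthesize_vmi(th2, 100), 2 * v)
  # negative thicknesses kept unless clipping is requested
  thn <- th
  thn$A1[1, 1] <- -1
  expect_equal(synthesize_vmi(thn, 100)[1, 1], -mu1 + mu2 * 0.5)
  expect_equal(synthesize_vmi(thn, 100, clip_negative = TRUE)[1, 1],
               mu2 * 0.5)
})

test_that("decomposition models round-trip through JSON", {
  f <- tempfile(fileext = ".json")
  on.exit(unlink(f))
  save_model(poly10(), f)
  pm <- load_model(f)
  expect_s3_class(pm, "poly_model")
  expect_equal(pm$d1, poly10()$d1)
  save_model(atable10(), f)
  am <- load_model(f)
  expect_s3_class(am, "atable_model")
  expect_equal(am$M, atable10()$M)
  expect_equal(am$nodes, atable10()$nodes)
  # restored model decomposes identically
  cal <- calib10()
  e0 <- apply_atable(atable10(), cal$P1[15], cal$P2[15])
  e1 <- apply_atable(am, cal$P1[15], cal$P2[15])
  expect_equal(e1, e0)
})

test_that("with noise, node estimates are unbiased where counts are moderate", {
  cal <- calib10()
  am <- atable10()
  node <- which(cal$A1 == sort(unique(cal$A1))[5] &
                  cal$A2 == sort(unique(cal$A2))[5])
  n0 <- 1e5
  blank <- attr(cal, "blank") / 1e7 * n0
  lam <- exp(-c(cal$P1[node], cal$P2[node])) * blank
  set.seed(1)
  reps <- 500
  N1 <- pmax(rpois(reps, lam[1]), 0.5)
  N2 <- pmax(rpois(reps, lam[2]), 0.5)
  est <- apply_atable(am, -log(N1 / blank[1]), -log(N2 / blank[2]))
  se <- c(sd(est$A1), sd(est$A2)) / sqrt(reps)
  expect_lt(abs(mean(est$A1) - cal$A1[node]), 3 * se[1])
  expect_lt(abs(mean(est$A2) - cal$A2[node]), 3 * se[2])
})
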