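# Projection-based two-material decomposition ---------------------------
#
# Calibration measurements are simulated in slab geometry: a thickness
# pair (A1, A2) of the basis materials produces per-bin log projections
# through the same polychromatic Beer-Lambert model as the projector.
# Two decomposition algorithms invert the (P1, P2) -> (A1, A2) map:
#
#  * the reverse polynomial model fits each thickness on the quadratic
#    basis {1, P1, P2, P1^2, P1*P2, P2^2};
#  * the "Atable" model fits an effective 2x2 linear attenuation matrix
#    M (P ~ M A, no intercept), inverts it per ray by weighted maximum
#    likelihood, and corrects the residual beam-hardening bias with a
#    look-up table of corrections dA = A_calib - A_MLE tabulated at the
#    calibration points' own MLE estimates.

#' Simulate slab-geometry calibration measurements
#'
#' For every thickness pair of the design, per-bin expected counts are
#' computed in closed form (no ray tracing) and optionally replaced by
#' a Poisson draw.
#'
#' @param design A `calibration_design`.
#' @param spectrum A `spectrum`.
#' @param detector A `detector_model`.
#' @param n0 Blank-scan photons per measurement.
#' @param seed Integer seed for Poisson noise, or NULL (default) for
#'   noise-free means.
#' @param floor_counts Count floor applied before the log of noisy
#'   draws (noise-free means are positive and used as-is).
#' @return Object of class `calibration_set`: a data frame with columns
#'   `A1`, `A2` (cm), `P1`, `P2`, `N1`, `N2`, plus attributes `basis`,
#'   `n1`, `n2`, `blank`.
#' @export
simulate_calibration <- function(design, spectrum, detector, n0 = 1e7,
                                 seed = NULL, floor_counts = 0.5) {
  basis <- attr(design, "basis")
  w <- bin_weights(spectrum, detector)
  keep <- which(rowSums(w) > 0)
  e <- spectrum$energies[keep]
  mu1 <- linear_attenuation(basis$m1, e)
  mu2 <- linear_attenuation(basis$m2, e)
  atten <- exp(-outer(design$A1, mu1) - outer(design$A2, mu2))
  counts <- n0 * atten %*% w[keep, ]                 # n_pairs x 2
  blank <- unname(n0 * colSums(w))
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", globalenv())) {
      get(".Random.seed", globalenv())
    }
    on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
    set.seed(seed)
    counts[] <- rpois(length(counts), counts)
    counts <- pmax(counts, floor_counts)
  }
  p <- -log(sweep(counts, 2, blank, "/"))
  df <- data.frame(A1 = design$A1, A2 = design$A2,
                   P1 = p[, 1], P2 = p[, 2],
                   N1 = counts[, 1], N2 = counts[, 2])
  structure(df, basis = basis, n1 = attr(design, "n1"),
            n2 = attr(design, "n2"), blank = blank,
            class = c("calibration_set", "data.frame"))
}

poly_basis <- function(p1, p2) {
  cbind(1, p1, p2, p1^2, p1 * p2, p2^2)
}

#' Fit the reverse polynomial decomposition model
#'
#' Least-squares fit of each basis-material thickness on the six-term
#' quadratic basis of the two bin log projections.
#'
#' @param calib A `calibration_set` with at least 6 points.
#' @return Object of class `poly_model` with coefficient vectors `d1`,
#'   `d2` and the per-channel RMS thickness residual `fit_residual`
#'   (cm) on the calibration points.
#' @export
fit_poly <- function(calib) {
  stopifnot(nrow(calib) >= 6)
  X <- poly_basis(calib$P1, calib$P2)
  fit <- lm.fit(X, cbind(calib$A1, calib$A2))
  if (fit$rank < 6) stop("calibration design is rank-deficient in (P1, P2)")
  res <- sqrt(colMeans(fit$residuals^2))
  structure(list(d1 = unname(fit$coefficients[, 1]),
                 d2 = unname(fit$coefficients[, 2]),
                 fit_residual = unname(res),
                 basis = attr(calib, "basis")),
            class = "poly_model")
}

#' @export
print.poly_model <- function(x, ...) {
  cat(sprintf("<poly_model> RMS calibration residual %.4g / %.4g cm\n",
              x$fit_residual[1], x$fit_residual[2]))
  invisible(x)
}

#' Evaluate the reverse polynomial model
#'
#' @param model A `poly_model`.
#' @param p1,p2 Bin log projections (vectorized).
#' @return List with vectors `A1`, `A2` (cm); no clipping is applied.
#' @export
apply_poly <- function(model, p1, p2) {
  X <- poly_basis(p1, p2)
  list(A1 = drop(X %*% model$d1), A2 = drop(X %*% model$d2))
}

#' Fit the linear-MLE decomposition model with error-correction LUT
#'
#' The effective attenuation matrix `M` is the no-intercept least
#' squares solution of `P_calib ~ M A_calib` over the design.  Each
#' calibration point is then decomposed by the linear MLE and the
#' correction `dA = A_calib - A_MLE` is stored at the node `A_MLE`,
#' giving a deformed-grid look-up table in MLE space.
#'
#' @param calib A `calibration_set` from a factorial design (the grid
#'   structure indexes the LUT mesh).
#' @return Object of class `atable_model` with the 2x2 matrix `M`
#'   (1/cm), LUT `nodes` (A_MLE of the calibration points, n x 2) and
#'   `values` (dA, n x 2), and the design dimensions.
#' @export
fit_atable <- function(calib) {
  stopifnot(nrow(calib) >= 3)
  A <- cbind(calib$A1, calib$A2)
  P <- cbind(calib$P1, calib$P2)
  fit <- lm.fit(A, P)
  if (fit$rank < 2) stop("singular calibration design")
  M <- t(unname(fit$coefficients))            # P ~ M %*% A
  a_mle <- t(solve(M, t(P)))                  # exact for a square system
  structure(list(M = M, nodes = a_mle, values = A - a_mle,
                 n1 = attr(calib, "n1"), n2 = attr(calib, "n2"),
                 basis = attr(calib, "basis")),
            class = "atable_model")
}

#' @export
print.atable_model <- function(x, ...) {
  cat("<atable_model> M =\n")
  print(signif(x$M, 4))
  cat(sprintf("  LUT: %d nodes (max |dA| = %.3g cm)\n",
              nrow(x$nodes), max(abs(x$values))))
  invisible(x)
}

#' Linear maximum-likelihood thickness estimate
#'
#' Weighted least squares `(M' R^-1 M)^-1 M' R^-1 P` with the
#' first-order Poisson covariance `R = diag(1/N1, 1/N2)` of the log
#' projections.  For the square two-bin system the estimate reduces to
#' `M^-1 P` and is independent of the weights.
#'
#' @param model An `atable_model`.
#' @param p1,p2 Bin log projections (vectorized).
#' @param n1,n2 Measured counts for the covariance (optional; ignored
#'   for the square system).
#' @return List with vectors `A1`, `A2` (cm).
#' @export
mle_estimate <- function(model, p1, p2, n1 = NULL, n2 = NULL) {
  Minv <- solve(model$M)
  list(A1 = Minv[1, 1] * p1 + Minv[1, 2] * p2,
       A2 = Minv[2, 1] * p1 + Minv[2, 2] * p2)
}

# separable bilinear interpolation of grid z (n1 x n2) at fractional
# index coordinates (gi, gj) (1-based).  Piecewise-linear is preferred
# over higher-order stencils here because the correction field is
# strongly curved near the thin-thickness edge of the mesh, where
# cubic interpolants overshoot.
bilinear_grid <- function(z, gi, gj) {
  n1 <- nrow(z)
  n2 <- ncol(z)
  i0 <- pmin(pmax(floor(gi), 1L), n1 - 1L)
  j0 <- pmin(pmax(floor(gj), 1L), n2 - 1L)
  fi <- gi - i0
  fj <- gj - j0
  (1 - fi) * (1 - fj) * z[cbind(i0, j0)] +
    fi * (1 - fj) * z[cbind(i0 + 1L, j0)] +
    (1 - fi) * fj * z[cbind(i0, j0 + 1L)] +
    fi * fj * z[cbind(i0 + 1L, j0 + 1L)]
}

# Interpolation of the dA field over the deformed calibration lattice
# in A_MLE space.  Nodes form an (n1 x n2) structured mesh (design
# order: A1 fastest); each query point is located in a quad cell, the
# bilinear cell map is inverted by Newton iteration for local
# coordinates, and the correction is interpolated bilinearly (exact at
# nodes).  Queries outside every cell fall back to the nearest node.
lut_interpolate <- function(model, q1, q2) {
  n1 <- model$n1
  n2 <- model$n2
  nx <- model$nodes[, 1]
  ny <- model$nodes[, 2]
  z1 <- matrix(model$values[, 1], n1, n2)
  z2 <- matrix(model$values[, 2], n1, n2)
  nq <- length(q1)
  gi <- rep(NA_real_, nq)
  gj <- rep(NA_real_, nq)
  idx <- function(i, j) (j - 1L) * n1 + i
  tol <- 1e-9 * (max(abs(nx)) + max(abs(ny)))
  for (j in seq_len(n2 - 1L)) {
    for (i in seq_len(n1 - 1L)) {
      k <- c(idx(i, j), idx(i + 1L, j), idx(i + 1L, j + 1L), idx(i, j + 1L))
      px <- nx[k]
      py <- ny[k]
      open <- which(is.na(gi))
      if (!length(open)) break
      # point-in-convex-quad via cross products (counter-clockwise cell)
      inside <- rep(TRUE, length(open))
      for (e in 1:4) {
        e2 <- e %% 4 + 1
        cr <- (px[e2] - px[e]) * (q2[open] - py[e]) -
              (py[e2] - py[e]) * (q1[open] - px[e])
        inside <- inside & (cr >= -tol)
      }
      sel <- open[inside]
      if (!length(sel)) next
      # invert bilinear map x(s,t) for local coordinates
      s <- rep(0.5, length(sel))
      t <- rep(0.5, length(sel))
      for (it in 1:12) {
        b0 <- (1 - s) * (1 - t)
        b1 <- s * (1 - t)
        b2 <- s * t
        b3 <- (1 - s) * t
        fx <- b0 * px[1] + b1 * px[2] + b2 * px[3] + b3 * px[4] - q1[sel]
        fy <- b0 * py[1] + b1 * py[2] + b2 * py[3] + b3 * py[4] - q2[sel]
        dxds <- (1 - t) * (px[2] - px[1]) + t * (px[3] - px[4])
        dxdt <- (1 - s) * (px[4] - px[1]) + s * (px[3] - px[2])
        dyds <- (1 - t) * (py[2] - py[1]) + t * (py[3] - py[4])
        dydt <- (1 - s) * (py[4] - py[1]) + s * (py[3] - py[2])
        det <- dxds * dydt - dxdt * dyds
        det[abs(det) < 1e-300] <- 1e-300
        s <- s - (fx * dydt - fy * dxdt) / det
        t <- t - (fy * dxds - fx * dyds) / det
      }
      gi[sel] <- i + pmin(pmax(s, 0), 1)
      gj[sel] <- j + pmin(pmax(t, 0), 1)
    }
  }
  miss <- which(is.na(gi))
  hit <- which(!is.na(gi))
  out1 <- numeric(nq)
  out2 <- numeric(nq)
  if (length(hit)) {
    out1[hit] <- bilinear_grid(z1, gi[hit], gj[hit])
    out2[hit] <- bilinear_grid(z2, gi[hit], gj[hit])
  }
  if (length(miss)) {
    for (m in miss) {
      d2 <- (nx - q1[m])^2 + (ny - q2[m])^2
      kk <- which.min(d2)
      out1[m] <- model$values[kk, 1]
      out2[m] <- model$values[kk, 2]
    }
  }
  list(dA1 = out1, dA2 = out2, n_outside = length(miss))
}

#' Decompose log projections with the Atable model
#'
#' `A = A_MLE + dA(A_MLE)`: the linear MLE estimate plus the
#' interpolated error correction.
#'
#' @inheritParams mle_estimate
#' @return List with vectors `A1`, `A2` (cm) and `n_outside`, the
#'   number of queries outside the LUT mesh (corrected with the nearest
#'   node).
#' @export
apply_atable <- function(model, p1, p2, n1 = NULL, n2 = NULL) {
  mle <- mle_estimate(model, p1, p2, n1, n2)
  corr <- lut_interpolate(model, mle$A1, mle$A2)
  list(A1 = mle$A1 + corr$dA1, A2 = mle$A2 + corr$dA2,
       n_outside = corr$n_outside)
}

#' Decompose a full two-bin sinogram into basis-material thicknesses
#'
#' @param model A `poly_model` or `atable_model`.
#' @param sino A `binned_sinogram` (two bins).
#' @param floor_counts Count floor before the log.
#' @return Object of class `thickness_sinogram`: matrices `A1`, `A2`
#'   (n_det x n_views, cm), the basis pair, and `outside_frac` (Atable
#'   only) - the fraction of rays whose MLE fell outside the LUT mesh.
#' @export
decompose_sinogram <- function(model, sino, floor_counts = 0.5) {
  stopifnot(dim(sino$counts)[3] == 2)
  p <- log_projections(sino, floor_counts)
  dm <- dim(p)
  p1 <- as.vector(p[, , 1])
  p2 <- as.vector(p[, , 2])
  if (inherits(model, "poly_model")) {
    a <- apply_poly(model, p1, p2)
    outside <- NA_real_
  } else if (inherits(model, "atable_model")) {
    a <- apply_atable(model, p1, p2,
                      as.vector(sino$counts[, , 1]),
                      as.vector(sino$counts[, , 2]))
    outside <- a$n_outside / length(p1)
  } else stop("unknown decomposition model")
  structure(list(A1 = matrix(a$A1, dm[1], dm[2]),
                 A2 = matrix(a$A2, dm[1], dm[2]),
                 basis = model$basis, outside_frac = outside),
            class = "thickness_sinogram")
}

#' Synthesize a virtual monochromatic sinogram
#'
#' `P(E) = mu_m1(E) A_m1 + mu_m2(E) A_m2`: an ideal single-energy
#' projection free of beam hardening.  Negative thicknesses are kept by
#' default; clipping them biases the ramp-filtered reconstruction.
#'
#' @param thick A `thickness_sinogram`.
#' @param energy Virtual monochromatic energy in keV (default 100).
#' @param clip_negative Zero negative thicknesses first (default FALSE).
#' @return Matrix (n_det, n_views) of monochromatic log projections.
#' @export
synthesize_vmi <- function(thick, energy = 100, clip_negative = FALSE) {
  mu1 <- linear_attenuation(thick$basis$m1, energy)
  mu2 <- linear_attenuation(thick$basis$m2, energy)
  a1 <- thick$A1
  a2 <- thick$A2
  if (clip_negative) {
    a1 <- pmax(a1, 0)
    a2 <- pmax(a2, 0)
  }
  mu1 * a1 + mu2 * a2
}

#' Serialize / restore a fitted decomposition model as JSON
#'
#' @param model A `poly_model` or `atable_model`.
#' @param path JSON file path.
#' @export
save_model <- function(model, path) {
  obj <- unclass(model)
  obj$basis <- c(obj$basis$m1$name, obj$basis$m2$name)
  obj$class <- class(model)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname save_model
#' @export
load_model <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  cls <- obj$class
  obj$class <- NULL
  obj$basis <- basis_pair(obj$basis[1], obj$basis[2])
  structure(obj, class = cls)
}
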