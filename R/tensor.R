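#' Fit the diffusion tensor per voxel
#'
#' Log-linear least-squares fit of the single diffusion tensor, followed by
#' one weighted re-fit with weights equal to the squared predicted signal
#' (standard WLLS). Only volumes with `b <= max_b` enter the fit; the default
#' `max_b = 1000` keeps the low-b shells where the Gaussian tensor model
#' holds. Signals at or below zero are clamped to `1e-6 * S0` before the log.
#'
#' @param signal 4-D array (x, y, z, volume) or a matrix (voxel x volume).
#' @param gtab a `gradient_table` matching the last dimension.
#' @param mask logical array over the spatial grid (default: all voxels).
#' @param max_b highest b-value used in the fit (s/mm^2).
#' @return object of class `dti_fit`: `tensor6` array `(x,y,z,6)` with
#'   elements Dxx, Dyy, Dzz, Dxy, Dxz, Dyz (mm^2/s), `S0` map, logical
#'   `npd` flag map marking voxels whose fitted tensor is not positive
#'   semi-definite, and the `mask`.
#' @export
fit_tensor <- function(signal, gtab, mask = NULL, max_b = 1000) {
  validate_gradient_table(gtab)
  dm_full <- dim(signal)
  if (length(dm_full) == 4) {
    dm <- dm_full[1:3]
    Y <- matrix(signal, prod(dm), dm_full[4])
  } else if (length(dm_full) == 2) {
    dm <- c(dm_full[1], 1L, 1L)
    Y <- signal
  } else stop("signal must be 4-D (x,y,z,volume) or voxel x volume")
  if (ncol(Y) != n_volumes(gtab)) {
    stop("volume count mismatch: signal has ", ncol(Y), ", gradient table ",
         n_volumes(gtab))
  }
  keep <- gtab$bvals <= max_b
  b <- gtab$bvals[keep]
  g <- gtab$bvecs[keep, , drop = FALSE]
  if (sum(b > 0) < 6 || !any(b == 0)) {
    stop("need >= 6 diffusion-weighted volumes and >= 1 b = 0 at b <= max_b")
  }
  # design: log S = log S0 - b g' D g, 7 coefficients
  X <- cbind(1,
             -b * g[, 1]^2, -b * g[, 2]^2, -b * g[, 3]^2,
             -2 * b * g[, 1] * g[, 2],
             -2 * b * g[, 1] * g[, 3],
             -2 * b * g[, 2] * g[, 3])
  qrX <- qr(X)
  if (qrX$rank < 7) {
    bad <- setdiff(seq_len(7), qrX$pivot[seq_len(qrX$rank)])
    stop("rank-deficient tensor design (fewer than 6 independent ",
         "directions); aliased columns: ", paste(bad, collapse = ", "))
  }
  if (is.null(mask)) mask <- array(TRUE, dim = dm)
  vox <- which(as.vector(mask))

  Yk <- Y[vox, keep, drop = FALSE]
  s0_guess <- rowMeans(Yk[, b == 0, drop = FALSE])
  floor_val <- pmax(1e-6 * s0_guess, .Machine$double.xmin)
  Yc <- pmax(Yk, matrix(floor_val, nrow(Yk), ncol(Yk)))
  L <- log(Yc)
  # OLS pass (shared design): coef = solve(X'X) X' log(S), vectorized
  beta <- t(qr.coef(qrX, t(L)))        # nvox x 7
  # one WLLS pass with weights = predicted signal squared (per voxel)
  pred <- exp(beta %*% t(X))
  XtX_inv_solve <- function(w, y) {
    Xw <- X * w
    qr.coef(qr(Xw), y * w)
  }
  for (i in seq_len(nrow(beta))) {
    w <- pred[i, ]
    beta[i, ] <- XtX_inv_solve(w, L[i, ])
  }
  tensor6 <- array(0, dim = c(dm, 6))
  S0map <- array(NA_real_, dim = dm)
  npd <- array(FALSE, dim = dm)
  flat6 <- matrix(0, prod(dm), 6)
  flat6[vox, ] <- beta[, 2:7, drop = FALSE]
  tensor6 <- array(flat6, dim = c(dm, 6))
  s0v <- rep(NA_real_, prod(dm)); s0v[vox] <- exp(beta[, 1])
  S0map <- array(s0v, dim = dm)
  # PSD check via eigenvalues
  npdv <- rep(FALSE, prod(dm))
  for (j in seq_along(vox)) {
    d6 <- beta[j, 2:7]
    D <- matrix(c(d6[1], d6[4], d6[5],
                  d6[4], d6[2], d6[6],
                  d6[5], d6[6], d6[3]), 3, 3)
    if (min(eigen(D, symmetric = TRUE, only.values = TRUE)$values) < -1e-12) {
      npdv[vox[j]] <- TRUE
    }
  }
  structure(list(tensor6 = tensor6, S0 = S0map,
                 npd = array(npdv, dim = dm), mask = mask,
                 max_b = max_b),
            class = "dti_fit")
}

#' @export
print.dti_fit <- function(x, ...) {
  cat("Diffusion tensor fit:", paste(dim(x$S0), collapse = " x "),
      "grid;", sum(x$mask), "voxels in mask;",
      sum(x$npd), "non-PSD flagged\n")
  invisible(x)
}

#' Axis diffusivity maps from a tensor field
#'
#' Returns the tensor diagonal elements in the scanner frame (Dxx, Dyy, Dzz)
#' -- the raw (1,1), (2,2), (3,3) elements, not eigenvalues. These are the
#' quantities the ALPS ratio consumes.
#'
#' @param fit a `dti_fit` (or a bare `(x,y,z,6)` tensor array).
#' @return list of class `diffusivity_maps` with 3-D arrays `Dxx`, `Dyy`,
#'   `Dzz` (mm^2/s).
#' @export
axis_diffusivities <- function(fit) {
  t6 <- if (inherits(fit, "dti_fit")) fit$tensor6 else fit
  dm <- dim(t6)[1:3]
  pick <- function(k) array(t6[, , , k], dim = dm)
  structure(list(Dxx = pick(1), Dyy = pick(2), Dzz = pick(3)),
            class = "diffusivity_maps")
}
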