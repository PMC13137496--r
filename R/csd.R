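#' Single-fibre response function from phantom voxels
#'
#' Takes voxels known (from phantom truth) or inferred (FA threshold on a
#' tensor fit) to contain a single fibre population, rotates each voxel's
#' gradient directions so its fibre axis lies on +z, and projects the shell
#' signal onto zonal (m = 0) harmonics. Coefficients are averaged across
#' voxels. Signals are normalized by the voxel's mean b = 0 intensity.
#'
#' @param signal 4-D signal array or voxel x volume matrix.
#' @param gtab matching `gradient_table`.
#' @param orientations matrix (one unit row vector per selected voxel).
#' @param voxels integer indices (into the flattened spatial grid / rows).
#' @param lmax even harmonic order (default 8).
#' @param shell b-value of the shell used (default 2000).
#' @param shell_tol shell matching tolerance (s/mm^2).
#' @return object of class `fod_response`: zonal coefficients `r_l` for
#'   l = 0, 2, ..., lmax, plus `lmax` and `shell`.
#' @export
estimate_response <- function(signal, gtab, orientations, voxels,
                              lmax = 8, shell = 2000, shell_tol = 50) {
  validate_gradient_table(gtab)
  if (length(voxels) < 1) stop("no candidate single-fibre voxels")
  Y <- if (length(dim(signal)) == 4) {
    matrix(signal, prod(dim(signal)[1:3]), dim(signal)[4])
  } else signal
  sel <- abs(gtab$bvals - shell) <= shell_tol
  if (sum(sel) < length(seq(0, lmax, by = 2))) {
    stop("not enough directions on the requested shell")
  }
  g <- gtab$bvecs[sel, , drop = FALSE]
  b0 <- gtab$bvals == 0
  coefs <- matrix(0, length(voxels), lmax / 2 + 1)
  for (i in seq_along(voxels)) {
    v <- voxels[i]
    s0 <- mean(Y[v, b0])
    s <- Y[v, sel] / s0
    R <- rotation_to_z(orientations[i, ])
    grot <- g %*% t(R)
    Z <- sh_zonal_basis(grot[, 3] / sqrt(rowSums(grot^2)), lmax)
    coefs[i, ] <- qr.coef(qr(Z), s)
  }
  structure(list(r_l = colMeans(coefs), lmax = lmax, shell = shell),
            class = "fod_response")
}

#' Response function of a phantom's single-fibre truth voxels
#'
#' @param phantom an `alps_phantom`.
#' @param lmax,shell,max_voxels see [estimate_response()].
#' @return a `fod_response`.
#' @export
phantom_response <- function(phantom, lmax = 8, shell = 2000,
                             max_voxels = 30) {
  single <- which(as.vector(phantom$truth$n_fixels == 1L))
  if (length(single) == 0) stop("phantom has no single-fibre voxels")
  use <- single[unique(round(seq(1, length(single),
                                 length.out = min(max_voxels,
                                                  length(single)))))]
  ori <- t(vapply(use, function(v)
    phantom$truth$populations[[v]][[1]]$orientation, numeric(3)))
  estimate_response(phantom$signal, phantom$gtab, ori, use,
                    lmax = lmax, shell = shell)
}

#' Constrained spherical deconvolution of one shell
#'
#' Single-shell, single-tissue CSD: per voxel the shell signal (normalized by
#' b = 0) is deconvolved with the response, with an iterative hard
#' non-negativity constraint on a deterministic 300-point hemisphere grid
#' (amplitudes below a small threshold are driven to zero by penalty rows;
#' the active set is re-estimated until it stabilizes or `max_iter` is hit).
#'
#' @param signal 4-D array or voxel x volume matrix.
#' @param gtab matching `gradient_table`.
#' @param response a `fod_response` with order >= `lmax`.
#' @param lmax even FOD order (default 8).
#' @param shell b-value of the shell deconvolved (default `response$shell`).
#' @param mask logical spatial mask (default all voxels).
#' @param grid_n constraint-grid size (default 300).
#' @param lambda constraint weight (default 1).
#' @param max_iter iteration cap (default 50).
#' @return object of class `fod_field`: `coef` (voxel x n_coef matrix, zero
#'   rows outside mask), `lmax`, `dim`, `mask`, logical `converged` vector.
#' @export
csd_fit <- function(signal, gtab, response, lmax = 8,
                    shell = response$shell, mask = NULL,
                    grid_n = 300, lambda = 1, max_iter = 50) {
  validate_gradient_table(gtab)
  if (2 * (length(response$r_l) - 1) < lmax) {
    stop("response order (", 2 * (length(response$r_l) - 1),
         ") below requested lmax (", lmax, ")")
  }
  dm4 <- dim(signal)
  if (length(dm4) == 4) {
    dm <- dm4[1:3]; Y <- matrix(signal, prod(dm), dm4[4])
  } else {
    dm <- c(nrow(signal), 1L, 1L); Y <- signal
  }
  sel <- abs(gtab$bvals - shell) <= 50
  ncoef <- sh_n_coef(lmax)
  if (sum(sel) < ncoef) {
    stop("shell has ", sum(sel), " directions; need >= ", ncoef,
         " for lmax ", lmax)
  }
  g <- gtab$bvecs[sel, , drop = FALSE]
  b0 <- gtab$bvals == 0
  conv <- sh_convolution_weights(response$r_l[seq_len(lmax / 2 + 1)], lmax)
  A <- sh_basis(g, lmax) * rep(conv, each = nrow(g))
  grid <- fibonacci_sphere(grid_n, hemisphere = TRUE)
  B <- sh_basis(grid, lmax)

  if (is.null(mask)) mask <- array(TRUE, dim = dm)
  vox <- which(as.vector(mask))
  coef <- matrix(0, prod(dm), ncoef)
  converged <- rep(NA, prod(dm))
  qrA <- qr(A)
  for (v in vox) {
    s0 <- mean(Y[v, b0])
    s <- Y[v, sel] / s0
    x <- qr.coef(qrA, s)                       # unconstrained start
    amp0 <- drop(B %*% x)
    tau <- 0.1 * mean(pmax(amp0, 0))
    active_prev <- NULL
    ok <- FALSE
    for (it in seq_len(max_iter)) {
      amp <- drop(B %*% x)
      active <- which(amp < tau)
      if (!is.null(active_prev) && identical(active, active_prev)) {
        ok <- TRUE; break
      }
      active_prev <- active
      if (length(active) == 0) { ok <- TRUE; break }
      M <- rbind(A, lambda * B[active, , drop = FALSE])
      rhs <- c(s, rep(0, length(active)))
      x <- qr.coef(qr(M), rhs)
    }
    coef[v, ] <- x
    converged[v] <- ok
  }
  structure(list(coef = coef, lmax = lmax, dim = dm, mask = mask,
                 converged = converged, grid_n = grid_n),
            class = "fod_field")
}

#' Segment an FOD into fixels
#'
#' Local maxima of the FOD amplitude on a deterministic antipodally-symmetric
#' hemisphere grid become candidate fixels; every grid point is assigned to
#' its uphill maximum by discrete steepest-ascent (watershed), and the fibre
#' density of a fixel is the weighted sum of the positive amplitudes in its
#' lobe. Peaks whose refined amplitude falls below
#' `peak_threshold * max peak amplitude` are discarded. Orientations are
#' refined off-grid by local optimization of the SH amplitude.
#'
#' @param fod_coef SH coefficient vector of one voxel.
#' @param lmax harmonic order of `fod_coef`.
#' @param grid_n grid size (default 300).
#' @param peak_threshold relative peak amplitude cutoff (default 0.1).
#' @param iso_threshold minimum relative amplitude range: when
#'   `max - min < iso_threshold * max` the FOD is effectively isotropic
#'   (no genuine lobes) and no fixels are returned.
#' @return object of class `fixel_set`: list with `orientation` (k x 3),
#'   `density` (length k, descending) and `peak_amp`.
#' @export
segment_fixels <- function(fod_coef, lmax = 8, grid_n = 300,
                           peak_threshold = 0.1, iso_threshold = 0.1) {
  grid <- fibonacci_sphere(grid_n, hemisphere = TRUE)
  nb <- fixel_grid_neighbors(grid_n)
  amp <- drop(sh_basis(grid, lmax) %*% fod_coef)
  n <- nrow(grid)
  empty <- structure(list(orientation = matrix(0, 0, 3),
                          density = numeric(0), peak_amp = numeric(0)),
                     class = "fixel_set")
  if (max(amp) <= 0) return(empty)
  if (max(amp) - max(min(amp), 0) < iso_threshold * max(amp)) {
    return(empty)                      # flat FOD: no distinct lobes
  }
  # steepest-ascent parent; points that beat all neighbours are maxima
  parent <- integer(n)
  for (i in seq_len(n)) {
    cand <- nb[[i]]
    j <- cand[which.max(amp[cand])]
    parent[i] <- if (amp[j] > amp[i]) j else i
  }
  # path-compress to root maxima
  root <- seq_len(n)
  for (i in seq_len(n)) {
    r <- i
    for (k in seq_len(n)) {          # bounded walk
      if (parent[r] == r) break
      r <- parent[r]
    }
    root[i] <- r
  }
  maxima <- unique(root[amp[root] > 0])
  if (length(maxima) == 0) return(empty)
  w <- 2 * pi / n                     # hemisphere quadrature weight
  ori <- matrix(0, length(maxima), 3)
  dens <- peak <- numeric(length(maxima))
  for (k in seq_along(maxima)) {
    mx <- maxima[k]
    lobe <- which(root == mx & amp > 0)
    dens[k] <- sum(amp[lobe]) * w
    # off-grid refinement of the peak direction
    sp <- cart_to_sph(grid[mx, , drop = FALSE])
    opt <- stats::optim(c(sp$theta, sp$phi), function(p) {
      d <- c(sin(p[1]) * cos(p[2]), sin(p[1]) * sin(p[2]), cos(p[1]))
      -sh_amplitude(fod_coef, matrix(d, 1), lmax)
    }, method = "Nelder-Mead", control = list(reltol = 1e-10))
    d <- c(sin(opt$par[1]) * cos(opt$par[2]),
           sin(opt$par[1]) * sin(opt$par[2]), cos(opt$par[1]))
    if (d[3] < 0) d <- -d             # canonical hemisphere
    ori[k, ] <- d
    peak[k] <- -opt$value
  }
  keep <- peak >= peak_threshold * max(peak)
  ori <- ori[keep, , drop = FALSE]; dens <- dens[keep]; peak <- peak[keep]
  o <- order(dens, decreasing = TRUE)
  structure(list(orientation = ori[o, , drop = FALSE], density = dens[o],
                 peak_amp = peak[o]), class = "fixel_set")
}

# cached k-nearest-neighbour lists on the antipodal hemisphere grid
.fixel_nb_cache <- new.env(parent = emptyenv())
fixel_grid_neighbors <- function(grid_n, k = 8) {
  key <- paste0(grid_n, "_", k)
  if (!is.null(.fixel_nb_cache[[key]])) return(.fixel_nb_cache[[key]])
  grid <- fibonacci_sphere(grid_n, hemisphere = TRUE)
  # antipodally symmetric angular distance
  dots <- abs(grid %*% t(grid))
  nb <- lapply(seq_len(grid_n), function(i) {
    order(dots[i, ], decreasing = TRUE)[2:(k + 1)]
  })
  .fixel_nb_cache[[key]] <- nb
  nb
}

#' Crossing-fibre complexity of one voxel
#'
#' With fixel densities `f1 >= ... >= fN`:
#' 0 when `N <= 1`, otherwise `(N / (N - 1)) * (1 - f1 / sum(f))`. Ranges
#' over \[0, 1\]: 0 when all fibres share one orientation, 1 when N >= 2
#' bundles have equal density (the largest bundle holds the smallest
#' possible share). Invariant to uniform density rescaling.
#'
#' @param fixels a `fixel_set`, or a numeric density vector.
#' @return scalar in \[0, 1\].
#' @export
voxel_complexity <- function(fixels) {
  f <- if (inherits(fixels, "fixel_set")) fixels$density else fixels
  if (any(f < 0)) stop("negative fibre density")
  n <- length(f)
  if (n <= 1) return(0)
  f <- sort(f, decreasing = TRUE)
  tot <- sum(f)
  if (tot == 0) return(0)
  (n / (n - 1)) * (1 - f[1] / tot)
}

#' Complexity map over a grid
#'
#' Runs CSD + fixel segmentation + [voxel_complexity()] over the masked
#' voxels of a 4-D signal.
#'
#' @param signal,gtab,response,lmax,shell,mask,peak_threshold see
#'   [csd_fit()] / [segment_fixels()].
#' @return 3-D array of complexity values (NA outside mask).
#' @export
complexity_map <- function(signal, gtab, response, lmax = 8,
                           shell = response$shell, mask = NULL,
                           peak_threshold = 0.1) {
  fod <- csd_fit(signal, gtab, response, lmax = lmax, shell = shell,
                 mask = mask)
  out <- rep(NA_real_, prod(fod$dim))
  for (v in which(as.vector(fod$mask))) {
    fx <- segment_fixels(fod$coef[v, ], lmax = lmax,
                         peak_threshold = peak_threshold)
    out[v] <- voxel_complexity(fx)
  }
  array(out, dim = fod$dim)
}

#' ROI-averaged complexity
#'
#' Mean complexity over each of the four ALPS regions plus the subject-level
#' covariate, the mean of the four ROI averages.
#'
#' @param cmap 3-D complexity array.
#' @param rois an `alps_rois`.
#' @return list with the four ROI means and `subject_average`.
#' @export
roi_mean_complexity <- function(cmap, rois) {
  vals <- lapply(c("SLF_L", "SLF_R", "SCR_L", "SCR_R"), function(nm)
    as.numeric(extract_roi_mean(cmap, rois[[nm]])))
  names(vals) <- c("SLF_L", "SLF_R", "SCR_L", "SCR_R")
  c(vals, list(subject_average = mean(unlist(vals))))
}
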