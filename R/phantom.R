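#' Axially symmetric diffusion tensor from an orientation
#'
#' @param orientation unit 3-vector (fibre axis).
#' @param axial,radial axial and radial diffusivities (mm^2/s),
#'   `axial >= radial >= 0`.
#' @return symmetric 3 x 3 tensor (mm^2/s).
#' @export
tensor_from_axis <- function(orientation, axial, radial) {
  v <- orientation / sqrt(sum(orientation^2))
  if (!(axial >= radial && radial >= 0)) {
    stop("require axial >= radial >= 0")
  }
  radial * diag(3) + (axial - radial) * tcrossprod(v)
}

#' Fibre population descriptor
#'
#' @param orientation unit 3-vector.
#' @param volume_fraction fraction in [0, 1].
#' @param axial,radial diffusivities (mm^2/s).
#' @return list of class `fiber_population`.
#' @export
fiber_population <- function(orientation, volume_fraction,
                             axial = 1.7e-3, radial = 0.3e-3) {
  nrm <- sqrt(sum(orientation^2))
  if (abs(nrm - 1) > 1e-8) orientation <- orientation / nrm
  if (volume_fraction < 0 || volume_fraction > 1) {
    stop("volume_fraction must lie in [0, 1]")
  }
  if (!(axial >= radial && radial >= 0)) stop("require axial >= radial >= 0")
  structure(list(orientation = orientation,
                 volume_fraction = volume_fraction,
                 axial = axial, radial = radial),
            class = "fiber_population")
}

#' Noise model for simulated MR magnitude data
#'
#' @param kind one of `"none"`, `"gaussian"`, `"rician"`.
#' @param sigma noise standard deviation, signal units (>= 0).
#' @param seed integer RNG seed.
#' @return list of class `noise_model`.
#' @export
noise_model <- function(kind = c("none", "gaussian", "rician"),
                        sigma = 0, seed = 1L) {
  kind <- match.arg(kind)
  if (sigma < 0) stop("sigma must be >= 0")
  structure(list(kind = kind, sigma = sigma, seed = as.integer(seed)),
            class = "noise_model")
}

apply_noise <- function(signal, noise) {
  if (noise$kind == "none" || noise$sigma == 0) return(signal)
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(noise$seed)
  n <- length(signal)
  if (noise$kind == "gaussian") {
    out <- signal + stats::rnorm(n, 0, noise$sigma)
  } else {
    # magnitude of a complex Gaussian-corrupted signal
    re <- signal + stats::rnorm(n, 0, noise$sigma)
    im <- stats::rnorm(n, 0, noise$sigma)
    out <- sqrt(re^2 + im^2)
  }
  array(out, dim = dim(signal) %||% length(signal))
}

.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
}

.Random.seed_restore <- function(old) {
  if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Multi-tensor forward signal for one voxel
#'
#' Standard multi-compartment Gaussian model:
#' `S(b, g) = S0 * sum_i f_i * exp(-b * g' D_i g)`, with an optional isotropic
#' or generic-tensor compartment. Noiseless signal equals `S0` at b = 0 and is
#' non-increasing in b for a fixed direction.
#'
#' @param populations list of [fiber_population()] objects.
#' @param iso_fraction volume fraction of the extra compartment.
#' @param iso_tensor 3 x 3 tensor of the extra compartment (may be
#'   anisotropic, e.g. a perivascular compartment), or a scalar diffusivity.
#' @param gtab a `gradient_table`.
#' @param S0 non-negative baseline signal.
#' @param noise a [noise_model()].
#' @return numeric vector of length `n_volumes(gtab)`.
#' @export
simulate_voxel_signal <- function(populations, iso_fraction = 0,
                                  iso_tensor = NULL, gtab, S0 = 100,
                                  noise = noise_model("none")) {
  validate_gradient_table(gtab)
  if (S0 < 0) stop("S0 must be non-negative")
  fr <- vapply(populations, function(p) p$volume_fraction, 1.0)
  tot <- sum(fr) + iso_fraction
  if (abs(tot - 1) > 1e-9) {
    stop("volume fractions must sum to 1 (got ", format(tot), ")")
  }
  sig <- numeric(n_volumes(gtab))
  add_comp <- function(f, D) {
    # b * g' D g for all volumes at once
    g <- gtab$bvecs
    q <- gtab$bvals * (g[, 1]^2 * D[1, 1] + g[, 2]^2 * D[2, 2] +
                       g[, 3]^2 * D[3, 3] + 2 * g[, 1] * g[, 2] * D[1, 2] +
                       2 * g[, 1] * g[, 3] * D[1, 3] +
                       2 * g[, 2] * g[, 3] * D[2, 3])
    f * exp(-q)
  }
  for (p in populations) {
    sig <- sig + add_comp(p$volume_fraction,
                          tensor_from_axis(p$orientation, p$axial, p$radial))
  }
  if (iso_fraction > 0) {
    D <- if (is.matrix(iso_tensor)) iso_tensor else diag(3) * iso_tensor
    sig <- sig + add_comp(iso_fraction, D)
  }
  apply_noise(S0 * sig, noise)
}

#' Default ALPS phantom configuration
#'
#' The phantom emulates the periventricular geometry the ALPS index assumes:
#' y-oriented association-fibre (SLF) regions, z-oriented projection-fibre
#' (SCR) regions, an x-oriented perivascular water compartment inside both,
#' and a configurable share of crossing-fibre voxels (`crossing_fraction`,
#' with the secondary bundle holding `crossing_ratio` of the white-matter
#' fraction). Values are typical 3 T white matter: axial 1.7e-3, radial
#' 0.3e-3 mm^2/s; background isotropic 0.8e-3 mm^2/s; Rician noise at
#' SNR(b=0) = 30. `compartment_model = "multi"` (default) sums the
#' compartment exponentials; `"averaged"` generates each voxel from its
#' single volume-fraction-weighted mean tensor, making the diffusion-tensor
#' model exact (used by the formula-correctness checks).
#'
#' @param ... overrides of any default field.
#' @return named list.
#' @export
alps_phantom_config <- function(...) {
  cfg <- list(
    dim = c(20L, 20L, 12L),
    voxel_size = 2,                     # mm
    roi_centres = list(SLF_L = c(3, 10, 6),  SCR_L = c(8, 10, 6),
                       SCR_R = c(13, 10, 6), SLF_R = c(18, 10, 6)),
    roi_radius = 2,                     # voxels
    fiber_axial = 1.7e-3, fiber_radial = 0.3e-3,   # mm^2/s
    f_pvs = 0.1,
    pvs_axial = 1.5e-3, pvs_radial = 0.2e-3,       # x-dominant compartment
    background_d = 0.8e-3,
    crossing_fraction = 0.2,
    crossing_ratio = 0.35,              # secondary bundle's share of WM
    compartment_model = "multi",        # or "averaged" (single mean tensor)
    S0 = 100,
    gtab = NULL,                        # NULL -> gradient_table("4shell")
    noise = noise_model("rician", sigma = 100 / 30, seed = 1L)
  )
  ov <- list(...)
  cfg[names(ov)] <- ov
  cfg
}

sphere_mask <- function(dim, centre, radius) {
  g <- expand.grid(x = seq_len(dim[1]), y = seq_len(dim[2]),
                   z = seq_len(dim[3]))
  d2 <- (g$x - centre[1])^2 + (g$y - centre[2])^2 + (g$z - centre[3])^2
  array(d2 <= radius^2, dim = dim)
}

#' Build the ALPS phantom
#'
#' Synthesizes a 4-D diffusion-weighted volume with ground truth. SCR regions
#' hold z-oriented fibre populations, SLF regions y-oriented ones; both carry
#' an x-dominant perivascular fraction `f_pvs`. A deterministic subset
#' (`crossing_fraction`) of each region's voxels receives an equal-density
#' orthogonal second bundle. The fibre composition (the truth) depends only on
#' the configuration; the noise seed affects the signal alone.
#'
#' @param config from [alps_phantom_config()].
#' @return object of class `alps_phantom`: `signal` (4-D array), `truth`
#'   (per-voxel mean tensor as a `(x,y,z,6)` array in the order Dxx, Dyy,
#'   Dzz, Dxy, Dxz, Dyz; per-voxel population list; fixel-count array),
#'   `roi_labels` (integer array, 0 = background, 1..4 = SLF_L, SLF_R,
#'   SCR_L, SCR_R), `gtab`, `voxel_size`, `config`.
#' @export
build_alps_phantom <- function(config = alps_phantom_config()) {
  cfg <- config
  gtab <- cfg$gtab %||% gradient_table("4shell")
  dm <- cfg$dim
  labels <- array(0L, dim = dm)
  roi_names <- c("SLF_L", "SLF_R", "SCR_L", "SCR_R")
  masks <- lapply(roi_names, function(nm)
    sphere_mask(dm, cfg$roi_centres[[nm]], cfg$roi_radius))
  names(masks) <- roi_names
  # pairwise overlap forbidden
  overlap <- Reduce(`+`, masks)
  if (any(overlap > 1)) stop("ROIs overlap; adjust centres or radius")
  for (i in seq_along(roi_names)) {
    if (!any(masks[[i]])) stop("empty ROI: ", roi_names[i])
    labels[masks[[i]]] <- i
  }

  y_axis <- c(0, 1, 0); z_axis <- c(0, 0, 1)
  pvs_tensor <- tensor_from_axis(c(1, 0, 0), cfg$pvs_axial, cfg$pvs_radial)
  wm_f <- 1 - cfg$f_pvs

  cr <- cfg$crossing_ratio %||% 0.35
  make_pops <- function(primary, crossing) {
    if (crossing) {
      list(fiber_population(primary, wm_f * (1 - cr), cfg$fiber_axial,
                            cfg$fiber_radial),
           fiber_population(if (all(primary == y_axis)) z_axis else y_axis,
                            wm_f * cr, cfg$fiber_axial, cfg$fiber_radial))
    } else {
      list(fiber_population(primary, wm_f, cfg$fiber_axial, cfg$fiber_radial))
    }
  }

  nvox <- prod(dm); nvol <- n_volumes(gtab)
  # voxel type: 0 bg, per-ROI pure / crossing
  type <- integer(nvox)
  crossing <- logical(nvox)
  for (i in seq_along(roi_names)) {
    idx <- which(as.vector(masks[[i]]))
    type[idx] <- i
    n_cross <- floor(cfg$crossing_fraction * length(idx))
    if (n_cross > 0) {
      # deterministic, evenly spread selection
      sel <- idx[unique(round(seq(1, length(idx), length.out = n_cross)))]
      crossing[sel] <- TRUE
    }
  }

  noiseless <- matrix(0, nrow = nvox, ncol = nvol)
  truth_t6 <- matrix(0, nrow = nvox, ncol = 6)
  n_fixels <- integer(nvox)
  populations <- vector("list", nvox)

  # unique voxel compositions -> compute signal once per composition
  compositions <- list(
    bg = list(pops = list(), iso_f = 1, iso_D = diag(3) * cfg$background_d)
  )
  for (i in seq_along(roi_names)) {
    primary <- if (grepl("^SLF", roi_names[i])) y_axis else z_axis
    compositions[[paste0(roi_names[i], "_pure")]] <-
      list(pops = make_pops(primary, FALSE), iso_f = cfg$f_pvs,
           iso_D = pvs_tensor)
    compositions[[paste0(roi_names[i], "_cross")]] <-
      list(pops = make_pops(primary, TRUE), iso_f = cfg$f_pvs,
           iso_D = pvs_tensor)
  }
  comp_key <- ifelse(type == 0, "bg",
                     paste0(roi_names[pmax(type, 1)],
                            ifelse(crossing, "_cross", "_pure")))
  comp_key[type == 0] <- "bg"
  averaged <- identical(cfg$compartment_model, "averaged")
  for (key in unique(comp_key)) {
    comp <- compositions[[key]]
    Dbar <- comp$iso_f * comp$iso_D
    for (p in comp$pops) {
      Dbar <- Dbar + p$volume_fraction *
        tensor_from_axis(p$orientation, p$axial, p$radial)
    }
    sig <- if (averaged) {
      # DTI-consistent mode: mono-exponential signal of the mean tensor
      simulate_voxel_signal(list(), 1, Dbar, gtab, S0 = cfg$S0,
                            noise = noise_model("none"))
    } else {
      simulate_voxel_signal(comp$pops, comp$iso_f, comp$iso_D, gtab,
                            S0 = cfg$S0, noise = noise_model("none"))
    }
    rows <- comp_key == key
    noiseless[rows, ] <- matrix(sig, sum(rows), nvol, byrow = TRUE)
    truth_t6[rows, ] <- matrix(c(Dbar[1, 1], Dbar[2, 2], Dbar[3, 3],
                                 Dbar[1, 2], Dbar[1, 3], Dbar[2, 3]),
                               sum(rows), 6, byrow = TRUE)
    n_fixels[rows] <- length(comp$pops)
    populations[rows] <- list(comp$pops)
  }

  signal <- apply_noise(array(noiseless, dim = c(dm, nvol)), cfg$noise)

  structure(list(
    signal = signal,
    truth = list(tensor6 = array(truth_t6, dim = c(dm, 6)),
                 populations = populations,
                 n_fixels = array(n_fixels, dim = dm),
                 crossing = array(crossing, dim = dm)),
    roi_labels = labels,
    roi_names = roi_names,
    gtab = gtab,
    voxel_size = cfg$voxel_size,
    config = cfg
  ), class = "alps_phantom")
}

#' @export
print.alps_phantom <- function(x, ...) {
  cat("ALPS phantom:", paste(dim(x$signal), collapse = " x "), "\n")
  cat("  ROIs:", paste(sprintf("%s (%d vox)", x$roi_names,
      vapply(seq_along(x$roi_names),
             function(i) sum(x$roi_labels == i), 1L)), collapse = ", "), "\n")
  cat("  perivascular fraction:", x$config$f_pvs,
      " crossing fraction:", x$config$crossing_fraction, "\n")
  invisible(x)
}

#' Analytic ground-truth ALPS index of a phantom
#'
#' Applies the ALPS ratio to the noiseless volume-fraction-weighted tensor
#' diagonals averaged over each region:
#' `ALPS = mean(Dxx_SCR, Dxx_SLF) / mean(Dyy_SCR, Dzz_SLF)` per hemisphere.
#' This is the oracle the fitted pipeline is checked against.
#'
#' @param phantom an `alps_phantom`.
#' @return list with `left`, `right`, `bilateral`.
#' @export
ground_truth_alps <- function(phantom) {
  t6 <- phantom$truth$tensor6
  lab <- phantom$roi_labels
  roi_mean <- function(name, comp) {
    i <- match(name, phantom$roi_names)
    m <- lab == i
    if (!any(m)) stop("empty ROI: ", name)
    v <- t6[, , , comp, drop = FALSE]
    mean(v[m])
  }
  one_side <- function(side) {
    slf <- paste0("SLF_", side); scr <- paste0("SCR_", side)
    num <- mean(c(roi_mean(scr, 1), roi_mean(slf, 1)))        # Dxx proj, assoc
    den <- mean(c(roi_mean(scr, 2), roi_mean(slf, 3)))        # Dyy proj, Dzz assoc
    num / den
  }
  left <- one_side("L"); right <- one_side("R")
  list(left = left, right = right, bilateral = (left + right) / 2)
}
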