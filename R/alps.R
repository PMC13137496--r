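#' ALPS regions of interest
#'
#' Four spherical regions, one association-fibre (SLF) and one
#' projection-fibre (SCR) region per hemisphere, given as centre voxel
#' coordinates (1-based indices in the map's own grid) plus a radius in
#' voxels, or as explicit logical masks. The JHU-atlas template coordinates
#' printed in the ALPS literature apply only to maps already in that template
#' space; phantom analyses use phantom-frame centres.
#'
#' @param SLF_L,SLF_R,SCR_L,SCR_R either `list(centre = c(x, y, z),
#'   radius = r)` or a logical array mask.
#' @return object of class `alps_rois`.
#' @export
alps_rois <- function(SLF_L, SLF_R, SCR_L, SCR_R) {
  rois <- list(SLF_L = SLF_L, SLF_R = SLF_R, SCR_L = SCR_L, SCR_R = SCR_R)
  structure(rois, class = "alps_rois")
}

#' ROIs of a phantom, from its own label map
#'
#' @param phantom an `alps_phantom`.
#' @return an `alps_rois` of explicit masks.
#' @export
phantom_rois <- function(phantom) {
  mk <- function(nm) phantom$roi_labels == match(nm, phantom$roi_names)
  alps_rois(mk("SLF_L"), mk("SLF_R"), mk("SCR_L"), mk("SCR_R"))
}

roi_mask_for <- function(roi, dim) {
  if (is.array(roi) && is.logical(roi)) {
    if (!identical(dim(roi), as.integer(dim))) {
      stop("ROI mask grid does not match map grid")
    }
    return(roi)
  }
  if (is.list(roi) && !is.null(roi$centre)) {
    if (any(roi$centre < 1) || any(roi$centre > dim)) {
      stop("ROI centre outside grid bounds")
    }
    return(sphere_mask(dim, roi$centre, roi$radius))
  }
  stop("ROI must be a logical mask or list(centre=, radius=)")
}

#' Mean of a diffusivity map over one ROI
#'
#' Arithmetic mean over the ROI's voxels; NaN/NA voxels are excluded and
#' counted. An all-missing ROI is an error.
#'
#' @param map 3-D numeric array.
#' @param roi ROI spec (mask or centre/radius list).
#' @return scalar mean, with attribute `n_excluded`.
#' @export
extract_roi_mean <- function(map, roi) {
  m <- roi_mask_for(roi, dim(map))
  if (!any(m)) stop("empty ROI")
  v <- map[m]
  bad <- !is.finite(v)
  if (all(bad)) stop("ROI contains no finite voxels")
  out <- mean(v[!bad])
  attr(out, "n_excluded") <- sum(bad)
  out
}

#' DTI-ALPS index for one hemisphere
#'
#' `ALPS = mean(Dxx_SCR, Dxx_SLF) / mean(Dyy_SCR, Dzz_SLF)` where each term
#' is the ROI mean of the corresponding axis-diffusivity map and the outer
#' means are unweighted two-term averages of ROI means (not pooled voxels).
#'
#' @param maps a `diffusivity_maps` object (fields Dxx, Dyy, Dzz).
#' @param rois an `alps_rois`.
#' @param hemisphere `"L"` or `"R"`.
#' @return scalar ALPS with attribute `roi_means` (named: Dxx_proj,
#'   Dxx_assoc, Dyy_proj, Dzz_assoc).
#' @export
alps_index <- function(maps, rois, hemisphere = c("L", "R")) {
  hemisphere <- match.arg(hemisphere)
  slf <- rois[[paste0("SLF_", hemisphere)]]
  scr <- rois[[paste0("SCR_", hemisphere)]]
  terms <- c(Dxx_proj  = as.numeric(extract_roi_mean(maps$Dxx, scr)),
             Dxx_assoc = as.numeric(extract_roi_mean(maps$Dxx, slf)),
             Dyy_proj  = as.numeric(extract_roi_mean(maps$Dyy, scr)),
             Dzz_assoc = as.numeric(extract_roi_mean(maps$Dzz, slf)))
  den <- mean(terms[c("Dyy_proj", "Dzz_assoc")])
  if (!is.finite(den) || den <= 0) {
    stop("non-positive ALPS denominator; ROI means: ",
         paste(sprintf("%s=%.3g", names(terms), terms), collapse = ", "))
  }
  out <- mean(terms[c("Dxx_proj", "Dxx_assoc")]) / den
  attr(out, "roi_means") <- terms
  out
}

#' Bilateral ALPS
#'
#' The per-subject index is the arithmetic mean of the two hemispheres.
#'
#' @param left,right finite per-hemisphere ALPS values.
#' @return scalar.
#' @export
bilateral_alps <- function(left, right) {
  stopifnot(is.finite(left), is.finite(right))
  (as.numeric(left) + as.numeric(right)) / 2
}

#' Full ALPS computation from diffusivity maps
#'
#' Convenience wrapper: both hemispheres plus the bilateral average and the
#' four ROI means per side.
#'
#' @param maps a `diffusivity_maps`.
#' @param rois an `alps_rois`.
#' @return object of class `alps_result`.
#' @export
compute_alps <- function(maps, rois) {
  left <- alps_index(maps, rois, "L")
  right <- alps_index(maps, rois, "R")
  structure(list(alps_left = as.numeric(left),
                 alps_right = as.numeric(right),
                 alps = bilateral_alps(left, right),
                 roi_means_left = attr(left, "roi_means"),
                 roi_means_right = attr(right, "roi_means")),
            class = "alps_result")
}

#' @export
print.alps_result <- function(x, digits = 4, ...) {
  cat("DTI-ALPS index\n")
  cat(sprintf("  left  %.4f   right %.4f   bilateral %.4f\n",
              x$alps_left, x$alps_right, x$alps))
  cat("  ROI means (mm^2/s), left:\n")
  print(signif(x$roi_means_left, digits))
  invisible(x)
}
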