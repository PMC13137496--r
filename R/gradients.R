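#' Deterministic spherical-Fibonacci point set
#'
#' Generates `n` unit vectors approximately uniform on the sphere (or on a
#' hemisphere when `hemisphere = TRUE`, for antipodally symmetric sampling).
#' The layout is fully deterministic: no seed is consumed.
#'
#' @param n number of directions (>= 1).
#' @param hemisphere if TRUE, points are folded to the z >= 0 hemisphere.
#' @return an `n x 3` matrix of unit row vectors.
#' @export
fibonacci_sphere <- function(n, hemisphere = FALSE) {
  stopifnot(is.numeric(n), length(n) == 1, n >= 1)
  n <- as.integer(n)
  i <- seq_len(n) - 0.5
  golden <- (1 + sqrt(5)) / 2
  if (hemisphere) {
    # cos(theta) in (0, 1): spiral over the upper hemisphere only
    z <- 1 - i / n
  } else {
    z <- 1 - 2 * i / n
  }
  r <- sqrt(pmax(0, 1 - z^2))
  phi <- 2 * pi * i / golden
  cbind(x = r * cos(phi), y = r * sin(phi), z = z)
}

#' Diffusion gradient table
#'
#' Builds a `gradient_table` from a list of shells, each a `list(b = , n = )`,
#' or from the preset string `"4shell"` which expands to the reference 4-shell
#' scheme (b = 50 s/mm^2 x 17, 300 x 8, 1000 x 64, 2000 x 64 directions) plus
#' `n_b0` unweighted volumes. Directions on each shell are laid out by a
#' deterministic spherical-Fibonacci spiral, rotated per shell so that shells
#' do not share directions.
#'
#' @param spec `"4shell"` or a list of shells, e.g.
#'   `list(list(b = 1000, n = 64))`.
#' @param n_b0 number of b = 0 volumes prepended (default 1).
#' @return object of class `gradient_table`: list with `bvals` (length-N
#'   numeric, s/mm^2) and `bvecs` (N x 3 matrix of unit vectors; zero rows at
#'   b = 0).
#' @export
gradient_table <- function(spec = "4shell", n_b0 = 1L) {
  if (identical(spec, "4shell")) {
    spec <- list(
      list(b = 50, n = 17L),
      list(b = 300, n = 8L),
      list(b = 1000, n = 64L),
      list(b = 2000, n = 64L)
    )
  }
  stopifnot(is.list(spec), length(spec) >= 1, n_b0 >= 0)
  bvals <- rep(0, n_b0)
  bvecs <- matrix(0, nrow = n_b0, ncol = 3)
  for (k in seq_along(spec)) {
    sh <- spec[[k]]
    if (is.null(sh$b) || is.null(sh$n)) {
      stop("each shell needs fields 'b' and 'n'")
    }
    if (sh$b < 0) stop("b-values must be non-negative")
    if (sh$b > 0 && sh$n < 1) {
      stop("invalid shell spec: zero directions on a nonzero shell (b = ",
           sh$b, ")")
    }
    if (sh$b == 0) {
      bvals <- c(bvals, rep(0, sh$n))
      bvecs <- rbind(bvecs, matrix(0, sh$n, 3))
      next
    }
    dirs <- fibonacci_sphere(sh$n, hemisphere = TRUE)
    # small per-shell rotation about z so shells are not collinear copies
    ang <- (k - 1) * pi / 7
    rot <- matrix(c(cos(ang), -sin(ang), 0,
                    sin(ang),  cos(ang), 0,
                    0, 0, 1), 3, 3, byrow = TRUE)
    dirs <- dirs %*% t(rot)
    bvals <- c(bvals, rep(sh$b, sh$n))
    bvecs <- rbind(bvecs, dirs)
  }
  if (!any(bvals == 0)) stop("gradient table must contain at least one b = 0 volume")
  gt <- structure(list(bvals = bvals, bvecs = unname(bvecs)),
                  class = "gradient_table")
  validate_gradient_table(gt)
  gt
}

#' Validate a gradient table
#'
#' Checks the invariants: equal lengths, non-negative b, unit-norm directions
#' on diffusion-weighted volumes, and at least one b = 0 volume.
#'
#' @param gt a `gradient_table`.
#' @return `gt`, invisibly, or an error.
#' @export
validate_gradient_table <- function(gt) {
  stopifnot(inherits(gt, "gradient_table"))
  if (length(gt$bvals) != nrow(gt$bvecs)) {
    stop("bvals and bvecs disagree in length: ", length(gt$bvals), " vs ",
         nrow(gt$bvecs))
  }
  if (any(gt$bvals < 0)) stop("negative b-values")
  if (!any(gt$bvals == 0)) stop("no b = 0 volume present")
  dw <- gt$bvals > 0
  if (any(dw)) {
    nrm <- sqrt(rowSums(gt$bvecs[dw, , drop = FALSE]^2))
    if (any(abs(nrm - 1) > 1e-8)) {
      stop("non-unit gradient direction at b > 0 (max |norm-1| = ",
           format(max(abs(nrm - 1))), ")")
    }
  }
  invisible(gt)
}

#' @export
print.gradient_table <- function(x, ...) {
  tab <- table(x$bvals)
  cat("Gradient table:", length(x$bvals), "volumes\n")
  for (b in names(tab)) {
    cat(sprintf("  b = %6s s/mm^2 : %d volumes\n", b, tab[[b]]))
  }
  invisible(x)
}

#' Number of volumes in a gradient table
#' @param gt a `gradient_table`.
#' @return integer count.
#' @export
n_volumes <- function(gt) length(gt$bvals)

#' Write / read FSL-style bvec and bval files
#'
#' The FSL dialect stores b-values as one whitespace-separated row and
#' directions as a 3 x N matrix (three rows). `read_bvec_bval()` also accepts
#' the transposed N x 3 layout, sniffing the orientation from the shape.
#'
#' @param gt a `gradient_table`.
#' @param bval_path,bvec_path file paths.
#' @return `read_bvec_bval` returns a `gradient_table`.
#' @export
write_bvec_bval <- function(gt, bval_path, bvec_path) {
  validate_gradient_table(gt)
  writeLines(paste(format(gt$bvals, trim = TRUE, scientific = FALSE),
                   collapse = " "), bval_path)
  m <- t(gt$bvecs)
  lines <- apply(m, 1, function(r) paste(format(r, trim = TRUE, digits = 15),
                                         collapse = " "))
  writeLines(lines, bvec_path)
  invisible(gt)
}

#' @rdname write_bvec_bval
#' @export
read_bvec_bval <- function(bval_path, bvec_path) {
  if (!file.exists(bval_path)) stop("bval file not found: ", bval_path)
  if (!file.exists(bvec_path)) stop("bvec file not found: ", bvec_path)
  bvals <- scan(bval_path, quiet = TRUE)
  rows <- lapply(strsplit(trimws(readLines(bvec_path)), "\\s+"), as.numeric)
  rows <- rows[vapply(rows, length, 1L) > 0]
  m <- do.call(rbind, rows)
  if (nrow(m) == 3 && ncol(m) != 3) {
    m <- t(m)                      # FSL 3 x N layout
  } else if (ncol(m) != 3) {
    stop("bvec file is neither 3 x N nor N x 3")
  } else if (nrow(m) == 3 && ncol(m) == 3 && length(bvals) != 3) {
    stop("ambiguous 3 x 3 bvec with ", length(bvals), " b-values")
  }
  if (nrow(m) != length(bvals)) {
    stop("gradient count mismatch: ", length(bvals), " b-values vs ",
         nrow(m), " directions")
  }
  # normalize dw rows, warn if far off
  dw <- bvals > 0
  nrm <- sqrt(rowSums(m^2))
  if (any(dw & abs(nrm - 1) > 1e-4)) {
    warning("re-normalizing gradient directions with |norm - 1| > 1e-4")
  }
  m[dw, ] <- m[dw, , drop = FALSE] / nrm[dw]
  structure(list(bvals = bvals, bvecs = unname(m)), class = "gradient_table")
}
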