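# Real even-order spherical harmonic machinery used by the CSD and fixel
# code. Basis ordering: l = 0, 2, ..., lmax; within l, m = -l..l.
# Associated Legendre values use the standard stable three-term recurrence
# (Condon-Shortley phase included, matching pracma::legendre, which serves
# as the cross-check oracle in the tests); normalization is orthonormal
# over the sphere.

# P_l^m(x) for all l = 0..lmax, m = 0..l, vectorized over x.
# Returns a list indexed by l+1; element [[l+1]] is length(x) x (l+1).
assoc_legendre_all <- function(x, lmax) {
  n <- length(x)
  P <- lapply(0:lmax, function(l) matrix(0, n, l + 1))
  P[[1]][, 1] <- 1
  if (lmax == 0) return(P)
  somx2 <- sqrt(pmax(0, 1 - x^2))
  pmm <- rep(1, n)
  for (m in 1:lmax) {
    pmm <- -pmm * (2 * m - 1) * somx2        # P_m^m, CS phase
    P[[m + 1]][, m + 1] <- pmm
  }
  for (m in 0:(lmax - 1)) {
    P[[m + 2]][, m + 1] <- x * (2 * m + 1) * P[[m + 1]][, m + 1]
  }
  if (lmax >= 2) {
    for (m in 0:(lmax - 2)) {
      for (l in (m + 2):lmax) {
        P[[l + 1]][, m + 1] <- ((2 * l - 1) * x * P[[l]][, m + 1] -
                                  (l + m - 1) * P[[l - 1]][, m + 1]) /
          (l - m)
      }
    }
  }
  P
}

sh_n_coef <- function(lmax) as.integer((lmax + 1) * (lmax + 2) / 2)

sh_degrees <- function(lmax) {
  unlist(lapply(seq(0, lmax, by = 2), function(l) rep(l, 2 * l + 1)))
}

cart_to_sph <- function(dirs) {
  dirs <- dirs / sqrt(rowSums(dirs^2))
  list(theta = acos(pmin(1, pmax(-1, dirs[, 3]))),
       phi = atan2(dirs[, 2], dirs[, 1]))
}

#' Real even-order spherical harmonic basis
#'
#' @param dirs N x 3 matrix of unit directions.
#' @param lmax maximum (even) harmonic order.
#' @return N x `(lmax+1)(lmax+2)/2` design matrix.
#' @export
sh_basis <- function(dirs, lmax = 8) {
  if (lmax %% 2 != 0) stop("lmax must be even")
  sp <- cart_to_sph(dirs)
  ct <- cos(sp$theta)
  n <- nrow(dirs)
  out <- matrix(0, n, sh_n_coef(lmax))
  P <- assoc_legendre_all(ct, lmax)
  col <- 1
  for (l in seq(0, lmax, by = 2)) {
    for (m in -l:l) {
      am <- abs(m)
      # orthonormal factor; (l-m)!/(l+m)! via lgamma for stability
      Nlm <- sqrt((2 * l + 1) / (4 * pi) *
                    exp(lgamma(l - am + 1) - lgamma(l + am + 1)))
      Pm <- P[[l + 1]][, am + 1]
      out[, col] <- if (m < 0) {
        sqrt(2) * Nlm * Pm * sin(am * sp$phi)
      } else if (m == 0) {
        Nlm * Pm
      } else {
        sqrt(2) * Nlm * Pm * cos(am * sp$phi)
      }
      col <- col + 1
    }
  }
  out
}

# zonal (m = 0 only) basis for axially symmetric functions of theta
sh_zonal_basis <- function(ct, lmax) {
  ls <- seq(0, lmax, by = 2)
  P <- assoc_legendre_all(ct, lmax)
  out <- matrix(0, length(ct), length(ls))
  for (j in seq_along(ls)) {
    l <- ls[j]
    out[, j] <- sqrt((2 * l + 1) / (4 * pi)) * P[[l + 1]][, 1]
  }
  out
}

# per-coefficient convolution factors turning FOD SH coefs into signal SH
# coefs for an axially symmetric kernel with zonal coefs r_l
sh_convolution_weights <- function(r_l, lmax) {
  ls <- seq(0, lmax, by = 2)
  per_l <- sqrt(4 * pi / (2 * ls + 1)) * r_l
  per_l[match(sh_degrees(lmax), ls)]
}

# rotation carrying unit vector v onto the +z axis
rotation_to_z <- function(v) {
  v <- v / sqrt(sum(v^2))
  z <- c(0, 0, 1)
  c_ <- sum(v * z)
  if (c_ > 1 - 1e-12) return(diag(3))
  if (c_ < -1 + 1e-12) return(diag(c(1, -1, -1)))
  axis <- c(v[2] * z[3] - v[3] * z[2],
            v[3] * z[1] - v[1] * z[3],
            v[1] * z[2] - v[2] * z[1])
  s <- sqrt(sum(axis^2))
  axis <- axis / s
  K <- matrix(c(0, -axis[3], axis[2],
                axis[3], 0, -axis[1],
                -axis[2], axis[1], 0), 3, 3, byrow = TRUE)
  diag(3) + s * K + (1 - c_) * (K %*% K)
}

# amplitude of an SH series at arbitrary directions
sh_amplitude <- function(coef, dirs, lmax) {
  drop(sh_basis(dirs, lmax) %*% coef)
}
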