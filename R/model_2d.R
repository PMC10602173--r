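#' Solve the 2D force balance on a periodic grid by a spectral method
#'
#' Generalises the 1D force balance to two dimensions: the isotropic
#' myosin stress \eqn{\sigma_{myo}\mathbf{I}} and internal viscous stress
#' \eqn{\mu w \mathbf{I}} (with \eqn{w = -\nabla\cdot\mathbf{v}}) balance
#' the external drag \eqn{\lambda\mathbf{v}}:
#' \eqn{\nabla\cdot[(\sigma_{myo} + \mu\nabla\cdot\mathbf{v})\mathbf{I}] =
#' \lambda\mathbf{v}}. On a periodic cell lattice this is solved mode by
#' mode with the FFT: only the longitudinal velocity component is excited,
#' \eqn{\hat{\mathbf v}_k \propto \hat k}, with
#' \eqn{\hat w = c_k\hat\sigma/(\lambda + \mu c_k)} where \eqn{c_k} is the
#' discrete Laplacian symbol. Staggered forward/backward difference symbols
#' are used so that for a stress varying along one axis only the solution
#' coincides with the 1D cell-level solver ([solve_contraction_rate()]),
#' and the discrete dissipation identity
#' \eqn{\lambda\sum|\mathbf v|^2 + \mu\sum w^2 = \sum\sigma w} holds
#' exactly. The k = 0 mode carries no force and is set to zero, so the
#' velocity field has zero spatial mean.
#'
#' @param sigma numeric matrix of myosin stress per node (pN per unit cell
#'   length); rows index the first (ventral-lateral) axis, columns the
#'   second (anterior-posterior) axis; periodic wrap assumed. The grid
#'   should extend well beyond the stress support (padding >= 4x the
#'   envelope width) to suppress wrap-around artefacts.
#' @param params a [vff_params()] object (uniform drag; `beta_cells` is
#'   ignored in 2D).
#' @return An object of class `"vff_field2d"`: matrices `vx`, `vy`
#'   (velocity components, nm/s), `w` (contraction rate, nm/s),
#'   `wx`, `wy` (directional contraction rates
#'   \eqn{-\partial v_x/\partial x}, \eqn{-\partial v_y/\partial y};
#'   `w = wx + wy`), plus the input `sigma` and `params`.
#' @examples
#' p <- vff_params()
#' sig <- matrix(0, 64, 64)
#' f2 <- solve_velocity_field_2d(sig + 100, p)  # uniform stress: no motion
#' max(abs(f2$w))
#' @export
solve_velocity_field_2d <- function(sigma, params) {
  sigma <- as.matrix(sigma)
  nx <- nrow(sigma); ny <- ncol(sigma)
  if (nx < 4 || ny < 4) stop("grid too small")
  if (any(!is.finite(sigma))) stop("`sigma` must be finite")
  mu <- params$mu; lam <- params$lambda
  kx <- 2 * pi * (0:(nx - 1)) / nx
  ky <- 2 * pi * (0:(ny - 1)) / ny
  gx <- matrix(exp(1i * kx) - 1, nx, ny)              # forward difference, axis 1
  gy <- matrix(exp(1i * ky) - 1, nx, ny, byrow = TRUE)
  ck <- Mod(gx)^2 + Mod(gy)^2                          # discrete Laplacian symbol
  S <- stats::fft(sigma)
  What <- ck * S / (lam + mu * ck)
  F <- (S - mu * What) / lam
  vx <- Re(stats::fft(gx * F, inverse = TRUE)) / (nx * ny)
  vy <- Re(stats::fft(gy * F, inverse = TRUE)) / (nx * ny)
  w <- Re(stats::fft(What, inverse = TRUE)) / (nx * ny)
  back_diff <- function(m, axis) {
    if (axis == 1) m - m[c(nx, seq_len(nx - 1)), , drop = FALSE]
    else m - m[, c(ny, seq_len(ny - 1)), drop = FALSE]
  }
  structure(list(vx = vx, vy = vy, w = w,
                 wx = -back_diff(vx, 1), wy = -back_diff(vy, 2),
                 sigma = sigma, params = params),
            class = "vff_field2d")
}

#' @export
print.vff_field2d <- function(x, ...) {
  cat(sprintf("2D velocity/contraction field on a %d x %d periodic grid\n",
              nrow(x$w), ncol(x$w)))
  cat(sprintf("  max contraction rate %.4g nm/s, max |v| %.4g nm/s\n",
              max(x$w), sqrt(max(x$vx^2 + x$vy^2))))
  invisible(x)
}

#' Extrude a 1D tension slice into a 2D stress field
#'
#' Builds the experimental geometry of the ventral myosin patch: the
#' ventral-lateral profile `T_slice` (curvature axis) extended with
#' constant amplitude over `extent` cells along the anterior-posterior
#' axis, with a raised-cosine taper of `taper` cells at the two ends so
#' the field is compactly supported on the periodic grid.
#'
#' @param T_slice 1D tension values (pN), compactly supported.
#' @param n_grid periodic grid size per side (default 128).
#' @param extent flat extent along the second axis, cells (default 30).
#' @param taper taper length, cells.
#' @return `n_grid x n_grid` stress matrix with the patch centred.
#' @export
extrude_stress <- function(T_slice, n_grid = 128, extent = 30, taper = 6) {
  m <- length(T_slice)
  if (m > n_grid) stop("`T_slice` longer than the grid")
  tx <- numeric(n_grid)
  i0 <- floor((n_grid - m) / 2)
  tx[i0 + seq_len(m)] <- T_slice
  yc <- (n_grid + 1) / 2
  d <- abs(seq_len(n_grid) - yc)
  fy <- ifelse(d <= extent / 2, 1,
               ifelse(d <= extent / 2 + taper,
                      0.5 * (1 + cos(pi * (d - extent / 2) / taper)), 0))
  outer(tx, fy)
}

#' Per-axis contraction summary for an anisotropic stress field
#'
#' Demonstrates that contraction follows the curvature of the myosin
#' patterning direction by direction: for a stress with curvature along
#' the first axis but flat along the second, cells contract along the
#' first axis only. Reports the directional contraction rates at the
#' stress maximum and their profiles through it.
#'
#' @param sigma stress matrix (see [solve_velocity_field_2d()]).
#' @param params a [vff_params()] object.
#' @return list with `w_axis1`, `w_axis2` (directional contraction rates
#'   at the stress centre, nm/s), `flat_to_curved_ratio`
#'   (|w_axis2|/|w_axis1|), and profiles `profile_axis1`
#'   (`wx` along axis 1 through the centre), `profile_axis2` (`wy` along
#'   axis 2).
#' @export
anisotropy_report <- function(sigma, params) {
  f <- solve_velocity_field_2d(sigma, params)
  # centre of the maximal-stress set (a flat plateau for extruded fields)
  ij <- round(colMeans(which(sigma >= max(sigma) * (1 - 1e-12), arr.ind = TRUE)))
  w1 <- f$wx[ij[1], ij[2]]
  w2 <- f$wy[ij[1], ij[2]]
  list(w_axis1 = w1, w_axis2 = w2,
       flat_to_curved_ratio = abs(w2) / abs(w1),
       profile_axis1 = f$wx[, ij[2]],
       profile_axis2 = f$wy[ij[1], ],
       centre = ij, field = f)
}
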