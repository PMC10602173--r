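# Thomas algorithm for tridiagonal systems; lower/upper have length n-1.
solve_tridiag <- function(lower, diagv, upper, rhs) {
  n <- length(diagv)
  cp <- numeric(n)
  dp <- numeric(n)
  cp[1] <- upper[1] / diagv[1]
  dp[1] <- rhs[1] / diagv[1]
  for (i in 2:n) {
    m <- diagv[i] - lower[i - 1] * cp[i - 1]
    if (abs(m) < .Machine$double.eps * 1e3) stop("singular tridiagonal system")
    if (i < n) cp[i] <- upper[i] / m
    dp[i] <- (rhs[i] - lower[i - 1] * dp[i - 1]) / m
  }
  x <- numeric(n)
  x[n] <- dp[n]
  for (i in (n - 1):1) x[i] <- dp[i] - cp[i] * x[i + 1]
  x
}

#' Solve the quasi-static force balance for contraction rates
#'
#' Given one instantaneous tension slice \eqn{T(n)} (pN) on a contiguous
#' cell grid with unit spacing, solves the overdamped viscous force balance
#' for the contraction-rate profile \eqn{w(n)} (nm/s), with the sign
#' convention \eqn{w > 0 \iff} contraction.
#'
#' Two equivalent discretisations are provided:
#' * `"discrete"` (default): the cell-level force balance. Edge velocities
#'   `u` between adjacent cells satisfy
#'   \eqn{T_{tot}(n+1) - T_{tot}(n) = \bar\lambda_j u_j} with
#'   \eqn{T_{tot} = T - \mu w} and \eqn{w(n) = u_{left} - u_{right}}; edge
#'   drag \eqn{\bar\lambda_j} averages the per-cell drag of the flanking
#'   cells. This is the only valid form under spatially varying drag, and
#'   for uniform drag eliminating `u` reproduces the `"continuum"` system
#'   exactly (row by row at interior cells).
#' * `"continuum"`: the second-order form
#'   \eqn{\mu D^2 w - \lambda w = D^2 T} with the standard second difference
#'   `D^2` and Dirichlet conditions \eqn{w(\pm N) = 0}; only valid for
#'   uniform drag.
#'
#' @param T_slice numeric vector of tensions (pN) on the grid; its spatial
#'   variation must be compactly supported (constant, typically zero, at
#'   the two boundary cells).
#' @param params a [vff_params()] object (requires `lambda > 0`).
#' @param drag_factor optional per-cell multiplier on `lambda` in (0, 1]
#'   (same length as `T_slice`); default uniform 1.
#' @param method `"auto"` (discrete), `"discrete"` or `"continuum"`.
#' @param spacing grid spacing in cells for the `"continuum"` method
#'   (default 1); values < 1 refine the continuum equation for convergence
#'   studies. The `"discrete"` cell form is inherently unit spacing.
#' @param return_velocity if `TRUE`, attach the cell velocities (nm/s,
#'   mean of the two edge velocities; `"discrete"` method only) as
#'   attribute `"velocity"`.
#' @return Numeric vector `w` of contraction rates, nm/s.
#' @examples
#' p <- vff_params()
#' n <- -40:40
#' Th <- ifelse(abs(n) < 10, p$T_star, 0)        # top-hat, h = 20
#' w <- solve_contraction_rate(Th, p)
#' w[n == 0]  # ~ w* exp(-h/(2 xi)), tiny: no contraction away from edges
#' @export
solve_contraction_rate <- function(T_slice, params, drag_factor = NULL,
                                   method = c("auto", "discrete", "continuum"),
                                   spacing = 1, return_velocity = FALSE) {
  method <- match.arg(method)
  m <- length(T_slice)
  if (m < 5) stop("grid too small (need at least 5 cells)")
  if (!is.numeric(T_slice) || any(!is.finite(T_slice)))
    stop("`T_slice` must be finite numeric")
  # the solver only sees tension differences, so a constant offset is
  # harmless; what invalidates the boundary conditions is tension
  # *variation* reaching the domain ends at a non-negligible fraction of
  # the interior gradients
  gmax <- max(abs(diff(T_slice)))
  if (gmax > 0) {
    tol <- 1e-3 * gmax
    if (abs(T_slice[2] - T_slice[1]) > tol || abs(T_slice[m] - T_slice[m - 1]) > tol)
      stop("tension varies at the grid boundary; enlarge the domain")
  }
  if (is.null(drag_factor)) drag_factor <- rep(1, m)
  if (length(drag_factor) != m) stop("`drag_factor` must match `T_slice` in length")
  if (any(drag_factor <= 0) || any(drag_factor > 1))
    stop("`drag_factor` entries must lie in (0, 1]")
  mu <- params$mu
  lam <- params$lambda * drag_factor
  if (method == "auto") method <- "discrete"

  if (method == "continuum") {
    if (diff(range(drag_factor)) > 0)
      stop("the continuum form assumes uniform drag; use method = \"discrete\"")
    if (spacing <= 0) stop("`spacing` must be positive")
    h2 <- spacing^2
    d2T <- (T_slice[1:(m - 2)] - 2 * T_slice[2:(m - 1)] + T_slice[3:m]) / h2
    w_int <- solve_tridiag(rep(mu / h2, m - 3),
                           rep(-(2 * mu / h2 + lam[1]), m - 2),
                           rep(mu / h2, m - 3), d2T)
    w <- c(0, w_int, 0)
    if (return_velocity) attr(w, "velocity") <- solve_velocity(w) * spacing
    return(w)
  }
  if (spacing != 1) stop("the discrete cell form uses unit spacing")

  # discrete cell-level balance: unknown edge velocities u_j, j between
  # cells j and j+1; outer edges clamped at 0
  lam_edge <- (lam[1:(m - 1)] + lam[2:m]) / 2
  rhs <- T_slice[1:(m - 1)] - T_slice[2:m]
  u <- solve_tridiag(rep(mu, m - 2), -(2 * mu + lam_edge), rep(mu, m - 2), rhs)
  uu <- c(0, u, 0)
  w <- uu[1:m] - uu[2:(m + 1)]
  if (return_velocity) attr(w, "velocity") <- (uu[1:m] + uu[2:(m + 1)]) / 2
  w
}

#' Integrate contraction rates into a velocity profile
#'
#' The contraction rate is minus the velocity gradient,
#' \eqn{w \equiv -\partial v/\partial n}; this inverts that relation by
#' trapezoidal accumulation, anchoring the integration constant so that the
#' velocity is antisymmetric for symmetric `w` (zero at the midline). When
#' the zero-sum property \eqn{\sum_n w(n) = 0} holds, the boundary
#' velocities come out ~0.
#'
#' @param w contraction-rate vector (nm/s) on the full grid.
#' @param grid optional [cell_grid()] (only used for a length check).
#' @return Velocity vector (nm/s), positive toward larger `n`.
#' @export
solve_velocity <- function(w, grid = NULL) {
  if (!is.null(grid) && length(w) != length(grid$indices))
    stop("`w` must be defined on the full grid")
  m <- length(w)
  V <- c(0, cumsum((w[1:(m - 1)] + w[2:m]) / 2))
  mid <- if (m %% 2 == 1) V[(m + 1) / 2] else (V[m / 2] + V[m / 2 + 1]) / 2
  -(V - mid)
}

#' Closed-form contraction-rate profiles for hypothetical envelopes
#'
#' Analytic solutions of the continuum force balance
#' \eqn{w'' - w/\xi^2 = T''/\mu} for three time-independent envelope
#' shapes, obtained with the exponential Green's function
#' \eqn{G(n, m) = -(\xi/2) e^{-|n-m|/\xi}} applied to the distributional
#' second derivative of \eqn{T(n)}:
#' * `"top_hat"`: \eqn{T = T^*} on \eqn{|n| < h/2};
#'   \eqn{w(n) = (w^*/2)[\mathrm{sgn}(n+h/2)e^{-|n+h/2|/\xi} -
#'   \mathrm{sgn}(n-h/2)e^{-|n-h/2|/\xi}]}.
#' * `"triangular"`: \eqn{T = T^*(1-|n|/h)_+} (support `2h` wide);
#'   \eqn{w(n) = (w^*\xi/2h)[2e^{-|n|/\xi} - e^{-|n+h|/\xi} -
#'   e^{-|n-h|/\xi}]}.
#' * `"parabolic"`: \eqn{T = T^*(1-(2n/h)^2)_+};
#'   \eqn{w(n) = -(2 w^* \xi/h)(e^{-|n-h/2|/\xi} + e^{-|n+h/2|/\xi})
#'   + 4 w^* (\xi/h)^2 \times} \{\eqn{2 - e^{-(h/2-|n|)/\xi} -
#'   e^{-(h/2+|n|)/\xi}} inside the support;
#'   \eqn{(e^{h/2\xi} - e^{-h/2\xi}) e^{-|n|/\xi}} outside\}.
#'
#' Contraction is confined to within \eqn{\sim\xi} of the singular points
#' for the curvature-free shapes (top-hat edges, triangle vertex), whereas
#' the parabolic profile contracts its whole interior: the closed forms are
#' the quantitative statement that tissue contraction requires envelope
#' curvature. These expressions serve as the independent oracle for
#' [solve_contraction_rate()].
#'
#' @param shape `"top_hat"`, `"triangular"` or `"parabolic"`.
#' @param n cell coordinate(s), may be non-integer.
#' @param h profile width parameter, cells.
#' @param params a [vff_params()] object (supplies `xi` and `w_star`).
#' @return Contraction rate(s) `w(n)`, nm/s.
#' @examples
#' p <- vff_params()
#' closed_form_w("top_hat", 0, h = 20, p)     # ~ w* exp(-4): essentially zero
#' closed_form_w("parabolic", 0, h = 8, p)    # broad central contraction
#' @export
closed_form_w <- function(shape = c("top_hat", "triangular", "parabolic"),
                          n, h, params) {
  shape <- match.arg(shape)
  if (h <= 0) stop("`h` must be positive")
  xi <- params$xi
  ws <- params$w_star
  E <- function(x) exp(-abs(x) / xi)
  switch(shape,
    top_hat = (ws / 2) * (sign(n + h / 2) * E(n + h / 2) -
                          sign(n - h / 2) * E(n - h / 2)),
    triangular = (ws * xi / (2 * h)) * (2 * E(n) - E(n + h) - E(n - h)),
    parabolic = {
      an <- abs(n)
      edge <- -(2 * ws * xi / h) * (E(n - h / 2) + E(n + h / 2))
      inside <- 4 * ws * (xi / h)^2 *
        (2 - exp(-(h / 2 - pmin(an, h / 2)) / xi) - exp(-(h / 2 + an) / xi))
      outside <- 4 * ws * (xi / h)^2 *
        (exp(h / (2 * xi)) - exp(-h / (2 * xi))) * exp(-an / xi)
      edge + ifelse(an < h / 2, inside, outside)
    })
}
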