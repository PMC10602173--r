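#' Physical parameters of the viscous force-balance model
#'
#' Bundles the constants governing apical constriction mechanics during
#' ventral furrow formation: the internal viscosity \eqn{\mu} (pN s/nm)
#' resisting apical width change, the external drag coefficient per cell
#' \eqn{\lambda \equiv \tilde\lambda/2} (pN s/nm) resisting translation of
#' cells relative to the vitelline membrane, an optional elastic constant
#' \eqn{k} (pN/\eqn{\mu}m), and the peak actomyosin tension \eqn{T^*} (pN).
#' Two derived quantities control all solutions of the force balance: the
#' damping length \eqn{\xi = \sqrt{\mu/\lambda}} (cells), separating
#' viscosity-dominated from drag-dominated scales, and the characteristic
#' contraction rate \eqn{w^* = T^*/\mu} (nm/s).
#'
#' All internal computation uses pN, nm and s, so tensions are pN, `mu` and
#' `lambda` are pN s/nm and contraction rates/velocities come out in nm/s.
#' Cell widths and areas are reported in \eqn{\mu}m and \eqn{\mu}m\eqn{^2}.
#'
#' @param mu internal viscosity, pN s/nm. Default 36.
#' @param xi damping length in cells; only used to derive the default
#'   `lambda = mu/xi^2`. Default 2.5.
#' @param lambda external drag coefficient per cell, pN s/nm.
#' @param k_elastic elastic constant resisting apical width change,
#'   pN/\eqn{\mu}m. Default 0 (elastic forces are ~20-fold weaker than the
#'   myosin tensions and are discarded in the baseline model).
#' @param T_star peak myosin tension, pN. Default 1500 (= 1.5 nN).
#' @param b_len effective anterior-posterior cell length, \eqn{\mu}m.
#' @param L_rest resting apical cell width, \eqn{\mu}m.
#' @param H cell height, \eqn{\mu}m.
#' @param V conserved cell volume, \eqn{\mu}m\eqn{^3}. Default
#'   `L_rest * b_len * H` = 1556.1 so that the rest state is exactly flat.
#' @param beta drag reduction factor applied on `beta_cells` (models local
#'   detachment from the vitelline membrane); must lie in (0, 1].
#' @param beta_cells integer cell indices over which `beta` applies, or
#'   `NULL` for uniform drag.
#'
#' @return An object of class `"vff_params"`: a list with the fields above
#'   plus derived `xi` and `w_star`.
#' @examples
#' p <- vff_params()
#' p$xi      # 2.5 cells
#' p$w_star  # ~41.7 nm/s
#' @export
vff_params <- function(mu = 36, xi = 2.5, lambda = mu / xi^2,
                       k_elastic = 0, T_star = 1500, b_len = 5.7,
                       L_rest = 7, H = 39, V = L_rest * b_len * H,
                       beta = 1, beta_cells = NULL) {
  num1 <- function(x, nm) {
    if (!is.numeric(x) || length(x) != 1L || !is.finite(x))
      stop("`", nm, "` must be a single finite number", call. = FALSE)
  }
  num1(mu, "mu"); num1(lambda, "lambda"); num1(k_elastic, "k_elastic")
  num1(T_star, "T_star"); num1(b_len, "b_len"); num1(L_rest, "L_rest")
  num1(H, "H"); num1(V, "V"); num1(beta, "beta")
  if (mu <= 0) stop("internal viscosity `mu` must be positive")
  if (lambda <= 0) stop("external drag `lambda` must be positive (the system is singular otherwise)")
  if (k_elastic < 0) stop("`k_elastic` must be >= 0")
  if (T_star < 0) stop("`T_star` must be >= 0")
  if (b_len <= 0 || L_rest <= 0 || H <= 0 || V <= 0)
    stop("geometry constants `b_len`, `L_rest`, `H`, `V` must be positive")
  if (beta <= 0 || beta > 1)
    stop("drag reduction factor `beta` must lie in (0, 1]")
  if (!is.null(beta_cells)) {
    if (!is.numeric(beta_cells) || any(beta_cells != round(beta_cells)))
      stop("`beta_cells` must be integer cell indices")
    beta_cells <- as.integer(beta_cells)
  }
  structure(
    list(mu = mu, lambda = lambda, k_elastic = k_elastic, T_star = T_star,
         b_len = b_len, L_rest = L_rest, H = H, V = V,
         beta = beta, beta_cells = beta_cells,
         xi = sqrt(mu / lambda), w_star = T_star / mu),
    class = "vff_params")
}

#' @export
print.vff_params <- function(x, ...) {
  cat("Viscous force-balance parameters\n")
  cat(sprintf("  mu     = %.4g pN s/nm   (internal viscosity)\n", x$mu))
  cat(sprintf("  lambda = %.4g pN s/nm   (external drag per cell)\n", x$lambda))
  cat(sprintf("  k      = %.4g pN/um     (elastic constant)\n", x$k_elastic))
  cat(sprintf("  T*     = %.4g pN        (peak myosin tension)\n", x$T_star))
  cat(sprintf("  xi     = %.4g cells     (damping length)\n", x$xi))
  cat(sprintf("  w*     = %.4g nm/s      (characteristic contraction rate)\n", x$w_star))
  if (!is.null(x$beta_cells))
    cat(sprintf("  drag reduced by beta = %.3g on cells %d..%d\n",
                x$beta, min(x$beta_cells), max(x$beta_cells)))
  invisible(x)
}

#' Discrete cell grid along the ventral-lateral axis
#'
#' Integer cell positions `n` in `[-N, N]` with the midline cell at `n = 0`;
#' the default `N = 40` gives 81 cells, matching the ~80 connected cells that
#' span the ventral-lateral axis at the embryo's widest point. `N` must be at
#' least twice the envelope half-width so that tension profiles are compactly
#' supported well inside the boundary.
#'
#' @param N half-domain size in cells (integer >= 2).
#' @return An object of class `"cell_grid"` with fields `indices` and `N`.
#' @export
cell_grid <- function(N = 40) {
  if (!is.numeric(N) || length(N) != 1L || N != round(N) || N < 2)
    stop("`N` must be a single integer >= 2")
  N <- as.integer(N)
  structure(list(indices = seq.int(-N, N), N = N), class = "cell_grid")
}

#' @export
print.cell_grid <- function(x, ...) {
  cat(sprintf("Cell grid: n = %d..%d (%d cells)\n", -x$N, x$N, 2L * x$N + 1L))
  invisible(x)
}

#' Per-cell drag multiplier profile
#'
#' Expands the `beta`/`beta_cells` fields of [vff_params()] into a per-cell
#' multiplier on `lambda` over a grid (1 everywhere by default).
#'
#' @param params a [vff_params()] object.
#' @param grid a [cell_grid()] object.
#' @return Numeric vector of multipliers in (0, 1], one per grid cell.
#' @export
drag_profile <- function(params, grid) {
  f <- rep(1, length(grid$indices))
  if (!is.null(params$beta_cells))
    f[grid$indices %in% params$beta_cells] <- params$beta
  f
}

#' Derive viscosity and drag from fitted reduced parameters
#'
#' The solutions of the force balance involve only the reduced parameters
#' \eqn{\xi} and \eqn{w^*}; with an independently measured peak tension
#' \eqn{T^*} these determine the physical constants via
#' \eqn{\mu = T^*/w^*} and \eqn{\lambda = T^*/(\xi^2 w^*)}.
#'
#' @param T_star peak myosin tension, pN.
#' @param w_star characteristic contraction rate, nm/s.
#' @param xi damping length, cells.
#' @return list with components `mu` and `lambda` (pN s/nm).
#' @examples
#' derive_mu_lambda(1500, 42, 2.5)  # mu ~ 35.7, lambda ~ 5.7
#' @export
derive_mu_lambda <- function(T_star, w_star, xi) {
  if (any(c(T_star, w_star, xi) <= 0)) stop("all inputs must be positive")
  list(mu = T_star / w_star, lambda = T_star / (xi^2 * w_star))
}

#' Critical relative myosin fluctuation
#'
#' A frozen per-cell myosin deficit competes with the envelope-driven
#' contraction; the deficit wins (the cell expands) for relative fluctuations
#' of order \eqn{\epsilon_{crit} = (2\xi/h)^2} or greater, where `h` is the
#' envelope width in cells.
#'
#' @param xi damping length, cells.
#' @param h envelope width, cells.
#' @return `(2*xi/h)^2` as a fraction (vectorised).
#' @examples
#' epsilon_crit(2, 8)  # 0.25
#' @export
epsilon_crit <- function(xi, h) {
  if (any(h <= 0)) stop("`h` must be positive")
  (2 * xi / h)^2
}

#' Local expansion and envelope contraction rate scales
#'
#' Order-of-magnitude rates entering the critical-fluctuation argument: a
#' cell with relative myosin deficit `eps` expands at rate
#' \eqn{\epsilon T_{env}/\mu} (its contraction is resisted by internal
#' viscosity on sub-\eqn{\xi} scales), while the curvature of an envelope of
#' width `h` contracts cells at rate \eqn{2 T_{env}/(h^2\lambda)}. Equating
#' the two reproduces [epsilon_crit()] up to a factor-2 convention.
#'
#' @param eps relative fluctuation magnitude (fraction).
#' @param T_env local envelope tension, pN.
#' @param params a [vff_params()] object.
#' @param h envelope width, cells.
#' @return list with `expansion_rate` and `envelope_rate`, both nm/s.
#' @export
local_rate_estimates <- function(eps, T_env, params, h) {
  if (any(T_env < 0) || any(h <= 0)) stop("`T_env` must be >= 0 and `h` > 0")
  list(expansion_rate = eps * T_env / params$mu,
       envelope_rate = 2 * T_env / (h^2 * params$lambda))
}

#' Elastic versus myosin force comparison
#'
#' Elastic stresses resisting apical width change are of order
#' \eqn{k\,\Delta L}; with the measured \eqn{k = 7} pN/\eqn{\mu}m even a
#' full-width strain (\eqn{\Delta L = 7\ \mu}m) gives ~50 pN, over 20-fold
#' smaller than the ~1.5 nN actomyosin tensions, which justifies dropping
#' the elastic term from the baseline force balance.
#'
#' @param T_star peak myosin tension, pN.
#' @param k elastic constant, pN/\eqn{\mu}m.
#' @param delta_L width change, \eqn{\mu}m.
#' @return list with `elastic_force` (pN) and `ratio` (myosin : elastic).
#' @examples
#' elastic_myosin_ratio()  # ~50 pN, ratio ~30
#' @export
elastic_myosin_ratio <- function(T_star = 1500, k = 7, delta_L = 7) {
  f <- k * delta_L
  list(elastic_force = f, ratio = T_star / f)
}
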