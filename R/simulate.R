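#' Integrate tissue dynamics under a tension profile
#'
#' Quasi-static time integration of the viscous force balance: at each time
#' step the contraction-rate profile `w` is solved from the current tension
#' slice (the overdamped dynamics have no inertia, so `w` responds
#' instantaneously), then cell widths are updated by
#' \eqn{L \leftarrow L - w\,dt} (with nm to \eqn{\mu}m conversion) and
#' apical areas follow as \eqn{A = b L} (fixed anterior-posterior cell
#' length). When `k_elastic > 0` the elastic restoring term enters as an
#' effective tension \eqn{T + k (L - L_{rest})}, recomputed each step from
#' the current widths (explicit coupling).
#'
#' A cell whose width falls to `removal_width` or below is marked dead,
#' its width reported as 0 thereafter, and it is excised from the grid for
#' subsequent solves: its neighbours become mechanically adjacent. Cell
#' labels are never re-indexed in the output.
#'
#' @param profile a [tension_profile()]; its time points define the
#'   integration steps (must be uniformly spaced).
#' @param params a [vff_params()] object.
#' @param drag_factor optional per-cell drag multiplier; default taken from
#'   `params` via [drag_profile()].
#' @param L_init initial widths, \eqn{\mu}m (default `L_rest` everywhere).
#' @param removal_width width (\eqn{\mu}m) at or below which a cell is
#'   removed (a strict zero is never reached in finite steps).
#' @return An object of class `"vff_sim"`: list with `times`, `grid`,
#'   cells-by-times matrices `L` (width, \eqn{\mu}m), `A` (area,
#'   \eqn{\mu}m\eqn{^2}), `w` (contraction rate, nm/s), `v` (velocity,
#'   nm/s), logical `alive`, plus `params`, `dt` and `removal_width`.
#'   `w` and `v` are `NA` for dead cells.
#' @examples
#' env <- make_envelope("parabolic", h = 8, times = seq(0, 500, 5))
#' sim <- simulate_furrow(env)
#' summary(sim)
#' @export
simulate_furrow <- function(profile, params = vff_params(), drag_factor = NULL,
                            L_init = NULL, removal_width = 0.5) {
  if (!inherits(profile, "tension_profile")) stop("`profile` must be a tension_profile")
  times <- profile$times
  nt <- length(times)
  if (nt < 2) stop("profile must have at least two time points")
  dts <- diff(times)
  if (diff(range(dts)) > 1e-9 * max(dts))
    stop("profile time points must be uniformly spaced")
  dt <- dts[1]
  if (dt <= 0) stop("time step must be positive")
  if (dt > 1 + 1e-9)
    warning("dt > 1 s: the quasi-static update may be inaccurate for fast fluctuations")
  grid <- profile$grid
  nc <- length(grid$indices)
  if (is.null(drag_factor)) drag_factor <- drag_profile(params, grid)
  if (is.null(L_init)) L_init <- rep(params$L_rest, nc)
  if (length(L_init) != nc || any(L_init <= 0))
    stop("`L_init` must give a positive width for every cell")

  L <- matrix(NA_real_, nc, nt)
  w <- matrix(NA_real_, nc, nt)
  v <- matrix(NA_real_, nc, nt)
  alive <- matrix(FALSE, nc, nt)
  Lcur <- L_init
  alive_cur <- rep(TRUE, nc)
  L[, 1] <- Lcur
  alive[, 1] <- TRUE
  truncated <- FALSE

  for (k in seq_len(nt)) {
    if (k > 1) {
      L[, k] <- Lcur
      alive[, k] <- alive_cur
    }
    idx <- which(alive_cur)
    if (length(idx) < 5) {
      warning("fewer than 5 live cells remain; trajectory truncated at t = ",
              times[k], " s")
      truncated <- TRUE
      break
    }
    Teff <- profile$values[idx, k]
    if (params$k_elastic > 0)
      Teff <- Teff + params$k_elastic * (Lcur[idx] - params$L_rest)
    wk <- solve_contraction_rate(Teff, params, drag_factor = drag_factor[idx],
                                 method = "discrete", return_velocity = TRUE)
    w[idx, k] <- wk
    v[idx, k] <- attr(wk, "velocity")
    if (k == nt) break
    Lnew <- Lcur[idx] - as.numeric(wk) * dt * 1e-3   # nm -> um
    dead <- Lnew <= removal_width
    Lcur[idx] <- ifelse(dead, 0, pmax(Lnew, 0))
    alive_cur[idx[dead]] <- FALSE
  }

  A <- params$b_len * L
  structure(list(times = times, grid = grid, L = L, A = A, w = w, v = v,
                 alive = alive, params = params, dt = dt,
                 removal_width = removal_width, truncated = truncated),
            class = "vff_sim")
}

#' Final (or time-matched) apical area profile of a simulation
#'
#' @param sim a [simulate_furrow()] result.
#' @param time time in seconds (default: end of the run); nearest stored
#'   time point is used.
#' @return Numeric vector of apical areas (\eqn{\mu}m\eqn{^2}) per cell.
#' @export
final_areas <- function(sim, time = NULL) {
  i <- if (is.null(time)) ncol(sim$A) else which.min(abs(sim$times - time))
  structure(sim$A[, i], time = sim$times[i])
}

#' @export
print.vff_sim <- function(x, ...) {
  nt <- ncol(x$L)
  ndead <- sum(!x$alive[, nt])
  cat(sprintf("Tissue simulation: %d cells, t = %g..%g s (dt = %g s)\n",
              nrow(x$L), min(x$times), max(x$times), x$dt))
  cat(sprintf("  final midline width %.3g um (rest %.3g um); %d cell(s) removed\n",
              x$L[x$grid$indices == 0, nt], x$params$L_rest, ndead))
  if (isTRUE(x$truncated)) cat("  [trajectory truncated: too few live cells]\n")
  invisible(x)
}

#' @export
summary.vff_sim <- function(object, ...) {
  nt <- ncol(object$A)
  a <- object$A[, nt]
  out <- list(
    n_cells = nrow(object$A),
    t_end = max(object$times),
    n_dead = sum(!object$alive[, nt]),
    area_quartiles = stats::quantile(a, c(0, .25, .5, .75, 1)),
    midline_area = a[object$grid$indices == 0],
    rest_area = object$params$b_len * object$params$L_rest)
  class(out) <- "summary.vff_sim"
  out
}

#' @export
print.summary.vff_sim <- function(x, ...) {
  cat(sprintf("Simulation of %d cells to t = %g s; %d cell(s) removed\n",
              x$n_cells, x$t_end, x$n_dead))
  cat(sprintf("  midline apical area %.3g um^2 (rest %.3g um^2)\n",
              x$midline_area, x$rest_area))
  cat("  final area quartiles (um^2):\n")
  print(round(x$area_quartiles, 2))
  invisible(x)
}

#' @export
plot.vff_sim <- function(x, time = NULL, ...) {
  a <- final_areas(x, time)
  n <- x$grid$indices
  graphics::plot(n, a, type = "h", lwd = 3, col = "steelblue",
                 xlab = "cell n (from ventral midline)",
                 ylab = expression(paste("apical area (", mu, m^2, ")")),
                 main = sprintf("Apical area profile at t = %g s", attr(a, "time")), ...)
  graphics::abline(h = x$params$b_len * x$params$L_rest, lty = 2, col = "red")
  invisible(x)
}

#' Long-format data frame of a simulated trajectory
#'
#' @param x a `vff_sim` object.
#' @param row.names,optional,... passed through for S3 compatibility.
#' @return data frame with columns `time_s`, `cell_n`, `width_um`,
#'   `area_um2`, `velocity_nm_s`, `contraction_nm_s`, `alive`.
#' @export
as.data.frame.vff_sim <- function(x, row.names = NULL, optional = FALSE, ...) {
  nc <- nrow(x$L); nt <- ncol(x$L)
  data.frame(
    time_s = rep(x$times, each = nc),
    cell_n = rep(x$grid$indices, nt),
    width_um = as.vector(x$L),
    area_um2 = as.vector(x$A),
    velocity_nm_s = as.vector(x$v),
    contraction_nm_s = as.vector(x$w),
    alive = as.vector(x$alive))
}
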