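#' Spatiotemporal myosin tension profile
#'
#' The model's sole driver: the actomyosin tension \eqn{T_{myo}(n, t)} (pN),
#' assumed proportional to the amount of activated apical myosin, stored as a
#' cells-by-times matrix on a [cell_grid()].
#'
#' @param values numeric matrix, `length(grid$indices)` rows by
#'   `length(times)` columns, tension in pN; must be non-negative and vanish
#'   at the boundary cells (compact support).
#' @param grid a [cell_grid()].
#' @param times strictly increasing time points, s.
#' @return An object of class `"tension_profile"`.
#' @export
tension_profile <- function(values, grid, times) {
  values <- as.matrix(values)
  if (!inherits(grid, "cell_grid")) stop("`grid` must be a cell_grid")
  if (nrow(values) != length(grid$indices) || ncol(values) != length(times))
    stop("`values` must be a cells x times matrix matching `grid` and `times`")
  if (any(!is.finite(values))) stop("tension values must be finite")
  if (any(values < 0)) stop("tension values must be >= 0")
  if (length(times) > 1 && any(diff(times) <= 0))
    stop("`times` must be strictly increasing")
  structure(list(values = values, grid = grid, times = as.numeric(times)),
            class = "tension_profile")
}

#' @export
print.tension_profile <- function(x, ...) {
  cat(sprintf("Tension profile: %d cells (n = %d..%d), %d time points (%.6g..%.6g s)\n",
              nrow(x$values), -x$grid$N, x$grid$N, length(x$times),
              min(x$times), max(x$times)))
  cat(sprintf("  peak tension %.4g pN\n", max(x$values)))
  invisible(x)
}

#' Extract one time slice of a tension profile
#'
#' @param profile a [tension_profile()].
#' @param time time in seconds; the nearest stored time point is used.
#' @return Numeric vector of tensions (pN) over the grid, with the matched
#'   time as attribute `"time"`.
#' @export
profile_slice <- function(profile, time) {
  i <- which.min(abs(profile$times - time))
  structure(profile$values[, i], time = profile$times[i])
}

# spatial shape factors, unit peak, on integer cell positions n
envelope_shape <- function(shape, n, h, shoulder) {
  switch(shape,
    parabolic = pmax(1 - (2 * n / h)^2, 0),
    gaussian = {
      s <- h / (2 * sqrt(2 * log(2)))  # FWHM = h
      v <- exp(-n^2 / (2 * s^2))
      v[v < 1e-8] <- 0
      v
    },
    top_hat = ifelse(abs(n) <= h / 2, 1,
                     if (shoulder > 0) pmax(1 - (abs(n) - h / 2) / shoulder, 0) else 0),
    triangular = pmax(1 - abs(n) / h, 0),
    stop("unknown envelope shape: ", shape))
}

#' Ramping myosin envelope
#'
#' Builds the smooth (fluctuation-free) component of the myosin patterning:
#' a symmetric spatial shape of width `h` cells whose amplitude ramps up
#' linearly, reaching the peak tension `T_star` at `ramp_duration` seconds,
#' i.e. \eqn{A(t) = T^* t/t_{ramp}}. With `cap = TRUE` (default) the
#' amplitude is held at `T_star` after the ramp; with `cap = FALSE` it keeps
#' growing linearly, the convention under which \eqn{T^*} is simply the
#' amplitude measured at \eqn{t = t_{ramp}} of an ongoing ramp (used by the
#' wild-type presets, where \eqn{T^*} is the 300-s amplitude).
#'
#' Supported shapes (all symmetric about the midline, zero outside their
#' support):
#' * `"parabolic"`: \eqn{T^*(1-(2n/h)^2)_+}, support `h` cells wide -- the
#'   wild-type stand-in (the only hypothetical shape with curvature in its
#'   interior). Note `h` here is the full support width; the half-width
#'   symbol used in the critical-fluctuation scaling ([epsilon_crit()])
#'   equals `h/2`, so the wild-type presets (envelope ~8 cells to half
#'   maximum... i.e. the measured 10--15-cell-wide bell) use `h = 16`.
#' * `"gaussian"`: full width at half maximum `h`, truncated to zero where
#'   negligible; an alternative bell shape.
#' * `"top_hat"`: constant plateau `h` cells wide falling linearly to zero
#'   over `shoulder` cells -- the Spn27A RNAi stand-in (~13-cell plateau
#'   dropping over 1-2 cells).
#' * `"triangular"`: \eqn{T^*(1-|n|/h)_+}; note its support is `2h` cells
#'   wide, matching the convention of the closed-form solutions.
#'
#' @param shape one of `"parabolic"`, `"gaussian"`, `"top_hat"`,
#'   `"triangular"`.
#' @param h envelope width parameter, cells (see shape descriptions).
#' @param T_star peak tension, pN.
#' @param ramp_duration linear ramp time, s.
#' @param shoulder for `"top_hat"`, cells over which the plateau falls to 0.
#' @param cap hold the amplitude at `T_star` after the ramp (default
#'   `TRUE`)?
#' @param grid a [cell_grid()].
#' @param times time points, s.
#' @return A [tension_profile()].
#' @examples
#' env <- make_envelope("parabolic", h = 8, ramp_duration = 500,
#'                      times = seq(0, 500, 50))
#' profile_slice(env, 500)[cell_grid()$indices == 0]  # peak = T* = 1500 pN
#' @export
make_envelope <- function(shape = c("parabolic", "gaussian", "top_hat", "triangular"),
                          h, T_star = 1500, ramp_duration = 500, shoulder = 2,
                          cap = TRUE, grid = cell_grid(),
                          times = seq(0, 500, by = 1)) {
  shape <- match.arg(shape)
  if (h <= 0) stop("envelope width `h` must be positive")
  if (ramp_duration <= 0) stop("`ramp_duration` must be positive")
  sv <- envelope_shape(shape, grid$indices, h, shoulder)
  nb <- length(sv)
  if (sv[1] > 0 || sv[nb] > 0)
    stop("envelope support reaches the grid boundary; enlarge the grid")
  amp <- T_star * pmax(times, 0) / ramp_duration
  if (cap) amp <- pmin(amp, T_star)
  p <- tension_profile(outer(sv, amp), grid, times)
  p$spec <- list(shape = shape, h = h, T_star = T_star,
                 ramp_duration = ramp_duration, shoulder = shoulder, cap = cap)
  p
}

#' Sample relative myosin fluctuations
#'
#' Generates the relative fluctuation field \eqn{\epsilon_{fluc}(n, t)} as
#' independent stationary Ornstein-Uhlenbeck processes, one per cell, with
#' stationary standard deviation `sigma` and autocorrelation
#' \eqn{e^{-\Delta t/\tau}}:
#' * `"pulsatile"` (wild-type): correlation time `tau` (~1 min pulsing).
#' * `"frozen"` (C-GAP RNAi): one draw per cell from the stationary law,
#'   held for the whole run (the \eqn{\tau \to \infty} limit).
#' * `"slow"`: correlation time `slow_factor * tau`, the "changes slowly"
#'   variant of the C-GAP condition.
#'
#' The exact discretisation
#' \eqn{\epsilon_{t+dt} = a\,\epsilon_t + \sigma\sqrt{1-a^2}\,Z},
#' \eqn{a = e^{-dt/\tau}}, is used, so the marginal law is stationary at any
#' step size. Fluctuations for distinct cells are statistically independent.
#'
#' @param grid a [cell_grid()].
#' @param times time points, s.
#' @param sigma stationary relative standard deviation (default 0.45, the
#'   measured ~45% cell-to-cell variation about the envelope).
#' @param tau correlation time, s (default 75, midpoint of the observed
#'   60-90 s pulsing time).
#' @param mode `"pulsatile"`, `"frozen"` or `"slow"`.
#' @param seed integer RNG seed (mandatory: runs must be reproducible).
#' @param slow_factor multiplier on `tau` for `mode = "slow"`.
#' @return Numeric cells-by-times matrix of relative fluctuations, with
#'   attributes `sigma`, `tau`, `mode`.
#' @export
sample_fluctuations <- function(grid, times, sigma = 0.45, tau = 75,
                                mode = c("pulsatile", "frozen", "slow"),
                                seed, slow_factor = 10) {
  mode <- match.arg(mode)
  if (missing(seed) || is.null(seed)) stop("`seed` is required for fluctuation sampling")
  if (sigma < 0) stop("`sigma` must be >= 0")
  if (mode != "frozen" && tau <= 0) stop("`tau` must be positive")
  set.seed(as.integer(seed))
  nc <- length(grid$indices)
  nt <- length(times)
  eps <- matrix(0, nc, nt)
  if (sigma > 0) {
    if (mode == "frozen") {
      eps[] <- rnorm(nc, 0, sigma)
    } else {
      tau_eff <- if (mode == "slow") slow_factor * tau else tau
      eps[, 1] <- rnorm(nc, 0, sigma)
      if (nt > 1) {
        dts <- diff(times)
        for (k in 2:nt) {
          a <- exp(-dts[k - 1] / tau_eff)
          eps[, k] <- a * eps[, k - 1] + sigma * sqrt(1 - a^2) * rnorm(nc)
        }
      }
    }
  }
  attr(eps, "sigma") <- sigma
  attr(eps, "tau") <- if (mode == "frozen") Inf else if (mode == "slow") slow_factor * tau else tau
  attr(eps, "mode") <- mode
  eps
}

#' Compose envelope and fluctuations into a full tension profile
#'
#' Pointwise product \eqn{T_{myo}(n,t) = [1 + \epsilon_{fluc}(n,t)]\,
#' T^{env}_{myo}(n,t)}, with the multiplier `1 + eps` clamped below at
#' `clamp_floor` so tension never goes negative.
#'
#' @param envelope a [tension_profile()] (the smooth envelope).
#' @param eps cells-by-times fluctuation matrix (e.g. from
#'   [sample_fluctuations()]).
#' @param clamp_floor minimum allowed value of `1 + eps` (default 0).
#' @return A [tension_profile()].
#' @export
compose_profile <- function(envelope, eps, clamp_floor = 0) {
  if (!inherits(envelope, "tension_profile")) stop("`envelope` must be a tension_profile")
  eps <- as.matrix(eps)
  if (!all(dim(eps) == dim(envelope$values)))
    stop("`eps` dimensions must match the envelope (cells x times)")
  if (clamp_floor < 0) stop("`clamp_floor` must be >= 0")
  mult <- matrix(pmax(1 + as.numeric(eps), clamp_floor), nrow(eps), ncol(eps))
  p <- tension_profile(envelope$values * mult, envelope$grid, envelope$times)
  p$spec <- envelope$spec
  p
}

#' Stochastic pulse-train tension profile (twist RNAi condition)
#'
#' In twist-depleted embryos the myosin envelope never ramps up; cells near
#' the midline instead fire asynchronous myosin pulses on a zero baseline.
#' Each active cell carries an independent renewal pulse train: pulses of
#' duration `pulse_duration` separated by gaps drawn uniformly from
#' `interval_range`, with amplitudes drawn uniformly from
#' `amplitude_range * T_star`. Tension is zero between pulses and outside
#' `active_cells`.
#'
#' @param grid a [cell_grid()].
#' @param times time points, s.
#' @param T_star wild-type peak tension, pN (amplitude reference).
#' @param pulse_duration pulse length, s (default 35).
#' @param interval_range inter-pulse gap range, s (default `c(30, 330)`).
#' @param amplitude_range pulse amplitude range as fractions of `T_star`
#'   (default `c(0, 2)`).
#' @param active_cells cell indices that pulse (default `-6:7`).
#' @param pulse_shape `"raised_cosine"` (smooth, default) or
#'   `"rectangular"`.
#' @param seed integer RNG seed (mandatory).
#' @return A [tension_profile()].
#' @export
make_twist_profile <- function(grid = cell_grid(), times = seq(0, 500, by = 1),
                               T_star = 1500, pulse_duration = 35,
                               interval_range = c(30, 330),
                               amplitude_range = c(0, 2),
                               active_cells = -6:7,
                               pulse_shape = c("raised_cosine", "rectangular"),
                               seed) {
  pulse_shape <- match.arg(pulse_shape)
  if (missing(seed) || is.null(seed)) stop("`seed` is required for pulse-train sampling")
  if (pulse_duration <= 0) stop("`pulse_duration` must be positive")
  if (interval_range[1] < 0 || diff(interval_range) < 0)
    stop("`interval_range` must be an increasing non-negative pair")
  if (amplitude_range[1] < 0 || diff(amplitude_range) < 0)
    stop("`amplitude_range` must be an increasing non-negative pair")
  set.seed(as.integer(seed))
  vals <- matrix(0, length(grid$indices), length(times))
  t_end <- max(times)
  rows <- which(grid$indices %in% active_cells)
  for (r in rows) {
    cursor <- 0
    repeat {
      start <- cursor + runif(1, interval_range[1], interval_range[2])
      if (start > t_end) break
      amp <- T_star * runif(1, amplitude_range[1], amplitude_range[2])
      sel <- times >= start & times <= start + pulse_duration
      if (any(sel)) {
        vals[r, sel] <- vals[r, sel] + if (pulse_shape == "raised_cosine")
          amp * 0.5 * (1 - cos(2 * pi * (times[sel] - start) / pulse_duration))
        else amp
      }
      cursor <- start + pulse_duration
    }
  }
  p <- tension_profile(vals, grid, times)
  p$spec <- list(shape = "pulse_train", pulse_duration = pulse_duration,
                 interval_range = interval_range,
                 amplitude_range = amplitude_range,
                 active_cells = active_cells, pulse_shape = pulse_shape)
  p
}

#' Assemble a modeled experimental condition
#'
#' Bundles the tension profile and parameter set for each modeled genotype:
#' * `"wildtype"`: parabolic envelope of half-width 8 cells (full support
#'   16 cells, the measured 10--15-cell-wide bell) ramping linearly with
#'   amplitude `T_star * t / 300 s` (the peak tension is the 300-s
#'   amplitude of an ongoing ramp), pulsatile fluctuations (sd 0.45,
#'   correlation time 75 s), uniform drag.
#' * `"cgap"`: same envelope, fluctuations frozen in time (one draw per
#'   cell) -- the C-GAP RNAi condition.
#' * `"spn27a"`: top-hat envelope (13-cell plateau, 2-cell shoulders)
#'   ramping over 700 s, drag reduced by `beta = 0.5` on cells -6..6 where
#'   the tissue detaches from the vitelline membrane; no fluctuations.
#' * `"twist"`: pulse trains on a zero baseline for cells -6..7 (see
#'   [make_twist_profile()]).
#' * `"single_deficit"`: the wild-type envelope with a frozen
#'   \eqn{\epsilon = -0.45} deficit on one near-peak cell (n = 1);
#'   deterministic.
#'
#' @param name condition preset name.
#' @param seed integer RNG seed; required for the stochastic presets
#'   (`wildtype`, `cgap`, `twist`).
#' @param grid a [cell_grid()].
#' @param dt time step, s.
#' @param t_end end time, s (defaults: 500, except 700 for `spn27a`).
#' @param sigma fluctuation sd for wildtype/cgap.
#' @param tau pulsatile correlation time, s.
#' @param cgap_mode `"frozen"` (default, used for ensemble statistics) or
#'   `"slow"` for the slowly drifting variant.
#' @return An object of class `"vff_condition"`: list with `name`,
#'   `profile`, `envelope` (the fluctuation-free profile), `params`,
#'   `grid`, `times`, `dt`, `t_end`, `seed`.
#' @export
preset_condition <- function(name = c("wildtype", "cgap", "spn27a", "twist", "single_deficit"),
                             seed = NULL, grid = cell_grid(), dt = 1,
                             t_end = NULL, sigma = 0.45, tau = 75,
                             cgap_mode = c("frozen", "slow")) {
  name <- match.arg(name)
  cgap_mode <- match.arg(cgap_mode)
  if (is.null(t_end)) t_end <- if (name == "spn27a") 700 else 500
  times <- seq(0, t_end, by = dt)
  needs_seed <- name %in% c("wildtype", "cgap", "twist")
  if (needs_seed && is.null(seed))
    stop("`seed` is required for the stochastic preset \"", name, "\"")
  params <- vff_params()
  wt_env <- function() make_envelope("parabolic", h = 16, T_star = params$T_star,
                                     ramp_duration = 300, cap = FALSE,
                                     grid = grid, times = times)
  envelope <- NULL
  profile <- switch(name,
    wildtype = {
      envelope <- wt_env()
      compose_profile(envelope, sample_fluctuations(grid, times, sigma, tau,
                                                    "pulsatile", seed = seed))
    },
    cgap = {
      envelope <- wt_env()
      compose_profile(envelope, sample_fluctuations(grid, times, sigma, tau,
                                                    cgap_mode, seed = seed))
    },
    spn27a = {
      params <- vff_params(beta = 0.5, beta_cells = -6:6)
      envelope <- make_envelope("top_hat", h = 13, shoulder = 2,
                                T_star = params$T_star, ramp_duration = 700,
                                grid = grid, times = times)
      envelope
    },
    twist = {
      envelope <- tension_profile(matrix(0, length(grid$indices), length(times)),
                                  grid, times)
      make_twist_profile(grid, times, T_star = params$T_star, seed = seed)
    },
    single_deficit = {
      envelope <- wt_env()
      eps <- matrix(0, length(grid$indices), length(times))
      eps[grid$indices == 1L, ] <- -0.45
      compose_profile(envelope, eps)
    })
  structure(list(name = name, profile = profile, envelope = envelope,
                 params = params, grid = grid, times = times, dt = dt,
                 t_end = t_end, seed = seed),
            class = "vff_condition")
}

#' @export
print.vff_condition <- function(x, ...) {
  cat(sprintf("Condition preset \"%s\": %d cells, t = 0..%g s (dt = %g s)%s\n",
              x$name, length(x$grid$indices), x$t_end, x$dt,
              if (!is.null(x$seed)) sprintf(", seed %d", x$seed) else ""))
  invisible(x)
}
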