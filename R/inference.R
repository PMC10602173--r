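#' Fit the reduced model parameters to observed profiles
#'
#' Solutions of the force balance involve only two reduced parameters: the
#' damping length \eqn{\xi} and the characteristic contraction rate
#' \eqn{w^* = T^*/\mu}. Mirroring the two-stage experimental fit, \eqn{\xi}
#' is estimated from the *shape* of the apical area profile (which is
#' amplitude-free: for a fixed-shape ramping envelope the area change
#' profile is proportional to the contraction-rate profile), and \eqn{w^*}
#' from the *amplitude* of the contraction-rate profile. Stage 1 runs a
#' grid search over `xi_grid` followed by golden-section refinement on the
#' normalised-profile least squares; stage 2 is a linear least-squares
#' scale fit. The procedure is deterministic given its inputs.
#'
#' @param area_profile observed apical areas (\eqn{\mu}m\eqn{^2}) on the
#'   full grid, at time `t_area`.
#' @param contraction_profile observed contraction rates (nm/s) on the
#'   full grid, at time `t_rate`.
#' @param envelope a [tension_profile()]: the known myosin envelope.
#' @param t_area,t_rate observation times, s (defaults: last envelope time
#'   for the area; 300 s, the conventional reference point, for the rate,
#'   capped at the last time).
#' @param params_ref a [vff_params()] supplying `T_star`, `b_len`,
#'   `L_rest` and a reference viscosity for the internal solves.
#' @param xi_grid grid-search values for \eqn{\xi}, cells.
#' @return An object of class `"vff_fit"` with `xi_hat` (cells),
#'   `w_star_hat` (nm/s), `residual` (total sum of squares),
#'   `covariance_proxy` (2 x 2 curvature-based approximation) and the
#'   inputs needed by `predict()`/`residuals()`.
#' @examples
#' env <- make_envelope("parabolic", h = 8, times = seq(0, 500, 5))
#' sim <- simulate_furrow(env)
#' fit <- fit_xi_wstar(final_areas(sim, 400), sim$w[, sim$times == 300], env)
#' coef(fit)  # recovers xi = 2.5, w* = T*/mu
#' @export
fit_xi_wstar <- function(area_profile, contraction_profile, envelope,
                         t_area = NULL, t_rate = 300,
                         params_ref = vff_params(),
                         xi_grid = seq(0.5, 8, by = 0.05)) {
  if (!inherits(envelope, "tension_profile")) stop("`envelope` must be a tension_profile")
  if (is.null(t_area)) t_area <- max(envelope$times)
  t_rate <- min(t_rate, max(envelope$times))
  T_area <- as.numeric(profile_slice(envelope, t_area))
  T_rate <- as.numeric(profile_slice(envelope, t_rate))
  A_rest <- params_ref$b_len * params_ref$L_rest
  dA <- area_profile - A_rest
  if (!any(is.finite(dA)) || stats::sd(dA, na.rm = TRUE) < 1e-12)
    stop("flat area profile: xi is not identifiable")
  if (stats::sd(contraction_profile, na.rm = TRUE) < 1e-15 &&
      max(abs(contraction_profile), na.rm = TRUE) < 1e-15)
    stop("flat contraction profile: w* is not identifiable")
  ok <- is.finite(dA)
  u_obs <- dA[ok] / sqrt(sum(dA[ok]^2))

  model_shape <- function(xi) {
    p <- vff_params(mu = params_ref$mu, lambda = params_ref$mu / xi^2,
                    T_star = params_ref$T_star)
    w <- solve_contraction_rate(T_area, p)
    mw <- -w[ok]                               # dA is proportional to -w
    mw / sqrt(sum(mw^2))
  }
  ss <- function(xi) sum((u_obs - model_shape(xi))^2)
  ss_grid <- vapply(xi_grid, ss, numeric(1))
  i_best <- which.min(ss_grid)
  lo <- xi_grid[max(1, i_best - 1)]
  hi <- xi_grid[min(length(xi_grid), i_best + 1)]
  opt <- stats::optimize(ss, c(lo, hi), tol = 1e-6)
  xi_hat <- opt$minimum

  p_hat <- vff_params(mu = params_ref$mu, lambda = params_ref$mu / xi_hat^2,
                      T_star = params_ref$T_star)
  w_pred <- solve_contraction_rate(T_rate, p_hat)
  ok2 <- is.finite(contraction_profile)
  s <- sum(contraction_profile[ok2] * w_pred[ok2]) / sum(w_pred[ok2]^2)
  if (s <= 0) stop("contraction profile inconsistent with the envelope (non-positive scale)")
  w_star_hat <- s * params_ref$T_star / params_ref$mu
  resid2 <- sum((contraction_profile[ok2] - s * w_pred[ok2])^2)

  # curvature-based covariance proxy from the joint objective
  obj <- function(th) {
    xi <- th[1]; ws <- th[2]
    sc <- ws / w_star_hat * s
    p <- vff_params(mu = params_ref$mu, lambda = params_ref$mu / xi^2,
                    T_star = params_ref$T_star)
    wA <- solve_contraction_rate(T_area, p)
    mw <- -wA[ok]; mw <- mw / sqrt(sum(mw^2))
    wR <- solve_contraction_rate(T_rate, p)
    sum((u_obs - mw)^2) + sum((contraction_profile[ok2] - sc * wR[ok2])^2)
  }
  th0 <- c(xi_hat, w_star_hat)
  hstep <- c(0.01, 0.01 * max(w_star_hat, 1))
  Hm <- matrix(0, 2, 2)
  for (i in 1:2) for (j in 1:2) {
    ei <- ej <- c(0, 0); ei[i] <- hstep[i]; ej[j] <- hstep[j]
    Hm[i, j] <- (obj(th0 + ei + ej) - obj(th0 + ei - ej) -
                 obj(th0 - ei + ej) + obj(th0 - ei - ej)) / (4 * hstep[i] * hstep[j])
  }
  cov_proxy <- tryCatch(solve(Hm / 2) * (opt$objective + resid2) /
                          max(1, sum(ok) + sum(ok2) - 2),
                        error = function(e) matrix(NA_real_, 2, 2))
  dimnames(cov_proxy) <- list(c("xi", "w_star"), c("xi", "w_star"))

  structure(list(xi_hat = xi_hat, w_star_hat = w_star_hat,
                 residual = opt$objective + resid2,
                 covariance_proxy = cov_proxy,
                 envelope = envelope, t_area = t_area, t_rate = t_rate,
                 params_ref = params_ref,
                 area_profile = area_profile,
                 contraction_profile = contraction_profile),
            class = "vff_fit")
}

#' @export
coef.vff_fit <- function(object, ...) {
  c(xi = object$xi_hat, w_star = object$w_star_hat)
}

#' @export
print.vff_fit <- function(x, ...) {
  cat("Reduced-parameter fit of the force-balance model\n")
  cat(sprintf("  xi  = %.4g cells (damping length)\n", x$xi_hat))
  cat(sprintf("  w*  = %.4g nm/s  (characteristic contraction rate)\n", x$w_star_hat))
  cat(sprintf("  residual SS = %.4g\n", x$residual))
  invisible(x)
}

#' @export
summary.vff_fit <- function(object, ...) {
  se <- sqrt(pmax(diag(object$covariance_proxy), 0))
  d <- derive_mu_lambda(object$params_ref$T_star, object$w_star_hat, object$xi_hat)
  out <- list(coef = coef(object), se_proxy = se, residual = object$residual,
              mu = d$mu, lambda = d$lambda, T_star = object$params_ref$T_star)
  class(out) <- "summary.vff_fit"
  out
}

#' @export
print.summary.vff_fit <- function(x, ...) {
  cat("Two-stage fit (xi from area-profile shape, w* from contraction amplitude)\n")
  cat(sprintf("  xi = %.4g cells (se proxy %.3g)\n", x$coef[1], x$se_proxy[1]))
  cat(sprintf("  w* = %.4g nm/s  (se proxy %.3g)\n", x$coef[2], x$se_proxy[2]))
  cat(sprintf("  implied mu = %.4g, lambda = %.4g pN s/nm at T* = %g pN\n",
              x$mu, x$lambda, x$T_star))
  invisible(x)
}

#' Predicted profiles at the fitted parameters
#'
#' @param object a `vff_fit`.
#' @param what `"area"` (apical areas at `t_area`) or `"contraction"`
#'   (contraction rates at `t_rate`).
#' @param ... unused.
#' @return Numeric vector over the grid.
#' @export
predict.vff_fit <- function(object, what = c("area", "contraction"), ...) {
  what <- match.arg(what)
  pr <- object$params_ref
  d <- derive_mu_lambda(pr$T_star, object$w_star_hat, object$xi_hat)
  p <- vff_params(mu = d$mu, lambda = d$lambda, T_star = pr$T_star,
                  b_len = pr$b_len, L_rest = pr$L_rest)
  if (what == "contraction") {
    return(solve_contraction_rate(
      as.numeric(profile_slice(object$envelope, object$t_rate)), p))
  }
  # integrate the ramping envelope up to t_area for the area prediction
  times <- object$envelope$times
  sel <- times <= object$t_area + 1e-9
  sub <- tension_profile(object$envelope$values[, sel, drop = FALSE],
                         object$envelope$grid, times[sel])
  sim <- simulate_furrow(sub, p)
  as.numeric(final_areas(sim))
}

#' @export
residuals.vff_fit <- function(object, what = c("area", "contraction"), ...) {
  what <- match.arg(what)
  obs <- if (what == "area") object$area_profile else object$contraction_profile
  obs - predict(object, what)
}

#' Run a stochastic ensemble of a condition preset
#'
#' Repeats the full pipeline (profile synthesis, time integration, furrow
#' reconstruction, failure classification) over `n_runs` independent
#' seeds and aggregates failure rates, per-cell area statistics and depth
#' statistics. Classification is against the fluctuation-free wild-type
#' furrow depth at the same time point, computed once.
#'
#' @param condition preset name (see [preset_condition()]).
#' @param n_runs number of realisations.
#' @param seed master seed; per-run seeds are drawn from it, so the whole
#'   ensemble is reproducible.
#' @param grid a [cell_grid()].
#' @param dt time step, s.
#' @param t_end end time, s (preset default if `NULL`).
#' @param ... further arguments passed to [preset_condition()] (e.g.
#'   `sigma`, `tau`, `cgap_mode`).
#' @return An object of class `"vff_ensemble"`: `failure_rate`, logical
#'   `failed` per run, `reasons`, `depths`, `reference_depth`, `areas`
#'   (cells x runs matrix of final apical areas), `area_fivenum`
#'   (box-whisker five-number summary per cell), `depth_stats`, `seeds`.
#' @examples
#' \donttest{
#' ens <- ensemble_run("cgap", n_runs = 10, seed = 1)
#' ens$failure_rate
#' }
#' @export
ensemble_run <- function(condition, n_runs = 50, seed, grid = cell_grid(),
                         dt = 1, t_end = NULL, ...) {
  if (n_runs < 1) stop("`n_runs` must be >= 1")
  if (missing(seed)) stop("`seed` is required")
  set.seed(as.integer(seed))
  run_seeds <- sample.int(.Machine$integer.max - 1L, n_runs)

  t_ref <- if (is.null(t_end)) {
    if (identical(condition, "spn27a")) 700 else 500
  } else t_end
  ref <- reference_run(grid = grid, dt = dt, t_end = t_ref)
  nc <- length(grid$indices)
  areas <- matrix(NA_real_, nc, n_runs)
  depths <- rep(NA_real_, n_runs)
  failed <- rep(NA, n_runs)
  reasons <- rep(NA_character_, n_runs)
  errors <- rep(NA_character_, n_runs)
  for (i in seq_len(n_runs)) {
    res <- tryCatch({
      cond <- preset_condition(condition, seed = run_seeds[i], grid = grid,
                               dt = dt, t_end = t_end, ...)
      sim <- simulate_furrow(cond$profile, cond$params)
      sh <- classify_failure(furrow_shape(sim), ref$depth)
      list(areas = as.numeric(final_areas(sim)), depth = sh$depth,
           failed = sh$failed, reason = sh$failure_reason)
    }, error = function(e) e)
    if (inherits(res, "error")) {
      errors[i] <- conditionMessage(res)
      failed[i] <- TRUE
      reasons[i] <- paste0("run error: ", conditionMessage(res))
    } else {
      areas[, i] <- res$areas
      depths[i] <- res$depth
      failed[i] <- res$failed
      reasons[i] <- res$reason
    }
  }
  fn <- t(apply(areas, 1, function(a) {
    a <- a[is.finite(a)]
    if (!length(a)) rep(NA_real_, 5) else stats::fivenum(a)
  }))
  colnames(fn) <- c("whisker_lo", "q1", "median", "q3", "whisker_hi")
  dsts <- c(mean = mean(depths, na.rm = TRUE), sd = stats::sd(depths, na.rm = TRUE),
            stats::quantile(depths, c(.25, .5, .75), na.rm = TRUE))
  structure(list(condition = condition, n_runs = n_runs,
                 failure_rate = mean(failed),
                 failed = failed, reasons = reasons, run_errors = errors,
                 depths = depths, depth_stats = dsts,
                 reference_depth = ref$depth,
                 areas = areas, area_fivenum = fn,
                 rest_area = ref$rest_area,
                 seeds = run_seeds, master_seed = as.integer(seed)),
            class = "vff_ensemble")
}

# fluctuation-free wild-type reference (envelope only), used as the depth
# yardstick for failure classification
reference_run <- function(grid = cell_grid(), dt = 1, t_end = 500) {
  params <- vff_params()
  env <- make_envelope("parabolic", h = 16, T_star = params$T_star,
                       ramp_duration = 300, cap = FALSE, grid = grid,
                       times = seq(0, t_end, by = dt))
  sim <- simulate_furrow(env, params)
  sh <- furrow_shape(sim)
  list(depth = sh$depth, sim = sim, shape = sh,
       rest_area = params$b_len * params$L_rest)
}

#' @export
print.vff_ensemble <- function(x, ...) {
  cat(sprintf("Ensemble: %d \"%s\" runs (master seed %d)\n",
              x$n_runs, x$condition, x$master_seed))
  cat(sprintf("  failure rate %.3g (reference depth %.3g um)\n",
              x$failure_rate, x$reference_depth))
  cat(sprintf("  depth mean %.3g um, sd %.3g um\n",
              x$depth_stats["mean"], x$depth_stats["sd"]))
  invisible(x)
}

#' @export
summary.vff_ensemble <- function(object, ...) {
  tab <- table(object$reasons[object$failed %in% TRUE])
  out <- list(condition = object$condition, n_runs = object$n_runs,
              failure_rate = object$failure_rate, reasons = tab,
              depth_stats = object$depth_stats,
              reference_depth = object$reference_depth)
  class(out) <- "summary.vff_ensemble"
  out
}

#' @export
print.summary.vff_ensemble <- function(x, ...) {
  cat(sprintf("\"%s\" ensemble, n = %d: failure rate %.3g\n",
              x$condition, x$n_runs, x$failure_rate))
  if (length(x$reasons)) {
    cat("  failure reasons:\n")
    for (r in names(x$reasons)) cat(sprintf("    %s: %d\n", r, x$reasons[[r]]))
  }
  cat(sprintf("  depths: mean %.3g um (reference %.3g um)\n",
              x$depth_stats["mean"], x$reference_depth))
  invisible(x)
}

#' @export
plot.vff_ensemble <- function(x, cells = -10:10, ...) {
  sel <- x$areas[match(cells, seq.int(-(nrow(x$areas) - 1) / 2,
                                      (nrow(x$areas) - 1) / 2)), , drop = FALSE]
  graphics::boxplot(t(sel), names = cells, col = "lightsteelblue",
                    xlab = "cell n", ylab = expression(paste("apical area (", mu, m^2, ")")),
                    main = sprintf("\"%s\" ensemble (n = %d)", x$condition, x$n_runs), ...)
  graphics::abline(h = x$rest_area, lty = 2, col = "red")
  invisible(x)
}

#' Power spectrum of the pulsatile myosin component
#'
#' The pulsatile component of a cell's myosin signal is the full signal
#' minus the envelope value. Its one-sided FFT periodogram (mean removed)
#' quantifies where the fluctuation power sits in frequency; for pulsatile
#' (Ornstein-Uhlenbeck) fluctuations it is Lorentzian with corner
#' frequency \eqn{1/(2\pi\tau)}. Time-averaging over a window `t`
#' suppresses frequencies above \eqn{1/t}: the cumulative power and the
#' sliding-window variance of the running time-average expose this
#' low-pass filtering directly.
#'
#' @param series tension (or fluctuation) time series for one cell;
#'   a matrix is treated as one realisation per row and periodograms are
#'   averaged.
#' @param envelope_series envelope values at the same times (vector, or
#'   matrix matching `series`); subtracted before analysis.
#' @param dt sampling interval, s.
#' @param windows window lengths (s) for the running-average variance
#'   (defaults to ~8 log-spaced values up to a quarter of the record).
#' @return An object of class `"vff_spectrum"`: `freq` (Hz), `power`
#'   (one-sided spectral density), `cum_power`, `total_power`,
#'   `series_variance`, `windows` and `timeavg_variance`.
#' @export
pulsatile_spectrum <- function(series, envelope_series = 0, dt = 1,
                               windows = NULL) {
  x <- if (is.matrix(series)) series else matrix(series, nrow = 1)
  e <- if (is.matrix(envelope_series)) envelope_series
       else matrix(envelope_series, nrow = nrow(x), ncol = ncol(x), byrow = TRUE)
  if (!all(dim(e) == dim(x))) stop("envelope dimensions do not match the series")
  n <- ncol(x)
  if (n < 8) stop("series too short for spectral analysis (need >= 8 samples)")
  p <- x - e
  p <- p - rowMeans(p)
  nf <- floor(n / 2)
  pow <- matrix(0, nrow(p), nf)
  for (r in seq_len(nrow(p))) {
    P <- Mod(stats::fft(p[r, ]))^2 * dt / n
    pow[r, ] <- 2 * P[2:(nf + 1)]
  }
  if (n %% 2 == 0) pow[, nf] <- pow[, nf] / 2   # Nyquist bin is not doubled
  power <- colMeans(pow)
  freq <- (1:nf) / (n * dt)
  df <- 1 / (n * dt)
  if (is.null(windows))
    windows <- unique(round(exp(seq(log(2 * dt), log(n * dt / 4), length.out = 8))))
  tav <- vapply(windows, function(wlen) {
    k <- max(2, round(wlen / dt))
    ra <- apply(p, 1, function(z) {
      cs <- cumsum(z)
      (cs[k:n] - c(0, cs)[1:(n - k + 1)]) / k
    })
    stats::var(as.vector(ra))
  }, numeric(1))
  structure(list(freq = freq, power = power,
                 cum_power = cumsum(power) * df,
                 total_power = sum(power) * df,
                 series_variance = mean(apply(p, 1, stats::var)),
                 windows = windows, timeavg_variance = tav,
                 n = n, dt = dt, n_realisations = nrow(p)),
            class = "vff_spectrum")
}

#' @export
print.vff_spectrum <- function(x, ...) {
  cat(sprintf("Pulsatile-component spectrum: %d samples at dt = %g s (%d realisation(s))\n",
              x$n, x$dt, x$n_realisations))
  cat(sprintf("  total power %.4g vs series variance %.4g\n",
              x$total_power, x$series_variance))
  invisible(x)
}

#' @export
plot.vff_spectrum <- function(x, ...) {
  graphics::plot(x$freq, x$power, type = "l", log = "xy", col = "steelblue",
                 xlab = "frequency (1/s)", ylab = "power density",
                 main = "Pulsatile myosin power spectrum", ...)
  invisible(x)
}

#' Fit the Lorentzian corner frequency of a fluctuation spectrum
#'
#' Least-squares fit of \eqn{\log P(f)} to a Lorentzian
#' \eqn{A/(1 + (2\pi f\tau)^2)}, profiling out the amplitude; returns the
#' implied correlation time and corner frequency \eqn{f_c = 1/(2\pi\tau)}.
#' The periodogram is first averaged into log-spaced frequency bins so that
#' the dense high-frequency tail does not dominate the fit.
#'
#' @param spectrum a [pulsatile_spectrum()] result.
#' @param tau_range search range for \eqn{\tau}, s.
#' @param n_bins number of logarithmic frequency bins.
#' @return list with `tau` (s) and `f_corner` (Hz).
#' @export
fit_spectrum_corner <- function(spectrum, tau_range = c(1, 1000), n_bins = 25) {
  f <- spectrum$freq
  p <- spectrum$power
  edges <- exp(seq(log(min(f)), log(max(f)), length.out = n_bins + 1))
  bin <- cut(f, edges, include.lowest = TRUE)
  fb <- tapply(f, bin, mean)
  pb <- tapply(p, bin, mean)
  keep <- is.finite(fb) & is.finite(pb) & pb > 0
  fb <- fb[keep]; pb <- pb[keep]
  lp <- log(pb)
  obj <- function(tau) {
    ll <- -log1p((2 * pi * fb * tau)^2)
    a <- mean(lp - ll)
    sum((lp - a - ll)^2)
  }
  tau <- stats::optimize(obj, tau_range)$minimum
  list(tau = tau, f_corner = 1 / (2 * pi * tau))
}

#' Variance of the running time-average of an OU process
#'
#' Closed form for a stationary Ornstein-Uhlenbeck process with sd
#' `sigma` and correlation time `tau`:
#' \deqn{Var\left[\frac{1}{t}\int_0^t \epsilon\,ds\right] =
#'  \frac{2\sigma^2\tau}{t}\left[1 - \frac{\tau}{t}(1 - e^{-t/\tau})\right]}
#' which tends to \eqn{2\sigma^2\tau/t} for \eqn{t \gg \tau}: pulsatile
#' fluctuations are averaged away, while frozen fluctuations
#' (\eqn{\tau = \infty}) keep variance \eqn{\sigma^2} at all window
#' lengths. This is the quantitative content of the low-pass filter
#' mechanism.
#'
#' @param sigma stationary sd.
#' @param tau correlation time, s (may be `Inf`).
#' @param t averaging window length(s), s.
#' @return Variance of the window mean (vectorised over `t`).
#' @export
ou_timeavg_var <- function(sigma, tau, t) {
  if (any(t <= 0)) stop("`t` must be positive")
  if (is.infinite(tau)) return(rep(sigma^2, length(t)))
  r <- t / tau
  sigma^2 * (2 / r) * (1 - (1 - exp(-r)) / r)
}
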