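test_that("noise-free profiles recover the generating reduced parameters", {
  env <- wt_envelope()
  sim <- simulate_furrow(env, P)
  fit <- fit_xi_wstar(final_areas(sim, 400), sim$w[, sim$times == 300], env)
  expect_equal(unname(coef(fit)["xi"]), P$xi, tolerance = 0.02)
  expect_equal(unname(coef(fit)["w_star"]), P$w_star, tolerance = 0.02)
  # linearity: doubling the tension scale doubles w* but leaves xi alone
  fit2 <- fit_xi_wstar(final_areas(sim, 400), 2 * sim$w[, sim$times == 300], env)
  expect_equal(unname(coef(fit2)["w_star"]), 2 * P$w_star, tolerance = 0.02)
  expect_equal(unname(coef(fit2)["xi"]), unname(coef(fit)["xi"]))
  # classic accessors
  expect_s3_class(fit, "vff_fit")
  expect_named(coef(fit), c("xi", "w_star"))
  pr <- predict(fit, "contraction")
  expect_equal(pr, as.numeric(sim$w[, sim$times == 300]), tolerance = 0.02)
  expect_lt(max(abs(residuals(fit, "contraction"))), 0.02 * max(abs(pr)))
})

test_that("fits from a mis-specified starting xi still converge to the truth", {
  p_gen <- vff_params(mu = 36, lambda = 36 / 1.8^2)    # xi = 1.8
  env <- wt_envelope()
  sim <- simulate_furrow(env, p_gen)
  fit <- fit_xi_wstar(final_areas(sim, 400), sim$w[, sim$times == 300], env)
  expect_equal(unname(coef(fit)["xi"]), 1.8, tolerance = 0.02)
})

test_that("noisy observations recover xi within the reported uncertainty band", {
  env <- wt_envelope()
  sim <- simulate_furrow(env, P)
  a0 <- final_areas(sim, 400)
  w0 <- sim$w[, sim$times == 300]
  set.seed(77)
  xis <- vapply(1:20, function(i) {
    a <- a0 * (1 + rnorm(81, 0, 0.10))
    w <- w0 * (1 + rnorm(81, 0, 0.10))
    coef(fit_xi_wstar(a, w, env))["xi"]
  }, numeric(1))
  expect_lt(abs(median(xis) - 2.5), 1.2)
})

test_that("degenerate profiles are rejected as unidentifiable", {
  env <- wt_envelope(t_end = 100, dt = 50)
  expect_error(fit_xi_wstar(rep(A_REST, 81), rep(0, 81), env), "identifiable")
})

test_that("fluctuation-free ensembles have zero across-run variance", {
  e <- ensemble_run("cgap", n_runs = 3, seed = 5, sigma = 0)
  expect_equal(e$areas[, 1], e$areas[, 2])
  expect_equal(e$areas[, 1], e$areas[, 3])
  expect_equal(sd(e$depths), 0)
  expect_equal(e$failure_rate, 0)
})

test_that("ensembles are reproducible and size-one ensembles match single runs", {
  e1 <- ensemble_run("cgap", n_runs = 3, seed = 11)
  e2 <- ensemble_run("cgap", n_runs = 3, seed = 11)
  expect_identical(e1$areas, e2$areas)
  expect_identical(e1$failed, e2$failed)
  e3 <- ensemble_run("twist", n_runs = 1, seed = 11)
  cond <- preset_condition("twist", seed = e3$seeds[1])
  sim <- simulate_furrow(cond$profile, cond$params)
  expect_equal(e3$areas[, 1], as.numeric(final_areas(sim)))
  expect_true(all(diff(t(e3$area_fivenum)) >= 0))   # quantiles ordered
})

test_that("failure rate grows with fluctuation magnitude and persistence", {
  rate <- function(sigma, mode) {
    ensemble_run("cgap", n_runs = 30, seed = 21, sigma = sigma,
                 cgap_mode = mode)$failure_rate
  }
  # persistence at fixed sd: pulsatile (wild-type) vs frozen (C-GAP)
  r_puls <- ensemble_run("wildtype", n_runs = 30, seed = 21)$failure_rate
  r_frozen <- rate(0.45, "frozen")
  expect_lte(r_puls, r_frozen)
  # magnitude at fixed (frozen) persistence
  expect_lte(rate(0, "frozen"), rate(0.2, "frozen"))
  expect_lte(rate(0.2, "frozen"), r_frozen)
})

test_that("the pulsatile spectrum is Lorentzian with the OU corner frequency", {
  eps <- 0.45 * do.call(rbind, lapply(1:5, function(s)
    sample_fluctuations(cell_grid(5), 0:4095, sigma = 1, seed = 300 + s)))
  sp <- pulsatile_spectrum(eps, 0, dt = 1)
  expect_equal(sp$total_power, sp$series_variance, tolerance = 0.05)  # Parseval
  fc <- fit_spectrum_corner(sp)
  expect_equal(fc$f_corner, 1 / (2 * pi * 75), tolerance = 0.2)
  expect_equal(fc$tau, 75, tolerance = 0.2)
  # running-average variance matches the OU closed form at t = 100 s
  i100 <- which.min(abs(sp$windows - 100))
  sp100 <- pulsatile_spectrum(eps, 0, dt = 1, windows = 100)
  expect_equal(sp100$timeavg_variance, ou_timeavg_var(0.45, 75, 100),
               tolerance = 0.1)
})

test_that("an envelope-only signal carries no pulsatile power", {
  env <- wt_envelope(t_end = 400, dt = 1)
  x <- env$values[NIDX == 0, ]
  sp <- pulsatile_spectrum(x, x, dt = 1)
  expect_equal(sp$total_power, 0)
  expect_true(all(sp$power == 0))
  expect_error(pulsatile_spectrum(x[1:4], x[1:4]), "short")
})
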