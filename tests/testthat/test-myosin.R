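test_that("envelopes have the documented shapes, supports and ramps", {
  env <- make_envelope("parabolic", h = 8, ramp_duration = 500, times = 0:500)
  v <- env$values
  expect_equal(v[NIDX == 0, 501], 1500)            # peak reaches T* at ramp end
  expect_equal(v[NIDX == 0, 251], 750)             # linear ramp
  expect_true(all(v[abs(NIDX) >= 4, ] == 0))       # support edge |n| = h/2
  # capped vs uncapped ramp
  capped <- make_envelope("parabolic", h = 8, ramp_duration = 300, times = 0:500)
  expect_equal(capped$values[NIDX == 0, 501], 1500)
  free <- make_envelope("parabolic", h = 8, ramp_duration = 300, cap = FALSE,
                        times = 0:500)
  expect_equal(free$values[NIDX == 0, 501], 1500 * 500 / 300)

  th <- make_envelope("top_hat", h = 13, shoulder = 2, times = c(0, 700),
                      ramp_duration = 700)
  s <- th$values[, 2]
  expect_true(all(s[abs(NIDX) <= 6] == 1500))      # 13-cell plateau
  expect_equal(s[NIDX == 7], 1500 * 0.75)          # linear 2-cell shoulder
  expect_equal(s[NIDX == 8], 1500 * 0.25)
  expect_true(all(s[abs(NIDX) >= 9] == 0))

  tr <- make_envelope("triangular", h = 10, times = c(0, 500))
  expect_true(all(tr$values[abs(NIDX) >= 10, ] == 0))  # support 2h
  ga <- make_envelope("gaussian", h = 10, times = c(0, 500))
  expect_equal(ga$values[NIDX == 5, 2] / ga$values[NIDX == 0, 2], 0.5,
               tolerance = 1e-6)                   # h is the FWHM
  expect_error(make_envelope("parabolic", h = 200, times = 0:10), "boundary")
  expect_error(make_envelope("parabolic", h = -8, times = 0:10), "h")
})

test_that("OU fluctuations have the stationary sd and correlation time", {
  eps <- sample_fluctuations(G, 0:4000, seed = 101)
  expect_equal(sd(eps), 0.45, tolerance = 0.02)
  nt <- ncol(eps)
  lag <- 75
  # non-centred autocorrelation (the process mean is known to be zero;
  # sample-mean centring would bias the estimate downward by ~2 tau/T)
  ac <- sum(eps[, 1:(nt - lag)] * eps[, (lag + 1):nt]) / sum(eps[, 1:(nt - lag)]^2)
  expect_lt(abs(ac - exp(-1)), 0.05)
  # sigma = 0 degenerates to the bare envelope
  z <- sample_fluctuations(G, 0:10, sigma = 0, seed = 1)
  expect_true(all(z == 0))
})

test_that("frozen fluctuations are one stationary draw per cell, held in time", {
  eps <- sample_fluctuations(G, 0:500, mode = "frozen", seed = 7)
  expect_equal(eps[, 1], eps[, 501])
  expect_equal(apply(eps, 1, sd), rep(0, 81))
  draws <- unlist(lapply(1:10, function(s)
    sample_fluctuations(G, 0, mode = "frozen", seed = s)))
  expect_equal(sd(draws), 0.45, tolerance = 0.05)
  # frozen is the tau -> infinity limit of the pulsatile process
  slowest <- sample_fluctuations(G, 0:500, tau = 1e12, seed = 7)
  expect_lt(max(abs(slowest - slowest[, 1])), 1e-4)
  # slow mode sits in between: correlation decays 10x slower
  sl <- sample_fluctuations(G, 0:4000, mode = "slow", seed = 8)
  nt <- ncol(sl)
  ac <- sum(sl[, 1:(nt - 75)] * sl[, 76:nt]) / sum(sl[, 1:(nt - 75)]^2)
  expect_lt(abs(ac - exp(-0.1)), 0.05)
})

test_that("fluctuations of distinct cells are statistically independent", {
  eps <- sample_fluctuations(G, 0:3000, seed = 42)
  a <- exp(-1 / 75)
  innov <- eps[, -1] - a * eps[, -ncol(eps)]   # iid innovations per cell
  pairs <- cbind(1:40, 42:81)
  cors <- vapply(seq_len(nrow(pairs)), function(k)
    cor(innov[pairs[k, 1], ], innov[pairs[k, 2], ]), numeric(1))
  expect_true(all(abs(cors) < 3 / sqrt(ncol(innov))))
  expect_lt(abs(mean(cors)), 3 / sqrt(ncol(innov) * nrow(pairs)))
})

test_that("identical seeds reproduce profiles bit for bit", {
  e1 <- sample_fluctuations(G, 0:100, seed = 9)
  e2 <- sample_fluctuations(G, 0:100, seed = 9)
  expect_identical(e1, e2)
  t1 <- make_twist_profile(G, 0:200, seed = 9)
  t2 <- make_twist_profile(G, 0:200, seed = 9)
  expect_identical(t1$values, t2$values)
  expect_false(identical(t1$values, make_twist_profile(G, 0:200, seed = 10)$values))
  expect_error(sample_fluctuations(G, 0:10), "seed")
  expect_error(make_twist_profile(G, 0:10), "seed")
})

test_that("composition multiplies the envelope and clamps at zero tension", {
  env <- wt_envelope(t_end = 100, dt = 10)
  z <- matrix(0, 81, 11)
  expect_equal(compose_profile(env, z)$values, env$values)
  eps <- z; eps[NIDX == 1, ] <- -0.45
  comp <- compose_profile(env, eps)
  expect_equal(comp$values[NIDX == 1, ], 0.55 * env$values[NIDX == 1, ])
  expect_equal(comp$values[NIDX != 1, ], env$values[NIDX != 1, ])
  expect_true(all(compose_profile(env, z - 1)$values == 0))    # full deficit
  expect_true(all(compose_profile(env, z - 2)$values == 0))    # clamp floor
  expect_error(compose_profile(env, matrix(0, 3, 3)), "dimensions")
})

test_that("twist pulse trains have the stated pulse and interval statistics", {
  long <- seq(0, 60000, 1)
  tp <- make_twist_profile(G, long, pulse_shape = "rectangular", seed = 31)
  x <- tp$values[NIDX == 0, ]
  expect_true(all(tp$values[!(NIDX %in% -6:7), ] == 0))   # inactive cells silent
  r <- rle(x > 0)
  on <- r$lengths[r$values]
  expect_true(all(abs(on[-length(on)] - 35) <= 1))        # 35 s pulses
  gaps <- r$lengths[!r$values]
  gaps <- gaps[-c(1, length(gaps))]
  expect_equal(mean(gaps), 180, tolerance = 0.1)          # U[30, 330] gaps
  expect_true(all(gaps >= 29 & gaps <= 331))
  amps <- tapply(x[x > 0], cumsum(c(1, diff(which(x > 0)) > 1)), max)
  expect_equal(mean(amps), 1500, tolerance = 0.1)         # U[0, 2 T*] amplitudes
  expect_lte(max(amps), 3000)
  # raised-cosine pulses are smooth and peak at the drawn amplitude
  rc <- make_twist_profile(G, 0:500, seed = 31)
  expect_true(all(rc$values >= 0))
})

test_that("condition presets assemble the documented recipes", {
  wt <- preset_condition("wildtype", seed = 5)
  expect_equal(max(wt$envelope$values[NIDX == 0, ]), 1500 * 500 / 300)
  rel <- wt$profile$values[NIDX == 0, ] / wt$envelope$values[NIDX == 0, ]
  expect_gt(sd(rel[-1]), 0.1)                      # pulsatile: ratio wanders
  cg <- preset_condition("cgap", seed = 5)
  relc <- cg$profile$values[NIDX == 2, -1] / cg$envelope$values[NIDX == 2, -1]
  expect_lt(diff(range(relc)), 1e-12)              # frozen: fixed shape ramp-up
  sp <- preset_condition("spn27a")
  expect_equal(sp$t_end, 700)
  expect_equal(sp$params$beta, 0.5)
  expect_equal(sp$params$beta_cells, -6:6)
  plateau <- sp$profile$values[abs(NIDX) <= 6, 701]
  expect_true(all(plateau == plateau[1]))          # curvature-free plateau
  tw <- preset_condition("twist", seed = 5)
  expect_true(all(tw$envelope$values == 0))        # zero baseline
  sd1 <- preset_condition("single_deficit")
  expect_equal(sd1$profile$values[NIDX == 1, ] / sd1$envelope$values[NIDX == 1, ],
               c(NaN, rep(0.55, 500)))
  expect_error(preset_condition("wildtype"), "seed")
  expect_error(preset_condition("nonsense", seed = 1))
})

test_that("time-averaging suppresses pulsatile but not frozen fluctuations", {
  # Monte-Carlo check of the OU running-average variance (low-pass law)
  eps <- do.call(rbind, lapply(1:10, function(s)
    sample_fluctuations(G, 0:1999, seed = 100 + s)))
  wins <- c(150, 300, 600)
  v <- vapply(wins, function(t) var(rowMeans(eps[, 1:t])), numeric(1))
  expect_equal(v, ou_timeavg_var(0.45, 75, wins), tolerance = 0.1)
  expect_true(all(diff(v) < 0))                    # strictly decreasing
  # t >> tau asymptote 2 sigma^2 tau / t
  expect_equal(ou_timeavg_var(0.45, 75, 6000), 2 * 0.45^2 * 75 / 6000,
               tolerance = 0.02)
  # frozen fluctuations are untouched by averaging
  expect_equal(ou_timeavg_var(0.45, Inf, wins), rep(0.45^2, 3))
  fr <- do.call(rbind, lapply(1:10, function(s)
    sample_fluctuations(G, 0:1999, mode = "frozen", seed = 200 + s)))
  vf <- vapply(wins, function(t) var(rowMeans(fr[, 1:t])), numeric(1))
  expect_equal(vf, rep(vf[1], 3))
})
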