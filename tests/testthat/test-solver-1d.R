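test_that("flat tension produces no contraction anywhere", {
  expect_equal(solve_contraction_rate(rep(0, 81), P), rep(0, 81))
  expect_equal(solve_contraction_rate(rep(800, 81), P), rep(0, 81))
})

test_that("closed forms match their frozen values and the Green's quadrature", {
  # top-hat and triangular, spot values at the default parameters
  expect_equal(closed_form_w("top_hat", 0, 20, P), 0.763152, tolerance = 1e-6)
  expect_equal(closed_form_w("top_hat", 9, 20, P), 13.975427, tolerance = 1e-6)
  expect_equal(closed_form_w("triangular", 0, 20, P), 5.206586, tolerance = 1e-6)
  expect_equal(closed_form_w("triangular", 0, 20, P),
               (P$w_star * P$xi / 20) * (1 - exp(-20 / P$xi)))
  # parabolic: frozen regression values fixed by the independent
  # Green's-function quadrature oracle
  expect_equal(closed_form_w("parabolic", c(0, 2, 6), 8, P),
               c(15.464487, 9.698535, -5.163054), tolerance = 1e-6)
  expect_equal(closed_form_w("parabolic", c(0, 1.3, 2, 3.7, 6, 11), 8, P),
               green_parabolic_w(c(0, 1.3, 2, 3.7, 6, 11), 8, P),
               tolerance = 1e-9)
  # top-hat with edges infinitely far away: no contraction at the centre
  expect_lt(closed_form_w("top_hat", 0, 200, P), 1e-10)
  expect_error(closed_form_w("top_hat", 0, -1, P), "h")
})

test_that("numerical solver agrees with the closed forms under refinement", {
  shapes <- list(
    top_hat = list(f = function(n) ifelse(abs(n) < 10, P$T_star, 0),
                   h = 20, sing = c(-10, 10)),
    triangular = list(f = function(n) P$T_star * pmax(1 - abs(n) / 10, 0),
                      h = 10, sing = c(-10, 0, 10)),
    parabolic = list(f = function(n) P$T_star * pmax(1 - (2 * n / 8)^2, 0),
                     h = 8, sing = c(-4, 4)))
  for (nm in names(shapes)) {
    s <- shapes[[nm]]
    err <- vapply(c(0.2, 0.05), function(sp) {
      nf <- seq(-40, 40, by = sp)
      wf <- solve_contraction_rate(s$f(nf), P, method = "continuum", spacing = sp)
      wa <- closed_form_w(nm, nf, s$h, P)
      away <- apply(abs(outer(nf, s$sing, "-")), 1, min) > 1
      max(abs(wf - wa)[away]) / max(abs(wa))
    }, numeric(1))
    expect_lt(err[2], 0.01)       # < 1% at fine discretisation
    expect_lt(err[2], err[1])     # and convergent under refinement
  }
})

test_that("discrete cell form and continuum form coincide for uniform drag", {
  Tp <- P$T_star * pmax(1 - (2 * NIDX / 16)^2, 0)
  wd <- solve_contraction_rate(Tp, P, method = "discrete")
  wc <- solve_contraction_rate(Tp, P, method = "continuum")
  expect_lt(max(abs(wd - wc)) / max(abs(wd)), 1e-4)
  # the discrete solution satisfies mu D^2 w - lambda w = D^2 T row by row
  i <- 3:79
  resid <- P$mu * (wd[i - 1] - 2 * wd[i] + wd[i + 1]) - P$lambda * wd[i] -
    (Tp[i - 1] - 2 * Tp[i] + Tp[i + 1])
  expect_lt(max(abs(resid)), 1e-9)
})

test_that("zero-sum, linearity and symmetry hold for compact tension", {
  set.seed(4)
  for (rep in 1:5) {
    Tv <- numeric(81)
    Tv[21:61] <- runif(41, 0, 2000)
    Tv[21] <- Tv[61] <- 0
    w <- solve_contraction_rate(Tv, P)
    expect_lt(abs(sum(w)), 1e-6 * max(abs(w)))              # zero-sum
    expect_equal(solve_contraction_rate(2 * Tv, P), 2 * w)  # linearity
  }
  Ts <- P$T_star * pmax(1 - (2 * NIDX / 16)^2, 0)
  ws <- solve_contraction_rate(Ts, P, return_velocity = TRUE)
  v <- attr(ws, "velocity")
  expect_equal(as.numeric(ws), rev(as.numeric(ws)))          # symmetric w
  expect_equal(v, -rev(v))                                   # antisymmetric v
})

test_that("a linear tension ramp only contracts near its endpoints", {
  Tl <- c(rep(0, 20), seq(0, 1000, length.out = 41), rep(1000, 20))
  w <- solve_contraction_rate(Tl, P)
  far <- abs(NIDX + 20) > 5 * P$xi & abs(NIDX - 20) > 5 * P$xi
  expect_lt(max(abs(w[far])), 0.05 * max(abs(w)))
})

test_that("drag forces dominate for envelopes much wider than xi", {
  g <- cell_grid(70)
  Tp <- P$T_star * pmax(1 - (2 * g$indices / 100)^2, 0)
  w <- solve_contraction_rate(Tp, P)
  i0 <- which(g$indices == 0)
  d2T <- Tp[i0 - 1] - 2 * Tp[i0] + Tp[i0 + 1]
  expect_equal(P$lambda * w[i0], -d2T, tolerance = 0.1)
})

test_that("spatially varying drag uses the cell-level form", {
  Tp <- P$T_star * pmax(1 - (2 * NIDX / 16)^2, 0)
  df <- ifelse(abs(NIDX) <= 6, 0.5, 1)
  w_red <- solve_contraction_rate(Tp, P, drag_factor = df)
  w_uni <- solve_contraction_rate(Tp, P)
  expect_false(isTRUE(all.equal(w_red, w_uni)))
  # reduced drag in the centre increases central mobility/contraction
  expect_gt(w_red[NIDX == 0], w_uni[NIDX == 0])
  expect_error(solve_contraction_rate(Tp, P, drag_factor = df, method = "continuum"),
               "uniform")
  expect_error(solve_contraction_rate(Tp, P, drag_factor = rep(2, 81)), "0, 1")
})

test_that("solver rejects tension variation at the domain boundary", {
  Tbad <- P$T_star * pmax(1 - (2 * NIDX / 100)^2, 0)  # support wider than grid
  expect_error(solve_contraction_rate(Tbad, P), "boundary")
})

test_that("velocity integration is antisymmetric and anchored at the midline", {
  expect_equal(solve_velocity(rep(0, 81), G), rep(0, 81))
  Tp <- P$T_star * pmax(1 - (2 * NIDX / 16)^2, 0)
  w <- solve_contraction_rate(Tp, P)
  v <- solve_velocity(w, G)
  expect_equal(v[NIDX == 0], 0)
  expect_equal(v, -rev(v))
  expect_lt(abs(v[1]), 1e-6 * max(abs(v)))   # zero-sum => quiescent boundary
  expect_lt(abs(v[81]), 1e-6 * max(abs(v)))
})
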