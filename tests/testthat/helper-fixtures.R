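# shared fixtures: default parameters, grids, and a fast wild-type envelope
P <- vff_params()
G <- cell_grid()
NIDX <- G$indices
A_REST <- P$b_len * P$L_rest   # 39.9 um^2

# wild-type envelope: parabola of half-width 8 (support 16 cells), linear
# ramp reaching T* at 300 s and continuing
wt_envelope <- function(t_end = 500, dt = 1, grid = G) {
  make_envelope("parabolic", h = 16, T_star = P$T_star, ramp_duration = 300,
                cap = FALSE, grid = grid, times = seq(0, t_end, by = dt))
}

# independent Green's-function quadrature oracle for the parabolic profile:
# kernel applied to the distributional second derivative (constant interior
# curvature plus edge delta functions)
green_parabolic_w <- function(n, h, params) {
  G <- function(x) -(params$xi / 2) * exp(-abs(x) / params$xi)
  vapply(n, function(nn) {
    sm <- stats::integrate(function(m) G(nn - m) * (-8 * params$T_star / h^2),
                           -h / 2, h / 2, rel.tol = 1e-12)$value
    (sm + (4 * params$T_star / h) * (G(nn - h / 2) + G(nn + h / 2))) / params$mu
  }, numeric(1))
}
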