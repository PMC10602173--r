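test_that("cell shapes conserve volume and follow the radii-ratio rule", {
  q <- cell_shape_from_area(A_REST)              # rest cell is rectangular
  expect_equal(q$basal_width, 7)
  expect_equal(q$apical_width, 7)
  expect_equal(q$wedge_angle, 0)
  expect_equal(q$R_apical, Inf)
  q2 <- cell_shape_from_area(19.95)
  expect_equal(q2$basal_width, 10.5)
  expect_equal(q2$wedge_angle, 2 * atan(7 / 78))
  set.seed(2)
  for (a in runif(20, 1, 79)) {
    q <- cell_shape_from_area(a)
    expect_equal(q$volume, 1556.1, tolerance = 1e-3)   # within 0.1%
    # apical/basal = R/(R + H) wherever the widths differ
    if (is.finite(q$R_apical))
      expect_equal(q$apical_width / q$basal_width,
                   q$R_apical / (q$R_apical + q$height))
  }
  expect_error(cell_shape_from_area(80), "conserve volume")
  expect_error(cell_shape_from_area(-1), ">= 0")
})

test_that("a rest-area profile assembles into a flat sheet on the lattice", {
  sh <- assemble_tissue_cross_section(rep(A_REST, 81))
  expect_equal(sh$depth, 0, tolerance = 1e-12)
  expect_equal(max(abs(sh$y)), 0, tolerance = 1e-12)
  expect_equal(diff(sh$x), rep(P$L_rest, 81))    # vertices on the undeformed lattice
  expect_false(sh$self_intersecting)
})

test_that("symmetric area profiles give mirror-symmetric furrows", {
  sim <- simulate_furrow(wt_envelope(), P)
  sh <- furrow_shape(sim)
  expect_equal(sh$y, rev(sh$y), tolerance = 1e-9)
  expect_equal(sh$x, -rev(sh$x), tolerance = 1e-9)
  # wild-type-like profile: a single smooth minimum at the midline
  expect_gt(sh$depth, 5)
  deep <- sh$y < -0.2 * sh$depth
  expect_true(all(diff(which(deep)) == 1))       # one contiguous valley
  expect_true(which.min(sh$y) %in% c(41L, 42L))  # valley bottom at the midline
})

test_that("top-hat-driven furrows are wide and flat with high edge curvature", {
  sp <- preset_condition("spn27a")
  sim <- simulate_furrow(sp$profile, sp$params)
  sh <- furrow_shape(sim)
  phi <- sh$wedge_angle
  edge <- abs(NIDX) %in% 5:8                     # active-zone edge cells
  centre <- abs(NIDX) <= 3
  expect_gt(max(phi[edge]), 2 * max(abs(phi[centre])))  # curvature at the edges
  # flat depression: central cells barely contracted relative to the edges
  A <- final_areas(sim)
  expect_gt(A[NIDX == 0], 0.8 * A_REST)
})

test_that("furrow depth is monotone in the strength of central contraction", {
  bump <- exp(-(NIDX / 5)^2)
  depths <- vapply(seq(0, 0.5, length.out = 6), function(c) {
    assemble_tissue_cross_section(A_REST * (1 - c * bump))$depth
  }, numeric(1))
  expect_true(all(diff(depths) > 0))
})

test_that("failure classification distinguishes the documented modes", {
  ref <- assemble_tissue_cross_section(
    final_areas(simulate_furrow(wt_envelope(), P)))
  ok <- classify_failure(ref, ref$depth)
  expect_false(ok$failed)                        # reference equals itself
  flat <- classify_failure(assemble_tissue_cross_section(rep(A_REST, 81)), ref$depth)
  expect_true(flat$failed)                       # no furrow at all
  expect_match(flat$failure_reason, "depth")
  # two separated contraction foci (a two-peak envelope) give a fragmented,
  # twin-valley surface
  bump <- function(n) pmax(1 - (2 * n / 12)^2, 0)
  w2 <- solve_contraction_rate(P$T_star * (bump(NIDX - 13) + bump(NIDX + 13)), P)
  a2 <- A_REST - P$b_len * as.numeric(w2) * 0.3
  twin <- classify_failure(assemble_tissue_cross_section(a2), ref$depth)
  expect_true(twin$failed)
  expect_match(twin$failure_reason, "minima")
  # a cell that cannot conserve volume propagates as a geometry error
  abad <- rep(A_REST, 81); abad[30] <- 100
  gsh <- assemble_tissue_cross_section(abad)
  expect_false(is.null(gsh$geometry_error))
  gcl <- classify_failure(gsh, ref$depth)
  expect_true(gcl$failed)
  expect_match(gcl$failure_reason, "geometry")
  # a collapsed central block folds the surface onto itself
  afold <- rep(A_REST, 81); afold[abs(NIDX) <= 5] <- 0
  fsh <- assemble_tissue_cross_section(afold)
  expect_true(fsh$self_intersecting)
  expect_true(classify_failure(fsh, ref$depth)$failed)
  expect_error(classify_failure(ref, -1), "reference")
})
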