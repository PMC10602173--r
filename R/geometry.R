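geometry_error <- function(msg) {
  stop(errorCondition(msg, class = c("vff_geometry_error", "error", "condition")))
}

#' Cross-sectional cell shape from an apical area
#'
#' Each cell is modeled as a trapezoidal prism of anterior-posterior depth
#' `b_len`, height `H` and conserved volume `V`. Volume conservation fixes
#' the basal width given the apical width:
#' \eqn{L_{basal} = 2V/(b H) - L_{apical}}, and the wedge angle subtended
#' between the two lateral edges is
#' \eqn{\phi = 2\,\mathrm{atan}[(L_{basal} - L_{apical})/(2H)]}
#' (negative for expanded cells, which bulge outward). For thin wedges this
#' is equivalent to requiring the apical and basal surfaces to lie on
#' concentric arcs with areas in the ratio of their radii of curvature,
#' \eqn{L_{apical}/L_{basal} = R_{apical}/(R_{apical} + H)}.
#'
#' @param apical_area apical area, \eqn{\mu}m\eqn{^2}; must satisfy
#'   `0 <= apical_area < 2V/H` so the basal width stays positive.
#' @param b_len,H,V geometry constants (defaults as in [vff_params()]).
#' @return An object of class `"cell_quad"`: `apical_width`, `basal_width`,
#'   `height`, `volume`, `wedge_angle` (rad), `R_apical` (\eqn{\mu}m,
#'   `Inf` for a rectangular cell) and `vertices` (4 x 2, local coordinates
#'   with the apical edge on y = 0 and the basal edge on y = -H).
#' @examples
#' q <- cell_shape_from_area(40)     # rest cell: rectangular
#' q$wedge_angle                     # 0
#' cell_shape_from_area(19.95)$basal_width  # 10.5 um
#' @export
cell_shape_from_area <- function(apical_area, b_len = 5.7, H = 39, V = 1556.1) {
  if (!is.finite(apical_area) || apical_area < 0)
    geometry_error("apical area must be finite and >= 0")
  a <- apical_area / b_len
  basal <- 2 * V / (b_len * H) - a
  if (basal <= 0)
    geometry_error(sprintf(
      "apical area %.3g um^2 too large: cell cannot conserve volume (basal width <= 0)",
      apical_area))
  phi <- 2 * atan((basal - a) / (2 * H))
  structure(list(
    apical_width = a, basal_width = basal, height = H,
    volume = (a + basal) / 2 * H * b_len,
    wedge_angle = phi,
    R_apical = if (abs(basal - a) < 1e-12) Inf else H * a / (basal - a),
    vertices = matrix(c(-a / 2, 0, a / 2, 0, basal / 2, -H, -basal / 2, -H),
                      ncol = 2, byrow = TRUE,
                      dimnames = list(c("apical_L", "apical_R", "basal_R", "basal_L"),
                                      c("x", "y")))),
    class = "cell_quad")
}

#' Reconstruct the cross-sectional tissue shape from an area profile
#'
#' Converts a per-cell apical area profile into the furrowed tissue
#' cross-section: each cell becomes a trapezoid ([cell_shape_from_area()]),
#' and cells are chained outward from the midline sharing lateral edges,
#' each apical facet rotated by the cumulative sum of half wedge angles.
#' Contracted cells (positive wedge) curve the sheet into a valley;
#' expanded cells (negative wedge) bend it back, so for a wild-type-like
#' profile the expansion wings smoothly rejoin the flat unfurrowed tissue.
#' The undeformed apical line through the outermost (rest) cells anchors
#' the depth baseline; the furrow depth is the drop of the lowest apical
#' point below that baseline.
#'
#' Cells whose area cannot conserve volume yield a geometry error, recorded
#' on the returned shape (not thrown); a self-intersecting apical polyline
#' (backtracking x) is flagged, not repaired.
#'
#' @param area_profile apical areas (\eqn{\mu}m\eqn{^2}) on the full grid,
#'   ordered from `n = -N` to `N`; dead cells enter with area 0.
#' @param grid optional [cell_grid()]; inferred from the profile length if
#'   omitted.
#' @param b_len,H,V,L_rest geometry constants.
#' @return An object of class `"furrow_shape"`: apical polyline `x`, `y`
#'   (\eqn{\mu}m, baseline at y = 0), `depth` (\eqn{\mu}m), per-cell
#'   `wedge_angle`, flags `geometry_error` and `self_intersecting`,
#'   `failed`/`failure_reason` (set by [classify_failure()], `NA` until
#'   then) and the input `areas`.
#' @export
assemble_tissue_cross_section <- function(area_profile, grid = NULL,
                                          b_len = 5.7, H = 39, V = 1556.1,
                                          L_rest = 7) {
  m <- length(area_profile)
  if (m %% 2 != 1) stop("`area_profile` must cover a symmetric grid -N..N (odd length)")
  if (is.null(grid)) grid <- cell_grid((m - 1) / 2)
  if (length(grid$indices) != m) stop("`area_profile` length does not match `grid`")

  quads <- vector("list", m)
  geom_err <- NULL
  for (i in seq_len(m)) {
    q <- tryCatch(cell_shape_from_area(area_profile[i], b_len, H, V),
                  vff_geometry_error = function(e) e)
    if (inherits(q, "error")) {
      geom_err <- sprintf("cell n = %d: %s", grid$indices[i], conditionMessage(q))
      break
    }
    quads[[i]] <- q
  }
  if (!is.null(geom_err)) {
    out <- structure(list(x = NULL, y = NULL, depth = NA_real_,
                          wedge_angle = NULL, geometry_error = geom_err,
                          self_intersecting = NA, failed = NA,
                          failure_reason = NA_character_,
                          areas = area_profile, grid = grid),
                     class = "furrow_shape")
    return(out)
  }
  phi <- vapply(quads, `[[`, numeric(1), "wedge_angle")
  aw <- vapply(quads, `[[`, numeric(1), "apical_width")
  ic <- (m + 1) / 2

  # right half: facet angles accumulate half-wedges of adjacent cells
  xr <- numeric(m - ic + 1); yr <- numeric(m - ic + 1)
  xr[1] <- aw[ic] / 2; yr[1] <- 0
  beta <- 0
  if (ic < m) for (j in (ic + 1):m) {
    beta <- beta + (phi[j - 1] + phi[j]) / 2
    k <- j - ic + 1
    xr[k] <- xr[k - 1] + aw[j] * cos(beta)
    yr[k] <- yr[k - 1] + aw[j] * sin(beta)
  }
  # left half, mirrored accumulation
  xl <- numeric(ic); yl <- numeric(ic)
  xl[1] <- -aw[ic] / 2; yl[1] <- 0
  gamma <- 0
  if (ic > 1) for (j in (ic - 1):1) {
    gamma <- gamma + (phi[j + 1] + phi[j]) / 2
    k <- ic - j + 1
    xl[k] <- xl[k - 1] - aw[j] * cos(gamma)
    yl[k] <- yl[k - 1] + aw[j] * sin(gamma)
  }
  x <- c(rev(xl), xr)
  y <- c(rev(yl), yr)

  # baseline: the undeformed apical line through the far lateral (rest)
  # cells. Asymmetric area profiles rigidly tilt the construction (which is
  # anchored at the midline facet), so a line is fitted through the outer
  # vertices of both wings and subtracted.
  kb <- min(4, (length(y) - 1) %/% 2)
  sel <- c(seq_len(kb), seq.int(length(y) - kb + 1, length(y)))
  cf <- stats::lm.fit(cbind(1, x[sel]), y[sel])$coefficients
  y <- y - (cf[1] + cf[2] * x)
  structure(list(x = x, y = y, depth = -min(y),
                 wedge_angle = phi,
                 geometry_error = NULL,
                 self_intersecting = any(diff(x) < 0),
                 failed = NA, failure_reason = NA_character_,
                 areas = area_profile, grid = grid),
            class = "furrow_shape")
}

#' Furrow shape from a simulation
#'
#' Convenience wrapper: extracts the apical area profile of a [simulate_furrow()]
#' run at `time` and reconstructs the cross-sectional shape.
#'
#' @param sim a `vff_sim` object.
#' @param time time in seconds (default end of run).
#' @return A `"furrow_shape"` object (see [assemble_tissue_cross_section()]).
#' @export
furrow_shape <- function(sim, time = NULL) {
  p <- sim$params
  assemble_tissue_cross_section(final_areas(sim, time), sim$grid,
                                b_len = p$b_len, H = p$H, V = p$V,
                                L_rest = p$L_rest)
}

#' @export
print.furrow_shape <- function(x, ...) {
  if (!is.null(x$geometry_error)) {
    cat("Furrow shape: geometry error (", x$geometry_error, ")\n", sep = "")
  } else {
    cat(sprintf("Furrow shape: depth %.3g um over %d cells%s\n",
                x$depth, length(x$areas),
                if (isTRUE(x$self_intersecting)) " [self-intersecting]" else ""))
  }
  if (!is.na(x$failed))
    cat(sprintf("  classified: %s%s\n", if (x$failed) "FAILED" else "ok",
                if (x$failed) paste0(" (", x$failure_reason, ")") else ""))
  invisible(x)
}

#' @export
plot.furrow_shape <- function(x, ...) {
  if (!is.null(x$geometry_error)) stop("cannot plot: ", x$geometry_error)
  graphics::plot(x$x, x$y, type = "l", lwd = 2, col = "steelblue", asp = 1,
                 xlab = expression(paste("x (", mu, "m)")),
                 ylab = expression(paste("y (", mu, "m)")),
                 main = sprintf("Apical surface (depth %.2g um)", x$depth), ...)
  graphics::abline(h = 0, lty = 2, col = "grey50")
  invisible(x)
}

# strict local minima of the apical polyline, returned as depths below the
# baseline (um)
polyline_minima_depths <- function(y) {
  n <- length(y)
  if (n < 3) return(numeric(0))
  i <- 2:(n - 1)
  mins <- i[y[i] < y[i - 1] & y[i] < y[i + 1]]
  -y[mins]
}

#' Classify furrow success or failure
#'
#' A furrow counts as failed when its depth falls below
#' `depth_frac` times the reference depth (from a fluctuation-free
#' wild-type run at the same time point), when the apical polyline has more
#' than one local minimum deeper than `minima_frac` times the reference
#' depth (a fragmented, multi-valley surface instead of a single furrow),
#' when the shape self-intersects, or when any cell failed the geometry
#' construction.
#'
#' @param shape a `"furrow_shape"` object.
#' @param reference_depth depth (\eqn{\mu}m) of the fluctuation-free
#'   wild-type furrow at the same time point.
#' @param depth_frac minimum acceptable depth as a fraction of the
#'   reference (default 0.5).
#' @param minima_frac depth fraction above which a secondary local minimum
#'   counts (default 0.2).
#' @return The shape with `failed` (logical) and `failure_reason` filled
#'   in.
#' @export
classify_failure <- function(shape, reference_depth, depth_frac = 0.5,
                             minima_frac = 0.2) {
  if (!inherits(shape, "furrow_shape")) stop("`shape` must be a furrow_shape")
  if (!is.finite(reference_depth) || reference_depth <= 0)
    stop("`reference_depth` must be a positive depth")
  if (!is.null(shape$geometry_error)) {
    shape$failed <- TRUE
    shape$failure_reason <- paste0("geometry error: ", shape$geometry_error)
    return(shape)
  }
  if (isTRUE(shape$self_intersecting)) {
    shape$failed <- TRUE
    shape$failure_reason <- "self-intersecting cross-section"
    return(shape)
  }
  if (shape$depth < depth_frac * reference_depth) {
    shape$failed <- TRUE
    shape$failure_reason <- sprintf("depth %.3g um < %g x reference (%.3g um)",
                                    shape$depth, depth_frac, reference_depth)
    return(shape)
  }
  deep <- polyline_minima_depths(shape$y)
  n_deep <- sum(deep > minima_frac * reference_depth)
  if (n_deep > 1) {
    shape$failed <- TRUE
    shape$failure_reason <- sprintf("%d local minima deeper than %g x reference",
                                    n_deep, minima_frac)
    return(shape)
  }
  shape$failed <- FALSE
  shape$failure_reason <- NA_character_
  shape
}
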