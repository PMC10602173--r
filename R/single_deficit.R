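#' Single frozen myosin deficit: local furrow defect
#'
#' Solves the model for a hypothetical myosin profile consisting of the
#' ramping wild-type envelope plus a single frozen relative deficit
#' \eqn{\epsilon} on one near-peak cell, together with the matching
#' fluctuation-free reference run. A persistent deficit of the measured
#' ~45% magnitude exceeds the critical fluctuation
#' \eqn{(2\xi/h)^2 \approx 39\%} (at \eqn{\xi = 2.5} and envelope
#' half-width 8 cells), so it does not merely prevent the cell from
#' contracting: the cell expands roughly 30% above its resting area by
#' 400 s while its neighbours constrict, producing a local defect in the
#' furrow shape.
#'
#' `net_change_pct` is the headline statistic: the carrying cell's area
#' change at `t_eval` relative to its own resting area,
#' \eqn{100\,(A_{deficit} - A_{rest})/A_{rest}}. The deficit-attributable
#' excess over the fluctuation-free reference at the same instant
#' (`expansion_pct`, in percent of the resting area) is also returned.
#'
#' @param eps frozen relative fluctuation (default -0.45, a 45% deficit).
#' @param deficit_cell cell index carrying the deficit (default 1, adjacent
#'   to the peak).
#' @param h envelope full support width, cells (default 16, i.e. the
#'   half-width symbol of the scaling arguments equals 8).
#' @param ramp_duration time at which the ramping envelope reaches
#'   `T_star`, s; the ramp continues past it (default 300).
#' @param t_end simulated duration, s.
#' @param t_eval evaluation time, s.
#' @param params a [vff_params()] object.
#' @param grid a [cell_grid()].
#' @param dt time step, s.
#' @return list with `net_change_pct`, `expansion_pct`, `area_deficit`,
#'   `area_reference`, `area_rest` (\eqn{\mu}m\eqn{^2}), `t_eval`, and the
#'   two simulations (`sim_deficit`, `sim_reference`).
#' @examples
#' \donttest{
#' d <- single_deficit_expansion(dt = 5)
#' d$net_change_pct  # ~ +30%
#' }
#' @export
single_deficit_expansion <- function(eps = -0.45, deficit_cell = 1, h = 16,
                                     ramp_duration = 300, t_end = 500,
                                     t_eval = 400, params = vff_params(),
                                     grid = cell_grid(), dt = 1) {
  times <- seq(0, t_end, by = dt)
  env <- make_envelope("parabolic", h = h, T_star = params$T_star,
                       ramp_duration = ramp_duration, cap = FALSE,
                       grid = grid, times = times)
  em <- matrix(0, length(grid$indices), length(times))
  em[grid$indices == deficit_cell, ] <- eps
  sim_def <- simulate_furrow(compose_profile(env, em), params)
  sim_ref <- simulate_furrow(env, params)
  i <- which(grid$indices == deficit_cell)
  a_def <- final_areas(sim_def, t_eval)[i]
  a_ref <- final_areas(sim_ref, t_eval)[i]
  a_rest <- params$b_len * params$L_rest
  list(net_change_pct = 100 * (a_def - a_rest) / a_rest,
       expansion_pct = 100 * (a_def - a_ref) / a_rest,
       area_deficit = a_def, area_reference = a_ref, area_rest = a_rest,
       t_eval = t_eval, deficit_cell = deficit_cell,
       sim_deficit = sim_def, sim_reference = sim_ref)
}
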