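#' Read and write tension profiles as CSV
#'
#' The canonical interchange format is long CSV with columns `time_s`,
#' `cell_n`, `tension_pN`; a dense matrix dialect (one row per time, first
#' column `time_s`, remaining columns named by cell index) is also
#' accepted on read and available on write. Numeric content round-trips
#' to better than 12 significant digits.
#'
#' @param profile a [tension_profile()].
#' @param path file path.
#' @param format `"long"` (default) or `"dense"`.
#' @return `write_tension_profile()` returns `path` invisibly;
#'   `read_tension_profile()` returns a [tension_profile()].
#' @export
write_tension_profile <- function(profile, path, format = c("long", "dense")) {
  format <- match.arg(format)
  if (format == "long") {
    nc <- nrow(profile$values); nt <- ncol(profile$values)
    df <- data.frame(time_s = rep(profile$times, each = nc),
                     cell_n = rep(profile$grid$indices, nt),
                     tension_pN = as.vector(profile$values))
  } else {
    df <- data.frame(time_s = profile$times, t(profile$values),
                     check.names = FALSE)
    names(df) <- c("time_s", profile$grid$indices)
  }
  utils::write.csv(format(df, digits = 15, trim = TRUE, scientific = FALSE),
                   path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_tension_profile
#' @export
read_tension_profile <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE)
  if (all(c("time_s", "cell_n", "tension_pN") %in% names(df))) {
    times <- sort(unique(df$time_s))
    cells <- sort(unique(df$cell_n))
    vals <- matrix(NA_real_, length(cells), length(times))
    vals[cbind(match(df$cell_n, cells), match(df$time_s, times))] <- df$tension_pN
    if (anyNA(vals)) {
      bad <- which(is.na(vals), arr.ind = TRUE)[1, ]
      stop(sprintf("missing tension for cell %d at time %g", cells[bad[1]], times[bad[2]]))
    }
  } else if (names(df)[1] == "time_s") {
    cells <- suppressWarnings(as.integer(names(df)[-1]))
    if (anyNA(cells)) stop("dense CSV must have a header row of integer cell indices")
    times <- df$time_s
    vals <- unname(t(as.matrix(df[, -1, drop = FALSE])))
  } else {
    stop("unrecognised tension CSV dialect: expected long (time_s, cell_n, tension_pN) or dense (time_s, <cell indices>)")
  }
  N <- max(abs(cells))
  if (!identical(as.integer(cells), seq.int(-N, N)))
    stop("cell indices must be contiguous and symmetric about 0")
  tension_profile(vals, cell_grid(N), times)
}

#' Write a simulated tissue trajectory as long CSV
#'
#' Columns: `time_s`, `cell_n`, `width_um`, `area_um2`, `velocity_nm_s`,
#' `contraction_nm_s`, `alive`.
#'
#' @param sim a `vff_sim` object.
#' @param path file path.
#' @return `path`, invisibly.
#' @export
write_tissue_state <- function(sim, path) {
  df <- as.data.frame(sim)
  num <- vapply(df, is.numeric, logical(1))
  df[num] <- lapply(df[num], function(x) format(x, digits = 15, trim = TRUE))
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_tissue_state
#' @export
read_tissue_state <- function(path) {
  df <- utils::read.csv(path)
  need <- c("time_s", "cell_n", "width_um", "area_um2",
            "velocity_nm_s", "contraction_nm_s", "alive")
  miss <- setdiff(need, names(df))
  if (length(miss)) stop("tissue-state CSV missing column(s): ",
                         paste(miss, collapse = ", "))
  df$alive <- as.logical(df$alive)
  df
}

#' Write a furrow shape as CSV polyline plus JSON summary
#'
#' @param shape a `"furrow_shape"` object.
#' @param csv_path path for the apical polyline (`x_um`, `y_um`).
#' @param json_path path for the summary (`depth_um`, `failed`, `reason`).
#' @return list of the two paths, invisibly.
#' @export
write_furrow_shape <- function(shape, csv_path, json_path) {
  if (is.null(shape$geometry_error)) {
    utils::write.csv(data.frame(x_um = shape$x, y_um = shape$y),
                     csv_path, row.names = FALSE, quote = FALSE)
  } else {
    utils::write.csv(data.frame(x_um = numeric(0), y_um = numeric(0)),
                     csv_path, row.names = FALSE, quote = FALSE)
  }
  jsonlite::write_json(list(depth_um = shape$depth,
                            failed = shape$failed,
                            reason = shape$failure_reason,
                            geometry_error = shape$geometry_error,
                            self_intersecting = shape$self_intersecting),
                       json_path, auto_unbox = TRUE, digits = NA, null = "null",
                       na = "null")
  invisible(list(csv = csv_path, json = json_path))
}

#' Read, validate and normalise a run configuration
#'
#' Configurations are YAML or JSON with blocks `condition` (preset name or
#' `"custom"`), `params` (`mu`, `lambda`, `k`, `T_star`, `b`,
#' `beta`, `beta_cells`), `envelope` / `fluctuations` / `pulses` specs for
#' custom runs, `grid` (`N`), `integration` (`dt`, `t_end`) and `seed`.
#' Validation happens before any computation; stochastic modes without a
#' seed are a configuration error.
#'
#' @param path path to a `.yaml`/`.yml`/`.json` file.
#' @return A validated configuration list of class `"vff_config"`.
#' @export
read_run_config <- function(path) {
  cfg <- if (grepl("\\.json$", path, ignore.case = TRUE))
    jsonlite::read_json(path, simplifyVector = TRUE)
  else yaml::read_yaml(path)
  validate_run_config(cfg)
}

#' @rdname read_run_config
#' @param config a configuration list (as from [read_run_config()]).
#' @export
validate_run_config <- function(config) {
  if (!is.list(config)) stop("configuration must be a mapping")
  known <- c("condition", "params", "envelope", "fluctuations", "pulses",
             "grid", "integration", "seed", "out_dir", "n_runs")
  unknown <- setdiff(names(config), known)
  if (length(unknown))
    stop("unknown configuration field(s): ", paste(unknown, collapse = ", "))
  cond <- config$condition %||% "wildtype"
  presets <- c("wildtype", "cgap", "spn27a", "twist", "single_deficit", "custom")
  if (!cond %in% presets)
    stop("`condition` must be one of: ", paste(presets, collapse = ", "))
  stochastic <- cond %in% c("wildtype", "cgap", "twist") ||
    (cond == "custom" && (!is.null(config$fluctuations) || !is.null(config$pulses)))
  if (stochastic && is.null(config$seed))
    stop("configuration error: `seed` is mandatory for stochastic modes")
  if (!is.null(config$seed) &&
      (!is.numeric(config$seed) || config$seed != round(config$seed)))
    stop("`seed` must be an integer")
  g <- config$grid$N %||% 40
  if (!is.numeric(g) || g < 2) stop("`grid.N` must be an integer >= 2")
  it <- config$integration
  if (!is.null(it$dt) && it$dt <= 0) stop("`integration.dt` must be positive")
  if (!is.null(it$t_end) && it$t_end <= 0) stop("`integration.t_end` must be positive")
  structure(config, class = c("vff_config", "list"))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Build model inputs from a validated configuration
#'
#' @param config a `"vff_config"` (see [read_run_config()]).
#' @return list with `profile` ([tension_profile()]), `params`
#'   ([vff_params()]), `grid`, `dt`, `t_end`, `seed`, `condition`.
#' @export
config_to_inputs <- function(config) {
  config <- validate_run_config(config)
  grid <- cell_grid(config$grid$N %||% 40)
  dt <- config$integration$dt %||% 1
  cond <- config$condition %||% "wildtype"
  pc <- config$params
  params <- vff_params(mu = pc$mu %||% 36,
                       lambda = pc$lambda %||% ((pc$mu %||% 36) / 2.5^2),
                       k_elastic = pc$k %||% 0,
                       T_star = pc$T_star %||% 1500,
                       b_len = pc$b %||% 5.7,
                       beta = pc$beta %||% 1,
                       beta_cells = pc$beta_cells)
  if (cond != "custom") {
    pre <- preset_condition(cond, seed = config$seed, grid = grid, dt = dt,
                            t_end = config$integration$t_end)
    if (is.null(config$params)) params <- pre$params
    return(list(profile = pre$profile, envelope = pre$envelope, params = params,
                grid = grid, dt = dt, t_end = pre$t_end, seed = config$seed,
                condition = cond))
  }
  t_end <- config$integration$t_end %||% 500
  times <- seq(0, t_end, by = dt)
  if (!is.null(config$pulses)) {
    ps <- config$pulses
    profile <- make_twist_profile(grid, times, T_star = params$T_star,
      pulse_duration = ps$pulse_duration %||% 35,
      interval_range = unlist(ps$interval_range %||% c(30, 330)),
      amplitude_range = unlist(ps$amplitude_range %||% c(0, 2)),
      active_cells = unlist(ps$active_cells %||% (-6:7)),
      pulse_shape = ps$pulse_shape %||% "raised_cosine",
      seed = config$seed)
    envelope <- tension_profile(matrix(0, length(grid$indices), length(times)),
                                grid, times)
  } else {
    es <- config$envelope %||% list()
    envelope <- make_envelope(es$shape %||% "parabolic", h = es$h %||% 8,
                              T_star = params$T_star,
                              ramp_duration = es$ramp_duration %||% 500,
                              shoulder = es$shoulder %||% 2,
                              grid = grid, times = times)
    profile <- envelope
    if (!is.null(config$fluctuations)) {
      fs <- config$fluctuations
      eps <- sample_fluctuations(grid, times, sigma = fs$sigma %||% 0.45,
                                 tau = fs$tau %||% 75,
                                 mode = fs$mode %||% "pulsatile",
                                 seed = config$seed)
      profile <- compose_profile(envelope, eps,
                                 clamp_floor = fs$clamp_floor %||% 0)
    }
  }
  list(profile = profile, envelope = envelope, params = params, grid = grid,
       dt = dt, t_end = t_end, seed = config$seed, condition = cond)
}
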