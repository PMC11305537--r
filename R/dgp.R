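#' Intervention shapes available in the data-generating process
#'
#' The four intervention patterns the simulator can impose on a score panel:
#' an immediate level drop only (`"step_only"`), a change in the growth
#' trend only (`"slope_only"`), both at once (`"step_slope"`), or both plus
#' a smaller second level drop later in the series (`"two_steps_slope"`).
#'
#' @return Character vector of shape names.
#' @export
its_shapes <- function() {
  c("step_only", "slope_only", "step_slope", "two_steps_slope")
}

#' Sampling modes for panel generation
#'
#' `"cross_sectional"` draws a fresh baseline deviation for every
#' (subject, occasion) record, so all records are independent.
#' `"longitudinal"` draws one baseline deviation per subject, shared across
#' that subject's occasions, giving persistent growth curves.
#'
#' @return Character vector of mode names.
#' @export
its_sampling_modes <- function() {
  c("cross_sectional", "longitudinal")
}

#' Define one simulation scenario
#'
#' A scenario is one cell of the simulation grid: the panel dimensions, the
#' intervention effect size, the intervention shape and the generative
#' constants of the score process. Scores follow a linear growth process:
#' the occasion-1 score is drawn around `baseline_mean` with variance
#' `baseline_var`, grows by `slope` score units per occasion, and receives
#' independent occasion-level noise with variance `noise_var`. Intervention
#' effects are expressed as a fraction `effect_size` of the growth slope and
#' enter with a negative sign (a shock that sets learning back).
#'
#' @param n_timepoints Even integer number of measurement occasions (>= 4);
#'   the first intervention is placed at the series midpoint, which requires
#'   an even count.
#' @param n_subjects Number of scores observed per occasion.
#' @param effect_size Intervention effect as a (dimensionless) fraction of
#'   the pre-intervention slope. Positive values give the conventional
#'   negative shock; negative values flip the sign of the shock.
#' @param shape One of [its_shapes()].
#' @param sampling_mode One of [its_sampling_modes()].
#' @param baseline_mean Expected score at the first occasion (score units).
#' @param baseline_var Between-subject variance of the occasion-1 score
#'   (score units squared); may be zero for noiseless fixtures.
#' @param slope Deterministic growth per measurement occasion (score units).
#' @param noise_var Occasion-level noise variance (score units squared);
#'   may be zero.
#' @param second_step_fraction Size of the second step change relative to
#'   the first, used only for shape `"two_steps_slope"`.
#'
#' @return An object of class `its_scenario` (a named list).
#' @examples
#' scenario_spec(12, 1100, 0.15, shape = "step_slope")
#' @export
scenario_spec <- function(n_timepoints,
                          n_subjects,
                          effect_size,
                          shape = "step_slope",
                          sampling_mode = "cross_sectional",
                          baseline_mean = 170,
                          baseline_var = 25,
                          slope = 16.5,
                          noise_var = 25,
                          second_step_fraction = 0.5) {
  n_timepoints <- as.integer(n_timepoints)
  n_subjects <- as.integer(n_subjects)
  if (length(n_timepoints) != 1L || is.na(n_timepoints) || n_timepoints < 4L) {
    stop("`n_timepoints` must be a single integer >= 4", call. = FALSE)
  }
  if (n_timepoints %% 2L != 0L) {
    stop("`n_timepoints` must be even: the intervention is placed at the ",
         "series midpoint, between the two middle occasions", call. = FALSE)
  }
  if (length(n_subjects) != 1L || is.na(n_subjects) || n_subjects < 1L) {
    stop("`n_subjects` must be a single positive integer", call. = FALSE)
  }
  shape <- match.arg(shape, its_shapes())
  sampling_mode <- match.arg(sampling_mode, its_sampling_modes())
  if (shape == "two_steps_slope" && n_timepoints < 6L) {
    stop("shape 'two_steps_slope' requires at least 6 time points", call. = FALSE)
  }
  if (baseline_var < 0 || noise_var < 0) {
    stop("variances must be non-negative", call. = FALSE)
  }
  structure(
    list(
      n_timepoints = n_timepoints,
      n_subjects = n_subjects,
      effect_size = as.numeric(effect_size),
      shape = shape,
      sampling_mode = sampling_mode,
      baseline_mean = as.numeric(baseline_mean),
      baseline_var = as.numeric(baseline_var),
      slope = as.numeric(slope),
      noise_var = as.numeric(noise_var),
      second_step_fraction = as.numeric(second_step_fraction)
    ),
    class = "its_scenario"
  )
}

#' @export
print.its_scenario <- function(x, ...) {
  cat(sprintf(
    "ITS scenario: T=%d occasions, n=%d subjects/occasion, effect=%.3g, shape=%s (%s)\n",
    x$n_timepoints, x$n_subjects, x$effect_size, x$shape, x$sampling_mode
  ))
  invisible(x)
}

#' Build the full scenario grid
#'
#' Cartesian product of time-point counts, subjects-per-occasion counts and
#' effect sizes, in deterministic lexicographic order (time points vary
#' slowest, effect sizes fastest). The defaults reproduce the study grid of
#' 8 x 8 x 6 = 384 data-generating scenarios.
#'
#' @param timepoint_values Even time-point counts (default 6 to 20 by 2).
#' @param subject_values Subjects per occasion (default 100 to 1500 by 200).
#' @param effect_values Effect sizes as fractions of the slope
#'   (default 0.01, 0.025, 0.05, 0.10, 0.15, 0.30).
#' @param ... Further arguments passed to [scenario_spec()] (shape,
#'   sampling_mode, generative constants).
#'
#' @return A list of `its_scenario` objects.
#' @examples
#' length(build_scenario_grid()) # 384
#' @export
build_scenario_grid <- function(timepoint_values = seq(6L, 20L, by = 2L),
                                subject_values = seq(100L, 1500L, by = 200L),
                                effect_values = c(0.01, 0.025, 0.05, 0.10, 0.15, 0.30),
                                ...) {
  if (length(timepoint_values) == 0L || length(subject_values) == 0L ||
      length(effect_values) == 0L) {
    stop("all grid value lists must be non-empty", call. = FALSE)
  }
  if (any(timepoint_values <= 0) || any(subject_values <= 0)) {
    stop("grid values must be positive", call. = FALSE)
  }
  if (any(as.integer(timepoint_values) %% 2L != 0L)) {
    stop("all `timepoint_values` must be even (midpoint intervention placement)",
         call. = FALSE)
  }
  out <- vector("list", length(timepoint_values) * length(subject_values) *
                  length(effect_values))
  i <- 0L
  for (tt in timepoint_values) {
    for (nn in subject_values) {
      for (ee in effect_values) {
        i <- i + 1L
        out[[i]] <- scenario_spec(tt, nn, ee, ...)
      }
    }
  }
  out
}

#' Intervention timing for a series of occasions
#'
#' Maps raw occasion indices 1..T to a centered time axis with 0 at the
#' first intervention, which sits between the two middle occasions, so the
#' centered times are the half-integers -(T-1)/2, ..., -0.5, +0.5, ...,
#' +(T-1)/2. The post-intervention indicator `x1` is 1 for the last T/2
#' occasions. For shape `"two_steps_slope"` a second intervention is placed
#' at 75% of the series: after occasion `k = floor(0.75 T + 0.5)`
#' (round half up), with indicator `x2` equal to 1 strictly after occasion
#' `k`.
#'
#' @param n_timepoints Even number of occasions, at least 4 (6 for the
#'   two-intervention shape).
#' @param shape One of [its_shapes()].
#'
#' @return An object of class `its_schedule`: a list with `raw_times`,
#'   `centered_times`, `x1`, `x2` and `second_boundary_index` (`NA` for
#'   single-intervention shapes, where `x2` is all zero).
#' @examples
#' intervention_schedule(6, "step_slope")$centered_times
#' intervention_schedule(8, "two_steps_slope")$x2
#' @export
intervention_schedule <- function(n_timepoints, shape = "step_slope") {
  n_timepoints <- as.integer(n_timepoints)
  shape <- match.arg(shape, its_shapes())
  if (n_timepoints < 4L || n_timepoints %% 2L != 0L) {
    stop("`n_timepoints` must be an even integer >= 4", call. = FALSE)
  }
  raw <- seq_len(n_timepoints)
  centered <- raw - (n_timepoints / 2 + 0.5)
  x1 <- as.numeric(centered > 0)
  if (shape == "two_steps_slope") {
    k <- as.integer(floor(0.75 * n_timepoints + 0.5)) # round half up
    if (k >= n_timepoints) {
      stop("no occasion lies after the second intervention (boundary k = ",
           k, " with T = ", n_timepoints, ")", call. = FALSE)
    }
    x2 <- as.numeric(raw > k)
  } else {
    k <- NA_integer_
    x2 <- numeric(n_timepoints)
  }
  structure(
    list(
      raw_times = raw,
      centered_times = centered,
      x1 = x1,
      x2 = x2,
      second_boundary_index = k,
      shape = shape
    ),
    class = "its_schedule"
  )
}

#' Generative coefficients implied by a scenario
#'
#' Translates a scenario into the coefficient vector of the generative mean
#' model. The step change and slope change each equal
#' `-effect_size * slope` when present in the shape (negative shocks), the
#' incremental second step is `second_step_fraction` times the first step,
#' and the quadratic coefficient is always zero: curvature exists only in
#' fitted models, never in the data. The intercept is the noiseless mean
#' extrapolated to centered time 0,
#' `baseline_mean + slope * (T/2 - 0.5)`.
#'
#' @param scenario An `its_scenario`.
#' @param shape Intervention shape; defaults to the scenario's own.
#'
#' @return An object of class `its_true_params`: a list with elements
#'   `beta0`, `beta1`, `beta_step`, `beta_slope_change`, `beta_step2`,
#'   `beta_t2`.
#' @examples
#' true_coefficients(scenario_spec(6, 100, 0.30, "step_slope"))
#' @export
true_coefficients <- function(scenario, shape = scenario$shape) {
  stopifnot(inherits(scenario, "its_scenario"))
  shape <- match.arg(shape, its_shapes())
  eff <- -scenario$effect_size * scenario$slope
  has_step <- shape %in% c("step_only", "step_slope", "two_steps_slope")
  has_slope <- shape %in% c("slope_only", "step_slope", "two_steps_slope")
  beta_step <- if (has_step) eff else 0
  structure(
    list(
      beta0 = scenario$baseline_mean +
        scenario$slope * (scenario$n_timepoints / 2 - 0.5),
      beta1 = scenario$slope,
      beta_step = beta_step,
      beta_slope_change = if (has_slope) eff else 0,
      beta_step2 = if (shape == "two_steps_slope") {
        scenario$second_step_fraction * beta_step
      } else 0,
      beta_t2 = 0
    ),
    class = "its_true_params"
  )
}

#' True coefficient values keyed by design-term name
#'
#' Convenience mapping from [true_coefficients()] to the term names used by
#' the model catalogue, with 0 for terms that never appear in the
#' data-generating process (the quadratic trend and a post-second-
#' intervention slope change).
#'
#' @param true_params An `its_true_params` object.
#' @return Named numeric vector over all seven possible design terms.
#' @export
true_term_values <- function(true_params) {
  stopifnot(inherits(true_params, "its_true_params"))
  c(
    intercept = true_params$beta0,
    time = true_params$beta1,
    step = true_params$beta_step,
    slope_change = true_params$beta_slope_change,
    step2 = true_params$beta_step2,
    slope_change2 = 0,
    time_sq = true_params$beta_t2
  )
}

#' Expected score under the generative model
#'
#' The noiseless mean:
#' `beta0 + beta1 t + x1 (beta_step + beta_slope_change t) + x2 beta_step2`,
#' evaluated elementwise. Equivalent to the incremental description of the
#' process: the score grows by `slope` per occasion before the intervention
#' and by `slope * (1 - effect_size)` after it, with level drops at each
#' intervention boundary.
#'
#' @param centered_time Numeric vector of centered times.
#' @param x1,x2 Post-intervention indicator vectors (same length).
#' @param true_params An `its_true_params` object.
#' @return Numeric vector of expected scores.
#' @export
mean_function <- function(centered_time, x1, x2, true_params) {
  stopifnot(inherits(true_params, "its_true_params"))
  true_params$beta0 +
    true_params$beta1 * centered_time +
    x1 * (true_params$beta_step + true_params$beta_slope_change * centered_time) +
    x2 * true_params$beta_step2
}

# Score draws for one replication: baseline deviations first, then
# occasion-level noise, in subject-major record order (subject 1 occasions
# 1..T, subject 2 occasions 1..T, ...). RNG order is part of the
# reproducibility contract.
panel_scores <- function(n_subjects, n_timepoints, mu, baseline_sd, noise_sd,
                         sampling_mode) {
  n_rec <- n_subjects * n_timepoints
  b <- if (sampling_mode == "longitudinal") {
    rep(stats::rnorm(n_subjects, 0, baseline_sd), each = n_timepoints)
  } else {
    stats::rnorm(n_rec, 0, baseline_sd)
  }
  eps <- stats::rnorm(n_rec, 0, noise_sd)
  rep(mu, times = n_subjects) + b + eps
}

#' Generate one synthetic score panel
#'
#' Draws a full panel of `n_subjects * n_timepoints` scores from the
#' scenario's generative process: expected score from [mean_function()],
#' plus a baseline deviation with variance `baseline_var` (per record in
#' cross-sectional mode, per subject in longitudinal mode), plus
#' independent occasion noise with variance `noise_var`. The same seed
#' always reproduces the identical panel.
#'
#' @param scenario An `its_scenario`.
#' @param shape Intervention shape; defaults to the scenario's own shape.
#' @param seed Integer seed for this panel.
#'
#' @return An `its_panel`: a data frame with columns `subject_id`,
#'   `occasion`, `centered_time`, `score` (subject-major order) and
#'   attributes `scenario`, `schedule`, `shape`, `seed`.
#' @examples
#' p <- generate_panel(scenario_spec(6, 10, 0.3), seed = 1)
#' head(p)
#' @export
generate_panel <- function(scenario, shape = scenario$shape, seed) {
  stopifnot(inherits(scenario, "its_scenario"))
  shape <- match.arg(shape, its_shapes())
  if (length(seed) != 1L || is.na(seed)) {
    stop("`seed` must be a single integer", call. = FALSE)
  }
  sched <- intervention_schedule(scenario$n_timepoints, shape)
  tp <- true_coefficients(scenario, shape)
  mu <- mean_function(sched$centered_times, sched$x1, sched$x2, tp)
  set.seed(as.integer(seed))
  score <- panel_scores(
    scenario$n_subjects, scenario$n_timepoints, mu,
    sqrt(scenario$baseline_var), sqrt(scenario$noise_var),
    scenario$sampling_mode
  )
  occ <- rep(seq_len(scenario$n_timepoints), times = scenario$n_subjects)
  out <- data.frame(
    subject_id = rep(seq_len(scenario$n_subjects),
                     each = scenario$n_timepoints),
    occasion = occ,
    centered_time = sched$centered_times[occ],
    score = score
  )
  attr(out, "scenario") <- scenario
  attr(out, "schedule") <- sched
  attr(out, "shape") <- shape
  attr(out, "seed") <- as.integer(seed)
  class(out) <- c("its_panel", "data.frame")
  out
}

#' Write a panel as tidy CSV
#'
#' @param panel An `its_panel` (or any data frame with the panel columns).
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_panel_csv <- function(panel, path) {
  cols <- c("subject_id", "occasion", "centered_time", "score")
  if (!all(cols %in% names(panel))) {
    stop("panel must have columns ", paste(cols, collapse = ", "), call. = FALSE)
  }
  utils::write.csv(as.data.frame(panel)[cols], path, row.names = FALSE)
  invisible(path)
}

#' Read a panel from tidy CSV
#'
#' @param path CSV file written by [write_panel_csv()].
#' @return A data frame with the panel columns.
#' @export
read_panel_csv <- function(path) {
  utils::read.csv(path, colClasses = c(
    subject_id = "integer", occasion = "integer",
    centered_time = "numeric", score = "numeric"
  ))
}

#' Default run configuration
#'
#' The study-default configuration: the full 8 x 8 x 6 scenario grid, all
#' four intervention shapes, cross-sectional sampling, 1000 replications
#' per cell and a two-sided test level of 0.05.
#'
#' @return A named list with entries `timepoints`, `subjects`, `effects`,
#'   `shapes`, `sampling_mode`, `reps`, `base_seed`, `alpha`.
#' @export
default_grid_config <- function() {
  list(
    timepoints = seq(6L, 20L, by = 2L),
    subjects = seq(100L, 1500L, by = 200L),
    effects = c(0.01, 0.025, 0.05, 0.10, 0.15, 0.30),
    shapes = its_shapes(),
    sampling_mode = "cross_sectional",
    reps = 1000L,
    base_seed = 1L,
    alpha = 0.05
  )
}

#' Read or write a run configuration as YAML
#'
#' Configurations use the fixed key set of [default_grid_config()]; missing
#' keys are filled from the defaults, unknown keys rejected.
#'
#' @param path YAML file path.
#' @return For `read_grid_config`, the completed configuration list.
#' @export
read_grid_config <- function(path) {
  raw <- yaml::read_yaml(path)
  defaults <- default_grid_config()
  unknown <- setdiff(names(raw), names(defaults))
  if (length(unknown)) {
    stop("unknown configuration keys: ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  out <- utils::modifyList(defaults, raw)
  out$reps <- as.integer(out$reps)
  out$base_seed <- as.integer(out$base_seed)
  out
}

#' @rdname read_grid_config
#' @param config Configuration list.
#' @export
write_grid_config <- function(config, path) {
  yaml::write_yaml(config, path)
  invisible(path)
}
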