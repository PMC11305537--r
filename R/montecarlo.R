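#' Data-shape / model pairings of the simulation design
#'
#' The six studied pairings of generating shape and fitted model, each
#' labelled by fit quality: `right_fit` when the model matches the
#' generating process, `overfit` when it carries terms the process lacks,
#' `underfit` when it omits terms the process contains.
#'
#' @return Data frame with columns `model`, `shape`, `fit_quality`.
#' @export
simulation_pairings <- function() {
  data.frame(
    model = c("basic", "basic", "basic", "basic",
              "two_intervention_steps", "quadratic"),
    shape = c("step_slope", "step_only", "slope_only", "two_steps_slope",
              "two_steps_slope", "step_slope"),
    fit_quality = c("right_fit", "overfit", "overfit", "underfit",
                    "right_fit", "overfit"),
    stringsAsFactors = FALSE
  )
}

fit_quality_of <- function(shape, model_name) {
  p <- simulation_pairings()
  hit <- p$fit_quality[p$shape == shape & p$model == model_name]
  if (length(hit)) hit[[1L]] else "custom"
}

#' Replication seed derivation
#'
#' Deterministic map from (base seed, scenario index, shape, replication
#' index) to a 31-bit seed, so any single replication can be reproduced in
#' isolation with [generate_panel()]. Panels are shared across fitted
#' models within a (scenario, shape, replication) triple, enabling paired
#' model comparisons on identical data.
#'
#' @param base_seed Run-level integer seed.
#' @param scenario_id Integer index of the scenario within its grid.
#' @param shape Intervention shape name.
#' @param rep Replication index (1-based).
#' @return A single integer seed.
#' @export
derive_seed <- function(base_seed, scenario_id, shape, rep) {
  shape_code <- match(shape, its_shapes())
  if (is.na(shape_code)) stop("unknown shape: ", shape, call. = FALSE)
  m <- 2147483563
  s <- as.numeric(base_seed) %% m
  for (v in c(scenario_id, shape_code, rep)) {
    s <- (s * 69069 + as.numeric(v)) %% m
  }
  as.integer(s)
}

#' Empirical power of a coefficient test
#'
#' Proportion of replications whose two-sided p-value falls strictly below
#' `alpha`. Applied to a coefficient whose true value is zero this is the
#' empirical type-I error rate.
#'
#' @param p_values Numeric vector of per-replication p-values.
#' @param alpha Test level in (0, 1).
#' @return Proportion in \[0, 1\].
#' @examples
#' empirical_power(c(0.01, 0.2, 0.04, 0.8), 0.05) # 0.5
#' @export
empirical_power <- function(p_values, alpha = 0.05) {
  if (length(p_values) == 0L) stop("`p_values` must be non-empty", call. = FALSE)
  if (length(alpha) != 1L || alpha <= 0 || alpha >= 1) {
    stop("`alpha` must lie in (0, 1)", call. = FALSE)
  }
  mean(p_values < alpha)
}

#' Absolute bias of an estimator
#'
#' Absolute difference between the mean of the replication estimates and
#' the generative parameter value (aggregation before the absolute value,
#' so opposite-signed errors cancel).
#'
#' @param estimates Numeric vector of per-replication estimates.
#' @param true_value The generative parameter.
#' @return Non-negative scalar in the units of the estimate.
#' @examples
#' bias(c(-5.1, -4.9), -4.95) # 0.05
#' @export
bias <- function(estimates, true_value) {
  if (length(estimates) == 0L) stop("`estimates` must be non-empty", call. = FALSE)
  abs(mean(estimates) - true_value)
}

#' Precision of an estimator
#'
#' Mean of the per-replication model-based standard errors. The empirical
#' standard deviation of the estimates is reported alongside in cell
#' summaries as a diagnostic.
#'
#' @param standard_errors Numeric vector of positive standard errors.
#' @return Mean standard error.
#' @examples
#' precision(c(0.2, 0.2, 0.2)) # 0.2
#' @export
precision <- function(standard_errors) {
  if (length(standard_errors) == 0L) {
    stop("`standard_errors` must be non-empty", call. = FALSE)
  }
  if (any(standard_errors <= 0)) {
    stop("standard errors must be positive", call. = FALSE)
  }
  mean(standard_errors)
}

#' Run one replicated simulation cell
#'
#' Generates `reps` panels under the scenario and shape, fits the given
#' model to every panel, and aggregates per-coefficient empirical power,
#' absolute bias, precision, mean estimate and empirical SD against the
#' generative coefficients (a term absent from the generating process has
#' true value 0, so its power is a type-I error rate).
#'
#' The design matrix is fixed within a cell, so it is factorised once and
#' applied to all replication responses at once; results are identical to
#' refitting each replication separately. Replications whose fit produces
#' non-finite estimates are dropped and counted as failures; the cell
#' errors if more than 1% of fits fail.
#'
#' @param scenario An `its_scenario`.
#' @param model An `its_model` or variant name.
#' @param shape Intervention shape; defaults to the scenario's own.
#' @param reps Number of replications (>= 1; the study default is 1000).
#' @param base_seed Run-level seed; per-replication seeds come from
#'   [derive_seed()].
#' @param alpha Two-sided test level.
#' @param scenario_id Index of the scenario within its grid (seed input).
#' @param chunk_size Replications fitted per batch (memory control only;
#'   no effect on results).
#' @return An `its_cell`: list with the cell key, `reps`, `failures`,
#'   and `stats`, a data frame with one row per model term and columns
#'   `term`, `true_value`, `power`, `bias`, `precision`, `mean_estimate`,
#'   `empirical_sd`.
#' @examples
#' run_cell(scenario_spec(6, 50, 0.3), "basic", reps = 50, base_seed = 7)
#' @export
run_cell <- function(scenario, model, shape = scenario$shape, reps = 1000L,
                     base_seed = 1L, alpha = 0.05, scenario_id = 1L,
                     chunk_size = 250L) {
  stopifnot(inherits(scenario, "its_scenario"))
  if (is.character(model)) model <- model_spec(model)
  stopifnot(inherits(model, "its_model"))
  reps <- as.integer(reps)
  if (reps < 1L) stop("`reps` must be >= 1", call. = FALSE)
  shape <- match.arg(shape, its_shapes())

  sched <- intervention_schedule(scenario$n_timepoints, shape)
  tp <- true_coefficients(scenario, shape)
  mu <- mean_function(sched$centered_times, sched$x1, sched$x2, tp)
  X <- build_design(sched, model, n_per_occasion = scenario$n_subjects)
  truth <- true_term_values(tp)[model$terms]
  p <- length(model$terms)
  n_rec <- nrow(X)
  baseline_sd <- sqrt(scenario$baseline_var)
  noise_sd <- sqrt(scenario$noise_var)

  est <- se <- pv <- matrix(NA_real_, p, reps,
                            dimnames = list(model$terms, NULL))
  done <- 0L
  while (done < reps) {
    k <- min(chunk_size, reps - done)
    Y <- matrix(NA_real_, n_rec, k)
    for (j in seq_len(k)) {
      set.seed(derive_seed(base_seed, scenario_id, shape, done + j))
      Y[, j] <- panel_scores(scenario$n_subjects, scenario$n_timepoints, mu,
                             baseline_sd, noise_sd, scenario$sampling_mode)
    }
    b <- ols_batch(X, Y)
    idx <- done + seq_len(k)
    est[, idx] <- b$estimates
    se[, idx] <- b$se
    pv[, idx] <- b$p_value
    done <- done + k
  }

  ok <- colSums(!is.finite(est)) == 0L
  failures <- reps - sum(ok)
  if (failures > 0.01 * reps) {
    stop("more than 1% of fits failed in this cell (", failures, "/", reps,
         ")", call. = FALSE)
  }
  est <- est[, ok, drop = FALSE]
  se <- se[, ok, drop = FALSE]
  pv <- pv[, ok, drop = FALSE]

  stats_df <- data.frame(
    term = model$terms,
    true_value = as.numeric(truth),
    power = apply(pv, 1L, empirical_power, alpha = alpha),
    bias = vapply(seq_len(p), function(i) bias(est[i, ], truth[[i]]),
                  numeric(1)),
    precision = apply(se, 1L, mean),
    mean_estimate = rowMeans(est),
    empirical_sd = apply(est, 1L, stats::sd),
    stringsAsFactors = FALSE
  )
  structure(
    list(
      scenario = scenario,
      scenario_id = as.integer(scenario_id),
      shape = shape,
      model = model$name,
      fit_quality = fit_quality_of(shape, model$name),
      reps = sum(ok),
      failures = failures,
      alpha = alpha,
      base_seed = as.integer(base_seed),
      stats = stats_df
    ),
    class = "its_cell"
  )
}

#' @export
print.its_cell <- function(x, ...) {
  cat(sprintf(
    "ITS simulation cell: T=%d, n=%d, effect=%.3g | shape=%s, model=%s (%s)\n",
    x$scenario$n_timepoints, x$scenario$n_subjects, x$scenario$effect_size,
    x$shape, x$model, x$fit_quality
  ))
  cat(sprintf("%d successful replications (%d failures), alpha=%.3g\n",
              x$reps, x$failures, x$alpha))
  print(x$stats, row.names = FALSE, digits = 4)
  invisible(x)
}

#' Flatten a cell into long-format result rows
#'
#' One row per (coefficient, metric) with the metrics `power`, `bias`,
#' `precision`, `mean_estimate` and `empirical_sd`.
#'
#' @param x An `its_cell`.
#' @param ... Unused.
#' @return Data frame with columns `scenario_id`, `timepoints`, `subjects`,
#'   `effect`, `shape`, `model`, `coefficient`, `metric`, `value`, `reps`,
#'   `failures`, `seed`.
#' @export
as.data.frame.its_cell <- function(x, ...) {
  metrics <- c("power", "bias", "precision", "mean_estimate", "empirical_sd")
  s <- x$stats
  nt <- nrow(s)
  data.frame(
    scenario_id = x$scenario_id,
    timepoints = x$scenario$n_timepoints,
    subjects = x$scenario$n_subjects,
    effect = x$scenario$effect_size,
    shape = x$shape,
    model = x$model,
    coefficient = rep(s$term, times = length(metrics)),
    metric = rep(metrics, each = nt),
    value = c(s$power, s$bias, s$precision, s$mean_estimate, s$empirical_sd),
    reps = x$reps,
    failures = x$failures,
    seed = x$base_seed,
    stringsAsFactors = FALSE
  )
}

.result_columns <- c("scenario_id", "timepoints", "subjects", "effect",
                     "shape", "model", "coefficient", "metric", "value",
                     "reps", "failures", "seed")

cell_key <- function(scenario_id, shape, model) {
  paste(scenario_id, shape, model, sep = "|")
}

#' Run the full simulation grid
#'
#' Iterates every scenario of the configured grid over the configured
#' shape/model pairings (the six studied pairings by default, restricted
#' to the configured shapes), running one cell per combination and
#' collecting long-format results. When `out_file` is given, rows are
#' appended after every cell so partial results survive interruption, and
#' with `resume = TRUE` cells already present in the file are skipped.
#' Results are independent of execution order: every replication seed is
#' derived from (base seed, scenario index, shape, replication).
#'
#' @param config Configuration list as from [default_grid_config()] or
#'   [read_grid_config()].
#' @param pairings Data frame with columns `model` and `shape`; defaults to
#'   [simulation_pairings()] filtered to `config$shapes`.
#' @param out_file Optional CSV path for incremental output.
#' @param resume Skip cells already present in `out_file`.
#' @param quiet Suppress per-cell progress messages.
#' @return Long-format result data frame (see [as.data.frame.its_cell()]).
#' @export
run_grid <- function(config = default_grid_config(), pairings = NULL,
                     out_file = NULL, resume = FALSE, quiet = FALSE) {
  scenarios <- build_scenario_grid(
    config$timepoints, config$subjects, config$effects,
    sampling_mode = config$sampling_mode
  )
  if (is.null(pairings)) {
    pairings <- simulation_pairings()
    pairings <- pairings[pairings$shape %in% config$shapes, , drop = FALSE]
  }
  if (nrow(pairings) == 0L) stop("no shape/model pairings to run", call. = FALSE)

  existing <- character(0)
  rows <- list()
  if (!is.null(out_file) && resume && file.exists(out_file)) {
    prev <- read_results(out_file)
    rows <- list(prev)
    existing <- unique(cell_key(prev$scenario_id, prev$shape, prev$model))
  } else if (!is.null(out_file)) {
    utils::write.table(t(.result_columns), out_file, sep = ",",
                       col.names = FALSE, row.names = FALSE)
  }

  for (i in seq_along(scenarios)) {
    sc <- scenarios[[i]]
    for (r in seq_len(nrow(pairings))) {
      shape <- pairings$shape[r]
      model_name <- pairings$model[r]
      key <- cell_key(i, shape, model_name)
      if (key %in% existing) next
      t0 <- proc.time()[["elapsed"]]
      cell <- run_cell(sc, model_name, shape = shape, reps = config$reps,
                       base_seed = config$base_seed, alpha = config$alpha,
                       scenario_id = i)
      df <- as.data.frame(cell)
      rows[[length(rows) + 1L]] <- df
      if (!is.null(out_file)) {
        utils::write.table(df, out_file, sep = ",", append = TRUE,
                           col.names = FALSE, row.names = FALSE)
      }
      if (!quiet) {
        message(sprintf(
          "cell scenario=%d T=%d n=%d effect=%.3g shape=%s model=%s seed=%d failures=%d elapsed=%.2fs",
          i, sc$n_timepoints, sc$n_subjects, sc$effect_size, shape,
          model_name, config$base_seed, cell$failures,
          proc.time()[["elapsed"]] - t0
        ))
      }
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Read a long-format result table written by [run_grid()] or
#' [export_report()]
#'
#' @param path CSV path.
#' @return Result data frame with the standard columns.
#' @export
read_results <- function(path) {
  utils::read.csv(path, colClasses = c(
    scenario_id = "integer", timepoints = "integer", subjects = "integer",
    effect = "numeric", shape = "character", model = "character",
    coefficient = "character", metric = "character", value = "numeric",
    reps = "integer", failures = "integer", seed = "integer"
  ))
}
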