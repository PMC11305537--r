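#' Heatmap-ready grid for one result slice
#'
#' Projects a long-format result table onto a dense
#' subjects-by-timepoints matrix for one (shape, model, coefficient,
#' metric, effect size) slice, with both axes ascending. Grid cells absent
#' from the table are `NA` (flagged, never imputed).
#'
#' @param results Long-format result table from [run_grid()].
#' @param shape,model,coefficient,metric Slice keys.
#' @param effect_size Effect size of the slice.
#' @return Numeric matrix; rows named by subjects, columns by timepoints.
#' @export
heatmap_grid <- function(results, shape, model, coefficient, metric,
                         effect_size) {
  sub <- results[
    results$shape == shape & results$model == model &
      results$coefficient == coefficient & results$metric == metric &
      abs(results$effect - effect_size) < 1e-12, , drop = FALSE
  ]
  if (nrow(sub) == 0L) {
    stop("no results for slice shape=", shape, ", model=", model,
         ", coefficient=", coefficient, ", metric=", metric,
         ", effect=", effect_size, call. = FALSE)
  }
  ns <- sort(unique(sub$subjects))
  ts <- sort(unique(sub$timepoints))
  m <- matrix(NA_real_, length(ns), length(ts),
              dimnames = list(subjects = ns, timepoints = ts))
  for (i in seq_len(nrow(sub))) {
    m[as.character(sub$subjects[i]), as.character(sub$timepoints[i])] <-
      sub$value[i]
  }
  m
}

#' Minimum-requirement power frontiers
#'
#' For each (shape, model, coefficient, effect size) with power rows in the
#' table, finds the Pareto-minimal (subjects, timepoints) pairs whose
#' empirical power exceeds the adequacy threshold: no reported pair is
#' dominated by another adequate pair that is no larger on both axes.
#'
#' @param results Long-format result table.
#' @param threshold Adequacy threshold (default 0.80).
#' @param strict Use strict `power > threshold` (default, matching the
#'   "power above .80" reading); `FALSE` uses `>=`.
#' @return Data frame with columns `shape`, `model`, `coefficient`,
#'   `effect`, `n_subjects`, `n_timepoints`, `power`, `threshold`; zero
#'   rows when no cell is adequate.
#' @export
minimum_requirements <- function(results, threshold = 0.80, strict = TRUE) {
  pw <- results[results$metric == "power", , drop = FALSE]
  if (nrow(pw) == 0L) stop("no power rows in the result table", call. = FALSE)
  adequate <- if (strict) pw$value > threshold else pw$value >= threshold
  cand <- pw[adequate, , drop = FALSE]
  empty <- data.frame(
    shape = character(0), model = character(0), coefficient = character(0),
    effect = numeric(0), n_subjects = integer(0), n_timepoints = integer(0),
    power = numeric(0), threshold = numeric(0), stringsAsFactors = FALSE
  )
  if (nrow(cand) == 0L) return(empty)
  groups <- split(cand, list(cand$shape, cand$model, cand$coefficient,
                             cand$effect), drop = TRUE)
  out <- lapply(groups, function(g) {
    keep <- vapply(seq_len(nrow(g)), function(i) {
      dominated <- g$subjects <= g$subjects[i] &
        g$timepoints <= g$timepoints[i] &
        (g$subjects < g$subjects[i] | g$timepoints < g$timepoints[i])
      !any(dominated)
    }, logical(1))
    g <- g[keep, , drop = FALSE]
    data.frame(
      shape = g$shape, model = g$model, coefficient = g$coefficient,
      effect = g$effect, n_subjects = g$subjects,
      n_timepoints = g$timepoints, power = g$value, threshold = threshold,
      stringsAsFactors = FALSE
    )
  })
  out <- do.call(rbind, out)
  out <- out[order(out$shape, out$model, out$coefficient, out$effect,
                   out$n_subjects, out$n_timepoints), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Export a result table, frontiers and grids to a directory
#'
#' Writes `results.csv` (the long table), `frontier.csv` (the minimum
#' requirements at `threshold`), optionally `config.yaml` (an echo of the
#' run configuration) and, with `grids = TRUE`, one CSV grid per (shape,
#' model, coefficient, metric, effect) slice under `grids/`. Re-running
#' with identical inputs reproduces identical bytes.
#'
#' @param results Long-format result table.
#' @param out_dir Output directory (created if needed).
#' @param threshold Adequacy threshold for the frontier file.
#' @param config Optional configuration list to echo.
#' @param grids Also write per-slice CSV grids.
#' @return Character vector of written paths, invisibly.
#' @export
export_report <- function(results, out_dir, threshold = 0.80, config = NULL,
                          grids = FALSE) {
  if (!dir.exists(out_dir)) {
    ok <- dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    if (!ok) stop("cannot create output directory ", out_dir, call. = FALSE)
  }
  paths <- character(0)
  res_path <- file.path(out_dir, "results.csv")
  utils::write.csv(results, res_path, row.names = FALSE)
  paths <- c(paths, res_path)

  fr_path <- file.path(out_dir, "frontier.csv")
  fr <- if (any(results$metric == "power")) {
    minimum_requirements(results, threshold)
  } else {
    data.frame(
      shape = character(0), model = character(0), coefficient = character(0),
      effect = numeric(0), n_subjects = integer(0), n_timepoints = integer(0),
      power = numeric(0), threshold = numeric(0), stringsAsFactors = FALSE
    )
  }
  utils::write.csv(fr, fr_path, row.names = FALSE)
  paths <- c(paths, fr_path)

  if (!is.null(config)) {
    cfg_path <- file.path(out_dir, "config.yaml")
    write_grid_config(config, cfg_path)
    paths <- c(paths, cfg_path)
  }

  if (grids && nrow(results) > 0L) {
    gdir <- file.path(out_dir, "grids")
    dir.create(gdir, showWarnings = FALSE)
    keys <- unique(results[c("shape", "model", "coefficient", "metric",
                             "effect")])
    keys <- keys[order(keys$shape, keys$model, keys$coefficient, keys$metric,
                       keys$effect), , drop = FALSE]
    for (i in seq_len(nrow(keys))) {
      k <- keys[i, ]
      g <- heatmap_grid(results, k$shape, k$model, k$coefficient, k$metric,
                        k$effect)
      gp <- file.path(gdir, sprintf(
        "%s_%s_%s_%s_e%s.csv", k$shape, k$model, k$coefficient, k$metric,
        format(k$effect, trim = TRUE)
      ))
      utils::write.csv(
        data.frame(subjects = as.integer(rownames(g)), g,
                   check.names = FALSE),
        gp, row.names = FALSE
      )
      paths <- c(paths, gp)
    }
  }
  invisible(paths)
}
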