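test_that("performance metrics compute their defining formulas", {
  expect_equal(empirical_power(c(0.01, 0.2, 0.04, 0.8), 0.05), 0.5)
  expect_equal(empirical_power(c(0.06, 0.5, 1), 0.05), 0)
  # strict inequality at the boundary
  expect_equal(empirical_power(c(0.05, 0.049), 0.05), 0.5)
  expect_error(empirical_power(numeric(0)), "non-empty")
  expect_error(empirical_power(0.5, alpha = 1.2), "alpha")

  expect_equal(bias(c(-5.0, -4.9), -4.95), 0)
  expect_equal(bias(c(-5.0, -5.0), -4.95), 0.05)
  expect_error(bias(numeric(0), 0), "non-empty")

  expect_equal(precision(c(0.2, 0.2, 0.2)), 0.2)
  expect_error(precision(numeric(0)), "non-empty")
  expect_error(precision(c(0.1, -0.1)), "positive")
})

test_that("replication seeds are deterministic, distinct and 31-bit", {
  s1 <- derive_seed(1L, 3L, "step_slope", 10L)
  expect_identical(s1, derive_seed(1L, 3L, "step_slope", 10L))
  expect_true(s1 >= 0 && s1 < 2^31)
  many <- vapply(1:500, function(r) derive_seed(1L, 3L, "step_slope", r),
                 integer(1))
  expect_equal(length(unique(many)), 500L)
  expect_false(derive_seed(1L, 3L, "step_slope", 1L) ==
                 derive_seed(1L, 3L, "step_only", 1L))
  expect_false(derive_seed(1L, 3L, "step_slope", 1L) ==
                 derive_seed(2L, 3L, "step_slope", 1L))
})

test_that("run_cell is reproducible and matches the naive per-replication refit", {
  s <- scenario_spec(6L, 20L, 0.2, "step_slope")
  cell <- run_cell(s, "basic", reps = 25L, base_seed = 11L, scenario_id = 4L)
  cell2 <- run_cell(s, "basic", reps = 25L, base_seed = 11L, scenario_id = 4L)
  expect_identical(cell$stats, cell2$stats)
  # chunking is memory plumbing only
  cell3 <- run_cell(s, "basic", reps = 25L, base_seed = 11L, scenario_id = 4L,
                    chunk_size = 7L)
  expect_equal(cell$stats, cell3$stats)

  # naive path: regenerate each panel in isolation and refit with lm
  est <- se <- pv <- matrix(NA_real_, 4, 25)
  for (r in 1:25) {
    p <- generate_panel(s, seed = derive_seed(11L, 4L, "step_slope", r))
    X <- build_design(p, "basic")
    sm <- summary(lm(p$score ~ 0 + X))$coefficients
    est[, r] <- sm[, 1]; se[, r] <- sm[, 2]; pv[, r] <- sm[, 4]
  }
  truth <- true_term_values(true_coefficients(s))[cell$stats$term]
  expect_equal(cell$stats$power, apply(pv, 1, empirical_power, alpha = 0.05),
               tolerance = 1e-12)
  expect_equal(cell$stats$mean_estimate, rowMeans(est), tolerance = 1e-10)
  expect_equal(cell$stats$bias,
               vapply(1:4, function(i) bias(est[i, ], truth[[i]]), numeric(1)),
               tolerance = 1e-10)
  expect_equal(cell$stats$precision, rowMeans(se), tolerance = 1e-10)
})

test_that("coefficients absent from the generating process reject at the nominal rate", {
  reps <- 600L
  # step-only data, full basic model: the slope-change test is a null test
  c1 <- run_cell(scenario_spec(8L, 200L, 0.15, "step_only"), "basic",
                 reps = reps, base_seed = 21L)
  p_null <- c1$stats$power[c1$stats$term == "slope_change"]
  expect_lt(abs(p_null - 0.05), mc_band(0.05, reps))

  # slope-only data: the step test is a null test
  c2 <- run_cell(scenario_spec(8L, 200L, 0.15, "slope_only"), "basic",
                 reps = reps, base_seed = 22L)
  expect_lt(abs(c2$stats$power[c2$stats$term == "step"] - 0.05),
            mc_band(0.05, reps))

  # quadratic model on linear-trend data: the curvature test is a null test
  c3 <- run_cell(scenario_spec(8L, 200L, 0.15, "step_slope"), "quadratic",
                 reps = reps, base_seed = 23L)
  expect_lt(abs(c3$stats$power[c3$stats$term == "time_sq"] - 0.05),
            mc_band(0.05, reps))
})

test_that("power rises with sample size and with effect size", {
  pw <- function(n, e) {
    cell <- run_cell(scenario_spec(8L, n, e, "step_slope"), "basic",
                     reps = 300L, base_seed = 31L)
    cell$stats$power[cell$stats$term == "slope_change"]
  }
  slack <- 0.05
  by_n <- vapply(c(100L, 400L, 1600L), pw, numeric(1), e = 0.02)
  expect_true(all(diff(by_n) > -slack))
  expect_gt(by_n[3L], by_n[1L] + 0.15)
  # common random numbers across effect sizes: same seeds, same noise draws
  by_e <- vapply(c(0.01, 0.03, 0.08), function(e) pw(800L, e), numeric(1))
  expect_true(all(diff(by_e) > -slack))
  expect_gt(by_e[3L], by_e[1L] + 0.3)
})

test_that("mirrored effect signs give the same power", {
  run <- function(e) {
    run_cell(scenario_spec(6L, 100L, e, "step_slope"), "basic",
             reps = 400L, base_seed = 41L)$stats
  }
  pos <- run(0.05)
  neg <- run(-0.05)
  iv <- pos$term %in% c("step", "slope_change")
  # 3 SE for a difference of two proportions at 400 reps, worst case p = 0.5
  expect_true(all(abs(pos$power[iv] - neg$power[iv]) < 3 * sqrt(2 * 0.25 / 400)))
  # and the estimated shocks mirror around zero
  expect_true(all(abs(pos$mean_estimate[iv] + neg$mean_estimate[iv]) < 0.2))
})

test_that("ignoring a second intervention biases step and slope in the known directions", {
  # exact expectations from projecting the generative mean onto the model
  s <- function(T) scenario_spec(T, 300L, 0.3, "two_steps_slope")
  truth <- true_coefficients(s(8L))
  proj <- lapply(seq(6L, 20L, 2L), function(T) {
    projected_coefficients(s(T), "two_steps_slope", "basic")
  })
  names(proj) <- seq(6L, 20L, 2L)
  for (p in proj) {
    # signed overestimate of the (negative) step: smaller drop than generated
    expect_gt(p[["step"]], truth$beta_step)
    # signed underestimate of the slope change: steeper decline than generated
    expect_lt(p[["slope_change"]], truth$beta_slope_change)
  }
  step_bias <- vapply(proj, function(p) abs(p[["step"]] - truth$beta_step),
                      numeric(1))
  slope_bias <- vapply(proj,
                       function(p) abs(p[["slope_change"]] - truth$beta_slope_change),
                       numeric(1))
  # slope bias shrinks steadily with more occasions
  expect_true(all(diff(slope_bias) < 0))
  # step bias oscillates with the parity of the second boundary but falls overall
  expect_lt(step_bias[["20"]], step_bias[["8"]])
  for (T in c("10", "14", "18")) {
    lo <- as.character(as.integer(T) - 2L)
    hi <- as.character(as.integer(T) + 2L)
    expect_gt(step_bias[[T]], step_bias[[lo]])
    expect_gt(step_bias[[T]], step_bias[[hi]])
  }

  # the Monte Carlo cell reproduces the analytic expectation
  cell <- run_cell(s(8L), "basic", reps = 300L, base_seed = 51L)
  expect_equal(cell$stats$mean_estimate[cell$stats$term == "step"],
               proj[["8"]][["step"]], tolerance = 0.05)
})

test_that("an unnecessary quadratic term costs slope power and precision", {
  sc <- scenario_spec(8L, 200L, 0.02, "step_slope")
  cb <- run_cell(sc, "basic", reps = 400L, base_seed = 61L)
  cq <- run_cell(sc, "quadratic", reps = 400L, base_seed = 61L)
  slope_row <- function(cell) cell$stats[cell$stats$term == "slope_change", ]
  expect_gt(slope_row(cb)$power, slope_row(cq)$power + 0.05)
  expect_gt(slope_row(cq)$precision, slope_row(cb)$precision)
  # step power is essentially unaffected by the extra term
  step_row <- function(cell) cell$stats[cell$stats$term == "step", ]
  expect_lt(abs(step_row(cb)$power - step_row(cq)$power), 0.1)
})

test_that("precision scales with the noise standard deviation", {
  base <- list(n_timepoints = 8L, n_subjects = 150L, effect = 0.1)
  prec <- function(nv) {
    sc <- scenario_spec(base$n_timepoints, base$n_subjects, base$effect,
                        "step_slope", baseline_var = 0, noise_var = nv)
    cell <- run_cell(sc, "basic", reps = 200L, base_seed = 71L)
    cell$stats$precision[cell$stats$term == "step"]
  }
  expect_equal(prec(50) / prec(25), sqrt(2), tolerance = 0.05)
})

test_that("run_grid flattens cells consistently and supports resume", {
  cfg <- default_grid_config()
  cfg$timepoints <- c(6L, 8L)
  cfg$subjects <- 30L
  cfg$effects <- 0.2
  cfg$shapes <- "step_slope"
  cfg$reps <- 40L
  cfg$base_seed <- 5L

  out <- tempfile(fileext = ".csv")
  res <- run_grid(cfg, out_file = out, quiet = TRUE)
  # 2 scenarios x 2 pairings with shape step_slope (basic right fit, quadratic overfit)
  expect_equal(length(unique(paste(res$scenario_id, res$model))), 4L)
  expect_equal(sort(unique(res$metric)),
               sort(c("power", "bias", "precision", "mean_estimate",
                      "empirical_sd")))

  # the single-cell slice equals a direct run_cell
  cell <- run_cell(scenario_spec(6L, 30L, 0.2, "step_slope"), "basic",
                   reps = 40L, base_seed = 5L, scenario_id = 1L)
  slice <- res[res$scenario_id == 1L & res$model == "basic" &
                 res$metric == "power", ]
  expect_equal(slice$value[match(cell$stats$term, slice$coefficient)],
               cell$stats$power)

  # resuming from the finished file re-runs nothing and reproduces the table
  res2 <- run_grid(cfg, out_file = out, resume = TRUE, quiet = TRUE)
  expect_equal(res2[order(res2$scenario_id, res2$model, res2$metric,
                          res2$coefficient), ],
               res[order(res$scenario_id, res$model, res$metric,
                         res$coefficient), ],
               ignore_attr = TRUE)

  # the on-disk file round-trips
  disk <- read_results(out)
  expect_equal(nrow(disk), nrow(res))
  expect_equal(sum(disk$value), sum(res$value), tolerance = 1e-12)
})
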