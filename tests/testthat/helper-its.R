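# Brute-force OLS oracle: explicit normal-equations solve, independent of
# the package's QR engine.
ols_oracle <- function(X, y) {
  XtXi <- solve(crossprod(X))
  beta <- drop(XtXi %*% crossprod(X, y))
  dof <- nrow(X) - ncol(X)
  s2 <- sum((y - X %*% beta)^2) / dof
  se <- sqrt(s2 * diag(XtXi))
  tt <- beta / se
  list(estimate = beta, se = se, statistic = tt,
       p_value = 2 * pt(abs(tt), dof, lower.tail = FALSE),
       sigma2 = s2, dof = dof)
}

# Expected value of the fitted coefficients when `model` is fitted to data
# whose generative mean comes from `shape`: the projection of the mean
# function onto the model's column space. Exact, no Monte Carlo error.
projected_coefficients <- function(scenario, shape, model) {
  sch <- intervention_schedule(scenario$n_timepoints, shape)
  tp <- true_coefficients(scenario, shape)
  mu <- mean_function(sch$centered_times, sch$x1, sch$x2, tp)
  X <- build_design(sch, model)
  drop(solve(crossprod(X), crossprod(X, mu)))
}

# One small random design/response instance for property tests.
random_ols_instance <- function() {
  T <- sample(c(6L, 8L, 10L), 1L)
  shape <- sample(its_shapes(), 1L)
  models <- c("basic", "quadratic")
  if (shape == "two_steps_slope") {
    models <- c(models, "two_intervention_steps")
    # a separate second slope needs at least two occasions after the
    # second boundary, i.e. T >= 8 under the 75% placement rule
    if (T >= 8L) models <- c(models, "combined", "two_intervention_full")
  }
  model <- sample(models, 1L)
  npo <- sample(2:4, 1L)
  sch <- intervention_schedule(T, shape)
  X <- build_design(sch, model, n_per_occasion = npo)
  list(X = X, y = rnorm(nrow(X), mean = 100, sd = 5))
}

# Monte Carlo tolerance for a binomial proportion.
mc_band <- function(p, reps, k = 3) k * sqrt(p * (1 - p) / reps)
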