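# Term definitions shared by all model variants. Column values are pure
# functions of the centered time axis and the intervention indicators.
.its_all_terms <- c("intercept", "time", "step", "slope_change",
                    "step2", "slope_change2", "time_sq")

.its_model_terms <- list(
  # level + trend + step + slope change at the first intervention
  basic = c("intercept", "time", "step", "slope_change"),
  # adds a second step dummy; the post-intervention slope term is shared
  # across both segments (too few occasions to separate a second slope)
  two_intervention_steps = c("intercept", "time", "step", "step2",
                             "slope_change"),
  # adds a quadratic trend to the basic model
  quadratic = c("intercept", "time", "step", "slope_change", "time_sq"),
  # second intervention with its own step and slope change
  two_intervention_full = c("intercept", "time", "step", "slope_change",
                            "step2", "slope_change2"),
  # everything: two interventions plus quadratic trend
  combined = c("intercept", "time", "step", "slope_change",
               "step2", "slope_change2", "time_sq")
)

#' Segmented-regression model specification
#'
#' The available variants, by name:
#' \describe{
#'   \item{basic}{`Y = b0 + b1 T + b2 X1 + b3 T X1`: the classical ITS
#'     model with one step change and one slope change.}
#'   \item{two_intervention_steps}{`Y = b0 + b1 T + b2 X1 + b3 X2 + b4 T X1`:
#'     a separate step for a second intervention, with a single shared
#'     post-intervention slope change.}
#'   \item{quadratic}{basic plus a `T^2` trend term.}
#'   \item{two_intervention_full}{two interventions, each with its own step
#'     and slope change.}
#'   \item{combined}{two full interventions plus the quadratic trend.}
#' }
#' Term names used throughout: `intercept`, `time` (centered time T),
#' `step` (first post-intervention indicator X1), `slope_change` (T x X1),
#' `step2` (second-intervention indicator X2, coded additively so its
#' coefficient is the *incremental* second step), `slope_change2` (T x X2),
#' `time_sq` (T squared).
#'
#' @param name One of the variant names above.
#' @return An object of class `its_model`: list with `name` and `terms`.
#' @examples
#' model_spec("basic")$terms
#' @export
model_spec <- function(name) {
  name <- match.arg(name, names(.its_model_terms))
  structure(list(name = name, terms = .its_model_terms[[name]]),
            class = "its_model")
}

#' @export
print.its_model <- function(x, ...) {
  cat(sprintf("ITS model '%s': %s\n", x$name, paste(x$terms, collapse = " + ")))
  invisible(x)
}

#' Catalogue of model variants
#'
#' All five distinct segmented-regression specifications, in stable order.
#'
#' @return Named list of `its_model` objects.
#' @export
model_catalog <- function() {
  out <- lapply(names(.its_model_terms), model_spec)
  names(out) <- names(.its_model_terms)
  out
}

#' Build the design matrix for a model on a panel or schedule
#'
#' Columns appear in the model's term order and are computed elementwise
#' from the centered time axis and the intervention indicators. Models with
#' second-intervention terms require a schedule that actually defines a
#' second intervention boundary.
#'
#' @param x An `its_panel` (one row per record) or an `its_schedule`
#'   (one row per occasion, replicated `n_per_occasion` times).
#' @param model An `its_model` or a variant name.
#' @param n_per_occasion For a schedule input, how many records per
#'   occasion (rows are replicated subject-major to match
#'   [generate_panel()] record order).
#' @return Numeric matrix with one column per model term.
#' @examples
#' build_design(intervention_schedule(6, "step_slope"), "basic")
#' @export
build_design <- function(x, model, n_per_occasion = 1L) {
  if (is.character(model)) model <- model_spec(model)
  stopifnot(inherits(model, "its_model"))
  if (inherits(x, "its_panel")) {
    sched <- attr(x, "schedule")
    occ <- x$occasion
    ct <- sched$centered_times[occ]
    x1 <- sched$x1[occ]
    x2 <- sched$x2[occ]
    has_second <- !is.na(sched$second_boundary_index)
  } else if (inherits(x, "its_schedule")) {
    idx <- rep(seq_along(x$raw_times), times = n_per_occasion)
    ct <- x$centered_times[idx]
    x1 <- x$x1[idx]
    x2 <- x$x2[idx]
    has_second <- !is.na(x$second_boundary_index)
  } else {
    stop("`x` must be an its_panel or its_schedule", call. = FALSE)
  }
  needs_second <- any(c("step2", "slope_change2") %in% model$terms)
  if (needs_second && !has_second) {
    stop("model '", model$name, "' includes second-intervention terms but ",
         "the schedule defines no second intervention boundary", call. = FALSE)
  }
  cols <- list(
    intercept = rep(1, length(ct)),
    time = ct,
    step = x1,
    slope_change = ct * x1,
    step2 = x2,
    slope_change2 = ct * x2,
    time_sq = ct^2
  )
  X <- do.call(cbind, cols[model$terms])
  colnames(X) <- model$terms
  X
}

# Shared OLS engine: QR factorisation computed once, applied to a response
# matrix (columns = replications). Classical homoskedastic standard errors
# from the unpivoted diagonal of (X'X)^{-1}.
ols_batch <- function(X, Y) {
  Y <- as.matrix(Y)
  p <- ncol(X)
  n <- nrow(X)
  if (nrow(Y) != n) stop("response length does not match design rows", call. = FALSE)
  dof <- n - p
  if (dof <= 0) {
    stop("non-positive residual degrees of freedom (", n, " rows, ",
         p, " terms)", call. = FALSE)
  }
  qrx <- qr(X)
  if (qrx$rank < p) {
    bad <- colnames(X)[qrx$pivot[(qrx$rank + 1L):p]]
    stop("singular design matrix; collinear terms: ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  B <- qr.coef(qrx, Y)
  res <- Y - X %*% B
  rss <- colSums(res^2)
  sigma2 <- rss / dof
  inv <- chol2inv(qr.R(qrx))
  d <- numeric(p)
  d[qrx$pivot] <- diag(inv) # undo column pivoting
  se <- sqrt(outer(d, sigma2))
  tstat <- B / se
  pval <- 2 * stats::pt(abs(tstat), dof, lower.tail = FALSE)
  list(estimates = B, se = se, statistic = tstat, p_value = pval,
       sigma2 = sigma2, dof = dof)
}

#' Ordinary least squares fit with coefficient inference
#'
#' Fits the design by QR-based least squares with classical homoskedastic
#' standard errors and two-sided p-values from the t distribution on
#' `N - p` degrees of freedom. When both `step` and `step2` are present the
#' total level change since the second intervention (`step + step2`) is
#' reported as a derived contrast.
#'
#' @param design Design matrix from [build_design()].
#' @param responses Numeric response vector, one per design row.
#' @return An `its_fit`: list with `coefficients` (data frame `term`,
#'   `estimate`, `se`, `statistic`, `p_value`), `residual_variance`, `dof`,
#'   `n_obs` and (when defined) `second_step_total`.
#' @examples
#' sched <- intervention_schedule(6, "step_slope")
#' X <- build_design(sched, "basic")
#' fit_ols(X, 170 + 16.5 * sched$centered_times + rnorm(6))
#' @export
fit_ols <- function(design, responses) {
  responses <- as.numeric(responses)
  if (anyNA(responses) || anyNA(design)) {
    stop("design and responses must be free of missing values", call. = FALSE)
  }
  b <- ols_batch(design, matrix(responses, ncol = 1L))
  coefs <- data.frame(
    term = colnames(design),
    estimate = as.numeric(b$estimates),
    se = as.numeric(b$se),
    statistic = as.numeric(b$statistic),
    p_value = as.numeric(b$p_value),
    stringsAsFactors = FALSE
  )
  out <- list(
    coefficients = coefs,
    residual_variance = b$sigma2[[1L]],
    dof = b$dof,
    n_obs = nrow(design)
  )
  if (all(c("step", "step2") %in% coefs$term)) {
    out$second_step_total <- sum(coefs$estimate[coefs$term %in% c("step", "step2")])
  }
  class(out) <- "its_fit"
  out
}

#' @export
print.its_fit <- function(x, ...) {
  cat(sprintf("ITS OLS fit: %d observations, %d residual df, sigma^2 = %.4g\n",
              x$n_obs, x$dof, x$residual_variance))
  print(x$coefficients, row.names = FALSE, digits = 4)
  if (!is.null(x$second_step_total)) {
    cat(sprintf("Total level change since second intervention: %.4g\n",
                x$second_step_total))
  }
  invisible(x)
}

#' Serialise a fit to JSON
#'
#' @param fit An `its_fit`.
#' @param path Optional output file; when `NULL` the JSON string is returned.
#' @return JSON string (invisibly when written to file).
#' @export
fit_to_json <- function(fit, path = NULL) {
  stopifnot(inherits(fit, "its_fit"))
  obj <- list(
    coefficients = fit$coefficients,
    residual_variance = fit$residual_variance,
    dof = fit$dof,
    n_obs = fit$n_obs
  )
  if (!is.null(fit$second_step_total)) {
    obj$second_step_total <- fit$second_step_total
  }
  js <- jsonlite::toJSON(obj, dataframe = "rows", auto_unbox = TRUE,
                         digits = NA)
  if (is.null(path)) return(js)
  writeLines(js, path)
  invisible(js)
}
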