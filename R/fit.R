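# Sum-of-squared-residuals objective on the normalized-volume fitting scale.
# Non-finite predictions (closed-form overflow, ODE failure) are a rejection
# signal: the candidate gets a huge finite cost instead of crashing the
# optimizer.
.ssr_objective <- function(model, series, v0) {
  times <- series$times
  obs <- series$volumes_norm
  function(par) {
    pred <- evaluate_volume(model, par, v0, times)
    if (any(!is.finite(pred))) return(1e10)
    sum((obs - pred)^2)
  }
}

.series_v0 <- function(series) max(series$volumes_norm[1], 1e-9)

# Data-derived candidate starting points, in the spirit of self-starting
# nonlinear growth models: an effective exponential rate from the series
# endpoints, and plateau guesses anchored at the last observation. They are
# injected into the differential-evolution population (and polished as
# fallback starts), which keeps narrow basins -- e.g. a logistic decaying to
# a tiny carrying capacity -- represented from generation zero.
.heuristic_starts <- function(model, series, v0) {
  vend <- max(series$volumes_norm[series$n_points], 1e-9)
  tend <- max(series$times[series$n_points], 1)
  r_hat <- log(vend / v0) / tend
  g0 <- max(abs(r_hat), 1e-3)
  starts <- switch(model$name,
    exponential = list(c(r = r_hat)),
    logistic = list(c(gamma = 2 * g0, K = vend),
                    c(gamma = r_hat, K = 1)),
    gompertz = list(c(gamma = 1e-3, delta = r_hat),        # exponential-like
                    c(gamma = 2 * g0, delta = 2 * g0 * log(vend))),
    general_gompertz = list(
      c(gamma = 1e-3, delta = r_hat, lambda = 1),
      c(gamma = 2 * g0, delta = 2 * g0 * log(vend), lambda = 1)),
    classic_bertalanffy = list(
      c(alpha = 2 * g0 * vend^(1 / 3), beta = 2 * g0),
      c(alpha = max(r_hat, 0) / max(v0, 1e-3)^(1 / 3), beta = max(-r_hat, 0))),
    general_bertalanffy = list(
      c(alpha = max(r_hat, 0) + 0.01, beta = 0.01 - min(r_hat, 0),
        lambda = 1 - 1e-3),                                 # exponential limit
      c(alpha = 2 * g0 * vend^(1 / 3), beta = 2 * g0, lambda = 2 / 3)))
  mat <- do.call(rbind, starts)
  # clamp into the feasible box
  pmin(pmax(mat, rep(model$lower, each = nrow(mat))),
       rep(model$upper, each = nrow(mat)))
}

#' Global parameter search by differential evolution
#'
#' Seeds the local least-squares refinement with a population-based global
#' search over the model's parameter box, minimizing the sum of squared
#' residuals. The strategy is best/1/bin with population size `15 * k`,
#' crossover probability 0.7, mutation factor dithered uniformly in
#' [0.5, 1) per generation, at most `max_gen` generations, stopping early
#' when the population's cost spread falls below `tol` times the mean cost.
#'
#' @param model A `growth_model` or model name.
#' @param series A normalized `patient_series` with at least 2 points.
#' @param seed Integer seed; the search is reproducible given the seed.
#' @param lower,upper Optional bound overrides (named or in registry order).
#' @param max_gen Maximum generations (default 200).
#' @param tol Relative early-stopping tolerance (default 0.01).
#' @return Named numeric vector of parameters inside the bounds.
#' @export
global_initialize <- function(model, series, seed = NULL,
                              lower = NULL, upper = NULL,
                              max_gen = 200L, tol = 0.01) {
  if (is.character(model)) model <- growth_model(model)
  stopifnot(inherits(series, "patient_series"), series$n_points >= 2L)
  if (is.null(series$volumes_norm)) {
    stop("series is not normalized; run normalize_cohort() first",
         call. = FALSE)
  }
  if (!is.null(seed)) set.seed(seed)
  lo <- if (is.null(lower)) model$lower else lower
  hi <- if (is.null(upper)) model$upper else upper
  d <- model$k
  np <- 15L * d
  f <- .ssr_objective(model, series, .series_v0(series))

  pop <- matrix(stats::runif(np * d, rep(lo, each = np), rep(hi, each = np)),
                nrow = np, ncol = d)
  seeds <- .heuristic_starts(model, series, .series_v0(series))
  pop[seq_len(min(nrow(seeds), np)), ] <- seeds[seq_len(min(nrow(seeds), np)), ]
  cost <- apply(pop, 1, f)
  if (all(cost >= 1e10)) {
    stop("objective non-finite over the entire initial population",
         call. = FALSE)
  }
  for (gen in seq_len(max_gen)) {
    fmut <- stats::runif(1, 0.5, 1.0)
    best <- pop[which.min(cost), ]
    for (i in seq_len(np)) {
      idx <- sample(seq_len(np)[-i], 2L)
      trial <- best + fmut * (pop[idx[1], ] - pop[idx[2], ])
      cross <- stats::runif(d) < 0.7
      cross[sample.int(d, 1L)] <- TRUE
      trial <- ifelse(cross, trial, pop[i, ])
      trial <- pmin(pmax(trial, lo), hi)
      ct <- f(trial)
      if (ct <= cost[i]) {
        pop[i, ] <- trial
        cost[i] <- ct
      }
    }
    if (stats::sd(cost) <= tol * abs(mean(cost)) + 1e-12) break
  }
  out <- pop[which.min(cost), ]
  names(out) <- model$parameter_names
  out
}

#' Refine a parameter estimate by bounded nonlinear least squares
#'
#' Polishes a (typically differential-evolution) starting point with
#' box-constrained Levenberg–Marquardt least squares (minpack.lm), capped at
#' 1000 iterations. If the refined point is worse than the start (which can
#' happen when the optimizer stalls on a rejection plateau), the start is
#' kept.
#'
#' @inheritParams global_initialize
#' @param init Starting parameter vector inside the bounds.
#' @return A `growth_fit`: model name, estimated parameters, fixed `v0`,
#'   per-point predictions, goodness metrics (`mae`, `rmse`, `r_squared`,
#'   `aic`), `converged` flag, `n_obs`, `k`, and `ssr`.
#' @export
refine_fit <- function(model, series, init, lower = NULL, upper = NULL) {
  if (is.character(model)) model <- growth_model(model)
  stopifnot(inherits(series, "patient_series"))
  lo <- if (is.null(lower)) model$lower else lower
  hi <- if (is.null(upper)) model$upper else upper
  v0 <- .series_v0(series)
  obs <- series$volumes_norm
  times <- series$times
  resid_fn <- function(par) {
    pred <- evaluate_volume(model, par, v0, times)
    r <- obs - pred
    r[!is.finite(r)] <- 1e5
    r
  }
  init <- pmin(pmax(init, lo), hi)
  res <- try(suppressWarnings(minpack.lm::nls.lm(
    par = init, lower = unname(lo), upper = unname(hi), fn = resid_fn,
    control = minpack.lm::nls.lm.control(maxiter = 1000, maxfev = 10000,
                                         ftol = 1e-15, ptol = 1e-15)
  )), silent = TRUE)
  f <- .ssr_objective(model, series, v0)
  if (inherits(res, "try-error")) {
    par <- init
    converged <- FALSE
  } else {
    par <- stats::coef(res)
    converged <- res$info %in% 1:4
    if (f(par) > f(init)) {  # keep the better of start and refinement
      par <- init
      converged <- FALSE
    }
  }
  names(par) <- model$parameter_names
  pred <- evaluate_volume(model, par, v0, times)
  metrics <- goodness_metrics(obs, pred, model$k)
  structure(list(
    patient_id = series$patient_id,
    model = model$name,
    par = par,
    v0 = v0,
    predicted = pred,
    metrics = metrics,
    converged = converged && all(is.finite(pred)),
    n_obs = length(obs),
    k = model$k,
    ssr = if (all(is.finite(pred))) sum((obs - pred)^2) else Inf
  ), class = "growth_fit")
}

#' @export
print.growth_fit <- function(x, ...) {
  cat(sprintf("<growth_fit> %s on %s (n = %d, k = %d, %s)\n",
              x$model, x$patient_id, x$n_obs, x$k,
              if (x$converged) "converged" else "not converged"))
  cat("  par:", paste(sprintf("%s = %.5g", names(x$par), x$par),
                      collapse = ", "), "\n")
  cat(sprintf("  MAE %.4g | RMSE %.4g | R^2 %.4g | AIC %.4g\n",
              x$metrics$mae, x$metrics$rmse, x$metrics$r_squared,
              x$metrics$aic))
  invisible(x)
}

#' Fit one growth model to one patient series
#'
#' Runs the full two-stage estimation: differential-evolution global search
#' followed by bounded least-squares refinement. V0 is fixed to the first
#' observed normalized volume and times are measured from the first visit.
#'
#' @inheritParams global_initialize
#' @return A `growth_fit` (see [refine_fit()]).
#' @export
fit_patient <- function(model, series, seed = NULL,
                        lower = NULL, upper = NULL, ...) {
  if (is.character(model)) model <- growth_model(model)
  init <- global_initialize(model, series, seed = seed,
                            lower = lower, upper = upper, ...)
  fit <- refine_fit(model, series, init, lower = lower, upper = upper)
  # If refinement from the global-search point is not essentially exact,
  # also polish the self-start candidates and keep the best result; this
  # guards against the global search collapsing onto a flat cost plateau.
  if (fit$ssr > 1e-12 * max(fit$n_obs, 1)) {
    alt_starts <- .heuristic_starts(model, series, .series_v0(series))
    for (r in seq_len(nrow(alt_starts))) {
      alt <- refine_fit(model, series, alt_starts[r, ],
                        lower = lower, upper = upper)
      if (alt$ssr < fit$ssr) fit <- alt
    }
  }
  fit
}

#' Goodness-of-fit metrics for one fitted series
#'
#' Computes, on the fitting scale:
#' MAE = sum(|y - yhat|)/n; RMSE = sqrt(sum((y - yhat)^2)/n);
#' R^2 = 1 - RSS/TSS (NA when the observations are constant);
#' AIC = n log(RSS/n) + 2k, the least-squares form of 2k - 2 log(L) under
#' iid Gaussian residuals with profiled variance and additive constants
#' dropped (they cancel in any comparison between models on the same
#' series). A perfect fit (RSS = 0) yields AIC = -Inf, reported as perfect.
#'
#' @param observed,predicted Equal-length numeric vectors (n >= 1).
#' @param k Number of free model parameters.
#' @return A list `mae`, `rmse`, `r_squared`, `aic`.
#' @examples
#' goodness_metrics(c(1, 2, 3), c(1, 2, 4), k = 1)
#' @export
goodness_metrics <- function(observed, predicted, k) {
  n <- length(observed)
  if (n == 0L) stop("no observations", call. = FALSE)
  if (length(predicted) != n) stop("length mismatch", call. = FALSE)
  e <- observed - predicted
  rss <- sum(e^2)
  tss <- sum((observed - mean(observed))^2)
  list(
    mae = sum(abs(e)) / n,
    rmse = sqrt(rss / n),
    r_squared = if (tss > 0) 1 - rss / tss else NA_real_,
    aic = if (rss > 0) n * log(rss / n) + 2 * k else -Inf
  )
}
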