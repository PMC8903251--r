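#' Classical tumor growth models
#'
#' The package works with six classical growth laws for tumor volume V(t),
#' all expressed on the normalized (dimensionless) volume scale with time in
#' days. The initial volume V0 is always fixed to the first observed volume
#' and is never a free parameter, so the free-parameter counts are:
#' exponential 1, logistic 2, Gompertz 2, general Gompertz 3, classic von
#' Bertalanffy 2, general von Bertalanffy 3.
#'
#' * exponential: dV/dt = r V, with r the effective net growth rate
#'   (birth minus death rate collapsed into one parameter).
#' * logistic: dV/dt = gamma V (1 - V/K), K the carrying capacity.
#' * gompertz: dV/dt = V (delta - gamma ln V).
#' * general_gompertz: dV/dt = V^lambda (delta - gamma ln V); no closed-form
#'   solution, evaluated by adaptive numeric integration.
#' * classic_bertalanffy: dV/dt = alpha V^(2/3) - beta V.
#' * general_bertalanffy: dV/dt = alpha V^lambda - beta V.
#'
#' @param name Model name, one of `growth_model_names()`.
#' @return `growth_model()` returns an object of class `"growth_model"`:
#'   a list with elements `name`, `parameter_names`, `k` (number of free
#'   parameters), `lower`/`upper` (per-parameter finite bounds), and
#'   `has_closed_form`.
#' @examples
#' m <- growth_model("gompertz")
#' evaluate_volume(m, c(gamma = 0.02, delta = -0.01), v0 = 0.3,
#'                 times = c(0, 50, 100))
#' @export
growth_model <- function(name) {
  name <- match.arg(name, growth_model_names())
  spec <- .model_registry[[name]]
  structure(spec, class = "growth_model")
}

#' @rdname growth_model
#' @export
growth_model_names <- function() {
  c("exponential", "logistic", "gompertz", "general_gompertz",
    "classic_bertalanffy", "general_bertalanffy")
}

# Volume floor applied before any logarithm: lesions classified CR reach
# diameter 0, and the Gompertz family needs log(V) to exist.
.V_FLOOR <- 1e-9

# Rate bounds on the normalized-volume / day scale. Tumors double over weeks
# to months, so |rate| <= 0.5/day is generous; alpha and beta are labelled
# birth/death rates and kept non-negative. Bounds can be overridden per fit.
.model_registry <- list(
  exponential = list(
    name = "exponential",
    parameter_names = "r",
    k = 1L,
    lower = c(r = -0.5),
    upper = c(r = 0.5),
    has_closed_form = TRUE
  ),
  logistic = list(
    name = "logistic",
    parameter_names = c("gamma", "K"),
    k = 2L,
    lower = c(gamma = -0.5, K = 1e-6),
    upper = c(gamma = 0.5, K = 2),
    has_closed_form = TRUE
  ),
  gompertz = list(
    name = "gompertz",
    parameter_names = c("gamma", "delta"),
    k = 2L,
    lower = c(gamma = -0.5, delta = -0.5),
    upper = c(gamma = 0.5, delta = 0.5),
    has_closed_form = TRUE
  ),
  general_gompertz = list(
    name = "general_gompertz",
    parameter_names = c("gamma", "delta", "lambda"),
    k = 3L,
    lower = c(gamma = -0.5, delta = -0.5, lambda = 0),
    upper = c(gamma = 0.5, delta = 0.5, lambda = 1.5),
    has_closed_form = FALSE
  ),
  classic_bertalanffy = list(
    name = "classic_bertalanffy",
    parameter_names = c("alpha", "beta"),
    k = 2L,
    lower = c(alpha = 0, beta = 0),
    upper = c(alpha = 0.5, beta = 0.5),
    has_closed_form = TRUE
  ),
  general_bertalanffy = list(
    name = "general_bertalanffy",
    parameter_names = c("alpha", "beta", "lambda"),
    k = 3L,
    lower = c(alpha = 0, beta = 0, lambda = 0),
    upper = c(alpha = 0.5, beta = 0.5, lambda = 1.5),
    has_closed_form = TRUE
  )
)

#' @export
print.growth_model <- function(x, ...) {
  cat("<growth_model>", x$name, "\n")
  cat("  parameters:", paste(x$parameter_names, collapse = ", "),
      sprintf("(k = %d, V0 fixed)\n", x$k))
  cat("  bounds:",
      paste(sprintf("%s in [%g, %g]", x$parameter_names, x$lower, x$upper),
            collapse = "; "), "\n")
  cat("  closed form:", if (x$has_closed_form) "yes" else "no (numeric ODE)", "\n")
  invisible(x)
}

.check_params <- function(model, par) {
  if (length(par) != model$k) {
    stop(sprintf("model '%s' expects %d parameter(s): %s", model$name, model$k,
                 paste(model$parameter_names, collapse = ", ")), call. = FALSE)
  }
  if (is.null(names(par)) || !all(names(par) == model$parameter_names)) {
    # accept positional parameters in registry order
    names(par) <- model$parameter_names
  }
  par
}

#' Evaluate tumor volume over time under a growth model
#'
#' Evaluates V(t) for the given model, parameters, and fixed initial volume
#' `v0` (the first observed normalized volume; times are measured from that
#' first observation, so `evaluate_volume(..., times = 0)` returns `v0`).
#' Closed forms are used where they exist; the general Gompertz model is
#' integrated numerically (lsoda, rtol 1e-8, atol 1e-10).
#'
#' Parameter regimes that overflow the closed form (e.g. a large positive
#' rate at large t) yield non-finite volumes; these are not an error here but
#' are treated as a rejection signal by the fitting routines.
#'
#' @param model A `growth_model` or a model name.
#' @param par Numeric vector of parameters in registry order (may be named).
#' @param v0 Initial normalized volume, > 0 (volumes below 1e-9 are floored
#'   so that logarithms stay defined).
#' @param times Ascending, non-negative day offsets.
#' @return Numeric vector of volumes, one per time.
#' @export
evaluate_volume <- function(model, par, v0, times) {
  if (is.character(model)) model <- growth_model(model)
  par <- .check_params(model, par)
  stopifnot(length(v0) == 1L, is.finite(v0), v0 >= 0)
  if (length(times) == 0L) return(numeric(0))
  if (is.unsorted(times)) stop("times must be sorted ascending", call. = FALSE)
  if (times[1] < 0) stop("times must be non-negative", call. = FALSE)
  v0 <- max(v0, .V_FLOOR)

  switch(model$name,
    exponential = v0 * exp(par[["r"]] * times),
    logistic = {
      # K / (1 + ((K - v0)/v0) e^(-gamma t)): overflow-safe for gamma t >> 0
      g <- par[["gamma"]]; K <- par[["K"]]
      pmax(K / (1 + ((K - v0) / v0) * exp(-g * times)), .V_FLOOR)
    },
    gompertz = .gompertz_closed(par[["gamma"]], par[["delta"]], v0, times),
    general_gompertz = .integrate_rhs(model, par, v0, times),
    classic_bertalanffy = {
      a <- par[["alpha"]]; b <- par[["beta"]]
      .bertalanffy_closed(a, b, lambda = 2 / 3, v0, times)
    },
    general_bertalanffy = {
      a <- par[["alpha"]]; b <- par[["beta"]]; lam <- par[["lambda"]]
      if (abs(1 - lam) < 1e-6) {
        # 1/(1-lambda) singularity: exponential limit with net rate alpha-beta
        v0 * exp((a - b) * times)
      } else {
        .bertalanffy_closed(a, b, lam, v0, times)
      }
    },
    stop("unknown model")
  )
}

# ln V(t) = delta/gamma + (ln v0 - delta/gamma) exp(-gamma t); gamma -> 0
# degenerates to ln V = ln v0 + delta t.
.gompertz_closed <- function(gamma, delta, v0, times) {
  lv0 <- log(v0)
  if (abs(gamma) < 1e-12) return(exp(lv0 + delta * times))
  a <- delta / gamma
  exp(a + (lv0 - a) * exp(-gamma * times))
}

# V(t) = (alpha/beta + (v0^(1-lambda) - alpha/beta) exp(-beta (1-lambda) t))^(1/(1-lambda))
# beta -> 0 degenerates to v0^(1-lambda) + alpha (1-lambda) t inside the root.
# A shrinking lesion can drive the bracket through zero (volume hits 0);
# the bracket is floored so fractional powers stay real.
.bertalanffy_closed <- function(alpha, beta, lambda, v0, times) {
  p <- 1 - lambda
  base <- if (beta < 1e-12) {
    v0^p + alpha * p * times
  } else {
    ab <- alpha / beta
    ab + (v0^p - ab) * exp(-beta * p * times)
  }
  base <- pmax(base, .V_FLOOR^abs(p))
  base^(1 / p)
}

.integrate_rhs <- function(model, par, v0, times, rtol = 1e-8, atol = 1e-10) {
  if (all(times == 0)) return(rep(v0, length(times)))
  grid <- times
  prepend <- grid[1] > 0
  if (prepend) grid <- c(0, grid)
  sol <- try(suppressWarnings(deSolve::ode(
    y = c(V = v0), times = grid,
    func = "tg_ggompertz_rhs", dllname = "tumorgrowth",
    initfunc = "tg_ggompertz_init",
    parms = c(par[["gamma"]], par[["delta"]], par[["lambda"]]),
    method = "lsoda", rtol = rtol, atol = atol
  )), silent = TRUE)
  if (inherits(sol, "try-error") || nrow(sol) < length(grid)) {
    return(rep(NaN, length(times)))
  }
  out <- sol[, "V"]
  if (prepend) out <- out[-1]
  unname(out)
}

#' Instantaneous growth rate dV/dt
#'
#' The right-hand side of the model's differential equation at volume `v`.
#'
#' @inheritParams evaluate_volume
#' @param v Current volume, > 0.
#' @return dV/dt at volume `v` (vectorized over `v`).
#' @export
growth_rhs <- function(model, par, v) {
  if (is.character(model)) model <- growth_model(model)
  par <- .check_params(model, par)
  if (any(v <= 0)) stop("volume must be positive", call. = FALSE)
  switch(model$name,
    exponential = par[["r"]] * v,
    logistic = par[["gamma"]] * v * (1 - v / par[["K"]]),
    gompertz = v * (par[["delta"]] - par[["gamma"]] * log(v)),
    general_gompertz = v^par[["lambda"]] *
      (par[["delta"]] - par[["gamma"]] * log(v)),
    classic_bertalanffy = par[["alpha"]] * v^(2 / 3) - par[["beta"]] * v,
    general_bertalanffy = par[["alpha"]] * v^par[["lambda"]] - par[["beta"]] * v,
    stop("unknown model")
  )
}
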