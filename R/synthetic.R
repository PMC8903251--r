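#' Configuration of the synthetic cohort generator
#'
#' Builds a validated configuration for [simulate_cohort()]. The defaults
#' emulate the visit structure reported for the clinical target-lesion data
#' the pipeline is designed for: inter-visit intervals normal with mean
#' 50.62 days and sd 6.2 (truncated positive), points per patient with mean
#' 3.63 and sd 3.22 on support 1..15 (a shifted negative binomial,
#' moment-matched after truncation, standing in for heterogeneous early
#' dropout), three trajectory types (up / down / fluctuate), lesion dynamics
#' drawn from the six growth models, and multiplicative lognormal
#' measurement noise on the diameter scale (5% default — radiologists
#' measure diameters, so that is where the error lives).
#'
#' Fluctuating patients are generated as two-phase piecewise trajectories
#' (decline then regrowth or the reverse, continuous at the breakpoint),
#' because no single model in the family can produce a U-shape.
#'
#' @param n_patients Number of patients.
#' @param study_id Study label stamped on every record.
#' @param arms Treatment-arm labels, assigned uniformly.
#' @param p_up,p_down,p_fluctuate Trajectory-type mixture (must sum to 1).
#' @param models Generating-model pool (default: all six).
#' @param interval_mean,interval_sd Inter-visit interval distribution, days.
#' @param points_mean,points_sd,points_min,points_max Points-per-patient
#'   distribution (moment targets after truncation to
#'   `[points_min, points_max]`).
#' @param noise_sigma Lognormal sigma of the diameter measurement noise
#'   (0 = noise-free).
#' @param baseline_ld_range Baseline longest-diameter range, mm.
#' @param v_ref Reference volume (mm^3) defining the generator's relative
#'   volume scale; default the volume of a 100 mm lesion.
#' @param seed Master seed for [simulate_cohort()].
#' @return A list of class `"synthetic_config"`.
#' @export
synthetic_config <- function(n_patients = 100L,
                             study_id = "SYN01",
                             arms = c("arm_A", "arm_B"),
                             p_up = 0.40, p_down = 0.25, p_fluctuate = 0.35,
                             models = growth_model_names(),
                             interval_mean = 50.62, interval_sd = 6.2,
                             points_mean = 3.63, points_sd = 3.22,
                             points_min = 1L, points_max = 15L,
                             noise_sigma = 0.05,
                             baseline_ld_range = c(10, 80),
                             v_ref = 0.5 * 100^3,
                             seed = NULL) {
  stopifnot(n_patients >= 1, interval_mean > 0, interval_sd >= 0,
            points_min >= 1, points_max >= points_min,
            noise_sigma >= 0, v_ref > 0,
            length(baseline_ld_range) == 2, baseline_ld_range[1] > 0)
  p <- c(p_up, p_down, p_fluctuate)
  if (any(p < 0) || abs(sum(p) - 1) > 1e-8) {
    stop("trajectory mixture probabilities must be non-negative and sum to 1",
         call. = FALSE)
  }
  models <- match.arg(models, growth_model_names(), several.ok = TRUE)
  cfg <- list(
    n_patients = as.integer(n_patients), study_id = study_id, arms = arms,
    p_up = p_up, p_down = p_down, p_fluctuate = p_fluctuate,
    models = models,
    interval_mean = interval_mean, interval_sd = interval_sd,
    points_mean = points_mean, points_sd = points_sd,
    points_min = as.integer(points_min), points_max = as.integer(points_max),
    noise_sigma = noise_sigma,
    baseline_ld_range = baseline_ld_range, v_ref = v_ref, seed = seed
  )
  cfg$points_dist <- .points_distribution(cfg)
  structure(cfg, class = "synthetic_config")
}

# Probability mass over points_min..points_max. Overdispersed targets use a
# shifted negative binomial (the gamma-mixed per-visit dropout marginal),
# with (mu, size) solved so the *truncated* distribution matches the target
# mean/sd; under- or equi-dispersed targets fall back to a discretized
# normal. Returns a data.frame(n, p).
.points_distribution <- function(cfg) {
  supp <- cfg$points_min:cfg$points_max
  if (length(supp) == 1L) return(data.frame(n = supp, p = 1))
  shift <- cfg$points_min
  target <- c(cfg$points_mean, cfg$points_sd)
  trunc_moments <- function(mu, size) {
    p <- stats::dnbinom(supp - shift, mu = mu, size = size)
    p <- p / sum(p)
    m <- sum(supp * p)
    c(m, sqrt(sum((supp - m)^2 * p)))
  }
  overdispersed <- target[2]^2 > (target[1] - shift) * 1.05
  if (overdispersed) {
    obj <- function(lp) {
      mom <- trunc_moments(exp(lp[1]), exp(lp[2]))
      sum((mom - target)^2)
    }
    mu0 <- max(target[1] - shift, 0.1)
    size0 <- max(mu0^2 / max(target[2]^2 - mu0, 0.05), 0.05)
    opt <- stats::optim(log(c(mu0, size0)), obj, method = "Nelder-Mead",
                        control = list(maxit = 2000, reltol = 1e-12))
    p <- stats::dnbinom(supp - shift, mu = exp(opt$par[1]),
                        size = exp(opt$par[2]))
  } else {
    p <- stats::dnorm(supp, mean = target[1], sd = max(target[2], 1e-6))
  }
  data.frame(n = supp, p = p / sum(p))
}

#' @export
print.synthetic_config <- function(x, ...) {
  cat("<synthetic_config>", x$n_patients, "patients,",
      length(x$arms), "arm(s)\n")
  cat(sprintf("  trajectories: up %.2f / down %.2f / fluctuate %.2f\n",
              x$p_up, x$p_down, x$p_fluctuate))
  cat(sprintf("  visits: interval %.2f +/- %.2f d, points %.2f +/- %.2f in [%d, %d]\n",
              x$interval_mean, x$interval_sd, x$points_mean, x$points_sd,
              x$points_min, x$points_max))
  cat(sprintf("  noise sigma %.3f (diameter scale)\n", x$noise_sigma))
  invisible(x)
}

# Parameter priors per (model, direction). "up" draws dynamics with net
# growth, "down" with net shrinkage; rates sit well inside the fitting
# bounds and give doubling/halving over weeks-to-months. u0 is the baseline
# volume on the generator's relative scale.
.draw_params <- function(model, direction, u0) {
  runif1 <- function(a, b) stats::runif(1, a, b)
  plateau <- if (direction == "up") u0 * runif1(2.5, 5) else u0 * runif1(0.15, 0.5)
  switch(model,
    exponential = c(r = if (direction == "up") runif1(0.003, 0.012)
                        else runif1(-0.012, -0.003)),
    logistic = c(gamma = runif1(0.008, 0.03), K = plateau),
    gompertz = {
      g <- runif1(0.005, 0.03)
      c(gamma = g, delta = g * log(plateau))
    },
    general_gompertz = {
      g <- runif1(0.005, 0.03)
      c(gamma = g, delta = g * log(plateau), lambda = runif1(0.75, 1.25))
    },
    classic_bertalanffy = {
      b <- runif1(0.008, 0.03)
      c(alpha = b * plateau^(1 / 3), beta = b)
    },
    general_bertalanffy = {
      lam <- runif1(0.4, 0.85)
      b <- runif1(0.008, 0.03)
      c(alpha = b * plateau^(1 - lam), beta = b, lambda = lam)
    },
    stop("unknown model")
  )
}

#' Simulate one patient's target-lesion series
#'
#' Draws visit times, a trajectory type, a generating model and parameters,
#' evaluates the volume trajectory on the relative scale, inverts it to
#' longest diameters through LD = (2 V)^(1/3), and applies multiplicative
#' lognormal noise. Fluctuating patients get a two-phase piecewise
#' trajectory with a mid-series breakpoint. Uses the current RNG state; seed
#' handling lives in [simulate_cohort()].
#'
#' @param config A `synthetic_config`.
#' @param patient_id,arm Identifiers stamped on the records.
#' @return A list: `records` (measurement data.frame rows) and `truth`
#'   (one-row data.frame: trajectory, model(s), parameters, breakpoint).
#' @export
simulate_patient <- function(config, patient_id = "SYN-0001",
                             arm = config$arms[1]) {
  stopifnot(inherits(config, "synthetic_config"))
  # draw via indices: sample(x, 1) on a length-1 numeric x would expand to 1:x
  draw1 <- function(x, prob = NULL) x[sample.int(length(x), 1L, prob = prob)]
  n <- draw1(config$points_dist$n, prob = config$points_dist$p)
  gaps <- stats::rnorm(max(n - 1L, 0L), config$interval_mean,
                       config$interval_sd)
  gaps <- pmax(gaps, 1)
  times <- c(0, cumsum(gaps))
  ld0 <- stats::runif(1, config$baseline_ld_range[1],
                      config$baseline_ld_range[2])
  u0 <- diameter_to_volume(ld0) / config$v_ref
  traj <- draw1(c("up", "down", "fluctuate"),
                prob = c(config$p_up, config$p_down, config$p_fluctuate))
  model <- draw1(config$models)

  if (traj == "fluctuate" && n >= 3L) {
    first <- draw1(c("down", "up"))
    second <- if (first == "down") "up" else "down"
    brk <- draw1(2:(n - 1))  # breakpoint visit index
    par1 <- .draw_params(model, first, u0)
    u_first <- evaluate_volume(model, par1, u0, times[1:brk])
    u_mid <- u_first[brk]
    model2 <- draw1(config$models)
    par2 <- .draw_params(model2, second, u_mid)
    u_second <- evaluate_volume(model2, par2, u_mid,
                                times[brk:n] - times[brk])
    u <- c(u_first, u_second[-1])
    truth_model <- paste(model, model2, sep = "+")
    par_str <- paste(
      paste(sprintf("%s=%.6g", names(par1), par1), collapse = ";"),
      paste(sprintf("%s=%.6g", names(par2), par2), collapse = ";"),
      sep = " | ")
    brk_time <- times[brk]
  } else {
    if (traj == "fluctuate") traj <- draw1(c("up", "down"))  # n too short
    par1 <- .draw_params(model, traj, u0)
    u <- evaluate_volume(model, par1, u0, times)
    truth_model <- model
    par_str <- paste(sprintf("%s=%.6g", names(par1), par1), collapse = ";")
    brk_time <- NA_real_
  }

  ld_true <- (2 * u * config$v_ref)^(1 / 3)
  noise <- if (config$noise_sigma > 0) {
    exp(stats::rnorm(n, 0, config$noise_sigma))
  } else rep(1, n)
  ld_obs <- ld_true * noise

  records <- data.frame(
    patient_id = patient_id, study_id = config$study_id, arm = arm,
    lesion_id = "INV-T001", time_days = times,
    longest_diameter_mm = ld_obs, shortest_diameter_mm = NA_real_,
    stringsAsFactors = FALSE
  )
  truth <- data.frame(
    patient_id = patient_id, arm = arm, trajectory = traj,
    model = truth_model, params = par_str, u0 = u0, n_points = n,
    breakpoint_time = brk_time, stringsAsFactors = FALSE
  )
  list(records = records, truth = truth)
}

#' Simulate a full synthetic cohort
#'
#' @param config A `synthetic_config`; its `seed` (if set) makes the cohort
#'   reproducible.
#' @return A list: `records` (measurement table readable by
#'   [build_series()]), `truth` (per-patient ground-truth table), and
#'   `v_ref` (the generator's reference volume, usable as a fixed
#'   normalization constant in [normalize_cohort()]).
#' @export
simulate_cohort <- function(config) {
  stopifnot(inherits(config, "synthetic_config"))
  if (!is.null(config$seed)) set.seed(config$seed)
  ids <- sprintf("SYN-%05d", seq_len(config$n_patients))
  arms <- sample(config$arms, config$n_patients, replace = TRUE)
  sims <- lapply(seq_len(config$n_patients), function(i) {
    simulate_patient(config, patient_id = ids[i], arm = arms[i])
  })
  list(
    records = do.call(rbind, c(lapply(sims, `[[`, "records"),
                               list(make.row.names = FALSE))),
    truth = do.call(rbind, c(lapply(sims, `[[`, "truth"),
                             list(make.row.names = FALSE))),
    v_ref = config$v_ref
  )
}

# Parse a single-phase truth params string back to a named numeric vector.
.parse_truth_params <- function(s) {
  kv <- strsplit(strsplit(s, " | ", fixed = TRUE)[[1]][1], ";")[[1]]
  parts <- strsplit(kv, "=", fixed = TRUE)
  stats::setNames(vapply(parts, function(p) as.numeric(p[2]), numeric(1)),
                  vapply(parts, `[[`, "", 1))
}
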