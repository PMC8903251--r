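# Derive one reproducible sub-seed per (patient, model) from a master seed,
# keeping everything inside 32-bit integer range.
.fit_seed <- function(master, i, j) {
  if (is.null(master)) return(NULL)
  as.integer((as.numeric(master) * 7919 + i * 131 + j * 17) %% .Machine$integer.max)
}

.subset_series <- function(series, idx) {
  s <- series
  s$times <- series$times[idx]
  s$ld_mm <- series$ld_mm[idx]
  s$volumes_raw <- series$volumes_raw[idx]
  s$volumes_norm <- series$volumes_norm[idx]
  s$n_points <- length(idx)
  s
}

.fits_to_table <- function(fits) {
  do.call(rbind, c(lapply(fits, function(f) {
    data.frame(patient_id = f$patient_id, model = f$model,
               params = paste(sprintf("%s=%.8g", names(f$par), f$par),
                              collapse = ";"),
               mae = f$metrics$mae, rmse = f$metrics$rmse,
               r_squared = f$metrics$r_squared, aic = f$metrics$aic,
               converged = f$converged, n_obs = f$n_obs, k = f$k,
               stringsAsFactors = FALSE)
  }), list(make.row.names = FALSE)))
}

#' Experiment 1: fit every model to every full patient series
#'
#' Fits each requested model to the entire time series of every patient in
#' the (already filtered and normalized) cohort, then aggregates the four
#' goodness-of-fit metrics (MAE, RMSE, R^2, AIC) into comparison grids
#' stratified by treatment arm x final RECIST group and by treatment arm x
#' trajectory label.
#'
#' @param cohort A normalized `tumor_cohort`, already filtered to the
#'   desired minimum series length (the study uses 3 or 6).
#' @param models Character vector of model names (default all six).
#' @param seed Master seed; every (patient, model) fit gets a derived
#'   sub-seed, so the whole experiment is reproducible.
#' @return A list of class `"experiment1"`: `fits` (list of `growth_fit`),
#'   `fit_table` (per-fit data.frame), `labels` (per-patient labels), and
#'   `summaries` (list of `cohort_summary` grids, one per metric and
#'   stratification).
#' @export
run_experiment1 <- function(cohort, models = growth_model_names(),
                            seed = NULL) {
  stopifnot(inherits(cohort, "tumor_cohort"))
  series <- cohort$series
  if (!length(series)) stop("empty cohort", call. = FALSE)
  fits <- list()
  for (i in seq_along(series)) {
    for (j in seq_along(models)) {
      f <- fit_patient(models[j], series[[i]],
                       seed = .fit_seed(seed, i, j))
      fits[[length(fits) + 1L]] <- f
    }
  }
  fit_table <- .fits_to_table(fits)
  labels <- classify_cohort(cohort)
  summaries <- list(
    recist = lapply(stats::setNames(nm = c("mae", "rmse", "r_squared", "aic")),
                    function(m) summarize_metrics(fit_table, labels, m,
                                                  group = "recist_collapsed")),
    trajectory = lapply(stats::setNames(nm = c("mae", "rmse", "r_squared", "aic")),
                        function(m) summarize_metrics(fit_table, labels, m,
                                                      group = "trajectory"))
  )
  structure(list(fits = fits, fit_table = fit_table, labels = labels,
                 summaries = summaries), class = "experiment1")
}

#' Experiment 2: holdout forecasting of the last three measurements
#'
#' For every patient (who must have at least 6 points so that at least 3
#' training points remain), fits each model to all but the last three
#' points, extrapolates to the three held-out times, and scores the
#' forecast by MAE on normalized volumes. The training fit's V0 is the
#' first observation; the held-out data never enter the fit.
#'
#' @inheritParams run_experiment1
#' @return A list of class `"experiment2"`: `forecasts` (data.frame with
#'   one row per (patient, model): training size, holdout MAE, convergence)
#'   and `summaries` (holdout-MAE grids by arm x RECIST group and arm x
#'   trajectory).
#' @export
run_experiment2 <- function(cohort, models = growth_model_names(),
                            seed = NULL) {
  stopifnot(inherits(cohort, "tumor_cohort"))
  series <- cohort$series
  short <- vapply(series, function(s) s$n_points < 6L, logical(1))
  if (any(short)) {
    stop("experiment 2 needs >= 6 points per patient; run ",
         "filter_min_points(cohort, 6) first", call. = FALSE)
  }
  rows <- list()
  for (i in seq_along(series)) {
    s <- series[[i]]
    n <- s$n_points
    train <- .subset_series(s, seq_len(n - 3L))
    hold_t <- s$times[(n - 2L):n]
    hold_v <- s$volumes_norm[(n - 2L):n]
    for (j in seq_along(models)) {
      f <- fit_patient(models[j], train, seed = .fit_seed(seed, i, j))
      pred <- evaluate_volume(f$model, f$par, f$v0, hold_t)
      hm <- if (all(is.finite(pred))) mean(abs(hold_v - pred)) else Inf
      rows[[length(rows) + 1L]] <- data.frame(
        patient_id = s$patient_id, model = f$model,
        n_train = train$n_points, n_holdout = 3L,
        holdout_mae = hm, train_mae = f$metrics$mae,
        converged = f$converged, stringsAsFactors = FALSE)
    }
  }
  forecasts <- do.call(rbind, c(rows, list(make.row.names = FALSE)))
  labels <- classify_cohort(cohort)
  ftab <- forecasts
  names(ftab)[names(ftab) == "holdout_mae"] <- "mae"
  summaries <- list(
    recist = summarize_metrics(ftab, labels, "mae",
                               group = "recist_collapsed"),
    trajectory = summarize_metrics(ftab, labels, "mae",
                                   group = "trajectory")
  )
  structure(list(forecasts = forecasts, labels = labels,
                 summaries = summaries), class = "experiment2")
}

#' Aggregate per-fit metrics into a stratum x model grid
#'
#' Means of one metric within each (arm, response-group) stratum, one
#' column per model, computed over converged fits only. Strata with no
#' eligible fit are omitted.
#'
#' @param fit_table Per-fit data.frame (needs `patient_id`, `model`,
#'   `converged` and the metric column).
#' @param labels Per-patient label table from [classify_cohort()].
#' @param metric Metric column name (`"mae"`, `"rmse"`, `"r_squared"`,
#'   `"aic"`).
#' @param group Label column defining the response grouping
#'   (`"recist_collapsed"` or `"trajectory"`).
#' @return A `cohort_summary`: data.frame with `arm`, `group`, `n_patients`
#'   and one column per model holding the stratum mean.
#' @export
summarize_metrics <- function(fit_table, labels, metric = "mae",
                              group = c("recist_collapsed", "trajectory")) {
  group <- match.arg(group)
  stopifnot(metric %in% names(fit_table))
  df <- merge(fit_table, labels[c("patient_id", "arm", group)],
              by = "patient_id")
  df <- df[df$converged & is.finite(df[[metric]]) & !is.na(df[[group]]), ]
  if (nrow(df) == 0L) {
    out <- data.frame(arm = character(0), group = character(0),
                      n_patients = integer(0))
    return(structure(out, class = c("cohort_summary", "data.frame"),
                     metric = metric))
  }
  models <- unique(df$model)
  strata <- unique(df[c("arm", group)])
  rows <- lapply(seq_len(nrow(strata)), function(r) {
    sub <- df[df$arm == strata$arm[r] & df[[group]] == strata[[group]][r], ]
    means <- vapply(models, function(m) {
      v <- sub[[metric]][sub$model == m]
      if (length(v)) mean(v) else NA_real_
    }, numeric(1))
    cbind(data.frame(arm = strata$arm[r], group = strata[[group]][r],
                     n_patients = length(unique(sub$patient_id)),
                     stringsAsFactors = FALSE),
          as.data.frame(as.list(means)))
  })
  out <- do.call(rbind, c(rows, list(make.row.names = FALSE)))
  out <- out[order(out$arm, out$group), , drop = FALSE]
  rownames(out) <- NULL
  structure(out, class = c("cohort_summary", "data.frame"), metric = metric)
}

#' Row-wise min-max normalization of a summary grid
#'
#' Rescales each stratum row of a [summarize_metrics()] grid to [0, 1] by
#' (x - min) / (max - min), and flags the best (`*`, row minimum) and worst
#' (`#`, row maximum) model per row; ties are broken by model column order.
#' A constant row is degenerate: all zeros, flagged as such, no best/worst.
#'
#' @param summary_grid A `cohort_summary`.
#' @return A list: `normalized` (grid with model columns rescaled), `best`
#'   and `worst` (model name per row, NA for degenerate rows), `degenerate`
#'   (logical per row).
#' @export
row_normalize <- function(summary_grid) {
  meta <- intersect(c("arm", "group", "n_patients"), names(summary_grid))
  model_cols <- setdiff(names(summary_grid), meta)
  stopifnot(length(model_cols) >= 1)
  norm <- summary_grid
  best <- worst <- rep(NA_character_, nrow(summary_grid))
  degenerate <- logical(nrow(summary_grid))
  for (r in seq_len(nrow(summary_grid))) {
    x <- as.numeric(summary_grid[r, model_cols])
    fin <- is.finite(x)
    if (sum(fin) < 2L || diff(range(x[fin])) == 0) {
      norm[r, model_cols] <- ifelse(fin, 0, NA)
      degenerate[r] <- TRUE
      next
    }
    lo <- min(x[fin]); hi <- max(x[fin])
    norm[r, model_cols] <- (x - lo) / (hi - lo)
    best[r] <- model_cols[which(x == lo)[1]]
    worst[r] <- model_cols[which(x == hi)[1]]
  }
  list(normalized = norm, best = best, worst = worst, degenerate = degenerate)
}

#' Distribution of fitted parameters by response group
#'
#' Summarizes the fitted parameter values of converged fits per (model,
#' parameter, group): mean, sd, and quartiles. Groups with a single fit get
#' an NA sd; empty groups are omitted.
#'
#' @param fit_table Per-fit table from [run_experiment1()] (`fit_table`
#'   element), holding a `params` column of `name=value;...` strings.
#' @param labels Per-patient labels from [classify_cohort()].
#' @param group Grouping column, default `"trajectory"`.
#' @return A data.frame: model, parameter, group, n, mean, sd, q25, median,
#'   q75.
#' @export
parameter_distributions <- function(fit_table, labels,
                                    group = "trajectory") {
  df <- merge(fit_table, labels[c("patient_id", group)], by = "patient_id")
  df <- df[df$converged & !is.na(df[[group]]), ]
  rows <- list()
  for (m in unique(df$model)) {
    sub <- df[df$model == m, ]
    pars <- lapply(sub$params, .parse_truth_params)
    pnames <- names(pars[[1]])
    for (pn in pnames) {
      vals <- vapply(pars, `[[`, numeric(1), pn)
      for (g in unique(sub[[group]])) {
        v <- vals[sub[[group]] == g]
        if (!length(v)) next
        q <- stats::quantile(v, c(0.25, 0.5, 0.75), names = FALSE)
        rows[[length(rows) + 1L]] <- data.frame(
          model = m, parameter = pn, group = g, n = length(v),
          mean = mean(v), sd = if (length(v) > 1) stats::sd(v) else NA_real_,
          q25 = q[1], median = q[2], q75 = q[3], stringsAsFactors = FALSE)
      }
    }
  }
  do.call(rbind, c(rows, list(make.row.names = FALSE)))
}
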