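# Default run configuration. Every recognized key and its default; unknown
# keys in a config file are rejected so typos fail loudly.
.config_defaults <- function() {
  list(
    input = NULL,                  # measurement table (CSV/TSV/XLSX); NULL = simulate
    target_lesion = "INV-T001",
    min_points = 3L,               # series-length filter (the study uses 3 or 6)
    models = growth_model_names(),
    seed = 1L,
    out_dir = "tumorgrowth-run",
    normalization_scope = "cohort",  # or "study"
    sd_type = "sample",
    run_forecast = TRUE,           # experiment 2 on the >= 6-point subset
    n_patients = 100L,             # synthetic cohort size when input is NULL
    noise_sigma = 0.05,
    de_max_gen = 200L,
    de_tol = 0.01
  )
}

#' Load and validate a run configuration
#'
#' Reads a flat YAML key/value file, validates it against the schema of
#' recognized keys, fills defaults for everything unset, and returns the
#' fully-resolved configuration. An empty (or missing-content) file yields
#' all defaults.
#'
#' @param path Path to a YAML file, or `NULL` for pure defaults.
#' @return A named list of class `"run_config"`.
#' @export
load_config <- function(path = NULL) {
  defaults <- .config_defaults()
  user <- list()
  if (!is.null(path)) {
    if (!file.exists(path)) stop("config file not found: ", path, call. = FALSE)
    user <- yaml::read_yaml(path)
    if (is.null(user)) user <- list()
    if (!is.list(user)) stop("config must be a YAML mapping", call. = FALSE)
  }
  unknown <- setdiff(names(user), names(defaults))
  if (length(unknown)) {
    stop("unknown config key(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  cfg <- utils::modifyList(defaults, user)
  # validation
  stopifnot(cfg$min_points >= 1)
  cfg$min_points <- as.integer(cfg$min_points)
  cfg$models <- match.arg(cfg$models, growth_model_names(), several.ok = TRUE)
  if (!cfg$normalization_scope %in% c("cohort", "study")) {
    stop("normalization_scope must be 'cohort' or 'study'", call. = FALSE)
  }
  if (!cfg$sd_type %in% c("sample", "population")) {
    stop("sd_type must be 'sample' or 'population'", call. = FALSE)
  }
  cfg$seed <- as.integer(cfg$seed)
  structure(cfg, class = "run_config")
}

#' @export
print.run_config <- function(x, ...) {
  cat("<run_config>\n")
  for (k in names(x)) {
    v <- x[[k]]
    cat(sprintf("  %-20s %s\n", k,
                if (is.null(v)) "NULL" else paste(v, collapse = ", ")))
  }
  invisible(x)
}

#' Run the full analysis pipeline
#'
#' Sequences the whole analysis: ingest (or simulate) measurements, build
#' and normalize target-lesion series, filter by series length, classify
#' responses, fit all models to all patients (experiment 1), forecast the
#' last three points on the six-plus subset (experiment 2), and write every
#' artifact under `config$out_dir`: per-fit and forecast records, label and
#' concordance tables, the contingency table, raw and row-normalized
#' summary grids, and a manifest recording the input checksum, resolved
#' configuration, seed and package version. Input files are never mutated.
#'
#' Per-patient fit failures are recorded (converged = FALSE) and excluded
#' from summary means; only a global failure stops the run.
#'
#' @param config A `run_config` from [load_config()] (or `NULL` for
#'   defaults).
#' @return Invisibly, a list with the main in-memory results and the output
#'   directory.
#' @export
run_pipeline <- function(config = NULL) {
  if (is.null(config)) config <- load_config(NULL)
  stopifnot(inherits(config, "run_config"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)

  if (is.null(config$input)) {
    sim <- simulate_cohort(synthetic_config(
      n_patients = config$n_patients, noise_sigma = config$noise_sigma,
      seed = config$seed))
    records <- sim$records
    utils::write.csv(sim$truth, file.path(config$out_dir, "ground_truth.csv"),
                     row.names = FALSE)
    input_checksum <- NA_character_
  } else {
    records <- read_measurements(config$input)
    input_checksum <- unname(tools::md5sum(config$input))
  }

  cohort <- build_series(records, target_lesion = config$target_lesion)
  cohort <- normalize_cohort(cohort, scope = config$normalization_scope)
  cohort <- filter_min_points(cohort, config$min_points)
  if (!length(cohort$series)) stop("no series survive the filter", call. = FALSE)
  write_cohort(cohort, file.path(config$out_dir, "cohort_normalized.csv"),
               settings = list(min_points = config$min_points,
                               normalization_scope = config$normalization_scope))

  labels <- classify_cohort(cohort)
  utils::write.csv(labels, file.path(config$out_dir, "labels.csv"),
                   row.names = FALSE)
  conc <- do.call(rbind, lapply(1:4, function(i) {
    r <- recist_concordance(cohort, i)
    if (nrow(r$per_arm) == 0L) return(NULL)
    cbind(eval_index = i, r$per_arm,
          median_across_arms = r$median)
  }))
  if (!is.null(conc)) {
    utils::write.csv(conc, file.path(config$out_dir, "concordance.csv"),
                     row.names = FALSE)
  }
  ct <- crosstab_groupings(cohort)
  utils::write.csv(as.data.frame.matrix(ct),
                   file.path(config$out_dir, "crosstab.csv"))

  exp1 <- run_experiment1(cohort, models = config$models, seed = config$seed)
  utils::write.csv(exp1$fit_table, file.path(config$out_dir, "fits.csv"),
                   row.names = FALSE)
  for (strat in names(exp1$summaries)) {
    for (metric in names(exp1$summaries[[strat]])) {
      g <- exp1$summaries[[strat]][[metric]]
      utils::write.csv(g, file.path(config$out_dir,
                                    sprintf("summary_%s_%s.csv", strat, metric)),
                       row.names = FALSE)
      if (nrow(g)) {
        utils::write.csv(row_normalize(g)$normalized,
                         file.path(config$out_dir,
                                   sprintf("summary_%s_%s_rownorm.csv",
                                           strat, metric)),
                         row.names = FALSE)
      }
    }
  }

  exp2 <- NULL
  if (isTRUE(config$run_forecast)) {
    cohort6 <- filter_min_points(cohort, 6L)
    if (length(cohort6$series)) {
      exp2 <- run_experiment2(cohort6, models = config$models,
                              seed = config$seed)
      utils::write.csv(exp2$forecasts,
                       file.path(config$out_dir, "forecasts.csv"),
                       row.names = FALSE)
    }
  }

  manifest <- list(
    package_version = as.character(utils::packageVersion("tumorgrowth")),
    r_version = as.character(getRversion()),
    seed = config$seed,
    input = if (is.null(config$input)) "synthetic" else config$input,
    input_md5 = input_checksum,
    config = unclass(config),
    n_patients = length(cohort$series),
    timestamp = format(Sys.time(), tz = "UTC", usetz = TRUE)
  )
  jsonlite::write_json(manifest, file.path(config$out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, null = "null",
                       pretty = TRUE)

  invisible(list(cohort = cohort, labels = labels, experiment1 = exp1,
                 experiment2 = exp2, out_dir = config$out_dir))
}
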