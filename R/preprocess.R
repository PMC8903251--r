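#' Convert a lesion's longest diameter to tumor volume
#'
#' Applies the standard one-dimensional conversion V = LD^3 * 0.5, treating
#' the lesion as roughly spherical with the longest diameter as the measured
#' axis. A diameter of 0 (lesion disappearance, complete response) maps to
#' volume 0.
#'
#' @param ld_mm Longest diameter(s) in mm, non-negative.
#' @return Volume(s) in mm^3.
#' @examples
#' diameter_to_volume(10) # 500 mm^3
#' @export
diameter_to_volume <- function(ld_mm) {
  if (any(!is.finite(ld_mm)) || any(ld_mm < 0)) {
    stop("longest diameter must be finite and non-negative", call. = FALSE)
  }
  ld_mm^3 * 0.5
}

#' Read a table of lesion measurements
#'
#' Reads a delimited (CSV/TSV) or spreadsheet (XLSX, via readxl) table of
#' per-visit lesion measurements into the standard record layout:
#' `patient_id`, `study_id`, `arm`, `lesion_id`, `time_days`,
#' `longest_diameter_mm` and optionally `shortest_diameter_mm`. Source
#' columns with different names can be mapped via `col_map`.
#'
#' @param path File path (.csv, .tsv/.txt, or .xlsx).
#' @param col_map Named character vector mapping standard names to the
#'   source column names, e.g. `c(longest_diameter_mm = "LDIAM")`.
#' @return A data.frame of measurement records.
#' @export
read_measurements <- function(path, col_map = NULL) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  ext <- tolower(tools::file_ext(path))
  df <- if (ext == "xlsx") {
    if (!requireNamespace("readxl", quietly = TRUE)) {
      stop("reading .xlsx requires the 'readxl' package", call. = FALSE)
    }
    as.data.frame(readxl::read_excel(path))
  } else if (ext %in% c("csv", "tsv", "txt")) {
    sep <- if (ext == "csv") "," else "\t"
    utils::read.table(path, header = TRUE, sep = sep,
                      stringsAsFactors = FALSE, check.names = FALSE)
  } else {
    stop("unsupported file extension: .", ext, call. = FALSE)
  }
  as_measurement_records(df, col_map = col_map)
}

#' @rdname read_measurements
#' @param df A data.frame already holding the measurement columns.
#' @export
as_measurement_records <- function(df, col_map = NULL) {
  std <- c("patient_id", "study_id", "arm", "lesion_id", "time_days",
           "longest_diameter_mm", "shortest_diameter_mm")
  if (!is.null(col_map)) {
    bad <- setdiff(names(col_map), std)
    if (length(bad)) stop("unknown column-map keys: ",
                          paste(bad, collapse = ", "), call. = FALSE)
    for (k in names(col_map)) {
      if (!col_map[[k]] %in% names(df)) {
        stop("mapped column not in table: ", col_map[[k]], call. = FALSE)
      }
      names(df)[names(df) == col_map[[k]]] <- k
    }
  }
  required <- setdiff(std, "shortest_diameter_mm")
  missing <- setdiff(required, names(df))
  if (length(missing)) {
    stop("missing required column(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  if (!"shortest_diameter_mm" %in% names(df)) {
    df[["shortest_diameter_mm"]] <- rep(NA_real_, nrow(df))
  }
  df <- df[std]
  df$time_days <- as.numeric(df$time_days)
  df$longest_diameter_mm <- as.numeric(df$longest_diameter_mm)
  if (any(is.finite(df$time_days) & df$time_days < 0)) {
    stop("time_days must be non-negative", call. = FALSE)
  }
  if (any(is.finite(df$longest_diameter_mm) & df$longest_diameter_mm < 0)) {
    stop("longest_diameter_mm must be non-negative", call. = FALSE)
  }
  df
}

#' Build one target-lesion series per patient
#'
#' Selects, for every patient, the rows of the configured target lesion
#' (`"INV-T001"` by default, the first target lesion), averages duplicate
#' (patient, time) measurements, sorts by time, re-origins time so the first
#' visit is day 0, and converts diameters to volumes. Patients that lack the
#' target lesion, or whose target-lesion rows carry only shortest-diameter
#' values, are dropped with a warning.
#'
#' @param records Measurement records (see [read_measurements()]).
#' @param target_lesion Lesion label identifying the target lesion.
#' @return A `tumor_cohort`: a list of `patient_series` objects plus
#'   normalization metadata (populated by [normalize_cohort()]).
#' @export
build_series <- function(records, target_lesion = "INV-T001") {
  records <- as_measurement_records(records)
  dropped <- character(0)
  series <- list()
  for (pid in unique(records$patient_id)) {
    rows <- records[records$patient_id == pid &
                      records$lesion_id == target_lesion, , drop = FALSE]
    rows <- rows[is.finite(rows$longest_diameter_mm) &
                   is.finite(rows$time_days), , drop = FALSE]
    if (nrow(rows) == 0L) {
      dropped <- c(dropped, pid)
      next
    }
    ld <- tapply(rows$longest_diameter_mm, rows$time_days, mean)
    t_raw <- as.numeric(names(ld))
    o <- order(t_raw)
    t_raw <- t_raw[o]
    ld <- as.numeric(ld)[o]
    series[[pid]] <- structure(list(
      patient_id = pid,
      study_id = rows$study_id[1],
      arm = rows$arm[1],
      times = t_raw - t_raw[1],
      ld_mm = ld,
      volumes_raw = diameter_to_volume(ld),
      volumes_norm = NULL,
      n_points = length(ld)
    ), class = "patient_series")
  }
  if (length(dropped)) {
    warning(length(dropped), " patient(s) without usable '", target_lesion,
            "' measurements dropped: ",
            paste(utils::head(dropped, 5), collapse = ", "),
            if (length(dropped) > 5) ", ..." else "", call. = FALSE)
  }
  structure(list(series = series, v_max = NULL, normalized = FALSE),
            class = "tumor_cohort")
}

#' @export
print.tumor_cohort <- function(x, ...) {
  n <- length(x$series)
  cat("<tumor_cohort>", n, "patient series\n")
  if (n) {
    np <- vapply(x$series, function(s) s$n_points, integer(1))
    cat(sprintf("  points per patient: median %g, range [%d, %d]\n",
                stats::median(np), min(np), max(np)))
  }
  if (x$normalized) cat(sprintf("  normalized (V_max = %g mm^3)\n", x$v_max))
  invisible(x)
}

#' @export
print.patient_series <- function(x, ...) {
  cat(sprintf("<patient_series> %s (%s / %s): %d points over %g days\n",
              x$patient_id, x$study_id, x$arm, x$n_points, max(x$times)))
  invisible(x)
}

#' Normalize all volumes by the cohort-wide maximum
#'
#' Divides every raw volume by the maximum volume observed anywhere in the
#' cohort, so normalized volumes lie in [0, 1] with the largest lesion at
#' exactly 1. The maximum (`v_max`) is stored on the cohort for the inverse
#' transform. An explicit `v_max` can be supplied to put several cohorts (or
#' a simulation and its fit) on a common scale.
#'
#' @param cohort A `tumor_cohort`.
#' @param v_max Optional fixed normalization constant in mm^3; defaults to
#'   the cohort-wide maximum raw volume.
#' @param scope `"cohort"` (default: one constant for the whole data set,
#'   all studies pooled) or `"study"` (one constant per study).
#' @return The cohort with `volumes_norm` populated and `v_max` recorded
#'   (a named per-study vector under `scope = "study"`).
#' @export
normalize_cohort <- function(cohort, v_max = NULL,
                             scope = c("cohort", "study")) {
  stopifnot(inherits(cohort, "tumor_cohort"))
  scope <- match.arg(scope)
  if (length(cohort$series) == 0L) stop("empty cohort", call. = FALSE)
  series_max <- vapply(cohort$series, function(s) max(s$volumes_raw),
                       numeric(1))
  if (scope == "study" && is.null(v_max)) {
    studies <- vapply(cohort$series, function(s) s$study_id, character(1))
    v_max <- vapply(split(series_max, studies), max, numeric(1))
    if (any(!is.finite(v_max)) || any(v_max <= 0)) {
      stop("a study has no positive volume to normalize by", call. = FALSE)
    }
    cohort$series <- lapply(cohort$series, function(s) {
      s$volumes_norm <- s$volumes_raw / v_max[[s$study_id]]
      s
    })
  } else {
    if (is.null(v_max)) v_max <- max(series_max)
    if (!is.finite(v_max) || v_max <= 0) {
      stop("cohort has no positive volume to normalize by", call. = FALSE)
    }
    cohort$series <- lapply(cohort$series, function(s) {
      s$volumes_norm <- s$volumes_raw / v_max
      s
    })
  }
  cohort$v_max <- v_max
  cohort$normalized <- TRUE
  cohort
}

#' Keep only patients with at least `min_n` measurements
#'
#' @param cohort A `tumor_cohort`.
#' @param min_n Minimum number of points (the study uses 3 and 6).
#' @return The filtered cohort, input order preserved.
#' @export
filter_min_points <- function(cohort, min_n) {
  stopifnot(inherits(cohort, "tumor_cohort"), min_n >= 1)
  keep <- vapply(cohort$series, function(s) s$n_points >= min_n, logical(1))
  cohort$series <- cohort$series[keep]
  cohort
}

#' Summary statistics of a cohort's visit structure
#'
#' @param cohort A `tumor_cohort` with at least one series.
#' @param sd_type `"sample"` (n-1 denominator, default) or `"population"`.
#' @return A list: `n_patients`, `mean_interval_days`, `sd_interval_days`
#'   (over all consecutive within-patient visit gaps), `mean_points`,
#'   `sd_points`.
#' @export
cohort_statistics <- function(cohort, sd_type = c("sample", "population")) {
  stopifnot(inherits(cohort, "tumor_cohort"))
  sd_type <- match.arg(sd_type)
  if (length(cohort$series) == 0L) stop("empty cohort", call. = FALSE)
  intervals <- unlist(lapply(cohort$series, function(s) diff(s$times)),
                      use.names = FALSE)
  np <- vapply(cohort$series, function(s) s$n_points, integer(1))
  sdv <- function(x) {
    if (length(x) < 2L) return(0)
    s <- stats::sd(x)
    if (sd_type == "population") s <- s * sqrt((length(x) - 1) / length(x))
    s
  }
  list(
    n_patients = length(np),
    mean_interval_days = if (length(intervals)) mean(intervals) else NA_real_,
    sd_interval_days = if (length(intervals)) sdv(intervals) else NA_real_,
    mean_points = mean(np),
    sd_points = sdv(np)
  )
}

#' Flatten a cohort to a per-visit data.frame
#'
#' @param cohort A `tumor_cohort`.
#' @return A data.frame with one row per (patient, visit).
#' @export
cohort_table <- function(cohort) {
  stopifnot(inherits(cohort, "tumor_cohort"))
  do.call(rbind, c(lapply(unname(cohort$series), function(s) {
    data.frame(patient_id = s$patient_id, study_id = s$study_id, arm = s$arm,
               time_days = s$times, longest_diameter_mm = s$ld_mm,
               volume_mm3 = s$volumes_raw,
               volume_norm = if (is.null(s$volumes_norm)) NA_real_
                             else s$volumes_norm,
               stringsAsFactors = FALSE)
  }), list(make.row.names = FALSE)))
}

#' Write a normalized cohort to disk
#'
#' Writes the per-visit table as CSV and a JSON sidecar recording `v_max`
#' and any filter settings, so the normalization is invertible later.
#'
#' @param cohort A normalized `tumor_cohort`.
#' @param path Output CSV path; the sidecar gets the same path with
#'   extension `.json`.
#' @param settings Optional named list stored in the sidecar.
#' @return Invisibly, the two paths written.
#' @export
write_cohort <- function(cohort, path, settings = list()) {
  stopifnot(inherits(cohort, "tumor_cohort"))
  utils::write.csv(cohort_table(cohort), path, row.names = FALSE)
  side <- sub("\\.[^.]+$", ".json", path)
  jsonlite::write_json(
    c(list(v_max = cohort$v_max, n_patients = length(cohort$series)),
      settings),
    side, auto_unbox = TRUE, digits = NA, null = "null")
  invisible(c(csv = path, json = side))
}
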