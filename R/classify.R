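#' RECIST status of a single evaluation against baseline
#'
#' Classifies a target-lesion longest diameter against its baseline value:
#' CR (complete response) when the lesion has disappeared (diameter 0),
#' PD (progressive disease) at an increase of at least 20% over baseline,
#' PR (partial response) at a decrease of at least 30% from baseline, and
#' SD (stable disease) otherwise. Both thresholds are inclusive ("at least").
#' The reference is always the baseline measurement, not the nadir.
#'
#' @param baseline_ld Baseline longest diameter in mm, > 0.
#' @param current_ld Current longest diameter in mm, >= 0 (vectorized).
#' @return Character vector with values in `c("CR", "PR", "SD", "PD")`.
#' @examples
#' recist_status(10, c(0, 6.9, 7.0, 11.9, 12.0)) # CR PR PR SD PD
#' @export
recist_status <- function(baseline_ld, current_ld) {
  if (!is.finite(baseline_ld) || baseline_ld <= 0) {
    stop("baseline diameter must be positive", call. = FALSE)
  }
  if (any(!is.finite(current_ld)) || any(current_ld < 0)) {
    stop("current diameter must be finite and non-negative", call. = FALSE)
  }
  change <- (current_ld - baseline_ld) / baseline_ld
  out <- rep("SD", length(current_ld))
  out[change >= 0.20] <- "PD"    # checked before PR; regimes are disjoint
  out[-change >= 0.30] <- "PR"
  out[current_ld == 0] <- "CR"
  out
}

#' Per-evaluation RECIST statuses of a series
#'
#' Evaluation i compares measurement i+1 to the baseline (first) measurement,
#' so a series of n points yields n-1 statuses.
#'
#' @param series A `patient_series` (or numeric vector of diameters).
#' @return Character vector of statuses, length `n_points - 1`.
#' @export
recist_series <- function(series) {
  ld <- if (inherits(series, "patient_series")) series$ld_mm else series
  if (length(ld) < 2L) return(character(0))
  recist_status(ld[1], ld[-1])
}

#' Trajectory label (up / down / fluctuate) from a diameter series
#'
#' Labels a patient's full diameter time course from the vector of
#' consecutive differences d[i] = LD(t[i+1]) - LD(t[i]):
#' \itemize{
#'   \item "up": all differences positive, or the first difference positive
#'     and the ratio of the sum of positive differences to the absolute sum
#'     of negative differences > 2;
#'   \item "down": the mirrored rule (all negative, or first difference
#'     negative and negative-to-positive sum ratio > 2);
#'   \item "fluctuate": everything else (the catch-all).
#' }
#' Zero differences count to neither sum and break the "always
#' positive/negative" conditions. A zero opposing sum with a non-zero own
#' sum makes the ratio +Inf (> 2).
#'
#' @param x A `patient_series`, a numeric vector of diameters (length >= 2),
#'   or — with `diffs = TRUE` — a difference vector itself.
#' @param diffs Set `TRUE` when `x` already holds consecutive differences.
#' @return One of `"up"`, `"down"`, `"fluctuate"`.
#' @examples
#' trajectory_label(c(10, 12, 14, 15))   # up
#' trajectory_label(c(10, 14, 13, 16))   # up (ratio 7/1 > 2)
#' trajectory_label(c(10, 12, 8, 11))    # fluctuate
#' @export
trajectory_label <- function(x, diffs = FALSE) {
  d <- if (inherits(x, "patient_series")) diff(x$ld_mm)
       else if (diffs) x
       else diff(as.numeric(x))
  if (length(d) == 0L) stop("need at least two measurements", call. = FALSE)
  pos <- sum(d[d > 0])
  neg <- -sum(d[d < 0])  # absolute value of the negative sum
  ratio_up <- if (neg == 0) (if (pos > 0) Inf else 0) else pos / neg
  ratio_down <- if (pos == 0) (if (neg > 0) Inf else 0) else neg / pos
  if (all(d > 0) || (d[1] > 0 && ratio_up > 2)) return("up")
  if (all(d < 0) || (d[1] < 0 && ratio_down > 2)) return("down")
  "fluctuate"
}

#' Per-patient response labels for a whole cohort
#'
#' @param cohort A `tumor_cohort`; series with fewer than 2 points get NA
#'   labels.
#' @return A data.frame with one row per patient: `patient_id`, `study_id`,
#'   `arm`, `n_points`, `final_recist` (status at the last evaluation),
#'   `recist_collapsed` (CR/PR merged) and `trajectory`.
#' @export
classify_cohort <- function(cohort) {
  stopifnot(inherits(cohort, "tumor_cohort"))
  rows <- lapply(unname(cohort$series), function(s) {
    ok <- s$n_points >= 2L
    fin <- if (ok) utils::tail(recist_series(s), 1) else NA_character_
    data.frame(
      patient_id = s$patient_id, study_id = s$study_id, arm = s$arm,
      n_points = s$n_points,
      final_recist = fin,
      recist_collapsed = if (is.na(fin)) NA_character_
                         else if (fin %in% c("CR", "PR")) "CR/PR" else fin,
      trajectory = if (ok) trajectory_label(s) else NA_character_,
      stringsAsFactors = FALSE
    )
  })
  do.call(rbind, c(rows, list(make.row.names = FALSE)))
}

#' Concordance of an early RECIST evaluation with the final one
#'
#' For each treatment arm, the percentage of patients whose RECIST status at
#' evaluation `eval_index` (evaluation 1 = first post-baseline measurement)
#' equals their final RECIST status (status at the last evaluation).
#' Patients without that many evaluations are excluded from the denominator.
#'
#' @param cohort A `tumor_cohort`.
#' @param eval_index Evaluation number, >= 1.
#' @return A list with `per_arm` (data.frame: arm, n, concordance in %) and
#'   `median` (median concordance across arms, %). Arms with no eligible
#'   patient are omitted; with none at all both are `NA`.
#' @export
recist_concordance <- function(cohort, eval_index) {
  stopifnot(inherits(cohort, "tumor_cohort"), eval_index >= 1)
  rows <- lapply(unname(cohort$series), function(s) {
    st <- recist_series(s)
    if (length(st) < eval_index) return(NULL)
    data.frame(arm = s$arm,
               agree = st[eval_index] == st[length(st)],
               stringsAsFactors = FALSE)
  })
  rows <- do.call(rbind, rows)
  if (is.null(rows) || nrow(rows) == 0L) {
    return(list(per_arm = data.frame(arm = character(0), n = integer(0),
                                     concordance = numeric(0)),
                median = NA_real_))
  }
  per_arm <- do.call(rbind, lapply(split(rows, rows$arm), function(g) {
    data.frame(arm = g$arm[1], n = nrow(g),
               concordance = 100 * mean(g$agree), stringsAsFactors = FALSE)
  }))
  rownames(per_arm) <- NULL
  list(per_arm = per_arm, median = stats::median(per_arm$concordance))
}

#' Cross-tabulation of trajectory labels against collapsed RECIST
#'
#' Counts patients in each cell of trajectory type (up / down / fluctuate)
#' by collapsed final RECIST (CR/PR, SD, PD). Patients with fewer than two
#' measurements (no labels) are excluded.
#'
#' @param cohort A `tumor_cohort`.
#' @return A 3 x 3 integer table, rows = trajectory, columns = RECIST group.
#' @export
crosstab_groupings <- function(cohort) {
  lab <- classify_cohort(cohort)
  lab <- lab[!is.na(lab$trajectory) & !is.na(lab$recist_collapsed), ]
  table(
    trajectory = factor(lab$trajectory, levels = c("up", "down", "fluctuate")),
    recist = factor(lab$recist_collapsed, levels = c("CR/PR", "SD", "PD"))
  )
}
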