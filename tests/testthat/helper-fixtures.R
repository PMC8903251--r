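# Fixture builders shared across the suite. Everything is generated in code;
# no files on disk.

V_REF <- 0.5 * 100^3  # volume of a 100 mm lesion, the generator's reference

# A one-patient normalized series with prescribed normalized volumes at the
# given day offsets, built through the real ingestion path (LD inversion,
# volume conversion, fixed-constant normalization).
series_from_norm <- function(times, v, patient_id = "P1", arm = "arm_A",
                             study_id = "S1") {
  ld <- (2 * v * V_REF)^(1 / 3)
  rec <- data.frame(patient_id = patient_id, study_id = study_id, arm = arm,
                    lesion_id = "INV-T001", time_days = times,
                    longest_diameter_mm = ld, stringsAsFactors = FALSE)
  co <- normalize_cohort(build_series(rec), v_max = V_REF)
  co$series[[1]]
}

# A multi-patient cohort from a list of LD vectors (times 0, 50, 100, ...),
# one patient per element; arms recycle over the supplied labels.
cohort_from_ld <- function(ld_list, arms = "arm_A") {
  rows <- lapply(seq_along(ld_list), function(i) {
    ld <- ld_list[[i]]
    data.frame(patient_id = sprintf("P%03d", i), study_id = "S1",
               arm = arms[(i - 1) %% length(arms) + 1],
               lesion_id = "INV-T001",
               time_days = seq(0, by = 50, length.out = length(ld)),
               longest_diameter_mm = ld, stringsAsFactors = FALSE)
  })
  normalize_cohort(build_series(do.call(rbind, rows)))
}

# A noise-free single-model synthetic cohort whose every series has at
# least `min_pts` points (for recovery and forecasting checks).
recovery_config <- function(model, n, seed, direction = "both",
                            min_pts = 7, max_pts = 12) {
  p_up <- switch(direction, up = 1, down = 0, both = 0.5)
  synthetic_config(
    n_patients = n, models = model,
    p_up = p_up, p_down = 1 - p_up, p_fluctuate = 0,
    points_mean = (min_pts + max_pts) / 2, points_sd = 1.5,
    points_min = min_pts, points_max = max_pts,
    noise_sigma = 0, seed = seed)
}
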