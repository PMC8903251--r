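make_records <- function(...) {
  rows <- list(...)
  do.call(rbind, lapply(rows, function(r) {
    data.frame(patient_id = r[[1]], study_id = "S1", arm = "arm_A",
               lesion_id = r[[2]], time_days = r[[3]],
               longest_diameter_mm = r[[4]], stringsAsFactors = FALSE)
  }))
}

test_that("diameter-to-volume conversion follows V = LD^3 / 2", {
  expect_equal(diameter_to_volume(10), 500)
  expect_equal(diameter_to_volume(0), 0)
  expect_equal(diameter_to_volume(20), 4000)
  expect_equal(diameter_to_volume(c(10, 20)), c(500, 4000))
  expect_error(diameter_to_volume(-1), "non-negative")
})

test_that("cohort normalization divides by the cohort-wide maximum", {
  ld <- function(v) (2 * v)^(1 / 3)  # diameter giving raw volume v
  rec <- make_records(
    list("A", "INV-T001", 0, ld(500)), list("A", "INV-T001", 50, ld(1000)),
    list("B", "INV-T001", 0, ld(2000)))
  co <- normalize_cohort(build_series(rec))
  expect_equal(co$v_max, 2000)
  expect_equal(co$series[["A"]]$volumes_norm, c(0.25, 0.5))
  expect_equal(co$series[["B"]]$volumes_norm, 1.0)
  # maximum over cohort is exactly 1
  expect_identical(max(unlist(lapply(co$series, `[[`, "volumes_norm"))), 1)
})

test_that("normalization handles constant series, is idempotent, round-trips", {
  rec <- make_records(list("A", "INV-T001", 0, 2), list("A", "INV-T001", 50, 2))
  co <- normalize_cohort(build_series(rec))
  expect_equal(co$series[[1]]$volumes_norm, c(1, 1))
  co2 <- normalize_cohort(co)  # idempotent: renormalizing changes nothing
  expect_equal(co2$series[[1]]$volumes_norm, co$series[[1]]$volumes_norm)
  expect_equal(co2$v_max, co$v_max)
  # round-trip to raw volumes
  s <- co$series[[1]]
  expect_equal(s$volumes_norm * co$v_max, s$volumes_raw, tolerance = 1e-12)
  # degenerate cohorts
  expect_error(normalize_cohort(build_series(rec[0, ])), "empty")
  zero <- make_records(list("A", "INV-T001", 0, 0))
  expect_error(normalize_cohort(build_series(zero)), "positive volume")
})

test_that("per-study normalization scope uses one constant per study", {
  ld <- function(v) (2 * v)^(1 / 3)
  rec <- rbind(
    data.frame(patient_id = "A", study_id = "S1", arm = "a",
               lesion_id = "INV-T001", time_days = 0,
               longest_diameter_mm = ld(1000)),
    data.frame(patient_id = "B", study_id = "S2", arm = "a",
               lesion_id = "INV-T001", time_days = 0,
               longest_diameter_mm = ld(400)))
  co <- normalize_cohort(build_series(rec), scope = "study")
  expect_equal(co$series[["A"]]$volumes_norm, 1)
  expect_equal(co$series[["B"]]$volumes_norm, 1)
  expect_equal(sort(unname(co$v_max)), c(400, 1000))
})

test_that("target-lesion selection keeps INV-T001, averages duplicates, re-origins time", {
  rec <- make_records(
    list("A", "INV-T001", 30, 10), list("A", "INV-T001", 80, 12),
    list("A", "INV-T002", 30, 50),                 # other lesion ignored
    list("A", "INV-T001", 80, 14),                 # duplicate time, mean 13
    list("B", "INV-T002", 0, 9))                   # lacks target lesion
  expect_warning(co <- build_series(rec), "without usable")
  expect_named(co$series, "A")
  s <- co$series[["A"]]
  expect_equal(s$times, c(0, 50))                  # re-origined to day 0
  expect_equal(s$ld_mm, c(10, 13))                 # (12 + 14) / 2
  expect_equal(s$n_points, 2L)
})

test_that("patients with only shortest-diameter measurements are excluded", {
  rec <- make_records(list("A", "INV-T001", 0, 10), list("A", "INV-T001", 50, 12))
  rec2 <- data.frame(patient_id = "B", study_id = "S1", arm = "arm_A",
                     lesion_id = "INV-T001", time_days = 0,
                     longest_diameter_mm = NA_real_,
                     shortest_diameter_mm = 8)
  rec$shortest_diameter_mm <- NA_real_
  expect_warning(co <- build_series(rbind(rec, rec2)), "without usable")
  expect_named(co$series, "A")
})

test_that("series-length filter keeps exactly the long-enough series, nested", {
  lds <- list(c(10, 11), c(10, 11, 12), rep(10, 6), rep(11, 7))
  co <- cohort_from_ld(lds)
  expect_length(filter_min_points(co, 3)$series, 3L)
  expect_length(filter_min_points(co, 6)$series, 2L)
  expect_length(filter_min_points(co, 1)$series, 4L)
  # the >=6 set is a subset of the >=3 set
  expect_true(all(names(filter_min_points(co, 6)$series) %in%
                    names(filter_min_points(co, 3)$series)))
})

test_that("cohort statistics summarize visit structure", {
  rec <- make_records(
    list("A", "INV-T001", 0, 10), list("A", "INV-T001", 50, 11),
    list("A", "INV-T001", 100, 12))
  st <- cohort_statistics(normalize_cohort(build_series(rec)))
  expect_equal(st$mean_interval_days, 50)
  expect_equal(st$sd_interval_days, 0)
  expect_equal(st$mean_points, 3)
  co2 <- cohort_from_ld(list(c(10, 11, 12), rep(10, 6)))
  expect_equal(cohort_statistics(co2)$mean_points, 4.5)
  expect_error(cohort_statistics(build_series(rec[0, ])), "empty")
})

test_that("delimited round trip and column mapping work", {
  cfg <- synthetic_config(n_patients = 6, seed = 11)
  sim <- simulate_cohort(cfg)
  tmp <- withr::local_tempfile(fileext = ".csv")
  utils::write.csv(sim$records, tmp, row.names = FALSE)
  back <- read_measurements(tmp)
  expect_equal(back$longest_diameter_mm, sim$records$longest_diameter_mm,
               tolerance = 1e-12)
  # column mapping
  renamed <- sim$records
  names(renamed)[names(renamed) == "longest_diameter_mm"] <- "LDIAM"
  tmp2 <- withr::local_tempfile(fileext = ".csv")
  utils::write.csv(renamed, tmp2, row.names = FALSE)
  expect_error(read_measurements(tmp2), "longest_diameter_mm")
  back2 <- read_measurements(tmp2, col_map = c(longest_diameter_mm = "LDIAM"))
  expect_equal(back2$longest_diameter_mm, sim$records$longest_diameter_mm,
               tolerance = 1e-12)
})

test_that("cohort writer emits the CSV plus a JSON sidecar with v_max", {
  co <- cohort_from_ld(list(c(10, 12, 14), c(20, 18)))
  tmp <- withr::local_tempfile(fileext = ".csv")
  paths <- write_cohort(co, tmp, settings = list(min_points = 3))
  expect_true(all(file.exists(paths)))
  side <- jsonlite::read_json(paths[["json"]])
  expect_equal(side$v_max, co$v_max)
  expect_equal(side$min_points, 3)
  tab <- utils::read.csv(paths[["csv"]])
  expect_equal(nrow(tab), 5L)
  expect_equal(max(tab$volume_norm), 1)
})
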