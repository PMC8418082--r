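test_that("aggregate-count summaries reproduce the headline table cells", {
  pc <- paper_counts
  overall <- report_from_counts(pc$overall$detected_fda, pc$overall$cs,
                                pc$overall$fa_fda, pc$overall$hours)
  expect_equal(round(overall$far, 2), 0.83)
  expect_equal(round(overall$csensitivity$estimate, 2), 0.96)
  expect_equal(round(overall$precision$estimate, 2), 0.15)
  ped <- report_from_counts(pc$pediatric$detected_fda, pc$pediatric$cs,
                            pc$pediatric$fa_fda, pc$pediatric$hours)
  expect_equal(round(ped$far, 2), 1.26)
  adu <- report_from_counts(pc$adult$detected_fda, pc$adult$cs,
                            pc$adult$fa_fda, pc$adult$hours)
  expect_equal(round(adu$far, 2), 0.57)
  ped_act <- report_from_counts(32, 35, pc$pediatric$fa_active,
                                pc$pediatric$hours)
  expect_equal(round(ped_act$far, 2), 0.40)
  adu_act <- report_from_counts(31, 31, pc$adult$fa_active, pc$adult$hours)
  expect_equal(round(adu_act$far, 2), 0.18)
})

test_that("p-value rendering follows the <10^-3 convention", {
  expect_equal(format_p(2e-14), "<10^-3")
  expect_equal(format_p(0.177), "0.177")
  expect_equal(format_p(1), "1.000")
})

test_that("group tests: rate comparisons on the printed counts are highly
           significant, identical strata are not", {
  p <- far_ratio_test(207, 3939, 150, 6357)
  expect_lt(p$p_value, 1e-3)
  expect_equal(format_p(p$p_value), "<10^-3")
  same <- far_ratio_test(50, 1000, 50, 1000)
  expect_equal(same$p_value, 1)
})

test_that("the full report covers every stratum-condition-mode cell with
           well-ordered intervals", {
  co <- simulate_event_cohort(cohort_params(n_patients = 50, seed = 19))
  rep <- performance_report(co$sessions, co$rest_intervals,
                            bootstrap_iterations = 1000, seed = 2)
  expect_setequal(unique(rep$condition), c("all_data", "rest"))
  expect_setequal(unique(rep$stratum), c("overall", "pediatric", "adult"))
  expect_setequal(unique(rep$mode), c("FDA_CLEARED", "ACTIVE"))
  has_cs <- !is.na(rep$csensitivity)
  expect_true(all(rep$csens_lower[has_cs] <= rep$csensitivity[has_cs]))
  expect_true(all(rep$csens_upper[has_cs] >= rep$csensitivity[has_cs]))
  hasfar <- !is.na(rep$far_lower)
  expect_true(all(rep$far_lower[hasfar] <= rep$far[hasfar] + 1e-9))
  expect_true(all(rep$far_upper[hasfar] >= rep$far[hasfar] - 1e-9))
  # overall counts decompose over age strata within each condition/mode
  for (cond in c("all_data", "rest")) {
    for (m in c("FDA_CLEARED", "ACTIVE")) {
      sel <- rep$condition == cond & rep$mode == m
      ov <- rep[sel & rep$stratum == "overall", ]
      parts <- rep[sel & rep$stratum != "overall", ]
      expect_equal(sum(parts$false_alarms), ov$false_alarms)
      expect_equal(sum(parts$total_cs), ov$total_cs)
      expect_equal(sum(parts$hours), ov$hours, tolerance = 1e-9)
    }
  }
  gt <- group_tests(co$sessions, co$rest_intervals)
  expect_equal(nrow(gt), 8L)
  expect_true(all(gt$p_value >= 0 & gt$p_value <= 1, na.rm = TRUE))
})

test_that("the file pipeline adjudicates, scores and writes reports", {
  set.seed(61)
  co <- simulate_event_cohort(cohort_params(n_patients = 12, p_seizing = 0.5,
                                            seed = 61))
  dir <- withr::local_tempdir()
  sess_file <- file.path(dir, "sessions.json")
  # strip seizures/alarms: the pipeline re-derives them from the files
  bare <- lapply(co$sessions, function(s) {
    recording_session(s$patient_id, s$age_years, s$device, s$wear_intervals)
  })
  write_sessions(bare, sess_file)
  truth <- do.call(rbind, lapply(co$sessions, function(s) {
    if (!nrow(s$seizures)) return(NULL)
    data.frame(patient_id = s$patient_id, onset = s$seizures$onset,
               offset = s$seizures$offset, type = s$seizures$type)
  }))
  ann <- reviewer_noise(truth, jitter_sd = 2, miss_prob = 0.05, seed = 9)
  ann_file <- file.path(dir, "annotations.csv")
  write.csv(data.frame(reviewer_id = ann$reviewer_id,
                       patient_id = ann$patient_id,
                       clinical_onset = ann$onset,
                       clinical_offset = ann$offset,
                       seizure_type = ann$seizure_type),
            ann_file, row.names = FALSE)
  al <- do.call(rbind, lapply(co$sessions, function(s) {
    if (!nrow(s$alarms)) return(NULL)
    data.frame(patient_id = s$patient_id, timestamp = s$alarms$time,
               mode = s$alarms$mode)
  }))
  al_file <- file.path(dir, "alarms.csv")
  write.csv(al, al_file, row.names = FALSE)

  rep <- run_pipeline(sess_file, ann_file, al_file, file.path(dir, "out"),
                      bootstrap_iterations = 500, seed = 3)
  expect_true(file.exists(file.path(dir, "out", "report.csv")))
  expect_true(file.exists(file.path(dir, "out", "stats_report.json")))
  expect_gt(rep$total_cs[rep$stratum == "overall" &
                           rep$mode == "FDA_CLEARED"], 0)
  js <- jsonlite::read_json(file.path(dir, "out", "stats_report.json"))
  expect_equal(js$config$seed, 3)

  # an empty alarm file zeroes FAR and sensitivity everywhere
  write.csv(data.frame(patient_id = character(0), timestamp = numeric(0),
                       mode = character(0)),
            al_file, row.names = FALSE)
  rep0 <- run_pipeline(sess_file, ann_file, al_file, file.path(dir, "out0"),
                       bootstrap_iterations = 0, seed = 3)
  expect_true(all(rep0$far == 0))
  expect_true(all(rep0$sensitivity == 0, na.rm = TRUE))
})

test_that("rendered report values are the statistics rounded to 2 decimals", {
  co <- simulate_event_cohort(cohort_params(n_patients = 10, p_seizing = 0.5,
                                            seed = 77))
  rep <- performance_report(co$sessions)
  rendered <- round(rep$far, 2)
  expect_true(all(abs(rendered - rep$far) <= 0.005 + 1e-12))
})
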