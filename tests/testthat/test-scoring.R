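session_with <- function(seizures = NULL, alarm_times = numeric(0),
                         hours = 24, mode = "FDA_CLEARED") {
  alarms <- if (length(alarm_times)) {
    data.frame(time = alarm_times, mode = mode)
  } else NULL
  recording_session("p1", 30, "E4",
                    data.frame(start = 0, end = hours * 3600),
                    alarms = alarms, seizures = seizures)
}

gtc <- function(onset, offset) {
  data.frame(onset = onset, offset = offset, type = "GTC", n_supporting = 3L)
}

test_that("first in-seizure alarm is the true positive, later ones absorbed", {
  s <- session_with(gtc(100, 180), c(137, 150))
  sc <- score_session(s)
  expect_equal(sc$n_detected, 1L)
  expect_equal(sc$latencies, 37)
  expect_equal(sc$n_false_alarms, 0L)
})

test_that("alarms with no seizure are all false alarms", {
  sc <- score_session(session_with(NULL, c(1000, 2000, 3000)))
  expect_equal(sc$n_detected, 0L)
  expect_equal(sc$n_false_alarms, 3L)
})

test_that("a pre-onset alarm misses the seizure (half-open boundary)", {
  sc <- score_session(session_with(gtc(100, 180), 99.9))
  expect_equal(sc$n_detected, 0L)
  expect_equal(sc$n_false_alarms, 1L)
  # an alarm exactly at the offset is also outside the event
  sc2 <- score_session(session_with(gtc(100, 180), 180))
  expect_equal(sc2$n_detected, 0L)
  expect_equal(sc2$n_false_alarms, 1L)
  # at onset it is inside, latency 0
  sc3 <- score_session(session_with(gtc(100, 180), 100))
  expect_equal(sc3$n_detected, 1L)
  expect_equal(sc3$latencies, 0)
})

test_that("score_session agrees with the brute-force pair enumerator", {
  set.seed(123)
  for (i in 1:200) {
    s <- random_session(sprintf("bf%d", i))
    got <- score_session(s)
    want <- brute_force_score(s$seizures, s$alarms$time)
    expect_equal(got$n_detected, want$n_detected)
    expect_equal(sort(got$latencies), want$latencies)
    expect_equal(got$n_false_alarms, want$n_false_alarms)
    expect_equal(got$n_detected + (got$n_seizures - got$n_detected),
                 got$n_seizures)
  }
})

test_that("latency summary returns mean, sample sd and median", {
  s1 <- session_with(gtc(0, 100), 30)
  s2 <- session_with(gtc(0, 100), 40)
  s3 <- session_with(gtc(0, 100), 50)
  cs <- cohort_score(lapply(list(s1, s2, s3), score_session))
  lat <- latency_summary(cs)
  expect_equal(lat$mean, 40)
  expect_equal(lat$sd, 10)
  expect_equal(lat$median, 40)
  single <- cohort_score(list(score_session(session_with(gtc(0, 100), 37))))
  lsingle <- latency_summary(single)
  expect_equal(lsingle$mean, 37)
  expect_equal(lsingle$sd, 0)
  expect_true(lsingle$degenerate)
  none <- cohort_score(list(score_session(session_with(gtc(0, 100)))))
  expect_error(latency_summary(none), "latency undefined")
})

test_that("pooled FAR is exposure-homogeneous", {
  sessions <- lapply(1:5, function(i) counts_session(paste0("h", i), 24, i))
  far1 <- pooled_far(score_cohort(sessions))
  doubled <- lapply(1:5, function(i) counts_session(paste0("d", i), 48, i))
  far2 <- pooled_far(score_cohort(doubled))
  expect_equal(far2, far1 / 2)
})

test_that("age and rest strata partition the cohort totals", {
  co <- simulate_event_cohort(cohort_params(n_patients = 40, seed = 21))
  overall <- score_cohort(co$sessions, mode = "FDA_CLEARED")
  age <- stratify_age(co$sessions)
  byage <- lapply(age, score_cohort, mode = "FDA_CLEARED")
  for (f in c("seizures", "detected", "false_alarms", "hours")) {
    expect_equal(byage$pediatric$totals[[f]] + byage$adult$totals[[f]],
                 overall$totals[[f]], tolerance = 1e-9)
  }
  st <- stratify_rest(co$sessions, co$rest_intervals)
  byrest <- lapply(st, score_cohort, mode = "FDA_CLEARED")
  for (f in c("seizures", "detected", "false_alarms", "hours")) {
    expect_equal(byrest$rest$totals[[f]] + byrest$active$totals[[f]],
                 overall$totals[[f]], tolerance = 1e-9)
  }
})

test_that("rest stratum membership is decided by clinical onset", {
  seiz <- gtc(3500, 3700)                    # onset in rest, offset outside
  s <- session_with(seiz, 3550)
  rest <- data.frame(start = 0, end = 3600)
  r <- restrict_session(s, rest)
  expect_equal(nrow(r$seizures), 1L)
  a <- restrict_session(s, rest, complement = TRUE)
  expect_equal(nrow(a$seizures), 0L)
  # all-rest session contributes nothing to the active stratum
  allrest <- restrict_session(s, data.frame(start = 0, end = 24 * 3600),
                              complement = TRUE)
  expect_null(allrest)
})

test_that("mode filtering scores only the requested operating point", {
  alarms <- data.frame(time = c(150, 150, 5000),
                       mode = c("FDA_CLEARED", "ACTIVE", "FDA_CLEARED"))
  s <- recording_session("p1", 30, "E4", data.frame(start = 0, end = 86400),
                         alarms = alarms, seizures = gtc(100, 180))
  fda <- score_session(s, "FDA_CLEARED")
  act <- score_session(s, "ACTIVE")
  expect_equal(fda$n_detected, 1L)
  expect_equal(fda$n_false_alarms, 1L)
  expect_equal(act$n_detected, 1L)
  expect_equal(act$n_false_alarms, 0L)
})
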