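# Report generation: performance tables over the overall / pediatric / adult
# strata, for all data and for automatically detected rest, at each operating
# point, plus the group-comparison table. Values are kept unrounded until
# rendering (round half to even at 2 decimals).

#' Performance summary from aggregate counts
#'
#' Computes the headline statistics that depend only on pooled counts:
#' pooled sensitivity, cluster-corrected sensitivity under a supplied
#' design effect (as the Wilson midpoint on effective counts), precision
#' (with the Laplace rule-of-succession fallback at zero false alarms),
#' and the FAR per 24 h worn.
#'
#' @param detected detected consensus seizures.
#' @param total_cs total consensus seizures.
#' @param false_alarms total false alarms.
#' @param hours total worn hours.
#' @param design_effect variance-inflation factor (default 1).
#' @param confidence confidence level.
#' @return list of `sensitivity`, `csensitivity` (`interval_estimate`),
#'   `precision` (`interval_estimate`), `far`, `far_reduction_vs` helper
#'   fields.
#' @export
report_from_counts <- function(detected, total_cs, false_alarms, hours,
                               design_effect = 1, confidence = 0.95) {
  stopifnot(total_cs >= 1, hours > 0, design_effect >= 1)
  cs <- wilson(detected / design_effect, total_cs / design_effect, confidence)
  cs$method <- "WILSON_CLUSTER"
  list(sensitivity = detected / total_cs,
       csensitivity = cs,
       precision = precision_estimate(detected, false_alarms, confidence),
       far = 24 * false_alarms / hours,
       detected = detected, total_cs = total_cs,
       false_alarms = false_alarms, hours = hours)
}

#' Relative false-alarm reduction between two operating modes
#'
#' @param fa_reference false alarms at the reference (more sensitive)
#'   mode.
#' @param fa_alternative false alarms at the alternative mode.
#' @return percentage reduction `100 * (1 - fa_alternative /
#'   fa_reference)`.
#' @export
far_reduction_pct <- function(fa_reference, fa_alternative) {
  stopifnot(fa_reference > 0)
  100 * (1 - fa_alternative / fa_reference)
}

summarise_stratum <- function(sessions, mode, confidence = 0.95,
                              bootstrap_iterations = 0, seed = NULL) {
  if (!length(sessions)) return(NULL)
  cs <- score_cohort(sessions, mode = mode)
  tot <- cs$totals
  out <- list(
    n_patients = nrow(cs$sessions),
    n_with_cs = sum(cs$sessions$n_seizures > 0),
    hours = tot$hours,
    mean_hours_pooled = tot$hours / nrow(cs$sessions),
    total_cs = tot$seizures,
    mean_duration = cs$mean_cs_duration,
    sd_duration = cs$sd_cs_duration,
    detected = tot$detected,
    false_alarms = tot$false_alarms,
    far = if (tot$hours > 0) 24 * tot$false_alarms / tot$hours else NA_real_)
  if (tot$seizures > 0) {
    out$sensitivity <- pooled_sensitivity(cs)
    cse <- corrected_sensitivity(cluster_outcomes(cs), confidence)
    out$csensitivity <- cse$estimate
    out$csens_lower <- cse$lower; out$csens_upper <- cse$upper
    if (tot$detected > 0) {
      pr <- precision_estimate(tot$detected, tot$false_alarms, confidence)
      out$precision <- pr$estimate
      out$prec_lower <- pr$lower; out$prec_upper <- pr$upper
      lat <- latency_summary(cs)
      out$mean_delay <- lat$mean; out$sd_delay <- lat$sd
      out$median_delay <- lat$median
    }
  }
  if (bootstrap_iterations > 0 && nrow(cs$sessions) > 1) {
    bs <- far_bootstrap_ci(cs$sessions$n_false_alarms, cs$sessions$hours,
                           n_iterations = bootstrap_iterations,
                           confidence = confidence, seed = seed)
    out$far_lower <- bs$lower; out$far_upper <- bs$upper
  }
  out
}

#' Performance report over strata, conditions, and operating modes
#'
#' Mirrors the study's summary-table layout: strata overall / pediatric /
#' adult crossed with all-data / rest conditions and both operating
#' modes, each cell traceable to one scoring or inference operation.
#'
#' @param sessions list of [recording_session()].
#' @param rest_list optional list of rest-interval tables parallel to
#'   `sessions`; when supplied, rest-condition rows are included.
#' @param modes operating-mode names to report.
#' @param confidence confidence level.
#' @param bootstrap_iterations patient-level bootstrap replicates for the
#'   FAR interval (0 to skip).
#' @param seed bootstrap seed.
#' @return long-format `data.frame`: one row per (condition, stratum,
#'   mode) with all summary statistics.
#' @export
performance_report <- function(sessions, rest_list = NULL,
                               modes = c("FDA_CLEARED", "ACTIVE"),
                               confidence = 0.95,
                               bootstrap_iterations = 0, seed = NULL) {
  conditions <- list(all_data = sessions)
  if (!is.null(rest_list)) {
    conditions$rest <- stratify_rest(sessions, rest_list)$rest
  }
  rows <- list()
  for (cond in names(conditions)) {
    ses <- conditions[[cond]]
    strata <- c(list(overall = ses), stratify_age(ses))
    for (st in names(strata)) {
      for (mode in modes) {
        s <- summarise_stratum(strata[[st]], mode, confidence,
                               bootstrap_iterations, seed)
        if (is.null(s)) next
        row <- data.frame(condition = cond, stratum = st, mode = mode)
        for (nm in names(s)) row[[nm]] <- s[[nm]]
        rows[[length(rows) + 1L]] <- row
      }
    }
  }
  nm <- unique(unlist(lapply(rows, names)))
  rows <- lapply(rows, function(r) {
    r[setdiff(nm, names(r))] <- NA
    r[nm]
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Format a p-value with the `< 10^-3` convention
#'
#' @param p p-value.
#' @return character: `"<10^-3"` below 0.001, otherwise three decimals.
#' @export
format_p <- function(p) {
  ifelse(p < 1e-3, "<10^-3", sprintf("%.3f", p))
}

#' Group-comparison table (sensitivity and FAR tests)
#'
#' For each operating mode: the cluster-corrected sensitivity difference
#' test and the exposure-adjusted FAR ratio test, children vs adults and
#' rest vs active.
#'
#' @param sessions list of [recording_session()].
#' @param rest_list list of rest-interval tables parallel to `sessions`.
#' @param modes operating-mode names.
#' @param confidence confidence level.
#' @return `data.frame(mode, variable, groups, p_value, p_rendered)`;
#'   comparisons whose strata are missing are skipped with a note column.
#' @export
group_tests <- function(sessions, rest_list,
                        modes = c("FDA_CLEARED", "ACTIVE"),
                        confidence = 0.95) {
  age <- stratify_age(sessions)
  rest <- stratify_rest(sessions, rest_list)
  rows <- list()
  add <- function(mode, variable, groups, p, note = NA_character_) {
    rows[[length(rows) + 1L]] <<- data.frame(
      mode = mode, variable = variable, groups = groups,
      p_value = p, p_rendered = if (is.na(p)) NA_character_ else format_p(p),
      note = note)
  }
  for (mode in modes) {
    pairs <- list(
      list(var = "cSensitivity", groups = "children_vs_adults",
           a = age$pediatric, b = age$adult),
      list(var = "cSensitivity", groups = "rest_vs_active",
           a = rest$rest, b = rest$active),
      list(var = "FAR_ratio", groups = "children_vs_adults",
           a = age$pediatric, b = age$adult),
      list(var = "FAR_ratio", groups = "rest_vs_active",
           a = rest$rest, b = rest$active))
    for (pr in pairs) {
      if (!length(pr$a) || !length(pr$b)) {
        add(mode, pr$var, pr$groups, NA_real_, "stratum missing")
        next
      }
      ca <- score_cohort(pr$a, mode = mode)
      cb <- score_cohort(pr$b, mode = mode)
      if (pr$var == "cSensitivity") {
        oa <- cluster_outcomes(ca); ob <- cluster_outcomes(cb)
        if (!nrow(oa) || !nrow(ob)) {
          add(mode, pr$var, pr$groups, NA_real_, "no events in a stratum")
          next
        }
        add(mode, pr$var, pr$groups,
            clustered_diff_test(oa, ob, confidence)$p_value)
      } else {
        add(mode, pr$var, pr$groups,
            far_ratio_test(ca$totals$false_alarms, ca$totals$hours,
                           cb$totals$false_alarms, cb$totals$hours)$p_value)
      }
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Run the full evaluation pipeline from interchange files
#'
#' Reads sessions, reviewer annotations and alarms; adjudicates consensus
#' seizures; attaches seizures and alarms to the sessions; scores both
#' operating modes; and writes `report.csv` and `stats_report.json` to
#' `out_dir`. Every configuration value and seed is recorded in the JSON.
#'
#' @param sessions_file sessions JSON (see [write_sessions()]).
#' @param annotations_file reviewer annotations CSV.
#' @param alarms_file alarms CSV.
#' @param out_dir output directory (created if needed).
#' @param adjudication an [adjudication_config()].
#' @param confidence confidence level.
#' @param bootstrap_iterations bootstrap replicates for FAR intervals.
#' @param seed integer seed.
#' @return the report `data.frame`, invisibly; side effect: files in
#'   `out_dir`.
#' @export
run_pipeline <- function(sessions_file, annotations_file, alarms_file,
                         out_dir, adjudication = adjudication_config(),
                         confidence = 0.95, bootstrap_iterations = 10000,
                         seed = 1L) {
  sessions <- read_sessions(sessions_file)
  anns <- read_annotations(annotations_file)
  alarms <- read_alarms(alarms_file)
  consensus <- adjudicate(anns, adjudication)
  sessions <- lapply(sessions, function(s) {
    se <- consensus[consensus$patient_id == s$patient_id, , drop = FALSE]
    al <- alarms[alarms$patient_id == s$patient_id, c("time", "mode")]
    recording_session(s$patient_id, s$age_years, s$device, s$wear_intervals,
                      alarms = if (nrow(al)) al else NULL,
                      seizures = if (nrow(se)) se else NULL, sex = s$sex)
  })
  rep <- performance_report(sessions, confidence = confidence,
                            bootstrap_iterations = bootstrap_iterations,
                            seed = seed)
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  rendered <- rep
  num <- vapply(rendered, is.numeric, logical(1))
  rendered[num] <- lapply(rendered[num], round, digits = 2)
  utils::write.csv(rendered, file.path(out_dir, "report.csv"),
                   row.names = FALSE)
  jsonlite::write_json(
    list(config = list(confidence = confidence,
                       bootstrap_iterations = bootstrap_iterations,
                       seed = seed,
                       min_supporting = adjudication$min_supporting,
                       consensus_time = adjudication$consensus_time),
         consensus_seizures = nrow(consensus),
         report = rep),
    file.path(out_dir, "stats_report.json"),
    auto_unbox = TRUE, digits = NA, na = "null")
  invisible(rep)
}
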