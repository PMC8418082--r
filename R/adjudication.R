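# Consensus adjudication: three independent reviewers each annotate seizure
# intervals from video-EEG; an event enters the reference standard only if
# at least 2 of the 3 reviewers marked it (a "2 out of 3" majority rule).

#' Adjudication configuration
#'
#' @param min_supporting minimum number of reviewers that must mark an
#'   event (2 = majority rule, 3 = unanimity).
#' @param consensus_time how supporting onsets/offsets are pooled:
#'   `"median"` (element-wise median, robust with three raters) or
#'   `"earliest"` (earliest onset and earliest offset).
#' @param require_type_agreement if `TRUE` (default) the supporting
#'   reviewers must agree on the seizure type (a 2-of-3 type majority
#'   decides); if `FALSE`, agreement on presence alone suffices and the
#'   majority type is attached.
#' @return an `adjudication_config` list.
#' @export
adjudication_config <- function(min_supporting = 2L,
                                consensus_time = c("median", "earliest"),
                                require_type_agreement = TRUE) {
  min_supporting <- as.integer(min_supporting)
  if (!min_supporting %in% c(2L, 3L)) stop("min_supporting must be 2 or 3")
  structure(list(min_supporting = min_supporting,
                 consensus_time = match.arg(consensus_time),
                 require_type_agreement = isTRUE(require_type_agreement)),
            class = "adjudication_config")
}

# transitive-closure grouping of overlapping half-open intervals; input must
# be sorted by onset. Returns an integer group id per row.
overlap_groups <- function(onset, offset) {
  n <- length(onset)
  grp <- integer(n)
  if (!n) return(grp)
  grp[1] <- 1L
  reach <- offset[1]
  for (i in seq_len(n)[-1]) {
    if (onset[i] < reach) {
      grp[i] <- grp[i - 1L]
      reach <- max(reach, offset[i])
    } else {
      grp[i] <- grp[i - 1L] + 1L
      reach <- offset[i]
    }
  }
  grp
}

#' Merge reviewer annotations into consensus seizures
#'
#' Annotations of one patient are grouped by temporal overlap (transitive
#' closure of pairwise intersection of the half-open intervals). A group
#' becomes a consensus seizure when at least `min_supporting` distinct
#' reviewers contributed and, under type agreement, at least
#' `min_supporting` of them agree on the same convulsive type; the
#' majority type wins. Consensus onset/offset are pooled per the
#' `consensus_time` rule over the supporting annotations. Only convulsive
#' types (GTC, FBTC) can form consensus events; other annotated types are
#' carried in but never emitted.
#'
#' @param annotations `data.frame` with columns `reviewer_id`,
#'   `patient_id`, `onset`, `offset`, `seizure_type` (see
#'   [read_annotations()]).
#' @param config an [adjudication_config()].
#' @return `data.frame(patient_id, onset, offset, type, n_supporting)`,
#'   sorted by patient then onset.
#' @export
adjudicate <- function(annotations, config = adjudication_config()) {
  stopifnot(inherits(config, "adjudication_config"))
  need <- c("reviewer_id", "patient_id", "onset", "offset", "seizure_type")
  miss <- setdiff(need, names(annotations))
  if (length(miss)) stop("missing columns: ", paste(miss, collapse = ", "))
  if (length(unique(annotations$reviewer_id)) > 3L) {
    stop("more than 3 reviewer ids present")
  }

  out <- lapply(split(annotations, annotations$patient_id), function(a) {
    a <- a[order(a$onset), , drop = FALSE]
    # each reviewer's own events must be non-overlapping
    for (r in unique(a$reviewer_id)) {
      ar <- a[a$reviewer_id == r, , drop = FALSE]
      if (nrow(ar) > 1L && any(ar$onset[-1L] < ar$offset[-nrow(ar)])) {
        stop(sprintf("reviewer %s has overlapping annotations for patient %s",
                     r, a$patient_id[1]))
      }
    }
    grp <- overlap_groups(a$onset, a$offset)
    res <- lapply(unique(grp), function(g) {
      ag <- a[grp == g, , drop = FALSE]
      if (length(unique(ag$reviewer_id)) < config$min_supporting) return(NULL)
      # votes per convulsive type: distinct reviewers marking that type
      votes <- vapply(CS_TYPES, function(ty)
        length(unique(ag$reviewer_id[ag$seizure_type == ty])), integer(1))
      if (config$require_type_agreement) {
        if (max(votes) < config$min_supporting) return(NULL)
        ty <- CS_TYPES[which.max(votes)]
        sup <- ag[ag$seizure_type == ty, , drop = FALSE]
      } else {
        sup <- ag[ag$seizure_type %in% CS_TYPES, , drop = FALSE]
        if (length(unique(sup$reviewer_id)) < config$min_supporting) return(NULL)
        ty <- CS_TYPES[which.max(votes)]
      }
      pool <- switch(config$consensus_time,
                     median = c(stats::median(sup$onset), stats::median(sup$offset)),
                     earliest = c(min(sup$onset), min(sup$offset)))
      if (pool[2] <= pool[1]) pool[2] <- max(sup$offset)
      data.frame(patient_id = a$patient_id[1],
                 onset = pool[1], offset = pool[2], type = ty,
                 n_supporting = length(unique(sup$reviewer_id)))
    })
    res <- res[!vapply(res, is.null, logical(1))]
    if (!length(res)) return(NULL)
    do.call(rbind, res)
  })
  out <- out[!vapply(out, is.null, logical(1))]
  if (!length(out)) {
    return(data.frame(patient_id = character(0), onset = numeric(0),
                      offset = numeric(0), type = character(0),
                      n_supporting = integer(0)))
  }
  res <- do.call(rbind, out)
  res <- res[order(res$patient_id, res$onset), , drop = FALSE]
  rownames(res) <- NULL
  res
}
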