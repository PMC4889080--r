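# Per-subject session extraction; sessions come back sorted by age.
subject_sessions <- function(cohort, subject) {
  s <- cohort$sessions
  si <- s[s$subject_id == subject, , drop = FALSE]
  if (nrow(si) == 0) stop("unknown subject: ", subject)
  si[order(si$age_weeks), , drop = FALSE]
}

session_rates <- function(si, code) {
  si[[code]] / (si$duration_minutes / 60)
}

#' Milestone initiation age
#'
#' The age of the earliest session at which the behavior was observed
#' (count > 0) or, for a locomotor stage, at which the stage flag is
#' `TRUE`. `NA` (censored) if never observed within the follow-up window.
#' A behavior already present at the subject's very first session is
#' returned with a left-censoring warning attached (attribute
#' `left_censored`), not excluded.
#'
#' @param cohort An [rr_cohort()].
#' @param subject Subject id.
#' @param code A behavior code or locomotor stage.
#' @return Age in weeks (possibly `NA`), with attribute `left_censored`.
#' @export
detect_initiation <- function(cohort, subject, code) {
  si <- subject_sessions(cohort, subject)
  hit <- if (is_stage(code)) which(as.logical(si[[code]]))
         else which(si[[code]] > 0)
  if (length(hit) == 0)
    return(structure(NA_real_, left_censored = FALSE))
  age <- si$age_weeks[hit[1]]
  lc <- hit[1] == 1L
  if (lc)
    warning(sprintf("subject %s: %s already present at first session (age %g); initiation age is left-censored",
                    subject, code, age))
  structure(age, left_censored = lc)
}

#' Pre-anchor peak rate
#'
#' The maximum observed rate (counts/hour) over all sessions strictly
#' before `anchor_age`, with ties broken by the earliest age. Errors if
#' the subject has no session before the anchor: that subject must be
#' excluded from the corresponding peak-vs-emergence contrast.
#'
#' @inheritParams detect_initiation
#' @param anchor_age Anchor milestone age in weeks.
#' @return Named list `peak_age`, `peak_rate`.
#' @export
detect_peak <- function(cohort, subject, code, anchor_age) {
  si <- subject_sessions(cohort, subject)
  pre <- si[si$age_weeks < anchor_age, , drop = FALSE]
  if (nrow(pre) == 0)
    stop(sprintf("subject %s has no session before anchor age %g; exclude from this contrast",
                 subject, anchor_age))
  r <- session_rates(pre, code)
  i <- which.max(r)  # which.max returns the first (earliest) maximum
  list(peak_age = pre$age_weeks[i], peak_rate = r[i])
}

#' Observed rate at an exact session age
#'
#' Counts/hour at the subject's session at exactly `age` (no
#' interpolation: all quantities are defined at observed sessions only).
#'
#' @inheritParams detect_peak
#' @param age Session age in weeks; must match an observed session.
#' @return Rate in counts/hour.
#' @export
rate_at <- function(cohort, subject, code, age) {
  si <- subject_sessions(cohort, subject)
  i <- which(abs(si$age_weeks - age) < 1e-8)
  if (length(i) != 1)
    stop(sprintf("subject %s has no session at age %g (no interpolation)", subject, age))
  session_rates(si[i, , drop = FALSE], code)
}

#' Post-anchor rebound rate
#'
#' The maximum rate over sessions strictly after `anchor_age`; `NA` if no
#' later session exists.
#'
#' @inheritParams detect_peak
#' @return Rate in counts/hour, or `NA`.
#' @export
detect_rebound <- function(cohort, subject, code, anchor_age) {
  si <- subject_sessions(cohort, subject)
  post <- si[si$age_weeks > anchor_age, , drop = FALSE]
  if (nrow(post) == 0) return(NA_real_)
  max(session_rates(post, code))
}

#' Milestone table for a cohort
#'
#' One record per subject x tracked milestone (all behavior codes and
#' locomotor stages): initiation age (with censoring flags), and — for
#' behaviors wired to an anchor milestone (see [anchor_wiring()]) — the
#' pre-anchor peak, the rate at the anchor session, and the post-anchor
#' rebound. Censored anchors propagate `NA`.
#'
#' @param cohort An [rr_cohort()].
#' @return data.frame with columns `subject_id`, `code`,
#'   `initiation_age_weeks`, `left_censored`, `censored`, `anchor`,
#'   `anchor_age_weeks`, `peak_age_weeks`, `peak_rate`, `rate_at_anchor`,
#'   `rebound_rate`, plus (repeated per subject) `all_pre_walking`:
#'   whether all four symbolic levels and single-word utterances emerged
#'   before walking.
#' @export
milestone_table <- function(cohort) {
  stopifnot(inherits(cohort, "rr_cohort"))
  subjects <- unique(cohort$sessions$subject_id)
  wiring <- anchor_wiring()
  out <- vector("list", length(subjects))
  s_all <- cohort$sessions
  for (k in seq_along(subjects)) {
    id <- subjects[k]
    # single-subject view so the per-operation subsetting stays cheap
    mini <- structure(list(
      sessions = s_all[s_all$subject_id == id, , drop = FALSE]),
      class = "rr_cohort")
    init <- numeric(0); lc <- logical(0)
    for (m in all_milestones()) {
      a <- withCallingHandlers(detect_initiation(mini, id, m),
                               warning = function(w) invokeRestart("muffleWarning"))
      init[m] <- as.numeric(a)
      lc[m] <- attr(a, "left_censored")
    }
    pre_walk <- !is.na(init["WALKING"]) &&
      all(!is.na(init[c("SYMB1", "SYMB2", "SYMB3", "SYMB4", "VERB2")])) &&
      all(init[c("SYMB1", "SYMB2", "SYMB3", "SYMB4", "VERB2")] < init["WALKING"])
    rec <- data.frame(subject_id = id, code = all_milestones(),
                      initiation_age_weeks = unname(init),
                      left_censored = unname(lc),
                      censored = is.na(unname(init)),
                      anchor = NA_character_, anchor_age_weeks = NA_real_,
                      peak_age_weeks = NA_real_, peak_rate = NA_real_,
                      rate_at_anchor = NA_real_, rebound_rate = NA_real_,
                      all_pre_walking = pre_walk,
                      stringsAsFactors = FALSE)
    for (code in names(wiring)) {
      i <- match(code, rec$code)
      anchor_m <- unname(wiring[code])
      rec$anchor[i] <- anchor_m
      a <- init[[anchor_m]]
      if (is.na(a)) next  # censored anchor propagates NA fields
      rec$anchor_age_weeks[i] <- a
      pk <- tryCatch(detect_peak(mini, id, code, a), error = function(e) NULL)
      if (!is.null(pk)) {
        rec$peak_age_weeks[i] <- pk$peak_age
        rec$peak_rate[i] <- pk$peak_rate
      }
      rec$rate_at_anchor[i] <- rate_at(mini, id, code, a)
      rec$rebound_rate[i] <- detect_rebound(mini, id, code, a)
    }
    out[[k]] <- rec
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
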