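#' Event-aligned two-point rate change
#'
#' The change coefficient \eqn{\Delta X/\Delta t}: the difference between
#' a behavior's rate at the anchor session and at the immediately
#' preceding session, divided by the actual gap between those sessions in
#' weeks (2 in the bi-weekly phase, 3 in the tri-weekly phase). A fixed
#' nominal gap can be forced via `fixed_dt_weeks` to reproduce the
#' constant-interval reading of the design.
#'
#' @param cohort An [rr_cohort()].
#' @param subject Subject id.
#' @param code Behavior code.
#' @param anchor_age Age of the anchor session (must be an observed
#'   session age for the subject).
#' @param fixed_dt_weeks Optional fixed \eqn{\Delta t} in weeks replacing
#'   the actual inter-session gap in the denominator.
#' @return Rate change per week; `NA` (censored) if the anchor is the
#'   subject's first session, so no preceding observation exists.
#' @export
event_aligned_delta <- function(cohort, subject, code, anchor_age,
                                fixed_dt_weeks = NULL) {
  si <- subject_sessions(cohort, subject)
  i <- which(abs(si$age_weeks - anchor_age) < 1e-8)
  if (length(i) != 1)
    stop(sprintf("subject %s has no session at anchor age %g", subject, anchor_age))
  if (i == 1L) return(NA_real_)
  r <- session_rates(si, code)
  dt <- if (is.null(fixed_dt_weeks)) si$age_weeks[i] - si$age_weeks[i - 1L]
        else fixed_dt_weeks
  (r[i] - r[i - 1L]) / dt
}

#' Resource-reallocation composite
#'
#' `RR = d_sp2 - (d_symb2 - d_symb3)`: the net of the speech rate change
#' at the walking transition against the difference between the
#' single-object-sequence change at word onset and the multi-object-play
#' change at complex-play onset. Any censored (`NA`) component censors
#' the result.
#'
#' @param d_sp2 Speech (single-word utterance) rate change per week at
#'   the walking transition.
#' @param d_symb2 Single-object-sequence rate change at word onset.
#' @param d_symb3 Multi-object-play rate change at complex-play onset.
#' @return `d_sp2 - d_symb2 + d_symb3`, vectorized; `NA` propagates.
#' @export
#' @examples
#' compute_rr(1.0, -2.0, -0.5)  # 2.5
compute_rr <- function(d_sp2, d_symb2, d_symb3) {
  d_sp2 - d_symb2 + d_symb3
}

#' Per-subject change coefficients and RR
#'
#' Computes, for every subject, the event-aligned deltas at their own
#' milestone sessions: the speech delta at the walking session (Tw), the
#' single-object-sequence delta at the word-onset session (Tl), the
#' multi-object-play delta at the complex-play-onset session (Ts), the
#' social-bid deltas (anchored at word onset by default, configurable to
#' walking), and the RR composite. Subjects with a censored required
#' anchor carry censored (`NA`) coefficients.
#'
#' @param cohort An [rr_cohort()].
#' @param milestones Output of [milestone_table()]; computed if omitted.
#' @param fixed_dt_weeks See [event_aligned_delta()].
#' @param soc_anchor Anchor milestone for the social-bid deltas:
#'   `"VERB2"` (word onset, default) or `"WALKING"`.
#' @return data.frame with one row per subject: `subject_id`, `d_sp2`,
#'   `d_symb2`, `d_symb3`, `d_soc_infant`, `d_soc_mother`, `rr`,
#'   `rr_censored`, and the anchor ages `t_walk`, `t_lang`, `t_seq`.
#' @export
coefficients_table <- function(cohort, milestones = NULL,
                               fixed_dt_weeks = NULL,
                               soc_anchor = c("VERB2", "WALKING")) {
  stopifnot(inherits(cohort, "rr_cohort"))
  soc_anchor <- match.arg(soc_anchor)
  if (is.null(milestones)) milestones <- milestone_table(cohort)
  subjects <- unique(milestones$subject_id)

  init_of <- function(id, m) {
    v <- milestones$initiation_age_weeks[milestones$subject_id == id &
                                           milestones$code == m]
    if (length(v) == 0) NA_real_ else v[1]
  }
  s_all <- cohort$sessions
  rows <- lapply(subjects, function(id) {
    mini <- structure(list(
      sessions = s_all[s_all$subject_id == id, , drop = FALSE]),
      class = "rr_cohort")
    delta_or_na <- function(id, code, anchor) {
      if (is.na(anchor)) return(NA_real_)
      event_aligned_delta(mini, id, code, anchor, fixed_dt_weeks)
    }
    tw <- init_of(id, "WALKING")
    tl <- init_of(id, "VERB2")
    ts <- init_of(id, "SYMB4")
    t_soc <- if (soc_anchor == "VERB2") tl else tw
    d_sp2 <- delta_or_na(id, "VERB2", tw)
    d_symb2 <- delta_or_na(id, "SYMB2", tl)
    d_symb3 <- delta_or_na(id, "SYMB3", ts)
    data.frame(subject_id = id,
               d_sp2 = d_sp2, d_symb2 = d_symb2, d_symb3 = d_symb3,
               d_soc_infant = delta_or_na(id, "SOC_INFANT", t_soc),
               d_soc_mother = delta_or_na(id, "SOC_MOTHER", t_soc),
               rr = compute_rr(d_sp2, d_symb2, d_symb3),
               rr_censored = is.na(d_sp2) || is.na(d_symb2) || is.na(d_symb3),
               t_walk = tw, t_lang = tl, t_seq = ts,
               stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, rows)
  rownames(res) <- NULL
  res
}
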