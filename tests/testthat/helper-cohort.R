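# Build a small cohort from per-subject specifications.
#
# subjects: named list; each element is a list with
#   ages   - session ages in weeks
#   counts - named list code -> count vector (unnamed codes default to 0)
#   stages - named list stage -> logical vector (default: PRE_SITTING TRUE,
#            others FALSE)
#   duration - minutes (default 60), scalar or vector
make_cohort <- function(subjects, check = TRUE) {
  rows <- lapply(names(subjects), function(id) {
    sp <- subjects[[id]]
    n <- length(sp$ages)
    df <- data.frame(subject_id = id, session_index = seq_len(n),
                     age_weeks = sp$ages,
                     duration_minutes = if (is.null(sp$duration)) 60 else sp$duration,
                     stringsAsFactors = FALSE)
    for (code in behavior_codes())
      df[[code]] <- if (!is.null(sp$counts[[code]])) sp$counts[[code]] else 0
    stage_default <- list(PRE_SITTING = TRUE, SITTING = FALSE,
                          CRAWLING = FALSE, WALKING = FALSE)
    for (st in locomotor_stages())
      df[[st]] <- if (!is.null(sp$stages[[st]])) sp$stages[[st]] else
        stage_default[[st]]
    df
  })
  rr_cohort(do.call(rbind, rows), check = check)
}
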