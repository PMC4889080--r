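#' Construct a cohort of observation sessions
#'
#' A cohort bundles one row per subject x session with the per-session
#' behavior counts (dense: zeros stored explicitly) and the attained
#' locomotor-stage flags. Internally the session table is wide — one
#' column per behavior code and per stage — which is the natural shape
#' for event-aligned computation; the on-disk interchange format is long
#' CSV (see [read_cohort()] / [write_cohort()]).
#'
#' @param sessions data.frame with columns `subject_id`, `session_index`,
#'   `age_weeks`, `duration_minutes`, one integer count column per code in
#'   [behavior_codes()], and one logical column per stage in
#'   [locomotor_stages()].
#' @param check If `TRUE` (default), hard invariants are enforced:
#'   non-negative integer counts, positive duration, strictly increasing
#'   ages and at least two sessions per subject, no duplicated
#'   (subject, age) pairs. Soft findings (e.g. a walking-flag regression)
#'   never block construction; see [validate_cohort()].
#' @return An object of class `rr_cohort`.
#' @export
rr_cohort <- function(sessions, check = TRUE) {
  stopifnot(is.data.frame(sessions))
  need <- c("subject_id", "session_index", "age_weeks", "duration_minutes",
            behavior_codes(), locomotor_stages())
  miss <- setdiff(need, names(sessions))
  if (length(miss) > 0)
    stop("sessions table is missing columns: ", paste(miss, collapse = ", "))
  sessions <- sessions[, need]
  sessions$subject_id <- as.character(sessions$subject_id)
  sessions$session_index <- as.integer(sessions$session_index)
  sessions$age_weeks <- as.numeric(sessions$age_weeks)
  sessions$duration_minutes <- as.numeric(sessions$duration_minutes)
  for (code in behavior_codes()) sessions[[code]] <- as.numeric(sessions[[code]])
  for (st in locomotor_stages()) sessions[[st]] <- as.logical(sessions[[st]])
  ord <- order(sessions$subject_id, sessions$age_weeks)
  sessions <- sessions[ord, , drop = FALSE]
  rownames(sessions) <- NULL
  x <- structure(list(sessions = sessions), class = "rr_cohort")
  if (check) {
    rep <- validate_cohort(x)
    err <- rep[rep$severity == "error", , drop = FALSE]
    if (nrow(err) > 0)
      stop("invalid cohort:\n", paste("-", err$message, collapse = "\n"))
  }
  x
}

#' @export
print.rr_cohort <- function(x, ...) {
  s <- x$sessions
  cat("<rr_cohort>", length(unique(s$subject_id)), "subjects,",
      nrow(s), "sessions, ages",
      format(min(s$age_weeks)), "-", format(max(s$age_weeks)), "weeks\n")
  invisible(x)
}

#' Validate a cohort and report findings
#'
#' Validation is total: it never raises on well-typed input. Hard
#' invariant violations are returned with severity `"error"`
#' (negative/non-integer counts, non-positive duration, duplicated or
#' non-increasing ages within a subject, subjects with a single session);
#' a walking flag that reverts to `FALSE` after being `TRUE` is a
#' `"warning"` finding, as are regressions of the other stage flags.
#'
#' @param cohort An `rr_cohort`, or a bare session data.frame of the same
#'   shape.
#' @return data.frame with columns `severity`, `subject_id`, `message`;
#'   zero rows iff all invariants hold.
#' @export
validate_cohort <- function(cohort) {
  s <- if (inherits(cohort, "rr_cohort")) cohort$sessions else cohort
  findings <- list()
  add <- function(severity, subject, message)
    findings[[length(findings) + 1L]] <<- data.frame(
      severity = severity, subject_id = subject, message = message,
      stringsAsFactors = FALSE)

  cnt <- as.matrix(s[, behavior_codes()])
  bad <- which(cnt < 0 | (is.finite(cnt) & cnt != round(cnt)), arr.ind = TRUE)
  if (nrow(bad) > 0)
    for (i in seq_len(nrow(bad)))
      add("error", s$subject_id[bad[i, 1]],
          sprintf("row %d: count for %s is %s (must be a non-negative integer)",
                  bad[i, 1], behavior_codes()[bad[i, 2]], cnt[bad[i, 1], bad[i, 2]]))
  if (any(is.na(cnt)))
    add("error", NA_character_, "missing behavior counts")
  if (any(!is.finite(s$duration_minutes) | s$duration_minutes <= 0))
    add("error", NA_character_, "non-positive session duration")

  for (id in unique(s$subject_id)) {
    si <- s[s$subject_id == id, , drop = FALSE]
    si <- si[order(si$age_weeks), , drop = FALSE]
    if (nrow(si) < 2)
      add("error", id, sprintf("subject %s has fewer than 2 sessions", id))
    if (anyDuplicated(si$age_weeks))
      add("error", id, sprintf("subject %s has duplicated session ages", id))
    if (is.unsorted(si$age_weeks, strictly = TRUE) && !anyDuplicated(si$age_weeks))
      add("error", id, sprintf("subject %s has non-increasing session ages", id))
    for (st in locomotor_stages()) {
      f <- as.logical(si[[st]])
      if (any(diff(f) < 0))
        add("warning", id,
            sprintf("subject %s: %s flag reverts to FALSE after being TRUE", id, st))
    }
  }
  if (length(findings) == 0)
    return(data.frame(severity = character(), subject_id = character(),
                      message = character(), stringsAsFactors = FALSE))
  do.call(rbind, findings)
}

#' Read a cohort from its long-CSV file pair
#'
#' The interchange format is a pair of UTF-8 CSV files: a session table
#' with header exactly
#' `subject_id,session_index,age_weeks,duration_minutes,behavior_code,count`
#' (dense long format, one row per session x behavior code, zeros
#' explicit) and a locomotor table with header
#' `subject_id,age_weeks,stage,observed` (`observed` in 0/1).
#'
#' @param sessions_path Path to the session CSV.
#' @param locomotor_path Path to the locomotor CSV.
#' @return An `rr_cohort`. Rows with unknown behavior codes or stages are
#'   rejected with an error naming the offending row; schema (missing
#'   column) and invariant violations (negative counts, non-monotone ages)
#'   also error.
#' @seealso [write_cohort()]
#' @export
read_cohort <- function(sessions_path, locomotor_path) {
  for (p in c(sessions_path, locomotor_path))
    if (!file.exists(p)) stop("file not found: ", p)
  long <- utils::read.csv(sessions_path, stringsAsFactors = FALSE,
                          colClasses = c(subject_id = "character"))
  need <- c("subject_id", "session_index", "age_weeks", "duration_minutes",
            "behavior_code", "count")
  miss <- setdiff(need, names(long))
  if (length(miss) > 0)
    stop("session CSV is missing columns: ", paste(miss, collapse = ", "))
  unknown <- which(!long$behavior_code %in% behavior_codes())
  if (length(unknown) > 0)
    stop(sprintf("unknown behavior code '%s' in session CSV row %d",
                 long$behavior_code[unknown[1]], unknown[1]))
  neg <- which(long$count < 0)
  if (length(neg) > 0)
    stop(sprintf("negative count in session CSV row %d (subject %s)",
                 neg[1], long$subject_id[neg[1]]))

  loco <- utils::read.csv(locomotor_path, stringsAsFactors = FALSE,
                          colClasses = c(subject_id = "character"))
  lneed <- c("subject_id", "age_weeks", "stage", "observed")
  lmiss <- setdiff(lneed, names(loco))
  if (length(lmiss) > 0)
    stop("locomotor CSV is missing columns: ", paste(lmiss, collapse = ", "))
  lunknown <- which(!loco$stage %in% locomotor_stages())
  if (length(lunknown) > 0)
    stop(sprintf("unknown locomotor stage '%s' in locomotor CSV row %d",
                 loco$stage[lunknown[1]], lunknown[1]))

  # long -> wide counts
  key <- paste(long$subject_id, long$age_weeks, sep = "\r")
  ukey <- unique(key)
  idx <- match(key, ukey)
  first <- match(ukey, key)
  wide <- data.frame(subject_id = long$subject_id[first],
                     session_index = long$session_index[first],
                     age_weeks = long$age_weeks[first],
                     duration_minutes = long$duration_minutes[first],
                     stringsAsFactors = FALSE)
  for (code in behavior_codes()) {
    v <- rep(NA_real_, length(ukey))
    sel <- long$behavior_code == code
    v[idx[sel]] <- long$count[sel]
    wide[[code]] <- v
  }
  lkey <- paste(loco$subject_id, loco$age_weeks, sep = "\r")
  for (st in locomotor_stages()) {
    v <- rep(NA, length(ukey))
    sel <- loco$stage == st
    v[match(lkey[sel], ukey)] <- as.logical(loco$observed[sel])
    wide[[st]] <- v
  }
  if (any(is.na(as.matrix(wide[, locomotor_stages()]))))
    stop("locomotor CSV does not cover every (subject, age) session")

  # non-monotone ages are a hard read error, per contract
  for (id in unique(wide$subject_id)) {
    a <- wide$age_weeks[wide$subject_id == id]
    if (anyDuplicated(a))
      stop("subject ", id, " has duplicated session ages")
  }
  rr_cohort(wide)
}

#' Write a cohort to its long-CSV file pair
#'
#' Inverse of [read_cohort()]: `read_cohort()` after `write_cohort()` is
#' the identity on valid cohorts, and two writes of the same cohort are
#' byte-identical. Zero counts are written explicitly.
#'
#' @param cohort An `rr_cohort`.
#' @param sessions_path,locomotor_path Output CSV paths.
#' @return Invisibly, the two paths.
#' @export
write_cohort <- function(cohort, sessions_path, locomotor_path) {
  stopifnot(inherits(cohort, "rr_cohort"))
  s <- cohort$sessions
  n <- nrow(s)
  codes <- behavior_codes()
  long <- data.frame(
    subject_id = rep(s$subject_id, each = length(codes)),
    session_index = rep(s$session_index, each = length(codes)),
    age_weeks = rep(s$age_weeks, each = length(codes)),
    duration_minutes = rep(s$duration_minutes, each = length(codes)),
    behavior_code = rep(codes, times = n),
    count = as.vector(t(as.matrix(s[, codes]))),
    stringsAsFactors = FALSE)
  stages <- locomotor_stages()
  loco <- data.frame(
    subject_id = rep(s$subject_id, each = length(stages)),
    age_weeks = rep(s$age_weeks, each = length(stages)),
    stage = rep(stages, times = n),
    observed = as.integer(as.vector(t(as.matrix(s[, stages])))),
    stringsAsFactors = FALSE)
  utils::write.csv(format_for_csv(long), sessions_path,
                   row.names = FALSE, quote = FALSE)
  utils::write.csv(format_for_csv(loco), locomotor_path,
                   row.names = FALSE, quote = FALSE)
  invisible(c(sessions_path, locomotor_path))
}

# Full-precision, locale-independent numeric formatting so that
# write -> read round-trips exactly and writes are deterministic.
format_for_csv <- function(df) {
  for (nm in names(df)) {
    if (is.double(df[[nm]]))
      df[[nm]] <- vapply(df[[nm]], function(v)
        format(v, digits = 17, scientific = FALSE, trim = TRUE), "")
  }
  df
}
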