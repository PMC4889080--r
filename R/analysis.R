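#' Run the full resource-reallocation analysis
#'
#' The central entry point: takes a cohort (or a simulation configuration,
#' which is simulated first) and produces the three-hypothesis report —
#'
#' \describe{
#'   \item{H1 (ordering)}{per-subject milestone orderings; how many
#'     subjects attained all four symbolic-play levels and single-word
#'     utterances before walking, and the mean lead times in weeks.}
#'   \item{H2 (pre-milestone dips)}{paired t contrasts of each behavior's
#'     pre-anchor peak rate against its rate at the anchor session
#'     (single-object sequences at word onset; words and infant social
#'     bids at walking onset), plus rebound summaries.}
#'   \item{H3 (individual differences)}{Pearson correlations, with
#'     parametric and permutation p-values, of each change coefficient
#'     and the RR composite against walking age (and the speech/social
#'     deltas against crawling age).}
#' }
#'
#' Subjects with censored anchors are excluded pairwise and itemized in
#' `$exclusions`; if fewer than 3 subjects have a defined value for a
#' correlation it is reported with status `"insufficient_data"`, never
#' silently omitted. The result is deterministic given `(input, seed)`.
#'
#' @param x An [rr_cohort()], an `rr_sim`, or an [rr_sim_config()].
#' @param permutations Permutations per correlation (0 disables the
#'   permutation p-values).
#' @param seed Integer seed for the permutation streams (and for
#'   simulation when `x` is a config and carries no seed).
#' @param fixed_dt_weeks Optional fixed event-alignment gap; see
#'   [event_aligned_delta()].
#' @param soc_anchor Anchor for the social-bid deltas; see
#'   [coefficients_table()].
#' @return An object of class `rr_analysis` with elements
#'   `cohort_summary`, `h1`, `h2`, `h3`, `milestones`, `coefficients`,
#'   `exclusions`, `provenance`; methods: [print()], [summary()],
#'   [coef()], [plot()].
#' @export
rr_analysis <- function(x, permutations = 999, seed = 1L,
                        fixed_dt_weeks = NULL,
                        soc_anchor = c("VERB2", "WALKING")) {
  soc_anchor <- match.arg(soc_anchor)
  sim_seed <- NULL
  if (inherits(x, "rr_sim_config")) x <- simulate_rr_cohort(x, seed = x$seed)
  if (inherits(x, "rr_sim")) { sim_seed <- x$seed; x <- x$cohort }
  stopifnot(inherits(x, "rr_cohort"))
  cohort <- x

  ms <- milestone_table(cohort)
  coefs <- coefficients_table(cohort, ms, fixed_dt_weeks = fixed_dt_weeks,
                              soc_anchor = soc_anchor)
  subjects <- unique(ms$subject_id)
  init_wide <- function(m) {
    v <- ms$initiation_age_weeks[ms$code == m]
    stats::setNames(v, ms$subject_id[ms$code == m])[subjects]
  }
  walk_age <- init_wide("WALKING")
  crawl_age <- init_wide("CRAWLING")

  # ---- H1: orderings and lead times -------------------------------------
  pre_walk <- ms$all_pre_walking[match(subjects, ms$subject_id)]
  lead_symb4 <- walk_age - init_wide("SYMB4")
  lead_verb2 <- walk_age - init_wide("VERB2")
  h1 <- list(
    n_subjects = length(subjects),
    n_walking_observed = sum(!is.na(walk_age)),
    n_all_pre_walking = sum(pre_walk, na.rm = TRUE),
    mean_lead_symb4_weeks = mean(lead_symb4, na.rm = TRUE),
    mean_lead_verb2_weeks = mean(lead_verb2, na.rm = TRUE),
    per_subject = data.frame(subject_id = subjects,
                             all_pre_walking = pre_walk,
                             lead_symb4_weeks = unname(lead_symb4),
                             lead_verb2_weeks = unname(lead_verb2),
                             stringsAsFactors = FALSE))

  # ---- H2: peak-vs-emergence contrasts and rebounds ---------------------
  contrast_codes <- c(SYMB2 = "single-object sequences at word onset",
                      VERB2 = "single-word utterances at walking onset",
                      SOC_INFANT = "infant social bids at walking onset")
  h2 <- list(contrasts = list(), rebounds = list())
  for (code in names(contrast_codes)) {
    sel <- ms$code == code
    pk <- ms$peak_rate[sel]
    at <- ms$rate_at_anchor[sel]
    h2$contrasts[[code]] <- tryCatch(
      paired_t(pk, at, label = contrast_codes[[code]]),
      error = function(e) list(label = contrast_codes[[code]],
                               n = sum(is.finite(pk) & is.finite(at)),
                               status = conditionMessage(e)))
    rb <- ms$rebound_rate[sel]
    h2$rebounds[[code]] <- list(
      code = code, n = sum(is.finite(rb)),
      mean_rebound_rate = mean(rb, na.rm = TRUE),
      mean_rate_at_anchor = mean(at, na.rm = TRUE),
      prop_rebound_above_anchor = mean(rb > at, na.rm = TRUE))
  }

  # ---- H3: correlations -------------------------------------------------
  vars <- list(d_symb2 = coefs$d_symb2, d_symb3 = coefs$d_symb3,
               d_sp2 = coefs$d_sp2, d_soc_infant = coefs$d_soc_infant,
               d_soc_mother = coefs$d_soc_mother, rr = coefs$rr)
  targets <- c(rep("walking_age_weeks", 6), rep("crawling_age_weeks", 3))
  xs <- c(names(vars), c("d_sp2", "d_soc_infant", "d_soc_mother"))
  h3 <- vector("list", length(xs))
  for (k in seq_along(xs)) {
    vx <- vars[[xs[k]]]
    vy <- if (targets[k] == "walking_age_weeks") unname(walk_age) else unname(crawl_age)
    h3[[k]] <- correlate_pair(vx, vy, xs[k], targets[k],
                              permutations = permutations,
                              seed = as.integer(seed) + k)
  }
  names(h3) <- paste(xs, "vs", ifelse(targets == "walking_age_weeks",
                                      "walking", "crawling"), sep = "_")

  exclusions <- coefs[coefs$rr_censored, "subject_id", drop = TRUE]
  cohort_summary <- list(
    n_subjects = length(subjects),
    n_sessions = nrow(cohort$sessions),
    age_range_weeks = range(cohort$sessions$age_weeks))
  provenance <- list(seed = as.integer(seed), sim_seed = sim_seed,
                     permutations = as.integer(permutations),
                     fixed_dt_weeks = fixed_dt_weeks,
                     soc_anchor = soc_anchor,
                     cohort_checksum = cohort_checksum(cohort),
                     package_version = as.character(utils::packageVersion("rralloc")))

  structure(list(cohort_summary = cohort_summary, h1 = h1, h2 = h2, h3 = h3,
                 milestones = ms, coefficients = coefs,
                 exclusions = exclusions, provenance = provenance),
            class = "rr_analysis")
}

correlate_pair <- function(x, y, name_x, name_y, permutations, seed) {
  res <- tryCatch(pearson_r(x, y, labels = c(name_x, name_y)),
                  error = function(e) e)
  if (inherits(res, "error")) {
    return(list(variable_x = name_x, variable_y = name_y,
                n = sum(is.finite(x) & is.finite(y)),
                status = "insufficient_data",
                message = conditionMessage(res)))
  }
  if (permutations > 0) {
    res$p_permutation <- permutation_p(x, y, n_permutations = permutations,
                                       seed = seed)
    res$n_permutations <- as.integer(permutations)
  }
  res
}

# Deterministic plain-arithmetic checksum of a cohort, for provenance.
cohort_checksum <- function(cohort) {
  s <- cohort$sessions
  m <- as.matrix(s[, behavior_codes()])
  v <- c(sum(m * seq_len(ncol(m))[col(m)]), sum(s$age_weeks), nrow(s),
         sum(as.matrix(s[, locomotor_stages()])))
  sprintf("%.6f", sum(v * c(1, 1e-3, 1, 7)))
}

#' @export
print.rr_analysis <- function(x, ...) {
  cat("Resource-reallocation analysis\n")
  cat(sprintf("  %d subjects, %d sessions (ages %g-%g wk)\n",
              x$cohort_summary$n_subjects, x$cohort_summary$n_sessions,
              x$cohort_summary$age_range_weeks[1],
              x$cohort_summary$age_range_weeks[2]))
  cat(sprintf("H1: %d of %d subjects attained all symbolic levels and words before walking\n",
              x$h1$n_all_pre_walking, x$h1$n_walking_observed))
  cat(sprintf("    mean lead: complex play %.1f wk, words %.1f wk\n",
              x$h1$mean_lead_symb4_weeks, x$h1$mean_lead_verb2_weeks))
  cat("H2: peak vs at-emergence contrasts\n")
  for (ct in x$h2$contrasts) {
    if (inherits(ct, "rr_paired")) { cat("    "); print(ct) }
    else cat("    ", ct$label, ": ", ct$status, "\n", sep = "")
  }
  cat("H3: correlations with milestone ages\n")
  for (co in x$h3) {
    cat("    ")
    if (inherits(co, "rr_cor")) print(co)
    else cat(sprintf("r(%s, %s): insufficient data (n = %d)\n",
                     co$variable_x, co$variable_y, co$n))
  }
  if (length(x$exclusions))
    cat("  censored RR (excluded pairwise):",
        paste(x$exclusions, collapse = ", "), "\n")
  invisible(x)
}

#' @export
summary.rr_analysis <- function(object, ...) {
  print(object)
  cat("\nPer-subject change coefficients:\n")
  print(object$coefficients[, c("subject_id", "d_sp2", "d_symb2", "d_symb3",
                                "d_soc_infant", "d_soc_mother", "rr")],
        digits = 3, row.names = FALSE)
  invisible(object)
}

#' Extract the per-subject change coefficients
#'
#' @param object An `rr_analysis`.
#' @param ... Unused.
#' @return The coefficients data.frame (one row per subject) as produced
#'   by [coefficients_table()].
#' @export
coef.rr_analysis <- function(object, ...) {
  object$coefficients
}

#' Plot mean behavior trajectories
#'
#' Base-graphics panel of cohort-mean rates per behavior code against
#' age, with the mean anchor-milestone ages marked; the visual
#' counterpart of the H2 block.
#'
#' @param x An `rr_analysis`.
#' @param cohort The [rr_cohort()] the analysis was run on (the analysis
#'   object keeps only derived tables, not the raw sessions).
#' @param codes Behavior codes to draw.
#' @param ... Passed to [graphics::matplot()].
#' @return Invisibly, the matrix of mean rates (age x code).
#' @export
plot.rr_analysis <- function(x, cohort, codes = c("SYMB2", "SYMB3", "VERB2",
                                                  "SOC_INFANT"), ...) {
  stopifnot(inherits(cohort, "rr_cohort"))
  s <- cohort$sessions
  ages <- sort(unique(s$age_weeks))
  m <- sapply(codes, function(code)
    vapply(ages, function(a) {
      sel <- s$age_weeks == a
      mean(s[[code]][sel] / (s$duration_minutes[sel] / 60))
    }, numeric(1)))
  graphics::matplot(ages, m, type = "l", lty = 1, lwd = 2,
                    xlab = "age (weeks)", ylab = "mean rate (counts/hour)", ...)
  for (anchor in c("VERB2", "SYMB4")) {
    aa <- x$milestones$initiation_age_weeks[x$milestones$code == anchor]
    graphics::abline(v = mean(aa, na.rm = TRUE), lty = 3)
  }
  wa <- x$milestones$initiation_age_weeks[x$milestones$code == "WALKING"]
  graphics::abline(v = mean(wa, na.rm = TRUE), lty = 2)
  graphics::legend("topleft", legend = codes, col = seq_along(codes),
                   lty = 1, lwd = 2, bty = "n")
  invisible(m)
}

#' Serialize an analysis report to JSON
#'
#' Machine-readable counterpart of [print.rr_analysis()]: the H1/H2/H3
#' blocks, exclusions and provenance as schema-stable JSON. Writing the
#' same analysis twice produces byte-identical files.
#'
#' @param x An `rr_analysis`.
#' @param path Output path; if `NULL`, the JSON string is returned.
#' @return The JSON string (invisibly when `path` is given).
#' @export
write_report <- function(x, path = NULL) {
  stopifnot(inherits(x, "rr_analysis"))
  strip <- function(o) if (is.list(o)) lapply(unclass(o), strip) else o
  payload <- list(cohort = x$cohort_summary,
                  h1 = strip(x$h1[setdiff(names(x$h1), "per_subject")]),
                  h1_per_subject = x$h1$per_subject,
                  h2 = strip(x$h2),
                  h3 = lapply(x$h3, strip),
                  exclusions = x$exclusions,
                  provenance = strip(x$provenance))
  js <- jsonlite::toJSON(payload, auto_unbox = TRUE, digits = NA,
                         na = "null", null = "null", pretty = TRUE)
  if (is.null(path)) return(as.character(js))
  writeLines(js, path)
  invisible(as.character(js))
}
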