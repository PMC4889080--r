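#' Canonical validation design for parameter-recovery experiments
#'
#' A simulation configuration designed to isolate estimator error from
#' developmental overlap: high plateau rates (so Poisson noise is small
#' relative to the dip signal), widely separated transition milestones
#' (so the word/complex-play/walking anchors rarely cross even under
#' strong RR coupling), tight gap sds, and a follow-up window extended to
#' 88 weeks so walking is almost never right-censored. With the default
#' `coupling_beta` the realized correlation between latent RR and
#' walking age is about -0.8.
#'
#' @param n_subjects Cohort size.
#' @param coupling_beta Coupling strength (weeks per unit RR deviation).
#' @param base Plateau intensity (counts/hour) applied to every code.
#' @param ... Further overrides passed to [rr_sim_config()].
#' @return An [rr_sim_config()].
#' @export
rr_validation_config <- function(n_subjects = 60, coupling_beta = -0.34,
                                 base = 150, ...) {
  rr_sim_config(
    n_subjects = n_subjects,
    schedule = sort(unique(c(seq(26, 52, by = 2), seq(52, 88, by = 3)))),
    base_intensity = stats::setNames(rep(base, 8), behavior_codes()),
    milestone_age_means = c(SYMB1 = 34, SYMB2 = 40, SYMB3 = 46, SYMB4 = 56,
                            VERB1 = 34, VERB2 = 56, SOC_INFANT = 28,
                            SOC_MOTHER = 28, SITTING = 30, CRAWLING = 36,
                            WALKING = 70),
    milestone_age_sds = c(SYMB1 = 2, SYMB2 = 2, SYMB3 = 2, SYMB4 = 2,
                          VERB1 = 2, VERB2 = 1.5, SOC_INFANT = 2,
                          SOC_MOTHER = 2, SITTING = 2, CRAWLING = 2,
                          WALKING = 2),
    coupling_beta = coupling_beta,
    ...)
}

#' Parameter-recovery experiment for the RR-walking coupling
#'
#' Validation harness for the RR claim: simulates replicate cohorts over
#' a grid of coupling strengths, runs the full pipeline on each, and
#' compares the estimated RR-vs-walking-age correlation against the
#' realized correlation between the latent (noise-free) RR and walking
#' age in the simulation truth.
#'
#' @param config An [rr_sim_config()]; the grid is taken over
#'   `coupling_betas` with all other fields fixed.
#' @param coupling_betas Numeric vector of coupling strengths (weeks per
#'   unit RR deviation).
#' @param n_replicates Replicate cohorts per grid point.
#' @param seed Base seed; replicate `j` of grid point `g` uses
#'   `seed + (g-1)*n_replicates + (j-1)`.
#' @return data.frame of class `rr_recovery`, one row per (grid point,
#'   replicate): `coupling_beta`, `replicate`, `seed`, `n_complete`
#'   (subjects with defined RR and walking age), `r_est` (pipeline
#'   estimate), `r_latent` (realized latent correlation from truth),
#'   `sign_agree`. Aggregate with [summary()].
#' @export
recovery_experiment <- function(config, coupling_betas = config$coupling_beta,
                                n_replicates = 20, seed = 1L) {
  stopifnot(inherits(config, "rr_sim_config"), n_replicates >= 1)
  seed <- as.integer(seed)
  rows <- vector("list", length(coupling_betas) * n_replicates)
  k <- 0L
  for (g in seq_along(coupling_betas)) {
    cfg <- config
    cfg$coupling_beta <- coupling_betas[g]
    for (j in seq_len(n_replicates)) {
      k <- k + 1L
      s <- seed + (g - 1L) * n_replicates + (j - 1L)
      sim <- simulate_rr_cohort(cfg, seed = s)
      an <- rr_analysis(sim, permutations = 0, seed = s)
      est <- an$h3$rr_vs_walking
      r_est <- if (inherits(est, "rr_cor")) est$r else NA_real_
      tr <- sim$truth
      keep <- is.finite(tr$latent_rr) & !tr$right_censored
      r_lat <- if (sum(keep) >= 3 && stats::sd(tr$latent_rr[keep]) > 0)
        stats::cor(tr$latent_rr[keep], tr$WALKING[keep]) else NA_real_
      rows[[k]] <- data.frame(
        coupling_beta = coupling_betas[g], replicate = j, seed = s,
        n_complete = if (inherits(est, "rr_cor")) est$n else 0L,
        r_est = r_est, r_latent = r_lat,
        sign_agree = !is.na(r_est) & !is.na(r_lat) &
          (sign(r_est) == sign(r_lat) | r_lat == 0))
    }
  }
  res <- do.call(rbind, rows)
  rownames(res) <- NULL
  class(res) <- c("rr_recovery", "data.frame")
  res
}

#' @export
summary.rr_recovery <- function(object, ...) {
  sp <- split(as.data.frame(object), object$coupling_beta)
  out <- do.call(rbind, lapply(sp, function(d) data.frame(
    coupling_beta = d$coupling_beta[1],
    n_replicates = nrow(d),
    mean_r_est = mean(d$r_est, na.rm = TRUE),
    sd_r_est = stats::sd(d$r_est, na.rm = TRUE),
    mean_abs_r_est = mean(abs(d$r_est), na.rm = TRUE),
    mean_r_latent = mean(d$r_latent, na.rm = TRUE),
    mean_abs_r_latent = mean(abs(d$r_latent), na.rm = TRUE),
    bias_abs = mean(abs(d$r_est), na.rm = TRUE) -
      mean(abs(d$r_latent), na.rm = TRUE),
    sign_agreement = mean(d$sign_agree, na.rm = TRUE))))
  out <- out[order(out$coupling_beta), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Compare detected initiation ages against simulation truth
#'
#' For every subject x milestone, tabulates the true age, the first
#' scheduled session at/after it (the quantization target), and the age
#' the pipeline detected from the observed counts/flags.
#'
#' @param sim An `rr_sim`.
#' @param milestones Optional precomputed [milestone_table()].
#' @return data.frame with columns `subject_id`, `code`, `true_age`,
#'   `first_grid_age`, `detected_age`, `match`.
#' @export
initiation_vs_truth <- function(sim, milestones = NULL) {
  stopifnot(inherits(sim, "rr_sim"))
  if (is.null(milestones)) milestones <- milestone_table(sim$cohort)
  sched <- sim$config$schedule
  first_grid <- function(a) {
    i <- match(TRUE, sched >= a)
    if (is.na(i)) NA_real_ else sched[i]
  }
  tr <- sim$truth
  ms <- milestones
  ms$true_age <- NA_real_
  for (m in all_milestones()) {
    sel <- ms$code == m
    ms$true_age[sel] <- tr[[m]][match(ms$subject_id[sel], tr$subject_id)]
  }
  ms$first_grid_age <- vapply(ms$true_age, first_grid, numeric(1))
  data.frame(subject_id = ms$subject_id, code = ms$code,
             true_age = ms$true_age, first_grid_age = ms$first_grid_age,
             detected_age = ms$initiation_age_weeks,
             match = !is.na(ms$initiation_age_weeks) &
               !is.na(ms$first_grid_age) &
               abs(ms$initiation_age_weeks - ms$first_grid_age) < 1e-8,
             stringsAsFactors = FALSE)
}

#' Recover the configured dip fraction from observed rates
#'
#' For one dipped behavior, the across-subject mean rate at the anchor
#' session divided by the across-subject mean plateau rate (sessions
#' after the behavior's ramp completes and before its anchor). With a
#' configured dip fraction d the expected ratio is `1 - d`.
#'
#' @param sim An `rr_sim`.
#' @param code A dipped behavior code (see [anchor_wiring()]).
#' @return List with `mean_anchor_rate`, `mean_plateau_rate`, `ratio`,
#'   `n_subjects` (subjects contributing both quantities).
#' @export
dip_recovery_ratio <- function(sim, code = "SYMB2") {
  stopifnot(inherits(sim, "rr_sim"), code %in% names(anchor_wiring()))
  cfg <- sim$config
  anchor_m <- unname(anchor_wiring()[code])
  s <- sim$cohort$sessions
  tr <- sim$truth
  sched <- cfg$schedule
  anchor_rates <- c(); plateau_rates <- c(); n_used <- 0L
  for (i in seq_len(nrow(tr))) {
    emerge <- tr[[code]][i]
    a <- tr[[anchor_m]][i]
    ia <- match(TRUE, sched >= a)
    if (is.na(ia)) next
    si <- s[s$subject_id == tr$subject_id[i], , drop = FALSE]
    plateau <- si$age_weeks >= emerge + cfg$rise_time_weeks & si$age_weeks < a
    if (!any(plateau)) next
    r <- si[[code]] / (si$duration_minutes / 60)
    anchor_rates <- c(anchor_rates, r[si$age_weeks == sched[ia]])
    plateau_rates <- c(plateau_rates, mean(r[plateau]))
    n_used <- n_used + 1L
  }
  list(mean_anchor_rate = mean(anchor_rates),
       mean_plateau_rate = mean(plateau_rates),
       ratio = mean(anchor_rates) / mean(plateau_rates),
       n_subjects = n_used)
}
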