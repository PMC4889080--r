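#' Default bi-/tri-weekly observation schedule
#'
#' One-hour home observation sessions every 2 weeks from 26 to 52 weeks of
#' age (6-12 months) and every 3 weeks from 52 to 78 weeks (12-18 months):
#' 22 scheduled ages in all.
#'
#' @return Numeric vector of session ages in weeks, strictly increasing.
#' @export
default_schedule <- function() {
  sort(unique(c(seq(26, 52, by = 2), seq(52, 78, by = 3))))
}

#' Simulation configuration for a synthetic infant cohort
#'
#' Defines the latent generative model the analysis assumes: per-subject
#' milestone ages with within-domain ordering enforced by construction
#' (positive truncated-normal inter-milestone gaps, lower bound 1 week),
#' Poisson session counts whose intensity ramps up after a behavior's
#' emergence, drops by a multiplicative dip factor in a trough locked to
#' the anchor-milestone transition and partially rebounds afterwards, and
#' a linear coupling between a subject's latent resource-reallocation
#' (RR) score and their walking-onset age.
#'
#' Subject heterogeneity in the dip factors is driven by a single latent
#' reallocation propensity \eqn{z \sim N(0,1)}: subjects with larger `z`
#' suppress symbolic play more deeply while boosting speech and social
#' bids (negative loadings), which is what makes the analysis-side change
#' coefficients mutually correlated and gives RR its variance.
#'
#' @param n_subjects Number of subjects (>= 2).
#' @param schedule Session ages in weeks, strictly increasing.
#' @param base_intensity Named vector, expected counts/hour at plateau for
#'   each behavior code. Defaults sit at the per-hour rate scale of
#'   home-observation play coding (around 2-4 events/hour).
#' @param rise_time_weeks Weeks over which a newly emerged behavior ramps
#'   from `emergence_fraction` of plateau to plateau.
#' @param emergence_fraction Fraction of plateau intensity expressed at
#'   the moment of emergence (in (0, 1]).
#' @param dip_fraction Named vector over dipped codes (see
#'   [anchor_wiring()]): mean multiplicative suppression in the trough
#'   (0 = none, 1 = full; negative values model a boost).
#' @param dip_loading Named vector: per-unit-\eqn{z} shift of each dip
#'   factor (sign encodes whether the behavior dips more or boosts as
#'   reallocation propensity grows).
#' @param dip_idio_sd Idiosyncratic (subject x code) dip noise sd.
#' @param dip_window_weeks Width of the full-suppression trough, starting
#'   at the anchor-milestone age; must be at least the longest
#'   inter-session gap for the anchor session to sit inside the trough.
#' @param rebound_fraction Fraction of the dip recovered after the trough
#'   (1 = full rebound to plateau).
#' @param milestone_age_means,milestone_age_sds Named vectors over
#'   milestones (behavior codes and locomotor stages) of mean initiation
#'   ages in weeks and their sds. Chain interiors are sampled as gaps, so
#'   ordering holds for every draw.
#' @param coupling_beta Weeks of walking-age shift per unit of latent RR
#'   deviation from its cohort mean (negative: greater RR, earlier
#'   walking).
#' @param noise_sd_weeks Gaussian noise sd added to walking age.
#' @param nominal_dt_weeks Nominal inter-session gap (weeks) used in the
#'   analytic RR that drives the coupling; 3, the gap of the tri-weekly
#'   phase in which the word/complex-play/walking transitions fall.
#' @param duration_minutes Session duration (all sessions).
#' @param seed Default seed used by [simulate_rr_cohort()] when no seed is
#'   passed explicitly.
#' @return An object of class `rr_sim_config` (a validated list).
#' @seealso [simulate_rr_cohort()], [draw_milestone_ages()],
#'   [behavior_intensity()]
#' @export
rr_sim_config <- function(n_subjects = 9,
                          schedule = default_schedule(),
                          base_intensity = c(SYMB1 = 3, SYMB2 = 2, SYMB3 = 2,
                                             SYMB4 = 1.5, VERB1 = 4, VERB2 = 1.67,
                                             SOC_INFANT = 3.7, SOC_MOTHER = 3.5),
                          rise_time_weeks = 4,
                          emergence_fraction = 0.5,
                          dip_fraction = c(SYMB2 = 0.72, SYMB3 = 0.3, VERB2 = 0.74,
                                           SOC_INFANT = 0.4, SOC_MOTHER = 0.4),
                          dip_loading = c(SYMB2 = 0.25, SYMB3 = 0.1, VERB2 = -0.25,
                                          SOC_INFANT = -0.25, SOC_MOTHER = -0.25),
                          dip_idio_sd = 0.05,
                          dip_window_weeks = 4,
                          rebound_fraction = 0.8,
                          milestone_age_means = c(SYMB1 = 36, SYMB2 = 44, SYMB3 = 50,
                                                  SYMB4 = 56, VERB1 = 34, VERB2 = 58,
                                                  SOC_INFANT = 28, SOC_MOTHER = 28,
                                                  SITTING = 30, CRAWLING = 38,
                                                  WALKING = 62),
                          milestone_age_sds = c(SYMB1 = 3, SYMB2 = 2, SYMB3 = 2,
                                                SYMB4 = 2, VERB1 = 3, VERB2 = 2,
                                                SOC_INFANT = 2, SOC_MOTHER = 2,
                                                SITTING = 2, CRAWLING = 2,
                                                WALKING = 3),
                          coupling_beta = -10,
                          noise_sd_weeks = 2,
                          nominal_dt_weeks = 3,
                          duration_minutes = 60,
                          seed = 1L) {
  cfg <- list(n_subjects = as.integer(n_subjects), schedule = as.numeric(schedule),
              base_intensity = fill_named(base_intensity, behavior_codes(), 0),
              rise_time_weeks = rise_time_weeks,
              emergence_fraction = emergence_fraction,
              dip_fraction = fill_named(dip_fraction, names(anchor_wiring()), 0),
              dip_loading = fill_named(dip_loading, names(anchor_wiring()), 0),
              dip_idio_sd = dip_idio_sd,
              dip_window_weeks = dip_window_weeks,
              rebound_fraction = rebound_fraction,
              milestone_age_means = fill_named(milestone_age_means,
                                               setdiff(all_milestones(), "PRE_SITTING")),
              milestone_age_sds = fill_named(milestone_age_sds,
                                             setdiff(all_milestones(), "PRE_SITTING")),
              coupling_beta = coupling_beta, noise_sd_weeks = noise_sd_weeks,
              nominal_dt_weeks = nominal_dt_weeks,
              duration_minutes = duration_minutes, seed = as.integer(seed))
  validate_sim_config(cfg)
  structure(cfg, class = "rr_sim_config")
}

fill_named <- function(x, full, default = NA_real_) {
  out <- stats::setNames(rep(default, length(full)), full)
  if (length(x)) {
    if (is.null(names(x)) && length(x) == length(full)) names(x) <- full
    bad <- setdiff(names(x), full)
    if (length(bad)) stop("unknown names: ", paste(bad, collapse = ", "))
    out[names(x)] <- x
  }
  out
}

validate_sim_config <- function(cfg) {
  stopifnot(cfg$n_subjects >= 2,
            length(cfg$schedule) >= 2,
            all(diff(cfg$schedule) > 0),
            all(cfg$base_intensity >= 0),
            cfg$rise_time_weeks > 0,
            cfg$emergence_fraction > 0, cfg$emergence_fraction <= 1,
            all(cfg$dip_fraction >= -1), all(cfg$dip_fraction <= 1),
            cfg$dip_window_weeks > 0,
            cfg$rebound_fraction >= 0, cfg$rebound_fraction <= 1,
            all(is.finite(cfg$milestone_age_means)),
            all(cfg$milestone_age_sds >= 0),
            cfg$noise_sd_weeks >= 0,
            cfg$nominal_dt_weeks > 0,
            cfg$duration_minutes > 0)
  if (cfg$dip_window_weeks < max(diff(cfg$schedule)))
    warning("dip_window_weeks is shorter than the longest inter-session gap; ",
            "anchor sessions may fall outside the trough")
  invisible(cfg)
}

#' @export
print.rr_sim_config <- function(x, ...) {
  cat("<rr_sim_config>", x$n_subjects, "subjects,",
      length(x$schedule), "sessions (",
      min(x$schedule), "-", max(x$schedule), "wk ), coupling_beta =",
      x$coupling_beta, "\n")
  invisible(x)
}

#' Read a simulation configuration from YAML or JSON
#'
#' Field names match the arguments of [rr_sim_config()]; unspecified
#' fields keep their defaults.
#'
#' @param path Path to a `.yaml`/`.yml` or `.json` file.
#' @return An `rr_sim_config`.
#' @export
read_sim_config <- function(path) {
  lst <- if (grepl("\\.ya?ml$", path, ignore.case = TRUE)) {
    if (!requireNamespace("yaml", quietly = TRUE))
      stop("the 'yaml' package is required to read YAML configs")
    yaml::read_yaml(path)
  } else {
    jsonlite::read_json(path, simplifyVector = TRUE)
  }
  do.call(rr_sim_config, lst)
}

# Truncated-normal draws with a lower bound, by inverse CDF. sd = 0
# degenerates to max(mean, lower) so that zero-sd configs are exact.
rtrunc_lower <- function(n, mean, sd, lower) {
  if (sd == 0) return(rep(max(mean, lower), n))
  plo <- stats::pnorm(lower, mean, sd)
  if (plo >= 1) return(rep(lower, n))
  stats::qnorm(plo + stats::runif(n) * (1 - plo), mean, sd)
}

# Analytic RR implied by a set of dip factors: the noise-free value of
# the composite when each two-point delta realizes its full drop
# -dip * plateau over one nominal inter-session gap.
rr_from_dips <- function(cfg, d_verb2, d_symb2, d_symb3) {
  (-d_verb2 * cfg$base_intensity[["VERB2"]] +
     d_symb2 * cfg$base_intensity[["SYMB2"]] -
     d_symb3 * cfg$base_intensity[["SYMB3"]]) / cfg$nominal_dt_weeks
}

# Draw the full per-subject latent state: reallocation propensity z,
# dip factors, milestone ages (ordered by construction) and the
# RR-coupled walking age. Uses the current RNG state.
draw_subject_truth <- function(cfg) {
  n <- cfg$n_subjects
  mu <- cfg$milestone_age_means
  sd <- cfg$milestone_age_sds
  z <- stats::rnorm(n)
  dips <- list()
  for (code in names(anchor_wiring())) {
    d <- cfg$dip_fraction[[code]] + cfg$dip_loading[[code]] * z +
      stats::rnorm(n, 0, cfg$dip_idio_sd)
    dips[[code]] <- pmin(pmax(d, -1), 1)
  }

  chain_gap <- function(prev_ages, m_prev, m) {
    prev_ages + rtrunc_lower(n, mu[[m]] - mu[[m_prev]], sd[[m]], 1)
  }

  symb1 <- stats::rnorm(n, mu[["SYMB1"]], sd[["SYMB1"]])
  symb2 <- chain_gap(symb1, "SYMB1", "SYMB2")
  symb3 <- chain_gap(symb2, "SYMB2", "SYMB3")
  symb4 <- chain_gap(symb3, "SYMB3", "SYMB4")
  verb1 <- stats::rnorm(n, mu[["VERB1"]], sd[["VERB1"]])
  verb2 <- chain_gap(verb1, "VERB1", "VERB2")
  soc_i <- stats::rnorm(n, mu[["SOC_INFANT"]], sd[["SOC_INFANT"]])
  soc_m <- stats::rnorm(n, mu[["SOC_MOTHER"]], sd[["SOC_MOTHER"]])
  sitting <- stats::rnorm(n, mu[["SITTING"]], sd[["SITTING"]])
  crawling <- chain_gap(sitting, "SITTING", "CRAWLING")
  walk_base <- chain_gap(crawling, "CRAWLING", "WALKING")

  rr_param <- rr_from_dips(cfg, dips$VERB2, dips$SYMB2, dips$SYMB3)
  rr_center <- rr_from_dips(cfg, cfg$dip_fraction[["VERB2"]],
                            cfg$dip_fraction[["SYMB2"]],
                            cfg$dip_fraction[["SYMB3"]])
  walking <- walk_base + cfg$coupling_beta * (rr_param - rr_center) +
    stats::rnorm(n, 0, cfg$noise_sd_weeks)
  walking <- pmax(walking, crawling + 1)

  truth <- data.frame(
    subject_id = sprintf("S%03d", seq_len(n)),
    SYMB1 = symb1, SYMB2 = symb2, SYMB3 = symb3, SYMB4 = symb4,
    VERB1 = verb1, VERB2 = verb2, SOC_INFANT = soc_i, SOC_MOTHER = soc_m,
    PRE_SITTING = 0, SITTING = sitting, CRAWLING = crawling, WALKING = walking,
    z = z, stringsAsFactors = FALSE)
  for (code in names(anchor_wiring()))
    truth[[paste0("dip_", code)]] <- dips[[code]]
  truth$rr_param <- rr_param
  truth$right_censored <- truth$WALKING > max(cfg$schedule)
  truth$latent_rr <- vapply(seq_len(n), function(i)
    latent_rr_grid(cfg, truth[i, , drop = FALSE]), numeric(1))
  truth
}

#' Draw per-subject milestone initiation ages
#'
#' Ages within each domain chain (symbolic levels 1-4; babbling before
#' words; sitting before crawling before walking) are sampled as a start
#' age plus positive truncated-normal gaps (lower bound 1 week), so the
#' orderings hold for every subject by construction, not by rejection.
#' The walking age includes the RR coupling shift and Gaussian noise and
#' is clipped to stay at least one week after crawling. With all sds
#' zero the draw is degenerate at the configured means (plus the coupling
#' shift on walking).
#'
#' @param config An [rr_sim_config()].
#' @return data.frame, one row per subject, one column per milestone
#'   (behavior codes and locomotor stages) holding true initiation ages in
#'   weeks. Uses the current RNG state; seed via [set.seed()] or use
#'   [simulate_rr_cohort()].
#' @export
draw_milestone_ages <- function(config) {
  stopifnot(inherits(config, "rr_sim_config"))
  truth <- draw_subject_truth(config)
  truth[, c("subject_id", all_milestones())]
}

#' Latent count intensity of a behavior for one subject
#'
#' The expected counts/hour as a function of age: 0 before the behavior's
#' emergence age; a linear ramp from `emergence_fraction` of plateau to
#' plateau over `rise_time_weeks`; multiplied by `(1 - dip)` inside the
#' trough `[anchor, anchor + dip_window_weeks)` locked to the behavior's
#' anchor-milestone transition (only if the behavior emerged before the
#' anchor — an unexpressed behavior has nothing to suppress); then linear
#' recovery toward `plateau * (1 - dip * (1 - rebound_fraction))`.
#'
#' @param config An [rr_sim_config()].
#' @param subject_truth One row of the truth table (see
#'   [simulate_rr_cohort()]) or of [draw_milestone_ages()] output
#'   augmented with `dip_*` columns; columns named by milestone give true
#'   ages.
#' @param code A behavior code.
#' @param age_weeks Numeric vector of ages.
#' @return Expected counts/hour at each age.
#' @export
behavior_intensity <- function(config, subject_truth, code, age_weeks) {
  if (!code %in% behavior_codes()) stop("unknown behavior code: ", code)
  emerge <- subject_truth[[code]]
  base <- config$base_intensity[[code]]
  ef <- config$emergence_fraction
  ramp <- ifelse(age_weeks < emerge, 0,
                 ef + (1 - ef) * pmin(1, (age_weeks - emerge) / config$rise_time_weeks))
  s <- rep(1, length(age_weeks))
  anchor_m <- anchor_wiring()[code]
  if (!is.na(anchor_m)) {
    dip_col <- paste0("dip_", code)
    d <- if (dip_col %in% names(subject_truth)) subject_truth[[dip_col]] else
      config$dip_fraction[[code]]
    a <- subject_truth[[unname(anchor_m)]]
    if (!is.na(a) && emerge < a && d != 0) {
      w <- config$dip_window_weeks
      in_trough <- age_weeks >= a & age_weeks < a + w
      post <- age_weeks >= a + w
      s[in_trough] <- 1 - d
      rec <- d * config$rebound_fraction *
        pmin(1, (age_weeks[post] - a - w) / config$rise_time_weeks)
      s[post] <- 1 - d + rec
    }
  }
  pmax(0, base * ramp * s)
}

# Noise-free RR on the subject's actual session grid: anchors are the
# first scheduled session at/after the true anchor age, deltas are the
# analysis-side two-point difference quotients applied to expected
# intensities. This is the estimand the pipeline recovers.
latent_rr_grid <- function(cfg, truth_row) {
  sched <- cfg$schedule
  grid_delta <- function(code, anchor_age) {
    i <- match(TRUE, sched >= anchor_age)
    if (is.na(i) || i == 1L) return(NA_real_)
    y1 <- behavior_intensity(cfg, truth_row, code, sched[i])
    y0 <- behavior_intensity(cfg, truth_row, code, sched[i - 1L])
    (y1 - y0) / (sched[i] - sched[i - 1L])
  }
  d_sp2 <- grid_delta("VERB2", truth_row$WALKING)
  d_s2 <- grid_delta("SYMB2", truth_row$VERB2)
  d_s3 <- grid_delta("SYMB3", truth_row$SYMB4)
  compute_rr(d_sp2, d_s2, d_s3)
}

#' Simulate a synthetic cohort with ground truth
#'
#' Draws per-subject latent state ([draw_milestone_ages()] plus dip
#' factors and the latent RR), then Poisson session counts
#' `Poisson(intensity x duration_hours)` at each scheduled age, and
#' locomotor flags set `TRUE` from the first scheduled session at/after
#' each stage's true age. Fully deterministic given `(config, seed)`.
#'
#' @param config An [rr_sim_config()].
#' @param seed Integer seed; defaults to `config$seed`.
#' @return An object of class `rr_sim`: a list with elements
#'   \describe{
#'     \item{cohort}{an [rr_cohort()] of observed sessions;}
#'     \item{truth}{data.frame of per-subject latent state: true milestone
#'       ages, `dip_*` factors, reallocation propensity `z`, the analytic
#'       `rr_param` that drives the walking coupling, the grid-evaluated
#'       noise-free `latent_rr` (the estimand), realized `WALKING` age and
#'       a `right_censored` flag for subjects whose walking age falls
#'       beyond the schedule;}
#'     \item{config, seed}{provenance.}
#'   }
#' @export
simulate_rr_cohort <- function(config, seed = NULL) {
  stopifnot(inherits(config, "rr_sim_config"))
  if (is.null(seed)) seed <- config$seed
  set.seed(as.integer(seed))
  truth <- draw_subject_truth(config)
  sched <- config$schedule
  dur_h <- config$duration_minutes / 60
  n_ses <- length(sched)
  rows <- vector("list", config$n_subjects)
  for (i in seq_len(config$n_subjects)) {
    tr <- truth[i, , drop = FALSE]
    df <- data.frame(subject_id = tr$subject_id,
                     session_index = seq_len(n_ses),
                     age_weeks = sched,
                     duration_minutes = config$duration_minutes,
                     stringsAsFactors = FALSE)
    for (code in behavior_codes()) {
      lambda <- behavior_intensity(config, tr, code, sched) * dur_h
      df[[code]] <- as.numeric(stats::rpois(n_ses, lambda))
    }
    for (st in locomotor_stages())
      df[[st]] <- sched >= tr[[st]]
    rows[[i]] <- df
  }
  cohort <- rr_cohort(do.call(rbind, rows), check = FALSE)
  structure(list(cohort = cohort, truth = truth, config = config,
                 seed = as.integer(seed)),
            class = "rr_sim")
}

#' @export
print.rr_sim <- function(x, ...) {
  cat("<rr_sim> seed", x$seed, "\n")
  print(x$cohort)
  cat(" right-censored (never walk in window):",
      sum(x$truth$right_censored), "subjects\n")
  invisible(x)
}

#' Simulate cohorts from a configuration
#'
#' [stats::simulate()] method for `rr_sim_config`: draws `nsim`
#' independent cohorts, advancing the seed by one per replicate.
#'
#' @param object An [rr_sim_config()].
#' @param nsim Number of cohorts.
#' @param seed Base seed (defaults to `object$seed`).
#' @param ... Unused.
#' @return A list of `rr_sim` objects (length `nsim`), or a single
#'   `rr_sim` when `nsim = 1`.
#' @export
simulate.rr_sim_config <- function(object, nsim = 1, seed = NULL, ...) {
  if (is.null(seed)) seed <- object$seed
  sims <- lapply(seq_len(nsim) - 1L,
                 function(k) simulate_rr_cohort(object, seed = seed + k))
  if (nsim == 1) sims[[1]] else sims
}

#' Export simulation ground truth as CSV
#'
#' Writes the two plain-text truth tables: a long table
#' `subject_id,milestone,true_age_weeks` and a per-subject table
#' `subject_id,latent_rr,walking_age_weeks`.
#'
#' @param sim An `rr_sim` from [simulate_rr_cohort()].
#' @param ages_path,rr_path Output CSV paths.
#' @return Invisibly, the two paths.
#' @export
write_truth <- function(sim, ages_path, rr_path) {
  stopifnot(inherits(sim, "rr_sim"))
  tr <- sim$truth
  ms <- all_milestones()
  long <- data.frame(
    subject_id = rep(tr$subject_id, each = length(ms)),
    milestone = rep(ms, times = nrow(tr)),
    true_age_weeks = as.vector(t(as.matrix(tr[, ms]))),
    stringsAsFactors = FALSE)
  utils::write.csv(format_for_csv(long), ages_path, row.names = FALSE, quote = FALSE)
  rrdf <- tr[, c("subject_id", "latent_rr", "WALKING")]
  names(rrdf) <- c("subject_id", "latent_rr", "walking_age_weeks")
  utils::write.csv(format_for_csv(rrdf), rr_path, row.names = FALSE, quote = FALSE)
  invisible(c(ages_path, rr_path))
}
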