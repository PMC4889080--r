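test_that("milestone-age draws respect every ordering constraint by construction", {
  for (seed in c(1, 99)) {
    cfg <- rr_sim_config(n_subjects = 200, seed = seed)
    set.seed(seed)
    ages <- draw_milestone_ages(cfg)
    expect_true(all(ages$SYMB1 < ages$SYMB2))
    expect_true(all(ages$SYMB2 < ages$SYMB3))
    expect_true(all(ages$SYMB3 < ages$SYMB4))
    expect_true(all(ages$VERB1 < ages$VERB2))
    expect_true(all(ages$SITTING < ages$CRAWLING))
    expect_true(all(ages$CRAWLING < ages$WALKING))
  }
})

test_that("zero-sd configuration degenerates to the configured means", {
  cfg <- rr_sim_config(n_subjects = 5,
                       milestone_age_sds = stats::setNames(
                         rep(0, 11), setdiff(c(behavior_codes(), locomotor_stages()),
                                             "PRE_SITTING")),
                       dip_loading = stats::setNames(rep(0, 5), names(anchor_wiring())),
                       dip_idio_sd = 0,
                       noise_sd_weeks = 0)
  set.seed(1)
  ages <- draw_milestone_ages(cfg)
  mu <- cfg$milestone_age_means
  for (m in names(mu))
    expect_equal(ages[[m]], rep(unname(mu[[m]]), 5), tolerance = 1e-12)
  # all dip heterogeneity off: the coupling shift is exactly zero too
  expect_equal(ages$WALKING, rep(unname(mu[["WALKING"]]), 5))
})

test_that("simulation is deterministic given a seed and sensitive to it", {
  cfg <- rr_sim_config(n_subjects = 8)
  s1 <- simulate_rr_cohort(cfg, seed = 7)
  s2 <- simulate_rr_cohort(cfg, seed = 7)
  expect_identical(s1$cohort$sessions, s2$cohort$sessions)
  expect_identical(s1$truth, s2$truth)
  s3 <- simulate_rr_cohort(cfg, seed = 8)
  expect_false(identical(s1$cohort$sessions, s3$cohort$sessions))
})

test_that("a zero base intensity yields all-zero counts for that code", {
  base <- c(SYMB1 = 0, SYMB2 = 2, SYMB3 = 2, SYMB4 = 1.5, VERB1 = 4,
            VERB2 = 1.67, SOC_INFANT = 3.7, SOC_MOTHER = 3.5)
  sim <- simulate_rr_cohort(rr_sim_config(n_subjects = 20, base_intensity = base),
                            seed = 2)
  expect_true(all(sim$cohort$sessions$SYMB1 == 0))
  expect_true(any(sim$cohort$sessions$SYMB2 > 0))
})

test_that("intensity is zero pre-emergence, ramps to plateau, and halves in the trough", {
  cfg <- rr_sim_config(n_subjects = 2, dip_fraction = c(SYMB2 = 0.5),
                       dip_loading = c(SYMB2 = 0), dip_idio_sd = 0)
  truth <- data.frame(SYMB2 = 40, VERB2 = 58, dip_SYMB2 = 0.5)
  expect_equal(behavior_intensity(cfg, truth, "SYMB2", 39.9), 0)
  # ramp: emergence_fraction at onset, linear to plateau over rise_time
  expect_equal(behavior_intensity(cfg, truth, "SYMB2", 40),
               cfg$base_intensity[["SYMB2"]] * cfg$emergence_fraction)
  expect_equal(behavior_intensity(cfg, truth, "SYMB2", 40 + cfg$rise_time_weeks),
               cfg$base_intensity[["SYMB2"]])
  # plateau holds up to the anchor, halves inside the trough
  expect_equal(behavior_intensity(cfg, truth, "SYMB2", 57.9),
               cfg$base_intensity[["SYMB2"]])
  expect_equal(behavior_intensity(cfg, truth, "SYMB2", 59),
               cfg$base_intensity[["SYMB2"]] * 0.5)
  # recovery approaches plateau * (1 - dip*(1 - rebound_fraction))
  far <- 58 + cfg$dip_window_weeks + cfg$rise_time_weeks + 10
  expect_equal(behavior_intensity(cfg, truth, "SYMB2", far),
               cfg$base_intensity[["SYMB2"]] * (1 - 0.5 * (1 - cfg$rebound_fraction)))
  # no dip: plain ramp/plateau at all ages
  truth0 <- data.frame(SYMB2 = 40, VERB2 = 58, dip_SYMB2 = 0)
  expect_equal(behavior_intensity(cfg, truth0, "SYMB2", c(59, far)),
               rep(cfg$base_intensity[["SYMB2"]], 2))
  expect_error(behavior_intensity(cfg, truth, "NOPE", 50), "unknown behavior code")
})

test_that("no behavior is ever observed before its true emergence age", {
  sim <- simulate_rr_cohort(rr_sim_config(n_subjects = 100), seed = 5)
  s <- sim$cohort$sessions
  tr <- sim$truth
  for (code in behavior_codes()) {
    first_pos <- tapply(seq_len(nrow(s)), s$subject_id, function(ix) {
      pos <- ix[s[[code]][ix] > 0]
      if (length(pos) == 0) NA_real_ else min(s$age_weeks[pos])
    })
    tru <- tr[[code]][match(names(first_pos), tr$subject_id)]
    ok <- is.na(first_pos) | first_pos >= tru - 1e-9
    expect_true(all(ok))
  }
})

test_that("plateau counts match base_intensity x duration on average", {
  # law-of-large-numbers check at n = 500: plateau sessions for SYMB1,
  # which has no dip, between ramp completion and end of follow-up
  cfg <- rr_sim_config(n_subjects = 500)
  sim <- simulate_rr_cohort(cfg, seed = 11)
  s <- sim$cohort$sessions
  tr <- sim$truth
  emerge <- tr$SYMB1[match(s$subject_id, tr$subject_id)]
  sel <- s$age_weeks >= emerge + cfg$rise_time_weeks
  m <- mean(s$SYMB1[sel])
  expected <- cfg$base_intensity[["SYMB1"]] * cfg$duration_minutes / 60
  se <- stats::sd(s$SYMB1[sel]) / sqrt(sum(sel))
  expect_lt(abs(m - expected), 3 * se + 1e-9)
})

test_that("latent RR is uncorrelated with walking age when the coupling is off", {
  # the analytic RR that drives the coupling is independent of walking age
  # by construction under the study-scale conditions
  cfg <- rr_sim_config(n_subjects = 200, coupling_beta = 0)
  sim <- simulate_rr_cohort(cfg, seed = 13)
  tr <- sim$truth
  expect_lt(abs(stats::cor(tr$rr_param, tr$WALKING)), 2 / sqrt(200))
  # the grid-evaluated latent RR also decorrelates once the transition
  # milestones are well separated (the validation design)
  simv <- simulate_rr_cohort(rr_validation_config(n_subjects = 200,
                                                  coupling_beta = 0), seed = 13)
  trv <- simv$truth
  keep <- is.finite(trv$latent_rr)
  expect_lt(abs(stats::cor(trv$latent_rr[keep], trv$WALKING[keep])),
            2.5 / sqrt(sum(keep)))
})

test_that("config invariants are enforced and configs round-trip through JSON", {
  expect_error(rr_sim_config(n_subjects = 1))
  expect_error(rr_sim_config(schedule = c(30, 28)))
  expect_error(rr_sim_config(dip_fraction = c(SYMB2 = 1.5)))
  expect_error(rr_sim_config(rebound_fraction = 2))
  expect_error(rr_sim_config(base_intensity = c(SYMB2 = -1)))

  cfgfile <- withr::local_tempfile(fileext = ".json")
  jsonlite::write_json(list(n_subjects = 12, coupling_beta = -3,
                            dip_fraction = list(SYMB2 = 0.5)),
                       cfgfile, auto_unbox = TRUE)
  cfg <- read_sim_config(cfgfile)
  expect_equal(cfg$n_subjects, 12L)
  expect_equal(cfg$coupling_beta, -3)
  expect_equal(unname(cfg$dip_fraction[["SYMB2"]]), 0.5)
})

test_that("truth export writes the documented CSV tables", {
  sim <- simulate_rr_cohort(rr_sim_config(n_subjects = 4), seed = 9)
  sdir <- withr::local_tempdir()
  pa <- file.path(sdir, "ages.csv"); pr <- file.path(sdir, "rr.csv")
  write_truth(sim, pa, pr)
  ages <- utils::read.csv(pa)
  expect_equal(names(ages), c("subject_id", "milestone", "true_age_weeks"))
  expect_equal(nrow(ages), 4 * length(c(behavior_codes(), locomotor_stages())))
  rrt <- utils::read.csv(pr)
  expect_equal(names(rrt), c("subject_id", "latent_rr", "walking_age_weeks"))
  expect_equal(rrt$walking_age_weeks, sim$truth$WALKING)
})
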