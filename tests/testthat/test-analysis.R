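# Three hand-built subjects observed at 50, 52, 55, 58 weeks; all deltas
# below are hand-computed from the two-point difference quotients.
fixture_cohort <- function() {
  make_cohort(list(
    A = list(ages = c(50, 52, 55, 58),
             counts = list(VERB2 = c(0, 0, 2, 1), SYMB2 = c(3, 2, 4, 1),
                           SYMB3 = c(2, 1, 1, 0), SYMB4 = c(0, 1, 1, 1),
                           SOC_INFANT = c(1, 2, 5, 0), SOC_MOTHER = c(0, 0, 3, 0)),
             stages = list(WALKING = c(FALSE, FALSE, FALSE, TRUE),
                           CRAWLING = c(TRUE, TRUE, TRUE, TRUE))),
    B = list(ages = c(50, 52, 55, 58),
             counts = list(VERB2 = c(0, 1, 2, 2), SYMB2 = c(2, 2, 1, 1),
                           SYMB3 = c(1, 3, 0, 2), SYMB4 = c(0, 0, 2, 2),
                           SOC_INFANT = c(2, 4, 1, 1), SOC_MOTHER = c(1, 1, 1, 1)),
             stages = list(WALKING = c(FALSE, FALSE, TRUE, TRUE),
                           CRAWLING = c(TRUE, TRUE, TRUE, TRUE))),
    C = list(ages = c(50, 52, 55, 58),
             counts = list(VERB2 = c(0, 2, 0, 0), SYMB2 = c(4, 1, 0, 0),
                           SYMB3 = c(2, 2, 2, 2), SYMB4 = c(0, 2, 1, 1),
                           SOC_INFANT = c(0, 3, 1, 1), SOC_MOTHER = c(0, 2, 1, 1)),
             stages = list(WALKING = c(FALSE, TRUE, TRUE, TRUE),
                           CRAWLING = c(TRUE, TRUE, TRUE, TRUE)))))
}

test_that("the report matches hand-computed coefficients field-for-field", {
  an <- rr_analysis(fixture_cohort(), permutations = 0)
  co <- coef(an)
  co <- co[order(co$subject_id), ]
  # A: Tw 58, Tl 55, Ts 52
  expect_equal(co$d_sp2[1], (1 - 2) / 3)
  expect_equal(co$d_symb2[1], (4 - 2) / 3)
  expect_equal(co$d_symb3[1], (1 - 2) / 2)
  expect_equal(co$d_soc_infant[1], (5 - 2) / 3)
  expect_equal(co$d_soc_mother[1], (3 - 0) / 3)
  expect_equal(co$rr[1], -1/3 - 2/3 - 1/2)
  # B: Tw 55, Tl 52, Ts 55
  expect_equal(co$d_sp2[2], (2 - 1) / 3)
  expect_equal(co$d_symb2[2], 0)
  expect_equal(co$d_symb3[2], (0 - 3) / 3)
  expect_equal(co$rr[2], 1/3 - 0 - 1)
  # C: Tw 52, Tl 52, Ts 52
  expect_equal(co$d_sp2[3], (2 - 0) / 2)
  expect_equal(co$d_symb2[3], (1 - 4) / 2)
  expect_equal(co$d_symb3[3], 0)
  expect_equal(co$rr[3], 1 + 3/2)
  # H3: RR against walking age, against the directly computed correlation
  rr_hand <- c(-1.5, -2/3, 2.5)
  walk_hand <- c(58, 55, 52)
  expect_equal(an$h3$rr_vs_walking$r, stats::cor(rr_hand, walk_hand),
               tolerance = 1e-12)
  expect_equal(an$h3$rr_vs_walking$n, 3)
})

test_that("milestone anchors in the fixture are the subjects' own transition sessions", {
  ms <- milestone_table(fixture_cohort())
  a_symb2 <- ms[ms$subject_id == "A" & ms$code == "SYMB2", ]
  expect_equal(a_symb2$anchor_age_weeks, 55)   # A's word onset
  expect_equal(a_symb2$peak_rate, 3)           # max pre-anchor rate, earliest at 50
  expect_equal(a_symb2$peak_age_weeks, 50)
  expect_equal(a_symb2$rate_at_anchor, 4)
  expect_equal(a_symb2$rebound_rate, 1)
  b_verb2 <- ms[ms$subject_id == "B" & ms$code == "VERB2", ]
  expect_equal(b_verb2$anchor_age_weeks, 55)   # B walks at 55
  expect_equal(b_verb2$initiation_age_weeks, 52)
})

test_that("a cohort where nobody walks reports insufficient data, not silence", {
  ch <- make_cohort(list(
    A = list(ages = c(50, 52, 55),
             counts = list(VERB2 = c(0, 1, 1), SYMB2 = c(1, 1, 1),
                           SYMB3 = c(1, 2, 1), SYMB4 = c(0, 1, 1))),
    B = list(ages = c(50, 52, 55),
             counts = list(VERB2 = c(0, 0, 2), SYMB2 = c(2, 1, 1),
                           SYMB3 = c(1, 1, 1), SYMB4 = c(0, 0, 1)))))
  an <- rr_analysis(ch, permutations = 0)
  expect_equal(length(an$h3), 9)
  expect_true(all(vapply(an$h3, function(e) !inherits(e, "rr_cor"), logical(1))))
  expect_equal(an$h3$rr_vs_walking$status, "insufficient_data")
  # H1/H2 remain partially populated
  expect_equal(an$h1$n_walking_observed, 0)
  expect_s3_class(an$h2$contrasts$SYMB2, "rr_paired")
})

test_that("simulate -> analyze -> report is reproducible given the seed", {
  cfg <- rr_sim_config(n_subjects = 9)
  r1 <- write_report(rr_analysis(simulate_rr_cohort(cfg, seed = 4),
                                 permutations = 99, seed = 1))
  r2 <- write_report(rr_analysis(simulate_rr_cohort(cfg, seed = 4),
                                 permutations = 99, seed = 1))
  expect_identical(r1, r2)
  parsed <- jsonlite::fromJSON(r1)
  expect_setequal(names(parsed), c("cohort", "h1", "h1_per_subject", "h2",
                                   "h3", "exclusions", "provenance"))
  expect_true(all(c("n", "r", "p_parametric", "p_permutation") %in%
                    names(parsed$h3$rr_vs_walking)))
})

test_that("analysis methods print and summarize without error", {
  an <- rr_analysis(fixture_cohort(), permutations = 0)
  expect_output(print(an), "Resource-reallocation analysis")
  expect_output(summary(an), "Per-subject change coefficients")
  expect_silent(grDevices::pdf(NULL))
  expect_no_error(plot(an, fixture_cohort()))
  grDevices::dev.off()
})

test_that("recovery tables are seed-reproducible and monotone in the coupling", {
  cfg <- rr_validation_config(n_subjects = 30)
  r1 <- recovery_experiment(cfg, coupling_betas = c(0, -0.34),
                            n_replicates = 2, seed = 6)
  r2 <- recovery_experiment(cfg, coupling_betas = c(0, -0.34),
                            n_replicates = 2, seed = 6)
  expect_identical(r1, r2)

  betas <- c(0, -0.15, -0.34)
  rec <- recovery_experiment(cfg, coupling_betas = betas, n_replicates = 5,
                             seed = 30)
  s <- summary(rec)
  s <- s[match(betas, s$coupling_beta), ]
  # mean |r| rises monotonically with the coupling strength
  expect_equal(stats::cor(abs(betas), s$mean_abs_r_est, method = "spearman"), 1)
})
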