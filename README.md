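# rralloc

Event-aligned analysis of longitudinal infant observation cohorts, built
around a *resource-reallocation* (RR) composite: the idea that infants
transiently suppress recently mastered behaviors (symbolic play, early
speech, social bids) around the emergence of a new milestone — most
prominently walking — and that the degree of this reallocation relates to
*when* the new milestone appears.

The package is for developmental researchers working with coded
observation-session tables: one count per subject × session × behavior,
plus session-level locomotor-stage flags. It provides

- a **coding schema and CSV interchange format** for such cohorts
  (`read_cohort()`, `write_cohort()`, `validate_cohort()`);
- **milestone extraction**: initiation ages ("first session in which the
  behavior was observed"), pre-milestone peak rates, rates at each
  subject's own transition sessions, post-milestone rebounds
  (`milestone_table()`);
- **event-aligned change coefficients and the RR composite**
  (`coefficients_table()`, `compute_rr()`);
- **small-sample inference**: Pearson correlations with parametric *and*
  permutation p-values, paired t contrasts, Cohen's kappa
  (`pearson_r()`, `permutation_p()`, `paired_t()`, `cohens_kappa()`);
- a **synthetic-cohort simulator** with ground truth
  (`simulate_rr_cohort()`) and a **parameter-recovery harness**
  (`recovery_experiment()`) for validating the whole pipeline.

## The statistic

For each subject, behaviors are aligned to that subject's *own*
transition sessions: `T_w` (first session with independent walking),
`T_l` (first session with single-word utterances), `T_s` (first session
with multi-object sequence play). With session rates in counts/hour and
`Δt` the actual gap to the immediately preceding session (2 weeks in the
bi-weekly phase, 3 in the tri-weekly phase), the change coefficients are
two-point difference quotients, e.g.

    ΔSp2/Δt  = [Sp2(T_w) − Sp2(T_w − Δt)] / Δt

for the speech rate `Sp2` at the walking transition, and analogously
`ΔSymb2/Δt` (single-object sequences at `T_l`) and `ΔSymb3/Δt`
(multi-object play at `T_s`). The composite is

    RR = ΔSp2/Δt − (ΔSymb2/Δt − ΔSymb3/Δt)

i.e. speech recruitment net of the difference between the two symbolic
suppression terms. RR is then correlated with walking-onset age across
subjects, with censored components (milestones never observed in the
follow-up window) propagated and excluded pairwise.

## Worked example

Simulate a nine-subject cohort under the default (study-scale)
conditions and run the full analysis:

```r
library(rralloc)
cfg <- rr_sim_config(n_subjects = 9)
sim <- simulate_rr_cohort(cfg, seed = 42)
an  <- rr_analysis(sim, permutations = 999, seed = 1)
an
```

```
Resource-reallocation analysis
  9 subjects, 198 sessions (ages 26-76 wk)
H1: 2 of 9 subjects attained all symbolic levels and words before walking
    mean lead: complex play -0.8 wk, words -1.7 wk
H2: peak vs at-emergence contrasts
    single-object sequences at word onset: 3 (±1.1) -> 0.778 (±1.3), t(8) = 5.121, p = 0.0009055, n = 9
    single-word utterances at walking onset: 0.667 (±1.1) -> 0.444 (±0.73), t(8) = 0.610, p = 0.5588, n = 9
    infant social bids at walking onset: 6.89 (±0.93) -> 2.56 (±2.6), t(8) = 5.814, p = 0.0003989, n = 9
H3: correlations with milestone ages
    Pearson r(d_symb2, walking_age_weeks) = 0.103, n = 9, p = 0.7928 (permutation p = 0.833, B = 999)
    ...
    Pearson r(rr, walking_age_weeks) = -0.499, n = 9, p = 0.1719 (permutation p = 0.213, B = 999)
```

Reading the output: the **H1** block counts subjects whose four
symbolic-play levels and first words all preceded walking, with mean
lead times in weeks (negative means detected initiation fell after
walking — at rates of ~2 events/hour, first detection lags true
emergence by a session or two, which is part of what the simulator lets
you study). **H2** shows each behavior's pre-transition peak rate
against its rate at the transition session — here single-object
sequences drop from 3.0 to 0.8 events/hour at word onset. **H3** gives
the per-coefficient correlations with walking age; with n = 9 the
permutation p-values are the ones to trust. `coef(an)` returns the
per-subject coefficient table, `write_report(an, "report.json")` the
machine-readable report, and `plot(an, sim$cohort)` the mean-trajectory
panel.

Validation of the estimator against ground truth:

```r
rec <- recovery_experiment(rr_validation_config(n_subjects = 60),
                           n_replicates = 50, seed = 1)
summary(rec)   # estimated |r| tracks the realized latent |r| within ~0.06
```

## Command line

A thin wrapper over the same functions is installed as `exec/rralloc`:

```sh
rralloc simulate --config cfg.json --seed 1 --out data/
rralloc analyze  --sessions data/sessions.csv --locomotor data/locomotor.csv --out report.json
rralloc recover  --betas "0,-0.17,-0.34" --replicates 20 --out recovery.csv
rralloc validate --sessions data/sessions.csv --locomotor data/locomotor.csv
```

See `vignettes/resource-reallocation.Rmd` for the model, the simulator's
design and its limitations.
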