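---
title: "Event-aligned resource-reallocation analysis: model, simulator and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Event-aligned resource-reallocation analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rralloc)
```

## The analysis

The package analyzes longitudinal observation cohorts in which infants
are coded, session by session, for eight count-valued behaviors — four
ordered symbolic-play levels (single-object play `SYMB1`, single-object
sequences `SYMB2`, multi-object play `SYMB3`, multi-object sequences
`SYMB4`), two verbal levels (babbling `VERB1`, single-word utterances
`VERB2`) and two social-bid channels (`SOC_INFANT`, `SOC_MOTHER`) — plus
session-level locomotor-stage flags (pre-sitting, sitting, crawling,
walking). Ages are kept in weeks throughout; counts are converted to
rates as count / (duration/60), so a one-hour session's rate equals its
count and variable-duration sessions normalize correctly.

Three quantities are extracted per subject and behavior:

1. **Initiation age** — the age of the first session in which the
   behavior is observed (count > 0, or a stage flag turning `TRUE`). A
   behavior never observed is *censored* (`NA`) and propagates; a
   behavior already present at the very first session is flagged
   left-censored with a warning but retained, since early behaviors are
   expected to predate a follow-up that starts at six months.
2. **Event-aligned change coefficient** — the two-point difference
   quotient between the behavior's rate at an *anchor* session (the
   subject's own transition: word onset `T_l`, complex-play onset `T_s`,
   walking onset `T_w`) and at the immediately preceding session,
   divided by the actual inter-session gap in weeks. No interpolation or
   smoothing is done anywhere: every quantity lives on observed
   sessions. When the anchor is the subject's first session the
   coefficient is censored (no preceding observation).
3. **Peak / at-anchor / rebound rates** — the maximum rate strictly
   before the anchor (ties broken by earliest age; a global maximum, not
   a local one), the rate at the anchor session, and the maximum rate
   strictly after it.

The composite is `RR = ΔSp2/Δt − (ΔSymb2/Δt − ΔSymb3/Δt)`: speech
recruitment at the walking transition net of the difference between the
two symbolic-play suppression terms. The anchor wiring —
`SYMB2 → T_l`, `SYMB3 → T_s`, `VERB2`/`SOC_* → T_w` for the dip
contrasts — is fixed; the social-bid *coefficients* are anchored at word
onset by default with walking onset available via `soc_anchor`, because
the observational literature motivating them describes social-bid
changes before speech onset, and the choice is genuinely underdetermined.
Social bids are treated as per-session counts (not per play episode);
the coding unit is the session everywhere else, and a per-episode unit
would require episode segmentation the data model does not carry.

### Δt: actual gap, not nominal

The observation design is bi-weekly from 26 to 52 weeks and tri-weekly
from 52 to 78 (`default_schedule()`, 22 sessions). A fixed two-week Δt
would be internally inconsistent for anchors in the tri-weekly phase —
where the word, complex-play and walking transitions typically fall — so
the denominators use the subject's actual gap (2 or 3 weeks), keeping
every coefficient in per-week units. `fixed_dt_weeks` restores the
constant-interval convention for sensitivity analyses.

### Inference

Correlations use the product-moment formula with the two-sided
parametric p from the t transform on n−2 df, *plus* a seeded permutation
p-value, `p = (1 + #{|r*| ≥ |r_obs|})/(B + 1)` — the add-one estimator,
never exactly zero and valid for the small n this design produces.
Paired peak-vs-at-anchor contrasts use the two-sided paired t-test on
n−1 df with both arms' means and sds reported. All p-values are
two-sided (the substantive hypotheses are directional, but sidedness is
left conservative), and no multiple-testing correction is applied — the
report instead carries every test's n and the list of censored
exclusions, because nine-subject analyses stand or fall on exclusion
transparency. Cohen's kappa is provided for inter-coder reliability of
the play-level coding; the degenerate case where both coders produce a
single identical label (chance agreement 1) is defined as κ = 1 with a
warning.

## The simulator

`simulate_rr_cohort()` generates cohorts with the statistical structure
the analysis assumes, plus the ground truth needed to test it.

**Milestone ages.** Each within-domain chain (symbolic levels 1→4,
babbling→words, sitting→crawling→walking) is sampled as a start age plus
positive inter-milestone gaps drawn from truncated normals with a
one-week lower bound, so orderings hold for *every* draw by
construction rather than by rejection. Defaults (weeks): `SYMB1` 36,
`SYMB2` 44, `SYMB3` 50, `SYMB4` 56, `VERB1` 34, `VERB2` 58, `SITTING`
30, `CRAWLING` 38, `WALKING` 62 — complex play leading walking by six
weeks and words by four on average — with gap sds of 2–3 weeks chosen so
that a majority (not all) of subjects attain all four play levels and
words before walking, as heterogeneous real cohorts do. Zero sds
degenerate exactly to the means.

**Count intensities.** A behavior's expected rate is 0 before its
emergence age, ramps linearly from `emergence_fraction` (default 0.5) of
plateau to the plateau `base_intensity` over `rise_time_weeks` (default
4), and sessions draw counts as Poisson(intensity × duration-hours) —
the minimal dispersion model for non-negative session counts. Default
plateaus sit at the 2–4 events/hour scale of home-observation play
coding.

**Dips and rebounds.** Each behavior wired to an anchor milestone is
suppressed by a factor `(1 − dip)` in a trough starting *at* the anchor
transition and holding for `dip_window_weeks` (default 4, at least one
inter-session gap so the anchor session always samples the trough),
then recovers linearly toward `plateau × (1 − dip(1 − rebound))`. Two
deliberate choices here:

- *The trough is locked to the transition, not spread over a window
  before it.* At bi-/tri-weekly resolution a drop inside the final
  inter-session interval is observationally indistinguishable from one
  at the transition; locking it there gives the two-point coefficient a
  well-defined noise-free target (−dip × plateau / Δt) and reproduces
  the peak-before / trough-at-emergence pattern the analysis measures.
  A flat suppression window *preceding* the anchor would put both the
  anchor session and its predecessor inside the window, making the
  expected coefficient zero and the composite unidentifiable — no
  estimator could recover the coupling from such data.
- *A dip applies only if the behavior emerged before its anchor.* An
  unexpressed behavior has nothing to suppress; this also means
  emergence detection is never degraded by another milestone's trough.

**Subject heterogeneity and the walking coupling.** A single latent
reallocation propensity `z ~ N(0,1)` shifts all dip factors (deeper
symbolic dips, speech/social boosts as `z` grows, via `dip_loading`),
which is what makes the coefficients mutually correlated and gives RR
its between-subject variance. The analytic RR implied by a subject's dip
parameters at the nominal three-week gap (`rr_param` in the truth table)
shifts walking age linearly: `coupling_beta` weeks per unit RR
*deviation from the cohort-expected RR*. Centering is deliberate: with
an uncentered shift, any nonzero coupling would move the whole cohort's
mean walking age by beta × E[RR] and the configured walking mean would
be meaningless. Walking is clipped to stay at least a week after
crawling, and subjects whose walking age falls beyond the schedule are
flagged right-censored.

The truth table carries a second latent quantity, `latent_rr`: the RR
obtained by applying the analysis-side formula to the *noise-free*
intensities on the subject's actual session grid with grid-detected
anchors. This is the estimand the pipeline can at best recover — it
differs from `rr_param` through session quantization, ramp overlap and
milestone crossings — and recovery experiments compare the estimate
against it, like with like.

## Validation designs and problem sizes

`recovery_experiment()` simulates replicate cohorts over a grid of
coupling strengths and compares the pipeline's estimated RR-vs-walking
correlation with the realized latent correlation per replicate.
`rr_validation_config()` is the canonical design for this: plateau 150
events/hour, transition milestones pulled apart (`VERB2` 56, `WALKING`
70, follow-up to 88 weeks), tight gap sds and `coupling_beta = −0.34`,
which realizes a latent correlation of about −0.8. The high rate is
essential, not cosmetic: at study-scale rates of ~2/hour the Poisson
noise of a two-point rate difference (sd ≈ 0.7/week) dwarfs the
between-subject spread of the latent coefficients (≈ 0.25/week), so the
estimated correlation is attenuated to roughly a fifth of the latent
value and *no* estimator of this form could track it — a fact worth
knowing before applying the composite to nine-subject field data. Under
the validation design the attenuation is ~0.05–0.06 and the estimated
sign always agrees with the latent one (200 replicates of 60 subjects in
the acceptance suite; 50 in the acceptance script).

Null calibration uses the same design with the coupling off and
nine-subject cohorts: across replicates, the permutation test at
α = 0.05 rejects at its nominal rate. Note that under the *default*
(study-scale, overlapping-milestone) conditions the grid-evaluated
latent RR is mildly correlated with walking age even at zero coupling —
developmental overlap itself induces structure, because the speech
coefficient's value depends on where the walking session falls relative
to the speech ramp and trough. The validation design separates the
milestones precisely to remove this confound; analysts should be aware
of it when interpreting event-aligned coefficients in real cohorts
where milestones crowd together.

Structural-fidelity checks run at plateau 30/hour with all dip
fractions 0.5 and 200 subjects: every simulated subject satisfies the
ordering constraints; every detected initiation age equals the first
schedule point at/after the true age (at this rate a first-session
Poisson zero is essentially impossible, which is the premise of the
quantization property); and the anchor-vs-plateau mean-rate ratio
recovers 1 − dip within ±0.05.

## What the simulator does not emulate

- No biomechanics of gait and no maternal-behavior dynamics beyond a
  count channel; social bids are a rate, not an interaction model.
- Counts are conditionally Poisson; real coded counts may be over- or
  under-dispersed (bursty play bouts, coder fatigue).
- Milestone ages across domains are independent apart from the RR
  coupling; real domains share maturational factors, so real
  cross-domain age correlations will exceed the simulated ones.
- Sessions never go missing and durations are constant by default;
  real cohorts lose visits.

Passing recovery tests therefore shows the *estimator* is consistent
with its own generative assumptions at adequate signal-to-noise — not
that field data at 2/hour rates can support the same inference.

## Numerical conventions

Session-age matching uses a 1e-8 week tolerance; peak ties break to the
earliest age (`which.max`); censored values are `NA` and propagate
through `compute_rr`; the permutation stream, the simulator and every
analysis stage are seeded, and a fixed seed reproduces reports
bit-for-bit. Truncated-normal gaps use inverse-CDF sampling, with zero
sd degenerating to `max(mean, lower bound)`. The cohort CSV writer
formats doubles at 17 significant digits so write→read is the identity
and repeated writes are byte-identical.
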