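---
title: "Measuring emotional contagion to faces in a 3-D affective space: methods and conventions"
author: "contagion3d"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring emotional contagion to faces in a 3-D affective space}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(contagion3d)
```

## The measurement model

`contagion3d` operationalizes emotional contagion as affective *proximity*
in a three-dimensional monopolar rating space. Each affective state is a
coordinate $(n, p, a) \in [0, 100]^3$: negativity, positivity and arousal,
each rated on its own 0–100 scale ("not bad at all" … "very bad", and so
on). Keeping positivity and negativity as separate monopolar axes follows
the evaluative space model, in which the two are partially independent
rather than ends of one bipolar valence axis.

Two coordinates are compared per face trial: the participant's self-reported
state immediately after an emotional induction video, $(n_v, p_v, a_v)$, and
the affect the participant attributes to a face, $(n_f, p_f, a_f)$. The face
judgment is read as an *indirect* probe of the participant's state at that
moment: by the affect-as-information heuristic, people use their own state
when attributing emotions to others. The contagion score is

$$
ec \;=\; 1 \;-\; \sqrt{\frac{(n_v-n_f)^2 + (p_v-p_f)^2 + (a_v-a_f)^2}
                             {100^2 \cdot 3}} ,
$$

one minus the Euclidean distance rescaled by the maximal possible distance
$100\sqrt{3}$ between two points of the cube. The statistic is symmetric in
its two arguments, invariant under a common permutation of the three
dimensions (the axes are equally weighted), strictly decreasing in each
absolute dimension difference, and attains 1 exactly when the coordinates
coincide and 0 only for opposite corners of the cube.

**A note on the normalization constant.** The divisor is $100^2 \cdot 3$
*inside* the radical (equivalently $100\sqrt{3}$ outside). A divisor of
$100 \cdot 3$ inside the radical, which one sometimes sees written, does not
map the statistic onto $[0, 1]$; only the squared maximal distance does, and
the package implements that convention throughout.

**Boundary condition.** The score measures proximity, not change. If the two
coordinates are close for reasons unrelated to any induction — e.g. both
states are neutral mid-scale points — the score is high regardless of how
much affect was actually transferred. The statistic is therefore meaningful
only under designs where a contagion process is plausibly in operation, and
the inference layer always compares scores *between* conditions rather than
interpreting absolute levels.

## The study design and the inference chain

The supported design is a 2 × 2 split-plot: induction group
(`negative_induction` vs `positive_induction`, between subjects, sizes may
differ) crossed with face valence (10 happy and 10 angry trials per
participant, within subjects). `contagion_analysis()` runs the fixed chain

1. hard validation (`validate_dataset()`): ratings in $[0,100]$, unique
   participant ids, 10 + 10 complete trials per participant;
2. per-trial scoring and per-participant aggregation: the arithmetic mean of
   the 10 per-trial scores within each valence category is the dependent
   variable (one value per participant per cell, matching a two-level
   within factor);
3. outlier screening: a participant is excluded when its mean happy **or**
   mean angry score lies outside the Tukey fences
   $[Q_1 - k\,\mathrm{IQR},\; Q_3 + k\,\mathrm{IQR}]$ computed within its
   own group ($k = 1.5$ by default, configurable). Screening happens once,
   before all inference, and every exclusion is logged with its fence
   values. Screening on the contagion summaries (rather than raw ratings)
   is a package choice: the summaries are the analysis variable, so the
   boxplot the fences emulate is the one an analyst would actually draw;
4. the split-plot ANOVA, per-group paired t-tests (angry − happy, two-sided,
   Bonferroni $m = 2$), Shapiro–Wilk per design cell, Brown–Forsythe per
   valence across groups;
5. Pearson correlations between cell means and any questionnaire totals
   present (ECS, IRI, BES, QPC), unadjusted by default — deliberately, to
   mirror the convention of reporting each instrument separately — with an
   opt-in Bonferroni switch;
6. a likelihood-ratio test for gender (below).

### The split-plot decomposition

With a two-level within factor the design decomposes into two orthogonal
univariate strata: participant means $m_i = (h_i + g_i)/2$ carry the between
stratum and participant differences $d_i = g_i - h_i$ (angry − happy) carry
the within stratum. With group sizes $n_1, n_2$ ($N = n_1 + n_2$):

* $SS_{\text{group}} = 2\sum_j n_j(\bar m_j - \bar m)^2$, tested against
  $SS_{\text{subj}} = 2\sum_i (m_i - \bar m_{g(i)})^2$ on $(1, N-2)$;
* $SS_{\text{valence}} = 2\bar d_u^2 / (1/n_1 + 1/n_2)$ with
  $\bar d_u = (\bar d_1 + \bar d_2)/2$ the *unweighted* marginal mean;
* $SS_{\text{interaction}} = (\bar d_1 - \bar d_2)^2 / \{2(1/n_1+1/n_2)\}$;
* both tested against $SS_{\text{werr}} = \sum_i (d_i - \bar d_{g(i)})^2/2$
  on $(1, N-2)$.

The unweighted-marginal (Type III) convention matters only when groups are
unbalanced (as with 32 vs 35): it prevents the group imbalance from leaking
into the valence main effect. The implementation is verified in the test
suite against two independent routes — a least-squares model-comparison
oracle, and the multivariate repeated-measures Type III analysis — to
$10^{-10}$ on enumerable toy designs. Partial eta squared is
$SS_e/(SS_e + SS_{\text{err}})$ for the matching error stratum, which
satisfies the identity $\eta_p^2 = F \cdot df_1 / (F \cdot df_1 + df_2)$ for
every effect.

Two reporting conventions are deliberate. First, all within-stratum effects
are tested at the participant level ($df_2 = N_{\text{analyzed}} - 2$); the
package never uses a trial-level error stratum for the valence main effect,
because trials are nested in participants and a trial-level $F$ would treat
correlated observations as independent. Second, the degrees of freedom
reflect the participants actually analyzed after exclusion; the report
carries both the input and analyzed counts so the df are always auditable.

### The gender likelihood-ratio test

Trial-level scores are modeled with two nested linear mixed models fitted by
maximum likelihood with `lme4`:

* reference: `score ~ group + valence + (1 | participant_id)`
* augmented: `score ~ group + valence + gender + (1 | participant_id)`

and compared by a $\chi^2_1$ likelihood-ratio test. The random-effects
structure is deliberately a plain random intercept per participant. Richer
structures ("random slopes for the effect of contagion", with contagion as
the outcome) are not statable — an outcome cannot have a random slope on
itself — and a by-face-valence random effect is not identifiable with only
two within levels and a participant intercept already present. Singular-fit
and convergence warnings from the optimizer are attached to the result as a
diagnostics note rather than raised: a boundary estimate of a variance
component is information, not a failure. With constant gender the two models
are identical and the statistic is exactly 0. Under the null generator the
statistic's distribution is checked against its nominal $\chi^2_1$ reference
in the test suite (60 replicates at 12 + 12 participants — small by design;
the check is a sanity constraint on mean and rejection rate, not a precise
size estimate).

## The synthetic-cohort generator

`simulate_cohort()` draws datasets with the statistical structure the
analysis assumes. For participant $i$ in group $g$, with all noise Gaussian
and truncated to $[0, 100]$:

* a participant-level shift $b_i \sim N(0, \sigma_P^2 I_3)$ — a stable
  response style shared by all of that participant's ratings;
* the video coordinate $v_i$ around the group's video anchor
  $V_g + b_i$ with SD $\sigma_R$ per dimension;
* each face judgment around
  $F_k + \delta\,(v_i - F_k) + b_i$ with SD $\sigma_R$, where $F_k$ is the
  happy or angry face anchor and $\delta \in [0, 1]$ is the **assimilation
  fraction** — the generative formalization of the affect-as-information
  heuristic. $\delta = 0$ makes judgments ignore the induced state entirely;
  $\delta = 1$ reproduces it exactly (and, composed with the statistic,
  forces every noiseless score to 1 — a closed form the tests exploit);
* presentation order is a fresh random permutation of the 20 faces per
  participant;
* questionnaire totals are drawn by a Gaussian-copula-style construction
  around each participant's realized mean contagion with configurable
  correlation (default 0 — by default individual differences are *not*
  built into the questionnaires); the instrument scales (ECS 45 ± 8,
  IRI 56 ± 12, BES 70 ± 10, QPC 50 ± 9) are synthetic plausible totals,
  not estimates from any dataset;
* gender (default 50.7% women) and age (21.6 ± 3.7 years) are generated
  independently of all effects.

**Parameters that matter.** `assimilation` ($\delta$, unitless fraction) and
the four anchors (rating units) control the mean structure; `rating_sd`
($\sigma_R$, rating units, default 10) sets per-rating noise; and
`participant_sd` ($\sigma_P$, rating units, default 10) the between-person
response-style spread. Group sizes default to 32 + 35.

**Numerical choices.** Truncation to $[0, 100]$ is by CDF inversion — a
uniform draw between $\Phi(0)$ and $\Phi(100)$ mapped back through the
normal quantile function — which samples the truncated normal exactly, with
one uniform per draw and no rejection loop; a final clamp guards quantile
overflow when a mean sits many SDs outside the range. `sd = 0` degenerates
to the (clamped) mean, which gives the noiseless closed-form cases their
exact equalities. All randomness flows through R's global RNG from a single
`set.seed()` call in a fixed documented draw order (gender, age, shifts,
video ratings, presentation orders, judgments, questionnaire noise), so one
seed yields byte-identical datasets and CSVs.

`simulate_null_cohort()` reuses the machinery with one video anchor and one
face anchor for all cells, so the four design cells are identically
distributed *by construction* — the reference distribution for checking the
interaction test's type-I error (held at 0.05 ± 0.01 over 2000 replicates of
20 + 20 participants in the acceptance suite).

### Calibration of the default configuration

`default_calibrated_config()` is frozen from a one-time search
(`scripts/calibrate.R`, reproducible via `calibrate_generator()`): an
L-BFGS-B search over the two video anchors and $\delta$, within the
$[0,100]$ box and $\delta \in [0.02, 0.6]$, minimizing the summed squared
deviation of simulated cell means (2000 participants per group, fixed
internal seed, hence a deterministic objective) from the target pattern

|                    | happy | angry |
|--------------------|-------|-------|
| negative induction | 0.41  | 0.76  |
| positive induction | 0.71  | 0.54  |

Face anchors are held fixed at stereotyped judgments (happy: low negativity,
high positivity, moderate arousal; angry: the reverse) because the statistic
only sees video-to-face *distances*: freeing both anchor sets adds
translation directions the objective cannot identify. The frozen optimum
places the negative-induction video state near the high-negativity,
high-arousal region (with the arousal coordinate on the box boundary — the
far cell of the target pattern demands nearly the maximal attainable
affective distance, so the search pushes into the corner) and recovers the
target means to three decimals; the acceptance suite verifies ±0.02 at
2000 participants per group on an unrelated seed.

### What the generator does and does not emulate

It emulates: two induction conditions with distinct mean induced states,
the 10 + 10 within design with randomized order, bounded monopolar ratings,
an assimilation pull of judgments toward the induced state, stable
participant-level response styles, and null questionnaire structure.

It does **not** emulate: per-participant *heterogeneity in the assimilation
fraction* itself (one $\delta$ is shared). A consequence worth knowing: the
between-participant SDs of the cell means come out near 0.05 — tighter than
the 0.08–0.18 range real cohorts show — because with a shared $\delta$ the
participant shift enters the video–face distance only with weight $\delta$.
Effect sizes at study size are correspondingly inflated (interaction
$\eta_p^2 \approx 0.95$). Passing tests therefore certify the mean
structure, the statistic, and the inferential machinery — not that the
generator reproduces realistic between-person variability in contagion.
There is also no pre-induction baseline state (the design measures affect
only after the video), no trial-order effects, and no item-level
questionnaire structure.

## Data formats and degenerate inputs

The canonical CSV is the long dialect (one row per rating event: a `video`
row plus 20 `face` rows per participant); a wide dialect (one row per
participant) eases hand-made fixtures. Files carry a schema-version comment
line; numeric fields are written with 17 significant digits so round trips
are lossless. Out-of-range and unparseable cells are *errors naming the
participant and field*, never silently clamped; missing ratings make a trial
incomplete, which excludes it from aggregation with a warning (and breaks
the 10-trial-per-valence invariant, surfacing in validation). Missing
questionnaire totals and demographics are warnings only. Mapping shims
(`col_map`, `group_map`, `valence_map`) translate externally deposited
files whose headers or labels differ from the schema.

Degenerate inputs are defined, not crashed on: identical summaries give
$F = 0$ and $\eta_p^2 = 0$; zero-variance paired differences give a flagged
$t$ with $p = 1$ (when all differences are zero) rather than 0/0; a constant
sample makes Shapiro–Wilk a flagged result; constant gender gives an exact
zero LR statistic; Tukey fences with zero IQR still contain the common
value, and fewer than 4 participants per group is a precondition error
because quartile fences are not meaningful below that.

## Problem sizes used by the test suite

The suite favors sizes that make each property sharp: $10^4$ random
coordinate pairs for the statistic's invariants; 4–8-participant enumerable
designs for the ANOVA oracles; 2000 replicates of 20 + 20 for the type-I
error of the interaction test; 2000 + 2000 participants for calibration
recovery; 60 small-cohort refits for the LRT null. These are the package's
chosen verification sizes — large enough that the Monte-Carlo bands quoted
above are decisive, small enough to run routinely.
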