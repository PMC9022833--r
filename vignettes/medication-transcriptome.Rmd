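---
title: "Medication-transcriptome association: models, defaults and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Medication-transcriptome association: models, defaults and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pharmtx)
```

# The problem

In population cohorts most participants take medication, and usually more
than one drug at a time. Blood gene expression therefore reflects a
mixture of drug effects, demographics, blood-cell composition and
technical artefacts. `pharmtx` implements an association pipeline that
(i) cleans a probe-level microarray intensity matrix, (ii) builds an
adjustment model for the most influential co-medications, (iii) tests
each active substance against every probe with empirical-Bayes moderated
t-statistics, (iv) confirms discoveries in an independent cohort under a
hierarchical, selective multiple-testing correction, and (v) summarizes
replicated genes by pathway over-representation.

This vignette documents the statistical model of each stage, the
defaults and why they were chosen, what the synthetic-cohort generator
does and does not emulate, and the numerical corner cases.

# Preprocessing model

**Detection filter.** A probe is kept when its detection p-value is
≤ `alpha` (0.05) in at least `min_fraction` (5%) of samples, boundary
inclusive. The inclusive reading keeps a probe detected in exactly 5% of
samples, which is the conventional interpretation of "at least". Note a
consequence of these defaults: for a probe whose detection p-values are
exactly uniform (pure background), the keep threshold sits at the mean
of the binomial detection count, so about half of such probes survive at
any sample size. The filter separates expressed from unexpressed probes
sharply only because real (and simulated) expressed probes have strongly
sub-uniform detection p-values.

**Quantile normalization and log2.** Every sample's sorted intensity
vector is replaced by the mean of the samples' order statistics
(`limma::normalizeQuantiles`), then values are log2-transformed with a
configurable offset (default 0; the pipeline performs no background
subtraction, so raw intensities are positive). Quantile normalization
assumes the bulk of the distribution is shared across samples. When a
drug shifts many probes in the *same* direction, part of that mass shift
is redistributed onto null probes; with sign-balanced effects (the
situation observed in practice — up- and down-regulation roughly
balance) the distortion is negligible. This matters when interpreting
simulation results: we plant sign-balanced effects by default
(`down_fraction = 0.5` in `substance_spec()`).

**Mahalanobis sample QC.** Each sample's vector of chip-level QC
features is compared with an artificial average sample via
`d_i = sqrt((x_i - x̄)' S^{-1} (x_i - x̄))` with `S` the sample
covariance. Samples with `d > median(d) + 4·IQR(d)` are removed. The
fence is one-sided and upper because distances are non-negative and only
large values indicate failure. The covariance is estimated from all
samples including contaminants; at the planted contamination levels used
in tests (≤ 5%, ≥ 6 SD shifts on one to three features) this masking
costs little sensitivity (≈ 95% of planted failures are flagged), but a
much heavier contamination would call for a robust covariance, which we
deliberately do not use because the procedure is specified with the
plain sample covariance.

**Batch adjustment.** Known chip batches are removed with the parametric
empirical-Bayes location/scale model: per probe, data are standardized
by the overall fit, per-batch means `γ̂` and variances `δ̂²` are shrunk
toward normal and inverse-gamma priors whose hyperparameters come from
method-of-moments estimates across probes, and the shrunken estimates
are found by fixed-point iteration of the conditional posterior means
(tolerance 1e-4, ≤ 100 iterations). Each batch needs ≥ 2 samples; the
pipeline drops samples in singleton batches before adjusting, and a
single-batch cohort is passed through unchanged.

Two numerical facts about this estimator are worth stating because they
set realistic expectations for tests. First, when the true batch effect
is *homogeneous* across probes, the prior cannot distinguish real
heterogeneity from estimation noise in the batch means, the shrinkage
weight tends to 1/2, and roughly half of the per-probe estimation noise
remains; the residual per-probe batch-mean difference scales like
`0.5·sqrt(2/n_batch)`, i.e. ≈ 0.025 at 500 samples per batch. Second,
the adjustment is not strictly idempotent: every pass re-estimates batch
moments from finite data and shrinks the new estimation noise, so a
second pass moves values by a small but nonzero amount (an order of
magnitude less than the first). Both behaviours are shared exactly by
the reference implementation (`sva::ComBat`), with which the package
agrees to ~1e-6 in tests.

**ANOVA verification.** After adjustment, a per-probe one-way F-test of
expression on batch summarizes residual batch signal as the fraction of
probes with p < 0.05. Before adjustment this fraction is near 1 for real
batch effects; after a successful adjustment it falls *below* the
nominal 0.05 (typically near 0), because subtracting the estimated batch
means makes the F-test conservative. The check is therefore read
one-sidedly: large fractions indicate failure; very small fractions are
expected.

**Euclidean expression filter.** An artificial reference sample is the
probe-wise mean after setting aside the 10% of samples farthest from the
overall mean; samples farther than `median + 4·IQR` from this trimmed
reference are removed. The trim makes the reference robust to the very
outliers the filter is meant to catch.

The stage order is fixed: detection filter → quantile normalization →
log2 → Mahalanobis QC → batch adjustment (+ ANOVA check) → Euclidean
filter. Stages can be toggled off via `pipeline_config()` but not
reordered.

# Polymedication adjustment model

Candidates are substances taken by strictly more than 5% of samples
("more than", hence a substance at exactly 5.0% is excluded). Each
candidate is tested alone on top of the base covariates (sex, age,
lymphocyte %, monocyte %, smoking status, log-BMI); candidates with ≥ 1
probe at BH q ≤ 0.05 enter the adjustment model. Cell fractions may be
entered as percentages or proportions — this rescales the coefficient,
not the test. BMI enters as its natural logarithm.

Variance inflation factors (`VIF_j = 1/(1 - R²_j)`, intercept included
in the auxiliary regressions) are reported for the final design and
flagged above 5, but never trigger automatic removal: pruning is the job
of the odds-ratio screen, which is applied per tested substance. Before
testing substance *t*, every adjustment drug is cross-tabulated with *t*
over the analysis samples; drugs with OR < 0.125 or OR > 8 are dropped
for that test. Zero cells receive the Haldane–Anscombe +0.5 correction
on all four cells so the rule is total. The tested substance is removed
from the adjustment set first — a variable cannot adjust for itself. The
screen uses all analysis samples (not only medication takers), which is
the natural reading when intake indicators are defined for everyone.

# Differential expression

For each substance with ≥ 20 users, ordinary least squares is run for
every probe against the design above. The residual variances `s²_g`
(all with the same residual df `d`) are shrunk toward a common prior:
with `e_g = log s²_g − ψ(d/2) + log(d/2)`, the excess of `var(e)` over
`ψ'(d/2)` identifies the prior df `d₀` through the trigamma inverse
(Newton iteration, tolerance 1e-8), and
`s₀² = exp(mean(e) + ψ(d₀/2) − log(d₀/2))`. Posterior variances are
`s̃²_g = (d₀s₀² + d s²_g)/(d₀ + d)`; when the excess is non-positive,
`d₀ = ∞` and all `s̃²_g = s₀²`. The moderated t for the tested
coefficient has `d₀ + d` degrees of freedom and two-sided p-values;
direction is reported separately as `sign(β̂)`. Probes with `s² = 0`
are excluded from hyperparameter estimation but still receive a valid
posterior variance. BH adjustment is applied per substance ("5% FDR per
substance"), never globally across substances. A gene is significant
when at least one of its probes is; a probe mapped to several genes
contributes to each (gene-level counts deduplicate downstream). Best
probes are chosen by minimal q, ties broken by larger |t|, then by
probe id, so results are deterministic.

# Hierarchical replication

Discovery-significant probes of one substance form a family; only
probes present on the replication platform and substances recorded in
the replication medication table are testable (exclusions are recorded
with reasons). The replication model re-uses the discovery adjustment
substances, with the odds-ratio screen re-run on replication
frequencies. Variance moderation in the replication cohort uses the
full probe ensemble (not just the family), which keeps the prior
estimate stable even for one-probe families.

The multiplicity correction is: BH within each family → family
statistic = minimum q → BH across the M family statistics at level
q → S selected families → within selected families, probes are
declared significant at the selection-adjusted level `q·S/M`. This is
the standard average-FDR-over-selected-families construction for
testing families of hypotheses; because the method's published name
does not pin down the within-family step, the package also implements
the simpler variant that keeps the within-family level at `q`
(`variant = "family_bh"`), with the selective variant as default — it
is the construction with a proven error-control guarantee, and the
family-level error rate under a global null is verified by simulation
in the tests. The family statistic is the minimum *q* (not p), as the
procedure is described operationally. A probe replicates only when it
is significant under this scheme *and* keeps its discovery direction;
a gene replicates when ≥ 1 of its probes does. Nominal significance
(p ≤ 0.05, same direction) and a two-sided exact binomial sign test of
direction concordance are reported as sensitivity analyses — exact
rather than approximate, because families have at most a few hundred
probes.

# Enrichment

Replicated genes per substance are tested against each supplied gene
set by the hypergeometric upper tail `P(X ≥ k)`, with the universe
restricted to all analysed genes (unique genes behind the analysed
probes — genes, not probes, because hits and sets are gene-level
objects). Sets are intersected with the universe before the set size K
is computed. BH runs across all sets of all supplied collections
jointly within a substance. Among significant sets, those driven by an
identical hit-gene list are collapsed to the single set with the
highest odds ratio (ties: smaller p, then set name). Only
over-representation is tested; depletion is out of scope.

# The synthetic cohort generator

`generate_cohort()` emulates the data structures above. On the log2
scale, probe g in sample i is

```
baseline_g + Σ_cov effect_cov · covariate_i + Σ_drug β(drug, g) · intake_i(drug)
           + location_batch(g) + scale_batch(g) · ε,   ε ~ N(0, noise_sd²)
```

and raw intensities are `2^signal`. Defaults, chosen once as plausible
for an adult population cohort and all overridable: sex ~ Bernoulli(0.5);
age ~ N(60, 12) truncated to [18, 90]; lymphocyte % ~ N(30, 7.9);
monocyte % ~ N(8.2, 2.1); smoking ~ Bernoulli(0.2); BMI ~ N(27.9, 4.8)
truncated positive; noise_sd = 1 log2 unit; 90% of probes expressed;
expressed-probe detection p ~ Beta(0.5, 20), unexpressed ~ Uniform(0,1);
batch locations ~ N(0, 0.3); batch variance multipliers ~ inverse-gamma
with mean 1 (shape 50), exactly the family the batch-adjustment prior
assumes, so its parametric assumptions are satisfiable in tests. The
cohorts the generator targets do not publish their residual noise
variance or null-probe fraction, so these two defaults are stated
assumptions rather than measured values.

Co-medication is pairwise: a declared partner pair is drawn from the
2×2 distribution with the two marginal prevalences and the requested
odds ratio (Plackett construction; no higher-order interactions —
enough to exercise the OR screen). Infeasible combinations (an implied
cell probability of zero, e.g. an infinite OR) raise an error. A
configurable `control_fraction` of samples takes no medication at all,
mirroring the no-medication control groups of population cohorts;
marginal prevalences are preserved by rescaling intake among the rest,
at the cost of mildly inflating realized pairwise ORs (forced
concordant zeros), which is why the OR-accuracy tests run without
forced controls.

Planted drug effects are uniform on a configurable range, with a
sign-flip fraction defaulting to 0.5 (balanced up/down, as observed in
real drug signatures). The probe-level structure — gene map, expressed
flags, affected probe sets, effect sizes — depends only on the
configuration seed, while samples, medication, batch effects and noise
also depend on a cohort index: `generate_cohort(cfg, cohort = 1)` and
`cohort = 2` are independent cohorts sharing the same planted truth,
i.e. a ready-made discovery/replication pair.

What the generator does **not** emulate: bead-level array artefacts,
probe sequences, gene–gene correlation networks (probes are
conditionally independent given the design), dose effects, or
disease–drug confounding. Consequently, passing tests demonstrate
calibration and recovery under the model's own assumptions — they do
not certify behaviour under correlated expression or indication bias,
which real cohorts have.

# Numerical choices and degenerate inputs

* Fixed-point iteration for the batch model stops at relative change
  1e-4 (≤ 100 iterations); the trigamma inverse uses Newton steps to
  1e-8.
* Quantile normalization needs ≥ 2 samples; the Euclidean filter ≥ 10;
  Mahalanobis QC needs more samples than features (+1) and a
  non-singular feature covariance (an optional ridge is off by
  default); missing QC features are mean-imputed with a warning.
* A rank-deficient association design is an error naming the dependent
  columns; a perfectly collinear VIF column is reported as infinite
  with a flag instead.
* Substances below 20 users are skipped with a recorded reason, not an
  error; zero significant findings is a valid pipeline outcome.
* All tabular output is written with 10 significant digits, making
  write→read→write a fixed point and whole-pipeline reruns bitwise
  reproducible.

# Problem sizes used in the shipped checks

The packaged tests and the acceptance script measure: FDR control on
cohorts of 3000 samples × 2000 probes with 10% non-null probes (20 and
10 seeds respectively); family-level replication error on 9 families ×
50 probes under a global null; planted-effect recovery at β = +0.45 and
β = −0.75 (3000 samples, prevalence 0.15); hyperparameter recovery on
5000 simulated variances; batch adjustment at 500 samples/batch; and QC
sensitivity at 1000 samples with 5% planted failures. These sizes were
chosen so each property is measured with comfortable Monte-Carlo margin
at desk scale.

# Known limitations

Preprocessing assumes positive raw intensities (no background
subtraction is implemented). The OR screen and adjustment selection are
marginal procedures; a drug pair that is jointly but not marginally
collinear with the tested substance would pass. Replication assumes the
same probe identifiers across platforms. The enrichment stage treats
gene sets as flat lists (no topology, no semantic similarity). And the
generator's independence assumptions mean power estimates from
simulation are optimistic relative to correlated real transcriptomes.
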