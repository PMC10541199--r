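---
title: "Methods: clinical-genomic stratification of ICB-treated HNSCC"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: clinical-genomic stratification of ICB-treated HNSCC}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(icbstrat)
```

# The problem

Recurrent/metastatic head and neck squamous cell carcinoma (HNSCC) is
treated with immune checkpoint blockade (ICB), but only a minority of
patients respond, and single biomarkers — tumor mutational burden (TMB),
PD-L1 combined positive score (CPS), T-cell infiltration — discriminate
modestly. HNSCC is two diseases etiologically: virus-associated
(HPV/EBV, "V-positive") and carcinogen-driven ("V-negative") tumors with
different genomic landscapes (TP53 mutation, smoking mutational
signature, ploidy) and different outcomes. `icbstrat` implements a
stratification pipeline built on that structure: per-patient feature
derivation, survival-guided molecular subtyping, a portable rule-based
subtype classifier, a random-survival-forest (RSF) protocol, and a
three-feature recursive-partitioning (RPA) risk classifier, plus a
synthetic-cohort generator so the whole pipeline is testable without any
patient data.

# Feature derivation

Somatic SNVs pass a six-criterion confidence filter (tumor VAF ≥ 0.05,
tumor depth ≥ 50, normal depth ≥ 20, tumor alt reads ≥ 5,
VAF~normal~/VAF~tumor~ < 0.2, both strands). The filter is applied to
indels identically: the calling pipeline the filter comes from does not
state a separate indel rule, so uniform application is the assumption of
least surprise (it is recorded as an assumption, not a fact). TMB is the
filtered mutation count divided by exonic megabases; clonal load counts
mutations with cancer cell fraction strictly above 0.5, with missing
CCFs excluded and tallied (clonal load is legitimately available for
only a subset of samples in practice). SIRI is
(neutrophils × monocytes)/lymphocytes in 10⁹ cells/L; non-positive lab
values raise an error instead of being coerced, because they indicate a
data-entry problem a statistician should see. CPS can exceed 100 by
construction (the numerator counts immune cells too); it is capped at
100 by clinical convention, with a message. A chromosome arm counts as
deleted/amplified when more than 20% of its genes carry the event
(strict inequality). Mean copy number 1.5–2.5 is diploid, above 2.5
hyperploid; values below 1.5 are flagged `NA` with a warning and should
be excluded from ploidy-based comparisons rather than guessed at. HPV
status integrates up to four assays: a single performed test stands
alone; with several, all must be positive, except that a negative DNA
ISH (a low-sensitivity assay) is overridden by a positive p16 IHC or RNA
ISH. Objective response is CR/PR; clinical benefit additionally admits
stable disease lasting at least 6 months (the boundary is ≥ 6.0 months —
the stricter of the two phrasings in circulation).

Tables are tab-separated UTF-8 with empty-string missing values;
numerics are written with 17 significant digits so a write/read
round-trip is bit-exact.

# Molecular subtyping

Candidate features are screened by univariable Cox regression in three
strata (V-positive, V-negative, combined); a feature survives if
p ≤ 0.1 in any stratum. Retained continuous features are dichotomized at
the threshold maximizing the two-group log-rank statistic over midpoints
of consecutive sorted unique values, restricted to the 10th–90th
percentile window so no one-versus-rest split can win; ties go to the
more balanced split, then the smaller threshold. Two numerical points
deserve emphasis:

* The maximized log-rank statistic is *maximally selected*: its nominal
  p-value is anti-conservative and must not gate anything. The screen's
  continuous-covariate Cox p (`screen_p`) is the calibrated gate — under
  a null feature it fires at exactly the nominal 10% rate, which is what
  the package's null-calibration test asserts.
* Searching midpoints makes the *partition* invariant under strictly
  monotone transforms of the feature (the threshold itself maps through
  the transform only approximately, since midpoints are not preserved).

The binarized matrix (canonically: TP53 mutation, TMB ≥ 3.34 muts/Mbp,
clonal and indel load above the cohort median, smoking/APOBEC/aging
signature presence at a 0.05 contribution fraction, 9p24.1 deletion,
HLA LOH, hyperploidy, purity above the cohort median, viral status) is
clustered with Euclidean distance and complete linkage — the defaults of
the heatmap tooling the reference analysis names — and the tree is cut
at exactly k = 6. Binary matrices produce many tied distances, and
agglomerative linkage is not permutation-invariant under ties, so rows
are sorted lexicographically before linkage; the result is then
independent of patient order. The exact 13-feature list in the reference
analysis is figure-derived, so the matrix builder is a default, not a
contract: every threshold and the column set are arguments.

Cluster labels are canonicalized deterministically to match the
published subtype semantics: TP53-mutant-majority clusters take labels
1–3, with the 9p24.1-deletion-dominated cluster fixed as subtype 2 and
the remaining two ordered by ascending TMB-high fraction; wild-type
clusters take labels 4–6, with the TMB-high cluster as subtype 4 and the
higher-purity cluster of the remainder as subtype 6. (A simpler two-key
rule — TP53 descending, then TMB ascending — was considered and
rejected: in the wild-type half it assigns the TMB-high, best-outcome
cluster the label 6, which the fixed risk map low = {3,4,5},
high = {1,2,6} would then misclassify. The implemented rule keeps the
risk map meaningful.) Radar profiles report the fractions positive for
the seven response-associated parameters (CD8 above the cohort median,
CPS ≥ 1, TMB ≥ 3.34, virus positivity, intact 9p24.1, absent smoking
signature, present APOBEC signature).

# The 4-feature rule classifier

The portable classifier reduces a subtype call to four binaries. TP53
mutant: 9p24.1 deleted → subtype 2; else TMB-high → 3; else 1. TP53
wild-type: TMB-high → 4; else purity-high → 6; else 5. The wild-type
branch order is configurable because the source prose does not pin down
the TMB-high + purity-high cell; the default checks TMB first. The TMB
threshold transfers across assays by quantile mapping: the threshold's
quantile in the reference distribution (inverse of the type-7 sample
quantile, linear between order statistics, chosen for bit-reproducible
behavior) is evaluated in the target distribution. Purity has no
published cutpoint; the default is the cohort median, overridable, and
frozen into the serialized rule model. Hypermutated outliers (TMB above
10× the cohort median, e.g. POLE-driven) are excluded from rule
classification with a message, mirroring the validation-cohort
accounting in which 107 samples reduce to 102.

# Survival primitives

Kaplan–Meier estimation and the k-sample log-rank test are implemented
from first principles (product-limit with Greenwood variance and
log(−log) intervals; observed-minus-expected with the hypergeometric
covariance and a generalized inverse fallback for degenerate risk sets).
Cox models delegate to `survival::coxph` with Efron tie handling — the
field-standard implementation — and monotone-likelihood or
non-convergent fits are flagged (`converged = FALSE` plus a warning),
never returned silently. Harrell's C delegates to
`survival::concordance` (score ties count 0.5); a brute-force pair
enumeration serves as the test oracle, and a small C++ C-index drives
the forest's permutation-importance loop (tested equal to the public
function). The time-dependent ROC is the cumulative-case /
dynamic-control estimator with inverse-probability-of-censoring weights
1/G(T⁻) on cases (Uno form) — the estimator is named nowhere in the
source analysis, so this choice is documented and swappable; without
censoring before the horizon it reduces exactly to the binary ROC, and
on a frozen fixture it agrees with scikit-survival's
`cumulative_dynamic_auc` to seven decimals. Binary response endpoints
use the plain rank-based AUC, not the time-dependent machinery.

# The random-survival-forest protocol

The cohort splits 70/30 by drawing candidate splits (reference count:
1000) and keeping the one with the smallest imbalance score. Continuous
terms are |median difference| divided by the cohort IQR — the reference
description sums raw median differences, which mixes units; IQR
normalization is required for the sum to mean anything and is a
documented deviation. Categorical terms are total-variation distances
between level frequencies. Zero-IQR variables are excluded with a
warning. Features are screened at p < 0.2 (same three strata), features
with missing values are dropped, and a-priori clinical features are
appended.

The forest itself is built in C++ (`src/forest.cpp`): bootstrap per
tree, log-rank splitting over `nsplit = 10` random candidate values per
tried feature (`mtry = ⌊√p⌋`), minimum node size 15, leaf prediction =
Nelson–Aalen cumulative hazard summed over the cohort's event-time grid
("ensemble mortality"). The established package the reference analysis
used is not available offline, so the built-in forest — explicitly
sanctioned as the fallback — is the implementation; the protocol around
it is the contract. Training repeats `n_repeats` times (reference: 1000;
tests scale to 50 and say so) under seeds `seed + r − 1`; permutation
importance is the drop in out-of-bag C-index when a feature's column is
permuted, averaged across repeats; pruning retains strictly positive
mean importance and retrains (RF14-style naming). Predicted survival is
the negative of the repeat-averaged mortality; test patients at or above
the median predicted survival form the high-survival group (ties to
high, with a warning when all scores tie). Missing features in external
cohorts are imputed by forest proximity (terminal-node co-membership),
falling back to the training median when a feature is entirely absent.

# The RPA risk classifier

The survival tree splits greedily on the feature/midpoint pair
maximizing the log-rank statistic (left branch = value ≤ threshold),
with minimum leaf size 15 and depth ≤ 3. A naive χ²(1) acceptance
threshold of 3.84 overgrows the tree badly, because the best split is
maximally selected over every candidate threshold and feature; the
default acceptance level is therefore the 5% critical value of the
maximally selected statistic (Miller–Siegmund tail approximation over
the admissible split-proportion window, Bonferroni-corrected across
candidate features, recomputed per node). This is the same correction
maxstat-style cutpoint methods use. The reference analysis fit its tree
with an exponential-scaling survival method; that criterion is a
one-step full-exponential-likelihood approximation to log-rank
splitting, so the direct log-rank criterion used here is substantively
equivalent.

Leaves are then merged agglomeratively: the hazard-adjacent pair of
groups with the smallest pooled Cox HR ratio merges while that ratio is
below 1.25 (the tolerance is configuration; the source states only that
"similar" hazards were merged). Pooled re-estimation matters — merging
on single-leaf point estimates under-merges, because two leaves with the
same true hazard routinely show a ratio above 1.25 at leaf-sized n.
Final groups are ordered by hazard and labelled low / intermediate /
high when three remain. Viral status is offered to the search as a bias
control and, with hazards orthogonal to it, is essentially never
retained — reproducing the reference behavior as a property. When the
smoking-signature column is absent (targeted panels), a clinical history
of ≥ 10 pack-years substitutes for a present signature; the routing
anchor is the tree's own smoking threshold, so the proxy is exact for
single-threshold trees. The shipped classifier
(`inst/extdata/rpa_classifier_synthetic.json`) is fitted to the default
synthetic cohort and labelled synthetic: the published tree's numeric
cutpoints exist only in a figure and were not available to this
implementation.

# Contingency and rank statistics

The 2×2 Fisher test enumerates the hypergeometric support directly; the
two-sided p uses the probability-mass rule (sum of probabilities ≤ the
observed table's), the most common convention and the one matching
`stats::fisher.test`. The Freeman–Halton extension is exact (network
algorithm) for grand totals up to 200 and Monte-Carlo beyond: tables are
drawn from the conditional null given both margins (Patefield's
algorithm via `r2dtable`) and compared on multivariate hypergeometric
log-probability, with the binomial standard error reported. The Woolf
odds-ratio interval is exp(log OR ± z·√(Σ1/cell)), with the
Haldane–Anscombe 0.5 correction (flagged) for zero cells. One-sided
p-values are reserved for directional validation-cohort hypotheses,
mirroring the source's reporting policy.

# The synthetic cohort: what it emulates, what it does not

`cohort_spec()` encodes the stated world. Anchored to printed values:
the 52% virus-positive fraction (with HPV:EBV ≈ 56:13 within), subtype
response probabilities (13, 7, 32, 48, 20, 18)%, PFS hazard multipliers
4.42 and 3.76 for subtypes 1–2 against a subtype-4 exponential baseline
with median 9.1 months, TMB log-normals fitted to printed
medians/IQRs by etiology (3.72, 2.66, 1.70 muts/Mbp), 9p24.1 deletion
at 86% in subtype 2 with etiology marginals near 36/9/15%, hyperploidy
and HLA-LOH with etiology marginals near 59/27/23% and 27/41/8%, TP53
probabilities (0.90/0.90/0.88 vs 0.05/0.20/0.06 by subtype) calibrated
so the virus-negative marginal lands near the printed 67%, and irAE
rates reproducing the 23% prevalence with the responder enrichment.
Chosen once where nothing is printed, and documented here: subtype
mixture weights (0.18, 0.10, 0.13, 0.16, 0.28, 0.15) solving the viral
marginal; subtype-3/5/6 hazard multipliers interpolated between the
printed extremes by risk group; an OS baseline of 20 months with
attenuated multipliers; lab log-normals with medians 4.5/0.6/1.2 ×10⁹/L
(typical oncology differentials); censoring targeted at 25% via a
uniform administrative horizon tuned by root-finding on the realized
latent times; a SIRI log-hazard slope of 0.5 per log-unit (SIRI is the
reference analysis's top RPA feature and must be prognostic for the
downstream stages to be exercised); smoking pack-years rank-correlated
with the SBS4 fraction. Signature Dirichlets, TMB subtype multipliers
and the subtype-6 purity Beta encode the printed qualitative archetypes
(smoking-dominated subtypes 1–2/6, smoking+APOBEC 3, APOBEC-without-
smoking 4, high-purity 6).

What the generator does **not** emulate: inter-feature dependence beyond
the subtype/etiology structure (real mutational co-occurrence,
lab–tumor-burden coupling), non-proportional hazards, informative
censoring, measurement error in CCF/purity, or cohort-level batch
structure. A green test therefore establishes that the pipeline recovers
structure *of the planted kind at the planted strength* — not that it
would perform identically on real data. Conversely, the subtype-recovery
behavior of hierarchical clustering on this generator is honest about a
real limitation: complete-linkage clustering of noisy binary vectors at
n ≈ 130–300 is unstable, and run-to-run risk-concordance between the
4-feature rule and a fresh clustering varies around the low 0.8s — the
same order as, but not above, the ≈ 0.86 reported on the real cohort,
where feature co-segregation is stronger than independent-given-subtype
sampling can produce.

# Scaling in the test suite

The reference protocol's 1000 forest repeats and 1000 split candidates
are configuration defaults; the acceptance suite runs 50 study
replicates with 50 forest repeats and 100 split candidates (flagged as
scaled down) to stay within a desk-scale time budget, and the
Monte-Carlo Freeman–Halton check uses 2×10⁴ draws. Parameter-recovery
bounds with no stated rate (the RPA battery) were fixed from the
behavior of the stated world before freezing, with wide binomial
margins, and are documented inline.

# Known limitations

* The 13-feature subtype matrix and the 23-feature RSF candidate list
  are best-reading defaults, not the unpublishable originals.
* The forest is a minimal RSF: no competing risks, no alternative split
  rules, no honest variance estimates; importance is Breiman-style
  permutation at forest level.
* `map_tmb_threshold` clamps thresholds outside the reference range to
  the boundary quantiles.
* Cox models here are univariable by design; the multivariable and
  time-dependent analyses of the source (e.g. immortal-time-bias
  correction for irAEs) are out of scope.
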