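# icbstrat

Clinical-genomic risk stratification for immune-checkpoint-blockade (ICB)
treated head and neck squamous cell carcinoma (HNSCC).

Only 15–25% of patients with recurrent/metastatic HNSCC respond to
anti-PD-1/PD-L1 therapy, and the approved biomarkers (tumor mutational
burden, PD-L1 combined positive score) discriminate poorly on their own.
`icbstrat` re-implements, as a tested and reusable pipeline, a
stratification analysis that combines whole-exome and routine clinical
data:

1. **Feature derivation** (`cohort_io`): the six-criterion somatic-SNV
   confidence filter (tumor VAF ≥ 0.05, DP.tumor ≥ 50, DP.normal ≥ 20,
   AD.tumor ≥ 5, VAF-ratio < 0.2, both strands), TMB = mutations /
   exonic Mbp, clonal load (CCF > 0.5), SIRI = neutrophils × monocytes /
   lymphocytes, CPS = 100 × PD-L1⁺ cells / tumor cells (capped at 100),
   arm-level copy-number calls (> 20% of genes), ploidy bands
   (diploid 1.5–2.5, hyperploid > 2.5), multi-assay HPV integration, and
   RECIST-derived response/clinical-benefit endpoints.
2. **Molecular subtyping** (`subtype_discovery`): univariable Cox
   screening (p ≤ 0.1 in any of the virus-positive / virus-negative /
   combined strata), survival-guided dichotomization at the threshold
   maximizing the log-rank statistic, hierarchical clustering (Euclidean,
   complete linkage) of the binarized feature matrix cut at k = 6, and
   the fixed risk map low = {3,4,5}, high = {1,2,6}.
3. **Portable rule classifier** (`rule_classifier`): the 4-feature
   decision table (TP53, 9p24.1 deletion, TMB-high, purity-high) with
   type-7 quantile mapping of the 3.34 muts/Mbp TMB threshold onto other
   panels, hypermutator exclusion, and concordance auditing.
4. **Random-survival-forest protocol** (`predictive_models`): balanced
   70/30 split by IQR-normalized imbalance score over candidate splits,
   p < 0.2 screening, a built-in log-rank-splitting survival forest
   (Rcpp; 100 trees) trained repeatedly with out-of-bag permutation
   importance averaged across repeats, pruning to positive-importance
   features (RF14-style), median-split survival groups, C-index and
   IPCW time-dependent ROC evaluation, proximity-based imputation.
5. **Recursive-partitioning risk classifier** (`rpa_model`): a survival
   tree on SIRI / TMB / smoking signature (maximally-selected log-rank
   splits with a Miller–Siegmund-corrected acceptance level), similar-
   hazard leaves merged (HR ratio < 1.25), yielding low / intermediate /
   high risk groups; ≥ 10 pack-years substitutes for a missing smoking
   signature in targeted-panel cohorts.
6. **Statistics** (`stats_utils`, `survival_core`): exact Fisher 2×2 and
   Freeman–Halton r×c tests, Woolf odds-ratio intervals, Wilcoxon /
   Kruskal–Wallis dispatch, Kaplan–Meier with Greenwood log-log
   intervals, k-sample log-rank, Cox (Efron ties), Harrell's C, and a
   cumulative/dynamic IPCW ROC.
7. **Synthetic cohorts** (`synthetic_cohort`): a generator that
   reproduces the published cohort's statistical structure — 52%
   virus-positive, TP53–viral-status anti-correlation (≈ 67% vs ≈ 10%),
   viral-status-specific TMB log-normals, six subtype archetypes with
   response rates from 7% to 48% and PFS hazard multipliers up to 4.42,
   tuned uniform censoring — so every stage is testable offline.

## Worked example

```r
library(icbstrat)

co <- generate_cohort(cohort_spec(n_patients = 300, seed = 1))

# molecular subtyping on the canonical binarized features
m  <- make_binary_matrix(co)          # TMB >= 3.34, signatures > 0.05, ...
sm <- cluster_subtypes(m)             # Euclidean + complete linkage, k = 6
rg <- subtype_risk_group(sm$assignments)
mean(co$response[rg == "low_risk"])   # 0.31
mean(co$response[rg == "high_risk"])  # 0.20

# the portable 4-feature rule against the clustering
rules <- apply_rule_model(rule_model(), co)
audit_concordance(rules, sm$assignments)$risk_concordance  # 0.82

# the shipped (synthetic-cohort-derived) 3-feature RPA classifier
tree <- read_rpa(system.file("extdata", "rpa_classifier_synthetic.json",
                             package = "icbstrat"))
g <- apply_rpa(tree, co)
table(g)
#          low intermediate         high
#           86           84          130
logrank_test(co$pfs_time, co$pfs_event, g)$p   # 1.5e-13
```

The RPA groups separate progression-free survival with hazard ratios of
1.83 (95% CI 1.25–2.69) for intermediate and 3.94 (2.71–5.72) for high
risk versus low risk, and objective response rates of 42% / 19% / 16% —
the same ordering the published classifier shows (53% / 16% / 6%).

## Command line

```sh
CLI=$(Rscript -e 'cat(system.file("cli/icbstrat.R", package = "icbstrat"))')
Rscript "$CLI" synth-cohort --n 133 --seed 7 --out demo/
Rscript "$CLI" cohort-build --clinical demo/clinical.tsv --mutations demo/mutations.tsv \
        --cna demo/cna.tsv --signatures demo/signatures.tsv --out demo/cohort.tsv
Rscript "$CLI" rpa-fit --cohort demo/cohort.tsv --out demo/tree.json
Rscript "$CLI" rpa-apply --tree demo/tree.json --cohort demo/cohort.tsv --out demo/groups.tsv
```

## Documentation

The methods vignette (`vignettes/icb-stratification.Rmd`) describes the
models, the synthetic-data assumptions, the numerical choices (tie
handling, threshold windows, split-acceptance correction, merge rule)
and what the tests do and do not establish.
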