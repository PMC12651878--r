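# eaccd

Data-driven prognostic staging from registry-style survival cohorts, via
ensemble clustering of survival curves (EACCD — the Ensemble Algorithm for
Clustering Cancer Data).

Committee-defined TNM staging for pancreatic neuroendocrine tumors
separates survival poorly between neighbouring stages. This package instead
*learns* the grouping: every factor-level combination (a cell such as
`T2N0M0`) is an object, pairwise survival differences between cells are
measured with a Gehan–Wilcoxon effect size, an ensemble of
partitioning-around-medoids runs turns them into a consensus dissimilarity,
and a minimax-linkage dendrogram is cut at the knee of the Harrell C-index
curve. The result is a *prognostic system*: dendrogram, ordered group
assignments, C-index with bootstrap CI, and per-group Kaplan–Meier curves.
A rule-based AJCC stage comparator and a synthetic cohort generator with
known ground truth round out the toolkit.

## The method in brief

For cells $C_1,\dots,C_n$ and weights $w_k \ge 0$, $\sum w_k = 1$:

1. $\mathrm{dis}_0(C_i,C_j) = |z|/\sqrt{m+n}$, the sample-size-stabilized
   magnitude of the standardized Gehan–Wilcoxon statistic between the two
   cells' survival samples (permutation variance
   $\mathrm{Var}(U) = \frac{mn}{(m+n)(m+n-1)}\sum_k s_k^2$).
2. For each $k=1..n$, PAM partitions the cells on $\mathrm{dis}_0$;
   $\mathrm{dis}(C_i,C_j) = \sum_k w_k\,\delta_k(i,j)$, the weighted share
   of partitions separating the pair.
3. Minimax-linkage hierarchical clustering on $\mathrm{dis}$; cut at
   $n^\*$ groups chosen where the C-index curve $C(k)$ flattens
   (smallest $k$ with all later gains below `knee_tol`).

## Worked example

The `analysis/` directory is a numbered workflow over a synthetic
registry-like cohort (16 TNM cells, 3278 patients, 5-year survival spanning
~26–95%). Running it end to end:

```sh
Rscript analysis/01_simulate_cohort.R   # writes results/cohorts/
Rscript analysis/02_ajcc_staging.R      # rule-based AJCC baseline
Rscript analysis/03_eaccd_tnm.R         # EACCD on T, N, M
Rscript analysis/04_eaccd_tnma.R        # EACCD on T, N, M + dichotomized age
Rscript analysis/05_compare_systems.R   # head-to-head comparison
```

Step 2 prints the rule-based baseline on this cohort:

```
 stage    n deaths     surv5
     I 1254    135 0.9423698
    II  997    215 0.8886603
   III  477    222 0.7449580
    IV  550    417 0.4516118
C-index: 0.7515 (95% CI 0.7368-0.7666)
```

Step 5 contrasts it with the learned grouping:

```
    system groups    cindex
 AJCC rule      4 0.7515026
     EACCD      6 0.7570834
C-index difference (EACCD - AJCC): 0.0056 (95% CI 0.0033-0.0078, p = 0.000)
```

Read: on this synthetic cohort the learned system splits the 16 cells into
6 groups and orders survival slightly but consistently better than the
4-stage rule (the paired-bootstrap CI of the difference excludes 0). The
same objects are available programmatically:

```r
library(eaccd)
cfg <- seer_like_preset(seed = 1)
sim <- simulate_cohort(cfg)
cohort <- filter_small_combinations(
  build_combinations(sim$records, cfg$scheme), min_n = 15)$cohort
sys <- build_prognostic_system(cohort, B = 1000, seed = 1)
print(sys)           # groups, sizes, deaths, 5-year survival, C-index
group_table(sys)     # cell -> group export
assign_patient(sys, c(T = "T2", N = "N0", M = "M0"))
```

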