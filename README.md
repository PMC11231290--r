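# clustric

Temporal stratification of patients into disease-progression groups by
combining triclustering of three-way clinical data with hierarchical
clustering.

## The problem

Progressive diseases such as ALS are heterogeneous: patients decline at
different speeds and in different functional domains (bulbar, limb,
trunk, respiratory), with plateaus and occasional transient improvements
along the way. Cross-sectional staging ignores this temporal structure,
and univariate trajectory models miss relations *between* features.
`clustric` stratifies a longitudinal cohort using the joint temporal
behaviour of several clinical scores at once, then characterises and
validates the resulting groups. It is aimed at biostatisticians and
clinical researchers working with repeated functional assessments
(here: the 12-item ALSFRS-R scale, its five domain subscores, and the
MiToS stage).

## The method

1. **Snapshot alignment.** Raw assessments arrive on misaligned dates.
   Per patient, records are grouped by constrained agglomerative
   clustering on day distance into *snapshots* (appointments): a
   snapshot spans at most 100 days and never contains the same test
   twice. The first three feature-complete appointments of each patient
   form a three-way dataset `D = {d_ijk}` over subjects `X`, features
   `Y`, contexts (appointments) `Z`; patients with fewer than three
   complete appointments are excluded.

2. **Triclustering.** A tricluster `T = (I, J, K)`, `I ⊆ X`, `J ⊆ Y`,
   `K ⊆ Z` with `K` temporally contiguous, is *coherent* when for every
   feature pair `(a, b) ⊆ J` and context `k ∈ K` the cross-feature
   ratios `r_i = d_ibk / d_iak` (on positively shifted values) satisfy
   `max(r) / min(r) ≤ 1 + ε`. Mining proceeds per time slice by building
   a ratio-range multigraph (maximal coherent subject ranges per feature
   pair), growing maximal biclusters over it, and combining biclusters
   across adjacent slices into maximal contiguous triclusters.

3. **Virtual patterns.** Each tricluster `T_l` is summarised by its 3D
   virtual pattern `P_l = {ρ_k | k ∈ K}` with
   `ρ_k = { mean_i∈I d_ijk | j ∈ J }` (mode for categorical features
   such as the MiToS stage).

4. **Pattern-distance transform.** Every patient (member of a tricluster
   or not) is embedded as the `|X| × (|K|·L)` matrix of Euclidean
   distances `S(P_l, F_k(x_i)) = sqrt(Σ_e (F_k(x_i)_e − ρ_k,e)²)` to
   every pattern at every context.

5. **Progression groups.** Ward-linkage (Ward.D2) hierarchical
   clustering of the embedding rows; the cluster count is chosen from a
   dendrogram plus a validity panel (silhouette, Calinski-Harabasz,
   Davies-Bouldin) over candidate k. Groups are then characterised by
   mean feature trajectories with 95% confidence bands and
   inter-appointment slopes, and validated by Kaplan-Meier curves,
   2-year survival rates (Greenwood CIs) and log-rank tests.

Because the clinical cohorts this kind of analysis targets are
access-restricted, the package ships a seeded synthetic-cohort generator
with four planted progression groups (slow; moderate-bulbar;
moderate-spinal; fast), irregular visit schedules, item-level ALSFRS-R
decline with noise/plateaus/improvements, and per-group survival — so
the whole pipeline is testable end to end.

## Worked example

```r
library(clustric)

cohort <- generateCohort(120, seed = 7)              # synthetic ALS-like cohort
snaps  <- buildSnapshots(cohortToRecords(cohort), windowDays = 100)
cube   <- assembleThreeWay(featureTable(snaps), nContexts = 3,
                           staticData = cohortStaticData(cohort))
sol    <- mineTriclusters(cube)                      # epsilon = 0.05 defaults
pdm    <- transformDataset(cube, virtualPatterns(sol, cube))
groups <- progressionClusters(pdm, candidates = 3:5)
groups
#> ProgressionClustering: k = 4
#> cluster
#>  1  2  3  4
#> 40 32 31 17
#>  validity panel:
#>  k silhouette calinski_harabasz davies_bouldin
#>  3  0.5469026          201.2688      0.7039452
#>  4  0.6455052          366.0820      0.5249242
#>  5  0.6158634          322.7075      0.6363522
```

All three indices prefer k = 4 (silhouette and Calinski-Harabasz
highest, Davies-Bouldin lowest), matching the four planted groups. The
groups differ sharply in survival:

```r
sv <- survivalByGroup(staticData(cube), clusterLabels(groups))
print(sv$table, digits = 3)
#>   group  n events median_survival two_year_rate two_year_lower two_year_upper
#> 1     1 40     25            62.7         0.759          0.621          0.897
#> 2     2 32     27            37.4         0.656          0.492          0.821
#> 3     3 31     14            94.4         0.930          0.836          1.000
#> 4     4 17     14            23.8         0.435          0.175          0.695
sv$logrank$p
#> 1.76e-06
```

Median survival is in months from the first visit; `two_year_rate` is
the Kaplan-Meier survival probability at 24 months with its Greenwood
95% interval. Cluster 3 behaves like slow progressors (93% two-year
survival), cluster 4 like fast progressors (43%).

A command-line front end mirrors the stages
(`simulate`, `preprocess`, `tricluster`, `transform`, `cluster`,
`evaluate`, `run`); see `inst/exec/clustric`.

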