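# mtxtraj

Multivariate trajectory clustering of methotrexate (MTX) response in
juvenile idiopathic arthritis (JIA).

Methotrexate is the first-line disease-modifying drug in JIA, but
"response" is heterogeneous: the four JADAS71 disease-activity
components — active joint count (AJC, 0–71), physician global assessment
(PGA, 0–100 mm), parent global evaluation (PGE, 0–100 mm) and ESR
(mm/h) — may improve fast, slowly, transiently, or diverge from one
another.  `mtxtraj` is for epidemiologists and biostatisticians working
with longitudinal JIA treatment registries who want to move beyond
binary response/non-response labels: it classifies children into latent
clusters of joint trajectories over the 14 months after MTX initiation.

## The model

Outcomes are analysed as `log1p(y)`.  A K-group multivariate
group-based trajectory model (GBTM) assumes child *i* belongs to latent
group *k* with probability π<sub>k</sub>; given the group, every
observed component is an independent censored-normal (Tobit) draw
around a polynomial mean,

> μ<sub>kot</sub> = Σ<sub>p</sub> β<sub>kop</sub> t<sup>p</sup>,  y\* ~
> N(μ, σ<sub>o</sub>²),  y = clamp(y\*, lo<sub>o</sub>, hi<sub>o</sub>),

with observations at a bound contributing tail mass instead of density.
Models are fitted by multi-start EM with stepwise (group-splitting) warm
starts, screened by admissibility rules (every group ≥1% of the cohort,
per-group mean posterior probability ≥70%, relative entropy ≥0.5), and
selected by BIC nearest zero.  Downstream, the package scores ACR Pedi
30/90 composite response at 6 and 12 months, and characterizes clusters
by multinomial logistic regression, one-vs-rest AUCs and Kaplan–Meier
time to biologic therapy.

Because the UK registry data behind this design are access-controlled,
the package includes a seeded synthetic-cohort generator emulating their
structure (six latent trajectory patterns, jittered 0/3/6/12-month
visits, component-level missingness, cluster-dependent biologic
switching); the whole pipeline is validated by parameter recovery
against it.

## Worked example

```r
library(mtxtraj)

cohort <- generate_cohort(synthetic_config(n_children = 657, seed = 1))
prep   <- preprocess_cohort(cohort)
prep$exclusions
#>           no_mtx_date biologic_within_month       cid_at_baseline
#>                     0                     9                     4
#> no_complete_timepoint              retained
#>                    16                   628

grid <- run_grid(prep$model_frame, orders = 2, K_range = 1:8,
                 n_starts = 8, seed = 1)
grid$selected_label
#> [1] "P2_K6"
grid$selected
#> Censored-normal GBTM: K=6, order 2, n=628 children (7433 obs)
#>   loglik -8226.24 | BIC -8487.17 | entropy 0.866 | converged: TRUE
#>   shares: 0.414 0.176 0.143 0.105 0.082 0.080
#>   AvePP : 0.892 0.879 0.913 0.979 0.918 0.936
```

The grid fits quadratic models with 1–8 groups, discards inadmissible
ones, and picks the BIC-optimal fit: here six clusters, whose shares
(41%, 18%, 14%, 10%, 8%, 8%) recover the generating mixture
(44%, 16%, 13%, 11%, 8%, 7%) within binomial sampling error, with sharp
classification (entropy 0.87, every per-group mean posterior
probability ≥ 0.88).  `trajectory_means(grid$selected)` returns the
fitted group means for plotting; `score_acr()` plus
`response_by_cluster()` tabulate ACR Pedi 30/90 by cluster, and
`fit_multinomial()`, `auc_one_vs_rest()` and `km_logrank()` relate
baseline factors and biologic switching to cluster membership.

`run_pipeline(pipeline_config(...))` chains every stage and writes CSV
and JSON reports plus a reproducibility manifest; a thin command-line
wrapper with `simulate`/`preprocess`/`run-all`-style subcommands lives
at `inst/cli/mtxtraj.R`.

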