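# gazefatigue

Mental-fatigue assessment from eye-movement recordings, for human-factors
researchers and operator-monitoring applications.  Long monotonous work
changes oculomotor behaviour — fixations lengthen, fixational drift slows,
gaze trajectories grow more tortuous — and `gazefatigue` turns those
changes into a binary fatigue estimate:

1. **Events and kinematics.** Dispersion-threshold (I-DT) fixation
   detection as a function of the *fixation-area diameter* d (dispersion =
   max pairwise angular distance ≤ d), derived saccades, and per-sample
   velocity v(t) = |Δp|/Δt, acceleration, and Menger curvature
   κ = 1/R_circum of each sample triplet.
2. **A 27-entry characteristic catalogue** per recording or sliding
   window: velocity within the fixation area (net displacement/duration)
   and speed (path length/duration), curvature statistics over 1-s
   intervals, saccade length/duration statistics, duration-bin percentages
   (<150 ms, [150, 900) ms, ≥900 ms, 180 ms splits), per-minute counts.
3. **Four-criterion relevance screening** against session ground truth:
   a two-sided Wilcoxon rank-sum test across the high/low
   mental-performance split (Landolt Au index, threshold 1.5);
   inner-session dynamics max(P(increase), P(decrease)) between session
   start and end blocks; and maximal |Spearman ρ| over the diameter grid
   against the choice-reaction-time delta (post − pre mean RT) and the
   VAS-F fatigue score.  Screened characteristics (p < 0.05) are ranked
   and combined with expert additions.
4. **A classification pipeline**: z-score normalization,
   quasi-constant/Kendall-τ/PCA feature selection, a grid of six model
   families (random forest, decision tree, k-NN, MLP, logistic
   regression, SVM), a balanced held-out split plus stratified 10-fold
   CV, and sliding-window assessment of streaming gaze (`assess_stream()`).
5. **A seeded synthetic study simulator** (participants × days × sessions)
   with a controllable fatigue level that shifts the generator's
   parameters monotonically and produces matching Au/CRT/VAS-F ground
   truth — so the whole pipeline is testable offline.

## Worked example

```r
library(gazefatigue)

design <- study_design(n_participants = 8, n_days = 1, sessions_per_day = 3,
                       session_duration = 60, seed = 1)
study <- simulate_study(design)
#> <gaze_study> 8 participants x 1 days x 3 sessions (24 recordings of 60 s)

tab <- compile_relevance_table(study,
         relevance_config(diameter_grid = seq(0.5, 2.5, by = 0.5)))
head(as.data.frame(tab)[, c("characteristic", "wilcoxon_p",
                            "dynamics_score", "crt_corr")], 5)
#>                             characteristic wilcoxon_p dynamics_score crt_corr
#> 1                    avg_velocity_fixation    7.1e-06           0.54    0.226
#> 2 modulus_avg_acceleration_second_interval    7.1e-06           0.50    0.187
#> 3                       avg_speed_fixation    1.2e-05           0.88    0.220
#> 4             min_velocity_second_interval    3.1e-05           0.54    0.056
#> 5                            avg_curvature    4.6e-05           0.96   -0.217
```

The table reads like the screening stage of the method: every
characteristic with its rank-test p-value against the high/low
mental-performance groups, the share of sessions in which it moved
consistently within a session, and its best correlation with the
reaction-time delta over the diameter grid.  Fatigue in this simulated
study slows fixational drift and raises trajectory curvature, so the
velocity- and curvature-family characteristics screen to the top.

```r
fm <- build_feature_matrix(study, feature_sets = c("coordinates", "selected"),
                           window_s = 20, step_s = 20)
model <- grid_train(fm, families = "random_forest",
                    cfg = pipeline_config(test_per_class = 12, seed = 1))
model
#> <fatigue_model> best: random_forest (20) | split acc 0.792 F1 0.762 | CV acc 0.812 F1 0.764

stream <- simulate_recording(sim_params(), 45, seed = 99)
head(assess_stream(model, stream, window_s = 20, step_s = 5))
#>   time            status label score
#> 1    5 insufficient_data  <NA>    NA
#> 2   10 insufficient_data  <NA>    NA
#> 3   15 insufficient_data  <NA>    NA
#> 4   20                ok  high  0.15
#> 5   25                ok  high  0.20
#> 6   30                ok  high  0.15
```

A 45-s rested stream: the first steps lack a full 20-s window, after which
every window is classified non-fatigued (`high` mental performance) with a
low fatigue score (the model's probability of the fatigued class).  The
numbers above are what the code prints at these seeds; accuracies around
0.8 on a 24-session desk-scale study are expected, not a performance claim
about real recordings — see the methods vignette
(`vignettes/fatigue-assessment-methods.Rmd`) for what the simulator does
and does not emulate.

A thin command-line wrapper with `simulate`, `extract`, `relevance`,
`train` and `assess` subcommands lives at `inst/cli/gazefatigue-cli.R`.

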