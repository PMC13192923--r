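# dynograph

Graph-based temporal modeling of longitudinal cohort panels.

`dynograph` is for biostatisticians and epidemiologists who follow a cohort
across a handful of visits — multi-domain features (genetic liability
scores, environment, family context, physical health, technology use,
neurocognition, brain measures), continuous symptom trajectories
(externalizing / internalizing behavior scales), and rare time-to-event
outcomes such as substance-use initiation — and want to model the cohort as
a *dynamic system*: domain-level nodes whose states interact over time,
rather than a flat regression per visit.

## What it computes

**Panel → sequences.** Visits are mapped to integer time indices
`t ∈ {0,…,T}`. For a continuous outcome the lag `y_{i,t−1}` and change
score `Δy_{i,t} = y_{i,t} − y_{i,t−1}` are derived (defined only across
consecutively observed visits). A time-to-event pair `(T_i, δ_i)` becomes a
discrete-time survival label sequence

    y_{i,t} = 1  if δ_i = 1 and T_i ≤ t
            = 0  if T_i > t
            = missing otherwise (censored by t),

the person-period coding that lets longitudinal classifiers model hazards.
Sequences are padded to a common length with an observation mask `m_{i,t}`;
masked slots carry zeros and are excluded from every loss and metric.

**Preprocessing.** Train-set-only median imputation, standardization
`x' = (x − μ_x)/σ_x` (population convention), and covariate residualization
`X_res = X − C(CᵀC)⁻¹CᵀX` against sex, age, genetic principal components
and site (computed by QR, with an intercept always in the span of `C`).

**Graph.** Features map to `N` domain nodes by name prefix; node values are
mean standardized features. Edges are absolute Pearson correlations between
node summaries across training rows, thresholded at `τ`, with unit
self-loops, then row-normalized — so message passing `x_graph,t = A x_t` is
a convex averaging over neighbors.

**Temporal models.** Two masked recurrent architectures, both trained with
Adam, minibatches, and validation-based early stopping:

* **Graph-LSTM** — `h_t = LSTM(h_{t−1}, x̃_t)` on the feature sequences,
  with a linear head for continuous outcomes (masked MSE) or a logistic
  head for event outcomes (masked cross-entropy);
* **Graph-GTRNN** — a GRU fed the message-passed node vector `A x_t` at
  each step. With `A = I` it is exactly a plain GRU.

The recurrent cores (forward passes, backpropagation through time, Adam)
are implemented in the package and verified against numerical
differentiation.

**Evaluation.** RMSE, MAE, `R² = 1 − SS_res/SS_tot`, Pearson `r` for
continuous outcomes; AUROC (Mann–Whitney, ties ½), PR-AUC
(average-precision step convention) and the Brier score for event outcomes,
all over valid subject-periods only, with multi-seed mean ± SD summaries.

**Latent system energy.** From a state vector `x_t` (the trained GTRNN
hidden state by default, or the node summaries):

    E_t       = (1/N) Σ_j x_{j,t}²          system activation
    E_graph,t = (1/N) Σ_j (A x_t)_j²        after one message-passing step
    ΔE_t      = E_t − E_{t−1}               energy change
    collapse_t = 1  iff  ΔE_t > μ_ΔE + σ_ΔE  (cohort-referenced)

plus high-risk vs comparison group contrasts of mean energy, final energy
and mean energy change.

**Synthetic cohorts.** A first-class generator plants known structure —
AR(1) latent node states, a linear outcome signal with chosen generative
R², a calibrated logistic event hazard, censoring, MCAR missingness, and a
high-volatility subgroup — so the whole pipeline is testable end to end
with recoverable ground truth.

## Worked example

```r
library(dynograph)

spec <- cohort_spec(n_subjects = 400, continuous_effect_size = 0.5,
                    volatility_ratio = 2, seed = 42)
cohort <- generate_cohort(spec)

split <- split_subjects(unique(cohort$panel$subject_id), seed = 1)
prep  <- fit_preprocess(cohort$panel[cohort$panel$subject_id %in% split$train, ])
panel <- build_continuous_targets(apply_preprocess(cohort$panel, prep))
feats <- prep$standardize$feature_cols

graph <- build_graph(panel[panel$subject_id %in% split$train, ], feats)
batch <- build_sequences(panel, feats, event_labels = FALSE)
nodes <- node_batch(batch, graph$map, graph$nodes)
nb    <- lapply(split, function(ids) subset_batch(nodes, ids))

cfg <- model_config("graph_gtrnn", input_width = length(graph$nodes),
                    head = "continuous", seed = 1)
fit <- train_model(cfg, nb$train, nb$val, graph)

pred <- forward_graph_gtrnn(fit, graph, nb$test)
unlist(regression_metrics(nb$test$target, pred,
                          nb$test$target_valid & nb$test$mask == 1))

traces <- compute_energy_traces(nb$test, graph, fit, source = "hidden_state")
risk <- with(cohort$truth$subjects,
             setNames(ifelse(high_risk, "high", "comparison"), subject_id))
group_contrast(traces, risk[nb$test$subjects], high = "high")
```

Output:

```
Synthetic cohort: 400 subjects, 1884 rows, 11 nodes, 55 features
  event prevalence 0.050 | generative R2 0.473
Trained graph_gtrnn (continuous head): hidden 32, best epoch 64/74, val loss 0.5509
       rmse         mae          r2           r           n
  3.1640759   2.5456151   0.3595154   0.6195868 383.0000000
Energy contrast: high (n=22) vs comparison (n=58)
      group  n mean_energy final_energy mean_delta
       high 22  0.12380289   0.15018284 0.03085170
 comparison 58  0.06859471   0.09415976 0.01680243
difference (high - comparison): mean +0.0552, final +0.0560, delta +0.0140
```

The model recovers a test R² of 0.36 against a generative signal fraction
of 0.47 (the remainder is measurement noise and finite-sample loss), and
the planted high-volatility subgroup shows higher mean, final, and
accumulating hidden-state energy — the qualitative signature the energy
summaries are designed to detect.

The end-to-end pipeline is also available behind a single YAML config
(`run_pipeline(config, out_dir)`) and a thin CLI
(`Rscript inst/cli/dynograph.R simulate|run …`), which writes tidy metric
CSVs, the graph JSON, energy traces, group summaries, and a reproducibility
manifest.

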