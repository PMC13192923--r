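# Shared fixtures, built in code.

# tiny hand-written long panel (2 subjects, explicit values)
tiny_panel <- function() {
  data.frame(
    subject_id = c("A", "A", "A", "B", "B"),
    t = c(0L, 1L, 2L, 0L, 2L),
    cov_sex = c(1, 1, 1, 0, 0),
    cov_age = c(9, 10, 11, 10, 12),
    y = c(10, 12, 15, 5, 7),
    event = c(0L, 0L, 0L, 1L, 1L),
    event_time = c(2L, 2L, 2L, 2L, 2L),
    env__a = c(0.1, 0.2, 0.3, -0.1, 0.0),
    env__b = c(1, 2, 3, 4, 5),
    brain__c = c(-1, 0, 1, 2, -2),
    stringsAsFactors = FALSE
  )
}

# small preprocessed cohort with model-ready batches, for model tests
small_model_data <- function(n = 60, seed = 42, event_rate = 0.1,
                             volatility_ratio = 1) {
  # few PC covariates: tiny cohorts cannot support a 10-column PC design
  sp <- cohort_spec(n_subjects = n, seed = seed, event_rate = event_rate,
                    volatility_ratio = volatility_ratio, n_pcs = 2L,
                    n_sites = 2L)
  co <- generate_cohort(sp)
  panel <- encode_event_labels(co$panel)
  split <- split_subjects(unique(panel$subject_id), seed = seed + 1L)
  prep <- fit_preprocess(panel[panel$subject_id %in% split$train, ])
  pp <- build_continuous_targets(apply_preprocess(panel, prep))
  fc <- prep$standardize$feature_cols
  graph <- build_graph(pp[pp$subject_id %in% split$train, ], fc)
  batch <- build_sequences(pp, fc)
  list(cohort = co, panel = panel, split = split, prep = prep, pp = pp,
       fc = fc, graph = graph, batch = batch,
       nb = node_batch(batch, graph$map, graph$nodes))
}

# a minimal model object with fixed parameters (no training)
manual_model <- function(arch, p, h, head = "continuous", seed = 7) {
  cfg <- model_config(arch, input_width = p, head = head, hidden = h,
                      seed = seed)
  params <- dynograph:::with_seed(seed, dynograph:::init_params(
    dynograph:::core_arch(arch), p, h))
  list(config = cfg, params = params, target_scale = NULL)
}
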