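#' Subject-level train/validation/test split
#'
#' Splits subjects (never rows) into disjoint, exhaustive sets,
#' deterministically under the seed. Sizes follow sequential hold-out
#' arithmetic: the test set takes `ceiling(n * f_test)` subjects, the
#' validation set `ceiling` of its share of the remainder, and the training
#' set what is left — so 2,620 subjects at 64/16/20 give 1,676/420/524.
#'
#' @param subjects Character/integer vector of subject ids.
#' @param fractions Numeric length-3 vector (train, val, test) summing to 1.
#' @param seed Integer seed.
#' @return List with `train`, `val`, `test` id vectors.
#' @export
split_subjects <- function(subjects, fractions = c(0.64, 0.16, 0.20),
                           seed = 1L) {
  subjects <- unique(subjects)
  n <- length(subjects)
  if (n < 3) stopf("need at least 3 subjects to split")
  assert_that(length(fractions) == 3 && all(fractions > 0),
              "fractions must be 3 positive numbers")
  if (abs(sum(fractions) - 1) > 1e-8)
    stopf("split fractions must sum to 1 (got %.4f)", sum(fractions))
  n_test <- ceiling(n * fractions[3])
  n_rem <- n - n_test
  n_val <- ceiling(n_rem * fractions[2] / (fractions[1] + fractions[2]))
  n_train <- n_rem - n_val
  if (min(n_train, n_val, n_test) < 1) stopf("a split would be empty")
  perm <- with_seed(seed, sample(subjects))
  list(train = sort(perm[seq_len(n_train)]),
       val = sort(perm[n_train + seq_len(n_val)]),
       test = sort(perm[n_train + n_val + seq_len(n_test)]))
}

#' Run the full pipeline behind one configuration
#'
#' Orchestrates simulate (or load) -> targets -> split -> preprocess ->
#' graph -> train -> evaluate -> energy analysis, writing tidy CSVs, the
#' graph JSON, and a manifest capturing seeds and sizes. Deterministic:
#' rerunning an identical config reproduces every output.
#'
#' The config is a named list (or YAML file path) with elements:
#' \describe{
#'   \item{simulate}{[cohort_spec()] arguments, or `panel` = path to a CSV.}
#'   \item{outcomes}{List of `list(name=, type=)` with type `"continuous"`
#'     or `"binary"`; defaults to the continuous outcome `y`.}
#'   \item{split}{Fractions (train, val, test); default `c(.64, .16, .20)`.}
#'   \item{graph}{`method` and `tau` for [build_adjacency()].}
#'   \item{model}{[model_config()] overrides (hidden, learning_rate, ...).}
#'   \item{architectures}{Subset of `c("graph_lstm", "graph_gtrnn")`.}
#'   \item{seeds}{Model seeds (default `1:5`).}
#'   \item{seed}{Global seed expanded into stage seeds (default 1).}
#' }
#'
#' @param config Named list or path to a YAML file.
#' @param out_dir Output directory (created if needed).
#' @return Invisibly, the manifest list.
#' @export
run_pipeline <- function(config, out_dir) {
  if (is.character(config) && length(config) == 1L)
    config <- yaml::read_yaml(config)
  fractions <- as.numeric(config$split %||% c(0.64, 0.16, 0.20))
  if (abs(sum(fractions) - 1) > 1e-8)
    stopf("split fractions must sum to 1 (got %.4f)", sum(fractions))
  outcomes <- config$outcomes %||% list(list(name = "y", type = "continuous"))
  archs <- config$architectures %||% c("graph_lstm", "graph_gtrnn")
  seeds <- as.integer(unlist(config$seeds %||% 1:5))
  gseed <- as.integer(config$seed %||% 1L)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)

  if (!is.null(config$panel)) {
    panel <- read_panel(config$panel)
    truth <- NULL
  } else {
    spec <- do.call(cohort_spec, c(config$simulate %||% list(n_subjects = 500L),
                                   list()))
    cohort <- generate_cohort(spec)
    panel <- cohort$panel
    truth <- cohort$truth
    write_panel(panel, file.path(out_dir, "panel.csv"))
  }
  for (oc in outcomes)
    if (!(oc$name %in% names(panel)) &&
        !(oc$type == "binary" && all(c("event", "event_time") %in% names(panel))))
      stopf("outcome column '%s' not found in panel", oc$name)

  split <- split_subjects(unique(panel$subject_id), fractions,
                          seed = derive_seed(gseed, 1L))
  fc <- feature_columns(panel)
  train_rows <- panel$subject_id %in% split$train
  prep <- fit_preprocess(panel[train_rows, , drop = FALSE], fc)
  panel_pp <- apply_preprocess(panel, prep)
  fc <- prep$standardize$feature_cols
  graph <- build_graph(panel_pp[panel_pp$subject_id %in% split$train, ,
                                drop = FALSE],
                       fc, tau = config$graph$tau %||% 0.1,
                       method = config$graph$method %||% "correlation")
  write_graph(graph, file.path(out_dir, "graph.json"))
  write_preprocess_state(prep, file.path(out_dir, "preprocess.json"))

  metric_rows <- list()
  for (oc in outcomes) {
    if (oc$type == "continuous") {
      pp <- build_continuous_targets(panel_pp, oc$name)
      batch <- build_sequences(pp, fc, outcome = oc$name,
                               event_labels = FALSE)
    } else {
      pp <- encode_event_labels(panel_pp)
      batch <- build_sequences(pp, fc, outcome = NULL, event_labels = TRUE)
    }
    head <- if (oc$type == "continuous") "continuous" else "binary"
    nb <- node_batch(batch, graph$map, graph$nodes)
    batches <- lapply(split, function(ids) subset_batch(batch, ids))
    nbatches <- lapply(split, function(ids) subset_batch(nb, ids))
    for (arch in archs) {
      is_g <- arch == "graph_gtrnn"
      b <- if (is_g) nbatches else batches
      cfg <- do.call(model_config, c(
        list(architecture = arch,
             input_width = if (is_g) length(graph$nodes) else length(fc),
             head = head),
        config$model %||% list()))
      run <- multi_seed_run(cfg, b$train, b$val, b$test,
                            graph = if (is_g) graph, seeds = seeds)
      ps <- run$per_seed
      ps$outcome <- oc$name; ps$model <- arch
      metric_rows[[paste(oc$name, arch)]] <- ps
      if (is_g) {
        fit <- run$models[[1]]
        traces <- compute_energy_traces(nbatches$test, graph, fit,
                                        source = "hidden_state")
        groups <- if (oc$type == "continuous")
          high_symptom_groups(panel[panel$subject_id %in% split$test, ],
                              oc$name)
        else event_groups(panel[panel$subject_id %in% split$test, ])
        gc_ok <- length(unique(groups)) == 2
        write_energy_csv(traces,
                         file.path(out_dir, sprintf("energy_%s.csv", oc$name)))
        if (gc_ok) {
          contrast <- group_contrast(traces, groups)
          write_energy_csv(contrast,
                           file.path(out_dir,
                                     sprintf("energy_groups_%s.csv", oc$name)))
        }
      }
    }
  }
  all_cols <- unique(unlist(lapply(metric_rows, names)))
  metrics <- do.call(rbind, lapply(metric_rows, function(d) {
    for (cl in setdiff(all_cols, names(d))) d[[cl]] <- NA
    d[all_cols]
  }))
  rownames(metrics) <- NULL
  utils::write.csv(metrics, file.path(out_dir, "metrics.csv"),
                   row.names = FALSE)
  manifest <- list(
    n_subjects = length(unique(panel$subject_id)),
    n_rows = nrow(panel),
    split_sizes = lapply(split, length),
    fractions = fractions,
    outcomes = outcomes,
    architectures = archs,
    seeds = seeds,
    global_seed = gseed,
    feature_count = length(fc),
    nodes = graph$nodes,
    generative_r2 = if (!is.null(truth)) truth$generative_r2
  )
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(manifest)
}
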