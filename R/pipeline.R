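# End-to-end pipeline: data -> filter -> featurize -> SMOTE -> graph ->
# local graphs -> split -> episodic meta-training -> meta-test
# evaluation, driven by one nested configuration list, with a run
# manifest for reproducibility.

#' Default pipeline configuration
#'
#' Returns the nested configuration list consumed by [run_pipeline()].
#' Every stochastic stage derives its seed from the top-level `seed`.
#' Paths may point at a FASTA + label TSV; when absent, the synthetic
#' generator section is used instead.
#'
#' @param seed Top-level integer seed.
#' @return Nested configuration list.
#' @export
default_config <- function(seed = 1) {
  list(
    seed = as.integer(seed),
    paths = list(fasta = NULL, labels = NULL, out_dir = NULL),
    synthetic = list(preset = "dataset1-like", separation = 5,
                     length_range = c(200, 500), order = 0),
    filter = list(forbidden_symbols = c("N", "R", "S", "Y"),
                  max_length = Inf),
    features = list(method = "kmer", k = 5, lambda = 150, weight = 0.3,
                    pca_dims = NULL),
    balancing = list(enabled = TRUE, neighbor_count = 5,
                     mode = "standard"),
    graph = list(tau = 0.7, layers = 1),
    model = list(hidden = 32, dropout = 0),
    meta = list(inner_lr = 0.01, outer_lr = 0.005, inner_steps = 1,
                meta_iterations = 60, order = "first", optimizer = "adam",
                fine_tune_steps = 30,
                m = 4, k_support = 5, k_query = 5),
    split = list(fractions = c(0.8, 0.1, 0.1)),
    evaluation = list(real_test_only = FALSE)
  )
}

#' Validate a pipeline configuration
#'
#' Checks cross-field constraints without running anything. Problems are
#' returned, not thrown.
#'
#' @param config Configuration list (see [default_config()]).
#' @return Character vector of problems; empty when valid.
#' @export
validate_config <- function(config) {
  problems <- character()
  add <- function(msg) problems <<- c(problems, msg)
  if (is.null(config$seed) || !is.numeric(config$seed))
    add("seed: missing or non-numeric")
  tau <- config$graph$tau
  if (is.null(tau) || !is.numeric(tau) || tau < -1 || tau > 1)
    add("graph$tau: must lie in [-1, 1]")
  if (!isTRUE(config$graph$layers %in% c(1, 2)))
    add("graph$layers: must be 1 or 2")
  fx <- config$features
  if (!fx$method %in% c("kmer", "revkmer", "psednc"))
    add("features$method: must be kmer, revkmer or psednc")
  if (fx$method %in% c("kmer", "revkmer")) {
    if (!is.numeric(fx$k) || fx$k < 1 || fx$k > 7)
      add("features$k: must be an integer in [1, 7]")
    min_len <- if (!is.null(config$synthetic$length_range))
      config$synthetic$length_range[1] else NULL
    if (!is.null(min_len) && is.numeric(fx$k) && fx$k > min_len)
      add("features$k: exceeds the minimum sequence length")
  }
  if (fx$method == "psednc") {
    min_len <- if (!is.null(config$synthetic$length_range))
      config$synthetic$length_range[1] else NULL
    if (!is.null(min_len) && fx$lambda + 2 > min_len)
      add("features$lambda: needs sequences of length >= lambda + 2")
  }
  using_files <- !is.null(config$paths$fasta)
  if (using_files && is.null(config$paths$labels))
    add("paths$labels: required when paths$fasta is set")
  if (!using_files) {
    preset <- config$synthetic$preset
    if (is.null(preset) || !preset %in% names(.BENCHMARK_COUNTS))
      add("synthetic$preset: unknown preset")
    else {
      counts <- .BENCHMARK_COUNTS[[preset]]
      target <- max(counts)
      need <- config$meta$k_support + config$meta$k_query
      if (is.numeric(need) && need > target)
        add(paste0("meta$k_support + k_query = ", need,
                   " exceeds the per-class sample count ", target,
                   " after balancing"))
      if (!isTRUE(config$balancing$enabled) &&
          is.numeric(need) && need > min(counts))
        add(paste0("meta$k_support + k_query = ", need,
                   " exceeds the smallest class (", min(counts),
                   ") and balancing is disabled"))
    }
  }
  mt <- config$meta
  for (f in c("inner_lr", "outer_lr")) {
    if (!is.numeric(mt[[f]]) || mt[[f]] <= 0)
      add(paste0("meta$", f, ": must be positive"))
  }
  if (!is.numeric(mt$inner_steps) || mt$inner_steps < 0)
    add("meta$inner_steps: must be >= 0")
  if (!mt$order %in% c("first", "second"))
    add("meta$order: must be first or second")
  fr <- config$split$fractions
  if (is.null(fr) || length(fr) != 3 || abs(sum(fr) - 1) > 1e-8)
    add("split$fractions: three fractions summing to 1")
  problems
}

#' Read / write a pipeline configuration as YAML
#'
#' @param path YAML file path.
#' @param config Configuration list.
#' @return `read_config`: the configuration list; `write_config`:
#'   `path`, invisibly.
#' @export
read_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  base <- default_config()
  modifyList(base, cfg)
}

#' @rdname read_config
#' @export
write_config <- function(config, path) {
  yaml::write_yaml(config, path)
  invisible(path)
}

# md5 of the YAML-serialized config (file-based; no extra dependency)
config_hash <- function(config) {
  tf <- tempfile(fileext = ".yaml")
  on.exit(unlink(tf))
  yaml::write_yaml(config, tf)
  unname(tools::md5sum(tf))
}

#' Run the full localization pipeline
#'
#' Executes the five flow-chart stages in order: (1) build the dataset
#' (files or synthetic) and filter it; (2) balance classes with SMOTE;
#' (3) build the similarity graph and extract local graphs; (4) train
#' the GCN under MAML and fine-tune on the meta-test support set; (5)
#' evaluate the meta-test query set. When `config$paths$out_dir` is set,
#' artifacts (removal report, graph stats, metrics, manifest, training
#' log) are written there.
#'
#' @param config Configuration list (see [default_config()]); validated
#'   before any compute.
#' @param quiet Suppress per-stage messages (default TRUE).
#' @return List with `metrics`, `accuracy`, `graph_stats`,
#'   `class_levels`, `meta_params`, `train_log`, `evaluation` (the full
#'   [fine_tune_and_evaluate()] result), `manifest`, and the
#'   intermediate `n_*` sizes.
#' @export
run_pipeline <- function(config = default_config(), quiet = TRUE) {
  problems <- validate_config(config)
  if (length(problems) > 0) {
    stop("invalid configuration:\n  - ", paste(problems, collapse = "\n  - "))
  }
  say <- function(...) if (!quiet) message("[", ..., "]")
  seed <- as.integer(config$seed)
  manifest <- list(config_hash = config_hash(config), seed = seed,
                   started = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
                   package_version = as.character(utils::packageVersion("metalncloc")),
                   stages = list())
  stage <- function(name, expr) {
    say("stage: ", name)
    t0 <- proc.time()[["elapsed"]]
    out <- tryCatch(expr, error = function(e) {
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE)
    })
    manifest$stages[[name]] <<- list(seconds = round(proc.time()[["elapsed"]] - t0, 3))
    out
  }

  records <- stage("dataset", {
    if (!is.null(config$paths$fasta)) {
      r <- read_fasta(config$paths$fasta)
      attach_labels(r, read_labels(config$paths$labels))
    } else {
      sy <- config$synthetic
      generate_imbalanced_benchmark(sy$preset, separation = sy$separation,
                                    seed = seed,
                                    length_range = sy$length_range,
                                    order = sy$order)
    }
  })
  flt <- stage("filter", {
    pol <- filter_policy(config$filter$forbidden_symbols,
                         config$filter$max_length)
    filter_records(records, pol)
  })
  records <- flt$kept
  feats <- stage("featurize", {
    fx <- config$features
    featurize_dataset(records, feature_config(fx$method, fx$k, fx$lambda,
                                              fx$weight, fx$pca_dims))
  })
  bal <- stage("balance", {
    if (isTRUE(config$balancing$enabled)) {
      smote_balance(feats, records$label,
                    smote_config(config$balancing$neighbor_count,
                                 seed = seed + 1L,
                                 mode = config$balancing$mode))
    } else {
      list(features = feats, labels = records$label,
           provenance = records$provenance,
           parents = data.frame(center = integer(), neighbor = integer(),
                                u = numeric()))
    }
  })
  g <- stage("graph", {
    build_similarity_graph(bal$features, bal$labels, tau = config$graph$tau,
                           provenance = bal$provenance)
  })
  gstats <- graph_stats(g)
  locals <- stage("local_graphs", extract_local_graphs(g, config$graph$layers))

  class_levels <- sort(unique(bal$labels))
  mt <- config$meta
  meta <- meta_config(inner_lr = mt$inner_lr, outer_lr = mt$outer_lr,
                      inner_steps = mt$inner_steps,
                      meta_iterations = mt$meta_iterations,
                      order = mt$order, optimizer = mt$optimizer,
                      fine_tune_steps = mt$fine_tune_steps,
                      seed = seed + 2L)
  episode <- episode_config(m = mt$m, k_support = mt$k_support,
                            k_query = mt$k_query,
                            num_classes = length(class_levels))
  gcfg <- gcn_config(c(ncol(bal$features), config$model$hidden,
                       length(class_levels)),
                     dropout = config$model$dropout)
  model <- gcn_meta_model(locals, g$features, gcfg, class_levels)

  split <- stage("split", {
    split_dataset(bal$labels, fractions = config$split$fractions,
                  seed = seed + 3L)
  })
  fit <- stage("meta_train", {
    train_idx <- split$train
    stream <- function(it) {
      tk <- sample_tasks(bal$labels[train_idx], episode,
                         seed = meta$seed + it, class_levels = class_levels)
      lapply(tk, function(t) list(
        support = model$make_data(train_idx[t$support]),
        query = model$make_data(train_idx[t$query])))
    }
    meta_train(model, stream, init = model$init(meta$seed), meta = meta)
  })
  ev <- stage("meta_test", {
    qfilter <- if (isTRUE(config$evaluation$real_test_only))
      bal$provenance == "real" else NULL
    task <- make_test_task(model, bal$labels, split$test,
                           k_support = episode$k_support,
                           seed = seed + 4L, query_filter = qfilter)
    fine_tune_and_evaluate(model, task, fit$params, meta)
  })

  manifest$finished <- format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")
  out_dir <- config$paths$out_dir
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    write_removal_report(flt$removed, file.path(out_dir, "removed.tsv"))
    write_edge_list(g, file.path(out_dir, "edges.tsv"))
    jsonlite::write_json(gstats, file.path(out_dir, "graph_stats.json"),
                         auto_unbox = TRUE, digits = NA)
    write_metrics_json(ev$metrics, file.path(out_dir, "metrics.json"))
    utils::write.csv(fit$log, file.path(out_dir, "train_log.csv"),
                     row.names = FALSE)
    saveRDS(list(params = fit$params, config_hash = manifest$config_hash),
            file.path(out_dir, "checkpoint.rds"))
    jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA)
  }
  list(metrics = ev$metrics, accuracy = ev$accuracy, graph_stats = gstats,
       class_levels = class_levels, meta_params = fit$params,
       train_log = fit$log, evaluation = ev, manifest = manifest,
       n_input = nrow(records) + nrow(flt$removed),
       n_filtered = nrow(records),
       n_balanced = length(bal$labels),
       n_local_graphs = length(locals))
}
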