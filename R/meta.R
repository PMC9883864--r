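# Model-agnostic meta-learning (MAML) over local-graph classification
# tasks: episodic N-way K-shot sampling, inner-loop adaptation on the
# support set, an outer-loop meta-update from the summed post-adaptation
# query losses (second-order by default), and meta-test fine-tuning.
#
# The engine is model-agnostic in code too: it talks to the model through
# a small interface (loss / grad / hvp / predict closures), which the GCN
# provides and which toy models in the test-suite provide equally well.

#' Episode (task) configuration
#'
#' A task holds `num_classes * (k_support + k_query)` samples:
#' `k_support` support and `k_query` query samples per class.
#'
#' @param m Tasks per meta-batch (default 8).
#' @param k_support,k_query Shots per class (defaults 5 and 5).
#' @param num_classes Number of compartments |C|.
#' @return An `episode_config` object.
#' @export
episode_config <- function(m = 8, k_support = 5, k_query = 5, num_classes) {
  stopifnot(m >= 1, k_support >= 1, k_query >= 1, num_classes >= 2)
  structure(list(m = as.integer(m), k_support = as.integer(k_support),
                 k_query = as.integer(k_query),
                 num_classes = as.integer(num_classes)),
            class = "episode_config")
}

#' Meta-learning configuration
#'
#' All defaults are package choices (the source method does not publish
#' its hyperparameters); every one is a plain config entry.
#'
#' @param inner_lr Inner-loop (task adaptation) step size, default 0.01.
#' @param outer_lr Outer-loop (meta-update) step size, default 0.001.
#' @param inner_steps Gradient steps per task adaptation (0 allowed:
#'   meta-training degenerates to plain training on the query sets).
#' @param meta_iterations Outer iterations, default 1000.
#' @param order `"second"` (default; exact meta-gradient through the
#'   inner trajectory via Hessian-vector products) or `"first"`
#'   (first-order approximation: query gradient at the adapted
#'   parameters).
#' @param optimizer Outer optimizer, `"adam"` (default) or `"sgd"`.
#' @param fine_tune_steps Gradient steps on the meta-test support set
#'   (default 10).
#' @param seed Integer seed governing episode sampling.
#' @return A `meta_config` object.
#' @export
meta_config <- function(inner_lr = 0.01, outer_lr = 0.001, inner_steps = 5,
                        meta_iterations = 1000, order = c("second", "first"),
                        optimizer = c("adam", "sgd"), fine_tune_steps = 10,
                        seed = 1) {
  order <- match.arg(order)
  optimizer <- match.arg(optimizer)
  stopifnot(inner_lr > 0, outer_lr > 0, inner_steps >= 0,
            meta_iterations >= 1, fine_tune_steps >= 0)
  structure(list(inner_lr = inner_lr, outer_lr = outer_lr,
                 inner_steps = as.integer(inner_steps),
                 meta_iterations = as.integer(meta_iterations),
                 order = order, optimizer = optimizer,
                 fine_tune_steps = as.integer(fine_tune_steps),
                 seed = as.integer(seed)),
            class = "meta_config")
}

#' Sample episodic tasks from a labeled pool
#'
#' Draws `episode$m` tasks. Within a task, each class contributes
#' `k_support + k_query` distinct samples (sampling without replacement
#' within the task); across tasks sampling is with replacement, so the
#' same pool sample may appear in many tasks.
#'
#' @param labels Character labels of the pool samples.
#' @param episode An [episode_config()]; `num_classes` must equal the
#'   number of distinct labels.
#' @param seed Integer seed; the draw is deterministic given it.
#' @param class_levels Optional fixed class ordering (defaults to sorted
#'   unique labels).
#' @return List of `episode$m` tasks, each a list with integer index
#'   vectors `support` and `query` (disjoint within the task).
#' @export
sample_tasks <- function(labels, episode, seed = 1,
                         class_levels = sort(unique(labels))) {
  need <- episode$k_support + episode$k_query
  by_class <- split(seq_along(labels), factor(labels, levels = class_levels))
  sizes <- vapply(by_class, length, integer(1))
  if (any(sizes < need)) {
    bad <- names(sizes)[which(sizes < need)[1]]
    stop("class '", bad, "' has ", sizes[[bad]], " samples; a task needs ",
         need, " (k_support + k_query) per class")
  }
  withr::with_seed(seed, {
    lapply(seq_len(episode$m), function(t) {
      sup <- integer(); qry <- integer()
      for (cl in class_levels) {
        pick <- sample(by_class[[cl]], need)
        sup <- c(sup, pick[seq_len(episode$k_support)])
        qry <- c(qry, pick[episode$k_support + seq_len(episode$k_query)])
      }
      list(support = sup, query = qry)
    })
  })
}

#' Wrap a GCN and a local-graph pool as a meta-learnable model
#'
#' Produces the closure interface the MAML engine consumes: `init(seed)`,
#' `loss(params, data)`, `grad(params, data)`, `hvp(params, data, v)`,
#' `predict(params, data)`, and `make_data(idx)` turning pool indices
#' into a batch.
#'
#' @param locals List of `local_graph` objects (the sample pool).
#' @param X_pool Node feature matrix of the parent graph.
#' @param config A [gcn_config()].
#' @param class_levels Fixed class ordering.
#' @return A `meta_model` list of closures.
#' @export
gcn_meta_model <- function(locals, X_pool, config, class_levels) {
  force(locals); force(X_pool); force(config); force(class_levels)
  structure(list(
    init = function(seed = 1) gcn_init_params(config, seed),
    make_data = function(idx) build_task_batch(locals[idx], class_levels),
    loss = function(params, data) gcn_batch_loss(params, data, X_pool),
    grad = function(params, data) gcn_batch_grad(params, data, X_pool),
    hvp = function(params, data, v) gcn_batch_hvp(params, data, X_pool, v),
    predict = function(params, data) gcn_batch_predict(params, data, X_pool),
    class_levels = class_levels,
    config = config
  ), class = "meta_model")
}

#' Inner-loop adaptation on a support set
#'
#' Runs `meta$inner_steps` plain gradient-descent steps of the support
#' loss from `params` (which is not modified). With `inner_steps = 0`
#' the input parameters are returned unchanged.
#'
#' @param model A `meta_model`.
#' @param params Parameter list (the shared initialization theta).
#' @param data Support-set data (a batch for the GCN model).
#' @param meta A [meta_config()].
#' @return List with `params` (adapted theta_i) and `trajectory` (the
#'   parameter list before each inner step, used by the second-order
#'   meta-gradient).
#' @export
inner_adapt <- function(model, params, data, meta) {
  traj <- vector("list", meta$inner_steps)
  th <- params
  if (meta$inner_steps > 0) {
    for (t in seq_len(meta$inner_steps)) {
      traj[[t]] <- th
      g <- model$grad(th, data)
      th <- par_axpy(th, -meta$inner_lr, g$grad)
    }
  }
  list(params = th, trajectory = traj)
}

# meta-gradient of one task: reverse accumulation through the inner
# gradient-descent trajectory. second order:
#   g <- grad_query(theta_T);  g <- (I - alpha H_support(theta_t)) g
# first order: the query gradient at theta_T.
maml_task_gradient <- function(model, params, task_data, meta) {
  ad <- inner_adapt(model, params, task_data$support, meta)
  gq <- model$grad(ad$params, task_data$query)
  g <- gq$grad
  if (meta$order == "second" && meta$inner_steps > 0) {
    for (t in rev(seq_len(meta$inner_steps))) {
      hv <- model$hvp(ad$trajectory[[t]], task_data$support, g)
      g <- par_axpy(g, -meta$inner_lr, hv)
    }
  }
  list(grad = g, query_loss = gq$loss)
}

#' Meta-train: learn meta-parameters theta' over a task stream
#'
#' Each outer iteration draws a meta-batch of tasks, adapts a copy of
#' the current parameters on every task's support set, sums the
#' post-adaptation query-loss meta-gradients over the batch, and applies
#' one outer optimizer step. The returned parameters are the
#' meta-parameters theta'.
#'
#' @param model A `meta_model`.
#' @param task_stream Function `(iteration)` returning the meta-batch: a
#'   list of tasks, each a list with `support` and `query` data objects.
#' @param init Initial parameter list (default: `model$init(meta$seed)`).
#' @param meta A [meta_config()].
#' @return List with `params` (theta'), and `log`: a data.frame with one
#'   row per outer iteration (`iteration`, `query_loss` = summed
#'   post-adaptation query loss of the meta-batch).
#' @export
meta_train <- function(model, task_stream, init = NULL, meta = meta_config()) {
  th <- if (is.null(init)) model$init(meta$seed) else init
  log_loss <- numeric(meta$meta_iterations)
  adam_m <- par_zero(th); adam_v <- par_zero(th)
  b1 <- 0.9; b2 <- 0.999; eps <- 1e-8
  for (it in seq_len(meta$meta_iterations)) {
    tasks <- task_stream(it)
    total <- par_zero(th)
    qloss <- 0
    for (task in tasks) {
      tg <- maml_task_gradient(model, th, task, meta)
      total <- par_add(total, tg$grad)
      qloss <- qloss + tg$query_loss
    }
    if (!is.finite(qloss) || !par_finite(total)) {
      stop("meta-training diverged at iteration ", it,
           " (non-finite loss or gradient); lower the learning rates")
    }
    if (meta$optimizer == "adam") {
      adam_m <- mapply(function(m, g) b1 * m + (1 - b1) * g, adam_m, total,
                       SIMPLIFY = FALSE)
      adam_v <- mapply(function(v, g) b2 * v + (1 - b2) * g^2, adam_v, total,
                       SIMPLIFY = FALSE)
      mhat <- par_scale(adam_m, 1 / (1 - b1^it))
      vhat <- par_scale(adam_v, 1 / (1 - b2^it))
      step <- mapply(function(m, v) m / (sqrt(v) + eps), mhat, vhat,
                     SIMPLIFY = FALSE)
      th <- par_axpy(th, -meta$outer_lr, step)
    } else {
      th <- par_axpy(th, -meta$outer_lr, total)
    }
    log_loss[it] <- qloss
  }
  list(params = th,
       log = data.frame(iteration = seq_len(meta$meta_iterations),
                        query_loss = log_loss))
}

#' Fine-tune meta-parameters on a test task and evaluate its query set
#'
#' Starts from theta' (left unmodified), runs `meta$fine_tune_steps`
#' gradient steps on the test support set at the inner learning rate,
#' predicts the test query set, and computes the full metrics report.
#'
#' @param model A `meta_model`.
#' @param test_task List with `support` and `query` data objects; for
#'   metric computation the query data must carry true labels (`y`).
#' @param meta_params Meta-parameters theta' from [meta_train()].
#' @param meta A [meta_config()].
#' @return List with `metrics` (see [compute_metrics()]), `accuracy`,
#'   `predicted` and `truth` (integer class indices), `probs`, and the
#'   fine-tuned `params`.
#' @export
fine_tune_and_evaluate <- function(model, test_task, meta_params,
                                   meta = meta_config()) {
  th <- meta_params
  if (meta$fine_tune_steps > 0) {
    for (t in seq_len(meta$fine_tune_steps)) {
      g <- model$grad(th, test_task$support)
      th <- par_axpy(th, -meta$inner_lr, g$grad)
    }
  }
  probs <- model$predict(th, test_task$query)
  pred <- max.col(probs, ties.method = "first")
  truth <- test_task$query$y
  counts <- confusion_counts(truth, pred, ncol(probs))
  metrics <- compute_metrics(counts)
  list(metrics = metrics, accuracy = metrics$accuracy,
       predicted = pred, truth = truth, probs = probs, params = th)
}

#' Stratified split of a labeled pool
#'
#' Either fraction mode (`fractions`, summing to 1) or fold mode
#' (`folds` + `fold`: the held-out fold is the test set, the rest is
#' split into train and validation by `val_fraction`). Splits are
#' disjoint, exhaustive, stratified by label, and deterministic under
#' the seed.
#'
#' @param labels Character labels of the pool.
#' @param fractions Named or positional numeric vector
#'   (train, val, test), default `c(0.8, 0.1, 0.1)`.
#' @param folds,fold Fold mode: total folds and the held-out fold index.
#' @param val_fraction Fraction of the non-test samples used for
#'   validation in fold mode (default 0.1).
#' @param seed Integer seed.
#' @return List of integer index vectors `train`, `val`, `test`.
#' @export
split_dataset <- function(labels, fractions = c(0.8, 0.1, 0.1),
                          folds = NULL, fold = NULL, val_fraction = 0.1,
                          seed = 1) {
  n <- length(labels)
  if (!is.null(folds)) {
    stopifnot(!is.null(fold), fold >= 1, fold <= folds)
    fa <- stratified_folds(labels, folds, seed)
    test <- which(fa == fold)
    rest <- which(fa != fold)
    withr::with_seed(seed + 1L, {
      by_class <- split(rest, labels[rest])
      val <- unlist(lapply(by_class, function(ix) {
        k <- round(length(ix) * val_fraction)
        if (k == 0) integer() else sample(ix, k)
      }), use.names = FALSE)
    })
    train <- setdiff(rest, val)
  } else {
    stopifnot(length(fractions) == 3, abs(sum(fractions) - 1) < 1e-8)
    idx <- withr::with_seed(seed, {
      by_class <- split(seq_len(n), labels)
      parts <- list(train = integer(), val = integer(), test = integer())
      for (ix in by_class) {
        ix <- sample(ix)
        m <- length(ix)
        cuts <- round(cumsum(fractions) * m)
        parts$train <- c(parts$train, ix[seq_len(cuts[1])])
        if (cuts[2] > cuts[1])
          parts$val <- c(parts$val, ix[(cuts[1] + 1):cuts[2]])
        if (m > cuts[2])
          parts$test <- c(parts$test, ix[(cuts[2] + 1):m])
      }
      parts
    })
    train <- idx$train; val <- idx$val; test <- idx$test
  }
  out <- list(train = sort(train), val = sort(val), test = sort(test))
  if (any(vapply(out, length, integer(1)) == 0)) {
    stop("a split is empty; adjust fractions or pool size")
  }
  out
}

# deterministic stratified fold assignment: within each class, shuffled
# samples are dealt round-robin over folds
stratified_folds <- function(labels, folds, seed = 1) {
  fa <- integer(length(labels))
  withr::with_seed(seed, {
    for (ix in split(seq_along(labels), labels)) {
      ix <- sample(ix)
      fa[ix] <- rep_len(seq_len(folds), length(ix))
    }
  })
  fa
}

#' Build a single meta-test task from a held-out index set
#'
#' The conventional meta-test protocol here treats the whole held-out
#' set as one task: `k_support` samples per class form the fine-tuning
#' support set and every remaining sample is query.
#'
#' @param model A `meta_model` (supplies `make_data`).
#' @param labels Pool labels.
#' @param test_idx Indices of the held-out samples.
#' @param k_support Support shots per class.
#' @param seed Integer seed for the support draw.
#' @param query_filter Optional logical vector over the pool (e.g.
#'   real-provenance flags); query samples failing it are dropped.
#' @return List with `support` and `query` data objects and the index
#'   vectors `support_idx`, `query_idx`.
#' @export
make_test_task <- function(model, labels, test_idx, k_support = 5,
                           seed = 1, query_filter = NULL) {
  by_class <- split(test_idx, labels[test_idx])
  short <- vapply(by_class, length, integer(1)) <= k_support
  if (any(short)) {
    stop("class '", names(by_class)[which(short)[1]],
         "' has too few held-out samples for k_support = ", k_support)
  }
  sup <- withr::with_seed(seed, {
    unlist(lapply(by_class, function(ix) sample(ix, k_support)),
           use.names = FALSE)
  })
  qry <- setdiff(test_idx, sup)
  if (!is.null(query_filter)) qry <- qry[query_filter[qry]]
  if (length(qry) == 0) stop("no query samples left after filtering")
  list(support = model$make_data(sup), query = model$make_data(qry),
       support_idx = sup, query_idx = qry)
}
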