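# Episodic task sampling, inner-loop adaptation, meta-gradients,
# meta-training and meta-test fine-tuning

test_that("tasks hold |C| x (k_support + k_query) samples, disjoint within", {
  labels <- rep(paste0("c", 1:5), times = c(20, 15, 12, 9, 8))
  ep <- episode_config(m = 6, k_support = 1, k_query = 1, num_classes = 5)
  tasks <- sample_tasks(labels, ep, seed = 4)
  expect_length(tasks, 6)
  for (t in tasks) {
    expect_length(c(t$support, t$query), 10)
    expect_length(intersect(t$support, t$query), 0)
    expect_equal(as.integer(table(labels[t$support])), rep(1L, 5))
    expect_equal(as.integer(table(labels[t$query])), rep(1L, 5))
  }

  ep2 <- episode_config(m = 2, k_support = 3, k_query = 2, num_classes = 5)
  tasks2 <- sample_tasks(labels, ep2, seed = 1)
  expect_length(tasks2[[1]]$support, 15)
  expect_length(tasks2[[1]]$query, 10)

  expect_identical(sample_tasks(labels, ep, seed = 9),
                   sample_tasks(labels, ep, seed = 9))
})

test_that("a class too small for the episode is named in the error", {
  labels <- c(rep("big", 10), "tiny")
  ep <- episode_config(m = 1, k_support = 1, k_query = 1, num_classes = 2)
  expect_error(sample_tasks(labels, ep), "tiny")
})

test_that("inner adaptation follows the closed-form quadratic step", {
  model <- toy_model()
  d <- list(a = c(1, 1), b = c(0, 0), t = matrix(c(2, -1), 2, 1))
  th0 <- list(matrix(c(0, 0), 2, 1))
  meta <- meta_config(inner_lr = 0.1, inner_steps = 1, meta_iterations = 1)
  ad <- inner_adapt(model, th0, d, meta)
  # one GD step on L = ||theta - t||^2 / 2: theta + lr (t - theta)
  expect_equal(ad$params[[1]], th0[[1]] + 0.1 * (d$t - th0[[1]]))

  meta0 <- meta_config(inner_steps = 0, meta_iterations = 1)
  expect_identical(inner_adapt(model, th0, d, meta0)$params, th0)
})

test_that("adaptation does not increase the support loss at small rates", {
  pool <- make_blob_pool(n_per_class = 10, n_classes = 3, d = 6, seed = 8)
  cfg <- gcn_config(c(6, 4, 3))
  model <- gcn_meta_model(pool$locals, pool$X, cfg, pool$class_levels)
  meta <- meta_config(inner_lr = 0.01, inner_steps = 5, meta_iterations = 1)
  for (trial in 1:20) {
    th <- model$init(trial)
    data <- model$make_data(withr::with_seed(trial, sample(30, 12)))
    before <- model$loss(th, data)
    after <- model$loss(inner_adapt(model, th, data, meta)$params, data)
    expect_lte(after, before + 1e-12)
  }
})

test_that("with zero inner steps the meta-gradient is the query gradient", {
  pool <- make_blob_pool(n_per_class = 8, n_classes = 2, d = 5, seed = 2)
  cfg <- gcn_config(c(5, 4, 2))
  model <- gcn_meta_model(pool$locals, pool$X, cfg, pool$class_levels)
  th <- model$init(3)
  task <- list(support = model$make_data(1:6),
               query = model$make_data(7:12))
  for (ord in c("first", "second")) {
    meta <- meta_config(inner_steps = 0, order = ord, meta_iterations = 1)
    mg <- metalncloc:::maml_task_gradient(model, th, task, meta)
    plain <- model$grad(th, task$query)$grad
    expect_lt(metalncloc:::par_max_abs_diff(mg$grad, plain), 1e-5)
  }
})

test_that("second-order meta-gradient matches finite differences of the
           meta-objective on a two-parameter toy", {
  model <- toy_model()
  support <- list(a = c(1.0, 2.0), b = c(0.5, 0.3), t = matrix(c(1, -1), 2, 1))
  query <- list(a = c(2.0, 0.7), b = c(0.2, 0.6), t = matrix(c(-0.5, 2), 2, 1))
  task <- list(support = support, query = query)
  for (steps in c(1, 3)) {
    meta <- meta_config(inner_lr = 0.05, inner_steps = steps,
                        order = "second", meta_iterations = 1)
    th <- list(matrix(c(0.4, -0.3), 2, 1))
    mg <- metalncloc:::maml_task_gradient(model, th, task, meta)
    # oracle: central finite differences of theta -> L_q(adapt(theta))
    meta_obj <- function(thvec) {
      p <- list(matrix(thvec, 2, 1))
      ad <- inner_adapt(model, p, support, meta)
      model$loss(ad$params, query)
    }
    eps <- 1e-6
    for (i in 1:2) {
      tp <- c(0.4, -0.3); tp[i] <- tp[i] + eps
      tm <- c(0.4, -0.3); tm[i] <- tm[i] - eps
      fd <- (meta_obj(tp) - meta_obj(tm)) / (2 * eps)
      expect_equal(mg$grad[[1]][i, 1], fd, tolerance = 1e-4)
    }
    # first-order approximation differs once curvature is present
    meta1 <- meta_config(inner_lr = 0.05, inner_steps = steps,
                         order = "first", meta_iterations = 1)
    mg1 <- metalncloc:::maml_task_gradient(model, th, task, meta1)
    expect_gt(metalncloc:::par_max_abs_diff(mg$grad, mg1$grad), 1e-6)
  }
})

test_that("with inner_steps = 0 and one task meta-training is plain
           gradient descent on the query loss", {
  pool <- make_blob_pool(n_per_class = 8, n_classes = 2, d = 5, seed = 6)
  cfg <- gcn_config(c(5, 3, 2))
  model <- gcn_meta_model(pool$locals, pool$X, cfg, pool$class_levels)
  qidx <- c(1:4, 9:12)
  task <- list(support = model$make_data(5:8), query = model$make_data(qidx))
  meta <- meta_config(inner_steps = 0, outer_lr = 0.1, optimizer = "sgd",
                      meta_iterations = 5, seed = 1)
  fit <- meta_train(model, function(it) list(task), init = model$init(1),
                    meta = meta)
  # hand-rolled gradient descent on the same query batch
  th <- model$init(1)
  losses <- numeric(5)
  for (it in 1:5) {
    g <- model$grad(th, task$query)
    losses[it] <- g$loss
    th <- metalncloc:::par_axpy(th, -0.1, g$grad)
  }
  expect_equal(fit$log$query_loss, losses, tolerance = 1e-12)
  expect_params_equal(fit$params, th, tol = 1e-12)
})

test_that("meta-training is deterministic and learns separable episodes", {
  pool <- make_blob_pool(n_per_class = 20, n_classes = 3, d = 6,
                         blob_sep = 4, seed = 10)
  cfg <- gcn_config(c(6, 8, 3))
  model <- gcn_meta_model(pool$locals, pool$X, cfg, pool$class_levels)
  ep <- episode_config(m = 2, k_support = 3, k_query = 3, num_classes = 3)
  stream <- function(it) {
    tasks <- sample_tasks(pool$labels, ep, seed = 100 + it,
                          class_levels = pool$class_levels)
    lapply(tasks, function(t) list(support = model$make_data(t$support),
                                   query = model$make_data(t$query)))
  }
  meta <- meta_config(inner_lr = 0.1, outer_lr = 0.05, inner_steps = 1,
                      meta_iterations = 30, order = "second", seed = 5)
  fit1 <- meta_train(model, stream, meta = meta)
  fit2 <- meta_train(model, stream, meta = meta)
  expect_identical(fit1$log, fit2$log)
  expect_params_equal(fit1$params, fit2$params, tol = 1e-15)
  # total query loss comes down over the first iterations
  expect_lt(mean(tail(fit1$log$query_loss, 5)),
            mean(head(fit1$log$query_loss, 5)))
})

test_that("meta-test fine-tuning memorizes a separable support set and
           chance-level holds for an untrained network", {
  pool <- make_blob_pool(n_per_class = 12, n_classes = 2, d = 5,
                         blob_sep = 5, seed = 4)
  cfg <- gcn_config(c(5, 4, 2))
  model <- gcn_meta_model(pool$locals, pool$X, cfg, pool$class_levels)
  idx <- c(1:6, 13:18)
  task <- list(support = model$make_data(idx), query = model$make_data(idx))
  meta <- meta_config(inner_lr = 0.1, fine_tune_steps = 200,
                      meta_iterations = 1)
  ev <- fine_tune_and_evaluate(model, task, model$init(2), meta)
  expect_equal(ev$accuracy, 1)

  # zero fine-tune steps: predictions are those of theta' itself
  meta0 <- meta_config(fine_tune_steps = 0, meta_iterations = 1)
  th <- model$init(2)
  ev0 <- fine_tune_and_evaluate(model, task, th, meta0)
  expect_equal(ev0$probs, model$predict(th, task$query))

  # untrained 5-class balanced query sits near chance
  pool5 <- make_blob_pool(n_per_class = 60, n_classes = 5, d = 6,
                          blob_sep = 0, seed = 9)
  m5 <- gcn_meta_model(pool5$locals, pool5$X, gcn_config(c(6, 4, 5)),
                       pool5$class_levels)
  t5 <- list(support = m5$make_data(1:10),
             query = m5$make_data(seq_len(300)))
  acc <- fine_tune_and_evaluate(m5, t5, m5$init(11), meta0)$accuracy
  expect_gt(acc, 0.2 - 3 * sqrt(0.2 * 0.8 / 300) - 0.05)
  expect_lt(acc, 0.2 + 3 * sqrt(0.2 * 0.8 / 300) + 0.05)
})

test_that("fine-tuning from meta-parameters reaches a target loss in fewer
           steps than from a random initialization", {
  pool <- make_blob_pool(n_per_class = 20, n_classes = 3, d = 6,
                         blob_sep = 4, seed = 12)
  cfg <- gcn_config(c(6, 8, 3))
  model <- gcn_meta_model(pool$locals, pool$X, cfg, pool$class_levels)
  ep <- episode_config(m = 2, k_support = 3, k_query = 3, num_classes = 3)
  stream <- function(it) {
    tasks <- sample_tasks(pool$labels, ep, seed = 500 + it,
                          class_levels = pool$class_levels)
    lapply(tasks, function(t) list(support = model$make_data(t$support),
                                   query = model$make_data(t$query)))
  }
  meta <- meta_config(inner_lr = 0.1, outer_lr = 0.05, inner_steps = 1,
                      meta_iterations = 40, order = "second", seed = 7)
  fit <- meta_train(model, stream, meta = meta)
  support <- model$make_data(withr::with_seed(3, sample(60, 9)))
  steps_to <- function(th, target, max_steps = 400) {
    for (s in 0:max_steps) {
      if (model$loss(th, support) <= target) return(s)
      th <- metalncloc:::par_axpy(th, -0.1, model$grad(th, support)$grad)
    }
    Inf
  }
  target <- 0.35
  expect_lte(steps_to(fit$params, target), steps_to(model$init(99), target))
})

test_that("split_dataset is disjoint, exhaustive and stratified", {
  labels <- rep(c("a", "b"), each = 50)
  sp <- split_dataset(labels, fractions = c(0.8, 0.1, 0.1), seed = 2)
  expect_length(sp$train, 80)
  expect_length(sp$val, 10)
  expect_length(sp$test, 10)
  expect_length(intersect(sp$train, c(sp$val, sp$test)), 0)
  expect_setequal(c(sp$train, sp$val, sp$test), 1:100)
  # stratification within one sample of the pool proportions
  for (part in sp) {
    tab <- table(factor(labels[part], levels = c("a", "b")))
    expect_lte(abs(tab[["a"]] - tab[["b"]]), 1)
  }
  expect_identical(sp, split_dataset(labels, seed = 2))

  # fold mode: held-out fold is the test set
  sp10 <- split_dataset(labels, folds = 10, fold = 3, seed = 5)
  fa <- metalncloc:::stratified_folds(labels, 10, 5)
  expect_equal(sp10$test, which(fa == 3))
  expect_setequal(c(sp10$train, sp10$val, sp10$test), 1:100)
  expect_length(intersect(sp10$val, sp10$train), 0)

  expect_error(split_dataset(labels, fractions = c(1, 0, 0)), "empty")
})
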