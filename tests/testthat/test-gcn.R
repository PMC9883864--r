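# GCN forward pass, normalized propagation, gradients and
# Hessian-vector products

test_that("normalize_adjacency matches hand-computed cases", {
  iso <- structure(list(center = 1L, nodes = 1L,
                        edges = matrix(integer(0), ncol = 2), label = "a",
                        features_pool = matrix(1, 1, 1)),
                   class = "local_graph")
  expect_equal(normalize_adjacency(iso), matrix(1, 1, 1))

  pair <- matrix(c(0, 1, 1, 0), 2, 2)
  expect_equal(normalize_adjacency(pair), matrix(0.5, 2, 2))

  # d-regular ring: every row of the propagation matrix sums to 1
  ring <- matrix(0, 5, 5)
  for (i in 1:5) { j <- i %% 5 + 1; ring[i, j] <- 1; ring[j, i] <- 1 }
  expect_equal(rowSums(normalize_adjacency(ring)), rep(1, 5))
})

test_that("gcn_forward equals the explicit dense propagation chain", {
  withr::with_seed(31, {
    for (trial in 1:50) {
      n <- sample(2:8, 1)
      d <- sample(3:6, 1)
      local <- random_local_graph(n, d)
      cfg <- gcn_config(c(d, 5, 3))
      params <- gcn_init_params(cfg, seed = trial)
      out <- gcn_forward(local, params, cfg)

      # independent recomputation: build A by hand, chain the formula
      A <- matrix(0, n, n)
      if (nrow(local$edges) > 0) {
        for (r in seq_len(nrow(local$edges))) {
          A[local$edges[r, 1], local$edges[r, 2]] <- 1
          A[local$edges[r, 2], local$edges[r, 1]] <- 1
        }
      }
      Ap <- A + diag(n)
      Dm <- diag(1 / sqrt(rowSums(Ap)))
      Ahat <- Dm %*% Ap %*% Dm
      H <- pmax(Ahat %*% local$features_pool %*% params[[1]], 0)
      Z <- Ahat %*% H %*% params[[2]]
      P <- exp(Z) / rowSums(exp(Z))
      expect_lt(max(abs(out - P)), 1e-6)
      expect_equal(rowSums(out), rep(1, n), tolerance = 1e-9)
    }
  })
})

test_that("an isolated node with identity weights passes features through", {
  d <- 4
  local <- structure(list(center = 1L, nodes = 1L,
                          edges = matrix(integer(0), ncol = 2), label = "a",
                          features_pool = matrix(c(2, -1, 0.5, 3), 1, 4)),
                     class = "local_graph")
  cfg <- gcn_config(c(d, d))
  out <- gcn_forward(local, list(diag(d)), cfg)
  # single linear layer: softmax of the features themselves
  expect_equal(as.numeric(out),
               as.numeric(exp(local$features_pool) / sum(exp(local$features_pool))))
})

test_that("batched evaluation reproduces per-graph forward passes", {
  withr::with_seed(17, {
    pool <- matrix(rnorm(30 * 4), 30, 4)
    locals <- lapply(1:6, function(i) {
      nodes <- c(i, sample(setdiff(1:30, i), sample(0:4, 1)))
      edges <- if (length(nodes) > 1) cbind(nodes[1], nodes[-1]) else
        matrix(integer(0), ncol = 2)
      structure(list(center = i, nodes = nodes, edges = edges,
                     label = c("a", "b")[1 + i %% 2], features_pool = pool),
                class = "local_graph")
    })
  })
  cfg <- gcn_config(c(4, 5, 2))
  params <- gcn_init_params(cfg, 3)
  batch <- build_task_batch(locals, c("a", "b"))
  probs <- metalncloc:::gcn_batch_predict(params, batch, pool)
  for (i in seq_along(locals)) {
    single <- gcn_forward(locals[[i]], params, cfg)
    expect_equal(unname(probs[i, ]), unname(single[1, ]), tolerance = 1e-9)
  }
})

test_that("analytic gradients match central finite differences", {
  withr::with_seed(23, {
    pool <- matrix(rnorm(20 * 5), 20, 5)
    locals <- lapply(1:8, function(i) {
      nodes <- c(i, sample(setdiff(1:20, i), 3))
      structure(list(center = i, nodes = nodes,
                     edges = cbind(nodes[1], nodes[-1]),
                     label = c("a", "b", "c")[1 + i %% 3],
                     features_pool = pool),
                class = "local_graph")
    })
    batch <- build_task_batch(locals, c("a", "b", "c"))
    cfg <- gcn_config(c(5, 4, 3))
    params <- gcn_init_params(cfg, 1)
    gr <- metalncloc:::gcn_batch_grad(params, batch, pool)
    eps <- 1e-6
    for (l in 1:2) {
      for (trial in 1:6) {
        i <- sample(nrow(params[[l]]), 1); j <- sample(ncol(params[[l]]), 1)
        pp <- params; pp[[l]][i, j] <- pp[[l]][i, j] + eps
        pm <- params; pm[[l]][i, j] <- pm[[l]][i, j] - eps
        fd <- (metalncloc:::gcn_batch_loss(pp, batch, pool) -
                 metalncloc:::gcn_batch_loss(pm, batch, pool)) / (2 * eps)
        expect_equal(gr$grad[[l]][i, j], fd, tolerance = 1e-5)
      }
    }
  })
})

test_that("hessian-vector products match finite differences of the gradient", {
  withr::with_seed(29, {
    pool <- matrix(rnorm(15 * 4), 15, 4)
    locals <- lapply(1:6, function(i) {
      nodes <- c(i, sample(setdiff(1:15, i), 2))
      structure(list(center = i, nodes = nodes,
                     edges = cbind(nodes[1], nodes[-1]),
                     label = c("a", "b")[1 + i %% 2], features_pool = pool),
                class = "local_graph")
    })
    batch <- build_task_batch(locals, c("a", "b"))
    cfg <- gcn_config(c(4, 3, 2))
    params <- gcn_init_params(cfg, 2)
    for (trial in 1:5) {
      v <- lapply(params, function(m) matrix(rnorm(length(m)), nrow(m)))
      hv <- metalncloc:::gcn_batch_hvp(params, batch, pool, v)
      h <- 1e-5
      gp <- metalncloc:::gcn_batch_grad(metalncloc:::par_axpy(params, h, v),
                                        batch, pool)$grad
      gm <- metalncloc:::gcn_batch_grad(metalncloc:::par_axpy(params, -h, v),
                                        batch, pool)$grad
      fd <- mapply(function(a, b) (a - b) / (2 * h), gp, gm, SIMPLIFY = FALSE)
      expect_lt(metalncloc:::par_max_abs_diff(hv, fd), 1e-5)
    }
  })
})

test_that("feature-dimension mismatches are rejected", {
  local <- random_local_graph(3, 4)
  cfg <- gcn_config(c(6, 3, 2))
  params <- gcn_init_params(cfg, 1)
  expect_error(gcn_forward(local, params, cfg), "dimension")
})
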