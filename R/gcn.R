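# Graph convolutional classifier over local (ego) graphs.
#
# Each layer propagates node features through the symmetrically
# normalized self-looped adjacency Ahat = D'^-1/2 (A + I) D'^-1/2 and a
# weight matrix: H_l = relu(Ahat H_{l-1} W_l); the final layer applies a
# row softmax and the sample's prediction is the center node's row.
#
# Training needs gradients and, for second-order meta-learning,
# Hessian-vector products. Both are written out by hand: reverse-mode
# backprop for the gradient, and forward-over-reverse dual-number
# propagation for exact HVPs (exact almost everywhere; the ReLU kink
# contributes no measure).
#
# For speed, all local graphs in a task are evaluated in one shot as a
# block-diagonal batch. Ego graphs overlap heavily, so the batch keeps a
# sparse expansion matrix P mapping the batch's unique pool nodes to
# batch rows: the expensive dense product X W is done once per unique
# node, then propagated sparsely.

#' GCN architecture configuration
#'
#' @param layer_dims Integer vector `input -> hidden(s) -> classes`; the
#'   default architecture elsewhere in the package is two layers
#'   (`c(d, 64, C)`).
#' @param activation Hidden activation; only `"relu"` is provided.
#' @param dropout Dropout rate in \[0, 1) applied to each layer input
#'   during training (0 disables; default).
#' @return A `gcn_config` object.
#' @export
gcn_config <- function(layer_dims, activation = "relu", dropout = 0) {
  stopifnot(length(layer_dims) >= 2, all(layer_dims >= 1),
            activation == "relu", dropout >= 0, dropout < 1)
  structure(list(layer_dims = as.integer(layer_dims),
                 activation = activation, dropout = dropout),
            class = "gcn_config")
}

#' Initialize GCN weights
#'
#' Glorot-uniform initialization, deterministic under the seed.
#'
#' @param config A [gcn_config()].
#' @param seed Integer seed.
#' @return List of weight matrices, one per layer.
#' @export
gcn_init_params <- function(config, seed = 1) {
  dims <- config$layer_dims
  withr::with_seed(seed, {
    lapply(seq_len(length(dims) - 1), function(l) {
      fan_in <- dims[l]; fan_out <- dims[l + 1]
      lim <- sqrt(6 / (fan_in + fan_out))
      matrix(runif(fan_in * fan_out, -lim, lim), fan_in, fan_out)
    })
  })
}

#' Symmetrically normalized self-looped adjacency
#'
#' Computes `D'^-1/2 (A + I) D'^-1/2` where `A` is the 0/1 adjacency of
#' a local graph (or any adjacency matrix) and `D'` the diagonal degree
#' matrix of `A + I`.
#'
#' @param x A `local_graph` or a square 0/1 adjacency matrix without
#'   self-loops.
#' @return Dense numeric matrix of the same size.
#' @export
normalize_adjacency <- function(x) {
  if (inherits(x, "local_graph")) {
    n <- length(x$nodes)
    A <- matrix(0, n, n)
    if (nrow(x$edges) > 0) {
      i <- match(x$edges[, 1], x$nodes)
      j <- match(x$edges[, 2], x$nodes)
      A[cbind(i, j)] <- 1
      A[cbind(j, i)] <- 1
    }
  } else {
    A <- as.matrix(x)
    stopifnot(nrow(A) == ncol(A))
  }
  Ap <- A + diag(nrow(A))
  dinv <- 1 / sqrt(rowSums(Ap))
  Ap * outer(dinv, dinv)
}

softmax_rows <- function(z) {
  z <- z - apply(z, 1, max)
  e <- exp(z)
  e / rowSums(e)
}

#' GCN forward pass on one local graph
#'
#' Runs the full layer stack on a single local graph and returns the
#' per-node class probabilities (every row sums to 1). The sample-level
#' prediction is row 1, the center node.
#'
#' @param local A `local_graph` from [extract_local_graphs()].
#' @param params Weight list from [gcn_init_params()].
#' @param config The matching [gcn_config()].
#' @return Numeric matrix, nodes x classes, rows summing to 1.
#' @export
gcn_forward <- function(local, params, config) {
  X <- local$features_pool[local$nodes, , drop = FALSE]
  if (ncol(X) != config$layer_dims[1]) {
    stop("feature dimension ", ncol(X), " does not match layer_dims[1] = ",
         config$layer_dims[1])
  }
  Ahat <- normalize_adjacency(local)
  H <- X
  L <- length(params)
  for (l in seq_len(L)) {
    Z <- Ahat %*% (H %*% params[[l]])
    H <- if (l < L) pmax(Z, 0) else softmax_rows(Z)
  }
  H
}

# ---- batched evaluation over many local graphs --------------------------

#' Assemble a batch of local graphs for training
#'
#' Builds the block-diagonal normalized adjacency over the given local
#' graphs, the sparse expansion matrix from the batch's unique pool
#' nodes to batch rows, the center-row extractor, and the center labels.
#'
#' @param locals List of `local_graph` objects.
#' @param class_levels Character vector fixing the label-to-index map.
#' @return A `gcn_batch` object (internal structure).
#' @export
build_task_batch <- function(locals, class_levels) {
  sizes <- vapply(locals, function(g) length(g$nodes), integer(1))
  offsets <- cumsum(c(0L, sizes[-length(sizes)]))
  R <- sum(sizes)
  rows_nodes <- unlist(lapply(locals, function(g) g$nodes), use.names = FALSE)
  uniq <- sort(unique(rows_nodes))
  P <- Matrix::sparseMatrix(i = seq_len(R), j = match(rows_nodes, uniq),
                            x = 1, dims = c(R, length(uniq)))
  trip_i <- vector("list", length(locals))
  trip_j <- vector("list", length(locals))
  trip_x <- vector("list", length(locals))
  for (t in seq_along(locals)) {
    g <- locals[[t]]
    n <- length(g$nodes)
    # normalized self-looped adjacency straight from the edge list:
    # entry (i, j) = 1 / sqrt(d'_i d'_j), d' = degree + 1
    ei <- match(g$edges[, 1], g$nodes)
    ej <- match(g$edges[, 2], g$nodes)
    dprime <- tabulate(c(ei, ej), nbins = n) + 1
    dinv <- 1 / sqrt(dprime)
    trip_i[[t]] <- c(seq_len(n), ei, ej) + offsets[t]
    trip_j[[t]] <- c(seq_len(n), ej, ei) + offsets[t]
    trip_x[[t]] <- c(1 / dprime, dinv[ei] * dinv[ej], dinv[ej] * dinv[ei])
  }
  A <- Matrix::sparseMatrix(i = unlist(trip_i), j = unlist(trip_j),
                            x = unlist(trip_x), dims = c(R, R))
  centers <- offsets + 1L
  y <- vapply(locals, function(g) g$label, character(1))
  yi <- match(y, class_levels)
  if (anyNA(yi)) stop("label(s) outside class_levels: ",
                      paste(unique(y[is.na(yi)]), collapse = ", "))
  structure(list(A = A, P = P, AP = A %*% P, nodes = uniq,
                 centers = centers, y = yi,
                 Ac = A[centers, , drop = FALSE],
                 n_graphs = length(locals),
                 class_levels = class_levels),
            class = "gcn_batch")
}

# forward pass over a batch; returns per-layer caches for backprop
gcn_batch_forward <- function(params, batch, X_pool) {
  Xu <- X_pool[batch$nodes, , drop = FALSE]
  L <- length(params)
  Z <- vector("list", L); H <- vector("list", L)
  Z[[1]] <- as.matrix(batch$AP %*% (Xu %*% params[[1]]))
  if (L == 1) {
    Zc <- Z[[1]][batch$centers, , drop = FALSE]
    return(list(Xu = Xu, Z = Z, H = H, Zc = Zc, probs = softmax_rows(Zc)))
  }
  H[[1]] <- pmax(Z[[1]], 0)
  if (L > 2) {
    for (l in 2:(L - 1)) {
      Z[[l]] <- as.matrix(batch$A %*% (H[[l - 1]] %*% params[[l]]))
      H[[l]] <- pmax(Z[[l]], 0)
    }
  }
  Zc <- as.matrix(batch$Ac %*% (H[[L - 1]] %*% params[[L]]))
  list(Xu = Xu, Z = Z, H = H, Zc = Zc, probs = softmax_rows(Zc))
}

# mean cross-entropy at the centers
gcn_batch_loss <- function(params, batch, X_pool) {
  fw <- gcn_batch_forward(params, batch, X_pool)
  p <- fw$probs[cbind(seq_len(nrow(fw$probs)), batch$y)]
  -mean(log(pmax(p, 1e-300)))
}

# loss and gradient (reverse mode); one-layer case folds into the L>=2 path
gcn_batch_grad <- function(params, batch, X_pool) {
  L <- length(params)
  fw <- gcn_batch_forward(params, batch, X_pool)
  nC <- nrow(fw$probs)
  Y <- matrix(0, nC, ncol(fw$probs)); Y[cbind(seq_len(nC), batch$y)] <- 1
  loss <- -mean(log(pmax(fw$probs[cbind(seq_len(nC), batch$y)], 1e-300)))
  dZc <- (fw$probs - Y) / nC
  grad <- vector("list", L)
  if (L == 1) {
    # Z1 = AP (Xu W1); centers rows only matter for the loss
    dZ1 <- matrix(0, nrow(fw$Z[[1]]), ncol(fw$Z[[1]]))
    dZ1[batch$centers, ] <- dZc
    grad[[1]] <- crossprod(fw$Xu, as.matrix(Matrix::crossprod(batch$AP, dZ1)))
    return(list(loss = loss, grad = grad))
  }
  U <- as.matrix(Matrix::crossprod(batch$Ac, dZc))
  grad[[L]] <- crossprod(fw$H[[L - 1]], U)
  dH <- U %*% t(params[[L]])
  if (L > 2) {
    for (l in (L - 1):2) {
      dZ <- dH * (fw$Z[[l]] > 0)
      V <- as.matrix(Matrix::crossprod(batch$A, dZ))
      grad[[l]] <- crossprod(fw$H[[l - 1]], V)
      dH <- V %*% t(params[[l]])
    }
  }
  dZ1 <- dH * (fw$Z[[1]] > 0)
  grad[[1]] <- crossprod(fw$Xu, as.matrix(Matrix::crossprod(batch$AP, dZ1)))
  list(loss = loss, grad = grad)
}

# exact Hessian-vector product via forward-over-reverse dual propagation:
# every primal quantity of the forward and backward pass carries a
# tangent; the tangent of the gradient is H %*% v
gcn_batch_hvp <- function(params, batch, X_pool, v) {
  L <- length(params)
  fw <- gcn_batch_forward(params, batch, X_pool)
  nC <- nrow(fw$probs)
  Y <- matrix(0, nC, ncol(fw$probs)); Y[cbind(seq_len(nC), batch$y)] <- 1

  # forward duals
  Zd <- vector("list", L); Hd <- vector("list", L)
  Zd[[1]] <- as.matrix(batch$AP %*% (fw$Xu %*% v[[1]]))
  if (L >= 2) {
    Hd[[1]] <- Zd[[1]] * (fw$Z[[1]] > 0)
    if (L > 2) {
      for (l in 2:(L - 1)) {
        Zd[[l]] <- as.matrix(batch$A %*% (Hd[[l - 1]] %*% params[[l]] +
                                            fw$H[[l - 1]] %*% v[[l]]))
        Hd[[l]] <- Zd[[l]] * (fw$Z[[l]] > 0)
      }
    }
    Zcd <- as.matrix(batch$Ac %*% (Hd[[L - 1]] %*% params[[L]] +
                                     fw$H[[L - 1]] %*% v[[L]]))
  } else {
    Zcd <- Zd[[1]][batch$centers, , drop = FALSE]
  }
  P <- fw$probs
  Pd <- P * (Zcd - rowSums(P * Zcd))

  # backward duals
  dZc <- (P - Y) / nC
  dZcd <- Pd / nC
  hv <- vector("list", L)
  if (L == 1) {
    dZ1d <- matrix(0, nrow(fw$Z[[1]]), ncol(fw$Z[[1]]))
    dZ1d[batch$centers, ] <- dZcd
    hv[[1]] <- crossprod(fw$Xu, as.matrix(Matrix::crossprod(batch$AP, dZ1d)))
    return(hv)
  }
  U <- as.matrix(Matrix::crossprod(batch$Ac, dZc))
  Ud <- as.matrix(Matrix::crossprod(batch$Ac, dZcd))
  hv[[L]] <- crossprod(Hd[[L - 1]], U) + crossprod(fw$H[[L - 1]], Ud)
  dH <- U %*% t(params[[L]])
  dHd <- Ud %*% t(params[[L]]) + U %*% t(v[[L]])
  if (L > 2) {
    for (l in (L - 1):2) {
      m <- (fw$Z[[l]] > 0)
      dZ <- dH * m; dZd <- dHd * m
      V <- as.matrix(Matrix::crossprod(batch$A, dZ))
      Vd <- as.matrix(Matrix::crossprod(batch$A, dZd))
      hv[[l]] <- crossprod(Hd[[l - 1]], V) + crossprod(fw$H[[l - 1]], Vd)
      dH <- V %*% t(params[[l]])
      dHd <- Vd %*% t(params[[l]]) + V %*% t(v[[l]])
    }
  }
  m1 <- (fw$Z[[1]] > 0)
  dZ1d <- dHd * m1
  hv[[1]] <- crossprod(fw$Xu, as.matrix(Matrix::crossprod(batch$AP, dZ1d)))
  hv
}

# class probabilities at the centers of a batch
gcn_batch_predict <- function(params, batch, X_pool) {
  gcn_batch_forward(params, batch, X_pool)$probs
}

# ---- parameter-list arithmetic ------------------------------------------

par_axpy <- function(x, a, y) mapply(function(xi, yi) xi + a * yi, x, y,
                                     SIMPLIFY = FALSE)
par_add <- function(x, y) mapply(`+`, x, y, SIMPLIFY = FALSE)
par_scale <- function(x, a) lapply(x, function(m) a * m)
par_zero <- function(x) lapply(x, function(m) m * 0)
par_finite <- function(x) all(vapply(x, function(m) all(is.finite(m)), logical(1)))
par_max_abs_diff <- function(x, y) {
  max(mapply(function(a, b) max(abs(a - b)), x, y))
}
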