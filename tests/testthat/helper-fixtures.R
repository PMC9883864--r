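# Shared fixtures and independent oracles, all built in code.

# independent k-mer oracle: explicit double loop over windows and words
naive_kmer_frequencies <- function(sequence, k) {
  s <- chartr("U", "T", toupper(sequence))
  L <- nchar(s)
  words <- metalncloc:::all_kmers(k)
  counts <- setNames(numeric(length(words)), words)
  for (i in seq_len(L - k + 1)) {
    w <- substr(s, i, i + k - 1)
    for (j in seq_along(words)) {
      if (words[j] == w) counts[j] <- counts[j] + 1
    }
  }
  counts / (L - k + 1)
}

random_dna <- function(n, seed = NULL) {
  draw <- function() paste(sample(c("A", "C", "G", "T"), n, replace = TRUE),
                           collapse = "")
  if (is.null(seed)) draw() else withr::with_seed(seed, draw())
}

# brute-force O(n^2) threshold-graph oracle built on the scalar cosine
brute_force_edges <- function(x, tau) {
  n <- nrow(x)
  out <- NULL
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      if (cosine_similarity(x[i, ], x[j, ]) >= tau) out <- rbind(out, c(i, j))
    }
  }
  if (is.null(out)) matrix(integer(0), ncol = 2) else out
}

# a random local graph over a fresh feature pool (not necessarily a star)
random_local_graph <- function(n_nodes, d, n_classes = 3, p_edge = 0.4) {
  pool <- matrix(rnorm(n_nodes * d), n_nodes, d)
  pairs <- which(upper.tri(matrix(0, n_nodes, n_nodes)), arr.ind = TRUE)
  keep <- runif(nrow(pairs)) < p_edge
  edges <- pairs[keep, , drop = FALSE]
  structure(list(center = 1L, nodes = seq_len(n_nodes),
                 edges = unname(edges), label = "c1",
                 features_pool = pool),
            class = "local_graph")
}

# Gaussian-blob pool of singleton local graphs: the GCN degenerates to
# softmax regression, which keeps learnability tests fast
make_blob_pool <- function(n_per_class = 30, n_classes = 3, d = 8,
                           blob_sep = 3, seed = 1) {
  withr::with_seed(seed, {
    centers <- matrix(rnorm(n_classes * d), n_classes, d) * blob_sep
    X <- do.call(rbind, lapply(seq_len(n_classes), function(c) {
      matrix(rnorm(n_per_class * d), n_per_class, d) +
        matrix(centers[c, ], n_per_class, d, byrow = TRUE)
    }))
  })
  labels <- rep(paste0("class", seq_len(n_classes)), each = n_per_class)
  locals <- lapply(seq_len(nrow(X)), function(i) {
    structure(list(center = i, nodes = i,
                   edges = matrix(integer(0), ncol = 2),
                   label = labels[i], features_pool = X),
              class = "local_graph")
  })
  list(locals = locals, X = X, labels = labels,
       class_levels = sort(unique(labels)))
}

# 2-parameter toy model with a non-constant Hessian, for meta-gradient
# checks: L(theta; a, b, t) = sum(a (theta-t)^2 / 2 + b (theta-t)^4 / 4)
toy_model <- function() {
  structure(list(
    init = function(seed = 1) list(matrix(c(0.3, -0.2), 2, 1)),
    loss = function(p, d) {
      r <- p[[1]] - d$t
      sum(d$a * r^2 / 2 + d$b * r^4 / 4)
    },
    grad = function(p, d) {
      r <- p[[1]] - d$t
      list(loss = sum(d$a * r^2 / 2 + d$b * r^4 / 4),
           grad = list(d$a * r + d$b * r^3))
    },
    hvp = function(p, d, v) {
      r <- p[[1]] - d$t
      list((d$a + 3 * d$b * r^2) * v[[1]])
    },
    predict = function(p, d) stop("toy model has no predictions"),
    class_levels = NULL
  ), class = "meta_model")
}

expect_params_equal <- function(a, b, tol = 1e-12) {
  expect_lt(metalncloc:::par_max_abs_diff(a, b), tol)
}
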