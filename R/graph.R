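# Sequence-similarity graph: nodes are transcripts, an undirected edge
# joins two nodes whenever the cosine similarity of their low-level
# feature vectors reaches the threshold tau. Each node's local (ego)
# graph is the per-sample unit handed to the classifier.

#' Cosine similarity of two vectors
#'
#' @param a,b Numeric vectors of equal length; neither may be all-zero.
#' @return `dot(a, b) / (||a|| ||b||)`; lies in \[0, 1\] for
#'   non-negative inputs.
#' @export
cosine_similarity <- function(a, b) {
  stopifnot(length(a) == length(b))
  na <- sqrt(sum(a^2)); nb <- sqrt(sum(b^2))
  if (na == 0 || nb == 0) stop("cosine similarity is undefined for a zero vector")
  sum(a * b) / (na * nb)
}

#' Build the thresholded cosine-similarity graph
#'
#' For every unordered node pair the cosine similarity of the designated
#' similarity features is computed; an edge is created iff the similarity
#' is greater than or equal to `tau` (ties create an edge). Isolated
#' nodes are permitted. Node features carried by the graph may differ
#' from the features used for similarity.
#'
#' @param features Numeric matrix of node features X (rows = nodes).
#' @param labels Compartment labels aligned to rows.
#' @param tau Similarity threshold in \[-1, 1\]; default 0.7.
#' @param similarity_features Matrix used for the similarity computation;
#'   defaults to `features`.
#' @param provenance Optional per-node real/synthetic flags.
#' @return A `similarity_graph` object: list with `n`, `ids`, `features`,
#'   `labels`, `provenance`, `tau`, `adjacency` (sparse symmetric 0/1,
#'   no self-loops) and `edges` (data.frame `i`, `j`, `similarity` with
#'   `i < j`).
#' @export
build_similarity_graph <- function(features, labels, tau = 0.7,
                                   similarity_features = features,
                                   provenance = NULL) {
  features <- as.matrix(features)
  sim <- as.matrix(similarity_features)
  n <- nrow(features)
  stopifnot(nrow(sim) == n, length(labels) == n)
  if (!(is.numeric(tau) && length(tau) == 1 && tau >= -1 && tau <= 1)) {
    stop("tau must lie in [-1, 1]")
  }
  norms <- sqrt(rowSums(sim^2))
  if (any(norms == 0)) {
    stop("similarity features of node ", which(norms == 0)[1],
         " are all zero; cosine similarity undefined")
  }
  S <- tcrossprod(sim / norms)
  up <- upper.tri(S)
  hit <- which(up & S >= tau, arr.ind = TRUE)
  edges <- data.frame(i = hit[, 1], j = hit[, 2],
                      similarity = S[hit])
  edges <- edges[order(edges$i, edges$j), , drop = FALSE]
  rownames(edges) <- NULL
  adj <- Matrix::sparseMatrix(i = c(edges$i, edges$j),
                              j = c(edges$j, edges$i),
                              x = 1, dims = c(n, n))
  ids <- rownames(features)
  if (is.null(ids)) ids <- as.character(seq_len(n))
  structure(list(n = n, ids = ids, features = features,
                 labels = as.character(labels),
                 provenance = if (is.null(provenance)) rep("real", n) else provenance,
                 tau = tau, adjacency = adj, edges = edges),
            class = "similarity_graph")
}

#' @export
print.similarity_graph <- function(x, ...) {
  st <- graph_stats(x)
  cat("similarity_graph:", x$n, "nodes,", st$edge_count,
      "edges (tau =", x$tau, "),", st$isolated_count, "isolated\n")
  invisible(x)
}

#' Summary statistics of a similarity graph
#'
#' "Key edges" are edges whose two endpoints carry the same compartment
#' label — the edges a label-propagating classifier can exploit; their
#' fraction rises with tau as weak cross-class similarities are pruned.
#'
#' @param g A `similarity_graph`.
#' @return List with `isolated_count` (degree-0 nodes), `edge_count`, and
#'   `key_edge_fraction` (NA when the graph has no edges).
#' @export
graph_stats <- function(g) {
  stopifnot(inherits(g, "similarity_graph"))
  deg <- Matrix::rowSums(g$adjacency)
  key <- if (nrow(g$edges) > 0) {
    mean(g$labels[g$edges$i] == g$labels[g$edges$j])
  } else NA_real_
  list(isolated_count = sum(deg == 0),
       edge_count = nrow(g$edges),
       key_edge_fraction = key)
}

#' Extract one local (ego) graph per node
#'
#' With `layers = 1` a node's local graph contains the node, its direct
#' neighbors, and the center's incident edges (a star). With `layers = 2`
#' it additionally contains the neighbors' neighbors and the edges
#' connecting first-layer members to any member. The center is always
#' the first node. Node features are shared by reference with the parent
#' graph's feature matrix (no per-graph copy).
#'
#' @param g A `similarity_graph`.
#' @param layers 1 (default) or 2 neighbor layers.
#' @return List of `local_graph` objects, one per node and in node
#'   order, each with `center` (index into the parent graph), `nodes`
#'   (center first), `edges` (m x 2 matrix of parent indices), `label`,
#'   and `features_pool` (the parent feature matrix).
#' @export
extract_local_graphs <- function(g, layers = 1) {
  stopifnot(inherits(g, "similarity_graph"), layers %in% c(1, 2))
  ends <- factor(c(g$edges$i, g$edges$j), levels = seq_len(g$n))
  nbrs <- split(c(g$edges$j, g$edges$i), ends)
  nbrs <- lapply(nbrs, sort)
  lapply(seq_len(g$n), function(i) {
    n1 <- nbrs[[i]]
    if (layers == 1) {
      nodes <- c(i, n1)
      edges <- if (length(n1) > 0) cbind(i, n1) else
        matrix(integer(0), ncol = 2)
    } else {
      n2 <- unique(unlist(nbrs[n1]))
      nodes <- unique(c(i, n1, n2))
      inner <- c(i, n1)  # edges must touch the center or a first-layer node
      e <- do.call(rbind, lapply(inner, function(v) {
        w <- nbrs[[v]]
        w <- w[w %in% nodes]
        if (length(w) > 0) cbind(v, w) else NULL
      }))
      if (is.null(e)) e <- matrix(integer(0), ncol = 2)
      # canonical undirected form, deduplicated
      e <- unique(cbind(pmin(e[, 1], e[, 2]), pmax(e[, 1], e[, 2])))
      edges <- e
    }
    structure(list(center = i, nodes = nodes, edges = edges,
                   label = g$labels[i], features_pool = g$features),
              class = "local_graph")
  })
}

#' Write the edge list of a similarity graph as TSV
#'
#' @param g A `similarity_graph`.
#' @param path Output TSV path (columns node_i, node_j, similarity).
#' @return `path`, invisibly.
#' @export
write_edge_list <- function(g, path) {
  df <- data.frame(node_i = g$ids[g$edges$i], node_j = g$ids[g$edges$j],
                   similarity = g$edges$similarity)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
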