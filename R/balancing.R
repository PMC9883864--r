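# SMOTE oversampling in feature space: every minority compartment is
# filled up to the majority-class count with points interpolated between
# a class member and one of its same-class nearest neighbors.

#' Class label distribution
#'
#' @param labels Character vector of compartment names.
#' @return Named integer vector of counts, decreasing.
#' @export
class_distribution <- function(labels) {
  if (length(labels) == 0) return(setNames(integer(), character()))
  tab <- table(labels)
  counts <- sort(as.integer(tab), decreasing = TRUE)
  # stable ordering: by count desc, ties by name
  ord <- order(-as.integer(tab), names(tab))
  setNames(as.integer(tab)[ord], names(tab)[ord])
}

#' SMOTE configuration
#'
#' @param neighbor_count Nearest-neighbor pool size for `mode =
#'   "standard"` (classic SMOTE, default 5). Capped per class at class
#'   size minus one.
#' @param seed Integer seed; all draws (centers, neighbors,
#'   interpolation positions) are deterministic given the seed.
#' @param mode `"standard"` (classic SMOTE: each synthetic point picks a
#'   random class member as center and one of its `neighbor_count`
#'   nearest same-class neighbors) or `"paper"` (one random center per
#'   round donates deficit-many nearest neighbors, one synthetic per
#'   neighbor, iterating until the class is full — a literal reproduction
#'   of the published procedure, kept as an opt-in variant).
#' @return A `smote_config` object.
#' @export
smote_config <- function(neighbor_count = 5, seed = 1,
                         mode = c("standard", "paper")) {
  mode <- match.arg(mode)
  stopifnot(is.numeric(neighbor_count), neighbor_count >= 1,
            neighbor_count == round(neighbor_count))
  structure(list(neighbor_count = as.integer(neighbor_count),
                 seed = as.integer(seed), mode = mode),
            class = "smote_config")
}

#' Balance classes by SMOTE oversampling
#'
#' Brings every class up to the majority-class count. Original samples
#' are returned unchanged (flagged `real`), followed by the synthetic
#' samples (flagged `synthetic`); each synthetic point is the convex
#' combination `x_c + u * (x_n - x_c)`, `u ~ Uniform(0, 1)`, of a
#' minority-class center `x_c` and a same-class nearest neighbor `x_n`
#' under the Euclidean metric. Parentage (center row, neighbor row, `u`)
#' is recorded for every synthetic point.
#'
#' @param x Numeric feature matrix, rows = samples.
#' @param labels Compartment labels aligned to rows of `x`.
#' @param config A [smote_config()].
#' @return List with `features` (originals then synthetics), `labels`,
#'   `provenance` (`"real"`/`"synthetic"`), and `parents` (data.frame
#'   `center`, `neighbor`, `u` with row indices into `features`, one row
#'   per synthetic point).
#' @export
smote_balance <- function(x, labels, config = smote_config()) {
  x <- as.matrix(x)
  stopifnot(nrow(x) == length(labels))
  labels <- as.character(labels)
  counts <- table(labels)
  target <- max(counts)
  need <- target - counts
  for (cl in names(counts)) {
    if (need[[cl]] > 0 && counts[[cl]] < 2) {
      stop("class '", cl, "' has fewer than 2 samples; ",
           "no line segment exists for SMOTE interpolation")
    }
  }
  syn_feats <- list()
  syn_labels <- character()
  parents <- list()
  withr::with_seed(config$seed, {
    for (cl in sort(names(counts))) {
      deficit <- need[[cl]]
      if (deficit == 0) next
      idx <- which(labels == cl)
      xc <- x[idx, , drop = FALSE]
      D <- as.matrix(dist(xc))
      diag(D) <- Inf
      if (config$mode == "standard") {
        k <- min(config$neighbor_count, length(idx) - 1)
        nn <- t(apply(D, 1, function(d) order(d)[seq_len(k)]))
        centers <- sample.int(length(idx), deficit, replace = TRUE)
        picks <- vapply(centers, function(ci) {
          nn[ci, sample.int(k, 1)]
        }, integer(1))
        u <- runif(deficit)
        s <- xc[centers, , drop = FALSE] +
          u * (xc[picks, , drop = FALSE] - xc[centers, , drop = FALSE])
        syn_feats[[cl]] <- s
        syn_labels <- c(syn_labels, rep(cl, deficit))
        parents[[cl]] <- data.frame(center = idx[centers],
                                    neighbor = idx[picks], u = u)
      } else {
        # literal published procedure: one random center per round hands
        # out its deficit-many nearest neighbors, one synthetic each
        rows <- list(); ctr <- integer(); nbr <- integer(); uu <- numeric()
        left <- deficit
        while (left > 0) {
          ci <- sample.int(length(idx), 1)
          d <- min(left, length(idx) - 1)
          nns <- order(D[ci, ])[seq_len(d)]
          u <- runif(d)
          s <- matrix(xc[ci, ], nrow = d, ncol = ncol(x), byrow = TRUE)
          s <- s + u * (xc[nns, , drop = FALSE] - s)
          rows[[length(rows) + 1]] <- s
          ctr <- c(ctr, rep(idx[ci], d)); nbr <- c(nbr, idx[nns])
          uu <- c(uu, u)
          left <- left - d
        }
        syn_feats[[cl]] <- do.call(rbind, rows)
        syn_labels <- c(syn_labels, rep(cl, deficit))
        parents[[cl]] <- data.frame(center = ctr, neighbor = nbr, u = uu)
      }
    }
  })
  syn <- if (length(syn_feats) > 0) do.call(rbind, syn_feats) else
    matrix(numeric(0), nrow = 0, ncol = ncol(x))
  par_df <- if (length(parents) > 0) do.call(rbind, parents) else
    data.frame(center = integer(), neighbor = integer(), u = numeric())
  rownames(par_df) <- NULL
  n_syn <- nrow(syn)
  ids <- rownames(x)
  if (!is.null(ids) && n_syn > 0) {
    rownames(syn) <- sprintf("synthetic_%04d", seq_len(n_syn))
  }
  out_x <- rbind(x, syn)
  list(features = out_x,
       labels = c(labels, syn_labels),
       provenance = c(rep("real", nrow(x)), rep("synthetic", n_syn)),
       parents = par_df)
}
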