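# Low-level sequence feature extraction: k-mer frequencies,
# reverse-complement-collapsed k-mers, pseudo dinucleotide composition
# (PseDNC), and optional PCA reduction.

#' Feature extraction configuration
#'
#' @param method One of `"kmer"`, `"revkmer"`, `"psednc"`.
#' @param k Substring length for kmer/revkmer, in 1..7. The default 7
#'   gives the strongest classifier in the accompanying benchmarks; use
#'   3-5 for fast experimentation (the 7-mer vector has 16384 entries).
#' @param lambda Number of PseDNC sequence-order correlation factors
#'   (default 150); requires sequences of length at least `lambda + 2`.
#' @param weight PseDNC weight omega in (0, 1] (default 0.3) balancing
#'   dinucleotide composition against the correlation factors.
#' @param pca_dims Optional positive integer: project feature vectors
#'   onto this many principal components. `NULL` (default) disables PCA,
#'   which in practice preserves accuracy.
#' @return A `feature_config` object.
#' @export
feature_config <- function(method = c("kmer", "revkmer", "psednc"),
                           k = 7, lambda = 150, weight = 0.3,
                           pca_dims = NULL) {
  method <- match.arg(method)
  if (!(is.numeric(k) && length(k) == 1 && k >= 1 && k <= 7 && k == round(k)))
    stop("k must be an integer in [1, 7]")
  if (!(is.numeric(lambda) && lambda >= 0 && lambda == round(lambda)))
    stop("lambda must be a non-negative integer")
  if (!(is.numeric(weight) && weight > 0 && weight <= 1) &&
      !(method == "psednc" && weight == 0))
    stop("weight must lie in (0, 1]")
  if (!is.null(pca_dims) &&
      !(is.numeric(pca_dims) && pca_dims >= 1 && pca_dims == round(pca_dims)))
    stop("pca_dims must be a positive integer or NULL")
  structure(list(method = method, k = as.integer(k),
                 lambda = as.integer(lambda), weight = weight,
                 pca_dims = pca_dims),
            class = "feature_config")
}

# U -> T so RNA and DNA spellings hash to the same k-mers; errors on any
# residual ambiguity code (filtering should already have removed them).
canonicalize_sequence <- function(sequence, id = NULL) {
  s <- chartr("U", "T", toupper(sequence))
  bad <- grepl("[^ACGT]", s)
  if (any(bad)) {
    who <- if (is.null(id)) paste0("sequence ", which(bad)[1]) else
      paste0("sequence '", id[which(bad)[1]], "'")
    stop(who, " contains non-ACGT characters after U->T canonicalization; ",
         "apply filter_records() first")
  }
  s
}

# all 4^k k-mers in lexicographic order (A < C < G < T)
all_kmers <- function(k) {
  if (k == 0) return("")
  grid <- expand.grid(rep(list(.NUC), k), stringsAsFactors = FALSE)[, k:1, drop = FALSE]
  out <- do.call(paste0, grid)
  sort(out)
}

#' k-mer frequency vector of one sequence
#'
#' Counts every length-`k` window of the sequence and divides by the
#' window count `L - k + 1`, giving a composition vector on the simplex
#' (length-invariant, which keeps cosine similarity comparable across
#' transcripts of different lengths). Entries are indexed by the `4^k`
#' k-mers in lexicographic order (A < C < G < T).
#'
#' @param sequence A single sequence string (U or T spelling).
#' @param k Window length, >= 1; the sequence must be at least `k` long.
#' @return Named numeric vector of length `4^k` summing to 1.
#' @examples
#' kmer_frequencies("ACGT", 1)
#' @export
kmer_frequencies <- function(sequence, k) {
  s <- canonicalize_sequence(sequence)
  if (nchar(s) < k) {
    stop("sequence of length ", nchar(s), " is shorter than k = ", k)
  }
  counts <- Biostrings::oligonucleotideFrequency(Biostrings::DNAString(s),
                                                 width = k)
  counts / (nchar(s) - k + 1)
}

#' Reverse-complement equivalence classes of k-mers
#'
#' Each class pools a k-mer with its reverse complement and is keyed by
#' the lexicographically smaller member (palindromic k-mers form
#' singleton classes).
#'
#' @param k Word length.
#' @return Character vector of sorted class keys.
#' @export
revkmer_classes <- function(k) {
  km <- all_kmers(k)
  rc <- as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(km)))
  sort(unique(pmin(km, rc)))
}

#' Reverse-complement-collapsed k-mer frequencies
#'
#' k-mer frequencies with each reverse-complement pair pooled into one
#' entry, so a sequence and its reverse complement map to the same
#' vector.
#'
#' @inheritParams kmer_frequencies
#' @return Named numeric vector over the reverse-complement classes of
#'   [revkmer_classes()], summing to 1.
#' @export
revkmer_frequencies <- function(sequence, k) {
  f <- kmer_frequencies(sequence, k)
  km <- names(f)
  rc <- as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(km)))
  key <- pmin(km, rc)
  out <- tapply(f, key, sum)
  out <- out[sort(names(out))]
  setNames(as.numeric(out), names(out))
}

# 16 x 6 standardized dinucleotide physicochemical property matrix
# (helical step parameters: twist, tilt, roll, shift, slide, rise).
# Columns are re-standardized to zero mean / unit variance across the 16
# dinucleotides, as the PseDNC correlation function expects.
dinucleotide_properties <- function() {
  path <- system.file("extdata", "dinucleotide_properties.tsv",
                      package = "metalncloc", mustWork = TRUE)
  tab <- read.delim(path, header = TRUE, stringsAsFactors = FALSE)
  m <- as.matrix(tab[, -1])
  rownames(m) <- tab[[1]]
  scale(m)[, , drop = FALSE]
}

#' Pseudo dinucleotide composition (PseDNC)
#'
#' The 16 normalized dinucleotide frequencies followed by `lambda`
#' sequence-order correlation factors. Factor j averages, over all
#' dinucleotide pairs j steps apart, the mean squared difference of six
#' standardized physicochemical properties (helical step parameters);
#' factors enter the final vector with weight `weight` so that the whole
#' vector sums to 1.
#'
#' @inheritParams kmer_frequencies
#' @param lambda Number of correlation tiers; the sequence must be at
#'   least `lambda + 2` long.
#' @param weight Weight omega of the correlation factors, in \[0, 1\].
#' @return Named numeric vector of length `16 + lambda` summing to 1.
#' @export
psednc_features <- function(sequence, lambda = 150, weight = 0.3) {
  s <- canonicalize_sequence(sequence)
  L <- nchar(s)
  if (L < lambda + 2) {
    stop("sequence of length ", L, " is too short for lambda = ", lambda,
         " (needs length >= lambda + 2)")
  }
  props <- dinucleotide_properties()
  di <- substring(s, 1:(L - 1), 2:L)
  f <- tabulate(match(di, rownames(props)), nbins = 16)
  f <- f / sum(f)
  names(f) <- rownames(props)
  P <- props[di, , drop = FALSE]  # (L-1) x 6 property profile
  theta <- numeric(lambda)
  if (lambda > 0) {
    for (j in seq_len(lambda)) {
      n <- L - 1 - j
      d <- P[seq_len(n), , drop = FALSE] - P[j + seq_len(n), , drop = FALSE]
      theta[j] <- mean(rowMeans(d^2))
    }
  }
  denom <- 1 + weight * sum(theta)
  out <- c(f, weight * theta) / denom
  names(out) <- c(rownames(props),
                  if (lambda > 0) paste0("theta", seq_len(lambda)))
  out
}

#' PCA projection of a feature matrix
#'
#' Fits a principal-component projection on a designated subset of rows
#' (all rows by default) and applies it to every row. Centering uses the
#' fitting subset's mean; features are not rescaled.
#'
#' @param x Numeric matrix, rows = samples.
#' @param target_dims Number of components to keep; must not exceed the
#'   original dimension or the fitting-subset size.
#' @param fit_idx Row indices used to fit the projection (default: all).
#' @return Matrix with `target_dims` columns, same rownames as `x`.
#' @export
pca_reduce <- function(x, target_dims, fit_idx = NULL) {
  x <- as.matrix(x)
  if (is.null(fit_idx)) fit_idx <- seq_len(nrow(x))
  if (target_dims > ncol(x) || target_dims > length(fit_idx)) {
    stop("target_dims = ", target_dims, " exceeds the original dimension (",
         ncol(x), ") or the fitting subset size (", length(fit_idx), ")")
  }
  pc <- prcomp(x[fit_idx, , drop = FALSE], center = TRUE, scale. = FALSE,
               rank. = target_dims)
  out <- sweep(x, 2, pc$center) %*% pc$rotation
  rownames(out) <- rownames(x)
  out
}

#' Featurize a set of sequence records
#'
#' Applies the configured feature method to every record, returning one
#' feature matrix row per record in input order. All rows share one
#' dimension; any per-sequence failure aborts with the offending id.
#'
#' @param records Sequence records data.frame (see [read_fasta()]).
#' @param config A [feature_config()].
#' @return Numeric matrix, rows named by record id, with attribute
#'   `method_tag` describing the featurization.
#' @export
featurize_dataset <- function(records, config = feature_config()) {
  n <- nrow(records)
  tag <- switch(config$method,
                kmer = paste0("kmer(k=", config$k, ")"),
                revkmer = paste0("revkmer(k=", config$k, ")"),
                psednc = paste0("psednc(lambda=", config$lambda,
                                ",omega=", config$weight, ")"))
  if (n == 0) {
    d <- switch(config$method,
                kmer = 4^config$k,
                revkmer = length(revkmer_classes(config$k)),
                psednc = 16 + config$lambda)
    out <- matrix(numeric(0), nrow = 0, ncol = d)
    attr(out, "method_tag") <- tag
    return(out)
  }
  seqs <- canonicalize_sequence(records$sequence, id = records$id)
  if (config$method %in% c("kmer", "revkmer")) {
    short <- nchar(seqs) < config$k
    if (any(short)) {
      stop("sequence '", records$id[which(short)[1]],
           "' is shorter than k = ", config$k)
    }
    set <- Biostrings::DNAStringSet(seqs)
    counts <- Biostrings::oligonucleotideFrequency(set, width = config$k)
    out <- counts / (nchar(seqs) - config$k + 1)
    if (config$method == "revkmer") {
      km <- colnames(out)
      rc <- as.character(Biostrings::reverseComplement(
        Biostrings::DNAStringSet(km)))
      key <- pmin(km, rc)
      classes <- sort(unique(key))
      pooled <- matrix(0, nrow = n, ncol = length(classes),
                       dimnames = list(NULL, classes))
      for (cl in classes) {
        pooled[, cl] <- rowSums(out[, key == cl, drop = FALSE])
      }
      out <- pooled
    }
  } else {
    short <- nchar(seqs) < config$lambda + 2
    if (any(short)) {
      stop("sequence '", records$id[which(short)[1]],
           "' is too short for lambda = ", config$lambda)
    }
    rows <- lapply(seqs, psednc_features, lambda = config$lambda,
                   weight = config$weight)
    out <- do.call(rbind, rows)
  }
  rownames(out) <- records$id
  if (!is.null(config$pca_dims)) {
    out <- pca_reduce(out, config$pca_dims)
    tag <- paste0(tag, "+pca(", config$pca_dims, ")")
  }
  attr(out, "method_tag") <- tag
  out
}

#' Write a feature matrix as TSV
#'
#' @param x Feature matrix with rownames (sequence ids).
#' @param path Output path; rows are sequences, columns feature names.
#' @param provenance Optional character vector (real/synthetic) appended
#'   as a final column.
#' @return `path`, invisibly.
#' @export
write_feature_matrix <- function(x, path, provenance = NULL) {
  df <- data.frame(id = rownames(x), as.data.frame(x),
                   check.names = FALSE)
  if (!is.null(provenance)) df$provenance <- provenance
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
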