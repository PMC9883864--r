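# Reading, validating and filtering sequence records and label tables.
#
# Records are plain data.frames with columns id, sequence, label,
# provenance ("real" for anything read from disk, "synthetic" for
# generator/SMOTE output), one row per transcript, in input order.

#' Construct a sequence records table
#'
#' The in-memory representation used throughout the package: a plain
#' data.frame with one row per transcript and columns `id`, `sequence`
#' (uppercased), `label` and `provenance`.
#'
#' @param id,sequence Character vectors of equal length.
#' @param label Compartment names (recycled; default NA).
#' @param provenance `"real"` or `"synthetic"` (recycled).
#' @return A sequence records data.frame.
#' @export
new_sequence_records <- function(id, sequence, label = NA_character_,
                                 provenance = "real") {
  stopifnot(length(id) == length(sequence))
  data.frame(id = as.character(id),
             sequence = toupper(as.character(sequence)),
             label = rep_len(as.character(label), length(id)),
             provenance = rep_len(provenance, length(id)),
             stringsAsFactors = FALSE)
}

#' Read sequences from a FASTA file
#'
#' Parses a (multi-)FASTA file of RNA or DNA sequences. Sequences are
#' uppercased; both U and T spellings are accepted and preserved (the
#' feature extractors canonicalize U to T). Record ids are the FASTA
#' header up to the first whitespace.
#'
#' @param path Path to a FASTA file.
#' @return A data.frame of sequence records with columns `id`,
#'   `sequence`, `label` (NA; see [read_labels()]) and `provenance`
#'   (always `"real"` for file input), in file order.
#' @examples
#' fa <- tempfile(fileext = ".fa")
#' writeLines(c(">a", "ACGU", ">b", "acgt"), fa)
#' read_fasta(fa)$sequence
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stop("FASTA file not found: ", path)
  set <- tryCatch(Biostrings::readBStringSet(path),
                  error = function(e) {
                    stop("malformed FASTA '", path, "': ",
                         conditionMessage(e), call. = FALSE)
                  })
  if (length(set) == 0) return(new_sequence_records(character(), character()))
  ids <- sub("\\s.*$", "", names(set))
  widths <- Biostrings::width(set)
  if (any(widths == 0)) {
    stop("malformed FASTA: entry '", ids[which(widths == 0)[1]],
         "' has a header but no sequence")
  }
  seqs <- toupper(as.character(set))
  letters_used <- unique(strsplit(paste(seqs, collapse = ""), "")[[1]])
  illegal <- setdiff(letters_used, .IUPAC)
  if (length(illegal) > 0) {
    bad <- grepl(paste0("[", paste(illegal, collapse = ""), "]"), seqs)
    stop("malformed FASTA: entry '", ids[which(bad)[1]],
         "' contains non-IUPAC character(s): ",
         paste(illegal, collapse = ", "))
  }
  new_sequence_records(ids, seqs)
}

#' Read an id-to-compartment label table
#'
#' Reads a headerless two-column tab-separated table mapping sequence ids
#' to subcellular compartment names.
#'
#' @param path Path to a TSV file with columns (id, compartment).
#' @return A named character vector: `names()` are sequence ids, values
#'   are compartment names.
#' @export
read_labels <- function(path) {
  if (!file.exists(path)) stop("label table not found: ", path)
  if (file.size(path) == 0) return(setNames(character(), character()))
  tab <- read.delim(path, header = FALSE, sep = "\t",
                    colClasses = "character", quote = "",
                    comment.char = "")
  if (ncol(tab) < 2) {
    stop("label table '", path, "' must have two columns (id, compartment), found ",
         ncol(tab))
  }
  ids <- tab[[1]]
  if (anyDuplicated(ids)) {
    stop("duplicate sequence id(s) in label table: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  }
  setNames(tab[[2]], ids)
}

#' Attach compartment labels to sequence records
#'
#' @param records Sequence records from [read_fasta()] or the generator.
#' @param labels Named character vector from [read_labels()].
#' @param require_all Error if any record lacks a label (default TRUE).
#' @return The records with the `label` column filled in.
#' @export
attach_labels <- function(records, labels, require_all = TRUE) {
  hit <- match(records$id, names(labels))
  if (require_all && anyNA(hit)) {
    stop("no label for sequence id(s): ",
         paste(head(records$id[is.na(hit)], 5), collapse = ", "))
  }
  records$label <- unname(labels[hit])
  records
}

#' Construct a sequence filtering policy
#'
#' A record is removed when its sequence contains any forbidden symbol or
#' exceeds `max_length`. The default forbidden set (N, R, S, Y) drops
#' sequences carrying the ambiguity codes commonly present in lncRNA
#' compartment benchmarks; extreme-length outliers can be cut with a
#' finite `max_length` (unbounded by default).
#'
#' @param forbidden_symbols Character vector of single letters; must be
#'   disjoint from the unambiguous alphabet A, C, G, T, U.
#' @param max_length Positive number or `Inf`.
#' @return A `filter_policy` object.
#' @export
filter_policy <- function(forbidden_symbols = c("N", "R", "S", "Y"),
                          max_length = Inf) {
  forbidden_symbols <- toupper(as.character(forbidden_symbols))
  clash <- intersect(forbidden_symbols, c("A", "C", "G", "T", "U"))
  if (length(clash) > 0) {
    stop("forbidden_symbols may not include unambiguous nucleotides: ",
         paste(clash, collapse = ", "))
  }
  if (!(is.numeric(max_length) && length(max_length) == 1 && max_length > 0)) {
    stop("max_length must be a positive number or Inf")
  }
  structure(list(forbidden_symbols = forbidden_symbols,
                 max_length = max_length),
            class = "filter_policy")
}

#' Filter sequence records by symbol content and length
#'
#' Partitions the input into kept and removed records. A record is
#' removed iff its sequence contains a forbidden symbol or is longer than
#' the policy's `max_length`; both partitions preserve input order and
#' together account for every input record exactly once.
#'
#' @param records Sequence records data.frame.
#' @param policy A [filter_policy()].
#' @return A list with `kept` (records data.frame) and `removed` (records
#'   data.frame with an extra `reason` column).
#' @export
filter_records <- function(records, policy = filter_policy()) {
  stopifnot(inherits(policy, "filter_policy"))
  n <- nrow(records)
  reason <- rep(NA_character_, n)
  if (n > 0) {
    for (sym in policy$forbidden_symbols) {
      hit <- is.na(reason) & grepl(sym, records$sequence, fixed = TRUE)
      reason[hit] <- paste0("forbidden symbol ", sym)
    }
    if (is.finite(policy$max_length)) {
      len <- nchar(records$sequence)
      hit <- is.na(reason) & len > policy$max_length
      reason[hit] <- paste0("length ", len[hit], " exceeds max_length ",
                            policy$max_length)
    }
  }
  removed <- records[!is.na(reason), , drop = FALSE]
  if (nrow(removed) > 0) removed$reason <- reason[!is.na(reason)]
  else removed$reason <- character(0)
  kept <- records[is.na(reason), , drop = FALSE]
  rownames(kept) <- NULL
  rownames(removed) <- NULL
  list(kept = kept, removed = removed)
}

#' Write the removal report of a filtering run
#'
#' @param removed The `removed` component of [filter_records()].
#' @param path Output TSV path (columns id, reason).
#' @return `path`, invisibly.
#' @export
write_removal_report <- function(removed, path) {
  write.table(removed[, c("id", "reason")], path, sep = "\t",
              quote = FALSE, row.names = FALSE, col.names = TRUE)
  invisible(path)
}

#' Write sequence records as FASTA plus a label TSV
#'
#' @param records Sequence records with labels.
#' @param fasta Output FASTA path.
#' @param labels_tsv Optional output path for the headerless (id, label)
#'   TSV; skipped if `NULL`.
#' @return `fasta`, invisibly.
#' @export
write_fasta <- function(records, fasta, labels_tsv = NULL) {
  set <- Biostrings::BStringSet(records$sequence)
  names(set) <- records$id
  Biostrings::writeXStringSet(set, fasta)
  if (!is.null(labels_tsv)) {
    write.table(data.frame(records$id, records$label), labels_tsv,
                sep = "\t", quote = FALSE, row.names = FALSE,
                col.names = FALSE)
  }
  invisible(fasta)
}
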