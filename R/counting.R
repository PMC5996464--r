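# FASTA ingestion and the L-mer occurrence table (the algorithm's
# hashtable): every L-mer present in the positive set, with occurrence
# counts and sequence-presence sets in both datasets.

#' Read a multi-FASTA file into a sequence set
#'
#' Loads DNA sequences with [Biostrings::readDNAStringSet()], uppercases
#' them and preserves record order and identifiers. Ambiguous characters
#' are retained; windows containing them are skipped later during L-mer
#' extraction.
#'
#' @param path Path to a FASTA file.
#' @return A `sequence_set`: list with elements `id` (record identifiers)
#'   and `seq` (uppercase sequence strings).
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) {
    stop("FASTA file not found: ", path, call. = FALSE)
  }
  x <- tryCatch(
    Biostrings::readDNAStringSet(path),
    error = function(e) stop("malformed FASTA (", path, "): ",
                             conditionMessage(e), call. = FALSE)
  )
  if (length(x) == 0) {
    warning("FASTA file contains no records: ", path, call. = FALSE)
  }
  sequence_set(toupper(as.character(x)), ids = names(x))
}

#' Construct a sequence set from character vectors
#'
#' @param seqs Character vector of DNA sequences.
#' @param ids Optional record identifiers (defaults to `seq_1`, `seq_2`, ...).
#' @return A `sequence_set` object.
#' @export
sequence_set <- function(seqs, ids = NULL) {
  seqs <- toupper(as.character(seqs))
  if (is.null(ids)) ids <- paste0("seq_", seq_along(seqs))
  structure(list(id = as.character(ids), seq = unname(seqs)),
            class = "sequence_set")
}

#' @export
print.sequence_set <- function(x, ...) {
  cat("sequence_set with", length(x$seq), "sequences\n")
  n <- min(3L, length(x$seq))
  for (i in seq_len(n)) {
    s <- x$seq[i]
    cat(" ", x$id[i], ": ",
        if (nchar(s) > 50) paste0(substr(s, 1, 50), "...") else s,
        " (", nchar(s), " bp)\n", sep = "")
  }
  if (length(x$seq) > n) cat("  ...\n")
  invisible(x)
}

.as_sequence_set <- function(x) {
  if (inherits(x, "sequence_set")) return(x)
  if (is.character(x) && length(x) == 1 && file.exists(x)) return(read_fasta(x))
  if (is.character(x)) return(sequence_set(x))
  stop("expected a sequence_set, a character vector or a FASTA path",
       call. = FALSE)
}

# Resolve the fixed-position anchor to a 0-based window start per sequence:
# -1 = scanning, -2 = sequence skipped (no valid anchored window).
.resolve_offsets <- function(seqs, L, mode, anchor) {
  len <- nchar(seqs$seq)
  if (mode == "scanning") return(rep.int(-1L, length(len)))
  if (identical(anchor, "start")) {
    off <- rep.int(0L, length(len))
  } else if (identical(anchor, "end")) {
    off <- len - L
  } else if (is.numeric(anchor) && length(anchor) == 1 && anchor >= 0) {
    off <- rep.int(as.integer(anchor), length(len))
  } else {
    stop("anchor must be \"start\", \"end\" or a 0-based offset", call. = FALSE)
  }
  off[off < 0 | off + L > len] <- -2L
  as.integer(off)
}

#' Extract L-mer windows from a sequence set
#'
#' In scanning mode every window of length `L` is emitted, one base at a
#' time; in fixed-position mode exactly one window per sequence is emitted
#' at the anchored offset. Windows containing any character outside
#' A,C,G,T are skipped entirely.
#'
#' @param seqs A `sequence_set` (or character vector / FASTA path).
#' @param L Window length.
#' @param mode `"scanning"` or `"fixed"`.
#' @param anchor Fixed-mode anchor: `"start"`, `"end"` (default) or an
#'   explicit 0-based offset.
#' @return A data frame with columns `seq_index` (1-based) and `lmer`, in
#'   emission order.
#' @examples
#' extract_lmers(sequence_set("ACGTA"), 4)
#' @export
extract_lmers <- function(seqs, L, mode = c("scanning", "fixed"),
                          anchor = "end") {
  seqs <- .as_sequence_set(seqs)
  mode <- match.arg(mode)
  stopifnot(L >= 1)
  off <- .resolve_offsets(seqs, L, mode, anchor)
  out <- lapply(seq_along(seqs$seq), function(i) {
    s <- seqs$seq[i]
    n <- nchar(s)
    if (off[i] == -2L || n < L) return(character(0))
    starts <- if (off[i] == -1L) seq_len(n - L + 1L) else off[i] + 1L
    w <- substring(s, starts, starts + L - 1L)
    w[!grepl("[^ACGT]", w)]
  })
  k <- lengths(out)
  if (sum(k) == 0) {
    warning("no valid window of length ", L, " in the sequence set",
            call. = FALSE)
  }
  data.frame(seq_index = rep.int(seq_along(out), k),
             lmer = unlist(out, use.names = FALSE),
             stringsAsFactors = FALSE)
}

#' Build the L-mer table for a positive/negative dataset pair
#'
#' Counts every L-mer present in the positive set: occurrence counts and
#' sequence-presence sets in both datasets. L-mers occurring only in the
#' negative set are not stored. Keys are returned in alphabetical order.
#'
#' @param pos,neg Positive (signal) and negative (control) sequences: a
#'   `sequence_set`, a character vector, or a FASTA path.
#' @inheritParams extract_lmers
#' @return An `lmer_table`: list with `L`, `mode`, `anchor`, `lmer`,
#'   `occ_pos`, `occ_neg`, `seqs_pos`, `seqs_neg` (lists of 1-based
#'   sequence indices), `n_pos`, `n_neg`.
#' @export
build_lmer_table <- function(pos, neg, L, mode = c("scanning", "fixed"),
                             anchor = "end") {
  pos <- .as_sequence_set(pos)
  neg <- .as_sequence_set(neg)
  mode <- match.arg(mode)
  stopifnot(L >= 1)
  if (length(pos$seq) == 0 || length(neg$seq) == 0) {
    stop("both datasets must be non-empty", call. = FALSE)
  }
  counts <- cpp_count_lmers(pos$seq, neg$seq, as.integer(L),
                            .resolve_offsets(pos, L, mode, anchor),
                            .resolve_offsets(neg, L, mode, anchor))
  if (length(counts$lmer) == 0) {
    stop("no valid window of length ", L, " in the positive set",
         call. = FALSE)
  }
  structure(list(L = as.integer(L), mode = mode, anchor = anchor,
                 lmer = counts$lmer,
                 occ_pos = counts$occ_pos, occ_neg = counts$occ_neg,
                 seqs_pos = counts$seqs_pos, seqs_neg = counts$seqs_neg,
                 n_pos = length(pos$seq), n_neg = length(neg$seq),
                 n_windows_pos = counts$n_windows_pos,
                 n_windows_neg = counts$n_windows_neg),
            class = "lmer_table")
}

#' @export
print.lmer_table <- function(x, ...) {
  cat("lmer_table: ", length(x$lmer), " distinct ", x$L, "-mers (",
      x$mode, " mode), ", x$n_pos, " positive / ", x$n_neg,
      " negative sequences\n", sep = "")
  invisible(x)
}

#' @export
as.data.frame.lmer_table <- function(x, ...) {
  data.frame(lmer = x$lmer,
             occ_pos = x$occ_pos, occ_neg = x$occ_neg,
             nseq_pos = lengths(x$seqs_pos), nseq_neg = lengths(x$seqs_neg),
             stringsAsFactors = FALSE)
}

#' Write an L-mer table dump as TSV
#'
#' @param table An `lmer_table`.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_lmer_table_tsv <- function(table, path) {
  write.table(as.data.frame(table), path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}
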