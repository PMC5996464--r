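# The lattice of IUPAC motifs whose instances are all present in the
# positive key set, with per-node contingency tables and mutual
# information, dominance simplification and in-lattice masking.  The node
# store lives in compiled code; this file is the user-facing surface.

#' Build the IUPAC motif lattice
#'
#' Constructs the lattice of all IUPAC motifs of length `L` with at most
#' `d` degenerate characters whose exact instances are all keys of the
#' L-mer table. Motifs are generalized level by level: a position is
#' promoted to a degenerate character only when every word obtained by
#' substituting one of its bases is itself present, so the node set is
#' exactly the instance-closed motif family and absent motifs are never
#' explored.
#'
#' @param table An [`lmer_table`][build_lmer_table].
#' @param d Maximum number of degenerate characters per motif
#'   (`0 <= d <= L`).
#' @return A `motif_lattice` object. Call [attach_tables()] before
#'   simplification.
#' @export
build_lattice <- function(table, d) {
  stopifnot(inherits(table, "lmer_table"))
  d <- as.integer(d)
  if (d < 0 || d > table$L) {
    stop("d must satisfy 0 <= d <= L", call. = FALSE)
  }
  ptr <- cpp_build_lattice(table$lmer, table$occ_pos, table$occ_neg,
                           table$seqs_pos, table$seqs_neg,
                           table$n_pos, table$n_neg, d)
  structure(list(ptr = ptr, L = table$L, d = d,
                 n_pos = table$n_pos, n_neg = table$n_neg,
                 n_windows_pos = table$n_windows_pos,
                 n_windows_neg = table$n_windows_neg),
            class = "motif_lattice")
}

#' Attach contingency tables and mutual information to a lattice
#'
#' For every node, computes the sequence-level contingency table: `a` is
#' the number of positive sequences containing at least one instance of
#' the motif (the size of the union of the per-instance sequence sets, not
#' a sum of counts), `b` likewise for the negative dataset, and `c`, `d`
#' follow by complement. Total occurrence counts (sums over instances) are
#' recorded for reporting, and the mutual information of each table is
#' computed in bits.
#'
#' @param lattice A `motif_lattice`.
#' @param table The `lmer_table` the lattice was built from (accepted for
#'   interface symmetry; the lattice already holds the counts).
#' @param stat Which contingency cells drive MI (and downstream testing):
#'   `"sequence"` (default) scores sequence-presence counts as in the
#'   contingency model; `"occurrence"` scores raw occurrence counts
#'   against the total number of scanned windows per dataset. In
#'   fixed-position mode the two coincide (one window per sequence).
#' @return The lattice, invisibly (tables are attached in place).
#' @export
attach_tables <- function(lattice, table = NULL,
                          stat = c("sequence", "occurrence")) {
  stopifnot(inherits(lattice, "motif_lattice"))
  stat <- match.arg(stat)
  if (!is.null(table)) {
    stopifnot(inherits(table, "lmer_table"))
    if (table$n_pos != lattice$n_pos || table$n_neg != lattice$n_neg) {
      stop("table does not match the lattice datasets", call. = FALSE)
    }
  }
  cpp_attach_tables(lattice$ptr, identical(stat, "occurrence"),
                    lattice$n_windows_pos, lattice$n_windows_neg)
  invisible(lattice)
}

#' @export
print.motif_lattice <- function(x, ...) {
  info <- cpp_lattice_info(x$ptr)
  cat("motif_lattice: L=", info$L, ", d=", info$d, ", ",
      format(info$n_nodes, big.mark = ","), " nodes (",
      info$nodes_per_weight[1], " exact words), ",
      info$n_pos, "/", info$n_neg, " pos/neg sequences",
      if (info$attached) ", tables attached" else "", "\n", sep = "")
  invisible(x)
}

#' Lattice size summary
#'
#' @param lattice A `motif_lattice`.
#' @return List with `L`, `d`, `n_nodes`, `nodes_per_weight` (node counts
#'   grouped by total generalization weight), dataset sizes.
#' @export
lattice_info <- function(lattice) {
  stopifnot(inherits(lattice, "motif_lattice"))
  cpp_lattice_info(lattice$ptr)
}

#' Dump all lattice nodes
#'
#' Materializes every node with its contingency counts, occurrence totals,
#' mutual information and masking status. Intended for inspection and
#' debugging of small lattices; a scanning run over large datasets can
#' hold millions of nodes.
#'
#' @param lattice A `motif_lattice` (tables attached for statistics).
#' @return A data frame with columns `motif`, `level` (degenerate-character
#'   count), `a`, `b`, `c`, `d`, `occ_pos`, `occ_neg`, `mi`, `status`.
#' @export
lattice_nodes <- function(lattice) {
  stopifnot(inherits(lattice, "motif_lattice"))
  df <- cpp_all_nodes(lattice$ptr)
  df$c <- lattice$n_pos - df$a
  df$d <- lattice$n_neg - df$b
  df[, c("motif", "level", "a", "b", "c", "d",
         "occ_pos", "occ_neg", "mi", "status")]
}

#' Look up the status of motifs in a lattice
#'
#' @param lattice A `motif_lattice`.
#' @param motifs Character vector of IUPAC motifs.
#' @return Character vector: `"active"`, `"removed"` (masked) or
#'   `"absent"`.
#' @export
motif_status <- function(lattice, motifs) {
  stopifnot(inherits(lattice, "motif_lattice"))
  c("absent", "active", "removed")[cpp_status(lattice$ptr, motifs) + 2L]
}

#' Mutual information of a 2x2 contingency table
#'
#' Computes the mutual information, in bits, between motif
#' presence/absence and the dataset label from the sequence-count table
#' `(a, b, c, d)`: `a`/`b` are positive/negative sequences containing the
#' motif, `c`/`d` the remaining ones. Joint probabilities are the cell
#' frequencies and marginals the row/column sums; cells with zero count
#' contribute zero.
#'
#' @param a,b,c,d Non-negative cell counts (vectorized).
#' @return Numeric vector of MI values in bits (non-negative).
#' @examples
#' mutual_information(5, 5, 5, 5)    # 0: independent
#' mutual_information(10, 0, 0, 10)  # 1 bit: perfect association
#' @export
mutual_information <- function(a, b, c, d) {
  n <- a + b + c + d
  if (any(n <= 0)) stop("empty contingency table", call. = FALSE)
  if (any(c(a, b, c, d) < 0)) stop("negative cell count", call. = FALSE)
  term <- function(cell, row, col) {
    ifelse(cell > 0, (cell / n) * log2(cell * n / (row * col)), 0)
  }
  mi <- term(a, a + b, a + c) + term(b, a + b, b + d) +
    term(c, c + d, a + c) + term(d, c + d, b + d)
  pmax(mi, 0)
}

#' Reduce the lattice to dominant non-dominated motifs
#'
#' Greedy dominance selection: nodes are visited by decreasing mutual
#' information (ties broken by larger `a`, then by motif text under the
#' canonical character order); each visited node still active is selected
#' and all of its lattice ancestors and descendants are set aside for this
#' pass. The selection is an antichain of the generalization order.
#' Masked (removed) nodes are never selected; the pass itself does not
#' permanently remove nodes, so it can be repeated after [mask_motif()].
#'
#' @param lattice A `motif_lattice` with tables attached.
#' @return A data frame of the selected nodes, in selection (decreasing
#'   MI) order, with columns `motif`, `level`, `a`, `b`, `c`, `d`,
#'   `occ_pos`, `occ_neg`, `mi`.
#' @export
simplify_lattice <- function(lattice) {
  stopifnot(inherits(lattice, "motif_lattice"))
  ids <- cpp_simplify(lattice$ptr)
  df <- cpp_node_info(lattice$ptr, ids)
  df$c <- lattice$n_pos - df$a
  df$d <- lattice$n_neg - df$b
  df[, c("motif", "level", "a", "b", "c", "d", "occ_pos", "occ_neg", "mi")]
}

#' Mask a motif's instance closure in the lattice
#'
#' Permanently removes every node sharing at least one exact instance with
#' `motif` — equivalently, every ancestor of any of its exact-word
#' descendants, including the motif itself. After masking, all remaining
#' active nodes are instance-disjoint from `motif`, which is how secondary
#' motifs are found without rescanning the sequences.
#'
#' @param lattice A `motif_lattice`.
#' @param motif A motif string that is a node of the lattice.
#' @return The lattice, invisibly (modified in place).
#' @export
mask_motif <- function(lattice, motif) {
  stopifnot(inherits(lattice, "motif_lattice"))
  cpp_mask(lattice$ptr, toupper(motif))
  invisible(lattice)
}

#' Write a lattice debug dump as TSV
#'
#' One row per node: motif, level, contingency counts, occurrence totals,
#' MI and status. Intended for small lattices.
#'
#' @param lattice A `motif_lattice`.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_lattice_tsv <- function(lattice, path) {
  write.table(lattice_nodes(lattice), path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}

# free the compiled node store ahead of garbage collection (used by
# discover(), which builds one lattice per run)
release_lattice <- function(lattice) {
  stopifnot(inherits(lattice, "motif_lattice"))
  cpp_free_lattice(lattice$ptr)
  invisible(NULL)
}
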