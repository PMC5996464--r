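# Post-processing for scanning mode: group overlapping motifs around
# highest-MI reference motifs.

#' Test whether two motifs align at a given shift
#'
#' Aligns `other` against `ref` shifted by `shift` positions (position `j`
#' of `other` faces position `j + shift` of `ref`). The alignment is
#' admissible when the overlap spans at least `ceiling(L / 2)` columns —
#' a motif may not extend beyond half the reference on either side — and
#' every overlapping column pair is compatible (identical characters or
#' one base set included in the other).
#'
#' @param ref,other IUPAC motif strings of equal length.
#' @param shift Integer offset of `other` relative to `ref`.
#' @return `TRUE` or `FALSE`.
#' @examples
#' overlap_match("AMGT", "MRTN", 1)   # TRUE: G is included in R
#' overlap_match("AMGT", "NACG", -1)  # TRUE: A and C are included in M
#' @export
overlap_match <- function(ref, other, shift) {
  rc <- .check_motif(ref)
  oc <- .check_motif(other)
  L <- length(rc)
  if (length(oc) != L) stop("motifs must have equal length", call. = FALSE)
  shift <- as.integer(shift)
  if (L - abs(shift) < ceiling(L / 2)) return(FALSE)
  jj <- seq_len(L) - 1L
  jj <- jj[jj + shift >= 0L & jj + shift < L]
  all(vapply(jj, function(j) characters_compatible(oc[j + 1L], rc[j + shift + 1L]),
             logical(1)))
}

.admissible_shifts <- function(L) {
  m <- L - ceiling(L / 2)
  if (m == 0) return(0L)
  s <- seq.int(-m, m)
  s[order(abs(s), s)]  # smallest |shift| first, negative before positive
}

#' Cluster overlapping motifs around high-MI references
#'
#' Greedy clustering of a result set: the unassigned motif with the
#' highest mutual information becomes the reference of a new cluster, and
#' every other unassigned motif that aligns with it at some admissible
#' shift joins the cluster (the smallest admissible `|shift|` is recorded,
#' negative before positive on ties). The procedure repeats until all
#' motifs are assigned; each motif belongs to exactly one cluster.
#'
#' @param results A data frame carrying at least `motif` and `mi` columns
#'   (as returned by [discover()] or [simplify_lattice()]).
#' @return `results` with `cluster_id` and `shift` filled in (references
#'   have shift 0), and a `clusters` attribute summarizing each cluster
#'   (`cluster_id`, `reference`, `n_members`).
#' @export
cluster_results <- function(results) {
  results <- as.data.frame(results)
  n <- nrow(results)
  results$cluster_id <- rep(NA_integer_, n)
  results$shift <- rep(NA_integer_, n)
  if (n == 0) {
    attr(results, "clusters") <- data.frame(cluster_id = integer(0),
                                            reference = character(0),
                                            n_members = integer(0))
    return(results)
  }
  L <- nchar(results$motif[1])
  shifts <- .admissible_shifts(L)
  # stable processing order: decreasing MI, input order on ties
  ord <- order(-results$mi, seq_len(n))
  assigned <- logical(n)
  cid <- 0L
  refs <- character(0)
  sizes <- integer(0)
  for (i in ord) {
    if (assigned[i]) next
    cid <- cid + 1L
    assigned[i] <- TRUE
    results$cluster_id[i] <- cid
    results$shift[i] <- 0L
    members <- 1L
    for (j in ord) {
      if (assigned[j]) next
      for (s in shifts) {
        if (overlap_match(results$motif[i], results$motif[j], s)) {
          assigned[j] <- TRUE
          results$cluster_id[j] <- cid
          results$shift[j] <- s
          members <- members + 1L
          break
        }
      }
    }
    refs <- c(refs, results$motif[i])
    sizes <- c(sizes, members)
  }
  attr(results, "clusters") <- data.frame(cluster_id = seq_len(cid),
                                          reference = refs,
                                          n_members = sizes,
                                          stringsAsFactors = FALSE)
  results
}

#' Write a cluster summary TSV
#'
#' Lists each cluster's reference and member motifs with their shifts.
#'
#' @param results A clustered `motif_results` data frame.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_cluster_summary_tsv <- function(results, path) {
  df <- as.data.frame(results)
  if (!nrow(df) || all(is.na(df$cluster_id))) {
    out <- data.frame(cluster_id = integer(0), reference = character(0),
                      motif = character(0), shift = integer(0))
  } else {
    cl <- attr(results, "clusters")
    ref <- if (!is.null(cl)) {
      setNames(cl$reference, cl$cluster_id)
    } else {
      vapply(split(df, df$cluster_id),
             function(g) g$motif[which.max(g$mi)], character(1))
    }
    out <- data.frame(cluster_id = df$cluster_id,
                      reference = ref[as.character(df$cluster_id)],
                      motif = df$motif, shift = df$shift,
                      stringsAsFactors = FALSE)
    out <- out[order(out$cluster_id, abs(out$shift), out$shift), ]
  }
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
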