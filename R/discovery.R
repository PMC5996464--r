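# Pipeline orchestration: Fisher's exact test, Holm-Bonferroni adjustment,
# significance filtering, and the mask-and-rerun loop that yields
# secondary motifs.

#' One-sided Fisher exact test for motif over-representation
#'
#' Hypergeometric tail probability `P(A >= a)` with the margins of the
#' sequence-count table fixed; the alternative is over-representation in
#' the positive dataset. Equivalent to `fisher.test(alternative =
#' "greater")` on the 2x2 table.
#'
#' @param a,b,c,d Non-negative cell counts (vectorized): positive/negative
#'   sequences with the motif (`a`, `b`) and without it (`c`, `d`).
#' @return Numeric vector of one-sided p-values.
#' @examples
#' fisher_exact_one_sided(5, 0, 0, 5)  # 1/252
#' @export
fisher_exact_one_sided <- function(a, b, c, d) {
  if (any(c(a, b, c, d) < 0)) stop("negative cell count", call. = FALSE)
  phyper(a - 1, a + b, c + d, a + c, lower.tail = FALSE)
}

#' Holm-Bonferroni step-down adjustment
#'
#' Adjusts p-values with the Holm step-down procedure: in ascending order
#' the i-th smallest p-value is multiplied by (m - i + 1), running maxima
#' are enforced along the sorted order, and results are clipped at 1 and
#' returned in the original input order.
#'
#' @param p Numeric vector of raw p-values in `[0, 1]`.
#' @return Adjusted p-values, same order as the input.
#' @examples
#' holm_bonferroni(c(0.01, 0.04))  # 0.02 0.04
#' @export
holm_bonferroni <- function(p) {
  if (length(p) == 0) return(numeric(0))
  if (any(is.na(p)) || any(p < 0 | p > 1)) {
    stop("p-values must lie in [0, 1]", call. = FALSE)
  }
  p.adjust(p, method = "holm")
}

#' Discover over-represented IUPAC motifs
#'
#' Runs the full discriminative pipeline: count the L-mers of the positive
#' set (and their negative-set counts), build the instance-closed IUPAC
#' motif lattice up to degeneracy `d`, attach sequence-level contingency
#' tables and mutual information, reduce to dominant non-dominated motifs,
#' and keep the candidates whose one-sided Fisher p-value, Holm-adjusted
#' within the candidate family, falls strictly below `alpha`. Kept motifs
#' have their instance closures masked in the lattice and the
#' select-test-mask cycle repeats, so later rounds yield secondary motifs
#' sharing no instance with earlier ones. In scanning mode, overlapping
#' results are optionally clustered around highest-MI references.
#'
#' @param pos,neg Positive and negative datasets: `sequence_set`,
#'   character vector, or FASTA path.
#' @param L Motif length.
#' @param d Maximum number of degenerate characters (default `L`).
#' @param alpha Adjusted p-value threshold (strict), default 0.05.
#' @param mode `"scanning"` (every window) or `"fixed"` (one anchored
#'   window per sequence).
#' @param anchor Fixed-mode anchor: `"start"`, `"end"` (default) or a
#'   0-based offset.
#' @param max_rounds Maximum number of mask-and-rerun rounds (default 10).
#' @param cluster Cluster overlapping results (default: on in scanning
#'   mode, ignored in fixed mode).
#' @param holm_scope `"per_round"` adjusts each round's candidates as their
#'   own family; `"joint"` adjusts each round jointly with all candidates
#'   tested in earlier rounds (a cumulative family).
#' @param stat Contingency cells driving MI and the Fisher test:
#'   `"sequence"` (default) uses sequence-presence counts per the
#'   contingency model; `"occurrence"` uses occurrence counts against the
#'   total scanned windows per dataset, which weights motifs by total
#'   evidence and is stricter on weakly-supported highly degenerate
#'   motifs in scanning mode. The two coincide in fixed-position mode.
#'   Reported `a`, `b`, `c`, `d` columns are always sequence counts;
#'   `p_raw`, `p_holm` and `mi` follow the chosen statistic.
#' @return A `motif_results` data frame ordered by round then decreasing
#'   MI, with columns `rank`, `round`, `motif`, `a`, `b`, `c`, `d`,
#'   `occ_pos`, `occ_neg`, `mi`, `p_raw`, `p_holm`, `cluster_id`, `shift`.
#'   Zero rows when nothing is significant.
#' @export
discover <- function(pos, neg, L, d = L, alpha = 0.05,
                     mode = c("scanning", "fixed"), anchor = "end",
                     max_rounds = 10, cluster = NULL,
                     holm_scope = c("per_round", "joint"),
                     stat = c("sequence", "occurrence")) {
  mode <- match.arg(mode)
  holm_scope <- match.arg(holm_scope)
  stat <- match.arg(stat)
  stopifnot(L >= 1, d >= 0, d <= L, max_rounds >= 1)
  if (!(alpha > 0 && alpha <= 1)) {
    stop("alpha must lie in (0, 1]", call. = FALSE)
  }
  if (is.null(cluster)) cluster <- mode == "scanning"

  tbl <- build_lmer_table(pos, neg, L, mode, anchor)
  lat <- build_lattice(tbl, d)
  on.exit(release_lattice(lat), add = TRUE)
  attach_tables(lat, stat = stat)

  rounds <- list()
  prior_p <- numeric(0)
  for (round in seq_len(max_rounds)) {
    cand <- simplify_lattice(lat)
    if (nrow(cand) == 0) break
    cand$p_raw <- if (stat == "sequence") {
      fisher_exact_one_sided(cand$a, cand$b, cand$c, cand$d)
    } else {
      fisher_exact_one_sided(cand$occ_pos, cand$occ_neg,
                             lat$n_windows_pos - cand$occ_pos,
                             lat$n_windows_neg - cand$occ_neg)
    }
    if (holm_scope == "per_round") {
      cand$p_holm <- holm_bonferroni(cand$p_raw)
    } else {
      adj <- holm_bonferroni(c(prior_p, cand$p_raw))
      cand$p_holm <- adj[length(prior_p) + seq_len(nrow(cand))]
      prior_p <- c(prior_p, cand$p_raw)
    }
    keep <- cand[cand$p_holm < alpha, , drop = FALSE]
    if (nrow(keep) == 0) break
    keep$round <- round - 1L
    rounds[[round]] <- keep
    for (m in keep$motif) mask_motif(lat, m)
  }

  res <- if (length(rounds)) do.call(rbind, rounds) else
    data.frame(motif = character(0), level = integer(0), a = integer(0),
               b = integer(0), c = integer(0), d = integer(0),
               occ_pos = numeric(0), occ_neg = numeric(0), mi = numeric(0),
               p_raw = numeric(0), p_holm = numeric(0), round = integer(0))
  res$rank <- seq_len(nrow(res))
  res$cluster_id <- rep(NA_integer_, nrow(res))
  res$shift <- rep(NA_integer_, nrow(res))
  res <- res[, c("rank", "round", "motif", "a", "b", "c", "d",
                 "occ_pos", "occ_neg", "mi", "p_raw", "p_holm",
                 "cluster_id", "shift")]
  rownames(res) <- NULL
  if (cluster && mode == "scanning" && nrow(res) > 0) {
    res <- cluster_results(res)
  }
  structure(res,
            class = c("motif_results", "data.frame"),
            params = list(L = L, d = d, alpha = alpha, mode = mode,
                          anchor = anchor, max_rounds = max_rounds,
                          holm_scope = holm_scope, stat = stat,
                          cluster = cluster))
}

#' Write discovery results as TSV
#'
#' One header line, full-precision numbers, motifs as IUPAC text.
#'
#' @param results A `motif_results` data frame.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_results_tsv <- function(results, path) {
  out <- as.data.frame(results)
  for (col in c("occ_pos", "occ_neg", "mi", "p_raw", "p_holm")) {
    out[[col]] <- formatC(out[[col]], digits = 17, format = "g")
  }
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a results TSV written by [write_results_tsv()]
#'
#' @param path Path to the TSV file.
#' @return A data frame.
#' @export
read_results_tsv <- function(path) {
  read.delim(path, stringsAsFactors = FALSE)
}
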