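# Self-contained benchmark experiments: specificity on motif-free data
# and recovery of implanted exact motifs.

#' Specificity experiment on motif-free data
#'
#' Generates seeded pairs of uniform random datasets with no implanted
#' motifs, runs the full discovery pipeline on each pair, and scores the
#' nucleotide-level specificity `SPC = TN / N` of the reported motifs
#' against the all-negative ground truth of the positive file.
#'
#' @param n_pairs Number of dataset pairs.
#' @param n_sequences Sequences per file (default 5000).
#' @param seq_length Sequence length (default 100 bp).
#' @param L,d,alpha Discovery parameters (defaults 6, 6, 0.05).
#' @param stat Contingency statistic passed to [discover()].
#' @param seed Base seed; pair `i` uses `seed + i`.
#' @param verbose Print one line per pair.
#' @return Data frame with one row per pair: `pair`, `seed`,
#'   `n_motifs_reported`, `spc`.
#' @export
specificity_experiment <- function(n_pairs = 20, n_sequences = 5000,
                                   seq_length = 100, L = 6, d = 6,
                                   alpha = 0.05, stat = "sequence",
                                   seed = 1, verbose = FALSE) {
  res <- vector("list", n_pairs)
  for (i in seq_len(n_pairs)) {
    sim <- simulate_dataset(n_sequences, seq_length, frequency = 0,
                            seed = seed + i)
    hits <- discover(sim$pos, sim$neg, L = L, d = d, alpha = alpha,
                     mode = "scanning", cluster = TRUE, stat = stat)
    counts <- score_predictions(NULL, hits, sim$pos)
    spc <- specificity(counts, sum(nchar(sim$pos$seq)))
    res[[i]] <- data.frame(pair = i, seed = seed + i,
                           n_motifs_reported = nrow(hits), spc = spc)
    if (verbose) {
      message(sprintf("pair %d: %d motifs reported, SPC = %.6f",
                      i, nrow(hits), spc))
    }
    rm(sim, hits)
    gc(FALSE)
  }
  do.call(rbind, res)
}

#' Recovery experiment with implanted exact motifs
#'
#' Implants one exact motif (IUPAC content equal to its length) per run at
#' the given frequency and checks whether the top-ranked discovery result
#' is the implanted motif or a specialization of it (every instance of the
#' reported motif is an instance of the implanted one).
#'
#' @param n_runs Number of simulated runs.
#' @param n_sequences,seq_length Dataset dimensions (defaults 5000, 100).
#' @param motif_length Implanted motif length (default 6).
#' @param frequency Implant frequency (default 0.05).
#' @param alpha Significance threshold (default 0.05).
#' @param seed Base seed; run `i` uses `seed + i`.
#' @param verbose Print one line per run.
#' @return Data frame with one row per run: `run`, `seed`, `motif`
#'   (implanted), `top_hit`, `p_holm`, `recovered`.
#' @export
recovery_experiment <- function(n_runs = 20, n_sequences = 5000,
                                seq_length = 100, motif_length = 6,
                                frequency = 0.05, alpha = 0.05, seed = 1,
                                verbose = FALSE) {
  res <- vector("list", n_runs)
  for (i in seq_len(n_runs)) {
    sim <- simulate_dataset(n_sequences, seq_length,
                            motif_length = motif_length, n_motifs = 1,
                            iupac_content = motif_length,
                            frequency = frequency, seed = seed + i)
    hits <- discover(sim$pos, sim$neg, L = motif_length, d = motif_length,
                     alpha = alpha, mode = "scanning", cluster = FALSE)
    recovered <- FALSE
    top <- NA_character_
    p <- NA_real_
    if (nrow(hits) > 0) {
      top <- hits$motif[1]
      p <- hits$p_holm[1]
      recovered <- p < alpha &&
        all(motif_instances(top) %in% motif_instances(sim$motifs[1]))
    }
    res[[i]] <- data.frame(run = i, seed = seed + i,
                           motif = sim$motifs[1], top_hit = top,
                           p_holm = p, recovered = recovered,
                           stringsAsFactors = FALSE)
    if (verbose) {
      message(sprintf("run %d: implanted %s, top hit %s, recovered = %s",
                      i, sim$motifs[1], top, recovered))
    }
    rm(sim, hits)
    gc(FALSE)
  }
  do.call(rbind, res)
}
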