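# Synthetic benchmark: uniform random sequence sets, random IUPAC motif
# sets of controlled size and IUPAC content, uniform-instance implantation
# at controlled frequencies, and nucleotide-level nCC / SPC scoring.

.with_seed <- function(seed, expr) {
  if (is.null(seed)) return(eval.parent(substitute(expr)))
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) runif(1)
  old <- get(".Random.seed", envir = globalenv())
  on.exit(assign(".Random.seed", old, envir = globalenv()))
  set.seed(as.integer(seed))
  eval.parent(substitute(expr))
}

#' Generate uniform random DNA sequences
#'
#' Sequences are i.i.d. uniform over A, C, G, T (independent and
#' equiprobable bases), reproducible from `seed`.
#'
#' @param n Number of sequences.
#' @param length Sequence length in bp.
#' @param seed Optional integer seed; when `NULL` the current RNG state is
#'   used (and advanced).
#' @return A [`sequence_set`][sequence_set].
#' @export
generate_sequences <- function(n, length, seed = NULL) {
  stopifnot(n >= 1, length >= 1)
  .with_seed(seed, {
    m <- matrix(sample(c("A", "C", "G", "T"), n * length, replace = TRUE),
                nrow = n)
    sequence_set(apply(m, 1, paste0, collapse = ""))
  })
}

# all compositions of `content` into `len` parts, each part in 1..4
.level_compositions <- function(len, content) {
  grid <- do.call(expand.grid, rep(list(1:4), len))
  grid[rowSums(grid) == content, , drop = FALSE]
}

#' Sample random IUPAC motifs of fixed IUPAC content
#'
#' Each motif is drawn independently: a composition of `iupac_content`
#' into `motif_length` per-position degeneracy levels (each 1..4) is
#' sampled uniformly over all valid compositions, then each position gets
#' a uniformly chosen IUPAC character of that level. Content
#' `motif_length` forces exact motifs; content `4 * motif_length` forces
#' all-N.
#'
#' @param n_motifs Number of motifs to draw.
#' @param motif_length Motif length L.
#' @param iupac_content Target sum of degeneracy levels
#'   (`motif_length <= iupac_content <= 4 * motif_length`).
#' @param seed Optional integer seed.
#' @return Character vector of IUPAC motif strings.
#' @export
sample_motif_set <- function(n_motifs, motif_length, iupac_content,
                             seed = NULL) {
  stopifnot(n_motifs >= 1, motif_length >= 1)
  if (iupac_content < motif_length || iupac_content > 4 * motif_length) {
    stop("iupac_content must lie in [L, 4L]", call. = FALSE)
  }
  comps <- .level_compositions(motif_length, iupac_content)
  by_level <- split(iupac_alphabet()$symbol, iupac_alphabet()$level)
  .with_seed(seed, {
    vapply(seq_len(n_motifs), function(k) {
      lv <- as.integer(comps[sample.int(nrow(comps), 1), ])
      paste0(vapply(lv, function(l) {
        pool <- by_level[[l]]
        pool[sample.int(length(pool), 1)]
      }, character(1)), collapse = "")
    }, character(1))
  })
}

#' Implant motif instances into a sequence set
#'
#' For each motif, `round(frequency * n_sequences)` implants are placed:
#' each implant draws an instance uniformly from the motif's exact
#' instances, a target sequence uniformly, and a start position uniformly
#' among positions not overlapping implants already present in that
#' sequence. Implants overwrite the background in place (sequence lengths
#' are preserved) and a sequence may receive several implants.
#'
#' @param seqs A `sequence_set` (or character vector).
#' @param motifs Character vector of IUPAC motifs to implant.
#' @param frequency Implant frequency as a fraction of the number of
#'   sequences (e.g. 0.05 for 5%).
#' @param seed Optional integer seed.
#' @param max_tries Placement attempts per implant before failing.
#' @return List with `seqs` (the modified `sequence_set`) and `truth`, a
#'   data frame of ground-truth implants: `seq_index` (1-based), `start`
#'   (0-based), `end` (half-open), `motif`, `instance`.
#' @export
implant_motifs <- function(seqs, motifs, frequency, seed = NULL,
                           max_tries = 1000) {
  seqs <- .as_sequence_set(seqs)
  n <- length(seqs$seq)
  n_implants <- round(frequency * n)
  if (n_implants < 1) {
    stop("frequency too low: round(frequency * n) must be >= 1",
         call. = FALSE)
  }
  lens <- nchar(seqs$seq)
  .with_seed(seed, {
    occupied <- vector("list", n)
    rows <- vector("list", length(motifs) * n_implants)
    ri <- 0L
    for (m in motifs) {
      inst <- motif_instances(m)
      L <- nchar(m)
      if (any(lens < L)) {
        stop("sequences shorter than the motif length", call. = FALSE)
      }
      for (k in seq_len(n_implants)) {
        placed <- FALSE
        for (try in seq_len(max_tries)) {
          s <- sample.int(n, 1)
          start <- sample.int(lens[s] - L + 1L, 1) - 1L  # 0-based
          clash <- any(vapply(occupied[[s]], function(iv)
            start < iv[2] && iv[1] < start + L, logical(1)))
          if (!clash) {
            w <- inst[sample.int(length(inst), 1)]
            substr(seqs$seq[s], start + 1L, start + L) <- w
            occupied[[s]] <- c(occupied[[s]], list(c(start, start + L)))
            ri <- ri + 1L
            rows[[ri]] <- data.frame(seq_index = s, start = start,
                                     end = start + L, motif = m,
                                     instance = w, stringsAsFactors = FALSE)
            placed <- TRUE
            break
          }
        }
        if (!placed) {
          stop("could not place an implant without overlap after ",
               max_tries, " tries (sequence budget exhausted)", call. = FALSE)
        }
      }
    }
    truth <- do.call(rbind, rows[seq_len(ri)])
    rownames(truth) <- NULL
    list(seqs = seqs, truth = truth)
  })
}

#' Nucleotide-level correlation coefficient (nCC)
#'
#' Matthews-type correlation between predicted and true motif-covered
#' nucleotides, in `[-1, 1]`: 1 is perfect prediction, 0 no correlation,
#' -1 perfect inverse prediction. Undefined (any zero marginal factor)
#' yields `NA`, never a silent 0.
#'
#' @param counts A list or data frame with elements `TP`, `TN`, `FP`,
#'   `FN` (nucleotide counts).
#' @return A single numeric value, or `NA` when undefined.
#' @export
ncc <- function(counts) {
  TP <- as.numeric(counts$TP); TN <- as.numeric(counts$TN)
  FP <- as.numeric(counts$FP); FN <- as.numeric(counts$FN)
  den <- (TP + FN) * (TN + FP) * (TP + FP) * (TN + FN)
  if (den == 0) return(NA_real_)
  (TP * TN - FN * FP) / sqrt(den)
}

#' Specificity (SPC)
#'
#' Proportion of true-negative nucleotides among all evaluated
#' nucleotides: `SPC = TN / N`.
#'
#' @param counts A list or data frame with element `TN`.
#' @param total_nucleotides Total number of evaluated nucleotides `N`.
#' @return A single numeric value in `[0, 1]`.
#' @export
specificity <- function(counts, total_nucleotides) {
  stopifnot(total_nucleotides > 0)
  as.numeric(counts$TN) / total_nucleotides
}

#' Nucleotide-level scoring of predictions against ground truth
#'
#' Over the positive dataset, a nucleotide is truth-positive when covered
#' by a ground-truth implant interval and prediction-positive when covered
#' by a scanning-mode occurrence of any predicted motif; TP/FP/FN/TN are
#' tallied per nucleotide. Optionally the negative dataset (all
#' truth-negative) is included in the tally.
#'
#' @param truth Ground-truth data frame as produced by [implant_motifs()]
#'   (`NULL` or zero rows for motif-free data).
#' @param predicted Character vector of predicted IUPAC motifs (or a
#'   `motif_results` data frame, whose `motif` column is used).
#' @param seqs The positive `sequence_set` that was scored.
#' @param neg_seqs Optional negative `sequence_set` to include as
#'   truth-negative nucleotides.
#' @return A list with nucleotide counts `TP`, `TN`, `FP`, `FN`.
#' @export
score_predictions <- function(truth, predicted, seqs, neg_seqs = NULL) {
  seqs <- .as_sequence_set(seqs)
  if (is.data.frame(predicted)) predicted <- predicted$motif
  lens <- nchar(seqs$seq)
  truth_mask <- lapply(lens, function(l) logical(l))
  if (!is.null(truth) && nrow(truth) > 0) {
    for (r in seq_len(nrow(truth))) {
      s <- truth$seq_index[r]
      truth_mask[[s]][(truth$start[r] + 1L):truth$end[r]] <- TRUE
    }
  }
  pred_mask <- lapply(lens, function(l) logical(l))
  for (m in predicted) {
    L <- nchar(m)
    hits <- cpp_scan_motif(seqs$seq, toupper(m))
    for (s in seq_along(hits)) {
      for (h in hits[[s]]) pred_mask[[s]][h:(h + L - 1L)] <- TRUE
    }
  }
  tv <- unlist(truth_mask, use.names = FALSE)
  pv <- unlist(pred_mask, use.names = FALSE)
  TP <- sum(tv & pv); FN <- sum(tv & !pv)
  FP <- sum(!tv & pv); TN <- sum(!tv & !pv)
  if (!is.null(neg_seqs)) {
    neg_seqs <- .as_sequence_set(neg_seqs)
    npv <- logical(sum(nchar(neg_seqs$seq)))
    off <- 0L
    for (m in predicted) {
      L <- nchar(m)
      hits <- cpp_scan_motif(neg_seqs$seq, toupper(m))
      off <- 0L
      for (s in seq_along(hits)) {
        for (h in hits[[s]]) npv[off + (h:(h + L - 1L))] <- TRUE
        off <- off + nchar(neg_seqs$seq[s])
      }
    }
    FP <- FP + sum(npv)
    TN <- TN + sum(!npv)
  }
  list(TP = TP, TN = TN, FP = FP, FN = FN)
}

#' Enumerate a simulation design grid
#'
#' Builds the full factorial design of the synthetic benchmark: motif-set
#' sizes crossed with IUPAC contents, each combination replicated into
#' independent motif sets, crossed with implant frequencies and
#' repetitions. Every row carries a unique `design_key` and a derived
#' deterministic seed.
#'
#' @param n_motifs Motif-set sizes (default 1:4).
#' @param iupac_content IUPAC content values (default 6, 8, 10, 12, 14).
#' @param motif_sets Motif-set replicates per combination (default 5).
#' @param frequencies Implant frequencies (default 5% down to 0.5%).
#' @param repetitions Dataset repetitions per cell (default 100).
#' @param base_seed Integer folded into every derived seed.
#' @return A data frame with one row per dataset to simulate.
#' @export
simulation_designs <- function(n_motifs = 1:4,
                               iupac_content = c(6, 8, 10, 12, 14),
                               motif_sets = 5,
                               frequencies = c(0.05, 0.04, 0.03, 0.02,
                                               0.01, 0.005),
                               repetitions = 100,
                               base_seed = 1) {
  g <- expand.grid(n_motifs = n_motifs, iupac_content = iupac_content,
                   motif_set = seq_len(motif_sets),
                   frequency = frequencies,
                   repetition = seq_len(repetitions),
                   KEEP.OUT.ATTRS = FALSE)
  g$design_key <- sprintf("m%d_c%d_s%d_f%g_r%d", g$n_motifs,
                          g$iupac_content, g$motif_set, g$frequency,
                          g$repetition)
  g$seed <- vapply(g$design_key, design_seed, numeric(1),
                   base_seed = base_seed)
  g
}

#' Deterministic seed for a simulation design key
#'
#' Polynomial string hash (base 31, modulo 2^31 - 1) of the design key,
#' folded with `base_seed`; documented so any single cell of the design
#' grid can be regenerated in isolation.
#'
#' @param design_key Character design key.
#' @param base_seed Integer offset.
#' @return An integer-valued seed below 2^31.
#' @export
design_seed <- function(design_key, base_seed = 1) {
  h <- as.numeric(base_seed) %% 2147483647
  for (v in utf8ToInt(design_key)) h <- (h * 31 + v) %% 2147483647
  h
}

#' Simulate one benchmark dataset pair
#'
#' Generates a fresh negative control set and a positive set from the same
#' uniform distribution, then implants the given (or freshly sampled)
#' motif set into the positive sequences.
#'
#' @param n_sequences Sequences per file (default 5000).
#' @param seq_length Sequence length in bp (default 100).
#' @param motif_length Motif length (default 6).
#' @param n_motifs Number of motifs when `motifs` is not supplied.
#' @param iupac_content IUPAC content when `motifs` is not supplied.
#' @param frequency Implant frequency; 0 yields a motif-free positive set.
#' @param motifs Optional explicit motif set (overrides sampling).
#' @param seed Optional integer seed covering the whole simulation.
#' @return List with `pos`, `neg` (`sequence_set`s), `motifs`, `truth`.
#' @export
simulate_dataset <- function(n_sequences = 5000, seq_length = 100,
                             motif_length = 6, n_motifs = 1,
                             iupac_content = 6, frequency = 0.05,
                             motifs = NULL, seed = NULL) {
  .with_seed(seed, {
    neg <- generate_sequences(n_sequences, seq_length)
    pos <- generate_sequences(n_sequences, seq_length)
    truth <- NULL
    if (frequency > 0) {
      if (is.null(motifs)) {
        motifs <- sample_motif_set(n_motifs, motif_length, iupac_content)
      }
      imp <- implant_motifs(pos, motifs, frequency)
      pos <- imp$seqs
      truth <- imp$truth
    } else {
      motifs <- character(0)
    }
    list(pos = pos, neg = neg, motifs = motifs, truth = truth)
  })
}
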