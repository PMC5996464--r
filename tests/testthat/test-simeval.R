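test_that("random sequences are uniform, reproducible and boundary-safe", {
  s1 <- generate_sequences(200, 100, seed = 61)
  s2 <- generate_sequences(200, 100, seed = 61)
  expect_identical(s1$seq, s2$seq)
  # each base frequency within 3 standard errors of 1/4
  bases <- strsplit(paste0(s1$seq, collapse = ""), "")[[1]]
  n <- length(bases)
  se <- sqrt(0.25 * 0.75 / n)
  for (b in c("A", "C", "G", "T")) {
    expect_lt(abs(mean(bases == b) - 0.25), 3 * se)
  }
  tiny <- generate_sequences(1, 1, seed = 62)
  expect_equal(nchar(tiny$seq), 1)
})

test_that("motif sets honour the requested IUPAC content", {
  expect_equal(sample_motif_set(1, 6, 6, seed = 63),
               toupper(sample_motif_set(1, 6, 6, seed = 63)))
  # content = L forces exact motifs; content = 4L forces all-N
  for (m in sample_motif_set(5, 6, 6, seed = 64)) {
    expect_equal(motif_degeneracy(m), 0)
  }
  expect_equal(sample_motif_set(2, 6, 24, seed = 65), rep("NNNNNN", 2))
  # intermediate contents sum exactly
  for (m in sample_motif_set(20, 6, 14, seed = 66)) {
    expect_equal(iupac_content(m), 14)
    expect_equal(nchar(m), 6)
  }
  expect_error(sample_motif_set(1, 6, 25), "\\[L, 4L\\]")
  expect_error(sample_motif_set(1, 6, 5), "\\[L, 4L\\]")
})

test_that("implantation counts, instances and intervals follow the design", {
  seqs <- generate_sequences(200, 50, seed = 67)
  imp <- implant_motifs(seqs, c("ARTC", "TTKG"), frequency = 0.05, seed = 68)
  # round(0.05 * 200) = 10 implants per motif
  expect_equal(nrow(imp$truth), 20)
  expect_equal(as.vector(table(imp$truth$motif)), c(10, 10))
  # every instance matches its motif and sits where recorded
  for (r in seq_len(nrow(imp$truth))) {
    tr <- imp$truth[r, ]
    expect_true(motif_matches(tr$instance, tr$motif))
    expect_equal(substr(imp$seqs$seq[tr$seq_index], tr$start + 1, tr$end),
                 tr$instance)
  }
  # sequence lengths preserved; implants within one sequence never overlap
  expect_true(all(nchar(imp$seqs$seq) == 50))
  for (s in unique(imp$truth$seq_index)) {
    iv <- imp$truth[imp$truth$seq_index == s, c("start", "end")]
    iv <- iv[order(iv$start), ]
    if (nrow(iv) > 1) expect_true(all(iv$start[-1] >= iv$end[-nrow(iv)]))
  }
  # low frequencies still implant exact counts
  imp2 <- implant_motifs(generate_sequences(1000, 20, seed = 69), "ACGTCA",
                         frequency = 0.005, seed = 70)
  expect_equal(nrow(imp2$truth), 5)
  expect_error(implant_motifs(seqs, "ACGT", frequency = 0.001), ">= 1")
})

test_that("nCC follows the Matthews formula with flagged undefined cases", {
  expect_equal(ncc(list(TP = 10, TN = 20, FP = 0, FN = 0)), 1)
  expect_equal(ncc(list(TP = 5, TN = 5, FP = 5, FN = 5)), 0)
  expect_true(is.na(ncc(list(TP = 0, TN = 10, FP = 0, FN = 0))))
  set.seed(71)
  for (rep in 1:50) {
    x <- as.list(setNames(sample(1:40, 4, replace = TRUE),
                          c("TP", "TN", "FP", "FN")))
    mcc <- with(x, (TP * TN - FN * FP) /
                  (sqrt(TP + FN) * sqrt(TN + FP) * sqrt(TP + FP) *
                     sqrt(TN + FN)))
    expect_equal(ncc(x), mcc, tolerance = 1e-12)
    expect_true(ncc(x) >= -1 && ncc(x) <= 1)
  }
})

test_that("nucleotide scoring matches a hand tally on a small fixture", {
  # three 10 bp sequences; implant AAAA at seq 1 pos 0 and seq 2 pos 4
  seqs <- sequence_set(c("AAAACCCCCC", "GGGGAAAAGG", "CCCCCCCCCC"))
  truth <- data.frame(seq_index = c(1L, 2L), start = c(0L, 4L),
                      end = c(4L, 8L), motif = "AAAA", instance = "AAAA")
  counts <- score_predictions(truth, "AAAA", seqs)
  # predictions cover exactly the two implants: TP = 8, no FP/FN
  expect_equal(counts, list(TP = 8L, TN = 22L, FP = 0L, FN = 0L))
  expect_equal(ncc(counts), 1)
  # a prediction that covers one implant only
  counts2 <- score_predictions(truth, "GAAAAG", seqs)
  expect_equal(counts2, list(TP = 4L, TN = 20L, FP = 2L, FN = 4L))
  # empty predictions: SPC 1, nCC undefined
  counts3 <- score_predictions(NULL, character(0), seqs)
  expect_equal(counts3$TP + counts3$FP, 0)
  expect_true(is.na(ncc(counts3)))
  expect_equal(specificity(counts3, 30), 1)
})

test_that("specificity is the true-negative proportion", {
  # one predicted 6-mer occurrence on motif-free data of 600 nucleotides
  expect_equal(specificity(list(TN = 594), 600), 0.99)
  expect_equal(specificity(list(TN = 0), 10), 0)
})

test_that("the design iterator enumerates unique keyed cells", {
  g <- simulation_designs(motif_sets = 2, repetitions = 3)
  expect_equal(nrow(g), 4 * 5 * 2 * 6 * 3)
  expect_equal(anyDuplicated(g$design_key), 0)
  expect_true(all(g$seed >= 0 & g$seed < 2^31))
  expect_equal(design_seed("m1_c6_s1_f0.05_r1"),
               design_seed("m1_c6_s1_f0.05_r1"))
  expect_false(design_seed("m1_c6_s1_f0.05_r1") ==
                 design_seed("m1_c6_s1_f0.05_r2"))
})

test_that("simulated dataset pairs are reproducible and correctly shaped", {
  s1 <- simulate_dataset(50, 30, frequency = 0.1, seed = 72)
  s2 <- simulate_dataset(50, 30, frequency = 0.1, seed = 72)
  expect_identical(s1$pos$seq, s2$pos$seq)
  expect_identical(s1$neg$seq, s2$neg$seq)
  expect_identical(s1$truth, s2$truth)
  expect_equal(nrow(s1$truth), 5)  # round(0.1 * 50)
  # the negative file is never implanted: no ground truth rows refer to it
  s0 <- simulate_dataset(20, 25, frequency = 0, seed = 73)
  expect_null(s0$truth)
  expect_equal(length(s0$motifs), 0)
})
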