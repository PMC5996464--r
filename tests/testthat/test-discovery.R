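test_that("one-sided Fisher matches closed forms and exhaustive enumeration", {
  expect_equal(fisher_exact_one_sided(5, 0, 0, 5), 1 / 252)
  expect_equal(fisher_exact_one_sided(0, 3, 4, 2), 1)
  set.seed(41)
  tabs <- random_tables(300, max_cell = 10)  # totals <= 40
  p <- fisher_exact_one_sided(tabs$a, tabs$b, tabs$c, tabs$d)
  p_oracle <- mapply(oracle_fisher_greater, tabs$a, tabs$b, tabs$c, tabs$d)
  expect_equal(p, p_oracle, tolerance = 1e-10)
  # spot-check against fisher.test on a few tables
  for (k in sample(nrow(tabs), 5)) {
    ft <- fisher.test(matrix(as.numeric(tabs[k, ]), 2, byrow = TRUE),
                      alternative = "greater")
    expect_equal(p[k], unname(ft$p.value), tolerance = 1e-10)
  }
})

test_that("Holm adjustment follows the step-down formula and dominates raw p", {
  expect_equal(holm_bonferroni(c(0.01, 0.04)), c(0.02, 0.04))
  expect_equal(holm_bonferroni(0.3), 0.3)
  set.seed(42)
  for (rep in 1:20) {
    p <- runif(sample(1:12, 1))
    adj <- holm_bonferroni(p)
    expect_equal(adj, oracle_holm(p))
    expect_true(all(adj >= p))
    expect_true(all(adj <= 1))
    # rejections at any level include all plain-Bonferroni rejections
    alpha <- runif(1)
    expect_true(all(which(pmin(1, p * length(p)) < alpha) %in%
                      which(adj < alpha)))
  }
  expect_error(holm_bonferroni(c(0.5, 1.2)), "0, 1")
})

test_that("discovery flags a strongly implanted motif as the top hit", {
  # At this heavy implantation level a degenerate generalization of the
  # implant can carry more mutual information than the exact word itself,
  # so the check is that the top hit matches the implanted signal (the
  # implanted instance is an instance of the reported motif); the strict
  # instance-subset property is checked at full benchmark scale.
  sim <- simulate_dataset(n_sequences = 150, seq_length = 30,
                          motif_length = 4, n_motifs = 1, iupac_content = 4,
                          frequency = 0.3, seed = 430)
  res <- discover(sim$pos, sim$neg, L = 4, d = 4, alpha = 0.05,
                  cluster = FALSE)
  expect_gt(nrow(res), 0)
  expect_true(motif_matches(sim$motifs[1], res$motif[1]))
  expect_lt(res$p_holm[1], 0.05)
  expect_true(all(res$p_holm >= res$p_raw))
})

test_that("identical positive and negative sets yield no motif", {
  set.seed(44)
  for (rep in 1:10) {
    seqs <- generate_sequences(40, 25)
    res <- discover(seqs, seqs, L = 4, d = 4, alpha = 0.05, cluster = FALSE)
    expect_equal(nrow(res), 0)
  }
})

test_that("motifs reported in different rounds are instance-disjoint", {
  set.seed(45)
  for (rep in 1:10) {
    pos <- generate_sequences(30, 15)
    neg <- generate_sequences(30, 15)
    res <- discover(pos, neg, L = 3, d = 3, alpha = 1, max_rounds = 5,
                    cluster = FALSE)
    if (nrow(res) < 2) next
    inst <- lapply(res$motif, oracle_instances)
    for (i in seq_len(nrow(res))) for (j in seq_len(nrow(res))) {
      if (res$round[i] != res$round[j]) {
        expect_length(intersect(inst[[i]], inst[[j]]), 0)
      }
    }
    # round indices are contiguous from zero and ordering is by round
    expect_true(all(diff(res$round) >= 0))
    expect_equal(res$rank, seq_len(nrow(res)))
  }
})

test_that("discovery is deterministic for fixed inputs", {
  sim <- simulate_dataset(n_sequences = 60, seq_length = 20,
                          motif_length = 4, frequency = 0.2, seed = 460)
  r1 <- discover(sim$pos, sim$neg, L = 4, alpha = 0.5)
  r2 <- discover(sim$pos, sim$neg, L = 4, alpha = 0.5)
  expect_identical(as.data.frame(r1), as.data.frame(r2))
})

test_that("the fixed-position toy configuration runs end-to-end", {
  pos <- sequence_set(c("TACT", "TACT", "TACT", "CATT", "CATT", "CAGT",
                        "CAGT", "CACT"))
  neg <- sequence_set(c("CACT", "CACT", "CAGT", "GGGG", "TTTT", "AAAA",
                        "CCCC", "ACGT"))
  res <- discover(pos, neg, L = 4, d = 4, alpha = 0.05, mode = "fixed")
  # candidates come from the simplified set only: never a dominated motif
  # together with its dominating ancestor/descendant
  if (nrow(res) >= 2) {
    inst <- lapply(res$motif, oracle_instances)
    same_round <- outer(res$round, res$round, "==")
    for (i in seq_len(nrow(res))) for (j in seq_len(nrow(res))) {
      if (i != j && same_round[i, j]) {
        expect_false(all(inst[[i]] %in% inst[[j]]))
      }
    }
  }
  expect_s3_class(res, "motif_results")
})

test_that("joint Holm scope accumulates the testing family across rounds", {
  set.seed(47)
  sim <- simulate_dataset(n_sequences = 80, seq_length = 20,
                          motif_length = 4, frequency = 0.25, seed = 470)
  per <- discover(sim$pos, sim$neg, L = 4, alpha = 0.2, cluster = FALSE,
                  holm_scope = "per_round")
  joint <- discover(sim$pos, sim$neg, L = 4, alpha = 0.2, cluster = FALSE,
                    holm_scope = "joint")
  # both modes agree in round 0 (same family there)
  expect_equal(per$motif[per$round == 0], joint$motif[joint$round == 0])
  # the cumulative family can only raise later-round adjusted p-values
  if (any(joint$round > 0)) {
    shared <- intersect(per$motif[per$round > 0], joint$motif[joint$round > 0])
    for (m in shared) {
      expect_gte(joint$p_holm[joint$motif == m], per$p_holm[per$motif == m])
    }
  }
})

test_that("sequence and occurrence statistics coincide exactly in fixed mode", {
  pos <- sequence_set(c("TACT", "TACT", "TACT", "CATT", "CATT", "CAGT",
                        "CAGT", "CACT"))
  neg <- sequence_set(c("CACT", "CACT", "CAGT", "GGGG", "TTTT", "AAAA",
                        "CCCC", "ACGT"))
  a <- discover(pos, neg, L = 4, mode = "fixed", alpha = 1,
                stat = "sequence")
  b <- discover(pos, neg, L = 4, mode = "fixed", alpha = 1,
                stat = "occurrence")
  # identical values; only the recorded stat name in params differs
  expect_equal(as.data.frame(a), as.data.frame(b), ignore_attr = TRUE)
})

test_that("the occurrence statistic scores repeated occurrences, not sequences", {
  # ACGT twice in one positive sequence; one negative occurrence
  pos <- sequence_set(c("ACGTACGT", "TTTTTTTT"))
  neg <- sequence_set(c("ACGTTTTT", "GGGGGGGG"))
  tbl <- build_lmer_table(pos, neg, 4)
  lat <- build_lattice(tbl, 4)
  # sequence statistic: a = 1 of 2 sequences vs b = 1 of 2 -> MI 0
  attach_tables(lat, stat = "sequence")
  n_seq <- lattice_nodes(lat)
  expect_equal(n_seq$mi[n_seq$motif == "ACGT"], 0)
  # occurrence statistic: 2 of 10 windows vs 1 of 10 -> positive MI
  attach_tables(lat, stat = "occurrence")
  n_occ <- lattice_nodes(lat)
  expect_gt(n_occ$mi[n_occ$motif == "ACGT"], 0)
  expect_equal(n_occ$mi[n_occ$motif == "ACGT"],
               mutual_information(2, 1, 10 - 2, 10 - 1), tolerance = 1e-12)
})

test_that("invalid parameters are rejected", {
  ss <- sequence_set(c("ACGT", "TTTT"))
  expect_error(discover(ss, ss, L = 4, alpha = 0), "alpha")
  expect_error(discover(ss, ss, L = 4, d = 5), "d <= L")
})
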