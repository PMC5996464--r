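# fixture reproducing the four-key worked example (fixed-position mode):
# positive words TACT x3, CATT x2, CAGT x2, CACT x1 against a negative set
# in which TACT and CATT never occur
worked_example <- function() {
  pos <- sequence_set(c("TACT", "TACT", "TACT", "CATT", "CATT", "CAGT",
                        "CAGT", "CACT"))
  neg <- sequence_set(c("CACT", "CACT", "CAGT", "GGGG", "TTTT", "AAAA",
                        "CCCC", "ACGT"))
  build_lmer_table(pos, neg, 4, mode = "fixed")
}

test_that("generalization follows the present-word rule of the worked example", {
  lat <- build_lattice(worked_example(), 4)
  nodes <- lattice_nodes(lat)
  # from CACT, position 2 only YACT (TACT present; AACT, GACT absent)
  expect_true("YACT" %in% nodes$motif)
  expect_false(any(c("MACT", "RACT", "WACT", "SACT", "KACT", "DACT",
                     "BACT", "HACT", "VACT", "NACT") %in% nodes$motif))
  # position 4 combinations of C,G,T: CAST, CAYT, CAKT, CABT
  expect_true(all(c("CAST", "CAYT", "CAKT", "CABT") %in% nodes$motif))
  # YAST is not a node: TAGT, an instance of it, is absent
  expect_false("YAST" %in% nodes$motif)
  # the node set is exactly the instance-closed family
  expect_setequal(nodes$motif,
                  c("CACT", "TACT", "CAGT", "CATT",
                    "YACT", "CAST", "CAYT", "CAKT", "CABT"))
})

test_that("lattice node sets equal the exhaustive 15^L filter", {
  set.seed(31)
  for (rep in 1:4) {
    keys <- random_words(30, 3)
    pos <- sequence_set(keys)
    neg <- sequence_set(random_words(10, 3))
    tbl <- build_lmer_table(pos, neg, 3, mode = "fixed")
    for (d in c(1L, 3L)) {
      lat <- build_lattice(tbl, d)
      expect_setequal(lattice_nodes(lat)$motif,
                      oracle_lattice_nodes(tbl$lmer, 3, d))
    }
  }
  # a single key admits no generalization at any d
  tbl1 <- build_lmer_table(sequence_set("ACG"), sequence_set("ACG"), 3,
                           mode = "fixed")
  expect_equal(lattice_nodes(build_lattice(tbl1, 3))$motif, "ACG")
  expect_error(build_lattice(tbl1, 5), "d must")
})

test_that("contingency tables use sequence-set unions, not occurrence sums", {
  lat <- build_lattice(worked_example(), 4)
  attach_tables(lat)
  nodes <- lattice_nodes(lat)
  rownames(nodes) <- nodes$motif
  # exact nodes: direct sequence counts
  expect_equal(nodes["TACT", "a"], 3)
  expect_equal(nodes["TACT", "b"], 0)
  expect_equal(nodes["CACT", "b"], 2)
  # union semantics: YACT covers the CACT and TACT sequences
  expect_equal(nodes["YACT", "a"], 4)
  expect_equal(nodes["YACT", "b"], 2)
  # margins hold at every node
  expect_true(all(nodes$a + nodes$c == 8))
  expect_true(all(nodes$b + nodes$d == 8))
  # occurrence totals are instance sums
  expect_equal(nodes["CABT", "occ_pos"], 1 + 2 + 2)
  # two instances in one sequence count that sequence once
  pos2 <- sequence_set(c("ACGTAAGT", "TTTTTTTT"))
  neg2 <- sequence_set("CCCCCCCC")
  lat2 <- build_lattice(build_lmer_table(pos2, neg2, 4), 4)
  attach_tables(lat2)
  n2 <- lattice_nodes(lat2)
  expect_equal(n2$a[n2$motif == "AMGT"], 1)       # union of {1} and {1}
  expect_equal(n2$occ_pos[n2$motif == "AMGT"], 2) # sum of occurrences
})

test_that("support is monotone along generalization edges", {
  lat <- build_lattice(worked_example(), 4)
  attach_tables(lat)
  nodes <- lattice_nodes(lat)
  for (i in seq_len(nrow(nodes))) for (j in seq_len(nrow(nodes))) {
    if (i == j) next
    ii <- oracle_instances(nodes$motif[i])
    jj <- oracle_instances(nodes$motif[j])
    if (all(ii %in% jj)) {
      expect_gte(nodes$a[j], nodes$a[i])
      expect_gte(nodes$b[j], nodes$b[i])
    }
  }
})

test_that("mutual information matches the entropy identity and its symmetries", {
  expect_equal(mutual_information(5, 5, 5, 5), 0)
  expect_equal(mutual_information(10, 0, 0, 10), 1)
  set.seed(32)
  tabs <- random_tables(500)
  mi <- mutual_information(tabs$a, tabs$b, tabs$c, tabs$d)
  mi_oracle <- mapply(oracle_mi, tabs$a, tabs$b, tabs$c, tabs$d)
  expect_equal(mi, mi_oracle, tolerance = 1e-12)
  # invariant under swapping datasets (columns) and presence/absence (rows)
  expect_equal(mi, mutual_information(tabs$b, tabs$a, tabs$d, tabs$c),
               tolerance = 1e-12)
  expect_equal(mi, mutual_information(tabs$c, tabs$d, tabs$a, tabs$b),
               tolerance = 1e-12)
  expect_error(mutual_information(0, 0, 0, 0), "empty")
})

test_that("attached node MI equals the R-level computation", {
  lat <- build_lattice(worked_example(), 4)
  attach_tables(lat)
  nodes <- lattice_nodes(lat)
  expect_equal(nodes$mi,
               mutual_information(nodes$a, nodes$b, nodes$c, nodes$d),
               tolerance = 1e-12)
})

test_that("dominance simplification keeps TACT over YACT in the worked example", {
  lat <- build_lattice(worked_example(), 4)
  attach_tables(lat)
  sel <- simplify_lattice(lat)
  expect_true("TACT" %in% sel$motif)
  expect_false("YACT" %in% sel$motif)
  mi <- lattice_nodes(lat)
  expect_gt(mi$mi[mi$motif == "TACT"], mi$mi[mi$motif == "YACT"])
  # selection order is decreasing MI
  expect_true(all(diff(sel$mi) <= 0))
})

test_that("simplification equals the greedy replay oracle and is an antichain", {
  set.seed(33)
  for (rep in 1:5) {
    keys <- random_words(25, 3)
    pos <- sequence_set(sample(keys, 40, replace = TRUE))
    neg <- sequence_set(random_words(30, 3))
    tbl <- build_lmer_table(pos, neg, 3, mode = "fixed")
    lat <- build_lattice(tbl, 3)
    attach_tables(lat)
    sel <- simplify_lattice(lat)
    expect_equal(sel$motif, oracle_simplify(lattice_nodes(lat)))
    # antichain: no two selected motifs are instance-nested
    inst <- lapply(sel$motif, oracle_instances)
    for (i in seq_along(inst)) for (j in seq_along(inst)) {
      if (i != j) expect_false(all(inst[[i]] %in% inst[[j]]))
    }
  }
})

test_that("masking removes exactly the instance-sharing closure", {
  lat <- build_lattice(worked_example(), 4)
  attach_tables(lat)
  mask_motif(lat, "CABT")
  st <- motif_status(lat, c("CABT", "CAST", "CAYT", "CAKT", "YACT",
                            "CACT", "CAGT", "CATT", "TACT"))
  expect_equal(st, c(rep("removed", 8), "active"))
  # masking an exact motif removes it and all its ancestors
  lat2 <- build_lattice(worked_example(), 4)
  attach_tables(lat2)
  mask_motif(lat2, "TACT")
  expect_equal(motif_status(lat2, c("TACT", "YACT")), c("removed", "removed"))
  expect_equal(motif_status(lat2, "CACT"), "active")
  expect_error(mask_motif(lat2, "GGGG"), "not a lattice node")
})

test_that("after masking, active nodes share no instance with the mask", {
  set.seed(34)
  for (rep in 1:5) {
    keys <- random_words(25, 3)
    tbl <- build_lmer_table(sequence_set(keys),
                            sequence_set(random_words(10, 3)), 3,
                            mode = "fixed")
    lat <- build_lattice(tbl, 3)
    attach_tables(lat)
    nodes <- lattice_nodes(lat)
    m <- sample(nodes$motif, 1)
    mask_motif(lat, m)
    after <- lattice_nodes(lat)
    masked_inst <- oracle_instances(m)
    for (k in seq_len(nrow(after))) {
      shares <- any(oracle_instances(after$motif[k]) %in% masked_inst)
      expect_equal(after$status[k] == "removed", shares, info = after$motif[k])
    }
  }
})

test_that("a released lattice refuses further use", {
  lat <- build_lattice(worked_example(), 4)
  dismotif:::release_lattice(lat)
  expect_error(lattice_info(lat), "released")
})
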