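# Independent oracles used to freeze expected values: these re-derive
# results by brute force (enumeration, closed forms) without touching the
# package's own code paths.

# independent IUPAC map (keyed by sorted base string)
oracle_iupac <- c(
  A = "A", C = "C", G = "G", T = "T",
  AC = "M", AG = "R", AT = "W", CG = "S", CT = "Y", GT = "K",
  CGT = "B", AGT = "D", ACT = "H", ACG = "V", ACGT = "N"
)
oracle_letters <- setNames(names(oracle_iupac), oracle_iupac)

# brute-force instance enumeration by recursive expansion
oracle_instances <- function(motif) {
  chars <- strsplit(motif, "")[[1]]
  sets <- lapply(chars, function(ch) strsplit(oracle_letters[[ch]], "")[[1]])
  words <- ""
  for (s in sets) words <- as.vector(outer(words, s, paste0))
  sort(words)
}

# all 15^L IUPAC motifs of length L (L small)
oracle_all_motifs <- function(L) {
  syms <- unname(oracle_iupac)
  words <- ""
  for (i in seq_len(L)) words <- as.vector(outer(words, syms, paste0))
  words
}

# brute-force lattice node set: instance-closed motifs with <= d degenerate
# characters
oracle_lattice_nodes <- function(keys, L, d) {
  cand <- oracle_all_motifs(L)
  deg <- vapply(cand, function(m) {
    sum(nchar(oracle_letters[strsplit(m, "")[[1]]]) >= 2)
  }, numeric(1))
  cand <- cand[deg <= d]
  cand[vapply(cand, function(m) all(oracle_instances(m) %in% keys),
              logical(1))]
}

# entropy-identity MI oracle: MI = H(row) + H(col) - H(joint), in bits
oracle_mi <- function(a, b, c, d) {
  n <- a + b + c + d
  ent <- function(p) {
    p <- p[p > 0] / n
    -sum(p * log2(p))
  }
  ent(c(a + b, c + d)) + ent(c(a + c, b + d)) - ent(c(a, b, c, d))
}

# exhaustive hypergeometric tail: enumerate every table with the same
# margins and sum the probabilities of those at least as extreme in a
oracle_fisher_greater <- function(a, b, c, d) {
  n <- a + b + c + d
  ks <- max(0, (a + b) - (b + d)):min(a + b, a + c)
  prob <- choose(a + b, ks) * choose(c + d, (a + c) - ks) / choose(n, a + c)
  stopifnot(abs(sum(prob) - 1) < 1e-9)
  sum(prob[ks >= a])
}

# direct step-down Holm formula
oracle_holm <- function(p) {
  m <- length(p)
  o <- order(p)
  adj <- pmin(1, cummax((m - seq_len(m) + 1) * p[o]))
  out <- numeric(m)
  out[o] <- adj
  out
}

# greedy dominance replay over a materialized ancestor/descendant relation
# (containment of instance sets), with the package's documented tie-breaks
oracle_simplify <- function(nodes) {
  inst <- lapply(nodes$motif, oracle_instances)
  n <- nrow(nodes)
  related <- outer(seq_len(n), seq_len(n), Vectorize(function(i, j) {
    i != j && (all(inst[[i]] %in% inst[[j]]) || all(inst[[j]] %in% inst[[i]]))
  }))
  canon <- c("A", "C", "G", "T", "M", "R", "W", "S", "Y", "K", "V", "H",
             "D", "B", "N")
  lex <- vapply(nodes$motif, function(m) {
    paste0(letters[match(strsplit(m, "")[[1]], canon)], collapse = "")
  }, character(1))
  ord <- order(-nodes$mi, -nodes$a, lex)
  state <- rep("active", n)
  sel <- integer(0)
  for (i in ord) {
    if (state[i] != "active") next
    state[i] <- "selected"
    sel <- c(sel, i)
    state[related[i, ] & state == "active"] <- "removed"
  }
  nodes$motif[sel]
}

# random 2x2 tables with positive total
random_tables <- function(n, max_cell = 30) {
  data.frame(a = sample.int(max_cell + 1, n, replace = TRUE) - 1,
             b = sample.int(max_cell + 1, n, replace = TRUE) - 1,
             c = sample.int(max_cell + 1, n, replace = TRUE) - 1,
             d = sample.int(max_cell + 1, n, replace = TRUE) - 1) |>
    subset(a + b + c + d > 0)
}

random_motif <- function(L, symbols = unname(oracle_iupac)) {
  paste0(sample(symbols, L, replace = TRUE), collapse = "")
}

random_words <- function(n, L) {
  unique(vapply(seq_len(n), function(i) {
    paste0(sample(c("A", "C", "G", "T"), L, replace = TRUE), collapse = "")
  }, character(1)))
}
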