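# Fixtures are built in code; nothing is read from disk except files the
# tests themselves write into tempdirs.

AA20 <- setdiff(lc_alphabet(), LC_GAP)

# Deterministic synthetic germline with the conserved-gap windows (58-64,
# CDR3 110-113) empty, as in human light chains.
fixture_germline <- function(gene = "IGLVT-1", allele = "*01", seed = 42) {
  withr::with_seed(seed, {
    res <- sample(AA20, IMGT_LENGTH, replace = TRUE)
    res[c(58:64, 110:113)] <- LC_GAP
    # pin a few positions the tests edit, so edits are real changes
    res[20] <- "S"; res[25] <- "R"; res[37] <- "G"; res[40] <- "N"
    res[52] <- "L"; res[94] <- "L"
    germline_allele(gene, allele, res)
  })
}

# n copies of the germline as a sequence set, with optional point edits
# given as list(list(row, position, residue), ...)
fixture_set <- function(germline, n, cohort = "AL", edits = list()) {
  res <- matrix(germline$residues, nrow = n, ncol = IMGT_LENGTH, byrow = TRUE)
  for (e in edits) res[e[[1]], e[[2]]] <- e[[3]]
  sequence_set(res, gene = germline$gene, cohort = cohort)
}

# Registry with three genes differing at a handful of positions.
fixture_registry <- function() {
  g1 <- fixture_germline("IGLVT-1", seed = 42)
  r2 <- g1$residues; r2[37] <- "D"; r2[20] <- "A"
  g2 <- germline_allele("IGLVT-2", "*01", r2)
  r3 <- g1$residues; r3[20] <- "S"; r3[25] <- "R"
  g3 <- germline_allele("IGLVT-3", "*01", r3)
  germline_registry(list(g1, g2, g3))
}

# Random valid residue matrix (for property tests)
fixture_random_set <- function(n, gene = "IGLVT-1", cohort = "AL", seed = 1) {
  withr::with_seed(seed,
    sequence_set(matrix(sample(lc_alphabet(), n * IMGT_LENGTH, replace = TRUE),
                        nrow = n),
                 gene = gene, cohort = cohort))
}

# Random consensus matrix from a small random set
fixture_random_matrix <- function(n = 5, gene = "IGLVT-1", cohort = "AL",
                                  seed = 1) {
  build_consensus(fixture_random_set(n, gene, cohort, seed))
}

# Independent step-up BH oracle (rank-wise, no p.adjust)
bh_oracle <- function(p) {
  m <- length(p)
  o <- order(p)
  q_sorted <- p[o] * m / seq_len(m)
  q_sorted <- rev(cummin(rev(q_sorted)))
  q <- numeric(m)
  q[o] <- pmin(q_sorted, 1)
  q
}
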