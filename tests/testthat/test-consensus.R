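test_that("consensus counts conserve the set size at every position", {
  gl <- fixture_germline()
  set <- fixture_set(gl, 2)
  m <- build_consensus(set)
  expect_true(all(rowSums(m$counts) == 2))
  expect_equal(rowSums(m$fractions), rep(1, 127), tolerance = 1e-9,
               ignore_attr = TRUE)
  # identical sequences: fraction 1 at the sequence symbol, 0 elsewhere
  expect_true(all(consensus_fraction(m, 1:127, gl$residues) == 1))

  rnd <- fixture_random_set(9, seed = 7)
  mr <- build_consensus(rnd)
  expect_true(all(rowSums(mr$counts) == 9))
  expect_equal(rowSums(mr$fractions), rep(1, 127), tolerance = 1e-9,
               ignore_attr = TRUE)
})

test_that("consensus equals a per-cell tabulation oracle", {
  set <- fixture_random_set(6, seed = 11)
  m <- build_consensus(set)
  for (p in c(1, 58, 94, 127)) for (s in c("A", "V", LC_GAP)) {
    expect_equal(m$counts[p, s], sum(set$residues[, p] == s))
  }
})

test_that("adding one sequence increments exactly 127 count cells by 1", {
  gl <- fixture_germline()
  base <- fixture_random_set(5, seed = 2)
  bigger <- sequence_set(rbind(base$residues, gl$residues),
                         gene = base$gene, cohort = base$cohort)
  d <- build_consensus(bigger)$counts - build_consensus(base)$counts
  expect_true(all(d %in% c(0L, 1L)))
  expect_equal(sum(d), 127)
})

test_that("empty or invalid sets are refused", {
  expect_error(sequence_set(matrix(character(0), 0, 127), "g", "AL"),
               "at least one")
  set <- fixture_set(fixture_germline(), 2)
  set$residues[1, 5] <- "X"
  expect_error(build_consensus(set), "non-alphabet")
})

test_that("difference matrices are antisymmetric with zero row sums", {
  a <- fixture_random_matrix(6, seed = 1)
  b <- fixture_random_matrix(4, seed = 2)
  d <- difference_matrix(a, b)
  expect_equal(rowSums(d$values), rep(0, 127), tolerance = 1e-9,
               ignore_attr = TRUE)
  expect_true(all(d$values >= -1 & d$values <= 1))
  expect_equal(d$values, -difference_matrix(b, a)$values)
  expect_true(all(difference_matrix(a, a)$values == 0))
  c_other <- fixture_random_matrix(3, gene = "IGLVT-2", seed = 3)
  expect_error(difference_matrix(a, c_other), "gene mismatch")
})

test_that("a two-residue shift shows up only in its own row", {
  gl <- fixture_germline()
  gl$residues[5] <- "G"
  a <- build_consensus(fixture_set(gl, 10, edits = lapply(1:6, function(i)
    list(i, 5, "A"))))
  b <- build_consensus(fixture_set(gl, 10, edits = lapply(1:5, function(i)
    list(i, 5, "A"))))
  d <- difference_matrix(a, b)$values
  expect_equal(d[5, "A"], 0.1)
  expect_equal(sum(abs(d)), 0.2)  # +0.1 for A, -0.1 for the germline residue
})

test_that("Gini hits its endpoints and the derived two-mass value", {
  point <- c(1, rep(0, 20))
  uniform <- rep(1 / 21, 21)
  two <- c(0.5, 0.5, rep(0, 19))
  m <- consensus_from_counts(
    matrix(c(rep(c(20L, rep(0L, 20)), 50),
             rep(rep(0L, 21), 0),
             rep(c(20L, rep(0L, 20)), 77)),
           nrow = 127, ncol = 21, byrow = TRUE), "g", "x")
  expect_equal(unname(position_gini(m, 1)), 1)
  expect_equal(lcprofiler:::.gini(point), 1)
  expect_equal(lcprofiler:::.gini(uniform), 0)
  expect_equal(lcprofiler:::.gini(two), 0.95)
  # against the mean-absolute-difference definition, corrected
  mad_gini <- function(x) {
    n <- length(x); mu <- mean(x)
    sum(abs(outer(x, x, "-"))) / (2 * n^2 * mu) * n / (n - 1)
  }
  for (seed in 1:5) {
    x <- withr::with_seed(seed, stats::runif(21))
    x <- x / sum(x)
    expect_equal(lcprofiler:::.gini(x), mad_gini(x), tolerance = 1e-12)
  }
})

test_that("Gini is permutation-invariant and monotone under transfers", {
  x <- c(0.4, 0.3, 0.2, 0.1, rep(0, 17))
  for (seed in 1:5) {
    perm <- withr::with_seed(seed, sample(x))
    expect_equal(lcprofiler:::.gini(perm), lcprofiler:::.gini(x))
  }
  # Robin-Hood transfer: moving mass from a larger to a smaller entry
  # never increases inequality
  y <- x; y[1] <- y[1] - 0.05; y[4] <- y[4] + 0.05
  expect_lte(lcprofiler:::.gini(y), lcprofiler:::.gini(x))
})

test_that("position correlation matches the indicator closed form", {
  gl <- fixture_germline()
  a <- build_consensus(fixture_set(gl, 3, edits = list(list(1, 10, "W"))))
  paa <- position_correlation(a, a)
  expect_equal(paa$rho[!paa$undefined], rep(1, sum(!paa$undefined)),
               tolerance = 1e-12)

  ga <- gl; ga$residues[5] <- "A"
  gg <- gl; gg$residues[5] <- "G"
  ma <- build_consensus(fixture_set(ga, 2))
  mg <- build_consensus(fixture_set(gg, 2))
  pc <- position_correlation(ma, mg)
  expect_equal(pc$rho[pc$position == 5], -1 / 20)

  # zero-variance rows are flagged undefined, not silently dropped
  ua <- consensus_from_counts(matrix(1L, 127, 21), "IGLVT-1", "u")
  pc2 <- position_correlation(ua, ma)
  expect_true(all(pc2$undefined))
  expect_true(all(is.na(pc2$rho)))
})

test_that("matrix distance matches a loop oracle and the metric axioms", {
  a <- fixture_random_matrix(5, seed = 4)
  b <- fixture_random_matrix(7, seed = 5)
  brute <- 0
  for (p in 1:127) for (k in 1:21)
    brute <- brute + (a$fractions[p, k] - b$fractions[p, k])^2
  expect_equal(matrix_distance(a, b), sqrt(brute), tolerance = 1e-12)
  expect_equal(matrix_distance(a, a), 0)

  # two-cell case: {A:+0.1, G:-0.1} at one position
  gl <- fixture_germline("IGLVT-1", seed = 42)
  gl$residues[5] <- "A"
  x <- build_consensus(fixture_set(gl, 10, edits = lapply(1:5, function(i)
    list(i, 5, "G"))))
  y <- build_consensus(fixture_set(gl, 10, edits = lapply(1:4, function(i)
    list(i, 5, "G"))))
  expect_equal(matrix_distance(x, y), sqrt(0.01 + 0.01), tolerance = 1e-12)

  for (seed in 1:5) {
    ms <- lapply(1:3, function(i) fixture_random_matrix(4, seed = seed * 10 + i))
    dab <- matrix_distance(ms[[1]], ms[[2]])
    dba <- matrix_distance(ms[[2]], ms[[1]])
    dac <- matrix_distance(ms[[1]], ms[[3]])
    dcb <- matrix_distance(ms[[3]], ms[[2]])
    expect_equal(dab, dba)
    expect_lte(dab, dac + dcb + 1e-12)
    expect_gte(dab, 0)
  }
})

test_that("clustering merges the closest pair first and exports newick", {
  gl <- fixture_germline()
  a <- build_consensus(fixture_set(gl, 10, cohort = "AL",
                                   edits = list(list(1, 5, "W"))))
  b <- build_consensus(fixture_set(gl, 10, cohort = "MM",
                                   edits = list(list(1, 5, "W"), list(2, 7, "H"))))
  far <- fixture_random_matrix(10, cohort = "OAS", seed = 9)
  dend <- cluster_matrices(list(a, b, far))
  expect_equal(sort(abs(dend$hclust$merge[1, ])), c(1, 2))  # a,b first
  expect_true(all(diff(dend$hclust$height) >= 0))
  nwk <- as_newick(dend)
  expect_equal(length(ape::read.tree(text = nwk)$tip.label), 3)

  same <- cluster_matrices(list(a, a, a))
  expect_true(all(same$hclust$height == 0))
  expect_error(cluster_matrices(list(a)), "at least two")
})

test_that("logo data drops the single most frequent residue per position", {
  gl <- fixture_germline()
  gl$residues[5] <- "A"
  set <- fixture_set(gl, 10, edits = c(lapply(1:2, function(i) list(i, 5, "G")),
                                       list(list(3, 5, "S"))))
  logo <- logo_data(build_consensus(set))
  row5 <- logo[logo$position == 5, ]
  expect_setequal(row5$residue, c("G", "S"))
  expect_equal(row5$height[row5$residue == "G"], 0.2)
  expect_equal(row5$height[row5$residue == "S"], 0.1)

  # point-mass positions contribute no letters
  expect_false(6 %in% logo$position)

  # tie at 0.5/0.5: the alphabet-first residue is excluded
  tie <- fixture_set(gl, 2, edits = list(list(1, 5, "G")))  # A and G at 0.5
  lt <- logo_data(build_consensus(tie))
  r5 <- lt[lt$position == 5, ]
  expect_identical(r5$residue, "G")
  expect_equal(r5$height, 0.5)
})

test_that("logo heights per position sum to 1 minus the max fraction", {
  m <- fixture_random_matrix(8, seed = 12)
  logo <- logo_data(m)
  for (p in unique(logo$position)) {
    expect_equal(sum(logo$height[logo$position == p]),
                 1 - max(m$fractions[p, ]), tolerance = 1e-9)
  }
})

test_that("fraction matrices with stated n reconstruct valid counts", {
  m <- fixture_random_matrix(9, seed = 13)
  back <- consensus_from_fractions(m$fractions, m$n, m$gene, m$cohort)
  expect_equal(back$counts, m$counts, ignore_attr = TRUE)
  expect_error(consensus_from_fractions(m$fractions, m$n + 1, m$gene, m$cohort),
               "not consistent")
})
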