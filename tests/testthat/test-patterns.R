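test_that("pattern labels parse into the documented kinds", {
  g <- parse_pattern("X86N")
  expect_identical(g$kind, "gain")
  expect_equal(g$position, 86)
  expect_identical(g$residues, "N")

  l <- parse_pattern("ST20X")
  expect_identical(l$kind, "loss")
  expect_equal(l$position, 20)
  expect_setequal(l$residues, c("S", "T"))

  e <- parse_pattern("K56DE", gene_scope = "IGKV1-5")
  expect_identical(e$kind, "exact")
  expect_setequal(e$residues, c("D", "E"))
  expect_identical(e$germline_set, "K")

  ins <- parse_pattern("P115PP")
  expect_identical(ins$kind, "insertion_PP")
  expect_equal(ins$position, 115)

  u <- parse_pattern("U52")
  expect_identical(u$kind, "any_uncommon")

  expect_error(parse_pattern("foo"), "unparseable")
  expect_error(parse_pattern("X20X"), "unparseable")
})

test_that("labels round-trip through the parser", {
  for (lab in c("X86N", "ST20X", "I29X", "K56DE", "P115PP", "R25G", "X37D")) {
    p1 <- parse_pattern(lab)
    p2 <- parse_pattern(p1$label)
    expect_identical(p2[c("kind", "position", "residues", "germline_set")],
                     p1[c("kind", "position", "residues", "germline_set")])
  }
})

test_that("gene eligibility excludes impossible changes", {
  reg <- fixture_registry()  # IGLVT-2 has D at 37 and A at 20; IGLVT-3 S at 20
  gain <- parse_pattern("X37D")
  eg <- eligible_genes(gain, reg)
  expect_false("IGLVT-2" %in% eg)   # already has the gained residue
  expect_true("IGLVT-1" %in% eg)

  loss <- parse_pattern("ST20X")
  el <- eligible_genes(loss, reg)
  expect_false("IGLVT-2" %in% el)   # A at 20: nothing to lose
  expect_true("IGLVT-3" %in% el)    # S at 20

  exact <- parse_pattern("R25G", gene_scope = "IGLVT-3")
  expect_identical(eligible_genes(exact, reg), "IGLVT-3")

  # post-eligibility invariant: no eligible gene's germline residue is in
  # the gained set
  for (g in eg)
    expect_false(reference_allele_of(reg, g)$residues[37] %in% gain$residues)
})

test_that("sequence matching follows gain/loss/exact semantics", {
  gl <- fixture_germline()
  gl$residues[86] <- "D"
  gain <- parse_pattern("X86N")
  res <- gl$residues; res[86] <- "N"
  expect_true(sequence_matches(gain, res, gl))
  expect_false(sequence_matches(gain, gl$residues, gl))
  # a gap never counts as the gained residue
  res_gap <- gl$residues; res_gap[86] <- LC_GAP
  expect_false(sequence_matches(gain, res_gap, gl))

  gl$residues[72] <- "P"
  loss <- parse_pattern("P72X")
  res2 <- gl$residues; res2[72] <- "S"
  expect_true(sequence_matches(loss, res2, gl))
  expect_false(sequence_matches(loss, gl$residues, gl))
  # observed gap counts as a loss under the default, not with the switch off
  res3 <- gl$residues; res3[72] <- LC_GAP
  expect_true(sequence_matches(loss, res3, gl))
  expect_false(sequence_matches(loss, res3, gl, gap_counts_as_loss = FALSE))

  gl$residues[25] <- "R"
  exact <- parse_pattern("R25G", gene_scope = gl$gene)
  res4 <- gl$residues; res4[25] <- "G"
  expect_true(sequence_matches(exact, res4, gl))
  expect_false(sequence_matches(exact, gl$residues, gl))
})

test_that("any-uncommon patterns delegate to the rarity classifier", {
  gl <- fixture_germline()
  ref <- build_consensus(fixture_set(gl, 100, cohort = "OAS",
                                     edits = lapply(1:5, function(i)
                                       list(i, 52, "W"))))
  u <- parse_pattern("U52")
  res <- gl$residues; res[52] <- "W"   # 5% in reference -> uncommon
  expect_true(sequence_matches(u, res, gl, reference = ref))
  expect_false(sequence_matches(u, gl$residues, gl, reference = ref))
  expect_error(sequence_matches(u, res, gl), "reference")
})

test_that("the CDR3 proline insertion rule needs both conditions", {
  gl <- fixture_germline()
  gl$residues[114] <- "S"; gl$residues[115] <- "P"; gl$residues[116] <- "T"
  # germline-like CDR3: single P at 115, no insertion
  expect_false(detect_p115pp(gl$residues, gl))
  # insertion at 111 plus P at 114 and 115 -> adjacent prolines
  res <- gl$residues; res[111] <- "A"; res[114] <- "P"
  expect_true(detect_p115pp(res, gl))
  # insertion but no second proline
  res2 <- gl$residues; res2[111] <- "A"
  expect_false(detect_p115pp(res2, gl))
  # two prolines but no insertion into 110-113
  res3 <- gl$residues; res3[114] <- "P"
  expect_false(detect_p115pp(res3, gl))
  # adjacency skips gap slots: insertion at 113 only, P at 113 and 115
  # with 114 deleted -> occupied neighbors 113,115 both P
  res4 <- gl$residues; res4[113] <- "P"; res4[115] <- "P"; res4[114] <- LC_GAP
  expect_true(detect_p115pp(res4, gl))
})

test_that("pattern counting equals a naive per-sequence oracle", {
  reg <- fixture_registry()
  pats <- list(parse_pattern("X37D"), parse_pattern("ST20X"),
               parse_pattern("R25G", gene_scope = "IGLVT-3"))
  sets <- lapply(reg$genes, function(g) {
    gl <- reference_allele_of(reg, g)
    simulate_repertoire(simulation_config(
      gl, 30, cohort = "AL", seed = 7 + match(g, reg$genes)))$set
  })
  for (pat in pats) {
    pc <- count_pattern(pat, sets, reg)
    elig <- eligible_genes(pat, reg, genes = reg$genes)
    carriers <- 0L; eligible_n <- 0L
    for (s in sets) {
      if (!(s$gene %in% elig)) next
      gl <- reference_allele_of(reg, s$gene)
      eligible_n <- eligible_n + length(s)
      for (i in seq_len(length(s)))
        carriers <- carriers + sequence_matches(pat, s$residues[i, ], gl)
    }
    expect_equal(pc$carriers, carriers)
    expect_equal(pc$eligible_n, eligible_n)
    expect_lte(pc$carriers, pc$eligible_n)
    expect_equal(sum(pc$per_gene$carriers), pc$carriers)
    expect_equal(sum(pc$per_gene$eligible_n), pc$eligible_n)
  }
})

test_that("ineligible genes contribute nothing to the denominator", {
  reg <- fixture_registry()
  pat <- parse_pattern("X37D")
  gl2 <- reference_allele_of(reg, "IGLVT-2")  # germline D at 37: ineligible
  set2 <- fixture_set(gl2, 10, cohort = "AL")
  pc <- count_pattern(pat, list(set2), reg)
  expect_equal(pc$eligible_n, 0)
  expect_equal(pc$carriers, 0)
})

test_that("a fully matching cohort saturates its eligible denominator", {
  reg <- fixture_registry()
  gl <- reference_allele_of(reg, "IGLVT-1")
  pat <- parse_pattern("X37D")
  set <- fixture_set(gl, 8, cohort = "AL",
                     edits = lapply(1:8, function(i) list(i, 37, "D")))
  pc <- count_pattern(pat, list(set), reg)
  expect_equal(pc$carriers, pc$eligible_n)
})

test_that("pattern enrichment reproduces printed worked examples", {
  cfg <- enrichment_config()
  r75n <- pattern_enrichment(carrier_table(7, 23, 0, 5), cfg)
  expect_equal(signif(r75n$ratio, 2), 16)
  x76v <- pattern_enrichment(carrier_table(1, 192, 31514, 4295181), cfg)
  expect_equal(round(x76v$ratio, 2), 0.78)
  eq <- pattern_enrichment(carrier_table(10, 100, 10, 100), cfg)
  expect_equal(eq$ratio, 1)
})

test_that("published carrier counts reproduce the printed ratios", {
  pub <- published_changes()
  expect_gt(nrow(pub), 40)
  sig_digits <- function(x) {
    s <- as.character(x)
    s <- sub("^0\\.0*", "", s)      # leading zeros of a decimal
    s <- sub("\\.", "", s)
    s <- sub("0+$", "", s)          # trailing zeros: not significant here
    max(nchar(s), 1L)
  }
  for (i in seq_len(nrow(pub))) {
    r_mm <- corrected_ratio(carrier_table(pub$al_a[i], pub$al_n[i],
                                          pub$mm_a[i], pub$mm_n[i]))
    r_oas <- corrected_ratio(carrier_table(pub$al_a[i], pub$al_n[i],
                                           pub$oas_a[i], pub$oas_n[i]))
    expect_equal(signif(r_mm, sig_digits(pub$or_al_mm[i])), pub$or_al_mm[i],
                 info = paste(pub$label[i], "AL vs MM"))
    expect_equal(signif(r_oas, sig_digits(pub$or_al_oas[i])), pub$or_al_oas[i],
                 info = paste(pub$label[i], "AL vs OAS"))
  }
})

test_that("pattern files parse and bad lines are named", {
  path <- tempfile(fileext = ".tsv")
  writeLines(c("ALL_KV\tX86N", "IGKV1-33\tY103H"), path)
  pats <- read_pattern_file(path)
  expect_length(pats, 2)
  expect_null(pats[[1]]$gene_scope)
  expect_identical(pats[[2]]$gene_scope, "IGKV1-33")

  bad <- tempfile(fileext = ".tsv")
  writeLines(c("ALL_KV\tX86N", "IGKV1-33\t???"), bad)
  expect_error(read_pattern_file(bad), "line 2")
  empty <- tempfile(fileext = ".tsv")
  writeLines(character(0), empty)
  expect_error(read_pattern_file(empty), "empty")
})
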