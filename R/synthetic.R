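#' Per-position mutation-rate profile with a target mean
#'
#' Builds the per-position somatic residue-change probabilities for the
#' simulator. Rates are spread over the germline's occupied (non-gap)
#' positions so that they sum to \code{target_mean} -- the expected number
#' of residue changes per sequence (default 10; a typical light chain
#' accumulates 5-15). Hotspot positions receive \code{hotspot_weight} times
#' the base weight. Germline gap positions get rate 0 (insertions are not
#' simulated by default).
#'
#' @param germline A \code{\link{germline_allele}}.
#' @param target_mean Expected residue changes per sequence (>= 0).
#' @param hotspot_positions Optional positions to up-weight.
#' @param hotspot_weight Multiplicative weight for hotspots (default 1).
#' @return Numeric vector of 127 per-position probabilities summing to
#'   \code{target_mean}; errors if any single rate would exceed 1.
#' @export
make_mean_changes_profile <- function(germline, target_mean = 10,
                                      hotspot_positions = NULL,
                                      hotspot_weight = 1) {
  if (target_mean < 0) stop("target_mean must be >= 0")
  occupied <- which(germline$residues != LC_GAP)
  w <- rep(0, IMGT_LENGTH)
  w[occupied] <- 1
  if (!is.null(hotspot_positions)) {
    if (any(!(hotspot_positions %in% occupied)))
      stop("hotspot positions must be occupied in the germline")
    w[hotspot_positions] <- hotspot_weight
  }
  if (target_mean == 0) return(rep(0, IMGT_LENGTH))
  rates <- target_mean * w / sum(w)
  if (any(rates > 1))
    stop("infeasible profile: a per-position rate exceeds 1")
  rates
}

#' Simulation configuration for a synthetic cohort
#'
#' Describes one cohort of germline-derived light chains: the germline
#' backbone(s) with allele frequencies, per-position residue-change rates,
#' the replacement distribution, optional planted enrichment effects, and
#' the seed. A planted effect at a position multiplies that position's
#' carrier rate by \code{multiplier} (capped at 1) and forces carriers to a
#' single specified residue, so the uncommon-carrier rate ratio against an
#' unplanted cohort equals the multiplier by construction.
#'
#' @param germline A \code{\link{germline_allele}} (the reference
#'   backbone), or a list of alleles with \code{allele_frequencies}.
#' @param n Number of sequences to draw.
#' @param cohort Cohort label, e.g. \code{"AL"} or \code{"OAS"}.
#' @param rates Per-position change probabilities (default
#'   \code{\link{make_mean_changes_profile}} with mean 10).
#' @param gap_prob Probability that a change at an occupied position is a
#'   deletion to gap (default 0.01).
#' @param substitution Optional named list mapping a germline residue to a
#'   named probability vector over replacement symbols; the default is
#'   uniform over the 19 non-germline amino acids (after the gap draw).
#' @param allele_frequencies Sampling probabilities over the allele list.
#' @param planted_effects List of \code{list(position=, residue=,
#'   multiplier=)} entries; positions must be distinct and occupied.
#' @param seed Integer seed; the draw is fully reproducible from it.
#' @return Object of class \code{simulation_config}.
#' @export
simulation_config <- function(germline, n, cohort = "synthetic", rates = NULL,
                              gap_prob = 0.01, substitution = NULL,
                              allele_frequencies = NULL,
                              planted_effects = list(), seed = NULL) {
  alleles <- if (inherits(germline, "germline_allele")) list(germline) else germline
  for (a in alleles)
    if (!inherits(a, "germline_allele")) stop("germline must be germline_allele(s)")
  if (is.null(allele_frequencies)) allele_frequencies <- rep(1 / length(alleles), length(alleles))
  if (length(allele_frequencies) != length(alleles))
    stop("one frequency per allele required")
  if (abs(sum(allele_frequencies) - 1) > 1e-8 || any(allele_frequencies < 0))
    stop("allele frequencies must be non-negative and sum to 1")
  if (is.null(rates)) rates <- make_mean_changes_profile(alleles[[1]])
  if (length(rates) != IMGT_LENGTH || any(rates < 0 | rates > 1))
    stop("rates must be 127 probabilities")
  if (gap_prob < 0 || gap_prob > 1) stop("gap_prob must be a probability")
  pp <- vapply(planted_effects, function(e) as.integer(e$position), integer(1))
  if (anyDuplicated(pp)) stop("planted effect positions must be distinct")
  for (e in planted_effects) {
    if (!(e$residue %in% setdiff(lc_alphabet(), LC_GAP)))
      stop("planted residue must be a standard amino acid")
    if (e$multiplier <= 0) stop("planted multipliers must be > 0")
    if (alleles[[1]]$residues[e$position] == LC_GAP)
      stop("planted position must be occupied in the germline")
  }
  structure(list(alleles = alleles, allele_frequencies = allele_frequencies,
                 n = as.integer(n), cohort = cohort, rates = rates,
                 gap_prob = gap_prob, substitution = substitution,
                 planted_effects = planted_effects, seed = seed),
            class = "simulation_config")
}

#' Add a germline allele polymorphism to a simulation config
#'
#' Extends the config with a second allele that differs from the reference
#' backbone at one position (e.g. an R/G polymorphism at position 25) and
#' sets the allele sampling frequencies.
#'
#' @param config A \code{\link{simulation_config}}.
#' @param position Polymorphic position.
#' @param residue The variant allele's residue at that position.
#' @param frequency Sampling frequency of the variant allele.
#' @param allele_id Suffix for the new allele (default \code{"*02"}).
#' @return The extended config.
#' @export
plant_allele_polymorphism <- function(config, position, residue, frequency,
                                      allele_id = "*02") {
  if (frequency < 0 || frequency > 1) stop("frequency must be a probability")
  planted_pos <- vapply(config$planted_effects, function(e) e$position, numeric(1))
  if (position %in% planted_pos)
    stop("position conflicts with an existing planted effect")
  ref <- config$alleles[[1]]
  res <- ref$residues
  res[position] <- residue
  config$alleles <- c(config$alleles,
                      list(germline_allele(ref$gene, allele_id, res)))
  config$allele_frequencies <- c((1 - frequency) * config$allele_frequencies,
                                 frequency)
  config
}

# replacement symbols for m changed cells whose backbone symbols are `bk`
.draw_replacements <- function(bk, gap_prob, substitution) {
  m <- length(bk)
  out <- character(m)
  if (!is.null(substitution)) {
    for (b in unique(bk)) {
      i <- which(bk == b)
      dist <- substitution[[b]]
      if (is.null(dist)) stop("no substitution distribution for residue ", b)
      out[i] <- sample(names(dist), length(i), replace = TRUE, prob = dist)
    }
    return(out)
  }
  aa <- setdiff(lc_alphabet(), LC_GAP)
  to_gap <- stats::runif(m) < gap_prob
  out[to_gap] <- LC_GAP
  i <- which(!to_gap)
  if (length(i)) {
    bi <- match(bk[i], aa)
    r <- sample.int(19L, length(i), replace = TRUE)
    r <- r + (r >= bi)   # skip the backbone residue
    out[i] <- aa[r]
  }
  out
}

#' Simulate a cohort of germline-derived light chains
#'
#' Each sequence is drawn by (i) sampling an allele backbone, (ii) mutating
#' each non-planted position independently with its configured rate,
#' drawing the replacement from the substitution distribution (default
#' uniform over the 19 non-germline residues, with a small gap
#' probability), and (iii) at planted positions, forcing the effect residue
#' with probability \code{min(1, multiplier x rate)} and otherwise leaving
#' the backbone residue. Fully reproducible from the config's seed;
#' sequences are drawn in index order so enlarging \code{n} never
#' reshuffles earlier sequences.
#'
#' @param config A \code{\link{simulation_config}}.
#' @return \code{list(set = sequence_set, truth = list(...))} where
#'   \code{truth} records, per sequence, the drawn allele and changed
#'   positions, the planted-effect carrier flags, and per-position realized
#'   change rates -- all recomputable by diffing the emitted sequences
#'   against their backbones.
#' @export
simulate_repertoire <- function(config) {
  stopifnot(inherits(config, "simulation_config"))
  if (!is.null(config$seed)) set.seed(config$seed)
  n <- config$n
  gene <- config$alleles[[1]]$gene
  allele_labels <- vapply(config$alleles, `[[`, character(1), "allele")

  ai <- if (length(config$alleles) == 1L) rep(1L, n)
        else sample.int(length(config$alleles), n, replace = TRUE,
                        prob = config$allele_frequencies)
  backbones <- do.call(rbind, lapply(config$alleles, `[[`, "residues"))
  res <- backbones[ai, , drop = FALSE]

  planted_pos <- vapply(config$planted_effects, function(e) as.integer(e$position),
                        integer(1))
  planted_carrier <- matrix(FALSE, n, length(planted_pos))

  # ordinary somatic changes (skip planted columns)
  rates <- config$rates
  rates[planted_pos] <- 0
  mask <- matrix(stats::runif(n * IMGT_LENGTH), n) <
    matrix(rates, n, IMGT_LENGTH, byrow = TRUE)
  cells <- which(mask)
  if (length(cells))
    res[cells] <- .draw_replacements(res[cells], config$gap_prob,
                                     config$substitution)

  # planted effects: carrier rate = min(1, multiplier x base rate)
  for (k in seq_along(config$planted_effects)) {
    e <- config$planted_effects[[k]]
    pr <- min(1, e$multiplier * config$rates[e$position])
    carrier <- stats::runif(n) < pr
    res[carrier, e$position] <- e$residue
    planted_carrier[, k] <- carrier
  }

  set <- sequence_set(res, gene = gene, cohort = config$cohort,
                      ids = sprintf("%s_%s_%06d", gene, config$cohort, seq_len(n)),
                      alleles = allele_labels[ai])
  changed <- res != backbones[ai, , drop = FALSE]
  cells_chg <- which(changed)
  chg_row <- ((cells_chg - 1L) %% n) + 1L
  chg_col <- ((cells_chg - 1L) %/% n) + 1L
  changed_positions <- unname(split(chg_col, factor(chg_row, levels = seq_len(n))))
  truth <- list(
    allele = allele_labels[ai],
    changed_positions = changed_positions,
    planted_positions = planted_pos,
    planted_carrier = planted_carrier,
    realized_change_rate = colMeans(changed)
  )
  list(set = set, truth = truth)
}

#' End-to-end recovery of planted enrichment effects
#'
#' Simulates a target cohort (with planted effects) and a comparator cohort
#' (same generative process, no planted effects), builds the rarity
#' reference from the comparator, scans positions, and reports detection
#' per planted position and false calls elsewhere.
#'
#' @param target_config \code{\link{simulation_config}} for the target
#'   cohort (carries the planted effects).
#' @param comparator_config Config for the comparator/reference cohort.
#' @param thresholds \code{\link{rarity_thresholds}}.
#' @param config \code{\link{enrichment_config}}.
#' @param fdr_cutoff Detection threshold on q (default 0.05).
#' @return List with the \code{scan}, a \code{planted} data frame
#'   (position, multiplier, ratio, q, detected) and the
#'   \code{false_call_rate} over testable non-planted positions.
#' @export
end_to_end_recovery <- function(target_config, comparator_config,
                                thresholds = rarity_thresholds(),
                                config = enrichment_config(),
                                fdr_cutoff = 0.05) {
  tgt <- simulate_repertoire(target_config)
  cmp <- simulate_repertoire(comparator_config)
  reference <- build_consensus(cmp$set)
  scan <- scan_positions(tgt$set, reference, reference,
                         comparator_config$alleles[[1]],
                         config = config, thresholds = thresholds,
                         comparison = paste0(target_config$cohort, "_vs_",
                                             comparator_config$cohort),
                         artifact_filter = TRUE)
  planted_pos <- vapply(target_config$planted_effects,
                        function(e) as.integer(e$position), integer(1))
  mult <- vapply(target_config$planted_effects,
                 function(e) as.numeric(e$multiplier), numeric(1))
  rows <- match(planted_pos, scan$position)
  planted <- data.frame(position = planted_pos, multiplier = mult,
                        ratio = scan$ratio[rows], q = scan$q[rows],
                        detected = !is.na(scan$q[rows]) &
                          scan$q[rows] < fdr_cutoff & scan$ratio[rows] > 1)
  testable <- !scan$excluded & !scan$not_plotted &
    !(scan$position %in% planted_pos)
  false_calls <- sum(scan$q[testable] < fdr_cutoff, na.rm = TRUE)
  list(scan = scan, planted = planted,
       false_call_rate = false_calls / max(1, sum(testable)))
}

#' Write simulation truth as TSV
#'
#' @param truth Truth component of \code{\link{simulate_repertoire}}.
#' @param set The matching \code{sequence_set}.
#' @param path Output path.
#' @export
write_truth_tsv <- function(truth, set, path) {
  df <- data.frame(
    id = set$ids,
    allele = truth$allele,
    changed_positions = vapply(truth$changed_positions, paste,
                               character(1), collapse = ","),
    stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
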