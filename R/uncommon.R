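#' Rarity thresholds for residue classification
#'
#' A residue is "common" when its reference-matrix fraction is at or above
#' the uncommon cutoff (default 10\%), "uncommon" below it, and additionally
#' "rare" below the rare cutoff (default 1\%). The boundary fraction equal
#' to the cutoff is common. Rare residues are a subset of uncommon residues.
#'
#' @param uncommon_cutoff Fraction below which a residue is uncommon.
#' @param rare_cutoff Fraction below which a residue is rare.
#' @return Object of class \code{rarity_thresholds}.
#' @export
rarity_thresholds <- function(uncommon_cutoff = 0.10, rare_cutoff = 0.01) {
  if (!(0 < rare_cutoff && rare_cutoff < uncommon_cutoff && uncommon_cutoff < 1))
    stop("need 0 < rare_cutoff < uncommon_cutoff < 1")
  structure(list(uncommon_cutoff = uncommon_cutoff, rare_cutoff = rare_cutoff),
            class = "rarity_thresholds")
}

.rarity_class <- function(fraction, thresholds) {
  ifelse(fraction >= thresholds$uncommon_cutoff, "common",
         ifelse(fraction < thresholds$rare_cutoff, "rare", "uncommon"))
}

#' Classify a residue's rarity against a reference consensus matrix
#'
#' @param reference The reference (polyclonal-role) \code{consensus_matrix}.
#' @param position IMGT position.
#' @param residue Alphabet symbol (gap allowed; its reference fraction is
#'   the gap fraction at that position).
#' @param thresholds \code{\link{rarity_thresholds}}.
#' @return \code{"common"}, \code{"uncommon"} or \code{"rare"} ("rare"
#'   implies uncommon; a residue never observed in the reference is rare).
#' @export
classify_residue <- function(reference, position, residue,
                             thresholds = rarity_thresholds()) {
  if (any(!residue %in% lc_alphabet())) stop("residue not in alphabet")
  .rarity_class(consensus_fraction(reference, position, residue), thresholds)
}

# 127-vector of reference fractions for one residue vector
.profile_fractions <- function(residues, reference) {
  reference$fractions[cbind(1:IMGT_LENGTH, match(residues, lc_alphabet()))]
}

#' Per-sequence frequency profile against a reference matrix
#'
#' For each of the 127 positions, reports the reference-matrix fraction of
#' the residue observed in the query sequence (gap included) and its rarity
#' class. Plotted as an inverted bar chart this is the "frequency profile"
#' used to prioritize destabilizing residue changes.
#'
#' @param seq An \code{aligned_light_chain} of the reference's gene.
#' @param reference The reference \code{consensus_matrix}.
#' @param thresholds \code{\link{rarity_thresholds}}.
#' @param check_gene Enforce gene agreement.
#' @return Data frame with 127 rows: \code{position}, \code{residue},
#'   \code{frequency}, \code{class}.
#' @export
frequency_profile <- function(seq, reference, thresholds = rarity_thresholds(),
                              check_gene = TRUE) {
  res <- if (inherits(seq, "aligned_light_chain")) seq$residues else as.character(seq)
  if (check_gene && inherits(seq, "aligned_light_chain") && !is.na(seq$gene) &&
      normalize_gene_name(seq$gene) != normalize_gene_name(reference$gene))
    stop("gene mismatch: ", seq$gene, " vs reference ", reference$gene)
  f <- .profile_fractions(res, reference)
  data.frame(position = 1:IMGT_LENGTH, residue = res, frequency = f,
             class = .rarity_class(f, thresholds), stringsAsFactors = FALSE)
}

#' Write a frequency profile as TSV
#'
#' @param profile Output of \code{\link{frequency_profile}}.
#' @param path Output path.
#' @export
write_profile_tsv <- function(profile, path) {
  utils::write.table(profile, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

# Logical 127 x 21 lookup: is symbol k uncommon at position p?
.uncommon_lookup <- function(reference, thresholds) {
  reference$fractions < thresholds$uncommon_cutoff
}

#' Count sequences carrying an uncommon residue at each position
#'
#' For each IMGT position, the number of member sequences whose residue at
#' that position is uncommon under the reference matrix.
#'
#' @param set A \code{\link{sequence_set}}.
#' @param reference Reference \code{consensus_matrix} on the same gene.
#' @param thresholds \code{\link{rarity_thresholds}}.
#' @param check_gene Enforce gene agreement.
#' @return Object of class \code{carrier_counts}: integer vector of length
#'   127 with attributes \code{gene}, \code{cohort} and \code{n}.
#' @export
count_uncommon_carriers <- function(set, reference,
                                    thresholds = rarity_thresholds(),
                                    check_gene = TRUE) {
  if (check_gene &&
      normalize_gene_name(set$gene) != normalize_gene_name(reference$gene))
    stop("gene mismatch: ", set$gene, " vs reference ", reference$gene)
  lk <- .uncommon_lookup(reference, thresholds)
  n <- length(set)
  sym <- match(set$residues, lc_alphabet())      # n*127 vector, column-major
  pos <- rep(1:IMGT_LENGTH, each = n)
  unc <- matrix(lk[cbind(pos, sym)], nrow = n)
  structure(as.integer(.colSums(unc, n, IMGT_LENGTH)),
            gene = set$gene, cohort = set$cohort, n = n,
            class = "carrier_counts")
}

#' Carrier counts implied by a consensus matrix
#'
#' Per-position carrier counts decompose over symbols, so a cohort supplied
#' only as a consensus matrix (with its n) yields exactly the counts an
#' explicit sequence set would: the sum of counts of symbols that are
#' uncommon under the reference.
#'
#' @param matrix The cohort's \code{consensus_matrix}.
#' @inheritParams count_uncommon_carriers
#' @export
carriers_from_matrix <- function(matrix, reference,
                                 thresholds = rarity_thresholds(),
                                 check_gene = TRUE) {
  if (check_gene &&
      normalize_gene_name(matrix$gene) != normalize_gene_name(reference$gene))
    stop("gene mismatch: ", matrix$gene, " vs reference ", reference$gene)
  lk <- .uncommon_lookup(reference, thresholds)
  structure(as.integer(rowSums(matrix$counts * lk)),
            gene = matrix$gene, cohort = matrix$cohort, n = matrix$n,
            class = "carrier_counts")
}

#' Reference frequencies of every residue in a set (rarity histogram data)
#'
#' One observation per (sequence, position): the reference-matrix fraction
#' of the residue that sequence carries there. With gaps included the total
#' number of observations is 127 x n. Bin for plotting with
#' \code{\link[graphics]{hist}} or the returned \code{breaks}.
#'
#' @inheritParams count_uncommon_carriers
#' @param include_gaps Include positions where the observed symbol is a gap
#'   (default TRUE).
#' @return Object of class \code{rarity_histogram}: list with
#'   \code{values} (numeric vector of reference frequencies), \code{n},
#'   \code{gene}, \code{cohort}.
#' @export
rarity_histogram <- function(set, reference, thresholds = rarity_thresholds(),
                             include_gaps = TRUE, check_gene = TRUE) {
  if (check_gene &&
      normalize_gene_name(set$gene) != normalize_gene_name(reference$gene))
    stop("gene mismatch: ", set$gene, " vs reference ", reference$gene)
  n <- length(set)
  sym <- match(set$residues, lc_alphabet())
  pos <- rep(1:IMGT_LENGTH, each = n)
  vals <- reference$fractions[cbind(pos, sym)]
  if (!include_gaps) vals <- vals[set$residues != LC_GAP]
  structure(list(values = vals, n = n, gene = set$gene, cohort = set$cohort,
                 include_gaps = include_gaps),
            class = "rarity_histogram")
}

#' @export
print.rarity_histogram <- function(x, ...) {
  cat("<rarity_histogram>", x$gene, x$cohort, length(x$values),
      "observations\n")
  invisible(x)
}
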