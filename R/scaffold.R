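#' The 21-symbol light-chain residue alphabet
#'
#' The twenty standard amino-acid one-letter codes in alphabetical order,
#' followed by the gap symbol \code{"-"}. Gaps are first-class residues on the
#' IMGT scaffold: conserved gaps accommodate insertions, so every consensus,
#' rarity and distance computation treats the gap as an ordinary 21st symbol.
#'
#' @return Character vector of length 21; the gap symbol is last.
#' @export
lc_alphabet <- function() {
  c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
    "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y", LC_GAP)
}

#' @rdname lc_alphabet
#' @export
LC_GAP <- "-"

#' Number of positions on the IMGT light-chain scaffold
#' @export
IMGT_LENGTH <- 127L

# Default IMGT unique-numbering region boundaries for light chains.
# These are convention, not data: callers may override them when building a
# scaffold, and every region-dependent output records the map it used.
.default_regions <- list(
  FR1  = 1:26,
  CDR1 = 27:38,
  FR2  = 39:55,
  CDR2 = 56:65,
  FR3  = 66:104,
  CDR3 = 105:117,
  FR4  = 118:127
)

#' Fixed 127-position IMGT scaffold with region annotations
#'
#' Constructs the scaffold object holding the position -> region map. The
#' seven regions (FR1, CDR1, FR2, CDR2, FR3, CDR3, FR4) must partition
#' positions 1..127 into contiguous blocks.
#'
#' @param regions Named list of integer position vectors, one per region, in
#'   order. Defaults to the IMGT unique-numbering convention
#'   (FR1 1-26, CDR1 27-38, FR2 39-55, CDR2 56-65, FR3 66-104, CDR3 105-117,
#'   FR4 118-127).
#' @return An object of class \code{imgt_scaffold} with elements
#'   \code{positions} (1..127) and \code{region} (character vector of length
#'   127 mapping each position to its region label).
#' @export
imgt_scaffold <- function(regions = .default_regions) {
  pos <- unlist(regions, use.names = FALSE)
  if (!identical(sort(pos), 1:IMGT_LENGTH))
    stop("region map must partition positions 1..", IMGT_LENGTH)
  region <- character(IMGT_LENGTH)
  for (nm in names(regions)) region[regions[[nm]]] <- nm
  structure(
    list(positions = 1:IMGT_LENGTH, region = region,
         region_names = names(regions)),
    class = "imgt_scaffold"
  )
}

#' Region of an IMGT position
#'
#' @param position Integer position in 1..127.
#' @param scaffold An \code{\link{imgt_scaffold}}.
#' @return Region label, e.g. \code{"CDR3"} for position 115 under the
#'   default map.
#' @export
region_of <- function(position, scaffold = imgt_scaffold()) {
  position <- as.integer(position)
  if (any(is.na(position)) || any(position < 1L) || any(position > IMGT_LENGTH))
    stop("position out of range 1..", IMGT_LENGTH)
  scaffold$region[position]
}

#' Germline gene allele on the IMGT scaffold
#'
#' @param gene Gene name, e.g. \code{"IGKV1-33"}.
#' @param allele Allele suffix, e.g. \code{"*01"}.
#' @param residues Character vector of 127 alphabet symbols (gaps allowed).
#' @return Object of class \code{germline_allele}.
#' @export
germline_allele <- function(gene, allele, residues) {
  residues <- as.character(residues)
  if (length(residues) != IMGT_LENGTH)
    stop("germline residue vector must have length ", IMGT_LENGTH)
  bad <- setdiff(unique(residues), lc_alphabet())
  if (length(bad))
    stop("germline contains non-alphabet symbols: ", paste(bad, collapse = ", "))
  structure(list(gene = gene, allele = allele, residues = residues),
            class = "germline_allele")
}

#' @export
print.germline_allele <- function(x, ...) {
  cat("<germline_allele>", paste0(x$gene, x$allele), "\n")
  invisible(x)
}

#' Germline gene/allele registry
#'
#' Holds the germline reference alleles per gene and the policy naming which
#' allele is "the" reference (default \code{"*01"}). Gene names are
#' normalized so that distal-locus paralogs (e.g. \code{IGKV1D-33}) are
#' counted under the proximal gene (\code{IGKV1-33}).
#'
#' @param alleles List of \code{\link{germline_allele}} objects.
#' @param reference_allele Which allele suffix is the per-gene reference.
#' @return Object of class \code{germline_registry}.
#' @export
germline_registry <- function(alleles, reference_allele = "*01") {
  stopifnot(length(alleles) >= 1L)
  for (a in alleles)
    if (!inherits(a, "germline_allele")) stop("all entries must be germline_allele")
  genes <- vapply(alleles, `[[`, character(1), "gene")
  reg <- structure(list(alleles = alleles, genes = unique(genes),
                        reference_allele = reference_allele),
                   class = "germline_registry")
  for (g in reg$genes) {
    if (is.null(tryCatch(reference_allele_of(reg, g), error = function(e) NULL)))
      stop("gene ", g, " has no reference allele ", reference_allele)
  }
  reg
}

#' Normalize a germline gene name
#'
#' Collapses distal-locus IGKV paralogs onto the proximal gene
#' (\code{IGKV1D-33} -> \code{IGKV1-33}).
#'
#' @param gene Character vector of gene names.
#' @export
normalize_gene_name <- function(gene) {
  sub("^(IG[KL]V[0-9]+)D-", "\\1-", gene)
}

#' Alleles registered for a gene
#'
#' @param registry A \code{\link{germline_registry}}.
#' @param gene Gene name.
#' @return List of \code{germline_allele} objects.
#' @export
alleles_of <- function(registry, gene) {
  gene <- normalize_gene_name(gene)
  hit <- Filter(function(a) a$gene == gene, registry$alleles)
  if (!length(hit)) stop("gene not in registry: ", gene)
  hit
}

#' The reference allele of a gene (default *01)
#'
#' @inheritParams alleles_of
#' @param allele Allele suffix; defaults to the registry's policy.
#' @export
reference_allele_of <- function(registry, gene, allele = registry$reference_allele) {
  hit <- Filter(function(a) a$allele == allele, alleles_of(registry, gene))
  if (!length(hit)) stop("no allele ", allele, " for gene ", gene)
  hit[[1]]
}

#' Validate a raw sequence against the scaffold and alphabet
#'
#' Sequences must span exactly 127 scaffold columns and contain only the 21
#' alphabet symbols; any ambiguity code (e.g. \code{X}, \code{B}) rejects the
#' sequence. Rejections are data, not errors: the return value is either an
#' \code{aligned_light_chain} or a rejection record with a reason.
#'
#' @param id Sequence identifier.
#' @param residues Character vector of candidate symbols (or a single string,
#'   which is split into characters).
#' @param gene,cohort,allele Labels attached to an accepted sequence.
#' @param alphabet The residue alphabet.
#' @return An \code{aligned_light_chain}, or an object of class
#'   \code{lc_rejection} with fields \code{id} and \code{reason}.
#' @export
validate_sequence <- function(id, residues, gene = NA_character_,
                              cohort = NA_character_, allele = NA_character_,
                              alphabet = lc_alphabet()) {
  if (length(residues) == 1L && nchar(residues[1]) > 1L)
    residues <- strsplit(residues, "")[[1]]
  residues <- as.character(residues)
  residues[residues == "."] <- LC_GAP
  if (length(residues) > IMGT_LENGTH)
    return(lc_rejection(id, "over-length insertion"))
  if (length(residues) != IMGT_LENGTH)
    return(lc_rejection(id, "wrong scaffold length"))
  if (!all(residues %in% alphabet))
    return(lc_rejection(id, "ambiguous residue"))
  aligned_light_chain(id, residues, gene = gene, cohort = cohort, allele = allele)
}

lc_rejection <- function(id, reason) {
  structure(list(id = id, reason = reason), class = "lc_rejection")
}

#' A single aligned light chain on the IMGT scaffold
#'
#' @param id Sequence identifier.
#' @param residues Character vector of 127 alphabet symbols.
#' @param gene,cohort,allele Labels.
#' @return Object of class \code{aligned_light_chain}.
#' @export
aligned_light_chain <- function(id, residues, gene = NA_character_,
                                cohort = NA_character_, allele = NA_character_) {
  residues <- as.character(residues)
  stopifnot(length(residues) == IMGT_LENGTH)
  structure(list(id = id, gene = gene, allele = allele, cohort = cohort,
                 residues = residues),
            class = "aligned_light_chain")
}

#' A set of aligned light chains from one gene and cohort
#'
#' Residues are stored as an n x 127 character matrix for efficient
#' tabulation; row order is the ingestion order but all set-level operations
#' are order-independent.
#'
#' @param residues n x 127 character matrix (or a list of
#'   \code{aligned_light_chain}).
#' @param gene,cohort Set labels.
#' @param ids Sequence identifiers (default \code{seq_1..n}).
#' @param alleles Optional per-sequence allele assignments.
#' @return Object of class \code{sequence_set}.
#' @export
sequence_set <- function(residues, gene, cohort, ids = NULL, alleles = NULL) {
  if (is.list(residues) && !is.matrix(residues)) {
    seqs <- residues
    residues <- do.call(rbind, lapply(seqs, `[[`, "residues"))
    if (is.null(ids)) ids <- vapply(seqs, function(s) as.character(s$id), character(1))
    if (is.null(alleles)) alleles <- vapply(seqs, function(s) as.character(s$allele), character(1))
  }
  if (!is.matrix(residues) || ncol(residues) != IMGT_LENGTH)
    stop("residues must be an n x ", IMGT_LENGTH, " character matrix")
  n <- nrow(residues)
  if (n < 1L) stop("a sequence set needs at least one sequence")
  if (is.null(ids)) ids <- paste0("seq_", seq_len(n))
  if (is.null(alleles)) alleles <- rep(NA_character_, n)
  structure(list(gene = gene, cohort = cohort, ids = as.character(ids),
                 alleles = as.character(alleles), residues = residues),
            class = "sequence_set")
}

#' @export
length.sequence_set <- function(x) nrow(x$residues)

#' @export
print.sequence_set <- function(x, ...) {
  cat("<sequence_set>", x$gene, x$cohort, "n =", length(x), "\n")
  invisible(x)
}

#' Extract one member of a set as an aligned_light_chain
#'
#' @param set A \code{\link{sequence_set}}.
#' @param i Row index or sequence id.
#' @export
set_member <- function(set, i) {
  if (is.character(i)) i <- match(i, set$ids)
  aligned_light_chain(set$ids[i], set$residues[i, ], gene = set$gene,
                      cohort = set$cohort, allele = set$alleles[i])
}

#' Residue changes between a sequence and its germline
#'
#' Lists every scaffold position where the observed residue differs from the
#' germline residue, including residue-to-gap (deletion-type) and
#' gap-to-residue (insertion-type) differences. "Residue change" is used in
#' preference to "mutation" because only protein sequences are compared.
#'
#' @param seq An \code{aligned_light_chain} (or bare 127-symbol vector).
#' @param germline A \code{\link{germline_allele}} of the same gene.
#' @param check_gene Enforce that the sequence and germline genes agree.
#' @return Data frame with columns \code{position}, \code{germline},
#'   \code{observed}; zero rows iff the vectors are identical.
#' @export
residue_differences <- function(seq, germline, check_gene = TRUE) {
  res <- if (inherits(seq, "aligned_light_chain")) seq$residues else as.character(seq)
  if (check_gene && inherits(seq, "aligned_light_chain") && !is.na(seq$gene) &&
      normalize_gene_name(seq$gene) != germline$gene)
    stop("gene mismatch: sequence ", seq$gene, " vs germline ", germline$gene)
  idx <- which(res != germline$residues)
  data.frame(position = idx, germline = germline$residues[idx],
             observed = res[idx], stringsAsFactors = FALSE)
}
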