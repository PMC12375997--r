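#' Read a germline registry from gapped FASTA
#'
#' Headers carry the gene and allele as \code{">IGKV1-33*01"}; sequences are
#' pre-gapped to 127 scaffold columns ("." accepted as a gap synonym).
#' Distal-locus paralog names are normalized at ingestion.
#'
#' @param path FASTA file.
#' @param reference_allele Allele suffix used as the per-gene reference.
#' @return A \code{\link{germline_registry}}.
#' @export
read_germline_fasta <- function(path, reference_allele = "*01") {
  recs <- Biostrings::readBStringSet(path)
  if (length(recs) == 0L) stop("empty germline FASTA: ", path)
  alleles <- lapply(seq_along(recs), function(i) {
    hdr <- sub("\\s.*$", "", names(recs)[i])
    parts <- strsplit(hdr, "*", fixed = TRUE)[[1]]
    if (length(parts) != 2L)
      stop("germline header must look like GENE*ALLELE: ", hdr)
    res <- strsplit(as.character(recs[[i]]), "")[[1]]
    res[res == "."] <- LC_GAP
    germline_allele(normalize_gene_name(parts[1]), paste0("*", parts[2]), res)
  })
  germline_registry(alleles, reference_allele = reference_allele)
}

#' Write a germline registry as gapped FASTA
#'
#' @param registry A \code{\link{germline_registry}}.
#' @param path Output path.
#' @export
write_germline_fasta <- function(registry, path) {
  seqs <- vapply(registry$alleles, function(a) paste(a$residues, collapse = ""),
                 character(1))
  x <- Biostrings::BStringSet(seqs)
  names(x) <- vapply(registry$alleles, function(a) paste0(a$gene, a$allele),
                     character(1))
  Biostrings::writeXStringSet(x, path)
  invisible(path)
}

#' Read a germline registry from TSV
#'
#' Columns: \code{gene}, \code{allele}, then 127 residue columns (or one
#' \code{residues} column with the full gapped string).
#'
#' @inheritParams read_germline_fasta
#' @export
read_germline_tsv <- function(path, reference_allele = "*01") {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  if (nrow(tab) == 0L) stop("empty germline TSV: ", path)
  alleles <- lapply(seq_len(nrow(tab)), function(i) {
    res <- if ("residues" %in% names(tab)) strsplit(tab$residues[i], "")[[1]]
           else as.character(tab[i, -(1:2)])
    res[res == "."] <- LC_GAP
    germline_allele(normalize_gene_name(tab$gene[i]), tab$allele[i], res)
  })
  germline_registry(alleles, reference_allele = reference_allele)
}
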