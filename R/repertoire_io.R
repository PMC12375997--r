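#' Ingest report bookkeeping
#'
#' @param n_read Number of records read.
#' @param rejections Data frame with columns \code{id}, \code{reason} (zero
#'   rows when everything was accepted).
#' @return Object of class \code{ingest_report} with \code{n_read},
#'   \code{n_accepted} and \code{rejections}; counts always reconcile
#'   (\code{n_read == n_accepted + nrow(rejections)}).
#' @export
ingest_report <- function(n_read, rejections) {
  structure(list(n_read = as.integer(n_read),
                 n_accepted = as.integer(n_read - nrow(rejections)),
                 rejections = rejections),
            class = "ingest_report")
}

#' @export
print.ingest_report <- function(x, ...) {
  cat("<ingest_report> read", x$n_read, "accepted", x$n_accepted,
      "rejected", nrow(x$rejections), "\n")
  invisible(x)
}

.empty_rejections <- function() {
  data.frame(id = character(0), reason = character(0), stringsAsFactors = FALSE)
}

.assemble_set <- function(accepted, rejections, gene, cohort, n_read,
                          dedup = FALSE) {
  rej <- if (length(rejections)) {
    data.frame(id = vapply(rejections, `[[`, character(1), "id"),
               reason = vapply(rejections, `[[`, character(1), "reason"),
               stringsAsFactors = FALSE)
  } else .empty_rejections()
  report <- ingest_report(n_read, rej)
  if (!length(accepted))
    stop("no sequences accepted from input (", nrow(rej), " rejected)")
  set <- sequence_set(accepted, gene = normalize_gene_name(gene), cohort = cohort)
  if (dedup) {
    keys <- apply(set$residues, 1, paste, collapse = "")
    keep <- !duplicated(keys)
    set <- sequence_set(set$residues[keep, , drop = FALSE], gene = set$gene,
                        cohort = set$cohort, ids = set$ids[keep],
                        alleles = set$alleles[keep])
  }
  list(set = set, report = report)
}

#' Read a 127-column gapped FASTA into a sequence set
#'
#' Applies the inclusion filters: records with a wrong scaffold length,
#' over-length CDR3 insertions (more than 127 columns) or ambiguity codes
#' are rejected with reasons; \code{"."} is accepted as a gap synonym and
#' normalized to \code{"-"}. An optional allele suffix in the header
#' (\code{">id gene=IGKV1-33 allele=*01"} or \code{">id|IGKV1-33*01"}) is
#' ignored here; per-sequence alleles are set by the caller if known.
#'
#' @param path FASTA file of pre-gapped, IMGT-numbered protein sequences.
#' @param gene,cohort Labels for the resulting set.
#' @param alphabet Residue alphabet.
#' @param dedup Drop duplicate sequences after acceptance (default off).
#' @return \code{list(set = sequence_set, report = ingest_report)}.
#' @export
read_aligned_fasta <- function(path, gene, cohort, alphabet = lc_alphabet(),
                               dedup = FALSE) {
  if (!file.exists(path)) stop("cannot read file: ", path)
  recs <- Biostrings::readBStringSet(path)
  if (length(recs) == 0L) stop("empty FASTA: ", path)
  ids <- sub("\\s.*$", "", names(recs))
  accepted <- list(); rejections <- list()
  for (i in seq_along(recs)) {
    v <- validate_sequence(ids[i], as.character(recs[[i]]), gene = gene,
                           cohort = cohort, alphabet = alphabet)
    if (inherits(v, "lc_rejection")) rejections[[length(rejections) + 1L]] <- v
    else accepted[[length(accepted) + 1L]] <- v
  }
  .assemble_set(accepted, rejections, gene, cohort, length(recs), dedup)
}

#' Write a sequence set as 127-column gapped FASTA
#'
#' @param set A \code{\link{sequence_set}}.
#' @param path Output path.
#' @export
write_aligned_fasta <- function(set, path) {
  seqs <- apply(set$residues, 1, paste, collapse = "")
  x <- Biostrings::BStringSet(seqs)
  names(x) <- set$ids
  Biostrings::writeXStringSet(x, path)
  invisible(path)
}

#' Read position-numbered tabular sequences (ANARCI-style)
#'
#' One row per (sequence, position): columns \code{id}, \code{imgt_position},
#' \code{residue} and an optional \code{over_length} flag column. Positions
#' absent from the table become gaps; duplicate (id, position) rows reject
#' that id; a truthy over-length flag rejects the id (CDR3 insertions longer
#' than the scaffold can only be detected upstream of numbering, so the
#' dialect carries the flag through).
#'
#' @inheritParams read_aligned_fasta
#' @return \code{list(set = sequence_set, report = ingest_report)}.
#' @export
read_numbered_table <- function(path, gene, cohort, alphabet = lc_alphabet(),
                                dedup = FALSE) {
  if (!file.exists(path)) stop("cannot read file: ", path)
  tab <- tryCatch(
    utils::read.delim(path, stringsAsFactors = FALSE),
    error = function(e) stop("malformed numbered table: ", conditionMessage(e)))
  if (nrow(tab) == 0L) stop("empty numbered table: ", path)
  need <- c("id", "imgt_position", "residue")
  if (!all(need %in% names(tab)))
    stop("numbered table must have columns: ", paste(need, collapse = ", "))
  bad_pos <- which(is.na(suppressWarnings(as.integer(tab$imgt_position))) |
                     tab$imgt_position < 1 | tab$imgt_position > IMGT_LENGTH)
  if (length(bad_pos))
    stop("malformed row ", bad_pos[1] + 1L, ": bad imgt_position")
  accepted <- list(); rejections <- list()
  for (sid in unique(tab$id)) {
    rows <- tab[tab$id == sid, , drop = FALSE]
    if ("over_length" %in% names(rows) &&
        any(rows$over_length %in% c(TRUE, 1, "1", "TRUE", "true", "yes"))) {
      rejections[[length(rejections) + 1L]] <- lc_rejection(sid, "over-length insertion")
      next
    }
    if (anyDuplicated(rows$imgt_position)) {
      rejections[[length(rejections) + 1L]] <- lc_rejection(sid, "duplicate position")
      next
    }
    res <- rep(LC_GAP, IMGT_LENGTH)
    res[as.integer(rows$imgt_position)] <- as.character(rows$residue)
    v <- validate_sequence(sid, res, gene = gene, cohort = cohort,
                           alphabet = alphabet)
    if (inherits(v, "lc_rejection")) rejections[[length(rejections) + 1L]] <- v
    else accepted[[length(accepted) + 1L]] <- v
  }
  .assemble_set(accepted, rejections, gene, cohort, length(unique(tab$id)), dedup)
}

#' Write an ingest report as TSV
#'
#' @param report An \code{\link{ingest_report}}.
#' @param path Output path.
#' @export
write_ingest_report <- function(report, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# n_read=%d\tn_accepted=%d", report$n_read,
                     report$n_accepted), con)
  utils::write.table(report$rejections, con, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Serialize / deserialize a consensus matrix as TSV
#'
#' The file has comment-style header lines carrying the gene, cohort and
#' sequence count, then a 127-row table: first column the IMGT position,
#' then the 21 symbol count columns (gap column named \code{gap}). Fractions
#' are recomputed as counts / n on read, so the round trip is lossless.
#' Row sums inconsistent with n fail the read.
#'
#' @param matrix A \code{consensus_matrix}.
#' @param path File path.
#' @export
write_consensus_tsv <- function(matrix, path) {
  stopifnot(inherits(matrix, "consensus_matrix"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(sprintf("# gene=%s", matrix$gene),
               sprintf("# cohort=%s", matrix$cohort),
               sprintf("# n_sequences=%d", matrix$n)), con)
  cols <- ifelse(colnames(matrix$counts) == LC_GAP, "gap", colnames(matrix$counts))
  df <- data.frame(position = 1:IMGT_LENGTH, matrix$counts, check.names = FALSE)
  names(df) <- c("position", cols)
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_consensus_tsv
#' @export
read_consensus_tsv <- function(path) {
  lines <- readLines(path)
  hdr <- grep("^#", lines, value = TRUE)
  field <- function(key) {
    hit <- grep(paste0("^# ", key, "="), hdr, value = TRUE)
    if (!length(hit)) stop("consensus TSV missing header field: ", key)
    sub(paste0("^# ", key, "="), "", hit[1])
  }
  gene <- field("gene"); cohort <- field("cohort")
  n <- as.integer(field("n_sequences"))
  tab <- utils::read.delim(text = lines[!grepl("^#", lines)],
                           check.names = FALSE)
  if (nrow(tab) != IMGT_LENGTH)
    stop("consensus TSV must have ", IMGT_LENGTH, " rows")
  counts <- as.matrix(tab[, -1, drop = FALSE])
  colnames(counts)[colnames(counts) == "gap"] <- LC_GAP
  counts <- counts[, lc_alphabet(), drop = FALSE]
  if (any(abs(rowSums(counts) - n) > 0))
    stop("consensus TSV format error: row sums inconsistent with n_sequences")
  consensus_from_counts(counts, gene = gene, cohort = cohort)
}
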