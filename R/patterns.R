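#' Parse a published residue-change pattern label
#'
#' The grammar covers the pattern families used for published amyloid-
#' associated changes:
#' \itemize{
#'   \item gain: \code{"X37D"} -- any germline residue replaced by D (the
#'     gained set may have several letters, e.g. \code{"X56DE"});
#'   \item loss: \code{"ST20X"} -- a germline serine or threonine at 20
#'     replaced by any residue outside the lost set;
#'   \item exact: \code{"R25G"}, \code{"K56DE"} -- the stated germline
#'     anchor replaced by the target residue (or any member of the target
#'     set, \code{DE} meaning aspartate or glutamate);
#'   \item proline insertion: \code{"P115PP"} -- a second proline adjacent
#'     to the germline CDR3 proline with at least one residue inserted into
#'     the 110-113 germline gap (see \code{\link{detect_p115pp}});
#'   \item any-uncommon: \code{"U52"} -- any uncommon residue at the
#'     position, delegated to the rarity classifier.
#' }
#'
#' @param label Pattern label text.
#' @param gene_scope Optional explicit gene list; \code{NULL} means all
#'   eligible genes in the registry (gain/loss patterns) or must be
#'   supplied for exact patterns when counting.
#' @return Object of class \code{residue_change_pattern} with fields
#'   \code{kind}, \code{position}, \code{residues}, \code{germline_set},
#'   \code{gene_scope}, \code{label}. The label round-trips:
#'   \code{parse_pattern(x$label)} reproduces the pattern.
#' @export
parse_pattern <- function(label, gene_scope = NULL) {
  label <- trimws(label)
  mk <- function(kind, position, residues = character(0),
                 germline_set = character(0)) {
    structure(list(kind = kind, position = as.integer(position),
                   residues = residues, germline_set = germline_set,
                   gene_scope = gene_scope, label = label),
              class = "residue_change_pattern")
  }
  aa <- setdiff(lc_alphabet(), LC_GAP)
  m <- regmatches(label, regexec("^P([0-9]+)PP$", label))[[1]]
  if (length(m)) return(mk("insertion_PP", m[2], residues = "P",
                           germline_set = "P"))
  m <- regmatches(label, regexec("^U([0-9]+)$", label))[[1]]
  if (length(m)) return(mk("any_uncommon", m[2]))
  m <- regmatches(label, regexec("^([A-Z]+)([0-9]+)([A-Z]+)$", label))[[1]]
  if (!length(m)) stop("unparseable pattern label: ", label)
  left <- strsplit(m[2], "")[[1]]
  pos <- m[3]
  right <- strsplit(m[4], "")[[1]]
  if (identical(left, "X") && !any(right == "X")) {
    if (!all(right %in% aa)) stop("bad gained residue in: ", label)
    return(mk("gain", pos, residues = right))
  }
  if (identical(right, "X") && !any(left == "X")) {
    if (!all(left %in% aa)) stop("bad lost residue in: ", label)
    return(mk("loss", pos, residues = left))
  }
  if (!any(c(left, right) == "X")) {
    if (!all(c(left, right) %in% aa)) stop("bad residue in: ", label)
    return(mk("exact", pos, residues = right, germline_set = left))
  }
  stop("unparseable pattern label: ", label)
}

#' Genes where a pattern's residue change is possible
#'
#' Eligibility is judged on each gene's reference allele: gain patterns
#' exclude genes whose germline residue at the position is already in the
#' gained set; loss patterns keep only genes whose germline residue is in
#' the lost set; exact and insertion patterns are restricted to their
#' stated gene scope; any-uncommon patterns accept every gene in scope.
#'
#' @param pattern A \code{residue_change_pattern}.
#' @param registry A \code{\link{germline_registry}}.
#' @param genes Candidate genes (default: the pattern's scope if set,
#'   otherwise every gene in the registry).
#' @return Character vector of eligible gene names.
#' @export
eligible_genes <- function(pattern, registry, genes = NULL) {
  if (is.null(genes))
    genes <- if (!is.null(pattern$gene_scope)) pattern$gene_scope else registry$genes
  genes <- normalize_gene_name(genes)
  if (pattern$kind %in% c("exact", "insertion_PP")) {
    if (!is.null(pattern$gene_scope)) return(normalize_gene_name(pattern$gene_scope))
    return(genes)
  }
  if (pattern$kind == "any_uncommon") return(genes)
  keep <- vapply(genes, function(g) {
    gl <- reference_allele_of(registry, g)$residues[pattern$position]
    if (pattern$kind == "gain") !(gl %in% pattern$residues)
    else gl %in% pattern$residues            # loss: germline must carry it
  }, logical(1))
  genes[keep]
}

#' Does a sequence match a residue-change pattern?
#'
#' Matching semantics by kind (gap rules are documented and switchable):
#' gain -- the observed residue is in the gained set and the germline
#' residue is not (a gap never counts as the gained residue); loss -- the
#' germline residue is in the lost set and the observed residue is outside
#' it (an observed gap counts as a loss when \code{gap_counts_as_loss});
#' exact -- the observed residue is in the target set; any-uncommon --
#' delegated to \code{\link{classify_residue}} (requires \code{reference});
#' insertion_PP -- \code{\link{detect_p115pp}}.
#'
#' @param pattern A \code{residue_change_pattern}.
#' @param seq An \code{aligned_light_chain} or bare 127-symbol vector.
#' @param germline The gene's \code{\link{germline_allele}}.
#' @param reference Reference \code{consensus_matrix} (any-uncommon only).
#' @param thresholds \code{\link{rarity_thresholds}} (any-uncommon only).
#' @param gap_counts_as_loss Whether an observed gap counts as losing the
#'   germline residue (default TRUE).
#' @return Logical scalar.
#' @export
sequence_matches <- function(pattern, seq, germline, reference = NULL,
                             thresholds = rarity_thresholds(),
                             gap_counts_as_loss = TRUE) {
  res <- if (inherits(seq, "aligned_light_chain")) seq$residues else as.character(seq)
  p <- pattern$position
  obs <- res[p]
  gl <- germline$residues[p]
  switch(pattern$kind,
    gain = obs != LC_GAP && obs %in% pattern$residues && !(gl %in% pattern$residues),
    loss = {
      lost <- gl %in% pattern$residues && !(obs %in% pattern$residues)
      if (!gap_counts_as_loss && obs == LC_GAP) FALSE else lost
    },
    exact = obs %in% pattern$residues,
    any_uncommon = {
      if (is.null(reference)) stop("any_uncommon patterns need a reference matrix")
      classify_residue(reference, p, obs, thresholds) != "common"
    },
    insertion_PP = detect_p115pp(res, germline, anchor = p),
    stop("unknown pattern kind: ", pattern$kind)
  )
}

#' Detect the CDR3 double-proline insertion (P115PP)
#'
#' TRUE iff (i) at least one position of the germline CDR3 gap window
#' (110-113) is occupied by a residue, and (ii) two adjacent occupied
#' scaffold positions within the anchor window (113-117) both carry
#' proline. Adjacency skips gap slots, since IMGT insertions need not be
#' physically adjacent in scaffold coordinates.
#'
#' @param seq An \code{aligned_light_chain} or bare 127-symbol vector.
#' @param germline The gene's \code{\link{germline_allele}} (used to locate
#'   the germline gap window).
#' @param insert_window Positions that constitute the CDR3 germline gap
#'   (default 110:113).
#' @param anchor_window Window in which the two prolines must be adjacent
#'   (default 113:117).
#' @param anchor Unused convenience alias accepted from pattern dispatch.
#' @return Logical scalar.
#' @export
detect_p115pp <- function(seq, germline, insert_window = 110:113,
                          anchor_window = 113:117, anchor = NULL) {
  res <- if (inherits(seq, "aligned_light_chain")) seq$residues else as.character(seq)
  gapwin <- insert_window[germline$residues[insert_window] == LC_GAP]
  inserted <- length(gapwin) > 0 && any(res[gapwin] != LC_GAP)
  if (!inserted) return(FALSE)
  occ <- anchor_window[res[anchor_window] != LC_GAP]
  if (length(occ) < 2L) return(FALSE)
  pp <- res[occ] == "P"
  any(pp[-length(pp)] & pp[-1])
}

#' Count pattern carriers across gene-segregated cohort sets
#'
#' Aggregates carriers and eligible denominators over the genes where the
#' pattern's change is possible; sets from ineligible genes contribute
#' nothing.
#'
#' @param pattern A \code{residue_change_pattern}.
#' @param sets List of \code{\link{sequence_set}}s (one per gene, all from
#'   one cohort).
#' @param registry A \code{\link{germline_registry}}.
#' @param reference,thresholds Passed through for any-uncommon patterns
#'   (reference may be a named list of matrices keyed by gene).
#' @param gap_counts_as_loss See \code{\link{sequence_matches}}.
#' @return Object of class \code{pattern_count}: list with \code{pattern},
#'   \code{cohort}, \code{carriers}, \code{eligible_n} and \code{per_gene}
#'   data frame breakdown.
#' @export
count_pattern <- function(pattern, sets, registry, reference = NULL,
                          thresholds = rarity_thresholds(),
                          gap_counts_as_loss = TRUE) {
  if (inherits(sets, "sequence_set")) sets <- list(sets)
  elig <- eligible_genes(pattern, registry,
                         genes = unique(vapply(sets, `[[`, character(1), "gene")))
  cohorts <- unique(vapply(sets, `[[`, character(1), "cohort"))
  if (length(cohorts) != 1L) stop("count_pattern expects sets from one cohort")
  per <- lapply(sets, function(s) {
    g <- normalize_gene_name(s$gene)
    if (!(g %in% elig)) return(NULL)
    gl <- reference_allele_of(registry, g)
    ref <- if (is.list(reference) && !inherits(reference, "consensus_matrix"))
      reference[[g]] else reference
    hits <- vapply(seq_len(length(s)), function(i)
      sequence_matches(pattern, s$residues[i, ], gl, reference = ref,
                       thresholds = thresholds,
                       gap_counts_as_loss = gap_counts_as_loss), logical(1))
    data.frame(gene = g, carriers = sum(hits), eligible_n = length(s),
               stringsAsFactors = FALSE)
  })
  per <- do.call(rbind, per)
  if (is.null(per))
    per <- data.frame(gene = character(0), carriers = integer(0),
                      eligible_n = integer(0))
  structure(list(pattern = pattern, cohort = cohorts,
                 carriers = sum(per$carriers), eligible_n = sum(per$eligible_n),
                 per_gene = per),
            class = "pattern_count")
}

#' @export
print.pattern_count <- function(x, ...) {
  cat("<pattern_count>", x$pattern$label, x$cohort,
      sprintf("%d/%d", x$carriers, x$eligible_n), "\n")
  invisible(x)
}

#' Enrichment statistics for a pattern between two cohorts
#'
#' @param target,comparator \code{pattern_count} objects computed on
#'   identical eligibility, or bare \code{carrier_table} counts.
#' @param config \code{\link{enrichment_config}}.
#' @param id Identifier (defaults to the pattern label and cohorts).
#' @return One-row enrichment result (see \code{\link{enrichment_test}}).
#' @export
pattern_enrichment <- function(target, comparator, config = enrichment_config(),
                               id = NULL) {
  if (inherits(target, "pattern_count")) {
    if (is.null(id))
      id <- paste0(target$pattern$label, ":", target$cohort, "_vs_",
                   comparator$cohort)
    tab <- carrier_table(target$carriers, target$eligible_n,
                         comparator$carriers, comparator$eligible_n)
  } else tab <- target
  if (is.null(id)) id <- NA_character_
  enrichment_test(tab, config, id = id)
}

#' Read a pattern file (gene_scope TAB label per line)
#'
#' Scope \code{ALL} (or \code{ALL_KV}/\code{ALL_LV}) leaves gene
#' eligibility to the registry; otherwise the scope is an explicit gene.
#'
#' @param path Pattern file path.
#' @return List of \code{residue_change_pattern}s.
#' @export
read_pattern_file <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines)) & !grepl("^#", lines)]
  if (!length(lines)) stop("empty pattern file: ", path)
  lapply(seq_along(lines), function(i) {
    parts <- strsplit(lines[i], "\t")[[1]]
    if (length(parts) != 2L)
      stop("unparseable pattern file line ", i, ": ", lines[i])
    scope <- if (grepl("^ALL", parts[1])) NULL else parts[1]
    tryCatch(parse_pattern(parts[2], gene_scope = scope),
             error = function(e) stop("pattern file line ", i, ": ",
                                      conditionMessage(e)))
  })
}

#' Published residue-change carrier counts (regression fixture)
#'
#' The packaged table of previously reported amyloid-associated residue
#' changes with their carrier counts in the AL, MM and polyclonal (OAS)
#' cohorts and the enrichment ratios as printed in the source tables.
#' Columns: \code{group} (kappa-wide, kappa-gene, lambda-gene),
#' \code{gene_scope}, \code{label}, \code{al_a}, \code{al_n}, \code{mm_a},
#' \code{mm_n}, \code{oas_a}, \code{oas_n}, \code{or_al_mm},
#' \code{or_al_oas}.
#'
#' @return Data frame of published pattern counts.
#' @export
published_changes <- function() {
  path <- system.file("extdata", "published_changes.tsv", package = "lcprofiler",
                      mustWork = TRUE)
  utils::read.delim(path, stringsAsFactors = FALSE)
}
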