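#' 2x2 carrier table
#'
#' Counts of sequences carrying / not carrying a residue feature in two
#' cohorts: \code{a} of \code{n1} carriers in cohort 1 and \code{c} of
#' \code{n2} in cohort 2.
#'
#' @param a,n1 Carriers and size of cohort 1.
#' @param c,n2 Carriers and size of cohort 2.
#' @return Object of class \code{carrier_table}.
#' @export
carrier_table <- function(a, n1, c, n2) {
  v <- c(a = a, n1 = n1, c = c, n2 = n2)
  if (any(v != round(v)) || any(v < 0)) stop("carrier table cells must be non-negative integers")
  if (n1 < 1 || n2 < 1) stop("cohort sizes must be >= 1")
  if (a > n1 || c > n2) stop("carriers cannot exceed cohort size")
  structure(list(a = a, n1 = n1, c = c, n2 = n2), class = "carrier_table")
}

#' Swap the cohorts of a carrier table
#' @param table A \code{\link{carrier_table}}.
#' @export
swap_cohorts <- function(table) {
  carrier_table(table$c, table$n2, table$a, table$n1)
}

#' Enrichment configuration
#'
#' The additive count correction (default 0.1, applied to each of the four
#' interior cells, hence +0.2 on each cohort total) removes zero divisions.
#' The default \code{ratio_form = "proportion_ratio"} is the corrected
#' ratio of carrier proportions
#' \deqn{[(a+\delta)/(n_1+2\delta)] / [(c+\delta)/(n_2+2\delta)]}{
#'   [(a+d)/(n1+2d)] / [(c+d)/(n2+2d)]}
#' which is the statistic reported as "OR" throughout this package's
#' outputs; the textbook cross-product odds ratio is available as
#' \code{"odds_ratio"}. The standard error on the log scale defaults to the
#' log-ratio-of-proportions form \eqn{\sqrt{1/a' - 1/n_1' + 1/c' - 1/n_2'}}
#' on corrected counts; the classic Woolf odds-ratio SE is the option
#' \code{se_form = "woolf"}.
#'
#' @param correction Additive correction delta (>= 0).
#' @param ci_level Confidence level (default 0.95).
#' @param ratio_form \code{"proportion_ratio"} (default) or
#'   \code{"odds_ratio"}.
#' @param se_form \code{"proportion"} (default) or \code{"woolf"}.
#' @return Object of class \code{enrichment_config}.
#' @export
enrichment_config <- function(correction = 0.1, ci_level = 0.95,
                              ratio_form = c("proportion_ratio", "odds_ratio"),
                              se_form = c("proportion", "woolf")) {
  if (correction < 0) stop("correction must be >= 0")
  if (!(ci_level > 0 && ci_level < 1)) stop("ci_level must be in (0, 1)")
  structure(list(correction = correction, ci_level = ci_level,
                 ratio_form = match.arg(ratio_form),
                 se_form = match.arg(se_form)),
            class = "enrichment_config")
}

.corrected_cells <- function(table, d) {
  list(a = table$a + d, b = table$n1 - table$a + d,
       c = table$c + d, e = table$n2 - table$c + d,
       n1 = table$n1 + 2 * d, n2 = table$n2 + 2 * d)
}

#' Corrected enrichment ratio from a 2x2 carrier table
#'
#' @param table A \code{\link{carrier_table}}.
#' @param config An \code{\link{enrichment_config}}.
#' @return Positive scalar ratio (cohort 1 relative to cohort 2).
#' @export
corrected_ratio <- function(table, config = enrichment_config()) {
  x <- .corrected_cells(table, config$correction)
  if (config$ratio_form == "proportion_ratio") (x$a / x$n1) / (x$c / x$n2)
  else (x$a * x$e) / (x$b * x$c)
}

#' Wald interval and p-value on the log ratio
#'
#' The log ratio's standard error is computed on corrected counts; the CI
#' is \eqn{\exp(\ln r \pm z \cdot se)} and the two-sided p-value the normal
#' tail probability of \eqn{\ln r / se}.
#'
#' @inheritParams corrected_ratio
#' @return List with \code{log_se}, \code{ci_low}, \code{ci_high}, \code{p}.
#' @export
wald_test <- function(table, config = enrichment_config()) {
  x <- .corrected_cells(table, config$correction)
  r <- corrected_ratio(table, config)
  se <- if (config$se_form == "proportion")
    sqrt(1 / x$a - 1 / x$n1 + 1 / x$c - 1 / x$n2)
  else
    sqrt(1 / x$a + 1 / x$b + 1 / x$c + 1 / x$e)
  z <- stats::qnorm(1 - (1 - config$ci_level) / 2)
  list(log_se = se,
       ci_low = exp(log(r) - z * se),
       ci_high = exp(log(r) + z * se),
       p = 2 * stats::pnorm(-abs(log(r) / se)))
}

#' Full enrichment result for one carrier table
#'
#' @inheritParams corrected_ratio
#' @param id Identifier label (gene, position or pattern, comparison).
#' @return One-row data frame: \code{id}, \code{a}, \code{n1}, \code{c},
#'   \code{n2}, \code{ratio}, \code{log_se}, \code{ci_low}, \code{ci_high},
#'   \code{p}. FDR q-values are added family-wise by
#'   \code{\link{fdr_adjust}}.
#' @export
enrichment_test <- function(table, config = enrichment_config(), id = NA_character_) {
  w <- wald_test(table, config)
  data.frame(id = id, a = table$a, n1 = table$n1, c = table$c, n2 = table$n2,
             ratio = corrected_ratio(table, config), log_se = w$log_se,
             ci_low = w$ci_low, ci_high = w$ci_high, p = w$p,
             stringsAsFactors = FALSE)
}

#' Benjamini-Hochberg FDR adjustment within families
#'
#' Step-up FDR control applied separately within each family (e.g. one
#' family per gene x comparison for position scans, or per published-change
#' table for pattern tests).
#'
#' @param p Numeric vector of p-values in [0, 1] (extreme Wald z-scores can
#'   underflow to 0).
#' @param family Optional grouping vector; NULL treats all p as one family.
#' @return Vector of q-values, same length and order as \code{p}.
#' @export
fdr_adjust <- function(p, family = NULL) {
  if (any(!is.na(p) & (p < 0 | p > 1))) stop("p-values must lie in [0, 1]")
  if (is.null(family)) return(stats::p.adjust(p, method = "BH"))
  q <- rep(NA_real_, length(p))
  for (f in unique(family)) {
    i <- which(family == f)
    q[i] <- stats::p.adjust(p[i], method = "BH")
  }
  q
}

#' Per-position uncommon-residue enrichment scan
#'
#' For every IMGT position, builds the 2x2 table of uncommon-residue
#' carriers (under \code{reference} and \code{thresholds}) in the target
#' cohort versus the comparator, and computes the corrected ratio, Wald CI,
#' p-value and family-wise q-value. The comparator may be an explicit
#' \code{sequence_set} or a \code{consensus_matrix} with its n (identical
#' results, since per-position carrier counts decompose over symbols).
#'
#' Positions where the germline residue is a gap are flagged
#' \code{not_plotted}. When \code{artifact_filter} is TRUE (appropriate for
#' the target-vs-polyclonal-reference comparison), positions with ratio > 1
#' where the target cohort carries only the germline residue are excluded
#' as sample-size artifacts. q-values are computed over the testable family
#' (not flagged, not excluded).
#'
#' @param target Target \code{sequence_set} (e.g. the AL cohort).
#' @param comparator Comparator \code{sequence_set} or
#'   \code{consensus_matrix}.
#' @param reference Rarity reference \code{consensus_matrix} (polyclonal
#'   role).
#' @param germline The gene's reference \code{\link{germline_allele}}.
#' @param config \code{\link{enrichment_config}}.
#' @param thresholds \code{\link{rarity_thresholds}}.
#' @param comparison Label for the comparison, e.g. \code{"AL_vs_OAS"}.
#' @param artifact_filter Apply the germline-only artifact exclusion.
#' @return Object of class \code{position_scan}: a data frame with one row
#'   per position (gene, position, region, germline residue, counts, ratio,
#'   CI, p, q, flags) plus attributes recording the inputs.
#' @export
scan_positions <- function(target, comparator, reference, germline,
                           config = enrichment_config(),
                           thresholds = rarity_thresholds(),
                           comparison = "target_vs_comparator",
                           artifact_filter = FALSE) {
  genes <- c(normalize_gene_name(target$gene),
             normalize_gene_name(reference$gene), germline$gene)
  cg <- if (inherits(comparator, "consensus_matrix")) comparator$gene else comparator$gene
  genes <- c(genes, normalize_gene_name(cg))
  if (length(unique(genes)) != 1L)
    stop("gene mismatch across scan inputs: ", paste(unique(genes), collapse = ", "))

  tc <- count_uncommon_carriers(target, reference, thresholds)
  cc <- if (inherits(comparator, "consensus_matrix"))
    carriers_from_matrix(comparator, reference, thresholds)
  else count_uncommon_carriers(comparator, reference, thresholds)
  n1 <- attr(tc, "n"); n2 <- attr(cc, "n")

  rows <- lapply(1:IMGT_LENGTH, function(p) {
    enrichment_test(carrier_table(tc[p], n1, cc[p], n2), config,
                    id = paste0(target$gene, ":", p))
  })
  out <- do.call(rbind, rows)
  out <- data.frame(gene = target$gene, position = 1:IMGT_LENGTH,
                    region = region_of(1:IMGT_LENGTH),
                    germline = germline$residues,
                    out[, c("a", "n1", "c", "n2", "ratio", "log_se",
                            "ci_low", "ci_high", "p")],
                    stringsAsFactors = FALSE)
  out$not_plotted <- out$germline == LC_GAP
  out$excluded <- FALSE
  out$exclusion_reason <- NA_character_
  out$q <- NA_real_
  attr(out, "comparison") <- comparison
  attr(out, "thresholds") <- thresholds
  attr(out, "config") <- config
  class(out) <- c("position_scan", "data.frame")
  if (artifact_filter) out <- apply_artifact_filter(out, target, germline)
  .scan_refresh_q(out)
}

.scan_refresh_q <- function(scan) {
  testable <- !scan$excluded & !scan$not_plotted
  scan$q <- NA_real_
  scan$q[testable] <- fdr_adjust(scan$p[testable])
  scan
}

#' Exclude germline-only artifact positions from a scan
#'
#' In comparisons against a much larger cohort, a position can show a
#' positive ratio even though every target sequence carries exactly the
#' germline residue there (the reference's residue diversity alone drives
#' the signal). Such positions are marked excluded with reason
#' \code{"germline-only artifact"} and q-values are recomputed over the
#' remaining family.
#'
#' @param scan A \code{position_scan}.
#' @param target The target \code{sequence_set} the scan was computed from.
#' @param germline The gene's \code{\link{germline_allele}}.
#' @return The scan with exclusion flags and refreshed q-values.
#' @export
apply_artifact_filter <- function(scan, target, germline) {
  n <- length(target)
  germline_only <- vapply(1:IMGT_LENGTH, function(p)
    all(target$residues[, p] == germline$residues[p]), logical(1))
  hit <- scan$ratio > 1 & germline_only[scan$position]
  scan$excluded[hit] <- TRUE
  scan$exclusion_reason[hit] <- "germline-only artifact"
  .scan_refresh_q(scan)
}

#' Write a position scan as TSV
#'
#' @param scan A \code{position_scan}.
#' @param path Output path.
#' @export
write_scan_tsv <- function(scan, path) {
  utils::write.table(as.data.frame(scan), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Residue-by-allele contingency at one position
#'
#' Cross-tabulates the residues observed at a position against the
#' per-sequence allele assignments; sequences without an assignment are
#' grouped under \code{"unassigned"}. Residue marginals equal the position's
#' consensus counts.
#'
#' @param set A \code{\link{sequence_set}} carrying allele assignments.
#' @param position IMGT position.
#' @return A contingency \code{table} (residue x allele).
#' @export
allele_stratify <- function(set, position) {
  if (position < 1L || position > IMGT_LENGTH)
    stop("position out of range 1..", IMGT_LENGTH)
  allele <- set$alleles
  allele[is.na(allele) | allele == ""] <- "unassigned"
  table(residue = set$residues[, position], allele = allele)
}

#' Positions where germline alleles of a gene disagree
#'
#' @param alleles List of \code{\link{germline_allele}} objects for one
#'   gene.
#' @return Sorted integer vector of positions with at least two distinct
#'   symbols across the alleles; empty when fewer than two alleles are
#'   given.
#' @export
allele_differing_positions <- function(alleles) {
  if (length(alleles) < 2L) return(integer(0))
  m <- do.call(rbind, lapply(alleles, `[[`, "residues"))
  which(apply(m, 2, function(col) length(unique(col)) > 1L))
}
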