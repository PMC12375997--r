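#' Build a 127 x 21 residue consensus matrix from a sequence set
#'
#' Tabulates, at each of the 127 IMGT positions, the number and fraction of
#' sequences carrying each of the 21 symbols (20 amino acids plus gap).
#' Every position's counts sum to the set size and its fractions to 1.
#'
#' @param set A \code{\link{sequence_set}} with n >= 1 members.
#' @return Object of class \code{consensus_matrix} with fields \code{gene},
#'   \code{cohort}, \code{n}, \code{counts} (127 x 21 integer matrix) and
#'   \code{fractions} (counts / n).
#' @export
build_consensus <- function(set) {
  stopifnot(inherits(set, "sequence_set"))
  n <- length(set)
  if (n < 1L) stop("cannot build a consensus matrix from an empty set")
  ab <- lc_alphabet()
  codes <- match(set$residues, ab)
  if (anyNA(codes)) stop("set contains non-alphabet symbols")
  # one-pass tabulation over (position, symbol) cells
  idx <- (rep(1:IMGT_LENGTH, each = n) - 1L) * length(ab) + codes
  tab <- tabulate(idx, nbins = length(ab) * IMGT_LENGTH)
  counts <- matrix(tab, nrow = IMGT_LENGTH, ncol = length(ab), byrow = TRUE,
                   dimnames = list(1:IMGT_LENGTH, ab))
  consensus_from_counts(counts, gene = set$gene, cohort = set$cohort)
}

#' Construct a consensus matrix from explicit counts or fractions
#'
#' \code{consensus_from_counts} is the canonical constructor.
#' \code{consensus_from_fractions} reconstructs integer counts by rounding
#' fraction x n, for large published cohorts (e.g. an OAS-scale matrix
#' shipped as fractions plus a sequence count) where storing the sequences
#' is impractical; the rounded counts must re-normalize to the given
#' fractions within tolerance.
#'
#' @param counts 127 x 21 non-negative integer matrix (columns in alphabet
#'   order, gap last).
#' @param fractions 127 x 21 matrix of fractions, rows summing to 1.
#' @param n Number of sequences behind a fraction matrix.
#' @param gene,cohort Labels.
#' @param tol Maximum |round(f*n)/n - f| tolerated per cell.
#' @return A \code{consensus_matrix}.
#' @export
consensus_from_counts <- function(counts, gene, cohort) {
  counts <- as.matrix(counts)
  stopifnot(nrow(counts) == IMGT_LENGTH, ncol(counts) == length(lc_alphabet()))
  if (any(counts < 0)) stop("counts must be non-negative")
  rs <- rowSums(counts)
  n <- rs[1]
  if (any(rs != n)) stop("every position's counts must sum to the same n")
  dimnames(counts) <- list(1:IMGT_LENGTH, lc_alphabet())
  structure(list(gene = gene, cohort = cohort, n = as.integer(n),
                 counts = counts, fractions = counts / n),
            class = "consensus_matrix")
}

#' @rdname consensus_from_counts
#' @export
consensus_from_fractions <- function(fractions, n, gene, cohort, tol = 1e-6) {
  fractions <- as.matrix(fractions)
  counts <- round(fractions * n)
  if (max(abs(counts / n - fractions)) > tol)
    stop("fractions are not consistent with n sequences (tolerance ", tol, ")")
  # repair rounding drift so each row sums exactly to n, adjusting the
  # largest cell (error bounded by 21 half-units of 1/n)
  drift <- n - rowSums(counts)
  for (p in which(drift != 0)) {
    k <- which.max(counts[p, ])
    counts[p, k] <- counts[p, k] + drift[p]
  }
  consensus_from_counts(counts, gene = gene, cohort = cohort)
}

#' @export
print.consensus_matrix <- function(x, ...) {
  cat("<consensus_matrix>", x$gene, x$cohort, "n =", x$n, "\n")
  invisible(x)
}

#' Look up the consensus fraction of a residue at a position
#'
#' @param matrix A \code{consensus_matrix}.
#' @param position IMGT position.
#' @param residue Alphabet symbol.
#' @export
consensus_fraction <- function(matrix, position, residue) {
  unname(matrix$fractions[cbind(position, match(residue, lc_alphabet()))])
}

#' Difference matrix between two consensus matrices
#'
#' Element-wise subtraction of fractions (a - b) for the same gene; every
#' position's values sum to 0 and each entry lies in [-1, 1].
#'
#' @param a,b \code{consensus_matrix} objects on the same gene.
#' @return Object of class \code{difference_matrix} with \code{values}.
#' @export
difference_matrix <- function(a, b) {
  if (normalize_gene_name(a$gene) != normalize_gene_name(b$gene))
    stop("gene mismatch: ", a$gene, " vs ", b$gene)
  structure(list(gene = a$gene, cohort_a = a$cohort, cohort_b = b$cohort,
                 values = a$fractions - b$fractions),
            class = "difference_matrix")
}

# Gini coefficient of a non-negative vector via the sorted closed form;
# equals the mean-absolute-difference definition sum|xi-xj| / (2 n^2 mu).
.gini <- function(x, corrected = TRUE) {
  n <- length(x)
  s <- sum(x)
  if (s <= 0) return(0)
  x <- sort(x)
  g <- 2 * sum(seq_len(n) * x) / (n * s) - (n + 1) / n
  if (corrected) g <- g * n / (n - 1)
  min(max(g, 0), 1)
}

#' Per-position Gini coefficient of residue diversity
#'
#' Measures the inequality of the 21-entry residue fraction distribution at
#' each position: 0 when all 21 symbols are equally frequent, 1 when a
#' single symbol accounts for every sequence. The default applies the
#' small-sample correction (x n/(n-1) with n = 21 symbols), which is what
#' makes a point mass reach exactly 1.
#'
#' @param matrix A \code{consensus_matrix}.
#' @param positions Positions to evaluate (default all 127).
#' @param corrected Apply the sample correction (default TRUE).
#' @return Named numeric vector of Gini coefficients in [0, 1].
#' @export
position_gini <- function(matrix, positions = 1:IMGT_LENGTH, corrected = TRUE) {
  if (any(positions < 1L | positions > IMGT_LENGTH))
    stop("position out of range 1..", IMGT_LENGTH)
  out <- vapply(positions, function(p) .gini(matrix$fractions[p, ], corrected),
                numeric(1))
  names(out) <- positions
  out
}

#' Position-wise Pearson correlation between two consensus matrices
#'
#' For each position, the Pearson correlation between the two 21-entry
#' residue fraction vectors; rho = 1 for identical residue distributions.
#' Positions where either vector has zero variance (all fractions equal)
#' are flagged undefined. \code{mode = "residue"} instead correlates the
#' 127-entry position profiles of each residue column.
#'
#' @param a,b \code{consensus_matrix} objects on the same gene.
#' @param mode \code{"position"} (default) or \code{"residue"}.
#' @return Data frame with \code{position} (or \code{residue}), \code{rho}
#'   and logical \code{undefined}.
#' @export
position_correlation <- function(a, b, mode = c("position", "residue")) {
  mode <- match.arg(mode)
  if (normalize_gene_name(a$gene) != normalize_gene_name(b$gene))
    stop("gene mismatch: ", a$gene, " vs ", b$gene)
  if (mode == "position") {
    rho <- vapply(1:IMGT_LENGTH, function(p) {
      x <- a$fractions[p, ]; y <- b$fractions[p, ]
      if (stats::sd(x) == 0 || stats::sd(y) == 0) return(NA_real_)
      stats::cor(x, y)
    }, numeric(1))
    data.frame(position = 1:IMGT_LENGTH, rho = rho, undefined = is.na(rho))
  } else {
    ab <- lc_alphabet()
    rho <- vapply(seq_along(ab), function(k) {
      x <- a$fractions[, k]; y <- b$fractions[, k]
      if (stats::sd(x) == 0 || stats::sd(y) == 0) return(NA_real_)
      stats::cor(x, y)
    }, numeric(1))
    data.frame(residue = ab, rho = rho, undefined = is.na(rho))
  }
}

#' Euclidean distance between consensus matrices
#'
#' The square root of the sum of squared element-wise differences over all
#' 127 x 21 cells (the Frobenius norm of the difference matrix); genes may
#' differ since the scaffold is shared.
#'
#' @param a,b \code{consensus_matrix} objects.
#' @param on Compare \code{"fractions"} (default) or raw \code{"counts"}.
#' @return Non-negative scalar; 0 iff the compared matrices are identical.
#' @export
matrix_distance <- function(a, b, on = c("fractions", "counts")) {
  on <- match.arg(on)
  sqrt(sum((a[[on]] - b[[on]])^2))
}

#' Hierarchical clustering of consensus matrices
#'
#' Agglomerative clustering on the pairwise Euclidean distance matrix,
#' yielding a dendrogram whose leaves are gene/cohort labels. Complete
#' linkage by default (the default of \code{\link[stats]{hclust}}).
#'
#' @param matrices List of at least two \code{consensus_matrix} objects.
#' @param method Linkage: \code{"complete"}, \code{"average"} or
#'   \code{"single"}.
#' @param on Distance over fractions or counts.
#' @return Object of class \code{consensus_dendrogram} wrapping the
#'   \code{hclust} fit; export with \code{\link{as_newick}}.
#' @export
cluster_matrices <- function(matrices, method = c("complete", "average", "single"),
                             on = "fractions") {
  method <- match.arg(method)
  m <- length(matrices)
  if (m < 2L) stop("need at least two matrices to cluster")
  labels <- vapply(matrices, function(x) paste(x$gene, x$cohort, sep = "_"),
                   character(1))
  d <- matrix(0, m, m, dimnames = list(labels, labels))
  for (i in seq_len(m - 1)) for (j in (i + 1):m)
    d[i, j] <- d[j, i] <- matrix_distance(matrices[[i]], matrices[[j]], on = on)
  fit <- stats::hclust(stats::as.dist(d), method = method)
  structure(list(hclust = fit, method = method, labels = labels),
            class = "consensus_dendrogram")
}

#' Export a consensus dendrogram as a newick string or file
#'
#' @param dendrogram A \code{consensus_dendrogram}.
#' @param path Optional file to write; otherwise the newick string is
#'   returned.
#' @export
as_newick <- function(dendrogram, path = NULL) {
  phy <- ape::as.phylo(dendrogram$hclust)
  if (is.null(path)) ape::write.tree(phy)
  else { ape::write.tree(phy, file = path); invisible(path) }
}

#' Modified sequence-logo data: all but the most frequent residue
#'
#' Because the germline residue dominates most positions, the standard
#' information-content logo hides somatic variation. This variant drops the
#' single most frequent residue at each position (alphabet-first tie-break)
#' and reports every other residue with height equal to its raw fraction,
#' so per-position heights sum to 1 minus the maximum fraction.
#'
#' @param matrix A \code{consensus_matrix}.
#' @return Data frame (long form) with \code{position}, \code{residue},
#'   \code{height}; zero-height rows are dropped.
#' @export
logo_data <- function(matrix) {
  ab <- lc_alphabet()
  out <- lapply(1:IMGT_LENGTH, function(p) {
    f <- matrix$fractions[p, ]
    top <- which.max(f)  # ties: first index in alphabet order wins exclusion
    keep <- setdiff(seq_along(ab), top)
    keep <- keep[f[keep] > 0]
    if (!length(keep)) return(NULL)
    data.frame(position = p, residue = ab[keep], height = unname(f[keep]),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  if (is.null(out))
    out <- data.frame(position = integer(0), residue = character(0),
                      height = numeric(0))
  rownames(out) <- NULL
  out
}

#' Write logo data as long-form TSV
#'
#' @param logo Output of \code{\link{logo_data}}.
#' @param path Output path.
#' @export
write_logo_tsv <- function(logo, path) {
  utils::write.table(logo, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
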