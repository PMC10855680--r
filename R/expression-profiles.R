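# Tissue-expression summarization for SRCR genes.

#' Normalize an expression matrix for heatmap display
#'
#' Standard heatmap convention: \code{log2(value + pseudo)} followed by a
#' per-gene z-score. Constant rows map to all-zero rows. Multiplying the raw
#' matrix by a positive constant leaves the result unchanged (the log shift
#' is absorbed by the z-score).
#'
#' @param x \code{SummarizedExperiment} with a \code{"tpm"} assay, or a
#'   non-negative numeric matrix (genes x tissues).
#' @param pseudo pseudocount added before the log (default 1).
#' @param log2_transform,zscore flags for the two steps.
#' @return numeric matrix of the same shape.
#' @export
normalizeExpression <- function(x, pseudo = 1, log2_transform = TRUE,
                                zscore = TRUE) {
  m <- if (methods::is(x, "SummarizedExperiment"))
    SummarizedExperiment::assay(x, "tpm") else x
  stopifnot(is.matrix(m))
  if (any(m < 0)) stop("expression values must be non-negative")
  if (log2_transform) m <- log2(m + pseudo)
  if (zscore) {
    mu <- rowMeans(m)
    sdp <- sqrt(rowMeans((m - mu)^2))  # population sd: rows get unit variance
    m <- (m - mu) / ifelse(sdp > 0, sdp, 1)
    m[sdp == 0, ] <- 0
  }
  m
}

#' Tissue-enrichment summary for SRCR genes
#'
#' For each SRCR gene, the tissue of maximal normalized expression (ties
#' broken by tissue column order); the per-tissue counts of SRCR genes
#' maximal there; and the fraction of SRCR genes whose argmax tissue is
#' flagged digestive-associated. Under a uniform null this fraction is
#' expected near \code{length(digestive_tissues) / n_tissues}.
#'
#' @param normalized matrix from \code{\link{normalizeExpression}}.
#' @param srcr_gene_ids SRCR gene ids (must intersect rownames).
#' @param digestive_tissues subset of colnames flagged digestive-associated.
#' @return list with \code{argmax_tissue} (named character),
#'   \code{tissue_counts} (named integer over all tissues),
#'   \code{digestive_fraction} and \code{null_expectation}.
#' @export
tissueEnrichmentSummary <- function(normalized, srcr_gene_ids,
                                    digestive_tissues) {
  stopifnot(all(digestive_tissues %in% colnames(normalized)))
  ids <- intersect(srcr_gene_ids, rownames(normalized))
  if (!length(ids)) stop("no SRCR genes in the expression matrix")
  m <- normalized[ids, , drop = FALSE]
  am <- colnames(m)[apply(m, 1, which.max)]
  names(am) <- ids
  counts <- table(factor(am, levels = colnames(m)))
  frac <- mean(am %in% digestive_tissues)
  list(argmax_tissue = am,
       tissue_counts = stats::setNames(as.integer(counts), colnames(m)),
       digestive_fraction = frac,
       null_expectation = length(digestive_tissues) / ncol(normalized))
}
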