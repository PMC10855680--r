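# Conserved-cysteine column detection and Group A/B/C classification.

.alnMatrix <- function(alignment) {
  if (methods::is(alignment, "XStringSet"))
    alignment <- stats::setNames(as.character(alignment), names(alignment))
  stopifnot(is.character(alignment))
  if (length(alignment) < 2L)
    stop("conservation analysis needs at least 2 aligned rows")
  n <- unique(nchar(alignment))
  if (length(n) != 1L) stop("aligned rows must have equal length")
  do.call(rbind, strsplit(toupper(alignment), ""))
}

#' Conserved cysteine columns of a domain alignment
#'
#' A column is a conserved-cysteine column when the fraction of cysteines
#' among its non-gap rows is at least \code{tau}.
#'
#' @param alignment \code{AAStringSet} or named character vector of
#'   equal-length aligned sequences (gap character \code{-}); >= 2 rows.
#' @param tau occupancy threshold in (0, 1]; default 0.7. Raising \code{tau}
#'   can only remove columns.
#' @return sorted integer vector of column indices.
#' @export
conservedCysteineColumns <- function(alignment, tau = 0.7) {
  stopifnot(tau > 0, tau <= 1)
  m <- .alnMatrix(alignment)
  nonGap <- colSums(m != "-")
  cys <- colSums(m == "C")
  which(nonGap > 0 & cys / pmax(nonGap, 1L) >= tau)
}

# Complete-slot template match over a sequence's cysteine position list.
# Slot 1 must fall in start_range; consecutive matched slots must be spaced
# within the template gap ranges; non-template cysteines may be skipped.
# Returns matched positions or NULL. Depth-first over candidate positions,
# earliest-position match preferred.
.matchTemplate <- function(cysPos, tpl) {
  k <- length(tpl$positions)
  if (length(cysPos) < k) return(NULL)
  rec <- function(slot, prevPos) {
    if (slot > k) return(integer(0))
    cand <- if (slot == 1L)
      cysPos[cysPos >= tpl$start_range[1] & cysPos <= tpl$start_range[2]]
    else {
      lo <- prevPos + tpl$gap_ranges[slot - 1L, 1]
      hi <- prevPos + tpl$gap_ranges[slot - 1L, 2]
      cysPos[cysPos >= lo & cysPos <= hi]
    }
    for (p in cand) {
      rest <- rec(slot + 1L, p)
      if (!is.null(rest)) return(c(p, rest))
    }
    NULL
  }
  rec(1L, NA_integer_)
}

#' Classify an SRCR domain into Group A, B or C
#'
#' Matches the sequence's cysteine positions against each group template's
#' spacing constraints (extra, non-template cysteines may be skipped).
#' Because the six core slots of Group A are a subset of both the B and C
#' templates, a true Group B or C domain also matches A; templates are
#' therefore tried most-specific first (B, then C, then A) and the first
#' complete match wins. No complete match gives \code{"unclassified"}.
#'
#' @param domain_seq unaligned amino-acid sequence (character scalar).
#' @param templates see \code{\link{srcrTemplates}}.
#' @return list with \code{group} (\code{"A"/"B"/"C"/"unclassified"}) and
#'   \code{slots} (matched cysteine positions, empty if unclassified).
#' @export
classifyDomain <- function(domain_seq, templates = srcrTemplates()) {
  seqc <- strsplit(gsub("-", "", toupper(domain_seq)), "")[[1]]
  cysPos <- which(seqc == "C")
  for (g in c("B", "C", "A")) {
    hit <- .matchTemplate(cysPos, templates[[g]])
    if (!is.null(hit)) return(list(group = g, slots = hit))
  }
  list(group = "unclassified", slots = integer(0))
}

#' Classify a set of domains
#'
#' @param seqs named character vector or \code{AAStringSet} of domain
#'   sequences (gaps tolerated and stripped).
#' @param templates see \code{\link{srcrTemplates}}.
#' @return data.frame with columns \code{domain_id}, \code{group},
#'   \code{cys_count} (number of matched template slots; 0 if unclassified).
#' @export
classifyDomains <- function(seqs, templates = srcrTemplates()) {
  if (methods::is(seqs, "XStringSet"))
    seqs <- stats::setNames(as.character(seqs), names(seqs))
  ids <- if (is.null(names(seqs))) as.character(seq_along(seqs)) else
    names(seqs)
  res <- lapply(seqs, classifyDomain, templates = templates)
  data.frame(domain_id = ids,
             group = vapply(res, `[[`, character(1), "group"),
             cys_count = vapply(res, function(r) length(r$slots), integer(1)),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Cysteine profile of an aligned domain set
#'
#' Combines column-level conservation with per-domain template
#' classification of the degapped rows.
#'
#' @param alignment as in \code{\link{conservedCysteineColumns}}.
#' @param tau occupancy threshold.
#' @param templates see \code{\link{srcrTemplates}}.
#' @return a \linkS4class{CysteineProfile}.
#' @export
cysteineProfile <- function(alignment, tau = 0.7,
                            templates = srcrTemplates()) {
  m <- .alnMatrix(alignment)
  cols <- conservedCysteineColumns(alignment, tau)
  rows <- apply(m, 1, paste, collapse = "")
  cls <- classifyDomains(stats::setNames(rows, rownames(m)), templates)
  cls$cys_at_conserved <- apply(m[, cols, drop = FALSE] == "C", 1, sum)
  methods::new("CysteineProfile", columns = as.integer(cols),
               perDomain = cls, tau = tau)
}

#' Per-group gene and domain census
#'
#' Counts domains per group and genes containing at least one domain of each
#' group; a multi-group gene is counted once under every group it contains.
#'
#' @param classifications data.frame with columns \code{gene_id} and
#'   \code{group} (one row per domain).
#' @return list with \code{domain_counts} and \code{gene_counts}, named
#'   integer vectors over A/B/C/unclassified (zero-filled).
#' @export
groupCensus <- function(classifications) {
  lv <- c("A", "B", "C", "unclassified")
  if (!nrow(classifications)) {
    z <- stats::setNames(integer(length(lv)), lv)
    return(list(domain_counts = z, gene_counts = z))
  }
  g <- factor(classifications$group, levels = lv)
  domain_counts <- table(g)
  gene_counts <- vapply(lv, function(gl)
    length(unique(classifications$gene_id[classifications$group == gl])),
    integer(1))
  list(domain_counts = stats::setNames(as.integer(domain_counts), lv),
       gene_counts = stats::setNames(as.integer(gene_counts), lv))
}

#' Extract SRCR domain sequences from confirmed genes
#'
#' Cuts each SRCR domain hit out of its protein, naming the result
#' \code{<gene>.d<i>} in \code{start_aa} order.
#'
#' @param x a \linkS4class{SrcrGeneSet}.
#' @param prot \code{AAStringSet} of protein sequences named by gene id.
#' @return named character vector of domain sequences.
#' @export
srcrDomainSeqs <- function(x, prot) {
  h <- srcrDomainHits(x)
  out <- character(0)
  for (g in unique(h$gene_id)) {
    hg <- h[h$gene_id == g, , drop = FALSE]
    hg <- hg[order(hg$start_aa), , drop = FALSE]
    p <- as.character(prot[[g]])
    for (d in seq_len(nrow(hg)))
      out[paste0(g, ".d", d)] <- substr(p, hg$start_aa[d], hg$end_aa[d])
  }
  out
}
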