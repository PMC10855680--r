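# Candidate integration and the per-species SRCR-SF inventory.

#' Integrate domain and homology evidence into a candidate list
#'
#' Takes the union of genes with at least one SRCR domain hit at
#' \code{evalue <= evalue_max} and genes appearing in the homology table
#' (query or subject) at \code{evalue <= evalue_max}, removes redundancy
#' (one entry per gene), and records which screens supported each gene.
#' Genes referenced by a hit but absent from the annotation are dropped with
#' a message.
#'
#' @param domainHits data.frame from \code{\link{readDomainHits}}.
#' @param blastHits data.frame from \code{\link{readBlastTab}} (may be
#'   zero-row).
#' @param models a \linkS4class{GeneModelSet} defining known gene ids.
#' @param evalue_max screening threshold (default \code{1e-5}).
#' @param srcrAccession accession(s) treated as the SRCR domain.
#' @return data.frame with columns \code{gene_id}, \code{evidence}
#'   (comma-joined subset of \code{hmm,blast}); one row per candidate.
#' @export
integrateCandidates <- function(domainHits, blastHits, models,
                                evalue_max = 1e-5,
                                srcrAccession = "PF00530") {
  stopifnot(evalue_max > 0)
  known <- geneIds(models)
  dh <- domainHits[domainHits$accession %in% srcrAccession &
                     domainHits$evalue <= evalue_max, , drop = FALSE]
  hmmGenes <- unique(dh$gene_id)
  bh <- blastHits[blastHits$evalue <= evalue_max, , drop = FALSE]
  blastGenes <- unique(c(bh$query_id, bh$subject_id))
  blastGenes <- blastGenes[blastGenes %in% known]  # seed ids are not genes
  cand <- union(hmmGenes, blastGenes)
  unknown <- setdiff(cand, known)
  if (length(unknown)) {
    message(length(unknown), " candidate id(s) absent from annotation, ",
            "dropped: ", paste(utils::head(unknown, 5), collapse = ", "))
    cand <- setdiff(cand, unknown)
  }
  cand <- cand[order(match(cand, known))]
  ev <- vapply(cand, function(g) paste(
    c(if (g %in% hmmGenes) "hmm", if (g %in% blastGenes) "blast"),
    collapse = ","), character(1))
  data.frame(gene_id = cand, evidence = unname(ev), stringsAsFactors = FALSE)
}

#' Confirm candidates by SRCR domain content
#'
#' Retains only candidates with at least one SRCR \code{DomainHit} at the
#' threshold (homology evidence alone does not admit a gene), collapses
#' duplicate hits, merges near-identical hits from different sources
#' (>= 50\% reciprocal overlap, keeping the lower E-value), and classifies
#' each confirmed gene as solely-SRCR or not.
#'
#' @param candidates data.frame from \code{\link{integrateCandidates}}.
#' @param domainHits full domain-hit table (SRCR and other accessions).
#' @param evalue_max screening threshold applied to SRCR hits.
#' @param srcrAccession accession(s) treated as the SRCR domain.
#' @return a \linkS4class{SrcrGeneSet}.
#' @export
confirmSrcrGenes <- function(candidates, domainHits, evalue_max = 1e-5,
                             srcrAccession = "PF00530") {
  dh <- domainHits[domainHits$gene_id %in% candidates$gene_id, , drop = FALSE]
  isSrcr <- dh$accession %in% srcrAccession & dh$evalue <= evalue_max
  srcr <- .collapseHits(dh[isSrcr, , drop = FALSE])
  other <- .collapseHits(dh[!dh$accession %in% srcrAccession, , drop = FALSE])
  confirmed <- unique(srcr$gene_id)
  confirmed <- candidates$gene_id[candidates$gene_id %in% confirmed]
  other <- other[other$gene_id %in% confirmed, , drop = FALSE]
  nS <- table(factor(srcr$gene_id, levels = confirmed))
  tab <- data.frame(
    gene_id = confirmed,
    n_srcr_domains = as.integer(nS[confirmed]),
    solely_srcr = !(confirmed %in% other$gene_id),
    evidence = candidates$evidence[match(confirmed, candidates$gene_id)],
    stringsAsFactors = FALSE)
  methods::new("SrcrGeneSet", table = tab,
               srcrHits = srcr[srcr$gene_id %in% confirmed, , drop = FALSE],
               otherHits = other)
}

# Collapse exact-duplicate hits (same gene, accession, span) and merge hits
# of the same accession with >= 50% reciprocal overlap, keeping the lower
# E-value. Hits are returned sorted by gene then start_aa.
.collapseHits <- function(h) {
  if (!nrow(h)) return(h[, , drop = FALSE])
  h <- h[order(h$gene_id, h$accession, h$start_aa, h$evalue), , drop = FALSE]
  keep <- rep(TRUE, nrow(h))
  for (i in seq_len(nrow(h))[-1]) {
    for (j in which(keep[seq_len(i - 1)])) {
      if (h$gene_id[j] != h$gene_id[i] || h$accession[j] != h$accession[i])
        next
      ov <- min(h$end_aa[i], h$end_aa[j]) - max(h$start_aa[i], h$start_aa[j]) + 1L
      if (ov <= 0) next
      wi <- h$end_aa[i] - h$start_aa[i] + 1L
      wj <- h$end_aa[j] - h$start_aa[j] + 1L
      if (ov >= 0.5 * wi && ov >= 0.5 * wj) {
        # merge into the lower-evalue row
        if (h$evalue[i] < h$evalue[j]) {
          h[j, c("start_aa", "end_aa", "evalue", "source")] <-
            h[i, c("start_aa", "end_aa", "evalue", "source")]
        }
        keep[i] <- FALSE
        break
      }
    }
  }
  h <- h[keep, , drop = FALSE]
  h <- h[order(h$gene_id, h$start_aa), , drop = FALSE]
  rownames(h) <- NULL
  h
}

#' Domain-composition summary over non-SRCR domains
#'
#' Counts each non-SRCR accession occurrence across the confirmed genes and
#' reports the \code{top_k} accessions with their percentage of all non-SRCR
#' occurrences (two decimals, half-up); ties broken lexicographically by
#' accession.
#'
#' @param x a \linkS4class{SrcrGeneSet}.
#' @param top_k number of rows to report.
#' @return data.frame with columns \code{accession}, \code{name},
#'   \code{count}, \code{percent}; zero rows when there are no non-SRCR
#'   occurrences.
#' @export
domainComposition <- function(x, top_k = 5L) {
  oh <- otherDomainHits(x)
  if (!nrow(oh))
    return(data.frame(accession = character(0), name = character(0),
                      count = integer(0), percent = numeric(0)))
  cnt <- table(oh$accession)
  df <- data.frame(accession = names(cnt), count = as.integer(cnt),
                   stringsAsFactors = FALSE)
  df$name <- oh$name[match(df$accession, oh$accession)]
  df <- df[order(-df$count, df$accession), , drop = FALSE]
  df$percent <- roundHalfUp(100 * df$count / sum(df$count), 2)
  rownames(df) <- NULL
  utils::head(df[, c("accession", "name", "count", "percent")], top_k)
}

#' Fraction of genes encoding solely the SRCR domain
#'
#' @param x a \linkS4class{SrcrGeneSet} (non-empty).
#' @return percentage (0-100), two decimals, half-up.
#' @export
solelySrcrFraction <- function(x) {
  if (length(x) == 0) stop("no SRCR genes")
  roundHalfUp(100 * sum(x@table$solely_srcr) / length(x), 2)
}

#' Per-species inventory report
#'
#' @param x a \linkS4class{SrcrGeneSet}.
#' @param species_label free-text label for the report.
#' @param top_k rows in the domain-composition table.
#' @return list with \code{species_label}, \code{n_srcr_genes},
#'   \code{n_solely_srcr}, \code{solely_percent}, \code{composition}
#'   (data.frame) and \code{gene_table}.
#' @export
inventoryReport <- function(x, species_label = "synthetic", top_k = 5L) {
  list(species_label = species_label,
       n_srcr_genes = length(x),
       n_solely_srcr = sum(x@table$solely_srcr),
       solely_percent = if (length(x)) solelySrcrFraction(x) else NA_real_,
       composition = domainComposition(x, top_k),
       gene_table = x@table)
}
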