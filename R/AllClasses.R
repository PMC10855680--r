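#' Gene models parsed from genome annotation
#'
#' Container for one-protein-per-gene models: gene spans, exons and CDS
#' segments in transcription order, and the encoded proteins. Coordinates are
#' 1-based inclusive throughout (the GRanges convention), so GFF3 import and
#' export are the identity on coordinates. For multi-isoform annotations the
#' isoform with the longest total CDS represents the gene.
#'
#' The \code{rank} of a gene is its ordinal position among all genes on its
#' scaffold sorted by start coordinate; tandem-cluster calling operates on
#' rank differences, not base-pair distances.
#'
#' @slot genes \code{GRanges}, one range per gene, with metadata columns
#'   \code{gene_id} and \code{rank}.
#' @slot exons \code{GRangesList} named by gene id; ranges in transcription
#'   order (decreasing start on the minus strand).
#' @slot cds \code{GRangesList} named by gene id, transcription order, with a
#'   \code{phase} metadata column (0/1/2, GFF3 convention).
#' @slot proteins \code{AAStringSet} named by gene id; may cover a subset of
#'   genes (proteins are optional).
#'
#' @importClassesFrom GenomicRanges GRanges CompressedGRangesList
#' @importClassesFrom Biostrings AAStringSet
#' @exportClass GeneModelSet
setClass("GeneModelSet",
  slots = c(
    genes = "GRanges",
    exons = "CompressedGRangesList",
    cds = "CompressedGRangesList",
    proteins = "AAStringSet"
  )
)

.validGeneModelSet <- function(object) {
  msg <- character(0)
  ids <- object@genes$gene_id
  if (is.null(ids) || anyDuplicated(ids))
    msg <- c(msg, "gene_id metadata column must exist and be unique")
  if (!identical(names(object@exons), ids) ||
      !identical(names(object@cds), ids))
    msg <- c(msg, "exons and cds must be named by gene_id in gene order")
  # rank unique per scaffold
  rk <- object@genes$rank
  if (is.null(rk)) {
    msg <- c(msg, "rank metadata column missing")
  } else {
    sc <- as.character(GenomicRanges::seqnames(object@genes))
    if (any(vapply(split(rk, sc), anyDuplicated, integer(1)) > 0))
      msg <- c(msg, "gene ranks must be unique per scaffold")
  }
  # exons sorted in transcription order and non-overlapping
  for (i in seq_along(object@exons)) {
    ex <- object@exons[[i]]
    if (length(ex) < 2) next
    st <- BiocGenerics::start(ex)
    minus <- as.character(BiocGenerics::strand(ex)[1]) == "-"
    if (minus && any(diff(st) >= 0))
      msg <- c(msg, sprintf("exons of %s not in transcription order", ids[i]))
    if (!minus && any(diff(st) <= 0))
      msg <- c(msg, sprintf("exons of %s not in transcription order", ids[i]))
    srt <- sort(ex)
    if (any(BiocGenerics::start(srt)[-1] <=
            BiocGenerics::end(srt)[-length(srt)]))
      msg <- c(msg, sprintf("exons of %s overlap", ids[i]))
  }
  # CDS length consistency with protein where a protein is present:
  # either 3*len(protein) (no annotated stop) or 3*len(protein)+3
  for (id in names(object@proteins)) {
    if (!id %in% ids) {
      msg <- c(msg, sprintf("protein %s has no gene model", id))
      next
    }
    cw <- sum(BiocGenerics::width(object@cds[[id]]))
    pl <- length(object@proteins[[id]])
    if (cw %% 3L != 0L)
      msg <- c(msg, sprintf("CDS length of %s not a multiple of 3", id))
    else if (cw != 3L * pl && cw != 3L * pl + 3L)
      msg <- c(msg, sprintf(
        "CDS length of %s (%d) inconsistent with protein length %d", id, cw, pl))
  }
  if (length(msg)) msg else TRUE
}

setValidity("GeneModelSet", .validGeneModelSet)

#' Construct a GeneModelSet
#'
#' @param genes \code{GRanges} with \code{gene_id} metadata column; \code{rank}
#'   is computed here (per-scaffold start order) if absent.
#' @param exons,cds named \code{GRangesList}s in transcription order.
#' @param proteins optional named \code{AAStringSet}.
#' @return a validated \code{GeneModelSet}.
#' @export
GeneModelSet <- function(genes, exons, cds,
                         proteins = Biostrings::AAStringSet()) {
  if (is.null(genes$rank)) {
    sc <- as.character(GenomicRanges::seqnames(genes))
    rk <- integer(length(genes))
    for (s in unique(sc)) {
      i <- which(sc == s)
      rk[i] <- rank(BiocGenerics::start(genes)[i], ties.method = "first")
    }
    genes$rank <- rk
  }
  exons <- exons[genes$gene_id]
  cds <- cds[genes$gene_id]
  methods::new("GeneModelSet", genes = genes,
               exons = GenomicRanges::GRangesList(exons),
               cds = GenomicRanges::GRangesList(cds),
               proteins = proteins)
}

#' @rdname GeneModelSet-class
#' @aliases geneIds geneRanges geneExons geneCds proteins geneRanks
#' @export
setMethod("geneIds", "GeneModelSet", function(x) x@genes$gene_id)

#' @rdname GeneModelSet-class
#' @export
setMethod("geneRanges", "GeneModelSet", function(x) x@genes)

#' @rdname GeneModelSet-class
#' @export
setMethod("geneExons", "GeneModelSet", function(x) x@exons)

#' @rdname GeneModelSet-class
#' @export
setMethod("geneCds", "GeneModelSet", function(x) x@cds)

#' @rdname GeneModelSet-class
#' @export
setMethod("proteins", "GeneModelSet", function(x) x@proteins)

#' @rdname GeneModelSet-class
#' @export
setMethod("geneRanks", "GeneModelSet", function(x) {
  stats::setNames(x@genes$rank, x@genes$gene_id)
})

#' @rdname GeneModelSet-class
#' @export
setMethod("length", "GeneModelSet", function(x) length(x@genes))

setMethod("show", "GeneModelSet", function(object) {
  sc <- unique(as.character(GenomicRanges::seqnames(object@genes)))
  cat("GeneModelSet with", length(object@genes), "genes on",
      length(sc), "scaffolds;", length(object@proteins),
      "proteins attached\n")
})

#' Confirmed SRCR-superfamily genes
#'
#' One row per gene that carries at least one confirmed SRCR domain hit.
#' \code{solely_srcr} is TRUE iff the protein has no non-SRCR domain hit;
#' \code{evidence} records which screens (hmm, blast) supported the gene.
#'
#' @slot table \code{data.frame} with columns \code{gene_id},
#'   \code{n_srcr_domains}, \code{solely_srcr}, \code{evidence}.
#' @slot srcrHits \code{data.frame} of SRCR domain hits (collapsed, sorted by
#'   \code{start_aa} within gene).
#' @slot otherHits \code{data.frame} of non-SRCR domain hits.
#' @exportClass SrcrGeneSet
setClass("SrcrGeneSet",
  slots = c(table = "data.frame", srcrHits = "data.frame",
            otherHits = "data.frame")
)

.validSrcrGeneSet <- function(object) {
  msg <- character(0)
  tb <- object@table
  need <- c("gene_id", "n_srcr_domains", "solely_srcr", "evidence")
  if (!all(need %in% names(tb)))
    msg <- c(msg, "table must have gene_id, n_srcr_domains, solely_srcr, evidence")
  else {
    if (any(tb$n_srcr_domains < 1))
      msg <- c(msg, "every SRCR gene must have >= 1 SRCR domain")
    hasOther <- tb$gene_id %in% object@otherHits$gene_id
    if (any(tb$solely_srcr & hasOther) || any(!tb$solely_srcr & !hasOther))
      msg <- c(msg, "solely_srcr flag inconsistent with otherHits")
  }
  if (length(msg)) msg else TRUE
}

setValidity("SrcrGeneSet", .validSrcrGeneSet)

#' @rdname SrcrGeneSet-class
#' @param x a \code{SrcrGeneSet}.
#' @aliases srcrDomainHits otherDomainHits solelySrcr
#' @export
setMethod("geneIds", "SrcrGeneSet", function(x) x@table$gene_id)

#' @rdname SrcrGeneSet-class
#' @export
setMethod("srcrDomainHits", "SrcrGeneSet", function(x) x@srcrHits)

#' @rdname SrcrGeneSet-class
#' @export
setMethod("otherDomainHits", "SrcrGeneSet", function(x) x@otherHits)

#' @rdname SrcrGeneSet-class
#' @export
setMethod("solelySrcr", "SrcrGeneSet", function(x) {
  stats::setNames(x@table$solely_srcr, x@table$gene_id)
})

#' @rdname SrcrGeneSet-class
#' @export
setMethod("length", "SrcrGeneSet", function(x) nrow(x@table))

setMethod("show", "SrcrGeneSet", function(object) {
  cat("SrcrGeneSet:", nrow(object@table), "SRCR-SF genes;",
      sum(object@table$solely_srcr), "solely-SRCR\n")
})

#' Tandem clusters of SRCR genes
#'
#' Result of chaining SRCR genes along each scaffold under the gene-rank
#' distance rule: consecutive members at most \code{max_distance} gene ranks
#' apart, clusters of size >= 2, singletons reported as scattered.
#'
#' @slot clusters \code{data.frame} with columns \code{cluster_id},
#'   \code{scaffold}, \code{size}, \code{max_gap}.
#' @slot members named list: \code{cluster_id} -> character vector of member
#'   gene ids ordered by rank.
#' @slot scattered character vector of SRCR gene ids in no cluster.
#' @slot maxDistance the rank-distance threshold used.
#' @exportClass TandemClusterSet
setClass("TandemClusterSet",
  slots = c(clusters = "data.frame", members = "list",
            scattered = "character", maxDistance = "integer")
)

.validTandemClusterSet <- function(object) {
  msg <- character(0)
  cl <- object@clusters
  if (nrow(cl) != length(object@members))
    msg <- c(msg, "one member list per cluster row required")
  else if (nrow(cl)) {
    sz <- lengths(object@members[cl$cluster_id])
    if (any(cl$size != sz))
      msg <- c(msg, "cluster size must equal member count")
    if (any(cl$size < 2))
      msg <- c(msg, "clusters must have size >= 2")
    if (any(cl$max_gap > object@maxDistance))
      msg <- c(msg, "member rank gap exceeds the distance threshold")
  }
  memb <- unlist(object@members, use.names = FALSE)
  if (length(intersect(memb, object@scattered)))
    msg <- c(msg, "a gene cannot be both clustered and scattered")
  if (anyDuplicated(memb))
    msg <- c(msg, "a gene cannot belong to two clusters")
  if (length(msg)) msg else TRUE
}

setValidity("TandemClusterSet", .validTandemClusterSet)

#' @rdname TandemClusterSet-class
#' @param x a \code{TandemClusterSet}.
#' @aliases clusterTable clusterMembers scatteredGenes
#' @export
setMethod("clusterTable", "TandemClusterSet", function(x) x@clusters)

#' @rdname TandemClusterSet-class
#' @export
setMethod("clusterMembers", "TandemClusterSet", function(x) x@members)

#' @rdname TandemClusterSet-class
#' @export
setMethod("scatteredGenes", "TandemClusterSet", function(x) x@scattered)

#' @rdname TandemClusterSet-class
#' @export
setMethod("length", "TandemClusterSet", function(x) nrow(x@clusters))

setMethod("show", "TandemClusterSet", function(object) {
  cat("TandemClusterSet:", nrow(object@clusters), "clusters (",
      sum(object@clusters$size), "tandem genes ),",
      length(object@scattered), "scattered; max rank distance",
      object@maxDistance, "\n")
})

#' Conserved-cysteine profile of an SRCR domain alignment
#'
#' Columns of a multiple alignment whose cysteine occupancy among non-gap
#' rows reaches the threshold \code{tau}, plus the per-domain group call.
#' Groups follow the conserved-cysteine count convention: A = 6, B = 8
#' (the 6 core cysteines plus two B-specific ones), C = 7 (core plus the
#' C1 cysteine at a position distinct from both B-specific positions).
#'
#' @slot columns integer vector of conserved-cysteine column indices (sorted).
#' @slot perDomain \code{data.frame} with columns \code{domain_id},
#'   \code{cys_count}, \code{group} (A/B/C/unclassified).
#' @slot tau occupancy threshold used.
#' @exportClass CysteineProfile
setClass("CysteineProfile",
  slots = c(columns = "integer", perDomain = "data.frame", tau = "numeric")
)

.validCysteineProfile <- function(object) {
  msg <- character(0)
  if (object@tau <= 0 || object@tau > 1)
    msg <- c(msg, "tau must lie in (0, 1]")
  if (is.unsorted(object@columns))
    msg <- c(msg, "conserved columns must be sorted")
  pd <- object@perDomain
  if (nrow(pd)) {
    expected <- c(A = 6L, B = 8L, C = 7L)
    lab <- pd$group %in% names(expected)
    if (any(pd$cys_count[lab] != expected[pd$group[lab]]))
      msg <- c(msg, "group label inconsistent with conserved-cysteine count")
  }
  if (length(msg)) msg else TRUE
}

setValidity("CysteineProfile", .validCysteineProfile)

#' @rdname CysteineProfile-class
#' @param x a \code{CysteineProfile}.
#' @aliases conservedColumns domainGroups
#' @export
setMethod("conservedColumns", "CysteineProfile", function(x) x@columns)

#' @rdname CysteineProfile-class
#' @export
setMethod("domainGroups", "CysteineProfile", function(x) {
  stats::setNames(x@perDomain$group, x@perDomain$domain_id)
})

setMethod("show", "CysteineProfile", function(object) {
  cat("CysteineProfile:", length(object@columns),
      "conserved cysteine columns (tau =", object@tau, ");",
      nrow(object@perDomain), "domains\n")
})
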