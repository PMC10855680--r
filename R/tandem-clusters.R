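# Tandem-cluster calling by the gene-rank distance rule.

# Accepts either a GeneModelSet or a data.frame(gene_id, scaffold, rank).
.geneTableOf <- function(genes) {
  if (methods::is(genes, "GeneModelSet")) {
    gr <- geneRanges(genes)
    data.frame(gene_id = gr$gene_id,
               scaffold = as.character(GenomicRanges::seqnames(gr)),
               rank = gr$rank, stringsAsFactors = FALSE)
  } else {
    stopifnot(is.data.frame(genes),
              all(c("gene_id", "scaffold", "rank") %in% names(genes)))
    genes
  }
}

#' Call tandem clusters of SRCR genes
#'
#' Per scaffold, SRCR genes are chained whenever the rank difference between
#' consecutive SRCR genes is at most \code{max_distance} ("the distance
#' between two SRCR genes is no more than five genes", read as rank
#' difference <= 5); maximal chains of size >= 2 become clusters, singletons
#' are scattered. Chains are maximal by construction: no SRCR gene within
#' \code{max_distance} of either end is left out.
#'
#' @param srcrIds character vector of SRCR gene ids.
#' @param genes a \linkS4class{GeneModelSet} or a data.frame with columns
#'   \code{gene_id}, \code{scaffold}, \code{rank} covering all genes (SRCR
#'   and non-SRCR) so ranks reflect the full gene order.
#' @param max_distance rank-distance threshold (>= 1; default 5).
#' @return a \linkS4class{TandemClusterSet}.
#' @export
callTandemClusters <- function(srcrIds, genes, max_distance = 5L) {
  stopifnot(max_distance >= 1L)
  gt <- .geneTableOf(genes)
  missing <- setdiff(srcrIds, gt$gene_id)
  if (length(missing))
    stop("SRCR gene(s) with unknown scaffold: ",
         paste(utils::head(missing, 5), collapse = ", "))
  s <- gt[gt$gene_id %in% srcrIds, , drop = FALSE]
  clusters <- list(); rows <- list(); scattered <- character(0)
  ci <- 0L
  for (sc in unique(s$scaffold)) {
    ss <- s[s$scaffold == sc, , drop = FALSE]
    ss <- ss[order(ss$rank), , drop = FALSE]
    brk <- c(0L, which(diff(ss$rank) > max_distance), nrow(ss))
    for (k in seq_len(length(brk) - 1L)) {
      idx <- (brk[k] + 1L):brk[k + 1L]
      if (length(idx) < 2L) {
        scattered <- c(scattered, ss$gene_id[idx])
        next
      }
      ci <- ci + 1L
      cid <- sprintf("TC%03d", ci)
      clusters[[cid]] <- ss$gene_id[idx]
      rows[[cid]] <- data.frame(
        cluster_id = cid, scaffold = sc, size = length(idx),
        max_gap = max(diff(ss$rank[idx])), stringsAsFactors = FALSE)
    }
  }
  methods::new("TandemClusterSet",
               clusters = if (length(rows)) do.call(rbind, rows) else
                 data.frame(cluster_id = character(0), scaffold = character(0),
                            size = integer(0), max_gap = integer(0)),
               members = clusters, scattered = scattered,
               maxDistance = as.integer(max_distance))
}

#' Tandem / scattered statistics and cluster-size histogram
#'
#' @param x a \linkS4class{TandemClusterSet}.
#' @param srcrIds all SRCR gene ids the clustering was run over; the
#'   denominator of the tandem percentage. Must be non-empty.
#' @return list with \code{n_tandem}, \code{n_scattered}, \code{total},
#'   \code{tandem_percent} (two decimals, half-up) and
#'   \code{size_histogram} (named integer vector: cluster size -> count).
#' @export
tandemStatistics <- function(x, srcrIds) {
  total <- length(unique(srcrIds))
  if (total == 0) stop("no SRCR genes")
  nT <- sum(clusterTable(x)$size)
  hist <- table(clusterTable(x)$size)
  list(n_tandem = nT, n_scattered = total - nT, total = total,
       tandem_percent = roundHalfUp(100 * nT / total, 2),
       size_histogram = stats::setNames(as.integer(hist), names(hist)))
}

#' Split a cluster into strictly adjacent sub-runs
#'
#' Realizes the strict-adjacency reading of tandem organization: maximal runs
#' of SRCR genes at consecutive ranks (gap = 1), as when a cluster is
#' segregated into subclusters by intervening non-SRCR genes.
#'
#' @param x a \linkS4class{TandemClusterSet}.
#' @param cluster_id which cluster to split.
#' @param genes gene table or \linkS4class{GeneModelSet} (for ranks).
#' @return list of character vectors, one per adjacency run (rank order).
#' @export
subclustersByAdjacency <- function(x, cluster_id, genes) {
  gt <- .geneTableOf(genes)
  memb <- clusterMembers(x)[[cluster_id]]
  if (is.null(memb)) stop("unknown cluster: ", cluster_id)
  rk <- gt$rank[match(memb, gt$gene_id)]
  o <- order(rk); memb <- memb[o]; rk <- rk[o]
  brk <- c(0L, which(diff(rk) > 1L), length(memb))
  lapply(seq_len(length(brk) - 1L), function(k)
    memb[(brk[k] + 1L):brk[k + 1L]])
}

#' Cluster report tables for export
#'
#' @param x a \linkS4class{TandemClusterSet}.
#' @param srcrIds all SRCR gene ids.
#' @return list of data.frames: \code{clusters} (with comma-joined members)
#'   and \code{summary} (one row of tandem statistics).
#' @export
tandemReportTables <- function(x, srcrIds) {
  st <- tandemStatistics(x, srcrIds)
  cl <- clusterTable(x)
  cl$members <- joinIds(clusterMembers(x)[cl$cluster_id])
  list(clusters = cl,
       summary = data.frame(
         n_tandem = st$n_tandem, n_scattered = st$n_scattered,
         total = st$total, tandem_percent = st$tandem_percent))
}
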