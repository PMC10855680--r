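#' @import methods
#' @importFrom BiocGenerics start end width strand
NULL

#' @rdname GeneModelSet-class
#' @param x a \code{GeneModelSet} (or other container with gene identifiers).
#' @export
setGeneric("geneIds", function(x) standardGeneric("geneIds"))

#' @rdname GeneModelSet-class
#' @export
setGeneric("geneRanges", function(x) standardGeneric("geneRanges"))

#' @rdname GeneModelSet-class
#' @export
setGeneric("geneExons", function(x) standardGeneric("geneExons"))

#' @rdname GeneModelSet-class
#' @export
setGeneric("geneCds", function(x) standardGeneric("geneCds"))

#' @rdname GeneModelSet-class
#' @export
setGeneric("proteins", function(x) standardGeneric("proteins"))

#' @rdname GeneModelSet-class
#' @export
setGeneric("geneRanks", function(x) standardGeneric("geneRanks"))

#' @rdname SrcrGeneSet-class
#' @export
setGeneric("srcrDomainHits", function(x) standardGeneric("srcrDomainHits"))

#' @rdname SrcrGeneSet-class
#' @export
setGeneric("otherDomainHits", function(x) standardGeneric("otherDomainHits"))

#' @rdname SrcrGeneSet-class
#' @export
setGeneric("solelySrcr", function(x) standardGeneric("solelySrcr"))

#' @rdname TandemClusterSet-class
#' @export
setGeneric("clusterTable", function(x) standardGeneric("clusterTable"))

#' @rdname TandemClusterSet-class
#' @export
setGeneric("clusterMembers", function(x) standardGeneric("clusterMembers"))

#' @rdname TandemClusterSet-class
#' @export
setGeneric("scatteredGenes", function(x) standardGeneric("scatteredGenes"))

#' @rdname CysteineProfile-class
#' @export
setGeneric("conservedColumns", function(x) standardGeneric("conservedColumns"))

#' @rdname CysteineProfile-class
#' @export
setGeneric("domainGroups", function(x) standardGeneric("domainGroups"))
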