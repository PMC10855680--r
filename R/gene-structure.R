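# Exon-intron architecture, domain-to-genome projection, paralog exon
# similarity, exon-loss detection and duplication-unit typing.

#' Project a protein-domain hit onto the genome
#'
#' Protein position p occupies spliced-CDS nucleotides 3(p-1)+1 .. 3p; those
#' coordinates are lifted through the gene's CDS segments (transcription
#' order, strand-aware) into genomic intervals.
#'
#' @param models a \linkS4class{GeneModelSet}.
#' @param gene_id gene carrying the domain.
#' @param start_aa,end_aa 1-based inclusive protein coordinates.
#' @return \code{GRanges} in genomic order. Total width always equals
#'   \code{3 * (end_aa - start_aa + 1)}.
#' @export
projectDomainToGenome <- function(models, gene_id, start_aa, end_aa) {
  cd <- geneCds(models)[[gene_id]]
  if (is.null(cd) || length(cd) == 0L) stop("gene has no CDS: ", gene_id)
  w <- BiocGenerics::width(cd)
  ntS <- 3L * (start_aa - 1L) + 1L
  ntE <- 3L * end_aa
  if (ntE > sum(w))
    stop("domain ", start_aa, "-", end_aa, " aa extends past the CDS of ",
         gene_id)
  minus <- as.character(BiocGenerics::strand(cd)[1]) == "-"
  cum <- 0L
  pieces <- list()
  for (j in seq_along(cd)) {
    a <- max(ntS, cum + 1L); b <- min(ntE, cum + w[j])
    if (a <= b) {
      offA <- a - cum; offB <- b - cum   # 1-based within segment
      if (!minus) {
        gs <- BiocGenerics::start(cd)[j] + offA - 1L
        ge <- BiocGenerics::start(cd)[j] + offB - 1L
      } else {
        gs <- BiocGenerics::end(cd)[j] - offB + 1L
        ge <- BiocGenerics::end(cd)[j] - offA + 1L
      }
      pieces[[length(pieces) + 1L]] <- GenomicRanges::GRanges(
        as.character(GenomicRanges::seqnames(cd))[j],
        IRanges::IRanges(gs, ge),
        as.character(BiocGenerics::strand(cd))[j])
    }
    cum <- cum + w[j]
  }
  out <- unlist(GenomicRanges::GRangesList(pieces))
  sort(out, ignore.strand = TRUE)
}

#' Exon architecture of a gene
#'
#' Maps every SRCR domain of a gene to the (CDS-bearing) exons its genomic
#' projection overlaps by at least 1 nt, and derives the gene's structure
#' key: \code{"<n_exons>:<per-exon domain-segment counts>"}. Genes sharing a
#' key share an exon-intron structure type.
#'
#' @param models a \linkS4class{GeneModelSet}.
#' @param gene_id the gene.
#' @param srcrHits data.frame of the gene's SRCR domain hits (columns
#'   \code{start_aa}, \code{end_aa}); rows in \code{start_aa} order.
#' @return list with \code{gene_id}, \code{exon_lengths} (transcription
#'   order, CDS-bearing exons only), \code{domain_exon_map} (list of exon
#'   index vectors, one per domain), \code{exons_per_domain} (modal count)
#'   and \code{structure_key}.
#' @export
exonArchitecture <- function(models, gene_id, srcrHits) {
  ex <- geneExons(models)[[gene_id]]
  cd <- geneCds(models)[[gene_id]]
  keep <- IRanges::overlapsAny(GenomicRanges::granges(ex),
                               GenomicRanges::granges(cd), ignore.strand = TRUE)
  ex <- ex[keep]
  nEx <- length(ex)
  srcrHits <- srcrHits[order(srcrHits$start_aa), , drop = FALSE]
  counts <- integer(nEx)
  dmap <- vector("list", nrow(srcrHits))
  for (d in seq_len(nrow(srcrHits))) {
    proj <- projectDomainToGenome(models, gene_id,
                                  srcrHits$start_aa[d], srcrHits$end_aa[d])
    hitEx <- which(IRanges::overlapsAny(GenomicRanges::granges(ex),
                                        GenomicRanges::granges(proj),
                                        ignore.strand = TRUE))
    dmap[[d]] <- sort(hitEx)
    counts[hitEx] <- counts[hitEx] + 1L
  }
  epd <- lengths(dmap)
  modal <- if (length(epd)) as.integer(names(sort(table(epd),
                                                  decreasing = TRUE))[1])
           else NA_integer_
  list(gene_id = gene_id,
       exon_lengths = BiocGenerics::width(ex),
       domain_exon_map = dmap,
       exons_per_domain = modal,
       structure_key = paste0(nEx, ":", paste(counts, collapse = ",")))
}

#' Group genes by exon-intron structure type
#'
#' Genes with identical structure keys form one type. Types are numbered
#' deterministically: keys sorted lexicographically, \code{type01} upward.
#'
#' @param architectures list of results from \code{\link{exonArchitecture}}.
#' @return list with \code{assignment} (data.frame \code{gene_id},
#'   \code{structure_key}, \code{type}) and \code{types} (named list
#'   type -> gene ids).
#' @export
groupStructureTypes <- function(architectures) {
  stopifnot(length(architectures) > 0)
  keys <- vapply(architectures, `[[`, character(1), "structure_key")
  ids <- vapply(architectures, `[[`, character(1), "gene_id")
  uk <- sort(unique(keys))
  ty <- sprintf("type%02d", match(keys, uk))
  list(assignment = data.frame(gene_id = ids, structure_key = keys,
                               type = ty, stringsAsFactors = FALSE),
       types = split(ids, ty))
}

# match/mismatch +1/-1 substitution matrices, built once per alphabet
.subMat <- function(letters) {
  m <- matrix(-1, length(letters), length(letters),
              dimnames = list(letters, letters))
  diag(m) <- 1
  m
}

.NT_MAT <- NULL
.AA_MAT <- NULL

.ntMat <- function() {
  if (is.null(.NT_MAT))
    utils::assignInMyNamespace(".NT_MAT", .subMat(c("A", "C", "G", "T", "N")))
  .NT_MAT
}

.aaMat <- function() {
  if (is.null(.AA_MAT))
    utils::assignInMyNamespace(".AA_MAT",
      .subMat(strsplit("ACDEFGHIKLMNPQRSTVWYX*", "")[[1]]))
  .AA_MAT
}

.alnIdentity <- function(a, b, mat, xstring) {
  if (!nzchar(a) || !nzchar(b)) stop("empty sequence")
  al <- Biostrings::pairwiseAlignment(
    xstring(a), xstring(b), type = "global", substitutionMatrix = mat,
    gapOpening = 2, gapExtension = 1)
  pa <- strsplit(as.character(Biostrings::alignedPattern(al)), "")[[1]]
  sa <- strsplit(as.character(Biostrings::alignedSubject(al)), "")[[1]]
  id <- roundHalfUp(100 * sum(pa == sa & pa != "-") / length(pa), 2)
  attr(id, "score") <- Biostrings::score(al)
  attr(id, "columns") <- length(pa)
  id
}

#' Global-alignment percent identity of two nucleotide sequences
#'
#' Needleman-Wunsch with affine gaps: match +1, mismatch -1, a gap of length
#' L costs 2 + L (opening 2, extension 1). Identity is 100 x matches /
#' alignment columns (gap columns included in the denominator), two
#' decimals, half-up. The alignment score and column count are attached as
#' attributes \code{"score"} and \code{"columns"}.
#'
#' @param seq_a,seq_b non-empty nucleotide strings.
#' @return numeric percent identity in [0, 100].
#' @export
exonPercentIdentity <- function(seq_a, seq_b) {
  .alnIdentity(toupper(as.character(seq_a)), toupper(as.character(seq_b)),
               .ntMat(), Biostrings::DNAString)
}

#' Global-alignment percent identity of two protein sequences
#'
#' Same scoring and identity convention as
#' \code{\link{exonPercentIdentity}}, over the amino-acid alphabet.
#'
#' @param seq_a,seq_b non-empty amino-acid strings.
#' @return numeric percent identity in [0, 100].
#' @export
proteinPercentIdentity <- function(seq_a, seq_b) {
  .alnIdentity(toupper(as.character(seq_a)), toupper(as.character(seq_b)),
               .aaMat(), Biostrings::AAString)
}

#' Exon (CDS segment) sequences of a gene
#'
#' @param models a \linkS4class{GeneModelSet}.
#' @param genome \code{DNAStringSet} named by scaffold.
#' @param gene_id the gene.
#' @return \code{DNAStringSet} of CDS segment sequences, transcription order,
#'   each oriented 5' to 3'.
#' @export
exonSequences <- function(models, genome, gene_id) {
  cd <- geneCds(models)[[gene_id]]
  sc <- as.character(GenomicRanges::seqnames(cd))[1]
  segs <- lapply(seq_along(cd), function(j) {
    s <- Biostrings::subseq(genome[[sc]], BiocGenerics::start(cd)[j],
                            BiocGenerics::end(cd)[j])
    if (as.character(BiocGenerics::strand(cd)[j]) == "-")
      s <- Biostrings::reverseComplement(s)
    s
  })
  stats::setNames(Biostrings::DNAStringSet(segs),
                  paste0(gene_id, ".e", seq_along(cd)))
}

#' Detect exon loss via a premature in-frame stop codon
#'
#' Given a sibling paralog pair, exons of the longer-CDS gene are matched to
#' exons of the shorter gene by global-alignment identity. A longer-gene
#' exon with no counterpart at \code{min_identity}, lying beyond the shorter
#' gene's annotated CDS end, is searched for in the shorter gene's
#' downstream genomic sequence (local alignment); the homologous region is
#' then scanned codon-by-codon in the longer gene's reading frame, and the
#' first position where the shorter gene carries a stop codon while the
#' sibling carries a sense codon is reported as the causal mutation.
#'
#' @param pair character vector of two gene ids.
#' @param models a \linkS4class{GeneModelSet}.
#' @param genome \code{DNAStringSet} named by scaffold.
#' @param min_identity minimum exon percent identity to accept homology
#'   (default 70).
#' @param window_nt how far beyond the annotated gene end to search.
#' @return data.frame with columns \code{gene} (the exon-losing, shorter
#'   gene), \code{sibling}, \code{exon_index} (in the sibling, transcription
#'   order), \code{stop_offset_nt} (0-based offset of the stop codon within
#'   that exon), \code{from_codon}, \code{to_codon}, \code{exon_identity};
#'   zero rows when no event is found.
#' @export
detectExonLoss <- function(pair, models, genome, min_identity = 70,
                           window_nt = 1200L) {
  stopifnot(length(pair) == 2L)
  cdsLen <- vapply(pair, function(g)
    sum(BiocGenerics::width(geneCds(models)[[g]])), numeric(1))
  lg <- pair[which.max(cdsLen)]   # longer: the exon-retaining sibling
  sg <- pair[which.min(cdsLen)]
  empty <- data.frame(gene = character(0), sibling = character(0),
                      exon_index = integer(0), stop_offset_nt = integer(0),
                      from_codon = character(0), to_codon = character(0),
                      exon_identity = numeric(0), stringsAsFactors = FALSE)
  if (lg == sg || cdsLen[lg] == cdsLen[sg]) return(empty)
  exL <- exonSequences(models, genome, lg)
  exS <- exonSequences(models, genome, sg)
  wL <- BiocGenerics::width(exL)
  matched <- vapply(seq_along(exL), function(i)
    any(vapply(seq_along(exS), function(j)
      as.numeric(exonPercentIdentity(as.character(exL[[i]]),
                                     as.character(exS[[j]]))) >= min_identity,
      logical(1))), logical(1))
  lost <- which(!matched)
  if (!length(lost)) return(empty)

  # shorter gene's downstream genomic window, transcription direction
  cdS <- geneCds(models)[[sg]]
  sc <- as.character(GenomicRanges::seqnames(cdS))[1]
  minus <- as.character(BiocGenerics::strand(cdS)[1]) == "-"
  scLen <- length(genome[[sc]])
  if (!minus) {
    from <- max(BiocGenerics::end(cdS)) + 1L
    win <- Biostrings::subseq(genome[[sc]], from,
                              min(scLen, from + window_nt))
  } else {
    to <- min(BiocGenerics::start(cdS)) - 1L
    win <- Biostrings::reverseComplement(
      Biostrings::subseq(genome[[sc]], max(1L, to - window_nt), to))
  }
  winC <- as.character(win)
  cumL <- c(0L, cumsum(wL))
  rows <- list()
  for (i in lost) {
    exSeq <- as.character(exL[[i]])
    al <- Biostrings::pairwiseAlignment(
      Biostrings::DNAString(exSeq), Biostrings::DNAString(winC),
      type = "local", substitutionMatrix = .ntMat(),
      gapOpening = 2, gapExtension = 1)
    pw <- Biostrings::width(Biostrings::pattern(al))
    if (pw < 0.5 * nchar(exSeq)) next
    pa <- strsplit(as.character(Biostrings::alignedPattern(al)), "")[[1]]
    sa <- strsplit(as.character(Biostrings::alignedSubject(al)), "")[[1]]
    locId <- 100 * sum(pa == sa & pa != "-") / length(pa)
    if (locId < min_identity) next
    off <- BiocGenerics::start(Biostrings::subject(al)) -
      BiocGenerics::start(Biostrings::pattern(al))
    # first in-frame codon start within exon i (longer gene's frame)
    cum <- cumL[i]
    p0 <- ((3L - (cum %% 3L)) %% 3L) + 1L
    p <- p0
    while (p + 2L <= nchar(exSeq)) {
      codL <- substr(exSeq, p, p + 2L)
      q <- p + off
      if (q >= 1L && q + 2L <= nchar(winC)) {
        codS <- substr(winC, q, q + 2L)
        if (codS %in% .STOPS && !(codL %in% .STOPS)) {
          rows[[length(rows) + 1L]] <- data.frame(
            gene = sg, sibling = lg, exon_index = i,
            stop_offset_nt = p - 1L, from_codon = codL, to_codon = codS,
            exon_identity = roundHalfUp(locId, 2), stringsAsFactors = FALSE)
          break
        }
      }
      p <- p + 3L
    }
  }
  if (!length(rows)) return(empty)
  do.call(rbind, rows)
}

# All segmentations of n positions into consecutive blocks of size 1 or 2.
.blockSegmentations <- function(n) {
  if (n == 0L) return(list(list()))
  out <- list()
  rec <- function(at, acc) {
    if (at > n) { out[[length(out) + 1L]] <<- acc; return(invisible()) }
    rec(at + 1L, c(acc, list(at)))
    if (at + 1L <= n) rec(at + 2L, c(acc, list(c(at, at + 1L))))
  }
  rec(1L, list())
  out
}

# Score of a segmentation: mean identity over all unordered pairs of
# same-size blocks (size-2 blocks compared position-wise). No comparable
# pair -> -Inf.
.segmentationScore <- function(seg, idm) {
  vals <- numeric(0)
  for (i in seq_along(seg)) for (j in seq_len(i - 1L)) {
    a <- seg[[i]]; b <- seg[[j]]
    if (length(a) != length(b)) next
    vals <- c(vals, mean(idm[cbind(a, b)]))
  }
  if (!length(vals)) -Inf else mean(vals)
}

#' Type the duplication unit of a multi-domain SRCR gene
#'
#' Computes the pairwise amino-acid identity matrix over the gene's SRCR
#' domain sequences and asks which repeated block best explains the domain
#' order: Type1 = the gene expanded by copying a single domain (all blocks
#' of size 1), Type2 = a two-domain block repeated (all blocks of size 2),
#' Type3/4 = a mixture of single- and two-domain blocks. The best
#' segmentation maximizes the mean identity between same-size blocks (ties
#' resolved toward more, smaller blocks); if its score is below \code{theta}
#' the call is NA.
#'
#' @param domSeqs character vector of the gene's domain amino-acid sequences
#'   in protein order.
#' @param theta percent-identity threshold for calling a repeat (default 60).
#' @return list with \code{unit_type} (\code{"Type1"}, \code{"Type2"},
#'   \code{"Type3/4"} or \code{NA}), \code{segmentation} (list of domain
#'   index blocks), \code{score} and \code{identity_matrix}.
#' @export
typeDuplicationUnits <- function(domSeqs, theta = 60) {
  n <- length(domSeqs)
  if (n < 2L)
    return(list(unit_type = NA_character_, segmentation = list(),
                score = NA_real_, identity_matrix = matrix(numeric(0), 0, 0)))
  idm <- matrix(100, n, n)
  for (i in seq_len(n)) for (j in seq_len(i - 1L)) {
    idm[i, j] <- idm[j, i] <-
      as.numeric(proteinPercentIdentity(domSeqs[i], domSeqs[j]))
  }
  segs <- .blockSegmentations(n)
  scores <- vapply(segs, .segmentationScore, numeric(1), idm = idm)
  nb <- vapply(segs, length, integer(1))
  best <- order(-scores, -nb)[1]
  if (!is.finite(scores[best]) || scores[best] < theta)
    return(list(unit_type = NA_character_, segmentation = list(),
                score = if (is.finite(scores[best])) scores[best] else
                  NA_real_,
                identity_matrix = idm))
  sizes <- lengths(segs[[best]])
  ut <- if (all(sizes == 1L)) "Type1"
        else if (all(sizes == 2L)) "Type2"
        else "Type3/4"
  list(unit_type = ut, segmentation = segs[[best]], score = scores[best],
       identity_matrix = idm)
}

#' Reciprocal-best-hit sibling pairs from a homology table
#'
#' Tree-free surrogate for phylogenetic sibling selection: pairs (a, b)
#' where b is a's best-bitscore hit and a is b's (self hits ignored).
#'
#' @param blastHits data.frame from \code{\link{readBlastTab}}.
#' @return data.frame with columns \code{gene_a}, \code{gene_b} (a < b).
#' @export
reciprocalBestPairs <- function(blastHits) {
  bh <- blastHits[blastHits$query_id != blastHits$subject_id, , drop = FALSE]
  if (!nrow(bh))
    return(data.frame(gene_a = character(0), gene_b = character(0)))
  bh <- bh[order(-bh$bitscore), , drop = FALSE]
  best <- bh[!duplicated(bh$query_id), c("query_id", "subject_id")]
  bb <- stats::setNames(best$subject_id, best$query_id)
  pairs <- unique(t(apply(best, 1, function(r) {
    a <- r[["query_id"]]; b <- r[["subject_id"]]
    if (!is.na(bb[b]) && bb[b] == a) sort(c(a, b)) else c(NA, NA)
  })))
  pairs <- pairs[!is.na(pairs[, 1]), , drop = FALSE]
  data.frame(gene_a = pairs[, 1], gene_b = pairs[, 2],
             stringsAsFactors = FALSE)
}
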