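#' Read gene models from a GFF3 annotation
#'
#' Parses gene/mRNA/exon/CDS features linked by ID/Parent into a
#' \linkS4class{GeneModelSet}. For multi-isoform genes the isoform with the
#' longest total CDS is kept, so downstream counting is per gene, not per
#' transcript. Minus-strand exon and CDS lists are put in transcription order
#' (decreasing genomic start). Gene ranks (per-scaffold start order) are
#' assigned on import.
#'
#' @param path GFF3 file.
#' @param proteinFasta optional protein FASTA whose record ids match gene ids;
#'   attached as the \code{proteins} slot.
#' @return a \linkS4class{GeneModelSet}.
#' @details A CDS whose total length is not a multiple of 3 triggers a warning
#'   naming the gene and is flagged in the gene metadata column
#'   \code{cds_incomplete}; the gene is retained. Broken ID/Parent linkage is
#'   a hard error naming the offending feature.
#' @importFrom rtracklayer import export
#' @export
readGeneModels <- function(path, proteinFasta = NULL) {
  gff <- rtracklayer::import(path, format = "gff3")
  type <- as.character(gff$type)
  genes <- gff[type == "gene"]
  mrnas <- gff[type == "mRNA"]
  parts <- gff[type %in% c("exon", "CDS")]
  if (length(genes) == 0L) stop("no gene features in ", path)

  geneIdsV <- as.character(genes$ID)
  mrnaParent <- vapply(mrnas$Parent, function(p) {
    if (length(p) != 1L) NA_character_ else p
  }, character(1))
  bad <- which(is.na(mrnaParent) | !(mrnaParent %in% geneIdsV))
  if (length(bad))
    stop("mRNA feature with unresolvable Parent: ",
         as.character(mrnas$ID)[bad[1]])
  mrnaIdsV <- as.character(mrnas$ID)
  partParent <- vapply(parts$Parent, function(p) {
    if (length(p) != 1L) NA_character_ else p
  }, character(1))
  bad <- which(is.na(partParent) | !(partParent %in% mrnaIdsV))
  if (length(bad))
    stop("exon/CDS feature with unresolvable Parent near ",
         as.character(GenomicRanges::seqnames(parts))[bad[1]], ":",
         BiocGenerics::start(parts)[bad[1]])

  partType <- as.character(parts$type)
  cdsLenByMrna <- tapply(
    BiocGenerics::width(parts)[partType == "CDS"],
    partParent[partType == "CDS"], sum)

  exL <- vector("list", length(genes))
  cdL <- vector("list", length(genes))
  incomplete <- logical(length(genes))
  for (i in seq_along(genes)) {
    gid <- geneIdsV[i]
    tx <- mrnaIdsV[mrnaParent == gid]
    if (length(tx) == 0L) stop("gene without mRNA child: ", gid)
    lens <- cdsLenByMrna[tx]
    lens[is.na(lens)] <- 0
    best <- tx[which.max(lens)]
    minus <- as.character(BiocGenerics::strand(genes)[i]) == "-"
    pick <- function(what) {
      p <- parts[partType == what & partParent == best]
      p <- p[order(BiocGenerics::start(p), decreasing = minus)]
      mcols(p) <- S4Vectors::DataFrame(phase = if (what == "CDS")
        .phaseOf(p) else rep(NA_integer_, length(p)))
      p
    }
    exL[[i]] <- pick("exon")
    cd <- pick("CDS")
    cdL[[i]] <- cd
    tot <- sum(BiocGenerics::width(cd))
    if (tot %% 3L != 0L) {
      warning("CDS length of gene ", gid, " (", tot,
              ") is not a multiple of 3; gene flagged", call. = FALSE)
      incomplete[i] <- TRUE
    }
  }
  g <- GenomicRanges::granges(genes)
  g$gene_id <- geneIdsV
  g$cds_incomplete <- incomplete
  names(exL) <- names(cdL) <- geneIdsV

  prot <- Biostrings::AAStringSet()
  if (!is.null(proteinFasta)) {
    prot <- readFastaSeqs(proteinFasta, type = "AA")
    prot <- prot[intersect(names(prot), geneIdsV)]
  }
  GeneModelSet(g, GenomicRanges::GRangesList(exL),
               GenomicRanges::GRangesList(cdL), prot)
}

# GFF3 phase of CDS segments given in transcription order: number of bases to
# skip to reach the first complete codon.
.phaseOf <- function(cds) {
  if (!is.null(cds$phase) && !any(is.na(cds$phase)))
    return(as.integer(cds$phase))
  w <- BiocGenerics::width(cds)
  cum <- c(0L, cumsum(w))[seq_along(w)]
  as.integer((3L - (cum %% 3L)) %% 3L)
}

#' Write gene models as GFF3
#'
#' Emits gene, mRNA, exon and CDS features (one mRNA per gene, id
#' \code{<gene>.t1}) with CDS phase, such that
#' \code{readGeneModels(writeGeneModels(x, f))} reproduces \code{x}.
#'
#' @param x a \linkS4class{GeneModelSet}.
#' @param path output file.
#' @return \code{path}, invisibly.
#' @export
writeGeneModels <- function(x, path) {
  rows <- list()
  gr <- geneRanges(x)
  for (i in seq_along(gr)) {
    gid <- gr$gene_id[i]
    tid <- paste0(gid, ".t1")
    gene <- GenomicRanges::granges(gr[i])
    S4Vectors::mcols(gene) <- S4Vectors::DataFrame(
      type = "gene", ID = gid, Parent = NA_character_, phase = NA_integer_)
    mrna <- gene
    mrna$type <- "mRNA"; mrna$ID <- tid; mrna$Parent <- gid
    ex <- sort(geneExons(x)[[gid]])
    cd <- geneCds(x)[[gid]]
    phase <- cd$phase[order(BiocGenerics::start(cd))]
    cdS <- sort(cd)
    S4Vectors::mcols(ex) <- S4Vectors::DataFrame(
      type = "exon", ID = NA_character_, Parent = tid, phase = NA_integer_)
    S4Vectors::mcols(cdS) <- S4Vectors::DataFrame(
      type = "CDS", ID = NA_character_, Parent = tid, phase = phase)
    rows[[length(rows) + 1L]] <- c(gene, mrna, ex, cdS)
  }
  out <- do.call(c, rows)
  out$type <- factor(out$type, levels = c("gene", "mRNA", "exon", "CDS"))
  out$Parent <- ifelse(is.na(out$Parent), NA, out$Parent)
  rtracklayer::export(out, path, format = "gff3")
  invisible(path)
}

#' Read protein-domain hit tables
#'
#' Supports two dialects: HMMER3 \code{--domtblout} (whitespace-delimited,
#' comment lines starting with \code{#}) and 15-column InterProScan TSV.
#' Protein coordinates stay 1-based inclusive as in both formats. For
#' domtblout the envelope coordinates (columns 20-21) define the domain span
#' and the per-domain independent E-value (column 13) is reported; for
#' InterProScan only member-database rows carrying a signature accession are
#' kept. Rows whose E-value does not parse as a number are skipped with a
#' message giving the count.
#'
#' @param path hit-table file.
#' @param dialect \code{"domtblout"} or \code{"interproscan_tsv"}.
#' @return \code{data.frame} with columns \code{gene_id}, \code{accession},
#'   \code{name}, \code{start_aa}, \code{end_aa}, \code{evalue},
#'   \code{source}. Empty input gives a zero-row frame.
#' @export
readDomainHits <- function(path, dialect = c("domtblout", "interproscan_tsv")) {
  dialect <- match.arg(dialect)
  lines <- readLines(path)
  empty <- .emptyDomainHits()
  if (dialect == "domtblout") {
    lines <- lines[!startsWith(lines, "#") & nzchar(trimws(lines))]
    if (!length(lines)) return(empty)
    fields <- strsplit(trimws(lines), "[[:space:]]+")
    short <- vapply(fields, length, integer(1)) < 22L
    if (any(short)) stop("domtblout row with fewer than 22 fields: line ",
                         which(short)[1])
    ev <- suppressWarnings(vapply(fields, function(f) as.numeric(f[13]),
                                  numeric(1)))
    keep <- is.finite(ev)
    if (any(!keep))
      message(sum(!keep), " domtblout row(s) skipped: non-numeric E-value")
    fields <- fields[keep]
    if (!length(fields)) return(empty)
    df <- data.frame(
      gene_id = vapply(fields, `[`, "", 1),
      accession = sub("\\.\\d+$", "", vapply(fields, `[`, "", 5)),
      name = vapply(fields, `[`, "", 4),
      start_aa = as.integer(vapply(fields, `[`, "", 20)),
      end_aa = as.integer(vapply(fields, `[`, "", 21)),
      evalue = ev[keep],
      source = "hmmer", stringsAsFactors = FALSE)
  } else {
    lines <- lines[nzchar(lines)]
    if (!length(lines)) return(empty)
    fields <- strsplit(lines, "\t", fixed = TRUE)
    acc <- vapply(fields, function(f) if (length(f) >= 5) f[5] else "", "")
    keep <- nzchar(acc) & acc != "-"
    fields <- fields[keep]
    if (!length(fields)) return(empty)
    ev <- suppressWarnings(vapply(fields, function(f) as.numeric(f[9]),
                                  numeric(1)))
    ok <- is.finite(ev)
    if (any(!ok))
      message(sum(!ok), " InterProScan row(s) skipped: non-numeric E-value")
    fields <- fields[ok]
    if (!length(fields)) return(empty)
    df <- data.frame(
      gene_id = vapply(fields, `[`, "", 1),
      accession = vapply(fields, `[`, "", 5),
      name = vapply(fields, `[`, "", 6),
      start_aa = as.integer(vapply(fields, `[`, "", 7)),
      end_aa = as.integer(vapply(fields, `[`, "", 8)),
      evalue = ev[ok],
      source = "interproscan", stringsAsFactors = FALSE)
  }
  if (any(df$start_aa < 1L | df$start_aa > df$end_aa))
    stop("domain hit with invalid protein coordinates in ", path)
  rownames(df) <- NULL
  df
}

.emptyDomainHits <- function() {
  data.frame(gene_id = character(0), accession = character(0),
             name = character(0), start_aa = integer(0), end_aa = integer(0),
             evalue = numeric(0), source = character(0),
             stringsAsFactors = FALSE)
}

#' Read 12-column tabular BLAST output (outfmt 6)
#'
#' @param path tabular BLAST file.
#' @return \code{data.frame} with the standard columns \code{query_id},
#'   \code{subject_id}, \code{percent_identity}, \code{aln_length},
#'   \code{mismatches}, \code{gap_opens}, \code{qstart}, \code{qend},
#'   \code{sstart}, \code{send}, \code{evalue}, \code{bitscore}.
#' @export
readBlastTab <- function(path) {
  cols <- c("query_id", "subject_id", "percent_identity", "aln_length",
            "mismatches", "gap_opens", "qstart", "qend", "sstart", "send",
            "evalue", "bitscore")
  info <- file.info(path)
  if (!is.na(info$size) && info$size == 0)
    return(stats::setNames(
      data.frame(matrix(nrow = 0, ncol = 12)), cols))
  df <- utils::read.table(path, sep = "\t", header = FALSE,
                          stringsAsFactors = FALSE)
  if (ncol(df) != 12L) stop("expected 12 tab-separated columns, got ",
                            ncol(df))
  stats::setNames(df, cols)
}

#' Read FASTA sequences
#'
#' Thin wrapper over Biostrings readers that strips descriptions from record
#' ids and refuses duplicate ids.
#'
#' @param path FASTA file.
#' @param type \code{"DNA"} or \code{"AA"}.
#' @return \code{DNAStringSet} or \code{AAStringSet} named by record id.
#' @export
readFastaSeqs <- function(path, type = c("DNA", "AA")) {
  type <- match.arg(type)
  seqs <- if (type == "DNA") Biostrings::readDNAStringSet(path)
          else Biostrings::readAAStringSet(path)
  names(seqs) <- sub("\\s.*$", "", names(seqs))
  dup <- unique(names(seqs)[duplicated(names(seqs))])
  if (length(dup))
    stop("duplicate sequence ids in ", path, ": ",
         paste(dup, collapse = ", "))
  seqs
}

#' Read a gene-by-tissue expression matrix (TSV of TPM)
#'
#' First column holds gene ids, the header row holds tissue labels.
#'
#' @param path TSV file.
#' @return \code{SummarizedExperiment} with one assay \code{"tpm"}.
#' @importFrom SummarizedExperiment SummarizedExperiment assay
#' @export
readExpressionTsv <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = TRUE, row.names = 1,
                          check.names = FALSE, stringsAsFactors = FALSE)
  m <- as.matrix(df)
  if (!is.numeric(m)) stop("expression matrix has non-numeric entries")
  if (any(m < 0)) stop("expression values must be non-negative")
  SummarizedExperiment::SummarizedExperiment(assays = list(tpm = m))
}

#' Splice CDS sequences out of a genome
#'
#' Extracts each gene's CDS segments from the scaffold sequence in
#' transcription order (reverse-complementing on the minus strand) and
#' concatenates them into the coding sequence.
#'
#' @param x a \linkS4class{GeneModelSet}.
#' @param genome \code{DNAStringSet} named by scaffold.
#' @return \code{DNAStringSet} of spliced CDS, named by gene id.
#' @export
splicedCds <- function(x, genome) {
  ids <- geneIds(x)
  out <- lapply(ids, function(gid) {
    cd <- geneCds(x)[[gid]]
    sc <- as.character(GenomicRanges::seqnames(cd))[1]
    if (!sc %in% names(genome)) stop("scaffold ", sc, " missing from genome")
    segs <- lapply(seq_along(cd), function(j) {
      s <- Biostrings::subseq(genome[[sc]], BiocGenerics::start(cd)[j],
                              BiocGenerics::end(cd)[j])
      if (as.character(BiocGenerics::strand(cd)[j]) == "-")
        s <- Biostrings::reverseComplement(s)
      s
    })
    do.call(Biostrings::xscat, segs)
  })
  stats::setNames(Biostrings::DNAStringSet(out), ids)
}
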