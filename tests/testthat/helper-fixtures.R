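# Shared synthetic fixtures, generated once per test run.

.fixtureCache <- new.env(parent = emptyenv())

# A compact genome exercising every planted structure: the 9-member cluster
# split 6+3, a 3-member cluster, scattered genes, one 0.84-identity
# duplicate pair, one TAC->TAG exon-loss event, decoys.
sharedSim <- function() {
  if (is.null(.fixtureCache$sim))
    .fixtureCache$sim <- generateGenome(
      synthesisConfig(seed = 101, duplicate_pairs = 0.84,
                      exon_loss_events = 1))
  .fixtureCache$sim
}

# Confirmed SRCR gene set for the shared fixture.
sharedSrcr <- function() {
  if (is.null(.fixtureCache$srcr)) {
    sim <- sharedSim()
    cand <- integrateCandidates(sim$domainHits, sim$blastHits, sim$models)
    .fixtureCache$srcr <- confirmSrcrGenes(cand, sim$domainHits)
  }
  .fixtureCache$srcr
}

# Minimal hand-built gene pair for exon-loss detection with a non-TAC stop:
# two single-domain-like genes whose second exon exists in both genomic
# sequences but is annotated only in the sibling; the shorter gene carries
# TGG -> TGA at the first codon of the lost exon.
manualLossPair <- function() {
  ex1 <- "ATGGATCGTACTGAAGTTCCAGGTAAGCAT"          # 30 nt, 10 codons
  ex2 <- "TGGCCAACTGGTCGATTCATGGAGTGGTAA"          # starts TGG, ends TAA
  intron <- "GTAAGTACGTACGTACGTAG"                  # 20 nt
  geneL <- paste0(ex1, intron, ex2)
  ex2S <- sub("^TGG", "TGA", ex2)
  geneS <- paste0(ex1, intron, ex2S)
  spacer <- strrep("T", 20)
  scaffold <- paste0(spacer, geneL, spacer, geneS, strrep("T", 60))
  offL <- nchar(spacer)
  offS <- nchar(spacer) * 2 + nchar(geneL)
  mkRanges <- function(off, exonsOnly1) {
    s1 <- off + 1; e1 <- off + 30
    s2 <- off + 51; e2 <- off + 80
    if (exonsOnly1) IRanges::IRanges(s1, e1) else IRanges::IRanges(c(s1, s2), c(e1, e2))
  }
  gr <- GenomicRanges::GRanges("chr", IRanges::IRanges(
    c(offL + 1, offS + 1), c(offL + 80, offS + 30)), "+")
  gr$gene_id <- c("geneL", "geneS")
  mk <- function(ir) {
    g <- GenomicRanges::GRanges("chr", ir, "+")
    w <- BiocGenerics::width(g)
    S4Vectors::mcols(g) <- S4Vectors::DataFrame(
      phase = as.integer((3 - (c(0, cumsum(w))[seq_along(w)] %% 3)) %% 3))
    g
  }
  exons <- GenomicRanges::GRangesList(
    geneL = mk(mkRanges(offL, FALSE)), geneS = mk(mkRanges(offS, TRUE)))
  protL <- as.character(Biostrings::translate(Biostrings::DNAString(
    paste0(ex1, substr(ex2, 1, 27)))))
  protS <- as.character(Biostrings::translate(Biostrings::DNAString(ex1)))
  models <- GeneModelSet(gr, exons, exons,
                         Biostrings::AAStringSet(c(geneL = protL,
                                                   geneS = protS)))
  list(models = models,
       genome = Biostrings::DNAStringSet(c(chr = scaffold)))
}
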