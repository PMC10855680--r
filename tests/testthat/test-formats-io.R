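test_that("GFF3 import keeps 1-based coordinates and transcription order", {
  gff <- c(
    "##gff-version 3",
    "chr1\tsrc\tgene\t11\t100\t.\t+\t.\tID=gplus",
    "chr1\tsrc\tmRNA\t11\t100\t.\t+\t.\tID=gplus.t1;Parent=gplus",
    "chr1\tsrc\texon\t11\t40\t.\t+\t.\tParent=gplus.t1",
    "chr1\tsrc\texon\t61\t100\t.\t+\t.\tParent=gplus.t1",
    "chr1\tsrc\tCDS\t11\t40\t.\t+\t0\tParent=gplus.t1",
    "chr1\tsrc\tCDS\t61\t100\t.\t+\t0\tParent=gplus.t1",
    "chr1\tsrc\tgene\t10\t160\t.\t-\t.\tID=gminus",
    "chr1\tsrc\tmRNA\t10\t160\t.\t-\t.\tID=gminus.t1;Parent=gminus",
    "chr1\tsrc\texon\t100\t160\t.\t-\t.\tParent=gminus.t1",
    "chr1\tsrc\texon\t10\t70\t.\t-\t.\tParent=gminus.t1",
    "chr1\tsrc\tCDS\t100\t159\t.\t-\t0\tParent=gminus.t1",
    "chr1\tsrc\tCDS\t11\t70\t.\t-\t0\tParent=gminus.t1")
  f <- withr::local_tempfile(fileext = ".gff3")
  writeLines(gff, f)
  suppressWarnings(m <- readGeneModels(f))
  gp <- geneRanges(m)[geneRanges(m)$gene_id == "gplus"]
  expect_equal(GenomicRanges::start(gp), 11)
  expect_equal(GenomicRanges::end(gp), 100)
  # minus-strand exons reported in transcription order: downstream first
  exm <- geneExons(m)[["gminus"]]
  expect_equal(GenomicRanges::start(exm), c(100, 10))
  expect_equal(GenomicRanges::end(exm), c(160, 70))
  # ranks follow per-scaffold start order
  expect_equal(unname(geneRanks(m)[c("gminus", "gplus")]), c(1L, 2L))
})

test_that("multi-isoform genes keep the longest-CDS isoform", {
  gff <- c(
    "##gff-version 3",
    "chr1\tsrc\tgene\t1\t90\t.\t+\t.\tID=g1",
    "chr1\tsrc\tmRNA\t1\t90\t.\t+\t.\tID=g1.t1;Parent=g1",
    "chr1\tsrc\texon\t1\t30\t.\t+\t.\tParent=g1.t1",
    "chr1\tsrc\tCDS\t1\t30\t.\t+\t0\tParent=g1.t1",
    "chr1\tsrc\tmRNA\t1\t90\t.\t+\t.\tID=g1.t2;Parent=g1",
    "chr1\tsrc\texon\t1\t90\t.\t+\t.\tParent=g1.t2",
    "chr1\tsrc\tCDS\t1\t90\t.\t+\t0\tParent=g1.t2")
  f <- withr::local_tempfile(fileext = ".gff3")
  writeLines(gff, f)
  m <- readGeneModels(f)
  expect_equal(sum(BiocGenerics::width(geneCds(m)[["g1"]])), 90)
})

test_that("broken Parent linkage errors; out-of-frame CDS warns and flags", {
  f <- withr::local_tempfile(fileext = ".gff3")
  writeLines(c(
    "##gff-version 3",
    "chr1\tsrc\tgene\t1\t90\t.\t+\t.\tID=g1",
    "chr1\tsrc\tmRNA\t1\t90\t.\t+\t.\tID=g1.t1;Parent=gMISSING",
    "chr1\tsrc\texon\t1\t90\t.\t+\t.\tParent=g1.t1",
    "chr1\tsrc\tCDS\t1\t90\t.\t+\t0\tParent=g1.t1"), f)
  expect_error(readGeneModels(f), "Parent")

  writeLines(c(
    "##gff-version 3",
    "chr1\tsrc\tgene\t1\t80\t.\t+\t.\tID=g1",
    "chr1\tsrc\tmRNA\t1\t80\t.\t+\t.\tID=g1.t1;Parent=g1",
    "chr1\tsrc\texon\t1\t80\t.\t+\t.\tParent=g1.t1",
    "chr1\tsrc\tCDS\t1\t80\t.\t+\t0\tParent=g1.t1"), f)
  expect_warning(m <- readGeneModels(f), "multiple of 3")
  expect_true(geneRanges(m)$cds_incomplete[1])
})

test_that("generator GFF3 round-trips through write/read identically", {
  sim <- sharedSim()
  f <- withr::local_tempfile(fileext = ".gff3")
  p <- withr::local_tempfile(fileext = ".fa")
  writeGeneModels(sim$models, f)
  Biostrings::writeXStringSet(proteins(sim$models), p)
  m2 <- readGeneModels(f, p)
  m1 <- sim$models
  expect_identical(geneIds(m1), geneIds(m2))
  expect_identical(as.character(geneRanges(m1)), as.character(geneRanges(m2)))
  expect_identical(geneRanks(m1), geneRanks(m2))
  for (g in geneIds(m1)) {
    expect_identical(as.character(geneExons(m1)[[g]]),
                     as.character(geneExons(m2)[[g]]))
    expect_identical(as.character(geneCds(m1)[[g]]),
                     as.character(geneCds(m2)[[g]]))
    expect_identical(geneCds(m1)[[g]]$phase, geneCds(m2)[[g]]$phase)
  }
  expect_identical(as.character(proteins(m1)), as.character(proteins(m2)))
})

test_that("spliced CDS of every parsed gene translates to its protein", {
  sim <- sharedSim()
  sp <- splicedCds(sim$models, sim$genome)
  pr <- proteins(sim$models)
  for (g in names(pr)) {
    body <- Biostrings::subseq(sp[[g]], 1, 3 * length(pr[[g]]))
    expect_identical(as.character(Biostrings::translate(body)),
                     as.character(pr[[g]]))
  }
})

test_that("domtblout rows map envelope coordinates and i-Evalue", {
  f <- withr::local_tempfile()
  writeLines(c(
    "# a comment line",
    paste("geneX - 250 SRCR PF00530.12 110 1e-30 55 0.1 1 1 1e-25 2e-20",
          "50 0.1 2 100 10 108 12 115 0.9 some description"),
    paste("geneY - 250 SRCR PF00530.12 110 1e-30 55 0.1 1 1 1e-25 NOTNUM",
          "50 0.1 2 100 10 108 12 115 0.9 bad row")), f)
  expect_message(h <- readDomainHits(f, "domtblout"), "skipped")
  expect_equal(nrow(h), 1)
  expect_equal(h$start_aa, 12)
  expect_equal(h$end_aa, 115)
  expect_equal(h$evalue, 2e-20)
  expect_equal(h$accession, "PF00530")
  expect_equal(h$source, "hmmer")
})

test_that("InterProScan TSV keeps only accession-bearing member-db rows", {
  f <- withr::local_tempfile()
  writeLines(c(
    paste("geneX", "md5", "300", "Pfam", "PF00530", "SRCR", "10", "115",
          "3.2e-21", "T", "-", "-", "-", "-", "-", sep = "\t"),
    paste("geneX", "md5", "300", "MobiDBLite", "-", "disorder", "1", "40",
          "-", "T", "-", "-", "-", "-", "-", sep = "\t")), f)
  h <- readDomainHits(f, "interproscan_tsv")
  expect_equal(nrow(h), 1)
  expect_equal(h$accession, "PF00530")
  expect_equal(h$evalue, 3.2e-21)

  empty <- withr::local_tempfile()
  writeLines(character(0), empty)
  expect_equal(nrow(readDomainHits(empty, "interproscan_tsv")), 0)
  expect_equal(nrow(readDomainHits(empty, "domtblout")), 0)
  expect_error(readDomainHits(f, "nosuch"))
})

test_that("FASTA, BLAST and expression readers follow their contracts", {
  f <- withr::local_tempfile(fileext = ".fa")
  writeLines(c(">seq1 some desc", "MKV"), f)
  s <- readFastaSeqs(f, "AA")
  expect_identical(as.character(s[["seq1"]]), "MKV")
  writeLines(c(">dup", "MKV", ">dup", "MAV"), f)
  expect_error(readFastaSeqs(f, "AA"), "dup")

  b <- withr::local_tempfile()
  writeLines(paste("q1", "s1", "84.00", "100", "16", "0", "1", "100", "1",
                   "100", "1e-30", "180", sep = "\t"), b)
  bh <- readBlastTab(b)
  expect_equal(bh$percent_identity, 84.0)
  expect_equal(ncol(bh), 12)

  e <- withr::local_tempfile()
  writeLines(c("gene_id\tgut\tgill", "g1\t1\t2", "g2\t0\t0", "g3\t5\t1"), e)
  se <- readExpressionTsv(e)
  expect_equal(dim(SummarizedExperiment::assay(se, "tpm")), c(3L, 2L))
  writeLines(c("gene_id\tgut", "g1\t-1"), e)
  expect_error(readExpressionTsv(e), "non-negative")
})
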