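# Small hand-built tables used across inventory tests.
.invFixture <- function() {
  genes <- GenomicRanges::GRanges("s1", IRanges::IRanges(
    c(1, 101, 201, 301), width = 50), "+")
  genes$gene_id <- c("g1", "g2", "g3", "g4")
  ex <- GenomicRanges::GRangesList(lapply(seq_along(genes), function(i) {
    g <- GenomicRanges::granges(genes[i])
    S4Vectors::mcols(g) <- S4Vectors::DataFrame(phase = 0L)
    g
  }))
  names(ex) <- genes$gene_id
  GeneModelSet(genes, ex, ex)
}

.hit <- function(gene, acc, ev, s = 1L, e = 100L, name = acc) {
  data.frame(gene_id = gene, accession = acc, name = name, start_aa = s,
             end_aa = e, evalue = ev, source = "hmmer",
             stringsAsFactors = FALSE)
}

.blastRow <- function(q, ev) {
  data.frame(query_id = q, subject_id = "SRCR_seed", percent_identity = 50,
             aln_length = 100L, mismatches = 50L, gap_opens = 0L, qstart = 1L,
             qend = 100L, sstart = 1L, send = 100L, evalue = ev,
             bitscore = 100, stringsAsFactors = FALSE)
}

test_that("candidate integration takes the union and screens by E-value", {
  m <- .invFixture()
  hits <- rbind(.hit("g1", "PF00530", 1e-6), .hit("g2", "PF00530", 1e-4))
  blast <- rbind(.blastRow("g1", 1e-8), .blastRow("g3", 1e-9),
                 .blastRow("g4", 1e-4))
  cand <- integrateCandidates(hits, blast, m, 1e-5)
  # g1 by both routes, once; g2 fails the domain threshold but has no blast;
  # g3 blast-only; g4 blast above threshold
  expect_identical(cand$gene_id, c("g1", "g3"))
  expect_identical(cand$evidence[cand$gene_id == "g1"], "hmm,blast")
  expect_identical(cand$evidence[cand$gene_id == "g3"], "blast")
  # exactly at threshold is included
  cand2 <- integrateCandidates(.hit("g2", "PF00530", 1e-5), blast[0, ], m)
  expect_identical(cand2$gene_id, "g2")
  # unknown ids are dropped with a message
  expect_message(
    cand3 <- integrateCandidates(.hit("ghost", "PF00530", 1e-9), blast[0, ], m),
    "absent")
  expect_equal(nrow(cand3), 0)
})

test_that("relaxing the threshold never shrinks the candidate set; idempotent", {
  m <- .invFixture()
  hits <- rbind(.hit("g1", "PF00530", 1e-6), .hit("g2", "PF00530", 1e-4),
                .hit("g3", "PF00530", 1e-12))
  prev <- character(0)
  for (ev in c(1e-13, 1e-6, 1e-4, 1e-2)) {
    cur <- integrateCandidates(hits, .blastRow("g1", 1)[0, ], m, ev)$gene_id
    expect_true(all(prev %in% cur))
    prev <- cur
  }
  # integrating candidates again changes nothing
  c1 <- integrateCandidates(hits, .blastRow("g1", 1e-9), m)
  c2 <- integrateCandidates(hits, .blastRow("g1", 1e-9), m)
  expect_identical(c1, c2)
})

test_that("confirmation requires a domain hit and sets solely_srcr", {
  m <- .invFixture()
  hits <- rbind(.hit("g1", "PF00530", 1e-8, 1, 100),
                .hit("g1", "PF00530", 1e-7, 120, 220),
                .hit("g1", "PF00008", 1e-9, 230, 260, "EGF"),
                .hit("g3", "PF00008", 1e-9, 1, 40, "EGF"))
  blast <- .blastRow("g3", 1e-10)
  cand <- integrateCandidates(hits, blast, m)
  srcr <- confirmSrcrGenes(cand, hits)
  # g3 has blast evidence but no SRCR domain: dropped
  expect_identical(geneIds(srcr), "g1")
  expect_false(unname(solelySrcr(srcr)["g1"]))
  expect_equal(srcr@table$n_srcr_domains, 2L)
})

test_that("overlapping same-span hits collapse, keeping the lower E-value", {
  m <- .invFixture()
  hits <- rbind(.hit("g1", "PF00530", 1e-8, 10, 110),
                .hit("g1", "PF00530", 1e-20, 12, 112),   # >=50% overlap
                .hit("g1", "PF00530", 1e-6, 150, 250))
  cand <- integrateCandidates(hits, .blastRow("g1", 1)[0, ], m)
  srcr <- confirmSrcrGenes(cand, hits)
  sh <- srcrDomainHits(srcr)
  expect_equal(nrow(sh), 2)
  expect_true(1e-20 %in% sh$evalue)
  expect_false(1e-8 %in% sh$evalue)
})

test_that("domain composition percentages follow count order with ties by accession", {
  m <- .invFixture()
  hits <- rbind(.hit("g1", "PF00530", 1e-8, 1, 100),
                .hit("g1", "PF00008", 1e-9, 110, 140, "EGF"),
                .hit("g2", "PF00530", 1e-8, 1, 100),
                .hit("g2", "PF00008", 1e-9, 110, 140, "EGF"),
                .hit("g3", "PF00530", 1e-8, 1, 100),
                .hit("g3", "PF00431", 1e-9, 110, 140, "CUB"))
  cand <- integrateCandidates(hits, .blastRow("g1", 1)[0, ], m)
  srcr <- confirmSrcrGenes(cand, hits)
  comp <- domainComposition(srcr, top_k = 5)
  expect_identical(comp$accession, c("PF00008", "PF00431"))
  expect_equal(comp$percent, c(66.67, 33.33))
  # a 39-of-155 accession prints as 25.16%
  expect_equal(roundHalfUp(100 * 39 / 155, 2), 25.16)
  # no non-SRCR occurrences -> empty table
  only <- confirmSrcrGenes(
    integrateCandidates(.hit("g1", "PF00530", 1e-8), .blastRow("g1", 1)[0, ], m),
    .hit("g1", "PF00530", 1e-8))
  expect_equal(nrow(domainComposition(only)), 0)
})

test_that("solely-SRCR fraction is a two-decimal percentage", {
  mk <- function(solely) {
    tab <- data.frame(gene_id = paste0("g", seq_along(solely)),
                      n_srcr_domains = 1L, solely_srcr = solely,
                      evidence = "hmm", stringsAsFactors = FALSE)
    oh <- .hit(tab$gene_id[!solely], "PF00008", 1e-9, 1, 30, "EGF")
    methods::new("SrcrGeneSet", table = tab,
                 srcrHits = .hit(tab$gene_id, "PF00530", 1e-9),
                 otherHits = oh[seq_len(sum(!solely)), , drop = FALSE])
  }
  expect_equal(solelySrcrFraction(mk(c(TRUE, TRUE, FALSE))), 66.67)
  expect_equal(solelySrcrFraction(mk(rep(FALSE, 5))), 0)
  expect_error(solelySrcrFraction(
    methods::new("SrcrGeneSet",
                 table = data.frame(gene_id = character(0),
                                    n_srcr_domains = integer(0),
                                    solely_srcr = logical(0),
                                    evidence = character(0)),
                 srcrHits = .hit("x", "PF00530", 1)[0, ],
                 otherHits = .hit("x", "PF00008", 1)[0, ])), "no SRCR")
})

test_that("planted genes are recovered with precision and recall 1", {
  sim <- sharedSim()
  srcr <- sharedSrcr()
  expect_setequal(geneIds(srcr), sim$truth$srcr_gene_ids)
  # solely flags match the planted decoy assignment
  expect_equal(solelySrcr(srcr)[names(sim$truth$solely_srcr)],
               sim$truth$solely_srcr)
})
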