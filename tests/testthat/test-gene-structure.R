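# Hand-built single-gene models for projection and architecture edge cases.
.mkModel <- function(exonStarts, exonEnds, strand = "+", gene_id = "g1",
                     protLen = NULL) {
  o <- order(exonStarts, decreasing = (strand == "-"))
  ir <- IRanges::IRanges(exonStarts[o], exonEnds[o])
  g <- GenomicRanges::GRanges("chr", ir, strand)
  w <- BiocGenerics::width(g)
  S4Vectors::mcols(g) <- S4Vectors::DataFrame(
    phase = as.integer((3 - (c(0, cumsum(w))[seq_along(w)] %% 3)) %% 3))
  gr <- GenomicRanges::GRanges("chr",
    IRanges::IRanges(min(exonStarts), max(exonEnds)), strand)
  gr$gene_id <- gene_id
  ex <- GenomicRanges::GRangesList(stats::setNames(list(g), gene_id))
  GeneModelSet(gr, ex, ex)
}

test_that("projection maps protein coordinates through the splice structure", {
  # single exon starting at genomic 1: aa 1-10 -> one interval of width 30
  m1 <- .mkModel(1, 90)
  p1 <- projectDomainToGenome(m1, "g1", 1, 10)
  expect_length(p1, 1)
  expect_equal(GenomicRanges::start(p1), 1)
  expect_equal(GenomicRanges::end(p1), 30)
  # domain spanning a 2-exon junction: two intervals summing to 3*aa
  m2 <- .mkModel(c(1, 100), c(45, 150))
  p2 <- projectDomainToGenome(m2, "g1", 10, 25)
  expect_length(p2, 2)
  expect_equal(sum(BiocGenerics::width(p2)), 3 * (25 - 10 + 1))
  # past-CDS domain errors
  expect_error(projectDomainToGenome(m2, "g1", 1, 40), "past the CDS")
})

test_that("projection equals the per-base oracle, both strands", {
  set.seed(51)
  for (rep in 1:20) {
    nEx <- sample(1:4, 1)
    lens <- sample(seq(9, 60, 3), nEx, replace = TRUE)
    gapw <- sample(20:60, nEx, replace = TRUE)
    starts <- cumsum(c(1, utils::head(lens + gapw, -1)))
    ends <- starts + lens - 1
    strand <- sample(c("+", "-"), 1)
    m <- .mkModel(starts, ends, strand)
    aaTot <- sum(lens) / 3
    s <- sample(seq_len(aaTot - 1), 1)
    e <- sample(seq(s, aaTot), 1)
    proj <- projectDomainToGenome(m, "g1", s, e)
    expect_equal(sum(BiocGenerics::width(proj)), 3 * (e - s + 1))
    got <- sort(unlist(mapply(seq, BiocGenerics::start(proj),
                              BiocGenerics::end(proj), SIMPLIFY = FALSE)))
    expect_equal(as.integer(got), perBaseProjection(m, "g1", s, e))
    # genomic order regardless of strand
    expect_true(!is.unsorted(BiocGenerics::start(proj)))
  }
})

test_that("exon regimes give the expected domains-to-exons mapping", {
  sim <- sharedSim()
  srcr <- sharedSrcr()
  truthKeys <- sim$truth$structure_type_labels
  hits <- srcrDomainHits(srcr)
  checked3 <- FALSE; checked1 <- FALSE
  for (g in geneIds(srcr)) {
    arch <- exonArchitecture(sim$models, g,
                             hits[hits$gene_id == g, , drop = FALSE])
    expect_equal(arch$structure_key, truthKeys[[g]])
    nEx <- as.integer(sub(":.*", "", arch$structure_key))
    nd <- length(arch$domain_exon_map)
    if (nEx == 3 * nd && nd >= 1) {        # three-exons-per-domain regime
      expect_true(all(lengths(arch$domain_exon_map) == 3))
      checked3 <- TRUE
    }
    if (nEx == nd && nd >= 1) {            # one-exon-per-domain regime
      expect_true(all(lengths(arch$domain_exon_map) == 1))
      checked1 <- TRUE
    }
  }
  expect_true(checked3 && checked1)
})

test_that("a domain straddling an exon boundary by 1 nt maps to 2 exons", {
  m <- .mkModel(c(1, 100), c(30, 159))  # exon1 30 nt, exon2 60 nt
  # aa 10 occupies nt 28-30; aa 11 starts exon 2: domain aa 10-11 hits both
  arch <- exonArchitecture(m, "g1",
                           data.frame(start_aa = 10L, end_aa = 11L))
  expect_equal(arch$domain_exon_map[[1]], c(1L, 2L))
})

test_that("structure typing partitions by key with deterministic numbering", {
  sim <- sharedSim()
  srcr <- sharedSrcr()
  hits <- srcrDomainHits(srcr)
  archs <- lapply(geneIds(srcr), function(g)
    exonArchitecture(sim$models, g, hits[hits$gene_id == g, , drop = FALSE]))
  sty <- groupStructureTypes(archs)
  truthKeys <- unlist(sim$truth$structure_type_labels)
  expect_equal(length(sty$types), length(unique(truthKeys)))
  # same key iff same type
  for (ty in names(sty$types)) {
    ks <- unique(truthKeys[sty$types[[ty]]])
    expect_length(ks, 1)
  }
  # degenerate partitions
  one <- groupStructureTypes(list(
    list(gene_id = "a", structure_key = "2:1,1"),
    list(gene_id = "b", structure_key = "2:1,1")))
  expect_length(one$types, 1)
  all_diff <- groupStructureTypes(list(
    list(gene_id = "a", structure_key = "2:1,1"),
    list(gene_id = "b", structure_key = "3:1,1,1"),
    list(gene_id = "c", structure_key = "1:2")))
  expect_length(all_diff$types, 3)
})

test_that("16 genes planted in 7 structure classes give exactly 7 types", {
  # exon counts 1,2,4,5 (one exon per domain) and 3,6,9 (three per domain):
  # seven pairwise-distinct structure keys
  plan <- list(
    list(n_domains = 1, regime = "one_per_domain"),
    list(n_domains = 2, regime = "one_per_domain"),
    list(n_domains = 4, regime = "one_per_domain"),
    list(n_domains = 5, regime = "one_per_domain"),
    list(n_domains = 1, regime = "three_per_domain"),
    list(n_domains = 2, regime = "three_per_domain"),
    list(n_domains = 3, regime = "three_per_domain"))
  cfg <- synthesisConfig(
    seed = 61, n_scaffolds = 1, genes_per_scaffold = 130,
    planted_clusters = list(list(scaffold = 1, size = 16,
                                 gaps = rep(0, 15))),
    n_scattered = 0, decoy_only_genes = 0, structure_plan = plan)
  sim <- generateGenome(cfg)
  cand <- integrateCandidates(sim$domainHits, sim$blastHits, sim$models)
  srcr <- confirmSrcrGenes(cand, sim$domainHits)
  expect_length(srcr, 16)
  hits <- srcrDomainHits(srcr)
  archs <- lapply(geneIds(srcr), function(g)
    exonArchitecture(sim$models, g, hits[hits$gene_id == g, , drop = FALSE]))
  expect_length(groupStructureTypes(archs)$types, 7)
})

test_that("percent identity matches direct substitution counting", {
  s <- paste(rep("ACGT", 30), collapse = "")
  expect_equal(as.numeric(exonPercentIdentity(s, s)), 100)
  # 16 substitutions in 100 nt, no-gap optimum
  set.seed(71)
  a <- paste(sample(c("A", "C", "G", "T"), 100, TRUE), collapse = "")
  av <- strsplit(a, "")[[1]]
  idx <- sample(100, 16)
  for (i in idx) av[i] <- setdiff(c("A", "C", "G", "T"), av[i])[1]
  expect_equal(as.numeric(exonPercentIdentity(a, paste(av, collapse = ""))),
               84)
  expect_error(exonPercentIdentity("", "ACGT"), "empty")
})

test_that("alignment scores equal the independent DP oracle", {
  set.seed(73)
  for (rep in 1:30) {
    a <- paste(sample(c("A", "C", "G", "T"), sample(10:80, 1), TRUE),
               collapse = "")
    b <- paste(sample(c("A", "C", "G", "T"), sample(10:80, 1), TRUE),
               collapse = "")
    idAB <- exonPercentIdentity(a, b)
    expect_equal(attr(idAB, "score"), dpAlignScore(a, b))
    # symmetry of the identity
    expect_equal(as.numeric(idAB), as.numeric(exonPercentIdentity(b, a)))
  }
})

test_that("exon loss: planted TAC->TAG events are found with correct offset", {
  sim <- sharedSim()
  el <- sim$truth$exon_loss
  ev <- detectExonLoss(c(el$sibling, el$gene), sim$models, sim$genome)
  expect_equal(nrow(ev), 1)
  expect_equal(ev$gene, el$gene)
  expect_equal(ev$exon_index, el$exon_index)
  expect_equal(ev$stop_offset_nt, el$stop_offset_nt)
  expect_equal(ev$from_codon, "TAC")
  expect_equal(ev$to_codon, "TAG")
  # identical siblings yield no event
  dp <- sim$truth$duplicate_pairs
  none <- detectExonLoss(c(dp$gene_a, dp$gene_a), sim$models, sim$genome)
  expect_equal(nrow(none), 0)
})

test_that("exon loss detects a non-TAC stop (TGG->TGA) in a manual pair", {
  fx <- manualLossPair()
  ev <- detectExonLoss(c("geneL", "geneS"), fx$models, fx$genome)
  expect_equal(nrow(ev), 1)
  expect_equal(ev$gene, "geneS")
  expect_equal(ev$exon_index, 2L)
  expect_equal(ev$stop_offset_nt, 0L)
  expect_equal(ev$from_codon, "TGG")
  expect_equal(ev$to_codon, "TGA")
})

test_that("duplication-unit typing calls the planted repeat period", {
  set.seed(81)
  A <- generateSrcrDomain("A")
  B <- generateSrcrDomain("B")
  expect_equal(typeDuplicationUnits(rep(A, 4))$unit_type, "Type1")
  t2 <- typeDuplicationUnits(c(A, B, A, B, A, B))
  expect_equal(t2$unit_type, "Type2")
  expect_equal(lengths(t2$segmentation), c(2, 2, 2))
  expect_equal(typeDuplicationUnits(c(A, A, B, A, B))$unit_type, "Type3/4")
  expect_true(is.na(typeDuplicationUnits(A)$unit_type))
  # unrelated domains: no pattern reaches the threshold
  set.seed(82)
  rand <- vapply(1:3, function(i)
    paste(sample(strsplit("ADEFGHIKLMNPQRSTVWY", "")[[1]], 100, TRUE),
          collapse = ""), character(1))
  expect_true(is.na(typeDuplicationUnits(rand)$unit_type))
})

test_that("unit calls equal the exhaustive segmentation oracle up to 6 domains", {
  set.seed(83)
  A <- generateSrcrDomain("A"); B <- generateSrcrDomain("B")
  C <- generateSrcrDomain("C")
  fixtures <- list(c(A, A), c(A, B), c(A, A, A), c(A, B, A), c(A, A, B, A, B),
                   c(A, B, A, B), c(A, B, C, A, B, C), c(A, A, B, B),
                   c(C, A, B, A, B, C), c(A, B, A, B, A, B))
  for (fx in fixtures) {
    got <- typeDuplicationUnits(fx)
    expect_equal(got$unit_type,
                 oracleDuplicationType(got$identity_matrix, 60))
  }
})

test_that("reciprocal-best pairs require mutual best bitscores", {
  bh <- data.frame(
    query_id = c("a", "b", "b", "c"),
    subject_id = c("b", "a", "c", "b"),
    percent_identity = 90, aln_length = 100L, mismatches = 0L,
    gap_opens = 0L, qstart = 1L, qend = 100L, sstart = 1L, send = 100L,
    evalue = 1e-50, bitscore = c(200, 190, 150, 140),
    stringsAsFactors = FALSE)
  rb <- reciprocalBestPairs(bh)
  expect_equal(nrow(rb), 1)
  expect_equal(c(rb$gene_a, rb$gene_b), c("a", "b"))
})
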