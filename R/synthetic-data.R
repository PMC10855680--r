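# Synthetic genomes with planted SRCR-superfamily structure.
#
# The generator emits everything the analysis consumes -- genome FASTA, GFF3,
# protein FASTA, a domain-hit table, a BLAST-style homology table, an
# expression matrix -- together with a ground-truth ledger of every planted
# event, so each analysis stage can be checked for exact recovery.

.DECOY_DOMAINS <- data.frame(
  accession = c("PF00008", "PF07645", "PF00431", "PF00057", "PF01391"),
  name = c("EGF", "EGF_CA", "CUB", "Ldl_recept_a", "Collagen"),
  stringsAsFactors = FALSE)

.SRCR_ACC <- "PF00530"

# amino-acid background excludes cysteine so conserved-cysteine columns carry
# no noise by default
.AA_BACKGROUND <- strsplit("ADEFGHIKLMNPQRSTVWY", "")[[1]]

.REV_CODONS <- NULL  # filled lazily from the standard genetic code

.revCodons <- function() {
  if (is.null(.REV_CODONS)) {
    gc <- Biostrings::GENETIC_CODE
    tab <- split(names(gc), unname(gc))
    utils::assignInMyNamespace(".REV_CODONS", tab)
  }
  .REV_CODONS
}

#' SRCR cysteine-group templates
#'
#' Loads the spacing templates that define Groups A, B and C. All three
#' groups share six core cysteine slots; Group B adds two B-specific slots
#' (a disulfide-bonded pair), Group C adds the single C1 slot at a position
#' distinct from both B-specific slots (C1 has no internal disulfide
#' partner -- recorded as metadata only). Each slot carries a nominal
#' position and a tolerated range; consecutive-slot spacing ranges drive
#' template matching in \code{\link{classifyDomain}}.
#'
#' @param path JSON template file; defaults to the copy shipped with the
#'   package. The schema is documented in the file itself.
#' @return named list of group templates, each with \code{positions},
#'   \code{start_range}, \code{gap_ranges} and \code{meta}.
#' @export
srcrTemplates <- function(path = system.file("extdata",
                                             "cysteine_templates.json",
                                             package = "SRCRfam")) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  lapply(raw$groups, function(g) {
    gr <- g$gap_ranges
    if (!is.matrix(gr))
      gr <- matrix(as.integer(unlist(gr)), ncol = 2, byrow = TRUE)
    storage.mode(gr) <- "integer"
    list(positions = as.integer(g$positions),
         start_range = as.integer(g$start_range),
         gap_ranges = gr,
         meta = g$meta)
  })
}

#' Generate one SRCR domain sequence
#'
#' Draws a ~108-aa domain with cysteines at the template positions of the
#' requested group (A: 6, B: 8, C: 7 cysteines) and all other positions from
#' a cysteine-free background composition. With \code{jitter = 0} (the
#' default) cysteines sit exactly at the nominal template positions, so sets
#' of domains are mutually aligned without an MSA step.
#'
#' @param group \code{"A"}, \code{"B"} or \code{"C"}.
#' @param templates group templates, see \code{\link{srcrTemplates}}.
#' @param jitter maximum uniform shift applied independently to each cysteine
#'   position (kept order-safe by the template spacing).
#' @return a character scalar (amino-acid sequence). Uses the R random
#'   stream; seed with \code{set.seed()} for reproducibility.
#' @export
generateSrcrDomain <- function(group = c("A", "B", "C"),
                               templates = srcrTemplates(), jitter = 0) {
  group <- match.arg(group)
  tpl <- templates[[group]]
  len <- max(tpl$positions) + 5L
  pos <- tpl$positions
  if (jitter > 0)
    pos <- pos + sample(seq(-jitter, jitter), length(pos), replace = TRUE)
  seq <- sample(.AA_BACKGROUND, len, replace = TRUE)
  seq[pos] <- "C"
  paste(seq, collapse = "")
}

#' Generate a pre-aligned set of SRCR domains
#'
#' Because generated domains of one group share exact template positions and
#' length, the set is columnar as-is and can feed
#' \code{\link{conservedCysteineColumns}} directly.
#'
#' @param group,templates as in \code{\link{generateSrcrDomain}}.
#' @param n number of domain rows.
#' @return named character vector of equal-length sequences.
#' @export
generateDomainAlignment <- function(group, n, templates = srcrTemplates()) {
  stats::setNames(
    vapply(seq_len(n), function(i)
      generateSrcrDomain(group, templates, jitter = 0), character(1)),
    paste0(group, "_dom", seq_len(n)))
}

#' Configuration for the synthetic-genome generator
#'
#' Defaults describe a compact genome with every structure the pipeline must
#' detect: multi-scaffold gene orderings with planted tandem clusters
#' (including a 9-member cluster split 6+3 by intervening non-SRCR genes),
#' genes carrying 1-6 SRCR domains in the A/B/C group mix, both
#' exon-encoding regimes (three exons per domain, as in the sponge, and one
#' exon per domain, as in the sea urchin), recent duplicate pairs at a target
#' nucleotide identity, stop-codon-driven exon-loss events, decoy domains,
#' and a tissue expression matrix with an elevated digestive-tissue mean for
#' SRCR genes.
#'
#' @param seed integer seed; a fixed seed gives byte-identical outputs.
#' @param n_scaffolds,genes_per_scaffold genome shape.
#' @param planted_clusters list of \code{list(scaffold=, size=, gaps=)}
#'   where \code{gaps} (length \code{size-1}) counts intervening non-SRCR
#'   genes between consecutive members (0 = adjacent; must keep the rank gap
#'   within the calling distance of 5).
#' @param n_scattered SRCR genes planted in isolation (>5 gene ranks from any
#'   other SRCR gene).
#' @param domain_group_mix proportions over groups A/B/C (must sum to 1).
#' @param domains_per_gene integer vector sampled for each gene's domain count.
#' @param regime_mix proportions over \code{three_per_domain} /
#'   \code{one_per_domain}.
#' @param structure_plan optional list of \code{list(n_domains=, regime=)}
#'   recycled over SRCR genes, overriding the sampled plans (used to plant
#'   explicit exon-intron structure classes).
#' @param duplicate_pairs numeric vector of target nucleotide identities in
#'   (0,1]; each plants one adjacent duplicate pair.
#' @param exon_loss_events number of planted premature-stop exon losses
#'   (each rides on its own high-identity duplicate pair).
#' @param decoy_domain_rate fraction of SRCR genes that also carry one decoy
#'   (non-SRCR) domain.
#' @param decoy_only_genes count of non-SRCR genes given decoy domain hits
#'   and a weak homology hit, to exercise candidate screening.
#' @param tissues tissue labels for the expression matrix.
#' @param digestive_tissue the label flagged digestive-associated.
#' @param digestive_shift log2 TPM shift added to SRCR genes in the
#'   digestive tissue (0 plants no signal).
#' @return a validated config list of class \code{"synthesis_config"}.
#' @export
synthesisConfig <- function(seed = 1L,
                            n_scaffolds = 3L,
                            genes_per_scaffold = 60L,
                            planted_clusters = list(
                              list(scaffold = 1L, size = 9L,
                                   gaps = c(0, 0, 0, 0, 0, 1, 0, 0)),
                              list(scaffold = 2L, size = 3L,
                                   gaps = c(0, 0))),
                            n_scattered = 4L,
                            domain_group_mix = c(A = 0.5, B = 0.3, C = 0.2),
                            domains_per_gene = 1:6,
                            regime_mix = c(three_per_domain = 0.5,
                                           one_per_domain = 0.5),
                            structure_plan = NULL,
                            duplicate_pairs = numeric(0),
                            exon_loss_events = 0L,
                            decoy_domain_rate = 0.2,
                            decoy_only_genes = 3L,
                            tissues = c("digestive_gland", "gill", "muscle",
                                        "nerve", "gonad"),
                            digestive_tissue = "digestive_gland",
                            digestive_shift = 2) {
  stopifnot(abs(sum(domain_group_mix) - 1) < 1e-8,
            all(duplicate_pairs > 0 & duplicate_pairs <= 1),
            digestive_tissue %in% tissues,
            n_scaffolds >= 1, genes_per_scaffold >= 1)
  cfg <- list(seed = as.integer(seed), n_scaffolds = as.integer(n_scaffolds),
              genes_per_scaffold = as.integer(genes_per_scaffold),
              planted_clusters = planted_clusters,
              n_scattered = as.integer(n_scattered),
              domain_group_mix = domain_group_mix,
              domains_per_gene = domains_per_gene,
              regime_mix = regime_mix,
              structure_plan = structure_plan,
              duplicate_pairs = duplicate_pairs,
              exon_loss_events = as.integer(exon_loss_events),
              decoy_domain_rate = decoy_domain_rate,
              decoy_only_genes = as.integer(decoy_only_genes),
              tissues = tissues, digestive_tissue = digestive_tissue,
              digestive_shift = digestive_shift)
  class(cfg) <- "synthesis_config"
  cfg
}

# ---- gene layout -----------------------------------------------------------
# A layout is the SRCR / non-SRCR ordering of genes along each scaffold plus
# the planted cluster membership. Buffers of 6 non-SRCR genes separate
# independent SRCR placements so that nothing merges under the default
# distance rule (rank gap <= 5).

.BUFFER <- 6L

#' Lay out gene order and planted clusters without sequences
#'
#' The layout stage of the generator: deterministic given the config, and
#' usable on its own for cluster-statistics runs at sizes where full sequence
#' synthesis is unnecessary.
#'
#' @param config a \code{\link{synthesisConfig}}.
#' @return list with \code{geneTable} (columns \code{gene_id},
#'   \code{scaffold}, \code{rank}, \code{role}, \code{tag}),
#'   \code{clusters} (named list cluster id -> member gene ids) and
#'   \code{scattered} (character vector of scattered SRCR ids).
#' @export
generateGeneLayout <- function(config) {
  stopifnot(inherits(config, "synthesis_config"))
  slots <- rep(list(character(0)), config$n_scaffolds)  # role strings
  tags <- rep(list(character(0)), config$n_scaffolds)
  addSlot <- function(s, role, tag = "") {
    slots[[s]] <<- c(slots[[s]], role)
    tags[[s]] <<- c(tags[[s]], tag)
  }
  pad <- function(s, n) for (i in seq_len(n)) addSlot(s, "nonsrcr")

  for (s in seq_len(config$n_scaffolds)) pad(s, .BUFFER)
  ci <- 0L
  for (cl in config$planted_clusters) {
    ci <- ci + 1L
    s <- cl$scaffold
    if (s > config$n_scaffolds) stop("cluster on unknown scaffold ", s)
    gaps <- if (is.null(cl$gaps)) rep(0L, cl$size - 1L) else as.integer(cl$gaps)
    if (length(gaps) != cl$size - 1L)
      stop("gaps must have length size-1 for cluster ", ci)
    if (any(gaps + 1L > 5L))
      stop("cluster ", ci, " gap exceeds the calling distance")
    cid <- sprintf("cluster%02d", ci)
    for (j in seq_len(cl$size)) {
      addSlot(s, "srcr", cid)
      if (j < cl$size) pad(s, gaps[j])
    }
    pad(s, .BUFFER)
  }
  # duplicate / exon-loss pairs: adjacent SRCR pairs, own clusters
  nPairs <- length(config$duplicate_pairs) + config$exon_loss_events
  for (p in seq_len(nPairs)) {
    s <- ((p - 1L) %% config$n_scaffolds) + 1L
    cid <- sprintf("pair%02d", p)
    addSlot(s, "srcr", cid); addSlot(s, "srcr", cid)
    pad(s, .BUFFER)
  }
  for (k in seq_len(config$n_scattered)) {
    s <- ((k - 1L) %% config$n_scaffolds) + 1L
    addSlot(s, "srcr", "scattered")
    pad(s, .BUFFER)
  }
  for (k in seq_len(config$decoy_only_genes)) {
    s <- ((k - 1L) %% config$n_scaffolds) + 1L
    addSlot(s, "decoy_only")
    pad(s, 1L)
  }
  used <- vapply(slots, length, integer(1))
  if (any(used > config$genes_per_scaffold))
    stop("planted layout needs ", max(used),
         " genes on a scaffold but genes_per_scaffold = ",
         config$genes_per_scaffold)
  for (s in seq_len(config$n_scaffolds))
    pad(s, config$genes_per_scaffold - used[s])

  rows <- list(); clusters <- list(); scattered <- character(0)
  for (s in seq_len(config$n_scaffolds)) {
    n <- length(slots[[s]])
    ids <- sprintf("scf%02d_g%03d", s, seq_len(n))
    rows[[s]] <- data.frame(
      gene_id = ids, scaffold = sprintf("scaffold_%02d", s),
      rank = seq_len(n), role = slots[[s]], tag = tags[[s]],
      stringsAsFactors = FALSE)
    for (i in seq_len(n)) {
      if (slots[[s]][i] != "srcr") next
      tg <- tags[[s]][i]
      if (tg == "scattered") scattered <- c(scattered, ids[i])
      else clusters[[tg]] <- c(clusters[[tg]], ids[i])
    }
  }
  list(geneTable = do.call(rbind, rows), clusters = clusters,
       scattered = scattered)
}

# ---- sequence-level helpers ------------------------------------------------

.randProtein <- function(n) paste(sample(.AA_BACKGROUND, n, TRUE), collapse = "")

.reverseTranslate <- function(protein) {
  tab <- .revCodons()
  aa <- strsplit(protein, "")[[1]]
  paste(vapply(aa, function(a) {
    cods <- tab[[a]]
    if (length(cods) == 1L) cods else sample(cods, 1L)
  }, character(1)), collapse = "")
}

.randIntron <- function() {
  n <- sample(60:150, 1L)
  paste0("GT", paste(sample(c("A", "C", "G", "T"), n - 4L, TRUE),
                     collapse = ""), "AG")
}

# Build the spliced-CDS cut positions (nt, cut after position p) for a gene
# whose domains occupy aa ranges dom_aa (matrix start,end), under a regime.
# codon_aligned forces cuts onto codon boundaries (needed when a downstream
# truncation must leave a translatable CDS).
.exonCuts <- function(domAa, regime, totalNt, codonAligned = FALSE) {
  al <- function(p) if (codonAligned) 3L * (p %/% 3L) else p
  cuts <- integer(0)
  nd <- nrow(domAa)
  ntS <- 3L * (domAa[, 1] - 1L)   # nt before domain start
  ntE <- 3L * domAa[, 2]          # nt through domain end
  if (nd > 1) for (d in seq_len(nd - 1))
    cuts <- c(cuts, al((ntE[d] + ntS[d + 1]) %/% 2L))
  if (regime == "three_per_domain") {
    for (d in seq_len(nd)) {
      span <- ntE[d] - ntS[d]
      cuts <- c(cuts, al(ntS[d] + span %/% 3L), al(ntS[d] + 2L * span %/% 3L))
    }
  }
  sort(unique(cuts[cuts > 0 & cuts < totalNt]))
}

# Per-exon count of SRCR-domain segments and the structure key.
.structureKey <- function(cuts, domAa, totalNt) {
  bounds <- c(0L, cuts, totalNt)
  nEx <- length(bounds) - 1L
  counts <- integer(nEx)
  for (d in seq_len(nrow(domAa))) {
    s <- 3L * (domAa[d, 1] - 1L) + 1L; e <- 3L * domAa[d, 2]
    for (i in seq_len(nEx))
      if (s <= bounds[i + 1L] && e > bounds[i]) counts[i] <- counts[i] + 1L
  }
  paste0(nEx, ":", paste(counts, collapse = ","))
}

# Substitute sites i.i.d. to hit an identity target in expectation; skips
# protected positions, intron splice dinucleotides and substitutions that
# would create an in-frame stop inside the annotated CDS.
.mutateGeneSeq <- function(geneSeq, pSub, protectNt = integer(0)) {
  b <- strsplit(geneSeq, "")[[1]]
  hit <- which(stats::runif(length(b)) < pSub)
  hit <- setdiff(hit, protectNt)
  for (i in hit) b[i] <- sample(setdiff(c("A", "C", "G", "T"), b[i]), 1L)
  paste(b, collapse = "")
}

.STOPS <- c("TAA", "TAG", "TGA")

.codonsOf <- function(nt) substring(nt, seq(1, nchar(nt) - 2, 3),
                                    seq(3, nchar(nt), 3))

# ---- gene builders ---------------------------------------------------------

# Builds one SRCR gene: protein with leader/linkers/tail, spliced CDS (stop
# included), exon cuts, domain aa coordinates, structure key.
.buildSrcrGene <- function(groups, regime, templates, decoy = FALSE,
                           codonAligned = FALSE, plantTyrLastDomain = FALSE) {
  nd <- length(groups)
  leader <- paste0("M", .randProtein(4L))
  tailAa <- .randProtein(if (decoy) 30L else 4L)
  parts <- character(0); domAa <- matrix(0L, nd, 2)
  pos <- nchar(leader)
  doms <- character(nd)
  for (d in seq_len(nd)) {
    doms[d] <- generateSrcrDomain(groups[d], templates)
    domAa[d, ] <- c(pos + 1L, pos + nchar(doms[d]))
    pos <- pos + nchar(doms[d])
    if (d < nd) { parts <- c(parts, doms[d], .randProtein(6L)); pos <- pos + 6L }
    else parts <- c(parts, doms[d])
  }
  protein <- paste0(leader, paste(parts, collapse = ""), tailAa)
  tyrOffsetNt <- NA_integer_
  if (plantTyrLastDomain) {
    # a tyrosine inside the last domain, 10 aa in, later encoded as TAC so a
    # single third-position substitution yields the TAG stop
    aaIdx <- domAa[nd, 1] + 10L
    p <- strsplit(protein, "")[[1]]; p[aaIdx] <- "Y"
    protein <- paste(p, collapse = "")
    tyrOffsetNt <- 3L * (aaIdx - 1L) + 1L
  }
  cdsNt <- paste0(.reverseTranslate(protein), "TAA")
  if (!is.na(tyrOffsetNt))
    substr(cdsNt, tyrOffsetNt, tyrOffsetNt + 2L) <- "TAC"
  totalNt <- nchar(cdsNt)
  cuts <- .exonCuts(domAa, regime, totalNt, codonAligned)
  list(protein = protein, cds = cdsNt, cuts = cuts, domAa = domAa,
       groups = groups, regime = regime,
       key = .structureKey(cuts, domAa, totalNt), tyrNt = tyrOffsetNt,
       decoy = decoy)
}

.buildNonSrcrGene <- function() {
  protein <- paste0("M", .randProtein(49L))
  list(protein = protein, cds = paste0(.reverseTranslate(protein), "TAA"),
       cuts = integer(0), domAa = matrix(0L, 0, 2), groups = character(0),
       regime = "none", key = NA_character_, tyrNt = NA_integer_,
       decoy = FALSE)
}

# Turn a built gene (spliced CDS + cuts) into genomic pieces: exon sequences
# interleaved with fresh introns. Returns gene_seq and exon-relative ranges.
.layGene <- function(build) {
  totalNt <- nchar(build$cds)
  bounds <- c(0L, build$cuts, totalNt)
  nEx <- length(bounds) - 1L
  exSeq <- substring(build$cds, bounds[-length(bounds)] + 1L, bounds[-1])
  introns <- if (nEx > 1) vapply(seq_len(nEx - 1L), function(i) .randIntron(),
                                 character(1)) else character(0)
  rel <- matrix(0L, nEx, 2); at <- 0L; pieces <- character(0)
  for (i in seq_len(nEx)) {
    rel[i, ] <- c(at + 1L, at + nchar(exSeq[i]))
    pieces <- c(pieces, exSeq[i]); at <- at + nchar(exSeq[i])
    if (i < nEx) { pieces <- c(pieces, introns[i]); at <- at + nchar(introns[i]) }
  }
  list(seq = paste(pieces, collapse = ""), rel = rel)
}

# ---- the full generator ----------------------------------------------------

#' Generate a synthetic genome with ground truth
#'
#' Runs the layout stage, synthesizes sequences and annotation for every
#' gene, plants duplicate pairs and exon-loss events, draws the expression
#' matrix, and (optionally) writes all artifacts to \code{dir}:
#' \code{genome.fasta}, \code{annotation.gff3}, \code{proteins.fasta},
#' \code{domain_hits.tsv} (InterProScan-style 15-column),
#' \code{blast_hits.tsv} (12-column tabular), \code{expression.tsv} and
#' \code{ground_truth.json}.
#'
#' Duplicate pairs are planted by copying a fresh SRCR gene and applying
#' i.i.d. per-site substitutions (uniform alternative base) at rate
#' \code{1 - identity_target}; splice dinucleotides and in-frame stop
#' creation are protected, so realized identity is recorded in the ground
#' truth. Exon-loss events plant a TAC codon in the last domain exon of a
#' high-identity pair, mutate it to TAG in the copy, and truncate the copy's
#' annotation upstream of that exon.
#'
#' @param config a \code{\link{synthesisConfig}}.
#' @param dir output directory (created if needed); \code{NULL} keeps
#'   everything in memory.
#' @return list with \code{genome} (\code{DNAStringSet}), \code{models}
#'   (\linkS4class{GeneModelSet}), \code{domainHits}, \code{blastHits}
#'   (data.frames), \code{expression} (\code{SummarizedExperiment}),
#'   \code{truth} (ground-truth list) and \code{dir}.
#' @export
generateGenome <- function(config, dir = NULL) {
  stopifnot(inherits(config, "synthesis_config"))
  set.seed(config$seed)
  templates <- srcrTemplates()
  layout <- generateGeneLayout(config)
  gt <- layout$geneTable

  pairIds <- grep("^pair", names(layout$clusters), value = TRUE)
  nDup <- length(config$duplicate_pairs)
  pairKind <- c(rep("dup", nDup), rep("loss", config$exon_loss_events))
  pairTarget <- c(config$duplicate_pairs, rep(0.92, config$exon_loss_events))
  names(pairKind) <- names(pairTarget) <- pairIds

  planIdx <- 0L
  nextPlan <- function() {
    if (!is.null(config$structure_plan)) {
      planIdx <<- planIdx + 1L
      p <- config$structure_plan[[((planIdx - 1L) %%
                                     length(config$structure_plan)) + 1L]]
      list(nd = p$n_domains, regime = p$regime)
    } else {
      list(nd = sample(config$domains_per_gene, 1L),
           regime = sample(names(config$regime_mix), 1L,
                           prob = config$regime_mix))
    }
  }

  builds <- vector("list", nrow(gt)); names(builds) <- gt$gene_id
  truthGroups <- list(); truthKeys <- list()
  dupRows <- list(); lossRows <- list(); mutated <- character(0)
  pairFirst <- list()  # pair tag -> built A

  for (i in seq_len(nrow(gt))) {
    role <- gt$role[i]; tag <- gt$tag[i]; gid <- gt$gene_id[i]
    if (role == "nonsrcr" || role == "decoy_only") {
      builds[[i]] <- .buildNonSrcrGene()
      next
    }
    isPair <- startsWith(tag, "pair")
    if (isPair && !is.null(pairFirst[[tag]])) {
      # second member: mutate a copy of the first
      A <- pairFirst[[tag]]
      kind <- pairKind[[tag]]
      b <- .planted_copy(A, pairTarget[[tag]], kind)
      builds[[i]] <- b$build
      mutated <- c(mutated, gid)
      aGid <- gt$gene_id[which(gt$tag == tag)[1]]
      if (kind == "dup") {
        dupRows[[length(dupRows) + 1L]] <- data.frame(
          gene_a = aGid, gene_b = gid,
          target_identity = pairTarget[[tag]],
          realized_identity = b$realized, stringsAsFactors = FALSE)
      } else {
        lossRows[[length(lossRows) + 1L]] <- data.frame(
          gene = gid, sibling = aGid, exon_index = b$lostExon,
          stop_offset_nt = b$stopOffset, from_codon = "TAC",
          to_codon = "TAG", stringsAsFactors = FALSE)
      }
      truthKeys[[gid]] <- builds[[i]]$key
      next
    }
    if (isPair) {
      kind <- pairKind[[tag]]
      plan <- nextPlan()
      nd <- max(2L, plan$nd)
      groups <- sample(names(config$domain_group_mix), nd, TRUE,
                       prob = config$domain_group_mix)
      A <- .buildSrcrGene(groups, "one_per_domain", templates,
                          codonAligned = TRUE,
                          plantTyrLastDomain = (kind == "loss"))
      pairFirst[[tag]] <- A
      builds[[i]] <- A
    } else {
      plan <- nextPlan()
      groups <- sample(names(config$domain_group_mix), plan$nd, TRUE,
                       prob = config$domain_group_mix)
      decoy <- stats::runif(1) < config$decoy_domain_rate
      builds[[i]] <- .buildSrcrGene(groups, plan$regime, templates,
                                    decoy = decoy)
    }
    b <- builds[[i]]
    truthKeys[[gid]] <- b$key
    for (d in seq_along(b$groups))
      truthGroups[[paste0(gid, ".d", d)]] <- b$groups[d]
  }

  asm <- .assembleScaffolds(gt, builds, lossTruncate = lossRows)
  models <- asm$models; genome <- asm$genome

  hits <- .emitDomainHits(gt, builds, models)
  blast <- .emitBlastHits(gt)
  expr <- .emitExpression(gt, config)

  truth <- list(
    srcr_gene_ids = gt$gene_id[gt$role == "srcr"],
    cluster_membership = layout$clusters,
    scattered = layout$scattered,
    domain_group_labels = truthGroups,
    structure_type_labels = truthKeys,
    duplicate_pairs = if (length(dupRows)) do.call(rbind, dupRows) else NULL,
    exon_loss = if (length(lossRows)) do.call(rbind, lossRows) else NULL,
    mutated_gene_ids = mutated,
    solely_srcr = stats::setNames(
      !vapply(builds[gt$role == "srcr"], `[[`, logical(1), "decoy"),
      gt$gene_id[gt$role == "srcr"]),
    digestive_tissue = config$digestive_tissue,
    digestive_shift = config$digestive_shift)

  out <- list(genome = genome, models = models, domainHits = hits,
              blastHits = blast, expression = expr, truth = truth, dir = dir)
  if (!is.null(dir)) .writeFixtureDir(out, dir)
  out
}

# Copy-and-mutate the second member of a planted pair. For exon-loss pairs
# the planted TAC codon is protected during substitution, then switched to
# TAG, and the annotation plan drops the last exon.
.planted_copy <- function(A, identity, kind) {
  cds <- A$cds
  protect <- integer(0)
  if (kind == "loss") protect <- A$tyrNt + 0:2
  pSub <- 1 - identity
  b <- strsplit(cds, "")[[1]]
  hit <- setdiff(which(stats::runif(length(b)) < pSub), protect)
  for (i in hit) b[i] <- sample(setdiff(c("A", "C", "G", "T"), b[i]), 1L)
  mut <- paste(b, collapse = "")
  # revert substitutions that created an in-frame stop upstream of the
  # annotated stop (keeps the copy translatable)
  cods <- .codonsOf(mut); ref <- .codonsOf(cds)
  bad <- which(cods %in% .STOPS & !(ref %in% .STOPS))
  bad <- setdiff(bad, if (kind == "loss") (A$tyrNt - 1L) %/% 3L + 1L else integer(0))
  for (ci in bad) substr(mut, 3L * ci - 2L, 3L * ci) <- ref[ci]
  realized <- mean(strsplit(mut, "")[[1]] == strsplit(cds, "")[[1]])

  build <- A
  build$cds <- mut
  build$protein <- .translateCds(substr(mut, 1L, nchar(mut) - 3L))
  lostExon <- NA_integer_; stopOffset <- NA_integer_
  if (kind == "loss") {
    substr(build$cds, A$tyrNt + 2L, A$tyrNt + 2L) <- "G"   # TAC -> TAG
    bounds <- c(0L, A$cuts, nchar(A$cds))
    nEx <- length(bounds) - 1L
    lostExon <- nEx
    stopOffset <- A$tyrNt - bounds[nEx] - 1L  # 0-based nt offset within exon
    build$truncate_at_cut <- A$cuts[length(A$cuts)]  # annotate exons 1..nEx-1
    build$protein <- .translateCds(substr(build$cds, 1L,
                                          build$truncate_at_cut))
    # domains wholly within the retained CDS keep their hits
    keep <- build$domAa[, 2] * 3L <= build$truncate_at_cut
    build$domAa <- build$domAa[keep, , drop = FALSE]
    build$groups <- build$groups[keep]
    # the annotated structure drops the lost exon
    build$key <- .structureKey(A$cuts[-length(A$cuts)], build$domAa,
                               build$truncate_at_cut)
  }
  list(build = build, realized = realized, lostExon = lostExon,
       stopOffset = stopOffset)
}

.translateCds <- function(nt) {
  as.character(Biostrings::translate(Biostrings::DNAString(nt),
                                     if.fuzzy.codon = "X"))
}

# Place every built gene on its scaffold: spacers, strand choice, GFF
# coordinates, phases; returns GeneModelSet + genome. Exon-loss copies keep
# their full genomic sequence but annotate only the retained exons.
.assembleScaffolds <- function(gt, builds, lossTruncate) {
  lossGenes <- if (length(lossTruncate))
    vapply(lossTruncate, function(r) r$gene, character(1)) else character(0)
  scfs <- unique(gt$scaffold)
  seqs <- stats::setNames(vector("list", length(scfs)), scfs)
  geneRows <- list(); exL <- list(); cdL <- list(); prots <- character(0)

  for (sc in scfs) {
    idx <- which(gt$scaffold == sc)
    at <- 0L; pieces <- character(0)
    for (i in idx) {
      gid <- gt$gene_id[i]
      build <- builds[[i]]
      spacer <- paste(sample(c("A", "C", "G", "T"), sample(200:400, 1L), TRUE),
                      collapse = "")
      pieces <- c(pieces, spacer); at <- at + nchar(spacer)
      lay <- .layGene(build)
      glen <- nchar(lay$seq)
      minus <- gid %in% lossGenes || !is.na(build$tyrNt)
      minus <- if (minus) FALSE else stats::runif(1) < 0.35
      gstart <- at + 1L
      rel <- lay$rel
      nEx <- nrow(rel)
      keepEx <- seq_len(nEx)
      if (!is.null(build$truncate_at_cut)) keepEx <- seq_len(nEx - 1L)
      if (!minus) {
        exS <- gstart + rel[, 1] - 1L; exE <- gstart + rel[, 2] - 1L
        pieces <- c(pieces, lay$seq)
      } else {
        exS <- gstart + glen - rel[, 2]; exE <- gstart + glen - rel[, 1]
        pieces <- c(pieces, as.character(Biostrings::reverseComplement(
          Biostrings::DNAString(lay$seq))))
      }
      at <- at + glen
      exS <- exS[keepEx]; exE <- exE[keepEx]
      w <- exE - exS + 1L
      phase <- as.integer((3L - (c(0L, cumsum(w))[seq_along(w)] %% 3L)) %% 3L)
      strand <- if (minus) "-" else "+"
      gr <- GenomicRanges::GRanges(sc, IRanges::IRanges(exS, exE), strand)
      geneRows[[gid]] <- GenomicRanges::GRanges(
        sc, IRanges::IRanges(min(exS), max(exE)), strand)
      ex <- gr
      S4Vectors::mcols(ex) <- S4Vectors::DataFrame(
        phase = rep(NA_integer_, length(gr)))
      cd <- gr
      S4Vectors::mcols(cd) <- S4Vectors::DataFrame(phase = phase)
      exL[[gid]] <- ex; cdL[[gid]] <- cd
      prots[gid] <- build$protein
    }
    tailSpacer <- paste(sample(c("A", "C", "G", "T"), 300L, TRUE),
                        collapse = "")
    seqs[[sc]] <- paste(c(pieces, tailSpacer), collapse = "")
  }
  genome <- Biostrings::DNAStringSet(unlist(seqs))
  genes <- unlist(GenomicRanges::GRangesList(geneRows))
  genes$gene_id <- names(geneRows)
  names(genes) <- NULL
  models <- GeneModelSet(genes, GenomicRanges::GRangesList(exL),
                         GenomicRanges::GRangesList(cdL),
                         Biostrings::AAStringSet(prots))
  list(models = models, genome = genome)
}

# Domain-hit table straight from ground truth (InterProScan-like content).
.emitDomainHits <- function(gt, builds, models) {
  rows <- list()
  for (i in seq_len(nrow(gt))) {
    gid <- gt$gene_id[i]; b <- builds[[i]]
    if (gt$role[i] == "srcr") {
      for (d in seq_len(nrow(b$domAa)))
        rows[[length(rows) + 1L]] <- data.frame(
          gene_id = gid, accession = .SRCR_ACC, name = "SRCR",
          start_aa = b$domAa[d, 1], end_aa = b$domAa[d, 2],
          evalue = 10^-stats::runif(1, 10, 40), source = "interproscan",
          stringsAsFactors = FALSE)
      if (isTRUE(b$decoy)) {
        dk <- .DECOY_DOMAINS[sample(nrow(.DECOY_DOMAINS), 1L), ]
        pl <- nchar(b$protein)
        rows[[length(rows) + 1L]] <- data.frame(
          gene_id = gid, accession = dk$accession, name = dk$name,
          start_aa = pl - 24L, end_aa = pl, evalue = 1e-8,
          source = "interproscan", stringsAsFactors = FALSE)
      }
    } else if (gt$role[i] == "decoy_only") {
      dk <- .DECOY_DOMAINS[sample(nrow(.DECOY_DOMAINS), 1L), ]
      rows[[length(rows) + 1L]] <- data.frame(
        gene_id = gid, accession = dk$accession, name = dk$name,
        start_aa = 5L, end_aa = 40L, evalue = 1e-9,
        source = "interproscan", stringsAsFactors = FALSE)
    }
  }
  if (!length(rows)) return(.emptyDomainHits())
  do.call(rbind, rows)
}

# Homology table: SRCR genes hit the seed strongly; decoy-only genes get a
# weak hit above any sensible screening threshold.
.emitBlastHits <- function(gt) {
  srcr <- gt$gene_id[gt$role == "srcr"]
  decoy <- gt$gene_id[gt$role == "decoy_only"]
  df <- data.frame(
    query_id = c(srcr, decoy), subject_id = "SRCR_seed",
    percent_identity = round(c(stats::runif(length(srcr), 35, 70),
                               stats::runif(length(decoy), 22, 28)), 2),
    aln_length = 100L, mismatches = 40L, gap_opens = 2L,
    qstart = 1L, qend = 100L, sstart = 1L, send = 100L,
    evalue = c(10^-stats::runif(length(srcr), 10, 50),
               10^-stats::runif(length(decoy), 2, 4)),
    bitscore = round(stats::runif(length(srcr) + length(decoy), 50, 300), 1),
    stringsAsFactors = FALSE)
  df
}

.emitExpression <- function(gt, config) {
  nT <- length(config$tissues)
  lg <- matrix(stats::rnorm(nrow(gt) * nT, mean = 3, sd = 1), nrow(gt), nT,
               dimnames = list(gt$gene_id, config$tissues))
  dig <- which(config$tissues == config$digestive_tissue)
  srcr <- gt$role == "srcr"
  lg[srcr, dig] <- lg[srcr, dig] + config$digestive_shift
  tpm <- round(2^lg, 3)
  SummarizedExperiment::SummarizedExperiment(assays = list(tpm = tpm))
}

#' Generate only the expression matrix for a config
#'
#' Runs the layout stage and draws the tissue expression matrix without
#' synthesizing sequences; used for replicate-heavy calibration of the
#' expression summary.
#'
#' @param config a \code{\link{synthesisConfig}}.
#' @return list with \code{expression} (\code{SummarizedExperiment}) and
#'   \code{srcr_gene_ids}.
#' @export
generateExpression <- function(config) {
  stopifnot(inherits(config, "synthesis_config"))
  set.seed(config$seed)
  layout <- generateGeneLayout(config)
  gt <- layout$geneTable
  list(expression = .emitExpression(gt, config),
       srcr_gene_ids = gt$gene_id[gt$role == "srcr"])
}

.writeFixtureDir <- function(out, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  Biostrings::writeXStringSet(out$genome, file.path(dir, "genome.fasta"))
  writeGeneModels(out$models, file.path(dir, "annotation.gff3"))
  Biostrings::writeXStringSet(proteins(out$models),
                              file.path(dir, "proteins.fasta"))
  h <- out$domainHits
  ips <- data.frame(h$gene_id, "-",
                    vapply(h$gene_id, function(g)
                      length(proteins(out$models)[[g]]), integer(1)),
                    "Pfam", h$accession, h$name, h$start_aa, h$end_aa,
                    format(h$evalue, scientific = TRUE), "T", "-", "-", "-",
                    "-", "-", stringsAsFactors = FALSE)
  utils::write.table(ips, file.path(dir, "domain_hits.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE, col.names = FALSE)
  utils::write.table(out$blastHits, file.path(dir, "blast_hits.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE,
                     col.names = FALSE)
  m <- SummarizedExperiment::assay(out$expression, "tpm")
  df <- data.frame(gene_id = rownames(m), m, check.names = FALSE)
  utils::write.table(df, file.path(dir, "expression.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE, col.names = TRUE)
  truth <- out$truth
  jsonlite::write_json(truth, file.path(dir, "ground_truth.json"),
                       auto_unbox = TRUE, digits = NA, null = "null",
                       dataframe = "rows")
  invisible(dir)
}
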