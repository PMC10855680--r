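# End-to-end orchestration: one config, deterministic seeds, TSV + JSON
# reports per stage. The exported functions are the programmatic interface;
# inst/scripts/srcr-pipeline.R wraps them for shell use.

#' Pipeline run configuration
#'
#' Collects every threshold that affects output, with the screening defaults
#' used throughout: domain/homology E-value 1e-5, tandem rank distance 5,
#' cysteine occupancy tau 0.7, exon homology identity 70, repeat-period
#' identity theta 60.
#'
#' @param evalue_max domain/homology screening threshold.
#' @param max_distance tandem rank-distance threshold.
#' @param tau conserved-cysteine occupancy threshold.
#' @param min_identity exon homology threshold (percent).
#' @param theta duplication-unit repeat threshold (percent).
#' @param seed integer seed for any stochastic stage.
#' @return validated list of class \code{"run_config"}.
#' @export
runConfig <- function(evalue_max = 1e-5, max_distance = 5L, tau = 0.7,
                      min_identity = 70, theta = 60, seed = 1L) {
  stopifnot(evalue_max > 0, max_distance >= 1, tau > 0, tau <= 1,
            min_identity >= 0, min_identity <= 100,
            theta >= 0, theta <= 100)
  structure(list(evalue_max = evalue_max,
                 max_distance = as.integer(max_distance), tau = tau,
                 min_identity = min_identity, theta = theta,
                 seed = as.integer(seed)),
            class = "run_config")
}

#' Write / read a run configuration
#'
#' JSON round-trip so runs can be reproduced from the manifest alone.
#'
#' @param config a \code{\link{runConfig}}.
#' @param path JSON file.
#' @return \code{path} / the restored config.
#' @export
writeRunConfig <- function(config, path) {
  jsonlite::write_json(unclass(config), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname writeRunConfig
#' @export
readRunConfig <- function(path) {
  v <- jsonlite::read_json(path, simplifyVector = TRUE)
  do.call(runConfig, v)
}

#' Generate synthetic fixtures on disk
#'
#' Thin wrapper over \code{\link{generateGenome}} for the simulate stage;
#' identical seed and config give byte-identical files.
#'
#' @param config a \code{\link{synthesisConfig}}.
#' @param dir output directory.
#' @return the generator result, invisibly.
#' @export
simulateFixtures <- function(config, dir) {
  invisible(generateGenome(config, dir = dir))
}

#' Run the full analysis pipeline on a fixture directory
#'
#' Chains the stages inventory -> tandem -> motif -> structure -> expression
#' on the standard fixture files (as written by
#' \code{\link{simulateFixtures}}: \code{annotation.gff3},
#' \code{genome.fasta}, \code{proteins.fasta}, \code{domain_hits.tsv},
#' \code{blast_hits.tsv}, \code{expression.tsv}), writing per-stage TSV
#' reports plus a JSON run manifest (thresholds, seed, counts) to
#' \code{outDir}. A missing input is an error naming the path; a stage
#' failure propagates with the stage name.
#'
#' @param inputDir fixture directory.
#' @param outDir report directory (created if needed).
#' @param config a \code{\link{runConfig}}.
#' @param digestive_tissues tissue labels treated as digestive-associated.
#' @return list of stage results: \code{inventory}, \code{tandem} (and its
#'   statistics), \code{motif}, \code{structure}, \code{expression},
#'   \code{manifest}.
#' @export
runPipeline <- function(inputDir, outDir, config = runConfig(),
                        digestive_tissues = "digestive_gland") {
  need <- c("annotation.gff3", "genome.fasta", "proteins.fasta",
            "domain_hits.tsv", "blast_hits.tsv", "expression.tsv")
  paths <- file.path(inputDir, need)
  missing <- paths[!file.exists(paths)]
  if (length(missing))
    stop("missing input file(s): ", paste(missing, collapse = ", "))
  dir.create(outDir, recursive = TRUE, showWarnings = FALSE)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop("stage ", name, " failed: ", conditionMessage(e), call. = FALSE))
  }

  models <- stage("io", readGeneModels(file.path(inputDir, "annotation.gff3"),
                                       file.path(inputDir, "proteins.fasta")))
  genome <- stage("io", readFastaSeqs(file.path(inputDir, "genome.fasta"),
                                      "DNA"))
  hits <- stage("io", readDomainHits(file.path(inputDir, "domain_hits.tsv"),
                                     "interproscan_tsv"))
  blast <- stage("io", readBlastTab(file.path(inputDir, "blast_hits.tsv")))
  expr <- stage("io", readExpressionTsv(file.path(inputDir,
                                                  "expression.tsv")))

  cand <- stage("inventory",
                integrateCandidates(hits, blast, models, config$evalue_max))
  srcr <- stage("inventory",
                confirmSrcrGenes(cand, hits, config$evalue_max))
  inv <- inventoryReport(srcr)
  writeTsvReport(srcr@table, file.path(outDir, "inventory.tsv"))
  writeTsvReport(inv$composition, file.path(outDir,
                                            "domain_composition.tsv"))

  clusters <- stage("tandem",
                    callTandemClusters(geneIds(srcr), models,
                                       config$max_distance))
  trep <- tandemReportTables(clusters, geneIds(srcr))
  writeTsvReport(trep$clusters, file.path(outDir, "tandem_clusters.tsv"))
  writeTsvReport(trep$summary, file.path(outDir, "tandem_summary.tsv"))

  domSeqs <- stage("motif", srcrDomainSeqs(srcr, proteins(models)))
  cls <- stage("motif", classifyDomains(domSeqs))
  cls$gene_id <- sub("\\.d\\d+$", "", cls$domain_id)
  census <- groupCensus(cls)
  writeTsvReport(cls, file.path(outDir, "motif_classification.tsv"))
  writeTsvReport(
    data.frame(group = names(census$domain_counts),
               domains = census$domain_counts,
               genes = census$gene_counts),
    file.path(outDir, "motif_census.tsv"))

  archs <- stage("structure", lapply(geneIds(srcr), function(g)
    exonArchitecture(models, g,
                     srcrDomainHits(srcr)[srcrDomainHits(srcr)$gene_id == g,
                                          , drop = FALSE])))
  sty <- groupStructureTypes(archs)
  writeTsvReport(sty$assignment, file.path(outDir, "structure_types.tsv"))

  norm <- stage("expression", normalizeExpression(expr))
  enr <- stage("expression",
               tissueEnrichmentSummary(norm, geneIds(srcr),
                                       digestive_tissues))
  writeTsvReport(
    data.frame(tissue = names(enr$tissue_counts),
               srcr_argmax = enr$tissue_counts),
    file.path(outDir, "expression_summary.tsv"))

  manifest <- list(
    config = unclass(config),
    digestive_tissues = digestive_tissues,
    n_srcr_genes = length(srcr),
    n_tandem = sum(clusterTable(clusters)$size),
    n_scattered = length(scatteredGenes(clusters)),
    n_structure_types = length(sty$types),
    digestive_fraction = enr$digestive_fraction)
  jsonlite::write_json(manifest, file.path(outDir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(list(inventory = inv, srcr = srcr, tandem = clusters,
                 tandem_stats = tandemStatistics(clusters, geneIds(srcr)),
                 motif = list(classification = cls, census = census),
                 structure = sty, expression = enr, manifest = manifest))
}
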