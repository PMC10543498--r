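# Pipeline orchestration: validated YAML configuration, composable stages
# with JSON run manifests, and the end-to-end simulation benchmark.

.CONFIG_SCHEMA <- list(
  version = 1,
  seed = 0L,
  output_dir = ".",
  simulate = list(n_species = 10L, barcodes_per_species = 100L,
                  genome_length = 1e5, gc = 0.5, read_length = 150L,
                  amplicon_min = 400L, amplicon_max = 1000L,
                  contamination_min = 0, contamination_max = 0.49,
                  reads_min = 1000L, reads_max = 10000L,
                  substitution_error_rate = 0,
                  contamination_mode = "per_barcode"),
  demux = list(whitelist = "", r1 = "", r2 = "", barcode_offset = 0L,
               min_reads = 1000L),
  classify = list(k = 21L, rank = "genus"),
  tda = list(min_reads = 1000, min_classified_fraction = 0.5,
             min_purity = 0.8, contig_min_purity = 0.9,
             n_neighbors = 15L, min_dist = 0.1, resolution = 0.1),
  strain = list(epsilon = 0.01, alpha = 0.1, min_abundance = 0.15,
                max_mismatches = 5L, seed_step = 5L),
  analytics = list(load_rate = 0.02, gels_per_droplet = 5L,
                   mapq_min = 42L, min_cells_per_gene = 10L,
                   min_genes_per_cell = 10L))

.validateConfigSection <- function(user, schema, path = "") {
  for (key in names(user)) {
    if (!key %in% names(schema))
      stop("unknown configuration key: ", paste0(path, key))
    if (is.list(schema[[key]]) && !is.list(user[[key]]))
      stop("configuration key ", paste0(path, key), " must be a mapping")
    if (is.list(schema[[key]]))
      .validateConfigSection(user[[key]], schema[[key]],
                             paste0(path, key, "."))
  }
}

#' Load and validate a pipeline configuration
#'
#' Reads a YAML file (or takes a list), checks every key against the
#' configuration schema — unknown keys are rejected — and fills unset keys
#' with defaults (the standard workflow thresholds).
#'
#' @param path YAML file path, or a named list of overrides.
#' @return a validated configuration list (class `PipelineConfig`).
#' @export
pipelineConfig <- function(path = list()) {
  user <- if (is.character(path)) yaml::read_yaml(path) else path
  if (is.null(user)) user <- list()
  .validateConfigSection(user, .CONFIG_SCHEMA)
  merge2 <- function(def, usr) {
    for (key in names(usr)) {
      def[[key]] <- if (is.list(def[[key]]))
        merge2(def[[key]], usr[[key]]) else usr[[key]]
    }
    def
  }
  structure(merge2(.CONFIG_SCHEMA, user), class = "PipelineConfig")
}

.simConfigFromPipeline <- function(cfg) {
  s <- cfg$simulate
  simulationConfig(
    nSpecies = s$n_species, barcodesPerSpecies = s$barcodes_per_species,
    readLength = s$read_length,
    ampliconRange = c(s$amplicon_min, s$amplicon_max),
    contaminationRange = c(s$contamination_min, s$contamination_max),
    readsPerBarcodeRange = c(s$reads_min, s$reads_max),
    substitutionErrorRate = s$substitution_error_rate,
    contaminationMode = s$contamination_mode)
}

.writeManifest <- function(outDir, stage, parameters, seed, outputs) {
  checksums <- as.list(tools::md5sum(outputs))
  names(checksums) <- basename(outputs)
  manifest <- list(stage = stage, seed = seed, parameters = parameters,
                   outputs = checksums)
  path <- file.path(outDir, paste0("manifest_", stage, ".json"))
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, pretty = TRUE,
                       digits = NA)
  path
}

#' Write rank abundance profiles to TSV
#' @param profiles list of [RankAbundance-class].
#' @param path output TSV.
#' @return `path`, invisibly.
#' @export
writeRankAbundance <- function(profiles, path) {
  rows <- lapply(profiles, function(p) {
    if (length(p@counts) == 0) return(NULL)
    data.frame(barcode_id = p@barcodeId, rank = p@rank,
               taxid = names(p@counts), name = p@taxnames,
               count = unname(p@counts), total_reads = p@total,
               unclassified = p@unclassified, dropped = p@dropped)
  })
  df <- do.call(rbind, rows)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read rank abundance profiles from TSV
#' @param path TSV written by [writeRankAbundance()].
#' @return named list of [RankAbundance-class].
#' @export
readRankAbundance <- function(path) {
  df <- read.table(path, sep = "\t", header = TRUE, stringsAsFactors = FALSE)
  out <- lapply(split(df, df$barcode_id), function(d) {
    new("RankAbundance", barcodeId = d$barcode_id[1], rank = d$rank[1],
        counts = setNames(as.numeric(d$count), as.character(d$taxid)),
        taxnames = as.character(d$name), unclassified = d$unclassified[1],
        dropped = d$dropped[1], total = d$total_reads[1])
  })
  out[order(names(out))]
}

#' Run one pipeline stage
#'
#' Stages write their artifacts plus a JSON manifest (stage name, seed,
#' parameters, md5 checksums of outputs) into `output_dir` and compose
#' through the files they produce: `simulate` writes the community FASTA,
#' taxonomy TSV, paired FASTQ and truth tables; `classify` rebuilds the
#' index from those files and writes rank abundance TSV; `tda` filters,
#' clusters and writes the cluster map TSV; `demux` writes per-barcode
#' counts; `analytics` writes occupancy probabilities; `benchmark` runs
#' [runTdaBenchmark()] and writes its report. Reruns with an identical
#' configuration produce byte-identical artifacts, hence identical manifest
#' checksums.
#'
#' @param name one of `"simulate"`, `"demux"`, `"classify"`, `"tda"`,
#'   `"strain"`, `"analytics"`, `"benchmark"`.
#' @param config a [pipelineConfig()] object (or list of overrides).
#' @return invisibly, a list with the stage's in-memory results and the
#'   manifest path.
#' @export
runStage <- function(name = c("simulate", "demux", "classify", "tda",
                              "strain", "analytics", "benchmark"),
                     config = pipelineConfig()) {
  name <- match.arg(name)
  if (!inherits(config, "PipelineConfig")) config <- pipelineConfig(config)
  outDir <- config$output_dir
  dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
  seed <- config$seed
  message(sprintf("[%s] starting (seed = %d, output = %s)", name, seed, outDir))
  result <- switch(name,
    simulate = .stageSimulate(config, outDir, seed),
    demux = .stageDemux(config, outDir, seed),
    classify = .stageClassify(config, outDir, seed),
    tda = .stageTda(config, outDir, seed),
    strain = .stageStrain(config, outDir, seed),
    analytics = .stageAnalytics(config, outDir, seed),
    benchmark = .stageBenchmark(config, outDir, seed))
  message(sprintf("[%s] done", name))
  invisible(result)
}

.stageSimulate <- function(config, outDir, seed) {
  sim <- .simConfigFromPipeline(config)
  refset <- syntheticCommunity(config$simulate$n_species,
                               genomeLength = config$simulate$genome_length,
                               gc = config$simulate$gc, seed = seed)
  fa <- file.path(outDir, "community.fasta")
  writeReferenceFasta(refset, fa)
  taxPath <- file.path(outDir, "taxonomy.tsv")
  tax <- refset@taxonomy
  write.table(data.frame(taxid = tax@taxid, parent_taxid = tax@parent,
                         rank = tax@rank, name = tax@name),
              taxPath, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = FALSE)
  gt <- genomeTaxids(refset)
  gtPath <- file.path(outDir, "genome_taxids.tsv")
  write.table(data.frame(genome_id = names(gt), taxid = unname(gt)),
              gtPath, sep = "\t", quote = FALSE, row.names = FALSE)
  ds <- simulateDataset(refset, sim, seed = seed + 1L,
                        fastqPrefix = file.path(outDir, "sim"))
  bt <- file.path(outDir, "sim_barcode_truth.tsv")
  write.table(ds$barcodeTruth, bt, sep = "\t", quote = FALSE,
              row.names = FALSE)
  manifest <- .writeManifest(outDir, "simulate", config$simulate, seed,
                             c(fa, taxPath, gtPath, ds$fastq, ds$truthPath, bt))
  list(refset = refset, dataset = ds, manifest = manifest)
}

.stageDemux <- function(config, outDir, seed) {
  d <- config$demux
  if (!nzchar(d$whitelist)) stop("demux stage needs demux$whitelist")
  wl <- readLines(d$whitelist)
  res <- demultiplex(d$r1, d$r2, wl, barcodeOffset = d$barcode_offset)
  countsPath <- file.path(outDir, "barcode_counts.tsv")
  write.table(data.frame(barcode = names(res$counts),
                         reads = unname(res$counts)),
              countsPath, sep = "\t", quote = FALSE, row.names = FALSE)
  retained <- filterByReadCount(res$counts, d$min_reads)
  keepPath <- file.path(outDir, "barcodes_retained.txt")
  writeLines(retained, keepPath)
  manifest <- .writeManifest(outDir, "demux", d, seed,
                             c(countsPath, keepPath))
  list(demux = res, retained = retained, manifest = manifest)
}

.readSimulatedGroups <- function(outDir) {
  r1 <- readFastq(file.path(outDir, "sim_R1.fastq"))
  r2 <- readFastq(file.path(outDir, "sim_R2.fastq"))
  bc <- sub(":.*$", "", r1$id)
  idx <- split(seq_along(bc), bc)
  lapply(idx, function(sel)
    new("BarcodeGroup", barcodeId = bc[sel[1]],
        mate1 = r1$seq[sel], mate2 = r2$seq[sel],
        qual1 = r1$qual[sel], qual2 = r2$qual[sel],
        batch = "single_cell", truth = NULL, truthHost = NA_character_,
        truthContamination = NA_real_))
}

.stageClassify <- function(config, outDir, seed) {
  tax <- loadTaxonomy(file.path(outDir, "taxonomy.tsv"))
  gt <- read.table(file.path(outDir, "genome_taxids.tsv"), header = TRUE,
                   sep = "\t", stringsAsFactors = FALSE)
  refset <- readReferenceFasta(file.path(outDir, "community.fasta"),
                               setNames(gt$taxid, gt$genome_id), tax)
  index <- buildKmerIndex(refset, k = config$classify$k)
  groups <- .readSimulatedGroups(outDir)
  profiles <- lapply(groups, function(g)
    redistributeToRank(classifyGroup(g, index), tax, config$classify$rank))
  abPath <- file.path(outDir, "rank_abundance.tsv")
  writeRankAbundance(profiles, abPath)
  manifest <- .writeManifest(outDir, "classify", config$classify, seed,
                             abPath)
  list(profiles = profiles, index = index, manifest = manifest)
}

.stageTda <- function(config, outDir, seed) {
  profiles <- readRankAbundance(file.path(outDir, "rank_abundance.tsv"))
  vectors <- lapply(profiles, toAbundanceVector)
  t <- config$tda
  fl <- filterVectors(vectors, filterThresholds(
    minReads = t$min_reads,
    minClassifiedFraction = t$min_classified_fraction,
    minPurity = t$min_purity, contigMinPurity = t$contig_min_purity))
  sce <- assembleMatrix(fl$retained)
  sce <- embedCluster(sce, nNeighbors = t$n_neighbors, minDist = t$min_dist,
                      resolution = t$resolution, seed = seed)
  sce <- annotateClusters(sce)
  cm <- clusterMap(sce)
  cmPath <- file.path(outDir, "cluster_map.tsv")
  write.table(cm, cmPath, sep = "\t", quote = FALSE, row.names = FALSE)
  manifest <- .writeManifest(outDir, "tda", t, seed, cmPath)
  list(sce = sce, clusterMap = cm, rejected = fl$rejected,
       manifest = manifest)
}

.stageStrain <- function(config, outDir, seed) {
  s <- config$strain
  panelFa <- file.path(outDir, "strain_panel.fasta")
  if (!file.exists(panelFa))
    stop("strain stage needs ", panelFa)
  genomes <- Biostrings::readDNAStringSet(panelFa)
  panel <- strainPanel(genomes)
  groups <- .readSimulatedGroups(outDir)
  rows <- lapply(groups, function(g) {
    lik <- alignReadsToPanel(g, panel, epsilon = s$epsilon,
                             maxMismatches = s$max_mismatches,
                             seedStep = s$seed_step)
    post <- assignStrain(estimateAbundanceVB(lik, alpha = s$alpha),
                         minAbundance = s$min_abundance)
    c(list(barcode_id = g@barcodeId, assignment = post@assignment),
      as.list(setNames(post@theta, names(post@theta))))
  })
  df <- do.call(rbind, lapply(rows, function(r)
    as.data.frame(r, stringsAsFactors = FALSE)))
  outPath <- file.path(outDir, "strain_posteriors.tsv")
  write.table(df, outPath, sep = "\t", quote = FALSE, row.names = FALSE)
  manifest <- .writeManifest(outDir, "strain", s, seed, outPath)
  list(posteriors = df, manifest = manifest)
}

.stageAnalytics <- function(config, outDir, seed) {
  a <- config$analytics
  occ <- dropletOccupancy(a$load_rate, a$gels_per_droplet)
  occPath <- file.path(outDir, "droplet_occupancy.json")
  jsonlite::write_json(list(p0 = occ$p0, p1 = occ$p1, pMulti = occ$pMulti,
                            pOccupied = occ$pOccupied),
                       occPath, auto_unbox = TRUE, digits = NA)
  manifest <- .writeManifest(outDir, "analytics", a, seed, occPath)
  list(occupancy = occ, manifest = manifest)
}

.stageBenchmark <- function(config, outDir, seed) {
  bench <- runTdaBenchmark(
    nSpecies = config$simulate$n_species,
    barcodesPerSpecies = config$simulate$barcodes_per_species,
    genomeLength = config$simulate$genome_length,
    config = .simConfigFromPipeline(config),
    k = config$classify$k, rank = config$classify$rank,
    thresholds = filterThresholds(
      minReads = config$tda$min_reads,
      minClassifiedFraction = config$tda$min_classified_fraction,
      minPurity = config$tda$min_purity,
      contigMinPurity = config$tda$contig_min_purity),
    seed = seed)
  repPath <- file.path(outDir, "benchmark_report.json")
  jsonlite::write_json(list(
    identification_accuracy = bench$report$identificationAccuracy,
    mean_purity = bench$report$meanPurity,
    retained = bench$report$retained,
    n_clusters = bench$nClusters,
    retention_curve = bench$report$retentionCurve),
    repPath, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  manifest <- .writeManifest(outDir, "benchmark",
                             list(seed = seed), seed, repPath)
  c(bench, list(manifest = manifest))
}

#' Run the simulation-based clustering benchmark end to end
#'
#' Generates a synthetic community, streams one simulated barcode group at a
#' time through classification and rank redistribution (reads are discarded
#' after classification, keeping memory flat), filters the abundance
#' vectors, clusters them, annotates, and scores against the simulation
#' truth.
#'
#' @param nSpecies,barcodesPerSpecies community design.
#' @param genomeLength genome length in bp.
#' @param config a [SimulationConfig-class] for read-level parameters.
#' @param k k-mer size for the classifier index.
#' @param rank working rank (default `"genus"`).
#' @param thresholds a [filterThresholds()] list.
#' @param nNeighbors,minDist,resolution clustering parameters
#'   (see [embedCluster()]).
#' @param seed integer seed controlling the whole run.
#' @return list with `sce` (annotated experiment), `report`
#'   (`BenchmarkReport`), `nClusters`, `vectors`, `truth` (per-barcode) and
#'   `refset`.
#' @export
runTdaBenchmark <- function(nSpecies = 10L, barcodesPerSpecies = 50L,
                            genomeLength = 1e5,
                            config = simulationConfig(
                              nSpecies = nSpecies,
                              barcodesPerSpecies = barcodesPerSpecies),
                            k = 21L, rank = "genus",
                            thresholds = filterThresholds(),
                            nNeighbors = 15L, minDist = 0.1, resolution = 0.1,
                            seed = 0L) {
  .withSeed(seed, {
    refset <- syntheticCommunity(nSpecies, genomeLength = genomeLength)
    index <- buildKmerIndex(refset, k = k)
    tax <- refset@taxonomy
    ids <- genomeIds(refset)
    vectors <- list()
    truth <- list()
    for (g in ids) {
      for (b in seq_len(barcodesPerSpecies)) {
        grp <- simulateBarcodeGroup(refset, g, config,
                                    barcodeId = sprintf("%s_bc%03d", g, b))
        vec <- toAbundanceVector(
          redistributeToRank(classifyGroup(grp, index), tax, rank),
          totalReads = readPairCount(grp))
        vectors[[vec@unitId]] <- vec
        truth[[vec@unitId]] <- data.frame(
          barcode_id = vec@unitId, host_genome = g,
          host_taxid = unname(genomeTaxids(refset, g)),
          contamination = grp@truthContamination,
          n_pairs = readPairCount(grp))
      }
    }
    truth <- do.call(rbind, truth)
    fl <- filterVectors(vectors, thresholds)
    sce <- assembleMatrix(fl$retained)
    sce <- embedCluster(sce, nNeighbors = nNeighbors, minDist = minDist,
                        resolution = resolution, seed = seed)
    sce <- annotateClusters(sce)
    report <- evaluateBenchmark(sce, unname(vectors), truth, tax)
    list(sce = sce, report = report,
         nClusters = length(unique(SummarizedExperiment::colData(sce)$cluster)),
         vectors = vectors, truth = truth, refset = refset)
  })
}
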