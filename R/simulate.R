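# Synthetic barcode-group simulator. Defaults reproduce the validation
# design: 150 bp paired-end reads from amplicons of 400-1000 bp, 1,000-10,000
# pairs per barcode, 0-49% contaminant reads drawn from the other community
# members, 100 barcode groups per species.

#' Run an expression with a temporary RNG seed
#' @noRd
.withSeed <- function(seed, expr) {
  if (is.null(seed)) return(eval.parent(substitute(expr)))
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  eval.parent(substitute(expr))
}

.revcomp <- function(x) {
  if (length(x) == 0) return(character())
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

#' Simulation configuration
#'
#' @slot nSpecies number of community species to simulate.
#' @slot barcodesPerSpecies barcode groups per species (default 100).
#' @slot readLength read length in bp (default 150).
#' @slot ampliconRange min/max amplicon length in bp (default 400-1000).
#' @slot contaminationRange min/max contaminant read fraction per barcode
#'   (default 0-0.49).
#' @slot readsPerBarcodeRange min/max read pairs per barcode
#'   (default 1000-10000).
#' @slot substitutionErrorRate per-base substitution probability (default 0).
#' @slot contaminationMode `"per_barcode"` draws the contaminant fraction
#'   uniformly from `contaminationRange` for every barcode; `"fixed"` uses the
#'   midpoint for all barcodes.
#' @export
setClass("SimulationConfig",
  representation(nSpecies = "integer", barcodesPerSpecies = "integer",
                 readLength = "integer", ampliconRange = "integer",
                 contaminationRange = "numeric",
                 readsPerBarcodeRange = "integer",
                 substitutionErrorRate = "numeric",
                 contaminationMode = "character"))

setValidity("SimulationConfig", function(object) {
  rng <- function(x) length(x) == 2 && x[1] <= x[2]
  if (!rng(object@ampliconRange)) return("ampliconRange must be ordered [min,max]")
  if (!rng(object@contaminationRange) || object@contaminationRange[1] < 0 ||
      object@contaminationRange[2] >= 1)
    return("contaminationRange must be ordered with max < 1")
  if (!rng(object@readsPerBarcodeRange) || object@readsPerBarcodeRange[1] < 1)
    return("readsPerBarcodeRange must be ordered and positive")
  if (object@readLength < 1) return("readLength must be positive")
  if (object@ampliconRange[1] < object@readLength)
    return("amplicons must be at least one read long")
  if (object@substitutionErrorRate < 0 || object@substitutionErrorRate >= 1)
    return("substitutionErrorRate must be in [0,1)")
  if (!object@contaminationMode %in% c("per_barcode", "fixed"))
    return("contaminationMode must be per_barcode or fixed")
  TRUE
})

#' Create a simulation configuration
#'
#' Defaults match the package's standard validation design; see the class
#' documentation [SimulationConfig-class] for the meaning of each field.
#'
#' @param nSpecies,barcodesPerSpecies community size and groups per species.
#' @param readLength read length (bp).
#' @param ampliconRange,contaminationRange,readsPerBarcodeRange ranges.
#' @param substitutionErrorRate per-base substitution probability.
#' @param contaminationMode `"per_barcode"` (default) or `"fixed"`.
#' @return a validated [SimulationConfig-class].
#' @export
simulationConfig <- function(nSpecies = 10L, barcodesPerSpecies = 100L,
                             readLength = 150L, ampliconRange = c(400L, 1000L),
                             contaminationRange = c(0, 0.49),
                             readsPerBarcodeRange = c(1000L, 10000L),
                             substitutionErrorRate = 0,
                             contaminationMode = "per_barcode") {
  obj <- new("SimulationConfig", nSpecies = as.integer(nSpecies),
             barcodesPerSpecies = as.integer(barcodesPerSpecies),
             readLength = as.integer(readLength),
             ampliconRange = as.integer(ampliconRange),
             contaminationRange = as.numeric(contaminationRange),
             readsPerBarcodeRange = as.integer(readsPerBarcodeRange),
             substitutionErrorRate = as.numeric(substitutionErrorRate),
             contaminationMode = contaminationMode)
  validObject(obj)
  obj
}

setMethod("show", "SimulationConfig", function(object) {
  cat(sprintf(paste0(
    "SimulationConfig: %d species x %d barcodes, %d bp reads,\n",
    "  amplicons %d-%d bp, %d-%d pairs/barcode, contamination %.2f-%.2f (%s),\n",
    "  substitution error %.4g\n"),
    object@nSpecies, object@barcodesPerSpecies, object@readLength,
    object@ampliconRange[1], object@ampliconRange[2],
    object@readsPerBarcodeRange[1], object@readsPerBarcodeRange[2],
    object@contaminationRange[1], object@contaminationRange[2],
    object@contaminationMode, object@substitutionErrorRate))
})

#' Generate a random genome sequence
#'
#' Bases are drawn i.i.d. with `P(G) + P(C) = gc`, split evenly within the
#' GC and AT pairs.
#'
#' @param length genome length in bp.
#' @param gc GC fraction in `[0, 1]`.
#' @param seed integer seed (deterministic output per seed), or `NULL`.
#' @return a character scalar of `length` bases.
#' @export
generateGenome <- function(length, gc = 0.5, seed = NULL) {
  if (length <= 0) stop("length must be positive")
  if (gc < 0 || gc > 1) stop("gc must be in [0,1]")
  .withSeed(seed, {
    probs <- c(A = (1 - gc) / 2, C = gc / 2, G = gc / 2, T = (1 - gc) / 2)
    paste(sample(names(probs), length, replace = TRUE, prob = probs),
          collapse = "")
  })
}

#' Mutate a genome by i.i.d. substitutions
#'
#' Each base is substituted, independently with probability
#' `substitutionRate`, by one of the three other bases chosen uniformly.
#' Used to derive strain panels at a chosen divergence (a rate of 0.01 gives
#' about 99% identity to the ancestor).
#'
#' @param genome character scalar genome sequence.
#' @param substitutionRate per-base substitution probability in `[0, 1)`.
#' @param seed integer seed or `NULL`.
#' @return the mutated sequence (same length).
#' @export
mutateGenome <- function(genome, substitutionRate, seed = NULL) {
  if (substitutionRate < 0 || substitutionRate >= 1)
    stop("substitutionRate must be in [0,1)")
  if (substitutionRate == 0) return(genome)
  .withSeed(seed, {
    bases <- strsplit(genome, "", fixed = TRUE)[[1]]
    hit <- which(runif(length(bases)) < substitutionRate)
    if (length(hit) > 0) {
      alts <- c("A", "C", "G", "T")
      repl <- vapply(bases[hit], function(b)
        sample(setdiff(alts, b), 1), character(1), USE.NAMES = FALSE)
      bases[hit] <- repl
    }
    paste(bases, collapse = "")
  })
}

#' Build a synthetic reference community with its taxonomy
#'
#' Creates `nSpecies` random genomes under a simple taxonomy
#' (root / superkingdom / genus / species). By default each species sits in
#' its own genus; `speciesPerGenus > 1` groups consecutive species under
#' shared genera (useful for species-level subclustering fixtures).
#'
#' @param nSpecies number of species genomes.
#' @param genomeLength genome length in bp (default 1e5).
#' @param gc GC fraction.
#' @param speciesPerGenus species assigned to each genus.
#' @param seed integer seed or `NULL`.
#' @return a [ReferenceSet-class].
#' @export
syntheticCommunity <- function(nSpecies, genomeLength = 1e5, gc = 0.5,
                               speciesPerGenus = 1L, seed = NULL) {
  .withSeed(seed, {
    nGenus <- ceiling(nSpecies / speciesPerGenus)
    genusIds <- 100L + seq_len(nGenus)
    spIds <- 1000L + seq_len(nSpecies)
    spGenus <- genusIds[ceiling(seq_len(nSpecies) / speciesPerGenus)]
    df <- data.frame(
      taxid = c(1L, 2L, genusIds, spIds),
      parent_taxid = c(1L, 1L, rep(2L, nGenus), spGenus),
      rank = c("root", "superkingdom", rep("genus", nGenus),
               rep("species", nSpecies)),
      name = c("root", "Bacteria", sprintf("Genus%02d", seq_len(nGenus)),
               sprintf("Species%03d", seq_len(nSpecies))))
    tax <- taxonomyFromDataFrame(df)
    genomes <- vapply(seq_len(nSpecies), function(i)
      generateGenome(genomeLength, gc), character(1))
    names(genomes) <- sprintf("genome%03d", seq_len(nSpecies))
    referenceSet(genomes, setNames(spIds, names(genomes)), tax)
  })
}

#' Draw amplicons and produce mate sequences from a genome string
#' @return list(mate1, mate2, start, len) for `n` amplicons
#' @noRd
.drawAmplicons <- function(genome, n, ampliconRange, readLength) {
  L <- nchar(genome)
  if (L < ampliconRange[2])
    stop("genome shorter than maximum amplicon length")
  lens <- ampliconRange[1] + (sample.int(ampliconRange[2] - ampliconRange[1] + 1L,
                                         n, replace = TRUE) - 1L)
  starts <- vapply(L - lens + 1L, sample.int, integer(1), size = 1L)
  mate1 <- substring(genome, starts, starts + readLength - 1L)
  mate2 <- .revcomp(substring(genome, starts + lens - readLength,
                              starts + lens - 1L))
  list(mate1 = mate1, mate2 = mate2, start = starts, len = lens)
}

#' Apply i.i.d. substitution errors to a vector of read sequences
#' @noRd
.injectErrors <- function(reads, rate) {
  if (rate <= 0 || length(reads) == 0) return(reads)
  rl <- nchar(reads[1])
  nerr <- rbinom(length(reads), rl, rate)
  idx <- which(nerr > 0)
  alts <- c("A", "C", "G", "T")
  for (i in idx) {
    pos <- sample.int(rl, nerr[i])
    chars <- strsplit(reads[i], "", fixed = TRUE)[[1]]
    for (p in pos) chars[p] <- sample(setdiff(alts, chars[p]), 1)
    reads[i] <- paste(chars, collapse = "")
  }
  reads
}

.qualChar <- function(rate) {
  q <- if (rate <= 0) 37L else max(2L, min(40L, round(-10 * log10(rate))))
  rawToChar(as.raw(q + 33L))
}

#' Simulate one barcode group
#'
#' Draws the pair count uniformly from the configured range and the
#' contaminant fraction from the contamination range (the contaminant pair
#' count is `round(n * fraction)`, round-half-to-even). Host and contaminant
#' reads alike are 150 bp mates cut from uniformly placed amplicons of
#' uniformly drawn length: mate 1 reads the 5' end of the amplicon, mate 2 is
#' the reverse complement of its 3' end. Contaminant reads come from
#' uniformly chosen other genomes of the community. A per-read truth table is
#' attached.
#'
#' @param refset a [ReferenceSet-class].
#' @param host genome id the cell is simulated from.
#' @param config a [SimulationConfig-class].
#' @param seed integer seed or `NULL`.
#' @param barcodeId identifier for the group (default derived from `host`).
#' @param nPairs,contamination optional fixed overrides for the random draws.
#' @return a [BarcodeGroup-class] with truth fields populated.
#' @export
simulateBarcodeGroup <- function(refset, host, config = simulationConfig(),
                                 seed = NULL, barcodeId = paste0("bc_", host),
                                 nPairs = NULL, contamination = NULL) {
  ids <- genomeIds(refset)
  if (!host %in% ids) stop("host genome not in reference set: ", host)
  .withSeed(seed, {
    rng <- config@readsPerBarcodeRange
    if (is.null(nPairs))
      nPairs <- rng[1] + sample.int(rng[2] - rng[1] + 1L, 1L) - 1L
    if (is.null(contamination)) {
      cr <- config@contaminationRange
      contamination <- if (config@contaminationMode == "fixed") mean(cr)
                       else runif(1, cr[1], cr[2])
    }
    if (contamination > 0 && length(ids) < 2)
      stop("contamination requires at least two genomes")
    nContam <- as.integer(round(nPairs * contamination))
    nHost <- nPairs - nContam

    srcGenome <- rep(host, nHost)
    if (nContam > 0) {
      others <- setdiff(ids, host)
      srcGenome <- c(srcGenome, others[sample.int(length(others), nContam,
                                                  replace = TRUE)])
    }
    mate1 <- character(nPairs); mate2 <- character(nPairs)
    start <- integer(nPairs); alen <- integer(nPairs)
    for (g in unique(srcGenome)) {
      sel <- which(srcGenome == g)
      gseq <- as.character(genomeSequences(refset, g))
      gseq <- gseq[which.max(nchar(gseq))]  # per-group source sequence
      amp <- .drawAmplicons(gseq, length(sel), config@ampliconRange,
                            config@readLength)
      mate1[sel] <- amp$mate1; mate2[sel] <- amp$mate2
      start[sel] <- amp$start; alen[sel] <- amp$len
    }
    mate1 <- .injectErrors(mate1, config@substitutionErrorRate)
    mate2 <- .injectErrors(mate2, config@substitutionErrorRate)
    qc <- .qualChar(config@substitutionErrorRate)
    qual <- strrep(qc, config@readLength)
    readId <- sprintf("%s:%06d", barcodeId, seq_len(nPairs))
    truth <- S4Vectors::DataFrame(
      read_id = readId, source_genome = srcGenome,
      source_taxid = unname(genomeTaxids(refset, srcGenome)),
      start = start, amplicon_len = alen,
      is_contaminant = srcGenome != host)
    new("BarcodeGroup", barcodeId = barcodeId, mate1 = mate1, mate2 = mate2,
        qual1 = rep(qual, nPairs), qual2 = rep(qual, nPairs),
        batch = "single_cell", truth = truth, truthHost = host,
        truthContamination = contamination)
  })
}

#' Simulate a full community dataset
#'
#' Generates `barcodesPerSpecies` barcode groups for every genome in the
#' reference set (up to `nSpecies`), optionally writing a paired FASTQ file
#' set and a truth TSV. Read ids follow `<barcode>:<serial>/<mate>`. Output
#' is fully deterministic for a fixed seed.
#'
#' @param refset a [ReferenceSet-class].
#' @param config a [SimulationConfig-class].
#' @param seed integer seed or `NULL`.
#' @param fastqPrefix if non-`NULL`, write `<prefix>_R1.fastq` /
#'   `<prefix>_R2.fastq` and `<prefix>_truth.tsv`.
#' @param embedBarcodes named character vector of barcode sequences (names =
#'   barcode ids) to prepend to mate 1 (for demultiplexing fixtures), or
#'   `NULL` (default).
#' @return a list with `groups` (list of [BarcodeGroup-class]), `truth`
#'   (per-read `DataFrame`), `barcodeTruth` (per-barcode data.frame) and, when
#'   written, the output paths.
#' @export
simulateDataset <- function(refset, config = simulationConfig(), seed = NULL,
                            fastqPrefix = NULL, embedBarcodes = NULL) {
  ids <- genomeIds(refset)
  if (length(ids) < config@nSpecies)
    stop("reference set has fewer genomes than nSpecies")
  ids <- ids[seq_len(config@nSpecies)]
  .withSeed(seed, {
    groups <- vector("list", length(ids) * config@barcodesPerSpecies)
    k <- 0L
    for (g in ids) {
      for (b in seq_len(config@barcodesPerSpecies)) {
        k <- k + 1L
        groups[[k]] <- simulateBarcodeGroup(
          refset, g, config, seed = NULL,
          barcodeId = sprintf("%s_bc%03d", g, b))
      }
    }
    names(groups) <- vapply(groups, function(g) g@barcodeId, character(1))
    truth <- do.call(rbind, lapply(groups, groupTruth))
    barcodeTruth <- data.frame(
      barcode_id = names(groups),
      host_genome = vapply(groups, function(g) g@truthHost, character(1)),
      host_taxid = unname(genomeTaxids(refset,
        vapply(groups, function(g) g@truthHost, character(1)))),
      contamination = vapply(groups, function(g) g@truthContamination,
                             numeric(1)),
      n_pairs = vapply(groups, readPairCount, integer(1)),
      row.names = NULL)
    out <- list(groups = groups, truth = truth, barcodeTruth = barcodeTruth)
    if (!is.null(fastqPrefix)) {
      r1 <- paste0(fastqPrefix, "_R1.fastq")
      r2 <- paste0(fastqPrefix, "_R2.fastq")
      writeGroupFastq(groups, r1, r2, embedBarcodes = embedBarcodes)
      tt <- paste0(fastqPrefix, "_truth.tsv")
      write.table(as.data.frame(truth), tt, sep = "\t", quote = FALSE,
                  row.names = FALSE)
      out$fastq <- c(R1 = r1, R2 = r2)
      out$truthPath <- tt
    }
    out
  })
}

#' Simulate metagenomic contig read groups
#'
#' Each pseudo-contig is a window of a community genome; its read group is
#' drawn from the window, plus an impurity fraction of reads from other
#' genomes (modelling chimeric or misassembled contigs). Groups are tagged
#' `batch = "contig"` and carry truth tables like simulated barcodes.
#'
#' @param refset a [ReferenceSet-class].
#' @param nContigs number of pseudo-contigs.
#' @param contigLengthRange min/max window length in bp.
#' @param readsPerContigRange min/max read pairs per contig group.
#' @param impurityRange min/max foreign-read fraction.
#' @param config a [SimulationConfig-class] (read/amplicon geometry).
#' @param seed integer seed or `NULL`.
#' @return a named list of [BarcodeGroup-class] with `batch = "contig"`.
#' @export
simulateContigGroups <- function(refset, nContigs,
                                 contigLengthRange = c(5000L, 20000L),
                                 readsPerContigRange = c(200L, 2000L),
                                 impurityRange = c(0, 0.1),
                                 config = simulationConfig(), seed = NULL) {
  ids <- genomeIds(refset)
  .withSeed(seed, {
    groups <- vector("list", nContigs)
    for (i in seq_len(nContigs)) {
      g <- ids[sample.int(length(ids), 1L)]
      gseq <- as.character(genomeSequences(refset, g))
      gseq <- gseq[which.max(nchar(gseq))]
      L <- nchar(gseq)
      wlen <- contigLengthRange[1] +
        sample.int(contigLengthRange[2] - contigLengthRange[1] + 1L, 1L) - 1L
      if (wlen > L) stop("contig window exceeds genome length")
      wstart <- sample.int(L - wlen + 1L, 1L)
      window <- substring(gseq, wstart, wstart + wlen - 1L)
      n <- readsPerContigRange[1] +
        sample.int(readsPerContigRange[2] - readsPerContigRange[1] + 1L, 1L) - 1L
      imp <- runif(1, impurityRange[1], impurityRange[2])
      nForeign <- as.integer(round(n * imp))
      nOwn <- n - nForeign
      amp <- .drawAmplicons(window, nOwn, config@ampliconRange,
                            config@readLength)
      m1 <- amp$mate1; m2 <- amp$mate2
      src <- rep(g, nOwn); st <- amp$start + wstart - 1L; al <- amp$len
      if (nForeign > 0) {
        others <- setdiff(ids, g)
        fg <- others[sample.int(length(others), nForeign, replace = TRUE)]
        for (og in unique(fg)) {
          sel <- which(fg == og)
          oseq <- as.character(genomeSequences(refset, og))
          oseq <- oseq[which.max(nchar(oseq))]
          famp <- .drawAmplicons(oseq, length(sel), config@ampliconRange,
                                 config@readLength)
          m1 <- c(m1, famp$mate1); m2 <- c(m2, famp$mate2)
          st <- c(st, famp$start); al <- c(al, famp$len)
        }
        # reads were appended grouped by source genome; keep src aligned
        src <- c(rep(g, nOwn), unlist(lapply(unique(fg), function(og)
          rep(og, sum(fg == og)))))
      }
      cid <- sprintf("contig%04d", i)
      qual <- strrep(.qualChar(config@substitutionErrorRate),
                     config@readLength)
      truth <- S4Vectors::DataFrame(
        read_id = sprintf("%s:%06d", cid, seq_len(n)),
        source_genome = src,
        source_taxid = unname(genomeTaxids(refset, src)),
        start = st, amplicon_len = al, is_contaminant = src != g)
      groups[[i]] <- new("BarcodeGroup", barcodeId = cid,
                         mate1 = .injectErrors(m1, config@substitutionErrorRate),
                         mate2 = .injectErrors(m2, config@substitutionErrorRate),
                         qual1 = rep(qual, n), qual2 = rep(qual, n),
                         batch = "contig", truth = truth, truthHost = g,
                         truthContamination = imp)
    }
    names(groups) <- vapply(groups, function(x) x@barcodeId, character(1))
    groups
  })
}

#' Write barcode groups as a paired FASTQ file set
#'
#' Read ids are `<barcode>:<serial>/1` and `/2`. With `embedBarcodes`, the
#' group's barcode sequence is prepended to mate 1 (with matching quality
#' characters), producing raw-style input for [demultiplex()].
#'
#' @param groups list of [BarcodeGroup-class].
#' @param r1Path,r2Path output FASTQ paths (`.gz` suffix gzips).
#' @param embedBarcodes optional named character vector (barcode id ->
#'   barcode sequence).
#' @return invisibly, `c(r1Path, r2Path)`.
#' @export
writeGroupFastq <- function(groups, r1Path, r2Path, embedBarcodes = NULL) {
  m1 <- unlist(lapply(groups, function(g) g@mate1), use.names = FALSE)
  m2 <- unlist(lapply(groups, function(g) g@mate2), use.names = FALSE)
  q1 <- unlist(lapply(groups, function(g) g@qual1), use.names = FALSE)
  q2 <- unlist(lapply(groups, function(g) g@qual2), use.names = FALSE)
  ids <- unlist(lapply(groups, function(g)
    sprintf("%s:%06d", g@barcodeId, seq_len(readPairCount(g)))),
    use.names = FALSE)
  if (!is.null(embedBarcodes)) {
    bc <- unlist(lapply(groups, function(g)
      rep(unname(embedBarcodes[g@barcodeId]), readPairCount(g))),
      use.names = FALSE)
    if (anyNA(bc)) stop("missing barcode sequence for some group(s)")
    m1 <- paste0(bc, m1)
    q1 <- paste0(strrep("I", nchar(bc)), q1)
  }
  .writeFastq(ids, m1, q1, "/1", r1Path)
  .writeFastq(ids, m2, q2, "/2", r2Path)
  invisible(c(r1Path, r2Path))
}

.writeFastq <- function(ids, seqs, quals, mate, path) {
  con <- if (grepl("\\.gz$", path)) gzfile(path, "wb") else file(path, "wb")
  on.exit(close(con))
  writeLines(paste0("@", ids, mate, "\n", seqs, "\n+\n", quals), con, sep = "\n")
}

#' Read a FASTQ file into id/sequence/quality vectors
#'
#' @param path FASTQ file (optionally gzipped).
#' @return a list with character vectors `id`, `seq`, `qual`.
#' @export
readFastq <- function(path) {
  lines <- readLines(path)
  if (length(lines) %% 4 != 0) stop("truncated FASTQ: ", path)
  n <- length(lines) / 4
  idx <- seq_len(n)
  list(id = sub("^@", "", lines[4 * idx - 3]),
       seq = lines[4 * idx - 2],
       qual = lines[4 * idx])
}

#' Derive a strain panel from a common ancestor
#'
#' Generates an ancestor genome and `nStrains` descendants, each mutated
#' independently at `divergence` substitutions per base (so each strain is
#' about `1 - divergence` identical to the ancestor).
#'
#' @param nStrains number of strains.
#' @param genomeLength ancestor length in bp.
#' @param divergence per-base substitution rate from the ancestor.
#' @param gc ancestor GC fraction.
#' @param seed integer seed or `NULL`.
#' @return named character vector of strain genome sequences
#'   (`strain01`, ...).
#' @export
simulateStrainGenomes <- function(nStrains, genomeLength = 1e5,
                                  divergence = 0.01, gc = 0.5, seed = NULL) {
  .withSeed(seed, {
    anc <- generateGenome(genomeLength, gc)
    out <- vapply(seq_len(nStrains), function(i)
      mutateGenome(anc, divergence), character(1))
    names(out) <- sprintf("strain%02d", seq_len(nStrains))
    out
  })
}
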