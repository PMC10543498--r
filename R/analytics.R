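# Cluster-level post-processing: read pooling, coverage and rarefaction,
# error rates, gene presence/absence filtering and subclustering, MAPQ-
# filtered per-feature RPM counting, and droplet-occupancy arithmetic.

#' Pool barcode groups by cluster label
#'
#' Concatenates the reads of all groups sharing a cluster label into one
#' pooled group per cluster (e.g. for external assembly). Barcodes are
#' processed in lexicographic order within each cluster, and reads keep
#' their serial order, so output is deterministic. Read counts are
#' conserved.
#'
#' @param groups named list of [BarcodeGroup-class].
#' @param labels named vector (cluster label per barcode id) covering every
#'   group.
#' @return named list of pooled [BarcodeGroup-class], one per cluster.
#' @export
poolClusters <- function(groups, labels) {
  ids <- names(groups)
  if (!all(ids %in% names(labels)))
    stop("unlabeled barcode(s): ",
         paste(head(setdiff(ids, names(labels))), collapse = ", "))
  labels <- labels[ids]
  out <- list()
  for (cl in sort(unique(as.character(labels)))) {
    members <- sort(ids[as.character(labels) == cl])
    gl <- groups[members]
    truths <- lapply(gl, groupTruth)
    truth <- if (any(vapply(truths, is.null, logical(1)))) NULL
             else do.call(rbind, truths)
    out[[cl]] <- new("BarcodeGroup",
      barcodeId = paste0("cluster_", cl),
      mate1 = unlist(lapply(gl, function(g) g@mate1), use.names = FALSE),
      mate2 = unlist(lapply(gl, function(g) g@mate2), use.names = FALSE),
      qual1 = unlist(lapply(gl, function(g) g@qual1), use.names = FALSE),
      qual2 = unlist(lapply(gl, function(g) g@qual2), use.names = FALSE),
      batch = "single_cell", truth = truth,
      truthHost = NA_character_, truthContamination = NA_real_)
  }
  out
}

#' Covered fraction and mean depth of placements on a reference
#'
#' Placements are read (or amplicon) intervals given as 1-based start
#' positions and lengths; internally they are treated as half-open
#' intervals. Covered fraction is the number of distinct covered bases over
#' the genome length; mean depth is total placed bases over genome length.
#'
#' @param starts integer vector of 1-based start positions.
#' @param lengths integer vector of interval lengths.
#' @param referenceLength genome length in bp.
#' @return list with `coveredFraction` and `meanDepth`.
#' @export
coverageStats <- function(starts, lengths, referenceLength) {
  if (length(starts) == 0)
    return(list(coveredFraction = 0, meanDepth = 0))
  if (any(starts < 1) || any(starts + lengths - 1 > referenceLength))
    stop("placement beyond reference end")
  ir <- IRanges::reduce(IRanges::IRanges(start = starts, width = lengths))
  list(coveredFraction = sum(IRanges::width(ir)) / referenceLength,
       meanDepth = sum(as.numeric(lengths)) / referenceLength)
}

#' Read/mate placement intervals from a simulated group's truth table
#'
#' Each pair contributes two intervals: mate 1 at the amplicon 5' end and
#' mate 2 at its 3' end.
#'
#' @param group a simulated [BarcodeGroup-class].
#' @param hostOnly keep only non-contaminant reads (default TRUE).
#' @return data.frame with `start` and `len` (1-based starts).
#' @export
truthPlacements <- function(group, hostOnly = TRUE) {
  tr <- groupTruth(group)
  if (is.null(tr)) stop("group has no truth table")
  rl <- nchar(group@mate1[1])
  keep <- if (hostOnly) !tr$is_contaminant else rep(TRUE, nrow(tr))
  data.frame(
    start = c(tr$start[keep], tr$start[keep] + tr$amplicon_len[keep] - rl),
    len = rl)
}

#' Rarefaction curve of coverage versus subsampled reads
#'
#' Samples up to `nTotal` placements without replacement (default 10000,
#' capped at the available count) and evaluates the covered fraction at
#' `nPoints` evenly spaced sampling depths. The final point equals
#' [coverageStats()] of the full sample; the curve is non-decreasing.
#'
#' @param placements data.frame with `start` and `len` columns.
#' @param referenceLength genome length in bp.
#' @param nTotal reads to sample (default 10000).
#' @param nPoints number of curve points (default 20).
#' @param seed integer seed or `NULL`.
#' @return data.frame with `reads` and `coveredFraction` (class
#'   `RarefactionCurve`).
#' @export
rarefaction <- function(placements, referenceLength, nTotal = 10000L,
                        nPoints = 20L, seed = NULL) {
  n <- min(nrow(placements), nTotal)
  .withSeed(seed, {
    ord <- sample.int(nrow(placements), n)
    depths <- unique(pmax(1L, round(seq(0, n, length.out = nPoints + 1L))[-1]))
    cov <- vapply(depths, function(d) {
      sel <- ord[seq_len(d)]
      coverageStats(placements$start[sel], placements$len[sel],
                    referenceLength)$coveredFraction
    }, numeric(1))
    structure(data.frame(reads = depths, coveredFraction = cov),
              class = c("RarefactionCurve", "data.frame"))
  })
}

#' Cluster error rate
#'
#' Truth mode: the fraction of pooled reads whose source taxon does not
#' match the cluster's assigned taxon at the given rank. Alignment mode
#' (logical input): the fraction of reads not aligned to the cluster
#' reference.
#'
#' @param x either an integer vector of per-read source taxids, or a
#'   logical vector (`TRUE` = read attributable/aligned).
#' @param clusterTaxid assigned taxon (truth mode only).
#' @param taxonomy a [Taxonomy-class] (truth mode only).
#' @param rank comparison rank (default `"genus"`).
#' @return error-rate fraction in `[0, 1]`.
#' @export
clusterErrorRate <- function(x, clusterTaxid = NULL, taxonomy = NULL,
                             rank = "genus") {
  if (is.logical(x)) return(mean(!x))
  if (is.null(clusterTaxid) || is.null(taxonomy))
    stop("truth mode needs clusterTaxid and taxonomy")
  target <- ancestorAtRank(taxonomy, clusterTaxid, rank)
  at <- vapply(unique(x), function(t) ancestorAtRank(taxonomy, t, rank),
               integer(1))
  readRank <- at[match(x, unique(x))]
  mean(is.na(readRank) | readRank != target)
}

#' Filter a gene presence/absence matrix
#'
#' Drops genes present in fewer than `minCellsPerGene` cells, then cells
#' with fewer than `minGenesPerCell` remaining genes — one pass, in that
#' order. Defaults are 10 and 10.
#'
#' @param mat cells-by-genes matrix (counts or 0/1; presence is `> 0`).
#' @param minCellsPerGene,minGenesPerCell inclusive thresholds.
#' @return the filtered matrix.
#' @export
filterGeneMatrix <- function(mat, minCellsPerGene = 10L,
                             minGenesPerCell = 10L) {
  if (any(mat < 0)) stop("negative entries in gene matrix")
  pres <- mat > 0
  keepGenes <- colSums(pres) >= minCellsPerGene
  mat <- mat[, keepGenes, drop = FALSE]
  keepCells <- rowSums(mat > 0) >= minGenesPerCell
  mat[keepCells, , drop = FALSE]
}

#' Subcluster cells on a binary gene matrix
#'
#' Builds the cell-cell graph weighted by Jaccard similarity of gene
#' presence sets and partitions it with the Leiden algorithm. Deterministic
#' for a fixed seed; a degenerate matrix (identical rows) yields one
#' cluster.
#'
#' @param mat cells-by-genes matrix (presence is `> 0`).
#' @param resolution Leiden resolution (default 1).
#' @param seed integer seed (default 0).
#' @return integer cluster label per cell (named by rownames).
#' @export
subclusterGenes <- function(mat, resolution = 1, seed = 0L) {
  n <- nrow(mat)
  if (n < 2) stop("need at least 2 cells")
  P <- (mat > 0) * 1
  inter <- tcrossprod(P)
  sizes <- rowSums(P)
  un <- outer(sizes, sizes, "+") - inter
  J <- ifelse(un > 0, inter / un, 0)
  diag(J) <- 0
  if (all(J[upper.tri(J)] %in% c(0, 1)) && all(J[upper.tri(J)] == 1))
    return(setNames(rep(1L, n), rownames(mat)))
  edges <- which(upper.tri(J) & J > 0, arr.ind = TRUE)
  .withSeed(seed, {
    g <- igraph::make_empty_graph(n, directed = FALSE)
    if (nrow(edges) > 0) {
      g <- igraph::add_edges(g, as.vector(t(edges)))
      igraph::E(g)$weight <- J[edges]
    }
    cl <- igraph::cluster_leiden(g, objective_function = "modularity",
                                 resolution = resolution, n_iterations = 5)
    setNames(as.integer(igraph::membership(cl)), rownames(mat))
  })
}

#' Count per-feature read hits and reads-per-million
#'
#' Keeps alignment records with `mapq >= mapqMin` (default 42, i.e. reads
#' without mismatches under the usual aligner convention), removes duplicate
#' records at identical (feature, position), and reports unique hit counts
#' and RPM = hits * 1e6 / totalReads. Output is invariant to record order.
#'
#' @param records data.frame with columns `feature_id`, `mapq`, `position`
#'   (and optionally `read_id`).
#' @param mapqMin MAPQ threshold (default 42).
#' @param totalReads total read count of the pooled unit (RPM denominator).
#' @return data.frame with `feature_id`, `hits`, `rpm`, sorted by
#'   `feature_id`.
#' @export
countFeatureHits <- function(records, mapqMin = 42L, totalReads) {
  if (totalReads <= 0) stop("totalReads must be positive")
  rec <- records[records$mapq >= mapqMin, , drop = FALSE]
  if (nrow(rec) == 0)
    return(data.frame(feature_id = character(0), hits = integer(0),
                      rpm = numeric(0)))
  rec <- rec[!duplicated(rec[, c("feature_id", "position")]), , drop = FALSE]
  tab <- table(rec$feature_id)
  data.frame(feature_id = sort(names(tab)),
             hits = as.integer(tab[sort(names(tab))]),
             rpm = as.numeric(tab[sort(names(tab))]) * 1e6 / totalReads,
             row.names = NULL)
}

#' Droplet occupancy probabilities
#'
#' With hydrogels loaded with cells at rate `loadRate` and `gelsPerDroplet`
#' gels per droplet, the number of cell-bearing gels per droplet is
#' `Binomial(n, p)` (or its Poisson approximation with `lambda = n * p`).
#' Defaults (p = 0.02, n = 5) give about 9.6% of droplets with at least one
#' cell.
#'
#' @param loadRate per-gel cell probability in `[0, 1]`.
#' @param gelsPerDroplet gels per droplet (non-negative integer).
#' @param model `"binomial"` (exact, default) or `"poisson"`.
#' @return list (class `OccupancyProfile`) with `p0`, `p1`, `pMulti`
#'   (P(>=2)), `pOccupied` (P(>=1)) and the per-count `distribution`.
#' @export
dropletOccupancy <- function(loadRate = 0.02, gelsPerDroplet = 5L,
                             model = c("binomial", "poisson")) {
  model <- match.arg(model)
  if (loadRate < 0 || loadRate > 1) stop("loadRate must be in [0,1]")
  if (gelsPerDroplet < 0) stop("gelsPerDroplet must be non-negative")
  n <- as.integer(gelsPerDroplet)
  if (model == "binomial") {
    dist <- dbinom(0:n, n, loadRate)
  } else {
    lambda <- n * loadRate
    # truncate at a mass-complete tail and fold the remainder into the last bin
    kmax <- max(n, ceiling(lambda + 10 * sqrt(lambda + 1)))
    dist <- dpois(0:kmax, lambda)
    dist[length(dist)] <- dist[length(dist)] +
      stats::ppois(kmax, lambda, lower.tail = FALSE)
  }
  names(dist) <- as.character(seq_along(dist) - 1L)
  structure(list(p0 = dist[["0"]],
                 p1 = if ("1" %in% names(dist)) dist[["1"]] else 0,
                 pMulti = sum(dist[-(1:2)]),
                 pOccupied = 1 - dist[["0"]],
                 distribution = dist,
                 model = model, loadRate = loadRate,
                 gelsPerDroplet = n),
            class = "OccupancyProfile")
}

#' @export
print.OccupancyProfile <- function(x, ...) {
  cat(sprintf(paste0("OccupancyProfile (%s, p = %g, n = %d): ",
                     "P(0) = %.4f, P(1) = %.4f, P(>=2) = %.4f\n"),
              x$model, x$loadRate, x$gelsPerDroplet, x$p0, x$p1, x$pMulti))
  invisible(x)
}

#' Parse a minimal SAM record subset
#'
#' Reads a text SAM file keeping `QNAME`, `FLAG`, `RNAME`, `POS`, `MAPQ` and
#' the `NM` tag (NA when absent). Header lines are skipped; unmapped records
#' (`RNAME == "*"`) get `rname = NA`.
#'
#' @param path SAM file.
#' @return data.frame with `qname`, `flag`, `rname`, `pos`, `mapq`, `nm`.
#' @export
readSamSubset <- function(path) {
  lines <- readLines(path)
  lines <- lines[!startsWith(lines, "@")]
  if (length(lines) == 0)
    return(data.frame(qname = character(0), flag = integer(0),
                      rname = character(0), pos = integer(0),
                      mapq = integer(0), nm = integer(0)))
  fields <- strsplit(lines, "\t", fixed = TRUE)
  bad <- which(lengths(fields) < 11)
  if (length(bad) > 0)
    stop("malformed SAM record at line ", bad[1], ": fewer than 11 fields")
  nm <- vapply(fields, function(f) {
    tag <- grep("^NM:i:", f[-(1:11)], value = TRUE)
    if (length(tag) == 0) NA_integer_
    else as.integer(sub("^NM:i:", "", tag[1]))
  }, integer(1))
  data.frame(
    qname = vapply(fields, `[`, character(1), 1),
    flag = as.integer(vapply(fields, `[`, character(1), 2)),
    rname = ifelse(vapply(fields, `[`, character(1), 3) == "*", NA_character_,
                   vapply(fields, `[`, character(1), 3)),
    pos = as.integer(vapply(fields, `[`, character(1), 4)),
    mapq = as.integer(vapply(fields, `[`, character(1), 5)),
    nm = nm,
    seqlen = nchar(vapply(fields, `[`, character(1), 10)),
    row.names = NULL)
}
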