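# Taxonomic Discovery Algorithm: per-unit rank abundance vectors, quality
# filters, joint matrix assembly, UMAP embedding with Leiden clustering on
# the shared-nearest-neighbor graph, dominant-taxon annotation, contig
# integration and benchmark scoring against simulation truth.

#' Per-unit relative abundance vector at a fixed rank
#'
#' @slot unitId barcode or contig id.
#' @slot batch `"single_cell"` or `"contig"`.
#' @slot rank rank label.
#' @slot abundance numeric vector named by taxid; sums to 1 over classified
#'   reads, or is empty/all-zero when nothing was classified at the rank.
#' @slot taxnames taxon names parallel to `abundance`.
#' @slot readCount total reads in the unit.
#' @slot classifiedFraction reads classified at the rank / total reads.
#' @slot purity maximum relative abundance (0 when nothing classified).
#' @export
setClass("AbundanceVector",
  representation(unitId = "character", batch = "character", rank = "character",
                 abundance = "numeric", taxnames = "character",
                 readCount = "numeric", classifiedFraction = "numeric",
                 purity = "numeric"))

setValidity("AbundanceVector", function(object) {
  if (any(object@abundance < 0)) return("negative abundance")
  s <- sum(object@abundance)
  if (length(object@abundance) > 0 && s > 0 && abs(s - 1) > 1e-8)
    return("abundances must sum to 1 over classified reads")
  if (object@classifiedFraction < 0 || object@classifiedFraction > 1)
    return("classifiedFraction outside [0,1]")
  if (length(object@abundance) > 0 &&
      abs(object@purity - max(object@abundance)) > 1e-8)
    return("purity must equal the maximum abundance")
  TRUE
})

setMethod("show", "AbundanceVector", function(object) {
  cat(sprintf("AbundanceVector %s (%s, %s): %d taxa, purity %.3f, classified %.3f of %g reads\n",
              object@unitId, object@batch, object@rank,
              length(object@abundance), object@purity,
              object@classifiedFraction, object@readCount))
})

#' Purity of an abundance vector (dominant-taxon fraction)
#' @param x an [AbundanceVector-class].
#' @return numeric scalar in `[0, 1]`.
#' @export
vectorPurity <- function(x) x@purity

#' Convert a rank abundance profile to a relative abundance vector
#'
#' Counts are normalised to fractions of the reads classified at the rank;
#' `purity` is the maximum fraction and `classifiedFraction` the classified
#' share of all reads in the unit.
#'
#' @param abund a [RankAbundance-class].
#' @param totalReads total reads in the unit (defaults to the profile's
#'   recorded total).
#' @param batch `"single_cell"` or `"contig"`.
#' @return an [AbundanceVector-class].
#' @export
toAbundanceVector <- function(abund, totalReads = abund@total,
                              batch = "single_cell") {
  if (any(abund@counts < 0)) stop("negative counts")
  classified <- sum(abund@counts)
  if (totalReads < classified) stop("totalReads smaller than classified reads")
  ab <- if (classified > 0) abund@counts / classified else abund@counts
  obj <- new("AbundanceVector", unitId = abund@barcodeId, batch = batch,
             rank = abund@rank, abundance = ab, taxnames = abund@taxnames,
             readCount = as.numeric(totalReads),
             classifiedFraction = if (totalReads > 0) classified / totalReads else 0,
             purity = if (length(ab) > 0 && classified > 0) max(ab) else 0)
  validObject(obj)
  obj
}

#' Quality-filter thresholds for abundance vectors
#'
#' Defaults follow the standard workflow: at least 1000 reads, at least 50%
#' of reads classified, purity of at least 0.8 for single cells and 0.9 for
#' contig units. All comparisons are inclusive (a unit exactly at a
#' threshold is retained).
#'
#' @param minReads minimum reads per unit.
#' @param minClassifiedFraction minimum classified fraction.
#' @param minPurity minimum purity for single-cell units.
#' @param contigMinPurity minimum purity for contig units.
#' @return a named list of thresholds (class `FilterThresholds`).
#' @export
filterThresholds <- function(minReads = 1000, minClassifiedFraction = 0.5,
                             minPurity = 0.8, contigMinPurity = 0.9) {
  stopifnot(minReads >= 0, minClassifiedFraction >= 0,
            minClassifiedFraction <= 1, minPurity >= 0, minPurity <= 1,
            contigMinPurity >= 0, contigMinPurity <= 1)
  structure(list(minReads = minReads,
                 minClassifiedFraction = minClassifiedFraction,
                 minPurity = minPurity, contigMinPurity = contigMinPurity),
            class = "FilterThresholds")
}

#' Filter abundance vectors by reads, classified fraction and purity
#'
#' A unit is retained iff `readCount >= minReads` and
#' `classifiedFraction >= minClassifiedFraction` and
#' `purity >=` the batch-appropriate purity threshold. The rejection log
#' records the first failed test per rejected unit.
#'
#' @param vectors list of [AbundanceVector-class].
#' @param thresholds a [filterThresholds()] list.
#' @return list with `retained` (vectors) and `rejected`
#'   (data.frame `unit_id`, `reason`).
#' @export
filterVectors <- function(vectors, thresholds = filterThresholds()) {
  reasons <- vapply(vectors, function(v) {
    if (v@readCount < thresholds$minReads) return("read_count")
    if (v@classifiedFraction < thresholds$minClassifiedFraction)
      return("classified_fraction")
    pmin <- if (v@batch == "contig") thresholds$contigMinPurity
            else thresholds$minPurity
    if (v@purity < pmin) return("purity")
    ""
  }, character(1))
  keep <- reasons == ""
  list(retained = vectors[keep],
       rejected = data.frame(
         unit_id = vapply(vectors[!keep], function(v) v@unitId, character(1)),
         reason = reasons[!keep], row.names = NULL))
}

#' Assemble abundance vectors into a units-by-taxa experiment
#'
#' Columns are units, rows the union of taxa seen across the vectors
#' (missing taxa filled with zero). Unit order follows the input. Per-unit
#' metadata (`batch`, `readCount`, `classifiedFraction`, `purity`) is stored
#' in `colData`; the rank in `metadata(x)$rank`.
#'
#' @param vectors non-empty list of [AbundanceVector-class], all at the same
#'   rank.
#' @return a [SingleCellExperiment::SingleCellExperiment] with assay
#'   `"abundance"`.
#' @export
assembleMatrix <- function(vectors) {
  if (length(vectors) == 0) stop("no vectors to assemble")
  ranks <- unique(vapply(vectors, function(v) v@rank, character(1)))
  if (length(ranks) != 1) stop("vectors at different ranks: ",
                               paste(ranks, collapse = ", "))
  taxids <- unique(unlist(lapply(vectors, function(v) names(v@abundance))))
  taxids <- sort(taxids)
  nameOf <- do.call(c, unname(lapply(vectors, function(v)
    setNames(v@taxnames, names(v@abundance)))))
  nameOf <- nameOf[!duplicated(names(nameOf))]
  mat <- vapply(vectors, function(v) {
    out <- setNames(numeric(length(taxids)), taxids)
    out[names(v@abundance)] <- v@abundance
    out
  }, numeric(length(taxids)))
  mat <- matrix(mat, nrow = length(taxids),
                dimnames = list(taxids,
                                vapply(vectors, function(v) v@unitId,
                                       character(1))))
  sce <- SingleCellExperiment::SingleCellExperiment(
    assays = list(abundance = mat),
    rowData = S4Vectors::DataFrame(taxid = as.integer(taxids),
                                   name = unname(nameOf[taxids])),
    colData = S4Vectors::DataFrame(
      unit_id = colnames(mat),
      batch = vapply(vectors, function(v) v@batch, character(1)),
      readCount = vapply(vectors, function(v) v@readCount, numeric(1)),
      classifiedFraction = vapply(vectors, function(v) v@classifiedFraction,
                                  numeric(1)),
      purity = vapply(vectors, function(v) v@purity, numeric(1))))
  S4Vectors::metadata(sce)$rank <- ranks
  sce
}

#' Cosine k-nearest-neighbour shared-neighbour graph
#' @noRd
.snnGraph <- function(X, nNeighbors) {
  n <- nrow(X)
  k <- min(nNeighbors, n - 1L)
  norms <- sqrt(rowSums(X^2))
  norms[norms == 0] <- 1
  S <- tcrossprod(X / norms)
  diag(S) <- -Inf
  nbr <- t(apply(S, 1, function(r) order(r, decreasing = TRUE)[seq_len(k)]))
  # shared-neighbor (Jaccard) weights over the union of directed kNN edges
  edges <- cbind(rep(seq_len(n), each = k), as.vector(t(nbr)))
  edges <- unique(t(apply(edges, 1, sort)))
  nbrSets <- lapply(seq_len(n), function(i) c(i, nbr[i, ]))
  w <- apply(edges, 1, function(e) {
    a <- nbrSets[[e[1]]]; b <- nbrSets[[e[2]]]
    length(intersect(a, b)) / length(union(a, b))
  })
  keep <- w > 0
  g <- igraph::make_empty_graph(n, directed = FALSE)
  g <- igraph::add_edges(g, as.vector(t(edges[keep, , drop = FALSE])))
  igraph::E(g)$weight <- w[keep]
  g
}

#' Embed and cluster an assembled abundance matrix
#'
#' Units are embedded in 2-D with UMAP (cosine metric) for display, and
#' clustered with the Leiden algorithm on the shared-nearest-neighbour graph
#' built in the original vector space (not on the 2-D embedding). Both steps
#' are deterministic for a fixed `seed`. A degenerate matrix whose rows are
#' all identical yields a single cluster.
#'
#' @param sce a [SingleCellExperiment::SingleCellExperiment] from
#'   [assembleMatrix()].
#' @param nNeighbors neighbourhood size (default 15, clamped to n-1).
#' @param minDist UMAP `min_dist` (default 0.1).
#' @param resolution Leiden resolution parameter (default 0.1; low enough
#'   not to over-partition homogeneous populations, while disconnected
#'   populations are never merged at any positive resolution).
#' @param seed integer seed (default 0).
#' @return the experiment with `reducedDim(x, "UMAP")` and a `cluster`
#'   column (factor) in `colData`.
#' @export
embedCluster <- function(sce, nNeighbors = 15L, minDist = 0.1,
                         resolution = 0.1, seed = 0L) {
  X <- t(SummarizedExperiment::assay(sce, "abundance"))
  n <- nrow(X)
  if (n < 2) stop("need at least 2 units to cluster")
  if (all(apply(X, 2, function(col) length(unique(col)) == 1))) {
    SingleCellExperiment::reducedDim(sce, "UMAP") <-
      matrix(0, n, 2, dimnames = list(rownames(X), c("UMAP1", "UMAP2")))
    SummarizedExperiment::colData(sce)$cluster <- factor(rep(1L, n))
    return(sce)
  }
  .withSeed(seed, {
    g <- .snnGraph(X, nNeighbors)
    cl <- igraph::cluster_leiden(g, objective_function = "modularity",
                                 resolution = resolution, n_iterations = 5)
    labels <- igraph::membership(cl)
    emb <- if (n >= 15) {
      uwot::umap(X, n_neighbors = min(nNeighbors, n - 1L),
                 min_dist = minDist, metric = "cosine",
                 n_threads = 1, n_sgd_threads = 0, batch = TRUE)
    } else {
      # tiny inputs: classical MDS on cosine distances is stable and enough
      norms <- sqrt(rowSums(X^2)); norms[norms == 0] <- 1
      d <- stats::as.dist(1 - tcrossprod(X / norms))
      cmd <- stats::cmdscale(d, k = 2)
      if (ncol(cmd) < 2) cmd <- cbind(cmd, 0)
      cmd
    }
    dimnames(emb) <- list(rownames(X), c("UMAP1", "UMAP2"))
    SingleCellExperiment::reducedDim(sce, "UMAP") <- emb
    SummarizedExperiment::colData(sce)$cluster <-
      factor(as.integer(labels))
    sce
  })
}

#' Annotate units and clusters with dominant taxa
#'
#' Each unit is annotated with its most abundant taxon (ties broken
#' lexicographically by name and flagged); each cluster with the modal unit
#' annotation (same tie rule).
#'
#' @param sce a clustered experiment from [embedCluster()].
#' @return the experiment with `annotation`, `annotationTie` and
#'   `clusterAnnotation` columns in `colData`.
#' @export
annotateClusters <- function(sce) {
  cd <- SummarizedExperiment::colData(sce)
  if (is.null(cd$cluster)) stop("run embedCluster() first")
  A <- SummarizedExperiment::assay(sce, "abundance")
  rn <- SummarizedExperiment::rowData(sce)$name
  ann <- character(ncol(A)); tie <- logical(ncol(A))
  for (j in seq_len(ncol(A))) {
    m <- max(A[, j])
    best <- rn[A[, j] == m]
    if (m == 0) { ann[j] <- NA_character_; next }
    tie[j] <- length(best) > 1
    ann[j] <- sort(best)[1]
  }
  clAnn <- tapply(ann, cd$cluster, function(a) {
    tab <- sort(table(a), decreasing = TRUE)
    top <- names(tab)[tab == max(tab)]
    sort(top)[1]
  })
  cd$annotation <- ann
  cd$annotationTie <- tie
  cd$clusterAnnotation <- as.character(clAnn[as.character(cd$cluster)])
  SummarizedExperiment::colData(sce) <- cd
  sce
}

#' Integrate contig pseudo-barcode vectors with single-cell vectors
#'
#' Contig vectors are filtered at `contigMinPurity` (default 0.9) and then
#' concatenated with the cell vectors into one experiment; the `batch`
#' column distinguishes the two sources for joint embedding.
#'
#' @param cellVectors,contigVectors lists of [AbundanceVector-class] at the
#'   same rank.
#' @param contigMinPurity purity cutoff applied to contig vectors.
#' @return a [SingleCellExperiment::SingleCellExperiment].
#' @export
integrateContigs <- function(cellVectors, contigVectors,
                             contigMinPurity = 0.9) {
  ranks <- unique(c(vapply(cellVectors, function(v) v@rank, character(1)),
                    vapply(contigVectors, function(v) v@rank, character(1))))
  if (length(ranks) > 1) stop("cell and contig vectors at different ranks")
  keep <- vapply(contigVectors, function(v) v@purity >= contigMinPurity,
                 logical(1))
  assembleMatrix(c(cellVectors, contigVectors[keep]))
}

#' Subcluster the units of one cluster at species rank
#'
#' Re-runs matrix assembly and embedding/clustering on species-level
#' abundance vectors restricted to the given units — the standard way to
#' split a genus-level cluster into its species populations.
#'
#' @param speciesVectors list of species-rank [AbundanceVector-class]
#'   covering at least the requested units.
#' @param unitIds units (of one genus cluster) to subcluster.
#' @param ... passed to [embedCluster()].
#' @return a clustered [SingleCellExperiment::SingleCellExperiment].
#' @export
subcluster <- function(speciesVectors, unitIds, ...) {
  ids <- vapply(speciesVectors, function(v) v@unitId, character(1))
  sel <- speciesVectors[ids %in% unitIds]
  if (length(sel) < 2) stop("need at least 2 units to subcluster")
  embedCluster(assembleMatrix(sel), ...)
}

#' Flat cluster map of an annotated experiment
#' @param sce an annotated, clustered experiment.
#' @return data.frame with `unit_id`, `batch`, `x`, `y`, `cluster`,
#'   `annotation`, `cluster_annotation`.
#' @export
clusterMap <- function(sce) {
  cd <- SummarizedExperiment::colData(sce)
  emb <- SingleCellExperiment::reducedDim(sce, "UMAP")
  data.frame(unit_id = cd$unit_id, batch = cd$batch,
             x = emb[, 1], y = emb[, 2],
             cluster = as.integer(as.character(cd$cluster)),
             annotation = if (!is.null(cd$annotation)) cd$annotation else NA,
             cluster_annotation = if (!is.null(cd$clusterAnnotation))
               cd$clusterAnnotation else NA,
             row.names = NULL)
}

#' Score a clustering run against simulation truth
#'
#' Computes the identification accuracy (fraction of units whose dominant
#' taxon annotation matches the truth taxon of their host genome at the
#' working rank), the mean after-filter purity, the retained unit count and
#' a purity-threshold retention curve.
#'
#' @param sce an annotated experiment covering the retained units.
#' @param vectors the unfiltered list of [AbundanceVector-class] (used for
#'   the retention curve).
#' @param truth data.frame with columns `barcode_id` and `host_taxid`
#'   (the per-barcode truth table of [simulateDataset()]).
#' @param taxonomy a [Taxonomy-class].
#' @param thresholdGrid purity thresholds for the retention curve
#'   (default `seq(0.5, 0.99, by = 0.07)`).
#' @return a list (class `BenchmarkReport`): `identificationAccuracy`,
#'   `meanPurity`, `retained`, `retentionCurve`.
#' @export
evaluateBenchmark <- function(sce, vectors, truth, taxonomy,
                              thresholdGrid = seq(0.5, 0.99, by = 0.07)) {
  cd <- SummarizedExperiment::colData(sce)
  if (is.null(cd$annotation)) stop("run annotateClusters() first")
  rank <- S4Vectors::metadata(sce)$rank
  m <- match(cd$unit_id, truth$barcode_id)
  if (anyNA(m)) stop("truth table missing unit(s): ",
                     paste(head(cd$unit_id[is.na(m)]), collapse = ", "))
  truthRank <- vapply(truth$host_taxid[m], function(t) {
    a <- ancestorAtRank(taxonomy, t, rank)
    if (is.na(a)) NA_character_ else taxonName(taxonomy, a)
  }, character(1))
  acc <- mean(cd$annotation == truthRank, na.rm = FALSE)
  pur <- vapply(vectors, vectorPurity, numeric(1))
  curve <- data.frame(
    threshold = thresholdGrid,
    retained = vapply(thresholdGrid, function(th) sum(pur >= th), integer(1)),
    meanPurity = vapply(thresholdGrid, function(th)
      if (any(pur >= th)) mean(pur[pur >= th]) else NA_real_, numeric(1)))
  structure(list(identificationAccuracy = acc,
                 meanPurity = mean(cd$purity),
                 retained = ncol(sce),
                 retentionCurve = curve),
            class = "BenchmarkReport")
}

#' @export
print.BenchmarkReport <- function(x, ...) {
  cat(sprintf(paste0("BenchmarkReport: identification accuracy %.4f, ",
                     "mean after-filter purity %.4f, %d unit(s) retained\n"),
              x$identificationAccuracy, x$meanPurity, x$retained))
  invisible(x)
}

#' Classify a set of barcode groups into rank abundance vectors
#'
#' Streams the groups one at a time (reads are not kept), classifying with
#' the k-mer index and redistributing counts to `rank`.
#'
#' @param groups list of [BarcodeGroup-class].
#' @param index a [KmerIndex-class].
#' @param rank target rank (default `"genus"`).
#' @return named list of [AbundanceVector-class].
#' @export
groupsToVectors <- function(groups, index, rank = "genus") {
  tax <- index@taxonomy
  out <- lapply(groups, function(g) {
    tc <- classifyGroup(g, index)
    toAbundanceVector(redistributeToRank(tc, tax, rank),
                      totalReads = readPairCount(g), batch = g@batch)
  })
  names(out) <- vapply(out, function(v) v@unitId, character(1))
  out
}
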