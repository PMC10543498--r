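mkVec <- function(id, ab, names = NULL, total = 1000, batch = "single_cell",
                  rank = "genus") {
  counts <- ab
  if (is.null(names)) names <- paste0("tax", names(ab))
  ra <- new("RankAbundance", barcodeId = id, rank = rank, counts = counts,
            taxnames = names, unclassified = 0, dropped = 0,
            total = total)
  toAbundanceVector(ra, totalReads = total, batch = batch)
}

test_that("toAbundanceVector normalises, sets purity and classified
           fraction", {
  v <- mkVec("u1", c("10" = 90, "11" = 10), total = 200)
  expect_equal(unname(v@abundance), c(0.9, 0.1))
  expect_equal(v@purity, 0.9)
  expect_equal(v@classifiedFraction, 0.5)

  v2 <- mkVec("u2", c("10" = 100), total = 100)
  expect_equal(v2@purity, 1); expect_equal(v2@classifiedFraction, 1)

  v3 <- mkVec("u3", setNames(numeric(0), character(0)), names = character(0),
              total = 50)
  expect_equal(v3@purity, 0)
  expect_equal(v3@classifiedFraction, 0)
  expect_error(toAbundanceVector(
    new("RankAbundance", barcodeId = "x", rank = "genus",
        counts = c("10" = 100), taxnames = "A", unclassified = 0,
        dropped = 0, total = 100), totalReads = 50), "smaller")
})

test_that("purity and classified fraction are invariant under read
           permutation within a group", {
  refset <- toyRefset()
  idx <- buildKmerIndex(refset)
  g <- simulateBarcodeGroup(refset, "spA1",
    simulationConfig(readsPerBarcodeRange = c(300L, 300L)), seed = 41,
    contamination = 0.3)
  perm <- sample(readPairCount(g))
  gp <- new("BarcodeGroup", barcodeId = g@barcodeId,
            mate1 = g@mate1[perm], mate2 = g@mate2[perm],
            qual1 = g@qual1[perm], qual2 = g@qual2[perm],
            batch = "single_cell", truth = NULL,
            truthHost = NA_character_, truthContamination = NA_real_)
  v1 <- groupsToVectors(list(g), idx)[[1]]
  v2 <- groupsToVectors(list(gp), idx)[[1]]
  expect_equal(v1@purity, v2@purity)
  expect_equal(v1@classifiedFraction, v2@classifiedFraction)
  expect_equal(v1@abundance, v2@abundance)
})

test_that("filterVectors applies inclusive thresholds per batch and logs
           reasons", {
  th <- filterThresholds()
  vs <- list(
    ok = mkVec("ok", c("10" = 0.8, "11" = 0.2) * 1000, total = 1000),
    lowPurity = mkVec("lowPurity", c("10" = 0.79, "11" = 0.21) * 1000,
                      total = 1000),
    lowReads = mkVec("lowReads", c("10" = 999), total = 999),
    lowClass = mkVec("lowClass", c("10" = 499), total = 1000),
    contigHi = mkVec("contigHi", c("10" = 0.95, "11" = 0.05) * 1000,
                     total = 1000, batch = "contig"),
    contigLo = mkVec("contigLo", c("10" = 0.85, "11" = 0.15) * 1000,
                     total = 1000, batch = "contig"))
  fl <- filterVectors(vs, th)
  kept <- vapply(fl$retained, function(v) v@unitId, character(1))
  expect_setequal(kept, c("ok", "contigHi"))
  expect_identical(fl$rejected$reason[fl$rejected$unit_id == "lowPurity"],
                   "purity")
  expect_identical(fl$rejected$reason[fl$rejected$unit_id == "lowReads"],
                   "read_count")
  expect_identical(fl$rejected$reason[fl$rejected$unit_id == "lowClass"],
                   "classified_fraction")
  # boundary: exactly at every default threshold is retained
  vb <- mkVec("b", c("10" = 0.8, "11" = 0.2) * 500, total = 1000)
  expect_length(filterVectors(list(vb), th)$retained, 1)
})

test_that("filter retention is monotone non-increasing in each threshold", {
  set.seed(5)
  vs <- lapply(1:50, function(i) {
    p <- runif(1, 0.5, 1)
    mkVec(paste0("u", i), c("10" = p, "11" = 1 - p) * 2000,
          total = round(2000 / runif(1, 0.5, 1)))
  })
  for (grid in list(
    lapply(seq(0, 1, 0.25), function(x) filterThresholds(minPurity = x)),
    lapply(seq(0, 3000, 750), function(x) filterThresholds(minReads = x)),
    lapply(seq(0, 1, 0.25), function(x)
      filterThresholds(minClassifiedFraction = x)))) {
    counts <- vapply(grid, function(th)
      length(filterVectors(vs, th)$retained), integer(1))
    expect_true(all(diff(counts) <= 0))
  }
})

test_that("assembleMatrix unions taxa, keeps order and row sums", {
  v1 <- mkVec("a", c("10" = 500), names = "A")
  v2 <- mkVec("b", c("11" = 400), names = "B")
  sce <- assembleMatrix(list(v1, v2))
  m <- SummarizedExperiment::assay(sce, "abundance")
  expect_identical(dim(m), c(2L, 2L))
  expect_equal(unname(t(m)), matrix(c(1, 0, 0, 1), 2, byrow = TRUE))
  expect_identical(colnames(m), c("a", "b"))
  sce2 <- assembleMatrix(list(v1, v2))
  expect_identical(SummarizedExperiment::assay(sce2), m)
  v3 <- mkVec("c", c("10" = 300, "12" = 100), names = c("A", "C"))
  m3 <- SummarizedExperiment::assay(assembleMatrix(list(v1, v2, v3)))
  expect_equal(unname(colSums(m3)), c(1, 1, 1))
  expect_error(assembleMatrix(list(v1, mkVec("d", c("10" = 1),
                                             rank = "species"))),
               "different ranks")
})

test_that("embedCluster separates one-hot populations, is deterministic,
           and collapses degenerate input", {
  vs <- list()
  for (g in 1:6) for (i in 1:20) {
    ab <- setNames(1, as.character(g))
    vs[[paste0("g", g, "_", i)]] <- mkVec(paste0("g", g, "_", i), ab * 1000,
                                          names = paste0("Genus", g))
  }
  sce <- embedCluster(assembleMatrix(vs), seed = 1)
  cl <- SummarizedExperiment::colData(sce)$cluster
  expect_identical(length(unique(cl)), 6L)
  truthLab <- rep(1:6, each = 20)
  expect_equal(mclust::adjustedRandIndex(cl, truthLab), 1.0)
  sce2 <- embedCluster(assembleMatrix(vs), seed = 1)
  expect_identical(SummarizedExperiment::colData(sce2)$cluster, cl)
  expect_identical(SingleCellExperiment::reducedDim(sce2, "UMAP"),
                   SingleCellExperiment::reducedDim(sce, "UMAP"))
  # identical rows -> one cluster
  same <- lapply(1:5, function(i) mkVec(paste0("s", i), c("10" = 1000)))
  sceD <- embedCluster(assembleMatrix(same), seed = 1)
  expect_identical(length(unique(SummarizedExperiment::colData(sceD)$cluster)),
                   1L)
  expect_error(embedCluster(assembleMatrix(same[1])), "at least 2")
})

test_that("annotateClusters assigns dominant taxa and modal cluster labels
           with lexicographic ties", {
  vs <- list(mkVec("u1", c("10" = 900, "11" = 100), names = c("A", "B")),
             mkVec("u2", c("10" = 800, "11" = 200), names = c("A", "B")),
             mkVec("u3", c("10" = 400, "11" = 600), names = c("A", "B")),
             mkVec("u4", c("10" = 500, "11" = 500), names = c("A", "B")))
  sce <- assembleMatrix(vs)
  SummarizedExperiment::colData(sce)$cluster <- factor(c(1, 1, 1, 2))
  sce <- annotateClusters(sce)
  cd <- SummarizedExperiment::colData(sce)
  expect_identical(cd$annotation, c("A", "A", "B", "A"))
  expect_identical(cd$annotationTie, c(FALSE, FALSE, FALSE, TRUE))
  # cluster 1 units annotated {A, A, B} -> modal annotation A
  expect_identical(unique(cd$clusterAnnotation[cd$cluster == 1]), "A")
})

test_that("integrateContigs filters contigs by purity then concatenates", {
  cells <- lapply(1:10, function(i)
    mkVec(paste0("c", i), c("10" = 900, "11" = 100)))
  contigs <- c(
    lapply(1:3, function(i)
      mkVec(paste0("ctg_hi", i), c("10" = 950, "11" = 50),
            batch = "contig")),
    lapply(1:2, function(i)
      mkVec(paste0("ctg_lo", i), c("10" = 850, "11" = 150),
            batch = "contig")))
  sce <- integrateContigs(cells, contigs, contigMinPurity = 0.9)
  expect_identical(ncol(sce), 13L)  # 10 cells + 3 contigs at >= 0.9
  expect_identical(sum(SummarizedExperiment::colData(sce)$batch == "contig"),
                   3L)
  # boundary 0.9 retained
  b <- mkVec("ctg_b", c("10" = 900, "11" = 100), batch = "contig")
  expect_identical(ncol(integrateContigs(cells, list(b))), 11L)
  # zero passing contigs -> cell-only matrix
  none <- integrateContigs(cells, list(mkVec("x", c("10" = 500, "11" = 500),
                                             batch = "contig")))
  expect_identical(ncol(none), 10L)
})

test_that("subcluster splits a two-species genus cluster at species rank", {
  vs <- list()
  for (sp in 1:2) for (i in 1:15) {
    id <- paste0("sp", sp, "_", i)
    vs[[id]] <- mkVec(id, setNames(1000, as.character(1000 + sp)),
                      names = paste0("Species", sp), rank = "species")
  }
  sub <- subcluster(vs, names(vs), seed = 1)
  cl <- SummarizedExperiment::colData(sub)$cluster
  expect_identical(length(unique(cl)), 2L)
  expect_equal(mclust::adjustedRandIndex(cl, rep(1:2, each = 15)), 1.0)
  sub2 <- subcluster(vs, names(vs), seed = 1)
  expect_identical(SummarizedExperiment::colData(sub2)$cluster, cl)
  expect_error(subcluster(vs, "sp1_1"), "at least 2")
})

test_that("evaluateBenchmark counts identification accuracy exactly", {
  tax <- toyTaxonomy()
  vs <- list(mkVec("u1", c("10" = 1000), names = "GenusA"),
             mkVec("u2", c("10" = 1000), names = "GenusA"),
             mkVec("u3", c("11" = 1000), names = "GenusB"),
             mkVec("u4", c("10" = 1000), names = "GenusA"))
  sce <- assembleMatrix(vs)
  SummarizedExperiment::colData(sce)$cluster <- factor(rep(1, 4))
  sce <- annotateClusters(sce)
  truth <- data.frame(barcode_id = paste0("u", 1:4),
                      host_taxid = c(100L, 100L, 100L, 100L))
  rep <- evaluateBenchmark(sce, vs, truth, tax)
  expect_equal(rep$identificationAccuracy, 0.75)
  expect_true(all(diff(rep$retentionCurve$retained) <= 0))
  expect_error(evaluateBenchmark(sce, vs,
    data.frame(barcode_id = "u1", host_taxid = 100L), tax), "missing")
})
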