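mkGroup <- function(id, n) {
  new("BarcodeGroup", barcodeId = id,
      mate1 = rep(strrep("A", 20), n), mate2 = rep(strrep("C", 20), n),
      qual1 = rep(strrep("I", 20), n), qual2 = rep(strrep("I", 20), n),
      batch = "single_cell", truth = NULL, truthHost = NA_character_,
      truthContamination = NA_real_)
}

test_that("poolClusters conserves reads with stable ordering", {
  groups <- list(b1 = mkGroup("b1", 100), b2 = mkGroup("b2", 100),
                 b3 = mkGroup("b3", 100), b4 = mkGroup("b4", 50))
  labels <- c(b1 = 1, b2 = 1, b3 = 1, b4 = 2)
  pooled <- poolClusters(groups, labels)
  expect_identical(readPairCount(pooled[["1"]]), 300L)
  expect_identical(sum(vapply(pooled, readPairCount, integer(1))), 350L)
  pooled2 <- poolClusters(groups[c(3, 1, 4, 2)], labels)
  expect_identical(pooled2[["1"]]@mate1, pooled[["1"]]@mate1)
  expect_error(poolClusters(groups, labels[1:3]), "unlabeled")
})

test_that("coverageStats does half-open interval arithmetic", {
  cs <- coverageStats(1, 400, 10000)
  expect_equal(cs$coveredFraction, 0.04)
  expect_equal(cs$meanDepth, 0.04)
  expect_equal(coverageStats(integer(0), integer(0), 1000),
               list(coveredFraction = 0, meanDepth = 0))
  # duplicate placement: coverage unchanged, depth doubled
  cs2 <- coverageStats(c(1, 1), c(400, 400), 10000)
  expect_equal(cs2$coveredFraction, 0.04)
  expect_equal(cs2$meanDepth, 0.08)
  # overlap is merged
  cs3 <- coverageStats(c(1, 201), c(400, 400), 10000)
  expect_equal(cs3$coveredFraction, 0.06)
  expect_error(coverageStats(9800, 400, 10000), "beyond")
})

test_that("rarefaction is cumulative, non-decreasing and hits the full
           coverage at its endpoint", {
  set.seed(71)
  pl <- data.frame(start = sample(1:9000, 500, replace = TRUE), len = 150)
  rc <- rarefaction(pl, 10000, nTotal = 10000, nPoints = 10, seed = 1)
  expect_true(all(diff(rc$coveredFraction) >= 0))
  full <- coverageStats(pl$start, pl$len, 10000)$coveredFraction
  expect_equal(rc$coveredFraction[nrow(rc)], full)
  # two seeds agree exactly at the endpoint
  rc2 <- rarefaction(pl, 10000, nTotal = 10000, nPoints = 10, seed = 2)
  expect_equal(rc2$coveredFraction[nrow(rc2)], full)
  expect_identical(formals(rarefaction)$nTotal, 10000L)
})

test_that("clusterErrorRate counts foreign reads in both modes", {
  tax <- toyTaxonomy()
  expect_equal(clusterErrorRate(rep(c(100L, 101L), c(90, 0)), 100L, tax), 0)
  expect_equal(clusterErrorRate(c(rep(100L, 90), rep(110L, 10)), 100L, tax),
               0.1)
  expect_equal(clusterErrorRate(rep(110L, 20), 100L, tax), 1)
  # same-genus species are not errors at genus rank
  expect_equal(clusterErrorRate(c(rep(100L, 50), rep(101L, 50)), 100L, tax),
               0)
  expect_equal(clusterErrorRate(c(TRUE, TRUE, FALSE, TRUE)), 0.25)
})

test_that("filterGeneMatrix drops sparse genes then sparse cells, in that
           order", {
  set.seed(72)
  mat <- matrix(1, 20, 12, dimnames = list(paste0("c", 1:20),
                                           paste0("g", 1:12)))
  expect_identical(filterGeneMatrix(mat), mat)
  mat2 <- mat[, 1:5]
  mat2[4:20, 3] <- 0  # gene g3 present in only 3 cells
  out <- filterGeneMatrix(mat2, 10, 4)
  expect_false("g3" %in% colnames(out))
  expect_identical(nrow(out), 20L)
  # cells falling under the gene minimum after gene removal are dropped
  mat3 <- matrix(0, 12, 12, dimnames = list(paste0("c", 1:12),
                                            paste0("g", 1:12)))
  mat3[1:11, 1:11] <- 1
  mat3[12, 12] <- 1
  out3 <- filterGeneMatrix(mat3, 10, 10)
  expect_identical(dim(out3), c(11L, 11L))
  expect_identical(formals(filterGeneMatrix)$minCellsPerGene, 10L)
})

test_that("subclusterGenes separates disjoint gene blocks and is
           deterministic", {
  mat <- matrix(0, 30, 40, dimnames = list(paste0("c", 1:30), NULL))
  mat[1:15, 1:20] <- 1
  mat[16:30, 21:40] <- 1
  cl <- subclusterGenes(mat, seed = 1)
  expect_identical(length(unique(cl)), 2L)
  expect_equal(mclust::adjustedRandIndex(cl, rep(1:2, each = 15)), 1.0)
  expect_identical(subclusterGenes(mat, seed = 1), cl)
  same <- matrix(1, 6, 10, dimnames = list(paste0("c", 1:6), NULL))
  expect_identical(length(unique(subclusterGenes(same, seed = 1))), 1L)
})

test_that("countFeatureHits filters by MAPQ, deduplicates and computes RPM", {
  rec <- data.frame(
    feature_id = c(rep("X", 6), "Y"),
    mapq = c(42, 42, 42, 42, 42, 42, 30),
    position = c(1, 2, 3, 4, 5, 5, 1))  # one duplicate position on X
  out <- countFeatureHits(rec, 42, 2e6)
  expect_identical(out$feature_id, "X")
  expect_identical(out$hits, 5L)
  expect_equal(out$rpm, 2.5)
  # below-threshold records vanish
  expect_identical(nrow(countFeatureHits(
    data.frame(feature_id = "X", mapq = 30, position = 1), 42, 1e6)), 0L)
  # order invariance
  out2 <- countFeatureHits(rec[sample(nrow(rec)), ], 42, 2e6)
  expect_identical(out2, out)
})

test_that("dropletOccupancy reproduces binomial loading arithmetic and
           approaches Poisson", {
  occ <- dropletOccupancy(0.02, 5, "binomial")
  expect_equal(occ$pOccupied, 1 - 0.98^5, tolerance = 1e-12)
  expect_equal(occ$p1, 5 * 0.02 * 0.98^4, tolerance = 1e-12)
  expect_equal(sum(occ$distribution), 1, tolerance = 1e-12)
  expect_equal(dropletOccupancy(0, 5)$p0, 1)
  # binomial -> Poisson convergence at fixed lambda
  lam <- 0.1
  bin <- dropletOccupancy(lam / 1e4, 1e4, "binomial")$distribution
  poi <- dropletOccupancy(lam / 1e4, 1e4, "poisson")$distribution
  k <- seq_len(min(length(bin), length(poi)))
  expect_lt(max(abs(bin[k] - poi[k])), 1e-3)
  for (p in c(0.01, 0.02, 0.5)) for (n in c(1L, 5L, 20L))
    expect_equal(sum(dropletOccupancy(p, n)$distribution), 1,
                 tolerance = 1e-12)
  expect_error(dropletOccupancy(-0.1), "loadRate")
})

test_that("readSamSubset extracts the minimal field set with NM tags", {
  sam <- tempfile(fileext = ".sam")
  writeLines(c(
    "@HD\tVN:1.6",
    "@SQ\tSN:ref1\tLN:10000",
    paste("r1", "0", "ref1", "100", "42", "150M", "*", "0", "0",
          strrep("A", 150), strrep("I", 150), "NM:i:0", sep = "\t"),
    paste("r2", "4", "*", "0", "0", "*", "*", "0", "0",
          strrep("A", 50), strrep("I", 50), sep = "\t")), sam)
  df <- readSamSubset(sam)
  expect_identical(df$qname, c("r1", "r2"))
  expect_identical(df$nm, c(0L, NA_integer_))
  expect_true(is.na(df$rname[2]))
  expect_identical(df$mapq[1], 42L)
  expect_identical(df$seqlen, c(150L, 50L))
  bad <- tempfile(); writeLines("r1\t0\tref", bad)
  expect_error(readSamSubset(bad), "malformed")
})
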