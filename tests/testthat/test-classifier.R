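test_that("buildKmerIndex stores unique k-mers under their genome taxid and
           shared k-mers under the LCA", {
  tax <- toyTaxonomy()
  # two same-genus genomes sharing a block, plus a distinct genus-B genome
  shared <- generateGenome(60, seed = 1)
  a1 <- paste0(generateGenome(60, seed = 2), shared)
  a2 <- paste0(generateGenome(60, seed = 3), shared)
  b1 <- generateGenome(120, seed = 4)
  refset <- referenceSet(c(spA1 = a1, spA2 = a2, spB1 = b1),
                         c(spA1 = 100L, spA2 = 101L, spB1 = 110L), tax)
  idx <- buildKmerIndex(refset, k = 21L)
  kmA1only <- substring(a1, 1, 21)
  expect_identical(kmerLookup(idx, kmA1only), 100L)
  kmShared <- substring(shared, 1, 21)
  expect_identical(kmerLookup(idx, kmShared), 10L)  # LCA of spA1, spA2
  # canonicalization: reverse complement queries the same entry
  expect_identical(kmerLookup(idx, oracleRevcomp(kmShared)), 10L)
  expect_true(is.na(kmerLookup(idx, strrep("A", 21))) ||
              kmerLookup(idx, strrep("A", 21)) %in% tax@taxid)
  expect_error(buildKmerIndex(refset, k = 20L), "odd")
})

test_that("adding a genome never deepens an existing k-mer entry", {
  tax <- toyTaxonomy()
  g1 <- generateGenome(2000, seed = 5)
  g2 <- generateGenome(2000, seed = 6)
  r1 <- referenceSet(c(spA1 = g1), c(spA1 = 100L), tax)
  r2 <- referenceSet(c(spA1 = g1, spA2 = paste0(g2, substring(g1, 1, 500))),
                     c(spA1 = 100L, spA2 = 101L), tax)
  i1 <- buildKmerIndex(r1); i2 <- buildKmerIndex(r2)
  kms <- substring(g1, seq(1, 1900, by = 37), seq(21, 1920, by = 37))
  depth <- function(t) if (is.na(t)) NA_integer_
                       else length(oracleRootPath(tax, t))
  d1 <- vapply(kmerLookup(i1, kms), depth, integer(1))
  d2 <- vapply(kmerLookup(i2, kms), depth, integer(1))
  expect_true(all(d2 <= d1))
})

test_that("classifyReads handles unique, shared and unindexed content", {
  refset <- toyRefset()
  idx <- buildKmerIndex(refset)
  gA1 <- as.character(genomeSequences(refset, "spA1")[[1]])
  read <- substring(gA1, 101, 250)
  expect_identical(classifyReads(idx, read), 100L)
  # no indexed k-mer -> unclassified
  expect_true(is.na(classifyReads(idx, strrep("A", 150))))
  # a read made only of genus-shared k-mers resolves to the genus node
  tax <- toyTaxonomy()
  shared <- generateGenome(150, seed = 7)
  refShared <- referenceSet(
    c(spA1 = paste0(generateGenome(500, seed = 8), shared),
      spA2 = paste0(generateGenome(500, seed = 9), shared)),
    c(spA1 = 100L, spA2 = 101L), tax)
  idxS <- buildKmerIndex(refShared)
  expect_identical(classifyReads(idxS, shared), 10L)
})

test_that("classifyReads matches the brute-force path-score oracle on a
           simulated toy dataset", {
  refset <- toyRefset(genomeLength = 4000L, seed = 10)
  idx <- buildKmerIndex(refset, k = 21L)
  table <- oracleKmerTable(refset, 21L)
  tax <- refset@taxonomy
  cfg <- simulationConfig(readsPerBarcodeRange = c(120L, 120L),
                          ampliconRange = c(400L, 800L),
                          contaminationRange = c(0.2, 0.4),
                          substitutionErrorRate = 0.005)
  for (host in genomeIds(refset)) {
    g <- simulateBarcodeGroup(refset, host, cfg, seed = match(host, genomeIds(refset)))
    got <- classifyReads(idx, g@mate1, g@mate2)
    expected <- vapply(seq_len(readPairCount(g)), function(i)
      oracleClassify(g@mate1[i], g@mate2[i], table, tax, 21L), integer(1))
    expect_identical(got, expected)
  }
})

test_that("classifyGroup aggregates with conservation and reflects
           contamination", {
  refset <- toyRefset()
  idx <- buildKmerIndex(refset)
  g <- simulateBarcodeGroup(refset, "spA1",
    simulationConfig(readsPerBarcodeRange = c(1000L, 1000L)),
    seed = 11, contamination = 0.25)
  tc <- classifyGroup(g, idx)
  expect_equal(sum(tc@counts) + tc@unclassified, tc@total)
  expect_equal(tc@total, 1000)
  # ~25% of classified reads fall outside spA1's subtree
  inA1 <- sum(tc@counts[names(tc@counts) %in% c("100")])
  expect_lt(abs((1 - inA1 / sum(tc@counts)) - 0.25), 0.05)
  empty <- new("BarcodeGroup", barcodeId = "e", mate1 = character(0),
               mate2 = character(0), qual1 = character(0),
               qual2 = character(0), batch = "single_cell", truth = NULL,
               truthHost = NA_character_, truthContamination = NA_real_)
  tcE <- classifyGroup(empty, idx)
  expect_identical(tcE@total, 0)
})

test_that("redistributeToRank lifts, splits proportionally and falls back
           to uniform", {
  tax <- toyTaxonomy()
  # lift only
  ra <- redistributeToRank(taxonCounts("x", c("100" = 300, "101" = 100)),
                           tax, "genus")
  expect_equal(ra@counts, c("10" = 400))
  # proportional split of an above-rank count
  ra2 <- redistributeToRank(
    taxonCounts("x", c("100" = 300, "110" = 100, "2" = 100)), tax, "genus")
  expect_equal(ra2@counts[["10"]], 375)
  expect_equal(ra2@counts[["11"]], 125)
  # uniform fallback when no rank-level counts exist
  ra3 <- redistributeToRank(taxonCounts("x", c("2" = 50)), tax, "genus")
  expect_equal(unname(ra3@counts[c("10", "11")]), c(25, 25))
  # a node with no rank-level node on or below its path drops its reads
  tax2 <- taxonomyFromDataFrame(data.frame(
    taxid = c(1L, 2L, 10L, 12L, 100L),
    parent_taxid = c(1L, 1L, 2L, 2L, 10L),
    rank = c("root", "superkingdom", "genus", "genus", "species"),
    name = c("root", "Bacteria", "GenusA", "GenusC", "spA1")))
  ra4 <- redistributeToRank(taxonCounts("x", c("12" = 10, "100" = 5)),
                            tax2, "species")
  expect_equal(ra4@dropped, 10)
  expect_equal(ra4@counts, c("100" = 5))
})

test_that("redistribution conserves classified reads on random toy
           instances", {
  tax <- toyTaxonomy()
  set.seed(99)
  for (i in 1:300) {
    nodes <- sample(tax@taxid, sample(1:7, 1))
    counts <- setNames(as.numeric(sample(0:50, length(nodes), replace = TRUE)),
                       nodes)
    counts <- counts[counts > 0]
    if (length(counts) == 0) next
    tc <- taxonCounts("r", counts, unclassified = sample(0:10, 1))
    rank <- sample(c("genus", "species"), 1)
    ra <- redistributeToRank(tc, tax, rank)
    expect_equal(sum(ra@counts) + ra@dropped, sum(tc@counts),
                 tolerance = 1e-9)
  }
})

test_that("importExternalReport parses both report dialects", {
  rep <- tempfile(fileext = ".txt")
  writeLines(c(
    "10.00\t10\t10\tU\t0\tunclassified",
    "90.00\t100\t0\tR\t1\troot",
    "81.00\t90\t0\tG\t10\t  GenusA",
    "9.00\t10\t0\tG\t11\t  GenusB"), rep)
  ra <- importExternalReport(rep, "kraken2_report", rank = "genus")
  expect_equal(ra@counts, c("10" = 90, "11" = 10))
  expect_identical(ra@taxnames, c("GenusA", "GenusB"))
  expect_equal(ra@unclassified, 10)

  empty <- tempfile(); file.create(empty)
  raE <- importExternalReport(empty, "kraken2_report")
  expect_length(raE@counts, 0)

  br <- tempfile(fileext = ".tsv")
  writeLines(c(
    paste("name", "taxonomy_id", "taxonomy_lvl", "kraken_assigned_reads",
          "added_reads", "new_est_reads", "fraction_total_reads", sep = "\t"),
    paste("GenusA", "10", "G", "80", "10", "90", "0.9", sep = "\t"),
    paste("GenusB", "11", "G", "8", "2", "10", "0.1", sep = "\t")), br)
  raB <- importExternalReport(br, "bracken_tsv", rank = "genus")
  expect_equal(raB@counts, c("10" = 90, "11" = 10))

  bad <- tempfile(); writeLines("only\tthree\tfields", bad)
  expect_error(importExternalReport(bad, "kraken2_report"), "line 1")
})
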