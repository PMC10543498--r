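# Shared fixtures and independent oracle implementations. Oracles are kept
# deliberately naive (path enumeration, brute-force scans, plain EM) so they
# exercise none of the package's optimised code paths.

# Toy taxonomy: root=1 -> Bacteria=2 -> GenusA=10 -> {spA1=100, spA2=101},
#                                       GenusB=11 -> {spB1=110}
toyTaxonomy <- function() {
  taxonomyFromDataFrame(data.frame(
    taxid = c(1L, 2L, 10L, 11L, 100L, 101L, 110L),
    parent_taxid = c(1L, 1L, 2L, 2L, 10L, 10L, 11L),
    rank = c("root", "superkingdom", "genus", "genus",
             "species", "species", "species"),
    name = c("root", "Bacteria", "GenusA", "GenusB",
             "spA1", "spA2", "spB1")))
}

toyRefset <- function(genomeLength = 20000L, seed = 42L) {
  tax <- toyTaxonomy()
  genomes <- setNames(
    vapply(1:3, function(i) generateGenome(genomeLength, seed = seed + i),
           character(1)),
    c("spA1", "spA2", "spB1"))
  referenceSet(genomes, c(spA1 = 100L, spA2 = 101L, spB1 = 110L), tax)
}

# Root path of a taxid by naive parent walking on the node table.
oracleRootPath <- function(tax, t) {
  path <- integer()
  repeat {
    path <- c(path, t)
    p <- tax@parent[match(t, tax@taxid)]
    if (p == t) break
    t <- p
  }
  path
}

# LCA by intersecting root paths (deepest common element).
oracleLca <- function(tax, a, b) {
  intersect(oracleRootPath(tax, a), oracleRootPath(tax, b))[1]
}

oracleRevcomp <- function(x)
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))

# Brute-force canonical k-mer -> LCA table from a reference set, built with
# vectorised substring enumeration (no native code).
oracleKmerTable <- function(refset, k) {
  mc <- S4Vectors::mcols(refset@sequences)
  tax <- refset@taxonomy
  all <- list()
  for (i in seq_along(refset@sequences)) {
    g <- as.character(refset@sequences[[i]])
    L <- nchar(g)
    km <- substring(g, 1:(L - k + 1), k:L)
    canon <- pmin(km, oracleRevcomp(km))
    all[[i]] <- data.frame(kmer = canon, taxid = mc$taxid[i])
  }
  df <- unique(do.call(rbind, all))
  tapply(df$taxid, df$kmer, function(tids) Reduce(function(a, b)
    oracleLca(tax, a, b), unique(tids)))
}

# Brute-force classification of one read pair: enumerate every k-mer of
# both mates, look each up, then score every root-to-leaf path.
oracleClassify <- function(mate1, mate2, table, tax, k) {
  kmers <- character(0)
  for (s in c(mate1, mate2)) {
    L <- nchar(s)
    if (L >= k) kmers <- c(kmers, substring(s, 1:(L - k + 1), k:L))
  }
  canon <- pmin(kmers, oracleRevcomp(kmers))
  hits <- table[canon]
  hits <- hits[!is.na(hits)]
  if (length(hits) == 0) return(NA_integer_)
  counts <- tapply(rep(1, length(hits)), hits, sum)
  leaves <- taxonomyLeaves(tax)
  scores <- vapply(leaves, function(leaf) {
    path <- oracleRootPath(tax, leaf)
    sum(counts[as.character(path)], na.rm = TRUE)
  }, numeric(1))
  best <- leaves[scores == max(scores)]
  Reduce(function(a, b) oracleLca(tax, a, b), best)
}

# Plain EM for the read mixture model (uniform prior, fixed iterations).
oracleEm <- function(L, iters = 10000L) {
  K <- ncol(L)
  theta <- rep(1 / K, K)
  for (i in seq_len(iters)) {
    R <- sweep(L, 2, theta, "*")
    R <- R / rowSums(R)
    theta <- colMeans(R)
  }
  theta
}

# Merge two simulated groups into one artificial doublet group.
mergeGroups <- function(a, b, barcodeId = "doublet") {
  new("BarcodeGroup", barcodeId = barcodeId,
      mate1 = c(a@mate1, b@mate1), mate2 = c(a@mate2, b@mate2),
      qual1 = c(a@qual1, b@qual1), qual2 = c(a@qual2, b@qual2),
      batch = "single_cell", truth = NULL,
      truthHost = NA_character_, truthContamination = NA_real_)
}

# Strain community fixture: panel genomes wrapped as a ReferenceSet (one
# genus, one species per strain) so the simulator can generate reads.
strainRefset <- function(genomes) {
  n <- length(genomes)
  tax <- taxonomyFromDataFrame(data.frame(
    taxid = c(1L, 2L, 10L, 100L + seq_len(n)),
    parent_taxid = c(1L, 1L, 2L, rep(10L, n)),
    rank = c("root", "superkingdom", "genus", rep("species", n)),
    name = c("root", "Bacteria", "GenusS", names(genomes))))
  referenceSet(genomes, setNames(100L + seq_len(n), names(genomes)), tax)
}
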