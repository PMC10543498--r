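# Self-contained k-mer LCA read classification and Bracken-style
# redistribution of classified counts to a target rank, plus importers for
# reports produced by external classifiers.

#' Canonical k-mer LCA index
#'
#' Maps every canonical k-mer (a k-mer and its reverse complement share one
#' entry) of the reference genomes to the LCA of all genomes containing it.
#' The index lives in native memory and is rebuilt, not serialised.
#'
#' @slot ptr external pointer to the native index.
#' @slot k k-mer size.
#' @slot taxonomy the [Taxonomy-class] used for LCA computation.
#' @export
setClass("KmerIndex",
  representation(ptr = "externalptr", k = "integer", taxonomy = "Taxonomy"))

setMethod("show", "KmerIndex", function(object) {
  cat(sprintf("KmerIndex: k = %d, %s canonical k-mer(s)\n", object@k,
              format(cpp_kmer_index_size(object@ptr), big.mark = ",")))
})

#' Build a canonical k-mer LCA index from a reference set
#'
#' Every k-mer of every genome is indexed under the LCA of the taxids of all
#' genomes containing it. Plain exact canonical k-mer lookup; no minimizers,
#' spaced seeds or confidence thresholds.
#'
#' @param refset a [ReferenceSet-class].
#' @param k odd k-mer size between 11 and 31 (default 21).
#' @return a [KmerIndex-class].
#' @export
buildKmerIndex <- function(refset, k = 21L) {
  k <- as.integer(k)
  if (k %% 2 == 0 || k < 11 || k > 31)
    stop("k must be odd and in [11, 31]")
  mc <- S4Vectors::mcols(refset@sequences)
  tax <- refset@taxonomy
  ptr <- cpp_kmer_index_build(as.character(refset@sequences),
                              as.integer(mc$taxid), k,
                              tax@taxid, tax@parent, tax@root)
  new("KmerIndex", ptr = ptr, k = k, taxonomy = tax)
}

#' Number of k-mers stored in an index
#' @param index a [KmerIndex-class].
#' @return numeric count of distinct canonical k-mers.
#' @export
kmerIndexSize <- function(index) cpp_kmer_index_size(index@ptr)

#' Look up k-mers in the index
#' @param index a [KmerIndex-class].
#' @param kmers character vector of k-length sequences.
#' @return integer taxids (`NA` for absent k-mers).
#' @export
kmerLookup <- function(index, kmers) cpp_kmer_lookup(index@ptr, kmers)

#' Classify read pairs against a k-mer index
#'
#' K-mer hits from both mates are pooled into one hit multiset. Every
#' root-to-leaf path of the taxonomy is scored by the summed hit counts of
#' its nodes; the read is assigned to the leaf-most node of the best path,
#' with ties between paths resolved by taking the LCA of their terminal
#' nodes. A read pair with no indexed k-mer is unclassified (`NA`).
#'
#' @param index a [KmerIndex-class].
#' @param mate1 character vector of read sequences.
#' @param mate2 optional character vector of mate-2 sequences.
#' @return integer vector of assigned taxids (`NA` = unclassified).
#' @export
classifyReads <- function(index, mate1, mate2 = character(0)) {
  if (length(mate2) > 0 && length(mate2) != length(mate1))
    stop("mate1/mate2 length mismatch")
  cpp_classify_pairs(index@ptr, mate1, mate2)
}

#' Per-barcode taxon counts
#'
#' Direct read counts at the node where each read was assigned, before any
#' rank redistribution. `sum(counts) + unclassified == total`.
#'
#' @slot barcodeId group identifier.
#' @slot counts numeric vector of direct read counts, named by taxid.
#' @slot unclassified count of unclassified reads.
#' @slot total total reads in the group.
#' @export
setClass("TaxonCounts",
  representation(barcodeId = "character", counts = "numeric",
                 unclassified = "numeric", total = "numeric"))

setValidity("TaxonCounts", function(object) {
  if (any(object@counts < 0) || object@unclassified < 0)
    return("negative counts")
  if (abs(sum(object@counts) + object@unclassified - object@total) > 1e-8)
    return("counts + unclassified must equal total")
  TRUE
})

setMethod("show", "TaxonCounts", function(object) {
  cat(sprintf("TaxonCounts %s: %d taxa, %g classified + %g unclassified of %g reads\n",
              object@barcodeId, length(object@counts), sum(object@counts),
              object@unclassified, object@total))
})

#' Construct TaxonCounts
#' @param barcodeId group id.
#' @param counts numeric vector named by taxid.
#' @param unclassified unclassified read count.
#' @return a [TaxonCounts-class].
#' @export
taxonCounts <- function(barcodeId, counts, unclassified = 0) {
  obj <- new("TaxonCounts", barcodeId = barcodeId,
             counts = counts, unclassified = as.numeric(unclassified),
             total = sum(counts) + unclassified)
  validObject(obj)
  obj
}

#' Classify all reads of a barcode group
#'
#' @param group a [BarcodeGroup-class].
#' @param index a [KmerIndex-class].
#' @return a [TaxonCounts-class].
#' @export
classifyGroup <- function(group, index) {
  if (readPairCount(group) == 0)
    return(taxonCounts(group@barcodeId, setNames(numeric(0), character(0)), 0))
  tx <- classifyReads(index, group@mate1, group@mate2)
  tab <- table(tx, useNA = "no")
  taxonCounts(group@barcodeId,
              setNames(as.numeric(tab), names(tab)),
              unclassified = sum(is.na(tx)))
}

#' Rank-level abundance of a barcode group
#'
#' Read counts after redistribution to a fixed rank. Counts can be
#' fractional (proportional redistribution splits reads).
#'
#' @slot barcodeId group identifier.
#' @slot rank rank label.
#' @slot counts numeric vector named by taxid-at-rank.
#' @slot taxnames character vector of taxon names, parallel to `counts`.
#' @slot unclassified reads not classified at all.
#' @slot dropped classified reads on paths with no node at `rank`.
#' @slot total total reads in the group.
#' @export
setClass("RankAbundance",
  representation(barcodeId = "character", rank = "character",
                 counts = "numeric", taxnames = "character",
                 unclassified = "numeric", dropped = "numeric",
                 total = "numeric"))

setValidity("RankAbundance", function(object) {
  if (any(object@counts < 0)) return("negative counts")
  if (length(object@taxnames) != length(object@counts))
    return("taxnames/counts length mismatch")
  TRUE
})

setMethod("show", "RankAbundance", function(object) {
  cat(sprintf("RankAbundance %s at %s: %d taxa, %g reads at rank (%g dropped, %g unclassified)\n",
              object@barcodeId, object@rank, length(object@counts),
              sum(object@counts), object@dropped, object@unclassified))
})

#' Reads attributed to the rank (after redistribution)
#' @param x a [RankAbundance-class].
#' @return numeric scalar.
#' @export
classifiedAtRank <- function(x) sum(x@counts)

#' Redistribute direct taxon counts to a target rank
#'
#' Reads assigned at or below the rank are lifted to their rank-level
#' ancestor. Reads assigned above the rank are redistributed among the
#' node's rank-level descendants proportionally to those descendants'
#' already-lifted counts, or uniformly when all lifted counts are zero.
#' Reads whose root path contains no node at the rank are dropped from the
#' profile. Lifted + redistributed + dropped equals the classified total.
#'
#' @param counts a [TaxonCounts-class].
#' @param taxonomy a [Taxonomy-class].
#' @param rank target rank label (default `"genus"`).
#' @return a [RankAbundance-class].
#' @export
redistributeToRank <- function(counts, taxonomy, rank = "genus") {
  if (!rank %in% TAX_RANKS) stop("unknown rank: ", rank)
  tids <- as.integer(names(counts@counts))
  .taxCheck(taxonomy, tids)
  lifted <- numeric(0)
  above <- list()
  dropped <- 0
  for (i in seq_along(tids)) {
    a <- ancestorAtRank(taxonomy, tids[i], rank)
    if (!is.na(a)) {
      key <- as.character(a)
      lifted[key] <- (if (key %in% names(lifted)) lifted[key] else 0) +
        counts@counts[i]
    } else {
      d <- descendantsAtRank(taxonomy, tids[i], rank)
      if (length(d) == 0) dropped <- dropped + unname(counts@counts[i])
      else above[[length(above) + 1L]] <- list(n = counts@counts[i], desc = d)
    }
  }
  redist <- lifted
  for (ab in above) {
    keys <- as.character(ab$desc)
    w <- vapply(keys, function(k)
      if (k %in% names(lifted)) lifted[[k]] else 0, numeric(1))
    if (sum(w) == 0) w <- rep(1, length(w))
    add <- ab$n * w / sum(w)
    for (j in seq_along(keys)) {
      k <- keys[j]
      redist[k] <- (if (k %in% names(redist)) redist[[k]] else 0) + add[j]
    }
  }
  new("RankAbundance", barcodeId = counts@barcodeId, rank = rank,
      counts = redist,
      taxnames = taxonName(taxonomy, as.integer(names(redist))),
      unclassified = counts@unclassified, dropped = dropped,
      total = counts@total)
}

.KRAKEN_RANK_CODES <- c(root = "R", superkingdom = "D", phylum = "P",
                        class = "C", order = "O", family = "F",
                        genus = "G", species = "S", strain = "S1")

#' Import an external classifier report
#'
#' Parses a standard 6-column report (`percent`, `clade_reads`,
#' `direct_reads`, `rank_code`, `taxid`, two-space-indented `name`) or a
#' per-taxon abundance re-estimation TSV (counts taken from the
#' `new_est_reads` column) into a [RankAbundance-class], so downstream
#' clustering can run on real classifier output.
#'
#' @param path report file.
#' @param format `"kraken2_report"` or `"bracken_tsv"`.
#' @param rank rank to extract (default `"genus"`).
#' @param barcodeId id to attach (default the file name).
#' @return a [RankAbundance-class].
#' @export
importExternalReport <- function(path, format = c("kraken2_report",
                                                  "bracken_tsv"),
                                 rank = "genus",
                                 barcodeId = basename(path)) {
  format <- match.arg(format)
  if (!rank %in% TAX_RANKS) stop("unknown rank: ", rank)
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0)
    return(new("RankAbundance", barcodeId = barcodeId, rank = rank,
               counts = setNames(numeric(0), character(0)),
               taxnames = character(0), unclassified = 0, dropped = 0,
               total = 0))
  if (format == "kraken2_report") {
    fields <- strsplit(lines, "\t", fixed = TRUE)
    bad <- which(lengths(fields) != 6)
    if (length(bad) > 0)
      stop(sprintf("malformed report line %d: expected 6 tab-separated fields",
                   bad[1]))
    m <- do.call(rbind, fields)
    cladeReads <- suppressWarnings(as.numeric(m[, 2]))
    taxid <- suppressWarnings(as.integer(m[, 5]))
    if (anyNA(cladeReads) || anyNA(taxid))
      stop("non-numeric clade_reads or taxid in report")
    code <- m[, 4]
    name <- sub("^ +", "", m[, 6])
    unclassified <- sum(cladeReads[code == "U"])
    sel <- code == .KRAKEN_RANK_CODES[[rank]]
    counts <- setNames(cladeReads[sel], taxid[sel])
    total <- sum(cladeReads[code %in% c("U", "R")])
    new("RankAbundance", barcodeId = barcodeId, rank = rank, counts = counts,
        taxnames = name[sel], unclassified = unclassified,
        dropped = max(0, total - unclassified - sum(counts)), total = total)
  } else {
    df <- read.table(path, sep = "\t", header = TRUE,
                     stringsAsFactors = FALSE, quote = "")
    need <- c("name", "taxonomy_id", "new_est_reads")
    if (!all(need %in% colnames(df)))
      stop("bracken TSV must have columns: ", paste(need, collapse = ", "))
    if ("taxonomy_lvl" %in% colnames(df)) {
      sel <- df$taxonomy_lvl == .KRAKEN_RANK_CODES[[rank]]
      df <- df[sel, , drop = FALSE]
    }
    counts <- setNames(as.numeric(df$new_est_reads),
                       as.character(df$taxonomy_id))
    new("RankAbundance", barcodeId = barcodeId, rank = rank, counts = counts,
        taxnames = df$name, unclassified = 0, dropped = 0,
        total = sum(counts))
  }
}
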