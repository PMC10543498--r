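# Cell-barcode extraction, Hamming-distance-1 correction against a
# whitelist, and demultiplexing of paired FASTQ into barcode groups.

.checkWhitelist <- function(whitelist) {
  if (length(whitelist) == 0) stop("empty whitelist")
  L <- nchar(whitelist)
  if (length(unique(L)) != 1) stop("whitelist barcodes differ in length")
  if (anyDuplicated(whitelist)) stop("duplicated whitelist barcodes")
  if (any(grepl("[^ACGT]", whitelist))) stop("whitelist must be over ACGT")
  L[1]
}

#' Generate a random barcode whitelist
#'
#' Draws barcodes so that every pair is at Hamming distance of at least
#' `minDist` (3 by default, which makes distance-1 correction unambiguous).
#'
#' @param n number of barcodes.
#' @param length barcode length (default 8).
#' @param minDist minimum pairwise Hamming distance.
#' @param seed integer seed or `NULL`.
#' @return character vector of barcodes.
#' @export
makeWhitelist <- function(n, length = 8L, minDist = 3L, seed = NULL) {
  .withSeed(seed, {
    out <- character(0)
    tries <- 0L
    while (length(out) < n) {
      cand <- paste(sample(c("A", "C", "G", "T"), length, replace = TRUE),
                    collapse = "")
      if (all(.hammingTo(cand, out) >= minDist)) out <- c(out, cand)
      tries <- tries + 1L
      if (tries > 1000L * n)
        stop("cannot place ", n, " barcodes at pairwise distance ", minDist)
    }
    out
  })
}

#' Hamming distances from one sequence to a set of equal-length sequences
#' @noRd
.hammingTo <- function(x, set) {
  if (length(set) == 0) return(integer(0))
  a <- strsplit(x, "", fixed = TRUE)[[1]]
  vapply(strsplit(set, "", fixed = TRUE),
         function(b) sum(a != b), integer(1))
}

#' Correct an observed barcode against a whitelist
#'
#' Returns the whitelist entry at Hamming distance 0 if present; otherwise
#' the *unique* entry at distance 1; otherwise `NA` (two or more candidates
#' at distance 1 are treated as ambiguous and rejected).
#'
#' @param observed character vector of observed barcode sequences, same
#'   length as the whitelist barcodes.
#' @param whitelist character vector of whitelist barcodes.
#' @return character vector: corrected barcode or `NA` per observation.
#' @export
correctBarcode <- function(observed, whitelist) {
  L <- .checkWhitelist(whitelist)
  if (any(nchar(observed) != L))
    stop("observed barcode length differs from whitelist length")
  out <- ifelse(observed %in% whitelist, observed, NA_character_)
  todo <- which(is.na(out))
  if (length(todo) == 0) return(out)
  # index whitelist by its 4*L single-substitution variants
  variants <- .oneSubVariants(whitelist, L)
  hits <- variants$target[match(observed[todo], variants$variant)]
  amb <- observed[todo] %in% variants$ambiguous
  hits[amb] <- NA_character_
  out[todo] <- hits
  out
}

# All distance-1 variants of every whitelist entry; variants reachable from
# more than one entry are recorded as ambiguous.
.oneSubVariants <- function(whitelist, L) {
  alts <- c("A", "C", "G", "T")
  var <- character(0); tgt <- character(0)
  for (p in seq_len(L)) {
    cur <- substring(whitelist, p, p)
    for (a in alts) {
      keep <- cur != a
      v <- paste0(substring(whitelist[keep], 1, p - 1), a,
                  substring(whitelist[keep], p + 1, L))
      var <- c(var, v)
      tgt <- c(tgt, whitelist[keep])
    }
  }
  dup <- unique(var[duplicated(var)])
  # a variant hitting two entries is ambiguous; drop all its mappings
  keep <- !var %in% dup
  list(variant = var[keep], target = tgt[keep], ambiguous = dup)
}

#' Demultiplex paired FASTQ by cell barcode
#'
#' Parses the barcode from read 1 at the configured offset/length, corrects
#' it against the whitelist within Hamming distance 1 ([correctBarcode()]),
#' trims barcode bases (and optional adapters) and groups reads by corrected
#' barcode. Reads whose barcode cannot be corrected are counted as rejected.
#'
#' @param r1Path,r2Path paired FASTQ files (in sync; optionally gzipped).
#' @param whitelist character vector of barcodes.
#' @param barcodeOffset 0-based offset of the barcode in read 1 (default 0).
#' @param adapter5,adapter3 optional adapter sequences removed from the
#'   start/end of both mates after barcode trimming, by exact prefix/suffix
#'   match allowing `adapterMismatches` mismatches.
#' @param adapterMismatches allowed adapter mismatches (default 1).
#' @return a list (class `DemuxResult`): `groups` (named list of
#'   [BarcodeGroup-class]), `counts` (reads per corrected barcode) and
#'   `rejected` (uncorrectable read count). `sum(counts) + rejected` equals
#'   the number of input pairs.
#' @export
demultiplex <- function(r1Path, r2Path, whitelist, barcodeOffset = 0L,
                        adapter5 = NULL, adapter3 = NULL,
                        adapterMismatches = 1L) {
  L <- .checkWhitelist(whitelist)
  f1 <- readFastq(r1Path)
  f2 <- readFastq(r2Path)
  if (length(f1$seq) != length(f2$seq))
    stop("unpaired FASTQ input: read counts differ")
  n <- length(f1$seq)
  if (n == 0)
    return(structure(list(groups = list(), counts = integer(0),
                          rejected = 0L), class = "DemuxResult"))
  if (any(sub("/1$", "", f1$id) != sub("/2$", "", f2$id)))
    stop("paired FASTQ files are out of sync")
  obs <- substring(f1$seq, barcodeOffset + 1L, barcodeOffset + L)
  if (any(nchar(obs) < L)) stop("read 1 shorter than barcode layout")
  corrected <- correctBarcode(obs, whitelist)
  keep <- !is.na(corrected)
  seq1 <- paste0(substring(f1$seq, 1, barcodeOffset),
                 substring(f1$seq, barcodeOffset + L + 1L))
  qual1 <- paste0(substring(f1$qual, 1, barcodeOffset),
                  substring(f1$qual, barcodeOffset + L + 1L))
  trim <- function(s, q) {
    if (!is.null(adapter5)) {
      hit <- .prefixMatch(s, adapter5, adapterMismatches)
      s[hit] <- substring(s[hit], nchar(adapter5) + 1L)
      q[hit] <- substring(q[hit], nchar(adapter5) + 1L)
    }
    if (!is.null(adapter3)) {
      hit <- .suffixMatch(s, adapter3, adapterMismatches)
      s[hit] <- substring(s[hit], 1L, nchar(s[hit]) - nchar(adapter3))
      q[hit] <- substring(q[hit], 1L, nchar(q[hit]) - nchar(adapter3))
    }
    list(s = s, q = q)
  }
  t1 <- trim(seq1, qual1)
  t2 <- trim(f2$seq, f2$qual)
  groups <- list()
  for (bc in unique(corrected[keep])) {
    sel <- which(keep & corrected == bc)
    groups[[bc]] <- new("BarcodeGroup", barcodeId = bc,
                        mate1 = t1$s[sel], mate2 = t2$s[sel],
                        qual1 = t1$q[sel], qual2 = t2$q[sel],
                        batch = "single_cell", truth = NULL,
                        truthHost = NA_character_,
                        truthContamination = NA_real_)
  }
  counts <- vapply(groups, readPairCount, integer(1))
  structure(list(groups = groups, counts = counts,
                 rejected = as.integer(sum(!keep))),
            class = "DemuxResult")
}

.prefixMatch <- function(s, adapter, mm) {
  a <- strsplit(adapter, "", fixed = TRUE)[[1]]
  pre <- substring(s, 1, length(a))
  d <- vapply(strsplit(pre, "", fixed = TRUE), function(b)
    if (length(b) < length(a)) Inf else sum(b != a), numeric(1))
  d <= mm
}

.suffixMatch <- function(s, adapter, mm) {
  a <- strsplit(adapter, "", fixed = TRUE)[[1]]
  suf <- substring(s, nchar(s) - length(a) + 1L)
  d <- vapply(strsplit(suf, "", fixed = TRUE), function(b)
    if (length(b) < length(a)) Inf else sum(b != a), numeric(1))
  d <= mm
}

#' @export
print.DemuxResult <- function(x, ...) {
  cat(sprintf("DemuxResult: %d barcode group(s), %d assigned + %d rejected reads\n",
              length(x$groups), sum(x$counts), x$rejected))
  invisible(x)
}

#' Filter barcodes by read count
#'
#' Retains barcodes whose read-pair count is at least `minReads`; barcodes
#' with strictly fewer reads are removed (the boundary is kept). The default
#' cutoff is 1000 reads.
#'
#' @param counts named integer vector of reads per barcode, or a
#'   `DemuxResult`.
#' @param minReads minimum read count (default 1000).
#' @return character vector of retained barcode ids.
#' @export
filterByReadCount <- function(counts, minReads = 1000L) {
  if (inherits(counts, "DemuxResult")) counts <- counts$counts
  if (minReads < 0) stop("minReads must be non-negative")
  names(counts)[counts >= minReads]
}
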