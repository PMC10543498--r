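#' A barcode group: paired reads sharing one (corrected) cell barcode
#'
#' The unit of analysis standing in for a single microbial cell (or, with
#' `batch = "contig"`, for a metagenomic contig's associated read group).
#' Simulated groups carry a per-read truth table; groups demultiplexed from
#' real FASTQ do not.
#'
#' @slot barcodeId character identifier.
#' @slot mate1,mate2 character vectors of read sequences (equal length).
#' @slot qual1,qual2 character vectors of Phred+33 quality strings.
#' @slot batch `"single_cell"` or `"contig"`.
#' @slot truth `NULL`, or a `DataFrame` with one row per pair and columns
#'   `read_id`, `source_genome`, `source_taxid`, `start`, `amplicon_len`,
#'   `is_contaminant`.
#' @slot truthHost genome id the group was simulated from, or `NA`.
#' @slot truthContamination simulated contaminant read fraction, or `NA`.
#'
#' @export
setClass("BarcodeGroup",
  representation(barcodeId = "character", mate1 = "character",
                 mate2 = "character", qual1 = "character", qual2 = "character",
                 batch = "character", truth = "ANY",
                 truthHost = "character", truthContamination = "numeric"))

setValidity("BarcodeGroup", function(object) {
  n <- length(object@mate1)
  if (length(object@mate2) != n) return("mate1/mate2 length mismatch")
  if (length(object@qual1) != n || length(object@qual2) != n)
    return("quality/sequence length mismatch")
  if (!object@batch %in% c("single_cell", "contig"))
    return("batch must be single_cell or contig")
  if (!is.null(object@truth) && nrow(object@truth) != n)
    return("truth table must have one row per read pair")
  TRUE
})

setMethod("show", "BarcodeGroup", function(object) {
  cat(sprintf("BarcodeGroup %s (%s): %d read pairs%s\n", object@barcodeId,
              object@batch, length(object@mate1),
              if (!is.na(object@truthHost))
                sprintf(", simulated from %s (contamination %.3f)",
                        object@truthHost, object@truthContamination) else ""))
})

#' Number of read pairs in a barcode group
#' @param group a [BarcodeGroup-class].
#' @return integer count of pairs.
#' @export
readPairCount <- function(group) length(group@mate1)

#' Per-read truth table of a simulated group
#' @param group a [BarcodeGroup-class].
#' @return a `DataFrame`, or `NULL` for non-simulated groups.
#' @export
groupTruth <- function(group) group@truth
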