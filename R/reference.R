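#' Reference genome set
#'
#' A collection of reference genomes tied to a taxonomy. Each sequence belongs
#' to a genome (`genome_id` in `mcols`), and each genome carries a species- or
#' strain-level taxid present in the taxonomy.
#'
#' @slot sequences a [Biostrings::DNAStringSet] with `mcols` columns
#'   `genome_id` and `taxid` (one row per sequence; genomes may span several
#'   sequences).
#' @slot taxonomy the [Taxonomy-class] the taxids refer to.
#'
#' @export
setClass("ReferenceSet",
  representation(sequences = "DNAStringSet", taxonomy = "Taxonomy"))

setValidity("ReferenceSet", function(object) {
  mc <- S4Vectors::mcols(object@sequences)
  if (is.null(mc) || !all(c("genome_id", "taxid") %in% colnames(mc)))
    return("sequences need mcols genome_id and taxid")
  if (any(Biostrings::width(object@sequences) == 0))
    return("zero-length sequence")
  if (!all(mc$taxid %in% object@taxonomy@taxid))
    return("genome taxid absent from taxonomy")
  per <- tapply(as.integer(mc$taxid), as.character(mc$genome_id),
                function(x) length(unique(x)))
  if (any(per != 1)) return("a genome maps to more than one taxid")
  TRUE
})

setMethod("show", "ReferenceSet", function(object) {
  mc <- S4Vectors::mcols(object@sequences)
  cat(sprintf("ReferenceSet: %d genome(s), %d sequence(s), %s bp total\n",
              length(unique(mc$genome_id)), length(object@sequences),
              format(sum(as.numeric(Biostrings::width(object@sequences))),
                     big.mark = ",")))
})

#' Construct a ReferenceSet
#'
#' @param genomes a named character vector or named
#'   [Biostrings::DNAStringSet]; names are genome ids.
#' @param taxids named integer vector mapping genome id to taxid.
#' @param taxonomy a [Taxonomy-class].
#' @return a [ReferenceSet-class].
#' @export
referenceSet <- function(genomes, taxids, taxonomy) {
  if (is.character(genomes)) genomes <- Biostrings::DNAStringSet(genomes)
  ids <- names(genomes)
  if (is.null(ids) || any(!nzchar(ids))) stop("genomes must be named")
  if (!all(ids %in% names(taxids))) stop("missing taxid for some genome(s)")
  S4Vectors::mcols(genomes) <- S4Vectors::DataFrame(
    genome_id = ids, taxid = as.integer(taxids[ids]))
  obj <- new("ReferenceSet", sequences = genomes, taxonomy = taxonomy)
  validObject(obj)
  obj
}

#' Genome ids of a ReferenceSet
#' @param refset a [ReferenceSet-class].
#' @return character vector of genome ids.
#' @export
genomeIds <- function(refset) {
  unique(as.character(S4Vectors::mcols(refset@sequences)$genome_id))
}

#' Taxids of genomes
#' @param refset a [ReferenceSet-class].
#' @param ids genome ids (default all).
#' @return named integer vector, taxid per genome id.
#' @export
genomeTaxids <- function(refset, ids = genomeIds(refset)) {
  mc <- S4Vectors::mcols(refset@sequences)
  m <- match(ids, as.character(mc$genome_id))
  setNames(as.integer(mc$taxid[m]), ids)
}

#' Sequences of one genome
#' @param refset a [ReferenceSet-class].
#' @param id a genome id.
#' @return a [Biostrings::DNAStringSet].
#' @export
genomeSequences <- function(refset, id) {
  mc <- S4Vectors::mcols(refset@sequences)
  refset@sequences[as.character(mc$genome_id) == id]
}

#' Read reference genomes from FASTA
#'
#' Multi-record, wrapped-line FASTA; matching is case-insensitive (sequences
#' are uppercased on load). Characters outside A/C/G/T are either rejected
#' with an error or masked to `N` depending on `nonACGT`.
#'
#' @param path FASTA file.
#' @param taxids named integer vector mapping record name (first whitespace
#'   token of the header) to taxid.
#' @param taxonomy a [Taxonomy-class].
#' @param nonACGT `"reject"` (default) or `"mask"`.
#' @return a [ReferenceSet-class] with one genome per FASTA record.
#' @export
readReferenceFasta <- function(path, taxids, taxonomy,
                               nonACGT = c("reject", "mask")) {
  nonACGT <- match.arg(nonACGT)
  seqs <- Biostrings::readDNAStringSet(path)
  names(seqs) <- sub("\\s.*$", "", names(seqs))
  chars <- as.character(seqs)
  chars <- toupper(chars)
  bad <- grepl("[^ACGT]", chars)
  if (any(bad)) {
    if (nonACGT == "reject")
      stop("non-ACGT characters in record(s): ",
           paste(names(seqs)[bad], collapse = ", "))
    chars[bad] <- gsub("[^ACGT]", "N", chars[bad])
  }
  referenceSet(setNames(chars, names(seqs)), taxids, taxonomy)
}

#' Write a ReferenceSet to FASTA
#' @param refset a [ReferenceSet-class].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
writeReferenceFasta <- function(refset, path) {
  Biostrings::writeXStringSet(refset@sequences, path)
  invisible(path)
}
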