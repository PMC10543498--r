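# Per-barcode strain resolution: multi-mapping alignment likelihoods against
# a panel of closely related genomes, variational-Bayes abundance estimation
# under a Dirichlet prior, and the maximum-abundance assignment rule.

#' Strain panel
#'
#' An ordered set of closely related reference genomes (typically ~99%
#' identity) with a shared k-mer seed index for candidate placement lookup.
#'
#' @slot genomes a [Biostrings::DNAStringSet], names are strain ids.
#' @slot ptr external pointer to the native seed index.
#' @slot seedK seed k-mer length.
#' @export
setClass("StrainPanel",
  representation(genomes = "DNAStringSet", ptr = "externalptr",
                 seedK = "integer"))

setValidity("StrainPanel", function(object) {
  if (length(object@genomes) < 2) return("need at least 2 strains")
  if (anyDuplicated(names(object@genomes))) return("duplicated strain ids")
  TRUE
})

setMethod("show", "StrainPanel", function(object) {
  cat(sprintf("StrainPanel: %d strains, seed k = %d\n",
              length(object@genomes), object@seedK))
})

#' Build a strain panel with its seed index
#'
#' @param genomes named character vector or named
#'   [Biostrings::DNAStringSet] of strain genomes.
#' @param seedK seed length for candidate lookup (default 21).
#' @return a [StrainPanel-class].
#' @export
strainPanel <- function(genomes, seedK = 21L) {
  if (is.character(genomes)) genomes <- Biostrings::DNAStringSet(genomes)
  if (is.null(names(genomes))) stop("strain genomes must be named")
  ptr <- cpp_seed_index_build(as.character(genomes), as.integer(seedK))
  obj <- new("StrainPanel", genomes = genomes, ptr = ptr,
             seedK = as.integer(seedK))
  validObject(obj)
  obj
}

#' Strain ids of a panel
#' @param panel a [StrainPanel-class].
#' @return character vector.
#' @export
strainIds <- function(panel) names(panel@genomes)

#' Per-read, per-strain alignment log-likelihoods for one barcode group
#'
#' @slot barcodeId group identifier.
#' @slot logLik reads-by-strains matrix of log-likelihoods; `-Inf` where no
#'   placement was found.
#' @slot readIds read identifiers (row names).
#' @export
setClass("AlignmentLikelihoods",
  representation(barcodeId = "character", logLik = "matrix",
                 readIds = "character"))

setValidity("AlignmentLikelihoods", function(object) {
  if (nrow(object@logLik) > 0 && !any(is.finite(object@logLik)))
    return("no finite likelihood entries")
  if (any(rowSums(is.finite(object@logLik)) == 0))
    return("every retained read needs at least one finite entry")
  TRUE
})

setMethod("show", "AlignmentLikelihoods", function(object) {
  cat(sprintf("AlignmentLikelihoods %s: %d read(s) x %d strain(s)\n",
              object@barcodeId, nrow(object@logLik), ncol(object@logLik)))
})

#' Align a barcode group's reads against a strain panel
#'
#' Candidate placements are found by exact k-mer seeding and ungapped
#' extension; the per-(read, strain) log-likelihood at the best placement
#' with `m` mismatches over read length `L` is
#' `m * log(epsilon/3) + (L - m) * log(1 - epsilon)`. Mates contribute the
#' sum of their log-likelihoods on strains where both place; where only one
#' mate places the pair falls back to that mate alone. Pairs with no
#' placement on any strain are dropped from the matrix.
#'
#' @param group a [BarcodeGroup-class].
#' @param panel a [StrainPanel-class].
#' @param epsilon per-base error probability, in (0, 0.25).
#' @param maxMismatches mismatch cap for a valid placement (default 5).
#' @param seedStep stride between successive seed positions (default 5).
#' @return an [AlignmentLikelihoods-class].
#' @export
alignReadsToPanel <- function(group, panel, epsilon = 0.01,
                              maxMismatches = 5L, seedStep = 5L) {
  if (epsilon <= 0 || epsilon >= 0.25) stop("epsilon must be in (0, 0.25)")
  if (any(nchar(c(group@mate1, group@mate2)) < panel@seedK))
    stop("read shorter than seed length")
  mm1 <- cpp_align_reads(panel@ptr, group@mate1, as.integer(maxMismatches),
                         as.integer(seedStep))
  mm2 <- cpp_align_reads(panel@ptr, group@mate2, as.integer(maxMismatches),
                         as.integer(seedStep))
  L1 <- nchar(group@mate1); L2 <- nchar(group@mate2)
  ll <- function(mm, L) {
    out <- mm * log(epsilon / 3) + (L - mm) * log(1 - epsilon)
    out[is.na(mm)] <- -Inf
    out
  }
  l1 <- ll(mm1, L1); l2 <- ll(mm2, L2)
  both <- is.finite(l1) & is.finite(l2)
  combined <- matrix(-Inf, nrow(l1), ncol(l1))
  combined[both] <- l1[both] + l2[both]
  only1 <- is.finite(l1) & !both
  combined[only1] <- l1[only1]
  only2 <- is.finite(l2) & !both
  combined[only2] <- l2[only2]
  keep <- rowSums(is.finite(combined)) > 0
  combined <- combined[keep, , drop = FALSE]
  ids <- sprintf("%s:%06d", group@barcodeId, which(keep))
  dimnames(combined) <- list(ids, strainIds(panel))
  new("AlignmentLikelihoods", barcodeId = group@barcodeId,
      logLik = combined, readIds = ids)
}

#' Build alignment likelihoods from a SAM record subset
#'
#' For real data aligned externally with all-hits reporting: mismatch counts
#' are taken from `NM` tags and the best (lowest-NM) record per (read,
#' reference) is used.
#'
#' @param sam data.frame from [readSamSubset()] (columns `qname`, `rname`,
#'   `mapq`, `nm`, plus `seqlen`).
#' @param strains character vector of reference/strain names (matrix column
#'   order).
#' @param epsilon per-base error probability.
#' @param barcodeId group id to attach.
#' @return an [AlignmentLikelihoods-class].
#' @export
likelihoodsFromSam <- function(sam, strains, epsilon = 0.01,
                               barcodeId = "sam") {
  if (epsilon <= 0 || epsilon >= 0.25) stop("epsilon must be in (0, 0.25)")
  sam <- sam[!is.na(sam$rname) & sam$rname %in% strains, , drop = FALSE]
  reads <- unique(sam$qname)
  M <- matrix(-Inf, length(reads), length(strains),
              dimnames = list(reads, strains))
  best <- aggregate(nm ~ qname + rname, data = sam, FUN = min)
  lens <- sam$seqlen[match(paste(best$qname, best$rname),
                           paste(sam$qname, sam$rname))]
  M[cbind(match(best$qname, reads), match(best$rname, strains))] <-
    best$nm * log(epsilon / 3) + (lens - best$nm) * log(1 - epsilon)
  new("AlignmentLikelihoods", barcodeId = barcodeId, logLik = M,
      readIds = reads)
}

#' Strain abundance posterior for one barcode group
#'
#' @slot theta posterior-mean strain abundances (simplex).
#' @slot elbo evidence-lower-bound trace over iterations (non-decreasing).
#' @slot converged logical; `FALSE` when `maxIter` was hit first.
#' @slot nInformativeReads reads whose likelihoods differ across strains.
#' @slot assignment strain id or `"mixed"`; set by [assignStrain()].
#' @export
setClass("StrainPosterior",
  representation(theta = "numeric", elbo = "numeric", converged = "logical",
                 nInformativeReads = "integer", assignment = "character"))

setMethod("show", "StrainPosterior", function(object) {
  top <- sort(object@theta, decreasing = TRUE)[1]
  cat(sprintf("StrainPosterior: %d strains, max theta %.3f (%s), %s, %d informative read(s)\n",
              length(object@theta), top, names(top),
              if (object@converged) "converged" else "NOT converged",
              object@nInformativeReads))
})

#' Estimate strain abundances by variational Bayes
#'
#' Mixture model `P(read i | theta) = sum_s theta_s * L_is` with a
#' `Dirichlet(alpha)` prior on `theta`. Mean-field coordinate ascent
#' iterates responsibilities `r_is proportional to L_is * exp(E[log theta_s])`
#' and Dirichlet pseudo-counts `alpha + sum_i r_is` until the change in the
#' posterior-mean `theta` falls below `tol`. The evidence lower bound is
#' tracked and is non-decreasing by construction.
#'
#' @param lik an [AlignmentLikelihoods-class] with at least one read.
#' @param alpha Dirichlet prior concentration (default 0.1, sparse).
#' @param tol convergence tolerance on `max |delta theta|` (default 1e-8).
#' @param maxIter iteration cap (default 1000).
#' @return a [StrainPosterior-class] with posterior-mean `theta`.
#' @export
estimateAbundanceVB <- function(lik, alpha = 0.1, tol = 1e-8,
                                maxIter = 1000L) {
  logL <- lik@logLik
  n <- nrow(logL); K <- ncol(logL)
  if (n == 0) stop("no reads with finite likelihoods")
  # per-read normalisation: a constant offset per read, harmless to r and theta
  off <- apply(logL, 1, max)
  logLn <- logL - off
  informative <- sum(apply(logL, 1, function(x) {
    f <- is.finite(x)
    !all(f) || max(x) - min(x) > 1e-12
  }))
  a <- rep(alpha + n / K, K)   # start from uniform responsibilities
  theta <- a / sum(a)
  elbo <- numeric(0)
  converged <- FALSE
  for (it in seq_len(maxIter)) {
    elog <- digamma(a) - digamma(sum(a))
    S <- sweep(logLn, 2, elog, "+")
    rowMax <- apply(S, 1, max)
    R <- exp(S - rowMax)
    R <- R / rowSums(R)
    aNew <- alpha + colSums(R)
    thetaNew <- aNew / sum(aNew)
    # ELBO under the new responsibilities and old q(theta)
    readTerm <- sum(R * (logLn + rep(elog, each = n) - log(pmax(R, 1e-300))),
                    na.rm = TRUE)
    prior <- lgamma(K * alpha) - K * lgamma(alpha) + (alpha - 1) * sum(elog)
    entq <- lgamma(sum(a)) - sum(lgamma(a)) + sum((a - 1) * elog)
    elbo <- c(elbo, readTerm + prior - entq)
    delta <- max(abs(thetaNew - theta))
    a <- aNew; theta <- thetaNew
    if (delta < tol) { converged <- TRUE; break }
  }
  if (!converged)
    warning("VB did not converge in ", maxIter,
            " iterations; returning last iterate")
  new("StrainPosterior", theta = setNames(theta, colnames(logL)),
      elbo = elbo, converged = converged,
      nInformativeReads = as.integer(informative),
      assignment = NA_character_)
}

#' Assign a barcode group to a strain
#'
#' The group is assigned to the strain of maximum posterior abundance when
#' that maximum is at least `minAbundance` (default 0.15); otherwise — or
#' when the maximum is tied — the group is called `"mixed"` (a multiplet or
#' unresolved cell).
#'
#' @param posterior a [StrainPosterior-class].
#' @param minAbundance assignment threshold (default 0.15).
#' @return the posterior with the `assignment` slot set.
#' @export
assignStrain <- function(posterior, minAbundance = 0.15) {
  th <- posterior@theta
  m <- max(th)
  tied <- sum(abs(th - m) < 1e-9) > 1
  posterior@assignment <-
    if (m >= minAbundance && !tied) names(th)[which.max(th)] else "mixed"
  posterior
}

#' Assignment of a posterior
#' @param posterior a [StrainPosterior-class].
#' @return strain id or `"mixed"` (or `NA` before [assignStrain()]).
#' @export
strainAssignment <- function(posterior) posterior@assignment
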