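#' Recognised taxonomic ranks, from root down
#'
#' The fixed rank enumeration used throughout the package, ordered from the
#' root of the tree towards the leaves. Rank labels outside this set are
#' rejected when a taxonomy is loaded.
#'
#' @export
TAX_RANKS <- c("root", "superkingdom", "phylum", "class", "order",
               "family", "genus", "species", "strain")

#' Taxonomy tree
#'
#' A rooted taxonomy over integer taxids. Each node carries a parent pointer
#' (the root is its own parent), a rank drawn from [TAX_RANKS] and a name.
#' Validity enforces unique taxids, existing parents, absence of cycles and
#' non-increasing rank depth along every root-to-leaf path.
#'
#' @slot taxid integer vector of node identifiers.
#' @slot parent integer vector, parent taxid per node.
#' @slot rank character vector of rank labels.
#' @slot name character vector of node names.
#' @slot root the root taxid.
#'
#' @export
setClass("Taxonomy",
  representation(taxid = "integer", parent = "integer",
                 rank = "character", name = "character", root = "integer"))

setValidity("Taxonomy", function(object) {
  msgs <- character()
  n <- length(object@taxid)
  if (length(object@parent) != n || length(object@rank) != n ||
      length(object@name) != n)
    return("slot lengths differ")
  if (anyDuplicated(object@taxid))
    msgs <- c(msgs, "duplicated taxids")
  if (!all(object@rank %in% TAX_RANKS))
    msgs <- c(msgs, sprintf("unknown rank label(s): %s",
                            paste(setdiff(object@rank, TAX_RANKS), collapse = ", ")))
  if (!all(object@parent %in% object@taxid))
    msgs <- c(msgs, "orphan parent taxid(s)")
  roots <- object@taxid[object@taxid == object@parent]
  if (length(roots) != 1L || roots != object@root)
    msgs <- c(msgs, "exactly one self-parented root required")
  if (length(msgs) > 0) return(msgs)
  # cycle check + rank monotonicity by walking each node to the root
  idx <- match(object@parent, object@taxid)
  rk <- match(object@rank, TAX_RANKS)
  for (i in seq_len(n)) {
    seen <- 0L
    j <- i
    while (object@taxid[j] != object@parent[j]) {
      pj <- idx[j]
      if (rk[pj] > rk[j])
        return(sprintf("rank of node %d deeper than its child %d",
                       object@taxid[pj], object@taxid[j]))
      j <- pj
      seen <- seen + 1L
      if (seen > n) return("cycle detected in parent pointers")
    }
  }
  TRUE
})

setMethod("show", "Taxonomy", function(object) {
  cat(sprintf("Taxonomy with %d nodes (root taxid %d)\n",
              length(object@taxid), object@root))
  tab <- table(factor(object@rank, levels = TAX_RANKS))
  tab <- tab[tab > 0]
  cat("  ranks:", paste(sprintf("%s=%d", names(tab), tab), collapse = ", "), "\n")
})

#' Build a Taxonomy from a data.frame
#'
#' @param df data.frame with columns `taxid`, `parent_taxid`, `rank`, `name`.
#' @return a validated [Taxonomy-class] object.
#' @export
taxonomyFromDataFrame <- function(df) {
  need <- c("taxid", "parent_taxid", "rank", "name")
  if (!all(need %in% colnames(df)))
    stop("taxonomy table needs columns: ", paste(need, collapse = ", "))
  taxid <- as.integer(df$taxid)
  parent <- as.integer(df$parent_taxid)
  if (anyNA(taxid) || anyNA(parent) || any(taxid <= 0))
    stop("taxids must be positive integers")
  root <- taxid[taxid == parent]
  if (length(root) != 1L)
    stop("exactly one root (self-parented node) required, found ", length(root))
  obj <- new("Taxonomy", taxid = taxid, parent = parent,
             rank = as.character(df$rank), name = as.character(df$name),
             root = root)
  validObject(obj)
  obj
}

#' Load a taxonomy from a 4-column TSV file
#'
#' Expects tab-separated columns `taxid`, `parent_taxid`, `rank`, `name`;
#' a header line is detected and skipped if present. The root node must be
#' its own parent. Cycles, orphan parents, duplicate taxids and unknown rank
#' labels are rejected.
#'
#' @param path path to the TSV file.
#' @return a [Taxonomy-class] object.
#' @examples
#' tf <- tempfile(fileext = ".tsv")
#' writeLines(c("1\t1\troot\troot", "2\t1\tgenus\tGenusA",
#'              "3\t2\tspecies\tspA"), tf)
#' tax <- loadTaxonomy(tf)
#' @export
loadTaxonomy <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0) stop("empty taxonomy file: ", path)
  fields <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf != 4))
    stop(sprintf("malformed taxonomy row (expected 4 tab-separated fields) at line %d",
                 which(nf != 4)[1]))
  m <- do.call(rbind, fields)
  if (is.na(suppressWarnings(as.integer(m[1, 1])))) m <- m[-1, , drop = FALSE]
  if (nrow(m) == 0) stop("taxonomy file has no data rows")
  if (anyNA(suppressWarnings(as.integer(m[, 1]))))
    stop("non-integer taxid in taxonomy file")
  taxonomyFromDataFrame(data.frame(
    taxid = as.integer(m[, 1]), parent_taxid = as.integer(m[, 2]),
    rank = m[, 3], name = m[, 4], stringsAsFactors = FALSE))
}

.taxCheck <- function(taxonomy, t) {
  if (!all(t %in% taxonomy@taxid))
    stop("unknown taxid(s): ", paste(setdiff(t, taxonomy@taxid), collapse = ", "))
}

.rootPath <- function(taxonomy, t) {
  idx <- match(t, taxonomy@taxid)
  path <- integer()
  repeat {
    path <- c(path, taxonomy@taxid[idx])
    if (taxonomy@taxid[idx] == taxonomy@parent[idx]) break
    idx <- match(taxonomy@parent[idx], taxonomy@taxid)
  }
  path
}

#' Lowest common ancestor of two taxa
#'
#' @param taxonomy a [Taxonomy-class].
#' @param a,b taxids present in the taxonomy.
#' @return the taxid of the deepest common ancestor.
#' @export
lca <- function(taxonomy, a, b) {
  stopifnot(is(taxonomy, "Taxonomy"))
  .taxCheck(taxonomy, c(a, b))
  if (a == b) return(a)
  pa <- .rootPath(taxonomy, a)
  pb <- .rootPath(taxonomy, b)
  common <- intersect(pa, pb)
  common[1]  # .rootPath orders leaf -> root; first common entry is deepest
}

#' Ancestor of a taxon at a given rank
#'
#' Walks parent pointers from `t` towards the root and returns the unique
#' node at the requested rank (possibly `t` itself), or `NA` if the path to
#' the root has no node of that rank.
#'
#' @param taxonomy a [Taxonomy-class].
#' @param t a taxid.
#' @param rank a rank label from [TAX_RANKS].
#' @return a taxid, or `NA_integer_` when the path skips the rank.
#' @export
ancestorAtRank <- function(taxonomy, t, rank) {
  stopifnot(is(taxonomy, "Taxonomy"))
  .taxCheck(taxonomy, t)
  if (!rank %in% TAX_RANKS) stop("unknown rank: ", rank)
  path <- .rootPath(taxonomy, t)
  ranks <- taxonomy@rank[match(path, taxonomy@taxid)]
  hit <- path[ranks == rank]
  if (length(hit) == 0) NA_integer_ else hit[1]
}

#' Taxon names for taxids
#' @param taxonomy a [Taxonomy-class].
#' @param t taxids.
#' @return character vector of names.
#' @export
taxonName <- function(taxonomy, t) taxonomy@name[match(t, taxonomy@taxid)]

#' Taxids of the leaves (nodes without children)
#' @param taxonomy a [Taxonomy-class].
#' @return integer vector of leaf taxids.
#' @export
taxonomyLeaves <- function(taxonomy) {
  nonroot <- taxonomy@taxid != taxonomy@parent
  setdiff(taxonomy@taxid, taxonomy@parent[nonroot])
}

#' Descendants of a node at a given rank
#' @param taxonomy a [Taxonomy-class].
#' @param t a taxid.
#' @param rank target rank label.
#' @return integer vector of taxids at `rank` whose ancestor is `t`
#'   (includes `t` itself when `t` is at `rank`).
#' @export
descendantsAtRank <- function(taxonomy, t, rank) {
  .taxCheck(taxonomy, t)
  if (!rank %in% TAX_RANKS) stop("unknown rank: ", rank)
  at <- taxonomy@taxid[taxonomy@rank == rank]
  at[vapply(at, function(x) t %in% .rootPath(taxonomy, x), logical(1))]
}
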