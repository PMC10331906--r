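#' Parse a Newick string into a phylogeny
#'
#' Thin validating wrapper around [ape::read.tree()]. The returned tree is the
#' standard `phylo` object used throughout the package. Polytomies (including
#' a basal polytomy, i.e. a star tree) are accepted; duplicate tip labels and
#' negative branch lengths are rejected.
#'
#' @param text a single Newick string, terminated by `;`.
#' @return an object of class `phylo` with `edge.length` set.
#' @export
parse_newick <- function(text) {
  stopifnot(is.character(text), length(text) == 1L)
  .newick_prescan(text)
  tree <- tryCatch(
    ape::read.tree(text = text),
    error = function(e) stop("Newick parse error: ", conditionMessage(e), call. = FALSE)
  )
  if (is.null(tree)) stop("Newick parse error: no tree could be read", call. = FALSE)
  validate_phylogeny(tree)
  tree
}

# cheap syntax pre-scan so common malformations report a character offset
.newick_prescan <- function(text) {
  chars <- strsplit(text, "", fixed = TRUE)[[1]]
  depth <- 0L
  for (i in seq_along(chars)) {
    if (chars[i] == "(") depth <- depth + 1L
    if (chars[i] == ")") {
      depth <- depth - 1L
      if (depth < 0L)
        stop("Newick parse error: unmatched ')' at character offset ", i, call. = FALSE)
    }
  }
  if (depth > 0L)
    stop("Newick parse error: ", depth, " unclosed '(' by character offset ",
         length(chars), call. = FALSE)
  if (!grepl(";", text, fixed = TRUE))
    stop("Newick parse error: missing ';' terminator at character offset ",
         length(chars), call. = FALSE)
  invisible(TRUE)
}

#' Validate the phylogeny invariants used by this package
#'
#' Checks that a `phylo` object has unique tip labels, at least two tips, and
#' non-negative branch lengths (zero-length branches are allowed).
#'
#' @param tree a `phylo` object.
#' @return the tree, invisibly, if valid.
#' @export
validate_phylogeny <- function(tree) {
  if (!inherits(tree, "phylo")) stop("not a 'phylo' object", call. = FALSE)
  if (ape::Ntip(tree) < 2L) stop("tree must have at least 2 tips", call. = FALSE)
  dup <- unique(tree$tip.label[duplicated(tree$tip.label)])
  if (length(dup) > 0L)
    stop("duplicate tip label(s): ", paste(dup, collapse = ", "), call. = FALSE)
  if (is.null(tree$edge.length))
    stop("tree has no branch lengths", call. = FALSE)
  if (any(tree$edge.length < 0))
    stop("negative branch length(s) found; branch lengths must be >= 0", call. = FALSE)
  invisible(tree)
}

#' Serialize a phylogeny to a Newick string
#'
#' Branch lengths are written with 9 significant digits so that
#' parse -> serialize -> parse round-trips preserve lengths to well below
#' 1e-9 relative error.
#'
#' @param tree a `phylo` object.
#' @param digits significant digits for branch lengths.
#' @return a single Newick string.
#' @export
serialize_newick <- function(tree, digits = 9L) {
  ape::write.tree(tree, digits = digits)
}

#' Read a set of phylogenies sharing one taxon set
#'
#' Reads either one Newick tree per line or a NEXUS TREES block (with optional
#' TRANSLATE table, resolved by [ape::read.nexus()]). File order is preserved
#' and every tree is checked against the tip set of the first; a mismatch
#' reports the offending tree index.
#'
#' @param path path to the tree file.
#' @param format `"newick"` or `"nexus"`.
#' @return a `multiPhylo` list of trees.
#' @export
read_tree_set <- function(path, format = c("newick", "nexus")) {
  format <- match.arg(format)
  trees <- switch(format,
    newick = ape::read.tree(path),
    nexus  = ape::read.nexus(path)
  )
  if (inherits(trees, "phylo")) trees <- c(trees)  # promote single tree
  if (length(trees) == 0L) stop("no trees found in ", path, call. = FALSE)
  as_tree_set(trees)
}

#' Validate a list of trees as a tree set
#'
#' @param trees a `multiPhylo` object or list of `phylo` trees.
#' @return a validated `multiPhylo`.
#' @export
as_tree_set <- function(trees) {
  if (inherits(trees, "phylo")) trees <- c(trees)
  class(trees) <- "multiPhylo"
  lapply(trees, validate_phylogeny)
  ref <- sort(trees[[1]]$tip.label)
  for (i in seq_along(trees)) {
    if (!identical(sort(trees[[i]]$tip.label), ref))
      stop("tree ", i, " has a different tip set from tree 1", call. = FALSE)
  }
  trees
}

#' Prune a phylogeny to a subset of taxa
#'
#' Restricts the tree to `keep`, suppressing degree-2 internal nodes with
#' branch lengths summed, so root-to-tip distances of retained tips are
#' unchanged.
#'
#' @param tree a `phylo` object.
#' @param keep character vector of tip labels to retain (>= 2).
#' @return the pruned `phylo`.
#' @export
prune_to_taxa <- function(tree, keep) {
  validate_phylogeny(tree)
  keep <- unique(as.character(keep))
  missing <- setdiff(keep, tree$tip.label)
  if (length(missing) > 0L)
    stop("taxa not in tree: ", paste(missing, collapse = ", "), call. = FALSE)
  if (length(keep) < 2L)
    stop("need at least 2 taxa to keep, got ", length(keep), call. = FALSE)
  if (setequal(keep, tree$tip.label)) return(tree)
  pr <- ape::keep.tip(tree, keep)
  # pruning can collapse a shared basal path; keep it as a root edge so
  # root-to-tip distances (and the Brownian covariance) are preserved exactly
  depth_of <- function(tr) {
    d <- ape::node.depth.edgelength(tr)
    stats::setNames(d[seq_along(tr$tip.label)], tr$tip.label)
  }
  deficit <- depth_of(tree)[keep] - depth_of(pr)[keep]
  stem <- (tree$root.edge %||% 0) + deficit[1]
  stopifnot(max(abs(deficit - deficit[1])) < 1e-10)
  if (stem > 1e-12) pr$root.edge <- unname(stem)
  pr
}

#' Normalize species labels for cross-file matching
#'
#' Spaces become underscores (the birdtree.org convention for binomials);
#' matching is otherwise exact and case-sensitive.
#'
#' @param x character vector of species names.
#' @return normalized character vector.
#' @export
normalize_labels <- function(x) gsub(" ", "_", as.character(x), fixed = TRUE)

#' Phylogenetic variance-covariance matrix
#'
#' Under Brownian motion the expected trait covariance between two species is
#' the shared branch length from the root to their most recent common
#' ancestor; the diagonal holds root-to-tip distances. Computed with
#' [ape::vcv.phylo()] and tagged with a `"lambda"` attribute (`NA` meaning no
#' lambda transform has been applied yet).
#'
#' @param tree a `phylo` object.
#' @param order optional character vector, a permutation of the tip labels,
#'   giving the row/column order of the result.
#' @return a symmetric numeric matrix with species dimnames and attribute
#'   `lambda = NA_real_`.
#' @export
phylo_vcv <- function(tree, order = NULL) {
  validate_phylogeny(tree)
  V <- ape::vcv.phylo(tree)
  # a root edge is history shared by every tip
  re <- tree$root.edge
  if (length(re) == 1L && is.finite(re) && re > 0) V <- V + re
  if (!is.null(order)) {
    if (!setequal(order, rownames(V)) || length(order) != nrow(V))
      stop("'order' must be a permutation of the tip labels", call. = FALSE)
    V <- V[order, order, drop = FALSE]
  }
  attr(V, "lambda") <- NA_real_
  V
}

#' Pagel's lambda branch-length transform of a covariance matrix
#'
#' Multiplies the off-diagonal (shared-history) entries by `lambda`, leaving
#' root-to-tip variances on the diagonal unchanged. `lambda = 1` returns the
#' full Brownian covariance, `lambda = 0` the star-phylogeny (independence)
#' covariance. A matrix may only be transformed once.
#'
#' @param V matrix from [phylo_vcv()] (attribute `lambda` must be `NA`).
#' @param lambda scalar in `[0, lambda_max]`.
#' @param lambda_max upper bound of the admissible range; defaults to 1.
#' @return the transformed matrix with attribute `lambda` set.
#' @export
lambda_transform <- function(V, lambda, lambda_max = 1) {
  if (!is.na(attr(V, "lambda") %||% NA_real_))
    stop("matrix has already been lambda-transformed (lambda = ",
         attr(V, "lambda"), ")", call. = FALSE)
  if (!is.numeric(lambda) || length(lambda) != 1L || is.na(lambda) ||
      lambda < 0 || lambda > lambda_max)
    stop("lambda must be a single value in [0, ", lambda_max, "]", call. = FALSE)
  d <- diag(V)
  W <- V * lambda
  diag(W) <- d
  attr(W, "lambda") <- lambda
  W
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# canonical string key for a clade = sorted tip labels it subtends
.clade_keys <- function(tree) {
  pp <- ape::prop.part(tree)
  labs <- attr(pp, "labels")
  vapply(pp, function(idx) paste(sort(labs[idx]), collapse = "\r"), character(1))
}

#' Maximum clade credibility tree of a tree set
#'
#' Scores every member tree by the sum over its internal clades of the log of
#' that clade's frequency in the set (the standard tree-annotator convention)
#' and returns the highest-scoring member; ties are broken by lowest tree
#' index. A clade is identified by the set of tip labels it subtends.
#'
#' @param trees a `multiPhylo` over one shared tip set.
#' @return list with `tree` (the winning `phylo`), `index`, and `scores`
#'   (log-credibility per member).
#' @export
maximum_clade_credibility <- function(trees) {
  trees <- as_tree_set(trees)
  n <- length(trees)
  per_tree <- lapply(trees, .clade_keys)
  counts <- table(unlist(per_tree, use.names = FALSE))
  scores <- vapply(per_tree, function(keys) {
    sum(log(as.numeric(counts[keys]) / n))
  }, numeric(1))
  idx <- which.max(scores)  # first max = lowest index on ties
  list(tree = trees[[idx]], index = idx, scores = scores)
}
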