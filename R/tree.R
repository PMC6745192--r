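# Neighbor-joining trees, nonparametric bootstrap supports, and
# low-support collapse. Tree inference itself is standard machinery
# (ape/phangorn); this file wires it to the alignment representation and
# adds the validation and support-handling conventions used by the
# placement diagnostic.

#' Neighbor-joining tree from a distance matrix
#'
#' A validated wrapper around [ape::nj()]. NJ recovers the generating
#' tree exactly (topology and branch lengths) whenever the input matrix
#' is additive, which is what makes the downstream placement diagnostic
#' testable against brute force.
#'
#' @param dist Symmetric numeric matrix (or `dist`) with zero diagonal
#'   and no negative or non-finite entries; at least 3 taxa.
#' @return An unrooted [ape::phylo] tree.
#' @export
nj_tree <- function(dist) {
  if (inherits(dist, "dist")) dist <- as.matrix(dist)
  if (!is.matrix(dist) || nrow(dist) != ncol(dist))
    stop("'dist' must be a square matrix")
  if (nrow(dist) < 3L) stop("need at least 3 taxa for a tree")
  if (any(!is.finite(dist))) stop("non-finite values in distance matrix")
  if (any(dist < 0)) stop("negative values in distance matrix")
  if (any(abs(dist - t(dist)) > 1e-8)) stop("distance matrix not symmetric")
  if (is.null(rownames(dist)))
    rownames(dist) <- colnames(dist) <- paste0("t", seq_len(nrow(dist)))
  ape::nj(stats::as.dist(dist))
}

# Internal-node support values as a numeric vector (NA where absent).
node_supports <- function(tree) {
  if (is.null(tree$node.label)) return(rep(NA_real_, tree$Nnode))
  suppressWarnings(as.numeric(tree$node.label))
}

#' Distance tree with nonparametric bootstrap supports
#'
#' Builds the point-estimate NJ tree from the full alignment, then
#' resamples alignment columns with replacement `replicates` times,
#' rebuilds a tree per replicate, and records for each internal edge of
#' the point tree the percentage of replicate trees containing the same
#' bipartition (supports rounded to integers, stored in `node.label`).
#' A replicate whose column draw leaves some pair of taxa with no
#' comparable sites is discarded and redrawn.
#'
#' @param aln An alignment ([as_alignment()]), at least 4 taxa.
#' @param model Distance model, see [pairwise_distance()].
#' @param replicates Number of bootstrap pseudoreplicates (default 100).
#' @param seed Integer seed; the run is reproducible given the seed.
#' @return An [ape::phylo] tree with integer supports (0..100) in
#'   `node.label` (root entry `NA`).
#' @export
bootstrap_tree <- function(aln, model = "JC69", replicates = 100L,
                           seed = 1L) {
  aln <- as_alignment(aln)
  replicates <- as.integer(replicates)
  if (replicates < 1L) stop("'replicates' must be >= 1")
  point <- nj_tree(pairwise_distance(aln, model))
  ncol_aln <- ncol(aln)
  boot <- with_local_seed(seed, {
    lapply(seq_len(replicates), function(r) {
      for (attempt in 1:100) {
        idx <- sample.int(ncol_aln, ncol_aln, replace = TRUE)
        tr <- tryCatch(
          nj_tree(suppressWarnings(
            pairwise_distance(aln[, idx, drop = FALSE], model))),
          error = function(e) NULL)
        if (!is.null(tr)) return(tr)
      }
      stop("could not draw a usable bootstrap replicate in 100 attempts")
    })
  })
  class(boot) <- "multiPhylo"
  counts <- ape::prop.clades(point, boot, rooted = FALSE)
  supp <- round(100 * counts / replicates)
  supp[is.na(supp)] <- NA_integer_
  point$node.label <- supp
  point
}

#' Collapse weakly supported clades
#'
#' Contracts every internal edge whose bootstrap support is below the
#' threshold (the conventional cutoff is 70), producing a multifurcating
#' tree in which every surviving internal edge has support >=
#' `threshold`. Edges without a numeric support (e.g. the root label) are
#' kept.
#'
#' @param tree An [ape::phylo] with supports in `node.label` (as from
#'   [bootstrap_tree()]).
#' @param threshold Minimum support to keep an internal edge (default 70).
#' @return The collapsed [ape::phylo].
#' @export
collapse_low_support <- function(tree, threshold = 70) {
  stopifnot(inherits(tree, "phylo"))
  supp <- node_supports(tree)
  if (all(is.na(supp))) return(tree)
  # phangorn::pruneTree collapses edges below the cutoff but requires
  # numeric labels everywhere; pad missing ones (root) so they survive.
  padded <- tree
  lab <- supp
  lab[is.na(lab)] <- 100
  padded$node.label <- lab
  if (is.null(padded$edge.length))
    padded$edge.length <- rep(1, nrow(padded$edge))
  out <- phangorn::pruneTree(padded, threshold)
  out
}

#' Bipartitions (splits) of a tree
#'
#' Every internal edge of an unrooted tree splits the taxa in two; this
#' returns, for each internal edge, the side not containing the first tip
#' label (a canonical representation), as sorted character vectors of
#' taxon labels. Trivial splits (single leaves) are excluded.
#'
#' @param tree An [ape::phylo].
#' @return List of character vectors (possibly empty for a star tree).
#' @export
tree_splits <- function(tree) {
  stopifnot(inherits(tree, "phylo"))
  tips <- tree$tip.label
  parts <- ape::prop.part(tree)
  ref <- tips[1L]
  out <- lapply(parts, function(idx) sort(tips[idx]))
  # canonical side: the one excluding the reference taxon
  out <- lapply(out, function(side)
    if (ref %in% side) sort(setdiff(tips, side)) else side)
  out <- out[vapply(out, function(s)
    length(s) >= 2L && length(s) <= length(tips) - 2L, logical(1))]
  unique(out)
}
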