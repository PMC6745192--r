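# Placement of a focal taxon among labelled groups, and the paired
# before/after AT-column-removal convergence test.

#' Validate a taxon-to-group map against an alignment or tree
#'
#' @param groups Named character vector (`taxon -> group label`).
#' @param taxa Taxa that must all be assigned.
#' @return `groups`, invisibly.
#' @export
validate_groups <- function(groups, taxa) {
  if (is.null(names(groups))) stop("'groups' must be named by taxon")
  missing <- setdiff(taxa, names(groups))
  if (length(missing))
    stop("taxa without a group label: ", paste(missing, collapse = ", "))
  invisible(groups)
}

#' Group placement of a focal taxon in a (collapsed) tree
#'
#' Operationalises "where does the focal taxon sit" as an explicit rule:
#' among all bipartition sides of the unrooted tree that contain the
#' focal taxon together with at least one other taxon, take the smallest
#' (the smallest informative clade around the focal leaf; ties broken by
#' the lexicographically first member set). The placement label is the
#' group holding a strict majority of that clade's non-focal members;
#' any tie or absent majority yields `"unresolved"`. The report also
#' tallies, per group, the taxa on the far side of the focal leaf's own
#' edge (the attachment bipartition).
#'
#' @param tree An [ape::phylo], typically after [collapse_low_support()].
#' @param focal Focal taxon label (must be a tip).
#' @param groups Named character vector mapping every tip to a group.
#' @return A `placement_report`: list with `focal`, `label`, `clade`
#'   (members of the smallest informative clade), `clade_tally` (named
#'   counts of non-focal members per group), `attachment_tally`, and
#'   `rule` (a short versioned description of the placement rule).
#' @export
placement <- function(tree, focal, groups) {
  stopifnot(inherits(tree, "phylo"))
  tips <- tree$tip.label
  if (!focal %in% tips) stop("focal taxon '", focal, "' not in tree")
  validate_groups(groups, tips)

  # candidate sides: both sides of every non-trivial split plus, as
  # fallback, the all-but-one-leaf sides of leaf edges (covers star trees)
  splits <- tree_splits(tree)
  sides <- c(splits, lapply(splits, function(s) sort(setdiff(tips, s))))
  sides <- c(sides, lapply(tips, function(t) sort(setdiff(tips, t))))
  sides <- unique(sides[vapply(sides, function(s)
    focal %in% s && length(s) >= 2L, logical(1))])
  sizes <- lengths(sides)
  smallest <- sides[sizes == min(sizes)]
  keys <- vapply(smallest, paste, character(1), collapse = "\r")
  clade <- smallest[[order(keys)[1L]]]

  tally <- function(members) {
    g <- groups[setdiff(members, focal)]
    tab <- table(g)
    stats::setNames(as.integer(tab), names(tab))
  }
  clade_tally <- tally(clade)
  label <- majority_label(clade_tally)
  structure(list(
    focal = focal,
    label = label,
    clade = clade,
    clade_tally = clade_tally,
    attachment_tally = tally(tips),
    rule = paste("smallest-informative-clade strict-majority rule v1:",
                 "smallest bipartition side containing the focal taxon",
                 "plus >=1 other taxon; label = group with a strict",
                 "majority of its non-focal members, else 'unresolved'")),
    class = "placement_report")
}

majority_label <- function(tally) {
  if (length(tally) == 0L) return("unresolved")
  top <- max(tally)
  if (sum(tally == top) > 1L || top <= sum(tally) / 2)
    return("unresolved")
  names(tally)[which.max(tally)]
}

#' @export
print.placement_report <- function(x, ...) {
  cat("Placement of '", x$focal, "': ", x$label, "\n", sep = "")
  cat("  smallest informative clade (", length(x$clade), " taxa): ",
      paste(utils::head(x$clade, 8L), collapse = ", "),
      if (length(x$clade) > 8L) ", ..." else "", "\n", sep = "")
  cat("  non-focal tally:",
      paste(names(x$clade_tally), x$clade_tally, sep = "=",
            collapse = ", "), "\n")
  invisible(x)
}

#' AT-column-removal convergence test
#'
#' Runs the full diagnostic for one focal taxon: (1) bootstrap NJ tree
#' from the unfiltered alignment, collapse weak clades, read off the
#' focal placement; (2) remove all columns in which the focal taxon has
#' an A or T ([filter_at_columns()]) and repeat; (3) report whether the
#' placement label moved. A focal taxon whose grouping was driven by
#' shared AT-richness rather than ancestry typically moves (or dissolves
#' into an unresolved placement) once its A/T columns are removed.
#'
#' @param aln An alignment ([as_alignment()]).
#' @param focal Focal taxon label.
#' @param groups Named character vector mapping every taxon to a group.
#' @param model Distance model, see [pairwise_distance()].
#' @param replicates Bootstrap replicates (default 100).
#' @param seed Integer seed (default 1).
#' @param support_threshold Collapse threshold (default 70).
#' @param min_columns If fewer filtered columns survive, a warning is
#'   recorded in the report (default 50).
#' @return A `convergence_report`: list with `before` and `after`
#'   [placement()] reports, `moved`, column counts, parameters, and any
#'   `warnings`.
#' @export
convergence_test <- function(aln, focal, groups, model = "JC69",
                             replicates = 100L, seed = 1L,
                             support_threshold = 70, min_columns = 50L) {
  aln <- as_alignment(aln)
  validate_groups(groups, rownames(aln))
  if (!focal %in% rownames(aln))
    stop("focal taxon '", focal, "' not in alignment")
  warnings <- character(0)

  run_one <- function(a, run_seed) {
    tree <- bootstrap_tree(a, model = model, replicates = replicates,
                           seed = run_seed)
    placement(collapse_low_support(tree, support_threshold), focal,
              groups)
  }
  before <- run_one(aln, seed)
  filtered <- filter_at_columns(aln, focal)
  if (ncol(filtered) < min_columns)
    warnings <- c(warnings, paste0(
      "only ", ncol(filtered), " columns survive the A/T filter ",
      "(minimum ", min_columns, "); filtered placement may be unstable"))
  after <- run_one(filtered, seed + 1L)

  structure(list(
    focal = focal, before = before, after = after,
    moved = !identical(before$label, after$label),
    n_columns_before = ncol(aln), n_columns_after = ncol(filtered),
    params = list(model = model, replicates = as.integer(replicates),
                  seed = as.integer(seed),
                  support_threshold = support_threshold,
                  min_columns = as.integer(min_columns)),
    warnings = warnings),
    class = "convergence_report")
}

#' @export
print.convergence_report <- function(x, ...) {
  cat("AT-column-removal convergence test for '", x$focal, "'\n",
      sep = "")
  cat("  before filter (", x$n_columns_before, " columns): ",
      x$before$label, "\n", sep = "")
  cat("  after filter  (", x$n_columns_after, " columns): ",
      x$after$label, "\n", sep = "")
  cat("  placement moved:", if (x$moved) "YES" else "no", "\n")
  for (w in x$warnings) cat("  warning:", w, "\n")
  invisible(x)
}
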