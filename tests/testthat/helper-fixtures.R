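# Shared fixtures: random sequences/alignments and the brute-force
# least-squares topology oracle used to validate neighbor joining.

rand_seq <- function(n, at = 0.5, seed = NULL) {
  draw <- function() paste0(
    sample(c("A", "C", "G", "T"), n, replace = TRUE,
           prob = c(at / 2, (1 - at) / 2, (1 - at) / 2, at / 2)),
    collapse = "")
  if (is.null(seed)) draw() else withr::with_seed(seed, draw())
}

rand_alignment <- function(ntaxa, ncols, seed, gap_prob = 0) {
  withr::with_seed(seed, {
    chars <- c("A", "C", "G", "T")
    m <- matrix(sample(chars, ntaxa * ncols, replace = TRUE),
                nrow = ntaxa)
    if (gap_prob > 0) {
      gaps <- matrix(stats::runif(ntaxa * ncols) < gap_prob, ntaxa)
      m[gaps] <- "-"
    }
    rownames(m) <- paste0("t", seq_len(ntaxa))
    as_alignment(m)
  })
}

# Alignment of rows derived from one ancestor by random substitution,
# so pairwise divergence stays below saturation.
rand_related_alignment <- function(ntaxa, ncols, seed, sub_prob = 0.15) {
  withr::with_seed(seed, {
    chars <- c("A", "C", "G", "T")
    anc <- sample(chars, ncols, replace = TRUE)
    m <- t(vapply(seq_len(ntaxa), function(i) {
      mut <- stats::runif(ncols) < sub_prob
      out <- anc
      out[mut] <- sample(chars, sum(mut), replace = TRUE)
      out
    }, character(ncols)))
    rownames(m) <- paste0("t", seq_len(ntaxa))
    as_alignment(m)
  })
}

# Random additive distance matrix plus its generating (unrooted) tree.
rand_additive <- function(ntaxa, seed) {
  withr::with_seed(seed, {
    tr <- ape::rtree(ntaxa, br = function(n) stats::runif(n, 0.2, 1))
    tr <- ape::unroot(tr)
    list(tree = tr, dist = ape::cophenetic.phylo(tr))
  })
}

# Least-squares branch-length fit of a fixed topology to a distance
# matrix; returns the residual sum of squares.
ls_rss <- function(topo, d) {
  tips <- topo$tip.label
  pairs <- t(utils::combn(length(tips), 2L))
  A <- matrix(0, nrow(pairs), nrow(topo$edge))
  for (r in seq_len(nrow(pairs))) {
    np <- ape::nodepath(topo, pairs[r, 1L], pairs[r, 2L])
    for (i in seq_len(length(np) - 1L)) {
      e <- which((topo$edge[, 1L] == np[i] & topo$edge[, 2L] == np[i + 1L]) |
                 (topo$edge[, 1L] == np[i + 1L] & topo$edge[, 2L] == np[i]))
      A[r, e] <- 1
    }
  }
  dv <- d[cbind(tips[pairs[, 1L]], tips[pairs[, 2L]])]
  sum(stats::lm.fit(A, dv)$residuals^2)
}

# Exhaustive search over all unrooted topologies: the tree whose
# least-squares fit to `d` is best.
best_topology <- function(d) {
  tips <- rownames(d)
  topos <- phangorn::allTrees(length(tips), rooted = FALSE,
                              tip.label = tips)
  rss <- vapply(topos, ls_rss, numeric(1), d = d)
  topos[[which.min(rss)]]
}

same_topology <- function(t1, t2) {
  phangorn::RF.dist(ape::unroot(t1), ape::unroot(t2)) == 0
}
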