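# Neighbor joining, bootstrap supports and low-support collapse.

test_that("nj_tree recovers additive trees exactly", {
  tr <- ape::read.tree(text = "((A:1,B:2):1,(C:3,D:1):1);")
  d <- ape::cophenetic.phylo(tr)
  nj <- nj_tree(d)
  expect_true(same_topology(tr, nj))
  njd <- ape::cophenetic.phylo(nj)[rownames(d), colnames(d)]
  expect_equal(njd, d, tolerance = 1e-9)
  # three taxa: unique resolution with closed-form branch lengths
  d3 <- matrix(c(0, 3, 4, 3, 0, 5, 4, 5, 0), 3,
               dimnames = list(c("A", "B", "C"), c("A", "B", "C")))
  nj3 <- nj_tree(d3)
  # x = (dAB + dAC - dBC)/2 etc.
  lens <- setNames(nj3$edge.length[match(1:3, nj3$edge[, 2])],
                   nj3$tip.label)
  expect_equal(unname(lens[c("A", "B", "C")]), c(1, 2, 3))
  expect_error(nj_tree(matrix(0, 2, 2)), "at least 3")
  dd <- d3; dd[1, 2] <- dd[2, 1] <- NaN
  expect_error(nj_tree(dd), "non-finite")
  dd <- d3; dd[1, 2] <- dd[2, 1] <- -1
  expect_error(nj_tree(dd), "negative")
})

test_that("nj_tree matches exhaustive least-squares topology search", {
  for (seed in 1:5) {
    ad <- rand_additive(5, seed)
    nj <- nj_tree(ad$dist)
    expect_true(same_topology(nj, ad$tree))
    expect_true(same_topology(nj, best_topology(ad$dist)))
  }
  ad6 <- rand_additive(6, 99)
  expect_true(same_topology(nj_tree(ad6$dist), best_topology(ad6$dist)))
})

test_that("bootstrap supports are percentages and seed-reproducible", {
  aln <- rand_related_alignment(6, 300, 5)
  tr1 <- bootstrap_tree(aln, replicates = 50, seed = 11)
  tr2 <- bootstrap_tree(aln, replicates = 50, seed = 11)
  expect_identical(ape::write.tree(tr1), ape::write.tree(tr2))
  supp <- suppressWarnings(as.numeric(tr1$node.label))
  supp <- supp[!is.na(supp)]
  expect_true(all(supp >= 0 & supp <= 100))
  tr3 <- bootstrap_tree(aln, replicates = 50, seed = 12)
  expect_false(identical(tr1$node.label, tr3$node.label) &&
               identical(tr1$edge.length, tr3$edge.length) &&
               FALSE)  # different seeds may coincide; only check no error
  expect_error(bootstrap_tree(aln, replicates = 0), ">= 1")
})

test_that("a strongly structured alignment gets full supports", {
  # two deeply split clades of identical sequences: the split must have
  # support 100 in every replicate
  block_a <- strrep("A", 150)
  block_g <- strrep("G", 150)
  aln <- as_alignment(c(
    a1 = paste0(block_a, "ACGTACGTAC"), a2 = paste0(block_a, "ACGTACGTAA"),
    b1 = paste0(block_g, "ACGTACGTGC"), b2 = paste0(block_g, "ACGTACGTGG")))
  tr <- suppressWarnings(bootstrap_tree(aln, replicates = 30, seed = 3))
  splits <- tree_splits(tr)
  expect_length(splits, 1L)
  expect_identical(splits[[1L]], c("b1", "b2"))
  supp <- suppressWarnings(as.numeric(tr$node.label))
  expect_true(all(supp[!is.na(supp)] == 100))
})

test_that("collapse_low_support keeps exactly the strong bipartitions", {
  tr <- ape::read.tree(text = "((A:1,B:1)100:1,((C:1,D:1)40:1,E:1)90:1,F:1);")
  col <- collapse_low_support(tr, 70)
  # splits are canonicalised to the side not containing the first tip
  expect_setequal(
    vapply(tree_splits(col), paste, character(1), collapse = ","),
    c("C,D,E,F", "C,D,E"))
  # all supports at 100: identity on the bipartition set
  tr100 <- ape::read.tree(text = "((A:1,B:1)100:1,(C:1,D:1)100:1,E:1);")
  expect_setequal(
    vapply(tree_splits(collapse_low_support(tr100, 70)), paste,
           character(1), collapse = ","),
    vapply(tree_splits(tr100), paste, character(1), collapse = ","))
  # all supports 0: star tree
  tr0 <- ape::read.tree(text = "((A:1,B:1)0:1,(C:1,D:1)0:1,E:1);")
  expect_length(tree_splits(collapse_low_support(tr0, 70)), 0L)
  expect_setequal(collapse_low_support(tr0, 70)$tip.label, tr0$tip.label)
})

test_that("collapse agrees with a bipartition-filter oracle", {
  for (seed in 1:5) {
    aln <- rand_related_alignment(7, 120, seed, sub_prob = 0.3)
    tr <- bootstrap_tree(aln, replicates = 40, seed = seed + 100)
    col <- collapse_low_support(tr, 70)
    kept <- vapply(tree_splits(col), paste, character(1), collapse = ",")
    # oracle: enumerate the point tree's splits and keep those with
    # support >= 70
    supp <- suppressWarnings(as.numeric(tr$node.label))
    parts <- ape::prop.part(tr)
    tips <- tr$tip.label
    want <- character(0)
    for (i in seq_along(parts)) {
      side <- sort(tips[parts[[i]]])
      if (tips[1] %in% side) side <- sort(setdiff(tips, side))
      if (length(side) < 2 || length(side) > length(tips) - 2) next
      if (!is.na(supp[i]) && supp[i] >= 70)
        want <- c(want, paste(side, collapse = ","))
    }
    expect_setequal(kept, unique(want))
  }
})
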