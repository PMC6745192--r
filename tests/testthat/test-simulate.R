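# Synthetic-data generators: determinism, stationarity and the
# statistical structure each downstream analysis assumes.

test_that("every generator is byte-identical under a fixed seed", {
  sc <- convergence_scenario(seq_length = 200, seed = 4)
  a1 <- simulate_alignment(sc$scenario)$alignment
  a2 <- simulate_alignment(sc$scenario)$alignment
  expect_identical(unclass(a1), unclass(a2))

  g1 <- simulate_genome(length = 5000, seed = 9)
  g2 <- simulate_genome(length = 5000, seed = 9)
  expect_identical(g1, g2)

  cs <- coverage_scenario(seed = 6)
  d1 <- simulate_depth(cs, g1$sequence)
  d2 <- simulate_depth(cs, g1$sequence)
  expect_identical(d1$depth$depth, d2$depth$depth)
  expect_identical(d1$inserts, d2$inserts)

  h1 <- simulate_kmer_histogram(1e5, 30, seed = 2)
  h2 <- simulate_kmer_histogram(1e5, 30, seed = 2)
  expect_identical(h1, h2)
  # generators do not disturb the caller's RNG state
  withr::with_seed(1, {
    before <- runif(1)
  })
  withr::with_seed(1, {
    invisible(simulate_kmer_histogram(1e4, 20, seed = 77))
    expect_equal(runif(1), before)
  })
})

test_that("zero branch lengths copy the root sequence to every tip", {
  sc <- evolution_scenario("((A:0,B:0):0,(C:0,D:0):0);", 300, seed = 5)
  aln <- simulate_alignment(sc)$alignment
  expect_equal(nrow(unique(unclass(aln))), 1L)
})

test_that("long branches reach their equilibrium composition", {
  shifted <- c(A = 0.44, C = 0.06, G = 0.06, T = 0.44)
  sc <- evolution_scenario(
    "(X:50,Y:0.001);", 20000, seed = 2,
    branch_overrides = list(X = list(freq = shifted)))
  aln <- simulate_alignment(sc)$alignment
  x <- unclass(aln)["X", ]
  for (b in names(shifted)) {
    se <- sqrt(shifted[b] * (1 - shifted[b]) / 20000)
    expect_lt(abs(mean(x == b) - shifted[b]), 3 * se)
  }
})

test_that("the convergence scenario drives focal rows AT-rich", {
  ats <- vapply(1:4, function(s) {
    aln <- simulate_alignment(convergence_scenario(seed = s)$scenario)$alignment
    at_content(paste0(unclass(aln)["Focal", ], collapse = ""))
  }, numeric(1))
  expect_true(all(ats > 0.8 & ats < 0.95))
})

test_that("simulated distances are consistent with branch lengths", {
  # balanced homogeneous tree: JC69 estimates should straddle the true
  # path lengths within 3 standard errors at 10-kb sites
  sc <- evolution_scenario(
    "((A:0.05,B:0.05):0.05,(C:0.05,D:0.05):0.05);", 10000, seed = 13)
  sim <- simulate_alignment(sc)
  d <- pairwise_distance(sim$alignment, "JC69")
  true_d <- ape::cophenetic.phylo(sim$tree)
  for (pair in list(c("A", "B"), c("A", "C"), c("B", "D"))) {
    td <- true_d[pair[1], pair[2]]
    p <- 0.75 * (1 - exp(-4 * td / 3))
    se_d <- sqrt(p * (1 - p) / 10000) / (1 - 4 * p / 3)
    expect_lt(abs(d[pair[1], pair[2]] - td), 3 * se_d)
  }
})

test_that("guide trees must be rooted, binary and measured", {
  expect_error(evolution_scenario("(A:1,B:1,C:1);", 100, seed = 1),
               "binary")
  expect_error(evolution_scenario("((A,B),C);", 100, seed = 1),
               "branch lengths")
  expect_error(evolution_scenario("((A:1,B:1):1,C:1);", 100,
                                  base_freq = c(1, 1, 1, 1), seed = 1),
               "summing to 1")
  expect_error(convergence_scenario(), "seed")
})

test_that("simulate_genome hits its per-kind AT targets", {
  g <- simulate_genome(length = 20000, seed = 17)
  expect_equal(nchar(g$sequence), 20000L)
  fw <- feature_weighted_at(g$sequence, g$features)
  pk <- fw$per_kind
  expect_lt(abs(pk$at[pk$kind == "protein_coding"] - 0.881), 0.02)
  expect_lt(abs(pk$at[pk$kind == "ncRNA"] - 0.775), 0.02)
  expect_lt(abs(pk$at[pk$kind == "intergenic"] - 0.938), 0.02)
  expect_lt(abs(fw$coding_fraction - 0.785), 0.02)
  # features tile the genome without gaps or overlap
  expect_equal(g$features$start[-1],
               g$features$end[-nrow(g$features)])
  expect_equal(g$features$start[1], 0L)
  expect_equal(g$features$end[nrow(g$features)], 20000L)
})

test_that("simulate_depth follows its deterministic curve as noise -> 0", {
  g <- simulate_genome(length = 10000, seed = 23)
  cs0 <- coverage_scenario(dispersion = 0, seed = 24)
  sim <- simulate_depth(cs0, g$sequence)
  prof <- window_profile(g$sequence, sim$depth, 200)
  mu <- sim$windows$mu
  expect_true(all(abs(prof$mean_depth - mu) / mu < 0.01))
  # endpoints: max_depth at the least AT-rich window, min_depth at the most
  expect_equal(mu[which.min(sim$windows$at)], 3000)
  expect_equal(mu[which.max(sim$windows$at)], 17)
})

test_that("paper-scale depth parameters give strongly negative rho", {
  for (s in 1:3) {
    g <- simulate_genome(length = 10000, seed = s)
    sim <- simulate_depth(coverage_scenario(seed = s + 40), g$sequence)
    rep <- at_coverage_report(g$sequence, sim$depth, sim$inserts)
    expect_lte(rep$rho_depth, -0.8)
    expect_lt(rep$rho_insert, -0.5)
  }
})

test_that("a homogeneous-AT genome surfaces the undefined correlation", {
  s <- strrep("AT", 2000)
  sim <- simulate_depth(coverage_scenario(dispersion = 0, seed = 3), s)
  expect_error(at_coverage_report(s, sim$depth), "zero rank variance")
})
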