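# AT profiling, usage tables and the stop-codon probability model.

test_that("at_content counts A+T over called bases only", {
  expect_equal(at_content("ATAT"), 1)
  expect_equal(at_content("GCGC"), 0)
  expect_equal(at_content("ATGC"), 0.5)
  # ambiguity codes and gaps are excluded from the denominator
  expect_equal(at_content("ATGCNNN--RY"), 0.5)
  # case-insensitive, U treated as T
  expect_equal(at_content("augc"), 0.5)
  expect_error(at_content(""), "no unambiguous")
  expect_error(at_content("NNN--"), "no unambiguous")
})

test_that("windowed_at matches independent slice-wise recomputation", {
  expect_equal(windowed_at(strrep("AT", 200), 200)$at, c(1, 1))
  w <- windowed_at(paste0(strrep("A", 200), strrep("G", 200)), 200)
  expect_equal(w$start, c(0L, 200L))
  expect_equal(w$at, c(1, 0))
  s <- rand_seq(1000, at = 0.7, seed = 42)
  w <- windowed_at(s, 200)
  expect_equal(nrow(w), 5L)
  manual <- vapply(w$start, function(st)
    at_content(substr(s, st + 1, st + 200)), numeric(1))
  expect_equal(w$at, manual)
  # trailing partial window dropped by default, kept on request
  s2 <- rand_seq(1050, seed = 1)
  expect_equal(nrow(windowed_at(s2, 200)), 5L)
  wp <- windowed_at(s2, 200, keep_partial = TRUE)
  expect_equal(nrow(wp), 6L)
  expect_equal(wp$end[6L], 1050L)
  expect_warning(out <- windowed_at("ATGC", 200), "longer than")
  expect_equal(nrow(out), 0L)
})

test_that("weighted_at equals at_content of the concatenation", {
  expect_equal(weighted_at(c("ATAT", "GC")), 4 / 6)
  expect_equal(weighted_at("ATGCGG"), at_content("ATGCGG"))
  for (seed in 1:5) {
    recs <- withr::with_seed(seed, vapply(
      sample(5:50, 10), function(n) rand_seq(n, at = runif(1)),
      character(1)))
    expect_equal(weighted_at(recs),
                 at_content(paste0(recs, collapse = "")))
  }
  expect_error(weighted_at(character(0)), "at least one")
})

test_that("codon_usage counts all codons and flags bad lengths", {
  cu <- codon_usage(c(g1 = "ATGATTATTTAA", g2 = "ATGAAA"))
  expect_equal(sum(cu$count), 6L)
  expect_equal(sum(cu$freq), 1)
  expect_equal(cu$count[cu$codon == "ATT"], 2L)
  expect_error(codon_usage(c(ok = "ATGTAA", bad = "ATGA")), "bad")
})

test_that("aa_usage equals codon_usage aggregated by amino acid", {
  au <- aa_usage("ATGATTATTTAA")
  expect_equal(au$freq[au$aa == "M"], 1 / 3)
  expect_equal(au$freq[au$aa == "I"], 2 / 3)
  expect_equal(nrow(au), 20L)
  code <- genetic_code()
  for (seed in 1:3) {
    cds <- withr::with_seed(seed, paste0(
      sample(c("A", "C", "G", "T"), 300, replace = TRUE), collapse = ""))
    cu <- codon_usage(cds, code)
    au <- aa_usage(cds, code)
    nonstop <- cu[cu$aa != "*", ]
    for (a in au$aa[au$count > 0])
      expect_equal(au$count[au$aa == a], sum(nonstop$count[nonstop$aa == a]))
    expect_equal(sum(au$freq), 1)
  }
  expect_error(aa_usage("TAA"), "no non-stop")
})

test_that("expected codon/aa frequencies form proper distributions", {
  for (alpha in c(0, 0.25, 0.5, 0.88, 1)) {
    ec <- expected_codon_freq(at_composition(alpha))
    expect_equal(sum(ec$prob), 1, tolerance = 1e-9)
    expect_true(all(ec$prob >= 0))
  }
  # uniform composition: every codon 1/64, Leu = 6/61 after stop removal
  ea <- expected_aa_freq(base_composition(rep(0.25, 4)))
  expect_equal(ea$prob[ea$aa == "L"], 6 / 61)
  expect_equal(sum(ea$prob), 1)
  # alpha = 1: GC-requiring amino acids impossible
  ea1 <- expected_aa_freq(at_composition(1))
  expect_equal(ea1$prob[ea1$aa %in% c("G", "A", "P")], c(0, 0, 0))
  expect_gt(ea1$prob[ea1$aa == "I"], 0)
  # AT-shifted composition: isoleucine expectation exceeds glycine
  ea88 <- expected_aa_freq(at_composition(0.88))
  expect_gt(ea88$prob[ea88$aa == "I"], ea88$prob[ea88$aa == "G"])
})

test_that("position-specific composition feeds the codon null", {
  m <- rbind(c(0.7, 0.1, 0.1, 0.1),
             c(0.1, 0.7, 0.1, 0.1),
             c(0.1, 0.1, 0.1, 0.7))
  colnames(m) <- c("A", "C", "G", "T")
  ec <- expected_codon_freq(base_composition(m))
  expect_equal(ec$prob[ec$codon == "ACT"], 0.7^3)
  expect_equal(ec$prob[ec$codon == "TGA"], 0.1 * 0.1 * 0.1)
  expect_equal(sum(ec$prob), 1, tolerance = 1e-9)
})

test_that("stop_probability matches the closed form and Monte Carlo", {
  # closed form alpha^2/4 - alpha^3/8 vs 64-codon enumeration
  alphas <- seq(0, 1, length.out = 101)
  for (a in alphas)
    expect_equal(stop_probability(a), a^2 / 4 - a^3 / 8,
                 tolerance = 1e-12)
  expect_equal(stop_probability(0.88), 0.108416, tolerance = 1e-9)
  expect_equal(stop_probability(0), 0)
  expect_equal(stop_probability(1), 0.125)
  # strictly increasing on [0, 1]
  vals <- vapply(alphas, stop_probability, numeric(1))
  expect_true(all(diff(vals) > 0))
  # sampling oracle on an asymmetric composition
  p <- c(A = 0.5, C = 0.1, G = 0.15, T = 0.25)
  comp <- base_composition(p)
  p_stop <- stop_probability(comp)
  n <- 1e6
  hits <- withr::with_seed(99, {
    draws <- matrix(sample(names(p), 3 * n, replace = TRUE, prob = p),
                    ncol = 3)
    codons <- paste0(draws[, 1], draws[, 2], draws[, 3])
    sum(codons %in% c("TAA", "TAG", "TGA"))
  })
  se <- sqrt(p_stop * (1 - p_stop) / n)
  expect_lt(abs(hits / n - p_stop), 3 * se)
})

test_that("expected_stop_spacing floors the reciprocal stop rate", {
  expect_identical(expected_stop_spacing(0.88), 9L)
  expect_identical(expected_stop_spacing(1), 8L)
  expect_identical(expected_stop_spacing(base_composition(rep(0.25, 4))),
                   21L)
  expect_error(expected_stop_spacing(0), "zero")
})

test_that("genetic codes validate and support non-canonical variants", {
  code <- genetic_code()
  expect_setequal(code$stop_codons, c("TAA", "TAG", "TGA"))
  # TAG reassigned to tryptophan, as in some AT-rich plastomes
  tab <- Biostrings::getGeneticCode("11")
  tab["TAG"] <- "W"
  code2 <- genetic_code(codon_to_aa = tab)
  expect_setequal(code2$stop_codons, c("TAA", "TGA"))
  expect_gt(stop_probability(at_composition(0.88), code),
            stop_probability(at_composition(0.88), code2))
  expect_error(genetic_code(codon_to_aa = tab[-1]), "64")
})

test_that("feature_weighted_at summarises per kind and coding fraction", {
  genome <- paste0(strrep("AT", 150), strrep("GC", 100), strrep("A", 100))
  feats <- data.frame(
    seq_id = "g", start = c(0, 300, 500), end = c(300, 500, 600),
    strand = "+", kind = c("protein_coding", "intergenic", "ncRNA"),
    name = c("gene1", "igs1", "rrn1"))
  fw <- feature_weighted_at(genome, feats)
  pk <- fw$per_kind
  expect_equal(pk$at[pk$kind == "protein_coding"], 1)
  expect_equal(pk$at[pk$kind == "intergenic"], 0)
  expect_equal(pk$at[pk$kind == "ncRNA"], 1)
  expect_equal(fw$coding_fraction, 400 / 600)
  # overlapping coding features are counted once
  feats2 <- rbind(feats, data.frame(
    seq_id = "g", start = 100, end = 350, strand = "+",
    kind = "protein_coding", name = "gene2"))
  expect_equal(feature_weighted_at(genome, feats2)$coding_fraction,
               450 / 600)
  expect_error(feature_weighted_at(genome, transform(feats, kind = "x")),
               "kind")
})
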