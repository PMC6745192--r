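# Synthetic-data generators: alignments under branch-specific HKY
# models, AT-dependent depth and insert tracks, composite genomes with
# feature tables, and k-mer spectra. Every generator takes an explicit
# seed and leaves the caller's RNG state untouched.

dna_bases <- c("A", "C", "G", "T")

check_freq <- function(freq, what = "base frequencies") {
  if (length(freq) != 4L || any(freq < 0) || abs(sum(freq) - 1) > 1e-9)
    stop(what, " must be 4 non-negative numbers summing to 1")
  if (is.null(names(freq))) names(freq) <- dna_bases
  freq[dna_bases]
}

# HKY rate matrix scaled to one expected substitution per unit time at
# equilibrium.
hky_rate_matrix <- function(freq, kappa = 2) {
  freq <- check_freq(freq)
  Q <- matrix(0, 4, 4, dimnames = list(dna_bases, dna_bases))
  transitions <- rbind(c("A", "G"), c("G", "A"), c("C", "T"), c("T", "C"))
  for (i in dna_bases) for (j in dna_bases) {
    if (i == j) next
    ti <- any(transitions[, 1] == i & transitions[, 2] == j)
    Q[i, j] <- if (ti) kappa * freq[j] else freq[j]
  }
  diag(Q) <- -rowSums(Q)
  scale <- -sum(freq * diag(Q))
  Q / scale
}

#' Specification of a sequence-evolution simulation
#'
#' Bundles a rooted binary guide tree with the substitution model used on
#' each branch: an HKY model with a global transition/transversion ratio
#' `kappa` and, per branch, an equilibrium base-frequency vector and a
#' rate multiplier. Branch-specific equilibria are what allow two distant
#' lineages to drift independently towards extreme AT content -- the
#' nonhomogeneous setting in which compositional attraction arises.
#'
#' @param tree A rooted, binary [ape::phylo] or a Newick string, with
#'   branch lengths in substitutions/site.
#' @param seq_length Number of sites to simulate.
#' @param base_freq Root and default branch equilibrium frequencies
#'   (A, C, G, T); default uniform.
#' @param kappa Transition/transversion rate ratio (default 2).
#' @param branch_overrides Named list; names are tip (or internal node)
#'   labels, each value a list with optional `freq` (length-4) and
#'   `rate` (> 0) applying to the branch leading to that node.
#' @param seed Integer seed (mandatory).
#' @return An `evolution_scenario` object.
#' @export
evolution_scenario <- function(tree, seq_length, base_freq = rep(0.25, 4),
                               kappa = 2, branch_overrides = list(),
                               seed) {
  if (missing(seed)) stop("an explicit seed is required")
  if (is.character(tree)) tree <- ape::read.tree(text = tree)
  stopifnot(inherits(tree, "phylo"))
  if (!ape::is.binary(tree) || !ape::is.rooted(tree))
    stop("guide tree must be rooted and binary")
  if (is.null(tree$edge.length)) stop("guide tree needs branch lengths")
  base_freq <- check_freq(base_freq)
  for (nm in names(branch_overrides)) {
    ov <- branch_overrides[[nm]]
    if (!is.null(ov$freq)) branch_overrides[[nm]]$freq <- check_freq(ov$freq)
    if (!is.null(ov$rate) && ov$rate <= 0) stop("rate multiplier must be > 0")
  }
  structure(list(tree = tree, seq_length = as.integer(seq_length),
                 base_freq = base_freq, kappa = kappa,
                 branch_overrides = branch_overrides,
                 seed = as.integer(seed)),
            class = "evolution_scenario")
}

# Label of a node for override lookup: tip label or node label.
node_label <- function(tree, node) {
  ntip <- length(tree$tip.label)
  if (node <= ntip) tree$tip.label[node]
  else if (!is.null(tree$node.label)) tree$node.label[node - ntip]
  else NA_character_
}

#' Simulate an alignment along a guide tree
#'
#' Draws the root sequence from the scenario's base frequencies and
#' evolves it along each branch under HKY with that branch's equilibrium
#' frequencies and rate multiplier, using the exact transition
#' probabilities `expm(Q * t)` applied site-wise. Sites are independent;
#' no indels are generated, so the rows are an alignment by construction.
#'
#' @param scenario An [evolution_scenario()].
#' @return List with `alignment` (an [as_alignment()] matrix over the
#'   tips) and `tree` (the guide tree).
#' @export
simulate_alignment <- function(scenario) {
  stopifnot(inherits(scenario, "evolution_scenario"))
  tree <- scenario$tree
  ntip <- length(tree$tip.label)
  nnode <- ntip + tree$Nnode
  L <- scenario$seq_length
  root <- ntip + 1L
  edge_order <- order(tree$edge[, 1L])  # parents before children holds
  # precompute P matrices per edge
  P_list <- vector("list", nrow(tree$edge))
  for (e in seq_len(nrow(tree$edge))) {
    child <- tree$edge[e, 2L]
    lab <- node_label(tree, child)
    ov <- if (!is.na(lab)) scenario$branch_overrides[[lab]] else NULL
    freq <- if (!is.null(ov$freq)) ov$freq else scenario$base_freq
    rate <- if (!is.null(ov$rate)) ov$rate else 1
    t <- tree$edge.length[e] * rate
    Q <- hky_rate_matrix(freq, scenario$kappa)
    P <- as.matrix(Matrix::expm(Q * t))
    P[P < 0] <- 0
    P <- P / rowSums(P)
    P_list[[e]] <- P
  }
  seqs <- with_local_seed(scenario$seed, {
    states <- matrix(NA_integer_, nnode, L)
    states[root, ] <- sample.int(4L, L, replace = TRUE,
                                 prob = scenario$base_freq)
    # preorder: process edges so that parents are simulated first
    done <- rep(FALSE, nnode); done[root] <- TRUE
    pending <- seq_len(nrow(tree$edge))
    while (length(pending)) {
      ready <- pending[done[tree$edge[pending, 1L]]]
      if (!length(ready)) stop("guide tree edges are not connected")
      for (e in ready) {
        parent <- tree$edge[e, 1L]; child <- tree$edge[e, 2L]
        P <- P_list[[e]]
        child_states <- integer(L)
        for (s in 1:4) {
          idx <- which(states[parent, ] == s)
          if (length(idx))
            child_states[idx] <- sample.int(4L, length(idx),
                                            replace = TRUE, prob = P[s, ])
        }
        states[child, ] <- child_states
        done[child] <- TRUE
      }
      pending <- setdiff(pending, ready)
    }
    states[seq_len(ntip), , drop = FALSE]
  })
  aln <- matrix(dna_bases[seqs], nrow = ntip,
                dimnames = list(tree$tip.label, NULL))
  list(alignment = as_alignment(aln), tree = tree)
}

balanced_newick <- function(labels, tip_len, internal_len) {
  build <- function(lab) {
    if (length(lab) == 1L) return(paste0(lab, ":", tip_len))
    half <- length(lab) %/% 2L
    paste0("(", build(lab[seq_len(half)]), ",",
           build(lab[-seq_len(half)]), "):", internal_len)
  }
  build(labels)
}

#' Default compositional-attraction scenario
#'
#' A balanced 16-taxon tree of two clades, A and B. One tip in each clade
#' (`Focal` in A, `Attractor` in B) evolves on its terminal branch at an
#' elevated substitution rate towards a strongly AT-shifted equilibrium
#' (`p_A = p_T = at_shift/2`); all other branches use the background
#' composition. The two shifted tips are phylogenetically distant, so any
#' grouping of them in a reconstructed tree is artifactual -- the
#' signature this package's convergence test is designed to detect.
#'
#' @param seq_length Alignment length in sites (default 1000).
#' @param at_shift Equilibrium AT content of the shifted branches
#'   (default 0.88).
#' @param rate_mult Rate multiplier of the shifted branches (default 20).
#' @param tip_len,internal_len Branch lengths in substitutions/site
#'   (defaults 0.1 and 0.05).
#' @param kappa Transition/transversion ratio (default 2).
#' @param seed Integer seed (mandatory).
#' @return List with the [evolution_scenario()] (`scenario`), the focal
#'   and attractor labels, and `groups` (taxon -> clade label, suitable
#'   for [convergence_test()]).
#' @export
convergence_scenario <- function(seq_length = 1000L, at_shift = 0.88,
                                 rate_mult = 20, tip_len = 0.1,
                                 internal_len = 0.05, kappa = 2, seed) {
  if (missing(seed)) stop("an explicit seed is required")
  a_labs <- c(paste0("A", 1:7), "Focal")
  b_labs <- c(paste0("B", 1:7), "Attractor")
  nwk <- paste0("(", balanced_newick(a_labs, tip_len, internal_len), ",",
                balanced_newick(b_labs, tip_len, internal_len), ");")
  shifted <- c(A = at_shift / 2, C = (1 - at_shift) / 2,
               G = (1 - at_shift) / 2, T = at_shift / 2)
  scenario <- evolution_scenario(
    nwk, seq_length = seq_length, kappa = kappa, seed = seed,
    branch_overrides = list(
      Focal = list(freq = shifted, rate = rate_mult),
      Attractor = list(freq = shifted, rate = rate_mult)))
  groups <- stats::setNames(
    c(rep("cladeA", length(a_labs)), rep("cladeB", length(b_labs))),
    c(a_labs, b_labs))
  list(scenario = scenario, focal = "Focal", attractor = "Attractor",
       groups = groups)
}

#' Specification of an AT-dependent coverage simulation
#'
#' Parameters of the depth and insert-size model used by
#' [simulate_depth()]. Window mean depth decays exponentially in window
#' AT content, calibrated so the least AT-rich window gets `max_depth`
#' and the most AT-rich gets `min_depth`; per-position depths are
#' negative-binomial around the window mean. Insert sizes fall linearly
#' from `insert_low_at` at the least AT-rich window to `insert_high_at`
#' at the most AT-rich. The exponential form is a modelling choice: the
#' PCR-dropout mechanism motivating it is only characterised by its
#' endpoints, not by a curve.
#'
#' @param max_depth Mean depth of the least AT-rich window (default 3000).
#' @param min_depth Mean depth of the most AT-rich window (default 17).
#' @param decay_shape Exponential shape (per unit AT; default 8; larger =
#'   faster drop at low AT).
#' @param dispersion Negative-binomial overdispersion `d` with variance
#'   `mu + d mu^2`; `0` means deterministic rounded means (default 0.1).
#' @param insert_low_at,insert_high_at Mean insert size (bp) at the
#'   lowest/highest window AT (defaults 300 and 200).
#' @param insert_sd Within-window insert-size standard deviation
#'   (default 10 bp).
#' @param pairs_per_window Read pairs whose insert sizes are emitted per
#'   window (default 20).
#' @param window Window width in bp (default 200).
#' @param seed Integer seed (mandatory).
#' @return A `coverage_scenario` object.
#' @export
coverage_scenario <- function(max_depth = 3000, min_depth = 17,
                              decay_shape = 8, dispersion = 0.1,
                              insert_low_at = 300, insert_high_at = 200,
                              insert_sd = 10, pairs_per_window = 20L,
                              window = 200L, seed) {
  if (missing(seed)) stop("an explicit seed is required")
  if (!(max_depth >= min_depth) || min_depth <= 0)
    stop("need max_depth >= min_depth > 0")
  if (decay_shape <= 0) stop("'decay_shape' must be > 0")
  if (dispersion < 0) stop("'dispersion' must be >= 0")
  structure(list(max_depth = max_depth, min_depth = min_depth,
                 decay_shape = decay_shape, dispersion = dispersion,
                 insert_low_at = insert_low_at,
                 insert_high_at = insert_high_at, insert_sd = insert_sd,
                 pairs_per_window = as.integer(pairs_per_window),
                 window = as.integer(window), seed = as.integer(seed)),
            class = "coverage_scenario")
}

#' Simulate an AT-biased depth track and insert sizes
#'
#' Computes the window AT profile of `seq`, maps it through the
#' scenario's depth curve
#' `mu(AT) = min + (max - min) * (e^{-s(AT - ATmin)} - e^{-s dAT}) /
#' (1 - e^{-s dAT})` (which hits `max_depth` at the observed minimum
#' window AT and `min_depth` at the maximum), draws per-position depths
#' negative-binomially around the window mean, and draws per-window read
#' pairs whose insert sizes fall linearly with AT.
#'
#' @param scenario A [coverage_scenario()].
#' @param seq Reference sequence (character or `DNAString`); must span at
#'   least one full window and vary in AT across windows.
#' @return List with `depth` (a `depth_track`), `inserts` (data frame
#'   `ref`, `midpoint`, `size`) and `windows` (the window table with the
#'   deterministic mean depth `mu`).
#' @export
simulate_depth <- function(scenario, seq) {
  stopifnot(inherits(scenario, "coverage_scenario"))
  s <- norm_seq(seq)
  if (length(s) != 1L) stop("'seq' must be a single sequence")
  at <- windowed_at(s, window = scenario$window)
  if (nrow(at) == 0L) stop("sequence shorter than one window")
  a <- at$at
  a_min <- min(a); a_max <- max(a)
  if (a_max > a_min) {
    sdecay <- scenario$decay_shape
    e_full <- exp(-sdecay * (a_max - a_min))
    mu <- scenario$min_depth + (scenario$max_depth - scenario$min_depth) *
      (exp(-sdecay * (a - a_min)) - e_full) / (1 - e_full)
  } else {
    mu <- rep(scenario$max_depth, length(a))
  }
  at$mu <- mu
  ins_mean <- if (a_max > a_min) {
    scenario$insert_low_at + (scenario$insert_high_at -
      scenario$insert_low_at) * (a - a_min) / (a_max - a_min)
  } else rep(scenario$insert_low_at, length(a))

  out <- with_local_seed(scenario$seed, {
    depth <- unlist(lapply(seq_len(nrow(at)), function(i) {
      w <- at$end[i] - at$start[i]
      if (scenario$dispersion == 0) rep(round(mu[i]), w)
      else stats::rnbinom(w, size = 1 / scenario$dispersion, mu = mu[i])
    }))
    npairs <- scenario$pairs_per_window
    inserts <- do.call(rbind, lapply(seq_len(nrow(at)), function(i) {
      size <- pmax(50, stats::rnorm(npairs, ins_mean[i],
                                    scenario$insert_sd))
      data.frame(ref = "sim",
                 midpoint = round(stats::runif(npairs, at$start[i] + 1L,
                                               at$end[i])),
                 size = size)
    }))
    list(depth = depth, inserts = inserts)
  })
  track <- depth_track("sim", seq_along(out$depth), out$depth,
                       seq_length = nchar(s))
  # positions past the last full window carry no simulated depth
  list(depth = track, inserts = out$inserts, windows = at)
}

random_at_seq <- function(n, at) {
  p <- c(at / 2, (1 - at) / 2, (1 - at) / 2, at / 2)
  paste0(sample(dna_bases, n, replace = TRUE, prob = p), collapse = "")
}

#' Simulate a genome with contrasting AT content between feature kinds
#'
#' Lays out alternating intergenic spacers and genes (a given fraction of
#' them ncRNA genes, the first two protein genes carrying a short
#' intron), then draws each segment's bases i.i.d. with the target AT
#' content of its kind. The defaults emulate a strongly reduced,
#' AT-skewed plastome: 18.6 kb, 78.5% coding, protein genes ~88% AT,
#' ncRNA genes ~77.5% AT, intergenic DNA ~94% AT.
#'
#' @param length Genome length in bp (default 18622).
#' @param coding_fraction Fraction of the genome covered by genes
#'   (protein_coding + ncRNA; default 0.785).
#' @param at_coding,at_ncrna,at_intergenic Target AT contents by kind
#'   (defaults 0.881, 0.775, 0.938). Introns use `at_intergenic`.
#' @param n_genes Number of genes (default 14).
#' @param ncrna_genes How many of the genes are ncRNA (default 2).
#' @param intron_len Length of each of the two introns (default 150 bp;
#'   0 disables introns).
#' @param seed Integer seed (mandatory).
#' @return List with `sequence` (character) and `features` (data frame
#'   `seq_id`, `start`, `end`, `strand`, `kind`, `name`).
#' @export
simulate_genome <- function(length = 18622L, coding_fraction = 0.785,
                            at_coding = 0.881, at_ncrna = 0.775,
                            at_intergenic = 0.938, n_genes = 14L,
                            ncrna_genes = 2L, intron_len = 150L, seed) {
  if (missing(seed)) stop("an explicit seed is required")
  length <- as.integer(length)
  if (length < 1000L) stop("genome length must be >= 1000 bp")
  if (coding_fraction <= 0 || coding_fraction >= 1)
    stop("'coding_fraction' must be in (0, 1)")
  n_genes <- as.integer(n_genes)
  n_intron <- if (intron_len > 0) min(2L, n_genes - ncrna_genes) else 0L
  coding_bp <- round(length * coding_fraction)
  gene_len <- rep(coding_bp %/% n_genes, n_genes)
  gene_len[seq_len(coding_bp %% n_genes)] <-
    gene_len[seq_len(coding_bp %% n_genes)] + 1L
  inter_bp <- length - coding_bp - n_intron * intron_len
  if (inter_bp < n_genes + 1L)
    stop("no room for intergenic spacers; lower coding_fraction")
  spacer_len <- rep(inter_bp %/% (n_genes + 1L), n_genes + 1L)
  spacer_len[seq_len(inter_bp %% (n_genes + 1L))] <-
    spacer_len[seq_len(inter_bp %% (n_genes + 1L))] + 1L

  kind_of_gene <- c(rep("ncRNA", ncrna_genes),
                    rep("protein_coding", n_genes - ncrna_genes))
  at_of <- c(protein_coding = at_coding, ncRNA = at_ncrna,
             intron = at_intergenic, intergenic = at_intergenic)

  with_local_seed(seed, {
    segs <- list(); feats <- list(); pos <- 0L
    add <- function(kind, len, name) {
      if (len <= 0L) return(invisible())
      segs[[length(segs) + 1L]] <<- random_at_seq(len, at_of[[kind]])
      feats[[length(feats) + 1L]] <<- data.frame(
        seq_id = "sim_genome", start = pos, end = pos + len,
        strand = "+", kind = kind, name = name)
      pos <<- pos + len
    }
    gi <- 0L
    for (g in seq_len(n_genes)) {
      add("intergenic", spacer_len[g], paste0("igs", g))
      kind <- kind_of_gene[g]
      gname <- paste0(if (kind == "ncRNA") "rrn" else "gene", g)
      if (kind == "protein_coding" && gi < n_intron) {
        gi <- gi + 1L
        half <- gene_len[g] %/% 2L
        add(kind, half, gname)
        add("intron", intron_len, paste0(gname, "_intron"))
        add(kind, gene_len[g] - half, gname)
      } else {
        add(kind, gene_len[g], gname)
      }
    }
    add("intergenic", spacer_len[n_genes + 1L], paste0("igs", n_genes + 1L))
    features <- do.call(rbind, feats)
    list(sequence = paste0(unlist(segs), collapse = ""),
         features = validate_features(features))
  })
}

#' Simulate a k-mer coverage histogram
#'
#' Produces the two-peaked spectrum of a whole-genome sequencing run: a
#' genome peak -- distinct genomic k-mers whose multiplicities are
#' Poisson around the k-mer coverage -- and an error peak at low
#' multiplicity from sequencing-error k-mers (geometric, concentrated at
#' multiplicity 1). Bin counts carry Poisson noise, so the construction
#' scales to arbitrarily large genomes without simulating reads.
#'
#' @param genome_size Genome size in bp.
#' @param coverage K-mer fold coverage of the genome peak.
#' @param error_rate Per-base sequencing error rate (default 0.005); a
#'   k-mer containing any error is counted as a (nearly unique) error
#'   k-mer, so roughly `error_rate * k` of the k-mer mass feeds the
#'   error peak.
#' @param k k-mer size (default 21).
#' @param seed Integer seed (mandatory).
#' @return A [kmer_histogram()].
#' @export
simulate_kmer_histogram <- function(genome_size, coverage,
                                    error_rate = 0.005, k = 21L, seed) {
  if (missing(seed)) stop("an explicit seed is required")
  check_positive(genome_size = genome_size, coverage = coverage)
  m_max <- max(stats::qpois(1 - 1e-9, coverage), 10L)
  m <- seq_len(m_max)
  # error-containing k-mers are diverted from genomic positions, so the
  # genome peak sits at the error-depleted effective coverage
  err_frac <- min(1, 1 - (1 - error_rate)^k)
  eff_cov <- coverage * (1 - err_frac)
  genome_mass <- genome_size * stats::dpois(m, eff_cov)
  n_error <- genome_size * coverage * err_frac
  error_mass <- n_error * stats::dgeom(m - 1L, 0.9)
  lambda <- genome_mass + error_mass
  with_local_seed(seed, {
    # rpois overflows integer range for very large bins; switch to the
    # normal approximation there
    big <- lambda > 1e9
    counts <- numeric(m_max)
    counts[!big] <- stats::rpois(sum(!big), lambda[!big])
    counts[big] <- pmax(0, round(lambda[big] +
      stats::rnorm(sum(big)) * sqrt(lambda[big])))
    kmer_histogram(m, counts, k = k)
  })
}
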