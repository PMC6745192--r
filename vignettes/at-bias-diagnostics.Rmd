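---
title: "Diagnosing the artifacts of extreme AT content"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Diagnosing the artifacts of extreme AT content}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(atbias)
```

Strongly reduced organellar genomes — the motivating case is a ~18.6 kb
holoparasite plastome at ~87% AT — sit in a regime where composition
itself becomes the dominant signal: in random sequence at that
composition stop codons appear every few codons, unrelated AT-rich
lineages converge in sequence, and PCR-based sequencing libraries
underrepresent exactly the AT-richest regions. This vignette documents
the models behind each diagnostic in `atbias`, the tunable parameters
and their defaults, what the synthetic-data generators do and do not
emulate, and the numerical conventions.

## The stop-codon probability model

Model a codon as three independent draws from a base composition. For
the symmetric composition parameterised by AT content $\alpha$
($p_A = p_T = \alpha/2$, $p_C = p_G = (1-\alpha)/2$) and the standard
stop set $\{TAA,\ TGA,\ TAG\}$,

$$P(\mathrm{stop}) = \left(\tfrac{\alpha}{2}\right)^3
  + 2\left(\tfrac{\alpha}{2}\right)^2\tfrac{1-\alpha}{2}
  = \frac{\alpha^2}{4} - \frac{\alpha^3}{8}.$$

`stop_probability()` evaluates the general form — the sum of
$\prod_i p_i(b_i)$ over the code's stop codons — so it accepts
position-specific compositions (in the style of the F3×4 codon model)
and non-canonical genetic codes (e.g. a plastome reading TAG as
tryptophan). The closed form above is a test oracle, checked against
the 64-codon enumeration to $10^{-12}$ on a 101-point $\alpha$ grid.
`expected_stop_spacing()` is $\lfloor 1/P(\mathrm{stop}) \rfloor$:

```{r}
stop_probability(0.88)
expected_stop_spacing(0.88)
```

$P(\mathrm{stop})$ is strictly increasing in $\alpha$ (its derivative
$\alpha/2 - 3\alpha^2/8$ is positive on $(0,1)$), which is the formal
statement of "the more AT-rich the genome, the harder it is to keep a
reading frame open by chance".

The amino-acid null `expected_aa_freq()` aggregates the codon null by
amino acid and **renormalises over non-stop codons**: observed proteins
contain no internal stops, so a comparable null must condition on
non-stop. Under this null an AT content of 0.88 pushes isoleucine
(AT-rich codons) far above glycine (GC-rich codons), the direction seen
in AT-shifted proteomes.

## AT profiling conventions

* AT content is the fraction of A+T among **called** bases: gaps, `N`
  and IUPAC ambiguity codes are excluded from the denominator. This is
  a package convention (stated, not inherited from any external
  definition); it keeps the statistic a fraction of observed bases.
* `U` is normalised to `T` at ingest, so RNA genes and DNA share one
  alphabet; all handling is case-insensitive.
* Windows are fixed-width, half-open, non-overlapping by default
  (200 bp), and a trailing partial window is dropped unless
  `keep_partial = TRUE`. Length-weighted summaries (`weighted_at()`)
  are defined as the AT content of the concatenation, which is the
  identity the property tests exercise.

## The convergence diagnostic

The test asks whether a focal taxon's placement among labelled groups
is carried by its A/T columns:

1. `filter_at_columns()` removes every column where the focal taxon has
   A, T or U. A gap or `N` in the focal taxon **retains** the column —
   the focal taxon shows neither A nor T there. (The choice matters
   only for gappy data and is stated here because no external
   convention exists.)
2. Trees are built by neighbor joining on pairwise distances
   (p-distance, JC69 or K2P; JC69 default) with pairwise deletion.
   Saturated pairs ($p \ge 0.749$ under JC69) are capped at a
   documented ceiling of 10 substitutions/site with a warning rather
   than propagating infinities; NJ tolerates a few capped entries,
   and the cap is far above any resolvable distance.
3. Nonparametric bootstrap (default 100 column-resampling replicates,
   explicit seed) gives each internal edge the percentage of replicate
   trees containing its bipartition; edges below the conventional
   threshold of 70 are contracted (`collapse_low_support()`).
4. `placement()` applies a versioned rule printed in every report:
   among all bipartition sides containing the focal taxon plus at least
   one other taxon, take the smallest (ties broken by lexicographically
   first member set); the label is the group with a **strict majority**
   of that clade's non-focal members, otherwise `"unresolved"`. Ties
   never produce an arbitrary assignment. On a fully collapsed (star)
   tree the rule degrades to the attachment bipartition, i.e. the
   all-but-one-leaf side.
5. `convergence_test()` pairs the unfiltered and filtered runs;
   `moved` records whether the labels differ. If fewer than
   `min_columns` (default 50) columns survive filtering, a warning is
   embedded in the report rather than aborting: a thin filtered
   alignment is informative but unstable.

Design choice: the reference analyses behind this diagnostic used
maximum-likelihood trees. Here the tree engine is distance + NJ, for
two reasons: the diagnostic's substance is the filter and the placement
rule, not the optimiser; and NJ is exactly testable — it reproduces
additive matrices to $10^{-9}$ and matches exhaustive least-squares
topology search at $n \le 6$ in the test suite. Any external ML engine
can be slotted behind the same placement interface by supplying its
tree to `collapse_low_support()`/`placement()` directly. Likewise the
bootstrap replicate count is fixed and seeded rather than chosen by a
convergence criterion, trading adaptivity for reproducibility at desk
scale.

## Coverage-bias analysis

`window_profile()` joins window AT content with window mean depth;
`at_coverage_report()` reports Spearman correlations of AT against
depth and against the mean insert size of pairs whose midpoint falls in
the window (midpoint assignment is the package's convention — the
association is window-level and no external assignment rule exists).
Windows with zero covered bases are excluded from the depth
correlation, with the excluded count reported. Spearman's $\rho$ is the
Pearson correlation of mid-ranks (ties averaged), delegated to
`stats::cor`; zero rank variance raises an error rather than returning
`NA`, so degenerate inputs (e.g. a compositionally homogeneous genome)
surface loudly.

## Genome-size estimation

Read arithmetic is exact algebra: `coverage = n·L/G` and its inverse.
For k-mer spectra, `histogram_peak()` takes the largest count at
multiplicity **above** an explicit error cutoff (default 3) — the
low-multiplicity error peak is excluded by construction, and an
all-below-cutoff histogram is an error, since then only a lower bound
on genome size is possible (obtained from read arithmetic with the
cutoff as a coverage ceiling). `size_from_histogram()` divides the
k-mer mass above the cutoff by the peak multiplicity; with $k \ll$ read
length, k-mer coverage approximates read coverage. The estimator's
intrinsic bias is $\lambda/\lfloor\lambda\rfloor$ (Poisson mode), under
4% at coverage ≥ 15×.

## What the generators emulate — and what they do not

`simulate_alignment()` evolves i.i.d. sites along a rooted binary guide
tree under HKY with **branch-specific equilibrium frequencies and rate
multipliers**, via exact transition matrices `expm(Q t)`. HKY (κ
default 2) is the minimal model producing compositional attraction;
there are no indels, no among-site rate variation, no selection. The
default `convergence_scenario()` puts 16 taxa in two balanced clades
and lets one tip per clade (`Focal`, `Attractor`) evolve at 20× rate
toward 88% AT equilibrium on its terminal branch (0.1 subs/site × 20 =
2 expected substitutions/site), with uniform background composition —
enough to pull the focal rows to ~0.85–0.9 realised AT and to induce
the artifactual grouping in unfiltered trees. Alignment length defaults
to 1000 sites, the scale of a single ribosomal RNA gene.

`simulate_depth()` maps window AT through a normalised exponential

$$\mu(a) = d_{\min} + (d_{\max}-d_{\min})\,
  \frac{e^{-s(a-a_{\min})} - e^{-s(a_{\max}-a_{\min})}}
       {1 - e^{-s(a_{\max}-a_{\min})}},$$

which hits $d_{\max}$ (default 3000) at the least AT-rich observed
window and $d_{\min}$ (default 17) at the most AT-rich, with free shape
$s$ (default 8). The exponential form is a modelling stand-in: the
PCR-dropout mechanism is characterised only by its endpoints, not by a
curve. Per-position depths are negative-binomial around the window mean
(variance $\mu + d\mu^2$, $d$ default 0.1; $d = 0$ is exactly
deterministic), and insert means fall linearly from 300 bp to 200 bp
across the observed AT range. Real coverage tracks have mappability
structure, strand effects and long-range autocorrelation that this
model does not attempt; passing tests show the pipeline's statistics
behave correctly under the assumed monotone AT–depth link, not that the
link has this form in any particular dataset.

`simulate_genome()` tiles intergenic spacers and genes (defaults:
18,622 bp, 78.5% coding, 14 genes of which 2 ncRNA, two 150-bp introns)
with i.i.d. bases at per-kind AT targets (0.881 coding / 0.775 ncRNA /
0.938 intergenic) — composition without codon structure, motifs or
repeats. `simulate_kmer_histogram()` works at the histogram level:
genomic k-mers Poisson at the error-depleted effective coverage, error
k-mers (per-base error default 0.005, so ~10% of 21-mers) geometric at
multiplicity ≈ 1, Poisson noise per bin. It never simulates reads, and
assumes a haploid, repeat-free genome — no heterozygosity shoulder, no
repeat tail.

Every generator requires an explicit seed, restores the caller's RNG
state, and is byte-identical under a fixed seed.

## Numerical and testing choices

* Probability vectors must sum to 1 within $10^{-9}$; the closed-form
  vs enumeration agreement is asserted at $10^{-12}$.
* Distance saturation cap: 10 substitutions/site, with warning.
* Problem sizes in the test suite are chosen for a laptop-scale run:
  exhaustive topology search at 5–6 taxa (15/105 topologies), 40–100
  bootstrap replicates, 1000-site alignments, 10-kb synthetic genomes,
  50 simulation seeds for the paired convergence property, 40 seeds for
  the coverage-correlation property. The paired property — artifactual
  grouping strictly decreases after filtering — is asserted over seeds,
  not per seed: any single filtered replicate may retain or lose the
  artifact.
* JSON reports print numbers at 6 significant digits and keep
  timestamps in a `metadata` field so reruns are otherwise
  byte-identical.

## Known limitations

* NJ + JC69/K2P underestimates divergence near saturation; the
  convergence diagnostic is qualitative (does the placement move), not
  an estimate of the true tree.
* The placement rule is one defensible operationalisation of "where
  does the taxon sit"; other rules (e.g. transfer distances) could be
  layered on the same reports.
* The AT–depth curve and the k-mer error model are generative
  conveniences for testing, not fitted models of any instrument.
* `read_features()` understands a minimal GFF3 subset (single-line
  features; `CDS`/`gene`/`mRNA`, `rRNA`/`tRNA`/`ncRNA`, `intron`,
  `intergenic`).
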