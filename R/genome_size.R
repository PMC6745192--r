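# Genome-size and coverage arithmetic from read counts, and peak-based
# estimation from k-mer spectra.

#' Fold coverage from read count, read length and genome size
#'
#' `coverage = n_reads * read_len / genome_size`. E.g. 400 million
#' 150-bp reads over a 500-Mbp genome give 120x.
#'
#' @param n_reads Number of reads (> 0).
#' @param read_len Read length in bp (> 0).
#' @param genome_size Genome size in bp (> 0).
#' @return Fold coverage.
#' @export
coverage_from_reads <- function(n_reads, read_len, genome_size) {
  check_positive(n_reads = n_reads, read_len = read_len,
                 genome_size = genome_size)
  n_reads * read_len / genome_size
}

#' Genome size from read count, read length and coverage
#'
#' The exact inverse of [coverage_from_reads()]:
#' `genome_size = n_reads * read_len / coverage`. With a k-mer peak that
#' can only be bounded above (e.g. below 2x), this gives a lower bound on
#' genome size: 400 million 150-bp reads at 2x imply at least 30,000 Mbp.
#'
#' @inheritParams coverage_from_reads
#' @param coverage Fold coverage (> 0).
#' @return Genome size in bp.
#' @export
size_from_reads <- function(n_reads, read_len, coverage) {
  check_positive(n_reads = n_reads, read_len = read_len,
                 coverage = coverage)
  n_reads * read_len / coverage
}

check_positive <- function(...) {
  args <- list(...)
  for (nm in names(args)) {
    v <- args[[nm]]
    if (!is.numeric(v) || length(v) != 1L || is.na(v) || v <= 0)
      stop("'", nm, "' must be a single number > 0")
  }
  invisible(TRUE)
}

#' Genome peak of a k-mer histogram
#'
#' The multiplicity with the largest distinct-k-mer count among bins
#' above the error cutoff. Low-multiplicity bins are dominated by
#' sequencing-error k-mers (the "error peak"), so they are excluded; the
#' remaining maximum corresponds to the k-mer coverage of the genome.
#' Ties are resolved to the lowest multiplicity, with a warning.
#'
#' @param hist A [kmer_histogram()].
#' @param error_cutoff Bins with multiplicity <= `error_cutoff` are
#'   ignored (default 3).
#' @return Peak multiplicity (integer).
#' @export
histogram_peak <- function(hist, error_cutoff = 3L) {
  stopifnot(inherits(hist, "kmer_histogram"))
  keep <- hist$multiplicity > error_cutoff & hist$count > 0
  if (!any(keep))
    stop("peak below cutoff: no histogram mass above multiplicity ",
         error_cutoff, "; only a genome-size lower bound is possible")
  m <- hist$multiplicity[keep]
  cnt <- hist$count[keep]
  top <- which(cnt == max(cnt))
  if (length(top) > 1L)
    warning("tied peak counts; returning the lowest multiplicity")
  m[top[1L]]
}

#' Genome size from a k-mer histogram
#'
#' Total k-mer mass above the error cutoff divided by the peak
#' multiplicity: `sum(multiplicity * count) / peak`. When the k-mer size
#' is much smaller than the read length the k-mer coverage approximates
#' the read coverage, so the peak multiplicity stands in for coverage and
#' the ratio estimates the genome size in bp.
#'
#' @inheritParams histogram_peak
#' @return List with `size` (bp), `peak` (multiplicity used as
#'   coverage) and `kmer_mass` (total counted k-mers above cutoff).
#' @export
size_from_histogram <- function(hist, error_cutoff = 3L) {
  peak <- histogram_peak(hist, error_cutoff)
  keep <- hist$multiplicity > error_cutoff
  mass <- sum(as.numeric(hist$multiplicity[keep]) * hist$count[keep])
  list(size = mass / peak, peak = peak, kmer_mass = mass)
}
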