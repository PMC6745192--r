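# Base composition, codon/amino-acid usage and the stop-codon probability
# model for AT-biased coding sequences.

#' Per-position base composition
#'
#' A `base_composition` stores the probabilities of A, C, G and T at each of
#' the three codon positions. Most analyses use a position-independent
#' composition (the same vector at every position); a position-specific
#' composition (one vector per codon position, in the style of the F3x4
#' codon model) can be supplied as a 3x4 matrix.
#'
#' @param prob Either a length-4 probability vector or a 3x4 matrix (rows =
#'   codon positions) with columns named or ordered `A`, `C`, `G`, `T`.
#'   Each row must sum to 1 (tolerance `1e-9`).
#' @return An object of class `base_composition`: a list with `prob`
#'   (3x4 matrix) and `positional` (logical; whether positions differ).
#' @seealso [at_composition()] for the uniform AT-content constructor.
#' @examples
#' base_composition(c(A = 0.44, C = 0.06, G = 0.06, T = 0.44))
#' @export
base_composition <- function(prob) {
  bases <- c("A", "C", "G", "T")
  if (is.matrix(prob)) {
    if (!all(dim(prob) == c(3L, 4L)))
      stop("positional composition must be a 3x4 matrix (positions x bases)")
    m <- prob
    positional <- TRUE
  } else {
    if (length(prob) != 4L)
      stop("composition must have 4 entries (A, C, G, T)")
    m <- matrix(rep(as.numeric(prob), each = 3L), nrow = 3L)
    if (!is.null(names(prob))) colnames(m) <- names(prob)
    positional <- FALSE
  }
  if (is.null(colnames(m))) colnames(m) <- bases
  m <- m[, bases, drop = FALSE]
  rownames(m) <- paste0("pos", 1:3)
  if (any(m < 0) || any(m > 1))
    stop("base probabilities must lie in [0, 1]")
  if (any(abs(rowSums(m) - 1) > 1e-9))
    stop("base probabilities must sum to 1 at every codon position")
  structure(list(prob = m, positional = positional),
            class = "base_composition")
}

#' Uniform-AT base composition
#'
#' Builds the symmetric composition implied by an AT content `alpha`:
#' `p_A = p_T = alpha/2` and `p_C = p_G = (1 - alpha)/2`, identical at all
#' three codon positions. This is the composition under which the
#' closed-form stop-codon probability `alpha^2/4 - alpha^3/8` holds.
#'
#' @param alpha AT content, a number in `[0, 1]`.
#' @return A `base_composition`.
#' @examples
#' at_composition(0.88)
#' @export
at_composition <- function(alpha) {
  if (!is.numeric(alpha) || length(alpha) != 1L || is.na(alpha) ||
      alpha < 0 || alpha > 1)
    stop("'alpha' must be a single number in [0, 1]")
  base_composition(c(A = alpha / 2, C = (1 - alpha) / 2,
                     G = (1 - alpha) / 2, T = alpha / 2))
}

#' @export
print.base_composition <- function(x, ...) {
  cat("Base composition (",
      if (x$positional) "position-specific" else "position-independent",
      ")\n", sep = "")
  print(round(x$prob, 4))
  invisible(x)
}

#' Genetic code table
#'
#' Wraps an NCBI translation table as a 64-entry codon-to-amino-acid map
#' plus its stop-codon set. The default is table 11 (bacterial, archaeal
#' and plant plastid), whose stop set is the standard `{TAA, TAG, TGA}`.
#' Non-canonical codes -- e.g. a plastome reading TAG as tryptophan -- can
#' be expressed by passing a custom 64-entry map.
#'
#' @param table_id NCBI translation table number (default 11).
#' @param codon_to_aa Optional custom map: a named character vector of 64
#'   single-letter amino acids (`"*"` for stop) named by DNA codons.
#'   Overrides `table_id` for the mapping; `table_id` is then only a label.
#' @return An object of class `genetic_code`: list with `table_id`,
#'   `codon_to_aa` (64 entries) and `stop_codons`.
#' @examples
#' code <- genetic_code()
#' code$stop_codons
#' @export
genetic_code <- function(table_id = 11L, codon_to_aa = NULL) {
  if (is.null(codon_to_aa)) {
    codon_to_aa <- Biostrings::getGeneticCode(as.character(table_id))
  }
  codon_to_aa <- codon_to_aa[order(names(codon_to_aa))]
  if (length(codon_to_aa) != 64L ||
      !setequal(names(codon_to_aa), all_codons()))
    stop("a genetic code must map exactly the 64 DNA codons")
  stops <- names(codon_to_aa)[codon_to_aa == "*"]
  if (length(stops) == 0L)
    stop("a genetic code must contain at least one stop codon")
  structure(list(table_id = as.integer(table_id),
                 codon_to_aa = codon_to_aa,
                 stop_codons = stops),
            class = "genetic_code")
}

#' @export
print.genetic_code <- function(x, ...) {
  cat("Genetic code (NCBI table ", x$table_id, "), stops: ",
      paste(x$stop_codons, collapse = " "), "\n", sep = "")
  invisible(x)
}

all_codons <- function() {
  b <- c("A", "C", "G", "T")
  sort(apply(expand.grid(b, b, b, stringsAsFactors = FALSE), 1L,
             paste0, collapse = ""))
}

# Normalize a sequence: uppercase, RNA U -> T. Accepts XStringSet/XString.
norm_seq <- function(seq) {
  if (inherits(seq, "XStringSet") || inherits(seq, "XString"))
    seq <- as.character(seq)
  chartr("u", "T", chartr("U", "T", toupper(seq)))
}

#' AT content of a sequence
#'
#' Fraction of A + T among unambiguously called bases. Gaps, `N` and IUPAC
#' ambiguity codes are excluded from the denominator, so the value is the
#' AT fraction of called bases. `U` is treated as `T`.
#'
#' @param seq A DNA/RNA sequence: character string, or a
#'   [Biostrings::DNAString-class] / single-record set.
#' @return AT fraction in `[0, 1]`.
#' @examples
#' at_content("ATGC")  # 0.5
#' @export
at_content <- function(seq) {
  s <- norm_seq(seq)
  if (length(s) != 1L) stop("'seq' must be a single sequence")
  n_at <- nchar(gsub("[^AT]", "", s))
  n_called <- nchar(gsub("[^ACGT]", "", s))
  if (n_called == 0L)
    stop("sequence has no unambiguous A/C/G/T bases")
  n_at / n_called
}

#' Sliding-window AT content
#'
#' AT content in consecutive fixed-width windows along a sequence. Windows
#' are half-open `[start, start + window)`; a trailing window shorter than
#' `window` is dropped unless `keep_partial = TRUE`.
#'
#' @inheritParams at_content
#' @param window Window width in bp (default 200).
#' @param step Step between window starts in bp (default `window`, i.e.
#'   non-overlapping windows).
#' @param keep_partial Emit the trailing partial window too?
#' @return A data frame with `start` (0-based window start), `end`
#'   (exclusive) and `at` (AT fraction; `NA` if the window has no called
#'   bases).
#' @examples
#' windowed_at(strrep("AT", 200), window = 200)
#' @export
windowed_at <- function(seq, window = 200L, step = window,
                        keep_partial = FALSE) {
  s <- norm_seq(seq)
  window <- as.integer(window)
  step <- as.integer(step)
  if (window < 1L) stop("'window' must be >= 1")
  if (step < 1L) stop("'step' must be >= 1")
  n <- nchar(s)
  if (window > n) {
    warning("window (", window, " bp) longer than sequence (", n, " bp)")
    return(data.frame(start = integer(0), end = integer(0),
                      at = numeric(0)))
  }
  starts <- seq.int(0L, n - window, by = step)
  if (keep_partial && (max(starts) + window) < n)
    starts <- c(starts, max(starts) + step)
  ends <- pmin(starts + window, n)
  pieces <- substring(s, starts + 1L, ends)
  at <- vapply(pieces, function(p) {
    called <- nchar(gsub("[^ACGT]", "", p))
    if (called == 0L) return(NA_real_)
    nchar(gsub("[^AT]", "", p)) / called
  }, numeric(1), USE.NAMES = FALSE)
  data.frame(start = starts, end = ends, at = at)
}

#' Length-weighted AT content of a sequence set
#'
#' The AT content of the concatenation of the records, i.e. the per-record
#' AT contents weighted by their numbers of called bases. This is the
#' statistic used to summarise e.g. "all protein-coding genes" as one
#' number.
#'
#' @param records Character vector (optionally named) or
#'   [Biostrings::DNAStringSet-class] of sequences.
#' @return Weighted AT fraction in `[0, 1]`.
#' @examples
#' weighted_at(c("ATAT", "GC"))  # 4/6
#' @export
weighted_at <- function(records) {
  s <- norm_seq(records)
  if (length(s) == 0L) stop("'records' must contain at least one sequence")
  at_content(paste0(s, collapse = ""))
}

# Split coding sequences into codon vectors; errors name the record.
split_codons <- function(cds) {
  s <- norm_seq(cds)
  if (length(s) == 0L) stop("no coding sequences supplied")
  ids <- names(s)
  if (is.null(ids)) ids <- paste0("record_", seq_along(s))
  bad <- nchar(s) %% 3L != 0L | nchar(s) == 0L
  if (any(bad))
    stop("coding sequence length not a positive multiple of 3: ",
         paste(ids[bad], collapse = ", "))
  unlist(lapply(s, function(x)
    substring(x, seq(1L, nchar(x), 3L), seq(3L, nchar(x), 3L))),
    use.names = FALSE)
}

#' Codon usage of a set of coding sequences
#'
#' Counts every codon over all supplied CDS and returns counts and
#' relative frequencies for the full 64-codon table. Codons containing
#' ambiguous bases are dropped with a message.
#'
#' @param cds Coding sequences (character vector or `DNAStringSet`), each
#'   of length divisible by 3.
#' @param code A [genetic_code()].
#' @return Data frame with `codon`, `aa`, `count`, `freq`; frequencies sum
#'   to 1 over all codons.
#' @export
codon_usage <- function(cds, code = genetic_code()) {
  stopifnot(inherits(code, "genetic_code"))
  codons <- split_codons(cds)
  clean <- grepl("^[ACGT]{3}$", codons)
  if (!all(clean)) {
    message(sum(!clean), " codon(s) with ambiguous bases dropped")
    codons <- codons[clean]
  }
  if (length(codons) == 0L) stop("no unambiguous codons in input")
  counts <- table(factor(codons, levels = all_codons()))
  data.frame(codon = all_codons(),
             aa = unname(code$codon_to_aa[all_codons()]),
             count = as.integer(counts),
             freq = as.numeric(counts) / sum(counts),
             row.names = NULL)
}

#' Amino-acid usage of a set of coding sequences
#'
#' Aggregates [codon_usage()] by amino acid; stop codons are excluded and
#' frequencies renormalised over amino-acid-coding codons.
#'
#' @inheritParams codon_usage
#' @return Data frame with `aa`, `count`, `freq` over the code's amino
#'   acids; frequencies sum to 1.
#' @export
aa_usage <- function(cds, code = genetic_code()) {
  cu <- codon_usage(cds, code)
  cu <- cu[cu$aa != "*", , drop = FALSE]
  aas <- sort(unique(unname(code$codon_to_aa[code$codon_to_aa != "*"])))
  counts <- vapply(aas, function(a) sum(cu$count[cu$aa == a]), numeric(1))
  if (sum(counts) == 0)
    stop("no non-stop codons in input")
  data.frame(aa = aas, count = as.integer(counts),
             freq = counts / sum(counts), row.names = NULL)
}

#' Expected codon frequencies under a base-composition null
#'
#' The probability of each codon if bases at the three positions are drawn
#' independently from the composition: `P(b1 b2 b3) = p1(b1) p2(b2) p3(b3)`
#' (the three position vectors coincide for a position-independent
#' composition). Sums to 1 over the 64 codons.
#'
#' @param comp A [base_composition()].
#' @param code A [genetic_code()] (used only for amino-acid annotation).
#' @return Data frame with `codon`, `aa`, `prob`.
#' @export
expected_codon_freq <- function(comp, code = genetic_code()) {
  stopifnot(inherits(comp, "base_composition"),
            inherits(code, "genetic_code"))
  codons <- all_codons()
  pm <- comp$prob
  prob <- vapply(codons, function(cd) {
    b <- strsplit(cd, "")[[1]]
    pm[1L, b[1L]] * pm[2L, b[2L]] * pm[3L, b[3L]]
  }, numeric(1), USE.NAMES = FALSE)
  data.frame(codon = codons, aa = unname(code$codon_to_aa[codons]),
             prob = prob, row.names = NULL)
}

#' Expected amino-acid frequencies under a base-composition null
#'
#' Aggregates [expected_codon_freq()] by amino acid and renormalises over
#' non-stop codons. The conditioning on non-stop mirrors observed
#' proteins, which contain no internal stops, so the null is directly
#' comparable with [aa_usage()].
#'
#' @inheritParams expected_codon_freq
#' @return Data frame with `aa` and `prob` (sums to 1).
#' @export
expected_aa_freq <- function(comp, code = genetic_code()) {
  ec <- expected_codon_freq(comp, code)
  ec <- ec[ec$aa != "*", , drop = FALSE]
  aas <- sort(unique(ec$aa))
  prob <- vapply(aas, function(a) sum(ec$prob[ec$aa == a]), numeric(1))
  tot <- sum(prob)
  if (tot <= 0) stop("all non-stop codons have zero probability")
  data.frame(aa = aas, prob = prob / tot, row.names = NULL)
}

#' Probability that a random codon is a stop codon
#'
#' Sum of the composition-null probabilities of the code's stop codons.
#' For the uniform-AT composition ([at_composition()]) and the standard
#' three stops TAA, TGA, TAG this equals the closed form
#' `alpha^2/4 - alpha^3/8`: at the AT content of a strongly AT-shifted
#' plastome (alpha = 0.88) roughly 11% of random codons are stops, which
#' is why intact reading frames there imply ongoing purifying selection.
#'
#' @param comp A [base_composition()], or a single numeric AT content
#'   (shorthand for `at_composition(alpha)`).
#' @param code A [genetic_code()].
#' @return Probability in `[0, 1]`.
#' @examples
#' stop_probability(0.88)   # ~0.1084
#' @export
stop_probability <- function(comp, code = genetic_code()) {
  if (is.numeric(comp)) comp <- at_composition(comp)
  ec <- expected_codon_freq(comp, code)
  sum(ec$prob[ec$codon %in% code$stop_codons])
}

#' Expected spacing between stop codons in random sequence
#'
#' The typical number of codons one can read before hitting a stop, i.e.
#' `floor(1 / stop_probability)`.
#'
#' @inheritParams stop_probability
#' @return Integer number of codons.
#' @examples
#' expected_stop_spacing(0.88)  # 9: every 9th codon of random
#'                              # 88%-AT sequence is a stop
#' @export
expected_stop_spacing <- function(comp, code = genetic_code()) {
  p <- stop_probability(comp, code)
  if (p <= 0) stop("stop probability is zero; spacing undefined")
  as.integer(floor(1 / p))
}

#' Per-feature-kind AT content and coding fraction of a genome
#'
#' Extracts the subsequences of each feature kind (protein_coding, ncRNA,
#' intron, intergenic) and reports their length-weighted AT content, plus
#' the coding fraction of the genome: the proportion of bases covered by
#' protein_coding or ncRNA features (i.e. non-intergenic, non-intronic),
#' with overlapping features counted once.
#'
#' @param genome A single genome sequence (character or `DNAString`).
#' @param features A feature table as returned by [read_features()] or
#'   [simulate_genome()]: data frame with `seq_id`, `start`, `end`
#'   (0-based half-open), `strand`, `kind`, `name`.
#' @return List with `per_kind` (data frame `kind`, `bp`, `at`) and
#'   `coding_fraction`.
#' @export
feature_weighted_at <- function(genome, features) {
  s <- norm_seq(genome)
  if (length(s) != 1L) stop("'genome' must be a single sequence")
  n <- nchar(s)
  validate_features(features, n)
  kinds <- sort(unique(features$kind))
  per_kind <- do.call(rbind, lapply(kinds, function(k) {
    f <- features[features$kind == k, , drop = FALSE]
    subs <- substring(s, f$start + 1L, f$end)
    data.frame(kind = k, bp = sum(f$end - f$start),
               at = weighted_at(subs))
  }))
  coding <- features[features$kind %in% c("protein_coding", "ncRNA"), ,
                     drop = FALSE]
  coding_bp <- if (nrow(coding) == 0L) 0L else
    sum(IRanges::width(IRanges::reduce(
      IRanges::IRanges(start = coding$start + 1L, end = coding$end))))
  list(per_kind = per_kind, coding_fraction = coding_bp / n)
}

feature_kinds <- c("protein_coding", "ncRNA", "intron", "intergenic")

validate_features <- function(features, seq_len = NULL) {
  req <- c("seq_id", "start", "end", "strand", "kind", "name")
  if (!is.data.frame(features) || !all(req %in% names(features)))
    stop("feature table needs columns: ", paste(req, collapse = ", "))
  if (any(is.na(features$kind)) ||
      !all(features$kind %in% feature_kinds))
    stop("feature 'kind' must be one of: ",
         paste(feature_kinds, collapse = ", "))
  if (any(features$start < 0) || any(features$start >= features$end))
    stop("features must satisfy 0 <= start < end")
  if (!is.null(seq_len) && any(features$end > seq_len))
    stop("feature end beyond sequence length")
  invisible(features)
}
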