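# Readers and writers for the plain-text formats the pipeline consumes:
# FASTA, BED/GFF3 feature tables, samtools-depth TSV, insert-size TSV,
# jellyfish histo files and taxon-group tables.

#' Read a (multi-)FASTA file
#'
#' Sequences are uppercased and RNA `U` is normalised to `T` so that RNA
#' genes and DNA share one alphabet downstream.
#'
#' @param path Path to a FASTA file (may contain gaps for alignments).
#' @return Named character vector of sequences.
#' @export
read_fasta <- function(path) {
  set <- Biostrings::readBStringSet(path)
  if (length(set) == 0L) stop("no sequences in ", path)
  out <- norm_seq(set)
  names(out) <- sub("\\s.*$", "", names(set))
  out
}

#' Write sequences to FASTA
#'
#' @param seqs Named character vector of sequences.
#' @param path Output path.
#' @param width Line-wrap width (default 60 columns).
#' @return `path`, invisibly.
#' @export
write_fasta <- function(seqs, path, width = 60L) {
  if (is.null(names(seqs))) names(seqs) <- paste0("seq_", seq_along(seqs))
  set <- Biostrings::BStringSet(seqs)
  Biostrings::writeXStringSet(set, path, width = as.integer(width))
  invisible(path)
}

#' Read an aligned FASTA into an alignment matrix
#'
#' @param path Path to an aligned FASTA file.
#' @return A character matrix, rows = taxa (rownames), one column per
#'   alignment position; see [as_alignment()].
#' @export
read_alignment <- function(path) {
  as_alignment(read_fasta(path))
}

#' Read a taxon-to-group table
#'
#' A two-column TSV (taxon, group label), no header; lines starting with
#' `#` are skipped.
#'
#' @param path Path to the TSV.
#' @return Named character vector: `groups[taxon] = label`.
#' @export
read_groups <- function(path) {
  tab <- utils::read.delim(path, header = FALSE, comment.char = "#",
                           stringsAsFactors = FALSE)
  if (ncol(tab) < 2L) stop("group table needs two columns: taxon, group")
  if (anyDuplicated(tab[[1L]]))
    stop("duplicated taxa in group table: ",
         paste(unique(tab[[1L]][duplicated(tab[[1L]])]), collapse = ", "))
  stats::setNames(as.character(tab[[2L]]), as.character(tab[[1L]]))
}

#' Read a per-position depth table
#'
#' Expects the `samtools depth` format: reference name, 1-based position,
#' depth, tab-separated, no header. Positions absent from the file get
#' depth 0.
#'
#' @param path Path to the TSV.
#' @param seq_length Optional reference length; defaults to the largest
#'   position seen.
#' @return A `depth_track`: list with `ref`, `depth` (integer vector,
#'   element i = depth at 1-based position i).
#' @export
read_depth <- function(path, seq_length = NULL) {
  tab <- utils::read.delim(path, header = FALSE, comment.char = "#",
                           stringsAsFactors = FALSE)
  if (ncol(tab) < 3L)
    stop("depth table needs three columns: ref, pos (1-based), depth")
  ref <- unique(as.character(tab[[1L]]))
  if (length(ref) != 1L)
    stop("depth table must describe a single reference, found: ",
         paste(ref, collapse = ", "))
  pos <- as.integer(tab[[2L]])
  dep <- as.integer(tab[[3L]])
  if (any(pos < 1L)) stop("positions must be 1-based (>= 1)")
  if (any(dep < 0L)) stop("depths must be >= 0")
  depth_track(ref, pos, dep, seq_length)
}

#' Construct a depth track
#'
#' @param ref Reference sequence name.
#' @param pos 1-based positions.
#' @param depth Depth at each position.
#' @param seq_length Reference length (default `max(pos)`).
#' @return A `depth_track` object.
#' @export
depth_track <- function(ref, pos, depth, seq_length = NULL) {
  if (is.null(seq_length)) seq_length <- max(pos)
  if (any(pos > seq_length)) stop("position beyond reference length")
  d <- integer(seq_length)
  d[pos] <- as.integer(depth)
  structure(list(ref = ref, depth = d), class = "depth_track")
}

#' @export
print.depth_track <- function(x, ...) {
  cat("Depth track '", x$ref, "': ", length(x$depth), " bp, mean depth ",
      round(mean(x$depth), 1), "\n", sep = "")
  invisible(x)
}

#' Read read-pair insert sizes
#'
#' Three-column TSV: reference, pair midpoint (1-based), insert size (bp);
#' no header.
#'
#' @param path Path to the TSV.
#' @return Data frame with `ref`, `midpoint`, `size`.
#' @export
read_inserts <- function(path) {
  tab <- utils::read.delim(path, header = FALSE, comment.char = "#",
                           stringsAsFactors = FALSE)
  if (ncol(tab) < 3L)
    stop("insert table needs three columns: ref, midpoint, size")
  out <- data.frame(ref = as.character(tab[[1L]]),
                    midpoint = as.numeric(tab[[2L]]),
                    size = as.numeric(tab[[3L]]))
  if (any(out$size <= 0)) stop("insert sizes must be > 0")
  out
}

#' Read a k-mer coverage histogram
#'
#' The jellyfish `histo` format: one line per multiplicity, two
#' whitespace-separated integers (coverage multiplicity, number of
#' distinct k-mers).
#'
#' @param path Path to the histogram file.
#' @param k k-mer size the histogram was computed with (default 21).
#' @return A [kmer_histogram()].
#' @export
read_kmer_histogram <- function(path, k = 21L) {
  tab <- utils::read.table(path, header = FALSE)
  if (ncol(tab) < 2L)
    stop("k-mer histogram needs two columns: multiplicity, count")
  kmer_histogram(as.integer(tab[[1L]]), as.numeric(tab[[2L]]), k = k)
}

#' Construct a k-mer histogram
#'
#' @param multiplicity Strictly increasing coverage multiplicities (>= 1).
#' @param count Number of distinct k-mers at each multiplicity (>= 0).
#' @param k k-mer size.
#' @return Object of class `kmer_histogram`.
#' @export
kmer_histogram <- function(multiplicity, count, k = 21L) {
  multiplicity <- as.integer(multiplicity)
  if (any(multiplicity < 1L)) stop("multiplicities must be >= 1")
  if (is.unsorted(multiplicity, strictly = TRUE))
    stop("multiplicities must be strictly increasing")
  if (length(count) != length(multiplicity))
    stop("'multiplicity' and 'count' lengths differ")
  if (any(count < 0)) stop("counts must be >= 0")
  structure(list(multiplicity = multiplicity, count = as.numeric(count),
                 k = as.integer(k)),
            class = "kmer_histogram")
}

#' @export
print.kmer_histogram <- function(x, ...) {
  cat("k-mer histogram (k = ", x$k, "): ", length(x$multiplicity),
      " bins, multiplicities ", min(x$multiplicity), "..",
      max(x$multiplicity), "\n", sep = "")
  invisible(x)
}

#' Write a k-mer histogram in jellyfish `histo` format
#'
#' @param hist A [kmer_histogram()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_kmer_histogram <- function(hist, path) {
  stopifnot(inherits(hist, "kmer_histogram"))
  utils::write.table(
    data.frame(hist$multiplicity, hist$count), path,
    sep = " ", row.names = FALSE, col.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Write a depth track as a samtools-depth-style TSV
#'
#' @param track A `depth_track`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_depth <- function(track, path) {
  stopifnot(inherits(track, "depth_track"))
  utils::write.table(
    data.frame(track$ref, seq_along(track$depth), track$depth), path,
    sep = "\t", row.names = FALSE, col.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a feature table from BED or GFF3
#'
#' BED uses 0-based half-open coordinates directly; the `name` column
#' (column 4) must carry the feature kind, optionally as `kind:name`.
#' For GFF3 (1-based closed intervals, converted internally) the `type`
#' column is mapped to a kind: `CDS`/`gene`/`mRNA` to protein_coding;
#' `rRNA`/`tRNA`/`ncRNA` to ncRNA; `intron` to intron; anything else is an
#' error. Only a minimal GFF3 subset is understood (no multi-line
#' features, attributes other than `Name`/`ID` ignored).
#'
#' @param path Path to a `.bed`, `.gff`, `.gff3` file.
#' @param format `"bed"`, `"gff3"` or `"auto"` (by extension).
#' @return Data frame with `seq_id`, `start`, `end` (0-based half-open),
#'   `strand`, `kind`, `name`.
#' @export
read_features <- function(path, format = c("auto", "bed", "gff3")) {
  format <- match.arg(format)
  if (format == "auto") {
    ext <- tolower(sub(".*\\.", "", path))
    format <- if (ext == "bed") "bed" else if (ext %in% c("gff", "gff3"))
      "gff3" else stop("cannot infer format from extension '.", ext, "'")
  }
  gr <- rtracklayer::import(path, format = if (format == "bed") "BED"
                            else "GFF3")
  if (length(gr) == 0L) stop("no features in ", path)
  start0 <- BiocGenerics::start(gr) - 1L  # GRanges is 1-based closed
  end0 <- BiocGenerics::end(gr)
  strand <- as.character(BiocGenerics::strand(gr))
  strand[strand == "*"] <- "+"
  if (format == "bed") {
    raw <- as.character(gr$name)
    if (any(is.na(raw) | !nzchar(raw)))
      stop("BED needs a name column carrying the feature kind")
    parts <- strsplit(raw, ":", fixed = TRUE)
    kind <- vapply(parts, `[`, character(1), 1L)
    name <- vapply(parts, function(p) p[length(p)], character(1))
  } else {
    kind_map <- c(CDS = "protein_coding", gene = "protein_coding",
                  mRNA = "protein_coding", rRNA = "ncRNA", tRNA = "ncRNA",
                  ncRNA = "ncRNA", intron = "intron",
                  intergenic = "intergenic")
    type <- as.character(gr$type)
    bad <- !type %in% names(kind_map)
    if (any(bad))
      stop("unsupported GFF3 feature type: ",
           paste(unique(type[bad]), collapse = ", "))
    kind <- unname(kind_map[type])
    name <- if (!is.null(gr$Name)) as.character(gr$Name) else
      if (!is.null(gr$ID)) as.character(gr$ID) else type
    name[is.na(name)] <- type[is.na(name)]
  }
  feats <- data.frame(
    seq_id = as.character(GenomeInfoDb::seqnames(gr)),
    start = start0, end = end0, strand = strand,
    kind = kind, name = name)
  validate_features(feats)
}
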