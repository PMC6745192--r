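# Multiple alignments as character matrices (rows = taxa), the AT-column
# filter, and pairwise distances.

#' Coerce sequences to an alignment matrix
#'
#' The package represents a multiple alignment as a character matrix with
#' one row per taxon (rownames = taxon labels) and one single-character
#' column per alignment position, uppercase, with `U` normalised to `T`.
#'
#' @param x Named character vector of equal-length aligned sequences, a
#'   `DNAStringSet`/`BStringSet`, an [ape::DNAbin] matrix, or an existing
#'   character matrix.
#' @return Character matrix of class `at_alignment`.
#' @export
as_alignment <- function(x) {
  if (inherits(x, "DNAbin")) x <- toupper(as.character(x))
  if (is.matrix(x)) {
    m <- toupper(x)
    m[m == "U"] <- "T"
  } else {
    s <- norm_seq(x)
    if (is.null(names(s)))
      stop("aligned sequences must be named by taxon")
    if (length(unique(nchar(s))) != 1L)
      stop("aligned sequences must all have the same length")
    m <- do.call(rbind, strsplit(s, "", fixed = TRUE))
    rownames(m) <- names(s)
  }
  if (is.null(rownames(m)) || anyDuplicated(rownames(m)))
    stop("alignment taxa must be unique and named")
  class(m) <- c("at_alignment", class(m))
  m
}

#' @export
print.at_alignment <- function(x, ...) {
  cat("Alignment: ", nrow(x), " taxa x ", ncol(x), " columns\n", sep = "")
  invisible(x)
}

aln_to_strings <- function(aln) {
  stats::setNames(apply(aln, 1L, paste0, collapse = ""), rownames(aln))
}

#' Remove alignment columns that are A or T in focal taxa
#'
#' The compositional-convergence diagnostic: every column in which any of
#' the focal taxa carries an A, T (or U) is removed; all other columns are
#' retained unchanged and in order. Gaps, `N` and ambiguity codes in a
#' focal taxon retain the column, since the focal taxon shows neither A
#' nor T there. Removing the focal taxa's A/T columns strips the signal
#' that drives AT-rich lineages together, so a placement that survives the
#' filter is unlikely to be a compositional artifact.
#'
#' @param aln An alignment ([as_alignment()]).
#' @param focal Character vector of focal taxon labels (must be rows of
#'   `aln`).
#' @return The filtered alignment; attribute `kept` holds the retained
#'   0-based column indices.
#' @export
filter_at_columns <- function(aln, focal) {
  aln <- as_alignment(aln)
  missing <- setdiff(focal, rownames(aln))
  if (length(missing))
    stop("focal taxa not in alignment: ", paste(missing, collapse = ", "))
  sub <- aln[focal, , drop = FALSE]
  drop <- colSums(sub == "A" | sub == "T" | sub == "U") > 0L
  if (all(drop))
    stop("no columns survive the A/T filter for focal set {",
         paste(focal, collapse = ", "), "}")
  out <- aln[, !drop, drop = FALSE]
  class(out) <- c("at_alignment", "matrix", "array")
  attr(out, "kept") <- which(!drop) - 1L
  out
}

# Integer-code an alignment: A=1, C=2, G=3, T=4, everything else NA.
code_alignment <- function(aln) {
  codes <- matrix(match(aln, c("A", "C", "G", "T")), nrow = nrow(aln),
                  dimnames = list(rownames(aln), NULL))
  codes
}

#' Pairwise evolutionary distances from an alignment
#'
#' Computes a symmetric distance matrix under the p-distance, JC69 or K2P
#' model with pairwise deletion: for each pair only columns where both
#' taxa have an unambiguous A/C/G/T base are compared. JC69 applies
#' `d = -(3/4) log(1 - 4p/3)`; K2P uses the transition/transversion
#' decomposition. Pairs at or beyond the model's saturation point
#' (`p >= 0.749` for JC69, or a non-positive log argument for K2P) are
#' capped at `max_distance` with a warning rather than returning
#' infinite/undefined values.
#'
#' @param aln An alignment ([as_alignment()]).
#' @param model One of `"p-distance"`, `"JC69"`, `"K2P"`.
#' @param max_distance Ceiling applied to saturated pairs
#'   (substitutions/site; default 10).
#' @return Symmetric numeric matrix with zero diagonal, dimnames = taxa.
#' @export
pairwise_distance <- function(aln, model = c("JC69", "p-distance", "K2P"),
                              max_distance = 10) {
  model <- match.arg(model)
  aln <- as_alignment(aln)
  n <- nrow(aln)
  if (n < 2L) stop("need at least two taxa")
  codes <- code_alignment(aln)
  d <- matrix(0, n, n, dimnames = list(rownames(aln), rownames(aln)))
  saturated <- FALSE
  for (i in seq_len(n - 1L)) {
    xi <- codes[i, ]
    for (j in (i + 1L):n) {
      xj <- codes[j, ]
      ok <- !is.na(xi) & !is.na(xj)
      if (!any(ok))
        stop("no comparable sites between '", rownames(aln)[i],
             "' and '", rownames(aln)[j], "'")
      a <- xi[ok]; b <- xj[ok]
      p <- mean(a != b)
      dij <- switch(model,
        "p-distance" = p,
        "JC69" = {
          if (p >= 0.749) { saturated <- TRUE; max_distance }
          else -0.75 * log(1 - 4 * p / 3)
        },
        "K2P" = {
          diffs <- a != b
          # transitions: A<->G (1,3), C<->T (2,4)
          ts <- diffs & (((a == 1L) & (b == 3L)) | ((a == 3L) & (b == 1L)) |
                         ((a == 2L) & (b == 4L)) | ((a == 4L) & (b == 2L)))
          P <- mean(ts); Q <- p - P
          arg1 <- 1 - 2 * P - Q; arg2 <- 1 - 2 * Q
          if (arg1 <= 0 || arg2 <= 0) { saturated <- TRUE; max_distance }
          else -0.5 * log(arg1) - 0.25 * log(arg2)
        })
      d[i, j] <- d[j, i] <- min(dij, max_distance)
    }
  }
  if (saturated)
    warning("saturated pair(s) capped at distance ", max_distance)
  d
}
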