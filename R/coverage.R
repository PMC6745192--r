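# Window-level association between AT content and sequencing depth /
# insert size.

#' Windowed AT content and mean depth
#'
#' Splits the reference into consecutive half-open windows, computes the
#' AT content of each ([windowed_at()]) and the mean sequencing depth
#' over the same windows.
#'
#' @param seq Reference sequence (character or `DNAString`).
#' @param depth A `depth_track` ([read_depth()], [depth_track()]) whose
#'   length matches the sequence.
#' @param window Window width in bp (default 200).
#' @return Data frame with `start` (0-based), `end`, `at`, `mean_depth`.
#' @export
window_profile <- function(seq, depth, window = 200L) {
  stopifnot(inherits(depth, "depth_track"))
  s <- norm_seq(seq)
  if (nchar(s) != length(depth$depth))
    stop("depth track length (", length(depth$depth),
         ") does not match sequence length (", nchar(s), ")")
  at <- windowed_at(s, window = window)
  at$mean_depth <- vapply(seq_len(nrow(at)), function(i)
    mean(depth$depth[(at$start[i] + 1L):at$end[i]]), numeric(1))
  at
}

#' Spearman rank correlation
#'
#' The Pearson correlation of mid-ranks (ties receive their average
#' rank), as implemented by [stats::cor()] with `method = "spearman"`.
#' Errors rather than returning `NA` when either series has zero rank
#' variance, since a correlation is then undefined.
#'
#' @param x,y Equal-length numeric vectors, length >= 3. `NA` pairs are
#'   dropped.
#' @return Correlation in `[-1, 1]`.
#' @export
spearman_rho <- function(x, y) {
  if (length(x) != length(y)) stop("'x' and 'y' lengths differ")
  ok <- !is.na(x) & !is.na(y)
  x <- x[ok]; y <- y[ok]
  if (length(x) < 3L) stop("need at least 3 complete pairs")
  if (stats::var(rank(x)) == 0 || stats::var(rank(y)) == 0)
    stop("zero rank variance; Spearman correlation undefined")
  stats::cor(x, y, method = "spearman")
}

#' AT-content vs depth/insert-size correlation report
#'
#' The study-level summary of sequencing bias: the Spearman correlation
#' between window AT content and window mean depth, and (optionally)
#' between window AT content and the mean insert size of read pairs whose
#' midpoint falls in the window. Windows with no covered bases (mean
#' depth 0) are excluded from the depth correlation, with the excluded
#' count recorded.
#'
#' @inheritParams window_profile
#' @param inserts Optional insert-size table (`ref`, `midpoint` 1-based,
#'   `size`), as from [read_inserts()] or [simulate_depth()].
#' @return An `at_coverage_report`: list with `rho_depth`,
#'   `rho_insert` (`NA` if no inserts), the window `table`, `window`,
#'   `n_windows`, `n_excluded`.
#' @export
at_coverage_report <- function(seq, depth, inserts = NULL,
                               window = 200L) {
  prof <- window_profile(seq, depth, window = window)
  if (!is.null(inserts)) {
    win_idx <- (as.integer(inserts$midpoint) - 1L) %/% as.integer(window) + 1L
    win_idx[win_idx < 1L | win_idx > nrow(prof)] <- NA_integer_
    agg <- tapply(inserts$size,
                  factor(win_idx, levels = seq_len(nrow(prof))), mean)
    prof$mean_insert <- as.numeric(agg)
  }
  used <- prof$mean_depth > 0 & !is.na(prof$at)
  n_excluded <- sum(!used)
  rho_depth <- spearman_rho(prof$at[used], prof$mean_depth[used])
  rho_insert <- NA_real_
  if (!is.null(inserts)) {
    ok <- !is.na(prof$mean_insert) & !is.na(prof$at)
    rho_insert <- spearman_rho(prof$at[ok], prof$mean_insert[ok])
  }
  structure(list(rho_depth = rho_depth, rho_insert = rho_insert,
                 table = prof, window = as.integer(window),
                 n_windows = nrow(prof), n_excluded = n_excluded),
            class = "at_coverage_report")
}

#' @export
print.at_coverage_report <- function(x, ...) {
  cat("AT-content vs coverage (", x$n_windows, " windows of ", x$window,
      " bp, ", x$n_excluded, " excluded)\n", sep = "")
  cat("  Spearman rho (AT, depth):  ", round(x$rho_depth, 3), "\n")
  if (!is.na(x$rho_insert))
    cat("  Spearman rho (AT, insert): ", round(x$rho_insert, 3), "\n")
  invisible(x)
}
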