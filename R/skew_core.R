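SKEW_CLASSES <- c("total", "codon1", "codon2", "codon3", "noncoding")

#' Windowed GC skew
#'
#' Divides the replicon into consecutive non-overlapping windows of
#' `window_size` bases (trailing partial window discarded) and computes
#' `(G - C) / (G + C)` per window, counting only positions belonging to the
#' requested class: every position (`total`), positions at a fixed codon
#' position (`codon1`..`codon3`), or non-coding positions (`noncoding`).
#'
#' Counts are always taken from the reference (plus) strand at the labelled
#' positions, so a minus-strand gene contributes the complement of its coding
#' bases; set `gene_oriented = TRUE` to count the coding-strand base instead
#' (sensitivity analysis; decouples codon-class skews from gene orientation).
#' Windows where the class has no G or C get skew 0. `N` bases are never
#' counted.
#'
#' @param replicon a `replicon`.
#' @param labels a `position_labels` for the same replicon (may be `NULL` for
#'   class `"total"`).
#' @param skew_class one of `"total"`, `"codon1"`, `"codon2"`, `"codon3"`,
#'   `"noncoding"`.
#' @param window_size window length in bases (default 4096).
#' @param gene_oriented count bases as read on the coding strand.
#' @return object of class `skew_profile`: `replicon_id`, `skew_class`,
#'   `window_size`, `values`, `g_counts`, `c_counts`.
#' @export
windowed_skew <- function(replicon, labels = NULL, skew_class = "total",
                          window_size = 4096L, gene_oriented = FALSE) {
  skew_class <- match.arg(skew_class, SKEW_CLASSES)
  window_size <- as.integer(window_size)
  if (window_size < 1L) stop("window_size must be >= 1")
  n_win <- replicon$length %/% window_size
  if (n_win < 1L) stop("no complete window: replicon length ",
                       replicon$length, " < window_size ", window_size)
  if (skew_class != "total" && is.null(labels))
    stop("class '", skew_class, "' requires position labels")
  if (!is.null(labels) && length(labels$codon_label) != replicon$length)
    stop("label map does not match replicon length")

  used <- n_win * window_size
  codes <- base_codes(replicon)[seq_len(used)]
  if (gene_oriented && !is.null(labels)) {
    flip <- labels$strand_cover[seq_len(used)] == -1L
    comp <- c(4L, 3L, 2L, 1L)     # A<->T, C<->G
    idx <- flip & codes > 0L
    codes[idx] <- comp[codes[idx]]
  }
  keep <- switch(skew_class,
    total = rep(TRUE, used),
    codon1 = labels$codon_label[seq_len(used)] == 1L,
    codon2 = labels$codon_label[seq_len(used)] == 2L,
    codon3 = labels$codon_label[seq_len(used)] == 3L,
    noncoding = labels$codon_label[seq_len(used)] == 0L)
  win <- (seq_len(used) - 1L) %/% window_size + 1L
  g <- tabulate(win[keep & codes == 3L], nbins = n_win)
  c_ <- tabulate(win[keep & codes == 2L], nbins = n_win)
  denom <- g + c_
  vals <- ifelse(denom > 0L, (g - c_) / denom, 0)
  structure(list(replicon_id = replicon$id, skew_class = skew_class,
                 window_size = window_size, values = vals,
                 g_counts = g, c_counts = c_),
            class = "skew_profile")
}

#' Cumulative skew profile
#'
#' Running prefix sum of the per-window skew values; the cumulative GC skew
#' (CGC) curve as plotted along a replicon.
#'
#' @param profile a `skew_profile`.
#' @return object of class `cumulative_profile` with field `cumulative`.
#' @export
cumulative_profile <- function(profile) {
  if (length(profile$values) == 0L) stop("empty skew profile")
  structure(list(replicon_id = profile$replicon_id,
                 skew_class = profile$skew_class,
                 window_size = profile$window_size,
                 cumulative = cumsum(profile$values)),
            class = "cumulative_profile")
}

#' Cumulative gene strand bias (GSB) curve
#'
#' Per-nucleotide counter incremented by 1 inside plus-strand genes,
#' decremented by 1 inside minus-strand genes and unchanged elsewhere, sampled
#' at the last position of each complete window so it shares the index grid of
#' [cumulative_profile()] at the same `window_size`.
#'
#' @param labels a `position_labels`.
#' @param window_size window length in bases.
#' @return object of class `gsb_profile` with field `cumulative`.
#' @export
gsb_profile <- function(labels, window_size = 4096L) {
  window_size <- as.integer(window_size)
  if (window_size < 1L) stop("window_size must be >= 1")
  n <- length(labels$strand_cover)
  n_win <- n %/% window_size
  if (n_win < 1L) stop("no complete window: replicon length ", n,
                       " < window_size ", window_size)
  counter <- cumsum(labels$strand_cover)
  structure(list(replicon_id = labels$replicon_id, window_size = window_size,
                 cumulative = counter[seq_len(n_win) * window_size]),
            class = "gsb_profile")
}

#' Min-max normalise a curve for display
#'
#' Rescales to `[0, 1]` then shifts by `offset`. Display convenience only
#' (curve shape and any Pearson correlation are unchanged); a constant curve
#' returns `0.5 + offset` with a warning.
#'
#' @param curve numeric vector.
#' @param offset additive shift applied after scaling.
#' @return numeric vector.
#' @export
normalize_curve <- function(curve, offset = 0) {
  if (length(curve) == 0L) stop("empty curve")
  rng <- range(curve)
  if (rng[1L] == rng[2L]) {
    warning("constant curve; returning 0.5 + offset")
    return(rep(0.5 + offset, length(curve)))
  }
  (curve - rng[1L]) / (rng[2L] - rng[1L]) + offset
}

#' Write skew profiles to TSV
#'
#' One row per window with 1-based window start coordinates; columns
#' `replicon_id, window_index, window_start, skew_class, skew, cumulative`.
#'
#' @param profiles list of `skew_profile` objects (a single profile is
#'   accepted).
#' @param path output TSV.
#' @export
write_profiles_tsv <- function(profiles, path) {
  if (inherits(profiles, "skew_profile")) profiles <- list(profiles)
  rows <- lapply(profiles, function(p) {
    data.frame(replicon_id = p$replicon_id,
               window_index = seq_along(p$values),
               window_start = (seq_along(p$values) - 1L) * p$window_size + 1L,
               skew_class = p$skew_class,
               skew = p$values,
               cumulative = cumsum(p$values),
               stringsAsFactors = FALSE)
  })
  df <- do.call(rbind, rows)
  write.table(format(df, digits = 12, scientific = FALSE, trim = TRUE),
              path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a profile TSV written by [write_profiles_tsv()]
#' @param path TSV file.
#' @return data.frame with the writer's columns.
#' @export
read_profiles_tsv <- function(path) {
  read.delim(path, stringsAsFactors = FALSE)
}
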