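# Sliding-window aggregation-propensity profiling (AGGRESCAN-style).
#
# Each residue carries an intrinsic aggregation-propensity value (a3v);
# the profile value a4v is the centred moving average of a3v over a
# window whose size grows with sequence length, and a hot spot is a
# maximal run of >= 5 consecutive residues with a4v above the hot-spot
# threshold (HST), none of them proline.

#' Window size used for the aggregation profile
#'
#' Follows the published length classes: 5 for sequences of up to 75
#' residues, 7 up to 175, 9 up to 300, 11 beyond.
#'
#' @param n Sequence length.
#' @return Odd integer window length.
#' @export
aggrescan_window <- function(n) {
  if (n <= 75L) 5L else if (n <= 175L) 7L else if (n <= 300L) 9L else 11L
}

#' Aggregation-propensity profile of a protein sequence
#'
#' @param sequence Amino-acid string (1-letter codes).
#' @param window Odd window length; default chosen from the sequence
#'   length via [aggrescan_window()].
#' @param hst Hot-spot threshold on the windowed profile.
#' @return Object of class `"aggregation_profile"`: list with `a3v`,
#'   `a4v` (per-residue numeric vectors; termini averaged over the
#'   in-sequence part of the window), `hot_spots` (data.frame
#'   `start`/`end` of maximal proline-free runs of length >= 5 with
#'   `a4v > hst`), and `na4vss`, the area of the profile above the
#'   threshold normalised per residue.
#' @examples
#' p <- aggrescan_profile(strrep("S", 20))
#' p$hot_spots  # none: serine is aggregation-averse
#' @export
aggrescan_profile <- function(sequence, window = NULL, hst = AGGRESCAN_HST) {
  aa <- strsplit(toupper(sequence), "")[[1]]
  check_aa(aa)
  n <- length(aa)
  if (is.null(window)) window <- aggrescan_window(n)
  if (window %% 2L != 1L) stop("window length must be odd", call. = FALSE)
  if (n < window)
    stop(sprintf("sequence (length %d) shorter than window (%d)", n, window),
         call. = FALSE)
  a3v <- unname(AGGRESCAN_A3V[aa])
  half <- (window - 1L) %/% 2L
  cs <- cumsum(c(0, a3v))
  lo <- pmax(seq_len(n) - half, 1L)
  hi <- pmin(seq_len(n) + half, n)
  a4v <- (cs[hi + 1L] - cs[lo]) / (hi - lo + 1L)
  hs <- find_hot_spots(a4v, aa, hst)
  na4vss <- sum(pmax(a4v - hst, 0)) / n
  structure(list(sequence = sequence, window = window, hst = hst,
                 a3v = a3v, a4v = a4v, hot_spots = hs, na4vss = na4vss),
            class = "aggregation_profile")
}

# Maximal runs of length >= 5 where a4v > hst and the residue is not P.
find_hot_spots <- function(a4v, aa, hst) {
  ok <- a4v > hst & aa != "P"
  r <- rle(ok)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- r$values & r$lengths >= 5L
  data.frame(start = starts[keep], end = ends[keep])
}

#' @export
print.aggregation_profile <- function(x, ...) {
  cat(sprintf("<aggregation profile> %d residues, window %d, %d hot spot(s), na4vss %.4f\n",
              length(x$a4v), x$window, nrow(x$hot_spots), x$na4vss))
  invisible(x)
}

# Hot spots of `profile` that overlap a residue position (0 or 1 row).
hot_spot_at <- function(profile, position) {
  hs <- profile$hot_spots
  hs[hs$start <= position & hs$end >= position, , drop = FALSE]
}
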