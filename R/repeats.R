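# Seed-sliding identity voting.
#
# Every seed_length window of the mature sequence is a seed.  A seed is
# slid gaplessly over the whole sequence (all offsets with at least one
# overlapping residue, excluding the placement over its own source window)
# and its best placement is the one with the most identical aligned
# residues (smallest placement start on ties; X never matches).  The seed
# then votes for each of its own residues that is identical to its aligned
# partner at that best placement.  A position's score is its votes divided
# by the number of seed windows covering it, so scores live in [0, 1]:
# the fraction of covering seeds whose best self-alignment confirms the
# position as repeated.
#
# The raw mask is score > threshold.  The working mask smooths the scores
# with a centered running mean (window 5, truncated at the ends) before
# thresholding, then drops masked runs shorter than 5 positions: point
# mutations inside repeat units sit between score-1 neighbours and are
# bridged, while sporadic matches at a locally dominant lag in
# non-repetitive sequence are isolated and eliminated.  Both masks are
# kept on the track.

MIN_TRACK_LEN <- 16L
MASK_SMOOTH_HALF <- 2L
MASK_MIN_RUN <- 5L

#' Effective seed length for a mature sequence
#'
#' The configured seed length (default 40) is reduced to
#' `max(min_unit_len, floor(L/3))` for short sequences so that a seed
#' window can lie inside the repeated region of the smallest legal KEP
#' (three 8-residue units); a window much longer than the repeat span
#' dilutes its self-matches with flanking residues.
#'
#' @param length Mature sequence length.
#' @param seed_length Configured seed length.
#' @param min_unit_len Minimum repeat-unit length.
#' @return Integer seed length.
#' @export
effective_seed_length <- function(length, seed_length = 40L,
                                  min_unit_len = 8L) {
  as.integer(min(seed_length, max(min_unit_len, length %/% 3L)))
}

#' Score repeated positions in a mature sequence
#'
#' @param mature Mature amino-acid sequence (single string).
#' @param seed_length Seed window length; reduced for short sequences via
#'   [effective_seed_length()].
#' @param threshold Score above which a position is called repeated.
#' @param min_unit_len Minimum repeat-unit length (drives the seed-length
#'   floor and is recorded on the track).
#' @return An object of class `kep_track`: a list with `mature_length`,
#'   `seed_length` (as used), `n_seeds`, `threshold`, `scores`, `raw_mask`
#'   (`scores > threshold`), `mask` (morphologically cleaned), and
#'   `too_short` (TRUE when the sequence is below the scorable minimum of
#'   16 residues, in which case all scores are 0).
#' @export
#' @examples
#' tr <- repeat_score_track(strrep("YAIGSTVNDQ", 6))
#' all(tr$mask)
repeat_score_track <- function(mature, seed_length = 40L, threshold = 0.6,
                               min_unit_len = 8L) {
  stopifnot(is.character(mature), length(mature) == 1L)
  L <- nchar(mature)
  if (L < MIN_TRACK_LEN) {
    return(new_kep_track(L, NA_integer_, 0L, threshold,
                         numeric(L), too_short = TRUE))
  }
  k <- effective_seed_length(L, seed_length, min_unit_len)
  scores <- vote_scores(mature, k)
  new_kep_track(L, k, L - k + 1L, threshold, scores, too_short = FALSE)
}

new_kep_track <- function(L, k, n_seeds, threshold, scores, too_short) {
  raw <- scores > threshold
  structure(list(mature_length = L, seed_length = k, n_seeds = n_seeds,
                 threshold = threshold, scores = scores, raw_mask = raw,
                 mask = clean_mask(scores, threshold), too_short = too_short),
            class = "kep_track")
}

# fast O(L^2) scorer using per-lag prefix sums; vote-identical to the
# direct per-seed, per-placement definition (see tests for the oracle)
vote_scores <- function(mature, k) {
  x <- utf8ToInt(mature)
  L <- length(x)
  xc <- utf8ToInt("X")
  n_seeds <- L - k + 1L
  s_all <- seq_len(n_seeds)
  best_m <- rep(-1L, n_seeds)
  best_p <- rep(NA_integer_, n_seeds)
  for (d in seq_len(L - 1L)) {
    pm <- as.integer(x[seq_len(L - d)] == x[(1L + d):L] &
                       x[seq_len(L - d)] != xc)
    cs <- c(0L, cumsum(pm))
    # placement p = s - d: source t in [s, s+k-1] matched against t - d
    hi <- pmin(s_all + k - 1L - d, L - d)
    lo <- pmax(s_all - d, 1L)
    ok <- hi >= lo & (s_all - d) >= (2L - k)
    m <- rep(-1L, n_seeds)
    m[ok] <- cs[hi[ok] + 1L] - cs[lo[ok]]
    p <- s_all - d
    upd <- m > best_m | (m == best_m & p < best_p)
    upd[is.na(upd)] <- FALSE
    best_m[upd] <- m[upd]
    best_p[upd] <- p[upd]
    # placement p = s + d: source t matched against t + d
    hi <- pmin(s_all + k - 1L, L - d)
    lo <- s_all
    ok <- hi >= lo & (s_all + d) <= L
    m <- rep(-1L, n_seeds)
    m[ok] <- cs[hi[ok] + 1L] - cs[lo[ok]]
    p <- s_all + d
    upd <- m > best_m | (m == best_m & p < best_p)
    upd[is.na(upd)] <- FALSE
    best_m[upd] <- m[upd]
    best_p[upd] <- p[upd]
  }
  votes <- numeric(L)
  for (s in s_all) {
    if (best_m[s] <= 0L) next
    d <- s - best_p[s]
    t <- s:(s + k - 1L)
    t <- t[t - d >= 1L & t - d <= L]
    m <- x[t] == x[t - d] & x[t] != xc
    votes[t[m]] <- votes[t[m]] + 1
  }
  i <- seq_len(L)
  votes / (pmin(i, n_seeds) - pmax(1L, i - k + 1L) + 1L)
}

clean_mask <- function(scores, threshold) {
  L <- length(scores)
  if (L == 0) return(logical(0))
  cs <- c(0, cumsum(scores))
  lo <- pmax(1L, seq_len(L) - MASK_SMOOTH_HALF)
  hi <- pmin(L, seq_len(L) + MASK_SMOOTH_HALF)
  smoothed <- (cs[hi + 1L] - cs[lo]) / (hi - lo + 1L)
  m <- smoothed > threshold
  r <- rle(m)
  r$values[r$values & r$lengths < MASK_MIN_RUN] <- FALSE
  inverse.rle(r)
}

#' Number of parts induced by the repeat mask
#'
#' The sequence is partitioned at every position where the mask flips, so
#' alternating repeated/non-repeated blocks each count as one part.
#'
#' @param track A `kep_track`.
#' @return Integer number of maximal mask blocks (1 for an empty or
#'   constant mask).
#' @export
tandem_repeat_parts <- function(track) {
  stopifnot(inherits(track, "kep_track"))
  if (length(track$mask) == 0) return(1L)
  length(rle(track$mask)$lengths)
}

#' Is the sequence tandem-repetitive?
#'
#' TRUE when the mask divides the sequence into more than 2 parts.
#'
#' @param track A `kep_track`.
#' @return Logical.
#' @export
is_tandem_repetitive <- function(track) {
  tandem_repeat_parts(track) > 2L
}

#' @export
print.kep_track <- function(x, ...) {
  cat(sprintf("<kep_track> length %d, seed %s, %d seeds, %d/%d masked (%d parts)\n",
              x$mature_length,
              ifelse(is.na(x$seed_length), "-", x$seed_length),
              x$n_seeds, sum(x$mask), x$mature_length,
              tandem_repeat_parts(x)))
  invisible(x)
}

#' @rdname tidy.kep_track
#' @exportS3Method generics::tidy
tidy.kep_track <- function(x, ...) {
  tibble(position = seq_len(x$mature_length),
         score = x$scores, raw_mask = x$raw_mask, mask = x$mask)
}

#' Tidy a repeat score track
#'
#' @param x A `kep_track`.
#' @param ... Unused.
#' @return A tibble with one row per mature position: `position`, `score`,
#'   `raw_mask`, `mask`.
#' @name tidy.kep_track
NULL
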