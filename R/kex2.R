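# Dibasic-site parsing and the KEP acceptance filter.
#
# Rejection reasons, in pipeline order (each protein gets the first
# failing stage): NO_SIGNAL, TOO_SHORT, NOT_REPETITIVE, NO_KEX2_SITE,
# FRAGMENT_TOO_LONG, UNITS_TOO_SHORT, TOO_FEW_UNITS.

REJECTION_REASONS <- c("NO_SIGNAL", "TOO_SHORT", "NOT_REPETITIVE",
                       "NO_KEX2_SITE", "FRAGMENT_TOO_LONG",
                       "UNITS_TOO_SHORT", "TOO_FEW_UNITS")

#' Locate Kex2 recognition sites
#'
#' Scans left to right; at each position, if the 2-mer is one of the
#' dibasic motifs it is recorded and scanning resumes after it
#' (non-overlapping, leftmost-greedy), matching cleavage after the dibasic
#' motif by the Golgi protease.
#'
#' @param mature Mature sequence (single string).
#' @param motifs Dibasic motifs.
#' @return A tibble of 0-based half-open intervals (`start`, `end`), one
#'   row per site.
#' @export
#' @examples
#' find_kex2_sites("AAAKRBBBKKCCC")
find_kex2_sites <- function(mature, motifs = c("KR", "KK", "RK", "RR")) {
  stopifnot(is.character(mature), length(mature) == 1L, nchar(mature) > 0)
  x <- strsplit(mature, "")[[1]]
  L <- length(x)
  starts <- integer(0)
  i <- 1L
  while (i < L) {
    if (paste0(x[i], x[i + 1L]) %in% motifs) {
      starts <- c(starts, i)
      i <- i + 2L
    } else i <- i + 1L
  }
  tibble(start = starts - 1L, end = starts + 1L)
}

#' Split a mature sequence at Kex2 sites
#'
#' Fragments are the maximal intervals between consecutive sites and the
#' sequence ends; site residues are excluded and empty fragments dropped.
#' Motif content flags record whether a fragment contains Y, HH or W.
#'
#' @inheritParams find_kex2_sites
#' @return A tibble with 0-based half-open `start`, `end`, `sequence`,
#'   `contains_y`, `contains_hh`, `contains_w`.
#' @export
split_fragments <- function(mature, motifs = c("KR", "KK", "RK", "RR")) {
  sites <- find_kex2_sites(mature, motifs)
  L <- nchar(mature)
  bounds_start <- c(0L, sites$end)
  bounds_end <- c(sites$start, L)
  keep <- bounds_end > bounds_start
  out <- tibble(start = bounds_start[keep], end = bounds_end[keep])
  out$sequence <- if (nrow(out)) substring(mature, out$start + 1L, out$end)
    else character(0)
  out$contains_y <- grepl("Y", out$sequence, fixed = TRUE)
  out$contains_hh <- grepl("HH", out$sequence, fixed = TRUE)
  out$contains_w <- grepl("W", out$sequence, fixed = TRUE)
  out
}

#' Classify fragments as repeat units
#'
#' A fragment is a repeat unit when at least `min_masked_fraction` of its
#' positions are masked as repeated and its length lies in
#' `[min_unit_len, max_unit_len]`.
#'
#' @param fragments Tibble from [split_fragments()].
#' @param track `kep_track` computed on the same mature sequence.
#' @param min_masked_fraction Masked-fraction threshold.
#' @param min_unit_len,max_unit_len Unit length bounds.
#' @return `fragments` with `masked_fraction`, `is_candidate` (masked
#'   fraction passes, any length) and `is_repeat_unit` columns.
#' @export
classify_repeat_units <- function(fragments, track,
                                  min_masked_fraction = 0.5,
                                  min_unit_len = 8L, max_unit_len = 100L) {
  stopifnot(inherits(track, "kep_track"))
  if (nrow(fragments) > 0 &&
      max(fragments$end) > track$mature_length)
    stop("fragment coordinates exceed track length", call. = FALSE)
  frac <- vapply(seq_len(nrow(fragments)), function(z)
    mean(track$mask[(fragments$start[z] + 1L):fragments$end[z]]), 0)
  len <- fragments$end - fragments$start
  fragments$masked_fraction <- if (nrow(fragments)) frac else numeric(0)
  fragments$is_candidate <- fragments$masked_fraction >= min_masked_fraction
  fragments$is_repeat_unit <- fragments$is_candidate &
    len >= min_unit_len & len <= max_unit_len
  fragments
}

#' Call a single protein as KEP or rejected
#'
#' Applies the staged filter: signal peptide, mature length (>= 16),
#' tandem repetitiveness (mask splits the mature sequence into more than
#' 2 parts), presence of Kex2 sites, no fragment longer than
#' `max_fragment_len`, and at least `min_units` repeat units of
#' `min_unit_len` or more.  When fewer than `min_units` units qualify, the
#' reason is `UNITS_TOO_SHORT` if enough fragments pass the masked-fraction
#' rule but are too short, else `TOO_FEW_UNITS`.
#'
#' @param sequence Full protein sequence.
#' @param has_signal,cleavage_pos Signal prediction for this protein.
#' @param params [kep_params()].
#' @return A list with `accepted`, `reason` (NA when accepted), `mature`,
#'   `fragments` (tibble incl. unit classification), `track`.
#' @export
call_kep <- function(sequence, has_signal, cleavage_pos,
                     params = kep_params()) {
  reject <- function(reason, mature = NA_character_, fragments = NULL,
                     track = NULL)
    list(accepted = FALSE, reason = reason, mature = mature,
         fragments = fragments, track = track)
  if (!isTRUE(has_signal)) return(reject("NO_SIGNAL"))
  mature <- mature_sequence(sequence, cleavage_pos)
  if (nchar(mature) < MIN_TRACK_LEN) return(reject("TOO_SHORT", mature))
  track <- repeat_score_track(mature, params$seed_length,
                              params$repeat_threshold, params$min_unit_len)
  if (!is_tandem_repetitive(track))
    return(reject("NOT_REPETITIVE", mature, track = track))
  frags <- split_fragments(mature, params$kex2_motifs)
  sites <- find_kex2_sites(mature, params$kex2_motifs)
  if (nrow(sites) == 0)
    return(reject("NO_KEX2_SITE", mature, frags, track))
  if (any(frags$end - frags$start > params$max_fragment_len))
    return(reject("FRAGMENT_TOO_LONG", mature, frags, track))
  frags <- classify_repeat_units(frags, track, params$masked_fraction,
                                 params$min_unit_len, params$max_unit_len)
  n_units <- sum(frags$is_repeat_unit)
  if (n_units < params$min_units) {
    reason <- if (sum(frags$is_candidate) >= params$min_units)
      "UNITS_TOO_SHORT" else "TOO_FEW_UNITS"
    return(reject(reason, mature, frags, track))
  }
  list(accepted = TRUE, reason = NA_character_, mature = mature,
       fragments = frags, track = track)
}

#' Detect KEPs in a proteome
#'
#' Runs [call_kep()] over every protein and records the funnel counts
#' (proteins, signal-positive, tandem-repetitive, accepted KEPs) as the
#' `"funnel"` attribute (see [kep_funnel()]).
#'
#' @param proteins Proteins tibble.
#' @param predictions Signal predictions; when NULL the built-in heuristic
#'   [predict_signal()] is used.
#' @param params [kep_params()].
#' @return A tibble with one row per protein: identifiers, `accepted`,
#'   `reason`, `mature`, `n_fragments`, `n_units` and a `fragments`
#'   list-column.
#' @export
kep_detect <- function(proteins, predictions = NULL,
                       params = kep_params()) {
  if (is.null(predictions)) predictions <- predict_signal(proteins)
  withm <- add_mature(proteins, predictions)
  calls <- purrr::pmap(list(withm$sequence, withm$has_signal,
                            withm$cleavage_pos),
                       function(s, h, c) call_kep(s, h, c, params))
  out <- tibble(
    protein_id = withm$protein_id,
    strain_id = withm$strain_id %||% "",
    genus = withm$genus %||% "",
    phylum = withm$phylum %||% "",
    has_signal = withm$has_signal,
    accepted = vapply(calls, `[[`, TRUE, "accepted"),
    reason = vapply(calls, `[[`, "", "reason"),
    mature = vapply(calls, function(cl)
      cl$mature %||% NA_character_, ""),
    n_fragments = vapply(calls, function(cl)
      if (is.null(cl$fragments)) NA_integer_ else nrow(cl$fragments), 0L),
    n_units = vapply(calls, function(cl)
      if (is.null(cl$fragments) ||
          !"is_repeat_unit" %in% names(cl$fragments))
        NA_integer_ else sum(cl$fragments$is_repeat_unit), 0L),
    fragments = lapply(calls, `[[`, "fragments")
  )
  funnel <- c(proteins = nrow(out),
              with_signal = sum(out$has_signal),
              repetitive = sum(out$has_signal &
                                 !out$reason %in%
                                 c("NO_SIGNAL", "TOO_SHORT", "NOT_REPETITIVE")),
              keps = sum(out$accepted))
  attr(out, "funnel") <- funnel
  out
}

#' Funnel counts of a detection run
#'
#' @param detection Result of [kep_detect()].
#' @return Named integer vector: proteins, with_signal, repetitive, keps.
#' @export
kep_funnel <- function(detection) attr(detection, "funnel")

#' Repeat units of accepted KEPs
#'
#' @param detection Result of [kep_detect()].
#' @return One row per repeat unit: `protein_id`, `unit_id`, 0-based
#'   half-open `start`/`end` on the mature sequence, `sequence`.
#' @export
kep_units <- function(detection) {
  acc <- detection[detection$accepted, , drop = FALSE]
  if (nrow(acc) == 0)
    return(tibble(protein_id = character(), unit_id = character(),
                  start = integer(), end = integer(), sequence = character()))
  purrr::map2_dfr(acc$protein_id, acc$fragments, function(pid, fr) {
    fr <- fr[fr$is_repeat_unit, , drop = FALSE]
    tibble(protein_id = pid,
           unit_id = paste0(pid, "_u", seq_len(nrow(fr))),
           start = fr$start, end = fr$end, sequence = fr$sequence)
  })
}

`%||%` <- function(a, b) if (is.null(a)) b else a
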