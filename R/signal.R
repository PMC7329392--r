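# Built-in signal-peptide heuristic.  It mirrors the classic tripartite
# architecture of an ER signal peptide (positively charged n-region,
# hydrophobic h-region, small-residue c-region ending at the cleavage
# site) with fixed, auditable rules, so the test suite needs no external
# predictor.  Real analyses should supply SignalP output via
# read_signalp(); the synthetic generator constructs signals to these
# exact rules.

SIG_HYDRO <- c("A", "C", "F", "I", "L", "M", "V", "W")
SIG_SMALL <- c("A", "G", "S", "T", "C")

#' Heuristic signal-peptide prediction
#'
#' A protein is called signal-positive when, within its first 45 residues:
#' (i) at least one K or R occurs at positions 1-6; (ii) a run of 8 or more
#' consecutive hydrophobic residues (A, C, F, I, L, M, V, W) starts at a
#' position in 2-15; and (iii) a small-residue motif `[AGSTC]-x-[AGSTC]`
#' ends at a position p with `hEnd + 2 <= p <= 40`, where `hEnd` is the end
#' of the (maximal) hydrophobic run.  The cleavage position is the smallest
#' such p, i.e. the last residue of the signal peptide.  Sequences shorter
#' than 25 residues are signal-negative.
#'
#' @param proteins A proteins tibble (see [read_proteins()]), or a character
#'   vector of sequences.
#' @return A tibble with `protein_id`, `has_signal`, `cleavage_pos`
#'   (NA when signal-negative) and `source = "heuristic"`.
#' @export
#' @examples
#' predict_signal(tibble::tibble(protein_id = "p1",
#'   sequence = strrep("MKWLLVLLLIFDDDNQASAEQ", 3)))
predict_signal <- function(proteins) {
  if (is.character(proteins))
    proteins <- tibble(protein_id = if (!is.null(names(proteins)))
      names(proteins) else paste0("p", seq_along(proteins)),
      sequence = proteins)
  res <- vapply(proteins$sequence, signal_cleavage_pos, 0L, USE.NAMES = FALSE)
  tibble(protein_id = proteins$protein_id,
         has_signal = res > 0L,
         cleavage_pos = ifelse(res > 0L, res, NA_integer_),
         source = "heuristic")
}

# returns 0 when signal-negative, else the 1-based cleavage position
signal_cleavage_pos <- function(sequence) {
  L <- nchar(sequence)
  if (L < 25) return(0L)
  x <- strsplit(substr(sequence, 1, min(45L, L)), "")[[1]]
  n <- length(x)
  if (!any(x[1:6] %in% c("K", "R"))) return(0L)
  hydro <- x %in% SIG_HYDRO
  r <- rle(hydro)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  ok <- r$values & r$lengths >= 8 & starts >= 2 & starts <= 15
  if (!any(ok)) return(0L)
  h_end <- ends[which(ok)[1]]
  p_max <- min(40L, n)
  p_min <- h_end + 2L
  if (p_min > p_max || p_min < 3L) p_min <- max(p_min, 3L)
  if (p_min > p_max) return(0L)
  for (p in p_min:p_max)
    if (x[p - 2L] %in% SIG_SMALL && x[p] %in% SIG_SMALL) {
      if (p < L) return(as.integer(p))  # mature part must be non-empty
      return(0L)
    }
  0L
}

#' Mature sequence after signal-peptide removal
#'
#' @param sequence Full protein sequence(s).
#' @param cleavage_pos 1-based index of the last signal residue; NA means
#'   no signal.
#' @return Character vector of mature sequences; `NA` where there is no
#'   signal.  Errors if `cleavage_pos` is outside `[1, nchar - 1]`.
#' @export
mature_sequence <- function(sequence, cleavage_pos) {
  bad <- !is.na(cleavage_pos) &
    (cleavage_pos < 1L | cleavage_pos >= nchar(sequence))
  if (any(bad))
    stop("cleavage_pos out of range for sequence(s) ",
         paste(head(which(bad), 5), collapse = ", "), call. = FALSE)
  ifelse(is.na(cleavage_pos), NA_character_,
         substr(sequence, cleavage_pos + 1L, nchar(sequence)))
}

#' Attach signal predictions and mature sequences to a proteome
#'
#' @param proteins Proteins tibble.
#' @param predictions Signal predictions ([read_signalp()] or
#'   [predict_signal()]); proteins absent from the table are treated as
#'   signal-negative.
#' @return `proteins` with `has_signal`, `cleavage_pos` and `mature`
#'   columns appended.
#' @export
add_mature <- function(proteins, predictions) {
  out <- left_join(proteins,
                   predictions[, c("protein_id", "has_signal", "cleavage_pos")],
                   by = "protein_id")
  out$has_signal[is.na(out$has_signal)] <- FALSE
  out$cleavage_pos[!out$has_signal] <- NA_integer_
  out$mature <- mature_sequence(out$sequence, out$cleavage_pos)
  out
}
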