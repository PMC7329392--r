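#' Pipeline parameters
#'
#' Collects every numeric threshold used across the pipeline.  Defaults are
#' the published values of the KEP survey where one exists: a 40-residue
#' seed, a repeat score threshold of 0.6, repeat units of 8 to 100 residues,
#' at least 3 units, no Kex2 fragment longer than 100 residues, reciprocal
#' E-value < 1e-30 with coverage > 70% for typing, identity > 65% with
#' coverage > 70% for repeat-unit sub-typing, identity and coverage > 95%
#' for set comparison, E < 1e-10 for pheromone annotation, domain E-value
#' 1e-5, and a vicinity radius of 15 genes on each side.
#'
#' @param seed_length Seed window length in residues for repeat scoring.
#' @param repeat_threshold Per-position vote fraction above which a position
#'   is called repeated.
#' @param min_unit_len,max_unit_len Repeat-unit length bounds (residues).
#' @param max_fragment_len Longest admissible Kex2 fragment (residues).
#' @param min_units Minimum number of repeat units for a KEP call.
#' @param kex2_motifs Dibasic recognition motifs, scanned left to right
#'   without overlap.
#' @param masked_fraction Fraction of a fragment's positions that must be
#'   masked as repeated for the fragment to count as a repeat unit.
#' @param type_evalue,type_coverage Reciprocal-hit thresholds for KEP typing.
#' @param subtype_identity,subtype_coverage Reciprocal thresholds for
#'   grouping repeat units into sub-types.
#' @param setcompare_identity,setcompare_coverage Thresholds for declaring
#'   two KEPs from different surveys identical.
#' @param pheromone_evalue E-value below which a hit against a pheromone
#'   precursor query annotates a KEP as a pheromone.
#' @param domain_evalue Full-sequence E-value cut-off for domain hits.
#' @param vicinity_radius Gene-rank distance surveyed on each side of a
#'   KEP-encoding gene.
#' @param allhits_max_dist Distance cap when averaging over all vicinity
#'   hits rather than nearest hits.
#' @param alignment An [alignment_params()] object.
#'
#' @return A list of class `kep_params`.
#' @export
#' @examples
#' p <- kep_params(repeat_threshold = 0.5)
#' p$repeat_threshold
kep_params <- function(seed_length = 40,
                       repeat_threshold = 0.6,
                       min_unit_len = 8,
                       max_unit_len = 100,
                       max_fragment_len = 100,
                       min_units = 3,
                       kex2_motifs = c("KR", "KK", "RK", "RR"),
                       masked_fraction = 0.5,
                       type_evalue = 1e-30,
                       type_coverage = 0.70,
                       subtype_identity = 0.65,
                       subtype_coverage = 0.70,
                       setcompare_identity = 0.95,
                       setcompare_coverage = 0.95,
                       pheromone_evalue = 1e-10,
                       domain_evalue = 1e-5,
                       vicinity_radius = 15,
                       allhits_max_dist = 10,
                       alignment = alignment_params()) {
  stopifnot(seed_length >= 8, repeat_threshold > 0,
            min_unit_len >= 1, max_unit_len >= min_unit_len,
            max_fragment_len >= min_unit_len, min_units >= 1,
            all(nchar(kex2_motifs) == 2L),
            masked_fraction > 0, masked_fraction <= 1,
            type_evalue > 0, type_coverage > 0,
            vicinity_radius >= 0, allhits_max_dist >= 1)
  structure(list(
    seed_length = seed_length, repeat_threshold = repeat_threshold,
    min_unit_len = min_unit_len, max_unit_len = max_unit_len,
    max_fragment_len = max_fragment_len, min_units = min_units,
    kex2_motifs = kex2_motifs, masked_fraction = masked_fraction,
    type_evalue = type_evalue, type_coverage = type_coverage,
    subtype_identity = subtype_identity, subtype_coverage = subtype_coverage,
    setcompare_identity = setcompare_identity,
    setcompare_coverage = setcompare_coverage,
    pheromone_evalue = pheromone_evalue, domain_evalue = domain_evalue,
    vicinity_radius = vicinity_radius, allhits_max_dist = allhits_max_dist,
    alignment = alignment
  ), class = "kep_params")
}

#' Local-alignment scoring parameters
#'
#' Smith-Waterman scoring scheme and Karlin-Altschul constants used to turn
#' raw scores into E-values.  The defaults are BLOSUM62 with gap open 11 /
#' extend 1 and the standard gapped constants lambda = 0.267, K = 0.041 for
#' that scheme.  In `database` search-space mode the E-value uses the total
#' residue count of the database as `n`.
#'
#' @param matrix Substitution matrix name (resolved via
#'   `Biostrings`' bundled score matrices).
#' @param gap_open,gap_extend Positive gap penalties; a gap of length k
#'   costs `gap_open + k * gap_extend`.
#' @param ka_lambda,ka_k Karlin-Altschul parameters.
#'
#' @return A list of class `kep_alignment_params`.
#' @export
alignment_params <- function(matrix = "BLOSUM62", gap_open = 11,
                             gap_extend = 1, ka_lambda = 0.267,
                             ka_k = 0.041) {
  stopifnot(gap_open > 0, gap_extend > 0, ka_lambda > 0, ka_k > 0)
  structure(list(matrix = matrix, gap_open = gap_open,
                 gap_extend = gap_extend, ka_lambda = ka_lambda,
                 ka_k = ka_k),
            class = "kep_alignment_params")
}

#' @export
print.kep_params <- function(x, ...) {
  cat("<kep_params>\n")
  flat <- x[!vapply(x, inherits, TRUE, "kep_alignment_params")]
  for (nm in names(flat))
    cat(sprintf("  %-22s %s\n", nm, paste(flat[[nm]], collapse = " ")))
  cat(sprintf("  alignment: %s open=%d extend=%d lambda=%.3f K=%.3f\n",
              x$alignment$matrix, x$alignment$gap_open,
              x$alignment$gap_extend, x$alignment$ka_lambda,
              x$alignment$ka_k))
  invisible(x)
}
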