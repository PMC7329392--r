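# Functional annotation of KEPs and census tables.

PFAM_MF_ALPHA <- c("PF04648", "PF05436")

#' Flag yeast alpha-mating-factor KEPs
#'
#' TRUE for proteins carrying an MF_alpha (PF04648) or MF_alpha_N (PF05436)
#' domain hit at or below the domain E-value threshold.
#'
#' @param protein_ids Protein ids to flag.
#' @param domains Domain hits ([read_domains()]).
#' @param evalue_threshold Full-sequence E-value cut-off.
#' @return Logical vector parallel to `protein_ids`.
#' @export
flag_mating_factor <- function(protein_ids, domains,
                               evalue_threshold = 1e-5) {
  hits <- domains[domains$domain_accession %in% PFAM_MF_ALPHA &
                    domains$evalue <= evalue_threshold, ]
  protein_ids %in% hits$protein_id
}

#' Flag pheromone-like KEPs by similarity to precursor queries
#'
#' A sequence is flagged when its best local alignment against any query
#' has an E-value below the threshold, computed in database mode over the
#' total residue count of the query set.
#'
#' @param sequences Character vector of KEP sequences.
#' @param queries Named character vector of precursor peptide queries
#'   (empty set flags nothing).
#' @param e_threshold E-value threshold.
#' @param params [alignment_params()].
#' @return Logical vector parallel to `sequences`.
#' @export
flag_pheromone <- function(sequences, queries, e_threshold = 1e-10,
                           params = alignment_params()) {
  if (length(queries) == 0) return(rep(FALSE, length(sequences)))
  db <- sum(nchar(queries))
  vapply(sequences, function(s) {
    for (q in queries) {
      hit <- local_align(s, q, params, db_size = db)
      if (hit$evalue < e_threshold) return(TRUE)
    }
    FALSE
  }, TRUE, USE.NAMES = FALSE)
}

#' Motif content rate of repeat units
#'
#' Fraction of repeat units (restricted to the legal 8-100 residue length
#' range) containing at least one occurrence of a plain-substring motif
#' such as "Y", "HH" or "W".
#'
#' @param units Character vector of repeat-unit sequences.
#' @param motif Substring to search for.
#' @param min_len,max_len Length restriction applied before counting.
#' @return A fraction in \[0, 1\] (NaN for an empty set).
#' @export
#' @examples
#' motif_content_rate(c("YAIGSTVN", "AAAAAAAA"), "Y")
motif_content_rate <- function(units, motif, min_len = 8L, max_len = 100L) {
  units <- units[nchar(units) >= min_len & nchar(units) <= max_len]
  mean(grepl(motif, units, fixed = TRUE))
}

#' Per-phylum census of detected KEPs
#'
#' One row per phylum: strains surveyed, strains with at least one KEP,
#' genera, total KEPs (and how many have a DUF3328 gene in the vicinity),
#' mean and sample SD of per-strain KEP counts.  Means and SDs are taken
#' over all surveyed strains, with zero counts for strains in which
#' nothing was found, matching the published census arithmetic
#' (total KEPs / surveyed strains).
#'
#' @param keps Tibble with one row per accepted KEP: `protein_id`,
#'   `strain_id`, `genus`, `phylum`, and optionally `duf3328` (logical).
#' @param strains Tibble of surveyed strains: `strain_id`, `genus`,
#'   `phylum` (needed so strains without KEPs enter the denominator).
#' @return Tibble with one row per phylum plus a `Total` row.
#' @export
phylum_summary <- function(keps, strains) {
  stopifnot(all(c("strain_id", "phylum") %in% names(strains)))
  duf <- if ("duf3328" %in% names(keps)) keps$duf3328 else
    rep(FALSE, nrow(keps))
  per_strain <- strains |>
    left_join(keps |> count(.data$strain_id, name = "n_keps"),
              by = "strain_id") |>
    mutate(n_keps = dplyr::coalesce(.data$n_keps, 0L))
  one <- function(tbl, kp, dufv, label) {
    tibble(phylum = label,
           strains_surveyed = nrow(tbl),
           strains_found = sum(tbl$n_keps > 0),
           genera = dplyr::n_distinct(tbl$genus),
           total_keps = sum(tbl$n_keps),
           keps_with_duf3328 = sum(dufv),
           mean_keps_per_strain = mean(tbl$n_keps),
           sd_keps_per_strain = if (nrow(tbl) > 1) sd(tbl$n_keps) else 0)
  }
  phyla <- sort(unique(strains$phylum))
  rows <- lapply(phyla, function(ph)
    one(per_strain[per_strain$phylum == ph, ],
        keps[keps$phylum == ph, ], duf[keps$phylum == ph], ph))
  bind_rows(bind_rows(rows), one(per_strain, keps, duf, "Total"))
}

#' Per-type census of KEP types
#'
#' One row per type (stand-alone KEPs under label "0"): member count,
#' distinct strains, KEPs per strain, distinct genera and phyla, members
#' with and without a DUF3328 gene in the vicinity, and annotation flag
#' counts.
#'
#' @param keps Tibble with one row per accepted KEP: `protein_id`,
#'   `strain_id`, `genus`, `phylum`; optional logical columns `duf3328`,
#'   `mating_factor`, `pheromone`, `basidio_pheromone`.
#' @param types `kep_types` or an assignments tibble (`protein_id`,
#'   `type_label`).
#' @return Tibble sorted by decreasing count, stand-alones last.
#' @export
type_summary <- function(keps, types) {
  assignments <- if (inherits(types, "kep_types")) types$assignments else types
  x <- keps[, setdiff(names(keps), "type_label")]
  x <- left_join(x, assignments, by = "protein_id")
  lgl <- function(col) if (col %in% names(x)) x[[col]] else
    rep(FALSE, nrow(x))
  x$..duf <- lgl("duf3328")
  x$..mat <- lgl("mating_factor")
  x$..phe <- lgl("pheromone")
  x$..bas <- lgl("basidio_pheromone")
  out <- x |>
    group_by(.data$type_label) |>
    summarise(count = n(),
              strains = dplyr::n_distinct(.data$strain_id),
              keps_per_strain = n() / dplyr::n_distinct(.data$strain_id),
              genera = dplyr::n_distinct(.data$genus),
              phyla = dplyr::n_distinct(.data$phylum),
              mating_factors = sum(.data$..mat),
              pheromones = sum(.data$..phe),
              basidio_pheromones = sum(.data$..bas),
              with_duf3328 = sum(.data$..duf),
              without_duf3328 = sum(!.data$..duf),
              .groups = "drop") |>
    arrange(.data$type_label == "0", desc(.data$count), .data$type_label)
  out
}
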