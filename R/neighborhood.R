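# Gene-rank vicinity analysis around KEP-encoding genes.
#
# Distance between genes on the same contig is the absolute difference of
# their start-order ranks (adjacent genes = 1); strand is ignored and
# distances are undefined across contigs, because the survey counts genes,
# not base pairs.

#' Build a gene neighborhood from gene records
#'
#' Genes are ranked per contig by start coordinate.
#'
#' @param genes Tibble from [read_genes()] (or the simulator).
#' @return A tibble `gene_id`, `protein_id`, `contig_id`, `rank`, of class
#'   `kep_neighborhood`.
#' @export
gene_neighborhood <- function(genes) {
  out <- genes |>
    group_by(.data$contig_id) |>
    arrange(.data$start, .by_group = TRUE) |>
    mutate(rank = row_number()) |>
    ungroup() |>
    select("gene_id", "protein_id", "contig_id", "rank")
  class(out) <- c("kep_neighborhood", class(out))
  out
}

#' Genes in the vicinity of a protein's gene
#'
#' @param neighborhood From [gene_neighborhood()].
#' @param protein_id Protein whose gene anchors the window.
#' @param radius Rank distance included on each side.
#' @return Neighbor rows with a signed `distance` column (negative =
#'   upstream in rank order); the anchor gene itself is excluded and the
#'   window is truncated at contig ends.
#' @export
vicinity_genes <- function(neighborhood, protein_id, radius = 15L) {
  anchor <- neighborhood[neighborhood$protein_id == protein_id, ]
  if (nrow(anchor) == 0) {
    warning("protein ", protein_id, " has no gene in the neighborhood",
            call. = FALSE)
    return(neighborhood[0, ])
  }
  anchor <- anchor[1, ]
  out <- neighborhood |>
    filter(.data$contig_id == anchor$contig_id,
           .data$rank != anchor$rank,
           abs(.data$rank - anchor$rank) <= radius) |>
    mutate(distance = .data$rank - anchor$rank)
  out
}

#' Vicinity statistics for one domain label
#'
#' Counts labelled genes at every rank distance 1..radius around each KEP
#' gene (both sides summed), the per-KEP nearest labelled gene, and the
#' fraction of KEPs with at least one labelled gene in the window.
#' `nearest_mean` averages the nearest-hit distance over KEPs with a hit;
#' `allhits_mean` averages the distance of all hits at distance
#' `<= allhits_max_dist`.
#'
#' @param neighborhood From [gene_neighborhood()].
#' @param kep_ids Protein ids of the KEPs.
#' @param labels Tibble `protein_id`, `label` marking labelled genes
#'   (a protein may carry several labels).
#' @param label The label surveyed (e.g. `"DUF3328"`).
#' @param radius Window half-width in gene ranks.
#' @param allhits_max_dist Distance cap for `allhits_mean`.
#' @return Object of class `kep_vicinity`: list with `histogram`
#'   (`distance`, `count`), `nearest` (`protein_id`, `nearest`, NA when no
#'   hit), `total`, `nearest_mean`, `allhits_mean`,
#'   `fraction_of_keps_with_hit`, `label`, `radius`.
#' @export
domain_vicinity_stats <- function(neighborhood, kep_ids, labels, label,
                                  radius = 15L, allhits_max_dist = 10L) {
  labelled <- unique(labels$protein_id[labels$label == label])
  nb_lab <- neighborhood[neighborhood$protein_id %in% labelled, ]
  present <- kep_ids %in% neighborhood$protein_id
  if (any(!present))
    warning(sum(!present), " KEP(s) not mapped to a gene; excluded",
            call. = FALSE)
  kep_ids <- kep_ids[present]
  anchors <- neighborhood[match(kep_ids, neighborhood$protein_id), ]
  all_d <- integer(0)
  nearest <- rep(NA_integer_, length(kep_ids))
  for (z in seq_along(kep_ids)) {
    on_contig <- nb_lab[nb_lab$contig_id == anchors$contig_id[z], ]
    d <- abs(on_contig$rank - anchors$rank[z])
    d <- d[d >= 1L & d <= radius]
    if (length(d)) {
      nearest[z] <- min(d)
      all_d <- c(all_d, d)
    }
  }
  histogram <- tibble(distance = seq_len(radius),
                      count = vapply(seq_len(radius),
                                     function(d) sum(all_d == d), 0L))
  hit <- !is.na(nearest)
  structure(list(
    histogram = histogram,
    nearest = tibble(protein_id = kep_ids, nearest = nearest),
    total = length(all_d),
    nearest_mean = if (any(hit)) mean(nearest[hit]) else NA_real_,
    allhits_mean = if (any(all_d <= allhits_max_dist))
      mean(all_d[all_d <= allhits_max_dist]) else NA_real_,
    fraction_of_keps_with_hit = if (length(kep_ids)) mean(hit) else NA_real_,
    label = label, radius = radius
  ), class = "kep_vicinity")
}

#' Vicinity statistics stratified by a conditioning label
#'
#' KEPs are partitioned by whether any `condition_label` gene lies within
#' the radius; [domain_vicinity_stats()] for `domain_label` is computed
#' separately in each stratum (e.g. Tyrosinase counts conditioned on
#' DUF3328 presence).
#'
#' @inheritParams domain_vicinity_stats
#' @param domain_label Label whose counts are reported.
#' @param condition_label Label defining the strata.
#' @return List with elements `with` and `without`, each a `kep_vicinity`.
#' @export
conditional_histogram <- function(neighborhood, kep_ids, labels,
                                  domain_label, condition_label,
                                  radius = 15L, allhits_max_dist = 10L) {
  cond <- domain_vicinity_stats(neighborhood, kep_ids, labels,
                                condition_label, radius, allhits_max_dist)
  has <- cond$nearest$protein_id[!is.na(cond$nearest$nearest)]
  strata <- list(with = intersect(kep_ids, has),
                 without = setdiff(kep_ids, has))
  lapply(strata, function(ids)
    domain_vicinity_stats(neighborhood, ids, labels, domain_label,
                          radius, allhits_max_dist))
}

#' Co-occurrence of KEP-encoding genes
#'
#' Vicinity statistics where the surveyed label is "is a KEP": for each
#' KEP, other KEP genes within the radius.
#'
#' @inheritParams domain_vicinity_stats
#' @return A `kep_vicinity`.
#' @export
cooccurring_keps <- function(neighborhood, kep_ids, radius = 15L,
                             allhits_max_dist = 10L) {
  labels <- tibble(protein_id = kep_ids, label = "KEP")
  domain_vicinity_stats(neighborhood, kep_ids, labels, "KEP",
                        radius, allhits_max_dist)
}

#' @export
print.kep_vicinity <- function(x, ...) {
  cat(sprintf("<kep_vicinity> %s: %d hits within %d; fraction %.3f; nearest mean %.2f\n",
              x$label, x$total, x$radius,
              x$fraction_of_keps_with_hit %||% NA,
              x$nearest_mean %||% NA))
  invisible(x)
}

#' Tidy vicinity statistics
#'
#' @param x A `kep_vicinity`.
#' @param ... Unused.
#' @return The per-distance histogram tibble with the label attached.
#' @exportS3Method generics::tidy
tidy.kep_vicinity <- function(x, ...) {
  mutate(x$histogram, label = x$label)
}

#' One-row vicinity summary
#'
#' @param x A `kep_vicinity`.
#' @param ... Unused.
#' @return Tibble with label, totals, means and the fraction of KEPs with
#'   a hit.
#' @exportS3Method generics::glance
glance.kep_vicinity <- function(x, ...) {
  tibble(label = x$label, total = x$total,
         nearest_mean = x$nearest_mean, allhits_mean = x$allhits_mean,
         fraction_of_keps_with_hit = x$fraction_of_keps_with_hit,
         radius = x$radius)
}
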