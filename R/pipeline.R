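# End-to-end orchestration: detect -> classify -> vicinity -> annotate ->
# report, with funnel logging and a reproducibility manifest.

#' Run the full KEP pipeline
#'
#' Stages: signal gating and repeat detection ([kep_detect()]), KEP typing
#' ([kep_type_clustering()]), repeat-unit sub-typing
#' ([subtype_repeat_units()]), DUF3328/Tyrosinase/KEP vicinity statistics,
#' pheromone and mating-factor annotation, and the census tables.  Funnel
#' counts (proteins, signal-positive, tandem-repetitive, KEPs) are logged
#' and returned; the resolved parameter set is kept as a manifest.
#'
#' @param proteins Proteins tibble ([read_proteins()]).
#' @param predictions Signal predictions; NULL uses the built-in heuristic.
#' @param genes Gene records ([read_genes()]); NULL skips vicinity stages.
#' @param domains Domain hits ([read_domains()]); used for vicinity labels
#'   and mating-factor flags.
#' @param strains Surveyed strain table (`strain_id`, `genus`, `phylum`);
#'   NULL derives it from the proteins (strains without KEPs then still
#'   appear because every protein carries its strain).
#' @param pheromone_queries,basidio_queries Named character vectors of
#'   precursor query peptides (optional).
#' @param params [kep_params()].
#' @param quiet Suppress progress messages.
#' @return Object of class `kep_pipeline`: list with `detection`, `keps`
#'   (annotated per-KEP table), `types`, `subtypes`, `units`, `vicinity`
#'   (list of `kep_vicinity` / strata), `phylum_table`, `type_table`,
#'   `funnel`, `params`.
#' @export
kep_run_pipeline <- function(proteins, predictions = NULL, genes = NULL,
                             domains = NULL, strains = NULL,
                             pheromone_queries = NULL,
                             basidio_queries = NULL,
                             params = kep_params(), quiet = FALSE) {
  say <- function(...) if (!quiet) message(...)
  detection <- kep_detect(proteins, predictions, params)
  funnel <- kep_funnel(detection)
  say("funnel: ", paste(names(funnel), funnel, sep = "=", collapse = " "))
  keps <- detection[detection$accepted,
                    c("protein_id", "strain_id", "genus", "phylum",
                      "mature", "n_fragments", "n_units")]
  keps <- left_join(keps,
                    proteins[, c("protein_id", "sequence")],
                    by = "protein_id")
  units <- kep_units(detection)

  types <- NULL; subtypes <- NULL
  if (nrow(keps) > 0) {
    types <- kep_type_clustering(keps, params)
    keps <- left_join(keps, types$assignments, by = "protein_id")
    subtypes <- subtype_repeat_units(units, types, params)
    say("types: ", glance(types)$n_types, " (+",
        glance(types)$n_standalone, " stand-alone)")
  }

  vicinity <- NULL
  if (!is.null(genes) && nrow(keps) > 0) {
    nbh <- gene_neighborhood(genes)
    labels <- if (!is.null(domains) && nrow(domains) > 0)
      tibble(protein_id = domains$protein_id,
             label = domains$domain_name) else
      tibble(protein_id = character(), label = character())
    duf <- domain_vicinity_stats(nbh, keps$protein_id, labels, "DUF3328",
                                 params$vicinity_radius,
                                 params$allhits_max_dist)
    tyr_cond <- conditional_histogram(nbh, keps$protein_id, labels,
                                      "Tyrosinase", "DUF3328",
                                      params$vicinity_radius,
                                      params$allhits_max_dist)
    mfs <- domain_vicinity_stats(nbh, keps$protein_id, labels, "MFS_1",
                                 params$vicinity_radius,
                                 params$allhits_max_dist)
    co <- cooccurring_keps(nbh, keps$protein_id, params$vicinity_radius,
                           params$allhits_max_dist)
    keps$duf3328 <- !is.na(duf$nearest$nearest[
      match(keps$protein_id, duf$nearest$protein_id)])
    keps$nearest_duf3328 <- duf$nearest$nearest[
      match(keps$protein_id, duf$nearest$protein_id)]
    vicinity <- list(duf3328 = duf, tyrosinase = tyr_cond, mfs = mfs,
                     keps = co)
    say(sprintf("DUF3328 vicinity: fraction %.3f, nearest mean %.2f",
                duf$fraction_of_keps_with_hit, duf$nearest_mean))
  }

  if (nrow(keps) > 0) {
    keps$mating_factor <- if (!is.null(domains))
      flag_mating_factor(keps$protein_id, domains,
                         params$domain_evalue) else FALSE
    keps$pheromone <- if (!is.null(pheromone_queries))
      flag_pheromone(keps$sequence, pheromone_queries,
                     params$pheromone_evalue, params$alignment) else FALSE
    keps$basidio_pheromone <- if (!is.null(basidio_queries))
      flag_pheromone(keps$sequence, basidio_queries,
                     params$pheromone_evalue, params$alignment) else FALSE
  }

  if (is.null(strains))
    strains <- distinct(proteins[, c("strain_id", "genus", "phylum")])
  phylum_table <- phylum_summary(keps, strains)
  type_table <- if (!is.null(types)) type_summary(keps, types) else NULL

  structure(list(detection = detection, keps = keps, units = units,
                 types = types, subtypes = subtypes, vicinity = vicinity,
                 phylum_table = phylum_table, type_table = type_table,
                 funnel = funnel, params = params),
            class = "kep_pipeline")
}

#' @export
print.kep_pipeline <- function(x, ...) {
  cat("<kep_pipeline>\n  funnel: ",
      paste(names(x$funnel), x$funnel, sep = "=", collapse = " "), "\n",
      sep = "")
  invisible(x)
}

#' One-row pipeline summary
#'
#' @param x A `kep_pipeline`.
#' @param ... Unused.
#' @return Tibble with the funnel counts, type counts and DUF3328 vicinity
#'   summary.
#' @exportS3Method generics::glance
glance.kep_pipeline <- function(x, ...) {
  out <- as_tibble(as.list(x$funnel))
  if (!is.null(x$types)) {
    g <- glance(x$types)
    out$n_types <- g$n_types
    out$n_standalone <- g$n_standalone
  }
  if (!is.null(x$vicinity)) {
    out$duf3328_fraction <- x$vicinity$duf3328$fraction_of_keps_with_hit
    out$duf3328_nearest_mean <- x$vicinity$duf3328$nearest_mean
  }
  out
}

#' Write pipeline result tables as TSV
#'
#' Emits the per-protein detection audit (with rejection reasons), the
#' KEP table, repeat units with sub-types, the per-type and per-phylum
#' census tables, and the DUF3328 vicinity histogram.
#'
#' @param result A `kep_pipeline`.
#' @param dir Output directory.
#' @return Named vector of paths written.
#' @export
write_kep_results <- function(result, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c()
  w <- function(x, name) {
    p <- file.path(dir, name)
    readr::write_tsv(x, p)
    paths[[name]] <<- p
  }
  audit <- result$detection[, c("protein_id", "strain_id", "accepted",
                                "reason", "n_fragments", "n_units")]
  w(audit, "detection_audit.tsv")
  if (nrow(result$keps))
    w(select(result$keps, -dplyr::any_of(c("sequence", "mature"))),
      "keps.tsv")
  if (!is.null(result$subtypes)) w(result$subtypes, "repeat_units.tsv")
  if (!is.null(result$type_table)) w(result$type_table, "type_table.tsv")
  w(result$phylum_table, "phylum_table.tsv")
  if (!is.null(result$vicinity))
    w(tidy(result$vicinity$duf3328), "duf3328_vicinity.tsv")
  invisible(unlist(paths))
}
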