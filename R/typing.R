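# Typing: single-linkage clustering over reciprocal similarity links,
# stable type labels, repeat-unit sub-typing, and center-star profiles.

#' Single-linkage clustering from a link table
#'
#' Connected components of the undirected link graph.
#'
#' @param ids All item ids (so that unlinked items form singletons).
#' @param links Tibble with columns `id_a`, `id_b`, one row per link.
#' @return Tibble `id`, `component` (integer, arbitrary but deterministic).
#' @export
cluster_single_linkage <- function(ids, links) {
  stopifnot(!anyDuplicated(ids))
  g <- igraph::graph_from_data_frame(
    links[, c("id_a", "id_b")], directed = FALSE,
    vertices = data.frame(name = ids))
  comp <- igraph::components(g)$membership
  tibble(id = names(comp), component = unname(comp))[match(ids, names(comp)), ]
}

#' Assign stable type labels to a partition
#'
#' Non-singleton components are sorted by decreasing size, ties broken by
#' the lexicographically smallest member id, and labelled `#1`, `#2`, ...;
#' singletons get the stand-alone label `"0"`.  The labelling is invariant
#' under permutation of the input.
#'
#' @param membership Tibble `id`, `component` from
#'   [cluster_single_linkage()].
#' @return Tibble `id`, `type_label`.
#' @export
assign_type_labels <- function(membership) {
  comp <- split(membership$id, membership$component)
  sizes <- lengths(comp)
  multi <- comp[sizes > 1]
  if (length(multi)) {
    ord <- order(-lengths(multi),
                 vapply(multi, function(m) min(sort(m)), ""))
    labels <- setNames(paste0("#", seq_along(multi)), names(multi)[ord])
  } else labels <- character(0)
  lab <- labels[as.character(membership$component)]
  lab[is.na(lab)] <- "0"
  tibble(id = membership$id, type_label = unname(lab))
}

#' Cluster KEPs into types
#'
#' Two KEPs link when their reciprocal E-values (database mode over the
#' total residue count of all KEPs) are below `type_evalue` and each
#' sequence's coverage exceeds `type_coverage`; types are the single-linkage
#' closure of the links, labelled by decreasing member count.
#'
#' @param keps Tibble with `protein_id` and `sequence` (full precursor).
#' @param params [kep_params()].
#' @return Object of class `kep_types`: list with `assignments`
#'   (`protein_id`, `type_label`), `links`, and `db_size`.
#' @export
kep_type_clustering <- function(keps, params = kep_params()) {
  stopifnot(all(c("protein_id", "sequence") %in% names(keps)))
  seqs <- setNames(keps$sequence, keps$protein_id)
  db <- sum(nchar(seqs))
  hits <- pairwise_hits(seqs, params$alignment, db_size = db)
  links <- filter(hits,
                  .data$evalue_a < params$type_evalue,
                  .data$evalue_b < params$type_evalue,
                  .data$coverage_a > params$type_coverage,
                  .data$coverage_b > params$type_coverage)
  membership <- cluster_single_linkage(names(seqs), links)
  assignments <- rename(assign_type_labels(membership), protein_id = "id")
  structure(list(assignments = assignments, links = links, db_size = db),
            class = "kep_types")
}

#' Group repeat units of each type into sub-types
#'
#' Within every KEP type, two repeat units link when their reciprocal
#' identity exceeds `subtype_identity` and coverage exceeds
#' `subtype_coverage`; sub-types are single-linkage components.  Sub-types
#' with 2 or fewer members are flagged small.
#'
#' @param units Tibble with `unit_id`, `protein_id`, `sequence` (from
#'   [kep_units()]).
#' @param types `kep_types` or an assignments tibble.
#' @param params [kep_params()].
#' @return Tibble `unit_id`, `protein_id`, `sequence`, `type_label`,
#'   `subtype_label` (`"<type>/s<k>"`, by decreasing size), `small`.
#' @export
subtype_repeat_units <- function(units, types, params = kep_params()) {
  assignments <- if (inherits(types, "kep_types")) types$assignments else types
  x <- left_join(units, assignments, by = "protein_id")
  x <- x[!is.na(x$type_label), , drop = FALSE]
  out <- lapply(split(x, x$type_label), function(grp) {
    seqs <- setNames(grp$sequence, grp$unit_id)
    hits <- pairwise_hits(seqs, params$alignment)
    links <- filter(hits,
                    .data$identity > params$subtype_identity,
                    .data$coverage_a > params$subtype_coverage,
                    .data$coverage_b > params$subtype_coverage)
    membership <- cluster_single_linkage(names(seqs), links)
    # stable sub-type labels within the type, by decreasing size
    comp <- split(membership$id, membership$component)
    ord <- order(-lengths(comp), vapply(comp, function(m) min(sort(m)), ""))
    lab <- setNames(paste0(grp$type_label[1], "/s", seq_along(comp)),
                    names(comp)[ord])
    grp$subtype_label <- unname(lab[as.character(membership$component[
      match(grp$unit_id, membership$id)])])
    grp
  })
  res <- bind_rows(out)
  sizes <- table(res$subtype_label)
  res$small <- sizes[res$subtype_label] <= 2
  res$small <- as.logical(res$small)
  res[order(match(res$unit_id, units$unit_id)), ]
}

#' Center-star alignment profile of a group of repeat units
#'
#' The center is the member with the greatest summed pairwise alignment
#' score; all other members are aligned to it pairwise (global alignment)
#' and merged over the center's coordinates, opening center gaps where a
#' member inserts.  The profile gives per-column residue frequencies over
#' the 20-letter alphabet with a pseudocount of 0.05 per residue; each
#' column sums to 1.
#'
#' @param sequences Character vector of unit sequences (length >= 1).
#' @param params [alignment_params()].
#' @param pseudocount Added to every residue count per column.
#' @return Object of class `kep_profile`: list with `alignment` (gapped
#'   strings of equal length), `profile` (20 x n-column frequency matrix),
#'   `center` (index of the center sequence).
#' @export
build_profile <- function(sequences, params = alignment_params(),
                          pseudocount = 0.05) {
  n <- length(sequences)
  stopifnot(n >= 1)
  if (n == 1) {
    aln <- sequences
    prof <- profile_matrix(aln, pseudocount)
    return(structure(list(alignment = aln, profile = prof, center = 1L),
                     class = "kep_profile"))
  }
  mat <- resolve_matrix(params)
  scores <- matrix(0, n, n)
  for (i in seq_len(n - 1)) {
    al <- Biostrings::pairwiseAlignment(
      Biostrings::AAStringSet(sequences[(i + 1):n]),
      Biostrings::AAString(sequences[i]), type = "global",
      substitutionMatrix = mat, gapOpening = params$gap_open,
      gapExtension = params$gap_extend)
    s <- Biostrings::score(al)
    scores[i, (i + 1):n] <- s
    scores[(i + 1):n, i] <- s
  }
  center <- which.max(rowSums(scores))
  others <- setdiff(seq_len(n), center)
  al <- Biostrings::pairwiseAlignment(
    Biostrings::AAStringSet(sequences[others]),
    Biostrings::AAString(sequences[center]), type = "global",
    substitutionMatrix = mat, gapOpening = params$gap_open,
    gapExtension = params$gap_extend)
  cen_rows <- as.character(Biostrings::alignedSubject(al))
  mem_rows <- as.character(Biostrings::alignedPattern(al))
  merged <- merge_center_star(sequences[center], cen_rows, mem_rows)
  # restore input order: center first in merged output
  aln <- character(n)
  aln[center] <- merged$center
  aln[others] <- merged$members
  prof <- profile_matrix(aln, pseudocount)
  structure(list(alignment = aln, profile = prof, center = center),
            class = "kep_profile")
}

# Merge pairwise center alignments into one MSA over center coordinates.
# For each pairwise alignment, record the insertion length before each
# center position; the master insertion is the maximum over members.
merge_center_star <- function(center_seq, cen_rows, mem_rows) {
  Lc <- nchar(center_seq)
  n <- length(cen_rows)
  # ins[[j]]: integer vector length Lc+1, insertions before center pos i
  ins <- matrix(0L, n, Lc + 1L)
  mem_split <- strsplit(mem_rows, "")
  cen_split <- strsplit(cen_rows, "")
  for (j in seq_len(n)) {
    pos <- 0L
    for (ch in cen_split[[j]]) {
      if (ch == "-") ins[j, pos + 1L] <- ins[j, pos + 1L] + 1L
      else pos <- pos + 1L
    }
  }
  master <- apply(ins, 2, max)
  pad <- function(chars, k) c(chars, rep("-", k))
  out_center <- character(0)
  cen_chars <- strsplit(center_seq, "")[[1]]
  for (i in 0:Lc) {
    if (master[i + 1L] > 0)
      out_center <- c(out_center, rep("-", master[i + 1L]))
    if (i < Lc) out_center <- c(out_center, cen_chars[i + 1L])
  }
  out_members <- character(n)
  for (j in seq_len(n)) {
    mchars <- mem_split[[j]]
    cchars <- cen_split[[j]]
    res <- character(0)
    pos <- 0L
    idx <- 1L
    # walk the pairwise alignment, emitting per center-slot blocks
    block_ins <- character(0)
    flush <- function(slot, block_ins) {
      k <- master[slot + 1L] - length(block_ins)
      c(block_ins, rep("-", k))
    }
    while (idx <= length(cchars)) {
      if (cchars[idx] == "-") {
        block_ins <- c(block_ins, mchars[idx])
      } else {
        res <- c(res, flush(pos, block_ins), mchars[idx])
        block_ins <- character(0)
        pos <- pos + 1L
      }
      idx <- idx + 1L
    }
    res <- c(res, flush(Lc, block_ins))
    out_members[j] <- paste(res, collapse = "")
  }
  list(center = paste(out_center, collapse = ""), members = out_members)
}

profile_matrix <- function(alignment, pseudocount = 0.05) {
  chars <- strsplit(alignment, "")
  stopifnot(length(unique(lengths(chars))) == 1)
  ncol <- lengths(chars)[1]
  m <- matrix(pseudocount, nrow = length(AA20), ncol = ncol,
              dimnames = list(AA20, NULL))
  for (row in chars) {
    hit <- row %in% AA20
    idx <- which(hit)
    m[cbind(match(row[hit], AA20), idx)] <-
      m[cbind(match(row[hit], AA20), idx)] + 1
  }
  sweep(m, 2, colSums(m), "/")
}

#' Compare two KEP sets
#'
#' Two KEPs from different sets are considered identical when their
#' reciprocal identity and coverage both exceed the set-comparison
#' thresholds (default 0.95).
#'
#' @param set_a,set_b Named character vectors of sequences.
#' @param params [kep_params()].
#' @return List with `matched_a`, `matched_b` (ids with a match in the
#'   other set), and counts `n_a`, `n_b`, `n_matched_a`, `n_matched_b`.
#' @export
compare_kep_sets <- function(set_a, set_b, params = kep_params()) {
  stopifnot(!is.null(names(set_a)), !is.null(names(set_b)))
  matched_a <- character(0)
  matched_b <- character(0)
  for (i in seq_along(set_a)) for (j in seq_along(set_b)) {
    if (reciprocal_link(set_a[[i]], set_b[[j]],
                        coverage_threshold = params$setcompare_coverage,
                        identity_threshold = params$setcompare_identity,
                        params = params$alignment)) {
      matched_a <- union(matched_a, names(set_a)[i])
      matched_b <- union(matched_b, names(set_b)[j])
    }
  }
  list(matched_a = matched_a, matched_b = matched_b,
       n_a = length(set_a), n_b = length(set_b),
       n_matched_a = length(matched_a), n_matched_b = length(matched_b))
}

#' @export
print.kep_types <- function(x, ...) {
  n_types <- length(setdiff(unique(x$assignments$type_label), "0"))
  cat(sprintf("<kep_types> %d KEPs in %d types, %d stand-alone\n",
              nrow(x$assignments), n_types,
              sum(x$assignments$type_label == "0")))
  invisible(x)
}

#' Tidy KEP type assignments
#'
#' @param x A `kep_types` object.
#' @param ... Unused.
#' @return The assignments tibble (`protein_id`, `type_label`).
#' @exportS3Method generics::tidy
tidy.kep_types <- function(x, ...) x$assignments

#' One-row summary of a typing result
#'
#' @param x A `kep_types` object.
#' @param ... Unused.
#' @return Tibble with `n_keps`, `n_types`, `n_standalone`, `n_links`.
#' @exportS3Method generics::glance
glance.kep_types <- function(x, ...) {
  tibble(n_keps = nrow(x$assignments),
         n_types = length(setdiff(unique(x$assignments$type_label), "0")),
         n_standalone = sum(x$assignments$type_label == "0"),
         n_links = nrow(x$links))
}
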