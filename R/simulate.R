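# Synthetic proteomes with planted KEP structure and exact ground truth.
#
# Planted precursor architecture: signal peptide (constructed to the exact
# rules of the built-in heuristic) + non-repeated leader pro-region +
# (mutated unit + dibasic site) x k + short tail.  Flanking regions are
# required by the ">2 parts" repetitiveness rule; the leader is sized
# 25-40 residues so that the shortest legal family (3 units of 8) still
# yields reciprocal E-values far below the typing threshold between family
# members.  Units never carry K/R at their ends or adjacent K/R inside, so
# the planted dibasic sites are exactly the sites the scanner finds and
# the truth intervals are exact.

SIM_RUN_SET <- c("L", "V", "F", "I", "W")
SIM_FILLER_SET <- c("D", "E", "N", "Q", "H", "P", "Y")
AA18 <- setdiff(AA20, c("K", "R"))

#' Synthetic study configuration
#'
#' Defaults describe the reference simulation: 20 strains of 250 genes,
#' 5 planted KEPs per strain drawn from 6 families, 5% per-residue unit
#' mutation, 6 decoys per rejection class per strain, DUF3328 planted near
#' 22% of KEP genes at gene-rank distances with mean about 3.09, and
#' Tyrosinase planted near half of the DUF3328-positive KEPs.
#'
#' @param seed Mandatory RNG seed; all randomness flows from it.
#' @param n_strains,genes_per_strain,keps_per_strain Study dimensions.
#' @param n_families Number of KEP families (shared precursor ancestors).
#' @param unit_len_range Ancestor repeat-unit length range.
#' @param units_range Units per KEP (sampled once per family).
#' @param leader_range,tail_range Flanking pro-region length ranges.
#' @param mutation_rate Per-residue substitution rate applied independently
#'   to every unit copy.
#' @param decoys_per_class Decoys per rejection class per strain (classes:
#'   no_signal, no_repeat, no_kex2, long_fragment, short_units, few_units).
#' @param duf3328_fraction Probability that a KEP gene gets a DUF3328
#'   neighbor.
#' @param duf3328_distance_probs Distribution of the planted gene-rank
#'   distance (vector over 1..15); default is a truncated geometric with
#'   mean approximately 3.09.
#' @param tyrosinase_given_duf3328 Probability of a Tyrosinase neighbor
#'   given a DUF3328 neighbor.
#' @param mfs_rate Per-gene background rate of the MFS_1 transporter label.
#' @return List of class `kep_sim_config`.
#' @export
sim_config <- function(seed,
                       n_strains = 20L,
                       genes_per_strain = 250L,
                       keps_per_strain = 5L,
                       n_families = 6L,
                       unit_len_range = c(8L, 30L),
                       units_range = c(3L, 12L),
                       leader_range = c(25L, 40L),
                       tail_range = c(5L, 10L),
                       mutation_rate = 0.05,
                       decoys_per_class = 6L,
                       duf3328_fraction = 0.22,
                       duf3328_distance_probs = NULL,
                       tyrosinase_given_duf3328 = 0.5,
                       mfs_rate = 0.03) {
  stopifnot(is.numeric(seed), length(seed) == 1L,
            mutation_rate >= 0, mutation_rate < 1,
            duf3328_fraction >= 0, duf3328_fraction <= 1,
            genes_per_strain >= keps_per_strain * 33L)
  if (is.null(duf3328_distance_probs)) {
    p <- 1 / 3.09
    duf3328_distance_probs <- p * (1 - p)^(0:14)
  }
  duf3328_distance_probs <- duf3328_distance_probs /
    sum(duf3328_distance_probs)
  stopifnot(length(duf3328_distance_probs) == 15L)
  structure(list(seed = as.integer(seed), n_strains = n_strains,
                 genes_per_strain = genes_per_strain,
                 keps_per_strain = keps_per_strain,
                 n_families = n_families,
                 unit_len_range = unit_len_range, units_range = units_range,
                 leader_range = leader_range, tail_range = tail_range,
                 mutation_rate = mutation_rate,
                 decoys_per_class = decoys_per_class,
                 duf3328_fraction = duf3328_fraction,
                 duf3328_distance_probs = duf3328_distance_probs,
                 tyrosinase_given_duf3328 = tyrosinase_given_duf3328,
                 mfs_rate = mfs_rate),
            class = "kep_sim_config")
}

sim_string <- function(n, alphabet) paste(sample(alphabet, n, TRUE),
                                          collapse = "")

# signal peptide satisfying the heuristic rules exactly, with a known
# cleavage position: M K [8 hydrophobic] [m filler] A S A
sim_signal <- function() {
  m <- sample(4:9, 1)
  sig <- paste0("MK", sim_string(8, SIM_RUN_SET),
                sim_string(m, SIM_FILLER_SET), "ASA")
  list(signal = sig, cleavage_pos = nchar(sig))
}

# ancestor unit: no K/R at either end, no adjacent K/R pairs
sim_unit <- function(len) {
  repeat {
    u <- strsplit(sim_string(len, AA20), "")[[1]]
    if (u[1] %in% c("K", "R") || u[len] %in% c("K", "R")) next
    if (len > 1 && any(u[-len] %in% c("K", "R") & u[-1] %in% c("K", "R")))
      next
    return(paste(u, collapse = ""))
  }
}

# substitute residues at `rate`, preserving the unit constraints
sim_mutate_unit <- function(unit, rate) {
  if (rate == 0) return(unit)
  x <- strsplit(unit, "")[[1]]
  len <- length(x)
  for (i in seq_len(len)) {
    if (stats::runif(1) >= rate) next
    repeat {
      cand <- sample(AA20, 1)
      if (cand == x[i]) next
      edge <- i == 1L || i == len
      left_kr <- i > 1L && x[i - 1L] %in% c("K", "R")
      right_kr <- i < len && x[i + 1L] %in% c("K", "R")
      if (cand %in% c("K", "R") && (edge || left_kr || right_kr)) next
      x[i] <- cand
      break
    }
  }
  paste(x, collapse = "")
}

unit_identity <- function(a, b) {
  la <- strsplit(a, "")[[1]]; lb <- strsplit(b, "")[[1]]
  n <- min(length(la), length(lb))
  sum(la[seq_len(n)] == lb[seq_len(n)]) / max(length(la), length(lb))
}

# family ancestors pairwise < 30% identical (rejection sampling)
sim_families <- function(config) {
  fams <- list()
  while (length(fams) < config$n_families) {
    len <- sample(config$unit_len_range[1]:config$unit_len_range[2], 1)
    cand <- sim_unit(len)
    if (all(vapply(fams, function(f)
      unit_identity(f$unit, cand) < 0.30, TRUE))) {
      sig <- sim_signal()
      fams[[length(fams) + 1L]] <- list(
        family_id = paste0("F", length(fams) + 1L),
        unit = cand,
        k = sample(config$units_range[1]:config$units_range[2], 1),
        signal = sig$signal, cleavage_pos = sig$cleavage_pos,
        leader = sim_string(sample(config$leader_range[1]:
                                     config$leader_range[2], 1), AA18),
        tail = sim_string(sample(config$tail_range[1]:
                                   config$tail_range[2], 1), AA18))
    }
  }
  fams
}

#' Build one planted KEP protein from a family ancestor
#'
#' @param family A family ancestor (internal structure produced by the
#'   simulator; fields `unit`, `k`, `signal`, `cleavage_pos`, `leader`,
#'   `tail`).
#' @param config [sim_config()].
#' @param protein_id Identifier for the record.
#' @return List with `sequence`, `cleavage_pos`, `mature`, and a tibble
#'   `units` of 0-based half-open planted unit intervals on the mature
#'   sequence.
#' @export
make_kep_protein <- function(family, config, protein_id = "kep1") {
  sites <- sample(c("KR", "KK", "RK", "RR"), family$k + 1L, TRUE)
  units <- vapply(seq_len(family$k), function(z)
    sim_mutate_unit(family$unit, config$mutation_rate), "")
  # a site also separates the leader pro-region from the first unit, so
  # every planted unit is its own Kex2 fragment
  mature <- paste0(family$leader, sites[1L],
                   paste0(units, sites[-1L], collapse = ""), family$tail)
  lens <- nchar(units)
  starts <- nchar(family$leader) + 2L +
    cumsum(c(0L, head(lens + 2L, -1L)))
  list(protein_id = protein_id,
       sequence = paste0(family$signal, mature),
       cleavage_pos = family$cleavage_pos,
       mature = mature,
       units = tibble(start = starts, end = starts + lens,
                      sequence = units))
}

# no repeated 5-mer anywhere: a detector-independent certificate that a
# decoy sequence carries no repeat signal
has_repeated_kmer <- function(seq, k = 5L) {
  L <- nchar(seq)
  if (L < 2L * k) return(FALSE)
  kmers <- substring(seq, 1:(L - k + 1L), k:L)
  anyDuplicated(kmers) > 0L
}

sim_nonrepetitive <- function(len, alphabet = AA18) {
  for (z in 1:100) {
    s <- sim_string(len, alphabet)
    if (!has_repeated_kmer(s)) return(s)
  }
  stop("failed to sample a repeat-free sequence", call. = FALSE)
}

#' Build one decoy protein
#'
#' Decoy classes exercise each rejection mode: `no_signal` (repeats behind
#' an invalid signal), `no_repeat` (signal + repeat-free sequence, certified
#' by 5-mer uniqueness), `no_kex2` (repeats without dibasic separators),
#' `long_fragment` (one inter-site fragment of 101-150 residues),
#' `short_units` (units of 5-7 residues), `few_units` (2 units).
#'
#' @param class Decoy class name.
#' @param config [sim_config()].
#' @param protein_id Identifier.
#' @return List with `sequence`, `cleavage_pos` (NA for `no_signal`),
#'   `class`.
#' @export
make_decoy <- function(class, config, protein_id = "decoy1") {
  body <- function(k, ulen, sep = TRUE) {
    unit <- sim_unit(ulen)
    units <- vapply(seq_len(k), function(z)
      sim_mutate_unit(unit, config$mutation_rate), "")
    sites <- if (sep) sample(c("KR", "KK", "RK", "RR"), k + 1L, TRUE) else
      rep("", k + 1L)
    paste0(sim_nonrepetitive(sample(config$leader_range[1]:
                                      config$leader_range[2], 1)),
           sites[1L], paste0(units, sites[-1L], collapse = ""),
           sim_nonrepetitive(sample(config$tail_range[1]:
                                      config$tail_range[2], 1)))
  }
  sig <- sim_signal()
  out <- switch(
    class,
    no_signal = list(sequence = paste0("M", sim_string(9, SIM_FILLER_SET),
                                       body(5, 12)),
                     cleavage_pos = NA_integer_),
    no_repeat = list(sequence = paste0(sig$signal,
                                       sim_nonrepetitive(sample(50:90, 1))),
                     cleavage_pos = sig$cleavage_pos),
    no_kex2 = list(sequence = paste0(sig$signal, body(5, 12, sep = FALSE)),
                   cleavage_pos = sig$cleavage_pos),
    long_fragment = {
      unit <- sim_unit(12)
      long <- sim_nonrepetitive(sample(101:150, 1))
      mat <- paste0(sim_nonrepetitive(30),
                    unit, "KR", long, "KR",
                    paste0(vapply(1:3, function(z)
                      sim_mutate_unit(unit, config$mutation_rate), ""),
                      sample(c("KR", "KK", "RK", "RR"), 3, TRUE),
                      collapse = ""),
                    sim_nonrepetitive(6))
      list(sequence = paste0(sig$signal, mat),
           cleavage_pos = sig$cleavage_pos)
    },
    short_units = list(sequence = paste0(sig$signal,
                                         body(6, sample(5:7, 1))),
                       cleavage_pos = sig$cleavage_pos),
    few_units = list(sequence = paste0(sig$signal,
                                       body(2, sample(20:30, 1))),
                     cleavage_pos = sig$cleavage_pos),
    stop("unknown decoy class: ", class, call. = FALSE)
  )
  c(list(protein_id = protein_id, class = class), out)
}

DECOY_CLASSES <- c("no_signal", "no_repeat", "no_kex2", "long_fragment",
                   "short_units", "few_units")

DECOY_REASON <- c(no_signal = "NO_SIGNAL", no_repeat = "NOT_REPETITIVE",
                  no_kex2 = "NO_KEX2_SITE",
                  long_fragment = "FRAGMENT_TOO_LONG",
                  short_units = "UNITS_TOO_SHORT",
                  few_units = "TOO_FEW_UNITS")

#' Simulate a complete KEP study
#'
#' Generates proteomes (planted KEPs, decoys, background proteins), signal
#' predictions, per-strain gene orders with planted DUF3328/Tyrosinase
#' neighbors and background MFS_1 labels, domain hits, and the ground
#' truth for all of it.
#'
#' @param config [sim_config()].
#' @return Object of class `kep_simulation`: list with `proteins`,
#'   `predictions`, `genes`, `domains`, `labels`, `strains`, `truth`
#'   (list: `proteins`, `placements`), and `config`.
#' @export
simulate_kep_study <- function(config) {
  stopifnot(inherits(config, "kep_sim_config"))
  set.seed(config$seed)
  families <- sim_families(config)
  phyla <- c("Ascomycota", "Basidiomycota")
  strains <- tibble(
    strain_id = sprintf("S%02d", seq_len(config$n_strains)),
    genus = sprintf("Genus%02d", (seq_len(config$n_strains) + 1L) %/% 2L),
    phylum = phyla[1L + (seq_len(config$n_strains) >
                           ceiling(config$n_strains * 0.6))])
  proteins <- list(); truth <- list(); placements <- list()
  genes <- list(); labels <- list()
  kep_counter <- 0L
  for (si in seq_len(config$n_strains)) {
    sid <- strains$strain_id[si]
    # planted KEPs, families assigned round-robin across the whole study
    kep_recs <- lapply(seq_len(config$keps_per_strain), function(z) {
      kep_counter <<- kep_counter + 1L
      fam <- families[[1L + (kep_counter - 1L) %% config$n_families]]
      rec <- make_kep_protein(fam, config,
                              sprintf("%s_KEP%02d", sid, z))
      rec$family_id <- fam$family_id
      rec
    })
    decoy_recs <- list()
    for (cls in DECOY_CLASSES)
      for (z in seq_len(config$decoys_per_class))
        decoy_recs <- c(decoy_recs, list(
          make_decoy(cls, config, sprintf("%s_%s%02d", sid, cls, z))))
    prot <- bind_rows(
      tibble(protein_id = vapply(kep_recs, `[[`, "", "protein_id"),
             class = "kep",
             family_id = vapply(kep_recs, `[[`, "", "family_id"),
             sequence = vapply(kep_recs, `[[`, "", "sequence"),
             cleavage_pos = vapply(kep_recs, `[[`, 0L, "cleavage_pos")),
      tibble(protein_id = vapply(decoy_recs, `[[`, "", "protein_id"),
             class = vapply(decoy_recs, `[[`, "", "class"),
             family_id = NA_character_,
             sequence = vapply(decoy_recs, `[[`, "", "sequence"),
             cleavage_pos = vapply(decoy_recs, function(r)
               as.integer(r$cleavage_pos), 0L)))
    prot$strain_id <- sid
    proteins[[si]] <- prot
    truth[[si]] <- tibble(
      protein_id = vapply(kep_recs, `[[`, "", "protein_id"),
      strain_id = sid,
      family_id = vapply(kep_recs, `[[`, "", "family_id"),
      mature = vapply(kep_recs, `[[`, "", "mature"),
      units = lapply(kep_recs, `[[`, "units"))
    # gene order: one contig per strain; KEP anchors evenly spaced with
    # +-1 jitter.  Anchor gaps stay above 30 = radius + max planted
    # distance, so a DUF3328 gene planted for one KEP can never fall
    # inside another KEP's 15-gene window.
    n_genes <- config$genes_per_strain
    n_keps <- length(kep_recs)
    spacing <- n_genes %/% n_keps
    anchor <- pmin(pmax(2L, as.integer(spacing %/% 2 +
                                         (seq_len(n_keps) - 1L) * spacing +
                                         sample(-1:1, n_keps, TRUE))),
                   n_genes - 1L)
    gene_pid <- sprintf("%s_g%03d", sid, seq_len(n_genes))
    gene_pid[anchor] <- vapply(kep_recs, `[[`, "", "protein_id")
    free <- setdiff(seq_len(n_genes), anchor)
    dslots <- sample(free, length(decoy_recs))
    gene_pid[dslots] <- vapply(decoy_recs, `[[`, "", "protein_id")
    lab <- tibble(protein_id = character(), label = character())
    place <- tibble(protein_id = vapply(kep_recs, `[[`, "", "protein_id"),
                    duf_distance = NA_integer_,
                    tyr_distance = NA_integer_)
    used <- anchor
    for (z in seq_len(n_keps)) {
      if (stats::runif(1) < config$duf3328_fraction) {
        d <- sample(1:15, 1, prob = config$duf3328_distance_probs)
        side <- sample(c(-1L, 1L), 1)
        pos <- anchor[z] + side * d
        if (pos < 1L || pos > n_genes) pos <- anchor[z] - side * d
        lab <- bind_rows(lab, tibble(protein_id = gene_pid[pos],
                                     label = "DUF3328"))
        place$duf_distance[z] <- d
        used <- c(used, pos)
        if (stats::runif(1) < config$tyrosinase_given_duf3328) {
          dt <- sample(1:10, 1)
          sidet <- sample(c(-1L, 1L), 1)
          post <- anchor[z] + sidet * dt
          if (post < 1L || post > n_genes || post %in% used)
            post <- anchor[z] - sidet * dt
          if (post >= 1L && post <= n_genes && !(post %in% used)) {
            lab <- bind_rows(lab, tibble(protein_id = gene_pid[post],
                                         label = "Tyrosinase"))
            place$tyr_distance[z] <- abs(post - anchor[z])
            used <- c(used, post)
          }
        }
      }
    }
    bg <- setdiff(seq_len(n_genes), used)
    mfs <- bg[stats::runif(length(bg)) < config$mfs_rate]
    if (length(mfs))
      lab <- bind_rows(lab, tibble(protein_id = gene_pid[mfs],
                                   label = "MFS_1"))
    genes[[si]] <- tibble(gene_id = sprintf("%s_gene%03d", sid,
                                            seq_len(n_genes)),
                          protein_id = gene_pid,
                          contig_id = paste0(sid, "_c1"),
                          start = seq_len(n_genes) * 1000L,
                          end = seq_len(n_genes) * 1000L + 500L,
                          strand = "+")
    labels[[si]] <- lab
    placements[[si]] <- place
  }
  proteins <- bind_rows(proteins)
  proteins <- left_join(proteins, strains, by = "strain_id")
  prot_tbl <- tibble(protein_id = proteins$protein_id,
                     strain_id = proteins$strain_id,
                     genus = proteins$genus, phylum = proteins$phylum,
                     sequence = proteins$sequence,
                     description = proteins$class)
  predictions <- tibble(protein_id = proteins$protein_id,
                        has_signal = !is.na(proteins$cleavage_pos),
                        cleavage_pos = proteins$cleavage_pos,
                        source = "file")
  labels <- bind_rows(labels)
  domains <- tibble(
    protein_id = labels$protein_id,
    domain_accession = c(DUF3328 = "PF11807", Tyrosinase = "PF00264",
                         MFS_1 = "PF07690")[labels$label],
    domain_name = labels$label,
    evalue = 1e-10, env_from = 1L, env_to = 90L)
  structure(list(
    proteins = prot_tbl,
    predictions = predictions,
    genes = bind_rows(genes),
    domains = domains,
    labels = labels,
    strains = strains,
    truth = list(proteins = tibble(protein_id = proteins$protein_id,
                                   strain_id = proteins$strain_id,
                                   class = proteins$class,
                                   family_id = proteins$family_id,
                                   cleavage_pos = proteins$cleavage_pos,
                                   expected_reason = ifelse(
                                     proteins$class == "kep", NA_character_,
                                     DECOY_REASON[proteins$class])),
                 keps = bind_rows(truth),
                 placements = bind_rows(placements)),
    config = config), class = "kep_simulation")
}

#' Write a simulation to disk in the pipeline's input formats
#'
#' Emits proteome FASTA, SignalP-short predictions, gene-order TSV,
#' a domtblout-format domain table, and the ground truth as JSON.
#'
#' @param sim A `kep_simulation`.
#' @param dir Output directory (created if needed).
#' @return Named character vector of the paths written.
#' @export
write_simulation <- function(sim, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(proteins = file.path(dir, "proteome.fasta"),
             signalp = file.path(dir, "signalp_short.txt"),
             genes = file.path(dir, "gene_order.tsv"),
             domains = file.path(dir, "domains.domtblout"),
             truth = file.path(dir, "truth.json"))
  write_proteins(sim$proteins, paths[["proteins"]])
  write_signalp(sim$predictions, paths[["signalp"]])
  write_genes(sim$genes, paths[["genes"]])
  write_domains(sim$domains, paths[["domains"]])
  if (!requireNamespace("jsonlite", quietly = TRUE))
    stop("writing truth JSON requires jsonlite", call. = FALSE)
  tr <- sim$truth
  tr$keps$units <- lapply(tr$keps$units, as.data.frame)
  jsonlite::write_json(list(proteins = tr$proteins, keps = tr$keps,
                            placements = tr$placements,
                            seed = sim$config$seed),
                       paths[["truth"]], dataframe = "rows",
                       auto_unbox = TRUE, digits = NA)
  invisible(paths)
}

#' @export
print.kep_simulation <- function(x, ...) {
  cat(sprintf("<kep_simulation> seed %d: %d strains, %d proteins (%d planted KEPs, %d decoys)\n",
              x$config$seed, x$config$n_strains, nrow(x$proteins),
              sum(x$truth$proteins$class == "kep"),
              sum(x$truth$proteins$class != "kep")))
  invisible(x)
}
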