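#' Read a protein FASTA file
#'
#' One row per record.  The first whitespace-delimited header token is the
#' protein id; optional `strain=`, `genus=` and `phylum=` key-value tokens
#' populate the metadata columns (plain FASTA without them is fine, the
#' columns are then empty strings).  Sequences are uppercased and must use
#' the 20-letter amino-acid alphabet plus X.
#'
#' @param path Path to a FASTA file.
#' @return A tibble with columns `protein_id`, `strain_id`, `genus`,
#'   `phylum`, `sequence`, `description`.
#' @export
read_proteins <- function(path) {
  stopifnot(file.exists(path))
  if (file.size(path) == 0) return(empty_proteins())
  set <- Biostrings::readAAStringSet(path)
  if (length(set) == 0) return(empty_proteins())
  headers <- names(set)
  ids <- sub("\\s.*$", "", headers)
  if (anyDuplicated(ids)) {
    dup <- unique(ids[duplicated(ids)])
    stop("duplicate protein id(s) in ", path, ": ",
         paste(head(dup, 5), collapse = ", "), call. = FALSE)
  }
  seqs <- toupper(as.character(set))
  bad <- grepl(paste0("[^", paste(AA_ALPHABET, collapse = ""), "]"), seqs) |
    !nzchar(seqs)
  if (any(bad))
    stop("invalid or empty sequence for record(s): ",
         paste(head(ids[bad], 5), collapse = ", "), call. = FALSE)
  grab <- function(key) {
    m <- regmatches(headers, regexpr(paste0(key, "=[^\\s]+"), headers, perl = TRUE))
    out <- character(length(headers))
    hit <- grepl(paste0(key, "="), headers)
    out[hit] <- sub(paste0("^", key, "="), "", m)
    out
  }
  tibble(protein_id = unname(ids),
         strain_id = grab("strain"),
         genus = grab("genus"),
         phylum = grab("phylum"),
         sequence = unname(seqs),
         description = trimws(sub("^\\S+\\s*", "", headers)))
}

empty_proteins <- function() {
  tibble(protein_id = character(), strain_id = character(),
         genus = character(), phylum = character(),
         sequence = character(), description = character())
}

#' Write proteins to FASTA
#'
#' Inverse of [read_proteins()]: metadata columns are emitted as
#' `strain=`/`genus=`/`phylum=` header tokens when non-empty.
#'
#' @param proteins A proteins tibble (see [read_proteins()]).
#' @param path Output file path.
#' @param width Line-wrap width.
#' @return `path`, invisibly.
#' @export
write_proteins <- function(proteins, path, width = 60L) {
  hdr <- proteins$protein_id
  keys <- c(strain_id = "strain", genus = "genus", phylum = "phylum")
  for (col in names(keys)) {
    val <- proteins[[col]]
    if (is.null(val)) next
    hdr <- ifelse(nzchar(val), paste0(hdr, " ", keys[[col]], "=", val), hdr)
  }
  if (!is.null(proteins$description))
    hdr <- ifelse(nzchar(proteins$description),
                  paste(hdr, proteins$description), hdr)
  set <- Biostrings::AAStringSet(setNames(proteins$sequence, hdr))
  Biostrings::writeXStringSet(set, path, width = width)
  invisible(path)
}

#' Read SignalP 4.1 short-format predictions
#'
#' Parses the whitespace-delimited short output table.  The `?` column is
#' the signal decision; the reported cleavage position (Ymax pos) is the
#' first mature residue, so `cleavage_pos` is stored as that value minus
#' one, i.e. the index of the last signal residue.
#'
#' @param path Path to the table; lines starting with `#` are ignored.
#' @return A tibble with `protein_id`, `has_signal`, `cleavage_pos`
#'   (NA when no signal) and `source = "file"`.
#' @export
read_signalp <- function(path) {
  stopifnot(file.exists(path))
  lines <- readLines(path)
  lines <- lines[!grepl("^\\s*#", lines) & nzchar(trimws(lines))]
  if (length(lines) == 0)
    return(tibble(protein_id = character(), has_signal = logical(),
                  cleavage_pos = integer(), source = character()))
  fields <- strsplit(trimws(lines), "\\s+")
  nf <- lengths(fields)
  if (any(nf < 10))
    stop("malformed SignalP row at line ", which(nf < 10)[1], call. = FALSE)
  pos <- suppressWarnings(as.integer(vapply(fields, `[[`, "", 5L)))
  if (anyNA(pos))
    stop("non-integer cleavage position at line ", which(is.na(pos))[1],
         call. = FALSE)
  decision <- vapply(fields, `[[`, "", 10L)
  has <- decision == "Y"
  tibble(protein_id = vapply(fields, `[[`, "", 1L),
         has_signal = has,
         cleavage_pos = ifelse(has, pos - 1L, NA_integer_),
         source = "file")
}

#' Write signal predictions in SignalP 4.1 short format
#'
#' Only the columns the pipeline consumes carry information (name, Ymax
#' position, decision); the score columns are filled with placeholders.
#'
#' @param predictions Tibble with `protein_id`, `has_signal`, `cleavage_pos`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_signalp <- function(predictions, path) {
  pos <- ifelse(predictions$has_signal, predictions$cleavage_pos + 1L, 1L)
  rows <- sprintf("%s  0.500 %3d  0.500 %3d  0.500 %3d  0.500  0.500 %s  0.450 SignalP-noTM",
                  predictions$protein_id, pos, pos, pos,
                  ifelse(predictions$has_signal, "Y", "N"))
  writeLines(c("# SignalP-4.1 euk predictions",
               "# name  Cmax pos  Ymax pos  Smax pos  Smean   D  ?  Dmaxcut  Networks-used",
               rows), path)
  invisible(path)
}

#' Read HMMER3 --domtblout domain hits
#'
#' Keeps rows whose full-sequence E-value passes the threshold.  Column
#' layout follows `hmmscan --domtblout` (target = domain profile, query =
#' protein); envelope coordinates are preserved.
#'
#' @param path Path to the table.
#' @param evalue_threshold Retain hits with full-sequence E-value at or
#'   below this value.
#' @return A tibble with `protein_id`, `domain_accession`, `domain_name`,
#'   `evalue`, `env_from`, `env_to`.
#' @export
read_domains <- function(path, evalue_threshold = 1e-5) {
  stopifnot(file.exists(path), evalue_threshold > 0)
  lines <- readLines(path)
  lines <- lines[!grepl("^#", lines) & nzchar(trimws(lines))]
  if (length(lines) == 0)
    return(tibble(protein_id = character(), domain_accession = character(),
                  domain_name = character(), evalue = double(),
                  env_from = integer(), env_to = integer()))
  fields <- strsplit(trimws(lines), "\\s+")
  if (any(lengths(fields) < 22))
    stop("domtblout row with too few columns at line ",
         which(lengths(fields) < 22)[1], call. = FALSE)
  f <- function(k) vapply(fields, `[[`, "", k)
  out <- tibble(protein_id = f(4L),
                domain_accession = sub("\\.\\d+$", "", f(2L)),
                domain_name = f(1L),
                evalue = as.numeric(f(7L)),
                env_from = as.integer(f(20L)),
                env_to = as.integer(f(21L)))
  if (anyNA(out$evalue)) stop("unparseable E-value in ", path, call. = FALSE)
  filter(out, .data$evalue <= evalue_threshold)
}

#' Write domain hits in a minimal --domtblout layout
#'
#' @param domains Tibble as returned by [read_domains()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_domains <- function(domains, path) {
  rows <- sprintf(paste("%s %s 100 %s - 500 %.2g 50.0 0.1 1 1 %.2g %.2g",
                        "45.0 0.1 1 100 %d %d %d %d 0.90 -"),
                  domains$domain_name, domains$domain_accession,
                  domains$protein_id, domains$evalue,
                  domains$evalue, domains$evalue,
                  domains$env_from, domains$env_to,
                  domains$env_from, domains$env_to)
  writeLines(c("# target name        accession   tlen query name           accession   qlen   E-value  score  bias   #  of  c-Evalue  i-Evalue  score  bias  from    to  from    to  from    to  acc description of target",
               rows), path)
  invisible(path)
}

#' Read gene order
#'
#' Two dialects: a 4-column TSV (`contig`, `start`, `gene_id`,
#' `protein_id`; `start` may be a plain rank) or GFF3, where `gene`
#' features are linked to proteins through the attribute named by
#' `protein_attr`.  Genes without a resolvable protein id are kept with an
#' empty `protein_id` and a warning.
#'
#' @param path Input path.
#' @param dialect `"tsv"` or `"gff3"`.
#' @param protein_attr GFF3 attribute carrying the protein id.
#' @return A tibble with `gene_id`, `protein_id`, `contig_id`, `start`,
#'   `end`, `strand`.
#' @export
read_genes <- function(path, dialect = c("tsv", "gff3"),
                       protein_attr = "protein_id") {
  dialect <- match.arg(dialect)
  stopifnot(file.exists(path))
  if (dialect == "tsv") {
    x <- readr::read_tsv(path, col_names = c("contig_id", "start", "gene_id",
                                             "protein_id"),
                         col_types = "cicc", progress = FALSE)
    out <- tibble(gene_id = x$gene_id,
                  protein_id = dplyr::coalesce(x$protein_id, ""),
                  contig_id = x$contig_id, start = x$start, end = x$start,
                  strand = "unknown")
  } else {
    if (!requireNamespace("rtracklayer", quietly = TRUE))
      stop("reading GFF3 requires the rtracklayer package", call. = FALSE)
    gr <- rtracklayer::import(path)
    gr <- gr[gr$type == "gene"]
    pid <- if (protein_attr %in% names(S4Vectors::mcols(gr)))
      as.character(S4Vectors::mcols(gr)[[protein_attr]]) else
        rep(NA_character_, length(gr))
    pid[is.na(pid)] <- ""
    out <- tibble(gene_id = as.character(gr$ID),
                  protein_id = pid,
                  contig_id = as.character(GenomicRanges::seqnames(gr)),
                  start = GenomicRanges::start(gr),
                  end = GenomicRanges::end(gr),
                  strand = as.character(GenomicRanges::strand(gr)))
    out$strand[!out$strand %in% c("+", "-")] <- "unknown"
  }
  if (any(out$end < out$start))
    stop("gene with end < start: ",
         out$gene_id[which(out$end < out$start)[1]], call. = FALSE)
  if (anyDuplicated(out$gene_id))
    stop("duplicate gene id(s): ",
         paste(head(unique(out$gene_id[duplicated(out$gene_id)]), 5),
               collapse = ", "), call. = FALSE)
  if (any(!nzchar(out$protein_id)))
    warning(sum(!nzchar(out$protein_id)),
            " gene(s) without a resolvable protein id", call. = FALSE)
  out
}

#' Write gene order as 4-column TSV
#'
#' @param genes Tibble as returned by [read_genes()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_genes <- function(genes, path) {
  readr::write_tsv(genes[, c("contig_id", "start", "gene_id", "protein_id")],
                   path, col_names = FALSE)
  invisible(path)
}
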