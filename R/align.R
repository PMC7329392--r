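# Local pairwise alignment with Karlin-Altschul E-values.
#
# The Smith-Waterman engine is Biostrings::pairwiseAlignment (BLOSUM62,
# gap open 11 / extend 1: a gap of length k costs 11 + k).  Identity is
# counted over aligned columns including gap columns, and an aligned X
# never counts as a match.  E-values use E = K * m * n * exp(-lambda * S);
# in database mode n is the total residue count of the database.

resolve_matrix <- function(params) {
  e <- new.env()
  utils::data(list = params$matrix, package = "Biostrings", envir = e)
  get(params$matrix, envir = e)
}

#' Karlin-Altschul E-value
#'
#' `E = K * m * n * exp(-lambda * S)`.
#'
#' @param score Raw alignment score(s).
#' @param m Query length.
#' @param n Subject length, or total database residue count in database
#'   mode.
#' @param params [alignment_params()].
#' @return E-value(s).
#' @export
#' @examples
#' karlin_altschul_evalue(50, 100, 100)
karlin_altschul_evalue <- function(score, m, n,
                                   params = alignment_params()) {
  stopifnot(m >= 1, n >= 1)
  params$ka_k * m * n * exp(-params$ka_lambda * score)
}

#' Optimal local alignment of two sequences
#'
#' @param a,b Amino-acid sequences (single strings).
#' @param params [alignment_params()].
#' @param db_size Total database residue count for database-mode E-values;
#'   NULL for pairwise mode (`n = nchar(b)`).
#' @return A one-row tibble: `score`, `evalue`, `identity` (matches over
#'   aligned columns, gaps count as columns and X never matches),
#'   `coverage_a`, `coverage_b` (aligned span over full length), and
#'   0-based half-open aligned intervals `a_start`, `a_end`, `b_start`,
#'   `b_end`.  A pair with no positive-scoring local alignment yields the
#'   empty-hit convention: score 0, identity 0, coverage 0.
#' @export
#' @examples
#' local_align("YAIG", "YVIG")$identity
local_align <- function(a, b, params = alignment_params(), db_size = NULL) {
  stopifnot(nchar(a) > 0, nchar(b) > 0)
  check_alphabet(c(a, b))
  al <- Biostrings::pairwiseAlignment(
    Biostrings::AAString(a), Biostrings::AAString(b), type = "local",
    substitutionMatrix = resolve_matrix(params),
    gapOpening = params$gap_open, gapExtension = params$gap_extend)
  s <- Biostrings::score(al)
  n_db <- if (is.null(db_size)) nchar(b) else db_size
  if (s <= 0 || nchar(as.character(Biostrings::pattern(al))) == 0) {
    return(tibble(score = 0, evalue = karlin_altschul_evalue(0, nchar(a),
                                                             n_db, params),
                  identity = 0, coverage_a = 0, coverage_b = 0,
                  a_start = 0L, a_end = 0L, b_start = 0L, b_end = 0L))
  }
  pa <- strsplit(as.character(Biostrings::pattern(al)), "")[[1]]
  pb <- strsplit(as.character(Biostrings::subject(al)), "")[[1]]
  ident <- mean(pa == pb & pa != "-" & pa != "X")
  a_span <- c(Biostrings::start(Biostrings::pattern(al)),
              Biostrings::end(Biostrings::pattern(al)))
  b_span <- c(Biostrings::start(Biostrings::subject(al)),
              Biostrings::end(Biostrings::subject(al)))
  tibble(score = s,
         evalue = karlin_altschul_evalue(s, nchar(a), n_db, params),
         identity = ident,
         coverage_a = (a_span[2] - a_span[1] + 1) / nchar(a),
         coverage_b = (b_span[2] - b_span[1] + 1) / nchar(b),
         a_start = a_span[1] - 1L, a_end = a_span[2],
         b_start = b_span[1] - 1L, b_end = b_span[2])
}

check_alphabet <- function(x) {
  bad <- grepl(paste0("[^", paste(AA_ALPHABET, collapse = ""), "]"), x)
  if (any(bad))
    stop("sequence contains residues outside the amino-acid alphabet",
         call. = FALSE)
  invisible(TRUE)
}

#' Reciprocal similarity link between two sequences
#'
#' TRUE when, in both directions, the E-value passes `e_threshold` (if
#' set), the query's coverage exceeds `coverage_threshold`, and identity
#' exceeds `identity_threshold` (if set).  With the symmetric scoring
#' scheme the optimal local alignment is computed once; the two directions
#' differ in which sequence's coverage (and query length, for database-mode
#' E-values) is tested.
#'
#' @param a,b Sequences.
#' @param e_threshold E-value must be strictly below this (NULL to skip).
#' @param coverage_threshold Query coverage must be strictly above this.
#' @param identity_threshold Identity must be strictly above this (NULL to
#'   skip).
#' @param params [alignment_params()].
#' @param db_size Database residue count for database-mode E-values.
#' @return Logical.
#' @export
reciprocal_link <- function(a, b, e_threshold = NULL,
                            coverage_threshold = 0,
                            identity_threshold = NULL,
                            params = alignment_params(),
                            db_size = NULL) {
  hit <- local_align(a, b, params, db_size)
  ok <- hit$coverage_a > coverage_threshold &
    hit$coverage_b > coverage_threshold
  if (!is.null(identity_threshold))
    ok <- ok && hit$identity > identity_threshold
  if (!is.null(e_threshold)) {
    n1 <- if (is.null(db_size)) nchar(b) else db_size
    n2 <- if (is.null(db_size)) nchar(a) else db_size
    e_ab <- karlin_altschul_evalue(hit$score, nchar(a), n1, params)
    e_ba <- karlin_altschul_evalue(hit$score, nchar(b), n2, params)
    ok <- ok && e_ab < e_threshold && e_ba < e_threshold
  }
  isTRUE(ok)
}

# All-vs-all hits among named sequences: one row per unordered pair.
# Alignments are vectorised per query against the remaining subjects.
pairwise_hits <- function(seqs, params = alignment_params(),
                          db_size = NULL) {
  n <- length(seqs)
  stopifnot(!is.null(names(seqs)), n >= 1)
  if (n < 2)
    return(tibble(id_a = character(), id_b = character(), score = double(),
                  identity = double(), coverage_a = double(),
                  coverage_b = double(), evalue_a = double(),
                  evalue_b = double()))
  mat <- resolve_matrix(params)
  n_db <- if (is.null(db_size)) NULL else db_size
  res <- vector("list", n - 1L)
  for (i in seq_len(n - 1L)) {
    rest <- seqs[(i + 1L):n]
    al <- Biostrings::pairwiseAlignment(
      Biostrings::AAStringSet(rest), Biostrings::AAString(seqs[[i]]),
      type = "local", substitutionMatrix = mat,
      gapOpening = params$gap_open, gapExtension = params$gap_extend)
    sc <- Biostrings::score(al)
    pat <- as.character(Biostrings::alignedPattern(al))
    sub <- as.character(Biostrings::alignedSubject(al))
    ident <- purrr::map2_dbl(pat, sub, function(x, y) {
      xs <- strsplit(x, "")[[1]]; ys <- strsplit(y, "")[[1]]
      if (length(xs) == 0) return(0)
      mean(xs == ys & xs != "-" & xs != "X")
    })
    # aligned spans on subject (= seqs[i]) and patterns (= rest)
    ss <- Biostrings::start(Biostrings::subject(al))
    se <- Biostrings::end(Biostrings::subject(al))
    ps <- Biostrings::start(Biostrings::pattern(al))
    pe <- Biostrings::end(Biostrings::pattern(al))
    empty <- sc <= 0
    cov_i <- ifelse(empty, 0, (se - ss + 1) / nchar(seqs[[i]]))
    cov_j <- ifelse(empty, 0, (pe - ps + 1) / nchar(rest))
    sc[empty] <- 0
    ident[empty] <- 0
    nb_i <- if (is.null(n_db)) nchar(rest) else n_db
    nb_j <- if (is.null(n_db)) nchar(seqs[[i]]) else n_db
    res[[i]] <- tibble(
      id_a = names(seqs)[i], id_b = names(rest),
      score = unname(sc), identity = unname(ident),
      coverage_a = unname(cov_i), coverage_b = unname(cov_j),
      evalue_a = unname(karlin_altschul_evalue(sc, nchar(seqs[[i]]),
                                               nb_i, params)),
      evalue_b = unname(karlin_altschul_evalue(sc, nchar(rest),
                                               nb_j, params)))
  }
  bind_rows(res)
}
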