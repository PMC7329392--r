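# Independent oracles, kept deliberately naive.

AA20_T <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]

rand_seq <- function(n, alphabet = AA20_T) {
  paste(sample(alphabet, n, TRUE), collapse = "")
}

# Brute-force seed-sliding scorer, written directly from the definition:
# for every seed window, try every gapless off-source placement, find the
# best (max identical residues, smallest placement start on ties), and let
# the seed vote for its own matched residues; a position's score is its
# votes over the number of windows covering it.  X never matches.
oracle_repeat_scores <- function(seq, k) {
  x <- strsplit(seq, "")[[1]]
  L <- length(x)
  n_seeds <- L - k + 1L
  votes <- numeric(L)
  for (s in seq_len(n_seeds)) {
    seed <- x[s:(s + k - 1L)]
    best_m <- -1L
    best_p <- NA_integer_
    for (p in (2L - k):L) {
      if (p == s) next
      j <- seq_len(k)
      i <- p + j - 1L
      ok <- i >= 1L & i <= L
      nm <- sum(x[i[ok]] == seed[j[ok]] & seed[j[ok]] != "X")
      if (nm > best_m) {
        best_m <- nm
        best_p <- p
      }
    }
    if (best_m > 0L) {
      j <- seq_len(k)
      i <- best_p + j - 1L
      ok <- i >= 1L & i <= L
      m <- ok & x[pmax(i, 1L)] == seed & seed != "X"
      src <- (s + j - 1L)[m]
      votes[src] <- votes[src] + 1
    }
  }
  i <- seq_len(L)
  votes / (pmin(i, n_seeds) - pmax(1L, i - k + 1L) + 1L)
}

# Textbook Smith-Waterman with affine gaps (Gotoh), gap of length k costs
# open + k * extend; returns the optimal local score.
oracle_sw_score <- function(a, b, open = 11, extend = 1) {
  B62 <- get_blosum62()
  xa <- strsplit(a, "")[[1]]
  xb <- strsplit(b, "")[[1]]
  n <- length(xa)
  m <- length(xb)
  NEG <- -1e9
  H <- matrix(0, n + 1L, m + 1L)
  E <- matrix(NEG, n + 1L, m + 1L)  # gap in a (consume b)
  F <- matrix(NEG, n + 1L, m + 1L)  # gap in b (consume a)
  best <- 0
  for (i in 2L:(n + 1L)) {
    for (j in 2L:(m + 1L)) {
      E[i, j] <- max(H[i, j - 1L] - open - extend, E[i, j - 1L] - extend)
      F[i, j] <- max(H[i - 1L, j] - open - extend, F[i - 1L, j] - extend)
      H[i, j] <- max(0,
                     H[i - 1L, j - 1L] + B62[xa[i - 1L], xb[j - 1L]],
                     E[i, j], F[i, j])
      if (H[i, j] > best) best <- H[i, j]
    }
  }
  best
}

get_blosum62 <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      e <- new.env()
      utils::data("BLOSUM62", package = "Biostrings", envir = e)
      cache <<- get("BLOSUM62", envir = e)
    }
    cache
  }
})

# Union-find partition oracle over a full link matrix.
oracle_partition <- function(ids, link_matrix) {
  parent <- seq_along(ids)
  find <- function(i) {
    while (parent[i] != i) i <- parent[i]
    i
  }
  n <- length(ids)
  for (i in seq_len(n - 1L)) for (j in (i + 1L):n) {
    if (link_matrix[i, j]) {
      ri <- find(i)
      rj <- find(j)
      if (ri != rj) parent[ri] <- rj
    }
  }
  vapply(seq_len(n), find, 0L)
}

# minimal track with a given mask, for parts-counting tests
fake_track <- function(mask) {
  structure(list(mature_length = length(mask), seed_length = 8L,
                 n_seeds = max(1L, length(mask) - 7L), threshold = 0.6,
                 scores = as.numeric(mask), raw_mask = mask, mask = mask,
                 too_short = FALSE), class = "kep_track")
}

# toy planted KEP in the generator's architecture; default flanks are
# fixed arbitrary non-repetitive K/R-free strings
toy_kep_sequence <- function(unit = "YAIGSTVN", k = 4L,
                             leader = "DNEQHPYWGFTCVMAEDQSHYLPGIW",
                             tail = "GDNHQE") {
  signal <- "MKLLVVFFIWDDEEASA"  # K at 2, run 3-10, filler, ASA ends at 17
  list(sequence = paste0(signal, leader, "KR",
                         paste(rep(paste0(unit, "KR"), k), collapse = ""),
                         tail),
       cleavage_pos = nchar(signal),
       mature = paste0(leader, "KR",
                       paste(rep(paste0(unit, "KR"), k), collapse = ""),
                       tail),
       unit_starts = nchar(leader) + 2L +
         (seq_len(k) - 1L) * (nchar(unit) + 2L))
}
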