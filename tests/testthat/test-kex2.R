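test_that("site scanning is leftmost-greedy and non-overlapping", {
  s <- find_kex2_sites("AAAKRGGGKKCCC")
  expect_equal(s$start, c(3L, 8L))
  expect_equal(s$end, c(5L, 10L))
  expect_equal(split_fragments("AAAKRGGGKKCCC")$sequence,
               c("AAA", "GGG", "CCC"))

  # greedy scan consumes KR first; the remaining R starts mid-pair
  s2 <- find_kex2_sites("AKRRG")
  expect_equal(nrow(s2), 1L)
  expect_equal(c(s2$start, s2$end), c(1L, 3L))
  expect_equal(split_fragments("AKRRG")$sequence, c("A", "RG"))

  expect_equal(nrow(find_kex2_sites("ACDEFG")), 0L)
  expect_equal(split_fragments("ACDEFG")$sequence, "ACDEFG")
  expect_equal(nrow(split_fragments("KRKR")), 0L)
})

test_that("site and fragment residues reconstruct the mature sequence", {
  set.seed(77)
  for (z in 1:20) {
    mature <- rand_seq(sample(20:120, 1))
    sites <- find_kex2_sites(mature)
    frags <- split_fragments(mature)
    site_seq <- if (nrow(sites))
      substring(mature, sites$start + 1, sites$end) else character(0)
    pieces <- dplyr::bind_rows(
      tibble::tibble(start = sites$start, end = sites$end,
                     sequence = site_seq),
      frags[, c("start", "end", "sequence")])
    pieces <- pieces[order(pieces$start), ]
    expect_equal(paste(pieces$sequence, collapse = ""), mature)
    # non-overlapping
    expect_true(all(pieces$start[-1] >= head(pieces$end, -1)))
  }
})

test_that("repeat-unit classification enforces masked fraction and length", {
  mk <- function(len, masked) {
    track <- fake_track(rep(masked, len))
    frag <- tibble::tibble(start = 0L, end = len,
                           sequence = strrep("A", len))
    classify_repeat_units(frag, track)
  }
  expect_true(mk(8, TRUE)$is_repeat_unit)     # boundary inclusion at 8
  expect_false(mk(7, TRUE)$is_repeat_unit)    # below the minimum length
  expect_false(mk(20, FALSE)$is_repeat_unit)  # unmasked fragment
  expect_true(mk(100, TRUE)$is_repeat_unit)   # boundary inclusion at 100
  expect_false(mk(101, TRUE)$is_repeat_unit)

  half <- fake_track(rep(c(TRUE, FALSE), 10))
  frag <- tibble::tibble(start = 0L, end = 20L, sequence = strrep("A", 20))
  expect_true(classify_repeat_units(frag, half)$is_repeat_unit)      # 0.5
  expect_false(classify_repeat_units(frag, half,
                                     min_masked_fraction = 0.6)$is_repeat_unit)

  bad <- tibble::tibble(start = 0L, end = 30L, sequence = strrep("A", 30))
  expect_error(classify_repeat_units(bad, fake_track(rep(TRUE, 10))),
               "track")
})

test_that("call_kep accepts a toy KEP with exactly the planted units", {
  toy <- toy_kep_sequence()
  res <- call_kep(toy$sequence, TRUE, toy$cleavage_pos)
  expect_true(res$accepted)
  units <- res$fragments[res$fragments$is_repeat_unit, ]
  expect_equal(nrow(units), 4L)
  expect_equal(units$start, toy$unit_starts)
  expect_equal(unique(units$sequence), "YAIGSTVN")
})

test_that("call_kep reports the first failing stage", {
  toy <- toy_kep_sequence()
  expect_equal(call_kep(toy$sequence, FALSE, NA_integer_)$reason,
               "NO_SIGNAL")
  expect_equal(call_kep("MKLLVVFFIWDDEEASAYAIGSTVN", TRUE, 17L)$reason,
               "TOO_SHORT")

  set.seed(5)
  rnd <- paste0("MKLLVVFFIWDDEEASA", rand_seq(60))
  expect_equal(call_kep(rnd, TRUE, 17L)$reason, "NOT_REPETITIVE")

  toy_nok <- toy_kep_sequence(k = 5)
  stripped <- gsub("KR", "", toy_nok$sequence, fixed = TRUE)
  # removing all sites keeps the repeats but leaves nothing to cleave
  expect_equal(call_kep(stripped, TRUE, toy_nok$cleavage_pos)$reason,
               "NO_KEX2_SITE")

  long <- toy_kep_sequence(tail = paste0(strrep("GDNHQE", 17), "GDN"))
  expect_equal(nchar(strsplit(long$mature, "KR")[[1]][6]), 105)
  expect_equal(call_kep(long$sequence, TRUE, long$cleavage_pos)$reason,
               "FRAGMENT_TOO_LONG")

  two <- toy_kep_sequence(k = 2)
  expect_equal(call_kep(two$sequence, TRUE, two$cleavage_pos)$reason,
               "TOO_FEW_UNITS")

  short <- toy_kep_sequence(unit = "YAIGSTV", k = 6)  # 7-residue units
  expect_equal(call_kep(short$sequence, TRUE, short$cleavage_pos)$reason,
               "UNITS_TOO_SHORT")
})

test_that("detection is order-independent and funnel counts are monotone", {
  sim <- simulate_kep_study(sim_config(seed = 21, n_strains = 3,
                                       keps_per_strain = 3,
                                       decoys_per_class = 1,
                                       genes_per_strain = 110))
  det1 <- kep_detect(sim$proteins, sim$predictions)
  shuffled <- sim$proteins[sample(nrow(sim$proteins)), ]
  det2 <- kep_detect(shuffled, sim$predictions)
  m1 <- det1[order(det1$protein_id), c("protein_id", "accepted", "reason")]
  m2 <- det2[order(det2$protein_id), c("protein_id", "accepted", "reason")]
  expect_equal(as.data.frame(m1), as.data.frame(m2))
  f <- kep_funnel(det1)
  expect_true(all(diff(f) <= 0))
  expect_equal(unname(f["keps"]), sum(det1$accepted))
})
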