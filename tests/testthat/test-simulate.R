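small_cfg <- function(seed, ...) {
  sim_config(seed = seed, n_strains = 3, keps_per_strain = 3,
             decoys_per_class = 2, genes_per_strain = 110, ...)
}

test_that("simulation is deterministic in the seed", {
  s1 <- simulate_kep_study(small_cfg(7))
  s2 <- simulate_kep_study(small_cfg(7))
  expect_identical(s1$proteins, s2$proteins)
  expect_identical(s1$genes, s2$genes)
  expect_identical(s1$labels, s2$labels)
  s3 <- simulate_kep_study(small_cfg(8))
  expect_false(identical(s1$proteins$sequence, s3$proteins$sequence))
})

test_that("planted KEPs at mutation 0 are accepted with the planted units", {
  sim <- simulate_kep_study(small_cfg(9, mutation_rate = 0))
  tk <- sim$truth$keps
  pr <- sim$truth$proteins
  for (i in seq_len(nrow(tk))) {
    pid <- tk$protein_id[i]
    cp <- pr$cleavage_pos[pr$protein_id == pid]
    seqn <- sim$proteins$sequence[sim$proteins$protein_id == pid]
    res <- call_kep(seqn, TRUE, cp)
    expect_true(res$accepted)
    got <- res$fragments[res$fragments$is_repeat_unit, ]
    expect_equal(got$start, tk$units[[i]]$start)
    expect_equal(got$end, tk$units[[i]]$end)
    expect_equal(got$sequence, tk$units[[i]]$sequence)
  }
})

test_that("every decoy class triggers its intended rejection reason", {
  sim <- simulate_kep_study(small_cfg(10))
  det <- kep_detect(sim$proteins, sim$predictions)
  m <- merge(det, sim$truth$proteins, by = "protein_id")
  dec <- m[m$class != "kep", ]
  expect_false(any(dec$accepted))
  expect_equal(dec$reason, unname(dec$expected_reason))
})

test_that("units carry no dibasic collisions with their separators", {
  sim <- simulate_kep_study(small_cfg(12))
  tk <- sim$truth$keps
  for (i in seq_len(nrow(tk))) {
    mat <- tk$mature[i]
    units <- tk$units[[i]]
    found <- find_kex2_sites(mat)
    # every planted unit is flanked by sites exactly at its boundaries
    expect_true(all((units$start - 2L) %in% found$start))
    expect_equal(substring(mat, units$start + 1, units$end),
                 units$sequence)
    expect_false(any(grepl("K[KR]|R[KR]", units$sequence)))
  }
})

test_that("emitted files reproduce the in-memory simulation byte for byte", {
  sim <- simulate_kep_study(small_cfg(13))
  dir <- withr::local_tempdir()
  paths <- write_simulation(sim, dir)
  expect_true(all(file.exists(paths)))

  prot <- read_proteins(paths[["proteins"]])
  expect_equal(prot$sequence, sim$proteins$sequence)
  expect_equal(prot$protein_id, sim$proteins$protein_id)
  expect_equal(prot$strain_id, sim$proteins$strain_id)

  pred <- read_signalp(paths[["signalp"]])
  expect_equal(pred$has_signal, sim$predictions$has_signal)
  expect_equal(pred$cleavage_pos, sim$predictions$cleavage_pos)

  genes <- suppressWarnings(read_genes(paths[["genes"]], dialect = "tsv"))
  expect_equal(genes$protein_id, sim$genes$protein_id)

  dom <- read_domains(paths[["domains"]])
  expect_equal(sort(unique(dom$domain_name)),
               sort(unique(sim$domains$domain_name)))
  expect_equal(nrow(dom), nrow(sim$domains))

  truth <- jsonlite::read_json(paths[["truth"]], simplifyVector = TRUE)
  expect_equal(truth$seed, sim$config$seed)
  expect_equal(nrow(truth$proteins), nrow(sim$truth$proteins))
})

test_that("planted gene distances are recovered exactly by the neighborhood", {
  sim <- simulate_kep_study(small_cfg(14, duf3328_fraction = 1))
  nbh <- gene_neighborhood(sim$genes)
  kep_ids <- sim$truth$keps$protein_id
  st <- domain_vicinity_stats(nbh, kep_ids, sim$labels, "DUF3328")
  place <- sim$truth$placements
  got <- st$nearest$nearest[match(place$protein_id, st$nearest$protein_id)]
  expect_equal(got, place$duf_distance)
  expect_equal(st$fraction_of_keps_with_hit, 1)
})

test_that("duf3328_fraction 0 yields no vicinity hits", {
  sim <- simulate_kep_study(small_cfg(15, duf3328_fraction = 0))
  nbh <- gene_neighborhood(sim$genes)
  st <- domain_vicinity_stats(nbh, sim$truth$keps$protein_id,
                              sim$labels, "DUF3328")
  expect_equal(st$fraction_of_keps_with_hit, 0)
  expect_equal(st$total, 0L)
})

test_that("family ancestors are pairwise dissimilar", {
  sim <- simulate_kep_study(small_cfg(16))
  tk <- sim$truth$keps
  # one representative unit per family (mutation makes them near, not
  # identical to, the ancestor; cross-family identity must stay low)
  reps <- tapply(seq_len(nrow(tk)), tk$family_id, function(ix) {
    tk$units[[ix[1]]]$sequence[1]
  })
  for (i in seq_along(reps)) for (j in seq_along(reps)) {
    if (i >= j) next
    hit <- local_align(reps[[i]], reps[[j]])
    matches <- hit$identity * (hit$a_end - hit$a_start)
    expect_lt(matches / max(nchar(reps[[i]]), nchar(reps[[j]])), 0.55)
  }
})
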