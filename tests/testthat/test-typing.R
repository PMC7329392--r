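test_that("single linkage takes the transitive closure of links", {
  links <- tibble::tibble(id_a = c("A", "B"), id_b = c("B", "C"))
  part <- cluster_single_linkage(c("A", "B", "C", "D"), links)
  expect_equal(part$component[part$id == "A"],
               part$component[part$id == "C"])
  expect_false(part$component[part$id == "D"] ==
                 part$component[part$id == "A"])

  none <- cluster_single_linkage(c("A", "B"), links[0, ])
  expect_equal(length(unique(none$component)), 2L)
})

test_that("single linkage matches a union-find oracle on random graphs", {
  set.seed(55)
  for (z in 1:10) {
    n <- 30
    ids <- paste0("i", sprintf("%02d", 1:n))
    m <- matrix(runif(n * n) < 0.05, n, n)
    m[lower.tri(m, diag = TRUE)] <- FALSE
    idx <- which(m, arr.ind = TRUE)
    links <- tibble::tibble(id_a = ids[idx[, 1]], id_b = ids[idx[, 2]])
    got <- cluster_single_linkage(ids, links)
    want <- oracle_partition(ids, m | t(m))
    # same partition up to relabeling
    expect_equal(length(unique(got$component)), length(unique(want)))
    tab <- table(got$component[match(ids, got$id)], want)
    expect_true(all(rowSums(tab > 0) == 1) && all(colSums(tab > 0) == 1))
  }
})

test_that("type labels order by size with smallest-member tie-break", {
  membership <- tibble::tibble(
    id = c("e1", "e2", "e3", "e4", "e5",   # size 5
           "b1", "b2", "b3",               # size 3, smallest member b1
           "a1", "a2", "a3",               # size 3, smallest member a1
           "solo"),
    component = c(rep(1L, 5), rep(2L, 3), rep(3L, 3), 4L))
  lab <- assign_type_labels(membership)
  expect_equal(unique(lab$type_label[startsWith(lab$id, "e")]), "#1")
  expect_equal(unique(lab$type_label[startsWith(lab$id, "a")]), "#2")
  expect_equal(unique(lab$type_label[startsWith(lab$id, "b")]), "#3")
  expect_equal(lab$type_label[lab$id == "solo"], "0")

  single <- assign_type_labels(tibble::tibble(id = c("x", "y"),
                                              component = 1L))
  expect_equal(unique(single$type_label), "#1")

  # permutation stability
  perm <- sample(nrow(membership))
  lab2 <- assign_type_labels(membership[perm, ])
  expect_equal(lab2$type_label[match(lab$id, lab2$id)], lab$type_label)
})

test_that("identical KEPs cluster together and unrelated ones stand alone", {
  set.seed(66)
  shared <- paste0("MKLLVVFFIWDDEEASA", rand_seq(100))
  other <- paste0("MKLLVVFFIWDDEEASA", rand_seq(90))
  keps <- tibble::tibble(protein_id = c("k1", "k2", "k3", "lone"),
                         sequence = c(shared, shared, shared, other))
  ty <- kep_type_clustering(keps)
  td <- tidy(ty)
  expect_equal(unique(td$type_label[td$protein_id != "lone"]), "#1")
  expect_equal(td$type_label[td$protein_id == "lone"], "0")
  expect_equal(glance(ty)$n_types, 1L)
  expect_equal(glance(ty)$n_standalone, 1L)
})

test_that("families mutated from one ancestor form one type each", {
  sim <- simulate_kep_study(sim_config(seed = 31, n_strains = 4,
                                       keps_per_strain = 5,
                                       n_families = 2,
                                       decoys_per_class = 0,
                                       genes_per_strain = 180))
  det <- kep_detect(sim$proteins, sim$predictions)
  keps <- merge(det[det$accepted, c("protein_id", "strain_id")],
                sim$proteins[, c("protein_id", "sequence")],
                by = "protein_id")
  ty <- kep_type_clustering(tibble::as_tibble(keps))
  truth <- sim$truth$proteins
  m <- merge(tidy(ty), truth[, c("protein_id", "family_id")],
             by = "protein_id")
  expect_equal(length(unique(m$type_label)), 2L)
  tab <- table(m$type_label, m$family_id)
  expect_true(all(rowSums(tab > 0) == 1) && all(colSums(tab > 0) == 1))
})

test_that("repeat units subdivide into within-type sub-types", {
  units <- tibble::tibble(
    unit_id = paste0("u", 1:6),
    protein_id = c("k1", "k1", "k2", "k2", "k3", "k3"),
    sequence = c("YAIGSTVNDQ", "WFCMHENQDT",
                 "YAIGSTVNDQ", "WFCMHENQDT",
                 "YVIGSTVNDQ", "WFCMHENQDS"))
  types <- tibble::tibble(protein_id = c("k1", "k2", "k3"),
                          type_label = "#1")
  st <- subtype_repeat_units(units, types)
  expect_equal(nrow(st), 6L)
  expect_equal(length(unique(st$subtype_label)), 2L)
  # each unit belongs to exactly one sub-type of its parent type
  expect_true(all(startsWith(st$subtype_label, "#1/")))
  expect_equal(st$subtype_label[1], st$subtype_label[3])
  expect_equal(st$subtype_label[2], st$subtype_label[4])
  expect_equal(st$subtype_label[1], st$subtype_label[5])
  expect_false(st$subtype_label[1] == st$subtype_label[2])
  expect_false(any(st$small))
})

test_that("center-star profiles give per-column frequencies with pseudocounts", {
  same <- build_profile(rep("YAIGSTVN", 5))
  # modal frequency per column: (5 + 0.05) / (5 + 20 * 0.05)
  expect_equal(unname(apply(same$profile, 2, max)), rep(5.05 / 6, 8))
  expect_equal(unname(colSums(same$profile)), rep(1, 8))
  expect_equal(length(unique(nchar(same$alignment))), 1L)

  # column 2: three A, two V; counts plus 0.05 pseudocount per residue
  mix <- build_profile(c("YAIGSTVN", "YAIGSTVN", "YAIGSTVN",
                         "YVIGSTVN", "YVIGSTVN"))
  expect_equal(unname(mix$profile["A", 2]), (3 + 0.05) / (5 + 20 * 0.05))
  expect_equal(unname(mix$profile["V", 2]), (2 + 0.05) / (5 + 20 * 0.05))

  set.seed(44)
  rnd <- build_profile(replicate(4, rand_seq(12)))
  expect_equal(unname(colSums(rnd$profile)),
               rep(1, ncol(rnd$profile)))

  single <- build_profile("YAIG")
  expect_equal(unname(single$profile["Y", 1]), (1 + 0.05) / (1 + 20 * 0.05))
})

test_that("center-star merging handles insertions against the center", {
  prof <- build_profile(c("YAIGSTVN", "YAIGWWSTVN", "YAIGSTVN"))
  expect_equal(length(unique(nchar(prof$alignment))), 1L)
  # every input is recoverable by dropping gaps
  expect_setequal(gsub("-", "", prof$alignment),
                  c("YAIGSTVN", "YAIGWWSTVN"))
})

test_that("set comparison matches near-identical sequences only", {
  set.seed(45)
  a <- setNames(c(strrep("YAIGSTVNDQ", 4), rand_seq(40)), c("x1", "x2"))
  b <- setNames(c(strrep("YAIGSTVNDQ", 4), rand_seq(40)), c("y1", "y2"))
  cmp <- compare_kep_sets(a, b)
  expect_equal(cmp$matched_a, "x1")
  expect_equal(cmp$matched_b, "y1")

  ident <- compare_kep_sets(a, setNames(a, c("z1", "z2")))
  expect_equal(ident$n_matched_a, 2L)
  expect_equal(ident$n_matched_b, 2L)

  # 10% of positions mutated: identity 0.9 < 0.95, unmatched
  mut <- strrep("YAIGSTVNDQ", 4)
  substr(mut, 1, 4) <- "WFCM"
  cmp2 <- compare_kep_sets(setNames(strrep("YAIGSTVNDQ", 4), "p"),
                           setNames(mut, "q"))
  expect_equal(cmp2$n_matched_a, 0L)
})
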