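make_contig <- function(n, kep_at = integer(0), labelled_at = integer(0),
                        label = "DUF3328", contig = "c1") {
  genes <- tibble::tibble(gene_id = paste0(contig, "_g", seq_len(n)),
                          protein_id = paste0(contig, "_p", seq_len(n)),
                          contig_id = contig,
                          start = seq_len(n) * 100L,
                          end = seq_len(n) * 100L + 50L,
                          strand = "+")
  list(nbh = gene_neighborhood(genes),
       kep_ids = paste0(contig, "_p", kep_at),
       labels = tibble::tibble(protein_id = paste0(contig, "_p", labelled_at),
                               label = label))
}

test_that("vicinity windows truncate at contig ends and exclude the anchor", {
  x <- make_contig(31, kep_at = 16)
  v <- vicinity_genes(x$nbh, x$kep_ids, radius = 15)
  expect_equal(nrow(v), 30L)
  expect_setequal(v$distance, setdiff(-15:15, 0))

  edge <- vicinity_genes(x$nbh, "c1_p1", radius = 15)
  expect_equal(sort(edge$distance), 1:15)

  expect_equal(nrow(vicinity_genes(x$nbh, x$kep_ids, radius = 0)), 0L)

  expect_warning(out <- vicinity_genes(x$nbh, "absent"), "no gene")
  expect_equal(nrow(out), 0L)
})

test_that("vicinity statistics aggregate nearest and all-hit distances", {
  # two KEPs with nearest labelled genes at distances 2 and 4
  x <- make_contig(80, kep_at = c(20, 60), labelled_at = c(22, 64))
  st <- domain_vicinity_stats(x$nbh, x$kep_ids, x$labels, "DUF3328")
  expect_equal(st$nearest_mean, 3)
  expect_equal(st$fraction_of_keps_with_hit, 1)
  expect_equal(st$total, 2L)
  expect_equal(st$histogram$count[st$histogram$distance %in% c(2, 4)],
               c(1L, 1L))

  # hits on both sides at the same distance are both counted
  y <- make_contig(40, kep_at = 20, labelled_at = c(17, 23))
  st2 <- domain_vicinity_stats(y$nbh, y$kep_ids, y$labels, "DUF3328")
  expect_equal(st2$histogram$count[st2$histogram$distance == 3], 2L)
  expect_equal(st2$nearest_mean, 3)
  expect_equal(st2$total, 2L)

  # no labelled genes at all
  z <- make_contig(40, kep_at = 20)
  st3 <- domain_vicinity_stats(z$nbh, z$kep_ids, z$labels, "DUF3328")
  expect_equal(st3$fraction_of_keps_with_hit, 0)
  expect_true(is.na(st3$nearest_mean))
  expect_true(is.na(st3$allhits_mean))

  # conservation: histogram counts sum to the total
  expect_equal(sum(st$histogram$count), st$total)
  expect_equal(sum(st2$histogram$count), st2$total)
})

test_that("allhits_mean respects its distance cap", {
  x <- make_contig(60, kep_at = 30, labelled_at = c(32, 42))  # d = 2 and 12
  st <- domain_vicinity_stats(x$nbh, x$kep_ids, x$labels, "DUF3328",
                              radius = 15, allhits_max_dist = 10)
  expect_equal(st$total, 2L)
  expect_equal(st$allhits_mean, 2)          # the 12 is beyond the cap
  expect_equal(st$nearest_mean, 2)
})

test_that("conditional histograms partition the unconditional counts", {
  # KEP at 20 has DUF3328 (d=2) and Tyrosinase (d=3); KEP at 60 has only
  # Tyrosinase (d=5)
  genes <- make_contig(90, kep_at = c(20, 60))
  labels <- tibble::tibble(
    protein_id = c("c1_p22", "c1_p23", "c1_p65"),
    label = c("DUF3328", "Tyrosinase", "Tyrosinase"))
  strata <- conditional_histogram(genes$nbh, genes$kep_ids, labels,
                                  "Tyrosinase", "DUF3328")
  expect_equal(sum(strata$with$histogram$count), 1L)
  expect_equal(sum(strata$without$histogram$count), 1L)
  expect_equal(strata$with$histogram$count[3], 1L)
  expect_equal(strata$without$histogram$count[5], 1L)
  uncond <- domain_vicinity_stats(genes$nbh, genes$kep_ids, labels,
                                  "Tyrosinase")
  expect_equal(strata$with$histogram$count + strata$without$histogram$count,
               uncond$histogram$count)

  # conditioning label absent everywhere: the negative stratum equals the
  # unconditional statistics
  none <- conditional_histogram(genes$nbh, genes$kep_ids, labels,
                                "Tyrosinase", "NoSuchDomain")
  expect_equal(none$without$histogram, uncond$histogram)
  expect_equal(sum(none$with$histogram$count), 0L)
})

test_that("KEP co-occurrence is symmetric", {
  x <- make_contig(50, kep_at = c(10, 14))
  st <- cooccurring_keps(x$nbh, x$kep_ids, radius = 15)
  expect_equal(st$fraction_of_keps_with_hit, 1)
  expect_equal(st$nearest, tibble::tibble(protein_id = x$kep_ids,
                                          nearest = c(4L, 4L)))
  far <- make_contig(80, kep_at = c(10, 60))
  st2 <- cooccurring_keps(far$nbh, far$kep_ids, radius = 15)
  expect_equal(st2$fraction_of_keps_with_hit, 0)
})

test_that("distances never cross contigs", {
  g1 <- make_contig(30, kep_at = 15, contig = "c1")
  g2 <- make_contig(30, labelled_at = 16, contig = "c2")
  nbh <- gene_neighborhood(dplyr::bind_rows(
    tibble::tibble(gene_id = g1$nbh$gene_id, protein_id = g1$nbh$protein_id,
                   contig_id = g1$nbh$contig_id,
                   start = g1$nbh$rank * 100L, end = g1$nbh$rank * 100L + 50L,
                   strand = "+"),
    tibble::tibble(gene_id = g2$nbh$gene_id, protein_id = g2$nbh$protein_id,
                   contig_id = g2$nbh$contig_id,
                   start = g2$nbh$rank * 100L, end = g2$nbh$rank * 100L + 50L,
                   strand = "+")))
  st <- domain_vicinity_stats(nbh, g1$kep_ids, g2$labels, "DUF3328")
  expect_equal(st$total, 0L)
  expect_equal(st$fraction_of_keps_with_hit, 0)
})
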