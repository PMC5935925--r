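# Alpha diversity: per-sample stats, rarefaction, group testing, composition.

make_table <- function(counts_long) {
  # counts_long: tibble(sample_id, otu_id, count); builds a minimal otu_tbl
  seqs <- tibble::tibble(
    sample_id = rep(counts_long$sample_id, counts_long$count),
    otu_id = rep(counts_long$otu_id, counts_long$count))
  reps <- stats::setNames(random_dna(length(unique(counts_long$otu_id)), 1400),
                          unique(counts_long$otu_id))
  seqs$sequence <- reps[seqs$otu_id]
  cluster_open_reference(seqs[, c("sample_id", "sequence")], NULL,
                         threshold = 1, min_otu_size = 1)
}

test_that("per-sample totals and richness are counted from the OTU table", {
  tab <- make_table(tibble::tibble(sample_id = "s1",
                                   otu_id = c("a", "b"), count = c(10L, 1L)))
  st <- sample_stats(tab, tibble::tibble(sample_id = "s1", group = "wild"))
  expect_equal(st$n_sequences, 11L)
  expect_equal(st$n_otus, 2L)
  expect_warning(sample_stats(tab, tibble::tibble(sample_id = "zz",
                                                  group = "wild")), "control")
})

test_that("the packaged per-larva fixture matches its in-text anchors", {
  tab <- load_table2_fixture()
  larvae <- tab[tab$group %in% c("wild", "domesticated"), ]
  expect_equal(nrow(larvae), 58)
  expect_equal(sum(larvae$n_sequences >= 1), 56)
  expect_equal(max(larvae$n_otus), 13L)
  expect_equal(larvae$sample_id[which.max(larvae$n_otus)], "Tum.P.D3")
  expect_equal(sum(larvae$group == "wild"), 35)
})

test_that("rarefaction reproduces closed-form expectations and vegan's exact curve", {
  # one OTU: always exactly one observed
  r1 <- rarefy(c(a = 100), depths = c(10, 50), iterations = 50, seed = 1)
  expect_equal(r1$mean_observed, c(1, 1))
  # two singletons at full depth: both observed with certainty
  r2 <- rarefy(c(a = 1, b = 1), depths = 2, iterations = 20, seed = 1)
  expect_equal(r2$mean_observed, 2)
  # {5, 5} at depth 2: E[distinct] = sum over OTUs of P(observed)
  #   = 2 * (1 - (5/10) * (4/9)) = 14/9 = 1.5556
  r3 <- rarefy(c(a = 5, b = 5), depths = 2, iterations = 4000, seed = 1)
  expect_lt(abs(r3$mean_observed - 2 * (1 - 5 * 4 / (10 * 9))), 0.03)
  # vegan's exact hypergeometric expectation as an independent oracle
  counts <- c(a = 40, b = 10, c = 5, d = 1)
  mine <- rarefy(counts, depths = c(10, 30), iterations = 4000, seed = 2)
  ve <- as.numeric(vegan::rarefy(counts, sample = c(10, 30)))
  expect_lt(max(abs(mine$mean_observed - ve)), 0.05)
  # monotone and converging to the OTU count at full depth
  full <- rarefy(counts, depths = c(10, 30, 56), iterations = 500, seed = 3)
  expect_true(all(diff(full$mean_observed) >= 0))
  expect_equal(dplyr::last(full$mean_observed), 4)
  # empty vector: empty curve
  expect_equal(nrow(rarefy(c(a = 0))), 0)
})

test_that("the exact one-tailed Mann-Whitney p matches small-case enumeration", {
  # A = {1,2}, B = {3,4}, testing B greater: 1 of C(4,2) = 6 orderings
  mw <- mann_whitney_one_tailed(c(1, 2), c(3, 4), alternative = "b_greater")
  expect_equal(mw$p.value, 1 / 6)
  expect_equal(mw$method, "exact")
  # identical multisets: no evidence
  same <- mann_whitney_one_tailed(c(2, 3, 3, 5), c(2, 3, 3, 5))
  expect_gte(same$p.value, 0.4)
})

test_that("exact and enumeration routes agree with a brute-force permutation oracle", {
  set.seed(41)
  for (i in 1:20) {
    na <- sample(2:5, 1); nb <- sample(2:5, 1)
    a <- sample(1:6, na, replace = TRUE)  # ties likely
    b <- sample(1:6, nb, replace = TRUE)
    mw <- mann_whitney_one_tailed(a, b, alternative = "a_greater")
    expect_equal(mw$p.value, permutation_mw_p(a, b), tolerance = 1e-10)
  }
  # tie-free route cross-checked against stats::wilcox.test exact p
  for (i in 1:10) {
    x <- sample(1:10000, 15)  # distinct pooled values: no ties possible
    a <- x[1:8]; b <- x[9:15]
    mw <- mann_whitney_one_tailed(a, b)
    expect_equal(mw$p.value,
                 stats::wilcox.test(a, b, alternative = "greater",
                                    exact = TRUE)$p.value,
                 tolerance = 1e-10)
  }
})

test_that("the normal approximation stays close to the exact p on tie-free data", {
  set.seed(43)
  for (i in 1:10) {
    a <- stats::rnorm(9); b <- stats::rnorm(8, mean = 0.5)
    exact <- mann_whitney_one_tailed(a, b)$p.value
    normal <- longamp:::.mw_normal_p(longamp:::.u_statistic(a, b), a, b)
    expect_lt(abs(exact - normal), 0.01)
  }
})

test_that("tidy and glance return one-row summaries", {
  mw <- mann_whitney_one_tailed(c(3, 4, 5), c(1, 2))
  td <- tidy(mw)
  expect_equal(nrow(td), 1)
  expect_named(td, c("statistic", "p.value", "method", "n_a", "n_b",
                     "alternative"))
  expect_equal(glance(mw), td)
})

test_that("rank abundance applies the strict cutoff and deterministic tie order", {
  tab <- make_table(tibble::tibble(
    sample_id = "s1", otu_id = c("A", "B", "C"), count = c(100L, 60L, 50L)))
  ra <- rank_abundance(tab, min_total = 50)
  expect_equal(nrow(ra), 2)
  expect_setequal(ra$total, c(100L, 60L))
  tab2 <- make_table(tibble::tibble(
    sample_id = "s1", otu_id = c("zB", "aA"), count = c(70L, 70L)))
  ra2 <- rank_abundance(tab2, min_total = 50)
  expect_equal(ra2$total, c(70L, 70L))
  expect_equal(ra2$otu_id, sort(ra2$otu_id))
  empty <- make_table(tibble::tibble(sample_id = "s1", otu_id = "A",
                                     count = 5L))
  expect_equal(nrow(rank_abundance(empty, min_total = 50)), 0)
})

test_that("relative abundance pools by rank, routes small OTUs to Other and sums to one", {
  s1 <- random_dna(1, 1400); s2 <- random_dna(1, 1400); s3 <- random_dna(1, 1400)
  ref <- tibble::tibble(
    id = c("r1", "r2", "r3"), sequence = c(s1, s2, s3),
    taxonomy = c("k__B; f__Acetobacteraceae; g__Asaia; s__",
                 "k__B; f__Leuconostocaceae; g__Leuconostoc; s__",
                 "k__B; f__Enterobacteriaceae; g__Enterobacter; s__"))
  seqs <- tibble::tibble(
    sample_id = c(rep("sA", 100), rep("sB", 75), rep("sB", 25)),
    sequence = c(rep(s1, 100), rep(s2, 75), rep(s3, 25)))
  tab <- cluster_open_reference(seqs, ref, min_otu_size = 1)
  comp <- relative_abundance_by_taxon(tab, rank = "genus")
  expect_equal(comp$fraction[comp$sample_id == "sA"], 1)
  expect_equal(sort(comp$fraction[comp$sample_id == "sB"]), c(0.25, 0.75))
  sums <- tapply(comp$fraction, comp$sample_id, sum)
  expect_true(all(abs(sums - 1) < 1e-9))
  # an OTU with total 5 goes to "Other"
  seqs2 <- tibble::tibble(sample_id = "sA",
                          sequence = c(rep(s1, 50), rep(s2, 5)))
  comp2 <- relative_abundance_by_taxon(
    cluster_open_reference(seqs2, ref, min_otu_size = 1), rank = "genus",
    other_threshold = 5)
  expect_setequal(comp2$taxon, c("Asaia", "Other"))
})
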