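# The library simulator: templates, study composition, tagging, sequencing.

test_that("strain variants differ from their base template at exactly the recorded positions", {
  ts <- generate_reference_templates(3, 1, seed = 1)
  expect_equal(nrow(ts$templates), 6)
  for (i in seq_len(nrow(ts$variant_map))) {
    vm <- ts$variant_map[i, ]
    base_id <- ts$templates$base_taxon[ts$templates$taxon_id == vm$taxon_id]
    base <- ts$templates$sequence[ts$templates$taxon_id == base_id]
    var <- ts$templates$sequence[ts$templates$taxon_id == vm$taxon_id]
    # position-by-position comparison
    diffs <- which(strsplit(base, "")[[1]] != strsplit(var, "")[[1]])
    expect_equal(diffs, vm$position)
    expect_equal(substr(var, vm$position, vm$position), vm$base)
  }
})

test_that("explicit variant positions are honoured and the no-variant case is a single template", {
  ts <- generate_reference_templates(
    1, 2, seed = 7, variant_positions = list(c("93" = "G", "191" = "T")))
  base <- ts$templates$sequence[1]
  v1 <- ts$templates$sequence[2]
  expect_equal(which(strsplit(base, "")[[1]] != strsplit(v1, "")[[1]]), 93L)
  ts0 <- generate_reference_templates(1, 0, seed = 7)
  expect_equal(nrow(ts0$templates), 1)
})

test_that("template generation is deterministic and validates the length range", {
  a <- generate_reference_templates(2, 0, seed = 9)
  b <- generate_reference_templates(2, 0, seed = 9)
  expect_identical(a$templates$sequence, b$templates$sequence)
  expect_error(generate_reference_templates(1, 0, length_range = c(1200, 1400)),
               "length_range")
  lens <- nchar(a$templates$sequence)
  expect_true(all(lens >= 1350 & lens <= 1450))
})

test_that("composed samples honour group richness and share taxon pools within a unit", {
  ts <- generate_reference_templates(8, 0, seed = 2)
  design <- study_design(
    samples = tibble::tibble(
      sample_id = c("w1", "w2", "w3", "d1", "d2"),
      group = c("wild", "wild", "wild", "domesticated", "domesticated"),
      unit_id = c("f1", "f1", "f2", "c1", "c1")),
    richness_by_group = list(wild = 4L, domesticated = 2L),
    dominant_taxon = "taxon01", dominant_fraction = 1)
  prof <- compose_samples(design, ts, seed = 3)
  rich <- table(prof$sample_id)
  expect_true(all(rich[c("w1", "w2", "w3")] == 4))
  expect_true(all(rich[c("d1", "d2")] == 2))
  # same unit, same taxon set
  expect_setequal(prof$taxon_id[prof$sample_id == "w1"],
                  prof$taxon_id[prof$sample_id == "w2"])
  expect_true(all(vapply(split(prof$taxon_id, prof$sample_id),
                         function(x) "taxon01" %in% x, TRUE)))
  expect_error(compose_samples(
    study_design(design$samples, design$richness_by_group,
                 dominant_taxon = "nope"), ts, seed = 1), "dominant_taxon")
})

test_that("single-sample single-taxon design puts all molecules on that taxon", {
  ts <- generate_reference_templates(1, 0, seed = 4)
  design <- study_design(
    samples = tibble::tibble(sample_id = "s1", group = "wild", unit_id = "u1"),
    richness_by_group = list(wild = 1L),
    dominant_taxon = "taxon01", dominant_fraction = 1,
    molecules_per_sample = 12L)
  prof <- compose_samples(design, ts, seed = 1)
  expect_equal(nrow(prof), 1)
  expect_equal(prof$taxon_id, "taxon01")
  expect_equal(prof$n_molecules, 12L)
})

test_that("error-free amplification reproduces templates exactly inside the tagged construct", {
  x <- tiny_error_free_library()
  mol <- x$amplified$molecules
  primers <- default_primers()
  rebuilt <- paste0(mol$barcode5, mol$tag5, primers$forward, mol$core,
                    revcomp(primers$reverse), revcomp(mol$tag3),
                    revcomp(mol$barcode3))
  expect_identical(mol$sequence, rebuilt)
  tpl <- x$templates$templates
  expect_identical(mol$core, tpl$sequence[match(mol$taxon_id, tpl$taxon_id)])
  expect_equal(x$amplified$params$effective_pcr_error, 0)
})

test_that("forced tag collisions are injected and random 10-nt tags are effectively unique", {
  x <- tiny_error_free_library()
  amp <- tag_and_amplify(x$profiles, x$templates, x$barcodes,
                         per_base_error = 0, chimera_rate = 0,
                         collision_mode = "forced_k", forced_k = 1, seed = 8)
  key <- paste(amp$molecules$tag5, amp$molecules$tag3)
  shared <- names(which(table(key) == 2))
  expect_length(shared, 1)
  # the shared pair joins two distinct molecules
  expect_equal(sum(key == shared), 2)
  # random mode: 10 molecules, 10 distinct pairs
  key0 <- paste(x$amplified$molecules$tag5, x$amplified$molecules$tag3)
  expect_equal(length(unique(key0)), length(key0))
  expect_true(all(nchar(x$amplified$molecules$tag5) == 10))
  expect_error(tag_and_amplify(x$profiles, x$templates,
                               x$barcodes[-1, ], seed = 1), "barcode")
})

test_that("sequencing truth conserves reads and covers each molecule end to end", {
  x <- tiny_error_free_library()
  lib <- x$lib
  expect_setequal(lib$reads$read_id, lib$truth$read_id)
  expect_equal(anyDuplicated(lib$truth$read_id), 0L)
  # molecule counts in truth match the composed profiles
  per_mol <- lib$molecules[!lib$molecules$is_chimera, ]
  truth_counts <- dplyr::count(per_mol, sample_id, taxon_id)
  prof <- x$profiles[order(x$profiles$sample_id, x$profiles$taxon_id), ]
  truth_counts <- truth_counts[order(truth_counts$sample_id,
                                     truth_counts$taxon_id), ]
  expect_equal(truth_counts$n, prof$n_molecules)
  # interval union covers [0, molecule length)
  for (mid in unique(lib$truth$molecule_id)[1:5]) {
    tr <- lib$truth[lib$truth$molecule_id == mid, ]
    L <- nchar(lib$molecules$sequence[lib$molecules$molecule_id == mid])
    covered <- rep(FALSE, L)
    for (i in seq_len(nrow(tr))) {
      s <- tr$frag_start[i]; e <- tr$frag_end[i]
      # a pair covers the two read-length ends of its fragment
      covered[(s + 1):min(s + 250, e)] <- TRUE
      covered[max(s + 1, e - 249):e] <- TRUE
    }
    expect_true(all(covered))
  }
})

test_that("a 1:0 full-to-fragment ratio yields only end reads and reruns are byte-identical", {
  x <- tiny_error_free_library()
  lib1 <- fragment_and_sequence(x$amplified, full_to_fragment_ratio = c(1, 0),
                                seq_error_rate = 0, seed = 6)
  expect_true(all(lib1$truth$type == "full"))
  lib2 <- fragment_and_sequence(x$amplified, full_to_fragment_ratio = c(1, 0),
                                seq_error_rate = 0, seed = 6)
  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  write_library(lib1, d1)
  write_library(lib2, d2)
  for (f in c("reads_R1.fastq", "reads_R2.fastq")) {
    expect_identical(readLines(file.path(d1, f)), readLines(file.path(d2, f)))
  }
})

test_that("doubling molecules at fixed read count halves the mean reads per tag", {
  ts <- generate_reference_templates(1, 0, seed = 5)
  mean_tag_count <- function(n_mol, rpm, seed) {
    design <- study_design(
      tibble::tibble(sample_id = "s1", group = "wild", unit_id = "u1"),
      richness_by_group = list(wild = 1L), dominant_taxon = "taxon01",
      dominant_fraction = 1, molecules_per_sample = n_mol)
    prof <- compose_samples(design, ts, seed = seed)
    bc <- make_barcode_table("s1", seed = seed)
    amp <- tag_and_amplify(prof, ts, bc, per_base_error = 0,
                           chimera_rate = 0, seed = seed)
    lib <- fragment_and_sequence(amp, reads_per_molecule = rpm,
                                 seq_error_rate = 0, seed = seed)
    ann <- trim_and_annotate(lib, bc)
    tc <- bin_reads(ann)$tag_counts
    mean(tc$count)
  }
  ratios <- vapply(1:5, function(s) {
    mean_tag_count(20, 24, s) / mean_tag_count(10, 48, s)
  }, 0)
  expect_true(abs(mean(ratios) - 0.5) < 0.05)
})
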