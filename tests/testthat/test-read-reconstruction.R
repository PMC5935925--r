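# Demultiplexing, binning and per-bin assembly.

bc_tbl <- tibble::tibble(sample_id = "s1",
                         barcode5 = "ACGTACGT", barcode3 = "TTGGCCAA")
primers <- default_primers()

test_that("end reads are recognised, tags extracted and payloads stripped", {
  payload <- random_dna(1, 180)
  r1 <- end_read("ACGTACGT", "ACGTACGTAC", primers$forward, payload)
  reads <- tibble::tibble(read_id = "r1", r1_seq = r1,
                          r1_qual = strrep("I", nchar(r1)),
                          r2_seq = random_dna(1, 250),
                          r2_qual = strrep("I", 250))
  ann <- trim_and_annotate(reads, bc_tbl)
  a1 <- ann[ann$mate == "R1", ]
  expect_equal(a1$tag_end, "5prime")
  expect_equal(a1$tag, "ACGTACGTAC")
  expect_equal(a1$sample_id, "s1")
  expect_equal(a1$payload, payload)
  # mate without any prefix is internal, full sequence kept
  a2 <- ann[ann$mate == "R2", ]
  expect_equal(a2$tag_end, "internal")
  expect_equal(nchar(a2$payload), 250)
})

test_that("primer mismatches are tolerated up to the limit; unknown barcodes go to the unassigned pool", {
  pf_mut <- primers$forward
  substr(pf_mut, 5, 5) <- ifelse(substr(pf_mut, 5, 5) == "A", "G", "A")
  r1 <- end_read("ACGTACGT", "AAAAAAAAAA", pf_mut, random_dna(1, 180))
  reads <- tibble::tibble(read_id = "r1", r1_seq = r1,
                          r1_qual = strrep("I", nchar(r1)),
                          r2_seq = random_dna(1, 250), r2_qual = strrep("I", 250))
  ann <- trim_and_annotate(reads, bc_tbl, max_primer_mismatch = 2)
  expect_equal(ann$tag_end[ann$mate == "R1"], "5prime")
  # same read with an unknown barcode: unassigned, not silently internal
  r1b <- end_read("GGGGGGGG", "AAAAAAAAAA", primers$forward, random_dna(1, 180))
  reads$r1_seq <- r1b
  ann2 <- trim_and_annotate(reads, bc_tbl)
  expect_equal(ann2$tag_end[ann2$mate == "R1"], "unassigned")
})

test_that("low-quality 3' tails are trimmed by the sliding window", {
  seqs <- random_dna(1, 100)
  qual <- paste0(strrep("I", 80), strrep("#", 20))  # phred 40 then phred 2
  reads <- tibble::tibble(read_id = "r", r1_seq = seqs, r1_qual = qual,
                          r2_seq = seqs, r2_qual = strrep("I", 100))
  ann <- trim_and_annotate(reads, bc_tbl, quality_floor = 15)
  # the cut lands at the start of the first window whose mean drops below
  # the floor: window 80..83 averages (40+2+2+2)/4 < 15, so 79 bases remain
  expect_equal(nchar(ann$payload[ann$mate == "R1"]), 79)
  expect_equal(nchar(ann$payload[ann$mate == "R2"]), 100)
})

make_pairs <- function(n, tag5, tag3, core, bc = bc_tbl) {
  p <- default_primers()
  m <- paste0(bc$barcode5, tag5, p$forward, core,
              revcomp(p$reverse), revcomp(tag3), revcomp(bc$barcode3))
  tibble::tibble(
    read_id = sprintf("p%03d", seq_len(n)),
    r1_seq = substr(m, 1, 250), r1_qual = strrep("I", 250),
    r2_seq = substr(revcomp(m), 1, 250), r2_qual = strrep("I", 250))
}

test_that("read pairs sharing a tag pair form one bin with the right count", {
  core <- random_dna(1, 1400)
  reads <- make_pairs(10, "AAAACCCCGG", "TTTTGGGGAA", core)
  ann <- trim_and_annotate(reads, bc_tbl)
  bins <- bin_reads(ann)
  expect_equal(nrow(bins$bins), 1)
  expect_equal(bins$bins$count, 10L)
  expect_equal(bins$bins$tag5, "AAAACCCCGG")
  expect_equal(bins$bins$tag3, "TTTTGGGGAA")
  # conservation: every end read is in the bin
  expect_equal(nrow(bins$bins$reads[[1]]), 20)
})

test_that("a Hamming-1 singleton tag is absorbed when merging is enabled", {
  core <- random_dna(1, 1400)
  good <- make_pairs(50, "AAAACCCCGG", "TTTTGGGGAA", core)
  stray <- make_pairs(1, "AAAACCCCGT", "TTTTGGGGAA", core)
  stray$read_id <- "stray1"
  ann <- trim_and_annotate(dplyr::bind_rows(good, stray), bc_tbl)
  merged <- bin_reads(ann, tag_merge_distance = 1)
  expect_equal(nrow(merged$bins), 1)
  expect_equal(merged$bins$count, 51L)
  # with exact matching the stray pair founds a count-1 error bin instead
  exact <- bin_reads(ann, tag_merge_distance = 0)
  expect_equal(nrow(exact$bins), 1)
  expect_equal(exact$bins$count, 50L)
  expect_equal(nrow(exact$error_bins), 1)
  # raw tag histogram is computed before merging
  expect_true(any(merged$tag_counts$count == 1))
})

test_that("greedy assembly of error-free tiling reads reproduces the template", {
  tpl <- random_dna(1, 1400)
  res <- assemble_bin(tiling_reads(tpl), min_overlap = 50,
                      kmer_correction = FALSE)
  expect_equal(res$scaffolds, tpl)
  expect_true(res$complete)
  expect_equal(res$reject_reason, "none")
})

test_that("greedy assembly agrees with the exhaustive ordering oracle on small error-free bins", {
  set.seed(31)
  for (i in 1:5) {
    tpl <- random_dna(1, 320)
    reads <- tiling_reads(tpl, read_len = 100, step = 55)
    expect_lte(length(reads), 7)
    oracle <- brute_force_assemble(reads, min_overlap = 10)
    got <- assemble_bin(reads, min_overlap = 10, kmer_correction = FALSE,
                        kmer_size = 9)
    expect_equal(got$scaffolds[1], oracle)
    expect_equal(got$scaffolds[1], tpl)
  }
})

test_that("bins mixing two templates split into scaffolds and fail completeness", {
  a <- random_dna(1, 1400)
  b <- random_dna(1, 1380)
  res <- assemble_bin(c(tiling_reads(a), tiling_reads(b)), min_overlap = 50,
                      kmer_correction = FALSE)
  expect_false(res$complete)
  expect_equal(res$reject_reason, "multi_scaffold")
  expect_gte(length(res$scaffolds), 2)
  # single-read bins are rejected outright
  one <- assemble_bin(substr(a, 1, 250))
  expect_equal(one$reject_reason, "insufficient_reads")
})

test_that("k-mer correction repairs an isolated substitution", {
  # step 40 gives every mid-template k-mer window at least 4 covering reads,
  # so the corrected k-mers reach the trusted count of 3 with one read in error
  set.seed(77)
  tpl <- random_dna(1, 600)
  reads <- tiling_reads(tpl, read_len = 200, step = 40)
  bad <- reads[4]
  substr(bad, 100, 100) <- ifelse(substr(bad, 100, 100) == "A", "C", "A")
  fixed <- correct_reads_kmer(c(reads[-4], bad), k = 15)
  expect_equal(sort(fixed), sort(reads))
})

test_that("the completeness filter applies the inclusive 1300-1500 nt single-scaffold rule", {
  fake <- tibble::tibble(
    key_id = c("k1", "k2", "k3"), sample_id = "s1", tag5 = "t", tag3 = "t",
    n_reads = 10L,
    scaffolds = list("x", c("x", "y"), "z"),
    n_scaffolds = c(1L, 2L, 1L),
    scaffold0_length = c(1400L, 1400L, 1299L),
    complete = NA, reject_reason = NA_character_)
  out <- filter_complete(fake)
  expect_equal(out$sequences$key_id, "k1")
  expect_equal(sort(names(out$report$reject_counts)),
               c("length_out_of_range", "multi_scaffold"))
  expect_equal(out$report$n_complete, 1L)
})

test_that("map-back fraction is 1 for clean reads and about half for a 50/50 chimera mixture", {
  tpl <- random_dna(1, 1400)
  clean <- tiling_reads(tpl, read_len = 200, step = 100)
  expect_equal(map_back_fraction(clean, tpl), 1)
  alien <- tiling_reads(random_dna(1, 1400), read_len = 200, step = 100)
  n <- min(length(clean), length(alien))
  frac <- map_back_fraction(c(clean[1:n], alien[1:n]), tpl)
  expect_lt(abs(frac - 0.5), 0.05)
  expect_warning(out <- map_back_fraction(clean, character(0)), "empty")
  expect_equal(out, 0)
})

test_that("residual primer motifs are trimmed, tolerating mismatches", {
  p <- default_primers()
  body <- random_dna(1, 1340)
  expect_equal(trim_residual_primers(paste0(p$forward, body)), body)
  expect_equal(trim_residual_primers(body), body)
  pf <- gsub("M", "A", p$forward)
  substr(pf, 3, 3) <- ifelse(substr(pf, 3, 3) == "A", "T", "A")
  expect_equal(trim_residual_primers(paste0(pf, body), max_mismatch = 2), body)
  # suffix: reverse-complement of the reverse primer
  expect_equal(trim_residual_primers(paste0(body, revcomp(p$reverse))), body)
})
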