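# End-to-end orchestration: simulate -> reconstruct -> cluster -> diversity
# -> haplotypes, with a validated configuration, a run manifest and
# truth-based evaluation.

#' Default pipeline configuration
#'
#' Every knob of every stage, with the defaults used throughout the package.
#' The structure can be written to / read from YAML.
#'
#' @return nested named list
#' @export
default_config <- function() {
  list(
    seed = 1,
    community = list(
      n_base_taxa = 5, n_variants_per_taxon = 0,
      length_range = c(1350, 1450),
      n_wild_units = 2, larvae_per_wild_unit = 3,
      n_dom_units = 2, larvae_per_dom_unit = 3,
      dominant_fraction = 55 / 56,
      molecules_per_sample = c(20, 30),
      include_chloroplast = FALSE
    ),
    library = list(
      tag_length = 10, pcr_cycles = 35, per_base_error = 1e-5,
      chimera_rate = 0.01, collision_mode = "random", forced_k = 0,
      reads_per_molecule = 40, full_to_fragment_ratio = c(1, 7),
      fragment_length_range = c(400, 1000), read_length = 250,
      seq_error_rate = 0.001
    ),
    reconstruction = list(
      quality_floor = 15, max_primer_mismatch = 2,
      tag_merge_distance = 0, min_tag_count = 2,
      min_overlap = 20, max_overlap_mismatch_rate = 0.05,
      kmer_correction = TRUE, kmer_size = 15,
      length_range = c(1300, 1500)
    ),
    clustering = list(
      threshold = 0.99, min_otu_size = 2, max_length_overhang = 4,
      remove_label = "Streptophyta"
    ),
    diversity = list(
      rarefaction_depths = c(10, 260, 10), rarefaction_iterations = 1000,
      alpha = 0.01
    ),
    haplotypes = list(
      top_n = 5, v4_max_mismatch = 2
    )
  )
}

#' Validate a pipeline configuration against the schema
#'
#' Unknown keys (at either level) are rejected; missing keys are filled with
#' defaults.
#'
#' @param config nested list (e.g. from [yaml::read_yaml()])
#' @return completed configuration
#' @export
validate_config <- function(config) {
  ref <- default_config()
  bad <- setdiff(names(config), names(ref))
  if (length(bad)) stop("unknown config section(s): ", paste(bad, collapse = ", "))
  for (sec in names(config)) {
    if (sec == "seed") next
    bad <- setdiff(names(config[[sec]]), names(ref[[sec]]))
    if (length(bad)) {
      stop("unknown key(s) in config section '", sec, "': ",
           paste(bad, collapse = ", "))
    }
    ref[[sec]][names(config[[sec]])] <- config[[sec]]
  }
  if (!is.null(config$seed)) ref$seed <- config$seed
  ref
}

#' Read and validate a pipeline configuration from a YAML file
#'
#' @param path YAML file with any subset of the keys in [default_config()]
#' @return completed, validated configuration
#' @export
read_config <- function(path) {
  validate_config(yaml::read_yaml(path))
}

#' Run the full pipeline on a configuration
#'
#' Simulates a dual-tagged library, reconstructs near full-length sequences,
#' clusters OTUs open-reference against the simulated template set, computes
#' diversity statistics and the focal-OTU haplotype comparison, and returns
#' everything with a manifest (seed, parameter hash, per-stage counts).
#'
#' @param config nested list, validated against [default_config()]
#' @param outdir optional directory; when given, FASTQ/truth/TSV/FASTA
#'   outputs are written there
#' @return a `longamp_run` list: sim, annotated, bins, assemblies, complete,
#'   table (pooled, taxon-filtered `otu_tbl`), stats, mw (group test),
#'   haplotypes, manifest
#' @export
run_all <- function(config = default_config(), outdir = NULL) {
  config <- validate_config(config)
  seed <- config$seed
  cc <- config$community
  templates <- generate_reference_templates(
    n_base_taxa = cc$n_base_taxa,
    n_variants_per_taxon = cc$n_variants_per_taxon,
    length_range = cc$length_range, seed = seed,
    include_chloroplast = cc$include_chloroplast)
  design <- default_study_design(
    n_wild_units = cc$n_wild_units,
    larvae_per_wild_unit = cc$larvae_per_wild_unit,
    n_dom_units = cc$n_dom_units,
    larvae_per_dom_unit = cc$larvae_per_dom_unit,
    dominant_fraction = cc$dominant_fraction,
    molecules_per_sample = seq(cc$molecules_per_sample[1],
                               cc$molecules_per_sample[length(cc$molecules_per_sample)]))
  profiles <- compose_samples(design, templates, seed = seed)
  barcodes <- make_barcode_table(unique(design$samples$sample_id), seed = seed)
  lc <- config$library
  amplified <- tag_and_amplify(
    profiles, templates, barcodes,
    tag_length = lc$tag_length, pcr_cycles = lc$pcr_cycles,
    per_base_error = lc$per_base_error, chimera_rate = lc$chimera_rate,
    collision_mode = lc$collision_mode, forced_k = lc$forced_k, seed = seed)
  sim <- fragment_and_sequence(
    amplified, reads_per_molecule = lc$reads_per_molecule,
    full_to_fragment_ratio = lc$full_to_fragment_ratio,
    fragment_length_range = lc$fragment_length_range,
    read_length = lc$read_length, seq_error_rate = lc$seq_error_rate,
    seed = seed)
  rc <- config$reconstruction
  annotated <- trim_and_annotate(
    sim, barcodes, quality_floor = rc$quality_floor,
    max_primer_mismatch = rc$max_primer_mismatch,
    tag_length = lc$tag_length)
  bins <- bin_reads(annotated, tag_merge_distance = rc$tag_merge_distance,
                    min_tag_count = rc$min_tag_count,
                    kmer_size = rc$kmer_size)
  assemblies <- assemble_bins(
    bins, min_overlap = rc$min_overlap,
    max_overlap_mismatch_rate = rc$max_overlap_mismatch_rate,
    kmer_correction = rc$kmer_correction, kmer_size = rc$kmer_size,
    length_range = rc$length_range)
  complete <- filter_complete(assemblies, length_range = rc$length_range)
  complete$sequences <- trim_residual_primers(complete$sequences)
  cl <- config$clustering
  # reference databases do not contain the community's novel strains: only
  # base templates are supplied; strain variants must cluster into them
  tpl <- templates$templates[!templates$templates$is_variant, ]
  reference <- tibble::tibble(id = tpl$taxon_id, sequence = tpl$sequence,
                              taxonomy = tpl$taxonomy)
  seqs <- complete$sequences
  seqs$seq_id <- seqs$key_id
  table <- cluster_open_reference(seqs, reference,
                                  threshold = cl$threshold,
                                  min_otu_size = cl$min_otu_size, seed = seed)
  n_before_removal <- sum(table$counts$count)
  table <- pool_equivalent_otus(table, cl$max_length_overhang)
  table <- remove_taxon(table, cl$remove_label)
  group_map <- design$samples[, c("sample_id", "group")]
  stats <- sample_stats(table, group_map)
  wild <- stats$n_otus[stats$group == "wild"]
  dom <- stats$n_otus[stats$group == "domesticated"]
  mw <- if (length(wild) && length(dom)) {
    mann_whitney_one_tailed(wild, dom, alternative = "a_greater")
  } else NULL
  haplotypes <- NULL
  if (nrow(table$otus) > 0) {
    members <- extract_otu_members(table, seqs)
    full_h <- cluster_unique(members, region = "full_length")
    v4 <- extract_v4(members, max_mismatch = config$haplotypes$v4_max_mismatch)
    v4m <- v4[v4$extractable, ]
    v4m$sequence <- v4m$v4
    v4_h <- if (nrow(v4m)) cluster_unique(v4m, region = "v4") else NULL
    haplotypes <- list(
      focal_otu_id = members$otu_id[1],
      full = full_h, v4 = v4_h,
      variant_table = variant_table(full_h, top_n = config$haplotypes$top_n),
      resolution = if (!is.null(v4_h)) compare_resolution(full_h, v4_h))
  }
  manifest <- list(
    package_version = as.character(utils::packageVersion("longamp")),
    seed = seed,
    parameter_hash = rlang::hash(config),
    counts = list(
      molecules = nrow(sim$molecules),
      chimeras = sum(sim$molecules$is_chimera),
      read_pairs = nrow(sim$reads),
      bins = nrow(bins$bins),
      error_tag_bins = nrow(bins$error_bins),
      complete_assemblies = nrow(complete$sequences),
      sequences_clustered = n_before_removal,
      sequences_after_taxon_removal = sum(table$counts$count),
      otus = nrow(table$otus)
    )
  )
  run <- list(config = config, templates = templates, design = design,
              sim = sim, annotated = annotated, bins = bins,
              assemblies = assemblies, complete = complete, table = table,
              stats = stats, mw = mw, haplotypes = haplotypes,
              manifest = manifest)
  class(run) <- "longamp_run"
  if (!is.null(outdir)) .write_run(run, outdir)
  run
}

#' @export
print.longamp_run <- function(x, ...) {
  cts <- x$manifest$counts
  cat("<longamp_run> seed ", x$manifest$seed, "\n",
      "  molecules: ", cts$molecules, " (", cts$chimeras, " chimeric), ",
      cts$read_pairs, " read pairs\n",
      "  bins: ", cts$bins, "; complete assemblies: ",
      cts$complete_assemblies, "\n",
      "  OTUs: ", cts$otus, " over ",
      cts$sequences_after_taxon_removal, " sequences\n", sep = "")
  if (!is.null(x$mw)) {
    cat("  wild vs domesticated richness: p = ",
        format(x$mw$p.value, digits = 3), " (", x$mw$method, ")\n", sep = "")
  }
  invisible(x)
}

.write_run <- function(run, outdir) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  write_library(run$sim, outdir)
  seqs <- run$complete$sequences
  if (nrow(seqs)) {
    write_fasta(tibble::tibble(
      id = sprintf("%s sample=%s tag=%s-%s", seqs$key_id, seqs$sample_id,
                   seqs$tag5, seqs$tag3),
      sequence = seqs$sequence), file.path(outdir, "complete_sequences.fasta"))
  }
  utils::write.table(as_tibble(run$table), file.path(outdir, "otu_table.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(run$stats, file.path(outdir, "sample_stats.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(run$bins$tag_counts, file.path(outdir, "tag_counts.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  jsonlite::write_json(run$manifest, file.path(outdir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(outdir)
}

#' Evaluate a run against the simulator's truth
#'
#' Classifies every non-chimeric simulated molecule as exactly recovered (a
#' complete assembly for its tag key equals its template core), recovered
#' with errors, or missed; reports the chimera exclusion rate and per-sample
#' Pearson correlation between truth molecule counts and OTU counts.
#'
#' @param run a `longamp_run` (or a list with sim, complete, table)
#' @return an `evaluation_report` list
#' @export
evaluate_against_truth <- function(run) {
  mol <- run$sim$molecules
  seqs <- run$complete$sequences
  key <- paste(seqs$tag5, seqs$tag3)
  recovered <- stats::setNames(seqs$sequence, key)
  tag_key <- paste(mol$tag5, mol$tag3)
  collided <- tag_key %in% tag_key[duplicated(tag_key)]
  real <- !mol$is_chimera
  eligible <- real & !collided
  assembled <- recovered[tag_key]
  category <- ifelse(!real, "chimera",
              ifelse(is.na(assembled), "missed",
              ifelse(assembled == mol$core, "exact", "with_errors")))
  if (sum(eligible) + sum(!real) + sum(real & collided) != nrow(mol)) {
    stop("molecule categories do not partition the truth set")
  }
  chim <- mol$is_chimera
  chimera_excluded <- if (any(chim)) {
    mean(is.na(assembled[chim]) | assembled[chim] != mol$core[chim])
  } else NA_real_
  # per-sample truth vs OTU-count correlation, via reference-named OTUs
  prof <- run$sim$profiles
  corr <- NA_real_
  if (!is.null(run$table)) {
    base_of <- stats::setNames(run$templates$templates$base_taxon,
                               run$templates$templates$taxon_id)
    truth_counts <- prof
    truth_counts$base <- base_of[truth_counts$taxon_id]
    truth_counts <- truth_counts |>
      dplyr::summarise(n_true = sum(.data$n_molecules),
                       .by = c("sample_id", "base"))
    obs <- run$table$counts
    obs$base <- base_of[obs$otu_id]
    obs <- obs[!is.na(obs$base), ] |>
      dplyr::summarise(n_obs = sum(.data$count), .by = c("sample_id", "base"))
    j <- dplyr::full_join(truth_counts, obs, by = c("sample_id", "base")) |>
      tidyr::replace_na(list(n_true = 0, n_obs = 0))
    if (nrow(j) > 2 && stats::sd(j$n_true) > 0 && stats::sd(j$n_obs) > 0) {
      corr <- stats::cor(j$n_true, j$n_obs)
    }
  }
  structure(list(
    n_molecules = nrow(mol),
    n_eligible = sum(eligible),
    categories = table(category),
    exact_recovery = mean(category[eligible] == "exact"),
    chimera_exclusion_rate = chimera_excluded,
    profile_correlation = corr
  ), class = "evaluation_report")
}

#' @export
print.evaluation_report <- function(x, ...) {
  cat("<evaluation_report> ", x$n_molecules, " molecules (",
      x$n_eligible, " eligible)\n  exact recovery: ",
      format(100 * x$exact_recovery, digits = 4), "%",
      if (!is.na(x$chimera_exclusion_rate))
        paste0("; chimera exclusion: ",
               format(100 * x$chimera_exclusion_rate, digits = 4), "%"),
      "\n", sep = "")
  invisible(x)
}

#' Load the packaged per-larva sequence and OTU count fixture
#'
#' Transcription of the study's per-sample table: 58 larval midgut samples
#' (35 wild from two peach-growing locations, 23 domesticated from three
#' colonies) plus blank and positive controls, each with its count of near
#' full-length (>1300 nt) sequences and 99%-identity OTUs (chloroplast OTUs
#' excluded).
#'
#' @return tibble with sample_id, group ("wild", "domesticated", "control"),
#'   location, unit_id, n_sequences, n_otus
#' @export
load_table2_fixture <- function() {
  path <- system.file("extdata", "table2_fixture.tsv", package = "longamp",
                      mustWork = TRUE)
  utils::read.delim(path, stringsAsFactors = FALSE) |>
    tibble::as_tibble()
}

#' Wild vs domesticated richness test on the packaged fixture
#'
#' @param include_zero_sequence_larvae keep the two larvae that yielded no
#'   sequences (their OTU count of 0 is real data); default TRUE
#' @return an `mw_test` (one-tailed, wild greater)
#' @export
fixture_richness_test <- function(include_zero_sequence_larvae = TRUE) {
  tab <- load_table2_fixture()
  larvae <- tab[tab$group %in% c("wild", "domesticated"), ]
  if (!include_zero_sequence_larvae) {
    larvae <- larvae[larvae$n_sequences > 0, ]
  }
  mann_whitney_one_tailed(
    larvae$n_otus[larvae$group == "wild"],
    larvae$n_otus[larvae$group == "domesticated"],
    alternative = "a_greater")
}
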