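# Ground-truthed simulation of dual-tagged near full-length 16S libraries.
#
# The generator emulates the physical library: every template molecule gets a
# sample barcode pair, a random 10-nt tag on each end and the 27F/1391R primer
# pair; libraries are sequenced as a mix of full-length amplicons (read pairs
# covering both tagged ends) and tagmented fragments that retain one tagged
# end, at a 1:7 molar ratio. PCR substitution errors, chimeric fusions and
# (optionally forced) tag collisions are recorded in a truth table.

#' Default primer motifs
#'
#' 27F / 1391R delimit the near full-length amplicon; 515F / 806R delimit the
#' V4 sub-region used by the haplotype comparison.
#' @export
default_primers <- function() {
  list(
    forward = "AGAGTTTGATCMTGGCTCAG",   # 27F
    reverse = "GACGGGCGGTGTGTRCA",      # 1391R
    v4_forward = "GTGYCAGCMGCCGCGGTAA", # 515F
    v4_reverse = "GGACTACNVGGGTWTCTAAT" # 806R
  )
}

# Families cycled over when labelling base taxa; the first is the dominant
# acetic acid bacterium analog present in nearly every sample.
.taxon_pool <- tibble::tibble(
  genus  = c("Asaia", "Enterobacter", "Leuconostoc", "Halomonas",
             "Pseudomonas", "Acetobacter", "Klebsiella", "Gluconobacter",
             "Pantoea", "Providencia"),
  family = c("Acetobacteraceae", "Enterobacteriaceae", "Leuconostocaceae",
             "Halomonadaceae", "Pseudomonadaceae", "Acetobacteraceae",
             "Enterobacteriaceae", "Acetobacteraceae", "Enterobacteriaceae",
             "Enterobacteriaceae"),
  class  = c("Alphaproteobacteria", "Gammaproteobacteria", "Bacilli",
             "Gammaproteobacteria", "Gammaproteobacteria",
             "Alphaproteobacteria", "Gammaproteobacteria",
             "Alphaproteobacteria", "Gammaproteobacteria",
             "Gammaproteobacteria")
)

.taxonomy_label <- function(class, family, genus) {
  phylum <- ifelse(class == "Bacilli", "Firmicutes", "Proteobacteria")
  order <- paste0(family, "les")
  paste0("k__Bacteria; p__", phylum, "; c__", class, "; o__", order,
         "; f__", family, "; g__", genus, "; s__")
}

#' Generate a reference template set with strain variants
#'
#' Builds `n_base_taxa` random near full-length 16S analog templates, each
#' carrying concrete instances of the V4 primer motifs at a realistic interior
#' position (so the V4 sub-region is extractable), plus single-nucleotide
#' strain variants of each base template at fixed positions.
#'
#' @param n_base_taxa number of base taxa (>= 1)
#' @param n_variants_per_taxon single-substitution strain variants per taxon
#' @param length_range template length range, within \[1300, 1500\]
#' @param seed integer seed; the template set is deterministic given it
#' @param variant_positions optional list (per base taxon) of named character
#'   vectors `c("93" = "G", ...)` fixing variant positions and bases; when
#'   `NULL` positions and bases are drawn at random
#' @param include_chloroplast add one extra template labelled as plant
#'   chloroplast ("Streptophyta"), useful for testing taxon removal
#' @param primers primer motif list, see [default_primers()]
#' @return a `template_set`: list with `templates` (tibble: taxon_id, sequence,
#'   taxonomy, base_taxon, is_variant) and `variant_map` (tibble: taxon_id,
#'   position, base)
#' @export
generate_reference_templates <- function(n_base_taxa,
                                         n_variants_per_taxon = 0,
                                         length_range = c(1350, 1450),
                                         seed = 1,
                                         variant_positions = NULL,
                                         include_chloroplast = FALSE,
                                         primers = default_primers()) {
  stopifnot(n_base_taxa >= 1)
  if (length_range[1] < 1300 || length_range[2] > 1500 ||
      length_range[1] > length_range[2]) {
    stop("length_range must lie within [1300, 1500]")
  }
  withr::with_seed(derive_seed(seed, "templates"), {
    n_extra <- if (include_chloroplast) 1L else 0L
    pool <- .taxon_pool[((seq_len(n_base_taxa) - 1L) %% nrow(.taxon_pool)) + 1L, ]
    templates <- vector("list", n_base_taxa + n_extra)
    variant_rows <- list()
    for (i in seq_len(n_base_taxa)) {
      len <- sample(seq(length_range[1], length_range[2]), 1L)
      fwd_site <- instantiate_motif(primers$v4_forward)
      rev_site <- revcomp(instantiate_motif(primers$v4_reverse))
      v4_len <- 253L
      pre_len <- 500L
      tail_len <- len - pre_len - nchar(fwd_site) - v4_len - nchar(rev_site)
      base_seq <- paste0(
        random_dna(1, pre_len), fwd_site, random_dna(1, v4_len),
        rev_site, random_dna(1, tail_len)
      )
      if (!is.null(variant_positions) && length(variant_positions) >= i) {
        # requested variant bases must differ from the base template
        for (v in seq_along(variant_positions[[i]])) {
          pos <- as.integer(names(variant_positions[[i]])[v])
          alt <- unname(variant_positions[[i]][v])
          if (substr(base_seq, pos, pos) == alt) {
            substr(base_seq, pos, pos) <-
              setdiff(c("A", "C", "G", "T"), alt)[1]
          }
        }
      }
      tax_id <- sprintf("taxon%02d", i)
      taxonomy <- .taxonomy_label(pool$class[i], pool$family[i],
                                  paste0(pool$genus[i], "_", i))
      rows <- tibble::tibble(
        taxon_id = tax_id, sequence = base_seq, taxonomy = taxonomy,
        base_taxon = tax_id, is_variant = FALSE
      )
      if (n_variants_per_taxon > 0) {
        for (v in seq_len(n_variants_per_taxon)) {
          if (!is.null(variant_positions)) {
            spec_v <- variant_positions[[i]]
            pos <- as.integer(names(spec_v)[v])
            alt <- unname(spec_v[v])
          } else {
            pos <- sample.int(nchar(base_seq), 1L)
            alt <- sample(setdiff(c("A", "C", "G", "T"),
                                  substr(base_seq, pos, pos)), 1L)
          }
          if (pos > nchar(base_seq)) stop("variant position beyond template length")
          var_seq <- base_seq
          substr(var_seq, pos, pos) <- alt
          vid <- sprintf("%s.v%d", tax_id, v)
          rows <- dplyr::bind_rows(rows, tibble::tibble(
            taxon_id = vid, sequence = var_seq, taxonomy = taxonomy,
            base_taxon = tax_id, is_variant = TRUE
          ))
          variant_rows[[length(variant_rows) + 1L]] <-
            tibble::tibble(taxon_id = vid, position = pos, base = alt)
        }
      }
      templates[[i]] <- rows
    }
    if (include_chloroplast) {
      len <- sample(seq(length_range[1], length_range[2]), 1L)
      templates[[n_base_taxa + 1L]] <- tibble::tibble(
        taxon_id = "chloroplast",
        sequence = random_dna(1, len),
        taxonomy = paste0("k__Bacteria; p__Cyanobacteria; c__Chloroplast; ",
                          "o__Streptophyta; f__; g__; s__"),
        base_taxon = "chloroplast", is_variant = FALSE
      )
    }
    out <- list(
      templates = dplyr::bind_rows(templates),
      variant_map = if (length(variant_rows)) dplyr::bind_rows(variant_rows)
        else tibble::tibble(taxon_id = character(), position = integer(),
                            base = character())
    )
    class(out) <- "template_set"
    out
  })
}

#' @export
print.template_set <- function(x, ...) {
  cat("<template_set> ", nrow(x$templates), " templates (",
      sum(!x$templates$is_variant), " base taxa, ",
      sum(x$templates$is_variant), " strain variants)\n", sep = "")
  invisible(x)
}

#' Describe a study design
#'
#' @param samples tibble with sample_id, group ("wild"/"domesticated"), and
#'   unit_id (fruit or colony); samples sharing a unit draw the same taxon set
#' @param richness_by_group named list of integer vectors to draw per-unit
#'   taxon richness from, one entry per group
#' @param dominant_taxon taxon_id expected in nearly every sample
#' @param dominant_fraction fraction of samples carrying the dominant taxon
#' @param molecules_per_sample integer vector to draw per-sample template
#'   molecule counts from
#' @return a `study_design` list
#' @export
study_design <- function(samples, richness_by_group,
                         dominant_taxon = "taxon01",
                         dominant_fraction = 55 / 56,
                         molecules_per_sample = 20:30) {
  stopifnot(all(c("sample_id", "group", "unit_id") %in% names(samples)),
            nrow(samples) >= 1)
  structure(list(
    samples = tibble::as_tibble(samples),
    richness_by_group = richness_by_group,
    dominant_taxon = dominant_taxon,
    dominant_fraction = dominant_fraction,
    molecules_per_sample = molecules_per_sample
  ), class = "study_design")
}

#' Default study design: fruit-structured wild units plus colonies
#'
#' Mirrors the study structure at desk scale: wild larvae sampled per fruit
#' (shared within-fruit taxon pools, median richness 4) and domesticated
#' larvae per colony (median richness 2).
#'
#' @param n_wild_units,larvae_per_wild_unit wild fruit count and larvae each
#' @param n_dom_units,larvae_per_dom_unit colony count and larvae each
#' @inheritParams study_design
#' @export
default_study_design <- function(n_wild_units = 2, larvae_per_wild_unit = 3,
                                 n_dom_units = 2, larvae_per_dom_unit = 3,
                                 dominant_taxon = "taxon01",
                                 dominant_fraction = 55 / 56,
                                 molecules_per_sample = 20:30) {
  wild <- tidyr::expand_grid(u = seq_len(n_wild_units),
                             l = seq_len(larvae_per_wild_unit))
  dom <- tidyr::expand_grid(u = seq_len(n_dom_units),
                            l = seq_len(larvae_per_dom_unit))
  samples <- dplyr::bind_rows(
    tibble::tibble(sample_id = sprintf("W.P.%s%d", LETTERS[wild$u], wild$l),
                   group = "wild", unit_id = sprintf("fruit_%s", LETTERS[wild$u])),
    tibble::tibble(sample_id = sprintf("D.Col.%d.%d", dom$u, dom$l),
                   group = "domesticated", unit_id = sprintf("colony_%d", dom$u))
  )
  study_design(samples,
               richness_by_group = list(wild = 3:5, domesticated = 1:3),
               dominant_taxon = dominant_taxon,
               dominant_fraction = dominant_fraction,
               molecules_per_sample = molecules_per_sample)
}

#' Realize per-sample taxon profiles from a study design
#'
#' Draws a shared taxon pool per unit (larvae in one fruit share profiles),
#' gives the dominant taxon the configured prevalence across samples, and
#' allocates each sample's template molecules across its taxa (the dominant
#' taxon receives the largest share).
#'
#' @param design a [study_design()]
#' @param templates a [generate_reference_templates()] result
#' @param seed integer seed
#' @return tibble with sample_id, group, unit_id, taxon_id, n_molecules
#' @export
compose_samples <- function(design, templates, seed = 1) {
  stopifnot(inherits(design, "study_design"))
  taxa <- templates$templates$taxon_id
  if (!design$dominant_taxon %in% taxa) {
    stop("dominant_taxon '", design$dominant_taxon, "' not in template set")
  }
  others <- setdiff(taxa, c(design$dominant_taxon, "chloroplast"))
  withr::with_seed(derive_seed(seed, "compose"), {
    units <- split(design$samples, design$samples$unit_id)
    rows <- lapply(units, function(su) {
      group <- su$group[1]
      rich_pool <- design$richness_by_group[[group]]
      if (is.null(rich_pool)) stop("no richness distribution for group ", group)
      r <- if (length(rich_pool) == 1L) rich_pool else sample(rich_pool, 1L)
      r <- max(1L, min(r, length(others) + 1L))
      pool_taxa <- c(design$dominant_taxon,
                     if (r > 1L) sample(others, r - 1L))
      dplyr::bind_rows(lapply(seq_len(nrow(su)), function(j) {
        taxon_set <- pool_taxa
        if (stats::runif(1) > design$dominant_fraction && length(taxon_set) > 1L) {
          taxon_set <- setdiff(taxon_set, design$dominant_taxon)
        }
        mps <- design$molecules_per_sample
        m <- if (length(mps) == 1L) mps else sample(mps, 1L)
        m <- max(m, length(taxon_set))
        w <- rep(1, length(taxon_set))
        w[taxon_set == design$dominant_taxon] <- 4
        counts <- as.vector(stats::rmultinom(1, m - length(taxon_set),
                                             w / sum(w))) + 1L
        tibble::tibble(sample_id = su$sample_id[j], group = group,
                       unit_id = su$unit_id[j], taxon_id = taxon_set,
                       n_molecules = counts)
      }))
    })
    dplyr::bind_rows(rows)
  })
}

#' Greedy barcode table with pairwise Hamming distance >= 3
#'
#' @param sample_ids sample identifiers
#' @param length barcode length in nt
#' @param seed integer seed
#' @return tibble with sample_id, barcode5, barcode3
#' @export
make_barcode_table <- function(sample_ids, length = 8, seed = 1) {
  n_needed <- 2L * length(sample_ids)
  withr::with_seed(derive_seed(seed, "barcodes"), {
    codes <- character(0)
    while (length(codes) < n_needed) {
      cand <- random_dna(1, length)
      if (all(vapply(codes, function(b) hamming(b, cand) >= 3L, logical(1)))) {
        codes <- c(codes, cand)
      }
    }
    tibble::tibble(
      sample_id = sample_ids,
      barcode5 = codes[seq_along(sample_ids)],
      barcode3 = codes[length(sample_ids) + seq_along(sample_ids)]
    )
  })
}

#' Tag template molecules and model PCR amplification
#'
#' Every template molecule receives its sample's barcode pair and an
#' independent random 10-nt tag on each end. PCR substitution errors are not
#' materialised per copy; the effective per-base substitution probability
#' `1 - (1 - per_base_error)^pcr_cycles` is recorded and applied once per
#' sequenced fragment by [fragment_and_sequence()] (each fragment derives from
#' a distinct amplified copy). Chimeras fuse two same-sample molecules at a
#' uniform breakpoint, keep the 5' parent's tag5 and the 3' parent's tag3, and
#' carry a read-depth weight `2^-cycle` for a formation cycle drawn uniformly
#' from 2..7 — early-cycle products are the ones abundant enough to sequence.
#'
#' @param profiles output of [compose_samples()]
#' @param templates a `template_set`
#' @param barcode_table tibble from [make_barcode_table()]
#' @param tag_length tag length per end (default 10)
#' @param pcr_cycles number of PCR cycles
#' @param per_base_error PCR substitution rate per base per cycle
#' @param chimera_rate expected chimeric molecules as a fraction of molecules
#' @param collision_mode "random" (tags uniform over 4^tag_length) or
#'   "forced_k" (inject `forced_k` tag-pair collisions for testing)
#' @param forced_k number of collisions to force under "forced_k"
#' @param seed integer seed
#' @param primers primer motif list
#' @return an `amplified_library`: list with `molecules` tibble (molecule_id,
#'   sample_id, taxon_id, core, sequence, barcode5, barcode3, tag5, tag3,
#'   is_chimera, parent_ids, read_weight) and `params`
#' @export
tag_and_amplify <- function(profiles, templates, barcode_table,
                            tag_length = 10, pcr_cycles = 35,
                            per_base_error = 1e-5, chimera_rate = 0.01,
                            collision_mode = c("random", "forced_k"),
                            forced_k = 0, seed = 1,
                            primers = default_primers()) {
  collision_mode <- match.arg(collision_mode)
  stopifnot(per_base_error >= 0, per_base_error <= 1,
            chimera_rate >= 0, chimera_rate <= 1)
  missing_bc <- setdiff(unique(profiles$sample_id), barcode_table$sample_id)
  if (length(missing_bc)) {
    stop("barcode_table missing samples: ", paste(missing_bc, collapse = ", "))
  }
  tpl <- templates$templates
  withr::with_seed(derive_seed(seed, "amplify"), {
    mol <- profiles[rep(seq_len(nrow(profiles)), profiles$n_molecules), ]
    n <- nrow(mol)
    mol$molecule_id <- sprintf("mol%05d", seq_len(n))
    mol$core <- tpl$sequence[match(mol$taxon_id, tpl$taxon_id)]
    bc <- barcode_table[match(mol$sample_id, barcode_table$sample_id), ]
    mol$barcode5 <- bc$barcode5
    mol$barcode3 <- bc$barcode3
    mol$tag5 <- random_dna(n, tag_length)
    mol$tag3 <- random_dna(n, tag_length)
    if (collision_mode == "forced_k" && forced_k > 0) {
      # Give molecule 2i the tag pair of molecule 2i-1: a true collision.
      stopifnot(2L * forced_k <= n)
      for (i in seq_len(forced_k)) {
        mol$tag5[2L * i] <- mol$tag5[2L * i - 1L]
        mol$tag3[2L * i] <- mol$tag3[2L * i - 1L]
      }
    }
    mol$is_chimera <- FALSE
    mol$parent_ids <- vector("list", n)
    mol$read_weight <- 1
    # Chimeric fusions between same-sample molecules.
    chim <- list()
    n_chim <- stats::rbinom(1, n, chimera_rate)
    by_sample <- split(seq_len(n), mol$sample_id)
    eligible <- names(by_sample)[vapply(by_sample, length, 1L) >= 2L]
    if (n_chim > 0 && length(eligible) > 0) {
      for (i in seq_len(n_chim)) {
        s <- sample(eligible, 1L)
        pair <- sample(by_sample[[s]], 2L)
        a <- pair[1]; b <- pair[2]
        bp <- sample.int(min(nchar(mol$core[a]), nchar(mol$core[b])) - 1L, 1L)
        fused <- paste0(substr(mol$core[a], 1, bp),
                        substr(mol$core[b], bp + 1L, nchar(mol$core[b])))
        cycle <- sample(2:7, 1L)
        chim[[i]] <- tibble::tibble(
          sample_id = s, group = mol$group[a], unit_id = mol$unit_id[a],
          taxon_id = NA_character_, n_molecules = 1L,
          molecule_id = sprintf("chim%04d", i), core = fused,
          barcode5 = mol$barcode5[a], barcode3 = mol$barcode3[b],
          tag5 = mol$tag5[a], tag3 = mol$tag3[b],
          is_chimera = TRUE,
          parent_ids = list(c(mol$molecule_id[a], mol$molecule_id[b])),
          read_weight = 2^(-cycle)
        )
      }
      mol <- dplyr::bind_rows(mol, dplyr::bind_rows(chim))
    }
    mol$sequence <- paste0(mol$barcode5, mol$tag5, primers$forward, mol$core,
                           revcomp(primers$reverse), revcomp(mol$tag3),
                           revcomp(mol$barcode3))
    mol$n_molecules <- NULL
    out <- list(
      molecules = tibble::as_tibble(mol),
      params = list(
        tag_length = tag_length, pcr_cycles = pcr_cycles,
        per_base_error = per_base_error,
        effective_pcr_error = 1 - (1 - per_base_error)^pcr_cycles,
        chimera_rate = chimera_rate, collision_mode = collision_mode,
        primers = primers, seed = seed
      )
    )
    class(out) <- "amplified_library"
    out
  })
}

#' Sequence an amplified library as paired 250-nt reads
#'
#' Read pairs come from two sources at `full_to_fragment_ratio`: intact
#' amplicons (mate 1 reads the 5' tagged end, mate 2 the 3' tagged end, so the
#' pair observes both tags) and tagmented fragments anchored at one tagged end
#' with a uniform 400-1000 nt length (mate 1 reads the tagged end, mate 2
#' reads inward from the breakpoint). Per-fragment PCR substitutions at the
#' recorded effective rate and per-base sequencing errors are applied; the
#' truth table maps every read pair to its molecule and interval (0-based
#' half-open, forward molecule coordinates).
#'
#' @param amplified an `amplified_library`
#' @param reads_per_molecule mean read pairs per unit-weight molecule
#' @param full_to_fragment_ratio numeric length-2, molar ratio of full-length
#'   amplicons to tagmented fragments (default `c(1, 7)`)
#' @param fragment_length_range tagmented fragment length range in nt
#' @param read_length read length (default 250)
#' @param seq_error_rate per-base sequencing substitution rate
#' @param seed integer seed
#' @return a `sim_library`: list with `reads` (read pairs), `truth` (read ->
#'   molecule map), `molecules`, `profiles` and `params`
#' @export
fragment_and_sequence <- function(amplified, reads_per_molecule = 40,
                                  full_to_fragment_ratio = c(1, 7),
                                  fragment_length_range = c(400, 1000),
                                  read_length = 250,
                                  seq_error_rate = 0.001, seed = 1) {
  stopifnot(inherits(amplified, "amplified_library"),
            read_length <= fragment_length_range[1])
  mol <- amplified$molecules
  p_full <- full_to_fragment_ratio[1] / sum(full_to_fragment_ratio)
  pcr_rate <- amplified$params$effective_pcr_error
  withr::with_seed(derive_seed(seed, "sequence"), {
    out <- vector("list", nrow(mol))
    for (i in seq_len(nrow(mol))) {
      m <- mol$sequence[i]
      L <- nchar(m)
      n_pairs <- max(0L, as.integer(round(reads_per_molecule * mol$read_weight[i])))
      if (n_pairs == 0L) next
      # Intact amplicons guarantee observation of both tags: every unit-weight
      # molecule contributes at least two full-length pairs.
      n_full <- max(if (mol$read_weight[i] >= 1) 2L else 0L,
                    stats::rbinom(1, n_pairs, p_full))
      n_full <- min(n_full, n_pairs)
      n_frag <- n_pairs - n_full
      # Tagmented fragment sizes: stratified across the selected size window
      # (with jitter), split evenly between the two anchored ends, so the
      # library represents the whole 400-1000 nt range at the depth it has.
      n5 <- n_frag %/% 2L + stats::rbinom(1, n_frag %% 2L, 0.5)
      n3 <- n_frag - n5
      lo <- fragment_length_range[1]
      hi <- min(fragment_length_range[2], L)
      strat_lengths <- function(k) {
        if (k == 0L) return(integer(0))
        step <- (hi - lo) / k
        mid <- lo + (seq_len(k) - 0.5) * step
        as.integer(pmin(hi, pmax(lo, round(
          mid + stats::runif(k, -step / 4, step / 4)))))
      }
      frag_len <- c(strat_lengths(n5), strat_lengths(n3))
      frag_side <- c(rep("frag5", n5), rep("frag3", n3))
      ord <- sample.int(n_frag)
      frag_len <- frag_len[ord]
      frag_side <- frag_side[ord]
      r1 <- r2 <- character(n_pairs)
      fs <- fe <- integer(n_pairs)
      type <- character(n_pairs)
      for (j in seq_len(n_pairs)) {
        copy <- if (pcr_rate > 0) mutate_seq(m, pcr_rate) else m
        if (j <= n_full) {
          r1[j] <- substr(copy, 1, read_length)
          r2[j] <- substr(revcomp(copy), 1, read_length)
          fs[j] <- 0L; fe[j] <- L; type[j] <- "full"
        } else {
          f <- frag_len[j - n_full]
          if (frag_side[j - n_full] == "frag5") { # anchored at the 5' tag
            r1[j] <- substr(copy, 1, read_length)
            r2[j] <- revcomp(substr(copy, f - read_length + 1L, f))
            fs[j] <- 0L; fe[j] <- f; type[j] <- "frag5"
          } else {                                # anchored at the 3' tag
            rc <- revcomp(copy)
            r1[j] <- substr(rc, 1, read_length)
            r2[j] <- revcomp(substr(rc, f - read_length + 1L, f))
            fs[j] <- L - f; fe[j] <- L; type[j] <- "frag3"
          }
        }
        if (seq_error_rate > 0) {
          r1[j] <- mutate_seq(r1[j], seq_error_rate)
          r2[j] <- mutate_seq(r2[j], seq_error_rate)
        }
      }
      out[[i]] <- tibble::tibble(
        molecule_id = mol$molecule_id[i], r1_seq = r1, r2_seq = r2,
        frag_start = fs, frag_end = fe, type = type
      )
    }
    reads <- dplyr::bind_rows(out)
    if (nrow(reads) == 0) stop("no reads generated")
    reads$read_id <- sprintf("read%06d", seq_len(nrow(reads)))
    qual <- quality_string(read_length, seq_error_rate)
    reads$r1_qual <- qual
    reads$r2_qual <- qual
    truth <- reads[, c("read_id", "molecule_id", "frag_start", "frag_end", "type")]
    profiles <- mol[!mol$is_chimera,
                    c("sample_id", "group", "unit_id", "taxon_id")] |>
      dplyr::count(.data$sample_id, .data$group, .data$unit_id,
                   .data$taxon_id, name = "n_molecules")
    lib <- list(
      reads = reads[, c("read_id", "r1_seq", "r1_qual", "r2_seq", "r2_qual")],
      truth = truth,
      molecules = mol,
      profiles = profiles,
      params = c(amplified$params, list(
        reads_per_molecule = reads_per_molecule,
        full_to_fragment_ratio = full_to_fragment_ratio,
        fragment_length_range = fragment_length_range,
        read_length = read_length, seq_error_rate = seq_error_rate,
        sequence_seed = seed
      ))
    )
    class(lib) <- "sim_library"
    lib
  })
}

#' @export
print.sim_library <- function(x, ...) {
  cat("<sim_library> ", nrow(x$reads), " read pairs from ",
      nrow(x$molecules), " tagged molecules (",
      sum(x$molecules$is_chimera), " chimeric), ",
      length(unique(x$molecules$sample_id)), " samples\n", sep = "")
  invisible(x)
}

#' Write a simulated library to disk
#'
#' Emits `reads_R1.fastq`, `reads_R2.fastq`, `truth.json` and `profiles.tsv`.
#'
#' @param lib a `sim_library`
#' @param dir output directory (created if needed)
#' @return the directory, invisibly
#' @export
write_library <- function(lib, dir) {
  stopifnot(inherits(lib, "sim_library"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_fastq_pairs(lib$reads, file.path(dir, "reads_R1.fastq"),
                    file.path(dir, "reads_R2.fastq"))
  mol <- lib$molecules
  mol$parent_ids <- vapply(mol$parent_ids, paste, character(1), collapse = ",")
  jsonlite::write_json(
    list(molecules = mol, reads = lib$truth,
         params = lib$params[setdiff(names(lib$params), "primers")]),
    file.path(dir, "truth.json"), auto_unbox = TRUE, digits = NA
  )
  utils::write.table(lib$profiles, file.path(dir, "profiles.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(dir)
}
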