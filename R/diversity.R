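# Alpha-diversity statistics on the OTU table.

#' Per-sample sequence totals and OTU richness
#'
#' @param table an `otu_tbl`
#' @param group_map tibble with sample_id and group; samples missing from it
#'   are labelled "control" with a warning
#' @return tibble with sample_id, group, n_sequences, n_otus
#' @export
sample_stats <- function(table, group_map = NULL) {
  stopifnot(inherits(table, "otu_tbl"))
  stats <- table$counts |>
    dplyr::summarise(n_sequences = sum(.data$count),
                     n_otus = sum(.data$count > 0), .by = "sample_id")
  all_samples <- tibble::tibble(sample_id = table$samples)
  stats <- dplyr::left_join(all_samples, stats, by = "sample_id") |>
    dplyr::mutate(n_sequences = dplyr::coalesce(.data$n_sequences, 0L),
                  n_otus = dplyr::coalesce(.data$n_otus, 0L))
  if (is.null(group_map)) {
    stats$group <- "control"
  } else {
    stats <- dplyr::left_join(stats, group_map[, c("sample_id", "group")],
                              by = "sample_id")
    if (anyNA(stats$group)) {
      warning("samples missing from group_map treated as controls: ",
              paste(stats$sample_id[is.na(stats$group)], collapse = ", "))
      stats$group[is.na(stats$group)] <- "control"
    }
  }
  stats[, c("sample_id", "group", "n_sequences", "n_otus")]
}

#' Rarefaction curve for one sample (observed OTUs)
#'
#' For each depth not exceeding the sample's sequence total, subsamples the
#' OTU count vector without replacement `iterations` times and averages the
#' number of distinct OTUs observed.
#'
#' @param counts named (or unnamed) integer vector of per-OTU counts
#' @param depths subsampling depths (depths above the total are omitted)
#' @param iterations Monte Carlo iterations per depth
#' @param seed integer seed
#' @return tibble with depth, mean_observed, iterations
#' @export
rarefy <- function(counts, depths = seq(10, 260, by = 10), iterations = 1000,
                   seed = 1) {
  counts <- counts[counts > 0]
  total <- sum(counts)
  if (total == 0) {
    return(tibble::tibble(depth = integer(0), mean_observed = numeric(0),
                          iterations = integer(0)))
  }
  depths <- depths[depths <= total]
  pool <- rep.int(seq_along(counts), counts)
  withr::with_seed(derive_seed(seed, "rarefy"), {
    mean_obs <- vapply(depths, function(d) {
      if (d == total) return(sum(counts > 0) + 0)
      mean(vapply(seq_len(iterations), function(i) {
        length(unique(pool[sample.int(total, d)]))
      }, 0L))
    }, 0)
  })
  tibble::tibble(depth = as.integer(depths), mean_observed = mean_obs,
                 iterations = as.integer(iterations))
}

#' Rarefaction curves for every sample of an OTU table
#'
#' @param table an `otu_tbl`
#' @param min_total samples with fewer sequences are skipped
#' @inheritParams rarefy
#' @return tibble with sample_id, depth, mean_observed, iterations
#' @export
rarefaction_curves <- function(table, depths = seq(10, 260, by = 10),
                               iterations = 1000, min_total = 10, seed = 1) {
  stopifnot(inherits(table, "otu_tbl"))
  per_sample <- split(table$counts, table$counts$sample_id)
  purrr::imap(per_sample, function(cs, sid) {
    if (sum(cs$count) < min_total) return(NULL)
    rc <- rarefy(cs$count, depths, iterations,
                 seed = derive_seed(seed, sid))
    rc$sample_id <- sid
    rc
  }) |>
    dplyr::bind_rows() |>
    dplyr::relocate("sample_id")
}

#' Rank abundance of OTUs above a total-count cutoff
#'
#' @param table an `otu_tbl`
#' @param group_map optional tibble with sample_id and group; adds logical
#'   presence flags per group
#' @param min_total OTUs with totals strictly greater than this are kept
#' @return tibble with rank, otu_id, taxonomy, total (plus presence flags)
#' @export
rank_abundance <- function(table, group_map = NULL, min_total = 50) {
  stopifnot(inherits(table, "otu_tbl"))
  out <- table$otus[table$otus$total > min_total,
                    c("otu_id", "taxonomy", "total")]
  out <- out[order(-out$total, out$otu_id), ]
  if (nrow(out)) out$rank <- seq_len(nrow(out))
  else out$rank <- integer(0)
  if (!is.null(group_map) && nrow(out)) {
    pres <- table$counts |>
      dplyr::left_join(group_map[, c("sample_id", "group")], by = "sample_id") |>
      dplyr::filter(!is.na(.data$group), .data$count > 0) |>
      dplyr::distinct(.data$otu_id, .data$group) |>
      dplyr::mutate(present = TRUE) |>
      tidyr::pivot_wider(names_from = "group", values_from = "present",
                         values_fill = FALSE, names_prefix = "present_")
    out <- dplyr::left_join(out, pres, by = "otu_id")
    flag_cols <- grep("^present_", names(out))
    out[flag_cols][is.na(out[flag_cols])] <- FALSE
  }
  dplyr::relocate(out, "rank")
}

#' Per-sample relative abundance pooled by taxonomic rank
#'
#' OTUs are pooled by the requested rank parsed from greengenes-style labels
#' (`f__Family`, `g__Genus`); unparseable labels go to "unclassified" and
#' OTUs whose dataset-wide total is at most `other_threshold` go to "Other".
#' Fractions sum to 1 for every sample with at least one sequence.
#'
#' @param table an `otu_tbl`
#' @param rank "family" or "genus"
#' @param other_threshold total-count cutoff for the "Other" bucket
#' @return tibble with sample_id, taxon, fraction
#' @export
relative_abundance_by_taxon <- function(table, rank = c("family", "genus"),
                                        other_threshold = 5) {
  stopifnot(inherits(table, "otu_tbl"))
  rank <- match.arg(rank)
  prefix <- if (rank == "family") "f__" else "g__"
  parse_rank <- function(lab) {
    m <- regmatches(lab, regexpr(paste0(prefix, "[^;]*"), lab))
    if (length(m) == 0) return("unclassified")
    v <- trimws(sub(prefix, "", m))
    if (nzchar(v)) v else "unclassified"
  }
  otus <- table$otus
  otus$taxon <- vapply(otus$taxonomy, parse_rank, "", USE.NAMES = FALSE)
  otus$taxon[otus$total <= other_threshold] <- "Other"
  joined <- dplyr::left_join(table$counts,
                             otus[, c("otu_id", "taxon")], by = "otu_id")
  joined |>
    dplyr::summarise(count = sum(.data$count),
                     .by = c("sample_id", "taxon")) |>
    dplyr::mutate(fraction = .data$count / sum(.data$count),
                  .by = "sample_id") |>
    dplyr::select("sample_id", "taxon", "fraction") |>
    dplyr::arrange(.data$sample_id, dplyr::desc(.data$fraction))
}
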