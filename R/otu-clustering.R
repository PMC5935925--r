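# Open-reference OTU clustering at a configurable identity threshold.
#
# Identity is computed from a free-end-gap global alignment with an
# IUPAC-aware scoring matrix; the reported value is the number of compatible
# aligned columns divided by the length of the longer sequence. With that
# denominator, identity 1.0 coincides with string equality for plain ACGT
# sequences (so 100% clustering is exact deduplication), while terminal
# length variants fall just below 1.0 and are handled by the dedicated
# pooling step — mirroring how such OTUs appeared separately and were pooled
# afterwards.

# Score matrix over the IUPAC alphabet: +1 when the codes share a base,
# -2 otherwise. Built once at load time.
.iupac_submat_cache <- NULL
.iupac_submat <- function() {
  if (is.null(.iupac_submat_cache)) {
    letters <- names(IUPAC_MASK)
    m <- outer(IUPAC_MASK, IUPAC_MASK,
               function(a, b) ifelse(bitwAnd(a, b) > 0L, 1, -2))
    dimnames(m) <- list(letters, letters)
    utils::assignInMyNamespace(".iupac_submat_cache", m)
  }
  .iupac_submat_cache
}

#' IUPAC-aware pairwise sequence identity
#'
#' Aligns two sequences globally with free terminal gaps and returns the
#' number of IUPAC-compatible aligned columns divided by the length of the
#' longer sequence. Identical sequences score 1.0; ambiguity codes match any
#' compatible base (`"ARG"` vs `"AAG"` is 1.0); a single substitution over
#' 1400 nt scores 1399/1400.
#'
#' @param a,b nonempty IUPAC DNA strings
#' @return identity fraction in \[0, 1\]
#' @export
pairwise_identity <- function(a, b) {
  stopifnot(nchar(a) > 0, nchar(b) > 0)
  if (!grepl("^[ACGTMRWSYKVHDBNacgtmrwsykvhdbn]+$", a) ||
      !grepl("^[ACGTMRWSYKVHDBNacgtmrwsykvhdbn]+$", b)) {
    stop("sequences must be IUPAC DNA")
  }
  a <- toupper(a); b <- toupper(b)
  if (a == b) return(1)
  if (nchar(a) == nchar(b) && iupac_mismatches(a, b) == 0L) return(1)
  aln <- Biostrings::pairwiseAlignment(
    Biostrings::DNAString(a), Biostrings::DNAString(b), type = "overlap",
    substitutionMatrix = .iupac_submat(), gapOpening = 4, gapExtension = 2)
  pa <- as.character(Biostrings::alignedPattern(aln))
  pb <- as.character(Biostrings::alignedSubject(aln))
  va <- utf8ToInt(pa); vb <- utf8ToInt(pb)
  gap <- utf8ToInt("-")
  both <- va != gap & vb != gap
  matches <- sum(bitwAnd(.mask_by_code[va[both]], .mask_by_code[vb[both]]) > 0L)
  matches / max(nchar(a), nchar(b))
}

# Fast decision "identity(a, b) >= threshold" used inside greedy clustering.
.identity_at_least <- function(a, b, threshold, a_acgt, b_acgt) {
  la <- nchar(a); lb <- nchar(b)
  if (min(la, lb) / max(la, lb) < threshold) return(FALSE)
  if (a_acgt && b_acgt && threshold >= 1) return(a == b)
  if (la == lb && iupac_mismatches(a, b) == 0L) return(TRUE)
  if (threshold >= 1) return(FALSE)
  pairwise_identity(a, b) >= threshold
}

#' Two-step open-reference OTU clustering
#'
#' Step 1 assigns each sequence to its best reference hit at or above the
#' identity threshold (closed reference). Step 2 clusters the remainder
#' greedily: sequences are processed in descending length (ties broken by
#' descending abundance, then lexicographically); the first sequence founds a
#' centroid and later sequences join the first centroid meeting the threshold
#' or found a new one. OTUs with fewer than `min_otu_size` sequences are
#' discarded. De novo OTU ids carry the prefix `de_novo`.
#'
#' @param sequences tibble with sample_id and sequence (and optionally seq_id)
#' @param reference tibble with id (or taxon_id), sequence, taxonomy; `NULL`
#'   for pure de novo clustering
#' @param threshold identity fraction in (0.5, 1]
#' @param min_otu_size minimum sequences per OTU (default 2)
#' @return an `otu_tbl`: list with `otus` (otu_id, source, taxonomy,
#'   representative, total), `counts` (otu_id, sample_id, count),
#'   `assignments` (seq_id, sample_id, otu_id incl. discarded OTUs as NA),
#'   `samples`, `threshold`, `dropped`, `n_input`
#' @export
cluster_open_reference <- function(sequences, reference = NULL,
                                   threshold = 0.99, min_otu_size = 2,
                                   seed = 1) {
  stopifnot(threshold > 0.5, threshold <= 1)
  sequences <- tibble::as_tibble(sequences)
  if (!"seq_id" %in% names(sequences)) {
    sequences$seq_id <- sprintf("seq%05d", seq_len(nrow(sequences)))
  }
  sequences$sequence <- toupper(sequences$sequence)
  if (!is.null(reference) && nrow(reference) > 0) {
    if (!"id" %in% names(reference)) reference$id <- reference$taxon_id
  } else {
    if (!is.null(reference)) warning("empty reference; pure de novo clustering")
    reference <- NULL
  }
  uniq <- sequences |>
    dplyr::count(.data$sequence, name = "abundance")
  uniq$acgt <- !grepl("[^ACGT]", uniq$sequence)
  # Closed-reference step.
  uniq$otu_id <- NA_character_
  if (!is.null(reference)) {
    ref_acgt <- !grepl("[^ACGT]", toupper(reference$sequence))
    for (i in seq_len(nrow(uniq))) {
      ids <- vapply(seq_len(nrow(reference)), function(j) {
        if (.identity_at_least(uniq$sequence[i],
                               toupper(reference$sequence[j]), threshold,
                               uniq$acgt[i], ref_acgt[j])) {
          pairwise_identity(uniq$sequence[i], toupper(reference$sequence[j]))
        } else NA_real_
      }, 0)
      if (any(!is.na(ids))) {
        uniq$otu_id[i] <- reference$id[which.max(ids)]
      }
    }
  }
  # De novo step, deterministic order.
  rest <- which(is.na(uniq$otu_id))
  rest <- rest[order(-nchar(uniq$sequence[rest]), -uniq$abundance[rest],
                     uniq$sequence[rest])]
  centroids <- integer(0)
  denovo_serial <- 0L
  for (i in rest) {
    joined <- FALSE
    for (cj in centroids) {
      if (.identity_at_least(uniq$sequence[i], uniq$sequence[cj], threshold,
                             uniq$acgt[i], uniq$acgt[cj])) {
        uniq$otu_id[i] <- uniq$otu_id[cj]
        joined <- TRUE
        break
      }
    }
    if (!joined) {
      denovo_serial <- denovo_serial + 1L
      uniq$otu_id[i] <- sprintf("de_novo%d", denovo_serial)
      centroids <- c(centroids, i)
    }
  }
  assignments <- dplyr::left_join(
    sequences[, c("seq_id", "sample_id", "sequence")],
    uniq[, c("sequence", "otu_id")], by = "sequence")
  counts <- assignments |>
    dplyr::count(.data$otu_id, .data$sample_id, name = "count")
  totals <- counts |>
    dplyr::summarise(total = sum(.data$count), .by = "otu_id")
  keep <- totals$otu_id[totals$total >= min_otu_size]
  dropped <- totals[!totals$otu_id %in% keep, ]
  assignments$otu_id[!assignments$otu_id %in% keep] <- NA_character_
  counts <- counts[counts$otu_id %in% keep, ]
  reps <- uniq |>
    dplyr::filter(.data$otu_id %in% keep) |>
    dplyr::arrange(dplyr::desc(.data$abundance)) |>
    dplyr::distinct(.data$otu_id, .keep_all = TRUE)
  otus <- tibble::tibble(
    otu_id = reps$otu_id,
    source = ifelse(grepl("^de_novo", reps$otu_id), "de_novo", "reference"),
    representative = reps$sequence,
    total = totals$total[match(reps$otu_id, totals$otu_id)]
  )
  if (!is.null(reference)) {
    ridx <- match(otus$otu_id, reference$id)
    otus$taxonomy <- ifelse(is.na(ridx), "unassigned", reference$taxonomy[ridx])
    otus$representative[!is.na(ridx)] <-
      toupper(reference$sequence[ridx[!is.na(ridx)]])
  } else {
    otus$taxonomy <- "unassigned"
  }
  otus <- otus[order(-otus$total, otus$otu_id),
               c("otu_id", "source", "taxonomy", "representative", "total")]
  structure(list(
    otus = otus, counts = counts,
    assignments = assignments[, c("seq_id", "sample_id", "otu_id")],
    samples = sort(unique(sequences$sample_id)),
    threshold = threshold,
    dropped = dropped, n_input = nrow(sequences)
  ), class = "otu_tbl")
}

#' @export
print.otu_tbl <- function(x, ...) {
  cat("<otu_tbl> ", nrow(x$otus), " OTUs x ", length(x$samples),
      " samples at ", x$threshold * 100, "% identity (",
      sum(x$counts$count), " of ", x$n_input, " sequences retained)\n",
      sep = "")
  invisible(x)
}

#' Wide counts matrix view of an OTU table
#'
#' @param x an `otu_tbl`
#' @param ... unused
#' @return tibble with otu_id, taxonomy and one count column per sample
#' @method as_tibble otu_tbl
#' @export
as_tibble.otu_tbl <- function(x, ...) {
  wide <- tidyr::pivot_wider(x$counts, names_from = "sample_id",
                             values_from = "count", values_fill = 0L)
  missing <- setdiff(x$samples, names(wide))
  for (s in missing) wide[[s]] <- 0L
  out <- dplyr::left_join(x$otus[, c("otu_id", "source", "taxonomy", "total")],
                          wide, by = "otu_id")
  out[is.na(out)] <- 0L
  out
}

#' Pool OTUs equivalent up to degeneracies or terminal length
#'
#' Two OTUs merge when one representative matches the other position-by-
#' position under IUPAC compatibility after allowing a terminal overhang of at
#' most `max_length_overhang` nt in total. The merged OTU keeps the more
#' abundant OTU's id and representative; counts are summed.
#'
#' @param table an `otu_tbl`
#' @param max_length_overhang maximum total terminal length difference
#' @return pooled `otu_tbl` (with a `pooled` attribute listing merges)
#' @export
pool_equivalent_otus <- function(table, max_length_overhang = 4) {
  stopifnot(inherits(table, "otu_tbl"))
  otus <- table$otus[order(-table$otus$total, table$otus$otu_id), ]
  merged_into <- stats::setNames(otus$otu_id, otus$otu_id)
  merges <- list()
  if (nrow(otus) >= 2) {
    for (i in seq_len(nrow(otus) - 1L)) {
      if (merged_into[otus$otu_id[i]] != otus$otu_id[i]) next
      for (j in (i + 1L):nrow(otus)) {
        if (merged_into[otus$otu_id[j]] != otus$otu_id[j]) next
        if (.equivalent_reps(otus$representative[i], otus$representative[j],
                             max_length_overhang)) {
          merged_into[otus$otu_id[j]] <- otus$otu_id[i]
          merges[[length(merges) + 1L]] <-
            c(from = otus$otu_id[j], into = otus$otu_id[i])
        }
      }
    }
  }
  table$counts$otu_id <- unname(merged_into[table$counts$otu_id])
  table$counts <- table$counts |>
    dplyr::summarise(count = sum(.data$count),
                     .by = c("otu_id", "sample_id"))
  table$assignments$otu_id <- ifelse(
    is.na(table$assignments$otu_id), NA_character_,
    unname(merged_into[table$assignments$otu_id]))
  table$otus <- table$otus[merged_into[table$otus$otu_id] == table$otus$otu_id, ]
  totals <- table$counts |>
    dplyr::summarise(total = sum(.data$count), .by = "otu_id")
  table$otus$total <- totals$total[match(table$otus$otu_id, totals$otu_id)]
  table$otus <- table$otus[order(-table$otus$total, table$otus$otu_id), ]
  attr(table, "pooled") <- merges
  table
}

# Equivalence rule: shorter rep matches inside longer at a terminal offset,
# all overlapping positions IUPAC-compatible, total overhang <= max_over.
.equivalent_reps <- function(a, b, max_over) {
  if (nchar(a) < nchar(b)) { tmp <- a; a <- b; b <- tmp }
  diff <- nchar(a) - nchar(b)
  if (diff > max_over) return(FALSE)
  for (left in 0:diff) {
    seg <- substr(a, left + 1L, left + nchar(b))
    if (iupac_mismatches(seg, b) == 0L) return(TRUE)
  }
  FALSE
}

#' Remove OTUs whose taxonomy matches a label
#'
#' @param table an `otu_tbl`
#' @param label_substring substring matched against taxonomy labels
#'   (e.g. `"Streptophyta"` for plant chloroplasts)
#' @return filtered `otu_tbl`; removed per-sample counts in the `removed`
#'   attribute
#' @export
remove_taxon <- function(table, label_substring) {
  stopifnot(inherits(table, "otu_tbl"))
  hit <- grepl(label_substring, table$otus$taxonomy, fixed = TRUE)
  removed_ids <- table$otus$otu_id[hit]
  removed <- table$counts[table$counts$otu_id %in% removed_ids, ]
  table$otus <- table$otus[!hit, ]
  table$counts <- table$counts[!table$counts$otu_id %in% removed_ids, ]
  table$assignments$otu_id[table$assignments$otu_id %in% removed_ids] <-
    NA_character_
  attr(table, "removed") <- removed
  table
}
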