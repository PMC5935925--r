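# Strain-level analysis of a focal OTU: 100%-identity haplotypes of its
# member sequences, V4 sub-region extraction with ambiguity masking, and
# variant-position tables contrasting full-length with V4 resolution.

#' Extract the member sequences of a focal OTU
#'
#' @param table an `otu_tbl` whose `assignments` map input sequences to OTUs
#' @param sequences the tibble of clustered input sequences (seq_id,
#'   sample_id, sequence); must be the same set the table was built from
#' @param focal_otu_id OTU to extract; `NULL` picks the OTU with the largest
#'   total count
#' @return tibble with seq_id, sample_id, sequence, otu_id
#' @export
extract_otu_members <- function(table, sequences, focal_otu_id = NULL) {
  stopifnot(inherits(table, "otu_tbl"))
  if (is.null(focal_otu_id)) {
    focal_otu_id <- table$otus$otu_id[which.max(table$otus$total)]
  }
  if (!focal_otu_id %in% table$otus$otu_id) {
    stop("unknown OTU id: ", focal_otu_id)
  }
  if (!"seq_id" %in% names(sequences)) {
    sequences$seq_id <- sprintf("seq%05d", seq_len(nrow(sequences)))
  }
  members <- table$assignments[
    !is.na(table$assignments$otu_id) &
      table$assignments$otu_id == focal_otu_id, ]
  if (nrow(members) == 0) stop("OTU ", focal_otu_id, " has no members")
  out <- dplyr::inner_join(
    members[, c("seq_id", "otu_id")],
    sequences[, c("seq_id", "sample_id", "sequence")], by = "seq_id")
  out[, c("seq_id", "sample_id", "sequence", "otu_id")]
}

#' Cluster sequences into exact (100% identity) haplotypes
#'
#' Exact-string clustering after uppercase normalisation: sequences of
#' different length, or differing by a single character (including ambiguity
#' codes), are distinct haplotypes.
#'
#' @param members tibble with sample_id and sequence (e.g. from
#'   [extract_otu_members()])
#' @param min_size haplotypes with fewer members are dropped (default 1
#'   retains singletons)
#' @param region label stored on the result ("full_length" or "v4")
#' @return a `haplotype_tbl`: list with `haplotypes` (hap_id, representative,
#'   n_sequences), `counts` (hap_id, sample_id, count), `membership`
#'   (seq_id -> hap_id), `region`
#' @export
cluster_unique <- function(members, min_size = 1, region = "full_length") {
  members <- tibble::as_tibble(members)
  if (!"seq_id" %in% names(members)) {
    members$seq_id <- sprintf("seq%05d", seq_len(nrow(members)))
  }
  members$sequence <- toupper(members$sequence)
  haps <- members |>
    dplyr::count(.data$sequence, name = "n_sequences") |>
    dplyr::arrange(dplyr::desc(.data$n_sequences), .data$sequence)
  haps$hap_id <- sprintf("hap%03d", seq_len(nrow(haps)))
  haps <- haps[haps$n_sequences >= min_size, ]
  membership <- dplyr::left_join(
    members[, c("seq_id", "sample_id", "sequence")],
    haps[, c("sequence", "hap_id")], by = "sequence")
  counts <- membership |>
    dplyr::filter(!is.na(.data$hap_id)) |>
    dplyr::count(.data$hap_id, .data$sample_id, name = "count")
  structure(list(
    haplotypes = haps[, c("hap_id", "sequence", "n_sequences")] |>
      dplyr::rename(representative = "sequence"),
    counts = counts,
    membership = membership[, c("seq_id", "sample_id", "hap_id")],
    region = region
  ), class = "haplotype_tbl")
}

#' @export
print.haplotype_tbl <- function(x, ...) {
  cat("<haplotype_tbl> ", nrow(x$haplotypes), " ", x$region,
      " haplotypes over ", sum(x$haplotypes$n_sequences), " sequences\n",
      sep = "")
  invisible(x)
}

#' Extract the V4 sub-region delimited by primer motifs
#'
#' Returns the subsequence strictly between the best IUPAC-aware matches of
#' the forward motif and of the reverse complement of the reverse motif, with
#' every non-ACGT character replaced by N. Sequences where either motif is
#' absent (more than `max_mismatch` mismatches) are flagged unextractable.
#'
#' @param sequences character vector, or tibble with a `sequence` column
#' @param forward_motif,reverse_motif IUPAC primer strings (defaults: the
#'   canonical V4 primer pair 515F/806R)
#' @param max_mismatch motif mismatch tolerance
#' @return tibble with sequence (input), v4, extractable
#' @export
extract_v4 <- function(sequences,
                       forward_motif = default_primers()$v4_forward,
                       reverse_motif = default_primers()$v4_reverse,
                       max_mismatch = 2) {
  seqs <- if (is.data.frame(sequences)) sequences$sequence else sequences
  rev_site <- revcomp(reverse_motif)
  one <- function(s) {
    su <- toupper(s)
    f <- .best_motif_match(forward_motif, su, max_mismatch)
    r <- .best_motif_match(rev_site, su, max_mismatch)
    if (is.na(f) || is.na(r)) return(c(NA_character_, "FALSE"))
    start <- f + nchar(forward_motif)
    end <- r - 1L
    if (start > end) return(c(NA_character_, "FALSE"))
    v4 <- substr(su, start, end)
    v4 <- gsub("[^ACGT]", "N", v4)
    c(v4, "TRUE")
  }
  res <- vapply(seqs, one, character(2), USE.NAMES = FALSE)
  out <- tibble::tibble(sequence = seqs, v4 = res[1, ],
                        extractable = res[2, ] == "TRUE")
  if (is.data.frame(sequences)) {
    dplyr::bind_cols(sequences[setdiff(names(sequences), "sequence")], out)
  } else {
    out
  }
}

# 1-based start of the best (fewest-mismatch, leftmost) IUPAC-aware motif
# match, or NA when none within max_mismatch.
.best_motif_match <- function(motif, subject, max_mismatch) {
  hits <- Biostrings::matchPattern(
    Biostrings::DNAString(motif), Biostrings::DNAString(subject),
    max.mismatch = max_mismatch, fixed = FALSE)
  if (length(hits) == 0L) return(NA_integer_)
  starts <- BiocGenerics::start(hits)
  mm <- vapply(starts, function(s) {
    iupac_mismatches(substr(subject, s, s + nchar(motif) - 1L), motif)
  }, 0L)
  starts[which.min(mm)]
}

#' Variant-position table for the top haplotypes
#'
#' Aligns the `top_n` most abundant haplotype representatives (free-end-gap,
#' anchored on the most abundant one), derives the abundance-weighted
#' majority consensus per column, and lists each haplotype's differing
#' positions (1-based on the consensus) and bases, IUPAC codes included.
#'
#' @param haps a `haplotype_tbl`
#' @param top_n number of haplotypes to compare (>= 2)
#' @return a `variant_tbl`: list with `consensus` and `rows` (tibble: hap_id,
#'   n_sequences, variants list-column of tibbles position/base)
#' @export
variant_table <- function(haps, top_n = 5) {
  stopifnot(inherits(haps, "haplotype_tbl"), top_n >= 2)
  hp <- haps$haplotypes
  if (nrow(hp) < 2) {
    out <- list(consensus = if (nrow(hp)) hp$representative[1] else "",
                rows = tibble::tibble(hap_id = character(),
                                      n_sequences = integer(),
                                      variants = list()),
                note = "fewer than 2 haplotypes; nothing to compare")
    class(out) <- "variant_tbl"
    return(out)
  }
  hp <- hp[seq_len(min(top_n, nrow(hp))), ]
  anchor <- hp$representative[1]
  L <- nchar(anchor)
  # Character matrix over anchor coordinates; reps identical in length align
  # trivially, length variants are placed by free-end-gap alignment.
  mat <- matrix(NA_character_, nrow = nrow(hp), ncol = L)
  mat[1, ] <- strsplit(anchor, "")[[1]]
  for (i in seq_len(nrow(hp))[-1]) {
    r <- hp$representative[i]
    if (nchar(r) == L) {
      mat[i, ] <- strsplit(r, "")[[1]]
    } else {
      aln <- Biostrings::pairwiseAlignment(
        Biostrings::DNAString(r), Biostrings::DNAString(anchor),
        type = "overlap", substitutionMatrix = .iupac_submat(),
        gapOpening = 4, gapExtension = 2)
      pa <- strsplit(as.character(Biostrings::alignedPattern(aln)), "")[[1]]
      pb <- strsplit(as.character(Biostrings::alignedSubject(aln)), "")[[1]]
      pos <- cumsum(pb != "-")
      keep <- pb != "-" & pa != "-"
      mat[i, pos[keep]] <- pa[keep]
    }
  }
  # Abundance-weighted majority consensus.
  consensus <- vapply(seq_len(L), function(j) {
    col <- mat[, j]
    w <- tapply(hp$n_sequences[!is.na(col)], col[!is.na(col)], sum)
    names(w)[which.max(w)]
  }, "")
  rows <- lapply(seq_len(nrow(hp)), function(i) {
    col <- mat[i, ]
    diffpos <- which(!is.na(col) & col != consensus)
    tibble::tibble(position = diffpos, base = col[diffpos])
  })
  out <- list(consensus = paste(consensus, collapse = ""),
              rows = tibble::tibble(hap_id = hp$hap_id,
                                    n_sequences = hp$n_sequences,
                                    variants = rows))
  class(out) <- "variant_tbl"
  out
}

#' @export
print.variant_tbl <- function(x, ...) {
  if (!is.null(x$note)) {
    cat("<variant_tbl> ", x$note, "\n", sep = "")
    return(invisible(x))
  }
  pos <- sort(unique(unlist(lapply(x$rows$variants, `[[`, "position"))))
  cat("<variant_tbl> ", nrow(x$rows), " haplotypes; variant positions: ",
      paste(pos, collapse = " "), "\n", sep = "")
  for (i in seq_len(nrow(x$rows))) {
    v <- x$rows$variants[[i]]
    lab <- if (nrow(v)) paste(sprintf("%d%s", v$position, v$base),
                              collapse = " ") else "(consensus)"
    cat("  ", x$rows$hap_id[i], " n=", x$rows$n_sequences[i], " ", lab,
        "\n", sep = "")
  }
  invisible(x)
}

#' Compare full-length and V4 haplotype resolution
#'
#' @param full,v4 `haplotype_tbl`s built from the same member set
#'   (full-length sequences vs their extracted V4 regions)
#' @return list with `n_haplotypes_full`, `n_haplotypes_v4`,
#'   `n_members_collapsed` (members separated by full length but merged by
#'   V4), and `dominant` (per-sample dominant haplotype under each region)
#' @export
compare_resolution <- function(full, v4) {
  stopifnot(inherits(full, "haplotype_tbl"), inherits(v4, "haplotype_tbl"))
  m <- dplyr::inner_join(full$membership, v4$membership,
                         by = c("seq_id", "sample_id"),
                         suffix = c("_full", "_v4"))
  # members merged by V4 that full-length separates: count members beyond the
  # largest full-length class within each v4 class
  collapsed <- m |>
    dplyr::filter(!is.na(.data$hap_id_full), !is.na(.data$hap_id_v4)) |>
    dplyr::count(.data$hap_id_v4, .data$hap_id_full) |>
    dplyr::summarise(extra = sum(.data$n) - max(.data$n),
                     .by = "hap_id_v4")
  dominant <- function(h) {
    h$counts |>
      dplyr::slice_max(.data$count, n = 1, with_ties = FALSE,
                       by = "sample_id") |>
      dplyr::select("sample_id", "hap_id")
  }
  dom <- dplyr::full_join(dominant(full), dominant(v4), by = "sample_id",
                          suffix = c("_full", "_v4"))
  list(
    n_haplotypes_full = nrow(full$haplotypes),
    n_haplotypes_v4 = nrow(v4$haplotypes),
    n_members_collapsed = sum(collapsed$extra),
    dominant = dom
  )
}
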