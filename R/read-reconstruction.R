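# Demultiplexing, trimming and tag binning.
#
# End reads open with barcode + 10-nt tag + amplicon primer; everything else
# is an internal (tagmented) read. Binning keys on the canonical (tag5, tag3)
# pair: a read pair whose mates carry a 5' and a 3' tag defines a key,
# single-tagged pairs extend existing keys, and tag-less reads are assigned by
# k-mer containment against each bin's end-read payloads.

#' Demultiplex, trim and annotate read pairs
#'
#' A mate whose prefix is an exact sample barcode followed by a `tag_length`
#' random tag and the expected primer (at most `max_primer_mismatch`
#' IUPAC-aware mismatches) is annotated as an end read; its tag is extracted
#' and barcode/tag/primer are removed from the payload. Mates that match a
#' primer layout but no known barcode are routed to an "unassigned" pool;
#' everything else is internal. Payloads are 3'-quality trimmed with a
#' sliding window (width 4, mean phred below `quality_floor` cuts).
#'
#' @param reads tibble with read_id, r1_seq, r1_qual, r2_seq, r2_qual
#'   (see [read_fastq_pairs()]), or a `sim_library`
#' @param barcode_table tibble with sample_id, barcode5, barcode3
#' @param primers primer motif list, see [default_primers()]
#' @param quality_floor phred threshold for 3' window trimming
#' @param max_primer_mismatch maximum mismatches tolerated in the primer motif
#' @param tag_length tag length in nt
#' @return tibble of annotated reads: read_id, mate, sample_id, tag_end
#'   ("5prime", "3prime", "internal", "unassigned"), tag, payload, qual
#' @export
trim_and_annotate <- function(reads, barcode_table,
                              primers = default_primers(),
                              quality_floor = 15, max_primer_mismatch = 2,
                              tag_length = 10) {
  if (inherits(reads, "sim_library")) reads <- reads$reads
  bl <- nchar(barcode_table$barcode5[1])
  pf <- primers$forward
  pr <- primers$reverse
  annotate_mate <- function(seqs, quals, mate) {
    n <- length(seqs)
    prefix <- substr(seqs, 1, bl)
    i5 <- match(prefix, barcode_table$barcode5)
    i3 <- match(prefix, barcode_table$barcode3)
    region_f <- substr(seqs, bl + tag_length + 1L, bl + tag_length + nchar(pf))
    region_r <- substr(seqs, bl + tag_length + 1L, bl + tag_length + nchar(pr))
    mm_f <- vapply(region_f, iupac_mismatches, 0L, b = pf, USE.NAMES = FALSE)
    mm_r <- vapply(region_r, iupac_mismatches, 0L, b = pr, USE.NAMES = FALSE)
    is5 <- !is.na(i5) & mm_f <= max_primer_mismatch
    is3 <- !is.na(i3) & mm_r <= max_primer_mismatch
    unas <- is.na(i5) & is.na(i3) &
      (mm_f <= max_primer_mismatch | mm_r <= max_primer_mismatch)
    tag_end <- rep("internal", n)
    tag_end[unas] <- "unassigned"
    tag_end[is3] <- "3prime"
    tag_end[is5] <- "5prime"
    cut5 <- integer(n)
    cut5[is5] <- bl + tag_length + nchar(pf)
    cut5[is3] <- bl + tag_length + nchar(pr)
    tag <- rep(NA_character_, n)
    tag[is5 | is3] <- substr(seqs[is5 | is3], bl + 1L, bl + tag_length)
    sample_id <- rep(NA_character_, n)
    sample_id[is5] <- barcode_table$sample_id[i5[is5]]
    sample_id[is3] <- barcode_table$sample_id[i3[is3]]
    payload <- substr(seqs, cut5 + 1L, nchar(seqs))
    pq <- substr(quals, cut5 + 1L, nchar(quals))
    keep_len <- .window_trim_length(pq, quality_floor)
    payload <- substr(payload, 1L, keep_len)
    pq <- substr(pq, 1L, keep_len)
    tibble::tibble(mate = mate, sample_id = sample_id, tag_end = tag_end,
                   tag = tag, payload = payload, qual = pq)
  }
  a1 <- annotate_mate(reads$r1_seq, reads$r1_qual, "R1")
  a2 <- annotate_mate(reads$r2_seq, reads$r2_qual, "R2")
  a1$read_id <- reads$read_id
  a2$read_id <- reads$read_id
  out <- dplyr::bind_rows(a1, a2)
  out[nchar(out$payload) > 0L,
      c("read_id", "mate", "sample_id", "tag_end", "tag", "payload", "qual")]
}

# Sliding-window 3' trim: returns, per quality string, the number of leading
# characters to keep (cut at the first width-4 window whose mean phred drops
# below the floor). Fast path for the common constant-quality case.
.window_trim_length <- function(quals, floor, width = 4L) {
  n_full <- nchar(quals)
  uq <- unique(quals)
  res <- vapply(uq, function(q) {
    ph <- phred_of(q)
    L <- length(ph)
    if (L == 0L || all(ph >= floor)) return(L)
    if (L <= width) return(if (mean(ph) < floor) 0L else L)
    cs <- cumsum(ph)
    wmean <- (cs[width:L] - c(0, cs[seq_len(L - width)])) / width
    bad <- which(wmean < floor)
    if (length(bad) == 0L) L else bad[1] - 1L
  }, 0L)
  unname(res[match(quals, uq)])
}

#' Group annotated reads into tag-pair bins
#'
#' @param annotated tibble from [trim_and_annotate()]
#' @param tag_merge_distance 0 (exact tags) or 1 (a tag seen once within
#'   Hamming distance 1 of a tag seen at least `min_tag_count` times is
#'   absorbed into it)
#' @param min_tag_count bins whose key was observed fewer times are classified
#'   as error-tag bins and excluded from assembly
#' @param kmer_size k-mer length for assigning tag-less internal reads
#' @return a `tag_bins` object: list with `bins` (tibble: key_id, sample_id,
#'   tag5, tag3, count, reads list-column), `error_bins`, `tag_counts` (raw
#'   per-end tag observation counts), `n_unassigned_internal`
#' @export
bin_reads <- function(annotated, tag_merge_distance = 0, min_tag_count = 2,
                      kmer_size = 15) {
  stopifnot(tag_merge_distance %in% c(0L, 1L))
  ends <- annotated[annotated$tag_end %in% c("5prime", "3prime"), ]
  if (nrow(ends) == 0L) {
    return(structure(list(
      bins = tibble::tibble(), error_bins = tibble::tibble(),
      tag_counts = tibble::tibble(end = character(), tag = character(),
                                  count = integer()),
      n_unassigned_internal = 0L
    ), class = "tag_bins"))
  }
  # Raw per-end tag observation histogram (before any merging).
  tag_counts <- ends |>
    dplyr::count(end = .data$tag_end, tag = .data$tag, name = "count") |>
    dplyr::arrange(.data$end, dplyr::desc(.data$count))
  if (tag_merge_distance == 1L) {
    ends$tag <- .absorb_error_tags(ends$tag, ends$tag_end, min_tag_count)
  }
  # Read-pair linkage: one row per read_id with its 5' and 3' tag (if any).
  link <- ends |>
    dplyr::distinct(.data$read_id, .data$tag_end, .data$tag, .data$sample_id) |>
    tidyr::pivot_wider(names_from = "tag_end",
                       values_from = c("tag", "sample_id"),
                       values_fn = dplyr::first)
  for (col in c("tag_5prime", "tag_3prime", "sample_id_5prime",
                "sample_id_3prime")) {
    if (!col %in% names(link)) link[[col]] <- NA_character_
  }
  dual <- link[!is.na(link$tag_5prime) & !is.na(link$tag_3prime), ]
  keys <- dual |>
    dplyr::count(tag5 = .data$tag_5prime, tag3 = .data$tag_3prime,
                 sample_id = .data$sample_id_5prime, name = "count") |>
    dplyr::arrange(dplyr::desc(.data$count))
  if (nrow(keys) > 0L) keys$key_id <- sprintf("bin%05d", seq_len(nrow(keys)))
  # Map every read pair to a key: dual pairs directly, single-tag pairs via a
  # unique match on their one tag.
  pair_key <- rep(NA_character_, nrow(link))
  if (nrow(keys) > 0L) {
    dual_idx <- !is.na(link$tag_5prime) & !is.na(link$tag_3prime)
    pair_key[dual_idx] <- keys$key_id[match(
      paste(link$tag_5prime[dual_idx], link$tag_3prime[dual_idx]),
      paste(keys$tag5, keys$tag3))]
    # Single-tag pairs extend credible keys only (count >= min_tag_count);
    # count-1 error keys must not make a true tag look ambiguous.
    true_keys <- keys[keys$count >= min_tag_count, ]
    amb5 <- names(which(table(true_keys$tag5) > 1L))
    amb3 <- names(which(table(true_keys$tag3) > 1L))
    only5 <- !dual_idx & !is.na(link$tag_5prime)
    ok5 <- only5 & !(link$tag_5prime %in% amb5)
    pair_key[ok5] <- true_keys$key_id[match(link$tag_5prime[ok5],
                                            true_keys$tag5)]
    only3 <- !dual_idx & !is.na(link$tag_3prime)
    ok3 <- only3 & !(link$tag_3prime %in% amb3)
    pair_key[ok3] <- true_keys$key_id[match(link$tag_3prime[ok3],
                                            true_keys$tag3)]
  }
  read_key <- tibble::tibble(read_id = link$read_id, key_id = pair_key)
  assigned <- dplyr::left_join(annotated, read_key, by = "read_id")
  # Tag-less pairs (neither mate matched a key): k-mer containment against
  # end-read payloads of each bin.
  # "unassigned" reads (primer layout but unknown barcode — usually a
  # sequencing error inside the barcode) keep their full prefix and would
  # corrupt a consensus, so they are never assigned to bins.
  orphan <- assigned[is.na(assigned$key_id) &
                       assigned$tag_end == "internal", ]
  n_unassigned <- 0L
  if (nrow(orphan) > 0L && nrow(keys) > 0L) {
    end_assigned <- assigned[!is.na(assigned$key_id) &
                               assigned$tag_end %in% c("5prime", "3prime"), ]
    km <- .bin_kmer_map(end_assigned, kmer_size)
    hits <- vapply(orphan$payload, .vote_bin, character(1),
                   map = km, k = kmer_size, USE.NAMES = FALSE)
    orphan$key_id <- dplyr::na_if(hits, "")
    n_unassigned <- sum(is.na(orphan$key_id))
    assigned <- dplyr::rows_update(
      assigned, orphan[, c("read_id", "mate", "key_id")],
      by = c("read_id", "mate"))
  } else {
    n_unassigned <- nrow(orphan)
  }
  member <- assigned[!is.na(assigned$key_id) &
                       assigned$tag_end != "unassigned", ]
  role <- ifelse(member$tag_end == "5prime", "end5",
                 ifelse(member$tag_end == "3prime", "end3", "internal"))
  member$role <- role
  reads_by_key <- split(
    member[, c("read_id", "mate", "role", "payload", "qual")], member$key_id)
  keys$reads <- unname(reads_by_key[keys$key_id])
  keys$reads[vapply(keys$reads, is.null, TRUE)] <- list(
    tibble::tibble(read_id = character(), mate = character(),
                   role = character(), payload = character(),
                   qual = character()))
  good <- keys$count >= min_tag_count
  structure(list(
    bins = keys[good, c("key_id", "sample_id", "tag5", "tag3", "count", "reads")],
    error_bins = keys[!good, c("key_id", "sample_id", "tag5", "tag3", "count")],
    tag_counts = tag_counts,
    n_unassigned_internal = n_unassigned
  ), class = "tag_bins")
}

#' @export
print.tag_bins <- function(x, ...) {
  cat("<tag_bins> ", nrow(x$bins), " bins (",
      nrow(x$error_bins), " error-tag bins excluded, ",
      x$n_unassigned_internal, " internal reads unassigned)\n", sep = "")
  invisible(x)
}

# Rewrite tags seen exactly once to a Hamming-1 neighbour seen >= min_count.
.absorb_error_tags <- function(tags, tag_end, min_count) {
  for (end in c("5prime", "3prime")) {
    idx <- tag_end == end
    tb <- table(tags[idx])
    rare <- names(tb)[tb == 1L]
    freq <- names(tb)[tb >= min_count]
    if (length(rare) == 0L || length(freq) == 0L) next
    for (r in rare) {
      d <- vapply(freq, function(f) hamming(f, r), 0L)
      hit <- which(d == 1L)
      if (length(hit) == 1L) tags[idx & tags == r] <- freq[hit]
    }
  }
  tags
}

# kmer -> key_id map built from assigned end-read payloads (both strands).
.bin_kmer_map <- function(end_reads, k) {
  if (nrow(end_reads) == 0L) return(list(kmer = character(), key = character()))
  kms <- lapply(seq_len(nrow(end_reads)), function(i) {
    p <- end_reads$payload[i]
    unique(c(kmers_of(p, k), kmers_of(revcomp(p), k)))
  })
  key <- rep(end_reads$key_id, lengths(kms))
  kmer <- unlist(kms, use.names = FALSE)
  dup <- duplicated(paste(kmer, key))
  list(kmer = kmer[!dup], key = key[!dup])
}

# Vote a payload into the bin sharing most k-mers; "" if no unique winner.
.vote_bin <- function(payload, map, k, min_votes = 3L) {
  qk <- unique(c(kmers_of(payload, k), kmers_of(revcomp(payload), k)))
  hit <- map$key[map$kmer %in% qk]
  if (length(hit) == 0L) return("")
  tb <- sort(table(hit), decreasing = TRUE)
  if (tb[1] < min_votes) return("")
  if (length(tb) > 1L && tb[2] == tb[1]) return("")
  names(tb)[1]
}
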