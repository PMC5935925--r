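# Per-bin consensus assembly and completeness filtering.
#
# Bins hold tens of reads from (ideally) one template molecule, so a greedy
# overlap-layout-consensus is adequate: seed with the longest read, repeatedly
# place the read (either orientation) with the best ungapped overlap against
# the growing consensus, and call a per-column majority consensus with IUPAC
# codes on exact ties. The error model upstream is substitution-only, which
# is why ungapped placement suffices.

#' Assemble one tag bin into scaffolds
#'
#' @param bin_reads character vector of read payloads (any orientation), or a
#'   one-row slice of the `bins` tibble from [bin_reads()]
#' @param min_overlap minimum suffix-prefix overlap to merge (nt)
#' @param max_overlap_mismatch_rate maximum mismatch fraction inside an overlap
#' @param kmer_correction correct likely sequencing errors before layout:
#'   a base whose spanning k-mers are all observed once in the bin is replaced
#'   by the unique alternative whose k-mers are observed at least 3 times
#' @param kmer_size k-mer length for correction and overlap seeding
#' @param length_range inclusive scaffold-0 length bounds for completeness
#' @param forward_hints,reverse_hints payloads of known orientation (5' end
#'   reads are forward, 3' end reads reverse); used to orient scaffolds onto
#'   the forward amplicon strand
#' @return an `assembly_result`: list with `scaffolds` (character, sorted by
#'   decreasing length), `complete`, `reject_reason` ("none",
#'   "multi_scaffold", "length_out_of_range", "insufficient_reads"),
#'   `n_reads_used`
#' @export
assemble_bin <- function(bin_reads, min_overlap = 20,
                         max_overlap_mismatch_rate = 0.05,
                         kmer_correction = TRUE, kmer_size = 15,
                         length_range = c(1300, 1500),
                         forward_hints = character(0),
                         reverse_hints = character(0)) {
  if (is.data.frame(bin_reads)) bin_reads <- bin_reads$payload
  reads <- bin_reads[nchar(bin_reads) >= max(min_overlap, 30L)]
  if (length(reads) < 2L) {
    return(structure(list(scaffolds = character(0), complete = FALSE,
                          reject_reason = "insufficient_reads",
                          n_reads_used = length(reads)),
                     class = "assembly_result"))
  }
  if (isTRUE(kmer_correction)) {
    reads <- correct_reads_kmer(reads, k = kmer_size)
  }
  scaffolds <- character(0)
  # Deterministic processing order: length desc, then lexicographic.
  pending <- reads[order(-nchar(reads), reads)]
  while (length(pending) > 0L) {
    ctg <- .new_contig(pending[1])
    pending <- pending[-1]
    repeat {
      if (length(pending) == 0L) break
      cons <- .contig_consensus(ctg)
      pl <- .best_placements(pending, cons, kmer_size, min_overlap,
                             max_overlap_mismatch_rate)
      ok <- which(pl$overlap > 0L)
      if (length(ok) == 0L) break
      # Place every read that anchored this round (best overlap first); the
      # snapshot offsets stay valid up to the cumulative left padding.
      ok <- ok[order(-pl$overlap[ok])]
      pad <- 0L
      for (pick in ok) {
        placed <- .place_read(ctg, if (pl$rc[pick]) revcomp(pending[pick])
                                   else pending[pick],
                              pl$offset[pick] + pad)
        ctg <- placed$ctg
        pad <- pad + placed$pad
      }
      pending <- pending[-ok]
    }
    scaffolds <- c(scaffolds, .contig_consensus_string(ctg))
  }
  scaffolds <- vapply(scaffolds, .orient_scaffold, "",
                      forward_hints = forward_hints,
                      reverse_hints = reverse_hints, k = kmer_size,
                      USE.NAMES = FALSE)
  scaffolds <- scaffolds[order(-nchar(scaffolds), scaffolds)]
  reason <- "none"
  complete <- TRUE
  if (length(scaffolds) > 1L) {
    complete <- FALSE
    reason <- "multi_scaffold"
  } else if (nchar(scaffolds[1]) < length_range[1] ||
             nchar(scaffolds[1]) > length_range[2]) {
    complete <- FALSE
    reason <- "length_out_of_range"
  }
  structure(list(scaffolds = scaffolds, complete = complete,
                 reject_reason = reason, n_reads_used = length(reads)),
            class = "assembly_result")
}

#' Assemble all bins of a `tag_bins` object
#'
#' @param bins a `tag_bins` object from [bin_reads()]
#' @inheritParams assemble_bin
#' @return tibble with key_id, sample_id, tag5, tag3, n_reads, scaffolds
#'   (list-column), n_scaffolds, scaffold0_length, complete, reject_reason
#' @export
assemble_bins <- function(bins, min_overlap = 20,
                          max_overlap_mismatch_rate = 0.05,
                          kmer_correction = TRUE, kmer_size = 15,
                          length_range = c(1300, 1500)) {
  stopifnot(inherits(bins, "tag_bins"))
  res <- purrr::map(bins$bins$reads, function(rd) {
    assemble_bin(rd$payload, min_overlap, max_overlap_mismatch_rate,
                 kmer_correction, kmer_size, length_range,
                 forward_hints = rd$payload[rd$role == "end5"],
                 reverse_hints = rd$payload[rd$role == "end3"])
  })
  tibble::tibble(
    key_id = bins$bins$key_id,
    sample_id = bins$bins$sample_id,
    tag5 = bins$bins$tag5,
    tag3 = bins$bins$tag3,
    n_reads = vapply(bins$bins$reads, nrow, 0L),
    scaffolds = purrr::map(res, "scaffolds"),
    n_scaffolds = vapply(res, function(r) length(r$scaffolds), 0L),
    scaffold0_length = vapply(res, function(r)
      if (length(r$scaffolds)) nchar(r$scaffolds[1]) else 0L, 0L),
    complete = vapply(res, function(r) r$complete, TRUE),
    reject_reason = vapply(res, function(r) r$reject_reason, "")
  )
}

#' Keep complete assemblies only
#'
#' A complete assembly has exactly one scaffold whose length falls inside
#' `length_range` (inclusive).
#'
#' @param results tibble from [assemble_bins()]
#' @param length_range inclusive scaffold-0 length bounds
#' @return list with `sequences` (tibble: sample_id, key_id, tag5, tag3,
#'   sequence) and `report` (reject-reason counts and the fraction of
#'   assemblies whose scaffold 0 exceeds the lower bound)
#' @export
filter_complete <- function(results, length_range = c(1300, 1500)) {
  complete <- results$n_scaffolds == 1L &
    results$scaffold0_length >= length_range[1] &
    results$scaffold0_length <= length_range[2]
  reason <- ifelse(complete, "none", ifelse(
    results$n_scaffolds > 1L, "multi_scaffold", ifelse(
      results$n_scaffolds == 1L, "length_out_of_range", "insufficient_reads")))
  seqs <- results[complete, ]
  sequences <- tibble::tibble(
    sample_id = seqs$sample_id, key_id = seqs$key_id,
    tag5 = seqs$tag5, tag3 = seqs$tag3,
    sequence = vapply(seqs$scaffolds, function(s) s[1], "")
  )
  report <- list(
    n_assemblies = nrow(results),
    n_complete = sum(complete),
    reject_counts = table(reason[!complete]),
    fraction_over_min = mean(results$scaffold0_length >= length_range[1])
  )
  list(sequences = sequences, report = report)
}

#' Fraction of reads that map back to the assembled sequences
#'
#' A read maps back when its payload (either orientation) aligns to some
#' assembled sequence with at least `1 - max_mismatch_rate` identity over at
#' least 90% of the payload.
#'
#' @param annotated tibble from [trim_and_annotate()] (payload column used)
#' @param sequences tibble with a `sequence` column (complete assemblies)
#' @param max_mismatch_rate allowed mismatch fraction
#' @param kmer_size k-mer length for candidate selection
#' @return fraction in \[0, 1\]
#' @export
map_back_fraction <- function(annotated, sequences, max_mismatch_rate = 0.03,
                              kmer_size = 15) {
  payloads <- if (is.data.frame(annotated)) annotated$payload else annotated
  payloads <- payloads[nchar(payloads) >= kmer_size]
  if (length(payloads) == 0L) stop("no reads to map")
  refs <- if (is.data.frame(sequences)) sequences$sequence else sequences
  if (length(refs) == 0L) {
    warning("empty assembly set; map-back fraction is 0")
    return(0)
  }
  # Candidate reference per read via shared k-mers, then a banded check by
  # global-local alignment of the payload inside the candidate.
  ref_kmers <- lapply(refs, kmers_of, k = kmer_size)
  ref_of <- rep(seq_along(refs), lengths(ref_kmers))
  all_kmers <- unlist(ref_kmers, use.names = FALSE)
  pick_candidate <- function(p) {
    qk <- kmers_of(p, kmer_size)
    hit <- ref_of[all_kmers %in% c(qk, kmers_of(revcomp(p), kmer_size))]
    if (length(hit) == 0L) return(NA_integer_)
    as.integer(names(sort(table(hit), decreasing = TRUE))[1])
  }
  cand <- vapply(payloads, pick_candidate, 0L, USE.NAMES = FALSE)
  mapped <- logical(length(payloads))
  need <- (1 - max_mismatch_rate) * 0.9
  for (r in unique(cand[!is.na(cand)])) {
    idx <- which(!is.na(cand) & cand == r)
    subj <- Biostrings::DNAString(refs[r])
    for (ori in 1:2) {
      todo <- idx[!mapped[idx]]
      if (length(todo) == 0L) break
      pats <- Biostrings::DNAStringSet(
        if (ori == 1L) payloads[todo] else revcomp(payloads[todo]))
      aln <- Biostrings::pairwiseAlignment(
        pats, subj, type = "global-local",
        substitutionMatrix = .iupac_submat(), gapOpening = 6, gapExtension = 2)
      nm <- Biostrings::nmatch(aln)
      mapped[todo] <- mapped[todo] | (nm >= need * nchar(payloads[todo]))
    }
  }
  mean(mapped)
}

#' Remove residual primer motifs from assembled sequences
#'
#' Checks each sequence's prefix against the forward primer and suffix against
#' the reverse complement of the reverse primer (IUPAC-aware, at most
#' `max_mismatch` mismatches) and strips any match.
#'
#' @param sequences character vector or tibble with a `sequence` column
#' @param primers primer motif list
#' @param max_mismatch tolerated mismatches per motif
#' @return same shape as the input, trimmed
#' @export
trim_residual_primers <- function(sequences, primers = default_primers(),
                                  max_mismatch = 2) {
  seqs <- if (is.data.frame(sequences)) sequences$sequence else sequences
  pf <- primers$forward
  pr_rc <- revcomp(primers$reverse)
  trim1 <- function(s) {
    if (nchar(s) > nchar(pf) &&
        iupac_mismatches(substr(s, 1, nchar(pf)), pf) <= max_mismatch) {
      s <- substr(s, nchar(pf) + 1L, nchar(s))
    }
    n <- nchar(s)
    if (n > nchar(pr_rc) &&
        iupac_mismatches(substr(s, n - nchar(pr_rc) + 1L, n), pr_rc) <=
          max_mismatch) {
      s <- substr(s, 1L, n - nchar(pr_rc))
    }
    s
  }
  out <- vapply(seqs, trim1, "", USE.NAMES = FALSE)
  if (is.data.frame(sequences)) {
    sequences$sequence <- out
    sequences
  } else {
    out
  }
}

# ---- contig internals (ungapped layout + counted consensus) ----------------

.base_codes <- utf8ToInt("ACGT")

.new_contig <- function(seed_read) {
  v <- utf8ToInt(seed_read)
  counts <- matrix(0L, nrow = 4L, ncol = length(v))
  for (b in 1:4) counts[b, v == .base_codes[b]] <- 1L
  list(counts = counts)
}

# Place a read (already oriented) at 1-based offset `off` on the contig
# coordinate system; off may be < 1 (extends left) or extend past the end.
# Returns the updated contig and the number of columns prepended.
.place_read <- function(ctg, read, off) {
  v <- utf8ToInt(read)
  L <- ncol(ctg$counts)
  pad <- 0L
  if (off < 1L) {
    pad <- 1L - off
    ctg$counts <- cbind(matrix(0L, 4L, pad), ctg$counts)
    off <- 1L
    L <- L + pad
  }
  end <- off + length(v) - 1L
  if (end > L) {
    ctg$counts <- cbind(ctg$counts, matrix(0L, 4L, end - L))
  }
  cols <- off:end
  for (b in 1:4) {
    hit <- cols[v == .base_codes[b]]
    ctg$counts[b, hit] <- ctg$counts[b, hit] + 1L
  }
  list(ctg = ctg, pad = pad)
}

# Orient a scaffold to the forward amplicon strand using reads of known
# orientation (5' end payloads read forward, 3' end payloads reverse).
.orient_scaffold <- function(scaffold, forward_hints, reverse_hints, k) {
  if (length(forward_hints) + length(reverse_hints) == 0L) return(scaffold)
  fwd_kmers <- unique(unlist(lapply(
    c(forward_hints, if (length(reverse_hints)) revcomp(reverse_hints)),
    kmers_of, k = k), use.names = FALSE))
  score_f <- sum(kmers_of(scaffold, k) %in% fwd_kmers)
  score_r <- sum(kmers_of(revcomp(scaffold), k) %in% fwd_kmers)
  if (score_r > score_f) revcomp(scaffold) else scaffold
}

# Majority consensus; exact ties emit the IUPAC code of the tied bases.
.contig_consensus <- function(ctg) {
  cm <- ctg$counts
  mx <- apply(cm, 2L, max)
  masks <- (1L * (cm[1, ] == mx)) + (2L * (cm[2, ] == mx)) +
    (4L * (cm[3, ] == mx)) + (8L * (cm[4, ] == mx))
  masks[mx == 0L] <- 15L
  .code_by_mask[masks]
}

.contig_consensus_string <- function(ctg) {
  paste(.contig_consensus(ctg), collapse = "")
}

# For every pending read, the best ungapped placement against the consensus
# (character vector), trying both orientations, seeded by shared k-mers.
.best_placements <- function(pending, cons, k, min_overlap, max_mm_rate) {
  cons_str <- paste(cons, collapse = "")
  cons_kmers <- kmers_of(cons_str, k)
  cons_int <- utf8ToInt(cons_str)
  cons_mask <- .mask_by_code[cons_int]
  L <- length(cons_int)
  n <- length(pending)
  overlap <- integer(n); offset <- integer(n); rc <- logical(n)
  for (i in seq_len(n)) {
    best_ov <- 0L; best_off <- 0L; best_rc <- FALSE
    for (orient in 1:2) {
      r <- if (orient == 1L) pending[i] else revcomp(pending[i])
      rk <- kmers_of(r, k)
      pos <- match(rk, cons_kmers)
      hit <- which(!is.na(pos))
      if (length(hit) == 0L) next
      offs <- pos[hit] - hit + 1L
      cand <- as.integer(names(sort(table(offs), decreasing = TRUE)))
      r_mask <- .mask_by_code[utf8ToInt(r)]
      Lr <- length(r_mask)
      for (o in cand[seq_len(min(3L, length(cand)))]) {
        c_lo <- max(1L, o); c_hi <- min(L, o + Lr - 1L)
        ov <- c_hi - c_lo + 1L
        if (ov < min_overlap || ov <= best_ov) next
        r_idx <- (c_lo - o + 1L):(c_hi - o + 1L)
        mm <- sum(bitwAnd(r_mask[r_idx], cons_mask[c_lo:c_hi]) == 0L)
        if (mm / ov <= max_mm_rate) {
          best_ov <- ov; best_off <- o; best_rc <- orient == 2L
        }
      }
    }
    overlap[i] <- best_ov; offset[i] <- best_off; rc[i] <- best_rc
  }
  list(overlap = overlap, offset = offset, rc = rc)
}

#' Correct likely sequencing errors within a bin by k-mer consensus
#'
#' @param reads character vector of payloads
#' @param k k-mer length
#' @param min_trusted minimum bin-wide count for a k-mer to be trusted
#' @return corrected payloads
#' @export
correct_reads_kmer <- function(reads, k = 15, min_trusted = 3) {
  canon <- function(kms) {
    rcs <- revcomp(kms)
    ifelse(kms <= rcs, kms, rcs)
  }
  all_k <- unlist(lapply(reads, function(r) canon(kmers_of(r, k))),
                  use.names = FALSE)
  if (length(all_k) == 0L) return(reads)
  counts <- table(all_k)
  lookup <- function(kms) {
    v <- counts[canon(kms)]
    v[is.na(v)] <- 0L
    as.integer(v)
  }
  bases <- c("A", "C", "G", "T")
  vapply(reads, function(r) {
    n <- nchar(r)
    if (n < k) return(r)
    kms <- kmers_of(r, k)
    cnt <- lookup(kms)
    if (all(cnt >= 2L)) return(r)
    singles <- which(cnt == 1L)
    runs <- split(singles, cumsum(c(1L, diff(singles) != 1L)))
    for (run in runs) {
      if (length(run) > k) next  # clustered errors: leave alone
      a <- run[1]; b <- run[length(run)]
      # an isolated substitution at p makes k-mers max(1, p-k+1)..p singletons
      p <- if (a == 1L) b else a + k - 1L
      if (p > n) next
      orig <- substr(r, p, p)
      fixes <- character(0)
      for (alt in setdiff(bases, orig)) {
        cand <- r
        substr(cand, p, p) <- alt
        span <- max(1L, p - k + 1L):min(p, n - k + 1L)
        ck <- substring(cand, span, span + k - 1L)
        if (all(lookup(ck) >= min_trusted)) fixes <- c(fixes, alt)
      }
      if (length(fixes) == 1L) substr(r, p, p) <- fixes
    }
    r
  }, "", USE.NAMES = FALSE)
}
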