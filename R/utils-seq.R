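# Low-level sequence utilities shared across modules.
#
# Sequences are plain uppercase character strings over the IUPAC alphabet.
# Biostrings is used for alignment, motif matching and FASTA/FASTQ I/O;
# everything cheap (reverse complement, Hamming distance, mutation) is done
# on raw strings to avoid per-call container overhead inside tight loops.

# 4-bit presence masks: A=1, C=2, G=4, T=8.
IUPAC_MASK <- c(
  A = 1L, C = 2L, G = 4L, T = 8L,
  M = 3L, R = 5L, W = 9L, S = 6L, Y = 10L, K = 12L,
  V = 7L, H = 11L, D = 13L, B = 14L, N = 15L
)

# Lookup table indexed by utf8 code so mask conversion is a single subscript.
.mask_by_code <- local({
  tab <- integer(128)
  tab[utf8ToInt(paste(names(IUPAC_MASK), collapse = ""))] <- unname(IUPAC_MASK)
  low <- utf8ToInt(paste(tolower(names(IUPAC_MASK)), collapse = ""))
  tab[low] <- unname(IUPAC_MASK)
  tab
})

# Reverse map: mask value -> IUPAC code (index = mask).
.code_by_mask <- local({
  out <- character(15)
  out[IUPAC_MASK] <- names(IUPAC_MASK)
  out
})

#' Convert a sequence to its vector of IUPAC presence masks
#' @param x a single sequence string
#' @return integer vector, one 4-bit mask per position (0 for non-IUPAC)
#' @keywords internal
seq_masks <- function(x) {
  .mask_by_code[utf8ToInt(x)]
}

#' Are two IUPAC characters compatible (share at least one base)?
#' @keywords internal
iupac_compatible <- function(a, b) {
  bitwAnd(.mask_by_code[utf8ToInt(a)], .mask_by_code[utf8ToInt(b)]) > 0L
}

#' Count IUPAC-aware mismatches between equal-length strings
#' @keywords internal
iupac_mismatches <- function(a, b) {
  sum(bitwAnd(.mask_by_code[utf8ToInt(a)], .mask_by_code[utf8ToInt(b)]) == 0L)
}

#' Reverse complement of IUPAC strings
#'
#' @param x character vector of sequences
#' @return character vector of reverse complements
#' @export
revcomp <- function(x) {
  stringi::stri_reverse(chartr(
    "ACGTMRWSYKVHDBNacgtmrwsykvhdbn",
    "TGCAKYWSRMBDHVNtgcakywsrmbdhvn", x
  ))
}

#' Random DNA strings
#' @keywords internal
random_dna <- function(n, len) {
  if (length(len) == 1L) len <- rep.int(len, n)
  vapply(len, function(l) {
    paste(sample(c("A", "C", "G", "T"), l, replace = TRUE), collapse = "")
  }, character(1))
}

#' Hamming distance between two equal-length strings (exact characters)
#' @keywords internal
hamming <- function(a, b) {
  ia <- utf8ToInt(a); ib <- utf8ToInt(b)
  stopifnot(length(ia) == length(ib))
  sum(ia != ib)
}

#' Apply independent per-base substitutions
#'
#' Each position mutates with probability `rate` to one of the three other
#' bases, uniformly. Positions holding non-ACGT characters are left alone.
#' @keywords internal
mutate_seq <- function(x, rate) {
  if (rate <= 0) return(x)
  v <- strsplit(x, "", fixed = TRUE)[[1]]
  hit <- which(stats::runif(length(v)) < rate & v %in% c("A", "C", "G", "T"))
  if (length(hit) == 0L) return(x)
  bases <- c("A", "C", "G", "T")
  for (i in hit) {
    v[i] <- sample(setdiff(bases, v[i]), 1L)
  }
  paste(v, collapse = "")
}

#' Instantiate an IUPAC motif as a concrete ACGT string
#' @keywords internal
instantiate_motif <- function(motif) {
  m <- seq_masks(motif)
  bases <- c("A", "C", "G", "T")
  paste(vapply(m, function(mask) {
    opts <- bases[bitwAnd(mask, c(1L, 2L, 4L, 8L)) > 0L]
    if (length(opts) == 1L) opts else sample(opts, 1L)
  }, character(1)), collapse = "")
}

#' Derive a reproducible per-stage seed from the pipeline seed
#'
#' @param seed integer pipeline seed
#' @param stage stage name
#' @return integer seed below 2^31
#' @export
derive_seed <- function(seed, stage) {
  h <- sum(utf8ToInt(stage) * seq_along(utf8ToInt(stage)))
  as.integer((abs(as.numeric(seed)) * 48271 + h * 7919) %% 2147483587) + 1L
}

#' All k-mers of a string (character vector, empty if too short)
#' @keywords internal
kmers_of <- function(x, k) {
  n <- nchar(x)
  if (n < k) return(character(0))
  substring(x, 1:(n - k + 1L), k:n)
}

#' Constant-quality phred+33 string for a given error rate
#' @keywords internal
quality_string <- function(len, error_rate) {
  q <- max(2L, min(40L, as.integer(round(-10 * log10(max(error_rate, 1e-4))))))
  strrep(intToUtf8(q + 33L), len)
}

#' Phred scores of a quality string
#' @keywords internal
phred_of <- function(qual) {
  utf8ToInt(qual) - 33L
}

#' Read paired FASTQ files into a read-pair tibble
#'
#' @param r1,r2 paths to the mate FASTQ files (phred+33)
#' @return tibble with read_id, r1_seq, r1_qual, r2_seq, r2_qual
#' @export
read_fastq_pairs <- function(r1, r2) {
  s1 <- Biostrings::readDNAStringSet(r1, format = "fastq", with.qualities = TRUE)
  s2 <- Biostrings::readDNAStringSet(r2, format = "fastq", with.qualities = TRUE)
  stopifnot(length(s1) == length(s2))
  tibble::tibble(
    read_id = sub(" .*", "", names(s1)),
    r1_seq = as.character(s1),
    r1_qual = as.character(S4Vectors::mcols(s1)$qualities),
    r2_seq = as.character(s2),
    r2_qual = as.character(S4Vectors::mcols(s2)$qualities)
  )
}

#' Write a read-pair tibble as two FASTQ files
#'
#' @param reads tibble as produced by [fragment_and_sequence()]
#' @param r1,r2 output paths
#' @export
write_fastq_pairs <- function(reads, r1, r2) {
  x1 <- Biostrings::DNAStringSet(reads$r1_seq)
  names(x1) <- reads$read_id
  x2 <- Biostrings::DNAStringSet(reads$r2_seq)
  names(x2) <- reads$read_id
  Biostrings::writeXStringSet(x1, r1, format = "fastq",
    qualities = Biostrings::BStringSet(reads$r1_qual))
  Biostrings::writeXStringSet(x2, r2, format = "fastq",
    qualities = Biostrings::BStringSet(reads$r2_qual))
  invisible(c(r1, r2))
}

#' Write sequences to FASTA
#' @param seqs named character vector or tibble with id/sequence columns
#' @param path output path
#' @export
write_fasta <- function(seqs, path) {
  if (is.data.frame(seqs)) {
    x <- Biostrings::DNAStringSet(seqs$sequence)
    names(x) <- seqs$id
  } else {
    x <- Biostrings::DNAStringSet(seqs)
  }
  Biostrings::writeXStringSet(x, path)
  invisible(path)
}

#' Read a FASTA file into a tibble
#' @param path FASTA path
#' @return tibble with id and sequence
#' @export
read_fasta <- function(path) {
  x <- Biostrings::readDNAStringSet(path)
  tibble::tibble(id = names(x), sequence = as.character(x))
}
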