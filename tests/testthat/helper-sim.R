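# Shared builders for the test suite. Everything is generated in code at
# test time; sizes are kept small so the whole suite runs in minutes.

# A tiny error-free library plus its reconstruction inputs, memoised per
# session because several test files inspect different stages of it.
.sim_cache <- new.env(parent = emptyenv())

tiny_error_free_library <- function() {
  if (!is.null(.sim_cache$lib)) return(.sim_cache$lib)
  ts <- generate_reference_templates(3, 0, seed = 42)
  design <- default_study_design(1, 2, 1, 2, molecules_per_sample = 5)
  prof <- compose_samples(design, ts, seed = 42)
  bc <- make_barcode_table(unique(design$samples$sample_id), seed = 42)
  amp <- tag_and_amplify(prof, ts, bc, per_base_error = 0, chimera_rate = 0,
                         seed = 42)
  lib <- fragment_and_sequence(amp, seq_error_rate = 0, seed = 42)
  out <- list(templates = ts, design = design, profiles = prof,
              barcodes = bc, amplified = amp, lib = lib)
  .sim_cache$lib <- out
  out
}

# Deterministic reads tiling a template with generous overlaps: the simplest
# assembly input with a known exact answer.
tiling_reads <- function(template, read_len = 250, step = 150) {
  L <- nchar(template)
  starts <- unique(c(seq(1, max(1, L - read_len + 1), by = step),
                     L - read_len + 1))
  substring(template, starts, pmin(L, starts + read_len - 1))
}

# Brute-force assembly oracle for small error-free bins: over all read
# orderings, merge sequentially at the best suffix-prefix overlap and keep
# the layout with the largest total overlap.
brute_force_assemble <- function(reads, min_overlap = 10) {
  best_merge <- function(a, b) {
    # largest exact suffix(a)-prefix(b) overlap
    max_ov <- 0L
    for (ov in min(nchar(a), nchar(b)):min_overlap) {
      if (substring(a, nchar(a) - ov + 1L) == substring(b, 1, ov)) {
        max_ov <- ov
        break
      }
    }
    max_ov
  }
  perms <- function(v) {
    if (length(v) == 1L) return(list(v))
    out <- list()
    for (i in seq_along(v)) {
      for (rest in perms(v[-i])) out[[length(out) + 1L]] <- c(v[i], rest)
    }
    out
  }
  best <- NULL
  best_total <- -1L
  for (ord in perms(seq_along(reads))) {
    ctg <- reads[ord[1]]
    total <- 0L
    ok <- TRUE
    for (i in ord[-1]) {
      ov <- best_merge(ctg, reads[i])
      ov_rev <- best_merge(reads[i], ctg)
      if (ov >= ov_rev && ov >= min_overlap) {
        ctg <- paste0(ctg, substring(reads[i], ov + 1L))
        total <- total + ov
      } else if (ov_rev >= min_overlap) {
        ctg <- paste0(reads[i], substring(ctg, ov_rev + 1L))
        total <- total + ov_rev
      } else {
        ok <- FALSE
        break
      }
    }
    if (ok && total > best_total) {
      best_total <- total
      best <- ctg
    }
  }
  best
}

# Brute-force one-tailed Mann-Whitney permutation p-value.
permutation_mw_p <- function(a, b) {
  pooled <- c(a, b)
  r <- rank(pooled)
  na <- length(a)
  u_obs <- sum(r[seq_len(na)]) - na * (na + 1) / 2
  idx <- utils::combn(length(pooled), na)
  u_all <- colSums(matrix(r[idx], nrow = na)) - na * (na + 1) / 2
  mean(u_all >= u_obs - 1e-9)
}

# Construct an annotated-read prefix: barcode + tag + primer.
end_read <- function(barcode, tag, primer, payload) {
  paste0(barcode, tag, primer, payload)
}
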