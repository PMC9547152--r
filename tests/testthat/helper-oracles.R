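# Shared generators and independent oracles used across the suite.

RNA_BASES <- c("A", "C", "G", "U")
RNA_COMP <- c(A = "U", U = "A", C = "G", G = "C")

random_rna <- function(n, alphabet = RNA_BASES) {
  paste(sample(alphabet, n, replace = TRUE), collapse = "")
}

# Padding that can create neither a C box (needs G) nor a CUGA within
# one mismatch (needs at least 3 of C,U,G,A in register; {A,C} strings
# always miss the U and the G).
safe_padding <- function(n) {
  if (n == 0L) return("")
  paste(sample(c("A", "C"), n, replace = TRUE), collapse = "")
}

revcomp_rna <- function(x) {
  paste(rev(RNA_COMP[strsplit(x, "")[[1]]]), collapse = "")
}

# Independent exhaustive-window duplex oracle: tests every target
# window base by base, entirely separate from the package scan.
brute_force_duplex <- function(element, target, min_core,
                               max_terminal_mismatches,
                               allow_wobble = FALSE) {
  el <- strsplit(element, "")[[1]]
  tg <- strsplit(target, "")[[1]]
  L <- length(el)
  res <- list()
  for (s in seq_len(length(tg) - L + 1L)) {
    paired <- logical(L)
    for (e in seq_len(L)) {
      tb <- tg[s + L - e]
      paired[e] <- RNA_COMP[[el[e]]] == tb ||
        (allow_wobble && ((el[e] == "G" && tb == "U") ||
                          (el[e] == "U" && tb == "G")))
    }
    best <- 0L; run <- 0L
    for (e in seq_len(L)) {
      run <- if (paired[e]) run + 1L else 0L
      best <- max(best, run)
    }
    mism <- which(!paired)
    in_zone <- all(mism <= max_terminal_mismatches |
                     mism > L - max_terminal_mismatches)
    if (best >= min_core && in_zone)
      res[[length(res) + 1L]] <- data.frame(
        target_start = s, core_length = best,
        n_mismatches = length(mism),
        mismatch_positions = paste(mism, collapse = ","))
  }
  out <- do.call(rbind, res)
  if (is.null(out))
    out <- data.frame(target_start = integer(), core_length = integer(),
                      n_mismatches = integer(),
                      mismatch_positions = character())
  out[order(-out$core_length, out$target_start), , drop = FALSE]
}

# A valid random tRNA record: 60-100 nt with a known anticodon substring.
random_trna_record <- function(id, len = sample(60:100, 1)) {
  seq <- random_rna(len)
  pos <- sample(seq_len(len - 2L), 1L)
  trna_record(id, seq, anticodon = substr(seq, pos, pos + 2L))
}

# Minimal two-reference setup with a shared block for multimapper tests.
make_multimap_refs <- function() {
  set.seed(991)
  shared <- random_rna(20)
  a_left <- random_rna(25); a_right <- random_rna(25)
  b_left <- random_rna(25); b_right <- random_rna(25)
  refA <- trna_record("refA", paste0(a_left, shared, a_right))
  refB <- trna_record("refB", paste0(b_left, shared, b_right))
  stopifnot(!grepl(substr(refA$sequence, 1, 20), refB$sequence, fixed = TRUE),
            !grepl(substr(refB$sequence, 1, 20), refA$sequence, fixed = TRUE))
  list(refA = refA, refB = refB, shared = shared)
}
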