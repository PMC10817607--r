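#' Reverse complement of DNA strings
#'
#' Vectorised reverse complement over plain character vectors. `N` is preserved.
#'
#' @param x Character vector of DNA sequences (A/C/G/T/N).
#' @return Character vector of the same length.
#' @export
revcomp <- function(x) {
  if (length(x) == 0L) return(character(0))
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

#' Random DNA sequence with a target GC fraction
#'
#' Bases are drawn i.i.d. with P(G) = P(C) = gc/2. Uses the current RNG state,
#' so results are reproducible under `set.seed()`.
#'
#' @param n Sequence length in bp.
#' @param gc Target GC fraction in `[0, 1]`.
#' @return A single character string of length `n`.
#' @export
random_dna <- function(n, gc = 0.5) {
  stopifnot(is_count(n), gc >= 0, gc <= 1)
  if (n == 0L) return("")
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE,
               prob = c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)),
        collapse = "")
}

#' GC fraction of sequences
#'
#' `N` bases are excluded from the denominator; an all-N sequence yields `NaN`.
#'
#' @param x Character vector of DNA sequences.
#' @return Numeric vector of GC fractions.
#' @export
gc_fraction <- function(x) {
  if (length(x) == 0L) return(numeric(0))
  ss <- Biostrings::DNAStringSet(x)
  gc <- Biostrings::letterFrequency(ss, letters = c("G", "C"))
  nn <- Biostrings::letterFrequency(ss, letters = "N")
  as.numeric(rowSums(gc) / (Biostrings::width(ss) - as.numeric(nn)))
}

# per-position mismatch count of `unit` laid at every start of `seq`
# (0-based starts 0..n-k); any non-matching character, including N, counts as
# a mismatch. Returns integer vector of length n-k+1 (empty if seq shorter).
frame_mismatches <- function(seq, unit) {
  s <- utf8ToInt(seq)
  u <- utf8ToInt(unit)
  k <- length(u)
  n <- length(s)
  if (n < k) return(integer(0))
  m <- n - k + 1L
  mm <- integer(m)
  for (j in seq_len(k)) {
    mm <- mm + as.integer(s[j:(m + j - 1L)] != u[j])
  }
  mm
}

# tandem-run length (in units) starting at every position: a run is a maximal
# chain of unit-length frames spaced exactly |unit| apart, each frame within
# `max_mismatch` mismatches of the unit; no insertions/deletions between
# frames. Returns integer vector aligned with frame_mismatches().
tandem_run_lengths <- function(seq, unit, max_mismatch = 0L) {
  mm <- frame_mismatches(seq, unit)
  if (length(mm) == 0L) return(integer(0))
  ok <- mm <= max_mismatch
  k <- nchar(unit)
  out <- integer(length(ok))
  for (r in seq_len(min(k, length(ok)))) {
    idx <- seq.int(r, length(ok), by = k)
    out[idx] <- run_start_lengths(ok[idx])
  }
  out
}

# maximum tandem copy count of `unit` anywhere in `seq`
max_tandem_copies <- function(seq, unit, max_mismatch = 0L) {
  runs <- tandem_run_lengths(seq, unit, max_mismatch)
  if (length(runs) == 0L) 0L else max(runs)
}
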