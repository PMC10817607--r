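#' Locate rDNA-unit matches and total matched length
#'
#' Seed-and-extend matching of the repeat unit against each sequence (both
#' strands); overlapping or abutting hits on the same sequence are merged
#' before length summation, so a read carrying three tandem unit copies
#' yields one merged hit of three unit lengths. `L_total` is the sum of
#' merged hit lengths over all sequences — the "total length of rDNA" of the
#' blast-coverage copy-number method.
#'
#' @param sequences Sequences to scan: a `"genome"`, a named character
#'   vector, or a read tibble (`read_id`, `seq`).
#' @param unit_seq The repeat-unit sequence (e.g. the 5,701 bp rDNA unit).
#' @param seed_k Exact seed length.
#' @param min_identity Minimum gapless identity of a projected unit copy.
#' @param min_hit_len Minimum hit length in bp.
#' @return List of class `"rdna_hits"`: `hits` (per-copy intervals), `merged`
#'   (per-sequence merged intervals, kind `rdna_hit`) and `L_total` (bp).
#' @export
find_unit_hits <- function(sequences, unit_seq, seed_k = 31L, min_identity = 0.9,
                           min_hit_len = 100L) {
  unit_seq <- toupper(unit_seq)
  if (length(unique(strsplit(unit_seq, "")[[1]])) == 1L) {
    cs_warn("repeat unit is a homopolymer; merged hit lengths will be inflated")
  }
  hits <- seed_extend_hits(sequences, unit_seq, seed_k = seed_k,
                           min_identity = min_identity, min_len = min_hit_len)
  if (nrow(hits) == 0L) {
    merged <- interval_track(kind = "rdna_hit")
  } else {
    merged <- merge_intervals(
      tibble(chrom = hits$seqname, start = hits$start, end = hits$end,
             strand = ".", label = NA_character_, kind = "rdna_hit"))
  }
  structure(list(hits = hits, merged = merged,
                 L_total = sum(merged$end - merged$start)),
            class = "rdna_hits")
}

#' @export
print.rdna_hits <- function(x, ...) {
  cat(sprintf("<rdna_hits> %d raw hits, %d merged, L_total = %s bp\n",
              nrow(x$hits), nrow(x$merged), format(x$L_total, big.mark = ",")))
  invisible(x)
}

#' rDNA copy number from the blast-coverage formula
#'
#' `copy_number = L_total / (C * U)` rounded to the nearest integer, where
#' `L_total` is the total merged length of unit matches in the reads, `C` the
#' genome-wide average read coverage and `U` the repeat-unit length. The
#' unrounded ratio is reported alongside.
#'
#' @param L_total Total matched length in bp (or an `"rdna_hits"` object).
#' @param C Average genome coverage (fold); must be positive.
#' @param U Repeat-unit length in bp; must be positive.
#' @return One-row tibble of class `"rdna_estimate"`: `U`, `C`, `L_total`,
#'   `ratio`, `copy_number`.
#' @export
rdna_copy_number <- function(L_total, C, U) {
  if (inherits(L_total, "rdna_hits")) L_total <- L_total$L_total
  if (!is.numeric(C) || C <= 0) cs_stop("coverage C must be positive")
  if (!is.numeric(U) || U <= 0) cs_stop("unit length U must be positive")
  if (L_total < 0) cs_stop("L_total must be non-negative")
  ratio <- L_total / (C * U)
  out <- tibble(U = U, C = C, L_total = L_total, ratio = ratio,
                copy_number = as.integer(round_half_up(ratio)))
  class(out) <- unique(c("rdna_estimate", class(out)))
  out
}

#' Flag chromosome ends terminating in rDNA repeats
#'
#' Reports, per chromosome end, the fraction of the terminal window covered
#' by merged unit hits; ends above `min_frac` are flagged as rDNA-terminal
#' (the signature of an end whose terminal repeats displaced the telomere in
#' the assembly).
#'
#' @param genome A `"genome"`.
#' @param unit_seq Repeat-unit sequence.
#' @param window Terminal window in bp.
#' @param min_frac Coverage fraction above which an end is flagged.
#' @param ... Passed to [find_unit_hits()].
#' @return Tibble `chrom`, `side`, `covered_frac`, `rdna_terminal`.
#' @export
terminal_rdna_check <- function(genome, unit_seq, window = 10000L,
                                min_frac = 0.5, ...) {
  genome <- as_genome(genome)
  lens <- genome_lengths(genome)
  if (window > min(lens)) cs_stop("window exceeds the shortest chromosome")
  res <- find_unit_hits(genome, unit_seq, ...)
  purrr::map_dfr(names(lens), function(ch) {
    L <- lens[[ch]]
    cov5 <- covered_bp(res$merged, ch, 0, window)
    cov3 <- covered_bp(res$merged, ch, L - window, L)
    tibble(chrom = ch, side = c("5prime", "3prime"),
           covered_frac = c(cov5, cov3) / window,
           rdna_terminal = c(cov5, cov3) / window > min_frac)
  })
}
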