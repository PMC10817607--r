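#' Detect telomeric repeat arrays at chromosome ends
#'
#' The 5' end of each chromosome is scanned for a tandem run of `unit`
#' (default `CCCTAA`) and the 3' end for its reverse complement (`TTAGGG`).
#' A tandem run is a maximal chain of unit-length frames spaced exactly
#' `nchar(unit)` apart, each within `max_mismatch_frac * nchar(unit)`
#' mismatches of the unit, with no insertions or deletions between frames.
#' An end is reported `present` iff a run of at least `min_copies` units
#' starts within `window` bp of the terminus (for the 3' end: ends within
#' `window` bp of it); `copies` is the length of the best such run in units.
#'
#' The scan is strand-consistent by construction: the 3' end is scanned by
#' reverse-complementing the chromosome and re-applying the 5' rule, so
#' reverse-complementing a chromosome exactly swaps its two end reports.
#'
#' @param genome A `"genome"`.
#' @param unit Telomere repeat unit (ACGT only).
#' @param window Terminal scan window in bp.
#' @param min_copies Minimum tandem copies for a positive call.
#' @param max_mismatch_frac Per-unit mismatch budget as a fraction of unit
#'   length (N counts as a mismatch).
#' @return A tibble of class `"telomere_report"` with one row per chromosome
#'   end: `chrom`, `side`, `present`, `copies`, `start`, `end`; the total
#'   number of telomeric ends is in attribute `n_present`.
#' @export
detect_telomeres <- function(genome, unit = "CCCTAA", window = 1000L,
                             min_copies = 5L, max_mismatch_frac = 1 / 6) {
  genome <- as_genome(genome)
  unit <- toupper(unit)
  if (grepl("[^ACGT]", unit)) cs_stop("telomere unit must contain only A, C, G, T")
  if (nchar(unit) < 4L) cs_stop("telomere unit must be at least 4 bp")
  lens <- genome_lengths(genome)
  if (window > min(lens)) cs_stop("scan window exceeds the shortest chromosome")
  max_mm <- floor(max_mismatch_frac * nchar(unit))

  scan5 <- function(seq) {
    # frames only need to be computed over the window plus the longest
    # possible run extension
    k <- nchar(unit)
    runs <- tandem_run_lengths(seq, unit, max_mm)
    if (length(runs) == 0L) return(list(present = FALSE, copies = 0L, start = NA, end = NA))
    lim <- min(window, length(runs))
    cand <- which(runs[seq_len(lim)] >= min_copies)
    if (length(cand) == 0L) return(list(present = FALSE, copies = 0L, start = NA, end = NA))
    best <- cand[which.max(runs[cand])]
    list(present = TRUE, copies = runs[best],
         start = best - 1L, end = best - 1L + k * runs[best])
  }

  rows <- purrr::map_dfr(names(genome), function(ch) {
    s <- chrom_seq(genome, ch)
    L <- nchar(s)
    five <- scan5(s)
    three <- scan5(revcomp(s))
    tibble(chrom = ch,
           side = c("5prime", "3prime"),
           present = c(five$present, three$present),
           copies = c(five$copies, three$copies),
           start = c(five$start, if (three$present) L - three$end else NA),
           end = c(five$end, if (three$present) L - three$start else NA))
  })
  attr(rows, "n_present") <- sum(rows$present)
  class(rows) <- unique(c("telomere_report", class(rows)))
  rows
}

#' Extract and orient telomere-bearing reads
#'
#' A read is extracted iff it contains at least `min_copies_read` tandem
#' copies of `unit` or of its reverse complement anywhere in the read
#' (scattered non-tandem units do not count). Reads matching the
#' reverse-complement form more strongly are reverse-complemented before
#' inclusion, so every library member carries the motif as `unit` reading
#' from its 5' side. The library is deduplicated by read id.
#'
#' @param reads Tibble with `read_id`, `seq` (e.g. from [simulate_reads()] or
#'   [read_reads_fastq()]).
#' @param unit Telomere repeat unit.
#' @param min_copies_read Minimum tandem copies for extraction.
#' @param max_mismatch Per-unit mismatch budget (exact by default).
#' @return Tibble `read_id`, `seq`, `copies`, `oriented` (TRUE if the read
#'   was reverse-complemented).
#' @export
extract_telomeric_reads <- function(reads, unit = "CCCTAA", min_copies_read = 10L,
                                    max_mismatch = 0L) {
  stopifnot(all(c("read_id", "seq") %in% names(reads)), min_copies_read >= 1L)
  unit <- toupper(unit)
  runit <- revcomp(unit)
  fwd <- vapply(reads$seq, max_tandem_copies, 0L, unit = unit,
                max_mismatch = max_mismatch, USE.NAMES = FALSE)
  rev <- vapply(reads$seq, max_tandem_copies, 0L, unit = runit,
                max_mismatch = max_mismatch, USE.NAMES = FALSE)
  hit <- pmax(fwd, rev) >= min_copies_read
  out <- tibble(read_id = reads$read_id[hit],
                seq = ifelse(rev[hit] > fwd[hit], revcomp(reads$seq[hit]),
                             reads$seq[hit]),
                copies = pmax(fwd, rev)[hit],
                oriented = rev[hit] > fwd[hit])
  distinct(out, read_id, .keep_all = TRUE)
}

#' Patch a telomere-missing chromosome end from a read library
#'
#' Implements an anchored-extension telomere rescue: the terminal
#' `anchor_len` bp of the named end are matched against each library read
#' (exact seed of the terminal `seed_len` bp, then gapless extension over the
#' full anchor at identity >= `min_anchor_identity`). Among anchored reads
#' whose distal portion terminates in a telomere array, the one extending the
#' chromosome farthest is spliced on (ties: highest anchor identity, then
#' lexicographically smallest read id). If no read anchors, the genome is
#' returned unchanged with a no-patch report. Patching never alters any other
#' chromosome and never shortens the named one.
#'
#' @param genome A `"genome"`.
#' @param chrom Chromosome to patch.
#' @param side `"5prime"` or `"3prime"`.
#' @param library Oriented read library from [extract_telomeric_reads()].
#' @param anchor_len Anchor length in bp.
#' @param min_anchor_identity Minimum anchor identity in `[0, 1]`.
#' @param seed_len Exact-seed length in bp.
#' @param unit Telomere unit used to verify the extension and to refuse
#'   patching an already-telomeric end.
#' @param min_copies Tandem copies required of the extension terminus.
#' @return List with `genome` (patched or unchanged) and `report` (one-row
#'   tibble: `chrom`, `side`, `patched`, `read_id`, `extension_bp`,
#'   `anchor_identity`).
#' @export
patch_missing_telomere <- function(genome, chrom, side = c("5prime", "3prime"),
                                   library, anchor_len = 500L,
                                   min_anchor_identity = 0.95, seed_len = 20L,
                                   unit = "CCCTAA", min_copies = 5L) {
  genome <- as_genome(genome)
  side <- match.arg(side)
  rep0 <- detect_telomeres(genome[chrom] |> as_genome(), unit = unit,
                           min_copies = min_copies)
  if (rep0$present[rep0$side == side]) {
    cs_stop("end %s:%s already carries a telomere; refusing to patch", chrom, side)
  }
  no_patch <- tibble(chrom = chrom, side = side, patched = FALSE,
                     read_id = NA_character_, extension_bp = 0L,
                     anchor_identity = NA_real_)
  if (is.null(library) || nrow(library) == 0L) {
    return(list(genome = genome, report = no_patch))
  }

  s <- chrom_seq(genome, chrom)
  work <- if (side == "5prime") revcomp(s) else s  # patch the 3' end of `work`
  L <- nchar(work)
  stopifnot(anchor_len >= seed_len, L > anchor_len)
  anchor <- substr(work, L - anchor_len + 1L, L)
  seedseq <- substr(work, L - seed_len + 1L, L)
  anchor_int <- utf8ToInt(anchor)
  runit <- revcomp(unit)  # a 3'-end extension terminates in TTAGGG-form units

  best <- NULL
  for (i in seq_len(nrow(library))) {
    # genome-oriented candidate: telomere motif moves to the read's 3' side
    cand <- revcomp(library$seq[i])
    occ <- gregexpr(seedseq, cand, fixed = TRUE)[[1]]
    if (occ[1] == -1L) next
    for (o in as.integer(occ)) {
      q <- o + seed_len - 1L  # read position aligned with the chromosome end
      if (q < anchor_len) next
      seg <- utf8ToInt(substr(cand, q - anchor_len + 1L, q))
      ident <- mean(seg == anchor_int)
      if (ident < min_anchor_identity) next
      ext <- substr(cand, q + 1L, nchar(cand))
      if (nchar(ext) == 0L) next
      # the extension must terminate in a telomere array
      tail_rep <- detect_telomeres(as_genome(c(x = ext)), unit = unit,
                                   window = min(nchar(ext), 60L),
                                   min_copies = min_copies)
      if (!tail_rep$present[tail_rep$side == "3prime"]) next
      rec <- list(read_id = library$read_id[i], ext = ext, identity = ident)
      if (is.null(best) ||
          nchar(rec$ext) > nchar(best$ext) ||
          (nchar(rec$ext) == nchar(best$ext) && rec$identity > best$identity) ||
          (nchar(rec$ext) == nchar(best$ext) && rec$identity == best$identity &&
             rec$read_id < best$read_id)) {
        best <- rec
      }
    }
  }
  if (is.null(best)) {
    return(list(genome = genome, report = no_patch))
  }
  patched_work <- paste0(work, best$ext)
  g <- unclass(genome)
  g[[chrom]] <- if (side == "5prime") revcomp(patched_work) else patched_work
  list(genome = as_genome(g),
       report = tibble(chrom = chrom, side = side, patched = TRUE,
                       read_id = best$read_id,
                       extension_bp = nchar(best$ext),
                       anchor_identity = best$identity))
}
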