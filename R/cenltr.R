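#' Find centromeric LTR monomer hits
#'
#' Seed-and-extend local matching of the monomer consensus (both strands)
#' against the genome. Overlapping hits are reduced to the best-scoring one
#' (identity x consensus coverage); surviving hits are classified `complete`
#' (consensus coverage >= `complete_cov` and identity >= `min_identity`) or
#' `shorter` (coverage in `[short_cov, complete_cov)`).
#'
#' @param genome A `"genome"`.
#' @param consensus_seq Monomer consensus, 50--2,000 bp, at most 20% N.
#' @param min_identity Minimum gapless identity.
#' @param complete_cov,short_cov Consensus-coverage cutoffs for the
#'   complete/shorter classes.
#' @param seed_k,stride Seeding parameters (see the package vignette).
#' @return Tibble of class `"ltr_hits"`: `chrom`, `start`, `end`, `strand`,
#'   `identity`, `coverage`, `class`.
#' @export
find_monomers <- function(genome, consensus_seq, min_identity = 0.8,
                          complete_cov = 0.8, short_cov = 0.4,
                          seed_k = 21L, stride = 7L) {
  consensus_seq <- toupper(consensus_seq)
  U <- nchar(consensus_seq)
  if (U < 50L || U > 2000L) cs_stop("consensus must be 50-2000 bp")
  n_frac <- stringr::str_count(consensus_seq, "N") / U
  if (n_frac > 0.2) cs_stop("consensus contains more than 20%% N")
  hits <- seed_extend_hits(as_genome(genome), consensus_seq, seed_k = seed_k,
                           stride = stride, min_identity = min_identity,
                           min_len = max(20L, floor(short_cov * U)))
  hits <- hits[hits$coverage >= short_cov, , drop = FALSE]
  if (nrow(hits) > 0L) {
    hits <- hits |>
      mutate(score = identity * coverage) |>
      group_by(seqname) |>
      dplyr::group_modify(~ reduce_overlaps(.x)) |>
      ungroup() |>
      select(-score)
  }
  out <- hits |>
    rename(chrom = seqname) |>
    mutate(class = ifelse(coverage >= complete_cov, "complete", "shorter")) |>
    arrange(chrom, start)
  class(out) <- unique(c("ltr_hits", class(out)))
  out
}

# keep the best-scoring hit among mutually overlapping candidates
# (>50% of the shorter hit shared)
reduce_overlaps <- function(h) {
  h <- arrange(h, dplyr::desc(score), start)
  keep <- logical(nrow(h))
  for (i in seq_len(nrow(h))) {
    ov <- which(keep & pmin(h$end[seq_len(nrow(h))], h$end[i]) -
                  pmax(h$start[seq_len(nrow(h))], h$start[i]) >
                  0.5 * pmin(h$end - h$start, h$end[i] - h$start[i]))
    if (length(ov) == 0L) keep[i] <- TRUE
  }
  arrange(h[keep, , drop = FALSE], start)
}

#' Assemble monomer hits into paired and solo LTR elements
#'
#' Greedy left-to-right pairing: for each unused hit, the nearest downstream
#' same-strand hit whose separation lies in `[internal_min, internal_max]`
#' and whose sequence aligns to the first at identity >=
#' `ltr_pair_identity` becomes its partner; hits that find no partner are
#' emitted as solo elements. Every hit is consumed by exactly one element.
#' Paired elements are checked for structural hallmarks of an intact element:
#' an identical flanking target-site duplication of `tsr_min`..`tsr_max` bp,
#' a primer-binding-site motif within 20 bp downstream of the 5' LTR (only
#' when `pbs_motif` is supplied; otherwise reported `NA`), a polypurine tract
#' (purine run >= `ppt_min_len` bp) within 30 bp upstream of the 3' LTR, and
#' the marker-domain order GAG-INT-RT-RH inside the internal region (when
#' `domain_motifs` is supplied). Minus-strand elements are evaluated on the
#' reverse-complemented element sequence, so all checks are strand-symmetric.
#'
#' @param hits An `"ltr_hits"` tibble from [find_monomers()].
#' @param genome The `"genome"` the hits refer to.
#' @param internal_min,internal_max Allowed internal-region span (bp).
#' @param ltr_pair_identity Minimum identity between the two LTR copies.
#' @param tsr_min,tsr_max Target-site-duplication length bounds (bp).
#' @param pbs_motif Optional primer-binding-site motif (exact match).
#' @param domain_motifs Optional named character vector
#'   `c(GAG=, INT=, RT=, RH=)` of domain marker sequences (exact match).
#' @param ppt_min_len Minimum polypurine-tract run (bp).
#' @return Tibble of class `"ltr_elements"`: one row per element with `type`
#'   (`paired`/`solo`), genome-forward coordinates of the LTRs and internal
#'   region, `tsr`, and flags `tsr_found`, `pbs_found`, `ppt_found`,
#'   `domain_order_ok`.
#' @export
pair_elements <- function(hits, genome, internal_min = 1000L, internal_max = 15000L,
                          ltr_pair_identity = 0.85, tsr_min = 4L, tsr_max = 6L,
                          pbs_motif = NULL, domain_motifs = NULL,
                          ppt_min_len = 10L) {
  genome <- as_genome(genome)
  hits <- arrange(hits, chrom, start)
  n <- nrow(hits)
  used <- logical(n)
  rows <- list()
  hit_seq <- function(i) {
    s <- substr(chrom_seq(genome, hits$chrom[i]), hits$start[i] + 1L, hits$end[i])
    if (hits$strand[i] == "-") revcomp(s) else s
  }
  pair_identity <- function(i, j) {
    a <- utf8ToInt(hit_seq(i)); b <- utf8ToInt(hit_seq(j))
    m <- min(length(a), length(b))
    mean(a[seq_len(m)] == b[seq_len(m)])
  }
  for (i in seq_len(n)) {
    if (used[i]) next
    partner <- NA_integer_
    j <- i + 1L
    while (!is.na(j) && j <= n && hits$chrom[j] == hits$chrom[i]) {
      gap <- hits$start[j] - hits$end[i]
      if (gap > internal_max) break
      if (!used[j] && hits$strand[j] == hits$strand[i] &&
          gap >= internal_min && pair_identity(i, j) >= ltr_pair_identity) {
        partner <- j
        break
      }
      j <- j + 1L
    }
    used[i] <- TRUE
    if (is.na(partner)) {
      rows[[length(rows) + 1L]] <-
        tibble(chrom = hits$chrom[i], type = "solo", strand = hits$strand[i],
               start = hits$start[i], end = hits$end[i],
               ltr5_start = hits$start[i], ltr5_end = hits$end[i],
               ltr3_start = NA_real_, ltr3_end = NA_real_,
               internal_start = NA_real_, internal_end = NA_real_,
               tsr = NA_character_, tsr_found = NA, pbs_found = NA,
               ppt_found = NA, domain_order_ok = NA)
      next
    }
    used[partner] <- TRUE
    rows[[length(rows) + 1L]] <-
      check_paired_element(genome, hits, i, partner, tsr_min, tsr_max,
                           pbs_motif, domain_motifs, ppt_min_len)
  }
  out <- if (length(rows)) arrange(bind_rows(rows), chrom, start) else
    tibble(chrom = character(0), type = character(0), strand = character(0),
           start = numeric(0), end = numeric(0))
  class(out) <- unique(c("ltr_elements", class(out)))
  out
}

check_paired_element <- function(genome, hits, i, j, tsr_min, tsr_max,
                                 pbs_motif, domain_motifs, ppt_min_len) {
  ch <- hits$chrom[i]
  seq <- chrom_seq(genome, ch)
  L <- nchar(seq)
  s0 <- hits$start[i]; e1 <- hits$end[j]
  strand <- hits$strand[i]
  flank <- min(tsr_max, s0, L - e1)
  # element plus flanks, oriented so transcription reads left to right
  es <- substr(seq, s0 - flank + 1L, e1 + flank)
  if (strand == "-") es <- revcomp(es)
  elen <- e1 - s0
  w5 <- if (strand == "+") hits$end[i] - hits$start[i] else hits$end[j] - hits$start[j]
  w3 <- if (strand == "+") hits$end[j] - hits$start[j] else hits$end[i] - hits$start[i]
  internal <- substr(es, flank + w5 + 1L, flank + elen - w3)

  tsr <- NA_character_
  if (flank >= tsr_min) {
    for (len in seq(flank, tsr_min)) {
      up <- substr(es, flank - len + 1L, flank)
      dn <- substr(es, flank + elen + 1L, flank + elen + len)
      if (identical(up, dn)) { tsr <- up; break }
    }
  }
  pbs_found <- if (is.null(pbs_motif)) NA else {
    zone <- substr(internal, 1L, 20L + nchar(pbs_motif))
    grepl(pbs_motif, zone, fixed = TRUE)
  }
  ppt_zone <- substr(internal, max(1L, nchar(internal) - 30L + 1L), nchar(internal))
  ppt_found <- grepl(sprintf("[AG]{%d,}", ppt_min_len), ppt_zone)
  domain_order_ok <- if (is.null(domain_motifs)) NA else {
    pos <- vapply(domain_motifs, function(m) {
      regexpr(m, internal, fixed = TRUE)[1]
    }, 0L)
    all(pos > 0L) && !is.unsorted(pos, strictly = TRUE)
  }
  tibble(chrom = ch, type = "paired", strand = strand,
         start = s0, end = e1,
         ltr5_start = if (strand == "+") hits$start[i] else hits$start[j],
         ltr5_end = if (strand == "+") hits$end[i] else hits$end[j],
         ltr3_start = if (strand == "+") hits$start[j] else hits$start[i],
         ltr3_end = if (strand == "+") hits$end[j] else hits$end[i],
         internal_start = hits$end[i], internal_end = hits$start[j],
         tsr = tsr, tsr_found = !is.na(tsr), pbs_found = pbs_found,
         ppt_found = ppt_found, domain_order_ok = domain_order_ok)
}

#' Centromere co-location of LTR elements
#'
#' Counts, per chromosome, the elements whose span overlaps the called
#' centromere region, plus the global fraction inside.
#'
#' @param elements An `"ltr_elements"` tibble.
#' @param calls A `"centromere_calls"` tibble (or any tibble with `chrom`,
#'   `start`, `end` regions).
#' @return List with `per_chrom` (tibble `chrom`, `n_inside`, `n_outside`)
#'   and `fraction_inside`.
#' @export
centromere_colocation <- function(elements, calls) {
  regions <- calls[!is.na(calls$start), c("chrom", "start", "end")]
  inside <- vapply(seq_len(nrow(elements)), function(i) {
    r <- regions[regions$chrom == elements$chrom[i], , drop = FALSE]
    any(r$start < elements$end[i] & r$end > elements$start[i])
  }, TRUE)
  per_chrom <- elements |>
    mutate(inside = inside) |>
    group_by(chrom) |>
    summarise(n_inside = sum(inside), n_outside = sum(!inside), .groups = "drop")
  list(per_chrom = per_chrom,
       fraction_inside = if (nrow(elements)) mean(inside) else NA_real_)
}

#' Per-chromosome monomer and element copy table
#'
#' Tabulates complete/shorter monomer hits and paired/solo elements per
#' chromosome. Totals always equal the input cardinalities (each paired
#' element consumes two hits, each solo element one).
#'
#' @param elements An `"ltr_elements"` tibble.
#' @param hits The `"ltr_hits"` tibble the elements were built from.
#' @return Tibble `chrom`, `n_complete`, `n_shorter`, `n_paired`, `n_solo`,
#'   `n_hits`.
#' @export
copy_table <- function(elements, hits) {
  chroms <- sort(unique(c(hits$chrom, elements$chrom)))
  purrr::map_dfr(chroms, function(ch) {
    h <- hits[hits$chrom == ch, , drop = FALSE]
    e <- elements[elements$chrom == ch, , drop = FALSE]
    tibble(chrom = ch,
           n_complete = sum(h$class == "complete"),
           n_shorter = sum(h$class == "shorter"),
           n_paired = sum(e$type == "paired"),
           n_solo = sum(e$type == "solo"),
           n_hits = nrow(h))
  })
}
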