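#' Binned read depth from an alignment table
#'
#' Bin depth is the total overlap (bp) of alignments with the bin divided by
#' the bin width; the final partial bin is normalised by its true width, so
#' total aligned bp is exactly conserved by binning:
#' `sum(depth * width) == sum(aligned bp)`.
#'
#' @param alignments Alignment tibble (`chrom`, `start`, `end`, 0-based
#'   half-open; e.g. from [read_alignment_table()] or [simulate_reads()]), or
#'   an existing `"depth_track"` (returned unchanged).
#' @param genome A `"genome"` defining chromosome lengths.
#' @param bin_size Bin width in bp (default 10 kb).
#' @return A `"depth_track"` tibble with attribute `genome_mean`, the
#'   length-weighted mean depth (total aligned bp / genome length).
#' @export
bin_depth <- function(alignments, genome, bin_size = 10000L) {
  genome <- as_genome(genome)
  if (inherits(alignments, "depth_track")) return(alignments)
  lens <- genome_lengths(genome)
  unknown <- setdiff(unique(alignments$chrom), names(lens))
  if (length(unknown)) {
    i <- which(alignments$chrom == unknown[1])[1]
    cs_stop("alignment %d references unknown chromosome '%s'", i, unknown[1])
  }
  if (any(alignments$start < 0 | alignments$end > lens[alignments$chrom])) {
    cs_stop("alignment outside chromosome bounds")
  }
  rows <- purrr::map_dfr(names(lens), function(ch) {
    L <- lens[[ch]]
    b <- tile_bins(L, bin_size)
    al <- alignments[alignments$chrom == ch, , drop = FALSE]
    if (nrow(al) == 0L) {
      return(tibble(chrom = ch, start = b$start, end = b$end, depth = 0))
    }
    cvg <- IRanges::coverage(IRanges::IRanges(al$start + 1L, al$end), width = L)
    v <- as.numeric(cvg)
    cums <- c(0, cumsum(v))
    sums <- cums[b$end + 1L] - cums[b$start + 1L]
    tibble(chrom = ch, start = b$start, end = b$end,
           depth = sums / (b$end - b$start))
  })
  out <- depth_track(rows, bin_size, genome)
  attr(out, "genome_mean") <- sum(rows$depth * (rows$end - rows$start)) / sum(lens)
  out
}

#' Flag low-coverage bins as local coverage anomalies
#'
#' In `absolute` mode a bin is anomalous iff its depth is strictly below
#' `threshold` (the field rule of thumb: 10 kb bins below 80x against a
#' genome-wide average of 248x). In `fraction` mode the cutoff is
#' `threshold * genome_mean`, for runs at other depths. Adjacent flagged bins
#' are merged into one interval. Flagging is monotone in the threshold.
#'
#' @param depth A `"depth_track"` from [bin_depth()].
#' @param mode `"absolute"` or `"fraction"`.
#' @param threshold Depth cutoff (absolute fold, or fraction of the genome
#'   mean).
#' @return An `"interval_track"` of kind `"anomaly"`.
#' @export
flag_anomalies <- function(depth, mode = c("absolute", "fraction"), threshold = 80) {
  mode <- match.arg(mode)
  stopifnot(inherits(depth, "depth_track"))
  if (threshold <= 0) cs_stop("threshold must be positive")
  cut <- if (mode == "absolute") threshold else {
    gm <- attr(depth, "genome_mean") %||%
      (sum(depth$depth * (depth$end - depth$start)) / sum(depth$end - depth$start))
    threshold * gm
  }
  flagged <- depth[depth$depth < cut, c("chrom", "start", "end")]
  if (nrow(flagged) == 0L) {
    return(interval_track(kind = "anomaly"))
  }
  merge_intervals(mutate(flagged, strand = ".", label = NA_character_,
                         kind = "anomaly"))
}

#' Flag bins dominated by mapping-quality-0 reads
#'
#' A bin is flagged iff it is overlapped by at least one read and the
#' fraction of overlapping reads with `mapq == 0` is at least
#' `min_mq0_fraction`. MQ0 dominance marks regions where reads map
#' ambiguously, the signature of collapsed repeats or local assembly errors.
#'
#' @param alignments Alignment tibble with a `mapq` column.
#' @param genome A `"genome"`.
#' @param bin_size Bin width in bp.
#' @param min_mq0_fraction Minimum MQ0 read fraction.
#' @return An `"interval_track"` of kind `"anomaly"` (label `mq0`), adjacent
#'   flagged bins merged.
#' @export
flag_mq0_bins <- function(alignments, genome, bin_size = 10000L,
                          min_mq0_fraction = 0.8) {
  genome <- as_genome(genome)
  stopifnot("mapq" %in% names(alignments))
  lens <- genome_lengths(genome)
  rows <- purrr::map_dfr(names(lens), function(ch) {
    b <- tile_bins(lens[[ch]], bin_size)
    al <- alignments[alignments$chrom == ch, , drop = FALSE]
    if (nrow(al) == 0L) return(tibble())
    bins <- IRanges::IRanges(b$start + 1L, b$end)
    reads <- IRanges::IRanges(al$start + 1L, al$end)
    ov <- IRanges::findOverlaps(bins, reads)
    qh <- S4Vectors::queryHits(ov)
    mq0 <- al$mapq[S4Vectors::subjectHits(ov)] == 0L
    n_all <- tapply(mq0, qh, length)
    n_mq0 <- tapply(mq0, qh, sum)
    idx <- as.integer(names(n_all))
    hitbin <- idx[(n_mq0 / n_all) >= min_mq0_fraction]
    if (length(hitbin) == 0L) return(tibble())
    tibble(chrom = ch, start = b$start[hitbin], end = b$end[hitbin])
  })
  if (nrow(rows) == 0L) return(interval_track(kind = "anomaly"))
  out <- merge_intervals(mutate(rows, strand = ".", label = "mq0", kind = "anomaly"))
  out$label <- "mq0"
  out
}

#' Read mapping-rate accounting
#'
#' Percentages are `100 * count / n_total`, reported to two decimals with
#' half-up rounding.
#'
#' @param n_nuclear Reads aligned to the nuclear assembly.
#' @param n_mito Reads aligned to the mitochondrial genome.
#' @param n_total Total filtered reads (`n_nuclear + n_mito <= n_total`).
#' @return One-row tibble of class `"mapping_rates"`: counts plus
#'   `pct_nuclear`, `pct_mito`, `pct_unmapped`.
#' @export
mapping_rates <- function(n_nuclear, n_mito, n_total) {
  stopifnot(is_count(n_nuclear), is_count(n_mito), is_count(n_total))
  if (n_total == 0) cs_stop("n_total must be positive")
  if (n_nuclear + n_mito > n_total) cs_stop("mapped reads exceed the total")
  n_unmapped <- n_total - n_nuclear - n_mito
  out <- tibble(n_total = n_total, n_nuclear = n_nuclear, n_mito = n_mito,
                n_unmapped = n_unmapped,
                pct_nuclear = round_half_up(100 * n_nuclear / n_total, 2),
                pct_mito = round_half_up(100 * n_mito / n_total, 2),
                pct_unmapped = round_half_up(100 * n_unmapped / n_total, 2))
  class(out) <- unique(c("mapping_rates", class(out)))
  out
}
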