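#' Depth tracks
#'
#' A depth track is a tibble with columns `chrom`, `start`, `end`, `depth`,
#' covering each chromosome with `ceiling(length / bin_size)` tiled bins (the
#' final bin may be partial and keeps its true width). The bin size is stored
#' in the `bin_size` attribute.
#'
#' @param tbl Tibble with `chrom`, `start`, `end`, `depth`.
#' @param bin_size Bin width in bp.
#' @param genome Optional genome to validate bin tiling against.
#' @return A tibble of class `"depth_track"`.
#' @export
depth_track <- function(tbl, bin_size, genome = NULL) {
  stopifnot(all(c("chrom", "start", "end", "depth") %in% names(tbl)))
  if (any(tbl$depth < 0)) cs_stop("depths must be non-negative")
  if (!is.null(genome)) {
    lens <- genome_lengths(genome)
    nb <- table(factor(tbl$chrom, levels = names(lens)))
    expect <- ceiling(lens / bin_size)
    if (any(as.integer(nb) != expect)) {
      cs_stop("depth track does not tile the genome at bin size %d", bin_size)
    }
  }
  tbl <- arrange(as_tibble(tbl), chrom, start)
  attr(tbl, "bin_size") <- as.integer(bin_size)
  class(tbl) <- unique(c("depth_track", class(tbl)))
  tbl
}

#' Read a depth track from bedGraph
#'
#' @param path bedGraph file (0-based half-open intervals with a score).
#' @param bin_size Bin size; inferred from the modal interval width when `NULL`.
#' @return A `"depth_track"` tibble.
#' @export
read_bedgraph <- function(path, bin_size = NULL) {
  if (!file.exists(path)) cs_stop("no such file: %s", path)
  gr <- rtracklayer::import(path, format = "bedGraph")
  tbl <- tibble(chrom = as.character(GenomicRanges::seqnames(gr)),
                start = BiocGenerics::start(gr) - 1L,
                end = BiocGenerics::end(gr),
                depth = as.numeric(S4Vectors::mcols(gr)$score))
  if (is.null(bin_size)) {
    w <- tbl$end - tbl$start
    bin_size <- as.integer(names(sort(table(w), decreasing = TRUE))[1])
  }
  depth_track(tbl, bin_size)
}

#' Write a depth track to bedGraph
#'
#' @param track A `"depth_track"` tibble.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_bedgraph <- function(track, path) {
  gr <- GenomicRanges::GRanges(track$chrom,
                               IRanges::IRanges(track$start + 1L, track$end),
                               score = track$depth)
  rtracklayer::export(gr, path, format = "bedGraph")
  invisible(path)
}

# bin boundaries tiling a chromosome, 0-based half-open
tile_bins <- function(len, bin_size) {
  nb <- ceiling(len / bin_size)
  start <- (seq_len(nb) - 1L) * bin_size
  tibble(start = start, end = pmin(start + bin_size, len))
}

# mean of a depth track over arbitrary windows on one chromosome
# (weighted by overlap width); windows must not be empty
depth_window_mean <- function(track, chrom, start, end) {
  tr <- track[track$chrom == chrom, , drop = FALSE]
  out <- rep(NA_real_, length(start))
  if (nrow(tr) == 0L) return(out)
  win <- IRanges::IRanges(start + 1L, end)
  src <- IRanges::IRanges(tr$start + 1L, tr$end)
  ov <- IRanges::findOverlaps(win, src)
  w <- IRanges::width(IRanges::pintersect(win[S4Vectors::queryHits(ov)],
                                          src[S4Vectors::subjectHits(ov)]))
  num <- tapply(w * tr$depth[S4Vectors::subjectHits(ov)], S4Vectors::queryHits(ov), sum)
  den <- tapply(w, S4Vectors::queryHits(ov), sum)
  out[as.integer(names(num))] <- as.numeric(num) / as.numeric(den)
  out
}
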