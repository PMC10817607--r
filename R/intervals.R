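#' Interval tracks
#'
#' An interval track is a tibble with columns `chrom`, `start`, `end`
#' (0-based half-open), `strand` (`+`, `-` or `.`), `label` and `kind`
#' (`gene`, `repeat`, `anomaly`, `ltr_hit`, `rdna_hit`, `telomere`), sorted by
#' `(chrom, start)`. Construction validates `0 <= start < end` and, when a
#' genome is supplied, that every interval fits its chromosome.
#'
#' @param chrom,start,end,strand,label,kind Column vectors (recycled where
#'   length 1).
#' @param genome Optional `"genome"` for bounds validation.
#' @return A tibble of class `"interval_track"`.
#' @export
interval_track <- function(chrom = character(0), start = integer(0), end = integer(0),
                           strand = ".", label = NA_character_, kind = NA_character_,
                           genome = NULL) {
  tr <- tibble(chrom = as.character(chrom), start = as.numeric(start),
               end = as.numeric(end), strand = as.character(strand),
               label = as.character(label), kind = as.character(kind))
  validate_intervals(tr, genome)
}

validate_intervals <- function(tr, genome = NULL) {
  if (nrow(tr) > 0) {
    if (any(!tr$strand %in% c("+", "-", "."))) cs_stop("strand must be one of +, -, .")
    bad <- which(tr$start < 0 | tr$start >= tr$end)
    if (length(bad)) {
      cs_stop("invalid interval %s:[%s, %s): need 0 <= start < end",
              tr$chrom[bad[1]], tr$start[bad[1]], tr$end[bad[1]])
    }
    if (!is.null(genome)) {
      lens <- genome_lengths(genome)
      unknown <- setdiff(unique(tr$chrom), names(lens))
      if (length(unknown)) cs_stop("interval on unknown chromosome '%s'", unknown[1])
      over <- which(tr$end > lens[tr$chrom])
      if (length(over)) {
        cs_stop("interval %s:[%s, %s) extends past chromosome end (%d bp)",
                tr$chrom[over[1]], tr$start[over[1]], tr$end[over[1]],
                lens[[tr$chrom[over[1]]]])
      }
    }
  }
  tr <- arrange(tr, chrom, start)
  class(tr) <- unique(c("interval_track", class(tr)))
  tr
}

#' Read intervals from BED or GFF3
#'
#' BED is parsed as 0-based half-open (the internal convention); GFF3 is
#' converted from 1-based closed coordinates. Output is sorted by
#' `(chrom, start)`, stably on ties.
#'
#' @param path Input file.
#' @param dialect `"bed"` or `"gff3"`.
#' @param genome Optional genome for chromosome validation.
#' @param kind Track kind recorded in the `kind` column; for GFF3 the feature
#'   `type` column is used when `kind` is `NULL`.
#' @return An `"interval_track"` tibble.
#' @export
read_intervals <- function(path, dialect = c("bed", "gff3"), genome = NULL, kind = NULL) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) cs_stop("no such file: %s", path)
  gr <- rtracklayer::import(path, format = if (dialect == "bed") "bed" else "gff3")
  md <- S4Vectors::mcols(gr)
  label <- if (dialect == "bed") {
    if ("name" %in% names(md)) as.character(md$name) else NA_character_
  } else {
    if ("Name" %in% names(md)) as.character(md$Name) else NA_character_
  }
  k <- if (!is.null(kind)) kind else if (dialect == "gff3") as.character(md$type) else NA_character_
  strand <- as.character(BiocGenerics::strand(gr))
  strand[strand == "*"] <- "."
  interval_track(chrom = as.character(GenomicRanges::seqnames(gr)),
                 start = BiocGenerics::start(gr) - 1L,
                 end = BiocGenerics::end(gr),
                 strand = strand, label = label, kind = k, genome = genome)
}

#' Write intervals to BED or GFF3
#'
#' Internal 0-based half-open coordinates are converted back at the boundary,
#' so a GFF3 line read with [read_intervals()] and written again regains its
#' original 1-based closed coordinates exactly.
#'
#' @param track An `"interval_track"` tibble.
#' @param path Output file.
#' @param dialect `"bed"` or `"gff3"`.
#' @return `path`, invisibly.
#' @export
write_intervals <- function(track, path, dialect = c("bed", "gff3")) {
  dialect <- match.arg(dialect)
  gr <- track_to_granges(track)
  if (dialect == "bed") {
    S4Vectors::mcols(gr)$name <- ifelse(is.na(track$label), ".", track$label)
    rtracklayer::export(gr, path, format = "bed")
  } else {
    S4Vectors::mcols(gr)$source <- "centroscan"
    S4Vectors::mcols(gr)$type <- ifelse(is.na(track$kind), "region", track$kind)
    if (!all(is.na(track$label))) S4Vectors::mcols(gr)$Name <- track$label
    rtracklayer::export(gr, path, format = "gff3")
  }
  invisible(path)
}

track_to_granges <- function(track) {
  strand <- ifelse(track$strand == ".", "*", track$strand)
  GenomicRanges::GRanges(track$chrom,
                         IRanges::IRanges(start = track$start + 1L, end = track$end),
                         strand = strand)
}

# merge overlapping or abutting intervals per chromosome (strand-blind)
merge_intervals <- function(track) {
  if (nrow(track) == 0L) return(track)
  out <- track |>
    group_by(chrom) |>
    dplyr::reframe({
      ir <- IRanges::reduce(IRanges::IRanges(start = start + 1L, end = end),
                            min.gapwidth = 1L)
      tibble(start = BiocGenerics::start(ir) - 1L, end = BiocGenerics::end(ir))
    }) |>
    mutate(strand = ".", label = NA_character_,
           kind = if (nrow(track)) track$kind[1] else NA_character_)
  validate_intervals(out)
}

# total bp covered by intervals of `track` within [start, end) on `chrom`
covered_bp <- function(track, chrom, start, end) {
  tr <- track[track$chrom == chrom, , drop = FALSE]
  if (nrow(tr) == 0L) return(numeric(length(start)))
  red <- IRanges::reduce(IRanges::IRanges(tr$start + 1L, tr$end))
  win <- IRanges::IRanges(start + 1L, end)
  ov <- IRanges::findOverlaps(win, red)
  w <- IRanges::width(IRanges::pintersect(win[S4Vectors::queryHits(ov)],
                                          red[S4Vectors::subjectHits(ov)]))
  out <- numeric(length(start))
  agg <- tapply(w, S4Vectors::queryHits(ov), sum)
  out[as.integer(names(agg))] <- as.numeric(agg)
  out
}
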