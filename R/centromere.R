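#' Windowed sequence-feature tracks
#'
#' Computes, per non-overlapping window: GC fraction (non-N denominator),
#' gene density and repeat density (covered bp / window width) and mean
#' transcription depth. These are the sequence characteristics that mark
#' centromeres: high repeat content, reduced gene density, low GC and minimal
#' transcription.
#'
#' @param genome A `"genome"`.
#' @param gene_track,repeat_track `"interval_track"`s validated against the
#'   genome.
#' @param rna_depth A `"depth_track"` of transcription depth whose bin size
#'   divides `window` (or `NULL` to skip).
#' @param window Window width in bp; the final window of each chromosome may
#'   be partial.
#' @return Tibble of class `"feature_tracks"` (`chrom`, `start`, `end`, `gc`,
#'   `gene_density`, `repeat_density`, `rna_depth`) with attribute `window`.
#' @export
compute_feature_tracks <- function(genome, gene_track = NULL, repeat_track = NULL,
                                   rna_depth = NULL, window = 10000L) {
  genome <- as_genome(genome)
  lens <- genome_lengths(genome)
  if (window > max(lens)) cs_warn("window exceeds every chromosome; single truncated windows")
  if (!is.null(rna_depth)) {
    rb <- attr(rna_depth, "bin_size")
    if (!is.null(rb) && window %% rb != 0L) {
      cs_stop("feature window (%d) must be a multiple of the RNA bin size (%d)",
              window, rb)
    }
  }
  out <- purrr::map_dfr(names(lens), function(ch) {
    L <- lens[[ch]]
    b <- tile_bins(L, window)
    v <- Biostrings::Views(Biostrings::DNAString(chrom_seq(genome, ch)),
                           start = b$start + 1L, end = b$end)
    gcn <- Biostrings::letterFrequency(v, c("G", "C", "N"))
    gc <- (gcn[, "G"] + gcn[, "C"]) / pmax(b$end - b$start - gcn[, "N"], 1)
    gd <- if (is.null(gene_track)) NA_real_ else
      covered_bp(gene_track, ch, b$start, b$end) / (b$end - b$start)
    rd <- if (is.null(repeat_track)) NA_real_ else
      covered_bp(repeat_track, ch, b$start, b$end) / (b$end - b$start)
    tx <- if (is.null(rna_depth)) NA_real_ else
      depth_window_mean(rna_depth, ch, b$start, b$end)
    tibble(chrom = ch, start = b$start, end = b$end, gc = as.numeric(gc),
           gene_density = gd, repeat_density = rd, rna_depth = tx)
  })
  attr(out, "window") <- as.integer(window)
  class(out) <- unique(c("feature_tracks", class(out)))
  out
}

#' Observed/expected transformation of a contact matrix
#'
#' For cis pairs the expected count at distance `|i - j|` bins is the mean
#' observed count over that diagonal within the chromosome, so the
#' per-diagonal mean of cis OE values is exactly 1 wherever defined
#' (self-normalisation). For trans pairs the expected count is the mean over
#' all trans entries. `OE = observed / (expected + epsilon)`. Two per-bin
#' summary scores are attached: the mean OE over all trans partners and the
#' mean OE over cis partners at distance >= `d_min` bins (`NA` when the
#' chromosome has no pair that distant).
#'
#' @param cm A `"contact_matrix"`.
#' @param d_min Minimum cis distance (bins) for the long-range cis score.
#' @param epsilon Guard against division by zero.
#' @return List of class `"oe_matrix"`: `oe` (matrix), `bins` (tibble with
#'   `trans_score`, `cis_score`), `bin_size`, `chroms`.
#' @export
compute_oe <- function(cm, d_min = 50L, epsilon = 1e-9) {
  stopifnot(inherits(cm, "contact_matrix"))
  if (all(cm$counts == 0)) cs_stop("no signal: contact matrix is all zero")
  bins <- contact_bins(cm)
  n <- nrow(bins)
  same <- outer(bins$chrom, bins$chrom, "==")
  d <- abs(outer(bins$bin, bins$bin, "-"))
  expected <- matrix(NA_real_, n, n)
  trans_mean <- mean(cm$counts[!same])
  expected[!same] <- trans_mean
  for (ch in unique(bins$chrom)) {
    idx <- which(bins$chrom == ch)
    block <- cm$counts[idx, idx, drop = FALSE]
    db <- d[idx, idx, drop = FALSE]
    diag_means <- tapply(block, db, mean)
    expected[idx, idx] <- diag_means[as.character(db)]
  }
  oe <- cm$counts / (expected + epsilon)
  trans_score <- vapply(seq_len(n), function(i) mean(oe[i, !same[i, ]]), 0.0)
  cis_score <- vapply(seq_len(n), function(i) {
    far <- same[i, ] & d[i, ] >= d_min
    if (!any(far)) NA_real_ else mean(oe[i, far])
  }, 0.0)
  bins$trans_score <- trans_score
  bins$cis_score <- cis_score
  structure(list(oe = oe, bins = bins, bin_size = cm$bin_size,
                 chroms = cm$chroms),
            class = "oe_matrix")
}

#' Predict centromere regions from OE intensity and sequence features
#'
#' Per chromosome, a combined interaction-intensity score (the mean of the
#' per-bin trans OE score and long-range cis OE score, on the OE scale) is
#' median-centred; a 3-bin moving mean locates the candidate peak bin (ties
#' break toward the chromosome middle, then the lower index) while peak
#' height and region growth use the unsmoothed centred score, whose noise
#' scale is well defined. The call is grown in both directions while the
#' centred score stays at or above `peak_fraction` of the peak height. A
#' chromosome yields no call when its peak does not exceed the background
#' (peak height below `min_peak_mads` robust deviations of the centred
#' score). Sequence
#' evidence flags compare the candidate region's mean GC, gene density,
#' repeat density and transcription against the chromosome means (strict
#' inequalities in the centromeric direction); a call is retained when at
#' least `min_evidence` flags pass. Calls whose midpoint lies in the
#' outermost `edge_frac` of the chromosome are annotated low-confidence — edge centromeres are
#' the known failure mode of OE-based prediction.
#'
#' @param oe An `"oe_matrix"` from [compute_oe()].
#' @param features A `"feature_tracks"` on the same windowing (or `NULL` to
#'   skip sequence evidence).
#' @param peak_fraction Region-growing threshold as a fraction of the peak.
#' @param min_evidence Minimum sequence-evidence flags for retention (0--4).
#' @param min_peak_mads Peak height requirement in units of the median
#'   absolute deviation of the centred per-bin score.
#' @param smooth_bins Moving-mean width (bins).
#' @param edge_frac Outermost fraction of the chromosome annotated low-confidence.
#' @return Tibble of class `"centromere_calls"`, one row per chromosome:
#'   `chrom`, `called`, `start`, `end`, `midpoint`, `R` (midpoint /
#'   chromosome length), `score`, evidence flags `ev_gc`, `ev_gene`,
#'   `ev_repeat`, `ev_rna`, `n_evidence`, `retained`, `low_confidence`.
#' @export
call_centromere <- function(oe, features = NULL, peak_fraction = 0.5,
                            min_evidence = 2L, min_peak_mads = 4,
                            smooth_bins = 3L, edge_frac = 0.05) {
  stopifnot(inherits(oe, "oe_matrix"))
  if (!is.null(features)) {
    if (attr(features, "window") != oe$bin_size) {
      cs_stop("feature window (%d) and OE bin size (%d) differ",
              attr(features, "window"), oe$bin_size)
    }
  }
  purrr::map_dfr(seq_len(nrow(oe$chroms)), function(ci) {
    ch <- oe$chroms$chrom[ci]
    L <- oe$chroms$length[ci]
    b <- oe$bins[oe$bins$chrom == ch, , drop = FALSE]
    n <- nrow(b)
    combined <- rowMeans(cbind(b$trans_score, b$cis_score), na.rm = TRUE)
    centred <- combined - median(combined)
    sm <- moving_mean(centred, smooth_bins)
    # noise scale from the unsmoothed centred scores: robust to the peak
    # occupying a sizeable fraction of a short chromosome
    spread <- mad(centred)
    cand <- which(sm == max(sm))
    mid_bin <- (n + 1) / 2
    peak <- cand[order(abs(cand - mid_bin), cand)][1]
    # snap to the raw maximum within the smoothing support: the smoothed
    # argmax can sit one bin off a single-bin peak
    half <- (smooth_bins - 1L) %/% 2L
    win <- max(1L, peak - half):min(n, peak + half)
    wc <- win[centred[win] == max(centred[win])]
    peak <- wc[order(abs(wc - mid_bin), wc)][1]
    peak_val <- centred[peak]
    no_call <- tibble(chrom = ch, called = FALSE, start = NA_real_,
                      end = NA_real_, midpoint = NA_real_, R = NA_real_,
                      score = peak_val, ev_gc = NA, ev_gene = NA,
                      ev_repeat = NA, ev_rna = NA, n_evidence = NA_integer_,
                      retained = FALSE, low_confidence = NA)
    if (peak_val <= 0 || (spread > 0 && peak_val < min_peak_mads * spread) ||
        spread == 0) {
      return(no_call)
    }
    # grow on the unsmoothed centred score: smoothing is for peak finding
    # only, and would bleed the region boundary into flanking bins
    lo <- peak
    while (lo > 1L && centred[lo - 1L] >= peak_fraction * peak_val) lo <- lo - 1L
    hi <- peak
    while (hi < n && centred[hi + 1L] >= peak_fraction * peak_val) hi <- hi + 1L
    rs <- b$start[lo]
    re <- b$end[hi]
    midpoint <- (rs + re) / 2
    flags <- c(ev_gc = NA, ev_gene = NA, ev_repeat = NA, ev_rna = NA)
    if (!is.null(features)) {
      f <- features[features$chrom == ch, , drop = FALSE]
      inreg <- f$start >= rs & f$end <= re
      cand_mean <- function(x) mean(x[inreg])
      chrom_mean <- function(x) mean(x)
      flags["ev_gc"] <- !all(is.na(f$gc)) && cand_mean(f$gc) < chrom_mean(f$gc)
      flags["ev_gene"] <- !all(is.na(f$gene_density)) &&
        cand_mean(f$gene_density) < chrom_mean(f$gene_density)
      flags["ev_repeat"] <- !all(is.na(f$repeat_density)) &&
        cand_mean(f$repeat_density) > chrom_mean(f$repeat_density)
      flags["ev_rna"] <- !all(is.na(f$rna_depth)) &&
        cand_mean(f$rna_depth) < chrom_mean(f$rna_depth)
    }
    n_ev <- sum(flags, na.rm = TRUE)
    tibble(chrom = ch, called = TRUE, start = rs, end = re,
           midpoint = midpoint, R = midpoint / L, score = peak_val,
           ev_gc = flags[["ev_gc"]], ev_gene = flags[["ev_gene"]],
           ev_repeat = flags[["ev_repeat"]], ev_rna = flags[["ev_rna"]],
           n_evidence = n_ev,
           retained = is.null(features) || n_ev >= min_evidence,
           low_confidence = midpoint <= edge_frac * L ||
             midpoint >= (1 - edge_frac) * L)
  }) -> out
  class(out) <- unique(c("centromere_calls", class(out)))
  out
}

#' Levan arm classification from a centromere midpoint
#'
#' Arm lengths are normalised to 10 units: `s = 10 * min(m, L - m) / L`,
#' `l = 10 - s`, with arm difference `d = l - s` and arm ratio `r = l / s`.
#' Chromosome type follows the d intervals: `[0, 2.5]` metacentric,
#' `(2.5, 5.0]` submetacentric, `(5.0, 7.5]` subtelocentric, `(7.5, 10)`
#' acrocentric. Values are reported to two decimals (half-up) and the type is
#' assigned from the rounded d. The classification is mirror-invariant:
#' reflecting the chromosome leaves `(s, l, d, r, type)` unchanged.
#'
#' @param chrom_length Chromosome length (bp); vectorised.
#' @param midpoint Centromere midpoint (bp), strictly inside the chromosome.
#' @return Tibble `s`, `l`, `d`, `r`, `type` (one row per input).
#' @export
classify_arms <- function(chrom_length, midpoint) {
  stopifnot(length(chrom_length) == length(midpoint))
  if (any(midpoint <= 0 | midpoint >= chrom_length)) {
    cs_stop("centromere midpoint must lie strictly inside the chromosome")
  }
  s <- 10 * pmin(midpoint, chrom_length - midpoint) / chrom_length
  levan_classify(s, 10 - s)
}

#' @rdname classify_arms
#' @param s,l Short- and long-arm lengths on the 10-unit normalisation
#'   (`s + l = 10`, `s <= l`).
#' @export
levan_classify <- function(s, l) {
  stopifnot(length(s) == length(l))
  if (any(abs(s + l - 10) > 1e-6)) cs_stop("arm lengths must satisfy s + l = 10")
  if (any(s > l)) cs_stop("short arm s must not exceed long arm l")
  if (any(s <= 0)) cs_stop("short arm s must be positive")
  d <- round_half_up(l - s, 2)
  r <- round_half_up(l / s, 2)
  type <- dplyr::case_when(d <= 2.5 ~ "metacentric",
                           d <= 5.0 ~ "submetacentric",
                           d <= 7.5 ~ "subtelocentric",
                           TRUE ~ "acrocentric")
  tibble(s = round_half_up(s, 2), l = round_half_up(l, 2), d = d, r = r,
         type = type)
}

#' Table-shaped centromere report
#'
#' Combines centromere calls and arm classification into the conventional
#' per-chromosome report: length, s, l, d, r, R and type.
#'
#' @param calls A `"centromere_calls"` tibble.
#' @param genome The `"genome"` the calls refer to.
#' @return Tibble with one row per called chromosome.
#' @export
centromere_report <- function(calls, genome) {
  lens <- genome_lengths(genome)
  called <- calls[calls$called, , drop = FALSE]
  if (nrow(called) == 0L) return(tibble())
  cls <- classify_arms(as.numeric(lens[called$chrom]), called$midpoint)
  dplyr::bind_cols(tibble(chrom = called$chrom,
                          length = as.numeric(lens[called$chrom])),
                   cls,
                   tibble(R = round_half_up(called$R, 3),
                          low_confidence = called$low_confidence))
}
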