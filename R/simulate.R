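#' Simulation parameters
#'
#' Parameters of the synthetic genome generator. The defaults describe a
#' miniature genome with the statistical structure the analysis stages assume:
#' three chromosomes of 300--500 kb at 56% background GC, 30-copy terminal
#' telomere arrays (`CCCTAA` at 5' ends, `TTAGGG` at 3' ends), one 10 kb
#' low-GC centromere per chromosome carrying a planted array of 427 bp LTR
#' monomers in paired and solo configurations, a 5,701 bp rDNA unit repeated
#' in a terminal tandem array, ~30x long reads with an occasional
#' collapsed-repeat coverage dip, and Hi-C matrices with power-law distance
#' decay plus centromere--centromere enrichment.
#'
#' @param seed Integer seed (mandatory); one root seed drives per-component
#'   sub-generators, so regenerating one component never perturbs the others.
#' @param chrom_lengths Named vector of chromosome lengths (bp).
#' @param gc_background Background GC fraction.
#' @param telomere_unit 5'-end telomere repeat unit.
#' @param telomere_copies Tandem copies planted at each end.
#' @param centromere_fraction Midpoint position of each centromere as a
#'   fraction of chromosome length (recycled).
#' @param centromere_width,centromere_gc Centromere span (bp) and GC fraction.
#' @param ltr_monomer_length Length of the centromeric LTR monomer consensus.
#' @param ltr_layout Per-chromosome list of planted element descriptors, each
#'   `list(type = "paired", internal_length =, tsr_length =, strand =)` or
#'   `list(type = "solo", strand =)`.
#' @param rdna_unit_length,rdna_copies rDNA repeat unit length and tandem copy
#'   count.
#' @param rdna_chrom,rdna_side Chromosome and end (`"3prime"`/`"5prime"`)
#'   carrying the terminal rDNA array; `rdna_chrom = NA` disables it.
#' @param rdna_divergence Per-base substitution rate applied independently to
#'   each rDNA copy (0 = exact tandem duplicates).
#' @param read_length_mean,read_length_sd,read_min_length Read length model (bp).
#' @param read_depth Target fold coverage.
#' @param read_error_rate Per-base i.i.d. substitution rate in reads.
#' @param anomaly_regions Tibble `chrom, start, end, depth_factor` of coverage
#'   anomalies (reads originating there are thinned by `depth_factor`).
#' @param mq0_regions Tibble `chrom, start, end`; reads originating there are
#'   emitted with mapping quality 0 (collapsed-repeat emulation).
#' @param hic_bin_size Hi-C bin size (bp).
#' @param hic_decay_exponent Cis contact decay exponent `alpha`:
#'   `E[count] = hic_cis_scale * d^-alpha` at distance `d` bins.
#' @param hic_cen_enrichment Multiplier applied to bin pairs where both bins
#'   overlap a centromere.
#' @param hic_noise Multiplicative log-normal noise `sdlog` (0 = none).
#' @param hic_cis_scale,hic_trans_scale Cis scale and constant trans
#'   background.
#' @param rna_bin_size RNA depth track bin (bp).
#' @param rna_depth_background,rna_depth_centromere Mean RNA-seq depth outside
#'   and inside centromeres (Poisson).
#' @param gene_mean_length,gene_gap_mean Gene and intergenic length scales for
#'   the planted gene track (no genes inside centromeres).
#' @return A validated list of class `"sim_params"`.
#' @export
sim_params <- function(seed,
                       chrom_lengths = c(chr1 = 500000L, chr2 = 400000L, chr3 = 300000L),
                       gc_background = 0.56,
                       telomere_unit = "CCCTAA",
                       telomere_copies = 30L,
                       centromere_fraction = c(0.45, 0.3, 0.65),
                       centromere_width = 10000L,
                       centromere_gc = 0.40,
                       ltr_monomer_length = 427L,
                       ltr_layout = NULL,
                       rdna_unit_length = 5701L,
                       rdna_copies = 10L,
                       rdna_chrom = "chr3",
                       rdna_side = "3prime",
                       rdna_divergence = 0,
                       read_length_mean = 8000,
                       read_length_sd = 1500,
                       read_min_length = 200,
                       read_depth = 30,
                       read_error_rate = 0.001,
                       anomaly_regions = tibble(chrom = "chr2", start = 50000, end = 90000, depth_factor = 0.25),
                       mq0_regions = tibble(chrom = "chr1", start = 340000, end = 370000),
                       hic_bin_size = 10000L,
                       hic_decay_exponent = 1.0,
                       hic_cen_enrichment = 5,
                       hic_noise = 0.1,
                       hic_cis_scale = 100,
                       hic_trans_scale = 1,
                       rna_bin_size = 1000L,
                       rna_depth_background = 20,
                       rna_depth_centromere = 0.2,
                       gene_mean_length = 1500,
                       gene_gap_mean = 1000) {
  if (missing(seed)) cs_stop("a simulation seed is mandatory")
  stopifnot(is_count(seed))
  n <- length(chrom_lengths)
  if (is.null(names(chrom_lengths))) {
    names(chrom_lengths) <- sprintf("chr%d", seq_len(n))
  }
  if (is.null(ltr_layout)) {
    ltr_layout <- rep(list(list(list(type = "paired", internal_length = 3000L,
                                     tsr_length = 5L, strand = "+"),
                              list(type = "solo", strand = "+"))), n)
    if (n >= 2) {
      ltr_layout[[2]] <- list(list(type = "solo", strand = "+"),
                              list(type = "solo", strand = "-"))
    }
    names(ltr_layout) <- names(chrom_lengths)
  }
  p <- list(seed = as.integer(seed), chrom_lengths = chrom_lengths,
            gc_background = gc_background, telomere_unit = toupper(telomere_unit),
            telomere_copies = as.integer(telomere_copies),
            centromere_fraction = rep_len(centromere_fraction, n),
            centromere_width = rep_len(as.integer(centromere_width), n),
            centromere_gc = centromere_gc,
            ltr_monomer_length = as.integer(ltr_monomer_length),
            ltr_layout = ltr_layout,
            rdna_unit_length = as.integer(rdna_unit_length),
            rdna_copies = as.integer(rdna_copies),
            rdna_chrom = rdna_chrom, rdna_side = rdna_side,
            rdna_divergence = rdna_divergence,
            read_length_mean = read_length_mean, read_length_sd = read_length_sd,
            read_min_length = read_min_length, read_depth = read_depth,
            read_error_rate = read_error_rate,
            anomaly_regions = anomaly_regions, mq0_regions = mq0_regions,
            hic_bin_size = as.integer(hic_bin_size),
            hic_decay_exponent = hic_decay_exponent,
            hic_cen_enrichment = hic_cen_enrichment, hic_noise = hic_noise,
            hic_cis_scale = hic_cis_scale, hic_trans_scale = hic_trans_scale,
            rna_bin_size = as.integer(rna_bin_size),
            rna_depth_background = rna_depth_background,
            rna_depth_centromere = rna_depth_centromere,
            gene_mean_length = gene_mean_length, gene_gap_mean = gene_gap_mean)
  validate_sim_params(p)
  structure(p, class = "sim_params")
}

validate_sim_params <- function(p) {
  stopifnot(all(p$chrom_lengths > 0),
            p$gc_background >= 0, p$gc_background <= 1,
            p$centromere_gc >= 0, p$centromere_gc <= 1,
            p$telomere_copies >= 1,
            all(p$centromere_fraction > 0), all(p$centromere_fraction < 1),
            p$read_depth > 0, p$read_error_rate >= 0, p$read_error_rate < 1,
            p$hic_cen_enrichment > 0, p$hic_noise >= 0,
            p$rdna_divergence >= 0, p$rdna_divergence < 1)
  if (grepl("[^ACGT]", p$telomere_unit)) cs_stop("telomere unit must be ACGT only")
  if (!is.null(p$anomaly_regions) && nrow(p$anomaly_regions) > 0 &&
      any(p$anomaly_regions$depth_factor <= 0 | p$anomaly_regions$depth_factor > 1)) {
    cs_stop("anomaly depth_factor must be in (0, 1]")
  }
  tel <- 6L * p$telomere_copies
  for (i in seq_along(p$chrom_lengths)) {
    L <- p$chrom_lengths[[i]]
    mid <- round(p$centromere_fraction[i] * L)
    cs <- mid - p$centromere_width[i] %/% 2L
    ce <- cs + p$centromere_width[i]
    if (cs < tel || ce > L - tel) {
      cs_stop("centromere of %s [%d, %d) collides with a chromosome end",
              names(p$chrom_lengths)[i], cs, ce)
    }
  }
  if (!is.na(p$rdna_chrom)) {
    L <- p$chrom_lengths[[p$rdna_chrom]]
    arr <- p$rdna_unit_length * p$rdna_copies
    mid <- round(p$centromere_fraction[match(p$rdna_chrom, names(p$chrom_lengths))] * L)
    lo <- if (p$rdna_side == "3prime") L - tel - arr else tel
    hi <- lo + arr
    if (lo < tel || hi > L - tel) cs_stop("rDNA array does not fit on %s", p$rdna_chrom)
    if (lo < mid + max(p$centromere_width) && hi > mid - max(p$centromere_width)) {
      cs_stop("rDNA array overlaps the centromere on %s", p$rdna_chrom)
    }
  }
  invisible(p)
}

# derive a stable per-component seed from the root seed
comp_seed <- function(seed, idx) {
  as.integer(((as.numeric(seed) %% 900000) * 2011 + idx * 7919) %% 2147483647) + 1L
}

#' Generate a synthetic genome with planted features and ground truth
#'
#' Deterministic given `params$seed`. Plants, per chromosome: terminal
#' telomere arrays (verbatim tandem units), one low-GC centromere containing
#' LTR retrotransposon elements (paired elements carry identical LTRs, a
#' target-site duplication, a primer-binding-site motif, GAG/INT/RT/RH domain
#' markers in order and a polypurine tract; solo elements are lone monomers),
#' an optional terminal rDNA tandem array, a gene track that avoids the
#' centromere, a repeat track that saturates it, and an RNA depth track that
#' drops to near zero inside it. Every planted sequence is recorded in the
#' truth object and is an exact substring of the emitted genome.
#'
#' @param params A [sim_params()] object.
#' @return List with elements `genome`, `truth` (class `"synthetic_truth"`),
#'   `genes`, `repeats` (interval tracks) and `rna_depth` (depth track).
#' @export
simulate_genome <- function(params) {
  stopifnot(inherits(params, "sim_params"))
  p <- params
  set.seed(comp_seed(p$seed, 1L))
  tel <- 6L * p$telomere_copies
  unit5 <- p$telomere_unit
  unit3 <- revcomp(unit5)

  consensus <- random_dna(p$ltr_monomer_length, p$centromere_gc)
  domain_motifs <- c(GAG = random_dna(60, p$centromere_gc),
                     INT = random_dna(60, p$centromere_gc),
                     RT = random_dna(60, p$centromere_gc),
                     RH = random_dna(60, p$centromere_gc))
  pbs_motif <- random_dna(12, 0.5)
  ppt_motif <- paste(sample(c("A", "G"), 12, replace = TRUE), collapse = "")
  rdna_unit <- random_dna(p$rdna_unit_length, p$gc_background)

  chroms <- names(p$chrom_lengths)
  seqs <- character(length(chroms))
  names(seqs) <- chroms
  telo_rows <- list(); cen_rows <- list(); ltr_rows <- list()
  gene_rows <- list(); rep_rows <- list(); rna_rows <- list()
  rdna_truth <- NULL

  for (i in seq_along(chroms)) {
    ch <- chroms[i]
    L <- as.integer(p$chrom_lengths[[i]])
    s <- random_dna(L, p$gc_background)

    # --- centromere with planted LTR array ---------------------------------
    mid <- as.integer(round(p$centromere_fraction[i] * L))
    w <- p$centromere_width[i]
    cs <- mid - w %/% 2L
    ce <- cs + w
    cen <- random_dna(w, p$centromere_gc)
    pos <- 300L  # local offset of the first element inside the centromere
    for (el in p$ltr_layout[[ch]]) {
      built <- build_ltr_element(el, consensus, domain_motifs, pbs_motif,
                                 ppt_motif, p$centromere_gc)
      if (pos + nchar(built$seq) + 300L > w) {
        cs_stop("planted LTR elements exceed the centromere width on %s", ch)
      }
      cen <- paste0(substr(cen, 1, pos), built$seq,
                    substr(cen, pos + nchar(built$seq) + 1L, w))
      g0 <- cs + pos  # genome coordinate of the element sequence start
      ltr_rows[[length(ltr_rows) + 1L]] <- mutate(built$truth,
        chrom = ch,
        across(c(start, end, ltr5_start, ltr5_end, ltr3_start, ltr3_end,
                 internal_start, internal_end), ~ .x + g0))
      pos <- pos + nchar(built$seq) + 400L
    }
    s <- paste0(substr(s, 1, cs), cen, substr(s, cs + w + 1L, L))
    cen_rows[[i]] <- tibble(chrom = ch, start = cs, end = ce, midpoint = (cs + ce) / 2)
    rep_rows[[length(rep_rows) + 1L]] <-
      tibble(chrom = ch, start = cs, end = ce, strand = ".",
             label = "cen_satellite", kind = "repeat")

    # --- terminal rDNA tandem array ----------------------------------------
    if (!is.na(p$rdna_chrom) && ch == p$rdna_chrom) {
      copies <- vapply(seq_len(p$rdna_copies), function(j) {
        mutate_seq(rdna_unit, p$rdna_divergence)
      }, "")
      arr <- paste(copies, collapse = "")
      a0 <- if (p$rdna_side == "3prime") L - tel - nchar(arr) else tel
      s <- paste0(substr(s, 1, a0), arr, substr(s, a0 + nchar(arr) + 1L, L))
      rdna_truth <- list(chrom = ch, side = p$rdna_side, start = a0,
                         end = a0 + nchar(arr), copies = p$rdna_copies,
                         unit = rdna_unit)
      rep_rows[[length(rep_rows) + 1L]] <-
        tibble(chrom = ch, start = a0, end = a0 + nchar(arr), strand = ".",
               label = "rdna_array", kind = "repeat")
    }

    # --- telomeres (verbatim tandem units at both termini) -----------------
    s <- paste0(strrep(unit5, p$telomere_copies),
                substr(s, tel + 1L, L - tel),
                strrep(unit3, p$telomere_copies))
    telo_rows[[length(telo_rows) + 1L]] <-
      tibble(chrom = ch, side = c("5prime", "3prime"),
             start = c(0L, L - tel), end = c(tel, L),
             copies = p$telomere_copies)

    # --- gene track: arms only, never inside the centromere ----------------
    forbid <- tibble(start = c(0, cs, if (!is.null(rdna_truth) && rdna_truth$chrom == ch) rdna_truth$start else numeric(0), L - tel),
                     end = c(tel, ce, if (!is.null(rdna_truth) && rdna_truth$chrom == ch) rdna_truth$end else numeric(0), L))
    forbid <- arrange(forbid, start)
    pos <- 0
    repeat {
      gap <- round(runif(1, 0.5, 1.5) * p$gene_gap_mean)
      glen <- round(runif(1, 0.5, 1.5) * p$gene_mean_length)
      g0 <- pos + gap
      g1 <- g0 + glen
      if (g1 > L) break
      hit <- which(forbid$start < g1 & forbid$end > g0)
      if (length(hit)) {
        pos <- max(forbid$end[hit])
        if (pos >= L) break
        next
      }
      gene_rows[[length(gene_rows) + 1L]] <-
        tibble(chrom = ch, start = g0, end = g1,
               strand = sample(c("+", "-"), 1), kind = "gene")
      pos <- g1
    }

    # --- sparse background repeats on the arms -----------------------------
    n_bg <- 5L
    bg0 <- sort(sample.int(L - 600L, n_bg))
    keep <- bg0 + 500 < cs | bg0 > ce  # keep clear of the centromere
    if (any(keep)) {
      rep_rows[[length(rep_rows) + 1L]] <-
        tibble(chrom = ch, start = bg0[keep], end = bg0[keep] + 500,
               strand = ".", label = "arm_repeat", kind = "repeat")
    }

    # --- RNA depth: background outside, near-silent inside the centromere --
    b <- tile_bins(L, p$rna_bin_size)
    in_cen <- (b$start + b$end) / 2 >= cs & (b$start + b$end) / 2 < ce
    depth <- ifelse(in_cen, rpois(nrow(b), p$rna_depth_centromere),
                    rpois(nrow(b), p$rna_depth_background))
    rna_rows[[i]] <- tibble(chrom = ch, start = b$start, end = b$end,
                            depth = as.numeric(depth))
    seqs[ch] <- s
  }

  genome <- as_genome(seqs)
  genes <- validate_intervals(
    mutate(bind_rows(gene_rows), label = sprintf("gene%04d", dplyr::row_number())),
    genome)
  repeats <- validate_intervals(
    mutate(bind_rows(rep_rows), strand = "."), genome)
  rna <- depth_track(bind_rows(rna_rows), p$rna_bin_size, genome)
  truth <- structure(list(params = p,
                          telomeres = bind_rows(telo_rows),
                          centromeres = bind_rows(cen_rows),
                          ltr_elements = bind_rows(ltr_rows),
                          ltr_consensus = consensus,
                          domain_motifs = domain_motifs,
                          pbs_motif = pbs_motif,
                          rdna = rdna_truth,
                          anomalies = p$anomaly_regions,
                          mq0_regions = p$mq0_regions),
                     class = "synthetic_truth")
  list(genome = genome, truth = truth, genes = genes, repeats = repeats,
       rna_depth = rna)
}

# assemble one planted LTR element; returns the sequence and a local-coordinate
# truth row (positions relative to the returned sequence start)
build_ltr_element <- function(el, consensus, domain_motifs, pbs_motif, ppt_motif, gc) {
  U <- nchar(consensus)
  if (identical(el$type, "solo")) {
    seq <- consensus
    truth <- tibble(type = "solo", strand = el$strand %||% "+",
                    start = 0L, end = U,
                    ltr5_start = 0L, ltr5_end = U,
                    ltr3_start = NA_integer_, ltr3_end = NA_integer_,
                    internal_start = NA_integer_, internal_end = NA_integer_,
                    tsr = NA_character_)
    if (identical(el$strand, "-")) seq <- revcomp(seq)
    return(list(seq = seq, truth = truth))
  }
  ilen <- as.integer(el$internal_length)
  stopifnot(ilen >= 400L)
  tsr <- random_dna(as.integer(el$tsr_length), 0.5)
  # internal region: PBS just downstream of the 5' LTR, domain markers in
  # order, PPT just upstream of the 3' LTR, random filler elsewhere
  internal <- random_dna(ilen, gc)
  put <- function(s, piece, at0) {  # 0-based insertion by overwrite
    paste0(substr(s, 1, at0), piece, substr(s, at0 + nchar(piece) + 1L, nchar(s)))
  }
  internal <- put(internal, pbs_motif, 2L)
  dom_at <- as.integer(floor(ilen * (seq_along(domain_motifs) + 0.5) / 6))
  dom_at <- pmin(pmax(dom_at, 30L), ilen - 100L)
  for (j in seq_along(domain_motifs)) {
    internal <- put(internal, domain_motifs[[j]], dom_at[j])
  }
  internal <- put(internal, ppt_motif, ilen - nchar(ppt_motif) - 3L)
  core <- paste0(consensus, internal, consensus)
  seq <- paste0(tsr, core, tsr)
  n_tsr <- nchar(tsr)
  # local coordinates of the element proper (excluding the flanking TSRs)
  truth <- tibble(type = "paired", strand = el$strand %||% "+",
                  start = n_tsr, end = n_tsr + nchar(core),
                  ltr5_start = n_tsr, ltr5_end = n_tsr + U,
                  ltr3_start = n_tsr + U + ilen, ltr3_end = n_tsr + nchar(core),
                  internal_start = n_tsr + U, internal_end = n_tsr + U + ilen,
                  tsr = tsr)
  if (identical(el$strand, "-")) {
    seq <- revcomp(seq)
    # mirror local coordinates; 5'/3' roles follow the minus strand
    tot <- nchar(seq)
    flip <- function(a, b) c(tot - b, tot - a)
    e <- flip(truth$start, truth$end)
    l5 <- flip(truth$ltr5_start, truth$ltr5_end)
    l3 <- flip(truth$ltr3_start, truth$ltr3_end)
    int <- flip(truth$internal_start, truth$internal_end)
    truth$start <- e[1]; truth$end <- e[2]
    truth$ltr5_start <- l5[1]; truth$ltr5_end <- l5[2]
    truth$ltr3_start <- l3[1]; truth$ltr3_end <- l3[2]
    truth$internal_start <- int[1]; truth$internal_end <- int[2]
  }
  list(seq = seq, truth = truth)
}

# i.i.d. substitutions at `rate` (never to the same base)
mutate_seq <- function(seq, rate) {
  n <- nchar(seq)
  if (rate <= 0 || n == 0L) return(seq)
  k <- rbinom(1, n, rate)
  if (k == 0L) return(seq)
  pos <- sample.int(n, k)
  x <- utf8ToInt(seq)
  bases <- utf8ToInt("ACGT")
  for (i in pos) {
    x[i] <- sample(setdiff(bases, x[i]), 1)
  }
  intToUtf8(x)
}

#' Simulate long reads with a true-origin alignment table
#'
#' Reads are sampled uniformly along the genome (lengths normal, truncated at
#' `read_min_length`, clipped at chromosome ends) except that reads whose
#' origin midpoint falls in an anomaly region are thinned by its
#' `depth_factor`. Per-base substitution errors are i.i.d. at
#' `read_error_rate`. The alignment table records true origins; reads
#' originating in an `mq0_region` carry mapping quality 0, all others 60.
#'
#' @param genome A `"genome"` (usually from [simulate_genome()]).
#' @param params A [sim_params()] object.
#' @param bin_size Bin size of the emitted depth track.
#' @return List with `reads` (tibble `read_id, seq, chrom, start, end, mapq`)
#'   and `depth` (the binned origin coverage as a `"depth_track"`, with
#'   attribute `genome_mean`).
#' @export
simulate_reads <- function(genome, params, bin_size = 10000L) {
  stopifnot(inherits(params, "sim_params"))
  p <- params
  genome <- as_genome(genome)
  set.seed(comp_seed(p$seed, 2L))
  lens <- genome_lengths(genome)
  target <- p$read_depth * sum(lens)

  rows <- list()
  got <- 0
  while (got < target) {
    n <- max(100L, ceiling((target - got) / p$read_length_mean * 1.4))
    len <- pmax(p$read_min_length,
                round(rnorm(n, p$read_length_mean, p$read_length_sd)))
    ch <- sample(names(lens), n, replace = TRUE, prob = lens)
    start <- floor(runif(n) * lens[ch])
    end <- pmin(start + len, lens[ch])
    midpt <- (start + end) / 2
    keep <- rep(TRUE, n)
    ar <- p$anomaly_regions
    if (!is.null(ar) && nrow(ar) > 0) {
      for (r in seq_len(nrow(ar))) {
        inside <- ch == ar$chrom[r] & midpt >= ar$start[r] & midpt < ar$end[r]
        keep[inside] <- keep[inside] & (runif(n)[inside] < ar$depth_factor[r])
      }
    }
    batch <- tibble(chrom = ch, start = as.numeric(start), end = as.numeric(end))[keep, ]
    bp <- cumsum(batch$end - batch$start)
    cut <- which(got + bp >= target)
    if (length(cut)) batch <- batch[seq_len(cut[1]), ]
    rows[[length(rows) + 1L]] <- batch
    got <- got + sum(batch$end - batch$start)
  }
  reads <- bind_rows(rows)
  reads$read_id <- sprintf("read%06d", seq_len(nrow(reads)))

  seqs <- substr(unclass(genome)[reads$chrom], reads$start + 1L, reads$end)
  if (p$read_error_rate > 0) {
    seqs <- vapply(seqs, mutate_seq, "", rate = p$read_error_rate, USE.NAMES = FALSE)
  }
  reads$seq <- unname(seqs)

  reads$mapq <- 60L
  mq <- p$mq0_regions
  if (!is.null(mq) && nrow(mq) > 0) {
    midpt <- (reads$start + reads$end) / 2
    for (r in seq_len(nrow(mq))) {
      reads$mapq[reads$chrom == mq$chrom[r] & midpt >= mq$start[r] &
                   midpt < mq$end[r]] <- 0L
    }
  }
  reads <- select(reads, read_id, seq, chrom, start, end, mapq)
  depth <- bin_depth(reads, genome, bin_size = bin_size)
  if (any(depth$depth == 0)) {
    cs_warn("%d depth bin(s) received no reads at %gx simulated coverage",
            sum(depth$depth == 0), p$read_depth)
  }
  list(reads = reads, depth = depth)
}

#' Simulate a binned Hi-C contact matrix
#'
#' Cis expectation follows a power-law decay in bin distance, trans pairs a
#' constant background; pairs of bins that both overlap a (planted) centromere
#' are multiplied by `hic_cen_enrichment`; multiplicative log-normal noise is
#' applied symmetrically. With `hic_noise = 0` the counts equal the expectation
#' exactly.
#'
#' @param genome A `"genome"`.
#' @param truth A `"synthetic_truth"` (for the planted centromere spans).
#' @param params A [sim_params()] object.
#' @return A `"contact_matrix"`.
#' @export
simulate_contacts <- function(genome, truth, params) {
  stopifnot(inherits(params, "sim_params"))
  p <- params
  genome <- as_genome(genome)
  set.seed(comp_seed(p$seed, 3L))
  lens <- genome_lengths(genome)
  bins <- contact_matrix(matrix(0, sum(ceiling(lens / p$hic_bin_size)),
                                sum(ceiling(lens / p$hic_bin_size))),
                         p$hic_bin_size, lens) |> contact_bins()
  n <- nrow(bins)
  cen <- rep(FALSE, n)
  for (r in seq_len(nrow(truth$centromeres))) {
    cc <- truth$centromeres[r, ]
    cen <- cen | (bins$chrom == cc$chrom & bins$start < cc$end & bins$end > cc$start)
  }
  same <- outer(bins$chrom, bins$chrom, "==")
  d <- abs(outer(bins$bin, bins$bin, "-"))
  expected <- ifelse(same, p$hic_cis_scale * pmax(d, 1)^(-p$hic_decay_exponent),
                     p$hic_trans_scale)
  both_cen <- outer(cen, cen, "&")
  expected[both_cen] <- expected[both_cen] * p$hic_cen_enrichment
  counts <- expected
  if (p$hic_noise > 0) {
    noise <- matrix(exp(rnorm(n * n, 0, p$hic_noise)), n, n)
    noise[lower.tri(noise)] <- t(noise)[lower.tri(noise)]
    counts <- counts * noise
  }
  contact_matrix(counts, p$hic_bin_size, lens)
}

#' Simulate a complete dataset, optionally writing all files
#'
#' Orchestrates [simulate_genome()], [simulate_reads()] and
#' [simulate_contacts()] and, when `out_dir` is given, writes genome FASTA,
#' reads FASTQ, the alignment table, gene/repeat GFF3, RNA and DNA depth
#' bedGraph, the contact matrix and the truth record (YAML).
#'
#' @param params A [sim_params()] object.
#' @param out_dir Output directory (created if missing); `NULL` = no files.
#' @return List with `genome`, `truth`, `genes`, `repeats`, `rna_depth`,
#'   `reads`, `read_depth`, `contacts`.
#' @export
simulate_dataset <- function(params, out_dir = NULL) {
  g <- simulate_genome(params)
  r <- simulate_reads(g$genome, params)
  cm <- simulate_contacts(g$genome, g$truth, params)
  out <- list(genome = g$genome, truth = g$truth, genes = g$genes,
              repeats = g$repeats, rna_depth = g$rna_depth,
              reads = r$reads, read_depth = r$depth, contacts = cm)
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    fp <- function(x) file.path(out_dir, x)
    write_genome_fasta(g$genome, fp("genome.fasta"))
    write_reads_fastq(r$reads, fp("reads.fastq"))
    write_alignment_table(r$reads, fp("alignments.tsv"))
    write_intervals(g$genes, fp("genes.gff3"), "gff3")
    write_intervals(g$repeats, fp("repeats.gff3"), "gff3")
    write_bedgraph(g$rna_depth, fp("rna_depth.bedgraph"))
    write_bedgraph(r$depth, fp("read_depth.bedgraph"))
    write_contacts(cm, fp("contacts.tsv"))
    write_truth_yaml(g$truth, fp("truth.yaml"))
  }
  out
}

#' Write a truth record as structured YAML
#'
#' @param truth A `"synthetic_truth"` object.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_truth_yaml <- function(truth, path) {
  to_plain <- function(x) {
    if (inherits(x, "tbl_df") || is.data.frame(x)) {
      lapply(as.list(as.data.frame(x)), as.vector)
    } else if (is.list(x)) {
      lapply(x, to_plain)
    } else {
      x
    }
  }
  yaml::write_yaml(to_plain(truth[setdiff(names(truth), "params")]), path)
  invisible(path)
}

#' Write reads as FASTQ
#'
#' @param reads Tibble with `read_id` and `seq`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_reads_fastq <- function(reads, path) {
  qual <- strrep("I", nchar(reads$seq))
  writeLines(paste0("@", reads$read_id, "\n", reads$seq, "\n+\n", qual), path)
  invisible(path)
}

#' Read a FASTQ file into a read tibble
#'
#' @param path FASTQ path.
#' @return Tibble with `read_id`, `seq`.
#' @export
read_reads_fastq <- function(path) {
  if (!file.exists(path)) cs_stop("no such file: %s", path)
  ss <- Biostrings::readDNAStringSet(path, format = "fastq")
  tibble(read_id = unname(sub("\\s.*$", "", names(ss))),
         seq = unname(as.character(ss)))
}

#' Write / read the tab-separated alignment table
#'
#' Columns `read_id`, `chrom`, `start`, `end`, `mapq`, 0-based half-open.
#'
#' @param reads Tibble with those columns.
#' @param path File path.
#' @return `path` (write) or a tibble (read).
#' @export
write_alignment_table <- function(reads, path) {
  utils::write.table(select(reads, read_id, chrom, start, end, mapq), path,
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_alignment_table
#' @param genome Optional genome for validation of chromosomes and bounds.
#' @export
read_alignment_table <- function(path, genome = NULL) {
  if (!file.exists(path)) cs_stop("no such file: %s", path)
  tbl <- as_tibble(utils::read.table(path, header = TRUE, sep = "\t",
                                     stringsAsFactors = FALSE))
  need <- c("read_id", "chrom", "start", "end", "mapq")
  if (!all(need %in% names(tbl))) {
    cs_stop("alignment table must have columns: %s", paste(need, collapse = ", "))
  }
  if (!is.null(genome)) {
    lens <- genome_lengths(genome)
    bad <- which(!tbl$chrom %in% names(lens))
    if (length(bad)) {
      cs_stop("alignment line %d references unknown chromosome '%s'",
              bad[1], tbl$chrom[bad[1]])
    }
  }
  tbl
}
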