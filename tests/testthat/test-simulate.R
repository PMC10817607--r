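test_that("the generator is deterministic given the seed", {
  p <- small_params(seed = 11)
  a <- simulate_genome(p)
  b <- simulate_genome(p)
  expect_identical(unclass(a$genome), unclass(b$genome))
  expect_identical(a$truth$ltr_elements, b$truth$ltr_elements)
  ra <- simulate_reads(a$genome, p)
  rb <- simulate_reads(b$genome, p)
  expect_identical(ra$reads, rb$reads)
  ca <- simulate_contacts(a$genome, a$truth, p)
  cb <- simulate_contacts(b$genome, b$truth, p)
  expect_identical(ca$counts, cb$counts)
})

test_that("telomere units are planted verbatim at every declared end", {
  ds <- default_sim()
  p <- ds$params
  tel <- strrep(p$telomere_unit, p$telomere_copies)
  telr <- strrep(revcomp(p$telomere_unit), p$telomere_copies)
  for (ch in names(ds$genome)) {
    s <- unclass(ds$genome)[[ch]]
    expect_identical(substr(s, 1, nchar(tel)), tel)
    expect_identical(substr(s, nchar(s) - nchar(telr) + 1, nchar(s)), telr)
  }
})

test_that("centromere windows carry the configured GC gap", {
  # recount GC with an independent counter (table over split characters)
  ds <- default_sim()
  p <- ds$params
  gc_of <- function(s) {
    tab <- table(strsplit(s, "")[[1]])
    sum(tab[c("G", "C")], na.rm = TRUE) / nchar(s)
  }
  for (i in seq_len(nrow(ds$truth$centromeres))) {
    cen <- ds$truth$centromeres[i, ]
    s <- unclass(ds$genome)[[cen$chrom]]
    win <- substr(s, cen$start + 1, cen$start + 10000)
    flank <- substr(s, cen$end + 20000 + 1, cen$end + 30000)
    gap <- gc_of(flank) - gc_of(win)
    expect_gt(gap, (p$gc_background - p$centromere_gc) - 0.02 - 0.01)
    expect_lt(gap, (p$gc_background - p$centromere_gc) + 0.02 + 0.01)
  }
})

test_that("every planted truth sequence is an exact substring of the genome", {
  ds <- default_sim()
  tr <- ds$truth
  for (i in seq_len(nrow(tr$ltr_elements))) {
    e <- tr$ltr_elements[i, ]
    s <- unclass(ds$genome)[[e$chrom]]
    ltr <- substr(s, e$ltr5_start + 1, e$ltr5_end)
    expected <- if (e$strand == "-") revcomp(tr$ltr_consensus) else tr$ltr_consensus
    expect_identical(ltr, expected)
    if (e$type == "paired") {
      # identical target-site duplication flanks the element
      expect_identical(substr(s, e$start - nchar(e$tsr) + 1, e$start), e$tsr)
      expect_identical(substr(s, e$end + 1, e$end + nchar(e$tsr)), e$tsr)
    }
  }
  rd <- tr$rdna
  expect_identical(substr(unclass(ds$genome)[[rd$chrom]], rd$start + 1,
                          rd$start + nchar(rd$unit)), rd$unit)
  expect_equal(rd$end - rd$start, nchar(rd$unit) * rd$copies)
})

test_that("gene track avoids the centromere; RNA depth collapses inside it", {
  ds <- default_sim()
  for (i in seq_len(nrow(ds$truth$centromeres))) {
    cen <- ds$truth$centromeres[i, ]
    g <- ds$genes[ds$genes$chrom == cen$chrom, ]
    expect_false(any(g$start < cen$end & g$end > cen$start))
    rna <- ds$rna_depth[ds$rna_depth$chrom == cen$chrom, ]
    inside <- rna$start >= cen$start & rna$end <= cen$end
    expect_lt(mean(rna$depth[inside]), 1)
    expect_gt(mean(rna$depth[!inside]), 10)
  }
})

test_that("error-free reads are exact substrings with faithful origin records", {
  p <- small_params(seed = 5, read_error_rate = 0)
  ds <- simulate_genome(p)
  r <- simulate_reads(ds$genome, p)
  idx <- seq(1, nrow(r$reads), by = 23)  # spot-check a deterministic subset
  for (i in idx) {
    s <- unclass(ds$genome)[[r$reads$chrom[i]]]
    expect_identical(substr(s, r$reads$start[i] + 1, r$reads$end[i]),
                     r$reads$seq[i])
  }
})

test_that("emitted depth equals an independent per-base recount of origins", {
  p <- small_params(seed = 6)
  ds <- simulate_genome(p)
  r <- simulate_reads(ds$genome, p)
  bs <- attr(r$depth, "bin_size")
  for (ch in names(ds$genome)) {
    L <- nchar(unclass(ds$genome)[[ch]])
    cov <- numeric(L)
    al <- r$reads[r$reads$chrom == ch, ]
    for (i in seq_len(nrow(al))) {
      cov[(al$start[i] + 1):al$end[i]] <- cov[(al$start[i] + 1):al$end[i]] + 1
    }
    want <- tapply(cov, (seq_len(L) - 1) %/% bs, mean)
    got <- r$depth$depth[r$depth$chrom == ch]
    expect_equal(as.numeric(want), got, tolerance = 1e-12)
  }
})

test_that("anomaly regions are thinned to the configured depth factor", {
  p <- sim_params(seed = 9,
                  chrom_lengths = c(chrA = 200000L),
                  centromere_fraction = 0.3, rdna_chrom = NA,
                  read_length_mean = 3000, read_length_sd = 300,
                  read_depth = 30, read_error_rate = 0,
                  anomaly_regions = tibble::tibble(chrom = "chrA", start = 80000,
                                                   end = 120000, depth_factor = 0.3),
                  mq0_regions = tibble::tibble(chrom = character(0), start = numeric(0),
                                               end = numeric(0)))
  ds <- simulate_genome(p)
  r <- suppressWarnings(simulate_reads(ds$genome, p))
  interior <- r$depth$start >= 90000 & r$depth$end <= 110000
  # binomial-thinning oracle: E = 0.3 * 30 = 9; sd(depth) ~ sqrt(9 * L_read / bin)
  sd3 <- 3 * sqrt(9 * 3000 / 10000)
  expect_lt(abs(mean(r$depth$depth[interior]) - 9), sd3)
  outside <- r$depth$start >= 10000 & r$depth$end <= 70000
  expect_gt(mean(r$depth$depth[outside]), 25)
})

test_that("noise-free contact matrices follow the decay model exactly", {
  p <- small_params(seed = 3, hic_noise = 0, hic_cen_enrichment = 1)
  ds <- simulate_genome(p)
  cm <- simulate_contacts(ds$genome, ds$truth, p)
  bins <- contact_bins(cm)
  trans <- outer(bins$chrom, bins$chrom, "!=")
  expect_true(all(cm$counts[trans] == p$hic_trans_scale))  # constant trans block
  idx <- which(bins$chrom == "chrA")
  for (k in c(1, 3, 7)) {
    d <- cm$counts[cbind(idx[1], idx[1 + k])]
    expect_equal(d, p$hic_cis_scale * k^(-p$hic_decay_exponent))
  }
  expect_equal(cm$counts, t(cm$counts))
})

test_that("centromere-pair enrichment lifts trans contact sums", {
  # recompute the sums independently from the bin table
  p <- sim_params(seed = 4, chrom_lengths = c(chrA = 300000L, chrB = 300000L),
                  centromere_fraction = c(0.4, 0.6), centromere_width = 100000L,
                  rdna_chrom = NA, hic_cen_enrichment = 10, hic_noise = 0.05)
  ds <- simulate_genome(p)
  cm <- simulate_contacts(ds$genome, ds$truth, p)
  bins <- contact_bins(cm)
  cen <- rep(FALSE, nrow(bins))
  for (i in 1:2) {
    cc <- ds$truth$centromeres[i, ]
    cen <- cen | (bins$chrom == cc$chrom & bins$start < cc$end & bins$end > cc$start)
  }
  trans <- outer(bins$chrom, bins$chrom, "!=")
  trans_sum <- vapply(seq_len(nrow(bins)),
                      function(i) sum(cm$counts[i, trans[i, ]]), 0.0)
  expect_gte(min(trans_sum[cen]) / median(trans_sum[!cen]), 3)
})

test_that("all emitted files re-parse through the package readers", {
  dir <- withr::local_tempdir()
  p <- small_params(seed = 8, rdna_chrom = "chrA", rdna_copies = 3L,
                    rdna_unit_length = 2000L)
  ds <- expect_no_warning(simulate_dataset(p, out_dir = dir))
  g <- read_genome_fasta(file.path(dir, "genome.fasta"))
  expect_identical(unclass(g), unclass(ds$genome))
  reads <- read_reads_fastq(file.path(dir, "reads.fastq"))
  expect_identical(reads$seq, ds$reads$seq)
  al <- read_alignment_table(file.path(dir, "alignments.tsv"), g)
  expect_equal(nrow(al), nrow(ds$reads))
  genes <- read_intervals(file.path(dir, "genes.gff3"), "gff3", genome = g)
  expect_equal(nrow(genes), nrow(ds$genes))
  expect_equal(genes$start, ds$genes$start)
  cm <- read_contacts(file.path(dir, "contacts.tsv"))
  expect_equal(cm$counts, ds$contacts$counts, tolerance = 1e-12)
  rna <- read_bedgraph(file.path(dir, "rna_depth.bedgraph"),
                       bin_size = p$rna_bin_size)
  expect_equal(sum(rna$depth), sum(ds$rna_depth$depth))
  expect_true(file.exists(file.path(dir, "truth.yaml")))
})
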