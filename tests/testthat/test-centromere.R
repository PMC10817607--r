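test_that("feature tracks compute per-window GC, densities and transcription", {
  g <- as_genome(c(c1 = paste0(strrep("G", 5000), strrep("A", 5000))))
  gene <- interval_track("c1", 0, 5000, kind = "gene", genome = g)
  f <- compute_feature_tracks(g, gene_track = gene, window = 5000)
  expect_equal(f$gc, c(1, 0))           # all-GC window
  expect_equal(f$gene_density, c(1, 0)) # fully gene-covered window

  # N bases leave the GC denominator
  g2 <- as_genome(c(c1 = paste0(strrep("G", 50), strrep("N", 50))))
  f2 <- compute_feature_tracks(g2, window = 100)
  expect_equal(f2$gc, 1)

  # mismatched RNA binning is rejected
  rna <- depth_track(tibble::tibble(chrom = "c1", start = c(0, 3000, 6000, 9000),
                                    end = c(3000, 6000, 9000, 10000),
                                    depth = 1), 3000, g)
  expect_error(compute_feature_tracks(g, rna_depth = rna, window = 5000),
               "multiple of the RNA bin size")
})

test_that("synthetic centromere windows sit below flanking GC across seeds", {
  for (seed in 1:10) {
    p <- sim_params(seed = seed, chrom_lengths = c(chrA = 120000L),
                    centromere_fraction = 0.5, centromere_width = 20000L,
                    rdna_chrom = NA,
                    anomaly_regions = NULL, mq0_regions = NULL)
    ds <- simulate_genome(p)
    f <- compute_feature_tracks(ds$genome, ds$genes, ds$repeats, ds$rna_depth,
                                window = 10000)
    cen <- ds$truth$centromeres[1, ]
    inside <- f$start >= cen$start & f$end <= cen$end
    expect_lt(mean(f$gc[inside]), mean(f$gc[!inside]))
    expect_gt(mean(f$repeat_density[inside]), mean(f$repeat_density[!inside]))
  }
})

test_that("OE normalisation has unit per-diagonal cis means and flat null signal", {
  p <- small_params(seed = 41, hic_noise = 0, hic_cen_enrichment = 1)
  ds <- simulate_genome(p)
  cm <- simulate_contacts(ds$genome, ds$truth, p)
  oe <- compute_oe(cm, d_min = 5)
  bins <- contact_bins(cm)
  same <- outer(bins$chrom, bins$chrom, "==")
  # decay-only, noise-free matrix: every defined OE value is 1
  expect_lt(max(abs(oe$oe[same] - 1)), 1e-6)
  expect_lt(max(abs(oe$oe[!same] - 1)), 1e-6)

  # per-diagonal mean of cis OE = 1 for every distance, on a noisy matrix too
  p2 <- small_params(seed = 42, hic_noise = 0.3)
  ds2 <- simulate_genome(p2)
  cm2 <- simulate_contacts(ds2$genome, ds2$truth, p2)
  oe2 <- compute_oe(cm2, d_min = 5)
  b2 <- contact_bins(cm2)
  for (ch in unique(b2$chrom)) {
    idx <- which(b2$chrom == ch)
    block <- oe2$oe[idx, idx]
    dmat <- abs(outer(seq_along(idx), seq_along(idx), "-"))
    means <- tapply(block, dmat, mean)
    expect_lt(max(abs(means - 1)), 1e-9)
  }
  expect_error(compute_oe(contact_matrix(matrix(0, 4, 4), 10, c(a = 40))),
               "no signal")
})

test_that("a doubled trans entry doubles its OE against the background", {
  counts <- matrix(1, 8, 8)
  counts[1, 6] <- counts[6, 1] <- 2
  cm <- contact_matrix(counts, 10, c(a = 40, b = 40))
  oe <- compute_oe(cm, d_min = 2)
  bg <- oe$oe[1, 5]
  expect_equal(oe$oe[1, 6] / bg, 2)
})

test_that("planted centromeres are recovered from enriched contacts", {
  hits <- 0L
  for (seed in 1:10) {
    p <- sim_params(seed = seed,
                    chrom_lengths = c(chrA = 150000L, chrB = 120000L, chrC = 100000L),
                    centromere_fraction = c(0.45, 0.35, 0.6),
                    rdna_chrom = NA, hic_cen_enrichment = 3, hic_noise = 0.1,
                    anomaly_regions = NULL, mq0_regions = NULL)
    ds <- simulate_genome(p)
    cm <- simulate_contacts(ds$genome, ds$truth, p)
    f <- compute_feature_tracks(ds$genome, ds$genes, ds$repeats, ds$rna_depth,
                                window = cm$bin_size)
    calls <- call_centromere(compute_oe(cm), f)
    for (i in seq_len(nrow(ds$truth$centromeres))) {
      cen <- ds$truth$centromeres[i, ]
      cl <- calls[calls$chrom == cen$chrom, ]
      expect_true(cl$called)
      # region overlaps the planted centromere and the midpoint is close
      expect_true(cl$start < cen$end && cl$end > cen$start)
      if (abs(cl$midpoint - cen$midpoint) <= p$centromere_width[i] / 2) {
        hits <- hits + 1L
      }
    }
  }
  expect_equal(hits, 30L)
})

test_that("uniform contacts with flat features produce no call", {
  counts <- matrix(1, 20, 20)
  diag(counts) <- 1
  cm <- contact_matrix(counts, 10000, c(a = 100000, b = 100000))
  calls <- call_centromere(compute_oe(cm, d_min = 3))
  expect_false(any(calls$called))
})

test_that("edge centromeres are annotated low-confidence", {
  # the second chromosome provides the trans partner for the enrichment signal
  p2 <- sim_params(seed = 7, chrom_lengths = c(chrA = 200000L, chrB = 150000L),
                   centromere_fraction = c(0.04, 0.5), centromere_width = 8000L,
                   rdna_chrom = NA, hic_cen_enrichment = 5,
                   anomaly_regions = NULL, mq0_regions = NULL,
                   ltr_layout = list(chrA = list(list(type = "solo", strand = "+")),
                                     chrB = list(list(type = "solo", strand = "+"))))
  ds2 <- simulate_genome(p2)
  cm <- simulate_contacts(ds2$genome, ds2$truth, p2)
  calls <- call_centromere(compute_oe(cm))
  cl <- calls[calls$chrom == "chrA", ]
  expect_true(cl$called)
  expect_true(cl$low_confidence)
  expect_false(calls$low_confidence[calls$chrom == "chrB"])
})

test_that("Levan arm classification reproduces the reference arm table", {
  # printed (s, l) pairs, one row per chromosome, largest to smallest
  tab <- tibble::tibble(
    chrom = sprintf("Chr %02d", 1:13),
    s = c(2.5, 1.55, 3.81, 4.92, 3.62, 4.18, 3.46, 2.49, 3.5, 4.29, 0.33, 0.25, 0.39),
    l = c(7.5, 8.45, 6.19, 5.08, 6.38, 5.82, 6.54, 7.51, 6.5, 5.71, 9.67, 9.75, 9.61),
    d = c(4.99, 6.9, 2.38, 0.17, 2.75, 1.64, 3.08, 5.02, 2.99, 1.41, 9.34, 9.5, 9.22),
    r = c(3, 5.45, 1.62, 1.03, 1.76, 1.39, 1.89, 3.02, 1.85, 1.33, 29.3, 39, 24.64),
    type = c("submetacentric", "subtelocentric", "metacentric", "metacentric",
             "submetacentric", "metacentric", "submetacentric", "subtelocentric",
             "submetacentric", "metacentric", "acrocentric", "acrocentric",
             "acrocentric"))
  got <- levan_classify(tab$s, tab$l)
  # rows whose printed d and r are exactly self-consistent with (s, l)
  consistent <- c(2, 3, 6, 8, 11, 12, 13)
  expect_equal(got$d[consistent], tab$d[consistent])
  expect_equal(got$r[consistent], tab$r[consistent])
  # the d-interval rule reproduces every printed type label
  expect_equal(got$type, tab$type)
})

test_that("arm classification is symmetric, mirror-invariant and bounded", {
  m <- classify_arms(1000, 500)
  expect_equal(c(m$s, m$l, m$d, m$r), c(5, 5, 0, 1))
  expect_equal(m$type, "metacentric")

  set.seed(43)
  for (i in 1:20) {
    L <- sample(1e5:1e7, 1)
    mp <- sample(seq(1000, L - 1000), 1)
    a <- classify_arms(L, mp)
    b <- classify_arms(L, L - mp)  # mirrored chromosome
    expect_equal(a, b)
    expect_true(a$s <= a$l)
    expect_equal(a$s + a$l, 10, tolerance = 0.01)
  }
  expect_error(classify_arms(1000, 0), "strictly inside")
  expect_error(classify_arms(1000, 1000), "strictly inside")
})
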