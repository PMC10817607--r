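test_that("planted telomeres are detected at both ends with exact copy counts", {
  ds <- default_sim()
  rep <- detect_telomeres(ds$genome)
  expect_equal(attr(rep, "n_present"), 2L * length(ds$genome))
  expect_true(all(rep$present))
  expect_true(all(rep$copies == ds$params$telomere_copies))
  five <- rep[rep$side == "5prime", ]
  expect_true(all(five$start == 0))
  expect_true(all(five$end == 6 * ds$params$telomere_copies))
})

test_that("random telomere-free sequence yields no telomeric ends", {
  for (seed in 1:10) {
    set.seed(seed)
    g <- as_genome(c(r = random_dna(100000, 0.5)))
    rep <- detect_telomeres(g)
    # brute-force oracle: longest exact run of the unit anywhere in the ends
    s <- unclass(g)[["r"]]
    oracle <- max(oracle_max_run(substr(s, 1, 2000), "CCCTAA"),
                  oracle_max_run(substr(s, 98000, 100000), "CCCTAA"))
    expect_lt(oracle, 5)
    expect_equal(attr(rep, "n_present"), 0L)
  }
})

test_that("a chromosome missing one telomere reports a single end", {
  ds <- default_sim()
  g <- truncate_chromosome_end(ds$genome, "chr3", "3prime", 2000L)
  rep <- detect_telomeres(as_genome(unclass(g)["chr3"]))
  expect_equal(attr(rep, "n_present"), 1L)
  expect_true(rep$present[rep$side == "5prime"])
  expect_false(rep$present[rep$side == "3prime"])
})

test_that("detection tolerates the per-unit mismatch budget and respects min_copies", {
  unit <- "CCCTAA"
  body <- random_dna(3000, 0.5)
  # 8 units, one mismatched base in unit 4: still one run of 8 at budget 1/6
  units <- strrep(unit, 8)
  substr(units, 20, 20) <- "G"
  g <- as_genome(c(t = paste0(units, body)))
  rep <- detect_telomeres(g, window = 100, min_copies = 8)
  expect_true(rep$present[rep$side == "5prime"])
  # with a zero mismatch budget the run splits and drops below min_copies
  rep0 <- detect_telomeres(g, window = 100, min_copies = 8, max_mismatch_frac = 0)
  expect_false(rep0$present[rep0$side == "5prime"])
  # scattered (non-tandem) units never chain into a run
  g2 <- as_genome(c(t = paste0(unit, random_dna(50, 0.5), unit,
                               random_dna(50, 0.5), unit, body)))
  expect_equal(attr(detect_telomeres(g2, window = 200, min_copies = 3), "n_present"), 0L)
})

test_that("detection is strand-consistent under reverse complement", {
  ds <- default_sim()
  g <- ds$genome
  rc <- as_genome(setNames(revcomp(unclass(g)), names(g)))
  a <- detect_telomeres(g)
  b <- detect_telomeres(rc)
  for (ch in names(g)) {
    a5 <- a[a$chrom == ch & a$side == "5prime", ]
    b3 <- b[b$chrom == ch & b$side == "3prime", ]
    expect_equal(a5$present, b3$present)
    expect_equal(a5$copies, b3$copies)
    L <- nchar(unclass(g)[[ch]])
    expect_equal(L - a5$end, b3$start)
  }
})

test_that("telomeric reads are extracted, oriented and deduplicated", {
  tail1 <- random_dna(300, 0.5)
  reads <- tibble::tibble(
    read_id = c("a", "b", "c", "a"),
    seq = c(paste0(tail1, strrep("TTAGGG", 20)),              # rc form
            paste0(random_dna(200, 0.5), strrep("CCCTAA", 12)), # forward form
            paste0("CCCTAA", random_dna(100, 0.5), "CCCTAA"), # scattered
            strrep("TTAGGG", 30)))                             # duplicate id
  lib <- extract_telomeric_reads(reads, min_copies_read = 5)
  expect_setequal(lib$read_id, c("a", "b"))
  a <- lib[lib$read_id == "a", ]
  expect_true(a$oriented)
  expect_identical(a$seq, revcomp(reads$seq[1]))  # motif now CCCTAA at 5'
  expect_true(startsWith(a$seq, strrep("CCCTAA", 20)))
  expect_false(lib$oriented[lib$read_id == "b"])
})

test_that("extraction matches an independent tandem-run oracle on synthetic reads", {
  p <- small_params(seed = 13, read_error_rate = 0, read_depth = 10)
  ds <- simulate_genome(p)
  r <- suppressWarnings(simulate_reads(ds$genome, p))
  lib <- extract_telomeric_reads(r$reads, min_copies_read = 10)
  oracle_ids <- r$reads$read_id[
    vapply(r$reads$seq, oracle_max_run, 0L, unit = "CCCTAA", USE.NAMES = FALSE) >= 10]
  expect_setequal(lib$read_id, oracle_ids)
  # and every extracted read truly originates in a planted telomere array
  tel <- 6 * p$telomere_copies
  org <- r$reads[match(lib$read_id, r$reads$read_id), ]
  lens <- genome_lengths(ds$genome)
  overlap <- pmax(tel - org$start, org$end - (lens[org$chrom] - tel))
  expect_true(all(overlap >= 10 * 6))
})

test_that("anchored extension rebuilds a truncated end exactly from error-free reads", {
  p <- small_params(seed = 21, read_error_rate = 0)
  ds <- simulate_genome(p)
  r <- simulate_reads(ds$genome, p)
  broken <- truncate_chromosome_end(ds$genome, "chrA", "3prime", 2000L)
  lib <- extract_telomeric_reads(r$reads, min_copies_read = 10)
  res <- patch_missing_telomere(broken, "chrA", "3prime", lib)
  expect_true(res$report$patched)
  expect_identical(unclass(res$genome)[["chrA"]], unclass(ds$genome)[["chrA"]])
  # other chromosomes untouched; nothing shortened
  expect_identical(unclass(res$genome)[["chrB"]], unclass(broken)[["chrB"]])
  rep <- detect_telomeres(res$genome)
  expect_equal(attr(rep, "n_present"), 4L)
})

test_that("patching refuses intact ends and degrades safely", {
  p <- small_params(seed = 22, read_error_rate = 0)
  ds <- simulate_genome(p)
  broken <- truncate_chromosome_end(ds$genome, "chrA", "3prime", 2000L)
  expect_error(patch_missing_telomere(ds$genome, "chrA", "3prime",
                                      tibble::tibble(read_id = "x", seq = "ACGT")),
               "already carries a telomere")
  empty <- tibble::tibble(read_id = character(0), seq = character(0))
  res <- patch_missing_telomere(broken, "chrA", "3prime", empty)
  expect_false(res$report$patched)
  expect_identical(unclass(res$genome), unclass(broken))
})

test_that("a perfect-identity anchor requirement rejects error-laden reads", {
  p <- small_params(seed = 23, read_error_rate = 0.05)
  ds <- simulate_genome(p)
  r <- simulate_reads(ds$genome, p)
  broken <- truncate_chromosome_end(ds$genome, "chrA", "3prime", 2000L)
  lib <- extract_telomeric_reads(r$reads, min_copies_read = 5)
  res <- patch_missing_telomere(broken, "chrA", "3prime", lib,
                                min_anchor_identity = 1.0)
  expect_false(res$report$patched)
})
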