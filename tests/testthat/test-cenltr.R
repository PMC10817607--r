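test_that("planted monomer copies are found at full identity and classified", {
  set.seed(50)
  cons <- random_dna(427, 0.4)
  spacer <- function(n) random_dna(n, 0.5)
  chrom <- paste0(spacer(3000), cons, spacer(2000), cons, spacer(2000), cons,
                  spacer(2000), substr(cons, 1, 213), spacer(2000),
                  revcomp(cons), spacer(3000))
  g <- as_genome(c(c1 = chrom))
  hits <- find_monomers(g, cons)
  expect_equal(nrow(hits), 5)
  full <- hits[hits$class == "complete", ]
  expect_equal(nrow(full), 4)
  expect_true(all(full$identity == 1))
  expect_equal(sum(hits$strand == "-"), 1)
  short <- hits[hits$class == "shorter", ]
  expect_equal(nrow(short), 1)
  expect_equal(short$coverage, 0.5, tolerance = 0.01)

  expect_error(find_monomers(g, strrep("N", 427)), "N")
  expect_error(find_monomers(g, "ACGT"), "50-2000")
})

test_that("hit finding agrees with an exhaustive sliding-identity oracle", {
  set.seed(51)
  cons <- random_dna(200, 0.45)
  mut <- function(s, k) {  # k substitutions at fixed spread positions
    x <- strsplit(s, "")[[1]]
    at <- round(seq(5, length(x) - 5, length.out = k))
    for (i in at) x[i] <- setdiff(c("A", "C", "G", "T"), x[i])[1]
    paste(x, collapse = "")
  }
  chrom <- paste0(random_dna(20000, 0.5), cons, random_dna(5000, 0.5),
                  mut(cons, 12), random_dna(5000, 0.5), mut(cons, 60),
                  random_dna(19800, 0.5))
  g <- as_genome(c(c1 = chrom))
  # oracle: gapless identity of the consensus at every offset, both strands
  best <- function(query) {
    mm <- centroscan:::frame_mismatches(chrom, query)
    which(mm <= 0.2 * nchar(query)) - 1L
  }
  oracle_starts <- sort(c(best(cons), best(revcomp(cons))))
  hits <- find_monomers(g, cons, min_identity = 0.8, seed_k = 11, stride = 5)
  expect_equal(sort(hits$start), oracle_starts)   # 60/200 mutations exceed 20%
  expect_equal(nrow(hits), 2)
})

test_that("paired elements are assembled with their structural hallmarks", {
  ds <- default_sim()
  tr <- ds$truth
  hits <- find_monomers(ds$genome, tr$ltr_consensus)
  els <- pair_elements(hits, ds$genome, pbs_motif = tr$pbs_motif,
                       domain_motifs = tr$domain_motifs)
  planted <- tr$ltr_elements
  expect_equal(nrow(els), nrow(planted))
  expect_equal(sum(els$type == "paired"), sum(planted$type == "paired"))
  expect_equal(sum(els$type == "solo"), sum(planted$type == "solo"))
  got_paired <- els[els$type == "paired", ]
  expect_true(all(got_paired$tsr_found))
  expect_true(all(got_paired$pbs_found))
  expect_true(all(got_paired$ppt_found))
  expect_true(all(got_paired$domain_order_ok))
  want_paired <- planted[planted$type == "paired", ]
  expect_equal(got_paired$start, want_paired$start)
  expect_equal(got_paired$end, want_paired$end)
  expect_equal(got_paired$tsr, want_paired$tsr)

  # pairing conservation: every hit is consumed exactly once
  expect_equal(2 * sum(els$type == "paired") + sum(els$type == "solo"),
               nrow(hits))
})

test_that("scrambled domain order and missing motifs are reported, not assumed", {
  set.seed(52)
  cons <- random_dna(427, 0.4)
  doms <- c(GAG = random_dna(60, 0.4), INT = random_dna(60, 0.4),
            RT = random_dna(60, 0.4), RH = random_dna(60, 0.4))
  tsr <- "GATCC"
  internal_ok <- paste0(random_dna(200, 0.4), doms["GAG"], random_dna(200, 0.4),
                        doms["INT"], random_dna(200, 0.4), doms["RT"],
                        random_dna(200, 0.4), doms["RH"],
                        random_dna(150, 0.4), strrep("AG", 8), random_dna(10, 0.4))
  internal_bad <- paste0(random_dna(200, 0.4), doms["RT"], random_dna(200, 0.4),
                         doms["INT"], random_dna(200, 0.4), doms["GAG"],
                         random_dna(200, 0.4), doms["RH"],
                         random_dna(150, 0.4), strrep("AG", 8), random_dna(10, 0.4))
  mk <- function(internal) paste0(tsr, cons, internal, cons, tsr)
  chrom <- paste0(random_dna(5000, 0.5), mk(internal_ok), random_dna(5000, 0.5),
                  mk(internal_bad), random_dna(5000, 0.5))
  g <- as_genome(c(c1 = chrom))
  hits <- find_monomers(g, cons)
  els <- pair_elements(hits, g, domain_motifs = doms)
  expect_equal(els$type, c("paired", "paired"))
  expect_equal(els$domain_order_ok, c(TRUE, FALSE))
  expect_true(all(els$ppt_found))
  expect_true(all(is.na(els$pbs_found)))  # no motif supplied -> not claimed
  expect_equal(els$tsr, c("GATCC", "GATCC"))
})

test_that("an isolated hit becomes a solo element; empty input stays empty", {
  set.seed(53)
  cons <- random_dna(427, 0.4)
  g <- as_genome(c(c1 = paste0(random_dna(2000, 0.5), cons, random_dna(2000, 0.5))))
  hits <- find_monomers(g, cons)
  els <- pair_elements(hits, g)
  expect_equal(els$type, "solo")
  empty <- pair_elements(hits[0, ], g)
  expect_equal(nrow(empty), 0)
})

test_that("monomer detection is monotone in identity and strand-symmetric", {
  fx <- ltr_fixture(seed = 54, mut_rate = 0.05)
  strict <- find_monomers(fx$genome, fx$consensus, min_identity = 0.9)
  loose <- find_monomers(fx$genome, fx$consensus, min_identity = 0.8)
  # every strict locus survives loosening (trim bounds may shift slightly)
  for (i in seq_len(nrow(strict))) {
    expect_true(any(loose$start < strict$end[i] & loose$end > strict$start[i]))
  }
  expect_gte(nrow(loose), nrow(strict))

  rc <- as_genome(c(fix = revcomp(unclass(fx$genome)[["fix"]])))
  a <- find_monomers(fx$genome, fx$consensus)
  b <- find_monomers(rc, fx$consensus)
  expect_equal(nrow(a), nrow(b))
  expect_equal(table(a$class), table(b$class))
  ea <- pair_elements(a, fx$genome)
  eb <- pair_elements(b, rc)
  expect_equal(table(ea$type), table(eb$type))
})

test_that("planted layouts are recovered exactly clean and within one at 5% divergence", {
  fx0 <- ltr_fixture(seed = 55, mut_rate = 0)
  h0 <- find_monomers(fx0$genome, fx0$consensus)
  e0 <- pair_elements(h0, fx0$genome)
  expect_equal(sum(e0$type == "paired"), fx0$n_paired)
  expect_equal(sum(e0$type == "solo"), fx0$n_solo)

  fx5 <- ltr_fixture(seed = 56, mut_rate = 0.05)
  h5 <- find_monomers(fx5$genome, fx5$consensus)
  e5 <- pair_elements(h5, fx5$genome)
  expect_lte(abs(sum(e5$type == "paired") - fx5$n_paired), 1)
  expect_lte(abs(sum(e5$type == "solo") - fx5$n_solo), 1)
})

test_that("copy tables and centromere co-location are conservative tabulations", {
  # emulate a per-chromosome layout with 2, 9 and 6 monomers
  set.seed(57)
  cons <- random_dna(427, 0.4)
  mkchrom <- function(n) {
    parts <- c(random_dna(3000, 0.5),
               unlist(lapply(seq_len(n), function(i) c(cons, random_dna(1500, 0.5)))))
    paste(parts, collapse = "")
  }
  g <- as_genome(c(chrA = mkchrom(2), chrB = mkchrom(9), chrC = mkchrom(6)))
  hits <- find_monomers(g, cons)
  els <- pair_elements(hits, g, internal_min = 100L)
  tab <- copy_table(els, hits)
  expect_equal(tab$n_hits, c(2L, 9L, 6L))
  expect_equal(sum(tab$n_hits), nrow(hits))
  expect_equal(2 * tab$n_paired + tab$n_solo, tab$n_hits)

  empty_tab <- copy_table(els[0, ], hits[0, ])
  expect_equal(nrow(empty_tab), 0)

  # all elements planted inside called centromeres -> fraction 1; an arm
  # element is reported outside
  ds <- default_sim()
  hits2 <- find_monomers(ds$genome, ds$truth$ltr_consensus)
  els2 <- pair_elements(hits2, ds$genome)
  col <- centromere_colocation(els2, ds$truth$centromeres)
  expect_equal(col$fraction_inside, 1.0)
  outside <- tibble::tibble(chrom = "chr1", type = "solo", strand = "+",
                            start = 10000, end = 10427)
  col2 <- centromere_colocation(dplyr::bind_rows(els2, outside),
                                ds$truth$centromeres)
  expect_lt(col2$fraction_inside, 1.0)
  expect_equal(sum(col2$per_chrom$n_outside), 1)
})
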