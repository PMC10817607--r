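# Shared fixtures, built in code. The default dataset is simulated once per
# test run and cached; size-sensitive tests build their own smaller worlds.

.fixture_cache <- new.env(parent = emptyenv())

default_sim <- function() {
  if (is.null(.fixture_cache$ds)) {
    p <- sim_params(seed = 42)
    .fixture_cache$ds <- c(simulate_genome(p), list(params = p))
  }
  .fixture_cache$ds
}

default_reads <- function() {
  if (is.null(.fixture_cache$reads)) {
    ds <- default_sim()
    .fixture_cache$reads <- simulate_reads(ds$genome, ds$params)
  }
  .fixture_cache$reads
}

# compact two-chromosome world for read-heavy tests
small_params <- function(seed, ...) {
  defaults <- list(chrom_lengths = c(chrA = 150000L, chrB = 100000L),
                   rdna_chrom = NA,
                   read_length_mean = 6000, read_length_sd = 800,
                   read_depth = 20,
                   anomaly_regions = NULL, mq0_regions = NULL)
  args <- utils::modifyList(defaults, list(...))
  do.call(sim_params, c(list(seed = seed), args))
}

# independent oracle: longest exact tandem run of `unit` (or its reverse
# complement) in a sequence, via regex rather than the package's frame chain
oracle_max_run <- function(seq, unit) {
  run_of <- function(u) {
    m <- gregexpr(sprintf("(?:%s)+", u), seq, perl = TRUE)[[1]]
    if (m[1] == -1L) return(0L)
    max(attr(m, "match.length")) %/% nchar(u)
  }
  max(run_of(unit), run_of(centroscan::revcomp(unit)))
}

# build a chromosome carrying hand-assembled LTR elements (independent of the
# package simulator); returns the genome, the consensus and the planted counts
ltr_fixture <- function(seed, mut_rate = 0) {
  set.seed(seed)
  sub_mutate <- function(s, rate) {
    if (rate <= 0) return(s)
    x <- strsplit(s, "")[[1]]
    hit <- which(runif(length(x)) < rate)
    for (i in hit) x[i] <- sample(setdiff(c("A", "C", "G", "T"), x[i]), 1)
    paste(x, collapse = "")
  }
  cons <- random_dna(427, 0.4)
  tsr <- random_dna(5, 0.5)
  internal <- random_dna(3000, 0.4)
  paired <- paste0(tsr, sub_mutate(cons, mut_rate), internal,
                   sub_mutate(cons, mut_rate), tsr)
  solo1 <- sub_mutate(cons, mut_rate)
  solo2 <- revcomp(sub_mutate(cons, mut_rate))
  chrom <- paste0(random_dna(8000, 0.5), paired, random_dna(6000, 0.5),
                  solo1, random_dna(7000, 0.5), solo2, random_dna(9000, 0.5))
  list(genome = as_genome(c(fix = chrom)), consensus = cons,
       n_paired = 1L, n_solo = 2L, n_hits = 4L)
}
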