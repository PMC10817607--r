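#' Count canonical k-mers
#'
#' Every window of length `k` contributes its canonical form (the
#' lexicographic minimum of the window and its reverse complement); windows
#' containing `N` are skipped. Counting is over *distinct* canonical k-mers
#' with multiplicities.
#'
#' @param x Sequences: a `"genome"`, character vector, `DNAStringSet`, or a
#'   read tibble with a `seq` column.
#' @param k Odd k-mer size, 3--31 (default 17).
#' @return Tibble `kmer`, `count`, sorted by `kmer`, with attribute
#'   `total_instances` (total counted windows) and `k`.
#' @export
count_canonical_kmers <- function(x, k = 17L) {
  k <- as.integer(k)
  if (k < 3L || k > 31L || k %% 2L == 0L) cs_stop("k must be odd and in 3..31")
  seqs <- extract_sequences(x)
  if (all(nchar(seqs) < k)) {
    cs_warn("k = %d exceeds every sequence length; empty k-mer set", k)
  }
  res <- .kmer_count_cpp(toupper(seqs), k)
  out <- tibble(kmer = as.character(res$kmer), count = as.numeric(res$count))
  out <- arrange(out, kmer)
  attr(out, "total_instances") <- res$total
  attr(out, "k") <- k
  out
}

extract_sequences <- function(x) {
  if (inherits(x, "genome")) return(unname(unclass(x)))
  if (methods::is(x, "XStringSet")) return(as.character(x))
  if (is.data.frame(x)) {
    if (!"seq" %in% names(x)) cs_stop("read tibble must have a 'seq' column")
    return(x$seq)
  }
  if (is.character(x)) return(unname(x))
  cs_stop("cannot extract sequences from a %s", class(x)[1])
}

#' Consensus quality value from assembly and read k-mer sets
#'
#' Every distinct canonical assembly k-mer is looked up in the read k-mer set;
#' those absent from the reads (`K_only` of `K_total`) are evidence of
#' consensus error. The per-base error estimate is
#' `E = 1 - (1 - K_only/K_total)^(1/k)`, the quality value
#' `QV = -10 log10(E)`, and the base accuracy `(1 - E) * 100` percent.
#'
#' @param assembly_kmers,read_kmers K-mer tibbles from
#'   [count_canonical_kmers()] (or character vectors of k-mers).
#' @param k K-mer size; taken from the `k` attribute when `NULL`.
#' @return See [kmer_qv_from_counts()].
#' @export
kmer_qv <- function(assembly_kmers, read_kmers, k = NULL) {
  k <- k %||% attr(assembly_kmers, "k")
  if (is.null(k)) cs_stop("k must be supplied")
  a <- if (is.data.frame(assembly_kmers)) assembly_kmers$kmer else assembly_kmers
  r <- if (is.data.frame(read_kmers)) read_kmers$kmer else read_kmers
  if (length(a) == 0L) cs_stop("assembly k-mer set is empty")
  a <- unique(a)
  K_total <- length(a)
  K_only <- sum(!(a %in% unique(r)))
  kmer_qv_from_counts(K_only, K_total, k)
}

#' Quality-value arithmetic from k-mer counts
#'
#' The closed-form error model of [kmer_qv()], applied directly to the two
#' distinct-k-mer counts. `accuracy_pct + 100 * E == 100` by construction.
#' `K_only = 0` gives `E = 0` and an infinite QV; `K_only = K_total` gives
#' `E = 1` and `QV = 0` with a warning.
#'
#' @param K_only Distinct assembly k-mers absent from the read set.
#' @param K_total Distinct assembly k-mers.
#' @param k K-mer size.
#' @return One-row tibble of class `"kmer_qc"`: `k`, `K_total`, `K_only`,
#'   `E`, `QV`, `accuracy_pct`.
#' @export
kmer_qv_from_counts <- function(K_only, K_total, k) {
  stopifnot(is_count(K_only), is_count(K_total), is_count(k), k >= 1)
  if (K_total == 0) cs_stop("assembly k-mer set is empty")
  if (K_only > K_total) cs_stop("K_only cannot exceed K_total")
  E <- 1 - (1 - K_only / K_total)^(1 / k)
  if (K_only == K_total) {
    cs_warn("every assembly k-mer is unsupported by the reads (E = 1, QV = 0)")
    QV <- 0
  } else if (K_only == 0) {
    QV <- Inf
  } else {
    QV <- -10 * log10(E)
  }
  out <- tibble(k = as.integer(k), K_total = K_total, K_only = K_only,
                E = E, QV = QV, accuracy_pct = (1 - E) * 100)
  class(out) <- unique(c("kmer_qc", class(out)))
  out
}

#' k-mer multiplicity histogram and peak-based genome-size estimate
#'
#' Builds the histogram of read k-mer multiplicities and locates the
#' homozygous peak: the modal multiplicity greater than 1, taken on a
#' 5-point moving mean of the histogram to stabilise the empirical mode
#' against bin-level sampling noise. The peak depth is then refined to the
#' histogram-weighted mean multiplicity within +/-30% of the mode (which
#' rides the top of the coverage distribution rather than a single noisy
#' bin), and genome size is estimated as total k-mer instances divided by
#' the peak depth. With no multiplicity above 1 the estimate is undefined
#' and a warning is issued.
#'
#' @param read_kmers K-mer tibble from [count_canonical_kmers()] on reads.
#' @return List of class `"kmer_histogram"`: `histogram` (tibble
#'   `multiplicity`, `n_kmers`), `total_instances`, `peak_multiplicity`
#'   (smoothed mode), `peak_depth` (refined), `genome_size_estimate`.
#' @export
kmer_histogram <- function(read_kmers) {
  stopifnot(is.data.frame(read_kmers), "count" %in% names(read_kmers))
  tab <- read_kmers |>
    dplyr::count(multiplicity = count, name = "n_kmers") |>
    arrange(multiplicity)
  total <- attr(read_kmers, "total_instances") %||% sum(tab$multiplicity * tab$n_kmers)
  above1 <- filter(tab, multiplicity > 1)
  if (nrow(above1) == 0L) {
    cs_warn("no k-mer multiplicity above 1; genome-size estimate undefined")
    mode_mult <- NA_real_
    peak <- NA_real_
    est <- NA_real_
  } else {
    grid <- tibble(multiplicity = seq(2, max(above1$multiplicity))) |>
      left_join(above1, by = "multiplicity") |>
      mutate(n_kmers = dplyr::coalesce(n_kmers, 0))
    sm <- moving_mean(grid$n_kmers, 5L)
    mode_mult <- grid$multiplicity[which.max(sm)]
    win <- grid$multiplicity >= 0.7 * mode_mult & grid$multiplicity <= 1.3 * mode_mult
    peak <- sum(grid$multiplicity[win] * grid$n_kmers[win]) / sum(grid$n_kmers[win])
    est <- total / peak
  }
  structure(list(histogram = tab, total_instances = total,
                 peak_multiplicity = mode_mult, peak_depth = peak,
                 genome_size_estimate = est),
            class = "kmer_histogram")
}

#' @export
print.kmer_histogram <- function(x, ...) {
  cat(sprintf("<kmer_histogram> %s instances; peak depth %s; size estimate %s bp\n",
              format(x$total_instances, big.mark = ","),
              format(x$peak_depth), format(round(x$genome_size_estimate))))
  invisible(x)
}
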