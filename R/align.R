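# Maximum-scoring contiguous segment of a 0/1 match vector under a per-base
# charge of `rate` (Kadane via prefix sums): the returned segment has mean
# match rate >= `rate` whenever one exists; NULL otherwise.
best_segment <- function(m, rate) {
  x <- m - rate
  # round prefix sums so mathematically tied prefixes compare equal and the
  # earliest (longest) segment wins the tie
  cs <- round(cumsum(x), 9)
  prior <- cummin(c(0, cs[-length(cs)]))
  gain <- cs - prior
  if (max(gain) <= 0) return(NULL)
  e <- which.max(gain)
  s <- which.min(c(0, cs[-length(cs)])[seq_len(e)])
  c(s, e)
}

# Shared gapless seed-and-extend matcher.
#
# Exact seeds of length `seed_k` are taken from the query every `stride` bp
# (plus the final offset) and located in each subject with matchPDict; each
# seed hit fixes an alignment diagonal, the full query is projected onto the
# subject along that diagonal (clipped at subject bounds, no indels) and the
# projection is scored by identity. One candidate per (subject, strand,
# diagonal). Suited to the planted-copy structure of this package's targets
# (tandem arrays and LTR monomers diverge by substitutions); it does not model
# insertions or deletions.
seed_extend_hits <- function(subjects, query, seed_k = 31L, stride = NULL,
                             min_identity = 0.9, min_len = 100L,
                             strands = c("+", "-")) {
  if (is.data.frame(subjects)) {
    subjects <- setNames(subjects$seq, subjects$read_id)
  }
  if (inherits(subjects, "genome")) subjects <- unclass(subjects)
  stopifnot(is.character(subjects), !is.null(names(subjects)))
  query <- toupper(query)
  U <- nchar(query)
  if (U == 0L) cs_stop("empty query sequence")
  seed_k <- min(as.integer(seed_k), U)
  stride <- as.integer(stride %||% seed_k)

  rows <- list()
  for (strand in strands) {
    q <- if (strand == "-") revcomp(query) else query
    offs <- unique(c(seq.int(0L, U - seed_k, by = stride), U - seed_k))
    seeds <- substring(q, offs + 1L, offs + seed_k)
    ok <- !grepl("N", seeds, fixed = TRUE)
    offs <- offs[ok]; seeds <- seeds[ok]
    if (length(seeds) == 0L) next
    dict <- Biostrings::PDict(Biostrings::DNAStringSet(seeds))
    qi <- utf8ToInt(q)
    for (sn in names(subjects)) {
      subj <- subjects[[sn]]
      Ls <- nchar(subj)
      if (Ls < seed_k) next
      mi <- Biostrings::matchPDict(dict, Biostrings::DNAString(subj))
      cnt <- S4Vectors::elementNROWS(mi)
      if (sum(cnt) == 0L) next
      starts <- BiocGenerics::start(unlist(mi))  # 1-based
      diag <- (starts - 1L) - rep(offs, cnt)
      for (dg in unique(diag)) {
        s0 <- max(dg, 0L)
        e0 <- min(dg + U, Ls)
        w <- e0 - s0
        if (w < min_len) next
        qs <- s0 - dg
        si <- utf8ToInt(substr(subj, s0 + 1L, e0))
        m <- as.integer(si == qi[(qs + 1L):(qs + w)])
        # trim the projection to its best local segment (handles partial
        # copies whose remainder runs into unrelated sequence)
        seg <- best_segment(m, min_identity)
        if (is.null(seg) || seg[2] - seg[1] + 1L < min_len) next
        ident <- mean(m[seg[1]:seg[2]])
        if (ident < min_identity) next
        rows[[length(rows) + 1L]] <-
          tibble(seqname = sn, start = s0 + seg[1] - 1L, end = s0 + seg[2],
                 strand = strand, identity = ident,
                 coverage = (seg[2] - seg[1] + 1L) / U)
      }
    }
  }
  if (length(rows) == 0L) {
    return(tibble(seqname = character(0), start = numeric(0), end = numeric(0),
                  strand = character(0), identity = numeric(0),
                  coverage = numeric(0)))
  }
  arrange(bind_rows(rows), seqname, start)
}
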