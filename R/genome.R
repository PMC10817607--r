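#' Genome container
#'
#' A genome is a named character vector of uppercase chromosome sequences with
#' class `"genome"`. Names must be unique and non-empty and the alphabet is
#' restricted to A, C, G, T, N. All internal coordinates in this package are
#' 0-based half-open; conversion to the 1-based closed convention happens only
#' at GFF3 I/O boundaries.
#'
#' @param x Named character vector of sequences, or a
#'   [Biostrings::DNAStringSet].
#' @return An object of class `"genome"`.
#' @export
as_genome <- function(x) {
  if (inherits(x, "genome")) return(x)
  if (methods::is(x, "XStringSet")) x <- setNames(as.character(x), names(x))
  if (!is.character(x)) cs_stop("a genome must be a named character vector or DNAStringSet")
  nm <- names(x)
  if (is.null(nm) || any(is.na(nm)) || any(!nzchar(nm))) {
    cs_stop("all chromosome names must be non-empty")
  }
  if (anyDuplicated(nm)) {
    cs_stop("duplicate chromosome name: '%s'", nm[duplicated(nm)][1])
  }
  x <- toupper(x)
  bad <- regexpr("[^ACGTN]", x)
  if (any(bad > 0L)) {
    i <- which(bad > 0L)[1]
    cs_stop("illegal character in record '%s' at offset %d", nm[i], as.integer(bad[i]))
  }
  structure(x, class = "genome")
}

#' @export
print.genome <- function(x, ...) {
  cat(sprintf("<genome> %d sequence(s), %s bp total\n",
              length(x), format(sum(nchar(x)), big.mark = ",")))
  for (i in seq_along(x)) {
    cat(sprintf("  %-12s %10s bp\n", names(x)[i], format(nchar(x[[i]]), big.mark = ",")))
  }
  invisible(x)
}

#' Chromosome lengths of a genome
#'
#' @param genome A [as_genome()] object.
#' @return Named integer vector of lengths in bp.
#' @export
genome_lengths <- function(genome) {
  genome <- as_genome(genome)
  setNames(nchar(unclass(genome)), names(genome))
}

#' Read a genome from FASTA
#'
#' Sequences are uppercased and validated (unique non-empty names, alphabet
#' A/C/G/T/N); record order is preserved.
#'
#' @param path Path to a FASTA file.
#' @return A `"genome"` object.
#' @export
read_genome_fasta <- function(path) {
  if (!file.exists(path)) cs_stop("no such file: %s", path)
  ss <- tryCatch(Biostrings::readBStringSet(path), error = function(e) {
    cs_stop("empty or malformed FASTA file %s (%s)", path, conditionMessage(e))
  })
  if (length(ss) == 0L) cs_stop("empty FASTA file: %s", path)
  # FASTA headers may carry descriptions; the record name is the first word
  names(ss) <- sub("\\s.*$", "", names(ss))
  as_genome(setNames(as.character(ss), names(ss)))
}

#' Write a genome to FASTA
#'
#' @param genome A `"genome"` object.
#' @param path Output path.
#' @param width Line width for sequence wrapping.
#' @return `path`, invisibly.
#' @export
write_genome_fasta <- function(genome, path, width = 80L) {
  genome <- as_genome(genome)
  ss <- Biostrings::DNAStringSet(unclass(genome))
  Biostrings::writeXStringSet(ss, path, width = width)
  invisible(path)
}

#' Remove terminal sequence from one chromosome end
#'
#' Utility for emulating an assembly whose terminal repeats were not resolved
#' (e.g. a chromosome that lost its telomere to a collapsed terminal array):
#' drops `n_bp` from the named end.
#'
#' @param genome A `"genome"` object.
#' @param chrom Chromosome name.
#' @param side `"5prime"` or `"3prime"`.
#' @param n_bp Number of bases to remove (< chromosome length).
#' @return The modified genome.
#' @export
truncate_chromosome_end <- function(genome, chrom, side = c("5prime", "3prime"), n_bp) {
  genome <- as_genome(genome)
  side <- match.arg(side)
  if (!chrom %in% names(genome)) cs_stop("unknown chromosome '%s'", chrom)
  stopifnot(is_count(n_bp))
  s <- unclass(genome)[[chrom]]
  if (n_bp >= nchar(s)) cs_stop("cannot remove %d bp from a %d bp chromosome", n_bp, nchar(s))
  g <- unclass(genome)
  g[[chrom]] <- if (side == "5prime") substr(s, n_bp + 1L, nchar(s)) else substr(s, 1L, nchar(s) - n_bp)
  as_genome(g)
}

# fetch one chromosome sequence (internal)
chrom_seq <- function(genome, chrom) {
  genome <- as_genome(genome)
  if (!chrom %in% names(genome)) cs_stop("unknown chromosome '%s'", chrom)
  unclass(genome)[[chrom]]
}
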