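#' Binned Hi-C contact matrices
#'
#' A contact matrix holds symmetric, non-negative binned contact counts over
#' all genome bins, with genome-global bin indexing: chromosome bins are laid
#' out consecutively and each chromosome records the offset of its first
#' global bin, so cis and trans blocks are addressable uniformly.
#'
#' @param counts Square numeric matrix of contact counts (global bins).
#' @param bin_size Bin width in bp.
#' @param chrom_lengths Named vector of chromosome lengths in bp; the order
#'   defines the global bin layout.
#' @return An object of class `"contact_matrix"`: a list with `counts`,
#'   `bin_size` and a `chroms` tibble (`chrom`, `length`, `n_bins`, `offset`).
#' @export
contact_matrix <- function(counts, bin_size, chrom_lengths) {
  stopifnot(is.matrix(counts), nrow(counts) == ncol(counts))
  if (any(counts < 0)) cs_stop("contact counts must be non-negative")
  if (max(abs(counts - t(counts))) > 1e-8) cs_stop("contact matrix must be symmetric")
  nb <- as.integer(ceiling(chrom_lengths / bin_size))
  if (sum(nb) != nrow(counts)) {
    cs_stop("matrix has %d bins but chromosome table implies %d", nrow(counts), sum(nb))
  }
  chroms <- tibble(chrom = names(chrom_lengths),
                   length = as.numeric(chrom_lengths),
                   n_bins = nb,
                   offset = c(0L, cumsum(nb)[-length(nb)]))
  structure(list(counts = counts, bin_size = as.integer(bin_size), chroms = chroms),
            class = "contact_matrix")
}

#' @export
print.contact_matrix <- function(x, ...) {
  cat(sprintf("<contact_matrix> %d chromosomes, %d global bins at %s bp\n",
              nrow(x$chroms), nrow(x$counts), format(x$bin_size, big.mark = ",")))
  invisible(x)
}

#' Global bin table of a contact matrix
#'
#' @param cm A `"contact_matrix"`.
#' @return Tibble with `chrom`, `bin` (global, 0-based), `start`, `end`.
#' @export
contact_bins <- function(cm) {
  purrr::pmap_dfr(cm$chroms, function(chrom, length, n_bins, offset) {
    b <- tile_bins(length, cm$bin_size)
    tibble(chrom = chrom, bin = offset + seq_len(n_bins) - 1L,
           start = b$start, end = b$end)
  })
}

#' Read a contact matrix from text
#'
#' The format is self-describing: header lines `#bin_size <bp>`,
#' one `#chrom <name> <length>` per chromosome, and `#format triplet|dense`.
#' A triplet body has lines `bin_i bin_j value` with 0-based global bin
#' indices (each value is assigned symmetrically to both `(i,j)` and `(j,i)`);
#' a dense body has one whitespace-separated row per global bin. An empty
#' triplet body yields an all-zero matrix of the declared shape.
#'
#' @param path Input file.
#' @return A `"contact_matrix"`.
#' @export
read_contacts <- function(path) {
  if (!file.exists(path)) cs_stop("no such file: %s", path)
  lines <- readLines(path)
  hdr <- lines[startsWith(lines, "#")]
  body <- lines[!startsWith(lines, "#") & nzchar(trimws(lines))]
  get1 <- function(key) {
    h <- hdr[startsWith(hdr, paste0("#", key))]
    if (length(h) != 1L) cs_stop("contact header must contain exactly one '#%s' line", key)
    strsplit(trimws(sub(paste0("^#", key), "", h)), "\\s+")[[1]]
  }
  bin_size <- as.integer(get1("bin_size"))
  fmt <- get1("format")
  ch <- hdr[startsWith(hdr, "#chrom")]
  if (length(ch) == 0L) cs_stop("contact header declares no chromosomes")
  parts <- strsplit(trimws(sub("^#chrom", "", ch)), "\\s+")
  lens <- setNames(as.numeric(vapply(parts, `[`, "", 2L)),
                   vapply(parts, `[`, "", 1L))
  n <- sum(ceiling(lens / bin_size))
  counts <- matrix(0, n, n)
  if (fmt == "triplet") {
    if (length(body)) {
      m <- do.call(rbind, lapply(strsplit(body, "\\s+"), as.numeric))
      if (any(is.na(m)) || ncol(m) != 3L) cs_stop("malformed triplet line in %s", path)
      if (any(m[, 3] < 0)) cs_stop("negative contact count in %s", path)
      if (any(m[, 1:2] < 0 | m[, 1:2] >= n)) cs_stop("bin index out of range in %s", path)
      i <- m[, 1] + 1L; j <- m[, 2] + 1L
      counts[cbind(i, j)] <- m[, 3]
      counts[cbind(j, i)] <- m[, 3]
    }
  } else if (fmt == "dense") {
    if (length(body) != n) cs_stop("dense matrix must have %d rows, found %d", n, length(body))
    counts <- do.call(rbind, lapply(strsplit(trimws(body), "\\s+"), as.numeric))
    if (any(is.na(counts))) cs_stop("malformed dense matrix in %s", path)
    counts <- (counts + t(counts)) / 2
  } else {
    cs_stop("unknown contact format '%s'", fmt)
  }
  contact_matrix(counts, bin_size, lens)
}

#' Write a contact matrix to text
#'
#' @param cm A `"contact_matrix"`.
#' @param path Output file.
#' @param format `"triplet"` (upper triangle, non-zero entries) or `"dense"`.
#' @return `path`, invisibly.
#' @export
write_contacts <- function(cm, path, format = c("triplet", "dense")) {
  format <- match.arg(format)
  hdr <- c(sprintf("#bin_size %d", cm$bin_size),
           sprintf("#chrom %s %d", cm$chroms$chrom, as.integer(cm$chroms$length)),
           sprintf("#format %s", format))
  if (format == "triplet") {
    idx <- which(upper.tri(cm$counts, diag = TRUE) & cm$counts != 0, arr.ind = TRUE)
    body <- sprintf("%d %d %s", idx[, 1] - 1L, idx[, 2] - 1L,
                    format(cm$counts[idx], digits = 17, scientific = FALSE, trim = TRUE))
  } else {
    body <- apply(cm$counts, 1L, function(r) {
      paste(format(r, digits = 17, scientific = FALSE, trim = TRUE), collapse = " ")
    })
  }
  writeLines(c(hdr, body), path)
  invisible(path)
}
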