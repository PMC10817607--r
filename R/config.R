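#' Pipeline configuration
#'
#' Stage parameters live in a flat key--value configuration. Every parameter
#' has a documented default and an allowed range that is validated at load
#' time; [resolve_config()] layers a file and explicit overrides on top of the
#' defaults and can log the fully resolved set for reproducibility of
#' threshold-sensitive calls.
#'
#' @return `default_config()` returns the default configuration as a named
#'   list.
#' @export
default_config <- function() {
  as.list(setNames(config_registry()$default, config_registry()$name))
}

config_registry <- function() {
  tibble(
    name = c("telomere_unit", "telomere_window", "telomere_min_copies",
             "telomere_max_mismatch_frac", "telomere_min_copies_read",
             "patch_anchor_len", "patch_min_anchor_identity",
             "kmer_k",
             "coverage_bin_size", "anomaly_mode", "anomaly_threshold",
             "anomaly_fraction", "mq0_min_fraction",
             "rdna_seed_k", "rdna_min_identity", "rdna_min_hit_len",
             "oe_d_min", "oe_epsilon", "cen_peak_fraction", "cen_min_evidence",
             "cen_smooth_bins", "cen_edge_frac", "cen_min_peak_mads",
             "ltr_min_identity", "ltr_complete_cov", "ltr_short_cov",
             "ltr_internal_min", "ltr_internal_max", "ltr_pair_identity",
             "ltr_tsr_min", "ltr_tsr_max"),
    default = list("CCCTAA", 1000L, 5L, 1 / 6, 10L,
                   500L, 0.95,
                   17L,
                   10000L, "absolute", 80, 0.32, 0.8,
                   31L, 0.9, 100L,
                   50L, 1e-9, 0.5, 2L, 3L, 0.05, 5,
                   0.8, 0.8, 0.4, 1000L, 15000L, 0.85, 4L, 6L),
    type = c("character", "integer", "integer", "numeric", "integer",
             "integer", "numeric",
             "integer",
             "integer", "character", "numeric", "numeric", "numeric",
             "integer", "numeric", "integer",
             "integer", "numeric", "numeric", "integer", "integer", "numeric",
             "numeric",
             "numeric", "numeric", "numeric", "integer", "integer", "numeric",
             "integer", "integer"),
    min = list(NA, 6, 1, 0, 1, 10, 0, 3, 1, NA, 1e-12, 1e-12, 0,
               4, 0, 1, 1, 0, 0, 0, 1, 0, 0,
               0, 0, 0, 1, 1, 0, 1, 1),
    max = list(NA, Inf, Inf, 1, Inf, Inf, 1, 31, Inf, NA, Inf, 1, 1,
               Inf, 1, Inf, Inf, 1, 1, 4, Inf, 0.5, Inf,
               1, 1, 1, Inf, Inf, 1, Inf, Inf)
  )
}

#' Read a key--value configuration file
#'
#' Lines have the form `key = value`; blank lines and `#` comments are
#' ignored. Unknown keys and out-of-range values are fatal.
#'
#' @param path Configuration file.
#' @return Named list of parsed values (defaults for keys not in the file).
#' @export
read_config <- function(path) {
  if (!file.exists(path)) cs_stop("no such file: %s", path)
  lines <- readLines(path)
  lines <- trimws(sub("#.*$", "", lines))
  lines <- lines[nzchar(lines)]
  kv <- strsplit(lines, "\\s*=\\s*")
  bad <- lengths(kv) != 2L
  if (any(bad)) cs_stop("malformed config line: '%s'", lines[bad][1])
  vals <- setNames(vapply(kv, `[`, "", 2L), vapply(kv, `[`, "", 1L))
  resolve_config(overrides = as.list(vals))
}

#' Resolve a configuration from defaults plus overrides
#'
#' @param config Base configuration (defaults when `NULL`).
#' @param overrides Named list of key--value overrides (e.g. CLI flags);
#'   values may be strings and are coerced to the declared type.
#' @param log Print the fully resolved parameter set via `message()`.
#' @return Validated named list.
#' @export
resolve_config <- function(config = NULL, overrides = list(), log = FALSE) {
  reg <- config_registry()
  out <- default_config()
  apply_layer <- function(out, layer) {
    for (key in names(layer)) {
      i <- match(key, reg$name)
      if (is.na(i)) cs_stop("unknown configuration key '%s'", key)
      v <- layer[[key]]
      v <- switch(reg$type[i],
                  integer = as.integer(v),
                  numeric = as.numeric(v),
                  character = as.character(v))
      if (reg$type[i] != "character") {
        if (is.na(v)) cs_stop("configuration key '%s' is not %s", key, reg$type[i])
        if (v < reg$min[[i]] || v > reg$max[[i]]) {
          cs_stop("configuration key '%s' = %s outside allowed range [%s, %s]",
                  key, v, reg$min[[i]], reg$max[[i]])
        }
      }
      out[[key]] <- v
    }
    out
  }
  out <- apply_layer(out, config %||% list())
  out <- apply_layer(out, overrides)
  if (log) {
    message("resolved configuration:")
    for (key in names(out)) message(sprintf("  %s = %s", key, out[[key]]))
  }
  out
}
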