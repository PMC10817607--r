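#' @import ggplot2
NULL

#' Plot a binned depth track
#'
#' One panel per chromosome; optional anomaly intervals are shaded.
#'
#' @param depth A `"depth_track"`.
#' @param anomalies Optional `"interval_track"` of anomalies.
#' @param threshold Optional horizontal cutoff line.
#' @return A ggplot object.
#' @export
plot_depth <- function(depth, anomalies = NULL, threshold = NULL) {
  p <- ggplot(depth, aes(x = (start + end) / 2e3, y = depth)) +
    geom_step(linewidth = 0.3) +
    facet_wrap(~chrom, scales = "free_x") +
    labs(x = "position (kb)", y = "depth (fold)") +
    theme_bw()
  if (!is.null(anomalies) && nrow(anomalies) > 0) {
    p <- p + geom_rect(data = as_tibble(anomalies),
                       aes(xmin = start / 1e3, xmax = end / 1e3),
                       ymin = -Inf, ymax = Inf, inherit.aes = FALSE,
                       fill = "firebrick", alpha = 0.25)
  }
  if (!is.null(threshold)) {
    p <- p + geom_hline(yintercept = threshold, linetype = 2, colour = "firebrick")
  }
  p
}

#' Plot per-bin OE intensity scores with centromere calls
#'
#' @param oe An `"oe_matrix"`.
#' @param calls Optional `"centromere_calls"` tibble; called regions are
#'   shaded.
#' @return A ggplot object.
#' @export
plot_oe_scores <- function(oe, calls = NULL) {
  b <- oe$bins
  long <- tidyr::pivot_longer(b, c(trans_score, cis_score),
                              names_to = "score", values_to = "value")
  p <- ggplot(long, aes(x = (start + end) / 2e3, y = value, colour = score)) +
    geom_line(linewidth = 0.4, na.rm = TRUE) +
    facet_wrap(~chrom, scales = "free_x") +
    labs(x = "position (kb)", y = "mean OE") +
    theme_bw()
  if (!is.null(calls)) {
    reg <- calls[calls$called, , drop = FALSE]
    if (nrow(reg) > 0) {
      p <- p + geom_rect(data = reg, aes(xmin = start / 1e3, xmax = end / 1e3),
                         ymin = -Inf, ymax = Inf, inherit.aes = FALSE,
                         fill = "steelblue", alpha = 0.2)
    }
  }
  p
}

#' Plot windowed sequence-feature tracks
#'
#' GC, gene density, repeat density and transcription in stacked panels per
#' chromosome — the characteristic plot used to verify centromere candidates.
#'
#' @param features A `"feature_tracks"` tibble.
#' @param calls Optional `"centromere_calls"`; called regions are shaded.
#' @return A ggplot object.
#' @export
plot_feature_tracks <- function(features, calls = NULL) {
  long <- tidyr::pivot_longer(features,
                              c(gc, gene_density, repeat_density, rna_depth),
                              names_to = "feature", values_to = "value")
  p <- ggplot(long, aes(x = (start + end) / 2e3, y = value)) +
    geom_line(linewidth = 0.3, na.rm = TRUE) +
    ggh4x_like_grid() +
    facet_grid(feature ~ chrom, scales = "free") +
    labs(x = "position (kb)", y = NULL) +
    theme_bw()
  if (!is.null(calls)) {
    reg <- calls[calls$called, , drop = FALSE]
    if (nrow(reg) > 0) {
      p <- p + geom_rect(data = reg, aes(xmin = start / 1e3, xmax = end / 1e3),
                         ymin = -Inf, ymax = Inf, inherit.aes = FALSE,
                         fill = "steelblue", alpha = 0.2)
    }
  }
  p
}

# placeholder for a grid tweak; kept separate so the plot builds without
# suggested packages
ggh4x_like_grid <- function() {
  theme(panel.spacing = grid::unit(2, "pt"))
}

#' Plot a contact matrix heatmap
#'
#' @param cm A `"contact_matrix"`.
#' @param log Log10-transform counts.
#' @return A ggplot object.
#' @export
plot_contact_matrix <- function(cm, log = TRUE) {
  n <- nrow(cm$counts)
  df <- tibble(i = rep(seq_len(n), n), j = rep(seq_len(n), each = n),
               value = as.vector(cm$counts))
  if (log) df$value <- log10(df$value + 1)
  ggplot(df, aes(i, j, fill = value)) +
    geom_raster() +
    scale_fill_viridis_c(name = if (log) "log10(n+1)" else "n") +
    geom_hline(yintercept = cumsum(cm$chroms$n_bins) + 0.5, linewidth = 0.2) +
    geom_vline(xintercept = cumsum(cm$chroms$n_bins) + 0.5, linewidth = 0.2) +
    coord_fixed() +
    labs(x = "bin", y = "bin") +
    theme_minimal()
}
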