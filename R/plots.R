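# ggplot2 views of the main result types.

#' Plot window ZHp along the genome
#'
#' One point per retained window at its midpoint, faceted by chromosome,
#' coloured by breed, with the calling threshold drawn as a dashed line.
#'
#' @param object An `hp_scan` from [scan_sweeps()].
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.hp_scan <- function(object, ...) {
  df <- object$windows |>
    filter(!.data$excluded) |>
    mutate(mid = (.data$start + .data$end) / 2)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$mid / 1e6, y = .data$zhp,
                                   colour = .data$breed)) +
    ggplot2::geom_point(size = 0.6, alpha = 0.7) +
    ggplot2::geom_hline(yintercept = object$params$zhp_threshold,
                        linetype = "dashed") +
    ggplot2::facet_wrap(~chrom, scales = "free_x") +
    ggplot2::labs(x = "position (Mb)", y = "ZHp", colour = "breed") +
    ggplot2::theme_minimal()
}

#' Plot a per-SNP Hp track across a region
#'
#' Red marks complete homozygosity (Hp = 0), green complete heterozygosity
#' (Hp = 0.5), one row per breed — the usual view of a candidate sweep
#' locus.
#'
#' @param track Output of [per_snp_hp_track()].
#' @return A ggplot.
#' @export
plot_hp_track <- function(track) {
  ggplot2::ggplot(track, ggplot2::aes(x = .data$pos / 1e6, y = .data$breed,
                                      colour = .data$hp_snp)) +
    ggplot2::geom_point(shape = 15, size = 2) +
    ggplot2::scale_colour_gradient(low = "red", high = "green3",
                                   limits = c(0, 0.5), name = "Hp") +
    ggplot2::labs(x = "position (Mb)", y = NULL) +
    ggplot2::theme_minimal()
}

#' Heatmap of the pairwise genotype-similarity matrix
#'
#' @param sim Matrix from [genotype_similarity()].
#' @param order Optional sample ordering (e.g. tree tip order).
#' @return A ggplot.
#' @export
plot_similarity <- function(sim, order = NULL) {
  if (!is.null(order)) sim <- sim[order, order]
  df <- as_tibble(sim, rownames = "a") |>
    pivot_longer(-"a", names_to = "b", values_to = "similarity") |>
    mutate(a = factor(.data$a, levels = rownames(sim)),
           b = factor(.data$b, levels = rownames(sim)))
  ggplot2::ggplot(df, ggplot2::aes(.data$a, .data$b,
                                   fill = .data$similarity)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_viridis_c(limits = c(0, 1)) +
    ggplot2::labs(x = NULL, y = NULL) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 90,
                                                       vjust = 0.5))
}
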