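# ggplot2 views of the main result types.

#' Plot a position weight profile
#'
#' @param object A [weight_profile()].
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot spp_weight_profile
#' @export
autoplot.spp_weight_profile <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(.data$offset, .data$weight)) +
    ggplot2::geom_line() +
    ggplot2::geom_point(size = 1) +
    ggplot2::labs(x = "offset from probe center (bp)",
                  y = "relative weight",
                  title = "Position weight profile") +
    ggplot2::theme_minimal()
}

#' Plot the permutation test along unigene positions
#'
#' -log10 FDR per 2 bp window, faceted by unigene, with the cutoff line.
#'
#' @param object An `spp_test` from [permutation_pvalues()].
#' @param fdr_cutoff Cutoff drawn as a horizontal line.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot spp_test
#' @export
autoplot.spp_test <- function(object, fdr_cutoff = 0.1, ...) {
  df <- mutate(as_tibble(object),
               neglog = -log10(pmax(.data$fdr, 1e-6)))
  ggplot2::ggplot(df, ggplot2::aes(.data$pos, .data$neglog)) +
    ggplot2::geom_point(size = 0.5) +
    ggplot2::geom_hline(yintercept = -log10(fdr_cutoff), linetype = 2,
                        colour = "red") +
    ggplot2::facet_wrap(~unigene_id, scales = "free_x") +
    ggplot2::labs(x = "position (bp)", y = "-log10 FDR",
                  title = "SPPdev permutation test") +
    ggplot2::theme_minimal()
}

#' Plot the D-statistic along unigene positions
#'
#' @param object An `spp_msa` from [msa_dstat()].
#' @param delta Threshold drawn as horizontal lines.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot spp_msa
#' @export
autoplot.spp_msa <- function(object, delta = 0.2, ...) {
  ggplot2::ggplot(as_tibble(object), ggplot2::aes(.data$pos, .data$d_stat)) +
    ggplot2::geom_point(size = 0.5) +
    ggplot2::geom_hline(yintercept = c(-delta, delta), linetype = 2,
                        colour = "red") +
    ggplot2::facet_wrap(~unigene_id, scales = "free_x") +
    ggplot2::labs(x = "position (bp)", y = "D-statistic",
                  title = "Positional D-statistic") +
    ggplot2::theme_minimal()
}

#' Plot per-array deviations along one unigene
#'
#' SPPdev traces per array, coloured by genotype: the visual form of the
#' evidence both the pair-wise and the panel callers consume.
#'
#' @param windows SPPdev windows from [sppdev_windows()].
#' @param samples Sample sheet (`array_id`, `genotype`).
#' @param unigene Unigene to show (default: the first).
#' @return A ggplot.
#' @export
plot_sppdev <- function(windows, samples, unigene = NULL) {
  unigene <- unigene %||% windows$unigene_id[1]
  df <- windows %>%
    filter(.data$unigene_id == unigene) %>%
    inner_join(samples[, c("array_id", "genotype")], by = "array_id")
  ggplot2::ggplot(df, ggplot2::aes(.data$pos, .data$sppdev,
                                   group = .data$array_id,
                                   colour = .data$genotype)) +
    ggplot2::geom_line(alpha = 0.7) +
    ggplot2::labs(x = "position (bp)", y = "SPPdev", colour = "genotype",
                  title = unigene) +
    ggplot2::theme_minimal()
}
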