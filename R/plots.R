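#' Plot junction support counts
#'
#' @param object A `support_table` from [count_spanning_reads()].
#' @param ... Unused.
#' @return A ggplot: spanning-read counts per junction path, coloured by
#'   native/recombinant status.
#' @export
autoplot.support_table <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(
    x = factor(.data$path, levels = unique(.data$path)),
    y = .data$n_spanning, fill = .data$kind)) +
    ggplot2::geom_col() +
    ggplot2::facet_grid(cols = ggplot2::vars(.data$repeat_id),
                        scales = "free_x", space = "free_x") +
    ggplot2::labs(x = "junction path", y = "spanning reads", fill = NULL) +
    ggplot2::theme_minimal()
}

#' Plot SSR counts by motif unit size
#'
#' @param object An `ssr_table` from [find_ssrs()].
#' @param ... Unused.
#' @return A ggplot of SSR counts per unit size.
#' @export
autoplot.ssr_table <- function(object, ...) {
  dat <- count(as_tibble(object), .data$unit_size, name = "n")
  ggplot2::ggplot(dat, ggplot2::aes(x = factor(.data$unit_size), y = .data$n)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::labs(x = "SSR unit size (bp)", y = "count") +
    ggplot2::theme_minimal()
}

#' Plot dispersed repeats by kind and length
#'
#' @param object A `dispersed_table` from [find_dispersed_repeats()].
#' @param ... Unused.
#' @return A ggplot histogram of repeat lengths, faceted by kind.
#' @export
autoplot.dispersed_table <- function(object, ...) {
  ggplot2::ggplot(as_tibble(object), ggplot2::aes(x = .data$length)) +
    ggplot2::geom_histogram(bins = 30, fill = "darkorange") +
    ggplot2::scale_x_log10() +
    ggplot2::facet_wrap(ggplot2::vars(.data$kind)) +
    ggplot2::labs(x = "repeat length (bp, log scale)", y = "pairs") +
    ggplot2::theme_minimal()
}

#' Plot relative synonymous codon usage by amino acid
#'
#' @param object An `rscu_table` from [compute_rscu()].
#' @param ... Unused.
#' @return A ggplot of stacked RSCU values per amino acid.
#' @export
autoplot.rscu_table <- function(object, ...) {
  dat <- as_tibble(object) |> filter(!is.na(.data$rscu))
  ggplot2::ggplot(dat, ggplot2::aes(x = .data$amino_acid, y = .data$rscu,
                                    group = .data$codon)) +
    ggplot2::geom_col(colour = "grey30", fill = "grey80", linewidth = 0.2) +
    ggplot2::geom_hline(yintercept = 1, linetype = 2, colour = "red") +
    ggplot2::labs(x = "amino acid", y = "RSCU (stacked over codons)") +
    ggplot2::theme_minimal()
}

#' Plot MTPT fragments
#'
#' @param object An `mtpt_table` from [find_homologous_fragments()].
#' @param ... Unused.
#' @return A ggplot of fragment length against alignment identity.
#' @export
autoplot.mtpt_table <- function(object, ...) {
  ggplot2::ggplot(as_tibble(object),
                  ggplot2::aes(x = .data$length, y = .data$identity)) +
    ggplot2::geom_point(colour = "darkgreen") +
    ggplot2::scale_x_log10() +
    ggplot2::labs(x = "fragment length (bp, log scale)", y = "identity (%)") +
    ggplot2::theme_minimal()
}
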