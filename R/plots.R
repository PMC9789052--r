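# ggplot2 views of the pipeline's result types.

#' @exportS3Method ggplot2::autoplot
autoplot.nte_ranking <- function(object, ...) {
  df <- as_tibble(object)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$rank,
                                   y = -log10(.data$p_comb),
                                   colour = .data$codon)) +
    ggplot2::geom_point(alpha = 0.7) +
    ggplot2::labs(x = "rank", y = expression(-log[10](p[comb])),
                  colour = "called codon") +
    ggplot2::theme_minimal()
}

#' Start-codon distribution of ranked calls
#'
#' @param ranked Ranked call tibble from [call_and_rank()].
#' @param top_n Restrict to the top `top_n` ranks (default all).
#' @return A ggplot.
#' @export
plot_start_codon_distribution <- function(ranked, top_n = Inf) {
  df <- as_tibble(ranked) |>
    filter(.data$rank <= top_n) |>
    dplyr::count(.data$codon) |>
    arrange(dplyr::desc(.data$n))
  ggplot2::ggplot(df, ggplot2::aes(x = stats::reorder(.data$codon, -.data$n),
                                   y = .data$n)) +
    ggplot2::geom_col(fill = "grey30") +
    ggplot2::labs(x = "start codon", y = "called extensions") +
    ggplot2::theme_minimal()
}

#' @exportS3Method ggplot2::autoplot
autoplot.rank_sweep <- function(object, ...) {
  df <- tidy(object) |>
    tidyr::pivot_longer(c("observed", "expected"),
                        names_to = "series", values_to = "increment")
  ggplot2::ggplot(df, ggplot2::aes(x = .data$threshold, y = .data$increment,
                                   colour = .data$series)) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::labs(x = "rank threshold", y = "new overlap genes in bin") +
    ggplot2::theme_minimal()
}

#' @exportS3Method ggplot2::autoplot
autoplot.context_matrix <- function(object, ...) {
  ggplot2::ggplot(as_tibble(object),
                  ggplot2::aes(x = .data$position, y = .data$freq,
                               fill = .data$base)) +
    ggplot2::geom_col() +
    ggplot2::labs(x = "position relative to start codon", y = "frequency") +
    ggplot2::theme_minimal()
}

#' @exportS3Method ggplot2::autoplot
autoplot.fold_profile <- function(object, ...) {
  ggplot2::ggplot(as_tibble(object),
                  ggplot2::aes(x = .data$offset, y = .data$energy)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "window offset from start codon (nt)",
                  y = sprintf("window energy (%s)",
                              attr(object, "energy_model_id"))) +
    ggplot2::theme_minimal()
}

#' Per-codon coding-score track
#'
#' @param track One row of a score-track tibble.
#' @return A ggplot of the per-codon scores over the window.
#' @export
plot_score_track <- function(track) {
  df <- tibble(codon_index = seq_along(track$per_codon[[1L]]),
               score = track$per_codon[[1L]])
  ggplot2::ggplot(df, ggplot2::aes(x = .data$codon_index, y = .data$score)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::geom_hline(yintercept = 0, linewidth = 0.3) +
    ggplot2::labs(x = "codon (5' to 3', window)", y = "coding score",
                  title = track$transcript_id) +
    ggplot2::theme_minimal()
}
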