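#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot a primer tiling
#'
#' Draws the amplicons as horizontal segments along the linearized circular
#' template, alternating between two lanes so the junction overlaps are
#' visible; primer binding sites are overlaid as ticks. An amplicon wrapping
#' the origin is drawn in two parts.
#'
#' @param object A `primer_tiling`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.primer_tiling <- function(object, ...) {
  L <- object$template_len
  p <- object$pairs
  segs <- purrr::map_dfr(seq_len(nrow(p)), function(i) {
    s <- p$fwd_start[i]; e <- s + p$product_len[i] - 1L
    lane <- (p$set[i] - 1L) %% 2L
    if (e <= L) {
      tibble::tibble(set = p$set[i], x = s, xend = e, lane = lane)
    } else {
      tibble::tibble(set = p$set[i], x = c(s, 1L), xend = c(L, e - L),
                     lane = lane)
    }
  })
  prim <- purrr::map_dfr(seq_len(nrow(p)), function(i) {
    tibble::tibble(
      set = p$set[i], lane = (p$set[i] - 1L) %% 2L,
      x = c(p$fwd_start[i], p$rev_start[i]),
      xend = c(p$fwd_start[i] + p$fwd_len[i] - 1L,
               p$rev_start[i] + p$rev_len[i] - 1L),
      primer = c("forward", "reverse"))
  })
  ggplot2::ggplot(segs) +
    ggplot2::geom_segment(ggplot2::aes(x = .data$x, xend = .data$xend,
                                       y = .data$lane, yend = .data$lane),
                          linewidth = 2, colour = "grey70") +
    ggplot2::geom_segment(
      data = prim,
      ggplot2::aes(x = .data$x, xend = .data$xend,
                   y = .data$lane, yend = .data$lane, colour = .data$primer),
      linewidth = 4) +
    ggplot2::scale_y_continuous(breaks = NULL, limits = c(-0.5, 1.5)) +
    ggplot2::labs(x = sprintf("position on %s (nt)", object$template_id),
                  y = NULL, colour = NULL,
                  title = sprintf("%d overlapping amplicons, %.1f%% coverage",
                                  nrow(p), 100 * tiling_coverage(object))) +
    ggplot2::theme_minimal()
}

#' Plot the optimization trace of a swarm
#'
#' @param result A `swarm_result` from [optimize_window()].
#' @return A ggplot object showing the nonincreasing global-best fitness.
#' @export
plot_fitness_history <- function(result) {
  ggplot2::ggplot(tidy.swarm_result(result),
                  ggplot2::aes(x = .data$iteration, y = .data$best_fitness)) +
    ggplot2::geom_step() +
    ggplot2::labs(x = "iteration", y = "global-best fitness") +
    ggplot2::theme_minimal()
}
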