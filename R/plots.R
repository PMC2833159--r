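# ggplot2 displays for the optimizer's diagnostics.

#' Plot a coverage curve
#'
#' Verified and predicted coverage against the threshold value, with the
#' verified-minus-predicted gap as bars (the quantity that drives candidate
#' range selection).
#'
#' @param object a [coverage_curve()] tibble.
#' @param ... unused.
#' @return A ggplot object.
#' @export
autoplot.coverage_curve <- function(object, ...) {
  long <- tidyr::pivot_longer(
    as_tibble(object), c("cov_verified", "cov_predicted"),
    names_to = "set", values_to = "coverage")
  long$set <- c(cov_verified = "verified", cov_predicted = "predicted")[long$set]
  ggplot2::ggplot(long, ggplot2::aes(x = .data$value)) +
    ggplot2::geom_col(
      data = as_tibble(object),
      mapping = ggplot2::aes(x = .data$value, y = .data$gap),
      fill = "gold", alpha = 0.6, inherit.aes = FALSE) +
    ggplot2::geom_line(ggplot2::aes(y = .data$coverage,
                                    colour = .data$set)) +
    ggplot2::geom_point(ggplot2::aes(y = .data$coverage,
                                     colour = .data$set), size = 1) +
    ggplot2::scale_colour_manual(
      values = c(verified = "darkorange", predicted = "steelblue")) +
    ggplot2::labs(x = paste0(object$feature[1], " threshold"),
                  y = "coverage (fraction kept)",
                  colour = NULL,
                  title = paste0("Coverage curve: ", object$feature[1])) +
    ggplot2::theme_minimal()
}

#' Plot a threshold grid search
#'
#' Every parameter combination as a point in the (enrichment, coverage)
#' plane, the EC-optimal combination highlighted.
#'
#' @param object a [grid_search()] result.
#' @param ... unused.
#' @return A ggplot object.
#' @export
autoplot.grid_search <- function(object, ...) {
  g <- object$grid
  ggplot2::ggplot(g, ggplot2::aes(x = .data$enrichment,
                                  y = .data$coverage_pct)) +
    ggplot2::geom_point(alpha = 0.5, size = 1.2) +
    ggplot2::geom_point(data = object$best, colour = "red", size = 2.5) +
    ggplot2::labs(x = "Enrichment (fold)",
                  y = "coverage of verified pairs (%)",
                  title = "Binding-parameter grid search",
                  subtitle = sprintf(
                    "best EC = %.1f at (%d, %d, %d, %d)",
                    object$best$ec, object$best$mm_mrna, object$best$mm_mirna,
                    object$best$gu_whole, object$best$gu_seed)) +
    ggplot2::theme_minimal()
}

#' Plot target-site positions along the 3'-UTR
#'
#' Site position relative to the stop codon, scaled by UTR length, per
#' family: a visual check of where predicted sites fall within UTRs.
#'
#' @param hits a duplex-hit tibble.
#' @return A ggplot object.
#' @export
plot_site_positions <- function(hits) {
  d <- mutate(hits, rel_pos = .data$dist_from_stop /
                pmax(1L, .data$utr_length - (.data$site_end - .data$site_start)))
  ggplot2::ggplot(d, ggplot2::aes(x = .data$rel_pos)) +
    ggplot2::geom_histogram(bins = 20, fill = "steelblue", colour = "white") +
    ggplot2::facet_wrap(ggplot2::vars(.data$family)) +
    ggplot2::labs(x = "site position (0 = stop codon, 1 = 3' end)",
                  y = "sites",
                  title = "Predicted target-site positions in 3'-UTRs") +
    ggplot2::theme_minimal()
}
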