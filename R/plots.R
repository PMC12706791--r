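#' Plot per-carbon deviations
#'
#' Lollipop plot of signed calculated-minus-experimental deviations by
#' carbon label, with guide lines at +/- sigma of the DP4 error model.
#'
#' @param dev A deviation tibble from [shift_deviations()].
#' @param sigma Reference scale drawn as dashed guides (default 2.306 ppm).
#' @return A ggplot object.
#' @export
plot_deviations <- function(dev, sigma = 2.306) {
  ggplot2::ggplot(dev, ggplot2::aes(x = stats::reorder(.data$label,
                                                       .data$delta),
                                    y = .data$delta)) +
    ggplot2::geom_hline(yintercept = 0, colour = "grey60") +
    ggplot2::geom_hline(yintercept = c(-sigma, sigma), linetype = "dashed",
                        colour = "grey70") +
    ggplot2::geom_segment(ggplot2::aes(xend = .data$label, yend = 0)) +
    ggplot2::geom_point(size = 2) +
    ggplot2::coord_flip() +
    ggplot2::labs(x = NULL, y = expression(Delta * delta ~ "(ppm, calc - exp)")) +
    ggplot2::theme_minimal()
}

#' @method autoplot candidate_ranking
#' @export
autoplot.candidate_ranking <- function(object, ...) {
  d <- tidy(object)
  d$candidate_id <- stats::reorder(d$candidate_id, -d$rank)
  long <- tidyr::pivot_longer(
    d[, c("candidate_id", "dp4", "rmsd")],
    cols = c("dp4", "rmsd"), names_to = "metric", values_to = "value"
  )
  ggplot2::ggplot(long, ggplot2::aes(x = .data$candidate_id,
                                     y = .data$value)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::coord_flip() +
    ggplot2::facet_wrap(~metric, scales = "free_x") +
    ggplot2::labs(x = NULL, y = NULL,
                  title = "Candidate ranking: DP4 probability and RMSD (ppm)") +
    ggplot2::theme_minimal()
}

#' @method autoplot subtype_diagnosis
#' @export
autoplot.subtype_diagnosis <- function(object, ...) {
  d <- tidy(object)
  d$subtype <- stats::reorder(d$subtype, d$frac_matched)
  ggplot2::ggplot(d, ggplot2::aes(x = .data$subtype,
                                  y = .data$frac_matched)) +
    ggplot2::geom_col(fill = "darkorange") +
    ggplot2::geom_hline(yintercept = attr(object, "floor"),
                        linetype = "dashed") +
    ggplot2::coord_flip() +
    ggplot2::labs(x = NULL, y = "fraction of markers matched",
                  title = "Subtype diagnosis") +
    ggplot2::theme_minimal()
}

#' @method autoplot revision_report
#' @export
autoplot.revision_report <- function(object, ...) {
  if (!is.null(object$scores)) {
    autoplot(object$scores) +
      ggplot2::labs(subtitle = paste0(object$entry_id, ": ", object$verdict))
  } else {
    autoplot(object$diagnosis) +
      ggplot2::labs(subtitle = paste0(object$entry_id, ": ", object$verdict))
  }
}
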