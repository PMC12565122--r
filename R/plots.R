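# ggplot2 views of the two result types.

#' Volcano-style plot of a per-gene association scan
#'
#' Correlation coefficient against -log10 raw p, colored by fast/slow/ns
#' class.
#'
#' @param assoc An `rer_assoc` tibble.
#' @param alpha Reference significance level drawn as a guide line on raw
#'   p (default: the scan's alpha).
#' @return A ggplot.
#' @export
plot_association <- function(assoc, alpha = NULL) {
  alpha <- alpha %||% attr(assoc, "alpha") %||% 0.05
  ggplot2::ggplot(
    as_tibble(assoc),
    ggplot2::aes(
      x = .data$rho, y = -log10(.data$p),
      colour = .data$class
    )
  ) +
    ggplot2::geom_point(alpha = 0.6, size = 1) +
    ggplot2::geom_hline(yintercept = -log10(alpha), linetype = "dashed") +
    ggplot2::scale_colour_manual(
      values = c(fast = "#d1495b", slow = "#00798c", ns = "grey60")
    ) +
    ggplot2::labs(
      x = "RER-trait correlation (rho)", y = expression(-log[10] ~ p),
      colour = NULL,
      title = attr(assoc, "trait_name") %||% NULL
    ) +
    ggplot2::theme_minimal()
}

#' @method autoplot rer_assoc
#' @export
autoplot.rer_assoc <- function(object, ...) plot_association(object, ...)

#' Plot gene-set enrichment results
#'
#' Mean member correlation per set, significant sets highlighted —
#' acceleration to the right, deceleration to the left.
#'
#' @param enrich An `rer_enrich` tibble.
#' @param top Show at most this many sets, ordered by q (default 30).
#' @return A ggplot.
#' @export
plot_enrichment <- function(enrich, top = 30) {
  d <- head(arrange(as_tibble(enrich), .data$q), top)
  d$set_name <- factor(d$set_name, levels = rev(d$set_name))
  ggplot2::ggplot(
    d,
    ggplot2::aes(
      x = .data$mean_rho, y = .data$set_name,
      colour = .data$direction, shape = .data$significant
    )
  ) +
    ggplot2::geom_vline(xintercept = 0, colour = "grey70") +
    ggplot2::geom_point(size = 2.5) +
    ggplot2::scale_colour_manual(
      values = c(accelerated = "#d1495b", decelerated = "#00798c")
    ) +
    ggplot2::scale_shape_manual(values = c(`TRUE` = 16, `FALSE` = 1)) +
    ggplot2::labs(
      x = "mean member rho", y = NULL,
      colour = NULL, shape = "q < alpha"
    ) +
    ggplot2::theme_minimal()
}

#' @method autoplot rer_enrich
#' @export
autoplot.rer_enrich <- function(object, ...) plot_enrichment(object, ...)
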