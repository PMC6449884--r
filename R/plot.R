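#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot a cumulative rank distribution
#'
#' @param object A `cumulative_rank` tibble from [cumulative_rank()].
#' @param ... Unused.
#' @return A ggplot: fraction of patients with true rank <= k.
#' @method autoplot cumulative_rank
#' @export
autoplot.cumulative_rank <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$k, y = .data$fraction)) +
    ggplot2::geom_step(direction = "hv") +
    ggplot2::geom_point() +
    ggplot2::scale_y_continuous(limits = c(0, 1)) +
    ggplot2::labs(x = "rank threshold k",
                  y = "cumulative probability of true-target rank") +
    ggplot2::theme_minimal()
}

#' Plot gene vs disease information content
#'
#' @param object An `ic_table` from [compute_ic()].
#' @param ... Unused.
#' @return A ggplot comparing the two IC sources per term.
#' @method autoplot ic_table
#' @export
autoplot.ic_table <- function(object, ...) {
  ggplot2::ggplot(object,
                  ggplot2::aes(x = .data$ic_gene, y = .data$ic_disease)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = 2,
                         colour = "grey60") +
    ggplot2::geom_point(alpha = 0.6) +
    ggplot2::labs(x = "IC from gene annotations (nats)",
                  y = "IC from disease annotations (nats)") +
    ggplot2::theme_minimal()
}

#' Plot a blending-weight sweep
#'
#' @param object A `w_sweep` from [sweep_w()].
#' @param ... Unused.
#' @return A ggplot of the cumulative rank fraction per `w` and threshold.
#' @method autoplot w_sweep
#' @export
autoplot.w_sweep <- function(object, ...) {
  ggplot2::ggplot(object$curves,
                  ggplot2::aes(x = .data$w, y = .data$fraction,
                               colour = factor(.data$k))) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::scale_y_continuous(limits = c(0, 1)) +
    ggplot2::labs(x = "gene/disease blending weight w",
                  y = "cumulative probability of true-target rank",
                  colour = "top-k") +
    ggplot2::theme_minimal()
}

#' @keywords internal
#' @importFrom rlang .data
"_PACKAGE"
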