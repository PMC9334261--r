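#' Plot a worm-like-chain force-extension curve
#'
#' @param object A `wlc_profile` from [wlc_profile()].
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot wlc_profile
#' @export
autoplot.wlc_profile <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$extension_nm, y = .data$force_pN)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "extension (nm)", y = "force (pN)",
                  title = "Worm-like-chain force-extension") +
    ggplot2::theme_minimal()
}

#' Plot equilibrium force against protein stiffness
#'
#' @param object A `force_profile_k` from [force_vs_kprotein()].
#' @param ... Unused.
#' @return A ggplot with a log-scaled stiffness axis.
#' @method autoplot force_profile_k
#' @export
autoplot.force_profile_k <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$k_protein, y = .data$force_pN)) +
    ggplot2::geom_line() +
    ggplot2::geom_point(size = 1) +
    ggplot2::scale_x_log10() +
    ggplot2::labs(x = expression(k[protein] ~ "(pN/nm)"),
                  y = "force on protein spring (pN)") +
    ggplot2::theme_minimal()
}

#' Plot an ensemble or sample distance distribution
#'
#' @param object An `ensemble_summary`.
#' @param ... Unused.
#' @return A ggplot of the density histogram with the mean marked.
#' @method autoplot ensemble_summary
#' @export
autoplot.ensemble_summary <- function(object, ...) {
  ggplot2::ggplot(object$histogram) +
    ggplot2::geom_rect(ggplot2::aes(xmin = .data$bin_lo, xmax = .data$bin_hi,
                                    ymin = 0, ymax = .data$density),
                       fill = "grey70", colour = "grey30") +
    ggplot2::geom_vline(xintercept = object$mean, linetype = 2) +
    ggplot2::labs(x = "distance (nm)", y = "density",
                  title = sprintf("%s distribution (mean %.1f nm)",
                                  object$source, object$mean)) +
    ggplot2::theme_minimal()
}

#' Plot an idealized current trace
#'
#' @param object A `trace_segmentation` from [segment_trace()].
#' @param ... Unused.
#' @return A ggplot of the trace coloured by assigned state, with state mean
#'   levels overlaid.
#' @method autoplot trace_segmentation
#' @export
autoplot.trace_segmentation <- function(object, ...) {
  ggplot2::ggplot(object$data,
                  ggplot2::aes(x = .data$time_s, y = .data$current_pA,
                               colour = .data$state)) +
    ggplot2::geom_line(linewidth = 0.2) +
    ggplot2::geom_hline(yintercept = object$states$mean_pA, linetype = 2) +
    ggplot2::scale_colour_manual(values = c(closed = "#3366aa", open = "#cc3333")) +
    ggplot2::labs(x = "time (s)", y = "current (pA)", colour = "state") +
    ggplot2::theme_minimal()
}
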