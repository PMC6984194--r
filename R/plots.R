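# ggplot2 visualizations for the main result objects.

#' Plot a time-frequency map
#'
#' Percent power change relative to baseline, trial-averaged; the MI onset
#' and the 0.5-1.5 s analysis interval are marked.
#'
#' @param object A `tf_map`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot tf_map
#' @export
autoplot.tf_map <- function(object, ...) {
  df <- tidyr::expand_grid(freq = object$freqs, time = object$times)
  df$change <- as.vector(t(object$values))
  ggplot(df, aes(x = .data$time, y = .data$freq, fill = .data$change)) +
    geom_raster() +
    scale_fill_gradient2(low = "blue", mid = "white", high = "red",
                         name = "% power\nchange") +
    geom_vline(xintercept = c(0, 0.5, 1.5), linetype = c(1, 2, 2)) +
    labs(x = "Time relative to MI onset (s)", y = "Frequency (Hz)") +
    theme_minimal()
}

#' Plot a controller trace
#'
#' Hand-state sequence over time with movement events marked.
#'
#' @param object A `controller_trace`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot controller_trace
#' @export
autoplot.controller_trace <- function(object, ...) {
  st <- object$states
  st$state <- factor(st$state, levels = hand_states())
  p <- ggplot(st, aes(x = .data$time, y = .data$state, group = 1)) +
    geom_step() +
    labs(x = "Time (s)", y = NULL) +
    theme_minimal()
  if (nrow(object$movements) > 0) {
    mv <- object$movements
    mv$state <- factor(ifelse(mv$label == "movement_flexion",
                              "CURRENTLY_FLEXING", "CURRENTLY_EXTENDING"),
                       levels = hand_states())
    p <- p + geom_point(data = mv, aes(shape = .data$label), size = 2)
  }
  p
}

#' Plot a trial ledger
#'
#' Reconstructed 5 s trials colored by outcome.
#'
#' @param object A `trial_ledger`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot trial_ledger
#' @export
autoplot.trial_ledger <- function(object, ...) {
  tr <- object$trials
  ggplot(tr, aes(xmin = .data$start, xmax = .data$end,
                 ymin = 0, ymax = 1, fill = .data$outcome)) +
    geom_rect(color = "white") +
    scale_fill_manual(values = c(TP = "#1b9e77", TN = "#66c2a5",
                                 FN = "#d95f02", FP = "#e7298a")) +
    labs(x = "Time (s)", y = NULL) +
    theme_minimal() +
    theme(axis.text.y = element_blank())
}

#' Plot per-component CSP eigenvalues
#'
#' @param object A `csp_model`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot csp_model
#' @export
autoplot.csp_model <- function(object, ...) {
  df <- tidy.csp_model(object)
  ggplot(df, aes(x = .data$component, y = .data$eigenvalue,
                 color = .data$selected)) +
    geom_point() +
    geom_hline(yintercept = 0.5, linetype = 2) +
    labs(x = "CSP component", y = "Class variance ratio") +
    theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
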