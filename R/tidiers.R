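# broom-style tidiers for the package's fitted objects.

#' Tidy a CSP model
#'
#' @param x A [fit_csp()] model.
#' @param ... Unused.
#' @return One row per component: `component`, `eigenvalue`, `selected`.
#' @method tidy csp_model
#' @export
tidy.csp_model <- function(x, ...) {
  tibble(component = seq_along(x$eigenvalues),
         eigenvalue = x$eigenvalues,
         selected = seq_along(x$eigenvalues) %in% x$selected)
}

#' @rdname tidy.csp_model
#' @method glance csp_model
#' @export
glance.csp_model <- function(x, ...) {
  tibble(n_channels = nrow(x$filters), n_selected = length(x$selected),
         class_a = x$class_pair[1], class_b = x$class_pair[2],
         top_eigenvalue = max(x$eigenvalues))
}

#' Tidy a bootstrap result
#'
#' @param x A `bootstrap_result`.
#' @param ... Unused.
#' @return A one-row tibble with the observed statistic, p-value, null CI
#'   bounds and replicate count.
#' @method tidy bootstrap_result
#' @export
tidy.bootstrap_result <- function(x, ...) {
  tibble(statistic = x$statistic, estimate = x$observed, p.value = x$p,
         conf.low = if (is.null(x$ci)) NA_real_ else x$ci[1],
         conf.high = if (is.null(x$ci)) NA_real_ else x$ci[2],
         B = x$B)
}

#' @rdname tidy.bootstrap_result
#' @method glance bootstrap_result
#' @export
glance.bootstrap_result <- function(x, ...) tidy.bootstrap_result(x)

#' Tidy a trial ledger
#'
#' @param x A [reconstruct_trials()] ledger.
#' @param ... Unused.
#' @return The trial tibble (`start`, `end`, `intended`, `outcome`).
#' @method tidy trial_ledger
#' @export
tidy.trial_ledger <- function(x, ...) x$trials

#' @rdname tidy.trial_ledger
#' @method glance trial_ledger
#' @export
glance.trial_ledger <- function(x, ...) {
  tibble(TP = x$counts[["TP"]], FN = x$counts[["FN"]],
         TN = x$counts[["TN"]], FP = x$counts[["FP"]],
         accuracy = feedback_accuracy(x))
}

#' Tidy a controller trace
#'
#' @param x A `controller_trace`.
#' @param ... Unused.
#' @return The per-tick state tibble.
#' @method tidy controller_trace
#' @export
tidy.controller_trace <- function(x, ...) x$states

#' @rdname tidy.controller_trace
#' @method glance controller_trace
#' @export
glance.controller_trace <- function(x, ...) {
  tibble(n_ticks = nrow(x$states),
         n_flexions = sum(x$movements$label == "movement_flexion"),
         n_extensions = sum(x$movements$label == "movement_extension"),
         duration = if (nrow(x$states)) diff(range(x$states$time)) else 0)
}

#' Tidy a CSP quality report
#'
#' @param x A [csp_quality_score()] report.
#' @param ... Unused.
#' @return Long tibble `criterion`, `filter`, `fulfilled`.
#' @method tidy csp_quality_report
#' @export
tidy.csp_quality_report <- function(x, ...) {
  tidyr::pivot_longer(x$criteria, cols = c("flexion", "extension"),
                      names_to = "filter", values_to = "fulfilled")
}

#' @rdname tidy.csp_quality_report
#' @method glance csp_quality_report
#' @export
glance.csp_quality_report <- function(x, ...) {
  tibble(total = x$total, max_score = 12L, plausible = x$plausible)
}
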