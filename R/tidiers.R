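#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Tidy an RWA result into per-stage rows
#' @param x An `rwa_result` from [score_recording()].
#' @param ... Unused.
#' @return The per-stage metric tibble (`stage`, `pct_miniepochs`,
#'   `duration_s`, `pct_duration`, `present`).
#' @export
tidy.rwa_result <- function(x, ...) x$per_stage

#' One-row summary of an RWA result
#' @param x An `rwa_result`.
#' @param ... Unused.
#' @return Tibble with `auto_rwa`, `n_rem_minis`, `n_events`, `rem_s`,
#'   `rem_pct`.
#' @export
glance.rwa_result <- function(x, ...) {
  tibble::tibble(
    auto_rwa = x$auto_rwa,
    n_rem_minis = x$n_rem_minis,
    n_events = nrow(x$events),
    rem_s = x$rem_s,
    rem_pct = x$rem_pct
  )
}

#' Tidy a ROC result into its operating points
#' @param x An `rwa_roc` from [roc()].
#' @param ... Unused.
#' @return Tibble of `threshold`, `sensitivity`, `specificity`.
#' @export
tidy.rwa_roc <- function(x, ...) x$curve

#' One-row summary of a ROC result
#' @param x An `rwa_roc`.
#' @param ... Unused.
#' @return Tibble with `auc`, `se`, `ci_low`, `ci_high`, `cut_point`,
#'   `sensitivity`, `specificity`, `n_pos`, `n_neg`.
#' @export
glance.rwa_roc <- function(x, ...) {
  tibble::tibble(
    auc = x$auc, se = x$se, ci_low = x$ci95[1], ci_high = x$ci95[2],
    cut_point = x$cut_point, sensitivity = x$sensitivity,
    specificity = x$specificity, n_pos = x$n_pos, n_neg = x$n_neg
  )
}

#' Plot a ROC curve
#' @param object An `rwa_roc`.
#' @param ... Unused.
#' @return A ggplot: sensitivity against 1 - specificity with the chance
#'   diagonal and the AUC in the subtitle.
#' @export
autoplot.rwa_roc <- function(object, ...) {
  d <- object$curve[order(1 - object$curve$specificity,
                          object$curve$sensitivity), ]
  ggplot2::ggplot(d, ggplot2::aes(x = 1 - .data$specificity,
                                  y = .data$sensitivity)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = 2,
                         colour = "grey60") +
    ggplot2::geom_step() +
    ggplot2::coord_equal() +
    ggplot2::labs(
      x = "1 - specificity", y = "Sensitivity",
      subtitle = sprintf("AUC = %.3f (95%% CI %.3f-%.3f)",
                         object$auc, object$ci95[1], object$ci95[2])
    )
}

#' Plot detected events over the mini-epoch grid of a result
#' @param object An `rwa_result`.
#' @param ... Unused.
#' @return A ggplot: mini-epoch occupancy over time, coloured by stage, with
#'   the positivity threshold marked.
#' @export
autoplot.rwa_result <- function(object, ...) {
  d <- object$minis
  thr <- object$config$occupancy_threshold
  ggplot2::ggplot(d, ggplot2::aes(x = .data$start / 3600, y = .data$occupancy,
                                  colour = .data$stage)) +
    ggplot2::geom_point(size = 0.4, alpha = 0.6) +
    ggplot2::geom_hline(yintercept = thr, linetype = 2) +
    ggplot2::labs(
      x = "Time (h)", y = "Mini-epoch occupancy",
      subtitle = sprintf("Automatic RWA = %.3f", object$auto_rwa)
    )
}

#' Plot the RWA parameter distributions of a cohort
#'
#' @param data Cohort tibble with `rbd` and the RWA parameter columns.
#' @param params Parameters to show.
#' @return A ggplot of boxplots by RBD status, faceted by parameter.
#' @export
plot_cohort_rwa <- function(data, params = c("any_pct", "tonic_pct",
                                             "phasic_pct", "auto_rwa")) {
  params <- intersect(params, names(data))
  long <- tidyr::pivot_longer(
    data[, c("rbd", params)], dplyr::all_of(params),
    names_to = "parameter", values_to = "value"
  )
  ggplot2::ggplot(long, ggplot2::aes(
    x = ifelse(.data$rbd, "RBD", "non-RBD"), y = .data$value
  )) +
    ggplot2::geom_boxplot(outlier.size = 0.5) +
    ggplot2::facet_wrap(~parameter, scales = "free_y") +
    ggplot2::labs(x = NULL, y = NULL)
}
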