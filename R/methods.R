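# broom-style accessors and ggplot2 autoplot methods

#' @export
tidy.combo_search <- function(x, ...) {
  tibble::as_tibble(x)
}

#' @export
glance.combo_search <- function(x, ...) {
  b <- best_combo(x)
  tibble::tibble(n_combos = nrow(x), n_discarded = sum(x$discarded),
                 n_repeats = attr(x, "n_repeats"),
                 best_combo = b$combo_id,
                 best_mean_kappa = x$mean_kappa[match(b$combo_id,
                                                      x$combo_id)],
                 n_errors = length(attr(x, "errors")))
}

#' @export
tidy.frozen_model <- function(x, ...) {
  x$predictions
}

#' @export
glance.frozen_model <- function(x, ...) {
  dplyr::mutate(tibble::as_tibble(x$metrics),
                combo_id = x$combo$combo_id,
                n_selected = length(x$selected), .before = 1)
}

#' @export
tidy.explain_report <- function(x, ...) {
  x$importance
}

#' @export
tidy.shap_values <- function(x, ...) {
  phi <- tibble::as_tibble(x$phi)
  phi$patient <- seq_len(nrow(phi))
  tidyr::pivot_longer(phi, -"patient", names_to = "feature",
                      values_to = "shap")
}

#' @export
autoplot.dsc_curve <- function(object, tp = NULL, ...) {
  p <- ggplot2::ggplot(object,
                       ggplot2::aes(x = .data$time_s, y = .data$signal)) +
    ggplot2::geom_line(color = "grey30") +
    ggplot2::geom_point(size = 0.8) +
    ggplot2::labs(x = "time (s)", y = "mean VOI signal (a.u.)")
  be <- attr(object, "baseline_end")
  if (!is.null(be))
    p <- p + ggplot2::geom_hline(yintercept = attr(object, "baseline_mean"),
                                 linetype = 2, color = "steelblue")
  if (!is.null(tp)) {
    pts <- tibble::tibble(
      idx = c(tp$t0_idx, tp$tmax_idx, tp$t2_idx),
      label = c("T0", "Tmax", "T2"))
    pts$time_s <- object$time_s[pts$idx]
    pts$signal <- object$signal[pts$idx]
    p <- p + ggplot2::geom_point(data = pts, color = "firebrick",
                                 size = 2) +
      ggplot2::geom_text(data = pts,
                         ggplot2::aes(label = .data$label),
                         vjust = -1, color = "firebrick")
  }
  p
}

#' @export
autoplot.combo_search <- function(object, top = 20, ...) {
  d <- utils::head(tibble::as_tibble(object), top)
  d$combo_id <- factor(d$combo_id, levels = rev(d$combo_id))
  ggplot2::ggplot(d, ggplot2::aes(x = .data$mean_kappa,
                                  y = .data$combo_id)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::geom_errorbarh(
      ggplot2::aes(xmin = .data$mean_kappa - .data$sd_kappa,
                   xmax = .data$mean_kappa + .data$sd_kappa),
      height = 0.3) +
    ggplot2::labs(x = "mean Cohen's kappa (validation folds)", y = NULL)
}

#' @export
autoplot.explain_report <- function(object, top = 20, ...) {
  d <- utils::head(object$importance, top)
  d$feature <- factor(d$feature, levels = rev(d$feature))
  ggplot2::ggplot(d, ggplot2::aes(x = .data$mean_importance,
                                  y = .data$feature)) +
    ggplot2::geom_col(fill = "darkorange") +
    ggplot2::geom_errorbarh(
      ggplot2::aes(xmin = .data$mean_importance - .data$sd_importance,
                   xmax = .data$mean_importance + .data$sd_importance),
      height = 0.3) +
    ggplot2::labs(x = "permutation importance (kappa drop)", y = NULL)
}

#' @export
autoplot.shap_values <- function(object, ...) {
  d <- tidy.shap_values(object)
  ord <- names(sort(tapply(abs(d$shap), d$feature, mean),
                    decreasing = FALSE))
  d$feature <- factor(d$feature, levels = ord)
  ggplot2::ggplot(d, ggplot2::aes(x = .data$shap, y = .data$feature)) +
    ggplot2::geom_jitter(height = 0.15, alpha = 0.5, size = 0.8) +
    ggplot2::geom_vline(xintercept = 0, linetype = 2) +
    ggplot2::labs(x = "SHAP value (margin scale)", y = NULL)
}
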