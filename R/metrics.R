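#' Confusion matrix with IDH-wildtype as the positive class
#'
#' @param truth,prediction Vectors of class labels (character or factor).
#' @param positive Positive class label (default `"wildtype"`).
#' @return List of class `confusion_matrix`: `tp`, `fn`, `fp`, `tn`,
#'   `positive`.
#' @export
confusion_matrix <- function(truth, prediction, positive = "wildtype") {
  truth <- as.character(truth)
  prediction <- as.character(prediction)
  stopifnot(length(truth) == length(prediction), length(truth) > 0)
  structure(list(
    tp = sum(truth == positive & prediction == positive),
    fn = sum(truth == positive & prediction != positive),
    fp = sum(truth != positive & prediction == positive),
    tn = sum(truth != positive & prediction != positive),
    positive = positive
  ), class = "confusion_matrix")
}

as_confusion_matrix <- function(tp, fn, fp, tn, positive = "wildtype") {
  stopifnot(tp >= 0, fn >= 0, fp >= 0, tn >= 0, tp + fn + fp + tn > 0)
  structure(list(tp = tp, fn = fn, fp = fp, tn = tn, positive = positive),
            class = "confusion_matrix")
}

# trapezoidal AUC of positive-class scores
auc_trapezoid <- function(scores, truth, positive = "wildtype") {
  pos <- as.character(truth) == positive
  if (!any(pos) || all(pos)) return(NA_real_)
  thr <- sort(unique(scores), decreasing = TRUE)
  tpr <- vapply(thr, function(t) mean(scores[pos] >= t), numeric(1))
  fpr <- vapply(thr, function(t) mean(scores[!pos] >= t), numeric(1))
  tpr <- c(0, tpr, 1)
  fpr <- c(0, fpr, 1)
  sum(diff(fpr) * (utils::head(tpr, -1) + utils::tail(tpr, -1)) / 2)
}

#' Full performance metric report from a confusion matrix
#'
#' Cohen's kappa uses the marginals-based expected agreement
#' `p_e = (n_pos * n_pred_pos + n_neg * n_pred_neg) / n^2`. Any metric
#' whose denominator is zero is reported as 0 and flagged.
#'
#' @param cm A [confusion_matrix()] (or a list with tp/fn/fp/tn).
#' @param scores Optional per-sample positive-class scores (for AUC).
#' @param truth Class labels matching `scores`.
#' @return Tibble of class `metrics_report` with one row: kappa, f1, auc,
#'   accuracy, sensitivity, specificity, ppv, npv; attribute
#'   `zero_division` names any zero-denominator metric.
#' @export
compute_metrics <- function(cm, scores = NULL, truth = NULL) {
  tp <- cm$tp; fn <- cm$fn; fp <- cm$fp; tn <- cm$tn
  n <- tp + fn + fp + tn
  if (n == 0) stop("empty confusion matrix")
  flagged <- character(0)
  safe <- function(num, den, nm) {
    if (den == 0) {
      flagged <<- c(flagged, nm)
      return(0)
    }
    num / den
  }
  sens <- safe(tp, tp + fn, "sensitivity")
  spec <- safe(tn, tn + fp, "specificity")
  ppv <- safe(tp, tp + fp, "ppv")
  npv <- safe(tn, tn + fn, "npv")
  acc <- (tp + tn) / n
  f1 <- safe(2 * ppv * sens, ppv + sens, "f1")
  po <- acc
  pe <- ((tp + fn) * (tp + fp) + (tn + fp) * (tn + fn)) / n^2
  kappa <- if (pe == 1) {
    flagged <- c(flagged, "kappa")
    0
  } else (po - pe) / (1 - pe)
  auc <- if (!is.null(scores)) auc_trapezoid(scores, truth,
                                             cm$positive %||% "wildtype")
         else NA_real_
  out <- tibble::tibble(kappa = kappa, f1 = f1, auc = auc, accuracy = acc,
                        sensitivity = sens, specificity = spec,
                        ppv = ppv, npv = npv)
  structure(out, class = c("metrics_report", class(out)),
            zero_division = flagged)
}

#' Signed percent change between two metric values
#'
#' `100 * (after - before) / before`; with `as_decrease = TRUE` the
#' magnitude of a decrease, `100 * (before - after) / before`.
#'
#' @param before,after Metric values; `before` must be non-zero.
#' @param as_decrease Report a decrease as a positive magnitude.
#' @return Percent change (scalar).
#' @export
percent_change <- function(before, after, as_decrease = FALSE) {
  if (before == 0) stop("percent change undefined for a zero baseline")
  if (as_decrease) 100 * (before - after) / before
  else 100 * (after - before) / before
}

#' Permutation feature importance on a validation set
#'
#' For every feature column in turn, shuffles that column only
#' (`n_shuffles` independent permutations) and records the drop of the
#' chosen metric relative to the unshuffled baseline; reported as
#' mean +/- SD, ranked in decreasing importance.
#'
#' @param model A frozen model from [external_validate()] (anything with a
#'   `predict_fn(X)` returning list(class, score)).
#' @param X Validation feature matrix/tibble (original feature space).
#' @param y Validation labels.
#' @param metric `"kappa"` (default) or any column of
#'   [compute_metrics()].
#' @param n_shuffles Number of independent shuffles per feature.
#' @param seed Integer seed.
#' @param features Columns to assess (default: the model's selected
#'   features).
#' @return Tibble: feature, mean_importance, sd_importance, rank.
#' @export
permutation_importance <- function(model, X, y, metric = "kappa",
                                   n_shuffles = 50, seed = 1L,
                                   features = NULL) {
  stopifnot(n_shuffles >= 2)
  X <- as.matrix(X)
  if (is.null(features)) features <- model$selected %||% colnames(X)
  eval_metric <- function(Xe) {
    pr <- model$predict_fn(Xe)
    rep <- compute_metrics(confusion_matrix(y, pr$class), pr$score, y)
    rep[[metric]]
  }
  base <- eval_metric(X)
  withr::local_seed(seed)
  res <- purrr::map(features, function(f) {
    drops <- vapply(seq_len(n_shuffles), function(s) {
      Xp <- X
      Xp[, f] <- sample(Xp[, f])
      base - eval_metric(Xp)
    }, numeric(1))
    tibble::tibble(feature = f, mean_importance = mean(drops),
                   sd_importance = stats::sd(drops))
  })
  out <- dplyr::arrange(dplyr::bind_rows(res),
                        dplyr::desc(.data$mean_importance))
  out$rank <- seq_len(nrow(out))
  structure(out, baseline = base, metric = metric)
}

#' Exact Shapley values of a linear scorer
#'
#' For a model linear on the margin scale, the Shapley contribution of
#' feature i for patient x is `phi_i = w_i * (x_i - mu_i)` with the
#' background mean `mu` taken from the exploratory set, and
#' `sum(phi) + base = margin(x)` exactly (`base = w . mu + intercept`).
#'
#' @param weights Named numeric vector of model weights.
#' @param intercept Model intercept.
#' @param background Named numeric vector of exploratory feature means.
#' @param X Matrix/tibble of validation patients (columns match
#'   `weights`).
#' @return List of class `shap_values`: `phi` (patients x features),
#'   `base`, `margin` (per patient).
#' @export
linear_shap <- function(weights, intercept, background, X) {
  X <- as.matrix(X)
  stopifnot(identical(colnames(X), names(weights)),
            identical(names(background), names(weights)))
  phi <- sweep(X, 2, background, "-") %*% diag(weights, length(weights))
  colnames(phi) <- names(weights)
  base <- sum(weights * background) + intercept
  margin <- drop(X %*% weights) + intercept
  structure(list(phi = phi, base = base, margin = margin),
            class = "shap_values")
}

#' Sampling-based Shapley values for a black-box scorer
#'
#' Monte-Carlo permutation estimate of Shapley contributions on the score
#' scale for models that are not linear; the fallback behind
#' [linear_shap()].
#'
#' @param score_fn Function mapping a feature matrix to numeric scores.
#' @param background Named numeric vector (reference feature values).
#' @param X Matrix of patients to explain.
#' @param n_perm Number of sampled permutations per patient.
#' @param seed Integer seed.
#' @return List of class `shap_values` (`phi`, `base`, `margin`).
#' @export
sampling_shap <- function(score_fn, background, X, n_perm = 64, seed = 1L) {
  X <- as.matrix(X)
  p <- ncol(X)
  withr::local_seed(seed)
  base <- score_fn(matrix(background, 1, dimnames = list(NULL, names(background))))
  phi <- matrix(0, nrow(X), p, dimnames = list(NULL, colnames(X)))
  for (i in seq_len(nrow(X))) {
    for (s in seq_len(n_perm)) {
      ord <- sample.int(p)
      cur <- background
      prev <- base
      for (j in ord) {
        cur[j] <- X[i, j]
        val <- score_fn(matrix(cur, 1, dimnames = list(NULL, names(cur))))
        phi[i, j] <- phi[i, j] + (val - prev) / n_perm
        prev <- val
      }
    }
  }
  structure(list(phi = phi, base = base,
                 margin = drop(score_fn(X))),
            class = "shap_values")
}

#' Side-by-side comparison of the np and p analysis runs
#'
#' Emits the exploratory (mean +/- SD over validation folds) and external
#' validation performance of both image versions plus the percent-change
#' table of the validation metrics (p relative to np), decreases labelled
#' as such. A missing run yields an absent column, not an error.
#'
#' @param np,p Lists with elements `exploratory` (tibble of per-fold
#'   metrics) and `validation` (one-row [compute_metrics()] tibble);
#'   either may be `NULL`.
#' @return List of class `run_summary`: `table` (Table-2-shaped tibble)
#'   and `percent_change` (tibble; `NULL` unless both runs present).
#' @export
summarize_run <- function(np = NULL, p = NULL) {
  metrics <- c("kappa", "f1", "auc", "accuracy", "sensitivity",
               "specificity", "ppv", "npv")
  fmt_expl <- function(run) {
    if (is.null(run)) return(rep(NA_character_, length(metrics)))
    vapply(metrics, function(m)
      sprintf("%.3f ± %.3f", mean(run$exploratory[[m]], na.rm = TRUE),
              stats::sd(run$exploratory[[m]], na.rm = TRUE)), character(1))
  }
  fmt_val <- function(run) {
    if (is.null(run)) return(rep(NA_real_, length(metrics)))
    vapply(metrics, function(m) round(run$validation[[m]], 3), numeric(1))
  }
  tab <- tibble::tibble(
    metric = metrics,
    exploratory_np = fmt_expl(np), exploratory_p = fmt_expl(p),
    validation_np = fmt_val(np), validation_p = fmt_val(p)
  )
  pc <- NULL
  if (!is.null(np) && !is.null(p)) {
    pc <- purrr::map_dfr(metrics, function(m) {
      b <- np$validation[[m]]; a <- p$validation[[m]]
      if (!is.finite(b) || !is.finite(a) || b == 0)
        return(tibble::tibble(metric = m, direction = NA_character_,
                              percent = NA_real_))
      dec <- a < b
      tibble::tibble(metric = m,
                     direction = if (dec) "decrease" else "increase",
                     percent = percent_change(b, a, as_decrease = dec))
    })
  }
  structure(list(table = tab, percent_change = pc), class = "run_summary")
}

#' @exportS3Method base::print
print.run_summary <- function(x, ...) {
  print(x$table)
  if (!is.null(x$percent_change)) {
    cat("\nValidation percent change (p vs np):\n")
    print(x$percent_change)
  }
  invisible(x)
}
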