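#' Stratified repeated cross-validation folds
#'
#' Per repeat, patients of each class are shuffled and dealt round-robin
#' into `n_folds` folds, so every fold's class proportions are within one
#' patient of the cohort proportions. Assignments are fully reproducible
#' from the seed and are meant to be computed once and reused by every
#' pipeline combination (and across image versions).
#'
#' @param labels Vector of class labels.
#' @param n_folds Number of folds (default 5).
#' @param n_repeats Number of repeats.
#' @param seed Integer seed.
#' @return Object of class `cv_scheme`: list of integer fold-assignment
#'   vectors (one per repeat), attributes `n_folds`, `seed`.
#' @export
make_folds <- function(labels, n_folds = 5L, n_repeats = 20L, seed = 1L) {
  tab <- table(labels)
  if (length(tab) < 2) stop("need both classes present")
  if (any(tab < n_folds))
    stop("class '", names(tab)[which.min(tab)], "' has fewer members (",
         min(tab), ") than folds (", n_folds, ")")
  withr::local_seed(seed)
  reps <- lapply(seq_len(n_repeats), function(r) {
    fold <- integer(length(labels))
    for (cl in names(tab)) {
      idx <- sample(which(labels == cl))
      fold[idx] <- rep_len(seq_len(n_folds), length(idx))
    }
    fold
  })
  structure(reps, class = "cv_scheme", n_folds = n_folds, seed = seed,
            n_repeats = n_repeats)
}

#' Enumerate pipeline combinations
#'
#' The full grid of (scaler, reducer, k, resampler, classifier); the
#' boosting-with-undersampling and balanced-bagging classifiers force
#' `resampler = "none"`, and the embedded reducers (lasso, elastic-net
#' logistic) carry no k.
#'
#' @param reducers,resamplers,classifiers Character vectors of component
#'   names (defaults: the full sets).
#' @param k_grid Numbers of retained features for ranking reducers.
#' @return Tibble with columns scaler, reducer, k, resampler, classifier
#'   and a canonical `combo_id`.
#' @export
enumerate_combos <- function(reducers = c("gini", "f_ratio", "info_gain",
                                          "spearman", "mrmr", "mim",
                                          "stir_relief", "lasso",
                                          "elasticnet_logistic"),
                             resamplers = c("smote", "adasyn",
                                            "smote_tomek", "rus",
                                            "nearmiss", "none"),
                             classifiers = c("svm_linear", "random_forest",
                                             "knn", "logreg_l2",
                                             "logreg_l1",
                                             "logreg_elasticnet",
                                             "adaboost_tree",
                                             "rusboost_tree",
                                             "gradient_boost",
                                             "balanced_bagging_trees"),
                             k_grid = pipeline_defaults()$k_grid) {
  embedded <- intersect(reducers, c("lasso", "elasticnet_logistic"))
  ranked <- setdiff(reducers, embedded)
  grid <- dplyr::bind_rows(
    tidyr::expand_grid(reducer = ranked, k = as.integer(k_grid)),
    tibble::tibble(reducer = embedded, k = NA_integer_)
  )
  out <- tidyr::expand_grid(scaler = "robust_center_scale", grid,
                            resampler = resamplers,
                            classifier = classifiers)
  forced <- out$classifier %in% c("rusboost_tree", "balanced_bagging_trees")
  out$resampler[forced] <- "none"
  out <- dplyr::distinct(out)
  out$combo_id <- paste(out$reducer,
                        ifelse(is.na(out$k), "auto", out$k),
                        out$resampler, out$classifier, sep = "|")
  out
}

# strip the metadata columns of a radiomics_features tibble
feature_matrix <- function(features) {
  if (is.matrix(features)) return(features)
  drop_cols <- intersect(c("patient_id", "center", "label"),
                         colnames(features))
  X <- as.matrix(features[, setdiff(colnames(features), drop_cols)])
  storage.mode(X) <- "double"
  X
}

#' Fit all training-phase transforms and apply them to train and test
#'
#' Scaler (median / interquartile range), reducer and resampler are fit
#' on the training rows only; the test rows are transformed with the
#' frozen parameters. This is the leakage barrier of the pipeline.
#'
#' @param combo One-row tibble (see [enumerate_combos()]).
#' @param X_train,y_train Training features (matrix) and labels.
#' @param X_test Test features.
#' @param seed Integer seed for the stochastic components.
#' @return List: `X_train`, `y_train` (resampled), `X_test` (transformed),
#'   `selected` (feature names), `scaler`.
#' @export
fit_transform_train_only <- function(combo, X_train, y_train, X_test,
                                     seed = 1L) {
  cfg <- pipeline_defaults()
  sc <- fit_scaler(X_train)
  Xtr <- apply_scaler(sc, X_train)
  Xte <- apply_scaler(sc, X_test)
  sel <- reduce_select(combo$reducer, Xtr, y_train,
                       k = if (is.na(combo$k)) NULL else combo$k,
                       seed = seed, cfg = cfg)
  Xtr <- Xtr[, sel, drop = FALSE]
  Xte <- Xte[, sel, drop = FALSE]
  rs <- resample_train(combo$resampler, Xtr, y_train, seed = seed,
                       cfg = cfg)
  list(X_train = rs$X, y_train = rs$y, X_test = Xte, selected = sel,
       scaler = sc)
}

fold_metrics <- function(truth, pred, score, positive) {
  compute_metrics(confusion_matrix(truth, pred, positive), score, truth)
}

#' Combinatorial model search ranked by Cohen's kappa
#'
#' Scores every pipeline combination on identical stratified CV folds,
#' fitting all transforms on training folds only, and ranks combinations
#' by mean validation-fold kappa (ties: ascending kappa SD, then
#' canonical combo order). Combinations whose mean kappa does not exceed
#' 0 (the chance baseline) are flagged `discarded`; individual combo
#' failures are caught, logged and scored as discarded without aborting
#' the search.
#'
#' @param features A `radiomics_features` tibble (or feature matrix).
#' @param labels Class labels (defaults to the `label` column).
#' @param combos Tibble from [enumerate_combos()] (possibly filtered).
#' @param scheme A [make_folds()] result (built from `labels` if `NULL`).
#' @param seed Seed for folds (when `scheme` is `NULL`) and per-fold
#'   component seeds.
#' @param n_repeats Repeats when building the default scheme.
#' @param verbose Print progress.
#' @return Tibble of class `combo_search`: one row per combo with
#'   mean/SD kappa, mean of every other metric, rank and `discarded`;
#'   attributes `scheme`, `selections` (per reducer x fold), `errors`.
#' @export
run_search <- function(features, labels = NULL, combos = NULL,
                       scheme = NULL, seed = 1L,
                       n_repeats = pipeline_defaults()$n_repeats,
                       verbose = FALSE) {
  cfg <- pipeline_defaults()
  if (is.null(labels) && is.data.frame(features)) labels <- features[["label"]]
  labels <- as.character(labels)
  X <- feature_matrix(features)
  stopifnot(nrow(X) == length(labels))
  if (min(table(labels)) < 2) stop("need at least 2 patients per class")
  if (is.null(combos)) combos <- enumerate_combos()
  if (is.null(scheme))
    scheme <- make_folds(labels, cfg$n_folds, n_repeats, seed)
  n_folds <- attr(scheme, "n_folds")

  red_keys <- unique(paste(combos$reducer, ifelse(is.na(combos$k), "auto",
                                                  combos$k), sep = "|"))
  metric_names <- c("kappa", "f1", "auc", "accuracy", "sensitivity",
                    "specificity", "ppv", "npv")
  acc <- array(NA_real_, dim = c(nrow(combos), length(scheme) * n_folds,
                                 length(metric_names)))
  selections <- list()
  errors <- character(0)

  fold_counter <- 0L
  for (r in seq_along(scheme)) {
    fold <- scheme[[r]]
    for (f in seq_len(n_folds)) {
      fold_counter <- fold_counter + 1L
      tr <- which(fold != f)
      te <- which(fold == f)
      fold_seed <- (seed * 1009L + r * 101L + f) %% .Machine$integer.max
      sc <- fit_scaler(X[tr, , drop = FALSE])
      Xtr_s <- apply_scaler(sc, X[tr, , drop = FALSE])
      Xte_s <- apply_scaler(sc, X[te, , drop = FALSE])
      # one selection per (reducer, k) per fold, shared across combos
      sel_by_key <- list()
      for (key in red_keys) {
        parts <- strsplit(key, "|", fixed = TRUE)[[1]]
        k <- if (parts[2] == "auto") NULL else as.integer(parts[2])
        sel_by_key[[key]] <- tryCatch(
          reduce_select(parts[1], Xtr_s, labels[tr], k = k,
                        seed = fold_seed, cfg = cfg),
          error = function(e) e)
        selections[[key]][[fold_counter]] <-
          if (inherits(sel_by_key[[key]], "error")) character(0)
          else sel_by_key[[key]]
      }
      rs_cache <- list()
      for (ci in seq_len(nrow(combos))) {
        cb <- combos[ci, ]
        key <- paste(cb$reducer, ifelse(is.na(cb$k), "auto", cb$k),
                     sep = "|")
        sel <- sel_by_key[[key]]
        if (inherits(sel, "error")) {
          errors <- c(errors, paste0(cb$combo_id, ": ",
                                     conditionMessage(sel)))
          next
        }
        res <- tryCatch({
          rs_key <- paste(key, cb$resampler, sep = "|")
          if (is.null(rs_cache[[rs_key]]))
            rs_cache[[rs_key]] <- resample_train(
              cb$resampler, Xtr_s[, sel, drop = FALSE], labels[tr],
              seed = fold_seed, cfg = cfg)
          rs <- rs_cache[[rs_key]]
          clf <- fit_classifier(cb$classifier, rs$X, rs$y,
                                seed = fold_seed, cfg = cfg)
          pr <- clf$predict_fn(Xte_s[, sel, drop = FALSE])
          m <- fold_metrics(labels[te], pr$class, pr$score,
                            cfg$positive_class)
          unlist(m[1, metric_names])
        }, error = function(e) {
          errors <<- c(errors, paste0(cb$combo_id, ": ",
                                      conditionMessage(e)))
          NULL
        })
        if (!is.null(res)) acc[ci, fold_counter, ] <- res
      }
    }
    if (verbose) message("repeat ", r, "/", length(scheme), " done")
  }

  mean_k <- apply(acc[, , 1, drop = FALSE], 1, mean, na.rm = TRUE)
  sd_k <- apply(acc[, , 1, drop = FALSE], 1, stats::sd, na.rm = TRUE)
  failed <- apply(acc[, , 1, drop = FALSE], 1, function(v) all(is.na(v)))
  mean_k[failed] <- -Inf
  others <- apply(acc, c(1, 3), mean, na.rm = TRUE)
  colnames(others) <- metric_names
  out <- dplyr::bind_cols(
    combos,
    tibble::tibble(mean_kappa = mean_k, sd_kappa = sd_k),
    tibble::as_tibble(others[, -1, drop = FALSE]) |>
      stats::setNames(paste0("mean_", metric_names[-1]))
  )
  out$discarded <- out$mean_kappa <= 0 | failed
  ord <- order(-out$mean_kappa, out$sd_kappa, seq_len(nrow(out)))
  out <- out[ord, ]
  out$rank <- seq_len(nrow(out))
  per_fold_kappa <- acc[ord, , 1, drop = FALSE]
  structure(out, class = c("combo_search", class(out)),
            scheme = scheme, selections = selections, errors = errors,
            metrics_per_fold = acc[ord, , , drop = FALSE],
            metric_names = metric_names, n_repeats = length(scheme),
            per_fold_kappa = per_fold_kappa)
}

#' Best non-discarded combination of a search
#' @param search A `combo_search` result.
#' @return One-row tibble.
#' @export
best_combo <- function(search) {
  keep <- !search$discarded
  if (!any(keep)) stop("all combinations were discarded")
  search[which(keep)[1], c("scaler", "reducer", "k", "resampler",
                           "classifier", "combo_id")]
}

#' Per-fold exploratory metrics of one combination
#' @param search A `combo_search` result.
#' @param combo_id Combo id (default: the best non-discarded one).
#' @return Tibble of per-fold metrics.
#' @export
exploratory_metrics <- function(search, combo_id = NULL) {
  if (is.null(combo_id)) combo_id <- best_combo(search)$combo_id
  i <- match(combo_id, search$combo_id)
  m <- attr(search, "metrics_per_fold")[i, , ]
  colnames(m) <- attr(search, "metric_names")
  tibble::as_tibble(m)
}

#' Freeze the winning pipeline on the exploratory set and test externally
#'
#' The full pipeline (scaler, reducer, resampler, classifier) is refit
#' once on the entire exploratory cohort and then applied, untouched, to
#' the validation cohort. IDH-wildtype is the positive class throughout.
#'
#' @param combo One-row combo tibble (e.g. [best_combo()]).
#' @param expl_features,expl_labels Exploratory cohort features/labels.
#' @param val_features,val_labels Validation cohort features/labels.
#' @param seed Integer seed for the stochastic components.
#' @return Object of class `frozen_model`: `metrics` (one-row tibble),
#'   `cm`, `predictions` (per-patient tibble), `selected`, `combo`,
#'   `predict_fn` (maps an original-space feature matrix to
#'   class/score), model `weights`/`intercept` when linear, and the
#'   transformed exploratory matrix `X_expl_t` for explainability.
#' @export
external_validate <- function(combo, expl_features, expl_labels = NULL,
                              val_features, val_labels = NULL,
                              seed = 1L) {
  cfg <- pipeline_defaults()
  if (is.null(expl_labels) && is.data.frame(expl_features)) expl_labels <- expl_features[["label"]]
  if (is.null(val_labels) && is.data.frame(val_features)) val_labels <- val_features[["label"]]
  Xe <- feature_matrix(expl_features)
  Xv <- feature_matrix(val_features)
  if (!identical(colnames(Xe), colnames(Xv)))
    stop("feature-name mismatch between exploratory and validation cohorts")
  get_ids <- function(x)
    if (is.data.frame(x) && !is.null(x[["patient_id"]])) x[["patient_id"]]
  ids_e <- get_ids(expl_features)
  ids_v <- get_ids(val_features)
  if (!is.null(ids_e) && !is.null(ids_v)) {
    overlap <- length(intersect(ids_e, ids_v))
    # a full copy is allowed (resubstitution consistency check);
    # partial overlap is a cohort-design error
    if (overlap > 0 && !setequal(ids_e, ids_v))
      stop("validation patients overlap the exploratory cohort")
  }

  ft <- fit_transform_train_only(combo, Xe, as.character(expl_labels), Xv,
                                 seed = seed)
  clf <- fit_classifier(combo$classifier, ft$X_train, ft$y_train,
                        seed = seed, cfg = cfg)
  predict_fn <- function(Xnew) {
    Xs <- apply_scaler(ft$scaler, as.matrix(Xnew))
    clf$predict_fn(Xs[, ft$selected, drop = FALSE])
  }
  pr <- predict_fn(Xv)
  cm <- confusion_matrix(val_labels, pr$class, cfg$positive_class)
  metrics <- compute_metrics(cm, pr$score, val_labels)
  preds <- tibble::tibble(
    patient_id = ids_v %||% sprintf("V%03d", seq_along(val_labels)),
    truth = as.character(val_labels), predicted = pr$class,
    score = pr$score)
  structure(list(metrics = metrics, cm = cm, predictions = preds,
                 selected = ft$selected, combo = combo,
                 predict_fn = predict_fn, classifier = clf,
                 scaler = ft$scaler,
                 weights = clf$weights, intercept = clf$intercept,
                 linear = isTRUE(clf$linear),
                 X_expl_t = apply_scaler(ft$scaler,
                                         Xe)[, ft$selected, drop = FALSE]),
            class = "frozen_model")
}

#' @exportS3Method base::print
print.frozen_model <- function(x, ...) {
  cat("Frozen pipeline:", x$combo$combo_id, "\n")
  cat("Selected features:", length(x$selected), "\n")
  print(x$metrics)
  invisible(x)
}

#' Explain a frozen model on the validation set
#'
#' Permutation importance of every selected feature (mean +/- SD drop of
#' Cohen's kappa over shuffles) plus Shapley values: exact closed-form
#' contributions on the margin scale for linear classifiers, a
#' sampling-based estimate otherwise. The explainer background is the
#' exploratory set; the explanations are computed on validation patients.
#'
#' @param model A [external_validate()] result.
#' @param val_features,val_labels Validation features/labels.
#' @param n_shuffles Permutations per feature.
#' @param seed Integer seed.
#' @return List of class `explain_report`: `importance` (tibble),
#'   `shap` (`shap_values`), `shap_scale`.
#' @export
explain_model <- function(model, val_features, val_labels = NULL,
                          n_shuffles = 50, seed = 1L) {
  if (is.null(val_labels) && is.data.frame(val_features)) val_labels <- val_features[["label"]]
  Xv <- feature_matrix(val_features)
  imp <- permutation_importance(model, Xv, as.character(val_labels),
                                metric = "kappa",
                                n_shuffles = n_shuffles, seed = seed)
  Xv_t <- apply_scaler(model$scaler, Xv)[, model$selected, drop = FALSE]
  bg <- colMeans(model$X_expl_t)
  shap <- if (model$linear && !is.null(model$weights)) {
    w <- model$weights[model$selected]
    linear_shap(w, model$intercept %||% 0, bg[names(w)],
                Xv_t[, names(w), drop = FALSE])
  } else {
    sampling_shap(function(Xn) model$classifier$predict_fn(Xn)$score,
                  bg, Xv_t, seed = seed)
  }
  structure(list(importance = imp, shap = shap,
                 shap_scale = if (model$linear) "margin" else "score"),
            class = "explain_report")
}
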