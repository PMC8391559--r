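planted_data <- function(n = 90, p = 50, seed = 5, noise = 1.2,
                         frac_pos = 0.45) {
  withr::local_seed(seed)
  X <- matrix(rnorm(n * p), n, p, dimnames = list(NULL, paste0("f", 1:p)))
  y <- ifelse(X[, 1] + X[, 2] + rnorm(n, 0, noise) >
                stats::qnorm(1 - frac_pos, sd = sqrt(2 + noise^2)),
              "wildtype", "mutant")
  list(X = X, y = y)
}

test_that("stratified folds keep class proportions within one patient", {
  labels <- c(rep("wildtype", 26), rep("mutant", 66))
  sch <- make_folds(labels, n_folds = 5, n_repeats = 8, seed = 2)
  for (fold in sch) {
    for (f in 1:5) {
      pos <- sum(labels[fold == f] == "wildtype")
      expect_true(pos %in% c(5L, 6L)) # 26 positives over 5 folds
    }
  }
  expect_identical(make_folds(labels, 5, 8, seed = 2), sch)
  expect_false(identical(make_folds(labels, 5, 8, seed = 3), sch))
  expect_error(make_folds(c(rep("a", 4), rep("b", 40)), 5, 1, 1),
               "fewer members")
})

test_that("combo enumeration honours the no-resampling constraint", {
  combos <- enumerate_combos()
  forced <- combos[combos$classifier %in%
                     c("rusboost_tree", "balanced_bagging_trees"), ]
  expect_true(all(forced$resampler == "none"))
  expect_true(all(is.na(combos$k[combos$reducer == "lasso"])))
  expect_false(any(duplicated(combos$combo_id)))
})

test_that("train-only fitting is leakage-free and k is honoured", {
  d <- planted_data()
  combo <- enumerate_combos(reducers = "gini", resamplers = "smote",
                            classifiers = "logreg_l2", k_grid = 15)[1, ]
  tr <- 1:60
  te <- 61:90
  ft <- fit_transform_train_only(combo, d$X[tr, ], d$y[tr], d$X[te, ],
                                 seed = 4)
  expect_length(ft$selected, 15)
  expect_equal(ncol(ft$X_test), 15)
  # leakage probe: perturbing test rows changes no fitted parameter
  Xte2 <- d$X[te, ] + matrix(rnorm(length(te) * 50, 0, 10), length(te))
  ft2 <- fit_transform_train_only(combo, d$X[tr, ], d$y[tr], Xte2,
                                  seed = 4)
  expect_identical(ft$scaler, ft2$scaler)
  expect_identical(ft$selected, ft2$selected)
  expect_identical(ft$X_train, ft2$X_train)
  expect_error(
    fit_transform_train_only(
      enumerate_combos(reducers = "gini", resamplers = "none",
                       classifiers = "knn", k_grid = 500)[1, ],
      d$X[tr, ], d$y[tr], d$X[te, ]),
    "exceeds")
})

test_that("oversamplers balance the training classes", {
  d <- planted_data(n = 60, frac_pos = 0.25)
  for (m in c("smote", "adasyn", "rus", "nearmiss")) {
    r <- dscradiomics:::resample_train(m, d$X[, 1:8], d$y, seed = 2)
    tab <- table(r$y)
    expect_equal(unname(tab[1]), unname(tab[2]))
  }
  r2 <- dscradiomics:::resample_train("smote_tomek", d$X[, 1:8], d$y,
                                      seed = 2)
  tab2 <- table(r2$y)
  expect_lte(abs(tab2[1] - tab2[2]), 4) # tomek cleaning removes pairs
  # synthetic points are convex combinations of minority samples
  rs <- dscradiomics:::resample_train("smote", d$X[, 1:2], d$y, seed = 7)
  new_rows <- utils::tail(rs$X, nrow(rs$X) - nrow(d$X))
  rng <- apply(d$X[d$y == names(which.min(table(d$y))), 1:2], 2, range)
  expect_true(all(new_rows[, 1] >= rng[1, 1] & new_rows[, 1] <= rng[2, 1]))
})

test_that("the search ranks by kappa, reuses folds and recovers signal", {
  d <- planted_data(n = 90, noise = 0.9)
  combos <- enumerate_combos(reducers = c("f_ratio", "gini"),
                             resamplers = c("smote", "none"),
                             classifiers = c("logreg_l2", "svm_linear"),
                             k_grid = 5)
  sr <- run_search(d$X, d$y, combos, n_repeats = 4, seed = 11)
  expect_equal(nrow(sr), nrow(combos))
  expect_true(all(diff(sr$mean_kappa) <= 1e-12))
  expect_gt(best_combo(sr)$combo_id %in% sr$combo_id, 0)
  expect_gt(sr$mean_kappa[1], 0.4) # planted effect is recoverable
  # selected features are dominated by the planted pair
  sel <- attr(sr, "selections")[["f_ratio|5"]]
  frac <- mean(vapply(sel, function(s) all(c("f1", "f2") %in% s),
                      logical(1)))
  expect_gt(frac, 0.8)
  # identical scheme across two feature versions under one seed
  sch1 <- attr(run_search(d$X, d$y, combos[1, ], n_repeats = 2,
                          seed = 99), "scheme")
  sch2 <- attr(run_search(d$X * 3 + 1, d$y, combos[1, ], n_repeats = 2,
                          seed = 99), "scheme")
  expect_identical(serialize(sch1, NULL), serialize(sch2, NULL))
})

test_that("label permutation drives the best kappa toward zero", {
  d <- planted_data(n = 200, p = 40, noise = 1)
  withr::local_seed(77)
  y_perm <- sample(d$y)
  combos <- enumerate_combos(reducers = c("f_ratio"),
                             resamplers = c("smote", "none"),
                             classifiers = c("logreg_l2", "knn"),
                             k_grid = c(5, 10))
  sr <- run_search(d$X, y_perm, combos, n_repeats = 4, seed = 8)
  expect_lt(abs(sr$mean_kappa[1]), 0.1)
})

test_that("search failures are caught, flagged and do not abort", {
  d <- planted_data(n = 60, p = 10, noise = 0.5)
  combos <- enumerate_combos(reducers = "gini", resamplers = "none",
                             classifiers = c("logreg_l2"),
                             k_grid = c(5, 200)) # k = 200 must fail
  sr <- run_search(d$X, d$y, combos, n_repeats = 2, seed = 1)
  expect_true(any(sr$discarded))
  expect_gt(length(attr(sr, "errors")), 0)
  expect_false(all(sr$discarded))
})

test_that("external validation freezes the pipeline and checks inputs", {
  d <- planted_data(n = 120, noise = 0.8)
  combo <- enumerate_combos(reducers = "f_ratio", resamplers = "smote",
                            classifiers = "logreg_l2", k_grid = 5)[1, ]
  tr <- 1:80
  te <- 81:120
  fm <- external_validate(combo, d$X[tr, ], d$y[tr], d$X[te, ], d$y[te],
                          seed = 3)
  expect_s3_class(fm$metrics, "metrics_report")
  expect_gt(fm$metrics$kappa, 0) # generalizes on held-out rows
  # resubstitution consistency: validation = copy of exploratory
  fm2 <- external_validate(combo, d$X[tr, ], d$y[tr], d$X[tr, ], d$y[tr],
                           seed = 3)
  pr <- fm2$predict_fn(d$X[tr, ])
  cm <- confusion_matrix(d$y[tr], pr$class)
  expect_equal(fm2$metrics$accuracy,
               (cm$tp + cm$tn) / length(tr))
  expect_error(
    external_validate(combo, d$X, d$y,
                      matrix(rnorm(40), 10,
                             dimnames = list(NULL, paste0("g", 1:4))),
                      d$y[1:10]),
    "mismatch")
})

test_that("tidy, glance and autoplot work on search results", {
  d <- planted_data(n = 50, p = 12)
  combos <- enumerate_combos(reducers = "f_ratio", resamplers = "none",
                             classifiers = "logreg_l2", k_grid = 5)
  sr <- run_search(d$X, d$y, combos, n_repeats = 2, seed = 4)
  expect_s3_class(tidy(sr), "tbl_df")
  g <- glance(sr)
  expect_equal(g$n_combos, 1L)
  p <- autoplot(sr)
  expect_s3_class(p, "ggplot")
  fm <- external_validate(sr[1, ], d$X[1:35, ], d$y[1:35], d$X[36:50, ],
                          d$y[36:50])
  expect_s3_class(tidy(fm), "tbl_df")
  expect_equal(nrow(tidy(fm)), 15)
})
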