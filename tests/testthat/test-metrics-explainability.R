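test_that("kappa matches the direct p_o / p_e recomputation everywhere", {
  withr::local_seed(42)
  for (i in 1:200) {
    cm <- dscradiomics:::as_confusion_matrix(sample(0:30, 1),
                                             sample(0:30, 1),
                                             sample(0:30, 1),
                                             sample(1:30, 1))
    m <- compute_metrics(cm)
    n <- cm$tp + cm$fn + cm$fp + cm$tn
    po <- (cm$tp + cm$tn) / n
    pe <- ((cm$tp + cm$fn) * (cm$tp + cm$fp) +
             (cm$tn + cm$fp) * (cm$tn + cm$fn)) / n^2
    expected <- if (pe == 1) 0 else (po - pe) / (1 - pe)
    expect_equal(m$kappa, expected, tolerance = 1e-12)
    expect_gte(m$kappa, -1)
    expect_lte(m$kappa, 1)
  }
})

test_that("label-independent predictions give kappa 0 by construction", {
  # predictions made independently of truth: expected kappa is 0; with
  # marginals fixed, any constant prediction gives exactly 0
  m <- compute_metrics(confusion_matrix(rep(c("wildtype", "mutant"),
                                            c(30, 70)),
                                        rep("mutant", 100)))
  expect_equal(m$kappa, 0)
})

test_that("perfect prediction yields kappa 1 and unit rates", {
  m <- compute_metrics(dscradiomics:::as_confusion_matrix(12, 0, 0, 30))
  expect_equal(m$kappa, 1)
  expect_equal(m$sensitivity, 1)
  expect_equal(m$specificity, 1)
  expect_equal(m$f1, 1)
})

test_that("zero-denominator metrics are 0 and flagged", {
  m <- compute_metrics(dscradiomics:::as_confusion_matrix(0, 0, 5, 20))
  expect_equal(m$sensitivity, 0)
  expect_true("sensitivity" %in% attr(m, "zero_division"))
  expect_error(compute_metrics(list(tp = 0, fn = 0, fp = 0, tn = 0)),
               "empty")
})

test_that("AUC equals the closed-form for separable scores", {
  truth <- rep(c("wildtype", "mutant"), each = 5)
  m <- compute_metrics(confusion_matrix(truth, truth),
                       scores = c(6:10, 1:5), truth = truth)
  expect_equal(m$auc, 1)
  m2 <- compute_metrics(confusion_matrix(truth, truth),
                        scores = rep(1, 10), truth = truth)
  expect_equal(m2$auc, 0.5)
})

test_that("percent change matches its definition and flags zero baselines", {
  expect_equal(percent_change(0.145, 0.282), 94.48276, tolerance = 1e-5)
  expect_equal(percent_change(0.5, 0.5), 0)
  expect_equal(percent_change(0.733, 0.600, as_decrease = TRUE),
               18.14461, tolerance = 1e-5)
  expect_error(percent_change(0, 1), "zero baseline")
})

test_that("permutation importance isolates the used feature", {
  # threshold model on feature A only; B is pure noise
  withr::local_seed(10)
  X <- cbind(A = rnorm(60), B = rnorm(60))
  y <- ifelse(X[, "A"] > 0, "wildtype", "mutant")
  model <- list(predict_fn = function(Xn)
    list(class = ifelse(Xn[, "A"] > 0, "wildtype", "mutant"),
         score = Xn[, "A"]),
    selected = c("A", "B"))
  imp <- permutation_importance(model, X, y, n_shuffles = 30, seed = 4)
  a <- imp[imp$feature == "A", ]
  b <- imp[imp$feature == "B", ]
  expect_equal(a$rank, 1L)
  expect_gt(a$mean_importance, 0.5)
  # unused feature: exactly zero drop for every shuffle
  expect_equal(b$mean_importance, 0)
  expect_equal(b$sd_importance, 0)
})

test_that("permutation importance matches brute-force expectation at n = 6", {
  # enumerate all 720 permutations of the single used feature
  X <- cbind(A = c(-3, -2, -1, 1, 2, 3))
  y <- ifelse(X[, "A"] > 0, "wildtype", "mutant")
  model <- list(predict_fn = function(Xn)
    list(class = ifelse(Xn[, "A"] > 0, "wildtype", "mutant"),
         score = Xn[, "A"]), selected = "A")
  kappa_of <- function(perm) {
    pr <- ifelse(X[perm, "A"] > 0, "wildtype", "mutant")
    compute_metrics(confusion_matrix(y, pr))$kappa
  }
  perms <- as.matrix(expand.grid(rep(list(1:6), 6)))
  perms <- perms[apply(perms, 1, function(r) !any(duplicated(r))), ]
  exact <- 1 - mean(apply(perms, 1, kappa_of))
  imp <- permutation_importance(model, X, y, n_shuffles = 400, seed = 2)
  expect_equal(imp$mean_importance[1], exact, tolerance = 0.08)
})

test_that("linear SHAP is exact: additivity and coalition enumeration", {
  expect_equal(
    unname(linear_shap(c(a = 2, b = 0), 0, c(a = 1, b = 1),
                       matrix(c(3, 5), 1,
                              dimnames = list(NULL, c("a", "b"))))$phi),
    matrix(c(4, 0), 1))
  withr::local_seed(3)
  p <- 5
  w <- stats::setNames(rnorm(p), paste0("x", 1:p))
  mu <- stats::setNames(rnorm(p), names(w))
  X <- matrix(rnorm(3 * p), 3, dimnames = list(NULL, names(w)))
  b0 <- 0.7
  sh <- linear_shap(w, b0, mu, X)
  expect_lt(max(abs(rowSums(sh$phi) + sh$base - sh$margin)), 1e-10)
  # x = mu gives all-zero contributions
  sh0 <- linear_shap(w, b0, mu, matrix(mu, 1,
                                       dimnames = list(NULL, names(w))))
  expect_equal(max(abs(sh0$phi)), 0)
  # full 2^5 coalition enumeration; absent features at the background
  for (r in 1:3) {
    value_fn <- function(s) {
      xx <- ifelse(s, X[r, ], mu)
      sum(w * xx) + b0
    }
    phi_oracle <- oracle_shapley(value_fn, p)
    expect_equal(unname(sh$phi[r, ]), phi_oracle, tolerance = 1e-10)
  }
})

test_that("the run summary reproduces the reference two-version comparison", {
  mk <- function(v) {
    tibble::tibble(kappa = v[1], f1 = v[2], auc = v[3], accuracy = v[4],
                   sensitivity = v[5], specificity = v[6], ppv = v[7],
                   npv = v[8])
  }
  expl <- tibble::as_tibble(matrix(runif(80), 10,
                                   dimnames = list(NULL,
                                                   c("kappa", "f1", "auc",
                                                     "accuracy",
                                                     "sensitivity",
                                                     "specificity", "ppv",
                                                     "npv"))))
  np <- list(exploratory = expl,
             validation = mk(c(0.145, 0.415, 0.639, 0.544, 0.733, 0.491,
                               0.290, 0.868)))
  p <- list(exploratory = expl,
            validation = mk(c(0.282, 0.474, 0.667, 0.706, 0.600, 0.736,
                              0.391, 0.868)))
  s <- summarize_run(np, p)
  pc <- s$percent_change
  get <- function(m) pc$percent[pc$metric == m]
  expect_equal(round(get("kappa"), 2), 94.48)
  expect_equal(round(get("accuracy"), 2), 29.78)
  expect_equal(round(get("specificity"), 2), 49.90)
  expect_equal(round(get("auc"), 2), 4.38)
  expect_equal(round(get("f1"), 2), 14.22)
  expect_equal(round(get("sensitivity"), 2), 18.14)
  expect_equal(pc$direction[pc$metric == "sensitivity"], "decrease")
  # identical inputs: all changes zero
  s0 <- summarize_run(np, np)
  expect_true(all(s0$percent_change$percent[
    is.finite(s0$percent_change$percent)] == 0))
  # missing run: absent column, no crash
  s1 <- summarize_run(np = np, p = NULL)
  expect_true(all(is.na(s1$table$validation_p)))
  expect_null(s1$percent_change)
})
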