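# ---- feature-level scaling (robust center/scale) --------------------------

fit_scaler <- function(X) {
  q <- cpp_col_quantiles(as.matrix(X), c(0.25, 0.5, 0.75))
  center <- stats::setNames(q[2, ], colnames(X))
  scale <- stats::setNames(q[3, ] - q[1, ], colnames(X))
  scale[scale == 0] <- 1
  list(center = center, scale = scale)
}

apply_scaler <- function(sc, X) {
  sweep(sweep(X, 2, sc$center, "-"), 2, sc$scale, "/")
}

# ---- univariate / multivariate feature scoring ----------------------------

# best-split impurity decrease per feature (gini or entropy)
impurity_gain_scores <- function(X, y01, impurity = c("gini", "entropy")) {
  impurity <- match.arg(impurity)
  stats::setNames(cpp_split_gain(as.matrix(X), as.integer(y01),
                                 impurity == "gini"),
                  colnames(X))
}

f_ratio_scores <- function(X, y01) {
  n1 <- sum(y01 == 1)
  n0 <- sum(y01 == 0)
  X1 <- X[y01 == 1, , drop = FALSE]
  X0 <- X[y01 == 0, , drop = FALSE]
  m1 <- colMeans(X1)
  m0 <- colMeans(X0)
  v1 <- (colSums(X1^2) - n1 * m1^2) / (n1 - 1)
  v0 <- (colSums(X0^2) - n0 * m0^2) / (n0 - 1)
  m <- (n1 * m1 + n0 * m0) / (n1 + n0)
  between <- n1 * (m1 - m)^2 + n0 * (m0 - m)^2
  within <- (n1 - 1) * v1 + (n0 - 1) * v0
  ifelse(within == 0, ifelse(between > 0, Inf, 0),
         (between / 1) / (within / (n1 + n0 - 2)))
}

spearman_scores <- function(X, y01) {
  R <- apply(X, 2, rank)
  abs(suppressWarnings(stats::cor(R, y01, method = "pearson"))[, 1]) |>
    (\(v) ifelse(is.na(v), 0, v))()
}

# quartile-bin a feature column (4 bins, ties collapse gracefully)
quartile_bins <- function(x) {
  q <- unique(stats::quantile(x, c(0.25, 0.5, 0.75), names = FALSE))
  findInterval(x, q) + 1L
}

mutual_information <- function(bx, by) {
  tab <- table(bx, by)
  p <- tab / sum(tab)
  px <- rowSums(p)
  py <- colSums(p)
  pos <- p > 0
  sum(p[pos] * log2(p[pos] / (outer(px, py)[pos])))
}

mim_scores <- function(X, y01) {
  stats::setNames(cpp_mi_quartile(as.matrix(X), as.integer(y01)),
                  colnames(X))
}

mrmr_select <- function(X, y01, k, pool_size = 150L) {
  rel <- mim_scores(X, y01)
  pool <- order(rel, decreasing = TRUE)[seq_len(min(pool_size, ncol(X)))]
  bins <- lapply(pool, function(j) quartile_bins(X[, j]))
  names(bins) <- as.character(pool)
  selected <- integer(0)
  red_sum <- numeric(length(pool)) # cumulative redundancy per pool entry
  remaining <- seq_along(pool)
  for (step in seq_len(min(k, length(pool)))) {
    crit <- rel[pool[remaining]] -
      if (length(selected)) red_sum[remaining] / length(selected) else 0
    pick <- remaining[which.max(crit)]
    selected <- c(selected, pick)
    remaining <- setdiff(remaining, pick)
    if (length(remaining))
      red_sum[remaining] <- red_sum[remaining] +
        vapply(remaining, function(r)
          mutual_information(bins[[r]], bins[[pick]]), numeric(1))
  }
  colnames(X)[pool[selected]]
}

# relief-based statistic with k nearest hits/misses, standardized as a
# two-sample t-like score of miss vs hit neighbour differences
stir_scores <- function(X, y01, neighbors = 10L) {
  n <- nrow(X)
  D <- as.matrix(stats::dist(X))
  diag(D) <- Inf
  kh <- min(neighbors, min(table(y01)) - 1L)
  kh <- max(kh, 1L)
  hit_idx <- matrix(0L, n, kh)
  miss_idx <- matrix(0L, n, kh)
  for (i in seq_len(n)) {
    same <- which(y01 == y01[i])
    diff <- which(y01 != y01[i])
    hit_idx[i, ] <- same[order(D[i, same])][seq_len(kh)]
    miss_idx[i, ] <- diff[order(D[i, diff])][seq_len(kh)]
  }
  ii <- rep(seq_len(n), kh)
  hd <- abs(X[ii, , drop = FALSE] - X[as.vector(hit_idx), , drop = FALSE])
  md <- abs(X[ii, , drop = FALSE] - X[as.vector(miss_idx), , drop = FALSE])
  mh <- colMeans(hd)
  mm <- colMeans(md)
  vh <- apply(hd, 2, stats::var)
  vm <- apply(md, 2, stats::var)
  se <- sqrt((vh + vm) / nrow(hd))
  ifelse(se == 0, 0, (mm - mh) / se)
}

glmnet_select <- function(X, y01, alpha, seed) {
  withr::local_seed(seed)
  foldid <- sample(rep_len(1:3, length(y01)))
  cv <- glmnet::cv.glmnet(X, y01, family = "binomial", alpha = alpha,
                          foldid = foldid, nlambda = 50)
  co <- stats::coef(cv, s = "lambda.min")
  nz <- rownames(co)[which(co[, 1] != 0)]
  nz <- setdiff(nz, "(Intercept)")
  if (length(nz) == 0) {
    fit <- glmnet::glmnet(X, y01, family = "binomial", alpha = alpha,
                          nlambda = 50)
    nzc <- fit$df
    s_ok <- fit$lambda[which(nzc >= 1)[1]]
    if (is.na(s_ok)) return(colnames(X)[1])
    co <- stats::coef(fit, s = s_ok)
    nz <- setdiff(rownames(co)[which(co[, 1] != 0)], "(Intercept)")
  }
  nz
}

# dispatch: returns selected feature names (train data only)
reduce_select <- function(method, X, y, k = NULL, seed = 1L,
                          cfg = pipeline_defaults()) {
  y01 <- as.integer(y == cfg$positive_class)
  ranked <- switch(
    method,
    gini = names(sort(impurity_gain_scores(X, y01, "gini"),
                      decreasing = TRUE)),
    f_ratio = names(sort(f_ratio_scores(X, y01), decreasing = TRUE)),
    info_gain = names(sort(impurity_gain_scores(X, y01, "entropy"),
                           decreasing = TRUE)),
    spearman = names(sort(spearman_scores(X, y01), decreasing = TRUE)),
    mim = names(sort(mim_scores(X, y01), decreasing = TRUE)),
    stir_relief = names(sort(stir_scores(X, y01, cfg$stir_neighbors),
                             decreasing = TRUE)),
    mrmr = mrmr_select(X, y01, k, cfg$mrmr_pool),
    lasso = glmnet_select(X, y01, alpha = 1, seed = seed),
    elasticnet_logistic = glmnet_select(X, y01, alpha = 0.5, seed = seed),
    stop("unknown reducer: ", method)
  )
  if (method %in% c("lasso", "elasticnet_logistic", "mrmr")) return(ranked)
  if (is.null(k)) stop("reducer '", method, "' needs k")
  if (k > ncol(X)) stop("k = ", k, " exceeds available features")
  ranked[seq_len(k)]
}

# ---- resamplers (training data only) --------------------------------------

cross_dist2 <- function(A, B) {
  outer(rowSums(A^2), rowSums(B^2), "+") - 2 * A %*% t(B)
}

knn_of <- function(A, B, k, exclude_self = FALSE) {
  D <- cross_dist2(A, B)
  if (exclude_self) D[cbind(seq_len(nrow(A)), seq_len(nrow(A)))] <- Inf
  t(apply(D, 1, function(d) order(d)[seq_len(k)]))
}

smote_interpolate <- function(Xmin, n_new, k, base_weights = NULL) {
  n <- nrow(Xmin)
  if (n == 1) return(Xmin[rep(1, n_new), , drop = FALSE])
  k <- min(k, n - 1)
  nn <- knn_of(Xmin, Xmin, k, exclude_self = TRUE)
  base <- if (is.null(base_weights)) sample.int(n, n_new, replace = TRUE)
          else sample.int(n, n_new, replace = TRUE, prob = base_weights)
  nb <- nn[cbind(base, sample.int(k, n_new, replace = TRUE))]
  u <- stats::runif(n_new)
  Xmin[base, , drop = FALSE] +
    u * (Xmin[nb, , drop = FALSE] - Xmin[base, , drop = FALSE])
}

tomek_remove <- function(X, y) {
  n <- nrow(X)
  if (n < 2) return(seq_len(n))
  D <- cross_dist2(X, X)
  diag(D) <- Inf
  nn1 <- apply(D, 1, which.min)
  drop <- rep(FALSE, n)
  for (i in seq_len(n)) {
    j <- nn1[i]
    if (nn1[j] == i && y[i] != y[j]) drop[c(i, j)] <- TRUE
  }
  which(!drop)
}

resample_train <- function(method, X, y, seed = 1L,
                           cfg = pipeline_defaults()) {
  if (method == "none") return(list(X = X, y = y))
  withr::local_seed(seed)
  tab <- table(y)
  minority <- names(tab)[which.min(tab)]
  majority <- names(tab)[which.max(tab)]
  if (minority == majority) return(list(X = X, y = y))
  Xmin <- X[y == minority, , drop = FALSE]
  Xmaj <- X[y == majority, , drop = FALSE]
  n_new <- nrow(Xmaj) - nrow(Xmin)
  k <- cfg$smote_k
  if (method %in% c("smote", "smote_tomek")) {
    Xs <- smote_interpolate(Xmin, n_new, k)
    X2 <- rbind(X, Xs)
    y2 <- c(y, rep(minority, n_new))
    if (method == "smote_tomek") {
      keep <- tomek_remove(X2, y2)
      X2 <- X2[keep, , drop = FALSE]
      y2 <- y2[keep]
    }
    return(list(X = X2, y = y2))
  }
  if (method == "adasyn") {
    kk <- min(k, nrow(X) - 1)
    nn <- knn_of(Xmin, X, kk + 1) # first neighbour is the point itself
    r <- vapply(seq_len(nrow(Xmin)), function(i)
      mean(y[nn[i, -1]] == majority), numeric(1))
    w <- if (sum(r) == 0) rep(1, nrow(Xmin)) else r
    Xs <- smote_interpolate(Xmin, n_new, k, base_weights = w)
    return(list(X = rbind(X, Xs), y = c(y, rep(minority, n_new))))
  }
  if (method == "rus") {
    keep_maj <- sample.int(nrow(Xmaj), nrow(Xmin))
    X2 <- rbind(Xmin, Xmaj[keep_maj, , drop = FALSE])
    y2 <- c(rep(minority, nrow(Xmin)), rep(majority, nrow(Xmin)))
    return(list(X = X2, y = y2))
  }
  if (method == "nearmiss") {
    kk <- min(cfg$nearmiss_k, nrow(Xmin))
    D <- cross_dist2(Xmaj, Xmin)
    score <- apply(D, 1, function(d) mean(sort(d)[seq_len(kk)]))
    keep_maj <- order(score)[seq_len(nrow(Xmin))]
    X2 <- rbind(Xmin, Xmaj[keep_maj, , drop = FALSE])
    y2 <- c(rep(minority, nrow(Xmin)), rep(majority, nrow(Xmin)))
    return(list(X = X2, y = y2))
  }
  stop("unknown resampler: ", method)
}

# ---- classifiers ----------------------------------------------------------

# every fit returns list(predict_fn = function(X) list(class, score),
# weights = named w or NULL, intercept); score is the positive-class
# probability or margin

fit_classifier <- function(name, X, y, seed = 1L,
                           cfg = pipeline_defaults()) {
  pos <- cfg$positive_class
  neg <- setdiff(unique(y), pos)[1] %||% "negative"
  yf <- factor(y, levels = c(neg, pos))
  y01 <- as.integer(yf) - 1L
  withr::local_seed(seed)
  switch(
    name,
    svm_linear = {
      fit <- e1071::svm(X, yf, kernel = "linear", scale = FALSE,
                        cost = cfg$svm_cost)
      # orient decision values toward the positive class
      dv_tr <- drop(attr(stats::predict(fit, X, decision.values = TRUE),
                         "decision.values"))
      sgn <- if (stats::cor(dv_tr, y01) >= 0 || is.na(stats::cor(dv_tr, y01)))
        1 else -1
      w <- drop(t(fit$coefs) %*% fit$SV) * sgn
      b <- -fit$rho * sgn
      list(predict_fn = function(Xn) {
        m <- drop(as.matrix(Xn)[, names(w), drop = FALSE] %*% w) + b
        list(class = ifelse(m > 0, pos, neg), score = m)
      }, weights = w, intercept = b, linear = TRUE)
    },
    random_forest = {
      fit <- ranger::ranger(x = X, y = yf, probability = TRUE,
                            num.trees = cfg$rf_trees, seed = seed,
                            num.threads = 1)
      list(predict_fn = function(Xn) {
        p <- stats::predict(fit, data = as.data.frame(Xn),
                            num.threads = 1)$predictions[, pos]
        list(class = ifelse(p > 0.5, pos, neg), score = p)
      }, weights = NULL, linear = FALSE)
    },
    knn = {
      Xtr <- X
      list(predict_fn = function(Xn) {
        set.seed(seed)
        pr <- class::knn(Xtr, as.matrix(Xn)[, colnames(Xtr), drop = FALSE],
                         yf, k = cfg$knn_k, prob = TRUE)
        pw <- attr(pr, "prob")
        score <- ifelse(pr == pos, pw, 1 - pw)
        list(class = as.character(pr), score = score)
      }, weights = NULL, linear = FALSE)
    },
    logreg_l2 = fit_glmnet_clf(X, y01, alpha = 0, pos, neg, cfg),
    logreg_l1 = fit_glmnet_clf(X, y01, alpha = 1, pos, neg, cfg),
    logreg_elasticnet = fit_glmnet_clf(X, y01, alpha = 0.5, pos, neg, cfg),
    adaboost_tree = fit_adaboost(X, yf, pos, neg, cfg, rus = FALSE,
                                 seed = seed),
    rusboost_tree = fit_adaboost(X, yf, pos, neg, cfg, rus = TRUE,
                                 seed = seed),
    gradient_boost = {
      dtr <- xgboost::xgb.DMatrix(X, label = y01, nthread = 1)
      fit <- xgboost::xgb.train(
        params = list(objective = "binary:logistic", eta = 0.3,
                      max_depth = 6, nthread = 1),
        data = dtr, nrounds = cfg$xgb_rounds, verbose = 0)
      list(predict_fn = function(Xn) {
        dn <- xgboost::xgb.DMatrix(
          as.matrix(Xn)[, colnames(X), drop = FALSE], nthread = 1)
        p <- stats::predict(fit, dn)
        list(class = ifelse(p > 0.5, pos, neg), score = p)
      }, weights = NULL, linear = FALSE)
    },
    balanced_bagging_trees = fit_balanced_bagging(X, yf, pos, neg, cfg,
                                                  seed = seed),
    stop("unknown classifier: ", name)
  )
}

fit_glmnet_clf <- function(X, y01, alpha, pos, neg, cfg) {
  lambda <- cfg$logreg_lambda_scale / nrow(X)
  path <- sort(unique(c(lambda * c(100, 10, 1))), decreasing = TRUE)
  fit <- glmnet::glmnet(X, y01, family = "binomial", alpha = alpha,
                        lambda = path)
  co <- stats::coef(fit, s = lambda, exact = FALSE)
  w <- stats::setNames(co[-1, 1], rownames(co)[-1])
  b <- co[1, 1]
  list(predict_fn = function(Xn) {
    m <- drop(as.matrix(Xn)[, names(w), drop = FALSE] %*% w) + b
    list(class = ifelse(m > 0, pos, neg), score = 1 / (1 + exp(-m)))
  }, weights = w, intercept = b, linear = TRUE)
}

fit_adaboost <- function(X, yf, pos, neg, cfg, rus = FALSE, seed = 1L) {
  df <- as.data.frame(X)
  n <- nrow(df)
  w <- rep(1 / n, n)
  stumps <- list()
  alphas <- numeric(0)
  ys <- ifelse(yf == pos, 1, -1)
  ctrl <- rpart::rpart.control(maxdepth = cfg$boost_depth, minsplit = 2,
                               cp = 0, xval = 0, maxcompete = 0,
                               maxsurrogate = 0)
  for (m in seq_len(cfg$boost_rounds)) {
    if (rus) {
      n_min <- min(table(yf))
      idx <- unlist(lapply(levels(yf), function(lv) {
        pool <- which(yf == lv)
        if (length(pool) <= n_min) pool
        else sample(pool, n_min, prob = w[pool])
      }))
      fit <- rpart::rpart(y ~ ., data = cbind(df[idx, , drop = FALSE],
                                              y = yf[idx]),
                          method = "class", control = ctrl)
    } else {
      fit <- rpart::rpart(y ~ ., data = cbind(df, y = yf), weights = w,
                          method = "class", control = ctrl)
    }
    pred <- ifelse(stats::predict(fit, df, type = "class") == pos, 1, -1)
    err <- sum(w[pred != ys]) / sum(w)
    if (err >= 0.5) {
      if (length(stumps) == 0) {
        stumps[[1]] <- fit
        alphas <- 1e-6
      }
      break
    }
    a <- 0.5 * log((1 - err) / max(err, 1e-12))
    stumps[[length(stumps) + 1]] <- fit
    alphas <- c(alphas, a)
    w <- w * exp(-a * ys * pred)
    w <- w / sum(w)
    if (err < 1e-12) break
  }
  list(predict_fn = function(Xn) {
    dn <- as.data.frame(as.matrix(Xn))
    colnames(dn) <- colnames(df)
    m <- numeric(nrow(dn))
    for (k in seq_along(stumps))
      m <- m + alphas[k] *
        ifelse(stats::predict(stumps[[k]], dn, type = "class") == pos,
               1, -1)
    list(class = ifelse(m > 0, pos, neg), score = m)
  }, weights = NULL, linear = FALSE)
}

fit_balanced_bagging <- function(X, yf, pos, neg, cfg, seed = 1L) {
  df <- as.data.frame(X)
  n_min <- min(table(yf))
  ctrl <- rpart::rpart.control(xval = 0, maxcompete = 0, maxsurrogate = 0,
                               cp = 0.01)
  trees <- lapply(seq_len(cfg$bag_rounds), function(b) {
    idx <- unlist(lapply(levels(yf), function(lv)
      sample(which(yf == lv), n_min, replace = TRUE)))
    rpart::rpart(y ~ ., data = cbind(df[idx, , drop = FALSE], y = yf[idx]),
                 method = "class", control = ctrl)
  })
  list(predict_fn = function(Xn) {
    dn <- as.data.frame(as.matrix(Xn))
    colnames(dn) <- colnames(df)
    p <- rowMeans(vapply(trees, function(tr)
      stats::predict(tr, dn, type = "prob")[, pos], numeric(nrow(dn))))
    list(class = ifelse(p > 0.5, pos, neg), score = p)
  }, weights = NULL, linear = FALSE)
}

#' Pinned default parameters of the analysis pipeline
#'
#' Reads the versioned configuration shipped with the package
#' (`inst/config/pipeline-defaults.yaml`); changing a classifier or
#' reducer default is a configuration change, not a code change.
#'
#' @return Named list of defaults.
#' @export
pipeline_defaults <- function() {
  cached <- get0("config", envir = .dscr_cache)
  if (!is.null(cached)) return(cached)
  path <- system.file("config", "pipeline-defaults.yaml",
                      package = "dscradiomics")
  if (!nzchar(path)) path <- "inst/config/pipeline-defaults.yaml"
  cfg <- yaml::read_yaml(path)
  assign("config", cfg, envir = .dscr_cache)
  cfg
}

.dscr_cache <- new.env(parent = emptyenv())
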