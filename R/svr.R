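#' epsilon-SVR hyperparameters
#'
#' @param C positive regularization constant: the price of residuals outside
#'   the epsilon tube.
#' @param epsilon non-negative half-width of the insensitive tube, in
#'   phenotype units.
#' @param kernel a [kernel_spec()].
#' @return An object of class `svr_hyper`.
#' @export
svr_hyper <- function(C, epsilon, kernel) {
  stopifnot(C > 0, epsilon >= 0, inherits(kernel, "kernel_spec"))
  structure(list(C = C, epsilon = epsilon, kernel = kernel),
            class = "svr_hyper")
}

standardize_fit <- function(X) {
  center <- colMeans(X)
  scale <- apply(X, 2, stats::sd)
  scale[scale == 0] <- 1  # constant column on this fold: leave centred at 0
  list(center = center, scale = scale)
}

standardize_apply <- function(X, std) {
  scale(X, center = std$center, scale = std$scale)[, , drop = FALSE]
}

#' Fit an epsilon support vector regression
#'
#' Solves the standard epsilon-SVR dual (box constraints `0 <= alpha,
#' alpha* <= C`, equality `sum(alpha - alpha*) = 0`) for the requested kernel.
#' Feature columns are standardized to zero mean / unit variance using the
#' training data only, then the kernel matrix is precomputed and passed to
#' the sequential-minimal-optimization solver of \pkg{kernlab}. The returned
#' model stores the full dual coefficient vector `beta = alpha - alpha*`
#' (zeros for non-support vectors) and intercept, so predictions are the
#' dual expansion `f(x) = sum_i beta_i K(x_i, x) + b`.
#'
#' @param X numeric matrix, samples x features (e.g. dosages of a SNP group).
#' @param y numeric response.
#' @param hyper an [svr_hyper()].
#' @param standardize standardize columns on the training data (default TRUE).
#' @param tol solver termination tolerance (passed to the SMO optimizer).
#' @return An object of class `svr_model`.
#' @export
fit_svr <- function(X, y, hyper, standardize = TRUE, tol = 1e-4) {
  X <- as.matrix(X)
  stopifnot(nrow(X) >= 2, length(y) == nrow(X), inherits(hyper, "svr_hyper"))
  if (!all(is.finite(X)) || !all(is.finite(y)))
    stop("non-finite values in SVR inputs")
  std <- if (standardize) standardize_fit(X) else
    list(center = rep(0, ncol(X)), scale = rep(1, ncol(X)))
  Xs <- standardize_apply(X, std)
  K <- kernel_matrix(Xs, Xs, hyper$kernel)
  fit <- tryCatch(
    kernlab::ksvm(kernlab::as.kernelMatrix(K), y, type = "eps-svr",
                  C = hyper$C, epsilon = hyper$epsilon, scaled = FALSE,
                  tol = tol),
    error = function(e) {
      # a target fully inside the epsilon tube has no support vectors; the
      # optimum is then the flat function w = 0, b = median(y)
      if (grepl("No Support Vectors", conditionMessage(e))) NULL
      else stop("SVR solver failed: ", conditionMessage(e))
    })
  beta <- numeric(nrow(X))
  b <- if (is.null(fit)) stats::median(y) else -kernlab::b(fit)
  if (!is.null(fit)) beta[kernlab::SVindex(fit)] <- unlist(kernlab::coef(fit))
  structure(list(X_train = Xs, std = std, beta = beta,
                 b = b, hyper = hyper,
                 fitted = drop(K %*% beta) + b),
            class = "svr_model")
}

#' Predict from a fitted epsilon-SVR
#'
#' @param object an `svr_model` from [fit_svr()].
#' @param newdata numeric matrix with the same columns as the training data.
#' @param ... unused.
#' @return Numeric vector of predictions.
#' @export
predict.svr_model <- function(object, newdata, ...) {
  newdata <- as.matrix(newdata)
  Xs <- standardize_apply(newdata, object$std)
  K <- kernel_matrix(Xs, object$X_train, object$hyper$kernel)
  drop(K %*% object$beta) + object$b
}

make_folds <- function(n, k, seed) {
  withr::with_seed(as.integer(seed), {
    idx <- sample.int(n)
  })
  fold <- integer(n)
  fold[idx] <- rep_len(seq_len(k), n)
  fold
}

#' Repeated k-fold cross-validated Pearson correlation
#'
#' For each of `r` repeats the samples are reshuffled (seed + repeat index)
#' and split into `k` folds; out-of-fold predictions for all samples are
#' pooled and ONE Pearson correlation with the observed phenotype is computed
#' per repeat, giving `r` correlation estimates. A repeat whose pooled
#' predictions are constant (degenerate model) is recorded as correlation 0
#' and flagged.
#'
#' @param X numeric matrix, samples x features.
#' @param y numeric response.
#' @param hyper an [svr_hyper()].
#' @param k number of folds (default 10).
#' @param r number of repeats (default 10).
#' @param seed base RNG seed; repeat `i` uses `seed + i`.
#' @param statistic `"pearson"` (default) or `"mse"` for mean squared error
#'   of the pooled out-of-fold predictions.
#' @param per_fold if `TRUE`, additionally return the correlation computed
#'   within each fold separately.
#' @return An object of class `cv_result`: per-repeat values, `mean`, `sd`,
#'   `k`, `r`, `seed`, `degenerate` flags.
#' @export
repeated_cv_correlation <- function(X, y, hyper, k = 10, r = 10, seed = 1L,
                                    statistic = c("pearson", "mse"),
                                    per_fold = FALSE) {
  statistic <- match.arg(statistic)
  X <- as.matrix(X)
  n <- nrow(X)
  stopifnot(n >= 2 * k, length(y) == n)
  vals <- numeric(r)
  degenerate <- logical(r)
  fold_vals <- if (per_fold) vector("list", r) else NULL
  for (i in seq_len(r)) {
    fold <- make_folds(n, k, seed + i)
    pred <- numeric(n)
    for (f in seq_len(k)) {
      test <- fold == f
      m <- fit_svr(X[!test, , drop = FALSE], y[!test], hyper)
      pred[test] <- predict(m, X[test, , drop = FALSE])
    }
    if (statistic == "mse") {
      vals[i] <- mean((pred - y)^2)
    } else if (stats::sd(pred) == 0 || stats::sd(y) == 0) {
      vals[i] <- 0
      degenerate[i] <- TRUE
    } else {
      vals[i] <- stats::cor(pred, y)
    }
    if (per_fold)
      fold_vals[[i]] <- vapply(seq_len(k), function(f) {
        s <- fold == f
        if (stats::sd(pred[s]) == 0 || stats::sd(y[s]) == 0) 0
        else stats::cor(pred[s], y[s])
      }, numeric(1))
  }
  structure(list(values = vals, mean = mean(vals), sd = stats::sd(vals),
                 statistic = statistic, k = k, r = r, seed = seed,
                 degenerate = degenerate, per_fold = fold_vals),
            class = "cv_result")
}

#' @export
print.cv_result <- function(x, ...) {
  cat(sprintf("cv_result (%s, %d-fold x %d): mean %.4f, sd %.4f\n",
              x$statistic, x$k, x$r, x$mean,
              if (is.na(x$sd)) 0 else x$sd))
  invisible(x)
}

#' Default hyperparameter grids
#'
#' `C` and the kernel parameters are absolute; the `epsilon` grid is
#' expressed as fractions of the phenotype standard deviation and scaled at
#' search time.
#'
#' @return Named list of numeric grids (`C`, `epsilon_frac`, `gamma`,
#'   `omega`, `sigma`).
#' @export
default_grids <- function() {
  list(C = c(0.1, 1, 10, 100, 1000),
       epsilon_frac = c(0.001, 0.01, 0.1, 1),
       gamma = 10^seq(-4, 1),
       omega = c(0.5, 1, 2, 4, 8, 16),
       sigma = c(0.25, 0.5, 1, 2, 4, 8))
}

#' Grid search over SVR hyperparameters
#'
#' Evaluates [repeated_cv_correlation()] at every point of the grid for the
#' given kernel family and returns the hyperparameter set with the highest
#' mean correlation; ties are broken by lower standard deviation, then
#' smaller `C`, then grid order.
#'
#' @param X,y design matrix and response.
#' @param family `"linear"`, `"rbf"` or `"puk"`.
#' @param grids named list as in [default_grids()] (only the components the
#'   family needs are used).
#' @param k,r,seed cross-validation settings passed through.
#' @return list(best = [svr_hyper()], cv = best `cv_result`, table =
#'   data.frame of all evaluated points with mean/sd).
#' @export
grid_search <- function(X, y, family = c("linear", "rbf", "puk"),
                        grids = default_grids(), k = 10, r = 10, seed = 1L) {
  family <- match.arg(family)
  eps_grid <- grids$epsilon_frac * stats::sd(y)
  tab <- switch(family,
    linear = expand.grid(C = grids$C, epsilon = eps_grid),
    rbf = expand.grid(C = grids$C, epsilon = eps_grid, gamma = grids$gamma),
    puk = expand.grid(C = grids$C, epsilon = eps_grid,
                      omega = grids$omega, sigma = grids$sigma))
  stopifnot(nrow(tab) >= 1)
  tab$mean <- NA_real_; tab$sd <- NA_real_
  results <- vector("list", nrow(tab))
  for (i in seq_len(nrow(tab))) {
    spec <- switch(family,
                   linear = kernel_spec("linear"),
                   rbf = kernel_spec("rbf", gamma = tab$gamma[i]),
                   puk = kernel_spec("puk", omega = tab$omega[i],
                                     sigma = tab$sigma[i]))
    hy <- svr_hyper(tab$C[i], tab$epsilon[i], spec)
    cv <- repeated_cv_correlation(X, y, hy, k = k, r = r, seed = seed)
    tab$mean[i] <- cv$mean
    tab$sd[i] <- if (is.na(cv$sd)) 0 else cv$sd
    results[[i]] <- list(hyper = hy, cv = cv)
  }
  ord <- order(-tab$mean, tab$sd, tab$C, seq_len(nrow(tab)))
  best <- ord[1]
  list(best = results[[best]]$hyper, cv = results[[best]]$cv, table = tab)
}

#' Choose the best marker group from its cross-validation results
#'
#' The winning group has the maximal mean CV correlation; among groups whose
#' mean is within `tie_tolerance` of the maximum, the one with the fewest
#' SNPs wins (parsimony), remaining ties broken by lower standard deviation
#' and then by lower threshold (earlier group).
#'
#' @param groups a `group_series` from [build_groups()].
#' @param evaluations list of `cv_result`s, one per group (`NULL` allowed for
#'   empty groups).
#' @param tie_tolerance mean-correlation margin treated as a tie
#'   (default 0.005, i.e. two printed decimals).
#' @return list(index, snp_ids, threshold, cv) of the chosen group.
#' @export
select_best_group <- function(groups, evaluations, tie_tolerance = 0.005) {
  stopifnot(inherits(groups, "group_series"),
            length(evaluations) == length(groups$members))
  means <- vapply(evaluations, function(e) if (is.null(e)) -Inf else e$mean,
                  numeric(1))
  sds <- vapply(evaluations, function(e)
    if (is.null(e) || is.na(e$sd)) Inf else e$sd, numeric(1))
  if (all(means == -Inf)) stop("no evaluated (non-empty) groups")
  near <- which(means >= max(means) - tie_tolerance)
  ord <- near[order(groups$sizes[near], sds[near], near)]
  i <- ord[1]
  list(index = i, snp_ids = groups$members[[i]],
       threshold = groups$thresholds[i], cv = evaluations[[i]])
}

#' Evaluate every group of a series with tuned SVR models
#'
#' For each non-empty group and each kernel family: tune hyperparameters by
#' [grid_search()] (with `tune_r` repeats), then evaluate the chosen
#' hyperparameters with the full `k x r` repeated CV. Produces the long-form
#' table (group, threshold, size, family, mean, sd) that mirrors the group
#' evaluation tables of the two-stage workflow.
#'
#' @param G a [genotype_matrix()] (imputed).
#' @param y phenotype vector.
#' @param groups a `group_series`.
#' @param families kernel families to evaluate.
#' @param grids hyperparameter grids ([default_grids()] form).
#' @param k,r folds and repeats of the reported CV.
#' @param tune_r repeats used during tuning (default 1 for speed).
#' @param seed base seed.
#' @return list(table = data.frame, evaluations = list by family of per-group
#'   `cv_result`s, hypers = list by family of per-group [svr_hyper()]s).
#' @export
evaluate_groups <- function(G, y, groups, families = c("linear", "rbf", "puk"),
                            grids = default_grids(), k = 10, r = 10,
                            tune_r = 1, seed = 1L) {
  stopifnot(inherits(G, "genotype_matrix"), inherits(groups, "group_series"))
  rows <- list()
  evaluations <- hypers <- stats::setNames(
    rep(list(vector("list", length(groups$members))), length(families)),
    families)
  for (fam in families) {
    for (gi in seq_along(groups$members)) {
      ids <- groups$members[[gi]]
      if (!length(ids)) next
      Xg <- G$values[, ids, drop = FALSE]
      gs <- grid_search(Xg, y, fam, grids = grids, k = k, r = tune_r,
                        seed = seed)
      cv <- repeated_cv_correlation(Xg, y, gs$best, k = k, r = r, seed = seed)
      evaluations[[fam]][[gi]] <- cv
      hypers[[fam]][[gi]] <- gs$best
      rows[[length(rows) + 1]] <-
        data.frame(group = gi, threshold = groups$thresholds[gi],
                   n_snps = length(ids), family = fam,
                   mean = cv$mean, sd = if (is.na(cv$sd)) 0 else cv$sd)
    }
  }
  list(table = do.call(rbind, rows), evaluations = evaluations,
       hypers = hypers)
}
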