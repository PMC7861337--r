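#' Default hyperparameter grids
#'
#' Grids for the three regression approaches: Elastic Net mixing values
#' 0.1..0.9 with a 100-value regularization path whose smallest/largest
#' ratio is 1e-4; SVR soft margin `C` over powers of two with exponents
#' -3..8 and tolerance `epsilon` with exponents -10..-5 (the kernel width
#' `gamma` is set analytically, see [svr_gamma_heuristic()]); boosted
#' trees over learning rates {0.1, 0.25, 0.5, 1}, 100..550 trees and tree
#' depths 1..log2(S-1).
#'
#' @param model One of `"svr"`, `"elastic_net"`, `"gbt"`; `NULL` returns
#'   all three.
#' @return A named list of grid components.
#' @export
default_grids <- function(model = NULL) {
  g <- list(
    svr = list(cost = 2^(-3:8), epsilon = 2^(-10:-5)),
    elastic_net = list(alpha = seq(0.1, 0.9, by = 0.1), nlambda = 100,
                       lambda_min_ratio = 1e-4),
    gbt = list(eta = c(0.1, 0.25, 0.5, 1), nrounds = seq(100, 550, by = 50),
               max_depth = NULL) # NULL: 1..floor(log2(S-1)) at fit time
  )
  if (is.null(model)) g else g[[model]]
}

derive_seeds <- function(seed, n) {
  set.seed(seed)
  sample.int(2^31 - 2, n)
}

#' Patient-level train/test split with distribution balance check
#'
#' Splits patients (not visits) into train and test sides and re-draws
#' until a two-sided Wilcoxon rank-sum test is non-significant (p >= 0.05)
#' for every feature between the sides, up to `max_attempts` draws.
#'
#' @param features Feature tibble with `patient_id`, `ga_months` and
#'   feature columns.
#' @param test_fraction Fraction of patients assigned to the test side.
#' @param seed Integer seed.
#' @param alpha Significance level of the balance check.
#' @param max_attempts Re-randomization cap.
#' @return List with `train`, `test` (row subsets of `features`),
#'   `attempts` and `min_p` (smallest balance p-value of the accepted
#'   split).
#' @export
split_cohort <- function(features, test_fraction = 0.2, seed = 1,
                         alpha = 0.05, max_attempts = 1000) {
  fn <- intersect(feature_names(), names(features))
  if (length(fn) == 0) fn <- setdiff(names(features),
                                     c("patient_id", "visit_id",
                                       "ga_months", "group"))
  by_month <- split(unique(features[c("patient_id", "ga_months")])$patient_id,
                    unique(features[c("patient_id", "ga_months")])$ga_months)
  if (any(lengths(by_month) < 2)) {
    stop("split_cohort: need at least 2 patients per gestational month",
         call. = FALSE)
  }
  patients <- unique(features$patient_id)
  n_test <- max(1, round(length(patients) * test_fraction))
  seeds <- derive_seeds(seed, max_attempts)
  for (a in seq_len(max_attempts)) {
    set.seed(seeds[a])
    test_p <- sample(patients, n_test)
    tr <- features[!features$patient_id %in% test_p, ]
    te <- features[features$patient_id %in% test_p, ]
    if (length(unique(te$ga_months)) < length(unique(features$ga_months))) {
      next
    }
    p <- vapply(fn, function(f) {
      suppressWarnings(wilcox.test(tr[[f]], te[[f]], exact = FALSE)$p.value)
    }, numeric(1))
    if (all(p >= alpha, na.rm = TRUE)) {
      return(list(train = tr, test = te, attempts = a, min_p = min(p)))
    }
  }
  stop("split_cohort: no balanced split found in ", max_attempts,
       " attempts", call. = FALSE)
}

#' ADASYN oversampling of minority gestational months
#'
#' Adaptive synthetic oversampling: every month is grown to the majority
#' month's count. Each minority point receives a share of synthetic points
#' proportional to the fraction of its k nearest neighbours (over the
#' whole set) belonging to other months — points near class borders are
#' oversampled hardest. A synthetic point is a convex combination
#' `x + u (x' - x)`, `u ~ U(0,1)`, of a real point and one of its k
#' nearest same-month neighbours, so no synthetic point leaves the convex
#' hull of its month.
#'
#' @param x Data frame or matrix of feature rows.
#' @param y Vector of month labels.
#' @param k_neighbors Neighbourhood size.
#' @param seed Integer seed.
#' @return List with `x` (original rows then synthetic rows), `y`,
#'   `synthetic` (logical), `base_index` (index into the original rows of
#'   each output row's seed point).
#' @export
adasyn_oversample <- function(x, y, k_neighbors = 5, seed = 1) {
  x <- as.matrix(x)
  set.seed(seed)
  counts <- table(y)
  if (any(counts < 2)) {
    stop("adasyn_oversample: every month needs at least 2 rows",
         call. = FALSE)
  }
  n_major <- max(counts)
  d <- as.matrix(stats::dist(x))
  new_x <- list(); new_y <- list(); new_base <- list()
  for (cls in names(counts)) {
    g <- counts[[cls]]
    need <- n_major - g
    if (need <= 0) next
    idx <- which(y == cls)
    k <- min(k_neighbors, nrow(x) - 1)
    r <- vapply(idx, function(i) {
      nn <- order(d[i, -i])[seq_len(k)]
      others <- setdiff(seq_len(nrow(x)), i)[nn]
      mean(y[others] != cls)
    }, numeric(1))
    w <- if (sum(r) > 0) r / sum(r) else rep(1 / length(idx), length(idx))
    gi <- floor(w * need)
    rem <- need - sum(gi)
    if (rem > 0) {
      extra <- order(w * need - gi, decreasing = TRUE)[seq_len(rem)]
      gi[extra] <- gi[extra] + 1
    }
    k_same <- min(k_neighbors, g - 1)
    for (j in seq_along(idx)) {
      if (gi[j] == 0) next
      i <- idx[j]
      same <- idx[idx != i]
      nn_same <- same[order(d[i, same])[seq_len(k_same)]]
      for (s in seq_len(gi[j])) {
        z <- if (length(nn_same) == 1) nn_same else sample(nn_same, 1)
        u <- runif(1)
        new_x[[length(new_x) + 1]] <- x[i, ] + u * (x[z, ] - x[i, ])
        new_y[[length(new_y) + 1]] <- y[i]
        new_base[[length(new_base) + 1]] <- i
      }
    }
  }
  n_new <- length(new_x)
  out_x <- rbind(x, if (n_new > 0) do.call(rbind, new_x))
  rownames(out_x) <- NULL
  list(x = out_x,
       y = c(y, unlist(new_y)),
       synthetic = c(rep(FALSE, nrow(x)), rep(TRUE, n_new)),
       base_index = c(seq_len(nrow(x)), unlist(new_base)))
}

#' Standardize features using training statistics only
#'
#' Subtracts the training mean and divides by the training standard
#' deviation, per feature; held-out rows are transformed with the training
#' statistics. Zero-variance training features are dropped with a warning.
#'
#' @param train Matrix/data frame of training rows.
#' @param ... Further row sets to transform with the training statistics.
#' @return List with `train`, the transformed extra sets (in order, named
#'   after the arguments when named), `center` and `scale`.
#' @export
standardize <- function(train, ...) {
  train <- as.matrix(train)
  center <- colMeans(train)
  # population (n-divisor) standard deviation, the usual ML scaler
  scale <- sqrt(colMeans(sweep(train, 2, center)^2))
  drop <- scale == 0 | !is.finite(scale)
  if (any(drop)) {
    warning("standardize: dropping zero-variance feature(s): ",
            paste(colnames(train)[drop], collapse = ", "), call. = FALSE)
    train <- train[, !drop, drop = FALSE]
    center <- center[!drop]
    scale <- scale[!drop]
  }
  tf <- function(m) {
    m <- as.matrix(m)[, names(center), drop = FALSE]
    sweep(sweep(m, 2, center), 2, scale, "/")
  }
  extras <- lapply(list(...), tf)
  c(list(train = tf(train), center = center, scale = scale), extras)
}

# mutual information (bits) of two discrete vectors
discrete_mi <- function(a, b) {
  j <- table(a, b) / length(a)
  pa <- rowSums(j); pb <- colSums(j)
  nz <- j > 0
  sum(j[nz] * log2(j[nz] / outer(pa, pb)[nz]))
}

quantile_bin <- function(v, bins = 4) {
  br <- unique(quantile(v, probs = seq(0, 1, length.out = bins + 1)))
  if (length(br) < 2) return(factor(rep(1, length(v))))
  cut(v, br, include.lowest = TRUE)
}

#' mRMR feature ranking (greedy mutual-information difference)
#'
#' Features are discretized into quartile bins; the first selected feature
#' maximizes mutual information with the month label, and each subsequent
#' feature maximizes relevance minus the mean mutual information with the
#' already-selected set. The full permutation is returned.
#'
#' @param x Data frame/matrix of feature rows.
#' @param y Class labels (gestational months).
#' @param bins Number of quantile bins for discretization.
#' @return Character vector: all feature names in rank order.
#' @export
mrmr_rank <- function(x, y, bins = 4) {
  x <- as.data.frame(x)
  disc <- lapply(x, quantile_bin, bins = bins)
  yf <- factor(y)
  rel <- vapply(disc, discrete_mi, numeric(1), b = yf)
  feats <- names(x)
  selected <- character(0)
  red_cache <- matrix(NA_real_, length(feats), length(feats),
                      dimnames = list(feats, feats))
  remaining <- feats
  while (length(remaining) > 0) {
    if (length(selected) == 0) {
      score <- rel[remaining]
    } else {
      red <- vapply(remaining, function(f) {
        vals <- vapply(selected, function(s) {
          if (is.na(red_cache[f, s])) {
            red_cache[f, s] <<- discrete_mi(disc[[f]], disc[[s]])
            red_cache[s, f] <<- red_cache[f, s]
          }
          red_cache[f, s]
        }, numeric(1))
        mean(vals)
      }, numeric(1))
      score <- rel[remaining] - red
    }
    best <- remaining[which.max(score)]
    selected <- c(selected, best)
    remaining <- setdiff(remaining, best)
  }
  selected
}

#' Gradient-boosted-tree feature ranking
#'
#' Trains a boosted tree ensemble (100 trees, learning rate 1) and ranks
#' features by total split gain across the weak learners. Features never
#' used by the ensemble are ranked after all used ones, in column order.
#'
#' @param x Data frame/matrix of feature rows.
#' @param y Numeric response (gestational months).
#' @param nrounds,eta Ensemble size and learning rate.
#' @return Character vector: all feature names in rank order.
#' @export
gbt_rank <- function(x, y, nrounds = 100, eta = 1) {
  x <- as.matrix(x)
  fit <- xgboost::xgb.train(
    params = list(eta = eta, objective = "reg:squarederror", nthread = 1),
    data = xgboost::xgb.DMatrix(x, label = as.numeric(y), nthread = 1),
    nrounds = nrounds, verbose = 0
  )
  imp <- xgboost::xgb.importance(model = fit)
  used <- as.character(imp$Feature)
  c(used, setdiff(colnames(x), used))
}

#' Analytic kernel-width heuristic for the Gaussian SVR
#'
#' `gamma` is the inverse of the median squared Euclidean distance
#' between points of a seeded 70% subsample of the training rows.
#'
#' @param x Data frame/matrix of training rows.
#' @param seed Integer seed for the subsample.
#' @param subsample Fraction of rows used.
#' @return `gamma` > 0.
#' @export
svr_gamma_heuristic <- function(x, seed = 1, subsample = 0.7) {
  x <- as.matrix(x)
  set.seed(seed)
  n <- nrow(x)
  m <- max(2, round(subsample * n))
  idx <- sample.int(n, m)
  d2 <- stats::dist(x[idx, , drop = FALSE])^2
  med <- median(d2)
  if (!is.finite(med) || med <= 0) {
    stop("svr_gamma_heuristic: degenerate (zero) pairwise distances",
         call. = FALSE)
  }
  1 / med
}

#' Random patient-grouped fold assignment
#'
#' @param patient_ids Vector of patient ids, one per visit row.
#' @param folds Number of folds.
#' @param seed Integer seed.
#' @return Integer fold label per row; all rows of a patient share one
#'   fold.
#' @export
make_grouped_folds <- function(patient_ids, folds = 5, seed = 1) {
  set.seed(seed)
  patients <- unique(patient_ids)
  f <- rep(seq_len(folds), length.out = length(patients))
  f <- f[sample.int(length(patients))]
  names(f) <- patients
  unname(f[as.character(patient_ids)])
}

# ---- model fitting internals ------------------------------------------------

fit_predict_svr <- function(x_tr, y_tr, x_te, cost, epsilon, gamma) {
  fit <- e1071::svm(x = x_tr, y = y_tr, type = "eps-regression",
                    kernel = "radial", gamma = gamma, cost = cost,
                    epsilon = epsilon, scale = FALSE)
  as.numeric(predict(fit, x_te))
}

grid_search_svr <- function(x, y, groups, grid, inner_folds = 3, seed = 1) {
  gamma <- svr_gamma_heuristic(x, seed)
  fold <- make_grouped_folds(groups, inner_folds, seed)
  combos <- expand.grid(cost = grid$cost, epsilon = grid$epsilon)
  mae <- vapply(seq_len(nrow(combos)), function(i) {
    errs <- numeric(0)
    for (f in seq_len(inner_folds)) {
      tr <- fold != f
      if (all(tr) || !any(tr)) next
      pred <- fit_predict_svr(x[tr, , drop = FALSE], y[tr],
                              x[!tr, , drop = FALSE],
                              combos$cost[i], combos$epsilon[i], gamma)
      errs <- c(errs, abs(pred - y[!tr]))
    }
    mean(errs)
  }, numeric(1))
  best <- which.min(mae)
  list(cost = combos$cost[best], epsilon = combos$epsilon[best],
       gamma = gamma)
}

grid_search_enet <- function(x, y, groups, grid, inner_folds = 3, seed = 1) {
  fold <- make_grouped_folds(groups, inner_folds, seed)
  best <- list(mae = Inf)
  for (alpha in grid$alpha) {
    ref <- glmnet::glmnet(x, y, alpha = alpha, nlambda = grid$nlambda,
                          lambda.min.ratio = grid$lambda_min_ratio)
    lam <- ref$lambda
    err <- matrix(NA_real_, 0, length(lam))
    for (f in seq_len(inner_folds)) {
      tr <- fold != f
      if (all(tr) || !any(tr)) next
      fit <- glmnet::glmnet(x[tr, , drop = FALSE], y[tr], alpha = alpha,
                            lambda = lam)
      pred <- predict(fit, x[!tr, , drop = FALSE], s = lam)
      err <- rbind(err, abs(pred - y[!tr]))
    }
    mae <- colMeans(err)
    i <- which.min(mae)
    if (mae[i] < best$mae) {
      best <- list(mae = mae[i], alpha = alpha, lambda = lam[i])
    }
  }
  best[c("alpha", "lambda")]
}

grid_search_gbt <- function(x, y, groups, grid, inner_folds = 3, seed = 1) {
  fold <- make_grouped_folds(groups, inner_folds, seed)
  depths <- grid$max_depth
  if (is.null(depths)) {
    depths <- seq_len(max(1, floor(log2(nrow(x) - 1))))
  }
  combos <- expand.grid(eta = grid$eta, max_depth = depths)
  nr_max <- max(grid$nrounds)
  best <- list(mae = Inf)
  for (i in seq_len(nrow(combos))) {
    err <- matrix(0, length(grid$nrounds), 2) # sum abs err, count
    for (f in seq_len(inner_folds)) {
      tr <- fold != f
      if (all(tr) || !any(tr)) next
      fit <- xgboost::xgb.train(
        params = list(eta = combos$eta[i], max_depth = combos$max_depth[i],
                      objective = "reg:squarederror", nthread = 1),
        data = xgboost::xgb.DMatrix(x[tr, , drop = FALSE], label = y[tr],
                                    nthread = 1),
        nrounds = nr_max, verbose = 0
      )
      for (j in seq_along(grid$nrounds)) {
        pred <- predict(fit, xgboost::xgb.DMatrix(x[!tr, , drop = FALSE],
                                                  nthread = 1),
                        iterationrange = c(1, grid$nrounds[j]))
        err[j, 1] <- err[j, 1] + sum(abs(pred - y[!tr]))
        err[j, 2] <- err[j, 2] + sum(!tr)
      }
    }
    mae <- err[, 1] / pmax(err[, 2], 1)
    j <- which.min(mae)
    if (mae[j] < best$mae) {
      best <- list(mae = mae[j], eta = combos$eta[i],
                   max_depth = combos$max_depth[i],
                   nrounds = grid$nrounds[j])
    }
  }
  best[c("eta", "max_depth", "nrounds")]
}

fit_predict_model <- function(model, x_tr, y_tr, x_te, pars) {
  switch(model,
    svr = fit_predict_svr(x_tr, y_tr, x_te, pars$cost, pars$epsilon,
                          pars$gamma),
    elastic_net = {
      fit <- glmnet::glmnet(x_tr, y_tr, alpha = pars$alpha,
                            lambda = pars$lambda)
      as.numeric(predict(fit, x_te, s = pars$lambda))
    },
    gbt = {
      fit <- xgboost::xgb.train(
        params = list(eta = pars$eta, max_depth = pars$max_depth,
                      objective = "reg:squarederror", nthread = 1),
        data = xgboost::xgb.DMatrix(x_tr, label = y_tr, nthread = 1),
        nrounds = pars$nrounds, verbose = 0
      )
      as.numeric(predict(fit, xgboost::xgb.DMatrix(x_te, nthread = 1)))
    },
    stop("unknown model: ", model, call. = FALSE)
  )
}

tune_model <- function(model, x, y, groups, grid, inner_folds, seed) {
  switch(model,
    svr = grid_search_svr(x, y, groups, grid, inner_folds, seed),
    elastic_net = grid_search_enet(x, y, groups, grid, inner_folds, seed),
    gbt = grid_search_gbt(x, y, groups, grid, inner_folds, seed)
  )
}

# A gestational month represented by a single visit in a training subset
# cannot seed ADASYN interpolation; duplicate such rows before balancing
# (the duplicate is inside the month's convex hull by definition).
expand_singleton_months <- function(rows, y) {
  counts <- table(y)
  singles <- names(counts)[counts == 1]
  if (length(singles) == 0) return(rows)
  c(rows, rows[y %in% singles])
}

# rank-order (binomial) confidence interval for the median
median_ci <- function(x, conf = 0.95) {
  x <- sort(x)
  n <- length(x)
  if (n < 3) return(c(lci = min(x), uci = max(x)))
  a <- (1 - conf) / 2
  lo <- stats::qbinom(a, n, 0.5)
  hi <- stats::qbinom(1 - a, n, 0.5) + 1
  c(lci = x[max(1, lo)], uci = x[min(n, hi)])
}

summarize_mae <- function(per_trial) {
  per_trial |>
    dplyr::group_by(.data$month) |>
    dplyr::summarise(
      median = median(.data$mae),
      iqr = stats::IQR(.data$mae),
      lci = median_ci(.data$mae)[["lci"]],
      uci = median_ci(.data$mae)[["uci"]],
      .groups = "drop"
    )
}

#' Repeated patient-grouped cross-validation of a GA regressor
#'
#' Runs `trials` repetitions of patient-grouped `folds`-fold
#' cross-validation. Within each iteration the training folds are balanced
#' with [adasyn_oversample()], standardized with balanced-training
#' statistics, a feature ranking is recorded (mRMR for the SVR, split-gain
#' for the boosted trees), hyperparameters are tuned by a nested grouped
#' grid search, and the held-out fold is predicted. Mean absolute errors
#' (months) are accumulated per trial and gestational month.
#'
#' @param features Tibble with `patient_id`, `ga_months` and feature
#'   columns.
#' @param model `"svr"`, `"elastic_net"` or `"gbt"`.
#' @param trials,folds Repetition and fold counts.
#' @param seed Master seed; all trial/fold seeds derive from it.
#' @param grid Hyperparameter grid (see [default_grids()]).
#' @param feature_set Optional subset of feature columns to use.
#' @param ranking `"mrmr"`, `"gbt"` or `"none"`; default follows the
#'   model (mRMR for SVR, split-gain for GBT, none for Elastic Net).
#' @param inner_folds Folds of the nested grid-search CV.
#' @param k_neighbors ADASYN neighbourhood size.
#' @return A `fetal_cv` object: list with `summary` (per-month and overall
#'   median/IQR/CI of MAE), `per_trial`, `errors`, `rank_table`
#'   (trial x fold feature rankings), `model`, `feature_set`.
#' @export
run_repeated_cv <- function(features, model = c("svr", "elastic_net", "gbt"),
                            trials = 50, folds = 5, seed = 1,
                            grid = NULL, feature_set = NULL,
                            ranking = NULL, inner_folds = 3,
                            k_neighbors = 5) {
  model <- match.arg(model)
  if (is.null(grid)) grid <- default_grids(model)
  if (is.null(ranking)) {
    ranking <- switch(model, svr = "mrmr", gbt = "gbt",
                      elastic_net = "none")
  }
  fn <- feature_set %||% intersect(feature_names(), names(features))
  if (length(fn) == 0) {
    fn <- setdiff(names(features),
                  c("patient_id", "visit_id", "ga_months", "group"))
  }
  x_all <- as.matrix(features[fn])
  y_all <- features$ga_months
  pid <- features$patient_id
  seeds <- derive_seeds(seed, trials)
  errors <- list(); ranks <- list()
  for (tr in seq_len(trials)) {
    fold <- make_grouped_folds(pid, folds, seeds[tr])
    it_seeds <- derive_seeds(seeds[tr], folds)
    for (f in seq_len(folds)) {
      in_tr <- fold != f
      tr_rows <- expand_singleton_months(which(in_tr), y_all[in_tr])
      bal <- adasyn_oversample(x_all[tr_rows, , drop = FALSE], y_all[tr_rows],
                               k_neighbors, it_seeds[f])
      std <- standardize(bal$x, held = x_all[!in_tr, , drop = FALSE])
      groups_bal <- pid[tr_rows][bal$base_index]
      if (ranking != "none") {
        rk <- if (ranking == "mrmr") {
          mrmr_rank(std$train, bal$y)
        } else {
          gbt_rank(std$train, bal$y)
        }
        ranks[[length(ranks) + 1]] <-
          tibble(trial = tr, fold = f, feature = rk,
                 rank = seq_along(rk))
      }
      pars <- tune_model(model, std$train, as.numeric(bal$y), groups_bal,
                         grid, inner_folds, it_seeds[f])
      pred <- fit_predict_model(model, std$train, as.numeric(bal$y),
                                std$held, pars)
      errors[[length(errors) + 1]] <- tibble(
        trial = tr, fold = f,
        patient_id = pid[!in_tr],
        month = y_all[!in_tr],
        abs_error = abs(pred - y_all[!in_tr])
      )
    }
  }
  errors <- dplyr::bind_rows(errors)
  per_trial <- dplyr::bind_rows(
    errors |>
      dplyr::group_by(.data$trial, month = as.character(.data$month)) |>
      dplyr::summarise(mae = mean(.data$abs_error), .groups = "drop"),
    errors |>
      dplyr::group_by(.data$trial) |>
      dplyr::summarise(mae = mean(.data$abs_error), .groups = "drop") |>
      dplyr::mutate(month = "all")
  ) |>
    dplyr::mutate(month = as.character(.data$month))
  out <- list(summary = summarize_mae(per_trial),
              per_trial = per_trial, errors = errors,
              rank_table = dplyr::bind_rows(ranks),
              model = model, feature_set = fn,
              trials = trials, folds = folds, seed = seed)
  class(out) <- "fetal_cv"
  out
}

#' @export
print.fetal_cv <- function(x, ...) {
  cat(sprintf("<fetal_cv: %s, %d trials x %d folds>\n",
              x$model, x$trials, x$folds))
  print(x$summary)
  invisible(x)
}

#' @rdname run_repeated_cv
#' @param x A `fetal_cv` object.
#' @param ... Unused.
#' @export
tidy.fetal_cv <- function(x, ...) x$summary

#' @rdname run_repeated_cv
#' @export
glance.fetal_cv <- function(x, ...) {
  ov <- x$summary[x$summary$month == "all", ]
  tibble(model = x$model, trials = x$trials, folds = x$folds,
         mae_median = ov$median, mae_iqr = ov$iqr,
         mae_lci = ov$lci, mae_uci = ov$uci)
}

#' Aggregate per-iteration feature rankings into top-k sets
#'
#' Mean rank per feature over all recorded rankings; top-k sets are the k
#' smallest mean ranks with ties broken by canonical feature order.
#'
#' @param rank_table Tibble (`trial`, `fold`, `feature`, `rank`) from
#'   [run_repeated_cv()].
#' @param k Vector of set sizes.
#' @return List with `mean_ranks` (tibble, ordered) and `top_k` (named
#'   list of character vectors).
#' @export
aggregate_feature_ranks <- function(rank_table, k = c(10, 15, 20)) {
  stopifnot(nrow(rank_table) > 0)
  canon <- union(feature_names(), unique(rank_table$feature))
  mr <- rank_table |>
    dplyr::group_by(.data$feature) |>
    dplyr::summarise(mean_rank = mean(.data$rank), .groups = "drop") |>
    dplyr::mutate(canon_order = match(.data$feature, canon)) |>
    dplyr::arrange(.data$mean_rank, .data$canon_order) |>
    dplyr::select(-"canon_order")
  top <- lapply(k, function(kk) mr$feature[seq_len(min(kk, nrow(mr)))])
  names(top) <- paste0("top", k)
  list(mean_ranks = mr, top_k = top)
}

#' Train the final model and test it repeatedly
#'
#' Re-balances the training set with a fresh ADASYN draw each repetition,
#' standardizes with balanced-training statistics, fits a grid-searched
#' model and predicts every test visit. The per-visit median estimate over
#' repetitions feeds the growth-restriction screening stage.
#'
#' @param train_features,test_features Tibbles with `patient_id`,
#'   `ga_months`, feature columns; `test_features` may carry a `group`
#'   column (e.g. NBW/LBW) and a `visit_id`.
#' @param feature_set Feature names to use (subset of the panel).
#' @param model Regressor (default SVR, the study's selected model).
#' @param repetitions Number of ADASYN/testing repetitions.
#' @param seed Master seed.
#' @param grid Hyperparameter grid.
#' @param inner_folds Nested grid-search folds.
#' @param tune_once If `TRUE`, hyperparameters are tuned on the first
#'   balanced draw and reused across repetitions.
#' @param k_neighbors ADASYN neighbourhood size.
#' @return A `fetal_test` object: `estimates` (per repetition x visit),
#'   `per_visit` (median estimate and error), `per_rep` (per-repetition
#'   MAE by group and month), `summary` (median/IQR/CI by group and
#'   month).
#' @export
train_final_and_test <- function(train_features, test_features, feature_set,
                                 model = "svr", repetitions = 100, seed = 1,
                                 grid = NULL, inner_folds = 3,
                                 tune_once = FALSE, k_neighbors = 5) {
  if (is.null(grid)) grid <- default_grids(model)
  stopifnot(all(feature_set %in% names(train_features)),
            all(feature_set %in% names(test_features)))
  x_tr <- as.matrix(train_features[feature_set])
  y_tr <- train_features$ga_months
  pid_tr <- train_features$patient_id
  x_te <- as.matrix(test_features[feature_set])
  te_meta <- tibble(
    visit_id = if ("visit_id" %in% names(test_features)) {
      test_features$visit_id
    } else paste0("visit", seq_len(nrow(test_features))),
    patient_id = test_features$patient_id,
    ga_months = test_features$ga_months,
    group = if ("group" %in% names(test_features)) {
      test_features$group
    } else rep("test", nrow(test_features))
  )
  seeds <- derive_seeds(seed, repetitions)
  pars <- NULL
  est <- list()
  tr_rows <- expand_singleton_months(seq_len(nrow(x_tr)), y_tr)
  for (r in seq_len(repetitions)) {
    bal <- adasyn_oversample(x_tr[tr_rows, , drop = FALSE], y_tr[tr_rows],
                             k_neighbors, seeds[r])
    std <- standardize(bal$x, held = x_te)
    groups_bal <- pid_tr[tr_rows][bal$base_index]
    if (is.null(pars) || !tune_once) {
      pars <- tune_model(model, std$train, as.numeric(bal$y), groups_bal,
                         grid, inner_folds, seeds[r])
    }
    pred <- fit_predict_model(model, std$train, as.numeric(bal$y),
                              std$held, pars)
    est[[r]] <- dplyr::bind_cols(te_meta,
                                 tibble(rep = r, estimate = pred))
  }
  estimates <- dplyr::bind_rows(est)
  per_visit <- estimates |>
    dplyr::group_by(.data$visit_id, .data$patient_id, .data$ga_months,
                    .data$group) |>
    dplyr::summarise(estimate = median(.data$estimate), .groups = "drop") |>
    dplyr::mutate(abs_error = abs(.data$estimate - .data$ga_months))
  per_rep <- dplyr::bind_rows(
    estimates |>
      dplyr::group_by(.data$rep, .data$group,
                      month = as.character(.data$ga_months)) |>
      dplyr::summarise(mae = mean(abs(.data$estimate - .data$ga_months)),
                       .groups = "drop"),
    estimates |>
      dplyr::group_by(.data$rep, .data$group) |>
      dplyr::summarise(mae = mean(abs(.data$estimate - .data$ga_months)),
                       .groups = "drop") |>
      dplyr::mutate(month = "all")
  )
  summary <- per_rep |>
    dplyr::group_by(.data$group, .data$month) |>
    dplyr::summarise(
      median = median(.data$mae),
      iqr = stats::IQR(.data$mae),
      lci = median_ci(.data$mae)[["lci"]],
      uci = median_ci(.data$mae)[["uci"]],
      .groups = "drop"
    )
  out <- list(estimates = estimates, per_visit = per_visit,
              per_rep = per_rep, summary = summary, model = model,
              feature_set = feature_set, repetitions = repetitions,
              seed = seed)
  class(out) <- "fetal_test"
  out
}

#' @export
print.fetal_test <- function(x, ...) {
  cat(sprintf("<fetal_test: %s, %d repetitions, %d visits>\n",
              x$model, x$repetitions, nrow(x$per_visit)))
  print(x$summary)
  invisible(x)
}

#' @rdname train_final_and_test
#' @param x A `fetal_test` object.
#' @param ... Unused.
#' @export
tidy.fetal_test <- function(x, ...) x$summary

#' @rdname train_final_and_test
#' @export
glance.fetal_test <- function(x, ...) {
  ov <- x$summary[x$summary$month == "all", ]
  tidyr::pivot_wider(ov[c("group", "median")], names_from = "group",
                     values_from = "median", names_prefix = "mae_") |>
    dplyr::mutate(model = x$model, repetitions = x$repetitions)
}

#' Pearson screening of features against gestational age
#'
#' Pearson correlation and two-sided p-value of every feature with the
#' gestational month, overall and within each birth-weight group.
#'
#' @param features Tibble with `ga_months`, feature columns and optionally
#'   a `group` column.
#' @return Tibble `feature`, `group` (`"overall"` plus group levels),
#'   `r`, `p_value`, `n`. Zero-variance features report `NA`.
#' @export
pearson_screen <- function(features) {
  fn <- intersect(feature_names(), names(features))
  if (length(fn) == 0) {
    fn <- setdiff(names(features),
                  c("patient_id", "visit_id", "ga_months", "group"))
  }
  sets <- list(overall = features)
  if ("group" %in% names(features)) {
    sets <- c(sets, split(features, features$group))
  }
  purrr::imap(sets, function(df, nm) {
    purrr::map(fn, function(f) {
      v <- df[[f]]
      if (length(v) < 3 || sd(v) == 0 || sd(df$ga_months) == 0) {
        return(tibble(feature = f, group = nm, r = NA_real_,
                      p_value = NA_real_, n = length(v)))
      }
      ct <- cor.test(v, df$ga_months)
      tibble(feature = f, group = nm, r = unname(ct$estimate),
             p_value = ct$p.value, n = length(v))
    }) |> dplyr::bind_rows()
  }) |> dplyr::bind_rows()
}

#' Two-sided rank-sum comparison of two error samples
#'
#' Exact Wilcoxon rank-sum test for small samples (< 20 combined), normal
#' approximation otherwise.
#'
#' @param errors_a,errors_b Numeric samples (e.g. per-visit absolute GA
#'   errors of the NBW and LBW groups).
#' @return Two-sided p-value.
#' @export
compare_group_errors <- function(errors_a, errors_b) {
  stopifnot(length(errors_a) > 0, length(errors_b) > 0)
  exact <- length(errors_a) + length(errors_b) < 20
  suppressWarnings(
    wilcox.test(errors_a, errors_b, exact = exact)$p.value
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a
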