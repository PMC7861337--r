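make_toy_features <- function(n = 80, seed = 9, informative = TRUE) {
  set.seed(seed)
  ft <- tibble::tibble(
    patient_id = sprintf("P%03d", seq_len(n)),
    ga_months = sample(6:9, n, replace = TRUE)
  )
  ft$f1 <- if (informative) ft$ga_months + rnorm(n, 0, 0.1) else rnorm(n)
  for (j in 2:6) ft[[paste0("f", j)]] <- rnorm(n)
  ft
}

test_that("cohort split is patient-disjoint, balanced and reproducible", {
  ft <- make_toy_features(100, seed = 1)
  sp <- split_cohort(ft, test_fraction = 0.25, seed = 3)
  expect_length(intersect(sp$train$patient_id, sp$test$patient_id), 0)
  expect_gte(sp$min_p, 0.05)
  sp2 <- split_cohort(ft, test_fraction = 0.25, seed = 3)
  expect_identical(sp$test$patient_id, sp2$test$patient_id)
  # identical distributions by construction: accepted within a few draws
  # (each feature's null Wilcoxon still rejects at rate alpha)
  acc <- vapply(1:20, function(s) {
    split_cohort(ft, 0.25, seed = s)$attempts <= 3
  }, logical(1))
  expect_gte(mean(acc), 0.9)
  # single patient in a month is an error
  ft1 <- ft[ft$ga_months != 6 | ft$patient_id == ft$patient_id[
    which(ft$ga_months == 6)[1]], ]
  expect_error(split_cohort(ft1, 0.25, seed = 1), "2 patients per")
})

test_that("ADASYN balances counts with convex-hull synthetic rows", {
  set.seed(7)
  x <- matrix(rnorm(16), 8, 2)
  y <- c(rep(6, 2), rep(9, 6))
  bal <- adasyn_oversample(x, y, k_neighbors = 3, seed = 1)
  expect_equal(sum(bal$y == 6), 6)
  expect_equal(sum(bal$y == 9), 6)
  expect_equal(sum(bal$synthetic), 4)
  # convex combination of two month-6 rows: affine coefficient in [0, 1]
  m6 <- x[y == 6, ]
  for (i in which(bal$synthetic)) {
    s <- bal$x[i, ]
    lam <- (s[1] - m6[2, 1]) / (m6[1, 1] - m6[2, 1])
    expect_gte(lam, -1e-9)
    expect_lte(lam, 1 + 1e-9)
    expect_equal(s[2], lam * m6[1, 2] + (1 - lam) * m6[2, 2],
                 tolerance = 1e-9)
  }
  expect_identical(adasyn_oversample(x, y, 3, seed = 5)$x,
                   adasyn_oversample(x, y, 3, seed = 5)$x)
  expect_error(adasyn_oversample(x, c(6, rep(9, 7)), 3, 1), "at least 2")
})

test_that("ADASYN contracts hold over many seeded draws", {
  for (s in 1:100) {
    set.seed(s)
    n6 <- sample(2:5, 1); n7 <- sample(2:8, 1); n9 <- sample(8:12, 1)
    x <- matrix(rnorm((n6 + n7 + n9) * 3), ncol = 3)
    y <- c(rep(6, n6), rep(7, n7), rep(9, n9))
    bal <- adasyn_oversample(x, y, k_neighbors = 5, seed = s)
    expect_true(all(table(bal$y) == max(table(y))))
    # synthetic rows stay inside the bounding box of their month (hull
    # projection onto each axis)
    for (cls in unique(y)) {
      syn <- bal$x[bal$synthetic & bal$y == cls, , drop = FALSE]
      if (nrow(syn) == 0) next
      real <- x[y == cls, , drop = FALSE]
      for (j in 1:3) {
        expect_gte(min(syn[, j]), min(real[, j]) - 1e-9)
        expect_lte(max(syn[, j]), max(real[, j]) + 1e-9)
      }
    }
  }
})

test_that("standardization uses training statistics only", {
  tr <- matrix(c(0, 2, 0, 2), 2)
  colnames(tr) <- c("a", "b")
  out <- standardize(tr, held = matrix(c(1, 1), 1,
                                       dimnames = list(NULL, c("a", "b"))))
  expect_equal(as.numeric(out$train), c(-1, 1, -1, 1))
  expect_equal(as.numeric(out$held), c(0, 0)) # equals train mean -> 0
  set.seed(1)
  big <- matrix(rnorm(200), 20)
  colnames(big) <- paste0("f", 1:10)
  s <- standardize(big)
  pop_sd <- function(v) sqrt(mean((v - mean(v))^2))
  expect_lt(max(abs(colMeans(s$train))), 1e-10)
  expect_lt(max(abs(apply(s$train, 2, pop_sd) - 1)), 1e-10)
  # zero-variance feature dropped with warning
  big2 <- cbind(big, const = 1)
  expect_warning(s2 <- standardize(big2), "zero-variance")
  expect_false("const" %in% colnames(s2$train))
})

test_that("mRMR ranks a near-copy of the label first, duplicates late", {
  hits <- 0
  for (s in 1:100) {
    set.seed(s)
    n <- 60
    y <- sample(6:9, n, replace = TRUE)
    x <- as.data.frame(matrix(rnorm(n * 10), n))
    x$sig <- y + rnorm(n, 0, 0.05)
    if (mrmr_rank(x, y)[1] == "sig") hits <- hits + 1
  }
  expect_gte(hits, 95)
  # duplicated informative feature is pushed behind independent signal
  set.seed(3)
  n <- 80
  y <- sample(6:9, n, replace = TRUE)
  x <- data.frame(a = y + rnorm(n, 0, 0.1), b = -y + rnorm(n, 0, 0.1),
                  c = y^2 + rnorm(n, 0, 0.1))
  x$a_copy <- x$a + rnorm(n, 0, 1e-6)
  rk <- mrmr_rank(x, y)
  expect_identical(rk[1], "a")
  expect_gt(match("a_copy", rk), 2)
  # permutation of all features
  expect_setequal(rk, names(x))
})

test_that("boosted-tree ranking tracks real signal", {
  set.seed(4)
  n <- 80
  y <- sample(6:9, n, replace = TRUE)
  x <- matrix(rnorm(n * 5), n)
  colnames(x) <- paste0("f", 1:5)
  x[, "f3"] <- y + rnorm(n, 0, 0.1)
  expect_identical(gbt_rank(x, y)[1], "f3")
  # permuting the signal column destroys its rank
  x2 <- x
  x2[, "f3"] <- sample(x2[, "f3"])
  expect_false(identical(gbt_rank(x2, y)[1], "f3"))
  # row order does not matter
  p <- sample(n)
  expect_identical(gbt_rank(x[p, ], y[p]), gbt_rank(x, y))
})

test_that("gamma heuristic inverts the median squared distance", {
  expect_equal(svr_gamma_heuristic(rbind(c(0, 0), c(1, 1)), seed = 1), 0.5)
  set.seed(2)
  x <- matrix(rnorm(60), 20)
  expect_equal(svr_gamma_heuristic(3 * x, 1),
               svr_gamma_heuristic(x, 1) / 9, tolerance = 1e-12)
  expect_error(svr_gamma_heuristic(matrix(1, 5, 2), 1), "degenerate")
})

test_that("grouped folds never leak a patient across folds", {
  ft <- cohort_fixture()$features
  pid <- ft$patient_id
  for (s in 1:50) {
    f <- make_grouped_folds(pid, folds = 5, seed = s)
    expect_equal(length(f), length(pid))
    leak <- tapply(f, pid, function(v) length(unique(v)))
    expect_true(all(leak == 1))
  }
})

test_that("elastic net path starts at the null model", {
  set.seed(5)
  x <- scale(matrix(rnorm(500), 100))
  y <- x[, 1] + rnorm(100, 0, 0.5)
  fit <- glmnet::glmnet(x, y, alpha = 0.5, nlambda = 100,
                        lambda.min.ratio = 1e-4)
  expect_true(all(abs(coef(fit)[-1, 1]) < 1e-12))
  # smallest penalty: training MSE below the null model's
  pred <- predict(fit, x, s = min(fit$lambda))
  expect_lt(mean((y - pred)^2), mean((y - mean(y))^2))
})

test_that("standardized SVR pipeline is invariant to affine feature scaling", {
  ft <- make_toy_features(60, seed = 6)
  fn <- paste0("f", 1:6)
  x <- as.matrix(ft[fn])
  x2 <- sweep(sweep(x, 2, c(2, 0.5, 3, 1, 4, 0.1), "*"), 2, 1:6, "+")
  s1 <- standardize(x)$train
  s2 <- standardize(x2)$train
  expect_equal(s1, s2, tolerance = 1e-9)
  g1 <- svr_gamma_heuristic(s1, 1)
  p1 <- fetalga:::fit_predict_svr(s1, ft$ga_months, s1, 4, 0.01, g1)
  p2 <- fetalga:::fit_predict_svr(s2, ft$ga_months, s2, 4, 0.01,
                                  svr_gamma_heuristic(s2, 1))
  expect_equal(p1, p2, tolerance = 1e-6)
})

test_that("repeated CV recovers a perfect noise-free signal", {
  set.seed(9)
  n <- 120
  ft <- tibble::tibble(patient_id = sprintf("P%03d", 1:n),
                       ga_months = sample(6:9, n, replace = TRUE))
  ft$f1 <- ft$ga_months
  ft$f2 <- 2 * ft$ga_months + 1
  ft$f3 <- ft$ga_months^2
  grid <- list(cost = 2^seq(-1, 7, by = 2), epsilon = 2^c(-10, -8, -6))
  cv <- run_repeated_cv(ft, "svr", trials = 2, folds = 5, seed = 1,
                        grid = grid)
  expect_lte(cv$summary$median[cv$summary$month == "all"], 0.1)
  # determinism of the full procedure
  cv2 <- run_repeated_cv(ft, "svr", trials = 2, folds = 5, seed = 1,
                         grid = grid)
  expect_identical(cv$errors, cv2$errors)
})

test_that("rank aggregation averages, tie-breaks and tops-k correctly", {
  rt <- tibble::tibble(
    trial = rep(1:2, each = 3), fold = 1,
    feature = c("a", "b", "c", "a", "c", "b"),
    rank = c(1, 2, 3, 1, 2, 3)
  )
  agg <- aggregate_feature_ranks(rt, k = c(1, 2))
  expect_identical(agg$mean_ranks$feature[1], "a")
  expect_equal(agg$mean_ranks$mean_rank[1], 1)
  expect_identical(agg$top_k$top1, "a")
  # b and c tie at 2.5: canonical (here insertion) order decides, stably
  expect_identical(agg$top_k$top2, c("a", "b"))
  # permuting ranking order changes nothing
  agg2 <- aggregate_feature_ranks(rt[sample(nrow(rt)), ], k = c(1, 2))
  expect_identical(agg$mean_ranks, agg2$mean_ranks)
})

test_that("final training and repeated testing is reproducible", {
  ft <- make_toy_features(70, seed = 12)
  sp <- split_cohort(ft, 0.25, seed = 2)
  grid <- test_grid_svr()
  t1 <- train_final_and_test(sp$train, sp$test, paste0("f", 1:6),
                             repetitions = 5, seed = 4, grid = grid,
                             tune_once = TRUE)
  t2 <- train_final_and_test(sp$train, sp$test, paste0("f", 1:6),
                             repetitions = 5, seed = 4, grid = grid,
                             tune_once = TRUE)
  expect_identical(t1$estimates, t2$estimates)
  expect_equal(nrow(t1$per_visit), nrow(sp$test))
  expect_equal(max(t1$estimates$rep), 5)
})

test_that("Pearson screen flags exact linear relations", {
  ft <- make_toy_features(50, seed = 8)
  ft$lin <- 2 * ft$ga_months
  ft$neg <- -ft$ga_months
  ps <- pearson_screen(ft)
  expect_equal(ps$r[ps$feature == "lin" & ps$group == "overall"], 1)
  expect_equal(ps$r[ps$feature == "neg" & ps$group == "overall"], -1)
  # independent noise stays sub-0.3 at n = 100 in almost all seeds
  ok <- vapply(1:40, function(s) {
    set.seed(s)
    df <- tibble::tibble(ga_months = sample(6:9, 100, replace = TRUE),
                         x = rnorm(100))
    abs(pearson_screen(df)$r[1]) < 0.3
  }, logical(1))
  expect_gte(mean(ok), 0.95)
})

test_that("rank-sum comparison behaves at its boundaries", {
  x <- c(1, 2, 3, 4, 5)
  expect_gte(compare_group_errors(x, x), 0.99)
  a <- 1:10; b <- 101:110
  expect_lt(compare_group_errors(a, b), 0.001)
  expect_equal(compare_group_errors(a, b), compare_group_errors(b, a))
})
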