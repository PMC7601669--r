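test_that("standardization is exact and leak-free", {
  set.seed(21)
  x <- matrix(rnorm(200, 5, 3), ncol = 2,
              dimnames = list(NULL, c("a", "b")))
  s <- standardize_features(x)
  expect_equal(unname(colMeans(s$x)), c(0, 0), tolerance = 1e-9)
  expect_equal(unname(apply(s$x, 2, sd)), c(1, 1), tolerance = 1e-9)
  # already standardized input: identity transform
  s2 <- standardize_features(s$x)
  expect_equal(s2$x, s$x, tolerance = 1e-9)
  # training statistics are applied unchanged to held-out data, so an
  # outlier in the held-out part cannot move the scaling
  test_x <- matrix(c(1e6, 1e6), ncol = 2,
                   dimnames = list(NULL, c("a", "b")))
  s3 <- standardize_features(test_x, center = s$center, scale = s$scale)
  expect_equal(s3$center, s$center)
  expect_equal(s3$scale, s$scale)
  expect_equal(unname(s3$x[1, 1]),
               (1e6 - s$center[["a"]]) / s$scale[["a"]])
  expect_error(standardize_features(cbind(x, flat = rep(2, 100))), "flat")
})

make_clusters <- function(n_per_class, sep, seed, sd = 1) {
  set.seed(seed)
  centers <- matrix(c(0, 0, sep, 0, 0, sep), ncol = 2, byrow = TRUE)
  out <- do.call(rbind, lapply(1:3, function(k) {
    data.frame(x = rnorm(n_per_class, centers[k, 1], sd),
               y = rnorm(n_per_class, centers[k, 2], sd),
               label = LETTERS[k])
  }))
  out
}

test_that("well-separated clusters are classified almost perfectly", {
  d <- make_clusters(100, sep = 5, seed = 31)
  rep5 <- train_eval_svm(d, d$label, feature_set = c("x", "y"), seed = 2,
                         cost_grid = c(1, 10), gamma_grid = c(0.1, 0.5))
  expect_gte(rep5$accuracy, 0.99)
  # bookkeeping: row sums equal class counts, accuracy equals trace/total
  expect_equal(unname(rowSums(rep5$confusion)), rep(100, 3))
  expect_equal(rep5$accuracy,
               sum(diag(rep5$confusion)) / sum(rep5$confusion))
  expect_equal(unname(rep5$per_class_recall),
               unname(diag(rep5$confusion) / rowSums(rep5$confusion)))
})

test_that("reports are reproducible bit-for-bit under a fixed seed", {
  d <- make_clusters(30, sep = 2, seed = 5)
  r1 <- train_eval_svm(d, d$label, feature_set = c("x", "y"), seed = 7,
                       cost_grid = 1, gamma_grid = c(0.2, 0.8))
  r2 <- train_eval_svm(d, d$label, feature_set = c("x", "y"), seed = 7,
                       cost_grid = 1, gamma_grid = c(0.2, 0.8))
  expect_identical(r1$confusion, r2$confusion)
  expect_identical(r1$accuracy, r2$accuracy)
})

test_that("permuted labels fall back to chance accuracy", {
  d <- make_clusters(80, sep = 5, seed = 41)
  set.seed(42)
  perm <- sample(d$label)
  rp <- train_eval_svm(d, perm, feature_set = c("x", "y"), seed = 3,
                       cost_grid = c(1, 10), gamma_grid = c(0.1, 0.5))
  n <- nrow(d)
  band <- 1.96 * sqrt((1 / 3) * (2 / 3) / n)
  expect_lt(abs(rp$accuracy - 1 / 3), band + 1e-9)
})

test_that("errors guide the user on degenerate inputs", {
  d <- make_clusters(3, sep = 5, seed = 2)
  expect_error(train_eval_svm(d, d$label, feature_set = c("x", "y"),
                              folds = 5, seed = 1), "fewer folds")
  expect_error(train_eval_svm(d, rep("A", 9), feature_set = c("x", "y")),
               "2 distinct")
})

test_that("paired comparison is honest about where the signal lives", {
  # signal only in the two classical features: five features add nothing
  set.seed(51)
  n <- 80
  base <- data.frame(
    rel_blockade = c(rnorm(n, 0.06, 0.01), rnorm(n, 0.09, 0.01),
                     rnorm(n, 0.12, 0.01)),
    dwell_s = rlnorm(3 * n, log(1e-3), 0.3),
    auc = rlnorm(3 * n, log(1e-13), 0.4),
    left_slope = rlnorm(3 * n, log(5e-8), 0.4),
    right_slope = -rlnorm(3 * n, log(5e-8), 0.4),
    label = rep(c("A", "B", "C"), each = n))
  cmp <- compare_feature_sets(base, base$label, seed = 9,
                              cost_grid = c(1, 10),
                              gamma_grid = c(0.1, 0.5))
  expect_lt(abs(cmp$accuracy_gain), 5)
  # identical class distributions: both sets sit at chance
  set.seed(52)
  null_d <- transform(base, rel_blockade = rnorm(3 * n, 0.09, 0.01))
  cmp0 <- compare_feature_sets(null_d, null_d$label, seed = 9,
                               cost_grid = c(1, 10),
                               gamma_grid = c(0.1, 0.5))
  band <- 1.96 * sqrt((1 / 3) * (2 / 3) / (3 * n))
  expect_lt(abs(cmp0$two$accuracy - 1 / 3), band + 0.05)
  expect_lt(abs(cmp0$five$accuracy - 1 / 3), band + 0.05)
})
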