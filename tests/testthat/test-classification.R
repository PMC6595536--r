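# classification: distances, KNN, cross-validation splits

test_that("pair_distance matches the textbook formulas", {
  expect_equal(pair_distance(c(0, 0), c(3, 4), "euclidean"), 5)
  expect_equal(pair_distance(c(0, 0), c(3, 4), "cityblock"), 7)
  u <- c(1, 2, 3)
  expect_equal(pair_distance(u, u, "cosine"), 0)
  expect_equal(pair_distance(u, 5 * u, "cosine"), 0)
  expect_equal(pair_distance(c(1, 0), c(0, 1), "cosine"), 1)
  expect_equal(pair_distance(c(1, 2, 3), c(3, 2, 1), "correlation"), 2)
  expect_error(pair_distance(c(0, 0), c(1, 1), "cosine"), "zero vector")
  expect_error(pair_distance(c(2, 2), c(1, 3), "correlation"), "constant")
  expect_error(pair_distance(1:3, 1:4), "length")
})

test_that("knn_predict votes among the k nearest with the documented ties", {
  train <- rbind(c(0, 0), c(1, 0), c(0, 1), c(5, 5))
  y <- c("apnea", "apnea", "non_apnea", "non_apnea")
  # k=1, exact training point
  p <- knn_predict(train, y, c(5, 5), knn_config(k = 1, distance = "euclidean"))
  expect_equal(p$pred, "non_apnea"); expect_equal(p$score, 0)
  # k=3 majority 2/3
  p3 <- knn_predict(train, y, c(0, 0), knn_config(k = 3, distance = "euclidean"))
  expect_equal(p3$pred, "apnea"); expect_equal(p3$score, 2 / 3)
  # even-k vote tie -> apnea by default, configurable
  tie_train <- rbind(c(0, 0), c(2, 0), c(50, 50))
  tie_y <- c("apnea", "non_apnea", "non_apnea")
  p2 <- knn_predict(tie_train, tie_y, c(1, 0), knn_config(k = 2, distance = "euclidean"))
  expect_equal(p2$score, 0.5); expect_equal(p2$pred, "apnea")
  p2b <- knn_predict(tie_train, tie_y, c(1, 0),
                     knn_config(k = 2, distance = "euclidean", tie_rule = "non_apnea"))
  expect_equal(p2b$pred, "non_apnea")
  # distance ties broken by lower training index
  dup <- rbind(c(1, 1), c(1, 1), c(9, 9))
  pd <- knn_predict(dup, c("non_apnea", "apnea", "apnea"), c(1, 1),
                    knn_config(k = 1, distance = "euclidean"))
  expect_equal(pd$pred, "non_apnea")
  expect_error(knn_predict(train[0, ], character(0), c(0, 0)), "empty training")
  expect_error(knn_predict(train, y, c(0, 0), knn_config(k = 9)), "exceeds")
})

test_that("knn_predict agrees with the exhaustive-search oracle", {
  set.seed(61)
  for (rep in 1:12) {
    n <- sample(10:40, 1); p <- sample(2:8, 1)
    x <- random_feature_matrix(n, p)
    y <- sample(c("apnea", "non_apnea"), n, replace = TRUE)
    tv <- exp(rnorm(p))
    for (method in c("cosine", "euclidean", "cityblock", "correlation")) {
      for (k in c(1, 3, 5, 7)) {
        got <- knn_predict(x, y, tv, knn_config(k = k, distance = method))
        want <- oracle_knn(x, y, tv, k, method)
        expect_identical(got$pred, want$pred)
        expect_equal(got$score, want$score)
      }
    }
  }
})

test_that("cosine predictions are invariant to positive per-sample scaling", {
  set.seed(62)
  x <- random_feature_matrix(30, 10)
  y <- sample(c("apnea", "non_apnea"), 30, replace = TRUE)
  tests <- random_feature_matrix(10, 10)
  cfg <- knn_config(k = 5, distance = "cosine")
  base <- knn_predict(x, y, tests, cfg)
  xs <- x * runif(30, 0.1, 10)               # row-wise positive rescale
  ts <- tests * runif(10, 0.1, 10)
  expect_equal(knn_predict(xs, y, ts, cfg), base, tolerance = 1e-12)
})

test_that("cv_split produces disjoint covering folds", {
  y6 <- rep(c("apnea", "non_apnea"), 3)
  loo <- cv_split(y6, cv_scheme("leave_one_out"))
  expect_length(loo, 6)
  expect_equal(sort(vapply(loo, function(f) f$test, integer(1))), 1:6)
  for (f in loo) expect_equal(sort(c(f$train, f$test)), 1:6)

  y10 <- rep(c("apnea", "non_apnea"), 5)
  f5 <- cv_split(y10, cv_scheme("m_fold", m = 5, seed = 3))
  expect_length(f5, 5)
  tests <- lapply(f5, `[[`, "test")
  expect_equal(sort(unlist(tests)), 1:10)
  for (te in tests) expect_equal(as.integer(table(y10[te])), c(1L, 1L))
  # seeded determinism
  f5b <- cv_split(y10, cv_scheme("m_fold", m = 5, seed = 3))
  expect_identical(f5, f5b)
  expect_false(identical(f5, cv_split(y10, cv_scheme("m_fold", m = 5, seed = 4))))
  expect_error(cv_split(y6, cv_scheme("m_fold", m = 7)), "exceeds")
  expect_error(cv_split("apnea"), "at least 2")
})

test_that("stratified fold class counts differ by at most one", {
  set.seed(63)
  for (rep in 1:5) {
    n <- sample(20:60, 1)
    y <- sample(c("apnea", "non_apnea"), n, replace = TRUE, prob = c(0.4, 0.6))
    m <- sample(2:5, 1)
    folds <- cv_split(y, cv_scheme("m_fold", m = m, seed = rep))
    for (cl in c("apnea", "non_apnea")) {
      cnt <- vapply(folds, function(f) sum(y[f$test] == cl), integer(1))
      expect_lte(diff(range(cnt)), 1)
    }
  }
})

test_that("cv_predict returns one out-of-fold prediction per sample", {
  set.seed(64)
  x <- rbind(random_feature_matrix(10, 4) * 10, random_feature_matrix(10, 4))
  y <- rep(c("apnea", "non_apnea"), each = 10)
  pr <- cv_predict(x, y, knn_config(k = 3), cv_scheme("m_fold", m = 5, seed = 1))
  expect_equal(pr$index, 1:20)
  expect_equal(pr$truth, y)
  # scores live on the k + 1 = 4-level grid
  expect_true(all(abs(pr$score * 3 - round(pr$score * 3)) < 1e-12))
  expect_true(all(pr$score >= 0 & pr$score <= 1))
})
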