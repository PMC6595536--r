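# K-nearest-neighbour classification with pluggable distances and the
# cross-validation schemes used for evaluation. Deliberately first-
# principles (exhaustive distances, explicit tie rules) so behaviour is
# verifiable against a brute-force oracle.

#' KNN configuration
#'
#' @param k Neighbour count (>= 1). The method reports consistent
#'   performance over a wide range of K; 5 is the package default.
#' @param distance One of `"cosine"` (the method's choice), `"euclidean"`,
#'   `"cityblock"`, `"correlation"`.
#' @param tie_rule Vote-tie policy for even splits: `"apnea"`
#'   (sensitivity-favouring default) or `"non_apnea"`. Distance ties are
#'   always broken by lower training index.
#' @return A `knn_config` list.
#' @export
knn_config <- function(k = 5,
                       distance = c("cosine", "euclidean", "cityblock", "correlation"),
                       tie_rule = c("apnea", "non_apnea")) {
  distance <- match.arg(distance)
  tie_rule <- match.arg(tie_rule)
  if (k < 1) stop("k must be >= 1", call. = FALSE)
  structure(list(k = as.integer(k), distance = distance, tie_rule = tie_rule),
            class = "knn_config")
}

#' Distance between two feature vectors
#'
#' euclidean: \eqn{\sqrt{\sum (u_i - v_i)^2}}; cityblock:
#' \eqn{\sum |u_i - v_i|}; cosine: \eqn{1 - u \cdot v / (|u||v|)};
#' correlation: \eqn{1 - r(u, v)} (Pearson).
#'
#' @param u,v Equal-length numeric vectors.
#' @param method Distance name.
#' @return Non-negative scalar (correlation distance lies in `[0, 2]`).
#' @export
pair_distance <- function(u, v,
                          method = c("cosine", "euclidean", "cityblock", "correlation")) {
  method <- match.arg(method)
  if (length(u) != length(v)) stop("vectors differ in length", call. = FALSE)
  switch(method,
    euclidean = sqrt(sum((u - v)^2)),
    cityblock = sum(abs(u - v)),
    cosine = {
      nu <- sqrt(sum(u^2)); nv <- sqrt(sum(v^2))
      if (nu == 0 || nv == 0)
        stop("cosine distance undefined for a zero vector", call. = FALSE)
      1 - sum(u * v) / (nu * nv)
    },
    correlation = {
      uc <- u - mean(u); vc <- v - mean(v)
      nu <- sqrt(sum(uc^2)); nv <- sqrt(sum(vc^2))
      if (nu == 0 || nv == 0)
        stop("correlation distance undefined for a constant vector", call. = FALSE)
      1 - sum(uc * vc) / (nu * nv)
    })
}

# distances from every row of a matrix to one vector, same arithmetic as
# pair_distance applied row-wise
dists_to <- function(train, v, method) {
  apply(train, 1L, pair_distance, v = v, method = method)
}

#' Classify one or more test vectors by K nearest neighbours
#'
#' For each test vector: compute distances to all training vectors, take
#' the `k` nearest (distance ties broken by lower training index), and
#' vote. The apnea score is the fraction of those `k` neighbours labelled
#' apnea — the ROC score of the classifier, on a grid of k + 1 levels.
#'
#' @param train_x Numeric matrix, one training vector per row.
#' @param train_y Labels (`"apnea"` / `"non_apnea"`), one per row.
#' @param test_x Numeric matrix (or single vector) of test points.
#' @param config A [knn_config()]; `k` must not exceed `nrow(train_x)`.
#' @return Data frame with columns `pred` and `score`.
#' @export
knn_predict <- function(train_x, train_y, test_x, config = knn_config()) {
  if (is.null(dim(train_x))) train_x <- matrix(train_x, ncol = 1)
  if (is.null(dim(test_x))) test_x <- matrix(test_x, nrow = 1)
  if (nrow(train_x) == 0L) stop("empty training set", call. = FALSE)
  if (length(train_y) != nrow(train_x))
    stop("train_y length must match nrow(train_x)", call. = FALSE)
  if (config$k > nrow(train_x))
    stop("k (", config$k, ") exceeds training-set size (", nrow(train_x), ")",
         call. = FALSE)
  is_apnea <- train_y == "apnea"
  n_test <- nrow(test_x)
  pred <- character(n_test); score <- numeric(n_test)
  for (i in seq_len(n_test)) {
    d <- dists_to(train_x, test_x[i, ], config$distance)
    nn <- order(d, seq_along(d))[seq_len(config$k)]
    s <- mean(is_apnea[nn])
    score[i] <- s
    pred[i] <- if (s > 0.5) "apnea"
      else if (s < 0.5) "non_apnea"
      else if (config$tie_rule == "apnea") "apnea" else "non_apnea"
  }
  data.frame(pred = pred, score = score, stringsAsFactors = FALSE)
}

#' Cross-validation scheme
#'
#' @param kind `"leave_one_out"` or `"m_fold"`.
#' @param m Fold count for `m_fold` (2, 5 and 10 reproduce the published
#'   grid; any m >= 2 is accepted).
#' @param stratified Stratify folds by class (default `TRUE`; on balanced
#'   sets this keeps every fold balanced).
#' @param seed Seed for the fold partition.
#' @return A `cv_scheme` list.
#' @export
cv_scheme <- function(kind = c("leave_one_out", "m_fold"), m = 10,
                      stratified = TRUE, seed = 1L) {
  kind <- match.arg(kind)
  if (kind == "m_fold" && m < 2) stop("m must be >= 2", call. = FALSE)
  structure(list(kind = kind, m = as.integer(m), stratified = stratified,
                 seed = as.integer(seed)),
            class = "cv_scheme")
}

#' Split sample indices into cross-validation folds
#'
#' Leave-one-out yields n singleton test folds. M-fold partitions the
#' indices into m disjoint covering folds, seeded; when stratified, class
#' counts per fold differ by at most one.
#'
#' @param labels Class labels (length n >= 2).
#' @param scheme A [cv_scheme()].
#' @return List of `list(train =, test =)` index pairs.
#' @export
cv_split <- function(labels, scheme = cv_scheme()) {
  n <- length(labels)
  if (n < 2L) stop("need at least 2 samples", call. = FALSE)
  if (scheme$kind == "leave_one_out") {
    return(lapply(seq_len(n), function(i)
      list(train = setdiff(seq_len(n), i), test = i)))
  }
  m <- scheme$m
  if (m > n) stop("m (", m, ") exceeds sample count (", n, ")", call. = FALSE)
  fold_of <- integer(n)
  with_seed(scheme$seed, {
    if (scheme$stratified) {
      for (cl in unique(labels)) {
        idx <- which(labels == cl)
        fold_of[idx] <- sample(rep_len(seq_len(m), length(idx)))
      }
    } else {
      fold_of <- sample(rep_len(seq_len(m), n))
    }
  })
  lapply(seq_len(m), function(f)
    list(train = which(fold_of != f), test = which(fold_of == f)))
}

#' Cross-validated KNN predictions for one subject
#'
#' Runs [knn_predict()] over the folds of `scheme` and collects
#' out-of-fold predictions and apnea scores for every sample.
#'
#' @param x Feature matrix (rows = frames).
#' @param y Labels.
#' @param config A [knn_config()].
#' @param scheme A [cv_scheme()].
#' @return Data frame with columns `index`, `truth`, `pred`, `score`,
#'   ordered by `index`.
#' @export
cv_predict <- function(x, y, config = knn_config(), scheme = cv_scheme("leave_one_out")) {
  if (is.null(dim(x))) x <- matrix(x, ncol = 1)
  folds <- cv_split(y, scheme)
  out <- vector("list", length(folds))
  for (f in seq_along(folds)) {
    tr <- folds[[f]]$train; te <- folds[[f]]$test
    if (length(unique(y[tr])) < 2L)
      warning("fold ", f, ": single-class training set")
    p <- knn_predict(x[tr, , drop = FALSE], y[tr], x[te, , drop = FALSE], config)
    out[[f]] <- data.frame(index = te, truth = y[te], pred = p$pred,
                           score = p$score, stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, out)
  res[order(res$index), , drop = FALSE]
}
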