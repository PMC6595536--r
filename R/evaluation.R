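# Confusion matrices, sensitivity/specificity/accuracy, ROC AUC,
# the geometrical separability index, and per-subject aggregation.

#' Confusion matrix of apnea predictions
#'
#' Apnea is the positive class: TP = apnea detected as apnea, FN = apnea
#' missed, FP = non-apnea flagged, TN = non-apnea passed.
#'
#' @param truth,pred Label vectors (`"apnea"` / `"non_apnea"`).
#' @return A `confusion_matrix` list with fields `tp`, `fn`, `fp`, `tn`.
#' @export
confusion_matrix <- function(truth, pred) {
  if (length(truth) != length(pred)) stop("length mismatch", call. = FALSE)
  structure(list(tp = sum(truth == "apnea" & pred == "apnea"),
                 fn = sum(truth == "apnea" & pred == "non_apnea"),
                 fp = sum(truth == "non_apnea" & pred == "apnea"),
                 tn = sum(truth == "non_apnea" & pred == "non_apnea")),
            class = "confusion_matrix")
}

#' @export
print.confusion_matrix <- function(x, ...) {
  m <- matrix(c(x$tp, x$fn, x$fp, x$tn), 2, byrow = TRUE,
              dimnames = list(truth = c("apnea", "non_apnea"),
                              predicted = c("apnea", "non_apnea")))
  print(m)
  invisible(x)
}

#' Sensitivity, specificity and accuracy (percent)
#'
#' sensitivity = 100 TP / (TP + FN); specificity = 100 TN / (TN + FP);
#' accuracy = 100 (TP + TN) / (TP + TN + FP + FN).
#'
#' @param cm A [confusion_matrix()], or a list with fields tp, fn, fp, tn.
#' @return Named numeric vector `sensitivity`, `specificity`, `accuracy`.
#' @export
#' @examples
#' classification_metrics(list(tp = 345, fn = 49, fp = 45, tn = 349))
classification_metrics <- function(cm) {
  with(cm, {
    if (tp + fn == 0) stop("no positive (apnea) frames: sensitivity undefined",
                           call. = FALSE)
    if (tn + fp == 0) stop("no negative (non-apnea) frames: specificity undefined",
                           call. = FALSE)
    c(sensitivity = 100 * tp / (tp + fn),
      specificity = 100 * tn / (tn + fp),
      accuracy = 100 * (tp + tn) / (tp + tn + fp + fn))
  })
}

#' Area under the ROC curve
#'
#' Mann–Whitney formulation with ties counted one half: the probability
#' that a random apnea frame outscores a random non-apnea frame. Exactly
#' equal to the trapezoidal area under the empirical ROC, and handles the
#' discrete k + 1-level score grid of a KNN classifier exactly.
#'
#' @param scores Numeric apnea scores, higher = more apnea-like.
#' @param labels Labels (`"apnea"` positive).
#' @return AUC in `[0, 1]`.
#' @export
roc_auc <- function(scores, labels) {
  pos <- labels == "apnea"
  n1 <- sum(pos); n0 <- sum(!pos)
  if (n1 == 0L || n0 == 0L)
    stop("both classes must be present to compute AUC", call. = FALSE)
  r <- rank(scores, ties.method = "average")
  (sum(r[pos]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Geometrical separability index
#'
#' The fraction of points whose nearest neighbour (self excluded, distance
#' ties broken by lower index) carries the same class label. 1 means the
#' two classes form well-separated clusters; values fall toward chance as
#' the classes interleave.
#'
#' @param x Feature matrix (rows = points, n >= 2).
#' @param labels Class labels.
#' @param metric Distance used for the neighbour search; euclidean by
#'   default, any [pair_distance()] method allowed.
#' @return Index in `[0, 1]`.
#' @export
gsi <- function(x, labels,
                metric = c("euclidean", "cosine", "cityblock", "correlation")) {
  metric <- match.arg(metric)
  if (is.null(dim(x))) x <- matrix(x, ncol = 1)
  n <- nrow(x)
  if (n < 2L) stop("need at least 2 points", call. = FALSE)
  if (length(labels) != n) stop("labels length mismatch", call. = FALSE)
  match_cnt <- 0L
  for (i in seq_len(n)) {
    d <- dists_to(x, x[i, ], metric)
    d[i] <- Inf
    nn <- order(d, seq_len(n))[1L]
    if (labels[nn] == labels[i]) match_cnt <- match_cnt + 1L
  }
  match_cnt / n
}

#' Evaluate one subject's feature matrix
#'
#' Runs cross-validated KNN, then computes the confusion matrix, the
#' percentage metrics, the AUC of the out-of-fold apnea scores, and the
#' GSI of the feature set.
#'
#' @param features Feature data frame as from [featurize_frames()], or a
#'   plain matrix with `labels` supplied.
#' @param labels Labels when `features` is a bare matrix.
#' @param config A [knn_config()].
#' @param scheme A [cv_scheme()].
#' @param gsi_metric Distance for the GSI neighbour search.
#' @return A `subject_result` list: `subject`, `cm`, `metrics`, `auc`,
#'   `gsi`, `predictions`.
#' @export
evaluate_subject <- function(features, labels = NULL, config = knn_config(),
                             scheme = cv_scheme("leave_one_out"),
                             gsi_metric = "euclidean") {
  if (is.data.frame(features) && "label" %in% names(features)) {
    labels <- features$label
    subject <- if ("subject_id" %in% names(features)) features$subject_id[1] else "subject"
    x <- feature_values(features)
  } else {
    if (is.null(labels)) stop("labels required for a bare feature matrix", call. = FALSE)
    subject <- "subject"
    x <- as.matrix(features)
  }
  if (length(unique(labels)) < 2L)
    stop("subject has a single class; cannot evaluate", call. = FALSE)
  pr <- cv_predict(x, labels, config, scheme)
  cm <- confusion_matrix(pr$truth, pr$pred)
  structure(list(subject = subject,
                 cm = cm,
                 metrics = classification_metrics(cm),
                 auc = roc_auc(pr$score, pr$truth),
                 gsi = gsi(x, labels, gsi_metric),
                 predictions = pr),
            class = "subject_result")
}

#' @export
print.subject_result <- function(x, ...) {
  cat("<subject_result> ", x$subject, "\n", sep = "")
  print(round(c(x$metrics, auc = x$auc, gsi = x$gsi), 4))
  invisible(x)
}

# MATLAB-convention (type-5, midpoint plotting position) quantiles
# reproduce the published IQR rows; R's default type 7 does not.
iqr_type5 <- function(x) {
  q <- stats::quantile(x, c(0.25, 0.75), type = 5, names = FALSE)
  q[2] - q[1]
}

#' Aggregate per-subject metrics
#'
#' Mean, sample standard deviation (n - 1 denominator) and interquartile
#' range (type-5 linear-interpolation quantiles) of each metric across
#' subjects, the layout of the published per-subject tables.
#'
#' @param per_subject Data frame of per-subject metric columns (any
#'   numeric columns are aggregated).
#' @return Data frame with rows `mean`, `sd`, `iqr`.
#' @export
aggregate_metrics <- function(per_subject) {
  num <- vapply(per_subject, is.numeric, logical(1))
  if (nrow(per_subject) < 2L) stop("need at least 2 subjects", call. = FALSE)
  vals <- per_subject[, num, drop = FALSE]
  out <- rbind(mean = vapply(vals, mean, numeric(1)),
               sd = vapply(vals, stats::sd, numeric(1)),
               iqr = vapply(vals, iqr_type5, numeric(1)))
  as.data.frame(out)
}

#' Evaluate a cohort of subjects and build the report
#'
#' @param feature_list Named list of per-subject feature data frames (as
#'   from [featurize_frames()] or [read_feature_matrix()]).
#' @param config,scheme,gsi_metric Passed to [evaluate_subject()].
#' @return An `apnea_report`: `per_subject` data frame (subject, tp, fn,
#'   fp, tn, sensitivity, specificity, accuracy, auc, gsi), `aggregates`,
#'   and the raw `results` list.
#' @export
evaluate_cohort <- function(feature_list, config = knn_config(),
                            scheme = cv_scheme("leave_one_out"),
                            gsi_metric = "euclidean") {
  results <- list()
  for (nm in names(feature_list)) {
    res <- tryCatch(evaluate_subject(feature_list[[nm]], config = config,
                                     scheme = scheme, gsi_metric = gsi_metric),
                    error = function(e) {
                      warning("subject ", nm, " skipped: ", conditionMessage(e))
                      NULL
                    })
    if (!is.null(res)) { res$subject <- nm; results[[nm]] <- res }
  }
  if (!length(results)) stop("no subject could be evaluated", call. = FALSE)
  per_subject <- do.call(rbind, lapply(results, function(r)
    data.frame(subject = r$subject, tp = r$cm$tp, fn = r$cm$fn, fp = r$cm$fp,
               tn = r$cm$tn,
               sensitivity = r$metrics[["sensitivity"]],
               specificity = r$metrics[["specificity"]],
               accuracy = r$metrics[["accuracy"]],
               auc = r$auc, gsi = r$gsi, stringsAsFactors = FALSE)))
  rownames(per_subject) <- NULL
  aggregates <- if (nrow(per_subject) >= 2)
    aggregate_metrics(per_subject[, c("sensitivity", "specificity",
                                      "accuracy", "auc", "gsi")])
  else NULL
  structure(list(per_subject = per_subject, aggregates = aggregates,
                 results = results),
            class = "apnea_report")
}

#' @export
print.apnea_report <- function(x, digits = 2, ...) {
  cat("<apnea_report> ", nrow(x$per_subject), " subject(s)\n", sep = "")
  df <- x$per_subject
  df[6:10] <- lapply(df[6:10], round, digits)
  print(df, row.names = FALSE)
  if (!is.null(x$aggregates)) {
    cat("aggregates:\n")
    print(round(x$aggregates, digits))
  }
  invisible(x)
}

#' Write an evaluation report to disk
#'
#' CSV with one row per subject plus `mean` / `sd` / `iqr` aggregate rows;
#' optionally a JSON mirror.
#'
#' @param report An `apnea_report`.
#' @param path CSV output path.
#' @param json Optional JSON output path.
#' @export
write_report <- function(report, path, json = NULL) {
  df <- report$per_subject
  if (!is.null(report$aggregates)) {
    agg <- report$aggregates
    pad <- data.frame(subject = rownames(agg), tp = NA, fn = NA, fp = NA, tn = NA,
                      sensitivity = agg$sensitivity, specificity = agg$specificity,
                      accuracy = agg$accuracy, auc = agg$auc, gsi = agg$gsi)
    df <- rbind(df, pad)
  }
  utils::write.csv(df, path, row.names = FALSE)
  if (!is.null(json))
    jsonlite::write_json(list(per_subject = report$per_subject,
                              aggregates = report$aggregates),
                         json, dataframe = "rows", digits = NA, pretty = TRUE)
  invisible(path)
}

#' Round half away from zero
#'
#' The print convention of the published tables (2 decimal places,
#' half-away-from-zero), unlike R's banker's rounding.
#'
#' @param x Numeric.
#' @param digits Decimal places.
#' @export
round_half_up <- function(x, digits = 2) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}
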