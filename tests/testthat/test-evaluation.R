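# evaluation: confusion metrics, AUC, GSI, aggregation

test_that("classification_metrics implements the percentage definitions", {
  m <- classification_metrics(list(tp = 345, fn = 49, fp = 45, tn = 349))
  expect_equal(round_half_up(m), c(sensitivity = 87.56, specificity = 88.58,
                                   accuracy = 88.07))
  m2 <- classification_metrics(list(tp = 96, fn = 3, fp = 2, tn = 97))
  expect_equal(round_half_up(m2[["accuracy"]]), 97.47)
  perfect <- classification_metrics(list(tp = 10, fn = 0, fp = 0, tn = 10))
  expect_equal(unname(perfect), c(100, 100, 100))
  expect_error(classification_metrics(list(tp = 0, fn = 0, fp = 1, tn = 9)),
               "sensitivity undefined")
  expect_error(classification_metrics(list(tp = 5, fn = 1, fp = 0, tn = 0)),
               "specificity undefined")
})

test_that("confusion_matrix counts the four cells", {
  truth <- c("apnea", "apnea", "non_apnea", "non_apnea", "apnea")
  pred <- c("apnea", "non_apnea", "non_apnea", "apnea", "apnea")
  cm <- confusion_matrix(truth, pred)
  expect_equal(unlist(cm[c("tp", "fn", "fp", "tn")]),
               c(tp = 2, fn = 1, fp = 1, tn = 1))
  # accuracy is the balanced mean of sensitivity and specificity on
  # balanced sets
  set.seed(71)
  truth <- rep(c("apnea", "non_apnea"), each = 25)
  pred <- sample(truth)
  m <- classification_metrics(confusion_matrix(truth, pred))
  expect_equal(m[["accuracy"]],
               (m[["sensitivity"]] + m[["specificity"]]) / 2)
})

test_that("roc_auc matches hand-counted and oracle values", {
  expect_equal(roc_auc(c(0.9, 0.8, 0.7, 0.6, 0.5),
                       c("apnea", "apnea", "non_apnea", "apnea", "non_apnea")),
               5 / 6)
  expect_equal(roc_auc(c(1, 1, 0, 0), c("apnea", "apnea", "non_apnea", "non_apnea")), 1)
  expect_error(roc_auc(c(1, 2), c("apnea", "apnea")), "both classes")
  set.seed(72)
  for (rep in 1:20) {
    n <- sample(5:50, 1)
    labels <- c("apnea", "non_apnea",
                sample(c("apnea", "non_apnea"), n - 2, replace = TRUE))
    scores <- sample(seq(0, 1, 0.125), n, replace = TRUE)   # many ties
    expect_equal(roc_auc(scores, labels), oracle_auc(scores, labels))
  }
  # label-independent scores, large n: AUC near 1/2
  set.seed(73)
  lab <- rep(c("apnea", "non_apnea"), each = 2000)
  expect_equal(roc_auc(runif(4000), lab), 0.5, tolerance = 0.05)
})

test_that("gsi matches hand-enumeration, limits and the oracle", {
  expect_equal(gsi(matrix(c(1, 2, 3), 3), rep("apnea", 3)), 1)
  # hand-enumerated: neighbours A<->A match, B->A and A->B mismatch
  x <- matrix(c(0, 0.1, 10, 10.1), 4)
  expect_equal(gsi(x, c("A", "A", "B", "A")), 0.5)
  # two tight well-separated opposite clusters
  set.seed(74)
  y <- rbind(matrix(rnorm(20, 0, 0.01), 10), matrix(rnorm(20, 5, 0.01), 10))
  expect_equal(gsi(y, rep(c("A", "B"), each = 10)), 1)
  expect_error(gsi(matrix(1, 1), "A"), "at least 2")
  for (rep in 1:10) {
    n <- sample(5:40, 1); p <- sample(1:6, 1)
    m <- matrix(rnorm(n * p), n)
    lab <- sample(c("apnea", "non_apnea"), n, replace = TRUE)
    expect_equal(gsi(m, lab), oracle_gsi(m, lab))
    # euclidean GSI is invariant to global scaling
    expect_equal(gsi(m * 7, lab), gsi(m, lab))
  }
})

test_that("aggregation reproduces the published mean/SD/IQR conventions", {
  ref <- metrics_from_confusion()
  agg <- ref$aggregates
  expect_equal(round_half_up(unlist(agg["mean", ])),
               c(sensitivity = 90.39, specificity = 94.04, accuracy = 92.21))
  expect_equal(round_half_up(agg["sd", "accuracy"]), 3.72)
  expect_equal(round_half_up(unlist(agg["iqr", ])),
               c(sensitivity = 6.70, specificity = 6.22, accuracy = 5.30))
  same <- data.frame(a = rep(4.2, 5))
  expect_equal(aggregate_metrics(same)["sd", "a"], 0)
  expect_equal(aggregate_metrics(same)["iqr", "a"], 0)
  expect_equal(unname(unlist(
    aggregate_metrics(data.frame(x = c(88.07, 93.18, 97.47, 93.08, 89.26)))["mean", ])),
    92.212)
  expect_error(aggregate_metrics(data.frame(a = 1)), "at least 2")
})

test_that("evaluate_subject and evaluate_cohort assemble the report", {
  set.seed(75)
  # classes must differ in *direction*, not just scale: the default cosine
  # distance is scale-invariant
  mk <- function(sep, n = 30, subject = "S") {
    x <- rbind(cbind(exp(rnorm(n, sep, 0.3)), exp(rnorm(n, 0, 0.3)),
                     exp(rnorm(n, 0, 0.3))),
               cbind(exp(rnorm(n, 0, 0.3)), exp(rnorm(n, 0, 0.3)),
                     exp(rnorm(n, sep, 0.3))))
    data.frame(subject_id = subject, frame_start_s = seq_len(2 * n) * 10,
               label = rep(c("apnea", "non_apnea"), each = n),
               a = x[, 1], b = x[, 2], c = x[, 3])
  }
  res <- evaluate_subject(mk(3), scheme = cv_scheme("leave_one_out"))
  expect_gt(res$metrics[["accuracy"]], 90)
  expect_gt(res$auc, 0.95)
  expect_gt(res$gsi, 0.9)
  expect_equal(res$cm$tp + res$cm$fn, 30)

  rep_ <- evaluate_cohort(list(A = mk(3, subject = "A"), B = mk(2.5, subject = "B"),
                               C = mk(3.5, subject = "C")),
                          scheme = cv_scheme("m_fold", m = 5, seed = 2))
  expect_equal(nrow(rep_$per_subject), 3)
  expect_equal(rownames(rep_$aggregates), c("mean", "sd", "iqr"))
  p <- withr::local_tempfile(fileext = ".csv")
  pj <- withr::local_tempfile(fileext = ".json")
  write_report(rep_, p, pj)
  tab <- read.csv(p)
  expect_equal(nrow(tab), 6)                       # 3 subjects + 3 aggregate rows
  expect_equal(tab$subject[4:6], c("mean", "sd", "iqr"))
  expect_true(jsonlite::validate(paste(readLines(pj), collapse = "\n")))
  expect_error(evaluate_subject(mk(3)[1:30, ]), "single class")
})
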