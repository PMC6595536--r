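# Independent brute-force oracles, written from scratch (plain loops, own
# distance formulas) so they share no code path with the package.

oracle_dist <- function(u, v, method) {
  if (method == "euclidean") {
    s <- 0
    for (j in seq_along(u)) s <- s + (u[j] - v[j])^2
    sqrt(s)
  } else if (method == "cityblock") {
    s <- 0
    for (j in seq_along(u)) s <- s + abs(u[j] - v[j])
    s
  } else if (method == "cosine") {
    dot <- 0; a <- 0; b <- 0
    for (j in seq_along(u)) { dot <- dot + u[j] * v[j]; a <- a + u[j]^2; b <- b + v[j]^2 }
    1 - dot / (sqrt(a) * sqrt(b))
  } else if (method == "correlation") {
    um <- sum(u) / length(u); vm <- sum(v) / length(v)
    oracle_dist(u - um, v - vm, "cosine")
  } else stop("unknown method")
}

# exhaustive-search KNN: all pairwise distances, selection of the k nearest
# with explicit lowest-index tie scanning, majority vote (ties -> apnea)
oracle_knn <- function(train_x, train_y, test_v, k, method, tie_rule = "apnea") {
  n <- nrow(train_x)
  d <- numeric(n)
  for (i in seq_len(n)) d[i] <- oracle_dist(train_x[i, ], test_v, method)
  remaining <- seq_len(n)
  nn <- integer(0)
  for (pick in seq_len(k)) {
    best <- remaining[1]
    for (i in remaining) if (d[i] < d[best]) best <- i  # strict <: keeps lowest index on ties
    nn <- c(nn, best)
    remaining <- setdiff(remaining, best)
  }
  votes <- sum(train_y[nn] == "apnea")
  list(
    pred = if (votes * 2 > k) "apnea"
           else if (votes * 2 < k) "non_apnea"
           else if (tie_rule == "apnea") "apnea" else "non_apnea",
    score = votes / k
  )
}

# pairwise-counting AUC: concordant pairs + half ties over all pos x neg pairs
oracle_auc <- function(scores, labels) {
  ip <- which(labels == "apnea"); in_ <- which(labels != "apnea")
  s <- 0
  for (i in ip) for (j in in_) {
    if (scores[i] > scores[j]) s <- s + 1
    else if (scores[i] == scores[j]) s <- s + 0.5
  }
  s / (length(ip) * length(in_))
}

# exhaustive nearest-neighbour GSI
oracle_gsi <- function(x, labels, method = "euclidean") {
  n <- nrow(x)
  hits <- 0
  for (i in seq_len(n)) {
    best <- NA_integer_; bd <- Inf
    for (j in seq_len(n)) {
      if (j == i) next
      dj <- oracle_dist(x[i, ], x[j, ], method)
      if (dj < bd) { bd <- dj; best <- j }
    }
    if (labels[best] == labels[i]) hits <- hits + 1
  }
  hits / n
}

# band energy of a signal measured directly on the periodogram, for
# checking time-domain band energies (Parseval)
oracle_band_energy_spectral <- function(x, fs, lo, hi) {
  n <- length(x)
  X <- fft(x)
  f <- pmin(seq_len(n) - 1, n - (seq_len(n) - 1)) * fs / n
  sum(Mod(X[f >= lo & f < hi])^2) / n
}

# small random feature-like matrix (strictly positive, ratio-style scales)
random_feature_matrix <- function(n, p) {
  matrix(exp(rnorm(n * p, 0, 1.5)), n, p)
}

make_frame_set <- function(samples, start, labels, fs = 128, dur = 10) {
  structure(list(samples = samples, start = start, labels = labels,
                 frame_duration = dur, sampling_rate = fs),
            class = "frame_set")
}
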