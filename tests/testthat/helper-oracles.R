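# Independent brute-force oracles for the graph metrics (Floyd-Warshall
# distances, exhaustive triple loops) and small fixture builders. These are
# deliberately naive and share no code with the package implementations.

fw_distances <- function(w, lengths = "inverse") {
  n <- nrow(w)
  d <- matrix(Inf, n, n)
  for (i in 1:n) for (j in 1:n) {
    if (w[i, j] > 0)
      d[i, j] <- if (lengths == "inverse") 1 / w[i, j] else 1 - w[i, j]
  }
  diag(d) <- 0
  for (k in 1:n) for (i in 1:n) for (j in 1:n)
    if (d[i, k] + d[k, j] < d[i, j]) d[i, j] <- d[i, k] + d[k, j]
  d
}

brute_ge <- function(w) {
  d <- fw_distances(w)
  n <- nrow(w)
  total <- 0
  for (i in 1:n) {
    acc <- 0
    for (j in 1:n)
      if (j != i && is.finite(d[i, j])) acc <- acc + 1 / d[i, j]
    total <- total + acc / (n - 1)
  }
  total / n
}

brute_L <- function(w) {
  d <- fw_distances(w)
  n <- nrow(w)
  total <- 0
  for (i in 1:n) {
    acc <- 0
    cnt <- 0
    for (j in 1:n)
      if (j != i && is.finite(d[i, j])) { acc <- acc + d[i, j]; cnt <- cnt + 1 }
    total <- total + acc / cnt
  }
  total / n
}

brute_clu <- function(w, normalize = "graph_max") {
  n <- nrow(w)
  mx <- if (normalize == "graph_max") max(w) else 1
  wh <- w / mx
  total <- 0
  for (i in 1:n) {
    k <- sum(w[i, ] > 0)
    if (k < 2) next
    acc <- 0
    for (j in 1:n) for (l in 1:n) {
      if (j == i || l == i || j == l) next
      acc <- acc + (wh[i, j] * wh[i, l] * wh[j, l])^(1 / 3)
    }
    total <- total + acc / (k * (k - 1))
  }
  total / n
}

brute_le <- function(w) {
  n <- nrow(w)
  total <- 0
  for (i in 1:n) {
    nb <- which(w[i, ] > 0)
    k <- length(nb)
    if (k < 2) next
    dsub <- fw_distances(w[nb, nb, drop = FALSE])
    acc <- 0
    for (a in seq_len(k)) for (b in seq_len(k)) {
      if (a == b) next
      if (!is.finite(dsub[a, b])) next
      acc <- acc + (w[i, nb[a]] * w[i, nb[b]] / dsub[a, b])^(1 / 3)
    }
    total <- total + acc / (k * (k - 1))
  }
  total / n
}

random_weights <- function(n, seed) {
  set.seed(seed)
  w <- matrix(0, n, n)
  ut <- upper.tri(w)
  w[ut] <- runif(sum(ut), 0.05, 1)
  w + t(w)
}

# coherence_matrix object built directly from values (for statistics tests)
make_cm <- function(values, labels = NULL) {
  if (is.null(labels)) labels <- paste0("e", seq_len(nrow(values)))
  dimnames(values) <- list(labels, labels)
  structure(list(values = values, labels = labels, band = c(1, 45),
                 n_segments_averaged = 1L,
                 welch = list(window = 1, overlap = 0.5)),
            class = "coherence_matrix")
}

sine_recording <- function(freq, fs = 1000, dur = 3, labels = "ch1",
                           amplitude = 1) {
  t <- seq(0, dur - 1 / fs, by = 1 / fs)
  data <- matrix(rep(amplitude * sin(2 * pi * freq * t),
                     length(labels)),
                 nrow = length(labels), byrow = TRUE)
  recording(data, fs, labels)
}

# scaled-down simulation config shared by EEG-based tests: same montage and
# coupling structure as the study conditions, shorter recordings at a lower
# sampling rate so the suite stays fast
test_config <- function(...) {
  args <- utils::modifyList(list(fs = 128, duration = 24), list(...))
  do.call(sim_config, args)
}
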