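# Independent brute-force oracle for simplex cross-map prediction.
# Exhaustive distance computation and sorting in plain R, sharing only the
# stated weight formula with the implementation under test.
oracle_cross_map <- function(target_values, lib, row_times, tp, n_neighbors,
                             exclusion_radius = 0) {
  N <- length(target_values)
  usable <- function(i) {
    ti <- row_times[i] + tp
    ti >= 0 && ti < N && is.finite(target_values[ti + 1])
  }
  cand <- Filter(usable, seq_len(nrow(lib)))
  queries <- Filter(usable, seq_len(nrow(lib)))
  preds <- obs <- numeric(0)
  times <- integer(0)
  for (i in queries) {
    ds <- sapply(cand, function(j) sqrt(sum((lib[i, ] - lib[j, ])^2)))
    keep <- abs(row_times[cand] - row_times[i]) > exclusion_radius
    dd <- ds[keep]; jj <- cand[keep]
    ord <- order(dd, row_times[jj])
    nb <- ord[seq_len(n_neighbors)]
    d1 <- dd[nb[1]]
    u <- if (d1 == 0) as.numeric(dd[nb] == 0) else exp(-dd[nb] / d1)
    w <- u / sum(u)
    preds <- c(preds, sum(w * target_values[row_times[jj[nb]] + tp + 1]))
    obs <- c(obs, target_values[row_times[i] + tp + 1])
    times <- c(times, row_times[i] + tp)
  }
  list(predictions = preds, observations = obs, prediction_times = times)
}

# deterministic chaotic logistic map trajectory
logistic_map <- function(n, r = 3.8, x0 = 0.31) {
  x <- numeric(n)
  x[1] <- x0
  for (t in seq_len(n - 1)) x[t + 1] <- r * x[t] * (1 - x[t])
  x
}

# unidirectionally coupled logistic maps: X drives Y with given coupling
coupled_maps <- function(n, coupling = 0.3, seed = 1, rx = 3.8, ry = 3.7,
                         burn = 100) {
  set.seed(seed)
  x <- runif(1, 0.2, 0.8); y <- runif(1, 0.2, 0.8)
  xs <- ys <- numeric(n)
  for (t in seq_len(n + burn)) {
    xn <- x * (rx - rx * x)
    yn <- y * (ry - ry * y - coupling * x)
    x <- min(max(xn, 1e-8), 1)
    y <- min(max(yn, 1e-8), 1)
    if (t > burn) { xs[t - burn] <- x; ys[t - burn] <- y }
  }
  list(x = xs, y = ys)
}
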