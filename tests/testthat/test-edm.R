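test_that("delay embedding produces the delay vectors the formula forces", {
  ss <- embed_series(uniform_series(1:5), embedding_params(E = 2, tau = 1))
  expect_equal(ss$vectors,
               matrix(c(2, 1, 3, 2, 4, 3, 5, 4), ncol = 2, byrow = TRUE))
  expect_equal(ss$row_times, 1:4)

  # E = 1 is the identity reconstruction
  x <- rnorm(20)
  ss1 <- embed_series(uniform_series(x), embedding_params(E = 1, tau = 7))
  expect_equal(drop(ss1$vectors), x)
  expect_equal(ss1$row_times, 0:19)

  # row count N - (E-1) tau and first row time (E-1) tau
  ss2 <- embed_series(uniform_series(rnorm(10)), embedding_params(E = 3, tau = 2))
  expect_equal(nrow(ss2$vectors), 6L)
  expect_equal(ss2$row_times[1L], 4L)
})

test_that("embedding rejects too-short series naming the minimum", {
  expect_error(
    embed_series(uniform_series(1:5), embedding_params(E = 4, tau = 2)),
    "at least 7")
})

test_that("embedding drops rows containing missing values", {
  x <- c(1, 2, NA, 4, 5, 6)
  ss <- embed_series(uniform_series(x), embedding_params(E = 2, tau = 1))
  # rows at t = 2 and t = 3 involve the NA and must be gone
  expect_equal(ss$row_times, c(1L, 4L, 5L))
  expect_false(anyNA(ss$vectors))
})

test_that("cross-map prediction matches the brute-force oracle", {
  set.seed(42)
  for (k in 1:30) {
    n <- sample(12:40, 1)
    E <- sample(1:3, 1)
    tau <- sample(1:2, 1)
    if ((E - 1) * tau + 1 >= n - E - 2) next
    tp <- sample(-2:1, 1)
    x <- uniform_series(rnorm(n), name = "x")
    y <- uniform_series(rnorm(n), name = "y")
    lib <- embed_series(y, embedding_params(E, tau, tp))
    got <- cross_map_predict(x, lib, tp = tp)
    want <- oracle_cross_map(x$values, lib$vectors, lib$row_times, tp, E + 1)
    expect_equal(got$predictions, want$predictions, tolerance = 1e-12)
    expect_equal(got$observations, want$observations, tolerance = 1e-12)
    expect_equal(got$prediction_times, want$prediction_times)
  }
})

test_that("equidistant neighbors receive uniform simplex weights", {
  # library at E = 1 with two points equidistant from the query
  y <- uniform_series(c(0, 1, -1, 3, -3), name = "y")
  lib <- embed_series(y, embedding_params(E = 1, tau = 1, tp = 0))
  x <- uniform_series(c(10, 4, 8, 100, -100), name = "x")
  res <- cross_map_predict(x, lib, tp = 0)
  # query at t=0 (value 0): neighbors 1 and -1 tie at distance 1,
  # uniform weights 1/2 each -> prediction mean(4, 8) = 6
  expect_equal(res$predictions[res$prediction_times == 0], 6)
})

test_that("rho is recomputable from stored predictions and observations", {
  m <- coupled_maps(300, coupling = 0.4, seed = 3)
  res <- ccm_rho(m$x, m$y, embedding_params(E = 2, tau = 1, tp = 0))
  expect_equal(res$rho, cor(res$predictions, res$observations))
  expect_equal(res$n_pred, length(res$predictions))
})

test_that("noiseless self cross-map achieves near-perfect skill", {
  x <- uniform_series(logistic_map(500), name = "x")
  res <- ccm_rho(x, x, embedding_params(E = 2, tau = 1, tp = 0))
  expect_gt(res$rho, 0.99)
})

test_that("constant target is flagged degenerate, not scored zero", {
  y <- uniform_series(logistic_map(60), name = "y")
  x <- uniform_series(rep(1, 60), name = "x")
  res <- ccm_rho(x, y, embedding_params(E = 2, tau = 1, tp = 0))
  expect_true(res$degenerate)
  expect_true(is.na(res$rho))
})

test_that("cross-map skill is invariant to positive affine rescaling", {
  m <- coupled_maps(400, coupling = 0.35, seed = 7)
  p <- embedding_params(E = 3, tau = 1, tp = 0)
  base <- ccm_rho(m$x, m$y, p)$rho
  expect_equal(ccm_rho(5 + 2 * m$x, m$y, p)$rho, base, tolerance = 1e-12)
  expect_equal(ccm_rho(m$x, 3 * m$y - 1, p)$rho, base, tolerance = 1e-12)
})

test_that("CCM recovers the direction of forcing in coupled maps", {
  m <- coupled_maps(1000, coupling = 0.3, seed = 11)
  p <- embedding_params(E = 2, tau = 1, tp = 0)
  rho_xy <- ccm_rho(m$x, m$y, p)$rho  # evidence x -> y (true direction)
  rho_yx <- ccm_rho(m$y, m$x, p)$rho
  expect_gt(rho_xy, rho_yx)
})

test_that("lag-maximized absolute cross-correlation behaves as defined", {
  x <- sin(2 * pi * (1:200) / 20)
  expect_equal(as.numeric(max_abs_xcorr(x, x, max_lag = 5)), 1)
  expect_equal(as.numeric(max_abs_xcorr(x, -x, max_lag = 5)), 1)
  y <- c(rep(NA, 3), head(x, -3))  # x shifted by 3 samples
  y[seq_len(3)] <- x[seq_len(3)]   # pad to keep finite
  r <- max_abs_xcorr(x, y, max_lag = 5)
  expect_gt(as.numeric(r), 0.99)
  expect_equal(attr(r, "lag"), 3L)
  expect_error(max_abs_xcorr(rep(1, 50), rnorm(50), max_lag = 2),
               "constant")
})

test_that("ccm_scan with a single E equals the single cross-map call", {
  m <- coupled_maps(200, coupling = 0.4, seed = 5)
  sc <- ccm_scan(m$x, m$y, E_range = 3, tau = 1, tp = -1)
  single <- ccm_rho(m$x, m$y, embedding_params(3, 1, -1))
  expect_equal(sc$best$rho, single$rho)
  expect_equal(nrow(sc$table), 1L)
})

test_that("ccm_scan returns one row per feasible E and the best result", {
  m <- coupled_maps(300, coupling = 0.4, seed = 6)
  sc <- ccm_scan(m$x, m$y, E_range = 1:5, tau = 1, tp = 0)
  expect_equal(sc$table$E, 1:5)
  expect_equal(sc$best$rho, max(sc$table$rho))
  expect_error(ccm_scan(rnorm(5), rnorm(5), E_range = 50, tau = 10),
               "feasible")
})

test_that("library sweep at full size equals the full-library skill", {
  m <- coupled_maps(250, coupling = 0.4, seed = 9)
  p <- embedding_params(E = 2, tau = 1, tp = 0)
  full <- ccm_rho(m$x, m$y, p)$rho
  n_avail <- 250 - 1  # rows for E = 2, tau = 1
  sw <- ccm_library_sweep(m$x, m$y, p, library_sizes = n_avail,
                          n_samples = 3, seed = 1)
  expect_equal(sw$mean_rho, full, tolerance = 1e-12)
  expect_error(
    ccm_library_sweep(m$x, m$y, p, library_sizes = 3, n_samples = 2, seed = 1),
    "E \\+ 2")
})

test_that("cross-map skill converges with library size under coupling", {
  m <- coupled_maps(600, coupling = 0.4, seed = 13)
  p <- embedding_params(E = 2, tau = 1, tp = 0)
  sw <- ccm_library_sweep(m$x, m$y, p, library_sizes = c(20, 80, 400),
                          n_samples = 15, seed = 2)
  expect_true(sw$mean_rho[3] > sw$mean_rho[1])
})

test_that("independent white noise shows no cross-map skill", {
  set.seed(21)
  x <- rnorm(500); y <- rnorm(500)
  p <- embedding_params(E = 3, tau = 1, tp = 0)
  obs <- ccm_rho(x, y, p)$rho
  null <- replicate(30, ccm_rho(sample(x), y, p)$rho)
  expect_lt(abs(obs), quantile(abs(null), 0.95) + 0.05)
})
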