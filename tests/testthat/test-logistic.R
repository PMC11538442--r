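test_that("interaction matrices have the prescribed density and signs", {
  for (C in c(0, 0.5, 1)) {
    cfg <- logistic_config(connectance = C, seed = 3)
    m <- make_interactions(cfg)
    expect_equal(sum(m$A_PP != 0), round(C * 100))
    expect_equal(sum(m$A_RP != 0), round(C * 100))
    expect_true(all(m$A_PP <= 0))
    expect_true(all(m$A_RP >= 0))
  }
  nz <- abs(make_interactions(logistic_config(0.5, seed = 1))$A_PP)
  nz <- nz[nz > 0]
  expect_true(all(nz >= 0.05 & nz <= 0.15))
})

test_that("the reciprocal constraint folds values above 1 and is idempotent", {
  v <- c(-2, 0.3, 1, 2.5, 10)
  w <- ccmweb:::reciprocal_constraint(v)
  expect_equal(w, c(-2, 0.3, 1, 0.4, 0.1))
  expect_equal(ccmweb:::reciprocal_constraint(w), w)
  expect_true(all(w <= 1))
})

test_that("with zero connectance every series decays geometrically", {
  cfg <- logistic_config(connectance = 0, n_steps = 30L, burn_in = 0L,
                         seed = 5)
  series <- simulate_logistic(cfg)
  init <- ccmweb:::with_seed(cfg$seed + 1L, runif(20, 0.1, 1))
  for (j in seq_along(series)) {
    expect_equal(series[[j]]$values, init[j] * 0.85^(1:30), tolerance = 1e-12)
  }
})

test_that("simulated series are reproducible and labeled by guild", {
  cfg <- logistic_config(connectance = 0.6, seed = 11)
  a <- simulate_logistic(cfg)
  b <- simulate_logistic(cfg)
  expect_identical(lapply(a, `[[`, "values"), lapply(b, `[[`, "values"))
  expect_equal(attr(a, "roles"), rep(c("prey", "pred"), each = 10))
  expect_length(a[[1]]$values, 500L)
})

test_that("aggregates are pointwise sums and skill is scale-invariant", {
  cfg <- logistic_config(connectance = 0.6, seed = 2)
  series <- simulate_logistic(cfg)
  vals <- sapply(series, function(s) s$values)
  roles <- attr(series, "roles")
  rec <- aggregate_and_score(series, connectance = 0.6, seed = 2)
  # doubling all prey series doubles the aggregate but not the skill
  doubled <- series
  for (j in which(roles == "prey")) {
    doubled[[j]] <- uniform_series(2 * series[[j]]$values,
                                   name = series[[j]]$name)
  }
  attr(doubled, "roles") <- roles
  rec2 <- aggregate_and_score(doubled, connectance = 0.6, seed = 2)
  expect_equal(rec2$rho, rec$rho, tolerance = 1e-12)
})

test_that("an uncoupled model yields no aggregate cross-map skill", {
  cfg <- logistic_config(connectance = 0, seed = 8)
  rec <- aggregate_and_score(simulate_logistic(cfg), connectance = 0, seed = 8)
  expect_true(rec$degenerate || abs(rec$rho) < 0.5)
})

test_that("the connectance sweep is reproducible and preserves signs", {
  s1 <- connectance_sweep(n_sims = 6, config = logistic_config(0.3, seed = 1),
                          seed = 99)
  s2 <- connectance_sweep(n_sims = 6, config = logistic_config(0.3, seed = 1),
                          seed = 99)
  expect_identical(s1$table, s2$table)
  expect_equal(nrow(s1$table), 6L)
  expect_true(all(s1$table$connectance >= 0.3 & s1$table$connectance <= 0.9))
  expect_true(s1$low_n == (sum(!s1$table$degenerate) < 10))
})

test_that("a two-simulation sweep still reports a (flagged) correlation", {
  s <- connectance_sweep(n_sims = 2, config = logistic_config(0.3, seed = 1),
                         seed = 5)
  expect_equal(nrow(s$table), 2L)
  expect_true(s$low_n)
})
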