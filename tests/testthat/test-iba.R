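# small worlds keep these tests fast; dynamics-scale behavior is exercised
# in the acceptance suite
small_cfg <- function(seed = 1, n_steps = 50L, ...) {
  iba_config(grid_size = 200, n_resources0 = 600L, n_pc0 = 60L, n_sc0 = 3L,
             resource_influx = 20L, sc_window = 20L,
             sc_survival_threshold = 10L, sc_repro_threshold = 20L,
             sc_repro_refractory = 10L, n_steps = n_steps, seed = seed, ...)
}

test_that("config validation rejects inconsistent parameterizations", {
  expect_error(iba_config(grid_size = -1), "grid_size")
  expect_error(iba_config(n_pc0 = -5), ">= 0")
  expect_error(iba_config(sc_repro_threshold = 10, sc_survival_threshold = 20),
               "sc_repro_threshold")
  expect_error(iba_config(speed_r = 0), "> 0")
})

test_that("world initialization honors counts, bounds and the seed", {
  cfg <- iba_config(n_steps = 1L)
  w <- init_world(cfg)
  expect_length(w$rx, 15000L)
  expect_length(w$pcx, 1500L)
  expect_length(w$scx, 20L)
  expect_true(all(w$rx >= 0 & w$rx < cfg$grid_size))
  expect_identical(init_world(cfg), w)      # same seed, same world
  # degenerate: a world without secondary consumers is legal
  w0 <- init_world(iba_config(n_sc0 = 0L, n_steps = 1L))
  expect_length(w0$scx, 0L)
  expect_equal(ncol(w0$sc_hist), 0L)
})

test_that("identical seed and config give bit-identical abundance series", {
  a <- run_iba(small_cfg(seed = 7, n_steps = 120L))
  b <- run_iba(small_cfg(seed = 7, n_steps = 120L))
  expect_identical(a$records, b$records)
  d <- run_iba(small_cfg(seed = 8, n_steps = 120L))
  expect_false(identical(a$records$resources, d$records$resources))
})

test_that("per-step resource ledger balances exactly", {
  run <- run_iba(small_cfg(seed = 2, n_steps = 150L))
  r <- run$records
  before <- c(small_cfg()$n_resources0, head(r$resources, -1))
  expect_equal(r$resources, before - r$resources_eaten + small_cfg()$resource_influx)
  expect_true(all(r$resources >= 0 & r$primary_consumers >= 0 &
                  r$secondary_consumers >= 0))
})

test_that("prey consumed per step never exceeds prey present", {
  run <- run_iba(small_cfg(seed = 3, n_steps = 150L))
  r <- run$records
  pc_before <- c(small_cfg()$n_pc0, head(r$primary_consumers, -1))
  # a PC present before the step can be eaten at most once
  expect_true(all(r$pc_eaten_by_sc <= pc_before))
  r_before <- c(small_cfg()$n_resources0, head(r$resources, -1))
  expect_true(all(r$resources_eaten <= r_before))
})

test_that("the spatial index reproduces exhaustive search exactly", {
  a <- run_iba(small_cfg(seed = 5, n_steps = 200L, spatial_index = TRUE))
  b <- run_iba(small_cfg(seed = 5, n_steps = 200L, spatial_index = FALSE))
  expect_identical(a$records, b$records)
  expect_identical(a$final_state, b$final_state)
})

test_that("stepping a world forward matches a single continuous run", {
  cfg <- small_cfg(seed = 9, n_steps = 80L)
  full <- run_iba(cfg)
  set.seed(cfg$seed)
  w <- ccmweb:::new_world(cfg)
  part1 <- iba_step(w, cfg, n_steps = 30L)
  part2 <- iba_step(part1$world, cfg, n_steps = 50L)
  expect_equal(rbind(part1$records, part2$records), full$records,
               ignore_attr = TRUE)
})

test_that("a resource-consumer pair persists without secondary consumers", {
  alive <- 0L
  for (seed in 1:3) {
    run <- run_iba(iba_config(seed = seed, n_sc0 = 0L, n_steps = 2000L))
    r <- run$records
    if (min(r$primary_consumers) > 0 && min(r$resources) > 0) alive <- alive + 1L
  }
  expect_gte(alive, 2L)
})

test_that("movement variants and consumption rules stay on the torus", {
  for (mv in c("axis", "radial", "axis_fixed", "mix")) {
    run <- run_iba(small_cfg(seed = 4, n_steps = 30L, movement = mv))
    st <- run$final_state
    expect_true(all(st$rx >= 0 & st$rx < 200 & st$ry >= 0 & st$ry < 200))
  }
})

test_that("the slow web refuses series too short for its embedding", {
  s <- lapply(c("resources", "primary_consumers", "secondary_consumers"),
              function(nm) uniform_series(rnorm(300), name = nm))
  expect_error(iba_causal_webs(s, E_range = 1:10, tau_slow = 500L),
               "too short")
})

test_that("run output series mirror the records", {
  run <- run_iba(small_cfg(seed = 6, n_steps = 100L))
  expect_length(run$series$resources$values, 100L)
  expect_equal(run$series$primary_consumers$values,
               as.numeric(run$records$primary_consumers))
  expect_equal(run$series$secondary_consumers$name, "secondary_consumers")
})
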