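seasonal_series <- function(n_years = 10, seed = 1, name = "s") {
  set.seed(seed)
  n <- 12 * n_years
  v <- pmax(sin(2 * pi * (1:n) / 12) + 1.2 + rnorm(n, 0, 0.3), 0)
  uniform_series(v, month_labels = rep(1:12, n_years), name = name)
}

test_that("sqrt-min-max normalization maps onto [0, 1] as stated", {
  expect_equal(normalize_sqrt(uniform_series(c(0, 1, 4)))$values,
               c(0, 0.5, 1))
  expect_equal(normalize_sqrt(uniform_series(c(5, 5, 9)))$values,
               c(0, 0, 1))
  expect_error(normalize_sqrt(uniform_series(c(3, 3, 3))), "zero range")
  x <- normalize_sqrt(uniform_series(rlnorm(100, 0, 2)))
  expect_true(all(x$values >= 0 & x$values <= 1))
})

test_that("group aggregation gives members equal weight", {
  a <- uniform_series(c(0, 5, 10), name = "a")
  b <- uniform_series(c(100, 300, 200), name = "b")
  # single member: plain min-max normalization
  expect_equal(aggregate_group(list(a))$values, c(0, 0.5, 1))
  agg <- aggregate_group(list(a, b))
  expect_equal(agg$values, c(0 + 0, 0.5 + 1, 1 + 0.5))
  # identical members: aggregate is twice the normalized series
  expect_equal(aggregate_group(list(a, a))$values, 2 * c(0, 0.5, 1))
  expect_error(aggregate_group(list()), "empty")
  expect_error(aggregate_group(list(uniform_series(c(1, 1)))), "constant")
})

test_that("seasonal surrogates permute only within calendar months", {
  x <- seasonal_series(n_years = 5, seed = 3)
  surr <- seasonal_surrogates(x, n_surrogates = 20, seed = 9)
  expect_length(surr, 20L)
  for (s in surr[1:5]) {
    for (m in 1:12) {
      i <- which(x$month_labels == m)
      expect_equal(sort(s$values[i]), sort(x$values[i]))
    }
  }
  # one sample per month: singleton blocks force identity
  x1 <- uniform_series(rnorm(12), month_labels = 1:12)
  s1 <- seasonal_surrogates(x1, n_surrogates = 3, seed = 1)
  expect_equal(s1[[2]]$values, x1$values)
  expect_error(seasonal_surrogates(uniform_series(rnorm(24)), 5, 1),
               "month_labels")
})

test_that("the surrogate link test applies the 95-of-100 rule", {
  p <- make_seasonal_pair(seasonal_config(n_years = 20, coupling = 0.5,
                                          seed = 4))
  params <- embedding_params(E = 3, tau = 1, tp = 0)
  link <- surrogate_link_test(p$X, p$Y, params, n_surrogates = 50,
                              min_exceeded = 48, seed = 2)
  expect_true(link$accepted)
  expect_gte(link$null_value, 48)
  # a vacuous threshold always accepts
  link0 <- surrogate_link_test(p$Y, p$X, params, n_surrogates = 10,
                               min_exceeded = 0, seed = 2)
  expect_true(link0$accepted)
})

test_that("build_network records every ordered pair exactly once", {
  m <- coupled_maps(300, coupling = 0.4, seed = 2)
  net <- build_network(list(x = m$x, y = m$y),
                       params = embedding_params(3, 1, -1),
                       null_kind = "xcorr", E_range = 1:3)
  expect_s3_class(net, "causal_network")
  expect_equal(nrow(net$links), 2L)
  expect_setequal(net$nodes, c("x", "y"))
  # accepted links re-verify their stated rule
  acc <- net$links[net$links$accepted, ]
  if (nrow(acc) > 0) {
    expect_true(all(acc$rho > acc$null_value & acc$rho > 0))
  }
})

test_that("network output is invariant to input series ordering", {
  set.seed(31)
  s <- list(a = uniform_series(rnorm(120), name = "a"),
            b = uniform_series(rnorm(120), name = "b"),
            c = uniform_series(rnorm(120), name = "c"))
  p <- embedding_params(2, 1, -1)
  n1 <- build_network(s, p, null_kind = "xcorr", E_range = 1:2)
  n2 <- build_network(s[c(3, 1, 2)], p, null_kind = "xcorr", E_range = 1:2)
  expect_equal(n1$links, n2$links)
})

test_that("untestable pairs are flagged rather than dropped", {
  s <- list(long = uniform_series(rnorm(100), name = "long"),
            flat = uniform_series(rep(2, 100), name = "flat"))
  net <- build_network(s, embedding_params(2, 1, -1), null_kind = "xcorr",
                       E_range = 1:2)
  expect_equal(nrow(net$links), 2L)
  expect_true(all(!net$links$accepted))
  expect_true(any(net$links$untestable | net$links$degenerate))
})

test_that("multiscale comparison partitions accepted links correctly", {
  mk <- function(links_accepted, label) {
    links <- do.call(rbind, lapply(links_accepted, function(st) {
      ccmweb:::causal_link(st[1], st[2], 0.9, "xcorr", 0.1, TRUE, 2L, 1L, 0L)
    }))
    ccmweb:::new_causal_network(c("a", "b", "c"), links, label)
  }
  nA <- mk(list(c("a", "b"), c("b", "c")), "tau=1")
  nB <- mk(list(c("b", "c"), c("c", "a")), "tau=12")
  cmp <- multiscale_compare(nA, nB)
  expect_equal(cmp$both, "b -> c")
  expect_equal(cmp$A_only, "a -> b")
  expect_equal(cmp$B_only, "c -> a")
  expect_equal(multiscale_compare(nA, nA)$B_only, character(0))
  nC <- mk(list(c("a", "b")), "x")
  nC$nodes <- c("a", "b", "d")
  expect_error(multiscale_compare(nA, nC), "node sets differ")
})

test_that("fine-scale connectance counts realized cross-group links", {
  links <- do.call(rbind, lapply(
    list(c("a1", "b1"), c("a1", "b2"), c("b3", "a2"), c("b1", "b2"),
         c("a1", "a2")),
    function(st) ccmweb:::causal_link(st[1], st[2], .9, "xcorr", .1, TRUE,
                                      2L, 1L, 0L)))
  net <- ccmweb:::new_causal_network(
    c("a1", "a2", "b1", "b2", "b3"), links, "tau=1")
  A <- c("a1", "a2"); B <- c("b1", "b2", "b3")
  # 3 cross links of 2 * 2 * 3 = 12 possible
  expect_equal(fine_scale_connectance(net, A, B), 3 / 12)
  expect_equal(fine_scale_connectance(net, B, A), 3 / 12)
  expect_equal(fine_scale_connectance(net, "a2", "b2"), 0)
  expect_error(fine_scale_connectance(net, A, c("a1", "b1")), "overlap")
})

test_that("linked/unlinked comparison runs a one-sided Welch t-test", {
  grp <- stats::setNames(paste0("group", rep(1:3, each = 3)),
                         paste0("s", 1:9))
  members <- split(names(grp), grp)
  # species net: many links from group1 members to group2 members
  sp_links <- do.call(rbind, c(
    lapply(members$group1, function(a) {
      do.call(rbind, lapply(members$group2, function(b) {
        ccmweb:::causal_link(a, b, .9, "xcorr", .1, TRUE, 2L, 1L, 0L)
      }))
    }),
    lapply(members$group1, function(a) {
      do.call(rbind, lapply(members$group3, function(b) {
        ccmweb:::causal_link(a, b, .8, "xcorr", .1, TRUE, 2L, 1L, 0L)
      }))
    }),
    list(ccmweb:::causal_link("s7", "s1", .9, "xcorr", .1, TRUE, 2L, 1L, 0L))
  ))
  sp_net <- ccmweb:::new_causal_network(names(grp), sp_links, "tau=1")
  agg_links <- rbind(
    ccmweb:::causal_link("group1", "group2", .9, "xcorr", .1, TRUE, 2L, 1L, 0L),
    ccmweb:::causal_link("group1", "group3", .8, "xcorr", .1, TRUE, 2L, 1L, 0L),
    ccmweb:::causal_link("group2", "group3", .4, "xcorr", .5, FALSE, 2L, 1L, 0L))
  agg_net <- ccmweb:::new_causal_network(paste0("group", 1:3), agg_links,
                                         "aggregate")
  res <- linked_vs_unlinked_test(agg_net, sp_net, grp)
  expect_equal(nrow(res$counts), 6L)
  expect_gt(res$mean_linked, res$mean_unlinked)
  expect_lt(res$p_value, 0.05)
})

test_that("food-web overlay categorizes directed edges per direction", {
  links <- rbind(
    ccmweb:::causal_link("x", "y", .9, "xcorr", .1, TRUE, 2L, 1L, 0L),
    ccmweb:::causal_link("y", "x", .8, "xcorr", .1, TRUE, 2L, 1L, 0L),
    ccmweb:::causal_link("x", "z", .7, "xcorr", .1, TRUE, 2L, 1L, 0L))
  net <- ccmweb:::new_causal_network(c("x", "y", "z"), links, "agg")
  # trophic edge y eats z; x->y trophic too
  cmp <- compare_foodweb(net, data.frame(source = c("x", "y"),
                                         target = c("y", "z")))
  expect_setequal(cmp$category[cmp$source == "x" & cmp$target == "y"],
                  "causal_and_trophic")
  # y->x causal matches trophic x->y in reverse direction
  expect_setequal(cmp$category[cmp$source == "y" & cmp$target == "x"],
                  "causal_and_trophic")
  expect_setequal(cmp$category[cmp$source == "x" & cmp$target == "z"],
                  "causal_only")
  expect_setequal(cmp$category[cmp$source == "y" & cmp$target == "z"],
                  "trophic_only")
  # empty trophic list: everything causal_only
  cmp0 <- compare_foodweb(net, data.frame(source = character(0),
                                          target = character(0)))
  expect_true(all(cmp0$category == "causal_only"))
  expect_error(compare_foodweb(net, data.frame(source = "q", target = "x")),
               "q")
})
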