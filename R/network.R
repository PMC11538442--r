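#' Square-root min-max normalization
#'
#' Rescales a series to `[0, 1]` (min to 0, max to 1) and then takes the
#' square root of each value. Abundance series often spike over several
#' orders of magnitude; the square root damps the influence of those spikes
#' on nearest-neighbor distances in the reconstructed state space.
#'
#' @param x A [uniform_series()] (or numeric vector) with at least two
#'   distinct values.
#' @return A [uniform_series()] with values in `[0, 1]`.
#' @export
#' @examples
#' normalize_sqrt(uniform_series(c(0, 1, 4)))$values  # 0, 0.5, 1
normalize_sqrt <- function(x) {
  x <- as_uniform_series(x)
  v <- x$values
  rng <- range(v, na.rm = TRUE)
  if (!all(is.finite(rng)) || rng[1L] == rng[2L]) {
    stop("series `", x$name, "` has zero range; normalization undefined")
  }
  uniform_series(sqrt((v - rng[1L]) / (rng[2L] - rng[1L])),
                 time_index = x$time_index, month_labels = x$month_labels,
                 name = x$name)
}

#' Aggregate a set of series into one functional-group series
#'
#' Each member series is min-max normalized to `[0, 1]` (no square root at
#' this stage) and the normalized series are summed pointwise, giving every
#' species equal contribution to the aggregate regardless of absolute
#' abundance.
#'
#' @param series List of [uniform_series()] with aligned time indices.
#' @param name Name of the aggregate series.
#' @return A [uniform_series()] with values in `[0, k]` for `k` members.
#' @export
aggregate_group <- function(series, name = "aggregate") {
  if (length(series) == 0L) stop("cannot aggregate an empty group")
  series <- lapply(series, as_uniform_series)
  for (s in series[-1L]) check_aligned(series[[1L]], s)
  norm <- lapply(series, function(s) {
    rng <- range(s$values, na.rm = TRUE)
    if (!all(is.finite(rng)) || rng[1L] == rng[2L]) {
      stop("series `", s$name, "` is constant; cannot normalize for aggregation")
    }
    (s$values - rng[1L]) / (rng[2L] - rng[1L])
  })
  uniform_series(Reduce(`+`, norm), time_index = series[[1L]]$time_index,
                 month_labels = series[[1L]]$month_labels, name = name)
}

#' Aggregate series by a functional-group map
#'
#' @param series Named list of [uniform_series()].
#' @param group_map Named character vector or list mapping series name to
#'   functional-group name.
#' @return Named list of aggregate [uniform_series()], one per group.
#' @export
aggregate_by_groups <- function(series, group_map) {
  group_map <- unlist(group_map)
  nm <- vapply(series, function(s) s$name, character(1L))
  names(series) <- nm
  missing <- setdiff(names(group_map), nm)
  if (length(missing) > 0L) {
    stop("group map names absent from series: ", paste(missing, collapse = ", "))
  }
  groups <- split(names(group_map), unname(group_map))
  lapply_named <- lapply(names(groups), function(g) {
    aggregate_group(series[groups[[g]]], name = g)
  })
  names(lapply_named) <- names(groups)
  lapply_named
}

#' Seasonal (within-month) surrogate series
#'
#' Generates null series that preserve the seasonal structure of `x` while
#' destroying all other temporal dependence, by permuting the observed
#' values within each calendar month (all January values shuffled among
#' January sampling dates, and so on).
#'
#' @param x A [uniform_series()] with `month_labels`.
#' @param n_surrogates Number of independent surrogate series.
#' @param seed RNG seed.
#' @return List of `n_surrogates` [uniform_series()].
#' @export
seasonal_surrogates <- function(x, n_surrogates = 100L, seed = 1L) {
  x <- as_uniform_series(x)
  if (is.null(x$month_labels)) {
    stop("series `", x$name, "` has no month_labels; seasonal surrogates undefined")
  }
  idx_by_month <- split(seq_along(x$values), x$month_labels)
  with_seed(seed, {
    lapply(seq_len(n_surrogates), function(k) {
      v <- x$values
      for (ii in idx_by_month) v[ii] <- v[ii][sample.int(length(ii))]
      uniform_series(v, time_index = x$time_index,
                     month_labels = x$month_labels,
                     name = paste0(x$name, "_surr", k))
    })
  })
}

causal_link <- function(source, target, rho, null_kind, null_value, accepted,
                        E_used, tau, tp, degenerate = FALSE,
                        untestable = FALSE) {
  data.frame(source = source, target = target, rho = rho,
             null_kind = null_kind, null_value = null_value,
             accepted = accepted, E_used = as.integer(E_used),
             tau = as.integer(tau), tp = as.integer(tp),
             degenerate = degenerate, untestable = untestable,
             stringsAsFactors = FALSE)
}

#' Seasonal-surrogate significance test for one directed link
#'
#' Computes the cross-map skill for `X` causing `Y` (see [ccm_rho()]), then
#' recomputes it with the shuffled side replaced by each of `n_surrogates`
#' within-month surrogates. The link is accepted when the actual skill
#' strictly exceeds at least `min_exceeded` of the surrogate skills.
#' Degenerate surrogate skills count as exceeded; if more than 10% of
#' surrogates are degenerate the result is flagged.
#'
#' @param X Putative driver (the series that is cross-mapped/predicted).
#' @param Y Putative response (the series that is embedded).
#' @param params [embedding_params()] for the cross map.
#' @param n_surrogates,min_exceeded The acceptance rule: with the defaults a
#'   link must beat 95 of 100 surrogates.
#' @param seed RNG seed for the surrogate permutations.
#' @param shuffle Which side is replaced by surrogates: the driver `X`
#'   (default) or the response `Y`.
#' @return A one-row `causal_link` data.frame; `null_value` is the number of
#'   surrogates exceeded.
#' @export
surrogate_link_test <- function(X, Y, params, n_surrogates = 100L,
                                min_exceeded = 95L, seed = 1L,
                                shuffle = c("driver", "response")) {
  shuffle <- match.arg(shuffle)
  X <- as_uniform_series(X, "X"); Y <- as_uniform_series(Y, "Y")
  actual <- ccm_rho(X, Y, params)
  side <- if (shuffle == "driver") X else Y
  surr <- seasonal_surrogates(side, n_surrogates = n_surrogates, seed = seed)
  surr_rho <- vapply(surr, function(s) {
    r <- if (shuffle == "driver") ccm_rho(s, Y, params) else ccm_rho(X, s, params)
    if (r$degenerate) -Inf else r$rho
  }, numeric(1L))
  n_degen <- sum(!is.finite(surr_rho))
  n_exceeded <- if (actual$degenerate) 0L else sum(actual$rho > surr_rho)
  accepted <- !actual$degenerate && n_exceeded >= min_exceeded
  causal_link(X$name, Y$name, rho = actual$rho,
              null_kind = "seasonal_surrogate", null_value = n_exceeded,
              accepted = accepted, E_used = params$E, tau = params$tau,
              tp = params$tp,
              degenerate = actual$degenerate ||
                n_degen > 0.1 * n_surrogates)
}

new_causal_network <- function(nodes, links, scale_label) {
  rownames(links) <- NULL
  structure(list(nodes = nodes, links = links, scale_label = scale_label),
            class = "causal_network")
}

#' @export
print.causal_network <- function(x, ...) {
  cat(sprintf("<causal_network> %s: %d nodes, %d/%d links accepted\n",
              x$scale_label, length(x$nodes), sum(x$links$accepted),
              nrow(x$links)))
  invisible(x)
}

#' Build a causal interaction network over a set of series
#'
#' Tests every ordered pair of series for a directed cross-map link at one
#' timescale. Two null procedures are available: `"xcorr"` accepts a link
#' when the skill maximized over `E_range` is positive and exceeds the
#' maximum absolute lagged cross-correlation of the pair (used for model
#' data), and `"seasonal_surrogate"` applies the within-month surrogate rule
#' of [surrogate_link_test()] at the single `params$E` (used for monthly
#' field-style data). Every tested link is recorded, accepted or not; pairs
#' failing length preconditions are flagged untestable rather than dropped.
#'
#' @param series List of [uniform_series()] (at least 2).
#' @param params [embedding_params()] giving `E`, `tau`, `tp`.
#' @param null_kind `"xcorr"` or `"seasonal_surrogate"`.
#' @param group_map Optional named map series name -> group; when supplied,
#'   series are aggregated with [aggregate_by_groups()] before testing.
#' @param E_range For the `"xcorr"` null: embedding dimensions scanned per
#'   link (default the single `params$E`).
#' @param max_lag Lag span of the cross-correlation null; default
#'   `(max(E_range) - 1) * tau`, the temporal span of the embedding. Use
#'   `0` for the lag-0 correlation only.
#' @param n_surrogates,min_exceeded,seed Surrogate-null settings.
#' @param shuffle Side shuffled by the surrogate null (see
#'   [surrogate_link_test()]).
#' @param normalize Apply [normalize_sqrt()] to each (possibly aggregated)
#'   series before testing.
#' @param max_queries Passed to [cross_map_predict()] for the `"xcorr"`
#'   null: cap on the number of prediction points per cross map (`0` =
#'   all).
#' @param scale_label Label stored on the network (defaults to
#'   `"tau=<tau>"`).
#' @return A `causal_network`: list with `nodes`, `links` (one row per
#'   ordered pair) and `scale_label`.
#' @export
build_network <- function(series, params,
                          null_kind = c("xcorr", "seasonal_surrogate"),
                          group_map = NULL, E_range = NULL, max_lag = NULL,
                          n_surrogates = 100L, min_exceeded = 95L,
                          seed = 1L, shuffle = "driver", normalize = TRUE,
                          scale_label = NULL, max_queries = 0L) {
  null_kind <- match.arg(null_kind)
  stopifnot(inherits(params, "embedding_params"))
  series <- lapply(seq_along(series), function(i) {
    as_uniform_series(series[[i]], names(series)[i] %||% paste0("s", i))
  })
  if (length(series) < 2L) stop("need at least 2 series to build a network")
  if (!is.null(group_map)) {
    names(series) <- vapply(series, function(s) s$name, character(1L))
    series <- aggregate_by_groups(series, group_map)
  }
  if (normalize) {
    # a constant series cannot be rescaled; keep it as-is so its links are
    # recorded as degenerate/untestable instead of failing the whole web
    series <- lapply(series, function(s) {
      tryCatch(normalize_sqrt(s), error = function(e) s)
    })
  }
  nodes <- vapply(series, function(s) s$name, character(1L))
  if (anyDuplicated(nodes)) stop("duplicate series names: ",
                                 paste(nodes[duplicated(nodes)], collapse = ", "))
  E_range <- as.integer(E_range %||% params$E)
  max_lag <- as.integer(max_lag %||% ((max(E_range) - 1L) * params$tau))
  pairs <- expand.grid(src = seq_along(series), tgt = seq_along(series))
  pairs <- pairs[pairs$src != pairs$tgt, ]
  links <- lapply(seq_len(nrow(pairs)), function(k) {
    i <- pairs$src[k]; j <- pairs$tgt[k]
    X <- series[[i]]; Y <- series[[j]]
    tryCatch({
      if (null_kind == "xcorr") {
        scan <- ccm_scan(X, Y, E_range = E_range, tau = params$tau,
                         tp = params$tp, max_queries = max_queries)
        best <- scan$best
        xc <- max_abs_xcorr(X, Y, max_lag = max_lag)
        accepted <- !best$degenerate && is.finite(best$rho) &&
          best$rho > 0 && best$rho > as.numeric(xc)
        causal_link(X$name, Y$name, rho = best$rho, null_kind = "xcorr",
                    null_value = as.numeric(xc), accepted = accepted,
                    E_used = best$params$E, tau = params$tau, tp = params$tp,
                    degenerate = best$degenerate)
      } else {
        # per-pair surrogate seed keeps pairs independent yet reproducible
        surrogate_link_test(X, Y, params, n_surrogates = n_surrogates,
                            min_exceeded = min_exceeded,
                            seed = seed + 7919L * k, shuffle = shuffle)
      }
    }, error = function(e) {
      causal_link(X$name, Y$name, rho = NA_real_, null_kind = null_kind,
                  null_value = NA_real_, accepted = FALSE,
                  E_used = params$E, tau = params$tau, tp = params$tp,
                  untestable = TRUE)
    })
  })
  links <- do.call(rbind, links)
  links <- links[order(links$source, links$target), ]
  new_causal_network(sort(nodes), links,
                     scale_label %||% paste0("tau=", params$tau))
}

accepted_pairs <- function(net) {
  l <- net$links[net$links$accepted, c("source", "target")]
  paste(l$source, l$target, sep = " -> ")
}

#' Compare two causal networks built at different scales
#'
#' Partitions the union of accepted links of two networks over the same node
#' set into links present in both, only in the first, and only in the
#' second.
#'
#' @param netA,netB `causal_network` objects over identical node sets.
#' @return List of character vectors `both`, `A_only`, `B_only`
#'   (`"source -> target"`), plus `labels` carrying the two scale labels.
#' @export
multiscale_compare <- function(netA, netB) {
  stopifnot(inherits(netA, "causal_network"), inherits(netB, "causal_network"))
  if (!setequal(netA$nodes, netB$nodes)) {
    stop("node sets differ: only in first: {",
         paste(setdiff(netA$nodes, netB$nodes), collapse = ", "),
         "}; only in second: {",
         paste(setdiff(netB$nodes, netA$nodes), collapse = ", "), "}")
  }
  a <- accepted_pairs(netA); b <- accepted_pairs(netB)
  list(both = sort(intersect(a, b)),
       A_only = sort(setdiff(a, b)),
       B_only = sort(setdiff(b, a)),
       labels = c(netA$scale_label, netB$scale_label))
}

#' Fine-scale connectance between two groups of species
#'
#' The proportion of potential directed species-level links between two
#' disjoint groups that are realized (accepted) in a species-resolution
#' network: accepted cross-group links divided by `2 * |A| * |B|`.
#'
#' @param species_net A `causal_network` at species resolution.
#' @param groupA,groupB Disjoint non-empty character vectors of node names.
#' @return A number in `[0, 1]`, symmetric in the two groups.
#' @export
fine_scale_connectance <- function(species_net, groupA, groupB) {
  stopifnot(inherits(species_net, "causal_network"))
  groupA <- unique(as.character(groupA)); groupB <- unique(as.character(groupB))
  if (length(groupA) == 0L || length(groupB) == 0L) {
    stop("groups must be non-empty")
  }
  if (length(intersect(groupA, groupB)) > 0L) {
    stop("groups overlap: ", paste(intersect(groupA, groupB), collapse = ", "))
  }
  l <- species_net$links[species_net$links$accepted, ]
  n_cross <- sum((l$source %in% groupA & l$target %in% groupB) |
                 (l$source %in% groupB & l$target %in% groupA))
  n_cross / (2 * length(groupA) * length(groupB))
}

#' Do causally linked aggregates have more fine-scale links?
#'
#' Classifies every ordered pair of functional-group aggregates as linked or
#' unlinked according to the aggregate-resolution network, counts the
#' accepted species-level links each pair spans in the species-resolution
#' network, and compares the two count distributions with a one-sided Welch
#' t-test (alternative: linked pairs have more fine-scale links).
#'
#' @param aggregate_net `causal_network` over functional-group aggregates.
#' @param species_net `causal_network` over individual series.
#' @param group_map Named map species name -> group name covering the
#'   species-network nodes.
#' @return List with `counts` (per ordered aggregate pair: class and
#'   fine-scale link count), `mean_linked`, `mean_unlinked`, `t_statistic`,
#'   `p_value` (NA with a message when either class has fewer than 2 pairs).
#' @export
linked_vs_unlinked_test <- function(aggregate_net, species_net, group_map) {
  stopifnot(inherits(aggregate_net, "causal_network"),
            inherits(species_net, "causal_network"))
  group_map <- unlist(group_map)
  groups <- aggregate_net$nodes
  members <- split(names(group_map), unname(group_map))
  missing <- setdiff(groups, names(members))
  if (length(missing) > 0L) {
    stop("aggregate nodes without members in group_map: ",
         paste(missing, collapse = ", "))
  }
  agg_links <- accepted_pairs(aggregate_net)
  sp <- species_net$links[species_net$links$accepted, ]
  pairs <- expand.grid(src = groups, tgt = groups, stringsAsFactors = FALSE)
  pairs <- pairs[pairs$src != pairs$tgt, ]
  counts <- data.frame(
    source = pairs$src, target = pairs$tgt,
    linked = paste(pairs$src, pairs$tgt, sep = " -> ") %in% agg_links,
    fine_links = mapply(function(a, b) {
      sum(sp$source %in% members[[a]] & sp$target %in% members[[b]])
    }, pairs$src, pairs$tgt)
  )
  rownames(counts) <- NULL
  x <- counts$fine_links[counts$linked]
  y <- counts$fine_links[!counts$linked]
  out <- list(counts = counts, mean_linked = mean(x), mean_unlinked = mean(y),
              t_statistic = NA_real_, p_value = NA_real_)
  if (length(x) >= 2L && length(y) >= 2L && (sd(x) > 0 || sd(y) > 0)) {
    tt <- t.test(x, y, alternative = "greater", var.equal = FALSE)
    out$t_statistic <- unname(tt$statistic)
    out$p_value <- tt$p.value
  } else {
    message("fewer than 2 pairs in a class (or zero variance); ",
            "reporting descriptive summary only")
  }
  out
}

#' Overlay a causal network on a trophic (food-web) edge list
#'
#' Partitions directed edges into those that are both causal and trophic,
#' causal only, and trophic only. A trophic edge A-eats-B is matched against
#' causal links in either direction (a feeding relation is expected to
#' induce causal influence both ways), and the match is reported per
#' direction.
#'
#' @param causal_net A `causal_network`.
#' @param trophic_edges data.frame with columns `source`, `target` (directed
#'   consumer-resource edges). All nodes must appear in the network.
#' @return data.frame with columns `source`, `target`, `category` in
#'   `{"causal_and_trophic", "causal_only", "trophic_only"}`.
#' @export
compare_foodweb <- function(causal_net, trophic_edges) {
  stopifnot(inherits(causal_net, "causal_network"))
  trophic_edges <- as.data.frame(trophic_edges)
  stopifnot(all(c("source", "target") %in% names(trophic_edges)))
  unknown <- setdiff(unique(c(trophic_edges$source, trophic_edges$target)),
                     causal_net$nodes)
  if (length(unknown) > 0L) {
    stop("trophic edge list names unknown nodes: ",
         paste(unknown, collapse = ", "))
  }
  sep <- ""  # node names may contain spaces
  cl <- causal_net$links[causal_net$links$accepted, c("source", "target")]
  ckey <- paste(cl$source, cl$target, sep = sep)
  tkey <- paste(trophic_edges$source, trophic_edges$target, sep = sep)
  flip <- function(keys) vapply(strsplit(keys, sep, fixed = TRUE),
                                function(p) paste(p[2L], p[1L], sep = sep),
                                character(1L))
  either_dir <- function(keys) unique(c(keys, flip(keys)))
  t_only <- setdiff(tkey, ckey)
  rows <- data.frame(
    key = c(ckey, t_only),
    category = c(
      ifelse(ckey %in% either_dir(tkey), "causal_and_trophic", "causal_only"),
      ifelse(t_only %in% either_dir(ckey), "causal_and_trophic", "trophic_only")
    )
  )
  parts <- strsplit(rows$key, sep, fixed = TRUE)
  out <- data.frame(
    source = vapply(parts, `[`, character(1L), 1L),
    target = vapply(parts, `[`, character(1L), 2L),
    category = rows$category
  )
  rownames(out) <- NULL
  out[order(out$category, out$source, out$target), , drop = FALSE]
}
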