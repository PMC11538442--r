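#' Embedding parameters for delay-coordinate reconstruction
#'
#' @param E Embedding dimension (number of delay coordinates), `E >= 1`.
#' @param tau Time delay between successive coordinates, in sample steps,
#'   `tau >= 1`. Varying `tau` probes dynamics at different timescales.
#' @param tp Prediction offset: a cross-map prediction made at query time `t`
#'   targets the value at `t + tp`. Negative values map to past states of the
#'   putative driver.
#'
#' @return An object of class `embedding_params`.
#' @export
#' @examples
#' embedding_params(E = 12, tau = 1, tp = 0)
embedding_params <- function(E, tau = 1L, tp = 0L) {
  E <- as.integer(E); tau <- as.integer(tau); tp <- as.integer(tp)
  stopifnot(length(E) == 1L, length(tau) == 1L, length(tp) == 1L)
  if (is.na(E) || E < 1L) stop("`E` must be a positive integer")
  if (is.na(tau) || tau < 1L) stop("`tau` must be a positive integer")
  structure(list(E = E, tau = tau, tp = tp), class = "embedding_params")
}

#' @export
print.embedding_params <- function(x, ...) {
  cat(sprintf("<embedding_params> E = %d, tau = %d, tp = %d\n",
              x$E, x$tau, x$tp))
  invisible(x)
}

#' Time-delay embedding of a series
#'
#' Builds the delay-coordinate reconstruction with rows
#' `(x(t), x(t - tau), ..., x(t - (E - 1) tau))` for every time `t` at which
#' the full delay vector exists. Rows containing missing values are dropped
#' (their times are excluded).
#'
#' @param x A [uniform_series()] (or plain numeric vector).
#' @param params An [embedding_params()].
#'
#' @return An object of class `state_space`: list with `vectors` (matrix, one
#'   row per reconstructed state), `row_times` (0-based time of each row) and
#'   `params`.
#' @export
#' @examples
#' ss <- embed_series(uniform_series(1:5), embedding_params(E = 2, tau = 1))
#' ss$vectors
embed_series <- function(x, params) {
  x <- as_uniform_series(x)
  stopifnot(inherits(params, "embedding_params"))
  E <- params$E; tau <- params$tau
  N <- length(x$values)
  min_len <- (E - 1L) * tau + 1L
  if (N < min_len) {
    stop(sprintf(
      "series `%s` has %d samples; embedding with E = %d, tau = %d needs at least %d",
      x$name, N, E, tau, min_len))
  }
  t0 <- x$time_index[1L]
  rows <- seq.int((E - 1L) * tau + 1L, N)  # 1-based positions of t
  M <- vapply(0:(E - 1L), function(j) x$values[rows - j * tau],
              numeric(length(rows)))
  M <- matrix(M, nrow = length(rows))
  keep <- rowSums(is.na(M)) == 0L
  structure(
    list(vectors = M[keep, , drop = FALSE],
         row_times = t0 + rows[keep] - 1L,
         params = params,
         series_name = x$name),
    class = "state_space"
  )
}

#' @export
print.state_space <- function(x, ...) {
  cat(sprintf("<state_space> %s: %d states, E = %d, tau = %d\n",
              x$series_name, nrow(x$vectors), x$params$E, x$params$tau))
  invisible(x)
}

cross_map_result <- function(rho, predictions, observations, prediction_times,
                             params, degenerate = FALSE) {
  structure(
    list(rho = rho, predictions = predictions, observations = observations,
         prediction_times = as.integer(prediction_times), params = params,
         n_pred = length(predictions), degenerate = isTRUE(degenerate)),
    class = "cross_map_result"
  )
}

#' @export
print.cross_map_result <- function(x, ...) {
  cat(sprintf("<cross_map_result> rho = %s over %d predictions (E = %d, tau = %d, tp = %d)%s\n",
              if (is.na(x$rho)) "NA" else sprintf("%.4f", x$rho), x$n_pred,
              x$params$E, x$params$tau, x$params$tp,
              if (x$degenerate) " [degenerate]" else ""))
  invisible(x)
}

# Pearson rho with explicit degeneracy handling: a constant prediction or
# observation vector has no defined correlation and is flagged, never
# silently scored 0.
safe_rho <- function(pred, obs) {
  ok <- is.finite(pred) & is.finite(obs)
  if (sum(ok) < 3L || sd(pred[ok]) == 0 || sd(obs[ok]) == 0) {
    return(list(rho = NA_real_, degenerate = TRUE))
  }
  list(rho = cor(pred[ok], obs[ok]), degenerate = FALSE)
}

#' Simplex-weighted cross-map prediction
#'
#' For each reconstructed state of `library` at time `t`, finds the `E + 1`
#' nearest library states (Euclidean distance, the query's own time excluded),
#' forms exponential simplex weights `u_i = exp(-d_i / d_1)` normalized to sum
#' to one, and predicts the `target` value at `t + tp` as the weighted sum of
#' the target values at the neighbors' (offset) times. Skill is the Pearson
#' correlation between predictions and observations.
#'
#' Ties in distance are broken by ascending time so output is deterministic.
#' If the nearest distance is exactly zero, all zero-distance neighbors share
#' equal weight and the rest get zero weight.
#'
#' @param target A [uniform_series()] holding the values to be predicted,
#'   sharing the time index of the series that generated `library`.
#' @param library A `state_space` from [embed_series()].
#' @param tp Prediction offset (defaults to the embedding's `tp`).
#' @param n_neighbors Number of neighbors; default `E + 1` (simplex
#'   convention).
#' @param exclusion_radius Rows within this many time steps of the query are
#'   excluded from its neighbor set; `0` (default) excludes only the query
#'   itself (leave-one-out).
#' @param lib_rows Optional integer vector (1-based rows of
#'   `library$vectors`) restricting the neighbor pool, used for library
#'   subsampling; predictions are still made at every valid query time.
#' @param max_queries When positive and the number of valid query times
#'   exceeds it, predictions are made at an evenly spaced subset of that
#'   size (deterministic). The neighbor pool is never thinned. `0`
#'   (default) predicts at every valid time.
#'
#' @return A `cross_map_result` with fields `rho`, `predictions`,
#'   `observations`, `prediction_times`, `params`, `n_pred`, `degenerate`.
#' @export
cross_map_predict <- function(target, library, tp = NULL, n_neighbors = NULL,
                              exclusion_radius = 0L, lib_rows = NULL,
                              max_queries = 0L) {
  target <- as_uniform_series(target)
  stopifnot(inherits(library, "state_space"))
  tp <- as.integer(tp %||% library$params$tp)
  E <- library$params$E
  nn <- as.integer(n_neighbors %||% (E + 1L))
  n_lib <- if (is.null(lib_rows)) nrow(library$vectors) else length(lib_rows)
  if (n_lib < E + 2L) {
    stop(sprintf("library has %d usable states; need at least E + 2 = %d",
                 n_lib, E + 2L))
  }
  t0 <- target$time_index[1L]
  res <- .cross_map_cpp(
    library$vectors, as.integer(library$row_times - t0), target$values,
    tp, nn, as.integer(exclusion_radius),
    if (is.null(lib_rows)) NULL else as.integer(lib_rows) - 1L,
    as.integer(max_queries)
  )
  r <- safe_rho(res$predictions, res$observations)
  params <- embedding_params(E, library$params$tau, tp)
  cross_map_result(r$rho, res$predictions, res$observations,
                   res$prediction_times + t0, params, r$degenerate)
}

#' Convergent cross mapping skill
#'
#' Embeds the putative response `Y`, cross-maps the putative driver `X` from
#' that embedding, and reports the cross-map skill `rho`. Under convergent
#' cross mapping a high `rho` is evidence that `X` causally influences `Y`:
#' the dynamics of an affected variable carry recoverable information about
#' its drivers.
#'
#' @param X Putative driver series (the one being predicted).
#' @param Y Putative response series (the one embedded).
#' @param params An [embedding_params()]; its `tp` sets the prediction offset.
#' @inheritParams cross_map_predict
#'
#' @return A `cross_map_result`.
#' @export
#' @examples
#' x <- uniform_series(as.numeric(scale(stats::arima.sim(list(ar = .8), 200))))
#' ccm_rho(x, x, embedding_params(E = 3))$rho  # self-map, ~1
ccm_rho <- function(X, Y, params, n_neighbors = NULL, exclusion_radius = 0L,
                    max_queries = 0L) {
  X <- as_uniform_series(X, "X"); Y <- as_uniform_series(Y, "Y")
  check_aligned(X, Y)
  lib <- embed_series(Y, params)
  cross_map_predict(X, lib, tp = params$tp, n_neighbors = n_neighbors,
                    exclusion_radius = exclusion_radius,
                    max_queries = max_queries)
}

#' Maximum absolute lagged cross-correlation
#'
#' The linear-association baseline used to screen cross-map links in model
#' data: the maximum over lags `-max_lag..max_lag` of the absolute Pearson
#' correlation between `X(t)` and `Y(t + lag)` on the overlapping segment.
#'
#' @param X,Y Series sharing a time index.
#' @param max_lag Non-negative integer; `0` reduces to the lag-0 absolute
#'   correlation.
#'
#' @return A number in `[0, 1]` with attribute `"lag"` giving the maximizing
#'   lag.
#' @export
max_abs_xcorr <- function(X, Y, max_lag) {
  X <- as_uniform_series(X, "X"); Y <- as_uniform_series(Y, "Y")
  check_aligned(X, Y)
  max_lag <- as.integer(max_lag)
  N <- length(X$values)
  if (max_lag < 0L) stop("`max_lag` must be non-negative")
  if (max_lag >= N / 2) stop("`max_lag` must be below half the series length")
  lags <- (-max_lag):max_lag
  vals <- vapply(lags, function(l) {
    if (l >= 0) {
      xs <- X$values[seq_len(N - l)]
      ys <- Y$values[seq_len(N - l) + l]
    } else {
      xs <- X$values[seq_len(N + l) - l]
      ys <- Y$values[seq_len(N + l)]
    }
    ok <- is.finite(xs) & is.finite(ys)
    # lags whose overlap is constant (or too short) carry no information
    # and are skipped; fully constant series error below
    if (sum(ok) < 3L || sd(xs[ok]) == 0 || sd(ys[ok]) == 0) {
      return(NA_real_)
    }
    abs(cor(xs[ok], ys[ok]))
  }, numeric(1L))
  if (all(is.na(vals))) {
    stop("cross-correlation undefined at every lag (constant series)")
  }
  i <- which.max(vals)
  structure(vals[i], lag = lags[i])
}

#' Cross-map skill maximized over embedding dimension
#'
#' Runs [ccm_rho()] for every `E` in `E_range` at fixed `tau` and `tp` and
#' returns the best result together with the full `(E, rho)` table. This is
#' the standard way to let the data choose the embedding dimension when
#' screening links.
#'
#' @param X,Y Series sharing a time index (driver, response).
#' @param E_range Integer vector of embedding dimensions to try. Dimensions
#'   infeasible for the series length are dropped with a warning; if none is
#'   feasible an error is raised.
#' @param tau,tp Delay and prediction offset applied at every `E`.
#' @inheritParams cross_map_predict
#'
#' @return A list with elements `best` (a `cross_map_result`) and `table`
#'   (data.frame with columns `E`, `rho`, `degenerate`).
#' @export
ccm_scan <- function(X, Y, E_range = 1:10, tau = 1L, tp = -1L,
                     n_neighbors = NULL, exclusion_radius = 0L,
                     max_queries = 0L) {
  E_range <- sort(unique(as.integer(E_range)))
  if (length(E_range) == 0L) stop("`E_range` must be non-empty")
  Y <- as_uniform_series(Y, "Y")
  feasible <- E_range[(E_range - 1L) * as.integer(tau) + 1L <= length(Y$values)]
  if (length(feasible) == 0L) {
    stop(sprintf(
      "no E in E_range is feasible for series length %d at tau = %d",
      length(Y$values), tau))
  }
  if (length(feasible) < length(E_range)) {
    warning(sprintf("dropping infeasible E values: %s",
                    paste(setdiff(E_range, feasible), collapse = ", ")))
  }
  results <- lapply(feasible, function(E) {
    ccm_rho(X, Y, embedding_params(E, tau, tp), n_neighbors = n_neighbors,
            exclusion_radius = exclusion_radius, max_queries = max_queries)
  })
  tab <- data.frame(
    E = feasible,
    rho = vapply(results, function(r) r$rho, numeric(1L)),
    degenerate = vapply(results, function(r) r$degenerate, logical(1L))
  )
  if (all(is.na(tab$rho))) {
    best <- results[[1L]]
  } else {
    best <- results[[which.max(replace(tab$rho, is.na(tab$rho), -Inf))]]
  }
  list(best = best, table = tab)
}

#' Cross-map convergence with library size
#'
#' Convergence of cross-map skill with growing library size is the signature
#' separating dynamic causation from mere correlation. For each requested
#' library size, neighbor pools are subsampled `n_samples` times and the mean
#' skill reported.
#'
#' @inheritParams ccm_rho
#' @param library_sizes Integer vector of library sizes (numbers of
#'   reconstructed states to use as neighbor pool); each must be at least
#'   `E + 2` and at most the number of available states.
#' @param n_samples Random subsamples per size.
#' @param seed Seed for the subsampling.
#'
#' @return data.frame with columns `lib_size`, `mean_rho`, `sd_rho`.
#' @export
ccm_library_sweep <- function(X, Y, params, library_sizes, n_samples = 20L,
                              seed = 1L) {
  X <- as_uniform_series(X, "X"); Y <- as_uniform_series(Y, "Y")
  check_aligned(X, Y)
  lib <- embed_series(Y, params)
  n_avail <- nrow(lib$vectors)
  library_sizes <- as.integer(library_sizes)
  if (any(library_sizes < params$E + 2L)) {
    stop(sprintf("library sizes below E + 2 = %d are not usable",
                 params$E + 2L))
  }
  if (any(library_sizes > n_avail)) {
    stop(sprintf("library sizes exceed available states (%d)", n_avail))
  }
  with_seed(seed, {
    rows <- lapply(library_sizes, function(L) {
      replicate(n_samples, sort(sample.int(n_avail, L)), simplify = FALSE)
    })
    res <- mapply(function(L, subsets) {
      rhos <- vapply(subsets, function(s) {
        cross_map_predict(X, lib, tp = params$tp, lib_rows = s)$rho
      }, numeric(1L))
      c(mean_rho = mean(rhos, na.rm = TRUE),
        sd_rho = sd(rhos))
    }, library_sizes, rows)
    data.frame(lib_size = library_sizes,
               mean_rho = res["mean_rho", ],
               sd_rho = res["sd_rho", ])
  })
}
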