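#' Configuration for seasonally forced series pairs
#'
#' Parameters of the seasonally forced logistic-map generator used to
#' emulate the two key statistical properties of monthly plankton-style
#' monitoring data: strong seasonal synchrony across series and (optionally)
#' nonlinear dynamic coupling between them.
#'
#' @param n_years Number of years (12 samples per year), `>= 3`.
#' @param seasonal_amplitude Relative amplitude of the shared sinusoidal
#'   seasonal envelope multiplying both observed series (`>= 0`, `< 1`).
#'   The default 0.4 gives the pair the strong within-year synchrony typical
#'   of monthly plankton monitoring.
#' @param growth_rate Growth rate of the latent logistic maps; must lie in
#'   `(0, 4]` (default 3.8, well inside the chaotic regime).
#' @param coupling Strength of the `X -> Y` coupling in the latent dynamics
#'   (0 = uncoupled).
#' @param noise_sd Standard deviation of additive observation noise.
#' @param seed RNG seed.
#' @return An object of class `seasonal_config`.
#' @export
seasonal_config <- function(n_years = 30L, seasonal_amplitude = 0.4,
                            growth_rate = 3.8, coupling = 0,
                            noise_sd = 0.03, seed = 1L) {
  cfg <- list(n_years = as.integer(n_years),
              seasonal_amplitude = as.numeric(seasonal_amplitude),
              growth_rate = as.numeric(growth_rate),
              coupling = as.numeric(coupling),
              noise_sd = as.numeric(noise_sd), seed = as.integer(seed))
  if (cfg$n_years < 3L) stop("`n_years` must be >= 3")
  if (cfg$seasonal_amplitude < 0 || cfg$seasonal_amplitude >= 1) {
    stop("`seasonal_amplitude` must lie in [0, 1)")
  }
  if (cfg$coupling < 0) stop("`coupling` must be >= 0")
  if (cfg$noise_sd < 0) stop("`noise_sd` must be >= 0")
  if (cfg$growth_rate <= 0 || cfg$growth_rate > 4) {
    stop("`growth_rate` must lie in (0, 4] for a bounded logistic map")
  }
  structure(cfg, class = "seasonal_config")
}

#' Seasonally synchronized, optionally coupled series pair
#'
#' Generates monthly series `X` and `Y` with the two statistical properties
#' the seasonal-surrogate machinery assumes of monthly monitoring data:
#' strong seasonal synchrony across series and (optionally) nonlinear
#' dynamic coupling between them. Latent dynamics are chaotic logistic
#' maps, with `Y` driven by `X` when `coupling > 0`:
#' \preformatted{
#'   x(t+1) = x(t) * (r - r * x(t))
#'   y(t+1) = y(t) * (r - r * y(t) - coupling * x(t))
#' }
#' The observed series multiply the latent states by a shared sinusoidal
#' seasonal envelope `1 + seasonal_amplitude * sin(2 pi month / 12)` (the
#' common bloom cycle that synchronizes co-monitored taxa) and add Gaussian
#' observation noise, truncated below at zero. Shuffling values within
#' months preserves the envelope while destroying the latent dynamics,
#' which is exactly the null the surrogate test needs.
#'
#' @param cfg A [seasonal_config()].
#' @return List of two [uniform_series()] `X`, `Y` with `month_labels`
#'   cycling 1..12.
#' @export
#' @examples
#' p <- make_seasonal_pair(seasonal_config(n_years = 5, coupling = 0.4))
#' p$X
make_seasonal_pair <- function(cfg) {
  stopifnot(inherits(cfg, "seasonal_config"))
  n <- 12L * cfg$n_years
  burn <- 120L
  r <- cfg$growth_rate
  with_seed(cfg$seed, {
    x <- runif(1, 0.2, 0.8); y <- runif(1, 0.2, 0.8)
    xs <- ys <- numeric(n)
    for (t in seq_len(n + burn)) {
      xn <- x * (r - r * x)
      yn <- y * (r - r * y - cfg$coupling * x)
      x <- min(max(xn, 1e-8), 1)
      y <- min(max(yn, 1e-8), 1)
      if (t > burn) { xs[t - burn] <- x; ys[t - burn] <- y }
    }
    months <- rep(1:12, cfg$n_years)
    env <- 1 + cfg$seasonal_amplitude * sin(2 * pi * months / 12)
    xs <- pmax(xs * env + rnorm(n, 0, cfg$noise_sd), 0)
    ys <- pmax(ys * env + rnorm(n, 0, cfg$noise_sd), 0)
    list(X = uniform_series(xs, month_labels = months, name = "X"),
         Y = uniform_series(ys, month_labels = months, name = "Y"))
  })
}

#' Three-series system with a fast and a slow causal channel
#'
#' A desk-scale analogue of a community whose interactions act on different
#' timescales. `A` and `B` are chaotic logistic maps coupled to each other
#' at lag 1 (fast channel, both directions). `B` additionally carries a
#' slow chaotic amplitude component (a logistic map advanced once per
#' `window` steps), and `C` is a damped integrator responding through a
#' saturating (logistic-sigmoid) nonlinearity to the `window`-step moving
#' average of `B` - a consumer that integrates prey availability over a
#' long window, like the slow consumption-window rules of the automata
#' model. The `A <-> B` channel is resolvable in a `tau = 1` web; the
#' `B -> C` channel carries only `B`'s slow (but aperiodic) component and
#' is resolved at a delay comparable to `window`.
#'
#' @param seed RNG seed.
#' @param n_steps Series length after burn-in.
#' @param window Integration window (samples) of the slow channel.
#' @param coupling_fast Strength of the fast `A <-> B` coupling.
#' @param response_mid,response_width Midpoint and width of `C`'s sigmoid
#'   response to the moving average of `B`.
#' @param damp Relaxation rate of `C` (its memory is roughly `1/damp`
#'   samples).
#' @return Named list of three [uniform_series()] `A`, `B`, `C`.
#' @export
make_two_timescale_system <- function(seed = 1L, n_steps = 1500L,
                                      window = 24L, coupling_fast = 0.32,
                                      response_mid = 0.42,
                                      response_width = 0.05, damp = 0.08) {
  n_steps <- as.integer(n_steps); window <- as.integer(window)
  with_seed(seed, {
    burn <- 13L * window
    total <- n_steps + burn
    a <- runif(1, 0.2, 0.8); bf <- runif(1, 0.2, 0.8)
    s <- runif(1, 0.2, 0.8); cc <- runif(1, 0.2, 0.8)
    A <- B <- Cv <- numeric(total)
    bhist <- rep(0.4, window)  # circular buffer of recent B values
    bsum <- sum(bhist)
    for (t in seq_len(total)) {
      if (t %% window == 1L) s <- 3.9 * s * (1 - s)  # slow chaotic amplitude
      an <- a * (3.8 - 3.8 * a - coupling_fast * bf)
      bn <- bf * (3.7 - 3.7 * bf - 1.1 * coupling_fast * a)
      a <- min(max(an, 1e-8), 1)
      bf <- min(max(bn, 1e-8), 1)
      b_obs <- bf * (0.4 + 0.6 * s)
      bbar <- bsum / window
      cc <- (1 - damp) * cc +
        damp * stats::plogis((bbar - response_mid) / response_width)
      i <- (t - 1L) %% window + 1L
      bsum <- bsum + b_obs - bhist[i]
      bhist[i] <- b_obs
      A[t] <- a; B[t] <- b_obs; Cv[t] <- cc
    }
    keep <- seq.int(burn + 1L, total)
    list(A = uniform_series(A[keep], name = "A"),
         B = uniform_series(B[keep], name = "B"),
         C = uniform_series(Cv[keep], name = "C"))
  })
}

#' Block-structured coupled community with known cross-group coupling
#'
#' Generates a community of `n_groups * species_per_group` series evolved
#' with the same update rule as the logistic predator-prey model
#' (self-damping plus reciprocal constraint), with interaction blocks
#' between groups populated at prescribed densities and no intra-group
#' interactions. The realized cross-block coupling density is returned as
#' ground truth for validating fine-scale connectance estimates.
#'
#' @param n_groups Number of functional groups (`>= 2`).
#' @param species_per_group Series per group.
#' @param cross_coupling Either a single density in `[0, 1]` applied to
#'   every ordered cross-group block, or an `n_groups x n_groups` matrix of
#'   densities (diagonal ignored). Entries from lower-indexed to
#'   higher-indexed groups are positive (resource-to-consumer), the reverse
#'   negative.
#' @param magnitude_low,magnitude_high Interaction magnitude range.
#' @param alpha Self-damping strength.
#' @param n_steps,burn_in Steps simulated / discarded.
#' @param seed RNG seed.
#' @return List with `series` (named list of [uniform_series()]),
#'   `group_map` (named character vector series -> group), and
#'   `realized_density` (matrix of realized cross-block densities).
#' @export
make_grouped_community <- function(n_groups = 2L, species_per_group = 5L,
                                   cross_coupling = 0.5,
                                   magnitude_low = 0.05,
                                   magnitude_high = 0.15, alpha = 0.15,
                                   n_steps = 1000L, burn_in = 500L,
                                   seed = 1L) {
  n_groups <- as.integer(n_groups)
  species_per_group <- as.integer(species_per_group)
  if (n_groups < 2L) stop("`n_groups` must be >= 2")
  dens <- if (is.matrix(cross_coupling)) {
    stopifnot(nrow(cross_coupling) == n_groups,
              ncol(cross_coupling) == n_groups)
    cross_coupling
  } else {
    matrix(as.numeric(cross_coupling), n_groups, n_groups)
  }
  if (any(dens < 0 | dens > 1)) stop("coupling densities must lie in [0, 1]")
  S <- n_groups * species_per_group
  grp <- rep(seq_len(n_groups), each = species_per_group)
  with_seed(seed, {
    K <- matrix(0, S, S)  # K[i, j]: effect of series j on series i
    realized <- matrix(0, n_groups, n_groups)
    for (gs in seq_len(n_groups)) for (gt in seq_len(n_groups)) {
      if (gs == gt) next
      rows <- which(grp == gt); cols <- which(grp == gs)
      n_cells <- length(rows) * length(cols)
      nz <- round(dens[gs, gt] * n_cells)
      realized[gs, gt] <- nz / n_cells
      if (nz == 0L) next
      sign <- if (gs < gt) 1 else -1
      block <- matrix(0, length(rows), length(cols))
      block[sample.int(n_cells, nz)] <-
        sign * runif(nz, magnitude_low, magnitude_high)
      K[rows, cols] <- block
    }
    x <- runif(S, 0.1, 1)
    out <- matrix(NA_real_, n_steps, S)
    for (t in seq_len(n_steps)) {
      x <- reciprocal_constraint(x + drop(K %*% x) - alpha * x)
      if (any(!is.finite(x))) {
        stop(sprintf("non-finite abundance at step %d", t))
      }
      out[t, ] <- x
    }
    keep <- seq.int(burn_in + 1L, n_steps)
    nm <- paste0("g", grp, "_s", sequence(rep(species_per_group, n_groups)))
    series <- lapply(seq_len(S), function(j) {
      uniform_series(out[keep, j], name = nm[j])
    })
    names(series) <- nm
    group_map <- stats::setNames(paste0("group", grp), nm)
    list(series = series, group_map = group_map,
         realized_density = realized)
  })
}
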