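#' Configuration of the individual-based automata model
#'
#' A three-trophic-level individual-based model on a continuous toroidal
#' square: resources, primary consumers (PC) grazing them within a small
#' radius, and secondary consumers (SC) taking PCs within a large radius.
#' PC survival and reproduction react to consumption within a single
#' timestep; SC survival and reproduction react to consumption summed over a
#' rolling `sc_window`-step window, so the two consumer levels couple to
#' their prey on timescales three orders of magnitude apart.
#'
#' @param grid_size Side length of the square arena.
#' @param n_resources0,n_pc0,n_sc0 Initial counts of resources, primary
#'   consumers and secondary consumers.
#' @param speed_r,speed_pc,speed_sc Movement speeds (distance scale per
#'   timestep) of the three classes.
#' @param radius_pc Radius within which a PC grazes resources.
#' @param radius_sc Radius within which an SC takes PCs.
#' @param resource_influx New resources added uniformly at random each step.
#' @param sc_window Length (steps) of the SC consumption window.
#' @param sc_survival_threshold Minimum PCs consumed over the window for an
#'   SC to survive (only enforced once the SC has a full window of history).
#' @param sc_repro_threshold PCs consumed over the window required for an SC
#'   offspring.
#' @param sc_repro_refractory Minimum steps between successive offspring of
#'   one SC.
#' @param n_steps Number of timesteps to simulate.
#' @param seed RNG seed; the whole run is reproducible from it.
#' @param movement Movement rule for resources and PCs. `"axis"` (default):
#'   per-axis displacement drawn uniformly from `[-s, s]`; `"radial"`:
#'   fixed step of length `s` in a uniform random direction; `"axis_fixed"`:
#'   displacement of exactly `s` in each axis with random signs; `"mix"`:
#'   relocate uniformly on the grid each step (the fast-mixing limit of
#'   random movement; the class's speed is then irrelevant).
#' @param movement_sc Movement rule for SCs; same choices. Default `"mix"`:
#'   with a capture radius of a tenth of the arena and the largest speed,
#'   the SC is treated as a wide-ranging forager sampling the whole arena,
#'   so its intake tracks the standing PC stock. Under literal slow
#'   movement an SC re-grazes its own depletion halo and its intake falls
#'   to roughly half the stated survival threshold, which extinguishes the
#'   SC level for every movement variant (see vignette).
#' @param spatial_index Use the uniform-cell spatial index for consumption
#'   queries (results are identical to exhaustive search; this only changes
#'   speed).
#' @param resource_sharing When `FALSE` (default) each resource feeds only
#'   the first PC (in random processing order) whose radius covers it; when
#'   `TRUE` a resource acts as a patch feeding every PC in reach in the same
#'   step before removal. SC predation on PCs is always exclusive (a PC is
#'   an individual, taken at most once).
#' @param pc_posthumous_repro When `TRUE`, a PC taken by an SC in the same
#'   step still leaves its offspring (if it grazed 2 or more resources)
#'   even though the parent is removed. Default `FALSE`: consumed PCs are
#'   removed before the survival/reproduction phase.
#' @param sc_max_meals Satiation: the largest number of PCs one SC takes in
#'   one step (`0` = unlimited). The default equals the per-step rate of
#'   the reproduction threshold (`sc_repro_threshold / sc_window` = 10):
#'   consumption beyond that rate confers no benefit under the window
#'   rules. Unlimited intake lets the founding cohort of 20 SCs remove
#'   prey far faster than PC recruitment can replace during the initial
#'   transient, which extinguishes the PC or SC level (see vignette).
#' @param sc_starvation How SC starvation is judged before an SC has a full
#'   `sc_window` of history. `"prorated"` (default): an SC dies whenever its
#'   rolling consumption falls below the survival threshold scaled to the
#'   history it actually has, so under-performing SCs die gradually and
#'   release prey to the rest. `"grace"`: no starvation at all until age
#'   `sc_window`, after which the full threshold applies; this synchronizes
#'   the first starvation check across the founding cohort (see vignette).
#' @param sc_predation_first When `TRUE`, SC predation is resolved before PC
#'   grazing within a step, so SCs select from the full PC pool including
#'   PCs that would starve that step. Default `FALSE` (grazing first).
#' @param offspring_placement Where offspring appear: `"disc"` (default)
#'   draws a uniform position within `offspring_dispersal` of the parent;
#'   `"random"` draws a uniform position on the grid (the infinite-
#'   dispersal limit); `"parent"` places offspring exactly at the parent's
#'   position (the zero-dispersal limit). Dispersal distance controls the
#'   spatial clumping of the prey field and with it both the amplitude of
#'   the slow resource-grazer cycles and the intake available to the SC
#'   level; the extremes respectively collapse the PC level under
#'   predation or freeze the SC level (see vignette).
#' @param offspring_dispersal Dispersal radius used when
#'   `offspring_placement = "disc"`.
#' @param sc_founders Initialization of the founding SC cohort.
#'   `"staggered"` (default): founder ages are drawn uniformly over the
#'   consumption window and their histories pre-filled at exactly the
#'   survival rate, so starvation checks desynchronize across founders and
#'   an oversized cohort shrinks gradually to a sustainable number.
#'   `"zero"`: all founders start with age 0 and empty histories, which
#'   synchronizes their first starvation check and can cascade the whole
#'   cohort (and with it the SC level) to extinction during the
#'   initialization transient (see vignette).
#'
#' @return An object of class `iba_config`.
#' @export
iba_config <- function(grid_size = 1000, n_resources0 = 15000L,
                       n_pc0 = 1500L, n_sc0 = 20L,
                       speed_r = 10, speed_pc = 10, speed_sc = 25,
                       radius_pc = 10, radius_sc = 100,
                       resource_influx = 500L, sc_window = 500L,
                       sc_survival_threshold = 3000L,
                       sc_repro_threshold = 5000L,
                       sc_repro_refractory = 200L,
                       n_steps = 15000L, seed = 1L,
                       movement = c("axis", "radial", "axis_fixed", "mix"),
                       movement_sc = c("mix", "axis", "radial", "axis_fixed"),
                       spatial_index = TRUE, resource_sharing = FALSE,
                       pc_posthumous_repro = FALSE,
                       sc_max_meals = 10L,
                       sc_starvation = c("prorated", "grace"),
                       sc_predation_first = FALSE,
                       offspring_placement = c("disc", "random", "parent"),
                       offspring_dispersal = 100,
                       sc_founders = c("staggered", "zero")) {
  movement <- match.arg(movement)
  movement_sc <- match.arg(movement_sc)
  sc_starvation <- match.arg(sc_starvation)
  offspring_placement <- match.arg(offspring_placement)
  sc_founders <- match.arg(sc_founders)
  cfg <- list(
    grid_size = as.numeric(grid_size),
    n_resources0 = as.integer(n_resources0), n_pc0 = as.integer(n_pc0),
    n_sc0 = as.integer(n_sc0),
    speed_r = as.numeric(speed_r), speed_pc = as.numeric(speed_pc),
    speed_sc = as.numeric(speed_sc),
    radius_pc = as.numeric(radius_pc), radius_sc = as.numeric(radius_sc),
    resource_influx = as.integer(resource_influx),
    sc_window = as.integer(sc_window),
    sc_survival_threshold = as.integer(sc_survival_threshold),
    sc_repro_threshold = as.integer(sc_repro_threshold),
    sc_repro_refractory = as.integer(sc_repro_refractory),
    n_steps = as.integer(n_steps), seed = as.integer(seed),
    movement = movement, movement_sc = movement_sc,
    spatial_index = isTRUE(spatial_index),
    resource_sharing = isTRUE(resource_sharing),
    pc_posthumous_repro = isTRUE(pc_posthumous_repro),
    sc_max_meals = as.integer(sc_max_meals),
    sc_starvation = sc_starvation,
    sc_predation_first = isTRUE(sc_predation_first),
    offspring_placement = offspring_placement,
    offspring_dispersal = as.numeric(offspring_dispersal),
    sc_founders = sc_founders
  )
  if (cfg$grid_size <= 0) stop("`grid_size` must be positive")
  if (any(c(cfg$n_resources0, cfg$n_pc0, cfg$n_sc0, cfg$resource_influx) < 0L)) {
    stop("initial counts and influx must be >= 0")
  }
  if (any(c(cfg$speed_r, cfg$speed_pc, cfg$speed_sc) <= 0) ||
      any(c(cfg$radius_pc, cfg$radius_sc) <= 0)) {
    stop("speeds and radii must be > 0")
  }
  if (cfg$sc_repro_threshold < cfg$sc_survival_threshold) {
    stop("`sc_repro_threshold` must be >= `sc_survival_threshold`")
  }
  if (cfg$sc_window < 1L || cfg$n_steps < 1L) {
    stop("`sc_window` and `n_steps` must be >= 1")
  }
  structure(cfg, class = "iba_config")
}

#' @export
print.iba_config <- function(x, ...) {
  cat(sprintf(
    "<iba_config> %gx%g torus; init R/PC/SC = %d/%d/%d; %d steps; seed %d\n",
    x$grid_size, x$grid_size, x$n_resources0, x$n_pc0, x$n_sc0, x$n_steps,
    x$seed))
  invisible(x)
}

#' Initialize the automata world
#'
#' Places all individuals uniformly at random on the square (seeded from
#' `config$seed`), with empty SC consumption histories.
#'
#' @param config An [iba_config()].
#' @return A `world_state` list: positions per class, SC window buffers,
#'   SC ages and reproduction clocks, and the current step counter.
#' @export
init_world <- function(config) {
  stopifnot(inherits(config, "iba_config"))
  with_seed(config$seed, new_world(config))
}

# construct the initial world from the current RNG stream
new_world <- function(config) {
  L <- config$grid_size
  nsc <- config$n_sc0
  w <- config$sc_window
  hist <- matrix(0L, nrow = w, ncol = nsc)
  age <- integer(nsc)
  since <- integer(nsc)
  if (config$sc_founders == "staggered" && nsc > 0L) {
    age <- sample.int(w, nsc, replace = TRUE) - 1L
    since <- vapply(age, function(a) {
      sample.int(min(a, config$sc_repro_refractory) + 1L, 1L) - 1L
    }, integer(1L))
    # pre-fill each founder's lived history at the survival rate; the
    # circular row pointer starts at row 1, so a founder of age a occupies
    # the a rows that will be overwritten last
    rate <- config$sc_survival_threshold / w
    for (j in seq_len(nsc)) {
      if (age[j] > 0L) {
        rows <- seq.int(w - age[j] + 1L, w)
        hist[rows, j] <- as.integer(ceiling(rate))
      }
    }
  }
  state <- list(
    rx = runif(config$n_resources0, 0, L),
    ry = runif(config$n_resources0, 0, L),
    pcx = runif(config$n_pc0, 0, L),
    pcy = runif(config$n_pc0, 0, L),
    scx = runif(nsc, 0, L),
    scy = runif(nsc, 0, L),
    sc_hist = hist,
    sc_age = age,
    sc_since_repro = since,
    current_step = 0L
  )
  class(state) <- "world_state"
  state
}

#' @export
print.world_state <- function(x, ...) {
  cat(sprintf("<world_state> step %d: %d resources, %d PC, %d SC\n",
              x$current_step, length(x$rx), length(x$pcx), length(x$scx)))
  invisible(x)
}

#' Advance the automata world
#'
#' Applies, in order: movement of every individual; PC grazing (each resource
#' consumed at most once); SC predation (each PC taken at most once); PC
#' survival/reproduction (0 meals starves, >= 1 survives, >= 2 yields one
#' offspring next step); SC rolling-window survival/reproduction; resource
#' influx; step counter increment. Uses the current RNG state; seed
#' explicitly (or use [run_iba()]) for reproducibility.
#'
#' @param world A `world_state`.
#' @param config The [iba_config()] used to create it.
#' @param n_steps Number of steps to advance.
#' @return A list with the updated `world` and a `records` data.frame (one
#'   row per step: abundances plus consumption/birth/death bookkeeping).
#' @export
iba_step <- function(world, config, n_steps = 1L) {
  stopifnot(inherits(config, "iba_config"))
  res <- .iba_run_cpp(unclass(world), unclass(config), as.integer(n_steps))
  class(res$state) <- "world_state"
  list(world = res$state, records = res$records)
}

#' Run the individual-based automata model
#'
#' Initializes the world from `config$seed` and advances it `config$n_steps`
#' steps, recording the three abundance series. Identical configs produce
#' bit-identical output.
#'
#' @param config An [iba_config()].
#' @return An object of class `iba_run`: list with `series` (named list of
#'   three [uniform_series()]: `resources`, `primary_consumers`,
#'   `secondary_consumers`), `records` (per-step bookkeeping data.frame),
#'   `final_state` and `config`.
#' @export
#' @examples
#' run <- run_iba(iba_config(n_steps = 50, n_resources0 = 500, n_pc0 = 50,
#'                           n_sc0 = 2, grid_size = 200))
#' head(run$records)
run_iba <- function(config) {
  stopifnot(inherits(config, "iba_config"))
  with_seed(config$seed, {
    world <- new_world(config)
    res <- .iba_run_cpp(unclass(world), unclass(config), config$n_steps)
    rec <- res$records
    series <- list(
      resources = uniform_series(rec$resources, name = "resources"),
      primary_consumers = uniform_series(rec$primary_consumers,
                                         name = "primary_consumers"),
      secondary_consumers = uniform_series(rec$secondary_consumers,
                                           name = "secondary_consumers")
    )
    class(res$state) <- "world_state"
    structure(list(series = series, records = rec, final_state = res$state,
                   config = config),
              class = "iba_run")
  })
}

#' @export
print.iba_run <- function(x, ...) {
  cat(sprintf("<iba_run> %d steps; final R/PC/SC = %d/%d/%d (seed %d)\n",
              x$config$n_steps, length(x$final_state$rx),
              length(x$final_state$pcx), length(x$final_state$scx),
              x$config$seed))
  invisible(x)
}

#' Fast- and slow-scale causal webs from the automata model
#'
#' Builds two cross-map interaction networks over the three abundance series:
#' a high-resolution web at `tau = 1, tp = -1` and a low-resolution web at
#' `tau = tau_slow, tp = -tau_slow`. For each ordered pair the cross-map
#' skill is maximized over `E_range`, and a link is accepted when that skill
#' is positive and exceeds the maximum absolute lagged cross-correlation of
#' the pair (the linear baseline).
#'
#' The fast web resolves the per-step channels (resource-PC grazing in both
#' directions, SC predation pressure on PCs and, transitively, resources)
#' while the influence of PCs on SCs, which acts through a
#' `sc_window`-step consumption window, only appears in the slow web.
#'
#' @param series Either an `iba_run` or a named list of three
#'   [uniform_series()].
#' @param E_range Embedding dimensions scanned per link.
#' @param tau_slow Delay (and negated prediction offset) of the slow web.
#' @param normalize Apply [normalize_sqrt()] to each series first.
#' @param max_queries Cap on prediction points per cross map (evenly
#'   spaced, deterministic; the neighbor library is never thinned). `0`
#'   uses every reconstructed state.
#'
#' @return A named list of two `causal_network` objects (`"tau=1"` and
#'   `"tau=<tau_slow>"`).
#' @export
iba_causal_webs <- function(series, E_range = 1:10, tau_slow = 500L,
                            normalize = TRUE, max_queries = 4000L) {
  if (inherits(series, "iba_run")) series <- series$series
  stopifnot(is.list(series), length(series) == 3L)
  series <- lapply(seq_along(series), function(i) {
    as_uniform_series(series[[i]], names(series)[i] %||% paste0("s", i))
  })
  N <- length(series[[1L]]$values)
  need <- (max(E_range) - 1L) * as.integer(tau_slow) + tau_slow + 1L
  if (N < need) {
    stop(sprintf(
      "series length %d too short for the slow web: E = %d at tau = %d needs >= %d",
      N, max(E_range), tau_slow, need))
  }
  webs <- lapply(c(1L, as.integer(tau_slow)), function(tau) {
    build_network(series, params = embedding_params(max(E_range), tau, -tau),
                  null_kind = "xcorr", E_range = E_range,
                  normalize = normalize, max_queries = max_queries)
  })
  names(webs) <- paste0("tau=", c(1L, as.integer(tau_slow)))
  webs
}
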