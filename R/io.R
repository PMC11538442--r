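#' Read a wide abundance CSV into a set of series
#'
#' The first column is either an integer sample index (named `t`) or an ISO
#' year-month date (`YYYY-MM` or `YYYY-MM-DD`), from which calendar-month
#' labels are derived. Every remaining column becomes one [uniform_series()]
#' named after its header. Empty cells and `"NA"` are read as missing.
#'
#' @param path Path to the CSV file.
#' @return Named list of [uniform_series()].
#' @export
read_series_csv <- function(path) {
  d <- read.csv(path, check.names = FALSE, na.strings = c("", "NA"))
  if (ncol(d) < 2L) stop("CSV must have a time column plus at least one series")
  hdr <- names(d)
  if (anyDuplicated(hdr)) {
    stop("duplicate column names: ",
         paste(unique(hdr[duplicated(hdr)]), collapse = ", "))
  }
  tc <- d[[1L]]
  months <- NULL
  if (is.character(tc)) {
    m <- regmatches(tc, regexec("^(\\d{4})-(\\d{2})(-\\d{2})?$", tc))
    bad <- which(vapply(m, length, integer(1L)) == 0L)
    if (length(bad) > 0L) {
      stop(sprintf("unparseable date '%s' in row %d (line %d)",
                   tc[bad[1L]], bad[1L], bad[1L] + 1L))
    }
    yr <- as.integer(vapply(m, `[`, character(1L), 2L))
    mo <- as.integer(vapply(m, `[`, character(1L), 3L))
    if (any(mo < 1L | mo > 12L)) {
      i <- which(mo < 1L | mo > 12L)[1L]
      stop(sprintf("month out of range in row %d (line %d)", i, i + 1L))
    }
    tnum <- yr * 12L + (mo - 1L)
    months <- mo
  } else {
    tnum <- as.integer(tc)
  }
  if (anyNA(tnum)) {
    i <- which(is.na(tnum))[1L]
    stop(sprintf("missing or invalid time value in row %d (line %d)", i, i + 1L))
  }
  if (length(tnum) > 1L && any(diff(tnum) != 1L)) {
    i <- which(diff(tnum) != 1L)[1L]
    stop(sprintf(
      "time must increase in unit steps; violation between rows %d and %d (lines %d-%d)",
      i, i + 1L, i + 1L, i + 2L))
  }
  series <- lapply(hdr[-1L], function(nm) {
    v <- d[[nm]]
    if (!is.numeric(v)) {
      stop("column `", nm, "` is not numeric")
    }
    uniform_series(v, time_index = tnum - tnum[1L], month_labels = months,
                   name = nm)
  })
  names(series) <- hdr[-1L]
  series
}

#' Write a set of series as a wide abundance CSV
#'
#' Inverse of [read_series_csv()] up to floating-point text precision
#' (values are written with 15 significant digits).
#'
#' @param series Named list of [uniform_series()] with aligned time indices.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_series_csv <- function(series, path) {
  stopifnot(length(series) >= 1L)
  series <- lapply(series, as_uniform_series)
  for (s in series[-1L]) check_aligned(series[[1L]], s)
  d <- data.frame(t = series[[1L]]$time_index)
  for (s in series) d[[s$name]] <- signif(s$values, 15L)
  write.csv(d, path, row.names = FALSE, na = "")
  invisible(path)
}

#' Read a JSON functional-group map
#'
#' @param path JSON file holding one object mapping series name to group
#'   name.
#' @return Named character vector.
#' @export
read_group_map <- function(path) {
  m <- jsonlite::fromJSON(path)
  if (!is.list(m) && !is.character(m)) stop("group map must be a JSON object")
  m <- unlist(m)
  if (is.null(names(m)) || any(names(m) == "")) {
    stop("every entry of the group map must be named")
  }
  m
}

#' Drop sparsely observed taxa
#'
#' Removes every series with fewer than `min_nonzero` non-zero (and
#' non-missing) samples; a series with exactly `min_nonzero` such samples is
#' retained. Each removal is reported via `message()`.
#'
#' @param series Named list of [uniform_series()].
#' @param min_nonzero Inclusive retention threshold (default 35).
#' @return The filtered list.
#' @export
filter_taxa <- function(series, min_nonzero = 35L) {
  series <- lapply(series, as_uniform_series)
  n_nz <- vapply(series, function(s) {
    sum(!is.na(s$values) & s$values != 0)
  }, integer(1L))
  drop <- n_nz < min_nonzero
  for (i in which(drop)) {
    message(sprintf("filter_taxa: removing `%s` (%d non-zero samples < %d)",
                    series[[i]]$name, n_nz[i], as.integer(min_nonzero)))
  }
  if (all(drop)) stop("all series removed by the non-zero filter")
  series[!drop]
}

# stable 32-bit polynomial hash of the JSON form of a config, for run
# manifests; arithmetic kept in doubles below 2^53 to stay exact
config_hash <- function(config) {
  s <- jsonlite::toJSON(config, auto_unbox = TRUE, digits = 10)
  bytes <- utf8ToInt(as.character(s))
  h <- 5381
  for (b in bytes) h <- (h * 33 + b) %% 4294967296
  paste0(sprintf("%04x", as.integer(h %/% 65536)),
         sprintf("%04x", as.integer(h %% 65536)))
}

#' Run the multiscale network pipeline on a series CSV
#'
#' Executes read -> filter -> (optional aggregate) -> normalize ->
#' network per timescale -> multiscale comparison, and writes one edge-list
#' CSV per scale, a comparison table, and a JSON manifest naming the config
#' hash and seed, into `out_dir`. Re-running the same config reproduces all
#' outputs byte for byte.
#'
#' @param config Named list (or path to a JSON file) with entries:
#'   `input` (series CSV path), `out_dir`, `scales` (list of
#'   `list(E, tau, tp)`, one per timescale), `null_kind`
#'   (`"xcorr"` or `"seasonal_surrogate"`), and optionally `group_map`
#'   (path to JSON group map), `E_range` (for the xcorr null),
#'   `n_surrogates` (default 100), `min_exceeded` (default 95),
#'   `min_nonzero` (default 35), `seed` (default 1).
#' @return Named list of written file paths, invisibly.
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- jsonlite::fromJSON(config)
  for (req in c("input", "out_dir", "scales", "null_kind")) {
    if (is.null(config[[req]])) stop("config is missing `", req, "`")
  }
  seed <- as.integer(config$seed %||% 1L)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop(sprintf("pipeline stage `%s` failed: %s", name,
                   conditionMessage(e)), call. = FALSE)
    })
  }
  series <- stage("read", read_series_csv(config$input))
  series <- stage("filter",
                  filter_taxa(series,
                              min_nonzero = config$min_nonzero %||% 35L))
  group_map <- if (!is.null(config$group_map)) {
    stage("group_map", read_group_map(config$group_map))
  }
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  hash <- config_hash(config)
  scales <- config$scales
  if (is.data.frame(scales)) scales <- split(scales, seq_len(nrow(scales)))
  nets <- stage("network", lapply(scales, function(sc) {
    build_network(series,
                  params = embedding_params(sc$E, sc$tau, sc$tp %||% 0L),
                  null_kind = config$null_kind, group_map = group_map,
                  E_range = config$E_range,
                  n_surrogates = config$n_surrogates %||% 100L,
                  min_exceeded = config$min_exceeded %||% 95L,
                  seed = seed)
  }))
  paths <- list()
  for (net in nets) {
    f <- file.path(config$out_dir,
                   paste0("edges_", gsub("[^0-9A-Za-z]+", "_", net$scale_label),
                          ".csv"))
    links <- net$links
    links$config_hash <- hash
    write.csv(links, f, row.names = FALSE)
    paths[[net$scale_label]] <- f
  }
  if (length(nets) >= 2L) {
    cmp <- stage("compare", multiscale_compare(nets[[1L]], nets[[2L]]))
    cmp_df <- data.frame(
      link = c(cmp$both, cmp$A_only, cmp$B_only),
      category = rep(c("both", paste0(cmp$labels[1L], "_only"),
                       paste0(cmp$labels[2L], "_only")),
                     c(length(cmp$both), length(cmp$A_only),
                       length(cmp$B_only))),
      config_hash = hash
    )
    f <- file.path(config$out_dir, "comparison.csv")
    write.csv(cmp_df, f, row.names = FALSE)
    paths$comparison <- f
  }
  manifest <- list(
    config = config, config_hash = hash, seed = seed,
    package_version = as.character(utils::packageVersion("ccmweb")),
    r_version = paste(R.version$major, R.version$minor, sep = ".")
  )
  f <- file.path(config$out_dir, "manifest.json")
  jsonlite::write_json(manifest, f, auto_unbox = TRUE, pretty = TRUE)
  paths$manifest <- f
  invisible(paths)
}
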