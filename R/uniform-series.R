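#' Regularly sampled abundance time series
#'
#' The basic data container of the package: one abundance series observed at
#' unit time steps, optionally carrying a calendar-month label per sample
#' (needed for seasonal surrogate nulls).
#'
#' @param values Numeric vector of abundances (arbitrary units; `NA` allowed).
#' @param time_index Integer vector of 0-based sample times. Must be strictly
#'   increasing with unit steps. Defaults to `0:(length(values) - 1)`.
#' @param month_labels Optional integer vector in `1..12`, same length as
#'   `values`, giving the calendar month of each sample.
#' @param name Identifier used in network node labels.
#'
#' @return An object of class `uniform_series`.
#' @export
#' @examples
#' x <- uniform_series(rnorm(24), month_labels = rep(1:12, 2), name = "diatoms")
#' x
uniform_series <- function(values, time_index = NULL, month_labels = NULL,
                           name = "series") {
  values <- as.numeric(values)
  n <- length(values)
  if (n < 1L) stop("`values` must have length >= 1")
  if (is.null(time_index)) time_index <- seq_len(n) - 1L
  time_index <- as.integer(time_index)
  if (length(time_index) != n) {
    stop("`time_index` and `values` must have equal length")
  }
  if (n > 1L && any(diff(time_index) != 1L)) {
    stop("`time_index` must be strictly increasing with unit steps")
  }
  if (!is.null(month_labels)) {
    month_labels <- as.integer(month_labels)
    if (length(month_labels) != n) {
      stop("`month_labels` must have the same length as `values`")
    }
    if (any(!is.na(month_labels) & (month_labels < 1L | month_labels > 12L))) {
      stop("`month_labels` must lie in 1..12")
    }
  }
  structure(
    list(values = values, time_index = time_index,
         month_labels = month_labels, name = as.character(name)[1L]),
    class = "uniform_series"
  )
}

#' @export
print.uniform_series <- function(x, ...) {
  cat(sprintf("<uniform_series> %s: %d samples, t = %d..%d%s\n", x$name,
              length(x$values), x$time_index[1L],
              x$time_index[length(x$time_index)],
              if (is.null(x$month_labels)) "" else ", monthly"))
  invisible(x)
}

#' @export
length.uniform_series <- function(x) length(x$values)

#' @export
as.data.frame.uniform_series <- function(x, ...) {
  d <- data.frame(t = x$time_index, value = x$values)
  if (!is.null(x$month_labels)) d$month <- x$month_labels
  d
}

as_uniform_series <- function(x, name = "series") {
  if (inherits(x, "uniform_series")) x else uniform_series(x, name = name)
}

# shared-index check for pairwise operations
check_aligned <- function(X, Y) {
  if (length(X$values) != length(Y$values) ||
      any(X$time_index != Y$time_index)) {
    stop("series `", X$name, "` and `", Y$name,
         "` do not share a common time index")
  }
  invisible(TRUE)
}
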