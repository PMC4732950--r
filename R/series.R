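#' Breath-indexed or time-indexed series
#'
#' Lightweight container for a univariate respiratory series: a numeric
#' vector carrying its unit and index kind as attributes. All analysis
#' functions in the package accept either a `breath_series` or a plain
#' numeric vector.
#'
#' @param values numeric vector; all values must be finite.
#' @param unit one of `"seconds"` (inter-breath intervals), `"liters"`
#'   (lung volumes) or `"dimensionless"`.
#' @param index_kind `"breath"` for breath-indexed series, `"time"` for
#'   uniformly sampled waveforms.
#' @param meta optional named list of provenance tags (seed, generator
#'   parameters, subject id, ...).
#'
#' @return A numeric vector of class `breath_series`.
#' @examples
#' ibi <- breath_series(c(3.2, 3.6, 3.4), unit = "seconds")
#' series_unit(ibi)
#' @export
breath_series <- function(values,
                          unit = c("dimensionless", "seconds", "liters"),
                          index_kind = c("breath", "time"),
                          meta = list()) {
  unit <- match.arg(unit)
  index_kind <- match.arg(index_kind)
  values <- as.numeric(values)
  if (length(values) < 1L) {
    stop("a series must contain at least one value", call. = FALSE)
  }
  if (!all(is.finite(values))) {
    stop("series values must all be finite", call. = FALSE)
  }
  if (unit == "seconds" && any(values <= 0)) {
    stop("inter-breath intervals (unit = 'seconds') must be strictly positive",
         call. = FALSE)
  }
  structure(values,
            unit = unit, index_kind = index_kind, meta = meta,
            class = "breath_series")
}

#' @rdname breath_series
#' @param x object to query.
#' @export
series_unit <- function(x) attr(x, "unit") %||% "dimensionless"

#' @export
print.breath_series <- function(x, ...) {
  cat(sprintf("<breath_series> n = %d, unit = %s, index = %s\n",
              length(x), series_unit(x), attr(x, "index_kind") %||% "breath"))
  print(utils::head(as.numeric(x), 10L))
  if (length(x) > 10L) cat(sprintf("... (%d more)\n", length(x) - 10L))
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Strip class/attributes for numeric work.
as_values <- function(x) as.numeric(unclass(x))

# Run `expr` under a fixed RNG seed, restoring the caller's RNG state.
# Generators are pure functions of their arguments (seed included).
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

# Sample SD (n-1 denominator) used throughout the package so that
# z-normalized series have sample SD exactly 1.
sample_sd <- function(x) stats::sd(as_values(x))
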