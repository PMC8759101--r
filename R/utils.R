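# Internal helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Run code with a temporary RNG seed, restoring global RNG state afterwards
#' @noRd
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

#' Estimate the sampling rate (Hz) from timestamps
#' @noRd
sampling_rate <- function(t) {
  dt <- diff(t)
  1 / stats::median(dt)
}

stop_data <- function(...) stop(sprintf(...), call. = FALSE)

#' Clamp to [-1, 1] before acos
#' @noRd
clamp1 <- function(x) pmin(1, pmax(-1, x))

#' Angle in degrees between rows of two unit-vector matrices
#' @noRd
angle_between_deg <- function(a, b) {
  # 2*asin(|a-b|/2) is better conditioned than acos(a.b) for small angles
  d <- sqrt(rowSums((a - b)^2))
  2 * asin(clamp1(d / 2)) * 180 / pi
}

#' Normalise rows of a matrix to unit length
#' @noRd
normalize_rows <- function(m) {
  n <- sqrt(rowSums(m^2))
  if (any(n == 0)) stop_data("cannot normalise a zero-norm vector")
  m / n
}

#' Maximal runs of TRUE in a logical vector as (start, end) index pairs
#' @noRd
true_runs <- function(x) {
  r <- rle(as.logical(x))
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- r$values & !is.na(r$values)
  cbind(start = starts[keep], end = ends[keep])
}
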