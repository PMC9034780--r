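# Internal helpers shared across the pipeline.

#' Evaluate an expression with a temporary RNG seed
#'
#' Restores the caller's RNG state afterwards, so generators are
#' deterministic without clobbering the session RNG.
#' @noRd
with_seed <- function(seed, expr) {
  if (!is.numeric(seed) || length(seed) != 1L || !is.finite(seed))
    stop("'seed' must be a single finite number", call. = FALSE)
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

#' Trapezoidal integral of uniformly sampled values
#' @param x numeric samples
#' @param dx sample spacing
#' @noRd
trapz <- function(x, dx) {
  n <- length(x)
  if (n < 2L) return(0)
  dx * (sum(x) - (x[1L] + x[n]) / 2)
}

#' Round half away from zero (62.5 -> 63, -62.5 -> -63)
#' @noRd
round_half_up <- function(x) sign(x) * floor(abs(x) + 0.5)

stopifnot_scalar <- function(x, name, positive = TRUE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x))
    stop(sprintf("'%s' must be a single finite number", name), call. = FALSE)
  if (positive && x <= 0)
    stop(sprintf("'%s' must be positive", name), call. = FALSE)
  invisible(x)
}
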