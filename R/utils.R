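# Internal helpers shared across modules.

# Evaluate `expr` under a local RNG stream seeded with `seed`, restoring the
# caller's .Random.seed afterwards so no hidden global state leaks between
# pipeline stages.
with_local_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  expr
}

# Deterministically derive `n` child seeds from a parent seed, all < 2^31.
spawn_seeds <- function(seed, n) {
  with_local_seed(seed, sample.int(.Machine$integer.max - 1L, n))
}

# Population (divisor n) standard deviation.
sd_pop <- function(x) {
  n <- length(x)
  if (n == 0) return(NA_real_)
  sqrt(sum((x - mean(x))^2) / n)
}

as_matrix_2d <- function(x, what = "raster") {
  if (inherits(x, "Image")) x <- EBImage::imageData(x)
  if (!is.matrix(x)) stop(what, " must be a 2-D matrix")
  x
}

stop_if_empty_raster <- function(x) {
  if (length(x) == 0) stop("raster is empty")
  invisible(x)
}
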