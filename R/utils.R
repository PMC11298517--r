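#' Evaluate code with a temporary RNG seed
#'
#' Runs `code` under `set.seed(seed)` and restores the caller's RNG state
#' afterwards, so deterministic generators do not disturb user code.
#'
#' @param seed integer seed.
#' @param code expression to evaluate.
#' @return the value of `code`.
#' @keywords internal
with_seed <- function(seed, code) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  force(code)
}

# derive a reproducible sub-seed from a master seed; stays below 2^31
derive_seed <- function(seed, offset) {
  (as.numeric(seed) * 1009 + offset) %% 2147483647
}

stopifnot_3d <- function(x, what = "volume") {
  if (!(is.array(x) && length(dim(x)) == 3L))
    stop(what, " must be a 3D array (z, y, x)", call. = FALSE)
}

# coerce 2D matrix to a single-slice 3D stack
as_stack3d <- function(x) {
  if (is.matrix(x)) array(x, dim = c(1L, dim(x))) else x
}
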