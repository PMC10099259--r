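#' Seedable random-number stream
#'
#' A small stream object wrapping R's Mersenne-Twister state so that every
#' stochastic operation in the package draws from an explicit stream instead
#' of the global RNG. Passing the same stream (same seed) twice reproduces
#' results bit for bit; the global `.Random.seed` is left untouched.
#'
#' @param seed Integer seed.
#' @return An object of class `gait_rng` (an environment holding the state).
#' @export
#' @examples
#' r <- gait_rng(42)
#' rng_draw(r, function() runif(3))
gait_rng <- function(seed) {
  if (missing(seed) || !is.numeric(seed) || length(seed) != 1L || is.na(seed))
    stop("gait_rng() requires a single integer seed", call. = FALSE)
  rng <- new.env(parent = emptyenv())
  rng$state <- NULL
  class(rng) <- "gait_rng"
  rng_draw(rng, function() NULL, init_seed = as.integer(seed))
  rng
}

#' Draw from a random stream
#'
#' Runs `fun()` with the global RNG temporarily set to the stream's state,
#' then stores the advanced state back in the stream and restores the global
#' state.
#'
#' @param rng A [gait_rng()] stream.
#' @param fun A zero-argument function performing the draws.
#' @param init_seed Internal; used once at stream construction.
#' @return The value of `fun()`.
#' @export
rng_draw <- function(rng, fun, init_seed = NULL) {
  if (!inherits(rng, "gait_rng"))
    stop("'rng' must be a gait_rng stream (no hidden global RNG state)",
         call. = FALSE)
  genv <- globalenv()
  had <- exists(".Random.seed", envir = genv, inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = genv, inherits = FALSE)
  on.exit({
    if (had) assign(".Random.seed", old, envir = genv)
    else if (exists(".Random.seed", envir = genv, inherits = FALSE))
      rm(".Random.seed", envir = genv)
  })
  if (!is.null(init_seed)) {
    set.seed(init_seed)
  } else {
    assign(".Random.seed", rng$state, envir = genv)
  }
  res <- fun()
  rng$state <- get(".Random.seed", envir = genv, inherits = FALSE)
  res
}
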