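#' Reproducible random-number streams
#'
#' A `rng_stream` encapsulates its own Mersenne-Twister state: two streams
#' created with the same seed yield bit-identical draw sequences, and a
#' stream's draws are unaffected by (and do not disturb) the caller's global
#' RNG state.  The engine consumes randomness exclusively through the three
#' stream methods, which is what makes whole simulations reproducible from
#' `(params, schedule, seed)` alone and allows scripted stand-ins
#' ([scripted_rng()]) in unit tests.
#'
#' Methods (closures stored in the returned environment):
#' \describe{
#'   \item{`$runif(n)`}{`n` iid Uniform(0,1) draws.}
#'   \item{`$rpois(lambda)`}{one Poisson draw per element of `lambda`.}
#'   \item{`$sample_int(k, n)`}{`n` iid uniform draws from `1:k`.}
#' }
#'
#' @param seed Integer seed.
#' @return An environment of class `rng_stream`.
#' @examples
#' r1 <- rng_stream(42); r2 <- rng_stream(42)
#' identical(r1$runif(5), r2$runif(5))
#' @export
rng_stream <- function(seed) {
  self <- new.env(parent = emptyenv())
  self$state <- local({
    old <- get_global_seed()
    set.seed(seed)
    s <- get_global_seed()
    set_global_seed(old)
    s
  })
  with_stream <- function(expr) {
    old <- get_global_seed()
    set_global_seed(self$state)
    on.exit(set_global_seed(old))
    out <- expr
    self$state <- get_global_seed()
    out
  }
  self$runif <- function(n) with_stream(stats::runif(n))
  self$rpois <- function(lambda) with_stream(stats::rpois(length(lambda), lambda))
  self$sample_int <- function(k, n) with_stream(sample.int(k, n, replace = TRUE))
  class(self) <- "rng_stream"
  self
}

get_global_seed <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv(), inherits = FALSE)
  else NULL
}

set_global_seed <- function(state) {
  if (is.null(state)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  } else {
    assign(".Random.seed", state, envir = globalenv())
  }
  invisible(NULL)
}

#' Scripted random-number stream for deterministic tests
#'
#' A drop-in replacement for [rng_stream()] whose "draws" are consumed from
#' fixed queues, so an engine step can be driven through an exactly
#' hand-computable trajectory.  `$runif(n)` pops `n` values from `uniforms`;
#' `$rpois(lambda)` pops one count per element of `lambda` from `counts`
#' (a queued count must be 0 wherever `lambda` is 0); `$sample_int(k, n)`
#' pops `n` values from `ints` (each must lie in `1:k`).  Over-consuming any
#' queue is an error — a script is never silently recycled.
#'
#' @param uniforms Numeric queue for `$runif`.
#' @param counts Integer queue for `$rpois`.
#' @param ints Integer queue for `$sample_int`.
#' @return An environment of class `c("scripted_rng", "rng_stream")`.
#' @seealso [make_micro()] for fixtures built on scripted streams.
#' @export
scripted_rng <- function(uniforms = numeric(), counts = integer(),
                         ints = integer()) {
  self <- new.env(parent = emptyenv())
  self$uniforms <- as.numeric(uniforms)
  self$counts <- as.integer(counts)
  self$ints <- as.integer(ints)
  pop <- function(queue, n, label) {
    have <- length(self[[queue]])
    if (n > have)
      stop(sprintf("scripted RNG exhausted: %s queue has %d values, %d requested",
                   label, have, n))
    out <- self[[queue]][seq_len(n)]
    self[[queue]] <- self[[queue]][-seq_len(n)]
    out
  }
  self$runif <- function(n) pop("uniforms", n, "uniform")
  self$rpois <- function(lambda) {
    out <- pop("counts", length(lambda), "count")
    if (any(out > 0 & lambda == 0))
      stop("scripted RNG: positive count scripted for a zero rate")
    out
  }
  self$sample_int <- function(k, n) {
    out <- pop("ints", n, "integer")
    if (n > 0 && any(out < 1 | out > k))
      stop("scripted RNG: scripted integer outside 1..k")
    out
  }
  class(self) <- c("scripted_rng", "rng_stream")
  self
}
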