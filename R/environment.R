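#' Environment schedules
#'
#' An environment schedule maps a (0-based) time step to the environmental
#' resource availability \eqn{R_0(t)} that every group receives as its
#' baseline.  Two kinds are supported: a constant baseline, and a sinusoid
#' \deqn{R_0(t) = R_0^0 + A \sin(2 \pi t / P)}
#' with amplitude `A` and period `P` steps.  The amplitude must satisfy
#' `A < R00` so that resources stay strictly positive (the reproduction and
#' sharing rules presume positive resources).
#'
#' @param R00 Baseline environmental resource availability (positive).
#' @param A Amplitude of the sinusoidal fluctuation (resource units),
#'   `0 <= A < R00`.
#' @param P Period of the fluctuation (steps, at least 2).
#' @return An object of class `env_schedule`.
#' @seealso [resource_at()]
#' @examples
#' resource_at(env_constant(8), 0:3)
#' resource_at(env_sinusoidal(4, A = 3, P = 500), c(0, 125))
#' @export
env_constant <- function(R00) {
  if (!(R00 > 0)) stop("invalid schedule: R00 must be positive")
  structure(list(kind = "constant", R00 = R00, A = 0, P = NA_real_),
            class = "env_schedule")
}

#' @rdname env_constant
#' @export
env_sinusoidal <- function(R00, A, P) {
  if (!(R00 > 0)) stop("invalid schedule: R00 must be positive")
  if (!(A >= 0)) stop("invalid schedule: A must be non-negative")
  if (A >= R00)
    stop("invalid schedule: A must be smaller than R00 (resources must stay positive)")
  if (!(P >= 2)) stop("invalid schedule: P must be at least 2 steps")
  structure(list(kind = "sinusoidal", R00 = R00, A = A, P = P),
            class = "env_schedule")
}

#' Environmental resource availability at a time step
#'
#' Evaluate an [env_constant()]/[env_sinusoidal()] schedule at integer step
#' `t` (0-based, vectorized).  Sinusoidal schedules are exactly periodic:
#' `resource_at(sch, t) == resource_at(sch, t + P)` for integer `t` and
#' integer `P`, and average to `R00` over any full period.
#'
#' @param schedule An `env_schedule`.
#' @param t Step index (non-negative integer(s)).
#' @return Resource availability, same length as `t`; always positive.
#' @export
resource_at <- function(schedule, t) {
  stopifnot(inherits(schedule, "env_schedule"))
  if (any(t < 0)) stop("invalid parameter: t must be non-negative")
  if (schedule$kind == "constant") {
    rep(schedule$R00, length(t))
  } else {
    # evaluate sin at the reduced phase so exact integer periodicity holds
    schedule$R00 + schedule$A * sin(2 * pi * (t %% schedule$P) / schedule$P)
  }
}

#' @export
print.env_schedule <- function(x, ...) {
  if (x$kind == "constant") {
    cat(sprintf("Constant environment: R0 = %g\n", x$R00))
  } else {
    cat(sprintf("Sinusoidal environment: R0(t) = %g + %g sin(2 pi t / %g)\n",
                x$R00, x$A, x$P))
  }
  invisible(x)
}
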