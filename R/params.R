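#' Simulation parameters
#'
#' Construct and validate the full parameter set of the individual-based
#' model.  Every model constant is held in one immutable list so that a run
#' is fully described by `(params, schedule, seed)`.
#'
#' The defaults not fixed by the model description (`alpha`, `beta`, `M`,
#' `Ks`, `I`, `c`, `age_standard`) are package calibration choices (see the
#' methods vignette and [calibrate()]): they are set so that non-social
#' populations persist under benign resource availability (`R00 = 8`) but
#' go extinct under harsh availability (`R00 = 1`), social populations with
#' high cooperation efficiency (`bK = 5`) persist even under harsh
#' availability, high-degree cooperation evolves under harsh availability
#' while benign populations retain only minimal-degree cooperation, and
#' sinusoidally forced social populations are buffered (less synchronized
#' with the forcing, and with a smaller relative-fluctuation spectrum peak)
#' relative to non-social ones.  In particular `beta = 1` makes cooperation
#' maximally costly, which is what lets cooperative investment collapse in
#' benign phases and rebound in harsh ones.
#'
#' @param R00 Baseline environmental resource availability per group
#'   (resource units); must be positive.
#' @param I Maximum resource increment rate (dimensionless multiplier on
#'   the baseline: cooperative benefits can raise group resources up to,
#'   but never to, `R00 * (1 + I)`).
#' @param bK Cooperation efficiency (resource units gained per unit of
#'   summed cooperation degree); `bK = 0` switches cooperative benefits off.
#' @param alpha Maximum per-individual reproductive rate (offspring per
#'   step).
#' @param beta Fractional reproduction cost per unit cooperation degree;
#'   must satisfy `0 < beta <= 1`.
#' @param M Metabolic consumption (resource units per individual per step);
#'   reproduction requires a per-capita share strictly above `M`.
#' @param Ks Half-saturation constant for reproduction (resource units):
#'   the net intake `s - M` at which the reproductive rate is `alpha/2`
#'   (for a free-rider).
#' @param c Newborn survival probability, in `(0, 1]`.
#' @param age_standard Survival e-folding age (steps): survival probability
#'   is `c * exp(-age / age_standard)`.
#' @param m Per-offspring mutation probability.
#' @param n_groups Number of group slots (patches).  Must be 1 when
#'   `scenario = "non_structured"`.
#' @param N_init Initial population size.
#' @param T Total number of simulation steps.
#' @param trait_levels Admissible cooperation degrees: exactly 11 equally
#'   spaced values spanning `[0, 1]`.
#' @param scenario One of `"social"` (heritable cooperation degree, free to
#'   evolve), `"non_social"` (trait locked at 0: a population consisting
#'   exclusively of free-riders), or `"non_structured"` (single well-mixed
#'   group, trait free to evolve).
#'
#' @return An object of class `sim_params`: a validated named list.
#' @examples
#' p <- sim_params(R00 = 1, bK = 5, T = 200)
#' p$alpha
#' @export
sim_params <- function(R00 = 4, I = 5, bK = 5, alpha = 2, beta = 1,
                       M = 1, Ks = 1, c = 0.9, age_standard = 5,
                       m = 0.001, n_groups = 90, N_init = 300, T = 10000,
                       trait_levels = seq(0, 1, by = 0.1),
                       scenario = c("social", "non_social",
                                    "non_structured")) {
  scenario <- match.arg(scenario)
  p <- list(R00 = R00, I = I, bK = bK, alpha = alpha, beta = beta,
            M = M, Ks = Ks, c = c, age_standard = age_standard, m = m,
            n_groups = as.integer(n_groups), N_init = as.integer(N_init),
            T = as.integer(T), trait_levels = as.numeric(trait_levels),
            scenario = scenario)
  validate_sim_params(p)
  structure(p, class = "sim_params")
}

validate_sim_params <- function(p) {
  stopifnot(is.numeric(p$R00), length(p$R00) == 1)
  if (!(p$R00 > 0)) stop("invalid parameter: R00 must be positive")
  if (!(p$I > 0)) stop("invalid parameter: I must be positive")
  if (!(p$bK >= 0)) stop("invalid parameter: bK must be non-negative")
  if (!(p$alpha > 0)) stop("invalid parameter: alpha must be positive")
  if (!(p$beta > 0 && p$beta <= 1))
    stop("invalid parameter: beta must satisfy 0 < beta <= 1")
  if (!(p$M >= 0)) stop("invalid parameter: M must be non-negative")
  if (!(p$Ks > 0)) stop("invalid parameter: Ks must be positive")
  if (!(p$c > 0 && p$c <= 1))
    stop("invalid parameter: c must satisfy 0 < c <= 1")
  if (!(p$age_standard > 0))
    stop("invalid parameter: age_standard must be positive")
  if (!(p$m >= 0 && p$m <= 1))
    stop("invalid parameter: m must be a probability")
  if (!(p$n_groups >= 1)) stop("invalid parameter: n_groups must be >= 1")
  if (!(p$N_init >= 1)) stop("invalid parameter: N_init must be >= 1")
  if (!(p$T >= 1)) stop("invalid parameter: T must be >= 1")
  tl <- p$trait_levels
  if (length(tl) != 11 || abs(tl[1]) > 1e-12 || abs(tl[11] - 1) > 1e-12 ||
      max(abs(diff(tl) - 0.1)) > 1e-9)
    stop("invalid parameter: trait_levels must be 11 equally spaced values in [0, 1]")
  if (p$scenario == "non_structured" && p$n_groups != 1L)
    stop("invalid parameter: non_structured scenario requires n_groups = 1")
  invisible(p)
}

#' @export
print.sim_params <- function(x, ...) {
  cat("Simulation parameters (", x$scenario, " scenario)\n", sep = "")
  cat(sprintf("  resources : R00=%g  I=%g  bK=%g  M=%g  Ks=%g\n",
              x$R00, x$I, x$bK, x$M, x$Ks))
  cat(sprintf("  life cycle: alpha=%g  beta=%g  c=%g  age_standard=%g  m=%g\n",
              x$alpha, x$beta, x$c, x$age_standard, x$m))
  cat(sprintf("  structure : n_groups=%d  N_init=%d  T=%d\n",
              x$n_groups, x$N_init, x$T))
  invisible(x)
}

#' Modify simulation parameters
#'
#' Return a copy of a [sim_params()] object with the named fields replaced
#' and all invariants revalidated.
#'
#' @param p A `sim_params` object.
#' @param ... Named fields to replace (e.g. `R00 = 1`, `scenario =
#'   "non_social"`).
#' @return A validated `sim_params` object.
#' @examples
#' update_params(sim_params(), R00 = 1, bK = 3)
#' @export
update_params <- function(p, ...) {
  new <- list(...)
  for (nm in names(new)) p[[nm]] <- new[[nm]]
  p$n_groups <- as.integer(p$n_groups)
  p$N_init <- as.integer(p$N_init)
  p$T <- as.integer(p$T)
  validate_sim_params(p)
  structure(p, class = "sim_params")
}
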