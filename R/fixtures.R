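#' Deterministic micro-scenarios for the engine
#'
#' Frozen single-step scenarios whose every random outcome is scripted
#' ([scripted_rng()]) and whose expected next state was computed by hand
#' from the model equations, so [step_population()] can be checked
#' bit-exactly.  Available fixtures:
#' \describe{
#'   \item{`three_cooperators`}{one group of three full cooperators —
#'     exercises the saturating group-resource chain
#'     R = 37/7, s = 37/21, F = 16/37 per member.}
#'   \item{`mixed_group`}{a free-rider and a half-cooperator sharing one
#'     group — exercises the reproduction cost asymmetry
#'     F(free-rider)/F(cooperator) = 1/(1 - beta * 0.5).}
#'   \item{`starvation`}{a group whose share never exceeds metabolic
#'     consumption — no births, deaths only.}
#'   \item{`aging_cohort`}{solitary individuals at ages 0, 5, 10
#'     (= 0, 1, 2 e-folding ages) — exercises the exponential survival
#'     decline.}
#' }
#'
#' Each fixture bundles the parameters, the explicit starting state, the
#' step's resource availability, a fresh scripted stream, and the expected
#' post-step record and member-level state (`phi`, `age`, `gid`) plus the
#' expected per-member reproductive rates.
#'
#' @param name Fixture name.
#' @return A list with elements `name`, `params`, `state`, `R0_t`, `rng`,
#'   and `expected` (list: `rates`, `record`, `phi`, `age`, `gid`).
#' @examples
#' fx <- make_micro("starvation")
#' out <- step_population(fx$state, fx$R0_t, fx$params, fx$rng)
#' out$record$N == fx$expected$record$N
#' @export
make_micro <- function(name = c("three_cooperators", "mixed_group",
                                "starvation", "aging_cohort")) {
  name <- match.arg(name)
  mk_state <- function(phi, age, gid, n_groups) {
    structure(list(phi = as.numeric(phi), age = as.integer(age),
                   gid = as.integer(gid), n_groups = as.integer(n_groups),
                   t = 0L, extinct = FALSE),
              class = "population_state")
  }
  rec <- function(R0, N, n_coop, prop_coop, mean_degree, births, deaths) {
    data.frame(t = 0L, R0 = R0, N = as.integer(N),
               n_coop = as.integer(n_coop), prop_coop = prop_coop,
               mean_degree = mean_degree, births = as.integer(births),
               deaths = as.integer(deaths))
  }
  # fixtures pin every life-cycle constant themselves (independent of the
  # shipped calibration defaults) so the hand-derived chains stay frozen
  base <- sim_params(R00 = 1, I = 5, bK = 5, alpha = 2, beta = 0.5,
                     M = 1, Ks = 1, c = 0.9, age_standard = 5, m = 0,
                     n_groups = 2, N_init = 3, T = 1)
  switch(name,
    three_cooperators = list(
      # R = 1*(1 + 5*15/(2.5 + 15)) = 37/7; s = 37/21;
      # F = 2*(1 - 0.5)*(16/21)/(1 + 16/21) = 16/37 for each member.
      name = name,
      params = base,
      state = mk_state(phi = c(1, 1, 1), age = c(1, 1, 1),
                       gid = c(1, 1, 1), n_groups = 2),
      R0_t = 1,
      rng = scripted_rng(
        counts = c(1L, 0L, 2L),            # offspring of members 1..3
        ints = c(2L, 1L, 2L),              # dispersal slots of offspring
        # survival: parents at age 1 (r = 0.9 e^{-0.2}), newborns (r = 0.9)
        uniforms = c(0.5, 0.99, 0.1, 0.95, 0.2, 0.3)),
      expected = list(
        rates = rep(16 / 37, 3),
        record = rec(R0 = 1, N = 4, n_coop = 4, prop_coop = 1,
                     mean_degree = 1, births = 3, deaths = 2),
        phi = c(1, 1, 1, 1), age = c(2L, 2L, 1L, 1L),
        gid = c(1L, 1L, 1L, 2L))),
    mixed_group = list(
      # R = 4*(1 + 5*2.5/(10 + 2.5)) = 8; s = 4;
      # F(free-rider) = 2*(3/4) = 1.5, F(phi = 0.5) = 1.5*0.75 = 1.125.
      name = name,
      params = update_params(base, R00 = 4),
      state = mk_state(phi = c(0, 0.5), age = c(3, 3), gid = c(1, 1),
                       n_groups = 2),
      R0_t = 4,
      rng = scripted_rng(
        counts = c(1L, 1L),
        ints = c(1L, 2L),
        # parents at age 3: r = 0.9 e^{-0.6} = 0.4939...; newborns 0.9
        uniforms = c(0.4, 0.6, 0.05, 0.05)),
      expected = list(
        rates = c(1.5, 1.125),
        record = rec(R0 = 4, N = 3, n_coop = 1, prop_coop = 1 / 3,
                     mean_degree = 0.5 / 3, births = 2, deaths = 1),
        phi = c(0, 0, 0.5), age = c(4L, 1L, 1L), gid = c(1L, 1L, 2L))),
    starvation = list(
      # share s = 2/3 < M = 1 in the only occupied group: no births ever.
      name = name,
      params = update_params(base, R00 = 2, scenario = "non_social"),
      state = mk_state(phi = c(0, 0, 0), age = c(0, 10, 20),
                       gid = c(1, 1, 1), n_groups = 2),
      R0_t = 2,
      rng = scripted_rng(
        counts = c(0L, 0L, 0L),
        # r = 0.9, 0.9 e^{-2} = 0.1218..., 0.9 e^{-4} = 0.01648...
        uniforms = c(0.8, 0.5, 0.5)),
      expected = list(
        rates = c(0, 0, 0),
        record = rec(R0 = 2, N = 1, n_coop = 0, prop_coop = 0,
                     mean_degree = 0, births = 0, deaths = 2),
        phi = 0, age = 1L, gid = 1L)),
    aging_cohort = list(
      # solitary free-riders, abundant resources (s = 40, F = 1.95 each);
      # survival probs 0.9, 0.9/e, 0.9/e^2 at ages 0, 5, 10.
      name = name,
      params = update_params(base, R00 = 40, bK = 0, n_groups = 3,
                             scenario = "non_social"),
      state = mk_state(phi = c(0, 0, 0), age = c(0, 5, 10),
                       gid = c(1, 2, 3), n_groups = 3),
      R0_t = 40,
      rng = scripted_rng(
        counts = c(2L, 0L, 1L),
        ints = c(1L, 2L, 3L),
        uniforms = c(0.85, 0.4, 0.13, 0.1, 0.2, 0.91)),
      expected = list(
        rates = rep(2 * 39 / 40, 3),
        survival = 0.9 * exp(-c(0, 1, 2)),
        record = rec(R0 = 40, N = 3, n_coop = 0, prop_coop = 0,
                     mean_degree = 0, births = 3, deaths = 3),
        phi = c(0, 0, 0), age = c(1L, 1L, 1L), gid = c(1L, 1L, 2L))))
}
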