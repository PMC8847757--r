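#' Initialize a population
#'
#' Create the step-0 state: `N_init` individuals, all at age 0, each
#' assigned a group slot uniformly at random among the `n_groups` slots.
#' In the `social` and `non_structured` scenarios each individual's
#' cooperation degree is drawn uniformly from the 11 trait levels; in the
#' `non_social` scenario every degree is 0 (a population consisting
#' exclusively of free-riders).
#'
#' Draw order (relevant for scripted streams): group slots first
#' (`sample_int(n_groups, N_init)`), then — unless `non_social` — trait
#' levels (`sample_int(11, N_init)`).
#'
#' @param params A [sim_params()] object.
#' @param rng A [rng_stream()] (or [scripted_rng()]).
#' @return An object of class `population_state`: a list with numeric
#'   `phi`, integer `age` and `gid` (parallel vectors, one element per
#'   individual), `n_groups`, the current step `t` (0 at initialization)
#'   and the `extinct` flag.
#' @export
initialize_population <- function(params, rng) {
  validate_sim_params(params)
  n <- params$N_init
  gid <- rng$sample_int(params$n_groups, n)
  phi <- if (params$scenario == "non_social") {
    numeric(n)
  } else {
    params$trait_levels[rng$sample_int(length(params$trait_levels), n)]
  }
  structure(list(phi = phi, age = integer(n), gid = as.integer(gid),
                 n_groups = params$n_groups, t = 0L, extinct = FALSE),
            class = "population_state")
}

#' @export
print.population_state <- function(x, ...) {
  cat(sprintf("Population state at t = %d: N = %d in %d group slots (%d occupied)\n",
              x$t, length(x$phi), x$n_groups, length(unique(x$gid))))
  if (length(x$phi))
    cat(sprintf("  cooperators: %d (%.1f%%), mean degree %.3f\n",
                sum(x$phi > 0), 100 * mean(x$phi > 0), mean(x$phi)))
  invisible(x)
}

# Cheap one-row data.frame (skips data.frame()'s per-call validation;
# called once per simulation step).
one_row <- function(...) {
  structure(list(...), class = "data.frame", row.names = c(NA, -1L))
}

# Summed cooperation degree per group slot (length n_groups; 0 for empty).
group_sum_phi <- function(phi, gid, n_groups) {
  out <- numeric(n_groups)
  if (length(phi)) {
    s <- rowsum(phi, gid)
    out[as.integer(rownames(s))] <- s[, 1]
  }
  out
}

#' Reproduction within one group
#'
#' Each member's reproductive rate is [reproductive_rate()] evaluated at the
#' group's equal share `s = R_group / length(phi)`; its realized offspring
#' count is drawn Poisson with that mean, so the expected total offspring of
#' the group equals the summed rates.  Offspring inherit the parent's
#' cooperation degree (mutation is applied separately, see
#' [mutate_degree()]) and start at age 0.
#'
#' @param phi Cooperation degrees of the group's members (non-empty).
#' @param R_group Group resources from [group_resource()].
#' @param params A [sim_params()] object.
#' @param rng A [rng_stream()].
#' @return A list with `rate` (per-member expected offspring), `n_offspring`
#'   (per-member realized counts) and `offspring_phi` (inherited degrees,
#'   one per offspring, in member order).
#' @export
reproduce_group <- function(phi, R_group, params, rng) {
  if (!length(phi)) stop("empty group: reproduction undefined")
  s <- per_capita_share(R_group, length(phi))
  rate <- reproductive_rate(params$alpha, params$beta, phi, s,
                            params$M, params$Ks)
  counts <- rng$rpois(rate)
  list(rate = rate, n_offspring = counts,
       offspring_phi = rep(phi, counts))
}

#' Mutate offspring cooperation degrees
#'
#' Each offspring independently keeps its inherited degree with probability
#' `1 - m`; with probability `m` its degree is redrawn uniformly from the 11
#' trait levels (possibly landing back on the parental value), so
#' cooperation can arise de novo even from an all-free-rider population.
#' In the `non_social` scenario the trait is locked: the result is always 0
#' and no randomness is consumed.
#'
#' Draw order: one uniform per offspring, then one level index per mutant.
#' No uniforms are consumed when `m = 0`.
#'
#' @param phi Inherited degree(s) (vectorized).
#' @inheritParams reproduce_group
#' @return Mutated degree(s), same length as `phi`.
#' @export
mutate_degree <- function(phi, params, rng) {
  if (params$scenario == "non_social") return(numeric(length(phi)))
  n <- length(phi)
  if (n == 0L || params$m == 0) return(phi)
  mutant <- rng$runif(n) < params$m
  k <- sum(mutant)
  if (k > 0)
    phi[mutant] <- params$trait_levels[rng$sample_int(length(params$trait_levels), k)]
  phi
}

#' Disperse offspring among group slots
#'
#' Offspring join group slots independently and uniformly at random over
#' all `n_groups` slots, including currently empty ones — there is no
#' explicit spatial structure and no natal-patch bias, so empty slots can
#' be recolonized.
#'
#' @param n_offspring Number of dispersing offspring.
#' @param n_groups Number of group slots.
#' @inheritParams reproduce_group
#' @return Integer vector of slot assignments (length `n_offspring`).
#' @export
disperse <- function(n_offspring, n_groups, rng) {
  if (n_groups < 1) stop("invalid parameter: n_groups must be >= 1")
  if (n_offspring == 0L) return(integer())
  as.integer(rng$sample_int(n_groups, n_offspring))
}

#' Apply age-dependent survival
#'
#' Every individual — parents and the current step's newborns alike —
#' survives independently with probability
#' [survival_probability()]`(c, age, age_standard)`; newborns face exactly
#' `c` because their age is 0.  Survivors' ages then increment by one, so a
#' newborn that survives its birth step enters the next step at age 1.
#'
#' Draw order: one uniform per individual, in storage order (parents first,
#' then this step's offspring); an individual survives when its uniform is
#' strictly below its survival probability.
#'
#' @param state A `population_state` (possibly already containing the
#'   step's offspring).
#' @inheritParams reproduce_group
#' @return A list with the post-survival `state` and the number of `deaths`.
#' @export
apply_survival <- function(state, params, rng) {
  n <- length(state$phi)
  if (n == 0L) return(list(state = state, deaths = 0L))
  r <- survival_probability(params$c, state$age, params$age_standard)
  alive <- rng$runif(n) < r
  state$phi <- state$phi[alive]
  state$age <- state$age[alive] + 1L
  state$gid <- state$gid[alive]
  list(state = state, deaths = sum(!alive))
}

#' Advance the population by one step
#'
#' One full life cycle, in fixed order: (1) each occupied group produces
#' resources ([group_resource()] at the step's `R0_t`) which members share
#' equally; (2) members reproduce ([reproduce_group()], Poisson offspring);
#' (3) offspring degrees mutate ([mutate_degree()]); (4) offspring disperse
#' uniformly over all slots ([disperse()]); (5) everyone faces survival
#' ([apply_survival()]); (6) the step counter increments.
#'
#' Reproductive observables (births, and the per-group snapshot if
#' requested) are recorded at the reproduction stage, before dispersal and
#' survival; population-composition observables (`N`, cooperator counts,
#' mean degree) are recorded after survival.  An extinct population (`N =
#' 0`) is absorbing: the step only advances `t` and records zeros.
#'
#' @param state A `population_state`.
#' @param R0_t Environmental resource availability this step (see
#'   [resource_at()]).
#' @inheritParams reproduce_group
#' @param collect_groups If `TRUE`, also return the per-group table
#'   (`group_id`, `size`, `sum_phi`, `R_group`, `total_offspring`,
#'   `per_capita_offspring`) captured at the reproduction stage.
#' @return A list with the advanced `state`, a one-row data.frame `record`
#'   (`t`, `R0`, `N`, `n_coop`, `prop_coop`, `mean_degree`, `births`,
#'   `deaths`; `t` is the 0-based index of the step just executed), and
#'   `groups` (data.frame or `NULL`).
#' @export
step_population <- function(state, R0_t, params, rng,
                            collect_groups = FALSE) {
  t0 <- state$t
  n <- length(state$phi)
  if (n == 0L) {
    state$t <- t0 + 1L
    state$extinct <- TRUE
    rec <- one_row(t = t0, R0 = R0_t, N = 0L, n_coop = 0L,
                   prop_coop = 0, mean_degree = 0, births = 0L,
                   deaths = 0L)
    return(list(state = state, record = rec, groups = NULL))
  }

  ng <- state$n_groups
  sizes <- tabulate(state$gid, nbins = ng)
  sum_phi <- group_sum_phi(state$phi, state$gid, ng)
  occupied <- sizes > 0L
  Rg <- rep(NA_real_, ng)
  Rg[occupied] <- group_resource(R0_t, params$I, params$bK,
                                 sum_phi[occupied])

  # reproduction: rates for every individual at its group's equal share,
  # Poisson counts drawn in storage order
  s_ind <- Rg[state$gid] / sizes[state$gid]
  rate <- reproductive_rate(params$alpha, params$beta, state$phi, s_ind,
                            params$M, params$Ks)
  counts <- rng$rpois(rate)
  births <- sum(counts)
  off_phi <- rep(state$phi, counts)
  off_parent_gid <- rep(state$gid, counts)

  groups <- NULL
  if (collect_groups) {
    tot_off <- numeric(ng)
    if (births > 0) {
      bo <- rowsum(counts, state$gid)
      tot_off[as.integer(rownames(bo))] <- bo[, 1]
    }
    groups <- data.frame(t = t0, group_id = which(occupied),
                         size = sizes[occupied],
                         sum_phi = sum_phi[occupied],
                         R_group = Rg[occupied],
                         total_offspring = tot_off[occupied])
    groups$per_capita_offspring <- groups$total_offspring / groups$size
  }

  off_phi <- mutate_degree(off_phi, params, rng)
  off_gid <- disperse(births, ng, rng)

  state$phi <- c(state$phi, off_phi)
  state$age <- c(state$age, integer(births))
  state$gid <- c(state$gid, off_gid)

  surv <- apply_survival(state, params, rng)
  state <- surv$state
  state$t <- t0 + 1L
  Npost <- length(state$phi)
  state$extinct <- Npost == 0L
  n_coop <- sum(state$phi > 0)
  rec <- one_row(t = t0, R0 = R0_t, N = Npost, n_coop = n_coop,
                 prop_coop = if (Npost) n_coop / Npost else 0,
                 mean_degree = if (Npost) mean(state$phi) else 0,
                 births = births, deaths = as.integer(surv$deaths))
  list(state = state, record = rec, groups = groups)
}

#' Run a full simulation
#'
#' Drive [step_population()] for `params$T` steps with per-step resource
#' availability taken from the schedule, starting from
#' [initialize_population()].  The run is deterministic given
#' `(params, schedule, seed)`.  After extinction the series continues with
#' `N = 0` rows so all replicates have equal length.
#'
#' @param params A [sim_params()] object.
#' @param schedule An `env_schedule`; defaults to a constant environment at
#'   `params$R00`.
#' @param seed Integer seed used to create the run's [rng_stream()]
#'   (ignored when `rng` is supplied).
#' @param rng Optionally, an existing stream (e.g. a [scripted_rng()]).
#' @param snapshot_steps Integer vector of 0-based step indices at which the
#'   per-group table is captured (the group-level reproduction surface).
#' @return A data.frame of class `replicate_series` with one row per step
#'   (`t`, `R0`, `N`, `n_coop`, `prop_coop`, `mean_degree`, `births`,
#'   `deaths`) and attributes `params`, `schedule`, `seed`, `extinct`
#'   (whether the run ended extinct) and `group_snapshots` (data.frame,
#'   possibly empty).
#' @examples
#' p <- sim_params(R00 = 8, scenario = "non_social", T = 50)
#' head(run_simulation(p, seed = 1))
#' @export
run_simulation <- function(params, schedule = NULL, seed = NULL,
                           rng = NULL, snapshot_steps = integer()) {
  validate_sim_params(params)
  if (is.null(schedule)) schedule <- env_constant(params$R00)
  stopifnot(inherits(schedule, "env_schedule"))
  if (is.null(rng)) {
    if (is.null(seed)) stop("supply either a seed or an rng stream")
    rng <- rng_stream(seed)
  }
  state <- initialize_population(params, rng)
  T <- params$T
  R0_all <- resource_at(schedule, seq_len(T) - 1L)
  rows <- vector("list", T)
  snaps <- list()
  for (i in seq_len(T)) {
    out <- step_population(state, R0_all[i], params, rng,
                           collect_groups = (i - 1L) %in% snapshot_steps)
    state <- out$state
    rows[[i]] <- out$record
    if (!is.null(out$groups)) snaps[[length(snaps) + 1L]] <- out$groups
  }
  series <- data.frame(
    t = vapply(rows, function(r) as.integer(r$t), integer(1)),
    R0 = vapply(rows, function(r) r$R0, numeric(1)),
    N = vapply(rows, function(r) as.integer(r$N), integer(1)),
    n_coop = vapply(rows, function(r) as.integer(r$n_coop), integer(1)),
    prop_coop = vapply(rows, function(r) r$prop_coop, numeric(1)),
    mean_degree = vapply(rows, function(r) r$mean_degree, numeric(1)),
    births = vapply(rows, function(r) as.integer(r$births), integer(1)),
    deaths = vapply(rows, function(r) as.integer(r$deaths), integer(1)))
  attr(series, "params") <- params
  attr(series, "schedule") <- schedule
  attr(series, "seed") <- seed
  attr(series, "extinct") <- state$extinct
  attr(series, "group_snapshots") <-
    if (length(snaps)) do.call(rbind, snaps) else
      data.frame(t = integer(), group_id = integer(), size = integer(),
                 sum_phi = numeric(), R_group = numeric(),
                 total_offspring = numeric(),
                 per_capita_offspring = numeric())
  class(series) <- c("replicate_series", "data.frame")
  series
}
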