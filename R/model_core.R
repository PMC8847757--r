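#' Group resources generated from cooperative benefits
#'
#' Resources available to one group in one step: the environmental baseline
#' plus a saturating (Monod-type) increment produced by the group's summed
#' cooperation degree,
#' \deqn{R = R_0 \left(1 + \frac{I \, b_K \Sigma\phi}{I R_0 / 2 + b_K
#'   \Sigma\phi}\right),}
#' where \eqn{I} is the maximum resource increment rate and \eqn{b_K} the
#' cooperation efficiency.  When `bK * sum_phi = I * R0_t / 2` the increment
#' is exactly half its maximum (`I/2` of the baseline).  Groups without
#' cooperative benefits (`bK * sum_phi = 0`) receive exactly the baseline
#' `R0_t`.  The result is strictly increasing in `sum_phi` and strictly
#' below `R0_t * (1 + I)`.
#'
#' @param R0_t Environmental resource availability at the current step
#'   (positive).
#' @param I Maximum resource increment rate.
#' @param bK Cooperation efficiency.
#' @param sum_phi Summed cooperation degree of the group's members
#'   (non-negative; vectorized).
#' @return Group resources, same length as `sum_phi`.
#' @examples
#' group_resource(4, I = 5, bK = 5, sum_phi = 0)   # baseline only
#' group_resource(1, I = 5, bK = 5, sum_phi = 3)   # 37/7
#' @export
group_resource <- function(R0_t, I, bK, sum_phi) {
  if (any(R0_t <= 0)) stop("invalid parameter: R0_t must be positive")
  if (any(sum_phi < 0)) stop("invalid parameter: sum_phi must be non-negative")
  if (bK < 0) stop("invalid parameter: bK must be non-negative")
  benefit <- bK * sum_phi
  R0_t * (1 + I * benefit / (I * R0_t / 2 + benefit))
}

#' Per-capita share of group resources
#'
#' Group resources are shared equally: each of `N_group` members receives
#' `R_group / N_group`, so shares sum exactly back to the group resource.
#'
#' @param R_group Group resources (non-negative).
#' @param N_group Number of members (at least 1).
#' @return The equal share per member.
#' @examples
#' per_capita_share(6, 3)
#' @export
per_capita_share <- function(R_group, N_group) {
  if (any(N_group == 0)) stop("empty group: per-capita share undefined")
  if (any(N_group < 0) || any(R_group < 0))
    stop("invalid parameter: R_group >= 0 and N_group >= 1 required")
  R_group / N_group
}

#' Per-individual reproductive rate
#'
#' Expected offspring per step: a Monod saturating function of the net
#' resource intake `s - M` (share minus metabolic consumption), discounted
#' by the cooperation cost,
#' \deqn{F = \alpha (1 - \beta \phi) \frac{s - M}{K_s + (s - M)}, \quad
#'   s > M,}
#' and 0 when `s <= M` (starvation halts reproduction but does not directly
#' kill; mortality is governed solely by [survival_probability()]).  `Ks` is
#' the half-saturation constant: at `s - M = Ks` a free-rider reproduces at
#' `alpha / 2`.
#'
#' @param alpha Maximum reproductive rate.
#' @param beta Fractional cost per unit cooperation degree (`0 < beta <= 1`).
#' @param phi Cooperation degree(s) in `[0, 1]` (vectorized).
#' @param s Per-capita resource share(s) (vectorized, recycled with `phi`).
#' @param M Metabolic consumption.
#' @param Ks Half-saturation constant (positive).
#' @return Reproductive rate(s) in `[0, alpha]`.
#' @examples
#' reproductive_rate(2, 0.5, phi = 0, s = 2, M = 1, Ks = 1)    # alpha/2
#' reproductive_rate(2, 0.5, phi = 0.4, s = 37/21, M = 1, Ks = 1)
#' @export
reproductive_rate <- function(alpha, beta, phi, s, M, Ks) {
  if (any(phi < 0 | phi > 1))
    stop("invalid parameter: phi must lie in [0, 1]")
  if (any(s < 0)) stop("invalid parameter: s must be non-negative")
  n <- max(length(phi), length(s))
  phi <- rep_len(phi, n)
  net <- rep_len(s, n) - M
  rate <- alpha * (1 - beta * phi) * net / (Ks + net)
  rate[net <= 0] <- 0
  rate
}

#' Age-dependent survival probability
#'
#' Survival declines exponentially with age:
#' \deqn{r = c \, e^{-\mathrm{age} / \mathrm{age}_{standard}},}
#' so a newborn (age 0) survives its birth step with probability `c` and
#' survival drops by a factor `e` every `age_standard` steps.
#'
#' @param c Newborn survival probability in `(0, 1]`.
#' @param age Completed steps alive (non-negative; vectorized).
#' @param age_standard E-folding age (positive).
#' @return Survival probability/probabilities in `(0, c]`.
#' @examples
#' survival_probability(0.9, age = 0, age_standard = 5)  # c itself
#' survival_probability(0.9, age = 5, age_standard = 5)  # c / e
#' @export
survival_probability <- function(c, age, age_standard) {
  if (!(c > 0 && c <= 1)) stop("invalid parameter: c must be in (0, 1]")
  if (any(age < 0)) stop("invalid parameter: age must be non-negative")
  if (!(age_standard > 0))
    stop("invalid parameter: age_standard must be positive")
  c * exp(-age / age_standard)
}
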