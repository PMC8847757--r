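#' Aggregate replicate series
#'
#' Pointwise mean and standard deviation of every shared numeric observable
#' across replicate runs (e.g. the 20- or 500-replicate summaries behind
#' mean-and-sd figures).  All series must have equal length; the step
#' column `t` is carried through unchanged.
#'
#' @param series_list A list of data.frames of equal length with identical
#'   column sets (e.g. [run_simulation()] outputs).
#' @return A data.frame of class `aggregate_series` with columns `t`,
#'   `mean_<var>` and `sd_<var>` for each observable, and attribute
#'   `n_replicates`.  With a single replicate the `sd_` columns are `NA`.
#' @export
aggregate_replicates <- function(series_list) {
  if (!length(series_list)) stop("no series supplied")
  lens <- vapply(series_list, nrow, integer(1))
  if (length(unique(lens)) != 1L)
    stop("shape mismatch: replicate series have unequal lengths")
  vars <- setdiff(names(series_list[[1]]), "t")
  for (s in series_list)
    if (!identical(setdiff(names(s), "t"), vars))
      stop("shape mismatch: replicate series have different columns")
  out <- data.frame(t = series_list[[1]]$t)
  nrep <- length(series_list)
  for (v in vars) {
    mat <- vapply(series_list, function(s) as.numeric(s[[v]]),
                  numeric(lens[1]))
    mat <- matrix(mat, nrow = lens[1])
    out[[paste0("mean_", v)]] <- rowMeans(mat)
    out[[paste0("sd_", v)]] <- if (nrep >= 2) apply(mat, 1, stats::sd)
                               else NA_real_
  }
  attr(out, "n_replicates") <- nrep
  class(out) <- c("aggregate_series", "data.frame")
  out
}

#' Drop the transient portion of a series
#'
#' Simulations are summarized on their late, relatively stable window: the
#' first `ceiling(fraction * length)` steps are discarded.  Works on
#' vectors and on data.frames (row-wise).
#'
#' @param x A vector or data.frame.
#' @param fraction Burn-in fraction in `[0, 1)`; default 0.5 (second half).
#' @return The trailing sub-series.
#' @examples
#' stable_window(1:10, 0.5)
#' @export
stable_window <- function(x, fraction = 0.5) {
  if (!(fraction >= 0 && fraction < 1))
    stop("invalid parameter: fraction must be in [0, 1)")
  n <- if (is.data.frame(x)) nrow(x) else length(x)
  drop <- ceiling(fraction * n)
  if (drop >= n) stop("stable window is empty")
  idx <- (drop + 1L):n
  if (is.data.frame(x)) x[idx, , drop = FALSE] else x[idx]
}

#' Time-lagged cross-correlation
#'
#' Pearson correlation of `x_t` with `y_{t+k}` for every integer lag `k` in
#' `[-max_lag, max_lag]`, each computed over the overlapping window (which
#' standardizes both windows by their own mean and sd, so amplitude drift
#' does not masquerade as synchrony).  Used to quantify synchrony between
#' environmental forcing and population dynamics: a large `|r|` at some lag
#' means the population tracks the environment (possibly delayed).
#'
#' A lag whose overlap window has zero variance in either series yields
#' `r = NA` with `defined = FALSE` — undefined, never silently 0.
#'
#' @param x,y Equal-length numeric series with `length > 2 * max_lag`.
#' @param max_lag Maximum lag (steps); for forced runs one forcing period
#'   is a natural choice.
#' @return A data.frame of class `lag_correlation` with columns `lag`, `r`
#'   and `defined`.  Satisfies `r_{x,y}(k) = r_{y,x}(-k)`.
#' @export
tlcc <- function(x, y, max_lag) {
  n <- length(x)
  if (length(y) != n) stop("shape mismatch: x and y differ in length")
  if (!(n > 2 * max_lag))
    stop("series too short: length must exceed 2 * max_lag")
  lags <- (-max_lag):max_lag
  r <- vapply(lags, function(k) {
    if (k >= 0) {
      xs <- x[seq_len(n - k)]
      ys <- y[seq_len(n - k) + k]
    } else {
      xs <- x[seq_len(n + k) - k]
      ys <- y[seq_len(n + k)]
    }
    if (stats::sd(xs) == 0 || stats::sd(ys) == 0) NA_real_
    else stats::cor(xs, ys)
  }, numeric(1))
  out <- data.frame(lag = lags, r = r, defined = !is.na(r))
  class(out) <- c("lag_correlation", "data.frame")
  out
}

#' Amplitude spectrum of mean-standardized population fluctuations
#'
#' The population-size series is standardized by its mean,
#' \eqn{z_t = (N_t - \bar N) / \bar N}, and transformed with an FFT.  The
#' one-sided amplitude spectrum reports, at each frequency `k/n` (cycles
#' per step, `k = 0 .. floor(n/2)`), the amplitude of the corresponding
#' sinusoidal component of `z`; a pure relative oscillation of amplitude
#' `a` and period `P` produces a single peak of height `a` at frequency
#' `1/P`.  The amplitude at frequency 0 is 0 by construction (`z` is
#' mean-centered).  Amplitudes satisfy Parseval's identity:
#' `mean(z^2)` equals `sum(amplitude^2) / 2`, with the Nyquist term (even
#' `n`) contributing `amplitude^2` unhalved.
#'
#' @param N Population-size series (length at least 8) with non-zero mean —
#'   typically the stable window of a run; an extinct window (mean 0) is an
#'   error, so extinct replicates must be excluded from spectrum averaging.
#' @return A data.frame of class `pop_spectrum` with columns `freq` (cycles
#'   per step) and `amplitude` (non-negative).
#' @export
population_spectrum <- function(N) {
  n <- length(N)
  if (n < 8) stop("series too short for a spectrum (need length >= 8)")
  mu <- mean(N)
  if (mu == 0)
    stop("undefined standardization: series mean is 0 (extinct window)")
  z <- (N - mu) / mu
  Z <- stats::fft(z)
  kmax <- floor(n / 2)
  k <- 0:kmax
  amp <- Mod(Z[k + 1]) / n
  scale2 <- k != 0 & !(n %% 2 == 0 & k == kmax)
  amp[scale2] <- 2 * amp[scale2]
  out <- data.frame(freq = k / n, amplitude = amp)
  class(out) <- c("pop_spectrum", "data.frame")
  out
}

#' Synchrony and variability summaries across forced replicates
#'
#' Convenience layer for fluctuating-environment experiments:
#' `fluctuation_synchrony()` computes the environment-vs-population-size
#' TLCC per replicate on the stable window and averages the correlation
#' curves; `fluctuation_spectrum()` computes the mean-standardized
#' amplitude spectrum per replicate on the stable window and averages
#' pointwise on the shared frequency grid.  Replicates whose stable window
#' is degenerate (extinct, or zero variance for the TLCC) are excluded and
#' counted in the `n_excluded` attribute.
#'
#' @param series_list List of [run_simulation()] outputs (need columns `R0`
#'   and `N`).
#' @param max_lag Maximum lag for the TLCC (steps).
#' @param burn_in Burn-in fraction passed to [stable_window()].
#' @return `fluctuation_synchrony()`: a `lag_correlation` data.frame of the
#'   averaged curves; `fluctuation_spectrum()`: a `pop_spectrum` data.frame
#'   of the averaged amplitudes.  Both carry attributes `n_used` and
#'   `n_excluded`.
#' @export
fluctuation_synchrony <- function(series_list, max_lag, burn_in = 0.5) {
  curves <- list()
  excluded <- 0L
  for (s in series_list) {
    w <- stable_window(s, burn_in)
    if (stats::sd(w$N) == 0 || stats::sd(w$R0) == 0) {
      excluded <- excluded + 1L
      next
    }
    curves[[length(curves) + 1L]] <- tlcc(w$R0, w$N, max_lag)$r
  }
  if (!length(curves))
    stop("no usable replicates: every stable window was degenerate")
  r <- rowMeans(matrix(unlist(curves), ncol = length(curves)))
  out <- data.frame(lag = (-max_lag):max_lag, r = r, defined = !is.na(r))
  attr(out, "n_used") <- length(curves)
  attr(out, "n_excluded") <- excluded
  class(out) <- c("lag_correlation", "data.frame")
  out
}

#' @rdname fluctuation_synchrony
#' @export
fluctuation_spectrum <- function(series_list, burn_in = 0.5) {
  specs <- list()
  excluded <- 0L
  for (s in series_list) {
    w <- stable_window(s, burn_in)
    if (mean(w$N) == 0) {
      excluded <- excluded + 1L
      next
    }
    specs[[length(specs) + 1L]] <- population_spectrum(w$N)
  }
  if (!length(specs))
    stop("no usable replicates: every stable window was extinct")
  amp <- rowMeans(matrix(vapply(specs, function(sp) sp$amplitude,
                                numeric(nrow(specs[[1]]))),
                         ncol = length(specs)))
  out <- data.frame(freq = specs[[1]]$freq, amplitude = amp)
  attr(out, "n_used") <- length(specs)
  attr(out, "n_excluded") <- excluded
  class(out) <- c("pop_spectrum", "data.frame")
  out
}
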