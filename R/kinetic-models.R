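#' Single-exponential cleavage progress model
#'
#' Fraction of DNA cleaved at time `t` under single-turnover conditions
#' (enzyme in excess over substrate), where cleavage approaches a final
#' plateau `Ff` with a single first-order rate constant `kc`:
#' \deqn{F(t) = F_f (1 - e^{-k_c t}).}
#' `Ff` absorbs any uncleavable fraction of substrate; `F(t)` is monotone
#' nondecreasing in `t` and bounded above by `Ff`.
#'
#' @param Ff final cleaved fraction, in `(0, 1]`.
#' @param kc cleavage rate constant (> 0, reciprocal time).
#' @param t nonnegative time(s), in the unit matching `kc`.
#' @return Cleaved fraction(s) at `t`.
#' @examples
#' exp_progress(Ff = 1, kc = 0.008, t = log(2) / 0.008)  # half the plateau
#' @seealso [fit_exponential()] to estimate `Ff` and `kc` from data.
#' @export
exp_progress <- function(Ff, kc, t) {
  if (!is.numeric(Ff) || length(Ff) != 1L || !is.finite(Ff) || Ff <= 0 || Ff > 1) {
    stop_domain("'Ff' must be a single number in (0, 1]")
  }
  if (!is.numeric(kc) || length(kc) != 1L || !is.finite(kc) || kc <= 0) {
    stop_domain("'kc' must be a single positive rate constant")
  }
  if (!is.numeric(t) || any(!is.finite(t) & !is.infinite(t)) || any(t < 0)) {
    stop_domain("'t' must be nonnegative")
  }
  Ff * (1 - exp(-kc * t))
}

# Relative |k2 - k1| below which the confluent (k1 == k2) limit form is used.
# Small enough that the two branches agree to well below any data noise,
# large enough to avoid catastrophic cancellation in exp(-k1 t) - exp(-k2 t).
.degeneracy_rtol <- 1e-8

#' Closed-form consecutive-cleavage kinetics of a supercoiled cruciform
#'
#' Analytic solution of the two-step irreversible first-order scheme
#' S -> N -> L (supercoiled -> nicked -> linear) with rate constants `k1`
#' and `k2`, starting from pure supercoiled substrate:
#' \deqn{f_S = e^{-k_1 t}, \quad
#'       f_N = \frac{k_1}{k_2 - k_1}\left(e^{-k_1 t} - e^{-k_2 t}\right), \quad
#'       f_L = 1 - f_S - f_N.}
#' When `k1` and `k2` coincide to within a relative tolerance of `1e-8` the
#' expression for `fN` is replaced by its analytic confluent limit
#' `k1 * t * exp(-k1 * t)`, which keeps the evaluation continuous across the
#' degeneracy instead of dividing by a vanishing `k2 - k1`.
#'
#' @param rates a [cruciform_rates()] object (or a numeric pair `c(k1, k2)`).
#' @param t nonnegative time(s) since reaction start (Mg2+ addition), in the
#'   time unit matching the rates.
#' @return A [cruciform_trajectory()] with one row per element of `t`; rows
#'   sum to 1 by construction.
#' @examples
#' r <- cruciform_rates(0.019, 0.20)
#' cruciform_fractions(r, c(0, 13, 120))
#' @export
cruciform_fractions <- function(rates, t) {
  rates <- as_cruciform_rates(rates)
  if (!is.numeric(t) || length(t) < 1L || !all(is.finite(t))) {
    stop_domain("'t' must be finite and numeric")
  }
  if (any(t < 0)) stop_domain("'t' must be nonnegative")
  k1 <- rates$k1; k2 <- rates$k2
  fS <- exp(-k1 * t)
  if (abs(k2 - k1) < .degeneracy_rtol * max(k1, k2)) {
    fN <- k1 * t * exp(-k1 * t)
  } else {
    fN <- k1 / (k2 - k1) * (exp(-k1 * t) - exp(-k2 * t))
  }
  fL <- 1 - fS - fN
  out <- structure(
    data.frame(time = as.numeric(t), fS = fS, fN = fN, fL = fL),
    class = c("cruciform_trajectory", "data.frame"),
    time_unit = time_unit_for(rates$unit)
  )
  out
}

#' Time and height of the nicked-intermediate maximum
#'
#' The nicked-circle fraction in the consecutive-cleavage scheme rises and
#' falls through a single interior maximum at
#' \eqn{t^* = \ln(k_2/k_1) / (k_2 - k_1)} (or \eqn{t^* = 1/k_1} in the
#' confluent `k1 == k2` limit). A low, early nicked peak is the visual
#' signature of fast second-strand cleavage.
#'
#' @inheritParams cruciform_fractions
#' @return A list with elements `time` (the peak time `t*`) and `height`
#'   (the nicked fraction at `t*`, always < 1).
#' @examples
#' nicked_peak(cruciform_rates(0.019, 0.20))
#' @export
nicked_peak <- function(rates) {
  rates <- as_cruciform_rates(rates)
  k1 <- rates$k1; k2 <- rates$k2
  t_star <- if (abs(k2 - k1) < .degeneracy_rtol * max(k1, k2)) {
    1 / k1
  } else {
    log(k2 / k1) / (k2 - k1)
  }
  list(time = t_star, height = cruciform_fractions(rates, t_star)$fN)
}

#' Numerical integration of the consecutive-cleavage rate equations
#'
#' Integrates the differential system
#' \deqn{dS/dt = -k_1 S, \quad dN/dt = k_1 S - k_2 N, \quad dL/dt = k_2 N}
#' from the initial state (1, 0, 0) with a stiffness-switching solver
#' (`deSolve::ode`, method `"lsoda"`). This is deliberately an independent
#' route to the same trajectory as [cruciform_fractions()]: the two agree to
#' better than `1e-6` absolutely, and the comparison is used throughout the
#' test suite as an oracle for the closed-form solution (including its
#' confluent-limit branch).
#'
#' @inheritParams cruciform_fractions
#' @param times sorted, nonnegative output time grid.
#' @return A [cruciform_trajectory()] on `times`.
#' @export
cruciform_ode <- function(rates, times) {
  rates <- as_cruciform_rates(rates)
  check_schedule(times, "times")
  grid <- times
  prepend0 <- grid[1] > 0
  if (prepend0) grid <- c(0, grid)
  deriv <- function(t, y, p) {
    list(c(-p$k1 * y[1], p$k1 * y[1] - p$k2 * y[2], p$k2 * y[2]))
  }
  sol <- deSolve::ode(
    y = c(S = 1, N = 0, L = 0), times = grid, func = deriv,
    parms = list(k1 = rates$k1, k2 = rates$k2),
    method = "lsoda", rtol = 1e-10, atol = 1e-12
  )
  istate <- attr(sol, "istate")
  if (!is.null(istate) && istate[1] < 0) {
    resolvr_stop(sprintf("ODE integration failed (istate = %d)", istate[1]),
                 "resolvr_integration_error")
  }
  sol <- as.data.frame(sol)
  if (anyNA(sol)) {
    resolvr_stop("ODE integration produced NA values", "resolvr_integration_error")
  }
  if (prepend0) sol <- sol[-1, , drop = FALSE]
  structure(
    data.frame(time = as.numeric(times), fS = sol$S, fN = sol$N, fL = sol$L),
    class = c("cruciform_trajectory", "data.frame"),
    time_unit = time_unit_for(rates$unit)
  )
}
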