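# Seeded synthetic gel-densitometry data with known ground truth.
#
# Each generator evaluates its model on a sampling schedule mirroring the
# corresponding experimental design, adds additive Gaussian densitometry
# noise on the fraction scale (default sd 0.03, typical phosphorimager
# scatter), and embeds the generating parameters and seed as attributes so
# closed-loop parameter-recovery tests can compare fit to truth. With
# noise_sd = 0 (and lane_sd = 0) the output equals the model evaluation
# exactly. Noisy fractions are NOT clipped to [0, 1] unless requested:
# clipping before fitting biases least squares.

#' Simulate a single-turnover cleavage progress curve
#'
#' Generates a [progress_curve()] from the single-exponential model
#' [exp_progress()] plus additive Gaussian noise. The default schedule (12
#' points over 600 s) matches the sampling density of a typical
#' single-turnover strand-cleavage assay.
#'
#' @param Ff,kc generating plateau and rate constant.
#' @param times sampling schedule (strictly increasing, nonnegative).
#' @param time_unit `"s"` (default) or `"min"`; `kc` is per this unit.
#' @param noise_sd additive Gaussian sd on the fraction scale (default 0.03).
#' @param seed integer seed; the caller's RNG state is preserved. `NULL`
#'   uses (and advances) the current RNG state.
#' @param clip clip noisy fractions to `[0, 1]` on output (default `FALSE`;
#'   intended for plotting only).
#' @return A [progress_curve()] with attributes `truth` (named list of
#'   generating parameters), `seed` and `noise_sd`.
#' @examples
#' simulate_cleavage_course(Ff = 1, kc = 0.008, noise_sd = 0)
#' @export
simulate_cleavage_course <- function(Ff = 1, kc = 0.008,
                                     times = seq(0, 600, length.out = 12),
                                     time_unit = "s", noise_sd = 0.03,
                                     seed = NULL, clip = FALSE) {
  check_schedule(times)
  check_noise_sd(noise_sd)
  F0 <- exp_progress(Ff, kc, times)
  F <- with_seed(seed, F0 + stats::rnorm(length(times), sd = noise_sd))
  if (clip) F <- pmin(pmax(F, 0), 1)
  set_truth(
    progress_curve(times, F, time_unit = time_unit),
    truth = list(Ff = Ff, kc = kc), seed = seed, noise_sd = noise_sd
  )
}

#' Simulate a cruciform cleavage time course
#'
#' Generates a [cruciform_trajectory()] from the consecutive-cleavage
#' solutions [cruciform_fractions()], emulating gel densitometry: the true
#' per-lane fractions are multiplied by an optional log-normal lane-loading
#' factor, perturbed by additive Gaussian band noise, floored at zero
#' (intensities are nonnegative), and per-lane renormalized exactly as the
#' analysis pipeline renormalizes real band intensities. Renormalization
#' cancels the lane factor in expectation, which is why lane-loading
#' variation is tolerable in this assay at all. Defaults follow a typical
#' time-course design — 10 lanes over 2 h, sampled densely at early times
#' so the transient nicked intermediate (peaking near 13 min at the default
#' rates) is actually observed — with rates in min^-1.
#'
#' @param k1,k2 generating rate constants.
#' @param times sampling schedule.
#' @param time_unit `"min"` (default) or `"s"`.
#' @param noise_sd additive Gaussian band-noise sd (default 0.03).
#' @param lane_sd sdlog of the multiplicative log-normal lane-loading factor
#'   (default 0 = off; 0.05 is typical when enabled).
#' @inheritParams simulate_cleavage_course
#' @return A [cruciform_trajectory()] with `truth`, `seed`, `noise_sd`
#'   attributes.
#' @export
simulate_cruciform_course <- function(k1 = 0.019, k2 = 0.20,
                                      times = c(0, 5, 10, 15, 20, 30,
                                                45, 60, 90, 120),
                                      time_unit = "min", noise_sd = 0.03,
                                      lane_sd = 0, seed = NULL, clip = FALSE) {
  check_schedule(times)
  check_noise_sd(noise_sd)
  check_noise_sd(lane_sd)
  rates <- cruciform_rates(k1, k2, unit = rate_unit_for(time_unit))
  tr <- cruciform_fractions(rates, times)
  M <- cbind(tr$fS, tr$fN, tr$fL)
  n <- length(times)
  M <- with_seed(seed, {
    lane <- if (lane_sd > 0) stats::rlnorm(n, meanlog = 0, sdlog = lane_sd) else rep(1, n)
    raw <- M * lane + matrix(stats::rnorm(3 * n, sd = noise_sd), ncol = 3)
    pmax(raw, 0)
  })
  out <- cruciform_trajectory(times, M[, 1], M[, 2], M[, 3],
                              time_unit = time_unit, renormalize = TRUE)
  if (clip) {
    for (cl in c("fS", "fN", "fL")) out[[cl]] <- pmin(pmax(out[[cl]], 0), 1)
  }
  set_truth(out, truth = list(k1 = k1, k2 = k2), seed = seed,
            noise_sd = noise_sd)
}

#' Simulate an equilibrium junction-binding titration
#'
#' Generates a [binding_titration()] from either the ligand-depletion
#' isotherm ([depletion_isotherm()], `model = "two_state"`) or the Hill
#' isotherm ([hill_isotherm()], `model = "hill"`), plus additive Gaussian
#' noise on the bound fraction. The default design mirrors a gel-shift
#' titration of an 82 pM junction with protein spanning 43 pM to 44 nM on
#' an 11-point geometric grid.
#'
#' @param Kd generating dissociation constant (two-state model), nM.
#' @param K_app,n generating Hill parameters (hill model).
#' @param Dt total junction concentration, nM (default 0.082).
#' @param Pt protein-concentration grid, nM (default 11-point geometric
#'   series from 0.043 to 44).
#' @param model `"two_state"` (default) or `"hill"`.
#' @param stoichiometry recorded convention for what `Pt` counts.
#' @inheritParams simulate_cleavage_course
#' @return A [binding_titration()] with `truth`, `seed`, `noise_sd`
#'   attributes.
#' @export
simulate_titration <- function(Kd = 10, K_app = NULL, n = NULL, Dt = 0.082,
                               Pt = NULL, model = c("two_state", "hill"),
                               stoichiometry = c("dimer", "monomer"),
                               noise_sd = 0.03, seed = NULL, clip = FALSE) {
  model <- match.arg(model)
  stoichiometry <- match.arg(stoichiometry)
  check_noise_sd(noise_sd)
  if (is.null(Pt)) Pt <- exp(seq(log(0.043), log(44), length.out = 11))
  check_schedule(Pt, "Pt")
  if (model == "two_state") {
    fb0 <- depletion_isotherm(Kd, Pt, Dt)
    truth <- list(model = "two_state", Kd = Kd, Dt = Dt)
  } else {
    if (is.null(K_app) || is.null(n)) {
      stop_domain("'K_app' and 'n' are required for the hill model")
    }
    fb0 <- hill_isotherm(K_app, n, Pt)
    truth <- list(model = "hill", K_app = K_app, n = n, Dt = Dt)
  }
  fb <- with_seed(seed, fb0 + stats::rnorm(length(Pt), sd = noise_sd))
  if (clip) fb <- pmin(pmax(fb, 0), 1)
  set_truth(
    binding_titration(Pt, fb, Dt, stoichiometry = stoichiometry),
    truth = truth, seed = seed, noise_sd = noise_sd
  )
}

check_noise_sd <- function(sd) {
  nm <- deparse(substitute(sd))
  if (!is.numeric(sd) || length(sd) != 1L || !is.finite(sd) || sd < 0) {
    stop_domain(sprintf("'%s' must be a single nonnegative number", nm))
  }
  invisible(sd)
}
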