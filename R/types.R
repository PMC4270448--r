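#' Rate-constant pair for consecutive cruciform cleavage
#'
#' Container for the two first-order rate constants of the consecutive
#' cleavage scheme supercoiled -> nicked -> linear: `k1` for the first
#' (junction-nicking) cleavage and `k2` for the second cleavage of the
#' already-nicked species. The derived `acceleration` is the dimensionless
#' ratio `k2 / k1`, the factor by which second-strand cleavage outpaces the
#' first.
#'
#' @param k1,k2 positive rate constants, in the unit given by `unit`.
#' @param unit reciprocal-time unit tag, `"per_min"` (default) or `"per_s"`.
#' @return An object of class `cruciform_rates`: a list with elements `k1`,
#'   `k2`, `acceleration` and `unit`.
#' @examples
#' cruciform_rates(0.019, 0.20)
#' @export
cruciform_rates <- function(k1, k2, unit = "per_min") {
  check_rate_unit(unit)
  if (!is.numeric(k1) || length(k1) != 1L || !is.finite(k1) || k1 <= 0 ||
      !is.numeric(k2) || length(k2) != 1L || !is.finite(k2) || k2 <= 0) {
    stop_domain("'k1' and 'k2' must be single positive finite numbers")
  }
  structure(
    list(k1 = k1, k2 = k2, acceleration = k2 / k1, unit = unit),
    class = "cruciform_rates"
  )
}

#' @export
print.cruciform_rates <- function(x, ...) {
  u <- sub("^per_", "", x$unit)
  cat(sprintf("Cruciform cleavage rates: k1 = %.4g %s^-1, k2 = %.4g %s^-1\n",
              x$k1, u, x$k2, u))
  cat(sprintf("Second-strand acceleration k2/k1 = %.3g-fold\n", x$acceleration))
  invisible(x)
}

as_cruciform_rates <- function(x, unit = "per_min") {
  if (inherits(x, "cruciform_rates")) return(x)
  if (is.numeric(x) && length(x) == 2L) return(cruciform_rates(x[[1]], x[[2]], unit))
  stop_domain("expected a 'cruciform_rates' object or a numeric pair (k1, k2)")
}

#' Single-strand cleavage progress curve
#'
#' A time course of the fraction of a radiolabeled strand cleaved, as
#' quantified from a denaturing gel. Times must be strictly increasing and
#' nonnegative; the cleaved fraction is not constrained to `[0, 1]` because
#' densitometry noise legitimately pushes observations slightly outside and
#' clipping before fitting would bias least squares.
#'
#' @param times strictly increasing, nonnegative time stamps.
#' @param F fraction of DNA cleaved at each time.
#' @param time_unit `"s"` (default) or `"min"`.
#' @return A data frame of class `progress_curve` with columns `time`, `F`.
#' @export
progress_curve <- function(times, F, time_unit = "s") {
  check_time_unit(time_unit)
  check_schedule(times, "times")
  if (!is.numeric(F) || length(F) != length(times) || !all(is.finite(F))) {
    stop_domain("'F' must be a finite numeric vector matching 'times'")
  }
  structure(
    data.frame(time = as.numeric(times), F = as.numeric(F)),
    class = c("progress_curve", "data.frame"),
    time_unit = time_unit
  )
}

#' Cruciform cleavage trajectory
#'
#' Time course of the fractional intensities of the three plasmid topological
#' species resolved on an agarose gel: supercoiled substrate (`fS`), nicked
#' circle (`fN`, the unilateral-cleavage intermediate) and linear product
#' (`fL`, bilateral cleavage). Each row is one gel lane; fractions are
#' per-lane renormalized so `fS + fN + fL = 1`.
#'
#' @param times strictly increasing, nonnegative time stamps.
#' @param fS,fN,fL fractional intensities of the three species.
#' @param time_unit `"min"` (default) or `"s"`.
#' @param renormalize divide each row by its sum (default `TRUE`). With
#'   `FALSE` the rows must already sum to 1 within `1e-6`.
#' @return A data frame of class `cruciform_trajectory` with columns `time`,
#'   `fS`, `fN`, `fL`.
#' @export
cruciform_trajectory <- function(times, fS, fN, fL, time_unit = "min",
                                 renormalize = TRUE) {
  check_time_unit(time_unit)
  check_schedule(times, "times")
  n <- length(times)
  for (nm in c("fS", "fN", "fL")) {
    v <- get(nm)
    if (!is.numeric(v) || length(v) != n || !all(is.finite(v))) {
      stop_domain(sprintf("'%s' must be a finite numeric vector matching 'times'", nm))
    }
    if (any(v < 0)) {
      stop_domain(sprintf("'%s' has negative intensities (row %d)", nm, which(v < 0)[1]))
    }
  }
  tot <- fS + fN + fL
  if (any(tot <= 0)) {
    stop_domain(sprintf("all species zero in row %d", which(tot <= 0)[1]))
  }
  if (renormalize) {
    fS <- fS / tot; fN <- fN / tot; fL <- fL / tot
  } else if (any(abs(tot - 1) > 1e-6)) {
    stop_domain("species fractions do not sum to 1; use renormalize = TRUE")
  }
  structure(
    data.frame(time = as.numeric(times), fS = fS, fN = fN, fL = fL),
    class = c("cruciform_trajectory", "data.frame"),
    time_unit = time_unit
  )
}

#' Equilibrium junction-binding titration
#'
#' A gel-shift (EMSA) titration: the fraction of DNA junction bound (`fb`) at
#' a series of total protein concentrations (`Pt`), with the total junction
#' concentration `Dt` held fixed. Because `Dt` is comparable to the
#' dissociation constant in these experiments, bound protein depletes the
#' free pool and the exact quadratic isotherm is required, hence `Dt` is part
#' of the data object. The `stoichiometry` flag records whether `Pt` counts
#' monomers or dimers; it is reported unchanged, never silently converted.
#'
#' @param Pt strictly increasing, nonnegative total protein concentrations (nM).
#' @param fb observed fraction of junction bound at each `Pt`.
#' @param Dt total DNA junction concentration (nM), a single positive number.
#' @param stoichiometry `"dimer"` (default) or `"monomer"`.
#' @return A data frame of class `binding_titration` with columns `Pt`, `fb`
#'   and attributes `Dt`, `stoichiometry`.
#' @export
binding_titration <- function(Pt, fb, Dt, stoichiometry = c("dimer", "monomer")) {
  stoichiometry <- match.arg(stoichiometry)
  if (!is.numeric(Pt) || length(Pt) < 1L || !all(is.finite(Pt)) || any(Pt < 0)) {
    stop_domain("'Pt' must be nonnegative finite concentrations")
  }
  if (any(diff(Pt) <= 0)) {
    stop_domain(sprintf("'Pt' must be strictly increasing (row %d)",
                        which(diff(Pt) <= 0)[1] + 1L))
  }
  if (!is.numeric(Dt) || length(Dt) != 1L || !is.finite(Dt) || Dt <= 0) {
    stop_domain("'Dt' must be a single positive concentration")
  }
  if (!is.numeric(fb) || length(fb) != length(Pt) || !all(is.finite(fb))) {
    stop_domain("'fb' must be a finite numeric vector matching 'Pt'")
  }
  structure(
    data.frame(Pt = as.numeric(Pt), fb = as.numeric(fb)),
    class = c("binding_titration", "data.frame"),
    Dt = Dt, stoichiometry = stoichiometry
  )
}

check_schedule <- function(times, what = "times") {
  if (!is.numeric(times) || length(times) < 1L || !all(is.finite(times))) {
    stop_domain(sprintf("'%s' must be a nonempty finite numeric vector", what))
  }
  if (any(times < 0)) {
    stop_domain(sprintf("'%s' must be nonnegative (element %d)",
                        what, which(times < 0)[1]))
  }
  if (length(times) > 1L && any(diff(times) <= 0)) {
    stop_domain(sprintf("'%s' must be strictly increasing (element %d)",
                        what, which(diff(times) <= 0)[1] + 1L))
  }
  invisible(times)
}

# Ground-truth metadata carried by synthetic objects (and round-tripped
# through the CSV dialect).
set_truth <- function(x, truth, seed = NULL, noise_sd = NULL) {
  attr(x, "truth") <- truth
  attr(x, "seed") <- seed
  attr(x, "noise_sd") <- noise_sd
  x
}

#' @export
print.progress_curve <- function(x, ...) {
  cat(sprintf("Cleavage progress curve: %d time points over %g %s\n",
              nrow(x), max(x$time), attr(x, "time_unit")))
  print.data.frame(x, ...)
  invisible(x)
}

#' @export
print.cruciform_trajectory <- function(x, ...) {
  cat(sprintf("Cruciform cleavage trajectory: %d lanes over %g %s\n",
              nrow(x), max(x$time), attr(x, "time_unit")))
  print.data.frame(x, ...)
  invisible(x)
}

#' @export
print.binding_titration <- function(x, ...) {
  cat(sprintf(
    "Junction-binding titration: %d points, Pt %.3g-%.3g nM, Dt = %g nM (%s)\n",
    nrow(x), min(x$Pt), max(x$Pt), attr(x, "Dt"), attr(x, "stoichiometry")))
  print.data.frame(x, ...)
  invisible(x)
}
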