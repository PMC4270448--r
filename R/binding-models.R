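#' Exact two-state binding isotherm with ligand depletion
#'
#' Fraction of DNA junction bound at equilibrium for the two-state reaction
#' P + D <-> PD when the DNA concentration `Dt` is not negligible relative to
#' the dissociation constant, so that bound protein depletes the free pool.
#' The bound fraction is the physical root of the mass-action quadratic:
#' \deqn{f_b = \frac{(K_d + P_t + D_t) -
#'   \sqrt{(K_d + P_t + D_t)^2 - 4 P_t D_t}}{2 D_t}.}
#' The minus branch is the physical one (it tends to 0 as `Pt -> 0`; the plus
#' branch exceeds 1). It is evaluated in the algebraically equivalent
#' conjugate form `2 Pt / (b + sqrt(b^2 - 4 Pt Dt))`, which avoids the
#' catastrophic cancellation the textbook form suffers when
#' `4 Pt Dt << (Kd + Pt + Dt)^2` — routine in titrations spanning pM to nM.
#' In the `Dt -> 0` limit the expression reduces to the familiar hyperbola
#' `Pt / (Pt + Kd)`.
#'
#' @param Kd dissociation constant (>= 0), same concentration unit as `Pt`, `Dt`.
#' @param Pt total protein concentration(s) (>= 0). Whether this counts
#'   monomers or dimers is a property of the titration, recorded on the data
#'   object and never converted implicitly.
#' @param Dt total DNA junction concentration (> 0).
#' @return Bound fraction(s) in `[0, min(1, Pt/Dt)]`, nondecreasing in `Pt`.
#' @examples
#' depletion_isotherm(Kd = 10, Pt = 10, Dt = 0.082)
#' @export
depletion_isotherm <- function(Kd, Pt, Dt) {
  if (!is.numeric(Kd) || length(Kd) != 1L || !is.finite(Kd) || Kd < 0) {
    stop_domain("'Kd' must be a single nonnegative concentration")
  }
  if (!is.numeric(Dt) || length(Dt) != 1L || !is.finite(Dt) || Dt <= 0) {
    stop_domain("'Dt' must be a single positive concentration")
  }
  if (!is.numeric(Pt) || any(!is.finite(Pt)) || any(Pt < 0)) {
    stop_domain("'Pt' must be nonnegative")
  }
  b <- Kd + Pt + Dt
  disc <- b^2 - 4 * Pt * Dt
  # (Kd + Pt + Dt)^2 >= 4 Pt Dt by AM-GM; a negative value can only be a bug.
  stopifnot(all(disc >= -1e-12 * b^2))
  fb <- 2 * Pt / (b + sqrt(pmax(disc, 0)))
  pmin(fb, 1)
}

#' Hill isotherm for cooperative binding
#'
#' Phenomenological cooperative binding curve
#' \deqn{f_b = \frac{P_t^{\,n}}{P_t^{\,n} + K_{app}},}
#' with Hill coefficient `n` (`n > 1` indicates cooperativity, here the
#' assembly of a protein dimer on the junction). Note the apparent constant
#' `K_app` sits in the denominator un-exponentiated, so its unit is
#' concentration^n; the concentration of half-saturation is
#' `K_app^(1/n)`, available via [hill_half_saturation()]. Ligand depletion is
#' not modelled by this form.
#'
#' @param K_app apparent constant (> 0), units concentration^n.
#' @param n Hill coefficient (> 0).
#' @param Pt total protein concentration(s) (>= 0).
#' @return Bound fraction(s) in `[0, 1)`, nondecreasing in `Pt`.
#' @examples
#' hill_isotherm(K_app = 100, n = 2, Pt = 10)  # half-saturated at 100^(1/2)
#' @export
hill_isotherm <- function(K_app, n, Pt) {
  if (!is.numeric(K_app) || length(K_app) != 1L || !is.finite(K_app) || K_app <= 0) {
    stop_domain("'K_app' must be a single positive constant")
  }
  if (!is.numeric(n) || length(n) != 1L || !is.finite(n) || n <= 0) {
    stop_domain("'n' must be a single positive Hill coefficient")
  }
  if (!is.numeric(Pt) || any(!is.finite(Pt)) || any(Pt < 0)) {
    stop_domain("'Pt' must be nonnegative")
  }
  Ptn <- Pt^n
  Ptn / (Ptn + K_app)
}

#' @rdname hill_isotherm
#' @return `hill_half_saturation()`: the protein concentration at which the
#'   Hill isotherm reaches 0.5, i.e. `K_app^(1/n)`.
#' @export
hill_half_saturation <- function(K_app, n) {
  if (!is.numeric(K_app) || length(K_app) != 1L || K_app <= 0 ||
      !is.numeric(n) || length(n) != 1L || n <= 0) {
    stop_domain("'K_app' and 'n' must be single positive numbers")
  }
  K_app^(1 / n)
}
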