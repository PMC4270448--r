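#' Predicted complex distribution in a two-variant dimer mixing experiment
#'
#' Formalizes the classic gel-shift dimer test: mix a native protein with a
#' size-shifted fusion variant (e.g. a GFP fusion), let dimeric complexes
#' assemble on the DNA junction, and count retarded bands. If the bound
#' complex is a dimer whose two subunits are drawn independently from the
#' pool, three bands appear — native/native, native/fusion and
#' fusion/fusion — with binomial weights
#' \deqn{(f_{AA}, f_{AB}, f_{BB}) = (p^2,\; 2p(1-p),\; (1-p)^2),}
#' where `p = concA / (concA + rho * concB)` is the effective incorporation
#' fraction of variant A. The single parameter `rho` captures any
#' non-equivalence of the fusion variant at the incorporation step (a fusion
#' that weakens affinity has `rho < 1`, shifting mass toward `fAA`); subunits
#' are otherwise assumed to assort independently, with no preferential homo-
#' or heterodimerization. A monomeric bound species would instead give two
#' bands at all mixing ratios, so the presence of the intermediate band — and
#' its maximal intensity at `p = 0.5` — is the dimer diagnostic.
#'
#' @param concA,concB concentrations of variant A (native) and variant B
#'   (fusion), same units, both >= 0 and not both zero.
#' @param rho relative incorporation weight of variant B (> 0; 1 means the
#'   variants are equivalent).
#' @return An object of class `complex_distribution`: a named numeric vector
#'   `c(fAA, fAB, fBB)` summing to 1, with the effective fraction `p` as an
#'   attribute.
#' @examples
#' predict_complex_fractions(40, 40)        # 0.25 / 0.50 / 0.25
#' predict_complex_fractions(40, 120)       # 0.0625 / 0.375 / 0.5625
#' @export
predict_complex_fractions <- function(concA, concB, rho = 1) {
  for (nm in c("concA", "concB", "rho")) {
    v <- get(nm)
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v)) {
      stop_domain(sprintf("'%s' must be a single finite number", nm))
    }
  }
  if (concA < 0 || concB < 0) stop_domain("concentrations must be nonnegative")
  if (concA == 0 && concB == 0) {
    stop_domain("at least one of 'concA', 'concB' must be positive")
  }
  if (rho <= 0) stop_domain("'rho' must be positive")
  p <- concA / (concA + rho * concB)
  structure(
    c(fAA = p^2, fAB = 2 * p * (1 - p), fBB = (1 - p)^2),
    class = "complex_distribution", p = p
  )
}

#' @export
print.complex_distribution <- function(x, ...) {
  cat("Predicted dimer-complex distribution (A = native, B = fusion):\n")
  cat(sprintf("  A:A %.4f   A:B %.4f   B:B %.4f   (p_A = %.4f)\n",
              x[["fAA"]], x[["fAB"]], x[["fBB"]], attr(x, "p")))
  invisible(x)
}
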