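# resolvr

Quantitative analysis of Holliday junction resolvase gel assays from
band-intensity tables.

Junction-resolving enzymes (resolvases) cut two strands of a four-way DNA
junction to yield duplex products. Their biochemistry is read out almost
entirely from gels: denaturing gels give single-strand cleavage progress
curves, agarose gels of a supercoil-stabilized cruciform plasmid report
first (nicking) and second (linearizing) cleavage events, and native
gel-shift (EMSA) titrations report junction binding and its stoichiometry.
`resolvr` implements the models behind all of these readouts, their
nonlinear least-squares fitters, and a seeded synthetic densitometry
generator, so the whole analysis pipeline can be validated in a closed loop
against known ground truth. It is aimed at enzymologists quantifying
resolvase (or any structure-selective nuclease) assays, and at anyone who
needs a tested reference implementation of these standard fits.

## Models

**Consecutive cruciform cleavage.** A cruciform extruded in a negatively
supercoiled plasmid is cleaved once (nicked circle, N) and then again
(linear, L) while the enzyme remains bound:

    S  --k1-->  N  --k2-->  L

with closed-form fractional concentrations

    fS = exp(-k1 t)
    fN = k1/(k2-k1) * (exp(-k1 t) - exp(-k2 t))      (k1*t*exp(-k1 t) if k1 = k2)
    fL = 1 - fS - fN

Fitting all three traces jointly yields `(k1, k2)`; the ratio `k2/k1` is the
second-strand acceleration that makes resolution bilateral within the
lifetime of the complex.

**Single-turnover strand cleavage.** `F(t) = Ff (1 - exp(-kc t))`.

**Equilibrium junction binding.** The exact two-state isotherm with ligand
depletion (the quadratic root, required when the junction concentration is
not negligible) and the cooperative Hill isotherm
`fb = Pt^n / (Pt^n + K_app)`, with AICc-based model comparison between them.

**Dimer stoichiometry.** Mixing native and size-shifted (fusion) protein
variants gives three gel-shift bands with binomial weights
`(p^2, 2p(1-p), (1-p)^2)`, `p = concA / (concA + rho * concB)` — the
signature of a dimeric bound complex.

## Worked example

```r
library(resolvr)

# simulate a noiseless cruciform time course at known rates, then refit it
traj <- simulate_cruciform_course(k1 = 0.019, k2 = 0.20, noise_sd = 0)
fit  <- fit_cruciform(traj)
fit$rates
#> Cruciform cleavage rates: k1 = 0.019 min^-1, k2 = 0.2 min^-1
#> Second-strand acceleration k2/k1 = 10.5-fold

# binding titration: 82 pM junction, protein 0.043-44 nM
tt <- simulate_titration(Kd = 10, Dt = 0.082, noise_sd = 0)
fit_binding(tt, model = "two_state")$estimate
#> Kd
#> 10
```

The recovered `k1` and `k2` are the generating rate constants (min^-1); the
acceleration ratio says the second cleavage is ~11-fold faster than the
first. The binding fit returns the dissociation constant in nM.

A command-line wrapper is installed under `exec/resolvr`:

```sh
resolvr simulate --kind cruciform --noise-sd 0 --out course.csv
resolvr fit-cruciform --input course.csv
resolvr predict-dimer --concA 40 --concB 40
```

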