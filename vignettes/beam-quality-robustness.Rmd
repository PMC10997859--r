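---
title: "Establishing RQR/RQA beam qualities and the robustness of SNR²/air kerma"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Establishing RQR/RQA beam qualities and the robustness of SNR²/air kerma}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rqbeam)
```

## The problem

The detective quantum efficiency (DQE) of a radiographic imaging detector is
normalised by the squared input signal-to-noise ratio per air kerma of the
beam, $SNR^2_{\mathrm{in}} = \int \varphi_E\,\mathrm{d}E \,/\, K_{\mathrm{air}}$,
where $\varphi_E$ is the photon fluence per unit energy and

$$K_{\mathrm{air}} = \int \varphi_E\, E\, \left(\mu_{\mathrm{tr}}/\rho\right)_{\mathrm{air}}(E)\,\mathrm{d}E.$$

The RQA standard radiation qualities used for DQE measurements are defined
procedurally, not spectrally: IEC 61267 fixes the tube voltage, a reference
first half-value layer (HVL) in aluminium and a fixed additional aluminium
filtration, but leaves the laboratory free in its anode angle, allows a
tolerance on the practical peak voltage (PPV), and accepts any establishment
whose HVL check lands inside a band.  Two laboratories can therefore realise
the *same* standard quality with *different* fluence spectra — and hence
different $SNR^2_{\mathrm{in}}$.  This package establishes the qualities
computationally and quantifies that spread as an uncertainty, following the
Monte Carlo procedure of GUM Supplement 2.

## The establishment procedure

For an RQR quality with nominal voltage $U$ and reference half-value layer
$\mathrm{HVL}_{\mathrm{ref}}$:

1. obtain the raw tube spectrum $\varphi_E$ at voltage $U + \Delta PPV$ and
   the chosen anode angle from a *spectrum provider*;
2. solve for the additional aluminium thickness $t_{\mathrm{ref}}$ such that
   the filtered beam's first HVL equals
   $(1 + \Delta\mathrm{HVL}_{\mathrm{ref}})\cdot \mathrm{HVL}_{\mathrm{ref}}$;
3. validate: behind a further aluminium test filter of the nominal
   $\mathrm{HVL}_{\mathrm{ref}}$ thickness the kerma ratio $K/K_0$ must lie
   in $[0.485, 0.515]$, and the homogeneity coefficient
   $h = \mathrm{HVL}_1/\mathrm{HVL}_2$ must sit within $\pm 0.03$ of its
   nominal value.

The linked RQA quality is the established RQR beam behind its fixed nominal
added aluminium (4 mm for RQA 2 up to 45 mm for RQA 10); $SNR^2_{\mathrm{in}}$
is evaluated on that heavily filtered beam.

Because air kerma is strictly decreasing in filter thickness, the condition
$\mathrm{HVL}(t) = \mathrm{HVL}_{\mathrm{target}}$ is equivalent to the single
signed equation

$$K(t + \mathrm{HVL}_{\mathrm{target}}) - \tfrac{1}{2}K(t) = 0,$$

which the package solves by bracketed Brent iteration (tolerance $10^{-9}$ mm
on $t$, verified residuals $<10^{-8}$ relative).  This replaces the nested
"solve HVL inside a squared-residual optimisation" formulation with a
result-identical single root find; the equivalence is asserted in the test
suite against a brute-force 1 µm thickness scan on beams with closed-form
attenuation.

## Numerical kernels

*Interpolation.* Interaction coefficients are interpolated quadratically on
the log–log scale through the three nearest nodes, exactly reproducing
tabulated nodes, and never across an absorption edge: edges (Al K at
1.56 keV, Ar K in air at 3.2 keV) are carried as doubled nodes delimiting
smooth segments.  The packaged files hold the NIST compilations on their
native grids (mass energy-absorption coefficients of dry air, which equal the
mass energy-transfer coefficients to well under 1 % below 160 keV where
radiative losses are negligible; XCOM total attenuation of aluminium with
coherent scattering at 2.699 g/cm³).  On load each table is densified to
about 2000 log-spaced nodes per smooth segment via the same interpolant —
the conventional fine logarithmic grid for this kind of data.  The expected
systematic on absolute $SNR^2_{\mathrm{in}}$ from using a published
compilation rather than dedicated Monte Carlo coefficient calculations is
below about 1 %.

*Quadrature.* Spectra are fixed histograms on their native grid (attenuation
never regrids, so quadrature error does not couple to filter thickness).
Integrals use the composite Simpson rule — pairs of intervals fitted by a
quadratic, a trailing odd interval by the trapezoid, a 1 keV lower cutoff —
and reduce to weighted sums, so every attenuated-kerma evaluation inside the
nested solvers is one vector exponential.  The fast path is bit-compatible
with naive attenuate-then-integrate evaluation (asserted to $10^{-12}$
relative).

*Units.* Energies are keV throughout; fluence is mm⁻² keV⁻¹; kerma is µGy
via the single centralised constant
$1.602\,176\,634\times 10^{-5}\,\mu\mathrm{Gy}$ per keV·cm²·g⁻¹·mm⁻².
$SNR^2_{\mathrm{in}}$ is reported in mm⁻²·µGy⁻¹ (parts of the standards
literature print mm⁻²·µGy; the defining ratio is dimensionally per µGy).

## The tolerance box and the uncertainty machinery

The three influence quantities are treated as independent rectangular
distributions: anode angle in $[9°, 30°]$ (the standard requires $>9°$ and
makes no upper recommendation; $30°$ covers the typical range), $\Delta PPV$
in $[-2.25, +2.25]$ kV (a conservative reading of the $1.5\,\%$ / $1.5$ kV,
$k=2$ PPV requirement), and $\Delta\mathrm{HVL}_{\mathrm{ref}}$ in
$[-5, +5]\,\%$ (the HVL shift that maps onto the $K/K_0$ acceptance band).
All three are configuration, not constants.

`corner_scan()` evaluates the $2^3$ box corners plus the $\Delta PPV = 0$
edge midpoints at both angle extremes — the voltage sensitivity changes sign
near RQA 7, so its extremum does not sit at a voltage corner.
`propagate_uncertainty()` is the GUM-S2 route: seeded uniform draws,
one full establishment per draw, sample mean, standard uncertainty $u$ (the
sample standard deviation), and the probabilistically symmetric 95 %
coverage interval as the [2.5, 97.5] percentile pair with linear
interpolation between order statistics (equal tail masses, not the shortest
interval).  The default $n = 10^4$ draws puts the Monte Carlo error on $u$
near 0.7 %; raw spectra are cached keyed exactly on the provider inputs, so
caching cannot alter results.  A full nine-quality run at $n = 10^4$ takes
on the order of eight minutes on one CPU; the test suite reuses one such run
across its statistical checks.

## The synthetic generator — what it emulates and what it does not

`synthetic_spectrum()` is a deterministic Kramers-form bremsstrahlung model:
$\varphi_E \propto (E_{\max} - E)/E$ on $[1\,\mathrm{keV}, E_{\max}]$,
hardened by an aluminium-equivalent anode self-filtration
$t = s\cdot\cot(\theta)$.  The scale $s = 0.1$ mm per unit cotangent puts
about 0.5 mm Al-equivalent in the beam at the conventional 12° angle —
typical of a lightly filtered diagnostic tube port — and keeps every RQR
establishment feasible down to RQR 2 at 9°.  There are no characteristic
tungsten lines and no electron-penetration model.  The generator exists so
that every algorithm in the package is exercised offline; an adapter to the
external SpekPy tungsten-anode model (`spekpy_provider()`) is provided for
absolute spectral work and records the model version in the spectrum
metadata.

Two structural consequences of this deliberate simplicity matter when
reading results produced with the synthetic generator:

* **The anode angle is inert after establishment.**  Because the synthetic
  self-filtration is aluminium-equivalent and the establishment solver adds
  aluminium, the solver absorbs the self-filtration exactly: established
  synthetic beams are independent of the anode angle.  With a real tungsten
  spectrum the angle changes the spectral *shape* (tungsten self-filtration
  and characteristic lines are not equivalent to any aluminium thickness),
  which is what produces the angle-driven effects reported for the hard
  qualities — the sign flip of the angle sensitivity across the quality
  range, the angle components of the extremal parameter triples, and part of
  the spread of the softest and hardest qualities.  None of these appear
  with the synthetic generator; the voltage- and HVL-driven structure (the
  $\Delta PPV$ sign flip across RQA 7, the extremal voltage/HVL corners, the
  decrease of the box's influence towards RQA 7) is genuine physics carried
  by the air coefficient curve and is reproduced.
* **Tolerance-box distributions come out nearly symmetric.**  The skewed
  $SNR^2_{\mathrm{in}}$ distributions seen for soft qualities with a real
  tube model stem from the nonlinear angle response; with the angle inert the
  synthetic distributions have skewness near zero.  Statistical quantities
  that are dominated by the voltage and HVL levers — the standard
  uncertainties themselves and their ordering across qualities — are
  nevertheless reproduced closely, consistent with the observation that the
  PPV tolerance, not the anode angle, dominates the uncertainty budget.

Absolute $SNR^2_{\mathrm{in}}$ values from the synthetic generator run
2–3.5 % below reference values for the same qualities (no characteristic
lines; coefficient-source systematics).  Ratios, spreads and uncertainties
are much less affected.

Known marginal case: at the extreme $\Delta\mathrm{HVL}_{\mathrm{ref}} =
\pm 5\,\%$ the nominal-thickness $K/K_0$ check lands essentially on the band
edge by construction; with the synthetic generator the softest quality
(RQR 2) overshoots the band by about 0.001 there, while all other qualities
stay inside.  At nominal $\Delta\mathrm{HVL}_{\mathrm{ref}}$ the band holds
for every quality and angle.

## Degenerate inputs, tie-breaks, tolerances

* Monoenergetic beams: HVL has the closed form $\ln 2/\mu(E_0)$, $h = 1$;
  the filtration solver correctly reports such beams infeasible for any
  other target (attenuation cannot change a monoenergetic HVL).
* A target equal to the raw beam's own HVL returns $t_{\mathrm{ref}} = 0$;
  targets below it raise an explicit "would need softening" error rather
  than returning a negative thickness.
* Root brackets grow by doubling and fail loudly at 200 mm (filtration) or
  1000 mm (HVL); residual checks guard against silent pseudo-convergence.
* The second HVL is defined as quarter-value layer minus first HVL, the
  conventional reading of "ratio of the first to the second HVL".
* Zero-width tolerance boxes are legal: the scan and the propagation both
  collapse to the single establishment (used as a test fixture).
* Integration grids with an even point count fall back to one trapezoid
  interval at the top end; generator grids are built with odd point counts
  at integer voltages, and the error at a 0.5 keV step is negligible either
  way.

## Worked example

```{r example, eval = FALSE}
library(rqbeam)

# Establish RQA 5 at a 12 degree anode, nominal voltage and HVL target
beam <- establish_rqa("RQA 5", anode_angle = 12)
beam
validate_beam(beam)

# Tolerance-box extrema
corner_scan("RQA 5")$spread_pct

# GUM-S2 Monte Carlo
res <- propagate_uncertainty("RQA 5", n_draws = 10000, seed = 101)
res
summarize_uncertainty(res, bins = 20)$summary
```

With the packaged defaults the RQA 5 establishment at 12° solves
$t_{\mathrm{ref}} = 3.16$ mm Al, achieves the 2.58 mm reference HVL to
better than $10^{-4}$ mm, passes $K/K_0 = 0.500$ and $\Delta h = +0.014$,
and yields $SNR^2_{\mathrm{in}} = 2.92\times 10^4$ mm⁻²·µGy⁻¹ with a
standard uncertainty of about 226 mm⁻²·µGy⁻¹ (0.77 %) over the tolerance
box.

## Limitations

* The synthetic generator's anode-angle inertness and missing
  characteristic lines, as discussed above; table-level absolute
  comparisons should use the external-model adapter.
* Coefficient-table uncertainty and spectrum-model uncertainty are not
  propagated; the three IEC tolerance dimensions are the only inputs.
* The $K/K_0$ device is idealised narrow-beam attenuation — no collimation,
  scatter or monitor-chamber geometry.
* No detector modelling: `dqe()` is a pure formula over caller-supplied
  MTF, kerma and noise-power values.
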