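---
title: "Designing tissue-mimicking liquid mixtures for microwave phantoms"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Designing tissue-mimicking liquid mixtures for microwave phantoms}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(phantomix)
```

## The problem

Microwave medical imaging systems (stroke detection helmets, breast
scanners) are validated on anthropomorphic phantoms: 3D-printed cavities
filled with liquids whose complex permittivity imitates biological tissues
over the working band, typically 0.5--3 GHz. A practical family of such
liquids are binary mixtures of Triton X-100 (a non-ionic surfactant with
low permittivity) and salted water (high permittivity, with conductivity
set by the NaCl content). Designing a tissue-mimicking material (TMM) then
amounts to answering: *which saline volume fraction `V2` and NaCl
concentration `S` make the mixture's spectrum match a target tissue?*

`phantomix` implements that design loop end to end: dispersive tissue
models, binary mixing laws, a Gauss--Newton fit of `(V2, S)`, bench-ready
recipes, a 1D field-penetration explorer for coupling-medium choices, and
STL/manifest plumbing to bind recipes to phantom cavity geometry.

## Dielectric models

All spectra use the convention `eps = eps' - j eps''` with time factor
`e^{+j w t}`, so passive media have `eps'' >= 0`; the effective
conductivity is `sigma_eff = 2 pi f eps0 eps''`. R complex values carry
`Im(eps) = -eps''`.

**Tissues** follow multi-pole Cole--Cole dispersion,

```
eps(w) = eps_inf + sum_n  d_eps_n / (1 + (j w tau_n)^(1 - alpha_n)) + sigma_s / (j w eps0),
```

with the standard four-pole literature parameter sets (Gabriel et al. 1996
survey) vendored as JSON fixtures for nine tissues (white/grey matter,
blood, cortical bone, CSF, muscle, nerve, fat, dry skin), each carrying a
provenance note. A tenth entry, `brain`, is the volume-weighted blend of
75 % white and 25 % grey matter; the blend rule is linear per-frequency
averaging of the complex permittivity, the simplest rule consistent with
the published reference value (`eps' = 42.0` at 1 GHz). Its conductivity
evaluates to 0.71 S/m at 1 GHz; published phantom tables sometimes quote
~1.0 S/m for the same blend, a discrepancy inherited from the reference
models rather than from this implementation (no test asserts the blend
conductivity).

**Triton X-100** is a single-pole Debye liquid. Its measured Debye fit is
not available in the open sources shipped here, so the fixture
`tx100_debye_synthetic.json` (`eps_s = 7.4`, `eps_inf = 2.5`,
`tau = 0.22 ns`) is an editable synthetic stand-in chosen inside the
published range for polyethoxylated surfactants and validated against
published 1 GHz mixture properties of head-tissue TMMs. Sensitivity checks
over that plausible range move the validated values by less than 0.1
permittivity units, so the exact choice is not load-bearing; replace the
file with a measured fit if one is available.

**Saline** uses a Stogryn-type parametric Debye model: static permittivity,
relaxation time and ionic conductivity are polynomials in normality
`N = S / 58.44` (S in g/L) and temperature. The declared validity window is
0--160 g/L and 0--50 degrees C. The analytic salinity derivative
`d eps2 / d S` -- required by the optimizer -- is implemented alongside and
agrees with central finite differences to ~1e-10 relative.

## Mixing laws

Five binary laws are implemented; `eps1` is TX-100, `eps2` saline, `v2`
the saline volume fraction:

* **Kraszewski** (square-root linear):
  `eps_m = (sqrt(eps1) + v2 (sqrt(eps2) - sqrt(eps1)))^2`. Principal
  square roots are unambiguous because all physical permittivities here
  lie in the right half-plane. `sqrt(eps_m)` is exactly affine in `v2`.
* **Bottcher** and **Bruggeman**: implicit effective-medium quadratics,
  solved in closed form; the admissible root is the passive one
  (`eps'' >= 0`, `Re > 0`) continuous with the `v2 -> 0` limit. If no
  root qualifies (only possible for non-passive inputs) the law errors
  naming itself and its inputs.
* **Lichtenecker** (logarithmic) and **Looyenga** (1/3-power), provided
  for comparison only: in the source study only Bottcher and Kraszewski
  reproduced measured mixture spectra, so the comparison laws are not
  wired into any design default.

All five laws have closed-form derivatives with respect to both unknowns
(implicit differentiation for the quadratic laws); the test suite checks
them against central finite differences at random compositions to 1e-6
relative.

## The recipe fit

The composition `x = (V2, S)` minimizes the weighted complex misfit over
the band,

```
J(x) = sum_f  w_f |eps_m(x; f) - eps_t(f)|^2,    w_f = 1 / |eps_t(f)|^2,
```

by damped Gauss--Newton: gradient
`g = 2 sum_f w_f Re[(eps_m - eps_t)* eps_m']` and approximate Hessian
`H = 2 sum_f w_f Re(eps_m'* eps_m'^T)` (symmetric PSD by construction),
update `x <- x - H^{-1} g`. The default grid is 26 linear points over
0.5--3 GHz; the relative weights make `J` dimensionless and O(1), so the
default start `(V2, S) = (0.5, 5 g/L)` converges for every vendored tissue
in 4--11 iterations.

Numerical safeguards (they never change a benign converged answer):

* **Step damping**: the Gauss--Newton step is halved until `J` does not
  increase, making the cost trace non-increasing by construction.
* **Box projection**: iterates are projected onto `V2 in [0, 1]`,
  `S in [0, 100] g/L`.
* **Active-set handling**: a coordinate pinned at a bound whose gradient
  points outward is frozen and the reduced 1D Newton step taken;
  stationarity is tested on the projected gradient. This matters for
  low-water tissues (cortical bone, fat) whose optimum sits on the `S = 0`
  bound: without it the full-gradient test never fires and multi-start
  results scatter at the 1e-4 level. With it, all ten vendored tissues are
  init-independent to better than 1e-9 across seeded random starts.
* **Rank-deficient `H`** falls back to an SVD pseudo-inverse and flags the
  fit (`singular_hessian`); with two well-scaled unknowns this does not
  occur for the vendored targets.
* Tolerances: projected-gradient norm `< 1e-10 (1 + J)` or step
  `< 1e-12`, cap 100 iterations -- far below the reporting precision
  (integer vol %, 0.1 g/L). Non-convergence is reported in the result,
  never thrown.

`grid_search_recipe()` provides a brute-force oracle: the fitted minimizer
is required (in the tests) to land within one cell of a 200 x 200 grid
minimum.

### What a green fit does and does not establish

The synthetic world the tests rely on is the vendored fixture stack:
Gabriel-style tissue targets, the Stogryn-type saline and the synthetic
TX-100 Debye stand-in. Against that world the inverse fits reproduce
published head-tissue recipes to about 1--2 vol % TX-100 and ~1 g/L NaCl.
Two caveats are documented rather than hidden:

* Fitted NaCl for the water-rich tissues runs ~1 g/L above the published
  concentrations (and brain ~1 g/L below), the imprint of component
  models (the study's TX-100 and saltwater references are not printed)
  whose loss per g/L differs slightly from this stack. TX-100 fractions
  are unaffected.
* Kraszewski and Bottcher recipes agree within 1 vol % for the four
  water-rich head tissues but diverge for cortical bone (77.6 vs 68.4
  vol % TX), the composition region where a square-root-linear rule and an
  effective-medium rule structurally differ most; the published columns
  differ by 5 vol % there with the study's own components. Both fits are
  verified global minima of their respective laws.

A green suite therefore establishes the correctness of the machinery
(models, laws, derivatives, optimizer, recipes) and desk-scale agreement
with the published design table -- not a replacement for measuring an
actual mixture, which is why the bench protocol retains its experimental
adjustment step.

## Recipes and the viscosity rule

`build_recipe()` converts a composition into masses for a batch volume:
TX-100 volume times density 1.07 g/mL, water at 0.997 g/mL, NaCl at
`S x saline volume`. The saline volume is approximated by its water volume
(the NaCl volume increment is neglected -- consistent with the g/L
definition of concentration, and exactly invertible: composition ->
recipe -> composition round-trips to 1e-12). Mixtures with TX-100 in the
closed band [40, 60] vol % are flagged viscous at 25 degrees C (the
nerve-mimicking mixture, ~44--46 vol %, is the canonical case); the
warning carries the standard mitigation (warm components separately, mix,
stir vigorously, rest at 45 degrees C until air bubbles vanish). Boundary
compositions at exactly 40 or 60 vol % warn (closed interval, a documented
convention).

## The 1D penetration proxy

`transfer_1d()` solves normal-incidence plane-wave propagation through a
layered stack with 2x2 transfer matrices, complex wavenumbers
`k = (2 pi f / c0) sqrt(eps)` and relative impedances `1/sqrt(eps)`. It is
deliberately a qualitative explorer -- one polarization, flat layers, no
antennas -- for questions like "does a coupling medium of dielectric
constant ~23 beat air?" For the canonical skull (7 mm) / CSF (2 mm) /
brain stack at 1 GHz it does, by roughly a factor 3 in transmitted field
amplitude; that inequality (not any field map) is the tested claim.
Energy conservation in lossless stacks holds to 1e-12 and the transfer
determinant equals the impedance ratio (a reciprocity identity) on random
stacks.

## Geometry and manifests

`read_stl()` parses both STL dialects (ASCII by keyword sniffing on
printable bytes; binary with strict 84 + 50n byte accounting, failing with
the byte offset on truncation) and reports triangle count, bounding box
and an edge-pairing watertightness heuristic. `build_manifest()` validates
a cavity-to-tissue configuration, fits one recipe per distinct tissue and
writes a schema-versioned JSON manifest atomically (nothing is written on
any validation failure); the output is byte-identical on reruns.

## Defaults worth knowing

| Parameter | Default | Why |
|---|---|---|
| Band | 26 linear points, 0.5--3 GHz | working band of head imaging systems; published recipes were derived on it |
| Temperature | 25 C | recipes are prepared and measured at room temperature; only the saline model is temperature-dependent |
| Law | `kraszewski` | explicit, smooth, matches measured mixtures; `bottcher` is the cross-check |
| Weights | `1/|eps_t|^2` | makes J relative and O(1) across tissues |
| Init | `(0.5, 5 g/L)` | mid-box; result is init-independent for all vendored tissues |
| TX-100 density | 1.07 g/mL | literature constant at 25 C (fixture) |

## Known limitations

* No fitting of Cole--Cole parameters to measured probe data; the tissue
  fixtures are literature constants used as-is (body-temperature values,
  as is conventional in phantom design).
* The TX-100 fixture is a documented synthetic stand-in (see above).
* The penetration module is 1D and normal-incidence only; it ranks
  coupling media, it does not predict field maps.
* No viscosity or shelf-life modelling beyond the warning band and the
  storage step of the protocol.
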