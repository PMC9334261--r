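---
title: "Modelling a DNA-origami piston actuator: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling a DNA-origami piston actuator: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(nanowinch)
```

## The device and the model

The package models a DNA-origami actuator built as a piston sliding inside a
concentric cylinder, moored to a membrane by rigid landing legs. Two sets of
DNA connectors — up to six between the backstop and the top of the cylinder,
and six between the cylinder and the piston tip — pull against one another.
In the *autonomous* mode both sets are single-stranded scaffold loops: floppy
polymers (persistence length about 1 nm) that act as entropic springs and
exert low-piconewton tension without any external trigger. In the *remote*
mode, complementary oligonucleotides hybridize the backstop-cylinder
connectors into stiff double-stranded DNA (persistence length about 50 nm),
ratcheting the piston outward by a programmable distance set by the connector
length. The piston tip engages a membrane protein, which we coarse-grain as a
linear spring of stiffness $k_{\mathrm{protein}}$.

All mechanics are expressed in pN, nm and pN·nm, with thermal energy
$k_BT = 4.089$ pN·nm at the default bath temperature of 296.15 K (23 °C).

## Worm-like-chain elasticity

Each connector is a worm-like chain with contour length
$L_c = n \times \mathrm{rise}$ and persistence length $L_p$. We use the
Marko–Siggia interpolation for its force–extension relation,

$$F(z) = \frac{k_BT}{L_p}\left[\frac{1}{4}\left(1-\frac{z}{L_c}\right)^{-2}
 - \frac{1}{4} + \frac{z}{L_c}\right],$$

because it is the standard single-parameter-family interpolation, is exact in
both the entropic-spring and high-force limits, and is cheaply invertible by
bracketed root finding (`wlc_extension_at_force()`, absolute tolerance
$10^{-9}$ nm). Its antiderivative (`wlc_energy()`) and derivative
(`wlc_stiffness()`) are closed-form, so the actuator potential below is
smooth and convex by construction. Near zero extension the model reduces to
the entropic spring constant $3k_BT/(2L_pL_c)$, about 0.10 pN/nm for a
97-nt single-stranded connector.

Defaults: single-stranded rise 0.63 nm/nt and $L_p$ = 1 nm; double-stranded
rise 0.34 nm/bp and $L_p$ = 50 nm. The double-stranded rise is fixed by the
anticipated 33 nm extension of a 97-bp connector; the single-stranded rise is
the conventional literature value. Salt dependence of $L_p$ is out of scope:
$L_p$ is a plain parameter.

Extensions are restricted to $0 \le z < L_c$. The force law diverges at
$L_c$, and negative extensions are meaningless for a tethered loop; callers
that need a connector *at* its contour length (the hybridized rigid-rod
picture) use the `remote_ds_rigid` actuator mode instead, where the top set
is a constraint, not a spring.

## The force balance and its calibrated geometry

A single coordinate $x$ — the distance between the bottom of the piston and
the bottom of the cylinder — determines both connector extensions through a
fixed end-to-end budget $D$ (`span_D`):

$$e_{\mathrm{top}}(x) = x + c_1, \qquad e_{\mathrm{bot}}(x) = D - x + c_2 .$$

The total potential in autonomous mode is

$$U(x) = n_{\mathrm{top}} E_{\mathrm{top}}(e_{\mathrm{top}}(x))
 + n_{\mathrm{bot}} E_{\mathrm{bot}}(e_{\mathrm{bot}}(x))
 + \tfrac{1}{2}k_{\mathrm{protein}}(x - x_{\mathrm{rest}})^2,$$

and `solve_equilibrium()` finds the unique interior minimum by a bracketed
root of $U'(x)$ after a numeric convexity check, with residual
$|U'(x_{\mathrm{eq}})| < 10^{-6}$ pN. The force delivered to the target is
$k_{\mathrm{protein}} \, (x_{\mathrm{eq}} - x_{\mathrm{rest}})$; the rest
position defaults to 0 (target relaxed at full retraction).

The two geometric unknowns $(D, c_1)$ are not derivable from the published
design drawings alone, so the package closes the model by a one-time
least-squares calibration (`calibrate_geometry()`) against the two published
anchor forces of the autonomous 97-nt device: 1.6 pN at
$k_{\mathrm{protein}} = 0.1$ pN/nm and 30 pN at 20 pN/nm. An unconstrained
fit would drive $c_1$ to $-2.4$ nm, which is unphysical (a connector cannot
have negative end-to-end extension anywhere in the working range), so the
fit constrains $c_1 \ge 0$ and lands on the boundary:

* `span_D` = 32.1795 nm, `top_offset` = 0, `bottom_offset` = 0,
* fitted forces 1.525 and 30.002 pN, residual 0.075 pN,

frozen as `calibrated_geometry()`. The soft-end force therefore sits 0.075 pN
below the nominal 1.6 pN anchor — well inside that number's own stated
±0.3 pN band — and we prefer this physically admissible boundary optimum to
an exact but unphysical fit. Both parameters remain user-overridable.

```{r}
force_vs_kprotein(actuator_model(), c(0.1, 1, 20))
```

## Remote modes

`remote_ds_rigid` treats hybridized connectors as rigid rods at contour
length: the anticipated extension is simply
$\mathrm{round}(n_{bp} \times 0.34\ \mathrm{nm})$ — 10, 20 and 33 nm for 30,
60 and 97 bp (`predict_anticipated_extension()`).

`remote_ds_effective` replaces the rod with a linear spring of device-level
effective stiffness (8.0 pN/nm for double-stranded, 3.0 pN/nm for
single-stranded 97-unit connectors — constants taken from the authors'
coarse-grained simulations, which we do not re-run) anchored at the contour
length. In this mode the antagonistic single-stranded set *resists*
extension: its extension must grow with $x$, which the autonomous map
$e_{\mathrm{bot}} = D - x + c_2$ cannot express (under that map the bottom
set always aids extension, and the equilibrium would sit *above* the contour
length whenever the bottom springs are taut — the opposite of what is
observed). We therefore give the remote mode the complementary map
$e_{\mathrm{bot}}(x) = \max(0,\, x - D + c_2)$, with `span_D` reinterpreted
as the slack budget stored in the reservoir loops before the antagonists
engage. The default slack of 20 nm is an illustrative round value, not a
fitted one; with it the free 97-bp device equilibrates slightly below its
33 nm contour prediction, qualitatively matching the measured shortfall.

Two small deterministic helpers complete the module: the hairpin benchmark
(`hairpin_force()`: $8.0\ \mathrm{pN/nm} \times 5.3\ \mathrm{nm} = 42$ pN at
two significant figures, exceeding the $F_{1/2} \approx 20$ pN unzipping
force; `hairpin_open_probability()` is the corresponding two-state logistic
with a default 10 nm opening distance, a typical hairpin value exposed as a
parameter), the linear membrane-indentation correction (0.1 nm per pN), and
the equipartition positioning precision $\sqrt{k_BT/(n k_{\mathrm{single}})}$
for $n$ parallel connectors.

## Thermal ensemble

The piston fluctuates thermally in $U(x)$;
$p(x) \propto e^{-U(x)/k_BT}$ on the admissible interval is what a TEM
distance histogram of many particles should resemble if staining and drying
artefacts are ignored. `boltzmann_moments()` evaluates the distribution by
adaptive quadrature (normalization error $< 10^{-8}$; quantiles from a
trapezoid CDF on a 0.05 nm grid), and `metropolis_sample()` is its seeded
stochastic twin: random-walk Metropolis, Gaussian proposals (default sd
1 nm), reflective boundaries, 10% burn-in, acceptance rate recorded and
warned about outside 5–95%. The ensemble is strictly one-dimensional:
tilting and rotation of the backstop against the cylinder are ignored, which
is the same simplification the effective-stiffness constants already carry.
Tests compare sampler and quadrature through batch-means Monte-Carlo errors
rather than naive standard errors, since the chain is autocorrelated.

The free autonomous 97-nt device equilibrates near 16.1 nm with a thermal sd
of about 1.5 nm — inside the observed 5–30 nm distance window but much
narrower than the measured spread, which is consistent with the measured
histograms being broadened by degrees of freedom (and specimen-preparation
effects) outside this 1-D model. Comparisons against measured tables are
therefore descriptive (`compare_to_model()`: mean difference, sd ratio,
Kolmogorov–Smirnov statistic only), never fits.

## Readout computations

**TEM distance tables.** CSV with a `distance_nm` column; negative or
non-numeric entries are rejected with the offending row named. The measured
backstop–cylinder distance maps to the actuation distance through an affine
map defaulting to the identity (`r_to_d()`), any offset being an explicit
parameter. Summaries use the unbiased sd and a density histogram with 2 nm
default bins.

**Bead calibration.** `fit_bead_calibration()` regresses
$\log_{10}(\text{molecules per bead})$ on $\log_{10}(\text{MFI})$ by
ordinary least squares (the log base is a parameter), and `count_from_mfi()`
inverts the line for a background-subtracted sample MFI. The $r^2$ is
computed directly from residuals so that noise-free calibration lines do not
trip `summary.lm`'s perfect-fit warning.

**LRET ratio.** `lret_ratio()` computes the scaled acceptor/donor ratio per
well (scale $10^4$, matching the magnitude convention of the printed
responses) and subtracts the mean antibody-only background. Because the
scale enters linearly, scaling before or after background subtraction is
mathematically identical, so no ordering switch is exposed.

**Trace idealization.** `segment_trace()` uses a deterministic 2-means split
(centers seeded at the 10/90% quantiles) for initial levels, a
threshold-with-hysteresis walk at the midpoint ±¼ of the level separation,
merging of dwells shorter than 5 samples (shortest first), and final
recomputation of per-state statistics. The single-state guard compares the
level separation against twice the within-state noise sd estimated robustly
from first differences, `mad(diff(i))/sqrt(2)`; estimating that sd from the
2-means clusters themselves would never flag a unimodal noisy trace
(a Gaussian always splits with separation ≈ 1.6σ), while the whole-trace sd
would wrongly flag a noiseless square wave. A hidden-Markov model would be
the tool of choice for poorly separated or multi-level channels; it is
deliberately out of scope for the two well-separated levels treated here.

## Synthetic data

Every consumed input has a seeded generator whose defaults *are* the
reported study statistics:

* `gen_tem_distances()`: zero-truncated normal; per-variant means 17.7 /
  14.0 / 9.3 nm (single-stranded 97/60/30 nt) and 10.7 / 19.0 / 31.3 nm
  (double-stranded 30/60/97 bp) in `tem_defaults()`. The common sd of 5 nm
  is a fixture convention chosen to match the visual spread of the measured
  histograms; per-variant SDs were not reported.
* `gen_bead_table()`: five populations spanning $10^2$–$10^6$ molecules on a
  slope-1, intercept-0 log-log line with lognormal MFI noise (cv 5%), plus
  replicate cell MFIs at a configured truth of 9,200 devices per cell.
* `gen_plate()`: donor at $10^4$ counts, acceptor set so the expected
  response equals the configured truth (default $1.23\times10^4$) above a
  background ratio of $0.5\times10^4$ — a round value on the order of the
  reported low-control responses, since the antibody-only level itself is
  not printed — with cv 10% lognormal noise on both intensities.
* `gen_trace()`: two-state continuous-time Markov chain, closed 4 pA / open
  16 pA, Gaussian noise sd 4 pA, sampled at 1 kHz. Mean dwells default to
  1 s per state: transitions are on the seconds scale in the recordings, and
  second-scale dwells keep boundary samples (the main idealization error
  source) rare. Dwell kinetics are a fixture convention, not a measured
  quantity.

Generators attach their seed and parameters as metadata;
`write_generated()` emits a JSON sidecar from which `regenerate()` rebuilds
the file byte-identically. What passing recovery tests on these fixtures
shows is that the *pipeline* is unbiased and correctly scaled at the study's
reported operating points — not that the physical model reproduces raw
instrument output, which contains drift, correlated noise and preparation
artefacts that the generators deliberately omit.

## Numerical choices and problem sizes

* Equilibria: `uniroot` at tolerance $10^{-13}$ on an analytic gradient;
  boundary solutions are flagged `converged = FALSE` rather than silently
  returned.
* Quadrature: `integrate` at relative tolerance $10^{-10}$; Metropolis
  agreement is asserted within 3 batch-means standard errors.
* Test and verification sizes: $10^5$ Metropolis steps, 500-particle TEM
  samples, 60 s traces at 1 kHz, 100 replicate bead experiments — sizes at
  which the statistical tolerances above are meaningful while the whole
  suite runs in well under a minute of numeric work.
* Ties and degenerate inputs: single-measurement summaries report an
  undefined (NA) sd; constant traces are single-state; `r_to_d()` floors at
  zero; extensions are clamped strictly inside $[0, L_c)$.

## Known limitations

* The calibrated one-coordinate geometry is a transparent stand-in for the
  full three-dimensional origami mechanics; it reproduces the published
  anchor forces by construction of its two free parameters and should not be
  read as an independent prediction of them.
* The remote-mode force range is a consistency illustration only; the
  effective-stiffness constants come from the authors' coarse-grained
  simulations and are used as given.
* The 1-D thermal ensemble understates the measured distance spread (see
  above).
* Trace idealization assumes exactly two well-separated levels and no
  baseline drift.
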