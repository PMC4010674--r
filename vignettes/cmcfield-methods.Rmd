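---
title: "Neural-field modelling of contrast-dependent cross-spectra: models and methods"
author: "cmcfield"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Neural-field modelling of contrast-dependent cross-spectra}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cmcfield)
```

# The scientific problem

Visually induced gamma oscillations in primary visual cortex change with
stimulus contrast: their peak frequency rises by roughly ten hertz from low
to high contrast, while single-unit work shows that receptive fields shrink
as contrast increases.  Three synaptic mechanisms could produce such
effects: changes in the recurrent (self) gain of pyramidal populations,
changes in the strength of couplings between populations, or changes in the
*spatial extent* of horizontal (lateral) connections.  Distinguishing them
requires a generative model that predicts what multi-electrode recordings
would look like under each mechanism, and a way to score those models
against data.  `cmcfield` implements such a model — a canonical-microcircuit
neural *field* — together with its Bayesian inversion machinery, and
exercises the whole pipeline on synthetic data that emulate a
multi-condition contrast experiment recorded with a subdural electrode
array.

# The generative model

## Neuronal dynamics

A one-dimensional cortical patch of length $\ell = 25$ mm (treated as a
ring, since the connectivity kernels depend only on distance) carries four
neuronal populations per location: spiny stellate input cells (1),
inhibitory interneurons (2), deep pyramidal cells (3) and superficial
pyramidal cells (4).  Mean depolarisation $V(x,t)$ obeys second-order
(critically damped) synaptic dynamics driven by horizontally coupled firing
rates and exogenous input,

$$\ddot V + 2B\dot V + B^2 V
  = B \int K(x - x')\, F(V(x', t - \upsilon|x - x'|))\, dx' + G\,U,$$

with $B = \mathrm{diag}(\kappa_1, \dots, \kappa_4)$ the inverse synaptic
time constants, $G = (\kappa_1, 0, 0, 0)^T$ routing the input fluctuations
$U$ into the stellate population, $\upsilon$ the inverse conduction speed,
and $F$ a sigmoid mapping depolarisation to normalised firing rate.  The
coupling kernel $K$ has one exponentially decaying entry
$\pm(\alpha_{ab}/2)e^{-c_{ab}|x|}$ per anatomical connection of the
microcircuit; ten connections are structurally present and their
excitatory/inhibitory signs are fixed (see `cmc_edges()`).  The decay rates
$c_{ab}$ *are* the effective spatial extents of lateral interactions — the
quantity of scientific interest for the receptive-field question.

Spectral responses are treated as fluctuations about a zero expansion
point: $F$ enters only through its slope $\gamma$ there, no fixed-point
search is performed, and the time-domain simulator uses the deviation form
$F(v) - F(0)$ in its nonlinear mode so that rest is a fixed point by
construction.

## Transfer functions

Under the Fourier convention with forward kernel $e^{-i\omega t}$ (the
convention of R's `fft`), differentiation maps to $+i\omega$ and a
conduction delay contributes $e^{-i\omega\upsilon|x|}$ inside the kernel
transform.  Each mode $(k, \omega)$ then satisfies a $4\times4$ linear
system, giving the population transfer functions

$$T(k,\omega) = \big[\mathrm{diag}\big((\kappa_a + i\omega)^2\big) -
  \gamma B D(k,\omega)\big]^{-1} G, \qquad
  D_{ab} = \pm\alpha_{ab}\frac{c_{ab} + i\upsilon\omega}
  {(c_{ab} + i\upsilon\omega)^2 + k^2}.$$

Published factorised expressions for this solution are typeset ambiguously
(signs and groupings cannot be recovered unambiguously from the printed
form), so the package carries *two independent implementations*: the
matrix-inverse route above (`transfer_matrix()`, authoritative) and an
explicit Cramer's-rule expansion over the microcircuit's sparsity pattern
(`transfer_closed_form()`).  Their agreement to $10^{-8}$ relative error
over wide random parameter draws is part of the test suite; the compiled
production predictor uses the closed form for speed.

Two structural facts are exploited throughout: $T$ depends on $k$ only
through $k^2$ (so only $k \ge 0$ is evaluated), and with a spatially white
input and frequency-independent lead fields all predicted cross-spectra
are exactly real — phase differences between sites cancel in the symmetric
wavenumber sum.  Imaginary parts of observed cross-spectra are therefore
modelled as pure noise, which is what finite-epoch estimates of a
mirror-symmetric process produce on average.

## Observation model

Each electrode $q$ sees the patch through a unit-mass Gaussian lead field
of width $\phi_q$ centred at $a_q$; its Fourier factor at angular
wavenumber $k$ is $E(\phi, k) = e^{-\phi^2 k^2/2}$ (equivalently
$e^{-2\pi^2\phi^2\xi^2}$ in cycle units $\xi = k/2\pi$).  Recording sites
are bipolar differences of electrode pairs (montage matrix with one $+1$
and one $-1$ per row), giving the site transfer
$\tilde T_l(k,\omega) = (e^{-ia_{l^+}k}E(\phi_{l^+},k) -
e^{-ia_{l^-}k}E(\phi_{l^-},k))\,Q\cdot T(k,\omega)$ with population mixing
weights $Q = (0.2, 0, 0.2, 0.6)$ — pyramidal populations dominate, the
interneurons contribute nothing.  Predicted cross-spectra sum over the
wavenumbers $k_n = 2\pi n/\ell$, $|n| \le N$:

$$\hat g_{lm}(\omega) = \sum_k \tilde T_l\, g_u(\omega)\, \tilde T_m^*
  + \delta_{lm}\, g_n(\omega) + g_c(\omega).$$

Input and noise spectra are white-plus-pink mixtures
$\alpha + \beta(1\,\mathrm{Hz}/f)$.  The published account leaves the
coloured form and the placement of channel noise open; we adopt the $1/f$
convention (exponent configurable) and a superset noise model — a
site-specific term on the auto-spectra plus a small common term on every
pair — that nests the per-site and common readings and can be switched off
through its amplitudes.

**Default sensor geometry.**  Eight electrodes $\ell/8$ apart centred on
the patch, dispersions $\ell/16$, paired into four sites sharing no
electrode.  The published prior table's lead-field row cannot be read
unambiguously; these values follow its surrounding text and are exposed as
ordinary configurable priors.

**The neural-mass restriction.**  Shrinking the patch to a point retains
only the $k = 0$ mode and removes conduction delays ($\upsilon$ fixed at
zero).  At $k = 0$ the bipolar difference cancels *exactly* (both
electrodes have $E = 1$ and no phase), so a literal mass restriction of the
bipolar observation model predicts zero signal.  The mass variant therefore
uses the classical point-source observation model: free per-site amplitude
gains replacing the spatial phase/dispersion structure.  This gives the
mass model a fair chance — it can scale each site freely — while it still
cannot reproduce spatial structure that genuinely arises from $k \ne 0$
modes.

## Priors and units

Internally everything is seconds and millimetres; the conventional prior
means are $\kappa = (1/2, 1/35, 1/35, 1/2)\,\mathrm{ms}^{-1}$ (converted on
input), $c_{ab} = 2\,\mathrm{mm}^{-1}$ for self-connections and
$0.6\,\mathrm{mm}^{-1}$ otherwise, conduction speed $0.3$ m/s, sigmoid
slope $r = 0.54$ at half-maximum potential $\eta = 0$.  The published table
lists ten coupling names against eight printed amplitudes; the package maps
the printed values in order to
$(\alpha_{11}, \alpha_{14}, \alpha_{12}, \alpha_{22}, \alpha_{21},
\alpha_{23}, \alpha_{33}, \alpha_{41})$ and assigns the last two printed
values to $\alpha_{32}, \alpha_{44}$.  Because the table is internally
inconsistent, the resolved mapping is archived with every command-line run
and is overridable.

Every scale parameter $\theta_j$ is estimated as
$\theta_j = \bar\theta_j e^{\vartheta_j}$ with
$\vartheta_j \sim N(0, v_j)$: $v_j = 1/16$ for couplings, decays,
dispersions, noise amplitudes and condition sensitivities, and $1/64$ for
rate constants, conduction speed and electrode centres (tighter because
these are strongly constrained physiologically and weakly identified
jointly).  The sigmoid slope is fixed — its effect is perfectly confounded
with a common rescaling of all couplings.

## Condition-specific effects and the model space

Contrast enters as a covariate $u_c$ = printed percentage / 100
($u \in [0, 0.82]$; a log-intensity coding is available since each
non-zero contrast step roughly doubled the luminous intensity).  A model is
a choice of which parameter subsets may change log-linearly with $u$:
**G** (recurrent pyramidal gains $\alpha_{33}, \alpha_{44}$), **L** (the
six between-population couplings), **E** (all ten spatial decays).  Each
modulated parameter gains a sensitivity $\beta_j$ with prior $N(0, 1/16)$,
so $\theta_j(c) = \bar\theta_j\exp(\vartheta_j + \beta_j u_c)$.  The
$2^3$ factorial gives 8 models (`model_space()`), numbered: 1-3 the single
factors, 4 gain+extent, 5 couplings+extent, 6 gain+couplings ("all but
extent"), 7 all three, 8 the null model.

# Inversion

`fit_csd()` maximises a variational (Laplace) free energy over a Gaussian
posterior on the packed log-scale vector: Gauss-Newton ascent with central
finite-difference Jacobians (step $10^{-3}$; predictions are smooth in the
log parameters), Levenberg-Marquardt damping that grows fourfold on
rejected steps and halves on acceptance, and a single noise log-precision
$\lambda$ updated by safeguarded Newton steps under a Gaussian hyperprior.
All conditions are fitted jointly; the likelihood factorises over
conditions, which realises the "product of per-condition evidences" view of
fixed-effects comparison with a single free energy per model.  Convergence
is declared after four consecutive accepted improvements below 0.01; the
iteration cap defaults to 128.

Three numerical choices deserve comment, all adopted after the obvious
defaults failed on synthetic benchmarks:

* **Residual weighting.**  Finite-epoch spectral estimates have standard
  errors proportional to spectral level, not constant: averaged
  periodograms are Wishart distributed with
  $\mathrm{sd}(\hat g_{lm}) \propto \sqrt{g_{ll} g_{mm} / n}$.  An
  unweighted Gaussian likelihood therefore lets the spectral peaks dominate
  and yields overconfident, mis-calibrated posteriors (about half the 90%
  intervals missed their generating values in our benchmarks).  By default
  each residual is scaled by $\sqrt{g_{ll} g_{mm}}$ of the *observed*
  auto-spectra — a fixed, model-independent transform of the data, so free
  energies remain comparable across models.  The hyperprior mean for
  $\lambda$ is matched to the sample variance of the (weighted) data; its
  variance defaults to 16, wide enough not to pin the residual variance to
  the raw data variance (a tight hyperprior there would make the
  likelihood vacuous, since the residual variance after fitting is orders
  of magnitude below the data variance).

* **Warm starting.**  The free-energy surface of condition-effect models is
  multimodal: an *increase* in the superficial-pyramidal self-inhibition
  can mimic part of the spectral trend that its *decrease* (with
  compensating coupling changes) produces.  Models with condition effects
  are initialised from a preliminary null-model fit, and the study
  protocols add a small deterministic multistart — antithetic pairs of
  jittered initialisations, best fit kept by free energy.  Precision
  annealing (capping the per-iteration growth of $\lambda$) was tried and
  *worsened* mode selection; it is available (`lambda_step`) but off by
  default.

* **Degenerate steps.**  A proposed step that changes the free energy by
  less than $10^{-8}$ in relative terms is treated as a converging
  acceptance without moving — at a stationary point the Gauss-Newton step
  is numerically zero and would otherwise be rejected forever.

Model comparison (`compare_models()`) is fixed-effects: posterior model
probabilities $\propto e^{F_m}$ under a uniform model prior; a log-evidence
difference of 3 corresponds to a likelihood ratio of about 20:1.

# Synthetic data: what it emulates and what it does not

`simulate_csd_dataset()` emulates the study design that motivates the
package: 9 contrast conditions (0-82%), 4 bipolar sites, spectra on 24
frequencies between 4 and 90 Hz, and finite-epoch estimation noise drawn
from the complex Wishart distribution with degrees of freedom equal to the
epoch count (256 by default, i.e. roughly two minutes of 500 ms epochs per
condition).  Wishart sampling — rather than additive Gaussian noise — is
used because it preserves Hermitian positive semidefiniteness and is the
exact sampling distribution of an averaged periodogram of Gaussian data.

The default ground truth (`cmc_truth()`) is a full condition-effect model
chosen once to reproduce the qualitative phenomenology of contrast
experiments: gamma-band peaks at every contrast whose frequency rises
monotonically by about 10 Hz across the design.  Exploration of the prior
landscape showed that the superficial-pyramidal disinhibition
($\beta_{\alpha_{44}} < 0$) *alone* lowers the predicted peak frequency;
the upward shift observed empirically requires the accompanying increases
in the stellate-pyramidal loop couplings ($\alpha_{14}, \alpha_{41}$) and
the extent changes (excitatory decay rates up, inhibitory down) that the
full model provides.  The generating deviations place the low-contrast
peak near 60 Hz and are all within two prior standard deviations.

What passing tests on these data do **not** show: robustness to real-data
features absent from the generator — line noise, artefacts, non-stationary
epochs, departures from the $1/f$ noise form, volume conduction, and real
cortical geometry (the patch is a 1-D ring; the field equations' radial
2-D analogue was deliberately not implemented).  Conclusions about the
monkey data of the motivating study are outside what this package can
establish.

# Stability of the prior-mean circuit

A finding that shapes how the package validates itself: at the tabulated
prior means the linearised field is **dynamically unstable**.  Newton root
scans of the characteristic determinant locate rightmost roots near
$+490 \pm 380i\ \mathrm{s}^{-1}$ at every wavenumber (and $+880$ even with
delays removed), driven by the interneuron/deep-pyramidal feedback loop
whose gain $\gamma^2\kappa_2\kappa_3 D_{23}D_{32}$ exceeds its critical
value $(\kappa_2\kappa_3)^2$ by six orders of magnitude under the published
amplitudes.  No parameter draw within three prior standard deviations is
stable, and no uniform rescaling of the amplitude table yields a stable
system that still resonates in the gamma band — the gamma-band peak of
$|T_4(0,\omega)|^2$ on the real frequency axis is precisely the shadow of
the unstable pole.  None of this affects spectral fitting: the likelihood
only ever evaluates transfer functions on the real axis, where they are
finite and smooth, which is exactly what conventional spectral DCM
implementations do.  But no stationary time-domain process exists at those
parameters, so direct simulation there diverges (and `simulate_field()`
says so rather than returning spurious spectra).

`stable_connectivity()` therefore provides the package's reference regime
for time-domain validation: a coupling table chosen once to sit comfortably
inside the stability region (rightmost roots $\approx -12\,\mathrm{s}^{-1}$
at every wavenumber) while keeping an underdamped gamma resonance
($|T_4(0,\omega)|^2$ peaking near 32 Hz, well above its low-frequency
floor), built by placing the stellate/superficial loop just below its
critical gain and the slow interneuron loop well below its much lower one.

# The time-domain simulator as an independent oracle

`simulate_field()` integrates the delayed stochastic field equations
directly on a ring lattice (128 points by default), with delays rounded to
integration steps (default $dt = 0.1$ ms, so the maximal delay
$\ell\upsilon/2 \approx 42$ ms spans ~417 steps), an exact exponential
propagator for the critically damped synaptic dynamics, an exact
discrete-time covariance for the stochastic input increment, and the first
second discarded as burn-in.  Sites are produced by integrating the
population mixture against periodic-Gaussian electrode weights and applying
the montage.  The simulator shares *no code* with the analytic predictor —
it never forms a transfer function — so agreement of its Welch
cross-spectra (Hann taper, non-overlapping 500 ms segments, two-sided
density per Hz) with `predict_csd()` is the package's strongest
correctness check.

The accuracy budget deserves care.  At $n$ averaged segments the
complex-Wishart sampling distribution of the estimate puts an irreducible
floor under the relative $L_2$ discrepancy,
$\sqrt{\sum_{f,l,m} g_{ll}g_{mm} / (n \sum |g_{lm}|^2)}$ — about 7.6% at
512 epochs for the default sensor geometry (auto-spectra alone would give
$1/\sqrt{512} \approx 4.4\%$, but weakly coherent site pairs contribute
noise without contributing signal norm).  The shipped full-scale check (512
epochs, stable regime, $dt = 5\times10^{-5}$ s — the finer step removes a
$\sim$10% high-frequency bias of the 0.1 ms default) measures about 7%,
at or *below* the floor, i.e. the simulator is statistically indistinguishable
from exact; a 3-bin band-averaged comparison (the Hann taper correlates
neighbouring bins, so averaging shrinks the noise by less than the naive
square root) bounds any systematic bias below 8%.  Agreement is
additionally checked across distinct stable parameter draws at reduced
epoch counts with floor-matched tolerances.

# Problem sizes used in the shipped studies

The validation studies run at deliberately chosen sizes: transfer-function
oracle on 1000 random draws within ±3 prior standard deviations; simulator
comparison with 512 epochs (the acceptance-test setting) or 256 (the
acceptance script); parameter recovery on 10 replicate datasets of 256
epochs fitted with a 16-order wavenumber truncation (indistinguishable
from 32 for these lead fields — the truncation check `adaptive_n_k()`
guards this); model recovery over the four single-factor hypotheses; and
field-versus-mass comparison on spatially structured data.  These sizes
give stable pass/fail behaviour while keeping a full run of the suite in
the tens of minutes on one core.

# Known limitations

* One-dimensional geometry; "rotational symmetry" of receptive fields is
  represented only through distance-dependent kernels on the line.
* Gaussian observation error on spectral estimates (with level weighting)
  rather than the exact Wishart likelihood.
* A single shared noise precision by default (per-condition precisions are
  available but not frequency-resolved ones).
* The Laplace posterior is unimodal by construction; the multistart
  protocol selects a mode but cannot represent genuine multimodality.
* Convolution-based synapses only — no conductance-based variants, gap
  junctions or nonstationary expansion points.
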