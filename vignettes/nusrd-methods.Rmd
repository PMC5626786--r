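---
title: "Models and methods behind nusrd"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind nusrd}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

nusrd simulates and analyses Carr–Purcell–Meiboom–Gill (CPMG) relaxation
dispersion experiments recorded with non-uniform sampling (NUS). This
vignette explains the models the package implements, the assumptions they
rest on, the tunable parameters and their defaults, the numerical choices
made where the design was genuinely open, and what the synthetic-data tests
do and do not demonstrate about real spectra.

## The physical model

A nucleus exchanging between a ground conformation A (population $p_A$) and a
sparsely populated excited conformation B ($p_B = 1 - p_A$) at rate
$k_\mathrm{ex} = k_{AB} + k_{BA}$ relaxes faster than either state alone when
its chemical shift differs between the states by $\Delta\varpi$ (ppm; in
angular units $\Delta\omega = 2\pi\,\Delta\varpi\,\gamma$-scaled by the
nucleus Larmor frequency). A CPMG train of 180° pulses applied at repetition
rate $\nu_\mathrm{cpmg}$ during a constant relaxation delay $T$ progressively
refocuses that exchange contribution, so the effective rate

$$R_{2,\mathrm{eff}}(\nu_\mathrm{cpmg}) = \frac{1}{T}\,
  \ln\frac{I_0}{I(\nu_\mathrm{cpmg})}$$

decays from $R_{2,0} + R_\mathrm{ex}$ toward the intrinsic $R_{2,0}$ as
$\nu_\mathrm{cpmg}$ grows. $I$ and $I_0$ are peak intensities with and
without the relaxation delay. The shape of that dispersion encodes
$k_\mathrm{ex}$, $p_B$ and $|\Delta\varpi|$; CPMG cannot determine the sign
of $\Delta\varpi$, so the package works with magnitudes throughout.

Two evaluators of the two-state model are provided and are deliberately
implemented along different routes:

* `bm_r2eff()` propagates the two-state transverse magnetization through an
  explicit pulse train: free precession under
  $L = \begin{pmatrix}-R_2 - k_{AB} & k_{BA}\\ k_{AB} & -R_2 - k_{BA} +
  i\Delta\omega\end{pmatrix}$ in blocks of $\tau = 1/(4\nu)$, complex
  conjugation at each 180° pulse, $n_{180} = \mathrm{round}(2\nu T/2)\cdot 2$
  pulses in total. The signal is the surviving ground-state component.
* `cr_r2eff()` evaluates the same quantity in closed form from the
  eigenstructure of the two-echo propagator (a Carver–Richards-type
  solution, exact for equal intrinsic rates and finite pulse trains). The
  classical dominant-eigenvalue Carver–Richards expression is its
  $n \to \infty$ limit; at the slow-pulsing end of a 40 ms train the
  transient terms that the classical formula drops contribute several
  percent, which is why the exact form is used for fitting.

Conventions: $\nu_\mathrm{cpmg} = 1/(2\delta)$ with $\delta$ the spacing
between the centres of successive 180° pulses; the ¹H frequency scale is
800.13 MHz at 18.8 T; magnetization starts from the equilibrium populations
and the ground-state component is detected. The ¹⁵N in-phase/anti-phase
relaxation difference is assumed to be equalised by the pulse-sequence
element designed for that purpose, so a pure in-phase two-site model is fit
(no anti-phase relaxation modelling).

## Synthetic multidimensional data

`make_system()` generates per-residue ground truth. The `sh3_like` template
emulates a small folded domain partially bound to a peptide ligand — all
residues share global $(k_\mathrm{ex}, p_B)$ while $|\Delta\varpi|$ varies
per residue — with defaults $k_\mathrm{ex} = 182\,\mathrm{s^{-1}}$,
$p_B = 2.9\%$, $|\Delta\varpi| \sim U(0.2, 3)$ ppm for ¹⁵N and
$173\,\mathrm{s^{-1}}$, $3.6\%$, $U(0.1, 1.2)$ ppm for ¹³CO. The `idp_flat`
template emulates a disordered chain without millisecond exchange: every
dispersion is flat at $R_{2,0}$. Peak positions are drawn inside the
spectral windows with a minimum mutual separation (≥ 3 indirect or ≥ 6
direct grid points) so peaks stay resolvable by grid-maximum readout;
linewidths, intrinsic rates and amplitudes are drawn from realistic ranges
(¹⁵N linewidths 4–9 Hz, $R_{2,0}$ 6–14 s⁻¹).

`synthesize_fid()` builds the time-domain series as a sum of separable,
exponentially damped sinusoids — one factor per dimension, States
quadrature for the indirect dimensions (stored as interleaved cosine/sine
components along each indirect axis). The plane recorded at frequency $\nu$
is the reference plane scaled by $\exp(-R_{2,\mathrm{eff}}(\nu)\,T)$, which
encodes the key structural assumption of the whole analysis: *positions and
line shapes are invariant to the CPMG frequency; only amplitudes change*.
Complex Gaussian noise is added independently per stored point.

The constant relaxation delay defaults to $T = 40$ ms, a typical value for
backbone experiments at this field. The default noise scale
(`noise_sigma = 0.05` against site amplitudes of order one) yields rate
errors of roughly 0.1–0.2 s⁻¹ through the full-sampling pipeline — the
precision scale of a well-recorded series — and was fixed once as a property
of the simulated study.

What the generator does **not** emulate: scalar-coupling evolution
(including the side-chain carbonyl coupling that distorts Asp/Asn ¹³CO
dispersions), off-resonance and finite-pulse effects, phase errors,
baseline and solvent artifacts, temperature or field drift, or non-Lorentzian
lineshapes. Passing tests therefore demonstrate the correctness and
calibration of the processing chain under the stated signal model, not
robustness to every experimental imperfection.

## NUS schedule design

`generate_schedule()` samples (indirect coordinate, CPMG plane) cells
without replacement with density $\propto \exp(-t/t_\mathrm{match})$ over
the indirect evolution time(s) and flat across planes;
$t_\mathrm{match} = 100$ ms by default. Draws for different planes are
independent; a `coupled` mode reuses one indirect point set for all planes.
An `ensure_coverage` option moves cells from the most-covered coordinates so
that every indirect coordinate is sampled in at least one plane — shared-shape
decomposition (below) leaves never-sampled coordinates unconstrained, so full
coverage makes the model identifiable point by point. It is off by default
(the plain exponential/flat design is the reference behaviour) and used where
an analysis needs the identifiability guarantee.

## Spectrum reconstruction

All paths share one per-dimension processing convention: first time-domain
point halved, cosine apodization, zero-filling (×2), FFT, real part. The
synthetic signals are generated phase-aligned so no phase correction is
applied.

**Reference path.** `full_ft()` requires complete sampling and defines the
ground-truth processing against which both NUS reconstructions are tested.

**Co-processed decomposition (co-MDD).** `comdd_fit()` models the *entire*
series jointly:

$$S^{(\nu)} \;=\; \sum_{i=1}^{R} \alpha_i^{(\nu)}\;
  a_i \otimes b_i \;[\otimes\, c_i]$$

with one normalized shape vector per dimension shared by all planes and one
real amplitude per component and plane. The direct dimension is Fourier
transformed first (it is always fully sampled), so $a_i$ live in the
frequency domain and the indirect shapes stay in the hypercomplex time
domain. Fitting is alternating least squares restricted to the sampled
cells; every sub-step is a ridge-regularised linear solve. Choices made
here, in order of consequence:

* **Regularisation.** The nominal weight is $\lambda = 10^{-4}$ with an
  iteration budget of 2000 sweeps. The ridge is applied *relative* to each
  sub-problem's normal matrix ($\lambda\,\mathrm{tr}(G)/R$ added to the
  diagonal) on data normalised to unit RMS, which makes $\lambda$
  scale-invariant and — importantly — suppresses the degenerate growth of
  mutually cancelling component pairs that masked CP decompositions are
  prone to.
* **Update order and normalisation.** Direct shapes, then indirect shapes,
  then amplitudes, one sweep each iteration; shapes renormalised to unit
  norm each sweep with norms absorbed into the amplitudes, signs fixed so
  each shape's largest-magnitude element is positive.
* **Initialisation and restarts.** Direct shapes start from the left
  singular vectors of the observed data matrix; indirect shapes start
  random; amplitudes start at one (they are attenuation factors — a flat
  positive start avoids sign-scrambled stationary points). Two independent
  starts are run by default and the lower-residual fit kept, which repairs
  the occasional component-swapped local optimum.
* **Acceleration.** After each sweep the update is extrapolated along the
  last sweep's direction with a slowly growing step
  ($\beta = \sqrt[3]{it} - 1$) and kept whenever it lowers the residual.
  Masked CP decompositions with near-collinear components cross long
  "swamp" plateaus where plain ALS crawls; the extrapolation cuts those by
  orders of magnitude and is what keeps held-out-cell generalisation tight
  at exchange-broadened peak overlap.
* **Convergence.** Early stop when the relative residual change falls below
  $10^{-9}$.
* **Components.** Default $R$ = expected peaks + 2 spare components for
  noise.

Because the shapes are shared across planes, any distortion a subsample
induces in a peak's reconstructed shape multiplies *all* of its planes
equally and cancels exactly in the intensity ratios that become
$R_{2,\mathrm{eff}}$ — the mechanism behind the method's freedom from
dispersion bias, and the property the NUS-bias tests verify. The residual
limitation is identifiability: an indirect coordinate sampled in no plane
contributes an unconstrained shape entry (driven to zero by the ridge),
which lowers absolute peak heights by that coordinate's apodized weight but
again cancels in the ratios.

**Sparse per-plane reconstruction (IRLS-VE).** `irls_ve_reconstruct()`
treats every (direct frequency, plane) column independently. The unknown is
the real absorptive spectrum on the virtual-echo-doubled grid: extending the
measured time-domain vector conjugate-symmetrically (`virtual_echo()`)
makes its transform real, and for a real spectrum the mirrored measurement
rows are redundant, so the real unknown encodes the extension implicitly.
The sampled points enter as inverse-DFT rows (first point halved and counted
once); one data-independent constraint per dimension family — the
fold-frequency (Nyquist) content is zero — completes the otherwise
rank-deficient operator, so at full sampling the system is square and the
output equals `full_ft()` exactly. Under NUS, iteratively reweighted least
squares drives the solution toward an $\ell_p$-sparse spectrum:
$w_j = (x_j^2 + \epsilon)^{(p-2)/2}$ with $p = 0.5$, $\epsilon$ starting at
$0.1\,\max x^2$ and halved each of the 30 iterations. The exact $p$ and
$\epsilon$ schedule are open choices; these defaults recover isolated peak
heights within ~1% at 25% per-plane sampling on noiseless data, and the
sensitivity of the dispersion analysis to them is bounded by the IRLS-vs-FT
and IRLS-vs-co-MDD comparisons in the test suite.

## Quantification

`extract_intensities()` locates each peak's maximum grid point inside a
search window on the reference plane and reads the *same* grid point on
every plane — the position-invariance assumption again; with a shared
readout point, sub-grid interpolation would only add second-order
corrections, so plain grid maxima are used. `compute_r2eff()` applies the
log-ratio formula with
$\sigma_{R_2} = \sqrt{(\sigma_I/I)^2 + (\sigma_{I_0}/I_0)^2}\,/\,T$ and
flags (rather than drops) non-positive intensities. Repeated CPMG
frequencies are averaged (`average_duplicates()`), with the repeat count
retained so the duplicate-based global error can be scaled per point.

## Error estimation

**Duplicates (classical).** `duplicate_global_error()` pools the RMS
half-difference between duplicate rates over all peaks and repeated
frequencies — one global number, estimating the error of a
duplicate-averaged point; singletons get $\sqrt2$ times that.

**Delete-d jackknife.** `jackknife_errors()` omits $d$ of the $N$ sampled
NUS points per trial (20 trials, $d$ defaulting to 17.5% of $N$ and never
below $\sqrt N$), reconstructs and re-quantifies each trial, and inflates
the spread by $F = \sqrt{N/d}$ — the omitted subsets overlap heavily, so the
raw SD underestimates. Two estimates are reported per peak and plane: the
intensity SD, and the SD of the per-trial rates. The latter is the one used
for fitting weights, because subsampling perturbs a peak's overall
reconstructed scale coherently across planes and that common mode cancels in
the rates; propagating the intensity SDs as if independent would overstate
the rate errors severely.

Calibration against a Monte-Carlo ground truth (independent noise
realizations of the same schedule) shows the inflated jackknife running
somewhat high — of order 10–30% at the simulated problem sizes — with the
excess shrinking as $N$ grows: part is the lower signal-to-noise of the
subsampled spectra, part is coverage churn, which at a few hundred NUS
points is not yet negligible the way it is for full-size experiments.

**Targeted acquisition.** `ta_run()` emulates incremental acquisition:
random nested orderings of the NUS points processed at growing fractions
(3.3% to the available level in 1% steps by default, 15 orderings). The
step-to-step intensity change is the real-time precision estimate. The
previous step is exactly one delete-d resample of the current one, so the
aggregated step difference is up-scaled by the same
$\sqrt{N_s/(N_s - N_{s-1})}$ inflation a multi-trial jackknife would use
(the raw aggregate is kept alongside); RMS aggregation over peaks and planes
keeps both tracks on the SD scale (median aggregation is available for
robustness but sits a factor ~0.67 low on half-normal differences). Below
roughly 5% NUS the reconstruction itself collapses and both tracks shoot up
— visible and expected; the tracks are compared in the stable regime.

## Fitting and significance

`fit_residue()` compares a flat model with an individual two-state fit by
weighted least squares. The intrinsic rate enters the model additively, so
it is profiled out linearly; the nonlinear parameters are optimised by
multi-start Nelder–Mead. The chi-square reduction is tested with an F-test
whose numerator degrees of freedom are the *effective* dimension of the
exchange family near the null: $k_\mathrm{ex}$, $p_B$ and $\Delta\varpi$
trade off along the $p_B\Delta\omega^2$ ridge, so the three raw parameters
buy far fewer than three effective degrees of freedom. A null-calibration
simulation (flat curves, known errors, the default 11-point frequency grid)
puts the effective dof at 1.6; with 3 the test is badly conservative and
with 1 it over-rejects. The calibrated test holds the nominal 1% size
within ±0.5% — the package's significance screen (`significant_peaks()`,
p < 0.01).

`fit_global()` fits all flagged residues jointly: shared
$(k_\mathrm{ex}, p_B)$, per-residue $(|\Delta\varpi|, R_{2,0})$. The outer
optimisation runs Nelder–Mead on $(\log k_\mathrm{ex},
\mathrm{logit}\,p_B)$ from a log-uniform multi-start grid
($k_\mathrm{ex} \in [10, 5000]\,\mathrm{s^{-1}}$, $p_B \in [0.001, 0.2]$,
≥ 10 starts); each inner evaluation profiles every residue's
$|\Delta\varpi|$ by a 1-D line search with $R_{2,0}$ solved linearly.
Uncertainties come from the Gauss–Newton covariance at the optimum; the
strong negative $k_\mathrm{ex}$–$p_B$ correlation (the well-known coupling)
is reported, and boundary-pinned optima are flagged.
`fit_global_resampled()` provides the alternative resampling route —
refitting per trial and summarising the parameter spread.

## Problem sizes used in validation

The package's own validation runs at deliberately small sizes chosen for
single-CPU turnaround: 2D grids of 64×48 complex points with 11 CPMG
frequencies (plus 3 duplicates and a reference plane), 3D grids with 5
frequencies (24×40×40 for the jackknife calibration — about 800 NUS points
at 8.3% — and 24×24×24 for targeted acquisition), 20 noise realizations for
the NUS-bias comparison, 30 Monte-Carlo realizations and 3 jackknifed
datasets for the jackknife calibration, and 4 targeted-acquisition
orderings with 6 jackknife trials per step. The
statistical conclusions (bias below the noise, calibrated error estimates)
are size-stable in the direction that matters: every resampling diagnostic
gets better, not worse, as $N$ grows toward experimental scale.

## Known limitations

* Single static field; multi-field global fits are a configuration
  extension, not implemented.
* In-phase two-site exchange only; no three-state models, no anti-phase
  relaxation, no off-resonance effects.
* $|\Delta\varpi|$ magnitudes only (inherent to CPMG).
* Peak quantification assumes resolvable peaks at known positions; there is
  no peak picking and no lineshape deconvolution of overlaps.
* The time-domain-regularised decomposition variant (smoothing the shapes
  themselves) is noted as an extension and not implemented.
* Maximum-likelihood estimates of $(k_\mathrm{ex}, p_B)$ carry a small
  finite-sample bias along the $p_B\Delta\omega^2$ ridge that grows with the
  estimator's variance. Because sparse sampling roughly doubles that
  variance at 25% NUS, the NUS-branch means can sit around one full-sampling
  SD away from the full-sampling means even when the reconstructed
  dispersion curves themselves are unbiased — an estimator property, not a
  reconstruction artefact.
* At very sparse sampling of small grids (tens of points), jackknife and
  step-difference error estimates run high relative to the noise-only truth;
  this is documented behaviour of the scaled-down regime, not of the method
  at experimental sizes.
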