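---
title: "The Medras model: mechanistic DSB repair, misrepair and cell survival"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{The Medras model: mechanistic DSB repair, misrepair and cell survival}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(medras)
```

## The problem the model addresses

Cells differ widely in their sensitivity to ionizing radiation, and most
predictive models absorb those differences into per-cell-line fitting
parameters (an LQ $\alpha/\beta$, or equivalents), which makes them
descriptive rather than predictive.  Medras instead predicts survival and
its intermediate endpoints — residual double-strand breaks (DSBs), repair
focus kinetics, misrepair, mutation, chromosome aberrations — from a
**minimal radiation phenotype**: genome size, chromosome number, NHEJ and
HR competence, G1-arrest (p53) status, and cell-cycle phase.  All other
parameters are global constants shared by every cell line
(`repair_parameters()`, `survival_parameters()`), so differences between
cell lines emerge mechanistically rather than by refitting.

## Damage induction

DSBs are the primary lesion.  Every radiation quality is assumed to
produce the same yield per unit dose, 5.738 DSB/GBP/Gy (35 DSB/Gy for a
6.1 GBP human cell); what changes with radiation quality is the *spatial
distribution* of those breaks.

* **Photons** (`generate_uniform()`): breaks Poisson in number and
  uniform in a spherical nucleus.
* **Ions** (`generate_track_pattern()`): breaks cluster around track
  trajectories described by a radial energy profile $E(r)$ (energy per
  primary per µm of depth in logarithmic radius bins).  Each bin
  contributes $E(r)\,\ell/E_\mathrm{DSB}$ breaks over a path of length
  $\ell$, where $E_\mathrm{DSB} = 56.5$ keV is the energy that on average
  makes one DSB regardless of how the energy is arranged.
* **External simulations**: damage can be exchanged through a plain-text
  dialect of the Standard for DNA Damage format (`read_sdd()`,
  `write_sdd()`).

$E_\mathrm{DSB}$ ties the nucleus size to the dose calibration: one Gray
deposits $6.2415\,\mathrm{keV}/\mu m^3$ at unit density, so requiring
35 DSB/Gy at 56.5 keV per DSB fixes the nuclear volume and hence
$r_\mathrm{nuc} = 4.23\,\mu m$.  We use the exact physical constant
rather than the convenient rounded coefficient
$r \approx 1.1\,E_\mathrm{DSB}^{1/3}$, which loses a digit.

Track geometry is simplified to central chords: tracks cross the nucleus
through its centre, break radii follow the in-nucleus bin energies,
depths are uniform along the in-sphere extent.  The track-number mean is
normalized with the energy actually deposited *inside* the nucleus, so
the expected DSB yield of the track generator equals the uniform
generator's at every dose exactly — a conservation property the test
suite checks.  The shipped `synthetic_track_profile()` (uniform core plus
$1/r^2$ penumbra) is a labelled synthetic stand-in for track-structure
simulations and is used for tests and qualitative LET scans only.

### Chromosome labels

Breaks carry a chromosome id and a genomic coordinate.  By default the
id comes from a *territory* model — each break takes the chromosome of
the nearest of $n_c$ territory centres drawn once per pattern — so that
nearby breaks tend to share a chromosome, as the analytic
intra-chromosome model assumes.  A position-independent `"uniform"`
assignment is available; with it the stochastic engine necessarily
reports a ~$1/n_c$ intra-chromosome misrepair fraction, which is
inconsistent with the analytic classifier and should only be used when
chromosome identity does not matter.

## Repair kinetics

Repair is two-step: free break ends are physically rejoined at
per-pathway rates, and repair proteins clear from the joined site after
an additional delay.  Physical breaks are what PFGE/PCC assays see; foci
(γH2AX-like) count physical plus protein-bearing joined breaks.

Breaks are simple (probability $1-p_\mathrm{complex}$) or complex.
Simple breaks use fast NHEJ everywhere; complex breaks use slow
processed NHEJ in G0/G1 and HR in S/G2.  In repair-deficient cells a
fraction $p_\mathrm{fail} = 0.74$ of the affected breaks is rescued by
backup MMEJ ("very slow"); the remainder stays on an available slow
route, or never repairs when none exists (e.g. simple breaks in an
NHEJ-null G1 cell).  An optional `long_term_failure_fraction` (0.22 for
the ATM-deficient case) removes breaks from all pathways and produces
the observed plateau in both break and focus curves.

For an acute exposure each compartment is a pure exponential; for
arbitrary dose-rate protocols the compartments obey
$\dot N_x = -\lambda_x N_x + p_x k \dot D(t)$ and
$\dot P_x = \lambda_x N_x - \nu_x P_x$.  Because the forcing is
piecewise constant, `repair_kinetics()` propagates the exact closed-form
solution across segment boundaries and impulses instead of running an
adaptive ODE integrator: there is no discretization error to control,
and the test suite uses an independent ODE solver (deSolve) as the
oracle.  The $\nu_x \to \lambda_x$ degeneracy uses the analytic limit
$N_0 p \lambda t e^{-\lambda t}$ when the rates agree to within
$10^{-9}$ relatively.  MMEJ has no measured clearance rate of its own;
its foci clear at the slow-pathway rate $\nu_s$ by default
(configurable via `nu_m`).  Proliferation during exposure is not
modelled, so protracted predictions describe quiescent or arrested
populations.

## Misrepair

Binary misrepair joins ends from two different DSBs.  The relative rate
for ends $r$ apart is Gaussian, $\zeta(r) = e^{-r^2/2\sigma^2}$ with
$\sigma = 0.0418\,R$, normalized so a break's own two ends interact at
rate 1.

### Analytic route

For uniform patterns the mean pairwise rate is
$\theta(R, \sigma) = \mathbb E[\zeta(r)]$ over the pair-distance density
of a sphere; we derived the closed form symbolically from that
definition (and its $r<r_D$ truncation for deletion sizes) and verify it
against direct quadrature and a $10^7$-pair Monte-Carlo sample, which is
the authoritative check.  For $\sigma > 10R$ the closed form loses
precision to cancellation and the implementation switches to
quadrature.  The per-break interaction rate in an $N$-break pattern is
$\eta = \eta' N$ with $\eta' = 2\theta$ (each partner break has two
ends).

While a population repairs from $N_0$ down to $N_1$ breaks, the expected
correct-repair probability is the interval mean of
$1/(1+\eta+\eta^2)$ — the quadratic term being a first-order correction
for ends orphaned by earlier misrepair — which integrates to an
arctangent closed form (`p_correct_partial()`, with
`p_correct_complete()` the $N_1 = 0$ case).  For protracted or
fractionated protocols `misrepair_analytic()` steps through the exact
kinetics applying the interval form per step (steps bounded at ~5%
repaired each, with step-halving convergence checks); for purely acute
exposures a change of variables makes the per-pathway integrals exact in
a single quadrature.  Intra-track clustering enters as an additive
per-break rate `eta_track()` estimated from sampled intra-track pair
distances, applied uniformly to all breaks of the exposure.

NHEJ and MMEJ additionally carry process fidelity factors
($\mu_\mathrm{NHEJ} = 0.985$, $\mu_\mathrm{MMEJ} = 0.44$) multiplying
the correct-repair probability; HR is fully faithful.  These
"single-hit" infidelity events are tallied separately from binary
events — they are dose-rate independent and linear in dose, and they are
what keeps chronically exposed or NHEJ-deficient cells accumulating
aberrations when binary misrepair vanishes.

### Stochastic route

`mc_repair()` implements the event-driven engine: every free end holds
an exponential clock at its pathway rate scaled by its total interaction
rate with all other free ends; the earliest clock fires, the end picks a
partner with probability $\propto \zeta$, the pair leaves the
simulation, and the affected rates and clocks are refreshed (exact under
memorylessness).  Late-induced breaks are inserted when their time
comes.  Per end we use half the per-break interaction rate, so an
isolated DSB rejoins at exactly $\lambda_x$ — matching the acute
closed form in the sparse limit, which the suite checks by a
Kolmogorov–Smirnov test.

The engine and the closed forms agree exactly where an exact comparison
exists (two co-located DSBs misrepair $2/3$ of breaks by enumeration).
On extended uniform patterns the engine produces systematically *more*
misrepair than the arctangent form — about +3% relative at 2 Gy,
+15% around 10–20 Gy, +9% at 80 Gy — because orphaned ends misrepair
with certainty while the analytic form models them only to first order
in $\eta$.  This is a genuine, reproducible property of the stated event
rules (we confirmed it with a second, independently coded variant of the
engine), not an implementation artefact; the two routes should be read
as agreeing at the 10–15% level, and the acceptance suite records the
comparison at its stricter nominal band accordingly.

## Consequences of misrepair

Each misrepair event (events equal misrepaired breaks: every incorrect
joining consumes one end from each of two breaks) is classified:

* **Intra- vs inter-chromosome** with probability
  $P_\mathrm{intra} = \theta(r_c,\sigma)/(n_c\,\theta(R,\sigma))$, where
  $r_c = R/n_c^{1/3}$ is the spherical-territory radius.  The $1/n_c$
  partner-counting factor is required for the quantity to be a
  probability and is what a territory-resolved simulation measures
  (~0.87 for human geometry); without it the ratio of $\theta$s alone
  exceeds 1.
* **Symmetric vs asymmetric** with equal probability; asymmetric
  inter-chromosome events are dicentrics, asymmetric intra-chromosome
  events are deletions.
* **Deletion size** from the monotone map $D = 2L r^3/R^3$ between
  spatial and genomic separation; $P(D < d)$ is a ratio of truncated
  $\theta$s.  Deletions of 3 MBP or more are counted as lethal.
* **Inter-arm events** (G2 lethality): asymmetric intra-chromosome
  events whose genomic span crosses the centromere, placed midway along
  the chromosome by default, with the span positioned uniformly.  The
  crossing probability given span $s$ is $\min(1, s/(\ell - s))$ for
  chromosome length $\ell$; this construction is our own stated
  assumption, isolated in one function.

`classify_events()` applies identical rules per event to a stochastic
log (sizes mapped from the spatial separations, for consistency with the
analytic route).  `mutation_rate()` adds gene-scale outcomes: structural
mutations when an event's span overlaps a uniformly placed gene
($\,(\mathbb E[s]+g)/L$ per binary event, $g/L$ for point-like process
events), and point mutations from correct in-gene repairs at
$p_\mathrm{mut} = 0.046$.

## Cell death

Three independent mechanisms multiply:

* **Lethal aberrations**: $S = e^{-N_\mathrm{dic} - N_{\mathrm{del}\ge 3}}$
  before replication (G0/G1) and
  $S = e^{-N_\mathrm{dic} - N_\mathrm{interarm}}$ after (S/G2).  The
  classifier is fed *total* misrepair — binary plus process-infidelity
  events.  We adopted this after finding that excluding process events
  makes NHEJ-null cells *more* radioresistant than competent ones at low
  dose (their MMEJ infidelity would have no lethal consequence), the
  opposite of what is observed; it is also what makes chronic-exposure
  aberration yields non-zero.
* **Mitotic catastrophe**: $S = e^{-\phi N_m}$, with $N_m$ the physical
  breaks present when the G2 checkpoint releases, taken as the first
  time the count falls below 20 (release is immediate below threshold;
  an optional fixed delay is configurable; if the unrepairable plateau
  never falls below threshold, the count at the 2000 h horizon is used).
* **Apoptosis**, cycling G1 cells only: $S = e^{-\psi N_{G1}}$ over all
  G1-induced breaks, $\psi_\mathrm{full} = 0.012$ with a functional G1
  checkpoint, $\psi_\mathrm{base} = 0.0007$ otherwise.  Non-cycling
  cells and other phases have no apoptosis term.

S-phase cells follow G2 repair routing and G2 aberration rules but no
apoptosis — the treatment of S is not pinned down by the underlying
model description, and this choice is flagged here.  Asynchronous
populations are convex mixtures over phases (default weights G1 0.6,
S 0.25, G2 0.15 — a generic cycling culture; override via
`phase_fractions`).

At high LET, when a track is expected to contribute more than 0.5 DSBs,
cell-to-cell Poisson fluctuation of track numbers matters:
`predict_survival()` then averages the full response over the track
count $k$ (the $k$ grid is sub-sampled and spline-interpolated on the
log scale when wide, keeping the averaging cheap at a ≲0.1% accuracy
cost).  This averaging is what produces the eventual *turnover* of RBE
at extreme LET.

## Dose response, MID, RBE

`dose_response()` evaluates the pipeline on a dose grid;
`mid()` integrates $\int_0^\infty S(D)\,dD$ (mean inactivation dose),
extending the grid until $S < 10^{-4}$ and adding an exponential-tail
correction, either by adaptive quadrature or — for model curves where
every integrand evaluation is a full pipeline run — by composite
Simpson's rule on a stated grid (~0.1% accuracy).  `mid_lq()` provides
the erfc closed form for LQ inputs, and `rbe_mid()` the
reference-to-test MID ratio.

## Problem sizes and reproducibility

Every stochastic entry point takes a `seed` and restores the caller's
RNG state; `run_pipeline()` derives per-stage sub-seeds from one global
seed by a fixed affine scheme and writes a manifest with config
snapshot, seed and output checksums.  The test suite runs its
Monte-Carlo cross-checks at deliberately moderate sizes — a $10^7$-pair
$\theta$ sample, tens of engine runs per dose at 2–80 Gy, thousands of
runs only for the tiny two-break systems — chosen so the whole suite
completes in minutes while keeping standard errors small relative to
the tolerances asserted.

## What the synthetic data do and do not show

The generators emulate the model's own damage assumptions (uniform
spheres, parametric clustered tracks, idealized territories).  Passing
tests therefore demonstrate internal consistency and correct
implementation of the stated model — not fidelity of any given input to
real track structure or real chromatin geometry.  In particular the
synthetic track profile compresses all energy inside 0.5 µm, which
exaggerates intra-track misrepair relative to measured proton RBE at low
LET; quantitative RBE work should import measured or simulated radial
profiles (`read_track_profile()`) or SDD damage files.

## Known limitations

* The analytic misrepair form underestimates the event process by
  10–15% at intermediate doses (first-order orphan correction only).
* Chromosome territories are equal-size and idealized; karyotype-level
  aberration spectra and complex (3+ break) exchanges are out of scope.
* Proliferation during exposure, checkpoint signalling dynamics, and
  hypoxia are not modelled.
* The inter-arm and centromere construction, S-phase death rules, and
  the MMEJ focus-clearance rate are stated assumptions, each isolated
  behind one function or parameter.
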