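---
title: "Testing sodium-channel dimerization: stoichiometry and coupled-gating analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Testing sodium-channel dimerization: stoichiometry and coupled-gating analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(chancoupler)
```

## The question

Voltage-gated sodium channel α-subunits were long assumed to work as
functional monomers: one gene encodes the whole pseudo-tetrameric pore.
Several lines of electrophysiological evidence challenge that picture —
dominant-negative (DN) mutants that suppress co-expressed wild-type current,
co-expressed mutants that shift each other's gating, and single-channel
records with direct closed-to-double-level transitions. `chancoupler`
implements the quantitative analyses by which such data discriminate
*independent monomers* from *a dimer that assembles and gates as a unit*,
together with simulators that generate data of known ground truth so every
analysis can be validated end to end.

Five analysis families are covered:

1. **Dominant-negative binomial analysis.** If channels assemble randomly
   into n-mers and one DN subunit silences the whole oligomer, the
   normalized current at mutant cDNA fraction $x$ is
   $y = (1-x)^n$. Independent monomers give the linear $n = 1$ curve, a
   dimer $n = 2$, a trimer $n = 3$. `fit_binomial_exponent()` compares the
   observed suppression against these parameter-free curves by weighted
   residual sum of squares and can profile a continuous exponent.
2. **Photobleaching step counting (SiMPull).** A surface-immobilized
   molecule with $n$ GFP-tagged subunits, each fluorescently mature with
   probability $p$, shows $k \sim \mathrm{Binomial}(n, p)$ bleaching steps.
   Dark molecules ($k = 0$) are never spotted, so inference uses the
   zero-truncated distribution
   $P(k \mid n, p, k \ge 1) = \binom{n}{k} p^k (1-p)^{n-k} / (1 - (1-p)^n)$.
   With the commonly used $p \approx 0.7$ for GFP, a dimer is expected to
   show two steps in $p^2 = 49\%$ of all molecules — the "nearly half"
   signature — and `fit_subunit_count()` recovers $n$ by maximum
   likelihood.
3. **Single-channel coupled gating.** Records from a patch holding a
   channel pair are segmented into 0.2-ms windows and each segment labelled
   closed, single-open (O1) or double-open (O2) by nearest amplitude. An
   opening that reaches O2 within two segments (0.4 ms) of its onset is
   classified *coupled* (simultaneous); a double-level event that builds up
   more slowly is *uncoupled stacking* of two independent openings and is
   tallied as two single-level openings.
4. **Whole-cell gating curves.** Activation and steady-state inactivation
   (SSI) follow the two-state Boltzmann function
   $Y = 1/\{1 + \exp[-(V_m - V_{1/2})/k]\}$. When two channel populations
   are co-expressed and function independently, the observed curve must be
   the mixture $w\,Y_a + (1-w)\,Y_b$; `coupling_deviation()` measures how
   far the data sit from that null and which single-population curve they
   track instead. Macroscopic decay is fitted with the standard fast/slow
   biexponential ($\tau_f \le \tau_s$).
5. **FRET.** Crosstalk-corrected FRET,
   $\mathrm{FRET}_c = \mathrm{FRET} - a\,\mathrm{CFP} - b\,\mathrm{YFP}$
   (defaults $a = 0.29$, $b = 0.04$), and the donor-dequenching summary
   after acceptor photobleaching (expected increase $100E/(1-E)$ percent at
   FRET efficiency $E$).

## The gating simulator

`simulate_sweeps()` draws, per sweep, whether the dimer gates as one
concerted unit (probability φ, `coupling_fraction`) or as two independent
protomers. Each protomer follows the minimal scheme with activation and
absorbing fast inactivation,

$$C \underset{k_{OC}}{\overset{k_{CO}}{\rightleftharpoons}} O
  \xrightarrow{k_{OI}} I,$$

simulated event-by-event with exponential waiting times (Gillespie), then
discretized to the sampling grid: a sample carries the state occupying the
majority of its interval. A concerted dimer is a single chain whose open
state conducts $2i$; independent protomers conduct $i$ each. Because both
modes share the same per-protomer law, the *mean* current is identical at
every φ — exactly the property that makes ensemble averages uninformative
about coupling while the O1/O2 event statistics are decisive. Gaussian
noise of SD `noise_sd` is added after discretization.

Defaults are chosen as a plausible cell-attached recording, not as fitted
constants: unitary current $i = -1.5$ pA, noise 0.15 pA RMS, 30 kHz
digitization, 100 sweeps of 50 ms from −100 mV holding. Two kinetic
regimes are used in the validation suite: a "moderate depolarization"
regime $(k_{CO}, k_{OC}, k_{OI}) = (0.05, 0.1, 0.5)\ \mathrm{ms}^{-1}$
(the package default), in which openings are scattered and late so
simultaneity is informative, and a "strong depolarization" regime
$(0.5, 0.1, 2.0)\ \mathrm{ms}^{-1}$ with early clustered openings. No
kinetic scheme is fitted to data anywhere; the simulator exists to give the
classifiers and fitters inputs with known truth. Recovery from
inactivation, voltage-dependent rates, filtering emulation and patches with
more than one dimer are deliberately out of scope.

The photobleaching simulator draws $k \sim \mathrm{Binomial}(n, p)$ active
fluorophores per molecule and independent exponential bleach times (default
rate 0.2 s⁻¹, 0.1-s frames, movie length of eight mean lifetimes so
essentially all bleaching is observed). Traces are monotone staircases plus
Gaussian noise; blinking and background drift are not modelled, matching
the assumption of the step counter. The dose–response and gating-curve
generators evaluate their closed forms and add Gaussian noise.

## What the analyses assume, and the numerical choices

**Level estimation** (`estimate_levels`). The closed baseline is the
dominant mode of the pooled all-points histogram, refined as a local
median; the noise SD is a median absolute deviation whose window is
anchored by a first global pass so it is not truncated when openings are
sparse or absent. Open levels are the two most populated density modes
beyond a 3-SD exclusion band, each refined as the median of its assigned
samples; candidate modes closer than two bands to baseline are rejected as
truncation artifacts of the noise tail, and modes closer than one band to
each other are merged. If only one open level is seen, O2 is extrapolated
as twice O1 under the dimer assumption and flagged — appropriate for fully
coupled records, which never dwell at O1.

**Idealization** (`idealize`). Segment means are assigned to the nearest of
{baseline, O1, O2}; exact ties break toward the lower level; a trailing
partial segment is dropped. The simulator's ground-truth labels for
validation are defined by the same nearest-level rule applied to the
noise-free segment mean. (A per-sample majority definition of truth cannot
agree exactly with any mean-based assignment at segments straddling a
transition: a segment four-sixths closed and two-sixths double-open has
majority "closed" but mean nearest O1. Defining truth through the
noise-free mean keeps the noiseless oracle comparison exact and isolates
the effect of noise.) The 0.2-ms segment is six samples at 30 kHz; the
coupling window of two segments is inclusive — offsets 0, 1 and 2 from
event onset all count as simultaneous, since an offset of two segments is
0.4 ms.

**Step detection** (`detect_steps`). Greedy binary segmentation of a
piecewise-constant model with a BIC stopping rule, followed by a size
filter: only downward jumps of at least `min_step_fraction` (default 0.5)
times the unit step (median downward jump) are counted; upward jumps
(blinking recovery) are ignored. The BIC charges *two* parameters per added
segment — its level and the location of the new change-point — plus one
shared variance. Charging only the level, the textbook count, over-segments
long noisy traces: the best spurious split gain in pure Gaussian noise
grows like $2\log n$ and systematically beats a $\log n$ penalty, which in
validation runs inflated step counts on several percent of traces and
corrupted the median-based unit-step estimate. With the two-parameter
charge, step counts match the truth for over 99% of detectable simulated
dimers, and the remaining errors are dominated by genuinely unresolvable
events — two fluorophores bleaching within a frame or two of each other.
On traces of 30 frames or fewer the greedy search returns the same
segmentation as an exhaustive dynamic-programming search under the same
criterion.

**Subunit-count MLE** (`fit_subunit_count`). $p$ is treated as known
(default 0.7) and held fixed; candidate $n$ runs from the largest observed
step count (the model assigns zero mass below it) to `n_max`, and ties
break toward the smaller $n$. The likelihood conditions on detection
($k \ge 1$); unconditional tallies exist only for simulated populations,
where the dark fraction is known.

**Binomial exponent fit** (`fit_binomial_exponent`). The three candidate
curves have no free parameters, so the comparison is a pure weighted-RSS
(weights $1/\mathrm{sem}^2$ where available) ranking; an optional
continuous exponent is profiled on $[0.5, 5]$ by 1-D minimization.
Normalization to the $x = 0$ reference (mean of replicates) makes the fit
scale-free.

**Boltzmann and decay fits.** Boltzmann fits use Levenberg–Marquardt with
initialization from the data (midpoint voltage at half range; slope from
the 20–80% span divided by 2.2, signed by the monotonic direction). One
signed equation serves both curve kinds: SSI curves carry negative $k$ so
availability falls with depolarization. Decay fits start at the peak
sample, use exponential peeling for initialization (slow tail first, fast
remainder second) with two fallback starts, enforce $\tau_f \le \tau_s$ by
swap, and fall back to a single exponential when the two-component fit
degenerates on a monotone decay. The reversal potential for conductance
transforms can be interpolated from the zero crossing on the depolarized
limb of the I/V curve.

**Conventions.** Sample index 0 is the step onset; segment index 0 the
first full segment; all intervals are half-open. Every generator takes an
explicit integer seed and identical inputs give bit-identical outputs.

## What the validation does and does not show

The test suite checks each analysis against an independent oracle at fixed
seeds: the master-equation (matrix-exponential) solution for occupancy of
the simulated chain (3,000 sweeps), exhaustive change-point search on short
traces, enumerated zero-truncated binomial distributions (10⁵ molecules),
order statistics of exponential bleach times, and closed-form curve
constructions. The coupled-gating contrast is validated on 5,000 sweeps per
condition: with φ = 1 at least 95% of double-level events classify as
coupled; with φ = 0 the coupled fraction matches the classification
computed from the simulator's own ground-truth labels within binomial
error, the level-2 share of openings differs at least three-fold between
conditions, and the two ensemble averages agree within Monte-Carlo error —
the macroscopic signature that coupling changes event structure, not mean
current.

Passing these tests shows the algorithms are correct on data satisfying
their assumptions. It does not show robustness to what real recordings add:
baseline drift, capacitive transients, filter shaping, more than one dimer
per patch, fluorophore blinking, heterogeneous bleach rates (real total
bleach times are over-dispersed relative to the two-exponential
prediction), or expression imbalance in co-transfections (the mixture
weight defaults to 0.5 but is exposed). The classifier assumes exactly one
dimer per record; patches with more channels need upstream exclusion, as in
practice. The paired comparison in `acceptor_photobleach_stat()` is a
two-sided paired t-test by default, with a Wilcoxon option for
non-Gaussian ROI distributions; it returns an NA p-value on degenerate
(constant-difference) input rather than failing.
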