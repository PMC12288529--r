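---
title: "Modelling Mg2+-dependent protein-DNA gate dynamics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling Mg2+-dependent protein-DNA gate dynamics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gatekin)
```

## The system and the model

Type IA topoisomerases relax supercoils and unlink catenanes by cleaving one
DNA strand and passing a second strand through a protein-mediated gate whose
opening is a ~6 nm conformational change, directly observable as a DNA
extension change in magnetic-tweezers experiments. Gate opening and closing
rates depend non-monotonically on Mg2+, peaking near 1 mM, and gate opening
is abolished altogether under Mg2+ depletion (EDTA).

`gatekin` models this behaviour with a salt-bridge-switch kinetic scheme.
The gate coordinate (CLOSED/OPEN) is coupled to the configuration of a
charged network around the acidic triad E454/E457/E458 in domain II:

* `B_CC` — the interdomain, *closed-competent* bridges (E457–R304,
  E454–R408) latch the gate closed;
* `B_OC` — the intradomain, *open-competent* bridge (E457–R447) licenses
  gate opening;
* `APO` — all bridges broken, triad Mg-free;
* `EMG` — bridges broken with Mg2+ bound at the triad.

The chain lives on the 8 product states. Within each gate state, Mg2+
catalyzes bridge disruption (`B_* -> EMG` at `k_cat * mg`, plus a slow
spontaneous channel `B_* -> APO` at `k_break0`), bridges reform from the apo
state (`APO -> B_CC`, `APO -> B_OC`), and Mg2+ exchanges at the triad
(`APO -> EMG` at `k_on * mg`, `EMG -> APO` at `k_off`). The gate opens only
from the open-competent configuration and closes through a fast latched
channel from `B_CC` plus a slow configuration-independent channel
(`k_gate_close0`), which is what lets the 2E2Q mutant keep cycling.

This structure produces the biphasic Mg2+ dependence by construction: at low
Mg2+ bridge *breaking* is rate limiting (`k_cat * mg` small), while at high
Mg2+ bridge *formation* is rate limiting, because the triad is increasingly
parked in the Mg-bound `EMG` state. Mutants are parameter modifiers, not new
topologies: 2E2Q (E454Q/E457Q) removes the Mg site and the interdomain
bridge (`k_on = k_cat = k_form_CC = 0`), so its dynamics are Mg-independent
and survive EDTA; R447G suppresses intradomain bridge formation
(`k_form_OC` scaled by 0.02 — residual rather than zero, since that mutant
retains traces of dynamics at saturating Mg2+ while showing no discernible
opening otherwise).

```{r rates}
ref <- calibrateReference()
scheme <- buildScheme(ref, "WT")
effectiveRates(scheme, c(0.3, 1, 3, 10))
```

## Effective rates, and what a dwell actually measures

The *effective* opening rate is the inverse mean first-passage time (MFPT)
from the latched closed state `(CLOSED, B_CC)` to any OPEN state, and the
effective closing rate the inverse MFPT from `(OPEN, B_OC)` back to CLOSED;
`k_cycle = 1/(1/k_open + 1/k_close)` serves as the activity proxy that
reproduces the falling activity branch between 3 and 10 mM.

Coarse-graining a simulated trajectory to open/closed macro-states does
**not** return exponential dwells at these rates. Open dwells do start at
`(OPEN, B_OC)` (gate opening is the only entry), so their mean is exactly
`1/k_close_eff`. Closed dwells, however, start wherever the gate happened to
close: the unlatched channel drops the chain into `(CLOSED, B_OC)`, which
usually reopens within ~0.1 s. Closed dwells are therefore a strongly
bimodal phase-type mixture of such flickers and long latched dwells, and
their inverse mean exceeds `k_open_eff` — by a factor of ~3 at 0.3 mM for
the reference parameters. `expectedDwellRates()` computes the inverse
macro-dwell means implied by the scheme (closed-dwell entry weighted by the
stationary closing flux); it is the quantity that per-condition
`fitDwellRate()` estimates converge to, and the package's tests verify the
two agree within Monte-Carlo error.

## Calibration

The paper-facing parameter set is defined operationally:
`calibrateReference()` starts from the base rates (`k_on = 10 /mM/s`,
`k_off = 10 /s` — a 1 mM Mg2+ site, `k_cat = 5 /mM/s`, `k_break0 = 0.01 /s`,
bridge formation 5 /s, gate transitions 20 /s with a 2 /s unlatched closing
channel; magnitudes chosen at the scales seen in single-molecule gate
kinetics, since no microscopic constants are tabulated for this system) and
then (i) root-finds `k_cat` so the `k_open_eff(mg)` optimum sits at 1 mM and
(ii) rescales all rates uniformly — which moves no optimum — so the peak
opening rate is 0.5 /s, a typical measured gate rate. Both one-dimensional
problems are solved to 0.1% tolerances; the optimum search runs on a
log-Mg grid over 0.02–50 mM.

## Synthetic data

`simulateStatePath()` is an exact (Gillespie) realization of the chain.
`renderExtensionTrace()` converts a path into what the instrument records:
`extension = amplitude x [gate open] + N(0, noise_sd)` sampled uniformly.
Defaults are the experimental conditions: 6 nm amplitude, 200 Hz, 300 s
traces; the 2 nm noise floor is a choice (the measurement noise is not
printed anywhere) giving SNR 3, typical of bead-tracking at these rates.
`generateDwellDataset()` emits exactly *n* complete open and closed dwells
per Mg2+ condition with first/last (censored) dwells flagged rather than
dropped; the headline study conditions are 61/274/313/58 events at
0.3/1/3/10 mM. `generateHairpinAssay()` reproduces the gate-opening assay
bookkeeping on a 579 bp hairpin (2 nt of ssDNA exposed per stem bp, gate
closing disabled at high force, EDTA modelled as `mg = 0` with
`k_break0 = 0`).

What the generator does *not* emulate: bead-tracking physics and camera
blur, drift, force-extension elasticity, multi-molecule tethers, and any
non-Markovian memory in the gate. Passing tests therefore demonstrate
internal consistency of model, simulation and inference at realistic sample
sizes — not that the scheme is the true mechanism of any particular dataset.

For 2E2Q, simulations start from `(CLOSED, APO)` rather than the latched
state: the interdomain bridge cannot form in that mutant, and starting from
it would (in EDTA) freeze the chain in a state the mutant cannot occupy.

## Trace idealization

`idealizeTrace()` fits a two-state Gaussian hidden-Markov model by
Baum-Welch and decodes with Viterbi (compiled; a median-filter +
half-amplitude threshold method is the fallback). Two numerical choices
matter. First, one-vs-two-state selection is by BIC on the *marginal* HMM
likelihood against a single Gaussian level; hard-assignment likelihoods
always prefer two states, even on pure noise. Second, segments shorter than
`min_dwell_frames` (default 3 frames = 15 ms at 200 Hz, an assumed detection
dead time; the original detection tool's dead time is not stated) are merged
into their neighbours shortest-first, so raising the dead time can only
reduce the dwell count. Boundary dwells are censored and dropped by default.
At SNR 3 the decoder exceeds 99% frame accuracy and recovers the 6 nm
amplitude to within a few hundredths of a nm averaged over ten traces.

## Inference

`fitDwellRate()` is the exponential MLE (`1/mean`) with a seeded
nonparametric bootstrap percentile interval. `fitMgDependence()` fits the
Mg2+ dependence:

* **mechanistic** (default): `k_cat`, `k_off`, `k_form_OC` and a global
  time scale free, all other rates pinned to the reference. Given dwell
  tables it maximizes the full phase-type likelihood of the dwell
  durations. This is a deliberate strengthening over least squares on
  per-condition mean rates: the closed-dwell mixture puts ~25% standard
  error on the mean at the two ~60-event conditions, and a correlated
  (`k_cat`, `k_off`) direction amplifies that into 50–60% median parameter
  error, while the dwell-level likelihood — which sees the flicker fraction
  and both mixture time scales — brings median recovery error below 20%
  at the same sample sizes and keeps the fitted optimum within
  [0.7, 1.1] mM across seeds. With only per-condition estimates available
  the fit falls back to weighted least squares on log rates against
  `expectedDwellRates()` (weights from the bootstrap CIs). Multi-start
  initialization uses a seeded Latin hypercube over two decades around the
  reference values; parameter intervals come from the observed information
  at the optimum; the reported `argmax_mg` is the optimum of the
  *effective* (MFPT) opening-rate curve at the fitted parameters.
* **phenomenological**: the substrate-inhibition-like law
  `k(mg) = k_max (mg/K1) / ((1 + mg/K1)(1 + mg/K2))`, argmax
  `sqrt(K1 K2)`, fitted per rate by Levenberg-Marquardt on log rates. The
  law is invariant under swapping `K1 <-> K2` (with `k_max` rescaled), so
  fits are canonicalized to `K1 <= K2`.

Each fit is AIC-compared against a monotonic saturation null
(`k_max mg/(K1+mg)`): as an exponential-dwell likelihood when dwell data
are present (so the two AICs are computed on the same data), as a
rate-curve fit otherwise. `predictActivityProfile()` maps a fit to the
`k_cycle(mg)` activity proxy.

```{r fit}
dwells <- generateDwellDataset(ref, "WT", mg = c(0.3, 1, 3, 10),
                               n = c(61, 274, 313, 58), seed = 1)
fit <- fitMgDependence(dwells, model = "mechanistic", reference = ref,
                       seed = 1)
fit
predictActivityProfile(fit, c(0.3, 1, 3, 10))
```

## Trajectory analysis

`readTrajectory()` parses multi-MODEL PDB files (one frame per MODEL,
atoms matched by residue number and atom name; inconsistent atom sets are
rejected naming the offenders). `detectSaltBridges()` scores a contact when
the minimum acidic side-chain O to basic side-chain N distance is at or
below 3.2 Å — the conventional side-chain salt-bridge criterion, since the
original detection cutoff is not stated — and is monotone in the cutoff by
construction. `comDistance()` uses unweighted charged-group centroids
(Glu: OE1/OE2/CD; Arg: NH1/NH2/NE/CZ) with mass weighting optional, because
the atom selection behind the published centre-of-mass traces is not
stated. `classifyConfiguration()` implements the four-row truth table over
the canonical E457–R304 / E457–R447 contacts (`mixed` and `none` complete
the table beyond the two depicted pure configurations).
`gateCoordinates()` reports the catalytic tyrosine CA displacement along
(+x, the pulling direction) and orthogonal to the force, and
`correlateConfigOpening()` attributes each increment of the opening
coordinate to the configuration under which it accrued.

`generateSyntheticTrajectory()` builds toy trajectories realizing a
schedule of configurations with contacts at exactly 2.8 Å and broken pairs
at 8.0 Å. Charged groups are collocated pseudo-atom clusters, a deliberate
degeneracy that makes contact and centroid distances coincide exactly;
coordinate jitter separates them when realism matters more than exactness.

## Problem sizes and limitations

The shipped tests run the study at its native scale: experiment-sized dwell
datasets (706 events per state across four Mg2+ conditions), ten 120–300 s
traces at 200 Hz for detection checks, 5000 Monte-Carlo first passages per
variant and concentration for the simulator/MFPT cross-check, 20 replicates
for parameter recovery and 100 for bootstrap coverage.

Known limitations: the scheme is one concrete realization of the
salt-bridge-switch mechanism, with a single Mg2+ affinity shared by the
open and closed gate states; rates are not fitted to any experimental
lifetime table (none is published in numeric form); the dwell likelihood
ignores censored boundary dwells rather than modelling them; and the
idealizer is strictly two-state.
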