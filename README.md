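# gatekin

Kinetic modelling and single-molecule analysis of the magnesium-regulated
protein–DNA gate of type IA topoisomerases.

Type IA topoisomerases pass one DNA strand through a transient break in
another via a protein-mediated gate whose opening is a ~6 nm motion,
measurable one molecule at a time with magnetic tweezers. Gate opening and
closing rates depend *biphasically* on Mg²⁺ — slow at 0.3 mM, maximal near
1 mM, slow again at 10 mM — and opening vanishes under Mg²⁺ depletion.
`gatekin` is for researchers who want to model, simulate and fit that
behaviour quantitatively.

At its core is an 8-state continuous-time Markov model on
{CLOSED, OPEN} × {B_CC, APO, EMG, B_OC}: the gate coordinate coupled to the
salt-bridge configuration of the acidic triad (E454/E457/E458). The
interdomain bridges E457–R304/E454–R408 (`B_CC`) latch the gate closed; the
intradomain bridge E457–R447 (`B_OC`) licenses opening; Mg²⁺ both catalyzes
bridge disruption (`B_* → [E+Mg]`, rate `k_cat·[Mg]`) and sequesters the
apo triad (`APO → [E+Mg]`, `k_on·[Mg]` vs `k_off`). Switching is thus
breaking-limited at low Mg²⁺ and formation-limited at high Mg²⁺, giving an
interior optimum. Effective rates are inverse mean first-passage times,

    k_open_eff(mg)  = 1 / E[T  (CLOSED,B_CC) → OPEN ],
    k_close_eff(mg) = 1 / E[T  (OPEN,B_OC)  → CLOSED ],
    k_cycle = (1/k_open_eff + 1/k_close_eff)⁻¹ ,

and the mutants are parameter modifiers: 2E2Q removes the Mg site and the
interdomain bridge (Mg-independent dynamics, survives EDTA), R447G
suppresses intradomain bridge formation (no opening even with Mg²⁺).

The package covers the full pipeline: exact stochastic (Gillespie)
simulation; synthesis of noisy extension traces (6 nm, 200 Hz), dwell-time
datasets and hairpin-assay results; two-state Gaussian HMM trace
idealization with dwell extraction; per-condition rate MLE with bootstrap
CIs; mechanistic (phase-type dwell likelihood) and phenomenological
biphasic Mg-dependence fitting with AIC model comparison; and salt-bridge /
gate-coordinate analysis of multi-MODEL PDB trajectories.

## Worked example

```r
library(gatekin)

ref <- calibrateReference()          # optimum at 1 mM, 0.5 /s at the peak
scheme <- buildScheme(ref, "WT")
effectiveRates(scheme, c(0.3, 1, 3, 10))
#>   mg_mM k_open_eff_s k_close_eff_s  k_cycle_s
#> 1   0.3   0.32509781      1.463513 0.26600806
#> 2   1.0   0.50000000      1.607146 0.38135610
#> 3   3.0   0.31540982      1.507554 0.26083750
#> 4  10.0   0.07334798      1.317370 0.06947952

## experiment-scale dwell datasets and the end-to-end fit
dwells <- generateDwellDataset(ref, "WT", mg = c(0.3, 1, 3, 10),
                               n = c(61, 274, 313, 58), seed = 1)
fit <- fitMgDependence(dwells, model = "mechanistic", reference = ref,
                       seed = 1)
fit
#> Mg-dependence fit (mechanistic model, variant WT)
#>   fitted opening-rate optimum at 0.993 mM
#>   AIC: fitted 3054 vs monotonic 3655.4 (biphasic preferred)
```

The rate table shows the model's biphasic opening rate (maximal at 1 mM,
4–7× slower at 0.3 and 10 mM) and the falling cycle rate between 3 and
10 mM that mirrors the enzyme's decreasing activity at high Mg²⁺. The fit
recovers the opening-rate optimum at ≈1 mM from dwell data of the
experiment's size, and AIC strongly prefers the biphasic mechanism over a
monotonic saturation null.

A single trace, idealized:

```r
path  <- simulateStatePath(scheme, mg = 3, duration = 300, seed = 1)
trace <- renderExtensionTrace(path, amplitude = 6, noise_sd = 2, seed = 1)
ideal <- idealizeTrace(trace, method = "hmm")
diff(ideal@levels[c("CLOSED", "OPEN")])   # ~6 nm recovered
head(extractDwells(ideal, mg = 3, trace_id = "demo"))
```

A thin command-line wrapper (`inst/scripts/gatekin`) exposes the same
pipeline as `rates`, `simulate`, `detect`, `fit` and `analyze-trajectory`
subcommands; the methods vignette (`vignettes/gate-kinetics.Rmd`) documents
the model, the estimators and the numerical choices.

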