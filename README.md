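# mcellsim

Desk-scale simulation of single-cell and multi-cell signaling networks,
with trend-level validation statistics.

Inflamed tissues and tumor microenvironments are shaped by several cell
types at once: each cell responds both to an added stimulus (LPS through
TLR4, a triacylated lipopeptide through TLR2/1, interferon-γ through its
receptor) and to the chemokines and cytokines its neighbours secrete.
`mcellsim` is for computational biologists who want to build such systems
as explicit, inspectable kinetic models: define a pathway as a typed
species–reaction graph, integrate it as a stiff ODE system, perturb it with
agonist doses or genomic lesions, couple several cell models through a
shared medium (autocrine/paracrine) or staged feed-forward input, and read
out biomarkers as percent change against an unperturbed control network.

## The model in brief

Each reaction contributes flux by one of eight rate laws. The saturating
kinds, with S the substrate, M activators and I inhibitors:

    induced:    v = Vmax · [M]/(Ka+[M]) · [S]/(Km+[S])     (Vmax may be kcat·[E])
    summed:     v = Σ_i Vmax_i · [M_i]/(Ka_i+[M_i]) · [S]/(Km+[S])
    inhibited:  v = Vmax · [S]/(Km+[S]) · Π_j 1/(1+[I_j]/Ki_j)

plus irreversible/reversible mass action `kf·Π[r]^n − kr·Π[p]^n` and
zeroth/first-order synthesis, degradation and secretion. The system
`dx/dt = N v(x)` is integrated with the implicit Radau method to a 64-hour
culture endpoint (reports at 16/32/64 h). Genomic lesions act as
multipliers: oncogene gain-of-function and tumor-suppressor
loss-of-function at the *activity* level, copy-number amplification and
deletion at the *expression* level.

Predicted-versus-observed validation is trend-based: per-marker percent
changes are classified up/down/no-change (dead-band θ = 5%), matches are
tabulated, and the match count k of n is scored with an exact binomial
tail under a null matching probability of 0.5,
`P(X ≥ k) = Σ_{j≥k} C(n,j)/2^n`, reported with its exact rational form.

## Worked example

Compose the shipped three-cell inflammation model (keratinocyte-like,
dendritic-cell-like, T-cell-like; ten chemokine/cytokine markers secreted
into a shared medium), stimulate with LPS, and read out the medium pools:

```r
library(mcellsim)

trio    <- build_inflammation_trio()
model   <- compose_coculture(trio$cells, trio$coupling)
control <- simulate_network(model$network)
lps     <- simulate_network(model$network,
                            perturbation = agonist_dose("LPS", 10))
resp    <- percent_change_readout(control, lps, trio$medium_markers)
resp
#>     marker control perturbed percent_change trend
#> 1   CCL3_m  1.5253     3.711        143.294    up
#> 2   CCL4_m  1.3165     3.224        144.896    up
#> 3   CCL5_m 10.6600    11.618          8.987    up
#> 4   CSF2_m  9.8823    13.009         31.643    up
#> 5  IL12B_m  0.6327     1.750        176.575    up
#> 6   IL1A_m  1.9254     4.049        110.303    up
#> 7    IL6_m  1.9762     4.648        135.208    up
#> 8    IL8_m  2.1744     5.355        146.264    up
#> 9    TNF_m  5.0531     8.742         72.997    up
#> 10 VEGFA_m  1.8294     3.966        116.782    up
```

Every marker rises — strongly where the promoter is far from saturation
(IL12B, +177%), weakly where basal NF-κB already saturates it (CCL5, +9%).
Compare those predictions against a synthetic "observed" panel (jittered
parameters + assay noise, seeded) and score the agreement:

```r
obs <- build_observed_responses(fixture_spec("inflammation_trio", seed = 17))
pred <- setNames(resp$percent_change, sub("_m$", "", resp$marker))
tabulate_matches(pred, setNames(obs$percent_change, obs$marker))
#> 9/10, 90%, p_one = 0.01074 (= 11/1024), p_two = 0.02148
```

Nine of ten marker trends agree (the noisy CCL5 observation lands inside
the dead-band); under a fair-coin null that agreement has one-sided
p = 11/1024 ≈ 0.011 — unlikely to be chance.

A command-line wrapper covers the same ground from a shell
(`inst/cli/mcsim.R`, subcommands `simulate`, `trendmatch`, `fixture`,
`validate`; exit codes 0/2/3 for success / configuration error / solver
failure), and every run emits a resolved config from which it replays
bit-identically.

## Package layout

- `R/network_model.R` — species/reaction/network types, YAML dialect,
  validation, exact-arithmetic moiety detection
- `R/ode_engine.R` — rate laws, derivative assembly, Radau integration,
  percent-change readout
- `R/perturbation.R` — agonist dosing, mutation/CNV semantics, predictor
  consensus
- `R/multicell.R` — medium-coupled co-culture composition and staged
  feed-forward runs
- `R/trend_stats.R` — trend classification, match tabulation, exact
  binomial test
- `R/fixtures.R` — the four seeded example systems
- `R/sbml.R`, `R/cli_io.R` — SBML L3 interchange; run configs and file I/O
- `vignettes/multicell-signaling.Rmd` — the methods vignette: model,
  assumptions, parameter choices, limitations
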