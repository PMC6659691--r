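---
title: "Modeling multi-cell signaling and validating biomarker trends"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modeling multi-cell signaling and validating biomarker trends}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mcellsim)
```

## The model

`mcellsim` treats a signaling pathway as a typed species–reaction graph: the
species (ligands, receptors, G-protein complexes, kinases, transcription
factors, secreted markers) are the state variables $x$ of an ODE system, and
each reaction contributes flux according to one of eight rate-law kinds.
With $S$ the substrate, $M$ an activating modifier ("inducer"), $I_j$
inhibitors and $E$ a catalysing enzyme:

* **Inducer-gated Michaelis–Menten** (`smm_induced`):
  $v = V_{max}\,\frac{[M]}{K_a+[M]}\,\frac{[S]}{K_m+[S]}$. The inducer term
  is a saturating occupancy — the simplest algebra using exactly the
  parameters $K_a$, $K_m$, $V_{max}$. When the step is enzyme-catalysed
  rather than ligand-induced, $V_{max}$ is supplied as
  $k_{cat}[E]$ and the occupancy term is dropped, giving classic
  single-substrate Michaelis–Menten kinetics.
* **Summed Michaelis–Menten** (`smm_summed`): when several activators drive
  one step (the PI3K node activated by both GAB2 and IRS2), each activator
  contributes an independent saturating term and the fluxes add:
  $v = \sum_i V_{max,i}\,\frac{[M_i]}{K_{a,i}+[M_i]}\,\frac{[S]}{K_m+[S]}$.
  Additivity is exact by construction and is asserted in the tests.
* **Inhibited Michaelis–Menten** (`smm_inhibited`): noncompetitive
  inhibition, $v = V_{max}\,\frac{[S]}{K_m+[S]}\prod_j \frac{1}{1+[I_j]/K_{i,j}}$.
  The single-parameter noncompetitive form is the minimal extension that
  lets inhibitory arms (a G$\alpha_i$ subunit acting on adenylyl cyclase,
  IL-10 acting on dendritic-cell maturation) be expressed without new
  mechanism.
* **Mass action**, irreversible and reversible:
  $v = k_f\prod_r [r]^{n_r} - k_r\prod_p [p]^{n_p}$, used for complex
  assembly, receptor deactivation, G-protein reassociation and STAT1
  dimerization.
* **Synthesis, degradation, secretion**: zeroth- and first-order boundary
  fluxes. Synthesis is scaled by the product's `expression_scale`;
  secretion moves mass from a cell into the shared medium, scaled by the
  cell:medium volume ratio so that volume-weighted moles are conserved.

Every species carries two dimensionless multipliers. `expression_scale`
multiplies initial amounts and synthesis fluxes (copy-number semantics);
`activity_scale` multiplies fluxes the species catalyses, i.e. those where
it is declared as an enzyme modifier (gain/loss-of-function semantics).
Modifiers never carry mass flux.

## Integration and readout

The systems are stiff — saturating rate laws next to fast binding steps —
so integration uses the implicit Radau method (`deSolve::radau`) at
`rtol = 1e-6`, `atol = 1e-9`. The default endpoint is **64 hours** with
reports at 16, 32 and 64 h, mirroring a typical agonist-exposure culture
protocol. Readouts are taken at the 64 h culture endpoint regardless of
whether a numerical steady state was reached; `steady_state_reached`
(infinity-norm of the derivative below `1e-8 / h`, relative) is reported
but not required. Reporting both was considered and rejected as redundant:
the endpoint is the measurable quantity.

Biomarker responses are percent change versus the unperturbed control
network, $100\,(x_{pert}-x_{ctrl})/x_{ctrl}$. When the control endpoint
sits at or below the floor $\varepsilon = 10^{-9}$ a.u. — legitimate for
inducible markers, and true of the GPCR fixture's cAMP — the percent is
reported as undefined and the trend falls back to the sign of the absolute
difference with dead-band $\varepsilon$.

## Perturbations

Agonists resolve by name against a network's input ports and set the
mapped ligand's initial amount to dose × conversion (default 1 a.u. per
µg/ml); a zero dose leaves the network identical to the control.

Genomic lesions arrive as records carrying external predictor calls and
copy-number states; the effect-prediction algorithms themselves are
published third-party tools and are consumed as input, never run. The
consensus rule is: a curated effect-library hit wins outright; otherwise a
strict majority over the non-unknown predictor calls; ties and empty call
sets yield `unknown`, which is reported and applied as a no-op. Deleterious
oncogene lesions multiply `activity_scale` by the gain factor (default 2),
deleterious tumor-suppressor lesions by the loss factor (default 0);
amplifications multiply `expression_scale` by the amplification factor
(default 2) and deletions zero it. The *directions* are the modeled claim;
the magnitudes are configurable policy with deliberately simple defaults,
surfaced in every report.

## Multi-cell composition

`compose_coculture` concatenates per-cell state vectors (namespaced
`cell.species`) and appends a well-mixed medium compartment with no
transport delay — the models are compartmental, not spatial. Secretions are
first-order fluxes into the medium; medium species may degrade. The default
uptake mode, `as_modifier`, lets a target cell *sense* a medium species
without consuming it: wherever the cell's input ligand appears as a
modifier, the medium species is appended as an additional modifier with the
ligand's own kinetic constants (promoting inducer-gated steps to the summed
form). This reduces exactly to the isolated cell when the medium is empty,
which is why decoupling (all secretion rates zero) reproduces single-cell
endpoints — a structural identity asserted at tight solver tolerances
(`rtol = 1e-10`, `atol = 1e-12`) so that integration error stays well below
the 1e-8 band being checked. Consumptive uptake is available as
`as_transport`.

`run_feedforward` is the staged alternative: sources are simulated to their
endpoint, the resulting medium concentrations are clamped as constant
inputs on the target's ports, and the target is simulated against a control
fed by *unperturbed* sources. Whether a published multi-cell prediction
used full bidirectional coupling or staging is often unknowable from the
outside; both modes are first-class here, and the tests assert that they
agree on target trends for the shipped myeloma → dendritic-cell fixture.

## Trend statistics

Trends classify percent changes with a dead-band $\theta$ (default 5%,
boundary inclusive): `up`, `down`, `no_change`. $\theta$ is a package
choice — published trend tables draw arrows without stating a threshold —
and is surfaced in every report. Predicted and observed labels are matched
under strict equality (`no_change` matches only `no_change`; how a flat
prediction against a moving observation "should" score is genuinely open,
and strict equality is the conservative rule). The match count is scored
with an exact binomial tail under a null matching probability of 0.5:
$P(X \ge k) = \sum_{j=k}^{n}\binom{n}{j}p_0^j(1-p_0)^{n-j}$, summed with
exact integer coefficients; under $p_0 = 1/2$ the exact rational form
(integer over $2^n$) is reported alongside. The two-sided value is
$2\min(P(X\ge k), P(X\le k))$ capped at 1 — the doubling convention, chosen
because it is the convention consistent with the printed two-sided value
for 9 matches of 10 ($2 \cdot 11/1024 = 0.02148$). Both conventions are
implemented and always labeled; no attempt is made to reconcile reports
that mix them. The naive multi-cell expectation (`expected_trend_sum`) is
the exact arithmetic sum of single-culture magnitudes, classified with the
same dead-band.

## The fixtures: what they emulate, and what they do not

No kinetic parameters are published for the pathways these fixtures
portray, and the full curated network library behind such platforms is
proprietary. The fixtures therefore carry invented, frozen, documented
parameters, and the tested contracts are *directional and structural*:
activation raises cAMP and the inhibitory arm tempers it; STAT1
dimerization is dose-monotone; summed fluxes add exactly; conserved
moieties stay conserved; heavier immunosuppressive lesion loads secrete
more IL-10/IL-6/VEGFA/PD-L1 and inhibit all five dendritic-cell maturation
markers more strongly. Passing tests demonstrate that the machinery
faithfully implements those mechanisms — not that any particular magnitude
would reproduce a wet-lab measurement.

* `gpcr_camp` — PGE2 drives PTGER4 (activation, via G$\alpha_s$) and GPR44
  (inhibition, via G$\alpha_i$) converging on adenylyl cyclase; closed
  receptor and G-protein cycles give six conserved moieties, found by exact
  integer null-space elimination on the mass-action submatrix and confirmed
  against every conversion reaction (restricting to mass-action species
  avoids spurious unit-vector "moieties"; confirming against conversions
  guarantees trajectory constancy once boundary fluxes are disabled).
* `ifng_stat1` — IFN-γ receptor/JAK assembly (mass action), FYN → GAB2/IRS2,
  a two-activator summed PI3K node, IKK-mediated NF-κB translocation, and
  STAT1 activation/dimerization. STAT1 and NF-κB pools have explicit
  turnover so endpoints are monotone functions of dose rather than
  transients of drainable reservoirs.
* `inflammation_trio` — keratinocyte-, dendritic- and T-cell-like models
  with distinct receptor complements (the T cell carries no LPS receptor
  and is recruited through paracrine IL-1α/TNF), an NF-κB hub, and the ten
  inflammation markers secreted into a shared medium. Cytokine receptors
  are desensitized (high $K_a$) relative to the TLR arms so the autocrine
  loop amplifies agonist responses without self-igniting, and marker
  promoters saturate at different NF-κB occupancies so responses are
  heterogeneous. Synthetic "observed" tables come from re-simulating with
  log-uniformly jittered parameters (×[1/3, 3]) plus multiplicative
  log-normal noise (σ = 0.2) on the response ratio, emulating an
  independent laboratory's cells and immunoassay replicate spread. Real
  immunoassay data would additionally carry detection floors, marker
  cross-talk and time-dependent noise that this generator does not model.
* `mm_dc_pair` — a generic myeloma cell with constitutive RAS/STAT3/MYC
  driver activities, two genomic profiles (a heavier, U266B1-like lesion
  load versus a lighter, MM.1S-like one), and a dendritic-cell target whose
  maturation markers are noncompetitively inhibited by sensed IL-10,
  TGF-β1 and IL-6. IL-6 and VEGFA production carry both RAS- and
  STAT3-driven arms so the two profiles separate strictly on all four
  contrasted markers. The precursor pool is buffered stiffly so production
  arms compete only weakly for substrate.

All fixture builders are RNG-free unless jitter is requested, and every
random draw runs under a locally scoped seed, so fixture output is
byte-identical per `(name, seed)`.

## Numerical choices and degenerate inputs

* Solver probes may dip infinitesimally negative; flux evaluation clamps
  state at zero and the public flux API rejects concentrations below
  −`atol`. Non-finite states abort with a state error carrying the time.
* Stoichiometries are positive integers; moiety arithmetic is exact
  (integer/rational elimination), so conservation tests are not at the
  mercy of floating-point rank decisions.
* Parsing is total: a document either yields a network whose invariants
  hold or a located error naming the offending key or species; unknown
  keys are rejected; species declaration order defines the state vector,
  making trajectories reproducible and diffable.
* Validation is a reporting operation. Reachability treats input ports and
  constitutive synthesis products as roots and propagates through
  substrate/activator/enzyme edges only — inhibitor arms do not transmit
  activating signal, so a marker whose only connection to its inputs is
  inhibitory is *not* thereby reachable.
* SBML Level 3 export writes genuine structure (compartments, species,
  reactions, explicit MathML kinetic laws over local parameters) for other
  tools; re-import reads the embedded canonical network annotation, which
  makes the round trip lossless and trajectory-identical.

## Problem sizes

The shipped models are deliberately desk-scale: 14–27 species per cell, a
76-dimensional composed three-cell system, 64-hour horizons. The full test
suite, including every co-culture simulation, runs in about a minute on a
single core; the acceptance script in a few seconds.

## Known limitations

Stochastic (SSA) simulation, spatial transport, cell proliferation and
death, and parameter estimation from data are out of scope. Kinetic
parameters are curated constants, not fitted quantities; the machine-learnt
parameterization used by proprietary platforms has no public description to
reimplement. The effect-prediction consensus uses an unweighted strict
majority because no weighting scheme is published; each lesion's resolution
is recorded in the application report so alternative policies can be
audited.
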