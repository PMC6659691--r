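## Tiny networks built in code for unit tests.

## one species with constant synthesis and first-order decay:
## dX/dt = k0 - kd * X, analytic steady state k0/kd
synth_deg_net <- function(k0 = 2, kd = 0.5, x0 = 0) {
  pathway_network(
    "toy",
    list(species("X", role = "metabolite", compartment = "cell:toy",
                 initial_amount = x0)),
    list(reaction("r_syn", "synthesis", products = c(X = 1),
                  params = list(kf = k0)),
         reaction("r_deg", "degradation", c(X = 1), params = list(kf = kd))),
    output_markers = "X")
}

## irreversible homodimerization 2 A -> D
dimer_net <- function(kf = 0.2, a0 = 3) {
  pathway_network(
    "dim",
    list(species("A", role = "tf_active", compartment = "cell:dim",
                 initial_amount = a0),
         species("D", role = "tf_active", compartment = "cell:dim",
                 initial_amount = 0)),
    list(reaction("r_dim", "mass_action_irrev", c(A = 2), c(D = 1),
                  params = list(kf = kf))),
    output_markers = "D")
}

## minimal secreting cell for medium mass-bookkeeping checks
secreting_cell <- function(cell_id = "sec", m0 = 10) {
  pathway_network(
    cell_id,
    list(species("M", role = "secreted_marker",
                 compartment = paste0("cell:", cell_id),
                 initial_amount = m0)),
    list(reaction("r_hold", "degradation", c(M = 1),
                  params = list(kf = 1e-12))),  # keeps M referenced
    output_markers = "M")
}

minimal_doc <- '
cell_id: mini
species:
  - {id: L, role: ligand, compartment: "cell:mini", initial_amount: 0}
  - {id: M, role: secreted_marker, compartment: "cell:mini", initial_amount: 0}
reactions:
  - id: r1
    kind: synthesis
    products: [{species: M, stoich: 1}]
    params: {kf: 1}
inputs:
  - {species: L, agonist: LIG}
outputs: [M]
'

strip_kinds <- function(net, kinds = c("synthesis", "degradation", "secretion")) {
  net$reactions <- Filter(function(r) !r$kind %in% kinds, net$reactions)
  net
}

panel_path <- function(f) system.file("extdata", f, package = "mcellsim")

`%||%` <- function(a, b) if (is.null(a)) b else a
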