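## Seeded, self-contained example models. Kinetic parameters here are
## curated for the fixtures (no published values exist for these steps);
## the directional behaviour of each pathway, not the magnitudes, is the
## tested contract. A seeded log-uniform jitter perturbs parameters for
## property tests and for generating synthetic "observed" data.

MARKER_HALFLIFE_KD <- log(2) / 8   # 8 h half-life on secreted markers

#' Fixture specification
#'
#' @param name One of `"gpcr_camp"`, `"ifng_stat1"`, `"inflammation_trio"`,
#'   `"mm_dc_pair"`.
#' @param seed Integer seed driving jitter and synthetic-noise draws.
#' @param jitter Apply log-uniform parameter jitter (off by default; the
#'   canonical fixture is fully deterministic and RNG-free).
#' @param jitter_range Multiplicative factor range, default `c(1/3, 3)`.
#' @param noise_sigma Log-normal sd for synthetic observed responses.
#' @return An object of class `"fixture_spec"`.
#' @export
fixture_spec <- function(name = c("gpcr_camp", "ifng_stat1",
                                  "inflammation_trio", "mm_dc_pair"),
                         seed = 1L, jitter = FALSE,
                         jitter_range = c(1 / 3, 3), noise_sigma = 0.2) {
  name <- match.arg(name)
  structure(list(name = name, seed = as.integer(seed), jitter = jitter,
                 jitter_range = jitter_range, noise_sigma = noise_sigma),
            class = "fixture_spec")
}

## run expr under a local RNG state so fixtures never disturb the caller's
with_local_seed <- function(seed, fn) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  fn()
}

#' Jitter a network's kinetic parameters log-uniformly
#'
#' Multiplies every kinetic constant (`Vmax`, `Km`, `Ka`, `Ki`, `kcat`,
#' `kf`, `kr`) by an independent factor drawn log-uniformly from `range`.
#' Deterministic for a given seed.
#'
#' @param net A `pathway_network`.
#' @param seed Integer seed.
#' @param range Factor range, default `c(1/3, 3)`.
#' @return A jittered copy of `net`.
#' @export
jitter_parameters <- function(net, seed, range = c(1 / 3, 3)) {
  with_local_seed(seed, function() {
    for (i in seq_along(net$reactions)) {
      p <- net$reactions[[i]]$params
      for (nm in intersect(names(p), c("Vmax", "Km", "Ka", "Ki", "kcat", "kf", "kr")))
        p[[nm]] <- p[[nm]] * exp(stats::runif(length(p[[nm]]),
                                              log(range[1]), log(range[2])))
      net$reactions[[i]]$params <- p
    }
    net
  })
}

maybe_jitter <- function(net, spec) {
  if (isTRUE(spec$jitter)) jitter_parameters(net, spec$seed, spec$jitter_range)
  else net
}

## ---- GPCR / cAMP fixture ---------------------------------------------------

#' Build the GPCR cAMP fixture
#'
#' A prostaglandin-driven G-protein-coupled-receptor pathway with an
#' activation arm (PGE2 -> PTGER4 -> Gs -> adenylyl cyclase -> cAMP) and an
#' inhibition arm (PGE2 -> GPR44 -> Gi noncompetitively inhibiting the
#' ATP -> cAMP conversion). Receptor deactivation and G-protein
#' reassociation close the receptor and G-protein moiety cycles, so the
#' fixture carries testable conservation invariants. Output marker: cAMP.
#'
#' @param spec A [fixture_spec()] (name `"gpcr_camp"`).
#' @return A `pathway_network` with cell id `"gpcr"`.
#' @export
build_gpcr_fixture <- function(spec = fixture_spec("gpcr_camp")) {
  cmp <- "cell:gpcr"
  sp <- list(
    species("PGE2", "prostaglandin E2", "ligand", cmp, 0),
    species("PTGER4", "PGE2 receptor EP4", "receptor", cmp, 10, gene = "PTGER4"),
    species("PTGER4_act", "active EP4", "receptor_active", cmp, 0, gene = "PTGER4"),
    species("GPR44", "PGD2 receptor CRTH2", "receptor", cmp, 10, gene = "PTGDR2"),
    species("GPR44_act", "active CRTH2", "receptor_active", cmp, 0, gene = "PTGDR2"),
    species("GDP_GNAS_GNBC", "inactive Gs trimer", "g_protein_complex", cmp, 20),
    species("GDP_GNAI_GNBC", "inactive Gi trimer", "g_protein_complex", cmp, 20),
    species("GTP_GNAS", "active Gs alpha", "subunit", cmp, 0, gene = "GNAS"),
    species("GTP_GNAI", "active Gi alpha", "subunit", cmp, 0, gene = "GNAI1"),
    species("GNBC", "G beta-gamma", "subunit", cmp, 0),
    species("ADCY1", "adenylyl cyclase 1", "enzyme", cmp, 10, gene = "ADCY1"),
    species("ADCY1_act", "active adenylyl cyclase", "enzyme_active", cmp, 0,
            gene = "ADCY1"),
    species("ATP", "ATP pool", "metabolite", cmp, 1000),
    species("cAMP", "cyclic AMP", "secreted_marker", cmp, 0))
  rx <- list(
    reaction("r_ptger4_act", "smm_induced", c(PTGER4 = 1), c(PTGER4_act = 1),
             c(PGE2 = "activator"), list(Vmax = 5, Ka = 2, Km = 5),
             provenance = "PMID:0000001"),
    reaction("r_gpr44_act", "smm_induced", c(GPR44 = 1), c(GPR44_act = 1),
             c(PGE2 = "activator"), list(Vmax = 3, Ka = 4, Km = 5)),
    reaction("r_gnas_act", "smm_induced", c(GDP_GNAS_GNBC = 1),
             c(GTP_GNAS = 1, GNBC = 1), c(PTGER4_act = "activator"),
             list(Vmax = 8, Ka = 1, Km = 10)),
    reaction("r_gnai_act", "smm_induced", c(GDP_GNAI_GNBC = 1),
             c(GTP_GNAI = 1, GNBC = 1), c(GPR44_act = "activator"),
             list(Vmax = 4, Ka = 1, Km = 10)),
    reaction("r_adcy_act", "smm_induced", c(ADCY1 = 1), c(ADCY1_act = 1),
             c(GTP_GNAS = "activator"), list(Vmax = 6, Ka = 2, Km = 5)),
    reaction("r_camp", "smm_inhibited", c(ATP = 1), c(cAMP = 1),
             c(ADCY1_act = "enzyme", GTP_GNAI = "inhibitor"),
             list(kcat = 2, Km = 50, Ki = 5)),
    reaction("r_ptger4_deact", "mass_action_irrev", c(PTGER4_act = 1),
             c(PTGER4 = 1), params = list(kf = 0.5)),
    reaction("r_gpr44_deact", "mass_action_irrev", c(GPR44_act = 1),
             c(GPR44 = 1), params = list(kf = 0.5)),
    reaction("r_gnas_reassoc", "mass_action_irrev", c(GTP_GNAS = 1, GNBC = 1),
             c(GDP_GNAS_GNBC = 1), params = list(kf = 0.2)),
    reaction("r_gnai_reassoc", "mass_action_irrev", c(GTP_GNAI = 1, GNBC = 1),
             c(GDP_GNAI_GNBC = 1), params = list(kf = 0.2)),
    reaction("r_adcy_deact", "mass_action_irrev", c(ADCY1_act = 1),
             c(ADCY1 = 1), params = list(kf = 0.5)),
    reaction("r_camp_deg", "degradation", c(cAMP = 1),
             params = list(kf = MARKER_HALFLIFE_KD)))
  net <- pathway_network("gpcr", sp, rx,
                         input_ports = data.frame(species = "PGE2",
                                                  agonist = "PGE2"),
                         output_markers = "cAMP")
  maybe_jitter(net, spec)
}

## ---- IFNG / JAK-STAT fixture -----------------------------------------------

#' Build the interferon-gamma JAK/STAT fixture
#'
#' Ligand-induced receptor activation (IFNG as inducer of the assembled
#' IFNGR-JAK complex), FYN-mediated adapter activation, a summed-flux
#' PI3K node driven by two activators (GAB2 and IRS2, each contributing an
#' independent saturating term), IKK-mediated NF-kB nuclear translocation,
#' and STAT1 activation with irreversible mass-action dimerization.
#' Receptor-complex assembly and STAT1 dimerization are irreversible mass
#' action; every activation step is inducer-gated Michaelis-Menten.
#' Output markers: STAT1_dimer and nuclear NF-kB.
#'
#' @param spec A [fixture_spec()] (name `"ifng_stat1"`).
#' @return A `pathway_network` with cell id `"ifng"`.
#' @export
build_ifng_fixture <- function(spec = fixture_spec("ifng_stat1")) {
  cmp <- "cell:ifng"
  inact <- function(id, name, role, amt, gene = NULL)
    species(id, name, role, cmp, amt, gene = gene)
  sp <- list(
    inact("IFNG", "interferon gamma", "ligand", 0, "IFNG"),
    inact("IFNGR1", "IFNG receptor alpha chain", "receptor", 10, "IFNGR1"),
    inact("IFNGR2", "IFNG receptor beta chain", "receptor", 10, "IFNGR2"),
    inact("JAK1", "Janus kinase 1", "kinase", 10, "JAK1"),
    inact("JAK2", "Janus kinase 2", "kinase", 10, "JAK2"),
    inact("IFNGR1_JAK1", "receptor alpha-JAK1 complex", "receptor", 0),
    inact("IFNGR2_JAK2", "receptor beta-JAK2 complex", "receptor", 0),
    inact("IFNGR_JAK", "assembled receptor-JAK complex", "receptor", 0),
    inact("IFNGR_JAK_act", "ligand-bound active receptor complex",
          "receptor_active", 0),
    inact("FYN", "FYN kinase", "kinase", 10, "FYN"),
    inact("FYN_act", "active FYN", "kinase", 0, "FYN"),
    inact("GAB2", "GAB2 adapter", "adapter", 10, "GAB2"),
    inact("GAB2_act", "active GAB2", "adapter", 0, "GAB2"),
    inact("IRS2", "IRS2 adapter", "adapter", 10, "IRS2"),
    inact("IRS2_act", "active IRS2", "adapter", 0, "IRS2"),
    inact("PIK3CA", "PI3K catalytic subunit", "kinase", 10, "PIK3CA"),
    inact("PIK3CA_act", "active PI3K", "kinase", 0, "PIK3CA"),
    inact("CHUK", "IKK alpha", "kinase", 10, "CHUK"),
    inact("CHUK_act", "active IKK alpha", "kinase", 0, "CHUK"),
    inact("IKBKB", "IKK beta", "kinase", 10, "IKBKB"),
    inact("IKBKB_act", "active IKK beta", "kinase", 0, "IKBKB"),
    inact("IKK", "CHUK-IKBKB complex", "kinase", 0),
    inact("NFKB_cyt", "cytosolic NF-kB", "transcription_factor", 10, "NFKB1"),
    inact("NFKB_nuc", "nuclear NF-kB", "tf_active", 0, "NFKB1"),
    inact("STAT1", "STAT1", "transcription_factor", 10, "STAT1"),
    inact("STAT1_act", "phosphorylated STAT1", "tf_active", 0, "STAT1"),
    inact("STAT1_dimer", "STAT1 homodimer", "tf_active", 0, "STAT1"))
  rx <- list(
    reaction("r_r1j1", "mass_action_irrev", c(IFNGR1 = 1, JAK1 = 1),
             c(IFNGR1_JAK1 = 1), params = list(kf = 0.05)),
    reaction("r_r2j2", "mass_action_irrev", c(IFNGR2 = 1, JAK2 = 1),
             c(IFNGR2_JAK2 = 1), params = list(kf = 0.05)),
    reaction("r_assemble", "mass_action_irrev",
             c(IFNGR1_JAK1 = 1, IFNGR2_JAK2 = 1), c(IFNGR_JAK = 1),
             params = list(kf = 0.05)),
    reaction("r_rc_act", "smm_induced", c(IFNGR_JAK = 1), c(IFNGR_JAK_act = 1),
             c(IFNG = "activator"), list(Vmax = 6, Ka = 2, Km = 5)),
    reaction("r_fyn", "smm_induced", c(FYN = 1), c(FYN_act = 1),
             c(IFNGR_JAK_act = "activator"), list(Vmax = 4, Ka = 1, Km = 5)),
    reaction("r_gab2", "smm_induced", c(GAB2 = 1), c(GAB2_act = 1),
             c(FYN_act = "activator"), list(Vmax = 4, Ka = 1, Km = 5)),
    reaction("r_irs2", "smm_induced", c(IRS2 = 1), c(IRS2_act = 1),
             c(FYN_act = "activator"), list(Vmax = 3, Ka = 1.5, Km = 5)),
    reaction("r_pik3ca", "smm_summed", c(PIK3CA = 1), c(PIK3CA_act = 1),
             c(GAB2_act = "activator", IRS2_act = "activator"),
             list(Vmax = c(3, 2), Ka = c(1, 2), Km = 5)),
    reaction("r_chuk", "smm_induced", c(CHUK = 1), c(CHUK_act = 1),
             c(PIK3CA_act = "activator"), list(Vmax = 3, Ka = 1, Km = 5)),
    reaction("r_ikbkb", "smm_induced", c(IKBKB = 1), c(IKBKB_act = 1),
             c(PIK3CA_act = "activator"), list(Vmax = 3, Ka = 1, Km = 5)),
    reaction("r_ikk", "mass_action_irrev", c(CHUK_act = 1, IKBKB_act = 1),
             c(IKK = 1), params = list(kf = 0.1)),
    reaction("r_nfkb", "smm_induced", c(NFKB_cyt = 1), c(NFKB_nuc = 1),
             c(IKK = "activator"), list(Vmax = 4, Ka = 1, Km = 5)),
    reaction("r_stat1", "smm_induced", c(STAT1 = 1), c(STAT1_act = 1),
             c(IFNGR_JAK_act = "activator"), list(Vmax = 5, Ka = 1, Km = 5)),
    ## STAT1 turnover (synthesis/degradation/dephosphorylation) keeps the
    ## pool open, so the dimer endpoint is a monotone function of dose
    ## rather than a transient of a drainable reservoir
    reaction("r_stat1_syn", "synthesis", products = c(STAT1 = 1),
             params = list(kf = 1)),
    reaction("r_stat1_deg", "degradation", c(STAT1 = 1),
             params = list(kf = 0.1)),
    reaction("r_stat1_deph", "mass_action_irrev", c(STAT1_act = 1),
             c(STAT1 = 1), params = list(kf = 0.3)),
    reaction("r_dimer", "mass_action_irrev", c(STAT1_act = 2),
             c(STAT1_dimer = 1), params = list(kf = 0.2)),
    reaction("r_nfkb_syn", "synthesis", products = c(NFKB_cyt = 1),
             params = list(kf = 1)),
    reaction("r_nfkb_deg", "degradation", c(NFKB_cyt = 1),
             params = list(kf = 0.1)),
    reaction("r_nfkb_export", "mass_action_irrev", c(NFKB_nuc = 1),
             c(NFKB_cyt = 1), params = list(kf = 0.2)),
    reaction("r_dimer_deg", "degradation", c(STAT1_dimer = 1),
             params = list(kf = MARKER_HALFLIFE_KD)),
    reaction("r_nfkbn_deg", "degradation", c(NFKB_nuc = 1),
             params = list(kf = MARKER_HALFLIFE_KD)))
  net <- pathway_network("ifng", sp, rx,
                         input_ports = data.frame(species = "IFNG",
                                                  agonist = "IFNG"),
                         output_markers = c("STAT1_dimer", "NFKB_nuc"))
  maybe_jitter(net, spec)
}

## ---- three-cell inflammation fixture ---------------------------------------

INFLAMMATION_MARKERS <- c("CCL3", "CCL4", "CCL5", "CSF2", "IL12B",
                          "IL1A", "IL6", "IL8", "TNF", "VEGFA")

## generic inflammatory cell: TLR/cytokine receptor arms converge on an
## NF-kB hub whose activity gates production of the ten markers from a
## buffered precursor pool; a small basal activity gives every marker a
## nonzero control baseline so percent changes are defined.
build_inflam_cell <- function(cell_id, receptors, marker_vmax) {
  cmp <- paste0("cell:", cell_id)
  ligand_of <- c(TLR4 = "LPS", TLR2 = "PAM", IL1R = "IL1A_ext",
                 TNFR = "TNF_ext")
  agonist_of <- c(TLR4 = "LPS", TLR2 = "Pam3CSK4", IL1R = "IL1A",
                  TNFR = "TNF")
  ## cytokine receptors are desensitized (high Ka) relative to the TLR arms
  ## so the autocrine loop amplifies agonist responses without self-igniting
  ka_of <- c(TLR4 = 2, TLR2 = 2, IL1R = 40, TNFR = 40)
  sp <- list(); rx <- list(); ports <- NULL
  for (rec in receptors) {
    lig <- ligand_of[[rec]]
    sp <- c(sp, list(
      species(lig, role = "ligand", compartment = cmp, initial_amount = 0),
      species(rec, role = "receptor", compartment = cmp, initial_amount = 10,
              gene = rec),
      species(paste0(rec, "_act"), role = "receptor_active", compartment = cmp,
              initial_amount = 0, gene = rec)))
    rx <- c(rx, list(
      reaction(paste0("r_", tolower(rec), "_act"), "smm_induced",
               stats::setNames(1, rec), stats::setNames(1, paste0(rec, "_act")),
               stats::setNames("activator", lig),
               list(Vmax = 5, Ka = ka_of[[rec]], Km = 5)),
      reaction(paste0("r_", tolower(rec), "_deact"), "mass_action_irrev",
               stats::setNames(1, paste0(rec, "_act")), stats::setNames(1, rec),
               params = list(kf = 0.5))))
    ports <- rbind(ports, data.frame(species = lig, agonist = agonist_of[[rec]]))
  }
  sp <- c(sp, list(
    species("NFKB", role = "transcription_factor", compartment = cmp,
            initial_amount = 10, gene = "NFKB1"),
    species("NFKB_act", role = "tf_active", compartment = cmp,
            initial_amount = 0.4, gene = "NFKB1"),
    species("PRE", "translation precursor pool", "metabolite", cmp, 100)))
  acts <- paste0(receptors, "_act")
  rx <- c(rx, list(
    if (length(acts) >= 2)
      reaction("r_nfkb_act", "smm_summed", c(NFKB = 1), c(NFKB_act = 1),
               stats::setNames(rep("activator", length(acts)), acts),
               list(Vmax = rep(4, length(acts)), Ka = rep(1, length(acts)),
                    Km = 5))
    else
      reaction("r_nfkb_act", "smm_induced", c(NFKB = 1), c(NFKB_act = 1),
               stats::setNames("activator", acts), list(Vmax = 4, Ka = 1, Km = 5)),
    reaction("r_nfkb_basal", "synthesis", products = c(NFKB_act = 1),
             params = list(kf = 0.2)),
    reaction("r_nfkb_deact", "mass_action_irrev", c(NFKB_act = 1), c(NFKB = 1),
             params = list(kf = 0.5)),
    reaction("r_pre_syn", "synthesis", products = c(PRE = 1),
             params = list(kf = 10)),
    reaction("r_pre_deg", "degradation", c(PRE = 1), params = list(kf = 0.1))))
  ## marker promoters saturate at different NF-kB occupancies: low-Ka
  ## markers are near-saturated at basal activity and respond weakly to
  ## agonist, high-Ka markers respond close to linearly
  marker_ka <- c(CCL3 = 20, CCL4 = 20, CCL5 = 0.5, CSF2 = 2, IL12B = 30,
                 IL1A = 10, IL6 = 25, IL8 = 25, TNF = 5, VEGFA = 15)
  for (mk in INFLAMMATION_MARKERS) {
    sp <- c(sp, list(species(mk, role = "secreted_marker", compartment = cmp,
                             initial_amount = 0, gene = mk)))
    rx <- c(rx, list(
      reaction(paste0("r_", tolower(mk)), "smm_induced", c(PRE = 1),
               stats::setNames(1, mk), c(NFKB_act = "activator"),
               list(Vmax = marker_vmax[[mk]], Ka = marker_ka[[mk]], Km = 50)),
      reaction(paste0("r_", tolower(mk), "_deg"), "degradation",
               stats::setNames(1, mk), params = list(kf = MARKER_HALFLIFE_KD))))
  }
  pathway_network(cell_id, sp, rx, input_ports = ports,
                  output_markers = INFLAMMATION_MARKERS)
}

#' Build the three-cell inflammation fixture
#'
#' Keratinocyte-like, dendritic-cell-like and helper-T-like cells, each
#' producing the ten inflammation markers (CCL3, CCL4, CCL5, CSF2, IL12B,
#' IL1A, IL6, IL8, TNF, VEGFA) at cell-specific rates, with distinct
#' receptor complements: the keratinocyte senses LPS (TLR4), Pam3CSK4
#' (TLR2) and paracrine TNF; the dendritic cell senses LPS, Pam3CSK4 and
#' paracrine IL1A; the T cell has no LPS receptor and responds to Pam3CSK4
#' and to IL1A/TNF produced by its neighbours. All cells secrete all ten
#' markers into a shared medium.
#'
#' @param spec A [fixture_spec()] (name `"inflammation_trio"`).
#' @return List: `cells` (three `pathway_network`s), `coupling`
#'   ([coupling_map()]), `markers`, `medium_markers`.
#' @export
build_inflammation_trio <- function(spec = fixture_spec("inflammation_trio")) {
  vm <- function(...) stats::setNames(c(...), INFLAMMATION_MARKERS)
  ##           CCL3 CCL4 CCL5 CSF2 IL12B IL1A IL6  IL8  TNF  VEGFA
  ker <- build_inflam_cell("ker", c("TLR4", "TLR2", "TNFR"),
                           vm(0.3, 0.2, 0.4, 1.5, 0.1, 1.2, 2.0, 2.5, 0.6, 1.8))
  dc <- build_inflam_cell("dc", c("TLR4", "TLR2", "IL1R"),
                          vm(2.0, 1.8, 1.2, 0.8, 1.5, 0.6, 1.5, 1.8, 1.6, 0.4))
  htl <- build_inflam_cell("htl", c("TLR2", "IL1R", "TNFR"),
                           vm(0.8, 0.7, 1.0, 1.2, 0.4, 0.2, 0.9, 0.7, 1.0, 0.3))
  cells <- list(ker, dc, htl)
  med <- paste0(INFLAMMATION_MARKERS, "_m")
  secretions <- do.call(rbind, lapply(c("ker", "dc", "htl"), function(cid)
    data.frame(cell = cid, species = INFLAMMATION_MARKERS, medium = med,
               ks = 0.2)))
  uptakes <- data.frame(
    medium = c("TNF_m", "IL1A_m", "IL1A_m", "TNF_m"),
    cell = c("ker", "dc", "htl", "htl"),
    species = c("TNF_ext", "IL1A_ext", "IL1A_ext", "TNF_ext"),
    mode = "as_modifier")
  coupling <- coupling_map(secretions, uptakes,
                           stats::setNames(rep(MARKER_HALFLIFE_KD, length(med)),
                                           med))
  cells <- lapply(cells, maybe_jitter, spec = spec)
  list(cells = cells, coupling = coupling, markers = INFLAMMATION_MARKERS,
       medium_markers = med)
}

#' Generate a synthetic observed-response table for the trio fixture
#'
#' Simulates the composed three-cell model with jittered parameters (the
#' "other lab's cells") and multiplies the resulting response ratios by
#' log-normal noise mimicking inter-replicate immunoassay spread, giving
#' the trend-match pipeline a reproducible, non-trivial target.
#'
#' @param spec A [fixture_spec()]; `seed` drives jitter and noise,
#'   `noise_sigma` the log-normal sd.
#' @param agonist,dose Agonist applied, default LPS at 10 ug/ml.
#' @param settings [simulation_settings()].
#' @return Data frame `marker`, `percent_change` over the ten medium
#'   markers.
#' @export
build_observed_responses <- function(spec = fixture_spec("inflammation_trio"),
                                     agonist = "LPS", dose = 10,
                                     settings = simulation_settings()) {
  jspec <- fixture_spec("inflammation_trio", seed = spec$seed, jitter = TRUE,
                        jitter_range = spec$jitter_range)
  trio <- build_inflammation_trio(jspec)
  model <- compose_coculture(trio$cells, trio$coupling)
  ctrl <- simulate_network(model$network, settings)
  pert <- simulate_network(model$network, settings,
                           perturbation = agonist_dose(agonist, dose))
  resp <- percent_change_readout(ctrl, pert, trio$medium_markers)
  noisy <- with_local_seed(spec$seed + 1L, function()
    100 * ((1 + resp$percent_change / 100) *
             exp(stats::rnorm(nrow(resp), 0, spec$noise_sigma)) - 1))
  data.frame(marker = sub("_m$", "", resp$marker), percent_change = noisy,
             stringsAsFactors = FALSE)
}

## ---- myeloma + dendritic cell fixture --------------------------------------

MM_MARKERS <- c("IL6", "IL10", "TGFB1", "VEGFA", "CD47", "FASL", "PDL1")
DC_MARKERS <- c("CD80", "CD86", "IL2", "IFNG", "IL12B")

build_mm_cell <- function() {
  cmp <- "cell:mm"
  driver <- function(id, gene) list(
    species(id, role = "enzyme_active", compartment = cmp, initial_amount = 0,
            gene = gene),
    reaction(paste0("r_", tolower(id), "_syn"), "synthesis",
             products = stats::setNames(1, id), params = list(kf = 1)),
    reaction(paste0("r_", tolower(id), "_deg"), "degradation",
             stats::setNames(1, id), params = list(kf = 0.5)))
  d1 <- driver("NRAS_act", "NRAS")
  d2 <- driver("STAT3_act", "STAT3")
  d3 <- driver("MYC_act", "MYC")
  sp <- list(d1[[1]], d2[[1]], d3[[1]],
             species("PRE", "translation precursor pool", "metabolite", cmp, 100))
  ## the precursor pool is buffered stiffly so marker arms compete only
  ## weakly for substrate and lesion effects stay close to proportional
  rx <- list(d1[[2]], d1[[3]], d2[[2]], d2[[3]], d3[[2]], d3[[3]],
             reaction("r_pre_syn", "synthesis", products = c(PRE = 1),
                      params = list(kf = 50)),
             reaction("r_pre_deg", "degradation", c(PRE = 1),
                      params = list(kf = 0.5)))
  ## marker -> (driver, kcat) production arms; IL6 and VEGFA are driven by
  ## both RAS and STAT3 so genomically distinct lines separate on them
  prod_arms <- list(
    IL6   = list(c("NRAS_act", 1.0), c("STAT3_act", 0.4)),
    VEGFA = list(c("NRAS_act", 0.8), c("STAT3_act", 0.3)),
    IL10  = list(c("STAT3_act", 0.8)),
    PDL1  = list(c("STAT3_act", 0.6)),
    TGFB1 = list(c("MYC_act", 0.6)),
    CD47  = list(c("MYC_act", 0.5)),
    FASL  = list(c("MYC_act", 0.4)))
  gene_of <- c(IL6 = "IL6", IL10 = "IL10", TGFB1 = "TGFB1", VEGFA = "VEGFA",
               CD47 = "CD47", FASL = "FASLG", PDL1 = "CD274")
  for (mk in MM_MARKERS) {
    role <- if (mk %in% c("CD47", "FASL", "PDL1")) "receptor" else "secreted_marker"
    sp <- c(sp, list(species(mk, role = role, compartment = cmp,
                             initial_amount = 0, gene = gene_of[[mk]])))
    for (j in seq_along(prod_arms[[mk]])) {
      arm <- prod_arms[[mk]][[j]]
      rx <- c(rx, list(reaction(
        sprintf("r_%s_%d", tolower(mk), j), "smm_induced", c(PRE = 1),
        stats::setNames(1, mk), stats::setNames("enzyme", arm[1]),
        list(kcat = as.numeric(arm[2]), Km = 50))))
    }
    rx <- c(rx, list(reaction(paste0("r_", tolower(mk), "_deg"), "degradation",
                              stats::setNames(1, mk),
                              params = list(kf = MARKER_HALFLIFE_KD))))
  }
  pathway_network("mm", sp, rx, output_markers = MM_MARKERS)
}

build_dc_target <- function() {
  cmp <- "cell:dc"
  sp <- list(
    species("IL10_in", "sensed IL-10", "ligand", cmp, 0),
    species("TGFB1_in", "sensed TGF-beta1", "ligand", cmp, 0),
    species("IL6_in", "sensed IL-6", "ligand", cmp, 0),
    species("ACT", "maturation activity hub", "enzyme_active", cmp, 0),
    species("PRE", "translation precursor pool", "metabolite", cmp, 100))
  rx <- list(
    reaction("r_act_syn", "synthesis", products = c(ACT = 1),
             params = list(kf = 1)),
    reaction("r_act_deg", "degradation", c(ACT = 1), params = list(kf = 0.5)),
    reaction("r_pre_syn", "synthesis", products = c(PRE = 1),
             params = list(kf = 10)),
    reaction("r_pre_deg", "degradation", c(PRE = 1), params = list(kf = 0.1)))
  kcats <- c(CD80 = 1.2, CD86 = 1.0, IL2 = 0.8, IFNG = 0.9, IL12B = 1.1)
  for (mk in DC_MARKERS) {
    sp <- c(sp, list(species(mk, role = "secreted_marker", compartment = cmp,
                             initial_amount = 0, gene = mk)))
    rx <- c(rx, list(
      reaction(paste0("r_", tolower(mk)), "smm_inhibited", c(PRE = 1),
               stats::setNames(1, mk),
               c(ACT = "enzyme", IL10_in = "inhibitor", TGFB1_in = "inhibitor",
                 IL6_in = "inhibitor"),
               list(kcat = kcats[[mk]], Km = 50, Ki = c(2, 2, 4))),
      reaction(paste0("r_", tolower(mk), "_deg"), "degradation",
               stats::setNames(1, mk), params = list(kf = MARKER_HALFLIFE_KD))))
  }
  pathway_network("dc", sp, rx,
                  input_ports = data.frame(
                    species = c("IL10_in", "TGFB1_in", "IL6_in"),
                    agonist = c("IL10", "TGFB1", "IL6")),
                  output_markers = DC_MARKERS)
}

#' Build the myeloma + dendritic cell fixture
#'
#' A generic multiple-myeloma cell whose constitutive RAS/STAT3/MYC driver
#' activities produce secreted (IL6, IL10, TGFB1, VEGFA) and
#' cell-associated (CD47, FASL, PD-L1) markers, two genomic profiles —
#' `strong` (heavier immunosuppressive lesion load: RAS and STAT3
#' gain-of-function plus a PD-L1 amplification) and `weak` (RAS
#' gain-of-function only) — and a dendritic-cell target whose maturation
#' markers (CD80, CD86, IL2, IFNG, IL12B) are noncompetitively inhibited by
#' sensed IL-10, TGF-beta1 and IL-6. The coupling map routes myeloma
#' secretions through the medium onto the dendritic cell's input ports for
#' staged feed-forward runs.
#'
#' @param spec A [fixture_spec()] (name `"mm_dc_pair"`).
#' @return List: `mm` (source network), `dc` (target network), `profiles`
#'   (list `strong`, `weak` of [genomic_profile()]s), `library`
#'   (effect library with the STAT3 lesion), `coupling`.
#' @export
build_mm_dc_pair <- function(spec = fixture_spec("mm_dc_pair")) {
  mm <- maybe_jitter(build_mm_cell(), spec)
  dc <- maybe_jitter(build_dc_target(), spec)
  lib <- effect_library("STAT3", "D661V", "deleterious")
  five <- c("FATHMM", "MutationAssessor", "PolyPhen", "PROVEAN", "SIFT")
  calls <- function(...) stats::setNames(c(...), five)
  strong <- genomic_profile("U266B1-like", list(
    mutation_record("NRAS", "Q61K", "oncogene",
                    calls("deleterious", "deleterious", "deleterious",
                          "neutral", "deleterious")),
    mutation_record("STAT3", "D661V", "oncogene",
                    calls("neutral", "neutral", "unknown", "neutral",
                          "neutral")),   # library call overrides the vote
    mutation_record("CD274", "", "other", cnv = "amplification"),
    mutation_record("TP53", "R175H", "tumor_suppressor",
                    calls("deleterious", "deleterious", "deleterious",
                          "deleterious", "deleterious"))))
  weak <- genomic_profile("MM.1S-like", list(
    mutation_record("NRAS", "Q61K", "oncogene",
                    calls("deleterious", "deleterious", "deleterious",
                          "neutral", "deleterious")),
    mutation_record("STAT3", "wt", "other",
                    calls("neutral", "neutral", "neutral", "neutral",
                          "neutral"))))
  secreted <- c("IL6", "IL10", "TGFB1", "VEGFA")
  coupling <- coupling_map(
    secretions = data.frame(cell = "mm", species = secreted,
                            medium = paste0(secreted, "_m"), ks = 0.2),
    uptakes = data.frame(medium = c("IL10_m", "TGFB1_m", "IL6_m"),
                         cell = "dc",
                         species = c("IL10_in", "TGFB1_in", "IL6_in"),
                         mode = "as_modifier"),
    medium_degradation = stats::setNames(rep(MARKER_HALFLIFE_KD, 4),
                                         paste0(secreted, "_m")))
  list(mm = mm, dc = dc, profiles = list(strong = strong, weak = weak),
       library = lib, coupling = coupling)
}

#' Build any fixture by name
#'
#' @param spec A [fixture_spec()].
#' @return The fixture object for `spec$name` (see the individual builders).
#' @export
build_fixture <- function(spec) {
  switch(spec$name,
         gpcr_camp = build_gpcr_fixture(spec),
         ifng_stat1 = build_ifng_fixture(spec),
         inflammation_trio = build_inflammation_trio(spec),
         mm_dc_pair = build_mm_dc_pair(spec))
}

#' Write a fixture's files to a directory
#'
#' Emits network YAMLs, a coupling YAML where the fixture has one, genomic
#' profile CSVs, and for the inflammation trio a synthetic observed-response
#' CSV. Byte-identical across runs for a fixed spec.
#'
#' @param spec A [fixture_spec()].
#' @param dir Output directory (created if needed).
#' @return Invisibly, the written paths.
#' @export
fixture_files <- function(spec, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- character()
  put <- function(name, text) {
    p <- file.path(dir, name)
    writeLines(text, p, sep = "")
    paths <<- c(paths, p)
  }
  obj <- build_fixture(spec)
  if (inherits(obj, "pathway_network")) {
    put(paste0(spec$name, ".yaml"), serialize_network(obj))
  } else if (spec$name == "inflammation_trio") {
    for (cell in obj$cells)
      put(paste0(cell$cell_id, ".yaml"), serialize_network(cell))
    put("coupling.yaml", serialize_coupling(obj$coupling))
    obs <- build_observed_responses(spec)
    p <- file.path(dir, "observed.csv")
    utils::write.csv(obs, p, row.names = FALSE, quote = FALSE)
    paths <- c(paths, p)
  } else if (spec$name == "mm_dc_pair") {
    put("mm.yaml", serialize_network(obj$mm))
    put("dc.yaml", serialize_network(obj$dc))
    put("coupling.yaml", serialize_coupling(obj$coupling))
    for (nm in names(obj$profiles)) {
      p <- file.path(dir, paste0("profile_", nm, ".csv"))
      write_genomic_profile(obj$profiles[[nm]], p)
      paths <- c(paths, p)
    }
    p <- file.path(dir, "effect_library.csv")
    utils::write.csv(data.frame(gene = "STAT3", variant = "D661V",
                                effect = "deleterious"),
                     p, row.names = FALSE, quote = FALSE)
    paths <- c(paths, p)
  }
  invisible(paths)
}

serialize_coupling <- function(coupling) {
  doc <- list(coupling = list(
    secretions = lapply(seq_len(nrow(coupling$secretions)), function(i)
      as.list(coupling$secretions[i, ])),
    uptakes = lapply(seq_len(nrow(coupling$uptakes)), function(i)
      as.list(coupling$uptakes[i, ])),
    medium_degradation = as.list(coupling$medium_degradation),
    volume_ratio = coupling$volume_ratio))
  yaml::as.yaml(doc, precision = 15L)
}

#' Read a coupling map from its YAML form
#'
#' @param path YAML file with a top-level `coupling:` section.
#' @return A [coupling_map()].
#' @export
read_coupling <- function(path) {
  doc <- yaml::read_yaml(path)$coupling
  to_df <- function(rows) if (length(rows)) do.call(rbind, lapply(rows, as.data.frame))
  coupling_map(to_df(doc$secretions), to_df(doc$uptakes),
               unlist(doc$medium_degradation) %||% numeric(),
               doc$volume_ratio %||% 1)
}

write_genomic_profile <- function(profile, path) {
  five <- c("FATHMM", "MutationAssessor", "PolyPhen", "PROVEAN", "SIFT")
  rows <- lapply(profile$records, function(r) {
    calls <- stats::setNames(rep("", length(five)), five)
    calls[names(r$predictor_calls)] <- r$predictor_calls
    cbind(data.frame(gene = r$gene, variant = r$variant,
                     gene_class = r$gene_class, cnv = r$cnv),
          as.data.frame(as.list(calls)))
  })
  utils::write.csv(do.call(rbind, rows), path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
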