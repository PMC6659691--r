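test_that("fixtures are deterministic per spec and seed", {
  for (nm in c("gpcr_camp", "ifng_stat1")) {
    a <- serialize_network(build_fixture(fixture_spec(nm, seed = 3, jitter = TRUE)))
    b <- serialize_network(build_fixture(fixture_spec(nm, seed = 3, jitter = TRUE)))
    expect_identical(a, b)
    c <- serialize_network(build_fixture(fixture_spec(nm, seed = 4, jitter = TRUE)))
    expect_false(identical(a, c))
  }
  o1 <- build_observed_responses(fixture_spec("inflammation_trio", seed = 17))
  o2 <- build_observed_responses(fixture_spec("inflammation_trio", seed = 17))
  expect_identical(o1, o2)
})

test_that("fixture file emission is byte-identical across runs", {
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  fixture_files(fixture_spec("mm_dc_pair"), d1)
  fixture_files(fixture_spec("mm_dc_pair"), d2)
  for (f in list.files(d1))
    expect_identical(readLines(file.path(d1, f)), readLines(file.path(d2, f)),
                     label = f)
})

test_that("every fixture network passes validation with an empty report", {
  nets <- c(list(build_gpcr_fixture(), build_ifng_fixture()),
            build_inflammation_trio()$cells,
            {fx <- build_mm_dc_pair(); list(fx$mm, fx$dc)})
  for (net in nets)
    expect_length(validate_network(net)$violations, 0)
})

test_that("GPCR fixture: activation raises cAMP, inhibition arm tempers it", {
  net <- build_gpcr_fixture()
  ctrl <- simulate_network(net)
  pert <- simulate_network(net, perturbation = agonist_dose("PGE2", 10))
  resp <- percent_change_readout(ctrl, pert, "cAMP")
  expect_equal(resp$trend, "up")          # fixture regression: net direction

  no_inhib <- net
  no_inhib$reactions <- Filter(function(r) r$id != "r_gpr44_act", net$reactions)
  pert2 <- simulate_network(no_inhib, perturbation = agonist_dose("PGE2", 10))
  expect_gt(pert2$endpoint[["cAMP"]], pert$endpoint[["cAMP"]])
  expect_gt(pert$endpoint[["cAMP"]], ctrl$endpoint[["cAMP"]])

  ## no agonist: nothing moves
  z <- simulate_network(net, perturbation = agonist_dose("PGE2", 0))
  expect_identical(z$trajectories, ctrl$trajectories)
})

test_that("summed-flux PI3K node is exactly additive in its activators", {
  net <- build_ifng_fixture()
  rxn <- mcellsim:::get_reaction(net, "r_pik3ca")
  state <- c(PIK3CA = 7, PIK3CA_act = 0, GAB2_act = 2, IRS2_act = 5)
  both <- reaction_flux(rxn, state)
  single <- function(keep) {
    r <- rxn
    i <- match(keep, names(r$modifiers))
    r$modifiers <- r$modifiers[i]
    r$params$Vmax <- r$params$Vmax[i]
    r$params$Ka <- r$params$Ka[i]
    r$kind <- "smm_induced"
    reaction_flux(r, state)
  }
  expect_equal(both, single("GAB2_act") + single("IRS2_act"))
})

test_that("STAT1 dimer endpoint rises monotonically with IFNG dose", {
  net <- build_ifng_fixture()
  ends <- vapply(c(0, 1, 3, 10), function(d)
    simulate_network(net, perturbation = agonist_dose("IFNG", d))$
      endpoint[["STAT1_dimer"]], 1)
  expect_true(all(diff(ends) >= -1e-9))
  expect_gt(ends[4], ends[1])
})

test_that("JAK1 deletion silences STAT1 dimerization", {
  net <- build_ifng_fixture()
  del <- genomic_profile("jak1del", list(
    mutation_record("JAK1", "", "other", cnv = "deletion")))
  pert <- apply_genomic_profile(net, del)$network
  res <- simulate_network(pert, perturbation = agonist_dose("IFNG", 10))
  expect_lt(res$endpoint[["STAT1_dimer"]], 1e-6)
})

test_that("trio fixture: agonists induce IL6/IL8 and the seed-17 panel is frozen", {
  trio <- build_inflammation_trio()
  model <- compose_coculture(trio$cells, trio$coupling)
  ctrl <- simulate_network(model$network)
  for (ag in c("LPS", "Pam3CSK4")) {
    pert <- simulate_network(model$network,
                             perturbation = agonist_dose(ag, 10))
    resp <- percent_change_readout(ctrl, pert, c("IL6_m", "IL8_m"))
    expect_true(all(resp$trend == "up"), label = ag)
  }
  ## agonist-free run: all markers 0%
  null <- percent_change_readout(ctrl, ctrl, trio$medium_markers)
  expect_true(all(null$percent_change == 0))

  ## frozen trend-match regression against the seed-17 synthetic observations
  lps <- simulate_network(model$network, perturbation = agonist_dose("LPS", 10))
  pred <- percent_change_readout(ctrl, lps, trio$medium_markers)
  obs <- build_observed_responses(fixture_spec("inflammation_trio", seed = 17))
  tt <- tabulate_matches(
    stats::setNames(pred$percent_change, sub("_m$", "", pred$marker)),
    stats::setNames(obs$percent_change, obs$marker))
  expect_equal(tt$k, 9)
  expect_equal(tt$n, 10)
  expect_identical(tt$table$marker[!tt$table$match], "CCL5")
})

test_that("myeloma profiles order marker outputs and DC inhibition", {
  fx <- build_mm_dc_pair()
  strong <- apply_genomic_profile(fx$mm, fx$profiles$strong, fx$library)$network
  weak <- apply_genomic_profile(fx$mm, fx$profiles$weak, fx$library)$network
  es <- simulate_network(strong)$endpoint
  ew <- simulate_network(weak)$endpoint
  for (mk in c("IL10", "IL6", "VEGFA", "PDL1"))
    expect_gte(es[[mk]], ew[[mk]])

  rs <- run_feedforward(list(strong), fx$dc, fx$coupling,
                        sources_control = list(fx$mm))
  rw <- run_feedforward(list(weak), fx$dc, fx$coupling,
                        sources_control = list(fx$mm))
  expect_true(all(rs$trend == "down"))
  expect_true(all(rs$percent_change <= rw$percent_change))

  ## with no lesions the two lines are the same cell: 0% on the DC side
  r0 <- run_feedforward(list(fx$mm), fx$dc, fx$coupling,
                        sources_control = list(fx$mm))
  expect_true(all(abs(r0$percent_change) < 1e-8))
})
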