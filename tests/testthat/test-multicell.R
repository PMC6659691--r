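test_that("composition bookkeeping: state dimension and namespacing", {
  trio <- build_inflammation_trio()
  model <- compose_coculture(trio$cells, trio$coupling)
  n_cell <- sum(vapply(trio$cells, function(c) length(c$species), 1L))
  expect_length(model$network$species, n_cell + length(trio$medium_markers))
  expect_true(all(paste0("ker.", mcellsim:::species_ids(trio$cells[[1]])) %in%
                    mcellsim:::species_ids(model$network)))
  ## coupling referencing a missing species fails composition
  bad <- trio$coupling
  bad$secretions$species[1] <- "NOPE"
  expect_error(compose_coculture(trio$cells, bad),
               class = "mcs_composition_error")
})

test_that("zero secretion rates decouple the co-culture into isolated cells", {
  trio <- build_inflammation_trio()
  cm <- trio$coupling
  cm$secretions$ks <- 0
  model <- compose_coculture(trio$cells, cm)
  lps <- agonist_dose("LPS", 10)
  ## the identity is structural; tight solver tolerances keep integration
  ## error below the 1e-8 band being asserted
  st <- simulation_settings(rtol = 1e-10, atol = 1e-12)
  composed <- simulate_network(model$network, st, perturbation = lps)
  for (cell in trio$cells[1:2]) {   # the two LPS-responsive cells
    alone <- simulate_network(cell, st, perturbation = lps)
    ids <- mcellsim:::species_ids(cell)
    got <- composed$endpoint[paste0(cell$cell_id, ".", ids)]
    want <- alone$endpoint[ids]
    rel <- abs(got - want) / pmax(abs(want), 1e-12)
    expect_lt(max(rel), 1e-8)
  }
})

test_that("a single cell with an empty medium behaves as the lone network", {
  net <- build_ifng_fixture()
  model <- compose_coculture(list(net), coupling_map())
  a <- simulate_network(model$network, perturbation = agonist_dose("IFNG", 5))
  b <- simulate_network(net, perturbation = agonist_dose("IFNG", 5))
  expect_equal(unname(a$endpoint[paste0("ifng.", names(b$endpoint))]),
               unname(b$endpoint), tolerance = 1e-10)
})

test_that("secretion conserves volume-weighted moles when degradation is off", {
  cell <- secreting_cell(m0 = 10)
  cm <- coupling_map(
    secretions = data.frame(cell = "sec", species = "M", medium = "M_m",
                            ks = 0.3),
    volume_ratio = 2)
  model <- compose_coculture(list(cell), cm)
  res <- simulate_network(model$network,
                          simulation_settings(report_grid = seq(4, 64, by = 4)))
  ## moles per unit medium volume: vr * [cell] + [medium]
  total <- 2 * res$trajectories[, "sec.M"] + res$trajectories[, "M_m"]
  expect_lt(diff(range(total)) / max(total), 1e-6)
})

test_that("cell order does not affect per-marker endpoints", {
  trio <- build_inflammation_trio()
  m1 <- compose_coculture(trio$cells, trio$coupling)
  m2 <- compose_coculture(rev(trio$cells), trio$coupling)
  lps <- agonist_dose("LPS", 10)
  e1 <- simulate_network(m1$network, perturbation = lps)$endpoint
  e2 <- simulate_network(m2$network, perturbation = lps)$endpoint
  expect_equal(unname(e1[m1$output_markers]), unname(e2[m1$output_markers]),
               tolerance = 1e-6)
})

test_that("feed-forward with zero secretions reads out 0% everywhere", {
  fx <- build_mm_dc_pair()
  cm <- fx$coupling
  cm$secretions$ks <- 0
  strong <- apply_genomic_profile(fx$mm, fx$profiles$strong, fx$library)$network
  resp <- run_feedforward(list(strong), fx$dc, cm,
                          sources_control = list(fx$mm))
  expect_true(all(abs(resp$percent_change) < 1e-8))
  expect_true(all(resp$trend == "no_change"))
})

test_that("feed-forward mapping errors are explicit", {
  fx <- build_mm_dc_pair()
  cm <- fx$coupling
  cm$uptakes <- cm$uptakes[0, ]
  expect_error(run_feedforward(list(fx$mm), fx$dc, cm),
               class = "mcs_mapping_error")
  bad <- fx$coupling
  bad$uptakes$species[1] <- "NOT_A_PORT"
  expect_error(run_feedforward(list(fx$mm), fx$dc, bad),
               class = "mcs_mapping_error")
})

test_that("feed-forward and full co-culture agree on target trends", {
  fx <- build_mm_dc_pair()
  strong <- apply_genomic_profile(fx$mm, fx$profiles$strong, fx$library)$network

  ff <- run_feedforward(list(strong), fx$dc, fx$coupling,
                        sources_control = list(fx$mm))

  cc_ctrl <- simulate_network(
    compose_coculture(list(fx$mm, fx$dc), fx$coupling)$network)
  cc_pert <- simulate_network(
    compose_coculture(list(strong, fx$dc), fx$coupling)$network)
  cc <- percent_change_readout(cc_ctrl, cc_pert,
                               paste0("dc.", fx$dc$output_markers))
  expect_equal(cc$trend, ff$trend)
  expect_true(all(ff$trend == "down"))
})
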