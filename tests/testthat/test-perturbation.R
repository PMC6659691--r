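test_that("agonist dosing sets the mapped ligand and leaves the input pure", {
  trio <- build_inflammation_trio()
  ker <- trio$cells[[1]]
  dosed <- apply_agonist(ker, agonist_dose("LPS", 10))
  expect_equal(mcellsim:::get_species(dosed, "LPS")$initial_amount, 10)
  expect_equal(mcellsim:::get_species(ker, "LPS")$initial_amount, 0)

  ## dose 0 leaves the network identical to the control
  expect_equal(apply_agonist(ker, agonist_dose("LPS", 0)), ker)

  ## no matching port is a port error (the GPCR cell knows no lipopeptide)
  expect_error(apply_agonist(build_gpcr_fixture(),
                             agonist_dose("Pam3CSK4", 10)),
               class = "mcs_port_error")

  ## conversion factor scales dose to concentration
  dosed2 <- apply_agonist(ker, agonist_dose("LPS", 10, conversion = 0.5))
  expect_equal(mcellsim:::get_species(dosed2, "LPS")$initial_amount, 5)
})

test_that("consensus effect: library precedence, strict majority, ties", {
  lib <- effect_library("KRAS", "G12D", "deleterious")
  rec <- mutation_record("KRAS", "G12D", "oncogene",
                         c(a = "neutral", b = "neutral", c = "neutral",
                           d = "neutral"))
  expect_equal(consensus_effect(rec, lib), "deleterious")  # library wins

  maj <- mutation_record("X", "v", "other",
                         c(a = "deleterious", b = "deleterious", c = "neutral"))
  expect_equal(consensus_effect(maj), "deleterious")

  tie <- mutation_record("X", "v", "other",
                         c(a = "deleterious", b = "neutral"))
  expect_equal(consensus_effect(tie), "unknown")

  unk <- mutation_record("X", "v", "other",
                         c(a = "unknown", b = "unknown"))
  expect_equal(consensus_effect(unk), "unknown")
})

test_that("genomic lesions map to activity and expression scales", {
  fx <- build_mm_dc_pair()
  lib <- fx$library

  res <- apply_genomic_profile(fx$mm, fx$profiles$strong, lib)
  nras <- Filter(function(s) identical(s$gene, "NRAS"), res$network$species)
  expect_true(all(vapply(nras, `[[`, 1, "activity_scale") == 2))
  pdl1 <- mcellsim:::get_species(res$network, "PDL1")
  expect_equal(pdl1$expression_scale, 2)   # CD274 amplification
  ## gene without species: warning row, not an error
  expect_match(res$report$action[res$report$gene == "TP53"], "no species")
  ## input untouched
  expect_true(all(vapply(fx$mm$species, `[[`, 1, "activity_scale") == 1))

  ## tumor suppressor with default loss factor zeroes activity
  ts_net <- pathway_network("t",
    list(species("P", role = "enzyme", compartment = "cell:t",
                 initial_amount = 1, gene = "TP53")),
    list(reaction("r", "degradation", c(P = 1), params = list(kf = 0.1))))
  prof <- genomic_profile("p", list(
    mutation_record("TP53", "R175H", "tumor_suppressor",
                    c(a = "deleterious", b = "deleterious"))))
  out <- apply_genomic_profile(ts_net, prof)
  expect_equal(mcellsim:::get_species(out$network, "P")$activity_scale, 0)

  ## unknown/neutral records are reported as skipped and change nothing
  skip_prof <- genomic_profile("q", list(
    mutation_record("TP53", "x", "tumor_suppressor",
                    c(a = "deleterious", b = "neutral"))))
  out2 <- apply_genomic_profile(ts_net, skip_prof)
  expect_match(out2$report$action, "skipped: unknown")
  expect_equal(out2$network, ts_net)
})

test_that("an all-neutral profile simulates bit-identically to control", {
  fx <- build_mm_dc_pair()
  neutral <- genomic_profile("none", list(
    mutation_record("NRAS", "wt", "oncogene",
                    c(a = "neutral", b = "neutral", c = "neutral")),
    mutation_record("STAT3", "wt", "other",
                    c(a = "neutral", b = "neutral", c = "neutral"))))
  pert <- apply_genomic_profile(fx$mm, neutral)$network
  expect_identical(simulate_network(pert)$trajectories,
                   simulate_network(fx$mm)$trajectories)
})

test_that("deleting a marker's sole driver gene lowers its endpoint", {
  fx <- build_mm_dc_pair()
  del <- genomic_profile("del", list(
    mutation_record("STAT3", "", "other", cnv = "deletion")))
  pert <- apply_genomic_profile(fx$mm, del)$network
  ctrl <- simulate_network(fx$mm)$endpoint
  down <- simulate_network(pert)$endpoint
  expect_lte(down[["IL10"]], ctrl[["IL10"]])   # STAT3 is IL10's only driver
  expect_lt(down[["IL10"]], 0.01 * ctrl[["IL10"]])
})

test_that("profile CSV and effect-library CSV round-trip through readers", {
  fx <- build_mm_dc_pair()
  dir <- withr::local_tempdir()
  fixture_files(fixture_spec("mm_dc_pair"), dir)
  prof <- read_genomic_profile(file.path(dir, "profile_strong.csv"))
  expect_length(prof$records, 4)
  expect_equal(prof$records[[1]]$gene, "NRAS")
  expect_equal(consensus_effect(prof$records[[1]]), "deleterious")
  lib <- read_effect_library(file.path(dir, "effect_library.csv"))
  expect_equal(mcellsim:::library_lookup(lib, "STAT3", "D661V"), "deleterious")
})
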