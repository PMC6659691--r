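test_that("minimal two-species document parses with order preserved", {
  net <- parse_network(minimal_doc)
  expect_s3_class(net, "pathway_network")
  expect_length(net$species, 2)
  expect_length(net$reactions, 1)
  expect_identical(vapply(net$species, `[[`, "", "id"), c("L", "M"))
  expect_identical(net$input_ports$agonist, "LIG")
})

test_that("serialization round-trips are identities on the fixtures", {
  for (nm in c("gpcr_camp", "ifng_stat1")) {
    net <- build_fixture(fixture_spec(nm))
    y1 <- serialize_network(net)
    reparsed <- parse_network(y1)
    expect_equal(reparsed, net)
    expect_identical(serialize_network(reparsed), y1)  # canonical, byte-level
  }
  mm <- build_mm_dc_pair()$mm
  expect_equal(parse_network(serialize_network(mm)), mm)
})

test_that("malformed documents yield located errors, never partial networks", {
  bad_ref <- sub("products: \\[\\{species: M", "products: [{species: XYZ",
                 minimal_doc)
  err <- expect_error(parse_network(bad_ref), class = "mcs_error")
  expect_match(conditionMessage(err), "XYZ")

  expect_error(parse_network(sub("kind: synthesis", "kind: frobnicate",
                                 minimal_doc)),
               class = "mcs_unsupported_kind_error")
  expect_error(parse_network(paste0(minimal_doc, "bogus_key: 1\n")),
               class = "mcs_parse_error")
  dup <- sub("\\{id: L,", "{id: M,", minimal_doc)
  expect_error(parse_network(dup), class = "mcs_uniqueness_error")
})

test_that("validator gives an empty report on fixtures and flags defects", {
  gpcr <- build_gpcr_fixture()
  expect_length(validate_network(gpcr)$violations, 0)

  ## deleting the cyclase activation edge disconnects cAMP from the agonist
  broken <- gpcr
  broken$reactions <- Filter(function(r) r$id != "r_adcy_act", gpcr$reactions)
  v <- validate_network(broken)$violations
  expect_true(any(grepl("cAMP", v) & grepl("unreachable", v)))

  ## a missing required parameter is reported, not thrown
  nopar <- gpcr
  i <- which(vapply(nopar$reactions, `[[`, "", "id") == "r_ptger4_act")
  nopar$reactions[[i]]$params$Vmax <- NULL
  expect_true(any(grepl("Vmax", validate_network(nopar)$violations)))

  ## unreferenced species are orphans
  orph <- gpcr
  orph$species <- c(orph$species,
                    list(species("LONER", role = "metabolite",
                                 compartment = "cell:gpcr")))
  expect_true(any(grepl("LONER", validate_network(orph)$violations)))
})

test_that("moiety detection recovers the closed cycles of the GPCR fixture", {
  gpcr <- build_gpcr_fixture()
  moi <- conserved_moieties(gpcr)
  expect_equal(ncol(moi), 6)
  ## the known conserved totals lie in the span of the returned basis
  known <- list(
    c("PTGER4", "PTGER4_act"),
    c("GPR44", "GPR44_act"),
    c("ADCY1", "ADCY1_act"),
    c("GDP_GNAS_GNBC", "GTP_GNAS"),
    c("GDP_GNAI_GNBC", "GTP_GNAI"),
    c("GNBC", "GDP_GNAS_GNBC", "GDP_GNAI_GNBC"))
  for (grp in known) {
    y <- stats::setNames(numeric(nrow(moi)), rownames(moi))
    y[grp] <- 1
    expect_equal(qr(cbind(moi, y))$rank, qr(moi)$rank,
                 label = paste("span contains", paste(grp, collapse = "+")))
  }
})

test_that("exact integer null space matches a numeric oracle", {
  A <- matrix(c(1, -1, 0,
                0, 1, -1), nrow = 2, byrow = TRUE)
  ns <- mcellsim:::int_nullspace(A)
  expect_equal(ncol(ns), 1)
  expect_true(all(A %*% ns == 0))
  expect_equal(abs(as.vector(ns)), c(1, 1, 1))  # the summed moiety
})
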