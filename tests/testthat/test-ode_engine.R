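test_that("rate laws evaluate to their closed forms", {
  ## inducer-gated Michaelis-Menten: 10 * (1/2) * (2/4) = 2.5
  r <- reaction("r", "smm_induced", c(S = 1), c(P = 1), c(M = "activator"),
                list(Vmax = 10, Ka = 1, Km = 2))
  expect_equal(reaction_flux(r, c(S = 2, P = 0, M = 1)), 2.5)

  ## bimolecular mass action: 0.1 * 2 * 3 = 0.6
  r2 <- reaction("r2", "mass_action_irrev", c(A = 1, B = 1), c(C = 1),
                 params = list(kf = 0.1))
  expect_equal(reaction_flux(r2, c(A = 2, B = 3, C = 0)), 0.6)

  ## enzyme form: kcat * [E] * S/(Km+S) = 2 * 4 * 10/60
  r3 <- reaction("r3", "smm_induced", c(S = 1), c(P = 1), c(E = "enzyme"),
                 list(kcat = 2, Km = 50))
  expect_equal(reaction_flux(r3, c(S = 10, P = 0, E = 4)), 2 * 4 * 10 / 60)

  ## noncompetitive inhibition multiplies 1/(1 + I/Ki) terms
  r4 <- reaction("r4", "smm_inhibited", c(S = 1), c(P = 1),
                 c(I1 = "inhibitor", I2 = "inhibitor"),
                 list(Vmax = 6, Km = 2, Ki = c(1, 2)))
  expect_equal(reaction_flux(r4, c(S = 2, P = 0, I1 = 1, I2 = 2)),
               6 * 0.5 * (1 / 2) * (1 / 2))

  ## reversible mass action nets forward minus reverse
  r5 <- reaction("r5", "mass_action_rev", c(A = 1), c(B = 1),
                 params = list(kf = 0.4, kr = 0.1))
  expect_equal(reaction_flux(r5, c(A = 5, B = 4)), 0.4 * 5 - 0.1 * 4)

  ## zero concentrations give zero flux for every kind
  expect_equal(reaction_flux(r, c(S = 0, P = 0, M = 0)), 0)
  expect_equal(reaction_flux(r2, c(A = 0, B = 0, C = 0)), 0)
  expect_equal(reaction_flux(r4, c(S = 0, P = 0, I1 = 0, I2 = 0)), 0)
  expect_equal(reaction_flux(r5, c(A = 0, B = 0)), 0)

  ## errors: missing parameter and negative state
  expect_error(reaction_flux(reaction("rx", "smm_induced", c(S = 1), c(P = 1),
                                      c(M = "activator"),
                                      list(Vmax = 1, Ka = 1)),
                             c(S = 1, P = 0, M = 1)),
               class = "mcs_config_error")
  expect_error(reaction_flux(r2, c(A = -1, B = 3, C = 0)),
               class = "mcs_state_error")
})

test_that("activity scale multiplies catalysed fluxes", {
  net <- pathway_network("a",
    list(species("S", role = "metabolite", compartment = "cell:a",
                 initial_amount = 10),
         species("P", role = "metabolite", compartment = "cell:a"),
         species("E", role = "enzyme", compartment = "cell:a",
                 initial_amount = 4, activity_scale = 3)),
    list(reaction("r", "smm_induced", c(S = 1), c(P = 1), c(E = "enzyme"),
                  list(kcat = 2, Km = 50))))
  r <- net$reactions[[1]]
  expect_equal(reaction_flux(r, c(S = 10, P = 0, E = 4), net),
               3 * 2 * 4 * 10 / 60)
})

test_that("assembled derivatives follow stoichiometry", {
  f <- assemble_derivatives(synth_deg_net(k0 = 2, kd = 0.5))
  expect_equal(f(0, c(X = 3))[[1]], 2 - 0.5 * 3)

  ## dimerization with stoichiometry 2: dA = -2*0.2*9, dD = +0.2*9
  fd <- assemble_derivatives(dimer_net(kf = 0.2, a0 = 3))
  expect_equal(fd(0, c(A = 3, D = 0))[[1]], c(-3.6, 1.8))

  ## moiety-weighted derivatives vanish at arbitrary states
  gpcr <- build_gpcr_fixture()
  conv <- strip_kinds(gpcr)
  moi <- conserved_moieties(gpcr)
  fg <- assemble_derivatives(conv)
  set.seed(42)
  for (i in 1:5) {
    x <- stats::runif(length(conv$species), 0, 10)
    names(x) <- vapply(conv$species, `[[`, "", "id")
    dx <- fg(0, x)[[1]]
    expect_equal(as.vector(crossprod(moi, dx)), numeric(ncol(moi)),
                 tolerance = 1e-12)
  }
})

test_that("Radau integration recovers the analytic steady state", {
  res <- simulate_network(synth_deg_net(k0 = 2, kd = 0.5, x0 = 0))
  expect_equal(unname(res$endpoint["X"]), 4, tolerance = 1e-5)
  expect_true(res$steady_state_reached)
  ## report grid plus endpoint, endpoint equals last trajectory row
  expect_equal(res$times, c(0, 16, 32, 64))
  expect_equal(res$endpoint, res$trajectories[nrow(res$trajectories), ])
  ## against the analytic transient and an explicit reference integrator
  analytic <- 4 * (1 - exp(-0.5 * res$times))
  expect_equal(unname(res$trajectories[, "X"]), analytic, tolerance = 1e-5)
  comp <- mcellsim:::compile_network(synth_deg_net())
  ref <- deSolve::ode(comp$x0, res$times, comp$deriv, parms = NULL,
                      method = "ode45", rtol = 1e-10, atol = 1e-12)
  expect_equal(unname(res$trajectories[, "X"]), unname(ref[, 2]),
               tolerance = 1e-4)
})

test_that("trajectories stay non-negative under seeded parameter jitter", {
  for (seed in 1:3) {
    for (nm in c("gpcr_camp", "ifng_stat1")) {
      net <- build_fixture(fixture_spec(nm, seed = seed, jitter = TRUE))
      agon <- if (nm == "gpcr_camp") "PGE2" else "IFNG"
      res <- simulate_network(net, perturbation = agonist_dose(agon, 10))
      expect_gte(min(res$trajectories), -1e-9)
    }
  }
})

test_that("identical inputs give bit-identical trajectories", {
  net <- build_ifng_fixture()
  a <- simulate_network(net, perturbation = agonist_dose("IFNG", 5))
  b <- simulate_network(net, perturbation = agonist_dose("IFNG", 5))
  expect_identical(a$trajectories, b$trajectories)
})

test_that("zero-dose agonist is indistinguishable from the control", {
  net <- build_ifng_fixture()
  ctrl <- simulate_network(net)
  z <- simulate_network(net, perturbation = agonist_dose("IFNG", 0))
  expect_identical(ctrl$trajectories, z$trajectories)
  resp <- percent_change_readout(ctrl, z, net$output_markers)
  expect_true(all(resp$trend == "no_change"))
})

test_that("percent-change readout handles defined and floored controls", {
  mk <- function(vals) {
    traj <- matrix(rep(vals, 2), nrow = 2, byrow = TRUE,
                   dimnames = list(NULL, names(vals)))
    structure(list(endpoint = vals, trajectories = traj), class = "simulation_result")
  }
  r <- percent_change_readout(mk(c(M = 100)), mk(c(M = 183.63)), "M")
  expect_equal(r$percent_change, 83.63)
  expect_equal(r$trend, "up")

  self <- percent_change_readout(mk(c(M = 7)), mk(c(M = 7)), "M")
  expect_equal(self$percent_change, 0)
  expect_equal(self$trend, "no_change")

  ## control at zero: undefined percent, absolute-difference trend
  fl <- percent_change_readout(mk(c(M = 0)), mk(c(M = 5)), "M")
  expect_true(is.na(fl$percent_change))
  expect_equal(fl$trend, "up")

  expect_error(percent_change_readout(mk(c(M = 1)), mk(c(M = 1)), "NOPE"),
               class = "mcs_unknown_marker_error")
})
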