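#' Simulation settings
#'
#' Defaults mirror a 64-hour culture endpoint with samples drawn at 16, 32
#' and 64 hours; the integrator is the implicit Radau method (suitable for
#' the stiff systems that saturating rate laws produce).
#'
#' @param t_end End time, hours.
#' @param rtol,atol Relative/absolute solver tolerances.
#' @param steady_state_tol Infinity-norm derivative threshold (1/hour) below
#'   which the endpoint is flagged as a numerical steady state.
#' @param max_step Optional maximum step size, hours.
#' @param report_grid Report times, hours; `t_end` is always appended.
#' @return An object of class `"simulation_settings"`.
#' @export
simulation_settings <- function(t_end = 64, rtol = 1e-6, atol = 1e-9,
                                steady_state_tol = 1e-8, max_step = NULL,
                                report_grid = c(16, 32, 64)) {
  if (t_end <= 0 || rtol <= 0 || atol <= 0 || steady_state_tol <= 0)
    mcs_error("t_end and tolerances must be positive", "mcs_config_error")
  structure(list(t_end = t_end, rtol = rtol, atol = atol,
                 steady_state_tol = steady_state_tol, max_step = max_step,
                 report_grid = report_grid),
            class = "simulation_settings")
}

## Compile a network into fast per-reaction index structures plus a
## derivative closure over the state vector (species declaration order).
compile_network <- function(net) {
  ids <- species_ids(net)
  idx <- stats::setNames(seq_along(ids), ids)
  expr_scale <- species_field(net, "expression_scale")
  act_scale <- species_field(net, "activity_scale")
  clamped <- vapply(net$species, `[[`, TRUE, "clamped")

  rxns <- lapply(net$reactions, function(r) {
    modes <- unname(r$modifiers)
    list(id = r$id, kind = r$kind,
         sub_i = idx[names(r$substrates)], sub_n = unname(r$substrates),
         prod_i = idx[names(r$products)], prod_n = unname(r$products),
         act_i = idx[names(r$modifiers)[modes == "activator"]],
         inh_i = idx[names(r$modifiers)[modes == "inhibitor"]],
         enz_i = idx[names(r$modifiers)[modes == "enzyme"]],
         p = r$params)
  })

  x0 <- species_field(net, "initial_amount") * expr_scale

  flux_one <- function(r, x) {
    p <- r$p
    vmax_eff <- function() {
      v <- if (!is.null(p$Vmax)) p$Vmax else p$kcat * x[r$enz_i]
      if (length(r$enz_i)) v <- v * act_scale[r$enz_i]
      v
    }
    switch(r$kind,
      smm_induced = {
        S <- x[r$sub_i]
        v <- vmax_eff() * (S / (p$Km + S))
        if (length(r$act_i)) { M <- x[r$act_i]; v <- v * (M / (p$Ka + M)) }
        v
      },
      smm_summed = {
        S <- x[r$sub_i]; M <- x[r$act_i]
        sum(p$Vmax * (M / (p$Ka + M))) * (S / (p$Km + S))
      },
      smm_inhibited = {
        S <- x[r$sub_i]
        v <- vmax_eff() * (S / (p$Km + S))
        if (length(r$inh_i)) v <- v * prod(1 / (1 + x[r$inh_i] / p$Ki))
        v
      },
      mass_action_irrev = p$kf * prod(x[r$sub_i]^r$sub_n),
      mass_action_rev = p$kf * prod(x[r$sub_i]^r$sub_n) -
                        p$kr * prod(x[r$prod_i]^r$prod_n),
      synthesis = p$kf * expr_scale[r$prod_i[1]],
      degradation = p$kf * x[r$sub_i],
      secretion = p$kf * x[r$sub_i])
  }

  deriv <- function(t, x, parms = NULL) {
    x <- pmax(x, 0)  # solver probes may dip below zero within tolerance
    dx <- numeric(length(x))
    for (r in rxns) {
      v <- flux_one(r, x)
      if (r$kind == "secretion") {
        vr <- if (is.null(r$p$vr)) 1 else r$p$vr
        dx[r$sub_i] <- dx[r$sub_i] - v
        dx[r$prod_i] <- dx[r$prod_i] + v * vr
      } else if (r$kind == "mass_action_rev") {
        dx[r$sub_i] <- dx[r$sub_i] - r$sub_n * v
        dx[r$prod_i] <- dx[r$prod_i] + r$prod_n * v
      } else {
        if (length(r$sub_i)) dx[r$sub_i] <- dx[r$sub_i] - r$sub_n * v
        if (length(r$prod_i)) dx[r$prod_i] <- dx[r$prod_i] + r$prod_n * v
      }
    }
    dx[clamped] <- 0
    list(dx)
  }

  list(ids = ids, x0 = x0, deriv = deriv, flux_one = flux_one, rxns = rxns)
}

#' Evaluate the flux of a single reaction
#'
#' Rate laws by kind, with `S` the sole substrate, `M_i` activator modifiers
#' and `I_j` inhibitor modifiers:
#' \describe{
#'   \item{smm_induced}{`v = Vmax * M/(Ka+M) * S/(Km+S)`; `Vmax` may be
#'     supplied as `kcat * [E]` through an enzyme modifier.}
#'   \item{smm_summed}{`v = sum_i Vmax_i * M_i/(Ka_i+M_i) * S/(Km+S)` —
#'     several activators drive the same step and their fluxes add.}
#'   \item{smm_inhibited}{`v = Vmax * S/(Km+S) * prod_j 1/(1+I_j/Ki_j)`
#'     (noncompetitive).}
#'   \item{mass_action_irrev / _rev}{`v = kf * prod [r]^stoich` minus
#'     `kr * prod [p]^stoich` for the reversible form.}
#'   \item{synthesis / degradation / secretion}{`kf` (scaled by the
#'     product's expression_scale), `kf*[S]`, and `kf*[S]` moving mass from
#'     cell to medium.}
#' }
#' When an enzyme modifier is declared the flux is additionally scaled by
#' that species' `activity_scale`.
#'
#' @param rxn An [reaction()] object.
#' @param state Named concentration vector covering all referenced species.
#' @param net Optional `pathway_network` supplying expression/activity
#'   scales; without it all scales are 1.
#' @return Flux in a.u./hour.
#' @export
reaction_flux <- function(rxn, state, net = NULL) {
  refs <- unique(c(names(rxn$substrates), names(rxn$products), names(rxn$modifiers)))
  missing <- setdiff(refs, names(state))
  if (length(missing))
    mcs_error(sprintf("state lacks species '%s'", missing[1]), "mcs_state_error")
  if (any(state < -1e-9))
    mcs_error("negative concentration beyond tolerance", "mcs_state_error")
  probs <- required_params(rxn)
  if (length(probs)) mcs_error(probs[1], "mcs_config_error")
  tmp <- if (is.null(net)) {
    sp <- lapply(names(state), function(id)
      species(id, role = "metabolite", initial_amount = max(state[[id]], 0)))
    pathway_network("tmp", sp, list(rxn))
  } else net
  comp <- compile_network(tmp)
  r <- Filter(function(z) z$id == rxn$id, comp$rxns)[[1]]
  unname(comp$flux_one(r, pmax(state[comp$ids], 0)))
}

#' Assemble the derivative function of a network
#'
#' Builds `dx/dt` over the state vector (species declaration order):
#' each species gains product-stoichiometry times flux and loses
#' substrate-stoichiometry times flux over all reactions; modifiers carry no
#' mass flux; clamped species are held at zero derivative. The returned
#' function is deterministic and side-effect free.
#'
#' @param net A `pathway_network`.
#' @return `function(t, x, parms)` in the form deSolve expects.
#' @export
assemble_derivatives <- function(net) compile_network(net)$deriv

#' Simulate a network to its culture endpoint
#'
#' Integrates the stiff ODE system with the implicit Radau method
#' ([deSolve::radau()]) and reports trajectories on the report grid plus the
#' endpoint. Readouts are taken at `t_end` regardless of steady state (the
#' culture endpoint, not equilibrium); `steady_state_reached` is reported
#' but not required.
#'
#' @param net A `pathway_network` (or `multicell_model`).
#' @param settings A [simulation_settings()] object.
#' @param perturbation Optional [agonist_dose()] applied before integration.
#' @return An object of class `"simulation_result"`: `times`,
#'   `trajectories` (time x species matrix), `endpoint` (named vector at
#'   `t_end`), `steady_state_reached`, `solver_stats`.
#' @export
simulate_network <- function(net, settings = simulation_settings(),
                             perturbation = NULL) {
  if (inherits(net, "multicell_model")) net <- net$network
  if (!is.null(perturbation)) net <- apply_agonist(net, perturbation)
  comp <- compile_network(net)
  times <- sort(unique(c(0, settings$report_grid[settings$report_grid <= settings$t_end],
                         settings$t_end)))
  out <- tryCatch(
    deSolve::radau(y = comp$x0, times = times, func = comp$deriv, parms = NULL,
                   rtol = settings$rtol, atol = settings$atol,
                   hmax = settings$max_step %||% settings$t_end),
    error = function(e) mcs_error(paste("solver failure:", conditionMessage(e)),
                                  "mcs_solver_error"))
  traj <- out[, -1, drop = FALSE]
  colnames(traj) <- comp$ids
  if (any(!is.finite(traj)))
    mcs_error("non-finite state in trajectory", "mcs_state_error")
  if (nrow(out) < length(times))
    mcs_error(sprintf("solver stopped early at t = %g h", out[nrow(out), 1]),
              "mcs_solver_error")
  endpoint <- traj[nrow(traj), ]
  d <- comp$deriv(settings$t_end, endpoint)[[1]]
  ss <- max(abs(d)) < settings$steady_state_tol * max(1, max(abs(endpoint)))
  diag <- attributes(out)
  structure(list(times = out[, 1], trajectories = traj, endpoint = endpoint,
                 steady_state_reached = ss,
                 solver_stats = diag$istate, settings = settings),
            class = "simulation_result")
}

#' @export
print.simulation_result <- function(x, ...) {
  cat(sprintf("<simulation_result: %d species, t = [%g, %g] h, steady state: %s>\n",
              ncol(x$trajectories), min(x$times), max(x$times),
              x$steady_state_reached))
  invisible(x)
}

#' Percent-change biomarker readout versus a control run
#'
#' For each marker, `percent_change = 100 * (perturbed - control) / control`.
#' When the control endpoint is at or below the floor `eps` the percent is
#' undefined (`NA`) and the trend falls back to the sign of the absolute
#' difference with dead-band `eps` — control networks can legitimately rest
#' at zero for inducible markers.
#'
#' @param control,perturbed `simulation_result`s from the same network
#'   topology and settings.
#' @param markers Species ids to read out.
#' @param theta Trend dead-band in percent (see [classify_trend()]).
#' @param eps Division floor, a.u.
#' @return Data frame of class `"marker_response"`: `marker`, `control`,
#'   `perturbed`, `percent_change`, `trend`.
#' @export
percent_change_readout <- function(control, perturbed, markers,
                                   theta = 5, eps = 1e-9) {
  if (!all(markers %in% colnames(control$trajectories)) ||
      !all(markers %in% colnames(perturbed$trajectories)))
    mcs_error(sprintf("unknown marker '%s'",
                      setdiff(markers, colnames(control$trajectories))[1]),
              "mcs_unknown_marker_error")
  ctrl <- control$endpoint[markers]
  pert <- perturbed$endpoint[markers]
  pct <- ifelse(ctrl > eps, 100 * (pert - ctrl) / ctrl, NA_real_)
  trend <- character(length(markers))
  defined <- !is.na(pct)
  trend[defined] <- classify_trend(pct[defined], theta)
  trend[!defined] <- ifelse(pert[!defined] - ctrl[!defined] > eps, "up",
                     ifelse(pert[!defined] - ctrl[!defined] < -eps, "down",
                            "no_change"))
  structure(data.frame(marker = markers, control = unname(ctrl),
                       perturbed = unname(pert), percent_change = unname(pct),
                       trend = trend, stringsAsFactors = FALSE),
            class = c("marker_response", "data.frame"), theta = theta, eps = eps)
}

#' Write marker responses as tidy CSV
#'
#' Columns: `cell_id`, `marker`, `control`, `perturbed`, `percent_change`,
#' `trend`, `t_end_hours`.
#'
#' @param responses A `marker_response` data frame.
#' @param path Output file.
#' @param cell_id Cell identifier column value.
#' @param t_end Endpoint time, hours.
#' @export
write_responses <- function(responses, path, cell_id = "cell", t_end = 64) {
  out <- cbind(cell_id = cell_id, responses, t_end_hours = t_end)
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
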