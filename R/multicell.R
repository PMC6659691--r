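#' Coupling map for multi-cell composition
#'
#' Describes how cells exchange signal through a shared, well-mixed medium:
#' secretions move marker mass from a cell into a medium species, uptakes
#' let a cell sense (default) or import a medium species, and medium
#' degradation bounds accumulation.
#'
#' @param secretions Data frame with columns `cell`, `species`
#'   (intracellular marker), `medium` (medium species id), `ks`
#'   (secretion rate, 1/hour).
#' @param uptakes Data frame with columns `medium`, `cell`, `species`
#'   (the cell's input ligand), `mode` (`"as_modifier"`: the ligand port
#'   senses the medium pool without consuming it; `"as_transport"`: mass
#'   moves medium to cell), optional `rate` (1/hour, transport only,
#'   default 1).
#' @param medium_degradation Named numeric, medium species -> first-order
#'   kd (1/hour).
#' @param volume_ratio Cell:medium volume ratio (dimensionless, default 1).
#' @return An object of class `"coupling_map"`.
#' @export
coupling_map <- function(secretions = NULL, uptakes = NULL,
                         medium_degradation = numeric(), volume_ratio = 1) {
  empty_sec <- data.frame(cell = character(), species = character(),
                          medium = character(), ks = numeric())
  empty_upt <- data.frame(medium = character(), cell = character(),
                          species = character(), mode = character(),
                          rate = numeric())
  secretions <- if (is.null(secretions)) empty_sec else
    as.data.frame(secretions, stringsAsFactors = FALSE)
  uptakes <- if (is.null(uptakes)) empty_upt else
    as.data.frame(uptakes, stringsAsFactors = FALSE)
  if (nrow(uptakes) && is.null(uptakes$rate)) uptakes$rate <- 1
  if (nrow(secretions) && any(secretions$ks < 0))
    mcs_error("secretion rates must be >= 0", "mcs_input_error")
  if (any(medium_degradation < 0))
    mcs_error("medium degradation rates must be >= 0", "mcs_input_error")
  if (nrow(uptakes) && !all(uptakes$mode %in% c("as_modifier", "as_transport")))
    mcs_error("uptake mode must be as_modifier or as_transport",
              "mcs_input_error")
  structure(list(secretions = secretions, uptakes = uptakes,
                 medium_degradation = medium_degradation,
                 volume_ratio = volume_ratio), class = "coupling_map")
}

ns_id <- function(cell_id, id) paste(cell_id, id, sep = ".")

#' Compose single-cell networks into a co-culture model
#'
#' Builds one simulatable system: per-cell species are namespaced as
#' `<cell_id>.<species_id>` and concatenated in cell order, followed by the
#' medium species (initially empty). Secretion reactions move mass cell to
#' medium scaled by the volume ratio; `as_modifier` uptakes append the
#' medium species as an additional modifier (with the ligand's own kinetic
#' constants) wherever the target ligand modifies a reaction, so the medium
#' pool drives the same receptor step additively and the composition
#' reduces exactly to isolated cells when the medium is empty;
#' `as_transport` uptakes move mass medium to cell. Autocrine loops are
#' permitted.
#'
#' @param cells List of `pathway_network`s with unique `cell_id`s.
#' @param coupling A [coupling_map()].
#' @return An object of class `"multicell_model"`: `network` (the composed
#'   `pathway_network`), `cells`, `coupling`, `medium_species`,
#'   `output_markers`.
#' @export
compose_coculture <- function(cells, coupling = coupling_map()) {
  cids <- vapply(cells, `[[`, "", "cell_id")
  if (anyDuplicated(cids))
    mcs_error("cell ids must be unique", "mcs_composition_error")
  lookup <- function(cell) {
    i <- match(cell, cids)
    if (is.na(i)) mcs_error(sprintf("coupling references unknown cell '%s'", cell),
                            "mcs_composition_error")
    cells[[i]]
  }
  check_sp <- function(cell, id) {
    if (!id %in% species_ids(lookup(cell)))
      mcs_error(sprintf("coupling references missing species '%s' in cell '%s'",
                        id, cell), "mcs_composition_error")
  }
  if (nrow(coupling$secretions))
    Map(check_sp, coupling$secretions$cell, coupling$secretions$species)
  if (nrow(coupling$uptakes))
    Map(check_sp, coupling$uptakes$cell, coupling$uptakes$species)

  all_species <- list(); all_rxns <- list()
  ports <- data.frame(species = character(), agonist = character())
  markers <- character()
  for (cell in cells) {
    for (s in cell$species) {
      s$id <- ns_id(cell$cell_id, s$id)
      all_species[[length(all_species) + 1L]] <- s
    }
    for (r in cell$reactions) {
      r$id <- ns_id(cell$cell_id, r$id)
      if (length(r$substrates))
        names(r$substrates) <- ns_id(cell$cell_id, names(r$substrates))
      if (length(r$products))
        names(r$products) <- ns_id(cell$cell_id, names(r$products))
      if (length(r$modifiers))
        names(r$modifiers) <- ns_id(cell$cell_id, names(r$modifiers))
      all_rxns[[length(all_rxns) + 1L]] <- r
    }
    if (nrow(cell$input_ports))
      ports <- rbind(ports, data.frame(
        species = ns_id(cell$cell_id, cell$input_ports$species),
        agonist = cell$input_ports$agonist))
    markers <- c(markers, ns_id(cell$cell_id, cell$output_markers))
  }

  medium_ids <- unique(c(coupling$secretions$medium, coupling$uptakes$medium,
                         names(coupling$medium_degradation)))
  for (m in medium_ids)
    all_species[[length(all_species) + 1L]] <-
      species(m, role = "secreted_marker", compartment = "medium")

  if (nrow(coupling$secretions))
    for (i in seq_len(nrow(coupling$secretions))) {
      sec <- coupling$secretions[i, ]
      all_rxns[[length(all_rxns) + 1L]] <- reaction(
        id = sprintf("sec.%s.%s", sec$cell, sec$species), kind = "secretion",
        substrates = stats::setNames(1, ns_id(sec$cell, sec$species)),
        products = stats::setNames(1, sec$medium),
        params = list(kf = sec$ks, vr = coupling$volume_ratio))
    }
  for (m in names(coupling$medium_degradation))
    all_rxns[[length(all_rxns) + 1L]] <- reaction(
      id = paste0("deg.", m), kind = "degradation",
      substrates = stats::setNames(1, m),
      params = list(kf = coupling$medium_degradation[[m]]))

  if (nrow(coupling$uptakes))
    for (i in seq_len(nrow(coupling$uptakes))) {
      up <- coupling$uptakes[i, ]
      ligand <- ns_id(up$cell, up$species)
      if (up$mode == "as_transport") {
        all_rxns[[length(all_rxns) + 1L]] <- reaction(
          id = sprintf("upt.%s.%s", up$cell, up$species),
          kind = "mass_action_irrev",
          substrates = stats::setNames(1, up$medium),
          products = stats::setNames(1, ligand),
          params = list(kf = up$rate %||% 1))
      } else {
        all_rxns <- graft_medium_modifier(all_rxns, ligand, up$medium, up$cell)
      }
    }

  net <- pathway_network(cell_id = paste(c(cids, "coculture"), collapse = "+"),
                         species = all_species, reactions = all_rxns,
                         input_ports = ports,
                         output_markers = c(markers, medium_ids))
  structure(list(network = net, cells = cells, coupling = coupling,
                 medium_species = medium_ids,
                 output_markers = c(markers, medium_ids)),
            class = "multicell_model")
}

## Append the medium species wherever `ligand` appears as a modifier in the
## target cell's reactions, duplicating the ligand's per-modifier kinetic
## constants; smm_induced is promoted to smm_summed (fluxes add).
graft_medium_modifier <- function(rxns, ligand, medium, cell) {
  prefix <- paste0(cell, ".")
  hit <- FALSE
  for (i in seq_along(rxns)) {
    r <- rxns[[i]]
    if (!startsWith(r$id, prefix)) next
    j <- match(ligand, names(r$modifiers))
    if (is.na(j)) next
    hit <- TRUE
    mode <- r$modifiers[[j]]
    if (mode == "activator" && r$kind == "smm_induced") {
      r$kind <- "smm_summed"
      r$params$Vmax <- rep(r$params$Vmax %||% r$params$kcat, 2)
      r$params$Ka <- rep(r$params$Ka, 2)
      r$params$kcat <- NULL
      r$modifiers <- c(r$modifiers, stats::setNames("activator", medium))
    } else if (mode == "activator" && r$kind == "smm_summed") {
      acts <- which(unname(r$modifiers) == "activator")
      pos <- match(j, acts)
      r$params$Vmax <- c(r$params$Vmax, r$params$Vmax[pos])
      r$params$Ka <- c(r$params$Ka, r$params$Ka[pos])
      r$modifiers <- c(r$modifiers, stats::setNames("activator", medium))
    } else if (mode == "inhibitor") {
      inhs <- which(unname(r$modifiers) == "inhibitor")
      pos <- match(j, inhs)
      r$params$Ki <- c(r$params$Ki, r$params$Ki[pos])
      r$modifiers <- c(r$modifiers, stats::setNames("inhibitor", medium))
    } else {
      mcs_error(sprintf("cannot graft medium '%s' onto reaction '%s' (%s)",
                        medium, r$id, r$kind), "mcs_composition_error")
    }
    rxns[[i]] <- r
  }
  if (!hit)
    mcs_error(sprintf("ligand '%s' is not a modifier of any reaction", ligand),
              "mcs_composition_error")
  rxns
}

#' @export
print.multicell_model <- function(x, ...) {
  cat(sprintf("<multicell_model: %d cells, %d medium species, state dim %d>\n",
              length(x$cells), length(x$medium_species),
              length(x$network$species)))
  invisible(x)
}

#' Staged feed-forward coupling: source endpoints feed a target cell
#'
#' Stage 1 simulates the source cells (with their secretions into the
#' medium) to the culture endpoint; stage 2 clamps the target cell's input
#' ligands at the resulting medium concentrations and simulates the target.
#' The control is the target fed with the endpoints of the *unperturbed*
#' sources, so the readout isolates the effect of the source perturbation
#' transmitted through secreted ligands.
#'
#' @param sources List of source `pathway_network`s (e.g. myeloma cells with
#'   genomic profiles applied).
#' @param target Target `pathway_network` (e.g. a dendritic cell).
#' @param coupling A [coupling_map()]: secretions describe source output
#'   into the medium, uptakes (rows whose `cell` is the target) map medium
#'   species onto the target's input-port ligands.
#' @param settings [simulation_settings()].
#' @param sources_control Unperturbed source list for the control stage;
#'   defaults to `sources` (yielding 0% change).
#' @param theta,eps Readout parameters, see [percent_change_readout()].
#' @return A `marker_response` data frame over the target's output markers.
#' @export
run_feedforward <- function(sources, target, coupling,
                            settings = simulation_settings(),
                            sources_control = sources, theta = 5, eps = 1e-9) {
  mapping <- coupling$uptakes[coupling$uptakes$cell == target$cell_id, , drop = FALSE]
  if (!nrow(mapping))
    mcs_error(sprintf("no uptake mapping into target '%s'", target$cell_id),
              "mcs_mapping_error")
  bad <- setdiff(mapping$species, target$input_ports$species)
  if (length(bad))
    mcs_error(sprintf("target '%s' has no input port species '%s'",
                      target$cell_id, bad[1]), "mcs_mapping_error")

  stage1 <- function(nets) {
    cm <- coupling_map(coupling$secretions, NULL, coupling$medium_degradation,
                       coupling$volume_ratio)
    model <- compose_coculture(nets, cm)
    sim <- simulate_network(model$network, settings)
    sim$endpoint[model$medium_species]
  }
  medium_pert <- stage1(sources)
  medium_ctrl <- stage1(sources_control)
  missing <- setdiff(mapping$medium, names(medium_pert))
  if (length(missing))
    mcs_error(sprintf("medium species '%s' not produced by any source",
                      missing[1]), "mcs_mapping_error")

  stage2 <- function(medium) {
    net <- target
    for (i in seq_len(nrow(mapping)))
      net <- modify_species(net, mapping$species[i],
                            initial_amount = unname(medium[mapping$medium[i]]),
                            expression_scale = 1, clamped = TRUE)
    simulate_network(net, settings)
  }
  percent_change_readout(stage2(medium_ctrl), stage2(medium_pert),
                         target$output_markers, theta = theta, eps = eps)
}
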