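SPECIES_ROLES <- c(
  "ligand", "receptor", "receptor_active", "g_protein_complex", "subunit",
  "enzyme", "enzyme_active", "adapter", "kinase", "transcription_factor",
  "tf_active", "metabolite", "secreted_marker"
)

REACTION_KINDS <- c(
  "smm_induced", "smm_summed", "smm_inhibited",
  "mass_action_irrev", "mass_action_rev",
  "synthesis", "degradation", "secretion"
)

MODIFIER_MODES <- c("activator", "inhibitor", "enzyme")

mcs_error <- function(msg, class, ...) {
  stop(errorCondition(msg, ..., class = c(class, "mcs_error")))
}

#' Create a network species
#'
#' A species is one state variable of the ODE system: a ligand, receptor,
#' enzyme, transcription factor, metabolite or secreted marker, living either
#' in a cell compartment (`cell:<id>`) or in the shared `medium`.
#'
#' @param id Short unique token used to reference the species in reactions.
#' @param name Free-text display name (defaults to `id`).
#' @param role One of the recognized species roles (see Details).
#' @param compartment `"cell:<cell_id>"` or `"medium"`.
#' @param initial_amount Initial concentration in arbitrary units (a.u.),
#'   non-negative.
#' @param expression_scale Dimensionless multiplier applied to the initial
#'   amount and to synthesis fluxes of this species (copy-number semantics).
#' @param activity_scale Dimensionless multiplier applied to fluxes this
#'   species catalyses (gain/loss-of-function semantics).
#' @param gene Optional gene symbol this species is a product of; genomic
#'   lesions are matched against it.
#' @param clamped If `TRUE` the species is held constant during integration
#'   (used for feed-forward inputs fixed at a source-culture endpoint).
#' @return An object of class `"mcs_species"`.
#' @export
species <- function(id, name = id, role, compartment = "cell:cell",
                    initial_amount = 0, expression_scale = 1,
                    activity_scale = 1, gene = NULL, clamped = FALSE) {
  if (!is.character(id) || length(id) != 1L || !nzchar(id))
    mcs_error("species id must be a non-empty string", "mcs_schema_error")
  if (!role %in% SPECIES_ROLES)
    mcs_error(sprintf("unknown species role '%s' for '%s'", role, id),
              "mcs_schema_error")
  if (!(identical(compartment, "medium") || grepl("^cell:", compartment)))
    mcs_error(sprintf("species '%s': compartment must be 'cell:<id>' or 'medium'", id),
              "mcs_schema_error")
  if (initial_amount < 0 || expression_scale < 0 || activity_scale < 0)
    mcs_error(sprintf("species '%s': amounts and scales must be >= 0", id),
              "mcs_schema_error")
  structure(list(id = id, name = name, role = role, compartment = compartment,
                 initial_amount = as.numeric(initial_amount),
                 expression_scale = as.numeric(expression_scale),
                 activity_scale = as.numeric(activity_scale),
                 gene = gene, clamped = isTRUE(clamped)),
            class = "mcs_species")
}

#' Create a reaction
#'
#' @param id Reaction token, unique within a network.
#' @param kind Rate-law kind, one of `smm_induced`, `smm_summed`,
#'   `smm_inhibited`, `mass_action_irrev`, `mass_action_rev`, `synthesis`,
#'   `degradation`, `secretion`.
#' @param substrates Named integer vector, species id -> stoichiometry.
#' @param products Named integer vector, species id -> stoichiometry.
#' @param modifiers Named character vector, species id -> mode
#'   (`activator`, `inhibitor` or `enzyme`). Modifiers carry no mass flux.
#' @param params Named list of kinetic parameters. Per kind:
#'   `smm_induced` needs `Km`, `Ka` and either `Vmax` or `kcat` (with an
#'   enzyme modifier); `smm_summed` needs vectors `Vmax`, `Ka` aligned with
#'   its activator modifiers plus scalar `Km`; `smm_inhibited` needs `Km`, a
#'   `Ki` per inhibitor and `Vmax` or `kcat`; mass-action kinds need `kf`
#'   (and `kr` for the reversible form); `synthesis`, `degradation` and
#'   `secretion` need `kf`. `secretion` accepts an optional volume ratio
#'   `vr` (cell:medium, default 1).
#' @param provenance Optional character vector of citation tokens; opaque
#'   bookkeeping, never resolved.
#' @return An object of class `"mcs_reaction"`.
#' @export
reaction <- function(id, kind, substrates = numeric(), products = numeric(),
                     modifiers = character(), params = list(),
                     provenance = NULL) {
  if (!kind %in% REACTION_KINDS)
    mcs_error(sprintf("reaction '%s': unknown rate-law kind '%s'", id, kind),
              "mcs_unsupported_kind_error")
  substrates <- as_stoich(substrates, id, "substrates")
  products <- as_stoich(products, id, "products")
  if (length(modifiers)) {
    if (is.null(names(modifiers)) || any(!nzchar(names(modifiers))))
      mcs_error(sprintf("reaction '%s': modifiers must be named by species", id),
                "mcs_schema_error")
    bad <- setdiff(unname(modifiers), MODIFIER_MODES)
    if (length(bad))
      mcs_error(sprintf("reaction '%s': unknown modifier mode '%s'", id, bad[1]),
                "mcs_schema_error")
  }
  params <- params[order(names(params))]  # canonical order for round-trips
  structure(list(id = id, kind = kind, substrates = substrates,
                 products = products, modifiers = modifiers,
                 params = params, provenance = provenance),
            class = "mcs_reaction")
}

as_stoich <- function(x, id, what) {
  if (!length(x)) return(stats::setNames(numeric(), character()))
  if (is.null(names(x)) || any(!nzchar(names(x))))
    mcs_error(sprintf("reaction '%s': %s must be named by species id", id, what),
              "mcs_schema_error")
  if (any(x <= 0) || any(x != round(x)))
    mcs_error(sprintf("reaction '%s': stoichiometries must be positive integers", id),
              "mcs_schema_error")
  stats::setNames(as.numeric(x), names(x))
}

#' Assemble a pathway network
#'
#' A pathway network is the static, typed species-reaction graph for one cell:
#' the state variables of the ODE system, the rate laws connecting them, the
#' agonist input ports and the biomarker output markers. Species declaration
#' order defines the state-vector order, so trajectories are reproducible and
#' diffable.
#'
#' @param cell_id Token naming the cell this network models.
#' @param species List of [species()] objects (order = state-vector order).
#' @param reactions List of [reaction()] objects.
#' @param input_ports Data frame with columns `species`, `agonist` mapping
#'   agonist names to ligand species.
#' @param output_markers Character vector of species ids read out as
#'   biomarkers.
#' @return An object of class `"pathway_network"`.
#' @export
pathway_network <- function(cell_id, species, reactions,
                            input_ports = data.frame(species = character(),
                                                     agonist = character()),
                            output_markers = character()) {
  ids <- vapply(species, `[[`, "", "id")
  if (anyDuplicated(ids))
    mcs_error(sprintf("duplicate species id '%s'", ids[duplicated(ids)][1]),
              "mcs_uniqueness_error")
  rids <- vapply(reactions, `[[`, "", "id")
  if (anyDuplicated(rids))
    mcs_error(sprintf("duplicate reaction id '%s'", rids[duplicated(rids)][1]),
              "mcs_uniqueness_error")
  for (rxn in reactions) {
    refs <- c(names(rxn$substrates), names(rxn$products), names(rxn$modifiers))
    missing <- setdiff(refs, ids)
    if (length(missing))
      mcs_error(sprintf("reaction '%s' references undeclared species '%s'",
                        rxn$id, missing[1]), "mcs_schema_error")
  }
  input_ports <- as.data.frame(input_ports, stringsAsFactors = FALSE)
  if (nrow(input_ports)) {
    bad <- setdiff(input_ports$species, ids)
    if (length(bad))
      mcs_error(sprintf("input port references undeclared species '%s'", bad[1]),
                "mcs_schema_error")
  }
  bad <- setdiff(output_markers, ids)
  if (length(bad))
    mcs_error(sprintf("output marker references undeclared species '%s'", bad[1]),
              "mcs_schema_error")
  structure(list(cell_id = cell_id, species = species, reactions = reactions,
                 input_ports = input_ports, output_markers = output_markers),
            class = "pathway_network")
}

#' @export
print.pathway_network <- function(x, ...) {
  cat(sprintf("<pathway_network '%s': %d species, %d reactions, %d input ports, %d markers>\n",
              x$cell_id, length(x$species), length(x$reactions),
              nrow(x$input_ports), length(x$output_markers)))
  invisible(x)
}

species_ids <- function(net) vapply(net$species, `[[`, "", "id")

species_field <- function(net, field) {
  stats::setNames(vapply(net$species, function(s) as.numeric(s[[field]]),
                         numeric(1)), species_ids(net))
}

get_species <- function(net, id) {
  i <- match(id, species_ids(net))
  if (is.na(i)) mcs_error(sprintf("no species '%s'", id), "mcs_schema_error")
  net$species[[i]]
}

get_reaction <- function(net, id) {
  i <- match(id, vapply(net$reactions, `[[`, "", "id"))
  if (is.na(i)) mcs_error(sprintf("no reaction '%s'", id), "mcs_schema_error")
  net$reactions[[i]]
}

modify_species <- function(net, id, ...) {
  i <- match(id, species_ids(net))
  changes <- list(...)
  for (f in names(changes)) net$species[[i]][[f]] <- changes[[f]]
  net
}

## ---- YAML schema -----------------------------------------------------------

TOP_KEYS <- c("cell_id", "species", "reactions", "inputs", "outputs")
SPECIES_KEYS <- c("id", "name", "role", "compartment", "initial_amount",
                  "expression_scale", "activity_scale", "gene", "clamped")
REACTION_KEYS <- c("id", "kind", "substrates", "products", "modifiers",
                   "params", "provenance")

check_keys <- function(x, allowed, where) {
  unknown <- setdiff(names(x), allowed)
  if (length(unknown))
    mcs_error(sprintf("unknown key '%s' in %s", unknown[1], where),
              "mcs_parse_error")
}

#' Parse a network document
#'
#' Reads the YAML network dialect (top-level keys `cell_id`, `species`,
#' `reactions`, `inputs`, `outputs`) into a [pathway_network()]. Parsing is
#' total: a document either yields a valid network or a located error;
#' unknown keys are rejected and species order is preserved as written.
#'
#' @param text A YAML document as a single string, or a file path when
#'   `is_file = TRUE`.
#' @param is_file Treat `text` as a path.
#' @return A `pathway_network`.
#' @seealso [serialize_network()] for the inverse; the pair is an identity
#'   on canonical documents.
#' @export
parse_network <- function(text, is_file = FALSE) {
  doc <- tryCatch(
    if (is_file) yaml::read_yaml(text) else yaml::yaml.load(text),
    error = function(e) mcs_error(paste("YAML error:", conditionMessage(e)),
                                  "mcs_parse_error"))
  if (!is.list(doc)) mcs_error("document is not a mapping", "mcs_parse_error")
  check_keys(doc, TOP_KEYS, "document")
  for (k in c("cell_id", "species", "reactions"))
    if (is.null(doc[[k]]))
      mcs_error(sprintf("missing required key '%s'", k), "mcs_parse_error")

  sp <- lapply(seq_along(doc$species), function(i) {
    s <- doc$species[[i]]
    check_keys(s, SPECIES_KEYS, sprintf("species[%d]", i))
    if (is.null(s$id) || is.null(s$role))
      mcs_error(sprintf("species[%d]: 'id' and 'role' are required", i),
                "mcs_parse_error")
    species(id = s$id, name = s$name %||% s$id, role = s$role,
            compartment = s$compartment %||% paste0("cell:", doc$cell_id),
            initial_amount = s$initial_amount %||% 0,
            expression_scale = s$expression_scale %||% 1,
            activity_scale = s$activity_scale %||% 1,
            gene = s$gene, clamped = s$clamped %||% FALSE)
  })

  rx <- lapply(seq_along(doc$reactions), function(i) {
    r <- doc$reactions[[i]]
    check_keys(r, REACTION_KEYS, sprintf("reactions[%d]", i))
    if (is.null(r$id) || is.null(r$kind))
      mcs_error(sprintf("reactions[%d]: 'id' and 'kind' are required", i),
                "mcs_parse_error")
    reaction(id = r$id, kind = r$kind,
             substrates = pairs_to_stoich(r$substrates, r$id),
             products = pairs_to_stoich(r$products, r$id),
             modifiers = pairs_to_modifiers(r$modifiers, r$id),
             params = lapply(r$params %||% list(), as.numeric),
             provenance = if (length(r$provenance)) as.character(r$provenance))
  })

  ports <- if (length(doc$inputs)) {
    data.frame(species = vapply(doc$inputs, `[[`, "", "species"),
               agonist = vapply(doc$inputs, `[[`, "", "agonist"),
               stringsAsFactors = FALSE)
  } else data.frame(species = character(), agonist = character())

  pathway_network(cell_id = doc$cell_id, species = sp, reactions = rx,
                  input_ports = ports,
                  output_markers = as.character(doc$outputs %||% character()))
}

pairs_to_stoich <- function(x, rid) {
  if (!length(x)) return(numeric())
  stats::setNames(vapply(x, function(p) as.numeric(p$stoich %||% 1), numeric(1)),
                  vapply(x, function(p) {
                    if (is.null(p$species))
                      mcs_error(sprintf("reaction '%s': entry missing 'species'", rid),
                                "mcs_parse_error")
                    p$species
                  }, ""))
}

pairs_to_modifiers <- function(x, rid) {
  if (!length(x)) return(character())
  stats::setNames(vapply(x, function(p) p$mode %||% "activator", ""),
                  vapply(x, `[[`, "", "species"))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Serialize a network to its canonical YAML document
#'
#' The canonical form writes keys in a fixed order and omits defaulted
#' fields, so `serialize(parse(serialize(net)))` is byte-identical to
#' `serialize(net)`.
#'
#' @param net A `pathway_network`.
#' @return A single YAML string.
#' @export
serialize_network <- function(net) {
  sp <- lapply(net$species, function(s) {
    out <- list(id = s$id, name = s$name, role = s$role,
                compartment = s$compartment,
                initial_amount = s$initial_amount)
    if (s$expression_scale != 1) out$expression_scale <- s$expression_scale
    if (s$activity_scale != 1) out$activity_scale <- s$activity_scale
    if (!is.null(s$gene)) out$gene <- s$gene
    if (s$clamped) out$clamped <- TRUE
    out
  })
  rx <- lapply(net$reactions, function(r) {
    out <- list(id = r$id, kind = r$kind)
    if (length(r$substrates))
      out$substrates <- unname(Map(function(sp, st) list(species = sp, stoich = st),
                                   names(r$substrates), r$substrates))
    if (length(r$products))
      out$products <- unname(Map(function(sp, st) list(species = sp, stoich = st),
                                 names(r$products), r$products))
    if (length(r$modifiers))
      out$modifiers <- unname(Map(function(sp, m) list(species = sp, mode = m),
                                  names(r$modifiers), r$modifiers))
    out$params <- r$params[order(names(r$params))]
    if (!is.null(r$provenance)) out$provenance <- as.list(r$provenance)
    out
  })
  doc <- list(cell_id = net$cell_id, species = sp, reactions = rx)
  if (nrow(net$input_ports))
    doc$inputs <- unname(Map(function(sp, ag) list(species = sp, agonist = ag),
                             net$input_ports$species, net$input_ports$agonist))
  if (length(net$output_markers)) doc$outputs <- as.list(net$output_markers)
  yaml::as.yaml(doc, precision = 15L)
}

## ---- validation ------------------------------------------------------------

required_params <- function(rxn) {
  modes <- unname(rxn$modifiers)
  n_act <- sum(modes == "activator")
  n_inh <- sum(modes == "inhibitor")
  n_enz <- sum(modes == "enzyme")
  p <- rxn$params
  has <- function(nm, len = 1L) {
    !is.null(p[[nm]]) && length(p[[nm]]) == len && all(p[[nm]] > 0)
  }
  probs <- character()
  add <- function(msg) probs <<- c(probs, sprintf("reaction '%s': %s", rxn$id, msg))
  vmax_or_kcat <- function() {
    if (!(has("Vmax") || (has("kcat") && n_enz == 1L)))
      add("needs Vmax, or kcat with one enzyme modifier")
  }
  switch(rxn$kind,
    smm_induced = {
      if (length(rxn$substrates) != 1L) add("smm_induced needs exactly one substrate")
      if (!has("Km")) add("missing positive Km")
      if (n_act == 1L) {        # inducer-gated form
        if (!has("Ka")) add("missing positive Ka")
        vmax_or_kcat()
      } else if (n_act == 0L) { # plain enzyme Michaelis-Menten form
        if (!(has("kcat") && n_enz == 1L))
          add("without an activator, smm_induced needs kcat and one enzyme modifier")
      } else add("smm_induced takes at most one activator modifier")
    },
    smm_summed = {
      if (length(rxn$substrates) != 1L) add("smm_summed needs exactly one substrate")
      if (n_act < 2L) add("smm_summed needs >= 2 activator modifiers")
      if (!has("Km")) add("missing positive Km")
      if (!has("Vmax", n_act)) add(sprintf("needs Vmax vector of length %d", n_act))
      if (!has("Ka", n_act)) add(sprintf("needs Ka vector of length %d", n_act))
    },
    smm_inhibited = {
      if (length(rxn$substrates) != 1L) add("smm_inhibited needs exactly one substrate")
      if (n_inh < 1L) add("smm_inhibited needs >= 1 inhibitor modifier")
      if (!has("Km")) add("missing positive Km")
      if (!has("Ki", n_inh)) add(sprintf("needs Ki vector of length %d", n_inh))
      vmax_or_kcat()
    },
    mass_action_irrev = {
      if (length(rxn$substrates) < 1L) add("needs >= 1 substrate")
      if (!has("kf")) add("missing positive kf")
    },
    mass_action_rev = {
      if (length(rxn$substrates) < 1L || length(rxn$products) < 1L)
        add("needs substrates and products")
      if (!has("kf")) add("missing positive kf")
      if (!has("kr")) add("missing positive kr")
    },
    synthesis = {
      if (length(rxn$products) < 1L) add("synthesis needs >= 1 product")
      if (length(rxn$substrates)) add("synthesis takes no substrates")
      if (!has("kf")) add("missing positive kf")
    },
    degradation = {
      if (length(rxn$substrates) != 1L) add("degradation needs exactly one substrate")
      if (!has("kf")) add("missing positive kf")
    },
    secretion = {
      if (length(rxn$substrates) != 1L || length(rxn$products) != 1L)
        add("secretion needs one substrate and one product")
      if (!has("kf")) add("missing positive kf")
    })
  probs
}

#' Validate a pathway network
#'
#' Reporting operation (never throws): checks output-marker reachability from
#' the input ports, orphan species, per-kind kinetic-parameter completeness,
#' and lists conservation-moiety candidates (closed mass-action cycles found
#' by exact integer null-space elimination, confirmed against every
#' mass-conserving conversion reaction).
#'
#' A network with an empty violation report assembles into an ODE system
#' without missing-symbol errors.
#'
#' @param net A `pathway_network`.
#' @return A list of class `"network_diagnostics"` with elements
#'   `violations` (character vector, empty when all invariants hold) and
#'   `moieties` (integer matrix, one column per confirmed conserved moiety,
#'   rows named by species).
#' @export
validate_network <- function(net) {
  violations <- character()
  ids <- species_ids(net)

  for (rxn in net$reactions) violations <- c(violations, required_params(rxn))

  ## reachability over activation edges (substrates, activator/enzyme
  ## modifiers -> reaction -> products); inhibitor arms do not propagate
  ## activating signal
  if (length(net$output_markers)) {
    g <- influence_graph(net)
    constitutive <- unlist(lapply(net$reactions, function(r)
      if (r$kind == "synthesis") names(r$products)))
    roots <- unique(c(net$input_ports$species, constitutive))
    reach <- unique(unlist(lapply(paste0("s:", roots),
      function(v) {
        if (!v %in% igraph::V(g)$name) return(character())
        names(igraph::subcomponent(g, v, mode = "out"))
      })))
    for (m in net$output_markers)
      if (!paste0("s:", m) %in% reach)
        violations <- c(violations,
          sprintf("output marker '%s' unreachable from any input port or constitutive source", m))
  }

  used <- unique(unlist(lapply(net$reactions, function(r)
    c(names(r$substrates), names(r$products), names(r$modifiers)))))
  orphan <- setdiff(ids, c(used, net$input_ports$species, net$output_markers))
  for (o in orphan)
    violations <- c(violations, sprintf("orphan species '%s' (unreferenced)", o))

  structure(list(violations = violations, moieties = conserved_moieties(net)),
            class = "network_diagnostics")
}

#' @export
print.network_diagnostics <- function(x, ...) {
  if (!length(x$violations)) cat("network OK: no violations\n")
  else cat(sprintf("%d violation(s):\n", length(x$violations)),
           paste0("  - ", x$violations, "\n"), sep = "")
  if (ncol(x$moieties))
    cat(sprintf("%d conserved moiety candidate(s)\n", ncol(x$moieties)))
  invisible(x)
}

influence_graph <- function(net) {
  edges <- character()
  for (rxn in net$reactions) {
    rv <- paste0("r:", rxn$id)
    for (s in names(rxn$substrates)) edges <- c(edges, paste0("s:", s), rv)
    mods <- rxn$modifiers[rxn$modifiers %in% c("activator", "enzyme")]
    for (s in names(mods)) edges <- c(edges, paste0("s:", s), rv)
    for (s in names(rxn$products)) edges <- c(edges, rv, paste0("s:", s))
  }
  verts <- unique(c(paste0("s:", species_ids(net)),
                    paste0("r:", vapply(net$reactions, `[[`, "", "id")), edges))
  igraph::graph_from_edgelist(matrix(edges, ncol = 2, byrow = TRUE)) |>
    igraph::add_vertices(0) -> g
  missing <- setdiff(verts, igraph::V(g)$name)
  if (length(missing)) g <- igraph::add_vertices(g, length(missing), name = missing)
  g
}

## stoichiometric matrix (species x reactions), optionally restricted by kind
stoich_matrix <- function(net, kinds = REACTION_KINDS) {
  ids <- species_ids(net)
  keep <- Filter(function(r) r$kind %in% kinds, net$reactions)
  S <- matrix(0, length(ids), length(keep),
              dimnames = list(ids, vapply(keep, `[[`, "", "id")))
  for (j in seq_along(keep)) {
    r <- keep[[j]]
    for (s in names(r$substrates)) S[s, j] <- S[s, j] - r$substrates[[s]]
    for (s in names(r$products)) S[s, j] <- S[s, j] + r$products[[s]]
  }
  S
}

#' Detect conserved moieties
#'
#' Candidates come from the exact integer left null space of the
#' stoichiometric matrix restricted to mass-action reactions (and to species
#' that participate in at least one); each candidate is then confirmed
#' against every conversion reaction (everything except synthesis,
#' degradation and secretion), so a reported moiety is constant along any
#' trajectory in which those boundary fluxes are disabled.
#'
#' @param net A `pathway_network`.
#' @return Integer matrix, species x moieties (possibly zero columns).
#' @export
conserved_moieties <- function(net) {
  ids <- species_ids(net)
  S_ma <- stoich_matrix(net, c("mass_action_irrev", "mass_action_rev"))
  empty <- matrix(0L, length(ids), 0, dimnames = list(ids, NULL))
  if (!ncol(S_ma)) return(empty)
  active <- rowSums(S_ma != 0) > 0
  if (!any(active)) return(empty)
  basis <- int_nullspace(t(S_ma[active, , drop = FALSE]))
  if (!ncol(basis)) return(empty)
  full <- matrix(0L, length(ids), ncol(basis), dimnames = list(ids, NULL))
  full[active, ] <- basis
  S_conv <- stoich_matrix(net, setdiff(REACTION_KINDS,
                                       c("synthesis", "degradation", "secretion")))
  ok <- apply(full, 2, function(y) all(crossprod(y, S_conv) == 0))
  full[, ok, drop = FALSE]
}

## exact integer right null space of an integer matrix A (n x m): basis of
## {y : A y = 0}, via rational Gauss-Jordan elimination kept exact with
## numerator/denominator integer arithmetic (entries are small stoichiometries)
int_nullspace <- function(A) {
  n <- nrow(A); m <- ncol(A)
  num <- matrix(as.numeric(A), n, m)
  den <- matrix(1, n, m)
  gcd <- function(a, b) { a <- abs(a); b <- abs(b)
    while (b > 0) { t <- a %% b; a <- b; b <- t }; max(a, 1) }
  reduce <- function(i) {
    for (j in seq_len(m)) {
      g <- gcd(num[i, j], den[i, j])
      num[i, j] <<- num[i, j] / g; den[i, j] <<- den[i, j] / g
      if (den[i, j] < 0) { num[i, j] <<- -num[i, j]; den[i, j] <<- -den[i, j] }
    }
  }
  pivots <- integer(0); row <- 1L
  for (col in seq_len(m)) {
    if (row > n) break
    p <- which(num[row:n, col] != 0)
    if (!length(p)) next
    p <- p[1] + row - 1L
    if (p != row) { num[c(p, row), ] <- num[c(row, p), ]; den[c(p, row), ] <- den[c(row, p), ] }
    ## scale pivot row to leading 1
    pn <- num[row, col]; pd <- den[row, col]
    num[row, ] <- num[row, ] * pd; den[row, ] <- den[row, ] * pn
    reduce(row)
    for (i in seq_len(n)) {
      if (i == row || num[i, col] == 0) next
      f_n <- num[i, col]; f_d <- den[i, col]
      ## row_i <- row_i - f * row_row
      for (j in seq_len(m)) {
        a_n <- num[i, j] * f_d * den[row, j] - f_n * num[row, j] * den[i, j]
        a_d <- den[i, j] * f_d * den[row, j]
        num[i, j] <- a_n; den[i, j] <- a_d
      }
      reduce(i)
    }
    pivots <- c(pivots, col); row <- row + 1L
  }
  free <- setdiff(seq_len(m), pivots)
  if (!length(free)) return(matrix(0L, m, 0))
  basis <- sapply(free, function(f) {
    y_n <- numeric(m); y_d <- rep(1, m)
    y_n[f] <- 1
    for (r in seq_along(pivots)) {
      y_n[pivots[r]] <- -num[r, f]; y_d[pivots[r]] <- den[r, f]
    }
    L <- Reduce(function(a, b) a * b / gcd(a, b), y_d, accumulate = FALSE)
    y <- y_n * (L / y_d)
    g <- Reduce(gcd, y[y != 0], accumulate = FALSE)
    y <- y / max(g, 1)
    lead <- y[which(y != 0)[1]]
    if (!is.na(lead) && lead < 0) y <- -y
    y
  })
  matrix(as.integer(round(basis)), m, length(free))
}
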