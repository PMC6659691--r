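#' Agonist dose
#'
#' @param agonist Agonist name (e.g. `"LPS"`, `"Pam3CSK4"`, `"IFNG"`,
#'   `"PGE2"`), resolved against the network's input ports.
#' @param dose Dose in ug/ml (or a.u.), non-negative.
#' @param conversion Concentration per dose unit (a.u. per ug/ml, default 1).
#' @return An object of class `"agonist_dose"`.
#' @export
agonist_dose <- function(agonist, dose, conversion = 1) {
  if (dose < 0) mcs_error("dose must be >= 0", "mcs_input_error")
  structure(list(agonist = agonist, dose = dose, conversion = conversion),
            class = "agonist_dose")
}

#' Apply an agonist dose to a network
#'
#' Sets the initial amount of every input-port ligand mapped to the agonist
#' (one port per cell) to `dose * conversion`. The input network is left
#' untouched; a zero dose returns a network identical to the control.
#'
#' @param net A `pathway_network`.
#' @param dose An [agonist_dose()].
#' @return A perturbed copy of `net`.
#' @export
apply_agonist <- function(net, dose) {
  ports <- net$input_ports[net$input_ports$agonist == dose$agonist, , drop = FALSE]
  if (!nrow(ports))
    mcs_error(sprintf("cell '%s' has no input port for agonist '%s'",
                      net$cell_id, dose$agonist), "mcs_port_error")
  for (sp in ports$species)
    net <- modify_species(net, sp, initial_amount = dose$dose * dose$conversion)
  net
}

#' Genomic lesion record
#'
#' One mutated or copy-number-altered gene with the external predictor calls
#' consumed as input (the prediction algorithms themselves are published
#' third-party tools and are not run here).
#'
#' @param gene Gene symbol.
#' @param variant Variant label (free text), used for effect-library lookup.
#' @param gene_class `"oncogene"`, `"tumor_suppressor"` or `"other"`.
#' @param predictor_calls Named character vector, predictor name ->
#'   `"deleterious"`, `"neutral"` or `"unknown"`.
#' @param library_effect Optional effect call carried on the record itself.
#' @param cnv `"none"`, `"amplification"` or `"deletion"`.
#' @return An object of class `"mutation_record"`.
#' @export
mutation_record <- function(gene, variant = "", gene_class = "other",
                            predictor_calls = character(),
                            library_effect = NULL, cnv = "none") {
  if (!gene_class %in% c("oncogene", "tumor_suppressor", "other"))
    mcs_error("gene_class must be oncogene/tumor_suppressor/other",
              "mcs_input_error")
  if (!cnv %in% c("none", "amplification", "deletion"))
    mcs_error("cnv must be none/amplification/deletion", "mcs_input_error")
  if (!length(predictor_calls) && is.null(library_effect) && cnv == "none")
    mcs_error("record needs predictor calls, a library effect, or a CNV",
              "mcs_input_error")
  bad <- setdiff(predictor_calls, c("deleterious", "neutral", "unknown"))
  if (length(bad))
    mcs_error(sprintf("unknown predictor call '%s'", bad[1]), "mcs_input_error")
  structure(list(gene = gene, variant = variant, gene_class = gene_class,
                 predictor_calls = predictor_calls,
                 library_effect = library_effect, cnv = cnv),
            class = "mutation_record")
}

#' Learnt mutation-effect library
#'
#' Deterministic gene+variant -> effect lookup; a missing key signals
#' absence (falling through to the predictor consensus), never an error.
#'
#' @param genes,variants,effects Parallel character vectors.
#' @return An object of class `"effect_library"`.
#' @export
effect_library <- function(genes = character(), variants = character(),
                           effects = character()) {
  stopifnot(length(genes) == length(variants), length(genes) == length(effects))
  structure(list(map = stats::setNames(as.character(effects),
                                       paste(genes, variants, sep = "|"))),
            class = "effect_library")
}

#' Read an effect library from a two-column-plus CSV
#'
#' Expects columns `gene`, `variant`, `effect`.
#' @param path CSV path.
#' @return An `effect_library`.
#' @export
read_effect_library <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  effect_library(df$gene, df$variant, df$effect)
}

library_lookup <- function(lib, gene, variant) {
  if (is.null(lib)) return(NULL)
  hit <- lib$map[paste(gene, variant, sep = "|")]
  if (is.na(hit)) NULL else unname(hit)
}

#' Consensus mutation effect
#'
#' The effect library wins outright when it has the gene+variant; otherwise
#' a strict majority vote over the non-unknown predictor calls decides, and
#' a tie (or no informative calls) yields `"unknown"`.
#'
#' @param rec A [mutation_record()].
#' @param lib Optional [effect_library()].
#' @return `"deleterious"`, `"neutral"` or `"unknown"`.
#' @export
consensus_effect <- function(rec, lib = NULL) {
  hit <- library_lookup(lib, rec$gene, rec$variant) %||% rec$library_effect
  if (!is.null(hit)) return(hit)
  calls <- rec$predictor_calls[rec$predictor_calls != "unknown"]
  if (!length(calls)) return("unknown")
  del <- sum(calls == "deleterious"); neu <- sum(calls == "neutral")
  if (del > neu) "deleterious" else if (neu > del) "neutral" else "unknown"
}

#' Genomic profile
#'
#' A cell line's lesion set plus the scale policy translating lesion calls
#' into network multipliers. The directions are the modeled claim —
#' oncogene gain-of-function and tumor-suppressor loss-of-function act at
#' the activity level, CNVs at the expression level; the magnitudes are
#' configurable policy.
#'
#' @param id Profile identifier (e.g. `"MM.1S-like"`).
#' @param records List of [mutation_record()]s.
#' @param gain Gain-of-function activity multiplier (> 1, default 2).
#' @param loss Loss-of-function activity multiplier (in `[0, 1)`, default 0).
#' @param amplification Expression multiplier for amplifications (> 1,
#'   default 2).
#' @return An object of class `"genomic_profile"`.
#' @export
genomic_profile <- function(id, records, gain = 2, loss = 0, amplification = 2) {
  if (gain <= 1 || loss < 0 || loss >= 1 || amplification <= 1)
    mcs_error("need gain > 1, 0 <= loss < 1, amplification > 1",
              "mcs_input_error")
  structure(list(id = id, records = records, gain = gain, loss = loss,
                 amplification = amplification), class = "genomic_profile")
}

#' Apply a genomic profile to a network
#'
#' For each record whose consensus effect is deleterious: oncogenes multiply
#' `activity_scale` by the gain factor and tumor suppressors by the loss
#' factor, on every species annotated with the gene; neutral or unknown
#' effects are skipped (and reported). Independently, CNV amplification
#' multiplies `expression_scale` by the amplification factor and CNV
#' deletion zeroes it. Genes without matching species produce a warning row
#' in the report, not an error.
#'
#' @param net A `pathway_network`.
#' @param profile A [genomic_profile()].
#' @param lib Optional [effect_library()].
#' @return List: `network` (perturbed copy) and `report` (data frame with
#'   one row per record: gene, variant, effect, action).
#' @export
apply_genomic_profile <- function(net, profile, lib = NULL) {
  genes <- vapply(net$species, function(s) s$gene %||% NA_character_, "")
  ids <- species_ids(net)
  rows <- list()
  for (rec in profile$records) {
    targets <- ids[!is.na(genes) & genes == rec$gene]
    effect <- consensus_effect(rec, lib)
    actions <- character()
    if (!length(targets)) {
      actions <- "warning: no species for gene"
    } else {
      has_mutation <- length(rec$predictor_calls) > 0 ||
        !is.null(rec$library_effect) ||
        !is.null(library_lookup(lib, rec$gene, rec$variant))
      if (has_mutation) {
        if (effect == "deleterious") {
          if (rec$gene_class == "oncogene") {
            for (t in targets) net <- modify_species(net, t,
              activity_scale = get_species(net, t)$activity_scale * profile$gain)
            actions <- c(actions, sprintf("activity_scale x%g (gain of function)",
                                          profile$gain))
          } else if (rec$gene_class == "tumor_suppressor") {
            for (t in targets) net <- modify_species(net, t,
              activity_scale = get_species(net, t)$activity_scale * profile$loss)
            actions <- c(actions, sprintf("activity_scale x%g (loss of function)",
                                          profile$loss))
          } else actions <- c(actions, "skipped: gene_class 'other'")
        } else actions <- c(actions, paste0("skipped: ", effect))
      }
      if (rec$cnv == "amplification") {
        for (t in targets) net <- modify_species(net, t,
          expression_scale = get_species(net, t)$expression_scale * profile$amplification)
        actions <- c(actions, sprintf("expression_scale x%g (amplification)",
                                      profile$amplification))
      } else if (rec$cnv == "deletion") {
        for (t in targets) net <- modify_species(net, t, expression_scale = 0)
        actions <- c(actions, "expression_scale = 0 (deletion)")
      }
      if (!length(actions)) actions <- "no action"
    }
    rows[[length(rows) + 1L]] <- data.frame(
      gene = rec$gene, variant = rec$variant, effect = effect,
      action = paste(actions, collapse = "; "), stringsAsFactors = FALSE)
  }
  list(network = net, report = do.call(rbind, rows) %||%
         data.frame(gene = character(), variant = character(),
                    effect = character(), action = character()))
}

#' Read a genomic profile from CSV
#'
#' Columns: `gene`, `variant`, `gene_class`, `cnv`, plus one column per
#' predictor whose values are `deleterious`/`neutral`/`unknown`.
#'
#' @param path CSV path.
#' @param id Profile id (defaults to the file name).
#' @param ... Scale-policy arguments passed to [genomic_profile()].
#' @return A `genomic_profile`.
#' @export
read_genomic_profile <- function(path, id = basename(path), ...) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  fixed <- c("gene", "variant", "gene_class", "cnv")
  predictors <- setdiff(names(df), fixed)
  records <- lapply(seq_len(nrow(df)), function(i) {
    calls <- stats::setNames(as.character(df[i, predictors]), predictors)
    calls <- calls[!is.na(calls) & nzchar(calls)]
    mutation_record(gene = df$gene[i], variant = df$variant[i] %||% "",
                    gene_class = df$gene_class[i],
                    predictor_calls = calls, cnv = df$cnv[i])
  })
  genomic_profile(id, records, ...)
}
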