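#' Construct a constraint-based metabolic network
#'
#' The container used by all stoichiometric analyses: a dense metabolite
#' x reaction stoichiometric matrix, flux bounds (mmol gDW^-1 h^-1;
#' biomass flux in h^-1), per-reaction source-organism tags, and
#' identified biomass/objective reactions. Exchange reactions are
#' reactions touching exactly one metabolite (negative coefficient =
#' species leaves the system when flux is positive... by convention here
#' an exchange `met ->` with coefficient -1 exports at positive flux and
#' imports at negative flux).
#'
#' @param id model identifier.
#' @param metabolites data frame with columns `id`, `formula`,
#'   `compartment` (optional `name`).
#' @param reactions data frame with columns `id`, `lower_bound`,
#'   `upper_bound` and optionally `name`, `source_organism` (default the
#'   model `id`).
#' @param stoich dense numeric matrix, metabolites x reactions, with
#'   dimnames matching the `id` columns.
#' @param biomass_id id of the biomass reaction (may be `NA`, with a
#'   warning, for partial models).
#' @param objective_id id of the objective reaction (default: biomass).
#' @return object of class `metabolic_network`.
#' @export
metabolic_network <- function(id, metabolites, reactions, stoich,
                              biomass_id, objective_id = biomass_id) {
  stopifnot(is.data.frame(metabolites), is.data.frame(reactions))
  if (!"formula" %in% names(metabolites)) metabolites$formula <- NA_character_
  if (!"compartment" %in% names(metabolites)) metabolites$compartment <- "c"
  if (!"source_organism" %in% names(reactions))
    reactions$source_organism <- id
  if (anyDuplicated(reactions$id))
    stop("duplicated reaction ids", call. = FALSE)
  if (anyDuplicated(metabolites$id))
    stop("duplicated metabolite ids", call. = FALSE)
  stoich <- as.matrix(stoich)
  if (!identical(rownames(stoich), metabolites$id) ||
      !identical(colnames(stoich), reactions$id))
    stop("stoich dimnames must match metabolite/reaction ids", call. = FALSE)
  if (any(reactions$lower_bound > reactions$upper_bound))
    stop("lower bound exceeds upper bound", call. = FALSE)
  reactions$exchange <- colSums(stoich != 0) == 1L
  if (is.na(biomass_id) || !biomass_id %in% reactions$id) {
    warning("biomass reaction not found; objective unset")
    biomass_id <- NA_character_
    if (!isTRUE(objective_id %in% reactions$id)) objective_id <- NA_character_
  }
  structure(
    list(id = id, metabolites = metabolites, reactions = reactions,
         stoich = stoich, biomass_id = biomass_id,
         objective_id = objective_id),
    class = "metabolic_network")
}

#' @export
print.metabolic_network <- function(x, ...) {
  cat(sprintf(
    "<metabolic_network> %s: %d metabolites, %d reactions (%d exchange)\n",
    x$id, nrow(x$metabolites), nrow(x$reactions),
    sum(x$reactions$exchange)))
  cat(sprintf("  biomass: %s, objective: %s\n", x$biomass_id, x$objective_id))
  invisible(x)
}

#' Number of carbon atoms in a metabolite formula
#'
#' Parses standard Hill-notation formulas (`C6H12O6`, `H2O`, `CO2`).
#'
#' @param formula character vector of formulas.
#' @return integer vector of carbon counts.
#' @export
carbon_content <- function(formula) {
  vapply(formula, function(f) {
    if (is.na(f) || !nzchar(f))
      stop("missing metabolite formula", call. = FALSE)
    el <- parse_formula(f)
    as.integer(el["C"] %||% 0L)
  }, integer(1), USE.NAMES = FALSE)
}

`%||%` <- function(a, b) if (is.null(a) || is.na(a)) b else a

#' @noRd
parse_formula <- function(f) {
  m <- gregexpr("([A-Z][a-z]?)([0-9]*)", f)[[1]]
  parts <- regmatches(f, list(m))[[1]]
  parts <- parts[nzchar(parts)]
  if (!length(parts) || paste(parts, collapse = "") != f)
    stop("unparseable formula: ", f, call. = FALSE)
  el <- sub("[0-9]*$", "", parts)
  cnt <- as.numeric(ifelse(grepl("[0-9]+$", parts),
                           sub("^[A-Za-z]+", "", parts), "1"))
  tapply(cnt, el, sum)
}

# Standard atomic weights (g/mol), enough for common biochemistry.
.atomic_weights <- c(
  C = 12.011, H = 1.008, O = 15.999, N = 14.007, P = 30.974, S = 32.06,
  Fe = 55.845, Mg = 24.305, K = 39.098, Na = 22.99, Ca = 40.078,
  Cl = 35.45, Zn = 65.38, Mn = 54.938, Co = 58.933, Cu = 63.546,
  Mo = 95.95, Se = 78.971, Ni = 58.693, W = 183.84)

#' Molecular weight (g/mol) from a formula
#' @param formula character vector of Hill-notation formulas.
#' @return numeric vector of molecular weights.
#' @export
molecular_weight <- function(formula) {
  vapply(formula, function(f) {
    el <- parse_formula(f)
    w <- .atomic_weights[names(el)]
    if (anyNA(w))
      stop("unknown element(s) in formula ", f, ": ",
           paste(names(el)[is.na(w)], collapse = ", "), call. = FALSE)
    sum(w * el)
  }, numeric(1), USE.NAMES = FALSE)
}

#' Read a constraint-based model (JSON dialect or SBML L3 FBC)
#'
#' The native on-disk format is the widely used constraint-based JSON
#' schema (top-level `metabolites`, `reactions`, each reaction carrying a
#' `metabolites` coefficient map and `lower_bound`/`upper_bound`); SBML
#' Level 3 with the FBC extension is imported into the same container.
#'
#' @param path file path.
#' @param format `"json"`, `"sbml"`, or `"auto"` (default: by file
#'   extension).
#' @param source_organism optional tag applied to all reactions
#'   (overrides file metadata).
#' @return a [metabolic_network()].
#' @export
read_model <- function(path, format = c("auto", "json", "sbml"),
                       source_organism = NULL) {
  format <- match.arg(format)
  if (format == "auto")
    format <- if (grepl("\\.(xml|sbml)$", path, ignore.case = TRUE))
      "sbml" else "json"
  model <- if (format == "json") read_model_json(path) else
    read_model_sbml(path)
  if (!is.null(source_organism))
    model$reactions$source_organism <- source_organism
  model
}

#' @noRd
read_model_json <- function(path) {
  j <- jsonlite::read_json(path, simplifyVector = FALSE)
  mets <- do.call(rbind, lapply(j$metabolites, function(m)
    data.frame(id = m$id, formula = m$formula %||% NA_character_,
               compartment = m$compartment %||% "c",
               name = m$name %||% m$id)))
  rxn_list <- j$reactions
  rxns <- do.call(rbind, lapply(rxn_list, function(r)
    data.frame(id = r$id, name = r$name %||% r$id,
               lower_bound = as.numeric(r$lower_bound %||% -1000),
               upper_bound = as.numeric(r$upper_bound %||% 1000),
               source_organism =
                 (r$notes$source_organism %||% j$id) %||% "unknown")))
  S <- matrix(0, nrow(mets), nrow(rxns),
              dimnames = list(mets$id, rxns$id))
  obj_id <- NA_character_
  for (r in rxn_list) {
    for (m in names(r$metabolites))
      S[m, r$id] <- as.numeric(r$metabolites[[m]])
    if (!is.null(r$objective_coefficient) &&
        as.numeric(r$objective_coefficient) != 0)
      obj_id <- r$id
  }
  biomass <- find_biomass(rxns$id, obj_id)
  metabolic_network(j$id %||% basename(path), mets, rxns, S,
                    biomass_id = biomass,
                    objective_id = if (!is.na(obj_id)) obj_id else biomass)
}

#' @noRd
find_biomass <- function(ids, objective_hint = NA_character_) {
  if (!is.na(objective_hint) && grepl("biomass", objective_hint,
                                      ignore.case = TRUE))
    return(objective_hint)
  hit <- grep("biomass", ids, ignore.case = TRUE, value = TRUE)
  if (length(hit)) hit[1] else objective_hint
}

#' @noRd
read_model_sbml <- function(path) {
  doc <- xml2::read_xml(path)
  xml2::xml_ns_strip(doc)
  sp <- xml2::xml_find_all(doc, ".//listOfSpecies/species")
  mets <- data.frame(
    id = xml2::xml_attr(sp, "id"),
    formula = xml2::xml_attr(sp, "chemicalFormula"),
    compartment = xml2::xml_attr(sp, "compartment"),
    name = xml2::xml_attr(sp, "name"))
  mets$name[is.na(mets$name)] <- mets$id[is.na(mets$name)]
  params <- xml2::xml_find_all(doc, ".//listOfParameters/parameter")
  pval <- stats::setNames(as.numeric(xml2::xml_attr(params, "value")),
                          xml2::xml_attr(params, "id"))
  rx <- xml2::xml_find_all(doc, ".//listOfReactions/reaction")
  get_bound <- function(node, attr, default) {
    ref <- xml2::xml_attr(node, attr)
    if (!is.na(ref) && ref %in% names(pval)) pval[[ref]] else default
  }
  rxns <- do.call(rbind, lapply(rx, function(node) {
    rev <- identical(xml2::xml_attr(node, "reversible"), "true")
    data.frame(
      id = xml2::xml_attr(node, "id"),
      name = xml2::xml_attr(node, "name") %||% xml2::xml_attr(node, "id"),
      lower_bound = get_bound(node, "lowerFluxBound",
                              if (rev) -1000 else 0),
      upper_bound = get_bound(node, "upperFluxBound", 1000),
      source_organism = NA_character_)
  }))
  rxns$name[is.na(rxns$name)] <- rxns$id[is.na(rxns$name)]
  S <- matrix(0, nrow(mets), nrow(rxns), dimnames = list(mets$id, rxns$id))
  for (node in rx) {
    rid <- xml2::xml_attr(node, "id")
    for (sr in xml2::xml_find_all(node, "./listOfReactants/speciesReference"))
      S[xml2::xml_attr(sr, "species"), rid] <-
        S[xml2::xml_attr(sr, "species"), rid] -
        as.numeric(xml2::xml_attr(sr, "stoichiometry") %||% "1")
    for (sr in xml2::xml_find_all(node, "./listOfProducts/speciesReference"))
      S[xml2::xml_attr(sr, "species"), rid] <-
        S[xml2::xml_attr(sr, "species"), rid] +
        as.numeric(xml2::xml_attr(sr, "stoichiometry") %||% "1")
  }
  obj <- xml2::xml_find_first(
    doc, ".//listOfObjectives/objective/listOfFluxObjectives/fluxObjective")
  obj_id <- if (!inherits(obj, "xml_missing"))
    xml2::xml_attr(obj, "reaction") else NA_character_
  mid <- xml2::xml_attr(xml2::xml_find_first(doc, ".//model"), "id")
  biomass <- find_biomass(rxns$id, obj_id)
  rxns$source_organism <- mid %||% basename(path)
  metabolic_network(mid %||% basename(path), mets, rxns, S,
                    biomass_id = biomass,
                    objective_id = if (!is.na(obj_id)) obj_id else biomass)
}

#' Write a model in the constraint-based JSON dialect
#'
#' @param model a [metabolic_network()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_model <- function(model, path) {
  mets <- lapply(seq_len(nrow(model$metabolites)), function(i) {
    m <- model$metabolites[i, ]
    out <- list(id = m$id, compartment = m$compartment,
                name = if ("name" %in% names(m)) m$name else m$id)
    if (!is.na(m$formula)) out$formula <- m$formula
    out
  })
  rxns <- lapply(seq_len(nrow(model$reactions)), function(i) {
    r <- model$reactions[i, ]
    coef <- stats::setNames(model$stoich[, r$id], rownames(model$stoich))
    coef <- coef[coef != 0]
    list(id = r$id,
         name = if ("name" %in% names(r)) r$name else r$id,
         metabolites = as.list(coef),
         lower_bound = r$lower_bound,
         upper_bound = r$upper_bound,
         objective_coefficient =
           if (identical(r$id, model$objective_id)) 1 else 0,
         notes = list(source_organism = r$source_organism))
  })
  jsonlite::write_json(
    list(id = model$id, metabolites = mets, reactions = rxns),
    path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' @noRd
reaction_index <- function(model, id) {
  i <- match(id, model$reactions$id)
  if (anyNA(i)) stop("unknown reaction id: ",
                     paste(id[is.na(i)], collapse = ", "), call. = FALSE)
  i
}

#' Set reaction bounds (returns a modified copy)
#' @param model a [metabolic_network()].
#' @param id reaction id(s).
#' @param lower,upper new bounds (recycled); `NULL` leaves a side as is.
#' @return the modified model.
#' @export
set_bounds <- function(model, id, lower = NULL, upper = NULL) {
  i <- reaction_index(model, id)
  if (!is.null(lower)) model$reactions$lower_bound[i] <- lower
  if (!is.null(upper)) model$reactions$upper_bound[i] <- upper
  if (any(model$reactions$lower_bound[i] > model$reactions$upper_bound[i]))
    stop("lower bound exceeds upper bound", call. = FALSE)
  model
}
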