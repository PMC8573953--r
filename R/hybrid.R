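#' Add a metabolite to a network (no-op if present)
#' @noRd
add_metabolite <- function(model, id, formula = NA_character_,
                           compartment = "c") {
  if (id %in% model$metabolites$id) return(model)
  row <- model$metabolites[1, , drop = FALSE]
  row[1, ] <- NA
  row$id <- id; row$formula <- formula; row$compartment <- compartment
  if ("name" %in% names(row)) row$name <- id
  model$metabolites <- rbind(model$metabolites, row)
  model$stoich <- rbind(model$stoich,
                        matrix(0, 1, ncol(model$stoich),
                               dimnames = list(id, colnames(model$stoich))))
  model
}

#' Add a reaction to a network
#'
#' @param model a [metabolic_network()].
#' @param id new reaction id (must not exist).
#' @param coef named numeric vector of stoichiometric coefficients
#'   (negative = consumed); metabolites are created (with optional
#'   `formulas`) when absent.
#' @param lower,upper flux bounds.
#' @param source_organism tag for the new reaction.
#' @param formulas optional named character vector of formulas for
#'   metabolites that need creating.
#' @return the extended model.
#' @export
add_reaction <- function(model, id, coef, lower = 0, upper = 1000,
                         source_organism = model$id, formulas = NULL) {
  if (id %in% model$reactions$id)
    stop("reaction already exists: ", id, call. = FALSE)
  for (m in names(coef))
    model <- add_metabolite(model, m,
                            formula = formulas[m] %||chr2% NA_character_)
  row <- model$reactions[1, , drop = FALSE]
  row[1, ] <- NA
  row$id <- id
  if ("name" %in% names(row)) row$name <- id
  row$lower_bound <- lower; row$upper_bound <- upper
  row$source_organism <- source_organism
  col <- matrix(0, nrow(model$stoich), 1,
                dimnames = list(rownames(model$stoich), id))
  col[names(coef), 1] <- coef
  model$stoich <- cbind(model$stoich, col)
  row$exchange <- sum(col != 0) == 1L
  model$reactions <- rbind(model$reactions, row)
  model
}

`%||chr2%` <- function(a, b) {
  if (is.null(a) || length(a) == 0 || is.na(a)) b else unname(a)
}

#' @noRd
find_met <- function(model, pattern) {
  hit <- grep(pattern, model$metabolites$id, value = TRUE)
  if (length(hit)) hit[1] else NA_character_
}

#' Augment an acetogen model with coculture-expressed solvent reactions
#'
#' Adds, when absent, the six reactions the acetogen needs to account for
#' secondary-alcohol and 2,3-butanediol production observed only in
#' coculture: exchange reactions for acetoin, acetone, 2,3-butanediol
#' and isopropanol, plus the two NADPH-dependent dehydrogenases
#' (secondary alcohol dehydrogenase, acetone + NADPH -> isopropanol +
#' NADP+; 2,3-butanediol dehydrogenase, acetoin + NADPH ->
#' 2,3-butanediol + NADP+). Already-present members are left untouched,
#' so the operation is idempotent.
#'
#' @param model an acetogen [metabolic_network()] carrying NADPH/NADP+
#'   metabolites (ids matched by pattern `nadph` / `nadp`).
#' @return the augmented model.
#' @export
augment_acetogen <- function(model) {
  nadph <- find_met(model, "^nadph")
  nadp <- {
    cands <- grep("^nadp", model$metabolites$id, value = TRUE)
    cands <- cands[!grepl("^nadph", cands)]
    if (length(cands)) cands[1] else NA_character_
  }
  if (is.na(nadph) || is.na(nadp))
    stop("NADPH/NADP+ metabolites absent; cannot add dehydrogenases",
         call. = FALSE)
  species <- list(
    acetone = list(pattern = "^acetone", id = "acetone", formula = "C3H6O"),
    acetoin = list(pattern = "^actn|^acetoin", id = "actn",
                   formula = "C4H8O2"),
    ipoh = list(pattern = "^ipoh|^2ppoh|isopropanol", id = "ipoh",
                formula = "C3H8O"),
    btd = list(pattern = "^btd|butanediol", id = "btd",
               formula = "C4H10O2"))
  ids <- lapply(species, function(s) {
    hit <- find_met(model, s$pattern)
    if (is.na(hit)) {
      model <<- add_metabolite(model, s$id, formula = s$formula)
      s$id
    } else hit
  })
  add_if_absent <- function(m, rid, coef, lower, upper) {
    if (rid %in% m$reactions$id) m
    else add_reaction(m, rid, coef, lower = lower, upper = upper,
                      source_organism = m$id)
  }
  for (s in names(ids)) {
    ex_id <- paste0("EX_", ids[[s]])
    model <- add_if_absent(model, ex_id,
                           stats::setNames(-1, ids[[s]]), -1000, 1000)
  }
  model <- add_if_absent(
    model, "SADH",
    stats::setNames(c(-1, -1, 1, 1),
                    c(ids$acetone, nadph, ids$ipoh, nadp)), 0, 1000)
  model <- add_if_absent(
    model, "BDH",
    stats::setNames(c(-1, -1, 1, 1),
                    c(ids$acetoin, nadph, ids$btd, nadp)), 0, 1000)
  model
}

#' @noRd
stoich_scale_match <- function(a, b, tol = 1e-9) {
  # returns scalar s with b == s * a, or NA
  ia <- which(abs(a) > tol); ib <- which(abs(b) > tol)
  if (!identical(ia, ib)) return(NA_real_)
  r <- b[ib] / a[ia]
  if (max(r) - min(r) < tol * max(1, abs(r[1]))) r[1] else NA_real_
}

#' Merge two metabolic networks into a hybrid model
#'
#' Builds a hybrid model as the union of reaction content: the host
#' model keeps its biomass equation and objective, the donor's biomass
#' and objective are dropped, and donor metabolites are translated into
#' the host namespace through `metabolite_id_map` (identity for ids the
#' map does not cover; unmatched donor metabolites are imported as new
#' species). Donor reactions whose mapped stoichiometry equals a host
#' reaction up to a scalar are considered the same reaction: kept once,
#' tagged `"shared"`, with union bounds. Remaining host reactions are
#' tagged `"host"`, remaining donor reactions `"donor"`.
#'
#' @param host,donor [metabolic_network()] objects.
#' @param metabolite_id_map named character vector `donor id -> host id`
#'   (default empty: exact id match).
#' @return a hybrid [metabolic_network()] (class also `hybrid_model`)
#'   with `source_organism` in `{"host", "donor", "shared"}` and
#'   attributes `host_id`, `donor_id`.
#' @export
merge_models <- function(host, donor, metabolite_id_map = character(0)) {
  map <- function(ids) {
    out <- ids
    hit <- ids %in% names(metabolite_id_map)
    out[hit] <- metabolite_id_map[ids[hit]]
    out
  }
  hy <- host
  hy$id <- paste0(host$id, "_", donor$id, "_hybrid")
  hy$reactions$source_organism <- "host"

  drop <- unique(stats::na.omit(c(donor$biomass_id, donor$objective_id)))
  donor_rxn_ids <- setdiff(donor$reactions$id, drop)

  for (rid in donor_rxn_ids) {
    coef <- stats::setNames(donor$stoich[, rid], rownames(donor$stoich))
    coef <- coef[coef != 0]
    mapped <- stats::setNames(as.numeric(coef), map(names(coef)))
    if (anyDuplicated(names(mapped)))
      stop("metabolite map collapses distinct donor metabolites in ", rid,
           call. = FALSE)
    di <- match(rid, donor$reactions$id)
    dlb <- donor$reactions$lower_bound[di]
    dub <- donor$reactions$upper_bound[di]

    # same id present in host: must be the same reaction up to scalar
    dup_id <- NA_character_
    if (rid %in% hy$reactions$id) {
      s <- column_scale_match(hy, rid, mapped)
      if (is.na(s))
        stop("stoichiometric conflict under identical reaction id: ", rid,
             call. = FALSE)
      dup_id <- rid
    } else {
      # scan host columns for a scalar-multiple duplicate
      for (hid in hy$reactions$id) {
        s <- column_scale_match(hy, hid, mapped)
        if (!is.na(s)) { dup_id <- hid; break }
      }
    }
    if (!is.na(dup_id)) {
      s <- column_scale_match(hy, dup_id, mapped)
      # donor flux d corresponds to host flux d/s; union of intervals
      cand <- c(dlb / s, dub / s)
      i <- match(dup_id, hy$reactions$id)
      hy$reactions$lower_bound[i] <- min(hy$reactions$lower_bound[i], cand)
      hy$reactions$upper_bound[i] <- max(hy$reactions$upper_bound[i], cand)
      hy$reactions$source_organism[i] <- "shared"
    } else {
      need <- setdiff(names(mapped), hy$metabolites$id)
      for (m in need) {
        j <- match(m, map(donor$metabolites$id))
        hy <- add_metabolite(hy, m,
                             formula = donor$metabolites$formula[j],
                             compartment = donor$metabolites$compartment[j])
      }
      hy <- add_reaction(hy, rid, mapped, lower = dlb, upper = dub,
                         source_organism = "donor")
    }
  }
  attr(hy, "host_id") <- host$id
  attr(hy, "donor_id") <- donor$id
  class(hy) <- c("hybrid_model", class(hy))
  hy
}

#' @noRd
column_scale_match <- function(model, rid, mapped_coef) {
  col <- model$stoich[, rid]
  full <- stats::setNames(numeric(nrow(model$stoich)),
                          rownames(model$stoich))
  keep <- names(mapped_coef) %in% names(full)
  if (!all(keep)) return(NA_real_)
  full[names(mapped_coef)] <- mapped_coef
  stoich_scale_match(col, full)
}

#' Remove energy-generating cycles
#'
#' Certifies and enforces that, with every exchange reaction closed, no
#' energy-dissipation reaction (ATP maintenance, or a constructed ATP
#' hydrolysis sink when none is present) can carry positive flux --- the
#' defining test for thermodynamically infeasible energy-generating
#' cycles. While a dissipation maximum is positive, a minimal-support
#' flux carrying the cycle is found (minimize `sum |v|` subject to
#' dissipation >= 1 with exchanges closed) and the cycle direction of the
#' largest-flux reversible member is closed; the certificate is then
#' recomputed. The returned model keeps its original exchange bounds;
#' only the loop-member direction constraints differ.
#'
#' @param model a [metabolic_network()].
#' @param dissipation_ids reaction ids to certify against; default: ids
#'   matching `ATPM`/`maintenance` plus, when an `atp`-like metabolite
#'   exists, a temporary ATP hydrolysis sink used only for the check.
#' @param tol flux-zero tolerance (default 1e-6).
#' @param max_iter safety cap on loop-removal iterations.
#' @return list with `model` (constrained copy) and `report` (data frame
#'   `reaction`, `closed_direction`), empty when the input is clean.
#' @export
strip_energy_generating_cycles <- function(model, dissipation_ids = NULL,
                                           tol = 1e-6, max_iter = 50L) {
  temp_sink <- FALSE
  work <- model
  if (is.null(dissipation_ids)) {
    dissipation_ids <- grep("ATPM|maintenance|NGAM", work$reactions$id,
                            ignore.case = TRUE, value = TRUE)
    if (!length(dissipation_ids)) {
      atp <- find_met(work, "^atp")
      if (is.na(atp))
        stop("no dissipation reaction identifiable and no ATP metabolite ",
             "to construct one", call. = FALSE)
      work <- add_reaction(work, ".EGC_ATP_SINK",
                           stats::setNames(-1, atp), 0, 1000)
      dissipation_ids <- ".EGC_ATP_SINK"
      temp_sink <- TRUE
    }
  }
  closed <- work
  ex <- closed$reactions$id[closed$reactions$exchange]
  ex <- setdiff(ex, dissipation_ids)
  if (length(ex)) closed <- set_bounds(closed, ex, lower = 0, upper = 0)

  report <- data.frame(reaction = character(0),
                       closed_direction = character(0))
  for (d in dissipation_ids) {
    for (iter in seq_len(max_iter)) {
      mx <- fba(closed, objective_id = d)
      if (mx$status != "optimal")
        stop("certification LP not optimal (", mx$status, ")", call. = FALSE)
      if (mx$objective <= tol) break
      v <- minimal_support_flux(closed, d)
      members <- names(v)[abs(v) > tol & names(v) != d]
      rev_ok <- members[
        model$reactions$lower_bound[match(members, model$reactions$id)] < 0 &
        model$reactions$upper_bound[match(members, model$reactions$id)] > 0]
      if (!length(rev_ok))
        stop("energy-generating cycle with no reversible member; cannot ",
             "constrain minimally", call. = FALSE)
      pick <- rev_ok[which.max(abs(v[rev_ok]))]
      if (v[pick] > 0) {
        closed <- set_bounds(closed, pick, upper = 0)
        work <- set_bounds(work, pick, upper = 0)
        dirn <- "forward"
      } else {
        closed <- set_bounds(closed, pick, lower = 0)
        work <- set_bounds(work, pick, lower = 0)
        dirn <- "reverse"
      }
      report <- rbind(report, data.frame(reaction = pick,
                                         closed_direction = dirn))
    }
  }
  if (temp_sink) {
    keep <- work$reactions$id != ".EGC_ATP_SINK"
    work$reactions <- work$reactions[keep, , drop = FALSE]
    work$stoich <- work$stoich[, keep, drop = FALSE]
  }
  list(model = work, report = report)
}

#' Minimize total absolute flux subject to positive dissipation
#' @noRd
minimal_support_flux <- function(closed, dissipation_id, eps = 1) {
  n <- nrow(closed$reactions)
  lb <- closed$reactions$lower_bound
  ub <- closed$reactions$upper_bound
  # variables: v (n) then t (n) with t >= |v|
  obj <- c(numeric(n), rep(1, n))
  Aeq <- cbind(closed$stoich, matrix(0, nrow(closed$stoich), n))
  A <- rbind(cbind(diag(n), -diag(n)),     # v - t <= 0
             cbind(-diag(n), -diag(n)))    # -v - t <= 0
  dir <- rep("<=", 2 * n)
  rhs <- rep(0, 2 * n)
  drow <- c(as.numeric(closed$reactions$id == dissipation_id), numeric(n))
  A <- rbind(A, drow); dir <- c(dir, ">=")
  # dissipation target: eps, or half the achievable max if smaller
  mx <- fba(closed, objective_id = dissipation_id)
  target <- min(eps, mx$objective / 2)
  rhs <- c(rhs, target)
  res <- solve_lp(obj, Aeq = Aeq, beq = rep(0, nrow(Aeq)),
                  lb = c(lb, numeric(n)),
                  ub = c(ub, pmax(abs(lb), abs(ub))),
                  A = A, dir = dir, rhs = rhs, maximize = FALSE)
  if (res$status != "optimal")
    stop("minimal-support LP not optimal (", res$status, ")", call. = FALSE)
  stats::setNames(res$flux[seq_len(n)], closed$reactions$id)
}

#' Closed-exchange energy-dissipation certificate
#'
#' Maximum achievable flux through each energy-dissipation reaction with
#' every exchange reaction (other than the dissipation reactions
#' themselves) closed. A thermodynamically sound network returns zeros;
#' positive values certify an energy-generating cycle.
#'
#' @param model a [metabolic_network()].
#' @param dissipation_ids reactions to certify (default: ATP-maintenance
#'   style ids, as in [strip_energy_generating_cycles()]).
#' @return named numeric vector of maxima.
#' @export
egc_certificate <- function(model, dissipation_ids = NULL) {
  if (is.null(dissipation_ids))
    dissipation_ids <- grep("ATPM|maintenance|NGAM", model$reactions$id,
                            ignore.case = TRUE, value = TRUE)
  if (!length(dissipation_ids))
    stop("no dissipation reactions identified", call. = FALSE)
  ex <- setdiff(model$reactions$id[model$reactions$exchange],
                dissipation_ids)
  closed <- if (length(ex)) set_bounds(model, ex, lower = 0, upper = 0)
  else model
  vapply(dissipation_ids, function(d) {
    r <- fba(closed, objective_id = d)
    if (r$status != "optimal")
      stop("certificate LP not optimal for ", d, call. = FALSE)
    r$objective
  }, numeric(1))
}

#' Flux-variability gain-of-function report for a hybrid model
#'
#' Quantifies what the donor's reaction content buys the host:
#' host-native reactions unblocked by the merge, donor reactions able to
#' carry flux in the hybrid, donor reactions *necessarily* active at
#' maximum growth (FVA range at objective fraction 1 excludes zero, so
#' they shape the optimal growth phenotype), and the percent change in
#' maximum growth rate.
#'
#' @param hybrid a [merge_models()] result built from `host_native`.
#' @param host_native the original host [metabolic_network()].
#' @param extra_bounds optional bounds (e.g. a defined medium) applied to
#'   both models for the growth comparison and the FVA.
#' @return object of class `gain_of_function_report`: list with
#'   `newly_unblocked_native`, `donor_reactions_carrying_flux`,
#'   `necessarily_active_nonnative` (data frame with FVA ranges),
#'   `growth_host`, `growth_hybrid`, `growth_delta` (percent).
#' @export
gain_of_function <- function(hybrid, host_native, extra_bounds = NULL) {
  blocked_host <- blocked_reactions(host_native)
  blocked_hyb <- blocked_reactions(hybrid)
  native_tags <- hybrid$reactions$source_organism %in% c("host", "shared")
  native_ids <- hybrid$reactions$id[native_tags]
  newly_unblocked <- setdiff(intersect(blocked_host, native_ids), blocked_hyb)
  donor_ids <- hybrid$reactions$id[hybrid$reactions$source_organism == "donor"]
  donor_flux <- setdiff(donor_ids, blocked_hyb)

  mu_host <- fba(apply_extra_bounds(host_native, extra_bounds))
  mu_hyb <- fba(apply_extra_bounds(hybrid, extra_bounds))
  if (mu_host$status != "optimal" || mu_hyb$status != "optimal")
    stop("growth FBA not optimal for host or hybrid", call. = FALSE)

  nec <- if (length(donor_ids)) {
    rng <- fva(hybrid, objective_fraction = 1, reaction_subset = donor_ids,
               extra_bounds = extra_bounds)
    rng[rng$class == "necessarily_active", c("id", "min", "max")]
  } else data.frame(id = character(0), min = numeric(0), max = numeric(0))

  structure(
    list(newly_unblocked_native = newly_unblocked,
         donor_reactions_carrying_flux = donor_flux,
         necessarily_active_nonnative = nec,
         growth_host = mu_host$objective,
         growth_hybrid = mu_hyb$objective,
         growth_delta = 100 * (mu_hyb$objective - mu_host$objective) /
           mu_host$objective),
    class = "gain_of_function_report")
}

#' @export
print.gain_of_function_report <- function(x, ...) {
  cat("<gain_of_function_report>\n")
  cat(sprintf("  newly unblocked native reactions: %d\n",
              length(x$newly_unblocked_native)))
  cat(sprintf("  donor reactions carrying flux:    %d\n",
              length(x$donor_reactions_carrying_flux)))
  cat(sprintf("  necessarily active nonnative:     %d\n",
              nrow(x$necessarily_active_nonnative)))
  cat(sprintf("  max growth: %.4g -> %.4g h^-1 (%+.2f%%)\n",
              x$growth_host, x$growth_hybrid, x$growth_delta))
  invisible(x)
}
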