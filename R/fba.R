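#' Flux balance analysis
#'
#' Maximizes (by default) the objective reaction flux subject to
#' steady-state mass balance `S v = 0` and flux bounds. Only the
#' objective value is contract-stable: at degenerate optima the returned
#' flux vector is one optimal vertex among many.
#'
#' @param model a [metabolic_network()].
#' @param objective_id reaction to optimize (default: model objective).
#' @param extra_bounds optional named list `id -> c(lower, upper)`
#'   overriding bounds for this solve only.
#' @param maximize logical (default `TRUE`).
#' @return object of class `flux_solution`: list with `status`
#'   (`"optimal"`, `"infeasible"`, ...), `objective`, and named `flux`
#'   vector (mmol gDW^-1 h^-1; biomass in h^-1).
#' @export
fba <- function(model, objective_id = model$objective_id,
                extra_bounds = NULL, maximize = TRUE) {
  if (is.na(objective_id))
    stop("model has no objective reaction", call. = FALSE)
  m <- apply_extra_bounds(model, extra_bounds)
  obj <- as.numeric(m$reactions$id == objective_id)
  if (!any(obj > 0)) stop("unknown objective: ", objective_id, call. = FALSE)
  res <- solve_lp(obj, Aeq = m$stoich, beq = rep(0, nrow(m$stoich)),
                  lb = m$reactions$lower_bound,
                  ub = m$reactions$upper_bound,
                  maximize = maximize)
  flux <- if (!is.null(res$flux))
    stats::setNames(res$flux, m$reactions$id) else NULL
  structure(list(status = res$status, objective = res$objective,
                 flux = flux, objective_id = objective_id),
            class = "flux_solution")
}

#' @export
print.flux_solution <- function(x, ...) {
  cat(sprintf("<flux_solution> %s: %s = %s\n", x$status, x$objective_id,
              format(x$objective)))
  invisible(x)
}

#' @noRd
apply_extra_bounds <- function(model, extra_bounds) {
  if (is.null(extra_bounds)) return(model)
  for (id in names(extra_bounds))
    model <- set_bounds(model, id,
                        lower = extra_bounds[[id]][1],
                        upper = extra_bounds[[id]][2])
  model
}

#' Flux variability analysis
#'
#' Per-reaction minimum and maximum flux with the objective constrained
#' to at least `objective_fraction` of its optimum. At fraction 0 the
#' objective constraint is dropped entirely, which is the setting used
#' for blocked-reaction classification.
#'
#' @param model a [metabolic_network()].
#' @param objective_fraction in `[0, 1]` (default 1).
#' @param reaction_subset reaction ids to scan (default: all).
#' @param extra_bounds as in [fba()].
#' @return data frame of class `fva_range`: `id`, `min`, `max`, and
#'   `class` (`"blocked"` if the range is `{0}` within tolerance,
#'   `"necessarily_active"` if the range excludes 0, else `"variable"`).
#' @export
fva <- function(model, objective_fraction = 1, reaction_subset = NULL,
                extra_bounds = NULL) {
  stopifnot(objective_fraction >= 0, objective_fraction <= 1)
  m <- apply_extra_bounds(model, extra_bounds)
  ids <- reaction_subset %||chr% m$reactions$id
  reaction_index(m, ids)
  A <- NULL; dir <- NULL; rhs <- NULL
  if (objective_fraction > 0) {
    base <- fba(m)
    if (base$status != "optimal")
      stop("infeasible base problem for FVA", call. = FALSE)
    obj_row <- as.numeric(m$reactions$id == m$objective_id)
    A <- matrix(obj_row, nrow = 1)
    dir <- ">="
    rhs <- objective_fraction * base$objective
  }
  res <- lapply(ids, function(id) {
    w <- as.numeric(m$reactions$id == id)
    lo <- solve_lp(w, Aeq = m$stoich, beq = rep(0, nrow(m$stoich)),
                   lb = m$reactions$lower_bound, ub = m$reactions$upper_bound,
                   A = A, dir = dir, rhs = rhs, maximize = FALSE)
    hi <- solve_lp(w, Aeq = m$stoich, beq = rep(0, nrow(m$stoich)),
                   lb = m$reactions$lower_bound, ub = m$reactions$upper_bound,
                   A = A, dir = dir, rhs = rhs, maximize = TRUE)
    if (lo$status != "optimal" || hi$status != "optimal")
      stop("FVA subproblem not optimal for ", id, " (", lo$status, "/",
           hi$status, ")", call. = FALSE)
    c(lo$objective, hi$objective)
  })
  out <- data.frame(id = ids,
                    min = vapply(res, `[`, numeric(1), 1L),
                    max = vapply(res, `[`, numeric(1), 2L))
  tol <- 1e-6
  out$class <- ifelse(abs(out$min) <= tol & abs(out$max) <= tol, "blocked",
               ifelse(out$min > tol | out$max < -tol, "necessarily_active",
                      "variable"))
  class(out) <- c("fva_range", "data.frame")
  out
}

`%||chr%` <- function(a, b) if (is.null(a)) b else a

#' Blocked reactions under open exchange bounds
#'
#' A reaction is blocked if it cannot carry nonzero flux in any feasible
#' steady state with every exchange reaction opened to `[-open, open]`
#' and no objective constraint. The complement is the "unblocked" (active
#' network) count used when characterizing model content.
#'
#' @param model a [metabolic_network()].
#' @param open exchange bound magnitude (default 1000).
#' @return character vector of blocked reaction ids.
#' @export
blocked_reactions <- function(model, open = 1000) {
  ex <- model$reactions$id[model$reactions$exchange]
  m <- model
  if (length(ex)) m <- set_bounds(m, ex, lower = -open, upper = open)
  ranges <- fva(m, objective_fraction = 0)
  ranges$id[ranges$class == "blocked"]
}

#' Rescale the biomass reaction to 1.0 g/mmol
#'
#' Standardizes the biomass equation so one unit of biomass flux drains
#' 1.0 g (1000 mg) of dry weight per mmol: every biomass coefficient is
#' multiplied by `1000 / M`, where `M` (mg/mmol) is the summed mass of
#' biomass reactants, `sum_j |coef_j| * MW_j` over consumed metabolites.
#' Growth-rate semantics are preserved in the sense that the FBA optimum
#' scales by the inverse factor (`M / 1000`), so after rescaling the
#' objective value reads directly in h^-1 for a gDW-normalized model. The
#' operation is idempotent.
#'
#' @param model a [metabolic_network()] whose biomass reactants all carry
#'   parseable formulas.
#' @return the rescaled model, with attribute `biomass_scale_factor`.
#' @export
rescale_biomass <- function(model) {
  if (is.na(model$biomass_id))
    stop("model has no biomass reaction", call. = FALSE)
  coef <- stats::setNames(model$stoich[, model$biomass_id],
                          rownames(model$stoich))
  reactants <- names(coef)[coef < 0]
  if (!length(reactants))
    stop("biomass reaction has no reactants", call. = FALSE)
  f <- model$metabolites$formula[match(reactants, model$metabolites$id)]
  bad <- reactants[is.na(f) | !nzchar(f)]
  if (length(bad))
    stop("unknown molecular weight for biomass component(s): ",
         paste(bad, collapse = ", "), call. = FALSE)
  mw <- molecular_weight(f)                      # g/mol == mg/mmol
  mass <- sum(abs(coef[reactants]) * mw)         # mg per mmol biomass flux
  s <- 1000 / mass
  model$stoich[, model$biomass_id] <- coef * s
  attr(model, "biomass_scale_factor") <- s
  model
}
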