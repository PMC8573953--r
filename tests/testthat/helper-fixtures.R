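# Shared fixtures, built once per test run.

toy <- toy_community_models()
toy_aug <- augment_acetogen(toy$acetogen)
toy_hybrid_fermenter <- merge_models(toy$fermenter, toy_aug)
toy_hybrid_acetogen <- merge_models(toy_aug, toy$fermenter)

tracked_products <- c("etoh", "ipoh", "btd", "btoh", "but", "acetone",
                      "ac", "lac", "actn")

# Minimal single-metabolite model for biomass-rescaling checks:
# alanine uptake (<= 5) feeding a biomass equation of 2 mmol alanine.
alanine_model <- function() {
  mets <- data.frame(id = "ala", formula = "C3H7NO2", compartment = "c",
                     name = "alanine")
  rxns <- data.frame(id = c("EX_ala", "BIOMASS"),
                     name = c("EX_ala", "BIOMASS"),
                     lower_bound = c(-5, 0), upper_bound = c(1000, 1000),
                     source_organism = "mini")
  S <- matrix(c(-1, -2), 1, 2, dimnames = list("ala", rxns$id))
  metabolic_network("mini", mets, rxns, S, biomass_id = "BIOMASS")
}

# Hand-solvable 3-reaction chain: uptake (<=10) -> conversion ->
# biomass consuming 2 B per unit flux; optimum 5.
chain_model <- function() {
  mets <- data.frame(id = c("S", "B"), formula = c("C2H4O2", "C2H4O2"),
                     compartment = "c", name = c("S", "B"))
  rxns <- data.frame(id = c("EX_S", "CONV", "BIOMASS"),
                     name = c("EX_S", "CONV", "BIOMASS"),
                     lower_bound = c(-10, 0, 0),
                     upper_bound = c(1000, 1000, 1000),
                     source_organism = "chain")
  S <- matrix(c(-1, 0, -1, 1, 0, -2), 2, 3,
              dimnames = list(c("S", "B"), rxns$id))
  metabolic_network("chain", mets, rxns, S, biomass_id = "BIOMASS")
}

# All feasible vertices of {S v = 0, lb <= v <= ub} by brute force:
# fix every size-d subset of fluxes at a bound (d = n - rank(S)) and
# solve for the rest. Independent of the simplex implementation.
vertex_enumeration_optimum <- function(model, objective_id, tol = 1e-8) {
  S <- unname(model$stoich)
  n <- ncol(S)
  lb <- model$reactions$lower_bound
  ub <- model$reactions$upper_bound
  obj <- as.numeric(model$reactions$id == objective_id)
  d <- n - qr(S)$rank
  best <- -Inf
  subsets <- utils::combn(n, d, simplify = FALSE)
  for (J in subsets) {
    free <- setdiff(seq_len(n), J)
    Sf <- S[, free, drop = FALSE]
    if (qr(Sf)$rank < length(free)) next
    grid <- expand.grid(rep(list(c(1, 2)), d))
    for (g in seq_len(nrow(grid))) {
      vJ <- ifelse(unlist(grid[g, ]) == 1, lb[J], ub[J])
      rhs <- -S[, J, drop = FALSE] %*% vJ
      vf <- tryCatch(qr.solve(Sf, rhs), error = function(e) NULL)
      if (is.null(vf)) next
      v <- numeric(n)
      v[J] <- vJ; v[free] <- vf
      if (max(abs(S %*% v)) > tol) next
      if (any(v < lb - tol) || any(v > ub + tol)) next
      best <- max(best, sum(obj * v))
    }
  }
  best
}

# Per-reaction elemental carbon balance of a network, treating the
# biomass reaction's reactant carbon as legitimately drained.
reaction_carbon_imbalance <- function(model) {
  C <- vapply(model$metabolites$formula, function(f)
    if (is.na(f)) 0L else carbon_content(f), integer(1))
  drop <- c(model$biomass_id,
            model$reactions$id[model$reactions$exchange])
  keep <- setdiff(model$reactions$id, drop)
  vapply(keep, function(r) sum(C * model$stoich[, r]), numeric(1))
}
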