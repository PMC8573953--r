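#' Hybrid-state glucose uptake efficiency
#'
#' Glucose uptake capacity is assumed proportional to the glucose
#' transporter content of a cell, which halves with the nonnative
#' proteome at each division after a fusion event. For the
#' glucose-native fermenter the nonhybrid state has full capacity and a
#' hybrid state `l >= 1` carries `1 - 2^-l` (half its transporters are
#' replaced at fusion and are regained over successive divisions); for
#' the glucose-nonnative acetogen the nonhybrid state has none and a
#' hybrid state carries the acquired `2^-l`.
#'
#' @param role `"fermenter"` (glucose-native) or `"acetogen"`
#'   (glucose-nonnative).
#' @param l hybrid state in `0..5` (vectorized).
#' @return uptake efficiency fraction(s) in `[0, 1]`.
#' @examples
#' uptake_efficiency("fermenter", 0:5) # 1, .5, .75, .875, .9375, .96875
#' uptake_efficiency("acetogen", 0:5)  # 0, .5, .25, .125, .0625, .03125
#' @export
uptake_efficiency <- function(role = c("fermenter", "acetogen"), l) {
  role <- match.arg(role)
  if (any(l < 0L | l > 5L | l != floor(l)))
    stop("hybrid state must be an integer in 0..5", call. = FALSE)
  if (role == "fermenter") ifelse(l == 0L, 1, 1 - 2^-l)
  else ifelse(l == 0L, 0, 2^-l)
}

#' Cross-feeding rules for a DMMM scenario
#'
#' * `nonfusing`: only the two nonhybrid models run, the acetogen's
#'   carbon/electron imports are limited to community-evolved CO2 and H2
#'   (no soluble-product cross-feeding).
#' * `fusing`: all twelve subpopulation models run and soluble product
#'   pools are open for cross-feeding wherever the growth-efficiency
#'   schedule permits consumption.
#' * `no_h2_crossfeed`: the fusing rules with acetogen H2 uptake fixed
#'   at zero.
#'
#' @param scenario one of `"nonfusing"`, `"fusing"`, `"no_h2_crossfeed"`.
#' @return list of rule flags used by [community_step()].
#' @export
crossfeed_rules <- function(scenario = c("fusing", "nonfusing",
                                         "no_h2_crossfeed")) {
  scenario <- match.arg(scenario)
  list(scenario = scenario,
       use_hybrids = scenario != "nonfusing",
       product_crossfeed = scenario != "nonfusing",
       h2_crossfeed = scenario != "no_h2_crossfeed")
}

#' Growth-efficiency and product-consumption schedule
#'
#' Encodes, per organism, non-overlapping time intervals with the
#' fraction of the theoretical-maximum growth rate the organism attains
#' and the fermentation products it is allowed (and observed) to
#' consume.
#'
#' @param intervals data frame with columns `start`, `end` (hours),
#'   `organism` (`"A"`/`"B"`), `fraction` in `(0, 1]`, and `consumes`
#'   (comma-separated product names, `""` for none).
#' @return object of class `growth_schedule`.
#' @export
growth_efficiency_schedule <- function(intervals) {
  need <- c("start", "end", "organism", "fraction", "consumes")
  stopifnot(all(need %in% names(intervals)))
  if (any(intervals$fraction <= 0 | intervals$fraction > 1))
    stop("growth fractions must lie in (0, 1]", call. = FALSE)
  for (k in unique(intervals$organism)) {
    iv <- intervals[intervals$organism == k, ]
    iv <- iv[order(iv$start), ]
    if (any(iv$end[-nrow(iv)] > iv$start[-1] + 1e-9))
      stop("overlapping schedule intervals for organism ", k, call. = FALSE)
  }
  structure(list(intervals = intervals), class = "growth_schedule")
}

#' Schedule matching the staged coculture fermentation
#'
#' Three stages: 0-10.4 h (fermenter exponential at 56% of maximum
#' growth; acetogen lag at 5%), 10.4-21 h (fermenter
#' solventogenesis/sporulation at 35% with butyrate and lactate
#' consumption; acetogen exponential at 100%), 21-33 h (as before, with
#' the acetogen additionally consuming acetone).
#'
#' @param t_final schedule end (default 33 h).
#' @return a [growth_efficiency_schedule()].
#' @export
default_growth_schedule <- function(t_final = 33) {
  growth_efficiency_schedule(data.frame(
    start = c(0, 0, 10.4, 10.4, 21, 21),
    end = c(10.4, 10.4, 21, 21, t_final, t_final),
    organism = c("A", "B", "A", "B", "A", "B"),
    fraction = c(0.56, 0.05, 0.35, 1, 0.35, 1),
    consumes = c("", "", "but,lac", "", "but,lac", "acetone")))
}

#' Flat schedule: both organisms maximize growth, nothing consumed
#' @param t_final schedule end (hours).
#' @return a [growth_efficiency_schedule()].
#' @export
flat_growth_schedule <- function(t_final = 33) {
  growth_efficiency_schedule(data.frame(
    start = c(0, 0), end = c(t_final, t_final),
    organism = c("A", "B"), fraction = c(1, 1), consumes = c("", "")))
}

#' @noRd
schedule_at <- function(schedule, organism, t) {
  iv <- schedule$intervals
  hit <- iv$organism == organism & t >= iv$start - 1e-9 & t < iv$end + 1e-9
  if (!any(hit))
    stop(sprintf("schedule gap for organism %s at t = %g h", organism, t),
         call. = FALSE)
  row <- iv[which(hit)[1], ]
  cons <- trimws(strsplit(row$consumes, ",")[[1]])
  list(fraction = row$fraction, consumes = cons[nzchar(cons)])
}

#' Subpopulation roster for a scenario
#'
#' The fusing scenarios track twelve subpopulations: the two nonhybrid
#' models plus five hybrid-state replicates of each hybrid model, each
#' with its own hybrid-state glucose uptake efficiency. The nonfusing
#' scenario tracks only the two nonhybrid models.
#'
#' @param fermenter,acetogen nonhybrid [metabolic_network()]s.
#' @param hybrid_fermenter,hybrid_acetogen hybrid models (required for
#'   fusing scenarios).
#' @param scenario scenario name, see [crossfeed_rules()].
#' @param n_states hybrid states (default 5).
#' @return list of subpopulation specs (organism, role, state, model,
#'   glucose uptake efficiency).
#' @export
build_subpopulations <- function(fermenter, acetogen,
                                 hybrid_fermenter = NULL,
                                 hybrid_acetogen = NULL,
                                 scenario = "fusing", n_states = 5L) {
  rules <- crossfeed_rules(scenario)
  mk <- function(org, role, l, model)
    list(id = sprintf("%s_l%d", org, l), organism = org, role = role,
         state = l, model = model,
         efficiency = uptake_efficiency(role, l))
  specs <- list(mk("A", "fermenter", 0L, fermenter),
                mk("B", "acetogen", 0L, acetogen))
  if (rules$use_hybrids) {
    if (is.null(hybrid_fermenter) || is.null(hybrid_acetogen))
      stop("fusing scenarios need both hybrid models", call. = FALSE)
    for (l in seq_len(n_states)) {
      specs <- c(specs, list(mk("A", "fermenter", l, hybrid_fermenter)))
      specs <- c(specs, list(mk("B", "acetogen", l, hybrid_acetogen)))
    }
  }
  specs
}

#' Partition culture substrate drawdown across subpopulations
#'
#' Glucose is allocated proportionally to `abundance x uptake
#' efficiency`; fructose proportionally to abundance among
#' fructose-capable subpopulations. Allocations are normalized so they
#' sum to the culture-level drawdown rate; with all-zero weights the
#' substrate goes unallocated (flagged) and accumulates unconsumed.
#'
#' @param drawdown named list/vector with elements `glc` and `fru`
#'   (mmol liter^-1 h^-1, `>= 0`).
#' @param state `community_state` abundances.
#' @param specs [build_subpopulations()] roster.
#' @return list with `glc`, `fru` (numeric allocations per spec) and
#'   `unallocated` (character vector of substrates with zero weights and
#'   positive drawdown).
#' @export
allocate_substrates <- function(drawdown, state, specs) {
  if (any(unlist(drawdown) < 0)) stop("negative drawdown", call. = FALSE)
  ab <- vapply(specs, function(s) state[s$organism, s$state + 1L],
               numeric(1))
  w_glc <- ab * vapply(specs, `[[`, numeric(1), "efficiency")
  fru_ok <- vapply(specs, function(s) "EX_fru" %in% s$model$reactions$id,
                   logical(1))
  w_fru <- ab * as.numeric(fru_ok)
  share <- function(w, total) {
    if (total <= 0) return(numeric(length(w)))
    if (sum(w) <= 0) return(numeric(length(w)))
    total * w / sum(w)
  }
  unalloc <- character(0)
  if (drawdown$glc > 0 && sum(w_glc) <= 0) unalloc <- c(unalloc, "glc")
  if (drawdown$fru > 0 && sum(w_fru) <= 0) unalloc <- c(unalloc, "fru")
  list(glc = share(w_glc, drawdown$glc),
       fru = share(w_fru, drawdown$fru),
       unallocated = unalloc)
}

#' Cheap test for whether a subpopulation has any carbon/electron input
#' this step; without one its LP is identically zero and is skipped.
#' @noRd
subpop_has_inputs <- function(spec, alloc_glc, alloc_fru, gas_budget,
                              sched, pools, rules, forced_uptake) {
  if (alloc_glc > 0 || alloc_fru > 0) return(TRUE)
  if (spec$role == "acetogen" && any(gas_budget > 0)) return(TRUE)
  if (rules$product_crossfeed && length(sched$consumes)) {
    avail <- vapply(sched$consumes, function(p)
      (p %in% names(pools)) && pools[[p]] > 0, logical(1))
    if (any(avail)) return(TRUE)
  }
  if (length(forced_uptake) && any(unlist(forced_uptake) > 0)) return(TRUE)
  FALSE
}

#' Share of the evolved-gas budget per subpopulation (by abundance,
#' among acetogen subpopulations; fermenters get zero)
#' @noRd
acetogen_shares <- function(state, specs) {
  ab <- vapply(specs, function(s)
    if (s$role == "acetogen") state[s$organism, s$state + 1L] else 0,
    numeric(1))
  if (sum(ab) <= 0) return(numeric(length(specs)))
  ab / sum(ab)
}

#' @noRd
exchange_id_for <- function(model, met) {
  id <- paste0("EX_", met)
  if (id %in% model$reactions$id) id else NA_character_
}

#' @noRd
spec_bounds <- function(spec, alloc_glc, alloc_fru, pools, dt, rules,
                        allowed_consume, forced_uptake, gas_budget) {
  m <- spec$model
  eb <- list()
  gl <- exchange_id_for(m, "glc")
  if (!is.na(gl)) eb[[gl]] <- c(-alloc_glc, 0)
  fr <- exchange_id_for(m, "fru")
  if (!is.na(fr)) eb[[fr]] <- c(-alloc_fru, 0)
  for (p in names(pools)) {
    if (p %in% c("glc", "fru", "h2", "co2")) next
    ex <- exchange_id_for(m, p)
    if (is.na(ex)) next
    lo <- 0
    hi <- 1000
    if (rules$product_crossfeed && p %in% allowed_consume)
      lo <- -max(0, pools[[p]]) / dt
    forced <- forced_uptake[[p]]
    if (!is.null(forced) && forced > 0 && p %in% allowed_consume) {
      # consumption at least the observed rate, capped by availability
      hi <- -min(forced, max(0, pools[[p]]) / dt)
      lo <- min(lo, hi)
    }
    eb[[ex]] <- c(lo, hi)
  }
  h2 <- exchange_id_for(m, "h2")
  co2 <- exchange_id_for(m, "co2")
  if (spec$role == "fermenter") {
    if (!is.na(h2)) eb[[h2]] <- c(0, 1000)
    if (!is.na(co2)) eb[[co2]] <- c(0, 1000)
  } else {
    if (!is.na(h2))
      eb[[h2]] <- c(if (rules$h2_crossfeed) -gas_budget[["h2"]] else 0, 1000)
    if (!is.na(co2)) eb[[co2]] <- c(-gas_budget[["co2"]], 1000)
  }
  eb
}

#' @noRd
solve_subpopulation <- function(spec, eb, fraction, products, rules,
                                maximize_gas) {
  m <- apply_extra_bounds(spec$model, eb)
  base <- fba(m)
  if (base$status != "optimal" || base$objective < 1e-9) {
    # idled subpopulation: zero flux everywhere
    return(list(flux = stats::setNames(numeric(nrow(m$reactions)),
                                       m$reactions$id),
                mu_max = 0, growth_floor = 0, idle = TRUE, model = m))
  }
  g <- fraction * base$objective
  m2 <- set_bounds(m, m$objective_id, lower = g, upper = g)
  # secondary objective: route remaining freedom toward exports (and,
  # for fermenters in cross-feeding scenarios, evolved H2/CO2)
  sec_ids <- stats::na.omit(vapply(products, function(p)
    exchange_id_for(m2, p), character(1)))
  if (spec$role == "fermenter" && maximize_gas) {
    for (g_ex in c("EX_h2", "EX_co2"))
      if (g_ex %in% m2$reactions$id) sec_ids <- c(sec_ids, g_ex)
  }
  obj <- as.numeric(m2$reactions$id %in% sec_ids)
  res <- solve_lp(obj, Aeq = m2$stoich, beq = rep(0, nrow(m2$stoich)),
                  lb = m2$reactions$lower_bound,
                  ub = m2$reactions$upper_bound, maximize = TRUE)
  flux <- if (res$status == "optimal")
    stats::setNames(res$flux, m2$reactions$id)
  else base$flux  # fall back to the growth-optimal vertex
  list(flux = flux, mu_max = base$objective, growth_floor = g,
       idle = FALSE, model = m)
}

#' One forward-Euler step of the community simulation
#'
#' Each subpopulation solves its own FBA problem with substrate bounds
#' from [allocate_substrates()], its growth fixed at the scheduled
#' fraction of its own maximum, and scenario cross-feeding rules;
#' fermenter subpopulations are solved first so the acetogen's H2/CO2
#' uptake budget equals what the community evolved within the step.
#' Extracellular pools are then updated
#' `pool <- pool + dt * sum(net community exchange flux)` and the step
#' is rejected and halved (recursively, at most `max_halvings` times)
#' if any pool would fall below zero.
#'
#' @param state `community_state` abundances at the step start.
#' @param pools named numeric vector of extracellular concentrations
#'   (mmol/liter).
#' @param dt step (hours).
#' @param specs subpopulation roster.
#' @param rules [crossfeed_rules()] list.
#' @param schedule [growth_efficiency_schedule()].
#' @param drawdown list with `glc`, `fru` drawdown rates (mmol/L/h).
#' @param t step start time (hours).
#' @param products character vector of tracked product pool names.
#' @param forced_uptake optional named list of observed consumption
#'   rates (mmol/L/h) used as uptake lower bounds.
#' @param max_halvings step-halving cap (default 20).
#' @return list with `pools` (updated), `fluxes` (named list per spec),
#'   `growth` (per-spec realized growth flux), `gas_evolved`
#'   (H2/CO2 evolved by fermenters), `halvings` used.
#' @export
community_step <- function(state, pools, dt, specs, rules, schedule,
                           drawdown, t, products,
                           forced_uptake = list(), max_halvings = 20L) {
  gas_shares <- acetogen_shares(state, specs)
  step_once <- function(pools, dt) {
    alloc <- allocate_substrates(drawdown, state, specs)
    fluxes <- vector("list", length(specs))
    names(fluxes) <- vapply(specs, `[[`, character(1), "id")
    growth <- stats::setNames(numeric(length(specs)), names(fluxes))
    floors <- growth
    gas <- c(h2 = 0, co2 = 0)
    order_idx <- order(vapply(specs, function(s)
      s$role != "fermenter", logical(1)))
    for (i in order_idx) {
      spec <- specs[[i]]
      sched <- schedule_at(schedule, spec$organism, t)
      if (!subpop_has_inputs(spec, alloc$glc[i], alloc$fru[i],
                             gas * gas_shares[i], sched, pools, rules,
                             forced_uptake)) {
        fluxes[[i]] <- stats::setNames(numeric(nrow(spec$model$reactions)),
                                       spec$model$reactions$id)
        next
      }
      eb <- spec_bounds(spec, alloc$glc[i], alloc$fru[i], pools, dt, rules,
                        sched$consumes, forced_uptake, gas * gas_shares[i])
      sol <- solve_subpopulation(spec, eb, sched$fraction, products, rules,
                                 maximize_gas = rules$h2_crossfeed ||
                                   rules$scenario == "nonfusing")
      fluxes[[i]] <- sol$flux
      growth[i] <- sol$growth_floor
      floors[i] <- sol$growth_floor
      if (spec$role == "fermenter" && !sol$idle) {
        for (g_ex in c(h2 = "EX_h2", co2 = "EX_co2")) {
          gname <- if (g_ex == "EX_h2") "h2" else "co2"
          if (g_ex %in% names(sol$flux))
            gas[gname] <- gas[gname] + max(0, sol$flux[[g_ex]])
        }
      }
    }
    new_pools <- pools
    for (p in names(pools)) {
      net <- 0
      for (i in seq_along(specs)) {
        ex <- exchange_id_for(specs[[i]]$model, p)
        if (!is.na(ex) && ex %in% names(fluxes[[i]]))
          net <- net + fluxes[[i]][[ex]]
      }
      new_pools[[p]] <- pools[[p]] + dt * net
    }
    list(pools = new_pools, fluxes = fluxes, growth = growth,
         floors = floors, gas_evolved = gas)
  }
  halvings <- 0L
  advance <- function(pools, dt, depth) {
    out <- step_once(pools, dt)
    if (all(out$pools >= -1e-9)) {
      out$pools[out$pools < 0] <- 0
      return(out)
    }
    if (depth >= max_halvings)
      stop("pool overshoot persists after ", max_halvings,
           " step halvings", call. = FALSE)
    halvings <<- max(halvings, depth + 1L)
    first <- advance(pools, dt / 2, depth + 1L)
    second <- advance(first$pools, dt / 2, depth + 1L)
    list(pools = second$pools, fluxes = second$fluxes,
         growth = second$growth, floors = second$floors,
         gas_evolved = second$gas_evolved)
  }
  out <- advance(pools, dt, 0L)
  out$halvings <- halvings
  out
}

#' Maximum theoretical product export rates at the current step
#'
#' For each tracked product, maximizes the total community export rate
#' subject to the step's substrate allocations, cross-feeding rules and
#' growth-efficiency floors (growth at least the scheduled fraction of
#' each subpopulation's maximum). The per-subpopulation problems are
#' separable once allocations and gas budgets are fixed, so the
#' community maximum is the sum of subpopulation maxima.
#'
#' @inheritParams community_step
#' @param gas_budget named vector `c(h2 = , co2 = )` of evolved gas
#'   available to the acetogen within the step.
#' @return named numeric vector of maximum export rates (mmol/L/h).
#' @export
max_product_titers <- function(state, pools, dt, specs, rules, schedule,
                               drawdown, t, products, gas_budget,
                               forced_uptake = list()) {
  alloc <- allocate_substrates(drawdown, state, specs)
  gas_shares <- acetogen_shares(state, specs)
  # one floored problem per subpopulation, then one export LP per product
  floored <- lapply(seq_along(specs), function(i) {
    spec <- specs[[i]]
    sched <- schedule_at(schedule, spec$organism, t)
    if (!subpop_has_inputs(spec, alloc$glc[i], alloc$fru[i],
                           gas_budget * gas_shares[i], sched, pools,
                           rules, forced_uptake)) return(NULL)
    eb <- spec_bounds(spec, alloc$glc[i], alloc$fru[i], pools, dt, rules,
                      sched$consumes, forced_uptake,
                      gas_budget * gas_shares[i])
    m <- apply_extra_bounds(spec$model, eb)
    base <- fba(m)
    if (base$status != "optimal" || base$objective < 1e-9) return(NULL)
    set_bounds(m, m$objective_id,
               lower = sched$fraction * base$objective)
  })
  out <- stats::setNames(numeric(length(products)), products)
  for (p in products) {
    total <- 0
    for (i in seq_along(specs)) {
      m2 <- floored[[i]]
      if (is.null(m2)) next
      ex <- exchange_id_for(m2, p)
      if (is.na(ex)) next
      sol <- fba(m2, objective_id = ex)
      if (sol$status == "optimal") total <- total + max(0, sol$objective)
    }
    out[[p]] <- total
  }
  out
}

#' Soluble carbon in extracellular product pools
#'
#' Total atomic carbon in the tracked fermentation product pools,
#' `sum_p conc_p (mmol/L) x C_p x 12.011 / 1000` in g carbon per liter.
#'
#' @param pools named numeric vector (mmol/liter).
#' @param formulas named character vector of product formulas.
#' @param products product names to include (default: all of `formulas`).
#' @return g carbon per liter.
#' @export
soluble_carbon <- function(pools, formulas, products = names(formulas)) {
  miss <- setdiff(products, names(formulas))
  if (length(miss))
    stop("missing formula for: ", paste(miss, collapse = ", "),
         call. = FALSE)
  sum(vapply(products, function(p)
    pools[[p]] * carbon_content(formulas[[p]]) * 12.011 / 1000,
    numeric(1)))
}

#' Product yields per mmol hexose consumed
#'
#' Cumulative product formation divided by cumulative glucose plus
#' fructose consumption, both in mmol/liter, at simulation time `t`.
#'
#' @param trajectory a [run_scenario()] result.
#' @param t time (hours) at which to evaluate (default: end).
#' @return named numeric vector, mmol product per mmol hexose.
#' @export
yields_per_hexose <- function(trajectory, t = max(trajectory$times)) {
  i <- max(which(trajectory$times <= t + 1e-9))
  hex <- trajectory$hexose_consumed[i]
  if (hex <= 0) stop("no hexose consumed by t = ", t, call. = FALSE)
  prod0 <- trajectory$pools[1, trajectory$products]
  prodt <- trajectory$pools[i, trajectory$products]
  (prodt - prod0) / hex
}

#' Run a DMMM scenario
#'
#' Couples the fusion growth model's abundance trajectory with the
#' subpopulation metabolic models over the configured span, using
#' forward Euler steps of `dt`. Substrate drawdown follows the monotone
#' interpolants of the configured concentration curves (finite
#' differences floored at zero); each step performs the community FBA
#' solve of [community_step()] and the per-product maximization of
#' [max_product_titers()], accumulating maximum theoretical titers.
#'
#' @param config list with elements:
#'   \describe{
#'     \item{fermenter, acetogen}{nonhybrid models;}
#'     \item{hybrid_fermenter, hybrid_acetogen}{hybrid models (fusing);}
#'     \item{scenario}{see [crossfeed_rules()];}
#'     \item{abundance}{a `fusion_trajectory` covering the span;}
#'     \item{schedule}{a [growth_efficiency_schedule()];}
#'     \item{substrate_curves}{list of `interpolated_series` in
#'       mmol/liter, elements `glc` and `fru`;}
#'     \item{product_curves}{optional list of `interpolated_series` for
#'       products whose observed consumption should bound uptake;}
#'     \item{products}{character vector of tracked product pool names
#'       (default: the nine standard fermentation products);}
#'     \item{t_final, dt}{span (default 33 h) and step (default 0.1 h).}
#'   }
#' @return object of class `titer_trajectory`: list with `times`,
#'   `pools` (matrix time x pool, mmol/L), `max_titer_g_l` (cumulative
#'   maximum theoretical titers, g/L), `soluble_carbon_g_l`,
#'   `hexose_consumed` (cumulative mmol/L), `growth` (matrix time x
#'   subpopulation), `products`, `formulas`, `scenario`.
#' @export
run_scenario <- function(config) {
  scenario <- config$scenario %||chr% "fusing"
  rules <- crossfeed_rules(scenario)
  t_final <- config$t_final %||num% 33
  dt <- config$dt %||num% 0.1
  products <- config$products %||chr%
    c("etoh", "ipoh", "btd", "btoh", "but", "acetone", "ac", "lac", "actn")
  schedule <- config$schedule %||chr% default_growth_schedule(t_final)
  specs <- build_subpopulations(config$fermenter, config$acetogen,
                                config$hybrid_fermenter,
                                config$hybrid_acetogen, scenario)
  traj <- config$abundance
  stopifnot(inherits(traj, "fusion_trajectory"))
  curves <- config$substrate_curves
  stopifnot(!is.null(curves$glc), !is.null(curves$fru))

  formulas <- product_formulas(specs, products)
  pool_names <- c("glc", "fru", products, "h2", "co2")
  pools <- stats::setNames(numeric(length(pool_names)), pool_names)
  pools[["glc"]] <- predict(curves$glc, 0)
  pools[["fru"]] <- predict(curves$fru, 0)
  if (!is.null(config$initial_pools))
    pools[names(config$initial_pools)] <- unlist(config$initial_pools)

  times <- seq(0, t_final, by = dt)
  n_t <- length(times)
  pool_mat <- matrix(NA_real_, n_t, length(pools),
                     dimnames = list(NULL, pool_names))
  titer <- matrix(0, n_t, length(products),
                  dimnames = list(NULL, products))
  growth_mat <- matrix(0, n_t, length(specs),
                       dimnames = list(NULL, vapply(specs, `[[`,
                                                    character(1), "id")))
  soluble <- numeric(n_t)
  hexose <- numeric(n_t)
  pool_mat[1, ] <- pools
  soluble[1] <- soluble_carbon(pools, formulas, products)

  if (n_t >= 2) for (i in seq_len(n_t - 1L)) {
    t <- times[i]
    state <- state_at(traj, t)
    drawdown <- list(
      glc = curve_drawdown(curves$glc, t, dt),
      fru = curve_drawdown(curves$fru, t, dt))
    forced <- forced_uptake_rates(config$product_curves, t, dt)
    step <- community_step(state, pools, dt, specs, rules, schedule,
                           drawdown, t, products, forced)
    rates <- max_product_titers(state, pools, dt, specs, rules, schedule,
                                drawdown, t, products, step$gas_evolved,
                                forced)
    consumed <- pools[["glc"]] + pools[["fru"]] -
      step$pools[["glc"]] - step$pools[["fru"]]
    pools <- step$pools
    pool_mat[i + 1L, ] <- pools
    titer[i + 1L, ] <- titer[i, ] + dt * rates *
      vapply(products, function(p) molecular_weight(formulas[[p]]),
             numeric(1)) / 1000
    growth_mat[i + 1L, ] <- step$growth
    hexose[i + 1L] <- hexose[i] + max(0, consumed)
    soluble[i + 1L] <- soluble_carbon(pools, formulas, products)
  }
  structure(
    list(times = times, pools = pool_mat, max_titer_g_l = titer,
         soluble_carbon_g_l = soluble, hexose_consumed = hexose,
         growth = growth_mat, products = products, formulas = formulas,
         scenario = scenario),
    class = "titer_trajectory")
}

#' @export
print.titer_trajectory <- function(x, ...) {
  cat(sprintf(
    "<titer_trajectory> scenario %s, %d steps over [0, %g] h\n",
    x$scenario, length(x$times) - 1L, max(x$times)))
  cat(sprintf("  soluble carbon at end: %.3g g/L; hexose consumed: %.3g mmol/L\n",
              x$soluble_carbon_g_l[length(x$times)],
              x$hexose_consumed[length(x$times)]))
  invisible(x)
}

`%||num%` <- function(a, b) if (is.null(a)) b else a

#' @noRd
product_formulas <- function(specs, products) {
  out <- stats::setNames(rep(NA_character_, length(products)), products)
  for (spec in specs) {
    mets <- spec$model$metabolites
    hit <- products %in% mets$id & is.na(out)
    out[products[hit]] <-
      mets$formula[match(products[hit], mets$id)]
  }
  miss <- names(out)[is.na(out)]
  if (length(miss))
    stop("no formula found in any model for product(s): ",
         paste(miss, collapse = ", "), call. = FALSE)
  out
}

#' @noRd
state_at <- function(traj, t) {
  i <- max(which(traj$times <= t + 1e-9))
  X <- traj$X[i, , ]
  class(X) <- c("community_state", class(X))
  X
}

#' @noRd
curve_drawdown <- function(curve, t, dt) {
  rng <- range(curve$knot_times)
  t1 <- min(t + dt, rng[2]); t0 <- min(t, rng[2])
  if (t1 <= t0) return(0)
  max(0, (predict(curve, t0) - predict(curve, t1)) / (t1 - t0))
}

#' @noRd
forced_uptake_rates <- function(product_curves, t, dt) {
  if (is.null(product_curves)) return(list())
  out <- list()
  for (p in names(product_curves))
    out[[p]] <- curve_drawdown(product_curves[[p]], t, dt)
  out
}
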