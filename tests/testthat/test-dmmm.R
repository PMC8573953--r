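make_dmmm_config <- function(scenario, t_final = 3, dt = 1, f = 1e-12,
                             schedule = flat_growth_schedule(t_final),
                             acetogen = toy_aug) {
  sched <- constant_rate_schedule(0.5, 0.2)
  ab <- integrate_growth(community_state(1e10, 9e10), sched, f, t_final,
                         0.01)
  list(fermenter = toy$fermenter, acetogen = acetogen,
       hybrid_fermenter = toy_hybrid_fermenter,
       hybrid_acetogen = toy_hybrid_acetogen,
       scenario = scenario, abundance = ab, schedule = schedule,
       substrate_curves = synthetic_substrate_profiles(t_final = max(t_final,
                                                                     1)),
       t_final = t_final, dt = dt)
}

test_that("hybrid-state glucose uptake efficiencies follow the closed forms", {
  expect_equal(uptake_efficiency("fermenter", 0:5),
               c(1, 0.5, 0.75, 0.875, 0.9375, 0.96875))
  expect_equal(uptake_efficiency("acetogen", 0:5),
               c(0, 0.5, 0.25, 0.125, 0.0625, 0.03125))
  expect_equal(uptake_efficiency("fermenter", 3), 0.875)
  expect_equal(uptake_efficiency("acetogen", 1), 0.50)
  expect_error(uptake_efficiency("fermenter", 6), "0..5")
})

test_that("scenario rules gate hybrids, soluble cross-feeding and H2", {
  expect_error(crossfeed_rules("bogus"))
  nf <- crossfeed_rules("nonfusing")
  expect_false(nf$use_hybrids); expect_false(nf$product_crossfeed)
  fu <- crossfeed_rules("fusing")
  expect_true(fu$use_hybrids); expect_true(fu$h2_crossfeed)
  nh <- crossfeed_rules("no_h2_crossfeed")
  expect_true(nh$use_hybrids); expect_false(nh$h2_crossfeed)
})

test_that("the subpopulation roster has 12 members when fusing, 2 otherwise", {
  specs <- build_subpopulations(toy$fermenter, toy_aug,
                                toy_hybrid_fermenter, toy_hybrid_acetogen,
                                "fusing")
  expect_length(specs, 12L)
  expect_equal(sum(vapply(specs, `[[`, numeric(1), "state") == 0), 2L)
  expect_length(build_subpopulations(toy$fermenter, toy_aug,
                                     scenario = "nonfusing"), 2L)
})

test_that("substrate allocations sum to the culture drawdown", {
  specs <- build_subpopulations(toy$fermenter, toy_aug,
                                toy_hybrid_fermenter, toy_hybrid_acetogen,
                                "fusing")
  set.seed(11)
  for (i in 1:10) {
    st <- community_state(runif(1, 1e9, 1e11), runif(1, 1e9, 1e11),
                          runif(5, 0, 1e10), runif(5, 0, 1e10))
    dd <- list(glc = runif(1, 0, 10), fru = runif(1, 0, 5))
    al <- allocate_substrates(dd, st, specs)
    expect_equal(sum(al$glc), dd$glc, tolerance = 1e-12)
    expect_equal(sum(al$fru), dd$fru, tolerance = 1e-12)
    # the nonhybrid acetogen never receives glucose
    i_b0 <- which(vapply(specs, `[[`, character(1), "id") == "B_l0")
    expect_equal(al$glc[i_b0], 0)
  }
})

test_that("zero-weight substrates are flagged as unallocated", {
  specs <- build_subpopulations(toy$fermenter, toy_aug,
                                scenario = "nonfusing")
  st <- community_state(0, 1e10)  # only the acetogen present
  al <- allocate_substrates(list(glc = 5, fru = 0), st, specs)
  expect_identical(al$unallocated, "glc")
  expect_true(all(al$glc == 0))
})

test_that("an idle community leaves pools unchanged", {
  specs <- build_subpopulations(toy$fermenter, toy_aug,
                                scenario = "nonfusing")
  st <- community_state(1e10, 9e10)
  pools <- stats::setNames(numeric(13),
                           c("glc", "fru", tracked_products, "h2", "co2"))
  pools["glc"] <- 50
  out <- community_step(st, pools, 0.5, specs, crossfeed_rules("nonfusing"),
                        flat_growth_schedule(5),
                        list(glc = 0, fru = 0), 0, tracked_products)
  expect_equal(out$pools, pools)
})

test_that("community steps close the carbon balance on the toy pair", {
  specs <- build_subpopulations(toy$fermenter, toy_aug,
                                toy_hybrid_fermenter, toy_hybrid_acetogen,
                                "fusing")
  sched <- constant_rate_schedule(0.5, 0.2)
  ab <- integrate_growth(community_state(1e10, 9e10), sched, 1e-12, 2, 0.01)
  pools <- stats::setNames(numeric(13),
                           c("glc", "fru", tracked_products, "h2", "co2"))
  pools["glc"] <- 60; pools["fru"] <- 28
  carbon_of <- c(glc = 6, fru = 6, etoh = 2, ipoh = 3, btd = 4, btoh = 4,
                 but = 4, acetone = 3, ac = 2, lac = 3, actn = 4, h2 = 0,
                 co2 = 1)
  st <- cofusion:::state_at(ab, 1)
  out <- community_step(st, pools, 0.5, specs, crossfeed_rules("fusing"),
                        flat_growth_schedule(5),
                        list(glc = 6, fru = 4), 1, tracked_products)
  # per-subpopulation balance: carbon in = carbon out + biomass carbon
  for (i in seq_along(out$fluxes)) {
    v <- out$fluxes[[i]]
    if (all(v == 0)) next
    m <- specs[[i]]$model
    ex <- grep("^EX_", names(v), value = TRUE)
    mets <- sub("^EX_", "", ex)
    net_export <- sum(v[ex] * carbon_of[mets])
    bio <- v[[m$biomass_id]] *
      sum(abs(m$stoich[, m$biomass_id][m$stoich[, m$biomass_id] < 0]) *
            vapply(rownames(m$stoich)[m$stoich[, m$biomass_id] < 0],
                   function(x) {
                     f <- m$metabolites$formula[m$metabolites$id == x]
                     if (is.na(f)) 0 else carbon_content(f)
                   }, numeric(1)))
    expect_lt(abs(net_export + bio), 1e-6)
  }
  # community level: pool carbon change equals biomass carbon drain
  d_pool <- sum((out$pools - pools) * carbon_of[names(pools)])
  bio_carbon <- 2 * sum(out$growth)   # both biomass equations drain 2 C
  expect_lt(abs(d_pool + 0.5 * bio_carbon), 1e-6)
})

test_that("no-H2 scenario forbids acetogen hydrogen uptake", {
  cfg <- make_dmmm_config("no_h2_crossfeed", t_final = 2, dt = 1)
  specs <- build_subpopulations(cfg$fermenter, cfg$acetogen,
                                cfg$hybrid_fermenter, cfg$hybrid_acetogen,
                                "no_h2_crossfeed")
  pools <- stats::setNames(numeric(13),
                           c("glc", "fru", tracked_products, "h2", "co2"))
  pools["glc"] <- 60; pools["fru"] <- 28
  st <- cofusion:::state_at(cfg$abundance, 1)
  out <- community_step(st, pools, 0.5, specs,
                        crossfeed_rules("no_h2_crossfeed"),
                        flat_growth_schedule(5), list(glc = 6, fru = 4), 1,
                        tracked_products)
  for (i in seq_along(specs)) {
    if (specs[[i]]$role != "acetogen") next
    v <- out$fluxes[[i]]
    if ("EX_h2" %in% names(v)) expect_gte(v[["EX_h2"]], -1e-9)
  }
})

test_that("fusing with zero fusion reproduces the nonfusing trajectory", {
  tf <- run_scenario(make_dmmm_config("fusing", t_final = 3, dt = 1, f = 0))
  tn <- run_scenario(make_dmmm_config("nonfusing", t_final = 3, dt = 1,
                                      f = 0))
  expect_equal(tf$pools, tn$pools, tolerance = 1e-8)
  expect_equal(tf$max_titer_g_l, tn$max_titer_g_l, tolerance = 1e-8)
  expect_equal(tf$soluble_carbon_g_l, tn$soluble_carbon_g_l,
               tolerance = 1e-8)
})

test_that("maximum export rates dominate the realized export rates", {
  cfg <- make_dmmm_config("fusing", t_final = 2, dt = 1,
                          schedule = default_growth_schedule(33))
  specs <- build_subpopulations(cfg$fermenter, cfg$acetogen,
                                cfg$hybrid_fermenter, cfg$hybrid_acetogen,
                                "fusing")
  pools <- stats::setNames(numeric(13),
                           c("glc", "fru", tracked_products, "h2", "co2"))
  pools["glc"] <- 60; pools["fru"] <- 28
  st <- cofusion:::state_at(cfg$abundance, 1)
  rules <- crossfeed_rules("fusing")
  dd <- list(glc = 6, fru = 4)
  out <- community_step(st, pools, 0.5, specs, rules, cfg$schedule, dd, 1,
                        tracked_products)
  rates <- max_product_titers(st, pools, 0.5, specs, rules, cfg$schedule,
                              dd, 1, tracked_products, out$gas_evolved)
  for (p in tracked_products) {
    realized <- (out$pools[[p]] - pools[[p]]) / 0.5
    expect_gte(rates[[p]] + 1e-6, realized)
  }
})

test_that("pools and cumulative titers behave over a fusing run", {
  tr <- run_scenario(make_dmmm_config("fusing", t_final = 3, dt = 1,
                                      schedule =
                                        default_growth_schedule(33)))
  expect_true(all(tr$pools >= -1e-9))
  # cumulative maximum titers are nondecreasing (nothing consumed here)
  expect_true(all(apply(tr$max_titer_g_l, 2, function(x)
    all(diff(x) >= -1e-9))))
  expect_true(all(diff(tr$hexose_consumed) >= 0))
})

test_that("a zero-duration run returns the initial pools", {
  cfg <- make_dmmm_config("fusing", t_final = 3, dt = 1)
  cfg$t_final <- 0
  tr <- run_scenario(cfg)
  expect_length(tr$times, 1L)
  expect_equal(unname(tr$pools[1, "glc"]),
               predict(cfg$substrate_curves$glc, 0))
})

test_that("soluble carbon arithmetic follows the formulas", {
  pools <- c(etoh = 1000, ac = 0)
  expect_equal(soluble_carbon(pools, c(etoh = "C2H6O", ac = "C2H4O2")),
               2 * 12.011)  # 1 mol/L ethanol = 24.022 g/L carbon
  expect_equal(soluble_carbon(c(etoh = 0, ac = 0),
                              c(etoh = "C2H6O", ac = "C2H4O2")), 0)
  expect_error(soluble_carbon(pools, c(etoh = "C2H6O"),
                              products = c("etoh", "ac")), "missing")
})

test_that("yields per hexose come out of the cumulative bookkeeping", {
  tr <- run_scenario(make_dmmm_config("fusing", t_final = 3, dt = 1,
                                      schedule =
                                        default_growth_schedule(33)))
  y <- yields_per_hexose(tr)
  expect_named(y, tracked_products)
  expect_true(all(y >= -1e-9))
  i <- length(tr$times)
  expect_equal(unname(y["ac"]),
               unname((tr$pools[i, "ac"] - tr$pools[1, "ac"]) /
                        tr$hexose_consumed[i]))
})

test_that("the staged growth schedule encodes the three fermentation phases", {
  s <- default_growth_schedule()
  at <- function(org, t) cofusion:::schedule_at(s, org, t)
  expect_equal(at("A", 5)$fraction, 0.56)
  expect_equal(at("B", 5)$fraction, 0.05)
  expect_equal(at("A", 15)$fraction, 0.35)
  expect_setequal(at("A", 15)$consumes, c("but", "lac"))
  expect_equal(at("B", 15)$fraction, 1)
  expect_length(at("B", 15)$consumes, 0)
  expect_equal(at("A", 25)$fraction, 0.35)
  expect_setequal(at("B", 25)$consumes, "acetone")
  expect_error(at("A", 40), "gap")
  expect_error(growth_efficiency_schedule(
    data.frame(start = c(0, 5), end = c(10, 15), organism = "A",
               fraction = 0.5, consumes = "")), "overlap")
})
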