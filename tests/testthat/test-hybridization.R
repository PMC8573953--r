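test_that("acetogen augmentation adds exactly the six coculture reactions", {
  added <- setdiff(toy_aug$reactions$id, toy$acetogen$reactions$id)
  expect_setequal(added, c("EX_acetone", "EX_actn", "EX_ipoh", "EX_btd",
                           "SADH", "BDH"))
  expect_identical(augment_acetogen(toy_aug)$reactions$id,
                   toy_aug$reactions$id)  # idempotent
})

test_that("augmented acetogen fed acetone and H2 secretes isopropanol", {
  sol <- fba(toy_aug, objective_id = "EX_ipoh",
             extra_bounds = list(EX_fru = c(0, 1000),
                                 EX_acetone = c(-5, 0),
                                 EX_h2 = c(-20, 1000)))
  expect_equal(sol$status, "optimal")
  expect_gt(sol$objective, 0)
  # base acetogen cannot: no dehydrogenase
  expect_error(fba(toy$acetogen, objective_id = "EX_ipoh"), "unknown")
})

test_that("augmentation requires NADPH/NADP metabolites", {
  expect_error(augment_acetogen(chain_model()), "NADPH")
})

test_that("self-merge reproduces the original optimum with no donor tags", {
  m <- merge_models(toy$fermenter, toy$fermenter)
  expect_equal(fba(m)$objective, fba(toy$fermenter)$objective)
  expect_false(any(m$reactions$source_organism == "donor"))
})

test_that("merging never decreases the host maximum growth rate", {
  pairs <- list(list(toy$fermenter, toy_aug),
                list(toy_aug, toy$fermenter),
                list(toy$acetogen, toy$fermenter),
                list(toy$fermenter, toy$acetogen))
  for (p in pairs) {
    host_mu <- fba(p[[1]])$objective
    hyb_mu <- fba(merge_models(p[[1]], p[[2]]))$objective
    expect_gte(hyb_mu + 1e-9, host_mu)
  }
})

test_that("hybrid models keep the host biomass and partition tags", {
  m <- toy_hybrid_acetogen
  expect_identical(m$biomass_id, "BIOMASS_a")
  expect_false("BIOMASS_f" %in% m$reactions$id)
  tags <- m$reactions$source_organism
  expect_setequal(unique(tags), c("host", "donor", "shared"))
  expect_equal(sum(tags == "host") + sum(tags == "donor") +
                 sum(tags == "shared"), nrow(m$reactions))
})

test_that("duplicate reactions are kept once with union bounds", {
  m <- toy_hybrid_acetogen
  # EX_fru exists in both models with different lower bounds
  i <- match("EX_fru", m$reactions$id)
  expect_identical(m$reactions$source_organism[i], "shared")
  expect_equal(m$reactions$lower_bound[i],
               min(toy$acetogen$reactions$lower_bound[
                 toy$acetogen$reactions$id == "EX_fru"],
                 toy$fermenter$reactions$lower_bound[
                   toy$fermenter$reactions$id == "EX_fru"]))
  expect_equal(sum(m$reactions$id == "EX_fru"), 1L)
})

test_that("conflicting stoichiometry under one reaction id is an error", {
  donor <- chain_model()
  host <- chain_model()
  host$stoich["B", "CONV"] <- 2  # same id, different chemistry
  expect_error(merge_models(host, donor), "conflict")
})

test_that("hybrid acetogen gains glucose growth from the fermenter donor", {
  expect_equal(fba(toy$acetogen,
                   extra_bounds = list(EX_fru = c(0, 1000)))$objective, 0)
  sol <- fba(toy_hybrid_acetogen,
             extra_bounds = list(EX_fru = c(0, 1000), EX_glc = c(-10, 0)))
  expect_gt(sol$objective, 0)
})

test_that("clean models pass the EGC certificate untouched", {
  for (m in list(toy$fermenter, toy$acetogen)) {
    res <- strip_energy_generating_cycles(m)
    expect_equal(nrow(res$report), 0L)
    expect_identical(res$model$reactions$lower_bound,
                     m$reactions$lower_bound)
  }
  cert <- egc_certificate(toy$fermenter)
  expect_true(all(cert <= 1e-6))
})

test_that("a planted ATP-generating loop is found, constrained, certified", {
  m <- add_reaction(toy$fermenter, "LOOP_A", c(pyr = -1, lac = 1, atp = 1),
                    lower = -1000, upper = 1000)
  m <- add_reaction(m, "LOOP_B", c(lac = -1, pyr = 1),
                    lower = -1000, upper = 1000)
  expect_gt(egc_certificate(m)[["ATPM"]], 1)
  res <- strip_energy_generating_cycles(m)
  expect_gt(nrow(res$report), 0L)
  expect_true(all(res$report$reaction %in% c("LOOP_A", "LOOP_B")))
  expect_lt(egc_certificate(res$model)[["ATPM"]], 1e-6)
  # growth is untouched by the minimal constraint
  expect_equal(fba(res$model)$objective, fba(toy$fermenter)$objective)
  # idempotent
  res2 <- strip_energy_generating_cycles(res$model)
  expect_equal(nrow(res2$report), 0L)
})

test_that("self-merge gain-of-function report is empty with zero delta", {
  m <- merge_models(toy$fermenter, toy$fermenter)
  rep <- gain_of_function(m, toy$fermenter)
  expect_length(rep$newly_unblocked_native, 0)
  expect_length(rep$donor_reactions_carrying_flux, 0)
  expect_equal(nrow(rep$necessarily_active_nonnative), 0L)
  expect_equal(rep$growth_delta, 0)
})

test_that("a donor transporter enabling sole-carbon growth is necessarily active", {
  # host: acetogen with fructose shut off; donor fermenter contributes
  # the only route to carbon (glucose uptake)
  host <- set_bounds(toy_aug, "EX_fru", lower = 0, upper = 0)
  hyb <- merge_models(host, toy$fermenter)
  hyb <- set_bounds(hyb, "EX_fru", lower = 0, upper = 0)
  hyb <- set_bounds(hyb, "EX_glc", lower = -10, upper = 0)
  rep <- gain_of_function(hyb, host)
  expect_true(all(c("EX_glc", "HEX_G") %in%
                    rep$necessarily_active_nonnative$id))
  expect_true(all(rep$necessarily_active_nonnative$id %in%
                    rep$donor_reactions_carrying_flux))
  rngs <- rep$necessarily_active_nonnative
  expect_true(all(rngs$min > 1e-6 | rngs$max < -1e-6))
  expect_gt(rep$growth_hybrid, 0)
})

test_that("donor content unblocks planted host dead ends", {
  # host: acetogen with a secondary-alcohol branch but no acetone
  # source; the fermenter donor's acetone synthesis unblocks it
  host <- add_reaction(toy$acetogen, "SADH",
                       c(acetone = -1, nadph = -1, ipoh = 1, nadp = 1),
                       formulas = c(acetone = "C3H6O", ipoh = "C3H8O"))
  host <- add_reaction(host, "EX_ipoh", c(ipoh = -1),
                       lower = -1000, upper = 1000)
  expect_true(all(c("SADH", "NPHYD") %in% blocked_reactions(host)))
  hyb <- merge_models(host, toy$fermenter)
  rep <- gain_of_function(hyb, host)
  expect_true(all(c("SADH", "NPHYD") %in% rep$newly_unblocked_native))
})
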