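test_that("fusion system vanishes on the zero state", {
  sched <- constant_rate_schedule(0.5, 0.2)
  st <- community_state(0, 0)
  expect_true(all(fusion_rhs(st, 0, sched, 1e-12) == 0))
})

test_that("without fusion or hybrids the system is pure Monod growth", {
  sched <- constant_rate_schedule(0.5, 0.2)
  st <- community_state(2e10, 3e10)
  d <- fusion_rhs(st, 0, sched, 0)
  expect_equal(d["A", 1], 0.5 * 2e10)
  expect_equal(d["B", 1], 0.2 * 3e10)
  expect_true(all(d[, -1] == 0))
})

test_that("fusion conserves cells: total derivative telescopes to nonhybrid growth", {
  sched <- constant_rate_schedule(0.45, 0.15)
  set.seed(101)
  for (i in 1:100) {
    st <- community_state(runif(1, 0, 1e11), runif(1, 0, 1e11),
                          runif(5, 0, 1e10), runif(5, 0, 1e10))
    d <- fusion_rhs(st, runif(1, 0, 48), sched, 10^runif(1, -14, -11))
    expected <- 0.45 * st["A", 1] + 0.15 * st["B", 1]
    expect_equal(sum(d), expected, tolerance = 1e-10)
  }
})

test_that("fusion rhs rejects invalid inputs", {
  sched <- constant_rate_schedule(0.5, 0.2)
  st <- community_state(1, 1)
  expect_error(fusion_rhs(st, 0, sched, -1), "nonnegative")
  bad <- st; bad["A", 1] <- -1
  expect_error(fusion_rhs(bad, 0, sched, 0), "negative")
})

test_that("integration matches the closed-form exponential without fusion", {
  sched <- constant_rate_schedule(0.5, 0.2)
  tr <- integrate_growth(community_state(1, 0), sched, 0, 2, 1e-3)
  endpoint <- tr$X[length(tr$times), "A", 1]
  expect_equal(endpoint, exp(1), tolerance = 1e-3)
})

test_that("Euler integration converges first order in the step size", {
  sched <- constant_rate_schedule(0.5, 0.2)
  init <- community_state(1e10, 9e10)
  ref <- integrate_growth(init, sched, 1e-12, 8, 0.0025)
  e_dt <- function(dt) {
    tr <- integrate_growth(init, sched, 1e-12, 8, dt)
    max(abs(tr$X[length(tr$times), , ] - ref$X[length(ref$times), , ]) /
          max(ref$X[length(ref$times), , ]))
  }
  e1 <- e_dt(0.04); e2 <- e_dt(0.02)
  expect_lt(e2, e1)
  expect_gt(e1 / e2, 1.5)  # first-order: halving dt ~halves the error
  expect_lt(e1 / e2, 3)
  # endpoint agreement between dt and dt/2 is itself small
  expect_lt(e2, 1e-2)
})

test_that("abundances stay nonnegative during integration", {
  sched <- constant_rate_schedule(0.5, 0.2)
  tr <- integrate_growth(community_state(1e10, 9e10), sched, 1e-11, 48, 0.1)
  expect_true(all(tr$X >= 0))
})

test_that("species fractions start at the inoculation split and sum to one", {
  sched <- constant_rate_schedule(0.5, 0.2)
  tr <- integrate_growth(community_state(1e10, 9e10), sched, 1e-12, 24, 0.02)
  sp <- species_abundance(tr)
  expect_equal(sp$frac_A[1], 0.10)
  expect_equal(sp$frac_B[1], 0.90)
  set.seed(7)
  idx <- sample(nrow(sp), 100)
  expect_equal(sp$frac_A[idx] + sp$frac_B[idx], rep(1, 100))
})

test_that("single-organism trajectory has fraction one throughout", {
  sched <- constant_rate_schedule(0.5, 0.2)
  tr <- integrate_growth(community_state(1e10, 0), sched, 0, 5, 0.01)
  sp <- species_abundance(tr)
  expect_true(all(sp$frac_A == 1))
})

test_that("state fractions are consistent community- and organism-level", {
  sched <- constant_rate_schedule(0.5, 0.2)
  tr <- integrate_growth(community_state(1e10, 9e10), sched, 1e-12, 24, 0.02)
  st <- state_abundance(tr)
  expect_equal(st$community$nonhybrid_A[1], 0.10)
  expect_equal(st$community$hybrid[1], 0)
  sums <- st$community$nonhybrid_A + st$community$nonhybrid_B +
    st$community$hybrid
  expect_equal(sums, rep(1, length(sums)))
  for (k in c("A", "B")) {
    w <- st$within[st$within$organism == k, paste0("l", 0:5)]
    expect_equal(unname(rowSums(w)), rep(1, nrow(w)), tolerance = 1e-12)
  }
})

test_that("fusion parameter is recovered from noiseless synthetic data", {
  sched <- constant_rate_schedule(0.5, 0.2)
  init <- community_state(1e10, 9e10)
  ds <- synthetic_fusion_dataset(1e-12, sched, init,
                                 obs_times = seq(0, 24, by = 4),
                                 noise_sd = 0, dt = 0.02)
  fit <- fit_fusion_parameter(ds$observed, sched, init, dt = 0.02)
  expect_lt(abs(fit$f - 1e-12) / 1e-12, 0.05)
})

test_that("zero true fusion rate fits to the lower bound", {
  sched <- constant_rate_schedule(0.5, 0.2)
  init <- community_state(1e10, 9e10)
  ds <- synthetic_fusion_dataset(0, sched, init,
                                 obs_times = seq(0, 24, by = 6),
                                 noise_sd = 0, dt = 0.05)
  fit <- fit_fusion_parameter(ds$observed, sched, init, dt = 0.05)
  expect_lte(fit$f, 1e-15)
})

test_that("fitted f is a local minimum of the weighted objective", {
  sched <- constant_rate_schedule(0.5, 0.2)
  init <- community_state(1e10, 9e10)
  ds <- synthetic_fusion_dataset(2e-12, sched, init,
                                 obs_times = seq(0, 24, by = 6),
                                 noise_sd = 0, dt = 0.05)
  fit <- fit_fusion_parameter(ds$observed, sched, init, dt = 0.05)
  obj <- function(f) cofusion:::fusion_objective(
    f, ds$observed, sched, init, 24, 0.05)
  expect_gte(obj(fit$f * 1.5), fit$objective_value)
  expect_gte(obj(fit$f * 0.5), fit$objective_value)
})

test_that("fit rejects degenerate inputs", {
  sched <- constant_rate_schedule(0.5, 0.2)
  init <- community_state(1e10, 9e10)
  obs <- data.frame(time = 0, organism = "A", fraction = 0.1, sd = 0.01)
  expect_error(fit_fusion_parameter(obs, sched, init), "two observation")
  obs2 <- rbind(obs, data.frame(time = 5, organism = "A", fraction = 0.3,
                                sd = 0.01))
  expect_error(fit_fusion_parameter(obs2, sched, init,
                                    f_bounds = c(1e-10, 1e-10)),
               "degenerate")
})
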