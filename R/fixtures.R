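# Deterministic toy community and seeded synthetic data generators.
#
# The toy pair emulates the biology of the coculture at lumped-pathway
# resolution: a solventogenic fermenter (glucose/fructose in; acetate,
# butyrate, butanol, acetone, ethanol, acetoin, lactate, CO2 and H2 out)
# and an acetogen that cannot take up glucose but grows on fructose or
# on CO2 + H2 through a Wood-Ljungdahl lump. Coefficients are integers
# and every reaction is carbon- and electron-balanced, so the FBA optima
# below are hand-checkable and the community simulation closes its
# carbon balance exactly. Cofactors (ATP, NAD(P)H) are lumped
# energy/electron carriers and carry carbon-free placeholder formulas.

#' @noRd
toy_metabolites <- function(ids) {
  formulas <- c(
    glc = "C6H12O6", fru = "C6H12O6", pyr = "C3H4O3", accoa = "C2H4O2",
    aacoa = "C4H6O3", co2 = "CO2", h2 = "H2",
    ac = "C2H4O2", etoh = "C2H6O", but = "C4H8O2", btoh = "C4H10O",
    acetone = "C3H6O", actn = "C4H8O2", lac = "C3H6O3",
    ipoh = "C3H8O", btd = "C4H10O2",
    atp = "HO4P", nadh = "H2", nadph = "H2", nadp = "H")
  data.frame(id = ids, formula = unname(formulas[ids]),
             compartment = "c", name = ids)
}

#' @noRd
build_toy <- function(id, rxns, biomass_id) {
  met_ids <- unique(unlist(lapply(rxns, function(r) names(r$coef))))
  mets <- toy_metabolites(met_ids)
  rxn_df <- data.frame(
    id = vapply(rxns, `[[`, character(1), "id"),
    name = vapply(rxns, `[[`, character(1), "id"),
    lower_bound = vapply(rxns, `[[`, numeric(1), "lb"),
    upper_bound = vapply(rxns, `[[`, numeric(1), "ub"),
    source_organism = id)
  S <- matrix(0, nrow(mets), nrow(rxn_df),
              dimnames = list(mets$id, rxn_df$id))
  for (r in rxns) S[names(r$coef), r$id] <- r$coef
  metabolic_network(id, mets, rxn_df, S, biomass_id = biomass_id)
}

#' @noRd
rx <- function(id, coef, lb = 0, ub = 1000) list(id = id, coef = coef,
                                                 lb = lb, ub = ub)

#' Toy fermenter/acetogen model pair with recorded optima
#'
#' Returns the deterministic two-member toy community used throughout
#' the test suite, together with its hand-solved FBA optima:
#'
#' * fermenter on 10 mmol gDW^-1 h^-1 glucose: maximum biomass flux 10
#'   (each glucose yields 2 acetyl-CoA + 2 ATP + 2 NADH; biomass drains
#'   1 acetyl-CoA + 3 ATP + 1 NADH, surplus acetyl-CoA goes to acetate
#'   for ATP, surplus NADH to H2);
#' * acetogen on 10 fructose: maximum biomass flux 12.5 (evolved CO2 is
#'   refixed through the Wood-Ljungdahl lump until NADH runs out);
#' * acetogen on gas only (10 CO2 + 20 H2): maximum biomass flux 1.25;
#' * acetogen on glucose alone: zero growth (no transporter).
#'
#' The acetogen additionally carries an H2-driven NADPH regeneration
#' reaction whose products have no consumer until [augment_acetogen()]
#' adds the secondary-alcohol/2,3-butanediol dehydrogenases -- a planted
#' blocked-reaction set.
#'
#' @return list of class `toy_community`: `fermenter`, `acetogen`
#'   (networks), `optima` (named list of the recorded values above),
#'   `biomass_carbon` (mol C drained per unit biomass flux, per model).
#' @export
toy_community_models <- function() {
  fermenter <- build_toy("toy_fermenter", list(
    rx("EX_glc", c(glc = -1), -10, 1000),
    rx("EX_fru", c(fru = -1), 0, 1000),
    rx("HEX_G", c(glc = -1, pyr = 2, atp = 2, nadh = 2)),
    rx("HEX_F", c(fru = -1, pyr = 2, atp = 2, nadh = 2)),
    rx("PFOR_H", c(pyr = -1, accoa = 1, co2 = 1, h2 = 1)),
    rx("ACK", c(accoa = -1, ac = 1, atp = 1)),
    rx("ADH", c(accoa = -1, nadh = -2, etoh = 1)),
    rx("THL", c(accoa = -2, aacoa = 1)),
    rx("BUK", c(aacoa = -1, nadh = -2, but = 1, atp = 1)),
    rx("BDHA", c(aacoa = -1, nadh = -4, btoh = 1)),
    rx("ADC", c(aacoa = -1, acetone = 1, co2 = 1)),
    rx("ALS", c(pyr = -2, actn = 1, co2 = 2)),
    rx("LDH", c(pyr = -1, nadh = -1, lac = 1)),
    rx("HYD", c(nadh = -1, h2 = 1)),
    rx("ATPM", c(atp = -1)),
    rx("BIOMASS_f", c(accoa = -1, atp = -3, nadh = -1)),
    rx("EX_ac", c(ac = -1)), rx("EX_etoh", c(etoh = -1)),
    rx("EX_but", c(but = -1)), rx("EX_btoh", c(btoh = -1)),
    rx("EX_acetone", c(acetone = -1)), rx("EX_actn", c(actn = -1)),
    rx("EX_lac", c(lac = -1)),
    rx("EX_co2", c(co2 = -1)), rx("EX_h2", c(h2 = -1))),
    biomass_id = "BIOMASS_f")

  acetogen <- build_toy("toy_acetogen", list(
    rx("EX_fru", c(fru = -1), -10, 1000),
    rx("EX_co2", c(co2 = -1), 0, 1000),
    rx("EX_h2", c(h2 = -1), 0, 1000),
    rx("HEX_F", c(fru = -1, pyr = 2, atp = 2, nadh = 2)),
    rx("PFOR", c(pyr = -1, accoa = 1, co2 = 1, nadh = 1)),
    rx("WLP", c(co2 = -2, nadh = -4, accoa = 1)),
    rx("HYDA", c(h2 = -1, nadh = 1)),
    rx("ACK", c(accoa = -1, ac = 1, atp = 1)),
    rx("ADH", c(accoa = -1, nadh = -2, etoh = 1)),
    rx("NPHYD", c(h2 = -1, nadp = -1, nadph = 1)),
    rx("ATPM", c(atp = -1)),
    rx("BIOMASS_a", c(accoa = -1, atp = -3)),
    rx("EX_ac", c(ac = -1)), rx("EX_etoh", c(etoh = -1))),
    biomass_id = "BIOMASS_a")

  structure(
    list(fermenter = fermenter, acetogen = acetogen,
         optima = list(fermenter_glc10 = 10,
                       acetogen_fru10 = 12.5,
                       acetogen_gas_co2_10_h2_20 = 1.25,
                       acetogen_glc_only = 0),
         biomass_carbon = c(toy_fermenter = 2, toy_acetogen = 2)),
    class = "toy_community")
}

#' Logistic monoculture OD600 series with seeded noise
#'
#' Emulates a 48-h batch monoculture growth curve: logistic growth from
#' inoculum `od0` at intrinsic rate `r` toward carrying capacity `K`,
#' sampled on `times`, with i.i.d. Gaussian noise truncated so values
#' stay positive. The defaults for the fermenter-like organism
#' (`r = 0.6 h^-1`, `K = 6`) are faster than the acetogen-like defaults
#' (`r = 0.25 h^-1`, `K = 3`), mirroring the growth-rate asymmetry of
#' the coculture.
#'
#' @param od0 inoculum OD600 (default 0.05).
#' @param r intrinsic growth rate, 1/h.
#' @param K carrying capacity (OD600 units), `> 0`.
#' @param times sampling times (default every 0.5 h over 48 h).
#' @param noise_sd Gaussian noise standard deviation (0 = exact).
#' @param seed RNG seed (required whenever `noise_sd > 0`).
#' @return data frame with columns `time_h`, `value`.
#' @export
synthetic_monoculture_od <- function(od0 = 0.05, r = 0.6, K = 6,
                                     times = seq(0, 48, by = 0.5),
                                     noise_sd = 0, seed = NULL) {
  if (K <= 0 || od0 <= 0 || r <= 0)
    stop("logistic parameters must be positive", call. = FALSE)
  od <- K * od0 * exp(r * times) / (K + od0 * (exp(r * times) - 1))
  if (noise_sd > 0) {
    if (is.null(seed)) stop("seed required when noise_sd > 0", call. = FALSE)
    rng <- local_rng(seed)
    od <- pmax(od + rng$rnorm(length(od), 0, noise_sd), 1e-4)
  }
  data.frame(time_h = times, value = od)
}

#' @noRd
local_rng <- function(seed) {
  # isolated RNG stream: no global .Random.seed side effects
  env <- new.env()
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed",
                                                      globalenv()) else NULL
  set.seed(seed)
  env$state <- get(".Random.seed", globalenv())
  restore <- function() {
    if (is.null(old)) rm(".Random.seed", envir = globalenv())
    else assign(".Random.seed", old, envir = globalenv())
  }
  restore()
  list(
    rnorm = function(n, mean = 0, sd = 1) {
      old2 <- if (exists(".Random.seed", globalenv()))
        get(".Random.seed", globalenv()) else NULL
      assign(".Random.seed", env$state, envir = globalenv())
      out <- stats::rnorm(n, mean, sd)
      env$state <- get(".Random.seed", globalenv())
      if (is.null(old2)) rm(".Random.seed", envir = globalenv())
      else assign(".Random.seed", old2, envir = globalenv())
      out
    })
}

#' Synthetic coculture fusion dataset with known ground truth
#'
#' Integrates the fusion ODE system at a known `f_true`, samples species
#' fractional abundances at `obs_times`, and adds seeded Gaussian noise;
#' the recorded standard deviations equal `max(noise_sd, 1e-3)`. The
#' default initial condition is the experimental inoculation convention:
#' 10% nonhybrid fermenter, 90% nonhybrid acetogen, on a total scale of
#' 1e11 cells/liter.
#'
#' @param f_true fusion rate constant (liter cells^-1 h^-1), `>= 0`.
#' @param rates a [rate_schedule()].
#' @param init `community_state` at t = 0.
#' @param obs_times observation times (hours), within the span.
#' @param noise_sd noise on fractions (0 = noiseless).
#' @param seed RNG seed (required whenever `noise_sd > 0`).
#' @param dt Euler step for the generating integration (default 0.01).
#' @return list of class `synthetic_fusion_dataset`: `observed` (data
#'   frame `time`, `organism`, `fraction`, `sd` for both organisms),
#'   `trajectory`, `f_true`, `init`.
#' @export
synthetic_fusion_dataset <- function(f_true, rates,
                                     init = community_state(1e10, 9e10),
                                     obs_times = seq(0, 48, by = 12),
                                     noise_sd = 0, seed = NULL, dt = 0.01) {
  if (f_true < 0) stop("f_true must be nonnegative", call. = FALSE)
  t_final <- max(obs_times)
  if (t_final <= 0) stop("invalid observation span", call. = FALSE)
  traj <- integrate_growth(init, rates, f_true, t_final, dt)
  sp <- species_abundance(traj)
  frac_A <- stats::approx(sp$time, sp$frac_A, xout = obs_times)$y
  if (noise_sd > 0) {
    if (is.null(seed)) stop("seed required when noise_sd > 0", call. = FALSE)
    rng <- local_rng(seed)
    frac_A <- pmin(pmax(frac_A + rng$rnorm(length(frac_A), 0, noise_sd),
                        0), 1)
  }
  sd <- rep(max(noise_sd, 1e-3), length(obs_times))
  observed <- rbind(
    data.frame(time = obs_times, organism = "A", fraction = frac_A,
               sd = sd),
    data.frame(time = obs_times, organism = "B", fraction = 1 - frac_A,
               sd = sd))
  structure(list(observed = observed, trajectory = traj, f_true = f_true,
                 init = init),
            class = "synthetic_fusion_dataset")
}

#' Smooth synthetic substrate depletion curves for community runs
#'
#' Monotone-declining glucose and fructose concentration profiles
#' (mmol/liter) standing in for measured fermentation substrate curves:
#' logistic-decay drawdown of `glc0` mmol/L glucose and `fru0` mmol/L
#' fructose over `t_final` hours, interpolated with
#' [interpolate_monotone()].
#'
#' @param glc0,fru0 initial concentrations (defaults 60 and 28 mmol/L).
#' @param t_final span (default 33 h).
#' @param k_glc,k_fru decay rate constants (1/h).
#' @return list with `glc`, `fru` (`interpolated_series`).
#' @export
synthetic_substrate_profiles <- function(glc0 = 60, fru0 = 28,
                                         t_final = 33,
                                         k_glc = 0.12, k_fru = 0.2) {
  times <- seq(0, t_final, length.out = 34)
  list(glc = interpolate_monotone(times, glc0 * exp(-k_glc * times)),
       fru = interpolate_monotone(times, fru0 * exp(-k_fru * times)))
}

#' Write the toy fixtures to disk
#'
#' Emits the toy model pair in the constraint-based JSON dialect plus a
#' seeded synthetic monoculture OD series and fusion dataset as CSV.
#'
#' @param dir output directory (created if needed).
#' @param seed RNG seed for the synthetic series.
#' @return `dir`, invisibly.
#' @export
write_fixtures <- function(dir, seed = 1L) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  toy <- toy_community_models()
  write_model(toy$fermenter, file.path(dir, "toy_fermenter.json"))
  write_model(toy$acetogen, file.path(dir, "toy_acetogen.json"))
  od <- synthetic_monoculture_od(noise_sd = 0.05, seed = seed)
  utils::write.csv(od, file.path(dir, "monoculture_od_fermenter.csv"),
                   row.names = FALSE)
  rates <- constant_rate_schedule(0.5, 0.2)
  ds <- synthetic_fusion_dataset(1e-12, rates, noise_sd = 0.02, seed = seed)
  utils::write.csv(ds$observed, file.path(dir, "coculture_abundance.csv"),
                   row.names = FALSE)
  invisible(dir)
}
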