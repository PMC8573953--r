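#' Read a measurement time series from delimited text
#'
#' Expects columns `time_h`, `value` and optionally `sd` (CSV or TSV,
#' autodetected). This is the on-disk layout for monoculture OD600
#' curves and extracellular concentration profiles; spreadsheet
#' supplements should be exported sheet-by-sheet to this layout (no
#' spreadsheet reader is bundled).
#'
#' @param path file path.
#' @return data frame with `time_h`, `value` and (if present) `sd`,
#'   sorted by time.
#' @export
read_timeseries <- function(path) {
  sep <- if (grepl("\\.tsv$", path, ignore.case = TRUE)) "\t" else ","
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          stringsAsFactors = FALSE)
  need <- c("time_h", "value")
  if (!all(need %in% names(df)))
    stop(path, " must have columns time_h, value[, sd]", call. = FALSE)
  df[order(df$time_h), intersect(c("time_h", "value", "sd"), names(df))]
}

#' Read coculture relative-abundance observations
#'
#' Expects columns `time` (h), `organism` (`"A"` for the fermenter
#' genotype, `"B"` for the acetogen genotype), `fraction` and `sd` --
#' the layout produced by [write_fixtures()] and the one a genome
#' copy-number table reduces to under the one-genome-per-cell
#' convention (relative abundance = copy-number share).
#'
#' @param path file path (CSV or TSV).
#' @return data frame suitable for [fit_fusion_parameter()].
#' @export
read_abundance <- function(path) {
  sep <- if (grepl("\\.tsv$", path, ignore.case = TRUE)) "\t" else ","
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          stringsAsFactors = FALSE)
  need <- c("time", "organism", "fraction", "sd")
  if (!all(need %in% names(df)))
    stop(path, " must have columns time, organism, fraction, sd",
         call. = FALSE)
  df[order(df$time, df$organism), need]
}

#' Build a rate schedule from two monoculture OD tables
#'
#' Interpolates each OD600 curve monotonically, computes interval
#' specific growth rates on the regular grid and wraps the two
#' piecewise-constant lookups in a [rate_schedule()] (all hybrid states
#' share the organism's monoculture rate).
#'
#' @param od_A,od_B data frames with `time_h`, `value` (fermenter and
#'   acetogen monocultures).
#' @param grid_step rate-interval width in hours (default 0.1).
#' @param n_states hybrid states (default 5).
#' @return a [rate_schedule()].
#' @export
schedule_from_od <- function(od_A, od_B, grid_step = 0.1, n_states = 5L) {
  mk <- function(od) {
    s <- interpolate_monotone(od$time_h, od$value, grid_step)
    rate_lookup(specific_growth_rates(s))
  }
  rate_schedule(mk(od_A), mk(od_B), n_states = n_states)
}

#' Read a DMMM run configuration (YAML)
#'
#' The configuration names the model files, scenario, schedule, curve
#' files, step and span; see the packaged example in
#' `system.file("extdata", "dmmm_config_example.yaml", package =
#' "cofusion")`. Paths are resolved relative to the configuration file.
#'
#' @param path YAML file.
#' @return a config list for [run_scenario()] (models and curves
#'   loaded).
#' @export
read_dmmm_config <- function(path) {
  y <- yaml::read_yaml(path)
  base <- dirname(path)
  rel <- function(p) if (is.null(p)) NULL else
    if (file.exists(p)) p else file.path(base, p)
  cfg <- list(
    scenario = y$scenario,
    t_final = y$t_final, dt = y$dt,
    fermenter = read_model(rel(y$models$fermenter)),
    acetogen = read_model(rel(y$models$acetogen)))
  if (!is.null(y$models$hybrid_fermenter))
    cfg$hybrid_fermenter <- read_model(rel(y$models$hybrid_fermenter))
  if (!is.null(y$models$hybrid_acetogen))
    cfg$hybrid_acetogen <- read_model(rel(y$models$hybrid_acetogen))
  if (!is.null(y$curves)) {
    mkcurve <- function(p) {
      df <- read_timeseries(rel(p))
      interpolate_monotone(df$time_h, df$value)
    }
    cfg$substrate_curves <- list(glc = mkcurve(y$curves$glc),
                                 fru = mkcurve(y$curves$fru))
    if (!is.null(y$curves$products))
      cfg$product_curves <- lapply(y$curves$products, mkcurve)
  }
  if (!is.null(y$schedule)) {
    iv <- do.call(rbind, lapply(y$schedule, function(row)
      data.frame(start = row$start, end = row$end,
                 organism = row$organism, fraction = row$fraction,
                 consumes = row$consumes %||chr2% "")))
    cfg$schedule <- growth_efficiency_schedule(iv)
  }
  if (!is.null(y$growth)) {
    init <- community_state(
      y$growth$init_total %||num% 1e11 * (y$growth$init_frac_A %||num% 0.1),
      y$growth$init_total %||num% 1e11 * (1 - (y$growth$init_frac_A
                                               %||num% 0.1)))
    rates <- if (!is.null(y$growth$od_A))
      schedule_from_od(read_timeseries(rel(y$growth$od_A)),
                       read_timeseries(rel(y$growth$od_B)))
    else constant_rate_schedule(y$growth$mu_A %||num% 0.5,
                                y$growth$mu_B %||num% 0.2)
    cfg$abundance <- integrate_growth(init, rates,
                                      y$growth$f %||num% 0,
                                      cfg$t_final %||num% 33)
  }
  cfg
}

#' Write a titer trajectory as TSV files
#'
#' @param trajectory a [run_scenario()] result.
#' @param dir output directory.
#' @return `dir`, invisibly.
#' @export
write_trajectory <- function(trajectory, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  pools <- data.frame(time_h = trajectory$times, trajectory$pools)
  utils::write.table(pools, file.path(dir, "pools_mmol_l.tsv"),
                     sep = "\t", row.names = FALSE, quote = FALSE)
  titer <- data.frame(time_h = trajectory$times, trajectory$max_titer_g_l,
                      soluble_carbon = trajectory$soluble_carbon_g_l)
  utils::write.table(titer, file.path(dir, "max_titer_g_l.tsv"),
                     sep = "\t", row.names = FALSE, quote = FALSE)
  growth <- data.frame(time_h = trajectory$times, trajectory$growth)
  utils::write.table(growth, file.path(dir, "subpopulation_growth.tsv"),
                     sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(dir)
}
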