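#' Monotone piecewise-cubic interpolation of a growth or concentration curve
#'
#' Fits a Fritsch-Carlson monotone cubic Hermite interpolant (the PCHIP
#' family) through measured time-series knots. The interpolant is exact at
#' the knots and preserves monotonicity between adjacent knots, so an
#' OD600 or metabolite-concentration curve never overshoots its
#' measurements -- a prerequisite for computing specific growth rates by
#' finite log-ratios, and for deriving substrate drawdown rates that never
#' change sign between measurements.
#'
#' @param times numeric vector of knot times (hours), strictly increasing.
#' @param values numeric vector of nonnegative knot values (OD600 or
#'   g/liter or mmol/liter), same length as `times`.
#' @param grid_step regular evaluation grid spacing in hours (default 0.1,
#'   the spacing used for specific-growth-rate intervals).
#' @return An object of class `interpolated_series` with fields
#'   `knot_times`, `knot_values`, `grid_step`, and a vectorized evaluator
#'   accessible through [predict.interpolated_series()].
#' @seealso [specific_growth_rates()]
#' @examples
#' s <- interpolate_monotone(c(0, 1, 2), c(0.1, 0.4, 0.8))
#' predict(s, c(0, 0.5, 1))
#' @export
interpolate_monotone <- function(times, values, grid_step = 0.1) {
  if (length(times) < 2L)
    stop("at least 2 knots are required", call. = FALSE)
  if (length(values) != length(times))
    stop("`times` and `values` must have equal length", call. = FALSE)
  if (anyNA(times) || anyNA(values))
    stop("knots must not contain NA", call. = FALSE)
  if (any(diff(times) <= 0))
    stop("`times` must be strictly increasing (no duplicates)", call. = FALSE)
  if (any(values < 0))
    stop("`values` must be nonnegative", call. = FALSE)
  if (!is.numeric(grid_step) || length(grid_step) != 1L || grid_step <= 0)
    stop("`grid_step` must be a positive scalar", call. = FALSE)
  fun <- stats::splinefun(times, values, method = "monoH.FC")
  structure(
    list(knot_times = as.numeric(times),
         knot_values = as.numeric(values),
         grid_step = grid_step,
         fun = fun),
    class = "interpolated_series")
}

#' Evaluate an interpolated series
#'
#' @param object an [interpolate_monotone()] result.
#' @param t numeric vector of query times (hours); must lie inside the
#'   knot span -- extrapolation is refused.
#' @param ... unused.
#' @return interpolated values at `t`.
#' @export
predict.interpolated_series <- function(object, t, ...) {
  rng <- range(object$knot_times)
  # tiny tolerance so the last grid point of seq() is never rejected
  eps <- 1e-9 * max(1, abs(rng[2]))
  if (any(t < rng[1] - eps | t > rng[2] + eps))
    stop(sprintf("query outside interpolation span [%g, %g]", rng[1], rng[2]),
         call. = FALSE)
  object$fun(pmin(pmax(t, rng[1]), rng[2]))
}

#' @export
print.interpolated_series <- function(x, ...) {
  cat(sprintf("<interpolated_series> %d knots over [%g, %g] h, grid step %g h\n",
              length(x$knot_times), min(x$knot_times), max(x$knot_times),
              x$grid_step))
  invisible(x)
}

#' Time-dependent specific growth rates from an interpolated OD curve
#'
#' Computes interval growth rates
#' \deqn{\mu_n = \ln(OD_n / OD_{n-1}) / (t_n - t_{n-1})}
#' on consecutive points of the regular evaluation grid. Over a 48-h curve
#' at the default 0.1-h spacing the grid carries 481 points and 480
#' interval rates; the grid point indices run 1..481 (returned as the
#' `grid_indices` attribute) while each rate is attached to the interval
#' ending at its `t_end`. Rates may be negative where the interpolated OD
#' declines (e.g. late stationary phase).
#'
#' @param series an [interpolate_monotone()] result (all interpolated
#'   values must be strictly positive -- the log-ratio is undefined at 0).
#' @param t_start,t_end optional sub-span (defaults: full knot span).
#' @return A data frame of class `rate_series` with columns `n` (interval
#'   index, 1-based), `t_start`, `t_end` (hours) and `mu` (per hour), plus
#'   attribute `grid_indices` (integer vector of grid point indices).
#' @export
specific_growth_rates <- function(series, t_start = NULL, t_end = NULL) {
  stopifnot(inherits(series, "interpolated_series"))
  rng <- range(series$knot_times)
  if (is.null(t_start)) t_start <- rng[1]
  if (is.null(t_end)) t_end <- rng[2]
  h <- series$grid_step
  grid <- seq(t_start, t_end, by = h)
  if (length(grid) < 2L)
    stop("span shorter than one grid step", call. = FALSE)
  od <- predict(series, grid)
  if (any(od <= 0))
    stop("interpolated OD must be strictly positive to take log-ratios",
         call. = FALSE)
  mu <- diff(log(od)) / diff(grid)
  out <- data.frame(n = seq_along(mu),
                    t_start = grid[-length(grid)],
                    t_end = grid[-1L],
                    mu = mu)
  attr(out, "grid_indices") <- seq_along(grid)
  class(out) <- c("rate_series", "data.frame")
  out
}

#' Piecewise-constant growth-rate lookup from interval rates
#'
#' Turns a [specific_growth_rates()] table into a function of time. Each
#' interval rate applies on its own grid interval (left-continuous
#' lookup): time `t` in `(t_start, t_end]` of interval `n` receives
#' `mu[n]`; `t` at or before the first interval start receives the first
#' rate.
#'
#' @param rates a `rate_series` data frame.
#' @return a vectorized function `time (h) -> mu (1/h)`.
#' @export
rate_lookup <- function(rates) {
  stopifnot(inherits(rates, "rate_series"))
  starts <- rates$t_start
  mu <- rates$mu
  t_max <- rates$t_end[nrow(rates)]
  function(t) {
    if (any(t > t_max + 1e-9))
      stop("rate lookup outside schedule span", call. = FALSE)
    idx <- findInterval(pmax(t, starts[1]), starts, rightmost.closed = FALSE)
    # findInterval puts t == t_start[n] into interval n, i.e. the interval
    # starting there; shift exact interior starts down to stay
    # left-continuous in (t_start, t_end]
    at_start <- idx > 1L & abs(t - starts[pmax(idx, 1L)]) < 1e-12
    idx[at_start] <- idx[at_start] - 1L
    mu[idx]
  }
}

#' Per-organism, per-hybrid-state growth-rate schedule
#'
#' Under the modeling assumption that all hybrid states of an organism
#' grow at the organism's monoculture rate, a schedule holds one
#' time-dependent rate function per organism, shared by all hybrid
#' states.
#'
#' @param mu_fun_A,mu_fun_B functions `time (h) -> mu (1/h)` for the
#'   fermenter-genotype (A, *Cac*) and acetogen-genotype (B, *Clj*)
#'   populations; typically [rate_lookup()] results or closures.
#' @param n_states number of hybrid states (default 5; state 0 is the
#'   nonhybrid state).
#' @return object of class `rate_schedule`: `$mu(k, l, t)` returns the
#'   rate for organism `k` ("A" or "B"), hybrid state `l` in `0..n_states`.
#' @export
rate_schedule <- function(mu_fun_A, mu_fun_B, n_states = 5L) {
  stopifnot(is.function(mu_fun_A), is.function(mu_fun_B), n_states >= 1L)
  funs <- list(A = mu_fun_A, B = mu_fun_B)
  structure(
    list(
      n_states = as.integer(n_states),
      mu = function(k, l, t) {
        if (!k %in% c("A", "B")) stop("unknown organism ", k, call. = FALSE)
        if (any(l < 0L) || any(l > n_states))
          stop("hybrid state out of range", call. = FALSE)
        funs[[k]](t)
      }),
    class = "rate_schedule")
}

#' Constant-rate schedule (convenience, mostly for tests and examples)
#' @param mu_A,mu_B constant specific growth rates (1/h).
#' @param n_states number of hybrid states.
#' @return a `rate_schedule`.
#' @export
constant_rate_schedule <- function(mu_A, mu_B, n_states = 5L) {
  rate_schedule(function(t) rep(mu_A, length(t)),
                function(t) rep(mu_B, length(t)),
                n_states = n_states)
}
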