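#' Community state: abundances by organism and hybrid state
#'
#' The coculture is tracked as `2 x (n_states + 1)` cell abundances
#' `X[k, l]` (cells per liter): organism `k` in \{A, B\} (A = the
#' *C. acetobutylicum* genotype, B = the *C. ljungdahlii* genotype) and
#' hybrid state `l` in \{0, .., n_states\}, where `l = 0` is the nonhybrid
#' state and `l >= 1` counts doubling times since a fusion event (each
#' division halves the nonnative proteome; after `n_states` doublings a
#' cell is considered reverted to nonhybrid).
#'
#' @param X0_A,X0_B nonhybrid abundances (cells/liter).
#' @param hybrid_A,hybrid_B numeric vectors of length `n_states` with
#'   hybrid-state abundances (default all zero).
#' @param n_states number of hybrid states (default 5).
#' @return matrix of class `community_state` with rownames `A`, `B` and
#'   colnames `l0..l<n>`.
#' @export
community_state <- function(X0_A, X0_B,
                            hybrid_A = numeric(n_states),
                            hybrid_B = numeric(n_states),
                            n_states = 5L) {
  n_states <- as.integer(n_states)
  stopifnot(length(hybrid_A) == n_states, length(hybrid_B) == n_states)
  X <- rbind(A = c(X0_A, hybrid_A), B = c(X0_B, hybrid_B))
  colnames(X) <- paste0("l", 0:n_states)
  if (any(X < 0)) stop("abundances must be nonnegative", call. = FALSE)
  if (any(!is.finite(X))) stop("abundances must be finite", call. = FALSE)
  class(X) <- c("community_state", class(X))
  X
}

#' Right-hand side of the hybrid-state cell fusion ODE system
#'
#' Implements the coupled balance on each organism `k` and hybrid state
#' `l`:
#' \deqn{dX_0^k/dt = \mu_0^k X_0^k - f X_0^A X_0^B + \mu_n^k X_n^k}
#' \deqn{dX_1^k/dt = f X_0^A X_0^B - \mu_1^k X_1^k}
#' \deqn{dX_l^k/dt = \mu_{l-1}^k X_{l-1}^k - \mu_l^k X_l^k, \quad l = 2..n}
#' The fusion term is second order in the two nonhybrid abundances with a
#' single rate constant `f` (liter cells^-1 h^-1); fusion events occur
#' only between nonhybrid cells, and the last hybrid state recycles into
#' the nonhybrid pool. Summing all equations telescopes to
#' `d(total)/dt = sum_k mu_0^k X_0^k`: fusion and hybrid-state transitions
#' conserve cell count, and only the nonhybrid growth terms add cells.
#'
#' @param state `community_state` matrix.
#' @param t time (hours).
#' @param rates a [rate_schedule()].
#' @param f fusion rate constant (liter cells^-1 h^-1), `>= 0`.
#' @return derivative matrix, same shape as `state`.
#' @export
fusion_rhs <- function(state, t, rates, f) {
  if (f < 0) stop("fusion parameter f must be nonnegative", call. = FALSE)
  if (any(state < 0)) stop("negative abundance in state", call. = FALSE)
  n <- ncol(state) - 1L
  if (rates$n_states != n)
    stop("rate schedule and state disagree on the number of hybrid states",
         call. = FALSE)
  dX <- state * 0
  fusion <- f * state["A", 1L] * state["B", 1L]
  for (k in c("A", "B")) {
    # all hybrid states share the organism's monoculture rate
    mu <- rep(rates$mu(k, 0L, t), n + 1L)
    dX[k, 1L] <- mu[1L] * state[k, 1L] - fusion + mu[n + 1L] * state[k, n + 1L]
    dX[k, 2L] <- fusion - mu[2L] * state[k, 2L]
    if (n >= 2L)
      for (l in 2:n)
        dX[k, l + 1L] <- mu[l] * state[k, l] - mu[l + 1L] * state[k, l + 1L]
  }
  dX
}

#' Integrate the fusion growth model (fixed-step forward Euler)
#'
#' Abundances are clamped at zero after each step; with the default step
#' of 0.01 h the integration is first-order convergent on the smooth
#' schedules used here (halving `dt` roughly halves the endpoint error).
#'
#' @param init `community_state` at `t = 0`.
#' @param rates a [rate_schedule()].
#' @param f fusion rate constant (liter cells^-1 h^-1).
#' @param t_final simulation end time (hours), `> 0`.
#' @param dt Euler step (hours), `> 0` (default 0.01).
#' @return object of class `fusion_trajectory`: list with `times` (length
#'   `m`) and `X`, an `m x 2 x (n_states+1)` array of abundances.
#' @export
integrate_growth <- function(init, rates, f, t_final, dt = 0.01) {
  stopifnot(dt > 0, t_final > 0)
  n_steps <- ceiling(t_final / dt - 1e-9)
  times <- c(0, seq_len(n_steps) * dt)
  times[length(times)] <- min(times[length(times)], t_final)
  X <- array(NA_real_, dim = c(length(times), nrow(init), ncol(init)),
             dimnames = list(NULL, rownames(init), colnames(init)))
  state <- unclass(init)
  X[1L, , ] <- state
  for (i in seq_len(n_steps)) {
    h <- times[i + 1L] - times[i]
    d <- fusion_rhs(state, times[i], rates, f)
    state <- state + h * d
    state[state < 0] <- 0
    if (any(!is.finite(state)))
      stop("non-finite state during integration (step too large?)",
           call. = FALSE)
    X[i + 1L, , ] <- state
  }
  structure(list(times = times, X = X, f = f), class = "fusion_trajectory")
}

#' @export
print.fusion_trajectory <- function(x, ...) {
  cat(sprintf("<fusion_trajectory> %d time points over [0, %g] h, f = %g\n",
              length(x$times), max(x$times), x$f))
  invisible(x)
}

#' Per-organism fractional abundance over time
#'
#' `fraction_k(t) = sum_l X[k, l](t) / sum_{k,l} X[k, l](t)`; the two
#' fractions sum to one at every time point.
#'
#' @param trajectory an [integrate_growth()] result.
#' @return data frame with columns `time`, `frac_A`, `frac_B`.
#' @export
species_abundance <- function(trajectory) {
  X <- trajectory$X
  tot_A <- unname(apply(X[, "A", , drop = FALSE], 1L, sum))
  tot_B <- unname(apply(X[, "B", , drop = FALSE], 1L, sum))
  tot <- tot_A + tot_B
  if (any(tot <= 0)) stop("total abundance is zero", call. = FALSE)
  data.frame(time = trajectory$times,
             frac_A = tot_A / tot,
             frac_B = tot_B / tot)
}

#' Nonhybrid/hybrid composition of the community over time
#'
#' Reports both views used when comparing against flow-cytometry style
#' measurements: community-level fractions of nonhybrid A, nonhybrid B
#' and (all) hybrid cells, which sum to one; and within-organism state
#' fractions (share of organism `k`'s cells in each hybrid state), which
#' sum to one per organism.
#'
#' @param trajectory an [integrate_growth()] result.
#' @return list with `community` (data frame: `time`,
#'   `nonhybrid_A`, `nonhybrid_B`, `hybrid`) and `within` (data frame:
#'   `time`, `organism`, one column per state `l0..ln`).
#' @export
state_abundance <- function(trajectory) {
  X <- trajectory$X
  m <- length(trajectory$times)
  n1 <- dim(X)[3L]
  tot <- unname(apply(X, 1L, sum))
  if (any(tot <= 0)) stop("total abundance is zero", call. = FALSE)
  hyb <- unname(apply(X[, , -1L, drop = FALSE], 1L, sum))
  community <- data.frame(
    time = trajectory$times,
    nonhybrid_A = unname(X[, "A", 1L]) / tot,
    nonhybrid_B = unname(X[, "B", 1L]) / tot,
    hybrid = hyb / tot)
  within <- do.call(rbind, lapply(c("A", "B"), function(k) {
    tot_k <- apply(X[, k, , drop = FALSE], 1L, sum)
    fr <- X[, k, ] / ifelse(tot_k > 0, tot_k, NA_real_)
    out <- data.frame(time = trajectory$times, organism = k)
    cbind(out, as.data.frame(fr))
  }))
  list(community = community, within = within)
}

#' Weighted objective for a candidate fusion parameter
#' @noRd
fusion_objective <- function(f, observed, rates, init, t_final, dt,
                             sd_floor = 1e-3) {
  traj <- integrate_growth(init, rates, f, t_final, dt)
  sp <- species_abundance(traj)
  pred <- stats::approx(sp$time, sp$frac_A, xout = observed$time)$y
  obs <- ifelse(observed$organism == "A", observed$fraction,
                1 - observed$fraction)
  sd <- pmax(observed$sd, sd_floor)
  sum((pred - obs)^2 / sd^2)
}

#' Fit the fusion rate constant to observed species fractions
#'
#' Minimizes the inverse-variance-weighted squared Euclidean distance
#' between predicted and observed species fractional abundances over the
#' fusion parameter `f`. The optimizer is deterministic and
#' derivative-free: a log-spaced grid scan over `f_bounds` followed by
#' golden-section refinement on the bracketing interval. Observation
#' standard deviations below `sd_floor` (fractional units) are clamped to
#' the floor before weighting.
#'
#' Because `f` multiplies absolute abundances, the fitted value trades
#' off exactly against the absolute inoculum scale; the scale used (total
#' cells/liter of `init`) is therefore recorded in the result.
#'
#' @param observed data frame with columns `time` (h), `organism`
#'   (`"A"`/`"B"`), `fraction` (observed species fractional abundance)
#'   and `sd` (standard deviation of the fraction); at least two
#'   observation times.
#' @param rates a [rate_schedule()].
#' @param init `community_state` at `t = 0` (absolute scale matters, see
#'   above).
#' @param f_bounds search interval for `f` (liter cells^-1 h^-1); default
#'   `c(1e-16, 1e-8)`.
#' @param t_final integration horizon (default: last observation time).
#' @param dt Euler step for each candidate integration (default 0.01 h).
#' @param n_grid log-spaced scan points (default 41).
#' @param sd_floor weighting floor for standard deviations (default 1e-3).
#' @return object of class `fusion_fit`: list with `f`,
#'   `objective_value`, `trajectory`, `abundance_scale` (total initial
#'   cells/liter) and the search settings.
#' @export
fit_fusion_parameter <- function(observed, rates, init,
                                 f_bounds = c(1e-16, 1e-8),
                                 t_final = NULL, dt = 0.01,
                                 n_grid = 41L, sd_floor = 1e-3) {
  need <- c("time", "organism", "fraction", "sd")
  if (!all(need %in% names(observed)))
    stop("`observed` needs columns ", paste(need, collapse = ", "),
         call. = FALSE)
  if (length(unique(observed$time)) < 2L)
    stop("at least two observation times are required", call. = FALSE)
  if (any(observed$sd < 0)) stop("negative sd", call. = FALSE)
  if (length(f_bounds) != 2L || f_bounds[1] < 0 || diff(f_bounds) <= 0)
    stop("degenerate `f_bounds`", call. = FALSE)
  if (is.null(t_final)) t_final <- max(observed$time)

  obj <- function(f) fusion_objective(f, observed, rates, init, t_final, dt,
                                      sd_floor)
  # log-spaced scan; include the lower boundary candidate explicitly
  lo <- max(f_bounds[1], 1e-300)
  grid <- exp(seq(log(lo), log(f_bounds[2]), length.out = n_grid))
  cand <- unique(c(f_bounds[1], grid))
  vals <- vapply(cand, obj, numeric(1))
  i <- which.min(vals)
  f_best <- cand[i]
  v_best <- vals[i]
  # golden-section refinement on the log-bracket around the grid minimum
  bracket <- c(max(cand[max(i - 1L, 1L)], lo),
               cand[min(i + 1L, length(cand))])
  if (bracket[2] > bracket[1] * (1 + 1e-12)) {
    opt <- stats::optimize(function(lf) obj(exp(lf)),
                           interval = log(bracket), tol = 1e-6)
    if (opt$objective < v_best) {
      f_best <- exp(opt$minimum)
      v_best <- opt$objective
    }
  }
  structure(
    list(f = f_best,
         objective_value = v_best,
         trajectory = integrate_growth(init, rates, f_best, t_final, dt),
         abundance_scale = sum(init),
         f_bounds = f_bounds, dt = dt, sd_floor = sd_floor),
    class = "fusion_fit")
}

#' @export
print.fusion_fit <- function(x, ...) {
  cat(sprintf(
    "<fusion_fit> f = %.4g liter cells^-1 h^-1 (weighted SSE %.4g)\n",
    x$f, x$objective_value))
  cat(sprintf("  abundance scale: %.3g cells/liter total inoculum\n",
              x$abundance_scale))
  invisible(x)
}
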