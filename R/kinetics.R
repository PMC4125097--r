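# Kinetic core of the simulator: tag incorporation at a locus in one cell
# follows the exchange ODE dF/dt = k (p(t) - F), where p(t) is the tagged
# fraction of the soluble pool, with a discrete replication-coupled reset
# F <- r F + (1 - r) p(t_rep) whenever the locus replicates. A population
# measurement averages F over cells whose cycle phases are uniform.

#' Tagged fraction of the soluble pool
#'
#' Saturating-exponential induction curve
#' `p(t) = 1 - exp(-(t - t0)/tau)` for `t > t0`, 0 otherwise; a step pool
#' when `tau = 0`. Vectorized over `t`.
#'
#' @param t hours since induction (>= 0).
#' @param params a [pool_params()].
#' @return pool tagged fraction(s) in \[0, 1\].
#' @examples
#' pool_fraction(6, pool_params(t0 = 2, tau = 4))  # 1 - exp(-1)
#' @export
pool_fraction <- function(t, params = pool_params()) {
  stopifnot(inherits(params, "pool_params"))
  if (any(t < 0)) stop("`t` must be nonnegative")
  out <- numeric(length(t))
  on_ <- t > params$t0
  if (params$tau == 0) {
    out[on_] <- 1
  } else {
    out[on_] <- 1 - exp(-(t[on_] - params$t0) / params$tau)
  }
  out
}

# Exact propagator of dF/dt = k (p - F) from time a to time b (vectors).
# Piecewise analytic: p = 0 before t0, saturating exponential (or step)
# after. Handles k = 0 and the k == 1/tau resonance.
propagate_exchange <- function(F, a, b, k, pool) {
  stopifnot(all(b >= a - 1e-12))
  t0 <- pool$t0; tau <- pool$tau
  # segment inside the dead time: p = 0, pure decay toward 0
  d1 <- pmax(0, pmin(b, t0) - a)
  F <- F * exp(-k * d1)
  a2 <- pmax(a, t0)
  act <- b > t0
  if (!any(act)) return(F)
  d <- b[act] - a2[act]
  kk <- if (length(k) == 1) rep(k, length(F)) else k
  ka <- kk[act]
  E <- exp(-ka * d)
  if (tau == 0) {
    F[act] <- 1 + (F[act] - 1) * E
  } else {
    dk <- ka - 1 / tau
    G <- ifelse(abs(dk) < 1e-12, d, expm1(dk * d) / ifelse(dk == 0, 1, dk))
    F[act] <- F[act] * E + (1 - E) -
      ka * exp(-(a2[act] - t0) / tau) * E * G
  }
  pmin(pmax(F, 0), 1)
}

# Core: vectorized over (k, phase, rep_offset); t scalar.
tagged_fraction_core <- function(t, k, pool, cc, phase, rep_offset) {
  n <- max(length(k), length(phase), length(rep_offset))
  k <- rep_len(k, n); phase <- rep_len(phase, n)
  rep_offset <- rep_len(rep_offset, n)
  F <- numeric(n)
  tcur <- numeric(n)
  if (!is.null(cc)) {
    T <- cc$T; r <- cc$retention
    tr <- (rep_offset - phase) %% T  # first replication after time 0
    jmax <- floor(t / T) + 1L
    for (j in seq_len(jmax)) {
      ej <- tr + (j - 1) * T
      act <- ej < t   # strictly before the measurement instant
      if (!any(act)) break
      F[act] <- propagate_exchange(F[act], tcur[act], ej[act], k[act], pool)
      F[act] <- r * F[act] + (1 - r) * pool_fraction(ej[act], pool)
      tcur[act] <- ej[act]
    }
  }
  propagate_exchange(F, tcur, t, k, pool)
}

#' Tagged chromatin fraction at a locus in a single cell
#'
#' Solves the exchange ODE `dF/dt = k (p(t) - F)` with `F(0) = 0`
#' analytically (piecewise closed form), applying the replication reset
#' `F <- r F + (1 - r) p(t_rep)` at every replication event strictly
#' before `t`. The cell replicates the locus whenever its cycle position
#' passes `rep_offset`; a cell at phase `phase` at induction first does so
#' at `(rep_offset - phase) mod T` hours.
#'
#' With a step pool from `t0 = 0`, no replication and exchange rate `k`,
#' this reduces to the textbook `F(t) = 1 - exp(-k t)`.
#'
#' @param t hours since induction (scalar, >= 0).
#' @param k exchange rate(s) per hour (>= 0); vectorized.
#' @param pool a [pool_params()].
#' @param cc a [cell_cycle_params()], or `NULL` to disable replication.
#' @param phase cell-cycle position(s) at induction, hours in `[0, T)`.
#' @param rep_offset replication time(s) of the locus within the cycle;
#'   defaults to mid-S phase.
#' @return tagged fraction(s) in \[0, 1\].
#' @examples
#' tagged_fraction(1, k = log(2), pool = pool_params(t0 = 0, tau = 0))  # 0.5
#' @export
tagged_fraction <- function(t, k, pool = pool_params(), cc = NULL,
                            phase = 0, rep_offset = NULL) {
  if (length(t) != 1 || t < 0) stop("`t` must be a nonnegative scalar")
  if (any(k < 0)) stop("exchange rate `k` must be nonnegative")
  if (!is.null(cc)) {
    stopifnot(inherits(cc, "cell_cycle_params"))
    if (any(phase < 0 | phase >= cc$T)) stop("`phase` must lie in [0, T)")
    if (is.null(rep_offset)) rep_offset <- (cc$s_start + cc$s_end) / 2
    if (any(rep_offset < cc$s_start | rep_offset >= cc$s_end)) {
      stop("`rep_offset` must lie in [s_start, s_end)")
    }
  } else {
    rep_offset <- 0
  }
  tagged_fraction_core(t, k, pool, cc, phase, rep_offset)
}

#' Expected tagged signal per locus over an asynchronous population
#'
#' Phase-averages [tagged_fraction()] over a uniform grid of cell-cycle
#' positions (midpoint quadrature, `n_phases >= 256`) and scales by locus
#' occupancy. This is the expectation a ChIP measurement samples: loci
#' with rapid exchange light up early, replication-only loci accumulate
#' tag gradually as cells transit S phase.
#'
#' @param truth a [kinetic_truth] table (see [assign_kinetics()]), or any
#'   data.frame with columns `locus_id`, `k`, `occupancy`, `rep_offset`.
#' @param t hours since induction (scalar).
#' @param pool a [pool_params()].
#' @param cc a [cell_cycle_params()], or `NULL` for exchange-only
#'   (non-replicating) populations.
#' @param n_phases phase-grid size (>= 256).
#' @return data.frame with `locus_id`, `mean_tagged` (phase-averaged F)
#'   and `signal` (= occupancy x mean_tagged).
#' @export
population_signal <- function(truth, t, pool = pool_params(),
                              cc = cell_cycle_params(), n_phases = 512L) {
  if (n_phases < 256) stop("`n_phases` must be at least 256")
  if (length(t) != 1 || t < 0) stop("`t` must be a nonnegative scalar")
  truth <- as.data.frame(truth)
  L <- nrow(truth)
  if (is.null(cc)) {
    # no replication: F is phase-independent
    meanF <- tagged_fraction_core(t, truth$k, pool, NULL, 0, 0)
  } else {
    stopifnot(inherits(cc, "cell_cycle_params"))
    phases <- (seq_len(n_phases) - 0.5) * cc$T / n_phases
    k <- rep(truth$k, each = n_phases)
    ro <- rep(truth$rep_offset, each = n_phases)
    ph <- rep(phases, times = L)
    F <- tagged_fraction_core(t, k, pool, cc, ph, ro)
    meanF <- rowMeans(matrix(F, nrow = L, byrow = TRUE))
  }
  data.frame(locus_id = truth$locus_id, mean_tagged = meanF,
             signal = truth$occupancy * meanF)
}
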