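#' Latency configuration of the performance model
#'
#' Clock-cycle latencies and design parameters that drive the analytical
#' performance model. Two sums matter: `L_sigma = IL_N + L_SYNC`, the cost of
#' a step in which no spike occurs, and
#' `L_sigma_se = L_RD + L_ODE + IL_N/2 + L_SE + L_IDS + L_RB + L_SYNC_SE`,
#' the fixed cost of a step that processes spike events (the `IL_N/2` term
#' reflects spike events arriving, on average, mid-way through a pipeline
#' iteration). The defaults are calibrated so the prototype
#' (`f_clk = 200` MHz, `IL_N = 64`, `L_DS = 110`) yields `L_sigma = 67` and
#' `L_sigma_se = 81` cycles; the split of `L_sigma_se`'s components is a
#' documented plausible decomposition — only the sums enter the equations.
#'
#' @param f_clk programmable-logic clock frequency (Hz).
#' @param h simulation step size (s).
#' @param IL_N ODE pipeline iteration latency (cycles): cycles to update all
#'   `N_P` neurons of one unit.
#' @param L_DS per-spike-event data-stream latency (cycles): external-memory
#'   transfer of one fixed-size target-list packet.
#' @param L_SYNC end-of-step synchronization (cycles, no-spike case).
#' @param L_RD,L_ODE initial memory read and pipeline fill after a restart.
#' @param L_SE spike-event serialization and buffering.
#' @param L_IDS data-stream initiation (address calculation and transfer).
#' @param L_RB ring-buffer pipeline drain at end of step.
#' @param L_SYNC_SE extra synchronization when spikes were processed.
#' @param T_COM inter-node transmission latency time (s), converted to
#'   cycles as `L_COM = f_clk * T_COM`.
#' @param alpha per-spike-event communication factor: each spike event adds
#'   `alpha * L_COM` cycles.
#' @return a `latency_config` list with derived `L_COM`, `L_sigma`,
#'   `L_sigma_se` and the exact per-step cycle budget `h * f_clk`.
#' @examples
#' latency_config()$L_sigma     # 67 for the prototype
#' @export
latency_config <- function(f_clk = 200e6, h = 1e-4, IL_N = 64, L_DS = 110,
                           L_SYNC = 3, L_RD = 4, L_ODE = 12, L_SE = 9,
                           L_IDS = 6, L_RB = 10, L_SYNC_SE = 8,
                           T_COM = 500e-9, alpha = 0.05) {
  vals <- c(f_clk = f_clk, h = h, IL_N = IL_N, L_DS = L_DS, L_SYNC = L_SYNC,
            L_RD = L_RD, L_ODE = L_ODE, L_SE = L_SE, L_IDS = L_IDS,
            L_RB = L_RB, L_SYNC_SE = L_SYNC_SE, T_COM = T_COM, alpha = alpha)
  if (any(vals < 0)) stop("latencies and parameters must be non-negative")
  cfg <- as.list(vals)
  cfg$L_COM <- f_clk * T_COM
  cfg$L_sigma <- IL_N + L_SYNC
  cfg$L_sigma_se <- L_RD + L_ODE + IL_N / 2 + L_SE + L_IDS + L_RB + L_SYNC_SE
  cfg$cycles_per_step <- h * f_clk
  structure(cfg, class = "latency_config")
}

#' Design parameter sets
#'
#' The four named design points explored with the performance model:
#' the prototype (2 data streams, 16 units of 64 neurons), high data-stream
#' parallelism (one stream per unit, cutting the memory-access latency
#' eightfold), high processing-unit parallelism (twice the units, half the
#' pipeline iteration latency) and low processing-unit parallelism (half the
#' units).
#'
#' @return tibble `name, DS, L_DS, P, N_P, IL_N`.
#' @export
param_sets <- function() {
  tibble::tibble(
    name = c("prototype", "high_ds", "high_proc", "low_proc"),
    DS = c(2L, 16L, 16L, 16L),
    L_DS = c(110, 14, 14, 14),
    P = c(16L, 16L, 32L, 8L),
    N_P = c(64L, 64L, 32L, 128L),
    IL_N = c(64, 64, 32, 128))
}

#' Apply a named design parameter set to a latency configuration
#'
#' @param set a row of [param_sets()] or a set name.
#' @param base base [latency_config()].
#' @return a `latency_config` with `IL_N` and `L_DS` replaced.
#' @export
latency_config_for <- function(set, base = latency_config()) {
  if (is.character(set)) {
    ps <- param_sets()
    if (!set %in% ps$name) stop("unknown parameter set: ", set)
    set <- ps[ps$name == set, ]
  }
  latency_config(f_clk = base$f_clk, h = base$h, IL_N = set$IL_N,
                 L_DS = set$L_DS, L_SYNC = base$L_SYNC, L_RD = base$L_RD,
                 L_ODE = base$L_ODE, L_SE = base$L_SE, L_IDS = base$L_IDS,
                 L_RB = base$L_RB, L_SYNC_SE = base$L_SYNC_SE,
                 T_COM = base$T_COM, alpha = base$alpha)
}

#' Workload model
#'
#' The node's workload measure is the average number of spike events per
#' simulation step, `nu_bar_k = N * nu_bar * h`: it grows with network size
#' and firing rate but is independent of how many nodes share the network.
#' The per-node connection count `C_M = eps * N / M` is constant for a given
#' connection probability `eps`, whatever the network size.
#'
#' @param N network size (neurons).
#' @param nu_bar average firing rate over all neurons (spks/s).
#' @param h step size (s).
#' @return spike events per simulation step.
#' @examples
#' nu_bar_k(1000, 7.0)   # 0.7
#' @export
nu_bar_k <- function(N, nu_bar, h = 1e-4) {
  stopifnot(all(N >= 0), all(nu_bar >= 0), all(h >= 0))
  N * nu_bar * h
}

#' @rdname nu_bar_k
#' @param eps connection probability.
#' @param M number of nodes.
#' @export
c_per_node <- function(eps, N, M = 1) {
  stopifnot(all(M >= 1), all(eps >= 0), all(N >= 0))
  eps * N / M
}

#' Acceleration factors of the performance model
#'
#' `f_s_max()` is the maximum single-node acceleration factor (no spikes, no
#' inter-node communication): `h * f_clk / L_sigma` in the many-step limit,
#' or the finite-step form
#' `k h f_clk / (L_RD + L_ODE + k (IL_N + L_SYNC))` when `k_steps` is given.
#' `f_s()` gives the acceleration under workload `nu_bar_k` without
#' communication; below one spike event per step the denominator mixes the
#' spiking and non-spiking step costs:
#' \deqn{F_S = h f_{clk} / (\nu (L_\Sigma^{SE} + L_{DS}) + (1-\nu) L_\Sigma)}
#' for \eqn{\nu < 1} and
#' \eqn{h f_{clk} / (L_\Sigma^{SE} + \nu L_{DS})} otherwise (both branches
#' agree at \eqn{\nu = 1}). `f_c()` adds inter-node communication: a fixed
#' `L_COM` per step plus `alpha * L_COM` per spike event; `f_c_max()` is its
#' zero-workload limit `h f_clk / (L_sigma + L_COM)`.
#'
#' @param cfg a [latency_config()].
#' @param nu workload `nu_bar_k` (spike events per step); vectorized.
#' @param k_steps optional finite number of simulation steps.
#' @return acceleration factor(s) relative to real time.
#' @examples
#' f_s_max(latency_config())          # 298.5...
#' f_s(latency_config(), c(1, 10, 20))
#' @export
f_s_max <- function(cfg, k_steps = NULL) {
  if (cfg$L_sigma == 0) stop("L_sigma must be positive")
  if (is.null(k_steps)) {
    return(cfg$cycles_per_step / cfg$L_sigma)
  }
  k_steps * cfg$cycles_per_step /
    (cfg$L_RD + cfg$L_ODE + k_steps * cfg$L_sigma)
}

#' @rdname f_s_max
#' @export
f_s <- function(cfg, nu) {
  stopifnot(all(nu >= 0))
  denom <- ifelse(nu < 1,
                  nu * (cfg$L_sigma_se + cfg$L_DS) + (1 - nu) * cfg$L_sigma,
                  cfg$L_sigma_se + nu * cfg$L_DS)
  cfg$cycles_per_step / denom
}

#' @rdname f_s_max
#' @export
f_c <- function(cfg, nu) {
  stopifnot(all(nu >= 0))
  spike_cost <- cfg$L_sigma_se + cfg$L_DS + cfg$alpha * cfg$L_COM
  denom <- ifelse(nu < 1,
                  nu * spike_cost + (1 - nu) * cfg$L_sigma + cfg$L_COM,
                  cfg$L_sigma_se + nu * (cfg$L_DS + cfg$alpha * cfg$L_COM) +
                    cfg$L_COM)
  cfg$cycles_per_step / denom
}

#' @rdname f_s_max
#' @export
f_c_max <- function(cfg) {
  cfg$cycles_per_step / (cfg$L_sigma + cfg$L_COM)
}

#' Performance-loss decomposition
#'
#' Relative losses with respect to the maximum single-node acceleration
#' `F_S_max`: the total `P_TOT = (1 - F_C / F_S_max) * 100` splits exactly
#' into the node-local presynaptic-data-processing loss
#' `P_S = (1 - F_S / F_S_max) * 100` and the inter-node communication loss
#' `P_C = (F_S - F_C) / F_S_max * 100`.
#'
#' @param cfg a [latency_config()].
#' @param nu workload values (spike events per step); vectorized.
#' @return tibble `nu_bar_k, P_S, P_C, P_TOT` (percent).
#' @examples
#' perf_loss(latency_config(), c(0, 1, 10))
#' @export
perf_loss <- function(cfg, nu) {
  fsm <- f_s_max(cfg)
  fs <- f_s(cfg, nu)
  fc <- f_c(cfg, nu)
  tibble::tibble(nu_bar_k = nu,
                 P_S = (1 - fs / fsm) * 100,
                 P_C = (fs - fc) / fsm * 100,
                 P_TOT = (1 - fc / fsm) * 100)
}

#' Acceleration-factor table across design parameter sets
#'
#' Evaluates the eight tabulated acceleration factors (maximum and the
#' low/medium/high workloads 1, 10 and 20 spike events per step, each with
#' and without inter-node communication) for each design parameter set.
#'
#' @param sets tibble of parameter sets, as [param_sets()].
#' @param base base [latency_config()].
#' @return tibble `set, measure, comm, nu_bar_k, value` of class
#'   `accel_table` (values unrounded; the conventional presentation rounds
#'   to one decimal).
#' @examples
#' accel_table() |> dplyr::filter(set == "prototype")
#' @export
accel_table <- function(sets = param_sets(), base = latency_config()) {
  nus <- c(1, 10, 20)
  rows <- purrr::map_dfr(seq_len(nrow(sets)), function(i) {
    cfg <- latency_config_for(sets[i, ], base)
    tibble::tibble(
      set = sets$name[i],
      measure = c("F_S_max", paste0("F_S(", nus, ")"),
                  "F_C_max", paste0("F_C(", nus, ")")),
      comm = rep(c(FALSE, TRUE), each = 4),
      nu_bar_k = rep(c(0, nus), 2),
      value = c(f_s_max(cfg), f_s(cfg, nus), f_c_max(cfg), f_c(cfg, nus)))
  })
  class(rows) <- c("accel_table", class(rows))
  rows
}

#' Acceleration curves over a workload range
#'
#' @param cfg a [latency_config()].
#' @param nu_max upper workload bound (spike events per step).
#' @param step grid step.
#' @return tibble `nu_bar_k, F_S, F_C` of class `accel_curve`.
#' @export
accel_curve <- function(cfg = latency_config(), nu_max = 30, step = 0.1) {
  nu <- seq(0, nu_max, by = step)
  out <- tibble::tibble(nu_bar_k = nu, F_S = f_s(cfg, nu), F_C = f_c(cfg, nu))
  class(out) <- c("accel_curve", class(out))
  out
}

#' Tidy and summarize a latency configuration
#'
#' `tidy()` lists the per-component latencies; `glance()` reports the derived
#' totals and limiting acceleration factors.
#'
#' @param x a `latency_config`.
#' @param ... unused.
#' @return a tibble.
#' @export
tidy.latency_config <- function(x, ...) {
  comp <- c("IL_N", "L_DS", "L_SYNC", "L_RD", "L_ODE", "L_SE", "L_IDS",
            "L_RB", "L_SYNC_SE", "L_COM")
  tibble::tibble(component = comp,
                 cycles = vapply(comp, function(nm) x[[nm]], numeric(1)))
}

#' @rdname tidy.latency_config
#' @export
glance.latency_config <- function(x, ...) {
  tibble::tibble(f_clk = x$f_clk, h = x$h,
                 cycles_per_step = x$cycles_per_step,
                 L_sigma = x$L_sigma, L_sigma_se = x$L_sigma_se,
                 F_S_max = f_s_max(x), F_C_max = f_c_max(x))
}

#' @rdname tidy.latency_config
#' @export
tidy <- function(x, ...) UseMethod("tidy")
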