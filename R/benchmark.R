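#' Two-population benchmark network specification
#'
#' The standard benchmark and validation network: 1,000 Izhikevich neurons,
#' 800 excitatory regular-spiking and 200 inhibitory fast-spiking, every
#' neuron drawing a fixed in-degree of `K_in = 100` connections. Excitatory
#' neurons project to both populations; inhibitory neurons project only to
#' excitatory targets. Weight and delay distributions are configurable
#' stand-ins: excitatory weights `U(0, 0.5] * weight_scale` pA, inhibitory
#' `U[-1, 0) * weight_scale` pA (the default scale of 10 puts the mean
#' inhibitory weight at -5 pA, the classic two-population value), excitatory
#' delays uniform on the 0.1 ms grid in `[1.0, K_RB * 0.1]` ms, inhibitory
#' delays 1.0 ms (the network's minimum synaptic delay).
#'
#' @param n_exc,n_inh population sizes.
#' @param k_in fixed in-degree.
#' @param weight_scale weight scale factor (pA).
#' @param delay_exc_max maximum excitatory delay (ms).
#' @param delay_inh inhibitory delay (ms).
#' @param pulse_amplitude,pulse_targets default random-input stimulus: per
#'   step, `pulse_targets` uniformly drawn neurons receive a
#'   `pulse_amplitude` pA pulse.
#' @param v_init initial membrane potential (mV); `u` starts at `b * v`.
#' @return a `two_pop_spec` list.
#' @export
two_pop_spec <- function(n_exc = 800L, n_inh = 200L, k_in = 100L,
                         weight_scale = 10, delay_exc_max = 6.4,
                         delay_inh = 1.0, pulse_amplitude = 1000,
                         pulse_targets = 1L, v_init = -65) {
  stopifnot(k_in >= 1, n_exc >= 1, n_inh >= 0)
  structure(list(n_exc = as.integer(n_exc), n_inh = as.integer(n_inh),
                 k_in = as.integer(k_in), weight_scale = weight_scale,
                 delay_exc_max = delay_exc_max, delay_inh = delay_inh,
                 pulse_amplitude = pulse_amplitude,
                 pulse_targets = as.integer(pulse_targets),
                 v_init = v_init),
            class = "two_pop_spec")
}

#' Build the two-population benchmark network
#'
#' Generates the network programmatically and deterministically per seed.
#' Excitatory targets draw their `k_in` sources without replacement from all
#' other neurons; inhibitory targets draw from the excitatory population
#' only. Weights and delays are sampled per connection according to the
#' source population. Because the node caps a source's targets at `c_cap`, a
#' deterministic capacity repair re-draws sources for over-subscribed
#' neurons, preserving the exact in-degree of every target.
#'
#' @param spec a [two_pop_spec()].
#' @param seed RNG seed.
#' @param config a [node_config()]; `n_exc + n_inh` must not exceed `N_M`.
#' @return an `izh_net`; excitatory ids are `0 .. n_exc-1` (RS), inhibitory
#'   `n_exc .. n_exc+n_inh-1` (FS). The spec is attached as attribute
#'   `"two_pop_spec"`.
#' @examples
#' net <- build_two_pop(two_pop_spec(n_exc = 40, n_inh = 10, k_in = 5))
#' nrow(connections(net))
#' @export
build_two_pop <- function(spec = two_pop_spec(), seed = 1L,
                          config = node_config()) {
  n <- spec$n_exc + spec$n_inh
  if (n > config$N_M) stop("network larger than the node capacity N_M")
  exc <- 0:(spec$n_exc - 1L)
  inh <- if (spec$n_inh > 0) spec$n_exc:(n - 1L) else integer(0)
  if (spec$k_in > n - 1L || (spec$n_inh > 0 && spec$k_in > spec$n_exc))
    stop("infeasible in-degree: more connections than allowed sources")
  set.seed(seed)
  # fixed in-degree draws, per target
  src <- vector("list", n)
  for (t in 0:(n - 1L)) {
    allowed <- if (t %in% inh) exc else setdiff(0:(n - 1L), t)
    src[[t + 1L]] <- sample(allowed, spec$k_in)
  }
  source <- unlist(src)
  target <- rep(0:(n - 1L), each = spec$k_in)
  # capacity repair: re-draw sources of over-subscribed neurons
  counts <- tabulate(source + 1L, nbins = n)
  over <- which(counts > config$c_cap) - 1L
  for (s in over) {
    idx <- which(source == s)
    drop_idx <- tail(idx, counts[s + 1L] - config$c_cap)
    for (i in drop_idx) {
      t <- target[i]
      allowed <- if (t %in% inh) exc else setdiff(0:(n - 1L), t)
      cand <- setdiff(allowed, source[target == t])
      cand <- cand[counts[cand + 1L] < config$c_cap]
      if (length(cand) == 0) stop("capacity repair failed")
      pick <- cand[sample.int(length(cand), 1L)]
      counts[source[i] + 1L] <- counts[source[i] + 1L] - 1L
      counts[pick + 1L] <- counts[pick + 1L] + 1L
      source[i] <- pick
    }
  }
  from_exc <- source < spec$n_exc
  m <- length(source)
  weight <- numeric(m)
  weight[from_exc] <- runif(sum(from_exc)) * 0.5 * spec$weight_scale
  weight[!from_exc] <- -runif(sum(!from_exc)) * spec$weight_scale
  delay_grid <- seq(1.0, spec$delay_exc_max, by = config$d_min)
  delay <- numeric(m)
  delay[from_exc] <- sample(delay_grid, sum(from_exc), replace = TRUE)
  delay[!from_exc] <- spec$delay_inh
  net <- new_network(config)
  net <- net_create(net, exc, izh_params("RS"), v0 = spec$v_init)
  if (spec$n_inh > 0)
    net <- net_create(net, inh, izh_params("FS"), v0 = spec$v_init)
  net <- net_connect(net, source, target, round(weight, 6), round(delay, 6))
  attr(net, "two_pop_spec") <- spec
  net
}

#' Stimulus sweep over external offset currents
#'
#' Runs the network once per offset current value (each run starting from
#' the initial state) and reports the resulting activity and workload, the
#' construction behind the performance-versus-workload characterization.
#'
#' @param net an `izh_net` (typically from [build_two_pop()]).
#' @param i_ext_values offset currents to sweep (pA).
#' @param T_bio biological time per value (s).
#' @param stimulus_base base [stim_spec()] providing the random-input
#'   component; its `i_ext` is replaced by each sweep value. Defaults to the
#'   attached benchmark spec's random input when available.
#' @param arithmetic arithmetic mode.
#' @param out_dir optional directory: when given, each run's spikes are
#'   written as `spikes_<i_ext>.txt`.
#' @return tibble `i_ext, n_spikes, nu_bar, nu_bar_k, saturations` (one row
#'   per sweep value; `nu_bar_k = nu_bar * N * h` holds by construction).
#' @export
sweep_stimulus <- function(net, i_ext_values, T_bio = 1,
                           stimulus_base = NULL,
                           arithmetic = c("fixed", "float"),
                           out_dir = NULL) {
  arithmetic <- match.arg(arithmetic)
  if (is.null(stimulus_base)) {
    sp <- attr(net, "two_pop_spec")
    stimulus_base <- if (is.null(sp)) {
      stim_spec()
    } else {
      stim_spec(pulse_amplitude = sp$pulse_amplitude,
                pulse_targets = sp$pulse_targets)
    }
  }
  k_steps <- as.integer(round(T_bio * 1000 / net$config$h))
  purrr::map_dfr(i_ext_values, function(i0) {
    stim <- stimulus_base
    stim$i_ext <- i0
    sim <- simulate_network(net, k_steps, stim, arithmetic)
    g <- glance(sim)
    if (!is.null(out_dir)) {
      dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
      write_spikes(sim$spikes,
                   file.path(out_dir, sprintf("spikes_%g.txt", i0)),
                   h = net$config$h)
    }
    tibble::tibble(i_ext = i0, n_spikes = g$n_spikes, nu_bar = g$nu_bar,
                   nu_bar_k = g$nu_bar_k, saturations = g$saturations)
  })
}
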