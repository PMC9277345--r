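#' Node hardware configuration
#'
#' Design parameters of a single compute node: `P` processing units each
#' updating `N_P` neurons through one ODE pipeline (`N_M = P * N_P` neurons
#' per node), `DS` external-memory data streams feeding the ring-buffer
#' FIFOs, the ring-buffer depth `K_RB`, and the step size `h` which equals
#' the minimum synaptic delay `d_min`. The prototype is
#' `(P = 16, N_P = 64, N_M = 1024, DS = 2)` at `h = d_min = 0.1` ms.
#'
#' @param P processing units. @param N_P neurons per unit.
#' @param DS data streams. @param K_RB ring-buffer segments (power of two);
#'   the maximum representable delay is `K_RB * d_min`.
#' @param h,d_min step size and minimum delay (ms); both fixed at 0.1.
#' @param c_cap maximum target connections per source neuron on the node
#'   (fixed-capacity padded target-list packet).
#' @return a `node_config` list.
#' @examples
#' node_config()
#' @export
node_config <- function(P = 16L, N_P = 64L, DS = 2L, K_RB = 64L,
                        h = 0.1, d_min = 0.1, c_cap = 128L) {
  stopifnot(P >= 1, N_P >= 1, DS >= 1, h == 0.1, d_min == h)
  if (K_RB < 2 || bitwAnd(as.integer(K_RB), as.integer(K_RB) - 1L) != 0L)
    stop("K_RB must be a power of two >= 2")
  structure(list(P = as.integer(P), N_P = as.integer(N_P),
                 N_M = as.integer(P * N_P), DS = as.integer(DS),
                 K_RB = as.integer(K_RB), h = h, d_min = d_min,
                 c_cap = as.integer(c_cap)),
            class = "node_config")
}

#' Create an empty node-local network
#'
#' @param config a [node_config()].
#' @return an `izh_net` to be populated with [net_create()] and
#'   [net_connect()].
#' @examples
#' net <- new_network()
#' @export
new_network <- function(config = node_config()) {
  n <- config$N_M
  structure(
    list(config = config,
         model = rep(NA_character_, n),
         a = numeric(n), b = numeric(n), c = numeric(n), d = numeric(n),
         v0 = numeric(n), u0 = numeric(n),
         active = rep(FALSE, n),
         conn = list(),
         out_count = integer(n)),
    class = "izh_net")
}

#' Instantiate neurons on the node
#'
#' Registers neurons under logical ids; the neuron manager maps each logical
#' id to a hardware resource (processing unit, pipeline slot) by the block
#' rule `unit = id %/% N_P`, `slot = id %% N_P` (see [map_neuron()]).
#' Vectorized: `id` may be a vector with `params` of one or `length(id)`
#' rows.
#'
#' @param net an `izh_net`.
#' @param id logical neuron ids, 0-based, `< N_M`, unused.
#' @param params parameter tibble from [izh_params()].
#' @param v0,u0 initial state; `u0` defaults to `b * v0`.
#' @return the updated network.
#' @examples
#' net <- new_network() |> net_create(0:1, izh_params("RS"))
#' @export
net_create <- function(net, id, params, v0 = -70, u0 = NULL) {
  stopifnot(inherits(net, "izh_net"))
  id <- as.integer(id)
  if (any(id < 0 | id >= net$config$N_M))
    stop("logical neuron id out of range [0, N_M)")
  if (any(net$active[id + 1L])) stop("duplicate logical neuron id")
  if (anyDuplicated(id)) stop("duplicate logical neuron id")
  n <- length(id)
  rn <- function(x) rep_len(as.numeric(x), n)
  v0 <- rn(v0)
  u0 <- if (is.null(u0)) rep_len(params$b, n) * v0 else rn(u0)
  i <- id + 1L
  net$model[i] <- rep_len(params$model, n)
  net$a[i] <- rn(params$a); net$b[i] <- rn(params$b)
  net$c[i] <- rn(params$c); net$d[i] <- rn(params$d)
  net$v0[i] <- v0; net$u0[i] <- u0
  net$active[i] <- TRUE
  net
}

#' Connect neurons
#'
#' Appends synaptic target quadruples `(s_ij, n_i, w_ij, d_ij)` to the source
#' neurons' fixed-capacity target lists. Targets are routed to the data
#' streams alternately per source (balanced load on the memory ports); the
#' delay must be a positive multiple of `d_min` not exceeding
#' `K_RB * d_min`, and a source may hold at most `c_cap` targets on the node.
#' Vectorized over all four arguments.
#'
#' @param net an `izh_net`.
#' @param source,target logical neuron ids (0-based, already created).
#' @param weight synaptic weight (pA); positive = excitatory lane,
#'   negative = inhibitory lane.
#' @param delay synaptic delay (ms).
#' @return the updated network.
#' @examples
#' net <- new_network() |>
#'   net_create(0:1, izh_params("RS")) |>
#'   net_connect(0, 1, weight = 2.5, delay = 0.5)
#' @export
net_connect <- function(net, source, target, weight, delay) {
  stopifnot(inherits(net, "izh_net"))
  n <- max(length(source), length(target), length(weight), length(delay))
  source <- rep_len(as.integer(source), n)
  target <- rep_len(as.integer(target), n)
  weight <- rep_len(as.numeric(weight), n)
  delay <- rep_len(as.numeric(delay), n)
  cfg <- net$config
  if (any(!net$active[source + 1L]) || any(!net$active[target + 1L]))
    stop("source and target neurons must be created before connecting")
  dsteps <- delay / cfg$d_min
  if (any(abs(dsteps - round(dsteps)) > 1e-9) || any(delay < cfg$d_min - 1e-12))
    stop("delay must be a positive multiple of d_min = ", cfg$d_min, " ms")
  dsteps <- as.integer(round(dsteps))
  if (any(dsteps > cfg$K_RB))
    stop("delay exceeds the ring-buffer capacity K_RB * d_min = ",
         cfg$K_RB * cfg$d_min, " ms")
  new_counts <- table(factor(source, levels = 0:(cfg$N_M - 1L)))
  if (any(net$out_count + as.integer(new_counts) > cfg$c_cap))
    stop("source neuron exceeds the per-node target capacity C_M = ", cfg$c_cap)
  # alternate targets across the DS data streams, per source
  idx_in_source <- stats::ave(seq_len(n), source, FUN = seq_along) - 1L
  stream <- (net$out_count[source + 1L] + idx_in_source) %% cfg$DS + 1L
  net$conn[[length(net$conn) + 1L]] <- tibble::tibble(
    source = source, target = target, weight_pA = weight, delay_ms = delay,
    delay_steps = dsteps, stream = paste0("S", stream),
    restart = needs_restart(dsteps))
  net$out_count <- net$out_count + as.integer(new_counts)
  net
}

#' Connection table of a network
#'
#' @param net an `izh_net`.
#' @return tibble of synaptic targets in creation (list) order.
#' @export
connections <- function(net) {
  stopifnot(inherits(net, "izh_net"))
  if (length(net$conn) == 0) {
    return(tibble::tibble(source = integer(), target = integer(),
                          weight_pA = numeric(), delay_ms = numeric(),
                          delay_steps = integer(), stream = character(),
                          restart = logical()))
  }
  dplyr::bind_rows(net$conn)
}

#' Neuron table of a network
#'
#' @param net an `izh_net`.
#' @return tibble `id, model, a, b, c, d, v0, u0` of created neurons.
#' @export
neurons <- function(net) {
  stopifnot(inherits(net, "izh_net"))
  i <- which(net$active)
  tibble::tibble(id = i - 1L, model = net$model[i],
                 a = net$a[i], b = net$b[i], c = net$c[i], d = net$d[i],
                 v0 = net$v0[i], u0 = net$u0[i])
}

#' Logical-id to hardware-resource mapping
#'
#' @param id logical neuron id(s), 0-based.
#' @param config a [node_config()].
#' @return tibble `id, unit, slot` with `unit = id %/% N_P`,
#'   `slot = id %% N_P` (bijective on `[0, N_M)`).
#' @examples
#' map_neuron(c(0, 64, 1023))
#' @export
map_neuron <- function(id, config = node_config()) {
  id <- as.integer(id)
  if (any(id < 0 | id >= config$N_M)) stop("logical neuron id out of range")
  tibble::tibble(id = id, unit = id %/% config$N_P, slot = id %% config$N_P)
}

#' Stimulus specification
#'
#' External input applied during a run: a constant offset current per neuron
#' plus an optional PRNG-driven random input that delivers a current pulse to
#' `pulse_targets` uniformly drawn instantiated neurons in every step (drawn
#' with the node's XNOR-shift generator, so runs are reproducible per seed).
#'
#' @param i_ext constant offset current (pA): a scalar, or a vector of length
#'   `N_M` indexed by logical id.
#' @param pulse_amplitude pulse current (pA); 0 disables the random input.
#' @param pulse_targets pulses per step.
#' @param seed 32-bit PRNG seed for the random input.
#' @return a `stim_spec` list.
#' @export
stim_spec <- function(i_ext = 0, pulse_amplitude = 0, pulse_targets = 1L,
                      seed = 1L) {
  structure(list(i_ext = i_ext, pulse_amplitude = pulse_amplitude,
                 pulse_targets = as.integer(pulse_targets),
                 seed = seed),
            class = "stim_spec")
}

#' Simulate the node
#'
#' Runs the node kernel for `k_steps` steps of `h = 0.1` ms. Each step:
#' every unit reads its neurons' accumulated synaptic input from the ring
#' buffer (validity-stamp checked), applies one forward-Euler update with the
#' external stimulus, spikes are serialized in ascending (unit, slot) order,
#' and each firing neuron's full target list is walked with every item
#' delivered to the target's ring-buffer entry before the next step begins.
#' Deterministic given the network, stimulus and arithmetic mode.
#'
#' @param net an `izh_net`.
#' @param k_steps number of steps.
#' @param stimulus a [stim_spec()].
#' @param arithmetic `"fixed"` (s16.23, pipeline-faithful) or `"float"`.
#' @return an `izh_sim` object: list with `spikes`
#'   (tibble `k, neuron, node, t_ms`), `workload` (tibble `k, n_spikes`),
#'   `saturations`, `final_state`, plus run metadata. See [glance.izh_sim()].
#' @examples
#' net <- new_network() |> net_create(0, izh_params("RS"))
#' sim <- simulate_network(net, 1000, stim_spec(i_ext = 10))
#' glance(sim)
#' @export
simulate_network <- function(net, k_steps, stimulus = stim_spec(),
                             arithmetic = c("fixed", "float")) {
  stopifnot(inherits(net, "izh_net"), k_steps >= 1)
  arithmetic <- match.arg(arithmetic)
  cfg <- net$config
  n <- cfg$N_M
  cn <- connections(net)
  # CSR over sources, preserving list order within each source
  ord <- order(cn$source)
  cn <- cn[ord, , drop = FALSE]
  counts <- tabulate(cn$source + 1L, nbins = n)
  src_ptr <- c(0L, cumsum(counts))
  i_ext <- stimulus$i_ext
  if (length(i_ext) == 1) i_ext <- rep(i_ext, n)
  if (length(i_ext) != n)
    stop("i_ext must be scalar or length N_M = ", n)
  i_ext[!net$active] <- 0
  pool <- which(net$active) - 1L
  seed <- xnorshift_seed(stimulus$seed)
  res <- sim_core(net$a, net$b, net$c, net$d, net$v0, net$u0, net$active,
                  as.integer(src_ptr), as.integer(cn$target),
                  as.numeric(cn$weight_pA), as.integer(cn$delay_steps),
                  as.integer(k_steps), cfg$K_RB,
                  as.numeric(i_ext),
                  stimulus$pulse_amplitude, stimulus$pulse_targets,
                  seed, as.integer(pool),
                  arithmetic == "fixed")
  spikes <- tibble::tibble(k = as.integer(res$spike_k),
                           neuron = as.integer(res$spike_neuron),
                           node = 0L)
  spikes$t_ms <- spikes$k * cfg$h
  structure(
    list(spikes = spikes,
         workload = tibble::tibble(k = seq_len(k_steps) - 1L,
                                   n_spikes = as.integer(res$workload)),
         saturations = res$saturations,
         final_state = tibble::tibble(id = pool,
                                      v = res$v[pool + 1L],
                                      u = res$u[pool + 1L]),
         k_steps = as.integer(k_steps),
         n_neurons = length(pool),
         arithmetic = arithmetic,
         config = cfg),
    class = "izh_sim")
}

#' @export
print.izh_sim <- function(x, ...) {
  cat(sprintf("<izh_sim> %d neurons, %d steps (%.1f ms biological), %s arithmetic\n",
              x$n_neurons, x$k_steps, x$k_steps * x$config$h, x$arithmetic))
  cat(sprintf("  %d spikes, mean workload %.4f spikes/step, %d saturation events\n",
              nrow(x$spikes), mean(x$workload$n_spikes), x$saturations))
  invisible(x)
}

#' One-row summary of a simulation
#'
#' @param x an `izh_sim`.
#' @param ... unused.
#' @return tibble with the number of steps and spikes, the biological time
#'   `T` (s), the population mean firing rate `nu_bar` (spks/s), the mean
#'   workload `nu_bar_k` (spike events per step), and the saturation count.
#' @export
glance.izh_sim <- function(x, ...) {
  T_s <- x$k_steps * x$config$h / 1000
  tibble::tibble(
    n_neurons = x$n_neurons, k_steps = x$k_steps, T_s = T_s,
    n_spikes = nrow(x$spikes),
    nu_bar = nrow(x$spikes) / (x$n_neurons * T_s),
    nu_bar_k = mean(x$workload$n_spikes),
    saturations = x$saturations,
    arithmetic = x$arithmetic)
}

#' @rdname glance.izh_sim
#' @export
glance <- function(x, ...) UseMethod("glance")

# degenerate-seed guard: 0x3FFFFFFF is the unique fixed point of the XNOR
# (13, 17, 5) recurrence (exhaustive search over all 2^32 states)
XNS_FIXED_POINT <- 1073741823
XNS_DEFAULT_SEED <- 305419896 # 0x12345678

xnorshift_seed <- function(seed) {
  seed <- as.numeric(seed) %% 2^32
  if (seed == XNS_FIXED_POINT) {
    warning("degenerate XNOR-shift seed remapped to the default seed")
    seed <- XNS_DEFAULT_SEED
  }
  seed
}

#' XNOR-shift pseudo-random number generator
#'
#' The node's hardware PRNG for random external stimulus: the Marsaglia
#' xorshift triplet (13, 17, 5) with each stage complemented (XNOR). State is
#' 32 bits; the unique degenerate state (the recurrence's fixed point) is
#' remapped to a default seed with a warning.
#'
#' @param state current 32-bit state (as a number).
#' @param n number of draws (for `xnorshift_run()`).
#' @return `xnorshift_next()`: list with the next `state` and a uniform
#'   `value` in `[0, 1)`. `xnorshift_run()`: tibble `state, value` of `n`
#'   consecutive draws.
#' @examples
#' xnorshift_next(1)
#' @export
xnorshift_next <- function(state) {
  r <- xnorshift_cpp(xnorshift_seed(state), 1L)
  list(state = r$state[1], value = r$value[1])
}

#' @rdname xnorshift_next
#' @export
xnorshift_run <- function(state, n) {
  r <- xnorshift_cpp(xnorshift_seed(state), as.integer(n))
  tibble::tibble(state = r$state, value = r$value)
}

#' Relabel a network across processing units
#'
#' Shifts every logical neuron id by `shift` modulo `N_M` (default one
#' processing unit, `N_P`), remapping the connectivity accordingly. Assigns
#' each neuron to a different hardware resource and thereby forces a
#' different spike serialization order — used to demonstrate that repeated
#' runs are spike-identical up to the relabeling.
#'
#' @param net an `izh_net`.
#' @param shift id offset (default `N_P`).
#' @return the relabeled network.
#' @export
relabel_network <- function(net, shift = net$config$N_P) {
  stopifnot(inherits(net, "izh_net"))
  cfg <- net$config
  map <- function(id) (id + shift) %% cfg$N_M
  nt <- neurons(net)
  cn <- connections(net)
  out <- new_network(cfg)
  out <- net_create(out, map(nt$id),
                    tibble::tibble(model = nt$model, a = nt$a, b = nt$b,
                                   c = nt$c, d = nt$d),
                    v0 = nt$v0, u0 = nt$u0)
  if (nrow(cn) > 0)
    out <- net_connect(out, map(cn$source), map(cn$target),
                       cn$weight_pA, cn$delay_ms)
  out
}
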