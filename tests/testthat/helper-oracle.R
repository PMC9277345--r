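# Independent pure-R oracles for the fixed-point arithmetic, the Euler
# pipeline and the simulation engine. The fixed-point multiply uses exact
# limb decomposition in doubles (every intermediate < 2^47, hence exact),
# so it never touches the package's C++ path.

R_RAW_MIN <- -2^39
R_RAW_MAX <- 2^39 - 1

r_fx_sat <- function(x) pmin(pmax(x, R_RAW_MIN), R_RAW_MAX)
r_fx_encode <- function(x) r_fx_sat(round(x * 2^23))
r_fx_decode <- function(raw) raw / 2^23
r_fx_add <- function(a, b) r_fx_sat(a + b)

# exact floor((a*b) / 2^23) for |a|,|b| < 2^40 via 23-bit limbs
r_fx_mul <- function(a, b) {
  ah <- floor(a / 2^23); al <- a - ah * 2^23
  bh <- floor(b / 2^23); bl <- b - bh * 2^23
  r_fx_sat(ah * bh * 2^23 + ah * bl + al * bh + floor(al * bl / 2^23))
}

# one Euler step on raw state, mirroring the documented pipeline order
r_euler_fixed <- function(v, u, A, B, Cr, D, iex, iinh, iext) {
  C004 <- r_fx_encode(0.04); C5 <- r_fx_encode(5); C140 <- r_fx_encode(140)
  H <- r_fx_encode(0.1); THR <- r_fx_encode(30)
  acc <- r_fx_mul(C004, r_fx_mul(v, v))
  acc <- r_fx_add(acc, r_fx_mul(C5, v))
  acc <- r_fx_add(acc, C140)
  acc <- r_fx_add(acc, -u)
  acc <- r_fx_add(acc, iex)
  acc <- r_fx_add(acc, iinh)
  acc <- r_fx_add(acc, iext)
  v1 <- r_fx_add(v, r_fx_mul(H, acc))
  tu <- r_fx_add(r_fx_mul(B, v), -u)
  u1 <- r_fx_add(u, r_fx_mul(H, r_fx_mul(A, tu)))
  spiked <- v1 >= THR
  v1[spiked] <- Cr[spiked]
  u1[spiked] <- r_fx_add(u1, D)[spiked]
  list(v = v1, u = u1, spiked = spiked)
}

r_euler_float <- function(v, u, a, b, cc, d, iex, iinh, iext) {
  acc <- 0.04 * v * v + 5.0 * v + 140.0 - u + iex + iinh + iext
  v1 <- v + 0.1 * acc
  u1 <- u + 0.1 * (a * (b * v - u))
  spiked <- v1 >= 30.0
  v1[spiked] <- cc[spiked]
  u1[spiked] <- (u1 + d)[spiked]
  list(v = v1, u = u1, spiked = spiked)
}

# Straightforward reference simulator: dense per-step delivery map keyed by
# absolute step, matching the engine's spike serialization (ascending id)
# and per-source list delivery order.
ref_simulate <- function(net, k_steps, i_ext = 0,
                         arithmetic = c("fixed", "float")) {
  arithmetic <- match.arg(arithmetic)
  cfg <- net$config
  n <- cfg$N_M
  active <- net$active
  cn <- connections(net)
  cn <- cn[order(cn$source), , drop = FALSE]
  if (length(i_ext) == 1) i_ext <- rep(i_ext, n)
  fixed <- arithmetic == "fixed"
  if (fixed) {
    v <- r_fx_encode(net$v0); u <- r_fx_encode(net$u0)
    A <- r_fx_encode(net$a); B <- r_fx_encode(net$b)
    Cr <- r_fx_encode(net$c); D <- r_fx_encode(net$d)
    IE <- r_fx_encode(i_ext)
    W <- r_fx_encode(cn$weight_pA)
  } else {
    v <- net$v0; u <- net$u0
    W <- cn$weight_pA
  }
  n_rows <- k_steps + cfg$K_RB + 1L
  pend_ex <- matrix(0, n_rows, n)
  pend_inh <- matrix(0, n_rows, n)
  spike_k <- integer(0); spike_n <- integer(0)
  workload <- integer(k_steps)
  by_source <- split(seq_len(nrow(cn)), cn$source)
  for (k in seq_len(k_steps) - 1L) {
    iex <- pend_ex[k + 1L, ]; iinh <- pend_inh[k + 1L, ]
    if (fixed) {
      st <- r_euler_fixed(v, u, A, B, Cr, D, iex, iinh, IE)
    } else {
      st <- r_euler_float(v, u, net$a, net$b, net$c, net$d, iex, iinh, i_ext)
    }
    st$spiked[!active] <- FALSE
    v <- ifelse(active, st$v, v); u <- ifelse(active, st$u, u)
    spikes <- which(st$spiked) - 1L # ascending id = (unit, slot) order
    for (s in spikes) {
      rows <- by_source[[as.character(s)]]
      for (j in rows) {
        row <- k + cn$delay_steps[j] + 1L
        if (row > n_rows) next
        tcol <- cn$target[j] + 1L
        if (cn$weight_pA[j] >= 0) {
          pend_ex[row, tcol] <- if (fixed) {
            r_fx_add(pend_ex[row, tcol], W[j])
          } else pend_ex[row, tcol] + W[j]
        } else {
          pend_inh[row, tcol] <- if (fixed) {
            r_fx_add(pend_inh[row, tcol], W[j])
          } else pend_inh[row, tcol] + W[j]
        }
      }
    }
    spike_k <- c(spike_k, rep(k, length(spikes)))
    spike_n <- c(spike_n, spikes)
    workload[k + 1L] <- length(spikes)
  }
  list(spikes = tibble::tibble(k = spike_k, neuron = spike_n),
       workload = workload)
}

# random small network + constant drive for end-to-end oracle checks
random_small_net <- function(seed, max_neurons = 24, max_targets = 8) {
  set.seed(seed)
  n <- sample(4:max_neurons, 1)
  cfg <- node_config(P = 2L, N_P = 32L, K_RB = 16L)
  models <- sample(c("RS", "FS"), n, replace = TRUE)
  net <- new_network(cfg)
  for (i in seq_len(n) - 1L) {
    net <- net_create(net, i, izh_params(models[i + 1]),
                      v0 = runif(1, -75, -60))
  }
  for (s in seq_len(n) - 1L) {
    nt <- sample(0:max_targets, 1)
    if (nt == 0) next
    tg <- sample(seq_len(n) - 1L, nt, replace = TRUE)
    wt <- round(runif(nt, -10, 10), 3)
    dl <- sample(seq_len(cfg$K_RB), nt, replace = TRUE) * cfg$d_min
    net <- net_connect(net, s, tg, wt, dl)
  }
  i_ext <- numeric(cfg$N_M)
  driven <- sample(seq_len(n) - 1L, max(1, n %/% 3))
  i_ext[driven + 1L] <- round(runif(length(driven), 5, 20), 2)
  list(net = net, i_ext = i_ext)
}
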