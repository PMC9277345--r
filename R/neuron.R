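#' Izhikevich neuron parameter sets
#'
#' Two-parameterization presets used throughout the node: regular-spiking
#' (RS, the excitatory population) and fast-spiking (FS, the inhibitory
#' population), plus free choice of the four parameters. The dynamics are
#' `dv/dt = 0.04 v^2 + 5 v + 140 - u + i_syn + i_ext` and
#' `du/dt = a (b v - u)`, with the reset `v <- c`, `u <- u + d` whenever
#' `v >= 30` mV.
#'
#' @param model `"RS"`, `"FS"`, or `"custom"`.
#' @param a recovery time-scale (1/ms scale); @param b recovery coupling;
#'   @param c reset potential (mV); @param d recovery increment. Only used
#'   (and required) for `model = "custom"`.
#' @return a one-row tibble with columns `model, a, b, c, d`.
#' @examples
#' izh_params("RS")
#' izh_params("custom", a = 0.02, b = 0.25, c = -55, d = 0.05)
#' @export
izh_params <- function(model = c("RS", "FS", "custom"),
                       a = NULL, b = NULL, c = NULL, d = NULL) {
  model <- match.arg(model)
  if (model == "RS") {
    a <- 0.02; b <- 0.2; c <- -65.0; d <- 8.0
  } else if (model == "FS") {
    a <- 0.1; b <- 0.2; c <- -65.0; d <- 2.0
  } else if (any(vapply(list(a, b, c, d), is.null, logical(1)))) {
    stop("custom model requires a, b, c, d")
  }
  stopifnot(is.finite(a), is.finite(b), is.finite(c), is.finite(d))
  tibble::tibble(model = model, a = a, b = b, c = c, d = d)
}

#' Single forward-Euler update step
#'
#' Advances the membrane state by one step of `h = 0.1` ms explicit forward
#' Euler, in either pipeline-faithful s16.23 fixed-point arithmetic or plain
#' double precision. Both derivatives are evaluated on the pre-update state;
#' the spike threshold `v >= 30` mV is tested on the post-update value, and on
#' a spike the reported membrane potential is clamped to 30 mV (spike-peak
#' normalization) while the stored state is reset per the model rule.
#'
#' @param v,u membrane potential (mV) and recovery variable; vectors.
#' @param params parameter tibble from [izh_params()] (one row, recycled) or
#'   a data frame with columns `a, b, c, d` matching the state length.
#' @param i_ex,i_inh,i_ext excitatory, inhibitory and external currents (pA).
#' @param arithmetic `"fixed"` (s16.23 pipeline arithmetic) or `"float"`.
#' @return tibble with columns `v`, `u` (post-update state), `v_reported`
#'   (clamped at 30 mV on spike steps), `spiked`; the number of fixed-point
#'   saturation events is attached as attribute `"saturations"`.
#' @examples
#' euler_step(-60, -12, izh_params("RS"), i_ext = 10)
#' @export
euler_step <- function(v, u, params, i_ex = 0, i_inh = 0, i_ext = 0,
                       arithmetic = c("float", "fixed")) {
  arithmetic <- match.arg(arithmetic)
  n <- length(v)
  stopifnot(length(u) == n)
  rep_n <- function(x) rep_len(as.numeric(x), n)
  res <- euler_step_cpp(as.numeric(v), as.numeric(u),
                        rep_n(params$a), rep_n(params$b),
                        rep_n(params$c), rep_n(params$d),
                        rep_n(i_ex), rep_n(i_inh), rep_n(i_ext),
                        arithmetic == "fixed")
  out <- tibble::tibble(v = res$v, u = res$u,
                        v_reported = res$v_reported, spiked = res$spiked)
  attr(out, "saturations") <- res$saturations
  out
}

#' Single-neuron Euler trajectory
#'
#' Runs one neuron for `steps` steps of `h = 0.1` ms. In fixed-point mode the
#' state stays in raw s16.23 across the whole run (no per-step re-encoding),
#' exactly as in the hardware pipeline.
#'
#' @inheritParams euler_step
#' @param i_ext external current (pA); scalar or per-step vector (recycled).
#' @param steps number of simulation steps.
#' @param v0,u0 initial state; `u0` defaults to `b * v0`.
#' @return tibble `t_ms, v, u, spiked` with attributes `"spike_times"` (ms)
#'   and `"saturations"`.
#' @examples
#' tr <- izh_trajectory(izh_params("RS"), i_ext = 10, steps = 5000)
#' length(attr(tr, "spike_times"))
#' @export
izh_trajectory <- function(params, i_ext = 0, steps = 1000,
                           arithmetic = c("float", "fixed"),
                           v0 = -70, u0 = params$b * v0) {
  arithmetic <- match.arg(arithmetic)
  stopifnot(steps >= 1)
  res <- izh_run_cpp(params$a, params$b, params$c, params$d,
                     v0, u0, as.numeric(i_ext), as.integer(steps),
                     arithmetic == "fixed")
  k <- seq_len(steps) - 1L
  out <- tibble::tibble(t_ms = (k + 1) * H_MS, v = res$v, u = res$u,
                        spiked = k %in% res$spike_steps)
  attr(out, "spike_times") <- (res$spike_steps + 1) * H_MS
  attr(out, "saturations") <- res$saturations
  out
}

#' Adaptive Runge-Kutta-Fehlberg(4,5) reference integration
#'
#' The verification oracle for the Euler pipelines: integrates the Izhikevich
#' equations with an adaptive RKF45 scheme at a given absolute local error
#' tolerance, locating the `v >= 30` mV threshold crossing by step bisection
#' (crossings resolved to `1e-6` ms) and applying the reset at the crossing.
#'
#' @param params one-row parameter tibble from [izh_params()].
#' @param i_of_t stimulus: a function of time (ms) returning the external
#'   current (pA), or a single number for constant input.
#' @param t_end end of integration (ms).
#' @param abs_tol absolute local error tolerance per step (on both state
#'   variables).
#' @param v0,u0 initial state.
#' @return list with `trajectory` (tibble `t, v, u` at accepted steps) and
#'   `spike_times` (ms).
#' @examples
#' orc <- rkf45_oracle(izh_params("RS"), i_of_t = 10, t_end = 200)
#' head(orc$spike_times)
#' @export
rkf45_oracle <- function(params, i_of_t, t_end, abs_tol = 1e-6,
                         v0 = -70, u0 = params$b * v0) {
  if (is.numeric(i_of_t)) {
    i_val <- i_of_t
    i_of_t <- function(t) i_val
  }
  a <- params$a; b <- params$b; cc <- params$c; d <- params$d
  deriv <- function(t, y) {
    c(0.04 * y[1]^2 + 5 * y[1] + 140 - y[2] + i_of_t(t),
      a * (b * y[1] - y[2]))
  }
  # classical Fehlberg coefficients
  rk_step <- function(t, y, h) {
    k1 <- deriv(t, y)
    k2 <- deriv(t + h / 4, y + h * k1 / 4)
    k3 <- deriv(t + 3 * h / 8, y + h * (3 * k1 + 9 * k2) / 32)
    k4 <- deriv(t + 12 * h / 13,
                y + h * (1932 * k1 - 7200 * k2 + 7296 * k3) / 2197)
    k5 <- deriv(t + h, y + h * (439 / 216 * k1 - 8 * k2 +
                                  3680 / 513 * k3 - 845 / 4104 * k4))
    k6 <- deriv(t + h / 2, y + h * (-8 / 27 * k1 + 2 * k2 -
                                      3544 / 2565 * k3 + 1859 / 4104 * k4 -
                                      11 / 40 * k5))
    y5 <- y + h * (16 / 135 * k1 + 6656 / 12825 * k3 +
                     28561 / 56430 * k4 - 9 / 50 * k5 + 2 / 55 * k6)
    y4 <- y + h * (25 / 216 * k1 + 1408 / 2565 * k3 +
                     2197 / 4104 * k4 - 1 / 5 * k5)
    list(y = y5, err = max(abs(y5 - y4)))
  }
  t <- 0; y <- c(v0, u0); h <- 0.01
  h_min <- 1e-9; h_event <- 1e-6
  ts <- numeric(0); vs <- numeric(0); us <- numeric(0); spikes <- numeric(0)
  max_iter <- 5e6; iter <- 0
  while (t < t_end) {
    iter <- iter + 1
    if (iter > max_iter) stop("rkf45_oracle: integration failure (iteration cap)")
    h <- min(h, t_end - t)
    st <- rk_step(t, y, h)
    if (st$err > abs_tol && h > h_min) {
      h <- max(h_min, h * max(0.1, 0.84 * (abs_tol / st$err)^0.25))
      next
    }
    if (st$y[1] >= 30) {
      if (h > h_event) { # bisect toward the crossing
        h <- h / 2
        next
      }
      t <- t + h
      spikes <- c(spikes, t)
      y <- c(cc, st$y[2] + d)
    } else {
      t <- t + h
      y <- st$y
      if (st$err > 0) {
        h <- min(1, h * min(4, max(0.1, 0.84 * (abs_tol / st$err)^0.25)))
      } else {
        h <- min(1, h * 4)
      }
    }
    ts <- c(ts, t); vs <- c(vs, y[1]); us <- c(us, y[2])
  }
  list(trajectory = tibble::tibble(t = ts, v = vs, u = us),
       spike_times = spikes)
}

#' Compare two spike-time lists
#'
#' Greedy nearest matching of two sorted spike-time lists within a window;
#' reports the largest matched offset and the number of unmatched spikes on
#' either side.
#'
#' @param spikes_a,spikes_b sorted numeric vectors of spike times (ms).
#' @param window maximum offset (ms) for two spikes to be considered the same
#'   event.
#' @return list with `max_offset` (ms, 0 when nothing matched), `count_diff`
#'   (total unmatched spikes) and `n_matched`.
#' @examples
#' compare_spike_timing(c(1, 2, 3), c(1.1, 2.1, 3.1))
#' @export
compare_spike_timing <- function(spikes_a, spikes_b, window = 1.0) {
  i <- 1L; j <- 1L
  offsets <- numeric(0); matched <- 0L
  na <- length(spikes_a); nb <- length(spikes_b)
  unmatched <- 0L
  while (i <= na && j <= nb) {
    dt <- spikes_a[i] - spikes_b[j]
    if (abs(dt) <= window) {
      offsets <- c(offsets, abs(dt))
      matched <- matched + 1L
      i <- i + 1L; j <- j + 1L
    } else if (dt > 0) {
      unmatched <- unmatched + 1L; j <- j + 1L
    } else {
      unmatched <- unmatched + 1L; i <- i + 1L
    }
  }
  unmatched <- unmatched + (na - i + 1L) + (nb - j + 1L)
  list(max_offset = if (matched > 0) max(offsets) else 0,
       count_diff = unmatched, n_matched = matched)
}

#' Pack and unpack 128-bit neuron state words
#'
#' The hardware stores each neuron's state as a 128-bit word: 120 state bits
#' (the raw s16.23 values of `v` in bits 0-39 and `u` in bits 40-79, bits
#' 80-119 zero) plus 8 control bits (bits 120-127), little-endian byte order.
#' `pack_state_word()` produces the 16-byte raw vector; `unpack_state_word()`
#' inverts it bit-exactly.
#'
#' @param v_raw,u_raw raw s16.23 values.
#' @param control control byte (0-255).
#' @param bytes a raw vector whose length is a multiple of 16.
#' @return `pack_state_word()`: raw vector of `16 * length(v_raw)` bytes;
#'   `unpack_state_word()`: tibble `v_raw, u_raw, control`.
#' @examples
#' w <- pack_state_word(fx_encode(-70), fx_encode(-14))
#' unpack_state_word(w)
#' @export
pack_state_word <- function(v_raw, u_raw, control = 0L) {
  n <- length(v_raw)
  stopifnot(length(u_raw) == n)
  control <- rep_len(as.integer(control), n)
  stopifnot(all(control >= 0 & control <= 255))
  to_bytes <- function(x, nbytes) { # two's-complement 40-bit, little-endian
    x <- x %% 2^40
    vapply(seq_len(nbytes), function(i) as.integer((x %/% 256^(i - 1)) %% 256),
           integer(length(x)))
  }
  vb <- matrix(to_bytes(v_raw, 5), nrow = n)
  ub <- matrix(to_bytes(u_raw, 5), nrow = n)
  out <- raw(16L * n)
  for (i in seq_len(n)) {
    word <- c(vb[i, ], ub[i, ], rep(0L, 5), control[i])
    out[(16L * (i - 1L) + 1L):(16L * i)] <- as.raw(word)
  }
  out
}

#' @rdname pack_state_word
#' @export
unpack_state_word <- function(bytes) {
  stopifnot(is.raw(bytes), length(bytes) %% 16 == 0)
  n <- length(bytes) %/% 16
  from_bytes <- function(b) { # 5 little-endian bytes -> signed 40-bit
    x <- sum(as.numeric(b) * 256^(0:4))
    if (x >= 2^39) x - 2^40 else x
  }
  v_raw <- numeric(n); u_raw <- numeric(n); control <- integer(n)
  for (i in seq_len(n)) {
    word <- bytes[(16L * (i - 1L) + 1L):(16L * i)]
    v_raw[i] <- from_bytes(word[1:5])
    u_raw[i] <- from_bytes(word[6:10])
    if (any(word[11:15] != as.raw(0))) stop("state word spare bits not zero")
    control[i] <- as.integer(word[16])
  }
  tibble::tibble(v_raw = v_raw, u_raw = u_raw, control = control)
}
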