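#' Synaptic-delay ring buffer with valid-timestamp invalidation
#'
#' Reference implementation of the per-unit ring buffer that realizes
#' synaptic transmission delays. The buffer holds `K_RB` segments of `N_P`
#' slots (one per neuron of the unit); each entry accumulates the lumped
#' excitatory and inhibitory input due at one future step together with a
#' validity stamp `k_val`. Stale entries are never cleared: a read at step `k`
#' only returns the stored input when the entry's stamp equals
#' `k %/% K_RB`, so entries left over from a previous buffer cycle are
#' ignored and overwritten on the next write. `K_RB * d_min` bounds the
#' representable delay; `d_min = h = 0.1` ms.
#'
#' Slots are 0-based, matching the hardware resource ids.
#'
#' @param K_RB number of segments; must be a power of two.
#' @param N_P slots per segment (neurons per processing unit).
#' @return `rb_new()`: a `ring_buffer` object.
#' @examples
#' rb <- rb_new(16, 4)
#' rb <- rb_write(rb, slot = 0, delay_steps = 3, weight = 2.0, k = 0)
#' rb_read(rb, slot = 0, k = 3)
#' @export
rb_new <- function(K_RB = 64L, N_P = 64L) {
  K_RB <- as.integer(K_RB); N_P <- as.integer(N_P)
  if (K_RB < 2 || bitwAnd(K_RB, K_RB - 1L) != 0L)
    stop("K_RB must be a power of two >= 2")
  structure(
    list(K_RB = K_RB, N_P = N_P,
         i_ex = matrix(0, K_RB, N_P),   # raw s16.23 accumulators
         i_inh = matrix(0, K_RB, N_P),
         k_val = matrix(-1, K_RB, N_P),
         saturations = 0L),
    class = "ring_buffer")
}

#' @rdname rb_new
#' @param rb a `ring_buffer`.
#' @param slot target slot (0-based, `< N_P`).
#' @param delay_steps synaptic delay in steps; `1 <= delay_steps <= K_RB`.
#' @param weight synaptic weight (pA); encoded to s16.23 and accumulated
#'   exactly in raw integer arithmetic.
#' @param sign input lane; defaults to the sign of `weight`.
#' @param k current simulation step.
#' @export
rb_write <- function(rb, slot, delay_steps, weight,
                     sign = if (weight >= 0) "exc" else "inh", k = 0L) {
  stopifnot(inherits(rb, "ring_buffer"))
  sign <- match.arg(sign, c("exc", "inh"))
  if (delay_steps < 1 || delay_steps > rb$K_RB)
    stop("undeliverable delay: delay_steps must be in [1, K_RB]")
  if (slot < 0 || slot >= rb$N_P) stop("slot out of range")
  k2 <- k + delay_steps
  seg <- k2 %% rb$K_RB + 1L
  stamp <- k2 %/% rb$K_RB
  wraw <- fx_encode(weight)
  i <- slot + 1L
  if (rb$k_val[seg, i] == stamp) { # accumulate into the signed lane
    if (sign == "exc") {
      r <- fx_add(rb$i_ex[seg, i], wraw)
    } else {
      r <- fx_add(rb$i_inh[seg, i], wraw)
    }
    rb$saturations <- rb$saturations + attr(r, "saturations")
    if (sign == "exc") rb$i_ex[seg, i] <- r else rb$i_inh[seg, i] <- r
  } else { # stale entry: overwrite, do not accumulate
    rb$i_ex[seg, i] <- if (sign == "exc") as.numeric(wraw) else 0
    rb$i_inh[seg, i] <- if (sign == "inh") as.numeric(wraw) else 0
    rb$k_val[seg, i] <- stamp
  }
  rb
}

#' @rdname rb_new
#' @export
rb_read <- function(rb, slot, k) {
  stopifnot(inherits(rb, "ring_buffer"))
  if (slot < 0 || slot >= rb$N_P) stop("slot out of range")
  seg <- k %% rb$K_RB + 1L
  i <- slot + 1L
  if (rb$k_val[seg, i] == k %/% rb$K_RB) {
    list(i_ex = fx_decode(rb$i_ex[seg, i]), i_inh = fx_decode(rb$i_inh[seg, i]))
  } else {
    list(i_ex = 0, i_inh = 0)
  }
}

#' @rdname rb_new
#' @export
rb_dump <- function(rb) {
  stopifnot(inherits(rb, "ring_buffer"))
  tibble::tibble(
    segment = rep(seq_len(rb$K_RB) - 1L, rb$N_P),
    slot = rep(seq_len(rb$N_P) - 1L, each = rb$K_RB),
    i_ex = fx_decode(as.vector(rb$i_ex)),
    i_inh = fx_decode(as.vector(rb$i_inh)),
    k_val = as.vector(rb$k_val))
}

#' ODE-pipeline restart condition
#'
#' A synapse at the minimum delay (`d_ij = d_min`, one step) writes into the
#' ring-buffer segment that is already being fetched for the next step; the
#' hardware must then reset and restart the ODE pipelines. The functional
#' simulation orders all deliveries before the next step's reads, so this
#' flag is consumed only by performance accounting, never by correctness.
#'
#' @param delay_steps integer delay in steps.
#' @return logical: `TRUE` iff `delay_steps == 1`.
#' @examples
#' needs_restart(1); needs_restart(2)
#' @export
needs_restart <- function(delay_steps) {
  stopifnot(all(delay_steps >= 1))
  delay_steps == 1
}

#' Separate multapse entries in a synaptic target list
#'
#' Consecutive presynaptic data items that address the same ring-buffer entry
#' (same target neuron and delay: a multapse) can collide in the RB pipeline
#' (read-before-write). The fix is purely a memory-layout one: permute the
#' target list so identical `(target, delay)` keys are at least `min_gap`
#' positions apart where possible, keeping the original order otherwise.
#'
#' @param targets data frame of synaptic targets with columns `target` and
#'   `delay` (other columns are carried along).
#' @param min_gap required minimum positional separation of identical keys;
#'   the default is a proxy for the RB-pipeline depth.
#' @return the permuted tibble; attribute `"separation_ok"` is `FALSE` when
#'   full separation was impossible (result is then best-effort).
#' @examples
#' tl <- tibble::tibble(target = c(1, 1, 2), delay = c(1, 1, 1))
#' reorder_targets(tl, min_gap = 2)
#' @export
reorder_targets <- function(targets, min_gap = 4L) {
  n <- nrow(targets)
  if (n == 0) {
    out <- tibble::as_tibble(targets)
    attr(out, "separation_ok") <- TRUE
    return(out)
  }
  key <- paste(targets$target, targets$delay, sep = "\r")
  remaining <- seq_len(n)
  order_out <- integer(0)
  recent <- character(0) # keys used in the last min_gap - 1 positions
  ok <- TRUE
  for (pos in seq_len(n)) {
    elig <- remaining[!(key[remaining] %in% recent)]
    if (length(elig) == 0) { # impossible separation: best effort
      ok <- FALSE
      pick <- remaining[1]
    } else {
      pick <- elig[1] # earliest original index keeps the order stable
    }
    order_out <- c(order_out, pick)
    remaining <- remaining[remaining != pick]
    recent <- c(recent, key[pick])
    if (length(recent) >= min_gap) recent <- recent[-1]
  }
  out <- tibble::as_tibble(targets[order_out, , drop = FALSE])
  attr(out, "separation_ok") <- ok
  out
}
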