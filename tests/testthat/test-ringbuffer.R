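test_that("writes land in the addressed segment with the right stamp", {
  rb <- rb_new(16, 8)
  rb <- rb_write(rb, slot = 0, delay_steps = 3, weight = 2.0, k = 0)
  d <- rb_dump(rb)
  entry <- d[d$segment == 3 & d$slot == 0, ]
  expect_equal(entry$i_ex, 2.0)
  expect_equal(entry$i_inh, 0)
  expect_equal(entry$k_val, 0) # 3 %/% 16
  expect_equal(rb_read(rb, 0, k = 3), list(i_ex = 2.0, i_inh = 0))
  # same entry written twice at the same target step accumulates
  rb <- rb_write(rb, 0, 3, 2.0, k = 0)
  expect_equal(rb_read(rb, 0, k = 3)$i_ex, 4.0)
})

test_that("validity stamps silently retire stale entries", {
  rb <- rb_new(16, 4)
  rb <- rb_write(rb, 1, 5, 1.5, k = 0)       # due at k' = 5, stamp 0
  expect_equal(rb_read(rb, 1, k = 5)$i_ex, 1.5)
  # re-addressed one buffer cycle later without rewrite: stale, reads zero
  expect_equal(rb_read(rb, 1, k = 5 + 16), list(i_ex = 0, i_inh = 0))
  # a write for the new cycle overwrites the stale entry, not accumulates
  rb <- rb_write(rb, 1, 5, 0.25, k = 16)     # due at k' = 21, stamp 1
  expect_equal(rb_read(rb, 1, k = 21)$i_ex, 0.25)
  expect_equal(rb_read(rb, 0, k = 3), list(i_ex = 0, i_inh = 0)) # untouched
})

test_that("delay bounds and slot bounds are enforced", {
  rb <- rb_new(8, 4)
  expect_error(rb_write(rb, 0, 0, 1, k = 0), "undeliverable")
  expect_error(rb_write(rb, 0, 9, 1, k = 0), "undeliverable")
  expect_error(rb_write(rb, 4, 1, 1, k = 0), "slot")
  expect_error(rb_new(12, 4), "power of two")
})

test_that("ring buffer equals a dense-queue oracle over random traffic", {
  # 1e4 random events interleaved with per-step reads of every slot
  K <- 16L; NP <- 8L; T_steps <- 420L
  set.seed(20)
  rb <- rb_new(K, NP)
  dense_ex <- matrix(0, T_steps + K + 1, NP) # raw accumulators keyed by k'
  dense_inh <- matrix(0, T_steps + K + 1, NP)
  written_ex <- 0
  delivered_ex <- 0
  n_events <- 0
  for (k in seq_len(T_steps) - 1L) {
    # reads first, then the step's event-driven updates: a delay of exactly
    # K_RB addresses the segment being processed, which the schedule only
    # permits after the step's reads have completed
    mismatches <- 0L
    for (slot in seq_len(NP) - 1L) {
      got <- rb_read(rb, slot, k = k)
      if (!identical(got$i_ex, r_fx_decode(dense_ex[k + 1L, slot + 1L])) ||
          !identical(got$i_inh, r_fx_decode(dense_inh[k + 1L, slot + 1L])))
        mismatches <- mismatches + 1L
      delivered_ex <- delivered_ex + r_fx_encode(got$i_ex)
    }
    expect_identical(mismatches, 0L)
    for (e in seq_len(24)) {
      slot <- sample(NP, 1) - 1L
      delay <- sample(K, 1)
      w <- round(runif(1, -4, 4), 3)
      rb <- rb_write(rb, slot, delay, w, k = k)
      row <- k + delay + 1L
      wraw <- r_fx_encode(w)
      if (w >= 0) {
        dense_ex[row, slot + 1L] <- r_fx_add(dense_ex[row, slot + 1L], wraw)
        written_ex <- written_ex + wraw
      } else {
        dense_inh[row, slot + 1L] <- r_fx_add(dense_inh[row, slot + 1L], wraw)
      }
      n_events <- n_events + 1
    }
  }
  expect_gte(n_events, 1e4)
  expect_equal(rb$saturations, 0L)
  # conservation over the fully-read horizon: tail deliveries still pending
  pending <- sum(dense_ex[(T_steps + 1):(T_steps + K + 1), ])
  expect_identical(delivered_ex + pending, written_ex)
})

test_that("a segment is re-addressed after exactly K_RB steps", {
  K <- 8L
  rb <- rb_new(K, 2)
  rb <- rb_write(rb, 0, K, 1.0, k = 0) # due at k' = K
  expect_equal(rb_read(rb, 0, k = 0)$i_ex, 0) # same segment, wrong stamp
  expect_equal(rb_read(rb, 0, k = K)$i_ex, 1.0)
  expect_equal(rb_read(rb, 0, k = 2 * K)$i_ex, 0) # stale again
})

test_that("restart condition flags only minimum-delay synapses", {
  expect_true(needs_restart(1))
  expect_false(needs_restart(2))
  expect_false(needs_restart(64))
  expect_equal(needs_restart(c(1, 3, 1)), c(TRUE, FALSE, TRUE))
})

test_that("multapse reordering separates duplicate keys and stays a permutation", {
  tl <- tibble::tibble(target = c("A", "A", "B"), delay = c(1, 1, 1))
  out <- reorder_targets(tl, min_gap = 2)
  expect_equal(out$target, c("A", "B", "A"))
  expect_true(attr(out, "separation_ok"))
  # all-distinct input is untouched
  tl2 <- tibble::tibble(target = 1:6, delay = 1)
  expect_equal(reorder_targets(tl2, min_gap = 4)$target, 1:6)
  # empty list
  expect_equal(nrow(reorder_targets(tl2[0, ], 4)), 0)
  # impossible separation reported, result still a permutation
  tl3 <- tibble::tibble(target = c(1, 1, 1, 1), delay = 1)
  out3 <- reorder_targets(tl3, min_gap = 4)
  expect_false(attr(out3, "separation_ok"))
  expect_equal(nrow(out3), 4)
  # property: permutation with key separation >= min_gap whenever feasible
  set.seed(21)
  for (rep in 1:20) {
    n <- sample(3:30, 1)
    tl <- tibble::tibble(target = sample(1:6, n, replace = TRUE),
                         delay = sample(1:2, n, replace = TRUE))
    gap <- sample(2:4, 1)
    out <- reorder_targets(tl, min_gap = gap)
    expect_equal(sort(paste(out$target, out$delay)),
                 sort(paste(tl$target, tl$delay)))
    if (attr(out, "separation_ok")) {
      key <- paste(out$target, out$delay)
      pos <- split(seq_len(n), key)
      expect_true(all(vapply(pos, function(p) {
        length(p) < 2 || min(diff(p)) >= gap
      }, logical(1))))
    }
  }
})
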