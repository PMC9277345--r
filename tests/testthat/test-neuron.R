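test_that("euler step reproduces hand-evaluated dynamics and the reset rule", {
  # (-70, -14) is an equilibrium of the RS dynamics with zero input
  st <- euler_step(-70, -14, izh_params("RS"))
  expect_equal(st$v, -70)
  expect_equal(st$u, -14)
  expect_false(st$spiked)
  # hand-evaluated step: dv = 6.0 * h
  st <- euler_step(-60, -12, izh_params("RS"), i_ex = 10)
  expect_equal(st$v, -59.4)
  expect_equal(st$u, -12.0)
  # post-update threshold test with reset v <- c, u <- u + d
  st <- euler_step(31, -10, izh_params("RS"))
  expect_true(st$spiked)
  expect_equal(st$v, -65)
  expect_equal(st$v_reported, 30) # spike-peak normalization
  st_float <- euler_step(31, -10, izh_params("RS"))
  expect_equal(st_float$u, -10 + 0.1 * 0.02 * (0.2 * 31 + 10) + 8)
})

test_that("fixed-point euler matches the independent limb-arithmetic oracle", {
  set.seed(10)
  n <- 1e4
  v <- runif(n, -80, 20); u <- runif(n, -20, 5)
  iex <- runif(n, 0, 5); iinh <- runif(n, -5, 0)
  p <- izh_params("RS")
  got <- euler_step(v, u, p, i_ex = iex, i_inh = iinh, arithmetic = "fixed")
  orc <- r_euler_fixed(r_fx_encode(v), r_fx_encode(u),
                       r_fx_encode(rep(p$a, n)), r_fx_encode(rep(p$b, n)),
                       r_fx_encode(rep(p$c, n)), r_fx_encode(rep(p$d, n)),
                       r_fx_encode(iex), r_fx_encode(iinh),
                       r_fx_encode(rep(0, n)))
  expect_equal(got$v, r_fx_decode(orc$v))
  expect_equal(got$u, r_fx_decode(orc$u))
  expect_equal(got$spiked, orc$spiked)
})

test_that("fixed and float arithmetic agree per subthreshold step", {
  set.seed(11)
  n <- 1e4
  v <- runif(n, -75, -50); u <- runif(n, -16, -8)
  p <- izh_params("RS")
  fx <- euler_step(v, u, p, i_ex = 2, arithmetic = "fixed")
  fl <- euler_step(v, u, p, i_ex = 2, arithmetic = "float")
  # dominant per-step deviation: the s16.23 quantization of the constant
  # 0.04 (|0.04 - round(0.04 * 2^23)/2^23| = 0.32 * 2^-23) amplified by v^2
  # and scaled by h, plus a few ulps of truncation in the remaining ops
  bound_v <- 0.1 * (0.32 * 2^-23) * max(v^2) + 10 * 2^-23
  expect_true(all(abs(fx$v - fl$v) < bound_v))
  expect_true(all(abs(fx$u - fl$u) < 10 * 2^-23))
})

test_that("fixed-point equilibrium drift stays truncation-bounded", {
  tr <- izh_trajectory(izh_params("RS"), i_ext = 0, steps = 1e5,
                       arithmetic = "fixed", v0 = -70)
  expect_lt(max(abs(tr$v + 70)), 0.01)
  expect_equal(length(attr(tr, "spike_times")), 0L)
  # float mode is exactly stationary at the equilibrium
  trf <- izh_trajectory(izh_params("RS"), i_ext = 0, steps = 1000,
                        arithmetic = "float", v0 = -70)
  expect_true(all(trf$v == -70))
})

test_that("RKF45 oracle validates the Euler pipelines' spike behaviour", {
  p <- izh_params("RS")
  # equilibrium: no spikes over a full second
  quiet <- rkf45_oracle(p, i_of_t = 0, t_end = 1000)
  expect_equal(length(quiet$spike_times), 0L)
  # RS at constant 10 pA: periodic train; fixed Euler, float Euler and the
  # oracle agree on the count over 1 s
  orc <- rkf45_oracle(p, i_of_t = 10, t_end = 1000)
  expect_gt(length(orc$spike_times), 5)
  isi <- diff(orc$spike_times)[-1] # discard the onset interval
  expect_lt(stats::sd(isi) / mean(isi), 0.01) # periodic
  eu_fx <- attr(izh_trajectory(p, i_ext = 10, steps = 10000, "fixed"),
                "spike_times")
  eu_fl <- attr(izh_trajectory(p, i_ext = 10, steps = 10000, "float"),
                "spike_times")
  expect_equal(length(eu_fx), length(eu_fl))
  cmp <- compare_spike_timing(eu_fx, orc$spike_times, window = 10)
  expect_equal(cmp$count_diff, 0L)
  # FS fires at least as fast as RS under the same drive
  orc_fs <- rkf45_oracle(izh_params("FS"), i_of_t = 10, t_end = 1000)
  expect_gte(length(orc_fs$spike_times), length(orc$spike_times))
})

test_that("RKF45 oracle agrees with an independent adaptive integrator", {
  skip_if_not_installed("deSolve")
  p <- izh_params("RS")
  f <- function(t, y, parms) {
    list(c(0.04 * y[1]^2 + 5 * y[1] + 140 - y[2] + 2,
           p$a * (p$b * y[1] - y[2])))
  }
  times <- seq(0, 50, by = 1)
  ref <- deSolve::lsodar(c(-70, -14), times, f, parms = NULL,
                         rtol = 1e-10, atol = 1e-10)
  orc <- rkf45_oracle(p, i_of_t = 2, t_end = 50, abs_tol = 1e-8)
  expect_equal(length(orc$spike_times), 0L)
  # compare at the deSolve grid; linear interpolation between accepted RKF45
  # steps dominates the discrepancy, so the bound is interpolation-level
  vi <- stats::approx(orc$trajectory$t, orc$trajectory$v, xout = times[-1])$y
  expect_lt(max(abs(vi - ref[-1, 2])), 2e-3)
  # spiking protocol: lsodar's own root-finding + event reset machinery
  # must agree with the oracle's bisection event location
  root <- function(t, y, parms) y[1] - 30
  evt <- function(t, y, parms) c(p$c, y[2] + p$d)
  f10 <- function(t, y, parms) {
    list(c(0.04 * y[1]^2 + 5 * y[1] + 140 - y[2] + 10,
           p$a * (p$b * y[1] - y[2])))
  }
  ref10 <- deSolve::lsodar(c(-70, -14), seq(0, 1000, by = 0.5), f10,
                           parms = NULL, rtol = 1e-8, atol = 1e-8,
                           rootfunc = root,
                           events = list(func = evt, root = TRUE))
  t_spikes_ref <- attr(ref10, "troot")
  orc10 <- rkf45_oracle(p, i_of_t = 10, t_end = 1000)
  expect_equal(length(orc10$spike_times), length(t_spikes_ref))
  expect_lt(max(abs(orc10$spike_times - t_spikes_ref)), 0.01)
})

test_that("spike-time comparison reports offsets and unmatched counts", {
  expect_equal(compare_spike_timing(c(1, 2, 3), c(1, 2, 3)),
               list(max_offset = 0, count_diff = 0L, n_matched = 3L))
  cmp <- compare_spike_timing(c(1, 2, 3), c(1.1, 2.1, 3.1))
  expect_equal(cmp$max_offset, 0.1)
  expect_equal(cmp$count_diff, 0L)
  cmp <- compare_spike_timing(c(1, 2), c(1, 2, 50))
  expect_equal(cmp$count_diff, 1L)
})

test_that("128-bit state words pack and unpack bit-exactly", {
  set.seed(12)
  v_raw <- fx_encode(runif(50, -65536, 65536))
  u_raw <- fx_encode(runif(50, -65536, 65536))
  ctl <- sample(0:255, 50, replace = TRUE)
  w <- pack_state_word(v_raw, u_raw, ctl)
  expect_length(w, 16 * 50)
  back <- unpack_state_word(w)
  expect_equal(back$v_raw, as.numeric(v_raw))
  expect_equal(back$u_raw, as.numeric(u_raw))
  expect_equal(back$control, ctl)
})
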