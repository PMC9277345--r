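test_that("neuron creation validates ids and round-trips state", {
  net <- new_network()
  net <- net_create(net, 0, izh_params("RS"), v0 = -70.3)
  expect_error(net_create(net, 0, izh_params("RS")), "duplicate")
  expect_error(net_create(net, 1024, izh_params("RS")), "out of range")
  nt <- neurons(net)
  expect_equal(nt$v0, -70.3)
  expect_equal(nt$u0, 0.2 * -70.3)
  # encode/decode round trip within one ulp of the format
  expect_lt(abs(fx_decode(fx_encode(nt$v0)) - nt$v0), 2^-23)
})

test_that("logical ids map block-wise onto units and slots", {
  m <- map_neuron(c(0, 64, 1023))
  expect_equal(m$unit, c(0, 1, 15))
  expect_equal(m$slot, c(0, 0, 63))
  expect_error(map_neuron(1024), "out of range")
  # bijective over the whole node
  all_ids <- 0:1023
  m <- map_neuron(all_ids)
  expect_equal(anyDuplicated(paste(m$unit, m$slot)), 0L)
})

test_that("connections validate delay, capacity and alternate streams", {
  net <- new_network() |> net_create(0:2, izh_params("RS"))
  expect_error(net_connect(net, 0, 1, 1, delay = 0.05), "multiple of d_min")
  expect_error(net_connect(net, 0, 1, 1, delay = 6.5), "ring-buffer capacity")
  expect_error(net_connect(net, 0, 5, 1, delay = 1), "created")
  net <- net_connect(net, 0, c(1, 2, 1, 2), 1, 1)
  expect_equal(connections(net)$stream, c("S1", "S2", "S1", "S2"))
  # stream alternation continues across calls
  net <- net_connect(net, 0, 1, 1, 1)
  expect_equal(tail(connections(net)$stream, 1), "S1")
  # 129th connection of one source is rejected
  net2 <- new_network() |> net_create(0:128, izh_params("RS"))
  net2 <- net_connect(net2, 0, rep(1:128), 1, 1)
  expect_error(net_connect(net2, 0, 1, 1, 1), "capacity")
})

test_that("a spike is delivered after exactly its synaptic delay", {
  # A -> B with 0.5 ms delay: the weight must arrive 5 steps after the spike
  net <- new_network() |>
    net_create(0:1, izh_params("RS")) |>
    net_connect(0, 1, 1000, 0.5)
  i_ext <- c(1000, rep(0, 1023)) # drives neuron 0 only
  sim <- simulate_network(net, 100, stim_spec(i_ext = i_ext), "float")
  kA <- sim$spikes$k[sim$spikes$neuron == 0][1]
  kB <- sim$spikes$k[sim$spikes$neuron == 1][1]
  # the suprathreshold weight arrives at kA + 5 and fires B on that step
  expect_equal(kB, kA + 5L)
  # the independent dense-queue reference reproduces the full spike set
  ref <- ref_simulate(net, 100, i_ext, "float")
  expect_equal(sim$spikes$k, ref$spikes$k)
  expect_equal(sim$spikes$neuron, ref$spikes$neuron)
})

test_that("engine equals the brute-force simulator on random small networks", {
  for (seed in 1:50) {
    rn <- random_small_net(seed)
    mode <- if (seed %% 2 == 0) "fixed" else "float"
    sim <- simulate_network(rn$net, 400, stim_spec(i_ext = rn$i_ext), mode)
    ref <- ref_simulate(rn$net, 400, rn$i_ext, mode)
    expect_identical(sim$spikes$k, as.integer(ref$spikes$k))
    expect_identical(sim$spikes$neuron, as.integer(ref$spikes$neuron))
    expect_identical(sim$workload$n_spikes, as.integer(ref$workload))
  }
})

test_that("repeated seeded runs are spike-identical and relabeling-invariant", {
  net <- build_two_pop(two_pop_spec(n_exc = 160, n_inh = 40, k_in = 20),
                       seed = 5)
  stim <- stim_spec(i_ext = 4, pulse_amplitude = 1000, pulse_targets = 1,
                    seed = 9)
  a <- simulate_network(net, 2000, stim, "fixed")
  b <- simulate_network(net, 2000, stim, "fixed")
  expect_identical(a$spikes, b$spikes)
  expect_gt(nrow(a$spikes), 0)
  expect_equal(a$saturations, 0L)
  # byte-identical spike files
  fa <- tempfile(); fb <- tempfile()
  write_spikes(a$spikes, fa, "binary")
  write_spikes(b$spikes, fb, "binary")
  expect_identical(readBin(fa, "raw", file.size(fa)),
                   readBin(fb, "raw", file.size(fb)))
  # relabeling across processing units: identical trains modulo the id map
  # (constant drive so the stimulus follows the relabeled neurons)
  stim2 <- stim_spec(i_ext = 4)
  base <- simulate_network(net, 2000, stim2, "fixed")
  shifted <- simulate_network(relabel_network(net, 64), 2000, stim2, "fixed")
  expect_equal(base$saturations + shifted$saturations, 0L)
  remapped <- (base$spikes$neuron + 64L) %% 1024L
  expect_identical(
    shifted$spikes[order(shifted$spikes$k, shifted$spikes$neuron),
                   c("k", "neuron")],
    tibble::tibble(k = base$spikes$k, neuron = remapped)[
      order(base$spikes$k, remapped), ])
})

test_that("workload trace mean equals the spike-count workload measure", {
  net <- build_two_pop(two_pop_spec(n_exc = 80, n_inh = 20, k_in = 10),
                       seed = 3)
  sim <- simulate_network(net, 1000,
                          stim_spec(pulse_amplitude = 1000), "fixed")
  g <- glance(sim)
  # nu_bar_k = (h / T) * sum n_sp = mean per-step spike count
  expect_equal(g$nu_bar_k, nrow(sim$spikes) / sim$k_steps)
  expect_equal(g$nu_bar_k, nu_bar_k(g$n_neurons, g$nu_bar))
})

test_that("XNOR-shift PRNG is reproducible, uniform and long-period", {
  s1 <- xnorshift_run(1, 1000)
  s2 <- xnorshift_run(1, 1000)
  expect_identical(s1, s2)
  draws <- xnorshift_run(12345, 1e5)
  expect_gt(mean(draws$value), 0.49)
  expect_lt(mean(draws$value), 0.51)
  expect_true(all(draws$value >= 0 & draws$value < 1))
  # no state repeat within 1e6 draws
  long <- xnorshift_run(42, 1e6)
  expect_equal(anyDuplicated(long$state), 0L)
  # degenerate seed (the recurrence's unique fixed point) is remapped
  expect_warning(r <- xnorshift_next(1073741823), "degenerate")
  expect_false(r$state == 1073741823)
})

test_that("spike files round-trip in both formats", {
  set.seed(30)
  rec <- tibble::tibble(k = sort(sample(0:1e5, 1e4, replace = TRUE)),
                        neuron = sample(0:1023, 1e4, replace = TRUE),
                        node = sample(0:3, 1e4, replace = TRUE))
  fb <- tempfile()
  write_spikes(rec, fb, "binary")
  back <- read_spikes(fb, "binary")
  expect_equal(back$k, rec$k)
  expect_equal(back$neuron, rec$neuron)
  expect_equal(back$node, rec$node)
  # text format: "t_ms neuron" at one decimal
  ft <- tempfile()
  write_spikes(tibble::tibble(k = 10L, neuron = 7L), ft, "text")
  expect_equal(readLines(ft), "1.0 7")
  tt <- read_spikes(ft, "text")
  expect_equal(tt$k, 10L)
  # empty simulation writes a readable empty file
  fe <- tempfile()
  write_spikes(tibble::tibble(k = integer(), neuron = integer()), fe, "text")
  expect_equal(nrow(read_spikes(fe, "text")), 0)
  # malformed input is rejected with a line number
  writeLines(c("1.0 7", "oops"), ft)
  expect_error(read_spikes(ft, "text"), "line 2")
})

test_that("network tables and configs round-trip through files", {
  net <- build_two_pop(two_pop_spec(n_exc = 40, n_inh = 10, k_in = 5),
                       seed = 2)
  dir <- tempfile()
  write_network(net, dir)
  back <- read_network(dir)
  expect_equal(neurons(back), neurons(net))
  cn_a <- connections(net); cn_b <- connections(back)
  expect_equal(cn_b[c("source", "target", "weight_pA", "delay_ms")],
               cn_a[c("source", "target", "weight_pA", "delay_ms")])
  # identical spike output after the round trip
  sa <- simulate_network(net, 500, stim_spec(i_ext = 5), "fixed")
  sb <- simulate_network(back, 500, stim_spec(i_ext = 5), "fixed")
  expect_identical(sa$spikes, sb$spikes)
  fc <- tempfile(fileext = ".json")
  write_sim_config(fc, node_config(), stim_spec(i_ext = 2, seed = 11),
                   k_steps = 250, arithmetic = "float")
  cfg <- read_sim_config(fc)
  expect_equal(cfg$k_steps, 250L)
  expect_equal(cfg$stimulus$i_ext, 2)
  expect_equal(cfg$config$N_M, 1024L)
})
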