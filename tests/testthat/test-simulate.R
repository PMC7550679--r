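test_that("activations and potentials respect their bounds everywhere", {
  circ <- build_default_circuit()
  tr <- run_protocol(circ, conditioning_protocol(),
                     sim_config(record_every = 3))
  phi <- circ$units$phi[match(colnames(tr$A), circ$units$name)]
  for (j in seq_len(ncol(tr$A))) {
    expect_true(all(tr$A[, j] >= 0 & tr$A[, j] <= phi[j] + 1e-9),
                label = paste("0 <= A <= phi for", colnames(tr$A)[j]))
  }
})

test_that("a unit with constant drive converges to its fixed point", {
  circ <- single_unit(tonic = 0.5)
  p <- conditioning_protocol(n_trials = 1, cs_s = 10, us_s = 0, iti_s = 5)
  tr <- run_protocol(circ, p, sim_config(record_every = 1))
  # during the CS: drive = tonic + w * 100, activation = transfer of it
  u_star <- 0.5 + 0.02 * 100
  a_star <- transfer(min(pi, u_star), 0.8, 40)
  mid <- tr$time_s > 12 & tr$time_s < 15
  expect_equal(unname(mean(tr$A[mid, "A"])), a_star, tolerance = 1e-6)
  # after offset it decays back toward the tonic point
  late <- tr$time_s > 19
  expect_equal(unname(mean(tr$A[late, "A"])), transfer(0.5, 0.8, 40),
               tolerance = 1e-6)
})

test_that("zero-weight, zero-tonic circuits decay to silence", {
  circ <- two_unit_chain(w = 0)
  p <- conditioning_protocol(n_trials = 0, iti_s = 2)
  tr <- run_protocol(circ, p, sim_config(record_every = 1))
  expect_true(all(tr$A[nrow(tr$A), ] == 0))
})

test_that("engine trajectories match the pure-R reference step for step", {
  circ <- two_unit_chain()
  cfg <- sim_config(dt_ms = 10, settle_s = 0, record_every = 1)
  p <- conditioning_protocol(n_trials = 1, cs_s = 0.5, us_s = 0,
                             iti_s = 0.2)
  tr <- run_protocol(circ, p, cfg)
  # replay with network_step (same synchronous order, no plasticity)
  st <- list(u = c(0, 0), a = c(0, 0))
  amps <- fearsim:::epoch_amplitudes(p, 10, 0)
  A <- matrix(NA_real_, amps$steps, 2)
  for (k in seq_len(amps$steps)) {
    st <- network_step(st, circ, external = c(CS = amps$cs[k],
                                              US = amps$us[k]), cfg)
    A[k, ] <- st$a
  }
  expect_equal(unname(tr$A), A, tolerance = 1e-12)
})

test_that("single-unit engine run agrees with closed-form relaxation at small dt", {
  circ <- single_unit(tonic = 0, tau = 20, phi = 40, psi = 0.8)
  cfg <- sim_config(dt_ms = 1, settle_s = 0, record_every = 1)
  p <- conditioning_protocol(n_trials = 1, cs_s = 2, us_s = 0, iti_s = 0.5)
  tr <- run_protocol(circ, p, cfg)
  drive <- 0.02 * 100
  on <- tr$time_s > 0.5 & tr$time_s <= 2.5
  t_rel <- (tr$time_s[on] - 0.5) * 1000
  u_exact <- relax(t_rel, 0, drive, 20)
  expect_equal(unname(tr$A[on, "A"]), transfer(u_exact, 0.8, 40),
               tolerance = 0.01)
})

test_that("replays are bit-identical and dt choices agree at steady state", {
  circ <- build_default_circuit()
  p <- conditioning_protocol(n_trials = 1)
  t1 <- run_protocol(circ, p, sim_config(record_every = 10))
  t2 <- run_protocol(circ, p, sim_config(record_every = 10))
  expect_identical(t1$A, t2$A)
  # dt = 1 vs dt = 10: steady-state activations within 5% relative
  c1 <- run_protocol(two_unit_chain(), p, sim_config(record_every = 10))
  c2 <- run_protocol(two_unit_chain(), p,
                     sim_config(dt_ms = 1, record_every = 100))
  mid1 <- colMeans(c1$A[c1$time_s > 50 & c1$time_s < 60, ])
  mid2 <- colMeans(c2$A[c2$time_s > 50 & c2$time_s < 60, ])
  expect_equal(mid1, mid2, tolerance = 0.05)
})

test_that("network_step validates external-drive names", {
  circ <- two_unit_chain()
  st <- list(u = c(0, 0), a = c(0, 0))
  expect_error(network_step(st, circ, external = c(Zz = 1)), "unknown unit")
  expect_error(network_step(list(u = 0, a = 0), circ), "every unit")
})

test_that("protocol builders produce the printed schedules", {
  p <- conditioning_protocol()
  expect_equal(sum(p$epochs$channel == "CS"), 3)
  expect_equal(sum(p$epochs$channel == "US"), 3)
  cs <- p$epochs[p$epochs$channel == "CS", ]
  us <- p$epochs[p$epochs$channel == "US", ]
  expect_true(all(cs$duration == 20))
  expect_true(all(us$duration == 0.5))
  # each US is coterminous with its CS
  expect_equal(us$t_start + us$duration, cs$t_start + cs$duration)
  expect_equal(sum(conditioning_protocol(n_trials = 0)$epochs$duration), 0)

  e <- extinction_protocol()
  expect_equal(sum(e$epochs$channel == "CS"), 20)
  expect_equal(sum(e$epochs$channel == "US"), 0)

  r <- reinstatement_protocol()
  expect_equal(r$epochs$channel, c("CS", "US", "CS"))
  expect_equal(r$epochs$duration, c(20, 0.5, 20))
  expect_error(conditioning_protocol(us_s = 25), "us_s")

  ch <- chain_protocols(p, e, e, r)
  expect_equal(length(ch$session_boundaries), 3)
  expect_equal(sum(ch$epochs$channel == "CS"), 3 + 20 + 20 + 2)
})

test_that("chained sessions reset transient weights at boundaries", {
  circ <- build_default_circuit()
  full <- chain_protocols(extinction_protocol(n_cs = 2),
                          extinction_protocol(n_cs = 1), gap_s = 30)
  cond_state <- run_protocol(circ, conditioning_protocol(),
                             sim_config(record_every = 50))$state
  tran <- !is.na(circ$connections$rule) &
    circ$connections$rule %in% c("DSI", "DSE")
  cond_state$w[tran] <- cond_state$w_ref[tran]
  tr <- run_protocol(circ, full, sim_config(record_every = 1),
                     init_state = cond_state)
  bnd <- full$session_boundaries[1]
  i_after <- which(tr$time_s > bnd + 0.2)[1]
  i_before <- which(tr$time_s > bnd - 0.2)[1]
  # at the boundary the DSI/DSE weights return to their initial values
  expect_equal(unname(tr$W[i_after, "BAp5->CeM"]),
               connection_weight(circ, "BAp5", "CeM"))
  # just before the boundary they were weakened
  expect_lt(tr$W[i_before, "BAp5->CeM"],
            connection_weight(circ, "BAp5", "CeM"))
})
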