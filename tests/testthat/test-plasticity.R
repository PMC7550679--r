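test_that("Hebbian delta switches sign at the postsynaptic threshold", {
  # at threshold, at ceiling, or without presynaptic firing: no change
  expect_equal(ltp_ltd_delta(1, pre = 5, post = 0.5 * 40, eta = 0.01,
                             M = 3, sigma = 0.5, phi = 40), 0)
  expect_equal(ltp_ltd_delta(3, pre = 5, post = 30, eta = 0.01, M = 3,
                             sigma = 0.5, phi = 40), 0)
  expect_equal(ltp_ltd_delta(1, pre = 0, post = 30, eta = 0.01, M = 3,
                             sigma = 0.5, phi = 40), 0)
  # direct substitution: 0.01 * (3-1) * (2-1) * 1 = 0.02
  expect_equal(ltp_ltd_delta(1, pre = 1, post = 2, eta = 0.01, M = 3,
                             sigma = 0.025, phi = 40), 0.02)
  # below threshold the change is negative (depression)
  expect_lt(ltp_ltd_delta(1, pre = 2, post = 1, eta = 0.01, M = 3,
                          sigma = 0.5, phi = 40), 0)
})

test_that("DSI/DSE delta requires the 10-s trigger and presynaptic firing", {
  expect_equal(dsi_dse_delta(2, pre = 1, eta = 0.1, timer = 9.99,
                             trigger_s = 10), 0)
  expect_equal(dsi_dse_delta(2, pre = 0, eta = 0.1, timer = 12,
                             trigger_s = 10), 0)
  expect_equal(dsi_dse_delta(2, pre = 1, eta = 0.1, timer = 12,
                             trigger_s = 10), -0.2)
})

test_that("depolarization timer accumulates continuously and resets on dips", {
  timer <- 0
  for (i in 1:1000)
    timer <- update_depolarization_timer(timer, post_activation = 10,
                                         phi = 40, dt = 10, theta_dsi = 0.2)
  expect_equal(timer, 10)          # 1000 steps x 10 ms = 10 s
  timer <- update_depolarization_timer(timer, post_activation = 7.9,
                                       phi = 40, dt = 10, theta_dsi = 0.2)
  expect_equal(timer, 0)           # dip below 20% of phi resets
  expect_equal(update_depolarization_timer(5, 0, 40, 10), 0)
})

test_that("engine DSI matches the multiplicative closed form", {
  # constant suprathreshold post and constant pre: after the trigger,
  # W(n) = W0 * (1 - eta*pre*dt/10)^n
  units <- data.frame(
    name = c("P", "Q"), tau = c(10, 10), tonic = c(2.0, 2.0),
    phi = c(30, 30), psi = c(0.2, 0.2),
    polarity = c("excitatory", "excitatory"),
    neuron_class = "pyramidal", stringsAsFactors = FALSE)
  conns <- data.frame(pre = "P", post = "Q", weight = 1,
                      rule = "DSI", eta = 1e-4, stringsAsFactors = FALSE)
  circ <- fear_circuit(units, conns, theta_dsi = 0.2, trigger_s = 10)
  p <- conditioning_protocol(n_trials = 1, cs_s = 30, us_s = 0, iti_s = 1)
  tr <- run_protocol(circ, p, sim_config(record_every = 1))
  a_pre <- transfer(2, 0.2, 30)  # P's tonic steady rate
  w <- tr$W[, 1]
  k0 <- which(w < 1)[1]          # first step after the 10-s trigger
  n <- length(w) - k0 + 1
  expect_equal(unname(w[length(w)]), (1 - 1e-4 * a_pre)^n,
               tolerance = 1e-9)
  # trigger engaged close to 10 s of sustained depolarization
  expect_equal(tr$time_s[k0], 10, tolerance = 0.1)
})

test_that("weights stay in [0, M] and DSI decay is monotone", {
  circ <- build_default_circuit()
  tr <- run_protocol(circ, conditioning_protocol(),
                     sim_config(record_every = 5))
  cn <- circ$connections
  for (i in seq_len(nrow(cn))) {
    expect_true(all(tr$W[, i] >= 0), label = paste("w>=0", cn$pre[i]))
    if (!is.na(cn$rule[i]) && cn$rule[i] %in% c("LTP", "LTP_LTD"))
      expect_true(all(tr$W[, i] <= cn$M[i] + 1e-12),
                  label = paste("w<=M", cn$pre[i], cn$post[i]))
    if (!is.na(cn$rule[i]) && cn$rule[i] %in% c("DSI", "DSE"))
      expect_true(all(diff(tr$W[, i]) <= 1e-12),
                  label = paste("DSI/DSE monotone", cn$pre[i]))
  }
})

test_that("LTP ceiling is 3x the initial weight throughout the default", {
  circ <- build_default_circuit()
  hebb <- !is.na(circ$connections$rule) &
    circ$connections$rule %in% c("LTP", "LTP_LTD")
  expect_equal(circ$connections$M[hebb],
               3 * circ$connections$initial_weight[hebb])
})

test_that("frozen plasticity leaves every weight untouched", {
  circ <- build_default_circuit()
  tr <- run_protocol(circ, conditioning_protocol(),
                     sim_config(record_every = 50),
                     freeze_plasticity = TRUE)
  expect_equal(tr$state$w, circ$connections$weight)
})
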