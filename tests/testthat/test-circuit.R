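test_that("default circuit matches the printed architecture", {
  circ <- build_default_circuit()
  expect_equal(nrow(circ$units), 21)
  expect_equal(sum(circ$units$polarity == "excitatory"), 9)
  expect_equal(sum(circ$units$polarity == "inhibitory"), 12)
  pl <- circ$connections[!is.na(circ$connections$rule), ]
  expect_equal(nrow(pl), 8)
  expect_setequal(
    paste(pl$pre, pl$post, pl$rule),
    c("CS LAp1 LTP", "LAp2 CeLon LTP", "PLp BAp4 LTP_LTD",
      "BAp2 ILp LTP_LTD", "BAp3 ITC LTP", "BAcck BAp2 DSI",
      "BAp4 CeM DSE", "BAp5 CeM DSE"))
  # printed anchor weights
  expect_equal(connection_weight(circ, "BAcck", "BAp1"), 0.7)
  expect_equal(connection_weight(circ, "BAcck", "BAp2"), 0.7)
  expect_equal(connection_weight(circ, "LAp1", "BAp1"), 7.0)
  expect_equal(connection_weight(circ, "LAp1", "BAp2"), 5.0)
  expect_equal(connection_weight(circ, "LAp1", "BAp5"), 3.0)
  expect_equal(circ$external_inputs$CS, 100)
  expect_equal(circ$external_inputs$US, 100)
  expect_equal(circ$trigger_s, 10)
  expect_true(all(circ$units$tau >= 7.7 & circ$units$tau <= 35.6))
  # tonic drives proportional to the 0.3 / 1.3 / 5.3 Hz basal rates
  ratio <- circ$units$tonic / circ$units$basal_hz
  expect_equal(ratio, rep(ratio[1], length(ratio)))
  # legacy connections can be re-enabled for exploration
  leg <- build_default_circuit(legacy_connections = TRUE)
  expect_equal(nrow(leg$units), 22)
  expect_true(all(c("ILp->BApv2", "US->CeM") %in% connection_ids(leg)))
})

test_that("circuit validation rejects malformed inputs", {
  circ <- build_default_circuit()
  bad <- circ$connections
  bad$pre[1] <- "NoSuchUnit"
  expect_error(fear_circuit(circ$units, bad), "NoSuchUnit")
  bad <- circ$connections
  bad$weight[3] <- -1
  expect_error(fear_circuit(circ$units, bad), "non-negative")
  bad <- circ$connections
  bad$rule[2] <- "HEBB"
  expect_error(fear_circuit(circ$units, bad), "rule")
  bad_u <- circ$units; bad_u$tau[1] <- 0
  expect_error(fear_circuit(bad_u, circ$connections), "tau")
})

test_that("snapshot/restore distinguishes transient from persistent weights", {
  circ <- build_default_circuit()
  snap <- snapshot_weights(circ)
  m <- set_connection_weight(circ, "BAcck", "BAp2", 0.3)     # DSI-attached
  m <- set_connection_weight(m, "BAp2", "ILp", 0.4)          # Hebbian
  m2 <- restore_weights(m, snap, only_transient = TRUE)
  expect_equal(connection_weight(m2, "BAcck", "BAp2"), 0.7)
  expect_equal(connection_weight(m2, "BAp2", "ILp"), 0.4)
  m3 <- restore_weights(m, snap, only_transient = FALSE)
  expect_equal(snapshot_weights(m3), snap)
  expect_error(restore_weights(circ, snap[-1]), "cover")
})

test_that("YAML round trip reproduces the circuit exactly", {
  circ <- build_default_circuit()
  f <- tempfile(fileext = ".yaml")
  save_circuit(circ, f)
  back <- load_circuit(f)
  expect_equal(back$units$tau, circ$units$tau)
  expect_equal(back$units$psi, circ$units$psi)
  expect_equal(back$connections$weight, circ$connections$weight)
  expect_equal(back$connections$rule, circ$connections$rule)
  expect_equal(back$connections$eta, circ$connections$eta)
  expect_equal(back$connections$M, circ$connections$M)
  expect_equal(back$theta_dsi, circ$theta_dsi)
  # identical simulation behavior
  p <- conditioning_protocol(n_trials = 1)
  t1 <- run_protocol(circ, p, sim_config(record_every = 20))
  t2 <- run_protocol(back, p, sim_config(record_every = 20))
  expect_equal(t2$A, t1$A)
  unlink(f)
})

test_that("malformed config files fail with informative errors", {
  f <- tempfile(fileext = ".yaml")
  yaml::write_yaml(list(version = 1, units = list()), f)
  expect_error(load_circuit(f), "connections")
  circ <- build_default_circuit()
  save_circuit(circ, f)
  obj <- yaml::read_yaml(f)
  obj$connections[[1]]$post <- "Ghost"
  yaml::write_yaml(obj, f)
  expect_error(load_circuit(f), "Ghost")
  unlink(f)
})

test_that("trace export round-trips through the reader", {
  circ <- build_default_circuit()
  tr <- run_protocol(circ, conditioning_protocol(n_trials = 1),
                     sim_config(record_every = 50))
  f <- tempfile(fileext = ".csv")
  write_trace(tr, f)
  long <- read_trace(f)
  cem <- long[long$series == "CeM", ]
  expect_equal(cem$value, unname(tr$A[, "CeM"]))
  expect_equal(long$value[long$series == "w:CS->LAp1"],
               unname(tr$W[, "CS->LAp1"]))
  unlink(f)
})
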