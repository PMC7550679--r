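test_that("PSP probe calibrates below the ceiling and scales with weight", {
  circ <- build_default_circuit()
  ref <- psp_probe(circ, "CS", "LAp1")
  expect_lt(ref$psp_mv, 10)
  expect_gt(ref$psp_mv, 9)   # bisection lands just under the ceiling
  # identical weights, identical drive: 0% change
  again <- psp_probe(circ, "CS", "LAp1", drive = ref$drive)
  expect_equal(again$psp_mv, ref$psp_mv)
  # the deflection is linear in the weight (slice-like isolation)
  w <- snapshot_weights(circ)
  w3 <- w; w3[["CS->LAp1"]] <- 3 * w3[["CS->LAp1"]]
  tripled <- psp_probe(circ, "CS", "LAp1", weights = w3,
                       drive = ref$drive)
  expect_equal(tripled$psp_mv / ref$psp_mv, 3, tolerance = 1e-6)
  expect_error(psp_probe(circ, "CS", "CeM"), "no connection")
})

test_that("unit-to-unit PSP probes work for excitatory and inhibitory pairs", {
  circ <- build_default_circuit()
  exc <- psp_probe(circ, "BAp2", "ILp")
  expect_true(exc$psp_mv > 9 && exc$psp_mv < 10)
  inh <- psp_probe(circ, "BAcck", "BAp2")
  expect_true(inh$psp_mv > 9 && inh$psp_mv < 10)  # |IPSP| reported
})

test_that("probe CS with frozen plasticity leaves the circuit unchanged", {
  circ <- build_default_circuit()
  st <- run_protocol(circ, conditioning_protocol(),
                     sim_config(record_every = 50))$state
  w_before <- st$w
  pk <- probe_cs(circ, st)
  expect_equal(attr(pk, "trace")$state$w, w_before)
  expect_named(pk)
  expect_true(all(pk >= 0))
})

test_that("classification follows the 20% activity rule", {
  circ <- build_default_circuit()
  phi <- stats::setNames(circ$units$phi, circ$units$name)
  nm <- circ$units$name
  post_cond <- stats::setNames(rep(0, 21), nm)
  post_ext <- post_cond
  post_cond[["BAp4"]] <- 0.5 * phi[["BAp4"]]   # fear: active then silent
  post_ext[["ILp"]] <- 0.3 * phi[["ILp"]]      # extinction: reverse
  post_cond[["LAp1"]] <- 0.9 * phi[["LAp1"]]   # persistent: active twice
  post_ext[["LAp1"]] <- 0.21 * phi[["LAp1"]]
  post_cond[["BAp3"]] <- 0.19 * phi[["BAp3"]]  # just below threshold
  cls <- classify_units(post_cond, post_ext, circ)
  expect_equal(unname(cls[["BAp4"]]), "fear")
  expect_equal(unname(cls[["ILp"]]), "extinction")
  expect_equal(unname(cls[["LAp1"]]), "persistent")
  expect_equal(unname(cls[["BAp3"]]), "none")
})

test_that("perturbation validation catches unknown targets", {
  circ <- build_default_circuit()
  p <- conditioning_protocol(n_trials = 1)
  expect_error(run_protocol(circ, p, sim_config(),
                            perturbations = perturbation("lesion_unit",
                                                         "Nope")),
               "unknown unit")
  expect_error(run_protocol(circ, p, sim_config(),
                            perturbations = perturbation(
                              "clamp_connection_output", "A->B",
                              value = 0)),
               "unknown connection")
  expect_error(run_protocol(circ, p, sim_config(),
                            perturbations = perturbation(
                              "block_plasticity", "DSI",
                              region = "XX")),
               "region")
  expect_error(perturbation("explode", "LAp1"), "unknown perturbation")
})

test_that("lesion and clamp perturbations act only inside their window", {
  circ <- build_default_circuit()
  p <- conditioning_protocol(n_trials = 1, cs_s = 10, us_s = 0, iti_s = 5)
  les <- perturbation("lesion_unit", "LAp2", window = c(6, 9))
  tr <- run_protocol(circ, p, sim_config(record_every = 1),
                     perturbations = les, freeze_plasticity = TRUE)
  inside <- tr$time_s > 6.5 & tr$time_s < 8.5
  outside <- tr$time_s > 10 & tr$time_s < 14.5
  expect_true(all(tr$A[inside, "LAp2"] == 0))
  expect_true(all(tr$A[outside, "LAp2"] > 10))
  mx <- perturbation("clamp_unit_max", "ILp", window = c(6, 9))
  tr2 <- run_protocol(circ, p, sim_config(record_every = 1),
                      perturbations = mx, freeze_plasticity = TRUE)
  expect_true(all(tr2$A[inside, "ILp"] == 20))
})

test_that("regional weight zeroing silences the region and then restores", {
  circ <- build_default_circuit()
  p <- conditioning_protocol(n_trials = 1, cs_s = 10, us_s = 0, iti_s = 5)
  ttx <- perturbation("zero_region_weights", "PL", window = c(0, 12))
  tr <- run_protocol(circ, p, sim_config(record_every = 1),
                     perturbations = ttx, freeze_plasticity = TRUE)
  during <- tr$time_s > 7 & tr$time_s < 11
  expect_true(all(tr$A[during, "PLp"] == 0))
  expect_true(all(tr$A[during, "PLs"] == 0))
  # weights themselves are untouched after the window
  expect_equal(tr$state$w, circ$connections$weight)
})
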