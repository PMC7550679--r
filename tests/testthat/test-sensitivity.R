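test_that("oat parameter list covers every weight and plasticity constant", {
  circ <- build_default_circuit()
  ids <- oat_parameters(circ)
  expect_equal(sum(startsWith(ids, "w:")), nrow(circ$connections))
  expect_equal(sum(startsWith(ids, "eta:")),
               sum(!is.na(circ$connections$rule)))
  expect_equal(sum(startsWith(ids, "eta_ltd:")),
               sum(circ$connections$rule %in% "LTP_LTD"))
})

test_that("scanning one parameter brackets the reference and stops early", {
  circ <- build_default_circuit()
  rep <- oat_scan(circ, params = "w:CeLoff->CeM", fast = TRUE,
                  verbose = FALSE)
  expect_s3_class(rep, "fear_oat_report")
  expect_equal(nrow(rep), 1)
  # boundaries bracket the reference on both sides
  expect_lt(rep$lower_pct, 0)
  expect_gt(rep$upper_pct, 0)
  # a reported boundary names the first experiment lost there
  if (is.finite(rep$upper_pct)) expect_true(nzchar(rep$lost_upper))
})

test_that("a removable parameter is reported as such", {
  # the legacy connections re-enabled at zero weight are removable by
  # construction: scanning them finds no lower failure boundary
  circ <- build_default_circuit(legacy_connections = TRUE)
  # give one a nonzero weight small enough to change nothing
  circ <- set_connection_weight(circ, "US", "CeM", 1e-6,
                                reset_initial = TRUE)
  rep <- oat_scan(circ, params = "w:US->CeM", fast = TRUE, verbose = FALSE)
  expect_equal(rep$lower_pct, -100)
  expect_equal(prune_removable(rep), "w:US->CeM")
})

test_that("zeroing any plasticity rate loses at least one experiment", {
  circ <- build_default_circuit()
  cfg <- sim_config(record_every = 5)
  core <- c("cond_acquisition", "within_session_extinction",
            "between_session_extinction", "reinstatement",
            "unit_taxonomy", "cond_ltp_cs_pathway", "cond_ltp_la_celon",
            "cond_ltp_pl_ba", "ext_ltd_pl_ba", "ext_ltp_ba_il",
            "ext_ltp_ba_itc", "ext_transient_dsie")
  ref <- run_registry(circ, cfg, ids = core)
  expect_true(all(ref$pass))
  zero_eta <- function(model, pre, post) {
    i <- which(model$connections$pre == pre & model$connections$post ==
                 post)
    model$connections$eta[i] <- 0
    if (!is.na(model$connections$eta_ltd[i]))
      model$connections$eta_ltd[i] <- 0
    fear_circuit(model$units, model$connections, model$external_inputs,
                 model$theta_dsi, model$trigger_s)
  }
  # one representative per rule class: LTP, LTP/LTD, DSI, DSE
  for (pp in list(c("CS", "LAp1"), c("PLp", "BAp4"), c("BAcck", "BAp2"),
                  c("BAp5", "CeM"))) {
    r <- run_registry(zero_eta(circ, pp[1], pp[2]), cfg, ids = core)
    expect_lt(sum(r$pass), length(core))
  }
})
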