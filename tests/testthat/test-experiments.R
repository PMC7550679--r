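# The baseline assessment and registry are computed once and shared.
base_cache <- new.env()
get_base <- function() {
  if (is.null(base_cache$b))
    base_cache$b <- baseline_assessment(build_default_circuit(),
                                        sim_config(record_every = 5))
  base_cache$b
}

test_that("the four-session course shows the canonical behavioral arc", {
  base <- get_base()
  expect_gte(base$course$cond[3], 70)            # fear acquired
  expect_gte(base$course$ext1[1], 70)            # expressed at ext start
  expect_lte(min(base$course$ext1), 20)          # within-session extinction
  expect_lte(base$course$ext2[1], base$course$ext1[1] - 5)  # retention
  expect_gte(base$course$ext2[1], 20)            # with a residual
  expect_gte(base$course$reinst[2], 70)          # reinstated fear
})

test_that("probe taxonomy recovers fear, extinction and persistent units", {
  cls <- get_base()$classification
  expect_setequal(names(cls)[cls == "fear"], c("BAp4", "CeM"))
  expect_true(all(cls[c("BAp3", "ILp", "ITC")] == "extinction"))
  expect_true(all(cls[c("LAp1", "BAp1", "BAp5", "BAcck", "BApv", "CeLon",
                        "PLp")] == "persistent"))
})

test_that("stage PSPs show the conditioning/extinction plasticity pattern", {
  base <- get_base()
  chg <- function(a, b) 100 * (base$psps[[b]] / base$psps[[a]] - 1)
  cond <- chg("naive", "cond")
  expect_gte(cond[["CS->LAp1"]], 20)
  expect_gte(cond[["LAp2->CeLon"]], 20)
  expect_gte(cond[["PLp->BAp4"]], 20)
  expect_lt(abs(cond[["BAp2->ILp"]]), 20)
  ext <- chg("cond", "ext")
  expect_lte(ext[["PLp->BAp4"]], -20)
  expect_gte(ext[["BAp2->ILp"]], 20)
  expect_gte(ext[["BAp3->ITC"]], 20)
  expect_lt(abs(ext[["CS->LAp1"]]), 20)
})

test_that("registry covers 25 experiments keyed to figure panels", {
  reg <- experiment_registry()
  expect_length(reg, 25)
  ids <- vapply(reg, `[[`, "", "id")
  expect_false(anyDuplicated(ids) > 0)
  expect_true(all(nzchar(vapply(reg, `[[`, "", "figure"))))
})

test_that("registry verdicts on the default circuit match the shipped state", {
  res <- run_registry(build_default_circuit(),
                      sim_config(record_every = 5), base = get_base())
  expect_s3_class(res, "fear_registry_results")
  expect_equal(nrow(res), 25)
  # every experiment passes except the reinstatement re-potentiation of
  # the prelimbic input to BAp4, a documented limitation of the Hebbian
  # ceiling factor in this architecture
  expect_identical(res$id[!res$pass], "reinst_replasticity")
  d <- attr(res, "details")[[which(res$id == "reinst_replasticity")]]
  expect_lte(d$measures[["ba_il_pct"]], -20)  # the BAp2->ILp half holds
})

test_that("subsetting the registry and unknown ids behave", {
  res <- run_registry(build_default_circuit(),
                      sim_config(record_every = 5), base = get_base(),
                      ids = c("cond_acquisition", "unit_taxonomy"))
  expect_equal(nrow(res), 2)
  expect_true(all(res$pass))
  expect_error(run_registry(ids = "nope"), "unknown experiment")
})

test_that("plasticity blockades leave targeted weights untouched", {
  circ <- build_default_circuit()
  st <- run_protocol(circ, conditioning_protocol(),
                     sim_config(record_every = 50))$state
  tran <- !is.na(circ$connections$rule) &
    circ$connections$rule %in% c("DSI", "DSE")
  st$w[tran] <- st$w_ref[tran]
  blk <- perturbation("block_plasticity", "DSI/DSE", region = "CeM")
  tr <- run_protocol(circ, extinction_protocol(n_cs = 3),
                     sim_config(record_every = 50), perturbations = blk,
                     init_state = st)
  ids <- colnames(tr$W)
  expect_equal(tr$state$w[match("BAp4->CeM", ids)],
               connection_weight(circ, "BAp4", "CeM"))
  expect_equal(tr$state$w[match("BAp5->CeM", ids)],
               connection_weight(circ, "BAp5", "CeM"))
  # the BA-located DSI is not covered by a CeM-region blockade
  expect_lt(tr$state$w[match("BAcck->BAp2", ids)],
            connection_weight(circ, "BAcck", "BAp2"))
})
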