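#' Baseline assessment: the full four-session course with probes
#'
#' Runs conditioning, two extinction sessions and reinstatement on an
#' unperturbed circuit, collecting per-trial CeM courses, plasticity-frozen
#' probe activations, PSP probes for every Hebbian-plastic connection at
#' each stage, and the fear/extinction/persistent unit taxonomy.  Transient
#' (DSI/DSE) weights are returned to their pre-protocol values between the
#' two extinction sessions and before reinstatement, the points at which
#' the endocannabinoid depression is forgotten; stage probes are taken on a
#' copy with transients likewise reset (a later test day).
#'
#' Most registry experiments evaluate against this shared control.
#'
#' @param model A \code{\link{fear_circuit}}.
#' @param cfg A \code{\link{sim_config}}.
#' @param criteria A \code{\link{criteria_config}}.
#' @return A `fear_baseline` list (stages, courses, probes, psps,
#'   classification).
#' @export
baseline_assessment <- function(model, cfg = sim_config(record_every = 2),
                                criteria = criteria_config()) {
  tran <- transient_mask(model)
  cond <- conditioning_protocol()
  ext <- extinction_protocol()
  rp <- reinstatement_protocol()

  w0 <- snapshot_weights(model)
  psp_ref <- psp_calibration(model, cfg)

  trc <- run_protocol(model, cond, cfg)
  st_cond <- trc$state
  tre1 <- run_protocol(model, ext, cfg,
                       init_state = reset_transients(st_cond, tran))
  tre2 <- run_protocol(model, ext, cfg,
                       init_state = reset_transients(tre1$state, tran))
  trr <- run_protocol(model, rp, cfg,
                      init_state = reset_transients(tre2$state, tran))

  cs1 <- cond$epochs$t_start[cond$epochs$channel == "CS"]
  ese <- ext$epochs$t_start[ext$epochs$channel == "CS"]
  csr <- rp$epochs$t_start[rp$epochs$channel == "CS"]
  cem_pct <- function(tr, starts) 100 * trial_peaks(tr, "CeM", starts) /
    unit_phi(model, "CeM")

  pk_cond <- probe_cs(model, reset_transients(st_cond, tran), cfg = cfg)
  pk_ext <- probe_cs(model, tre2$state, cfg = cfg)
  pk_naive <- probe_cs(model, NULL, cfg = cfg)

  wt_cond <- weights_as_table(model, st_cond$w)
  wt_ext1 <- weights_as_table(model, tre1$state$w)
  wt_ext <- weights_as_table(model, tre2$state$w)
  wt_reinst <- weights_as_table(model, trr$state$w)
  persistent_only <- function(wt) { wt[tran] <- w0[tran]; wt }

  psps <- list(
    naive = psp_measure(model, psp_ref, w0, cfg),
    cond = psp_measure(model, psp_ref, persistent_only(wt_cond), cfg),
    ext = psp_measure(model, psp_ref, persistent_only(wt_ext), cfg),
    reinst = psp_measure(model, psp_ref, persistent_only(wt_reinst), cfg))

  structure(list(
    model = model, cfg = cfg, criteria = criteria,
    protocols = list(cond = cond, ext = ext, reinst = rp),
    states = list(cond = st_cond, ext1 = tre1$state, ext2 = tre2$state,
                  reinst = trr$state),
    course = list(
      cond = cem_pct(trc, cs1),
      ext1 = cem_pct(tre1, ese),
      ext2 = cem_pct(tre2, ese),
      reinst = cem_pct(trr, csr)),
    probes = list(naive = pk_naive, cond = pk_cond, ext = pk_ext),
    weights = list(initial = w0, cond = wt_cond, ext1_end = wt_ext1,
                   ext = wt_ext, reinst = wt_reinst),
    psp_ref = psp_ref, psps = psps,
    classification = classify_units(pk_cond, pk_ext, model, criteria)),
    class = "fear_baseline")
}

#' @export
print.fear_baseline <- function(x, ...) {
  cat("<fear_baseline> CeM (% of max) per CS:\n")
  cat(" conditioning:", paste(round(x$course$cond), collapse = " "), "\n")
  cat(" extinction 1:", paste(round(x$course$ext1), collapse = " "), "\n")
  cat(" extinction 2:", paste(round(x$course$ext2), collapse = " "), "\n")
  cat(" reinstatement:", paste(round(x$course$reinst), collapse = " "), "\n")
  cls <- x$classification
  for (k in c("fear", "extinction", "persistent"))
    cat(sprintf(" %s units: %s\n", k,
                paste(names(cls)[cls == k], collapse = ", ")))
  invisible(x)
}

# ---- internal helpers -----------------------------------------------------

transient_mask <- function(model) {
  !is.na(model$connections$rule) &
    model$connections$rule %in% c("DSI", "DSE")
}
reset_transients <- function(state, tran) {
  state$w[tran] <- state$w_ref[tran]
  state
}
unit_phi <- function(model, u) model$units$phi[match(u, model$units$name)]
trial_peaks <- function(tr, unit, starts, cs_s = 20, skip_s = 2) {
  vapply(starts, function(s)
    max(peak_activation(tr, c(s + skip_s, s + cs_s), unit)), numeric(1))
}
hebbian_pairs <- function(model) {
  cn <- model$connections
  sel <- !is.na(cn$rule) & cn$rule %in% c("LTP", "LTP_LTD")
  Map(c, cn$pre[sel], cn$post[sel])
}
psp_calibration <- function(model, cfg) {
  pairs <- hebbian_pairs(model)
  out <- lapply(pairs, function(pp)
    psp_probe(model, pp[1], pp[2], cfg = cfg))
  names(out) <- vapply(pairs, paste, "", collapse = "->")
  out
}
psp_measure <- function(model, psp_ref, wtab, cfg) {
  vapply(names(psp_ref), function(id) {
    pp <- strsplit(id, "->", fixed = TRUE)[[1]]
    psp_probe(model, pp[1], pp[2], weights = wtab,
              drive = psp_ref[[id]]$drive, cfg = cfg)$psp_mv
  }, numeric(1))
}
psp_change <- function(base, stage_a, stage_b, id) {
  a <- base$psps[[stage_a]][[id]]; b <- base$psps[[stage_b]][[id]]
  if (a < 1e-9) return(if (b < 1e-9) 0 else Inf)
  100 * (b / a - 1)
}
first_below <- function(course, thr) {
  i <- which(course < thr)[1]
  if (is.na(i)) Inf else i
}
pctmax <- function(pk, model) percent_of_max(pk, model)

cs_windows <- function(protocol, last_s = NULL) {
  e <- protocol$epochs[protocol$epochs$channel == "CS", , drop = FALSE]
  if (is.null(last_s)) cbind(e$t_start, e$t_start + e$duration)
  else cbind(e$t_start + e$duration - last_s, e$t_start + e$duration)
}

# Run the two extinction sessions from the post-conditioning state with
# perturbations active in chosen sessions; returns CeM courses, end states.
run_extinction_pair <- function(base, pert1 = NULL, pert2 = NULL) {
  model <- base$model; cfg <- base$cfg
  tran <- transient_mask(model)
  ext <- base$protocols$ext
  ese <- ext$epochs$t_start[ext$epochs$channel == "CS"]
  tr1 <- run_protocol(model, ext, cfg, perturbations = pert1,
                      init_state = reset_transients(base$states$cond,
                                                    tran))
  tr2 <- run_protocol(model, ext, cfg, perturbations = pert2,
                      init_state = reset_transients(tr1$state, tran))
  list(cem1 = 100 * trial_peaks(tr1, "CeM", ese) / unit_phi(model, "CeM"),
       cem2 = 100 * trial_peaks(tr2, "CeM", ese) / unit_phi(model, "CeM"),
       state1 = tr1$state, state2 = tr2$state)
}

#' The registry of target experiments
#'
#' Returns the 25 registered in-silico experiments, each keyed to the
#' circuit phenomenon it reproduces and carrying an operational pass
#' criterion built from the global thresholds (unit active at 20% of
#' maximum, fear expressed at 70% of CeM maximum, plasticity detected at a
#' 20% PSP change).  Where a finding is comparative (a manipulation versus
#' control), the criterion compares against the shared baseline run with a
#' 5-10 point margin; these operationalizations are documented in the
#' methods vignette.
#'
#' @return A named list of experiment specs (`id`, `figure`, `description`,
#'   `run`).
#' @seealso \code{\link{run_registry}}
#' @export
experiment_registry <- function() {
  E <- function(id, figure, description, run)
    list(id = id, figure = figure, description = description, run = run)
  list(
    E("cond_acquisition", "Fig 3",
      "Three CS-US pairings establish fear: CeM reaches the 70% criterion at the third conditioning CS",
      function(base, cr) {
        v <- base$course$cond[3]
        list(pass = v >= 100 * cr$cem_fear_frac, measures = c(cem_cs3_pct = v))
      }),
    E("within_session_extinction", "Fig 3",
      "Fear declines within the first extinction session: CeM starts above the fear criterion and falls below the active threshold",
      function(base, cr) {
        c1 <- base$course$ext1
        list(pass = c1[1] >= 100 * cr$cem_fear_frac &&
               min(c1) <= 100 * cr$unit_active_frac,
             measures = c(first_pct = c1[1], min_pct = min(c1)))
      }),
    E("between_session_extinction", "Fig 3",
      "Extinction is retained across sessions: session 2 starts well below the initial fear level and re-extinguishes to baseline",
      function(base, cr) {
        c1 <- base$course$ext1; c2 <- base$course$ext2
        list(pass = c2[1] <= c1[1] - 10 &&
               min(c2) <= 100 * cr$unit_active_frac,
             measures = c(ext1_first = c1[1], ext2_first = c2[1],
                          ext2_min = min(c2)))
      }),
    E("reinstatement", "Fig 3",
      "A single unpaired US reinstates fear: residual CeM activity at the first reinstatement CS, full fear at the second",
      function(base, cr) {
        r <- base$course$reinst
        list(pass = r[1] >= 100 * cr$unit_active_frac &&
               r[2] >= 100 * cr$cem_fear_frac,
             measures = c(cs1_pct = r[1], cs2_pct = r[2]))
      }),
    E("unit_taxonomy", "Fig 3",
      "Probe CS responses classify the units: fear = {BAp4, CeM}; extinction includes BAp3, ILp, ITC; persistent includes LAp1, BAp1, BAp5, BAcck, BApv, CeLon, PLp",
      function(base, cr) {
        cls <- base$classification
        fear <- sort(names(cls)[cls == "fear"])
        ok_f <- identical(fear, sort(c("BAp4", "CeM")))
        ok_e <- all(cls[c("BAp3", "ILp", "ITC")] == "extinction")
        ok_p <- all(cls[c("LAp1", "BAp1", "BAp5", "BAcck", "BApv",
                          "CeLon", "PLp")] == "persistent")
        list(pass = ok_f && ok_e && ok_p,
             measures = c(fear_ok = ok_f, extinction_ok = ok_e,
                          persistent_ok = ok_p))
      }),
    E("cond_ltp_cs_pathway", "Fig 4",
      "Conditioning potentiates the CS pathway onto LA (PSP increase at least 20%)",
      function(base, cr) {
        v <- psp_change(base, "naive", "cond", "CS->LAp1")
        list(pass = v >= 100 * cr$psp_change_frac, measures = c(psp_pct = v))
      }),
    E("cond_ltp_la_celon", "Fig 4",
      "Conditioning potentiates LAp2 -> CeL-ON (the CeL gate learns the CS)",
      function(base, cr) {
        v <- psp_change(base, "naive", "cond", "LAp2->CeLon")
        list(pass = v >= 100 * cr$psp_change_frac, measures = c(psp_pct = v))
      }),
    E("cond_ltp_pl_ba", "Fig 4",
      "Conditioning potentiates the prelimbic input to the BA fear unit (PLp -> BAp4)",
      function(base, cr) {
        v <- psp_change(base, "naive", "cond", "PLp->BAp4")
        list(pass = v >= 100 * cr$psp_change_frac, measures = c(psp_pct = v))
      }),
    E("cond_stability", "Fig 4",
      "The extinction-circuit synapses are untouched by conditioning (BAp2 -> ILp and BAp3 -> ITC stable within 20%)",
      function(base, cr) {
        v1 <- psp_change(base, "naive", "cond", "BAp2->ILp")
        v2 <- psp_change(base, "naive", "cond", "BAp3->ITC")
        list(pass = abs(v1) < 100 * cr$psp_change_frac &&
               abs(v2) < 100 * cr$psp_change_frac,
             measures = c(ba_il_pct = v1, ba_itc_pct = v2))
      }),
    E("ext_ltd_pl_ba", "Fig 5",
      "Extinction depotentiates PLp -> BAp4 (reverting the conditioning LTP)",
      function(base, cr) {
        v <- psp_change(base, "cond", "ext", "PLp->BAp4")
        list(pass = v <= -100 * cr$psp_change_frac, measures = c(psp_pct = v))
      }),
    E("ext_ltp_ba_il", "Fig 5",
      "Extinction potentiates BAp2 -> ILp (the BA route into the infralimbic cortex)",
      function(base, cr) {
        v <- psp_change(base, "cond", "ext", "BAp2->ILp")
        list(pass = v >= 100 * cr$psp_change_frac, measures = c(psp_pct = v))
      }),
    E("ext_ltp_ba_itc", "Fig 5",
      "Extinction potentiates BAp3 -> ITC (recruiting the intercalated cells)",
      function(base, cr) {
        v <- psp_change(base, "cond", "ext", "BAp3->ITC")
        list(pass = v >= 100 * cr$psp_change_frac, measures = c(psp_pct = v))
      }),
    E("ext_stability_cs_pathway", "Fig 5",
      "Extinction does not depotentiate the conditioned CS pathway (CS -> LAp1 and LAp2 -> CeL-ON stable)",
      function(base, cr) {
        v1 <- psp_change(base, "cond", "ext", "CS->LAp1")
        v2 <- psp_change(base, "cond", "ext", "LAp2->CeLon")
        list(pass = abs(v1) < 100 * cr$psp_change_frac &&
               abs(v2) < 100 * cr$psp_change_frac,
             measures = c(cs_pct = v1, celon_pct = v2))
      }),
    E("ext_transient_dsie", "Fig 5",
      "DSI/DSE transiently weaken BAcck -> BAp2 and the BA -> CeM inputs by the end of an extinction session; the weights are restored between sessions",
      function(base, cr) {
        w0 <- base$weights$initial; we <- base$weights$ext1_end
        ids <- c("BAcck->BAp2", "BAp4->CeM", "BAp5->CeM")
        drop_pct <- 100 * (we[ids] / w0[ids] - 1)
        list(pass = all(drop_pct < -1), measures = drop_pct)
      }),
    E("reinst_replasticity", "Fig 6",
      "Reinstatement re-potentiates PLp -> BAp4 and depotentiates BAp2 -> ILp back toward pre-extinction values",
      function(base, cr) {
        v1 <- psp_change(base, "ext", "reinst", "PLp->BAp4")
        v2 <- psp_change(base, "ext", "reinst", "BAp2->ILp")
        list(pass = v1 >= 100 * cr$psp_change_frac &&
               v2 <= -100 * cr$psp_change_frac,
             measures = c(pl_ba_pct = v1, ba_il_pct = v2))
      }),
    E("pl_ttx", "Fig 7A",
      "PL inactivation (TTX) during conditioning reduces fear expression during training but leaves the learned association intact at test",
      function(base, cr) {
        model <- base$model; cfg <- base$cfg
        cond <- base$protocols$cond
        p <- perturbation("zero_region_weights", "PL",
                          window = c(0, cond$duration_s))
        tr <- run_protocol(model, cond, cfg, perturbations = p)
        cs <- cond$epochs$t_start[cond$epochs$channel == "CS"]
        cem3 <- 100 * trial_peaks(tr, "CeM", cs[3]) / unit_phi(model, "CeM")
        pk <- probe_cs(model, reset_transients(tr$state,
                                               transient_mask(model)),
                       cfg = cfg)
        test <- pctmax(pk, model)[["CeM"]]
        list(pass = cem3 <= base$course$cond[3] - 10 &&
               test >= 100 * cr$cem_fear_frac,
             measures = c(cond_cs3_pct = cem3,
                          control_cs3_pct = base$course$cond[3],
                          test_pct = test))
      }),
    E("opto_toggle", "Fig 7B",
      "Optogenetic toggling of the CS pathway: artificial LTP alone gives no fear; conditioning does; depotentiation removes it; re-potentiation restores it",
      function(base, cr) {
        model <- base$model; cfg <- base$cfg
        w0 <- connection_weight(model, "CS", "LAp1")
        probe_with_cs_weight <- function(state, w) {
          st <- state
          if (is.null(st)) {
            m2 <- set_connection_weight(model, "CS", "LAp1", w)
            pk <- probe_cs(m2, NULL, cfg = cfg)
          } else {
            i <- match("CS->LAp1", connection_ids(model))
            st$w[i] <- w
            pk <- probe_cs(model, st, cfg = cfg)
          }
          pctmax(pk, model)[["CeM"]]
        }
        st_cond <- reset_transients(base$states$cond, transient_mask(model))
        thr <- 100 * cr$cem_fear_frac
        ltp_only <- probe_with_cs_weight(NULL, 3 * w0)
        conditioned <- pctmax(base$probes$cond, model)[["CeM"]]
        depot <- probe_with_cs_weight(st_cond, 0)
        repot <- probe_with_cs_weight(st_cond, 3 * w0)
        list(pass = ltp_only < thr && conditioned >= thr &&
               depot < thr && repot >= thr,
             measures = c(ltp_only = ltp_only, conditioned = conditioned,
                          depotentiated = depot, repotentiated = repot))
      }),
    E("la_inactivation", "Fig 7C",
      "LA inactivation during conditioning abolishes learning: the CS fails to activate CeM at test",
      function(base, cr) inactivation_during_conditioning(base, cr,
                                                          c("LAp1", "LAp2"))),
    E("cel_inactivation", "Fig 7C",
      "CeL inactivation during conditioning abolishes learning (the CeM brake is never taught to release)",
      function(base, cr) inactivation_during_conditioning(base, cr,
                                                          c("CeLon",
                                                            "CeLoff"))),
    E("celon_celoff_reversal", "Fig 8A,B",
      "Conditioning makes CeL-ON CS-responsive and silences the tonic CeL-OFF response during the CS",
      function(base, cr) {
        act <- 100 * base$criteria$unit_active_frac
        on_naive <- pctmax(base$probes$naive, base$model)[["CeLon"]]
        on_cond <- pctmax(base$probes$cond, base$model)[["CeLon"]]
        off_naive <- pctmax(base$probes$naive, base$model)[["CeLoff"]]
        off_cond <- pctmax(base$probes$cond, base$model)[["CeLoff"]]
        list(pass = on_naive < act && on_cond >= act &&
               off_naive >= act && off_cond < act,
             measures = c(on_naive = on_naive, on_cond = on_cond,
                          off_naive = off_naive, off_cond = off_cond))
      }),
    E("us_substitution", "Fig 8C/9",
      "Replacing the US by LA depolarization yields conditioning that is real but weaker than standard (the extinction circuit is co-recruited); unpaired depolarization gives none; blocking BAp2 during the depolarization rescues full conditioning",
      function(base, cr) {
        model <- base$model; cfg <- base$cfg
        tran <- transient_mask(model)
        cond0 <- conditioning_protocol(us_s = 0)
        win <- cs_windows(base$protocols$cond, last_s = 0.5)
        clamp <- lapply(seq_len(nrow(win)), function(i)
          perturbation("clamp_unit_max", c("LAp1", "LAp2"), win[i, ]))
        pair3 <- cs_windows(cond0, last_s = 0.25)[3, ]
        trial3_cem <- function(perts) {
          # CeM engagement settled within the third pairing event
          tr <- run_protocol(model, cond0, cfg, perturbations = perts)
          sel <- tr$time_s >= pair3[1] & tr$time_s <= pair3[2]
          100 * mean(tr$A[sel, "CeM"]) / unit_phi(model, "CeM")
        }
        paired <- trial3_cem(clamp)
        unpaired_win <- win - 20  # during the inter-trial interval
        unpaired <- trial3_cem(lapply(seq_len(nrow(unpaired_win)),
          function(i) perturbation("clamp_unit_max", c("LAp1", "LAp2"),
                                   unpaired_win[i, ])))
        trial_win <- cs_windows(cond0)
        rescue <- trial3_cem(c(clamp,
          lapply(seq_len(nrow(trial_win)), function(i)
            perturbation("lesion_unit", "BAp2", trial_win[i, ]))))
        ctrl <- base$course$cond[3]
        act <- 100 * cr$unit_active_frac
        list(pass = paired >= act && paired <= ctrl - 10 &&
               unpaired < act && rescue >= paired + 5,
             measures = c(paired = paired, unpaired = unpaired,
                          rescue = rescue, control = ctrl))
      }),
    E("dsie_global", "Fig 10A",
      "Blocking DSI/DSE everywhere abolishes both within- and between-session extinction: fear persists across two full extinction sessions",
      function(base, cr) {
        blk <- perturbation("block_plasticity", "DSI/DSE")
        r <- run_extinction_pair(base, blk, blk)
        thr <- 100 * cr$cem_fear_frac
        list(pass = min(r$cem1) >= thr && min(r$cem2) >= thr,
             measures = c(min_s1 = min(r$cem1), min_s2 = min(r$cem2)))
      }),
    E("dsie_cem", "Fig 10B",
      "Blocking DSI/DSE in CeM during session 1 impairs within-session extinction but spares session 2",
      function(base, cr) {
        blk <- perturbation("block_plasticity", "DSI/DSE", region = "CeM")
        r <- run_extinction_pair(base, blk, NULL)
        ctrl1 <- base$course$ext1; ctrl2 <- base$course$ext2
        c_blk <- first_below(r$cem1, 100 * cr$cem_fear_frac)
        c_ctl <- first_below(ctrl1, 100 * cr$cem_fear_frac)
        list(pass = (c_blk >= c_ctl + 5 || !is.finite(c_blk)) &&
               abs(min(r$cem2) - min(ctrl2)) <= 15,
             measures = c(cross_blocked = c_blk, cross_control = c_ctl,
                          s2_min_blocked = min(r$cem2),
                          s2_min_control = min(ctrl2)))
      }),
    E("dsie_ba", "Fig 10C/11",
      "Blocking DSI in BA during session 1 spares within-session extinction but abolishes its between-session retention, and prevents the extinction-induced plasticity (no BAp2 -> ILp or BAp3 -> ITC LTP, no PLp -> BAp4 LTD)",
      function(base, cr) {
        model <- base$model; cfg <- base$cfg
        blk <- perturbation("block_plasticity", "DSI/DSE", region = "BA")
        r <- run_extinction_pair(base, blk, NULL)
        ctrl1 <- base$course$ext1
        decline_blk <- r$cem1[1] - min(r$cem1)
        decline_ctl <- ctrl1[1] - min(ctrl1)
        # plasticity after a fully blocked two-session extinction
        blk2 <- perturbation("block_plasticity", "DSI/DSE", region = "BA")
        rb <- run_extinction_pair(base, blk2, blk2)
        wt <- weights_as_table(model, rb$state2$w)
        tran <- transient_mask(model)
        wt[tran] <- base$weights$initial[tran]
        psp_blk <- psp_measure(model, base$psp_ref, wt, cfg)
        dpl <- 100 * (psp_blk / base$psps$cond - 1)
        thr <- 100 * cr$psp_change_frac
        list(pass = decline_blk >= 30 && decline_ctl >= 30 &&
               r$cem2[1] >= base$course$ext2[1] + 10 &&
               dpl[["BAp2->ILp"]] < thr && dpl[["BAp3->ITC"]] < thr &&
               dpl[["PLp->BAp4"]] > -thr,
             measures = c(decline_blocked = decline_blk,
                          decline_control = decline_ctl,
                          s2_first_blocked = r$cem2[1],
                          s2_first_control = base$course$ext2[1],
                          ba_il_pct = dpl[["BAp2->ILp"]],
                          ba_itc_pct = dpl[["BAp3->ITC"]],
                          pl_ba_pct = dpl[["PLp->BAp4"]]))
      }),
    E("il_pl_manipulations", "Fig 12",
      "IL lesion spares conditioning and within-session extinction but abolishes between-session extinction; IL stimulation speeds extinction; stimulating the PL -> IL projection speeds it and silencing it slows early extinction",
      function(base, cr) {
        thr <- 100 * cr$cem_fear_frac
        ctrl1 <- base$course$ext1
        c_ctl <- first_below(ctrl1, thr)
        les <- perturbation("lesion_unit", c("ILp", "ILpv", "ILs"))
        rl <- run_extinction_pair(base, les, les)
        ext <- base$protocols$ext
        stim_il <- lapply(seq_len(nrow(cs_windows(ext))), function(i)
          perturbation("clamp_unit_max", "ILp", cs_windows(ext)[i, ]))
        rs <- run_extinction_pair(base, stim_il, NULL)
        rps <- run_extinction_pair(base,
          perturbation("clamp_connection_output", "PLp->ILp", value = "max"),
          NULL)
        rpz <- run_extinction_pair(base,
          perturbation("clamp_connection_output", "PLp->ILp", value = 0),
          NULL)
        cross <- function(x) first_below(x, thr)
        early_mean <- function(x) mean(x[2:6])
        list(pass = (rl$cem1[1] - min(rl$cem1)) >= 30 &&
               rl$cem2[1] >= base$course$ext2[1] + 10 &&
               cross(rs$cem1) <= c_ctl - 1 &&
               cross(rps$cem1) <= c_ctl &&
               early_mean(rpz$cem1) >= early_mean(ctrl1) + 2,
             measures = c(
               il_lesion_decline_s1 = rl$cem1[1] - min(rl$cem1),
               il_lesion_s2_first = rl$cem2[1],
               control_s2_first = base$course$ext2[1],
               cross_control = c_ctl, cross_il_stim = cross(rs$cem1),
               cross_plil_stim = cross(rps$cem1),
               early_mean_plil_zero = early_mean(rpz$cem1),
               early_mean_control = early_mean(ctrl1)))
      })
  )
}

inactivation_during_conditioning <- function(base, cr, units) {
  model <- base$model; cfg <- base$cfg
  cond <- base$protocols$cond
  p <- perturbation("lesion_unit", units, window = c(0, cond$duration_s))
  tr <- run_protocol(model, cond, cfg, perturbations = p)
  pk <- probe_cs(model, reset_transients(tr$state, transient_mask(model)),
                 cfg = cfg)
  test <- pctmax(pk, model)[["CeM"]]
  list(pass = test < 100 * cr$cem_fear_frac,
       measures = c(test_pct = test,
                    control_pct = pctmax(base$probes$cond, model)[["CeM"]]))
}

#' Evaluate one experiment
#'
#' @param spec One element of \code{\link{experiment_registry}}.
#' @param base A \code{\link{baseline_assessment}}.
#' @param criteria A \code{\link{criteria_config}}.
#' @return List with `id`, `figure`, `pass`, `measures`.
#' @export
evaluate_experiment <- function(spec, base, criteria = criteria_config()) {
  r <- spec$run(base, criteria)
  list(id = spec$id, figure = spec$figure, description = spec$description,
       pass = isTRUE(r$pass), measures = r$measures)
}

#' Run the full experiment registry
#'
#' Evaluates every registered experiment against a shared baseline run.
#'
#' @param model A \code{\link{fear_circuit}} (default: the calibrated
#'   default).
#' @param cfg A \code{\link{sim_config}}.
#' @param criteria A \code{\link{criteria_config}}.
#' @param base Optional precomputed \code{\link{baseline_assessment}}.
#' @param ids Optional subset of experiment ids to run.
#' @return A `fear_registry_results` object: data frame of verdicts with
#'   per-experiment measures in `attr(, "details")`.
#' @examples
#' \donttest{
#' res <- run_registry(build_default_circuit())
#' print(res)
#' }
#' @export
run_registry <- function(model = build_default_circuit(),
                         cfg = sim_config(record_every = 2),
                         criteria = criteria_config(), base = NULL,
                         ids = NULL) {
  if (is.null(base)) base <- baseline_assessment(model, cfg, criteria)
  reg <- experiment_registry()
  if (!is.null(ids)) {
    miss <- setdiff(ids, vapply(reg, `[[`, "", "id"))
    if (length(miss)) stop("unknown experiment id(s): ",
                           paste(miss, collapse = ", "), call. = FALSE)
    reg <- Filter(function(e) e$id %in% ids, reg)
  }
  details <- lapply(reg, evaluate_experiment, base = base,
                    criteria = criteria)
  df <- data.frame(
    id = vapply(details, `[[`, "", "id"),
    figure = vapply(details, `[[`, "", "figure"),
    pass = vapply(details, `[[`, TRUE, "pass"))
  structure(df, details = details, baseline = base,
            class = c("fear_registry_results", "data.frame"))
}

#' @export
print.fear_registry_results <- function(x, ...) {
  cat(sprintf("<fear_registry_results> %d/%d experiments pass\n",
              sum(x$pass), nrow(x)))
  df <- as.data.frame(x)
  df$pass <- ifelse(df$pass, "pass", "FAIL")
  print(df, row.names = FALSE, right = FALSE)
  invisible(x)
}

#' @export
summary.fear_registry_results <- function(object, ...) {
  print(object)
  for (d in attr(object, "details")) {
    cat(sprintf("\n%s (%s): %s\n", d$id, d$figure,
                if (d$pass) "pass" else "FAIL"))
    print(round(unlist(d$measures), 2))
  }
  invisible(object)
}
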