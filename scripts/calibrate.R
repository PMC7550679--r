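#!/usr/bin/env Rscript
# Calibration tool for the default configuration: scores a circuit against
# the experiment registry and optionally polishes free parameters by
# deterministic coordinate descent (multiplicative steps), mirroring the
# incremental search used to derive the shipped defaults.  The printed
# anchors (LAp1 fan-out 7/5/3, BAcck weights 0.7, drive 100, M = 3x,
# 10-s trigger) are never touched.
#
# usage: Rscript scripts/calibrate.R [--polish] [--passes N] [--out FILE]
suppressMessages(library(fearsim))

args <- commandArgs(trailingOnly = TRUE)
polish <- "--polish" %in% args
passes <- if (length(i <- which(args == "--passes")))
  as.integer(args[i + 1]) else 2L
out <- if (length(i <- which(args == "--out"))) args[i + 1] else
  "default_circuit.yaml"

cfg <- sim_config(record_every = 5)
score <- function(m) {
  r <- try(run_registry(m, cfg), silent = TRUE)
  if (inherits(r, "try-error")) return(-1)
  sum(r$pass)
}

free_params <- function(model) {
  anchored <- c("w:LAp1->BAp1", "w:LAp1->BAp2", "w:LAp1->BAp5",
                "w:BAcck->BAp1", "w:BAcck->BAp2")
  setdiff(oat_parameters(model), anchored)
}

model <- build_default_circuit()
s0 <- score(model)
cat(sprintf("reference configuration: %d/25 registry experiments pass\n",
            s0))

if (polish) {
  best <- s0
  for (p in seq_len(passes)) {
    improved <- FALSE
    for (id in free_params(model)) {
      v <- fearsim:::oat_get(model, id)
      for (f in c(0.9, 0.95, 1.05, 1.1)) {
        cand <- try(fearsim:::oat_set(model, id, v * f), silent = TRUE)
        if (inherits(cand, "try-error")) next
        s <- score(cand)
        if (s > best) {
          model <- cand; best <- s; improved <- TRUE
          cat(sprintf("  %s x%.2f -> %.4g  (%d/25)\n", id, f, v * f, best))
          v <- fearsim:::oat_get(model, id)
        }
      }
    }
    cat(sprintf("pass %d: %d/25\n", p, best))
    if (!improved) break
  }
}

save_circuit(model, out)
cat("configuration written to", out, "\n")
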