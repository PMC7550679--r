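#!/usr/bin/env Rscript
# Command-line front end: simulate | experiments | classify | psp-probe |
# sensitivity | export-config.  Thin wrapper over the fearsim package.
suppressMessages({
  library(fearsim)
  library(optparse)
})

usage <- function() {
  cat("usage: fearsim.R <command> [options]\n",
      "commands:\n",
      "  simulate      run a stimulus protocol, write trace + manifest\n",
      "  experiments   run the 25-experiment registry, write verdicts\n",
      "  classify      fear/extinction/persistent unit taxonomy\n",
      "  psp-probe     synaptic-strength probe for one connection\n",
      "  sensitivity   one-factor-at-a-time scan (use --fast for CI)\n",
      "  export-config write the default circuit to a YAML file\n", sep = "")
  quit(status = 2)
}

args <- commandArgs(trailingOnly = TRUE)
if (length(args) < 1) usage()
cmd <- args[1]
rest <- args[-1]

common <- list(
  make_option("--circuit", type = "character", default = NULL,
              help = "circuit YAML (default: built-in calibrated circuit)"),
  make_option("--out", type = "character", default = "fearsim_out",
              help = "output directory [default %default]"),
  make_option("--dt", type = "double", default = 10,
              help = "integration step, ms [default %default]"),
  make_option("--seed", type = "integer", default = 1L,
              help = "seed (bookkeeping; dynamics are deterministic)"))

load_model <- function(opt) {
  if (is.null(opt$circuit)) build_default_circuit() else
    load_circuit(opt$circuit)
}
manifest <- function(opt, extra = list()) {
  c(list(command = paste(c(cmd, rest), collapse = " "),
         version = as.character(utils::packageVersion("fearsim")),
         dt_ms = opt$dt, seed = opt$seed,
         circuit = if (is.null(opt$circuit)) "<default>" else opt$circuit,
         timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")), extra)
}
emit <- function(opt, files, extra = list()) {
  dir.create(opt$out, showWarnings = FALSE, recursive = TRUE)
  jsonlite::write_json(manifest(opt, extra),
                       file.path(opt$out, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(files)
}

if (cmd == "simulate") {
  opts <- c(common, list(
    make_option("--protocol", type = "character", default = "full",
                help = "conditioning | extinction | reinstatement | full"),
    make_option("--freeze-plasticity", action = "store_true",
                default = FALSE, dest = "freeze"),
    make_option("--record-every", type = "integer", default = 5L)))
  opt <- parse_args(OptionParser(option_list = opts), rest)
  model <- load_model(opt)
  proto <- switch(opt$protocol,
    conditioning = conditioning_protocol(),
    extinction = extinction_protocol(),
    reinstatement = reinstatement_protocol(),
    full = chain_protocols(conditioning_protocol(), extinction_protocol(),
                           extinction_protocol(),
                           reinstatement_protocol()),
    stop("unknown protocol: ", opt$protocol))
  cfg <- sim_config(dt_ms = opt$dt, record_every = opt$`record-every`)
  tr <- run_protocol(model, proto, cfg, freeze_plasticity = opt$freeze)
  dir.create(opt$out, showWarnings = FALSE, recursive = TRUE)
  write_trace(tr, file.path(opt$out, "trace.csv"))
  emit(opt, "trace.csv", list(protocol = opt$protocol,
                              freeze_plasticity = opt$freeze))
  cat("wrote", file.path(opt$out, "trace.csv"), "\n")

} else if (cmd == "experiments") {
  opts <- c(common, list(
    make_option("--ids", type = "character", default = NULL,
                help = "comma-separated experiment ids (default: all 25)")))
  opt <- parse_args(OptionParser(option_list = opts), rest)
  model <- load_model(opt)
  ids <- if (is.null(opt$ids)) NULL else strsplit(opt$ids, ",")[[1]]
  res <- run_registry(model, sim_config(dt_ms = opt$dt, record_every = 5),
                      ids = ids)
  print(res)
  dir.create(opt$out, showWarnings = FALSE, recursive = TRUE)
  utils::write.csv(as.data.frame(res),
                   file.path(opt$out, "verdicts.csv"), row.names = FALSE)
  jsonlite::write_json(
    lapply(attr(res, "details"), function(d)
      list(id = d$id, figure = d$figure, pass = d$pass,
           measures = as.list(d$measures))),
    file.path(opt$out, "verdicts.json"), auto_unbox = TRUE, pretty = TRUE,
    digits = NA)
  emit(opt, c("verdicts.csv", "verdicts.json"))
  if (!all(res$pass)) quit(status = 1)

} else if (cmd == "classify") {
  opt <- parse_args(OptionParser(option_list = common), rest)
  model <- load_model(opt)
  base <- baseline_assessment(model, sim_config(dt_ms = opt$dt,
                                                record_every = 5))
  print(base)
  dir.create(opt$out, showWarnings = FALSE, recursive = TRUE)
  utils::write.csv(
    data.frame(unit = names(base$classification),
               class = unname(base$classification)),
    file.path(opt$out, "classification.csv"), row.names = FALSE)
  emit(opt, "classification.csv")

} else if (cmd == "psp-probe") {
  opts <- c(common, list(
    make_option("--pre", type = "character"),
    make_option("--post", type = "character")))
  opt <- parse_args(OptionParser(option_list = opts), rest)
  model <- load_model(opt)
  r <- psp_probe(model, opt$pre, opt$post,
                 cfg = sim_config(dt_ms = opt$dt))
  cat(sprintf("%s->%s: PSP %.3f mV at drive %.3f (weight %.4g)\n",
              opt$pre, opt$post, r$psp_mv, r$drive, r$weight))

} else if (cmd == "sensitivity") {
  opts <- c(common, list(
    make_option("--fast", action = "store_true", default = FALSE),
    make_option("--step", type = "double", default = 0.05),
    make_option("--cap", type = "double", default = 10)))
  opt <- parse_args(OptionParser(option_list = opts), rest)
  model <- load_model(opt)
  rep <- oat_scan(model, step_frac = opt$step, cap_frac = opt$cap,
                  fast = opt$fast, verbose = TRUE)
  dir.create(opt$out, showWarnings = FALSE, recursive = TRUE)
  utils::write.csv(as.data.frame(rep),
                   file.path(opt$out, "sensitivity.csv"),
                   row.names = FALSE)
  emit(opt, "sensitivity.csv", list(fast = opt$fast, step = opt$step))
  print(rep)

} else if (cmd == "export-config") {
  opt <- parse_args(OptionParser(option_list = common), rest)
  dir.create(opt$out, showWarnings = FALSE, recursive = TRUE)
  f <- file.path(opt$out, "default_circuit.yaml")
  save_circuit(build_default_circuit(), f)
  emit(opt, "default_circuit.yaml")
  cat("wrote", f, "\n")

} else usage()
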