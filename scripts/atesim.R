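#!/usr/bin/env Rscript
# Command-line front end over the nnaipw package.
#
#   Rscript scripts/atesim.R simulate  --config scen.yaml --out-dir out [--seed S]
#   Rscript scripts/atesim.R fit       --data out/sim --family jNN --widths 32,32,32
#                                      --cl1 0.1 --cl1tg 0.7 --out-dir out [--seed S]
#   Rscript scripts/atesim.R estimate  --data out/sim --net out/network.json --out-dir out
#   Rscript scripts/atesim.R experiment --config scen.yaml --reps 10 --out-dir out [--seed S]
#   Rscript scripts/atesim.R summarize --records out/records --true-beta 1 --out-dir out
#
# `--data` is the dataset file stem written by `simulate` (CSV + sidecars).

suppressPackageStartupMessages(library(nnaipw))

args <- commandArgs(trailingOnly = TRUE)
if (length(args) < 1) stop("usage: atesim.R <simulate|fit|estimate|experiment|summarize> [flags]")
cmd <- args[1]
flags <- args[-1]
get_flag <- function(name, default = NULL) {
  i <- which(flags == name)
  if (length(i) == 1 && i < length(flags)) flags[i + 1] else default
}
seed <- as.integer(get_flag("--seed", "1"))
out_dir <- get_flag("--out-dir", ".")
dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)

load_scenario <- function() {
  cfg_path <- get_flag("--config")
  if (is.null(cfg_path)) scenario_config(seed = seed)
  else read_scenario_config(cfg_path)
}

if (cmd == "simulate") {
  scen <- load_scenario()
  sim <- simulate_scenario(scen)
  stem <- file.path(out_dir, "sim")
  write_sim_dataset(sim, stem)
  cat("dataset written to", paste0(stem, ".csv"), "with sidecars\n")

} else if (cmd == "fit") {
  stem <- get_flag("--data")
  sim <- read_sim_dataset(stem)
  widths <- as.integer(strsplit(get_flag("--widths", "32,32,32"), ",")[[1]])
  family <- get_flag("--family", "jNN")
  p <- ncol(sim$w)
  net <- if (family == "jNN") joint_network(p, widths) else double_network(p, widths)
  fit <- fit_network(net, sim$w, sim$a, sim$y,
                     loss_config(cl1 = as.numeric(get_flag("--cl1", "0")),
                                 cl1tg = as.numeric(get_flag("--cl1tg", "0"))),
                     optimizer_config(epochs = as.integer(get_flag("--epochs", "200")),
                                      seed = seed))
  write_network(fit$net, file.path(out_dir, "network.json"))
  write_training_log(fit, file.path(out_dir, "training_log.csv"))
  preds <- fit$predictions
  utils::write.csv(data.frame(ghat = preds$ghat, qhat1 = preds$qhat1,
                              qhat0 = preds$qhat0),
                   file.path(out_dir, "predictions.csv"), row.names = FALSE)
  cat("fit written to", out_dir, "\n")

} else if (cmd == "estimate") {
  stem <- get_flag("--data")
  sim <- read_sim_dataset(stem)
  pred_path <- get_flag("--predictions",
                        file.path(out_dir, "predictions.csv"))
  pr <- utils::read.csv(pred_path)
  preds <- nuisance_predictions(pr$ghat, pr$qhat1, pr$qhat0)
  ests <- lapply(c("aipw", "naipw", "ipw", "nipw", "plug_in"),
                 asymptotic_ci, y = sim$y, a = sim$a, preds = preds)
  write_estimates(ests, file.path(out_dir, "estimates.csv"), seed = seed)
  for (e in ests) print(e)

} else if (cmd == "experiment") {
  scen <- load_scenario()
  settings <- default_grid(scen$p)
  reps <- as.integer(get_flag("--reps", "100"))
  recs <- run_grid(list(scenario = scen), settings, replications = reps,
                   master_seed = seed,
                   out_dir = file.path(out_dir, "records"))
  cat(length(recs), "replication records under",
      file.path(out_dir, "records"), "\n")

} else if (cmd == "summarize") {
  rec_dir <- get_flag("--records")
  paths <- list.files(rec_dir, pattern = "\\.json$", full.names = TRUE)
  recs <- lapply(paths, nnaipw:::read_record)
  tab <- summarize_records(recs,
                           true_beta = as.numeric(get_flag("--true-beta", "1")),
                           seed = seed)
  utils::write.csv(tab, file.path(out_dir, "summary.csv"), row.names = FALSE)
  cat("summary for", nrow(tab), "cells written to",
      file.path(out_dir, "summary.csv"), "\n")

} else {
  stop("unknown subcommand: ", cmd)
}
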