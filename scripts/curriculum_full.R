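#!/usr/bin/env Rscript
# Reduced-scale curriculum training run: three wind stages (0-2, 0-4,
# 0-6 m/s) at 2e5 simulated seconds each, followed by evaluation of the
# final agent on u = 0..6 m/s. This is the slow tier of the validation
# suite: expect several hours on one CPU. Results (training log,
# checkpoints, per-wind evaluation) are written under --out.
#
#   Rscript scripts/curriculum_full.R --seed 1 --out results/curriculum

suppressPackageStartupMessages({
  library(optparse)
  library(thermalsoar)
})

opts <- parse_args(OptionParser(option_list = list(
  make_option("--seed", type = "integer", default = 1L),
  make_option("--out", type = "character", default = "results/curriculum"),
  make_option("--budget", type = "double", default = 2e5,
              help = "simulated seconds per stage [default %default]")
)))
dir.create(opts$out, recursive = TRUE, showWarnings = FALSE)

sched <- curriculum_schedule(u_max = c(2, 4, 6), budget = opts$budget)
message("training: 3 stages x ", opts$budget, " simulated s")
res <- curriculum_train(sched, episode_config(), seed = opts$seed,
                        checkpoint_every = opts$budget / 2, verbose = TRUE)
readr::write_csv(res$log, file.path(opts$out, "training_log.csv"))
for (i in seq_along(res$checkpoints)) {
  save_checkpoint(res$checkpoints[[i]],
                  file.path(opts$out, sprintf("checkpoint_%02d.rds", i)))
}

message("evaluating at u = 0..6 m/s, 20 seeded runs each")
evals <- dplyr::bind_rows(lapply(0:6, function(u) {
  tibble::as_tibble(evaluate_agent(res$agent, u = u, n_runs = 20,
                                   seed = opts$seed))
}))
readr::write_csv(evals, file.path(opts$out, "evaluation.csv"))
summ <- evals |>
  dplyr::group_by(u) |>
  dplyr::summarise(mean_eta = mean(eta), mean_vz = mean(mean_vz),
                   frac_in_thermal = mean(frac_in_thermal),
                   crash_rate = mean(status == "crash"))
print(summ, n = Inf)
message("mean eta > 0 at every u: ", all(summ$mean_eta > 0))
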