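# Shared settings for the numbered analysis scripts. Each script sources
# this file, so every stage re-derives the same deterministic data.

library(v1sync)

MASTER_SEED <- 2026
RESULTS_DIR <- file.path("results")
dir.create(RESULTS_DIR, recursive = TRUE, showWarnings = FALSE)

# baseline condition: mixed population, weak stimuli recruit few neurons
baseline_config <- pipeline_config(seed = MASTER_SEED)

# hypersensitive condition: weak and strong stimuli recruit similarly
# (response probability to the small stimulus raised to the large-stimulus
# level) and spontaneous population-wide events are present
hyper_p <- rbind(c(0, 0.6), c(0.5, 0), c(0.5, 0.5), c(0, 0))
hyper_config <- pipeline_config(
  seed = MASTER_SEED,
  p_resp_by_type = hyper_p,
  type_fractions = c(0.10, 0.10, 0.45, 0.35),
  sync_rate = 0.05,
  sync_recruit = 0.6)

conditions <- list(baseline = baseline_config,
                   hypersensitive = hyper_config)

write_tsv <- function(x, name) {
  utils::write.table(x, file.path(RESULTS_DIR, name), sep = "\t",
                     row.names = FALSE, quote = FALSE)
  message("wrote results/", name)
}
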