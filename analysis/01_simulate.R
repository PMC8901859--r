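# Stage 1: simulate both conditions end to end and persist the per-neuron
# response table that every later stage builds on.

source(file.path("analysis", "00_config.R"))

rows <- lapply(names(conditions), function(cond) {
  res <- run_pipeline(conditions[[cond]])
  rt <- res$responses$table
  data.frame(condition = cond,
             neuron = seq_len(nrow(rt$prob)),
             x_um = res$population$positions[, 1],
             y_um = res$population$positions[, 2],
             type = res$responses$types,
             p_S1 = rt$prob[, "S1"],
             p_S4 = rt$prob[, "S4"])
})
write_tsv(do.call(rbind, rows), "01_responses_by_neuron.tsv")
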