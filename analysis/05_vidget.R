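# Stage 5: behavioral (piezo) readout: per-trial movement scores, response
# delays, and the piecewise slopes of the cumulative movement signal.

source(file.path("analysis", "00_config.R"))

rows <- lapply(names(conditions), function(cond) {
  res <- run_pipeline(conditions[[cond]])
  v <- res$vidget
  data.frame(condition = cond,
             trial = seq_len(nrow(v$score)),
             stimulus = v$score$stimulus,
             score = v$score$score,
             delay_s = v$delay$delay_s,
             k_baseline = v$slopes$k_baseline,
             k_stimulus = v$slopes$k_stimulus)
})
write_tsv(do.call(rbind, rows), "05_vidget.tsv")
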