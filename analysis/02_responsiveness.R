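# Stage 2: percent responsive per stimulus and the normalized adaptation
# index (NAI = percent responsive to the small stimulus / percent
# responsive to the large one) for both conditions.

source(file.path("analysis", "00_config.R"))

rows <- lapply(names(conditions), function(cond) {
  res <- run_pipeline(conditions[[cond]])
  rt <- res$responses$table
  data.frame(condition = cond,
             percent_S1 = rt$percent[["S1"]],
             percent_S4 = rt$percent[["S4"]],
             nai = res$responses$nai,
             mean_amp_S1 = mean(res$responses$amplitude[, "S1"],
                                na.rm = TRUE),
             mean_amp_S4 = mean(res$responses$amplitude[, "S4"],
                                na.rm = TRUE))
})
write_tsv(do.call(rbind, rows), "02_responsiveness.tsv")
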