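# Stage 3: n-order coincident firing against the count-preserving shuffle
# null, aggregated into the low (1-10 neurons) and high (11+) bands.

source(file.path("analysis", "00_config.R"))

rows <- lapply(names(conditions), function(cond) {
  res <- run_pipeline(conditions[[cond]])
  s <- res$summary$sync_ranges
  data.frame(condition = cond,
             band = names(s$observed),
             observed = unlist(s$observed),
             null_mean = unlist(s$null_mean),
             null_upper95 = unlist(s$null_upper),
             exceeds_null = unlist(s$observed) > unlist(s$null_upper))
})
write_tsv(do.call(rbind, rows), "03_synchrony_bands.tsv")
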