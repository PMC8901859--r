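# Stage 4: pairwise correlation versus cortical distance, and the random
# k-subgroup nearest-neighbor dispersion of each functional type.

source(file.path("analysis", "00_config.R"))

dist_rows <- lapply(names(conditions), function(cond) {
  res <- run_pipeline(conditions[[cond]])
  cbind(condition = cond, res$pairwise$by_bin)
})
write_tsv(do.call(rbind, dist_rows), "04_distance_correlation.tsv")

nnd_rows <- lapply(names(conditions), function(cond) {
  res <- run_pipeline(conditions[[cond]])
  data.frame(condition = cond,
             type = names(res$nnd$dispersion),
             dispersion_um = as.numeric(res$nnd$dispersion))
})
write_tsv(do.call(rbind, nnd_rows), "04_nnd_dispersion.tsv")
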