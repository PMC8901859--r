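# Stage 6: dendritic morphometrics of randomly generated reconstructions,
# normalized so the baseline condition's mean is 1.00.

source(file.path("analysis", "00_config.R"))

tabs <- lapply(names(conditions), function(cond) {
  res <- run_pipeline(conditions[[cond]])
  cbind(condition = cond, tree = seq_len(nrow(res$morpho$table)),
        res$morpho$table)
})
raw <- do.call(rbind, tabs)
write_tsv(raw, "06_morphometrics.tsv")

ref <- raw[raw$condition == "baseline",
           !(names(raw) %in% c("condition", "tree"))]
norm <- lapply(tabs, function(tb) {
  cbind(tb[, c("condition", "tree")],
        normalize_to_reference(tb[, !(names(tb) %in%
                                        c("condition", "tree"))], ref))
})
write_tsv(do.call(rbind, norm), "06_morphometrics_normalized.tsv")
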