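#' Default pipeline configuration
#'
#' All tunable parameters of the end-to-end synthetic pipeline with their
#' defaults: a 50-neuron baseline population, the 5-repeat S1/S4
#' protocol, OGB-1-like transients, and the standard analysis settings.
#'
#' @param seed master seed; every random stage consumes a derived sub-seed.
#' @param ... overrides for any default entry.
#' @return named list.
#' @export
pipeline_config <- function(seed = 1, ...) {
  cfg <- list(
    seed = seed,
    n_neurons = 50,
    fov_um = 517.77,
    type_fractions = c(0.40, 0.10, 0.10, 0.40),
    p_resp_by_type = default_p_resp(),
    f = 20.4,
    tau_decay = 1.0,
    amp = 0.12,
    noise_sd = 0.01,
    bg_rate = 0.02,
    sync_rate = 0,
    sync_recruit = 0.5,
    k_sd = 2.5,
    sync_N = 30,
    n_shuffles = 1000,
    n_subsamples = 5,
    nnd_k = 5,
    bin_um = 50,
    vidget_evoked_amp = 0.5,
    vidget_latency_s = 0.1,
    n_trees = 6,
    out_dir = NULL
  )
  over <- list(...)
  cfg[names(over)] <- over
  cfg
}

# deterministic sub-seed for stage `i` of a master seed (kept below 2^31)
sub_seed <- function(seed, i) (as.integer(seed) * 1000L + i) %% 2147483647L

#' Run the full synthetic analysis pipeline
#'
#' Simulates a population under the stimulus protocol, renders and analyzes
#' the calcium traces (transients, responsiveness, NAI, amplitudes), runs
#' the n-order synchrony analysis with its shuffle null, the pairwise
#' distance-binned correlation, the k-subgroup NND dispersion, the vidget
#' behavioral scoring, and the dendritic morphometrics, and returns one
#' machine-readable summary. Deterministic for a fixed seed.
#'
#' @param config list from [pipeline_config()].
#' @return nested list of stage results (`protocol`, `responses`, `sync`,
#'   `pairwise`, `nnd`, `vidget`, `morpho`, and the stage seeds). When
#'   `config$out_dir` is set, per-stage TSVs and `summary.json` are written
#'   there.
#' @export
run_pipeline <- function(config = pipeline_config()) {
  stage <- function(i) sub_seed(config$seed, i)

  protocol <- stim_protocol(seed = stage(1))
  pop <- make_population(config$n_neurons, fov_um = config$fov_um,
                         type_fractions = config$type_fractions,
                         p_resp_by_type = config$p_resp_by_type,
                         seed = stage(2))
  simc <- sim_config(f = config$f, T_s = protocol$total_s,
                     tau_decay = config$tau_decay, amp = config$amp,
                     noise_sd = config$noise_sd, bg_rate = config$bg_rate,
                     sync_rate = config$sync_rate,
                     sync_recruit = config$sync_recruit)
  gt <- simulate_activity(pop, protocol, simc, seed = stage(3))
  traces <- render_traces(gt, simc, pop = pop, seed = stage(4))
  traces <- compute_dff(traces)
  events <- detect_transients(traces, k_sd = config$k_sd)

  rt <- classify_responsive(events, protocol)
  amp <- response_amplitude(traces, events, protocol)
  nai <- compute_nai(rt)
  types <- assign_types(rt)

  sync <- sync_analysis(events, N = config$sync_N,
                        n_subsamples = config$n_subsamples,
                        n_shuffles = config$n_shuffles, seed = stage(5))
  psync <- pairwise_sync_counts(events, types)

  act <- preprocess_trace(traces$dff, f = traces$f)
  dcorr <- distance_binned_correlation(coefficient_matrix(act),
                                       pop$positions, bin_um = config$bin_um)

  nnd <- knn_subgroup_nnd(pop$positions, types, k = config$nnd_k,
                          seed = stage(6))

  piezo <- simulate_piezo(protocol, evoked_amp = config$vidget_evoked_amp,
                          latency_s = config$vidget_latency_s,
                          seed = stage(7))
  vscore <- vidget_score(piezo)
  vdelay <- vidget_delay(piezo)
  vslopes <- cumulative_fit(piezo)

  trees <- lapply(seq_len(config$n_trees), function(i)
    make_morphology(seed = sub_seed(config$seed, 100 + i)))
  mtab <- morpho_table(trees)
  mnorm <- normalize_to_reference(mtab, mtab)

  summary <- list(
    seed = config$seed,
    percent_responsive = as.list(rt$percent),
    nai = nai,
    mean_amplitude = as.list(colMeans(amp, na.rm = TRUE)),
    vidget = list(mean_score_by_stimulus =
                    as.list(tapply(vscore$score, vscore$stimulus, mean)),
                  mean_delay_s = mean(vdelay$delay_s, na.rm = TRUE),
                  k_baseline = mean(vslopes$k_baseline),
                  k_stimulus = mean(vslopes$k_stimulus)),
    sync_ranges = list(observed = as.list(sync$observed_ranges),
                       null_mean = as.list(sync$null_range_mean),
                       null_upper = as.list(sync$null_range_upper)),
    pairwise_sync_mean = psync$overall_mean,
    distance_correlation =
      stats::setNames(as.list(dcorr$by_bin$mean_coefficient),
                      paste0("bin_", dcorr$by_bin$bin_lo)),
    nnd_dispersion = as.list(nnd$dispersion),
    morpho_mean = as.list(colMeans(mtab))
  )

  if (!is.null(config$out_dir)) {
    dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
    wt <- function(x, f) utils::write.table(
      x, file.path(config$out_dir, f), sep = "\t", row.names = FALSE,
      quote = FALSE)
    wt(data.frame(neuron = seq_len(pop$n), pop$positions, type = types,
                  rt$prob), "responses.tsv")
    wt(vscore, "vidget_scores.tsv")
    wt(vslopes, "vidget_slopes.tsv")
    wt(dcorr$by_bin, "distance_correlation.tsv")
    wt(nnd$per_neuron, "nnd.tsv")
    wt(mtab, "morphometrics.tsv")
    jsonlite::write_json(summary, file.path(config$out_dir, "summary.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }

  invisible(list(protocol = protocol, population = pop, ground_truth = gt,
                 events = events,
                 responses = list(table = rt, amplitude = amp, nai = nai,
                                  types = types),
                 sync = sync, pairwise_sync = psync,
                 pairwise = dcorr, nnd = nnd,
                 vidget = list(score = vscore, delay = vdelay,
                               slopes = vslopes),
                 morpho = list(table = mtab, normalized = mnorm),
                 summary = summary))
}
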