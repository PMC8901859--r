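test_that("generators are deterministic under a fixed seed", {
  p1 <- make_population(40, seed = 11)
  p2 <- make_population(40, seed = 11)
  expect_identical(p1, p2)

  prot <- stim_protocol(seed = 5)
  cfg <- sim_config(T_s = prot$total_s)
  g1 <- simulate_activity(p1, prot, cfg, seed = 3)
  g2 <- simulate_activity(p2, prot, cfg, seed = 3)
  expect_identical(g1$spike_frames, g2$spike_frames)

  t1 <- render_traces(g1, cfg, seed = 9)
  t2 <- render_traces(g2, cfg, seed = 9)
  expect_identical(t1$F, t2$F)

  z1 <- simulate_piezo(prot, seed = 2)
  z2 <- simulate_piezo(prot, seed = 2)
  expect_identical(z1$voltage, z2$voltage)
})

test_that("population respects field-of-view bounds and type fractions", {
  pop <- make_population(500, fov_um = 517.77, seed = 4)
  expect_true(all(pop$positions >= 0 & pop$positions <= 517.77))
  expect_error(make_population(10, type_fractions = c(0.5, 0.5, 0.5, 0.5)),
               "sum to 1")
  # multinomial sanity on fractions
  pop2 <- make_population(4000, type_fractions = c(0.25, 0.25, 0.25, 0.25),
                          seed = 8)
  frac <- tabulate(pop2$type, 4) / 4000
  expect_true(all(abs(frac - 0.25) < 3 * sqrt(0.25 * 0.75 / 4000)))

  clus <- make_population(300, clustering = list(n_clusters = 4, sd_um = 20),
                          seed = 5)
  expect_true(all(clus$positions >= 0 & clus$positions <= 517.77))
})

test_that("uniform layout matches the Poisson-process nearest-neighbor law", {
  # complete spatial randomness: E[NND] = 0.5 / sqrt(intensity)
  pop <- make_population(10000, seed = 21)
  lambda <- 10000 / 517.77^2
  expected <- 0.5 / sqrt(lambda)
  nnd <- grid_nnd(pop$positions, cell = 3 * expected)
  expect_lt(abs(mean(nnd) - expected) / expected, 0.02)
})

test_that("evoked responses follow the per-trial Bernoulli model", {
  prot <- stim_protocol(seed = 1)
  cfg <- sim_config(T_s = prot$total_s, bg_rate = 0)
  # p_resp = 1: every trial window must contain a spike
  pm <- matrix(0, 4, 2); pm[3, ] <- c(1, 1)
  pop <- make_population(20, type_fractions = c(0, 0, 1, 0),
                         p_resp_by_type = pm, seed = 2)
  gt <- simulate_activity(pop, prot, cfg, seed = 3)
  for (j in seq_len(nrow(prot$trials))) {
    w <- range(v1sync:::frames_in_window(prot$trials$onset_s[j],
                                         prot$trials$onset_s[j] + 2,
                                         cfg$f, cfg$n_frames))
    hit <- vapply(gt$spike_frames, function(s)
      any(s >= w[1] & s <= w[2]), logical(1))
    expect_true(all(hit))
  }

  # p_resp = 0.35: empirical rate within binomial CI
  pm2 <- matrix(0, 4, 2); pm2[3, ] <- c(0.35, 0.35)
  pop2 <- make_population(400, type_fractions = c(0, 0, 1, 0),
                          p_resp_by_type = pm2, seed = 4)
  gt2 <- simulate_activity(pop2, prot, cfg, seed = 5)
  phat <- mean(gt2$evoked)
  n_bern <- length(gt2$evoked)
  expect_lt(abs(phat - 0.35), 3 * sqrt(0.35 * 0.65 / n_bern))
})

test_that("protocol validation rejects recordings shorter than the protocol", {
  prot <- stim_protocol(seed = 1)
  expect_error(sim_config(T_s = 10) |>
                 (\(cfg) simulate_activity(make_population(5, seed = 1),
                                           prot, cfg))(),
               "beyond the recording")
})

test_that("rendered traces follow the exponential-kernel model", {
  cfg <- sim_config(T_s = 10, noise_sd = 0, bg_rate = 0)
  gt <- make_gt(list(integer(0)), cfg)
  tr <- render_traces(gt, cfg)
  expect_true(all(tr$F == cfg$F0))

  cfg2 <- sim_config(T_s = 60, noise_sd = 0, bg_rate = 0)
  gt1 <- make_gt(list(500L), cfg2)
  tr1 <- compute_dff(render_traces(gt1, cfg2))
  expect_equal(max(tr1$dff), cfg2$amp, tolerance = 1e-6)
  expect_equal(which.max(tr1$dff[, 1]), 500L)
})

test_that("downstream detector has full recall at 5x-noise amplitude", {
  cfg <- sim_config(T_s = 200, noise_sd = 0.01, amp = 0.05, bg_rate = 0)
  set.seed(31)
  spikes <- sort(sample(seq(20, cfg$n_frames - 40), 100))
  spikes <- spikes[c(TRUE, diff(spikes) > 3 * cfg$tau_decay * cfg$f)]
  gt <- make_gt(list(spikes), cfg)
  tr <- compute_dff(render_traces(gt, cfg, seed = 32))
  ev <- detect_transients(tr)
  det <- which(ev$B[1, ] == 1)
  # noise can shift the apparent peak by up to one minimum-separation
  # window (0.25 s = 5 frames) at this signal-to-noise ratio
  hit <- vapply(spikes, function(s) any(abs(det - s) <= 5), logical(1))
  expect_true(all(hit))
})

test_that("movies round-trip through rendering, extraction and 16-bit TIFF", {
  cfg <- sim_config(T_s = 2, noise_sd = 0, bg_rate = 0, F0 = 100)
  gt <- make_gt(list(10L, 25L), cfg)
  tr <- render_traces(gt, cfg)
  tr$F <- round(tr$F)  # integer gray values survive 16-bit quantization
  rois <- make_roiset(rbind(c(10, 10), c(25, 25)), radius_px = 4,
                      dims = c(40, 40))
  mov <- render_movie(tr, rois, background = 7)
  back <- extract_roi_traces(mov, rois, f = cfg$f)
  expect_equal(back$F, tr$F, ignore_attr = TRUE)

  # off-ROI pixels hold only background
  inroi <- rois[[1]] | rois[[2]]
  expect_true(all(mov[, , 1][!inroi] == 7))

  path <- tempfile(fileext = ".tif")
  write_movie_tiff(mov, path)
  mov2 <- read_movie_tiff(path)
  expect_equal(mov2, mov, ignore_attr = TRUE)
})

test_that("piezo simulation is flat without a response and lawful with one", {
  prot <- stim_protocol(repeats = 2, seed = 6)
  quiet <- simulate_piezo(prot, evoked_amp = 0, noise_sd = 0.01, seed = 7)
  sc0 <- vidget_score(quiet)$score
  # statistically flat: stimulus-window scores match baseline-window scores
  base <- piezo_preprocess(quiet)
  expect_lt(mean(sc0), mean(base$rect) + 3 * sd(base$rect))

  # noiseless latency: first suprathreshold sample at onset + latency
  clean <- simulate_piezo(prot, evoked_amp = 1, latency_s = 0.1,
                          noise_sd = 0)
  i0 <- which(clean$voltage > 2 * 1.001)[1]
  expect_equal(clean$time_s[i0], prot$trials$onset_s[1] + 0.1,
               tolerance = 2e-3)

  # larger deflection, strictly larger score
  s1 <- mean(vidget_score(simulate_piezo(prot, evoked_amp = 0.5,
                                         noise_sd = 0.01, seed = 8))$score)
  s2 <- mean(vidget_score(simulate_piezo(prot, evoked_amp = 1.0,
                                         noise_sd = 0.01, seed = 8))$score)
  expect_gt(s2, s1)
})

test_that("random morphologies are valid trees with controllable branching", {
  unbranched <- make_morphology(n_primary = 3, branch_prob = 0, seed = 1)
  m <- branch_metrics(unbranched)
  expect_equal(m$n_nodes, 0)
  expect_equal(m$n_ends, 3)
  expect_equal(m$n_primary, 3)

  t1 <- make_morphology(seed = 42)
  t2 <- make_morphology(seed = 42)
  f1 <- tempfile(); f2 <- tempfile()
  write_swc(t1, f1); write_swc(t2, f2)
  expect_identical(readLines(f1), readLines(f2))

  nodes_at <- function(bp) mean(vapply(1:60, function(s)
    branch_metrics(make_morphology(branch_prob = bp, seed = s))$n_nodes,
    numeric(1)))
  expect_gt(nodes_at(0.5), nodes_at(0.1))
})
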