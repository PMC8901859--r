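test_that("ROI extraction averages mask pixels", {
  mov <- array(3, c(8, 8, 5))
  rois <- list(matrix(TRUE, 8, 8))
  expect_true(all(extract_roi_traces(mov, rois, f = 10)$F == 3))

  # checkerboard mask over half-0 / half-2v frame averages to v
  frame <- matrix(0, 8, 8)
  frame[, 5:8] <- 2 * 7
  mov2 <- array(rep(frame, 4), c(8, 8, 4))
  mask <- matrix(FALSE, 8, 8)
  mask[, c(1:2, 5:6)] <- TRUE
  expect_true(all(extract_roi_traces(mov2, list(mask), f = 10)$F == 7))

  expect_error(extract_roi_traces(mov, list(matrix(FALSE, 8, 8)), f = 10),
               "empty mask")
})

test_that("dF/F0 is zero on constant traces and exact on steps", {
  ts <- trace_set(matrix(100, 50, 2), f = 10)
  expect_true(all(compute_dff(ts)$dff == 0))

  F <- matrix(100, 60, 1)
  F[40, 1] <- 110
  d <- compute_dff(trace_set(F, f = 10))
  expect_equal(d$dff[40, 1], 0.1)  # (110 - 100) / 100

  expect_error(compute_dff(trace_set(matrix(-1, 10, 1), f = 10)),
               "nonpositive")
})

test_that("prestim-mean baseline re-references each stimulus epoch", {
  prot <- stim_protocol(repeats = 1, randomize = FALSE, pre_s = 3,
                        isi_s = 5)
  f <- 10
  Tn <- ceiling(prot$total_s * f)
  F <- matrix(200, Tn, 1)  # elevated global level
  on <- prot$trials$onset_s[1]
  pre <- v1sync:::frames_in_window(on - 1, on, f, Tn)
  F[pre, 1] <- 100  # the 1-s prestimulus window defines the local baseline
  win <- v1sync:::frames_in_window(on, on + 2, f, Tn)
  F[win[1], 1] <- 150
  d <- compute_dff(trace_set(F, f = f), protocol = prot,
                   baseline_mode = "prestim-mean")
  expect_equal(d$dff[win[1], 1], 0.5)  # (150 - 100) / 100
})

test_that("transient detection thresholds at k_sd baseline SDs", {
  cfg <- sim_config(T_s = 30, noise_sd = 0.01, bg_rate = 0)
  # a 5-sigma kernel transient is kept, a 2-sigma one rejected
  mk <- function(amp, seed) {
    c2 <- sim_config(T_s = 30, noise_sd = 0.01, bg_rate = 0, amp = amp)
    compute_dff(render_traces(make_gt(list(300L), c2), c2, seed = seed))
  }
  ev5 <- detect_transients(mk(0.05, 1))
  det5 <- which(ev5$B[1, ] == 1)
  expect_length(det5, 1)
  expect_lte(abs(det5 - 300L), 5)
  ev2 <- detect_transients(mk(0.02, 1))
  expect_equal(sum(ev2$B), 0)

  expect_error(detect_transients(compute_dff(trace_set(matrix(100, 50, 1),
                                                       f = 10))),
               "zero baseline variance")
})

test_that("detection has high precision on long noisy recordings", {
  cfg <- sim_config(T_s = 1000, noise_sd = 0.01, amp = 0.06, bg_rate = 0)
  set.seed(77)
  spikes <- sort(sample(seq(30, cfg$n_frames - 60), 100))
  spikes <- spikes[c(TRUE, diff(spikes) > 4 * cfg$tau_decay * cfg$f)]
  gt <- make_gt(list(spikes), cfg)
  tr <- compute_dff(render_traces(gt, cfg, seed = 78))
  det <- which(detect_transients(tr)$B[1, ] == 1)
  tp <- vapply(det, function(p) any(abs(spikes - p) <= 5), logical(1))
  recall <- sum(vapply(spikes, function(s) any(abs(det - s) <= 5),
                       logical(1))) / length(spikes)
  expect_equal(recall, 1)
  expect_gte(mean(tp), 0.95)
})

test_that("detection is invariant to positive rescaling of F", {
  cfg <- sim_config(T_s = 60, noise_sd = 0.01, bg_rate = 0)
  gt <- make_gt(list(c(100L, 500L, 900L)), cfg)
  tr <- render_traces(gt, cfg, seed = 5)
  ev1 <- detect_transients(compute_dff(tr))
  tr2 <- tr
  tr2$F <- tr$F * 7.3
  ev2 <- detect_transients(compute_dff(tr2))
  expect_identical(ev1$B, ev2$B)
})

test_that("responsiveness is scored per trial window", {
  prot <- stim_protocol(repeats = 5, randomize = FALSE, pre_s = 5, seed = 1)
  f <- 20.4
  Tn <- ceiling(prot$total_s * f)
  s1_on <- prot$trials$onset_s[prot$trials$stimulus == "S1"]

  # events 1 s into S1 trials 1 and 3; one event mid-ISI
  fr <- function(t) v1sync:::frames_in_window(t, t + 0.05, f, Tn)[1]
  ev <- make_events(list(c(fr(s1_on[1] + 1), fr(s1_on[3] + 1)),
                         fr(s1_on[2] + 10)),  # ISI only
                    Tn, f = f)
  rt <- classify_responsive(ev, prot)
  expect_equal(as.numeric(rt$prob[1, "S1"]), 0.4)  # trials {1,3} of 5
  expect_equal(as.numeric(rt$prob[2, "S1"]), 0)
  expect_equal(as.numeric(rt$prob[2, "S4"]), 0)
})

test_that("percent responsive is invariant to neuron and trial ordering", {
  prot <- stim_protocol(seed = 2)
  cfg <- sim_config(T_s = prot$total_s, bg_rate = 0.05)
  pop <- make_population(30, seed = 3)
  gt <- simulate_activity(pop, prot, cfg, seed = 4)
  tr <- compute_dff(render_traces(gt, cfg, seed = 5))
  ev <- detect_transients(tr)
  rt <- classify_responsive(ev, prot)

  perm <- sample(ev$n_neurons)
  ev_p <- event_train_set(ev$B[perm, ], f = ev$f)
  expect_equal(classify_responsive(ev_p, prot)$percent, rt$percent)
})

test_that("response amplitude averages peak dF/F over responsive trials", {
  prot <- stim_protocol(repeats = 2, randomize = FALSE, pre_s = 5)
  f <- 10
  Tn <- ceiling(prot$total_s * f)
  on <- prot$trials$onset_s[prot$trials$stimulus == "S1"]
  dff <- matrix(0, Tn, 1)
  p1 <- v1sync:::frames_in_window(on[1], on[1] + 2, f, Tn)[5]
  p2 <- v1sync:::frames_in_window(on[2], on[2] + 2, f, Tn)[5]
  dff[p1, 1] <- 0.1
  dff[p2, 1] <- 0.3
  ts <- trace_set(matrix(100, Tn, 1), f = f)
  ts$dff <- dff
  ev <- make_events(list(c(p1, p2)), Tn, f = f)
  amp <- response_amplitude(ts, ev, prot)
  expect_equal(as.numeric(amp[1, "S1"]), 0.2)  # mean of 0.1 and 0.3
  expect_true(is.na(amp[1, "S4"]))
})

test_that("NAI is the weak/strong percentage ratio", {
  expect_equal(compute_nai(c(S1 = 15, S4 = 30)), 0.5)
  expect_equal(compute_nai(c(S1 = 22, S4 = 22)), 1.0)
  expect_error(compute_nai(c(S1 = 10, S4 = 0)), "undefined")
})
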