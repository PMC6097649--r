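# Feature extraction from current-clamp and voltage-clamp traces, checked
# against the synthetic generator's recorded ground truth.

gt_wt <- group_truth("WT-D1")

test_that("passive features are recovered exactly from noise-free traces", {
  # cell with the pooled wild-type means as true values
  truth <- draw_cell_truth(gt_wt, 1)
  truth$vr <- -81.51; truth$rn <- 198.24; truth$tau <- 16.52
  g <- generate_current_clamp(gt_wt, "subthreshold", 1, noise_sd = 0,
                              truth = truth)
  ps <- suppressWarnings(extract_passive(g$traces))
  expect_equal(ps$vr, truth$vr, tolerance = 1e-6)
  expect_equal(ps$rn, truth$rn, tolerance = 0.01)
  expect_equal(ps$tau, truth$tau, tolerance = 0.01)
  # the V-I relation is linear over these steps, so the fit keeps all points
  expect_true(all(ps$vi$used))
})

test_that("passive recovery degrades gracefully at recording noise levels", {
  errs <- sapply(1:12, function(s) {
    g <- generate_current_clamp(gt_wt, "subthreshold", s, noise_sd = 0.3)
    ps <- suppressWarnings(extract_passive(g$traces))
    c(abs(ps$rn - g$truth$rn) / g$truth$rn,
      abs(ps$tau - g$truth$tau) / g$truth$tau)
  })
  expect_lt(median(errs[1, ]), 0.03)
  expect_lt(median(errs[2, ]), 0.06)
})

test_that("rheobase is read off the first spiking ramp", {
  truth <- draw_cell_truth(gt_wt, 2)
  truth$rheobase <- 120
  g <- generate_current_clamp(gt_wt, "ramp", 2, noise_sd = 0, truth = truth)
  expect_equal(extract_rheobase(g$traces[[1]]), 120, tolerance = 0.02)
  # ramp annotation is required
  tr <- g$traces[[1]]; tr$stim$segments <- NULL
  expect_error(extract_rheobase(tr), "annotation")
})

test_that("a spike at the end of the first ramp reads 100 pA from it", {
  dt <- 0.33
  n <- round(10000 / dt)
  tt <- seq_len(n) * dt
  v <- rep(-80, n)
  i_spk <- which.min(abs(tt - 4999))   # just before the 5 s ramp end
  v[i_spk + 0:2] <- c(-40, 5, 35)
  v[i_spk + 3:6] <- c(0, -30, -50, -80)
  segs <- data.frame(onset = c(0, 5000), duration = c(5000, 5000),
                     amp0 = c(0, 0), amp1 = c(100, 200))
  tr <- msncable:::new_trace(v, dt, "mV", stim = list(segments = segs))
  expect_equal(extract_rheobase(tr), 100, tolerance = 0.01)
})

test_that("subthreshold cells are flagged rheobase-unavailable", {
  truth <- draw_cell_truth(gt_wt, 3)
  truth$rheobase <- 280           # beyond both ramps
  g <- generate_current_clamp(gt_wt, "ramp", 3, noise_sd = 0, truth = truth)
  expect_warning(rh <- extract_rheobase(g$traces[[1]]), "no spike")
  expect_true(is.na(rh))
})

test_that("AP features are measured on the second spike of the weakest qualifying step", {
  truth <- draw_cell_truth(gt_wt, 4)
  truth$ap_threshold <- -39; truth$ap_amplitude <- 77
  g <- generate_current_clamp(gt_wt, "ap_steps", 4, noise_sd = 0,
                              truth = truth)
  ap <- extract_ap_features(g$traces)
  expect_equal(ap$threshold, -39, tolerance = 1 / 39)   # within 1 mV
  expect_equal(ap$amplitude, 77, tolerance = 0.02)
  # stylized triangular spike: half-width = (rise + fall) / 2
  expect_equal(ap$half_width, (truth$rise + truth$fall) / 2,
               tolerance = 0.15)
  expect_equal(ap$rise, truth$rise, tolerance = 0.15)
  expect_equal(ap$fall, truth$fall, tolerance = 0.15)
})

test_that("steps without three spikes are flagged", {
  truth <- draw_cell_truth(gt_wt, 5)
  g <- generate_current_clamp(gt_wt, "ap_steps", 5, noise_sd = 0,
                              truth = truth)
  two_spk <- lapply(g$traces, function(tr) {
    # truncate each step so at most two spikes remain
    tr$values <- tr$values[seq_len(round(90 / tr$dt))]
    tr$stim$duration <- 40
    tr
  })
  expect_warning(ap <- extract_ap_features(two_spk), "3 action potentials")
  expect_true(is.na(ap$threshold))
})

test_that("firing rates equal generator spike counts over two-second steps", {
  truth <- draw_cell_truth(gt_wt, 6)
  g <- generate_current_clamp(gt_wt, "fi_steps", 6, noise_sd = 0.3,
                              truth = truth)
  fi <- fi_curve(g$traces)
  expect_equal(fi$rate, g$truth$fi$rate)
  expect_true(all(fi$rate[fi$current <= 0] == 0))
  expect_true(all(diff(fi$rate) >= 0))
})

test_that("EPSC detection honours the threshold and recovers single events", {
  dt <- 0.15
  kin <- gt_wt$epsc_kinetics
  mk_kernel <- function(amp) {
    tk <- seq(0, 60, by = dt)
    tp <- kin$tau_rise * kin$tau_decay / (kin$tau_decay - kin$tau_rise) *
      log(kin$tau_decay / kin$tau_rise)
    -amp * (exp(-tk / kin$tau_decay) - exp(-tk / kin$tau_rise)) /
      (exp(-tp / kin$tau_decay) - exp(-tp / kin$tau_rise))
  }
  x <- rep(0, 40000)
  x[10000 + seq_along(mk_kernel(12))] <- mk_kernel(12)
  ev <- detect_epscs(msncable:::new_trace(x, dt, "pA"))
  expect_identical(ev$stats$count, 1L)
  expect_equal(ev$stats$amplitude, 12, tolerance = 0.5 / 12)
  # all-below-threshold events yield nothing
  x4 <- rep(0, 40000)
  for (i0 in c(5000, 15000, 25000)) x4[i0 + seq_along(mk_kernel(4))] <-
      mk_kernel(4)
  ev4 <- detect_epscs(msncable:::new_trace(x4, dt, "pA"))
  expect_identical(ev4$stats$count, 0L)
})

test_that("detected frequency tracks planted Poisson trains within counting error", {
  truth <- draw_cell_truth(gt_wt, 7)
  truth$epsc_freq <- 2; truth$epsc_amp <- 13
  g <- generate_vclamp_epsc(gt_wt, duration = 120, seed = 7, truth = truth)
  ev <- detect_epscs(g$trace)
  expect_lt(abs(ev$stats$frequency - nrow(g$events) / 120),
            3 * sqrt(2 / 120))
  # kinetics of the averaged event resemble the generating kernel
  expect_equal(ev$stats$decay, gt_wt$epsc_kinetics$tau_decay, tolerance = 0.2)
})

test_that("pure noise produces almost no false events", {
  set.seed(41)
  tr <- msncable:::new_trace(rnorm(800000, 0, 2.5), 0.15, "pA")
  ev <- detect_epscs(tr)
  expect_lt(ev$stats$frequency, 0.05)
})
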