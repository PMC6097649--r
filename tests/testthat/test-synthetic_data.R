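# Seeded synthetic-data generators: determinism, closed-form subthreshold
# behaviour, and ground-truth self-consistency.

test_that("group truth tables carry per-group sizes, means and SEM-derived SDs", {
  gt <- group_truth("WT-D1")
  tab <- gt$ephys
  expect_equal(tab$sd, tab$sem * sqrt(tab$n))
  r1 <- ephys_param(group_truth("WT-D1"), "rheobase")
  r2 <- ephys_param(group_truth("WT-D2"), "rheobase")
  expect_gt(r1, r2)   # D1 rheobase exceeds D2 in wild type
  expect_lt(ephys_param(group_truth("Q175-D1"), "epsc_freq"),
            ephys_param(group_truth("WT-D1"), "epsc_freq"))
})

test_that("morphology generation is byte-identical for a fixed seed", {
  gt <- group_truth("Q175-D2")
  f1 <- tempfile(); f2 <- tempfile()
  write_swc(generate_morphology(gt, 77), f1)
  write_swc(generate_morphology(gt, 77), f2)
  expect_identical(readLines(f1), readLines(f2))
  # degenerate config
  cfg <- gt$morphology; cfg$extent_mean <- 0.1
  expect_error(generate_morphology(cfg, 1), "degenerate")
})

test_that("generated cohorts reproduce the group ordering of arbor size", {
  n <- 15
  len <- function(g, s0) vapply(seq_len(n), function(i)
    morphometrics(generate_morphology(group_truth(g), s0 + i))$total_dendritic_length,
    numeric(1))
  wt1 <- len("WT-D1", 0); q1 <- len("Q175-D1", 400)
  wt2 <- len("WT-D2", 800); q2 <- len("Q175-D2", 1200)
  expect_lt(t.test(wt1, q1)$p.value, 0.01)
  expect_gt(mean(q1), mean(wt1))
  expect_gt(t.test(wt2, q2)$p.value, 0.05)
})

test_that("noise-free current steps follow the drawn RC closed form", {
  gt <- group_truth("WT-D2")
  truth <- draw_cell_truth(gt, 9)
  g <- generate_current_clamp(gt, "subthreshold", 9, noise_sd = 0,
                              truth = truth)
  tr <- g$traces[[which(vapply(g$traces, function(t_) t_$stim$amplitude,
                               numeric(1)) == -10)]]
  tt <- msncable:::trace_time(tr)
  on <- tr$stim$onset; du <- tr$stim$duration
  v_ss <- mean(tr$values[tt >= on + 0.75 * du & tt < on + du])
  expect_equal(v_ss - truth$vr, -10 * truth$rn * 1e-3, tolerance = 1e-3)
  # exponential relaxation with the drawn time constant
  i_tau <- which.min(abs(tt - (on + truth$tau)))
  expect_equal((tr$values[i_tau] - truth$vr) / (v_ss - truth$vr),
               1 - exp(-1), tolerance = 0.01)
})

test_that("the drawn rheobase emerges at the ramp threshold crossing", {
  gt <- group_truth("Q175-D1")
  for (s in 1:4) {
    truth <- draw_cell_truth(gt, s)
    if (truth$rheobase > 195) next
    g <- generate_current_clamp(gt, "ramp", s, noise_sd = 0, truth = truth)
    rh <- suppressWarnings(extract_rheobase(g$traces[[1]]))
    expect_equal(rh, truth$rheobase, tolerance = 0.02)
  }
})

test_that("trace generation is reproducible and noise obeys the configured SD", {
  gt <- group_truth("WT-D1")
  g1 <- generate_current_clamp(gt, "subthreshold", 12)
  g2 <- generate_current_clamp(gt, "subthreshold", 12)
  expect_identical(g1$traces[[1]]$values, g2$traces[[1]]$values)
  e1 <- generate_vclamp_epsc(gt, duration = 5, seed = 12)
  e2 <- generate_vclamp_epsc(gt, duration = 5, seed = 12)
  expect_identical(e1$trace$values, e2$trace$values)
  # residual noise around the baseline matches the requested RMS
  quiet <- generate_vclamp_epsc(gt, duration = 5, seed = 3, noise_rms = 2.5,
                                truth = within(draw_cell_truth(gt, 3),
                                               epsc_freq <- 1e-6))
  expect_equal(sd(quiet$trace$values), 2.5, tolerance = 0.05)
  expect_error(generate_vclamp_epsc(gt, duration = -1), "duration")
})

test_that("generators draw all randomness from the supplied seed", {
  gt <- group_truth("WT-D1")
  set.seed(123); before <- rnorm(1)
  set.seed(123)
  invisible(generate_morphology(gt, 5))
  invisible(generate_current_clamp(gt, "ap_steps", 5))
  invisible(generate_vclamp_epsc(gt, 2, 5))
  invisible(generate_spines_and_puncta(gt, 100, 5))
  after <- rnorm(1)
  expect_identical(before, after)
})
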