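# Synapse placement, voltage-clamp activation protocols, and the
# amplitude-distance regression.

test_that("density placement is uniform per length and seeded", {
  mod <- build_model(random_tree(31))
  L <- morphometrics(mod$morphology)$total_dendritic_length
  syn <- place_synapses(mod, density = 0.05, seed = 5)
  expect_lt(abs(nrow(syn) - 0.05 * L), 4 * sqrt(0.05 * L))
  syn2 <- place_synapses(mod, density = 0.05, seed = 5)
  expect_identical(syn, syn2)
  expect_error(place_synapses(mod, density = 0.05,
                              region_counts = c(1, 1, 1), seed = 1),
               "exactly one")
})

test_that("region placement puts exact counts in path-distance thirds", {
  mod <- build_model(random_tree(32))
  syn <- place_synapses(mod, region_counts = c(100, 100, 100), seed = 7)
  expect_identical(nrow(syn), 300L)
  maxd <- morphometrics(mod$morphology)$max_path_distance
  reg <- findInterval(syn$path_dist, c(0, maxd / 3, 2 * maxd / 3))
  expect_true(all(table(reg) >= 99))
})

test_that("a somatic synapse under ideal clamp peaks at g_max times the driving force", {
  mod <- build_model(cyl_morph())
  syns <- data.frame(section = 1L, pos = 0, path_dist = 0, comp = 1L)
  for (taus in list(c(2.29, 1.80), c(0.5, 5), c(2, 2.001))) {
    sp <- synapse_params(0.21, taus[1], taus[2])
    sa <- sequential_activation(mod, syns, sp)
    expect_equal(sa$amplitude, 0.21 * 70, tolerance = 5e-3)
  }
})

test_that("responses superpose under passive membrane and ideal clamp", {
  # one synapse per arm of a star: the clamped soma decouples the arms, so
  # summation must be exact up to driving-force perturbation at each site
  mod <- build_model(star_morph(k = 3, l = 250))
  syn <- data.frame(section = 1:3, pos = 0.5, path_dist = 125)
  syn$comp <- vapply(1:3, function(k)
    msncable:::comp_at(mod, k, 0.5), integer(1))
  sp <- synapse_params()
  proto <- stimulus_protocol("voltage", tstop = 80, dt = 0.05, hold = -70)
  together <- simulate_model(mod, proto, synapses = syn, syn_params = sp,
                             events = data.frame(synapse = 1:3, time = 20))
  base <- simulate_model(mod, proto)$i_clamp$values
  summed <- rep(0, length(base))
  for (k in 1:3) {
    one <- simulate_model(mod, proto, synapses = syn[k, ], syn_params = sp,
                          events = data.frame(synapse = 1, time = 20))
    summed <- summed + one$i_clamp$values - base
  }
  got <- together$i_clamp$values - base
  expect_lt(max(abs(got - summed)) / max(abs(summed)), 0.01)
})

test_that("sequential amplitudes decrease with distance along a cable", {
  mod <- build_model(cyl_morph(l = 300, d = 1))
  pos <- seq(0.1, 0.9, by = 0.2)
  syn <- data.frame(section = 1L, pos = pos, path_dist = pos * 300)
  syn$comp <- vapply(seq_along(pos), function(k)
    msncable:::comp_at(mod, 1L, syn$pos[k]), integer(1))
  sa <- sequential_activation(mod, syn, synapse_params(), dt = 0.05)
  expect_true(all(diff(sa$amplitude) < 0))
})

test_that("time-domain distance decay matches the frequency-domain attenuation", {
  # under an ideal somatic clamp the recorded EPSC scales with the transfer
  # impedance Z_tr(x), so ln(amplitude) against ln|Z_tr| at the event's
  # dominant frequency has unit slope
  mod <- build_model(cyl_morph(l = 350, d = 0.8, npts = 36))
  pos <- seq(0.06, 0.96, by = 0.1)
  syn <- data.frame(section = 1L, pos = pos, path_dist = pos * 350)
  syn$comp <- vapply(seq_along(pos), function(k)
    msncable:::comp_at(mod, 1L, syn$pos[k]), integer(1))
  sp <- synapse_params()       # rise 2.29 / decay 1.80 ms
  sa <- sequential_activation(mod, syn, sp, dt = 0.05)
  f_dom <- 1000 / (2 * pi * sqrt(sp$tau_rise * sp$tau_decay))
  im <- impedance_tree(mod, f_dom)
  ztr <- stats::approx(im$path_dist, log(Mod(im$z_tr)), xout = sa$path_dist)$y
  fit <- stats::lm(log(sa$amplitude) ~ ztr)
  expect_equal(unname(coef(fit)[2]), 1, tolerance = 0.15)
  expect_gt(summary(fit)$r.squared, 0.98)
})

test_that("distance-decay regression recovers a planted exponential", {
  set.seed(81)
  lam <- 320
  x <- runif(300, 10, 220)
  amp <- exp(log(14) - x / lam + rnorm(300, 0, 0.05))
  rec <- data.frame(amplitude = amp, path_dist = x,
                    group = rep(c("a", "b"), 150))
  fit <- fit_distance_decay(rec)
  expect_equal(mean(fit$slopes), -1 / lam, tolerance = 0.05)
  # identical groups: no group effect
  tval <- summary(fit$fit)$coefficients[, "t value"]
  expect_lt(abs(tval[["groupb"]]), 2)
  expect_gt(fit$r_squared, 0.5)
  # non-positive amplitudes excluded with a log message
  rec$amplitude[1] <- 0
  expect_message(fit_distance_decay(rec), "dropped 1")
})

test_that("unattainable synapse-fit targets fail fast", {
  mod <- build_model(cyl_morph(l = 100, npts = 6))
  syn <- data.frame(section = 1L, pos = 0.5, path_dist = 50,
                    comp = msncable:::comp_at(mod, 1L, 0.5))
  expect_error(
    fit_synapse_params(mod, syn, list(amplitude = 3, rise = 2, decay = 6,
                                      frequency = 1)),
    "below the")
})
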