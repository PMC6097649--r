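# Compartmental model construction and time-domain integration.

test_that("compartment rule: odd counts no longer than lambda(100 Hz)/100", {
  p <- passive_params()
  expect_equal(p$tau_m, 15.57, tolerance = 1e-12)
  expect_equal(lambda_dc(1), sqrt(17.3e3 * 1e-4 / 400) * 1e4)
  m <- cyl_morph(l = 100, d = 1)
  mod <- build_model(m, p)
  n <- mod$n_per_section[1]
  expect_identical(n %% 2L, 1L)
  q <- sqrt(complex(real = 1, imaginary = 2 * pi * 100 * p$tau_m * 1e-3))
  lam100 <- lambda_dc(1) / Re(q)
  expect_lte(100 / n, lam100 / 100)
  expect_gt(100 / (n - 2L), lam100 / 100)  # smallest such odd n
  mod2 <- build_model(random_tree(2), p)
  expect_true(all(mod2$n_per_section %% 2L == 1L))
})

test_that("membrane area is conserved exactly by discretization", {
  for (m in list(cyl_morph(), random_tree(7))) {
    mod <- build_model(m)
    expect_equal(surface_area(mod), surface_area(m), tolerance = 1e-3 * 0.1)
  }
})

test_that("zero-stimulus model settles to the leak reversal", {
  mod <- build_model(random_tree(1))
  proto <- stimulus_protocol("current", tstop = 300, dt = 0.05,
                             sample_every = 100L)
  sim <- simulate_model(mod, proto, init = rep(-70, length(mod$parent)))
  expect_equal(tail(sim$v[[1]]$values, 1), -84.4, tolerance = 1e-5)
})

test_that("single-compartment RC obeys the closed form", {
  p <- passive_params()
  area <- 4 * pi * (6.5e-4)^2                     # cm^2
  mod <- structure(list(parent = 0L, g_axial = 0,
                        g_leak = area / p$rm * 1e3,
                        cap = p$cm * area * 1e3, area = area,
                        e_leak = p$el, params = p),
                   class = "compartmental_model")
  proto <- stimulus_protocol("current", tstop = 160, dt = 0.01,
                             segments = data.frame(onset = 10, duration = 150,
                                                   amp0 = -10, amp1 = -10))
  sim <- simulate_model(mod, proto, init = "el")
  v <- sim$v[[1]]$values
  rm_mohm <- p$rm * 1e3 / area * 1e-6
  dv_ss <- -10e-3 * rm_mohm                        # nA * MOhm = mV
  expect_equal(tail(v, 1) - p$el, dv_ss, tolerance = 1e-4)
  # relaxation time constant: 63.2% of the step response at t = tau_m
  i_tau <- which.min(abs(sim$t - (10 + p$tau_m)))
  expect_equal((v[i_tau] - p$el) / dv_ss, 1 - exp(-1), tolerance = 2e-3)
})

test_that("sealed-cylinder DC input resistance matches R_inf coth(l/lambda)", {
  l <- 400; d <- 1
  mod <- build_model(cyl_morph(l = l, d = d))
  rc <- r_inf_mohm(d) / tanh(l / lambda_dc(d))
  pred <- 1 / (1 / rc + 1 / soma_r_mohm(13))       # soma in parallel
  expect_equal(input_resistance(mod), pred, tolerance = 0.01)
})

test_that("charge is conserved at DC steady state", {
  mod <- build_model(random_tree(6))
  inj <- 0.05   # nA
  v <- msncable:::.cable_steady(mod$parent - 1L, mod$g_axial, mod$g_leak,
                                mod$e_leak, -1L, 0, 0L, inj)
  leak <- sum(mod$g_leak * (v - mod$e_leak))
  expect_equal(leak, inj, tolerance = 1e-4 * inj)
})

test_that("voltage clamp at the leak reversal draws no current", {
  mod <- build_model(random_tree(8))
  proto <- stimulus_protocol("voltage", tstop = 50, dt = 0.05, hold = -84.4,
                             sample_every = 10L)
  sim <- simulate_model(mod, proto)
  expect_lt(max(abs(sim$i_clamp$values)), 1e-6)
})

test_that("time step halving and mesh refinement leave voltages stable", {
  m <- random_tree(3)
  proto_at <- function(dt) stimulus_protocol(
    "current", tstop = 100, dt = dt,
    segments = data.frame(onset = 10, duration = 90, amp0 = 40, amp1 = 40),
    sample_every = round(1 / dt))
  mod <- build_model(m)
  v1 <- simulate_model(mod, proto_at(0.05))$v[[1]]$values
  v2 <- simulate_model(mod, proto_at(0.025))$v[[1]]$values
  expect_lt(max(abs(tail(v1, 1) - tail(v2, 1)) / abs(tail(v2, 1))), 1e-3)
  # 4x more compartments
  mod4 <- build_model(m, lambda_fraction = 0.0025)
  v4 <- simulate_model(mod4, proto_at(0.05))$v[[1]]$values
  expect_lt(abs(tail(v1, 1) - tail(v4, 1)) / abs(tail(v4, 1)), 5e-3)
})

test_that("degenerate inputs are rejected", {
  expect_error(stimulus_protocol("current", tstop = 0), "tstop")
  expect_error(stimulus_protocol("current", tstop = 10, dt = -1), "dt")
  m <- cyl_morph()
  m$sections[[1]]$points[2, 4] <- -1
  expect_error(build_model(m), "diameter")
})
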