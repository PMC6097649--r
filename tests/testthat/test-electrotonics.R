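# Frequency-domain impedances, attenuation, and the morphoelectrotonic
# transform, validated against closed forms and the time-domain engine.

test_that("DC input impedance matches the membrane/cable closed forms", {
  l <- 400; d <- 1; soma_d <- 13
  mod <- build_model(cyl_morph(l = l, d = d, soma_d = soma_d))
  im <- impedance_tree(mod, 0)
  z <- attr(im, "z_soma")
  expect_equal(Im(z), 0, tolerance = 1e-12)
  rc <- r_inf_mohm(d) / tanh(l / lambda_dc(d))
  expect_equal(Re(z), 1 / (1 / rc + 1 / soma_r_mohm(soma_d)),
               tolerance = 1e-9)
  # near-isopotential limit: a stubby thick cable leaves the soma membrane
  # resistance dominant
  stub <- build_model(cyl_morph(l = 2, d = 0.3, soma_d = soma_d, npts = 3))
  z0 <- Re(attr(impedance_tree(stub, 0), "z_soma"))
  memb <- 1 / (1 / soma_r_mohm(soma_d) +
                 1 / (r_inf_mohm(0.3) / tanh(2 / lambda_dc(0.3))))
  expect_equal(z0, memb, tolerance = 1e-9)
})

test_that("outward tip attenuation of a sealed cable is ln cosh(l/lambda)", {
  l <- 400; d <- 1
  mod <- build_model(cyl_morph(l = l, d = d))
  im <- impedance_tree(mod, 0)
  tip <- im[im$is_tip, ]
  expect_equal(tip$l_out[nrow(tip)], log(cosh(l / lambda_dc(d))),
               tolerance = 1e-9)
  expect_true(all(im$l_out >= 0))
  expect_true(all(im$l_in >= 0))
  # L strictly increases with distance along the unbranched cable
  expect_true(all(diff(im$l_out) > 0))
  expect_true(all(diff(im$l_in) > 0))
})

test_that("reciprocity links inward attenuation, Z_in and Z_tr", {
  mod <- build_model(random_tree(12))
  for (f in c(0, 250)) {
    im <- impedance_tree(mod, f)
    expect_equal(exp(im$l_in), Mod(im$z_in / im$z_tr), tolerance = 1e-9)
    expect_equal(exp(im$l_out),
                 Mod(attr(im, "z_soma") / im$z_tr), tolerance = 1e-9)
    expect_true(all(Mod(im$z_tr) <=
                      pmin(Mod(im$z_in), Mod(attr(im, "z_soma"))) * (1 + 1e-9)))
  }
})

test_that("frequency-domain attenuation matches time-domain simulation", {
  # outward L interpolated to a recording compartment's position
  l_out_at_comp <- function(mod, im, comp) {
    s <- mod$map$section[comp]
    pd <- mod$map$path_dist[comp]
    rows <- im[im$section == s, ]
    off <- msncable:::section_path_offsets(mod$morphology)
    par <- mod$morphology$sections[[s]]$parent
    l0 <- if (par == 0L) 0 else {
      prow <- im[im$section == par, ]
      prow$l_out[nrow(prow)]
    }
    stats::approx(c(off[s], rows$path_dist), c(l0, rows$l_out), xout = pd)$y
  }
  # >= 5 random small trees; A and Z_in at 0/100/500 Hz within 2%
  for (seed in 1:5) {
    m <- random_tree(seed * 13, n_primary = 2)
    mod <- build_model(m)
    leaf_sec <- which(lengths(msncable:::section_children(m)) == 0L)[1]
    tip_comp <- msncable:::comp_at(mod, leaf_sec, 1)
    # DC: step response
    dv <- local({
      v0 <- msncable:::.cable_steady(mod$parent - 1L, mod$g_axial, mod$g_leak,
                                     mod$e_leak, -1L, 0, integer(0), numeric(0))
      v1 <- msncable:::.cable_steady(mod$parent - 1L, mod$g_axial, mod$g_leak,
                                     mod$e_leak, -1L, 0, 0L, 0.02)
      v1 - v0
    })
    im0 <- impedance_tree(mod, 0)
    expect_equal(dv[1] / 0.02, Mod(attr(im0, "z_soma")), tolerance = 0.02)
    expect_equal(dv[1] / dv[tip_comp], exp(l_out_at_comp(mod, im0, tip_comp)),
                 tolerance = 0.02)
    for (f in c(100, 500)) {
      imf <- impedance_tree(mod, f)
      proto <- stimulus_protocol(
        "current", tstop = 120, dt = 0.02,
        segments = data.frame(onset = 0, duration = 120, amp0 = 50,
                              amp1 = 50, freq = f),
        sample_every = 5L)
      sim <- simulate_model(mod, proto, record = c(1L, tip_comp))
      a_soma <- osc_amplitude(sim$v[[1]]$values)
      a_tip <- osc_amplitude(sim$v[[2]]$values)
      expect_equal(a_soma / a_tip, exp(l_out_at_comp(mod, imf, tip_comp)),
                   tolerance = 0.02)
      expect_equal(a_soma / 0.05, Mod(attr(imf, "z_soma")), tolerance = 0.02)
    }
  }
})

test_that("mean attenuation profiles are monotone in frequency and scheme-tagged", {
  mod <- build_model(random_tree(21))
  prof <- mean_attenuation_profile(mod, seq(0, 500, by = 100))
  expect_identical(attr(prof, "scheme"), "tips")
  expect_true(all(diff(prof$l_in) >= 0))
  expect_true(all(diff(prof$l_out) >= 0))
  prof2 <- mean_attenuation_profile(mod, c(0, 500), scheme = "points")
  expect_identical(attr(prof2, "scheme"), "points")
  expect_error(mean_attenuation_profile(mod, numeric(0)), "empty")
  expect_error(mean_attenuation_profile(mod, c(0, 600)), "500")
  expect_error(impedance_tree(mod, -5), "f must be")
})

test_that("a star of identical cables attenuates like any single arm", {
  mod <- build_model(star_morph(k = 4))
  im <- impedance_tree(mod, 100)
  tips_in <- im$l_in[im$is_tip]
  tips_out <- im$l_out[im$is_tip]
  expect_lt(diff(range(tips_in)), 1e-9)
  expect_lt(diff(range(tips_out)), 1e-9)
  prof <- mean_attenuation_profile(mod, 100)
  expect_equal(prof$l_in, tips_in[1], tolerance = 1e-9)
})

test_that("morphoelectrotonic transform adds attenuation along paths", {
  mod <- build_model(random_tree(17))
  for (dir in c("inward", "outward")) {
    met <- met_transform(mod, 100, dir, scale = 1)
    att <- attenuation(mod, 100, dir)
    # drawn root-to-tip path length equals the tip's total L
    ends <- which(att$is_tip)
    off <- msncable:::section_path_offsets(met)
    len <- vapply(met$sections, msncable:::section_length, numeric(1))
    for (e in ends) {
      s <- att$section[e]
      expect_equal(off[s] + len[s], att$L[e], tolerance = 1e-6)
    }
    # exportable and reloadable
    f <- tempfile(fileext = ".swc")
    write_swc(met, f)
    expect_s3_class(read_swc(f), "morphology")
  }
  # higher frequency draws longer
  m0 <- met_transform(mod, 0, "inward")
  m5 <- met_transform(mod, 500, "inward")
  tot <- function(mm) sum(vapply(mm$sections, msncable:::section_length,
                                 numeric(1)))
  expect_gt(tot(m5), tot(m0))
})
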