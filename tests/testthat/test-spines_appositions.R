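# Spine sub-typing, density profiles and apposition calling.

test_that("classification applies the rules with the documented precedence", {
  sp <- data.frame(
    head_diameter = c(0.6, 0.61, 0.9, 0.3, 0.3),
    neck = c(TRUE, TRUE, FALSE, TRUE, FALSE),
    length = c(1.5, 1.5, 1.0, 3.5, 3.5))
  out <- classify_spines(sp)
  # boundary inclusive: 0.6 um head with neck is thin
  expect_identical(out$subtype,
                   c("thin", "mushroom", "stubby", "filopodia", "filopodia"))
  # neckless spines are stubby regardless of head diameter
  out2 <- classify_spines(data.frame(head_diameter = c(0.3, 1.2),
                                     neck = FALSE, length = 1))
  expect_identical(out2$subtype, c("stubby", "stubby"))
  # alternative precedence: neck rule before length
  cfg <- spine_classifier_config(filopodia_first = FALSE)
  out3 <- classify_spines(data.frame(head_diameter = 0.3, neck = FALSE,
                                     length = 3.5), cfg)
  expect_identical(out3$subtype, "stubby")
})

test_that("classification is total and rejects incomplete records", {
  sp <- data.frame(head_diameter = c(0.5, NA, 0.7),
                   neck = c(TRUE, TRUE, TRUE),
                   length = c(1, 1, 2))
  expect_message(out <- classify_spines(sp), "rejected 1")
  expect_identical(nrow(out), 2L)
  expect_true(all(out$subtype %in% c("thin", "mushroom", "stubby",
                                     "filopodia")))
  expect_identical(sum(table(out$subtype)), 2L)
})

test_that("densities are counts per analysed length and scale correctly", {
  sp <- data.frame(head_diameter = runif(50, 0.3, 0.5), neck = TRUE,
                   length = 1.2, path_dist = seq(21, 119, length.out = 50))
  sp <- classify_spines(sp)
  d1 <- spine_density(sp, dendrite_length = 120)
  expect_equal(unname(d1$density["total"]), 0.5)
  d2 <- spine_density(sp, dendrite_length = 220)
  expect_equal(unname(d2$density["total"]), 50 / 200)
  expect_equal(sum(d1$bins$count), 50)
  expect_error(spine_density(sp, dendrite_length = 15), "exceed")
})

test_that("generator plants a recoverable subtype mixture", {
  gt <- group_truth("Q175-D1")
  g <- generate_spines_and_puncta(gt, dendrite_length = 120, seed = 3)
  out <- classify_spines(g$spines)
  expect_identical(out$subtype, out$true_subtype)
  g2 <- generate_spines_and_puncta(gt, dendrite_length = 120, seed = 3)
  expect_identical(g$spines, g2$spines)
  expect_identical(g$puncta, g2$puncta)
  expect_error(generate_spines_and_puncta(gt, dendrite_length = 18, seed = 1),
               "exceed 20")
})

test_that("apposition calling needs three consecutive slices of overlap", {
  spines <- data.frame(head_diameter = 0.5, neck = TRUE, length = 1.5,
                       path_dist = 50, head_x = 50, head_y = 1.75,
                       subtype = "thin")
  geom <- list(length = 120, shaft_radius = 0.5, shaft_z = c(-3L, 3L),
               offset = 20)
  p3 <- data.frame(channel = "Vglut1", x = 50, y = 2.1, z_lo = 0L, z_hi = 2L,
                   radius = 0.2)
  rep3 <- call_appositions(spines, p3, geom)
  expect_identical(unname(rep3$counts["head", "Vglut1"]), 1L)
  p2 <- p3; p2$z_hi <- 1L    # only two slices
  rep2 <- call_appositions(spines, p2, geom)
  expect_identical(sum(rep2$counts), 0L)
  # z-relabelling (shift) leaves the call unchanged
  p3s <- p3; p3s$z_lo <- p3$z_lo - 7L; p3s$z_hi <- p3$z_hi - 7L
  geom_s <- geom; geom_s$shaft_z <- geom$shaft_z - 7L
  rep3s <- call_appositions(spines, p3s, geom_s)
  expect_identical(rep3s$counts, rep3$counts)
  # puncta without z spans are rejected
  pbad <- p3; pbad$z_hi <- NA
  expect_message(call_appositions(spines, pbad, geom), "rejected 1")
})

test_that("planted apposition fractions are recovered within binomial error", {
  gt <- group_truth("WT-D1")
  hits <- misses <- 0
  for (s in 1:4) {
    g <- generate_spines_and_puncta(gt, dendrite_length = 120, seed = s)
    sp <- classify_spines(g$spines)
    rep_ <- call_appositions(sp, g$puncta, g$geometry)
    planted <- table(factor(g$puncta$true_target,
                            levels = c("shaft", "head", "neck", "none")))
    called <- rep_$puncta$target
    # every planted head/shaft apposition should be called as an apposition
    expect_gte(mean(called[g$puncta$true_target == "head"] == "head"), 0.95)
    expect_gte(mean(called[g$puncta$true_target != "none"] != "none"), 0.95)
    # background stays background
    expect_gte(mean(called[g$puncta$true_target == "none"] == "none"), 0.95)
  }
})

test_that("channel ratio approaches the configured 1.5:1", {
  gt <- group_truth("WT-D2")
  ratios <- sapply(1:6, function(s) {
    g <- generate_spines_and_puncta(gt, dendrite_length = 120, seed = 100 + s)
    rep_ <- call_appositions(classify_spines(g$spines), g$puncta, g$geometry)
    rep_$ratio
  })
  expect_equal(mean(ratios), 1.6, tolerance = 0.2)
})
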