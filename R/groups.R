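# Group-level generator ground truth for the four experimental groups
# (WT-D1, WT-D2, Q175-D1, Q175-D2) plus the two pooled "unidentified" groups
# (WT, Q175). Electrophysiological means, SEMs and group sizes are the
# published per-group values; per-cell standard deviations are reconstructed
# as SD = SEM * sqrt(n). Morphology-generator parameters are calibration
# defaults chosen to reproduce the published group orderings of dendritic
# length/complexity; they are not measured quantities.

.ephys_tables <- local({
  measures <- c("vr", "rn", "tau", "rheobase", "ap_threshold", "ap_amplitude",
                "epsc_freq", "epsc_amp")
  mk <- function(n, mean, sem) data.frame(measure = measures, n = n,
                                          mean = mean, sem = sem,
                                          sd = sem * sqrt(n))
  list(
    "WT-D1" = mk(c(40, 42, 41, 40, 42, 41, 28, 29),
                 c(-85.42, 144.28, 12.46, 156.94, -39.15, 79.86, 2.15, 11.99),
                 c(0.80, 10.08, 0.97, 10.92, 0.98, 1.17, 0.20, 0.50)),
    "Q175-D1" = mk(c(43, 37, 36, 34, 40, 40, 15, 16),
                   c(-79.19, 186.89, 18.18, 127.45, -35.56, 72.43, 1.68, 11.54),
                   c(1.23, 10.81, 1.33, 6.90, 0.74, 1.11, 0.12, 0.57)),
    "WT-D2" = mk(c(22, 27, 27, 23, 26, 27, 20, 20),
                 c(-85.18, 172.38, 17.53, 104.63, -44.04, 76.48, 1.81, 13.69),
                 c(0.56, 16.27, 2.06, 9.27, 1.00, 1.91, 0.19, 0.70)),
    "Q175-D2" = mk(c(89, 82, 88, 79, 84, 80, 51, 50),
                   c(-81.42, 226.52, 22.34, 107.22, -39.39, 75.02, 1.44, 12.96),
                   c(0.83, 11.26, 1.27, 6.92, 0.65, 0.53, 0.08, 0.40)),
    "WT" = mk(c(101, 101, 93, 90, 95, 95, 53, 53),
              c(-81.51, 198.24, 16.52, 147.99, -39.55, 76.73, 2.03, 13.03),
              c(0.91, 18.21, 1.13, 8.39, 0.64, 0.99, 0.15, 0.44)),
    "Q175" = mk(c(178, 179, 126, 154, 167, 167, 78, 76),
                c(-79.82, 277.39, 23.9, 117.8, -37.58, 71.83, 1.31, 12.89),
                c(1.01, 14.06, 1.23, 5.15, 0.53, 0.64, 0.08, 0.34))
  )
})

.morph_configs <- local({
  base <- list(
    n_primary = c(5L, 6L),       # uniform draw, inclusive
    step = 5,                    # growth step, um
    dir_jitter = 0.12,           # direction random-walk scale per step
    extent_mean = 185,           # mean per-primary maximal path extent, um
    extent_sd = 12,
    branch_base = 0.0035,        # branch probability per um outside windows
    branch_window = c(20, 100),  # elevated-branching window, um path distance
    branch_mid = 0.013,
    distal_window = NULL,        # optional second window (c(lo, hi, rate))
    side_len = c(16, 45),        # side-branch length range at a bifurcation
    min_branch_sep = 12,         # um between consecutive branch points
    d_primary = 1.7,             # proximal dendrite diameter, um
    d_taper = 0.004,             # diameter loss per um of path
    d_branch_ratio = 0.95,       # continuing-child/parent diameter at a branch
    side_d_ratio = 0.55,         # side-branch/parent diameter at a branch
    side_d_min = 0.45,
    d_min = 0.55,
    soma_diameter = 13
  )
  q1 <- base; q1$branch_mid <- 0.05           # denser branching 20-100 um
  q2 <- base
  q2$distal_window <- c(130, 150, 0.02)       # modest distal elaboration
  q2$extent_mean <- 192
  list("WT-D1" = base, "WT-D2" = base, "Q175-D1" = q1, "Q175-D2" = q2,
       "WT" = base, "Q175" = q1)
})

.spine_configs <- local({
  # densities in spines/um beyond the 20 um proximal offset
  base <- list(density = c(thin = 0.55, mushroom = 0.35, stubby = 0.15,
                           filopodia = 0.03),
               offset = 20)
  q1 <- base
  q1$density <- c(thin = 0.33, mushroom = 0.34, stubby = 0.23,
                  filopodia = 0.03)
  list("WT-D1" = base, "WT-D2" = base, "Q175-D1" = q1, "Q175-D2" = base,
       "WT" = base, "Q175" = q1)
})

.apposition_configs <- local({
  # shaft apposition densities per channel (per um); head/neck apposition
  # fractions of spines per channel
  mk <- function(v1, v2) list(shaft_density = c(Vglut1 = v1, Vglut2 = v2),
                              head_fraction = c(Vglut1 = 0.24, Vglut2 = 0.16),
                              neck_fraction = c(Vglut1 = 0.04, Vglut2 = 0.03),
                              background_density = 0.15)
  list("WT-D1" = mk(0.27, 0.16), "Q175-D1" = mk(0.20, 0.15),
       "WT-D2" = mk(0.32, 0.19), "Q175-D2" = mk(0.23, 0.15),
       "WT" = mk(0.27, 0.16), "Q175" = mk(0.20, 0.15))
})

#' Generator ground truth for an experimental group
#'
#' Bundles everything the synthetic-data generators need for one group:
#' per-cell electrophysiological means and dispersions, morphology-growth
#' configuration, spine subtype densities, apposition densities, and typical
#' spontaneous-EPSC kinetics.
#'
#' @param group one of `"WT-D1"`, `"Q175-D1"`, `"WT-D2"`, `"Q175-D2"`, or the
#'   pooled `"WT"` / `"Q175"`.
#' @return an object of class `group_truth`.
#' @export
group_truth <- function(group = c("WT-D1", "Q175-D1", "WT-D2", "Q175-D2",
                                  "WT", "Q175")) {
  group <- match.arg(group)
  structure(list(
    group = group,
    genotype = if (startsWith(group, "Q175")) "Q175" else "WT",
    cell_type = if (endsWith(group, "D1")) "D1"
                else if (endsWith(group, "D2")) "D2" else "pooled",
    ephys = .ephys_tables[[group]],
    morphology = .morph_configs[[group]],
    spines = .spine_configs[[group]],
    appositions = .apposition_configs[[group]],
    epsc_kinetics = list(tau_rise = 2.0, tau_decay = 6.0, amplitude_cv = 0.4),
    ap_shape = list(rise = 0.7, fall = 1.6, ahp = 12, fi_gain = 0.15)
  ), class = "group_truth")
}

#' @export
print.group_truth <- function(x, ...) {
  cat("<group_truth> ", x$group, "\n", sep = "")
  print(x$ephys, row.names = FALSE)
  invisible(x)
}

#' Look up a group's electrophysiological parameter
#'
#' @param gt a [group_truth()].
#' @param measure one of `vr`, `rn`, `tau`, `rheobase`, `ap_threshold`,
#'   `ap_amplitude`, `epsc_freq`, `epsc_amp`.
#' @param field `"mean"`, `"sem"`, `"sd"`, or `"n"`.
#' @return the requested value.
#' @export
ephys_param <- function(gt, measure, field = "mean") {
  tab <- gt$ephys
  tab[[field]][match(measure, tab$measure)]
}
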