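# Phenomenological single-cell generator for current-clamp and voltage-clamp
# traces. The subthreshold membrane is an RC element with drawn Vr, Rn and
# tau; approaching threshold the quasi-static V-I relation steepens smoothly
# so that the drawn rheobase (minimal current for a spike) and the drawn
# action-potential threshold voltage are simultaneously honoured, as in real
# spiny neurons where near-threshold inward currents amplify depolarisation.
# Spikes are stylized waveforms with exact, recorded ground truth; repetitive
# firing follows a linear rate-versus-current rule above rheobase. All draws
# flow from the supplied seed.

#' Draw one cell's ground-truth parameters from a group
#'
#' @param gt a [group_truth()].
#' @param seed integer seed.
#' @return list of per-cell true values (`vr`, `rn`, `tau`, `rheobase`,
#'   `ap_threshold`, `ap_amplitude`, `epsc_freq`, `epsc_amp`, and the AP
#'   shape constants).
#' @export
draw_cell_truth <- function(gt, seed = 1L) {
  with_seed(seed, {
    dr <- function(measure, lo = -Inf, hi = Inf) {
      mu <- ephys_param(gt, measure, "mean")
      sd <- ephys_param(gt, measure, "sd")
      min(hi, max(lo, stats::rnorm(1, mu, sd)))
    }
    tr <- list(
      vr = dr("vr", -100, -70),
      rn = dr("rn", 40, 450),
      tau = dr("tau", 4, 45),
      rheobase = dr("rheobase", 30, 320),
      ap_threshold = dr("ap_threshold", -55, -25),
      ap_amplitude = dr("ap_amplitude", 45, 110),
      epsc_freq = dr("epsc_freq", 0.2, 6),
      epsc_amp = dr("epsc_amp", 6.5, 25)
    )
    # keep the drive map monotone: threshold must sit above the linear region
    tr$ap_threshold <- max(tr$ap_threshold,
                           tr$vr + 0.9 * tr$rheobase * tr$rn * 1e-3)
    c(tr, gt$ap_shape)
  })
}

# quasi-static displayed depolarisation for a linear drive D (mV):
# identity below d1, smooth expansion mapping d_rheo to the threshold gap.
drive_map <- function(D, d_rheo, theta_gap, k = 2) {
  d1 <- min(0.7 * d_rheo, 0.8 * theta_gap)
  out <- D
  hi <- D > d1
  u <- pmin(1, (D[hi] - d1) / (d_rheo - d1))
  out[hi] <- d1 + (theta_gap - d1) * expm1(k * u) / expm1(k)
  out
}

# Build the voltage trace for one injected-current vector. Returns values and
# the generator's spike times.
synth_cc_trace <- function(truth, I, dt, noise_sd = 0.3) {
  n <- length(I)
  a <- exp(-dt / truth$tau)
  ifilt <- as.numeric(stats::filter((1 - a) * I, a, "recursive",
                                    init = I[1L]))
  D <- truth$rn * 1e-3 * ifilt
  d_rheo <- truth$rheobase * truth$rn * 1e-3
  theta_gap <- truth$ap_threshold - truth$vr
  vsub <- truth$vr + drive_map(pmin(D, d_rheo), d_rheo, theta_gap)

  # spike times from rheobase crossings of the drive
  spikes <- numeric(0)
  cross <- which(D >= d_rheo)
  if (length(cross)) {
    t1 <- cross[1L] * dt
    spikes <- t1
    repeat {
      i_now <- min(n, ceiling(spikes[length(spikes)] / dt))
      rate <- truth$fi_gain * (I[i_now] - truth$rheobase)
      isi <- 1000 / max(rate, 0.75)
      t_next <- spikes[length(spikes)] + isi
      i_next <- ceiling(t_next / dt)
      if (i_next > n || D[i_next] < d_rheo) break
      spikes <- c(spikes, t_next)
    }
  }
  v <- vsub
  theta <- truth$ap_threshold
  amp <- truth$ap_amplitude
  n_rise <- max(1L, round(truth$rise / dt))
  n_fall <- max(1L, round(truth$fall / dt))
  n_ahp_seg <- max(1L, round(truth$fall * truth$ahp / amp / dt))
  wav <- c(theta + amp * seq_len(n_rise) / n_rise,
           theta + amp - (amp + truth$ahp) * seq_len(n_fall + n_ahp_seg) /
             (n_fall + n_ahp_seg))
  for (ts in spikes) {
    i0 <- round(ts / dt)
    idx <- i0 + seq_along(wav)
    idx <- idx[idx <= n]
    v[idx] <- wav[seq_along(idx)]
    # AHP recovery toward the subthreshold trajectory
    iend <- i0 + length(wav)
    if (iend < n) {
      rec <- iend:n
      v[rec] <- pmin(vsub[rec] + (v[min(iend, n)] - vsub[min(iend, n)]) *
                       exp(-(rec - iend) * dt / 12), theta)
    }
  }
  if (noise_sd > 0) v <- v + stats::rnorm(n, 0, noise_sd)
  list(values = v, spikes = spikes)
}

cc_protocol_steps <- function(protocol) {
  switch(protocol,
    subthreshold = list(amps = c(-40, -30, -20, -10, 10, 20),
                        pre = 200, dur = 800, post = 200, dt = 0.1),
    ap_steps = list(amps = seq(50, 450, by = 25),
                    pre = 50, dur = 200, post = 50, dt = 0.08),
    fi_steps = list(amps = seq(-200, 450, by = 50),
                    pre = 100, dur = 2000, post = 100, dt = 0.08),
    stopf("generate_current_clamp: unknown protocol '%s'", protocol))
}

#' Generate current-clamp traces for a synthetic cell
#'
#' @param gt a [group_truth()].
#' @param protocol `"subthreshold"` (steps including -10 pA),
#'   `"ap_steps"` (200 ms depolarising series), `"fi_steps"` (2 s series,
#'   -200 to +450 pA) or `"ramp"` (10 s dual ramp, 0-100 then 0-200 pA).
#' @param seed integer seed; the same seed yields the same underlying cell
#'   across protocols.
#' @param noise_sd Gaussian voltage noise SD, mV (default 0.3).
#' @param truth optional pre-drawn [draw_cell_truth()] result.
#' @return list `traces` (list of voltage [trace]s with stimulus
#'   annotations), `truth` (the drawn ground truth, including per-step true
#'   spike counts for `fi_steps`).
#' @export
generate_current_clamp <- function(gt, protocol = c("subthreshold",
                                                    "ap_steps", "fi_steps",
                                                    "ramp"),
                                   seed = 1L, noise_sd = 0.3, truth = NULL) {
  protocol <- match.arg(protocol)
  truth <- truth %||% draw_cell_truth(gt, seed)
  with_seed(seed + 1000003L, {
    if (protocol == "ramp") {
      dt <- 0.33
      segs <- data.frame(onset = c(0, 5000), duration = c(5000, 5000),
                         amp0 = c(0, 0), amp1 = c(100, 200))
      tt <- seq(dt, 10000, by = dt)
      I <- proto_value(list(hold = 0, segments = segs), tt)
      out <- synth_cc_trace(truth, I, dt, noise_sd)
      tr <- new_trace(out$values, dt, "mV",
                      stim = list(segments = segs, protocol = "ramp"))
      truth$ramp_spikes <- out$spikes
      return(list(traces = list(tr), truth = truth))
    }
    cfg <- cc_protocol_steps(protocol)
    traces <- list()
    fi <- NULL
    for (ampl in cfg$amps) {
      nt <- round((cfg$pre + cfg$dur + cfg$post) / cfg$dt)
      tt <- seq_len(nt) * cfg$dt
      I <- ifelse(tt >= cfg$pre & tt < cfg$pre + cfg$dur, ampl, 0)
      out <- synth_cc_trace(truth, I, cfg$dt, noise_sd)
      traces[[length(traces) + 1L]] <-
        new_trace(out$values, cfg$dt, "mV",
                  stim = list(onset = cfg$pre, duration = cfg$dur,
                              amplitude = ampl, protocol = protocol))
      fi <- rbind(fi, data.frame(current = ampl,
                                 rate = length(out$spikes) / (cfg$dur / 1e3)))
    }
    if (protocol == "fi_steps") truth$fi <- fi
    list(traces = traces, truth = truth)
  })
}

#' Generate a voltage-clamp trace with spontaneous EPSC-like events
#'
#' Poisson event times at the group's (or cell's) EPSC frequency; each event
#' is a double-exponential inward current with lognormal amplitude; additive
#' Gaussian current noise; sampled at 6.67 kHz.
#'
#' @param gt a [group_truth()].
#' @param duration seconds (default 120).
#' @param seed integer seed.
#' @param noise_rms current noise RMS, pA (default 2.5; at most the 5 pA
#'   detection threshold).
#' @param truth optional pre-drawn [draw_cell_truth()] (uses its
#'   `epsc_freq` / `epsc_amp`).
#' @param amplitude_cv lognormal amplitude coefficient of variation.
#' @return list `trace` (current, pA), `events` (ground truth: `time` ms,
#'   `amplitude` pA), `truth`.
#' @export
generate_vclamp_epsc <- function(gt, duration = 120, seed = 1L,
                                 noise_rms = 2.5, truth = NULL,
                                 amplitude_cv = NULL) {
  if (duration <= 0) stopf("generate_vclamp_epsc: duration must be > 0")
  truth <- truth %||% draw_cell_truth(gt, seed)
  kin <- gt$epsc_kinetics
  cv <- amplitude_cv %||% kin$amplitude_cv
  dt <- 0.15  # ms, 6.67 kHz
  with_seed(seed + 2000003L, {
    n <- round(duration * 1e3 / dt)
    nev <- stats::rpois(1L, truth$epsc_freq * duration)
    tev <- sort(stats::runif(nev, 0, duration * 1e3))
    sdl <- sqrt(log(1 + cv^2))
    mul <- log(truth$epsc_amp) - sdl^2 / 2
    aev <- stats::rlnorm(nev, mul, sdl)
    x <- numeric(n)
    # double-exponential kernel, peak-normalised
    tp <- kin$tau_rise * kin$tau_decay / (kin$tau_decay - kin$tau_rise) *
      log(kin$tau_decay / kin$tau_rise)
    tk <- seq(0, 10 * kin$tau_decay, by = dt)
    kern <- (exp(-tk / kin$tau_decay) - exp(-tk / kin$tau_rise)) /
      (exp(-tp / kin$tau_decay) - exp(-tp / kin$tau_rise))
    for (i in seq_len(nev)) {
      i0 <- floor(tev[i] / dt) + 1L
      idx <- i0:min(n, i0 + length(kern) - 1L)
      x[idx] <- x[idx] - aev[i] * kern[seq_along(idx)]
    }
    if (noise_rms > 0) x <- x + stats::rnorm(n, 0, noise_rms)
    list(trace = new_trace(x, dt, "pA",
                           stim = list(protocol = "vclamp_epsc", hold = -80)),
         events = data.frame(time = tev, amplitude = aev),
         truth = truth)
  })
}

#' Generate and feature-extract a synthetic cohort
#'
#' For each cell: draws ground truth, synthesises the subthreshold, 200 ms
#' step, and dual-ramp current-clamp protocols plus a voltage-clamp EPSC
#' trace, and runs the extractors, returning one row per cell alongside the
#' true values (columns prefixed `true_`).
#'
#' @param groups character vector of group labels (see [group_truth()]).
#' @param n cells per group: integer, vector, or `"table"` to use each
#'   group's published Vr group size.
#' @param seed integer seed.
#' @param noise_sd voltage noise, mV.
#' @param epsc_duration seconds of voltage-clamp recording per cell.
#' @param protocols which feature families to run (`"passive"`, `"ap"`,
#'   `"ramp"`, `"epsc"`).
#' @return data frame, one row per cell.
#' @export
cohort_features <- function(groups = c("WT-D1", "Q175-D1", "WT-D2", "Q175-D2"),
                            n = 12L, seed = 1L, noise_sd = 0.3,
                            epsc_duration = 60,
                            protocols = c("passive", "ap", "ramp", "epsc")) {
  if (identical(n, "table"))
    n <- vapply(groups, function(g) ephys_param(group_truth(g), "vr", "n"),
                numeric(1))
  n <- rep_len(n, length(groups))
  rows <- list()
  cell_id <- 0L
  for (gi in seq_along(groups)) {
    gt <- group_truth(groups[gi])
    for (ci in seq_len(n[gi])) {
      cell_id <- cell_id + 1L
      cseed <- seed * 100000L + cell_id
      truth <- draw_cell_truth(gt, cseed)
      row <- data.frame(group = groups[gi], genotype = gt$genotype,
                        cell_type = gt$cell_type, cell = cell_id)
      for (f in names(truth)[vapply(truth, is.numeric, logical(1))])
        if (length(truth[[f]]) == 1L) row[[paste0("true_", f)]] <- truth[[f]]
      if ("passive" %in% protocols) {
        g <- generate_current_clamp(gt, "subthreshold", cseed, noise_sd, truth)
        ps <- extract_passive(g$traces)
        row$vr <- ps$vr; row$rn <- ps$rn; row$tau <- ps$tau
      }
      if ("ap" %in% protocols) {
        g <- generate_current_clamp(gt, "ap_steps", cseed, noise_sd, truth)
        ap <- extract_ap_features(g$traces)
        row$ap_threshold <- ap$threshold; row$ap_amplitude <- ap$amplitude
        row$ap_rise <- ap$rise; row$ap_half_width <- ap$half_width
      }
      if ("ramp" %in% protocols) {
        g <- generate_current_clamp(gt, "ramp", cseed, noise_sd, truth)
        row$rheobase <- suppressWarnings(extract_rheobase(g$traces[[1L]]))
      }
      if ("epsc" %in% protocols) {
        g <- generate_vclamp_epsc(gt, epsc_duration, cseed, truth = truth)
        ev <- detect_epscs(g$trace)
        row$epsc_freq <- ev$stats$frequency
        row$epsc_amp <- ev$stats$amplitude
      }
      rows[[cell_id]] <- row
    }
  }
  do.call(rbind, rows)
}
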