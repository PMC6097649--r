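# Extraction of intrinsic-membrane, action-potential and spontaneous-EPSC
# measures from traces, as operationalised for whole-cell recordings:
# Vr from the pre-stimulus baseline; Rn as the slope of the linear portion of
# the steady-state V-I relation; tau from a single-exponential fit to the
# -10 pA response; rheobase from the injected current at the first spike on a
# slow dual ramp; AP features from the second spike of the weakest step with
# >= 3 spikes; EPSCs by threshold-crossing detection at the noise floor.

dvdt <- function(v, dt) c(diff(v) / dt, 0)

# spike upstroke indices: dV/dt >= thresh mV/ms with 1 ms refractory
# grouping. The derivative is taken on a lightly smoothed copy (0.25 ms
# boxcar) so recording noise cannot fake the 20 mV/ms criterion; indices and
# voltages still refer to the raw trace.
spike_onsets <- function(v, dt, thresh = 20, refractory = 1) {
  k <- max(1L, round(0.25 / dt))
  vs <- if (k > 1L) {
    f <- as.numeric(stats::filter(v, rep(1 / k, k), sides = 2))
    f[is.na(f)] <- v[is.na(f)]
    f
  } else v
  dv <- dvdt(vs, dt)
  idx <- which(dv >= thresh)
  if (!length(idx)) return(integer(0))
  keep <- c(TRUE, diff(idx) * dt > refractory)
  idx[keep]
}

steady_window <- function(tr, onset, duration) {
  tt <- trace_time(tr)
  sel <- tt >= onset + 0.75 * duration & tt < onset + duration
  mean(tr$values[sel])
}

#' Extract passive membrane features from subthreshold steps
#'
#' `Vr` is the mean pre-stimulus voltage; `Rn` the slope of the best-fit line
#' through the linear portion of the steady-state V-I relation (the largest
#' |I| point is dropped iteratively until R^2 >= 0.99 or three points
#' remain); `tau` comes from a single-exponential fit to the -10 pA response.
#'
#' @param ts list of voltage [trace]s, each annotated with its step
#'   (`stim = list(onset, duration, amplitude)` in ms/pA).
#' @return list `vr` (mV), `rn` (MOhm), `tau` (ms), plus the V-I table used.
#' @export
extract_passive <- function(ts) {
  if (length(ts) < 3L) stopf("extract_passive: need >= 3 subthreshold steps")
  amps <- vapply(ts, function(tr) tr$stim$amplitude, numeric(1))
  vr <- mean(vapply(ts, function(tr) {
    tt <- trace_time(tr)
    mean(tr$values[tt < tr$stim$onset])
  }, numeric(1)))
  vss <- vapply(ts, function(tr)
    steady_window(tr, tr$stim$onset, tr$stim$duration), numeric(1))
  ord <- order(abs(amps))
  use <- seq_along(amps)
  repeat {
    fit <- stats::lm(vss[use] ~ amps[use])
    if (summary(fit)$r.squared >= 0.99 || length(use) <= 3L) break
    use <- use[-which.max(abs(amps[use]))]
  }
  rn <- unname(stats::coef(fit)[2L]) * 1e3   # mV/pA -> MOhm

  tau <- NA_real_
  i10 <- which(abs(amps + 10) < 1e-6)
  if (!length(i10)) {
    warning("extract_passive: no -10 pA step; tau unavailable")
  } else {
    tr <- ts[[i10[1L]]]
    tt <- trace_time(tr)
    on <- tr$stim$onset
    v0 <- mean(tr$values[tt < on])
    vs <- steady_window(tr, on, tr$stim$duration)
    sel <- tt >= on & tt <= on + tr$stim$duration
    y <- tr$values[sel] - vs
    x <- tt[sel] - on
    # log-linear fit over the first ~4 time constants, seeded by the 63% time
    a0 <- v0 - vs
    t63 <- x[which(abs(y) <= abs(a0) * exp(-1))[1L]]
    if (is.na(t63) || t63 <= 0) t63 <- max(x) / 4
    fitsel <- x <= 4 * t63 & sign(y) == sign(a0) & abs(y) >= 0.1 * abs(a0)
    fit2 <- stats::lm(log(abs(y[fitsel])) ~ x[fitsel])
    tau <- -1 / unname(stats::coef(fit2)[2L])
    # refine by nonlinear least squares (robust to baseline noise)
    tau <- tryCatch({
      nf <- stats::nls(y ~ A * exp(-x / tau_), algorithm = "port",
                       start = list(A = a0,
                                    tau_ = min(max(tau, 0.6), 180)),
                       lower = c(-Inf, 0.5), upper = c(Inf, 200),
                       control = list(warnOnly = TRUE))
      unname(stats::coef(nf)[["tau_"]])
    }, error = function(e) tau, warning = function(w) tau)
  }
  list(vr = vr, rn = rn, tau = tau,
       vi = data.frame(current = amps, voltage = vss,
                       used = seq_along(amps) %in% use))
}

#' Rheobase from a dual current ramp
#'
#' The injected current at the first action-potential threshold crossing on
#' the first ramp that elicits a spike (the steeper second ramp is consulted
#' only if the first stays subthreshold).
#'
#' @param tr voltage [trace] annotated with `stim$segments` (the ramp
#'   waveform) as produced by the synthetic generator or
#'   [stimulus_protocol()].
#' @param dvdt_thresh spike detection threshold, mV/ms.
#' @return rheobase in pA, or `NA` (with a warning) if no spike occurs.
#' @export
extract_rheobase <- function(tr, dvdt_thresh = 20) {
  segs <- tr$stim$segments
  if (is.null(segs)) stopf("extract_rheobase: trace lacks ramp annotation")
  tt <- trace_time(tr)
  sp <- spike_onsets(tr$values, tr$dt, dvdt_thresh)
  if (!length(sp)) {
    warning("extract_rheobase: no spike on either ramp")
    return(NA_real_)
  }
  for (k in seq_len(nrow(segs))) {
    on <- segs$onset[k]; du <- segs$duration[k]
    hit <- sp[tt[sp] >= on & tt[sp] < on + du]
    if (length(hit)) {
      t1 <- tt[hit[1L]]
      frac <- (t1 - on) / du
      return(segs$amp0[k] + frac * (segs$amp1[k] - segs$amp0[k]))
    }
  }
  warning("extract_rheobase: spikes outside annotated ramps")
  NA_real_
}

#' Action-potential features from 200 ms current steps
#'
#' Uses the second evoked spike of the lowest-amplitude step that elicits at
#' least three. Threshold is the voltage where dV/dt first exceeds
#' `dvdt_thresh` before that spike's peak; amplitude is threshold-to-peak;
#' rise is threshold-crossing-to-peak time; fall is peak-to-return-to-
#' threshold-level time; half-width is the duration above half amplitude.
#'
#' @param ts list of voltage [trace]s (200 ms steps).
#' @param dvdt_thresh threshold criterion, mV/ms (default 20).
#' @return list `threshold`, `amplitude` (mV), `rise`, `fall`, `half_width`
#'   (ms), `step` (pA used); all `NA` with a warning when no step qualifies.
#' @export
extract_ap_features <- function(ts, dvdt_thresh = 20) {
  amps <- vapply(ts, function(tr) tr$stim$amplitude, numeric(1))
  counts <- vapply(ts, function(tr) {
    tt <- trace_time(tr)
    sp <- spike_onsets(tr$values, tr$dt, dvdt_thresh)
    sum(tt[sp] >= tr$stim$onset & tt[sp] < tr$stim$onset + tr$stim$duration)
  }, numeric(1))
  ok <- which(counts >= 3)
  if (!length(ok)) {
    warning("extract_ap_features: no step with >= 3 action potentials")
    return(list(threshold = NA_real_, amplitude = NA_real_, rise = NA_real_,
                fall = NA_real_, half_width = NA_real_, step = NA_real_))
  }
  pick <- ok[which.min(amps[ok])]
  tr <- ts[[pick]]
  v <- tr$values; dt <- tr$dt
  sp <- spike_onsets(v, dt, dvdt_thresh)
  s2 <- sp[2L]
  # peak: maximum between this onset and the next onset (or +5 ms)
  lim <- if (length(sp) >= 3L) sp[3L] else min(length(v), s2 + round(5 / dt))
  pk_rel <- which.max(v[s2:lim])
  pk <- s2 + pk_rel - 1L
  thr <- v[s2]
  amp <- v[pk] - thr
  rise <- (pk - s2) * dt
  after <- v[pk:min(length(v), pk + round(10 / dt))]
  below <- which(after <= thr)
  fall <- if (length(below)) (below[1L] - 1L) * dt else NA_real_
  half <- thr + amp / 2
  above <- v[s2:min(length(v), pk + round(10 / dt))] >= half
  half_width <- sum(above) * dt
  list(threshold = thr, amplitude = amp, rise = rise, fall = fall,
       half_width = half_width, step = amps[pick])
}

#' Firing rate versus injected current from 2 s steps
#'
#' @param ts list of voltage [trace]s (2 s steps).
#' @param dvdt_thresh spike criterion, mV/ms.
#' @return data frame `current` (pA), `rate` (Hz).
#' @export
fi_curve <- function(ts, dvdt_thresh = 20) {
  rows <- lapply(ts, function(tr) {
    tt <- trace_time(tr)
    sp <- spike_onsets(tr$values, tr$dt, dvdt_thresh)
    nsp <- sum(tt[sp] >= tr$stim$onset & tt[sp] < tr$stim$onset + tr$stim$duration)
    data.frame(current = tr$stim$amplitude,
               rate = nsp / (tr$stim$duration * 1e-3))
  })
  do.call(rbind, rows)
}

# single-exponential rise/decay time constants of a positive-going averaged
# event sampled at dt (ms)
event_kinetics <- function(avg, dt) {
  pk <- which.max(avg)
  a <- avg[pk]
  decay <- NA_real_
  tailv <- avg[pk:length(avg)]
  sel <- which(tailv > 0.05 * a & tailv <= 0.95 * a)
  if (length(sel) >= 3L) {
    fit <- stats::lm(log(tailv[sel]) ~ I(sel * dt))
    decay <- -1 / unname(stats::coef(fit)[2L])
  }
  rise <- NA_real_
  if (pk >= 3L) {
    head <- avg[1:pk]
    # fit a * (1 - exp(-t/tau)) via log-linear on (a - v)
    sel <- which(head > 0.05 * a & head < 0.95 * a)
    if (length(sel) >= 3L) {
      fit <- stats::lm(log(a - head[sel]) ~ I(sel * dt))
      rise <- -1 / unname(stats::coef(fit)[2L])
    } else {
      # very fast rise relative to sampling: use 20-80% interval
      i20 <- which(head >= 0.2 * a)[1L]; i80 <- which(head >= 0.8 * a)[1L]
      if (!is.na(i20) && !is.na(i80)) rise <- (i80 - i20) * dt / log(4)
    }
  }
  list(rise = rise, decay = decay)
}

#' Detect spontaneous EPSCs in a voltage-clamp current trace
#'
#' Baseline-subtracted threshold-crossing detection: the (inward-negative)
#' current is inverted, lightly smoothed, and local maxima at or above the
#' threshold are taken as events. Peaks closer than two decay constants are
#' counted separately only when each rises at least one threshold above the
#' inter-peak minimum. Rise and decay time constants are fitted on the
#' averaged aligned event; per-event 20-80% rise times are also reported.
#'
#' @param tr a current [trace] (pA) under voltage clamp.
#' @param threshold detection threshold, pA (default 5, the empirical
#'   maximum RMS noise level).
#' @param smooth_ms boxcar width for peak finding, ms.
#' @param tau_decay_guess ms, used only for the peak-separation rule.
#' @return an `epsc_events` object: `events` data frame (`time` s,
#'   `amplitude` pA, `area` pA ms, `rise_2080` ms), summary `stats`
#'   (`frequency` Hz, `amplitude`, `rise`, `decay`, `count`, `threshold`).
#' @export
detect_epscs <- function(tr, threshold = 5, smooth_ms = 0.75,
                         tau_decay_guess = 6) {
  x <- tr$values
  if (!all(is.finite(x))) stopf("detect_epscs: saturated or non-finite trace")
  dt <- tr$dt
  y <- -(x - stats::median(x))
  k <- max(1L, round(smooth_ms / dt))
  ys <- stats::filter(y, rep(1 / k, k), sides = 2)
  ys[is.na(ys)] <- 0
  ys <- as.numeric(ys)
  n <- length(ys)
  loc <- which(ys >= threshold &
                 ys >= c(-Inf, ys[-n]) & ys > c(ys[-1], -Inf))
  if (length(loc) > 1L) {
    # merge near peaks unless separated by a deep enough valley
    keep <- rep(TRUE, length(loc))
    minsep <- 2 * tau_decay_guess
    j <- 1L
    for (i in 2L:length(loc)) {
      if ((loc[i] - loc[j]) * dt < minsep) {
        valley <- min(ys[loc[j]:loc[i]])
        if (min(ys[loc[i]], ys[loc[j]]) - valley < threshold) {
          # same event: keep the larger peak
          if (ys[loc[i]] > ys[loc[j]]) { keep[j] <- FALSE; j <- i }
          else keep[i] <- FALSE
          next
        }
      }
      j <- i
    }
    loc <- loc[keep]
  }
  ev_t <- loc * dt
  amp <- area <- rise2080 <- numeric(length(loc))
  win_pre <- round(10 / dt); win_post <- round(30 / dt)
  for (i in seq_along(loc)) {
    i0 <- max(1L, loc[i] - win_pre); i1 <- min(n, loc[i] + win_post)
    base <- stats::median(y[i0:max(i0, loc[i] - round(2 / dt))])
    amp[i] <- ys[loc[i]] - base
    seg <- y[i0:i1] - base
    area[i] <- sum(pmax(seg, 0)) * dt
    up <- y[i0:loc[i]] - base
    a <- amp[i]
    i20 <- which(up >= 0.2 * a); i80 <- which(up >= 0.8 * a)
    rise2080[i] <- if (length(i20) && length(i80))
      (i80[1L] - i20[1L]) * dt else NA_real_
  }
  sel <- amp >= threshold
  ev_t <- ev_t[sel]; amp <- amp[sel]; area <- area[sel]
  rise2080 <- rise2080[sel]; loc <- loc[sel]
  rise <- decay <- NA_real_
  if (length(loc) >= 1L) {
    wpre <- round(2 / dt); wpost <- round(25 / dt)
    okw <- loc - wpre >= 1L & loc + wpost <= n
    if (any(okw)) {
      mat <- vapply(loc[okw], function(l)
        y[(l - wpre):(l + wpost)] - stats::median(y[max(1L, l - win_pre):(l - round(2 / dt))]),
        numeric(wpre + wpost + 1L))
      avg <- rowMeans(mat)
      kin <- event_kinetics(avg, dt)
      rise <- kin$rise; decay <- kin$decay
    }
  }
  dur_s <- (length(x) - 1L) * dt * 1e-3
  structure(list(
    events = data.frame(time = ev_t * 1e-3, amplitude = amp, area = area,
                        rise_2080 = rise2080),
    stats = list(frequency = length(ev_t) / dur_s,
                 amplitude = if (length(amp)) mean(amp) else NA_real_,
                 rise = rise, decay = decay, count = length(ev_t),
                 threshold = threshold, duration = dur_s)
  ), class = "epsc_events")
}

#' @export
print.epsc_events <- function(x, ...) {
  s <- x$stats
  cat(sprintf("<epsc_events> %d events in %.1f s: %.3g Hz, mean amplitude %.3g pA\n",
              s$count, s$duration, s$frequency, s$amplitude))
  cat(sprintf("  averaged-event kinetics: rise %.3g ms, decay %.3g ms (threshold %g pA)\n",
              s$rise, s$decay, s$threshold))
  invisible(x)
}
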