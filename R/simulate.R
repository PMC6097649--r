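# Time-domain simulation: stimulus protocols, traces, and the simulate()
# front end over the compiled Crank-Nicolson core.

#' Stimulus protocol
#'
#' Describes a current- or voltage-clamp waveform as a baseline plus a set of
#' piecewise-linear (optionally sinusoidally modulated) segments.
#'
#' @param mode `"current"` (pA) or `"voltage"` (mV).
#' @param tstop total duration, ms.
#' @param dt integration time step, ms (default 0.05).
#' @param hold baseline value (pA or mV; default 0 pA / first segment value).
#' @param segments data frame with columns `onset`, `duration` (ms), `amp0`,
#'   `amp1` (segment start/end amplitude added to the baseline; equal values
#'   give a step, unequal a ramp) and optionally `freq` (Hz; if nonzero the
#'   segment contributes `amp * sin(2 pi f (t - onset))`).
#' @param site stimulus site: `"soma"` or a compartment index.
#' @param sample_every record every k-th step (default 1).
#' @return object of class `stimulus_protocol`.
#' @export
stimulus_protocol <- function(mode = c("current", "voltage"), tstop,
                              dt = 0.05, hold = 0, segments = NULL,
                              site = "soma", sample_every = 1L) {
  mode <- match.arg(mode)
  if (dt <= 0) stopf("stimulus_protocol: dt must be > 0")
  if (tstop <= 0) stopf("stimulus_protocol: tstop must be > 0")
  if (!is.null(segments)) {
    need <- c("onset", "duration", "amp0", "amp1")
    if (!all(need %in% names(segments)))
      stopf("stimulus_protocol: segments needs columns %s",
            paste(need, collapse = ", "))
    if (any(segments$duration < 0) || is.unsorted(segments$onset))
      stopf("stimulus_protocol: segment times must be monotone with duration >= 0")
  }
  structure(list(mode = mode, tstop = tstop, dt = dt, hold = hold,
                 segments = segments, site = site,
                 sample_every = as.integer(sample_every)),
            class = "stimulus_protocol")
}

# evaluate the protocol waveform at arbitrary times (ms)
proto_value <- function(proto, t) {
  v <- rep(proto$hold, length(t))
  segs <- proto$segments
  if (!is.null(segs)) {
    for (k in seq_len(nrow(segs))) {
      on <- segs$onset[k]; du <- segs$duration[k]
      inwin <- t >= on & t < on + du
      if (!any(inwin)) next
      frac <- (t[inwin] - on) / max(du, .Machine$double.eps)
      amp <- segs$amp0[k] + frac * (segs$amp1[k] - segs$amp0[k])
      f <- if (!is.null(segs$freq)) segs$freq[k] else 0
      if (isTRUE(f > 0)) amp <- amp * sin(2 * pi * f * (t[inwin] - on) * 1e-3)
      v[inwin] <- v[inwin] + amp
    }
  }
  v
}

new_trace <- function(values, dt, unit, stim = NULL, site = NA) {
  structure(list(values = values, dt = dt, unit = unit, stim = stim,
                 site = site), class = "trace")
}

#' @export
print.trace <- function(x, ...) {
  cat(sprintf("<trace> %d samples @ dt %.4g ms (%.4g ms), unit %s\n",
              length(x$values), x$dt, (length(x$values) - 1) * x$dt, x$unit))
  invisible(x)
}

trace_time <- function(tr) seq(0, by = tr$dt, length.out = length(tr$values))

#' Simulate a compartmental model under a stimulus protocol
#'
#' Second-order implicit (Crank-Nicolson) integration of the branched RC
#' network with a tree-structured direct solve per step. Voltage clamp is
#' ideal (zero series resistance): the clamped node follows the command and
#' the electrode current is recorded.
#'
#' @param model a [build_model()] result.
#' @param proto a [stimulus_protocol()].
#' @param record compartment indices (or `"soma"`) whose voltage to record.
#' @param synapses optional [place_synapses()] result.
#' @param syn_params optional [synapse_params()] used for all synapses.
#' @param events optional data frame of synaptic activations with columns
#'   `synapse` (row index into `synapses`) and `time` (ms).
#' @param init `"steady"` (default: relax to the protocol's t = 0 state),
#'   `"el"` (start at the leak reversal), or a numeric vector of initial
#'   voltages.
#' @return a list of class `simulation`: `v` (list of voltage [trace]s, mV),
#'   `i_clamp` (clamp-current [trace], pA, when voltage clamped), `t` (ms).
#' @export
simulate_model <- function(model, proto, record = "soma", synapses = NULL,
                           syn_params = NULL, events = NULL, init = "steady") {
  stopifnot(inherits(model, "compartmental_model"),
            inherits(proto, "stimulus_protocol"))
  n <- length(model$parent)
  site <- if (identical(proto$site, "soma")) 1L else as.integer(proto$site)
  if (site < 1L || site > n) stopf("simulate_model: stimulus site %d not in model", site)
  rec <- vapply(record, function(r) if (identical(r, "soma")) 1L else as.integer(r),
                integer(1))
  nstep <- ceiling(proto$tstop / proto$dt)
  tmid <- (seq_len(nstep) - 0.5) * proto$dt
  tsamp <- seq(0, nstep, by = 1) * proto$dt
  wave_mid <- proto_value(proto, tmid)

  if (proto$mode == "current") {
    stim <- wave_mid * 1e-3          # pA -> nA
    clamp_node <- -1L; clamp_v <- numeric(0)
  } else {
    stim <- numeric(0)
    clamp_node <- site - 1L
    clamp_v <- proto_value(proto, tsamp)
  }

  if (!is.null(synapses) && nrow(synapses) > 0) {
    sp <- syn_params %||% synapse_params()
    syn_node <- synapses$comp - 1L
    ns <- nrow(synapses)
    syn_gmax <- rep(sp$g_max * 1e-3, ns)   # nS -> uS
    syn_tr <- rep(sp$tau_rise, ns); syn_td <- rep(sp$tau_decay, ns)
    syn_erev <- rep(sp$e_rev, ns)
    if (is.null(events) || nrow(events) == 0L) {
      ev_syn <- integer(0); ev_step <- integer(0)
    } else {
      ord <- order(events$time)
      ev_syn <- as.integer(events$synapse[ord]) - 1L
      ev_step <- as.integer(floor(events$time[ord] / proto$dt))
    }
  } else {
    syn_node <- integer(0); syn_gmax <- syn_tr <- syn_td <- syn_erev <- numeric(0)
    ev_syn <- integer(0); ev_step <- integer(0)
  }

  v0 <- if (identical(init, "steady")) {
    if (proto$mode == "voltage")
      .cable_steady(model$parent - 1L, model$g_axial, model$g_leak,
                    model$e_leak, clamp_node, clamp_v[1L], integer(0), numeric(0))
    else
      .cable_steady(model$parent - 1L, model$g_axial, model$g_leak,
                    model$e_leak, -1L, 0, site - 1L,
                    proto_value(proto, 0) * 1e-3)
  } else if (identical(init, "el")) {
    model$e_leak
  } else rep_len(as.numeric(init), n)

  out <- .cable_sim(model$parent - 1L, model$g_axial, model$g_leak, model$cap,
                    model$e_leak, proto$dt, nstep, site - 1L, stim,
                    clamp_node, clamp_v, syn_node, syn_gmax, syn_tr, syn_td,
                    syn_erev, ev_syn, ev_step, rec - 1L, proto$sample_every,
                    v0)
  dts <- proto$dt * proto$sample_every
  vtr <- lapply(seq_along(rec), function(r)
    new_trace(out$v[r, ], dts, "mV", stim = proto, site = rec[r]))
  names(vtr) <- paste0("comp", rec)
  res <- list(v = vtr, t = seq(0, by = dts, length.out = ncol(out$v)))
  if (proto$mode == "voltage")
    res$i_clamp <- new_trace(out$i_clamp * 1e3, dts, "pA", stim = proto,
                             site = site)
  class(res) <- "simulation"
  res
}

#' @export
print.simulation <- function(x, ...) {
  cat(sprintf("<simulation> %d voltage trace(s), %d samples%s\n",
              length(x$v), length(x$t),
              if (!is.null(x$i_clamp)) ", with clamp current" else ""))
  invisible(x)
}
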