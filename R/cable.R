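# Discretization of a morphology into a passive compartmental model.

#' Passive membrane parameters
#'
#' Defaults are the fitted medium-spiny-neuron values: specific capacitance
#' 0.9 uF/cm^2, axial resistivity 100 Ohm cm, specific membrane resistance
#' 17.3 kOhm cm^2 and leak reversal -84.4 mV, giving a membrane time constant
#' `tau_m = Rm * Cm` of 15.57 ms.
#'
#' @param cm specific membrane capacitance, uF/cm^2.
#' @param ra axial resistivity, Ohm cm.
#' @param rm specific membrane resistance, kOhm cm^2.
#' @param el leak reversal potential, mV.
#' @return object of class `passive_params` with derived `tau_m` (ms).
#' @export
passive_params <- function(cm = 0.9, ra = 100, rm = 17.3, el = -84.4) {
  if (cm <= 0 || ra <= 0 || rm <= 0)
    stopf("passive_params: cm, ra, rm must be positive")
  structure(list(cm = cm, ra = ra, rm = rm, el = el, tau_m = rm * cm),
            class = "passive_params")
}

#' @export
print.passive_params <- function(x, ...) {
  cat(sprintf("<passive_params> Cm %.3g uF/cm2, Ra %.4g Ohm cm, Rm %.4g kOhm cm2, EL %.4g mV (tau_m %.4g ms)\n",
              x$cm, x$ra, x$rm, x$el, x$tau_m))
  invisible(x)
}

#' DC electrotonic length constant of a cylinder
#'
#' `lambda_DC = sqrt(Rm d / (4 Ra))`, returned in um for diameter in um.
#' @param d diameter, um.
#' @param p [passive_params()].
#' @return length constant, um.
#' @export
lambda_dc <- function(d, p = passive_params()) {
  # Rm kOhm cm2 -> Ohm cm2; d um -> cm; result cm -> um
  sqrt((p$rm * 1e3) * (d * 1e-4) / (4 * p$ra)) * 1e4
}

# Frequency-dependent length constant: lambda(f) = lambda_DC / Re sqrt(1 + i w tau)
lambda_f <- function(d, f, p = passive_params()) {
  q <- sqrt(complex(real = 1, imaginary = 2 * pi * f * p$tau_m * 1e-3))
  lambda_dc(d, p) / Re(q)
}

#' Build a passive compartmental model
#'
#' Each section is split into the smallest odd number of equal-arc
#' compartments whose length does not exceed 1/100 of that section's
#' electrotonic length constant at 100 Hz (computed from its length-weighted
#' mean diameter). The soma is a single isopotential spherical compartment.
#' Membrane area is conserved exactly: compartment areas are sums of the
#' morphology's own tapered-cylinder pieces.
#'
#' @param m a [morphology()].
#' @param p [passive_params()].
#' @param lambda_fraction maximum compartment length as a fraction of
#'   lambda(100 Hz) (default 1/100).
#' @return object of class `compartmental_model`: compartment vectors
#'   (`parent`, `g_axial` uS, `g_leak` uS, `cap` nF, `area` cm^2, `e_leak`
#'   mV), a compartment map (`section`, `pos`, `path_dist`), per-section
#'   compartment counts, and the source morphology.
#' @export
build_model <- function(m, p = passive_params(), lambda_fraction = 0.01) {
  validate_morphology(m)
  r_cm <- m$soma$diameter / 2 * 1e-4
  soma_area <- 4 * pi * r_cm^2                       # cm^2
  parent <- 0L; area <- soma_area
  sec_id <- 0L; pos <- 0.5; path <- 0
  g_ax <- 0
  r_half_dist <- NA_real_  # axial half-resistance (MOhm) at distal face
  last_comp <- integer(length(m$sections))
  r_half_last <- numeric(length(m$sections))
  n_per_sec <- integer(length(m$sections))
  off <- section_path_offsets(m)

  for (i in seq_along(m$sections)) {
    s <- m$sections[[i]]
    pts <- s$points
    l <- seg_lengths(pts[, 1:3, drop = FALSE])      # um
    L <- sum(l)
    dbar <- sum((pts[-1, 4] + pts[-nrow(pts), 4]) / 2 * l) / L
    lam100 <- lambda_f(dbar, 100, p)
    nc <- max(1L, as.integer(ceiling(L / (lambda_fraction * lam100))))
    if (nc %% 2L == 0L) nc <- nc + 1L
    n_per_sec[i] <- nc
    # split arc into nc equal pieces; interpolate diameter linearly in arc
    cuml <- c(0, cumsum(l))
    bounds <- seq(0, L, length.out = nc + 1L)
    dia_at <- stats::approx(cuml, pts[, 4], xout = bounds)$y
    # area and axial resistance per compartment by exact piecewise integration
    brk <- sort(unique(c(cuml, bounds)))
    piece_d0 <- stats::approx(cuml, pts[, 4], xout = brk[-length(brk)])$y
    piece_d1 <- stats::approx(cuml, pts[, 4], xout = brk[-1])$y
    piece_l <- diff(brk)
    comp_of_piece <- pmin(nc, findInterval(brk[-length(brk)] + piece_l / 2, bounds))
    a_piece <- pi * (piece_d0 + piece_d1) / 2 * piece_l * 1e-8   # cm^2
    # axial R of a linearly tapering piece: 4 Ra l / (pi d0 d1), Ohm
    r_piece <- 4 * p$ra * (piece_l * 1e-4) / (pi * piece_d0 * piece_d1 * 1e-8)
    a_comp <- vapply(seq_len(nc), function(k) sum(a_piece[comp_of_piece == k]), numeric(1))
    r_comp <- vapply(seq_len(nc), function(k) sum(r_piece[comp_of_piece == k]), numeric(1)) * 1e-6  # MOhm
    prox_comp <- if (s$parent == 0L) 1L else last_comp[s$parent]
    prox_rhalf <- if (s$parent == 0L) 0 else r_half_last[s$parent]
    for (k in seq_len(nc)) {
      parent <- c(parent, prox_comp)
      area <- c(area, a_comp[k])
      # coupling resistance: half of this compartment + half of the proximal one
      g_ax <- c(g_ax, 1 / (r_comp[k] / 2 + prox_rhalf))
      sec_id <- c(sec_id, i)
      pos <- c(pos, (k - 0.5) / nc)
      path <- c(path, off[i] + (bounds[k] + bounds[k + 1L]) / 2)
      prox_comp <- length(parent)
      prox_rhalf <- r_comp[k] / 2
    }
    last_comp[i] <- length(parent)
    r_half_last[i] <- r_comp[nc] / 2
  }
  g_leak <- area / p$rm * 1e3                # uS (area/rm in mS)
  cap <- p$cm * area * 1e3                   # nF
  structure(list(
    parent = as.integer(parent), g_axial = g_ax, g_leak = g_leak, cap = cap,
    area = area, e_leak = rep(p$el, length(area)),
    map = data.frame(section = as.integer(sec_id), pos = pos, path_dist = path),
    n_per_section = n_per_sec,
    params = p, morphology = m
  ), class = "compartmental_model")
}

#' @export
print.compartmental_model <- function(x, ...) {
  cat(sprintf("<compartmental_model> %d compartments over %d sections (+ soma)\n",
              length(x$parent) - 1L, length(x$n_per_section)))
  cat(sprintf("  membrane area %.4g cm^2, R_in(DC, soma) %.4g MOhm\n",
              sum(x$area), input_resistance(x)))
  invisible(x)
}

#' Total membrane surface of a model or morphology (um^2)
#' @param x a `compartmental_model` or [morphology()].
#' @return surface area in um^2.
#' @export
surface_area <- function(x) {
  if (inherits(x, "compartmental_model")) return(sum(x$area) * 1e8)
  validate_morphology(x)
  r <- x$soma$diameter / 2
  4 * pi * r^2 + sum(vapply(x$sections, function(s)
    frusta_area(s$points[, 1:3, drop = FALSE], s$points[, 4]), numeric(1)))
}

#' DC input resistance at a compartment (MOhm)
#'
#' Solves the steady-state conductance system for a small test current.
#' @param model a `compartmental_model`.
#' @param comp compartment index (default 1 = soma).
#' @return input resistance, MOhm.
#' @export
input_resistance <- function(model, comp = 1L) {
  v0 <- .cable_steady(model$parent - 1L, model$g_axial, model$g_leak,
                      model$e_leak, -1L, 0, integer(0), numeric(0))
  inj <- 0.01  # nA
  v1 <- .cable_steady(model$parent - 1L, model$g_axial, model$g_leak,
                      model$e_leak, -1L, 0, comp - 1L, inj)
  (v1[comp] - v0[comp]) / inj  # mV / nA = MOhm
}

# map an arc position on a section to the nearest compartment index
comp_at <- function(model, section, pos) {
  idx <- which(model$map$section == section)
  idx[which.min(abs(model$map$pos[idx] - pos))]
}

soma_steady_state <- function(model, clamp = NULL) {
  .cable_steady(model$parent - 1L, model$g_axial, model$g_leak, model$e_leak,
                if (is.null(clamp)) -1L else 0L,
                if (is.null(clamp)) 0 else clamp, integer(0), numeric(0))
}
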