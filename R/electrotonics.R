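# Frequency-domain analysis of a passive dendritic tree: complex input and
# transfer impedances by the hyperbolic (sealed-end cable) recursion, log
# voltage attenuation inward/outward, mean attenuation profiles over
# frequency, and the morphoelectrotonic transform.
#
# The closed-form recursion over the morphology's tapered-cylinder segments
# is the primary computation; the discretized compartment model serves as an
# independent time-domain oracle in the test-suite.

# per-segment cable constants at frequency f (Hz) for diameters d (um)
cable_constants <- function(d, f, p) {
  q <- sqrt(complex(real = 1, imaginary = 2 * pi * f * p$tau_m * 1e-3))
  lam <- lambda_dc(d, p) * 1e-4                     # cm
  rinf <- (2 / pi) * sqrt(p$rm * 1e3 * p$ra) / (d * 1e-4)^1.5 * 1e-6  # MOhm
  list(gamma = q / lam, zinf = rinf / q)            # per cm, MOhm
}

fold_cable <- function(zl, gamma, l, zinf) {
  th <- tanh(gamma * l)
  if (is.infinite(Re(zl)) || is.infinite(Mod(zl))) return(zinf / th)
  zinf * (zl + zinf * th) / (zinf + zl * th)
}

tfac_cable <- function(zl, gamma, l, zinf) {
  gl <- gamma * l
  if (is.infinite(Re(zl)) || is.infinite(Mod(zl))) return(1 / cosh(gl))
  zl / (zl * cosh(gl) + zinf * sinh(gl))
}

par_z <- function(zs) 1 / sum(vapply(zs, function(z) 1 / z, complex(1)))

etone_sections <- function(m, p) {
  lapply(m$sections, function(s) {
    pts <- s$points
    l <- seg_lengths(pts[, 1:3, drop = FALSE]) * 1e-4   # cm
    d <- (pts[-1, 4] + pts[-nrow(pts), 4]) / 2          # um
    list(parent = s$parent, l = l, d = d)
  })
}

#' Complex impedance map of a passive dendritic tree
#'
#' Computes, at one signal frequency, the complex input impedance `z_in` and
#' soma transfer impedance `z_tr` at every traced point of the tree, together
#' with inward and outward log attenuations, using the sealed-end hyperbolic
#' cable recursion (length and diameter of every segment enter the
#' calculation). The soma is an isopotential RC membrane at the root.
#'
#' @param model a [build_model()] result (or a [morphology()] plus `params`).
#' @param f signal frequency, Hz (>= 0).
#' @param params [passive_params()]; defaults to the model's.
#' @return an `impedance_map`: data frame (`section`, `node`, `path_dist`,
#'   `is_tip`, `z_in`, `z_tr` in complex MOhm, `l_in`, `l_out` in log units)
#'   with attributes `z_soma` (whole-cell somatic input impedance) and
#'   `frequency`.
#' @export
impedance_tree <- function(model, f, params = NULL) {
  if (f < 0) stopf("impedance_tree: f must be >= 0")
  m <- if (inherits(model, "compartmental_model")) model$morphology else model
  p <- params %||% (if (inherits(model, "compartmental_model")) model$params
                    else passive_params())
  secs <- etone_sections(m, p)
  ns <- length(secs)
  kids <- section_children(m)
  off <- section_path_offsets(m)
  omega_tau <- 2 * pi * f * p$tau_m * 1e-3
  soma_area <- 4 * pi * (m$soma$diameter / 2 * 1e-4)^2
  z_soma_memb <- (p$rm * 1e3 / soma_area) * 1e-6 /
    complex(real = 1, imaginary = omega_tau)

  cc <- lapply(secs, function(s) cable_constants(s$d, f, p))
  # downward pass: zdown[[s]][j + 1] = impedance looking distal from node j
  # (node 0 = proximal attachment), j = 0..k
  zdown <- vector("list", ns)
  for (s in rev(seq_len(ns))) {
    k <- length(secs[[s]]$l)
    zd <- vector("complex", k + 1L)
    zd[k + 1L] <- if (length(kids[[s]]))
      par_z(lapply(kids[[s]], function(cs) zdown[[cs]][1L]))
    else complex(real = Inf)
    for (j in k:1) {
      zd[j] <- fold_cable(zd[j + 1L], cc[[s]]$gamma[j], secs[[s]]$l[j],
                          cc[[s]]$zinf[j])
    }
    zdown[[s]] <- zd
  }
  roots <- which(vapply(secs, `[[`, numeric(1), "parent") == 0L)
  z_root <- par_z(c(list(z_soma_memb),
                    lapply(roots, function(s) zdown[[s]][1L])))

  # upward pass + transfer chains (root to leaves; sections parents-first)
  zup <- vector("list", ns)       # zup[[s]][j + 1]: looking proximal from node j
  cumTd <- vector("list", ns)     # outward transfer soma -> node j
  cumTu <- vector("list", ns)     # inward transfer node j -> soma
  z_other <- vector("complex", ns)
  for (s in seq_len(ns)) {
    par <- secs[[s]]$parent
    if (par == 0L) {
      others <- setdiff(roots, s)
      z_other[s] <- par_z(c(list(z_soma_memb),
                            lapply(others, function(o) zdown[[o]][1L])))
      td0 <- 1 + 0i; tu0 <- 1 + 0i
    } else {
      sibs <- setdiff(kids[[par]], s)
      kp <- length(secs[[par]]$l)
      z_other[s] <- par_z(c(list(zup[[par]][kp + 1L]),
                            lapply(sibs, function(o) zdown[[o]][1L])))
      td0 <- cumTd[[par]][kp + 1L]
      tu0 <- cumTu[[par]][kp + 1L]
    }
    k <- length(secs[[s]]$l)
    zu <- vector("complex", k + 1L); zu[1L] <- z_other[s]
    td <- vector("complex", k + 1L); td[1L] <- td0
    tu <- vector("complex", k + 1L); tu[1L] <- tu0
    for (j in seq_len(k)) {
      g <- cc[[s]]$gamma[j]; l <- secs[[s]]$l[j]; zi <- cc[[s]]$zinf[j]
      zu[j + 1L] <- fold_cable(zu[j], g, l, zi)
      td[j + 1L] <- td[j] * tfac_cable(zdown[[s]][j + 1L], g, l, zi)
      tu[j + 1L] <- tu[j] * tfac_cable(zu[j], g, l, zi)
    }
    zup[[s]] <- zu; cumTd[[s]] <- td; cumTu[[s]] <- tu
  }

  rows <- lapply(seq_len(ns), function(s) {
    k <- length(secs[[s]]$l)
    cum <- cumsum(secs[[s]]$l) * 1e4
    zin <- vapply(seq_len(k), function(j) {
      zd <- zdown[[s]][j + 1L]
      if (is.infinite(Re(zd)) || is.infinite(Mod(zd))) zup[[s]][j + 1L]
      else par_z(list(zup[[s]][j + 1L], zd))
    }, complex(1))
    data.frame(section = s, node = seq_len(k), path_dist = off[s] + cum,
               is_tip = length(kids[[s]]) == 0L & seq_len(k) == k,
               z_in = zin,
               z_tr = z_root * cumTd[[s]][-1L],
               l_out = -log(Mod(cumTd[[s]][-1L])),
               l_in = -log(Mod(cumTu[[s]][-1L])))
  })
  out <- do.call(rbind, rows)
  structure(out, class = c("impedance_map", "data.frame"),
            z_soma = z_root, frequency = f)
}

#' Log voltage attenuation at every traced point
#'
#' Outward: `L = ln |V(soma)/V(x)|` for a sustained sinusoidal source at the
#' soma. Inward: `L = ln |V(x)/V(soma)|` for a source at `x`. Both follow
#' from the two-port relation `V_target / V_source = Z_tr / Z_in(source)`.
#'
#' @param model a [build_model()] result or [morphology()].
#' @param f frequency, Hz.
#' @param direction `"inward"` or `"outward"`.
#' @param params optional [passive_params()].
#' @return data frame `section`, `node`, `path_dist`, `is_tip`, `L`.
#' @export
attenuation <- function(model, f, direction = c("inward", "outward"),
                        params = NULL) {
  direction <- match.arg(direction)
  im <- impedance_tree(model, f, params)
  data.frame(section = im$section, node = im$node, path_dist = im$path_dist,
             is_tip = im$is_tip,
             L = if (direction == "inward") im$l_in else im$l_out)
}

#' Mean inward/outward attenuation over a frequency grid
#'
#' Averages the log attenuation over all root-to-tip paths (one value per
#' terminal tip; default) or over all traced points, for each frequency.
#'
#' @param model a [build_model()] result or [morphology()].
#' @param frequencies Hz grid (default 0 to 500 in 25 Hz steps).
#' @param scheme `"tips"` (default) or `"points"` averaging.
#' @param params optional [passive_params()].
#' @return an `attenuation_profile`: data frame (`frequency`, `l_in`,
#'   `l_out`) with the averaging `scheme` as an attribute.
#' @export
mean_attenuation_profile <- function(model, frequencies = seq(0, 500, by = 25),
                                     scheme = c("tips", "points"),
                                     params = NULL) {
  scheme <- match.arg(scheme)
  if (!length(frequencies)) stopf("mean_attenuation_profile: empty frequency grid")
  if (any(frequencies < 0 | frequencies > 500))
    stopf("mean_attenuation_profile: frequencies must lie in [0, 500] Hz")
  rows <- lapply(frequencies, function(f) {
    im <- impedance_tree(model, f, params)
    sel <- if (scheme == "tips") im$is_tip else rep(TRUE, nrow(im))
    data.frame(frequency = f, l_in = mean(im$l_in[sel]),
               l_out = mean(im$l_out[sel]))
  })
  structure(do.call(rbind, rows),
            class = c("attenuation_profile", "data.frame"), scheme = scheme)
}

#' @export
plot.attenuation_profile <- function(x, ...) {
  graphics::matplot(x$frequency, cbind(x$l_in, x$l_out), type = "b",
                    pch = c(16, 1), lty = 1, xlab = "frequency (Hz)",
                    ylab = "mean log attenuation", ...)
  graphics::legend("topleft", c("inward", "outward"), pch = c(16, 1), lty = 1,
                   col = 1:2, bty = "n")
  invisible(x)
}

#' Morphoelectrotonic transform
#'
#' Returns a morphology with the same topology and diameters in which every
#' segment is redrawn with length equal to its incremental log attenuation
#' (times `scale`), so physical distance is replaced by electrotonic
#' distance. Log attenuations add along paths, so a tip's drawn path length
#' equals its total attenuation.
#'
#' @param model a [build_model()] result or [morphology()].
#' @param f frequency, Hz.
#' @param direction `"inward"` or `"outward"`.
#' @param scale um drawn per log-attenuation unit (default 100).
#' @param params optional [passive_params()].
#' @return a [morphology()] (zero-length segments permitted).
#' @export
met_transform <- function(model, f, direction = c("inward", "outward"),
                          scale = 100, params = NULL) {
  direction <- match.arg(direction)
  m <- if (inherits(model, "compartmental_model")) model$morphology else model
  att <- attenuation(model, f, direction, params)
  Lsec <- split(att$L, att$section)
  new_secs <- vector("list", length(m$sections))
  for (s in seq_along(m$sections)) {
    pts <- m$sections[[s]]$points
    par <- m$sections[[s]]$parent
    L <- Lsec[[as.character(s)]]
    L0 <- if (par == 0L) 0 else {
      Lp <- Lsec[[as.character(par)]]
      Lp[length(Lp)]
    }
    dL <- diff(c(L0, L)) * scale
    dL[dL < 0] <- 0
    start <- if (par == 0L) m$soma$center
             else new_secs[[par]]$points[nrow(new_secs[[par]]$points), 1:3]
    dirs <- pts[-1L, 1:3, drop = FALSE] - pts[-nrow(pts), 1:3, drop = FALSE]
    lens <- sqrt(rowSums(dirs^2))
    dirs <- dirs / pmax(lens, .Machine$double.eps)
    new_pts <- matrix(0, nrow(pts), 4L)
    new_pts[1L, ] <- c(start, pts[1L, 4L])
    for (j in seq_len(nrow(dirs)))
      new_pts[j + 1L, ] <- c(new_pts[j, 1:3] + dirs[j, ] * dL[j], pts[j + 1L, 4L])
    new_secs[[s]] <- list(parent = par, points = new_pts)
  }
  out <- structure(list(soma = m$soma, sections = new_secs),
                   class = "morphology")
  attr(out, "electrotonic") <- list(frequency = f, direction = direction,
                                    scale = scale)
  out
}
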