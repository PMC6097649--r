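# Dendritic spine sub-typing, density profiles, and Vglut1/Vglut2 apposition
# calling. Classification rules: thin (head diameter <= 0.6 um), mushroom
# (> 0.6 um), stubby (no neck), filopodium (total length > 3 um), with
# filopodium taking precedence (it is defined purely by length) and stubby
# before the head-diameter split. Quantification starts 20 um from the soma
# (the aspinous proximal zone). A punctum is an apposition when its xy
# footprint overlaps a structure through at least three consecutive optical
# slices; ties are resolved head > neck > shaft so each punctum counts once.

#' Spine classifier configuration
#' @param head_boundary thin/mushroom head-diameter boundary, um (0.6,
#'   inclusive for thin).
#' @param filopodium_length length threshold, um (exclusive, > 3).
#' @param proximal_exclusion um of dendrite next to the soma excluded (20).
#' @param filopodia_first if `TRUE` (default) the length rule precedes the
#'   neck rule.
#' @return list of class `spine_classifier_config`.
#' @export
spine_classifier_config <- function(head_boundary = 0.6,
                                    filopodium_length = 3,
                                    proximal_exclusion = 20,
                                    filopodia_first = TRUE) {
  stopifnot(head_boundary > 0, filopodium_length > 0, proximal_exclusion > 0)
  structure(list(head_boundary = head_boundary,
                 filopodium_length = filopodium_length,
                 proximal_exclusion = proximal_exclusion,
                 filopodia_first = filopodia_first),
            class = "spine_classifier_config")
}

#' Classify dendritic spines
#'
#' @param spines data frame with `head_diameter` (um), `neck` (logical),
#'   `length` (um). Records with missing fields are dropped with a message.
#' @param cfg a [spine_classifier_config()].
#' @return the data frame with a `subtype` column (`thin`, `mushroom`,
#'   `stubby`, `filopodia`).
#' @export
classify_spines <- function(spines, cfg = spine_classifier_config()) {
  need <- c("head_diameter", "neck", "length")
  miss <- !stats::complete.cases(spines[, need])
  if (any(miss)) {
    message(sprintf("classify_spines: rejected %d records with missing fields",
                    sum(miss)))
    spines <- spines[!miss, ]
  }
  lab <- ifelse(spines$head_diameter > cfg$head_boundary, "mushroom", "thin")
  if (cfg$filopodia_first) {
    lab[!spines$neck] <- "stubby"
    lab[spines$length > cfg$filopodium_length] <- "filopodia"
  } else {
    lab[spines$length > cfg$filopodium_length] <- "filopodia"
    lab[!spines$neck] <- "stubby"
  }
  spines$subtype <- lab
  spines
}

#' Spine densities and distance-binned counts
#'
#' Densities are counts per um of analysed dendrite (total length minus the
#' proximal exclusion); counts are also binned by path distance from the
#' soma.
#'
#' @param spines classified spine data frame (needs `path_dist`, `subtype`).
#' @param dendrite_length um (must exceed the proximal exclusion).
#' @param bin_width um (default 10).
#' @param cfg a [spine_classifier_config()].
#' @return list `density` (total and per subtype, spines/um), `bins`
#'   (data frame `from`, `to`, `count`).
#' @export
spine_density <- function(spines, dendrite_length, bin_width = 10,
                          cfg = spine_classifier_config()) {
  excl <- cfg$proximal_exclusion
  if (dendrite_length <= excl)
    stopf("spine_density: dendrite length must exceed the %g um proximal exclusion", excl)
  eff <- dendrite_length - excl
  subtypes <- c("thin", "mushroom", "stubby", "filopodia")
  dens <- c(total = nrow(spines) / eff,
            vapply(subtypes, function(s) sum(spines$subtype == s) / eff,
                   numeric(1)))
  brk <- seq(excl, dendrite_length + bin_width, by = bin_width)
  cnt <- vapply(seq_len(length(brk) - 1L), function(k)
    sum(spines$path_dist >= brk[k] & spines$path_dist < brk[k + 1L]),
    numeric(1))
  list(density = dens,
       bins = data.frame(from = brk[-length(brk)], to = brk[-1L],
                         count = cnt))
}

#' Apposition-calling configuration
#' @param min_slices consecutive optical z-slices of overlap required (3).
#' @param xy_tolerance extra xy contact distance, um.
#' @param z_thickness optical slice thickness, um (0.17).
#' @return list of class `apposition_config`.
#' @export
apposition_config <- function(min_slices = 3L, xy_tolerance = 0.05,
                              z_thickness = 0.17) {
  stopifnot(min_slices >= 1L)
  structure(list(min_slices = as.integer(min_slices),
                 xy_tolerance = xy_tolerance, z_thickness = z_thickness),
            class = "apposition_config")
}

#' Call Vglut1/Vglut2 appositions onto shaft, spine heads and necks
#'
#' A punctum is an apposition to a structure iff their xy footprints overlap
#' (centre distance at most the sum of radii plus tolerance) through at least
#' `min_slices` consecutive z-slices; each punctum is assigned to one
#' compartment with precedence head > neck > shaft.
#'
#' @param spines classified spine data frame with geometry columns
#'   (`path_dist`, `head_x`, `head_y`, `head_diameter`, `neck`, `length`).
#' @param puncta data frame: `channel` (`Vglut1`/`Vglut2`), `x`, `y` (um),
#'   `z_lo`, `z_hi` (slice index range), `radius` (um). Rows without z spans
#'   are rejected with a message.
#' @param geometry list: `length` (analysed dendrite length, um),
#'   `shaft_radius` (um), `shaft_z` (slice index range of the shaft,
#'   length-2), `offset` (analysed region start, default 20).
#' @param cfg an [apposition_config()].
#' @return an `apposition_report`: per-channel counts and densities on
#'   shaft/head/neck, per-subtype head-apposition fractions, and the
#'   Vglut1:Vglut2 ratio.
#' @export
call_appositions <- function(spines, puncta, geometry,
                             cfg = apposition_config()) {
  bad <- !is.finite(puncta$z_lo) | !is.finite(puncta$z_hi) |
    puncta$z_hi < puncta$z_lo
  if (any(bad)) {
    message(sprintf("call_appositions: rejected %d puncta without valid z spans",
                    sum(bad)))
    puncta <- puncta[!bad, ]
  }
  off <- geometry$offset %||% 20
  eff_len <- geometry$length - off
  shaft_z <- geometry$shaft_z %||% c(-3L, 3L)
  tol <- cfg$xy_tolerance
  # z overlap in consecutive slices: structures are in focus throughout their
  # own span, so the run length is the size of the span intersection
  z_overlap <- function(lo1, hi1, lo2, hi2)
    pmax(0L, pmin(hi1, hi2) - pmax(lo1, lo2) + 1L)

  n <- nrow(puncta)
  target <- rep("none", n)
  spine_hit <- rep(NA_integer_, n)
  for (i in seq_len(n)) {
    p <- puncta[i, ]
    # heads
    if (nrow(spines)) {
      dxy <- sqrt((spines$head_x - p$x)^2 + (spines$head_y - p$y)^2)
      okz <- z_overlap(p$z_lo, p$z_hi, shaft_z[1L], shaft_z[2L]) >= cfg$min_slices
      hit <- which(dxy <= spines$head_diameter / 2 + p$radius + tol & okz)
      if (length(hit)) { target[i] <- "head"; spine_hit[i] <- hit[1L]; next }
      # necks: midpoint between shaft surface and head base, small radius
      has_neck <- spines$neck
      nx <- spines$head_x
      ny <- (spines$head_y + sign(spines$head_y) * geometry$shaft_radius) / 2
      dxy <- sqrt((nx - p$x)^2 + (ny - p$y)^2)
      hit <- which(has_neck & dxy <= 0.1 + p$radius + tol & okz)
      if (length(hit)) { target[i] <- "neck"; spine_hit[i] <- hit[1L]; next }
    }
    # shaft: distance from the axis (y = 0) within the analysed window
    if (p$x >= off && p$x <= geometry$length &&
        abs(p$y) <= geometry$shaft_radius + p$radius + tol &&
        z_overlap(p$z_lo, p$z_hi, shaft_z[1L], shaft_z[2L]) >= cfg$min_slices)
      target[i] <- "shaft"
  }
  puncta$target <- target
  channels <- c("Vglut1", "Vglut2")
  counts <- sapply(channels, function(ch)
    c(shaft = sum(puncta$channel == ch & target == "shaft"),
      head = sum(puncta$channel == ch & target == "head"),
      neck = sum(puncta$channel == ch & target == "neck")))
  dens <- counts / eff_len
  subtype_frac <- NULL
  if (nrow(spines)) {
    subtype_frac <- sapply(channels, function(ch) {
      hits <- spine_hit[puncta$channel == ch & target == "head"]
      vapply(c("thin", "mushroom", "stubby", "filopodia"), function(s) {
        ns <- sum(spines$subtype == s)
        if (ns == 0) return(NA_real_)
        length(unique(hits[spines$subtype[hits] == s])) / ns
      }, numeric(1))
    })
  }
  tot <- colSums(counts)
  structure(list(counts = counts, densities = dens,
                 subtype_fractions = subtype_frac,
                 ratio = unname(tot["Vglut1"] / tot["Vglut2"]),
                 puncta = puncta, analysed_length = eff_len),
            class = "apposition_report")
}

#' @export
print.apposition_report <- function(x, ...) {
  cat("<apposition_report>\n  counts (per channel):\n")
  print(x$counts)
  cat(sprintf("  Vglut1:Vglut2 ratio %.2f over %.0f um analysed\n",
              x$ratio, x$analysed_length))
  invisible(x)
}

#' Generate spine and punctum records for one dendrite
#'
#' Places spines beyond the 20 um proximal offset with the group's subtype
#' mixture, gives each spine simple head geometry on a straight shaft, and
#' scatters Vglut1/Vglut2 puncta so that configured fractions form true
#' appositions (on shaft, heads and necks, through >= 3 z-slices) while the
#' rest are background. Ground truth (true subtype and target) is recorded
#' in `true_subtype` / `true_target` columns.
#'
#' @param gt a [group_truth()].
#' @param dendrite_length um (> 20).
#' @param seed integer seed.
#' @return list `spines`, `puncta`, `geometry`.
#' @export
generate_spines_and_puncta <- function(gt, dendrite_length = 120, seed = 1L) {
  if (dendrite_length <= 20)
    stopf("generate_spines_and_puncta: dendrite length must exceed 20 um")
  scf <- gt$spines; acf <- gt$appositions
  eff <- dendrite_length - scf$offset
  shaft_r <- 0.5
  with_seed(seed, {
    counts <- stats::rpois(4L, scf$density * eff)
    names(counts) <- names(scf$density)
    mk <- function(subtype, k) {
      if (k == 0L) return(NULL)
      geom <- switch(subtype,
        thin = data.frame(head_diameter = stats::runif(k, 0.25, 0.6),
                          neck = TRUE, length = stats::runif(k, 0.8, 2.4)),
        mushroom = data.frame(head_diameter = stats::runif(k, 0.62, 1.2),
                              neck = TRUE, length = stats::runif(k, 1.0, 2.6)),
        stubby = data.frame(head_diameter = stats::runif(k, 0.4, 0.9),
                            neck = FALSE, length = stats::runif(k, 0.3, 0.9)),
        filopodia = data.frame(head_diameter = stats::runif(k, 0.2, 0.45),
                               neck = TRUE, length = stats::runif(k, 3.1, 5)))
      geom$true_subtype <- subtype
      geom
    }
    sp <- do.call(rbind, lapply(names(counts), function(s) mk(s, counts[[s]])))
    nsp <- nrow(sp)
    sp$path_dist <- stats::runif(nsp, scf$offset, dendrite_length)
    side <- sample(c(-1, 1), nsp, replace = TRUE)
    sp$head_x <- sp$path_dist
    sp$head_y <- side * (shaft_r + sp$length - sp$head_diameter / 2)
    sp <- sp[order(sp$path_dist), ]
    rownames(sp) <- NULL

    mk_punctum <- function(ch, target, k) {
      if (k == 0L) return(NULL)
      r <- stats::runif(k, 0.15, 0.35)
      if (target == "shaft") {
        x <- stats::runif(k, scf$offset, dendrite_length)
        y <- sample(c(-1, 1), k, TRUE) * (shaft_r + r * stats::runif(k, 0, 0.8))
        sidx <- NA_integer_
      } else {
        pool <- if (target == "neck") which(sp$neck) else seq_len(nsp)
        sidx <- sample(pool, k, replace = FALSE)
        if (target == "head") {
          x <- sp$head_x[sidx]
          y <- sp$head_y[sidx] +
            sign(sp$head_y[sidx]) * (sp$head_diameter[sidx] / 2 + r * 0.5)
        } else {
          y0 <- (sp$head_y[sidx] + sign(sp$head_y[sidx]) * shaft_r) / 2
          x <- sp$head_x[sidx]
          y <- y0 + sample(c(-1, 1), k, TRUE) * r * 0.4
        }
      }
      zlo <- sample(-2:0, k, TRUE)
      data.frame(channel = ch, x = x, y = y,
                 z_lo = zlo, z_hi = zlo + sample(2:4, k, TRUE),
                 radius = r, true_target = target)
    }
    pk <- list()
    for (ch in c("Vglut1", "Vglut2")) {
      pk[[length(pk) + 1L]] <-
        mk_punctum(ch, "shaft", stats::rpois(1L, acf$shaft_density[[ch]] * eff))
      neckable <- sum(sp$neck)
      pk[[length(pk) + 1L]] <-
        mk_punctum(ch, "head",
                   min(nsp, stats::rpois(1L, acf$head_fraction[[ch]] * nsp)))
      pk[[length(pk) + 1L]] <-
        mk_punctum(ch, "neck",
                   min(neckable,
                       stats::rpois(1L, acf$neck_fraction[[ch]] * neckable)))
      # background: far from the dendrite or too few slices
      nbg <- stats::rpois(1L, acf$background_density * eff)
      if (nbg > 0) {
        r <- stats::runif(nbg, 0.15, 0.35)
        zlo <- sample(-2:0, nbg, TRUE)
        far <- data.frame(channel = ch,
                          x = stats::runif(nbg, 0, dendrite_length),
                          y = sample(c(-1, 1), nbg, TRUE) *
                            stats::runif(nbg, 6, 12),
                          z_lo = zlo, z_hi = zlo + sample(2:4, nbg, TRUE),
                          radius = r, true_target = "none")
        pk[[length(pk) + 1L]] <- far
      }
    }
    puncta <- do.call(rbind, pk)
    rownames(puncta) <- NULL
    list(spines = sp, puncta = puncta,
         geometry = list(length = dendrite_length, shaft_radius = shaft_r,
                         shaft_z = c(-3L, 3L), offset = scf$offset))
  })
}
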