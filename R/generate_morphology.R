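# Stochastic recursive dendritic-tree growth. Trees grow outward from the
# soma in fixed arc steps; at each step a growing tip may bifurcate with a
# path-distance-dependent probability, and it stops when it reaches its drawn
# maximal extent. Group configurations differ only in branching-rate windows
# and extent, which is what shifts total length, node and ending counts
# between groups while leaving the overall radial envelope comparable.

branch_rate <- function(x, cfg) {
  r <- rep(cfg$branch_base, length(x))
  w <- cfg$branch_window
  r[x >= w[1] & x < w[2]] <- cfg$branch_mid
  dw <- cfg$distal_window
  if (!is.null(dw)) r[x >= dw[1] & x < dw[2]] <- pmax(r[x >= dw[1] & x < dw[2]], dw[3])
  r
}

rand_unit <- function() {
  v <- stats::rnorm(3)
  v / sqrt(sum(v^2))
}

#' Generate a synthetic medium-spiny-neuron morphology
#'
#' Grows a group-configured stochastic dendritic tree (see [group_truth()]).
#' Deterministic for a fixed `(gt, seed)` pair. The returned morphology
#' carries a `truth` attribute with the generator's own bookkeeping totals
#' (length, nodes, endings, primaries).
#'
#' @param gt a [group_truth()] (or a morphology config list).
#' @param seed integer seed.
#' @return a [morphology()].
#' @export
generate_morphology <- function(gt, seed = 1L) {
  cfg <- if (inherits(gt, "group_truth")) gt$morphology else gt
  if (is.null(cfg$extent_mean) || cfg$extent_mean <= 20)
    stopf("generate_morphology: degenerate config (extent_mean must exceed 20 um)")
  with_seed(seed, {
    soma <- list(center = c(0, 0, 0), diameter = cfg$soma_diameter)
    nprim <- sample(cfg$n_primary[1]:cfg$n_primary[2], 1L)
    secs <- list()
    truth_len <- 0; n_end <- 0L; n_nodes <- 0L
    # frontier entries: start point, direction, diameter, path distance at
    # start, extent, parent section index
    frontier <- lapply(seq_len(nprim), function(i) {
      list(pt = c(0, 0, 0), dir = rand_unit(),
           d = cfg$d_primary * stats::runif(1, 0.9, 1.1),
           path = 0,
           extent = max(60, stats::rnorm(1, cfg$extent_mean, cfg$extent_sd)),
           parent = 0L)
    })
    while (length(frontier)) {
      tip <- frontier[[1L]]; frontier <- frontier[-1L]
      pts <- matrix(c(tip$pt, tip$d), nrow = 1L)
      dir <- tip$dir; x <- tip$path; d <- tip$d
      since_branch <- 0
      branched <- FALSE
      repeat {
        ds <- min(cfg$step, tip$extent - x)
        if (ds <= 0.5) break
        dir <- dir + cfg$dir_jitter * stats::rnorm(3)
        dir <- dir / sqrt(sum(dir^2))
        newpt <- pts[nrow(pts), 1:3] + ds * dir
        x <- x + ds
        d <- max(cfg$d_min, d - cfg$d_taper * ds)
        pts <- rbind(pts, c(newpt, d))
        since_branch <- since_branch + ds
        if (since_branch >= cfg$min_branch_sep && x < tip$extent - 10 &&
            stats::runif(1) < branch_rate(x, cfg) * ds) {
          branched <- TRUE
          break
        }
      }
      secs[[length(secs) + 1L]] <- list(parent = tip$parent, points = pts)
      truth_len <- truth_len + sum(seg_lengths(pts[, 1:3, drop = FALSE]))
      sec_id <- length(secs)
      if (branched) {
        n_nodes <- n_nodes + 1L
        # one child continues toward the drawn extent at near-parent calibre;
        # the other is a shorter, thinner side branch, as in real spiny-neuron
        # arbors where higher-order branches taper and terminate early
        ext1 <- tip$extent
        ext2 <- x + stats::runif(1, cfg$side_len[1], cfg$side_len[2])
        dd <- c(max(cfg$d_min, d * cfg$d_branch_ratio),
                max(cfg$side_d_min, d * cfg$side_d_ratio))
        for (ci in 1:2) {
          ddir <- dir + 0.55 * stats::rnorm(3)
          ddir <- ddir / sqrt(sum(ddir^2))
          frontier[[length(frontier) + 1L]] <-
            list(pt = pts[nrow(pts), 1:3], dir = ddir, d = dd[ci],
                 path = x, extent = c(ext1, ext2)[ci], parent = sec_id)
        }
      } else {
        n_end <- n_end + 1L
      }
    }
    m <- morphology(soma, secs)
    attr(m, "truth") <- list(total_dendritic_length = truth_len,
                             n_nodes = n_nodes, n_endings = n_end,
                             n_primary = nprim)
    m
  })
}
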