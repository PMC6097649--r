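# Morphologies: a rooted tree of 3D traced dendritic sections attached to a
# spherical-equivalent soma. Sections are stored parents-first; the first row
# of a section's point matrix is its attachment point on the parent (the soma
# centre for primary dendrites, the parent's distal node otherwise), so
# section arc length includes the attachment segment.

#' Construct a morphology
#'
#' @param soma list with `center` (xyz, um) and `diameter` (um) of the
#'   spherical-equivalent soma.
#' @param sections list of sections; each a list with `parent` (index of the
#'   parent section, `0` for the soma) and `points`, an n x 4 matrix with
#'   columns x, y, z (um) and diameter (um). The first row must coincide with
#'   the parent's distal point (or the soma centre).
#' @return an object of class `morphology`.
#' @export
morphology <- function(soma, sections) {
  m <- structure(list(soma = soma, sections = sections), class = "morphology")
  validate_morphology(m)
  m
}

#' @export
print.morphology <- function(x, ...) {
  mm <- morphometrics(x)
  cat("<morphology> ", length(x$sections), " dendritic sections\n", sep = "")
  cat(sprintf("  total length %.1f um, %d nodes, %d endings, %d primary\n",
              mm$total_dendritic_length, mm$n_nodes, mm$n_endings,
              mm$n_primary))
  cat(sprintf("  soma diameter %.2f um, max path distance %.1f um\n",
              x$soma$diameter, mm$max_path_distance))
  invisible(x)
}

validate_morphology <- function(m) {
  if (!is.list(m$soma) || length(m$soma$center) != 3L ||
      !is.numeric(m$soma$diameter) || m$soma$diameter <= 0)
    stopf("morphology: soma must have a 3D center and positive diameter")
  ns <- length(m$sections)
  if (ns == 0L)
    stopf("morphology: no dendritic sections")
  for (i in seq_len(ns)) {
    s <- m$sections[[i]]
    p <- s$parent
    if (!is.numeric(p) || length(p) != 1L || p < 0 || p >= i)
      stopf("morphology: section %d has invalid parent %s (sections must be ordered parents-first)",
            i, format(p))
    pts <- s$points
    if (!is.matrix(pts) || ncol(pts) != 4L || nrow(pts) < 2L)
      stopf("morphology: section %d needs an n x 4 point matrix with >= 2 rows", i)
    if (any(pts[, 4L] <= 0))
      stopf("morphology: section %d has non-positive diameters", i)
    # electrotonic (transformed) morphologies may legitimately collapse
    # segments to zero drawn length
    if (is.null(attr(m, "electrotonic")) &&
        sum(seg_lengths(pts[, 1:3, drop = FALSE])) <= 0)
      stopf("morphology: section %d has zero length", i)
  }
  invisible(TRUE)
}

section_children <- function(m) {
  parents <- vapply(m$sections, `[[`, numeric(1), "parent")
  lapply(seq_along(m$sections), function(i) which(parents == i))
}

#' Read a morphology from an SWC file
#'
#' Standard 7-column SWC (id, type, x, y, z, radius, parent). Soma samples
#' (type 1) are merged into a single surface-preserving spherical-equivalent
#' root; all other samples are treated as dendrite. Radii are converted to
#' diameters. Unbranched runs of samples become sections split at branch
#' points; primary sections attach at the soma centre.
#'
#' @param path SWC file.
#' @return a [morphology()] object.
#' @examples
#' f <- system.file("extdata", "msn_synthetic_wt_d1.swc", package = "msncable")
#' m <- read_swc(f)
#' morphometrics(m)
#' @export
read_swc <- function(path) {
  if (!file.exists(path)) stopf("read_swc: no such file: %s", path)
  lines <- readLines(path, warn = FALSE)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  if (!length(lines)) stopf("read_swc: %s contains no samples", path)
  tab <- read.table(text = lines, col.names = c("id", "type", "x", "y", "z",
                                                "radius", "parent"))
  if (anyDuplicated(tab$id)) stopf("read_swc: duplicate sample ids")
  if (any(tab$radius <= 0)) stopf("read_swc: non-positive radius")
  idx <- match(tab$parent, tab$id)           # NA for roots (-1)
  bad <- tab$parent != -1 & is.na(idx)
  if (any(bad))
    stopf("read_swc: sample %d references missing parent %d",
          tab$id[which(bad)[1L]], tab$parent[which(bad)[1L]])
  # cycle check: walking to the root must terminate
  n <- nrow(tab)
  depth <- rep.int(NA_integer_, n)
  for (i in seq_len(n)) {
    j <- i; steps <- 0L
    while (!is.na(j)) {
      if (!is.na(depth[j])) { steps <- steps + depth[j]; break }
      j <- idx[j]; steps <- steps + 1L
      if (steps > n) stopf("read_swc: cycle detected in parent pointers")
    }
    depth[i] <- steps
  }

  is_soma <- tab$type == 1L
  if (!any(is_soma)) stopf("read_swc: no soma (type 1) sample")
  soma_rows <- which(is_soma)
  center <- c(mean(tab$x[soma_rows]), mean(tab$y[soma_rows]),
              mean(tab$z[soma_rows]))
  if (length(soma_rows) == 1L) {
    soma_d <- 2 * tab$radius[soma_rows]
  } else {
    # surface-preserving equivalent sphere of the soma sample chain
    ord <- soma_rows[order(tab$id[soma_rows])]
    xyz <- as.matrix(tab[ord, c("x", "y", "z")])
    dia <- 2 * tab$radius[ord]
    surf <- frusta_area(xyz, dia)
    if (surf <= 0) surf <- 4 * pi * max(tab$radius[soma_rows])^2
    soma_d <- 2 * sqrt(surf / (4 * pi))
  }

  dend <- which(!is_soma)
  if (!length(dend)) stopf("read_swc: no dendrite samples")
  nchild <- tabulate(idx[dend], nbins = n)
  # a section starts where the parent is soma (or absent) or a branch point
  parent_row <- idx[dend]
  starts <- dend[is.na(parent_row) | is_soma[parent_row] |
                   nchild[parent_row] >= 2L]
  # map sample row -> (section, point index), build sections by walking chains
  secs <- list()
  sec_of_sample <- integer(n)
  children_of <- split(dend, factor(idx[dend], levels = seq_len(n)))
  for (s0 in starts) {
    chain <- s0
    repeat {
      kids <- children_of[[chain[length(chain)]]]
      if (length(kids) == 1L && !is_soma[kids]) chain <- c(chain, kids)
      else break
    }
    pr <- idx[s0]
    if (is.na(pr) || is_soma[pr]) {
      att_xyz <- center
      att_d <- 2 * tab$radius[s0]
      parent_sec <- 0L
    } else {
      att_xyz <- c(tab$x[pr], tab$y[pr], tab$z[pr])
      att_d <- 2 * tab$radius[pr]
      parent_sec <- sec_of_sample[pr]   # filled because parents precede
    }
    if (!is.na(pr) && !is_soma[pr] && parent_sec == 0L)
      stopf("read_swc: sample %d appears before its parent section; SWC must list parents first",
            tab$id[s0])
    pts <- rbind(c(att_xyz, att_d),
                 cbind(tab$x[chain], tab$y[chain], tab$z[chain],
                       2 * tab$radius[chain]))
    secs[[length(secs) + 1L]] <- list(parent = parent_sec, points = pts)
    sec_of_sample[chain] <- length(secs)
  }
  # sections are discovered in file order, which is parents-first for any
  # SWC in which parent samples precede their children (the convention);
  # morphology() validates this
  morphology(soma = list(center = center, diameter = soma_d), sections = secs)
}

#' Write a morphology to an SWC file
#'
#' Emits a single type-1 soma row followed by dendrite rows in topological
#' order (parent samples always precede children). The attachment row of each
#' section is not re-emitted; it is the parent's last sample (or the soma).
#'
#' @param m a [morphology()].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_swc <- function(m, path) {
  validate_morphology(m)
  rows <- list(sprintf("1 1 %.9g %.9g %.9g %.9g -1",
                       m$soma$center[1], m$soma$center[2], m$soma$center[3],
                       m$soma$diameter / 2))
  next_id <- 2L
  last_id <- integer(length(m$sections))   # id of each section's distal sample
  for (i in seq_along(m$sections)) {
    s <- m$sections[[i]]
    pid <- if (s$parent == 0L) 1L else last_id[s$parent]
    pts <- s$points
    for (j in 2:nrow(pts)) {
      rows[[length(rows) + 1L]] <-
        sprintf("%d 3 %.9g %.9g %.9g %.9g %d", next_id,
                pts[j, 1], pts[j, 2], pts[j, 3], pts[j, 4] / 2, pid)
      pid <- next_id
      next_id <- next_id + 1L
    }
    last_id[i] <- pid
  }
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("# SWC export (msncable)", unlist(rows)), con)
  invisible(path)
}

section_length <- function(s) sum(seg_lengths(s$points[, 1:3, drop = FALSE]))

# Path distance from the soma centre to the proximal end of each section.
section_path_offsets <- function(m) {
  off <- numeric(length(m$sections))
  len <- vapply(m$sections, section_length, numeric(1))
  for (i in seq_along(m$sections)) {
    p <- m$sections[[i]]$parent
    off[i] <- if (p == 0L) 0 else off[p] + len[p]
  }
  off
}

#' Morphometric summary of a dendritic tree
#'
#' Lengths are sums of 3D point-to-point Euclidean distances; branch nodes
#' are sections with two or more children; soma surface and volume come from
#' the spherical-equivalent root.
#'
#' @param m a [morphology()].
#' @return a list of class `morphometry_report`: `total_dendritic_length`
#'   (um), `n_nodes`, `n_endings`, `n_primary`, `max_path_distance` (um),
#'   `soma_surface` (um^2), `soma_volume` (um^3).
#' @export
morphometrics <- function(m) {
  validate_morphology(m)
  ch <- section_children(m)
  nch <- lengths(ch)
  len <- vapply(m$sections, section_length, numeric(1))
  off <- section_path_offsets(m)
  r <- m$soma$diameter / 2
  structure(list(
    total_dendritic_length = sum(len),
    n_nodes = sum(nch >= 2L),
    n_endings = sum(nch == 0L),
    n_primary = sum(vapply(m$sections, `[[`, numeric(1), "parent") == 0L),
    max_path_distance = max(off + len),
    soma_surface = 4 * pi * r^2,
    soma_volume = 4 / 3 * pi * r^3
  ), class = "morphometry_report")
}

#' @export
print.morphometry_report <- function(x, ...) {
  cat("<morphometry>\n")
  for (f in names(x)) cat(sprintf("  %-24s %.4g\n", f, x[[f]]))
  invisible(x)
}

#' Sholl analysis
#'
#' Counts crossings of concentric spheres centred on the soma and bins
#' dendritic arc length into the shells between them. Distance is radial
#' Euclidean from the soma centre by default; path distance along the
#' dendrite is available for comparison.
#'
#' @param m a [morphology()].
#' @param shell_width shell width in um (default 10).
#' @param distance `"euclidean"` (default) or `"path"`.
#' @param start radius of the innermost sphere (um). At `start = 0` the
#'   innermost count is defined as the number of primary dendrites.
#' @return a `sholl_profile`: data frame with `radius` (sphere radius, um),
#'   `center` (shell midpoint), `intersections`, and `length` (arc length in
#'   `[radius, radius + shell_width)`).
#' @export
sholl <- function(m, shell_width = 10, distance = c("euclidean", "path"),
                  start = 0) {
  validate_morphology(m)
  distance <- match.arg(distance)
  if (shell_width <= 0) stopf("sholl: shell_width must be > 0")
  off <- section_path_offsets(m)
  r0 <- r1 <- rmin <- slen <- numeric(0)
  mid <- numeric(0)
  ctr <- m$soma$center
  for (i in seq_along(m$sections)) {
    pts <- m$sections[[i]]$points[, 1:3, drop = FALSE]
    l <- seg_lengths(pts)
    a <- pts[-nrow(pts), , drop = FALSE]
    b <- pts[-1L, , drop = FALSE]
    if (distance == "euclidean") {
      ra <- sqrt(rowSums((a - rep(ctr, each = nrow(a)))^2))
      rb <- sqrt(rowSums((b - rep(ctr, each = nrow(b)))^2))
      # min radius on the segment: project the centre onto the segment
      ab <- b - a
      denom <- rowSums(ab^2)
      t_ <- ifelse(denom > 0,
                   pmin(1, pmax(0, rowSums((rep(ctr, each = nrow(a)) - a) * ab) / denom)),
                   0)
      p <- a + ab * t_
      rm_ <- sqrt(rowSums((p - rep(ctr, each = nrow(a)))^2))
    } else {
      cum <- off[i] + cumsum(c(0, l))
      ra <- cum[-length(cum)]
      rb <- cum[-1L]
      rm_ <- pmin(ra, rb)
    }
    r0 <- c(r0, ra); r1 <- c(r1, rb); rmin <- c(rmin, rm_); slen <- c(slen, l)
  }
  rmax_all <- max(r0, r1)
  radii <- seq(start, rmax_all + shell_width, by = shell_width)
  cross <- vapply(radii, function(b) {
    if (b <= 0) return(NA_integer_)
    sum((rmin < b) * ((r0 >= b) + (r1 >= b)))
  }, numeric(1))
  if (radii[1L] <= 0)
    cross[1L] <- sum(vapply(m$sections, `[[`, numeric(1), "parent") == 0L)
  # arc-length binning by dense subdivision (0.25 um pieces)
  nsub <- pmax(1L, ceiling(slen / 0.25))
  piece_r <- unlist(lapply(seq_along(slen), function(k) {
    tt <- (seq_len(nsub[k]) - 0.5) / nsub[k]
    # radius interpolated linearly between endpoint radii; adequate at 0.25 um
    r0[k] + tt * (r1[k] - r0[k])
  }))
  piece_l <- rep(slen / nsub, nsub)
  bin <- findInterval(piece_r, radii)
  lens <- vapply(seq_along(radii), function(k) sum(piece_l[bin == k]),
                 numeric(1))
  structure(data.frame(radius = radii, center = radii + shell_width / 2,
                       intersections = cross, length = lens),
            class = c("sholl_profile", "data.frame"),
            shell_width = shell_width, distance = distance)
}

#' @export
plot.sholl_profile <- function(x, which = c("intersections", "length"), ...) {
  which <- match.arg(which)
  graphics::plot(x$radius, x[[which]], type = "b", xlab = "distance (um)",
                 ylab = which, ...)
  invisible(x)
}
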