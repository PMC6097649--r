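# Shared fixtures: simple analytic geometries and small random trees, all
# built in code.

# straight cylinder of length l (um) and diameter d attached to a spherical
# soma; points every l/(npts-1) um along +x
cyl_morph <- function(l = 400, d = 1, soma_d = 13, npts = 21) {
  x <- seq(0, l, length.out = npts)
  morphology(list(center = c(0, 0, 0), diameter = soma_d),
             list(list(parent = 0L, points = cbind(x, 0, 0, d))))
}

# star of k identical straight cables leaving the soma in different directions
star_morph <- function(k = 3, l = 250, d = 1, soma_d = 13) {
  dirs <- cbind(cos(2 * pi * seq_len(k) / k), sin(2 * pi * seq_len(k) / k), 0)
  secs <- lapply(seq_len(k), function(i) {
    x <- seq(0, l, length.out = 11)
    list(parent = 0L, points = cbind(x * dirs[i, 1], x * dirs[i, 2],
                                     x * dirs[i, 3], d))
  })
  morphology(list(center = c(0, 0, 0), diameter = soma_d), secs)
}

# small random branched tree (reproducible); distinct from the package's own
# group-configured generator so oracle tests do not depend on its defaults
random_tree <- function(seed, n_primary = 2, depth = 2) {
  cfg <- group_truth("WT-D1")$morphology
  cfg$n_primary <- c(n_primary, n_primary)
  cfg$extent_mean <- 140
  cfg$extent_sd <- 25
  cfg$branch_mid <- 0.02
  generate_morphology(cfg, seed)
}

# analytic constants for a sealed cylinder with the default passive set
r_inf_mohm <- function(d_um, p = passive_params()) {
  (2 / pi) * sqrt(p$rm * 1e3 * p$ra) / (d_um * 1e-4)^1.5 * 1e-6
}
soma_r_mohm <- function(soma_d_um, p = passive_params()) {
  (p$rm * 1e3 / (4 * pi * (soma_d_um / 2 * 1e-4)^2)) * 1e-6
}

# steady-state sinusoidal amplitude of the tail of a trace
osc_amplitude <- function(values, frac = 1 / 3) {
  tail_v <- values[seq.int(floor(length(values) * (1 - frac)), length(values))]
  (max(tail_v) - min(tail_v)) / 2
}

write_swc_text <- function(lines) {
  f <- tempfile(fileext = ".swc")
  writeLines(lines, f)
  f
}
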