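# Group-comparison statistics: normality-gated two-sample comparison,
# two-way (genotype x cell type) ANOVA with post hoc t-tests, bootstrap
# median confidence intervals for pooling decisions, and the firing-rate
# linear model. No multiple-testing correction is applied by default (a Holm
# option exists), matching common practice in the source literature for
# these designs.

new_stat_result <- function(test, statistic, df, p, extra = list()) {
  structure(c(list(test = test, statistic = statistic, df = df, p = p),
              extra), class = "stat_result")
}

#' @export
print.stat_result <- function(x, ...) {
  cat(sprintf("<stat_result> %s: statistic %.4g, p = %.4g\n",
              x$test, x$statistic, x$p))
  invisible(x)
}

#' Normality-gated two-group comparison
#'
#' Shapiro-Wilk is applied to each group at alpha = 0.05; if both pass, an
#' unpaired (pooled-variance) t-test is used, otherwise the Mann-Whitney U
#' test. The path taken is recorded.
#'
#' @param a,b numeric vectors (n >= 3 each).
#' @param paired currently only `FALSE` is supported.
#' @param alpha normality gate level.
#' @return a `stat_result` with `path` (`"t"` or `"mann-whitney"`), group
#'   means/medians and the direction of effect.
#' @export
compare_two <- function(a, b, paired = FALSE, alpha = 0.05) {
  if (length(a) < 3L || length(b) < 3L)
    stopf("compare_two: need n >= 3 per group")
  if (paired) stopf("compare_two: paired comparisons not supported")
  normal <- function(x) {
    if (stats::sd(x) == 0) return(TRUE)   # degenerate: let the t path handle it
    stats::shapiro.test(x)$p.value >= alpha
  }
  use_t <- normal(a) && normal(b)
  if (use_t) {
    if (stats::sd(a) == 0 && stats::sd(b) == 0 && mean(a) == mean(b)) {
      res <- list(statistic = 0, parameter = length(a) + length(b) - 2L,
                  p.value = 1)
    } else res <- stats::t.test(a, b, var.equal = TRUE)
    out <- new_stat_result("t", unname(res$statistic),
                           unname(res$parameter), res$p.value)
  } else {
    res <- suppressWarnings(stats::wilcox.test(a, b, exact = FALSE))
    out <- new_stat_result("mann-whitney", unname(res$statistic), NA_real_,
                           res$p.value)
  }
  out$path <- if (use_t) "t" else "mann-whitney"
  out$means <- c(a = mean(a), b = mean(b))
  out$medians <- c(a = stats::median(a), b = stats::median(b))
  out$direction <- sign(mean(a) - mean(b))
  out
}

#' Two-way ANOVA (genotype x cell type) with post hoc t-tests
#'
#' Between-subject two-factor linear-model ANOVA with interaction, Type II
#' sums of squares for unbalanced cells, followed by the four post hoc
#' pairwise t-tests (within cell type across genotype, and within genotype
#' across cell type).
#'
#' @param value numeric response.
#' @param genotype,cell_type factors (2 levels each; all four cells must be
#'   non-empty).
#' @param holm apply Holm correction to the post hoc family (default FALSE).
#' @return list of class `anova2_result`: `table` (term, F, df1, df2, p),
#'   `posthoc` (contrast, p, means), and the fitted `lm`.
#' @export
two_way_anova <- function(value, genotype, cell_type, holm = FALSE) {
  genotype <- factor(genotype); cell_type <- factor(cell_type)
  keep <- is.finite(value)
  value <- value[keep]; genotype <- genotype[keep]
  cell_type <- cell_type[keep]
  if (nlevels(droplevels(genotype)) < 2L || nlevels(droplevels(cell_type)) < 2L ||
      any(table(genotype, cell_type) == 0L))
    stopf("two_way_anova: empty design cell")
  d <- data.frame(value = value, genotype = genotype, cell_type = cell_type)
  fit <- stats::lm(value ~ genotype * cell_type, data = d)
  a2 <- car::Anova(fit, type = 2)
  terms <- rownames(a2)[seq_len(3L)]
  tab <- data.frame(term = terms,
                    F = a2$`F value`[seq_len(3L)],
                    df1 = a2$Df[seq_len(3L)],
                    df2 = a2$Df[nrow(a2)],
                    p = a2$`Pr(>F)`[seq_len(3L)])
  ph <- list()
  for (ct in levels(cell_type)) {
    g <- levels(genotype)
    x <- value[genotype == g[1L] & cell_type == ct]
    y <- value[genotype == g[2L] & cell_type == ct]
    tt <- stats::t.test(x, y, var.equal = TRUE)
    ph[[length(ph) + 1L]] <- data.frame(
      contrast = sprintf("%s vs %s within %s", g[1L], g[2L], ct),
      mean_1 = mean(x), mean_2 = mean(y), p = tt$p.value)
  }
  for (gn in levels(genotype)) {
    ct <- levels(cell_type)
    x <- value[genotype == gn & cell_type == ct[1L]]
    y <- value[genotype == gn & cell_type == ct[2L]]
    tt <- stats::t.test(x, y, var.equal = TRUE)
    ph[[length(ph) + 1L]] <- data.frame(
      contrast = sprintf("%s vs %s within %s", ct[1L], ct[2L], gn),
      mean_1 = mean(x), mean_2 = mean(y), p = tt$p.value)
  }
  posthoc <- do.call(rbind, ph)
  if (holm) posthoc$p <- stats::p.adjust(posthoc$p, "holm")
  structure(list(table = tab, posthoc = posthoc, fit = fit),
            class = "anova2_result")
}

#' @export
print.anova2_result <- function(x, ...) {
  cat("<two-way ANOVA>\n")
  print(x$table, row.names = FALSE)
  cat("post hoc t-tests:\n")
  print(x$posthoc, row.names = FALSE)
  invisible(x)
}

#' Bootstrap median confidence intervals and pooling decision
#'
#' Percentile bootstrap 95% CI of the median for each group; the groups are
#' considered poolable when all pairwise CIs overlap.
#'
#' @param groups named list of numeric vectors (n >= 5 each).
#' @param n_boot bootstrap resamples (default 1e4).
#' @param conf confidence level.
#' @param seed integer seed.
#' @return list `ci` (matrix of lower/upper per group), `overlap` (logical).
#' @export
median_ci_overlap <- function(groups, n_boot = 1e4, conf = 0.95, seed = 1L) {
  if (any(lengths(groups) < 5L))
    stopf("median_ci_overlap: need n >= 5 per group")
  alpha <- (1 - conf) / 2
  ci <- with_seed(seed, vapply(groups, function(x) {
    n <- length(x)
    meds <- matrixStats_colMedians(matrix(sample(x, n * n_boot, replace = TRUE),
                                          nrow = n))
    stats::quantile(meds, c(alpha, 1 - alpha), names = FALSE)
  }, numeric(2)))
  rownames(ci) <- c("lower", "upper")
  k <- ncol(ci)
  overlap <- TRUE
  if (k >= 2L) {
    for (i in 1:(k - 1L)) for (j in (i + 1L):k)
      overlap <- overlap && ci["lower", i] <= ci["upper", j] &&
        ci["lower", j] <= ci["upper", i]
  }
  list(ci = ci, overlap = overlap)
}

# column medians without extra dependencies; sorts each column once
matrixStats_colMedians <- function(m) {
  n <- nrow(m)
  ms <- apply(m, 2L, sort.int, method = "quick")
  if (n %% 2L == 1L) ms[(n + 1L) %/% 2L, ]
  else (ms[n %/% 2L, ] + ms[n %/% 2L + 1L, ]) / 2
}

#' Linear model of firing rate on experimental covariates
#'
#' Models firing rate as a function of genotype, cell type, rheobase, input
#' resistance and injected current with all pairwise interactions;
#' rank-deficient terms are dropped with a message. Also reports the
#' firing-rate-versus-rheobase correlation at a chosen current level.
#'
#' @param records data frame: `rate` (Hz), `genotype`, `cell_type`,
#'   `rheobase` (pA), `rn` (MOhm), `current` (pA), `cell` id (>= 2 current
#'   levels per cell expected).
#' @param cor_current current level (pA) at which to report the rate-rheobase
#'   correlation (default 180).
#' @return list of class `firing_glm`: the `lm` fit, `r_squared`,
#'   coefficient table, `dropped` aliased terms, and `rheo_cor`
#'   (`r_squared`, `estimate` at `cor_current`).
#' @export
firing_glm <- function(records, cor_current = 180) {
  need <- c("rate", "genotype", "cell_type", "rheobase", "rn", "current")
  if (!all(need %in% names(records)))
    stopf("firing_glm: records needs columns %s", paste(need, collapse = ", "))
  d <- records
  d$genotype <- factor(d$genotype); d$cell_type <- factor(d$cell_type)
  fit <- stats::lm(rate ~ (genotype + cell_type + rheobase + rn + current)^2,
                   data = d)
  al <- stats::alias(fit)$Complete
  dropped <- rownames(al)
  if (!is.null(dropped) && length(dropped))
    message("firing_glm: dropped rank-deficient terms: ",
            paste(dropped, collapse = ", "))
  sm <- summary(fit)
  at_level <- d[abs(d$current - cor_current) < 1e-6, ]
  rheo_cor <- if (nrow(at_level) >= 3L) {
    ct <- stats::cor.test(at_level$rate, at_level$rheobase)
    list(estimate = unname(ct$estimate), r_squared = unname(ct$estimate)^2,
         p = ct$p.value, current = cor_current)
  } else NULL
  structure(list(fit = fit, r_squared = sm$r.squared,
                 coefficients = stats::coef(sm), dropped = dropped,
                 rheo_cor = rheo_cor),
            class = "firing_glm")
}

#' @export
print.firing_glm <- function(x, ...) {
  cat(sprintf("<firing_glm> R^2 = %.3f\n", x$r_squared))
  stats::printCoefmat(x$coefficients, P.values = TRUE, has.Pvalue = TRUE)
  if (!is.null(x$rheo_cor))
    cat(sprintf("rate vs rheobase at %g pA: r = %.3f (R^2 = %.3f)\n",
                x$rheo_cor$current, x$rheo_cor$estimate,
                x$rheo_cor$r_squared))
  invisible(x)
}
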