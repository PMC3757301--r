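# Group summaries and hypothesis tests used across the pipeline:
# two-tailed unpaired t-test, one/two-way ANOVA with Bonferroni post-hoc,
# Kruskal-Wallis with Dunn post-hoc, and the two-sample Kolmogorov-Smirnov
# test for pooled cumulative distributions.

group_summary <- function(values, group) {
  agg <- split(values, group)
  data.frame(group = names(agg),
             mean = vapply(agg, mean, numeric(1)),
             sem = vapply(agg, function(x)
               if (length(x) > 1L) sd(x) / sqrt(length(x)) else NA_real_,
               numeric(1)),
             n = vapply(agg, length, integer(1)),
             row.names = NULL)
}

new_group_comparison <- function(summary, test, statistic, p_value,
                                 posthoc = NULL, effects = NULL) {
  structure(list(summary = summary, test = test, statistic = statistic,
                 p_value = p_value, posthoc = posthoc, effects = effects),
            class = "group_comparison")
}

#' Two-group comparison by unpaired two-tailed t-test
#'
#' Classical (equal-variance) Student's t-test by default; Welch's
#' correction behind `welch = TRUE`. Two groups with zero variance and
#' equal means return t = 0, p = 1 by convention.
#'
#' @param a,b numeric value vectors (each n >= 2)
#' @param welch use the Welch unequal-variance test
#' @return object of class `group_comparison` with per-group mean, s.e.m.
#'   and n, the t statistic and the two-tailed p-value
#' @export
compare_two_groups <- function(a, b, welch = FALSE) {
  if (length(a) < 2L || length(b) < 2L)
    stop("each group needs n >= 2", call. = FALSE)
  smry <- group_summary(c(a, b), rep(c("a", "b"), c(length(a), length(b))))
  if (var(a) == 0 && var(b) == 0 && mean(a) == mean(b)) {
    return(new_group_comparison(smry, "t (two-tailed, unpaired)", 0, 1))
  }
  tt <- stats::t.test(a, b, var.equal = !welch)
  new_group_comparison(smry,
                       if (welch) "Welch t (two-tailed)" else
                         "t (two-tailed, unpaired)",
                       unname(tt$statistic), tt$p.value)
}

# Dunn's rank-based post-hoc comparisons after Kruskal-Wallis, with
# tie-corrected standard errors and Bonferroni family-wise adjustment.
dunn_posthoc <- function(values, group, adjust = "bonferroni") {
  g <- factor(group)
  r <- rank(values)
  N <- length(values)
  ties <- table(r)
  tie_corr <- sum(ties^3 - ties) / (12 * (N - 1))
  rbar <- tapply(r, g, mean)
  nn <- tapply(r, g, length)
  labs <- levels(g)
  pairs <- utils::combn(labs, 2)
  z <- p_raw <- numeric(ncol(pairs))
  for (j in seq_len(ncol(pairs))) {
    i1 <- pairs[1, j]; i2 <- pairs[2, j]
    se <- sqrt((N * (N + 1) / 12 - tie_corr) * (1 / nn[i1] + 1 / nn[i2]))
    z[j] <- (rbar[i1] - rbar[i2]) / se
    p_raw[j] <- 2 * stats::pnorm(-abs(z[j]))
  }
  data.frame(group1 = pairs[1, ], group2 = pairs[2, ], z = z,
             p_raw = p_raw, p_adjusted = stats::p.adjust(p_raw, adjust),
             row.names = NULL)
}

#' Multi-group comparison: ANOVA or Kruskal-Wallis with post-hoc tests
#'
#' `one_way`: one-way ANOVA with pairwise Bonferroni-adjusted t-tests
#' (pooled SD). `two_way`: two-way ANOVA with interaction (`factor2`
#' required); per-term F statistics are returned in `effects` and the
#' post-hoc compares levels of the first factor. `nonparametric`:
#' Kruskal-Wallis with Dunn's post-hoc (Bonferroni family-wise
#' adjustment).
#'
#' @param values numeric response vector
#' @param group primary grouping factor
#' @param design `"one_way"`, `"two_way"` or `"nonparametric"`
#' @param factor2 second factor for `two_way`
#' @return object of class `group_comparison`; `posthoc` holds the
#'   pairwise table (`p_adjusted >= p_raw` for Bonferroni), `effects` the
#'   per-term ANOVA table for `two_way`
#' @export
compare_multi_groups <- function(values, group,
                                 design = c("one_way", "two_way",
                                            "nonparametric"),
                                 factor2 = NULL) {
  design <- match.arg(design)
  g <- factor(group)
  if (any(table(g) == 0L))
    stop("every factor level needs n >= 1", call. = FALSE)
  if (design != "two_way" && nlevels(g) < 3L)
    stop("need >= 3 groups (use compare_two_groups for 2)", call. = FALSE)
  smry <- group_summary(values, g)
  if (design == "one_way") {
    fit <- stats::aov(values ~ g)
    tab <- summary(fit)[[1]]
    ph <- stats::pairwise.t.test(values, g, p.adjust.method = "none",
                                 pool.sd = TRUE)
    raw <- as.data.frame(as.table(ph$p.value))
    raw <- raw[!is.na(raw$Freq), ]
    posthoc <- data.frame(group1 = as.character(raw$Var1),
                          group2 = as.character(raw$Var2),
                          p_raw = raw$Freq,
                          p_adjusted = pmin(1, raw$Freq *
                                              choose(nlevels(g), 2)),
                          row.names = NULL)
    return(new_group_comparison(smry, "one-way ANOVA + Bonferroni",
                                tab[["F value"]][1], tab[["Pr(>F)"]][1],
                                posthoc))
  }
  if (design == "two_way") {
    if (is.null(factor2)) stop("'factor2' is required for two_way",
                               call. = FALSE)
    f2 <- factor(factor2)
    if (any(table(g, f2) == 0L))
      stop("every factor-level combination needs n >= 1", call. = FALSE)
    fit <- stats::aov(values ~ g * f2)
    tab <- summary(fit)[[1]]
    effects <- data.frame(term = trimws(rownames(tab)),
                          df = tab$Df, f = tab[["F value"]],
                          p = tab[["Pr(>F)"]], row.names = NULL)
    effects <- effects[effects$term != "Residuals", ]
    ph <- stats::pairwise.t.test(values, g, p.adjust.method = "none",
                                 pool.sd = TRUE)
    raw <- as.data.frame(as.table(ph$p.value))
    raw <- raw[!is.na(raw$Freq), ]
    posthoc <- data.frame(group1 = as.character(raw$Var1),
                          group2 = as.character(raw$Var2),
                          p_raw = raw$Freq,
                          p_adjusted = pmin(1, raw$Freq *
                                              choose(nlevels(g), 2)),
                          row.names = NULL)
    return(new_group_comparison(smry, "two-way ANOVA + Bonferroni",
                                effects$f[1], effects$p[1], posthoc,
                                effects))
  }
  kw <- stats::kruskal.test(values, g)
  new_group_comparison(smry, "Kruskal-Wallis + Dunn",
                       unname(kw$statistic), kw$p.value,
                       dunn_posthoc(values, g))
}

#' Two-sample Kolmogorov-Smirnov test on pooled distributions
#'
#' \eqn{D = \sup_x |ECDF_x - ECDF_y|} with the asymptotic Kolmogorov
#' p-value by default; `exact = TRUE` requests the exact small-sample
#' distribution (no ties).
#'
#' @param x,y pooled value vectors (non-empty)
#' @param exact use the exact null distribution
#' @return object of class `ks_result`: `statistic` (D), `p_value`,
#'   `n_x`, `n_y`
#' @export
ks_two_sample <- function(x, y, exact = FALSE) {
  if (!length(x) || !length(y))
    stop("both samples must be non-empty", call. = FALSE)
  kt <- suppressWarnings(stats::ks.test(x, y, exact = exact))
  structure(list(statistic = unname(kt$statistic), p_value = kt$p.value,
                 n_x = length(x), n_y = length(y)),
            class = "ks_result")
}
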