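#' One-way ANOVA with explained-variance effect sizes
#'
#' Decomposes the total sum of squares into between- and within-group
#' parts, with `F = (SS_b / df_b) / (SS_w / df_w)`, `R^2 = SS_b / SS_total`
#' and `R^2_adj = 1 - (1 - R^2) (n - 1) / (n - g)` for `g` groups.  For two
#' groups F equals the squared pooled-variance t statistic, so the same
#' routine doubles as a linear regression on a binary predictor.
#'
#' @param values Numeric response, one value per observation.
#' @param groups Group labels (two or more non-empty groups, total n >= 3).
#' @return Object of class `anova_result` with `f_stat`, `df_between`,
#'   `df_within`, `p_value`, `r2`, `r2_adj`, `group_means`, `group_sizes`.
#' @export
one_way_anova <- function(values, groups) {
  values <- as.numeric(values)
  groups <- factor(groups)
  if (length(values) != length(groups))
    stop("values and groups must have equal length")
  if (anyNA(values) || anyNA(groups))
    stop("missing values are not supported")
  if (nlevels(groups) < 2L)
    stop("need at least two groups")
  if (any(table(groups) == 0L))
    stop("every group must be non-empty")
  n <- length(values)
  if (n < 3L) stop("need at least three observations")
  fit <- stats::lm(values ~ groups)
  # degenerate decompositions are rejected explicitly below, so silence
  # R's own perfect-fit warning
  an <- suppressWarnings(stats::anova(fit))
  ss_b <- an$`Sum Sq`[1L]
  ss_w <- an$`Sum Sq`[2L]
  if (ss_w <= 0 && ss_b <= 0)
    stop("F undefined: zero within-group variance with equal group means")
  f_stat <- an$`F value`[1L]
  if (!is.finite(f_stat))
    stop("F undefined: zero within-group variance")
  r2 <- ss_b / (ss_b + ss_w)
  g <- nlevels(groups)
  structure(list(f_stat = f_stat,
                 df_between = an$Df[1L],
                 df_within = an$Df[2L],
                 p_value = an$`Pr(>F)`[1L],
                 r2 = r2,
                 r2_adj = 1 - (1 - r2) * (n - 1) / (n - g),
                 group_means = vapply(split(values, groups), mean,
                                      numeric(1)),
                 group_sizes = as.integer(table(groups))),
            class = "anova_result")
}

#' @export
print.anova_result <- function(x, ...) {
  cat(sprintf("One-way ANOVA: F(%d, %d) = %.3f, p = %.4g, R2 = %.3f, R2adj = %.3f\n",
              x$df_between, x$df_within, x$f_stat, x$p_value, x$r2, x$r2_adj))
  cat("Group means:", paste(sprintf("%s = %.3f", names(x$group_means),
                                    x$group_means), collapse = ", "), "\n")
  invisible(x)
}

#' Squared Pearson correlation of two features
#'
#' @param a,b Numeric vectors of equal length, both non-constant.
#' @param names Optional length-2 character vector of feature names.
#' @return Object of class `pairwise_r2` with `feature_a`, `feature_b`
#'   and `r2`.
#' @export
pairwise_r2 <- function(a, b, names = c("a", "b")) {
  a <- as.numeric(a); b <- as.numeric(b)
  if (length(a) != length(b))
    stop("inputs must have equal length")
  if (stats::sd(a) == 0 || stats::sd(b) == 0)
    stop("constant input: correlation undefined")
  structure(list(feature_a = names[1L], feature_b = names[2L],
                 r2 = stats::cor(a, b)^2),
            class = "pairwise_r2")
}

#' @export
print.pairwise_r2 <- function(x, ...) {
  cat(sprintf("R2(%s, %s) = %.4f\n", x$feature_a, x$feature_b, x$r2))
  invisible(x)
}

#' Per-feature per-group summary of a beauty dataset
#'
#' Raw-scale and z-scale group means (plus raw SDs) for each of the eight
#' features.  Because the z view is standardized over the pooled sample,
#' the group z-means of every feature satisfy
#' `n_beautiful * m_beautiful + n_ugly * m_ugly = 0`.
#'
#' @param ds A [beauty_dataset()].
#' @return Data frame with one row per feature: `feature`, `mean_beautiful`,
#'   `mean_ugly`, `sd_beautiful`, `sd_ugly`, `zmean_beautiful`,
#'   `zmean_ugly`.
#' @export
group_summary <- function(ds) {
  stopifnot(inherits(ds, "beauty_dataset"))
  b <- ds$labels == 1L
  data.frame(
    feature = colnames(ds$features),
    mean_beautiful = colMeans(ds$features[b, , drop = FALSE]),
    mean_ugly = colMeans(ds$features[!b, , drop = FALSE]),
    sd_beautiful = apply(ds$features[b, , drop = FALSE], 2L, stats::sd),
    sd_ugly = apply(ds$features[!b, , drop = FALSE], 2L, stats::sd),
    zmean_beautiful = colMeans(ds$z_features[b, , drop = FALSE]),
    zmean_ugly = colMeans(ds$z_features[!b, , drop = FALSE]),
    row.names = NULL)
}
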