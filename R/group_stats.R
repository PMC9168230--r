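# Group-level statistics on spatially averaged UQ summaries: a
# Shapiro-Wilk normality gate routing to either one-way ANOVA with paired
# t post-hoc tests or the Kruskal-Wallis rank test with Dunn's post-hoc
# test, all Bonferroni-corrected, plus the eta-squared effect size
# computed from the Kruskal-Wallis H statistic.
#
# Standard tests are delegated to stats::shapiro.test / oneway.test /
# t.test / kruskal.test; Dunn's rank-sum z statistics (no implementation
# in the installed stack) are computed here with mid-ranks and the usual
# tie correction.

.check_groups <- function(groups, min_n = 1) {
  if (is.null(names(groups)) || any(names(groups) == ""))
    stop("groups must be a named list of numeric vectors")
  if (length(groups) < 2) stop("need at least two groups")
  n <- vapply(groups, length, integer(1))
  if (any(n < min_n))
    stop(sprintf("every group needs >= %d observations", min_n))
  invisible(n)
}

#' Shapiro-Wilk normality test
#'
#' @param values Numeric vector, 3 to 5000 non-constant observations.
#' @return List of class `tes_test` with `statistic` (W), `p_value`.
#' @export
normality_test <- function(values) {
  if (length(values) < 3 || length(values) > 5000)
    stop("Shapiro-Wilk requires 3 <= n <= 5000")
  if (stats::sd(values) == 0)
    stop("undefined test: sample is constant")
  sw <- stats::shapiro.test(values)
  structure(list(test = "shapiro_wilk", statistic = unname(sw$statistic),
                 df = length(values), p_value = sw$p.value,
                 p_adjusted = sw$p.value, effect_size = NA_real_,
                 pairwise = NULL),
            class = "tes_test")
}

#' One-way ANOVA across groups
#'
#' Classical equal-variance one-way ANOVA (F against
#' `F(k - 1, N - k)`); with two groups F equals the squared pooled t
#' statistic.
#'
#' @param groups Named list of numeric vectors.
#' @param n_comparisons Bonferroni factor applied to the p value (e.g.
#'   the number of ROIs analysed); default 1.
#' @return A `tes_test` with `statistic` (F), `df` (c(df1, df2)).
#' @export
one_way_anova <- function(groups, n_comparisons = 1) {
  .check_groups(groups, min_n = 2)
  x <- unlist(groups, use.names = FALSE)
  if (stats::sd(x) == 0) stop("degenerate variance: all values identical")
  g <- factor(rep(names(groups), vapply(groups, length, integer(1))))
  ow <- stats::oneway.test(x ~ g, var.equal = TRUE)
  structure(list(test = "one_way_anova", statistic = unname(ow$statistic),
                 df = unname(ow$parameter), p_value = ow$p.value,
                 p_adjusted = min(1, n_comparisons * ow$p.value),
                 effect_size = NA_real_, pairwise = NULL),
            class = "tes_test")
}

#' Bonferroni-corrected paired t-tests for all group pairs
#'
#' Post-hoc companion of the ANOVA branch; groups are treated as matched
#' samples (equal sizes required, observations paired by position).
#'
#' @param groups Named list of equal-length numeric vectors.
#' @param n_comparisons Bonferroni factor; defaults to the number of
#'   pairs.
#' @return A `tes_test` whose `pairwise` data frame has one row per pair
#'   (`pair`, `t`, `df`, `p_raw`, `p_adj`).
#' @export
paired_t_bonferroni <- function(groups, n_comparisons = NULL) {
  n <- .check_groups(groups, min_n = 2)
  if (length(unique(n)) != 1)
    stop("paired tests require equal group sizes")
  nm <- names(groups)
  pairs <- utils::combn(nm, 2)
  if (is.null(n_comparisons)) n_comparisons <- ncol(pairs)
  rows <- lapply(seq_len(ncol(pairs)), function(j) {
    a <- pairs[1, j]; b <- pairs[2, j]
    tt <- stats::t.test(groups[[a]], groups[[b]], paired = TRUE)
    data.frame(pair = paste(a, b, sep = " vs "),
               t = unname(tt$statistic), df = unname(tt$parameter),
               p_raw = tt$p.value,
               p_adj = min(1, n_comparisons * tt$p.value),
               stringsAsFactors = FALSE)
  })
  structure(list(test = "paired_t_bonferroni", statistic = NA_real_,
                 df = NA_real_, p_value = NA_real_, p_adjusted = NA_real_,
                 effect_size = NA_real_, pairwise = do.call(rbind, rows)),
            class = "tes_test")
}

#' Kruskal-Wallis rank test with eta-squared effect size
#'
#' Tie-corrected H statistic against chi-square(k - 1), with the
#' H-based effect size `eta2 = (H - k + 1) / (N - k)`.
#'
#' @param groups Named list of numeric vectors.
#' @param n_comparisons Bonferroni factor for the omnibus p value.
#' @return A `tes_test` with `statistic` (H), `df`, `p_value`,
#'   `effect_size` (eta-squared).
#' @export
kruskal_wallis <- function(groups, n_comparisons = 1) {
  .check_groups(groups, min_n = 1)
  x <- unlist(groups, use.names = FALSE)
  if (length(unique(x)) == 1)
    stop("tie degeneracy: all observations identical")
  g <- factor(rep(names(groups), vapply(groups, length, integer(1))))
  kw <- stats::kruskal.test(x, g)
  k <- length(groups); N <- length(x)
  H <- unname(kw$statistic)
  structure(list(test = "kruskal_wallis", statistic = H,
                 df = unname(kw$parameter), p_value = kw$p.value,
                 p_adjusted = min(1, n_comparisons * kw$p.value),
                 effect_size = (H - k + 1) / (N - k),
                 pairwise = NULL),
            class = "tes_test")
}

#' Dunn's post-hoc test with Bonferroni correction
#'
#' Pairwise z statistics from the pooled mid-rank means,
#' `z = (Rbar_i - Rbar_j) / sqrt((N (N + 1) / 12 - T) (1/n_i + 1/n_j))`
#' with the tie correction `T = sum(t^3 - t) / (12 (N - 1))`; two-sided
#' normal p values, Bonferroni-corrected over the `k (k - 1) / 2` pairs.
#'
#' @param groups Named list of numeric vectors.
#' @param n_comparisons Bonferroni factor; defaults to the number of
#'   pairs.
#' @return A `tes_test` with a `pairwise` data frame (`pair`, `z`,
#'   `p_raw`, `p_adj`).
#' @export
dunn_test <- function(groups, n_comparisons = NULL) {
  .check_groups(groups, min_n = 1)
  x <- unlist(groups, use.names = FALSE)
  g <- rep(names(groups), vapply(groups, length, integer(1)))
  N <- length(x)
  r <- rank(x)                      # mid-ranks
  rbar <- tapply(r, g, mean)
  n <- tapply(r, g, length)
  ties <- table(x)
  Tcorr <- sum(ties^3 - ties) / (12 * (N - 1))
  s2 <- N * (N + 1) / 12 - Tcorr
  nm <- names(groups)
  pairs <- utils::combn(nm, 2)
  if (is.null(n_comparisons)) n_comparisons <- ncol(pairs)
  rows <- lapply(seq_len(ncol(pairs)), function(j) {
    a <- pairs[1, j]; b <- pairs[2, j]
    z <- (rbar[[a]] - rbar[[b]]) / sqrt(s2 * (1 / n[[a]] + 1 / n[[b]]))
    p <- 2 * stats::pnorm(-abs(z))
    data.frame(pair = paste(a, b, sep = " vs "), z = z, p_raw = p,
               p_adj = min(1, n_comparisons * p), stringsAsFactors = FALSE)
  })
  structure(list(test = "dunn_bonferroni", statistic = NA_real_,
                 df = NA_real_, p_value = NA_real_, p_adjusted = NA_real_,
                 effect_size = NA_real_, pairwise = do.call(rbind, rows)),
            class = "tes_test")
}

#' @export
print.tes_test <- function(x, ...) {
  cat(sprintf("%s:", x$test))
  if (is.finite(x$statistic))
    cat(sprintf(" statistic = %.4g, df = %s, p = %.4g (adj %.4g)",
                x$statistic, paste(signif(x$df, 4), collapse = ", "),
                x$p_value, x$p_adjusted))
  if (is.finite(x$effect_size)) cat(sprintf(", eta2 = %.4g", x$effect_size))
  cat("\n")
  if (!is.null(x$pairwise)) print(x$pairwise, row.names = FALSE, digits = 4)
  invisible(x)
}

#' Routed group comparison of an ROI summary metric
#'
#' The full statistical stage for one ROI/metric combination: every group
#' must pass the Shapiro-Wilk test at `alpha` for the ANOVA branch
#' (with paired t post-hoc tests); otherwise the Kruskal-Wallis branch is
#' taken (with Dunn's post-hoc test and the H-based eta-squared).  The
#' omnibus p value is Bonferroni-corrected by `n_rois`, the number of
#' regions analysed in the study.
#'
#' @param summaries Tidy summary table with at least `group` and `value`
#'   columns (e.g. from [run_group()]), already filtered — or pass
#'   `metric`/`roi`/`tissue` to filter here.
#' @param metric,roi,tissue Optional filters applied to the
#'   corresponding columns.
#' @param alpha Normality-gate level (default 0.05).
#' @param n_rois Bonferroni factor for the omnibus test (default 1).
#' @param expected_groups Group labels that must all be present (default:
#'   none enforced).
#' @return List of class `group_pipeline_result`: `route` ("anova" or
#'   "kruskal_wallis"), `normality` (per-group `tes_test`s), `omnibus`,
#'   `posthoc`.
#' @export
group_pipeline <- function(summaries, metric = NULL, roi = NULL,
                           tissue = NULL, alpha = 0.05, n_rois = 1,
                           expected_groups = NULL) {
  df <- summaries
  if (!is.null(metric)) df <- df[df$metric == metric, ]
  if (!is.null(roi)) df <- df[df$roi == roi, ]
  if (!is.null(tissue)) df <- df[!is.na(df$tissue) & df$tissue == tissue, ]
  if (!all(c("group", "value") %in% names(df)))
    stop("summaries must contain 'group' and 'value' columns")
  if (!is.null(expected_groups)) {
    missing <- setdiff(expected_groups, unique(df$group))
    if (length(missing))
      stop("missing groups: ", paste(missing, collapse = ", "),
           " (present: ", paste(unique(df$group), collapse = ", "), ")")
  }
  groups <- split(df$value, df$group)
  .check_groups(groups, min_n = 3)
  normality <- lapply(groups, normality_test)
  all_normal <- all(vapply(normality, function(t) t$p_value > alpha,
                           logical(1)))
  if (all_normal) {
    omnibus <- one_way_anova(groups, n_comparisons = n_rois)
    posthoc <- if (length(unique(lengths(groups))) == 1)
      paired_t_bonferroni(groups) else NULL
    route <- "anova"
  } else {
    omnibus <- kruskal_wallis(groups, n_comparisons = n_rois)
    posthoc <- dunn_test(groups)
    route <- "kruskal_wallis"
  }
  structure(list(route = route, normality = normality, omnibus = omnibus,
                 posthoc = posthoc, alpha = alpha, n_rois = n_rois),
            class = "group_pipeline_result")
}

#' @export
print.group_pipeline_result <- function(x, ...) {
  cat(sprintf("Group comparison (route: %s; normality gate alpha = %g, Bonferroni x%d)\n",
              x$route, x$alpha, x$n_rois))
  print(x$omnibus)
  if (!is.null(x$posthoc)) print(x$posthoc)
  invisible(x)
}
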