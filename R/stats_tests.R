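# The nonparametric test battery the analysis relies on, as thin uniform
# wrappers over the stats package: Kruskal-Wallis, pairwise Wilcoxon rank-sum
# with Benjamini-Hochberg correction, Spearman rank correlation, and the BH
# step-up itself. Every wrapper returns a plain list so results serialize
# cleanly into the pipeline report.

#' Kruskal-Wallis rank-sum test
#'
#' Tie-corrected H statistic with a chi-square p-value, via
#' [stats::kruskal.test()].
#'
#' @param values Numeric observations.
#' @param groups Group label per observation (>= 2 non-empty groups).
#' @return List: `statistic` (H), `p_value`, `df`, `method`.
#' @export
kruskal_wallis <- function(values, groups) {
  groups <- as.character(groups)
  if (length(values) != length(groups)) {
    stop("`values` and `groups` must align", call. = FALSE)
  }
  if (any(table(groups) == 0) || length(unique(groups)) < 2L) {
    stop("need at least 2 non-empty groups", call. = FALSE)
  }
  if (length(unique(values)) == 1L) {
    # all observations tied: no rank variation, H = 0 by convention
    return(list(statistic = 0, p_value = 1,
                df = length(unique(groups)) - 1L, method = "Kruskal-Wallis"))
  }
  kt <- stats::kruskal.test(values, factor(groups))
  list(statistic = unname(kt$statistic), p_value = kt$p.value,
       df = unname(kt$parameter), method = "Kruskal-Wallis")
}

#' Pairwise Wilcoxon rank-sum tests with FDR correction
#'
#' All group pairs via [stats::pairwise.wilcox.test()] with the normal
#' approximation (tie and continuity corrected) and Benjamini-Hochberg
#' adjustment across the pairs.
#'
#' @inheritParams kruskal_wallis
#' @return Data frame: `group1`, `group2`, `q_value` (BH-adjusted p).
#' @export
pairwise_wilcoxon_fdr <- function(values, groups) {
  groups <- factor(as.character(groups))
  if (nlevels(groups) < 2L) stop("need at least 2 groups", call. = FALSE)
  pw <- suppressWarnings(
    stats::pairwise.wilcox.test(values, groups, p.adjust.method = "fdr",
                                exact = FALSE, correct = TRUE))
  m <- pw$p.value
  out <- data.frame(group1 = rep(rownames(m), ncol(m)),
                    group2 = rep(colnames(m), each = nrow(m)),
                    q_value = as.vector(m), stringsAsFactors = FALSE)
  out[!is.na(out$q_value), , drop = FALSE]
}

#' Spearman rank correlation test
#'
#' Rho on average ranks with a t-approximation p-value (ties permitted), via
#' [stats::cor.test()].
#'
#' @param x,y Paired numeric vectors (>= 3 complete pairs; neither constant).
#' @return List: `estimate` (rho), `p_value`, `n`, `method`.
#' @export
spearman_test <- function(x, y) {
  keep <- stats::complete.cases(x, y)
  x <- x[keep]; y <- y[keep]
  if (length(x) < 3L) stop("need at least 3 paired observations", call. = FALSE)
  if (stats::var(x) == 0 || stats::var(y) == 0) {
    stop("a constant vector has no rank correlation", call. = FALSE)
  }
  ct <- suppressWarnings(stats::cor.test(x, y, method = "spearman", exact = FALSE))
  list(estimate = unname(ct$estimate), p_value = ct$p.value,
       n = length(x), method = "Spearman rank correlation")
}

#' Benjamini-Hochberg step-up adjustment
#'
#' `q_(i) = min_{j >= i} p_(j) * m / j`, capped at 1, returned in the input
#' order (a thin wrapper over [stats::p.adjust()]).
#'
#' @param p Vector of p-values.
#' @return Vector of q-values, same length and order.
#' @export
bh_adjust <- function(p) {
  stats::p.adjust(p, method = "BH")
}
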