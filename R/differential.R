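# SIMPER decomposition, differential ASV calling (SIMPER gate + per-ASV
# Kruskal-Wallis with BH correction), highly-prevalent rumen ASV sets, and
# per-swab core-capture fractions.

#' SIMPER: per-ASV contributions to between-group dissimilarity
#'
#' For every between-group sample pair (j, k) the Bray-Curtis dissimilarity
#' decomposes exactly as a sum of per-ASV terms
#' `delta_i = |x_ij - x_ik| / sum_i (x_ij + x_ik)`. The SIMPER contribution of
#' ASV i is the pair-averaged `delta_i` divided by the pair-averaged total
#' dissimilarity, so the contributions are non-negative and sum to 1.
#'
#' @param rel Samples x ASVs relative-abundance matrix (proportions mode).
#' @param group_a,group_b Non-overlapping, non-empty sample-id vectors.
#' @return Data frame sorted by decreasing contribution: `asv_id`,
#'   `mean_contribution`, `cumulative_contribution`, with the mean
#'   between-group dissimilarity as attribute `mean_dissimilarity`.
#' @export
simper_contributions <- function(rel, group_a, group_b) {
  validate_community(rel, mode = "proportions")
  if (length(group_a) == 0L || length(group_b) == 0L) {
    stop("both groups must be non-empty", call. = FALSE)
  }
  missing <- setdiff(c(group_a, group_b), rownames(rel))
  if (length(missing)) {
    stop("sample(s) absent from the table: ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  xa <- rel[group_a, , drop = FALSE]
  xb <- rel[group_b, , drop = FALSE]
  n_pairs <- nrow(xa) * nrow(xb)
  delta_sum <- numeric(ncol(rel))  # sum over pairs of per-ASV terms
  for (j in seq_len(nrow(xa))) {
    diffs <- abs(sweep(xb, 2, xa[j, ]))        # |x_b - x_a[j]| per pair
    denom <- rowSums(xb) + sum(xa[j, ])        # sum_i (x_ij + x_ik) per pair
    if (any(denom == 0)) {
      stop("a between-group pair has two all-zero samples", call. = FALSE)
    }
    delta_sum <- delta_sum + colSums(diffs / denom)
  }
  mean_delta <- delta_sum / n_pairs
  mean_bc <- sum(mean_delta)
  if (mean_bc == 0) {
    stop("groups are identical: mean between-group dissimilarity is zero, ",
         "SIMPER contributions undefined", call. = FALSE)
  }
  contrib <- mean_delta / mean_bc
  ord <- order(contrib, decreasing = TRUE)
  out <- data.frame(asv_id = colnames(rel)[ord],
                    mean_contribution = contrib[ord],
                    cumulative_contribution = cumsum(contrib[ord]),
                    row.names = NULL, stringsAsFactors = FALSE)
  attr(out, "mean_dissimilarity") <- mean_bc
  out
}

#' Differential ASVs between two groups (SIMPER gate + Kruskal-Wallis/FDR)
#'
#' ASVs contributing strictly more than `simper_threshold` of the mean
#' between-group Bray-Curtis dissimilarity are tested for an abundance
#' difference with a Kruskal-Wallis test on their relative abundances;
#' p-values are BH-adjusted over the gated set only. `direction` reports
#' which group has the higher median relative abundance.
#'
#' @param rel Samples x ASVs relative-abundance matrix.
#' @param group_a,group_b Sample-id vectors with >= 2 members each.
#' @param simper_threshold Contribution gate, strict `>` (default 0.01, i.e.
#'   a SIMPER score above 1%).
#' @param alpha Significance level on the q-values (default 0.05).
#' @return Data frame (possibly empty) of gated ASVs: `asv_id`,
#'   `simper_contribution`, `kw_p`, `q_value`, `significant`, `direction`.
#' @export
differential_asvs <- function(rel, group_a, group_b,
                              simper_threshold = 0.01, alpha = 0.05) {
  if (length(group_a) < 2L || length(group_b) < 2L) {
    stop("both groups need at least 2 members", call. = FALSE)
  }
  sim <- simper_contributions(rel, group_a, group_b)
  gated <- sim[sim$mean_contribution > simper_threshold, , drop = FALSE]
  if (nrow(gated) == 0L) {
    message("no ASV exceeds the SIMPER contribution gate of ", simper_threshold)
    return(data.frame(asv_id = character(), simper_contribution = numeric(),
                      kw_p = numeric(), q_value = numeric(),
                      significant = logical(), direction = character(),
                      stringsAsFactors = FALSE))
  }
  labels <- c(rep("A", length(group_a)), rep("B", length(group_b)))
  kw_p <- vapply(gated$asv_id, function(asv) {
    v <- c(rel[group_a, asv], rel[group_b, asv])
    kruskal_wallis(v, labels)$p_value
  }, numeric(1))
  direction <- vapply(gated$asv_id, function(asv) {
    ma <- stats::median(rel[group_a, asv])
    mb <- stats::median(rel[group_b, asv])
    if (ma > mb) "A" else if (mb > ma) "B" else "tie"
  }, character(1))
  q <- bh_adjust(kw_p)
  data.frame(asv_id = gated$asv_id,
             simper_contribution = gated$mean_contribution,
             kw_p = unname(kw_p), q_value = q,
             significant = q < alpha, direction = unname(direction),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Highly prevalent ASVs of a sample fraction
#'
#' Prevalence of an ASV in a fraction (e.g. the rumen solids) is the share of
#' that fraction's samples in which it is present (`count > 0`, i.e. at least
#' the minimum-filter depth before filtering). Membership requires prevalence
#' strictly above `threshold`. When `other_ids` is supplied, the ids unique
#' to this fraction (prevalent here but not in the other fraction) are also
#' reported.
#'
#' @param counts Samples x ASVs matrix (filtered counts).
#' @param fraction_ids Sample ids of the fraction (non-empty).
#' @param threshold Prevalence threshold, strict `>` (0.8 for bacteria, 0.5
#'   for fungi in a typical run).
#' @param other_ids Optional sample ids of the companion fraction.
#' @return List of class `prevalent_set`: `asv_ids`, `threshold`,
#'   `prevalence` (named, members only), `n_total`, `unique_ids`/`n_unique`
#'   (when `other_ids` given).
#' @export
prevalent_set <- function(counts, fraction_ids, threshold, other_ids = NULL) {
  validate_community(counts)
  if (length(fraction_ids) == 0L) stop("fraction has no samples", call. = FALSE)
  if (threshold < 0 || threshold >= 1) {
    stop("`threshold` must lie in [0, 1)", call. = FALSE)
  }
  missing <- setdiff(fraction_ids, rownames(counts))
  if (length(missing)) {
    stop("sample(s) absent from the table: ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  prev <- colMeans(counts[fraction_ids, , drop = FALSE] > 0)
  members <- names(prev)[prev > threshold]
  out <- list(asv_ids = members, threshold = threshold,
              prevalence = prev[members], n_total = length(members))
  if (!is.null(other_ids)) {
    other <- prevalent_set(counts, other_ids, threshold)
    out$unique_ids <- setdiff(members, other$asv_ids)
    out$n_unique <- length(out$unique_ids)
  }
  structure(out, class = "prevalent_set")
}

#' @export
print.prevalent_set <- function(x, ...) {
  cat(sprintf("<prevalent_set: %d ASVs at prevalence > %g%s>\n",
              x$n_total, x$threshold,
              if (!is.null(x$n_unique)) sprintf(", %d unique to this fraction", x$n_unique)
              else ""))
  invisible(x)
}

#' Per-swab capture of a highly prevalent ASV set
#'
#' For each swab, the count and percentage of the prevalent set's ASVs
#' present in the swab (`count > 0` in the filtered, rarefied table).
#'
#' @param counts Samples x ASVs matrix (filtered counts).
#' @param swab_ids Sample ids of the swabs.
#' @param set A `prevalent_set` with at least one member.
#' @return Data frame: `sample_id`, `captured`, `capture_pct` in `[0, 100]`.
#' @export
capture_fraction <- function(counts, swab_ids, set) {
  validate_community(counts)
  if (length(set$asv_ids) == 0L) stop("prevalent set is empty", call. = FALSE)
  missing <- setdiff(swab_ids, rownames(counts))
  if (length(missing)) {
    stop("swab(s) absent from the table: ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  present_cols <- intersect(set$asv_ids, colnames(counts))
  captured <- if (length(present_cols)) {
    rowSums(counts[swab_ids, present_cols, drop = FALSE] > 0)
  } else {
    rep(0, length(swab_ids))
  }
  data.frame(sample_id = swab_ids,
             captured = unname(captured),
             capture_pct = 100 * unname(captured) / length(set$asv_ids),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Correlation between darkness and core capture
#'
#' Spearman rank correlation of the per-swab capture percentage against the
#' swab darkness scores.
#'
#' @param records Output of [capture_fraction()].
#' @param darkness Named numeric vector of darkness scores (names = sample
#'   ids), or a vector aligned with `records`.
#' @return List: `estimate` (rho), `p_value`, `n`, `method`.
#' @export
capture_darkness_correlation <- function(records, darkness) {
  d <- if (!is.null(names(darkness))) darkness[records$sample_id] else darkness
  spearman_test(d, records$capture_pct)
}
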