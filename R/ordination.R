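# Principal coordinates analysis, PERMANOVA, darkness-vs-axes regression and
# mean ordination-space distance to the rumen reference groups.

#' Principal coordinates analysis (classical MDS)
#'
#' Gower double-centering of -D^2/2 followed by a symmetric
#' eigendecomposition; axis k is the k-th eigenvector scaled by the square
#' root of its eigenvalue. Negative eigenvalues (possible for non-Euclidean
#' dissimilarities such as Bray-Curtis) are reported but excluded from the
#' variance-explained denominator and never scaled into coordinates. Each
#' axis sign is fixed so the sample with the largest absolute loading is
#' positive.
#'
#' @param d Symmetric dissimilarity matrix with zero diagonal.
#' @param n_axes Number of axes to return (default all positive axes).
#' @return List of class `pcoa_result`: `coordinates` (samples x axes),
#'   `eigenvalues` (all, non-increasing), `proportion_explained` (per
#'   returned axis, relative to the sum of positive eigenvalues).
#' @export
pcoa_ordination <- function(d, n_axes = NULL) {
  check_distance(d)
  n <- nrow(d)
  if (!is.null(n_axes) && n_axes > n - 1L) {
    stop("`n_axes` cannot exceed n - 1", call. = FALSE)
  }
  a <- -0.5 * d^2
  centered <- sweep(sweep(a, 1, rowMeans(a)), 2, colMeans(a)) + mean(a)
  eig <- eigen((centered + t(centered)) / 2, symmetric = TRUE)
  values <- eig$values
  pos <- which(values > max(values[1], 0) * 1e-12)
  k <- if (is.null(n_axes)) length(pos) else min(n_axes, length(pos))
  axes <- eig$vectors[, pos[seq_len(k)], drop = FALSE] %*%
    diag(sqrt(values[pos[seq_len(k)]]), k, k)
  for (j in seq_len(k)) {
    imax <- which.max(abs(axes[, j]))
    if (axes[imax, j] < 0) axes[, j] <- -axes[, j]
  }
  dimnames(axes) <- list(rownames(d), paste0("Axis", seq_len(k)))
  structure(list(coordinates = axes,
                 eigenvalues = values,
                 proportion_explained = values[pos[seq_len(k)]] / sum(values[pos])),
            class = "pcoa_result")
}

#' @export
print.pcoa_result <- function(x, ...) {
  cat(sprintf("<pcoa_result: %d samples, %d axes; axis 1-2 explain %.1f%% + %.1f%%>\n",
              nrow(x$coordinates), ncol(x$coordinates),
              100 * x$proportion_explained[1],
              100 * (x$proportion_explained[2] %||% NA_real_)))
  invisible(x)
}

check_distance <- function(d) {
  if (!is.matrix(d) || nrow(d) != ncol(d)) {
    stop("distance must be a square matrix", call. = FALSE)
  }
  if (any(abs(d - t(d)) > 1e-12)) stop("distance matrix is not symmetric", call. = FALSE)
  if (any(diag(d) != 0)) stop("distance matrix has nonzero diagonal", call. = FALSE)
  if (any(d < 0)) stop("distance matrix has negative entries", call. = FALSE)
  invisible(d)
}

# All n! permutations of 1..n as rows, in lexicographic recursion order.
all_permutations <- function(n) {
  if (n == 1L) return(matrix(1L, 1, 1))
  sub <- all_permutations(n - 1L)
  do.call(rbind, lapply(seq_len(n), function(k) {
    cbind(k, sub + (sub >= k))
  }))
}

# One-factor PERMANOVA sums of squares: total and within-group, from squared
# distances. `g` is an integer group index per sample.
permanova_ss <- function(d2, g, sizes) {
  n <- nrow(d2)
  ss_total <- sum(d2[upper.tri(d2)]) / n
  ss_within <- 0
  for (k in seq_along(sizes)) {
    idx <- which(g == k)
    ss_within <- ss_within + sum(d2[idx, idx]) / (2 * sizes[k])
  }
  c(total = ss_total, within = ss_within)
}

#' One-factor PERMANOVA
#'
#' Permutational multivariate analysis of variance on a distance matrix.
#' The pseudo-F is `(SS_between / (a - 1)) / (SS_within / (n - a))` with
#' `SS_total = sum_{i<j} d_ij^2 / n` and `SS_within` its per-group analogue;
#' the p-value is `(1 + #{F_perm >= F_obs}) / (1 + n_perm)` over seeded label
#' permutations, so p is never exactly 0.
#'
#' With `exhaustive = TRUE` the p-value is computed over all `n!` label
#' orderings instead of random draws (`p = #\{F_perm >= F_obs\} / n!`, the
#' identity ordering included), feasible for n <= 8; label-set symmetry makes
#' this equal to enumeration over the distinct group assignments.
#'
#' If all pairwise distances are zero the statistic is undefined; the test
#' returns `F = NA`, `p = 1` with a message.
#'
#' @param d Symmetric distance matrix.
#' @param labels Group label per sample; every group needs >= 2 members.
#' @param n_perm Number of label permutations (default 999).
#' @param seed Integer seed for the permutations.
#' @param exhaustive Enumerate all label orderings instead of sampling.
#' @return List: `statistic` (pseudo-F), `p_value`, `r_squared`, `df`,
#'   `n_perm`, `method`.
#' @export
permanova <- function(d, labels, n_perm = 999L, seed = 1L, exhaustive = FALSE) {
  check_distance(d)
  labels <- as.character(labels)
  n <- nrow(d)
  if (length(labels) != n) stop("one label per sample required", call. = FALSE)
  sizes <- table(labels)
  if (length(sizes) < 2L) stop("need at least 2 groups", call. = FALSE)
  if (any(sizes < 2L)) {
    stop("group(s) with fewer than 2 members: ",
         paste(names(sizes)[sizes < 2], collapse = ", "), call. = FALSE)
  }
  a <- length(sizes)
  g <- as.integer(factor(labels, levels = names(sizes)))
  d2 <- d^2
  ss <- permanova_ss(d2, g, as.vector(sizes))
  if (ss[["total"]] <= 0) {
    message("all pairwise distances are zero; PERMANOVA undefined, returning p = 1")
    return(list(statistic = NA_real_, p_value = 1, r_squared = NA_real_,
                df = c(a - 1L, n - a), n_perm = n_perm, method = "PERMANOVA"))
  }
  f_stat <- function(ssv) {
    ((ssv[["total"]] - ssv[["within"]]) / (a - 1)) / (ssv[["within"]] / (n - a))
  }
  f_obs <- f_stat(ss)
  if (exhaustive) {
    if (n > 8L) stop("exhaustive enumeration is limited to n <= 8 samples", call. = FALSE)
    perms <- all_permutations(n)
    f_all <- vapply(seq_len(nrow(perms)), function(i) {
      f_stat(permanova_ss(d2, g[perms[i, ]], as.vector(sizes)))
    }, numeric(1))
    p_value <- mean(f_all >= f_obs - 1e-12)
    n_used <- nrow(perms)
    method <- "PERMANOVA (exhaustive)"
  } else {
    exceed <- local_seed(seed, {
      sum(vapply(seq_len(n_perm), function(i) {
        f_stat(permanova_ss(d2, sample(g), as.vector(sizes)))
      }, numeric(1)) >= f_obs)
    })
    p_value <- (1 + exceed) / (1 + n_perm)
    n_used <- n_perm
    method <- "PERMANOVA"
  }
  list(statistic = f_obs,
       p_value = p_value,
       r_squared = (ss[["total"]] - ss[["within"]]) / ss[["total"]],
       df = c(a - 1L, n - a),
       n_perm = n_used,
       method = method)
}

#' Regress darkness on the first two ordination axes
#'
#' Ordinary least squares `darkness ~ Axis1 + Axis2` over the swabs,
#' reporting per-axis coefficients, t statistics and p-values plus the model
#' R-squared. Used to ask whether a swab's position in community space tracks
#' its color.
#'
#' @param darkness Numeric darkness score per swab.
#' @param ordination A `pcoa_result`, or a samples x axes coordinate matrix.
#' @param swab_ids Optional sample ids selecting (and ordering) the rows of
#'   the coordinates to use; defaults to all rows, in which case `darkness`
#'   must align with the coordinate rows.
#' @return List: `coefficients` data frame (term, estimate, t, p) and
#'   `r_squared`.
#' @export
regress_on_axes <- function(darkness, ordination, swab_ids = NULL) {
  coords <- if (inherits(ordination, "pcoa_result")) ordination$coordinates
            else ordination
  if (!is.null(swab_ids)) coords <- coords[swab_ids, , drop = FALSE]
  if (ncol(coords) < 2L) stop("need at least two ordination axes", call. = FALSE)
  if (length(darkness) != nrow(coords)) {
    stop("`darkness` must align with the ordination rows", call. = FALSE)
  }
  if (length(darkness) < 3L) stop("need at least 3 swabs", call. = FALSE)
  if (stats::var(darkness) == 0) {
    stop("darkness is constant; regression undefined", call. = FALSE)
  }
  df <- data.frame(darkness = darkness, axis1 = coords[, 1], axis2 = coords[, 2])
  fit <- stats::lm(darkness ~ axis1 + axis2, data = df)
  sm <- summary(fit)
  co <- stats::coef(sm)
  list(coefficients = data.frame(term = rownames(co),
                                 estimate = co[, "Estimate"],
                                 t = co[, "t value"],
                                 p = co[, "Pr(>|t|)"],
                                 row.names = NULL, stringsAsFactors = FALSE),
       r_squared = sm$r.squared)
}

#' Mean ordination distance from each swab to a reference group
#'
#' For each swab, the arithmetic mean of Euclidean distances (in the first
#' two ordination axes by default) to every sample of a reference set, e.g.
#' the rumen solids. Downstream this is correlated with darkness.
#'
#' @param ordination A `pcoa_result` or coordinate matrix with named rows.
#' @param swab_ids Sample ids of the swabs.
#' @param reference_ids Sample ids of the (non-empty) reference group.
#' @param n_axes Number of leading axes to measure in (default 2, the plotted
#'   plane; use `ncol(coordinates)` for the full embedding).
#' @return Data frame `sample_id`, `mean_dist`.
#' @export
mean_distance_to_reference <- function(ordination, swab_ids, reference_ids,
                                       n_axes = 2L) {
  coords <- if (inherits(ordination, "pcoa_result")) ordination$coordinates
            else ordination
  if (length(reference_ids) == 0L) stop("reference set is empty", call. = FALSE)
  missing <- setdiff(c(swab_ids, reference_ids), rownames(coords))
  if (length(missing)) {
    stop("sample(s) absent from the ordination: ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  n_axes <- min(n_axes, ncol(coords))
  sw <- coords[swab_ids, seq_len(n_axes), drop = FALSE]
  rf <- coords[reference_ids, seq_len(n_axes), drop = FALSE]
  md <- vapply(seq_len(nrow(sw)), function(i) {
    mean(sqrt(colSums((t(rf) - sw[i, ])^2)))
  }, numeric(1))
  data.frame(sample_id = swab_ids, mean_dist = md,
             row.names = NULL, stringsAsFactors = FALSE)
}
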