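# Alpha-diversity estimators and beta-diversity dissimilarities, implemented
# from their standard definitions:
#
#   Chao1 (bias-corrected)  S_obs + F1 (F1 - 1) / (2 (F2 + 1))
#   Shannon (nats)          -sum p_i log p_i
#   inverse Simpson         1 / sum p_i^2
#   Bray-Curtis             sum |x_i - y_i| / sum (x_i + y_i)
#   quantitative Jaccard    2 BC / (1 + BC)
#   binary Jaccard          1 - |A n B| / |A u B| on the supports
#   unweighted UniFrac      branch length unique to one sample's leaves over
#                           branch length reaching either sample's leaves

#' Alpha diversity of one sample
#'
#' @param x Non-negative abundance vector for one sample (integer counts
#'   required for Chao1).
#' @param metric One of `"chao1"`, `"shannon"`, `"inv_simpson"`.
#' @return Numeric scalar.
#' @export
alpha_diversity <- function(x, metric = c("chao1", "shannon", "inv_simpson")) {
  metric <- match.arg(metric)
  if (anyNA(x) || any(x < 0)) stop("abundances must be non-negative", call. = FALSE)
  if (sum(x) == 0) stop("all-zero abundance vector", call. = FALSE)
  switch(metric,
    chao1 = {
      if (any(x != round(x))) {
        stop("Chao1 requires integer counts (singletons/doubletons are undefined otherwise)",
             call. = FALSE)
      }
      s_obs <- sum(x > 0)
      f1 <- sum(x == 1)
      f2 <- sum(x == 2)
      s_obs + f1 * (f1 - 1) / (2 * (f2 + 1))
    },
    shannon = {
      p <- x[x > 0] / sum(x)
      -sum(p * log(p))
    },
    inv_simpson = {
      p <- x / sum(x)
      1 / sum(p^2)
    })
}

#' Alpha-diversity table for every sample
#'
#' @param counts Samples x ASVs count matrix (rarefied, filtered counts in a
#'   typical workflow).
#' @return Data frame with columns `sample_id`, `chao1`, `shannon`,
#'   `inv_simpson`.
#' @export
alpha_diversity_table <- function(counts) {
  validate_community(counts)
  data.frame(
    sample_id   = rownames(counts),
    chao1       = apply(counts, 1, alpha_diversity, metric = "chao1"),
    shannon     = apply(counts, 1, alpha_diversity, metric = "shannon"),
    inv_simpson = apply(counts, 1, alpha_diversity, metric = "inv_simpson"),
    row.names = NULL, stringsAsFactors = FALSE)
}

#' Bray-Curtis dissimilarity between two samples
#'
#' @param x,y Equal-length non-negative abundance vectors, not both all-zero.
#' @return Dissimilarity in `[0, 1]`.
#' @export
bray_curtis <- function(x, y) {
  check_pair(x, y)
  sum(abs(x - y)) / sum(x + y)
}

#' Jaccard dissimilarity between two samples
#'
#' The quantitative form is the monotone Bray-Curtis transform
#' `2 BC / (1 + BC)`; the binary form works on presence/absence supports.
#'
#' @inheritParams bray_curtis
#' @param binary If `TRUE`, compute `1 - |A n B| / |A u B|` on supports.
#' @return Dissimilarity in `[0, 1]`.
#' @export
jaccard <- function(x, y, binary = FALSE) {
  check_pair(x, y)
  if (binary) {
    a <- x > 0
    b <- y > 0
    1 - sum(a & b) / sum(a | b)
  } else {
    bc <- bray_curtis(x, y)
    2 * bc / (1 + bc)
  }
}

check_pair <- function(x, y) {
  if (length(x) != length(y)) stop("vectors must have equal length", call. = FALSE)
  if (anyNA(x) || anyNA(y) || any(x < 0) || any(y < 0)) {
    stop("abundances must be non-negative", call. = FALSE)
  }
  if (sum(x) == 0 && sum(y) == 0) {
    stop("both samples are all-zero; dissimilarity undefined", call. = FALSE)
  }
  invisible(NULL)
}

# Branch (edge) x leaf incidence of a rooted tree: entry [e, l] is TRUE when
# leaf l descends from edge e. One postorder pass.
edge_leaf_incidence <- function(tree) {
  n_tip <- length(tree$tip.label)
  tr <- ape::reorder.phylo(tree, "postorder")
  n_node <- n_tip + tree$Nnode
  below <- matrix(FALSE, n_node, n_tip)
  below[cbind(seq_len(n_tip), seq_len(n_tip))] <- TRUE
  for (i in seq_len(nrow(tr$edge))) {
    parent <- tr$edge[i, 1]
    child <- tr$edge[i, 2]
    below[parent, ] <- below[parent, ] | below[child, ]
  }
  inc <- below[tr$edge[, 2], , drop = FALSE]
  colnames(inc) <- tree$tip.label
  list(incidence = inc, lengths = tr$edge.length)
}

#' Unweighted UniFrac distance matrix
#'
#' For each pair of samples, the fraction of branch length leading to leaves
#' present in exactly one of the two samples, out of the branch length leading
#' to leaves present in either. Presence is `count > 0`; every ASV column of
#' the table must be a leaf of the rooted tree.
#'
#' @param counts Samples x ASVs matrix (counts or proportions; only the
#'   support is used).
#' @param tree Rooted `phylo` tree with branch lengths whose tips cover the
#'   table's ASVs.
#' @return Symmetric n x n distance matrix with zero diagonal.
#' @export
unweighted_unifrac <- function(counts, tree) {
  validate_community(counts)
  missing <- setdiff(colnames(counts), tree$tip.label)
  if (length(missing)) {
    stop("ASV(s) missing from the tree: ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  if (is.null(tree$edge.length)) stop("tree has no branch lengths", call. = FALSE)
  el <- edge_leaf_incidence(tree)
  # edges x samples: does edge e lead to any leaf present in sample s?
  pres <- t(counts > 0)                                     # ASVs x samples
  pres_full <- matrix(FALSE, length(tree$tip.label), ncol(pres),
                      dimnames = list(tree$tip.label, colnames(pres)))
  pres_full[rownames(pres), ] <- pres
  reach <- (el$incidence %*% pres_full) > 0                 # edges x samples
  n <- nrow(counts)
  d <- matrix(0, n, n, dimnames = list(rownames(counts), rownames(counts)))
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      either <- reach[, i] | reach[, j]
      tot <- sum(el$lengths[either])
      if (tot == 0) {
        stop(sprintf("samples '%s' and '%s' reach no branch length; UniFrac undefined",
                     rownames(counts)[i], rownames(counts)[j]), call. = FALSE)
      }
      uniq <- sum(el$lengths[xor(reach[, i], reach[, j])])
      d[i, j] <- d[j, i] <- uniq / tot
    }
  }
  d
}

#' Pairwise dissimilarity matrix
#'
#' @param counts Samples x ASVs matrix with at least 2 samples.
#' @param metric `"bray"`, `"jaccard"`, `"jaccard_binary"` or `"unifrac"`.
#' @param tree Rooted `phylo`; required for `metric = "unifrac"`.
#' @return Symmetric matrix of dissimilarities with a `metric` attribute.
#' @export
distance_matrix <- function(counts, metric = c("bray", "jaccard",
                                               "jaccard_binary", "unifrac"),
                            tree = NULL) {
  metric <- match.arg(metric)
  validate_community(counts)
  if (nrow(counts) < 2L) stop("need at least 2 samples", call. = FALSE)
  if (metric == "unifrac") {
    if (is.null(tree)) stop("UniFrac requires a rooted tree", call. = FALSE)
    d <- unweighted_unifrac(counts, tree)
  } else {
    fun <- switch(metric,
                  bray = bray_curtis,
                  jaccard = function(x, y) jaccard(x, y, binary = FALSE),
                  jaccard_binary = function(x, y) jaccard(x, y, binary = TRUE))
    n <- nrow(counts)
    d <- matrix(0, n, n, dimnames = list(rownames(counts), rownames(counts)))
    for (i in seq_len(n - 1)) {
      for (j in (i + 1):n) {
        d[i, j] <- d[j, i] <- fun(counts[i, ], counts[j, ])
      }
    }
  }
  attr(d, "metric") <- metric
  d
}
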