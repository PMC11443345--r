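# Independent oracles and fixture builders shared across the suite. The
# oracles deliberately use different code paths (vegan/ape/naive loops) from
# the package implementations they check.

# Random count table with guaranteed non-empty samples.
rand_count_table <- function(n_samples, n_asvs, lambda = 5) {
  m <- matrix(stats::rpois(n_samples * n_asvs, lambda), n_samples, n_asvs,
              dimnames = list(sprintf("s%02d", seq_len(n_samples)),
                              sprintf("a%02d", seq_len(n_asvs))))
  empty <- rowSums(m) == 0
  m[empty, 1] <- 1
  m
}

# Brute-force unweighted UniFrac for one pair of presence vectors: enumerate
# every edge, find its descendant tips via ape clade extraction, and
# accumulate shared/unique branch length.
bf_unifrac_pair <- function(pres_a, pres_b, tree) {
  n_tip <- length(tree$tip.label)
  tips_a <- names(pres_a)[pres_a > 0]
  tips_b <- names(pres_b)[pres_b > 0]
  uniq <- 0; total <- 0
  for (e in seq_len(nrow(tree$edge))) {
    child <- tree$edge[e, 2]
    tips <- if (child <= n_tip) tree$tip.label[child]
            else ape::extract.clade(tree, child)$tip.label
    in_a <- any(tips %in% tips_a)
    in_b <- any(tips %in% tips_b)
    if (in_a || in_b) total <- total + tree$edge.length[e]
    if (xor(in_a, in_b)) uniq <- uniq + tree$edge.length[e]
  }
  uniq / total
}

# Independent one-factor pseudo-F from first principles (explicit loops).
bf_pseudo_f <- function(d, groups) {
  n <- nrow(d)
  lv <- unique(groups)
  d2 <- d^2
  sst <- 0
  for (i in seq_len(n - 1)) for (j in (i + 1):n) sst <- sst + d2[i, j]
  sst <- sst / n
  ssw <- 0
  for (g in lv) {
    idx <- which(groups == g)
    acc <- 0
    for (i in idx) for (j in idx) if (i < j) acc <- acc + d2[i, j]
    ssw <- ssw + acc / length(idx)
  }
  a <- length(lv)
  ((sst - ssw) / (a - 1)) / (ssw / (n - a))
}

# Exhaustive two-group PERMANOVA p over all n! label orderings, via distinct
# assignments (each assignment of sizes (k, n-k) corresponds to k!(n-k)!
# orderings, a constant, so the assignment-level mean equals the
# ordering-level mean).
bf_permanova_exhaustive_p <- function(d, groups) {
  n <- nrow(d)
  lv <- unique(groups)
  stopifnot(length(lv) == 2)
  k <- sum(groups == lv[1])
  f_obs <- bf_pseudo_f(d, groups)
  sets <- utils::combn(n, k)
  fs <- apply(sets, 2, function(idx) {
    g <- rep(lv[2], n); g[idx] <- lv[1]
    bf_pseudo_f(d, g)
  })
  mean(fs >= f_obs - 1e-12)
}

# Small distance matrix from a Euclidean point cloud.
euclid_dist <- function(pts, ids = sprintf("s%02d", seq_len(nrow(pts)))) {
  d <- as.matrix(stats::dist(pts))
  dimnames(d) <- list(ids, ids)
  d
}

# Default synthetic study used by the end-to-end tests (the generator's
# default conditions; built once per test run).
default_study <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      refs <- simulate_references()
      design <- mixture_design()
      cache <<- list(refs = refs, design = design,
                     dataset = simulate_dataset(design, refs))
    }
    cache
  }
})
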