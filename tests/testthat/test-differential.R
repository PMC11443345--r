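test_that("SIMPER reproduces the single-pair decomposition by hand", {
  rel <- rbind(g1 = c(0.6, 0.4), g2 = c(0.2, 0.8))
  colnames(rel) <- c("a1", "a2")
  rel <- swabshade::relative_abundance(rel * 100)  # mark as proportions
  sim <- simper_contributions(rel, "g1", "g2")
  # BC = (0.4 + 0.4) / 2 = 0.4; each ASV carries 0.4/2 = 0.2, i.e. half
  expect_equal(attr(sim, "mean_dissimilarity"), 0.4, tolerance = 1e-12)
  expect_equal(sim$mean_contribution, c(0.5, 0.5), tolerance = 1e-12)
  expect_equal(sim$cumulative_contribution, c(0.5, 1), tolerance = 1e-12)
})

test_that("SIMPER conserves the mean between-group dissimilarity", {
  set.seed(33)
  for (rep in 1:20) {
    rel <- relative_abundance(rand_count_table(12, 15))
    ga <- rownames(rel)[1:6]; gb <- rownames(rel)[7:12]
    sim <- simper_contributions(rel, ga, gb)
    expect_equal(sum(sim$mean_contribution), 1, tolerance = 1e-10)
    expect_true(all(sim$mean_contribution >= 0))
    # pair-averaged BC from the distance matrix equals the SIMPER total
    d <- distance_matrix(rel, "bray")
    expect_equal(attr(sim, "mean_dissimilarity"), mean(d[ga, gb]),
                 tolerance = 1e-10)
    # and the contributions agree with vegan's simper decomposition
    vs <- summary(vegan::simper(rel, rep(c("A", "B"), each = 6),
                                permutations = 0))[[1]]
    expect_equal(sim$mean_contribution[match(rownames(vs), sim$asv_id)],
                 vs$average / sum(vs$average), tolerance = 1e-10)
  }

  same <- relative_abundance(matrix(5, 4, 2,
                                    dimnames = list(paste0("s", 1:4),
                                                    c("a1", "a2"))))
  expect_error(simper_contributions(same, c("s1", "s2"), c("s3", "s4")),
               "identical")
})

test_that("the differential gate is strictly greater-than the SIMPER threshold", {
  set.seed(34)
  rel <- relative_abundance(rand_count_table(10, 8))
  ga <- rownames(rel)[1:5]; gb <- rownames(rel)[6:10]
  sim <- simper_contributions(rel, ga, gb)
  # gate at the largest contribution: strict > must exclude it
  top <- sim$mean_contribution[1]
  res <- suppressMessages(
    differential_asvs(rel, ga, gb, simper_threshold = top))
  expect_equal(nrow(res), 0)
  # gate just below: exactly the top ASV survives
  res2 <- differential_asvs(rel, ga, gb, simper_threshold = top - 1e-12)
  expect_equal(res2$asv_id, sim$asv_id[1])
})

test_that("a planted fully-separated ASV is recovered with the right direction", {
  set.seed(35)
  n <- 13
  counts <- rand_count_table(2 * n, 20, lambda = 30)
  counts[1:n, "a01"] <- sample(200:300, n)        # high in group A
  counts[(n + 1):(2 * n), "a01"] <- sample(0:3, n, replace = TRUE)
  rel <- relative_abundance(counts)
  ga <- rownames(rel)[1:n]; gb <- rownames(rel)[(n + 1):(2 * n)]
  res <- differential_asvs(rel, ga, gb)
  hit <- res[res$asv_id == "a01", ]
  expect_equal(nrow(hit), 1)
  expect_true(hit$significant)
  expect_lt(hit$q_value, 0.05)
  expect_equal(hit$direction, "A")
})

test_that("differential calls control the FDR on label-permuted data", {
  set.seed(36)
  false_pos <- replicate(500, {
    counts <- rand_count_table(12, 15, lambda = 25)
    rel <- relative_abundance(counts)
    ids <- sample(rownames(rel))        # exchangeable labels: global null
    res <- differential_asvs(rel, ids[1:6], ids[7:12])
    sum(res$significant)
  })
  # every discovery on null data is false; BH at q < 0.05 keeps the rate low
  expect_lt(mean(false_pos > 0), 0.08)
})

test_that("prevalent sets use strict thresholds and presence only", {
  counts <- matrix(0, 12, 3, dimnames = list(sprintf("r%02d", 1:12),
                                             c("a1", "a2", "a3")))
  counts[1:10, "a1"] <- 5     # prevalence 10/12 = 0.8333 > 0.8
  counts[, "a2"] <- 2         # prevalence 1 everywhere
  counts[1:8, "a3"] <- 9      # prevalence 8/10 = 0.8 exactly in r01..r10
  ps <- prevalent_set(counts, rownames(counts), threshold = 0.8)
  expect_setequal(ps$asv_ids, c("a1", "a2"))
  expect_equal(unname(ps$prevalence["a1"]), 10 / 12, tolerance = 1e-12)

  ps10 <- prevalent_set(counts, rownames(counts)[1:10], threshold = 0.8)
  expect_false("a3" %in% ps10$asv_ids)  # exactly 80% is excluded

  # presence/absence basis: rescaling depths changes nothing
  ps_scaled <- prevalent_set(counts * 17, rownames(counts), threshold = 0.8)
  expect_identical(ps_scaled$asv_ids, ps$asv_ids)

  # unique-to-fraction bookkeeping against a second fraction
  other <- counts; other[, "a1"] <- 0
  both <- rbind(counts, `rownames<-`(other, sprintf("q%02d", 1:12)))
  ps2 <- prevalent_set(both, sprintf("r%02d", 1:12), 0.8,
                       other_ids = sprintf("q%02d", 1:12))
  expect_setequal(ps2$unique_ids, "a1")
  expect_error(prevalent_set(counts, character(0), 0.8), "no samples")
  expect_error(prevalent_set(counts, rownames(counts), 1), "threshold")
})

test_that("capture percentages are anchored and monotone under augmentation", {
  counts <- rbind(sw1 = c(3, 5, 2, 0), sw2 = c(0, 0, 0, 4),
                  r1 = c(10, 10, 10, 0), r2 = c(10, 10, 10, 0))
  colnames(counts) <- paste0("a", 1:4)
  ps <- prevalent_set(counts, c("r1", "r2"), 0.8)
  expect_setequal(ps$asv_ids, c("a1", "a2", "a3"))
  cap <- capture_fraction(counts, c("sw1", "sw2"), ps)
  expect_equal(cap$capture_pct, c(100, 0))

  # adding reads of prevalent ASVs never lowers capture
  aug <- counts; aug["sw2", "a1"] <- 12
  cap2 <- capture_fraction(aug, c("sw1", "sw2"), ps)
  expect_true(all(cap2$capture_pct >= cap$capture_pct))

  dk <- c(sw1 = 0.7, sw2 = 0.4)
  ct <- capture_darkness_correlation(rbind(cap, cap, cap), rep(dk, 3))
  expect_equal(ct$estimate, 1)
})
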