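toy_counts <- function() {
  matrix(c(6, 2, 2,
           1, 9, 0,
           4, 4, 4), 3, 3, byrow = TRUE,
         dimnames = list(c("s1", "s2", "s3"), c("a1", "a2", "a3")))
}

test_that("count-table IO validates and round-trips", {
  dir <- withr::local_tempdir()
  path <- file.path(dir, "toy.tsv")
  write_count_table(toy_counts(), path)
  back <- read_count_table(path)
  expect_equal(unclass(back), toy_counts(), ignore_attr = TRUE)

  set.seed(8)
  rnd <- rand_count_table(7, 11)
  write_count_table(rnd, path)
  expect_equal(unclass(read_count_table(path)), rnd, ignore_attr = TRUE)

  writeLines(c("sample_id\ta1\ta2", "s1\t1\t2", "s1\t3\t4"), path)
  expect_error(read_count_table(path), "duplicate sample id 's1'")
  writeLines(c("sample_id\ta1\ta2", "s1\t1\t-2"), path)
  expect_error(read_count_table(path), "negative count")
  writeLines(c("sample_id\ta1\ta2", "s1\t1\tx"), path)
  expect_error(read_count_table(path), "non-numeric")
})

test_that("taxon-removal rules drop exactly the matching ASVs", {
  counts <- rand_count_table(4, 6)
  tax <- data.frame(asv_id = colnames(counts),
                    Kingdom = c("Bacteria", "Archaea", "Bacteria", "Bacteria",
                                "Bacteria", "Bacteria"),
                    Order = c("Clostridiales", "X", "Chloroplast", "X", "X", "X"),
                    Family = c("F1", "F2", "F3", "Mitochondria", "Mitochondria", "F6"),
                    stringsAsFactors = FALSE)
  out <- remove_taxa(counts, tax)
  expect_setequal(colnames(out), c("a01", "a06"))
  expect_equal(unclass(out), counts[, c("a01", "a06")], ignore_attr = TRUE)

  none <- remove_taxa(counts, transform(tax, Kingdom = "Bacteria",
                                        Order = "X", Family = "F"))
  expect_equal(unclass(none), counts, ignore_attr = TRUE)
})

test_that("rarefaction subsamples exactly and drops shallow samples", {
  set.seed(5)
  counts <- rand_count_table(8, 15, lambda = 20)
  counts["s03", ] <- 0; counts["s03", 1:2] <- c(3, 4)  # shallow sample
  rare <- suppressMessages(rarefy_counts(counts, depth = 100, seed = 2))
  expect_false("s03" %in% rownames(rare))
  expect_identical(attr(rare, "dropped"), "s03")
  expect_true(all(rowSums(rare) == 100))
  expect_true(all(rare <= counts[rownames(rare), ]))  # without replacement

  # a sample whose total equals the depth is returned unchanged
  exact <- matrix(c(60, 40, 10, 200), 2, 2, byrow = TRUE,
                  dimnames = list(c("s1", "s2"), c("a1", "a2")))
  r2 <- rarefy_counts(exact, depth = 100, seed = 1)
  expect_equal(r2["s1", ], c(a1 = 60, a2 = 40))

  # determinism and expectation-preservation of the subsample
  r3 <- suppressMessages(rarefy_counts(counts, depth = 100, seed = 2))
  expect_identical(unclass(rare), unclass(r3))
  expect_error(rarefy_counts(counts, depth = 0), "positive")
  expect_error(rarefy_counts(exact, depth = 1e6), "no samples survive")
})

test_that("the minimum-count filter zeroes sub-threshold cells and is idempotent", {
  m <- matrix(c(9, 10, 0, 11,
                1, 15, 9, 10), 2, 4, byrow = TRUE,
              dimnames = list(c("s1", "s2"), paste0("a", 1:4)))
  f <- min_count_filter(m, 10)
  expect_equal(f["s1", ], c(a2 = 10, a4 = 11))  # a1 column (9, 1) dropped entirely
  expect_equal(f["s2", ], c(a2 = 15, a4 = 10))  # the 9 in a3 is zeroed, column dropped
  expect_false(any(c("a1", "a3") %in% colnames(f)))
  expect_equal(unclass(min_count_filter(f, 10)), unclass(f), ignore_attr = TRUE)

  allbig <- matrix(10:13, 2, 2, dimnames = list(c("s1", "s2"), c("a1", "a2")))
  expect_equal(unclass(min_count_filter(allbig, 10)), allbig, ignore_attr = TRUE)
})

test_that("relative abundance normalizes rows", {
  rel <- relative_abundance(toy_counts())
  expect_equal(rel["s1", ], c(a1 = 0.6, a2 = 0.2, a3 = 0.2))
  expect_equal(unname(rowSums(rel)), rep(1, 3), tolerance = 1e-12)
  expect_equal(rel["s3", ], c(a1 = 1, a2 = 1, a3 = 1) / 3)
  zero <- toy_counts(); zero["s2", ] <- 0
  expect_error(relative_abundance(zero), "s2")
})

test_that("rank aggregation conserves abundance and top_taxa pools the rest", {
  counts <- rand_count_table(5, 8, lambda = 12)
  tax <- data.frame(asv_id = colnames(counts),
                    Phylum = c("P1", "P1", "P2", "P3", "P3", "P3", "P4", NA),
                    stringsAsFactors = FALSE)
  agg <- aggregate_rank(counts, tax, "Phylum")
  expect_equal(unname(rowSums(agg)), unname(rowSums(counts)))
  expect_equal(agg[, "P1"], counts[, 1] + counts[, 2])
  expect_true("Unclassified" %in% colnames(agg))
  expect_error(aggregate_rank(counts, tax, "Genus"), "Genus")

  rel <- relative_abundance(agg)
  groups <- c("g1", "g1", "g2", "g2", "g2")
  # hand-computed top-2: group means of each phylum, grand mean ranks
  gm <- rbind(colMeans(rel[1:2, ]), colMeans(rel[3:5, ]))
  keep <- names(sort(colMeans(gm), decreasing = TRUE))[1:2]
  tt <- top_taxa(rel, groups, n = 2)
  expect_setequal(colnames(tt), c(keep, "Other"))
  expect_equal(unname(tt[, "Other"]),
               unname(1 - rowSums(gm[, keep, drop = FALSE])), tolerance = 1e-12)
  # n larger than the number of taxa keeps everything, Other is empty
  tt_all <- top_taxa(rel, groups, n = 50)
  expect_equal(unname(tt_all[, "Other"]), c(0, 0))
})

meta_swabs <- function(darkness, ids = sprintf("sw%03d", seq_along(darkness))) {
  data.frame(sample_id = ids, sample_type = "swab", darkness = darkness,
             stringsAsFactors = FALSE)
}

test_that("decile groups partition ranks with the stated size rule", {
  m20 <- assign_percentile_groups(meta_swabs(seq(0.1, 0.9, length.out = 20)))
  expect_equal(as.vector(table(m20$percentile_group)), rep(2L, 10))
  darkest <- m20$sample_id[order(m20$darkness, decreasing = TRUE)][1:2]
  expect_true(all(m20$percentile_group[m20$sample_id %in% darkest] == "Hundredth"))

  m23 <- assign_percentile_groups(meta_swabs(runif(23)))
  expect_equal(as.vector(table(m23$percentile_group)),
               c(3L, 3L, 3L, rep(2L, 7)))

  # full ties: assignment falls back to sample-id order, deterministically
  tied <- suppressMessages(assign_percentile_groups(meta_swabs(rep(0.5, 20))))
  expect_equal(as.character(tied$percentile_group[1:2]), c("Tenth", "Tenth"))
  expect_equal(as.character(tied$percentile_group[19:20]),
               c("Hundredth", "Hundredth"))
  expect_error(assign_percentile_groups(meta_swabs(runif(9))), "at least 10")
})

test_that("extremes groups take the k lightest, k darkest and k rank-centered swabs", {
  set.seed(31)
  d39 <- runif(39)
  m39 <- assign_extremes_groups(meta_swabs(d39), k = 13)
  expect_equal(as.vector(table(m39$extremes_group)[c("Low", "Mid", "High")]),
               rep(13L, 3))
  expect_false(any(m39$extremes_group == "none"))
  ranks <- rank(d39, ties.method = "first")
  expect_setequal(m39$sample_id[m39$extremes_group == "Mid"],
                  m39$sample_id[ranks %in% 14:26])

  d100 <- runif(100)
  m100 <- assign_extremes_groups(meta_swabs(d100), k = 13)
  ranks100 <- rank(d100, ties.method = "first")
  expect_setequal(m100$sample_id[m100$extremes_group == "Mid"],
                  m100$sample_id[ranks100 %in% 44:56])
  expect_setequal(m100$sample_id[m100$extremes_group == "Low"],
                  m100$sample_id[ranks100 <= 13])
  expect_setequal(m100$sample_id[m100$extremes_group == "High"],
                  m100$sample_id[ranks100 >= 88])
  expect_equal(sum(m100$extremes_group == "none"), 61)
  expect_error(assign_extremes_groups(meta_swabs(runif(38)), k = 13), "3k")
})

test_that("group labels never land on rumen samples", {
  meta <- rbind(meta_swabs(runif(40)),
                data.frame(sample_id = c("L1", "S1"),
                           sample_type = c("rumen_liquid", "rumen_solid"),
                           darkness = NA_real_, stringsAsFactors = FALSE))
  meta <- assign_extremes_groups(assign_percentile_groups(meta), k = 13)
  rumen <- meta$sample_type != "swab"
  expect_true(all(is.na(meta$percentile_group[rumen])))
  expect_true(all(is.na(meta$extremes_group[rumen])))
  expect_true(all(!is.na(meta$percentile_group[!rumen])))
})
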