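test_that("reference pools honor overlap, normalization and determinism", {
  refs <- simulate_references(n_asvs_per_pool = 50, overlap = 0.5, seed = 7)
  solid_set <- names(refs$solid)[refs$solid > 0]
  liquid_set <- names(refs$liquid)[refs$liquid > 0]
  expect_length(intersect(solid_set, liquid_set), 25)
  oral_set <- names(refs$oral)[refs$oral > 0]
  expect_length(intersect(oral_set, union(solid_set, liquid_set)), 0)
  for (pool in c("solid", "liquid", "oral", "environmental")) {
    expect_equal(sum(refs[[pool]]), 1, tolerance = 1e-12)
    expect_true(all(refs[[pool]] >= 0))
  }

  disjoint <- simulate_references(n_asvs_per_pool = 20, overlap = 0, seed = 3)
  expect_length(intersect(names(disjoint$solid)[disjoint$solid > 0],
                          names(disjoint$liquid)[disjoint$liquid > 0]), 0)

  again <- simulate_references(n_asvs_per_pool = 50, overlap = 0.5, seed = 7)
  expect_identical(refs, again)
  expect_error(simulate_references(overlap = 1), "overlap")
})

test_that("a simulated swab mixes pools by alpha and sums to its depth", {
  refs <- simulate_references(n_asvs_per_pool = 30, overlap = 0, seed = 11)
  link0 <- c(d0 = 0.35, d1 = 0.39, sd = 0)

  set.seed(1)
  pure_rumen <- simulate_swab(1, refs, depth = 5000, link = link0)
  expect_identical(sum(pure_rumen$counts), 5000L)
  expect_equal(pure_rumen$darkness, 0.35 + 0.39)
  expect_equal(pure_rumen$expected, 0.5 * refs$solid + 0.5 * refs$liquid,
               tolerance = 1e-12)

  set.seed(2)
  pure_oral <- simulate_swab(0, refs, depth = 5000, link = link0)
  expect_equal(pure_oral$darkness, 0.35)
  expect_equal(pure_oral$expected, 0.7 * refs$oral + 0.3 * refs$environmental,
               tolerance = 1e-12)

  # with disjoint pools and no overdispersion, alpha = 0 yields zero rumen reads
  refs_inf <- simulate_references(n_asvs_per_pool = 30, overlap = 0,
                                  concentration = Inf, seed = 11)
  set.seed(3)
  none <- simulate_swab(0, refs_inf, depth = 20000, link = link0)
  rumen_asvs <- names(refs_inf$asv_source)[
    refs_inf$asv_source %in% c("rumen_solid", "rumen_liquid", "rumen_shared")]
  expect_identical(sum(none$counts[rumen_asvs]), 0L)

  # law of large numbers: huge depth, no overdispersion -> proportions near p
  set.seed(4)
  big <- simulate_swab(0.6, refs_inf, depth = 1e6, link = link0)
  expect_lt(max(abs(big$counts / 1e6 - big$expected)), 0.005)

  expect_error(simulate_swab(0.5, refs, depth = 0), "depth")
  expect_error(simulate_swab(1.2, refs, depth = 100), "alpha")
})

test_that("the default dataset has the study shape and a monotone darkness link", {
  study <- default_study()
  ds <- study$dataset
  expect_equal(dim(ds$counts)[1], 427)  # 402 swabs + 13 liquid + 12 solid
  expect_equal(as.vector(table(ds$metadata$sample_type)[c("swab", "rumen_liquid", "rumen_solid")]),
               c(402, 13, 12))
  expect_true(all(!is.na(ds$metadata$darkness[ds$metadata$sample_type == "swab"])))
  expect_true(all(is.na(ds$metadata$darkness[ds$metadata$sample_type != "swab"])))

  # noiseless darkness link: Spearman correlation with alpha is exactly 1
  design0 <- mixture_design(n_swabs = 60, n_liquid = 3, n_solid = 3,
                            link = c(d0 = 0.35, d1 = 0.39, sd = 0), seed = 5)
  refs_small <- simulate_references(n_asvs_per_pool = 20, seed = 5)
  ds0 <- simulate_dataset(design0, refs_small)
  sw <- ds0$metadata$sample_type == "swab"
  expect_equal(cor(ds0$metadata$darkness[sw], ds0$metadata$true_alpha[sw],
                   method = "spearman"), 1)

  # with noise, the link stays strongly monotone
  sw_all <- ds$metadata$sample_type == "swab"
  ct <- spearman_test(ds$metadata$darkness[sw_all], ds$metadata$true_alpha[sw_all])
  expect_gt(ct$estimate, 0.9)
  expect_lt(ct$p_value, 0.01)
})

test_that("writing a dataset twice under one seed is byte-identical", {
  refs <- simulate_references(n_asvs_per_pool = 15, seed = 9)
  design <- mixture_design(n_swabs = 45, n_liquid = 3, n_solid = 3,
                           depth_meanlog = log(3000), seed = 9)
  ds <- simulate_dataset(design, refs)
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  p1 <- write_dataset(ds, refs, d1, design)
  p2 <- write_dataset(simulate_dataset(design, refs), refs, d2, design)
  for (k in names(p1)) {
    expect_identical(readLines(p1[[k]]), readLines(p2[[k]]), label = k)
  }
  # round trip through the readers
  counts <- read_count_table(p1[["counts"]])
  expect_equal(unclass(counts), unclass(ds$counts), ignore_attr = TRUE)
  meta <- read_metadata(p1[["metadata"]])
  expect_equal(meta$darkness, ds$metadata$darkness, tolerance = 1e-12)
})

test_that("rendered swab images recover their target darkness", {
  flat <- render_swab_image(1, size = 100, texture_sd = 0)
  expect_true(all(unclass(flat) == 0))

  # flat rendering at the observed-median fixture value is exact
  img <- render_swab_image(0.4053, size = 120, texture_sd = 0)
  expect_equal(unclass(img)[1, 1], 151.6485, tolerance = 1e-12)
  expect_equal(score_swab_image(img), 0.4053, tolerance = 1e-12)

  set.seed(20)
  for (rep in 1:25) {
    noisy <- render_swab_image(0.5, size = 120, texture_sd = 10)
    expect_lt(abs(score_swab_image(noisy) - 0.5), 0.01)
  }
  expect_error(render_swab_image(0.5, size = 80), "at least 100")
  expect_error(render_swab_image(1.2), "darkness")
})

test_that("simulated trees cover the ASV set exactly and deterministically", {
  cherry <- simulate_tree(c("x", "y"), seed = 1)
  expect_setequal(cherry$tip.label, c("x", "y"))
  expect_true(ape::is.rooted(cherry))

  ids <- sprintf("ASV%03d", 1:37)
  tr <- simulate_tree(ids, seed = 4)
  expect_setequal(tr$tip.label, ids)
  expect_true(all(tr$edge.length > 0))
  expect_identical(ape::write.tree(tr), ape::write.tree(simulate_tree(ids, seed = 4)))
  expect_error(simulate_tree(c("a", "a")), "duplicate")
})
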