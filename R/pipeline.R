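# End-to-end orchestration: score images, normalize the ASV table, assign
# darkness groups, compute alpha/beta diversity, ordinate and test, decompose
# group differences, and measure core capture — from one validated config,
# with seeded reproducibility and a machine-readable report.

PIPELINE_DEFAULTS <- list(
  rarefaction_depth = 7000L,
  min_count = 10L,
  extremes_k = 13L,
  simper_threshold = 0.01,
  prevalence_threshold = 0.8,
  n_perm = 999L,
  seed = 1L,
  beta_metric = "bray",
  jaccard_binary = FALSE,
  reference_distance_axes = 2L,
  crop_size = 100L)

PIPELINE_PATH_KEYS <- c("counts", "taxonomy", "metadata", "tree", "image_manifest")

#' Validate a pipeline configuration
#'
#' Reads a YAML config (or takes a list), fills defaults
#' (`rarefaction_depth` 7000, `min_count` 10, `extremes_k` 13,
#' `simper_threshold` 0.01, `prevalence_threshold` 0.8, `n_perm` 999),
#' rejects unknown keys and reports all range/type violations at once.
#' `counts` and `metadata` paths are required; `taxonomy`, `tree` and
#' `image_manifest` are optional.
#'
#' @param config Path to a YAML file, or a named list.
#' @return Validated config list of class `pipeline_config`.
#' @export
validate_config <- function(config) {
  if (is.character(config) && length(config) == 1L) {
    if (!file.exists(config)) stop("config file not found: ", config, call. = FALSE)
    config <- yaml::read_yaml(config)
  }
  if (!is.list(config)) stop("config must be a YAML file or a list", call. = FALSE)
  known <- c(PIPELINE_PATH_KEYS, names(PIPELINE_DEFAULTS))
  problems <- character(0)
  unknown <- setdiff(names(config), known)
  if (length(unknown)) {
    problems <- c(problems, paste0("unknown key(s): ", paste(unknown, collapse = ", ")))
  }
  cfg <- utils::modifyList(PIPELINE_DEFAULTS, config[intersect(names(config), known)])
  for (key in c("counts", "metadata")) {
    if (is.null(cfg[[key]])) {
      problems <- c(problems, paste0("required path `", key, "` is missing"))
    }
  }
  for (key in intersect(PIPELINE_PATH_KEYS, names(cfg))) {
    if (!is.null(cfg[[key]]) && !file.exists(cfg[[key]])) {
      problems <- c(problems, sprintf("`%s` path does not exist: %s", key, cfg[[key]]))
    }
  }
  check_range <- function(key, lo, hi, integer = FALSE) {
    v <- cfg[[key]]
    if (!is.numeric(v) || length(v) != 1 || is.na(v) || v < lo || v > hi ||
        (integer && v != round(v))) {
      problems <<- c(problems, sprintf(
        "`%s` must be a%s number in [%s, %s], got %s", key,
        if (integer) "n integer" else "", format(lo), format(hi),
        paste(format(v), collapse = ", ")))
    }
  }
  check_range("rarefaction_depth", 1, Inf, integer = TRUE)
  check_range("min_count", 0, Inf, integer = TRUE)
  check_range("extremes_k", 1, Inf, integer = TRUE)
  check_range("simper_threshold", 0, 1)
  check_range("prevalence_threshold", 0, 1 - 1e-12)
  check_range("n_perm", 1, Inf, integer = TRUE)
  check_range("seed", -2^31 + 1, 2^31 - 1, integer = TRUE)
  check_range("reference_distance_axes", 1, Inf, integer = TRUE)
  if (!cfg$beta_metric %in% c("bray", "jaccard", "jaccard_binary", "unifrac")) {
    problems <- c(problems, "`beta_metric` must be one of bray, jaccard, jaccard_binary, unifrac")
  }
  if (identical(cfg$beta_metric, "unifrac") && is.null(cfg$tree)) {
    problems <- c(problems, "`beta_metric: unifrac` requires a `tree` path")
  }
  if (length(problems)) {
    stop("invalid pipeline config:\n  - ", paste(problems, collapse = "\n  - "),
         call. = FALSE)
  }
  structure(cfg, class = c("pipeline_config", "list"))
}

write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}

#' Run the full swab-color analysis pipeline
#'
#' Stages, in fixed order: (1) load inputs and, if an image manifest is
#' configured, score the swab photographs; (2) taxon removal, rarefaction to
#' the configured depth, per-cell minimum-count filter, relative abundance;
#' (3) darkness decile and extremes group assignment; (4) alpha diversity
#' with Kruskal-Wallis, pairwise Wilcoxon/FDR and darkness correlations;
#' (5) beta diversity, PCoA, PERMANOVA over extremes groups plus rumen
#' fractions, darkness-vs-axes regression, and mean ordination distance to
#' each rumen fraction with darkness correlations; (6) SIMPER plus
#' Kruskal-Wallis/FDR differential ASVs for Low-vs-High and
#' lightest-vs-darkest decile contrasts; (7) highly prevalent rumen ASV sets
#' and per-swab capture percentages with darkness correlations.
#'
#' Identical config and seed give identical outputs. Each stage writes its
#' table(s) under `out_dir` and the headline numbers are collected in
#' `report.json`.
#'
#' @param config A `pipeline_config` (or anything [validate_config()]
#'   accepts).
#' @param out_dir Output directory (created if needed).
#' @return The pipeline report, invisibly: a list with per-stage outputs,
#'   parameters, drop logs and headline statistics.
#' @export
run_pipeline <- function(config, out_dir) {
  cfg <- validate_config(config)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  report <- list(parameters = unclass(cfg), stages = list(), outputs = list())

  ## stage 1: load ------------------------------------------------------------
  counts <- read_count_table(cfg$counts)
  meta <- read_metadata(cfg$metadata)
  taxonomy <- if (!is.null(cfg$taxonomy)) read_taxonomy(cfg$taxonomy)
  tree <- if (!is.null(cfg$tree)) ape::read.tree(cfg$tree)
  if (!is.null(cfg$image_manifest)) {
    scores <- score_swab_manifest(cfg$image_manifest, crop_size = cfg$crop_size)
    meta$darkness[match(scores$sample_id, meta$sample_id)] <- scores$darkness
  }
  swab_rows <- meta$sample_type == "swab"
  if (any(swab_rows & is.na(meta$darkness))) {
    stop("swab(s) without a darkness score: ",
         paste(utils::head(meta$sample_id[swab_rows & is.na(meta$darkness)], 5),
               collapse = ", "), call. = FALSE)
  }
  missing <- setdiff(meta$sample_id, rownames(counts))
  if (length(missing)) {
    stop("metadata sample(s) absent from the count table: ",
         paste(utils::head(missing, 5), collapse = ", "), call. = FALSE)
  }
  counts <- counts[meta$sample_id, , drop = FALSE]
  report$stages$load <- list(n_samples = nrow(counts), n_asvs = ncol(counts))

  ## stage 2: normalize -------------------------------------------------------
  if (!is.null(taxonomy)) counts <- remove_taxa(counts, taxonomy)
  rare <- rarefy_counts(counts, cfg$rarefaction_depth, seed = cfg$seed + 1L)
  filt <- min_count_filter(rare, cfg$min_count)
  zero <- rowSums(filt) == 0
  if (any(zero)) {
    message("dropping ", sum(zero), " sample(s) emptied by the minimum-count filter")
    filt <- filt[!zero, , drop = FALSE]
  }
  meta <- meta[meta$sample_id %in% rownames(filt), , drop = FALSE]
  rel <- relative_abundance(filt)
  report$stages$normalize <- list(
    rarefaction_depth = cfg$rarefaction_depth, min_count = cfg$min_count,
    dropped_samples = attr(rare, "dropped"),
    n_samples = nrow(filt), n_asvs = ncol(filt))
  report$outputs$filtered_counts <- write_tsv(
    data.frame(sample_id = rownames(filt), filt, check.names = FALSE),
    file.path(out_dir, "filtered_counts.tsv"))

  ## stage 3: groups ----------------------------------------------------------
  meta <- assign_percentile_groups(meta)
  meta <- assign_extremes_groups(meta, k = cfg$extremes_k)
  report$outputs$metadata <- write_tsv(meta, file.path(out_dir, "metadata_groups.tsv"))
  swabs <- meta[meta$sample_type == "swab", ]
  solid_ids <- meta$sample_id[meta$sample_type == "rumen_solid"]
  liquid_ids <- meta$sample_id[meta$sample_type == "rumen_liquid"]

  ## stage 4: alpha diversity -------------------------------------------------
  alpha <- alpha_diversity_table(filt)
  report$outputs$alpha <- write_tsv(alpha, file.path(out_dir, "alpha_diversity.tsv"))
  ext_label <- ifelse(meta$sample_type == "swab",
                      as.character(meta$extremes_group), meta$sample_type)
  in_ext <- ext_label != "none"
  alpha_tests <- list()
  for (m in c("chao1", "shannon", "inv_simpson")) {
    v <- alpha[[m]][match(meta$sample_id, alpha$sample_id)]
    alpha_tests[[m]] <- list(
      kruskal_extremes = kruskal_wallis(v[in_ext], ext_label[in_ext]),
      darkness_spearman = spearman_test(
        meta$darkness[meta$sample_type == "swab"],
        v[meta$sample_type == "swab"]))
  }
  report$stages$alpha <- alpha_tests

  ## stage 5: beta diversity, ordination, tests -------------------------------
  d <- distance_matrix(if (cfg$beta_metric %in% c("bray", "jaccard")) rel else filt,
                       metric = cfg$beta_metric, tree = tree)
  ord <- pcoa_ordination(d)
  coords <- ord$coordinates
  report$outputs$ordination <- write_tsv(
    data.frame(sample_id = rownames(coords), coords[, 1:2, drop = FALSE],
               check.names = FALSE),
    file.path(out_dir, "pcoa_coordinates.tsv"))
  perm_ext <- permanova(d[in_ext, in_ext], ext_label[in_ext],
                        n_perm = cfg$n_perm, seed = cfg$seed + 2L)
  pct_label <- ifelse(meta$sample_type == "swab",
                      as.character(meta$percentile_group), meta$sample_type)
  perm_pct <- permanova(d, pct_label, n_perm = cfg$n_perm, seed = cfg$seed + 3L)
  reg <- regress_on_axes(swabs$darkness, ord, swab_ids = swabs$sample_id)
  dist_solid <- mean_distance_to_reference(ord, swabs$sample_id, solid_ids,
                                           n_axes = cfg$reference_distance_axes)
  dist_liquid <- mean_distance_to_reference(ord, swabs$sample_id, liquid_ids,
                                            n_axes = cfg$reference_distance_axes)
  ref_dist <- data.frame(sample_id = swabs$sample_id, darkness = swabs$darkness,
                         mean_dist_to_solid = dist_solid$mean_dist,
                         mean_dist_to_liquid = dist_liquid$mean_dist)
  report$outputs$reference_distance <- write_tsv(
    ref_dist, file.path(out_dir, "reference_distance.tsv"))
  report$stages$beta <- list(
    metric = cfg$beta_metric,
    permanova_extremes = perm_ext,
    permanova_percentiles = perm_pct,
    darkness_axes_regression = reg,
    darkness_vs_dist_solid = spearman_test(ref_dist$darkness,
                                           ref_dist$mean_dist_to_solid),
    darkness_vs_dist_liquid = spearman_test(ref_dist$darkness,
                                            ref_dist$mean_dist_to_liquid))

  ## stage 6: differential ASVs -----------------------------------------------
  low_ids <- swabs$sample_id[swabs$extremes_group == "Low"]
  high_ids <- swabs$sample_id[swabs$extremes_group == "High"]
  diff_ext <- differential_asvs(rel, low_ids, high_ids,
                                simper_threshold = cfg$simper_threshold)
  tenth_ids <- swabs$sample_id[swabs$percentile_group == "Tenth"]
  hundredth_ids <- swabs$sample_id[swabs$percentile_group == "Hundredth"]
  diff_pct <- differential_asvs(rel, tenth_ids, hundredth_ids,
                                simper_threshold = cfg$simper_threshold)
  report$outputs$differential_extremes <- write_tsv(
    diff_ext, file.path(out_dir, "differential_low_vs_high.tsv"))
  report$outputs$differential_percentiles <- write_tsv(
    diff_pct, file.path(out_dir, "differential_tenth_vs_hundredth.tsv"))
  report$stages$differential <- list(
    n_significant_extremes = sum(diff_ext$significant),
    n_significant_percentiles = sum(diff_pct$significant))

  ## stage 7: prevalence and capture ------------------------------------------
  set_solid <- prevalent_set(filt, solid_ids, cfg$prevalence_threshold,
                             other_ids = liquid_ids)
  set_liquid <- prevalent_set(filt, liquid_ids, cfg$prevalence_threshold,
                              other_ids = solid_ids)
  cap_solid <- capture_fraction(filt, swabs$sample_id, set_solid)
  cap_liquid <- capture_fraction(filt, swabs$sample_id, set_liquid)
  dk <- stats::setNames(swabs$darkness, swabs$sample_id)
  capture <- data.frame(sample_id = swabs$sample_id, darkness = swabs$darkness,
                        capture_pct_solid = cap_solid$capture_pct,
                        capture_pct_liquid = cap_liquid$capture_pct)
  report$outputs$capture <- write_tsv(capture, file.path(out_dir, "capture.tsv"))
  report$stages$prevalence <- list(
    threshold = cfg$prevalence_threshold,
    solid = list(n_total = set_solid$n_total, n_unique = set_solid$n_unique),
    liquid = list(n_total = set_liquid$n_total, n_unique = set_liquid$n_unique),
    darkness_vs_capture_solid = capture_darkness_correlation(cap_solid, dk),
    darkness_vs_capture_liquid = capture_darkness_correlation(cap_liquid, dk))

  report$headline <- list(
    n_samples = nrow(filt),
    permanova_p_extremes = perm_ext$p_value,
    darkness_axis1_p = reg$coefficients$p[reg$coefficients$term == "axis1"],
    rho_darkness_dist_solid = report$stages$beta$darkness_vs_dist_solid$estimate,
    rho_darkness_capture_solid =
      report$stages$prevalence$darkness_vs_capture_solid$estimate,
    n_differential_extremes = sum(diff_ext$significant))
  jsonlite::write_json(report, file.path(out_dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, null = "null",
                       force = TRUE)
  invisible(report)
}
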