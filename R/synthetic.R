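# Self-contained synthetic swab-color study generator.
#
# The generator emulates the sampling design of a herd-scale swab study: four
# source communities (rumen solids, rumen liquids, oral, environmental), each
# swab a proportion-level mixture of the rumen and oral/environmental pools
# with rumen fraction alpha, counts drawn Dirichlet-multinomially at a
# per-sample sequencing depth, and a darkness score linearly (plus noise)
# linked to alpha. Ground truth (per-swab alpha, per-ASV source, planted
# differential ASVs) is returned for recovery tests.

#' Simulate the four reference source communities
#'
#' Builds rumen-solid, rumen-liquid, oral and environmental reference pools
#' over a shared ASV universe. Each pool's base proportions are log-normally
#' ranked (sorted decreasing, normalized). The solid and liquid pools share
#' `round(overlap * n_asvs_per_pool)` ASVs — overlapping but distinct
#' communities — while the oral and environmental pools are disjoint from the
#' rumen pools and from each other.
#'
#' @param n_asvs_per_pool ASVs per pool (>= 5).
#' @param overlap Fraction of the solid/liquid pools that is shared,
#'   in `[0, 1)`.
#' @param concentration Dirichlet concentration scalar (> 0) controlling
#'   sample-to-sample overdispersion; `Inf` gives pure multinomial sampling.
#' @param lognorm_sd Log-scale SD of the ranked base proportions (rank
#'   steepness).
#' @param seed Integer seed.
#' @return List of class `reference_communities`: per-pool proportion vectors
#'   (`solid`, `liquid`, `oral`, `environmental`, each named over the full
#'   ASV universe), `asv_ids`, `asv_source` (one label per ASV:
#'   `rumen_solid`, `rumen_liquid`, `rumen_shared`, `oral`,
#'   `environmental`), and `concentration`.
#' @export
simulate_references <- function(n_asvs_per_pool = 150L, overlap = 0.5,
                                concentration = 100, lognorm_sd = 1.5,
                                seed = 1L) {
  n <- as.integer(n_asvs_per_pool)
  if (n < 5L) stop("`n_asvs_per_pool` must be at least 5", call. = FALSE)
  if (overlap < 0 || overlap >= 1) stop("`overlap` must lie in [0, 1)", call. = FALSE)
  if (concentration <= 0) stop("`concentration` must be positive", call. = FALSE)
  m <- as.integer(round(overlap * n))
  source_blocks <- c(rep("rumen_shared", m),
                     rep("rumen_solid", n - m),
                     rep("rumen_liquid", n - m),
                     rep("oral", n),
                     rep("environmental", n))
  n_total <- length(source_blocks)
  asv_ids <- sprintf("ASV%04d", seq_len(n_total))
  pool_members <- list(
    solid         = which(source_blocks %in% c("rumen_shared", "rumen_solid")),
    liquid        = which(source_blocks %in% c("rumen_shared", "rumen_liquid")),
    oral          = which(source_blocks == "oral"),
    environmental = which(source_blocks == "environmental"))
  refs <- local_seed(seed, {
    lapply(pool_members, function(idx) {
      raw <- sort(stats::rlnorm(length(idx), meanlog = 0, sdlog = lognorm_sd),
                  decreasing = TRUE)
      # randomize which member gets which rank so pools differ in ordering
      p <- numeric(n_total)
      p[sample(idx)] <- raw / sum(raw)
      names(p) <- asv_ids
      p
    })
  })
  structure(c(refs,
              list(asv_ids = asv_ids,
                   asv_source = stats::setNames(source_blocks, asv_ids),
                   concentration = concentration)),
            class = "reference_communities")
}

# One Dirichlet-multinomial draw: counts summing to `depth` with expected
# proportions `p` and concentration `conc` (Inf = multinomial).
rdirmult <- function(p, conc, depth) {
  if (is.infinite(conc)) {
    q <- p
  } else {
    g <- stats::rgamma(length(p), shape = conc * p, rate = 1)
    if (sum(g) == 0) g[which.max(p)] <- 1   # numerically degenerate draw
    q <- g / sum(g)
  }
  as.vector(stats::rmultinom(1, size = depth, prob = q))
}

#' Simulate one swab community and its darkness score
#'
#' The swab's expected composition is the alpha-weighted mixture of the rumen
#' pools and the oral/environmental pools,
#' `p = alpha (w_s solid + w_l liquid) + (1 - alpha)(w_o oral + w_e env)`,
#' counts are Dirichlet-multinomial at the given depth, and darkness is
#' `clip(d0 + d1 alpha + Normal(0, sd), 0, 1)`. Uses the current RNG state;
#' seed at the caller.
#'
#' @param alpha Rumen fraction of the swab, in `[0, 1]`.
#' @param refs A `reference_communities` object.
#' @param depth Sequencing depth (reads, > 0).
#' @param weights Mixture weights `c(solid, liquid, oral, environmental)`;
#'   the rumen pair and the non-rumen pair are each renormalized to sum to 1.
#' @param link Darkness link `c(d0, d1, sd)`: intercept, slope, noise SD.
#' @return List: `counts` (named integer vector summing to `depth`),
#'   `darkness`, `expected` (the mixture proportions).
#' @export
simulate_swab <- function(alpha, refs, depth,
                          weights = c(solid = 0.5, liquid = 0.5,
                                      oral = 0.7, environmental = 0.3),
                          link = c(d0 = 0.35, d1 = 0.39, sd = 0.02)) {
  if (alpha < 0 || alpha > 1) stop("`alpha` must lie in [0, 1]", call. = FALSE)
  if (depth <= 0) stop("`depth` must be positive", call. = FALSE)
  w_r <- weights[c("solid", "liquid")] / sum(weights[c("solid", "liquid")])
  w_n <- weights[c("oral", "environmental")] /
    sum(weights[c("oral", "environmental")])
  p <- alpha * (w_r[[1]] * refs$solid + w_r[[2]] * refs$liquid) +
    (1 - alpha) * (w_n[[1]] * refs$oral + w_n[[2]] * refs$environmental)
  counts <- rdirmult(p, refs$concentration, depth)
  names(counts) <- refs$asv_ids
  darkness <- min(1, max(0, link[[1]] + link[[2]] * alpha +
                              stats::rnorm(1, 0, link[[3]])))
  list(counts = counts, darkness = darkness, expected = p)
}

#' Mixture design of a synthetic study
#'
#' Default shape: 402 swabs plus 13 rumen-liquid and 12 rumen-solid samples;
#' rumen fraction `alpha ~ Beta(2, 2)`; darkness link
#' `0.35 + 0.39 alpha + Normal(0, 0.02)` (spanning roughly 0.35-0.74); depth
#' log-normal around 30,000 reads with log-SD 1 so a realistic minority of
#' swabs falls below a 7,000-read rarefaction depth.
#'
#' @param n_swabs,n_liquid,n_solid Sample counts (>= 1).
#' @param alpha_shape Beta shape parameters for the per-swab rumen fraction.
#' @param link Darkness link `c(d0, d1, sd)`; `d0` and `d0 + d1` must lie in
#'   `[0, 1]`.
#' @param depth_meanlog,depth_sdlog Log-normal sequencing-depth parameters.
#' @param weights Mixture weights, see [simulate_swab()].
#' @param planted_margin Minimum absolute expected-proportion difference
#'   between the pure rumen mixture and the pure oral/environmental mixture
#'   for an ASV to be recorded as a planted differential ASV.
#' @param seed Integer seed for the whole dataset draw.
#' @return List of class `mixture_design`.
#' @export
mixture_design <- function(n_swabs = 402L, n_liquid = 13L, n_solid = 12L,
                           alpha_shape = c(2, 2),
                           link = c(d0 = 0.35, d1 = 0.39, sd = 0.02),
                           depth_meanlog = log(30000), depth_sdlog = 1,
                           weights = c(solid = 0.5, liquid = 0.5,
                                       oral = 0.7, environmental = 0.3),
                           planted_margin = 0.02, seed = 42L) {
  if (min(n_swabs, n_liquid, n_solid) < 1L) {
    stop("sample counts must be at least 1", call. = FALSE)
  }
  if (link[[1]] < 0 || link[[1]] > 1 || link[[1]] + link[[2]] < 0 ||
      link[[1]] + link[[2]] > 1) {
    stop("darkness link must map [0, 1] into [0, 1]: need d0 and d0 + d1 in [0, 1]",
         call. = FALSE)
  }
  structure(list(n_swabs = as.integer(n_swabs), n_liquid = as.integer(n_liquid),
                 n_solid = as.integer(n_solid), alpha_shape = alpha_shape,
                 link = link, depth_meanlog = depth_meanlog,
                 depth_sdlog = depth_sdlog, weights = weights,
                 planted_margin = planted_margin, seed = as.integer(seed)),
            class = "mixture_design")
}

#' Simulate a full synthetic study
#'
#' Draws every swab from [simulate_swab()] with `alpha ~ Beta(shape1,
#' shape2)`, and the rumen samples Dirichlet-multinomially from their own
#' pool. Ground truth records the per-swab alpha, the per-ASV source label,
#' and the planted differential ASVs: those whose expected relative abundance
#' differs between the pure rumen mixture (`alpha = 1`) and the pure
#' oral/environmental mixture (`alpha = 0`) by at least the design's
#' `planted_margin`.
#'
#' @param design A `mixture_design`.
#' @param refs A `reference_communities` object.
#' @return List: `counts` (samples x ASVs integer matrix), `metadata` (data
#'   frame: `sample_id`, `sample_type`, `darkness`, `true_alpha`), `truth`
#'   (list: `alpha`, `asv_source`, `planted_differential`, `expected_rumen`,
#'   `expected_nonrumen`).
#' @export
simulate_dataset <- function(design, refs) {
  stopifnot(inherits(design, "mixture_design"),
            inherits(refs, "reference_communities"))
  local_seed(design$seed, {
    n_sw <- design$n_swabs
    ids <- c(sprintf("Swab%03d", seq_len(n_sw)),
             sprintf("Liquid%02d", seq_len(design$n_liquid)),
             sprintf("Solid%02d", seq_len(design$n_solid)))
    types <- c(rep("swab", n_sw), rep("rumen_liquid", design$n_liquid),
               rep("rumen_solid", design$n_solid))
    n_all <- length(ids)
    counts <- matrix(0L, n_all, length(refs$asv_ids),
                     dimnames = list(ids, refs$asv_ids))
    darkness <- rep(NA_real_, n_all)
    alpha <- rep(NA_real_, n_all)
    depths <- pmax(1000, round(stats::rlnorm(n_all, design$depth_meanlog,
                                             design$depth_sdlog)))
    for (i in seq_len(n_sw)) {
      a <- stats::rbeta(1, design$alpha_shape[1], design$alpha_shape[2])
      sw <- simulate_swab(a, refs, depths[i], weights = design$weights,
                          link = design$link)
      counts[i, ] <- sw$counts
      darkness[i] <- sw$darkness
      alpha[i] <- a
    }
    for (i in (n_sw + 1):n_all) {
      pool <- if (types[i] == "rumen_liquid") refs$liquid else refs$solid
      counts[i, ] <- rdirmult(pool, refs$concentration, depths[i])
    }
    w_r <- design$weights[c("solid", "liquid")] /
      sum(design$weights[c("solid", "liquid")])
    w_n <- design$weights[c("oral", "environmental")] /
      sum(design$weights[c("oral", "environmental")])
    exp_rumen <- w_r[[1]] * refs$solid + w_r[[2]] * refs$liquid
    exp_nonrumen <- w_n[[1]] * refs$oral + w_n[[2]] * refs$environmental
    planted <- refs$asv_ids[abs(exp_rumen - exp_nonrumen) >= design$planted_margin]
    list(counts = set_mode(counts, "counts"),
         metadata = data.frame(sample_id = ids, sample_type = types,
                               darkness = darkness, true_alpha = alpha,
                               stringsAsFactors = FALSE),
         truth = list(alpha = stats::setNames(alpha, ids)[seq_len(n_sw)],
                      asv_source = refs$asv_source,
                      planted_differential = planted,
                      expected_rumen = exp_rumen,
                      expected_nonrumen = exp_nonrumen))
  })
}

# Genus pools used when fabricating a taxonomy for simulated ASVs. Rumen and
# oral genera follow the marker taxa of bovine microbiome surveys.
SYNTH_GENUS_POOLS <- list(
  rumen = data.frame(
    Phylum = c("Bacteroidota", "Firmicutes", "Firmicutes", "Proteobacteria",
               "Fibrobacterota", "Firmicutes"),
    Genus = c("Prevotella", "Succiniclasticum", "Ruminococcus",
              "Succinivibrionaceae UCG-001", "Fibrobacter", "Butyrivibrio"),
    stringsAsFactors = FALSE),
  oral = data.frame(
    Phylum = c("Proteobacteria", "Actinobacteriota", "Firmicutes",
               "Proteobacteria", "Proteobacteria", "Proteobacteria"),
    Genus = c("Moraxella", "Rothia", "Streptococcus", "Bibersteinia",
              "Alysiella", "Neisseriaceae_unclassified"),
    stringsAsFactors = FALSE),
  environmental = data.frame(
    Phylum = c("Proteobacteria", "Actinobacteriota", "Firmicutes"),
    Genus = c("Sphingomonas", "Microbacterium", "Bacillus"),
    stringsAsFactors = FALSE))

#' Fabricate a taxonomy table for simulated ASVs
#'
#' Assigns each simulated ASV a Kingdom..Species classification with the
#' genus drawn from a fixed label pool matching its source (rumen-associated
#' genera for rumen-pool ASVs, known bovine oral genera for oral ASVs).
#' Synthetic labels for synthetic data: the table exists so that
#' taxonomy-dependent operations (taxon removal, rank aggregation) are
#' exercisable, not as a biological claim.
#'
#' @param refs A `reference_communities` object.
#' @param seed Integer seed.
#' @return Taxonomy data frame (`asv_id`, Kingdom..Species).
#' @export
simulate_taxonomy <- function(refs, seed = 1L) {
  src <- refs$asv_source
  grp <- ifelse(src %in% c("rumen_solid", "rumen_liquid", "rumen_shared"),
                "rumen", ifelse(src == "oral", "oral", "environmental"))
  local_seed(seed, {
    rows <- lapply(seq_along(src), function(i) {
      pool <- SYNTH_GENUS_POOLS[[grp[i]]]
      pool[sample.int(nrow(pool), 1), ]
    })
    tax <- do.call(rbind, rows)
    data.frame(asv_id = names(src), Kingdom = "Bacteria", Phylum = tax$Phylum,
               Class = "Unclassified", Order = "Unclassified",
               Family = "Unclassified", Genus = tax$Genus,
               Species = "Unclassified", row.names = NULL,
               stringsAsFactors = FALSE)
  })
}

#' Render a synthetic swab photograph at a target darkness
#'
#' Produces a `size x size` grayscale image whose pixel mean is
#' `255 (1 - darkness)` plus Gaussian texture noise, clipped to `[0, 255]`,
#' so that scoring the image recovers the target darkness up to
#' noise-of-the-mean and clipping. Uses the current RNG state.
#'
#' @param darkness Target darkness in `[0, 1]`.
#' @param size Image side in pixels (>= 100, so the image is croppable).
#' @param texture_sd SD of the per-pixel texture noise (0 = flat image).
#' @return A single-channel `swab_image`.
#' @export
render_swab_image <- function(darkness, size = 120L, texture_sd = 10) {
  if (darkness < 0 || darkness > 1) stop("`darkness` must lie in [0, 1]", call. = FALSE)
  size <- as.integer(size)
  if (size < 100L) {
    stop("`size` must be at least 100 px for the image to be scoreable", call. = FALSE)
  }
  base <- 255 * (1 - darkness)
  px <- matrix(base, size, size)
  if (texture_sd > 0) {
    px <- px + matrix(stats::rnorm(size * size, 0, texture_sd), size, size)
    px <- pmin(pmax(px, 0), 255)
  }
  swab_image(px)
}

#' Simulate a random rooted tree over the ASVs
#'
#' Random binary rooted topology with exponential branch lengths; the leaf
#' set equals `asv_ids` exactly. Used for the UniFrac stage.
#'
#' @param asv_ids Unique ASV ids (>= 2).
#' @param seed Integer seed.
#' @return A rooted `phylo` object.
#' @export
simulate_tree <- function(asv_ids, seed = 1L) {
  if (length(asv_ids) < 2L) stop("need at least 2 ASVs", call. = FALSE)
  if (anyDuplicated(asv_ids)) {
    stop("duplicate ASV id: ", asv_ids[duplicated(asv_ids)][1], call. = FALSE)
  }
  local_seed(seed, {
    tree <- ape::rtree(length(asv_ids), rooted = TRUE, br = stats::rexp)
    tree$tip.label <- asv_ids[as.integer(sub("^t", "", tree$tip.label))]
    tree
  })
}

#' Write a simulated study to disk
#'
#' Writes the counts, taxonomy and metadata TSVs, the Newick tree, a truth
#' JSON, and optionally one rendered PNG per swab with a matching image
#' manifest. Every TSV carries the design seed in a `#`-comment header so a
#' dataset on disk is traceable to its draw.
#'
#' @param dataset Output of [simulate_dataset()].
#' @param refs The `reference_communities` used.
#' @param dir Output directory (created if needed).
#' @param design The `mixture_design` used (for the seed header).
#' @param images If `TRUE`, render one PNG per swab (texture SD 10) and write
#'   an `image_manifest.tsv`.
#' @return Named character vector of written paths, invisibly.
#' @export
write_dataset <- function(dataset, refs, dir, design, images = FALSE) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  hdr <- sprintf("# synthetic dataset, seed %d", design$seed)
  paths <- c(counts = file.path(dir, "counts.tsv"),
             taxonomy = file.path(dir, "taxonomy.tsv"),
             metadata = file.path(dir, "metadata.tsv"),
             tree = file.path(dir, "tree.nwk"),
             truth = file.path(dir, "truth.json"))
  write_with_header <- function(df, path) {
    con <- file(path, "w")
    on.exit(close(con))
    writeLines(hdr, con)
    utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  }
  cdf <- data.frame(sample_id = rownames(dataset$counts), dataset$counts,
                    check.names = FALSE, stringsAsFactors = FALSE)
  write_with_header(cdf, paths[["counts"]])
  write_with_header(simulate_taxonomy(refs, seed = design$seed), paths[["taxonomy"]])
  write_with_header(dataset$metadata, paths[["metadata"]])
  ape::write.tree(simulate_tree(refs$asv_ids, seed = design$seed), paths[["tree"]])
  jsonlite::write_json(dataset$truth, paths[["truth"]], auto_unbox = TRUE,
                       digits = NA)
  if (images) {
    img_dir <- file.path(dir, "images")
    dir.create(img_dir, showWarnings = FALSE)
    swabs <- dataset$metadata[dataset$metadata$sample_type == "swab", ]
    img_paths <- file.path(img_dir, paste0(swabs$sample_id, ".png"))
    local_seed(design$seed, {
      for (i in seq_len(nrow(swabs))) {
        write_swab_image(render_swab_image(swabs$darkness[i], texture_sd = 10),
                         img_paths[i])
      }
    })
    manifest <- data.frame(sample_id = swabs$sample_id, image_path = img_paths,
                           stringsAsFactors = FALSE)
    paths[["image_manifest"]] <- file.path(dir, "image_manifest.tsv")
    write_with_header(manifest, paths[["image_manifest"]])
  }
  invisible(paths)
}
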