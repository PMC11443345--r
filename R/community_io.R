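# ASV table, taxonomy and metadata handling plus the normalization steps a
# swab-color study applies before any statistics: taxon removal, rarefaction,
# a per-cell minimum-abundance filter, relative abundance, taxonomic
# aggregation, and darkness-based group assignment.
#
# Community tables are plain numeric matrices with samples as rows and ASVs
# as columns (vegan orientation). A "mode" attribute distinguishes raw counts
# from row-normalized proportions.

TAXONOMY_RANKS <- c("Kingdom", "Phylum", "Class", "Order", "Family",
                    "Genus", "Species")

#' Validate a community table
#'
#' @param counts Numeric samples x ASVs matrix with row and column names.
#' @param mode Expected mode, `"counts"` or `"proportions"`; `NULL` skips the
#'   mode check.
#' @return The validated matrix, invisibly.
#' @keywords internal
validate_community <- function(counts, mode = NULL) {
  if (!is.matrix(counts) || !is.numeric(counts)) {
    stop("community table must be a numeric matrix (samples x ASVs)", call. = FALSE)
  }
  if (is.null(rownames(counts)) || is.null(colnames(counts))) {
    stop("community table must carry sample (row) and ASV (column) names",
         call. = FALSE)
  }
  if (anyNA(counts) || min(counts) < 0) {
    stop("community table must be non-negative with no missing values",
         call. = FALSE)
  }
  if (anyDuplicated(rownames(counts))) {
    stop("duplicated sample id: ", rownames(counts)[duplicated(rownames(counts))][1],
         call. = FALSE)
  }
  if (anyDuplicated(colnames(counts))) {
    stop("duplicated ASV id: ", colnames(counts)[duplicated(colnames(counts))][1],
         call. = FALSE)
  }
  if (identical(mode, "proportions")) {
    rs <- rowSums(counts)
    if (any(abs(rs - 1) > 1e-9)) {
      stop("proportions table has rows not summing to 1", call. = FALSE)
    }
  }
  invisible(counts)
}

table_mode <- function(counts) attr(counts, "mode") %||% "counts"

set_mode <- function(counts, mode) {
  attr(counts, "mode") <- mode
  counts
}

#' Read an ASV count table from TSV
#'
#' Expects a header row of ASV ids and one row per sample, first column the
#' sample id. Duplicate ids, negative and non-numeric cells are rejected with
#' the offending row/column named.
#'
#' @param path Path to a tab-separated table.
#' @return Numeric samples x ASVs matrix (mode `"counts"`).
#' @export
read_count_table <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE,
                          comment.char = "#")
  ids <- as.character(df[[1]])
  if (anyDuplicated(ids)) {
    stop(sprintf("duplicate sample id '%s' in %s", ids[duplicated(ids)][1], path),
         call. = FALSE)
  }
  m <- as.matrix(df[, -1, drop = FALSE])
  if (!is.numeric(m)) {
    bad <- which(!vapply(df[-1], is.numeric, logical(1)))[1]
    stop(sprintf("non-numeric counts in column '%s' of %s",
                 names(df)[-1][bad], path), call. = FALSE)
  }
  if (min(m) < 0) {
    idx <- which(m < 0, arr.ind = TRUE)[1, ]
    stop(sprintf("negative count at sample '%s', ASV '%s' in %s",
                 ids[idx[1]], colnames(m)[idx[2]], path), call. = FALSE)
  }
  rownames(m) <- ids
  validate_community(m)
  set_mode(m, "counts")
}

#' Write a community table to TSV
#'
#' @param counts Samples x ASVs matrix.
#' @param path Output path.
#' @param id_column Name for the sample-id column.
#' @return `path`, invisibly.
#' @export
write_count_table <- function(counts, path, id_column = "sample_id") {
  validate_community(counts)
  df <- data.frame(rownames(counts), counts, check.names = FALSE,
                   stringsAsFactors = FALSE)
  names(df)[1] <- id_column
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read sample metadata from TSV
#'
#' Requires columns `sample_id` and `sample_type` (one of `swab`,
#' `rumen_liquid`, `rumen_solid`); an optional `darkness` column carries the
#' colorimetric score for swabs.
#'
#' @param path Path to a tab-separated table.
#' @return Data frame with at least `sample_id`, `sample_type`, `darkness`.
#' @export
read_metadata <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE, comment.char = "#")
  if (!all(c("sample_id", "sample_type") %in% names(df))) {
    stop("metadata must have columns `sample_id` and `sample_type`", call. = FALSE)
  }
  df$sample_id <- as.character(df$sample_id)
  if (anyDuplicated(df$sample_id)) {
    stop("duplicate sample id '", df$sample_id[duplicated(df$sample_id)][1],
         "' in ", path, call. = FALSE)
  }
  bad <- setdiff(unique(df$sample_type), c("swab", "rumen_liquid", "rumen_solid"))
  if (length(bad)) {
    stop("unknown sample_type: ", paste(bad, collapse = ", "), call. = FALSE)
  }
  if (is.null(df$darkness)) df$darkness <- NA_real_
  df$darkness <- as.numeric(df$darkness)
  if (any(!is.na(df$darkness) & (df$darkness < 0 | df$darkness > 1))) {
    stop("darkness scores must lie in [0, 1]", call. = FALSE)
  }
  df
}

#' Read an ASV taxonomy table from TSV
#'
#' First column `asv_id`, remaining columns taxonomic ranks
#' (Kingdom..Species); unclassified cells may be empty or `NA`.
#'
#' @param path Path to a tab-separated table.
#' @return Data frame keyed by `asv_id`.
#' @export
read_taxonomy <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE, comment.char = "#")
  names(df)[1] <- "asv_id"
  df$asv_id <- as.character(df$asv_id)
  if (anyDuplicated(df$asv_id)) {
    stop("duplicate ASV id '", df$asv_id[duplicated(df$asv_id)][1], "' in ", path,
         call. = FALSE)
  }
  df
}

#' Drop ASVs matching taxon-removal rules
#'
#' Removes ASV columns whose taxonomy matches any `(rank, label)` rule. The
#' defaults discard chloroplast, mitochondrial and archaeal sequences, the
#' standard cleanup for 16S ASV tables.
#'
#' @param counts Samples x ASVs matrix.
#' @param taxonomy Taxonomy data frame (see [read_taxonomy()]).
#' @param rules Named character vector `c(rank = label, ...)`.
#' @return The table without the matching ASV columns.
#' @export
remove_taxa <- function(counts, taxonomy,
                        rules = c(Order = "Chloroplast",
                                  Family = "Mitochondria",
                                  Kingdom = "Archaea")) {
  validate_community(counts)
  drop <- character(0)
  for (i in seq_along(rules)) {
    rank <- names(rules)[i]
    if (!rank %in% names(taxonomy)) next
    hit <- taxonomy$asv_id[!is.na(taxonomy[[rank]]) & taxonomy[[rank]] == rules[[i]]]
    drop <- union(drop, hit)
  }
  keep <- setdiff(colnames(counts), drop)
  set_mode(counts[, keep, drop = FALSE], table_mode(counts))
}

#' Rarefy samples to a common depth
#'
#' Subsamples each sample's reads without replacement to exactly `depth`
#' reads. Samples with fewer than `depth` total reads are dropped and listed
#' in the `dropped` attribute of the result. Deterministic under `seed`.
#'
#' @param counts Integer samples x ASVs count matrix.
#' @param depth Target depth (reads per sample), >= 1.
#' @param seed Integer seed for the subsampling.
#' @return Rarefied count matrix with attribute `dropped` (character vector
#'   of removed sample ids).
#' @export
rarefy_counts <- function(counts, depth, seed = 1L) {
  validate_community(counts)
  if (table_mode(counts) != "counts") stop("rarefaction requires raw counts", call. = FALSE)
  depth <- as.integer(depth)
  if (is.na(depth) || depth < 1L) stop("`depth` must be a positive integer", call. = FALSE)
  totals <- rowSums(counts)
  dropped <- rownames(counts)[totals < depth]
  keep <- counts[totals >= depth, , drop = FALSE]
  if (nrow(keep) == 0L) {
    stop("no samples survive rarefaction: every sample has fewer than ",
         depth, " reads", call. = FALSE)
  }
  if (length(dropped)) {
    message(sprintf("rarefaction to %d dropped %d sample(s): %s", depth,
                    length(dropped), paste(dropped, collapse = ", ")))
  }
  # rrarefy nags when the smallest positive count exceeds 1, which filtered
  # ASV tables routinely do; that warning is muffled, all others propagate
  out <- local_seed(seed, withCallingHandlers(
    vegan::rrarefy(keep, sample = depth),
    warning = function(w) {
      if (grepl("observed counts", conditionMessage(w))) {
        invokeRestart("muffleWarning")
      }
    }))
  out <- set_mode(out, "counts")
  attr(out, "dropped") <- dropped
  out
}

#' Per-cell minimum-abundance filter
#'
#' Zeroes every cell whose count is positive but below `min_count` (an ASV a
#' sample does not support with at least `min_count` reads is treated as
#' absent from that sample); ASV columns that become all-zero are dropped.
#' Idempotent.
#'
#' @param counts Samples x ASVs count matrix.
#' @param min_count Minimum reads per ASV per sample to keep a cell
#'   (default 10).
#' @return Filtered count matrix.
#' @export
min_count_filter <- function(counts, min_count = 10) {
  validate_community(counts)
  if (table_mode(counts) != "counts") {
    stop("minimum-count filtering requires raw counts", call. = FALSE)
  }
  counts[counts > 0 & counts < min_count] <- 0
  keep <- colSums(counts) > 0
  set_mode(counts[, keep, drop = FALSE], "counts")
}

#' Convert counts to per-sample relative abundances
#'
#' @param counts Samples x ASVs count matrix without all-zero rows.
#' @return Proportions matrix (rows sum to 1; mode `"proportions"`).
#' @export
relative_abundance <- function(counts) {
  validate_community(counts)
  rs <- rowSums(counts)
  if (any(rs == 0)) {
    stop("all-zero sample(s): ", paste(rownames(counts)[rs == 0], collapse = ", "),
         call. = FALSE)
  }
  set_mode(counts / rs, "proportions")
}

#' Aggregate a community table at a taxonomic rank
#'
#' Sums ASV columns sharing the same label at `rank`. ASVs that are missing
#' from the taxonomy or unclassified at `rank` are pooled under
#' `"Unclassified"`.
#'
#' @param counts Samples x ASVs matrix (counts or proportions).
#' @param taxonomy Taxonomy data frame.
#' @param rank Rank column name, e.g. `"Phylum"`.
#' @return Samples x taxa matrix at the requested rank, same mode.
#' @export
aggregate_rank <- function(counts, taxonomy, rank) {
  validate_community(counts)
  if (!rank %in% names(taxonomy)) {
    stop(sprintf("rank '%s' not present in the taxonomy table", rank), call. = FALSE)
  }
  lab <- taxonomy[[rank]][match(colnames(counts), taxonomy$asv_id)]
  lab[is.na(lab) | lab == ""] <- "Unclassified"
  agg <- t(rowsum(t(counts), group = lab))
  set_mode(agg, table_mode(counts))
}

#' Group-averaged top taxa
#'
#' Averages per-sample relative abundances within groups, keeps the `n` taxa
#' with the highest grand mean and pools the remainder as `"Other"`. This is
#' the table behind the stacked "top 10 phyla" bar chart.
#'
#' @param rel Samples x taxa proportions matrix (e.g. from
#'   [aggregate_rank()] of a relative-abundance table).
#' @param groups Group label per sample (recycled against `rownames(rel)`).
#' @param n Number of taxa to keep (default 10).
#' @return Groups x (<= n + 1) matrix of mean relative abundances.
#' @export
top_taxa <- function(rel, groups, n = 10) {
  validate_community(rel, mode = "proportions")
  groups <- as.character(groups)
  if (length(groups) != nrow(rel)) {
    stop("`groups` must give one label per sample", call. = FALSE)
  }
  gm <- rowsum(rel, group = groups) / as.vector(table(groups)[sort(unique(groups))])
  ord <- order(colMeans(gm), decreasing = TRUE)
  keep <- colnames(gm)[ord][seq_len(min(n, ncol(gm)))]
  other <- setdiff(colnames(gm), keep)
  out <- gm[, keep, drop = FALSE]
  out <- cbind(out, Other = if (length(other)) rowSums(gm[, other, drop = FALSE])
                            else rep(0, nrow(gm)))
  out
}

# Rank swabs by darkness with deterministic lexicographic tie-breaking on
# sample id; returns the row indices of `meta` restricted to swabs, in rank
# order (lightest first).
darkness_rank_order <- function(meta) {
  swabs <- which(meta$sample_type == "swab" & !is.na(meta$darkness))
  swabs[order(meta$darkness[swabs], meta$sample_id[swabs])]
}

PERCENTILE_LABELS <- c("Tenth", "Twentieth", "Thirtieth", "Fortieth", "Fiftieth",
                       "Sixtieth", "Seventieth", "Eightieth", "Ninetieth",
                       "Hundredth")

#' Assign darkness decile (percentile) groups
#'
#' Ranks swabs by darkness (ties broken lexicographically by sample id) and
#' partitions the ranks into 10 contiguous blocks as equal as possible: the
#' first `n %% 10` blocks receive the extra member. Groups are labeled
#' `Tenth` (lightest) through `Hundredth` (darkest). Rumen samples get `NA`.
#'
#' @param meta Metadata data frame with `sample_id`, `sample_type`,
#'   `darkness`.
#' @return `meta` with a `percentile_group` factor column added.
#' @export
assign_percentile_groups <- function(meta) {
  ord <- darkness_rank_order(meta)
  n <- length(ord)
  if (n < 10L) stop("need at least 10 swabs with darkness scores", call. = FALSE)
  base <- n %/% 10L
  extra <- n %% 10L
  sizes <- rep(base, 10L) + c(rep(1L, extra), rep(0L, 10L - extra))
  grp <- rep(PERCENTILE_LABELS, times = sizes)
  meta$percentile_group <- factor(NA_character_, levels = PERCENTILE_LABELS)
  meta$percentile_group[ord] <- grp
  if (length(unique(meta$darkness[ord])) == 1L) {
    message("all darkness scores tied; decile assignment determined by sample-id order")
  }
  meta
}

#' Assign darkness extremes groups
#'
#' Places the `k` lightest swabs in `Low`, the `k` darkest in `High`, and the
#' `k` swabs whose darkness ranks are centered on the median rank in `Mid`
#' (ranks `floor((n-k)/2) + 1 .. floor((n-k)/2) + k`). All other swabs get
#' `none`; rumen samples get `NA`. The default `k = 13` matches a design
#' where group sizes are pinned to the number of rumen samples.
#'
#' @param meta Metadata data frame with `sample_id`, `sample_type`,
#'   `darkness`.
#' @param k Group size (default 13).
#' @return `meta` with an `extremes_group` factor column added
#'   (levels `Low`, `Mid`, `High`, `none`).
#' @export
assign_extremes_groups <- function(meta, k = 13L) {
  k <- as.integer(k)
  ord <- darkness_rank_order(meta)
  n <- length(ord)
  if (n < 3L * k) {
    stop(sprintf("need at least 3k = %d swabs with darkness scores, have %d",
                 3L * k, n), call. = FALSE)
  }
  grp <- rep("none", n)
  grp[seq_len(k)] <- "Low"
  grp[(n - k + 1L):n] <- "High"
  mid0 <- (n - k) %/% 2L
  grp[(mid0 + 1L):(mid0 + k)] <- "Mid"
  meta$extremes_group <- factor(NA_character_, levels = c("Low", "Mid", "High", "none"))
  meta$extremes_group[ord] <- grp
  meta
}

# Evaluate `expr` under a temporary RNG state seeded with `seed`, restoring
# the caller's RNG afterwards.
local_seed <- function(seed, expr) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}
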