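# Colorimetric darkness scoring of swab photographs.
#
# A swab image is an H x W (grayscale) or H x W x 3 (RGB) numeric array of
# intensities on the 0..255 scale. The darkness score of a swab is the mean
# pixel darkness of the 100 x 100 block at the center of the photograph after
# grayscale conversion, on a 0 (white) to 1 (black) scale.

#' Construct a swab image
#'
#' Wraps a pixel array as a `swab_image` object after validating its shape and
#' intensity range. Images are stored as numeric arrays on the 0..255 scale;
#' grayscale images are `H x W` matrices, color images `H x W x 3` arrays.
#'
#' @param pixels Numeric matrix (`H x W`) or array (`H x W x 3`) with values
#'   in `[0, 255]`. Values read from 8-bit files are integers; derived values
#'   (e.g. luma) may be fractional.
#' @param sample_id Character scalar identifying the photographed swab.
#' @return A `swab_image`: the pixel array with class and `sample_id`
#'   attributes.
#' @export
swab_image <- function(pixels, sample_id = NA_character_) {
  if (!is.numeric(pixels)) {
    stop("`pixels` must be numeric", call. = FALSE)
  }
  nd <- length(dim(pixels))
  if (nd == 0 || nd > 3 || (nd == 3 && dim(pixels)[3] != 3)) {
    stop("image must be an H x W matrix or an H x W x 3 array", call. = FALSE)
  }
  if (anyNA(pixels) || min(pixels) < 0 || max(pixels) > 255) {
    stop("pixel intensities must lie in [0, 255] with no missing values",
         call. = FALSE)
  }
  structure(pixels, class = "swab_image", sample_id = as.character(sample_id))
}

#' @export
print.swab_image <- function(x, ...) {
  d <- dim(x)
  ch <- if (length(d) == 3) d[3] else 1L
  cat(sprintf("<swab_image '%s': %d x %d px, %d channel%s>\n",
              attr(x, "sample_id"), d[1], d[2], ch, if (ch > 1) "s" else ""))
  invisible(x)
}

img_channels <- function(image) {
  d <- dim(image)
  if (length(d) == 3) d[3] else 1L
}

#' Crop the central square block of an image
#'
#' Extracts the `size` x `size` pixel block centered on the image, the region
#' assumed to be swab material in a trimmed swab photograph. The top-left
#' corner is placed at row `floor(H/2) - floor(size/2)` and column
#' `floor(W/2) - floor(size/2)` (0-based), so the crop is deterministic for
#' odd dimensions.
#'
#' @param image A `swab_image` (or bare numeric matrix/array).
#' @param size Side length of the square crop in pixels (default 100).
#' @return A `swab_image` of dimensions `size x size` (x channels).
#' @export
center_crop <- function(image, size = 100L) {
  size <- as.integer(size)
  if (size < 1L) stop("`size` must be a positive integer", call. = FALSE)
  d <- dim(image)
  if (d[1] < size) {
    stop(sprintf("image height %d px is smaller than crop size %d", d[1], size),
         call. = FALSE)
  }
  if (d[2] < size) {
    stop(sprintf("image width %d px is smaller than crop size %d", d[2], size),
         call. = FALSE)
  }
  r0 <- d[1] %/% 2L - size %/% 2L  # 0-based top-left corner
  c0 <- d[2] %/% 2L - size %/% 2L
  rows <- (r0 + 1L):(r0 + size)
  cols <- (c0 + 1L):(c0 + size)
  out <- if (length(d) == 3) image[rows, cols, , drop = FALSE]
         else image[rows, cols, drop = FALSE]
  swab_image(out, sample_id = attr(image, "sample_id") %||% NA_character_)
}

#' Convert an image to grayscale luma
#'
#' Applies the ITU-R BT.601 luma weights `Y = 0.299 R + 0.587 G + 0.114 B`
#' per pixel. Luma is kept in floating point (no 8-bit rounding) so that
#' downstream mean-darkness scores are exact. Single-channel input is
#' returned unchanged.
#'
#' @param image A `swab_image` with 1 or 3 channels.
#' @return A single-channel `swab_image`.
#' @export
to_grayscale <- function(image) {
  ch <- img_channels(image)
  if (ch == 1L) return(image)
  if (ch != 3L) {
    stop(sprintf("expected 1 or 3 channels, got %d", ch), call. = FALSE)
  }
  y <- 0.299 * image[, , 1] + 0.587 * image[, , 2] + 0.114 * image[, , 3]
  swab_image(y, sample_id = attr(image, "sample_id") %||% NA_character_)
}

#' Mean-pixel darkness score
#'
#' The darkness of a single-channel image: `1 - mean(pixels) / 255`, where 0
#' is pure white and 1 pure black. The mean is computed in floating point
#' over every pixel of the (already cropped) block.
#'
#' @param gray A single-channel `swab_image`.
#' @return Numeric scalar in `[0, 1]`.
#' @export
darkness_score <- function(gray) {
  if (img_channels(gray) != 1L) {
    stop("darkness_score() requires a single-channel image; call to_grayscale() first",
         call. = FALSE)
  }
  if (length(gray) == 0) stop("empty image", call. = FALSE)
  1 - mean(gray) / 255
}

#' Score a swab photograph end to end
#'
#' Convenience composition: center crop, grayscale conversion, darkness.
#'
#' @inheritParams center_crop
#' @param crop_size Side of the central square used for scoring (pixels).
#' @return Numeric darkness score in `[0, 1]`.
#' @export
score_swab_image <- function(image, crop_size = 100L) {
  darkness_score(to_grayscale(center_crop(image, size = crop_size)))
}

#' Read a swab photograph from a PNG file
#'
#' Reads an 8-bit PNG and rescales intensities to the 0..255 range. An alpha
#' channel, if present, is dropped.
#'
#' @param path Path to a PNG file.
#' @param sample_id Identifier attached to the image (defaults to the file
#'   name without extension).
#' @return A `swab_image`.
#' @export
read_swab_image <- function(path, sample_id = NULL) {
  if (!file.exists(path)) stop(sprintf("image file not found: %s", path), call. = FALSE)
  px <- png::readPNG(path)
  d <- dim(px)
  if (length(d) == 3 && d[3] == 2L) px <- px[, , 1]          # gray + alpha
  if (length(d) == 3 && d[3] == 4L) px <- px[, , 1:3]        # RGB + alpha
  if (is.null(sample_id)) sample_id <- sub("\\.[^.]*$", "", basename(path))
  swab_image(px * 255, sample_id = sample_id)
}

#' Write a swab image to an 8-bit PNG file
#'
#' Pixel values are quantized to 8 bits on write, so scores recovered from a
#' written file can differ from the in-memory image by up to `0.5/255`.
#'
#' @param image A `swab_image`.
#' @param path Output PNG path.
#' @return `path`, invisibly.
#' @export
write_swab_image <- function(image, path) {
  px <- unclass(image)
  attr(px, "sample_id") <- NULL
  png::writePNG(px / 255, target = path)
  invisible(path)
}

#' Score a manifest of swab photographs
#'
#' Reads a manifest table of sample ids and image paths, scores every image
#' (crop, grayscale, mean darkness) and returns one row per manifest row in
#' the input order. Unreadable or malformed images are recorded as errors
#' (with `NA` darkness) rather than aborting the run; the run fails only if
#' every row fails.
#'
#' @param manifest A data frame with columns `sample_id` and `image_path`,
#'   or the path to such a table as TSV.
#' @param crop_size Side of the central square used for scoring (pixels).
#' @return A data frame with columns `sample_id`, `darkness`, `error`
#'   (`NA` for clean rows).
#' @export
score_swab_manifest <- function(manifest, crop_size = 100L) {
  if (is.character(manifest) && length(manifest) == 1L) {
    manifest <- utils::read.delim(manifest, stringsAsFactors = FALSE,
                                  comment.char = "#")
  }
  if (!all(c("sample_id", "image_path") %in% names(manifest))) {
    stop("manifest must have columns `sample_id` and `image_path`", call. = FALSE)
  }
  if (nrow(manifest) == 0L) {
    warning("empty manifest: no swabs to score")
    return(data.frame(sample_id = character(), darkness = numeric(),
                      error = character(), stringsAsFactors = FALSE))
  }
  scores <- rep(NA_real_, nrow(manifest))
  errors <- rep(NA_character_, nrow(manifest))
  for (i in seq_len(nrow(manifest))) {
    res <- tryCatch(
      score_swab_image(read_swab_image(manifest$image_path[i],
                                       sample_id = manifest$sample_id[i]),
                       crop_size = crop_size),
      error = function(e) e)
    if (inherits(res, "error")) errors[i] <- conditionMessage(res)
    else scores[i] <- res
  }
  if (all(is.na(scores))) {
    stop("all manifest rows failed to score; first error: ", errors[1],
         call. = FALSE)
  }
  ok <- scores[!is.na(scores)]
  message(sprintf("scored %d/%d swabs (darkness min %.4f, median %.4f, max %.4f)",
                  length(ok), nrow(manifest), min(ok), stats::median(ok), max(ok)))
  data.frame(sample_id = as.character(manifest$sample_id), darkness = scores,
             error = errors, stringsAsFactors = FALSE)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
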