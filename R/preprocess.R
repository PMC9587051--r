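# Image preprocessing pipeline: luminance peak alignment, three-channel
# grayscale conversion, quadrisection, affine augmentation, bilinear resize,
# stage balancing and stratified splitting.
#
# Images are numeric arrays in [0,1]: a matrix (height x width) for grayscale
# or an array height x width x 3 for colour.

#' Align the luminance histogram peak of a grayscale image
#'
#' Normalizes illumination across images by additively shifting the image so
#' that its maximum luminance peak sits at a fixed reference level. The peak
#' is located as the maximal bin of a 64-bin intensity histogram over `[0,1]`
#' and estimated as the mean of the pixel values inside that bin; the image is
#' shifted by `reference - peak` and clipped to `[0,1]`. Shifts smaller than
#' half a bin width are suppressed, which makes the operation exactly
#' idempotent on images whose histogram peak is well defined (e.g.
#' background-dominated cytology). A constant-zero image maps to a constant
#' `reference` image.
#'
#' @param img Grayscale matrix with values in `[0,1]`.
#' @param reference Target peak level (default 0.8).
#' @param bins Number of histogram bins (default 64).
#' @return Matrix of the same dimensions, values in `[0,1]`.
#' @export
normalize_luminance <- function(img, reference = 0.8, bins = 64) {
  if (length(img) == 0) stopf("empty image")
  if (!is.matrix(img)) stopf("normalize_luminance expects a grayscale matrix")
  idx <- pmin(pmax(floor(img * bins), 0), bins - 1)  # bin of each pixel
  counts <- tabulate(idx + 1L, nbins = bins)
  mode_bin <- which.max(counts) - 1L
  peak <- mean(img[idx == mode_bin])
  shift <- reference - peak
  if (abs(shift) < 1 / (2 * bins)) return(img)
  clip01(img + shift)
}

#' Convert an image to three identical grayscale channels
#'
#' RGB input is reduced to a single luminance channel using ITU-R BT.601
#' weights (0.299, 0.587, 0.114) and replicated into three identical channels
#' so grayscale data meets the 3-channel input requirement of standard
#' convolutional backbones. Grayscale input is replicated directly.
#'
#' @param img Matrix (grayscale) or height x width x 3 array.
#' @return height x width x 3 array with three identical channels.
#' @export
to_three_channel_gray <- function(img) {
  g <- rgb_to_gray(img)
  array(g, dim = c(dim(g), 3))
}

rgb_to_gray <- function(img) {
  if (is.matrix(img)) return(img)
  if (length(dim(img)) == 3 && dim(img)[3] == 3) {
    return(0.299 * img[, , 1] + 0.587 * img[, , 2] + 0.114 * img[, , 3])
  }
  stopf("expected a grayscale matrix or a 3-channel array, got dims %s",
        paste(dim(img), collapse = "x"))
}

#' Quadrisect an image or an image record
#'
#' Splits an image into its four quadrants. The quadrants tile the image
#' exactly; for odd dimensions the top/left quadrants receive the extra
#' row/column. Applied to a manifest row (via [quadrisect_record()]) each
#' quadrant inherits the parent's metadata and stage label.
#'
#' @param img Matrix or height x width x channels array with both spatial
#'   dimensions at least 2.
#' @return List of four sub-images in order top-left, top-right, bottom-left,
#'   bottom-right.
#' @export
quadrisect <- function(img) {
  d <- dim(img)
  h <- d[1]; w <- d[2]
  if (h < 2 || w < 2) stopf("cannot quadrisect an image with a 1-pixel dimension")
  h1 <- ceiling(h / 2); w1 <- ceiling(w / 2)
  rows1 <- seq_len(h1); rows2 <- (h1 + 1):h
  cols1 <- seq_len(w1); cols2 <- (w1 + 1):w
  sub <- function(r, c) {
    if (length(d) == 2) img[r, c, drop = FALSE] else img[r, c, , drop = FALSE]
  }
  list(sub(rows1, cols1), sub(rows1, cols2), sub(rows2, cols1), sub(rows2, cols2))
}

#' @describeIn quadrisect Quadrisect the image behind one manifest row,
#'   writing four quadrant PNGs next to the parent (suffix `_q1..q4`) and
#'   returning a four-row manifest that inherits all parent metadata.
#' @param record A single-row `estrous_manifest`.
#' @param outdir Output directory for quadrant images (default: alongside the
#'   parent image).
#' @export
quadrisect_record <- function(record, outdir = NULL) {
  stopifnot(nrow(record) == 1)
  img <- load_image(record$image_path)
  quads <- quadrisect(img)
  outdir <- outdir %||% dirname(record$image_path)
  base <- tools::file_path_sans_ext(basename(record$image_path))
  rows <- lapply(seq_along(quads), function(i) {
    q <- quads[[i]]
    path <- file.path(outdir, sprintf("%s_q%d.png", base, i))
    png::writePNG(q, path)
    r <- as.data.frame(record)
    r$image_path <- path
    r$height <- dim(q)[1]
    r$width <- dim(q)[2]
    r
  })
  as_manifest(do.call(rbind, rows),
              provenance = sprintf("quadrants of %s", record$image_path))
}

#' Load an image file as a numeric array in [0,1]
#'
#' @param path PNG image path.
#' @return Matrix or height x width x channels array.
#' @export
load_image <- function(path) {
  if (!file.exists(path)) stopf("image not readable: %s", path)
  img <- png::readPNG(path)
  if (length(dim(img)) == 3 && dim(img)[3] == 4) img <- img[, , 1:3]  # drop alpha
  img
}

#' Augmentation parameters
#'
#' One random affine transform is drawn per [augment()] call from these
#' ranges: reflection per axis with probability `reflect_prob`, rotation angle
#' uniform on `[-rotation_range, rotation_range]` degrees about the image
#' centre, scale factor uniform on `scale_range`, and x/y translation uniform
#' on `[-translate_range, translate_range]` as a fraction of width/height.
#' Out-of-frame samples are filled by edge replication.
#'
#' @param reflect One of `"none"`, `"horizontal"`, `"vertical"`, `"both"`:
#'   which axes may be mirrored.
#' @param reflect_prob Probability of mirroring each permitted axis.
#' @param rotation_range Maximum absolute rotation in degrees.
#' @param scale_range Length-2 positive multiplicative interval.
#' @param translate_range Maximum translation fraction in `[0, 0.5]`.
#' @param seed Integer seed making the draw reproducible.
#' @return An `augment_params` list.
#' @export
augment_params <- function(reflect = "both", reflect_prob = 0.5,
                           rotation_range = 30, scale_range = c(0.9, 1.1),
                           translate_range = 0.1, seed = NULL) {
  reflect <- match.arg(reflect, c("none", "horizontal", "vertical", "both"))
  if (any(scale_range <= 0)) stopf("scale_range must be positive")
  if (translate_range < 0 || translate_range > 0.5) {
    stopf("translate_range must lie in [0, 0.5]")
  }
  structure(list(reflect = reflect, reflect_prob = reflect_prob,
                 rotation_range = rotation_range,
                 scale_range = sort(scale_range),
                 translate_range = translate_range, seed = seed),
            class = "augment_params")
}

#' Randomly augment an image
#'
#' Draws one affine transform (reflection, rotation, scaling, translation)
#' from the configured ranges and applies it with bilinear interpolation and
#' edge-replication fill. The output has the same shape as the input. With a
#' fixed `p$seed` the draw, and hence the output, is bit-reproducible; with
#' all ranges zero and `reflect = "none"` the image is returned unchanged.
#'
#' @param img Matrix or 3-channel array in `[0,1]`.
#' @param p An [augment_params()] object.
#' @return Augmented image of identical shape.
#' @export
augment <- function(img, p = augment_params()) {
  stopifnot(inherits(p, "augment_params"))
  draw <- with_seed(p$seed, {
    list(
      flip_h = p$reflect %in% c("horizontal", "both") && runif(1) < p$reflect_prob,
      flip_v = p$reflect %in% c("vertical", "both") && runif(1) < p$reflect_prob,
      angle = if (p$rotation_range > 0) runif(1, -p$rotation_range, p$rotation_range) else 0,
      scale = if (diff(p$scale_range) > 0) runif(1, p$scale_range[1], p$scale_range[2])
              else p$scale_range[1],
      tx = if (p$translate_range > 0) runif(1, -p$translate_range, p$translate_range) else 0,
      ty = if (p$translate_range > 0) runif(1, -p$translate_range, p$translate_range) else 0
    )
  })
  apply_affine(img, flip_h = draw$flip_h, flip_v = draw$flip_v,
               angle = draw$angle, scale = draw$scale,
               tx = draw$tx, ty = draw$ty)
}

#' Apply a deterministic affine transform to an image
#'
#' Centre-based affine resampling used by [augment()]: reflection, rotation
#' (degrees about the image centre, positive in the row-down raster
#' convention), isotropic scaling and
#' translation (fractions of width/height), with bilinear interpolation and
#' edge replication. The identity transform reproduces the input exactly.
#'
#' @param img Matrix or 3-channel array.
#' @param flip_h,flip_v Mirror horizontally / vertically.
#' @param angle Rotation in degrees.
#' @param scale Isotropic scale factor (> 1 zooms in).
#' @param tx,ty Translation as fraction of width / height.
#' @return Transformed image of identical shape.
#' @export
apply_affine <- function(img, flip_h = FALSE, flip_v = FALSE, angle = 0,
                         scale = 1, tx = 0, ty = 0) {
  d <- dim(img)
  h <- d[1]; w <- d[2]
  cy <- (h + 1) / 2; cx <- (w + 1) / 2
  # destination pixel grid, centre-based coordinates
  yy <- matrix(seq_len(h), h, w) - cy
  xx <- matrix(rep(seq_len(w), each = h), h, w) - cx
  # invert: undo translation, rotation, scale, then reflection
  x1 <- xx - tx * w
  y1 <- yy - ty * h
  th <- -angle * pi / 180
  xr <- cos(th) * x1 - sin(th) * y1
  yr <- sin(th) * x1 + cos(th) * y1
  xs <- xr / scale
  ys <- yr / scale
  if (flip_h) xs <- -xs
  if (flip_v) ys <- -ys
  sample_bilinear(img, ys + cy, xs + cx)
}

# Bilinear sampling at (possibly fractional) row/col coordinate matrices,
# clamping out-of-range coordinates to the border (edge replication).
sample_bilinear <- function(img, rows, cols) {
  d <- dim(img)
  h <- d[1]; w <- d[2]
  r0 <- floor(rows); c0 <- floor(cols)
  fr <- rows - r0; fc <- cols - c0
  cl <- function(x, n) pmin(pmax(x, 1), n)
  r0c <- cl(r0, h); r1c <- cl(r0 + 1, h)
  c0c <- cl(c0, w); c1c <- cl(c0 + 1, w)
  sample_plane <- function(plane) {
    v00 <- plane[cbind(as.vector(r0c), as.vector(c0c))]
    v01 <- plane[cbind(as.vector(r0c), as.vector(c1c))]
    v10 <- plane[cbind(as.vector(r1c), as.vector(c0c))]
    v11 <- plane[cbind(as.vector(r1c), as.vector(c1c))]
    out <- v00 * (1 - fr) * (1 - fc) + v01 * (1 - fr) * fc +
      v10 * fr * (1 - fc) + v11 * fr * fc
    matrix(out, nrow(rows), ncol(rows))
  }
  if (length(d) == 2) return(sample_plane(img))
  out <- array(0, c(dim(rows), d[3]))
  for (k in seq_len(d[3])) out[, , k] <- sample_plane(img[, , k])
  out
}

#' Bilinear resize
#'
#' Separable centre-aligned bilinear resize. Resizing to the input size is an
#' exact identity; a constant image stays constant; outputs remain inside the
#' input value range.
#'
#' @param img Matrix or 3-channel array.
#' @param height,width Target spatial dimensions.
#' @return Resized image.
#' @export
resize_bilinear <- function(img, height, width) {
  d <- dim(img)
  ry <- (seq_len(height) - 0.5) * d[1] / height + 0.5
  rx <- (seq_len(width) - 0.5) * d[2] / width + 0.5
  rows <- matrix(ry, height, width)
  cols <- matrix(rx, height, width, byrow = TRUE)
  sample_bilinear(img, rows, cols)
}

#' Resize an image to the 224 x 224 x 3 network input
#'
#' @param img height x width x 3 array in `[0,1]`.
#' @return 224 x 224 x 3 array.
#' @export
resize_to_input <- function(img) {
  if (length(dim(img)) != 3 || dim(img)[3] != 3) {
    stopf("resize_to_input expects a 3-channel image")
  }
  resize_bilinear(img, 224, 224)
}

#' Balance stage counts by seeded downsampling
#'
#' Downsamples every canonical stage, without replacement, to the minimum
#' per-stage record count so no stage biases training.
#'
#' @param m An `estrous_manifest` with `stage` set on every row.
#' @param seed Integer seed.
#' @return Balanced `estrous_manifest`.
#' @export
balance_stages <- function(m, seed = NULL) {
  counts <- table(factor(m$stage, levels = canonical_stages()))
  empty <- names(counts)[counts == 0]
  if (length(empty)) stopf("no records for stage(s): %s", paste(empty, collapse = ", "))
  n_min <- min(counts)
  keep <- with_seed(seed, {
    unlist(lapply(canonical_stages(), function(s) {
      idx <- which(m$stage == s)
      sort(sample(idx, n_min))
    }))
  })
  ec_log("balance_stages: downsampled to %d records per stage", n_min)
  out <- m[sort(keep), , drop = FALSE]
  rownames(out) <- NULL
  structure(out, provenance = attr(m, "provenance"), class = class(m))
}

#' Stratified train/validation/test split
#'
#' Randomly divides a manifest into training, validation and test partitions
#' (default 80/10/10) by sampling without replacement within strata defined by
#' the joint value of `strata_keys`, so each partition is proportionally
#' representative of the whole bank. Within every stratum the achieved
#' fractions hold to within one record (largest-remainder apportionment).
#' Strata with fewer than 3 records fall back into a pooled global stratum
#' with a logged warning. Quadrisection, when used, should be applied after
#' splitting so quadrants of one parent image never span two partitions.
#'
#' @param m An `estrous_manifest`.
#' @param fractions Length-3 numeric summing to 1: train, validation, test.
#' @param strata_keys Manifest columns whose joint value defines a stratum.
#' @param seed Integer seed.
#' @return A `dataset_split` list with elements `train`, `validation`, `test`
#'   (manifests) and `fractions`.
#' @export
split_dataset <- function(m, fractions = c(0.8, 0.1, 0.1),
                          strata_keys = c("stain", "species", "lab", "magnification"),
                          seed = NULL) {
  if (nrow(m) == 0) stopf("cannot split an empty manifest")
  if (abs(sum(fractions) - 1) > 1e-8 || length(fractions) != 3) {
    stopf("fractions must be three numbers summing to 1")
  }
  keys <- intersect(strata_keys, names(m))
  strat <- if (length(keys)) {
    apply(as.data.frame(m)[, keys, drop = FALSE], 1, function(r)
      paste(ifelse(is.na(r), "<na>", r), collapse = "|"))
  } else rep("all", nrow(m))
  tab <- table(strat)
  small <- names(tab)[tab < 3]
  if (length(small) && length(tab) > 1) {
    ec_log("split_dataset: %d stratum(-a) smaller than 3 records pooled globally",
           length(small))
    strat[strat %in% small] <- "<pooled>"
  }
  assign_part <- integer(nrow(m))
  with_seed(seed, {
    for (s in unique(strat)) {
      idx <- which(strat == s)
      idx <- sample(idx)  # seeded shuffle, then largest-remainder apportionment
      n <- length(idx)
      raw <- fractions * n
      base <- floor(raw)
      rem <- raw - base
      left <- n - sum(base)
      if (left > 0) {
        order_rem <- order(rem, decreasing = TRUE)  # ties favour train > val > test
        base[order_rem[seq_len(left)]] <- base[order_rem[seq_len(left)]] + 1
      }
      parts <- rep(1:3, times = base)
      assign_part[idx] <- parts
    }
  })
  take <- function(k) {
    out <- m[assign_part == k, , drop = FALSE]
    rownames(out) <- NULL
    structure(out, provenance = attr(m, "provenance"), class = class(m))
  }
  ec_log("split_dataset: %d/%d/%d records (train/val/test)",
         sum(assign_part == 1), sum(assign_part == 2), sum(assign_part == 3))
  structure(list(train = take(1), validation = take(2), test = take(3),
                 fractions = fractions),
            class = "dataset_split")
}

#' @export
print.dataset_split <- function(x, ...) {
  cat(sprintf("<dataset_split> train=%d validation=%d test=%d (fractions %s)\n",
              nrow(x$train), nrow(x$validation), nrow(x$test),
              paste(x$fractions, collapse = "/")))
  invisible(x)
}
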