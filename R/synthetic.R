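#' Scene specification for the synthetic leaf-on-board renderer
#'
#' Describes a single synthetic acquisition: a two-colour calibration board
#' of squares with known physical size, with one leaf lying on top of it.
#' The rendered scene carries exact ground truth (leaf mask, pixel and
#' physical area, per-square pixel area), so every downstream stage of the
#' pipeline can be tested against known values.
#'
#' @param image_width_px,image_height_px image size in pixels.
#' @param board_square_size_cm physical side length of one board square (cm).
#' @param board_square_size_px side length of one board square in pixels
#'   (must be at least 8).
#' @param board_colors 2x3 matrix (rows = the two square colours, RGB in
#'   0..255).
#' @param leaf_shape list describing the leaf: `type` one of `"ellipse"`,
#'   `"superellipse"`, `"rectangle"`; `center_px` numeric length-2
#'   (row, col); `semi_axes_px` numeric length-2 (semi-height, semi-width);
#'   `rotation_deg` rotation angle; for a superellipse, `exponent` (> 0,
#'   2 = ellipse).
#' @param leaf_color_mean RGB triple, mean leaf colour (0..255).
#' @param leaf_color_sd per-channel SD of the leaf colour jitter.
#' @param noise_sd SD of the Gaussian pixel noise added to the whole image
#'   (gray levels).
#' @param seed integer seed; the same spec renders a bit-identical scene.
#'
#' @return an object of class `scene_spec`.
#' @export
scene_spec <- function(image_width_px = 480L, image_height_px = 480L,
                       board_square_size_cm = 1.0, board_square_size_px = 40L,
                       board_colors = rbind(c(235, 235, 235), c(45, 45, 60)),
                       leaf_shape = list(type = "ellipse",
                                         center_px = c(240, 240),
                                         semi_axes_px = c(140, 55),
                                         rotation_deg = 25,
                                         exponent = 2),
                       leaf_color_mean = c(62, 148, 70),
                       leaf_color_sd = c(6, 8, 6),
                       noise_sd = 2,
                       seed = 1L) {
  spec <- list(image_width_px = as.integer(image_width_px),
               image_height_px = as.integer(image_height_px),
               board_square_size_cm = board_square_size_cm,
               board_square_size_px = as.integer(board_square_size_px),
               board_colors = board_colors,
               leaf_shape = leaf_shape,
               leaf_color_mean = leaf_color_mean,
               leaf_color_sd = leaf_color_sd,
               noise_sd = noise_sd,
               seed = as.integer(seed))
  class(spec) <- "scene_spec"
  validate_scene_spec(spec)
  spec
}

validate_scene_spec <- function(spec) {
  stopifnot(spec$image_width_px >= 1, spec$image_height_px >= 1)
  if (spec$board_square_size_px < 8)
    stop("board_square_size_px must be >= 8")
  if (spec$board_square_size_cm <= 0)
    stop("board_square_size_cm must be positive")
  cols <- rbind(spec$board_colors, spec$leaf_color_mean)
  if (any(cols < 0) || any(cols > 255))
    stop("all colour values must lie in [0, 255]")
  if (any(spec$leaf_color_sd < 0) || spec$noise_sd < 0)
    stop("noise standard deviations must be non-negative")
  sh <- spec$leaf_shape
  if (!sh$type %in% c("ellipse", "superellipse", "rectangle"))
    stop("unknown leaf_shape type: ", sh$type)
  invisible(spec)
}

# Pixel-inclusion test for the leaf shape. Pixel centers are at
# (i - 0.5, j - 0.5) for 1-indexed (row, col); hard inclusion (no
# anti-aliasing) so pixel counts are exact and reproducible.
leaf_shape_mask <- function(shape, height, width) {
  if (all(shape$semi_axes_px <= 0))
    return(matrix(0L, height, width))
  ctr <- shape$center_px
  rr <- matrix(seq_len(height) - 0.5 - ctr[1], height, width)
  cc <- matrix(rep(seq_len(width) - 0.5 - ctr[2], each = height), height, width)
  if (identical(shape$type, "rectangle")) {
    inside <- abs(rr) < shape$semi_axes_px[1] & abs(cc) < shape$semi_axes_px[2]
  } else {
    th <- (shape$rotation_deg %||% 0) * pi / 180
    u <- rr * cos(th) + cc * sin(th)
    v <- -rr * sin(th) + cc * cos(th)
    p <- if (identical(shape$type, "superellipse")) shape$exponent %||% 2 else 2
    inside <- (abs(u) / shape$semi_axes_px[1])^p +
      (abs(v) / shape$semi_axes_px[2])^p <= 1
  }
  mask <- matrix(0L, height, width)
  mask[inside] <- 1L
  mask
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Render a synthetic leaf-on-calibration-board scene
#'
#' Draws an alternating two-colour checkerboard spanning the whole image,
#' overlays a leaf given by a hard pixel-inclusion test of a parametric
#' shape, adds per-pixel colour jitter on the leaf and Gaussian noise on the
#' whole frame, and quantizes to 8-bit. Ground truth is exact: the leaf
#' mask is the inclusion mask itself, the per-square pixel area is
#' `board_square_size_px^2`, and the physical leaf area follows from the
#' pixel count times the board's cm-squared-per-pixel coefficient.
#'
#' @param spec a [scene_spec()].
#' @return a list with elements `image` (height x width x 3 numeric array,
#'   integer-valued 0..255) and `truth` (list: `leaf_mask`, `leaf_area_px`,
#'   `leaf_area_cm2`, `square_pixel_area`, `g_channel_mean`,
#'   `board_square_size_cm`).
#' @export
render_scene <- function(spec) {
  validate_scene_spec(spec)
  h <- spec$image_height_px; w <- spec$image_width_px
  set.seed(spec$seed)

  mask <- leaf_shape_mask(spec$leaf_shape, h, w)
  if (any(mask[1, ] == 1L) || any(mask[h, ] == 1L) ||
      any(mask[, 1] == 1L) || any(mask[, w] == 1L))
    stop("leaf extends beyond the image: shrink semi_axes_px or recenter")

  # checkerboard: square (i,j) colour alternates with floor parity
  s <- spec$board_square_size_px
  ri <- (seq_len(h) - 1L) %/% s
  ci <- (seq_len(w) - 1L) %/% s
  parity <- (outer(ri, ci, "+")) %% 2L
  img <- array(0, dim = c(h, w, 3))
  for (k in 1:3) {
    ch <- ifelse(parity == 0L, spec$board_colors[1, k], spec$board_colors[2, k])
    img[, , k] <- ch
  }

  idx <- which(mask == 1L)
  n_leaf <- length(idx)
  for (k in 1:3) {
    ch <- img[, , k]
    if (n_leaf > 0)
      ch[idx] <- spec$leaf_color_mean[k] +
        rnorm(n_leaf, 0, spec$leaf_color_sd[k])
    img[, , k] <- ch
  }
  if (spec$noise_sd > 0)
    img <- img + array(rnorm(length(img), 0, spec$noise_sd), dim = dim(img))
  img <- round(pmin(pmax(img, 0), 255))

  sq_px <- as.numeric(s)^2
  area_cm2 <- n_leaf * spec$board_square_size_cm^2 / sq_px
  g <- img[, , 2]
  truth <- list(leaf_mask = mask,
                leaf_area_px = n_leaf,
                leaf_area_cm2 = area_cm2,
                square_pixel_area = sq_px,
                g_channel_mean = if (n_leaf > 0) mean(g[idx]) else NA_real_,
                board_square_size_cm = spec$board_square_size_cm)
  list(image = img, truth = truth)
}

#' Simulation specification for feature-to-nitrogen datasets
#'
#' Defines a synthetic stand-in for a field study: per-sample features
#' (leaf area in cm2, G-channel mean and variance) drawn uniformly from
#' realistic per-stage ranges, and nitrogen computed from a known smooth
#' surface (a sum of Gaussian bumps over feature space) plus Gaussian
#' noise, clipped into the stage's observed nitrogen range
#' (9-11 g/kg growing, 15-19 g/kg mature).
#'
#' @param n_samples number of samples to draw (>= 1).
#' @param stage `"growing"` or `"mature"`.
#' @param nitrogen_range_gkg length-2 numeric; defaults to the stage's
#'   range (growing `c(9, 11)`, mature `c(15, 19)`).
#' @param surface list of bumps, each `list(center, amplitude, width)`;
#'   `center` in feature units (area_cm2, g_mean, g_var), `width` in
#'   feature-range-normalized units. `NULL` selects a stage default.
#' @param feature_ranges 3x2 matrix of (min, max) per feature, rows
#'   (area_cm2, g_mean, g_var).
#' @param noise_sd_gkg SD of the additive nitrogen noise (g/kg).
#' @param seed integer seed.
#' @return an object of class `sim_spec`.
#' @export
sim_spec <- function(n_samples, stage = c("growing", "mature"),
                     nitrogen_range_gkg = NULL, surface = NULL,
                     feature_ranges = rbind(area_cm2 = c(10, 40),
                                            g_mean = c(80, 180),
                                            g_var = c(50, 600)),
                     noise_sd_gkg = 0.2, seed = 1L) {
  stage <- match.arg(stage)
  if (n_samples < 1) stop("n_samples must be >= 1")
  if (noise_sd_gkg < 0) stop("noise_sd_gkg must be >= 0")
  if (is.null(nitrogen_range_gkg))
    nitrogen_range_gkg <- if (stage == "growing") c(9, 11) else c(15, 19)
  if (is.null(surface)) surface <- default_surface(stage, feature_ranges)
  if (length(surface) == 0) stop("surface must contain at least one bump")
  spec <- list(n_samples = as.integer(n_samples), stage = stage,
               nitrogen_range_gkg = nitrogen_range_gkg, surface = surface,
               feature_ranges = feature_ranges,
               noise_sd_gkg = noise_sd_gkg, seed = as.integer(seed))
  class(spec) <- "sim_spec"
  spec
}

# Stage defaults: one broad bump acting as the stage's nitrogen level plus
# two narrower positive/negative bumps that curve the surface, keeping most
# values inside the stage range before clipping.
default_surface <- function(stage, fr) {
  mid <- rowMeans(fr)
  lo <- fr[, 1] + 0.25 * (fr[, 2] - fr[, 1])
  hi <- fr[, 1] + 0.75 * (fr[, 2] - fr[, 1])
  if (stage == "growing") {
    list(list(center = mid, amplitude = 10.2, width = 4.0),
         list(center = c(lo[1], hi[2], lo[3]), amplitude = 0.8, width = 0.45),
         list(center = c(hi[1], lo[2], hi[3]), amplitude = -0.7, width = 0.45))
  } else {
    list(list(center = mid, amplitude = 17.2, width = 4.0),
         list(center = c(lo[1], hi[2], lo[3]), amplitude = 1.6, width = 0.45),
         list(center = c(hi[1], lo[2], hi[3]), amplitude = -1.5, width = 0.45))
  }
}

#' Evaluate a simulation surface at feature vectors
#'
#' Sums the spec's Gaussian bumps at each row of `X`, using
#' feature-range-normalized Euclidean distance, so bump widths are
#' dimensionless and comparable across features.
#'
#' @param spec a [sim_spec()].
#' @param X numeric matrix (n x 3), columns (area_cm2, g_mean, g_var).
#' @return numeric vector of surface values (g/kg, before noise/clipping).
#' @export
eval_surface <- function(spec, X) {
  X <- as.matrix(X)
  span <- spec$feature_ranges[, 2] - spec$feature_ranges[, 1]
  out <- numeric(nrow(X))
  for (b in spec$surface) {
    d2 <- rowSums(sweep(sweep(X, 2, b$center), 2, span, "/")^2)
    out <- out + b$amplitude * exp(-d2 / (2 * b$width^2))
  }
  out
}

#' Simulate a feature-to-nitrogen dataset
#'
#' Draws features uniformly from the spec's ranges, evaluates the true
#' surface, adds Gaussian noise and clips nitrogen into the stage range.
#' Deterministic given the seed. The pre-clipping noisy values and the
#' noiseless surface are attached as attributes `"nitrogen_preclip"` and
#' `"nitrogen_surface"` for generator diagnostics.
#'
#' @param spec a [sim_spec()].
#' @return data.frame with columns
#'   `sample_id, stage, area_cm2, g_mean, g_var, nitrogen_gkg`.
#' @export
simulate_dataset <- function(spec) {
  stopifnot(inherits(spec, "sim_spec"))
  set.seed(spec$seed)
  n <- spec$n_samples
  fr <- spec$feature_ranges
  X <- cbind(runif(n, fr[1, 1], fr[1, 2]),
             runif(n, fr[2, 1], fr[2, 2]),
             runif(n, fr[3, 1], fr[3, 2]))
  colnames(X) <- c("area_cm2", "g_mean", "g_var")
  surf <- eval_surface(spec, X)
  preclip <- surf + rnorm(n, 0, spec$noise_sd_gkg)
  nit <- pmin(pmax(preclip, spec$nitrogen_range_gkg[1]),
              spec$nitrogen_range_gkg[2])
  out <- data.frame(sample_id = sprintf("%s_%04d", spec$stage, seq_len(n)),
                    stage = spec$stage,
                    area_cm2 = X[, 1], g_mean = X[, 2], g_var = X[, 3],
                    nitrogen_gkg = nit,
                    stringsAsFactors = FALSE)
  attr(out, "nitrogen_preclip") <- preclip
  attr(out, "nitrogen_surface") <- surf
  out
}

#' Write a rendered scene to disk
#'
#' Saves the image as an 8-bit RGB PNG and the ground truth as a JSON
#' sidecar (`<stem>.json`) with the mask stored separately as a 0/255 PNG.
#'
#' @param scene output of [render_scene()].
#' @param stem file path without extension.
#' @return invisibly, the paths written.
#' @export
write_scene <- function(scene, stem) {
  img_path <- paste0(stem, ".png")
  mask_path <- paste0(stem, "_mask.png")
  json_path <- paste0(stem, ".json")
  png::writePNG(scene$image / 255, img_path)
  png::writePNG(scene$truth$leaf_mask * 1.0, mask_path)
  tr <- scene$truth
  jsonlite::write_json(
    list(leaf_area_px = tr$leaf_area_px, leaf_area_cm2 = tr$leaf_area_cm2,
         square_pixel_area = tr$square_pixel_area,
         g_channel_mean = tr$g_channel_mean,
         board_square_size_cm = tr$board_square_size_cm),
    json_path, auto_unbox = TRUE, digits = NA)
  invisible(c(img_path, mask_path, json_path))
}

#' Read an RGB image as a 0..255 array
#'
#' @param path PNG file path.
#' @return height x width x 3 numeric array with values in 0..255.
#' @export
read_image <- function(path) {
  a <- png::readPNG(path)
  if (length(dim(a)) == 2) a <- array(rep(a, 3), dim = c(dim(a), 3))
  round(a[, , 1:3, drop = FALSE] * 255)
}
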