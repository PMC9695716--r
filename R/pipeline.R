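#' Adaptive (Wiener-style) image denoising
#'
#' Locally adaptive smoothing applied per channel: within a sliding
#' `window` the local mean and variance are estimated, the noise variance
#' is taken as the mean of the local variances, and each pixel is shrunk
#' towards its local mean in proportion to the estimated local
#' signal-to-noise ratio. Flat regions are smoothed hard, structured
#' regions are preserved.
#'
#' @param image height x width x 3 numeric array, values 0..255.
#' @param window odd window size in pixels (default 5).
#' @return denoised array of the same shape, integer-valued 0..255.
#' @export
denoise <- function(image, window = 5L) {
  if (length(dim(image)) != 3 || dim(image)[3] != 3)
    stop("denoise expects a 3-channel image")
  k <- matrix(1 / (window * window), window, window)
  out <- image
  for (ch in 1:3) {
    x <- image[, , ch]
    m <- as.matrix(EBImage::filter2(x, k, boundary = "replicate"))
    m2 <- as.matrix(EBImage::filter2(x * x, k, boundary = "replicate"))
    v <- pmax(m2 - m * m, 0)
    nu <- mean(v)
    gain <- ifelse(v > 0, pmax(v - nu, 0) / pmax(v, nu), 0)
    out[, , ch] <- m + gain * (x - m)
  }
  round(pmin(pmax(out, 0), 255))
}

disc_brush <- function(radius) {
  EBImage::makeBrush(2L * as.integer(radius) + 1L, shape = "disc")
}

largest_component <- function(mask) {
  lab <- EBImage::bwlabel(mask)
  lab <- as.matrix(lab)
  n <- max(lab)
  if (n == 0) return(list(mask = mask * 0L, id = 0L, n = 0L))
  areas <- tabulate(lab[lab > 0], nbins = n)
  id <- which.max(areas)
  list(mask = matrix(as.integer(lab == id), nrow(mask), ncol(mask)),
       id = id, n = n)
}

#' Segment the leaf from a leaf-on-board image
#'
#' Colour-threshold segmentation by green dominance: a pixel is foreground
#' when its G value exceeds both R and B by `margin` gray levels. When that
#' rule selects nothing, an Otsu threshold on the `G - (R+B)/2` map is
#' tried; the fallback is accepted only if the candidate foreground is
#' actually green-dominant (mean map value above `min_dominance`), so a
#' board with no leaf still fails cleanly. The raw mask is cleaned by
#' morphological opening and closing (disc of radius `disk`), interior
#' holes are filled, and the largest 4-connected component is kept.
#'
#' @param image height x width x 3 numeric array, 0..255.
#' @param margin green-dominance margin in gray levels (default 20).
#' @param disk structuring-element radius in pixels (default 2).
#' @param min_dominance minimum mean green dominance (gray levels) for the
#'   Otsu fallback to be accepted (default 10).
#' @return a `leaf_segmentation` list: `leaf_mask` (0/1 matrix),
#'   `n_components_before_filter`, `selected_component_id`.
#' @export
segment_leaf <- function(image, margin = 20, disk = 2L, min_dominance = 10) {
  if (length(dim(image)) != 3 || dim(image)[3] != 3)
    stop("segment_leaf expects a 3-channel image")
  r <- image[, , 1]; g <- image[, , 2]; b <- image[, , 3]
  fg <- (g > r + margin) & (g > b + margin)
  if (!any(fg)) {
    map <- g - (r + b) / 2
    rng <- range(map)
    if (diff(rng) > 0) {
      norm <- (map - rng[1]) / diff(rng)
      th <- EBImage::otsu(EBImage::Image(norm), range = c(0, 1))
      cand <- norm > th
      if (any(cand) && mean(map[cand]) >= min_dominance) fg <- cand
    }
  }
  if (!any(fg)) stop("no leaf found: no green-dominant pixels")
  m <- matrix(as.integer(fg), nrow(fg), ncol(fg))
  br <- disc_brush(disk)
  m <- as.matrix(EBImage::closing(EBImage::opening(m, br), br))
  m <- as.matrix(EBImage::fillHull(m))
  lc <- largest_component(m)
  if (lc$n == 0) stop("no leaf found: mask empty after morphology")
  structure(list(leaf_mask = lc$mask,
                 n_components_before_filter = lc$n,
                 selected_component_id = lc$id),
            class = "leaf_segmentation")
}

#' Extract a closed one-pixel leaf boundary
#'
#' Gradient-magnitude (Sobel) edge detection with hysteresis thresholds
#' set from percentiles of the non-zero gradient distribution, followed by
#' morphological closing and hole filling. The Sobel response to a sharp
#' edge is two pixels wide (one ring each side of the true contour), so the
#' filled region is eroded by one pixel before the boundary is taken,
#' recovering the object's own inner boundary: foreground pixels with at
#' least one 4-neighbour in the background.
#'
#' @param x a 0/1 mask matrix or a 3-channel image (the G channel is used).
#' @param low_pct,high_pct hysteresis percentiles of the non-zero gradient
#'   magnitudes (defaults 70 and 90).
#' @param disk radius of the closing element (default 2).
#' @return 0/1 matrix marking the closed boundary; all-zero for a uniform
#'   input (no edges is not an error). The filled region is attached as
#'   attribute `"region"`.
#' @export
extract_leaf_edge <- function(x, low_pct = 70, high_pct = 90, disk = 2L) {
  img <- if (length(dim(x)) == 3) x[, , 2] else x
  img <- img * 1.0
  sx <- matrix(c(-1, -2, -1, 0, 0, 0, 1, 2, 1), 3, 3)
  gx <- as.matrix(EBImage::filter2(img, sx, boundary = "replicate"))
  gy <- as.matrix(EBImage::filter2(img, t(sx), boundary = "replicate"))
  mag <- sqrt(gx^2 + gy^2)
  nz <- mag[mag > 1e-9]
  empty <- matrix(0L, nrow(img), ncol(img))
  if (length(nz) == 0) return(structure(empty, region = empty))
  hi <- stats::quantile(nz, high_pct / 100, names = FALSE)
  # cap the weak threshold at half the strong one (classic hysteresis
  # ratio); percentiles alone can collapse on few-valued gradient maps
  lo <- min(stats::quantile(nz, low_pct / 100, names = FALSE), 0.5 * hi)
  weak <- matrix(as.integer(mag >= lo), nrow(img), ncol(img))
  strong <- mag >= hi
  lab <- as.matrix(EBImage::bwlabel(weak))
  keep <- unique(lab[strong & lab > 0])
  band <- matrix(as.integer(lab %in% keep), nrow(img), ncol(img))
  if (!any(band == 1L)) return(structure(empty, region = empty))
  band <- as.matrix(EBImage::closing(band, disc_brush(disk)))
  filled <- as.matrix(EBImage::fillHull(band))
  filled <- matrix(as.integer(filled > 0), nrow(img), ncol(img))
  region <- inner_erode4(filled)
  edge <- region - inner_erode4(region)
  structure(edge, region = region)
}

# erosion with the 4-neighbour cross: a pixel survives iff itself and its
# 4-neighbours are foreground (border pixels treated as having background
# outside, so the mask's rim counts as boundary)
inner_erode4 <- function(m) {
  h <- nrow(m); w <- ncol(m)
  up <- rbind(matrix(0L, 1, w), m[-h, , drop = FALSE])
  dn <- rbind(m[-1, , drop = FALSE], matrix(0L, 1, w))
  lf <- cbind(matrix(0L, h, 1), m[, -w, drop = FALSE])
  rt <- cbind(m[, -1, drop = FALSE], matrix(0L, h, 1))
  matrix(as.integer(m & up & dn & lf & rt), h, w)
}

#' Detect the calibration board and estimate the per-square pixel area
#'
#' Non-leaf pixels are classified into the two board colours by
#' nearest-colour assignment (the two colours are estimated by 2-means on
#' the non-leaf pixels, deterministically initialized at the darkest and
#' brightest of them). Each colour class is labelled into 4-connected
#' components; components touching the image border, smaller than
#' `min_size` pixels, or filling less than 80% of their bounding box
#' (board squares are solid rectangles; noise blobs are ragged) are
#' dropped, and components further than 20% from the median area are
#' discarded as partial (leaf-occluded) squares. The
#' per-square pixel area S2 is the median of the surviving component
#' areas — the quantity that converts pixel counts to physical units.
#'
#' @param image height x width x 3 numeric array, 0..255.
#' @param leaf_mask optional 0/1 matrix of leaf pixels to exclude (dilated
#'   by 2 px internally to suppress mixed border pixels).
#' @param min_size minimum component size in pixels (default 64, the
#'   smallest admissible square).
#' @return a `board_detection` list: `square_pixel_area` (S2),
#'   `n_squares`, `square_areas`, `board_colors` (2x3 matrix).
#' @export
detect_board <- function(image, leaf_mask = NULL, min_size = 64L) {
  if (length(dim(image)) != 3 || dim(image)[3] != 3)
    stop("detect_board expects a 3-channel image")
  h <- dim(image)[1]; w <- dim(image)[2]
  excl <- matrix(0L, h, w)
  if (!is.null(leaf_mask))
    excl <- as.matrix(EBImage::dilate(leaf_mask, disc_brush(2L)))
  pix <- cbind(as.vector(image[, , 1]), as.vector(image[, , 2]),
               as.vector(image[, , 3]))
  keep <- as.vector(excl) == 0
  if (sum(keep) < 2 * min_size) stop("board not detected: too few board pixels")
  bp <- pix[keep, , drop = FALSE]
  lum <- bp %*% c(0.299, 0.587, 0.114)
  init <- rbind(bp[which.max(lum), ], bp[which.min(lum), ])
  if (sum((init[1, ] - init[2, ])^2) < 1e-6)
    stop("board not detected: board colours indistinguishable")
  km <- stats::kmeans(bp, centers = init, iter.max = 30)
  centers <- km$centers

  d1 <- colSums((t(pix) - centers[1, ])^2)
  d2 <- colSums((t(pix) - centers[2, ])^2)
  assign <- matrix(ifelse(d1 <= d2, 1L, 2L), h, w)
  assign[excl == 1L] <- 0L

  areas <- c()
  for (cls in 1:2) {
    m <- matrix(as.integer(assign == cls), h, w)
    lab <- as.matrix(EBImage::bwlabel(m))
    n <- max(lab)
    if (n == 0) next
    border_ids <- unique(c(lab[1, ], lab[h, ], lab[, 1], lab[, w]))
    a <- tabulate(lab[lab > 0], nbins = n)
    ok <- setdiff(which(a >= min_size), border_ids)
    if (length(ok) == 0) next
    # board squares fill their bounding box; ragged noise blobs do not
    inside <- lab %in% ok
    rws <- row(lab)[inside]; cls_ <- col(lab)[inside]; ids <- lab[inside]
    r1 <- tapply(rws, ids, min); r2 <- tapply(rws, ids, max)
    c1 <- tapply(cls_, ids, min); c2 <- tapply(cls_, ids, max)
    fill <- a[as.integer(names(r1))] / ((r2 - r1 + 1) * (c2 - c1 + 1))
    areas <- c(areas, a[as.integer(names(r1))[fill >= 0.8]])
  }
  if (length(areas) >= 4) {
    med <- stats::median(areas)
    areas <- areas[abs(areas - med) <= 0.2 * med]
  }
  if (length(areas) < 4) stop("board not detected: fewer than 4 valid squares")
  structure(list(square_pixel_area = stats::median(areas),
                 n_squares = length(areas),
                 square_areas = areas,
                 board_colors = centers),
            class = "board_detection")
}
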