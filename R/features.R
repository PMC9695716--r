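#' Pixel-count area of a segmented region
#'
#' The leaf's pixel area is the number of foreground pixels in the binary
#' mask — the sum of its 0/1 entries.
#'
#' @param mask binary (0/1) matrix.
#' @return integer pixel count.
#' @export
pixel_area <- function(mask) {
  if (!all(mask %in% c(0, 1))) stop("pixel_area expects a binary 0/1 raster")
  as.integer(sum(mask))
}

#' G-channel mean and variance over the leaf mask
#'
#' The colour feature is the mean of the green channel over the masked
#' (leaf) pixels — equivalently the frequency-weighted mean
#' \eqn{\sum x_i f_i / \sum f_i} over the G-value histogram — together with
#' the population variance of the same pixels. Statistics are computed over
#' the leaf only; including board pixels would swamp the leaf signal.
#'
#' @param image height x width x 3 numeric array, 0..255.
#' @param mask binary matrix selecting the leaf pixels; must be non-empty.
#' @return list with `g_mean` (0..255) and `g_var` (population variance).
#' @export
g_channel_stats <- function(image, mask) {
  if (!all(mask %in% c(0, 1))) stop("mask must be a binary 0/1 raster")
  if (sum(mask) == 0) stop("empty mask: no pixels to average")
  g <- image[, , 2][mask == 1]
  mu <- mean(g)
  list(g_mean = mu, g_var = mean((g - mu)^2))
}

#' Actual-to-pixel scale ratio
#'
#' Ratio of a known physical value to its measurement in pixel units
#' (K = actual / pixel), taken from the calibration board.
#'
#' @param actual_value physical value (e.g. cm).
#' @param pixel_value the corresponding measurement in pixels; must be > 0.
#' @return the scale ratio.
#' @export
scale_ratio <- function(actual_value, pixel_value) {
  if (pixel_value <= 0) stop("pixel_value must be positive")
  actual_value / pixel_value
}

#' Physical size of a feature from the scale ratio
#'
#' Converts a feature measured in board units to physical units:
#' F = K * M, with M the known physical size of a board square.
#'
#' @param scale_ratio scale ratio K (> 0).
#' @param board_size known board square size M (> 0).
#' @return the physical feature size.
#' @export
actual_size <- function(scale_ratio, board_size) {
  if (scale_ratio <= 0 || board_size <= 0)
    stop("scale_ratio and board_size must be positive")
  scale_ratio * board_size
}

#' Area calibration coefficient (cm2 per pixel)
#'
#' Kc = S1 / S2: the physical area of one board square divided by the
#' number of pixels it occupies. A region of A pixels then has physical
#' area A * Kc.
#'
#' @param square_area_cm2 physical area of one board square, S1 (cm2).
#' @param square_pixel_area pixel area of one board square, S2.
#' @return cm2 per pixel.
#' @export
calibration_coefficient <- function(square_area_cm2, square_pixel_area) {
  if (square_area_cm2 <= 0 || square_pixel_area <= 0)
    stop("square areas must be positive")
  square_area_cm2 / square_pixel_area
}

#' Assemble the calibration result for a detected board
#'
#' @param board a `board_detection` from [detect_board()].
#' @param board_square_size_cm physical side length of a square (cm).
#' @return a `calibration_result` list: `scale_ratio` (cm per pixel, K),
#'   `board_square_size_cm` (M), `board_pixel_value` (L, square side in
#'   px), `square_area_cm2` (S1), `square_pixel_area` (S2),
#'   `area_coeff_cm2_per_px` (Kc).
#' @export
calibration_result <- function(board, board_square_size_cm = 1.0) {
  s2 <- board$square_pixel_area
  l <- sqrt(s2)
  s1 <- board_square_size_cm^2
  structure(list(scale_ratio = scale_ratio(board_square_size_cm, l),
                 board_square_size_cm = board_square_size_cm,
                 board_pixel_value = l,
                 square_area_cm2 = s1,
                 square_pixel_area = s2,
                 area_coeff_cm2_per_px = calibration_coefficient(s1, s2)),
            class = "calibration_result")
}

#' Extract the feature record for one sample
#'
#' Combines segmentation and board calibration into one row of features:
#' pixel area, physical area (pixel area times the cm2-per-pixel
#' coefficient), and G-channel mean/variance over the leaf.
#'
#' @param image height x width x 3 numeric array, 0..255.
#' @param segmentation a `leaf_segmentation` from [segment_leaf()].
#' @param board a `board_detection` from [detect_board()].
#' @param board_square_size_cm physical square size M (cm), default 1.
#' @param sample_id sample identifier string.
#' @param stage `"growing"` or `"mature"`.
#' @param nitrogen_gkg optional measured nitrogen (g/kg).
#' @return one-row data.frame: `sample_id, stage, area_px, area_cm2,
#'   g_mean, g_var, nitrogen_gkg`.
#' @export
extract_features <- function(image, segmentation, board,
                             board_square_size_cm = 1.0,
                             sample_id = "sample", stage = "growing",
                             nitrogen_gkg = NA_real_) {
  mask <- segmentation$leaf_mask
  a_px <- pixel_area(mask)
  cal <- calibration_result(board, board_square_size_cm)
  gs <- g_channel_stats(image, mask)
  data.frame(sample_id = sample_id, stage = stage,
             area_px = a_px,
             area_cm2 = a_px * cal$area_coeff_cm2_per_px,
             g_mean = gs$g_mean, g_var = gs$g_var,
             nitrogen_gkg = nitrogen_gkg,
             stringsAsFactors = FALSE)
}
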