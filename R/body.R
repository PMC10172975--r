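#' Weighted least-squares line fit
#'
#' Closed-form weighted linear regression minimising
#' `sum(w * (y - a - b x)^2)`.
#'
#' @param xs,ys Numeric vectors of equal length.
#' @param ws Non-negative weights (default all 1).
#' @return List with `slope` and `intercept`.
#' @export
weighted_linear_slope <- function(xs, ys, ws = rep(1, length(xs))) {
  if (length(xs) != length(ys) || length(xs) != length(ws)) {
    stop("xs, ys and ws must have equal length")
  }
  if (any(ws < 0)) stop("weights must be non-negative")
  keep <- ws > 0 & !is.na(xs) & !is.na(ys)
  x <- xs[keep]; y <- ys[keep]; w <- ws[keep]
  if (length(x) < 2 || length(unique(x)) < 2) {
    stop("degenerate regression: need >= 2 positively weighted points ",
         "with distinct x")
  }
  sw <- sum(w)
  xb <- sum(w * x) / sw
  yb <- sum(w * y) / sw
  sxx <- sum(w * (x - xb)^2)
  if (sxx == 0) stop("degenerate regression: zero weighted x variance")
  slope <- sum(w * (x - xb) * (y - yb)) / sxx
  list(slope = slope, intercept = yb - slope * xb)
}

#' Body-weight rate of change over a period
#'
#' Fits per-frame body-weight estimates against recording time by weighted
#' linear regression, using the per-frame confidence weights, and returns
#' the slope in grams per day.
#'
#' @param ch A `weight` [channel()].
#' @param period One row of a [derive_periods()] table.
#' @return Slope in g/day, or a missing value when the regression is
#'   degenerate (no positively weighted samples, or a single time point).
#' @export
weight_rate_of_change <- function(ch, period) {
  stopifnot(inherits(ch, "cage_channel"), ch$kind == "weight")
  ch <- clip_channel(ch, period$start, period$end)
  s <- ch$samples
  if (nrow(s) < 2) return(missing_value("fewer than 2 weight samples"))
  x_days <- (as.numeric(s$time) - as.numeric(period$start)) / 86400
  fit <- tryCatch(weighted_linear_slope(x_days, s$grams, s$weight_w),
                  error = function(e) NULL)
  if (is.null(fit)) return(missing_value("degenerate weight regression"))
  fit$slope
}

# 3x3 Sobel gradient magnitudes on the interior of a grayscale matrix,
# vectorised via shifted submatrices.  Rows index y (downward), columns x.
sobel_magnitude <- function(img) {
  nr <- nrow(img); nc <- ncol(img)
  ri <- 2:(nr - 1); ci <- 2:(nc - 1)
  sh <- function(dr, dc) img[ri + dr, ci + dc, drop = FALSE]
  gx <- (sh(-1, 1) + 2 * sh(0, 1) + sh(1, 1)) -
        (sh(-1, -1) + 2 * sh(0, -1) + sh(1, -1))
  gy <- (sh(1, -1) + 2 * sh(1, 0) + sh(1, 1)) -
        (sh(-1, -1) + 2 * sh(-1, 0) + sh(-1, 1))
  sqrt(gx^2 + gy^2)
}

#' Sobel-gradient roughness over a masked region
#'
#' Coat condition is summarised as image roughness: the mean Sobel
#' gradient magnitude `sqrt(Gx^2 + Gy^2)` (standard 3x3 kernels) over the
#' masked pixels of a grayscale image. The one-pixel image border is
#' excluded so every contributing pixel has a full 3x3 neighbourhood; no
#' padding is applied.
#'
#' @param img Numeric matrix of intensities (e.g. 0-255 grayscale).
#' @param mask Logical matrix of the same shape; `TRUE` marks mouse
#'   pixels.
#' @return Mean gradient magnitude (>= 0) over the masked interior.
#' @export
sobel_roughness <- function(img, mask) {
  if (!is.matrix(img) || !is.numeric(img)) stop("img must be a numeric matrix")
  if (!is.matrix(mask) || !is.logical(mask)) {
    stop("mask must be a logical matrix")
  }
  if (!all(dim(img) == dim(mask))) stop("img and mask shapes differ")
  if (nrow(img) < 3 || ncol(img) < 3) stop("image too small for 3x3 Sobel")
  inner <- mask[2:(nrow(mask) - 1), 2:(ncol(mask) - 1), drop = FALSE]
  if (!any(inner)) stop("mask has no interior pixels")
  mag <- sobel_magnitude(img)
  mean(mag[inner])
}

#' Read a grayscale image and mask pair from PNG files
#'
#' Convenience loader for applying [sobel_roughness()] to stored rasters.
#' RGB images are converted to grayscale by channel averaging; mask pixels
#' with value > 0.5 are treated as mouse.
#'
#' @param img_path,mask_path PNG file paths.
#' @return List with `img` (numeric matrix, 0-255) and `mask` (logical
#'   matrix).
#' @export
read_masked_image <- function(img_path, mask_path) {
  if (!requireNamespace("png", quietly = TRUE)) {
    stop("the 'png' package is required to read PNG images")
  }
  to_gray <- function(a) {
    if (length(dim(a)) == 3) a <- apply(a[, , 1:min(3, dim(a)[3])], c(1, 2), mean)
    a * 255
  }
  img <- to_gray(png::readPNG(img_path))
  m <- png::readPNG(mask_path)
  if (length(dim(m)) == 3) m <- m[, , 1]
  list(img = img, mask = m > 0.5)
}

#' Coat-roughness summary for a period
#'
#' Per-frame roughness values within the period are summarised by their
#' median, a summary insensitive to occasional segmentation failures.
#'
#' @param ch A `coat` [channel()].
#' @param period One row of a [derive_periods()] table.
#' @param min_samples Minimum sample count. Default 100.
#' @return Median roughness, or a missing value when too few samples fall
#'   in the period.
#' @export
coat_metric <- function(ch, period, min_samples = 100) {
  stopifnot(inherits(ch, "cage_channel"), ch$kind == "coat")
  ch <- clip_channel(ch, period$start, period$end)
  r <- ch$samples$roughness
  if (length(r) < min_samples) {
    return(missing_value(sprintf("only %d coat samples (need %d)",
                                 length(r), min_samples)))
  }
  stats::median(r)
}
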