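#' Binary outline images
#'
#' Genital outlines are handled as logical matrices (`TRUE` = foreground
#' outline pixel). [read_outline_image()] loads PNG or TIFF, collapses to
#' grayscale, and thresholds at 50% of the intensity range (configurable).
#'
#' @param path PNG or TIFF file.
#' @param threshold Binarization threshold as a fraction of the intensity
#'   range (default 0.5).
#' @param foreground `"dark"` if the outline is darker than the background
#'   (the usual ink-on-white tracing), `"light"` otherwise.
#' @return Logical matrix (rows x cols) of class `outline_image`.
#' @export
read_outline_image <- function(path, threshold = 0.5,
                               foreground = c("dark", "light")) {
  foreground <- match.arg(foreground)
  if (!file.exists(path)) stop("image file not found: ", path)
  ext <- tolower(tools::file_ext(path))
  arr <- switch(ext,
    png = png::readPNG(path),
    tif = ,
    tiff = tiff::readTIFF(path),
    stop("unsupported image format '.", ext, "' (need PNG or TIFF)")
  )
  if (length(dim(arr)) == 3L)
    arr <- apply(arr[, , seq_len(min(3L, dim(arr)[3L])), drop = FALSE],
                 c(1L, 2L), mean)
  rng <- range(arr)
  cut <- rng[1L] + threshold * (rng[2L] - rng[1L])
  img <- if (foreground == "dark") arr <= cut else arr >= cut
  as_outline_image(img)
}

#' @rdname read_outline_image
#' @param img A logical (or 0/1 numeric) matrix.
#' @export
as_outline_image <- function(img) {
  if (!is.matrix(img)) stop("expected a matrix")
  img <- img > 0
  if (!any(img)) stop("image has no foreground pixels")
  structure(img, class = c("outline_image", class(unclass(img))))
}

#' Standardize an outline to a fixed canvas and span
#'
#' Rescales the foreground so its vertical (base-to-apex) extent equals
#' `target_span` pixels, preserving aspect ratio, and centers it on a
#' square canvas of `target_canvas` pixels — the standard acquisition
#' geometry (2,100 px canvas, 2,000 px span) under which fractal dimensions
#' are comparable across species. Resampling is nearest-neighbour so the
#' output stays strictly binary.
#'
#' @param img An `outline_image` (or binarizable matrix).
#' @param target_canvas Canvas side in pixels (default 2100).
#' @param target_span Base-to-apex extent in pixels (default 2000).
#' @return An `outline_image` of size `target_canvas` x `target_canvas`.
#' @export
standardize_image <- function(img, target_canvas = 2100L,
                              target_span = 2000L) {
  img <- as_outline_image(img)
  if (target_span > target_canvas)
    stop("target_span must not exceed target_canvas")
  idx <- which(img, arr.ind = TRUE)
  r0 <- range(idx[, 1L]); c0 <- range(idx[, 2L])
  span <- r0[2L] - r0[1L] + 1L
  scale <- target_span / span
  h <- max(1L, as.integer(round(span * scale)))
  w <- max(1L, as.integer(round((c0[2L] - c0[1L] + 1L) * scale)))
  if (w > target_canvas)
    stop("shape wider than tall by more than the canvas/span ratio; ",
         "cannot fit the canvas at this span")
  # nearest-neighbour resample of the cropped bounding box
  crop <- img[r0[1L]:r0[2L], c0[1L]:c0[2L], drop = FALSE]
  src_r <- pmin(nrow(crop), pmax(1L, ceiling((seq_len(h) - 0.5) / scale)))
  src_c <- pmin(ncol(crop), pmax(1L, ceiling((seq_len(w) - 0.5) / scale)))
  resized <- crop[src_r, src_c, drop = FALSE]
  out <- matrix(FALSE, target_canvas, target_canvas)
  ro <- (target_canvas - h) %/% 2L
  co <- (target_canvas - w) %/% 2L
  out[ro + seq_len(h), co + seq_len(w)] <- resized
  as_outline_image(out)
}

#' Box counts over a set of scales
#'
#' For each box size s, overlays an origin-anchored grid of s x s cells and
#' counts cells containing at least one foreground pixel.
#'
#' @param img An `outline_image`.
#' @param box_sizes Strictly increasing integer sizes, each >= 1 and <=
#'   half the smaller canvas dimension.
#' @return data frame with columns `size` and `count`.
#' @export
box_count <- function(img, box_sizes) {
  img <- as_outline_image(img)
  box_sizes <- as.integer(box_sizes)
  if (any(box_sizes < 1L) || any(box_sizes > min(dim(img)) %/% 2L))
    stop("box sizes must be in [1, canvas/2]")
  if (is.unsorted(box_sizes, strictly = TRUE))
    stop("box sizes must be strictly increasing")
  idx <- which(img, arr.ind = TRUE)
  counts <- vapply(box_sizes, function(s) {
    cell <- (idx[, 1L] - 1L) %/% s * (1L + (dim(img)[2L] - 1L) %/% s) +
      (idx[, 2L] - 1L) %/% s
    length(unique(cell))
  }, integer(1))
  data.frame(size = box_sizes, count = counts)
}

#' Minkowski (box-counting) fractal dimension
#'
#' Estimates the fractal dimension of a binary outline as the absolute
#' slope of the ordinary least-squares fit of log(count) against log(box
#' size), over box sizes that are powers of two from 2 up to a quarter of
#' the canvas. For planar outlines the dimension lies in [1, 2]: 1 for
#' smooth curves, 2 for filled regions, intermediate for convoluted
#' (fractal-like) outlines — the complexity axis used for genital shape.
#'
#' @param img An `outline_image`.
#' @param box_sizes Optional explicit schedule; default powers of 2 in
#'   `[2, canvas/4]`.
#' @return Object of class `fractal_estimate`: `dimension`, `r2` (fit),
#'   `scales` (the size/count table), `n_scales`.
#' @export
fractal_dimension <- function(img, box_sizes = NULL) {
  img <- as_outline_image(img)
  idx <- which(img, arr.ind = TRUE)
  fg_span <- max(diff(range(idx[, 1L])), diff(range(idx[, 2L]))) + 1L
  if (fg_span < 32L)
    stop("foreground spans ", fg_span, " px; need >= 32 for a stable fit")
  if (is.null(box_sizes)) {
    smax <- min(dim(img)) %/% 4L
    box_sizes <- 2^(1:floor(log2(smax)))
  }
  if (length(box_sizes) < 4L)
    stop("need at least 4 usable scales, got ", length(box_sizes))
  bc <- box_count(img, box_sizes)
  fit <- stats::lm(log(count) ~ log(size), data = bc)
  structure(list(
    dimension = abs(unname(stats::coef(fit)[2L])),
    r2 = summary(fit)$r.squared,
    scales = bc,
    n_scales = nrow(bc)
  ), class = "fractal_estimate")
}

#' @export
print.fractal_estimate <- function(x, ...) {
  cat(sprintf("Box-counting fractal dimension %.4f (fit R^2 %.4f, %d scales)\n",
              x$dimension, x$r2, x$n_scales))
  invisible(x)
}

#' Perimeter-per-length genital complexity
#'
#' Standardizes a traced aedeagus perimeter by the aedeagus length, giving
#' complexity per unit length (dimensionless; a circle's outline against
#' its diameter gives pi).
#'
#' @param perimeter,aedeagus_length Positive lengths in the same unit (mm).
#' @return perimeter / length.
#' @export
perimeter_complexity <- function(perimeter, aedeagus_length) {
  if (any(perimeter <= 0) || any(aedeagus_length <= 0))
    stop("perimeter and length must be positive")
  perimeter / aedeagus_length
}
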