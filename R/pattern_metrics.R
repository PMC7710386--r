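#' Binary pattern container
#'
#' @param pigmented Logical (or 0/1) matrix, `TRUE` for pigmented pixels.
#' @param polarity `"dark_on_light"` or `"light_on_dark"`; bookkeeping for
#'   how the pigmented phase relates to image intensity.
#' @return A `binary_pattern` (logical matrix with a polarity attribute).
#' @export
binary_pattern <- function(pigmented, polarity = "dark_on_light") {
  m <- as.matrix(pigmented)
  if (!is.logical(m)) {
    if (!all(m %in% c(0, 1)))
      stop("pigmented must be logical or 0/1")
    m <- m > 0
  }
  structure(m, polarity = polarity, class = c("binary_pattern", "matrix"))
}

# Otsu's threshold: maximize between-class variance over histogram bins.
otsu_threshold <- function(gray, n_breaks = 256) {
  rng <- range(gray)
  if (diff(rng) < .Machine$double.eps^0.5)
    stop("flat image: Otsu threshold is undefined")
  breaks <- seq(rng[1], rng[2], length.out = n_breaks + 1)
  h <- tabulate(findInterval(gray, breaks, rightmost.closed = TRUE),
                nbins = n_breaks)
  mids <- (breaks[-1] + breaks[-length(breaks)]) / 2
  w1 <- cumsum(h)
  w2 <- sum(h) - w1
  m1 <- cumsum(h * mids) / w1
  m2 <- (sum(h * mids) - cumsum(h * mids)) / w2
  bcv <- w1 * w2 * (m1 - m2)^2
  bcv[!is.finite(bcv)] <- -Inf
  breaks[which.max(bcv) + 1L]
}

#' Binarize a grayscale image
#'
#' @param gray Single-channel intensity matrix.
#' @param method `"otsu"` (between-class variance maximization) or
#'   `"fixed"`.
#' @param threshold Threshold for `method = "fixed"`.
#' @param pigment Which side of the threshold is pigment: `"above"` (the
#'   default, matching [binarize_field()] where high `u` concentration is
#'   pigment) or `"below"` (dark markings in a photograph).
#' @return A [binary_pattern()].
#' @export
binarize_image <- function(gray, method = c("otsu", "fixed"),
                           threshold = NULL, pigment = c("above", "below")) {
  method <- match.arg(method)
  pigment <- match.arg(pigment)
  gray <- as.matrix(gray)
  thr <- if (method == "fixed") {
    if (is.null(threshold)) stop("fixed method needs a threshold")
    threshold
  } else otsu_threshold(gray)
  pig <- if (pigment == "above") gray > thr else gray < thr
  binary_pattern(pig, polarity = if (pigment == "below")
    "dark_on_light" else "light_on_dark")
}

# Circular moving average over the vertices of a closed polygon. Removes
# the half-pixel staircase of binary marching squares (which inflates the
# perimeter by ~5%) without changing contour topology; enclosed area is
# preserved to a fraction of a percent. The window is capped for very short
# contours so a polygon can never collapse to its centroid.
smooth_closed_polygon <- function(x, y, window = 2) {
  k <- length(x)
  w <- min(window, floor((k - 1) / 4))
  if (w < 1) return(list(x = x, y = y))
  kern <- rep(1 / (2 * w + 1), 2 * w + 1)
  list(x = as.numeric(stats::filter(x, kern, circular = TRUE)),
       y = as.numeric(stats::filter(y, kern, circular = TRUE)))
}

shoelace_area <- function(x, y) {
  n <- length(x)
  j <- c(n, seq_len(n - 1))
  abs(sum(x[j] * y - x * y[j])) / 2
}

polygon_perimeter <- function(x, y) {
  n <- length(x)
  j <- c(2:n, 1)
  sum(sqrt((x[j] - x)^2 + (y[j] - y)^2))
}

#' Build a pattern element from a closed polygon
#'
#' Computes area `S` (shoelace formula), perimeter `L` and isoperimetric
#' quotient `Q = 4 pi S / L^2` of a closed contour given as vertex
#' coordinates (last vertex implicitly joined to the first).
#'
#' @param x,y Vertex coordinates.
#' @return A `pattern_element` list with `S`, `L`, `Q` and the vertices.
#' @export
polygon_element <- function(x, y) {
  stopifnot(length(x) == length(y), length(x) >= 3)
  S <- shoelace_area(x, y)
  L <- polygon_perimeter(x, y)
  if (S <= 0 || L <= 0) stop("degenerate contour")
  structure(list(S = S, L = L, Q = 4 * pi * S / L^2, x = x, y = y),
            class = "pattern_element")
}

#' Extract pattern elements from a binary pattern
#'
#' Traces the 0.5-level isolines of the pigmented mask with a
#' marching-squares style contour tracer (sub-pixel vertices), yielding one
#' closed polygon per boundary. Outer boundaries and hole boundaries are
#' separate, independent elements, which treats dark-spot and light-spot
#' patterns symmetrically under polarity inversion. Each traced polygon is
#' then smoothed by a short circular moving average of its vertices, which
#' removes the half-pixel staircase bias of the raw trace (the staircase
#' inflates perimeters by about 5%); with the default window the
#' isoperimetric quotient of a rasterized disk of radius 50 px is within
#' 1% of 1, and the enclosed area changes by well under 1%. Elements
#' smaller than `min_area` square pixels are discarded as digitization
#' specks.
#'
#' @param bp A [binary_pattern()] (or logical matrix).
#' @param min_area Minimum element area in pixels squared.
#' @param smooth_window Half-width of the vertex moving average (0 = raw
#'   staircase trace).
#' @return List of `pattern_element`s.
#' @export
extract_elements <- function(bp, min_area = 9, smooth_window = 2) {
  m <- as.matrix(bp) * 1
  if (sum(m) == 0) stop("no pigmented pixels: no elements to extract")
  pad <- matrix(0, nrow(m) + 2, ncol(m) + 2)
  pad[2:(nrow(m) + 1), 2:(ncol(m) + 1)] <- m
  cl <- grDevices::contourLines(x = seq_len(nrow(pad)),
                                y = seq_len(ncol(pad)),
                                z = pad, levels = 0.5)
  els <- lapply(cl, function(cc) {
    if (length(cc$x) < 3) return(NULL)
    sm <- smooth_closed_polygon(cc$x, cc$y, smooth_window)
    polygon_element(sm$x, sm$y)
  })
  els <- Filter(function(e) !is.null(e) && e$S >= min_area, els)
  if (length(els) == 0)
    stop("no pattern element at or above min_area")
  els
}

#' Area-weighted pattern complexity score
#'
#' `PCS = 1 - sum_i w_i Q_i`, where `Q_i = 4 pi S_i / L_i^2` is the
#' isoperimetric quotient (circularity) of element `i` and
#' `w_i = S_i / sum_i S_i` its area weight. The score is 0 for a single
#' circle and grows toward 1 as the area-dominant elements become elongated
#' or convoluted; area weighting makes the score track the elements that
#' dominate the visual impression of the pattern.
#'
#' @param elements List of `pattern_element`s (see [extract_elements()],
#'   [polygon_element()]).
#' @return Numeric scalar in `[0, 1)` (up to discretization error).
#' @export
pattern_complexity <- function(elements) {
  if (length(elements) == 0) stop("no elements")
  S <- vapply(elements, `[[`, numeric(1), "S")
  Q <- vapply(elements, `[[`, numeric(1), "Q")
  if (sum(S) <= 0) stop("zero total area")
  w <- S / sum(S)
  1 - sum(w * Q)
}

#' Quantify a binary pattern
#'
#' Computes the two indicators used throughout the package: pattern
#' lightness (fraction of unpigmented pixels) and the pattern complexity
#' score ([pattern_complexity()]), together with the element count. Applied
#' identically to binarized photographs and to binarized simulation grids.
#'
#' @param bp A [binary_pattern()] (or logical matrix).
#' @param min_area Passed to [extract_elements()].
#' @return A list with `lightness`, `pcs`, `n_elements`.
#' @export
quantify <- function(bp, min_area = 9) {
  m <- as.matrix(bp) > 0
  lightness <- mean(!m)
  if (all(m) || !any(m))
    stop(sprintf("degenerate pattern (lightness %.1f): PCS undefined",
                 lightness))
  els <- extract_elements(bp, min_area = min_area)
  list(lightness = lightness, pcs = pattern_complexity(els),
       n_elements = length(els))
}

#' Read a grayscale image from a PNG file
#'
#' @param path PNG file; color channels are averaged.
#' @return An intensity matrix in `[0, 1]`.
#' @export
read_gray_image <- function(path) {
  if (!requireNamespace("png", quietly = TRUE))
    stop("reading PNG images requires the 'png' package")
  a <- png::readPNG(path)
  if (length(dim(a)) == 3) a <- apply(a[, , 1:min(3, dim(a)[3]), drop = FALSE],
                                      c(1, 2), mean)
  a
}

#' Write a matrix as an 8-bit grayscale PNG
#'
#' @param m Numeric matrix; rescaled to `[0, 1]` unless already within it.
#' @param path Output file.
#' @export
write_gray_png <- function(m, path) {
  if (!requireNamespace("png", quietly = TRUE))
    stop("writing PNG images requires the 'png' package")
  rng <- range(m)
  if (rng[1] < 0 || rng[2] > 1)
    m <- (m - rng[1]) / max(rng[2] - rng[1], .Machine$double.eps)
  png::writePNG(m, path)
  invisible(path)
}
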