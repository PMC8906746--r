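#' HSV image container
#'
#' Per-pixel hue (circular, in [0, 1)), saturation and value in [0, 1].
#'
#' @param h,s,v numeric matrices of equal dimension.
#' @return object of class \code{hsv_image}.
#' @export
hsv_image <- function(h, s, v) {
  stopifnot(is.matrix(h), identical(dim(h), dim(s)), identical(dim(h), dim(v)),
            all(h >= 0 & h < 1 + 1e-12), all(s >= -1e-12 & s <= 1 + 1e-12),
            all(v >= -1e-12 & v <= 1 + 1e-12))
  structure(list(h = h %% 1, s = pmin(pmax(s, 0), 1),
                 v = pmin(pmax(v, 0), 1)), class = "hsv_image")
}

#' Color classification configuration
#'
#' The study's calibrated HSV ranges: red hue in [0, 0.045] or [0.98, 1],
#' blue hue in [0.6, 0.728], black as value in [0, 0.3]; pixels must exceed
#' \code{min_value} in value to receive a hue class (black takes
#' precedence). No saturation gate is applied by default.
#'
#' @param red two-row matrix of hue ranges.
#' @param blue hue range.
#' @param black_v value range classified as black.
#' @param min_value minimum value for hue classification.
#' @return object of class \code{color_class_config}.
#' @export
color_class_config <- function(red = rbind(c(0, 0.045), c(0.98, 1)),
                               blue = c(0.6, 0.728),
                               black_v = c(0, 0.3), min_value = 0.3) {
  stopifnot(all(red >= 0 & red <= 1), all(blue >= 0 & blue <= 1),
            all(black_v >= 0 & black_v <= 1))
  structure(list(red = red, blue = blue, black_v = black_v,
                 min_value = min_value), class = "color_class_config")
}

in_ranges <- function(x, ranges) {
  if (is.null(dim(ranges))) ranges <- matrix(ranges, nrow = 1)
  out <- matrix(FALSE, nrow(x), ncol(x))
  for (r in seq_len(nrow(ranges)))
    out <- out | (x >= ranges[r, 1] & x <= ranges[r, 2])
  out
}

#' Classify pixels into red / blue / black / other
#'
#' Black if value is within the black range (precedence over hue classes);
#' otherwise red or blue by hue-range membership; otherwise other.
#'
#' @param image an \code{\link{hsv_image}} (calibrated).
#' @param config a \code{\link{color_class_config}}.
#' @return character matrix of labels.
#' @export
classify_pixels <- function(image, config = color_class_config()) {
  stopifnot(inherits(image, "hsv_image"))
  lab <- matrix("other", nrow(image$v), ncol(image$v))
  hueable <- image$v > config$min_value
  lab[hueable & in_ranges(image$h, config$red)] <- "red"
  lab[hueable & in_ranges(image$h, config$blue)] <- "blue"
  black <- image$v >= config$black_v[1] & image$v <= config$black_v[2]
  lab[black] <- "black"
  lab
}

# HSV -> linear RGB (h in [0,1)), vectorized.
hsv_to_rgb <- function(h, s, v) {
  h6 <- (h %% 1) * 6
  i <- floor(h6)
  f <- h6 - i
  p <- v * (1 - s); q <- v * (1 - s * f); t <- v * (1 - s * (1 - f))
  r <- ifelse(i == 0, v, ifelse(i == 1, q, ifelse(i == 2, p,
       ifelse(i == 3, p, ifelse(i == 4, t, v)))))
  g <- ifelse(i == 0, t, ifelse(i == 1, v, ifelse(i == 2, v,
       ifelse(i == 3, q, ifelse(i == 4, p, p)))))
  b <- ifelse(i == 0, p, ifelse(i == 1, p, ifelse(i == 2, t,
       ifelse(i == 3, v, ifelse(i == 4, v, q)))))
  cbind(r = as.vector(r), g = as.vector(g), b = as.vector(b))
}

rgb_to_hsv <- function(rgb) {
  rgb <- pmin(pmax(rgb, 0), 1)
  hsv <- t(grDevices::rgb2hsv(t(rgb), maxColorValue = 1))
  colnames(hsv) <- c("h", "s", "v")
  hsv
}

#' Color calibration from reference patches
#'
#' Fits, in linear RGB space, the least-squares affine transform (3x3
#' matrix plus offset) mapping the observed mean colors of the calibration
#' card patches onto their reference values.
#'
#' @param observed n x 3 matrix of observed patch colors (HSV rows), n >= 4.
#' @param reference n x 3 matrix of reference patch colors (HSV rows).
#' @return object of class \code{color_transform}: list(M, offset,
#'   residuals, rmse).
#' @export
calibrate_colors <- function(observed, reference) {
  observed <- as.matrix(observed); reference <- as.matrix(reference)
  stopifnot(ncol(observed) == 3, ncol(reference) == 3,
            nrow(observed) == nrow(reference))
  if (nrow(observed) < 4) stop("need at least 4 patch pairs (underdetermined)")
  obs_rgb <- hsv_to_rgb(observed[, 1], observed[, 2], observed[, 3])
  ref_rgb <- hsv_to_rgb(reference[, 1], reference[, 2], reference[, 3])
  X <- cbind(1, obs_rgb)
  if (qr(X)$rank < 4) stop("rank-deficient patch set")
  coef <- qr.solve(X, ref_rgb)
  fitted <- X %*% coef
  structure(list(M = coef[-1, , drop = FALSE], offset = coef[1, ],
                 residuals = ref_rgb - fitted,
                 rmse = sqrt(mean((ref_rgb - fitted)^2))),
            class = "color_transform")
}

#' Apply a color transform to an HSV image
#'
#' @param image an \code{\link{hsv_image}}.
#' @param transform a \code{\link{calibrate_colors}} result.
#' @return the corrected \code{hsv_image}.
#' @export
apply_calibration <- function(image, transform) {
  stopifnot(inherits(image, "hsv_image"), inherits(transform, "color_transform"))
  rgb <- hsv_to_rgb(image$h, image$s, image$v)
  corrected <- sweep(rgb %*% transform$M, 2, transform$offset, "+")
  hsv <- rgb_to_hsv(corrected)
  dims <- dim(image$h)
  hsv_image(matrix(hsv[, "h"], dims[1], dims[2]),
            matrix(hsv[, "s"], dims[1], dims[2]),
            matrix(hsv[, "v"], dims[1], dims[2]))
}

circular_mean_hue <- function(h) {
  if (!length(h)) return(NA_real_)
  ang <- atan2(mean(sin(2 * pi * h)), mean(cos(2 * pi * h))) / (2 * pi)
  ang %% 1
}

#' Per-region color statistics
#'
#' For each labelled anatomical region (background excluded): the
#' proportion of pixels classified red, blue, black and other, plus the
#' circular mean hue and the mean saturation and value of the red and of
#' the blue pixels. Regions with no pixels of a class report NA summaries.
#'
#' @param image an \code{\link{hsv_image}}.
#' @param mask integer matrix of region labels (0 = background), same shape
#'   as the image.
#' @param config a \code{\link{color_class_config}}.
#' @param region_names optional named translation of label integers.
#' @return data.frame: one row per region with proportions and class
#'   summaries.
#' @export
region_color_stats <- function(image, mask, config = color_class_config(),
                               region_names = NULL) {
  stopifnot(identical(dim(mask), dim(image$h)))
  labels <- classify_pixels(image, config)
  regions <- sort(setdiff(unique(as.vector(mask)), 0))
  rows <- lapply(regions, function(rg) {
    px <- mask == rg
    n <- sum(px)
    cls <- labels[px]
    prop <- vapply(c("red", "blue", "black", "other"),
                   function(cl) if (n > 0) mean(cls == cl) else NA_real_, 0)
    summ <- lapply(c(red = "red", blue = "blue"), function(cl) {
      sel <- px & labels == cl
      if (!sum(sel)) return(c(hue = NA_real_, sat = NA_real_, val = NA_real_))
      c(hue = circular_mean_hue(image$h[sel]),
        sat = mean(image$s[sel]), val = mean(image$v[sel]))
    })
    nm <- if (!is.null(region_names) && as.character(rg) %in% names(region_names))
      region_names[[as.character(rg)]] else as.character(rg)
    data.frame(region = nm, n_pixels = n,
               prop_red = prop[["red"]], prop_blue = prop[["blue"]],
               prop_black = prop[["black"]], prop_other = prop[["other"]],
               red_hue = summ$red[["hue"]], red_sat = summ$red[["sat"]],
               red_val = summ$red[["val"]],
               blue_hue = summ$blue[["hue"]], blue_sat = summ$blue[["sat"]],
               blue_val = summ$blue[["val"]],
               empty = n == 0, stringsAsFactors = FALSE)
  })
  do.call(rbind, c(rows, make.row.names = FALSE))
}

#' Synthetic HSV fixture with known region colors
#'
#' Builds an image of horizontal region bands, each filled with a
#' prototype color of its assigned class, plus optional Gaussian HSV noise
#' (hue wrapped circularly). Ground-truth class proportions per region are
#' returned for recovery tests.
#'
#' @param regions named list: region name -> list(class, h, s, v, rows)
#'   where class is one of red/blue/black/other and rows the band height in
#'   pixels.
#' @param width image width in pixels.
#' @param noise SD of the additive noise on each channel.
#' @param seed integer seed (fixture is bit-identical given the seed).
#' @return list with \code{image}, \code{mask}, \code{region_names},
#'   \code{truth} (data.frame region, class, proportion).
#' @export
make_color_fixture <- function(regions = default_fixture_regions(),
                               width = 40, noise = 0, seed = 1L) {
  heights <- vapply(regions, function(r) r$rows, 0L)
  total <- sum(heights)
  h <- s <- v <- matrix(0, total, width)
  mask <- matrix(0L, total, width)
  at <- 0L
  for (i in seq_along(regions)) {
    r <- regions[[i]]
    rowsel <- at + seq_len(r$rows)
    h[rowsel, ] <- r$h; s[rowsel, ] <- r$s; v[rowsel, ] <- r$v
    mask[rowsel, ] <- i
    at <- at + r$rows
  }
  if (noise > 0) {
    with_seed(seed, {
      h <- (h + matrix(stats::rnorm(length(h), 0, noise), total, width)) %% 1
      s <- pmin(pmax(s + matrix(stats::rnorm(length(s), 0, noise),
                                total, width), 0), 1)
      v <- pmin(pmax(v + matrix(stats::rnorm(length(v), 0, noise),
                                total, width), 0), 1)
    })
  }
  truth <- data.frame(region = names(regions),
                      class = vapply(regions, function(r) r$class, ""),
                      proportion = 1, stringsAsFactors = FALSE)
  list(image = hsv_image(h, s, v), mask = mask,
       region_names = stats::setNames(as.list(names(regions)),
                                      as.character(seq_along(regions))),
       truth = truth)
}

#' Default anatomical fixture layout
#' @return named list of region color specs for
#'   \code{\link{make_color_fixture}}.
#' @export
default_fixture_regions <- function() {
  list(
    anal_fin   = list(class = "red",   h = 0.02, s = 0.85, v = 0.75, rows = 8L),
    caudal_fin = list(class = "red",   h = 0.99, s = 0.80, v = 0.70, rows = 8L),
    dorsal_fin = list(class = "blue",  h = 0.66, s = 0.80, v = 0.70, rows = 8L),
    body_side  = list(class = "blue",  h = 0.62, s = 0.75, v = 0.65, rows = 8L),
    head       = list(class = "black", h = 0.50, s = 0.30, v = 0.12, rows = 8L)
  )
}
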