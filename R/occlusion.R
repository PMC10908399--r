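#' Occlusion sensitivity configuration
#'
#' @param patch Patch size in pixels, one integer (square) or
#'   `c(height, width)`; default 16.
#' @param stride Grid stride in pixels (default 8; flush bottom/right
#'   positions are appended so every pixel is covered).
#' @param baseline Intensity the occluding patch is filled with, in
#'   `[0, 1]` (default 0).
#' @return A list of class `eus_occlusion_config`.
#' @export
occlusion_config <- function(patch = 16, stride = 8, baseline = 0) {
  if (length(patch) == 1L) patch <- c(patch, patch)
  if (any(patch < 1) || stride < 1)
    abort_field("occlusion_config", "patch dims and stride must be >= 1")
  structure(list(patch = as.integer(patch), stride = as.integer(stride),
                 baseline = baseline),
            class = "eus_occlusion_config")
}

grid_positions <- function(n, patch, stride) {
  pos <- seq(1L, n - patch + 1L, by = stride)
  last <- n - patch + 1L
  if (pos[length(pos)] != last) pos <- c(pos, last)
  pos
}

#' Occlusion sensitivity map
#'
#' Slides an occluding patch over the image on a stride grid; at each
#' position the patch (all channels) is replaced by the baseline intensity
#' and the drop in the scorer's output, `score(original) -
#' score(occluded)`, is recorded. Each pixel's heat value is the mean drop
#' over all patches covering it: positive values (rendered red) mark
#' pixels whose occlusion lowers the score -- evidence for the prediction
#' -- and negative values (blue) mark counter-evidence.
#'
#' @param scorer Deterministic function mapping an image (matrix or
#'   `H x W x C` array) to a scalar score in `[0, 1]`.
#' @param image The input image.
#' @param config An [occlusion_config()]; the patch must fit inside the
#'   image.
#' @return An object of class `eus_heatmap`: `values` (matrix at image
#'   resolution), `score` (unoccluded score) and `config`.
#' @export
occlusion_map <- function(scorer, image, config = occlusion_config()) {
  px <- image_pixels(image)
  d <- dim(px); h <- d[1]; w <- d[2]
  if (config$patch[1] > h || config$patch[2] > w)
    stop(sprintf("patch %d x %d larger than image %d x %d",
                 config$patch[1], config$patch[2], h, w), call. = FALSE)
  s0 <- scorer(px)
  acc <- matrix(0, h, w); cnt <- matrix(0, h, w)
  for (top in grid_positions(h, config$patch[1], config$stride)) {
    ys <- top:(top + config$patch[1] - 1L)
    for (left in grid_positions(w, config$patch[2], config$stride)) {
      xs <- left:(left + config$patch[2] - 1L)
      occ <- px
      if (length(d) == 3L) occ[ys, xs, ] <- config$baseline
      else occ[ys, xs] <- config$baseline
      delta <- s0 - scorer(occ)
      acc[ys, xs] <- acc[ys, xs] + delta
      cnt[ys, xs] <- cnt[ys, xs] + 1
    }
  }
  structure(list(values = acc / cnt, score = s0, config = config),
            class = "eus_heatmap")
}

#' @export
print.eus_heatmap <- function(x, ...) {
  cat(sprintf("Occlusion heatmap %d x %d (patch %d x %d, stride %d, baseline %.2f)\n",
              nrow(x$values), ncol(x$values), x$config$patch[1],
              x$config$patch[2], x$config$stride, x$config$baseline))
  cat(sprintf("  unoccluded score %.3f; heat range [%.4f, %.4f]\n",
              x$score, min(x$values), max(x$values)))
  invisible(x)
}

# Diverging blue-white-red colormap on a symmetric scale about zero.
heat_to_rgb <- function(values) {
  m <- max(abs(values))
  v <- if (m == 0) values else values / m   # in [-1, 1]
  h <- nrow(values); w <- ncol(values)
  rgb <- array(1, c(h, w, 3L))
  pos <- pmax(v, 0); neg <- pmax(-v, 0)
  rgb[, , 1] <- 1 - neg          # red channel drops for negative values
  rgb[, , 2] <- 1 - pos - neg    # green drops for both
  rgb[, , 3] <- 1 - pos          # blue drops for positive values
  pmin(pmax(rgb, 0), 1)
}

#' Render an occlusion heatmap to a PNG file
#'
#' Maps the heat values onto a diverging colormap (red = positive =
#' relevant to the prediction, blue = negative, white = zero) with a
#' symmetric color scale about zero, optionally alpha-blended over the
#' grayscale underlay image, and writes an 8-bit PNG.
#'
#' @param heatmap An `eus_heatmap`.
#' @param file Output PNG path.
#' @param underlay Optional grayscale matrix (or quasi-RGB image, averaged
#'   to gray) of the same spatial dimensions.
#' @param alpha Heatmap opacity over the underlay (default 0.6).
#' @return The rendered `H x W x 3` array, invisibly.
#' @export
render_heatmap <- function(heatmap, file, underlay = NULL, alpha = 0.6) {
  stopifnot(inherits(heatmap, "eus_heatmap"))
  rgb <- heat_to_rgb(heatmap$values)
  if (!is.null(underlay)) {
    u <- image_pixels(underlay)
    if (length(dim(u)) == 3L) u <- (u[, , 1] + u[, , 2] + u[, , 3]) / 3
    if (!all(dim(u) == dim(heatmap$values)))
      stop("underlay dimensions do not match the heatmap", call. = FALSE)
    for (k in 1:3) rgb[, , k] <- alpha * rgb[, , k] + (1 - alpha) * u
  }
  png::writePNG(rgb, file)
  invisible(rgb)
}
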