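#' Crop box constructor
#'
#' A rectangular crop applied uniformly to every frame of a run, used to
#' remove the bottom band that ultrasound waves do not reach and any
#' annotation marks foreign to the image. `top`/`left` are 1-based.
#' The default output size is width 465 x height 489 pixels.
#'
#' @param top,left 1-based row/column of the top-left corner.
#' @param height,width Output dimensions in pixels.
#' @return A list of class `eus_crop_box`.
#' @export
crop_box <- function(top, left, height = 489, width = 465) {
  if (top < 1 || left < 1 || height < 1 || width < 1)
    abort_field("crop_box", "top/left must be >= 1 and dims positive")
  structure(list(top = as.integer(top), left = as.integer(left),
                 height = as.integer(height), width = as.integer(width)),
            class = "eus_crop_box")
}

#' Crop a raw frame
#'
#' @param raw 2-D intensity matrix.
#' @param box An [crop_box()]. A box extending beyond the raw frame is an
#'   error; there is no silent clamping.
#' @return The cropped matrix of dimension `height x width`, pixel values
#'   unchanged.
#' @export
crop_frame <- function(raw, box) {
  stopifnot(is.matrix(raw))
  if (box$top + box$height - 1L > nrow(raw) ||
      box$left + box$width - 1L > ncol(raw))
    stop(sprintf("crop box (%d+%d, %d+%d) exceeds raw frame %d x %d",
                 box$top, box$height, box$left, box$width,
                 nrow(raw), ncol(raw)), call. = FALSE)
  raw[box$top:(box$top + box$height - 1L),
      box$left:(box$left + box$width - 1L), drop = FALSE]
}

#' Crop every frame of a cohort
#'
#' Applies one crop box uniformly to all frames of all videos of all
#' patients. When `box` is `NULL` a box is derived from the cohort's raw
#' frame size: it removes the corner annotation marks at the top and the
#' bottom dark band, keeping the largest centered interior window.
#'
#' @param cohort An `eus_cohort`.
#' @param box An [crop_box()] or `NULL`.
#' @return The cohort with cropped frames; the box used is attached as
#'   attribute `"crop_box"`.
#' @export
preprocess_cohort <- function(cohort, box = NULL) {
  stopifnot(inherits(cohort, "eus_cohort"))
  if (is.null(box)) box <- default_crop_box(cohort$spec)
  for (i in seq_along(cohort$patients)) {
    for (v in seq_along(cohort$patients[[i]]$videos)) {
      cohort$patients[[i]]$videos[[v]] <-
        lapply(cohort$patients[[i]]$videos[[v]], crop_frame, box = box)
    }
  }
  attr(cohort, "crop_box") <- box
  cohort
}

# Interior window clearing the synthetic corner marks (top) and bottom
# band. For the default 540 x 500 raw frames this yields the standard
# 489 x 465 crop.
default_crop_box <- function(spec) {
  h <- spec$frame_height; w <- spec$frame_width
  band <- max(4L, round(0.08 * h))
  mark <- max(3L, round(0.012 * w))
  top <- mark + 2L
  height <- h - band - top + 1L
  width <- w - 2L * (mark + 2L) + 2L
  left <- (w - width) %/% 2L + 1L
  crop_box(top, left, height, width)
}

# --- bilinear resizing -----------------------------------------------------

# Half-pixel-center bilinear index/weight pair for one axis. When
# n_out == n_in the mapping is the identity (weights exactly 0/1), so a
# same-size resize is bit-identical.
bilinear_axis <- function(n_out, n_in) {
  pos <- (seq_len(n_out) - 0.5) * n_in / n_out + 0.5
  pos <- pmin(pmax(pos, 1), n_in)
  lo <- floor(pos)
  lo[lo > n_in - 1L] <- max(n_in - 1L, 1L)
  frac <- pos - lo
  if (n_in == 1L) { lo[] <- 1L; frac[] <- 0 }
  list(lo = as.integer(lo), frac = frac)
}

resize_matrix <- function(m, out_h, out_w) {
  ay <- bilinear_axis(out_h, nrow(m))
  ax <- bilinear_axis(out_w, ncol(m))
  y0 <- ay$lo; y1 <- pmin(ay$lo + 1L, nrow(m)); wy <- ay$frac
  x0 <- ax$lo; x1 <- pmin(ax$lo + 1L, ncol(m)); wx <- ax$frac
  (1 - wy) %o% (1 - wx) * m[y0, x0, drop = FALSE] +
    (1 - wy) %o% wx       * m[y0, x1, drop = FALSE] +
    wy %o% (1 - wx)       * m[y1, x0, drop = FALSE] +
    wy %o% wx             * m[y1, x1, drop = FALSE]
}

#' Bilinear image resize
#'
#' Deterministic bilinear interpolation with half-pixel-center coordinate
#' mapping; an input already at the target size is returned bit-identical.
#'
#' @param img A matrix (grayscale) or `H x W x C` array.
#' @param target Output size, either one integer (square) or `c(height,
#'   width)`; default 224.
#' @return Resized matrix or array of the same type.
#' @export
resize_image <- function(img, target = 224) {
  if (length(target) == 1L) target <- c(target, target)
  if (is.matrix(img)) {
    if (nrow(img) == 0L || ncol(img) == 0L) stop("empty image", call. = FALSE)
    return(resize_matrix(img, target[1], target[2]))
  }
  stopifnot(length(dim(img)) == 3L)
  out <- array(0, c(target[1], target[2], dim(img)[3]))
  for (k in seq_len(dim(img)[3]))
    out[, , k] <- resize_matrix(img[, , k], target[1], target[2])
  out
}

# --- quasi-RGB composition -------------------------------------------------

# Sample one (video, three ascending frame indices) triple for a patient.
# Uses the current RNG stream; callers seed it. When same_video_only the
# video is chosen uniformly among those with >= 3 frames, otherwise the
# three frames are drawn patient-wide (temporal order video-major).
sample_quasi_triple <- function(patient, same_video_only = TRUE) {
  n_per_video <- vapply(patient$videos, length, integer(1))
  if (same_video_only) {
    eligible <- which(n_per_video >= 3L)
    if (!length(eligible))
      stop(sprintf("patient %s has no video with >= 3 frames",
                   patient$patient_id), call. = FALSE)
    v <- eligible[runif_int(1, 1, length(eligible))]
    idx <- sort(sample(n_per_video[v], 3L))
    list(video = rep(names(patient$videos)[v], 3L), index = idx)
  } else {
    total <- sum(n_per_video)
    if (total < 3L)
      stop(sprintf("patient %s has fewer than 3 frames",
                   patient$patient_id), call. = FALSE)
    flat <- sort(sample(total, 3L))  # video-major global temporal order
    vid <- findInterval(flat - 1L, cumsum(c(0L, n_per_video)),
                        rightmost.closed = FALSE)
    idx <- flat - cumsum(c(0L, n_per_video))[vid]
    list(video = names(patient$videos)[vid], index = as.integer(idx))
  }
}

# Materialize a quasi-RGB image from a sampled triple.
build_quasi_rgb <- function(patient, triple, target = 224) {
  chans <- lapply(seq_len(3L), function(k) {
    fr <- patient$videos[[triple$video[k]]][[triple$index[k]]]
    resize_matrix(fr / 255, target, target)
  })
  pixels <- array(0, c(target, target, 3L))
  for (k in 1:3) pixels[, , k] <- chans[[k]]
  structure(list(pixels = pixels, patient_id = patient$patient_id,
                 video_id = triple$video, frame_index = triple$index,
                 label = patient$label),
            class = "eus_quasi_rgb")
}

#' Compose a quasi-RGB image from one patient's frames
#'
#' Three temporally distinct grayscale frames of one patient are sampled
#' without replacement and stacked as the red, green and blue channels in
#' ascending temporal order, then bilinearly resized to `target x target`
#' (default 224). Channel variation thus encodes temporal variation.
#'
#' @param patient A patient record (element of `eus_cohort$patients`).
#' @param seed Integer seed or `NULL` to use the ambient RNG stream.
#' @param same_video_only If `TRUE` (default) the three frames come from
#'   one randomly chosen video with at least three frames; otherwise they
#'   are drawn patient-wide.
#' @param target Output side length in pixels.
#' @return An object of class `eus_quasi_rgb`: `pixels` (`target x target
#'   x 3`, intensities in `[0, 1]`), provenance (`patient_id`, `video_id`,
#'   ascending `frame_index`) and `label`.
#' @export
compose_quasi_rgb <- function(patient, seed = NULL, same_video_only = TRUE,
                              target = 224) {
  with_seed(seed, {
    triple <- sample_quasi_triple(patient, same_video_only)
    build_quasi_rgb(patient, triple, target)
  })
}

# --- augmentation ----------------------------------------------------------

#' Augmentation configuration
#'
#' The default suite mirrors common light photometric/geometric training
#' augmentation: horizontal flip with probability 0.5, rotation within
#' +/- 10 degrees, brightness scaling within +/- 10 percent. Augmentation
#' is disabled everywhere by default and never used on evaluation paths.
#'
#' @param hflip Flip probability (0 disables).
#' @param max_rotate Maximum absolute rotation, degrees (0 disables).
#' @param max_brightness Maximum absolute relative brightness change
#'   (0 disables).
#' @return A list of class `eus_augment_config`.
#' @export
augment_config <- function(hflip = 0.5, max_rotate = 10,
                           max_brightness = 0.1) {
  structure(list(hflip = hflip, max_rotate = max_rotate,
                 max_brightness = max_brightness),
            class = "eus_augment_config")
}

rotate_matrix <- function(m, degrees) {
  h <- nrow(m); w <- ncol(m)
  th <- degrees * pi / 180
  cy <- (h + 1) / 2; cx <- (w + 1) / 2
  yy <- matrix(seq_len(h) - cy, h, w)
  xx <- matrix(rep(seq_len(w) - cx, each = h), h, w)
  sy <- pmin(pmax(cy + cos(th) * yy - sin(th) * xx, 1), h)
  sx <- pmin(pmax(cx + sin(th) * yy + cos(th) * xx, 1), w)
  y0 <- pmin(floor(sy), h - 1L); x0 <- pmin(floor(sx), w - 1L)
  fy <- sy - y0; fx <- sx - x0
  i00 <- cbind(as.vector(y0), as.vector(x0))
  i01 <- cbind(as.vector(y0), as.vector(x0) + 1L)
  i10 <- cbind(as.vector(y0) + 1L, as.vector(x0))
  i11 <- cbind(as.vector(y0) + 1L, as.vector(x0) + 1L)
  out <- (1 - fy) * (1 - fx) * m[i00] + (1 - fy) * fx * m[i01] +
    fy * (1 - fx) * m[i10] + fy * fx * m[i11]
  matrix(out, h, w)
}

#' Apply training augmentation to an image
#'
#' @param img Matrix or `H x W x C` array with intensities in `[0, 1]`,
#'   or an `eus_quasi_rgb`.
#' @param config An [augment_config()]; `NULL` is the identity.
#' @param seed Integer seed or `NULL` for the ambient RNG stream.
#' @return Augmented image of the same shape and type.
#' @export
augment_image <- function(img, config = augment_config(), seed = NULL) {
  is_qrgb <- inherits(img, "eus_quasi_rgb")
  px <- if (is_qrgb) img$pixels else img
  if (is.null(config)) return(img)
  with_seed(seed, {
    do_flip <- config$hflip > 0 && stats::runif(1) < config$hflip
    rot <- if (config$max_rotate > 0)
      stats::runif(1, -config$max_rotate, config$max_rotate) else 0
    bright <- if (config$max_brightness > 0)
      1 + stats::runif(1, -config$max_brightness, config$max_brightness) else 1
    apply_chan <- function(m) {
      if (do_flip) m <- m[, rev(seq_len(ncol(m))), drop = FALSE]
      if (rot != 0) m <- rotate_matrix(m, rot)
      pmin(pmax(m * bright, 0), 1)
    }
    if (is.matrix(px)) px <- apply_chan(px)
    else for (k in seq_len(dim(px)[3])) px[, , k] <- apply_chan(px[, , k])
    if (is_qrgb) { img$pixels <- px; img } else px
  })
}

# --- epoch and test-set sampling -------------------------------------------

#' Sampling configuration
#'
#' @param n_per_epoch Quasi-RGB images per training epoch (default 1000),
#'   split almost evenly between the classes.
#' @param n_test_per_patient Quasi-RGB images generated per test patient
#'   (default 300).
#' @param same_video_only Whether the three frames of one image must come
#'   from a single video (default `TRUE`).
#' @param augment An [augment_config()] applied to training images, or
#'   `NULL` (default) for none.
#' @param target Quasi-RGB side length in pixels (default 224).
#' @return A list of class `eus_sampling_config`.
#' @export
sampling_config <- function(n_per_epoch = 1000, n_test_per_patient = 300,
                            same_video_only = TRUE, augment = NULL,
                            target = 224) {
  if (n_per_epoch < 2) abort_field("n_per_epoch", "must be >= 2")
  if (n_test_per_patient < 1) abort_field("n_test_per_patient", "must be >= 1")
  structure(list(n_per_epoch = as.integer(n_per_epoch),
                 n_test_per_patient = as.integer(n_test_per_patient),
                 same_video_only = isTRUE(same_video_only),
                 augment = augment, target = as.integer(target)),
            class = "eus_sampling_config")
}

# Class-balanced per-patient image counts: the class counts differ by at
# most one (the extra image goes to class 1), and within a class the
# per-patient counts differ by at most one (round-robin in patient-id
# order).
epoch_quota <- function(patients, n_total) {
  labels <- vapply(patients, `[[`, integer(1), "label")
  ids <- vapply(patients, `[[`, character(1), "patient_id")
  for (cl in 0:1) if (!any(labels == cl))
    stop(sprintf("class %d absent from training patients", cl), call. = FALSE)
  n1 <- ceiling(n_total / 2); n0 <- n_total - n1
  quota <- integer(length(patients)); names(quota) <- ids
  for (cl in 0:1) {
    members <- ids[labels == cl][order(ids[labels == cl])]
    n_cl <- if (cl == 1L) n1 else n0
    base <- n_cl %/% length(members)
    extra <- n_cl %% length(members)
    quota[members] <- base + (seq_along(members) <= extra)
  }
  quota
}

# Sampling plan: one row per image with provenance. Pure function of
# (patients, config, seed).
sample_epoch_plan <- function(patients, config, seed = NULL) {
  quota <- epoch_quota(patients, config$n_per_epoch)
  ids <- vapply(patients, `[[`, character(1), "patient_id")
  with_seed(seed, {
    rows <- lapply(seq_along(patients), function(i) {
      n_i <- quota[[ids[i]]]
      if (n_i == 0L) return(NULL)
      triples <- replicate(n_i,
                           sample_quasi_triple(patients[[i]],
                                               config$same_video_only),
                           simplify = FALSE)
      data.frame(patient_id = ids[i],
                 label = patients[[i]]$label,
                 video_1 = vapply(triples, function(t) t$video[1], ""),
                 video_2 = vapply(triples, function(t) t$video[2], ""),
                 video_3 = vapply(triples, function(t) t$video[3], ""),
                 idx_1 = vapply(triples, function(t) t$index[1], 0L),
                 idx_2 = vapply(triples, function(t) t$index[2], 0L),
                 idx_3 = vapply(triples, function(t) t$index[3], 0L),
                 stringsAsFactors = FALSE)
    })
    do.call(rbind, rows)
  })
}

plan_to_images <- function(patients, plan, config, seed = NULL) {
  by_id <- stats::setNames(patients,
                           vapply(patients, `[[`, character(1), "patient_id"))
  imgs <- vector("list", nrow(plan))
  for (r in seq_len(nrow(plan))) {
    triple <- list(video = c(plan$video_1[r], plan$video_2[r], plan$video_3[r]),
                   index = c(plan$idx_1[r], plan$idx_2[r], plan$idx_3[r]))
    imgs[[r]] <- build_quasi_rgb(by_id[[plan$patient_id[r]]], triple,
                                 config$target)
  }
  if (!is.null(config$augment)) {
    with_seed(if (is.null(seed)) NULL else derive_seed(seed, "augment"), {
      imgs <- lapply(imgs, augment_image, config = config$augment,
                     seed = NULL)
    })
  }
  imgs
}

#' Sample one class-balanced training epoch of quasi-RGB images
#'
#' Draws `n_per_epoch` quasi-RGB images from the training patients with
#' the class counts differing by at most one (the odd image goes to the
#' positive class) and, within each class, per-patient counts differing by
#' at most one. Every image is composed from frames of a single patient.
#'
#' @param patients List of patient records (the training groups' patients);
#'   both classes must be present.
#' @param config A [sampling_config()].
#' @param seed Integer seed or `NULL`.
#' @param materialize If `FALSE`, return only the provenance plan (a data
#'   frame with `patient_id`, `label`, and the sampled video/frame triple
#'   per image) without building pixel arrays.
#' @return A list of `eus_quasi_rgb` (with the plan attached as attribute
#'   `"plan"`), or the plan itself when `materialize = FALSE`.
#' @export
sample_epoch <- function(patients, config = sampling_config(), seed = NULL,
                         materialize = TRUE) {
  plan <- sample_epoch_plan(patients, config, seed)
  if (!materialize) return(plan)
  imgs <- plan_to_images(patients, plan, config, seed)
  attr(imgs, "plan") <- plan
  imgs
}

#' Sample the test-time quasi-RGB images of one patient
#'
#' @param patient A patient record.
#' @param config A [sampling_config()]; `n_test_per_patient` images are
#'   drawn. No augmentation is applied at test time.
#' @param seed Integer seed or `NULL`.
#' @param materialize As in [sample_epoch()].
#' @return A list of `eus_quasi_rgb` or a provenance plan.
#' @export
sample_test_set <- function(patient, config = sampling_config(),
                            seed = NULL, materialize = TRUE) {
  plan <- with_seed(seed, {
    triples <- replicate(config$n_test_per_patient,
                         sample_quasi_triple(patient, config$same_video_only),
                         simplify = FALSE)
    data.frame(patient_id = patient$patient_id, label = patient$label,
               video_1 = vapply(triples, function(t) t$video[1], ""),
               video_2 = vapply(triples, function(t) t$video[2], ""),
               video_3 = vapply(triples, function(t) t$video[3], ""),
               idx_1 = vapply(triples, function(t) t$index[1], 0L),
               idx_2 = vapply(triples, function(t) t$index[2], 0L),
               idx_3 = vapply(triples, function(t) t$index[3], 0L),
               stringsAsFactors = FALSE)
  })
  if (!materialize) return(plan)
  cfg <- config; cfg$augment <- NULL
  imgs <- plan_to_images(list(patient), plan, cfg)
  attr(imgs, "plan") <- plan
  imgs
}
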