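#' Preprocessing: normalization, cropping, resizing, splitting, augmentation
#'
#' Standard slice preprocessing for 2-D grayscale inputs: per-image z-score
#' normalization over brain pixels, tight background cropping, resizing to the
#' model's input side, a seeded train/test split with a per-class push subset,
#' and six-fold geometric augmentation (two rotations, two shears, two skews).
#'
#' @name preprocessing
NULL

#' Split specification
#'
#' @param train_fraction Fraction of records assigned to training.
#' @param push_per_class Number of training records per class reserved (not
#'   removed) as the push set onto which prototypes are projected.
#' @param seed Integer seed for the shuffle.
#' @export
split_spec <- function(train_fraction = 0.70, push_per_class = 30L, seed = 1L) {
  stopifnot(train_fraction > 0, train_fraction < 1, push_per_class >= 1)
  structure(list(train_fraction = train_fraction,
                 push_per_class = as.integer(push_per_class),
                 seed = as.integer(seed)), class = "split_spec")
}

#' Augmentation specification
#'
#' Defaults follow common practice for axial MR slices: rotations up to 20
#' degrees either way, shears up to 10 degrees, skew magnitude 0.2, and two
#' copies per operation (six augmented images per original).
#'
#' @param rotation_limit Max absolute rotation, degrees.
#' @param shear_limit Max absolute horizontal shear, degrees.
#' @param skew_magnitude Max absolute vertical skew (tilt) factor, unitless.
#' @param copies_per_op Augmented copies per operation per original.
#' @param seed Integer seed.
#' @export
augment_spec <- function(rotation_limit = 20, shear_limit = 10,
                         skew_magnitude = 0.2, copies_per_op = 2L, seed = 1L) {
  stopifnot(rotation_limit > 0, shear_limit > 0, skew_magnitude > 0,
            copies_per_op >= 1)
  structure(list(rotation_limit = rotation_limit, shear_limit = shear_limit,
                 skew_magnitude = skew_magnitude,
                 copies_per_op = as.integer(copies_per_op),
                 seed = as.integer(seed)), class = "augment_spec")
}

brain_pixels_mask <- function(record) {
  if (!is.null(record$brain_mask)) record$brain_mask > 0 else record$pixels != 0
}

#' Z-score normalize one record
#'
#' Standardizes intensities to mean 0 / SD 1 over the brain pixels (the brain
#' mask when present, otherwise all nonzero pixels); pixels outside the brain
#' are set to exactly 0.  Statistics are per image, not per dataset, so images
#' with different acquisition gain are brought to a common scale.
#'
#' Standardization uses the population standard deviation (divisor `n`), so
#' two brain pixels `{2, 4}` normalize exactly to `{-1, +1}`.
#'
#' @param record An [image_record()].
#' @return The record with standardized pixels; masks unchanged.
#' @export
zscore_normalize <- function(record) {
  m <- brain_pixels_mask(record)
  v <- record$pixels[m]
  s <- sqrt(mean((v - mean(v))^2))
  if (length(v) < 2 || s == 0)
    stop("degenerate image: constant brain region, cannot z-score normalize")
  px <- record$pixels
  px[m] <- (v - mean(v)) / s
  px[!m] <- 0
  record$pixels <- px
  record
}

#' Crop away the background
#'
#' Crops the record to the tight bounding box of the brain (nonzero) pixels;
#' masks are cropped identically.
#'
#' @param record An [image_record()].
#' @export
crop_background <- function(record) {
  m <- brain_pixels_mask(record)
  if (!any(m)) stop("empty-content image: all pixels are zero")
  rows <- range(which(rowSums(m) > 0))
  cols <- range(which(colSums(m) > 0))
  crop <- function(x) if (is.null(x)) NULL else
    x[rows[1]:rows[2], cols[1]:cols[2], drop = FALSE]
  record$pixels <- crop(record$pixels)
  record$lesion_mask <- crop(record$lesion_mask)
  record$brain_mask <- crop(record$brain_mask)
  record
}

#' Resize a record to a square side
#'
#' Pixels are resized with bilinear interpolation; masks with
#' nearest-neighbour so they stay binary.
#'
#' @param record An [image_record()].
#' @param side Target side in pixels (>= 8).
#' @export
resize_image <- function(record, side) {
  stopifnot(side >= 8)
  if (all(dim(record$pixels) == c(side, side))) return(record)
  record$pixels <- EBImage::resize(record$pixels, w = side, h = side,
                                   filter = "bilinear")
  rs <- function(m) if (is.null(m)) NULL else {
    out <- EBImage::resize(m, w = side, h = side, filter = "none")
    (out > 0.5) + 0
  }
  record$lesion_mask <- rs(record$lesion_mask)
  record$brain_mask <- rs(record$brain_mask)
  record
}

# Inverse-mapped affine warp about the image center.  A is the 2x2 forward
# map in (row, col) coordinates; output pixel p gets the input value at
# center + A^{-1} (p - center).  filter "bilinear" for intensities,
# "nearest" for masks; out-of-range samples are filled with `fill`.
warp_affine <- function(px, A, filter = c("bilinear", "nearest"), fill = 0) {
  filter <- match.arg(filter)
  h <- nrow(px); w <- ncol(px)
  ctr <- c((h + 1) / 2, (w + 1) / 2)
  Ai <- solve(A)
  rr <- rep(seq_len(h), times = w) - ctr[1]
  cc <- rep(seq_len(w), each = h) - ctr[2]
  sr <- Ai[1, 1] * rr + Ai[1, 2] * cc + ctr[1]
  sc <- Ai[2, 1] * rr + Ai[2, 2] * cc + ctr[2]
  if (filter == "nearest") {
    ir <- round(sr); ic <- round(sc)
    ok <- ir >= 1 & ir <= h & ic >= 1 & ic <= w
    out <- rep(fill, h * w)
    out[ok] <- px[cbind(ir[ok], ic[ok])]
  } else {
    r0 <- floor(sr); c0 <- floor(sc)
    fr <- sr - r0; fc <- sc - c0
    gv <- function(ri, ci) {
      ok <- ri >= 1 & ri <= h & ci >= 1 & ci <= w
      v <- rep(fill, length(ri))
      v[ok] <- px[cbind(ri[ok], ci[ok])]
      v
    }
    out <- gv(r0, c0) * (1 - fr) * (1 - fc) + gv(r0 + 1, c0) * fr * (1 - fc) +
           gv(r0, c0 + 1) * (1 - fr) * fc + gv(r0 + 1, c0 + 1) * fr * fc
  }
  matrix(out, h, w)
}

warp_record <- function(record, A, transform, suffix) {
  out <- record
  out$pixels <- warp_affine(record$pixels, A, "bilinear", fill = 0)
  wm <- function(m) if (is.null(m)) NULL else
    warp_affine(m, A, "nearest", fill = 0)
  out$lesion_mask <- wm(record$lesion_mask)
  out$brain_mask <- wm(record$brain_mask)
  out$source_id <- record$source_id
  out$id <- paste0(record$id, suffix)
  out$transform <- transform
  out
}

rotation_matrix <- function(deg) {
  th <- deg * pi / 180
  matrix(c(cos(th), -sin(th), sin(th), cos(th)), 2, 2, byrow = TRUE)
}
shear_matrix <- function(deg) {           # horizontal (transverse) shear
  matrix(c(1, tan(deg * pi / 180), 0, 1), 2, 2, byrow = TRUE)
}
skew_matrix <- function(k) {              # vertical tilt by factor k
  matrix(c(1, 0, k, 1), 2, 2, byrow = TRUE)
}

#' Six-fold geometric augmentation
#'
#' For each input record emits `copies_per_op` random rotations, shears and
#' skews (6 augmented records per original at the defaults).  Masks are warped
#' with the identical geometric map as the pixels (nearest-neighbour);
#' introduced pixels are filled with background 0.  Originals are not included
#' in the return value; keep them separately if desired.
#'
#' @param records List of [image_record()]s.
#' @param spec An [augment_spec()].
#' @return List of augmented records with lineage in `source_id`.
#' @export
augment_six_fold <- function(records, spec = augment_spec()) {
  stopifnot(length(records) > 0)
  set.seed(spec$seed)
  out <- list()
  for (rec in records) {
    for (i in seq_len(spec$copies_per_op)) {
      a <- stats::runif(1, -spec$rotation_limit, spec$rotation_limit)
      out[[length(out) + 1L]] <- warp_record(
        rec, rotation_matrix(a), sprintf("rot%+.1f", a), paste0("_rot", i))
    }
    for (i in seq_len(spec$copies_per_op)) {
      a <- stats::runif(1, -spec$shear_limit, spec$shear_limit)
      out[[length(out) + 1L]] <- warp_record(
        rec, shear_matrix(a), sprintf("shear%+.1f", a), paste0("_shr", i))
    }
    for (i in seq_len(spec$copies_per_op)) {
      k <- stats::runif(1, -spec$skew_magnitude, spec$skew_magnitude)
      out[[length(out) + 1L]] <- warp_record(
        rec, skew_matrix(k), sprintf("skew%+.2f", k), paste0("_skw", i))
    }
  }
  out
}

#' Split records into train / test / push sets
#'
#' Seeded shuffle split into disjoint train and test sets; the push set is a
#' per-class random subset of the training set (`push_per_class` records per
#' class) used for prototype projection.
#'
#' @param records List of [image_record()]s.
#' @param spec A [split_spec()].
#' @return List with elements `train`, `test`, `push`.
#' @export
split_dataset <- function(records, spec = split_spec()) {
  n <- length(records)
  stopifnot(n >= 2)
  set.seed(spec$seed)
  idx <- sample.int(n)
  ntrain <- round(spec$train_fraction * n)
  train <- records[idx[seq_len(ntrain)]]
  test <- records[idx[(ntrain + 1):n]]
  labels <- vapply(train, `[[`, "", "label")
  push <- list()
  for (cl in sort(unique(labels))) {
    pos <- which(labels == cl)
    if (length(pos) < spec$push_per_class)
      stop(sprintf(
        "configuration error: class %s has %d training records, need %d for the push set",
        cl, length(pos), spec$push_per_class))
    push <- c(push, train[sample(pos, spec$push_per_class)])
  }
  list(train = train, test = test, push = push)
}
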