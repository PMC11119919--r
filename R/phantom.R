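#' Two-class lesion phantom generator
#'
#' Seeded generator of synthetic 2-D grayscale "brain" images carrying one of
#' two lesion types, with ground-truth lesion and brain masks.  Class `"A"`
#' emulates an aggressive, ring-enhancing lesion: a bright enhancing annulus
#' around a dark heterogeneous (noisy) core, surrounded by a dim wide halo of
#' altered tissue.  Class `"B"` emulates an indolent lesion: a single
#' homogeneous mid-intensity disk with a sharp, non-enhancing margin.  Each
#' class is therefore distinguishable by local part-level texture rather than
#' by global image statistics, which is exactly the regime a part-prototype
#' classifier is designed for.
#'
#' Intensity layout (before noise, on a 0--1 scale): background 0, brain
#' tissue at `brain_level` (default 0.50), and lesion parts as offsets from
#' the tissue level scaled by `contrast_gain`: halo -0.07, ring +0.45, core
#' -0.25, class-B disk +0.16.  Class-independent nuisance realism — per-image
#' tissue level and contrast gain, dark ventricle-like blobs, a smooth bias
#' field, pixel noise, and randomized brain-ellipse axes — ensures the class
#' signal lives in local lesion texture rather than in global image
#' statistics, which is the regime the architecture targets.
#'
#' @name phantom
NULL

#' Construct a phantom specification
#'
#' @param image_size Side length in pixels (square image).
#' @param class_label `"A"` (ring + heterogeneous core + halo) or `"B"`
#'   (homogeneous disk).
#' @param lesion_center Numeric length-2, (row, col) pixel coordinates of the
#'   lesion center.  Default: image center.
#' @param lesion_radius Radius in pixels of the lesion disk (class B) or of
#'   the enhancing ring's outer edge (class A).
#' @param ring_width Width in pixels of the enhancing annulus (class A only).
#' @param core_noise_sd Standard deviation of the heterogeneous-core intensity
#'   noise (class A only), in intensity units.
#' @param haze_radius Outer radius in pixels of the peritumoral halo (class A
#'   only); must exceed `lesion_radius`.
#' @param background_level Intensity of pixels outside the brain ellipse.
#' @param noise_sd Standard deviation of additive Gaussian pixel noise applied
#'   everywhere inside the brain mask.
#' @param brain_semi_axes Numeric length-2, (row, col) semi-axes in pixels of
#'   the brain ellipse; defaults scale with `image_size`.
#' @param brain_level Brain-tissue intensity (per-image gain nuisance).
#' @param texture_amp Amplitude of smooth random parenchymal texture added
#'   to brain tissue (gray/white-matter-like structure; 0 disables).
#' @param contrast_gain Multiplier on all lesion-part intensity offsets.
#' @param bias_amp Peak-to-center amplitude of a smooth linear bias field
#'   across the brain (0 disables).
#' @param ventricles Optional list of ventricle-like blobs, each
#'   `list(center = c(r, c), semi = c(a, b), amp = <negative offset>)`.
#' @param seed Integer seed; identical specs give bit-identical images.
#' @return A `phantom_spec` list.
#' @export
phantom_spec <- function(image_size = 224L,
                         class_label = c("A", "B"),
                         lesion_center = NULL,
                         lesion_radius = NULL,
                         ring_width = NULL,
                         core_noise_sd = 0.07,
                         haze_radius = NULL,
                         background_level = 0,
                         noise_sd = 0.02,
                         brain_semi_axes = NULL,
                         brain_level = 0.5,
                         texture_amp = 0,
                         contrast_gain = 1,
                         bias_amp = 0,
                         ventricles = NULL,
                         seed = 1L) {
  class_label <- match.arg(class_label)
  s <- image_size
  if (is.null(brain_semi_axes)) brain_semi_axes <- c(0.34, 0.42) * s
  if (is.null(lesion_center)) lesion_center <- c(s / 2, s / 2)
  if (is.null(lesion_radius)) lesion_radius <- round(0.16 * s)
  if (is.null(ring_width)) ring_width <- max(2, round(0.05 * s))
  if (is.null(haze_radius)) haze_radius <- round(lesion_radius * 1.6)
  spec <- structure(list(
    image_size = as.integer(s), class_label = class_label,
    lesion_center = as.numeric(lesion_center),
    lesion_radius = as.numeric(lesion_radius),
    ring_width = as.numeric(ring_width),
    core_noise_sd = as.numeric(core_noise_sd),
    haze_radius = as.numeric(haze_radius),
    background_level = as.numeric(background_level),
    noise_sd = as.numeric(noise_sd),
    brain_semi_axes = as.numeric(brain_semi_axes),
    brain_level = as.numeric(brain_level),
    texture_amp = as.numeric(texture_amp),
    contrast_gain = as.numeric(contrast_gain),
    bias_amp = as.numeric(bias_amp),
    ventricles = ventricles,
    seed = as.integer(seed)
  ), class = "phantom_spec")
  validate_phantom_spec(spec)
  spec
}

validate_phantom_spec <- function(spec) {
  s <- spec$image_size
  if (spec$ring_width >= spec$lesion_radius)
    stop("invalid phantom spec: ring_width must be smaller than lesion_radius")
  if (spec$class_label == "A" && spec$haze_radius <= spec$lesion_radius)
    stop("invalid phantom spec: haze_radius must exceed lesion_radius")
  ctr <- c(s / 2, s / 2)
  outer_r <- if (spec$class_label == "A") spec$haze_radius else spec$lesion_radius
  # lesion disk inside brain ellipse: check a dense sample of boundary points
  th <- seq(0, 2 * pi, length.out = 361)[-361]
  br <- (spec$lesion_center[1] + outer_r * cos(th) - ctr[1]) / spec$brain_semi_axes[1]
  bc <- (spec$lesion_center[2] + outer_r * sin(th) - ctr[2]) / spec$brain_semi_axes[2]
  if (max(br^2 + bc^2) > 1)
    stop("invalid phantom spec: lesion extends outside the brain ellipse")
  if (any(ctr + spec$brain_semi_axes > s) || any(ctr - spec$brain_semi_axes < 1))
    stop("invalid phantom spec: brain ellipse extends outside the image")
  invisible(spec)
}

#' Construct an image record
#'
#' The basic data unit passed between pipeline stages: a 2-D grayscale pixel
#' matrix with a class label, optional binary lesion/brain masks of the same
#' shape, and provenance ids.
#'
#' @param pixels Numeric matrix.
#' @param label Class label string.
#' @param lesion_mask,brain_mask Optional 0/1 matrices of the same shape;
#'   every lesion pixel must be a brain pixel.
#' @param id Record identifier.
#' @param source_id Id of the originating record (augmented copies keep
#'   lineage); defaults to `id`.
#' @param transform Description of how the record was derived.
#' @return An `image_record` list.
#' @export
image_record <- function(pixels, label, lesion_mask = NULL, brain_mask = NULL,
                         id = "img", source_id = id, transform = "original") {
  stopifnot(is.matrix(pixels))
  for (m in list(lesion_mask, brain_mask)) {
    if (!is.null(m) && !identical(dim(m), dim(pixels)))
      stop("mask shape must match pixel shape")
  }
  if (!is.null(lesion_mask) && !is.null(brain_mask) &&
      any(lesion_mask > 0 & brain_mask == 0))
    stop("lesion_mask must be contained in brain_mask")
  structure(list(pixels = pixels, label = as.character(label),
                 lesion_mask = lesion_mask, brain_mask = brain_mask,
                 id = as.character(id), source_id = as.character(source_id),
                 transform = transform),
            class = "image_record")
}

#' @export
print.image_record <- function(x, ...) {
  cat(sprintf("<image_record %s> %dx%d label=%s masks=%s transform=%s\n",
              x$id, nrow(x$pixels), ncol(x$pixels), x$label,
              if (is.null(x$lesion_mask)) "no" else "yes", x$transform))
  invisible(x)
}

#' Generate one lesion phantom
#'
#' Renders the phantom described by a [phantom_spec()]: brain ellipse on a
#' dark background, the class-specific lesion parts, additive Gaussian noise
#' inside the brain, and ground-truth lesion/brain masks.  The lesion mask
#' covers disk + ring + halo for class A and the disk for class B.
#'
#' @param spec A `phantom_spec`.
#' @param id Record id.
#' @return An [image_record()].
#' @examples
#' rec <- generate_phantom(phantom_spec(image_size = 64, class_label = "A",
#'                                      lesion_radius = 10, haze_radius = 16))
#' @export
generate_phantom <- function(spec, id = paste0(spec$class_label, "_1")) {
  validate_phantom_spec(spec)
  s <- spec$image_size
  rr <- matrix(seq_len(s), s, s)          # row coordinate of each pixel
  cc <- matrix(seq_len(s), s, s, byrow = TRUE)
  ctr <- c(s / 2, s / 2)
  brain <- ((rr - ctr[1]) / spec$brain_semi_axes[1])^2 +
           ((cc - ctr[2]) / spec$brain_semi_axes[2])^2 <= 1
  dist <- sqrt((rr - spec$lesion_center[1])^2 + (cc - spec$lesion_center[2])^2)

  px <- matrix(spec$background_level, s, s)
  b <- spec$brain_level
  g <- spec$contrast_gain
  px[brain] <- b
  set.seed(spec$seed)
  if (spec$texture_amp > 0) {
    # smooth parenchymal texture: coarse Gaussian grid, bilinear upsampled
    coarse <- matrix(stats::rnorm(64, sd = spec$texture_amp), 8, 8)
    field <- ebi_resize(coarse, s, "bilinear")
    px[brain] <- px[brain] + field[brain]
  }
  # ventricle-like dark blobs (class-independent distractors)
  for (v in spec$ventricles) {
    blob <- ((rr - v$center[1]) / v$semi[1])^2 +
            ((cc - v$center[2]) / v$semi[2])^2 <= 1
    px[blob & brain] <- b + v$amp
  }
  if (spec$class_label == "A") {
    haze <- dist <= spec$haze_radius
    ring <- dist <= spec$lesion_radius &
            dist > spec$lesion_radius - spec$ring_width
    core <- dist <= spec$lesion_radius - spec$ring_width
    px[haze] <- b - 0.12 * g
    px[ring] <- b + 0.45 * g
    n_core <- sum(core)
    px[core] <- b - 0.22 * g + stats::rnorm(n_core, sd = spec$core_noise_sd)
    lesion <- haze
  } else {
    # homogeneous mid-bright disk with a smooth dark cystic center: locally
    # nothing resembles the enhancing ring or the noisy necrotic core
    disk <- dist <= spec$lesion_radius
    cyst <- dist <= 0.5 * spec$lesion_radius
    px[disk] <- b + 0.16 * g
    px[cyst] <- b - 0.40 * g
    lesion <- disk
  }
  if (spec$bias_amp != 0) {
    th <- stats::runif(1, 0, 2 * pi)
    field <- ((rr - s / 2) * cos(th) + (cc - s / 2) * sin(th)) / (s / 2)
    px[brain] <- px[brain] + spec$bias_amp * field[brain]
  }
  if (spec$noise_sd > 0)
    px[brain] <- px[brain] + stats::rnorm(sum(brain), sd = spec$noise_sd)
  px <- pmin(pmax(px, 0), 1)

  image_record(px, spec$class_label,
               lesion_mask = matrix(as.numeric(lesion), s, s),
               brain_mask = matrix(as.numeric(brain), s, s),
               id = id, transform = "phantom")
}

#' Generate a balanced phantom dataset
#'
#' Draws `n_per_class` phantoms of each class with randomized lesion geometry
#' (center, radius, ring width, halo extent), reproducibly from `seed`.
#'
#' @param n_per_class Number of images per class (>= 1).
#' @param image_size Side length in pixels.
#' @param seed Integer seed controlling geometry and pixel noise.
#' @return List of [image_record()]s, classes interleaved A, B, A, B, ...
#' @export
generate_dataset <- function(n_per_class, image_size = 64L, seed = 1L) {
  stopifnot(n_per_class >= 1)
  s <- image_size
  set.seed(seed)
  specs <- vector("list", 2L * n_per_class)
  ids <- character(2L * n_per_class)
  k <- 0L
  # draw all randomized geometry from one dataset RNG stream, then render
  for (i in seq_len(n_per_class)) {
    for (cl in c("A", "B")) {
      k <- k + 1L
      # anatomy varies: randomized brain ellipse axes
      semi <- stats::runif(2, c(0.38, 0.42), c(0.44, 0.48)) * s
      margin <- 0.06 * s      # lesions are intraparenchymal: keep them
                              # clear of the brain edge
      # lesions are large, as in diagnostic glioma slices
      radius <- stats::runif(1, 0.13, 0.22) * s
      ring_w <- stats::runif(1, 0.025, 0.04) * s
      haze_r <- radius * stats::runif(1, 1.45, 1.75)
      # keep the whole lesion + margin placeable inside the smallest axis
      haze_r <- min(haze_r, 0.88 * min(semi) - margin)
      radius <- min(radius, if (cl == "A") haze_r / 1.35 else
        0.88 * min(semi) - margin)
      ring_w <- min(ring_w, 0.5 * radius)
      outer <- if (cl == "A") haze_r else radius
      ctr <- c(s / 2, s / 2)
      # rejection-sample a center keeping lesion + margin inside the brain
      th <- seq(0, 2 * pi, length.out = 121)[-121]
      repeat {
        off <- stats::runif(2, -1, 1) * pmax(semi - outer - margin, 0)
        br <- (off[1] + (outer + margin) * cos(th)) / semi[1]
        bc <- (off[2] + (outer + margin) * sin(th)) / semi[2]
        if (max(br^2 + bc^2) <= 1) break
      }
      # class-independent nuisance structure: ventricle-like dark blobs
      # placed clear of the lesion
      vents <- list()
      n_vent <- sample(2:5, 1)
      for (vi in seq_len(n_vent)) {
        vsemi <- stats::runif(2, 0.03, 0.09) * s
        for (try in 1:20) {
          voff <- stats::runif(2, -0.7, 0.7) * semi
          ok_brain <- max(((voff[1] + vsemi[1] * cos(th)) / semi[1])^2 +
                          ((voff[2] + vsemi[2] * sin(th)) / semi[2])^2) <= 1
          clear <- sqrt(sum((voff - off)^2)) > outer + max(vsemi) + 2
          if (ok_brain && clear) {
            vents[[length(vents) + 1L]] <-
              list(center = ctr + voff, semi = vsemi,
                   amp = -stats::runif(1, 0.15, 0.32))
            break
          }
        }
      }
      sp <- phantom_spec(image_size = s, class_label = cl,
                         lesion_center = ctr + off, lesion_radius = radius,
                         ring_width = ring_w, haze_radius = haze_r,
                         brain_semi_axes = semi,
                         brain_level = stats::runif(1, 0.48, 0.52),
                         texture_amp = stats::runif(1, 0.03, 0.05),
                         contrast_gain = stats::runif(1, 0.85, 1.15),
                         bias_amp = stats::runif(1, 0, 0.05),
                         ventricles = vents,
                         seed = sample.int(.Machine$integer.max, 1L))
      specs[[k]] <- sp
      ids[k] <- sprintf("%s_%04d", cl, i)
    }
  }
  Map(generate_phantom, specs, ids)
}
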