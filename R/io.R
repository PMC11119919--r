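#' Reading and writing datasets
#'
#' Records are stored on disk as 8-bit grayscale PNGs (`images/<id>.png`)
#' with optional mask PNGs (`masks/<id>_lesion.png`, `masks/<id>_brain.png`)
#' and a `labels.csv` with columns `id,label`.  PNG cannot hold signed
#' floats, so export quantizes each image by its own min-max range; masks
#' are stored as 0/255.
#'
#' @name io
NULL

#' Write a list of records to a dataset directory
#'
#' @param records List of [image_record()]s.
#' @param dir Output directory (created if needed).
#' @export
write_dataset <- function(records, dir) {
  dir.create(file.path(dir, "images"), recursive = TRUE, showWarnings = FALSE)
  dir.create(file.path(dir, "masks"), recursive = TRUE, showWarnings = FALSE)
  for (rec in records) {
    px <- rec$pixels
    rng <- range(px)
    if (diff(rng) > 0) px <- (px - rng[1]) / diff(rng)
    png::writePNG(px, file.path(dir, "images", paste0(rec$id, ".png")))
    if (!is.null(rec$lesion_mask))
      png::writePNG(rec$lesion_mask,
                    file.path(dir, "masks", paste0(rec$id, "_lesion.png")))
    if (!is.null(rec$brain_mask))
      png::writePNG(rec$brain_mask,
                    file.path(dir, "masks", paste0(rec$id, "_brain.png")))
  }
  utils::write.csv(data.frame(id = vapply(records, `[[`, "", "id"),
                              label = vapply(records, `[[`, "", "label")),
                   file.path(dir, "labels.csv"), row.names = FALSE)
  invisible(dir)
}

#' Read a dataset directory written by [write_dataset()]
#'
#' @param dir Dataset directory containing `images/` and `labels.csv`.
#' @return List of [image_record()]s.
#' @export
read_dataset <- function(dir) {
  lab <- utils::read.csv(file.path(dir, "labels.csv"),
                         colClasses = "character")
  lapply(seq_len(nrow(lab)), function(i) {
    id <- lab$id[i]
    px <- png_gray(file.path(dir, "images", paste0(id, ".png")))
    rm <- function(kind) {
      f <- file.path(dir, "masks", paste0(id, "_", kind, ".png"))
      if (file.exists(f)) (png_gray(f) > 0.5) + 0 else NULL
    }
    image_record(px, lab$label[i], lesion_mask = rm("lesion"),
                 brain_mask = rm("brain"), id = id)
  })
}

png_gray <- function(path) {
  a <- png::readPNG(path)
  if (length(dim(a)) == 3) a <- a[, , 1]
  a
}

#' Extract axial slices from a NIfTI volume
#'
#' Optional NIfTI input: reads a 3-D volume (requires the RNifti package)
#' and returns one record per axial slice; when a lesion-mask volume is
#' given, only slices with nonzero lesion mask are kept.
#'
#' @param path Path to the NIfTI image volume.
#' @param label Class label applied to every slice.
#' @param lesion_path,brain_path Optional mask volumes of the same shape.
#' @export
read_nifti_slices <- function(path, label, lesion_path = NULL,
                              brain_path = NULL) {
  if (!requireNamespace("RNifti", quietly = TRUE))
    stop("NIfTI input requires the RNifti package")
  vol <- as.array(RNifti::readNifti(path))
  stopifnot(length(dim(vol)) == 3)
  les <- if (!is.null(lesion_path)) as.array(RNifti::readNifti(lesion_path))
  brn <- if (!is.null(brain_path)) as.array(RNifti::readNifti(brain_path))
  base <- tools::file_path_sans_ext(basename(path), compression = TRUE)
  out <- list()
  for (z in seq_len(dim(vol)[3])) {
    lm <- if (!is.null(les)) (les[, , z] > 0) + 0 else NULL
    if (!is.null(lm) && !any(lm > 0)) next
    bm <- if (!is.null(brn)) (brn[, , z] > 0) + 0 else NULL
    out[[length(out) + 1L]] <- image_record(
      vol[, , z], label, lesion_mask = lm, brain_mask = bm,
      id = sprintf("%s_z%03d", base, z))
  }
  out
}
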