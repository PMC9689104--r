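##
## Training-stage augmentation.  GIA: identity, horizontal/vertical flips,
## 180 degree and +/-30 degree rotations, applied identically to image and
## label.  CBVIA: the image restricted to the (manually segmented) vessel
## mask, plus its vertical flip.  The test-time path never augments.
##

flip_h <- function(m) m[, ncol(m):1, drop = FALSE]
flip_v <- function(m) m[nrow(m):1, , drop = FALSE]

## Rotation about the image centre; canvas size kept, corners filled with 0.
## Bilinear interpolation for images, nearest-neighbour (then re-binarised)
## for labels.
rotate_grid <- function(m, angle, label = FALSE) {
  out <- EBImage::imageData(EBImage::rotate(
    m, angle,
    filter = if (label) "none" else "bilinear",
    output.dim = dim(m), bg.col = 0))
  if (label) out <- (out > 0.5) * 1
  out
}

check_aligned <- function(image, label) {
  if (!identical(dim(image), dim(label)))
    stop("image and label dimensions differ", call. = FALSE)
  invisible(TRUE)
}

check_binary <- function(mask, what = "mask") {
  if (!all(mask %in% c(0, 1)))
    stop(what, " must be strictly binary (0/1)", call. = FALSE)
  invisible(TRUE)
}

aug_pair <- function(image, label, provenance)
  list(image = image, label = label, provenance = provenance)

#' General image augmentation (GIA)
#'
#' Returns the six geometric variants of an image/label pair: identity,
#' horizontal flip, vertical flip, 180 degree rotation, and +/-30 degree
#' rotations about the centre.  The label undergoes exactly the same
#' transform as the image and stays binary (nearest-neighbour resampling
#' for the rotations).  N originals therefore become 6N training pairs.
#'
#' @param image H x W numeric matrix in `[0, 1]`.
#' @param label aligned binary matrix.
#' @return list of 6 pairs, each `list(image, label, provenance)` with
#'   provenance one of `"identity"`, `"H"`, `"V"`, `"R180"`, `"R+30"`,
#'   `"R-30"`.
#' @export
general_augment <- function(image, label) {
  check_aligned(image, label)
  check_binary(label, "label")
  list(
    aug_pair(image, label, "identity"),
    aug_pair(flip_h(image), flip_h(label), "H"),
    aug_pair(flip_v(image), flip_v(label), "V"),
    aug_pair(flip_h(flip_v(image)), flip_h(flip_v(label)), "R180"),
    aug_pair(rotate_grid(image, 30), rotate_grid(label, 30, label = TRUE),
             "R+30"),
    aug_pair(rotate_grid(image, -30), rotate_grid(label, -30, label = TRUE),
             "R-30")
  )
}

#' Crop the blood vessel from an image
#'
#' Elementwise product of the image with the binary vessel (adventitia)
#' mask: pixels outside the vessel become exactly 0.
#'
#' @param image H x W numeric matrix.
#' @param vessel_mask aligned binary matrix.
#' @return the cropped-blood-vessel (CBV) image.
#' @export
crop_blood_vessel <- function(image, vessel_mask) {
  check_aligned(image, vessel_mask)
  check_binary(vessel_mask, "vessel_mask")
  image * vessel_mask
}

#' Cropped-blood-vessel image augmentation (CBVIA)
#'
#' Returns the CBV image with the original plaque label, and its vertical
#' flip with the vertically flipped label; N originals become 2N pairs.
#' Because plaques lie inside the vessel, masking cannot remove label
#' pixels; a label pixel outside the vessel mask raises an error.
#'
#' @param image H x W numeric matrix.
#' @param label aligned binary plaque mask (subset of `vessel_mask`).
#' @param vessel_mask aligned binary vessel mask.
#' @return list of 2 pairs with provenance `"CV"` and `"V(CV)"`.
#' @export
cbv_augment <- function(image, label, vessel_mask) {
  check_aligned(image, label)
  check_aligned(image, vessel_mask)
  check_binary(label, "label")
  if (any(label == 1 & vessel_mask == 0))
    stop("plaque label pixels found outside the vessel mask", call. = FALSE)
  cv <- crop_blood_vessel(image, vessel_mask)
  list(
    aug_pair(cv, label, "CV"),
    aug_pair(flip_v(cv), flip_v(label), "V(CV)")
  )
}

#' Build the augmented training pool
#'
#' Concatenates GIA (6 pairs) and CBVIA (2 pairs) over every sample, so
#' `|out| = 8 * |samples|`; 40 originals yield the 320-pair training pool
#' (240 from GIA, 80 from CBVIA) and a 36-image cross-validation fold
#' yields 288.
#'
#' @param samples list of samples, each with `image`, `plaque_mask` and
#'   `vessel_mask` (e.g. from [generate_dataset()]).
#' @return flat list of augmented `list(image, label, provenance)` pairs.
#' @export
build_training_set <- function(samples) {
  out <- list()
  for (s in samples) {
    out <- c(out,
             general_augment(s$image, s$plaque_mask),
             cbv_augment(s$image, s$plaque_mask, s$vessel_mask))
  }
  out
}
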