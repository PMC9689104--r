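##
## Synthetic carotid-ultrasound phantoms: a longitudinal-view vessel (dark
## lumen band between bright wall layers), plaques protruding into the lumen
## from the near or far wall, multiplicative speckle, acoustic shadows and
## bright artifact streaks.  Every sample carries the image, the plaque mask
## and the vessel (adventitia) mask used by the CBV augmentation.
##

#' Parameters of the ultrasound phantom generator
#'
#' @param height,width image size in pixels.
#' @param lumen_center_frac vertical centre of the lumen as a fraction of
#'   the image height.
#' @param lumen_half_thickness half-height of the lumen band, pixels.
#' @param wall_thickness thickness of each bright wall layer, pixels.
#' @param wall_brightness,lumen_brightness mean intensities in `[0, 1]` of
#'   the wall layers and the lumen.
#' @param n_plaques number of plaques attached to the vessel walls.
#' @param plaque_axis_range `c(min, max)` plaque semi-axes in pixels; the
#'   vertical semi-axis is additionally capped at `lumen_half_thickness`
#'   so plaques never leave the vessel.
#' @param speckle_shape gamma shape of the unit-mean multiplicative
#'   speckle; larger values mean weaker speckle (the coefficient of
#'   variation is `1/sqrt(speckle_shape)`).
#' @param shadow_prob probability of a vertical acoustic-shadow column.
#' @param artifact_prob probability of a bright horizontal artifact streak.
#' @param seed RNG seed making the sample fully deterministic.
#' @return a validated `phantom_params` list.
#' @export
phantom_params <- function(height = 128L, width = 128L,
                           lumen_center_frac = 0.5,
                           lumen_half_thickness = 20L,
                           wall_thickness = 8L,
                           wall_brightness = 0.85,
                           lumen_brightness = 0.05,
                           n_plaques = 2L,
                           plaque_axis_range = c(8L, 18L),
                           speckle_shape = 4,
                           shadow_prob = 0.3,
                           artifact_prob = 0.3,
                           seed = 1L) {
  p <- list(height = as.integer(height), width = as.integer(width),
            lumen_center_frac = lumen_center_frac,
            lumen_half_thickness = as.integer(lumen_half_thickness),
            wall_thickness = as.integer(wall_thickness),
            wall_brightness = wall_brightness,
            lumen_brightness = lumen_brightness,
            n_plaques = as.integer(n_plaques),
            plaque_axis_range = as.integer(plaque_axis_range),
            speckle_shape = speckle_shape,
            shadow_prob = shadow_prob, artifact_prob = artifact_prob,
            seed = as.integer(seed))
  validate_phantom_params(p)
  class(p) <- "phantom_params"
  p
}

validate_phantom_params <- function(p) {
  if (p$height < 32L || p$width < 32L)
    stop("phantom must be at least 32 x 32 pixels", call. = FALSE)
  if (p$lumen_half_thickness <= 0L ||
      p$lumen_half_thickness >= p$height / 2)
    stop("need 0 < lumen_half_thickness < height/2", call. = FALSE)
  lc <- round(p$lumen_center_frac * p$height)
  if (lc - p$lumen_half_thickness - p$wall_thickness < 1L ||
      lc + p$lumen_half_thickness + p$wall_thickness > p$height)
    stop("vessel walls fall outside the frame; shrink lumen or walls",
         call. = FALSE)
  if (length(p$plaque_axis_range) != 2L ||
      any(p$plaque_axis_range < 1L) || diff(p$plaque_axis_range) < 0L)
    stop("plaque_axis_range must be increasing positive c(min, max)",
         call. = FALSE)
  if (p$plaque_axis_range[1] > p$lumen_half_thickness)
    stop("plaque semi-axes must fit inside the lumen half-thickness",
         call. = FALSE)
  for (f in c("wall_brightness", "lumen_brightness"))
    if (p[[f]] < 0 || p[[f]] > 1)
      stop(f, " must lie in [0, 1]", call. = FALSE)
  for (f in c("shadow_prob", "artifact_prob"))
    if (p[[f]] < 0 || p[[f]] > 1)
      stop(f, " must be a probability", call. = FALSE)
  if (p$speckle_shape <= 0) stop("speckle_shape must be > 0", call. = FALSE)
  if (p$n_plaques < 0L) stop("n_plaques must be >= 0", call. = FALSE)
  invisible(p)
}

#' Generate one synthetic ultrasound phantom
#'
#' Builds a clean longitudinal vessel scene (background tissue, bright
#' near/far wall layers, dark lumen, plaques attached to the walls),
#' optionally adds an acoustic-shadow column and a bright artifact streak,
#' then multiplies by unit-mean gamma speckle and clips to `[0, 1]`.
#' Deterministic for a fixed `params$seed`.
#'
#' @param params a [phantom_params()] object.
#' @return list with `image` (H x W matrix in `[0, 1]`), `plaque_mask` and
#'   `vessel_mask` (binary H x W matrices); the plaque mask is a subset of
#'   the vessel mask by construction.
#' @export
generate_phantom <- function(params) {
  validate_phantom_params(params)
  set.seed(params$seed)
  H <- params$height; W <- params$width
  lc <- as.integer(round(params$lumen_center_frac * H))
  lt <- params$lumen_half_thickness
  wt <- params$wall_thickness

  rows <- matrix(seq_len(H), H, W)
  cols <- matrix(seq_len(W), H, W, byrow = TRUE)

  ## background tissue with a slow horizontal brightness drift
  img <- 0.30 + 0.05 * sin(2 * pi * cols / W + stats::runif(1, 0, 2 * pi))

  near_wall <- rows >= lc - lt - wt & rows <= lc - lt - 1L
  far_wall  <- rows >= lc + lt + 1L & rows <= lc + lt + wt
  lumen     <- rows >= lc - lt & rows <= lc + lt
  img[near_wall | far_wall] <- params$wall_brightness
  img[lumen] <- params$lumen_brightness

  vessel_mask <- (rows >= lc - lt - wt & rows <= lc + lt + wt) * 1

  plaque_mask <- matrix(0, H, W)
  if (params$n_plaques > 0L) {
    ar <- params$plaque_axis_range
    for (i in seq_len(params$n_plaques)) {
      on_near <- stats::runif(1) < 0.5
      a <- stats::runif(1, ar[1], ar[2])                 # along the vessel
      b <- stats::runif(1, ar[1], min(ar[2], lt))        # into the lumen
      c0 <- stats::runif(1, a + 1, W - a)
      r0 <- if (on_near) lc - lt else lc + lt            # wall-lumen interface
      ell <- ((rows - r0) / b)^2 + ((cols - c0) / a)^2 <= 1
      ## plaques live strictly inside the vessel band
      ell <- ell & vessel_mask == 1
      plaque_int <- (params$wall_brightness + params$lumen_brightness) / 2 +
        stats::runif(1, -0.08, 0.08)
      img[ell] <- plaque_int
      plaque_mask[ell] <- 1
    }
  }

  if (stats::runif(1) < params$shadow_prob) {
    sw <- max(4L, W %/% 10L)
    s0 <- sample.int(W - sw, 1L)
    img[, s0:(s0 + sw - 1L)] <- img[, s0:(s0 + sw - 1L)] * 0.35
  }
  if (stats::runif(1) < params$artifact_prob) {
    ah <- 2L
    a0 <- sample.int(H - ah, 1L)
    img[a0:(a0 + ah - 1L), ] <-
      pmin(img[a0:(a0 + ah - 1L), ] + 0.35, 1)
  }

  speckle <- matrix(stats::rgamma(H * W, shape = params$speckle_shape,
                                  rate = params$speckle_shape), H, W)
  img <- pmin(pmax(img * speckle, 0), 1)

  list(image = img, plaque_mask = plaque_mask, vessel_mask = vessel_mask)
}

#' Generate a seeded phantom dataset
#'
#' Per-sample seeds are drawn reproducibly from the master seed, so two
#' calls with the same arguments return identical datasets.
#'
#' @param n number of samples (`>= 1`).
#' @param params template [phantom_params()]; the `seed` field is replaced
#'   per sample.
#' @param seed master seed.
#' @return list of `n` phantom samples.
#' @export
generate_dataset <- function(n, params = phantom_params(), seed = 1L) {
  if (n < 1L) stop("n must be >= 1", call. = FALSE)
  set.seed(seed)
  seeds <- sample.int(.Machine$integer.max, n)
  lapply(seeds, function(s) {
    params$seed <- s
    generate_phantom(params)
  })
}

#' Write a phantom dataset as 8-bit PNG triplets
#'
#' Files are named `img_%03d.png`, `plaque_%03d.png`, `vessel_%03d.png`;
#' masks are stored as 0/255.
#'
#' @param samples list of phantom samples.
#' @param dir output directory (created if missing).
#' @export
write_phantom_dataset <- function(samples, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (i in seq_along(samples)) {
    s <- samples[[i]]
    png::writePNG(s$image, file.path(dir, sprintf("img_%03d.png", i)))
    png::writePNG(s$plaque_mask, file.path(dir, sprintf("plaque_%03d.png", i)))
    png::writePNG(s$vessel_mask, file.path(dir, sprintf("vessel_%03d.png", i)))
  }
  invisible(dir)
}

#' Read a phantom dataset written by [write_phantom_dataset()]
#'
#' @param dir directory of PNG triplets.
#' @return list of phantom samples.
#' @export
read_phantom_dataset <- function(dir) {
  imgs <- sort(list.files(dir, "^img_[0-9]+\\.png$", full.names = TRUE))
  if (!length(imgs)) stop("no img_*.png files in ", dir, call. = FALSE)
  lapply(imgs, function(f) {
    idx <- sub("^img_", "", basename(f))
    list(image = png::readPNG(f),
         plaque_mask = round(png::readPNG(file.path(dir, paste0("plaque_", idx)))),
         vessel_mask = round(png::readPNG(file.path(dir, paste0("vessel_", idx)))))
  })
}
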