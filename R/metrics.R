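##
## Segmentation evaluation suite: Dice, IoU, pixel accuracy, modified
## Hausdorff distance on boundary point sets, plaque area / area error,
## Bland-Altman agreement and paired t-tests with Bonferroni correction.
##
## Empty-mask conventions: an empty-vs-empty pair scores Dice = IoU = 1
## (perfect agreement); empty-vs-nonempty scores 0; the MHD is undefined
## without boundary points and is reported as NA with a warning by the
## record-level wrapper.
##

check_mask_pair <- function(L, S) {
  if (!identical(dim(L), dim(S)))
    stop("masks are not aligned", call. = FALSE)
  check_binary(L, "ground-truth mask")
  check_binary(S, "segmentation mask")
  invisible(TRUE)
}

#' Dice coefficient of two binary masks
#'
#' `Dice = 2|L intersect S| / (|L| + |S|)`; 1 when both masks are empty.
#'
#' @param L ground-truth binary mask.
#' @param S segmentation binary mask, same dimensions.
#' @export
dice <- function(L, S) {
  check_mask_pair(L, S)
  denom <- sum(L) + sum(S)
  if (denom == 0) return(1)
  2 * sum(L * S) / denom
}

#' Intersection over union (Jaccard index)
#'
#' `IoU = |L intersect S| / (|L| + |S| - |L intersect S|)`, identically
#' `Dice / (2 - Dice)`; 1 when both masks are empty.
#'
#' @inheritParams dice
#' @export
iou <- function(L, S) {
  check_mask_pair(L, S)
  inter <- sum(L * S)
  denom <- sum(L) + sum(S) - inter
  if (denom == 0) return(1)
  inter / denom
}

#' Pixel accuracy
#'
#' Fraction of pixels on which the two masks agree,
#' `(TP + TN) / (TP + TN + FP + FN)`, computed over the full frame.
#'
#' @inheritParams dice
#' @export
accuracy <- function(L, S) {
  check_mask_pair(L, S)
  mean(L == S)
}

#' Boundary point set of a binary mask
#'
#' The inner 4-connectivity boundary: mask pixels with at least one
#' background pixel among their 4-neighbours, where the image border
#' counts as background.
#'
#' @param mask binary matrix.
#' @return integer matrix with columns `row`, `col` (0 rows if the mask is
#'   empty).
#' @export
extract_boundary <- function(mask) {
  check_binary(mask)
  H <- nrow(mask); W <- ncol(mask)
  pad <- matrix(0, H + 2L, W + 2L)
  pad[2:(H + 1L), 2:(W + 1L)] <- mask
  core <- pad[2:(H + 1L), 2:(W + 1L)]
  nb_min <- pmin(pad[1:H, 2:(W + 1L)], pad[3:(H + 2L), 2:(W + 1L)],
                 pad[2:(H + 1L), 1:W], pad[2:(H + 1L), 3:(W + 2L)])
  boundary <- core == 1 & nb_min == 0
  which(boundary, arr.ind = TRUE) |>
    `colnames<-`(c("row", "col"))
}

#' Modified Hausdorff distance between two boundary point sets
#'
#' `MHD = max(d(Lb, Sb), d(Sb, Lb))`, where `d(A, B)` is the mean over
#' points of `A` of the minimum Euclidean distance to `B`.  Symmetric, 0
#' iff the point sets are equal.
#'
#' @param Lb,Sb nonempty point matrices with columns `row`, `col` (as from
#'   [extract_boundary()]).
#' @return the distance in pixels.
#' @export
mhd <- function(Lb, Sb) {
  if (is.null(dim(Lb))) Lb <- matrix(Lb, ncol = 2)
  if (is.null(dim(Sb))) Sb <- matrix(Sb, ncol = 2)
  if (nrow(Lb) == 0L || nrow(Sb) == 0L)
    stop("MHD is undefined for an empty boundary point set", call. = FALSE)
  d2 <- outer(Lb[, 1], Sb[, 1], "-")^2 + outer(Lb[, 2], Sb[, 2], "-")^2
  d_ls <- mean(sqrt(apply(d2, 1, min)))
  d_sl <- mean(sqrt(apply(d2, 2, min)))
  max(d_ls, d_sl)
}

#' Plaque area of a mask
#'
#' Pixel count times the squared pixel spacing; with the default spacing
#' of 1 the area is in px^2, with a calibrated spacing in mm/pixel it is
#' in mm^2.
#'
#' @param mask binary matrix.
#' @param pixel_spacing pixel size (mm/pixel), `> 0`.
#' @export
plaque_area <- function(mask, pixel_spacing = 1) {
  check_binary(mask)
  if (pixel_spacing <= 0) stop("pixel_spacing must be > 0", call. = FALSE)
  sum(mask) * pixel_spacing^2
}

#' Bland-Altman agreement between ground-truth and predicted areas
#'
#' @param areas_gt,areas_pred equal-length numeric vectors of paired areas.
#' @return list with `differences` (pred - gt), `means`, `bias` (mean
#'   difference), `loa` (bias +/- 1.96 SD limits of agreement) and
#'   `abs_pct_error` (|difference| / ground truth; pairs with zero ground
#'   truth are dropped with a warning).
#' @export
bland_altman <- function(areas_gt, areas_pred) {
  if (length(areas_gt) != length(areas_pred))
    stop("paired area lists must have equal length", call. = FALSE)
  d <- areas_pred - areas_gt
  bias <- mean(d)
  s <- stats::sd(d)
  if (is.na(s)) s <- 0   # single pair
  ok <- areas_gt != 0
  if (any(!ok))
    warning(sum(!ok), " pair(s) with zero ground-truth area excluded from ",
            "percentage errors")
  list(differences = d,
       means = (areas_gt + areas_pred) / 2,
       bias = bias,
       loa = c(lower = bias - 1.96 * s, upper = bias + 1.96 * s),
       abs_pct_error = abs(d[ok]) / areas_gt[ok])
}

#' Paired t-test with Bonferroni correction
#'
#' Two-sided paired t-test between two metric vectors; the p-value is
#' multiplied by the number of comparisons and capped at 1.  Identical
#' inputs return 1; a zero-variance nonzero difference is degenerate and
#' returns NA with a warning.
#'
#' @param metric_a,metric_b equal-length paired samples (`n >= 2`).
#' @param n_comparisons number of tests in the family.
#' @return the corrected p-value.
#' @export
paired_ttest_bonferroni <- function(metric_a, metric_b, n_comparisons = 1L) {
  if (length(metric_a) != length(metric_b) || length(metric_a) < 2L)
    stop("need equal-length paired samples with n >= 2", call. = FALSE)
  d <- metric_a - metric_b
  if (diff(range(d)) <= 1e-12 * (1 + abs(mean(d)))) {  # constant differences
    if (abs(mean(d)) <= 1e-12) return(1)
    warning("zero-variance nonzero differences: t-test degenerate")
    return(NA_real_)
  }
  p <- stats::t.test(metric_a, metric_b, paired = TRUE)$p.value
  min(1, p * n_comparisons)
}

#' Per-image metric record
#'
#' Computes Dice, IoU, accuracy, MHD and plaque-area error for one
#' ground-truth / prediction mask pair.
#'
#' @param gt,pred aligned binary masks.
#' @param pixel_spacing mm/pixel (1 reports areas in px^2).
#' @return one-row data.frame with columns `dice`, `iou`, `acc`, `mhd`,
#'   `area_gt`, `area_pred`, `delta_tpa`.
#' @export
evaluate_masks <- function(gt, pred, pixel_spacing = 1) {
  check_mask_pair(gt, pred)
  m <- NA_real_
  if (sum(gt) > 0 && sum(pred) > 0) {
    m <- mhd(extract_boundary(gt), extract_boundary(pred)) * pixel_spacing
  } else if (xor(sum(gt) > 0, sum(pred) > 0)) {
    warning("one mask is empty; MHD undefined, reported as NA")
  }
  data.frame(dice = dice(gt, pred), iou = iou(gt, pred),
             acc = accuracy(gt, pred), mhd = m,
             area_gt = plaque_area(gt, pixel_spacing),
             area_pred = plaque_area(pred, pixel_spacing),
             delta_tpa = plaque_area(pred, pixel_spacing) -
               plaque_area(gt, pixel_spacing))
}
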