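# Image-derived readouts: nuclei segmentation, cytoplasmic granule
# detection, per-field statistics and compartment partition coefficients.
# Images are plain numeric matrices (one channel, y x x); EBImage supplies
# the filtering, thresholding and labelling primitives.

# threshold a smoothed/enhanced image: Otsu on the min-max normalized
# image (making counts invariant to linear intensity rescaling), or a
# fixed value applied to the raw filtered image
threshold_mask <- function(img, threshold) {
  if (is.numeric(threshold)) return(img > threshold)
  if (!identical(threshold, "otsu")) {
    stop("`threshold` must be \"otsu\" or a numeric value")
  }
  rng <- range(img)
  if (diff(rng) == 0) return(matrix(FALSE, nrow(img), ncol(img)))
  norm <- (img - rng[1]) / diff(rng)
  t <- EBImage::otsu(EBImage::Image(norm), range = c(0, 1))
  norm > t
}

# drop labelled regions smaller than min_area pixels, relabel compactly
filter_small <- function(labels, min_area) {
  if (max(labels) == 0L) return(labels)
  sizes <- tabulate(labels[labels > 0L])
  keep <- which(sizes >= min_area)
  remap <- integer(length(sizes))
  remap[keep] <- seq_along(keep)
  out <- labels
  out[labels > 0L] <- remap[labels[labels > 0L]]
  out
}

#' Segment nuclei from a DNA-stain channel
#'
#' Gaussian blur (sigma `blur_sigma` pixels) followed by intensity
#' thresholding and connected-component labelling; regions below
#' `min_area` pixels are discarded as noise.
#'
#' @param dna numeric matrix, DNA-stain intensities
#' @param blur_sigma Gaussian blur sigma in pixels (default 5)
#' @param threshold `"otsu"` (default) or a fixed numeric threshold applied
#'   to the blurred image
#' @param min_area minimum nucleus area in pixels (default 50)
#' @return integer label matrix (0 = background, 1..n = nuclei)
#' @export
segment_nuclei <- function(dna, blur_sigma = 5, threshold = "otsu",
                           min_area = 50) {
  stopifnot(is.matrix(dna), all(is.finite(dna)))
  if (diff(range(dna)) == 0) {
    return(matrix(0L, nrow(dna), ncol(dna)))
  }
  sm <- as.matrix(EBImage::gblur(EBImage::Image(dna), sigma = blur_sigma))
  mask <- threshold_mask(sm, threshold)
  labels <- EBImage::imageData(EBImage::bwlabel(EBImage::Image(mask * 1)))
  filter_small(matrix(as.integer(labels), nrow(dna)), min_area)
}

#' Detect cytoplasmic granules in a reporter channel
#'
#' The reporter image is unsharp-enhanced, `(img - w * blur(img)) /
#' (1 - w)` with blur sigma `unsharp_sigma` pixels and weight `w =
#' unsharp_weight`, then thresholded and labelled. Any connected component
#' touching the nuclei mask is removed, so only cytoplasmic granules
#' remain.
#'
#' @param reporter numeric matrix, granule-reporter intensities
#' @param nuclei integer/logical nuclei mask (same shape), from
#'   [segment_nuclei()]
#' @param unsharp_sigma unsharp blur sigma in pixels (default 10)
#' @param unsharp_weight unsharp weight in \[0, 1) (default 0.9)
#' @param threshold `"otsu"` or a fixed numeric threshold on the enhanced
#'   image
#' @param min_area minimum granule area in pixels (default 2)
#' @return integer label matrix of cytoplasmic granules
#' @export
detect_granules <- function(reporter, nuclei, unsharp_sigma = 10,
                            unsharp_weight = 0.9, threshold = "otsu",
                            min_area = 2) {
  stopifnot(is.matrix(reporter), all(is.finite(reporter)))
  if (!all(dim(reporter) == dim(nuclei))) {
    stop("`reporter` and `nuclei` must share dimensions")
  }
  if (unsharp_weight < 0 || unsharp_weight >= 1) {
    stop("`unsharp_weight` must be in [0, 1)")
  }
  if (diff(range(reporter)) == 0) {
    return(matrix(0L, nrow(reporter), ncol(reporter)))
  }
  blur <- as.matrix(EBImage::gblur(EBImage::Image(reporter),
                                   sigma = unsharp_sigma))
  enhanced <- (reporter - unsharp_weight * blur) / (1 - unsharp_weight)
  mask <- threshold_mask(enhanced, threshold)
  labels <- EBImage::imageData(EBImage::bwlabel(EBImage::Image(mask * 1)))
  labels <- matrix(as.integer(labels), nrow(reporter))
  # drop any component overlapping a nucleus
  in_nucleus <- unique(labels[nuclei > 0 & labels > 0L])
  if (length(in_nucleus)) labels[labels %in% in_nucleus] <- 0L
  filter_small(labels, min_area)
}

#' Granules per cell for one field of view
#'
#' @param n_granules number of cytoplasmic granules in the field
#' @param n_nuclei number of nuclei in the field
#' @return `n_granules / n_nuclei`; `NA` when no nuclei were found (the
#'   field is excluded from aggregation)
#' @export
granules_per_cell <- function(n_granules, n_nuclei) {
  stopifnot(n_granules >= 0, n_nuclei >= 0)
  if (n_nuclei < 1) return(NA_real_)
  n_granules / n_nuclei
}

#' Nuclear partition ratio of a reporter
#'
#' From the nuclear fraction of total signal a = v_n / v_t, the
#' nuclear-to-cytoplasmic partition is p = a / (1 - a).
#'
#' @param v_n summed reporter signal inside nuclei
#' @param v_t summed reporter signal over the whole field
#' @return partition ratio p (> 0)
#' @export
nuclear_partition <- function(v_n, v_t) {
  check_positive(v_t, "v_t")
  if (!is.numeric(v_n) || length(v_n) != 1L || v_n <= 0) {
    stop("`v_n` must be a single positive number")
  }
  if (v_n >= v_t) stop("nuclear signal must be smaller than total signal")
  a <- v_n / v_t
  a / (1 - a)
}

#' Percentage of cells with at least k granules
#'
#' @param counts integer vector, granules per cell
#' @param k minimum granule count (default 3)
#' @return percentage of cells with `counts >= k`
#' @export
pct_cells_with_granules <- function(counts, k = 3) {
  if (length(counts) == 0L) stop("empty count vector: percentage undefined")
  stopifnot(all(counts >= 0))
  100 * mean(counts >= k)
}

#' Compartment partition coefficients of a labelled compound
#'
#' Mean intensity of the `analog` channel in each compartment divided by
#' its mean intensity in the reference compartment (the cytoplasm
#' excluding granules and mitochondria).
#'
#' @param analog numeric matrix, labelled-compound channel
#' @param masks named list of logical matrices, pairwise disjoint; must
#'   include the reference compartment
#' @param reference name of the reference mask (default
#'   `"cytoplasm_rest"`)
#' @return named numeric vector of partition coefficients (`NA` for empty
#'   compartments); the reference maps to exactly 1
#' @export
compartment_partition <- function(analog, masks,
                                  reference = "cytoplasm_rest") {
  stopifnot(is.matrix(analog), is.list(masks))
  if (!reference %in% names(masks)) {
    stop(sprintf("reference mask '%s' missing", reference))
  }
  overlap <- Reduce(`+`, lapply(masks, function(m) m * 1))
  if (any(overlap > 1)) stop("compartment masks must be disjoint")
  ref_mask <- masks[[reference]]
  if (!any(ref_mask)) stop("reference compartment is empty")
  ref_mean <- mean(analog[ref_mask])
  vapply(masks, function(m) {
    if (!any(m)) return(NA_real_)
    mean(analog[m]) / ref_mean
  }, numeric(1))
}

#' Quantify one multichannel field of view
#'
#' Convenience wrapper: segments nuclei, detects cytoplasmic granules and
#' assembles the per-field statistics (granules per cell and nuclear
#' partition of the reporter).
#'
#' @param dna DNA-stain channel (matrix)
#' @param reporter granule-reporter channel (matrix, same shape)
#' @param ... passed on to [segment_nuclei()] and [detect_granules()]
#'   (matched by name: `blur_sigma`, `threshold`, `min_area` apply to
#'   nuclei; `unsharp_sigma`, `unsharp_weight`, `granule_threshold`,
#'   `granule_min_area` to granules)
#' @return data.frame with one row: `n_nuclei`, `n_granules`,
#'   `granules_per_cell`, `nuclear_fraction`, `nuclear_partition`
#' @export
quantify_field <- function(dna, reporter, ...) {
  args <- list(...)
  nuclei <- segment_nuclei(
    dna,
    blur_sigma = args$blur_sigma %||% 5,
    threshold = args$threshold %||% "otsu",
    min_area = args$min_area %||% 50)
  granules <- detect_granules(
    reporter, nuclei,
    unsharp_sigma = args$unsharp_sigma %||% 10,
    unsharp_weight = args$unsharp_weight %||% 0.9,
    threshold = args$granule_threshold %||% "otsu",
    min_area = args$granule_min_area %||% 2)
  n_nuc <- max(nuclei)
  n_gra <- max(granules)
  v_n <- sum(reporter[nuclei > 0])
  v_t <- sum(reporter)
  a <- if (v_t > 0) v_n / v_t else NA_real_
  p <- if (!is.na(a) && a > 0 && a < 1) a / (1 - a) else NA_real_
  data.frame(n_nuclei = n_nuc, n_granules = n_gra,
             granules_per_cell = granules_per_cell(n_gra, n_nuc),
             nuclear_fraction = a, nuclear_partition = p)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
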