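#' Dice Similarity Coefficient of two binary masks
#'
#' Relative overlap `2 * |A intersect R| / (|A| + |R|)` between an automatic
#' and a reference segmentation mask. Defined as 1 when both masks are empty
#' (two empty segmentations agree perfectly).
#'
#' @param a_mask,r_mask 0/1 matrices of identical shape.
#' @return Coefficient in [0, 1].
#' @export
dice <- function(a_mask, r_mask) {
  if (!identical(dim(a_mask), dim(r_mask))) {
    stop("masks must have identical shape", call. = FALSE)
  }
  na <- sum(a_mask > 0)
  nr <- sum(r_mask > 0)
  if (na + nr == 0L) return(1)
  2 * sum(a_mask > 0 & r_mask > 0) / (na + nr)
}

#' Physical volume of a binary mask
#'
#' Counts the foreground voxels and multiplies by the voxel volume
#' `spacing^2 * thickness` (isotropic in-plane spacing; a 2D mask is one
#' slice of the stated thickness).
#'
#' @param mask 0/1 matrix.
#' @param spacing in-plane pixel spacing in mm.
#' @param thickness slice thickness in mm.
#' @return Volume in mm^3.
#' @export
mask_volume <- function(mask, spacing = 1, thickness = 1) {
  stopifnot(spacing > 0, thickness > 0)
  sum(mask > 0) * spacing^2 * thickness
}

#' Summary statistics of a metric column
#'
#' Minimum, maximum, mean and sample standard deviation (n - 1 denominator;
#' `NA` for a single value) of a numeric vector, as a one-row tibble.
#'
#' @param values numeric vector (length >= 1).
#' @return Tibble with columns `n`, `min`, `max`, `mean`, `sd`.
#' @export
summarize_metrics <- function(values) {
  if (length(values) == 0L) stop("empty value list", call. = FALSE)
  tibble::tibble(
    n = length(values),
    min = min(values),
    max = max(values),
    mean = mean(values),
    sd = if (length(values) > 1L) stats::sd(values) else NA_real_
  )
}

#' Reference vertebra segmentation benchmark
#'
#' Published per-vertebra evaluation of the template graph-cut scheme on
#' nine vertebrae from spine MRI: manual and automatic segmentation volumes,
#' voxel counts and Dice Similarity Coefficients. Used as a worked example
#' for the evaluation arithmetic (volume = voxels x voxel volume; summary
#' rows); the underlying images are not redistributed. The voxel volume
#' implied by the table is `417.236 / 1709 = 0.244140625` mm^3 per voxel.
#'
#' @return Tibble with columns `vertebra`, `volume_manual_mm3`,
#'   `volume_auto_mm3`, `voxels_manual`, `voxels_auto`, `dsc_pct`.
#' @export
vertebra_benchmark <- function() {
  tibble::tibble(
    vertebra = 1:9,
    volume_manual_mm3 = c(417.236, 438.721, 461.914, 457.275, 510.498,
                          430.908, 404.541, 414.795, 247.803),
    volume_auto_mm3 = c(378.662, 397.705, 427.49, 439.453, 490.723,
                        481.201, 402.832, 377.686, 242.92),
    voxels_manual = c(1709L, 1797L, 1892L, 1873L, 2091L, 1765L, 1657L,
                      1699L, 1015L),
    voxels_auto = c(1551L, 1629L, 1751L, 1800L, 2010L, 1971L, 1650L,
                    1547L, 995L),
    dsc_pct = c(90.78, 90.83, 88.99, 92.02, 93.05, 87.37, 90.35, 90.39, 94.93)
  )
}

#' Evaluate an automatic mask against a reference mask
#'
#' One-row evaluation report: voxel counts, physical volumes and Dice
#' coefficient, in the package's standard CSV column layout.
#'
#' @param a_mask,r_mask 0/1 matrices of identical shape.
#' @param spacing,thickness voxel geometry in mm (see [mask_volume()]).
#' @param id identifier recorded in the report row.
#' @return Tibble with columns `id`, `n_voxels_auto`, `n_voxels_ref`,
#'   `volume_auto_mm3`, `volume_ref_mm3`, `dsc`.
#' @export
evaluate_masks <- function(a_mask, r_mask, spacing = 1, thickness = 1,
                           id = "mask") {
  tibble::tibble(
    id = id,
    n_voxels_auto = sum(a_mask > 0),
    n_voxels_ref = sum(r_mask > 0),
    volume_auto_mm3 = mask_volume(a_mask, spacing, thickness),
    volume_ref_mm3 = mask_volume(r_mask, spacing, thickness),
    dsc = dice(a_mask, r_mask)
  )
}
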