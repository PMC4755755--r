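#' Vascularized area from a pre/post-contrast T2*-w pair
#'
#' Counts voxels that are hypointense on the post-contrast volume inside the
#' ROI but not hypointense pre-contrast: vessels fill with susceptibility
#' contrast only after injection, whereas microbleeds and calcifications are
#' dark on both scans and must be excluded. The default threshold is the
#' mean minus two standard deviations of the intensities outside the ROI.
#'
#' @param pre,post co-registered [image_stack()]s on the same grid.
#' @param roi logical array of the same shape.
#' @param hypo_threshold intensity below which a voxel counts as
#'   hypointense; `NULL` for the outside-ROI `mean - 2 SD` default.
#' @return A `vascularized_area_result`: `area_mm2` (total),
#'   `area_mm2_per_slice`, `included_voxel_count`,
#'   `excluded_precontrast_voxel_count`, `threshold_used`, and the logical
#'   `included` map.
#' @export
vascularized_area <- function(pre, post, roi, hypo_threshold = NULL) {
  stopifnot_stack(pre); stopifnot_stack(post)
  if (!identical(dim(pre$values), dim(post$values))) {
    stop("pre and post volumes must share one grid")
  }
  if (!identical(dim(roi), dim(post$values))) stop("roi shape mismatch")
  if (any(abs(pre$spacing - post$spacing) > 1e-9)) {
    stop("pre and post volumes must share one voxel spacing")
  }
  if (is.null(hypo_threshold)) {
    outside <- post$values[!roi]
    if (length(outside) < 2) stop("cannot derive threshold: ROI covers grid")
    hypo_threshold <- mean(outside) - 2 * sd(outside)
  }
  hypo_post <- post$values < hypo_threshold
  hypo_pre <- pre$values < hypo_threshold
  included <- hypo_post & roi & !hypo_pre
  excluded <- hypo_post & roi & hypo_pre
  vox_area_mm2 <- prod(post$spacing[1:2]) / 1e6  # um^2 -> mm^2 in-plane
  d <- dim(post$values)
  per_slice <- if (length(d) == 3) {
    vapply(seq_len(d[3]), function(k) sum(included[, , k]) * vox_area_mm2,
           numeric(1))
  } else sum(included) * vox_area_mm2
  structure(list(area_mm2 = sum(included) * vox_area_mm2,
                 area_mm2_per_slice = per_slice,
                 included_voxel_count = sum(included),
                 excluded_precontrast_voxel_count = sum(excluded),
                 threshold_used = hypo_threshold,
                 included = included),
            class = "vascularized_area_result")
}

#' @export
print.vascularized_area_result <- function(x, ...) {
  cat(sprintf("<vascularized_area> %.4f mm^2 (%d voxels; %d excluded pre-contrast), threshold %.4g\n",
              x$area_mm2, x$included_voxel_count,
              x$excluded_precontrast_voxel_count, x$threshold_used))
  invisible(x)
}

#' Histogram normalization of tumor intensities against an outside region
#'
#' Normalizes using the reference formula
#' \deqn{(\mathrm{mean~voxel~intensity}_{tumor} -
#'   \mathrm{intensity}_{outside}) / SD,}
#' where the mean and SD are taken over the outside (healthy) region: the
#' scalar summary is \eqn{(\mu_{tumor}-\mu_{outside})/SD_{outside}} and the
#' per-voxel scores are \eqn{z_v = (I_v - \mu_{outside})/SD_{outside}} for
#' each tumor voxel (both returned, since the printed formula is a scalar
#' while histograms need the voxelwise version).
#'
#' @param volume an [image_stack()].
#' @param tumor_roi,outside_roi nonempty logical arrays of the volume's
#'   shape.
#' @return A `histogram_norm`: `summary`, `normalized_values` (tumor
#'   voxels), `tumor_mean`, `outside_mean`, `outside_sd`.
#' @export
histogram_normalize <- function(volume, tumor_roi, outside_roi) {
  stopifnot_stack(volume)
  v <- volume$values
  if (!identical(dim(tumor_roi), dim(v)) ||
      !identical(dim(outside_roi), dim(v))) stop("roi shape mismatch")
  if (!any(tumor_roi) || !any(outside_roi)) stop("empty ROI")
  mu_out <- mean(v[outside_roi])
  sd_out <- sd(v[outside_roi])
  if (is.na(sd_out) || sd_out == 0) stop("outside ROI has zero SD")
  tum <- v[tumor_roi]
  structure(list(summary = (mean(tum) - mu_out) / sd_out,
                 normalized_values = (tum - mu_out) / sd_out,
                 tumor_mean = mean(tum), outside_mean = mu_out,
                 outside_sd = sd_out),
            class = "histogram_norm")
}

#' @export
print.histogram_norm <- function(x, ...) {
  cat(sprintf("<histogram_norm> summary %.4f (tumor mean %.4g vs outside %.4g +/- %.4g)\n",
              x$summary, x$tumor_mean, x$outside_mean, x$outside_sd))
  invisible(x)
}

#' Tissue-clearing shrinkage report
#'
#' Solvent-based clearing dehydrates the specimen and shrinks it roughly
#' uniformly; comparing maximum brain dimensions measured before and after
#' clearing gives per-axis linear scale factors, whose mean is the
#' correction factor by which cleared-tissue morphometry (lengths, radii)
#' can be multiplied to recover in-vivo scale. Uniformity shows up as the
#' pre/post length-to-width ratios agreeing.
#'
#' @param pre_dims numeric `(length, width)` before clearing, cm.
#' @param post_dims numeric `(length, width)` after clearing, cm.
#' @return A `shrinkage_report`: per-axis factors, `correction_factor`
#'   (their mean), per-axis percent linear reduction, and the pre/post
#'   length/width ratios.
#' @export
shrinkage_report <- function(pre_dims, post_dims) {
  if (length(pre_dims) != 2 || length(post_dims) != 2) {
    stop("expected (length, width) pairs")
  }
  if (any(pre_dims <= 0) || any(post_dims <= 0)) {
    stop("dimensions must be positive")
  }
  length_factor <- pre_dims[1] / post_dims[1]
  width_factor <- pre_dims[2] / post_dims[2]
  structure(list(
    pre_length = pre_dims[1], pre_width = pre_dims[2],
    post_length = post_dims[1], post_width = post_dims[2],
    length_factor = length_factor, width_factor = width_factor,
    correction_factor = mean(c(length_factor, width_factor)),
    linear_reduction_pct = c(length = 100 * (1 - post_dims[1] / pre_dims[1]),
                             width = 100 * (1 - post_dims[2] / pre_dims[2])),
    volume_reduction_pct =
      100 * (1 - (post_dims[1] / pre_dims[1]) * (post_dims[2] / pre_dims[2])^2),
    pre_ratio = pre_dims[1] / pre_dims[2],
    post_ratio = post_dims[1] / post_dims[2]),
    class = "shrinkage_report")
}

#' @export
print.shrinkage_report <- function(x, ...) {
  cat(sprintf(paste0(
    "<shrinkage_report> correction factor %.3f ",
    "(length %.3f, width %.3f)\n",
    "  linear reduction %.1f%% / %.1f%%; ratio pre %.3f vs post %.3f\n"),
    x$correction_factor, x$length_factor, x$width_factor,
    x$linear_reduction_pct[1], x$linear_reduction_pct[2],
    x$pre_ratio, x$post_ratio))
  invisible(x)
}

#' Correlate MR and ultramicroscopy readouts
#'
#' Ordinary least-squares regression of paired per-animal (or per-region)
#' values from the two modalities; the coefficient of determination is the
#' squared Pearson correlation.
#'
#' @param mr_values,um_values paired numeric vectors (>= 3 pairs), or a
#'   two-column matrix/data.frame as the first argument.
#' @return List with `r_squared`, `slope`, `intercept`, `p_value`, `n`.
#' @export
correlate_mr_um <- function(mr_values, um_values = NULL) {
  if (is.null(um_values)) {
    stopifnot(ncol(mr_values) == 2)
    um_values <- mr_values[, 2]
    mr_values <- mr_values[, 1]
  }
  if (length(mr_values) != length(um_values)) stop("length mismatch")
  if (length(mr_values) < 3) stop("need at least 3 pairs")
  if (sd(mr_values) == 0 || sd(um_values) == 0) {
    stop("zero variance in one coordinate")
  }
  fit <- lm(um_values ~ mr_values)
  s <- summary(fit)
  list(r_squared = s$r.squared,
       slope = unname(coef(fit)[2]),
       intercept = unname(coef(fit)[1]),
       p_value = unname(s$coefficients[2, 4]),
       n = length(mr_values))
}
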