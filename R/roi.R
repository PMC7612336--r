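# Per-impact summary metrics: whole-brain 90th percentile of the voxelized
# strain and strain-rate fields, per-ROI means over the atlas labels, and
# the collapse to one sulcal and one gyral mean per impact.

#' Whole-brain 90th percentile of a voxel field
#'
#' The per-impact severity scalar: the 90th percentile of in-mask voxel
#' values (robust to abnormally large strains in poorly shaped elements),
#' using linear interpolation between closest order statistics (index
#' 0.9 * (n - 1)).
#'
#' @param field A [voxel_field()] (or bare numeric array).
#' @param mask Logical array congruent with the field; selects brain voxels.
#' @return Scalar 90th percentile.
#' @export
percentile_90 <- function(field, mask) {
  data <- if (inherits(field, "voxel_field")) field$data else field
  if (!any(mask)) stop("`mask` selects no voxels", call. = FALSE)
  stopifnot(length(mask) == length(data))
  unname(stats::quantile(data[mask], 0.9, type = 7))
}

#' Per-ROI mean of a voxel field
#'
#' Arithmetic mean of voxel values within each atlas label. Labels with zero
#' voxels are absent from the result, not reported as zero; the background
#' label 0 is never reported.
#'
#' @param field A [voxel_field()].
#' @param atlas_field Integer-label [voxel_field()] congruent with `field`
#'   (same grid shape and affine).
#' @return Tibble with `label`, `mean` and `n_voxels`.
#' @export
roi_means <- function(field, atlas_field) {
  stopifnot(inherits(field, "voxel_field"), inherits(atlas_field, "voxel_field"))
  if (!identical(dim(field$data), dim(atlas_field$data)) ||
      max(abs(field$affine - atlas_field$affine)) > 1e-6)
    stop("field and atlas volumes are not congruent (grid or affine mismatch)",
         call. = FALSE)
  lab <- as.integer(atlas_field$data)
  keep <- lab != 0L
  agg <- tibble::tibble(label = lab[keep], value = as.numeric(field$data)[keep]) |>
    dplyr::group_by(.data$label) |>
    dplyr::summarise(mean = mean(.data$value), n_voxels = dplyr::n(),
                     .groups = "drop")
  agg
}

#' Collapse per-ROI means to sulcal and gyral summary means
#'
#' Unweighted mean over ROI means within each class (each region counts
#' once, mirroring per-region averaging before the class collapse); the
#' voxel-weighted alternative is also computed and returned alongside.
#'
#' @param roi A tibble from [roi_means()].
#' @param region_table Region table (`label`, `name`, `class`) from the
#'   [build_sulcal_mesh()] atlas.
#' @return One-row tibble: `sulcal_mean`, `gyral_mean` (ROI-weighted) and
#'   `sulcal_mean_vox`, `gyral_mean_vox` (voxel-weighted).
#' @export
collapse_sulcal_gyral <- function(roi, region_table) {
  d <- dplyr::inner_join(roi, region_table, by = "label") |>
    dplyr::filter(.data$class %in% c("sulcal", "gyral"))
  cls <- unique(d$class)
  if (!all(c("sulcal", "gyral") %in% cls))
    stop("need at least one ROI of each class (sulcal, gyral); missing: ",
         paste(setdiff(c("sulcal", "gyral"), cls), collapse = ", "),
         call. = FALSE)
  s <- d |>
    dplyr::group_by(.data$class) |>
    dplyr::summarise(roi_wt = mean(.data$mean),
                     vox_wt = sum(.data$mean * .data$n_voxels) /
                       sum(.data$n_voxels), .groups = "drop")
  tibble::tibble(
    sulcal_mean = s$roi_wt[s$class == "sulcal"],
    gyral_mean = s$roi_wt[s$class == "gyral"],
    sulcal_mean_vox = s$vox_wt[s$class == "sulcal"],
    gyral_mean_vox = s$vox_wt[s$class == "gyral"])
}

#' Summarize one impact's voxel fields
#'
#' Computes the whole-brain 90th percentiles and the sulcal/gyral class
#' means of strain and strain rate for one impact.
#'
#' @param vox Output of [rasterize_impact()] for the impact.
#' @param region_table Region table from the atlas.
#' @param event_id Identifier carried into the result.
#' @return One-row tibble with `event_id`, `p90_strain`, `p90_strain_rate`,
#'   `sulcal_mean_strain`, `gyral_mean_strain`, `sulcal_mean_strain_rate`,
#'   `gyral_mean_strain_rate` and a list-column `roi` of per-ROI means.
#' @export
impact_summary <- function(vox, region_table, event_id = NA_character_) {
  roi_s <- roi_means(vox$strain, vox$atlas)
  roi_r <- roi_means(vox$strain_rate, vox$atlas)
  col_s <- collapse_sulcal_gyral(roi_s, region_table)
  col_r <- collapse_sulcal_gyral(roi_r, region_table)
  roi <- dplyr::inner_join(
    dplyr::rename(roi_s, mean_strain = "mean"),
    dplyr::rename(roi_r, mean_strain_rate = "mean")[, c("label", "mean_strain_rate")],
    by = "label") |>
    dplyr::inner_join(region_table, by = "label")
  tibble::tibble(
    event_id = event_id,
    p90_strain = percentile_90(vox$strain, vox$brain_mask),
    p90_strain_rate = percentile_90(vox$strain_rate, vox$brain_mask),
    sulcal_mean_strain = col_s$sulcal_mean,
    gyral_mean_strain = col_s$gyral_mean,
    sulcal_mean_strain_rate = col_r$sulcal_mean,
    gyral_mean_strain_rate = col_r$gyral_mean,
    sulcal_mean_strain_vox = col_s$sulcal_mean_vox,
    gyral_mean_strain_vox = col_s$gyral_mean_vox,
    roi = list(roi))
}

#' Assemble the cohort table
#'
#' One row per impact joining profile membership, peak kinematics and the
#' per-impact strain summaries.
#'
#' @param events List of `impact_event`s (or a [cohort_manifest()] tibble).
#' @param summaries Tibble of stacked [impact_summary()] rows, one per
#'   event, keyed by `event_id`.
#' @return Tibble of class `cohort_table`.
#' @export
summarize_cohort <- function(events, summaries) {
  manifest <- if (is.data.frame(events)) events else cohort_manifest(events)
  if (nrow(manifest) == 0) {
    out <- dplyr::bind_cols(manifest, summaries[0, -1, drop = FALSE])
  } else {
    missing <- setdiff(manifest$event_id, summaries$event_id)
    if (length(missing))
      stop("missing strain summaries for events: ",
           paste(utils::head(missing, 5), collapse = ", "), call. = FALSE)
    out <- dplyr::inner_join(manifest, summaries, by = "event_id")
  }
  class(out) <- c("cohort_table", class(out))
  out
}

#' Per-profile aggregation in the published layout
#'
#' Mean and SD of each kinematic and deformation measure per exposure
#' profile (rows: measures; columns: profiles), the layout of the published
#' per-profile summary table.
#'
#' @param cohort A `cohort_table`.
#' @return Tibble with `measure` and one `mean (sd)` pair of columns per
#'   profile, plus a tidy long-format attribute-free alternative via
#'   `tidy = TRUE`.
#' @param tidy If `TRUE`, return the long format (profile, measure, mean, sd, n).
#' @export
profile_table <- function(cohort, tidy = FALSE) {
  measures <- c(p90_strain = "90th Percentile Strain",
                p90_strain_rate = "90th Percentile Strain rate (1/s)",
                peak_lin_vel = "Linear Velocity (m/s)",
                peak_lin_acc = "Linear Acceleration (m/s^2)",
                peak_rot_vel = "Rotational Velocity (rad/s)",
                peak_rot_acc = "Rotational Acceleration (rad/s^2)")
  measures <- measures[names(measures) %in% names(cohort)]
  long <- cohort |>
    tidyr::pivot_longer(dplyr::all_of(names(measures)), names_to = "measure") |>
    dplyr::group_by(.data$profile, .data$measure) |>
    dplyr::summarise(mean = mean(.data$value), sd = stats::sd(.data$value),
                     n = dplyr::n(), .groups = "drop") |>
    dplyr::mutate(measure_label = measures[.data$measure])
  if (tidy) return(long)
  long |>
    dplyr::mutate(cell = sprintf("%.3g ± %.3g", .data$mean, .data$sd),
                  profile = sprintf("Profile %d (n = %d)", .data$profile,
                                    .data$n)) |>
    dplyr::select("measure_label", "profile", "cell") |>
    tidyr::pivot_wider(names_from = "profile", values_from = "cell") |>
    dplyr::rename(measure = "measure_label")
}
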