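# Reference-scaled readouts: static-window SUVr and VTr maps and per-region
# cohort readout tables.

#' Static-window SUVr map
#'
#' Duration-weighted mean image over the static window (default the
#' 20-40 min window, i.e. `[1200, 2400)` s by frame midpoint), divided
#' voxel-wise by the mean of that static image over the reference mask.
#'
#' @param img A [dynamic_image()].
#' @param reference_mask Logical 3D array.
#' @param window Static window `[t0, t1)` in seconds.
#' @return A [static_image()] with quantity `"SUVr"`.
#' @export
suvr_map <- function(img, reference_mask, window = c(1200, 2400)) {
  stopifnot(inherits(img, "dynamic_image"))
  if (!any(reference_mask)) .stop_validation("reference mask is empty")
  frames <- frames_in_window(img$schedule, window[1], window[2])
  static <- time_weighted_mean_image(img, frames)
  ref <- mean(static$voxels[reference_mask])
  if (!is.finite(ref) || ref <= 0)
    .stop_validation("reference mean is nonpositive")
  static_image(static$voxels / ref, img$spacing_mm, "SUVr")
}

#' VT-ratio map
#'
#' A VT parametric map divided voxel-wise by its mean over the reference
#' mask (`NA` sentinel voxels excluded from the reference mean).
#'
#' @param vt A [static_image()] with quantity `"VT"`.
#' @param reference_mask Logical 3D array.
#' @return A [static_image()] with quantity `"VTr"`.
#' @export
vtr_map <- function(vt, reference_mask) {
  stopifnot(inherits(vt, "static_image"))
  if (!any(reference_mask)) .stop_validation("reference mask is empty")
  ref <- mean(vt$voxels[reference_mask], na.rm = TRUE)
  if (!is.finite(ref) || ref <= 0)
    .stop_validation("reference mean is nonpositive")
  static_image(vt$voxels / ref, vt$spacing_mm, "VTr")
}

#' Cohort readout table
#'
#' Computes one row per subject with every requested
#' `target x reference x measure` readout. Readout columns are named
#' `<target>_<measure>_<reference>`. SUVr readouts come from the dynamic
#' images; VTr readouts from the supplied VT maps. Bilateral targets are
#' handled by the voxel-weighted mean over the (merged) target label.
#'
#' @param cohort A `phantom_cohort` / `phantom_vt_cohort`, or a list with
#'   `subjects` ([cohort_table()]) plus `images` and/or `vt_maps` named by
#'   subject id.
#' @param atlas A [label_atlas()].
#' @param references Named list of logical reference masks (or atlas region
#'   names).
#' @param targets Character vector of target region names.
#' @param measures Subset of `c("suvr", "vtr")`.
#' @param window Static SUVr window in seconds.
#' @return A [cohort_table()] with the readout columns appended. Subjects
#'   with missing images/maps are dropped; their ids are reported in the
#'   `skipped` attribute.
#' @export
cohort_readouts <- function(cohort, atlas, references, targets,
                            measures = c("suvr", "vtr"),
                            window = c(1200, 2400)) {
  measures <- match.arg(measures, several.ok = TRUE)
  stopifnot(inherits(atlas, "label_atlas"), length(targets) >= 1)
  subjects <- cohort$subjects
  ref_masks <- lapply(references, function(r)
    if (is.character(r)) atlas_mask(atlas, r) else r)
  if (is.null(names(ref_masks)) || any(names(ref_masks) == ""))
    .stop_validation("references must be named")
  tmask <- lapply(targets, function(tn) atlas_mask(atlas, tn))
  names(tmask) <- targets
  skipped <- character(0)
  rows <- list()
  for (i in seq_len(nrow(subjects))) {
    id <- subjects$id[i]
    vals <- list()
    ok <- TRUE
    for (ms in measures) {
      if (ms == "suvr") {
        img <- cohort$images[[id]]
        if (is.null(img)) { ok <- FALSE; break }
        for (rn in names(ref_masks)) {
          smap <- suvr_map(img, ref_masks[[rn]], window)
          for (tn in targets)
            vals[[paste(tn, "suvr", rn, sep = "_")]] <-
              mean(smap$voxels[tmask[[tn]]], na.rm = TRUE)
        }
      } else {
        vt <- cohort$vt_maps[[id]]
        if (is.null(vt)) { ok <- FALSE; break }
        for (rn in names(ref_masks)) {
          vmap <- vtr_map(vt, ref_masks[[rn]])
          for (tn in targets)
            vals[[paste(tn, "vtr", rn, sep = "_")]] <-
              mean(vmap$voxels[tmask[[tn]]], na.rm = TRUE)
        }
      }
    }
    if (!ok) { skipped <- c(skipped, id); next }
    rows[[id]] <- cbind(subjects[i, , drop = FALSE],
                        as.data.frame(vals, check.names = FALSE))
  }
  if (length(skipped))
    warning("petref: skipped subjects with missing data: ",
            paste(skipped, collapse = ", "), call. = FALSE)
  if (!length(rows)) .stop_validation("no subject had complete data")
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out <- cohort_table(out)
  attr(out, "skipped") <- skipped
  out
}
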