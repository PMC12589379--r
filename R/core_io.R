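# Domain types and shared infrastructure: frame schedules, dynamic / static
# images, label atlases, cohort tables, mask morphology and ROI readouts.

.stop_validation <- function(...) {
  stop(structure(class = c("petref_validation_error", "error", "condition"),
                 list(message = paste0(...), call = sys.call(-1))))
}
.stop_format <- function(...) {
  stop(structure(class = c("petref_format_error", "error", "condition"),
                 list(message = paste0(...), call = sys.call(-1))))
}
.stop_extraction <- function(...) {
  stop(structure(class = c("petref_extraction_failure", "error", "condition"),
                 list(message = paste0(...), call = sys.call(-1))))
}

# ---- frame schedule ---------------------------------------------------------

#' Construct a frame schedule
#'
#' A frame schedule describes a dynamic PET acquisition as contiguous,
#' non-overlapping frames: start times and durations in seconds, the first
#' frame starting at injection (t = 0).
#'
#' @param start_s Frame start times in seconds.
#' @param duration_s Frame durations in seconds.
#' @return An object of class `frame_schedule` with fields `start_s`,
#'   `duration_s` and `mid_s` (frame midpoints).
#' @export
frame_schedule <- function(start_s, duration_s) {
  start_s <- as.numeric(start_s); duration_s <- as.numeric(duration_s)
  if (length(start_s) != length(duration_s))
    .stop_format("start_s and duration_s differ in length")
  if (length(start_s) < 1L) .stop_validation("empty frame schedule")
  if (any(duration_s <= 0)) .stop_validation("all frame durations must be > 0")
  if (start_s[1] != 0) .stop_validation("first frame must start at 0 s")
  if (length(start_s) > 1L) {
    gaps <- start_s[-1] - (start_s[-length(start_s)] + duration_s[-length(duration_s)])
    if (any(abs(gaps) > 1e-6))
      .stop_validation("frames must be contiguous and non-overlapping")
  }
  structure(list(start_s = start_s, duration_s = duration_s,
                 mid_s = start_s + duration_s / 2),
            class = "frame_schedule")
}

#' @export
length.frame_schedule <- function(x) length(x$start_s)

#' @export
print.frame_schedule <- function(x, ...) {
  cat(sprintf("frame_schedule: %d frames, 0-%g s\n", length(x),
              x$start_s[length(x)] + x$duration_s[length(x)]))
  invisible(x)
}

#' Default 60-minute, 35-frame acquisition schedule
#'
#' The standard dynamic tau-PET framing used throughout the package:
#' 12 x 5 s, 6 x 10 s, 3 x 20 s, 7 x 60 s, 4 x 300 s and 3 x 600 s,
#' totalling 3600 s over 35 frames.
#'
#' @return A [frame_schedule()].
#' @export
default_frame_schedule <- function() {
  durations <- c(rep(5, 12), rep(10, 6), rep(20, 3),
                 rep(60, 7), rep(300, 4), rep(600, 3))
  frame_schedule(cumsum(c(0, durations[-length(durations)])), durations)
}

#' Frames whose midpoint falls in a time window
#'
#' Selects frame indices by the frame-midpoint convention on the half-open
#' window `[t0_s, t1_s)`.
#'
#' @param schedule A [frame_schedule()].
#' @param t0_s,t1_s Window bounds in seconds, `t0_s < t1_s`.
#' @return Integer frame indices (1-based).
#' @export
frames_in_window <- function(schedule, t0_s, t1_s) {
  stopifnot(inherits(schedule, "frame_schedule"))
  if (!(t0_s < t1_s)) .stop_validation("need t0_s < t1_s")
  idx <- which(schedule$mid_s >= t0_s & schedule$mid_s < t1_s)
  if (length(idx) == 0L)
    .stop_validation("no frame midpoint falls in [", t0_s, ", ", t1_s, ")")
  idx
}

# ---- images -----------------------------------------------------------------

#' Construct a dynamic (4D) PET image
#'
#' @param voxels 4D numeric array (x, y, z, frame), decay-corrected
#'   activity-concentration values (SUV scale assumed but not enforced).
#' @param spacing_mm Voxel edge lengths in mm (length 3).
#' @param schedule A [frame_schedule()] whose length matches the 4th
#'   dimension of `voxels`.
#' @return An object of class `dynamic_image`.
#' @export
dynamic_image <- function(voxels, spacing_mm, schedule) {
  stopifnot(inherits(schedule, "frame_schedule"))
  d <- dim(voxels)
  if (length(d) != 4L) .stop_format("voxels must be a 4D array")
  if (d[4] != length(schedule))
    .stop_format("frame count (", d[4], ") does not match schedule length (",
                 length(schedule), ")")
  if (any(!is.finite(voxels))) .stop_validation("non-finite voxel values")
  structure(list(voxels = voxels, spacing_mm = as.numeric(spacing_mm),
                 schedule = schedule),
            class = "dynamic_image")
}

#' Construct a static (3D) image or parametric map
#'
#' @param voxels 3D numeric array.
#' @param spacing_mm Voxel edge lengths in mm.
#' @param quantity One of `"SUV"`, `"SUVr"`, `"VT"`, `"VTr"`, `"tstat"`.
#' @return An object of class `static_image`.
#' @export
static_image <- function(voxels, spacing_mm,
                         quantity = c("SUV", "SUVr", "VT", "VTr", "tstat")) {
  quantity <- match.arg(quantity)
  if (length(dim(voxels)) != 3L) .stop_format("voxels must be a 3D array")
  structure(list(voxels = voxels, spacing_mm = as.numeric(spacing_mm),
                 quantity = quantity),
            class = "static_image")
}

#' @export
print.dynamic_image <- function(x, ...) {
  d <- dim(x$voxels)
  cat(sprintf("dynamic_image: %dx%dx%d voxels, %d frames, spacing %s mm\n",
              d[1], d[2], d[3], d[4], paste(x$spacing_mm, collapse = "x")))
  invisible(x)
}

#' Read a dynamic PET image with its frame-timing sidecar
#'
#' The sidecar is a BIDS-PET-style JSON file with keys `FrameTimesStart` and
#' `FrameDuration` (both seconds), of equal length matching the image's 4th
#' dimension.
#'
#' @param image_path NIfTI-1 4D image path.
#' @param sidecar_path JSON sidecar path.
#' @return A [dynamic_image()].
#' @export
read_dynamic_image <- function(image_path, sidecar_path) {
  nii <- read_nifti(image_path)
  if (length(dim(nii$data)) != 4L)
    .stop_format("expected a 4D image: ", image_path)
  sc <- jsonlite::fromJSON(sidecar_path)
  if (is.null(sc$FrameTimesStart) || is.null(sc$FrameDuration))
    .stop_format("sidecar missing FrameTimesStart/FrameDuration: ", sidecar_path)
  if (length(sc$FrameTimesStart) != length(sc$FrameDuration) ||
      length(sc$FrameDuration) != dim(nii$data)[4])
    .stop_format("sidecar frame timing does not match image frame count")
  dynamic_image(nii$data, nii$spacing_mm,
                frame_schedule(sc$FrameTimesStart, sc$FrameDuration))
}

#' Write a dynamic PET image and its frame-timing sidecar
#'
#' @param img A [dynamic_image()].
#' @param image_path Output NIfTI path.
#' @param sidecar_path Output JSON sidecar path.
#' @return `image_path`, invisibly.
#' @export
write_dynamic_image <- function(img, image_path, sidecar_path) {
  stopifnot(inherits(img, "dynamic_image"))
  write_nifti(img$voxels, image_path, img$spacing_mm)
  jsonlite::write_json(
    list(FrameTimesStart = img$schedule$start_s,
         FrameDuration = img$schedule$duration_s),
    sidecar_path, digits = NA)
  invisible(image_path)
}

# ---- label atlas ------------------------------------------------------------

.atlas_roles <- c("target", "candidate_reference", "conventional_reference",
                  "carotid_segment", "cortical_target", "other")

#' Construct a label atlas
#'
#' An integer-labelled parcellation (0 = background) with a label table
#' assigning each label a name and a role. Roles mark how the pipeline uses
#' a region: `target` (patient-vs-control readout region),
#' `candidate_reference` (reference-search family), `conventional_reference`,
#' `carotid_segment` (restriction mask for IDIF extraction),
#' `cortical_target`, `other`.
#'
#' @param labels 3D integer array.
#' @param table data.frame with columns `label`, `name`, `role`.
#' @param spacing_mm Voxel edge lengths in mm.
#' @return An object of class `label_atlas`.
#' @export
label_atlas <- function(labels, table, spacing_mm) {
  if (length(dim(labels)) != 3L) .stop_format("labels must be a 3D array")
  stopifnot(all(c("label", "name", "role") %in% names(table)))
  if (!all(table$role %in% .atlas_roles))
    .stop_validation("unknown atlas role(s): ",
                     paste(setdiff(table$role, .atlas_roles), collapse = ", "))
  present <- sort(unique(as.vector(labels)))
  present <- present[present != 0]
  missing <- setdiff(present, table$label)
  if (length(missing))
    .stop_validation("labels present in volume but absent from table: ",
                     paste(missing, collapse = ", "))
  if (anyDuplicated(table$label)) .stop_validation("duplicate labels in table")
  structure(list(labels = labels, table = table,
                 spacing_mm = as.numeric(spacing_mm)),
            class = "label_atlas")
}

#' @export
print.label_atlas <- function(x, ...) {
  cat(sprintf("label_atlas: %d labelled regions on a %s grid\n",
              nrow(x$table), paste(dim(x$labels), collapse = "x")))
  print(x$table, row.names = FALSE)
  invisible(x)
}

#' Binary mask of one atlas region (by label or name)
#' @param atlas A [label_atlas()].
#' @param label Integer label or region name.
#' @return Logical 3D array.
#' @export
atlas_mask <- function(atlas, label) {
  stopifnot(inherits(atlas, "label_atlas"))
  if (is.character(label)) {
    i <- match(label, atlas$table$name)
    if (is.na(i)) .stop_validation("no atlas region named '", label, "'")
    label <- atlas$table$label[i]
  }
  if (!label %in% atlas$table$label)
    .stop_validation("label ", label, " not in atlas table")
  atlas$labels == label
}

#' Region names carrying a given atlas role
#' @param atlas A [label_atlas()].
#' @param role One of the atlas roles (see [label_atlas()]).
#' @return Character vector of region names.
#' @export
atlas_regions_by_role <- function(atlas, role) {
  stopifnot(inherits(atlas, "label_atlas"), role %in% .atlas_roles)
  atlas$table$name[atlas$table$role == role]
}

#' Read / write a label atlas (NIfTI labels + TSV table)
#'
#' The table is tab-separated with a header row (`label`, `name`, `role`).
#'
#' @param labels_path NIfTI path of the integer label volume.
#' @param table_path TSV path of the label table.
#' @return A [label_atlas()].
#' @export
read_label_atlas <- function(labels_path, table_path) {
  nii <- read_nifti(labels_path)
  tab <- utils::read.delim(table_path, stringsAsFactors = FALSE)
  label_atlas(array(as.integer(round(nii$data)), dim = dim(nii$data)),
              tab, nii$spacing_mm)
}

#' @rdname read_label_atlas
#' @param atlas A [label_atlas()].
#' @export
write_label_atlas <- function(atlas, labels_path, table_path) {
  stopifnot(inherits(atlas, "label_atlas"))
  write_nifti(atlas$labels, labels_path, atlas$spacing_mm, datatype = "int32")
  utils::write.table(atlas$table, table_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(labels_path)
}

# ---- cohort table -----------------------------------------------------------

#' Construct a cohort table
#'
#' One row per subject: `id`, `group`, `age`, `sex` (`"m"`/`"f"`), optional
#' `severity` (clinical rating-scale analogue, `NA` allowed) and optional
#' `split` (`"discovery"` / `"validation"`). Further columns are treated as
#' per-subject scalar readouts.
#'
#' @param df data.frame with the columns above.
#' @return A data.frame of class `cohort_table`.
#' @export
cohort_table <- function(df) {
  req <- c("id", "group", "age", "sex")
  if (!all(req %in% names(df)))
    .stop_format("cohort table needs columns: ", paste(req, collapse = ", "))
  if (anyDuplicated(df$id)) .stop_validation("duplicate subject ids")
  if (any(df$age <= 0)) .stop_validation("ages must be > 0")
  if (!all(df$sex %in% c("m", "f"))) .stop_validation("sex must be 'm' or 'f'")
  if (!is.null(df$severity) && any(!is.na(df$severity) & df$severity < 0))
    .stop_validation("severity must be nonnegative or missing")
  class(df) <- c("cohort_table", "data.frame")
  df
}

#' Read / write a cohort table as TSV
#'
#' Missing severity is encoded as an empty field.
#'
#' @param path TSV path.
#' @return A [cohort_table()].
#' @export
read_cohort_table <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE,
                          colClasses = c(id = "character"))
  cohort_table(df)
}

#' @rdname read_cohort_table
#' @param tab A [cohort_table()].
#' @export
write_cohort_table <- function(tab, path) {
  utils::write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     na = "")
  invisible(path)
}

# ---- frame arithmetic and morphology ---------------------------------------

#' Duration-weighted mean over selected frames
#'
#' Averages the selected frames of a dynamic image, weighting each frame by
#' its duration (the exact time average of a frame-wise-constant signal).
#'
#' @param img A [dynamic_image()].
#' @param frames Nonempty integer frame indices.
#' @return A [static_image()] with quantity `"SUV"`.
#' @export
time_weighted_mean_image <- function(img, frames) {
  stopifnot(inherits(img, "dynamic_image"))
  if (length(frames) == 0L) .stop_validation("frames must be nonempty")
  w <- img$schedule$duration_s[frames]
  w <- w / sum(w)
  d <- dim(img$voxels)
  acc <- array(0, d[1:3])
  for (k in seq_along(frames))
    acc <- acc + w[k] * img$voxels[, , , frames[k]]
  static_image(acc, img$spacing_mm, "SUV")
}

.sphere_offsets <- function(radius_mm, spacing_mm) {
  r_vox <- pmax(0L, as.integer(floor(radius_mm / spacing_mm)))
  g <- expand.grid(dx = -r_vox[1]:r_vox[1], dy = -r_vox[2]:r_vox[2],
                   dz = -r_vox[3]:r_vox[3])
  d2 <- (g$dx * spacing_mm[1])^2 + (g$dy * spacing_mm[2])^2 +
        (g$dz * spacing_mm[3])^2
  g[d2 <= radius_mm^2 + 1e-9, , drop = FALSE]
}

.shift_mask <- function(mask, off) {
  d <- dim(mask)
  out <- array(FALSE, d)
  sx <- seq_len(d[1]); sy <- seq_len(d[2]); sz <- seq_len(d[3])
  fx <- sx + off[1]; fy <- sy + off[2]; fz <- sz + off[3]
  okx <- fx >= 1 & fx <= d[1]; oky <- fy >= 1 & fy <= d[2]
  okz <- fz >= 1 & fz <= d[3]
  out[sx[okx], sy[oky], sz[okz]] <- mask[fx[okx], fy[oky], fz[okz]]
  out
}

#' Erode a binary mask with a spherical structuring element
#'
#' Binary erosion with a discrete sphere of the given physical radius: a
#' voxel survives iff every voxel offset whose Euclidean distance (in mm)
#' is `<= radius_mm` lies inside the input mask. Voxels outside the volume
#' count as background, so the mask also erodes at the volume border.
#'
#' @param mask Logical (or 0/1) 3D array.
#' @param radius_mm Erosion radius in mm (`>= 0`; 0 is the identity).
#' @param spacing_mm Voxel edge lengths in mm.
#' @return Logical 3D array, a subset of `mask`. Warns if the result is
#'   empty.
#' @export
erode_mask <- function(mask, radius_mm, spacing_mm = c(1, 1, 1)) {
  if (radius_mm < 0) .stop_validation("radius_mm must be >= 0")
  mask <- array(as.logical(mask), dim = dim(mask))
  offs <- .sphere_offsets(radius_mm, spacing_mm)
  out <- mask
  for (i in seq_len(nrow(offs))) {
    off <- as.integer(offs[i, ])
    if (all(off == 0L)) next
    out <- out & .shift_mask(mask, off)
  }
  if (!any(out))
    warning("petref: erosion produced an empty mask", call. = FALSE)
  out
}

#' Dilate a binary mask with a spherical structuring element
#' @inheritParams erode_mask
#' @return Logical 3D array, a superset of `mask`.
#' @export
dilate_mask <- function(mask, radius_mm, spacing_mm = c(1, 1, 1)) {
  if (radius_mm < 0) .stop_validation("radius_mm must be >= 0")
  mask <- array(as.logical(mask), dim = dim(mask))
  offs <- .sphere_offsets(radius_mm, spacing_mm)
  out <- mask
  for (i in seq_len(nrow(offs))) {
    off <- as.integer(offs[i, ])
    if (all(off == 0L)) next
    out <- out | .shift_mask(mask, off)
  }
  out
}

#' Mean of a map over one atlas region
#'
#' @param map A [static_image()] (or parametric map).
#' @param atlas A [label_atlas()].
#' @param label Integer label or region name.
#' @return Scalar mean of the map over the region's voxels (`NA` sentinel
#'   voxels are excluded).
#' @export
region_mean <- function(map, atlas, label) {
  stopifnot(inherits(map, "static_image"))
  m <- atlas_mask(atlas, label)
  if (!any(m)) .stop_validation("region has no voxels: ", label)
  mean(map$voxels[m], na.rm = TRUE)
}

#' Mean of a map over an arbitrary binary mask
#' @param map A [static_image()].
#' @param mask Logical 3D array.
#' @return Scalar mean.
#' @export
mask_mean <- function(map, mask) {
  stopifnot(inherits(map, "static_image"))
  if (!any(mask)) .stop_validation("empty mask")
  mean(map$voxels[mask], na.rm = TRUE)
}
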