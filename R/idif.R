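# Image-derived input function extraction: spatial ICA over early frames,
# template-correlation component selection, segment masking + thresholding,
# erosion, and per-frame maximum extraction from the carotid mask.

#' Spatial ICA of a dynamic image
#'
#' Decomposes the frames-x-voxels matrix (restricted to an analysis mask
#' and, by default, to early frames where blood-borne signal dominates)
#' into spatially independent component maps using fixed-point symmetric
#' FastICA with the logcosh contrast. Each component map is zero-mean,
#' unit-variance over the mask and sign-aligned so its peak absolute
#' loading is positive. Deterministic given `seed`.
#'
#' @param img A [dynamic_image()].
#' @param analysis_mask Logical 3D array of voxels to decompose.
#' @param n_components Number of components (default 10).
#' @param seed Integer seed for the random orthogonal initialization.
#' @param early_window_s Restrict to frames with midpoint below this time
#'   (default 300 s); `Inf` uses all frames.
#' @param max_iter,tol Fixed-point iteration controls.
#' @return An object of class `ica_result`: `maps` (list of 3D arrays,
#'   zero outside the mask), `timecourses` (frames x components mixing
#'   matrix), `n_components`, `frames` (indices used).
#' @export
run_spatial_ica <- function(img, analysis_mask, n_components = 10L, seed = 1L,
                            early_window_s = 300, max_iter = 200L,
                            tol = 1e-6) {
  stopifnot(inherits(img, "dynamic_image"))
  if (!any(analysis_mask)) .stop_validation("analysis_mask is empty")
  frames <- which(img$schedule$mid_s < early_window_s)
  if (length(frames) == 0L) frames <- seq_along(img$schedule$mid_s)
  if (n_components >= length(frames))
    .stop_validation("n_components (", n_components,
                     ") must be below the number of frames used (",
                     length(frames), ")")
  d <- dim(img$voxels)
  idx <- which(analysis_mask)
  X <- matrix(img$voxels, prod(d[1:3]), d[4])[idx, frames, drop = FALSE]
  X <- t(X)                                   # frames x voxels
  X <- X - rowMeans(X)
  # whiten via SVD; drop near-null directions (rank deficiency)
  sv <- svd(X, nu = length(frames), nv = 0)
  keep <- sv$d > max(sv$d) * 1e-8
  if (sum(keep) < n_components) {
    warning("petref: data rank ", sum(keep), " below requested ",
            n_components, " components; reducing", call. = FALSE)
    n_components <- sum(keep)
  }
  K <- diag(1 / sv$d[1:n_components], n_components) %*%
    t(sv$u[, 1:n_components, drop = FALSE]) * sqrt(ncol(X))
  Z <- K %*% X                                # n_comp x voxels, whitened
  set.seed(seed)
  W <- qr.Q(qr(matrix(stats::rnorm(n_components^2), n_components)))
  sym_decorrelate <- function(W) {
    e <- eigen(W %*% t(W), symmetric = TRUE)
    e$vectors %*% diag(1 / sqrt(e$values), n_components) %*%
      t(e$vectors) %*% W
  }
  W <- sym_decorrelate(W)
  p <- ncol(Z)
  for (it in seq_len(max_iter)) {
    WZ <- W %*% Z
    G <- tanh(WZ)
    gprime <- rowMeans(1 - G^2)
    W1 <- G %*% t(Z) / p - diag(gprime, n_components) %*% W
    W1 <- sym_decorrelate(W1)
    delta <- max(abs(abs(rowSums(W1 * W)) - 1))
    W <- W1
    if (delta < tol) break
  }
  S <- W %*% Z                                # component maps (unit variance)
  # sign-align: peak |loading| positive
  signs <- apply(S, 1, function(s) sign(s[which.max(abs(s))]))
  S <- S * signs
  # mixing matrix (frames x components): X ~ A %*% S with S = W K X
  A <- sv$u[, 1:n_components, drop = FALSE] %*%
    diag(sv$d[1:n_components] / sqrt(p), n_components) %*% t(W)
  A <- A * rep(signs, each = nrow(A))
  maps <- lapply(seq_len(n_components), function(k) {
    vol <- array(0, d[1:3])
    vol[idx] <- S[k, ]
    vol
  })
  structure(list(maps = maps, timecourses = A,
                 n_components = n_components, frames = frames,
                 mask = analysis_mask),
            class = "ica_result")
}

#' Select the carotid component by template correlation
#'
#' Returns the component whose absolute spatial map correlates best
#' (Pearson, over the analysis mask) with a binary carotid template.
#' Correlation on absolute loadings makes selection sign-invariant.
#'
#' @param ica An [run_spatial_ica()] result.
#' @param template_mask Logical 3D array on the image grid.
#' @param min_correlation Extraction fails below this floor (default 0.1).
#' @return A list: `component` (index), `correlation`.
#' @export
select_carotid_component <- function(ica, template_mask,
                                     min_correlation = 0.1) {
  stopifnot(inherits(ica, "ica_result"))
  idx <- which(ica$mask)
  tpl <- as.numeric(template_mask[idx])
  if (stats::sd(tpl) == 0)
    .stop_validation("template empty (or full) within the analysis mask")
  cors <- vapply(ica$maps, function(m) {
    v <- abs(m[idx])
    if (stats::sd(v) == 0) return(-Inf)
    stats::cor(v, tpl)
  }, numeric(1))
  best <- which.max(cors)
  if (!is.finite(cors[best]) || cors[best] < min_correlation)
    .stop_extraction("no component correlates with the carotid template ",
                     "(best r = ", signif(max(cors), 3), ")")
  list(component = best, correlation = cors[best])
}

#' Binarize a component map within the carotid segment
#'
#' Standardizes the component loadings over the analysis mask and keeps
#' voxels with z-loading at or above `z_thresh`, intersected with the
#' carotid segment mask.
#'
#' @param map 3D component map (from [run_spatial_ica()]).
#' @param segment_mask Logical 3D array restricting the carotid to its
#'   upper cervical segment.
#' @param z_thresh Loading threshold in SD units (default 2).
#' @param analysis_mask Logical mask the loadings live on.
#' @return An object of class `carotid_mask`: `mask` (pre-erosion logical
#'   array), `z_thresh`.
#' @export
binarize_and_restrict <- function(map, segment_mask, z_thresh = 2,
                                  analysis_mask = NULL) {
  if (z_thresh <= 0) .stop_validation("z_thresh must be > 0")
  if (is.null(analysis_mask)) analysis_mask <- array(TRUE, dim(map))
  v <- map[analysis_mask]
  s <- stats::sd(v)
  if (!is.finite(s) || s == 0)
    .stop_extraction("degenerate (uniform) component map")
  z <- array(0, dim(map))
  z[analysis_mask] <- (v - mean(v)) / s
  m <- z >= z_thresh & segment_mask & analysis_mask
  if (!any(m))
    .stop_extraction("no suprathreshold carotid voxels within the segment")
  structure(list(mask = m, z_thresh = z_thresh), class = "carotid_mask")
}

#' Extract the IDIF from a carotid mask
#'
#' Erodes the carotid mask to shed vessel-wall voxels (falling back to the
#' pre-erosion mask with a warning if erosion empties it), then takes the
#' per-frame maximum voxel value inside the mask at every frame midpoint.
#'
#' @param img A [dynamic_image()].
#' @param mask A `carotid_mask` (from [binarize_and_restrict()]) or a
#'   logical 3D array.
#' @param erosion_voxels Erosion amount in voxels (default 1; 0 disables).
#' @param statistic `"max"` (default) or a percentile in (0, 100) applied
#'   per frame instead of the plain maximum.
#' @return An [input_function()] with source `"idif"`; attributes
#'   `mask_voxels` (post-erosion count) and `eroded` (logical).
#' @export
extract_idif <- function(img, mask, erosion_voxels = 1L, statistic = "max") {
  stopifnot(inherits(img, "dynamic_image"))
  m <- if (inherits(mask, "carotid_mask")) mask$mask else mask
  if (!any(m)) .stop_extraction("empty carotid mask")
  eroded <- m
  if (erosion_voxels > 0) {
    eroded <- suppressWarnings(
      erode_mask(m, erosion_voxels * min(img$spacing_mm), img$spacing_mm))
    if (!any(eroded)) {
      warning("petref: erosion emptied the carotid mask; using pre-erosion mask",
              call. = FALSE)
      eroded <- m
    }
  }
  d <- dim(img$voxels)
  vmat <- matrix(img$voxels, prod(d[1:3]), d[4])[which(eroded), , drop = FALSE]
  vals <- if (identical(statistic, "max")) {
    apply(vmat, 2, max)
  } else {
    stopifnot(is.numeric(statistic), statistic > 0, statistic < 100)
    apply(vmat, 2, stats::quantile, probs = statistic / 100, names = FALSE)
  }
  out <- input_function(img$schedule$mid_s, vals, "idif")
  attr(out, "mask_voxels") <- sum(eroded)
  attr(out, "eroded") <- !identical(eroded, m)
  out
}

#' Full automated IDIF extraction
#'
#' Chains [run_spatial_ica()], [select_carotid_component()],
#' [binarize_and_restrict()] and [extract_idif()] with the package
#' defaults, returning the IDIF together with QC information.
#'
#' @param img A [dynamic_image()].
#' @param segment_mask Logical carotid-segment restriction mask.
#' @param template_mask Logical carotid template mask.
#' @param analysis_mask Logical analysis mask (default: segment and
#'   template neighbourhood plus every nonzero-signal voxel).
#' @param n_components,seed,early_window_s Passed to [run_spatial_ica()].
#' @param z_thresh,erosion_voxels Passed to the masking stages.
#' @return A list: `idif` ([input_function()]), `qc` (selected component,
#'   template correlation, mask voxel counts).
#' @export
idif_pipeline <- function(img, segment_mask, template_mask,
                          analysis_mask = NULL, n_components = 10L,
                          seed = 1L, early_window_s = 300,
                          z_thresh = 2, erosion_voxels = 1L) {
  if (is.null(analysis_mask)) {
    # default: voxels with appreciable late-scan signal (tissue + vessels),
    # excluding empty background that would only add noise dimensions
    d <- dim(img$voxels)
    late <- rowMeans(matrix(img$voxels, prod(d[1:3]), d[4]))
    analysis_mask <- array(late > 0.05 * max(late), d[1:3])
  }
  ica <- run_spatial_ica(img, analysis_mask, n_components, seed,
                         early_window_s)
  sel <- select_carotid_component(ica, template_mask)
  cmask <- binarize_and_restrict(ica$maps[[sel$component]], segment_mask,
                                 z_thresh, analysis_mask)
  idif <- extract_idif(img, cmask, erosion_voxels)
  list(idif = idif,
       qc = list(component = sel$component, correlation = sel$correlation,
                 pre_erosion_voxels = sum(cmask$mask),
                 post_erosion_voxels = attr(idif, "mask_voxels"),
                 erosion_fallback = !attr(idif, "eroded") &&
                   erosion_voxels > 0))
}
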