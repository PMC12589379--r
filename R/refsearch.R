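# Iterative reference-region search: score every candidate white-matter
# region by the covariate-adjusted patient-vs-control separation of the
# target VT-ratio, control the family-wise error over the candidate family,
# and merge the survivors into one optimized reference mask.

#' Family-wise error adjustment
#'
#' @param p_values Raw p-values in `[0, 1]`.
#' @param method `"bonferroni"` (default) or `"holm"`.
#' @return Adjusted p-values (monotone in the input, clamped at 1).
#' @export
fwe_adjust <- function(p_values, method = c("bonferroni", "holm")) {
  method <- match.arg(method)
  if (any(p_values < 0 | p_values > 1, na.rm = TRUE))
    .stop_validation("p-values must lie in [0, 1]")
  if (method == "bonferroni") pmin(1, length(p_values) * p_values)
  else stats::p.adjust(p_values, "holm")
}

#' Score one candidate reference region
#'
#' Erodes the candidate, computes each discovery subject's target VTr
#' against the eroded candidate, and tests the two-group difference with an
#' ANCOVA adjusted for age and sex. The group statistic is signed so that
#' patient > control is positive.
#'
#' @param vt_maps Named list of VT [static_image()]s (one per subject id).
#' @param atlas A [label_atlas()].
#' @param target Target region name (e.g. `"pallidum"`).
#' @param candidate Candidate reference region name.
#' @param cohort A [cohort_table()] restricted to the two discovery groups;
#'   the patient group is the non-`"HC"` group unless `patient_group` says
#'   otherwise.
#' @param erosion_mm Erosion radius applied to the candidate (default 2).
#' @param min_voxels Candidates with fewer eroded voxels are unusable
#'   (default 10).
#' @param patient_group Optional explicit patient group label.
#' @return A one-row data.frame: candidate name, eroded voxel count, group
#'   t and p, per-group adjusted means, Cohen's d, `usable` flag.
#' @export
score_candidate <- function(vt_maps, atlas, target, candidate, cohort,
                            erosion_mm = 2, min_voxels = 10L,
                            patient_group = NULL) {
  stopifnot(inherits(atlas, "label_atlas"))
  groups <- unique(cohort$group)
  if (length(groups) != 2L)
    .stop_validation("discovery cohort must contain exactly two groups")
  if (any(table(cohort$group) < 3L))
    .stop_validation("each discovery group needs n >= 3")
  if (is.null(patient_group))
    patient_group <- if ("HC" %in% groups) setdiff(groups, "HC") else groups[1]
  cmask <- atlas_mask(atlas, candidate)
  emask <- suppressWarnings(erode_mask(cmask, erosion_mm, atlas$spacing_mm))
  nvox <- sum(emask)
  base <- data.frame(candidate = candidate, eroded_voxels = nvox,
                     t = NA_real_, p = NA_real_, p_adj = NA_real_,
                     mean_patient = NA_real_, mean_control = NA_real_,
                     cohens_d = NA_real_, usable = FALSE, selected = FALSE,
                     stringsAsFactors = FALSE)
  if (nvox < min_voxels) {
    warning("petref: candidate '", candidate, "' unusable after erosion (",
            nvox, " voxels)", call. = FALSE)
    return(base)
  }
  tmask <- atlas_mask(atlas, target)
  vtr <- vapply(cohort$id, function(id) {
    vm <- vtr_map(vt_maps[[id]], emask)
    mean(vm$voxels[tmask], na.rm = TRUE)
  }, numeric(1))
  is_pat <- cohort$group == patient_group
  fit <- ancova(vtr, factor(ifelse(is_pat, "patient", "control"),
                            levels = c("control", "patient")),
                age = cohort$age, sex = cohort$sex)
  base$t <- fit$group_t
  base$p <- fit$group_p
  base$mean_patient <- unname(fit$adjusted_means["patient"])
  base$mean_control <- unname(fit$adjusted_means["control"])
  base$cohens_d <- fit$cohens_d["patient", "control"]
  base$usable <- TRUE
  base
}

#' Search for an optimized reference region
#'
#' Scores every atlas region with role `candidate_reference` via
#' [score_candidate()], applies family-wise error control across the usable
#' family, and merges the eroded masks of the surviving candidates into one
#' reference. Refuses to run on subjects tagged `split == "validation"`.
#'
#' @inheritParams score_candidate
#' @param alpha Family-wise selection level (default 0.05).
#' @param method FWE method for [fwe_adjust()].
#' @return An object of class `reference_search_report`: `candidates`
#'   (ranked data.frame), `merged_mask` (logical array, may be empty),
#'   `n_selected`, `alpha`, `erosion_mm`, `patient_group`, `target`.
#' @export
search_reference <- function(vt_maps, atlas, target, cohort, alpha = 0.05,
                             erosion_mm = 2, min_voxels = 10L,
                             method = "bonferroni", patient_group = NULL) {
  if (!is.null(cohort$split) && any(cohort$split == "validation"))
    .stop_validation("reference search refuses subjects tagged 'validation'")
  cands <- atlas_regions_by_role(atlas, "candidate_reference")
  if (length(cands) < 2L)
    .stop_validation("atlas must flag >= 2 candidate_reference regions")
  res <- do.call(rbind, lapply(cands, function(cn)
    score_candidate(vt_maps, atlas, target, cn, cohort, erosion_mm,
                    min_voxels, patient_group)))
  usable <- which(res$usable)
  res$p_adj[usable] <- fwe_adjust(res$p[usable], method)
  res$selected <- !is.na(res$p_adj) & res$p_adj < alpha
  merged <- array(FALSE, dim(atlas$labels))
  for (cn in res$candidate[res$selected]) {
    emask <- suppressWarnings(
      erode_mask(atlas_mask(atlas, cn), erosion_mm, atlas$spacing_mm))
    merged <- merged | emask
  }
  res <- res[order(res$p), ]
  rownames(res) <- NULL
  structure(list(candidates = res, merged_mask = merged,
                 n_selected = sum(res$selected), alpha = alpha,
                 erosion_mm = erosion_mm, method = method,
                 target = target,
                 status = if (any(res$selected)) "ok" else "no_survivors"),
            class = "reference_search_report")
}

#' @export
print.reference_search_report <- function(x, ...) {
  cat(sprintf("reference_search_report: %d/%d candidates selected (alpha = %g, %s), status: %s\n",
              x$n_selected, nrow(x$candidates), x$alpha, x$method, x$status))
  print(x$candidates[c("candidate", "eroded_voxels", "t", "p", "p_adj",
                       "selected")], row.names = FALSE, digits = 4)
  invisible(x)
}
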