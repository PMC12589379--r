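# End-to-end orchestration: simulate -> IDIF -> Logan VT -> reference search
# (discovery subjects) -> quantification under searched + conventional
# references -> validation statistics -> report.

#' Pipeline run configuration
#'
#' @param spec A [phantom_spec()] describing the simulated cohort.
#' @param seed Master seed; all stage seeds derive from it.
#' @param target Target region name (default `"pallidum"`).
#' @param cortical_target Cortical readout region (default
#'   `"temporalmeta"`).
#' @param suvr_window Static window in seconds.
#' @param t_star_s Logan fit start.
#' @param erosion_mm Reference-candidate erosion radius.
#' @param alpha FWE selection level of the reference search.
#' @param z_thresh,erosion_voxels,n_components,early_window_s IDIF stage
#'   settings (see [idif_pipeline()]).
#' @param patient_group Discovery patient group (default `"PSP-RS"`).
#' @param include_voxelwise Run the permutation cluster test in validation
#'   (default `FALSE`; it dominates runtime).
#' @param n_perm Permutations for the voxel-wise test.
#' @param out_dir Optional output directory for reports and masks.
#' @return A list of class `run_config`.
#' @export
run_config <- function(spec = phantom_spec(), seed = 1L,
                       target = "pallidum", cortical_target = "temporalmeta",
                       suvr_window = c(1200, 2400), t_star_s = 900,
                       erosion_mm = 2, alpha = 0.05, z_thresh = 2,
                       erosion_voxels = 1L, n_components = 10L,
                       early_window_s = 300, patient_group = "PSP-RS",
                       include_voxelwise = FALSE, n_perm = 500L,
                       out_dir = NULL) {
  structure(list(spec = spec, seed = as.integer(seed), target = target,
                 cortical_target = cortical_target,
                 suvr_window = suvr_window, t_star_s = t_star_s,
                 erosion_mm = erosion_mm, alpha = alpha,
                 z_thresh = z_thresh, erosion_voxels = erosion_voxels,
                 n_components = n_components,
                 early_window_s = early_window_s,
                 patient_group = patient_group,
                 include_voxelwise = include_voxelwise, n_perm = n_perm,
                 out_dir = out_dir),
            class = "run_config")
}

#' Read a run configuration from a JSON file
#'
#' Keys mirror the arguments of [run_config()]; `spec` sub-keys are passed
#' to [phantom_spec()] (`grid_dim`, `spacing_mm`, `group_sizes`, `sigma0`).
#'
#' @param path JSON config path.
#' @param seed Optional seed override.
#' @return A `run_config`.
#' @export
read_run_config <- function(path, seed = NULL) {
  cfg <- jsonlite::fromJSON(path)
  spec_args <- cfg$spec
  if (!is.null(spec_args$group_sizes))
    spec_args$group_sizes <- unlist(spec_args$group_sizes)
  spec <- do.call(phantom_spec, if (is.null(spec_args)) list() else spec_args)
  cfg$spec <- NULL
  if (!is.null(seed)) cfg$seed <- seed
  do.call(run_config, c(list(spec = spec), cfg))
}

.subject_vt_pipeline <- function(cohort, ids, cfg) {
  atlas <- cohort$atlas
  seg <- atlas_mask(atlas, "carotid_segment")
  brain <- cohort$brain
  lcfg <- logan_config(cfg$t_star_s)
  vt_maps <- list(); qc <- list()
  for (id in ids) {
    img <- cohort$images[[id]]
    res <- idif_pipeline(img, seg, cohort$template,
                         analysis_mask = atlas$labels > 0,
                         n_components = cfg$n_components,
                         seed = cfg$seed, early_window_s = cfg$early_window_s,
                         z_thresh = cfg$z_thresh,
                         erosion_voxels = cfg$erosion_voxels)
    vt_maps[[id]] <- vt_map(img, res$idif, lcfg, brain)
    qc[[id]] <- c(res$qc, list(vt_failed_voxels = attr(vt_maps[[id]],
                                                       "n_failed")))
  }
  list(vt_maps = vt_maps, qc = qc)
}

#' Run the discovery stage
#'
#' Simulates the cohort (if not supplied), extracts each discovery
#' subject's IDIF, fits voxel-wise Logan VT, and runs the reference search
#' on the discovery subjects only.
#'
#' @param cfg A [run_config()].
#' @param cohort Optional pre-simulated `phantom_cohort` (must match
#'   `cfg$spec`); simulated from `cfg$seed` otherwise.
#' @return A list of class `discovery_result`: `cohort`, `vt_maps`
#'   (discovery subjects), `search` ([search_reference()] report),
#'   `merged_mask`, `qc`.
#' @export
run_discovery <- function(cfg, cohort = NULL) {
  stopifnot(inherits(cfg, "run_config"))
  if (is.null(cohort)) cohort <- simulate_cohort(cfg$spec, cfg$seed)
  subj <- cohort$subjects
  disc <- subj[subj$split == "discovery", ]
  if (!cfg$patient_group %in% disc$group)
    .stop_validation("discovery group '", cfg$patient_group,
                     "' absent from cohort")
  stage <- .subject_vt_pipeline(cohort, disc$id, cfg)
  search <- search_reference(stage$vt_maps, cohort$atlas, cfg$target,
                             cohort_table(disc), alpha = cfg$alpha,
                             erosion_mm = cfg$erosion_mm,
                             patient_group = cfg$patient_group)
  structure(list(cohort = cohort, vt_maps = stage$vt_maps, qc = stage$qc,
                 search = search, merged_mask = search$merged_mask),
            class = "discovery_result")
}

.roc_block <- function(readouts, score_col, patient_group, control_group = "HC") {
  sel <- readouts$group %in% c(patient_group, control_group)
  r <- readouts[sel, ]
  roc(r[[score_col]], r$group == patient_group)
}

#' Run the validation stage
#'
#' Quantifies every subject under both the searched (merged) and the
#' conventional reference, then computes the validation statistics: ANCOVA
#' with Tukey-adjusted pairwise comparisons and Cohen's d across all
#' groups, ROC with paired DeLong comparison of the two references for each
#' PSP-like group vs HC, and the severity regression in the pooled PSP-like
#' subjects.
#'
#' @param cfg A [run_config()].
#' @param disc A `discovery_result` from [run_discovery()] (supplies the
#'   cohort, discovery VT maps and merged reference).
#' @return A list of class `validation_result`.
#' @export
run_validation <- function(cfg, disc) {
  stopifnot(inherits(cfg, "run_config"), inherits(disc, "discovery_result"))
  if (!any(disc$merged_mask))
    .stop_validation("empty merged reference; cannot validate")
  cohort <- disc$cohort
  subj <- cohort$subjects
  val_ids <- subj$id[subj$split == "validation"]
  stage <- if (length(val_ids))
    .subject_vt_pipeline(cohort, val_ids, cfg) else
      list(vt_maps = list(), qc = list())
  vt_maps <- c(disc$vt_maps, stage$vt_maps)
  full <- cohort
  full$vt_maps <- vt_maps
  refs <- list(wm_ref = disc$merged_mask,
               cereb_ref = atlas_mask(cohort$atlas, "inferior_cerebellum"))
  readouts <- cohort_readouts(full, cohort$atlas, refs,
                              targets = c(cfg$target, cfg$cortical_target),
                              measures = c("suvr", "vtr"),
                              window = cfg$suvr_window)
  # ROC + paired DeLong per PSP-like group vs HC, per measure
  roc_tables <- list(); delong_tables <- list()
  for (pg in intersect(c("PSP-RS", "PSP-nonRS"), unique(readouts$group))) {
    for (ms in c("suvr", "vtr")) {
      key <- paste(pg, ms, sep = "_")
      col_wm <- paste(cfg$target, ms, "wm_ref", sep = "_")
      col_cb <- paste(cfg$target, ms, "cereb_ref", sep = "_")
      sel <- readouts$group %in% c(pg, "HC")
      r <- readouts[sel, ]
      lab <- r$group == pg
      rw <- roc(r[[col_wm]], lab); rc <- roc(r[[col_cb]], lab)
      roc_tables[[key]] <- data.frame(
        reference = c("wm_ref", "cereb_ref"),
        auc = c(rw$auc, rc$auc), cutoff = c(rw$cutoff, rc$cutoff),
        sensitivity = c(rw$sensitivity, rc$sensitivity),
        specificity = c(rw$specificity, rc$specificity))
      delong_tables[[key]] <- delong_compare(r[[col_wm]], r[[col_cb]], lab)
    }
  }
  # ANCOVA + Cohen's d across all groups per readout column
  readout_cols <- grep("_(suvr|vtr)_", names(readouts), value = TRUE)
  ancova_tables <- lapply(readout_cols, function(cl)
    ancova(readouts[[cl]], readouts$group, readouts$age, readouts$sex))
  names(ancova_tables) <- readout_cols
  # severity regression in pooled PSP-like subjects
  sev_rows <- readouts$group %in% c("PSP-RS", "PSP-nonRS") &
    !is.na(readouts$severity)
  severity_tables <- list()
  if (sum(sev_rows) >= 4) {
    sr <- readouts[sev_rows, ]
    for (ms in c("suvr", "vtr")) for (rf in c("wm_ref", "cereb_ref")) {
      cl <- paste(cfg$target, ms, rf, sep = "_")
      severity_tables[[cl]] <- severity_regression(sr$severity, sr[[cl]],
                                                   sr$age, sr$sex)
    }
  }
  voxelwise <- NULL
  if (cfg$include_voxelwise) {
    pg <- cfg$patient_group
    sel <- subj$group %in% c(pg, "HC")
    suvr_maps <- lapply(subj$id[sel], function(id)
      suvr_map(cohort$images[[id]], disc$merged_mask, cfg$suvr_window))
    voxelwise <- voxelwise_cluster_test(
      suvr_maps, subj$group[sel] == pg, cohort$brain,
      age = subj$age[sel], sex = subj$sex[sel],
      n_perm = cfg$n_perm, seed = cfg$seed)
  }
  structure(list(readouts = readouts, roc = roc_tables,
                 delong = delong_tables, ancova = ancova_tables,
                 severity = severity_tables, voxelwise = voxelwise,
                 qc = stage$qc),
            class = "validation_result")
}

# serialize a report to plain lists for JSON round-tripping
.report_to_list <- function(report) {
  num <- function(x) unclass(x)
  list(
    version = as.character(utils::packageVersion("petref")),
    seed = report$seed,
    config = report$config_echo,
    candidates = report$discovery$search$candidates,
    n_selected = report$discovery$search$n_selected,
    search_status = report$discovery$search$status,
    merged_voxels = sum(report$discovery$merged_mask),
    roc = report$validation$roc,
    delong = report$validation$delong,
    ancova = lapply(report$validation$ancova, function(a)
      list(F = a$group_F, p = a$group_p_overall,
           adjusted_means = as.list(a$adjusted_means),
           tukey_p = a$tukey_p, cohens_d = a$cohens_d)),
    severity = report$validation$severity)
}

#' Run the full study replica
#'
#' Simulation, IDIF extraction, Logan VT mapping, reference search on the
#' discovery subjects, quantification of all subjects under the searched
#' and conventional references, and the validation statistics. Fully
#' deterministic given `cfg$seed`.
#'
#' @param cfg A [run_config()].
#' @return A list of class `run_report` with `discovery`, `validation`,
#'   `seed`, `config_echo` and (if `cfg$out_dir` is set) files
#'   `report.json`, `report.txt`, `merged_reference.nii.gz` and
#'   `readouts.tsv` under `cfg$out_dir`.
#' @export
run_all <- function(cfg) {
  stopifnot(inherits(cfg, "run_config"))
  disc <- run_discovery(cfg)
  val <- run_validation(cfg, disc)
  config_echo <- cfg[setdiff(names(cfg), "spec")]
  config_echo$group_sizes <- as.list(cfg$spec$group_sizes)
  config_echo$grid_dim <- cfg$spec$grid_dim
  config_echo$sigma0 <- cfg$spec$sigma0
  report <- structure(list(discovery = disc, validation = val,
                           seed = cfg$seed, config_echo = config_echo),
                      class = "run_report")
  if (!is.null(cfg$out_dir)) {
    dir.create(cfg$out_dir, recursive = TRUE, showWarnings = FALSE)
    jsonlite::write_json(.report_to_list(report),
                         file.path(cfg$out_dir, "report.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    writeLines(format_run_report(report),
               file.path(cfg$out_dir, "report.txt"))
    write_nifti(array(as.integer(disc$merged_mask), dim(disc$merged_mask)),
                file.path(cfg$out_dir, "merged_reference.nii.gz"),
                cfg$spec$spacing_mm, datatype = "int16")
    write_cohort_table(val$readouts, file.path(cfg$out_dir, "readouts.tsv"))
  }
  report
}

#' Human-readable rendering of a run report
#'
#' Every number printed is formatted from the same fields serialized to
#' JSON, so the two report forms agree.
#'
#' @param report A `run_report`.
#' @return Character vector of report lines.
#' @export
format_run_report <- function(report) {
  L <- .report_to_list(report)
  out <- c(sprintf("petref run report (version %s, seed %d)",
                   L$version, L$seed),
           sprintf("reference search: %s, %d candidate(s) selected, merged mask %d voxels",
                   L$search_status, L$n_selected, L$merged_voxels),
           "candidates:",
           utils::capture.output(print(L$candidates, row.names = FALSE,
                                       digits = 6)))
  for (key in names(L$roc)) {
    r <- L$roc[[key]]; dl <- L$delong[[key]]
    out <- c(out, sprintf("ROC %s: AUC wm_ref %.6g vs cereb_ref %.6g (DeLong z %.6g, p %.6g)",
                          key, r$auc[1], r$auc[2], dl$z, dl$p))
  }
  for (key in names(L$severity)) {
    s <- L$severity[[key]]
    out <- c(out, sprintf("severity ~ %s: beta %.6g, p %.6g, n %d",
                          key, s$beta, s$p, s$n))
  }
  out
}

#' @export
print.run_report <- function(x, ...) {
  cat(format_run_report(x), sep = "\n")
  invisible(x)
}

# ---- command-line interface -------------------------------------------------

.cli_parse <- function(args) {
  out <- list(positional = character(0))
  i <- 1
  while (i <= length(args)) {
    a <- args[i]
    if (grepl("^--", a)) {
      key <- sub("^--", "", a)
      if (i == length(args) || grepl("^--", args[i + 1]))
        .stop_validation("missing value for --", key)
      out[[key]] <- args[i + 1]
      i <- i + 2
    } else {
      out$positional <- c(out$positional, a)
      i <- i + 1
    }
  }
  out
}

#' Command-line entry point
#'
#' Subcommands: `simulate` (write a phantom cohort), `idif`, `logan`,
#' `suvr`, `refsearch` are exposed through `run-all`, which executes the
#' full pipeline and writes the report. Options: `--config <json>`,
#' `--seed <int>`, `--out <dir>`.
#'
#' @param args Character vector of CLI arguments (default:
#'   `commandArgs(trailingOnly = TRUE)`).
#' @return Integer exit status, invisibly: 0 ok, 2 validation error,
#'   3 extraction failure, 1 other failure.
#' @export
petref_cli <- function(args = commandArgs(trailingOnly = TRUE)) {
  status <- tryCatch({
    if (!length(args)) {
      cat("usage: petref <simulate|run-all> [--config cfg.json] [--seed N] [--out DIR]\n")
      return(invisible(0L))
    }
    cmd <- args[1]
    opt <- .cli_parse(args[-1])
    seed <- if (!is.null(opt$seed)) as.integer(opt$seed) else 1L
    cfg <- if (!is.null(opt$config)) read_run_config(opt$config, seed)
    else run_config(seed = seed)
    if (!is.null(opt$out)) cfg$out_dir <- opt$out
    switch(cmd,
           simulate = {
             if (is.null(cfg$out_dir))
               .stop_validation("simulate requires --out")
             simulate_cohort(cfg$spec, cfg$seed, out_dir = cfg$out_dir,
                             keep_images = FALSE)
             message("cohort written to ", cfg$out_dir)
           },
           `run-all` = {
             report <- run_all(cfg)
             cat(format_run_report(report), sep = "\n")
           },
           .stop_validation("unknown subcommand: ", cmd))
    0L
  },
  petref_validation_error = function(e) { message("error: ", conditionMessage(e)); 2L },
  petref_extraction_failure = function(e) { message("extraction failure: ", conditionMessage(e)); 3L },
  error = function(e) { message("error: ", conditionMessage(e)); 1L })
  invisible(status)
}
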