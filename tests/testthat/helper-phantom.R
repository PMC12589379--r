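# Shared fixtures, built in code at test time.

# smallest grid supported by the full phantom geometry; used by every
# simulation-backed test to keep the suite fast
small_grid <- c(32L, 32L, 22L)

small_spec <- function(group_sizes = c(`PSP-RS` = 12L, HC = 12L), ...) {
  phantom_spec(grid_dim = small_grid, group_sizes = group_sizes, ...)
}

# spec with all group effects switched off (global null world)
null_spec <- function(group_sizes = c(`PSP-RS` = 12L, HC = 12L), ...) {
  sp <- small_spec(group_sizes = group_sizes, ...)
  for (g in names(sp$group_mult)) sp$group_mult[[g]][] <- 1
  sp
}

# one cached noiseless subject + one noisy subject on the small grid
# (simulated once per test run; several files reuse them)
.fixture_env <- new.env()

noiseless_subject <- function() {
  if (is.null(.fixture_env$noiseless)) {
    sp <- small_spec(sigma0 = 0)
    rec <- data.frame(id = "fx1", group = "PSP-RS", age = 70, sex = "m")
    .fixture_env$noiseless <- list(spec = sp,
                                   sim = simulate_subject(sp, rec, 424242))
  }
  .fixture_env$noiseless
}

noisy_subject <- function() {
  if (is.null(.fixture_env$noisy)) {
    sp <- small_spec()
    rec <- data.frame(id = "fx2", group = "HC", age = 68, sex = "f")
    .fixture_env$noisy <- list(spec = sp,
                               sim = simulate_subject(sp, rec, 424243))
  }
  .fixture_env$noisy
}

# scaled-down mixed cohort for end-to-end pipeline runs
pipeline_spec <- function() {
  phantom_spec(grid_dim = small_grid,
               group_sizes = c(`PSP-RS` = 6L, HC = 6L, `PSP-nonRS` = 3L,
                               AD = 3L, `alpha-syn` = 3L))
}

# frame-averaged true input curve for a spec
true_cp_frames <- function(spec) {
  tg <- seq(0, 3600, by = spec$fine_dt)
  frame_average(tg, aif(tg, spec$aif), spec$schedule)
}

# brute-force erosion oracle: tests every voxel's spherical neighbourhood
erode_oracle <- function(mask, radius_mm, spacing_mm) {
  d <- dim(mask)
  out <- array(FALSE, d)
  r_vox <- floor(radius_mm / spacing_mm)
  for (x in seq_len(d[1])) for (y in seq_len(d[2])) for (z in seq_len(d[3])) {
    if (!mask[x, y, z]) next
    keep <- TRUE
    for (dx in -r_vox[1]:r_vox[1]) for (dy in -r_vox[2]:r_vox[2])
      for (dz in -r_vox[3]:r_vox[3]) {
        if ((dx * spacing_mm[1])^2 + (dy * spacing_mm[2])^2 +
            (dz * spacing_mm[3])^2 > radius_mm^2 + 1e-9) next
        xx <- x + dx; yy <- y + dy; zz <- z + dz
        if (xx < 1 || xx > d[1] || yy < 1 || yy > d[2] ||
            zz < 1 || zz > d[3] || !mask[xx, yy, zz]) { keep <- FALSE; break }
      }
    out[x, y, z] <- keep
  }
  out
}

# pair-counting AUC oracle (exhaustive loop, ties count 1/2)
auc_oracle <- function(scores, labels) {
  sp <- scores[labels]; sc <- scores[!labels]
  tot <- 0
  for (a in sp) for (b in sc)
    tot <- tot + (a > b) + 0.5 * (a == b)
  tot / (length(sp) * length(sc))
}
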