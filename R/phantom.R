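# Synthetic dynamic-PET phantom cohorts with known kinetic ground truth.
#
# Generative model (defaults documented in the methods vignette):
#   * arterial input: tri-exponential bolus Cp(t), zero before a short delay;
#   * tissue: one-tissue compartment model, C_T = K1 * exp(-k2 t) (*) Cp,
#     so the planted total distribution volume is VT = K1 / k2;
#   * carotid signal: Cp scaled by a per-voxel partial-volume factor with a
#     tube core at 1.0;
#   * between-subject biology: lognormal global and per-region VT scatter,
#     plus a log-linear age slope;
#   * group effects: proportional VT elevation in the pallidum-like target
#     (PSP-like groups), cortical elevation (AD-like group), and optional
#     contamination of candidate / conventional reference regions;
#   * noise: zero-mean Gaussian per voxel-frame with SD
#     sigma0 * sqrt(max(value, eps) / duration_s), a documented Gaussian
#     stand-in for post-reconstruction count statistics.

# ---- arterial input function ------------------------------------------------

#' Tri-exponential bolus input-function parameters
#'
#' `Cp(t) = 0` for `t < delay_s`; for `u = t - delay_s >= 0`,
#' `Cp = (A1*u - A2 - A3) e^{L1 u} + A2 e^{L2 u} + A3 e^{L3 u}`.
#' All `L` are negative, `L1` the most negative, so `Cp(delay) = 0`,
#' the curve peaks shortly after the bolus and decays to 0. Construction
#' fails if the parameter set goes negative anywhere on [0, 3600] s.
#'
#' @param A1 Linear-rise amplitude (activity per second).
#' @param A2,A3 Exponential amplitudes (activity units).
#' @param L1,L2,L3 Rate constants, all `< 0`, `L1` most negative (1/s).
#' @param delay_s Appearance delay after injection (s).
#' @return An object of class `aif_params`.
#' @export
aif_params <- function(A1, A2, A3, L1, L2, L3, delay_s = 0) {
  if (delay_s < 0) .stop_validation("delay_s must be >= 0")
  if (!(L1 < 0 && L2 < 0 && L3 < 0)) .stop_validation("all L must be < 0")
  if (L1 > min(L2, L3)) .stop_validation("L1 must be the most negative rate")
  p <- structure(list(A1 = A1, A2 = A2, A3 = A3, L1 = L1, L2 = L2, L3 = L3,
                      delay_s = delay_s), class = "aif_params")
  probe <- aif(seq(0, 3600, by = 0.5), p)
  if (any(probe < -1e-9))
    .stop_validation("aif_params produce a negative Cp on [0, 3600] s")
  p
}

#' Default input-function parameters
#'
#' Scaled to SUV-like units: peak around 7 at roughly 25-35 s after a 10 s
#' appearance delay, with slow bi-exponential washout. The shape family and
#' rate constants follow the classic bolus-injection model used in kinetic
#' simulation studies.
#'
#' @return An [aif_params()] object.
#' @export
default_aif_params <- function() {
  aif_params(A1 = 1.0, A2 = 1.157, A3 = 1.1,
             L1 = -0.0689, L2 = -0.001985, L3 = -0.0001733,
             delay_s = 10)
}

#' Evaluate the input function
#' @param t_s Times in seconds (vectorized), `>= 0`.
#' @param p An [aif_params()] object.
#' @return `Cp(t)` in the same activity units as the amplitudes.
#' @export
aif <- function(t_s, p) {
  stopifnot(inherits(p, "aif_params"))
  u <- pmax(t_s - p$delay_s, 0)
  out <- (p$A1 * u - p$A2 - p$A3) * exp(p$L1 * u) +
    p$A2 * exp(p$L2 * u) + p$A3 * exp(p$L3 * u)
  out[t_s < p$delay_s] <- 0
  out
}

#' Analytic peak time of the input function
#'
#' Root of the closed-form derivative of the tri-exponential bolus,
#' bracketed between the delay and 600 s.
#'
#' @param p An [aif_params()] object.
#' @return Peak time in seconds (absolute, including the delay).
#' @export
aif_peak_time <- function(p) {
  stopifnot(inherits(p, "aif_params"))
  dCp <- function(u)
    (p$A1 + p$L1 * (p$A1 * u - p$A2 - p$A3)) * exp(p$L1 * u) +
    p$A2 * p$L2 * exp(p$L2 * u) + p$A3 * p$L3 * exp(p$L3 * u)
  stats::uniroot(dCp, c(1e-6, 600), tol = 1e-8)$root + p$delay_s
}

# ---- tissue kinetics --------------------------------------------------------

#' One-tissue-compartment kinetic parameters
#' @param K1 Influx rate (1/s), `>= 0`.
#' @param k2 Efflux rate (1/s), `> 0`. The implied distribution volume is
#'   `VT = K1 / k2`.
#' @return An object of class `kinetic_params`.
#' @export
kinetic_params <- function(K1, k2) {
  if (K1 < 0) .stop_validation("K1 must be >= 0")
  if (k2 <= 0) .stop_validation("k2 must be > 0")
  structure(list(K1 = K1, k2 = k2, VT = K1 / k2), class = "kinetic_params")
}

#' Simulate a tissue time-activity curve (1TCM)
#'
#' Solves `C_T(t) = K1 * int_0^t exp(-k2 (t - tau)) Cp(tau) dtau` on a fine
#' uniform grid with an exponential-integrator recursion (trapezoidal source
#' term), which is exact for frame-wise-linear input and O(dt^2) otherwise.
#'
#' @param p A [kinetic_params()] object.
#' @param aifp An [aif_params()] object, or a numeric vector giving `Cp`
#'   directly on `t_grid`.
#' @param t_grid Increasing uniform time grid starting at 0, step `<= 1` s.
#' @return `C_T` evaluated on `t_grid`.
#' @export
tissue_tac <- function(p, aifp, t_grid) {
  stopifnot(inherits(p, "kinetic_params"))
  n <- length(t_grid)
  if (n < 2L || t_grid[1] != 0) .stop_validation("t_grid must start at 0")
  dt <- diff(t_grid)
  if (any(dt <= 0)) .stop_validation("t_grid must be strictly increasing")
  if (max(dt) > 1 + 1e-9) .stop_validation("t_grid step must be <= 1 s")
  cp <- if (is.numeric(aifp)) {
    if (length(aifp) != n) .stop_validation("Cp vector must match t_grid")
    aifp
  } else aif(t_grid, aifp)
  if (p$K1 == 0) return(numeric(n))
  if (diff(range(dt)) < 1e-9) {        # uniform grid: recursive filter
    h <- dt[1]
    a <- exp(-p$k2 * h)
    src <- c(0, p$K1 * h * (cp[-1] + a * cp[-n]) / 2)
    as.numeric(stats::filter(src, a, method = "recursive"))
  } else {
    ct <- numeric(n)
    for (i in 2:n) {
      a <- exp(-p$k2 * dt[i - 1])
      ct[i] <- ct[i - 1] * a + p$K1 * dt[i - 1] * (cp[i] + a * cp[i - 1]) / 2
    }
    ct
  }
}

#' Average a fine-grid curve onto an acquisition frame schedule
#'
#' Per-frame value = duration-weighted time average of the curve over the
#' frame interval (trapezoidal quadrature on the fine grid), i.e. what an
#' idealized scanner frame records for a continuous signal.
#'
#' @param t_grid Increasing time grid covering `[0, end of last frame]`.
#' @param values Curve values on `t_grid`.
#' @param schedule A [frame_schedule()].
#' @return Numeric vector of per-frame averages.
#' @export
frame_average <- function(t_grid, values, schedule) {
  stopifnot(inherits(schedule, "frame_schedule"))
  ends <- schedule$start_s + schedule$duration_s
  if (t_grid[1] > 0 || t_grid[length(t_grid)] < max(ends) - 1e-9)
    .stop_validation("t_grid must cover [0, ", max(ends), "] s")
  cum <- cumtrapz(t_grid, values, anchor = FALSE)
  at <- function(t) stats::approx(t_grid, cum, xout = t, rule = 2)$y
  (at(ends) - at(schedule$start_s)) / schedule$duration_s
}

# ---- phantom specification --------------------------------------------------

#' Build the phantom label atlas and carotid geometry
#'
#' Deterministic geometry on a user-sized grid: an ellipsoidal brain with a
#' bilateral pallidum-like target (two spheres, one merged label), a lateral
#' cortical slab pair (temporal-meta stand-in), an inferior posterior sphere
#' (cerebellar conventional reference), eight white-matter candidate boxes,
#' and a carotid-like tube below the brain with a Gaussian partial-volume
#' profile plus its restriction segment and correlation template.
#'
#' @param grid_dim Integer grid dimensions (length 3).
#' @param spacing_mm Voxel edge lengths in mm.
#' @return A list: `atlas` ([label_atlas()]), `pv` (3D partial-volume factor
#'   array for the carotid tube), `tube_core` (logical mask of factor-1.0
#'   voxels), `template` (logical carotid template mask), `brain` (logical
#'   brain mask).
#' @export
build_phantom_atlas <- function(grid_dim = c(48L, 48L, 32L),
                                spacing_mm = c(2, 2, 2)) {
  d <- as.integer(grid_dim)
  stopifnot(length(d) == 3L, all(d >= 16L))
  ax <- seq_len(d[1]); ay <- seq_len(d[2]); az <- seq_len(d[3])
  X <- array(rep(ax, times = d[2] * d[3]), d)
  Y <- array(rep(rep(ay, each = d[1]), times = d[3]), d)
  Z <- array(rep(az, each = d[1] * d[2]), d)
  # scale geometry with grid size so small test grids stay anatomically alike
  cx <- (d[1] + 1) / 2; cy <- (d[2] + 1) / 2
  cz <- 0.63 * d[3]
  rx <- 0.38 * d[1]; ry <- 0.44 * d[2]; rz <- 0.34 * d[3]
  brain <- ((X - cx) / rx)^2 + ((Y - cy) / ry)^2 + ((Z - cz) / rz)^2 <= 1
  sphere <- function(x0, y0, z0, r)
    (X - x0)^2 + (Y - y0)^2 + (Z - z0)^2 <= r^2
  box <- function(x0, x1, y0, y1, z0, z1)
    X >= x0 & X <= x1 & Y >= y0 & Y <= y1 & Z >= z0 & Z <= z1

  rt <- max(2.5, 0.058 * d[1])                     # target sphere radius
  pall <- sphere(cx - 0.16 * d[1], cy, cz, rt) |
          sphere(cx + 0.16 * d[1], cy, cz, rt)
  tmeta <- (box(cx - 0.38 * d[1], cx - 0.28 * d[1],
                cy - 0.22 * d[2], cy + 0.22 * d[2],
                cz - 0.18 * d[3], cz + 0.18 * d[3]) |
            box(cx + 0.28 * d[1], cx + 0.38 * d[1],
                cy - 0.22 * d[2], cy + 0.22 * d[2],
                cz - 0.18 * d[3], cz + 0.18 * d[3])) & brain
  cereb <- sphere(cx, cy - 0.27 * d[2], cz - 0.28 * d[3],
                  max(2.5, 0.08 * d[1])) & brain
  # eight candidate WM boxes, bilateral pairs at two depths
  # half-widths floored so eroded candidates stay nonempty at 2 mm radius
  bw <- max(3, round(0.06 * d[1])); bh <- max(3, round(0.06 * d[2]))
  bd <- max(2, round(0.06 * d[3]))
  xs <- c(cx - 0.20 * d[1], cx + 0.20 * d[1])
  ys <- c(cy - 0.17 * d[2], cy + 0.17 * d[2])
  zs <- c(cz - 0.1 * d[3], cz + 0.12 * d[3])
  cand <- list()
  k <- 0
  for (zi in 1:2) for (yi in 1:2) for (xi in 1:2) {
    k <- k + 1
    cand[[k]] <- box(xs[xi] - bw, xs[xi] + bw, ys[yi] - bh, ys[yi] + bh,
                     zs[zi] - bd, zs[zi] + bd) & brain
  }
  # carotid tube below the brain; axis on integer voxel coordinates so the
  # core column carries partial-volume factor exactly 1
  tx <- round(cx); ty <- round(cy + 0.12 * d[2])
  z_lo <- max(2L, round(0.06 * d[3])); z_hi <- round(0.30 * d[3])
  dist_mm <- sqrt(((X - tx) * spacing_mm[1])^2 + ((Y - ty) * spacing_mm[2])^2)
  in_z <- Z >= z_lo & Z <= z_hi
  pv <- exp(-(dist_mm / 1.8)^2)
  pv[!in_z] <- 0
  pv[dist_mm < 1e-6 & in_z] <- 1
  tube <- pv > 0.2 & !brain
  pv[!tube] <- 0
  tube_core <- dist_mm < 1e-6 & in_z & !brain
  z_seg <- ceiling((z_lo + z_hi) / 2)              # upper tube segment
  seg <- box(tx - 3, tx + 3, ty - 3, ty + 3, z_seg, z_hi) & !brain
  template <- dilate_mask(tube, max(spacing_mm), spacing_mm) & seg

  labels <- array(0L, d)
  labels[brain] <- 30L
  paint <- function(labels, mask, lab) {
    if (any(labels[mask] != 30L & labels[mask] != 0L))
      stop("petref internal: overlapping phantom regions")
    labels[mask] <- lab
    labels
  }
  labels <- paint(labels, pall, 1L)
  labels <- paint(labels, tmeta, 2L)
  labels <- paint(labels, cereb, 3L)
  for (k in 1:8) labels <- paint(labels, cand[[k]], 10L + k)
  labels[seg] <- 20L
  tab <- data.frame(
    label = c(1L, 2L, 3L, 11:18, 20L, 30L),
    name = c("pallidum", "temporalmeta", "inferior_cerebellum",
             paste0("wm_", 1:8), "carotid_segment", "brain_bg"),
    role = c("target", "cortical_target", "conventional_reference",
             rep("candidate_reference", 8), "carotid_segment", "other"),
    stringsAsFactors = FALSE)
  list(atlas = label_atlas(labels, tab, spacing_mm),
       pv = pv, tube_core = tube_core, template = template, brain = brain)
}

#' Phantom cohort specification
#'
#' Bundles the geometry, kinetic ground truth, group effects, covariate
#' model and noise model. Defaults are the package's stated simulation
#' world (see the methods vignette for the rationale behind each value);
#' every element can be overridden via `...` after construction.
#'
#' @param grid_dim,spacing_mm Grid geometry passed to
#'   [build_phantom_atlas()].
#' @param group_sizes Named integer vector of subjects per group; names from
#'   `{"PSP-RS", "PSP-nonRS", "AD", "alpha-syn", "HC"}`, all sizes `>= 2`.
#' @param sigma0 Noise scale of the Gaussian count-statistics analogue.
#' @param seedless_geometry Unused placeholder for forward compatibility.
#' @return An object of class `phantom_spec`.
#' @export
phantom_spec <- function(grid_dim = c(48L, 48L, 32L), spacing_mm = c(2, 2, 2),
                         group_sizes = c(`PSP-RS` = 8L, HC = 8L,
                                         `PSP-nonRS` = 10L, AD = 7L,
                                         `alpha-syn` = 7L),
                         sigma0 = 0.3, seedless_geometry = TRUE) {
  known <- c("PSP-RS", "PSP-nonRS", "AD", "alpha-syn", "HC")
  if (!all(names(group_sizes) %in% known))
    .stop_validation("unknown group(s): ",
                     paste(setdiff(names(group_sizes), known), collapse = ", "))
  if (any(group_sizes < 2)) .stop_validation("all group sizes must be >= 2")
  geom <- build_phantom_atlas(grid_dim, spacing_mm)
  regions <- c("pallidum", "temporalmeta", "inferior_cerebellum",
               paste0("wm_", 1:8), "brain_bg")
  vt_base <- c(pallidum = 2.4, temporalmeta = 2.2, inferior_cerebellum = 2.4,
               stats::setNames(rep(2.0, 8), paste0("wm_", 1:8)),
               brain_bg = 2.1)
  K1 <- c(pallidum = 0.006, temporalmeta = 0.006, inferior_cerebellum = 0.006,
          stats::setNames(rep(0.003, 8), paste0("wm_", 1:8)),
          brain_bg = 0.0045)
  one <- stats::setNames(rep(1, length(regions)), regions)
  mult <- list(`HC` = one, `alpha-syn` = one,
               `PSP-RS` = one, `PSP-nonRS` = one, `AD` = one)
  # proportional VT elevations: target + contaminated references in PSP-like
  # groups, cortical + mild pallidal elevation in the AD-like group
  mult$`PSP-RS`[c("pallidum", "wm_7", "wm_8")] <- 1.5
  mult$`PSP-RS`["inferior_cerebellum"] <- 1.45
  mult$`PSP-nonRS`[c("pallidum", "wm_7", "wm_8")] <- 1.35
  mult$`PSP-nonRS`["inferior_cerebellum"] <- 1.32
  mult$AD["temporalmeta"] <- 1.4
  mult$AD["pallidum"] <- 1.1
  structure(list(
    grid_dim = as.integer(grid_dim), spacing_mm = spacing_mm,
    geometry = geom, regions = regions,
    vt_base = vt_base, K1 = K1, group_mult = mult,
    contaminated = c("wm_7", "wm_8"),
    group_sizes = group_sizes,
    splits = c(`PSP-RS` = "discovery", HC = "discovery",
               `PSP-nonRS` = "validation", AD = "validation",
               `alpha-syn` = "validation"),
    aif = default_aif_params(),
    covariates = list(age_mean = 70, age_sd = 8, age_min = 40,
                      p_male = 0.55, age_ref = 70,
                      age_slope_log = 0.004),
    between_subject = list(sd_log_global = 0.15, sd_log_region = 0.08),
    severity = list(a = 5, b = 8, sd = 6,
                    groups = c("PSP-RS", "PSP-nonRS")),
    sigma0 = sigma0, noise_eps = 0.01, fine_dt = 0.5,
    schedule = default_frame_schedule()),
    class = "phantom_spec")
}

#' @export
print.phantom_spec <- function(x, ...) {
  cat(sprintf("phantom_spec: %s grid @ %s mm, %d subjects (%s), sigma0=%g\n",
              paste(x$grid_dim, collapse = "x"),
              paste(x$spacing_mm, collapse = "x"),
              sum(x$group_sizes),
              paste(names(x$group_sizes), x$group_sizes,
                    sep = "=", collapse = ", "),
              x$sigma0))
  invisible(x)
}

# ---- simulation -------------------------------------------------------------

#' Frame-duration-dependent Gaussian noise
#'
#' Adds zero-mean Gaussian noise with per-element SD
#' `sigma0 * sqrt(max(value, eps) / duration_s)` — the package's documented
#' Gaussian analogue of Poisson count statistics after reconstruction.
#'
#' @param values Numeric vector/array of noiseless activity values.
#' @param duration_s Frame duration (scalar) in seconds.
#' @param sigma0 Noise scale.
#' @param eps Variance floor on the value (default 0.01).
#' @return `values` plus noise, same shape.
#' @export
add_phantom_noise <- function(values, duration_s, sigma0, eps = 0.01) {
  if (sigma0 == 0) return(values)
  sdv <- sigma0 * sqrt(pmax(values, eps) / duration_s)
  values + stats::rnorm(length(values), 0, sdv)
}

.subject_vt_truth <- function(spec, record, draws) {
  cov <- spec$covariates
  age_mult <- exp(cov$age_slope_log * (record$age - cov$age_ref))
  gm <- spec$group_mult[[record$group]]
  vt <- spec$vt_base * gm[spec$regions] * draws$global * draws$region *
    age_mult
  stats::setNames(as.numeric(vt), spec$regions)
}

.subject_draws <- function(spec) {
  bs <- spec$between_subject
  list(global = exp(stats::rnorm(1, 0, bs$sd_log_global)),
       region = exp(stats::rnorm(length(spec$regions), 0, bs$sd_log_region)))
}

#' Simulate one subject's dynamic image
#'
#' Fills each labelled region with its frame-averaged 1TCM curve under the
#' subject's true regional VT, fills the carotid tube with the
#' partial-volume-scaled frame-averaged input, and adds frame-duration
#' dependent noise. Reproducible: the subject's RNG is seeded internally.
#'
#' @param spec A [phantom_spec()].
#' @param record One-row data.frame with `id`, `group`, `age`, `sex`.
#' @param seed Integer seed for this subject.
#' @return A list: `image` ([dynamic_image()]), `truth` (named true VT per
#'   region), `severity` (clinical score or `NA`).
#' @export
simulate_subject <- function(spec, record, seed) {
  stopifnot(inherits(spec, "phantom_spec"))
  if (!record$group %in% names(spec$group_mult))
    .stop_validation("unknown group: ", record$group)
  set.seed(seed)
  draws <- .subject_draws(spec)
  vt_true <- .subject_vt_truth(spec, record, draws)
  sched <- spec$schedule
  t_end <- max(sched$start_s + sched$duration_s)
  t_grid <- seq(0, t_end, by = spec$fine_dt)
  cp_frames <- frame_average(t_grid, aif(t_grid, spec$aif), sched)

  d <- spec$grid_dim
  vox <- array(0, c(d, length(sched)))
  atlas <- spec$geometry$atlas
  region_frames <- lapply(spec$regions, function(rn) {
    kp <- kinetic_params(spec$K1[[rn]], spec$K1[[rn]] / vt_true[[rn]])
    frame_average(t_grid, tissue_tac(kp, spec$aif, t_grid), sched)
  })
  names(region_frames) <- spec$regions
  masks <- lapply(spec$regions, function(rn) atlas_mask(atlas, rn))
  pv <- spec$geometry$pv
  tube <- pv > 0
  for (f in seq_along(sched)) {
    sl <- array(0, d)
    for (j in seq_along(spec$regions))
      sl[masks[[j]]] <- region_frames[[j]][f]
    sl[tube] <- pv[tube] * cp_frames[f]
    if (spec$sigma0 > 0)
      sl <- array(add_phantom_noise(sl, sched$duration_s[f], spec$sigma0,
                                    spec$noise_eps), d)
    vox[, , , f] <- sl
  }
  sev <- NA_real_
  if (record$group %in% spec$severity$groups)
    sev <- max(0, spec$severity$a + spec$severity$b * vt_true[["pallidum"]] +
                 stats::rnorm(1, 0, spec$severity$sd))
  list(image = dynamic_image(vox, spec$spacing_mm, sched),
       truth = vt_true, severity = sev)
}

.draw_records <- function(spec) {
  cov <- spec$covariates
  groups <- rep(names(spec$group_sizes), spec$group_sizes)
  n <- length(groups)
  age <- numeric(n)
  for (i in seq_len(n)) {
    repeat {
      a <- stats::rnorm(1, cov$age_mean, cov$age_sd)
      if (a > cov$age_min) break
    }
    age[i] <- round(a, 1)
  }
  data.frame(id = sprintf("sub-%03d", seq_len(n)), group = groups, age = age,
             sex = ifelse(stats::runif(n) < cov$p_male, "m", "f"),
             split = unname(spec$splits[groups]),
             stringsAsFactors = FALSE)
}

#' Simulate a phantom cohort
#'
#' Draws subject demographics, simulates every subject's dynamic image, and
#' (optionally) writes the full cohort — images + JSON sidecars, atlas +
#' label table, carotid template mask, subject table and ground-truth
#' tables — in the standard formats the rest of the package reads.
#'
#' @param spec A [phantom_spec()].
#' @param seed Integer master seed; all randomness derives from it.
#' @param out_dir Optional output directory (created if needed).
#' @param keep_images Keep the simulated images in the returned object
#'   (default `TRUE`; set `FALSE` with `out_dir` for large cohorts).
#' @return A list of class `phantom_cohort`: `spec`, `subjects`
#'   ([cohort_table()] incl. severity and split), `images` (named list of
#'   [dynamic_image()] or `NULL`), `truth` (data.frame of true VT per
#'   subject x region), `atlas`, `template`, `dir`.
#' @export
simulate_cohort <- function(spec, seed, out_dir = NULL, keep_images = TRUE) {
  stopifnot(inherits(spec, "phantom_spec"))
  set.seed(seed)
  records <- .draw_records(spec)
  subject_seeds <- sample.int(.Machine$integer.max - 1L, nrow(records))
  images <- if (keep_images) vector("list", nrow(records)) else NULL
  truth <- NULL
  severity <- numeric(nrow(records))
  if (!is.null(out_dir)) dir.create(out_dir, recursive = TRUE,
                                    showWarnings = FALSE)
  for (i in seq_len(nrow(records))) {
    sim <- simulate_subject(spec, records[i, ], subject_seeds[i])
    severity[i] <- sim$severity
    truth <- rbind(truth, data.frame(id = records$id[i],
                                     t(sim$truth), check.names = FALSE))
    if (keep_images) images[[i]] <- sim$image
    if (!is.null(out_dir)) {
      write_dynamic_image(sim$image,
                          file.path(out_dir, paste0(records$id[i], "_pet.nii.gz")),
                          file.path(out_dir, paste0(records$id[i], "_pet.json")))
    }
  }
  if (keep_images) names(images) <- records$id
  subjects <- cohort_table(cbind(records[c("id", "group", "age", "sex")],
                                 severity = severity,
                                 split = records$split))
  atlas <- spec$geometry$atlas
  out <- structure(list(spec = spec, subjects = subjects, images = images,
                        truth = truth, atlas = atlas,
                        template = spec$geometry$template,
                        tube_core = spec$geometry$tube_core,
                        brain = spec$geometry$brain,
                        seed = seed, dir = out_dir),
                   class = "phantom_cohort")
  if (!is.null(out_dir)) {
    write_label_atlas(atlas, file.path(out_dir, "atlas.nii.gz"),
                      file.path(out_dir, "atlas_labels.tsv"))
    write_nifti(array(as.integer(spec$geometry$template),
                      dim = spec$grid_dim),
                file.path(out_dir, "carotid_template.nii.gz"),
                spec$spacing_mm, datatype = "int16")
    write_cohort_table(subjects, file.path(out_dir, "subjects.tsv"))
    utils::write.table(truth, file.path(out_dir, "ground_truth_vt.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    jsonlite::write_json(list(seed = seed, sigma0 = spec$sigma0,
                              contaminated = spec$contaminated,
                              severity = spec$severity[c("a", "b", "sd")],
                              group_sizes = as.list(spec$group_sizes)),
                         file.path(out_dir, "ground_truth_params.json"),
                         auto_unbox = TRUE, digits = NA)
  }
  out
}

#' Simulate ground-truth VT maps directly (kinetics-free shortcut)
#'
#' Produces per-subject VT parametric maps from the same generative VT model
#' as [simulate_cohort()] — group effects, covariates, between-subject
#' scatter — plus lognormal voxel-level scatter emulating the residual noise
#' of a voxel-wise Logan fit, but skipping the dynamic simulation and
#' kinetic inversion. Used for simulation studies of the reference search
#' and group statistics, where only the VT maps matter.
#'
#' @param spec A [phantom_spec()].
#' @param seed Integer master seed.
#' @param sd_log_voxel Lognormal SD of the voxel-level VT scatter
#'   (default 0.02, matching the low single-voxel Logan noise at the
#'   default `sigma0`).
#' @return A list of class `phantom_vt_cohort`: `subjects`, `vt_maps`
#'   (named list of [static_image()] with quantity `"VT"`), `truth`,
#'   `atlas`.
#' @export
simulate_vt_cohort <- function(spec, seed, sd_log_voxel = 0.02) {
  stopifnot(inherits(spec, "phantom_spec"))
  set.seed(seed)
  records <- .draw_records(spec)
  subject_seeds <- sample.int(.Machine$integer.max - 1L, nrow(records))
  atlas <- spec$geometry$atlas
  masks <- lapply(spec$regions, function(rn) atlas_mask(atlas, rn))
  names(masks) <- spec$regions
  vt_maps <- vector("list", nrow(records))
  truth <- NULL
  severity <- numeric(nrow(records))
  for (i in seq_len(nrow(records))) {
    set.seed(subject_seeds[i])
    draws <- .subject_draws(spec)
    vt_true <- .subject_vt_truth(spec, records[i, ], draws)
    vol <- array(NA_real_, spec$grid_dim)
    for (rn in spec$regions) {
      m <- masks[[rn]]
      vol[m] <- vt_true[[rn]] *
        exp(stats::rnorm(sum(m), 0, sd_log_voxel))
    }
    vt_maps[[i]] <- static_image(vol, spec$spacing_mm, "VT")
    truth <- rbind(truth, data.frame(id = records$id[i], t(vt_true),
                                     check.names = FALSE))
    severity[i] <- if (records$group[i] %in% spec$severity$groups)
      max(0, spec$severity$a + spec$severity$b * vt_true[["pallidum"]] +
            stats::rnorm(1, 0, spec$severity$sd)) else NA_real_
  }
  names(vt_maps) <- records$id
  subjects <- cohort_table(cbind(records[c("id", "group", "age", "sex")],
                                 severity = severity,
                                 split = records$split))
  structure(list(spec = spec, subjects = subjects, vt_maps = vt_maps,
                 truth = truth, atlas = atlas, seed = seed),
            class = "phantom_vt_cohort")
}
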