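# synthetic_phantom: input function, kinetics, frame averaging, simulation

test_that("input function is zero at the delay, peaks where the derivative vanishes, decays", {
  p <- default_aif_params()
  expect_equal(aif(p$delay_s, p), 0)
  expect_equal(aif(0, p), 0)
  tg <- seq(0, 600, by = 0.1)
  grid_peak <- tg[which.max(aif(tg, p))]
  expect_lt(abs(grid_peak - aif_peak_time(p)), 0.1)
  expect_lt(aif(36000, p), 1e-3 * max(aif(tg, p)))
  expect_true(all(aif(tg, p) >= 0))
})

test_that("aif_params rejects invalid parameter sets", {
  expect_error(aif_params(1, 1, 1, 0.1, -0.01, -0.001), "< 0")
  expect_error(aif_params(1, 1, 1, -0.001, -0.01, -0.1), "most negative")
  # strongly negative linear term drives Cp < 0
  expect_error(aif_params(-5, 1.157, 1.1, -0.0689, -0.002, -0.00017),
               class = "petref_validation_error")
})

test_that("tissue_tac matches the closed-form step response", {
  # constant Cp = c from t = 0, K1 = 0.02, k2 = 0.01 -> 2c(1 - e^{-0.01 t})
  tg <- seq(0, 200, by = 0.25)
  cc <- 3.7
  ct <- tissue_tac(kinetic_params(0.02, 0.01), rep(cc, length(tg)), tg)
  expected <- 2 * cc * (1 - exp(-0.01 * tg))
  i100 <- which(tg == 100)
  expect_lt(abs(ct[i100] - expected[i100]) / expected[i100], 0.001)
  expect_lt(max(abs(ct[-1] - expected[-1]) / expected[-1]), 0.002)
})

test_that("tissue_tac matches an independent RK4 integrator on default params", {
  p <- default_aif_params()
  kp <- kinetic_params(0.006, 0.002)
  tg <- seq(0, 600, by = 0.5)
  ct <- tissue_tac(kp, p, tg)
  # RK4 oracle at dt = 0.05 for dC/dt = K1 Cp - k2 C
  dt <- 0.05
  tt <- seq(0, 600, by = dt)
  f <- function(t, c) kp$K1 * aif(t, p) - kp$k2 * c
  cc <- numeric(length(tt))
  for (i in seq_len(length(tt) - 1)) {
    k1 <- f(tt[i], cc[i])
    k2 <- f(tt[i] + dt / 2, cc[i] + dt / 2 * k1)
    k3 <- f(tt[i] + dt / 2, cc[i] + dt / 2 * k2)
    k4 <- f(tt[i] + dt, cc[i] + dt * k3)
    cc[i + 1] <- cc[i] + dt / 6 * (k1 + 2 * k2 + 2 * k3 + k4)
  }
  oracle <- cc[match(tg, tt)]
  late <- tg > 60
  expect_lt(max(abs(ct[late] - oracle[late]) / oracle[late]), 0.001)
  expect_equal(tissue_tac(kinetic_params(0, 0.01), p, tg),
               numeric(length(tg)))
})

test_that("frame_average is exact for constants and linear curves", {
  s <- default_frame_schedule()
  tg <- seq(0, 3600, by = 0.5)
  expect_equal(frame_average(tg, rep(4.2, length(tg)), s),
               rep(4.2, 35))
  expect_equal(frame_average(tg, tg, s), s$mid_s)     # linear -> midpoint
  # cubic against the symbolic integral: mean of t^3 over [a,b]
  tg <- seq(0, 3600, by = 0.01)        # fine grid: quadrature error ~h^2
  fa <- frame_average(tg, tg^3, s)
  a <- s$start_s; b <- s$start_s + s$duration_s
  exact <- (b^4 - a^4) / (4 * (b - a))
  expect_lt(max(abs(fa - exact) / exact), 1e-5)
  expect_error(frame_average(seq(0, 100), seq(0, 100), s),
               class = "petref_validation_error")      # coverage gap
})

test_that("noise scaling follows sigma0 * sqrt(value / duration)", {
  set.seed(5)
  for (case in list(c(2.0, 300), c(8.0, 5), c(0.5, 600))) {
    v <- rep(case[1], 4000)
    noisy <- add_phantom_noise(v, case[2], sigma0 = 0.3)
    expect_lt(abs(sd(noisy - v) / (0.3 * sqrt(case[1] / case[2])) - 1), 0.1)
  }
  expect_identical(add_phantom_noise(1:3, 10, 0), 1:3)
})

test_that("noiseless simulation reproduces the analytic frame-averaged TACs", {
  fx <- noiseless_subject()
  sp <- fx$spec; sim <- fx$sim
  s <- sp$schedule
  tg <- seq(0, 3600, by = sp$fine_dt)
  for (rn in c("pallidum", "wm_1")) {
    kp <- kinetic_params(sp$K1[[rn]], sp$K1[[rn]] / sim$truth[[rn]])
    expected <- frame_average(tg, tissue_tac(kp, sp$aif, tg), s)
    m <- atlas_mask(sp$geometry$atlas, rn)
    got <- apply(matrix(sim$image$voxels, prod(sp$grid_dim), 35)[which(m), ],
                 2, mean)
    expect_equal(got, expected, tolerance = 1e-10)
  }
  # carotid tube core carries exactly the frame-averaged input
  core <- which(sp$geometry$tube_core)[1]
  got <- sim$image$voxels[arrayInd(core, sp$grid_dim)[1],
                          arrayInd(core, sp$grid_dim)[2],
                          arrayInd(core, sp$grid_dim)[3], ]
  expect_equal(as.numeric(got), true_cp_frames(sp), tolerance = 1e-10)
})

test_that("noiseless Logan closure: fitted VT recovers K1/k2 within 5%", {
  fx <- noiseless_subject()
  sp <- fx$spec; sim <- fx$sim
  inp <- input_function(sp$schedule$mid_s, true_cp_frames(sp), "true_aif")
  for (rn in c("pallidum", "inferior_cerebellum", "wm_3")) {
    m <- atlas_mask(sp$geometry$atlas, rn)
    tac <- colMeans(matrix(sim$image$voxels, prod(sp$grid_dim), 35)[which(m), ])
    fit <- logan_fit(tac, sp$schedule$mid_s, inp, logan_config(900))
    expect_lt(abs(fit$slope - sim$truth[[rn]]) / sim$truth[[rn]], 0.05)
  }
})

test_that("subject simulation is deterministic and group-checked", {
  sp <- small_spec(group_sizes = c(`PSP-RS` = 2L, HC = 2L), sigma0 = 0.1)
  rec <- data.frame(id = "d1", group = "HC", age = 66, sex = "f")
  a <- simulate_subject(sp, rec, 77)
  b <- simulate_subject(sp, rec, 77)
  expect_identical(a$image$voxels, b$image$voxels)
  expect_identical(a$truth, b$truth)
  expect_error(simulate_subject(sp, transform(rec, group = "XX"), 1),
               class = "petref_validation_error")
})

test_that("cohort simulation writes a complete, reproducible cohort", {
  sp <- phantom_spec(grid_dim = small_grid,
                     group_sizes = c(`PSP-RS` = 2L, HC = 2L), sigma0 = 0.2)
  dir <- file.path(tempdir(), "cohtest")
  co <- simulate_cohort(sp, seed = 31, out_dir = dir, keep_images = FALSE)
  expect_length(list.files(dir, pattern = "_pet\\.nii\\.gz$"), 4L)
  expect_length(list.files(dir, pattern = "_pet\\.json$"), 4L)
  expect_true(file.exists(file.path(dir, "atlas.nii.gz")))
  expect_true(file.exists(file.path(dir, "subjects.tsv")))
  expect_true(file.exists(file.path(dir, "ground_truth_vt.tsv")))
  # covariate reproducibility: same seed -> identical subject table
  co2 <- simulate_cohort(sp, seed = 31, keep_images = FALSE)
  expect_identical(as.data.frame(co$subjects), as.data.frame(co2$subjects))
  expect_identical(co$truth, co2$truth)
  # round-trip one image
  img <- read_dynamic_image(file.path(dir, "sub-001_pet.nii.gz"),
                            file.path(dir, "sub-001_pet.json"))
  expect_equal(dim(img$voxels), c(small_grid, 35L))
})

test_that("planted group effects appear in the ground truth as configured", {
  sp <- small_spec(group_sizes = c(`PSP-RS` = 5L, HC = 5L))
  vc <- simulate_vt_cohort(sp, seed = 8)
  tr <- merge(vc$truth, vc$subjects[c("id", "group", "age")], by = "id")
  # pallidum carries the planted 1.5x elevation (noisy at 5 subjects/group)
  expect_gt(mean(tr$pallidum[tr$group == "PSP-RS"]) /
              mean(tr$pallidum[tr$group == "HC"]), 1.2)
  sp0 <- null_spec(group_sizes = c(`PSP-RS` = 5L, HC = 5L))
  vc0 <- simulate_vt_cohort(sp0, seed = 8)
  tr0 <- merge(vc0$truth, vc0$subjects[c("id", "group")], by = "id")
  # same seed, null world: groups draw from one distribution
  expect_lt(abs(log(mean(tr0$pallidum[tr0$group == "PSP-RS"]) /
                      mean(tr0$pallidum[tr0$group == "HC"]))), 0.25)
})
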