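# core_io: schedules, images, atlases, cohort tables, morphology, readouts

test_that("default frame schedule matches the printed 35-frame acquisition", {
  s <- default_frame_schedule()
  expect_s3_class(s, "frame_schedule")
  expect_length(s, 35L)
  expect_equal(sum(s$duration_s), 3600)
  expect_equal(s$start_s[1], 0)
  expect_equal(s$duration_s[1], 5)
  expect_equal(s$start_s[35], 3000)          # cumulative sum of durations
  expect_equal(s$duration_s[35], 600)
  expect_true(all(diff(s$mid_s) > 0))
})

test_that("frame_schedule rejects malformed schedules", {
  expect_error(frame_schedule(c(0, 10), c(5, 5)), "contiguous")
  expect_error(frame_schedule(c(1, 6), c(5, 5)), "start at 0")
  expect_error(frame_schedule(0, -1), "> 0")
  expect_error(frame_schedule(c(0, 5), 5), class = "petref_format_error")
})

test_that("frames_in_window uses half-open midpoint membership", {
  s <- default_frame_schedule()
  # independent enumeration of all 35 midpoints from the printed durations
  durs <- c(rep(5, 12), rep(10, 6), rep(20, 3), rep(60, 7),
            rep(300, 4), rep(600, 3))
  mids <- cumsum(c(0, durs[-35])) + durs / 2
  expect_equal(frames_in_window(s, 1200, 2400),
               which(mids >= 1200 & mids < 2400))
  expect_equal(mids[frames_in_window(s, 1200, 2400)], c(1350, 1650, 2100))
  expect_equal(frames_in_window(s, 0, 3600), 1:35)
  expect_error(frames_in_window(s, 3600, 4000),
               class = "petref_validation_error")
  expect_error(frames_in_window(s, 100, 100),
               class = "petref_validation_error")
})

test_that("frames_in_window is monotone in the window", {
  s <- default_frame_schedule()
  set.seed(11)
  for (i in 1:20) {
    t0 <- runif(1, 0, 1800); t1 <- runif(1, t0 + 60, 3600)
    a <- tryCatch(frames_in_window(s, t0, t1),
                  petref_validation_error = function(e) NULL)
    if (is.null(a)) next                # window between late midpoints
    b <- frames_in_window(s, max(0, t0 - 100), min(3600, t1 + 100))
    expect_true(all(a %in% b))
  }
})

test_that("dynamic image round-trips through NIfTI + sidecar losslessly", {
  s <- frame_schedule(c(0, 5, 15), c(5, 10, 20))
  vox <- array(rnorm(6 * 5 * 4 * 3), c(6, 5, 4, 3))
  img <- dynamic_image(vox, c(2, 2, 2.5), s)
  ipath <- tempfile(fileext = ".nii.gz"); spath <- tempfile(fileext = ".json")
  write_dynamic_image(img, ipath, spath)
  back <- read_dynamic_image(ipath, spath)
  expect_identical(back$voxels, vox)
  expect_equal(back$spacing_mm, c(2, 2, 2.5), tolerance = 1e-6)
  expect_equal(back$schedule$start_s, s$start_s)
  expect_equal(back$schedule$duration_s, s$duration_s)
})

test_that("NIfTI writer agrees with an independent reader (nibabel)", {
  a <- array(rnorm(4 * 5 * 6), c(4, 5, 6))
  p <- tempfile(fileext = ".nii")
  write_nifti(a, p, c(1.5, 2, 2))
  txt <- tempfile(fileext = ".txt")
  py <- sprintf(
    "import nibabel, numpy; numpy.savetxt(%s, numpy.asarray(nibabel.load(%s).dataobj).ravel(order='F'))",
    shQuote(txt), shQuote(p))
  status <- system2("python", c("-c", shQuote(py)))
  expect_identical(status, 0L)
  expect_equal(scan(txt, quiet = TRUE), as.numeric(a), tolerance = 1e-12)
})

test_that("sidecar mismatches raise format errors", {
  s <- frame_schedule(c(0, 5), c(5, 10))
  img <- dynamic_image(array(1, c(3, 3, 3, 2)), c(2, 2, 2), s)
  ipath <- tempfile(fileext = ".nii"); spath <- tempfile(fileext = ".json")
  write_dynamic_image(img, ipath, spath)
  bad <- tempfile(fileext = ".json")
  jsonlite::write_json(list(FrameTimesStart = c(0, 5, 15),
                            FrameDuration = c(5, 10, 20)), bad, digits = NA)
  expect_error(read_dynamic_image(ipath, bad), class = "petref_format_error")
  # non-contiguous sidecar -> validation error
  bad2 <- tempfile(fileext = ".json")
  jsonlite::write_json(list(FrameTimesStart = c(0, 7),
                            FrameDuration = c(5, 10)), bad2, digits = NA)
  expect_error(read_dynamic_image(ipath, bad2),
               class = "petref_validation_error")
})

test_that("time_weighted_mean_image weights by duration and is linear", {
  s <- frame_schedule(c(0, 100), c(100, 300))
  vox <- array(0, c(2, 2, 2, 2))
  vox[, , , 1] <- 1; vox[, , , 2] <- 3
  img <- dynamic_image(vox, c(1, 1, 1), s)
  m <- time_weighted_mean_image(img, 1:2)
  expect_equal(unique(as.vector(m$voxels)), 2.5)      # (1*100 + 3*300)/400
  # constant image -> constant mean; equal durations -> plain mean
  s2 <- frame_schedule(c(0, 60), c(60, 60))
  v2 <- array(rnorm(16), c(2, 2, 2, 2))
  img2 <- dynamic_image(v2, c(1, 1, 1), s2)
  m2 <- time_weighted_mean_image(img2, 1:2)
  expect_equal(m2$voxels, (v2[, , , 1] + v2[, , , 2]) / 2)
  # linearity in the voxel data
  img3 <- dynamic_image(2 * v2 + 1, c(1, 1, 1), s2)
  m3 <- time_weighted_mean_image(img3, 1:2)
  expect_equal(m3$voxels, 2 * m2$voxels + 1, tolerance = 1e-12)
})

test_that("erode_mask matches the brute-force oracle and its contracts", {
  mask <- array(FALSE, c(9, 9, 9)); mask[3:7, 3:7, 3:7] <- TRUE
  er <- erode_mask(mask, 2, c(1, 1, 1))
  expect_identical(er, erode_oracle(mask, 2, c(1, 1, 1)))
  expect_true(all(er[!mask] == FALSE))                # output subset of input
  expect_identical(erode_mask(mask, 0, c(1, 1, 1)), mask)   # radius 0 = id
  # anisotropic spacing against the oracle
  er2 <- erode_mask(mask, 2, c(1, 1, 2))
  expect_identical(er2, erode_oracle(mask, 2, c(1, 1, 2)))
  # over-erosion empties with a warning
  tiny <- array(FALSE, c(5, 5, 5)); tiny[3, 3, 3] <- TRUE
  expect_warning(out <- erode_mask(tiny, 2, c(1, 1, 1)), "empty")
  expect_false(any(out))
})

test_that("erode_mask commutes with translation away from borders", {
  set.seed(21)
  mask <- array(FALSE, c(14, 14, 14))
  mask[5:9, 5:9, 5:9] <- array(runif(125) > 0.3, c(5, 5, 5))
  er <- suppressWarnings(erode_mask(mask, 1.5, c(1, 1, 1)))
  sh <- array(FALSE, c(14, 14, 14))
  sh[7:11, 6:10, 5:9] <- mask[5:9, 5:9, 5:9]          # translate +2,+1,0
  ersh <- suppressWarnings(erode_mask(sh, 1.5, c(1, 1, 1)))
  expect_identical(ersh[7:11, 6:10, 5:9], er[5:9, 5:9, 5:9])
})

test_that("label atlas and cohort table validate and round-trip", {
  labs <- array(0L, c(4, 4, 4)); labs[2, 2, 2] <- 1L; labs[3, 3, 3] <- 2L
  tab <- data.frame(label = 1:2, name = c("a", "b"),
                    role = c("target", "candidate_reference"))
  at <- label_atlas(labs, tab, c(2, 2, 2))
  lp <- tempfile(fileext = ".nii"); tp <- tempfile(fileext = ".tsv")
  write_label_atlas(at, lp, tp)
  back <- read_label_atlas(lp, tp)
  expect_identical(back$labels, labs)
  expect_equal(back$table$name, tab$name)
  expect_error(label_atlas(labs, tab[1, ], c(2, 2, 2)),
               class = "petref_validation_error")   # label missing from table
  expect_error(atlas_mask(at, "nope"), class = "petref_validation_error")

  ct <- cohort_table(data.frame(id = c("s1", "s2"), group = c("HC", "AD"),
                                age = c(70, 65.5), sex = c("m", "f"),
                                severity = c(NA, 12)))
  cp <- tempfile(fileext = ".tsv")
  write_cohort_table(ct, cp)
  back <- read_cohort_table(cp)
  expect_equal(back$age, ct$age)
  expect_true(is.na(back$severity[1]))
  expect_error(cohort_table(data.frame(id = c("s1", "s1"), group = "HC",
                                       age = 1, sex = "m")),
               class = "petref_validation_error")
})

test_that("region_mean and mask_mean behave on simple regions", {
  labs <- array(0L, c(4, 4, 4)); labs[1:2, 1, 1] <- 1L
  at <- label_atlas(labs, data.frame(label = 1L, name = "r", role = "other"),
                    c(1, 1, 1))
  vol <- array(5, c(4, 4, 4)); vol[1, 1, 1] <- 1; vol[2, 1, 1] <- 3
  m <- static_image(vol, c(1, 1, 1), "SUV")
  expect_equal(region_mean(m, at, "r"), 2)
  expect_equal(region_mean(m, at, 1L), 2)
  expect_error(region_mean(m, at, 99L), class = "petref_validation_error")
  expect_error(mask_mean(m, array(FALSE, c(4, 4, 4))),
               class = "petref_validation_error")
})
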