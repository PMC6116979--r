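cfg <- default_config()

test_that("schedule arithmetic: dense first year, then half-year windows", {
  s10 <- make_schedule(10)
  expect_length(s10$windows, 4 + 18)
  expect_equal(s10$windows[1:4], rep(90, 4))
  expect_true(all(s10$windows[-(1:4)] == 180))
  s2 <- make_schedule(2)
  expect_equal(s2$windows, c(90, 90, 90, 90, 180, 180))
  expect_equal(make_schedule(0.5)$windows, c(90, 90))
})

test_that("fusion scaling multiplies magnitudes and leaves hours alone", {
  prog <- daily_program()
  same <- apply_fusion(prog, load_change_factors())
  expect_identical(same, prog)
  up <- apply_fusion(prog, load_change_factors(compression = 1.2))
  expect_equal(up$activities$standing$load$magnitude, 360)
  expect_equal(up$activities$sitting$load$magnitude,
               prog$activities$sitting$load$magnitude)
  hours <- vapply(up$activities, function(a) a$hours, numeric(1))
  expect_identical(hours, vapply(prog$activities, function(a) a$hours,
                                 numeric(1)))
  # factors commute and compose multiplicatively
  f1 <- load_change_factors(compression = 1.2, flexion = 0.9)
  f2 <- load_change_factors(compression = 1.1, lateral_bending = 1.3)
  expect_equal(apply_fusion(apply_fusion(prog, f1), f2),
               apply_fusion(apply_fusion(prog, f2), f1))
  expect_error(apply_fusion(prog, c(compression = -1)), "positive")
})

test_that("null surgery keeps every snapshot at the initial state", {
  disc <- small_disc()
  bone <- make_vertebra(nx = 5, ny = 5, nz = 3, seed = 6)
  fit <- spine_adapt(disc, bone, load_change_factors(), horizon_years = 1,
                     config = cfg)
  np <- disc$composition$region == "NP"
  af0 <- disc$composition$region == "AF" &
    disc$mesh$r / disc$mesh$radius > 0.85
  for (s in fit$snapshots) {
    expect_identical(s$bvtv, bone$bvtv)       # bone exactly unchanged
    expect_equal(s$composition$collagen[np],
                 disc$composition$collagen[np], tolerance = 1e-6)
    expect_equal(s$composition$collagen[af0],
                 disc$composition$collagen[af0], tolerance = 1e-6)
  }
})

test_that("coupled runs are deterministic", {
  disc <- small_disc()
  bone <- make_vertebra(nx = 4, ny = 4, nz = 3, seed = 2)
  f1 <- spine_adapt(disc, bone, load_change_factors(compression = 1.3),
                    horizon_years = 1, config = cfg)
  f2 <- spine_adapt(disc, bone, load_change_factors(compression = 1.3),
                    horizon_years = 1, config = cfg)
  expect_identical(f1$snapshots, f2$snapshots)
  expect_identical(f1$log, f2$log)
})

test_that("macro-step refinement barely changes the two-year outcome", {
  disc <- small_disc()
  lc <- load_change_factors(1.5, 1.5, 1.5, 1.5)
  coarse <- spine_adapt(disc, NULL, lc, horizon_years = 2, config = cfg)
  cfg_fine <- cfg
  cfg_fine$schedule$first_year_window <- 30
  cfg_fine$schedule$later_window <- 30
  fine <- spine_adapt(disc, NULL, lc, horizon_years = 2, config = cfg_fine)
  a <- coarse$log[nrow(coarse$log), c("np_collagen", "np_gag", "np_water")]
  b <- fine$log[nrow(fine$log), c("np_collagen", "np_gag", "np_water")]
  expect_true(all(abs(unlist(a) / unlist(b) - 1) < 0.03))
})

test_that("increased compression drives the nucleus toward fibrous tissue", {
  disc <- small_disc()
  fit <- spine_adapt(disc, NULL, load_change_factors(1.5, 1.5, 1.5, 1.5),
                     horizon_years = 3, config = cfg)
  expect_true(all(diff(fit$log$np_collagen) >= -1e-12))
  expect_gt(fit$log$np_collagen[nrow(fit$log)],
            mean(disc$composition$collagen[disc$composition$region == "NP"]))
  expect_true(all(diff(fit$log$np_gag) <= 1e-12))
  expect_true(all(diff(fit$log$np_water) <= 1e-12))
})

test_that("fit object methods: print, summary, predict, plot, coercion", {
  disc <- small_disc()
  fit <- spine_adapt(disc, NULL, load_change_factors(1.5, 1.5, 1.5, 1.5),
                     horizon_years = 1, config = cfg)
  expect_output(print(fit), "Coupled disc adaptation")
  sm <- summary(fit)
  expect_s3_class(sm, "summary.spine_adapt")
  expect_output(print(sm), "Relative NP water change")
  expect_lt(sm$np_rel_water_change, 0)
  pr <- predict(fit, baseline_grade = "II")
  expect_equal(nrow(pr), length(fit$snapshots))
  expect_true(all(pr$grade %in% c("I", "II", "III", "IV", "V")))
  expect_true(all(diff(pr$grade_change) >= 0))
  df <- as.data.frame(fit)
  expect_identical(df, fit$log)
  pdf_file <- tempfile(fileext = ".pdf")
  grDevices::pdf(pdf_file)
  plot(fit)
  grDevices::dev.off()
  expect_true(file.size(pdf_file) > 0)
})
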