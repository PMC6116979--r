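cfg <- default_config()

test_that("Donnan pressure matches the ideal closed form and is monotone", {
  expect_identical(donnan_pressure(0, 0.15, 310), 0)
  # independent hand evaluation: RT * (sqrt(0.09 + 0.09) - 0.30)
  rt <- 8.314462618 * 310 * 1e-3
  expect_equal(donnan_pressure(0.30, 0.15, 310),
               rt * (sqrt(0.09 + 0.09) - 0.30), tolerance = 1e-12)
  fcd <- seq(0, 1, by = 0.01)
  expect_true(all(diff(donnan_pressure(fcd, 0.15, 310)) > 0))
  expect_gt(donnan_pressure(0.6, 0.15, 310),
            donnan_pressure(0.3, 0.15, 310))
  expect_error(donnan_pressure(-0.1, 0.15, 310), "non-negative")
  expect_error(donnan_pressure(0.1, 0, 310), "positive")
})

test_that("GAG to FCD conversion reproduces the baseline anchors", {
  cal <- gag_fcd_calibration()
  expect_equal(gag_to_fcd(0.85, 0.80, cal$cs_ks_ratio_np),
               0.30, tolerance = 1e-10)
  expect_equal(gag_to_fcd(0.35, 0.75, cal$cs_ks_ratio_af,
                          tissue_density = cal$tissue_density),
               0.20, tolerance = 1e-10)
})

test_that("GAG to FCD is linear in GAG and follows the dilution law", {
  expect_identical(gag_to_fcd(0, 0.8), 0)
  f1 <- gag_to_fcd(0.2, 0.8)
  expect_equal(gag_to_fcd(0.4, 0.8), 2 * f1, tolerance = 1e-12)
  expect_equal(gag_to_fcd(0.2, 0.4), 2 * f1, tolerance = 1e-12)
  expect_error(gag_to_fcd(0.2, 0), "water_fraction")
  expect_error(gag_to_fcd(-0.1, 0.5), "gag_fraction")
})

test_that("deviatoric strain: arithmetic, hydrostatic invariance, sign", {
  expect_identical(deviatoric_strain(0.02, 0.02, 0.02), 0)
  expect_equal(deviatoric_strain(0.01, 0, 0), 2 / 3 * sqrt(2) * 0.01,
               tolerance = 1e-12)
  set.seed(42)
  e <- matrix(stats::rnorm(3e4, 0, 0.05), ncol = 3)
  ed <- deviatoric_strain(e[, 1], e[, 2], e[, 3])
  expect_true(all(ed >= 0))
  c0 <- stats::runif(1e4, -0.1, 0.1)
  ed_shift <- deviatoric_strain(e[, 1] + c0, e[, 2] + c0, e[, 3] + c0)
  expect_equal(ed_shift, ed, tolerance = 1e-9)
  expect_error(deviatoric_strain(Inf, 0, 0), "finite")
})

test_that("stress evaluation: zero state, fibril tension, composition", {
  pt <- material_point(0.25, 0.65, fcd = 0, region_label = "AF")
  expect_equal(evaluate_stress(pt, matrix(0, 3, 3), cfg),
               matrix(0, 3, 3), tolerance = 1e-14)
  # uniaxial stretch along x loads the crossed AF fibres; stress grows
  # with collagen content
  eps <- diag(c(0.02, 0, 0))
  s_lo <- evaluate_stress(material_point(0.25, 0.3, region_label = "AF"),
                          eps, cfg)
  s_hi <- evaluate_stress(material_point(0.25, 0.65, region_label = "AF"),
                          eps, cfg)
  expect_gt(s_hi[1, 1], s_lo[1, 1])
  # fibrils carry no compression: compressive axial strain leaves only the
  # non-fibrillar part, so stress is insensitive to fibre directions
  epsc <- diag(c(-0.02, 0, 0))
  s_c <- evaluate_stress(material_point(0.25, 0.65, region_label = "AF"),
                         epsc, cfg)
  s_c2 <- evaluate_stress(
    material_point(0.25, 0.65, region_label = "AF",
                   fibre_dirs = rbind(c(1, 0, 0))), epsc, cfg)
  expect_equal(s_c[1, 1], s_c2[1, 1], tolerance = 1e-12)
  expect_error(material_point(0.5, 1.2), "fractions")
  expect_error(material_point(0.5, 0.5, water_fraction = 0.7),
               "exceeds 1")
})

test_that("free swelling balances osmotic pressure against network tension", {
  np <- cfg$composition$np
  w <- free_swelling_equilibrium(np$ns0, np$collagen, np$gag, "NP", cfg)
  # residual of the scalar balance, evaluated independently
  osm <- cfg$osmotic
  fcd <- gag_to_fcd(np$gag, w, osm$cs_ks_ratio_np)
  pi_w <- donnan_pressure(fcd, osm$ext_salt, osm$temperature)
  keff <- np$ns0 * ((1 - np$collagen) * cfg$mechanics$k_nonfibrillar +
                      np$collagen * cfg$mechanics$e_fibril / 9)
  tension <- keff * (w - (1 - np$ns0)) / np$ns0
  expect_equal(pi_w, tension, tolerance = 1e-6)
  # and the full stress tensor at the swollen state is self-balanced:
  # isotropic swelling strain vs osmotic pressure at equilibrium water
  e_sw <- (w - (1 - np$ns0)) / np$ns0 / 3
  pt <- material_point(np$ns0, np$collagen, np$gag, fcd = fcd,
                       water_fraction = w, region_label = "NP")
  sig <- evaluate_stress(pt, diag(rep(e_sw, 3)), cfg)
  expect_lt(abs(mean(diag(sig))) / pi_w, 1e-5)
})

test_that("free swelling: limits, NP vs AF ordering, GAG monotonicity", {
  expect_equal(free_swelling_equilibrium(0.2, 0.15, 0, "NP", cfg), 0.8,
               tolerance = 1e-12)
  w_np <- free_swelling_equilibrium(0.20, 0.15, 0.85, "NP", cfg)
  w_af <- free_swelling_equilibrium(0.25, 0.65, 0.35, "AF", cfg)
  expect_gt(w_np, w_af)
  gags <- seq(0.1, 0.9, by = 0.1)
  ws <- free_swelling_equilibrium(rep(0.2, 9), rep(0.15, 9), gags,
                                  rep("NP", 9), cfg)
  expect_true(all(diff(ws) > 0))
  # independent grid-search oracle for one case
  gag <- 0.5
  osm <- cfg$osmotic
  grid <- seq(0.8, 0.95, by = 1e-5)
  keff <- 0.2 * ((1 - 0.15) * cfg$mechanics$k_nonfibrillar +
                   0.15 * cfg$mechanics$e_fibril / 9)
  resid <- donnan_pressure(gag_to_fcd(gag, grid, osm$cs_ks_ratio_np),
                           osm$ext_salt, osm$temperature) -
    keff * (grid - 0.8) / 0.2
  w_oracle <- grid[which.min(abs(resid))]
  expect_equal(free_swelling_equilibrium(0.2, 0.15, gag, "NP", cfg),
               w_oracle, tolerance = 1e-4)
})

test_that("poroelastic provider: zero load, exact linearity, fluid mass", {
  disc <- make_disc(n_rings = 10, n_sectors = 10)  # 100-element fixture
  pcfg <- cfg
  pcfg$mechanics$provider <- "poroelastic"
  day <- load_case("compression", 300, creep_duration = 1)
  r0 <- solve_activity(disc$mesh, disc$composition,
                       load_case("compression", 0, creep_duration = 1), pcfg)
  expect_true(all(r0$eps_dev == 0) && all(r0$v_f == 0))
  r1 <- solve_activity(disc$mesh, disc$composition, day, pcfg)
  r2 <- solve_activity(disc$mesh, disc$composition,
                       load_case("compression", 600, creep_duration = 1),
                       pcfg)
  expect_equal(r2$eps_dev, 2 * r1$eps_dev, tolerance = 1e-9)
  expect_equal(r2$v_f, 2 * r1$v_f, tolerance = 1e-9)
  # total fluid volume change equals the boundary flux integral
  expect_equal(r1$fluid_volume_change, -r1$boundary_outflow,
               tolerance = 1e-3)
  expect_true(all(r1$eps_dev >= 0) && all(r1$v_f >= 0))
})

test_that("poroelastic provider responds to all four activity modes", {
  disc <- make_disc(n_rings = 8, n_sectors = 12)
  pcfg <- cfg
  pcfg$mechanics$provider <- "poroelastic"
  prog <- daily_program()
  for (a in names(prog$activities)) {
    r <- solve_activity(disc$mesh, disc$composition,
                        prog$activities[[a]]$load, pcfg)
    expect_true(all(is.finite(r$eps_dev)), label = a)
    expect_gt(max(r$eps_dev), 0, label = a)
  }
})

test_that("synthetic provider reproduces its prescribed profile exactly", {
  disc <- small_disc()
  prof <- disc$mesh$stimulus_profile
  r <- solve_activity(disc$mesh, disc$composition,
                      load_case("compression", 300, creep_duration = 1), cfg)
  expect_identical(r$eps_dev, prof$eps_dev)
  expect_identical(r$v_f, prof$v_f)
  r_half <- solve_activity(disc$mesh, disc$composition,
                           load_case("compression", 150,
                                     creep_duration = 1), cfg)
  expect_equal(r_half$eps_dev, prof$eps_dev / 2, tolerance = 1e-12)
})

test_that("preconditioning cycles settle monotonically", {
  disc <- make_disc(n_rings = 8, n_sectors = 8)
  pcfg <- cfg
  pcfg$mechanics$provider <- "poroelastic"
  pc0 <- precondition(disc$mesh, disc$composition, 0, pcfg)
  expect_identical(pc0$displacement, numeric(0))
  pc <- precondition(disc$mesh, disc$composition, 3, pcfg)
  expect_true(pc$converged)
  d <- abs(diff(pc$displacement))
  expect_true(all(diff(d) <= 1e-12))        # non-increasing cycle change
  # already-equilibrated: rerunning returns the same water field
  pc2 <- precondition(disc$mesh, disc$composition, 3, pcfg)
  expect_identical(pc$water, pc2$water)
})
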