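#' Idealised disc mesh with NP/AF composition fields
#'
#' Builds a polar element grid over an elliptical disc cross-section (a
#' generalised template geometry, not a patient shape): a nucleus pulposus
#' core (inner half of the radius), annulus fibrosus rings outside, and a
#' one-ring transition band at the interface.  Baseline composition:
#' NP solid fraction 0.20, collagen 0.15 of dry weight, FCD 0.30 mEq/ml;
#' AF 0.25 / 0.65 / 0.20; GAG is the dry-weight complement of collagen.
#' The AF carries two crossed fibre directions (about +/-30 degrees to the
#' circumferential plane).  Purely deterministic: the same arguments yield
#' byte-identical objects.
#'
#' @param radius disc outer radius (mm)
#' @param aspect anterior-posterior to lateral axis ratio of the ellipse
#' @param height disc height (mm)
#' @param n_rings,n_sectors polar resolution (defaults give an element size
#'   of about 1.5--2.5 mm)
#' @param np_fraction radial extent of the NP core (fraction of radius)
#' @param config model configuration supplying the baseline composition
#' @return object of class `disc_state`: `mesh` (class `disc_mesh`),
#'   `composition` (data.frame: `ns0`, `collagen`, `gag`, `fcd`, `water`,
#'   `region`), `cells` (data.frame: `c_fb`, `c_cc`)
#' @export
make_disc <- function(radius = 20, aspect = 0.75, height = 10,
                      n_rings = 12, n_sectors = 40, np_fraction = 0.5,
                      config = default_config()) {
  stopifnot(radius > 0, height > 0, n_rings >= 2, n_sectors >= 1,
            np_fraction > 0, np_fraction < 1)
  dr <- radius / n_rings
  ring <- rep(seq_len(n_rings), each = n_sectors)
  sector <- rep(seq_len(n_sectors), times = n_rings)
  r <- (ring - 0.5) * dr
  th <- (sector - 0.5) * 2 * pi / n_sectors
  x <- r * cos(th)
  y <- aspect * r * sin(th)
  n <- n_rings * n_sectors
  vol <- aspect * r * dr * (2 * pi / n_sectors) * height
  rel <- r / radius
  np_outer <- np_fraction - dr / radius / 2
  region <- ifelse(rel <= np_outer, "NP",
                   ifelse(rel <= np_fraction + dr / radius, "transition",
                          "AF"))
  np <- config$composition$np
  af <- config$composition$af
  is_np <- region == "NP"
  is_af <- region == "AF"
  mixw <- ifelse(is_np, 1, ifelse(is_af, 0, 0.5))
  ns0 <- mixw * np$ns0 + (1 - mixw) * af$ns0
  collagen <- mixw * np$collagen + (1 - mixw) * af$collagen
  gag <- 1 - collagen
  water <- 1 - ns0
  osm <- config$osmotic
  ratio <- ifelse(is_af, osm$cs_ks_ratio_af,
                  ifelse(is_np, osm$cs_ks_ratio_np,
                         (osm$cs_ks_ratio_np + osm$cs_ks_ratio_af) / 2))
  fcd <- gag_to_fcd(gag, water, ratio, osm$mw_cs, osm$mw_ks,
                    osm$charges_cs, osm$charges_ks, osm$tissue_density)
  mesh <- structure(list(
    centres = cbind(x = x, y = y, z = rep(height / 2, n)),
    volume = vol, r = r, dr = dr,
    ring = ring, sector = sector,
    n_rings = n_rings, n_sectors = n_sectors, n_elements = n,
    radius = radius, height = height,
    sector_index = lapply(seq_len(n_sectors), function(s)
      which(sector == s)[order(ring[sector == s])]),
    stimulus_profile = NULL
  ), class = "disc_mesh")
  composition <- data.frame(ns0 = ns0, collagen = collagen, gag = gag,
                            fcd = fcd, water = water, region = region,
                            stringsAsFactors = FALSE)
  # chondrocytes maintain the NP, fibroblasts the AF; both start at the
  # logistic fixed point of their preferred state
  cells <- data.frame(c_fb = ifelse(is_np, 0, ifelse(is_af, 0.9, 0.45)),
                      c_cc = ifelse(is_np, 0.9, ifelse(is_af, 0, 0.45)))
  structure(list(mesh = mesh, composition = composition, cells = cells),
            class = "disc_state")
}

#' Shell-and-core vertebra voxel grid
#'
#' Parametric surrogate for a vertebral body: a rectangular voxel grid
#' whose outer x/y layer is a near-unity-density cortical shell and whose
#' core is trabecular bone with BV/TV drawn from a truncated normal
#' distribution.  Deterministic per seed.
#'
#' @param nx,ny,nz voxel counts
#' @param voxel voxel edge length (mm)
#' @param shell_bvtv cortical shell density
#' @param core_mean,core_sd trabecular density distribution
#' @param seed RNG seed
#' @param params bone remodelling parameter list
#' @return a [bone_field()] whose `grid` carries `dims`, `centres`,
#'   `voxel` and a logical `core` mask
#' @export
make_vertebra <- function(nx = 10, ny = 10, nz = 8, voxel = 3,
                          shell_bvtv = 0.95, core_mean = 0.2,
                          core_sd = 0.05, seed = 1,
                          params = default_config()$bone) {
  stopifnot(nx >= 3, ny >= 3, nz >= 1, voxel > 0)
  ix <- rep(seq_len(nx), times = ny * nz)
  iy <- rep(rep(seq_len(ny), each = nx), times = nz)
  iz <- rep(seq_len(nz), each = nx * ny)
  centres <- cbind(x = (ix - 0.5) * voxel, y = (iy - 0.5) * voxel,
                   z = (iz - 0.5) * voxel)
  core <- ix > 1 & ix < nx & iy > 1 & iy < ny
  n <- nx * ny * nz
  old <- .Random.seed_store()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(seed)
  bvtv <- rep(shell_bvtv, n)
  bvtv[core] <- rtruncnorm(sum(core), core_mean, core_sd, 0, 1)
  grid <- list(nx = nx, ny = ny, nz = nz, voxel = voxel,
               dims = c(nx, ny, nz), centres = centres, core = core)
  bone_field(grid, bvtv, params)
}

rtruncnorm <- function(n, mean, sd, lo, hi) {
  if (mean <= lo || mean >= hi) {
    stop("truncated normal mean must lie inside (", lo, ", ", hi, ")")
  }
  if (sd == 0) return(rep(mean, n))
  x <- stats::rnorm(n, mean, sd)
  bad <- which(x <= lo | x >= hi)
  while (length(bad)) {
    x[bad] <- stats::rnorm(length(bad), mean, sd)
    bad <- which(x <= lo | x >= hi)
  }
  x
}

.Random.seed_store <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
}
.Random.seed_restore <- function(old) {
  if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
}

#' Noisy follow-up density field
#'
#' Adds i.i.d. Gaussian noise to a ground-truth density field and clamps
#' the result to `[0, 1]`, emulating a follow-up scan re-meshed onto the
#' template grid.  Deterministic per seed; `noise_sd = 0` returns the
#' input.
#'
#' @param truth per-element density field
#' @param noise_sd noise standard deviation
#' @param seed RNG seed
#' @return observed field
#' @export
make_followup <- function(truth, noise_sd, seed = 1) {
  stopifnot(noise_sd >= 0)
  if (noise_sd == 0) return(truth)
  old <- .Random.seed_store()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(seed)
  pmin(pmax(truth + stats::rnorm(length(truth), 0, noise_sd), 0), 1)
}

#' Synthetic radial stimulus profile
#'
#' Attaches analytic per-activity response fields to a disc mesh for the
#' synthetic mechanics provider: deviatoric strain and fluid speed grow
#' quadratically from the disc centre to the rim, calibrated so that at
#' the default daily program the NP falls in the cartilage window
#' (1 < psi <= 3) and the outer AF in the fibrous window (psi > 3).  The
#' profile stores the reference load magnitude of each activity mode;
#' [solve_activity()] scales the fields linearly with magnitude relative
#' to these references.
#'
#' @param mesh a `disc_mesh`
#' @param eps_centre,eps_rim deviatoric strain (percent) at centre and rim
#' @param v_centre,v_rim fluid speed (micrometre/s) at centre and rim
#' @param power radial profile exponent
#' @param program the daily program supplying reference magnitudes
#' @return the mesh with `stimulus_profile` attached
#' @export
make_stimulus_profile <- function(mesh, eps_centre = 9.5, eps_rim = 16,
                                  v_centre = 0.15, v_rim = 2, power = 2,
                                  program = daily_program()) {
  stopifnot(inherits(mesh, "disc_mesh"))
  rel <- (mesh$r / mesh$radius)^power
  eps <- (eps_centre + (eps_rim - eps_centre) * rel) / 100  # fraction
  v <- v_centre + (v_rim - v_centre) * rel
  h_scale <- 5                                             # MPa, nominal
  reference <- lapply(program$activities, function(a) a$load$magnitude)
  names(reference) <- vapply(program$activities,
                             function(a) a$load$mode, character(1))
  mesh$stimulus_profile <- list(eps_dev = eps, v_f = v,
                                sed = 0.5 * h_scale * eps^2,
                                reference = reference)
  mesh
}

#' Fusion load-change factors
#'
#' Per-mode multiplicative factors standing in for the percentage change
#' in adjacent-segment loading computed by a full lumbar-spine model
#' before/after fusion.
#'
#' @param compression,flexion,lateral_bending,axial_rotation positive
#'   factors (1 = unchanged)
#' @return named numeric vector of class `load_change`
#' @export
load_change_factors <- function(compression = 1, flexion = 1,
                                lateral_bending = 1, axial_rotation = 1) {
  f <- c(compression = compression, flexion = flexion,
         lateral_bending = lateral_bending, axial_rotation = axial_rotation)
  if (any(f <= 0)) stop("load change factors must be positive")
  structure(f, class = "load_change")
}
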