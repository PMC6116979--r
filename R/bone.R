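#' Bone surface density of a cylindrical-strut trabecular model
#'
#' With trabeculae modelled as cylindrical struts of radius `strut_radius`,
#' the specific surface is `BS/TV = 2 BV/TV / r` (surface-to-volume ratio
#' of a cylinder), linear in the volume fraction and zero at zero density.
#'
#' @param bvtv bone volume fraction (0--1), vectorised
#' @param strut_radius strut radius (mm)
#' @return bone surface per total volume (1/mm)
#' @export
#' @examples
#' bone_surface_density(0.2, 0.1)
bone_surface_density <- function(bvtv, strut_radius = 0.1) {
  stopifnot(strut_radius > 0)
  if (any(bvtv < 0 | bvtv > 1)) stop("bvtv must be in [0,1]")
  2 * bvtv / strut_radius
}

#' Density to modulus power law
#'
#' `E = e_tissue * bvtv^exponent`, the standard homogenised trabecular-bone
#' stiffness scaling (exponent 2 by default).
#'
#' @param bvtv bone volume fraction (0--1)
#' @param e_tissue tissue modulus at full density (MPa)
#' @param exponent power-law exponent
#' @return element modulus (MPa)
#' @export
density_to_modulus <- function(bvtv, e_tissue = 6000, exponent = 2) {
  if (any(bvtv < 0 | bvtv > 1)) stop("bvtv must be in [0,1]")
  e_tissue * bvtv^exponent
}

#' Construct a vertebral bone field
#'
#' @param grid a voxel grid from [make_vertebra()] (dims, centres, voxel
#'   size)
#' @param bvtv per-element bone volume fraction
#' @param params remodelling parameter list (see `bone` section of
#'   [default_config()])
#' @return object of class `bone_field`
#' @export
bone_field <- function(grid, bvtv, params = default_config()$bone) {
  if (any(bvtv < 0 | bvtv > 1)) stop("bvtv must be in [0,1]")
  structure(list(grid = grid, bvtv = bvtv, sed_ref = NULL, sed_cur = NULL,
                 params = params), class = "bone_field")
}

#' Strain energy density under the compressive load case
#'
#' Linear elastic evaluation of the voxel grid under a uniform axial
#' compressive force, as a statically determinate homogenised load path:
#' every vertical pillar of voxels carries the same axial stress
#' `sigma = F / A` (elements act in series along the load axis), and per
#' element `SED = sigma^2 / (2 E)` with the modulus from
#' [density_to_modulus()].  Stress-controlled loading makes the SED a
#' decreasing function of the element's own density, which is what keeps
#' the site-specific remodelling loop self-limiting.  Elements below
#' `params$bvtv_min` are floored and reported, since a fully resorbed
#' element makes the axial load path singular.
#'
#' @param bone a [bone_field()]
#' @param load compressive force (N)
#' @return per-element strain energy density (MPa)
#' @export
sed_field <- function(bone, load) {
  stopifnot(inherits(bone, "bone_field"), load >= 0)
  g <- bone$grid
  p <- bone$params
  bvtv <- bone$bvtv
  if (any(bvtv < p$bvtv_min)) {
    warning(sum(bvtv < p$bvtv_min),
            " fully resorbed element(s); density floored at bvtv_min")
    bvtv <- pmax(bvtv, p$bvtv_min)
  }
  E <- density_to_modulus(bvtv, p$e_tissue, p$modulus_exponent)
  area <- g$nx * g$ny * g$voxel^2        # mm^2 loaded cross-section
  sigma <- load / area                   # MPa, uniform axial stress
  sigma^2 / (2 * E)
}

#' Site-specific remodelling rate
#'
#' \deqn{\frac{d(BV/TV)}{dt} = g\,(SED_{post} - SED_{ref})\,\alpha\,
#'   \frac{BS}{TV}(BV/TV)}
#' where the gain `g` is the product of the osteoblast formation rate and
#' the osteocyte mechanosensitivity converted once to mm/(MPa day).  The
#' osteoclast terms of the underlying theory cancel exactly in this
#' difference form, so only load *changes* drive density change.
#'
#' @param sed_post,sed_ref current and reference strain energy density
#'   fields (MPa)
#' @param bvtv bone volume fraction field
#' @param params remodelling parameters (`gain`, `alpha`, `strut_radius`)
#' @return rate of change of BV/TV (1/day)
#' @export
#' @examples
#' remodelling_rate(0.002, 0.001, 0.2, default_config()$bone)
remodelling_rate <- function(sed_post, sed_ref, bvtv,
                             params = default_config()$bone) {
  if (length(sed_post) != length(sed_ref)) stop("SED fields not aligned")
  params$gain * (sed_post - sed_ref) * params$alpha *
    bone_surface_density(bvtv, params$strut_radius)
}

#' Integrate bone density to its temporary steady state
#'
#' Explicit Euler loop of [sed_field()] and [remodelling_rate()] until the
#' maximum absolute rate falls below `tol` (or `max_iter` is reached); the
#' density is clamped to `[0, 1]`.  Steps start at `dt` (one day) and,
#' because only the steady endpoint of the window matters, are allowed to
#' grow geometrically up to `dt_max` while the squared SED mismatch decays
#' monotonically (pseudo-time acceleration; stress-shielded regions have
#' very small remodelling rates and would otherwise need decades of daily
#' steps).  If the SED error grows while rates flip sign (incipient
#' oscillation) the step is halved with a warning.  At convergence the
#' current SED matches the reference wherever the density is unclamped.
#'
#' @param bone a [bone_field()] with `sed_ref` set from the pre-operative
#'   solve (see [set_reference_sed()])
#' @param load post-operative compressive force (N)
#' @return updated `bone_field` with fields `sed_cur`, `iterations`,
#'   `converged`
#' @export
remodel_to_steady <- function(bone, load) {
  stopifnot(inherits(bone, "bone_field"))
  if (is.null(bone$sed_ref)) {
    stop("sed_ref not set; call set_reference_sed() first")
  }
  p <- bone$params
  dt <- p$dt
  dt_limit <- p$dt_max
  bvtv <- bone$bvtv
  err_prev <- Inf
  rate_prev <- NULL
  n_halve <- 0
  it <- 0
  converged <- FALSE
  repeat {
    it <- it + 1
    sed <- sed_field(bone_swap(bone, bvtv), load)
    rate <- remodelling_rate(sed, bone$sed_ref, bvtv, p)
    # clamped elements cannot move further in the direction of their rate
    at_hi <- bvtv >= 1 & rate > 0
    at_lo <- bvtv <= 0 & rate < 0
    eff_rate <- rate
    eff_rate[at_hi | at_lo] <- 0
    free <- !(at_hi | at_lo)
    if (max(abs(eff_rate)) < p$tol) { converged <- TRUE; break }
    if (it >= p$max_iter) break
    err <- sum((sed[free] - bone$sed_ref[free])^2)
    if (abs(err - err_prev) <= 1e-10 * max(err_prev, 1e-300) &&
          is.finite(err_prev)) {
      # residual mismatch pinned by clamped elements: temporary steady state
      converged <- TRUE
      break
    }
    if (err > err_prev * (1 + 1e-9) && !is.null(rate_prev) &&
          any(sign(eff_rate) * sign(rate_prev) < 0)) {
      # oscillation: SED error grows while rates flip sign; halve the
      # step and stop the accelerator from regrowing past it
      dt <- max(dt / 2, p$dt / 16)
      dt_limit <- dt
      n_halve <- n_halve + 1
      if (n_halve <= 5) {
        warning("oscillating remodelling at iteration ", it,
                "; halving time step to ", dt, " day")
      }
      if (n_halve >= 20) break
    } else if (err < err_prev) {
      # monotone decay: accelerate the pseudo-time search for the steady
      # state (the endpoint, not the transient, is the quantity of
      # interest within a macro window)
      dt <- min(dt * 1.1, dt_limit)
    }
    err_prev <- err
    rate_prev <- eff_rate
    bvtv <- pmin(pmax(bvtv + dt * eff_rate, 0), 1)
  }
  bone$bvtv <- bvtv
  bone$sed_cur <- sed
  bone$iterations <- it
  bone$converged <- converged
  if (!converged) {
    warning("bone remodelling not converged after ", it,
            " iterations; max |rate| = ", signif(max(abs(eff_rate)), 3))
  }
  bone
}

bone_swap <- function(bone, bvtv) { bone$bvtv <- bvtv; bone }

#' Set the pre-operative reference strain energy density
#'
#' @param bone a [bone_field()]
#' @param load pre-operative compressive force (N)
#' @return `bone_field` with `sed_ref` filled in
#' @export
set_reference_sed <- function(bone, load) {
  bone$sed_ref <- sed_field(bone, load)
  bone
}
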