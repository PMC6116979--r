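#' Default model configuration
#'
#' Returns the full nested parameter list used throughout the simulator.
#' Every entry can be overridden from a YAML/JSON file via [load_config()].
#' The sections mirror the model structure:
#'
#' * `composition`: baseline nucleus pulposus (NP) and annulus fibrosus
#'   (AF) tissue make-up (initial solid volume fraction as fraction of wet
#'   weight, collagen and GAG as fractions of dry weight, fixed charge
#'   density in mEq/ml).
#' * `osmotic`: external salt concentration, temperature and the
#'   chondroitin/keratan-sulfate constants used to convert GAG content to
#'   fixed charge density (FCD).
#' * `mechanics`: effective small-strain moduli of the non-fibrillar
#'   matrix and the collagen fibril network, permeability, and the
#'   mechanics-provider selection.
#' * `program`: the daily activity program (loads, hours, stimulus
#'   divisors).
#' * `cells`, `matrix`, `turnover`: cell population and matrix
#'   synthesis/degradation rate constants (per day).
#' * `bone`: bone remodelling parameters (formation gain, surface model,
#'   density-modulus law) and the compressive bone load case.
#' * `grades`: degeneration-grade vs NP water-content lookup.
#' * `schedule`: macro/micro time-step plan.
#' * `outcomes`: smoothing radius and minimal detectable change.
#'
#' @return A named nested list.
#' @export
#' @examples
#' cfg <- default_config()
#' cfg$cells$fibroblast$f_prolif
default_config <- function() {
  gcal <- gag_fcd_calibration()
  list(
    composition = list(
      np = list(ns0 = 0.20, collagen = 0.15, gag = 0.85, fcd = 0.30),
      af = list(ns0 = 0.25, collagen = 0.65, gag = 0.35, fcd = 0.20)
    ),
    osmotic = list(
      ext_salt = 0.15,         # mEq/ml, physiological saline
      temperature = 310,       # K
      osmotic_coefficient = 1,
      activity_coefficient = 1,
      mw_cs = 513,             # g/mol per chondroitin-sulfate disaccharide
      mw_ks = 464,             # g/mol per keratan-sulfate disaccharide
      charges_cs = 2,
      charges_ks = 1,
      # calibrated so the NP/AF baselines reproduce FCD 0.30/0.20 mEq/ml
      tissue_density = gcal$tissue_density,     # g dry matrix per ml tissue
      cs_ks_ratio_np = gcal$cs_ks_ratio_np,     # CS:KS mass ratio, NP
      cs_ks_ratio_af = gcal$cs_ks_ratio_af      # CS:KS mass ratio, AF
    ),
    mechanics = list(
      provider = "synthetic",  # "synthetic" or "poroelastic"
      k_nonfibrillar = 17.6,   # MPa, effective bulk modulus of ground matrix
      g_nonfibrillar = 6.6,    # MPa, shear modulus of ground matrix
      e_fibril = 340,          # MPa, tension-only fibril modulus
      permeability = 1e-3,     # mm^4/(N s)
      day_compression = 300,   # N
      night_compression = 30,  # N
      disc_height = 10,        # mm (generic template)
      solver_tol = 1e-8
    ),
    program = daily_program(),
    cells = list(
      c_space = 1,
      fibroblast  = list(f_prolif = 0.5, f_differ = 0.2,  f_apopt = 0.05),
      chondrocyte = list(f_prolif = 0.2, f_differ = 0.14, f_apopt = 0.1)
    ),
    matrix = list(
      fibroblast = list(
        collagen = list(m_pref = 0.65, f_synth = 4.8e-3, degrad1 = 2.6e-3),
        gag      = list(m_pref = 0.35, f_synth = 0.85e-3, degrad1 = 0.45e-3)
      ),
      chondrocyte = list(
        collagen = list(m_pref = 0.15, f_synth = 3.1e-3, degrad1 = 1e-3),
        gag      = list(m_pref = 0.85, f_synth = 7.7e-3, degrad1 = 2e-3)
      ),
      degrad2 = 0.0011,        # 1/day, content-excess degradation
      c_ref = 0.9              # cell concentration of healthy tissue
    ),
    turnover = list(
      collagen = 0.00003,      # 1/day (half-life about 95 y)
      gag = 0.00016,           # 1/day (half-life about 12 y)
      gag_half_life_years = 12
    ),
    stimulus = list(
      strain_divisor = 4.67,   # percent deviatoric strain scale
      velocity_divisor = 3,    # micrometre/s fluid speed scale
      total_hours = 16,
      threshold_fibrous = 3,   # psi above which fibrous tissue is preferred
      threshold_low = 1        # psi at or below which stimulus is "low"
    ),
    bone = list(
      gain = 0.475,            # mm/(MPa day), tau*mu after unit conversion
      tau = 475,               # um^3/(nmol day)   (informational)
      mu = 1,                  # nmol/((MPa/s) um^2) (informational)
      f_ocl = 0.03,            # 1/(day mm^2); cancels in site-specific form
      v_res = 5.6e-5,          # mm^3; cancels in site-specific form
      alpha = 0.5,             # fraction of surface available for remodelling
      strut_radius = 0.1,      # mm, cylindrical strut model for BS/TV
      e_tissue = 6000,         # MPa, tissue modulus at BV/TV = 1
      modulus_exponent = 2,
      bvtv_min = 1e-3,
      load = 300,              # N, compressive bone load case
      dt = 1,                  # day
      dt_max = 64,             # day, pseudo-time cap for the steady search
      tol = 1e-7,              # 1/day, steady-state criterion on |rate|
      max_iter = 20000
    ),
    grades = grade_water_table(),
    schedule = list(
      first_year_window = 90,  # days
      later_window = 180,      # days
      micro_dt = 1,            # day
      order = "bone_then_disc"
    ),
    outcomes = list(
      smoothing_radius = 2,    # mm
      mdc = 1.9,               # percent, minimal detectable change
      density_floor = 0        # exclude rim elements below this BV/TV
    )
  )
}

#' Degeneration grade vs nucleus water content lookup
#'
#' Pfirrmann-style grades I--V tied to NP water volume fraction.  The
#' healthy--degenerate span 0.81--0.75 anchors the table; the interior
#' break points are an assumption (literature reports a monotone decrease
#' of NP water with grade but no universal break points) and every entry
#' can be overridden through the `grades` config section.
#'
#' @return data.frame with columns `grade` (I..V), `water` (representative
#'   water fraction) and `lower` (lower edge of the grade's water
#'   interval; the interval is `[lower, lower of previous grade)`).
#' @export
grade_water_table <- function() {
  data.frame(
    grade = c("I", "II", "III", "IV", "V"),
    water = c(0.810, 0.790, 0.775, 0.760, 0.745),
    lower = c(0.800, 0.7825, 0.7675, 0.7525, -Inf),
    stringsAsFactors = FALSE
  )
}

#' Calibrate the GAG to fixed-charge-density conversion
#'
#' The FCD carried by a unit of tissue fluid follows from the GAG dry-weight
#' fraction, the dry-matrix density, the fluid fraction, and the charge per
#' gram of the two sulfated GAG species (chondroitin sulfate, CS: 2 charges
#' per 513 g/mol disaccharide; keratan sulfate, KS: 1 charge per 464 g/mol).
#' Two scalars are free: the effective dry-matrix density and the AF CS:KS
#' ratio.  They are fixed once, in closed form, so that the baseline NP
#' (GAG 0.85 dry weight, water 0.80) maps to 0.30 mEq/ml and the baseline
#' AF (GAG 0.35, water 0.75) maps to 0.20 mEq/ml, with the NP CS:KS mass
#' ratio held at 0.25.
#'
#' @param fcd_np,fcd_af target baseline FCD values (mEq/ml)
#' @param cs_ks_ratio_np assumed NP chondroitin:keratan sulfate mass ratio
#' @return list with `tissue_density` (g/ml), `cs_ks_ratio_np`,
#'   `cs_ks_ratio_af`
#' @export
gag_fcd_calibration <- function(fcd_np = 0.30, fcd_af = 0.20,
                                cs_ks_ratio_np = 0.25) {
  q_cs <- 2 / 513 * 1000  # mEq per g CS
  q_ks <- 1 / 464 * 1000  # mEq per g KS
  r_np <- cs_ks_ratio_np / (1 + cs_ks_ratio_np)  # CS mass fraction
  q_np <- r_np * q_cs + (1 - r_np) * q_ks
  # anchors: fcd = rho_dry * q * gag / water
  rho_dry <- fcd_np * 0.80 / 0.85 / q_np
  q_af <- fcd_af * 0.75 / 0.35 / rho_dry
  r_af <- (q_af - q_ks) / (q_cs - q_ks)
  if (r_af < 0 || r_af > 1) {
    stop("GAG/FCD calibration infeasible: AF CS fraction ", signif(r_af, 4))
  }
  list(
    tissue_density = rho_dry,
    cs_ks_ratio_np = cs_ks_ratio_np,
    cs_ks_ratio_af = r_af / (1 - r_af)
  )
}

#' Load and validate a configuration file
#'
#' Reads a YAML (or JSON) configuration, rejects keys that do not exist in
#' [default_config()], and merges the overrides onto the defaults.  With
#' `merge_defaults = FALSE` the file must itself provide every key and a
#' missing key raises a named error.
#'
#' @param path path to a `.yaml`/`.yml`/`.json` file, or `NULL` for pure
#'   defaults
#' @param merge_defaults merge the file onto the defaults (default `TRUE`)
#' @return validated nested configuration list
#' @export
load_config <- function(path = NULL, merge_defaults = TRUE) {
  defaults <- default_config()
  if (is.null(path)) return(defaults)
  if (!file.exists(path)) stop("config file not found: ", path)
  over <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    yaml::read_yaml(path)
  }
  if (is.null(over)) over <- list()
  check_unknown_keys(over, defaults, "config")
  cfg <- if (merge_defaults) merge_config(defaults, over) else over
  validate_config(cfg, defaults, "config")
  cfg
}

check_unknown_keys <- function(over, defaults, path) {
  if (!is.list(over) || !is.list(defaults)) return(invisible())
  if (is.data.frame(defaults)) return(invisible())
  bad <- setdiff(names(over), names(defaults))
  if (length(bad)) {
    stop("unknown config key(s): ", paste0(path, "$", bad, collapse = ", "))
  }
  for (k in names(over)) {
    if (is.list(defaults[[k]]) && !is.data.frame(defaults[[k]])) {
      check_unknown_keys(over[[k]], defaults[[k]], paste0(path, "$", k))
    }
  }
  invisible()
}

merge_config <- function(defaults, over) {
  if (!is.list(over)) return(over)
  if (is.data.frame(over) || !is.list(defaults) || is.data.frame(defaults)) {
    return(over)
  }
  for (k in names(over)) {
    defaults[[k]] <- merge_config(defaults[[k]], over[[k]])
  }
  defaults
}

validate_config <- function(cfg, defaults, path) {
  if (!is.list(defaults) || is.data.frame(defaults)) return(invisible())
  missing <- setdiff(names(defaults), names(cfg))
  if (length(missing)) {
    stop("missing required config key(s): ",
         paste0(path, "$", missing, collapse = ", "))
  }
  for (k in names(defaults)) {
    validate_config(cfg[[k]], defaults[[k]], paste0(path, "$", k))
  }
  invisible()
}
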