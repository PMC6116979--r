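#' Daily activity program
#'
#' The generic daily loading pattern driving the disc: standing (axial
#' compression, 300 N) for 5.5 h, walking (lateral bending 1.5 deg at
#' 0.5 Hz) for 2 h, periodic movements (axial rotation 0.9 deg at 0.5 Hz)
#' for 4.5 h and sitting (flexion 2 deg plus a half-hour creep) for 4 h,
#' 16 waking hours in total.  The stimulus divisors scale percent
#' deviatoric strain (4.67) and fluid speed in micrometre/s (3).
#'
#' @param compression day compression force (N)
#' @param flexion_deg,lateral_deg,rotation_deg imposed angles (degrees)
#' @param hours named numeric vector of activity durations (h)
#' @param strain_divisor,velocity_divisor stimulus normalisation constants
#' @return object of class `daily_program`
#' @export
daily_program <- function(compression = 300, flexion_deg = 2,
                          lateral_deg = 1.5, rotation_deg = 0.9,
                          hours = c(standing = 5.5, walking = 2,
                                    periodic_movements = 4.5, sitting = 4),
                          strain_divisor = 4.67, velocity_divisor = 3) {
  stopifnot(strain_divisor > 0, velocity_divisor > 0, all(hours > 0))
  activities <- list(
    standing = list(load = load_case("compression", compression,
                                     creep_duration = 1),
                    hours = unname(hours["standing"])),
    walking = list(load = load_case("lateral_bending", lateral_deg,
                                    frequency = 0.5),
                   hours = unname(hours["walking"])),
    periodic_movements = list(load = load_case("axial_rotation", rotation_deg,
                                               frequency = 0.5),
                              hours = unname(hours["periodic_movements"])),
    sitting = list(load = load_case("flexion", flexion_deg,
                                    creep_duration = 0.5),
                   hours = unname(hours["sitting"]))
  )
  structure(list(activities = activities,
                 strain_divisor = strain_divisor,
                 velocity_divisor = velocity_divisor,
                 total_hours = sum(hours)),
            class = "daily_program")
}

#' Daily mechanical stimulus
#'
#' Aggregates the per-activity time-averaged deviatoric shear strain and
#' fluid speed into the daily stimulus
#' \deqn{\psi = \frac{1}{16}\left(\frac{\sum_a \varepsilon^{dev}_a[\%]\,h_a}
#'   {4.67} + \frac{\sum_a v_{f,a}[\mu m/s]\,h_a}{3}\right)}
#' where \eqn{h_a} are the activity hours.  Strain enters in percent, fluid
#' speed in micrometre/s.
#'
#' @param per_activity named list of [solve_activity()] results, one per
#'   program activity
#' @param program a [daily_program()]
#' @return numeric vector of per-element stimulus values
#' @export
daily_stimulus <- function(per_activity, program = daily_program()) {
  stopifnot(inherits(program, "daily_program"))
  missing <- setdiff(names(program$activities), names(per_activity))
  if (length(missing)) {
    stop("missing activity result(s): ", paste(missing, collapse = ", "))
  }
  n <- length(per_activity[[1]]$eps_dev)
  eps_acc <- numeric(n); v_acc <- numeric(n)
  for (a in names(program$activities)) {
    res <- per_activity[[a]]
    if (length(res$eps_dev) != n || length(res$v_f) != n) {
      stop("activity '", a, "' has mismatched field length")
    }
    h <- program$activities[[a]]$hours
    eps_acc <- eps_acc + 100 * res$eps_dev * h   # fraction -> percent
    v_acc <- v_acc + res$v_f * h
  }
  (eps_acc / program$strain_divisor + v_acc / program$velocity_divisor) /
    program$total_hours
}

#' Classify the preferred tissue phenotype
#'
#' Step classification of the daily stimulus: above 3 the fibroblast
#' (fibrous) phenotype is preferred, between 1 (exclusive) and 3 the
#' chondrocyte (cartilage) phenotype, and at or below 1 the stimulus is
#' flagged `low_stimulus` (treated as chondrocyte-preferred by the matrix
#' dynamics, since ossification of disc tissue is outside the model).
#' Boundary values fall into the lower class.
#'
#' @param psi non-negative stimulus values
#' @param threshold_fibrous,threshold_low class boundaries
#' @return factor with levels `low_stimulus`, `cartilage`, `fibrous`
#' @export
#' @examples
#' classify_phenotype(c(0.5, 2, 3, 4))
classify_phenotype <- function(psi, threshold_fibrous = 3,
                               threshold_low = 1) {
  if (any(psi < 0)) stop("psi must be non-negative")
  lab <- ifelse(psi > threshold_fibrous, "fibrous",
                ifelse(psi > threshold_low, "cartilage", "low_stimulus"))
  if (any(lab == "low_stimulus")) {
    message("note: ", sum(lab == "low_stimulus"),
            " point(s) in the low-stimulus regime ",
            "(treated as chondrocyte-preferred)")
  }
  factor(lab, levels = c("low_stimulus", "cartilage", "fibrous"))
}
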