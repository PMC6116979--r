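#' Macro-step schedule
#'
#' Default semi-coupled plan: four 90-day windows over the first
#' post-operative year (when the largest changes are expected), then
#' 180-day windows to the horizon.  Within each window bone remodelling
#' runs to its temporary steady state first, then disc adaptation runs
#' with daily micro steps.  The horizon is rounded down to whole windows.
#'
#' @param horizon_years simulation horizon (years of 365 days)
#' @param first_year_window,later_window window lengths (days)
#' @param micro_dt disc micro time step (days)
#' @return object of class `schedule` with `windows` (days) and `micro_dt`
#' @export
#' @examples
#' length(make_schedule(10)$windows)  # 4 + 18
make_schedule <- function(horizon_years, first_year_window = 90,
                          later_window = 180, micro_dt = 1) {
  stopifnot(horizon_years > 0, first_year_window > 0, later_window > 0)
  horizon <- round(horizon_years * 365)
  w <- rep(first_year_window, min(4, horizon %/% first_year_window))
  remaining <- horizon - sum(w)
  if (remaining >= later_window) {
    w <- c(w, rep(later_window, remaining %/% later_window))
  }
  structure(list(windows = w, micro_dt = micro_dt,
                 order = "bone_then_disc", horizon_days = sum(w)),
            class = "schedule")
}

#' Apply fusion load-change factors to a daily program
#'
#' Multiplies each activity's load magnitude by its mode's factor; time
#' weights are unchanged.  Factors commute and compose multiplicatively.
#'
#' @param program a [daily_program()]
#' @param load_change a [load_change_factors()] vector
#' @return the scaled program
#' @export
apply_fusion <- function(program, load_change) {
  stopifnot(inherits(program, "daily_program"))
  if (any(load_change <= 0)) stop("load change factors must be positive")
  for (a in names(program$activities)) {
    mode <- program$activities[[a]]$load$mode
    f <- unname(load_change[mode])
    if (is.na(f)) f <- 1
    program$activities[[a]]$load$magnitude <-
      program$activities[[a]]$load$magnitude * f
  }
  program
}

solve_all_activities <- function(disc, program, config) {
  res <- lapply(program$activities, function(a)
    solve_activity(disc$mesh, disc$composition, a$load, config))
  names(res) <- names(program$activities)
  res
}

region_means <- function(disc, psi) {
  comp <- disc$composition
  out <- list()
  for (reg in c("NP", "AF")) {
    sel <- comp$region == reg
    out[[reg]] <- c(collagen = mean(comp$collagen[sel]),
                    gag = mean(comp$gag[sel]),
                    water = mean(comp$water[sel]),
                    fcd = mean(comp$fcd[sel]),
                    psi = mean(psi[sel]))
  }
  out
}

#' Simulate coupled disc adaptation and bone remodelling after fusion
#'
#' The main model driver.  Starting from a (preconditioned) disc state and
#' a vertebral bone field with the pre-operative strain energy density as
#' reference, the post-fusion daily program is obtained by scaling each
#' activity with its load-change factor; then, per macro window: (1) bone
#' density remodels to its temporary steady state under the post-operative
#' compressive load, (2) the disc mechanics are re-solved for every
#' activity, the daily stimulus and preferred phenotype are updated, and
#' (3) the disc extracellular matrix adapts with daily explicit Euler
#' steps for the window length, after which water and fixed charge density
#' are re-equilibrated.  Deterministic given its inputs.
#'
#' @param disc a `disc_state` from [make_disc()] (with a stimulus profile
#'   attached when the synthetic provider is used)
#' @param bone a [bone_field()] from [make_vertebra()], or `NULL` to run
#'   the disc alone
#' @param load_change per-mode [load_change_factors()]
#' @param horizon_years simulation horizon
#' @param config model configuration
#' @param program pre-operative daily program
#' @param precondition_cycles compression/creep cycles before adaptation
#'   (poroelastic provider only)
#' @return object of class `spine_adapt`; see [summary.spine_adapt()]
#' @export
#' @examples
#' disc <- make_disc(n_rings = 6, n_sectors = 12)
#' disc$mesh <- make_stimulus_profile(disc$mesh)
#' fit <- spine_adapt(disc, bone = NULL,
#'                    load_change = load_change_factors(),
#'                    horizon_years = 1)
#' fit
spine_adapt <- function(disc, bone = NULL,
                        load_change = load_change_factors(),
                        horizon_years = 2, config = default_config(),
                        program = daily_program(),
                        precondition_cycles = 3) {
  stopifnot(inherits(disc, "disc_state"))
  schedule <- make_schedule(horizon_years, config$schedule$first_year_window,
                            config$schedule$later_window,
                            config$schedule$micro_dt)
  post_program <- apply_fusion(program, load_change)
  # mechanical preconditioning and initial swelling equilibrium
  if (config$mechanics$provider == "poroelastic" && precondition_cycles > 0) {
    pre <- precondition(disc$mesh, disc$composition, precondition_cycles,
                        config)
    disc$composition$water <- pre$water
  } else {
    disc$composition$water <- free_swelling_equilibrium(
      disc$composition$ns0, disc$composition$collagen, disc$composition$gag,
      disc$composition$region, config)
  }
  if (!is.null(bone)) {
    stopifnot(inherits(bone, "bone_field"))
    pre_load <- bone$params$load
    post_load <- pre_load * unname(load_change["compression"])
    bone <- set_reference_sed(bone, pre_load)
  }
  snapshots <- list()
  log <- data.frame()
  clock <- 0
  baseline <- region_means(disc, rep(NA_real_, disc$mesh$n_elements))
  for (step in seq_along(schedule$windows)) {
    window <- schedule$windows[step]
    if (!is.null(bone)) {
      bone <- remodel_to_steady(bone, post_load)
    }
    acts <- solve_all_activities(disc, post_program, config)
    psi <- daily_stimulus(acts, post_program)
    phenotype <- suppressMessages(
      classify_phenotype(psi, config$stimulus$threshold_fibrous,
                         config$stimulus$threshold_low))
    disc <- adaptation_window(disc, phenotype, window, config,
                              schedule$micro_dt)
    clock <- clock + window
    rm <- region_means(disc, psi)
    snapshots[[step]] <- list(
      day = clock,
      composition = disc$composition,
      cells = disc$cells,
      psi = psi, phenotype = phenotype,
      bvtv = if (!is.null(bone)) bone$bvtv else NULL
    )
    log <- rbind(log, data.frame(
      step = step, day = clock,
      mean_psi = mean(psi),
      np_collagen = rm$NP["collagen"], np_gag = rm$NP["gag"],
      np_water = rm$NP["water"], af_collagen = rm$AF["collagen"],
      mean_bvtv = if (!is.null(bone)) mean(bone$bvtv) else NA_real_,
      bone_iters = if (!is.null(bone)) bone$iterations else NA_integer_
    ))
  }
  rownames(log) <- NULL
  structure(list(
    snapshots = snapshots, log = log, schedule = schedule,
    disc = disc, bone = bone, load_change = load_change,
    baseline = baseline, config = config, program = program,
    post_program = post_program, horizon_years = horizon_years
  ), class = "spine_adapt")
}

#' @export
print.spine_adapt <- function(x, ...) {
  cat("Coupled disc adaptation / bone remodelling simulation\n")
  cat(sprintf("  horizon: %d days in %d macro windows (%s)\n",
              x$schedule$horizon_days, length(x$schedule$windows),
              x$schedule$order))
  cat("  load change factors:",
      paste(sprintf("%s=%.3g", names(x$load_change), x$load_change),
            collapse = ", "), "\n")
  last <- x$log[nrow(x$log), ]
  cat(sprintf("  final NP collagen %.3f, GAG %.3f, water %.3f\n",
              last$np_collagen, last$np_gag, last$np_water))
  if (!is.na(last$mean_bvtv)) {
    cat(sprintf("  final mean BV/TV %.4f\n", last$mean_bvtv))
  }
  invisible(x)
}

#' Summarise a coupled simulation
#'
#' @param object a `spine_adapt` fit
#' @param ... unused
#' @return object of class `summary.spine_adapt`: the per-window log plus
#'   relative NP water change and phenotype composition of the final state
#' @export
summary.spine_adapt <- function(object, ...) {
  last <- object$snapshots[[length(object$snapshots)]]
  w0 <- object$baseline$NP["water"]
  rel_water <- (object$log$np_water[nrow(object$log)] - w0) / w0
  structure(list(
    log = object$log,
    phenotype_table = table(last$phenotype),
    np_rel_water_change = unname(rel_water),
    horizon_days = object$schedule$horizon_days,
    load_change = object$load_change
  ), class = "summary.spine_adapt")
}

#' @export
print.summary.spine_adapt <- function(x, ...) {
  cat("Per-window summary:\n")
  print(x$log, digits = 4, row.names = FALSE)
  cat("\nFinal preferred phenotype counts:\n")
  print(x$phenotype_table)
  cat(sprintf("\nRelative NP water change: %+.3f%%\n",
              100 * x$np_rel_water_change))
  invisible(x)
}

#' Predict the degeneration grade trajectory
#'
#' Translates the simulated relative NP water change at each snapshot into
#' a degeneration grade via [translate_grade()], starting from a known
#' baseline grade.
#'
#' @param object a `spine_adapt` fit
#' @param baseline_grade pre-operative grade (`"I"`..`"V"`)
#' @param ... unused
#' @return data.frame with `day`, `rel_water_change`, `grade`,
#'   `grade_change`
#' @export
predict.spine_adapt <- function(object, baseline_grade = "II", ...) {
  w0 <- object$baseline$NP["water"]
  table <- object$config$grades
  out <- lapply(seq_along(object$snapshots), function(i) {
    s <- object$snapshots[[i]]
    sel <- s$composition$region == "NP"
    rel <- (mean(s$composition$water[sel]) - w0) / w0
    g <- translate_grade(baseline_grade, rel, table)
    data.frame(day = s$day, rel_water_change = unname(rel),
               grade = g$grade, grade_change = g$grade_change)
  })
  do.call(rbind, out)
}

#' @export
as.data.frame.spine_adapt <- function(x, ...) x$log

#' Plot simulated tissue time courses
#'
#' NP collagen/GAG/water trajectories and, when a bone field is present,
#' the mean bone volume fraction, against days since surgery.
#'
#' @param x a `spine_adapt` fit
#' @param ... passed to [graphics::matplot()]
#' @export
plot.spine_adapt <- function(x, ...) {
  log <- x$log
  has_bone <- !all(is.na(log$mean_bvtv))
  oldpar <- graphics::par(mfrow = c(1, if (has_bone) 2 else 1))
  on.exit(graphics::par(oldpar))
  graphics::matplot(log$day, cbind(log$np_collagen, log$np_gag,
                                   log$np_water),
                    type = "b", pch = 1:3, lty = 1,
                    xlab = "days since surgery", ylab = "fraction",
                    main = "NP composition", ...)
  graphics::legend("right", c("collagen", "GAG", "water"),
                   pch = 1:3, col = 1:3, lty = 1, bty = "n")
  if (has_bone) {
    graphics::plot(log$day, log$mean_bvtv, type = "b",
                   xlab = "days since surgery", ylab = "mean BV/TV",
                   main = "Bone density")
  }
  invisible(x)
}
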