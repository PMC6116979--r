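#' One explicit Euler step of the cell population dynamics
#'
#' Per point, fibroblast and chondrocyte concentrations (normalised to the
#' available cell space) evolve by logistic proliferation of the preferred
#' phenotype, conversion (differentiation) of the non-preferred into the
#' preferred type at the source type's differentiation rate, and
#' first-order apoptosis of both types.  The rate constants are switched
#' on/off by the preferred phenotype; `low_stimulus` counts as
#' chondrocyte-preferred.  Concentrations are clamped to `[0, c_space]`.
#'
#' @param cells data.frame with columns `c_fb`, `c_cc`
#' @param phenotype factor/character vector from [classify_phenotype()]
#' @param config model configuration (`cells` section)
#' @param dt_days time step (days, at most 1)
#' @return updated `cells` data.frame
#' @export
update_cells <- function(cells, phenotype, config = default_config(),
                         dt_days = 1) {
  if (dt_days <= 0 || dt_days > 1) stop("dt_days must be in (0, 1]")
  cc <- config$cells
  cs <- cc$c_space
  c_fb <- cells$c_fb; c_cc <- cells$c_cc
  if (any(c_fb < 0 | c_fb > cs | c_cc < 0 | c_cc > cs)) {
    stop("cell concentrations outside [0, c_space]")
  }
  fib_pref <- phenotype == "fibrous"
  fb <- cc$fibroblast; ch <- cc$chondrocyte
  # preferred type: logistic proliferation - apoptosis + influx from the
  # other type; non-preferred type: differentiation out + apoptosis
  d_fb <- ifelse(fib_pref,
                 fb$f_prolif * c_fb * (1 - c_fb / cs) - fb$f_apopt * c_fb +
                   ch$f_differ * c_cc,
                 -fb$f_differ * c_fb - fb$f_apopt * c_fb)
  d_cc <- ifelse(fib_pref,
                 -ch$f_differ * c_cc - ch$f_apopt * c_cc,
                 ch$f_prolif * c_cc * (1 - c_cc / cs) - ch$f_apopt * c_cc +
                   fb$f_differ * c_fb)
  cells$c_fb <- pmin(pmax(c_fb + dt_days * d_fb, 0), cs)
  cells$c_cc <- pmin(pmax(c_cc + dt_days * d_cc, 0), cs)
  cells
}

# net rate of change of one matrix species (vectorised over points)
matrix_rate <- function(m, c_fb, c_cc, fib_pref, p_fb, p_cc, k_turn, deg2,
                        c_ref) {
  synth_fb <- p_fb$f_synth * c_fb * pmax(1 - m / p_fb$m_pref, 0)
  synth_cc <- p_cc$f_synth * c_cc * pmax(1 - m / p_cc$m_pref, 0)
  deg2_fb <- deg2 * c_fb * pmax(m - p_fb$m_pref, 0) / p_fb$m_pref
  deg2_cc <- deg2 * c_cc * pmax(m - p_cc$m_pref, 0) / p_cc$m_pref
  # turnover by the preferred type: continuous degradation balanced by
  # baseline synthesis, net k_turn * (c/c_ref) * (m_pref - m) / m_pref
  turn <- ifelse(fib_pref,
                 k_turn * (c_fb / c_ref) * (p_fb$m_pref - m) / p_fb$m_pref,
                 k_turn * (c_cc / c_ref) * (p_cc$m_pref - m) / p_cc$m_pref)
  ifelse(fib_pref,
         synth_fb - p_cc$degrad1 * c_cc - deg2_fb - deg2_cc + turn,
         synth_cc - p_fb$degrad1 * c_fb - deg2_fb - deg2_cc + turn)
}

#' One explicit Euler step of the matrix dynamics
#'
#' Collagen and GAG dry-weight fractions evolve by: synthesis by the
#' preferred cell type toward its preferred content (shut off at and above
#' the target), constant-rate degradation by the non-preferred type,
#' content-excess degradation by either type whenever the current content
#' exceeds that type's preferred value, and a slow natural turnover by the
#' preferred type (half-life-derived degradation balanced by equal baseline
#' synthesis so healthy tissue is a fixed point).  All terms scale with the
#' cell concentrations; fractions are clamped to `[0, 1]`.
#'
#' @param state data.frame with columns `m_col`, `m_gag`, `c_fb`, `c_cc`
#' @param phenotype preferred phenotype labels
#' @param config model configuration (`matrix` + `turnover` sections)
#' @param dt_days time step (days, at most 1)
#' @return updated `state`
#' @export
update_matrix <- function(state, phenotype, config = default_config(),
                          dt_days = 1) {
  if (dt_days <= 0 || dt_days > 1) stop("dt_days must be in (0, 1]")
  mx <- config$matrix
  if (any(state$m_col < 0 | state$m_col > 1 |
            state$m_gag < 0 | state$m_gag > 1)) {
    stop("matrix fractions outside [0,1]")
  }
  fib_pref <- phenotype == "fibrous"
  d_col <- matrix_rate(state$m_col, state$c_fb, state$c_cc, fib_pref,
                       mx$fibroblast$collagen, mx$chondrocyte$collagen,
                       config$turnover$collagen, mx$degrad2, mx$c_ref)
  d_gag <- matrix_rate(state$m_gag, state$c_fb, state$c_cc, fib_pref,
                       mx$fibroblast$gag, mx$chondrocyte$gag,
                       config$turnover$gag, mx$degrad2, mx$c_ref)
  state$m_col <- pmin(pmax(state$m_col + dt_days * d_col, 0), 1)
  state$m_gag <- pmin(pmax(state$m_gag + dt_days * d_gag, 0), 1)
  state
}

#' Run the disc adaptation for a time window
#'
#' Daily explicit Euler loop of [update_cells()] then [update_matrix()] at
#' fixed stimulus, followed by a refresh of the fixed charge density
#' ([gag_to_fcd()]) and the swelling-equilibrium water content
#' ([free_swelling_equilibrium()]).
#'
#' @param disc a `disc_state` (see [make_disc()]) holding mesh,
#'   composition and cell fields
#' @param phenotype per-element preferred phenotype labels
#' @param window_days length of the window (days; 0 returns the input)
#' @param config model configuration
#' @param dt_days micro time step (days)
#' @return updated `disc_state`
#' @export
adaptation_window <- function(disc, phenotype, window_days,
                              config = default_config(), dt_days = 1) {
  stopifnot(inherits(disc, "disc_state"), window_days >= 0)
  if (window_days == 0) return(disc)
  state <- data.frame(m_col = disc$composition$collagen,
                      m_gag = disc$composition$gag,
                      c_fb = disc$cells$c_fb, c_cc = disc$cells$c_cc)
  n_steps <- round(window_days / dt_days)
  for (i in seq_len(n_steps)) {
    state[c("c_fb", "c_cc")] <-
      update_cells(state[c("c_fb", "c_cc")], phenotype, config, dt_days)
    state <- update_matrix(state, phenotype, config, dt_days)
  }
  disc$cells$c_fb <- state$c_fb
  disc$cells$c_cc <- state$c_cc
  disc$composition$collagen <- state$m_col
  disc$composition$gag <- state$m_gag
  disc$composition$water <- free_swelling_equilibrium(
    disc$composition$ns0, disc$composition$collagen, disc$composition$gag,
    disc$composition$region, config)
  osm <- config$osmotic
  ratio <- ifelse(disc$composition$region == "AF", osm$cs_ks_ratio_af,
                  ifelse(disc$composition$region == "NP", osm$cs_ks_ratio_np,
                         (osm$cs_ks_ratio_np + osm$cs_ks_ratio_af) / 2))
  disc$composition$fcd <- gag_to_fcd(
    disc$composition$gag, disc$composition$water, ratio,
    osm$mw_cs, osm$mw_ks, osm$charges_cs, osm$charges_ks,
    osm$tissue_density)
  disc
}

#' Translate a relative water change into a degeneration grade
#'
#' The predicted absolute NP water content is the baseline grade's
#' representative water content scaled by `1 + relative_change`; the
#' predicted grade is the row of the grade/water lookup whose interval
#' contains that value.  Water outside the table range is clamped with a
#' warning.
#'
#' @param baseline_grade one of `"I"`..`"V"`
#' @param relative_water_change relative change (e.g. -0.02 for a 2% drop)
#' @param table grade/water lookup, see [grade_water_table()]
#' @return list with `grade` (character), `water` (absolute content) and
#'   `grade_change` (integer steps from baseline)
#' @export
#' @examples
#' translate_grade("II", -0.03)
translate_grade <- function(baseline_grade, relative_water_change,
                            table = grade_water_table()) {
  if (!baseline_grade %in% table$grade) {
    stop("baseline_grade must be one of ", paste(table$grade, collapse = ", "))
  }
  if (any(diff(table$water) >= 0)) {
    stop("grade table must be monotone decreasing in water")
  }
  w0 <- table$water[table$grade == baseline_grade]
  w <- w0 * (1 + relative_water_change)
  if (w > max(table$water)) {
    warning("water content above table range; clamped")
    w <- max(table$water)
  }
  if (w < table$water[nrow(table)]) {
    warning("water content below table range; clamped to grade ",
            table$grade[nrow(table)])
  }
  idx <- which(w >= table$lower)[1]
  list(grade = table$grade[idx], water = w,
       grade_change = idx - which(table$grade == baseline_grade))
}
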