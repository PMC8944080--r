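#' Molar conversion of Trp to indole
#'
#' `100 * (indole / 117.15) / (trp / 204.23)` — moles of indole formed per
#' mole of Trp supplied, in percent. The reported figure is rounded to the
#' nearest integer (halves away from zero); the raw value is retained.
#'
#' @param indole_g_per_l indole titer (g/L).
#' @param trp_supplied_g_per_l total Trp supplied up to the sampling time
#'   (g/L; split feeds are summed), > 0.
#' @return a list with `raw` (%), `reported` (integer %); values above 100%
#'   indicate inconsistent inputs and set `flag = "exceeds_100"`.
#' @examples
#' mol_conversion(0.22, 1)$reported  # 38
#' mol_conversion(0.94, 4)$reported  # 41
#' @export
mol_conversion <- function(indole_g_per_l, trp_supplied_g_per_l) {
  stop_if(!is_number(trp_supplied_g_per_l) || trp_supplied_g_per_l <= 0,
          "'trp_supplied_g_per_l' must be > 0")
  stop_if(indole_g_per_l < 0, "'indole_g_per_l' must be >= 0")
  raw <- 100 * (indole_g_per_l / trp_constants$mw_indole) /
    (trp_supplied_g_per_l / trp_constants$mw_trp)
  list(raw = raw, reported = as.integer(round_half_away(raw)),
       flag = if (raw > 100) "exceeds_100" else NA_character_)
}

#' Theoretical indole titer at complete molar conversion
#'
#' `trp * 117.15 / 204.23` g/L; reported to one decimal, raw retained.
#'
#' @param trp_g_per_l Trp supplied (g/L), >= 0.
#' @return list with `raw` and `reported` (g/L).
#' @examples
#' theoretical_titer(10)$reported  # 5.7
#' @export
theoretical_titer <- function(trp_g_per_l) {
  stop_if(any(trp_g_per_l < 0), "'trp_g_per_l' must be >= 0")
  raw <- trp_g_per_l * trp_constants$mw_indole / trp_constants$mw_trp
  list(raw = raw, reported = round_half_away(raw, 1))
}

#' Space-time yield
#'
#' Product titer divided by elapsed process time, g/L/h; reported to two
#' decimals, raw retained.
#'
#' @param titer_g_per_l product titer (g/L).
#' @param elapsed_h elapsed time (h), > 0.
#' @return list with `raw` and `reported` (g/L/h).
#' @examples
#' space_time_yield(1.2, 9)$reported   # 0.13
#' space_time_yield(5.7, 24)$reported  # 0.24
#' @export
space_time_yield <- function(titer_g_per_l, elapsed_h) {
  stop_if(!is_number(elapsed_h) || elapsed_h <= 0, "'elapsed_h' must be > 0")
  raw <- titer_g_per_l / elapsed_h
  list(raw = raw, reported = round_half_away(raw, 2))
}

#' Medium-normalized titer of a two-phase culture
#'
#' Total solute mass divided by the aqueous (medium) volume:
#' `(c_org * v_org + c_aq * v_aq) / v_aq`. For a 20% (v/v, relative to the
#' medium) overlay holding nearly all the product this equals `c_org / 5` —
#' the product is 5-times concentrated in the overlay.
#'
#' @param state a [two_phase_state()].
#' @return normalized titer (g/L of medium).
#' @examples
#' st <- two_phase_state(v_aq = 1, v_org = 0.2, c_aq = 0, c_org = 28)
#' normalize_overlay(st)  # 5.6
#' @export
normalize_overlay <- function(state) {
  stop_if(!inherits(state, "two_phase_state"), "'state' must be a two_phase_state")
  (state$c_org * state$v_org + state$c_aq * state$v_aq) / state$v_aq
}

#' Extraction capacity of an organic overlay
#'
#' Percent of the solute's total mass in the organic phase at equilibrium:
#' `100 * c_org v_org / (c_org v_org + c_aq v_aq)`. Invariant under joint
#' scaling of both volumes.
#'
#' @param state a [two_phase_state()].
#' @return percent in `[0, 100]`; zero total mass returns `NA` with a
#'   warning.
#' @export
extraction_capacity <- function(state) {
  stop_if(!inherits(state, "two_phase_state"), "'state' must be a two_phase_state")
  m_org <- state$c_org * state$v_org
  m_aq <- state$c_aq * state$v_aq
  if (m_org + m_aq <= 0) {
    warning("zero total mass: extraction capacity undefined")
    return(NA_real_)
  }
  100 * m_org / (m_org + m_aq)
}

#' Molar mass balance of a bioconversion time course
#'
#' Closes the molar balance over a culture time course: Trp supplied (all
#' doses up to the final sample) versus residual Trp, indole produced and the
#' integrated off-gas loss; whatever remains is the unexplained gap. Off-gas
#' integration is `rate x duration / volume`. A gap above 5% of the supplied
#' moles is flagged.
#'
#' @param timecourse data frame with `time_h`, `trp_g_l`, `indole_g_l`,
#'   ordered in time (out-of-order samples are an error); e.g. from
#'   [simulate_fermentation()].
#' @param trp_doses data frame with `time_h`, `trp_g_l`.
#' @param offgas_rate_ug_h indole loss rate to the off-gas (ug/h).
#' @param volume_l working volume (L).
#' @return a `conversion_report` list: `mol_pct` (list raw/reported),
#'   `titer`, `space_time_yield` (list raw/reported),
#'   `theoretical_max_titer`, `balance_closure` (fraction of supplied moles
#'   accounted for), `losses_g_l` (off-gas, indole equivalents),
#'   `unexplained_g_l`, `flag`.
#' @export
mass_balance <- function(timecourse, trp_doses, offgas_rate_ug_h = 0,
                         volume_l = 1) {
  stop_if(nrow(timecourse) < 2L, "need at least 2 samples")
  stop_if(is.unsorted(timecourse$time_h), "samples out of time order")
  mw <- trp_constants
  t_final <- timecourse$time_h[nrow(timecourse)]
  elapsed <- t_final - timecourse$time_h[1]
  supplied_g <- sum(trp_doses$trp_g_l[trp_doses$time_h <= t_final + 1e-9])
  stop_if(supplied_g <= 0, "no Trp supplied before the final sample")

  trp_final <- timecourse$trp_g_l[nrow(timecourse)]
  indole_final <- timecourse$indole_g_l[nrow(timecourse)]
  offgas_g_l <- offgas_rate_ug_h * elapsed / 1e6 / volume_l

  supplied_mol <- supplied_g / mw$mw_trp
  residual_mol <- trp_final / mw$mw_trp
  indole_mol <- indole_final / mw$mw_indole
  offgas_mol <- offgas_g_l / mw$mw_indole
  unexplained_mol <- supplied_mol - residual_mol - indole_mol - offgas_mol
  closure <- (residual_mol + indole_mol + offgas_mol) / supplied_mol

  structure(list(
    mol_pct = mol_conversion(indole_final, supplied_g),
    titer = indole_final,
    space_time_yield = if (elapsed > 0) space_time_yield(indole_final, elapsed)
                       else list(raw = NA_real_, reported = NA_real_),
    theoretical_max_titer = theoretical_titer(supplied_g),
    balance_closure = closure,
    losses_g_l = offgas_g_l,
    unexplained_g_l = unexplained_mol * mw$mw_indole,
    flag = if (abs(unexplained_mol) > 0.05 * supplied_mol) "gap_over_5pct"
           else NA_character_
  ), class = "conversion_report")
}

#' @export
print.conversion_report <- function(x, ...) {
  cat("Bioconversion report\n")
  cat(sprintf("  titer               %.3g g/L (theoretical max %.1f g/L)\n",
              x$titer, x$theoretical_max_titer$reported))
  cat(sprintf("  molar conversion    %d mol-%% (raw %.1f)\n",
              x$mol_pct$reported, x$mol_pct$raw))
  cat(sprintf("  space-time yield    %.2f g/L/h\n",
              x$space_time_yield$reported))
  cat(sprintf("  balance closure     %.1f%%  (off-gas %.2g g/L, unexplained %.2g g/L)\n",
              100 * x$balance_closure, x$losses_g_l, x$unexplained_g_l))
  if (!is.na(x$flag)) cat("  flag:", x$flag, "\n")
  invisible(x)
}
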