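#' Specification of a simulated Trp-to-indole biotransformation
#'
#' Parameters of the discrete-time whole-cell bioconversion simulator: Trp
#' doses enter the broth at given times, are converted to indole with
#' first-order kinetics in the remaining Trp, and indole can be lost by a
#' late-stage decline (emulating the post-peak product loss seen in
#' cultivation) and by an off-gas stripping rate.
#'
#' @param trp_doses data frame with columns `time_h` and `trp_g_l`.
#' @param k_conv first-order conversion rate constant (1/h).
#' @param late_loss_rate indole loss rate (g/L/h) active from
#'   `late_loss_start_h` on; 0 disables.
#' @param late_loss_start_h onset of the late loss (h).
#' @param offgas_rate_ug_h indole loss to the off-gas (ug/h over the whole
#'   vessel).
#' @param volume_l working volume (L), converts the off-gas rate to g/L/h.
#' @param sample_times_h sampling grid (h).
#' @param dt_h integration step (h).
#' @param noise_sd additive Gaussian noise on sampled concentrations (g/L).
#' @param rng_seed integer seed.
#' @return a validated `fermentation_spec` list.
#' @export
fermentation_spec <- function(trp_doses = data.frame(time_h = 0, trp_g_l = 2),
                              k_conv = 0.5,
                              late_loss_rate = 0, late_loss_start_h = 24,
                              offgas_rate_ug_h = 0, volume_l = 0.75,
                              sample_times_h = seq(0, 48, by = 2),
                              dt_h = 0.1, noise_sd = 0, rng_seed = 1L) {
  stop_if(any(trp_doses$trp_g_l < 0), "doses must be non-negative")
  stop_if(!is_number(k_conv) || k_conv < 0, "'k_conv' must be >= 0")
  stop_if(late_loss_rate < 0 || offgas_rate_ug_h < 0 || noise_sd < 0,
          "rates and noise must be >= 0")
  stop_if(!is_number(volume_l) || volume_l <= 0, "'volume_l' must be > 0")
  structure(list(trp_doses = trp_doses, k_conv = k_conv,
                 late_loss_rate = late_loss_rate,
                 late_loss_start_h = late_loss_start_h,
                 offgas_rate_ug_h = offgas_rate_ug_h, volume_l = volume_l,
                 sample_times_h = sort(sample_times_h), dt_h = dt_h,
                 noise_sd = noise_sd, rng_seed = as.integer(rng_seed)),
            class = "fermentation_spec")
}

#' Simulate a fermentation time course
#'
#' Explicit forward integration on a fixed grid. Molar bookkeeping is exact at
#' every step: moles of Trp consumed equal moles of indole produced, and every
#' loss term (late decline, off-gas) is accumulated, so at zero noise
#' `supplied = residual Trp + indole + losses` in moles to machine precision.
#'
#' @param spec a [fermentation_spec()].
#' @return a tibble with columns `time_h`, `trp_g_l`, `indole_g_l` (noisy if
#'   `noise_sd > 0`, floored at 0); attributes `truth` (noiseless tibble
#'   including cumulative `loss_g_l` in indole equivalents), `supplied_g_l`
#'   (per sample time) and the spec.
#' @examples
#' fm <- simulate_fermentation(fermentation_spec(k_conv = 1))
#' tail(fm, 3)
#' @export
simulate_fermentation <- function(spec) {
  stop_if(!inherits(spec, "fermentation_spec"),
          "'spec' must be a fermentation_spec")
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(spec$rng_seed)

  mw <- trp_constants
  t_end <- max(spec$sample_times_h)
  grid <- seq(0, t_end, by = spec$dt_h)
  offgas_g_l_h <- spec$offgas_rate_ug_h / 1e6 / spec$volume_l

  trp <- 0; indole <- 0; loss <- 0
  out <- matrix(NA_real_, length(grid), 4,
                dimnames = list(NULL, c("time_h", "trp_g_l", "indole_g_l",
                                        "loss_g_l")))
  dosed <- logical(nrow(spec$trp_doses))
  for (i in seq_along(grid)) {
    t <- grid[i]
    due <- !dosed & spec$trp_doses$time_h <= t + 1e-9
    if (any(due)) {
      trp <- trp + sum(spec$trp_doses$trp_g_l[due])
      dosed[due] <- TRUE
    }
    out[i, ] <- c(t, trp, indole, loss)
    if (i == length(grid)) break
    # conversion: Trp mass converted this step, molar 1:1 to indole
    d_trp <- trp * (1 - exp(-spec$k_conv * spec$dt_h))
    trp <- trp - d_trp
    indole <- indole + d_trp * mw$mw_indole / mw$mw_trp
    # losses, floored so indole never goes negative
    l_rate <- offgas_g_l_h +
      if (grid[i + 1] > spec$late_loss_start_h) spec$late_loss_rate else 0
    d_loss <- min(indole, l_rate * spec$dt_h)
    indole <- indole - d_loss
    loss <- loss + d_loss
  }

  truth <- tibble::as_tibble(as.data.frame(out))
  idx <- vapply(spec$sample_times_h, function(ts)
    which.min(abs(grid - ts)), integer(1))
  sampled <- truth[idx, ]
  supplied <- vapply(sampled$time_h, function(ts)
    sum(spec$trp_doses$trp_g_l[spec$trp_doses$time_h <= ts + 1e-9]),
    numeric(1))
  noisy <- sampled
  if (spec$noise_sd > 0) {
    noisy$trp_g_l <- pmax(0, noisy$trp_g_l +
                            rnorm(nrow(noisy), 0, spec$noise_sd))
    noisy$indole_g_l <- pmax(0, noisy$indole_g_l +
                               rnorm(nrow(noisy), 0, spec$noise_sd))
  }
  structure(noisy[, c("time_h", "trp_g_l", "indole_g_l")],
            truth = sampled, supplied_g_l = supplied, spec = spec,
            class = c("culture_timecourse", class(tibble::tibble())))
}

#' Equilibrate a solute between aqueous and organic phases
#'
#' Closed-form two-phase equilibrium for in situ product recovery: given the
#' overall concentration (total mass over total volume), the phase volumes and
#' the partition coefficient `K = c_org / c_aq`, returns the state satisfying
#' both the partition ratio and mass conservation.
#'
#' @param c_total total mass / (v_aq + v_org), g/L.
#' @param v_aq,v_org phase volumes (L), > 0.
#' @param partition_coefficient `K >= 0`; 0 keeps all mass aqueous.
#' @param solvent optional solvent name.
#' @return a [two_phase_state()].
#' @examples
#' st <- simulate_two_phase(1, v_aq = 1, v_org = 1, partition_coefficient = 1)
#' extraction_capacity(st)  # 50
#' @export
simulate_two_phase <- function(c_total, v_aq, v_org, partition_coefficient,
                               solvent = NA_character_) {
  stop_if(!is_number(v_aq) || v_aq <= 0, "'v_aq' must be > 0")
  stop_if(!is_number(v_org) || v_org <= 0, "'v_org' must be > 0")
  stop_if(!is_number(partition_coefficient) || partition_coefficient < 0,
          "'partition_coefficient' must be >= 0")
  mass <- c_total * (v_aq + v_org)
  c_aq <- mass / (v_aq + partition_coefficient * v_org)
  c_org <- partition_coefficient * c_aq
  two_phase_state(v_aq = v_aq, v_org = v_org, c_aq = c_aq, c_org = c_org,
                  solvent = solvent)
}

#' Two-phase state container
#'
#' @param v_aq,v_org phase volumes (L), > 0.
#' @param c_aq,c_org solute concentrations (g/L), >= 0.
#' @param solvent optional solvent name.
#' @return a `two_phase_state` list.
#' @export
two_phase_state <- function(v_aq, v_org, c_aq, c_org,
                            solvent = NA_character_) {
  stop_if(v_aq <= 0 || v_org <= 0, "volumes must be > 0")
  stop_if(!is.finite(c_aq * v_aq) || !is.finite(c_org * v_org),
          "phase masses must be finite")
  structure(list(v_aq = v_aq, v_org = v_org, c_aq = c_aq, c_org = c_org,
                 solvent = solvent),
            class = "two_phase_state")
}
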