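#' Specification of a simulated coupled TNA-LDH/NADH assay
#'
#' Parameters of the coupled photometric assay: tryptophanase cleaves Trp to
#' indole + pyruvate + ammonia; lactate dehydrogenase (in excess) immediately
#' reduces the liberated pyruvate to lactate, oxidising one NADH per Trp
#' converted. The NADH absorbance at 340 nm therefore decays at the
#' tryptophanase rate (quasi-steady coupling).
#'
#' @param km_true Michaelis constant of the simulated enzyme (mM).
#' @param kcat_true turnover number (1/s).
#' @param enzyme_molar enzyme concentration (mM); together with `kcat_true`
#'   this sets `v_max = 60 * kcat * E` in mM/min.
#' @param substrate_levels assay substrate concentrations (mM), ascending;
#'   default a doubling series from 6.25e-3 to 6.4 plus 10 mM.
#' @param nadh0 initial NADH (mM).
#' @param epsilon_nadh molar absorption coefficient (mM^-1 cm^-1).
#' @param path_length optical path (cm).
#' @param noise_sd additive Gaussian absorbance noise (AU); and/or
#' @param noise_rel noise as a fraction of the clean trace's amplitude
#'   (max - min); the two standard deviations add in quadrature.
#' @param duration_s,sampling_interval_s trace length and sampling step (s).
#' @param rng_seed integer seed.
#' @return a validated `assay_spec` list.
#' @export
assay_spec <- function(km_true = 0.14, kcat_true = 1.65,
                       enzyme_molar = 1e-4,
                       substrate_levels = c(0.00625 * 2^(0:10), 10),
                       nadh0 = 0.2,
                       epsilon_nadh = trp_constants$epsilon_nadh,
                       path_length = 1,
                       noise_sd = 0, noise_rel = 0,
                       duration_s = 600, sampling_interval_s = 10,
                       rng_seed = 1L) {
  stop_if(!is_number(km_true) || km_true <= 0, "'km_true' must be > 0")
  stop_if(!is_number(kcat_true) || kcat_true <= 0, "'kcat_true' must be > 0")
  stop_if(!is_number(enzyme_molar) || enzyme_molar <= 0,
          "'enzyme_molar' must be > 0")
  stop_if(any(substrate_levels <= 0), "substrate levels must be > 0")
  stop_if(is.unsorted(substrate_levels, strictly = TRUE),
          "'substrate_levels' must be sorted ascending")
  stop_if(!is_number(nadh0) || nadh0 <= 0, "'nadh0' must be > 0")
  stop_if(noise_sd < 0 || noise_rel < 0, "noise must be >= 0")
  structure(list(km_true = km_true, kcat_true = kcat_true,
                 enzyme_molar = enzyme_molar,
                 substrate_levels = substrate_levels,
                 nadh0 = nadh0, epsilon_nadh = epsilon_nadh,
                 path_length = path_length,
                 noise_sd = noise_sd, noise_rel = noise_rel,
                 duration_s = duration_s,
                 sampling_interval_s = sampling_interval_s,
                 rng_seed = as.integer(rng_seed)),
            class = "assay_spec")
}

#' Simulate one absorbance trace of the coupled assay
#'
#' The initial-rate regime is simulated: substrate is treated as constant over
#' the trace, so NADH decays linearly at the Michaelis-Menten rate
#' `v = v_max * S / (Km + S)` until exhaustion, where the trace truncates and
#' is flagged. Absorbance is `epsilon * l * NADH(t)` plus Gaussian noise.
#'
#' @param spec an [assay_spec()].
#' @param substrate substrate concentration for this trace (mM).
#' @param rng_seed per-trace seed override; defaults to the spec seed.
#'   Distinct seeds change only the noise realisation, never the clean trace.
#' @return a `kinetic_trace` tibble with columns `time_s`, `absorbance`;
#'   attributes `conditions` (the spec plus this substrate), `exhausted_at_s`
#'   (NA if NADH never runs out) and `rate_true_mM_min`. NADH exhaustion
#'   before the second sample is an error.
#' @examples
#' tr <- simulate_assay_trace(assay_spec(noise_sd = 0), substrate = 0.14)
#' head(tr)
#' @export
simulate_assay_trace <- function(spec, substrate, rng_seed = NULL) {
  stop_if(!inherits(spec, "assay_spec"), "'spec' must be an assay_spec")
  stop_if(!is_number(substrate) || substrate <= 0, "'substrate' must be > 0")
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(rng_seed %||% spec$rng_seed)

  vmax <- 60 * spec$kcat_true * spec$enzyme_molar        # mM/min
  v <- vmax * substrate / (spec$km_true + substrate)      # mM/min
  t <- seq(0, spec$duration_s, by = spec$sampling_interval_s)
  nadh <- spec$nadh0 - v * t / 60
  exhausted_at <- if (any(nadh < 0)) t[which(nadh < 0)[1]] else NA_real_
  keep <- nadh >= 0
  stop_if(sum(keep) < 2L, "NADH exhausted before the second sample; ",
          "reduce enzyme or shorten the sampling interval")
  t <- t[keep]; nadh <- nadh[keep]
  clean <- spec$epsilon_nadh * spec$path_length * nadh
  sd_total <- sqrt(spec$noise_sd^2 +
                     (spec$noise_rel * (max(clean) - min(clean)))^2)
  absorbance <- clean + rnorm(length(clean), 0, sd_total)
  conditions <- c(unclass(spec), list(substrate = substrate))
  structure(tibble::tibble(time_s = t, absorbance = absorbance),
            conditions = conditions,
            exhausted_at_s = exhausted_at,
            rate_true_mM_min = v,
            class = c("kinetic_trace", class(tibble::tibble())))
}
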