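# R-squared without summary.lm (which warns on zero-residual fits)
r_squared <- function(fit, y) {
  ss_tot <- sum((y - mean(y))^2)
  if (ss_tot == 0) return(NA_real_)
  1 - sum(stats::residuals(fit)^2) / ss_tot
}

#' Initial rate from an absorbance trace
#'
#' Least-squares slope of absorbance vs time over a window, converted to an
#' NADH oxidation rate: `rate = -slope / (epsilon * l)` in mM/min. Because one
#' NADH is oxidised per Trp cleaved (via the lactate dehydrogenase indicator
#' reaction), this equals the tryptophanase rate.
#'
#' @param trace a `kinetic_trace` from [simulate_assay_trace()], or any data
#'   frame with `time_s` and `absorbance` plus `epsilon_nadh`/`path_length`
#'   passed explicitly.
#' @param window `c(t0, t1)` in seconds, or `NULL` for the default window.
#' @param method window default: `"head"` uses the first 10% of the trace (at
#'   least 3 points); `"auto"` slides a window of 25% of the points and keeps
#'   the one with maximal R-squared.
#' @param epsilon_nadh,path_length photometric constants; defaults taken from
#'   the trace conditions when present.
#' @return a `rate_estimate` list: `initial_rate` (mM/min, floored at 0),
#'   `fit_window` (s), `r_squared`, `substrate` (mM, if known), `n_points`.
#'   A window overlapping NADH exhaustion is an error; a noise-dominated
#'   window (R-squared < 0.5) warns.
#' @export
trace_to_rate <- function(trace, window = NULL, method = c("head", "auto"),
                          epsilon_nadh = NULL, path_length = NULL) {
  method <- match.arg(method)
  cond <- attr(trace, "conditions")
  epsilon_nadh <- epsilon_nadh %||% cond$epsilon_nadh %||%
    trp_constants$epsilon_nadh
  path_length <- path_length %||% cond$path_length %||% 1
  t <- trace$time_s
  a <- trace$absorbance
  stop_if(length(t) < 3L, "need at least 3 points")

  if (is.null(window)) {
    if (method == "head") {
      t1 <- t[1] + 0.1 * (t[length(t)] - t[1])
      idx <- which(t <= t1)
      if (length(idx) < 3L) idx <- seq_len(3L)
    } else {
      w <- max(3L, ceiling(0.25 * length(t)))
      best_r2 <- -Inf; idx <- seq_len(w)
      for (s in seq_len(length(t) - w + 1L)) {
        ii <- s:(s + w - 1L)
        r2 <- r_squared(lm(a[ii] ~ t[ii]), a[ii])
        if (is.finite(r2) && r2 > best_r2) { best_r2 <- r2; idx <- ii }
      }
    }
    window <- range(t[idx])
  } else {
    stop_if(window[1] < t[1] || window[2] > t[length(t)],
            "window outside trace span")
    idx <- which(t >= window[1] & t <= window[2])
    stop_if(length(idx) < 3L, "fewer than 3 points in window")
  }
  exhausted <- attr(trace, "exhausted_at_s")
  stop_if(!is.null(exhausted) && !is.na(exhausted) &&
            window[2] >= exhausted,
          "NADH exhausted within the fit window (at ", exhausted, " s)")

  fit <- lm(a[idx] ~ t[idx])
  slope_per_s <- unname(coef(fit)[2])
  r2 <- r_squared(fit, a[idx])
  if (!is.finite(r2)) r2 <- NA_real_
  if (!is.na(r2) && r2 < 0.5)
    warning("noise-dominated window: R-squared = ", signif(r2, 3))
  rate <- max(0, -slope_per_s * 60 / (epsilon_nadh * path_length))
  structure(list(initial_rate = rate, fit_window = window,
                 r_squared = r2, substrate = cond$substrate %||% NA_real_,
                 n_points = length(idx)),
            class = "rate_estimate")
}

#' Fit Michaelis-Menten kinetics to initial rates
#'
#' Nonlinear least squares on `v = v_max * S / (Km + S)`
#' (Levenberg-Marquardt), initialised at `v_max0 = max(rate)` and `Km0 =`
#' the substrate concentration at half-maximal rate (interpolated).
#' `k_cat = v_max / (60 * E)` converts the maximal rate (mM/min) to a
#' turnover number (1/s) via the molar enzyme concentration. Standard errors
#' come from the local curvature at the optimum.
#'
#' @param rates data frame with columns `substrate` (mM) and `rate` (mM/min);
#'   replicate rows per substrate are welcome. At least 4 distinct substrate
#'   levels are required (fewer leave Km and v_max unidentifiable).
#' @param enzyme_molar enzyme concentration (mM); `NA` leaves `kcat` `NA`.
#' @return an `mm_fit` list: `km`, `vmax`, `kcat`, `se_km`, `se_vmax`,
#'   `se_kcat`, `residual_sd`, `n_points`. Km outside the sampled substrate
#'   range triggers an extrapolation warning.
#' @examples
#' S <- c(0.025, 0.05, 0.14, 0.5, 2, 10)
#' v <- 0.0099 * S / (0.14 + S)
#' fit_mm(data.frame(substrate = S, rate = v), enzyme_molar = 1e-4)
#' @export
fit_mm <- function(rates, enzyme_molar = NA_real_) {
  stop_if(is.null(rates$substrate) || is.null(rates$rate),
          "'rates' needs 'substrate' and 'rate' columns")
  stop_if(length(unique(rates$substrate)) < 4L,
          "unidentifiable design: need >= 4 distinct substrate levels ",
          "spanning below and above the presumed Km")
  vmax0 <- max(rates$rate)
  mean_rate <- tapply(rates$rate, rates$substrate, mean)
  S_sorted <- as.numeric(names(mean_rate))
  km0 <- tryCatch(
    approx(as.numeric(mean_rate), S_sorted, xout = vmax0 / 2, ties = mean)$y,
    error = function(e) NA_real_)
  if (is.na(km0) || km0 <= 0) km0 <- stats::median(rates$substrate)

  fit <- tryCatch(
    minpack.lm::nlsLM(rate ~ vmax * substrate / (km + substrate),
                      data = rates,
                      start = list(vmax = vmax0, km = km0),
                      lower = c(vmax = 1e-12, km = 1e-12),
                      control = minpack.lm::nls.lm.control(maxiter = 200)),
    error = function(e)
      stop("Michaelis-Menten fit did not converge (started at vmax0 = ",
           signif(vmax0, 4), ", Km0 = ", signif(km0, 4), "): ",
           conditionMessage(e), call. = FALSE))
  est <- coef(fit)
  se <- tryCatch(sqrt(diag(vcov(fit))),
                 error = function(e) c(vmax = NA_real_, km = NA_real_))
  if (est[["km"]] < min(rates$substrate) || est[["km"]] > max(rates$substrate))
    warning("fitted Km (", signif(est[["km"]], 3),
            " mM) lies outside the sampled substrate range: extrapolation")
  kcat <- est[["vmax"]] / (60 * enzyme_molar)
  se_kcat <- se[["vmax"]] / (60 * enzyme_molar)
  structure(list(km = est[["km"]], vmax = est[["vmax"]], kcat = kcat,
                 se_km = se[["km"]], se_vmax = se[["vmax"]],
                 se_kcat = se_kcat,
                 residual_sd = sqrt(mean(stats::residuals(fit)^2)),
                 n_points = nrow(rates)),
            class = "mm_fit")
}

#' @export
print.mm_fit <- function(x, ...) {
  cat(sprintf("Michaelis-Menten fit (n = %d):\n", x$n_points))
  cat(sprintf("  Km    = %.2f +/- %.2f mM\n", x$km, x$se_km))
  cat(sprintf("  vmax  = %.4g +/- %.2g mM/min\n", x$vmax, x$se_vmax))
  if (!is.na(x$kcat))
    cat(sprintf("  kcat  = %.2f +/- %.2f 1/s\n", x$kcat, x$se_kcat))
  invisible(x)
}

#' Catalytic efficiency kcat/Km
#'
#' Central value `kcat / Km` in mM^-1 s^-1, reported to one decimal (the raw
#' value is retained). Uncertainty: the standard deviation of per-replicate
#' ratios when replicate `(kcat, km)` pairs are given, else first-order error
#' propagation from the standard errors.
#'
#' @param fit an `mm_fit`, or a numeric `kcat` when `km` is supplied.
#' @param km,se_kcat,se_km numerics, used when `fit` is a bare `kcat`.
#' @param replicates optional data frame with columns `kcat` and `km`, one
#'   row per replicate.
#' @return an `efficiency_result` list: `kcat_over_km` (raw), `reported`
#'   (1 decimal), `uncertainty`, `method`.
#' @examples
#' efficiency(1.65, km = 0.14)$reported  # 11.8
#' @export
efficiency <- function(fit, km = NULL, se_kcat = NULL, se_km = NULL,
                       replicates = NULL) {
  if (inherits(fit, "mm_fit")) {
    kcat <- fit$kcat; km <- fit$km
    se_kcat <- fit$se_kcat; se_km <- fit$se_km
  } else {
    kcat <- fit
    stop_if(is.null(km), "supply 'km' when 'fit' is a bare kcat value")
  }
  stop_if(!is_number(km) || km == 0, "Km must be nonzero")
  val <- kcat / km
  if (!is.null(replicates)) {
    ratios <- replicates$kcat / replicates$km
    unc <- sd(ratios)
    method <- "per-replicate"
  } else if (!is.null(se_kcat) && !is.null(se_km) &&
             !anyNA(c(se_kcat, se_km))) {
    unc <- abs(val) * sqrt((se_kcat / kcat)^2 + (se_km / km)^2)
    method <- "first-order"
  } else {
    unc <- NA_real_
    method <- "none"
  }
  structure(list(kcat_over_km = val,
                 reported = round_half_away(val, 1),
                 uncertainty = unc, method = method),
            class = "efficiency_result")
}

#' Specific enzymatic activity
#'
#' One unit (U) converts 1 umol substrate per minute; specific activity is
#' reported in mU per mg protein.
#'
#' @param rate_umol_min measured rate (umol/min).
#' @param protein_mg protein amount (mg), > 0.
#' @return specific activity in mU/mg.
#' @examples
#' specific_activity(0.087, 1)  # 87 mU/mg
#' @export
specific_activity <- function(rate_umol_min, protein_mg) {
  stop_if(any(protein_mg <= 0), "'protein_mg' must be > 0")
  1000 * rate_umol_min / protein_mg
}
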