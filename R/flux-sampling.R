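#' Artificial-centering hit-and-run flux sampling
#'
#' Samples the flux polytope `{S v = 0, lb <= v <= ub}` with the
#' artificial-centering hit-and-run Markov chain: warm-up points are the
#' per-reaction flux-variability optima, the chain starts at their mean, and
#' each step moves from the current point along the direction from the running
#' center to a randomly chosen stored point, by a uniform draw on the feasible
#' chord. Directions are projected onto the null space of `S` and the state is
#' re-projected periodically, so every retained sample satisfies the steady
#' state within tolerance.
#'
#' @param model a `metabolic_model`; non-finite bounds are capped at `cap`.
#' @param n number of retained samples (default 10000).
#' @param seed integer seed; the chain is deterministic given the seed.
#' @param burn_in iterations discarded before retention (default 1000).
#' @param thinning keep every `thinning`-th iterate (default 10).
#' @param cap cap for non-finite bounds.
#' @return an object of class `flux_samples`: list with `samples`
#'   (n x n_reactions matrix), `seed`, `n`. If the polytope is a single point
#'   the sampler warns and returns that point replicated.
#' @examples
#' s <- achr_sample(toy_segment_model(), n = 100, seed = 1,
#'                  burn_in = 50, thinning = 2)
#' colMeans(s$samples)
#' @export
achr_sample <- function(model, n = 10000, seed = NULL, burn_in = 1000,
                        thinning = 10, cap = 1000) {
  stop_if(!is_count(n), "'n' must be a positive count")
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  if (!is.null(seed)) set.seed(seed)

  S <- stoich_matrix(model)
  b <- cap_bounds(bounds_of(model), cap)
  lb <- b$lb; ub <- b$ub
  nr <- ncol(S)

  warm <- fva(model, cap = cap)$points
  if (nrow(warm) == 0L) stop("infeasible start: no warm-up points")

  make_result <- function(samples) {
    structure(list(samples = samples, seed = seed, n = nrow(samples)),
              class = "flux_samples")
  }
  spread <- apply(warm, 2, function(x) diff(range(x)))
  if (all(spread < 1e-9)) {
    warning("degenerate (zero-volume) polytope: returning the single ",
            "feasible point")
    samples <- matrix(rep(warm[1, ], each = n), n, nr,
                      dimnames = list(NULL, colnames(S)))
    return(make_result(samples))
  }

  # orthonormal basis of null(S) and the projector onto it
  qrt <- qr(t(S))
  r <- qrt$rank
  if (r < nr) {
    N <- qr.Q(qrt, complete = TRUE)[, (r + 1):nr, drop = FALSE]
    P <- N %*% t(N)
  } else {
    P <- matrix(0, nr, nr)
  }

  center <- colMeans(warm)
  x <- center
  pts <- matrix(NA_real_, nrow(warm) + n, nr)
  pts[seq_len(nrow(warm)), ] <- warm
  npts <- nrow(warm)
  samples <- matrix(NA_real_, n, nr, dimnames = list(NULL, colnames(S)))
  kept <- 0L
  total <- burn_in + n * thinning
  visited <- 0

  for (iter in seq_len(total)) {
    w <- pts[sample.int(npts, 1L), ]
    d <- as.numeric(P %*% (w - center))
    nd <- sqrt(sum(d^2))
    if (nd > 1e-10) {
      d <- d / nd
      move <- abs(d) > 1e-9
      tmax <- Inf; tmin <- -Inf
      hi <- (ub - x)[move] / d[move]
      lo <- (lb - x)[move] / d[move]
      tmax <- min(pmax(hi, lo))
      tmin <- max(pmin(hi, lo))
      if (tmax > tmin) {
        x <- x + runif(1, tmin, tmax) * d
        x <- pmin(pmax(x, lb), ub)
      }
    }
    visited <- visited + 1
    center <- (center * visited + x) / (visited + 1)
    if (iter %% 500L == 0L) x <- pmin(pmax(as.numeric(P %*% x), lb), ub)
    if (iter > burn_in && (iter - burn_in) %% thinning == 0L) {
      kept <- kept + 1L
      samples[kept, ] <- x
      npts <- npts + 1L
      pts[npts, ] <- x
      if (kept == n) break
    }
  }
  make_result(samples[seq_len(kept), , drop = FALSE])
}

#' @export
print.flux_samples <- function(x, ...) {
  cat("ACHR flux samples: ", x$n, " x ", ncol(x$samples), " reactions",
      if (!is.null(x$seed)) paste0(" (seed ", x$seed, ")"), "\n", sep = "")
  invisible(x)
}

#' Decompose the producers of a metabolite
#'
#' For each reaction, the production contribution to a target metabolite is
#' `stoichiometric coefficient x flux` whenever that signed product is
#' positive, so reversible reactions are counted by their realised direction
#' and consumers never appear. For a sample set the per-sample contributions
#' are averaged before normalising (gross accounting, default); `"net"`
#' instead applies the sign rule to the mean flux vector. Fractions sum to 1
#' whenever total production is positive.
#'
#' @param model a `metabolic_model`.
#' @param flux a `flux_vector` from [fba()], a named flux vector, or a
#'   `flux_samples` object from [achr_sample()].
#' @param metabolite metabolite id (e.g. pyruvate) whose producers to
#'   decompose.
#' @param method `"gross"` (per-sample realised direction) or `"net"`.
#' @return list with `status` (`"ok"` or `"no_production"`), `total`
#'   (production flux) and `breakdown` (tibble `reaction`, `contribution`,
#'   `fraction`, producers only, sorted by fraction).
#' @examples
#' m <- toy_twopath_model()
#' producer_breakdown(m, fba(m), "P")
#' @export
producer_breakdown <- function(model, flux, metabolite,
                               method = c("gross", "net")) {
  method <- match.arg(method)
  stop_if(!metabolite %in% model$metabolites$id,
          "no such metabolite: ", metabolite)
  rxns <- names(model$reactions)
  coef <- vapply(model$reactions, function(r)
    r$stoichiometry[metabolite] %||% 0, numeric(1))
  coef[is.na(coef)] <- 0

  if (inherits(flux, "flux_vector")) {
    stop_if(flux$status != "optimal", "flux vector has status ", flux$status)
    contrib <- pmax(coef * flux$fluxes[rxns], 0)
  } else if (inherits(flux, "flux_samples")) {
    sm <- flux$samples[, rxns, drop = FALSE]
    if (method == "gross") {
      contrib <- colMeans(pmax(sweep(sm, 2, coef, `*`), 0))
    } else {
      contrib <- pmax(coef * colMeans(sm), 0)
    }
  } else {
    contrib <- pmax(coef * flux[rxns], 0)
  }

  total <- sum(contrib)
  if (total <= 1e-12) {
    return(list(status = "no_production", total = 0,
                breakdown = tibble::tibble(reaction = character(0),
                                           contribution = numeric(0),
                                           fraction = numeric(0))))
  }
  keep <- contrib > 0
  out <- tibble::tibble(reaction = rxns[keep],
                        contribution = unname(contrib[keep]),
                        fraction = unname(contrib[keep]) / total)
  out <- out[order(-out$fraction), ]
  list(status = "ok", total = total, breakdown = out)
}
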