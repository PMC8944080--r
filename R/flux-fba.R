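# LP solve behind FBA: min/max obj'v s.t. S v = 0, lb <= v <= ub. Variables
# are shifted by their lower bound (w = v - lb >= 0) and upper bounds become
# equality rows with slacks, giving the standard form the two-phase simplex
# expects.
solve_lp <- function(obj, S, lb, ub, maximize = TRUE) {
  n <- length(obj)
  stopifnot(all(is.finite(lb)), all(is.finite(ub)))
  width <- ub - lb
  # rows: [S 0] [w; s] = -S lb  and  [I I] [w; s] = width
  A <- rbind(cbind(S, matrix(0, nrow(S), n)),
             cbind(diag(n), diag(n)))
  b <- c(as.numeric(-S %*% lb), width)
  cc <- c(if (maximize) -obj else obj, numeric(n))
  res <- lp_solve_cpp(cc, A, b)
  status <- switch(as.character(res$status),
                   "0" = "optimal", "1" = "infeasible",
                   "2" = "unbounded", "failed")
  if (status != "optimal")
    return(list(status = status, value = NA_real_, v = NULL))
  v <- res$x[seq_len(n)] + lb
  list(status = "optimal", value = sum(obj * v), v = v)
}

# Replace non-finite bounds by +/- cap (the polytope must be bounded for
# sampling and vertex enumeration; FBA uses a larger cap to detect
# unboundedness).
cap_bounds <- function(b, cap) {
  list(lb = pmax(b$lb, -cap), ub = pmin(b$ub, cap),
       capped = any(!is.finite(b$lb)) || any(!is.finite(b$ub)))
}

#' Flux balance analysis
#'
#' Solves `max (or min) v_obj` subject to `S v = 0` and `lb <= v <= ub`.
#' Infeasible and unbounded problems are reported distinctly in the `status`
#' field; in degenerate problems any optimal vertex may be returned.
#'
#' @param model a `metabolic_model`.
#' @param objective reaction id to optimise; defaults to the model objective.
#' @param direction `"max"` or `"min"`.
#' @return an object of class `flux_vector`: list with `objective_value`,
#'   `fluxes` (named vector), `status`, `objective`, `direction`.
#' @examples
#' sol <- fba(toy_chain_model())
#' sol$objective_value
#' @export
fba <- function(model, objective = NULL, direction = c("max", "min")) {
  direction <- match.arg(direction)
  objective <- objective %||% model$objective
  stop_if(!objective %in% names(model$reactions),
          "no such reaction: ", objective)
  S <- stoich_matrix(model)
  b <- bounds_of(model)
  big <- 1e6
  cb <- cap_bounds(b, big)
  obj <- setNames(numeric(ncol(S)), colnames(S))
  obj[objective] <- 1
  res <- solve_lp(obj, S, cb$lb, cb$ub, maximize = direction == "max")
  status <- res$status
  if (status == "optimal" && cb$capped && abs(res$value) >= big * (1 - 1e-6))
    status <- "unbounded"
  fluxes <- if (is.null(res$v)) NULL else setNames(res$v, colnames(S))
  structure(list(objective_value = if (status == "optimal") res$value
                 else NA_real_,
                 fluxes = fluxes, status = status,
                 objective = objective, direction = direction),
            class = "flux_vector")
}

#' @export
print.flux_vector <- function(x, ...) {
  cat("FBA (", x$direction, " ", x$objective, "): status ", x$status, sep = "")
  if (x$status == "optimal")
    cat(", objective ", format(x$objective_value), sep = "")
  cat("\n")
  invisible(x)
}

#' Flux variability analysis
#'
#' Minimum and maximum attainable flux for each reaction; the optimal flux
#' vectors are the warm-up points of the hit-and-run sampler.
#'
#' @param model a `metabolic_model` (bounds capped at `cap` if non-finite).
#' @param cap cap for non-finite bounds.
#' @return list with `ranges` (n x 2 matrix, min/max) and `points`
#'   (matrix of optimal flux vectors, one row per solved LP).
#' @export
fva <- function(model, cap = 1000) {
  S <- stoich_matrix(model)
  b <- cap_bounds(bounds_of(model), cap)
  n <- ncol(S)
  ranges <- matrix(NA_real_, n, 2,
                   dimnames = list(colnames(S), c("min", "max")))
  pts <- matrix(NA_real_, 0, n, dimnames = list(NULL, colnames(S)))
  for (i in seq_len(n)) {
    obj <- numeric(n); obj[i] <- 1
    for (dir in c("min", "max")) {
      res <- solve_lp(obj, S, b$lb, b$ub, maximize = dir == "max")
      stop_if(res$status != "optimal", "FVA ", dir, " of ", colnames(S)[i],
              ": ", res$status)
      ranges[i, dir] <- res$value
      pts <- rbind(pts, res$v)
    }
  }
  list(ranges = ranges, points = pts)
}

#' Enumerate the vertices of the flux polytope
#'
#' Brute-force vertex enumeration of `{S v = 0, lb <= v <= ub}`: every choice
#' of `n - rank(S)` variables fixed at a bound defines a candidate basic
#' solution; solvable, feasible candidates are vertices. Exponential in the
#' number of free dimensions — intended for toy models only, as the
#' independent check of the LP path.
#'
#' @param model a `metabolic_model` with finite bounds (non-finite capped at
#'   `cap`).
#' @param cap cap for non-finite bounds.
#' @param tol feasibility tolerance.
#' @return matrix of unique vertices (rows) with reaction-id columns.
#' @export
enumerate_vertices <- function(model, cap = 1000, tol = 1e-8) {
  S <- stoich_matrix(model)
  b <- cap_bounds(bounds_of(model), cap)
  n <- ncol(S)
  qrS <- qr(S)
  r <- qrS$rank
  nfree <- n - r
  stop_if(nfree < 0, "overdetermined stoichiometry")
  verts <- matrix(numeric(0), 0, n, dimnames = list(NULL, colnames(S)))
  if (nfree == 0) {
    sol <- tryCatch(qr.solve(S, rep(0, nrow(S))), error = function(e) NULL)
    if (!is.null(sol)) verts <- rbind(verts, sol)
  } else {
    combos <- combn(n, nfree)
    patterns <- as.matrix(expand.grid(rep(list(c(FALSE, TRUE)), nfree)))
    for (ci in seq_len(ncol(combos))) {
      fixed <- combos[, ci]
      free <- setdiff(seq_len(n), fixed)
      S_free <- S[, free, drop = FALSE]
      qf <- qr(S_free)
      if (qf$rank < length(free)) next
      for (pi in seq_len(nrow(patterns))) {
        v <- numeric(n)
        v[fixed] <- ifelse(patterns[pi, ], b$ub[fixed], b$lb[fixed])
        rhs <- -S[, fixed, drop = FALSE] %*% v[fixed]
        v[free] <- qr.coef(qf, rhs)
        if (anyNA(v)) next
        if (max(abs(S %*% v)) > tol) next
        if (any(v < b$lb - tol) || any(v > b$ub + tol)) next
        verts <- rbind(verts, pmin(pmax(v, b$lb), b$ub))
      }
    }
  }
  unique(round(verts, 9))
}
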