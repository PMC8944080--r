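# Independent oracles used across the suite. These deliberately avoid the
# implementation paths they check.

# Brute-force global alignment score: exhaustive recursion over all
# alignments. Exponential -- short strings only.
bf_align_score <- function(a, b, match = 1, mismatch = -1, gap = -1) {
  if (nchar(a) == 0L) return(nchar(b) * gap)
  if (nchar(b) == 0L) return(nchar(a) * gap)
  a1 <- substr(a, 1, 1); b1 <- substr(b, 1, 1)
  ra <- substr(a, 2, nchar(a)); rb <- substr(b, 2, nchar(b))
  max(bf_align_score(ra, rb, match, mismatch, gap) +
        if (a1 == b1) match else mismatch,
      bf_align_score(ra, b, match, mismatch, gap) + gap,
      bf_align_score(a, rb, match, mismatch, gap) + gap)
}

random_seq <- function(len) {
  paste(sample(c("A", "C", "D", "E", "F", "G"), len, replace = TRUE),
        collapse = "")
}

# Hand-executed complete-linkage agglomeration on a fixed 4 x 4 distance
# matrix (no ties): merges {1,2}@0.1, {3,4}@0.2, all@0.9.
manual_agglomeration <- list(
  d = matrix(c(0,   0.1, 0.7, 0.8,
               0.1, 0,   0.6, 0.9,
               0.7, 0.6, 0,   0.2,
               0.8, 0.9, 0.2, 0), 4, 4,
             dimnames = list(letters[1:4], letters[1:4])),
  heights = c(0.1, 0.2, 0.9),
  k2 = c(a = 1L, b = 1L, c = 2L, d = 2L)
)

# Adjusted Rand index between two labelings (closed-form contingency
# formula, independent of any clustering code).
ari <- function(x, y) {
  tab <- table(x, y)
  comb2 <- function(v) sum(choose(v, 2))
  n <- length(x)
  sum_ij <- comb2(as.vector(tab))
  sum_i <- comb2(rowSums(tab))
  sum_j <- comb2(colSums(tab))
  expected <- sum_i * sum_j / choose(n, 2)
  max_index <- (sum_i + sum_j) / 2
  if (max_index == expected) return(1)
  (sum_ij - expected) / (max_index - expected)
}

# Rates from a set of simulated traces (full-span window: the simulated
# initial-rate regime is linear throughout the trace).
rates_from_traces <- function(spec, replicates = 1, seed_base = NULL) {
  do.call(rbind, lapply(seq_along(spec$substrate_levels), function(i) {
    S <- spec$substrate_levels[i]
    do.call(rbind, lapply(seq_len(replicates), function(r) {
      seed <- if (is.null(seed_base)) NULL else seed_base + 100L * i + r
      tr <- simulate_assay_trace(spec, S, rng_seed = seed)
      est <- suppressWarnings(trace_to_rate(tr, window = range(tr$time_s)))
      data.frame(substrate = S, rate = est$initial_rate)
    }))
  }))
}
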