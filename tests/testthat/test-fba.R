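toy_suite <- function() list(toy_chain_model(), toy_twopath_model(),
                             toy_segment_model())

test_that("a linear chain pushes the uptake bound to the export objective", {
  sol <- fba(toy_chain_model())
  expect_equal(sol$status, "optimal")
  expect_equal(sol$objective_value, 10)
  expect_equal(unname(sol$fluxes), c(-10, 10, 10, 10))
})

test_that("closing all exchanges forces the zero flux vector", {
  m <- toy_chain_model()
  m$reactions$EX_A$lower_bound <- 0
  sol <- fba(m)
  expect_equal(sol$objective_value, 0)
  expect_equal(max(abs(sol$fluxes)), 0)
})

test_that("FBA equals brute-force vertex enumeration on every small toy", {
  for (m in toy_suite()) {
    verts <- enumerate_vertices(m)
    expect_gt(nrow(verts), 0)
    sol <- fba(m)
    expect_equal(sol$objective_value, max(verts[, m$objective]),
                 tolerance = 1e-9, info = m$id)
    S <- stoich_matrix(m)
    expect_lt(max(abs(S %*% sol$fluxes)), 1e-6)
    # every enumerated vertex is feasible
    for (i in seq_len(nrow(verts)))
      expect_true(check_flux_feasible(m, verts[i, ]), info = m$id)
  }
})

test_that("minimisation and maximisation directions are both solved", {
  m <- toy_segment_model()
  expect_equal(fba(m, direction = "min")$objective_value, 0)
  expect_equal(fba(m, direction = "max")$objective_value, 10)
})

test_that("infeasible and unbounded problems are reported distinctly", {
  m <- toy_chain_model()
  m$reactions$EX_A$lower_bound <- 5   # force uptake of 5 ...
  m$reactions$EX_A$upper_bound <- 5
  m$reactions$R1$upper_bound <- 1     # ... through a capacity-1 pipe
  expect_equal(fba(m)$status, "infeasible")

  m2 <- toy_chain_model()
  m2$reactions$EX_A$lower_bound <- -Inf
  m2$reactions$R1$upper_bound <- Inf
  m2$reactions$R2$upper_bound <- Inf
  m2$reactions$EX_C$upper_bound <- Inf
  expect_equal(fba(m2)$status, "unbounded")
})

test_that("FBA optimum dominates every sampled point", {
  m <- toy_twopath_model()
  opt <- fba(m)$objective_value
  s <- achr_sample(m, n = 300, seed = 4, burn_in = 100, thinning = 2)
  expect_true(all(s$samples[, m$objective] <= opt + 1e-6))
})

test_that("the chassis toy reproduces the expected growth physiology", {
  m <- toy_model()
  glc <- fba(m)
  expect_equal(glc$objective_value, 10)
  # indole production is absent at maximum growth on glucose
  expect_equal(glc$fluxes[["TNA"]], 0)
  # on gluconate the TNA and pyruvate kinase paths both carry flux
  m2 <- set_medium(m, carbon = "EX_glcn", trp = "EX_trp",
                   unlimited = "EX_h2o")
  glcn <- fba(m2)
  expect_equal(glcn$objective_value, 15)
  expect_gt(glcn$fluxes[["TNA"]], 0)
})

test_that("producer decomposition follows the sign rule and sums to one", {
  m <- toy_twopath_model()
  pb <- producer_breakdown(m, fba(m), "P")
  expect_equal(pb$status, "ok")
  expect_equal(sum(pb$breakdown$fraction), 1)
  expect_equal(pb$breakdown$fraction[pb$breakdown$reaction == "MAIN"], 0.92)
  expect_equal(pb$breakdown$fraction[pb$breakdown$reaction == "MINOR"], 0.08)
  # consumers never appear
  expect_false("EX_P" %in% pb$breakdown$reaction)
  # scaling invariance on a bare flux vector
  v <- setNames(c(-10, 9.2, 0.8, 10), names(m$reactions))
  f1 <- producer_breakdown(m, v, "P")$breakdown$fraction
  f2 <- producer_breakdown(m, v * 7, "P")$breakdown$fraction
  expect_equal(f1, f2)
  # single producer gets fraction 1
  pb1 <- producer_breakdown(toy_chain_model(), fba(toy_chain_model()), "B")
  expect_equal(pb1$breakdown$fraction, 1)
  expect_equal(pb1$breakdown$reaction, "R1")
  # zero production is an explicit status
  zero <- setNames(numeric(4), names(m$reactions))
  expect_equal(producer_breakdown(m, zero, "P")$status, "no_production")
})
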