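test_that("model JSON write-then-read is the identity on the toy fixture", {
  m <- toy_model()
  tf <- withr::local_tempfile(fileext = ".json")
  write_model(m, tf)
  m2 <- read_model(tf)
  expect_equal(m2$metabolites, m$metabolites)
  expect_equal(m2$genes, m$genes)
  expect_equal(m2$objective, m$objective)
  expect_equal(names(m2$reactions), names(m$reactions))
  for (id in names(m$reactions)) {
    expect_equal(m2$reactions[[id]]$stoichiometry,
                 m$reactions[[id]]$stoichiometry, info = id)
    expect_equal(m2$reactions[[id]]$lower_bound,
                 m$reactions[[id]]$lower_bound, info = id)
    expect_equal(m2$reactions[[id]]$gpr, m$reactions[[id]]$gpr, info = id)
  }
})

test_that("the bundled extdata fixture parses to the toy chassis", {
  path <- system.file("extdata", "toy_model.json", package = "trpindole")
  expect_true(nzchar(path))
  m <- read_model(path)
  expect_equal(length(m$reactions), length(toy_model()$reactions))
  expect_equal(fba(m)$objective_value, fba(toy_model())$objective_value)
})

test_that("schema violations are reported with context", {
  m <- toy_model()
  m$objective <- "NOPE"
  expect_error(validate_model(m), "no objective")
  m2 <- toy_model()
  m2$reactions$PYK$stoichiometry <- c(ghost_met = -1)
  expect_error(validate_model(m2), "PYK.*ghost_met")
})

test_that("GPR evaluation follows boolean semantics", {
  expect_false(evaluate_gpr("g1 and g2", "g1"))
  expect_true(evaluate_gpr("g1 or g2", "g1"))
  expect_true(evaluate_gpr("", "g1"))  # no gene dependence
  # full truth table of (g1 and g2) or g3
  for (del in list(character(0), "g1", "g2", "g3", c("g1", "g2"),
                   c("g1", "g3"), c("g2", "g3"), c("g1", "g2", "g3"))) {
    expected <- (!"g1" %in% del && !"g2" %in% del) || !"g3" %in% del
    expect_equal(evaluate_gpr("(g1 and g2) or g3", del), expected,
                 info = paste(del, collapse = ","))
  }
  expect_error(evaluate_gpr("g1 and (g2", "x"), "parse error")
  expect_error(evaluate_gpr("g1 ? g2", "x"), "position")
  expect_error(evaluate_gpr("and g1", "x"), "parse error")
})

test_that("model reduction removes exactly the GPR-inactivated reactions", {
  m <- toy_model()
  expect_equal(names(reduce_model(m, character(0))$reactions),
               names(m$reactions))
  r1 <- reduce_model(m, "pyk")
  expect_false("PYK" %in% names(r1$reactions))
  expect_equal(length(r1$reactions), length(m$reactions) - 1L)
  expect_equal(attr(r1, "removed"), "PYK")
  # idempotent (the gene is already gone, which also warns)
  r2 <- suppressWarnings(reduce_model(r1, "pyk"))
  expect_equal(names(r2$reactions), names(r1$reactions))
  expect_warning(reduce_model(m, "not_a_gene"), "not in model")
  # growth of the programmatically reduced model equals the hand-reduced one
  hand <- m
  hand$reactions <- hand$reactions[setdiff(names(hand$reactions), "PYK")]
  expect_equal(fba(r1)$objective_value, fba(hand)$objective_value)
  # deleting the objective's pathway entirely is refused when the objective
  # reaction itself carries the deleted gene
  m3 <- toy_chain_model()
  m3$reactions$EX_C$gpr <- "gx"
  expect_error(suppressWarnings(reduce_model(m3, "gx")), "objective")
})

test_that("the TNA reaction is element-balanced and created metabolites reported", {
  m <- toy_chain_model()  # lacks all TNA metabolites
  expect_message(m2 <- add_tna_reaction(m), "created metabolite")
  expect_setequal(attr(m2, "created"),
                  c("trp_c", "h2o_c", "indole_c", "pyr_c", "nh3_c"))
  bal <- element_balance(m2, "TNA")
  expect_equal(max(abs(bal)), 0)
  expect_error(add_tna_reaction(m2), "duplicate")
  # in the full toy the metabolites pre-exist
  bal2 <- element_balance(toy_model(), "TNA")
  expect_equal(max(abs(bal2)), 0)
})

test_that("exchanges can be added and an inert exchange leaves FBA unchanged", {
  m <- toy_chain_model()
  base <- fba(m)$objective_value
  m2 <- add_exchange(m, "B", lb = 0, ub = 0)
  expect_true("EX_B" %in% exchange_reactions(m2))
  expect_equal(fba(m2)$objective_value, base)
  expect_error(add_exchange(m2, "B"), "duplicate")
  expect_error(add_exchange(m, "nope"), "no such metabolite")
})

test_that("indole export equals TNA flux at the indole optimum", {
  m <- toy_model()
  sol <- fba(m, objective = "EX_indole")
  expect_equal(sol$status, "optimal")
  expect_gt(sol$objective_value, 0)
  expect_equal(sol$fluxes[["EX_indole"]], sol$fluxes[["TNA"]])
})

test_that("medium setting applies the -1000/-10 bound convention", {
  m <- toy_model()
  m2 <- set_medium(m, carbon = "EX_glcn", trp = "EX_trp",
                   unlimited = "EX_h2o")
  expect_equal(m2$reactions$EX_glcn$lower_bound, -10)
  expect_equal(m2$reactions$EX_trp$lower_bound, -10)
  expect_equal(m2$reactions$EX_h2o$lower_bound, -1000)
  # every other uptake is closed
  expect_equal(m2$reactions$EX_glc$lower_bound, 0)
  expect_error(set_medium(m, carbon = "EX_sucrose"), "EX_sucrose")
})
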