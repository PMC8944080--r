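#' Bundled toy metabolic models
#'
#' Small fully specified models used as test substrates for the
#' constraint-based machinery.
#'
#' * `toy_model()` — the default chassis emulation: PTS glucose uptake
#'   (phosphoenolpyruvate-coupled, co-producing pyruvate), a non-PTS gluconate
#'   path, a lumped glycolysis (`g6p -> 2 pep`), pyruvate kinase, a
#'   capacity-limited alternative pyruvate producer, Trp uptake, the
#'   tryptophanase reaction with indole export, pyruvate overflow secretion,
#'   and a biomass sink consuming pyruvate and phosphoenolpyruvate. Glucose
#'   and Trp uptake are open at -10 mmol/gDW/h.
#' * `toy_chain_model()` — linear chain `A -> B -> C` with uptake bound -10
#'   and export objective; the hand-solvable LP gives optimum 10.
#' * `toy_twopath_model()` — two parallel producers of `P` with capacities
#'   9.2 and 0.8; at the export optimum the producers split 92%/8%.
#' * `toy_segment_model()` — a single degree of freedom: throughput uniform
#'   on `[0, 10]`, the closed-form calibration target for the sampler.
#'
#' @return a `metabolic_model`.
#' @name toy_models
NULL

rxn <- function(id, stoich, lb = 0, ub = 1000, gpr = "", name = id) {
  list(id = id, name = name, stoichiometry = stoich,
       lower_bound = lb, upper_bound = ub, gpr = gpr)
}

#' @rdname toy_models
#' @export
toy_model <- function() {
  mets <- tibble::tibble(
    id = c("glc_e", "glcn_e", "g6p_c", "pep_c", "pyr_c",
           "trp_e", "trp_c", "h2o_c", "indole_c", "indole_e", "nh3_c"),
    name = c("glucose (ext)", "gluconate (ext)", "glucose 6-phosphate",
             "phosphoenolpyruvate", "pyruvate", "L-tryptophan (ext)",
             "L-tryptophan", "water", "indole", "indole (ext)", "ammonia"),
    formula = c("C6H12O6", "C6H12O7", "C6H13O9P", "C3H5O6P", "C3H4O3",
                "C11H12N2O2", "C11H12N2O2", "H2O", "C8H7N", "C8H7N", "NH3"),
    compartment = c("e", "e", "c", "c", "c", "e", "c", "c", "c", "e", "c")
  )
  reactions <- list(
    rxn("EX_glc", c(glc_e = -1), lb = -10, ub = 1000),
    rxn("EX_glcn", c(glcn_e = -1), lb = 0, ub = 1000),
    rxn("PTS", c(glc_e = -1, pep_c = -1, g6p_c = 1, pyr_c = 1), gpr = "pts"),
    rxn("GNT", c(glcn_e = -1, g6p_c = 1), gpr = "gntP"),
    rxn("GLY", c(g6p_c = -1, pep_c = 2), gpr = "gly1"),
    rxn("PYK", c(pep_c = -1, pyr_c = 1), gpr = "pyk",
        name = "pyruvate kinase"),
    rxn("PYRALT", c(pep_c = -1, pyr_c = 1), ub = 1, gpr = "alt1",
        name = "alternative pyruvate producer"),
    rxn("TRPt", c(trp_e = -1, trp_c = 1), gpr = "aroP"),
    rxn("EX_trp", c(trp_e = -1), lb = -10, ub = 1000),
    rxn("TNA", c(trp_c = -1, h2o_c = -1, indole_c = 1, pyr_c = 1, nh3_c = 1),
        gpr = "tna", name = "tryptophanase"),
    rxn("INDt", c(indole_c = -1, indole_e = 1)),
    rxn("EX_indole", c(indole_e = -1), lb = 0, ub = 1000),
    rxn("EX_pyr", c(pyr_c = -1), lb = 0, ub = 1000),
    rxn("EX_nh3", c(nh3_c = -1), lb = 0, ub = 1000),
    rxn("EX_h2o", c(h2o_c = -1), lb = -1000, ub = 1000),
    rxn("BIOMASS", c(pyr_c = -1, pep_c = -1), name = "biomass sink")
  )
  metabolic_model("toy_chassis", mets, reactions, objective = "BIOMASS")
}

#' @rdname toy_models
#' @export
toy_chain_model <- function() {
  mets <- tibble::tibble(id = c("A", "B", "C"))
  reactions <- list(
    rxn("EX_A", c(A = -1), lb = -10, ub = 1000),
    rxn("R1", c(A = -1, B = 1), gpr = "g1"),
    rxn("R2", c(B = -1, C = 1), gpr = "g2"),
    rxn("EX_C", c(C = -1), lb = 0, ub = 1000)
  )
  metabolic_model("toy_chain", mets, reactions, objective = "EX_C")
}

#' @rdname toy_models
#' @export
toy_twopath_model <- function() {
  mets <- tibble::tibble(id = c("A", "P"))
  reactions <- list(
    rxn("EX_A", c(A = -1), lb = -10, ub = 0),
    rxn("MAIN", c(A = -1, P = 1), ub = 9.2, gpr = "gmain"),
    rxn("MINOR", c(A = -1, P = 1), ub = 0.8, gpr = "gminor"),
    rxn("EX_P", c(P = -1), lb = 0, ub = 1000)
  )
  metabolic_model("toy_twopath", mets, reactions, objective = "EX_P")
}

#' @rdname toy_models
#' @export
toy_segment_model <- function() {
  mets <- tibble::tibble(id = c("A", "B"))
  reactions <- list(
    rxn("EX_A", c(A = -1), lb = -10, ub = 0),
    rxn("CONV", c(A = -1, B = 1)),
    rxn("EX_B", c(B = -1), lb = 0, ub = 1000)
  )
  metabolic_model("toy_segment", mets, reactions, objective = "EX_B")
}
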