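#' Construct a constraint-based metabolic model
#'
#' A lightweight container for constraint-based analysis: metabolites,
#' reactions with stoichiometry, flux bounds (mmol/gDW/h) and
#' gene-protein-reaction (GPR) boolean rules, a gene set and an objective
#' reaction. The feasible set is the flux polytope
#' `{v : S v = 0, lb <= v <= ub}`.
#'
#' @param id model identifier.
#' @param metabolites tibble with columns `id` and optionally `name`,
#'   `formula`, `compartment`.
#' @param reactions list of reactions, each a list with `id`, `stoichiometry`
#'   (named numeric, negative = consumed), `lower_bound`, `upper_bound` and
#'   optionally `name` and `gpr` (boolean expression string over gene ids).
#' @param objective id of the objective reaction.
#' @param genes character vector of gene ids; defaults to the genes mentioned
#'   in GPR rules.
#' @return an object of class `metabolic_model`.
#' @seealso [read_model()], [fba()], [toy_model()]
#' @export
metabolic_model <- function(id, metabolites, reactions, objective,
                            genes = NULL) {
  reactions <- lapply(reactions, function(r) {
    r$name <- r$name %||% r$id
    r$gpr <- r$gpr %||% ""
    r$stoichiometry <- unlist(r$stoichiometry)
    r
  })
  names(reactions) <- vapply(reactions, `[[`, "", "id")
  if (is.null(genes)) {
    genes <- sort(unique(unlist(lapply(reactions, function(r)
      gpr_genes(r$gpr)))))
  }
  metabolites <- tibble::as_tibble(metabolites)
  for (col in c("name", "formula", "compartment")) {
    if (is.null(metabolites[[col]])) metabolites[[col]] <- NA_character_
  }
  if (anyNA(metabolites$name)) {
    metabolites$name[is.na(metabolites$name)] <-
      metabolites$id[is.na(metabolites$name)]
  }
  model <- structure(list(id = id,
                          metabolites = metabolites,
                          reactions = reactions,
                          genes = genes,
                          objective = objective),
                     class = "metabolic_model")
  validate_model(model)
  model
}

#' Validate a metabolic model
#'
#' Checks that every stoichiometry key is a declared metabolite, bounds are
#' ordered, reaction ids are unique and the objective reaction exists.
#'
#' @param model a `metabolic_model`.
#' @return the model, invisibly; errors list the offending reaction ids.
#' @export
validate_model <- function(model) {
  stop_if(length(model$reactions) == 0L, "model has no reactions")
  stop_if(is.null(model$objective) || !model$objective %in%
            names(model$reactions),
          "no objective: objective reaction '",
          model$objective %||% "<missing>", "' not in model")
  ids <- names(model$reactions)
  stop_if(anyDuplicated(ids) > 0L, "duplicate reaction ids: ",
          paste(unique(ids[duplicated(ids)]), collapse = ", "))
  met_ids <- model$metabolites$id
  for (r in model$reactions) {
    stop_if(!is.null(r$lower_bound) && !is.null(r$upper_bound) &&
              r$lower_bound > r$upper_bound,
            "reaction ", r$id, ": lower_bound > upper_bound")
    unknown <- setdiff(names(r$stoichiometry), met_ids)
    stop_if(length(unknown) > 0L,
            "reaction ", r$id, ": unknown metabolite(s) ",
            paste(unknown, collapse = ", "))
    stop_if(length(r$stoichiometry) == 0L,
            "reaction ", r$id, ": empty stoichiometry")
  }
  invisible(model)
}

#' @export
print.metabolic_model <- function(x, ...) {
  cat("Metabolic model '", x$id, "': ", nrow(x$metabolites), " metabolites, ",
      length(x$reactions), " reactions, ", length(x$genes), " genes\n",
      "objective: ", x$objective, "\n", sep = "")
  invisible(x)
}

#' Stoichiometric matrix of a model
#'
#' @param model a `metabolic_model`.
#' @return numeric matrix, metabolites x reactions.
#' @export
stoich_matrix <- function(model) {
  mets <- model$metabolites$id
  rxns <- names(model$reactions)
  S <- matrix(0, length(mets), length(rxns), dimnames = list(mets, rxns))
  for (r in model$reactions) S[names(r$stoichiometry), r$id] <- r$stoichiometry
  S
}

bounds_of <- function(model) {
  lb <- vapply(model$reactions, function(r) r$lower_bound, numeric(1))
  ub <- vapply(model$reactions, function(r) r$upper_bound, numeric(1))
  list(lb = lb, ub = ub)
}

#' Exchange reactions of a model
#'
#' Exchange reactions are identified as reactions with a single-metabolite
#' stoichiometry (the convention `EX: met <-> nothing`, negative flux =
#' uptake).
#'
#' @param model a `metabolic_model`.
#' @return character vector of reaction ids.
#' @export
exchange_reactions <- function(model) {
  names(model$reactions)[vapply(model$reactions, function(r)
    length(r$stoichiometry) == 1L, logical(1))]
}

# ---- JSON I/O --------------------------------------------------------------

#' Read and write metabolic models as JSON
#'
#' The schema follows the community convention for constraint-based models:
#' top-level `metabolites` (objects with `id`, `name`, `formula`,
#' `compartment`), `reactions` (objects with `id`, `name`, `metabolites` map,
#' `lower_bound`, `upper_bound`, `gene_reaction_rule` and optionally
#' `objective_coefficient`), `genes` (strings or objects with `id`) and
#' optionally a top-level `objective` reaction id (takes precedence over
#' `objective_coefficient`). Write-then-read is the identity.
#'
#' @param path JSON file path.
#' @param model a `metabolic_model`.
#' @return `read_model()` returns a validated `metabolic_model`;
#'   `write_model()` returns `path` invisibly.
#' @export
read_model <- function(path) {
  stop_if(!file.exists(path), "file not found: ", path)
  j <- jsonlite::read_json(path)
  stop_if(is.null(j$reactions), "schema violation: no 'reactions' field")
  mets <- tibble::tibble(
    id = vapply(j$metabolites, function(m) m$id, ""),
    name = vapply(j$metabolites, function(m) m$name %||% m$id, ""),
    formula = vapply(j$metabolites, function(m) m$formula %||%
                       NA_character_, ""),
    compartment = vapply(j$metabolites, function(m) m$compartment %||%
                           NA_character_, "")
  )
  reactions <- lapply(j$reactions, function(r) {
    list(id = r$id, name = r$name %||% r$id,
         stoichiometry = unlist(r$metabolites),
         lower_bound = r$lower_bound %||% -1000,
         upper_bound = r$upper_bound %||% 1000,
         gpr = r$gene_reaction_rule %||% "")
  })
  genes <- vapply(j$genes, function(g) if (is.list(g)) g$id else g, "")
  objective <- j$objective
  if (is.null(objective)) {
    oc <- vapply(j$reactions, function(r) r$objective_coefficient %||% 0,
                 numeric(1))
    if (any(oc != 0)) objective <- reactions[[which(oc != 0)[1]]]$id
  }
  stop_if(is.null(objective), "no objective: neither a top-level 'objective' ",
          "nor any reaction with objective_coefficient != 0")
  metabolic_model(id = j$id %||% basename(path), metabolites = mets,
                  reactions = reactions, objective = objective,
                  genes = if (length(genes)) genes else NULL)
}

#' @rdname read_model
#' @export
write_model <- function(model, path) {
  mets <- lapply(seq_len(nrow(model$metabolites)), function(i) {
    m <- as.list(model$metabolites[i, ])
    m[!vapply(m, function(x) is.na(x), logical(1))]
  })
  rxns <- lapply(model$reactions, function(r) {
    list(id = r$id, name = r$name,
         metabolites = as.list(r$stoichiometry),
         lower_bound = r$lower_bound, upper_bound = r$upper_bound,
         gene_reaction_rule = r$gpr,
         objective_coefficient = if (r$id == model$objective) 1 else 0)
  })
  j <- list(id = model$id, metabolites = mets, reactions = unname(rxns),
            genes = as.list(model$genes), objective = model$objective)
  jsonlite::write_json(j, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

# ---- GPR rules -------------------------------------------------------------

gpr_tokenize <- function(expr) {
  tokens <- list(); pos <- 1L; n <- nchar(expr)
  while (pos <= n) {
    rest <- substr(expr, pos, n)
    if (grepl("^\\s", rest)) { pos <- pos + 1L; next }
    ch <- substr(rest, 1, 1)
    if (ch %in% c("(", ")")) {
      tokens[[length(tokens) + 1L]] <- list(type = ch, pos = pos)
      pos <- pos + 1L
    } else {
      m <- regmatches(rest, regexpr("^[A-Za-z0-9_.-]+", rest))
      stop_if(length(m) == 0L,
              "GPR parse error at position ", pos, ": unexpected '", ch, "'")
      type <- switch(tolower(m), "and" = "AND", "or" = "OR", "ID")
      tokens[[length(tokens) + 1L]] <- list(type = type, value = m, pos = pos)
      pos <- pos + nchar(m)
    }
  }
  tokens
}

gpr_parse <- function(expr) {
  tokens <- gpr_tokenize(expr)
  i <- 0L
  peek <- function() if (i < length(tokens)) tokens[[i + 1L]] else NULL
  advance <- function() { i <<- i + 1L; tokens[[i]] }
  # grammar: expr := term (OR term)* ; term := factor (AND factor)* ;
  #          factor := ID | '(' expr ')'
  parse_expr <- function() {
    node <- parse_term()
    while (!is.null(peek()) && peek()$type == "OR") {
      advance()
      node <- list(op = "or", left = node, right = parse_term())
    }
    node
  }
  parse_term <- function() {
    node <- parse_factor()
    while (!is.null(peek()) && peek()$type == "AND") {
      advance()
      node <- list(op = "and", left = node, right = parse_factor())
    }
    node
  }
  parse_factor <- function() {
    tok <- peek()
    stop_if(is.null(tok), "GPR parse error: unexpected end of expression")
    if (tok$type == "(") {
      advance()
      node <- parse_expr()
      cl <- peek()
      stop_if(is.null(cl) || cl$type != ")",
              "GPR parse error at position ",
              if (is.null(cl)) nchar(expr) + 1L else cl$pos,
              ": expected ')'")
      advance()
      return(node)
    }
    stop_if(tok$type != "ID", "GPR parse error at position ", tok$pos,
            ": expected gene id, got '", tok$value %||% tok$type, "'")
    advance()
    list(op = "id", value = tok$value)
  }
  tree <- parse_expr()
  tok <- peek()
  stop_if(!is.null(tok), "GPR parse error at position ", tok$pos,
          ": unexpected trailing '", tok$value %||% tok$type, "'")
  tree
}

gpr_genes <- function(expr) {
  if (is.null(expr) || is.na(expr) || !nzchar(trimws(expr)))
    return(character(0))
  toks <- gpr_tokenize(expr)
  unique(unlist(lapply(toks, function(t)
    if (t$type == "ID") t$value else NULL)))
}

#' Evaluate a gene-protein-reaction rule under gene deletions
#'
#' A GPR is a boolean expression over gene ids with `and`, `or` and
#' parentheses (case-insensitive keywords). `and` requires all operands
#' present, `or` any; an empty rule means the reaction has no gene dependence
#' and stays active.
#'
#' @param expr GPR string, e.g. `"(g1 and g2) or g3"`.
#' @param deleted_genes character vector of deleted gene ids.
#' @return `TRUE` if the reaction remains active.
#' @examples
#' evaluate_gpr("g1 or g2", "g1")          # TRUE
#' evaluate_gpr("(g1 and g2) or g3", c("g1", "g3"))  # FALSE
#' @export
evaluate_gpr <- function(expr, deleted_genes = character(0)) {
  if (is.null(expr) || is.na(expr) || !nzchar(trimws(expr))) return(TRUE)
  eval_node <- function(node) {
    switch(node$op,
           id = !(node$value %in% deleted_genes),
           and = eval_node(node$left) && eval_node(node$right),
           or = eval_node(node$left) || eval_node(node$right))
  }
  eval_node(gpr_parse(expr))
}

# ---- model editing ---------------------------------------------------------

#' Reduce a model for a gene-deleted chassis strain
#'
#' Removes every reaction whose GPR evaluates to inactive under the deletion
#' set (the procedure used to adapt a genome-scale model to a genome-reduced
#' chassis); all other reactions are untouched. Idempotent for a fixed gene
#' set.
#'
#' @param model a `metabolic_model`.
#' @param deleted_genes character vector; ids absent from the model's gene
#'   set trigger a warning, not an error.
#' @return the reduced model, with attribute `removed` listing removed
#'   reaction ids. Removing the objective reaction is an error.
#' @export
reduce_model <- function(model, deleted_genes) {
  unknown <- setdiff(deleted_genes, model$genes)
  if (length(unknown) > 0L)
    warning("deleted genes not in model: ", paste(unknown, collapse = ", "))
  active <- vapply(model$reactions, function(r)
    evaluate_gpr(r$gpr, deleted_genes), logical(1))
  removed <- names(model$reactions)[!active]
  stop_if(model$objective %in% removed,
          "reduction removes the objective reaction '", model$objective, "'")
  model$reactions <- model$reactions[active]
  model$genes <- setdiff(model$genes, deleted_genes)
  structure(validate_model(model), removed = removed)
}

add_metabolite_if_absent <- function(model, id, name, formula) {
  if (id %in% model$metabolites$id) return(list(model = model, created = NULL))
  model$metabolites <- rbind(model$metabolites,
                             tibble::tibble(id = id, name = name,
                                            formula = formula,
                                            compartment = "c"))
  list(model = model, created = id)
}

#' Add the tryptophanase reaction to a model
#'
#' Adds the irreversible TNA reaction
#' `trp + h2o -> indole + pyruvate + nh3`, element-balanced for C, H, N, O
#' (C11H12N2O2 + H2O -> C8H7N + C3H4O3 + NH3). Missing metabolites are
#' created (cytosolic, with their formulas) and reported in the `created`
#' attribute.
#'
#' @param model a `metabolic_model`.
#' @param id reaction id (duplicate ids are an error).
#' @param trp,h2o,indole,pyruvate,ammonia metabolite ids to use.
#' @return the augmented model, attribute `created` naming created
#'   metabolites.
#' @export
add_tna_reaction <- function(model, id = "TNA",
                             trp = "trp_c", h2o = "h2o_c",
                             indole = "indole_c", pyruvate = "pyr_c",
                             ammonia = "nh3_c") {
  stop_if(id %in% names(model$reactions), "duplicate reaction id: ", id)
  created <- character(0)
  specs <- list(list(trp, "L-tryptophan", "C11H12N2O2"),
                list(h2o, "water", "H2O"),
                list(indole, "indole", "C8H7N"),
                list(pyruvate, "pyruvate", "C3H4O3"),
                list(ammonia, "ammonia", "NH3"))
  for (s in specs) {
    res <- add_metabolite_if_absent(model, s[[1]], s[[2]], s[[3]])
    model <- res$model
    created <- c(created, res$created)
  }
  stoich <- setNames(c(-1, -1, 1, 1, 1),
                     c(trp, h2o, indole, pyruvate, ammonia))
  model$reactions[[id]] <- list(id = id, name = "tryptophanase",
                                stoichiometry = stoich,
                                lower_bound = 0, upper_bound = 1000,
                                gpr = "")
  if (length(created) > 0L)
    message("created metabolite(s): ", paste(created, collapse = ", "))
  structure(validate_model(model), created = created)
}

#' Add an exchange reaction for a metabolite
#'
#' @param model a `metabolic_model`.
#' @param metabolite existing metabolite id.
#' @param lb,ub bounds (mmol/gDW/h); negative flux is uptake.
#' @param id reaction id; defaults to `EX_<metabolite>`.
#' @return the augmented model.
#' @export
add_exchange <- function(model, metabolite, lb = 0, ub = 1000,
                         id = paste0("EX_", metabolite)) {
  stop_if(!metabolite %in% model$metabolites$id,
          "no such metabolite: ", metabolite)
  stop_if(id %in% names(model$reactions), "duplicate exchange: ", id)
  model$reactions[[id]] <- list(id = id,
                                name = paste(metabolite, "exchange"),
                                stoichiometry = setNames(-1, metabolite),
                                lower_bound = lb, upper_bound = ub,
                                gpr = "")
  validate_model(model)
}

#' Set medium composition via exchange bounds
#'
#' Applies the simulation medium convention: unlimited components (salts,
#' minerals, oxygen) get lower bound -1000 mmol/gDW/h, the carbon source and
#' Trp get -10 mmol/gDW/h, and every other exchange has its uptake closed
#' (lower bound 0) unless whitelisted. Secretion bounds are untouched.
#'
#' @param model a `metabolic_model`.
#' @param carbon exchange-reaction id of the carbon source.
#' @param trp exchange-reaction id of the Trp supply, or `NULL`.
#' @param unlimited exchange ids set to `unlimited_lb` (e.g. O2, NH3, salts).
#' @param whitelist exchange ids whose bounds are left as they are.
#' @param carbon_lb,trp_lb,unlimited_lb lower bounds applied.
#' @return the model with updated exchange bounds; naming an absent exchange
#'   is an error.
#' @export
set_medium <- function(model, carbon, trp = NULL,
                       unlimited = character(0), whitelist = character(0),
                       carbon_lb = -10, trp_lb = -10, unlimited_lb = -1000) {
  ex <- exchange_reactions(model)
  named <- c(carbon, trp, unlimited, whitelist)
  absent <- setdiff(named, ex)
  stop_if(length(absent) > 0L,
          "no such exchange reaction(s): ", paste(absent, collapse = ", "))
  for (rid in ex) {
    if (rid %in% whitelist) next
    lb <- if (rid == carbon) carbon_lb
          else if (!is.null(trp) && rid == trp) trp_lb
          else if (rid %in% unlimited) unlimited_lb
          else max(model$reactions[[rid]]$lower_bound, 0)
    model$reactions[[rid]]$lower_bound <- lb
  }
  validate_model(model)
}

# ---- elemental bookkeeping -------------------------------------------------

parse_formula <- function(formula) {
  stop_if(is.null(formula) || is.na(formula), "missing formula")
  m <- gregexpr("([A-Z][a-z]?)([0-9]*)", formula)[[1]]
  parts <- regmatches(formula, gregexpr("([A-Z][a-z]?)([0-9]*)", formula))[[1]]
  el <- sub("[0-9]*$", "", parts)
  ct <- sub("^[A-Za-z]+", "", parts)
  ct <- ifelse(ct == "", 1, as.numeric(ct))
  tapply(ct, el, sum)
}

#' Elemental balance of a reaction
#'
#' Net element counts (products minus substrates) computed from metabolite
#' formulas; a balanced reaction returns all zeros.
#'
#' @param model a `metabolic_model` with formulas on the involved metabolites.
#' @param reaction_id reaction to check.
#' @return named numeric vector of per-element imbalance.
#' @export
element_balance <- function(model, reaction_id) {
  r <- model$reactions[[reaction_id]]
  stop_if(is.null(r), "no such reaction: ", reaction_id)
  totals <- numeric(0)
  for (met in names(r$stoichiometry)) {
    formula <- model$metabolites$formula[model$metabolites$id == met]
    counts <- parse_formula(formula)
    for (el in names(counts)) {
      cur <- if (el %in% names(totals)) totals[[el]] else 0
      totals[el] <- cur + r$stoichiometry[[met]] * counts[[el]]
    }
  }
  totals
}

#' Check a flux vector against the model constraints
#'
#' @param model a `metabolic_model`.
#' @param v named (or ordered) flux vector.
#' @param tol_steady absolute tolerance on `max |S v|`.
#' @param tol_bounds tolerance on bound violation.
#' @return `TRUE` if `v` is feasible.
#' @export
check_flux_feasible <- function(model, v, tol_steady = 1e-6,
                                tol_bounds = 1e-9) {
  S <- stoich_matrix(model)
  b <- bounds_of(model)
  if (!is.null(names(v))) v <- v[colnames(S)]
  max(abs(S %*% v)) < tol_steady &&
    all(v >= b$lb - tol_bounds) && all(v <= b$ub + tol_bounds)
}
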