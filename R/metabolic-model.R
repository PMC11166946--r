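# Constraint-based metabolic model container, gene-reaction rules, the LP
# wrapper, and the fixed toy models used throughout the flux module.

#' Construct a metabolic model
#'
#' A lightweight constraint-based model: metabolites (with a boundary flag),
#' reactions with stoichiometry, flux bounds, an optional boolean
#' gene-reaction rule (`AND`/`OR`/parentheses over gene symbols), and a
#' free-text pathway tag.
#'
#' @param metabolites Data frame with columns `id` and logical `boundary`.
#' @param reactions List of reactions, each a list with elements `id`,
#'   `mets` (named numeric: metabolite -> coefficient), `lb`, `ub`,
#'   `rule` (may be `""`), `pathway`.
#' @param genes Character vector of gene symbols (defaults to the union of
#'   symbols referenced by the rules).
#' @param id Optional model identifier (used to cache derived quantities).
#' @return An object of class `metabolic_model` with the stoichiometric
#'   matrix `S` (rows = non-boundary metabolites, columns = reactions),
#'   bounds, rules and pathway tags.
#' @export
metabolic_model <- function(metabolites, reactions, genes = NULL, id = NULL) {
  assert_that(is.data.frame(metabolites) && all(c("id", "boundary") %in% names(metabolites)),
              "metabolites must have columns id, boundary")
  assert_that(!anyDuplicated(metabolites$id), "duplicate metabolite ids")
  rxn_ids <- vapply(reactions, function(r) r$id, character(1))
  assert_that(!anyDuplicated(rxn_ids), "duplicate reaction ids")
  internal <- metabolites$id[!metabolites$boundary]
  S <- matrix(0, nrow = length(internal), ncol = length(reactions),
              dimnames = list(internal, rxn_ids))
  lb <- ub <- numeric(length(reactions))
  rule <- pathway <- character(length(reactions))
  for (j in seq_along(reactions)) {
    r <- reactions[[j]]
    unknown <- setdiff(names(r$mets), metabolites$id)
    assert_that(length(unknown) == 0,
                "reaction ", r$id, " references unknown metabolites: ",
                paste(unknown, collapse = ", "))
    assert_that(r$lb <= r$ub, "reaction ", r$id, " has lb > ub")
    keep <- intersect(names(r$mets), internal)
    S[keep, j] <- unname(r$mets[keep])
    lb[j] <- r$lb; ub[j] <- r$ub
    rule[j] <- r$rule %||% ""
    pathway[j] <- r$pathway %||% ""
  }
  rule_genes <- unique(unlist(lapply(rule[nzchar(rule)], gpr_genes)))
  genes <- genes %||% rule_genes
  missing_genes <- setdiff(rule_genes, genes)
  assert_that(length(missing_genes) == 0,
              "rules reference genes absent from the gene list: ",
              paste(missing_genes, collapse = ", "))
  model <- structure(list(
    metabolites = metabolites,
    reactions = rxn_ids,
    S = S,
    lb = stats::setNames(lb, rxn_ids),
    ub = stats::setNames(ub, rxn_ids),
    rule = stats::setNames(rule, rxn_ids),
    pathway = stats::setNames(pathway, rxn_ids),
    genes = genes,
    mets = lapply(reactions, function(r) r$mets),
    id = id
  ), class = "metabolic_model")
  names(model$mets) <- rxn_ids
  model
}

#' @export
print.metabolic_model <- function(x, ...) {
  cat("metabolic_model:", nrow(x$metabolites), "metabolites,",
      length(x$reactions), "reactions,", length(x$genes), "genes\n")
  invisible(x)
}

#' Identify exchange (boundary) reactions
#'
#' A reaction is an exchange if all its stoichiometric coefficients over
#' internal metabolites share one sign: it only imports to, or only drains
#' from, the system.
#'
#' @param model A [metabolic_model()].
#' @return Logical vector, named by reaction.
#' @export
is_exchange_reaction <- function(model) {
  out <- vapply(seq_along(model$reactions), function(j) {
    s <- model$S[, j]
    all(s >= 0) || all(s <= 0)
  }, logical(1))
  stats::setNames(out, model$reactions)
}

# ---- gene-reaction rules ----------------------------------------------------

gpr_tokenize <- function(rule) {
  rule <- gsub("([()])", " \\1 ", rule)
  toks <- strsplit(trimws(rule), "[[:space:]]+")[[1]]
  toks[nzchar(toks)]
}

# Recursive-descent parse: expr := term (OR term)*; term := atom (AND atom)*;
# atom := gene | '(' expr ')'. Returns nested list AST.
gpr_parse <- function(rule, rxn = "?") {
  toks <- gpr_tokenize(rule)
  pos <- 1L
  peek <- function() if (pos <= length(toks)) toks[pos] else NA_character_
  take <- function() { t <- toks[pos]; pos <<- pos + 1L; t }
  fail <- function(msg) stop_invalid("malformed gene-reaction rule for reaction ",
                                     rxn, ": ", msg, " in '", rule, "'")
  parse_expr <- function() {
    node <- parse_term()
    while (!is.na(peek()) && toupper(peek()) == "OR") {
      take()
      node <- list(op = "OR", args = list(node, parse_term()))
    }
    node
  }
  parse_term <- function() {
    node <- parse_atom()
    while (!is.na(peek()) && toupper(peek()) == "AND") {
      take()
      node <- list(op = "AND", args = list(node, parse_atom()))
    }
    node
  }
  parse_atom <- function() {
    t <- peek()
    if (is.na(t)) fail("unexpected end of rule")
    if (t == "(") {
      take()
      node <- parse_expr()
      if (is.na(peek()) || peek() != ")") fail("missing closing parenthesis")
      take()
      return(node)
    }
    if (t %in% c(")", "AND", "OR", "and", "or")) fail(paste0("unexpected token '", t, "'"))
    take()
    list(op = "GENE", gene = t)
  }
  ast <- parse_expr()
  if (!is.na(peek())) fail(paste0("trailing token '", peek(), "'"))
  ast
}

gpr_genes <- function(rule) {
  toks <- gpr_tokenize(rule)
  toks[!(toupper(toks) %in% c("AND", "OR")) & !(toks %in% c("(", ")"))]
}

gpr_eval <- function(ast, expr) {
  switch(ast$op,
    GENE = if (ast$gene %in% names(expr)) unname(expr[[ast$gene]]) else 0,
    AND  = min(vapply(ast$args, gpr_eval, numeric(1), expr = expr)),
    OR   = max(vapply(ast$args, gpr_eval, numeric(1), expr = expr))
  )
}

#' Score reactions from one sample's gene expression
#'
#' Evaluates each reaction's gene-reaction rule with `AND` as minimum and
#' `OR` as maximum of the operand expression levels. Genes absent from the
#' expression vector score 0; reactions without a rule receive the median of
#' all rule-scored reactions.
#'
#' @param model A [metabolic_model()].
#' @param expression Named numeric vector of non-negative expression values.
#' @return Named numeric vector of per-reaction scores.
#' @export
reaction_expression <- function(model, expression) {
  assert_that(is.numeric(expression) && !is.null(names(expression)),
              "expression must be a named numeric vector")
  assert_that(all(expression >= 0), "expression values must be >= 0")
  has_rule <- nzchar(model$rule)
  scores <- stats::setNames(rep(NA_real_, length(model$reactions)), model$reactions)
  for (r in model$reactions[has_rule]) {
    ast <- gpr_parse(model$rule[[r]], rxn = r)
    scores[[r]] <- gpr_eval(ast, expression)
  }
  med <- stats::median(scores[has_rule])
  scores[!has_rule] <- if (is.na(med)) 0 else med
  scores
}

# ---- linear programming -----------------------------------------------------

# Maximize one reaction's flux over a model (optionally with extra >= rows).
# Asserts steady state and bounds on the returned solution.
maximize_reaction <- function(model, rxn, ge_mat = NULL, ge_rhs = NULL,
                              ss_tol = 1e-6) {
  j <- match(rxn, model$reactions)
  assert_that(!is.na(j), "unknown reaction: ", rxn)
  obj <- numeric(length(model$reactions)); obj[j] <- 1
  res <- solve_flux_lp(model$S, model$lb, model$ub, obj,
                       ge_mat = ge_mat, ge_rhs = ge_rhs)
  if (is.null(res)) return(NULL)
  v <- res$solution
  stopifnot(max(abs(model$S %*% v)) <= ss_tol,
            all(v >= model$lb - ss_tol), all(v <= model$ub + ss_tol))
  res
}

# ---- JSON / SBML ingest -----------------------------------------------------

#' Read a metabolic model from JSON
#'
#' Schema: `{metabolites:[{id, boundary}], reactions:[{id, mets:{id:coef},
#' lb, ub, rule, pathway}], genes:[...]}`.
#'
#' @param path Path to a JSON file.
#' @return A [metabolic_model()].
#' @export
read_model_json <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = FALSE)
  mets <- data.frame(
    id = vapply(x$metabolites, function(m) m$id, character(1)),
    boundary = vapply(x$metabolites, function(m) isTRUE(m$boundary), logical(1)),
    stringsAsFactors = FALSE
  )
  rxns <- lapply(x$reactions, function(r) {
    list(id = r$id,
         mets = stats::setNames(vapply(r$mets, as.numeric, numeric(1)), names(r$mets)),
         lb = as.numeric(r$lb), ub = as.numeric(r$ub),
         rule = r$rule %||% "", pathway = r$pathway %||% "")
  })
  genes <- if (!is.null(x$genes)) unlist(x$genes) else NULL
  metabolic_model(mets, rxns, genes = genes, id = x$id %||% NULL)
}

#' Write a metabolic model to JSON
#'
#' @param model A [metabolic_model()].
#' @param path Output path.
#' @export
write_model_json <- function(model, path) {
  x <- list(
    id = model$id,
    metabolites = lapply(seq_len(nrow(model$metabolites)), function(i) {
      list(id = model$metabolites$id[i], boundary = model$metabolites$boundary[i])
    }),
    reactions = lapply(model$reactions, function(r) {
      list(id = r, mets = as.list(model$mets[[r]]),
           lb = unname(model$lb[[r]]), ub = unname(model$ub[[r]]),
           rule = unname(model$rule[[r]]), pathway = unname(model$pathway[[r]]))
    }),
    genes = model$genes
  )
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' Read an SBML Level 3 FBC model
#'
#' Minimal reader mapping species, reactions (with `fbc` bounds and
#' gene-product associations) onto the package's model structure. `geneProductRef`
#' associations are translated to `AND`/`OR` rules.
#'
#' @param path Path to an SBML file.
#' @return A [metabolic_model()].
#' @export
read_model_sbml <- function(path) {
  doc <- xml2::read_xml(path)
  ns <- xml2::xml_ns(doc)
  species <- xml2::xml_find_all(doc, ".//*[local-name()='species']")
  mets <- data.frame(
    id = xml2::xml_attr(species, "id"),
    boundary = xml2::xml_attr(species, "boundaryCondition") %in% "true",
    stringsAsFactors = FALSE
  )
  params <- xml2::xml_find_all(doc, ".//*[local-name()='parameter']")
  pval <- stats::setNames(as.numeric(xml2::xml_attr(params, "value")),
                          xml2::xml_attr(params, "id"))
  assoc_to_rule <- function(node) {
    nm <- xml2::xml_name(node)
    if (nm == "geneProductRef") return(xml2::xml_attr(node, "geneProduct"))
    kids <- xml2::xml_children(node)
    parts <- vapply(kids, assoc_to_rule, character(1))
    op <- if (nm == "and") " AND " else " OR "
    paste0("(", paste(parts, collapse = op), ")")
  }
  rxn_nodes <- xml2::xml_find_all(doc, ".//*[local-name()='reaction']")
  rxns <- lapply(rxn_nodes, function(rn) {
    id <- xml2::xml_attr(rn, "id")
    get_side <- function(tag, sign) {
      refs <- xml2::xml_find_all(rn, paste0(".//*[local-name()='", tag,
                                            "']/*[local-name()='speciesReference']"))
      if (length(refs) == 0) return(numeric(0))
      st <- as.numeric(xml2::xml_attr(refs, "stoichiometry"))
      st[is.na(st)] <- 1
      stats::setNames(sign * st, xml2::xml_attr(refs, "species"))
    }
    mets_vec <- c(get_side("listOfReactants", -1), get_side("listOfProducts", 1))
    lb_id <- xml2::xml_attr(rn, "lowerFluxBound", ns = ns)
    ub_id <- xml2::xml_attr(rn, "upperFluxBound", ns = ns)
    if (is.na(lb_id)) lb_id <- xml2::xml_attr(rn, "lowerFluxBound")
    if (is.na(ub_id)) ub_id <- xml2::xml_attr(rn, "upperFluxBound")
    rev <- xml2::xml_attr(rn, "reversible") %in% "true"
    lb <- if (!is.na(lb_id) && lb_id %in% names(pval)) pval[[lb_id]] else if (rev) -1000 else 0
    ub <- if (!is.na(ub_id) && ub_id %in% names(pval)) pval[[ub_id]] else 1000
    gpa <- xml2::xml_find_first(rn, ".//*[local-name()='geneProductAssociation']")
    rule <- if (inherits(gpa, "xml_missing")) "" else {
      assoc_to_rule(xml2::xml_children(gpa)[[1]])
    }
    list(id = id, mets = mets_vec, lb = lb, ub = ub, rule = rule, pathway = "")
  })
  metabolic_model(mets, rxns)
}

# ---- fixed toy models -------------------------------------------------------

#' The fixed toy metabolic network
#'
#' A deterministic 17-metabolite / 25-reaction network: a glucose uptake
#' chain (bound 10 flux units), glycolysis, a pentose-phosphate branch
#' feeding NAD biosynthesis (`nad_c`), coenzyme-A synthesis/catabolism, a
#' fatty-acid synthesis/oxidation pair, a TCA/oxidative-phosphorylation
#' stub, a biomass drain, and a dedicated pyruvate secretion branch
#' (`PYRWASTE`/`EX_waste`) used to plant group differences. Gene-reaction
#' rules cover 21 synthetic genes `g1..g21`; pathway tags include all seven
#' essential-pathway names (see [essential_pathways()]).
#'
#' The NAD route capacity equals the uptake bound, so the NAD-sink optimum
#' of the full model is exactly 10.
#'
#' @return A [metabolic_model()] with `id = "toy_v1"`.
#' @export
toy_metabolic_model <- function() {
  met_ids <- c("glc_c", "g6p_c", "f6p_c", "g3p_c", "pep_c", "pyr_c", "lac_c",
               "accoa_c", "cit_c", "atp_c", "ribu5p_c", "nam_c", "nad_c",
               "pnto_c", "coa_c", "ffa_c", "waste_c")
  mets <- data.frame(id = met_ids, boundary = FALSE, stringsAsFactors = FALSE)
  rx <- function(id, mets, lb, ub, rule, pathway) {
    list(id = id, mets = mets, lb = lb, ub = ub, rule = rule, pathway = pathway)
  }
  reactions <- list(
    rx("EX_glc",   c(glc_c = 1),                    0, 10,   "",              "Exchange"),
    rx("HEX1",     c(glc_c = -1, g6p_c = 1),        0, 1000, "g1",            "Glycolysis/Gluconeogenesis"),
    rx("PGI",      c(g6p_c = -1, f6p_c = 1),        0, 1000, "g2",            "Glycolysis/Gluconeogenesis"),
    rx("PFKALD",   c(f6p_c = -1, g3p_c = 2),        0, 1000, "g3",            "Glycolysis/Gluconeogenesis"),
    rx("GAPDENO",  c(g3p_c = -1, pep_c = 1),        0, 1000, "g4",            "Glycolysis/Gluconeogenesis"),
    rx("PYK",      c(pep_c = -1, pyr_c = 1),        0, 1000, "g5",            "Glycolysis/Gluconeogenesis"),
    rx("LDH",      c(pyr_c = -1, lac_c = 1),    -1000, 1000, "g6",            "Pyruvate Metabolism"),
    rx("EX_lac",   c(lac_c = -1),                   0, 1000, "",              "Exchange"),
    rx("PDH",      c(pyr_c = -1, accoa_c = 1),      0, 1000, "g7 AND g8",     "Pyruvate Metabolism"),
    rx("CS",       c(accoa_c = -1, cit_c = 1),      0, 1000, "g9",            "Citric Acid Cycle"),
    rx("EX_cit",   c(cit_c = -1),                   0, 1000, "",              "Exchange"),
    rx("OXPHOS",   c(cit_c = -1, atp_c = 1),        0, 1000, "g10 OR g11",    "Oxidative Phosphorylation"),
    rx("ATPM",     c(atp_c = -1),                   0, 1000, "",              "ATP Maintenance"),
    rx("G6PDPPP",  c(g6p_c = -1, ribu5p_c = 1),     0, 1000, "g12",           "Pentose Phosphate Pathway"),
    rx("PRPPNAM",  c(ribu5p_c = -1, nam_c = 1),     0, 1000, "g13",           "NAD Metabolism"),
    rx("NADS",     c(nam_c = -1, nad_c = 1),        0, 1000, "g14 OR g15",    "NAD Metabolism"),
    rx("NADUSE",   c(nad_c = -1),                   0, 1000, "",              "NAD Metabolism"),
    rx("PANTO",    c(pyr_c = -1, pnto_c = 1),       0, 1000, "g16",           "CoA Synthesis"),
    rx("COAS",     c(pnto_c = -1, coa_c = 1),       0, 1000, "g17",           "CoA Synthesis"),
    rx("COAC",     c(coa_c = -1),                   0, 1000, "g18",           "CoA Catabolism"),
    rx("FAS",      c(accoa_c = -2, ffa_c = 1),      0, 1000, "g19 AND g20",   "Fatty Acid Synthesis"),
    rx("FAO",      c(ffa_c = -1, accoa_c = 2),      0, 1000, "g20",           "Fatty Acid Oxidation"),
    rx("BIOMASS",  c(f6p_c = -0.5, coa_c = -0.1),   0, 1000, "",              "Biomass and Maintenance Functions"),
    rx("PYRWASTE", c(pyr_c = -1, waste_c = 1),      0, 5,    "g21",           "Secretion"),
    rx("EX_waste", c(waste_c = -1),                 0, 1000, "",              "Exchange")
  )
  metabolic_model(mets, reactions, genes = paste0("g", 1:21), id = "toy_v1")
}

#' A linear uptake-to-NAD chain
#'
#' Uptake (bound `uptake_bound`) feeding `n_steps` sequential conversions
#' that end in `nad_c`. Used as the hand-solvable reference: the NAD-sink
#' optimum and every intermediate reaction's flux level equal the uptake
#' bound exactly.
#'
#' @param n_steps Number of internal conversion steps (>= 1).
#' @param uptake_bound Upper bound of the uptake reaction.
#' @return A [metabolic_model()].
#' @export
toy_linear_chain <- function(n_steps = 3, uptake_bound = 10) {
  assert_that(is_count(n_steps), "n_steps must be a positive integer")
  met_ids <- c(paste0("m", seq_len(n_steps)), "nad_c")
  mets <- data.frame(id = met_ids, boundary = FALSE, stringsAsFactors = FALSE)
  reactions <- vector("list", n_steps + 1)
  reactions[[1]] <- list(id = "UPTAKE", mets = c(m1 = 1), lb = 0,
                         ub = uptake_bound, rule = "", pathway = "Exchange")
  for (i in seq_len(n_steps)) {
    from <- met_ids[i]; to <- met_ids[i + 1]
    mv <- stats::setNames(c(-1, 1), c(from, to))
    reactions[[i + 1]] <- list(id = paste0("STEP", i), mets = mv, lb = 0,
                               ub = 1000, rule = "", pathway = "Chain")
  }
  metabolic_model(mets, reactions, genes = character(0),
                  id = paste0("chain_", n_steps, "_", uptake_bound))
}

#' Feasibility of a strictly positive steady-state flux
#'
#' Checks stoichiometric consistency: whether a flux vector with every
#' reaction at least `delta` (reversible reactions included, run forward)
#' satisfies steady state within bounds. One feasibility LP.
#'
#' @param model A [metabolic_model()].
#' @param delta Strictly positive lower flux (default 1e-3).
#' @return `TRUE` when such a vector exists.
#' @export
positive_flux_feasible <- function(model, delta = 1e-3) {
  lb <- pmax(model$lb, delta)
  res <- solve_flux_lp(model$S, lb, model$ub,
                       objective = numeric(length(model$reactions)))
  !is.null(res)
}
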