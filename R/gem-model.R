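#' Parse a gene-protein-reaction boolean rule
#'
#' Grammar: \code{expr := term ("or" term)*; term := factor ("and"
#' factor)*; factor := gene | "(" expr ")"}. AND encodes an enzyme
#' complex, OR isoenzymes. Case-insensitive keywords; an empty rule
#' parses to \code{NULL} (reaction not gene-gated).
#'
#' @param gpr rule string, e.g. \code{"(gA and gB) or gC"}.
#' @return a nested list tree (\code{list(op, args)} or
#'   \code{list(op = "gene", id)}), or \code{NULL} for an empty rule.
#' @export
parse_gpr <- function(gpr) {
  if (is.null(gpr) || is.na(gpr) || !nzchar(trimws(gpr))) return(NULL)
  tokens <- regmatches(gpr, gregexpr("\\(|\\)|[^()[:space:]]+", gpr))[[1]]
  pos <- 1L
  peek <- function() if (pos <= length(tokens)) tokens[pos] else NA_character_
  advance <- function() { tok <- peek(); pos <<- pos + 1L; tok }
  is_kw <- function(tok, kw) !is.na(tok) && tolower(tok) == kw
  parse_expr <- function() {
    args <- list(parse_term())
    while (is_kw(peek(), "or")) {
      advance()
      args[[length(args) + 1L]] <- parse_term()
    }
    if (length(args) == 1L) args[[1]] else list(op = "or", args = args)
  }
  parse_term <- function() {
    args <- list(parse_factor())
    while (is_kw(peek(), "and")) {
      advance()
      args[[length(args) + 1L]] <- parse_factor()
    }
    if (length(args) == 1L) args[[1]] else list(op = "and", args = args)
  }
  parse_factor <- function() {
    tok <- advance()
    if (is.na(tok)) stop("parse_gpr: unexpected end of rule: '", gpr, "'")
    if (tok == "(") {
      e <- parse_expr()
      if (!identical(advance(), ")"))
        stop("parse_gpr: missing ')' in rule: '", gpr, "'")
      return(e)
    }
    if (tok == ")" || is_kw(tok, "and") || is_kw(tok, "or"))
      stop("parse_gpr: malformed rule: '", gpr, "'")
    list(op = "gene", id = tok)
  }
  tree <- parse_expr()
  if (pos <= length(tokens))
    stop("parse_gpr: trailing tokens in rule: '", gpr, "'")
  tree
}

#' Evaluate a GPR tree on binary gene states
#'
#' AND is min, OR is max. An empty rule (NULL tree) evaluates to active
#' (1), as do genes absent from \code{gene_states} — absence of evidence
#' never switches a reaction off.
#'
#' @param tree output of \code{\link{parse_gpr}}.
#' @param gene_states named numeric/logical vector of 0/1 gene states.
#' @return 0 or 1.
#' @export
eval_gpr <- function(tree, gene_states) {
  if (is.null(tree)) return(1)
  if (tree$op == "gene") {
    s <- gene_states[tree$id]
    return(if (is.na(s)) 1 else as.numeric(s))
  }
  vals <- vapply(tree$args, eval_gpr, numeric(1),
                 gene_states = gene_states)
  if (tree$op == "and") min(vals) else max(vals)
}

#' Genes referenced by a GPR tree
#' @param tree output of \code{\link{parse_gpr}}.
#' @return character vector of gene identifiers (possibly empty).
#' @export
gpr_genes <- function(tree) {
  if (is.null(tree)) return(character(0))
  if (tree$op == "gene") return(tree$id)
  unique(unlist(lapply(tree$args, gpr_genes)))
}

#' Construct and validate a constraint-based metabolic model
#'
#' @param metabolites \code{data.frame} with columns \code{id},
#'   \code{compartment}.
#' @param reactions list of reactions, each a list with \code{id},
#'   \code{name}, \code{subsystem}, \code{lb}, \code{ub}, \code{gpr}
#'   (string) and \code{metabolites} (named coefficients; negative =
#'   consumed).
#' @param objective id of the objective reaction.
#' @param id model identifier.
#' @return validated object of class \code{metabolic_model} with the
#'   stoichiometric matrix \code{S} (metabolite x reaction), parsed GPR
#'   trees and the gene universe precomputed.
#' @export
metabolic_model <- function(metabolites, reactions, objective,
                            id = "model") {
  stopifnot(is.data.frame(metabolites),
            all(c("id", "compartment") %in% names(metabolites)))
  if (anyDuplicated(metabolites$id))
    stop("metabolic_model: duplicate metabolite ids")
  rids <- vapply(reactions, `[[`, "", "id")
  if (anyDuplicated(rids)) stop("metabolic_model: duplicate reaction ids")
  lb <- vapply(reactions, `[[`, 0, "lb")
  ub <- vapply(reactions, `[[`, 0, "ub")
  bad <- lb > ub
  if (any(bad))
    stop("metabolic_model: lb > ub for reaction(s): ",
         paste(rids[bad], collapse = ", "))
  if (!objective %in% rids)
    stop("metabolic_model: objective reaction '", objective, "' not found")
  subsys <- vapply(reactions, function(r)
    if (is.null(r$subsystem) || !nzchar(r$subsystem)) "Unassigned"
    else r$subsystem, "")
  S <- matrix(0, nrow(metabolites), length(reactions),
              dimnames = list(metabolites$id, rids))
  for (j in seq_along(reactions)) {
    st <- reactions[[j]]$metabolites
    unknown <- setdiff(names(st), metabolites$id)
    if (length(unknown))
      stop("metabolic_model: reaction '", rids[j],
           "' references unknown metabolite(s): ",
           paste(unknown, collapse = ", "))
    S[names(st), j] <- st
  }
  gpr_str <- vapply(reactions, function(r)
    if (is.null(r$gpr) || is.na(r$gpr)) "" else r$gpr, "")
  trees <- lapply(gpr_str, parse_gpr)
  structure(list(id = id, metabolites = metabolites,
                 reactions = stats::setNames(reactions, rids),
                 reaction_ids = rids, subsystems = stats::setNames(subsys, rids),
                 lb = stats::setNames(lb, rids), ub = stats::setNames(ub, rids),
                 S = S, gpr = stats::setNames(gpr_str, rids),
                 gpr_trees = stats::setNames(trees, rids),
                 genes = sort(unique(unlist(lapply(trees, gpr_genes)))),
                 objective = objective),
            class = "metabolic_model")
}

#' @export
print.metabolic_model <- function(x, ...) {
  cat("Metabolic model '", x$id, "': ", nrow(x$metabolites),
      " metabolites, ", length(x$reactions), " reactions, ",
      length(unique(x$subsystems)), " subsystems, ", length(x$genes),
      " genes; objective = ", x$objective, "\n", sep = "")
  invisible(x)
}

#' Read / write a metabolic model in the package JSON dialect
#'
#' Dialect: \code{{"metabolites": [{"id", "compartment"}], "reactions":
#' [{"id", "name", "subsystem", "lb", "ub", "gpr", "metabolites":
#' {mid: coef}}], "objective": rid}}.
#'
#' @param path file path.
#' @return \code{read_model_json}: a validated \code{metabolic_model}.
#' @export
read_model_json <- function(path) {
  raw <- jsonlite::read_json(path)
  mets <- data.frame(
    id = vapply(raw$metabolites, `[[`, "", "id"),
    compartment = vapply(raw$metabolites, `[[`, "", "compartment"),
    stringsAsFactors = FALSE)
  reactions <- lapply(unname(raw$reactions), function(r) {
    list(id = r$id, name = if (is.null(r$name)) r$id else r$name,
         subsystem = if (is.null(r$subsystem)) "Unassigned" else r$subsystem,
         lb = as.numeric(r$lb), ub = as.numeric(r$ub),
         gpr = if (is.null(r$gpr)) "" else r$gpr,
         metabolites = unlist(r$metabolites))
  })
  metabolic_model(mets, reactions, objective = raw$objective,
                  id = if (is.null(raw$id)) basename(path) else raw$id)
}

#' @param model a \code{metabolic_model}.
#' @rdname read_model_json
#' @export
write_model_json <- function(model, path) {
  stopifnot(inherits(model, "metabolic_model"))
  obj <- list(
    id = model$id,
    metabolites = lapply(seq_len(nrow(model$metabolites)), function(i)
      list(id = model$metabolites$id[i],
           compartment = model$metabolites$compartment[i])),
    reactions = lapply(unname(model$reactions), function(r)
      list(id = r$id, name = r$name, subsystem = r$subsystem,
           lb = r$lb, ub = r$ub, gpr = r$gpr,
           metabolites = as.list(r$metabolites))),
    objective = model$objective)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' Reaction states implied by binary gene states
#'
#' @param model a \code{metabolic_model}.
#' @param gene_states named 0/1 vector; missing genes count as active.
#' @return named 0/1 vector over reactions.
#' @export
reaction_states <- function(model, gene_states) {
  vapply(model$gpr_trees, eval_gpr, numeric(1), gene_states = gene_states)
}
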