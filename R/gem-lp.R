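# LP layer: bounded-variable linear programs over fluxes, solved with the
# package's two-phase simplex (lp-solver.R) via the substitution
# x = v - lb >= 0. Handles equality rows (S v = 0), variable upper
# bounds, and optional >= side constraints (objective functionality cuts).

solve_lp <- function(obj, S, lb, ub, geq_A = NULL, geq_b = NULL,
                     maximize = TRUE) {
  n <- length(lb)
  A_eq <- S
  b_eq <- -as.vector(S %*% lb)
  neg <- b_eq < 0
  A_eq[neg, ] <- -A_eq[neg, , drop = FALSE]
  b_eq[neg] <- -b_eq[neg]
  A <- rbind(A_eq, diag(n))
  b <- c(b_eq, ub - lb)
  type <- c(rep("eq", nrow(S)), rep("le", n))
  if (!is.null(geq_A)) {
    Ag <- matrix(geq_A, ncol = n)
    bg <- geq_b - as.vector(Ag %*% lb)
    flip <- bg < 0  # a >= row with negative rhs is a <= row after negation
    Ag[flip, ] <- -Ag[flip, , drop = FALSE]
    bg[flip] <- -bg[flip]
    A <- rbind(A, Ag)
    b <- c(b, bg)
    type <- c(type, ifelse(flip, "le", "ge"))
  }
  res <- lp_bland(obj, A, b, type, maximize = maximize)
  if (res$status != "optimal")
    return(list(status = res$status, value = NA_real_,
                fluxes = rep(NA_real_, n)))
  list(status = "optimal", value = res$value + sum(obj * lb),
       fluxes = res$x + lb)
}

# Flux bounds gated by binary reaction states (state 0 => fixed at 0).
gated_bounds <- function(model, states) {
  lb <- model$lb
  ub <- model$ub
  off <- states < 0.5
  lb[off] <- 0
  ub[off] <- 0
  list(lb = lb, ub = ub)
}

#' Flux balance analysis
#'
#' Maximizes the objective reaction flux subject to steady-state mass
#' balance \code{S v = 0} and flux bounds; reactions with state 0 are
#' constrained to zero flux.
#'
#' @param model a \code{metabolic_model}.
#' @param gene_states optional named 0/1 gene states; reaction states are
#'   derived through the GPR rules (missing genes are active).
#' @param states optional named 0/1 reaction states (overrides
#'   \code{gene_states}).
#' @return list with \code{objective} (optimal flux, NA if infeasible),
#'   \code{fluxes}, \code{status}, \code{states}.
#' @export
fba <- function(model, gene_states = NULL, states = NULL) {
  stopifnot(inherits(model, "metabolic_model"))
  if (is.null(states)) {
    states <- if (is.null(gene_states))
      stats::setNames(rep(1, length(model$reactions)), model$reaction_ids)
    else reaction_states(model, gene_states)
  }
  states <- states[model$reaction_ids]
  gb <- gated_bounds(model, states)
  obj <- as.numeric(model$reaction_ids == model$objective)
  res <- solve_lp(obj, model$S, gb$lb, gb$ub, maximize = TRUE)
  list(objective = res$value,
       fluxes = stats::setNames(res$fluxes, model$reaction_ids),
       status = res$status, states = states)
}

#' Flux variability analysis
#'
#' Per-reaction minimum and maximum flux under mass balance, (gated)
#' bounds and the functionality constraint that the objective flux stays
#' at or above a fraction \code{f} of the reference optimum. Reactions
#' with state 0 are reported as \code{[0, 0]} without solving.
#'
#' @param model a \code{metabolic_model}.
#' @param states named 0/1 reaction states for the condition.
#' @param f functionality fraction in [0, 1].
#' @param vstar reference optimum; computed by all-active FBA when NULL.
#' @return \code{data.frame} (class \code{fva_result}) with columns
#'   \code{reaction, state, lo, hi}.
#' @export
fva <- function(model, states = NULL, f = 0.3, vstar = NULL) {
  stopifnot(inherits(model, "metabolic_model"), f >= 0, f <= 1)
  if (is.null(states))
    states <- stats::setNames(rep(1, length(model$reactions)),
                              model$reaction_ids)
  states <- states[model$reaction_ids]
  if (is.null(vstar)) {
    ref <- fba(model)
    if (ref$status != "optimal")
      stop("fva: reference model FBA failed: ", ref$status)
    vstar <- ref$objective
  }
  cond <- fba(model, states = states)
  if (cond$status != "optimal" || cond$objective < f * vstar - 1e-9)
    stop("fva: condition model cannot reach the functionality threshold ",
         "(objective ", format(cond$objective), " < ", format(f * vstar), ")")
  gb <- gated_bounds(model, states)
  obj_row <- as.numeric(model$reaction_ids == model$objective)
  fcut <- f * vstar - 1e-9  # slack so a condition sitting exactly at the
                            # threshold stays feasible in floating point
  n <- length(states)
  lo <- hi <- numeric(n)
  for (j in seq_len(n)) {
    if (states[j] < 0.5) next
    cvec <- numeric(n)
    cvec[j] <- 1
    rmin <- solve_lp(cvec, model$S, gb$lb, gb$ub, geq_A = obj_row,
                     geq_b = fcut, maximize = FALSE)
    rmax <- solve_lp(cvec, model$S, gb$lb, gb$ub, geq_A = obj_row,
                     geq_b = fcut, maximize = TRUE)
    if (rmin$status != "optimal" || rmax$status != "optimal")
      stop("fva: LP failed for reaction ", model$reaction_ids[j])
    lo[j] <- rmin$value
    hi[j] <- rmax$value
  }
  # guard against sign-flipped rounding in near-degenerate solves
  swap <- lo > hi
  if (any(swap)) {
    tmp <- lo[swap]; lo[swap] <- hi[swap]; hi[swap] <- tmp
  }
  out <- data.frame(reaction = model$reaction_ids, state = unname(states),
                    lo = lo, hi = hi, row.names = NULL,
                    stringsAsFactors = FALSE)
  class(out) <- c("fva_result", "data.frame")
  attr(out, "f") <- f
  attr(out, "vstar") <- vstar
  out
}
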