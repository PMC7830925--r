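#' Differential-expression input for metabolic integration
#'
#' Converts a per-gene statistics table into the observed-transition form
#' the gene-state matcher consumes: \code{d} is the sign of the log fold
#' change for significant genes (FDR < alpha) and 0 otherwise; the
#' confidence weight is \code{w = -log10(p)} capped at \code{w_max}.
#'
#' @param stats a \code{gene_stats} data frame.
#' @param alpha FDR cutoff defining a significant transition.
#' @param w_max weight cap (zero p-values would otherwise give infinite
#'   weight).
#' @return \code{data.frame} with columns \code{gene_id, d, w}.
#' @export
make_de_input <- function(stats, alpha = 0.05, w_max = 10) {
  stopifnot(all(c("gene_id", "beta", "p", "fdr") %in% names(stats)))
  d <- ifelse(stats$fdr < alpha, sign(stats$beta), 0)
  w <- pmin(-log10(stats$p), w_max)
  w[!is.finite(w)] <- w_max
  w <- pmax(w, 0)
  data.frame(gene_id = stats$gene_id, d = as.integer(d), w = w,
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Integrate differential expression into a metabolic model (MADE-style)
#'
#' Assigns binary gene activity states to the wild-type and knockout
#' conditions so that the weighted number of matched observed transitions
#' is maximal, subject to both condition models remaining functional:
#' reaction states follow from the GPR rules, flux variables are gated by
#' reaction state, and each condition's objective flux must reach at least
#' \code{f} times the reference (all-active) optimum. A gene with
#' \code{d = +1} is matched by the transition 0 -> 1 (WT -> KO),
#' \code{d = -1} by 1 -> 0, and \code{d = 0} by equal states.
#'
#' The search is an exact branch-and-bound: genes without a significant
#' transition are fixed active in both conditions and genes outside the
#' network match freely (both choices weakly dominant because GPR rules
#' are monotone in gene activity), so branching is only over significant
#' network genes, between the matching transition and the always-feasible
#' all-active fallback, with LP feasibility pruning and a remaining-weight
#' bound. The returned solution is proven optimal unless the node limit
#' was hit.
#'
#' @param model a \code{metabolic_model} with a positive reference
#'   optimum.
#' @param de output of \code{\link{make_de_input}} (columns
#'   \code{gene_id, d, w}).
#' @param f functionality fraction of the reference optimum each
#'   condition must retain.
#' @param w_max weight cap re-applied defensively.
#' @param max_nodes search-node budget.
#' @return object of class \code{made_solution}: \code{gene_states}
#'   (gene x condition 0/1 matrix), \code{reaction_states},
#'   \code{objective_value} (matched weight), \code{match_fraction},
#'   \code{total_weight}, \code{solver_status}, \code{f}, \code{vstar}.
#' @export
made_integrate <- function(model, de, f = 0.3, w_max = 10,
                           max_nodes = 1e5) {
  stopifnot(inherits(model, "metabolic_model"),
            all(c("gene_id", "d", "w") %in% names(de)),
            f >= 0, f <= 1)
  if (anyDuplicated(de$gene_id))
    stop("made_integrate: duplicate gene ids in DE input")
  if (any(!de$d %in% c(-1L, 0L, 1L)))
    stop("made_integrate: d must be in {-1, 0, 1}")
  ref <- fba(model)
  if (ref$status != "optimal" || !(ref$objective > 1e-9))
    stop("made_integrate: reference model has no positive optimum")
  vstar <- ref$objective
  threshold <- f * vstar - 1e-9

  genes_all <- union(model$genes, de$gene_id)
  d <- stats::setNames(rep(0L, length(genes_all)), genes_all)
  w <- stats::setNames(rep(0, length(genes_all)), genes_all)
  d[de$gene_id] <- de$d
  w[de$gene_id] <- pmin(de$w, w_max)
  total_w <- sum(w)

  in_model <- genes_all %in% model$genes
  branch <- genes_all[in_model & d != 0L]
  branch <- branch[order(-w[branch])]
  # weight matched regardless of the branch outcome: unchanged genes are
  # fixed active in both conditions; off-network genes take their
  # matching states freely.
  base_match <- sum(w[d == 0L]) + sum(w[!in_model & d != 0L])

  ones <- stats::setNames(rep(1, length(model$genes)), model$genes)
  cond_feasible <- function(gene_states) {
    res <- fba(model, gene_states = gene_states)
    res$status == "optimal" && res$objective >= threshold
  }
  if (!cond_feasible(ones))
    stop("made_integrate: all-active model infeasible at f = ", f)

  nb <- length(branch)
  rem <- rev(cumsum(rev(c(w[branch], 0))))  # rem[i] = weight left from i
  best_extra <- 0
  best_wt <- best_ko <- ones
  nodes <- 0L
  hit_limit <- FALSE

  recurse <- function(i, awt, ako, extra) {
    nodes <<- nodes + 1L
    if (nodes > max_nodes) { hit_limit <<- TRUE; return(invisible()) }
    if (extra + rem[i] < best_extra + 1e-12) return(invisible())
    if (i > nb) {
      if (extra > best_extra) {
        best_extra <<- extra
        best_wt <<- awt
        best_ko <<- ako
      }
      return(invisible())
    }
    g <- branch[i]
    # matching transition: one condition loses the gene
    if (d[g] == 1L) {
      awt2 <- awt; awt2[g] <- 0
      if (cond_feasible(awt2)) recurse(i + 1L, awt2, ako, extra + w[g])
    } else {
      ako2 <- ako; ako2[g] <- 0
      if (cond_feasible(ako2)) recurse(i + 1L, awt, ako2, extra + w[g])
    }
    # fallback: gene stays active in both conditions (mismatch)
    recurse(i + 1L, awt, ako, extra)
  }
  if (nb > 0L) recurse(1L, ones, ones, 0)

  gene_states <- matrix(1, nrow = length(genes_all), ncol = 2L,
                        dimnames = list(genes_all, c("WT", "KO")))
  gene_states[names(best_wt), "WT"] <- best_wt
  gene_states[names(best_ko), "KO"] <- best_ko
  off_net <- genes_all[!in_model]
  gene_states[off_net, "WT"] <- ifelse(d[off_net] == 1L, 0, 1)
  gene_states[off_net, "KO"] <- ifelse(d[off_net] == -1L, 0, 1)

  rstates <- cbind(
    WT = reaction_states(model, gene_states[, "WT"]),
    KO = reaction_states(model, gene_states[, "KO"]))
  objective_value <- unname(base_match + best_extra)
  structure(list(gene_states = gene_states, reaction_states = rstates,
                 objective_value = objective_value,
                 match_fraction = if (total_w > 0)
                   objective_value / total_w else 1,
                 total_weight = total_w,
                 solver_status = if (hit_limit) "node_limit" else "optimal",
                 f = f, vstar = vstar, nodes = nodes),
            class = "made_solution")
}

#' @export
print.made_solution <- function(x, ...) {
  cat("MADE solution (", x$solver_status, "): matched weight ",
      format(x$objective_value), " of ", format(x$total_weight),
      " (fraction ", format(round(x$match_fraction, 4)), ")\n", sep = "")
  off <- colSums(x$gene_states == 0)
  cat("  inactive genes: WT ", off["WT"], ", KO ", off["KO"],
      "; reference optimum ", format(x$vstar), ", f = ", x$f, "\n",
      sep = "")
  invisible(x)
}

#' Classify reactions as up- or down-regulated from paired FVA results
#'
#' The flux capacity of a reaction in a condition is
#' \code{M = max(|lo|, |hi|)}. A reaction is up if the knockout capacity
#' exceeds the wild-type capacity by more than \code{eps}, down in the
#' opposite case, else unchanged. Reactions switched off by the gene
#' states (WT 1 -> KO 0) are down and switched-on reactions are up,
#' overriding the capacity comparison.
#'
#' @param fva_wt,fva_ko \code{fva_result} tables for the two conditions
#'   (same reaction order).
#' @param eps capacity-change tolerance (flux units).
#' @return \code{data.frame} with columns \code{reaction, state_WT,
#'   state_KO, M_WT, M_KO, class}.
#' @export
classify_reactions <- function(fva_wt, fva_ko, eps = 1e-6) {
  stopifnot(identical(fva_wt$reaction, fva_ko$reaction))
  m_wt <- pmax(abs(fva_wt$lo), abs(fva_wt$hi))
  m_ko <- pmax(abs(fva_ko$lo), abs(fva_ko$hi))
  cls <- rep("unchanged", length(m_wt))
  cls[m_ko - m_wt > eps] <- "up"
  cls[m_wt - m_ko > eps] <- "down"
  cls[fva_wt$state >= 0.5 & fva_ko$state < 0.5] <- "down"
  cls[fva_wt$state < 0.5 & fva_ko$state >= 0.5] <- "up"
  data.frame(reaction = fva_wt$reaction, state_WT = fva_wt$state,
             state_KO = fva_ko$state, M_WT = m_wt, M_KO = m_ko,
             class = cls, row.names = NULL, stringsAsFactors = FALSE)
}

#' Hypergeometric subsystem enrichment of regulated reactions
#'
#' For each direction separately, tests whether a subsystem's reactions
#' are over-represented among the reactions classified in that direction:
#' upper-tail hypergeometric p-value \code{P(X >= k)} with N reactions in
#' the model, K in the subsystem and n classified in the direction, BH
#' adjustment across subsystems within the direction, significance at
#' \code{fdr < alpha}. With no classified reactions in a direction all
#' its p-values are 1.
#'
#' @param classification output of \code{\link{classify_reactions}}.
#' @param model the \code{metabolic_model} (supplies subsystem labels).
#' @param alpha FDR cutoff.
#' @return \code{data.frame} with columns \code{subsystem, direction, K,
#'   N, n, k, p, fdr, significant}.
#' @export
subsystem_enrichment <- function(classification, model, alpha = 0.05) {
  stopifnot(inherits(model, "metabolic_model"),
            all(classification$reaction %in% model$reaction_ids))
  subsys <- model$subsystems[classification$reaction]
  N <- nrow(classification)
  subs <- sort(unique(subsys))
  out <- do.call(rbind, lapply(c("up", "down"), function(dir) {
    hit <- classification$class == dir
    n <- sum(hit)
    K <- vapply(subs, function(s) sum(subsys == s), 0)
    k <- vapply(subs, function(s) sum(hit & subsys == s), 0)
    p <- if (n == 0L) rep(1, length(subs))
         else stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE)
    data.frame(subsystem = subs, direction = dir, K = K, N = N, n = n,
               k = k, p = p, fdr = stats::p.adjust(p, method = "BH"),
               row.names = NULL, stringsAsFactors = FALSE)
  }))
  out$significant <- out$fdr < alpha
  out
}

#' Run the full metabolic integration for one model's DE results
#'
#' Convenience wrapper chaining \code{\link{make_de_input}},
#' \code{\link{made_integrate}}, per-condition \code{\link{fva}},
#' \code{\link{classify_reactions}} and
#' \code{\link{subsystem_enrichment}}.
#'
#' @param model a \code{metabolic_model}.
#' @param stats a \code{gene_stats} table.
#' @param alpha FDR cutoff (transitions and subsystem significance).
#' @param f functionality fraction.
#' @param w_max weight cap.
#' @param eps FVA capacity-change tolerance.
#' @return list with \code{solution}, \code{fva_wt}, \code{fva_ko},
#'   \code{classification}, \code{subsystems}.
#' @export
run_gem <- function(model, stats, alpha = 0.05, f = 0.3, w_max = 10,
                    eps = 1e-6) {
  de <- make_de_input(stats, alpha = alpha, w_max = w_max)
  sol <- made_integrate(model, de, f = f, w_max = w_max)
  fva_wt <- fva(model, states = sol$reaction_states[, "WT"], f = f,
                vstar = sol$vstar)
  fva_ko <- fva(model, states = sol$reaction_states[, "KO"], f = f,
                vstar = sol$vstar)
  cls <- classify_reactions(fva_wt, fva_ko, eps = eps)
  list(solution = sol, fva_wt = fva_wt, fva_ko = fva_ko,
       classification = cls,
       subsystems = subsystem_enrichment(cls, model, alpha = alpha))
}
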