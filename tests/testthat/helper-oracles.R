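# Independent reference implementations used as oracles. These
# deliberately use different algorithms / code paths than the package.

# Benjamini-Hochberg step-up executed literally: sort, cumulative minima
# of p * m / rank from the largest rank down.
bh_stepup_ref <- function(p) {
  m <- length(p)
  o <- order(p)
  adj <- p[o] * m / seq_len(m)
  adj <- rev(cummin(rev(adj)))
  adj <- pmin(adj, 1)
  out <- numeric(m)
  out[o] <- adj
  out
}

# Upper-tail hypergeometric probability P(X >= k) by direct summation of
# choose() terms (population N, K successes, n draws).
hyper_tail_ref <- function(k, K, N, n) {
  lo <- max(k, 0, n - (N - K))
  hi <- min(K, n)
  if (lo > hi) return(0)
  sum(choose(K, lo:hi) * choose(N - K, n - (lo:hi))) / choose(N, n)
}

# Naive O(n^3) average-linkage agglomeration returning merge heights.
avg_linkage_heights_ref <- function(d) {
  d <- as.matrix(d)
  n <- nrow(d)
  active <- as.list(seq_len(n))
  heights <- numeric(0)
  dist_ij <- function(a, b) mean(d[a, b])
  while (length(active) > 1L) {
    best <- c(NA, NA)
    bestd <- Inf
    for (i in seq_along(active)) for (j in seq_len(i - 1L)) {
      dd <- dist_ij(active[[i]], active[[j]])
      if (dd < bestd) { bestd <- dd; best <- c(i, j) }
    }
    heights <- c(heights, bestd)
    merged <- c(active[[best[1]]], active[[best[2]]])
    active <- active[-best]
    active[[length(active) + 1L]] <- merged
  }
  sort(heights)
}

# Independent numeric solve of the log-variance moment equations for the
# scaled inverse-chi-square prior: match mean and variance of e = log s2
# - digamma(df/2) + log(df/2) via uniroot on trigamma.
eb_prior_moments_ref <- function(s2, df) {
  e <- log(s2) - digamma(df / 2) + log(df / 2)
  excess <- var(e) - trigamma(df / 2)
  if (excess <= 0) return(list(d0 = Inf, s0sq = exp(mean(log(s2)))))
  half_d0 <- uniroot(function(y) trigamma(y) - excess,
                     lower = 1e-6, upper = 1e6, tol = 1e-12)$root
  list(d0 = 2 * half_d0,
       s0sq = exp(mean(e) + digamma(half_d0) - log(half_d0)))
}

# Exhaustive enumeration oracle for the gene-state matching problem: all
# 2^g gene-state vectors per condition, LP feasibility for each, then the
# best matched weight over all feasible (WT, KO) pairs.
made_enumerate_ref <- function(model, de, f) {
  ref <- fba(model)
  stopifnot(ref$status == "optimal", ref$objective > 1e-9)
  thr <- f * ref$objective - 1e-9
  genes <- model$genes
  ng <- length(genes)
  d <- stats::setNames(rep(0L, ng), genes)
  w <- stats::setNames(rep(0, ng), genes)
  idx <- de$gene_id %in% genes
  d[de$gene_id[idx]] <- de$d[idx]
  w[de$gene_id[idx]] <- de$w[idx]
  base_off <- sum(de$w[!idx])  # off-network genes always matchable
  combos <- as.matrix(expand.grid(rep(list(0:1), ng)))
  colnames(combos) <- genes
  feasible <- apply(combos, 1L, function(a) {
    res <- fba(model, gene_states = stats::setNames(a, genes))
    res$status == "optimal" && res$objective >= thr
  })
  Fs <- combos[feasible, , drop = FALSE]
  best <- -Inf
  for (i in seq_len(nrow(Fs))) {
    awt <- Fs[i, ]
    # matched weight is linear in the KO states given the WT states:
    # value(ako) = sum(alpha) + Fs %*% beta over candidate KO rows
    alpha <- ifelse(d == -1L & awt == 1, w,
                    ifelse(d == 0L & awt == 0, w, 0))
    beta <- ifelse(d == 1L & awt == 0, w,
                   ifelse(d == -1L & awt == 1, -w,
                          ifelse(d == 0L, ifelse(awt == 1, w, -w), 0)))
    vals <- sum(alpha) + as.vector(Fs %*% beta)
    best <- max(best, max(vals))
  }
  best + base_off
}

# Monte-Carlo sampler of the scaled inverse-chi-square prior.
rscinvchisq <- function(n, d0, s0sq) s0sq * d0 / rchisq(n, d0)

# Solve a flux LP with scipy.optimize.linprog (HiGHS) through the system
# python, as an implementation-independent FBA/FVA oracle.
scipy_lp_ref <- function(model, states = NULL, objective_id = NULL,
                         sense = "max", geq_value = NULL) {
  if (is.null(states))
    states <- stats::setNames(rep(1, length(model$reactions)),
                              model$reaction_ids)
  lb <- model$lb
  ub <- model$ub
  off <- states[model$reaction_ids] < 0.5
  lb[off] <- 0
  ub[off] <- 0
  if (is.null(objective_id)) objective_id <- model$objective
  obj <- as.numeric(model$reaction_ids == objective_id)
  payload <- list(S = unname(lapply(seq_len(nrow(model$S)), function(i)
                    as.numeric(model$S[i, ]))),
                  lb = unname(lb), ub = unname(ub), c = obj,
                  sense = sense)
  if (!is.null(geq_value))
    payload$functionality <- list(
      row = as.numeric(model$reaction_ids == model$objective),
      rhs = geq_value)
  infile <- tempfile(fileext = ".json")
  jsonlite::write_json(payload, infile, auto_unbox = TRUE, digits = NA)
  script <- '
import json, sys
import numpy as np
from scipy.optimize import linprog
p = json.load(open(sys.argv[1]))
S = np.array(p["S"], dtype=float)
c = np.array(p["c"], dtype=float)
sign = -1.0 if p["sense"] == "max" else 1.0
A_ub = b_ub = None
if "functionality" in p:
    A_ub = [[-x for x in p["functionality"]["row"]]]
    b_ub = [-float(p["functionality"]["rhs"])]
res = linprog(sign * c, A_eq=S, b_eq=np.zeros(S.shape[0]),
              A_ub=A_ub, b_ub=b_ub,
              bounds=list(zip(p["lb"], p["ub"])), method="highs")
val = None
if res.success:
    val = -float(res.fun) if p["sense"] == "max" else float(res.fun)
print(json.dumps({"success": bool(res.success), "value": val}))
'
  out <- system2("python", c("-c", shQuote(script), shQuote(infile)),
                 stdout = TRUE)
  jsonlite::fromJSON(out[length(out)])
}
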