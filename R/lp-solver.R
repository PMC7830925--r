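# Dense two-phase primal simplex with Bland's anti-cycling rule.
# Problems at the scale of this package (tens of reactions) are far below
# the size where sparse/revised implementations matter; correctness and
# guaranteed termination do.

# Minimize cost' x over the current tableau; T holds B^-1 A, b >= 0 the
# basic solution. Returns the updated tableau, basis and status.
simplex_iterate <- function(T, b, cost, basis, eps = 1e-9,
                            max_iter = 20000L) {
  m <- nrow(T)
  for (iter in seq_len(max_iter)) {
    red <- cost - as.vector(cost[basis] %*% T)
    red[basis] <- 0
    enter <- which(red < -eps)
    if (!length(enter))
      return(list(T = T, b = b, basis = basis, status = "optimal"))
    j <- enter[1L]  # Bland: smallest entering index
    col <- T[, j]
    pos <- which(col > eps)
    if (!length(pos))
      return(list(T = T, b = b, basis = basis, status = "unbounded"))
    ratios <- b[pos] / col[pos]
    rmin <- min(ratios)
    cand <- pos[ratios <= rmin + eps]
    i <- cand[which.min(basis[cand])]  # Bland: smallest leaving index
    piv <- T[i, j]
    T[i, ] <- T[i, ] / piv
    b[i] <- b[i] / piv
    fac <- T[, j]
    fac[i] <- 0
    T <- T - outer(fac, T[i, ])
    b <- b - fac * b[i]
    b[b < 0 & b > -eps] <- 0
    basis[i] <- j
  }
  list(T = T, b = b, basis = basis, status = "iteration_limit")
}

# Maximize (or minimize) cvec' x subject to A x (type) b, x >= 0, where
# type is "le", "ge" or "eq" per row. Rows must have b >= 0 (callers flip
# signs first).
lp_bland <- function(cvec, A, b, type, maximize = TRUE, eps = 1e-9) {
  m <- nrow(A)
  n0 <- ncol(A)
  stopifnot(length(b) == m, length(type) == m, all(b >= 0))
  le <- which(type == "le")
  ge <- which(type == "ge")
  art_rows <- which(type != "le")
  slack <- matrix(0, m, length(le))
  if (length(le)) slack[cbind(le, seq_along(le))] <- 1
  surplus <- matrix(0, m, length(ge))
  if (length(ge)) surplus[cbind(ge, seq_along(ge))] <- -1
  art <- matrix(0, m, length(art_rows))
  if (length(art_rows)) art[cbind(art_rows, seq_along(art_rows))] <- 1
  T <- cbind(A, slack, surplus, art)
  n_real <- n0 + length(le) + length(ge)
  K <- ncol(T)
  basis <- integer(m)
  basis[le] <- n0 + seq_along(le)
  basis[art_rows] <- n_real + seq_along(art_rows)
  bb <- b

  if (length(art_rows)) {
    cost1 <- c(rep(0, n_real), rep(1, length(art_rows)))
    ph1 <- simplex_iterate(T, bb, cost1, basis, eps = eps)
    if (ph1$status != "optimal")
      return(list(status = "infeasible", value = NA_real_,
                  x = rep(NA_real_, n0)))
    if (sum(cost1[ph1$basis] * ph1$b) > 1e-7)
      return(list(status = "infeasible", value = NA_real_,
                  x = rep(NA_real_, n0)))
    T <- ph1$T; bb <- ph1$b; basis <- ph1$basis
    # drive leftover zero-level artificials out of the basis
    drop_rows <- integer(0)
    for (i in which(basis > n_real)) {
      cols <- which(abs(T[i, seq_len(n_real)]) > eps)
      cols <- setdiff(cols, basis)
      if (!length(cols)) { drop_rows <- c(drop_rows, i); next }
      j <- cols[1L]
      piv <- T[i, j]
      T[i, ] <- T[i, ] / piv
      bb[i] <- bb[i] / piv
      fac <- T[, j]; fac[i] <- 0
      T <- T - outer(fac, T[i, ])
      bb <- bb - fac * bb[i]
      basis[i] <- j
    }
    if (length(drop_rows)) {  # redundant constraints
      T <- T[-drop_rows, , drop = FALSE]
      bb <- bb[-drop_rows]
      basis <- basis[-drop_rows]
    }
    T <- T[, seq_len(n_real), drop = FALSE]
  }

  cost2 <- c(if (maximize) -cvec else cvec, rep(0, n_real - n0))
  ph2 <- simplex_iterate(T, bb, cost2, basis, eps = eps)
  if (ph2$status == "unbounded")
    return(list(status = "unbounded", value = NA_real_,
                x = rep(NA_real_, n0)))
  if (ph2$status != "optimal")
    return(list(status = ph2$status, value = NA_real_,
                x = rep(NA_real_, n0)))
  x <- numeric(n_real)
  x[ph2$basis] <- ph2$b
  x <- x[seq_len(n0)]
  list(status = "optimal", value = sum(cvec * x), x = x)
}
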