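#' Per-gene two-group linear model fits
#'
#' Ordinary least squares for the knockout-vs-wild-type contrast reduces,
#' for a two-group design, to group means: the effect is the KO minus WT
#' mean and the residual variance is the pooled within-group variance.
#'
#' @param study an \code{\link{expression_study}}.
#' @return list with per-gene vectors \code{beta} (log2 fold change KO-WT),
#'   \code{s2} (pooled residual variance), scalars \code{df} (residual
#'   degrees of freedom) and \code{v} (unscaled variance of beta,
#'   \code{1/n_KO + 1/n_WT}), and \code{genes}.
#' @export
fit_gene_models <- function(study) {
  stopifnot(inherits(study, "expression_study"))
  wt <- study$group == "WT"
  ko <- study$group == "KO"
  n1 <- sum(wt); n2 <- sum(ko)
  if (n1 < 2L || n2 < 2L)
    stop("fit_gene_models: need >= 2 samples per group for residual df")
  x <- study$matrix
  m_wt <- rowMeans(x[, wt, drop = FALSE])
  m_ko <- rowMeans(x[, ko, drop = FALSE])
  df <- n1 + n2 - 2L
  rss <- rowSums((x[, wt, drop = FALSE] - m_wt)^2) +
    rowSums((x[, ko, drop = FALSE] - m_ko)^2)
  list(beta = m_ko - m_wt, s2 = rss / df, df = df, v = 1 / n1 + 1 / n2,
       genes = study$genes)
}

# Newton solve of trigamma(y) = x, vectorized; x > 0.
trigamma_inverse <- function(x) {
  stopifnot(all(x > 0))
  y <- 0.5 + 1 / x
  for (i in 1:60) {
    tri <- trigamma(y)
    dif <- tri * (1 - tri / x) / psigamma(y, deriv = 2L)
    y <- y + dif
    if (max(abs(dif / y)) < 1e-10) break
  }
  y
}

#' Estimate the empirical-Bayes variance prior
#'
#' Moment-matching on the log residual variances against the scaled-F
#' distribution they follow when gene variances are drawn from a scaled
#' inverse-chi-square prior: with \code{e = log s2 - digamma(df/2) +
#' log(df/2)}, the prior degrees of freedom solve
#' \code{trigamma(d0/2) = var(e) - trigamma(df/2)} and the prior scale is
#' \code{exp(mean(e) + digamma(d0/2) - log(d0/2))}. When the observed
#' spread of log variances does not exceed the chi-square sampling spread,
#' the prior is effectively infinite: \code{d0} is capped at \code{1e6}
#' and the scale falls back to the geometric mean of the variances.
#'
#' @param s2 per-gene residual variances (genes with \code{s2 <= 0} are
#'   excluded from estimation).
#' @param df residual degrees of freedom (scalar).
#' @param cap value standing in for an infinite prior df.
#' @return list \code{(d0, s0sq)} of class \code{ebayes_prior}.
#' @export
estimate_eb_prior <- function(s2, df, cap = 1e6) {
  stopifnot(length(df) == 1L, df > 0)
  s2ok <- s2[is.finite(s2) & s2 > 0]
  if (length(s2ok) < 2L)
    stop("estimate_eb_prior: need >= 2 genes with positive residual ",
         "variance; got ", length(s2ok),
         " (data degenerate, cannot estimate a variance prior)")
  z <- log(s2ok)
  e <- z - digamma(df / 2) + log(df / 2)
  excess <- stats::var(e) - trigamma(df / 2)
  if (excess > 0) {
    d0 <- 2 * trigamma_inverse(excess)
    if (d0 >= cap) d0 <- cap
    s0sq <- exp(mean(e) + digamma(d0 / 2) - log(d0 / 2))
  } else {
    d0 <- cap
    s0sq <- exp(mean(z))
  }
  structure(list(d0 = d0, s0sq = s0sq), class = "ebayes_prior")
}

#' @export
print.ebayes_prior <- function(x, ...) {
  cat("Empirical-Bayes variance prior: d0 =", format(x$d0),
      ", s0^2 =", format(x$s0sq), "\n")
  invisible(x)
}

#' Moderated t-statistics, p-values and BH false discovery rates
#'
#' Shrinks each gene's residual variance toward the prior,
#' \code{s2_post = (d0 s0sq + df s2) / (d0 + df)}, forms the moderated
#' statistic \code{t = beta / sqrt(s2_post v)} on \code{df + d0} degrees
#' of freedom, and adjusts two-sided p-values by the Benjamini-Hochberg
#' step-up. Significance is strict (\code{fdr < alpha}) with no fold-change
#' cutoff; direction is the sign of the effect.
#'
#' With \code{d0 = 0} (moderation forced off) the statistic is the ordinary
#' two-sample t; genes with zero residual variance then get \code{p = 0}
#' and are flagged in the \code{zero_var} column.
#'
#' @param fit output of \code{\link{fit_gene_models}}.
#' @param prior an \code{ebayes_prior} (or list with \code{d0}, \code{s0sq};
#'   \code{d0 = 0} disables moderation).
#' @param alpha FDR significance cutoff.
#' @return \code{data.frame} (class \code{gene_stats}) with columns
#'   \code{gene_id, beta, s2, df, v, t_mod, p, fdr, direction, zero_var}.
#' @export
moderated_stats <- function(fit, prior, alpha = 0.05) {
  d0 <- prior$d0
  s0sq <- prior$s0sq
  stopifnot(d0 >= 0, is.finite(d0))
  s2_post <- if (d0 > 0) (d0 * s0sq + fit$df * fit$s2) / (d0 + fit$df)
             else fit$s2
  se <- sqrt(s2_post * fit$v)
  t_mod <- ifelse(se > 0, fit$beta / se,
                  sign(fit$beta) * Inf)
  t_mod[se == 0 & fit$beta == 0] <- 0
  zero_var <- se == 0
  if (any(zero_var & fit$beta != 0))
    warning("moderated_stats: ", sum(zero_var & fit$beta != 0),
            " gene(s) with zero residual variance and nonzero effect; ",
            "p set to 0 (see zero_var column)")
  p <- 2 * stats::pt(-abs(t_mod), df = fit$df + d0)
  p[zero_var & fit$beta != 0] <- 0
  p[zero_var & fit$beta == 0] <- 1
  fdr <- stats::p.adjust(p, method = "BH")
  direction <- rep("ns", length(p))
  direction[fdr < alpha & fit$beta > 0] <- "up"
  direction[fdr < alpha & fit$beta < 0] <- "down"
  out <- data.frame(gene_id = fit$genes, beta = fit$beta, s2 = fit$s2,
                    df = fit$df, v = fit$v, t_mod = t_mod, p = p,
                    fdr = fdr, direction = direction, zero_var = zero_var,
                    row.names = NULL, stringsAsFactors = FALSE)
  class(out) <- c("gene_stats", "data.frame")
  attr(out, "alpha") <- alpha
  attr(out, "prior") <- list(d0 = d0, s0sq = s0sq)
  out
}

#' Full differential-expression analysis of one study
#'
#' Convenience wrapper: per-gene fits, prior estimation, moderated
#' statistics.
#'
#' @inheritParams fit_gene_models
#' @inheritParams moderated_stats
#' @return a \code{gene_stats} data frame (see \code{\link{moderated_stats}}).
#' @export
run_de <- function(study, alpha = 0.05) {
  fit <- fit_gene_models(study)
  prior <- estimate_eb_prior(fit$s2, fit$df)
  moderated_stats(fit, prior, alpha = alpha)
}
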