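#' Parametric per-sample gene-set activation scores
#'
#' Each gene is first converted to a per-sample log-ratio by subtracting
#' a per-gene reference level within the study. For a set with m present
#' members, the score of sample j is the one-sample t-statistic of the
#' member ratios against zero: \code{mean(r) * sqrt(m) / sd(r)}, with the
#' standard deviation floored at \code{sd_floor} so degenerate samples
#' stay finite. This is the parametric (PGSEA-style) alternative to
#' rank/permutation enrichment: the set-by-sample score matrix is then
#' analysed exactly like an expression matrix.
#'
#' The default reference is the grand mean over all samples, which makes
#' the downstream two-group contrast of scores first-order invariant to
#' the centering and keeps its null distribution calibrated. With
#' \code{reference = "wt"} ratios are taken against the wild-type group
#' mean instead; scores are then directly interpretable as activation
#' relative to wild type, but the asymmetric centering makes the
#' second-stage test measurably conservative under the null (see the
#' methods vignette).
#'
#' @param study an \code{\link{expression_study}}.
#' @param coll a filtered \code{\link{gene_set_collection}} (all members
#'   must be present in the study; use \code{\link{build_collection}}).
#' @param reference per-gene reference level for the log-ratios:
#'   \code{"all"} (grand mean, default) or \code{"wt"} (WT group mean).
#' @param sd_floor lower bound on the within-set ratio standard deviation.
#' @return object of class \code{set_score_matrix}: list with \code{score}
#'   (set x sample matrix), \code{member_counts}, \code{group},
#'   \code{model_label}.
#' @export
pgsea_scores <- function(study, coll, reference = c("all", "wt"),
                         sd_floor = 1e-8) {
  stopifnot(inherits(study, "expression_study"),
            inherits(coll, "gene_set_collection"))
  reference <- match.arg(reference)
  miss <- setdiff(unique(unlist(coll$sets)), study$genes)
  if (length(miss))
    stop("pgsea_scores: collection has members absent from the study; ",
         "filter with build_collection() first")
  if (any(lengths(coll$sets) < 2L))
    stop("pgsea_scores: internal error: set with < 2 members reached scoring")
  ref_cols <- if (reference == "wt") study$group == "WT"
              else rep(TRUE, ncol(study$matrix))
  ratios <- study$matrix -
    rowMeans(study$matrix[, ref_cols, drop = FALSE])
  score <- matrix(NA_real_, nrow = length(coll$sets),
                  ncol = ncol(ratios),
                  dimnames = list(names(coll$sets), colnames(ratios)))
  for (i in seq_along(coll$sets)) {
    r <- ratios[coll$sets[[i]], , drop = FALSE]
    m <- nrow(r)
    mu <- colMeans(r)
    sdev <- pmax(apply(r, 2L, stats::sd), sd_floor)
    sc <- mu * sqrt(m) / sdev
    sc[mu == 0] <- 0
    score[i, ] <- sc
  }
  structure(list(score = score, member_counts = lengths(coll$sets),
                 group = study$group, model_label = study$model_label),
            class = "set_score_matrix")
}

#' @export
print.set_score_matrix <- function(x, ...) {
  cat("Set score matrix: ", nrow(x$score), " sets x ", ncol(x$score),
      " samples ('", x$model_label, "')\n", sep = "")
  invisible(x)
}

#' Per-model gene-set enrichment inference
#'
#' Applies the same machinery as for individual genes to the set-by-sample
#' score matrix: two-group fits of the KO-vs-WT contrast, empirical-Bayes
#' moderation, BH adjustment. The estimate column is the KO-WT contrast of
#' set scores, reported as the pathway-level fold change.
#'
#' @param scores a \code{set_score_matrix}.
#' @param alpha FDR cutoff for calling a set positively/negatively
#'   enriched.
#' @return \code{data.frame} (class \code{set_stats}) with columns
#'   \code{set, est, t_mod, p, fdr, direction, m}; \code{direction} is
#'   \code{pos}, \code{neg} or \code{ns}.
#' @export
set_inference <- function(scores, alpha = 0.05) {
  stopifnot(inherits(scores, "set_score_matrix"))
  pseudo <- expression_study(scores$score, scores$group,
                             model_label = scores$model_label)
  fit <- fit_gene_models(pseudo)
  prior <- estimate_eb_prior(fit$s2, fit$df)
  gs <- moderated_stats(fit, prior, alpha = alpha)
  direction <- c(up = "pos", down = "neg", ns = "ns")[gs$direction]
  out <- data.frame(set = gs$gene_id, est = gs$beta, t_mod = gs$t_mod,
                    p = gs$p, fdr = gs$fdr,
                    direction = unname(direction),
                    m = unname(scores$member_counts[gs$gene_id]),
                    row.names = NULL, stringsAsFactors = FALSE)
  class(out) <- c("set_stats", "data.frame")
  attr(out, "alpha") <- alpha
  attr(out, "model_label") <- scores$model_label
  out
}
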