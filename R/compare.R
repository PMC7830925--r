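#' Partition per-model results by direction of change
#'
#' @param results named list of per-model \code{gene_stats} or
#'   \code{set_stats} tables (all computed at the same alpha).
#' @return object of class \code{direction_partition}: per model, the
#'   identifier sets \code{up} and \code{down} (positive/negative
#'   enrichment maps onto up/down).
#' @export
partition_by_direction <- function(results) {
  stopifnot(is.list(results), length(results) >= 1L,
            !is.null(names(results)))
  part <- lapply(results, function(r) {
    id <- if ("gene_id" %in% names(r)) r$gene_id else r$set
    dir <- r$direction
    list(up = id[dir %in% c("up", "pos")],
         down = id[dir %in% c("down", "neg")])
  })
  structure(part, class = "direction_partition")
}

#' @export
print.direction_partition <- function(x, ...) {
  counts <- t(vapply(x, function(p) c(up = length(p$up),
                                      down = length(p$down)),
                     numeric(2)))
  print(counts)
  invisible(x)
}

#' Exact Venn region counts across models
#'
#' Tabulates, for one direction, how many identifiers fall in each of the
#' 2^M - 1 non-empty model subsets (exclusive regions). Tabular output
#' only; with more than 6 models the region table explodes and the call is
#' refused.
#'
#' @param partition a \code{direction_partition}.
#' @param direction \code{"up"} or \code{"down"}.
#' @return \code{data.frame} with columns \code{region} (model names
#'   joined by \code{&}), \code{n_models}, \code{count}, \code{members}.
#' @export
venn_counts <- function(partition, direction = c("up", "down")) {
  direction <- match.arg(direction)
  stopifnot(inherits(partition, "direction_partition"))
  M <- length(partition)
  if (M < 2L) stop("venn_counts: need >= 2 models")
  if (M > 6L) stop("venn_counts: refusing > 6 models (2^M regions)")
  models <- names(partition)
  sets <- lapply(partition, `[[`, direction)
  ids <- unique(unlist(sets, use.names = FALSE))
  membership <- vapply(sets, function(s) ids %in% s,
                       logical(length(ids)))
  if (length(ids) == 1L) membership <- matrix(membership, nrow = 1L)
  masks <- seq_len(2^M - 1L)
  region_of <- if (length(ids))
    as.integer(membership %*% 2^(seq_len(M) - 1L)) else integer(0)
  out <- data.frame(
    region = vapply(masks, function(b)
      paste(models[bitwAnd(b, 2^(seq_len(M) - 1L)) > 0], collapse = "&"),
      ""),
    n_models = vapply(masks, function(b)
      sum(bitwAnd(b, 2^(seq_len(M) - 1L)) > 0), 0),
    count = vapply(masks, function(b) sum(region_of == b), 0),
    members = vapply(masks, function(b)
      paste(sort(ids[region_of == b]), collapse = ","), ""),
    stringsAsFactors = FALSE)
  attr(out, "direction") <- direction
  attr(out, "totals") <- lengths(sets)
  out
}

#' Asymmetric cross-model similarity-ratio matrices
#'
#' For every ordered model pair (a, b) the similarity is the fraction of
#' model a's significant changes that are shared with model b:
#' \code{pos[a, b] = |up_a intersect up_b| / |up_a|}, and analogously for
#' \code{neg} with the down sets. Ratios are normalized row-wise by the
#' row model's own count, so the matrices are generally non-symmetric. A
#' model with no changes in a direction yields a zero row (flagged in
#' \code{empty_rows}) rather than NaN; the diagonal is 1 exactly when the
#' model's own set is non-empty.
#'
#' @param partition a \code{direction_partition}.
#' @return list of class \code{similarity_matrix_pair}: \code{pos},
#'   \code{neg} (model x model), \code{counts} (per-model up/down totals),
#'   \code{empty_rows} (per-direction logical).
#' @export
similarity_matrices <- function(partition) {
  stopifnot(inherits(partition, "direction_partition"))
  models <- names(partition)
  one <- function(direction) {
    sets <- lapply(partition, `[[`, direction)
    M <- length(sets)
    mat <- matrix(0, M, M, dimnames = list(models, models))
    for (a in seq_len(M)) {
      if (length(sets[[a]]) == 0L) next
      for (b in seq_len(M))
        mat[a, b] <- length(intersect(sets[[a]], sets[[b]])) /
          length(sets[[a]])
    }
    mat
  }
  pos <- one("up"); neg <- one("down")
  counts <- cbind(up = lengths(lapply(partition, `[[`, "up")),
                  down = lengths(lapply(partition, `[[`, "down")))
  structure(list(pos = pos, neg = neg, counts = counts,
                 empty_rows = list(pos = counts[, "up"] == 0L,
                                   neg = counts[, "down"] == 0L)),
            class = "similarity_matrix_pair")
}

#' @export
print.similarity_matrix_pair <- function(x, digits = 2, ...) {
  cat("Positive-change similarity (row-normalized):\n")
  print(round(x$pos, digits))
  cat("Negative-change similarity (row-normalized):\n")
  print(round(x$neg, digits))
  invisible(x)
}

#' Per-sample scaling and hierarchical clustering of a gene subset
#'
#' Restricts the expression matrix to a gene subset, scales each sample
#' (column) to mean zero and unit standard deviation within the subset,
#' and clusters both genes and samples agglomeratively (Euclidean
#' distance, average linkage). Rows and columns are ordered
#' lexicographically before clustering so leaf order is deterministic:
#' ties in merge height are resolved by label order.
#'
#' @param matrix gene x sample numeric matrix (log2 scale).
#' @param genes_subset identifiers to retain (e.g. the common program).
#' @return list with \code{scaled} (subset matrix, column-standardized),
#'   \code{gene_hclust}, \code{sample_hclust} (objects of class
#'   \code{hclust}).
#' @export
scale_and_cluster <- function(matrix, genes_subset) {
  genes_subset <- intersect(genes_subset, rownames(matrix))
  if (length(genes_subset) == 0L)
    stop("scale_and_cluster: empty gene subset")
  sub <- matrix[sort(genes_subset), sort(colnames(matrix)), drop = FALSE]
  mu <- colMeans(sub)
  sdev <- apply(sub, 2L, stats::sd)
  if (any(sdev == 0)) {
    warning("scale_and_cluster: ", sum(sdev == 0),
            " constant sample column(s) left centered, not scaled")
    sdev[sdev == 0] <- 1
  }
  scaled <- sweep(sweep(sub, 2L, mu), 2L, sdev, `/`)
  gene_h <- if (nrow(scaled) >= 2L)
    stats::hclust(stats::dist(scaled), method = "average") else NULL
  sample_h <- if (ncol(scaled) >= 2L)
    stats::hclust(stats::dist(t(scaled)), method = "average") else NULL
  list(scaled = scaled, gene_hclust = gene_h, sample_hclust = sample_h)
}

#' Direction agreement against an external enrichment reference
#'
#' Compares a model's gene-set calls against a published
#' direction-of-enrichment table (e.g. human NAFLD/NASH signs): per set,
#' the model estimate and direction, the reference sign (\code{+},
#' \code{-} or \code{ns}), and a concordance flag. Reference \code{ns}
#' entries are excluded from the concordance denominator; sets absent
#' from the model results are reported as missing.
#'
#' @param set_stats a \code{set_stats} table for one model.
#' @param reference \code{data.frame} with columns \code{set} and
#'   \code{sign} (values \code{+}, \code{-}, \code{ns}), e.g. from
#'   \code{\link{read_reference_signs}}.
#' @return list with \code{table} (per-set comparison) and \code{summary}
#'   (counts of concordant / discordant / reference-ns / missing).
#' @export
reference_sign_overlap <- function(set_stats, reference) {
  stopifnot(inherits(set_stats, "set_stats"),
            all(c("set", "sign") %in% names(reference)))
  bad <- setdiff(unique(reference$sign), c("+", "-", "ns"))
  if (length(bad))
    stop("reference_sign_overlap: unknown reference sign(s): ",
         paste(bad, collapse = ", "))
  idx <- match(reference$set, set_stats$set)
  model_dir <- ifelse(is.na(idx), "missing", set_stats$direction[idx])
  concordance <- rep(NA_character_, nrow(reference))
  eligible <- reference$sign != "ns" & model_dir != "missing"
  agree <- (reference$sign == "+" & model_dir == "pos") |
    (reference$sign == "-" & model_dir == "neg")
  concordance[eligible] <- ifelse(agree[eligible], "concordant",
                                  "discordant")
  concordance[reference$sign == "ns"] <- "reference_ns"
  concordance[model_dir == "missing"] <- "missing"
  tab <- data.frame(set = reference$set,
                    est = set_stats$est[idx],
                    model_direction = model_dir,
                    reference_sign = reference$sign,
                    concordance = concordance,
                    stringsAsFactors = FALSE)
  summary <- c(concordant = sum(concordance == "concordant", na.rm = TRUE),
               discordant = sum(concordance == "discordant", na.rm = TRUE),
               reference_ns = sum(concordance == "reference_ns"),
               missing = sum(concordance == "missing"))
  list(table = tab, summary = summary)
}

#' Read an external enrichment-direction reference table
#'
#' TSV with columns \code{set} and \code{sign} (\code{+}, \code{-},
#' \code{ns}).
#'
#' @param path file path.
#' @return data.frame.
#' @export
read_reference_signs <- function(path) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE,
                           comment.char = "#")
  if (!all(c("set", "sign") %in% names(tab)))
    stop("read_reference_signs: need columns 'set' and 'sign'")
  tab
}
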