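#' Construct a gene-set collection
#'
#' @param sets named list of character vectors of gene identifiers.
#' @param provenance either a single source label or a per-set character
#'   vector; one of \code{kegg, reactome, tf, custom}.
#' @return object of class \code{gene_set_collection}.
#' @export
gene_set_collection <- function(sets, provenance = "custom") {
  if (!is.list(sets) || length(sets) == 0L)
    stop("gene_set_collection: 'sets' must be a non-empty named list")
  if (is.null(names(sets)) || anyDuplicated(names(sets)) ||
      any(!nzchar(names(sets))))
    stop("gene_set_collection: set names must be present and unique")
  sets <- lapply(sets, function(g) unique(as.character(g)))
  if (any(lengths(sets) < 1L))
    stop("gene_set_collection: empty gene set not allowed")
  provenance <- rep_len(as.character(provenance), length(sets))
  bad <- setdiff(unique(provenance), c("kegg", "reactome", "tf", "custom"))
  if (length(bad))
    stop("gene_set_collection: unknown provenance: ",
         paste(bad, collapse = ", "))
  structure(list(sets = sets,
                 provenance = stats::setNames(provenance, names(sets))),
            class = "gene_set_collection")
}

#' @export
print.gene_set_collection <- function(x, ...) {
  cat("Gene-set collection:", length(x$sets), "sets, sizes",
      min(lengths(x$sets)), "-", max(lengths(x$sets)), "\n")
  print(table(x$provenance))
  invisible(x)
}

#' Read / write gene sets in GMT format
#'
#' Standard tab-separated GMT: set name, description, then members.
#'
#' @param path file path.
#' @param provenance source label attached to all sets read.
#' @return \code{read_gmt}: a \code{gene_set_collection}.
#' @export
read_gmt <- function(path, provenance = "custom") {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  fields <- strsplit(lines, "\t", fixed = TRUE)
  sets <- lapply(fields, function(f) f[-(1:2)])
  names(sets) <- vapply(fields, `[`, "", 1L)
  gene_set_collection(sets, provenance = provenance)
}

#' @param coll a \code{gene_set_collection}.
#' @rdname read_gmt
#' @export
write_gmt <- function(coll, path) {
  stopifnot(inherits(coll, "gene_set_collection"))
  lines <- vapply(names(coll$sets), function(nm) {
    paste(c(nm, unname(coll$provenance[nm]), coll$sets[[nm]]),
          collapse = "\t")
  }, "")
  writeLines(lines, path)
  invisible(path)
}

#' Read a transcription-factor target table
#'
#' TSV with columns \code{factor_id}, \code{factor_name},
#' \code{target_gene}; one row per (factor record, target). Records are
#' kept separate here (one raw set per \code{factor_id}); merging of
#' records that share a factor identifier irrespective of binding site is
#' done by \code{\link{build_collection}} for \code{tf} provenance.
#'
#' @param path file path.
#' @return a \code{gene_set_collection} with provenance \code{tf}.
#' @export
read_tf_table <- function(path) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("factor_id", "target_gene")
  if (!all(need %in% names(tab)))
    stop("read_tf_table: need columns ", paste(need, collapse = ", "))
  sets <- split(tab$target_gene, tab$factor_id)
  gene_set_collection(sets, provenance = "tf")
}

#' Filter a raw collection against the expressed genes
#'
#' For \code{tf} provenance, records sharing a factor identifier (the part
#' of the set name before any \code{"|"} separator, i.e. irrespective of
#' binding site) are first merged to the union of their targets. Members
#' absent from \code{expressed_genes} are removed (counts recorded in the
#' \code{n_removed} attribute), and sets with fewer than \code{min_size}
#' remaining members are dropped.
#'
#' @param raw a \code{gene_set_collection} (e.g. from \code{\link{read_gmt}}
#'   or \code{\link{simulate_gene_sets}}).
#' @param expressed_genes identifiers present in the expression matrix.
#' @param min_size minimum number of present members (default 5).
#' @return a filtered \code{gene_set_collection}; errors if no set
#'   survives filtering.
#' @export
build_collection <- function(raw, expressed_genes, min_size = 5L) {
  stopifnot(inherits(raw, "gene_set_collection"), min_size >= 2L)
  sets <- raw$sets
  prov <- raw$provenance
  is_tf <- prov == "tf"
  if (any(is_tf)) {
    tf_sets <- sets[is_tf]
    factor_id <- sub("\\|.*$", "", names(tf_sets))
    merged <- lapply(split(tf_sets, factor_id),
                     function(x) unique(unlist(x, use.names = FALSE)))
    sets <- c(sets[!is_tf], merged)
    prov <- c(prov[!is_tf],
              stats::setNames(rep("tf", length(merged)), names(merged)))
  }
  filtered <- lapply(sets, intersect, y = expressed_genes)
  n_removed <- lengths(sets) - lengths(filtered)
  keep <- lengths(filtered) >= min_size
  if (!any(keep))
    stop("build_collection: no gene set has >= ", min_size,
         " members among the expressed genes")
  out <- gene_set_collection(filtered[keep], provenance = prov[keep])
  attr(out, "n_removed") <- n_removed[keep]
  attr(out, "min_size") <- min_size
  out
}
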