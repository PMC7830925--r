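# Plain-text I/O: expression TSV (first column gene_id), sample sheets,
# result tables with '#'-prefixed metadata header lines.

tsv_header <- function(meta) {
  if (length(meta) == 0L) return(character(0))
  paste0("# ", names(meta), ": ", unlist(meta))
}

write_tsv_with_meta <- function(df, path, meta = list()) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(tsv_header(meta), con)
  utils::write.table(df, con, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Write / read an expression study as TSV
#'
#' The expression file has a \code{gene_id} first column and one column
#' per sample; the sample sheet has columns \code{sample_id, model,
#' genotype} (WT/KO) and optional \code{sex}.
#'
#' @param study an \code{\link{expression_study}}.
#' @param expr_path,sheet_path output paths.
#' @return \code{read_expression_tsv}: an \code{expression_study}.
#' @export
write_expression_tsv <- function(study, expr_path, sheet_path) {
  stopifnot(inherits(study, "expression_study"))
  df <- data.frame(gene_id = study$genes, study$matrix,
                   check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(df, expr_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  sheet <- data.frame(sample_id = study$samples,
                      model = study$model_label,
                      genotype = as.character(study$group),
                      stringsAsFactors = FALSE)
  if (!is.null(study$sex)) sheet$sex <- study$sex
  utils::write.table(sheet, sheet_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(expr_path)
}

#' @rdname write_expression_tsv
#' @export
read_expression_tsv <- function(expr_path, sheet_path) {
  df <- utils::read.delim(expr_path, check.names = FALSE,
                          stringsAsFactors = FALSE)
  if (names(df)[1] != "gene_id")
    stop("read_expression_tsv: first column must be 'gene_id'")
  mat <- as.matrix(df[, -1, drop = FALSE])
  rownames(mat) <- df$gene_id
  sheet <- utils::read.delim(sheet_path, stringsAsFactors = FALSE)
  need <- c("sample_id", "model", "genotype")
  if (!all(need %in% names(sheet)))
    stop("read_expression_tsv: sample sheet needs columns ",
         paste(need, collapse = ", "))
  idx <- match(colnames(mat), sheet$sample_id)
  if (anyNA(idx))
    stop("read_expression_tsv: samples missing from sheet: ",
         paste(colnames(mat)[is.na(idx)], collapse = ", "))
  expression_study(mat, group = sheet$genotype[idx],
                   model_label = sheet$model[1],
                   sex = if ("sex" %in% names(sheet)) sheet$sex[idx])
}

write_truth_json <- function(truth, path) {
  stopifnot(inherits(truth, "ground_truth"))
  jsonlite::write_json(unclass(truth), path, auto_unbox = TRUE,
                       pretty = TRUE)
  invisible(path)
}

read_truth_json <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  raw$planted_sets <- unlist(raw$planted_sets)
  raw$subsystem <- unlist(raw$subsystem)
  structure(raw, class = "ground_truth")
}
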