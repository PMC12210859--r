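#' Read a taxonomy map
#'
#' TSV with columns `taxon_id`, `kingdom` (`bacteria` or `fungi`), `lineage`
#' (semicolon-delimited seven-rank string, `k__;p__;c__;o__;f__;g__;s__`
#' prefixes optional, empty ranks allowed) and `oral` (0/1; oral-cavity
#' catalogue membership, bacteria only).
#'
#' @param path TSV path.
#' @return a `data.frame` with columns `taxon_id`, `kingdom`, `lineage`,
#'   `oral` (logical).
#' @export
read_taxonomy <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  need <- c("taxon_id", "kingdom", "lineage", "oral")
  miss <- setdiff(need, names(df))
  if (length(miss)) stopf("taxonomy file lacks column(s): %s", paste(miss, collapse = ", "))
  validate_taxonomy(data.frame(taxon_id = as.character(df$taxon_id),
                               kingdom = as.character(df$kingdom),
                               lineage = as.character(df$lineage),
                               oral = as.logical(as.integer(df$oral)),
                               stringsAsFactors = FALSE))
}

validate_taxonomy <- function(tax) {
  if (anyDuplicated(tax$taxon_id)) stopf("duplicate taxon_id in taxonomy")
  bad <- !tax$kingdom %in% c("bacteria", "fungi")
  if (any(bad)) stopf("unknown kingdom value(s): %s", paste(unique(tax$kingdom[bad]), collapse = ", "))
  if (any(tax$oral & tax$kingdom != "bacteria"))
    stopf("oral flag may be TRUE only for bacteria")
  tax
}

#' @rdname read_taxonomy
#' @param tax taxonomy `data.frame`.
#' @export
write_taxonomy <- function(tax, path) {
  out <- tax
  out$oral <- as.integer(out$oral)
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read sample metadata
#'
#' TSV with columns `sample_id`, `group` and arbitrary covariate columns.
#' Group labels are validated against `groups` and returned as an ordered
#' factor in that order (the disease-stage ordering HC, ESINA, ESIN, ESCCA,
#' ESCC by default).
#'
#' @param path TSV path.
#' @param groups declared ordered set of group labels.
#' @return `data.frame` with `sample_id`, `group` (factor) and covariates.
#' @export
read_metadata <- function(path, groups = stage_groups()) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  if (!all(c("sample_id", "group") %in% names(df)))
    stopf("metadata needs 'sample_id' and 'group' columns")
  if (anyDuplicated(df$sample_id)) stopf("duplicate sample_id in metadata")
  bad <- setdiff(unique(df$group), groups)
  if (length(bad)) stopf("group label(s) outside the declared set: %s", paste(bad, collapse = ", "))
  df$group <- factor(df$group, levels = groups)
  df
}

#' @rdname read_metadata
#' @param meta metadata `data.frame`.
#' @export
write_metadata <- function(meta, path) {
  utils::write.table(meta, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Disease-stage group labels
#'
#' The five esophageal sampling groups in stage order: healthy controls (HC),
#' tissue adjacent to squamous intraepithelial neoplasia (ESINA), the
#' neoplasia itself (ESIN), tissue adjacent to squamous cell carcinoma
#' (ESCCA), and the carcinoma (ESCC).
#'
#' @return character vector of the five labels.
#' @export
stage_groups <- function() c("HC", "ESINA", "ESIN", "ESCCA", "ESCC")

#' Named group-label vector from metadata
#'
#' Convenience accessor: group labels named by sample id, optionally
#' restricted to (and ordered by) a set of sample ids.
#'
#' @param meta metadata `data.frame`.
#' @param ids optional sample ids to select, in order.
#' @return named character vector.
#' @export
group_vector <- function(meta, ids = NULL) {
  g <- stats::setNames(as.character(meta$group), meta$sample_id)
  if (!is.null(ids)) {
    if (anyNA(g[ids])) stopf("samples missing from metadata: %s",
                             paste(ids[is.na(g[ids])], collapse = ", "))
    g <- g[ids]
  }
  g
}
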