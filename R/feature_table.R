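#' Feature table of taxa by samples
#'
#' Container for an amplicon feature table (ASVs or collapsed ranks, rows) by
#' samples (columns). Counts are non-negative; a table may instead hold
#' relative abundances, in which case every sample column sums to one.
#'
#' @param counts numeric matrix, taxa as rows, samples as columns. Row and
#'   column names are the taxon and sample identifiers and must be unique.
#' @param relative logical; `TRUE` if the matrix holds per-sample proportions.
#' @return an object of class `feature_table`.
#' @examples
#' m <- matrix(c(5, 1, 0, 3), 2, 2,
#'             dimnames = list(c("ASV1", "ASV2"), c("S1", "S2")))
#' ft <- feature_table(m)
#' sample_depths(ft)
#' @export
feature_table <- function(counts, relative = FALSE) {
  counts <- as.matrix(counts)
  if (!is.numeric(counts)) stopf("feature table body must be numeric")
  if (is.null(rownames(counts)) || is.null(colnames(counts)))
    stopf("feature table needs taxon row names and sample column names")
  if (anyDuplicated(rownames(counts)))
    stopf("duplicate taxon identifiers: %s",
          paste(unique(rownames(counts)[duplicated(rownames(counts))]), collapse = ", "))
  if (anyDuplicated(colnames(counts)))
    stopf("duplicate sample identifiers: %s",
          paste(unique(colnames(counts)[duplicated(colnames(counts))]), collapse = ", "))
  if (anyNA(counts) || any(counts < 0))
    stopf("feature table contains negative or missing values")
  if (relative) {
    cs <- colSums(counts)
    if (any(abs(cs - 1) > 1e-9))
      stopf("relative table columns must each sum to 1 (worst deviation %.3g)",
            max(abs(cs - 1)))
  }
  structure(list(counts = counts, is_relative = isTRUE(relative)),
            class = "feature_table")
}

#' @export
print.feature_table <- function(x, ...) {
  cat(sprintf("<feature_table> %d taxa x %d samples (%s)\n",
              nrow(x$counts), ncol(x$counts),
              if (x$is_relative) "relative abundances" else "counts"))
  invisible(x)
}

#' @export
dim.feature_table <- function(x) dim(x$counts)

#' @rdname feature_table
#' @param x a `feature_table`.
#' @export
taxon_ids <- function(x) rownames(x$counts)

#' @rdname feature_table
#' @export
sample_ids <- function(x) colnames(x$counts)

#' @rdname feature_table
#' @export
sample_depths <- function(x) colSums(x$counts)

#' Read a feature table from TSV
#'
#' Parses a tab-separated table with one header row of identifiers and one
#' identifier column. The default orientation is taxa as rows; files written
#' samples-as-rows must say so explicitly — guessing the orientation of an
#' ambiguous table is a classic source of silent errors.
#'
#' @param path path to a TSV file.
#' @param orientation `"taxa_rows"` (default) or `"samples_rows"`.
#' @param relative logical; declare the body as relative abundances.
#' @return a [feature_table()].
#' @export
read_feature_table <- function(path, orientation = c("taxa_rows", "samples_rows"),
                               relative = FALSE) {
  orientation <- match.arg(orientation)
  df <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (ncol(df) < 2) stopf("'%s': need an identifier column plus at least one data column", path)
  ids <- as.character(df[[1]])
  body <- df[, -1, drop = FALSE]
  bad <- !vapply(body, is.numeric, logical(1))
  if (any(bad))
    stopf("'%s': non-numeric data column(s): %s", path,
          paste(names(body)[bad], collapse = ", "))
  m <- as.matrix(body)
  rownames(m) <- ids
  if (orientation == "samples_rows") m <- t(m)
  feature_table(m, relative = relative)
}

#' Write a feature table to TSV
#'
#' Taxa as rows, samples as header columns; round-trips exactly through
#' [read_feature_table()].
#'
#' @param x a `feature_table`.
#' @param path output path.
#' @export
write_feature_table <- function(x, path) {
  df <- data.frame(taxon_id = taxon_ids(x), x$counts,
                   check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Filter low-evidence features
#'
#' Retains taxa whose total reads reach `min_total_reads` and that are present
#' (at least one read) in at least `min_samples` samples. Defaults are the
#' conventional amplicon thresholds of 10 reads and 2 samples. Samples are
#' never dropped here.
#'
#' @param x a counts `feature_table`.
#' @param min_total_reads minimum summed reads per taxon.
#' @param min_samples minimum number of samples with >= 1 read.
#' @return the filtered `feature_table`.
#' @export
filter_features <- function(x, min_total_reads = 10, min_samples = 2) {
  if (x$is_relative) stopf("filter_features expects counts, not relative abundances")
  keep <- rowSums(x$counts) >= min_total_reads &
    rowSums(x$counts >= 1) >= min_samples
  feature_table(x$counts[keep, , drop = FALSE])
}

#' Filter samples by sequencing depth
#'
#' Drops samples whose column sum falls below `min_depth` (inclusive
#' retention at the threshold). Depth cut-offs in this package default to
#' 14000 reads for bacterial 16S tables and 19500 for fungal ITS tables;
#' pass the one that applies. Taxon rows are untouched — rows that become
#' all-zero stay, so that taxon pruning remains a separate, auditable step.
#'
#' @param x a counts `feature_table`.
#' @param min_depth minimum retained column sum.
#' @return the filtered `feature_table`.
#' @export
filter_samples_by_depth <- function(x, min_depth) {
  if (x$is_relative) stopf("depth filtering applies to counts tables")
  keep <- colSums(x$counts) >= min_depth
  if (!any(keep))
    stopf("all %d samples fall below the depth threshold %s",
          ncol(x$counts), format(min_depth, big.mark = ","))
  feature_table(x$counts[, keep, drop = FALSE])
}

#' Convert counts to relative abundances
#'
#' @param x a `feature_table`; already-relative tables pass through unchanged.
#' @return a relative `feature_table` (each column sums to 1).
#' @export
to_relative <- function(x) {
  if (x$is_relative) return(x)
  cs <- colSums(x$counts)
  if (any(cs <= 0))
    stopf("zero-depth sample(s): %s", paste(sample_ids(x)[cs <= 0], collapse = ", "))
  feature_table(sweep(x$counts, 2, cs, "/"), relative = TRUE)
}

#' Collapse a feature table to a taxonomic rank
#'
#' Sums rows sharing the same lineage prefix up to `rank`. Taxa whose lineage
#' is empty at that rank are pooled under `unclassified_<parent>`, where
#' parent is the deepest named ancestor; per-sample totals are conserved.
#'
#' @param x a `feature_table` (counts or relative).
#' @param taxonomy a taxonomy table from [read_taxonomy()] covering every taxon.
#' @param rank one of `"domain"`, `"phylum"`, `"class"`, `"order"`,
#'   `"family"`, `"genus"`, `"species"`.
#' @return a `feature_table` with one row per collapsed label.
#' @export
collapse_rank <- function(x, taxonomy, rank) {
  ranks <- tax_ranks()
  if (!rank %in% ranks) stopf("unknown rank '%s'", rank)
  miss <- setdiff(taxon_ids(x), taxonomy$taxon_id)
  if (length(miss))
    stopf("taxa missing from taxonomy: %s%s", paste(utils::head(miss, 5), collapse = ", "),
          if (length(miss) > 5) ", ..." else "")
  lin <- lineage_matrix(taxonomy)[taxon_ids(x), , drop = FALSE]
  depth <- match(rank, ranks)
  labels <- vapply(seq_len(nrow(lin)), function(i) {
    v <- lin[i, seq_len(depth)]
    if (nzchar(v[depth])) return(v[depth])
    named <- which(nzchar(v))
    parent <- if (length(named)) v[max(named)] else "root"
    paste0("unclassified_", parent)
  }, character(1))
  agg <- rowsum(x$counts, group = labels, reorder = TRUE)
  feature_table(agg, relative = x$is_relative)
}

#' Per-sample oral-microbiome fraction
#'
#' Fraction of each sample's bacterial abundance carried by taxa flagged as
#' oral-cavity residents (catalogue membership supplied in the taxonomy).
#' The per-group summary is the mean of per-sample fractions by default;
#' `pooled = TRUE` instead pools reads within a group before dividing.
#'
#' @param x a bacterial `feature_table` (counts or relative).
#' @param taxonomy taxonomy table with an `oral` flag.
#' @param groups optional named group vector (names = sample ids); when given,
#'   a per-group summary is attached as attribute `"group_summary"`.
#' @param pooled logical; pool reads within group instead of averaging
#'   per-sample fractions.
#' @return named numeric vector of per-sample fractions in \[0, 1\].
#' @export
oral_fraction <- function(x, taxonomy, groups = NULL, pooled = FALSE) {
  tt <- taxonomy[match(taxon_ids(x), taxonomy$taxon_id), ]
  if (anyNA(tt$taxon_id)) stopf("taxa missing from taxonomy")
  if (!any(tt$kingdom == "bacteria"))
    stopf("oral fraction is defined for bacterial tables only")
  oral <- tt$oral %in% TRUE
  tot <- colSums(x$counts)
  if (any(tot <= 0)) stopf("zero-total sample(s) have no defined fraction")
  frac <- colSums(x$counts[oral, , drop = FALSE]) / tot
  if (!is.null(groups)) {
    g <- groups[sample_ids(x)]
    attr(frac, "group_summary") <- if (pooled) {
      oral_reads <- tapply(colSums(x$counts[oral, , drop = FALSE]), g, sum)
      all_reads <- tapply(tot, g, sum)
      oral_reads / all_reads
    } else tapply(frac, g, mean)
  }
  frac
}

tax_ranks <- function() c("domain", "phylum", "class", "order", "family",
                          "genus", "species")

# lineage strings -> character matrix taxon x 7 ranks, prefixes stripped
lineage_matrix <- function(taxonomy) {
  parts <- strsplit(taxonomy$lineage, ";", fixed = TRUE)
  m <- t(vapply(parts, function(p) {
    p <- trimws(p)
    p <- sub("^[kdpcofgs]__", "", p)
    length(p) <- 7L
    p[is.na(p)] <- ""
    p
  }, character(7)))
  dimnames(m) <- list(taxonomy$taxon_id, tax_ranks())
  m
}
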