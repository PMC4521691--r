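#' Taxa composition table
#'
#' Container for a samples x taxa matrix of percent abundances (0-100 scale)
#' together with a three-rank taxonomy (genus -> family -> phylum). Per-sample
#' sums within any single rank may be below 100 (the remainder is unclassified)
#' but never above.
#'
#' @param abundance numeric matrix, samples in rows, taxa in columns; rownames
#'   are sample ids, colnames are taxon names. Values are percent (0-100).
#' @param taxonomy data.frame with columns `taxon`, `rank` (one of `"genus"`,
#'   `"family"`, `"phylum"`) and `parent` (taxon name of the parent rank, `NA`
#'   for phyla). Every column of `abundance` must appear in `taxonomy$taxon`.
#' @return An object of class `taxa_table`: a list with elements `abundance`
#'   and `taxonomy`.
#' @examples
#' tax <- data.frame(taxon = "Bacteroides", rank = "genus",
#'                   parent = "Bacteroidaceae")
#' m <- matrix(45, 1, 1, dimnames = list("s1", "Bacteroides"))
#' tt <- taxa_composition_table(m, tax)
#' @export
taxa_composition_table <- function(abundance, taxonomy) {
  if (!is.matrix(abundance) || !is.numeric(abundance))
    stop("`abundance` must be a numeric matrix (samples x taxa)")
  if (is.null(rownames(abundance)) || is.null(colnames(abundance)))
    stop("`abundance` needs sample rownames and taxon colnames")
  if (anyDuplicated(rownames(abundance)))
    stop("duplicate sample ids in abundance matrix")
  if (anyDuplicated(colnames(abundance)))
    stop("duplicate taxon names in abundance matrix")
  if (any(is.na(abundance)) || any(abundance < 0))
    stop("negative or missing abundances are not allowed")
  if (any(abundance > 100 + 1e-8))
    stop("abundances are percentages and cannot exceed 100")
  if (!is.data.frame(taxonomy) ||
      !all(c("taxon", "rank", "parent") %in% names(taxonomy)))
    stop("`taxonomy` must have columns taxon, rank, parent")
  taxonomy$taxon <- as.character(taxonomy$taxon)
  taxonomy$rank <- as.character(taxonomy$rank)
  taxonomy$parent <- as.character(taxonomy$parent)
  if (!all(taxonomy$rank %in% c("genus", "family", "phylum")))
    stop("taxonomy ranks must be genus, family or phylum")
  missing <- setdiff(colnames(abundance), taxonomy$taxon)
  if (length(missing))
    stop("taxa absent from taxonomy: ", paste(missing, collapse = ", "))
  # rank sums <= 100 per sample
  for (rk in intersect(unique(taxonomy$rank),
                       taxonomy$rank[match(colnames(abundance), taxonomy$taxon)])) {
    cols <- colnames(abundance)[
      taxonomy$rank[match(colnames(abundance), taxonomy$taxon)] == rk]
    if (length(cols)) {
      s <- rowSums(abundance[, cols, drop = FALSE])
      if (any(s > 100 + 1e-6))
        stop("per-sample ", rk, " abundances sum above 100")
    }
  }
  structure(list(abundance = abundance,
                 taxonomy = taxonomy[, c("taxon", "rank", "parent")]),
            class = "taxa_table")
}

#' @export
print.taxa_table <- function(x, ...) {
  cat("taxa_table:", nrow(x$abundance), "samples x",
      ncol(x$abundance), "taxa\n")
  rk <- table(x$taxonomy$rank[match(colnames(x$abundance), x$taxonomy$taxon)])
  cat("ranks:", paste(names(rk), rk, sep = "=", collapse = ", "), "\n")
  invisible(x)
}

#' Subset a taxa table to one taxonomic rank
#'
#' @param x a `taxa_table`
#' @param rank `"genus"`, `"family"` or `"phylum"`
#' @return a `taxa_table` holding only taxa of that rank
#' @export
subset_rank <- function(x, rank) {
  stopifnot(inherits(x, "taxa_table"))
  rk <- x$taxonomy$rank[match(colnames(x$abundance), x$taxonomy$taxon)]
  keep <- colnames(x$abundance)[rk == rank]
  if (!length(keep)) stop("no taxa at rank ", rank)
  taxa_composition_table(x$abundance[, keep, drop = FALSE], x$taxonomy)
}

#' Write / read a taxa composition table as TSV
#'
#' The on-disk layout has taxa in rows with `taxon`, `rank` and `parent`
#' columns first, followed by one column per sample. `read_composition_tsv()`
#' reconstructs the parent links and validates the table, so
#' `read_composition_tsv(write_composition_tsv(x, f))` equals `x`.
#'
#' @param x a `taxa_table`
#' @param path file path
#' @return `write_composition_tsv` returns `path` invisibly;
#'   `read_composition_tsv` returns a `taxa_table`.
#' @export
write_composition_tsv <- function(x, path) {
  stopifnot(inherits(x, "taxa_table"))
  idx <- match(colnames(x$abundance), x$taxonomy$taxon)
  df <- data.frame(taxon = colnames(x$abundance),
                   rank = x$taxonomy$rank[idx],
                   parent = x$taxonomy$parent[idx],
                   t(x$abundance), check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_composition_tsv
#' @export
read_composition_tsv <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = TRUE, check.names = FALSE,
                          stringsAsFactors = FALSE)
  if (!all(c("taxon", "rank", "parent") %in% names(df)[1:3]))
    stop("malformed header: expected taxon, rank, parent leading columns")
  sample_cols <- names(df)[-(1:3)]
  if (!length(sample_cols)) stop("malformed header: no sample columns")
  if (anyDuplicated(sample_cols)) stop("duplicate sample ids")
  m <- as.matrix(df[, sample_cols, drop = FALSE])
  if (!is.numeric(m)) stop("non-numeric abundances")
  if (any(m < 0, na.rm = TRUE)) stop("negative abundances")
  mat <- t(m)
  colnames(mat) <- df$taxon
  rownames(mat) <- sample_cols
  taxa_composition_table(mat,
    data.frame(taxon = df$taxon, rank = df$rank, parent = df$parent,
               stringsAsFactors = FALSE))
}

#' Write / read subject metadata as CSV
#'
#' One subject per row with columns `subject_id`, `group` (normal/obese),
#' `gender` (male/female), `age`, `bmi_zscore` and the blood markers
#' `glucose`, `tg`, `tchol`, `hdlc`, `hs_crp` (mg/dL).
#'
#' @param metadata data.frame of subject metadata
#' @param path file path
#' @export
write_metadata_csv <- function(metadata, path) {
  validate_metadata(metadata)
  utils::write.csv(metadata, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_metadata_csv
#' @export
read_metadata_csv <- function(path) {
  md <- utils::read.csv(path, stringsAsFactors = FALSE)
  validate_metadata(md)
  md
}

validate_metadata <- function(md) {
  need <- c("subject_id", "group", "gender", "age", "bmi_zscore",
            "glucose", "tg", "tchol", "hdlc", "hs_crp")
  if (!all(need %in% names(md)))
    stop("metadata must have columns: ", paste(need, collapse = ", "))
  if (!all(md$group %in% c("normal", "obese")))
    stop("group must be 'normal' or 'obese'")
  if (!all(md$gender %in% c("male", "female")))
    stop("gender must be 'male' or 'female'")
  markers <- c("glucose", "tg", "tchol", "hdlc", "hs_crp")
  if (any(unlist(md[markers]) < 0, na.rm = TRUE))
    stop("blood markers must be non-negative")
  if (anyDuplicated(md$subject_id)) stop("duplicate subject ids")
  invisible(md)
}
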