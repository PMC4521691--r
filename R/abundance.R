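#' Aggregate a composition table to a higher taxonomic rank
#'
#' Sums genus abundances into their parent family or phylum (and family into
#' phylum) following the parent links of the taxonomy. Aggregation conserves
#' per-sample totals exactly: the sum over output taxa equals the sum over the
#' input genus values.
#'
#' @param table a `taxa_table` containing genus-level rows
#' @param rank target rank, `"family"` or `"phylum"` (or `"genus"`, a no-op
#'   subset)
#' @return a `taxa_table` at the requested rank
#' @export
aggregate_to_rank <- function(table, rank = c("family", "phylum", "genus")) {
  rank <- match.arg(rank)
  stopifnot(inherits(table, "taxa_table"))
  if (rank == "genus") return(subset_rank(table, "genus"))
  gen <- subset_rank(table, "genus")
  tax <- table$taxonomy
  fam <- tax$parent[match(colnames(gen$abundance), tax$taxon)]
  if (any(is.na(fam)))
    stop("orphan genus without a family parent: ",
         paste(colnames(gen$abundance)[is.na(fam)], collapse = ", "))
  target <- fam
  if (rank == "phylum") {
    target <- tax$parent[match(fam, tax$taxon)]
    if (any(is.na(target)))
      stop("orphan family without a phylum parent: ",
           paste(unique(fam[is.na(target)]), collapse = ", "))
  }
  groups <- unique(target)
  out <- vapply(groups, function(g)
    rowSums(gen$abundance[, target == g, drop = FALSE]),
    numeric(nrow(gen$abundance)))
  if (nrow(gen$abundance) == 1L) {
    out <- matrix(out, nrow = 1, dimnames = list(rownames(gen$abundance), groups))
  } else colnames(out) <- groups
  taxa_composition_table(out, tax)
}

#' Firmicutes-to-Bacteroidetes ratio
#'
#' Per-sample ratio of the Firmicutes and Bacteroidetes phylum abundances,
#' with group mean and SD. Samples with zero Bacteroidetes have an undefined
#' ratio; they are excluded from the group summaries and their count is
#' reported.
#'
#' @param phylum_table a `taxa_table` containing `Firmicutes` and
#'   `Bacteroidetes` phylum rows (a genus-level table is rolled up first)
#' @param metadata optional subject metadata with `subject_id` and `group`;
#'   when given, per-group mean +/- SD is returned
#' @return list with `ratio` (named per-sample vector, `NA` when undefined),
#'   `n_undefined`, and if metadata is supplied a `by_group` data.frame of
#'   mean/sd/n.
#' @export
fb_ratio <- function(phylum_table, metadata = NULL) {
  stopifnot(inherits(phylum_table, "taxa_table"))
  ranks <- phylum_table$taxonomy$rank[
    match(colnames(phylum_table$abundance), phylum_table$taxonomy$taxon)]
  tab <- if (all(ranks == "phylum")) phylum_table else
    aggregate_to_rank(phylum_table, "phylum")
  ab <- tab$abundance
  if (!all(c("Firmicutes", "Bacteroidetes") %in% colnames(ab)))
    stop("phylum table must contain Firmicutes and Bacteroidetes")
  ratio <- ifelse(ab[, "Bacteroidetes"] > 0,
                  ab[, "Firmicutes"] / ab[, "Bacteroidetes"], NA_real_)
  names(ratio) <- rownames(ab)
  out <- list(ratio = ratio, n_undefined = sum(is.na(ratio)))
  if (!is.null(metadata)) {
    g <- metadata$group[match(names(ratio), metadata$subject_id)]
    if (any(is.na(g))) stop("samples missing from metadata")
    by <- lapply(split(ratio, g), function(r) {
      r <- r[!is.na(r)]
      c(mean = mean(r), sd = stats::sd(r), n = length(r))
    })
    out$by_group <- data.frame(group = names(by), do.call(rbind, by),
                               row.names = NULL)
  }
  out
}

#' Per-group mean composition summary
#'
#' Mean percent abundance per taxon within each subject group at a given rank,
#' pooling taxa whose group mean falls below `min_mean_percent` into an
#' `"other"` category (applied per group independently). This is the data
#' behind a donut-style average-composition figure showing all taxa above 1%.
#'
#' @param table a `taxa_table`
#' @param metadata subject metadata (`subject_id`, `group`)
#' @param rank rank to summarize at
#' @param min_mean_percent pooling threshold in percent (default 1)
#' @return data.frame with columns `group`, `taxon`, `mean_percent`, plus the
#'   threshold as attribute `min_mean_percent`.
#' @export
group_mean_summary <- function(table, metadata, rank = "genus",
                               min_mean_percent = 1.0) {
  tab <- if (rank == "genus") subset_rank(table, "genus") else
    aggregate_to_rank(table, rank)
  ab <- tab$abundance
  g <- metadata$group[match(rownames(ab), metadata$subject_id)]
  if (any(is.na(g))) stop("samples missing from metadata")
  res <- do.call(rbind, lapply(unique(g), function(gr) {
    m <- colMeans(ab[g == gr, , drop = FALSE])
    big <- m >= min_mean_percent
    df <- data.frame(group = rep(gr, sum(big)), taxon = names(m)[big],
                     mean_percent = unname(m[big]), stringsAsFactors = FALSE)
    if (any(!big))
      df <- rbind(df, data.frame(group = gr, taxon = "other",
                                 mean_percent = sum(m[!big])))
    df[order(-df$mean_percent), ]
  }))
  rownames(res) <- NULL
  attr(res, "min_mean_percent") <- min_mean_percent
  res
}
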