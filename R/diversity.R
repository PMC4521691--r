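#' Shannon diversity index
#'
#' H' = -sum(p_i * ln(p_i)) over taxa or OTUs with positive abundance, where
#' p_i is the within-sample proportion. Counts and proportions give the same
#' value (the index is invariant to rescaling); zero-abundance entries
#' contribute 0 by the usual limit convention. Natural-log units (nats).
#'
#' @param x non-negative numeric vector (one sample), or a samples x taxa
#'   matrix / `otu_count_table` (one value per row)
#' @return numeric H' >= 0 (vector for matrix input)
#' @examples
#' shannon_index(rep(1, 4))  # ln 4
#' @export
shannon_index <- function(x) {
  if (is.matrix(x)) {
    if (any(rowSums(x) <= 0)) stop("all-zero sample")
    return(vegan::diversity(x, index = "shannon"))
  }
  if (any(x < 0) || all(x == 0)) stop("need non-negative values, at least one positive")
  unname(vegan::diversity(matrix(x, 1), index = "shannon")[1])
}

#' Bray-Curtis dissimilarity matrix
#'
#' BC_ij = (S_i + S_j - 2 C_ij) / (S_i + S_j) where S_i is the total count of
#' sample i and C_ij the sum over shared OTUs of the minimum of the two
#' counts. Values lie in [0, 1]: 0 for identical samples, 1 for samples with
#' disjoint OTU sets.
#'
#' @param counts samples x OTUs non-negative matrix (e.g. an
#'   `otu_count_table`), >= 2 samples, no all-zero sample
#' @return symmetric numeric matrix with zero diagonal and the sample ids as
#'   dimnames
#' @export
bray_curtis <- function(counts) {
  counts <- unclass(counts)
  if (!is.matrix(counts) || nrow(counts) < 2) stop("need >= 2 samples")
  if (any(counts < 0)) stop("counts must be non-negative")
  if (any(rowSums(counts) == 0)) stop("sample with zero total count")
  d <- as.matrix(vegan::vegdist(counts, method = "bray"))
  dimnames(d) <- list(rownames(counts), rownames(counts))
  d
}

#' Principal coordinates ordination of a distance matrix
#'
#' Classical metric scaling (double-centered Gram matrix eigendecomposition)
#' of a dissimilarity matrix, the standard reading of "PCA on beta
#' diversities". Axes are ordered by eigenvalue; the solution is deterministic
#' up to per-axis sign. Negative eigenvalues (Bray-Curtis matrices need not be
#' Euclidean-embeddable) are zeroed with a warning and excluded from the
#' explained-variance denominator.
#'
#' @param dm square symmetric dissimilarity matrix (or `dist`)
#' @param n_axes number of axes to return (default 2; truncated with a
#'   warning if it exceeds the rank)
#' @return list with `coordinates` (samples x axes), `eigenvalues`, and
#'   `explained` (fraction of positive eigenvalue mass per returned axis)
#' @export
ordinate <- function(dm, n_axes = 2L) {
  if (inherits(dm, "dist")) dm <- as.matrix(dm)
  if (!isSymmetric(unname(dm)) || any(diag(dm) != 0))
    stop("dm must be symmetric with zero diagonal")
  n <- nrow(dm)
  # cmdscale chats about non-positive eigenvalues; we inspect them below
  fit <- suppressWarnings(stats::cmdscale(stats::as.dist(dm), k = n - 1, eig = TRUE))
  eig <- fit$eig
  if (any(eig < -1e-8 * max(abs(eig))))
    warning("negative eigenvalues zeroed (non-Euclidean dissimilarity)")
  pos <- pmax(eig, 0)
  rank <- sum(pos > max(pos) * 1e-10)
  if (n_axes > rank) {
    warning("n_axes exceeds rank ", rank, "; truncated")
    n_axes <- rank
  }
  coords <- fit$points[, seq_len(n_axes), drop = FALSE]
  rownames(coords) <- rownames(dm)
  colnames(coords) <- paste0("PCo", seq_len(n_axes))
  list(coordinates = coords, eigenvalues = eig,
       explained = pos[seq_len(n_axes)] / sum(pos))
}

#' Write a distance matrix as square TSV
#' @param dm square matrix
#' @param path file path
#' @export
write_distance_tsv <- function(dm, path) {
  utils::write.table(cbind(sample = rownames(dm), as.data.frame(dm)), path,
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
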