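#' Mann-Whitney U test
#'
#' Two-sided rank-sum test comparing two independent groups. For small
#' samples (both groups <= `exact_max`) the null distribution of U is
#' enumerated exactly over all group assignments of the pooled values (so
#' ties are handled exactly via midranks); otherwise the normal approximation
#' with tie-corrected variance is used.
#'
#' @param a,b numeric vectors, each non-empty
#' @param exact_max enumeration threshold per group (default 8)
#' @return list with `U` (statistic for the first group), `p` (two-sided) and
#'   `method`
#' @examples
#' mann_whitney(c(1, 2, 3), c(4, 5, 6))  # U = 0, exact p = 0.1
#' @export
mann_whitney <- function(a, b, exact_max = 8L) {
  if (!length(a) || !length(b)) stop("both groups must be non-empty")
  na <- length(a); nb <- length(b); n <- na + nb
  pooled <- c(a, b)
  r <- rank(pooled)
  u_obs <- sum(r[seq_len(na)]) - na * (na + 1) / 2
  if (na <= exact_max && nb <= exact_max) {
    combs <- utils::combn(n, na)
    us <- colSums(matrix(r[combs], nrow = na)) - na * (na + 1) / 2
    p <- min(1, 2 * min(mean(us <= u_obs + 1e-9), mean(us >= u_obs - 1e-9)))
    method <- "exact enumeration"
  } else {
    mu <- na * nb / 2
    ties <- table(pooled)
    sigma2 <- na * nb / 12 * ((n + 1) - sum(ties^3 - ties) / (n * (n - 1)))
    if (sigma2 <= 0) {
      p <- 1
    } else {
      z <- (u_obs - mu) / sqrt(sigma2)
      p <- min(1, 2 * stats::pnorm(-abs(z)))
    }
    method <- "normal approximation, tie-corrected"
  }
  list(U = u_obs, p = p, method = method)
}

#' Benjamini-Hochberg FDR adjustment
#'
#' Step-up adjusted p-values: sort ascending, take the running minimum of
#' p_(j) * n / j from the largest rank down, cap at 1, and map back to the
#' input order. Adjusted values are always >= the raw values and monotone
#' along the sorted raw p-values.
#'
#' @param p numeric vector of p-values in [0, 1]
#' @return adjusted p-values in input order
#' @export
bh_fdr <- function(p) {
  if (any(is.na(p)) || any(p < 0 | p > 1)) stop("p-values must lie in [0, 1]")
  stats::p.adjust(p, method = "BH")
}

#' Median fold change between groups
#'
#' Ratio of group medians (obese / normal). A zero normal-group median makes
#' the ratio undefined (reported as `Inf` with `undefined = TRUE`) rather
#' than being imputed.
#'
#' @param obese,normal numeric vectors of per-sample abundances
#' @return list with `median_obese`, `median_normal`, `ratio`, `undefined`
#' @export
fold_change <- function(obese, normal) {
  if (!length(obese) || !length(normal)) stop("both groups must be non-empty")
  mo <- stats::median(obese); mn <- stats::median(normal)
  if (mn == 0) {
    list(median_obese = mo, median_normal = mn, ratio = Inf, undefined = TRUE)
  } else {
    list(median_obese = mo, median_normal = mn, ratio = mo / mn,
         undefined = FALSE)
  }
}

#' Partial Pearson correlation
#'
#' Pearson correlation between the residuals of `x` and `y` after
#' least-squares regression on the covariates (plus intercept). With no
#' covariates this is the plain Pearson correlation. The p-value comes from
#' the t distribution with n - 2 - k degrees of freedom (k covariates).
#'
#' @param x,y numeric vectors
#' @param covariates optional numeric matrix / data.frame of covariates;
#'   character or factor columns (e.g. gender) are converted to 0/1 dummies
#' @return list with `r`, `p`, `df`, `controlled` (covariate names)
#' @export
partial_pearson <- function(x, y, covariates = NULL) {
  n <- length(x)
  if (length(y) != n) stop("x and y lengths differ")
  if (is.null(covariates) || (!is.null(dim(covariates)) && ncol(covariates) == 0)) {
    k <- 0L
    rx <- x - mean(x); ry <- y - mean(y)
    controlled <- character(0)
  } else {
    cv <- as.data.frame(covariates)
    controlled <- names(cv)
    for (j in seq_along(cv)) {
      if (is.character(cv[[j]]) || is.factor(cv[[j]]))
        cv[[j]] <- as.numeric(factor(cv[[j]])) - 1
    }
    M <- cbind(1, as.matrix(cv))
    k <- ncol(M) - 1L
    if (n <= k + 2) stop("need n > number of covariates + 2")
    rx <- stats::lm.fit(M, x)$residuals
    ry <- stats::lm.fit(M, y)$residuals
  }
  if (stats::sd(rx) == 0 || stats::sd(ry) == 0)
    stop("degenerate input: constant after residualization")
  r <- stats::cor(rx, ry)
  df <- n - 2L - k
  tval <- r * sqrt(df / max(1e-300, 1 - r^2))
  p <- 2 * stats::pt(-abs(tval), df)
  list(r = r, p = p, df = df, controlled = controlled)
}

#' Lilliefors (Kolmogorov-Smirnov) normality test
#'
#' KS distance between the empirical CDF and a normal CDF with mean and SD
#' estimated from the data; because the parameters are estimated, the p-value
#' is obtained from a seeded Monte-Carlo null (standard-normal samples of the
#' same size with re-estimated parameters) rather than the standard KS
#' distribution.
#'
#' @param values numeric vector, n >= 4, non-constant
#' @param nsim Monte-Carlo draws (default 10000)
#' @param seed seed for the null draws
#' @return list with `D` and `p`
#' @export
lilliefors_normality <- function(values, nsim = 10000L, seed = 1L) {
  n <- length(values)
  if (n < 4) stop("need at least 4 observations")
  if (stats::sd(values) == 0) stop("constant input")
  ks_d <- function(x) {
    z <- sort((x - mean(x)) / stats::sd(x))
    cdf <- stats::pnorm(z)
    i <- seq_along(z)
    max(i / length(z) - cdf, cdf - (i - 1) / length(z))
  }
  d_obs <- ks_d(values)
  old <- get0(".Random.seed", envir = globalenv())
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  d_null <- vapply(seq_len(nsim), function(i) ks_d(stats::rnorm(n)), numeric(1))
  list(D = d_obs, p = (1 + sum(d_null >= d_obs)) / (nsim + 1))
}

#' Pearson chi-square test for a 2x2 table (no continuity correction)
#'
#' @param counts 2x2 non-negative matrix
#' @return list with `chisq`, `p`, `df`
#' @export
chi_square_2x2 <- function(counts) {
  counts <- as.matrix(counts)
  if (!all(dim(counts) == c(2, 2)) || any(counts < 0))
    stop("counts must be a non-negative 2x2 table")
  if (any(rowSums(counts) == 0) || any(colSums(counts) == 0))
    stop("degenerate table: zero marginal")
  ct <- suppressWarnings(stats::chisq.test(counts, correct = FALSE))
  list(chisq = unname(ct$statistic), p = unname(ct$p.value),
       df = unname(ct$parameter))
}

#' Two-sided pooled-variance Student's t-test
#'
#' @param a,b numeric vectors with >= 2 values each
#' @return list with `t`, `p`, `df`
#' @export
t_test_groups <- function(a, b) {
  if (length(a) < 2 || length(b) < 2) stop("each group needs >= 2 values")
  tt <- stats::t.test(a, b, var.equal = TRUE)
  list(t = unname(tt$statistic), p = tt$p.value, df = unname(tt$parameter))
}

#' Natural-log transform selected columns of a marker table
#'
#' @param marker_table data.frame
#' @param columns character vector of columns to transform
#' @return the table with transformed columns; transformed column names are
#'   recorded in attribute `log_transformed`
#' @export
log_transform <- function(marker_table, columns) {
  stopifnot(all(columns %in% names(marker_table)))
  for (cl in columns) {
    v <- marker_table[[cl]]
    if (any(v < 0, na.rm = TRUE)) stop("negative values in ", cl)
    if (any(v == 0, na.rm = TRUE)) stop("zero values in ", cl, " cannot be log-transformed")
    marker_table[[cl]] <- log(v)
  }
  attr(marker_table, "log_transformed") <-
    union(attr(marker_table, "log_transformed"), columns)
  marker_table
}

#' Differential-abundance table between groups
#'
#' For every taxon at the requested rank: Mann-Whitney two-sided p, BH-FDR
#' adjusted p across taxa, group medians and the obese/normal median fold
#' change, in the layout of a per-rank differential-abundance result table.
#'
#' @param table a `taxa_table`
#' @param metadata subject metadata (`subject_id`, `group`)
#' @param rank `"genus"`, `"family"` or `"phylum"`
#' @param taxa optional subset of taxa to test (default: all at the rank)
#' @return data.frame with columns `taxon`, `p_raw`, `p_adjusted`,
#'   `median_obese`, `median_normal`, `fold_change`, `fold_undefined`, `test`
#' @export
compare_groups <- function(table, metadata, rank = "genus", taxa = NULL) {
  tab <- subset_rank(table, rank)
  ab <- tab$abundance
  if (!is.null(taxa)) {
    missing <- setdiff(taxa, colnames(ab))
    if (length(missing)) stop("taxa not in table: ", paste(missing, collapse = ", "))
    ab <- ab[, taxa, drop = FALSE]
  }
  g <- metadata$group[match(rownames(ab), metadata$subject_id)]
  if (any(is.na(g))) stop("samples missing from metadata")
  rows <- lapply(colnames(ab), function(tx) {
    ob <- ab[g == "obese", tx]; no <- ab[g == "normal", tx]
    mw <- mann_whitney(no, ob)
    fc <- fold_change(ob, no)
    data.frame(taxon = tx, p_raw = mw$p,
               median_obese = fc$median_obese, median_normal = fc$median_normal,
               fold_change = fc$ratio, fold_undefined = fc$undefined,
               test = "mann_whitney", stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, rows)
  res$p_adjusted <- bh_fdr(res$p_raw)
  res[, c("taxon", "p_raw", "p_adjusted", "median_obese", "median_normal",
          "fold_change", "fold_undefined", "test")]
}

#' Taxon-covariate partial correlations
#'
#' Age- and gender-adjusted Pearson partial correlations between taxon
#' abundances and the BMI z-score / blood markers, with the markers (not the
#' z-score) natural-log transformed beforehand.
#'
#' @param table a `taxa_table`
#' @param metadata subject metadata
#' @param taxa taxa to correlate
#' @param covariates metadata columns to correlate against
#' @param adjust_for covariates regressed out (default age and gender)
#' @param log_markers markers to log-transform first (set `character(0)` to
#'   disable)
#' @return data.frame with columns `taxon`, `covariate`, `r`, `p`,
#'   `controlled`
#' @export
taxa_covariate_correlation <- function(table, metadata, taxa,
                                       covariates = c("bmi_zscore", "glucose",
                                                      "tg", "tchol", "hdlc",
                                                      "hs_crp"),
                                       adjust_for = c("age", "gender"),
                                       log_markers = c("glucose", "tg", "tchol",
                                                       "hdlc", "hs_crp")) {
  tab <- subset_rank(table, "genus")
  ab <- tab$abundance
  md <- metadata[match(rownames(ab), metadata$subject_id), ]
  if (any(is.na(md$subject_id))) stop("samples missing from metadata")
  md <- log_transform(md, intersect(log_markers, covariates))
  ctrl <- md[, adjust_for, drop = FALSE]
  res <- do.call(rbind, lapply(taxa, function(tx) {
    do.call(rbind, lapply(covariates, function(cv) {
      pp <- partial_pearson(ab[, tx], md[[cv]], ctrl)
      data.frame(taxon = tx, covariate = cv, r = pp$r, p = pp$p,
                 controlled = paste(adjust_for, collapse = "+"),
                 stringsAsFactors = FALSE)
    }))
  }))
  rownames(res) <- NULL
  res
}
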