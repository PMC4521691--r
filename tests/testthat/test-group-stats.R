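test_that("Mann-Whitney exact branch matches enumeration arithmetic", {
  res <- mann_whitney(c(1, 2, 3), c(4, 5, 6))
  expect_equal(res$U, 0)
  expect_equal(res$p, 0.1)  # 2/20 orderings at least as extreme
  expect_match(res$method, "exact")

  same <- mann_whitney(c(2, 5, 9), c(2, 5, 9))
  expect_equal(same$p, 1)

  expect_error(mann_whitney(numeric(0), 1:3), "non-empty")
})

test_that("Mann-Whitney p is invariant under group swap and monotone maps", {
  set.seed(10)
  for (i in 1:10) {
    a <- rlnorm(sample(5:30, 1)); b <- rlnorm(sample(5:30, 1), meanlog = 0.5)
    p1 <- mann_whitney(a, b)$p
    expect_equal(mann_whitney(b, a)$p, p1, tolerance = 1e-12)
    expect_equal(mann_whitney(log(a), log(b))$p, p1, tolerance = 1e-12)
    expect_equal(mann_whitney(a^2, b^2)$p, p1, tolerance = 1e-12)
  }
})

test_that("Mann-Whitney approximation agrees with wilcox.test on large n", {
  set.seed(11)
  for (i in 1:5) {
    a <- rnorm(40); b <- rnorm(45, mean = 0.3)
    ours <- mann_whitney(a, b)
    ref <- wilcox.test(a, b, exact = FALSE, correct = FALSE)
    expect_equal(ours$U, unname(ref$statistic))
    expect_equal(ours$p, ref$p.value, tolerance = 1e-10)
    # with ties
    at <- round(a); bt <- round(b)
    expect_equal(mann_whitney(at, bt)$p,
                 wilcox.test(at, bt, exact = FALSE, correct = FALSE)$p.value,
                 tolerance = 1e-10)
  }
})

test_that("BH adjustment is a step-up with the expected properties", {
  # manual step-up oracle
  bh_oracle <- function(p) {
    n <- length(p); o <- order(p); q <- numeric(n)
    running <- 1
    for (i in n:1) {
      running <- min(running, p[o[i]] * n / i)
      q[o[i]] <- running
    }
    q
  }
  set.seed(12)
  for (i in 1:20) {
    p <- runif(sample(3:40, 1))^2
    q <- bh_fdr(p)
    expect_equal(q, bh_oracle(p), tolerance = 1e-12)
    expect_true(all(q >= p - 1e-15) && all(q <= 1))
    expect_true(all(diff(q[order(p)]) >= -1e-15))  # monotone along sorted p
  }
  expect_equal(bh_fdr(rep(0.05, 10)), rep(0.05, 10))
  expect_error(bh_fdr(c(0.2, 1.4)), "0, 1")
})

test_that("fold change is the ratio of medians with zero guarded", {
  fc <- fold_change(c(16, 17, 17.9), c(45, 46, 46.7))
  expect_equal(fc$ratio, 17 / 46)
  expect_false(fc$undefined)
  expect_equal(fold_change(1:5, 1:5)$ratio, 1)
  z <- fold_change(c(2, 3), c(0, 0))
  expect_true(z$undefined)
  expect_equal(z$ratio, Inf)
})

test_that("partial correlation equals residual and recursion formulas", {
  # y = x exactly
  x <- rnorm(20)
  expect_equal(partial_pearson(x, x)$r, 1)

  # orthogonal covariate leaves r untouched
  set.seed(13)
  x <- rnorm(64); y <- 0.5 * x + rnorm(64)
  z <- rep(c(-1, 1), 32)  # orthogonalize against x and y
  z <- lm.fit(cbind(1, x, y), z)$residuals
  pp <- partial_pearson(x, y, data.frame(z = z))
  expect_equal(pp$r, cor(x, y), tolerance = 1e-12)

  # n = 8 worked dataset vs the first-order recursion
  x8 <- c(2.1, 3.3, 1.7, 4.0, 5.2, 3.9, 2.8, 4.6)
  y8 <- c(1.0, 2.5, 1.1, 3.9, 4.8, 3.0, 2.2, 4.1)
  z8 <- c(0.3, 1.2, 0.8, 2.0, 2.5, 1.9, 1.1, 2.4)
  rec <- (cor(x8, y8) - cor(x8, z8) * cor(y8, z8)) /
    sqrt((1 - cor(x8, z8)^2) * (1 - cor(y8, z8)^2))
  got <- partial_pearson(x8, y8, data.frame(z = z8))
  expect_equal(got$r, rec, tolerance = 1e-12)
  expect_equal(got$df, 8 - 2 - 1)

  # empty covariate list reduces to plain Pearson with its textbook p
  plain <- partial_pearson(x8, y8)
  expect_equal(plain$r, cor(x8, y8), tolerance = 1e-15)
  expect_equal(plain$p, cor.test(x8, y8)$p.value, tolerance = 1e-12)

  # gender-style character covariates are coded 0/1
  gg <- rep(c("male", "female"), 4)
  expect_silent(partial_pearson(x8, y8, data.frame(gender = gg)))
  expect_error(partial_pearson(x8, rep(1, 8)), "degenerate")
})

test_that("Lilliefors test calibrates its statistic and Monte-Carlo p", {
  expect_error(lilliefors_normality(c(1, 2, 3)), "at least 4")
  expect_error(lilliefors_normality(rep(2, 10)), "constant")

  skip_if_not_installed("nortest")
  set.seed(14)
  x <- rnorm(50)
  expect_equal(lilliefors_normality(x, nsim = 100)$D,
               unname(nortest::lillie.test(x)$statistic), tolerance = 1e-12)

  # power: exponential data at n = 100 rejected in > 80% of replicates
  set.seed(15)
  rej <- vapply(1:25, function(i)
    lilliefors_normality(rexp(100), nsim = 400, seed = i)$p < 0.05, logical(1))
  expect_gt(mean(rej), 0.8)

  # size: standard-normal data rejected at roughly the nominal 5% level
  set.seed(16)
  pvals <- vapply(1:120, function(i)
    lilliefors_normality(rnorm(50), nsim = 400, seed = i)$p, numeric(1))
  expect_lt(abs(mean(pvals < 0.05) - 0.05), 0.05)
})

test_that("chi-square and t-test match their textbook forms", {
  gender <- matrix(c(37, 30, 41, 26), 2, byrow = TRUE)
  res <- chi_square_2x2(gender)
  expect_equal(round(res$p, 4), 0.4836)

  flat <- chi_square_2x2(matrix(10, 2, 2))
  expect_equal(flat$chisq, 0)
  expect_equal(flat$p, 1)
  expect_error(chi_square_2x2(matrix(c(0, 0, 3, 4), 2, byrow = TRUE)),
               "marginal")

  tt <- t_test_groups(c(1, 2, 3, 4), c(2.5, 1.5, 3.5, 2.5))
  expect_equal(tt$t, 0)
  expect_equal(tt$p, 1)
  expect_error(t_test_groups(1, 2:4), ">= 2")
})

test_that("log transform is the natural log with provenance recorded", {
  df <- data.frame(a = c(1, exp(1)), b = c(5, 5))
  out <- log_transform(df, "a")
  expect_equal(out$a, c(0, 1))
  expect_equal(out$b, df$b)
  expect_equal(attr(out, "log_transformed"), "a")
  expect_error(log_transform(data.frame(a = c(-1, 2)), "a"), "negative")
  expect_error(log_transform(data.frame(a = c(0, 2)), "a"), "zero")
})

test_that("log transformation improves marker normality in the cohort", {
  co <- generate_cohort(cohort_config(seed = 17))
  crp <- co$metadata$hs_crp[co$metadata$group == "normal"]
  raw <- lilliefors_normality(crp, nsim = 1000, seed = 1)
  logged <- lilliefors_normality(log(crp), nsim = 1000, seed = 1)
  expect_gt(logged$p, raw$p)
})

test_that("group comparison table carries tests, FDR and fold changes", {
  co <- generate_cohort(cohort_config(seed = 18))
  gs <- compare_groups(co$composition, co$metadata, "genus")
  expect_setequal(gs$taxon, default_taxa_spec()$taxon)
  expect_true(all(gs$p_adjusted >= gs$p_raw - 1e-15))
  expect_true(all(gs$p_adjusted <= 1))
  expect_equal(gs$p_adjusted, bh_fdr(gs$p_raw))
  # medians feed the fold change
  i <- match("Bacteroides", gs$taxon)
  expect_equal(gs$fold_change[i], gs$median_obese[i] / gs$median_normal[i])
  expect_error(compare_groups(co$composition, co$metadata, "genus",
                              taxa = "NotATaxon"), "not in table")
})

test_that("taxon-covariate correlations control for age and gender", {
  co <- generate_cohort(cohort_config(seed = 19))
  res <- taxa_covariate_correlation(co$composition, co$metadata,
                                    c("Bacteroides", "Prevotella"))
  expect_equal(nrow(res), 12L)  # 2 taxa x 6 covariates
  expect_true(all(abs(res$r) <= 1))
  expect_true(all(res$controlled == "age+gender"))
  bmi_b <- res$r[res$taxon == "Bacteroides" & res$covariate == "bmi_zscore"]
  bmi_p <- res$r[res$taxon == "Prevotella" & res$covariate == "bmi_zscore"]
  expect_lt(bmi_b, 0)
  expect_gt(bmi_p, 0)
})
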