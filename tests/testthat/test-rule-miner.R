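test_that("quartile discretization uses interpolated cuts and handles masses", {
  m <- matrix(1:8, 8, 1, dimnames = list(paste0("s", 1:8), "X"))
  d <- discretize_quartiles(m)
  expect_equal(as.numeric(d$breakpoints[1, c("cut1", "cut2", "cut3")]),
               c(2.75, 4.5, 6.25))
  expect_equal(unname(d$categories[, "X"]), c(1L, 1L, 2L, 2L, 3L, 3L, 4L, 4L))

  z <- matrix(0, 6, 1, dimnames = list(paste0("s", 1:6), "Z"))
  expect_warning(dz <- discretize_quartiles(z), "constant")
  expect_true(all(dz$categories == 1L))

  # zero mass pulls Q1 onto the minimum: zeros collapse into category 1
  v <- matrix(c(0, 0, 0, 0, 1, 2, 3, 4), 8, 1,
              dimnames = list(paste0("s", 1:8), "P"))
  dv <- discretize_quartiles(v)
  expect_true(dv$breakpoints$at_min1)
  expect_true(all(dv$categories[1:4, 1] == 1L))
  expect_true(all(dv$categories[5:8, 1] > 1L))

  expect_error(discretize_quartiles(m[1:3, , drop = FALSE]), ">= 4 samples")
  expect_error(discretize_quartiles(m, taxa = "Nope"), "not present")
})

test_that("fixed reference breakpoints reproduce published category semantics", {
  bp <- reference_breakpoints()
  m <- matrix(c(45, 0.3, 0, 1.5, 0.05,
                70, 3.0, 80, 9.0, 2.0,
                2, 0.01, 0.05, 0.5, 0.2), 3, 5, byrow = TRUE,
              dimnames = list(c("a", "b", "c"), bp$taxon))
  cats <- apply_breakpoints(m, bp)
  expect_equal(unname(cats["a", ]), c(3L, 2L, 1L, 2L, 1L))  # Bacteroides 45 -> "36-60"
  expect_equal(unname(cats["b", ]), c(4L, 4L, 4L, 4L, 4L))
  expect_equal(unname(cats["c", ]), c(1L, 1L, 2L, 1L, 2L))  # Prevotella 0.05 -> "0-0.1"
  expect_error(apply_breakpoints(m[, 1:3], bp), "absent")
})

test_that("FOIL gain matches its closed form and brute-force evaluation", {
  # perfect literal from balanced classes: gain = P * log 2
  expect_equal(foil_gain(10, 0, 10, 10), 10 * log(2))
  expect_identical(foil_gain(0, 0, 10, 10), -Inf)
  expect_error(foil_gain(-1, 0, 1, 1), "non-negative")

  toy <- matrix(c(4L, 1L, 4L, 2L, 1L, 1L, 2L, 4L), 4, 2,
                dimnames = list(paste0("s", 1:4), c("A", "B")))
  cls <- c("pos", "pos", "neg", "neg")
  w <- c(1, 0.5)  # decayed weights on the positives
  p_tot <- sum(w); n_tot <- 2
  for (tx in colnames(toy)) for (k in 1:4) {
    sat <- toy[, tx] == k
    p_prime <- sum(w[sat[1:2]])
    n_prime <- sum(sat[3:4])
    expected <- if (p_prime <= 0) -Inf else
      p_prime * (log(p_prime / (p_prime + n_prime)) - log(p_tot / (p_tot + n_tot)))
    expect_equal(foil_gain(p_prime, n_prime, p_tot, n_tot), expected)
  }
})

test_that("Laplace accuracy equals the Eq-style count ratio", {
  toy <- separable_toy()
  # N_total = 20, N_g = 18 -> 19/22
  cats <- matrix(rep(1L, 20), ncol = 1, dimnames = list(NULL, "T"))
  cls <- c(rep("g", 18), rep("h", 2))
  lap <- laplace_accuracy(c(T = 1L), "g", cats, cls)
  expect_equal(lap$accuracy, 19 / 22)
  expect_equal(lap$n_total, 20L)
  expect_equal(lap$n_g, 18L)

  # vacuous rule (empty coverage) scores 1/m
  lap0 <- laplace_accuracy(c(T = 4L), "g", cats, cls)
  expect_equal(lap0$accuracy, 1 / 2)
  expect_error(laplace_accuracy(c(Bogus = 1L), "g", cats, cls), "unknown taxa")

  # brute-force coverage oracle on random small datasets
  set.seed(20)
  for (i in 1:15) {
    n <- sample(6:14, 1)
    cats <- matrix(sample(1:4, n * 3, replace = TRUE), n, 3,
                   dimnames = list(NULL, c("X", "Y", "Z")))
    cls <- sample(c("a", "b"), n, replace = TRUE)
    if (length(unique(cls)) < 2) cls[1:2] <- c("a", "b")
    ante <- setNames(sample(1:4, 2), c("X", "Z"))
    got <- laplace_accuracy(ante, "a", cats, cls)
    expect_equal(got$accuracy, brute_laplace(ante, "a", cats, cls))
  }
})

test_that("CPAR finds the forced rule on separable data and is deterministic", {
  toy <- separable_toy()
  rs <- cpar_generate(toy$categories, toy$classes)
  keys <- vapply(rs$rules, function(r)
    paste(r$class, paste(names(r$antecedent), r$antecedent, collapse = ",")),
    character(1))
  i <- match("A TaxX 4", keys)
  expect_false(is.na(i))
  expect_equal(rs$rules[[i]]$laplace, 11 / 12)  # (10+1)/(10+2)

  rs2 <- cpar_generate(toy$categories, toy$classes)
  expect_identical(rs, rs2)

  expect_error(cpar_generate(toy$categories, rep("A", 20)), ">= 2 classes")
})

test_that("every emitted rule scores identically to exhaustive enumeration", {
  set.seed(21)
  for (i in 1:8) {
    n <- sample(8:12, 1)
    cats <- matrix(sample(1:4, n * 3, replace = TRUE), n, 3,
                   dimnames = list(NULL, c("X", "Y", "Z")))
    cls <- c("a", "b", sample(c("a", "b"), n - 2, replace = TRUE))
    rs <- cpar_generate(cats, cls)
    enum <- enumerate_rules(cats, cls, max_len = 3)
    enum_acc <- setNames(vapply(enum, `[[`, numeric(1), "accuracy"),
                         vapply(enum, `[[`, character(1), "key"))
    for (r in rs$rules) {
      key <- gutrules:::rule_key(r$antecedent, r$class)
      expect_true(key %in% names(enum_acc))
      expect_equal(r$laplace, unname(enum_acc[key]))
    }
  }
})

test_that("CPAR terminates on arbitrary data within the weight budget", {
  set.seed(22)
  cats <- matrix(sample(1:4, 60 * 4, replace = TRUE), 60, 4,
                 dimnames = list(NULL, paste0("T", 1:4)))
  cls <- sample(c("x", "y"), 60, replace = TRUE)
  expect_no_error(rs <- cpar_generate(cats, cls))
  expect_true(length(rs$rules) >= 1)
  # rules are unique
  keys <- vapply(rs$rules, function(r)
    gutrules:::rule_key(r$antecedent, r$class), character(1))
  expect_equal(anyDuplicated(keys), 0L)
})

test_that("rule filtering keeps the boundary and orders by accuracy", {
  mk <- function(acc, len, class = "normal") {
    ante <- setNames(rep(1L, len), paste0("T", seq_len(len)))
    structure(list(antecedent = ante, class = class, laplace = acc,
                   n_total = 10L, n_g = 9L, m = 2L), class = "cpar_rule")
  }
  rs <- structure(list(rules = list(mk(0.80, 2), mk(0.95, 1), mk(0.79, 1)),
                       params = cpar_params(), classes = c("normal", "obese")),
                  class = "cpar_ruleset")
  kept <- filter_rules(rs)
  expect_equal(vapply(kept$rules, `[[`, numeric(1), "laplace"), c(0.95, 0.80))

  empty <- filter_rules(structure(list(rules = list(), params = cpar_params(),
                                       classes = character(0)),
                        class = "cpar_ruleset"))
  expect_length(empty$rules, 0)

  # eleven published-style accuracies with the 0.80 floor: all kept, top 0.95
  accs <- c(0.86, 0.86, 0.83, 0.80, 0.80, 0.95, 0.89, 0.86, 0.86, 0.85, 0.80)
  rs11 <- structure(list(rules = lapply(accs, mk, len = 2),
                         params = cpar_params(), classes = c("normal", "obese")),
                    class = "cpar_ruleset")
  kept11 <- filter_rules(rs11)
  expect_length(kept11$rules, 11)
  expect_equal(kept11$rules[[1]]$laplace, 0.95)
})

test_that("rule explanations render interval conditions on the percent scale", {
  bp <- reference_breakpoints()
  mk <- function(ante, class, acc) {
    structure(list(antecedent = ante, class = class, laplace = acc,
                   n_total = 20L, n_g = 18L, m = 2L), class = "cpar_rule")
  }
  r1 <- mk(c(Prevotella = 4L, Faecalibacterium = 1L, Oscillibacter = 1L),
           "obese", 0.86)
  txt <- explain_rule(r1, bp)
  expect_match(txt, "Prevotella > 66", fixed = TRUE)
  expect_match(txt, "Faecalibacterium < 0.7", fixed = TRUE)
  expect_match(txt, "Oscillibacter < 0.1", fixed = TRUE)
  expect_match(txt, "obese with 86% accuracy", fixed = TRUE)

  # category 1 at a zero-collision cut is "exactly zero"
  r2 <- mk(c(Prevotella = 1L), "normal", 0.9)
  expect_match(explain_rule(r2, bp), "Prevotella = 0", fixed = TRUE)

  # middle category renders a closed range
  bp3 <- data.frame(taxon = "T", cut1 = 1, cut2 = 2, cut3 = 3,
                    at_min1 = FALSE, at_min2 = FALSE, at_min3 = FALSE)
  r3 <- mk(c(T = 2L), "normal", 0.85)
  expect_match(explain_rule(r3, bp3), "T 1-2", fixed = TRUE)

  expect_error(explain_rule(mk(c(Missing = 1L), "obese", 0.9), bp),
               "no breakpoints")
})

test_that("prediction averages best-k rules and abstains without a match", {
  toy <- separable_toy()
  rs <- filter_rules(cpar_generate(toy$categories, toy$classes), 0.5)
  pred <- predict(rs, toy$categories)
  expect_equal(pred$class, toy$classes)  # leave-in accuracy on separable data

  # leave-one-out stays perfect
  loo <- vapply(seq_len(nrow(toy$categories)), function(i) {
    rs_i <- filter_rules(cpar_generate(toy$categories[-i, ], toy$classes[-i]),
                         0.5)
    predict(rs_i, toy$categories[i, , drop = FALSE])$class
  }, character(1))
  expect_equal(loo, toy$classes)

  # unmatched sample abstains
  odd <- matrix(c(3L, 1L), 1, dimnames = list("q", c("TaxX", "TaxY")))
  expect_true(is.na(predict(rs, odd)$class))
})
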