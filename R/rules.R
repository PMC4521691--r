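#' Quartile discretization of taxa abundances
#'
#' Categorizes each taxon's percent abundance into four groups (1-4) at the
#' pooled-sample 25th/50th/75th percentiles (linear-interpolation quantiles):
#' category 1 below Q1, 2 in [Q1, Q2), 3 in [Q2, Q3), 4 at or above Q3. When
#' a cut coincides with the taxon minimum (a mass of zeros pulls a quartile
#' onto the minimum), membership at that cut collapses downward into the
#' lower category — so with Q1 = 0 the zeros form category 1 — and the
#' collision is recorded in the breakpoint table. A constant taxon yields a
#' single category with a warning.
#'
#' @param table a `taxa_table` or a samples x taxa numeric matrix
#' @param taxa taxa to discretize (default: all columns); needs >= 4 samples
#' @return list with `categories` (integer matrix, samples x taxa) and
#'   `breakpoints` (data.frame `taxon`, `cut1..3`, `at_min1..3`)
#' @examples
#' m <- matrix(1:8, 8, 1, dimnames = list(paste0("s", 1:8), "X"))
#' discretize_quartiles(m)$categories[, 1]  # 1 1 2 2 3 3 4 4
#' @export
discretize_quartiles <- function(table, taxa = NULL) {
  ab <- if (inherits(table, "taxa_table")) table$abundance else table
  if (!is.null(taxa)) {
    missing <- setdiff(taxa, colnames(ab))
    if (length(missing)) stop("taxa not present: ", paste(missing, collapse = ", "))
    ab <- ab[, taxa, drop = FALSE]
  }
  if (nrow(ab) < 4) stop("need >= 4 samples for quartile discretization")
  bp <- data.frame(taxon = colnames(ab), cut1 = NA_real_, cut2 = NA_real_,
                   cut3 = NA_real_, at_min1 = FALSE, at_min2 = FALSE,
                   at_min3 = FALSE, stringsAsFactors = FALSE)
  cats <- matrix(1L, nrow(ab), ncol(ab), dimnames = dimnames(ab))
  for (j in seq_len(ncol(ab))) {
    v <- ab[, j]
    q <- stats::quantile(v, c(0.25, 0.5, 0.75), names = FALSE, type = 7)
    at_min <- q <= min(v)
    if (length(unique(v)) == 1L)
      warning("constant taxon ", colnames(ab)[j], ": single category")
    bp[j, 2:4] <- q
    bp[j, 5:7] <- at_min
    cats[, j] <- categorize_values(v, q, at_min)
  }
  list(categories = cats, breakpoints = bp)
}

categorize_values <- function(v, cuts, at_min = rep(FALSE, 3)) {
  k <- rep(1L, length(v))
  for (i in 1:3) k <- k + if (at_min[i]) (v > cuts[i]) else (v >= cuts[i])
  as.integer(k)
}

#' Apply a fixed breakpoint table to abundances
#'
#' Discretizes with user-supplied cuts instead of estimating quartiles, e.g.
#' with [reference_breakpoints()]. Cuts equal to zero are treated as
#' minimum-collisions (category 1 is "exactly zero") unless `at_min*` columns
#' say otherwise.
#'
#' @param table a `taxa_table` or numeric matrix
#' @param breakpoints data.frame with `taxon`, `cut1`, `cut2`, `cut3` and
#'   optional logical `at_min1..3`
#' @return integer category matrix, samples x taxa
#' @export
apply_breakpoints <- function(table, breakpoints) {
  ab <- if (inherits(table, "taxa_table")) table$abundance else table
  missing <- setdiff(breakpoints$taxon, colnames(ab))
  if (length(missing)) stop("breakpoint taxa absent: ", paste(missing, collapse = ", "))
  ab <- ab[, breakpoints$taxon, drop = FALSE]
  cats <- matrix(1L, nrow(ab), ncol(ab), dimnames = dimnames(ab))
  for (j in seq_len(nrow(breakpoints))) {
    cuts <- as.numeric(breakpoints[j, c("cut1", "cut2", "cut3")])
    at_min <- if (all(c("at_min1", "at_min2", "at_min3") %in% names(breakpoints)))
      as.logical(breakpoints[j, c("at_min1", "at_min2", "at_min3")])
    else cuts == 0
    cats[, j] <- categorize_values(ab[, j], cuts, at_min)
  }
  cats
}

#' Reference quartile breakpoints for the five focal genera
#'
#' The rounded percent-scale category cuts used for rule generation in the
#' adolescent obesity cohort this package models (e.g. Bacteroides: <4, 4-36,
#' 36-60, >60; Prevotella category 1 is exactly 0). Shipping them as a fixture
#' lets printed-rule semantics be reproduced independently of quartile
#' estimation on any particular dataset.
#'
#' @return breakpoint data.frame usable with [apply_breakpoints()] and
#'   [explain_rule()]
#' @export
reference_breakpoints <- function() {
  data.frame(
    taxon = c("Bacteroides", "Alistipes", "Prevotella", "Faecalibacterium",
              "Oscillibacter"),
    cut1 = c(4, 0.04, 0, 0.7, 0.1),
    cut2 = c(36, 0.5, 0.1, 2, 0.3),
    cut3 = c(60, 2, 66, 7, 1),
    at_min1 = c(FALSE, FALSE, TRUE, FALSE, FALSE),
    at_min2 = FALSE, at_min3 = FALSE,
    stringsAsFactors = FALSE
  )
}

#' CPAR hyperparameters
#'
#' Defaults are the published CPAR settings: minimum FOIL gain 0.7 (natural
#' log), example-weight decay 2/3, stop when the remaining positive weight
#' falls below 5% of its initial total, parallel branches for literals within
#' 99% of the best gain, and best-5 rule averaging for prediction. The
#' antecedent length cap (3) and the rule-accuracy floor (0.80) match the
#' longest and weakest published rule respectively.
#'
#' @param min_gain minimum FOIL gain to extend a rule
#' @param delta weight-decay factor in (0, 1) applied to covered positives
#' @param total_weight_factor stop threshold as a fraction of initial weight
#' @param gain_similarity_ratio branch literals with gain >= ratio * best
#' @param max_antecedent_length maximum literals per rule
#' @param min_rule_accuracy Laplace-accuracy floor used by [filter_rules()]
#' @param k number of best rules averaged per class in [predict.cpar_ruleset()]
#' @return a `cpar_params` list
#' @export
cpar_params <- function(min_gain = 0.7, delta = 2 / 3,
                        total_weight_factor = 0.05,
                        gain_similarity_ratio = 0.99,
                        max_antecedent_length = 3L,
                        min_rule_accuracy = 0.80, k = 5L) {
  if (delta <= 0 || delta >= 1) stop("delta must lie in (0, 1)")
  if (gain_similarity_ratio <= 0 || gain_similarity_ratio > 1)
    stop("gain_similarity_ratio must lie in (0, 1]")
  if (max_antecedent_length < 1) stop("max_antecedent_length must be >= 1")
  if (total_weight_factor <= 0 || total_weight_factor >= 1)
    stop("total_weight_factor must lie in (0, 1)")
  structure(list(min_gain = min_gain, delta = delta,
                 total_weight_factor = total_weight_factor,
                 gain_similarity_ratio = gain_similarity_ratio,
                 max_antecedent_length = as.integer(max_antecedent_length),
                 min_rule_accuracy = min_rule_accuracy, k = as.integer(k)),
            class = "cpar_params")
}

#' FOIL gain of adding a literal
#'
#' `gain = P' * (log(P'/(P'+N')) - log(P/(P+N)))` in natural-log units, where
#' P and N are the total positive and negative example weights satisfying the
#' current rule body and P', N' those also satisfying the candidate literal.
#' A literal matching no positive weight returns `-Inf` (never selected).
#'
#' @param p_prime,n_prime positive/negative weight also satisfying the
#'   candidate literal
#' @param p,n positive/negative weight satisfying the current rule body
#' @return the gain in nats
#' @examples
#' foil_gain(10, 0, 10, 10)  # perfect literal: 10 * log(2)
#' @export
foil_gain <- function(p_prime, n_prime, p, n) {
  if (any(c(p_prime, n_prime, p, n) < 0)) stop("weights must be non-negative")
  if (p_prime <= 0) return(-Inf)
  p_prime * (log(p_prime / (p_prime + n_prime)) - log(p / (p + n)))
}

#' Laplace accuracy of a rule
#'
#' `(N_g + 1) / (N_total + m)` where N_total counts the examples satisfying
#' every antecedent literal, N_g those of the consequent class, and m the
#' number of classes. A rule matching nothing scores 1/m.
#'
#' @param antecedent named integer vector (taxon -> category), or a
#'   `cpar_rule`
#' @param consequent class label (ignored when a `cpar_rule` is given)
#' @param categories integer category matrix, samples x taxa
#' @param classes class label per sample
#' @return list with `accuracy`, `n_total`, `n_g`, `m`
#' @export
laplace_accuracy <- function(antecedent, consequent, categories, classes) {
  if (inherits(antecedent, "cpar_rule")) {
    consequent <- antecedent$class
    antecedent <- antecedent$antecedent
  }
  missing <- setdiff(names(antecedent), colnames(categories))
  if (length(missing))
    stop("antecedent references unknown taxa: ", paste(missing, collapse = ", "))
  m <- length(unique(classes))
  sat <- rep(TRUE, nrow(categories))
  for (tx in names(antecedent))
    sat <- sat & categories[, tx] == antecedent[[tx]]
  n_total <- sum(sat)
  n_g <- sum(sat & classes == consequent)
  list(accuracy = (n_g + 1) / (n_total + m), n_total = n_total, n_g = n_g,
       m = m)
}

new_cpar_rule <- function(antecedent, class, lap) {
  antecedent <- antecedent[order(names(antecedent))]
  structure(list(antecedent = antecedent, class = class,
                 laplace = lap$accuracy, n_total = lap$n_total,
                 n_g = lap$n_g, m = lap$m),
            class = "cpar_rule")
}

rule_key <- function(antecedent, class) {
  paste(class, paste(sort(paste0(names(antecedent), "=", antecedent)),
                     collapse = ","))
}

#' Generate classification rules with CPAR
#'
#' Greedy FOIL-gain rule induction with example-weight decay (Classification
#' based on Predictive Association Rules). Each class is treated in turn as
#' the positive class; rules are grown literal by literal by maximum gain on
#' the decayed weights, literals whose gain is within
#' `gain_similarity_ratio` of the best spawn parallel rules, growth stops at
#' the gain floor, at purity (no negatives left), or at the antecedent length
#' cap, and after each round the weights of covered positives are multiplied
#' by `delta` until the remaining positive weight drops below
#' `total_weight_factor` of its initial total. Every emitted rule is scored
#' by Laplace accuracy against the full, unweighted data; duplicates are
#' removed. Tie-breaking is lexicographic in taxon name then ascending
#' category, making the rule set deterministic.
#'
#' @param categories integer category matrix (samples x taxa), e.g. from
#'   [discretize_quartiles()]
#' @param classes class label per sample (>= 2 classes)
#' @param params a [cpar_params()]
#' @return a `cpar_ruleset`: list of `cpar_rule` objects plus the parameters
#' @export
cpar_generate <- function(categories, classes, params = cpar_params()) {
  stopifnot(inherits(params, "cpar_params"))
  if (!is.matrix(categories) || is.null(colnames(categories)))
    stop("categories must be a matrix with taxon colnames")
  classes <- as.character(classes)
  if (length(classes) != nrow(categories))
    stop("classes length must match the number of samples")
  lv <- sort(unique(classes))
  if (length(lv) < 2) stop("need >= 2 classes")
  taxa <- colnames(categories)
  # candidate literals in deterministic order: taxon lexicographic, category asc
  cand <- expand.grid(category = 1:4, taxon = taxa, stringsAsFactors = FALSE)
  cand <- cand[order(cand$taxon, cand$category), c("taxon", "category")]

  seen <- new.env(parent = emptyenv())
  rules <- list()
  for (g in lv) {
    pos <- which(classes == g)
    neg <- which(classes != g)
    w <- rep(1, length(pos))
    total0 <- length(pos)
    iter <- 0L
    while (sum(w) > params$total_weight_factor * total0 && iter < 500L) {
      iter <- iter + 1L
      emitted <- list()
      grow <- function(lits, pos_keep, neg_keep) {
        if (length(lits) >= params$max_antecedent_length) {
          emitted[[length(emitted) + 1L]] <<- lits
          return(invisible())
        }
        p_tot <- sum(w[pos_keep])
        n_tot <- length(neg_keep)
        free <- cand[!(cand$taxon %in% names(lits)), , drop = FALSE]
        if (!nrow(free)) {
          if (length(lits)) emitted[[length(emitted) + 1L]] <<- lits
          return(invisible())
        }
        gains <- numeric(nrow(free))
        for (i in seq_len(nrow(free))) {
          sat_p <- categories[pos[pos_keep], free$taxon[i]] == free$category[i]
          sat_n <- categories[neg[neg_keep], free$taxon[i]] == free$category[i]
          gains[i] <- foil_gain(sum(w[pos_keep][sat_p]), sum(sat_n),
                                p_tot, n_tot)
        }
        best <- max(gains)
        if (!is.finite(best) || best < params$min_gain) {
          if (length(lits)) emitted[[length(emitted) + 1L]] <<- lits
          return(invisible())
        }
        sel <- which(gains >= params$gain_similarity_ratio * best &
                     gains >= params$min_gain)
        for (i in sel) {
          lit <- stats::setNames(free$category[i], free$taxon[i])
          nl <- c(lits, lit)
          pk <- pos_keep[categories[pos[pos_keep], free$taxon[i]] == free$category[i]]
          nk <- neg_keep[categories[neg[neg_keep], free$taxon[i]] == free$category[i]]
          if (!length(nk)) {
            emitted[[length(emitted) + 1L]] <<- nl
          } else {
            grow(nl, pk, nk)
          }
        }
        invisible()
      }
      grow(stats::setNames(integer(0), character(0)),
           seq_along(pos), seq_along(neg))
      if (!length(emitted)) break
      covered <- rep(FALSE, length(pos))
      for (lits in emitted) {
        sat <- rep(TRUE, length(pos))
        for (tx in names(lits)) sat <- sat & categories[pos, tx] == lits[[tx]]
        covered <- covered | sat
        key <- rule_key(lits, g)
        if (is.null(seen[[key]])) {
          seen[[key]] <- TRUE
          lap <- laplace_accuracy(lits, g, categories, classes)
          rules[[length(rules) + 1L]] <- new_cpar_rule(lits, g, lap)
        }
      }
      if (!any(covered)) break
      w[covered] <- w[covered] * params$delta
    }
  }
  structure(list(rules = rules, params = params, classes = lv),
            class = "cpar_ruleset")
}

#' Filter and order a rule set by Laplace accuracy
#'
#' Keeps rules whose Laplace accuracy is at least `min_accuracy` (boundary
#' inclusive), sorted by descending accuracy then ascending antecedent
#' length.
#'
#' @param ruleset a `cpar_ruleset`
#' @param min_accuracy accuracy floor (default from the ruleset parameters,
#'   0.80)
#' @return a filtered `cpar_ruleset`
#' @export
filter_rules <- function(ruleset, min_accuracy = NULL) {
  stopifnot(inherits(ruleset, "cpar_ruleset"))
  if (is.null(min_accuracy)) min_accuracy <- ruleset$params$min_rule_accuracy
  keep <- Filter(function(r) r$laplace >= min_accuracy, ruleset$rules)
  if (length(keep)) {
    acc <- vapply(keep, `[[`, numeric(1), "laplace")
    len <- vapply(keep, function(r) length(r$antecedent), integer(1))
    keep <- keep[order(-acc, len)]
  }
  structure(list(rules = keep, params = ruleset$params,
                 classes = ruleset$classes),
            class = "cpar_ruleset")
}

#' Render a rule as an interval condition on the percent scale
#'
#' Translates category codes back into abundance intervals using a breakpoint
#' table: category 1 becomes "< cut1" (or "= cut1" for a minimum-collision
#' cut such as Prevotella's zero class), 4 becomes "> cut3", and the middle
#' categories closed ranges, followed by the class and accuracy as a
#' percentage.
#'
#' @param rule a `cpar_rule`
#' @param breakpoints breakpoint data.frame covering the rule's taxa
#' @return a single character string
#' @export
explain_rule <- function(rule, breakpoints) {
  stopifnot(inherits(rule, "cpar_rule"))
  missing <- setdiff(names(rule$antecedent), breakpoints$taxon)
  if (length(missing))
    stop("no breakpoints for: ", paste(missing, collapse = ", "))
  parts <- vapply(names(rule$antecedent), function(tx) {
    i <- match(tx, breakpoints$taxon)
    cuts_num <- as.numeric(breakpoints[i, c("cut1", "cut2", "cut3")])
    cuts <- sub("[.]?0+$", "",
                format(signif(cuts_num, 3), trim = TRUE, scientific = FALSE))
    at_min1 <- if ("at_min1" %in% names(breakpoints))
      isTRUE(breakpoints$at_min1[i]) else cuts_num[1] == 0
    switch(rule$antecedent[[tx]],
           if (at_min1) paste0(tx, " = ", cuts[1]) else paste0(tx, " < ", cuts[1]),
           paste0(tx, " ", cuts[1], "-", cuts[2]),
           paste0(tx, " ", cuts[2], "-", cuts[3]),
           paste0(tx, " > ", cuts[3]))
  }, character(1))
  cond <- if (length(parts) > 1)
    paste(paste(parts[-length(parts)], collapse = ", "), "and",
          parts[length(parts)])
  else parts
  sprintf("If the compositions of %s; the sample is %s with %d%% accuracy",
          cond, rule$class, round(100 * rule$laplace))
}

#' Predict class labels from a rule set
#'
#' CPAR best-k prediction: for each sample, the Laplace accuracies of the
#' best (at most) `k` matching rules are averaged per class and the highest
#' average wins; ties go to the class holding the single best matching rule.
#' Samples matching no rule abstain (`NA` class).
#'
#' @param object a `cpar_ruleset`
#' @param newdata integer category matrix (samples x taxa)
#' @param k rules averaged per class (default: ruleset parameter, 5)
#' @param ... unused
#' @return data.frame with `class` (NA = abstain) and `score`
#' @export
predict.cpar_ruleset <- function(object, newdata, k = NULL, ...) {
  if (!length(object$rules)) stop("empty rule set")
  if (is.null(k)) k <- object$params$k
  res <- data.frame(class = rep(NA_character_, nrow(newdata)),
                    score = NA_real_, stringsAsFactors = FALSE)
  for (s in seq_len(nrow(newdata))) {
    match_acc <- list()
    best_rule_class <- NA_character_; best_rule_acc <- -Inf
    for (r in object$rules) {
      if (all(newdata[s, names(r$antecedent)] == r$antecedent)) {
        match_acc[[r$class]] <- c(match_acc[[r$class]], r$laplace)
        if (r$laplace > best_rule_acc) {
          best_rule_acc <- r$laplace; best_rule_class <- r$class
        }
      }
    }
    if (!length(match_acc)) next
    scores <- vapply(match_acc, function(a)
      mean(sort(a, decreasing = TRUE)[seq_len(min(k, length(a)))]), numeric(1))
    top <- names(scores)[scores == max(scores)]
    res$class[s] <- if (length(top) > 1) best_rule_class else top
    res$score[s] <- max(scores)
  }
  res
}

#' @export
format.cpar_rule <- function(x, ...) {
  sprintf("%s -> %s (%.2f; %d/%d)",
          paste(sprintf("%s={%d}", names(x$antecedent), x$antecedent),
                collapse = ", "),
          x$class, x$laplace, x$n_g, x$n_total)
}

#' @export
print.cpar_rule <- function(x, ...) {
  cat(format(x), "\n")
  invisible(x)
}

#' @export
print.cpar_ruleset <- function(x, ...) {
  cat("cpar_ruleset with", length(x$rules), "rules\n")
  for (r in x$rules) cat(" ", format(r), "\n")
  invisible(x)
}

#' Serialize a rule set as JSON
#'
#' @param ruleset a `cpar_ruleset`
#' @param path file path
#' @export
write_rules_json <- function(ruleset, path) {
  out <- lapply(ruleset$rules, function(r)
    list(antecedent = as.list(r$antecedent), class = r$class,
         laplace_accuracy = r$laplace, n_total = r$n_total, n_g = r$n_g,
         m = r$m))
  jsonlite::write_json(list(rules = out, params = unclass(ruleset$params)),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
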