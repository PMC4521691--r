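# small cohort configurations used across tests; taxa specs are minimal so the
# generator calibration panel stays cheap and is cached within the session

tiny_taxa_spec <- function(median_normal = c(40, 5),
                           median_obese = c(20, 10),
                           dispersion = 0.5,
                           zero_normal = c(0, 0), zero_obese = c(0, 0)) {
  data.frame(taxon = c("TaxA", "TaxB"),
             family = c("FamA", "FamB"),
             phylum = c("Bacteroidetes", "Firmicutes"),
             median_normal = median_normal, median_obese = median_obese,
             dispersion_normal = dispersion, dispersion_obese = dispersion,
             zero_normal = zero_normal, zero_obese = zero_obese,
             stringsAsFactors = FALSE)
}

no_pairs <- function() {
  data.frame(taxon = character(0), covariate = character(0), r = numeric(0),
             stringsAsFactors = FALSE)
}

no_taxon_cor <- function() {
  data.frame(taxon1 = character(0), taxon2 = character(0), rho = numeric(0),
             stringsAsFactors = FALSE)
}

# two identical groups: every downstream group test is null by construction
null_config <- function(seed = 1L, n_per_group = 67L) {
  cohort_config(n_per_group = n_per_group,
                taxa_spec = tiny_taxa_spec(median_normal = c(30, 5),
                                           median_obese = c(30, 5)),
                male_fraction = c(normal = 0.5, obese = 0.5),
                planted_correlations = no_pairs(),
                taxon_latent_cor = no_taxon_cor(),
                seed = seed)
}

# small separable category dataset: TaxX category 4 <=> class A
separable_toy <- function() {
  cats <- matrix(c(rep(4L, 10), rep(1L, 10),
                   rep(2L, 10), rep(3L, 10)), ncol = 2,
                 dimnames = list(sprintf("s%02d", 1:20), c("TaxX", "TaxY")))
  list(categories = cats, classes = rep(c("A", "B"), each = 10))
}

# exhaustive Laplace scoring of every antecedent up to a given length
enumerate_rules <- function(categories, classes, max_len = 3L) {
  taxa <- colnames(categories)
  out <- list()
  for (len in seq_len(min(max_len, length(taxa)))) {
    for (tx_set in utils::combn(taxa, len, simplify = FALSE)) {
      grids <- do.call(expand.grid, rep(list(1:4), len))
      for (i in seq_len(nrow(grids))) {
        ante <- stats::setNames(as.integer(grids[i, ]), tx_set)
        for (g in unique(classes)) {
          lap <- laplace_accuracy(ante, g, categories, classes)
          out[[length(out) + 1L]] <- list(key = gutrules:::rule_key(ante, g),
                                          accuracy = lap$accuracy,
                                          n_total = lap$n_total,
                                          n_g = lap$n_g)
        }
      }
    }
  }
  out
}

# brute-force Laplace accuracy by row scan, independent of the implementation
brute_laplace <- function(antecedent, consequent, categories, classes) {
  m <- length(unique(classes))
  n_total <- 0L; n_g <- 0L
  for (i in seq_len(nrow(categories))) {
    ok <- TRUE
    for (tx in names(antecedent))
      if (categories[i, tx] != antecedent[[tx]]) { ok <- FALSE; break }
    if (ok) {
      n_total <- n_total + 1L
      if (classes[i] == consequent) n_g <- n_g + 1L
    }
  }
  (n_g + 1) / (n_total + m)
}
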