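#' Default pipeline configuration
#'
#' All analysis thresholds live here rather than in code: the read filters
#' (mean quality 25, length 300 bp, rejection at 2 ambiguous bases), the
#' 4-category quartile discretization, the 0.80 rule-accuracy floor and the
#' 0.05 FDR significance level.
#'
#' @return a nested list; see [run_pipeline()]
#' @export
default_pipeline_config <- function() {
  list(
    seed = 1L,
    output_dir = "gutrules_output",
    input = list(metadata_csv = NULL, composition_tsv = NULL, fastq = NULL),
    stages = list(simulate = TRUE, qc = FALSE, abundance = TRUE,
                  diversity = TRUE, stats = TRUE, correlate = TRUE,
                  mine = TRUE),
    synthetic = list(n_per_group = 67L),
    qc = list(min_mean_quality = 25, min_length = 300L,
              ambiguous_reject_threshold = 2L),
    diversity = list(otus_per_taxon = 20L, depth_range = c(2065L, 42522L),
                     n_axes = 2L),
    stats = list(fdr_alpha = 0.05),
    rules = list(n_categories = 4L, min_rule_accuracy = 0.80,
                 max_antecedent_length = 3L, min_gain = 0.7,
                 delta = 2 / 3, total_weight_factor = 0.05,
                 gain_similarity_ratio = 0.99, k = 5L,
                 taxa_selection = "significant")
  )
}

#' Read a pipeline configuration from YAML
#'
#' Fields absent from the file fall back to [default_pipeline_config()].
#'
#' @param path YAML file path
#' @return a configuration list
#' @export
read_pipeline_config <- function(path) {
  user <- yaml::read_yaml(path)
  merge_cfg <- function(def, usr) {
    for (nm in names(usr)) {
      def[[nm]] <- if (is.list(def[[nm]]) && is.list(usr[[nm]]))
        merge_cfg(def[[nm]], usr[[nm]]) else usr[[nm]]
    }
    def
  }
  merge_cfg(default_pipeline_config(), user)
}

stage_seed <- function(seed, stage) {
  offsets <- c(simulate = 1L, otu = 2L, lilliefors = 3L, permute = 4L)
  as.integer((as.numeric(seed) * 1009 + 104729 * offsets[[stage]]) %% 2147483647)
}

#' Run the full analysis pipeline
#'
#' Executes the enabled stages in order: synthesize-or-load the cohort,
#' optional FASTQ QC, rank aggregation and composition summaries, alpha/beta
#' diversity with ordination, group statistics with FDR correction,
#' age/gender-adjusted correlations, and quartile-discretized CPAR rule
#' mining. All artifacts are written under `config$output_dir` together with
#' a JSON run manifest (parameters, seed, file checksums) that fully
#' determines the run.
#'
#' @param config configuration list, see [default_pipeline_config()]
#' @return (invisibly) a report list with every stage's in-memory result and
#'   the manifest
#' @export
run_pipeline <- function(config = default_pipeline_config()) {
  dir.create(config$output_dir, showWarnings = FALSE, recursive = TRUE)
  report <- list(config = config)
  fail <- function(stage, e) stop("pipeline stage '", stage, "' failed: ",
                                  conditionMessage(e), call. = FALSE)

  # --- cohort: synthesize or load -------------------------------------------
  if (isTRUE(config$stages$simulate)) {
    tryCatch({
      cc <- cohort_config(n_per_group = config$synthetic$n_per_group,
                          seed = stage_seed(config$seed, "simulate"))
      cohort <- generate_cohort(cc)
      write_cohort(cohort, cc, config$output_dir)
    }, error = function(e) fail("simulate", e))
  } else {
    tryCatch({
      cohort <- list(metadata = read_metadata_csv(config$input$metadata_csv),
                     composition = read_composition_tsv(config$input$composition_tsv))
    }, error = function(e) fail("load", e))
  }
  report$metadata <- cohort$metadata
  report$composition <- cohort$composition

  # --- read QC (only when a FASTQ is supplied) ------------------------------
  if (isTRUE(config$stages$qc) && !is.null(config$input$fastq)) {
    tryCatch({
      qp <- qc_params(max_ambiguous = config$qc$ambiguous_reject_threshold - 1L,
                      min_mean_quality = config$qc$min_mean_quality,
                      min_length = config$qc$min_length)
      report$qc <- filter_fastq(config$input$fastq,
                                file.path(config$output_dir, "filtered.fastq"),
                                qp,
                                file.path(config$output_dir, "qc_summary.json"))
    }, error = function(e) fail("qc", e))
  }

  # --- composition summaries -------------------------------------------------
  if (isTRUE(config$stages$abundance)) {
    tryCatch({
      report$mean_composition <- lapply(
        c(genus = "genus", family = "family", phylum = "phylum"),
        function(rk) group_mean_summary(cohort$composition, cohort$metadata, rk))
      report$fb_ratio <- fb_ratio(cohort$composition, cohort$metadata)
      jsonlite::write_json(
        list(mean_composition = report$mean_composition,
             fb_ratio = report$fb_ratio$by_group,
             fb_undefined = report$fb_ratio$n_undefined),
        file.path(config$output_dir, "composition_summary.json"),
        auto_unbox = TRUE, digits = NA, dataframe = "rows")
    }, error = function(e) fail("abundance", e))
  }

  # --- diversity -------------------------------------------------------------
  if (isTRUE(config$stages$diversity)) {
    tryCatch({
      otu <- generate_otu_counts(cohort$composition,
                                 config$diversity$otus_per_taxon,
                                 config$diversity$depth_range,
                                 seed = stage_seed(config$seed, "otu"))
      report$shannon <- shannon_index(unclass(otu))
      dm <- bray_curtis(otu)
      report$ordination <- ordinate(dm, config$diversity$n_axes)
      write_distance_tsv(dm, file.path(config$output_dir, "bray_curtis.tsv"))
      utils::write.csv(
        data.frame(sample = rownames(report$ordination$coordinates),
                   report$ordination$coordinates,
                   shannon = report$shannon),
        file.path(config$output_dir, "diversity.csv"), row.names = FALSE)
    }, error = function(e) fail("diversity", e))
  }

  # --- group statistics ------------------------------------------------------
  if (isTRUE(config$stages$stats)) {
    tryCatch({
      report$genus_stats <- compare_groups(cohort$composition, cohort$metadata,
                                           "genus")
      report$family_stats <- compare_groups(cohort$composition, cohort$metadata,
                                            "family")
      md <- cohort$metadata
      gender_tab <- table(md$gender, md$group)
      report$gender_test <- chi_square_2x2(gender_tab)
      report$covariate_tests <- do.call(rbind, lapply(
        c("age", "bmi_zscore", "glucose", "tg", "tchol", "hdlc", "hs_crp"),
        function(cv) {
          tt <- t_test_groups(md[[cv]][md$group == "normal"],
                              md[[cv]][md$group == "obese"])
          data.frame(covariate = cv, t = tt$t, p = tt$p)
        }))
      for (nm in c("genus_stats", "family_stats"))
        utils::write.table(report[[nm]],
                           file.path(config$output_dir, paste0(nm, ".tsv")),
                           sep = "\t", quote = FALSE, row.names = FALSE)
    }, error = function(e) fail("stats", e))
  }

  # --- adjusted correlations -------------------------------------------------
  if (isTRUE(config$stages$correlate)) {
    tryCatch({
      sig <- report$genus_stats$taxon[
        report$genus_stats$p_adjusted < config$stats$fdr_alpha]
      if (length(sig)) {
        report$correlations <- taxa_covariate_correlation(
          cohort$composition, cohort$metadata, sig)
        utils::write.table(report$correlations,
                           file.path(config$output_dir, "correlations.tsv"),
                           sep = "\t", quote = FALSE, row.names = FALSE)
      }
    }, error = function(e) fail("correlate", e))
  }

  # --- rule mining -----------------------------------------------------------
  if (isTRUE(config$stages$mine)) {
    tryCatch({
      rl <- config$rules
      genus_ab <- subset_rank(cohort$composition, "genus")$abundance
      taxa <- if (identical(rl$taxa_selection, "median_positive")) {
        colnames(genus_ab)[apply(genus_ab, 2, stats::median) > 0]
      } else if (identical(rl$taxa_selection, "significant")) {
        report$genus_stats$taxon[report$genus_stats$p_adjusted <
                                   config$stats$fdr_alpha]
      } else rl$taxa_selection
      if (length(taxa) < 1) stop("no taxa selected for rule mining")
      disc <- discretize_quartiles(genus_ab, taxa)
      cls <- cohort$metadata$group[
        match(rownames(genus_ab), cohort$metadata$subject_id)]
      pars <- cpar_params(min_gain = rl$min_gain, delta = rl$delta,
                          total_weight_factor = rl$total_weight_factor,
                          gain_similarity_ratio = rl$gain_similarity_ratio,
                          max_antecedent_length = rl$max_antecedent_length,
                          min_rule_accuracy = rl$min_rule_accuracy, k = rl$k)
      all_rules <- cpar_generate(disc$categories, cls, pars)
      kept <- filter_rules(all_rules)
      report$breakpoints <- disc$breakpoints
      report$rules <- kept
      report$rules_all <- all_rules
      write_rules_json(kept, file.path(config$output_dir, "rules.json"))
      utils::write.table(disc$breakpoints,
                         file.path(config$output_dir, "breakpoints.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
      writeLines(c(vapply(kept$rules, format, character(1)),
                   "",
                   vapply(kept$rules, explain_rule, character(1),
                          breakpoints = disc$breakpoints)),
                 file.path(config$output_dir, "rules.txt"))
    }, error = function(e) fail("mine", e))
  }

  # --- manifest --------------------------------------------------------------
  files <- list.files(config$output_dir, full.names = TRUE, recursive = TRUE)
  files <- files[!grepl("manifest[.]json$", files)]
  manifest <- list(
    package = "gutrules",
    version = as.character(utils::packageVersion("gutrules")),
    r_version = paste(R.version$major, R.version$minor, sep = "."),
    seed = config$seed,
    config = config,
    checksums = as.list(tools::md5sum(sort(files)))
  )
  jsonlite::write_json(manifest,
                       file.path(config$output_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  report$manifest <- manifest
  invisible(report)
}
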