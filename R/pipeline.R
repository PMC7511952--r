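# Sequential orchestration of the full screen -> validate -> evaluate flow:
# genomic (variant filter, copy number, association), expression (normalize,
# volcano, abundance), methylation (marker screen on the screening set),
# validation (Mann-Whitney confirmation of candidate regions on the
# validation and re-validation sets), performance (stratified Table-style
# report on all baseline samples) and response (paired delta monitoring).
# The screening-set statistics never read held-out samples.

#' Pipeline configuration
#'
#' All stage thresholds with their published defaults, cohort sizes for the
#' simulate stage, stage toggles and the master seed. The methylation
#' dichotomization cutoff used by the performance stage has no default: the
#' clinically calibrated value is assay-specific and must be supplied (the
#' example config under `inst/extdata` ships 0.15 as a documented,
#' non-canonical placeholder).
#'
#' @param seed master seed for the simulate stage.
#' @param simulate generate inputs with [simulate_cohort()] (default TRUE);
#'   when FALSE, `input_dir` must contain per-set bundle directories
#'   `screening/`, `validation/`, `revalidation/` written by
#'   [write_cohort_bundle()].
#' @param input_dir directory of pre-existing bundles (when
#'   `simulate = FALSE`).
#' @param sim_config a [simulation_config()] (its `seed` is overridden by
#'   `seed`).
#' @param cohort_sizes named list of `c(n_pcr, n_nonpcr)` per set; defaults
#'   mirror a 36/47/55 screening/validation/re-validation split.
#' @param stages character vector of stages to run.
#' @param variant_strand_rule,cnv_gain,cnv_loss genomic-stage thresholds.
#' @param volcano_p,volcano_fc,min_intensity,expression_test
#'   expression-stage thresholds.
#' @param beta_max,beta_cut,acc_threshold,spec_threshold,min_consecutive,max_gap
#'   methylation-stage thresholds.
#' @param validation_alpha Mann-Whitney gate for (re-)validation (default
#'   0.05).
#' @param methylation_cutoff dichotomization cutoff for the performance
#'   stage (required if that stage runs).
#' @param age_breaks age strata boundaries (default `c(45, 55)`).
#' @param delta_convention,delta_threshold response-stage settings.
#' @return a list of class `"pipeline_config"`.
#' @export
pipeline_config <- function(seed = 1,
                            simulate = TRUE,
                            input_dir = NULL,
                            sim_config = simulation_config(),
                            cohort_sizes = list(
                              screening = c(n_pcr = 14, n_nonpcr = 20),
                              validation = c(n_pcr = 17, n_nonpcr = 30),
                              revalidation = c(n_pcr = 17, n_nonpcr = 38)),
                            stages = c("genomic", "expression", "methylation",
                                       "validation", "performance",
                                       "response"),
                            variant_strand_rule = "per_strand",
                            cnv_gain = 2, cnv_loss = 0.5,
                            volcano_p = 0.001, volcano_fc = 4,
                            min_intensity = 0.5,
                            expression_test = "welch",
                            beta_max = 0.2, beta_cut = 0.3,
                            acc_threshold = 0.67, spec_threshold = 0.85,
                            min_consecutive = 3, max_gap = 0,
                            validation_alpha = 0.05,
                            methylation_cutoff = NULL,
                            age_breaks = c(45, 55),
                            delta_convention = "absolute_points",
                            delta_threshold = 50) {
  cfg <- list(seed = seed, simulate = simulate, input_dir = input_dir,
              sim_config = sim_config, cohort_sizes = cohort_sizes,
              stages = stages, variant_strand_rule = variant_strand_rule,
              cnv_gain = cnv_gain, cnv_loss = cnv_loss,
              volcano_p = volcano_p, volcano_fc = volcano_fc,
              min_intensity = min_intensity,
              expression_test = expression_test, beta_max = beta_max,
              beta_cut = beta_cut, acc_threshold = acc_threshold,
              spec_threshold = spec_threshold,
              min_consecutive = min_consecutive, max_gap = max_gap,
              validation_alpha = validation_alpha,
              methylation_cutoff = methylation_cutoff,
              age_breaks = age_breaks,
              delta_convention = delta_convention,
              delta_threshold = delta_threshold)
  stopifnot(cfg$cnv_gain > cfg$cnv_loss, cfg$volcano_p > 0,
            cfg$volcano_fc >= 1, cfg$beta_max > 0, cfg$beta_max <= 1,
            cfg$beta_cut > 0, cfg$beta_cut < 1, cfg$min_consecutive >= 1,
            cfg$max_gap >= 0, cfg$validation_alpha > 0,
            cfg$validation_alpha < 1, cfg$delta_threshold >= 0)
  structure(cfg, class = "pipeline_config")
}

config_to_yaml <- function(config) {
  plain <- unclass(config)
  plain$sim_config <- unclass(plain$sim_config)
  # named atomic vectors render as plain sequences in YAML; keep the names
  plain$cohort_sizes <- lapply(plain$cohort_sizes, as.list)
  yaml::as.yaml(plain)
}

#' Read/write a pipeline config as YAML
#' @param path YAML file path.
#' @return for `read_pipeline_config`, a `"pipeline_config"`; for
#'   `write_pipeline_config`, `path` invisibly.
#' @export
read_pipeline_config <- function(path) {
  raw <- yaml::read_yaml(path)
  sim <- raw$sim_config
  raw$sim_config <- NULL
  args <- raw
  if (!is.null(sim)) {
    args$sim_config <- do.call(simulation_config, sim)
  }
  # cohort_sizes come back as plain lists of numerics
  if (!is.null(args$cohort_sizes)) {
    args$cohort_sizes <- lapply(args$cohort_sizes, unlist)
  }
  do.call(pipeline_config, args)
}

#' @rdname read_pipeline_config
#' @param config a `"pipeline_config"`.
#' @export
write_pipeline_config <- function(config, path) {
  writeLines(config_to_yaml(config), path)
  invisible(path)
}

read_cohort_bundle <- function(dir) {
  bm <- read_beta_matrix(file.path(dir, "beta.tsv"),
                         file.path(dir, "annotation.tsv"))
  ref <- read_beta_matrix(file.path(dir, "reference.tsv"),
                          file.path(dir, "annotation.tsv"))
  list(samples = read_sample_sheet(file.path(dir, "samples.tsv")),
       beta = bm$beta, annotation = bm$annotation, reference = ref$beta,
       expression = read_expression_matrix(file.path(dir, "expression.tsv")),
       variants = read_variant_table(file.path(dir, "variants.tsv")),
       coverage = utils::read.delim(file.path(dir, "coverage.tsv")),
       paired_beta = read_paired_levels(file.path(dir, "paired_beta.tsv")),
       paired_ki67 = read_paired_levels(file.path(dir, "paired_ki67.tsv")))
}

write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Run the full marker-discovery pipeline
#'
#' Executes the enabled stages in order on the three cohort sets and writes
#' per-stage TSV outputs, a `manifest.yaml` (config, config hash, seed,
#' package version, per-stage status and funnel counts) and a plain-text
#' `run.log` with in/out counts of every filter. Identical config and seed
#' give identical outputs.
#'
#' @param config a [pipeline_config()].
#' @param out_dir run directory (created; stage outputs are overwritten).
#' @return invisibly, a list with the stage results (`genomic`,
#'   `expression`, `methylation`, `validation`, `performance`, `response`),
#'   the `manifest`, and `out_dir`.
#' @export
run_pipeline <- function(config, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  log_path <- file.path(out_dir, "run.log")
  log_lines <- character(0)
  note <- function(...) {
    line <- sprintf(...)
    log_lines <<- c(log_lines, line)
  }
  status <- stats::setNames(rep("skipped", 6),
                            c("genomic", "expression", "methylation",
                              "validation", "performance", "response"))
  results <- list()

  # --- inputs ---------------------------------------------------------------
  sets <- c("screening", "validation", "revalidation")
  if (isTRUE(config$simulate)) {
    bundles <- lapply(sets, function(set) {
      sizes <- config$cohort_sizes[[set]]
      sc <- config$sim_config
      sc$seed <- as.integer(config$seed)
      sc$n_pcr <- unname(sizes["n_pcr"])
      sc$n_nonpcr <- unname(sizes["n_nonpcr"])
      simulate_cohort(sc, cohort_set = set)
    })
    names(bundles) <- sets
    note("simulate: generated %s cohorts with seed %d",
         paste(sets, collapse = "/"), config$seed)
  } else {
    if (is.null(config$input_dir)) {
      abort_stage("pipeline", "input_dir required when simulate = FALSE")
    }
    bundles <- lapply(sets, function(set) {
      read_cohort_bundle(file.path(config$input_dir, set))
    })
    names(bundles) <- sets
    note("inputs: read cohorts from %s", config$input_dir)
  }
  scr <- bundles$screening
  scr_outcomes <- stats::setNames(scr$samples$pcr, scr$samples$sample_id)

  # --- genomic --------------------------------------------------------------
  if ("genomic" %in% config$stages) {
    fv <- filter_variants(scr$variants, config$variant_strand_rule)
    cnv <- call_copy_number(
      stats::setNames(scr$coverage$tumor_depth, scr$coverage$region_id),
      stats::setNames(scr$coverage$normal_depth, scr$coverage$region_id),
      gain_threshold = config$cnv_gain, loss_threshold = config$cnv_loss)
    note("genomic: %d variants in, %d retained; %d regions, %d gains, %d losses",
         nrow(scr$variants), nrow(fv$retained), nrow(cnv),
         sum(cnv$state == "gain"), sum(cnv$state == "loss"))
    mutated <- stats::setNames(
      scr$samples$sample_id %in% fv$retained$sample_id,
      scr$samples$sample_id)
    assoc <- tryCatch(association_test_binary(mutated, scr_outcomes),
                      error = function(e) NULL)
    write_tsv(fv$retained, file.path(out_dir, "variants_retained.tsv"))
    write_tsv(fv$decisions, file.path(out_dir, "variant_decisions.tsv"))
    write_tsv(cnv, file.path(out_dir, "copy_number.tsv"))
    results$genomic <- list(filter = fv, cnv = cnv, association = assoc)
    status["genomic"] <- "run"
  }

  # --- expression -----------------------------------------------------------
  if ("expression" %in% config$stages) {
    norm <- normalize_expression(scr$expression)
    volcano <- volcano_screen(norm, scr_outcomes,
                              p_threshold = config$volcano_p,
                              fc_threshold = config$volcano_fc,
                              test = config$expression_test)
    abundant <- abundance_filter(volcano, config$min_intensity)
    note("expression: %d genes, %d selected, %d abundant",
         nrow(volcano), sum(volcano$selected), length(abundant))
    write_tsv(volcano, file.path(out_dir, "volcano.tsv"))
    results$expression <- list(volcano = volcano, abundant = abundant)
    status["expression"] <- "run"
  }

  # --- methylation screen (screening set only) ------------------------------
  if ("methylation" %in% config$stages) {
    screen <- screen_methylation_markers(
      scr$beta, scr$annotation, scr$reference, scr_outcomes,
      beta_max = config$beta_max, beta_cut = config$beta_cut,
      acc_threshold = config$acc_threshold,
      spec_threshold = config$spec_threshold,
      min_consecutive = config$min_consecutive, max_gap = config$max_gap)
    note("methylation funnel: %s",
         paste(names(screen$funnel), screen$funnel, sep = "=",
               collapse = ", "))
    write_tsv(screen$sites, file.path(out_dir, "methylation_sites.tsv"))
    write_tsv(screen$regions[, setdiff(names(screen$regions), "per_probe")],
              file.path(out_dir, "methylation_regions.tsv"))
    results$methylation <- screen
    status["methylation"] <- "run"
  }

  # --- validation / re-validation -------------------------------------------
  if ("validation" %in% config$stages) {
    if (is.null(results$methylation)) {
      abort_stage("validation", "methylation stage is required but was skipped")
    }
    screen <- results$methylation
    validated <- screen$regions
    val_rows <- list()
    for (set in c("validation", "revalidation")) {
      if (nrow(validated) == 0) break
      b <- bundles[[set]]
      lv <- predict(screen, b$beta)
      keep <- logical(nrow(validated))
      for (i in seq_len(nrow(validated))) {
        mw <- validate_marker_levels(lv[validated$marker_id[i], ],
                                     b$samples$pcr)
        val_rows[[length(val_rows) + 1]] <- data.frame(
          set = set, marker_id = validated$marker_id[i], p = mw$p)
        keep[i] <- mw$p < config$validation_alpha
      }
      note("%s: %d candidates in, %d confirmed at alpha %.3g",
           set, nrow(validated), sum(keep), config$validation_alpha)
      validated <- validated[keep, , drop = FALSE]
    }
    val_tab <- if (length(val_rows) > 0) {
      do.call(rbind, val_rows)
    } else {
      data.frame(set = character(0), marker_id = character(0), p = numeric(0))
    }
    write_tsv(val_tab, file.path(out_dir, "validation_tests.tsv"))
    results$validation <- list(tests = val_tab, validated = validated)
    status["validation"] <- "run"
  }

  # --- performance ----------------------------------------------------------
  if ("performance" %in% config$stages) {
    if (is.null(results$validation) ||
        nrow(results$validation$validated) == 0) {
      note("performance: no validated marker; stage not applicable")
      status["performance"] <- "no_marker"
    } else {
      if (is.null(config$methylation_cutoff)) {
        abort_stage("performance",
                    "methylation_cutoff must be set to run the performance stage")
      }
      marker <- results$validation$validated$marker_id[1]
      screen <- results$methylation
      all_samples <- do.call(rbind, lapply(bundles, `[[`, "samples"))
      rownames(all_samples) <- NULL
      levels <- unlist(lapply(bundles, function(b) {
        predict(screen, b$beta)[marker, ]
      }))
      names(levels) <- all_samples$sample_id
      meth_calls <- dichotomize(levels, config$methylation_cutoff)
      er_calls <- stats::setNames(all_samples$er_status == "negative",
                                  all_samples$sample_id)
      report <- stratified_report(all_samples, meth_calls, er_calls,
                                  config$age_breaks)
      note("performance: marker %s over %d samples in %d strata", marker,
           nrow(all_samples), length(report$strata))
      write_tsv(as.data.frame(report),
                file.path(out_dir, "performance_report.tsv"))
      results$performance <- list(marker = marker, report = report,
                                  levels = levels)
      status["performance"] <- "run"
    }
  }

  # --- response monitoring --------------------------------------------------
  if ("response" %in% config$stages) {
    pairs <- do.call(rbind, lapply(bundles, `[[`, "paired_beta"))
    pairs_ki <- do.call(rbind, lapply(bundles, `[[`, "paired_ki67"))
    rownames(pairs) <- rownames(pairs_ki) <- NULL
    cls <- classify_large_decrease(pairs, config$delta_threshold,
                                   config$delta_convention)
    chg <- paired_change_test(pairs$baseline[pairs$pcr],
                              pairs$on_treatment[pairs$pcr])
    cmp <- compare_response_markers(methylation = pairs, ki67 = pairs_ki,
                                    threshold = config$delta_threshold,
                                    convention = config$delta_convention)
    note("response: %d pairs, %d large decreases of which %d pCR",
         nrow(pairs), cls$summary$n_large, cls$summary$n_large_pcr)
    write_tsv(cls$classified, file.path(out_dir, "response_pairs.tsv"))
    write_tsv(cmp, file.path(out_dir, "response_comparison.tsv"))
    results$response <- list(classified = cls, change_test = chg,
                             comparison = cmp)
    status["response"] <- "run"
  }

  # --- manifest -------------------------------------------------------------
  cfg_yaml <- config_to_yaml(config)
  manifest <- list(
    package = "methmarker",
    version = as.character(utils::packageVersion("methmarker")),
    seed = config$seed,
    config_hash = config_hash(cfg_yaml),
    stages = as.list(status),
    funnel = if (!is.null(results$methylation)) {
      as.list(results$methylation$funnel)
    } else NULL,
    config = yaml::yaml.load(cfg_yaml)
  )
  writeLines(yaml::as.yaml(manifest), file.path(out_dir, "manifest.yaml"))
  writeLines(log_lines, log_path)
  invisible(list(results = results, manifest = manifest, out_dir = out_dir))
}
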