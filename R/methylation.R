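# The beta-value marker screen: restrict to CpG sites unmethylated in normal
# reference profiles, score each site as a threshold classifier of pCR in
# either direction, keep sites in CpG islands or genic regions, and call
# candidate marker regions as runs of >= 3 consecutive passing probes that
# agree in direction. The screen is exposed both as stage functions and as a
# fit-like front end, screen_methylation_markers(), returning a classed
# object with print/summary/plot/predict methods.

#' Select the normally-unmethylated CpG universe
#'
#' Keeps the probes whose beta value is below `beta_max` in every normal
#' reference profile (strict <). This restricts the screen to sites that are
#' unmethylated in normal tissue, so that hypermethylation in tumors is
#' interpretable.
#'
#' @param reference probes-by-profiles beta matrix of normal references
#'   (e.g. a mammary epithelial line and peripheral leukocytes).
#' @param beta_max exclusive upper bound (default 0.2).
#' @return character vector of probe ids in the universe.
#' @export
select_unmethylated_universe <- function(reference, beta_max = 0.2) {
  if (!is.matrix(reference) || ncol(reference) == 0) {
    abort_stage("methylation", "reference must be a non-empty beta matrix")
  }
  validate_beta_matrix(reference)
  rownames(reference)[rowSums(reference < beta_max) == ncol(reference)]
}

# vectorized two-direction classifier metrics for a beta matrix;
# returns a data.frame with one row per probe and both directions' metrics
site_metrics_matrix <- function(beta, outcomes, beta_cut = 0.3) {
  n_pcr <- sum(outcomes); n_non <- sum(!outcomes)
  if (n_pcr == 0 || n_non == 0) {
    abort_stage("methylation", "need at least one sample per outcome group")
  }
  meth <- beta > beta_cut
  m_pcr  <- rowSums(meth[, outcomes, drop = FALSE])
  m_non  <- rowSums(meth[, !outcomes, drop = FALSE])
  n <- n_pcr + n_non
  # hyper_in_pcr: methylated predicts pCR; negative class = non-pCR
  acc_pcr  <- (m_pcr + (n_non - m_non)) / n
  spec_pcr <- (n_non - m_non) / n_non
  # hyper_in_nonpcr: methylated predicts non-pCR; negative class = pCR
  acc_non  <- (m_non + (n_pcr - m_pcr)) / n
  spec_non <- (n_pcr - m_pcr) / n_pcr
  data.frame(probe_id = rownames(beta),
             acc_hyper_pcr = unname(acc_pcr),
             spec_hyper_pcr = unname(spec_pcr),
             acc_hyper_nonpcr = unname(acc_non),
             spec_hyper_nonpcr = unname(spec_non),
             stringsAsFactors = FALSE)
}

#' Threshold-classifier metrics for one CpG site
#'
#' Calls a sample methylated when its beta value exceeds `beta_cut`
#' (strict >; a value exactly at the cut is unmethylated). For direction
#' `hyper_in_pcr` the methylation call predicts pCR: accuracy is the
#' fraction of samples classified correctly and specificity is the fraction
#' of non-pCR samples called unmethylated. For `hyper_in_nonpcr` the roles
#' of the groups are swapped (specificity is computed on the pCR group, the
#' negative class for that direction).
#'
#' @param betas numeric beta values for one probe, one per sample.
#' @param outcomes logical pCR indicator per sample.
#' @param beta_cut methylation-call threshold (default 0.3).
#' @param direction `"hyper_in_pcr"` or `"hyper_in_nonpcr"`.
#' @return a list with `probe_id` (NA unless `betas` is named by a probe
#'   attribute), `direction`, `accuracy`, `specificity`.
#' @export
site_classifier_metrics <- function(betas, outcomes, beta_cut = 0.3,
                                    direction = c("hyper_in_pcr", "hyper_in_nonpcr")) {
  direction <- match.arg(direction)
  beta <- matrix(betas, nrow = 1, dimnames = list("site", NULL))
  m <- site_metrics_matrix(beta, outcomes, beta_cut)
  if (direction == "hyper_in_pcr") {
    list(direction = direction, accuracy = m$acc_hyper_pcr,
         specificity = m$spec_hyper_pcr)
  } else {
    list(direction = direction, accuracy = m$acc_hyper_nonpcr,
         specificity = m$spec_hyper_nonpcr)
  }
}

#' Screen CpG sites as differential-methylation classifiers
#'
#' Evaluates every probe in both directions (hypermethylated in pCR samples
#' or in non-pCR samples) and returns the sites passing the accuracy and
#' specificity gates (strict >) in at least one direction. When both
#' directions pass, the higher-accuracy one is recorded; exact ties break
#' toward `hyper_in_pcr`.
#'
#' @param beta probes-by-samples beta matrix, already restricted to the
#'   unmethylated universe.
#' @param outcomes logical pCR indicator per sample (named or column order).
#' @param beta_cut methylation-call threshold (default 0.3).
#' @param acc_threshold accuracy gate (default 0.67).
#' @param spec_threshold specificity gate (default 0.85).
#' @param all return all probes with a `passed` flag instead of passing only.
#' @return `data.frame` with `probe_id`, `direction`, `accuracy`,
#'   `specificity`, `passed`.
#' @export
screen_sites <- function(beta, outcomes, beta_cut = 0.3,
                         acc_threshold = 0.67, spec_threshold = 0.85,
                         all = FALSE) {
  if (nrow(beta) == 0) abort_stage("methylation", "probe universe is empty")
  if (!is.null(names(outcomes))) {
    if (!setequal(names(outcomes), colnames(beta))) {
      abort_stage("methylation", "outcome names do not match beta samples")
    }
    outcomes <- outcomes[colnames(beta)]
  }
  m <- site_metrics_matrix(beta, outcomes, beta_cut)
  pass_pcr <- m$acc_hyper_pcr > acc_threshold & m$spec_hyper_pcr > spec_threshold
  pass_non <- m$acc_hyper_nonpcr > acc_threshold & m$spec_hyper_nonpcr > spec_threshold
  use_pcr <- pass_pcr & (!pass_non | m$acc_hyper_pcr >= m$acc_hyper_nonpcr)
  out <- data.frame(
    probe_id = m$probe_id,
    direction = ifelse(use_pcr, "hyper_in_pcr", "hyper_in_nonpcr"),
    accuracy = ifelse(use_pcr, m$acc_hyper_pcr, m$acc_hyper_nonpcr),
    specificity = ifelse(use_pcr, m$spec_hyper_pcr, m$spec_hyper_nonpcr),
    passed = pass_pcr | pass_non,
    stringsAsFactors = FALSE
  )
  if (all) out else out[out$passed, , drop = FALSE]
}

#' Keep sites located in CpG islands or genic regions
#'
#' @param sites a site `data.frame` with a `probe_id` column.
#' @param annotation probe annotation covering every site.
#' @return the subset of `sites` whose `region_class` is `cpg_island` or
#'   `genic`, input order preserved.
#' @export
annotation_filter <- function(sites, annotation) {
  idx <- match(sites$probe_id, annotation$probe_id)
  if (any(is.na(idx))) {
    abort_stage("methylation", "sites missing annotation: ",
                paste(sites$probe_id[is.na(idx)], collapse = ", "))
  }
  sites[annotation$region_class[idx] %in% c("cpg_island", "genic"), ,
        drop = FALSE]
}

#' Aggregate passing sites into consecutive-probe marker regions
#'
#' Within each annotated region, the region's full probe list is ordered by
#' genomic position; a candidate marker region is every maximal run of at
#' least `min_consecutive` passing probes that are adjacent in that ordering
#' (at most `max_gap` intervening non-passing probes) and share direction.
#' A direction change breaks a run.
#'
#' @param passing_sites site `data.frame` (passing sites, with `direction`).
#' @param annotation probe annotation (supplies region membership and
#'   position; may cover more probes than `passing_sites`).
#' @param min_consecutive minimum run length (default 3).
#' @param max_gap intervening non-passing probes tolerated inside a run
#'   (default 0 = strict adjacency).
#' @return `data.frame` with one row per marker region: `marker_id`,
#'   `region_id`, `gene`, `direction`, `n_consecutive`, `probes`
#'   (comma-joined probe ids in positional order), plus a `per_probe`
#'   list-column of the member sites' metrics.
#' @export
aggregate_regions <- function(passing_sites, annotation, min_consecutive = 3,
                              max_gap = 0) {
  empty <- data.frame(marker_id = character(0), region_id = character(0),
                      gene = character(0), direction = character(0),
                      n_consecutive = integer(0), probes = character(0),
                      stringsAsFactors = FALSE)
  empty$per_probe <- list()
  if (nrow(passing_sites) == 0) return(empty)
  idx <- match(passing_sites$probe_id, annotation$probe_id)
  if (any(is.na(idx))) {
    abort_stage("methylation", "sites missing annotation: ",
                paste(passing_sites$probe_id[is.na(idx)], collapse = ", "))
  }
  regions <- unique(annotation$region_id[idx])
  out <- list()
  for (rid in regions) {
    ann_r <- annotation[annotation$region_id == rid, , drop = FALSE]
    ann_r <- ann_r[order(ann_r$pos), , drop = FALSE]
    site_idx <- match(ann_r$probe_id, passing_sites$probe_id)
    dir_r <- ifelse(is.na(site_idx), NA_character_,
                    passing_sites$direction[site_idx])
    runs <- find_runs(dir_r, max_gap)
    for (run in runs) {
      members <- run$members  # indices into ann_r of passing probes in run
      if (length(members) < min_consecutive) next
      probes <- ann_r$probe_id[members]
      genes <- setdiff(unique(ann_r$gene[members]), c(NA, ""))
      rec <- data.frame(
        marker_id = if (length(runs) > 1) {
          paste0(rid, ".", run$index)
        } else rid,
        region_id = rid,
        gene = if (length(genes) > 0) genes[1] else "",
        direction = run$direction,
        n_consecutive = length(members),
        probes = paste(probes, collapse = ","),
        stringsAsFactors = FALSE
      )
      rec$per_probe <- list(passing_sites[site_idx[members], , drop = FALSE])
      out[[length(out) + 1]] <- rec
    }
  }
  if (length(out) == 0) return(empty)
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

# Split a vector of per-probe directions (NA = not passing) into maximal
# same-direction runs, allowing up to max_gap consecutive NAs inside a run.
# Returns a list of lists: members (positions of passing probes), direction.
find_runs <- function(dirs, max_gap = 0) {
  runs <- list()
  cur <- integer(0); cur_dir <- NA_character_; gap <- 0; run_no <- 0
  flush <- function() {
    if (length(cur) > 0) {
      run_no <<- run_no + 1
      runs[[length(runs) + 1]] <<- list(members = cur, direction = cur_dir,
                                        index = run_no)
    }
    cur <<- integer(0); cur_dir <<- NA_character_; gap <<- 0
  }
  for (i in seq_along(dirs)) {
    d <- dirs[i]
    if (is.na(d)) {
      if (length(cur) > 0) {
        gap <- gap + 1
        if (gap > max_gap) flush()
      }
    } else if (length(cur) == 0) {
      cur <- i; cur_dir <- d; gap <- 0
    } else if (d == cur_dir) {
      cur <- c(cur, i); gap <- 0
    } else {
      flush()
      cur <- i; cur_dir <- d
    }
  }
  flush()
  runs
}

#' Mann-Whitney validation of a candidate marker's measured levels
#'
#' Compares locus-assay methylation levels (e.g. bisulfite pyrosequencing
#' fractions) between pCR and non-pCR samples of an independent cohort.
#'
#' @param levels numeric per-sample methylation fractions.
#' @param outcomes logical pCR indicator per sample.
#' @return a list with `p` (two-sided Mann-Whitney) and `U`.
#' @export
validate_marker_levels <- function(levels, outcomes) {
  res <- group_compare_continuous(levels, outcomes)
  list(p = res$p, U = res$U)
}

#' Run the full methylation marker screen
#'
#' The fit-like front end of the package: restricts the probe set to the
#' normally-unmethylated universe, scores every site as a two-direction
#' threshold classifier, keeps CpG-island/genic sites, and aggregates
#' consecutive passing probes into candidate marker regions. The funnel
#' counts at every stage are retained as the screen's audit trail.
#'
#' @param beta probes-by-samples beta matrix of the screening cohort.
#' @param annotation probe annotation `data.frame`.
#' @param reference probes-by-profiles beta matrix of normal references.
#' @param outcomes logical pCR indicator per screening sample.
#' @param beta_max universe gate: probes with reference beta below this in
#'   every profile are kept (default 0.2).
#' @param beta_cut methylation-call threshold for the per-site classifier
#'   (default 0.3).
#' @param acc_threshold,spec_threshold per-site classifier gates (defaults
#'   0.67 and 0.85).
#' @param min_consecutive minimum consecutive passing probes per region
#'   (default 3).
#' @param max_gap intervening non-passing probes tolerated (default 0).
#' @return an object of class `"meth_screen"`: a list with `regions` (the
#'   candidate `data.frame` from [aggregate_regions()]), `sites` (passing
#'   sites), `funnel` (named stage counts), `params`, and `outcomes`.
#' @seealso [predict.meth_screen()] to compute per-sample marker levels and
#'   calls for the candidates on new samples.
#' @export
screen_methylation_markers <- function(beta, annotation, reference, outcomes,
                                       beta_max = 0.2, beta_cut = 0.3,
                                       acc_threshold = 0.67,
                                       spec_threshold = 0.85,
                                       min_consecutive = 3, max_gap = 0) {
  validate_beta_matrix(beta)
  universe <- select_unmethylated_universe(reference, beta_max)
  universe <- intersect(rownames(beta), universe)
  if (length(universe) == 0) {
    abort_stage("methylation", "unmethylated universe is empty")
  }
  sites <- screen_sites(beta[universe, , drop = FALSE], outcomes,
                        beta_cut = beta_cut, acc_threshold = acc_threshold,
                        spec_threshold = spec_threshold)
  annotated <- annotation_filter(sites, annotation)
  regions <- aggregate_regions(annotated, annotation,
                               min_consecutive = min_consecutive,
                               max_gap = max_gap)
  structure(list(
    regions = regions,
    sites = sites,
    funnel = c(probes_total = nrow(beta),
               universe = length(universe),
               sites_passed = nrow(sites),
               sites_annotated = nrow(annotated),
               regions = nrow(regions)),
    params = list(beta_max = beta_max, beta_cut = beta_cut,
                  acc_threshold = acc_threshold,
                  spec_threshold = spec_threshold,
                  min_consecutive = min_consecutive, max_gap = max_gap),
    outcomes = outcomes
  ), class = "meth_screen")
}

#' @export
print.meth_screen <- function(x, ...) {
  cat("Methylation marker screen\n")
  cat(sprintf("  probes: %d -> universe (ref beta < %.2g): %d -> passing sites: %d -> CpG-island/genic: %d -> marker regions: %d\n",
              x$funnel["probes_total"], x$params$beta_max,
              x$funnel["universe"], x$funnel["sites_passed"],
              x$funnel["sites_annotated"], x$funnel["regions"]))
  if (nrow(x$regions) > 0) {
    cat("  candidate regions:\n")
    print(x$regions[, c("marker_id", "gene", "direction", "n_consecutive")],
          row.names = FALSE)
  } else {
    cat("  no candidate regions at these thresholds\n")
  }
  invisible(x)
}

#' @export
summary.meth_screen <- function(object, ...) {
  cat("Per-site classifier gates: accuracy >", object$params$acc_threshold,
      "and specificity >", object$params$spec_threshold,
      "at beta >", object$params$beta_cut, "\n")
  print(object)
  if (nrow(object$sites) > 0) {
    cat("\npassing-site accuracy: ")
    print(summary(object$sites$accuracy))
  }
  invisible(object)
}

#' Marker levels and calls for screened regions on (new) samples
#'
#' A candidate region's marker level in a sample is the mean beta value of
#' its member probes; the marker call is level > `beta_cut` (the screen's
#' methylation-call threshold).
#'
#' @param object a `"meth_screen"` object.
#' @param beta probes-by-samples beta matrix covering the member probes
#'   (e.g. a validation cohort).
#' @param type `"level"` (default) for the numeric region-mean beta, or
#'   `"call"` for the logical dichotomized call.
#' @param ... unused.
#' @return a regions-by-samples matrix (rownames = `marker_id`).
#' @export
predict.meth_screen <- function(object, beta, type = c("level", "call"), ...) {
  type <- match.arg(type)
  if (nrow(object$regions) == 0) {
    return(matrix(numeric(0), nrow = 0, ncol = ncol(beta),
                  dimnames = list(NULL, colnames(beta))))
  }
  levels <- do.call(rbind, lapply(strsplit(object$regions$probes, ","),
                                  function(probes) {
    missing <- setdiff(probes, rownames(beta))
    if (length(missing) > 0) {
      abort_stage("methylation", "beta matrix lacks marker probes: ",
                  paste(missing, collapse = ", "))
    }
    colMeans(beta[probes, , drop = FALSE])
  }))
  rownames(levels) <- object$regions$marker_id
  colnames(levels) <- colnames(beta)
  if (type == "call") levels > object$params$beta_cut else levels
}

#' Plot a screened marker region's levels by outcome
#'
#' Strip chart of the region-mean beta value per sample, split by pCR
#' outcome, for one candidate region of the screen.
#'
#' @param x a `"meth_screen"` object.
#' @param beta beta matrix the screen was fitted on (or a new cohort).
#' @param outcomes logical pCR indicator per sample (defaults to the
#'   screening outcomes).
#' @param marker_id which candidate to plot (default: the first).
#' @param ... passed to [graphics::stripchart()].
#' @return invisibly, the plotted per-sample levels.
#' @export
plot.meth_screen <- function(x, beta, outcomes = x$outcomes,
                             marker_id = NULL, ...) {
  if (nrow(x$regions) == 0) {
    abort_stage("methylation", "no candidate regions to plot")
  }
  marker_id <- marker_id %||% x$regions$marker_id[1]
  lv <- predict(x, beta)[marker_id, ]
  grp <- factor(ifelse(outcomes, "pCR", "non-pCR"),
                levels = c("pCR", "non-pCR"))
  graphics::stripchart(lv ~ grp, vertical = TRUE, method = "jitter",
                       pch = 19, ylab = "region mean beta-value",
                       main = marker_id, ylim = c(0, 1), ...)
  graphics::abline(h = x$params$beta_cut, lty = 2)
  invisible(lv)
}
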