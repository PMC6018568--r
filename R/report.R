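# End-to-end orchestration: configuration, the full study pipeline, report
# tables and figures, and provenance records.

#' Assemble a study configuration
#'
#' @param generator a \code{\link{generator_config}}.
#' @param min_overlap minimum lesion overlap for the analysis mask.
#' @param fwe_method "permutation_maxT" or "bonferroni".
#' @param alpha_voxel voxel-level FWE rate.
#' @param n_perm permutations for the maxT null.
#' @param tails 1 or 2 for the voxel contrast.
#' @param sizes,B,with_replacement,alphas resampling settings.
#' @param exact_r2 in-sample partial R2 the fixed cohort is pinned to
#'   before resampling.
#' @param output_dir where \code{\link{run_full_study}} writes.
#' @return an object of class \code{study_config}.
#' @export
study_config <- function(generator = generator_config(seed = 1L),
                         min_overlap = 5,
                         fwe_method = "permutation_maxT",
                         alpha_voxel = 0.05,
                         n_perm = 1000,
                         tails = 1,
                         sizes = c(30, 60, 90, 120, 180, 360),
                         B = 6000,
                         with_replacement = TRUE,
                         alphas = c(0.05, 0.001),
                         exact_r2 = generator$target_partial_r2,
                         output_dir = NULL) {
  stopifnot(inherits(generator, "generator_config"))
  structure(list(generator = generator,
                 analysis = list(min_overlap = min_overlap,
                                 fwe_method = fwe_method,
                                 alpha_voxel = alpha_voxel,
                                 n_perm = n_perm, tails = tails),
                 resampling = list(sizes = sizes, B = B,
                                   with_replacement = with_replacement,
                                   alphas = alphas),
                 exact_r2 = exact_r2,
                 output_dir = output_dir),
            class = "study_config")
}

#' Read a study configuration from YAML or JSON
#'
#' The file mirrors the \code{\link{study_config}} fields; generator
#' settings go under a \code{generator} key and are passed to
#' \code{\link{generator_config}}.
#'
#' @param path a .yaml/.yml or .json file.
#' @return a \code{study_config}.
#' @export
read_study_config <- function(path) {
  ext <- tolower(tools::file_ext(path))
  raw <- if (ext %in% c("yaml", "yml")) {
    if (!requireNamespace("yaml", quietly = TRUE))
      stop("the 'yaml' package is required to read YAML configs")
    yaml::read_yaml(path)
  } else if (ext == "json") {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else stop("unsupported config format: ", ext)
  gen_args <- raw$generator
  if (!is.null(gen_args$covariate_corr))
    gen_args$covariate_corr <- matrix(unlist(gen_args$covariate_corr), 5, 5)
  if (!is.null(gen_args$true_roi))
    gen_args$true_roi <- matrix(unlist(gen_args$true_roi), ncol = 3, byrow = TRUE)
  gen <- do.call(generator_config, gen_args)
  rest <- raw[setdiff(names(raw), "generator")]
  do.call(study_config, c(list(generator = gen), rest))
}

#' Run the full lesion-deficit reproducibility study
#'
#' Pipeline: calibrate the generator, draw the fixed cohort, pin its
#' in-sample partial R2, (in full mode) synthesise lesion volumes, build
#' the overlap map and analysis mask, discover the ROI by voxel-wise
#' regression with FWE correction, extract lesion load; compute the
#' full-cohort effect size with its credible interval; run the bootstrap
#' resampling study and all summary tables; write everything (plus figures
#' and a provenance record) to the output directory. In tabular mode
#' (\code{skip_imaging = TRUE}) the latent lesion load is used directly
#' and the imaging stages are skipped — the statistical claims live
#' entirely at the ROI level, so both modes give the same resampling
#' results when the ROI recovers the designated region.
#'
#' @param config a \code{\link{study_config}}.
#' @param output_dir output directory (overrides the config's).
#' @param skip_imaging run in tabular mode.
#' @param save_volumes write per-patient NIfTI volumes (full mode only;
#'   default FALSE, they are bulky).
#' @param make_figures write box-plot and histogram figures (default TRUE).
#' @return invisibly, a list with the main in-memory results (cohort,
#'   lesion load, effect, records, summaries, paths).
#' @export
run_full_study <- function(config, output_dir = config$output_dir,
                           skip_imaging = FALSE, save_volumes = FALSE,
                           make_figures = TRUE) {
  stopifnot(inherits(config, "study_config"))
  if (is.null(output_dir)) stop("an output directory is required")
  if (!dir.exists(output_dir)) dir.create(output_dir, recursive = TRUE)
  log_path <- file.path(output_dir, "run.log")
  logf <- function(...) {
    msg <- sprintf("[%s] %s", format(Sys.time(), "%H:%M:%S"), sprintf(...))
    message(msg)
    cat(msg, "\n", file = log_path, append = TRUE)
  }
  stage <- function(name, expr) {
    logf("stage: %s", name)
    tryCatch(expr, error = function(e)
      stop(sprintf("stage '%s' failed: %s", name, conditionMessage(e)), call. = FALSE))
  }
  warn_counts <- list(redraws = 0L, degenerate_voxels = 0L)

  gen <- stage("calibrate", calibrate_generator(config$generator))
  ch <- stage("generate_cohort", generate_cohort(gen))
  cohort <- ch$cohort

  latent_load <- stage("fix_sample_partial_r2",
                       fix_sample_partial_r2(cohort, ch$lesion_load, config$exact_r2))
  utils::write.csv(cohort, file.path(output_dir, "cohort.csv"), row.names = FALSE)

  roi <- NULL
  if (!skip_imaging) {
    vols <- stage("generate_lesion_volumes",
                  generate_lesion_volumes(gen, cohort, latent_load))
    if (save_volumes) {
      stage("write_volumes", {
        write_volumes(vols$fuzzy, file.path(output_dir, "volumes"))
        write_volumes(vols$binary, file.path(output_dir, "volumes"))
      })
    }
    overlap <- stage("overlap_map", build_overlap_map(vols$binary))
    mask <- stage("analysis_mask", make_analysis_mask(overlap, config$analysis$min_overlap))
    stats_map <- stage("voxelwise_glm", {
      design <- build_design_matrix(cohort)
      withCallingHandlers(
        fit_voxelwise_glm(vols$fuzzy, design, mask),
        warning = function(w) {
          warn_counts$degenerate_voxels <<- warn_counts$degenerate_voxels + 1L
          invokeRestart("muffleWarning")
        })
    })
    roi <- stage("fwe_threshold", {
      design <- build_design_matrix(cohort)
      fwe_threshold(stats_map, design, vols$fuzzy, mask,
                    alpha = config$analysis$alpha_voxel,
                    method = config$analysis$fwe_method,
                    n_perm = config$analysis$n_perm,
                    seed = derive_seed(gen$seed, 404L),
                    tails = config$analysis$tails)
    })
    stage("write_roi", {
      write_map_nifti(overlap, file.path(output_dir, "overlap.nii.gz"))
      write_roi(roi, file.path(output_dir, "roi.nii.gz"), gen$voxel_size_mm)
    })
    if (roi$n_voxels > 0) {
      lesion_load <- stage("extract_lesion_load", extract_lesion_load(vols$fuzzy, roi))
    } else {
      logf("ROI empty; falling back to the designated region for lesion load")
      lesion_load <- latent_load
    }
    rm(vols)
  } else {
    lesion_load <- latent_load
  }

  effect <- stage("effect_size", {
    covs <- as.matrix(cohort[, c(setdiff(SCORE_COLS, "score_repn"), "lesion_size_cm3")])
    partial_correlation(cohort$score_repn, lesion_load, covs)
  })
  interval <- credible_interval_r2(effect$r2, effect$n, effect$k,
                                   sign = sign(effect$r_partial))
  jsonlite::write_json(
    list(r_partial = effect$r_partial, r2 = effect$r2, p = effect$p_two_sided,
         df = effect$df, ci_lower_r2 = interval$lower_r2,
         ci_upper_r2 = interval$upper_r2, ci_level = interval$level),
    file.path(output_dir, "effect_size.json"), auto_unbox = TRUE, digits = NA)

  records <- stage("resampling", run_resampling_study(
    cohort, lesion_load,
    sizes = config$resampling$sizes, B = config$resampling$B,
    with_replacement = config$resampling$with_replacement,
    seed = derive_seed(gen$seed, 505L)))
  warn_counts$redraws <- attr(records, "n_redraws")
  utils::write.csv(records[, c("size", "replicate", "r2", "p", "sign")],
                   file.path(output_dir, "records.csv"), row.names = FALSE)

  summaries <- summarize_by_significance(records, config$resampling$alphas)
  classification <- classify_against_interval(records, interval,
                                              alpha = config$resampling$alphas[1])
  deciles <- select_decile_resamples(records)
  stage("report_tables",
        write_report_tables(summaries, classification, deciles, output_dir))

  if (make_figures) stage("figures", plot_study_figures(records, output_dir))

  cfg_json <- jsonlite::toJSON(
    list(generator_seed = gen$seed, exact_r2 = config$exact_r2,
         analysis = config$analysis, resampling = config$resampling),
    auto_unbox = TRUE, digits = NA)
  jsonlite::write_json(
    list(config_hash = config_hash(as.character(cfg_json)),
         seed = gen$seed,
         package_version = as.character(utils::packageVersion("lesionboot")),
         n_records = nrow(records),
         mode = if (skip_imaging) "tabular" else "full",
         roi_voxels = if (is.null(roi)) NA else roi$n_voxels,
         warnings = warn_counts),
    file.path(output_dir, "provenance.json"), auto_unbox = TRUE, digits = NA)
  jsonlite::write_json(list(n_records = nrow(records),
                            sizes = config$resampling$sizes,
                            B = config$resampling$B),
                       file.path(output_dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA)
  logf("done: %d records", nrow(records))
  invisible(list(cohort = cohort, lesion_load = lesion_load, roi = roi,
                 effect = effect, interval = interval, records = records,
                 summaries = summaries, classification = classification,
                 deciles = deciles, output_dir = output_dir))
}

#' Write the study's report tables as CSV
#'
#' Three tables mirroring the study's layouts: significance-split moments
#' per size and alpha, credible-interval classification counts, and the
#' decile selections. Displayed values are rounded to 2 decimals; empty
#' cells render as an en dash.
#'
#' @param summaries \code{\link{summarize_by_significance}} output.
#' @param classification \code{\link{classify_against_interval}} output.
#' @param deciles \code{\link{select_decile_resamples}} output.
#' @param out_dir output directory.
#' @return invisibly, the paths written.
#' @export
write_report_tables <- function(summaries, classification, deciles, out_dir) {
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  sizes <- sort(unique(summaries$size))

  # significance table: rows = statistic x alpha, columns = size x stratum
  stats_rows <- c("count", "mean_r2", "median_r2", "min_r2", "max_r2")
  alphas <- sort(unique(summaries$alpha), decreasing = TRUE)
  tab <- list()
  for (stat in stats_rows) for (alpha in alphas) {
    row <- list(statistic = stat, alpha = alpha)
    for (size in sizes) {
      for (grp in c("significant", "not_significant")) {
        cell <- summaries[summaries$size == size & summaries$alpha == alpha &
                            summaries$group == grp, ]
        val <- cell[[stat]]
        row[[sprintf("%s_%d", if (grp == "significant") "s" else "ns", size)]] <-
          if (stat == "count") as.character(val) else fmt2(val)
      }
    }
    tab[[length(tab) + 1L]] <- as.data.frame(row, check.names = FALSE)
  }
  sig_path <- file.path(out_dir, "table_significance.csv")
  utils::write.csv(do.call(rbind, tab), sig_path, row.names = FALSE)

  cls_path <- file.path(out_dir, "table_ci_classification.csv")
  utils::write.csv(classification, cls_path, row.names = FALSE)

  dec <- deciles
  dec$r2 <- sprintf("%.2f", dec$r2)
  dec$p <- sprintf("%.3f", dec$p)
  dec_path <- file.path(out_dir, "table_deciles.csv")
  utils::write.csv(dec, dec_path, row.names = FALSE)
  invisible(c(sig_path, cls_path, dec_path))
}

# box plot of R2 by size and per-size histograms, written as PDF
plot_study_figures <- function(records, out_dir) {
  box_path <- file.path(out_dir, "fig_effect_by_size.pdf")
  grDevices::pdf(box_path, width = 7, height = 5)
  graphics::boxplot(r2 ~ size, data = records,
                    xlab = "Sample size", ylab = expression(R^2),
                    main = "Bootstrap effect-size distributions by sample size")
  grDevices::dev.off()
  hist_path <- file.path(out_dir, "fig_effect_histograms.pdf")
  sizes <- sort(unique(records$size))
  grDevices::pdf(hist_path, width = 9, height = 6)
  op <- graphics::par(mfrow = c(2, ceiling(length(sizes) / 2)))
  for (s in sizes) {
    graphics::hist(records$r2[records$size == s], breaks = 40,
                   main = sprintf("N = %d", s), xlab = expression(R^2))
  }
  graphics::par(op)
  grDevices::dev.off()
  invisible(c(box_path, hist_path))
}
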