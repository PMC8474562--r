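#' Pipeline configuration
#'
#' Collects everything one end-to-end run needs: either paths to existing
#' blood/TAC/cohort CSV inputs or a simulation block, plus kinetic-fit, PVC
#' and statistics options. Can be loaded from a YAML file whose keys mirror
#' the arguments.
#'
#' @param simulate `NULL`, or a list passed to [simulation_config()]
#'   (e.g. `list(n_subjects = 20)`); when set, inputs are generated.
#' @param blood_csv,tacs_csv,cohort_csv Input paths when not simulating.
#' @param seed Master seed; all stage seeds derive from it.
#' @param frame_scheme_groups Frame scheme group list (default the 20-frame
#'   scheme).
#' @param fit_n_starts,fit_seed_offset 2TC multi-start options.
#' @param pvc Options list: `enabled`, `psf_fwhm_mm`, `mode`
#'   (`"tac"`/`"vt"`).
#' @param stats Options list: `raw_units`, `fdr_family`, `fdr_level`,
#'   `predictors`.
#' @return A `pipeline_config` object.
#' @export
pipeline_config <- function(simulate = list(n_subjects = 20),
                            blood_csv = NULL, tacs_csv = NULL,
                            cohort_csv = NULL, seed = 1,
                            frame_scheme_groups = NULL,
                            fit_n_starts = 10, fit_seed_offset = 0,
                            pvc = list(enabled = FALSE, psf_fwhm_mm = 5,
                                       mode = "tac"),
                            stats = list(raw_units = FALSE,
                                         fdr_family = "per_predictor",
                                         fdr_level = 0.05,
                                         predictors = NULL)) {
  if (!is.null(stats$fdr_level) &&
      (stats$fdr_level <= 0 || stats$fdr_level >= 1)) {
    stopf("FDR level must lie in (0, 1)")
  }
  if (is.null(simulate)) {
    for (p in c(blood_csv, tacs_csv, cohort_csv)) {
      if (!is.null(p) && !file.exists(p)) stopf("input path does not exist: %s", p)
    }
  }
  scheme <- if (is.null(frame_scheme_groups)) {
    default_frame_scheme()
  } else {
    frame_scheme(frame_scheme_groups)
  }
  structure(list(simulate = simulate, blood_csv = blood_csv,
                 tacs_csv = tacs_csv, cohort_csv = cohort_csv,
                 seed = as.integer(seed), frame_scheme = scheme,
                 fit_n_starts = fit_n_starts,
                 fit_seed_offset = fit_seed_offset,
                 pvc = modifyList(list(enabled = FALSE, psf_fwhm_mm = 5,
                                       mode = "tac"), pvc),
                 stats = modifyList(list(raw_units = FALSE,
                                         fdr_family = "per_predictor",
                                         fdr_level = 0.05, predictors = NULL),
                                    stats)),
            class = "pipeline_config")
}

#' @rdname pipeline_config
#' @param path YAML file with keys mirroring the arguments.
#' @export
read_pipeline_config <- function(path) {
  y <- yaml::read_yaml(path)
  do.call(pipeline_config, y[intersect(names(y), names(formals(pipeline_config)))])
}

#' Run the full quantification and association pipeline
#'
#' Stages: (1) simulate or load the cohort, blood data and TACs; (2) fit the
#' input-function chain per subject; (3) fit the 2TC model per subject and
#' region to obtain V_T; (4) optionally apply region-based partial-volume
#' correction; (5) run the per-region Gamma/log-link association analysis.
#' Writes `cohort.csv`, `blood.csv`, `tacs.csv`, `vt.csv`, `results.csv`,
#' `heatmap.csv`, a JSON run manifest and a log to `out_dir`. Identical
#' config and seed give identical outputs.
#'
#' @param config A [pipeline_config()].
#' @param out_dir Output directory (created if missing).
#' @param verbose Print stage progress.
#' @return Invisibly, a list with the run directory, the V_T table and the
#'   association results.
#' @export
run_pipeline <- function(config, out_dir, verbose = TRUE) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  log_path <- file.path(out_dir, "run.log")
  logf <- function(fmt, ...) {
    msg <- sprintf(fmt, ...)
    cat(msg, "\n", file = log_path, append = TRUE, sep = "")
    if (verbose) message(msg)
  }
  stage <- "setup"
  tryCatch({
    scheme <- config$frame_scheme

    if (!is.null(config$simulate)) {
      stage <- "simulate"
      sim_args <- modifyList(list(seed = config$seed), config$simulate)
      sc <- do.call(simulation_config, sim_args)
      sim <- simulate_cohort(sc)
      cohort <- sim$cohort
      truth <- sim$truth
      logf("simulate: %d subjects, %d regions", nrow(cohort), length(sc$regions))
      write.csv(cohort, file.path(out_dir, "cohort.csv"), row.names = FALSE)

      blood <- list(); tacs <- list()
      for (i in seq_len(nrow(cohort))) {
        sid <- cohort$subject_id[i]
        st <- subject_truth_from_cohort(truth, sid)
        bt <- sc$blood_truth
        blood[[sid]] <- simulate_blood_data(st$input, bt$hill, bt$ratio,
                                            noise_cv = 0.02,
                                            seed = derive_seed(config$seed,
                                                               paste0("blood", sid)))
        tacs[[sid]] <- simulate_tacs(st, blood[[sid]], scheme,
                                     noise_cv = sc$tac_noise_cv,
                                     seed = derive_seed(config$seed,
                                                        paste0("tac", sid)))
      }
      bpath <- file.path(out_dir, "blood.csv")
      blood_df <- do.call(rbind, lapply(names(blood), function(sid) {
        b <- blood[[sid]]
        rbind(
          data.frame(subject = sid, time_min = b$auto_times_s / 60,
                     source = "auto", wb_activity = b$auto_wb_activity,
                     plasma_activity = NA_real_, parent_fraction = NA_real_),
          data.frame(subject = sid, time_min = b$manual_times_min,
                     source = "manual", wb_activity = b$manual_wb_activity,
                     plasma_activity = b$manual_plasma_activity,
                     parent_fraction = b$manual_parent_fraction))
      }))
      write_csv_full(blood_df, bpath)
      tpath <- file.path(out_dir, "tacs.csv")
      if (file.exists(tpath)) file.remove(tpath)
      for (sid in names(tacs)) {
        write_tacs_csv(tacs[[sid]], tpath, sid, append = file.exists(tpath))
      }
    } else {
      stage <- "load"
      cohort <- read.csv(config$cohort_csv)
      tacs <- read_tacs_csv(config$tacs_csv)
      blood_df <- read.csv(config$blood_csv)
      sids <- if ("subject" %in% names(blood_df)) unique(blood_df$subject) else names(tacs)
      blood <- setNames(lapply(sids, function(s) {
        read_blood_csv(config$blood_csv,
                       subject = if ("subject" %in% names(blood_df)) s else NULL)
      }), sids)
      truth <- NULL
    }

    stage <- "inputfn"
    chains <- list()
    for (sid in names(blood)) {
      chains[[sid]] <- tryCatch(
        fit_input_chain(blood[[sid]],
                        seed = derive_seed(config$seed, paste0("ifn", sid))),
        error = function(e) stopf("input-function stage failed for %s: %s",
                                  sid, conditionMessage(e)))
    }
    logf("inputfn: fitted %d subjects", length(chains))

    stage <- "kinfit"
    fit_rows <- list()
    for (sid in names(tacs)) {
      ch <- chains[[sid]]
      for (r in names(tacs[[sid]])) {
        fit <- tryCatch(
          fit_2tc(tacs[[sid]][[r]], ch$input, ch$wb_curve,
                  n_starts = config$fit_n_starts,
                  seed = derive_seed(config$seed, paste0("fit", sid, r))),
          error = function(e) stopf("kinetic stage failed for %s/%s: %s",
                                    sid, r, conditionMessage(e)))
        p <- fit$params
        fit_rows[[length(fit_rows) + 1]] <- data.frame(
          subject_id = sid, region = r, VT = fit$VT, VT_se = fit$VT_se,
          K1 = p$K1, k2 = p$k2, k3 = p$k3, k4 = p$k4, rss = fit$rss,
          converged = fit$converged, pvc = FALSE)
      }
    }
    vt <- do.call(rbind, fit_rows)
    logf("kinfit: %d fits, %d converged", nrow(vt), sum(vt$converged))

    if (isTRUE(config$pvc$enabled)) {
      stage <- "pvc"
      vt <- apply_pipeline_pvc(vt, config$pvc)
      logf("pvc: mode=%s fwhm=%.1f mm", config$pvc$mode, config$pvc$psf_fwhm_mm)
    }
    write_vt_csv(vt, file.path(out_dir, "vt.csv"))

    stage <- "stats"
    results <- run_regional_analysis(vt, cohort,
                                     predictors = config$stats$predictors,
                                     raw_units = isTRUE(config$stats$raw_units),
                                     fdr_family = config$stats$fdr_family,
                                     fdr_level = config$stats$fdr_level)
    write_results_csv(results, file.path(out_dir, "results.csv"),
                      file.path(out_dir, "heatmap.csv"))
    logf("stats: %d region x predictor tests", nrow(results))

    stage <- "manifest"
    cfg_plain <- config
    cfg_plain$frame_scheme <- config$frame_scheme$groups
    manifest <- list(
      seed = config$seed,
      config_hash = sum(utf8ToInt(paste(deparse(cfg_plain), collapse = ""))),
      package_version = as.character(utils::packageVersion("tspovt")),
      r_version = R.version.string,
      n_subjects = nrow(cohort),
      regions = unique(vt$region),
      pvc_enabled = isTRUE(config$pvc$enabled))
    jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA)
    invisible(list(out_dir = out_dir, vt = vt, results = results,
                   cohort = cohort, truth = if (exists("truth")) truth else NULL))
  }, error = function(e) {
    stopf("pipeline stage '%s' failed: %s", stage, conditionMessage(e))
  })
}

# V_T-level regional PVC on a synthetic demo geometry: each subject's
# regional V_T values are painted onto the demo label volume, blurred by the
# stated PSF, re-extracted and corrected via the geometric transfer matrix.
apply_pipeline_pvc <- function(vt, pvc_opts) {
  labels <- demo_label_geometry()
  gtm <- build_gtm(labels, pvc_opts$psf_fwhm_mm)
  regions <- gtm$regions
  out <- vt
  for (sid in unique(vt$subject_id)) {
    sel <- vt$subject_id == sid & vt$region %in% regions
    vals <- setNames(vt$VT[sel], vt$region[sel])[regions]
    phant <- simulate_phantom(labels$labels, vals, pvc_opts$psf_fwhm_mm,
                              labels$voxel_size_mm)
    observed <- vapply(regions, function(r) {
      mean(phant$activity[labels$labels == labels$label_map[[r]]])
    }, numeric(1))
    corrected <- apply_gtm_pvc(observed, gtm)
    for (r in regions) {
      out$VT[out$subject_id == sid & out$region == r] <- corrected[[r]]
    }
  }
  out$pvc <- out$region %in% regions
  out
}
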