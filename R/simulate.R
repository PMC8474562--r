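#' Default ROI set
#'
#' The six anatomical regions quantified in the analysis plus the whole
#' brain (the union of all foreground labels).
#' @export
default_regions <- function() {
  c("frontal", "parietal", "temporal", "occipital", "cingulate",
    "hippocampus", "whole_brain")
}

default_alpha <- function(regions) {
  # Baseline regional V_T (mL/cm^3) on the log scale; generic
  # second-generation TSPO tracer plausibility, hippocampus highest.
  base <- c(frontal = 11, parietal = 10.5, temporal = 11.5, occipital = 10,
            cingulate = 11, hippocampus = 12, whole_brain = 11)
  out <- log(base[regions])
  out[is.na(out)] <- log(11)
  names(out) <- regions
  out
}

default_kinetics_base <- function(regions) {
  # Shared efflux/exchange rates; K1 is back-solved from each subject's V_T.
  setNames(lapply(regions, function(r) c(k2 = 0.08, k3 = 0.04, k4 = 0.02)),
           regions)
}

#' True blood-model parameter defaults for the simulator
#'
#' Bolus plasma input peaking at 1 min (100 kBq/mL) with a fast/medium/slow
#' tri-exponential tail, a Hill metabolite profile falling to an asymptotic
#' parent fraction of 0.2 with half-loss at 20 min, and a
#' whole-blood-to-plasma ratio relaxing from 0.9 to 0.6.
#' @export
default_blood_truth <- function() {
  list(
    input = input_function_model(t_peak = 1, c_peak = 100,
                                 A = c(60, 30, 10), lambda = c(3, 0.4, 0.02)),
    hill = parent_fraction_model(p_inf = 0.2, h = 2, t50 = 20),
    ratio = wb_plasma_ratio_model(r0 = 0.9, r_inf = 0.6, k_r = 0.1)
  )
}

#' Simulation configuration
#'
#' Defines a synthetic cohort: sample size, frame scheme, regions, baseline
#' kinetics, and the covariate effects on log V_T that the Gamma/log-link
#' generative model applies. Defaults emulate the study conditions: n = 20,
#' a 55% mixed-affinity-binder (MAB) genotype mix, and effect magnitudes in
#' the |d| ~ 0.3-0.75 range at n = 20 with a positive HAB binding offset.
#'
#' @param n_subjects Number of subjects (>= 1; default 20).
#' @param seed Integer seed; all generator draws derive from it.
#' @param frame_scheme A [frame_scheme()] (default the 20-frame scheme).
#' @param regions Character vector of ROI names (default [default_regions()]).
#' @param alpha_region Named log baseline V_T per region.
#' @param kinetics_base Named list of `c(k2, k3, k4)` per region; `K1` is
#'   solved from each subject's V_T so V_T is exactly controllable.
#' @param effect_beta_pcl Effect of PTSD symptom severity (per SD of PCL-5
#'   total) on log V_T.
#' @param effect_beta_months Effect of exposure duration (per SD of months
#'   on site) on log V_T.
#' @param effect_beta_hab Additive log V_T offset for high-affinity binders.
#' @param gamma_shape Gamma shape (dispersion) of V_T around its conditional
#'   mean (> 0; larger = tighter).
#' @param tac_noise_cv Coefficient of variation of TAC noise (>= 0).
#' @param p_mab Probability of MAB genotype, in `[0, 1]`.
#' @param p_mci Probability of MCI status (default 0.5, a matched design).
#' @param subscale_rho Latent correlation of the four PCL-5 symptom-cluster
#'   subscales (default 0.6).
#' @param blood_truth True blood model components (see
#'   [default_blood_truth()]).
#' @param region_effects Optional named list overriding `effect_beta_pcl`
#'   per region (e.g. a hippocampus-dominant profile).
#' @return A `simulation_config` object.
#' @export
simulation_config <- function(n_subjects = 20, seed = 1,
                              frame_scheme = default_frame_scheme(),
                              regions = default_regions(),
                              alpha_region = default_alpha(regions),
                              kinetics_base = default_kinetics_base(regions),
                              effect_beta_pcl = 0.15,
                              effect_beta_months = 0.08,
                              effect_beta_hab = 0.4,
                              gamma_shape = 25,
                              tac_noise_cv = 0.05,
                              p_mab = 0.55,
                              p_mci = 0.5,
                              subscale_rho = 0.6,
                              blood_truth = default_blood_truth(),
                              region_effects = NULL) {
  if (n_subjects < 1) stopf("'n_subjects' must be >= 1")
  if (!is.finite(gamma_shape) || gamma_shape <= 0) stopf("'gamma_shape' must be > 0")
  if (tac_noise_cv < 0) stopf("'tac_noise_cv' must be >= 0")
  if (p_mab < 0 || p_mab > 1) stopf("'p_mab' must lie in [0, 1]")
  if (!all(regions %in% names(alpha_region))) stopf("'alpha_region' must name every region")
  if (!all(regions %in% names(kinetics_base))) stopf("'kinetics_base' must name every region")
  for (r in regions) assert_positive(kinetics_base[[r]], paste0("kinetics_base$", r))
  structure(list(n_subjects = as.integer(n_subjects), seed = as.integer(seed),
                 frame_scheme = frame_scheme, regions = regions,
                 alpha_region = alpha_region, kinetics_base = kinetics_base,
                 effect_beta_pcl = effect_beta_pcl,
                 effect_beta_months = effect_beta_months,
                 effect_beta_hab = effect_beta_hab,
                 gamma_shape = gamma_shape, tac_noise_cv = tac_noise_cv,
                 p_mab = p_mab, p_mci = p_mci, subscale_rho = subscale_rho,
                 blood_truth = blood_truth, region_effects = region_effects),
            class = "simulation_config")
}

cognition_domains <- function() {
  c("response_time", "processing_time", "visual_memory", "episodic_memory",
    "visuospatial_learning", "visuospatial_memory")
}

#' Simulate a synthetic cohort with known ground truth
#'
#' Draws covariates (PCL-5 total and four symptom-cluster subscales, months
#' on site, TSPO rs6971 genotype, MCI status, six cognitive domain scores)
#' and regional V_T from the generative Gamma/log-link model: conditional
#' mean `mu = exp(alpha_region + beta_HAB * HAB + beta_PCL * z(pcl5) +
#' beta_months * z(months))`, V_T ~ Gamma(mean `mu`, shape `gamma_shape`).
#' Microparameters per subject and region are obtained by holding `k2, k3,
#' k4` at their regional base values and solving `K1 = V_T * k2 / (1 +
#' k3/k4)`, so the stored V_T is exact.
#'
#' @param config A [simulation_config()].
#' @return A list with `cohort` (one row per subject) and `truth` (list:
#'   `vt` long per-subject/region table with `mu`, `VT` and microparameters;
#'   `linear_predictor`; `input_params` per subject; `config`).
#' @export
simulate_cohort <- function(config) {
  stopifnot(inherits(config, "simulation_config"))
  n <- config$n_subjects
  with_seed(derive_seed(config$seed, "cohort"), {
    id <- sprintf("S%03d", seq_len(n))
    genotype <- ifelse(runif(n) < config$p_mab, "MAB", "HAB")
    # PCL-5 total: truncated normal on [0, 80].
    pcl <- rnorm(n, 30, 18)
    while (any(bad <- pcl < 0 | pcl > 80)) pcl[bad] <- rnorm(sum(bad), 30, 18)
    # Subscale scores: item-count-weighted fractions of the total (clusters
    # B/C/D/E have 5/2/7/6 items) plus correlated noise via a shared factor.
    wts <- c(re_experiencing = 5, avoidance = 2,
             negative_cognitions_mood = 7, arousal = 6) / 20
    shared <- rnorm(n)
    sub <- sapply(names(wts), function(nm) {
      eps <- config$subscale_rho * shared +
        sqrt(1 - config$subscale_rho^2) * rnorm(n)
      pmax(0, pcl * wts[[nm]] + 2 * eps)
    })
    colnames(sub) <- paste0("pcl5_", names(wts))
    months <- rlnorm(n, log(10), 0.7)
    mci <- ifelse(runif(n) < config$p_mci, "MCI", "CU")
    cog <- sapply(cognition_domains(), function(d) rnorm(n))
    if (n == 1) cog <- matrix(cog, nrow = 1, dimnames = list(NULL, cognition_domains()))

    zpcl <- if (n > 1 && sd(pcl) > 0) (pcl - mean(pcl)) / sd(pcl) else rep(0, n)
    zmonths <- if (n > 1 && sd(months) > 0) (months - mean(months)) / sd(months) else rep(0, n)
    hab <- as.numeric(genotype == "HAB")

    vt_rows <- vector("list", length(config$regions))
    lp_rows <- vector("list", length(config$regions))
    for (ri in seq_along(config$regions)) {
      r <- config$regions[ri]
      beta_pcl <- if (!is.null(config$region_effects) && r %in% names(config$region_effects)) {
        config$region_effects[[r]]
      } else config$effect_beta_pcl
      eta <- config$alpha_region[[r]] + config$effect_beta_hab * hab +
        beta_pcl * zpcl + config$effect_beta_months * zmonths
      mu <- exp(eta)
      if (any(!is.finite(mu)) || any(mu <= 0)) stopf("invalid config: non-positive conditional mean")
      vt <- rgamma(n, shape = config$gamma_shape, rate = config$gamma_shape / mu)
      kb <- config$kinetics_base[[r]]
      K1 <- vt * kb[["k2"]] / (1 + kb[["k3"]] / kb[["k4"]])
      vt_rows[[ri]] <- data.frame(subject_id = id, region = r, mu = mu, VT = vt,
                                  K1 = K1, k2 = kb[["k2"]], k3 = kb[["k3"]],
                                  k4 = kb[["k4"]])
      lp_rows[[ri]] <- data.frame(subject_id = id, region = r, eta = eta)
    }
    vt_truth <- do.call(rbind, vt_rows)

    # Per-subject input-function truth: shared shape with a 10% CV
    # lognormal jitter on the peak amplitude (injected-dose variation).
    bt <- config$blood_truth
    scale_amp <- rlnorm(n, 0, 0.1)
    input_params <- data.frame(subject_id = id, t_peak = bt$input$t_peak,
                               c_peak = bt$input$c_peak * scale_amp,
                               A1 = bt$input$A[1] * scale_amp,
                               A2 = bt$input$A[2] * scale_amp,
                               A3 = bt$input$A[3] * scale_amp,
                               lambda1 = bt$input$lambda[1],
                               lambda2 = bt$input$lambda[2],
                               lambda3 = bt$input$lambda[3])

    cohort <- data.frame(subject_id = id, pcl5_total = pcl, sub,
                         months_wtc = months, genotype = genotype,
                         mci_status = mci, cog, check.names = FALSE)
    list(cohort = cohort,
         truth = list(vt = vt_truth,
                      linear_predictor = do.call(rbind, lp_rows),
                      input_params = input_params,
                      config = config))
  })
}

#' Simulate one subject's arterial blood dataset
#'
#' Produces a dense automated whole-blood curve (1 Hz over the first 6 min)
#' and the seven manual arterial draws at 2.5, 7, 15, 30, 60, 90 and 120 min
#' carrying whole-blood activity, total plasma activity and parent fraction.
#' Total plasma is the metabolite-corrected input divided by the parent
#' fraction; whole blood is total plasma times the whole-blood-to-plasma
#' ratio. Noise is multiplicative Gaussian with the stated CV.
#'
#' @param input_params True `input_function_model` (metabolite-corrected
#'   plasma).
#' @param hill_params True `parent_fraction_model`.
#' @param ratio_params True `wb_plasma_ratio_model`.
#' @param noise_cv Multiplicative noise CV (>= 0; default 0).
#' @param seed Seed (default 1).
#' @param manual_times_min Manual draw times (default the 7-sample protocol).
#' @param auto_hz,auto_end_s Automated sampling rate and end time.
#' @return A [blood_dataset()].
#' @export
simulate_blood_data <- function(input_params, hill_params, ratio_params,
                                noise_cv = 0, seed = 1,
                                manual_times_min = c(2.5, 7, 15, 30, 60, 90, 120),
                                auto_hz = 1, auto_end_s = 360) {
  if (noise_cv < 0) stopf("'noise_cv' must be >= 0")
  cp <- function(t) evaluate_input(input_params, t)
  pf <- function(t) predict_parent_fraction(hill_params, t)
  total_plasma <- function(t) cp(t) / pmax(pf(t), 1e-12)
  wb <- function(t) total_plasma(t) * predict_ratio(ratio_params, t)

  with_seed(seed, {
    auto_t <- seq(0, auto_end_s, by = 1 / auto_hz)
    auto_wb <- wb(auto_t / 60) * (1 + noise_cv * rnorm(length(auto_t)))
    man_wb <- wb(manual_times_min) * (1 + noise_cv * rnorm(length(manual_times_min)))
    man_pl <- total_plasma(manual_times_min) *
      (1 + noise_cv * rnorm(length(manual_times_min)))
    man_pf <- pmin(1, pmax(0, pf(manual_times_min) *
                             (1 + noise_cv * rnorm(length(manual_times_min)))))
    blood_dataset(auto_t, pmax(auto_wb, 0), manual_times_min,
                  pmax(man_wb, 0), pmax(man_pl, 0), man_pf)
  })
}

#' Simulate frame-binned time-activity curves for one subject
#'
#' Runs the 2TC forward model for every region of the subject's ground-truth
#' kinetics against the subject's true plasma input, frame-averages over the
#' acquisition scheme (including the 5% whole-blood vascular term), and adds
#' zero-mean Gaussian noise with standard deviation
#' `noise_cv * activity / sqrt(frame_duration / max_duration)`.
#'
#' @param subject_truth List with `kinetics` (named list of
#'   [two_tc_params()] per region) and `input` (the subject's true
#'   `input_function_model`).
#' @param blood A [blood_dataset()] supplying the whole-blood curve for the
#'   vascular term (via [make_wb_curve()]).
#' @param scheme A [frame_scheme()].
#' @param noise_cv TAC noise CV (>= 0).
#' @param seed Seed.
#' @return Named list of [time_activity_curve()] objects, one per region.
#' @export
simulate_tacs <- function(subject_truth, blood, scheme, noise_cv = 0, seed = 1) {
  if (noise_cv < 0) stopf("'noise_cv' must be >= 0")
  if (!all(c("kinetics", "input") %in% names(subject_truth))) {
    stopf("'subject_truth' needs elements 'kinetics' and 'input'")
  }
  wb_fun <- make_wb_curve(blood)
  max_dur <- max(scheme$frame_dur_s)
  with_seed(seed, {
    out <- lapply(names(subject_truth$kinetics), function(r) {
      pars <- subject_truth$kinetics[[r]]
      act <- frame_average(function(t) forward_2tc(pars, subject_truth$input,
                                                   wb_fun, t), scheme)
      if (noise_cv > 0) {
        sdv <- noise_cv * abs(act) / sqrt(scheme$frame_dur_s / max_dur)
        act <- act + rnorm(length(act), 0, sdv)
      }
      time_activity_curve(r, scheme$frame_start_s, scheme$frame_dur_s, act)
    })
    setNames(out, names(subject_truth$kinetics))
  })
}

#' Build ground-truth kinetics for one subject from the cohort truth table
#'
#' @param truth The `truth` element returned by [simulate_cohort()].
#' @param subject_id Subject identifier.
#' @param vB Fractional blood volume (default 0.05).
#' @return A `subject_truth` list consumable by [simulate_tacs()].
#' @export
subject_truth_from_cohort <- function(truth, subject_id, vB = 0.05) {
  rows <- truth$vt[truth$vt$subject_id == subject_id, , drop = FALSE]
  if (!nrow(rows)) stopf("unknown subject '%s'", subject_id)
  kin <- setNames(lapply(seq_len(nrow(rows)), function(i) {
    two_tc_params(rows$K1[i], rows$k2[i], rows$k3[i], rows$k4[i], vB = vB)
  }), rows$region)
  ip <- truth$input_params[truth$input_params$subject_id == subject_id, ]
  input <- input_function_model(ip$t_peak, ip$c_peak,
                                c(ip$A1, ip$A2, ip$A3),
                                c(ip$lambda1, ip$lambda2, ip$lambda3))
  list(kinetics = kin, input = input)
}

#' Simulate a piecewise-constant phantom blurred by a Gaussian PSF
#'
#' Builds the true image (value `regional_values[j]` inside label `j`,
#' `background` elsewhere), convolves it with an isotropic Gaussian
#' point-spread function of the stated FWHM, and returns both volumes. Used
#' as the exactly-solvable fixture for region-based partial-volume
#' correction.
#'
#' @param label_geometry 3D integer array of region labels (0 = background),
#'   or a named list of disjoint logical masks.
#' @param regional_values Activity per label, in label order.
#' @param psf_fwhm_mm PSF full width at half maximum, mm (>= 0).
#' @param voxel_size_mm Isotropic voxel size, mm.
#' @param background Background value (default 0).
#' @return List with `activity` (blurred volume), `truth` (unblurred),
#'   `labels`, `voxel_size_mm`.
#' @export
simulate_phantom <- function(label_geometry, regional_values, psf_fwhm_mm,
                             voxel_size_mm = 2, background = 0) {
  if (psf_fwhm_mm < 0) stopf("'psf_fwhm_mm' must be >= 0")
  if (is.list(label_geometry)) {
    masks <- label_geometry
    overlap <- Reduce(`+`, lapply(masks, function(m) as.numeric(m)))
    if (any(overlap > 1)) stopf("overlapping labels")
    labels <- array(0L, dim = dim(masks[[1]]))
    for (j in seq_along(masks)) labels[masks[[j]]] <- j
  } else {
    labels <- label_geometry
    if (any(labels < 0)) stopf("labels must be non-negative")
  }
  ids <- sort(setdiff(unique(as.vector(labels)), 0L))
  if (length(regional_values) != length(ids)) {
    stopf("need one regional value per label (%d labels, %d values)",
          length(ids), length(regional_values))
  }
  truth <- array(background, dim = dim(labels))
  for (j in seq_along(ids)) truth[labels == ids[j]] <- regional_values[j]
  blurred <- gaussian_smooth_3d(truth, psf_fwhm_mm, voxel_size_mm)
  list(activity = blurred, truth = truth, labels = labels,
       voxel_size_mm = voxel_size_mm)
}
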