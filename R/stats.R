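#' Gamma GLM with log link
#'
#' Fits a generalized linear model with Gamma errors and a log link by
#' iteratively reweighted least squares. V_T is strictly positive and
#' right-skewed, which this family models directly. Dispersion is estimated
#' by the Pearson chi-square divided by the residual degrees of freedom;
#' coefficient standard errors come from the inverse Fisher information
#' scaled by the dispersion, and two-tailed p-values from the t distribution
#' with `n - p` degrees of freedom.
#'
#' @param y Strictly positive outcome vector.
#' @param X Design matrix (full column rank, including the intercept).
#' @return List: `coefficients`, `se`, `t`, `p`, `df`, `dispersion`,
#'   `fitted`, `loglik`.
#' @export
fit_gamma_glm_log <- function(y, X) {
  X <- as.matrix(X)
  if (any(!is.finite(y)) || any(y <= 0)) {
    stopf("Gamma GLM requires strictly positive outcomes (offending rows: %s)",
          paste(utils::head(which(!is.finite(y) | y <= 0), 5), collapse = ", "))
  }
  n <- length(y)
  if (nrow(X) != n) stopf("nrow(X) != length(y)")
  if (n <= ncol(X)) stopf("need more observations than columns")
  if (qr(X)$rank < ncol(X)) stopf("design matrix is rank deficient")

  fit <- glm.fit(X, y, family = Gamma(link = "log"))
  beta <- coef(fit)
  mu <- fit$fitted.values
  df <- n - ncol(X)
  dispersion <- sum((y - mu)^2 / mu^2) / df

  # Fisher information for the log link: X' W X with W = 1/dispersion
  # (unit weights after scaling); vcov = dispersion * (X'X weighted)^-1.
  # glm.fit's qr already holds the weighted design.
  R <- qr.R(fit$qr)
  vc <- dispersion * chol2inv(R)
  dimnames(vc) <- list(names(beta), names(beta))
  se <- setNames(sqrt(diag(vc)), names(beta))
  tval <- beta / se
  pval <- 2 * pt(abs(tval), df, lower.tail = FALSE)
  shape <- 1 / dispersion
  ll <- sum(dgamma(y, shape = shape, rate = shape / mu, log = TRUE))

  list(coefficients = beta, se = se, t = tval, p = pval, df = df,
       dispersion = dispersion, vcov = vc, fitted = mu, loglik = ll)
}

#' t-based effect sizes for a GLM coefficient
#'
#' Converts a coefficient test statistic `t = B/SE` on `df` degrees of
#' freedom into a correlation-type effect size `r = t / sqrt(t^2 + df)` and
#' a standardized mean difference `d = 2 t / sqrt(df)`. This is one standard
#' t-to-effect-size conversion; other conventions exist and would rescale
#' `d` by a constant.
#'
#' @param B Coefficient estimate.
#' @param SE Its standard error (> 0).
#' @param df Residual degrees of freedom (>= 1).
#' @return List with `t`, `d`, `r`.
#' @examples
#' effect_sizes(2, 1, 16)  # t = 2, d = 1, r = 0.447
#' @export
effect_sizes <- function(B, SE, df) {
  if (any(SE <= 0)) stopf("'SE' must be > 0")
  if (any(df < 1)) stopf("'df' must be >= 1")
  t <- B / SE
  list(t = t, d = 2 * t / sqrt(df), r = t / sqrt(t^2 + df))
}

#' Benjamini-Hochberg false-discovery-rate adjustment
#'
#' Step-up adjusted p-values: sorted ascending, `q_(i) = min_{j >= i}
#' p_(j) * m / j`, capped at 1 and returned in the input order.
#'
#' @param p Vector of p-values in `[0, 1]`.
#' @export
bh_fdr <- function(p) {
  if (any(!is.finite(p)) || any(p < 0 | p > 1)) stopf("p-values must lie in [0, 1]")
  p.adjust(p, method = "BH")
}

#' Regional V_T table
#'
#' @param subject_id,region,VT Vectors of equal length; `VT` strictly
#'   positive (mL/cm^3).
#' @param pvc Logical flag: partial-volume-corrected outcomes.
#' @export
regional_vt_table <- function(subject_id, region, VT, pvc = FALSE) {
  if (any(VT <= 0)) stopf("V_T must be strictly positive")
  data.frame(subject_id = subject_id, region = region, VT = VT, pvc = pvc)
}

default_predictor_specs <- function() {
  singles <- c("pcl5_total", "pcl5_re_experiencing", "pcl5_avoidance",
               "pcl5_negative_cognitions_mood", "pcl5_arousal", "months_wtc",
               cognition_domains())
  specs <- lapply(singles, function(v) list(name = v, vars = v, model = "single"))
  specs[[length(specs) + 1]] <- list(name = "pcl5_total+months_wtc",
                                     vars = c("pcl5_total", "months_wtc"),
                                     model = "joint")
  specs[[length(specs) + 1]] <- list(name = "mci_status", vars = "mci_status",
                                     model = "group")
  specs
}

#' Per-region Gamma/log-link association analysis
#'
#' For each region and predictor specification, fits
#' `V_T ~ genotype + predictor(s)` with a Gamma distribution and log link:
#' genotype (HAB = 1) enters as a fixed effect adjusting for the rs6971
#' binding-affinity difference. Continuous predictors are z-scored within
#' sample by default, so `B` is per predictor SD on the log-V_T scale
#' (`raw_units = TRUE` keeps the native scale). Effect sizes `d` and `r`
#' are derived from the coefficient t statistic, and BH-FDR adjustment is
#' applied within each predictor family across regions by default.
#'
#' @param vt_table Data frame with `subject_id`, `region`, `VT` (e.g.
#'   [regional_vt_table()] or the pipeline's vt.csv).
#' @param cohort Subject covariate table (one row per subject; see
#'   [simulate_cohort()]).
#' @param predictors Character vector of single predictors to test, or
#'   `NULL` for the full default battery (PCL-5 total, 4 symptom-cluster
#'   subscales, months on site, 6 cognitive domains, the joint
#'   severity+exposure model and the MCI group contrast).
#' @param adjust_genotype Include the HAB/MAB fixed effect (default TRUE).
#' @param raw_units Keep continuous predictors on their native scale.
#' @param fdr_family `"per_predictor"` (default: adjust across regions
#'   within each predictor) or `"global"` (one family over all tests).
#' @param fdr_level FDR level used for the significance marker (default
#'   0.05).
#' @return Long data frame of class `association_results`: `region`,
#'   `predictor`, `model_spec`, `B`, `SE`, `t`, `df`, `p`, `p_fdr`, `d`,
#'   `r`, `n`, `significant_fdr`.
#' @export
run_regional_analysis <- function(vt_table, cohort, predictors = NULL,
                                  adjust_genotype = TRUE, raw_units = FALSE,
                                  fdr_family = c("per_predictor", "global"),
                                  fdr_level = 0.05) {
  fdr_family <- match.arg(fdr_family)
  if (!all(vt_table$subject_id %in% cohort$subject_id)) {
    stopf("every subject in the V_T table must appear in the cohort")
  }
  if (adjust_genotype && length(unique(cohort$genotype)) < 2) {
    stopf("genotype adjustment needs both HAB and MAB groups present")
  }
  specs <- if (is.null(predictors)) {
    default_predictor_specs()
  } else {
    lapply(predictors, function(v) {
      list(name = v, vars = v,
           model = if (v %in% c("mci_status", "genotype")) "group" else "single")
    })
  }
  specs <- Filter(function(s) all(s$vars %in% names(cohort)), specs)
  regions <- unique(vt_table$region)

  rows <- list()
  for (spec in specs) {
    for (reg in regions) {
      sub <- vt_table[vt_table$region == reg, c("subject_id", "VT")]
      dat <- merge(sub, cohort, by = "subject_id", sort = TRUE)
      keep <- complete.cases(dat[, c("VT", "genotype", spec$vars)])
      n_dropped <- sum(!keep)
      if (n_dropped) {
        message(sprintf("%s/%s: excluding %d rows with missing covariates",
                        reg, spec$name, n_dropped))
      }
      dat <- dat[keep, , drop = FALSE]
      X <- matrix(1, nrow(dat), 1, dimnames = list(NULL, "(Intercept)"))
      if (adjust_genotype) {
        X <- cbind(X, genotype_hab = as.numeric(dat$genotype == "HAB"))
      }
      for (v in spec$vars) {
        col <- dat[[v]]
        if (is.character(col) || is.factor(col)) {
          lev <- sort(unique(as.character(col)))
          col <- as.numeric(as.character(col) == lev[length(lev)])
        } else if (!raw_units) {
          s <- sd(col)
          col <- if (s > 0) (col - mean(col)) / s else col * 0
        }
        X <- cbind(X, col)
        colnames(X)[ncol(X)] <- v
      }
      fit <- fit_gamma_glm_log(dat$VT, X)
      for (v in spec$vars) {
        es <- effect_sizes(fit$coefficients[[v]], fit$se[[v]], fit$df)
        rows[[length(rows) + 1]] <- data.frame(
          region = reg, predictor = v, model_spec = spec$name,
          B = fit$coefficients[[v]], SE = fit$se[[v]], t = es$t, df = fit$df,
          p = fit$p[[v]], d = es$d, r = es$r, n = nrow(dat))
      }
    }
  }
  res <- do.call(rbind, rows)
  res$p_fdr <- NA_real_
  if (fdr_family == "global") {
    res$p_fdr <- bh_fdr(res$p)
  } else {
    for (key in unique(paste(res$model_spec, res$predictor))) {
      sel <- paste(res$model_spec, res$predictor) == key
      res$p_fdr[sel] <- bh_fdr(res$p[sel])
    }
  }
  res$significant_fdr <- res$p_fdr < fdr_level
  res <- res[, c("region", "predictor", "model_spec", "B", "SE", "t", "df",
                 "p", "p_fdr", "d", "r", "n", "significant_fdr")]
  rownames(res) <- NULL
  class(res) <- c("association_results", "data.frame")
  res
}

#' Effect-size heat-map matrix
#'
#' Regions x predictors matrix of Cohen's d from single-predictor models,
#' with a companion marker matrix: `**` for p < 0.01, `*` for p < 0.05 and
#' `#` for 0.05 <= p < 0.1.
#'
#' @param results An `association_results` table.
#' @return List with numeric matrix `d` and character matrix `marker`.
#' @export
d_matrix <- function(results) {
  res <- results[results$model_spec == results$predictor, , drop = FALSE]
  if (!nrow(res)) res <- results
  regions <- unique(res$region)
  preds <- unique(res$predictor)
  D <- matrix(NA_real_, length(regions), length(preds),
              dimnames = list(regions, preds))
  M <- matrix("", length(regions), length(preds),
              dimnames = list(regions, preds))
  for (i in seq_len(nrow(res))) {
    D[res$region[i], res$predictor[i]] <- res$d[i]
    p <- res$p[i]
    M[res$region[i], res$predictor[i]] <-
      if (p < 0.01) "**" else if (p < 0.05) "*" else if (p < 0.1) "#" else ""
  }
  list(d = D, marker = M)
}

#' Write association results and heat-map CSV files
#'
#' @param results An `association_results` table.
#' @param results_path,heatmap_path Output CSV paths.
#' @export
write_results_csv <- function(results, results_path, heatmap_path = NULL) {
  write.csv(results, results_path, row.names = FALSE)
  if (!is.null(heatmap_path)) {
    hm <- d_matrix(results)
    out <- data.frame(region = rownames(hm$d), round(hm$d, 4),
                      check.names = FALSE)
    for (cn in colnames(hm$d)) {
      out[[cn]] <- paste0(out[[cn]], hm$marker[, cn])
    }
    write.csv(out, heatmap_path, row.names = FALSE)
  }
  invisible(results_path)
}
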