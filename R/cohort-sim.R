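#' Specification of a synthetic longitudinal CSVD cohort
#'
#' Defines the statistical structure of the simulated cohort: demographics
#' and vascular risk factors, a linear-mixed ALPS trajectory (random
#' intercept and slope), baseline imaging markers driven by a latent
#' disease-severity factor, cognition trajectories (age-standardized
#' z-scores) whose annual slopes depend on baseline ALPS, and a
#' Weibull-baseline proportional-hazards dementia process with
#' administrative censoring. Defaults are anchored to the marginals of a
#' single-center lacunar-stroke cohort: n = 120, mean age 70 (SD 8), 65%
#' male, mean annual ALPS slope -0.010, hazard ratio 0.328 per SD of
#' baseline ALPS, and about 18.2% five-year dementia incidence (the
#' Weibull scale is calibrated to that marginal incidence at
#' construction). Random-effect and residual SDs are the generator's own
#' choices, not estimated quantities.
#'
#' @param n number of subjects (>= 2).
#' @param mri_years MRI visit schedule in years (default 0:3).
#' @param cog_years cognition visit schedule in years (default 0:5).
#' @param age_mean,age_sd baseline age distribution.
#' @param male_frac male fraction.
#' @param p_htn,p_dm,p_chol risk-factor prevalences.
#' @param p_smoking probabilities for never/ex/current smoking.
#' @param nart_mean,nart_sd premorbid-IQ (NART) distribution.
#' @param alps_mean,alps_sd baseline ALPS distribution.
#' @param alps_slope fixed annual ALPS slope.
#' @param alps_slope_sd between-subject SD of the annual slope.
#' @param alps_resid_sd within-subject residual SD of ALPS.
#' @param severity_loading correlation of the latent severity factor with
#'   standardized baseline ALPS (negative: worse disease, lower ALPS).
#' @param cog_slope_mean named per-domain mean annual cognition slope
#'   (z-units/year).
#' @param cog_slope_per_alps named per-domain slope increment per SD of
#'   baseline ALPS (z-units/year).
#' @param cog_slope_sd,cog_resid_sd cognition random-slope and residual SDs.
#' @param hazard_shape Weibull baseline hazard shape.
#' @param hazard_scale Weibull scale (years); `NULL` calibrates it so that
#'   the marginal incidence at `censor_years` equals `target_incidence`
#'   under the stated log-hazard coefficients.
#' @param loghr_alps log hazard ratio per SD of baseline ALPS.
#' @param target_incidence marginal dementia incidence used for
#'   calibration when `hazard_scale` is `NULL`.
#' @param censor_years administrative censoring time.
#' @param seed integer seed used by [generate_cohort()].
#' @return object of class `cohort_spec`.
#' @export
cohort_spec <- function(n = 120,
                        mri_years = 0:3, cog_years = 0:5,
                        age_mean = 70, age_sd = 8, male_frac = 0.65,
                        p_htn = 0.85, p_dm = 0.20, p_chol = 0.60,
                        p_smoking = c(never = 0.35, ex = 0.45, current = 0.20),
                        nart_mean = 100, nart_sd = 12,
                        alps_mean = 1.30, alps_sd = 0.15,
                        alps_slope = -0.010, alps_slope_sd = 0.006,
                        alps_resid_sd = 0.03,
                        severity_loading = -0.5,
                        cog_slope_mean = c(global = -0.05, exec = -0.06,
                                           memory = -0.04, speed = -0.05),
                        cog_slope_per_alps = c(global = 0.030, exec = 0.060,
                                               memory = 0.045, speed = 0.010),
                        cog_slope_sd = 0.05, cog_resid_sd = 0.25,
                        hazard_shape = 1.2, hazard_scale = NULL,
                        loghr_alps = log(0.328),
                        target_incidence = 0.182,
                        censor_years = 5, seed = 1L) {
  stopifnot(n >= 2, age_sd > 0, nart_sd > 0, alps_sd > 0,
            alps_slope_sd >= 0, alps_resid_sd >= 0,
            cog_slope_sd >= 0, cog_resid_sd >= 0,
            hazard_shape > 0, censor_years > 0)
  probs <- c(male_frac, p_htn, p_dm, p_chol, p_smoking)
  if (any(probs < 0 | probs > 1)) stop("all probabilities must lie in [0, 1]")
  if (abs(sum(p_smoking) - 1) > 1e-8) stop("smoking probabilities must sum to 1")
  if (abs(severity_loading) > 1) stop("severity_loading must lie in [-1, 1]")
  if (is.null(hazard_scale)) {
    hazard_scale <- calibrate_weibull_scale(hazard_shape, loghr_alps,
                                            target_incidence, censor_years)
  }
  stopifnot(hazard_scale > 0)
  structure(list(
    n = as.integer(n), mri_years = mri_years, cog_years = cog_years,
    age_mean = age_mean, age_sd = age_sd, male_frac = male_frac,
    p_htn = p_htn, p_dm = p_dm, p_chol = p_chol, p_smoking = p_smoking,
    nart_mean = nart_mean, nart_sd = nart_sd,
    alps_mean = alps_mean, alps_sd = alps_sd,
    alps_slope = alps_slope, alps_slope_sd = alps_slope_sd,
    alps_resid_sd = alps_resid_sd, severity_loading = severity_loading,
    cog_slope_mean = cog_slope_mean, cog_slope_per_alps = cog_slope_per_alps,
    cog_slope_sd = cog_slope_sd, cog_resid_sd = cog_resid_sd,
    hazard_shape = hazard_shape, hazard_scale = hazard_scale,
    loghr_alps = loghr_alps, censor_years = censor_years,
    seed = as.integer(seed)
  ), class = "cohort_spec")
}

#' Calibrate the Weibull scale to a marginal event incidence
#'
#' Solves for the scale b such that the incidence by time `horizon`,
#' marginalized over a standard-normal covariate z with linear log hazard
#' `loghr * z`, equals `target`:
#' \deqn{E_z[1 - \exp(-(h/b)^k e^{\beta z})] = target.}
#' The expectation is evaluated by Gauss-type numerical integration; the
#' same integral serves as the closed-form oracle for the simulator's
#' incidence in tests.
#'
#' @param shape Weibull shape k.
#' @param loghr log hazard ratio per SD of the covariate.
#' @param target marginal incidence in (0, 1).
#' @param horizon time horizon.
#' @return the calibrated scale.
#' @export
calibrate_weibull_scale <- function(shape, loghr, target, horizon) {
  stopifnot(target > 0, target < 1)
  incidence <- function(scale) {
    f <- function(z) {
      (1 - exp(-(horizon / scale)^shape * exp(loghr * z))) * dnorm(z)
    }
    integrate(f, -8, 8, rel.tol = 1e-10)$value
  }
  uniroot(function(s) incidence(s) - target,
          interval = c(horizon * 1e-3, horizon * 1e4), tol = 1e-10)$root
}

#' Marginal incidence implied by a cohort specification
#'
#' Numerical integration of the Weibull proportional-hazards survival
#' function over the standardized baseline-ALPS distribution; the
#' independent oracle for the simulator's dementia incidence.
#'
#' @param spec a [cohort_spec()].
#' @param horizon time horizon (defaults to the censoring time).
#' @return expected event fraction by `horizon`.
#' @export
implied_incidence <- function(spec, horizon = spec$censor_years) {
  f <- function(z) {
    (1 - exp(-(horizon / spec$hazard_scale)^spec$hazard_shape *
               exp(spec$loghr_alps * z))) * dnorm(z)
  }
  integrate(f, -8, 8, rel.tol = 1e-10)$value
}

#' Generate a synthetic longitudinal cohort table
#'
#' Draws a long-format subject-visit table with the structure described in
#' [cohort_spec()]. Imaging markers (ALPS, PVS volumes, WMH, median MD,
#' PSMD) are observed at MRI visits, cognition at all cognition visits.
#' Dementia event times follow the Weibull proportional-hazards process
#' with log hazard `loghr_alps * z_alps` (z = standardized baseline ALPS),
#' censored administratively at `censor_years`.
#'
#' @param spec a [cohort_spec()].
#' @return list with `table` (long-format data.frame, one row per
#'   subject-visit over the cognition schedule) and `truth` (ground-truth
#'   parameters and per-subject latent values: `z_alps`, `severity`,
#'   per-subject ALPS slopes `alps_slope_i`, linear predictor `eta`, and
#'   uncensored event times `event_time`).
#' @export
generate_cohort <- function(spec) {
  stopifnot(inherits(spec, "cohort_spec"))
  if (spec$n < 2) stop("at least 2 subjects are required")
  set.seed(spec$seed)
  n <- spec$n
  lam <- spec$severity_loading
  z_alps <- rnorm(n)
  severity <- lam * z_alps + sqrt(1 - lam^2) * rnorm(n)
  subj <- data.frame(
    subject_id = sprintf("S%04d", seq_len(n)),
    age0 = round(spec$age_mean + spec$age_sd * rnorm(n), 1),
    sex = rbinom(n, 1, spec$male_frac),                    # 1 = male
    htn = rbinom(n, 1, spec$p_htn),
    dm = rbinom(n, 1, spec$p_dm),
    chol = rbinom(n, 1, spec$p_chol),
    smoking = sample(names(spec$p_smoking), n, TRUE, prob = spec$p_smoking),
    nart_iq = round(spec$nart_mean + spec$nart_sd * rnorm(n), 1),
    stringsAsFactors = FALSE
  )
  alps0 <- spec$alps_mean + spec$alps_sd * z_alps
  slope_i <- spec$alps_slope + spec$alps_slope_sd * rnorm(n)
  # baseline imaging markers driven by the latent severity factor
  subj$wmh <- -5.5 + 0.6 * severity + 0.4 * rnorm(n)       # log normalized WMH
  subj$lacunes <- rpois(n, exp(0.5 + 0.35 * severity))
  subj$microbleeds <- rpois(n, exp(-0.2 + 0.4 * severity))
  subj$md_median <- 0.90e-3 * (1 + 0.06 * severity + 0.03 * rnorm(n))
  subj$psmd <- 0.30e-3 * (1 + 0.12 * severity + 0.05 * rnorm(n))
  pvs0 <- list(
    pvs_wb = -6.2 + 0.25 * severity + 0.30 * rnorm(n),     # log normalized PVS
    pvs_bg = -7.6 + 0.25 * severity + 0.35 * rnorm(n),
    pvs_wm = -6.9 + 0.25 * severity + 0.35 * rnorm(n)
  )
  # dementia process
  eta <- spec$loghr_alps * z_alps
  u <- runif(n)
  event_time <- spec$hazard_scale * (-log(u) / exp(eta))^(1 / spec$hazard_shape)
  dementia_event <- as.integer(event_time <= spec$censor_years)
  dementia_time <- pmin(event_time, spec$censor_years)
  # cognition random slopes per domain
  domains <- names(spec$cog_slope_mean)
  cog_int <- matrix(rnorm(n * length(domains)), n,
                    dimnames = list(NULL, domains))
  cog_slope <- sapply(domains, function(d) {
    spec$cog_slope_mean[[d]] + spec$cog_slope_per_alps[[d]] * z_alps +
      spec$cog_slope_sd * rnorm(n)
  })

  years <- sort(unique(c(spec$mri_years, spec$cog_years)))
  rows <- vector("list", length(years))
  for (vi in seq_along(years)) {
    t <- years[vi]
    mri <- t %in% spec$mri_years
    cogv <- t %in% spec$cog_years
    r <- subj
    r$visit_year <- t
    r$alps <- if (mri) alps0 + slope_i * t + spec$alps_resid_sd * rnorm(n) else NA_real_
    for (nm in names(pvs0)) {
      r[[nm]] <- if (mri) pvs0[[nm]] + 0.10 * rnorm(n) else NA_real_
    }
    if (!mri) r[c("wmh", "md_median", "psmd")] <- NA_real_
    for (d in domains) {
      r[[paste0("cog_", d)]] <- if (cogv) {
        cog_int[, d] + cog_slope[, d] * t + spec$cog_resid_sd * rnorm(n)
      } else NA_real_
    }
    r$dementia_event <- dementia_event
    r$dementia_time <- dementia_time
    rows[[vi]] <- r
  }
  tab <- do.call(rbind, rows)
  tab <- tab[order(tab$subject_id, tab$visit_year), ]
  rownames(tab) <- NULL
  front <- c("subject_id", "visit_year")
  tab <- tab[, c(front, setdiff(names(tab), front))]
  truth <- list(spec = spec, z_alps = z_alps, severity = severity,
                alps0 = alps0, alps_slope_i = slope_i,
                cog_slope = cog_slope, eta = eta, event_time = event_time)
  list(table = tab, truth = truth)
}
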