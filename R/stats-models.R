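#' Named covariate sets for the nested model battery
#'
#' The covariate sets used throughout the analyses: `base` is age, sex and
#' the vascular risk factors (hypertension, diabetes,
#' hypercholesterolemia, 3-level smoking); `base_nart` adds premorbid IQ;
#' `csvd` additionally adjusts for the visible CSVD markers (WMH volume,
#' lacune count, microbleed count); `md` and `psmd` instead add one
#' conventional diffusion marker.
#'
#' @param set one of `"none"`, `"base"`, `"base_nart"`, `"csvd"`, `"md"`,
#'   `"psmd"`.
#' @return character vector of column names in the cohort table schema.
#' @export
covariate_set <- function(set = c("none", "base", "base_nart", "csvd",
                                  "md", "psmd")) {
  set <- match.arg(set)
  base <- c("age0", "sex", "htn", "dm", "chol", "smoking")
  switch(set,
         none = character(0),
         base = base,
         base_nart = c(base, "nart_iq"),
         csvd = c(base, "nart_iq", "wmh", "lacunes", "microbleeds"),
         md = c(base, "nart_iq", "md_median"),
         psmd = c(base, "nart_iq", "psmd"))
}

model_result <- function(term, estimate, conf.low, conf.high, p.value, n,
                         family, converged = TRUE, notes = character(0)) {
  structure(data.frame(term = term, estimate = estimate,
                       conf.low = conf.low, conf.high = conf.high,
                       p.value = p.value, n = n, family = family,
                       converged = converged, stringsAsFactors = FALSE),
            notes = notes, class = c("model_result", "data.frame"))
}

# z-score the continuous columns of a model frame; binary 0/1 columns and
# factors are left untouched so their coefficients keep their natural scale
standardize_frame <- function(df, cols) {
  for (cl in cols) {
    x <- df[[cl]]
    if (is.numeric(x) && length(unique(na.omit(x))) > 2) {
      df[[cl]] <- as.numeric(scale(x))
    }
  }
  df
}

check_rank <- function(df, vars) {
  mm <- model.matrix(as.formula(paste("~", paste(vars, collapse = "+"))), df)
  q <- qr(mm)
  if (q$rank < ncol(mm)) {
    bad <- colnames(mm)[q$pivot[(q$rank + 1):ncol(mm)]]
    stop("rank-deficient design; collinear columns: ", paste(bad, collapse = ", "))
  }
}

#' Cross-sectional linear regression with covariate adjustment
#'
#' Ordinary least squares of `outcome` on `predictor` plus a covariate
#' set. With `standardize = TRUE` (default) the outcome and all continuous
#' predictors are z-scored first, so the reported estimate is a
#' standardized beta.
#'
#' @param data data.frame (typically baseline rows of the cohort table).
#' @param outcome,predictor column names.
#' @param covariates character vector of covariate columns (see
#'   [covariate_set()]).
#' @param standardize z-score outcome and continuous predictors.
#' @return a `model_result` row for the predictor of interest.
#' @export
fit_linear <- function(data, outcome, predictor, covariates = character(0),
                       standardize = TRUE) {
  vars <- c(outcome, predictor, covariates)
  df <- data[complete.cases(data[, vars, drop = FALSE]), vars, drop = FALSE]
  if (nrow(df) < 10) stop("fewer than 10 complete cases")
  if (length(unique(df[[predictor]])) < 2) stop("predictor '", predictor, "' is constant")
  if (standardize) df <- standardize_frame(df, c(outcome, predictor, covariates))
  check_rank(df, c(predictor, covariates))
  f <- as.formula(paste(outcome, "~", paste(c(predictor, covariates), collapse = "+")))
  fit <- lm(f, data = df)
  est <- coef(fit)[[predictor]]
  ci <- confint(fit)[predictor, ]
  p <- summary(fit)$coefficients[predictor, 4]
  model_result(predictor, est, ci[1], ci[2], p, nrow(df), "linear")
}

#' Linear mixed model with random intercept and slope, plus slope extraction
#'
#' Fits `outcome ~ time (+ predictor * time + covariates)` with correlated
#' random intercept and random linear time slope per subject, by maximum
#' likelihood, with Satterthwaite degrees of freedom for the fixed-effect
#' p-values. When `predictor` is `NULL` the effect of interest is the mean
#' annual change (the fixed time slope); otherwise it is the
#' `predictor x time` interaction, i.e. how the annual change depends on
#' the baseline predictor. Per-subject slopes are extracted as
#' empirical-Bayes (BLUP) estimates by default, or as independent
#' per-subject OLS slopes.
#'
#' If the random-effects covariance is singular the model is refitted with
#' a random intercept only and the result is flagged
#' (`notes = "singular random slope; refit with random intercept only"`).
#'
#' @param data long-format data.frame.
#' @param outcome outcome column.
#' @param time time column (years), default `"visit_year"`.
#' @param predictor optional baseline predictor column (time-invariant).
#' @param covariates additional fixed-effect covariates.
#' @param subject grouping column, default `"subject_id"`.
#' @param standardize z-score outcome/continuous predictors before
#'   fitting (time is never standardized, so slopes stay per year).
#' @param slope_method `"blup"` (default) or `"ols"`.
#' @return list with `result` (a `model_result` for the effect of
#'   interest), `slopes` (data.frame subject/intercept/slope/method) and
#'   `fit` (the fitted lmerMod).
#' @export
fit_lmm <- function(data, outcome, time = "visit_year", predictor = NULL,
                    covariates = character(0), subject = "subject_id",
                    standardize = FALSE, slope_method = c("blup", "ols")) {
  slope_method <- match.arg(slope_method)
  vars <- c(outcome, time, predictor, covariates, subject)
  df <- data[complete.cases(data[, vars, drop = FALSE]), vars, drop = FALSE]
  nv <- table(df[[subject]])
  if (max(nv) < 2) stop("no subject has 2 or more visits: slope unidentifiable")
  if (mean(nv >= 2) < 0.5) stop("fewer than half of subjects have 2 or more visits")
  if (standardize) df <- standardize_frame(df, setdiff(c(outcome, predictor, covariates), time))
  fixed <- c(time, if (!is.null(predictor)) paste0(predictor, "*", time), covariates)
  f_full <- as.formula(paste(outcome, "~", paste(fixed, collapse = "+"),
                             "+ (1 +", time, "|", subject, ")"))
  notes <- character(0)
  fit <- suppressWarnings(suppressMessages(
    lmerTest::lmer(f_full, data = df, REML = FALSE)
  ))
  if (lme4::isSingular(fit, tol = 1e-5)) {
    f_ri <- as.formula(paste(outcome, "~", paste(fixed, collapse = "+"),
                             "+ (1 |", subject, ")"))
    fit <- suppressWarnings(suppressMessages(
      lmerTest::lmer(f_ri, data = df, REML = FALSE)
    ))
    notes <- "singular random slope; refit with random intercept only"
  }
  coefs <- summary(fit)$coefficients
  term <- if (is.null(predictor)) time else {
    hit <- grep(":", rownames(coefs), value = TRUE)
    hit[grepl(predictor, hit) & grepl(time, hit)][1]
  }
  est <- coefs[term, "Estimate"]
  se <- coefs[term, "Std. Error"]
  p <- coefs[term, "Pr(>|t|)"]
  res <- model_result(term, est, est - 1.96 * se, est + 1.96 * se, p,
                      length(unique(df[[subject]])), "linear-mixed",
                      converged = TRUE, notes = notes)
  slopes <- extract_slopes(fit, df, outcome, time, predictor, subject,
                           slope_method)
  list(result = res, slopes = slopes, fit = fit)
}

extract_slopes <- function(fit, df, outcome, time, predictor, subject,
                           method) {
  ids <- unique(df[[subject]])
  if (method == "ols") {
    sl <- t(vapply(ids, function(id) {
      d <- df[df[[subject]] == id, ]
      if (length(unique(d[[time]])) < 2) return(c(NA_real_, NA_real_))
      cf <- coef(lm(d[[outcome]] ~ d[[time]]))
      c(cf[1], cf[2])
    }, numeric(2)))
  } else {
    cf <- coef(fit)[[subject]]                   # fixed + BLUP per subject
    cf <- cf[match(ids, rownames(cf)), , drop = FALSE]
    slope <- cf[[time]]
    # interaction contribution: d outcome / d time includes predictor:time
    if (!is.null(predictor)) {
      inter <- grep(":", colnames(cf), value = TRUE)
      inter <- inter[grepl(predictor, inter) & grepl(time, inter)]
      if (length(inter) == 1) {
        x <- df[[predictor]][match(ids, df[[subject]])]
        slope <- slope + cf[[inter]] * x
      }
    }
    sl <- cbind(cf[["(Intercept)"]], slope)
  }
  data.frame(subject = ids, intercept = sl[, 1], slope = sl[, 2],
             method = method, stringsAsFactors = FALSE)
}

#' Logistic regression for binary marker outcomes
#'
#' Maximum-likelihood logistic fit of a binary outcome (e.g. any new
#' lacune / any new microbleed) on a predictor plus covariates; the
#' estimate is the odds ratio per unit (per SD when `standardize = TRUE`)
#' of the predictor. Complete separation is detected and reported as
#' non-convergence with `NA` estimates rather than a silently diverging
#' coefficient.
#'
#' @inheritParams fit_linear
#' @return a `model_result` row (estimate on the odds-ratio scale).
#' @export
fit_logistic <- function(data, outcome, predictor, covariates = character(0),
                         standardize = TRUE) {
  vars <- c(outcome, predictor, covariates)
  df <- data[complete.cases(data[, vars, drop = FALSE]), vars, drop = FALSE]
  y <- df[[outcome]]
  if (length(unique(y)) < 2) stop("outcome '", outcome, "' has a single class")
  if (standardize) df <- standardize_frame(df, c(predictor, covariates))
  f <- as.formula(paste(outcome, "~", paste(c(predictor, covariates), collapse = "+")))
  sep <- FALSE
  fit <- withCallingHandlers(
    glm(f, data = df, family = binomial()),
    warning = function(w) {
      if (grepl("fitted probabilities numerically 0 or 1|did not converge",
                conditionMessage(w))) {
        sep <<- TRUE
        invokeRestart("muffleWarning")
      }
    }
  )
  se <- sqrt(diag(vcov(fit)))[predictor]
  if (sep || !fit$converged || se > 1e3) {
    return(model_result(predictor, NA_real_, NA_real_, NA_real_, NA_real_,
                        nrow(df), "logistic", converged = FALSE,
                        notes = "complete or quasi-complete separation"))
  }
  b <- coef(fit)[[predictor]]
  p <- summary(fit)$coefficients[predictor, 4]
  model_result(predictor, exp(b), exp(b - 1.96 * se), exp(b + 1.96 * se), p,
               nrow(df), "logistic")
}

#' Cox proportional-hazards model for incident dementia
#'
#' Partial-likelihood Cox fit with Efron handling of tied event times.
#' With `standardize = TRUE` the predictor of interest (and continuous
#' covariates) are z-scored, so the hazard ratio is per SD of the
#' predictor. Covariate sets follow [covariate_set()] identifiers, making
#' the nested adjustment ladder reproducible.
#'
#' @param data data.frame with one row per subject (baseline rows).
#' @param time,event column names for follow-up time (> 0) and event
#'   indicator (0/1).
#' @param predictor predictor of interest.
#' @param covariates covariate columns or a single [covariate_set()]
#'   identifier.
#' @param standardize hazard ratio per SD of the predictor.
#' @return a `model_result` row (estimate on the hazard-ratio scale).
#' @export
fit_cox <- function(data, time = "dementia_time", event = "dementia_event",
                    predictor = "alps", covariates = character(0),
                    standardize = TRUE) {
  if (length(covariates) == 1 &&
      covariates %in% c("none", "base", "base_nart", "csvd", "md", "psmd")) {
    covariates <- covariate_set(covariates)
  }
  vars <- c(time, event, predictor, covariates)
  df <- data[complete.cases(data[, vars, drop = FALSE]), vars, drop = FALSE]
  if (any(df[[time]] <= 0)) stop("all follow-up times must be positive")
  nev <- sum(df[[event]])
  if (nev == 0) stop("no events: Cox model cannot be fitted")
  if (nev < 5) stop("fewer than 5 events; fit would be unstable")
  if (standardize) df <- standardize_frame(df, c(predictor, covariates))
  f <- as.formula(paste("survival::Surv(", time, ",", event, ") ~",
                        paste(c(predictor, covariates), collapse = "+")))
  notes <- character(0)
  fit <- withCallingHandlers(
    survival::coxph(f, data = df, ties = "efron"),
    warning = function(w) {
      msg <- conditionMessage(w)
      if (grepl("converge|infinite", msg)) {
        notes <<- c(notes, trimws(msg))
        invokeRestart("muffleWarning")
      }
    }
  )
  s <- summary(fit)
  converged <- length(notes) == 0
  if (!converged) {
    grad <- tryCatch(
      sqrt(sum(colSums(survival::coxph.detail(fit)$score)^2)),
      error = function(e) NA_real_
    )
    notes <- c(notes, sprintf("score gradient norm %.3g", grad))
  }
  b <- coef(fit)[[predictor]]
  se <- sqrt(diag(vcov(fit)))[[predictor]]
  p <- s$coefficients[predictor, "Pr(>|z|)"]
  model_result(predictor, exp(b), exp(b - 1.96 * se), exp(b + 1.96 * se), p,
               nrow(df), "cox", converged = converged, notes = notes)
}

#' Benjamini-Hochberg false discovery rate adjustment within families
#'
#' Step-up BH adjustment applied separately within each declared family
#' (a family is typically one results table). Adjusted values are monotone
#' in the raw p-values and capped at 1.
#'
#' @param p numeric vector of p-values in [0, 1] (`NA` passed through).
#' @param family optional vector defining families; `NULL` treats all
#'   p-values as one family.
#' @return adjusted p-values in the original order.
#' @export
fdr_adjust <- function(p, family = NULL) {
  if (any(p < 0 | p > 1, na.rm = TRUE)) stop("p-values must lie in [0, 1]")
  if (is.null(family)) return(p.adjust(p, method = "BH"))
  stopifnot(length(family) == length(p))
  out <- rep(NA_real_, length(p))
  for (f in unique(family)) {
    sel <- which(family == f)
    out[sel] <- p.adjust(p[sel], method = "BH")
  }
  out
}
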