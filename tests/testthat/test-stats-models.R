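baseline_table <- function(n = 300, seed = 1) {
  coh <- generate_cohort(cohort_spec(n = n, seed = seed))
  coh$table[coh$table$visit_year == 0, ]
}

test_that("standardized beta is 1 for a perfectly collinear outcome", {
  set.seed(2)
  d <- data.frame(x = rnorm(50))
  d$y <- 2 * d$x
  r <- suppressWarnings(fit_linear(d, "y", "x"))  # perfect fit warns in summary
  expect_equal(r$estimate, 1.0, tolerance = 1e-10)
  expect_lt(r$p.value, 1e-12)
})

test_that("null predictors give standardized betas inside the 3/sqrt(n) band", {
  set.seed(3)
  n <- 1000
  d <- data.frame(x = rnorm(n), y = rnorm(n))
  r <- fit_linear(d, "y", "x")
  expect_lt(abs(r$estimate), 3 / sqrt(n))
})

test_that("a planted partial coefficient is recovered within 2 SE", {
  set.seed(4)
  n <- 800
  age <- rnorm(n); sexv <- rbinom(n, 1, 0.5)
  x <- 0.5 * age + rnorm(n)
  y <- 0.3 * x + 0.4 * age + 0.2 * sexv + rnorm(n)
  d <- data.frame(y = y, x = x, age = age, sex = sexv)
  # oracle: the same partial coefficient from the standardized normal equations
  r <- fit_linear(d, "y", "x", covariates = c("age", "sex"))
  zfit <- lm(scale(y) ~ scale(x) + scale(age) + sex, data = d)
  expect_equal(r$estimate, unname(coef(zfit)[2]), tolerance = 1e-10)
  se <- summary(zfit)$coefficients[2, 2]
  planted_std <- 0.3 * sd(x) / sd(y)
  expect_lt(abs(r$estimate - planted_std), 2 * se)
})

test_that("collinear designs are rejected with the offending columns named", {
  d <- baseline_table(60, seed = 6)
  d$alps_copy <- d$alps
  expect_error(fit_linear(d, "wmh", "alps", covariates = "alps_copy"),
               "alps_copy")
  d$const <- 1
  expect_error(fit_linear(d, "wmh", "const"), "constant")
})

test_that("mixed model recovers planted fixed slope and shrinks subject slopes", {
  spec <- cohort_spec(n = 200, alps_slope = -0.010, alps_slope_sd = 0.005,
                      alps_resid_sd = 0.01, seed = 7)
  coh <- generate_cohort(spec)
  m <- fit_lmm(coh$table, "alps")
  se <- (m$result$conf.high - m$result$estimate) / 1.96
  expect_lt(abs(m$result$estimate - (-0.010)), 2 * se)
  # variance components within a loose factor of the planted values
  vc <- as.data.frame(lme4::VarCorr(m$fit))
  slope_sd <- vc$sdcor[!is.na(vc$var1) & vc$var1 == "visit_year" & is.na(vc$var2)]
  expect_gt(slope_sd, 0.002); expect_lt(slope_sd, 0.008)
  # BLUP slopes are shrunken: less dispersed than per-subject OLS slopes
  ols <- fit_lmm(coh$table, "alps", slope_method = "ols")$slopes
  expect_lt(var(m$slopes$slope), var(ols$slope, na.rm = TRUE))
  expect_equal(sort(m$slopes$subject), sort(unique(coh$table$subject_id)))
})

test_that("mixed model on single-visit data errors; few-visit data errors", {
  coh <- generate_cohort(cohort_spec(n = 20, seed = 8))
  one <- coh$table[coh$table$visit_year == 0, ]
  expect_error(fit_lmm(one, "alps"), "slope unidentifiable")
})

test_that("interaction route: baseline marker modifies the cognition slope", {
  spec <- cohort_spec(n = 400, cog_slope_sd = 0.02, cog_resid_sd = 0.15,
                      seed = 9)
  coh <- generate_cohort(spec)
  tab <- coh$table
  b <- tab[tab$visit_year == 0, c("subject_id", "alps")]
  names(b)[2] <- "alps0"
  tab <- merge(tab, b, by = "subject_id")
  m <- fit_lmm(tab, "cog_exec", predictor = "alps0")
  # planted: the slope rises 0.060 z/yr per SD of latent baseline ALPS,
  # i.e. 0.060 / alps_sd per unit of the (noisily observed) marker
  se <- (m$result$conf.high - m$result$estimate) / 1.96
  expect_lt(abs(m$result$estimate - 0.060 / spec$alps_sd), 3 * se)
  expect_lt(m$result$p.value, 1e-6)
})

test_that("logistic regression recovers planted odds ratios and flags separation", {
  set.seed(10)
  n <- 2000
  x <- rnorm(n)
  # null
  y0 <- rbinom(n, 1, 0.3)
  r0 <- fit_logistic(data.frame(y = y0, x = x), "y", "x", standardize = FALSE)
  se0 <- (log(r0$conf.high) - log(r0$estimate)) / 1.96
  expect_lt(abs(log(r0$estimate)), 3 * se0)
  # planted log-OR 1.0
  y1 <- rbinom(n, 1, plogis(-1 + 1.0 * x))
  r1 <- fit_logistic(data.frame(y = y1, x = x), "y", "x", standardize = FALSE)
  se1 <- (log(r1$conf.high) - log(r1$estimate)) / 1.96
  expect_lt(abs(log(r1$estimate) - 1.0), 2 * se1)
  # degenerate outcomes
  expect_error(fit_logistic(data.frame(y = rep(0, 50), x = rnorm(50)), "y", "x"),
               "single class")
  # complete separation is reported, not silently estimated
  d <- data.frame(x = c(rnorm(20, -3), rnorm(20, 3)), y = rep(0:1, each = 20))
  rs <- fit_logistic(d, "y", "x", standardize = FALSE)
  expect_false(rs$converged)
  expect_true(is.na(rs$estimate))
})

test_that("Cox model needs events and positive times", {
  b <- baseline_table(100, seed = 12)
  b$dementia_event <- 0
  expect_error(fit_cox(b, predictor = "alps"), "no events")
  b2 <- baseline_table(100, seed = 12)
  b2$dementia_time[1] <- 0
  expect_error(fit_cox(b2, predictor = "alps"), "positive")
})

test_that("Cox covariate-set identifiers expand to the documented sets", {
  b <- baseline_table(400, seed = 14)
  r1 <- fit_cox(b, predictor = "alps", covariates = "base_nart")
  r2 <- fit_cox(b, predictor = "alps", covariates = covariate_set("base_nart"))
  expect_equal(r1$estimate, r2$estimate)
  expect_identical(covariate_set("csvd"),
                   c("age0", "sex", "htn", "dm", "chol", "smoking", "nart_iq",
                     "wmh", "lacunes", "microbleeds"))
})

test_that("BH adjustment equals the brute-force oracle on all small subsets", {
  pool <- c(0.001, 0.008, 0.01, 0.02, 0.03, 0.04, 0.2, 0.7)
  for (k in 1:8) {
    combs <- utils::combn(8, k)
    for (j in seq_len(ncol(combs))) {
      p <- pool[combs[, j]]
      expect_equal(fdr_adjust(p), bh_oracle(p), tolerance = 1e-12)
    }
  }
  expect_equal(fdr_adjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(fdr_adjust(0.37), 0.37)
  expect_equal(fdr_adjust(c(0.5, 1.0)), c(1.0, 1.0))
  expect_error(fdr_adjust(c(0.5, 1.2)), "\\[0, 1\\]")
  # families adjusted independently
  p <- c(0.01, 0.04, 0.01, 0.04)
  fam <- c("a", "a", "b", "b")
  expect_equal(fdr_adjust(p, fam), c(bh_oracle(p[1:2]), bh_oracle(p[3:4])))
})
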