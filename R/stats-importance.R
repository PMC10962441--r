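#' Random-forest variable importance for a marker panel
#'
#' Fits a seeded random forest (regression for continuous outcomes,
#' probability classification for binary ones) and returns permutation
#' importance -- the mean increase in out-of-bag loss when a predictor is
#' permuted -- ranked in decreasing order. This is the pragmatic companion
#' to multivariable regression when the marker panel is collinear (WMH,
#' lacunes, microbleeds, ALPS, PVS volume, PSMD, median MD all track
#' disease severity). A standard permutation-importance forest is used;
#' conditional-inference forests are a known alternative and results are
#' labelled accordingly in the metadata.
#'
#' @param data data.frame.
#' @param outcome outcome column.
#' @param predictors character vector of predictor columns; the documented
#'   default panel is age, sex, NART-IQ, WMH, lacunes, microbleeds,
#'   DTI-ALPS, PVS volume, PSMD and median MD.
#' @param seed integer seed; results are deterministic given the seed.
#' @param num_trees number of trees (default 1000).
#' @return data.frame with columns `predictor` and `importance`, sorted
#'   decreasing, with attribute `metadata` (method, seed, n, trees).
#' @export
variable_importance <- function(data, outcome,
                                predictors = c("age0", "sex", "nart_iq",
                                               "wmh", "lacunes", "microbleeds",
                                               "alps", "pvs_wb", "psmd",
                                               "md_median"),
                                seed = 1L, num_trees = 1000) {
  stopifnot(length(predictors) >= 2)
  vars <- c(outcome, predictors)
  df <- data[complete.cases(data[, vars, drop = FALSE]), vars, drop = FALSE]
  y <- df[[outcome]]
  if (length(unique(y)) < 2) stop("outcome '", outcome, "' is constant")
  if (is.character(df[[outcome]])) df[[outcome]] <- factor(df[[outcome]])
  for (p in predictors) if (is.character(df[[p]])) df[[p]] <- factor(df[[p]])
  f <- as.formula(paste(outcome, "~", paste(predictors, collapse = "+")))
  fit <- ranger::ranger(f, data = df, num.trees = num_trees,
                        importance = "permutation", seed = seed,
                        respect.unordered.factors = "order")
  imp <- fit$variable.importance
  out <- data.frame(predictor = names(imp), importance = unname(imp),
                    stringsAsFactors = FALSE)
  out <- out[order(-out$importance), ]
  rownames(out) <- NULL
  attr(out, "metadata") <- list(
    method = "random forest, permutation importance (not a conditional-inference forest)",
    seed = seed, n = nrow(df), num_trees = num_trees
  )
  out
}
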