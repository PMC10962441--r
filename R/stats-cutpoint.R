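#' Optimal cutpoint by exhaustive Youden-index search
#'
#' Searches all midpoints between consecutive distinct score values for
#' the cutoff maximizing Youden's J = sensitivity + specificity - 1 for
#' classifying the event. The risk side is chosen from the sign of the
#' score-event association: when events have lower mean scores, scores at
#' or below the cutoff are called positive (`direction = "<="`), otherwise
#' scores at or above it (`direction = ">="`). Ties on J are broken toward
#' the cutoff with the more balanced group split, then toward the smaller
#' cutoff.
#'
#' @param scores numeric marker values (non-constant).
#' @param events 0/1 event indicator.
#' @param direction `"auto"` (default), `"<="` or `">="`.
#' @return list with `cutpoint`, `direction`, `youden`, `sensitivity`,
#'   `specificity`.
#' @export
best_cutpoint <- function(scores, events, direction = c("auto", "<=", ">=")) {
  direction <- match.arg(direction)
  ok <- complete.cases(scores, events)
  scores <- scores[ok]; events <- as.integer(events[ok])
  if (length(unique(scores)) < 2) stop("scores are constant; no cutpoint exists")
  if (length(unique(events)) < 2) stop("both event classes must be present")
  if (direction == "auto") {
    direction <- if (mean(scores[events == 1]) <= mean(scores[events == 0]))
      "<=" else ">="
  }
  su <- sort(unique(scores))
  cand <- (su[-1] + su[-length(su)]) / 2
  npos <- sum(events == 1); nneg <- sum(events == 0)
  best <- NULL
  for (cut in cand) {
    pred <- if (direction == "<=") scores <= cut else scores >= cut
    sens <- sum(pred & events == 1) / npos
    spec <- sum(!pred & events == 0) / nneg
    J <- sens + spec - 1
    imbalance <- abs(sum(pred) - sum(!pred))
    if (is.null(best) || J > best$youden + 1e-12 ||
        (abs(J - best$youden) <= 1e-12 &&
           (imbalance < best$imbalance ||
              (imbalance == best$imbalance && cut < best$cutpoint)))) {
      best <- list(cutpoint = cut, direction = direction, youden = J,
                   sensitivity = sens, specificity = spec,
                   imbalance = imbalance)
    }
  }
  best$imbalance <- NULL
  best
}

#' Kaplan-Meier curves and two-group log-rank test
#'
#' Kaplan-Meier survival estimates per group with a risk table, and the
#' log-rank test comparing the groups (the classic survival-curve display
#' for a marker dichotomized at its optimal cutpoint).
#'
#' @param time follow-up times.
#' @param event 0/1 event indicator.
#' @param group group labels (two non-empty groups).
#' @return list with `curves` (data.frame: group, time, n.risk, n.event,
#'   surv), `chisq`, `df`, `p` (log-rank; `NA` when there are no events)
#'   and `fit` (the survfit object).
#' @export
km_logrank <- function(time, event, group) {
  group <- as.factor(group)
  if (any(table(group) == 0) || nlevels(droplevels(group)) < 2) {
    stop("each group must contain at least one subject")
  }
  group <- droplevels(group)
  fit <- survival::survfit(survival::Surv(time, event) ~ group)
  strata <- rep(names(fit$strata), fit$strata)
  curves <- data.frame(group = sub("^group=", "", strata), time = fit$time,
                       n.risk = fit$n.risk, n.event = fit$n.event,
                       surv = fit$surv, stringsAsFactors = FALSE)
  if (sum(event) == 0) {
    return(list(curves = curves, chisq = NA_real_, df = NA_integer_,
                p = NA_real_, fit = fit))
  }
  sd <- survival::survdiff(survival::Surv(time, event) ~ group)
  df <- length(sd$n) - 1
  p <- pchisq(sd$chisq, df = df, lower.tail = FALSE)
  list(curves = curves, chisq = sd$chisq, df = df, p = p, fit = fit)
}
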