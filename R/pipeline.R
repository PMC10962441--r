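#' Imaging stage: per-subject markers from DWI and tissue maps
#'
#' Chains the imaging pipeline for a list of subject-visits: tensor fit,
#' diffusivity maps, DTI-ALPS with orientation QC, PVS volumetry, median
#' WM MD and simplified PSMD. Failures are isolated per subject: an
#' errored subject yields a row with the error message recorded and the
#' run continues; the failure count is attached to the result.
#'
#' @param subjects list; each element a list with `id`, `visit`, and
#'   either `acq` (a [dwi_acquisition()]) or `dwi` (path to NIfTI, with
#'   bval/bvec alongside); optional `affine` (map-to-template 4x4, default
#'   identity), `tissue` (a [tissue_maps()] for PVS volumetry), `wm_mask`
#'   and `skeleton_mask` on the DWI grid (default: all valid voxels).
#' @param rois ROI set (default [build_roi_set()]).
#' @param out_csv optional path; the marker table is written as CSV.
#' @return data.frame, one row per subject-visit, with ALPS
#'   (left/right/mean), PVS volumes (raw/normalized/log x whole-brain/BG/
#'   WM), median MD, PSMD and QC columns; attribute `n_failed` counts
#'   failed subjects.
#' @export
run_imaging <- function(subjects, rois = build_roi_set(), out_csv = NULL) {
  rows <- lapply(subjects, function(s) {
    base <- data.frame(subject_id = s$id, visit_year = s$visit %||% 0,
                       stringsAsFactors = FALSE)
    tryCatch({
      acq <- s$acq %||% read_dwi(s$dwi)
      affine <- s$affine %||% diag(4)
      if (is.character(affine)) affine <- read_affine(affine)
      tf <- fit_tensor(acq)
      maps <- derive_maps(tf)
      alps <- compute_alps(maps, rois, affine = affine)
      oqc <- roi_orientation_qc(tf, rois, affine = affine)
      wm <- s$wm_mask %||% maps$valid
      skel <- s$skeleton_mask %||% wm
      row <- cbind(base, data.frame(
        alps_left = alps$left, alps_right = alps$right, alps_mean = alps$mean,
        md_median = median_md(maps, wm), psmd = psmd(maps, skel),
        qc_invalid_roi_voxels = alps$qc$n_invalid_total,
        qc_negative_eig = tf$qc$n_negative_eig,
        qc_orientation_warn = any(oqc$warn),
        error = NA_character_, stringsAsFactors = FALSE))
      if (!is.null(s$tissue)) {
        pvs <- make_pvs_map(s$tissue)
        vols <- pvs_volumes(pvs, s$tissue)
        for (i in seq_len(nrow(vols))) {
          reg <- c(whole_brain = "wb", bg = "bg", wm = "wm")[[vols$region[i]]]
          row[[paste0("pvs_", reg, "_raw")]] <- vols$raw_mm3[i]
          row[[paste0("pvs_", reg, "_norm")]] <- vols$normalized[i]
          row[[paste0("pvs_", reg, "_log")]] <- vols$log_normalized[i]
        }
      }
      row
    }, error = function(e) {
      cbind(base, data.frame(alps_left = NA_real_, alps_right = NA_real_,
                             alps_mean = NA_real_, md_median = NA_real_,
                             psmd = NA_real_, qc_invalid_roi_voxels = NA,
                             qc_negative_eig = NA, qc_orientation_warn = NA,
                             error = conditionMessage(e),
                             stringsAsFactors = FALSE))
    })
  })
  all_cols <- unique(unlist(lapply(rows, names)))
  rows <- lapply(rows, function(r) {
    r[setdiff(all_cols, names(r))] <- NA
    r[all_cols]
  })
  out <- do.call(rbind, rows)
  attr(out, "n_failed") <- sum(!is.na(out$error))
  if (attr(out, "n_failed") > 0) {
    warning(attr(out, "n_failed"), " subject(s) failed the imaging stage")
  }
  if (!is.null(out_csv)) write.csv(out, out_csv, row.names = FALSE)
  out
}

# attach baseline marker values (visit_year == 0) as *_0 columns
with_baseline <- function(tab, markers = c("alps", "pvs_wb")) {
  b <- tab[tab$visit_year == 0, c("subject_id", markers)]
  names(b)[-1] <- paste0(markers, "0")
  merge(tab, b, by = "subject_id", all.x = TRUE, sort = FALSE)
}

#' Analysis stage: the full statistical battery over a cohort table
#'
#' Runs, in order: baseline cross-sectional associations of the PVS
#' markers (DTI-ALPS and whole-brain PVS volume) with CSVD imaging
#' markers; longitudinal change of the PVS markers (mixed-model time
#' slopes); baseline PVS markers as predictors of cognitive change
#' (marker x time interactions per domain); baseline markers as predictors
#' of incident dementia (Cox, nested covariate sets); optimal-cutpoint
#' survival stratification with Kaplan-Meier curves and a log-rank test;
#' and random-forest variable importance. Raw and FDR-adjusted p-values
#' are reported with one FDR family per results table.
#'
#' @param tab long-format cohort table (schema of [generate_cohort()]).
#' @param seed seed for the variable-importance forest.
#' @param predictors PVS marker columns analysed as predictors.
#' @return list of class `alpspvs_analysis` with elements `baseline`,
#'   `progression`, `cognition`, `dementia`, `cutpoint`, `survival`,
#'   `importance` and `manifest` (every model spec run). When the cohort
#'   has no dementia events, `dementia` is replaced by a skip record and
#'   cutpoint/survival are `NULL`.
#' @export
run_analysis <- function(tab, seed = 1L, predictors = c("alps", "pvs_wb")) {
  required <- c("subject_id", "visit_year", "age0", "sex", "htn", "dm", "chol",
                "smoking", "nart_iq", "alps", "pvs_wb", "wmh", "lacunes",
                "microbleeds", "md_median", "psmd", "dementia_event",
                "dementia_time")
  missing_cols <- setdiff(required, names(tab))
  if (length(missing_cols)) {
    stop("cohort table is missing columns: ", paste(missing_cols, collapse = ", "))
  }
  manifest <- list()
  note <- function(...) manifest[[length(manifest) + 1]] <<- list(...)
  base_rows <- tab[tab$visit_year == 0, ]
  tab <- with_baseline(tab, predictors)

  # -- baseline cross-sectional associations ------------------------------
  outcomes <- c("wmh", "lacunes", "microbleeds", "psmd", "md_median")
  baseline <- do.call(rbind, lapply(predictors, function(pr) {
    do.call(rbind, lapply(outcomes, function(oc) {
      r <- fit_linear(base_rows, oc, pr, covariate_set("base"))
      note(stage = "baseline", family = "linear", outcome = oc,
           predictor = pr, covariates = "base")
      cbind(predictor = pr, outcome = oc, r)
    }))
  }))
  baseline$p.fdr <- fdr_adjust(baseline$p.value)

  # -- longitudinal change of the markers ---------------------------------
  progression <- do.call(rbind, lapply(predictors, function(pr) {
    m <- fit_lmm(tab, pr)
    note(stage = "progression", family = "linear-mixed", outcome = pr,
         predictor = "visit_year", covariates = "none")
    cbind(marker = pr, m$result)
  }))
  progression$p.fdr <- fdr_adjust(progression$p.value)

  # -- baseline markers -> cognitive change -------------------------------
  domains <- grep("^cog_", names(tab), value = TRUE)
  cog_fits <- list()
  cognition <- do.call(rbind, lapply(predictors, function(pr) {
    pr0 <- paste0(pr, "0")
    do.call(rbind, lapply(domains, function(d) {
      m <- fit_lmm(tab, d, predictor = pr0,
                   covariates = covariate_set("base_nart"), standardize = TRUE)
      note(stage = "cognition", family = "linear-mixed", outcome = d,
           predictor = pr0, covariates = "base_nart")
      cog_fits[[paste(d, pr, sep = ".")]] <<- m
      cbind(predictor = pr, outcome = d, m$result)
    }))
  }))
  cognition$p.fdr <- fdr_adjust(cognition$p.value)

  # -- incident dementia ---------------------------------------------------
  n_events <- sum(base_rows$dementia_event)
  cutpoint <- survival_curves <- NULL
  if (n_events == 0) {
    dementia <- list(skipped = TRUE,
                     reason = "no dementia events in the cohort")
  } else {
    sets <- c("base_nart", "csvd", "md", "psmd")
    dementia <- do.call(rbind, lapply(predictors, function(pr) {
      do.call(rbind, lapply(sets, function(cs) {
        r <- fit_cox(base_rows, predictor = pr, covariates = cs)
        note(stage = "dementia", family = "cox", outcome = "dementia",
             predictor = pr, covariates = cs)
        cbind(predictor = pr, covariate_set = cs, r)
      }))
    }))
    dementia$p.fdr <- fdr_adjust(dementia$p.value)
    cutpoint <- best_cutpoint(base_rows$alps, base_rows$dementia_event)
    grp <- ifelse(
      if (cutpoint$direction == "<=") base_rows$alps <= cutpoint$cutpoint
      else base_rows$alps >= cutpoint$cutpoint,
      "high risk", "low risk")
    survival_curves <- km_logrank(base_rows$dementia_time,
                                  base_rows$dementia_event, grp)
    note(stage = "survival", family = "km-logrank", outcome = "dementia",
         predictor = "alps (dichotomized at optimal cutpoint)",
         covariates = "none")
  }

  # -- variable importance -------------------------------------------------
  slopes_g <- cog_fits[["cog_global.alps"]]$slopes
  imp_tab <- merge(base_rows,
                   data.frame(subject_id = slopes_g$subject,
                              cog_global_slope = slopes_g$slope),
                   by = "subject_id")
  importance <- variable_importance(imp_tab, "cog_global_slope", seed = seed)
  note(stage = "importance", family = "random-forest",
       outcome = "cog_global_slope", predictor = "panel", covariates = "none")

  structure(list(baseline = baseline, progression = progression,
                 cognition = cognition, dementia = dementia,
                 cutpoint = cutpoint, survival = survival_curves,
                 importance = importance, manifest = manifest),
            class = "alpspvs_analysis")
}

#' End-to-end demonstration on synthetic data
#'
#' Generates three ALPS phantoms with known planted diffusivities plus a
#' tissue phantom, runs the imaging stage, simulates a longitudinal cohort
#' with the default specification, runs the statistical battery, and
#' renders a short markdown report with the marker table, the four results
#' tables and the survival stratification.
#'
#' @param seed integer seed driving every stochastic component.
#' @param fast reduce the cohort size (n = 60) and forest size for a quick
#'   smoke run.
#' @param out_dir output directory (default a fresh temporary directory).
#' @return list with `markers`, `analysis`, `report` (path), invisibly.
#' @export
end_to_end_demo <- function(seed = 1L, fast = FALSE, out_dir = NULL) {
  out_dir <- out_dir %||% file.path(tempdir(), paste0("alpspvs_demo_", seed))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  planted <- list(
    A = c(1.5e-3, 1.5e-3, 0.5e-3, 0.5e-3),
    B = c(1.0e-3, 1.0e-3, 1.0e-3, 1.0e-3),
    C = c(1.2e-3, 0.8e-3, 0.5e-3, 0.5e-3)
  )
  tis <- generate_tissue_phantom(seed = seed)
  subjects <- lapply(names(planted), function(nm) {
    p <- planted[[nm]]
    ph <- generate_alps_phantom(p[1], p[2], p[3], p[4], seed = seed)
    list(id = nm, visit = 0, acq = ph$acq, tissue = tis$maps)
  })
  markers <- run_imaging(subjects,
                         out_csv = file.path(out_dir, "markers.csv"))
  spec <- cohort_spec(n = if (fast) 60 else 120, seed = seed)
  coh <- generate_cohort(spec)
  analysis <- run_analysis(coh$table, seed = seed)
  report <- file.path(out_dir, "report.md")
  render_report(markers, analysis, planted, report)
  invisible(list(markers = markers, analysis = analysis, report = report))
}

md_table <- function(df, digits = 4) {
  df <- as.data.frame(df)
  num <- vapply(df, is.numeric, logical(1))
  df[num] <- lapply(df[num], function(x) signif(x, digits))
  header <- paste("|", paste(names(df), collapse = " | "), "|")
  sep <- paste("|", paste(rep("---", ncol(df)), collapse = " | "), "|")
  body <- apply(df, 1, function(r) paste("|", paste(r, collapse = " | "), "|"))
  paste(c(header, sep, body), collapse = "\n")
}

render_report <- function(markers, analysis, planted, path) {
  expected <- vapply(planted, function(p) (p[1] + p[2]) / (p[3] + p[4]),
                     numeric(1))
  lines <- c(
    "# Synthetic PVS-marker pipeline report", "",
    "## Imaging stage: phantom ALPS indices",
    "",
    sprintf("Planted expected indices: %s.",
            paste(sprintf("%s = %.3f", names(expected), expected),
                  collapse = ", ")),
    "",
    md_table(markers[, c("subject_id", "alps_left", "alps_right", "alps_mean",
                         "md_median", "psmd")]),
    "", "## Baseline associations", "",
    md_table(analysis$baseline[, c("predictor", "outcome", "estimate",
                                   "conf.low", "conf.high", "p.value", "p.fdr")]),
    "", "## Longitudinal marker change", "",
    md_table(analysis$progression[, c("marker", "estimate", "conf.low",
                                      "conf.high", "p.value", "p.fdr")]),
    "", "## Baseline markers and cognitive change", "",
    md_table(analysis$cognition[, c("predictor", "outcome", "estimate",
                                    "conf.low", "conf.high", "p.value", "p.fdr")])
  )
  if (is.data.frame(analysis$dementia)) {
    lines <- c(lines, "", "## Incident dementia (Cox, nested covariate sets)", "",
               md_table(analysis$dementia[, c("predictor", "covariate_set",
                                              "estimate", "conf.low",
                                              "conf.high", "p.value", "p.fdr")]),
               "",
               sprintf("Optimal ALPS cutpoint %.3f (direction %s, Youden %.3f); log-rank p = %.3g.",
                       analysis$cutpoint$cutpoint, analysis$cutpoint$direction,
                       analysis$cutpoint$youden, analysis$survival$p))
  } else {
    lines <- c(lines, "", "## Incident dementia", "",
               "Skipped: no dementia events in the cohort.")
  }
  lines <- c(lines, "", "## Variable importance (random forest)", "",
             md_table(analysis$importance))
  writeLines(lines, path)
  invisible(path)
}
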