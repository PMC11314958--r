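# End-to-end orchestration: metrics, group comparisons, deviation tests,
# pathology and staging correlations, report writing.

#' Analysis configuration
#'
#' @param thresholdProportion fraction of connections kept (default 0.20).
#' @param thresholdBasis "possible" or "nonzero" (see
#'   [thresholdProportional()]).
#' @param lesionMode "delete" or "zero" (see [lesionNode()]).
#' @param fdrFamilies "per-metric" (default: the 8 regional tests of each of
#'   EC, CC and dGE form their own family) or "joint" (one family of 24).
#' @param ecNorm eigenvector centrality normalization, "unit" or "max".
#' @param outlierMad multiplier k of the median +/- k * MAD outlier flag
#'   (default 3).
#' @param alpha significance threshold applied to adjusted p-values.
#' @return a validated list of class "AnalysisConfig"
#' @export
analysisConfig <- function(thresholdProportion = 0.20,
                           thresholdBasis = c("possible", "nonzero"),
                           lesionMode = c("delete", "zero"),
                           fdrFamilies = c("per-metric", "joint"),
                           ecNorm = c("unit", "max"),
                           outlierMad = 3, alpha = 0.05) {
  if (thresholdProportion <= 0 || thresholdProportion > 1)
    stop("thresholdProportion must lie in (0, 1]")
  cfg <- list(thresholdProportion = thresholdProportion,
              thresholdBasis = match.arg(thresholdBasis),
              lesionMode = match.arg(lesionMode),
              fdrFamilies = match.arg(fdrFamilies),
              ecNorm = match.arg(ecNorm),
              outlierMad = outlierMad, alpha = alpha)
  class(cfg) <- "AnalysisConfig"
  cfg
}

#' Per-subject network metrics table
#'
#' For every subject: threshold, binarize, then global efficiency, mean
#' clustering, and per-ROI eigenvector centrality, clustering coefficient
#' and dGE (independent single-node lesions). Network metrics are computed
#' from the connectomes alone; group labels and pathology are never read
#' here.
#'
#' @param connectomes named list of [WeightedConnectome-class] (names are
#'   subject ids)
#' @param roiTable ROI table (default [defaultRoiTable()])
#' @param config an [analysisConfig()]
#' @return data.frame with columns subject_id, ge, mean_cc, ec_<roi>,
#'   cc_<roi>, dge_<roi> for the 8 short ROI keys
#' @export
runMetrics <- function(connectomes, roiTable = defaultRoiTable(),
                       config = analysisConfig()) {
  stopifnot(inherits(config, "AnalysisConfig"))
  if (is.null(names(connectomes)) || anyDuplicated(names(connectomes)))
    stop("connectomes must be a uniquely named list")
  keys <- names(.roiKeys)[match(roiTable$roi_name, .roiKeys)]
  keys[is.na(keys)] <- make.names(roiTable$roi_name[is.na(keys)])
  rows <- lapply(names(connectomes), function(id) {
    wc <- connectomes[[id]]
    res <- tryCatch({
      g <- binarize(thresholdProportional(wc, config$thresholdProportion,
                                          config$thresholdBasis))
      rois <- resolveRois(g@labels, roiTable)
      idx <- rois@nodeIndices
      ec <- .ec(g@adjacency, config$ecNorm)[idx]
      cc <- .cc(g@adjacency)[idx]
      dge <- resilienceProfile(g, rois, config$lesionMode)
      c(ge = .ge(g@adjacency), mean_cc = mean(.cc(g@adjacency)),
        structure(ec, names = paste0("ec_", keys)),
        structure(cc, names = paste0("cc_", keys)),
        structure(unname(dge), names = paste0("dge_", keys)))
    }, error = function(e)
      stop("metrics failed for subject ", id, ": ", conditionMessage(e),
           call. = FALSE))
    res
  })
  out <- as.data.frame(do.call(rbind, rows))
  cbind(subject_id = names(connectomes), out, stringsAsFactors = FALSE)
}

#' Long-format view of a metrics table
#'
#' @param metrics the [runMetrics()] output
#' @return data.frame with columns subject_id, metric, region, value
#' @export
metricsLong <- function(metrics) {
  cols <- setdiff(names(metrics), "subject_id")
  parts <- lapply(cols, function(cn) {
    sp <- regmatches(cn, regexpr("_", cn), invert = TRUE)[[1]]
    region <- if (cn %in% c("ge", "mean_cc")) "global" else sp[2]
    metric <- if (cn %in% c("ge", "mean_cc")) cn else sp[1]
    data.frame(subject_id = metrics$subject_id, metric = metric,
               region = region, value = metrics[[cn]],
               stringsAsFactors = FALSE)
  })
  do.call(rbind, parts)
}

.joinCheck <- function(metrics, subjects) {
  orphan <- setdiff(metrics$subject_id, subjects$subject_id)
  if (length(orphan))
    stop("subject(s) in metrics but not in subjects table: ",
         paste(orphan, collapse = ", "))
  subjects[match(metrics$subject_id, subjects$subject_id), , drop = FALSE]
}

.covariates <- function(subjects)
  data.frame(age = subjects$age_at_death,
             sex = as.numeric(subjects$sex == "M"),
             pmd = subjects$postmortem_delay)

# median +/- k*MAD outlier flag, computed within group so a group shift is
# not itself flagged
.outlierFlag <- function(values, group, k) {
  flag <- logical(length(values))
  for (gr in unique(group)) {
    i <- which(group == gr)
    med <- stats::median(values[i])
    mad <- stats::mad(values[i])
    if (mad > 0) flag[i] <- abs(values[i] - med) > k * mad
  }
  flag
}

.oneGroupTest <- function(values, subjects, metric, region, excludeOutliers,
                          config) {
  grp <- subjects$group
  keep <- rep(TRUE, length(values))
  if (excludeOutliers)
    keep <- !.outlierFlag(values, grp, config$outlierMad)
  res <- tryCatch(
    groupDifferenceTest(values[keep], grp[keep],
                        .covariates(subjects)[keep, , drop = FALSE]),
    error = function(e) e)
  if (inherits(res, "error"))
    return(data.frame(metric = metric, region = region, estimate = NA_real_,
                      d = NA_real_, p = NA_real_, p_fdr = NA_real_,
                      n_control = NA_integer_, n_pd = NA_integer_,
                      outliers_excluded = excludeOutliers,
                      n_excluded = sum(!keep),
                      status = conditionMessage(res),
                      stringsAsFactors = FALSE))
  data.frame(metric = metric, region = region, estimate = res$estimate,
             d = res$d, p = res$p, p_fdr = NA_real_,
             n_control = res$nControl, n_pd = res$nCase,
             outliers_excluded = excludeOutliers, n_excluded = sum(!keep),
             status = "ok", stringsAsFactors = FALSE)
}

#' Case-control comparisons of all network measures
#'
#' Rank-based group tests (case indicator + age, sex, postmortem delay
#' covariates) for the 8 regional eigenvector centralities, 8 regional
#' clustering coefficients and 8 regional dGE values, plus global
#' efficiency and mean clustering. FDR correction is applied within each
#' regional metric family of 8 (or jointly over 24 with
#' \code{fdrFamilies = "joint"}); the two global tests form their own
#' family. Every family is run twice: with all subjects and with
#' median +/- k*MAD outliers excluded (subjects are never silently
#' dropped; the flagged count is reported).
#'
#' @param metrics the [runMetrics()] output
#' @param subjects the subject metadata table
#' @param config an [analysisConfig()]
#' @return data.frame with columns metric, region, estimate, d, p, p_fdr,
#'   n_control, n_pd, outliers_excluded, n_excluded, status
#' @export
runGroupComparisons <- function(metrics, subjects,
                                config = analysisConfig()) {
  subjects <- .joinCheck(metrics, subjects)
  regional <- c("ec", "cc", "dge")
  keys <- sub("^ec_", "", grep("^ec_", names(metrics), value = TRUE))
  out <- list()
  for (excl in c(FALSE, TRUE)) {
    fam <- lapply(regional, function(m) {
      rows <- do.call(rbind, lapply(keys, function(k)
        .oneGroupTest(metrics[[paste0(m, "_", k)]], subjects, m, k, excl,
                      config)))
      rows
    })
    if (config$fdrFamilies == "per-metric") {
      fam <- lapply(fam, function(rows) {
        ok <- rows$status == "ok"
        rows$p_fdr[ok] <- bhFdr(rows$p[ok])
        rows
      })
      regRows <- do.call(rbind, fam)
    } else {
      regRows <- do.call(rbind, fam)
      ok <- regRows$status == "ok"
      regRows$p_fdr[ok] <- bhFdr(regRows$p[ok])
    }
    glob <- rbind(
      .oneGroupTest(metrics$ge, subjects, "ge", "global", excl, config),
      .oneGroupTest(metrics$mean_cc, subjects, "mean_cc", "global", excl,
                    config))
    ok <- glob$status == "ok"
    glob$p_fdr[ok] <- bhFdr(glob$p[ok])
    out[[length(out) + 1]] <- rbind(regRows, glob)
  }
  do.call(rbind, out)
}

#' Deviation-from-zero tests of control dGE values
#'
#' One-sample signed-rank test of the control group's dGE against zero for
#' every ROI, FDR-corrected across the 8 regions. Identifies the regions
#' whose failure measurably degrades the intact control network.
#'
#' @param metrics the [runMetrics()] output
#' @param subjects the subject metadata table
#' @param config an [analysisConfig()]
#' @return data.frame with columns region, statistic, n, p, p_fdr, status
#' @export
runDeviationTests <- function(metrics, subjects,
                              config = analysisConfig()) {
  subjects <- .joinCheck(metrics, subjects)
  ctrl <- subjects$group == "control"
  if (sum(ctrl) < 5) stop("need at least 5 control subjects")
  keys <- sub("^dge_", "", grep("^dge_", names(metrics), value = TRUE))
  rows <- lapply(keys, function(k) {
    res <- tryCatch(oneSampleSignedRank(metrics[[paste0("dge_", k)]][ctrl]),
                    error = function(e) e)
    if (inherits(res, "error"))
      data.frame(region = k, statistic = NA_real_, n = NA_integer_,
                 p = NA_real_, p_fdr = NA_real_,
                 status = conditionMessage(res), stringsAsFactors = FALSE)
    else
      data.frame(region = k, statistic = res$statistic, n = res$n,
                 p = res$p, p_fdr = NA_real_, status = "ok",
                 stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  ok <- out$status == "ok"
  out$p_fdr[ok] <- bhFdr(out$p[ok])
  out
}

.markers <- c("lb_density", "abeta_load", "ptau_load", "nfl_load",
              "syn_density")

#' Correlations of network measures with regional pathology
#'
#' Partial Spearman correlations (age, sex, postmortem delay covariates) of
#' configured (network measure, pathology ROI) pairs with each of the 5
#' markers, run both within the case group and across the whole cohort,
#' FDR-corrected across the 5 markers per (measure, pathology ROI, scope)
#' family. The default pairs follow the analysis design: insula dGE against
#' markers in the insula, anterior cingulate and entorhinal cortex, and
#' parahippocampal EC against parahippocampal markers.
#'
#' @param metrics the [runMetrics()] output
#' @param pathology tidy pathology table (subject_id, roi, markers)
#' @param subjects the subject metadata table
#' @param config an [analysisConfig()]
#' @param pairs data.frame with columns measure (a metrics column) and
#'   pathology_roi (a roi value of the pathology table); NULL for the
#'   default pairs
#' @return data.frame with columns measure, pathology_roi, marker, scope,
#'   r_s, n, p, p_fdr, status
#' @export
runPathologyCorrelations <- function(metrics, pathology, subjects,
                                     config = analysisConfig(),
                                     pairs = NULL) {
  subjects <- .joinCheck(metrics, subjects)
  if (is.null(pairs))
    pairs <- data.frame(
      measure = c("dge_dai", "dge_dai", "dge_dai", "ec_phg"),
      pathology_roi = c("dorsal_anterior_insula",
                        "anterior_cingulate_gyrus", "entorhinal_cortex",
                        "parahippocampal_gyrus"),
      stringsAsFactors = FALSE)
  orphan <- setdiff(pathology$subject_id, subjects$subject_id)
  if (length(orphan))
    stop("subject(s) in pathology but not in subjects table: ",
         paste(orphan, collapse = ", "))
  out <- list()
  for (i in seq_len(nrow(pairs))) {
    meas <- pairs$measure[i]
    proi <- pairs$pathology_roi[i]
    if (!meas %in% names(metrics)) stop("unknown measure column: ", meas)
    sub <- pathology[pathology$roi == proi, , drop = FALSE]
    if (nrow(sub) == 0) stop("pathology ROI absent from table: ", proi)
    sub <- sub[match(metrics$subject_id, sub$subject_id), , drop = FALSE]
    for (scope in c("PD", "whole")) {
      keep <- if (scope == "PD") subjects$group == "PD"
              else rep(TRUE, nrow(subjects))
      fam <- lapply(.markers, function(mk) {
        mv <- sub[[mk]][keep]
        if (all(is.na(mv)))
          return(data.frame(measure = meas, pathology_roi = proi,
                            marker = mk, scope = scope, r_s = NA_real_,
                            n = NA_integer_, p = NA_real_, p_fdr = NA_real_,
                            status = "all marker values missing",
                            stringsAsFactors = FALSE))
        res <- tryCatch(
          partialSpearman(metrics[[meas]][keep], mv,
                          .covariates(subjects)[keep, , drop = FALSE]),
          error = function(e) e)
        if (inherits(res, "error"))
          data.frame(measure = meas, pathology_roi = proi, marker = mk,
                     scope = scope, r_s = NA_real_, n = NA_integer_,
                     p = NA_real_, p_fdr = NA_real_,
                     status = conditionMessage(res), stringsAsFactors = FALSE)
        else
          data.frame(measure = meas, pathology_roi = proi, marker = mk,
                     scope = scope, r_s = res$estimate, n = res$n,
                     p = res$p, p_fdr = NA_real_, status = "ok",
                     stringsAsFactors = FALSE)
      })
      fam <- do.call(rbind, fam)
      ok <- fam$status == "ok"
      fam$p_fdr[ok] <- bhFdr(fam$p[ok])
      out[[length(out) + 1]] <- fam
    }
  }
  do.call(rbind, out)
}

#' Correlations of insula dGE with staging, demographics and clinical data
#'
#' Partial Spearman correlations of insula dGE with the three global
#' staging systems (Braak alpha-synuclein, Braak NFT, Thal) across the
#' whole cohort with age, sex and postmortem-delay covariates,
#' FDR-corrected across the 3 systems; plus correlations with demographics
#' (sex, age at death across the whole cohort; sex, age, disease duration
#' and CDR within cases) with postmortem delay as the only covariate. A
#' constant staging vector fails that test only; the others proceed.
#'
#' @param metrics the [runMetrics()] output
#' @param subjects the subject metadata table
#' @param config an [analysisConfig()]
#' @param measure metrics column to correlate (default "dge_dai")
#' @return data.frame with columns variable, scope, family, r_s, n, p,
#'   p_fdr, status
#' @export
runStagingCorrelations <- function(metrics, subjects,
                                   config = analysisConfig(),
                                   measure = "dge_dai") {
  subjects <- .joinCheck(metrics, subjects)
  if (!measure %in% names(metrics)) stop("unknown measure column: ", measure)
  y <- metrics[[measure]]
  onerow <- function(variable, scope, family, x, keep, covars) {
    res <- tryCatch(partialSpearman(y[keep], x[keep],
                                    covars[keep, , drop = FALSE]),
                    error = function(e) e)
    if (inherits(res, "error"))
      data.frame(variable = variable, scope = scope, family = family,
                 r_s = NA_real_, n = NA_integer_, p = NA_real_,
                 p_fdr = NA_real_, status = conditionMessage(res),
                 stringsAsFactors = FALSE)
    else
      data.frame(variable = variable, scope = scope, family = family,
                 r_s = res$estimate, n = res$n, p = res$p,
                 p_fdr = NA_real_, status = "ok", stringsAsFactors = FALSE)
  }
  all <- rep(TRUE, nrow(subjects))
  pd <- subjects$group == "PD"
  covFull <- .covariates(subjects)
  covPmd <- covFull[, "pmd", drop = FALSE]
  staging <- do.call(rbind, list(
    onerow("braak_asyn", "whole", "staging", subjects$braak_asyn, all,
           covFull),
    onerow("braak_nft", "whole", "staging", subjects$braak_nft, all,
           covFull),
    onerow("thal", "whole", "staging", subjects$thal, all, covFull)))
  ok <- staging$status == "ok"
  staging$p_fdr[ok] <- bhFdr(staging$p[ok])
  demo <- do.call(rbind, list(
    onerow("sex", "whole", "demographics",
           as.numeric(subjects$sex == "M"), all, covPmd),
    onerow("age_at_death", "whole", "demographics", subjects$age_at_death,
           all, covPmd),
    onerow("sex", "PD", "demographics", as.numeric(subjects$sex == "M"),
           pd, covPmd),
    onerow("age_at_death", "PD", "demographics", subjects$age_at_death, pd,
           covPmd),
    onerow("disease_duration", "PD", "demographics",
           subjects$disease_duration, pd, covPmd),
    onerow("cdr", "PD", "demographics", subjects$cdr, pd, covPmd)))
  ok <- demo$status == "ok"
  demo$p_fdr[ok] <- bhFdr(demo$p[ok])
  rbind(staging, demo)
}

#' Demographics comparison table
#'
#' Mann-Whitney tests for age at death and postmortem delay, Fisher exact
#' test for sex.
#'
#' @param subjects the subject metadata table
#' @return data.frame with columns variable, test, p
#' @export
demographicsTable <- function(subjects) {
  ctrl <- subjects$group == "control"
  sexTab <- table(factor(subjects$group, c("control", "PD")),
                  factor(subjects$sex, c("F", "M")))
  data.frame(
    variable = c("age_at_death", "postmortem_delay", "sex"),
    test = c("Mann-Whitney", "Mann-Whitney", "Fisher exact"),
    p = c(mannWhitney(subjects$age_at_death[ctrl],
                      subjects$age_at_death[!ctrl])$p,
          mannWhitney(subjects$postmortem_delay[ctrl],
                      subjects$postmortem_delay[!ctrl])$p,
          fisherExact(unclass(sexTab))$p),
    stringsAsFactors = FALSE)
}

#' Run the complete analysis on an in-memory cohort
#'
#' @param cohort list with subjects, pathology, connectomes (e.g. from
#'   [simulateCohort()] or [readCohort()])
#' @param config an [analysisConfig()]
#' @return list with metrics, groupTests, deviationTests,
#'   pathologyCorrelations, stagingCorrelations, demographics, config
#' @export
runPipeline <- function(cohort, config = analysisConfig()) {
  metrics <- runMetrics(cohort$connectomes, config = config)
  list(metrics = metrics,
       groupTests = runGroupComparisons(metrics, cohort$subjects, config),
       deviationTests = runDeviationTests(metrics, cohort$subjects, config),
       pathologyCorrelations = runPathologyCorrelations(
         metrics, cohort$pathology, cohort$subjects, config),
       stagingCorrelations = runStagingCorrelations(metrics,
                                                    cohort$subjects, config),
       demographics = demographicsTable(cohort$subjects),
       config = unclass(config))
}

#' Write machine- and human-readable reports
#'
#' Writes metrics.csv, group_tests.csv, deviation_tests.csv,
#' correlations.csv, results.json and report.md to a directory. The
#' Markdown report is rendered from the results.json content alone, so
#' regenerating it from that file yields identical text.
#'
#' @param results the [runPipeline()] output
#' @param outDir output directory (created if needed)
#' @return invisibly, the output directory
#' @export
writeReport <- function(results, outDir) {
  if (!dir.exists(outDir) &&
      !dir.create(outDir, recursive = TRUE, showWarnings = FALSE))
    stop("cannot create output directory: ", outDir)
  utils::write.csv(results$metrics, file.path(outDir, "metrics.csv"),
                   row.names = FALSE)
  utils::write.csv(metricsLong(results$metrics),
                   file.path(outDir, "metrics_long.csv"), row.names = FALSE)
  utils::write.csv(results$groupTests, file.path(outDir, "group_tests.csv"),
                   row.names = FALSE)
  utils::write.csv(results$deviationTests,
                   file.path(outDir, "deviation_tests.csv"),
                   row.names = FALSE)
  utils::write.csv(rbind(
    cbind(results$pathologyCorrelations[, c("marker", "scope", "r_s", "n",
                                            "p", "p_fdr", "status")],
          what = paste(results$pathologyCorrelations$measure, "vs",
                       results$pathologyCorrelations$pathology_roi)),
    cbind(results$stagingCorrelations[, c("scope", "r_s", "n", "p", "p_fdr",
                                          "status")],
          marker = results$stagingCorrelations$variable,
          what = results$stagingCorrelations$family)[,
      c("marker", "scope", "r_s", "n", "p", "p_fdr", "status", "what")]),
    file.path(outDir, "correlations.csv"), row.names = FALSE)
  jsonlite::write_json(results, file.path(outDir, "results.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       na = "null")
  writeLines(renderReport(file.path(outDir, "results.json")),
             file.path(outDir, "report.md"))
  invisible(outDir)
}

#' Render the Markdown report from a results.json file
#'
#' Pure function of the JSON content: no hidden state enters the report.
#'
#' @param resultsJson path to a results.json written by [writeReport()]
#' @return character vector of Markdown lines
#' @export
renderReport <- function(resultsJson) {
  res <- jsonlite::read_json(resultsJson, simplifyVector = TRUE)
  fmt <- function(df) {
    df <- as.data.frame(df)
    num <- vapply(df, is.numeric, logical(1))
    df[num] <- lapply(df[num], function(x) signif(x, 4))
    header <- paste("|", paste(names(df), collapse = " | "), "|")
    sep <- paste("|", paste(rep("---", ncol(df)), collapse = " | "), "|")
    body <- apply(df, 1, function(r)
      paste("|", paste(r, collapse = " | "), "|"))
    c(header, sep, body, "")
  }
  unname(c("# Structural network topology and resilience report", "",
    "## Configuration", "",
    paste0("    ", jsonlite::toJSON(res$config, auto_unbox = TRUE)), "",
    "## Demographics", "", fmt(res$demographics),
    "## Group comparisons", "", fmt(res$groupTests),
    "## Control dGE deviation from zero", "", fmt(res$deviationTests),
    "## Pathology correlations", "", fmt(res$pathologyCorrelations),
    "## Staging, demographic and clinical correlations", "",
    fmt(res$stagingCorrelations)))
}
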