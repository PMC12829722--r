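#' Run the end-to-end quantification and stratification pipeline
#'
#' Orchestrates the full workflow: quantify every frame of a cohort
#' (either an in-memory cohort from [makeCohort()] or a manifest of frame
#' and mask paths), aggregate per-frame elasticity indices per patient,
#' build the ROC curve against the malignant-potential groups, pick the
#' operating cutoff (Youden-optimal or fixed), and report diagnostic
#' metrics.  Frames rejected by QC (low colour coverage, achromatic mean,
#' degenerate lesion) are logged and excluded; processed plus excluded
#' counts always reconcile with the input.
#'
#' @param cohort either the list returned by [makeCohort()] or a
#'   data.frame manifest with columns `patient_id`, `frame_path`,
#'   `mask_path`, accompanied by a `groups` data.frame with columns
#'   `patient_id`, `group` (or `nih`).
#' @param groups optional patient-level data.frame (see above); ignored
#'   when `cohort` is a [makeCohort()] list.
#' @param cfg a [quantConfig()] list.
#' @param cutoff `"youden"` (default) or a fixed numeric cutoff.
#' @param aggregate per-patient aggregation of frame values, `"mean"`
#'   (default) or `"median"`.
#' @param ciMethod confidence-interval method for [diagnosticMetrics()].
#' @param reportPath optional path; when given, the report is written as
#'   JSON with sorted keys and 6-significant-digit numbers, so reruns are
#'   diff-stable.
#' @param seed recorded in the report for provenance.
#' @return A list (the report): `perFrame` (data.frame of frame-level
#'   results and QC), `perPatient` (data.frame with aggregated values and
#'   groups), `roc` ([RocCurve-class]), `auc`, `cutoff`, `cutoffPolicy`,
#'   `metrics` (diagnostic summary data.frame), `qc` (counts), `seed`.
#' @export
runPipeline <- function(cohort, groups = NULL, cfg = quantConfig(),
                        cutoff = "youden", aggregate = c("mean", "median"),
                        ciMethod = c("wald", "wilson"), reportPath = NULL,
                        seed = NULL) {
    aggregate <- match.arg(aggregate)
    ciMethod <- match.arg(ciMethod)
    if (is.list(cohort) && !is.null(cohort$manifest) &&
        !is.null(cohort$frames)) {
        manifest <- cohort$manifest
        getFrame <- function(k) cohort$frames[[manifest$frame[k]]]
        getMask <- function(k) cohort$masks[[manifest$frame[k]]]
        groups <- cohort$cohort
    } else {
        manifest <- as.data.frame(cohort)
        stopifnot(all(c("patient_id", "frame_path", "mask_path") %in%
                      names(manifest)))
        getFrame <- function(k) loadFrame(manifest$frame_path[k])
        getMask <- function(k) readMaskPng(manifest$mask_path[k])
        if (is.null(groups)) stop("'groups' is required with a manifest")
    }
    if (!"group" %in% names(groups) && "nih" %in% names(groups))
        groups$group <- groupNih(groups$nih)
    nFrames <- nrow(manifest)
    rows <- vector("list", nFrames)
    for (k in seq_len(nFrames)) {
        res <- tryCatch(computeEusEAi(getFrame(k), getMask(k), cfg),
                        error = function(e) e)
        if (inherits(res, "error")) {
            message(sprintf("frame %d (%s) excluded: %s", k,
                            manifest$patient_id[k], conditionMessage(res)))
            rows[[k]] <- data.frame(
                patient_id = manifest$patient_id[k], frame = k,
                eus_e_ai = NA_real_, n_mask = NA_integer_,
                n_solid = NA_integer_, n_color = NA_integer_,
                qc = conditionMessage(res))
        } else {
            rows[[k]] <- data.frame(
                patient_id = manifest$patient_id[k], frame = k,
                eus_e_ai = elasticity(res), n_mask = res@nMask,
                n_solid = res@nSolid, n_color = res@nColor,
                qc = paste(qcFlags(res), collapse = ";"))
        }
    }
    perFrame <- do.call(rbind, rows)
    ok <- !is.na(perFrame$eus_e_ai)
    aggFun <- if (aggregate == "mean") mean else stats::median
    vals <- tapply(perFrame$eus_e_ai[ok], perFrame$patient_id[ok], aggFun)
    perPatient <- data.frame(patient_id = names(vals),
                             eus_e_ai = as.numeric(vals))
    perPatient <- merge(perPatient,
                        groups[, intersect(c("patient_id", "group", "nih",
                                             "e_star"), names(groups))],
                        by = "patient_id")
    usable <- !is.na(perPatient$group)
    roc <- rocCurve(perPatient$eus_e_ai[usable],
                    perPatient$group[usable])
    if (identical(cutoff, "youden")) {
        yj <- youdenCutoff(roc)
        cut <- yj$cutoff
        policy <- "youden"
    } else {
        cut <- as.numeric(cutoff)
        policy <- "fixed"
    }
    cm <- confusionCounts(perPatient$eus_e_ai[usable],
                          perPatient$group[usable], cut)
    report <- list(
        perFrame = perFrame, perPatient = perPatient, roc = roc,
        auc = aucValue(roc), cutoff = cut, cutoffPolicy = policy,
        metrics = diagnosticMetrics(cm, ciMethod), confusion = cm,
        qc = list(frames = nFrames, processed = sum(ok),
                  excluded = sum(!ok)),
        seed = seed)
    if (!is.null(reportPath))
        writeReportJson(report, reportPath)
    report
}

# Serialise the report deterministically: sorted keys, 6 significant
# digits, frame/patient tables as data frames.
writeReportJson <- function(report, path) {
    out <- list(
        auc = signif(report$auc, 6),
        confusion = as.list(report$confusion),
        cutoff = signif(report$cutoff, 6),
        cutoffPolicy = report$cutoffPolicy,
        metrics = report$metrics,
        perPatient = report$perPatient[
            order(report$perPatient$patient_id), ],
        qc = report$qc,
        seed = report$seed)
    num <- function(x) if (is.numeric(x)) signif(x, 6) else x
    out$metrics[] <- lapply(out$metrics, num)
    out$perPatient[] <- lapply(out$perPatient, num)
    jsonlite::write_json(out[order(names(out))], path, auto_unbox = TRUE,
                         digits = NA, pretty = TRUE, na = "null")
    invisible(path)
}

#' Load a run configuration from YAML
#'
#' Reads a pipeline configuration file with optional keys `sMin`, `vMin`,
#' `solidTau`, `minColorFraction`, `colormap` (`"canonical"` or a CSV
#' path), `cutoff` (`"youden"` or a number), `aggregate`, `ciMethod` and
#' `seed`, and returns the corresponding [quantConfig()] plus pipeline
#' arguments.
#'
#' @param path path to a YAML file.
#' @return A list with elements `cfg` (a `QuantConfig`), `cutoff`,
#'   `aggregate`, `ciMethod`, `seed`.
#' @export
readRunConfig <- function(path) {
    y <- yaml::read_yaml(path)
    cmap <- if (is.null(y$colormap) || identical(y$colormap, "canonical"))
        NULL else readColormapCsv(y$colormap)
    pick <- function(key, default) if (is.null(y[[key]])) default
        else y[[key]]
    cfg <- quantConfig(
        sMin = pick("sMin", 0.15), vMin = pick("vMin", 0.10),
        solidTau = pick("solidTau", 20),
        minColorFraction = pick("minColorFraction", 0.10),
        colormap = cmap)
    list(cfg = cfg, cutoff = pick("cutoff", "youden"),
         aggregate = pick("aggregate", "mean"),
         ciMethod = pick("ciMethod", "wald"), seed = pick("seed", NULL))
}
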