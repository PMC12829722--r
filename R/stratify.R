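#' Collapse NIH risk categories into malignant-potential groups
#'
#' The four NIH consensus categories are grouped into binary malignant
#' potential: very-low and low risk form the low-risk group, intermediate
#' and high risk the high-risk group.  Unknown or missing categories are
#' returned as `NA` (excluded downstream) with a message.
#'
#' @param nih character vector with values among `"very_low"`, `"low"`,
#'   `"intermediate"`, `"high"`, `"unknown"`/`NA`.
#' @return Character vector of `"low_risk"` / `"high_risk"` (with `NA` for
#'   ungroupable entries).
#' @examples
#' groupNih(c("very_low", "low", "intermediate", "high"))
#' @export
groupNih <- function(nih) {
    out <- rep(NA_character_, length(nih))
    out[nih %in% c("very_low", "low")] <- "low_risk"
    out[nih %in% c("intermediate", "high")] <- "high_risk"
    bad <- is.na(out)
    if (any(bad))
        message(sprintf(
            "%d record(s) without a usable NIH category excluded from grouping",
            sum(bad)))
    out
}

#' Classify patients by an elasticity cutoff
#'
#' Lower elasticity means stiffer tissue and higher malignant potential:
#' a value strictly below the cutoff is called high risk, otherwise low
#' risk.  Missing values stay `NA`.
#'
#' @param values numeric elasticity indices in \[0, 1\].
#' @param cutoff the decision threshold.
#' @return Character vector of `"high_risk"` / `"low_risk"`.
#' @examples
#' classifyRisk(c(0.186, 0.268, 0.224), 0.224)
#' @export
classifyRisk <- function(values, cutoff) {
    ifelse(is.na(values), NA_character_,
           ifelse(values < cutoff, "high_risk", "low_risk"))
}

#' Confusion counts at a cutoff
#'
#' Cross-tabulates cutoff predictions against reference groups, with
#' high risk as the positive class.
#'
#' @param values numeric elasticity indices (no missing values).
#' @param labels reference groups, `"high_risk"` / `"low_risk"`.
#' @param cutoff decision threshold (strict `<` calls high risk).
#' @return Named integer vector `c(tp, fp, tn, fn)`.
#' @export
confusionCounts <- function(values, labels, cutoff) {
    if (length(values) != length(labels))
        stop("'values' and 'labels' must have equal length")
    if (anyNA(values) || anyNA(labels))
        stop("missing values are not allowed here; exclude them first")
    pred <- classifyRisk(values, cutoff)
    c(tp = sum(pred == "high_risk" & labels == "high_risk"),
      fp = sum(pred == "high_risk" & labels == "low_risk"),
      tn = sum(pred == "low_risk" & labels == "low_risk"),
      fn = sum(pred == "low_risk" & labels == "high_risk"))
}

# 95% CI for a proportion, on the percent scale, clamped to [0, 100].
propCi <- function(k, n, method = c("wald", "wilson")) {
    method <- match.arg(method)
    z <- stats::qnorm(0.975)
    p <- k / n
    if (method == "wald") {
        half <- z * sqrt(p * (1 - p) / n)
        lo <- p - half; hi <- p + half
    } else {
        den <- 1 + z^2 / n
        centre <- (p + z^2 / (2 * n)) / den
        half <- z * sqrt(p * (1 - p) / n + z^2 / (4 * n^2)) / den
        lo <- centre - half; hi <- centre + half
    }
    c(lower = max(0, lo) * 100, upper = min(1, hi) * 100)
}

#' Diagnostic performance metrics with confidence intervals
#'
#' Sensitivity, specificity, positive and negative predictive value and
#' accuracy from a confusion matrix, each with a 95% confidence interval
#' on the percent scale.  The default interval is Wald
#' (`p +/- 1.96 sqrt(p(1-p)/n)`) clamped to \[0, 100\]; Wilson is
#' available.  A metric whose denominator is zero is reported as `NA`
#' (undefined), not as 0.
#'
#' @param cm named counts `c(tp, fp, tn, fn)` from [confusionCounts()],
#'   or the four counts given separately.
#' @param ciMethod `"wald"` (default) or `"wilson"`.
#' @param tp,fp,tn,fn alternative to `cm`.
#' @return A data.frame with columns `metric`, `estimate`, `lower`,
#'   `upper` (percent).
#' @examples
#' diagnosticMetrics(c(tp = 3, fp = 5, tn = 22, fn = 1))
#' @export
diagnosticMetrics <- function(cm = NULL, ciMethod = c("wald", "wilson"),
                              tp = NULL, fp = NULL, tn = NULL, fn = NULL) {
    ciMethod <- match.arg(ciMethod)
    if (!is.null(cm)) {
        tp <- cm[["tp"]]; fp <- cm[["fp"]]
        tn <- cm[["tn"]]; fn <- cm[["fn"]]
    }
    n <- tp + fp + tn + fn
    if (n < 1L) stop("empty confusion matrix")
    one <- function(metric, k, d) {
        if (d == 0L)
            return(data.frame(metric = metric, estimate = NA_real_,
                              lower = NA_real_, upper = NA_real_))
        ci <- propCi(k, d, ciMethod)
        data.frame(metric = metric, estimate = 100 * k / d,
                   lower = ci[["lower"]], upper = ci[["upper"]])
    }
    rbind(one("sensitivity", tp, tp + fn),
          one("specificity", tn, tn + fp),
          one("ppv", tp, tp + fp),
          one("npv", tn, tn + fn),
          one("accuracy", tp + tn, n))
}

#' ROC curve of a negatively oriented elasticity score
#'
#' Builds the full ROC curve for distinguishing high-risk from low-risk
#' malignant potential, with the convention that lower elasticity predicts
#' high risk (a case is positive when its value falls strictly below the
#' cutoff).  Candidate cutoffs are the midpoints between consecutive
#' distinct values plus infinite sentinels; the AUC is the trapezoidal
#' area over (1 - specificity, sensitivity).
#'
#' @param values numeric elasticity indices.
#' @param labels `"high_risk"` / `"low_risk"` reference groups.
#' @return A [RocCurve-class] object.
#' @export
rocCurve <- function(values, labels) {
    if (length(values) != length(labels))
        stop("'values' and 'labels' must have equal length")
    keep <- !is.na(values) & !is.na(labels)
    values <- values[keep]; labels <- labels[keep]
    pos <- labels == "high_risk"
    if (!any(pos) || all(pos))
        stop("both classes must be present to build an ROC curve")
    sv <- sort(unique(values))
    cutoffs <- c(-Inf, if (length(sv) > 1)
        (sv[-length(sv)] + sv[-1]) / 2, Inf)
    sens <- vapply(cutoffs, function(cc) mean(values[pos] < cc), 0)
    spec <- vapply(cutoffs, function(cc) mean(values[!pos] >= cc), 0)
    fpr <- 1 - spec
    auc <- sum(diff(fpr) * (sens[-1] + sens[-length(sens)]) / 2)
    new("RocCurve", cutoffs = cutoffs, sensitivity = sens,
        specificity = spec, auc = auc)
}

#' Youden-optimal cutoff of an ROC curve
#'
#' Maximises the Youden index `J = sensitivity + specificity - 1` over the
#' curve's candidate cutoffs.  Ties resolve first toward higher
#' sensitivity (favouring detection of high-risk disease), then toward the
#' lower cutoff.
#'
#' @param curve a [RocCurve-class] from [rocCurve()].
#' @return A list with `cutoff`, `J`, `sensitivity`, `specificity`.
#' @export
youdenCutoff <- function(curve) {
    stopifnot(is(curve, "RocCurve"))
    J <- curve@sensitivity + curve@specificity - 1
    best <- which(J >= max(J) - 1e-12)
    best <- best[order(-curve@sensitivity[best], curve@cutoffs[best])][1]
    list(cutoff = curve@cutoffs[best], J = J[best],
         sensitivity = curve@sensitivity[best],
         specificity = curve@specificity[best])
}

#' Spearman rank correlation
#'
#' Pearson correlation of average-tie ranks, via [stats::cor()].
#'
#' @param x,y numeric vectors of equal length (at least 3).
#' @return The correlation coefficient rho.
#' @examples
#' spearmanRho(c(1, 2, 2, 4), c(1, 2, 3, 4))
#' @export
spearmanRho <- function(x, y) {
    if (length(x) != length(y)) stop("'x' and 'y' lengths differ")
    if (length(x) < 3L) stop("need at least 3 observations")
    if (stats::sd(x) == 0 || stats::sd(y) == 0)
        stop("correlation undefined for constant input")
    stats::cor(x, y, method = "spearman")
}

# Flag (quasi-)complete separation in a fitted binomial glm.
glmSeparated <- function(fit) {
    p <- stats::fitted(fit)
    eps <- 1e-8
    all(p[fit$y == 1] > 1 - eps) && all(p[fit$y == 0] < eps)
}

#' Univariable and multivariable logistic odds ratios
#'
#' Fits maximum-likelihood logistic regressions of a binary outcome on
#' each covariate alone (univariable) and on all covariates jointly
#' (multivariable), reporting odds ratios with Wald 95% confidence
#' intervals and p-values.  Complete separation is detected and reported
#' as an error naming the covariate rather than returning a divergent
#' estimate.
#'
#' @param data a data.frame holding outcome and covariates.
#' @param outcome name of the binary outcome column (logical, 0/1, or a
#'   two-level factor; for `"high_risk"`/`"low_risk"` labels, high risk is
#'   the event).
#' @param covariates character vector of covariate column names.
#' @return A data.frame with columns `term`, `analysis` (`"univariable"`/
#'   `"multivariable"`), `or`, `lower`, `upper`, `p`.
#' @export
logisticOrTable <- function(data, outcome, covariates) {
    y <- data[[outcome]]
    if (is.character(y) || is.factor(y)) {
        y <- as.character(y)
        lev <- sort(unique(y))
        if (setequal(lev, c("high_risk", "low_risk")))
            y <- as.integer(y == "high_risk")
        else {
            if (length(lev) != 2L) stop("outcome must be binary")
            y <- as.integer(y == lev[2])
        }
    }
    y <- as.numeric(y)
    if (length(unique(y)) < 2L)
        stop("separation: outcome has a single level")
    df <- data[, covariates, drop = FALSE]
    df$.y <- y
    fitOne <- function(vars, analysis) {
        fml <- stats::as.formula(paste(".y ~", paste(vars, collapse = "+")))
        fit <- suppressWarnings(stats::glm(fml, data = df,
                                           family = stats::binomial()))
        if (glmSeparated(fit) || any(abs(stats::coef(fit)[-1]) > 15,
                                     na.rm = TRUE))
            stop(sprintf("complete separation involving covariate '%s'",
                         paste(vars, collapse = ", ")))
        s <- summary(fit)$coefficients
        terms <- rownames(s)[-1]
        data.frame(term = terms, analysis = analysis,
                   or = exp(s[-1, 1]),
                   lower = exp(s[-1, 1] - stats::qnorm(0.975) * s[-1, 2]),
                   upper = exp(s[-1, 1] + stats::qnorm(0.975) * s[-1, 2]),
                   p = s[-1, 4], row.names = NULL)
    }
    uni <- do.call(rbind, lapply(covariates, fitOne,
                                 analysis = "univariable"))
    multi <- if (length(covariates) > 1L)
        fitOne(covariates, "multivariable") else NULL
    rbind(uni, multi)
}

# "n (pct%)" formatting used in baseline tables.
fmtCount <- function(k, n) sprintf("%d (%.1f)", k, 100 * k / n)

#' Baseline cohort summary table
#'
#' Summarises patient records overall and by malignant-potential group:
#' categorical variables as `n (%)` compared by chi-squared (or Fisher's
#' exact test when any expected cell count falls below 5), approximately
#' normal continuous variables as mean (SD) compared by t test, and
#' skewed continuous variables as median \[IQR\] compared by
#' Mann-Whitney.
#'
#' @param records data.frame of patient records; recognised columns are
#'   `age` (normal), `eus_e_ai` and `mitotic_count` (skewed), and any of
#'   `sex`, `size_class`, `location`, `nih` (categorical), plus `group`.
#' @param by grouping column for comparisons (default `"group"`); `NULL`
#'   for overall summaries only.
#' @return A data.frame with columns `variable`, `level`, `overall`, one
#'   column per group, and `p`.
#' @export
cohortSummary <- function(records, by = "group") {
    stopifnot(nrow(records) >= 1L)
    grp <- if (!is.null(by) && by %in% names(records) &&
               length(unique(stats::na.omit(records[[by]]))) == 2L)
        records[[by]] else NULL
    lv <- if (!is.null(grp)) sort(unique(stats::na.omit(grp)))
    n <- nrow(records)
    out <- list()
    addRow <- function(variable, level, overall, byVals, p) {
        row <- data.frame(variable = variable, level = level,
                          overall = overall, stringsAsFactors = FALSE)
        if (!is.null(grp)) {
            row[[lv[1]]] <- byVals[1]; row[[lv[2]]] <- byVals[2]
        }
        row$p <- p
        out[[length(out) + 1L]] <<- row
    }
    contVars <- list(age = "normal", eus_e_ai = "skewed",
                     mitotic_count = "skewed")
    for (v in intersect(names(contVars), names(records))) {
        x <- records[[v]]
        if (contVars[[v]] == "normal") {
            fmt <- function(z) sprintf("%.1f (%.2f)", mean(z, na.rm = TRUE),
                                       stats::sd(z, na.rm = TRUE))
            p <- if (!is.null(grp) && n > 3)
                tryCatch(stats::t.test(x ~ grp)$p.value,
                         error = function(e) NA_real_) else NA_real_
        } else {
            fmt <- function(z) {
                q <- stats::quantile(z, c(0.25, 0.5, 0.75), na.rm = TRUE)
                sprintf("%.3f [%.3f-%.3f]", q[2], q[1], q[3])
            }
            p <- if (!is.null(grp))
                tryCatch(stats::wilcox.test(x ~ grp)$p.value,
                         error = function(e) NA_real_) else NA_real_
        }
        byVals <- if (!is.null(grp))
            vapply(lv, function(g) fmt(x[grp == g]), "") else NULL
        addRow(v, "", fmt(x), byVals, p)
    }
    catVars <- intersect(c("sex", "size_class", "location", "nih"),
                         names(records))
    for (v in catVars) {
        x <- records[[v]]
        levs <- sort(unique(stats::na.omit(x)))
        p <- NA_real_
        if (!is.null(grp) && length(levs) >= 2L) {
            tab <- table(x, grp)
            exp <- outer(rowSums(tab), colSums(tab)) / sum(tab)
            p <- tryCatch(
                if (any(exp < 5)) stats::fisher.test(tab)$p.value
                else stats::chisq.test(tab)$p.value,
                error = function(e) NA_real_)
        }
        for (i in seq_along(levs)) {
            l <- levs[i]
            byVals <- if (!is.null(grp))
                vapply(lv, function(g)
                    fmtCount(sum(x == l & grp == g, na.rm = TRUE),
                             sum(grp == g, na.rm = TRUE)), "") else NULL
            addRow(v, l, fmtCount(sum(x == l, na.rm = TRUE), n), byVals,
                   if (i == 1L) p else NA_real_)
        }
    }
    do.call(rbind, out)
}
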