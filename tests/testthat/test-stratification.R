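test_that("NIH categories collapse into the binary malignant-potential groups", {
    expect_identical(groupNih("very_low"), "low_risk")
    expect_identical(groupNih("low"), "low_risk")
    expect_identical(groupNih("intermediate"), "high_risk")
    expect_identical(groupNih("high"), "high_risk")
    nih <- rep(c("very_low", "low", "intermediate", "high"),
               c(15, 31, 29, 9))
    g <- groupNih(nih)
    expect_identical(sum(g == "low_risk"), 46L)
    expect_identical(sum(g == "high_risk"), 38L)
    expect_message(g2 <- groupNih(c("low", "unknown")), "excluded")
    expect_true(is.na(g2[2]))
})

test_that("cutoff classification uses a strict inequality", {
    expect_identical(classifyRisk(0.186, 0.224), "high_risk")
    expect_identical(classifyRisk(0.268, 0.224), "low_risk")
    expect_identical(classifyRisk(0.224, 0.224), "low_risk")
    expect_true(is.na(classifyRisk(NA, 0.224)))
})

test_that("confusion counts conserve n and respect the orientation", {
    v <- c(0.1, 0.15, 0.3, 0.35)
    lab <- c("high_risk", "high_risk", "low_risk", "low_risk")
    cm <- confusionCounts(v, lab, 0.225)
    expect_identical(cm, c(tp = 2L, fp = 0L, tn = 2L, fn = 0L))
    # all low-risk labels, all values below the cutoff
    cm2 <- confusionCounts(v, rep("low_risk", 4), 1)
    expect_identical(cm2, c(tp = 0L, fp = 4L, tn = 0L, fn = 0L))
    set.seed(5)
    for (i in 1:20) {
        v <- runif(30)
        lab <- sample(c("high_risk", "low_risk"), 30, replace = TRUE)
        cm <- confusionCounts(v, lab, runif(1))
        expect_identical(sum(cm), 30L)
    }
})

test_that("diagnostic metrics reproduce small-sample worked arithmetic", {
    m <- diagnosticMetrics(c(tp = 3, fp = 5, tn = 22, fn = 1))
    acc <- m[m$metric == "accuracy", ]
    expect_equal(round(acc$estimate, 2), 80.65)
    sens <- m[m$metric == "sensitivity", ]
    expect_equal(sens$estimate, 75)
    expect_equal(round(sens$lower, 1), 32.6)
    expect_equal(sens$upper, 100)  # Wald upper clamped
    # undefined metrics are NA, not zero
    m2 <- diagnosticMetrics(c(tp = 0, fp = 2, tn = 3, fn = 0))
    expect_true(is.na(m2[m2$metric == "sensitivity", "estimate"]))
    # Wilson intervals stay inside [0, 100] without clamping
    m3 <- diagnosticMetrics(c(tp = 3, fp = 5, tn = 22, fn = 1),
                            ciMethod = "wilson")
    s3 <- m3[m3$metric == "sensitivity", ]
    expect_lt(s3$upper, 100)
    expect_gt(s3$lower, 0)
})

test_that("accuracy identity (sens*P + spec*N)/n holds exactly", {
    set.seed(17)
    for (i in 1:20) {
        v <- runif(40)
        lab <- sample(c("high_risk", "low_risk"), 40, replace = TRUE,
                      prob = c(0.4, 0.6))
        if (length(unique(lab)) < 2) next
        cm <- confusionCounts(v, lab, runif(1))
        m <- diagnosticMetrics(cm)
        P <- cm[["tp"]] + cm[["fn"]]; N <- cm[["tn"]] + cm[["fp"]]
        sens <- m[m$metric == "sensitivity", "estimate"]
        spec <- m[m$metric == "specificity", "estimate"]
        acc <- m[m$metric == "accuracy", "estimate"]
        if (P > 0 && N > 0)
            expect_equal(acc, (sens * P + spec * N) / (P + N))
    }
})

test_that("ROC curves behave at the extremes and under label flips", {
    v <- c(0.1, 0.15, 0.3, 0.35)
    lab <- c("high_risk", "high_risk", "low_risk", "low_risk")
    rc <- rocCurve(v, lab)
    expect_equal(aucValue(rc), 1)
    # uninformative score: AUC near 1/2 at large n
    set.seed(21)
    v2 <- runif(2000)
    lab2 <- sample(c("high_risk", "low_risk"), 2000, replace = TRUE)
    expect_lt(abs(aucValue(rocCurve(v2, lab2)) - 0.5), 0.05)
    # AUC(labels) + AUC(flipped labels) = 1
    for (i in 1:20) {
        v3 <- round(runif(30), 2)  # ties on purpose
        lab3 <- sample(c("high_risk", "low_risk"), 30, replace = TRUE)
        if (length(unique(lab3)) < 2) next
        flipped <- ifelse(lab3 == "high_risk", "low_risk", "high_risk")
        expect_equal(aucValue(rocCurve(v3, lab3)) +
                     aucValue(rocCurve(v3, flipped)), 1)
    }
    expect_error(rocCurve(v, rep("high_risk", 4)), "both classes")
})

test_that("trapezoidal AUC equals the tie-corrected rank statistic", {
    set.seed(31)
    for (i in 1:30) {
        n <- sample(10:60, 1)
        v <- round(runif(n), sample(1:3, 1))  # coarse rounding forces ties
        lab <- sample(c("high_risk", "low_risk"), n, replace = TRUE)
        if (length(unique(lab)) < 2) next
        expect_equal(aucValue(rocCurve(v, lab)), rankAuc(v, lab))
    }
})

test_that("Youden cutoff maximises J and places perfect splits at midpoints", {
    v <- c(0.1, 0.15, 0.3, 0.35)
    lab <- c("high_risk", "high_risk", "low_risk", "low_risk")
    yj <- youdenCutoff(rocCurve(v, lab))
    expect_equal(yj$cutoff, 0.225)
    expect_equal(yj$J, 1)
    set.seed(41)
    for (i in 1:30) {
        n <- sample(8:50, 1)
        v <- round(runif(n), 2)
        lab <- sample(c("high_risk", "low_risk"), n, replace = TRUE)
        if (length(unique(lab)) < 2) next
        yj <- youdenCutoff(rocCurve(v, lab))
        expect_equal(yj$J, bruteForceYouden(v, lab))
        # the returned cutoff actually achieves the returned J on the data
        pos <- lab == "high_risk"
        expect_equal(mean(v[pos] < yj$cutoff) +
                     mean(v[!pos] >= yj$cutoff) - 1, yj$J)
    }
})

test_that("negating values and swapping orientation leaves AUC and J invariant", {
    set.seed(51)
    for (i in 1:10) {
        v <- runif(30)
        lab <- sample(c("high_risk", "low_risk"), 30, replace = TRUE)
        if (length(unique(lab)) < 2) next
        flipped <- ifelse(lab == "high_risk", "low_risk", "high_risk")
        a1 <- rocCurve(v, lab); a2 <- rocCurve(-v, flipped)
        expect_equal(aucValue(a1), aucValue(a2))
        expect_equal(youdenCutoff(a1)$J, youdenCutoff(a2)$J)
    }
})

test_that("Spearman correlation handles ties by average ranks", {
    expect_equal(spearmanRho(1:10, 1:10), 1)
    expect_equal(spearmanRho(1:10, 10:1), -1)
    expect_equal(round(spearmanRho(c(1, 2, 2, 4), c(1, 2, 3, 4)), 4),
                 0.9487)
    expect_error(spearmanRho(rep(1, 5), 1:5), "constant")
})

test_that("logistic odds ratios match the closed-form 2x2 estimate", {
    df <- data.frame(
        x = rep(c(1, 1, 0, 0), c(10, 5, 2, 8)),
        y = rep(c(1, 0, 1, 0), c(10, 5, 2, 8)))
    tab <- logisticOrTable(df, "y", "x")
    expect_equal(tab$or[1], 8, tolerance = 1e-4)
    # covariate independent of a balanced outcome
    df2 <- data.frame(x = rep(c(1, 0), each = 20),
                      y = rep(c(1, 0, 1, 0), each = 10))
    tab2 <- logisticOrTable(df2, "y", "x")
    expect_equal(tab2$or[1], 1, tolerance = 1e-6)
    df3 <- data.frame(x = rnorm(20), y = rep(1, 20))
    expect_error(logisticOrTable(df3, "y", "x"), "separation")
    # perfectly separating covariate
    df4 <- data.frame(x = c(rep(0, 10), rep(1, 10)),
                      y = c(rep(0, 10), rep(1, 10)))
    expect_error(logisticOrTable(df4, "y", "x"), "separation")
})

test_that("cohort summaries print counts and percents as in baseline tables", {
    records <- data.frame(
        size_class = rep(c("gt2cm", "le2cm"), c(108, 81)),
        sex = rep(c("male", "female"), c(92, 97)),
        group = sample(rep(c("low_risk", "high_risk"), c(100, 89))))
    s <- cohortSummary(records)
    expect_identical(
        s[s$variable == "size_class" & s$level == "gt2cm", "overall"],
        "108 (57.1)")
    expect_identical(
        s[s$variable == "sex" & s$level == "male", "overall"],
        "92 (48.7)")
    # a single record summarises without tests
    s1 <- cohortSummary(data.frame(sex = "male", age = 60), by = NULL)
    expect_identical(s1[s1$variable == "sex", "overall"], "1 (100.0)")
    expect_true(all(is.na(s1$p)))
})
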