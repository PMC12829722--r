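# Shared fixture builders: everything is generated in code at test time.

# Small default phantom geometry keeps the suite fast; the quantification
# pipeline is size-independent.
smallPhantom <- function(eStar, ..., width = 240L, height = 160L) {
    makePhantom(eStar, width = width, height = height, ...)
}

# A raster filled with a single RGB colour.
flatRaster <- function(h, w, rgb) {
    r <- array(0, dim = c(h, w, 3L))
    r[, , 1] <- rgb[1]; r[, , 2] <- rgb[2]; r[, , 3] <- rgb[3]
    r
}

# Rectangular mask: rows/cols give the foreground block.
rectMask <- function(h, w, rows, cols, side = "left") {
    bits <- matrix(FALSE, h, w)
    bits[rows, cols] <- TRUE
    lesionMask(bits, side = side)
}

# Independent brute-force projection oracle: explicit loop over entries
# with the circular-hue metric, first minimum wins.
bruteForceProject <- function(hsv, cmap) {
    tab <- cmapHsv(cmap)
    best <- 1L; bestD <- Inf
    for (i in seq_len(nrow(tab))) {
        dh <- abs(tab[i, 1] - hsv[1])
        if (dh > 180) dh <- 360 - dh
        d <- (dh / 180)^2 + (tab[i, 2] - hsv[2])^2 + (tab[i, 3] - hsv[3])^2
        if (d < bestD) { bestD <- d; best <- i }
    }
    list(index = best - 1L, distance = unname(sqrt(bestD)))
}

# Independent Youden oracle: evaluate J at every achievable operating
# point (thresholds immediately above each sorted distinct value, plus
# the two extremes), straight from the data.
bruteForceYouden <- function(values, labels) {
    pos <- labels == "high_risk"
    cand <- c(-Inf, sort(unique(values)) + 1e-9, Inf)
    J <- vapply(cand, function(cc)
        mean(values[pos] < cc) + mean(values[!pos] >= cc) - 1, 0)
    max(J)
}

# Tie-corrected rank AUC (Mann-Whitney U / (n1 n0)) for the convention
# that lower values indicate the positive class.
rankAuc <- function(values, labels) {
    pos <- labels == "high_risk"
    r <- rank(values)
    n1 <- sum(pos); n0 <- sum(!pos)
    (sum(r[!pos]) - n0 * (n0 + 1) / 2) / (n0 * n1)
}
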