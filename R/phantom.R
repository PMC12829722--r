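#' Calibrate an elasticity distribution to a target median and IQR
#'
#' Fits a log-normal distribution truncated to \[0, 1\] whose median
#' equals the target and whose interquartile width (q3 - q1) matches the
#' target IQR, by solving the two quantile equations numerically.  Group
#' elasticity distributions reported only as median \[IQR\] can thereby be
#' emulated with a right-skew-capable two-parameter family.
#'
#' @param median target median, in (0, 1).
#' @param q1,q3 target quartiles, `0 < q1 < median < q3 < 1`.
#' @return An object of class `elasticityDist` (list with `meanlog`,
#'   `sdlog` and the targets) for [rElasticity()].
#' @examples
#' d <- calibrateDistribution(0.268, 0.243, 0.333)
#' quantile(rElasticity(1e4, d, seed = 1), c(0.25, 0.5, 0.75))
#' @export
calibrateDistribution <- function(median, q1, q3) {
    if (!(q1 < median && median < q3))
        stop("calibration error: need q1 < median < q3")
    if (q1 <= 0 || q3 >= 1)
        stop("calibration error: quantiles must lie strictly inside (0, 1)")
    qtl <- function(p, m, s) stats::qlnorm(p * stats::plnorm(1, m, s), m, s)
    resid <- function(par) {
        m <- par[1]; s <- exp(par[2])
        c(qtl(0.5, m, s) - median,
          (qtl(0.75, m, s) - qtl(0.25, m, s)) - (q3 - q1))
    }
    init <- c(log(median), log(log(q3 / q1) / 1.349))
    fit <- stats::optim(init, function(par) sum(resid(par)^2),
                        control = list(reltol = 1e-16, maxit = 10000))
    r <- resid(fit$par)
    if (any(abs(r) > 1e-6))
        stop("calibration error: quantile equations could not be solved")
    structure(list(meanlog = fit$par[1], sdlog = exp(fit$par[2]),
                   median = median, q1 = q1, q3 = q3),
              class = "elasticityDist")
}

#' Draw elasticity values from a calibrated distribution
#'
#' @param n number of draws.
#' @param dist an `elasticityDist` from [calibrateDistribution()].
#' @param seed optional RNG seed (the caller's RNG state is preserved).
#' @return Numeric vector of elasticity values in (0, 1).
#' @export
rElasticity <- function(n, dist, seed = NULL) {
    stopifnot(inherits(dist, "elasticityDist"))
    u <- withSeed(seed, stats::runif(n))
    stats::qlnorm(u * stats::plnorm(1, dist$meanlog, dist$sdlog),
                  dist$meanlog, dist$sdlog)
}

#' Group elasticity distributions of the reference cohort
#'
#' Convenience constructors for the calibrated low-risk (median 0.268,
#' IQR 0.243-0.333) and high-risk (median 0.186, IQR 0.176-0.199)
#' malignant-potential distributions used as the default cohort
#' conditions.
#'
#' @return An `elasticityDist`.
#' @export
lowRiskDist <- function() calibrateDistribution(0.268, 0.243, 0.333)

#' @rdname lowRiskDist
#' @export
highRiskDist <- function() calibrateDistribution(0.186, 0.176, 0.199)

# Ellipse membership matrix for a panel of size h x w.
ellipseBits <- function(h, w, center, semiAxes, rotation = 0) {
    x <- matrix(rep(seq_len(w), each = h), h) - center[1]
    y <- matrix(rep(seq_len(h), w), h) - center[2]
    ct <- cos(rotation); st <- sin(rotation)
    u <- (x * ct + y * st) / semiAxes[1]
    v <- (-x * st + y * ct) / semiAxes[2]
    u^2 + v^2 <= 1
}

#' Generate a synthetic dual-panel elastography phantom
#'
#' Emulates the geometry of a dual-panel EUS-E export: a grayscale B-mode
#' panel on the left with a hypoechoic (dark) elliptical lesion and an
#' optional near-black cystic core, a bright vertical marker band in the
#' middle, and a colour elastogram panel on the right.  Lesion pixels in
#' the elastogram carry the colormap hue corresponding to the ground-truth
#' elasticity `eStar` plus truncated Gaussian hue noise; background pixels
#' carry hues from `backgroundHueRange` (default the green/soft band, so
#' the background never mimics a stiff lesion).  The cystic core is
#' rendered dark and colourless in both panels.  Output is deterministic
#' for a given seed.
#'
#' @param eStar ground-truth elasticity in \[0, 1\].
#' @param width,height frame size in pixels (defaults 600 x 300).
#' @param markerWidth marker-band width (default 4); `width - markerWidth`
#'   should be even so the panels are congruent.
#' @param center,semiAxes,rotation lesion ellipse in left-panel
#'   coordinates; defaults centre the lesion with semi-axes a quarter of
#'   the panel size.
#' @param cysticFraction fraction of the lesion area covered by a
#'   concentric anechoic core, in \[0, 1) (default 0).
#' @param hueNoiseSd SD of the per-pixel hue noise in degrees (default 5);
#'   noise is truncated so hues stay within the 0-240 colour scale.
#' @param backgroundHueRange hue range of the background overlay.
#' @param seed RNG seed; the caller's RNG state is preserved.
#' @param nEntriesCmap colormap resolution used for painting (default 256).
#' @return A list with `frame` (raster array), `mask` (left-panel
#'   [LesionMask-class] of the full lesion including any cystic core) and
#'   `truth` (the generating parameters, including `splitX`).
#' @export
makePhantom <- function(eStar, width = 600L, height = 300L,
                        markerWidth = 4L, center = NULL, semiAxes = NULL,
                        rotation = 0, cysticFraction = 0, hueNoiseSd = 5,
                        backgroundHueRange = c(60, 150), seed = NULL,
                        nEntriesCmap = 256L) {
    if (eStar < 0 || eStar > 1) stop("'eStar' must lie in [0, 1]")
    if (cysticFraction < 0 || cysticFraction >= 1)
        stop("'cysticFraction' must lie in [0, 1)")
    leftW <- (width - markerWidth) %/% 2L
    splitX <- leftW + 1L
    if (is.null(center)) center <- c(leftW / 2, height / 2)
    if (is.null(semiAxes)) semiAxes <- c(leftW, height) * 0.25
    # lesion must sit fully inside the panel (bounding-box check)
    r <- max(semiAxes)
    if (center[1] - r < 1 || center[1] + r > leftW ||
        center[2] - r < 1 || center[2] + r > height)
        stop("lesion ellipse extends outside the left panel")
    withSeed(seed, {
        lesion <- ellipseBits(height, leftW, center, semiAxes, rotation)
        core <- if (cysticFraction > 0)
            ellipseBits(height, leftW, center,
                        semiAxes * sqrt(cysticFraction), rotation)
            else matrix(FALSE, height, leftW)
        core <- core & lesion
        # left panel: mid-gray background, hypoechoic lesion, near-black core
        g <- matrix(stats::rnorm(height * leftW, 150, 12), height)
        g[lesion] <- stats::rnorm(sum(lesion), 70, 8)
        g[core] <- stats::rnorm(sum(core), 6, 2)
        g <- pmin(pmax(round(g), 0), 255)
        left <- array(g, dim = c(height, leftW, 3L))
        # right panel: colour overlay
        nbg <- height * leftW
        hue <- matrix(stats::runif(nbg, backgroundHueRange[1],
                                   backgroundHueRange[2]), height)
        hueStar <- 240 * (1 - eStar)
        nles <- sum(lesion)
        if (hueNoiseSd > 0) {
            noise <- stats::rnorm(nles, 0, hueNoiseSd)
            noise <- pmin(pmax(noise, -3 * hueNoiseSd), 3 * hueNoiseSd)
        } else noise <- numeric(nles)
        hue[lesion] <- pmin(pmax(hueStar + noise, 0), 240)
        rgb <- hsvToRgb(cbind(as.vector(hue), 1, 1))
        right <- array(0, dim = c(height, leftW, 3L))
        right[, , 1] <- rgb[, 1]; right[, , 2] <- rgb[, 2]
        right[, , 3] <- rgb[, 3]
        # cystic core: dark and colourless in the elastogram too
        for (ch in 1:3) {
            plane <- right[, , ch]
            plane[core] <- 12
            right[, , ch] <- plane
        }
        frame <- array(0, dim = c(height, width, 3L))
        frame[, seq_len(leftW), ] <- left
        frame[, seq.int(splitX, splitX + markerWidth - 1L), ] <- 255
        frame[, seq.int(splitX + markerWidth, width), ] <- right
        list(frame = frame,
             mask = lesionMask(lesion, side = "left"),
             truth = list(eStar = eStar, center = center,
                          semiAxes = semiAxes, rotation = rotation,
                          cysticFraction = cysticFraction,
                          hueNoiseSd = hueNoiseSd, splitX = splitX,
                          markerWidth = markerWidth, seed = seed))
    })
}

#' Generate a calibrated synthetic patient cohort
#'
#' Draws a ground-truth elasticity per patient from the group's calibrated
#' distribution, renders `frameCount` phantom frames per patient (with
#' randomised lesion geometry), and assembles a cohort table with NIH
#' categories consistent with the group (low-risk patients split between
#' very-low and low risk, high-risk patients between intermediate and
#' high, in the reference cohort's proportions 15:31 and 29:9) plus
#' plausible age, sex, size-class and location covariates drawn from the
#' reference cohort's group-conditional frequencies.
#'
#' @param nLow,nHigh patients per malignant-potential group (defaults 46
#'   and 38, the reference cohort sizes).
#' @param lowDist,highDist `elasticityDist` objects (defaults
#'   [lowRiskDist()] / [highRiskDist()]).
#' @param frameCount phantom frames per patient (default 1).
#' @param width,height,markerWidth frame geometry passed to
#'   [makePhantom()].
#' @param hueNoiseSd per-pixel hue noise SD in degrees (default 5).
#' @param seed RNG seed; the whole cohort is deterministic given the seed.
#' @param outDir optional directory; when given, frames and masks are
#'   written as PNG with a manifest and truth CSV.
#' @return A list with `cohort` (data.frame: patient_id, group, nih,
#'   e_star, age, sex, size_class, location), `frames` and `masks`
#'   (lists indexed by frame, `NULL`-free only when `outDir` is `NULL`),
#'   and `manifest` (data.frame: patient_id, frame).
#' @export
makeCohort <- function(nLow = 46L, nHigh = 38L, lowDist = lowRiskDist(),
                       highDist = highRiskDist(), frameCount = 1L,
                       width = 600L, height = 300L, markerWidth = 4L,
                       hueNoiseSd = 5, seed = 1L, outDir = NULL) {
    stopifnot(nLow >= 1L, nHigh >= 1L, frameCount >= 1L)
    withSeed(seed, {
        nihLow <- sample(c("very_low", "low"), nLow, replace = TRUE,
                         prob = c(15, 31))
        nihHigh <- sample(c("intermediate", "high"), nHigh, replace = TRUE,
                          prob = c(29, 9))
        cohort <- data.frame(
            patient_id = sprintf("P%03d", seq_len(nLow + nHigh)),
            group = rep(c("low_risk", "high_risk"), c(nLow, nHigh)),
            nih = c(nihLow, nihHigh),
            e_star = c(rElasticity(nLow, lowDist),
                       rElasticity(nHigh, highDist)),
            age = round(c(stats::rnorm(nLow, 59.0, 10.87),
                          stats::rnorm(nHigh, 62.6, 10.92))),
            sex = c(sample(c("male", "female"), nLow, TRUE,
                           prob = c(16, 30)),
                    sample(c("male", "female"), nHigh, TRUE,
                           prob = c(19, 19))),
            size_class = c(sample(c("le2cm", "gt2cm"), nLow, TRUE,
                                  prob = c(27, 19)),
                           sample(c("le2cm", "gt2cm"), nHigh, TRUE,
                                  prob = c(4, 34))),
            location = c(sample(c("cardia", "fundus", "body", "antrum",
                                  "extragastric"), nLow, TRUE,
                                prob = c(1, 23, 19, 1, 2)),
                         sample(c("cardia", "fundus", "body", "antrum",
                                  "extragastric"), nHigh, TRUE,
                                prob = c(1, 22, 12, 0.5, 3))),
            stringsAsFactors = FALSE)
        leftW <- (width - markerWidth) %/% 2L
        frames <- list(); masks <- list(); manifest <- list()
        k <- 0L
        for (i in seq_len(nrow(cohort))) {
            for (f in seq_len(frameCount)) {
                k <- k + 1L
                ax <- c(stats::runif(1, 0.15, 0.3) * leftW,
                        stats::runif(1, 0.15, 0.3) * height)
                r <- max(ax)
                ctr <- c(stats::runif(1, r + 2, leftW - r - 1),
                         stats::runif(1, r + 2, height - r - 1))
                ph <- makePhantom(cohort$e_star[i], width = width,
                                  height = height,
                                  markerWidth = markerWidth,
                                  center = ctr, semiAxes = ax,
                                  rotation = stats::runif(1, 0, pi),
                                  hueNoiseSd = hueNoiseSd)
                frames[[k]] <- ph$frame
                masks[[k]] <- ph$mask
                manifest[[k]] <- data.frame(
                    patient_id = cohort$patient_id[i], frame = k)
            }
        }
        manifest <- do.call(rbind, manifest)
        if (!is.null(outDir)) {
            dir.create(outDir, recursive = TRUE, showWarnings = FALSE)
            manifest$frame_path <- file.path(
                outDir, sprintf("frame_%04d.png", manifest$frame))
            manifest$mask_path <- file.path(
                outDir, sprintf("mask_%04d.png", manifest$frame))
            for (k in seq_len(nrow(manifest))) {
                writeFrame(frames[[k]], manifest$frame_path[k])
                writeMaskPng(masks[[k]], manifest$mask_path[k])
            }
            utils::write.csv(manifest, file.path(outDir, "manifest.csv"),
                             row.names = FALSE)
            utils::write.csv(cohort, file.path(outDir, "cohort.csv"),
                             row.names = FALSE)
        }
        list(cohort = cohort, frames = frames, masks = masks,
             manifest = manifest)
    })
}
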