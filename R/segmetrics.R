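#' Overlap metrics between binary masks
#'
#' `diceCoefficient` computes `2|A n B| / (|A| + |B|)` and `iouScore`
#' computes `|A n B| / |A u B|`.  Two empty masks agree perfectly and
#' score 1 (the result then carries an `emptyPair` attribute as a QC
#' flag); an empty mask against a non-empty one scores 0.
#'
#' @param a,b [LesionMask-class] objects or logical matrices of equal
#'   dimensions.
#' @return A number in \[0, 1\].
#' @examples
#' m1 <- matrix(FALSE, 4, 4); m1[1:2, 1:2] <- TRUE
#' m2 <- matrix(FALSE, 4, 4); m2[2:3, 1:2] <- TRUE
#' diceCoefficient(m1, m2)  # 0.5
#' iouScore(m1, m2)         # 1/3
#' @export
diceCoefficient <- function(a, b) {
    a <- asBits(a, "a"); b <- asBits(b, "b")
    if (!all(dim(a) == dim(b))) stop("mask dimensions differ")
    sa <- sum(a); sb <- sum(b)
    if (sa + sb == 0L) return(structure(1, emptyPair = TRUE))
    2 * sum(a & b) / (sa + sb)
}

#' @rdname diceCoefficient
#' @export
iouScore <- function(a, b) {
    a <- asBits(a, "a"); b <- asBits(b, "b")
    if (!all(dim(a) == dim(b))) stop("mask dimensions differ")
    u <- sum(a | b)
    if (u == 0L) return(structure(1, emptyPair = TRUE))
    sum(a & b) / u
}

#' Detection precision and recall at an IoU threshold
#'
#' Evaluates lesion detection frame by frame: within each frame, predicted
#' masks are matched one-to-one to ground-truth masks greedily in
#' decreasing IoU order, and a match counts as a true positive when its
#' IoU reaches the threshold.  Precision is TP over predictions, recall TP
#' over truths.
#'
#' @param pred,truth lists with one element per frame; each element is a
#'   list of masks (possibly empty) for that frame.  A bare mask is
#'   treated as a single-frame, single-lesion input.
#' @param iouThreshold minimum IoU for a true positive (default 0.5).
#' @return A list with `precision`, `recall`, `tp`, `nPred`, `nTruth`.
#'   Empty inputs give precision/recall 1 with an `empty` flag.
#' @export
detectionPR <- function(pred, truth, iouThreshold = 0.5) {
    wrap <- function(x) {
        if (!is.list(x)) x <- list(x)
        lapply(x, function(f) if (is.list(f)) f else list(f))
    }
    pred <- wrap(pred); truth <- wrap(truth)
    if (length(pred) != length(truth))
        stop("'pred' and 'truth' must cover the same frames")
    tp <- 0L; nPred <- 0L; nTruth <- 0L
    for (f in seq_along(pred)) {
        ps <- pred[[f]]; ts <- truth[[f]]
        nPred <- nPred + length(ps); nTruth <- nTruth + length(ts)
        if (!length(ps) || !length(ts)) next
        iousM <- outer(seq_along(ps), seq_along(ts),
                       Vectorize(function(i, j) iouScore(ps[[i]], ts[[j]])))
        usedP <- logical(length(ps)); usedT <- logical(length(ts))
        ord <- order(iousM, decreasing = TRUE)
        for (k in ord) {
            if (iousM[k] < iouThreshold) break
            i <- (k - 1L) %% length(ps) + 1L
            j <- (k - 1L) %/% length(ps) + 1L
            if (usedP[i] || usedT[j]) next
            usedP[i] <- TRUE; usedT[j] <- TRUE
            tp <- tp + 1L
        }
    }
    if (nPred == 0L && nTruth == 0L)
        return(list(precision = 1, recall = 1, tp = 0L, nPred = 0L,
                    nTruth = 0L, empty = TRUE))
    list(precision = if (nPred) tp / nPred else 1,
         recall = if (nTruth) tp / nTruth else 1,
         tp = tp, nPred = nPred, nTruth = nTruth)
}

# Box-filter mean of a matrix with half-width k (edge-replicated), via an
# integral image; k = 0 returns the input.
boxMean <- function(m, k) {
    if (k == 0L) return(m)
    h <- nrow(m); w <- ncol(m)
    # cumulative sums along both axes with a zero border
    s <- rbind(0, apply(m, 2, cumsum))
    s <- cbind(0, t(apply(s, 1, cumsum)))
    r1 <- pmax(seq_len(h) - k, 1L); r2 <- pmin(seq_len(h) + k, h)
    c1 <- pmax(seq_len(w) - k, 1L); c2 <- pmin(seq_len(w) + k, w)
    tot <- s[r2 + 1L, c2 + 1L, drop = FALSE] -
        s[r1, c2 + 1L, drop = FALSE] -
        s[r2 + 1L, c1, drop = FALSE] + s[r1, c1, drop = FALSE]
    area <- outer(r2 - r1 + 1L, c2 - c1 + 1L)
    tot / area
}

# Per-pixel feature matrix for the toy segmenter: normalised intensity at
# several smoothing scales plus a local-contrast channel.
segFeatures <- function(bmode, scales = c(0L, 2L, 5L, 10L)) {
    l <- rasterLuma(bmode) / 255
    feats <- lapply(scales, function(k) as.vector(boxMean(l, k)))
    coarse <- boxMean(l, max(scales) * 2L)
    feats <- c(feats, list(as.vector(l - coarse)))
    do.call(cbind, feats)
}

#' Train a toy lesion segmenter on phantom frames
#'
#' A deliberately small demonstrator, not a reproduction of a clinical
#' deep segmentation model: a logistic pixel classifier over a 4-level
#' multi-scale intensity pyramid (box means at half-widths 0/2/5/10 plus a
#' local-contrast channel), fitted by iteratively reweighted least squares
#' on a seeded subsample of training pixels.  Training is deterministic
#' given the seed.  Prediction thresholds the per-pixel probability at 0.5
#' and keeps the largest connected component with filled holes.
#'
#' @param bmodes list of B-mode panel rasters (at least 50).
#' @param masks list of matching ground-truth left-panel masks.
#' @param epochs number of IRLS sweeps (default 8).
#' @param seed RNG seed controlling the pixel subsample.
#' @param pixelsPerFrame training pixels sampled per frame (default 400).
#' @return A model object of class `toySegmenter` for [predictMask()].
#' @export
trainToySegmenter <- function(bmodes, masks, epochs = 8L, seed = 1L,
                              pixelsPerFrame = 400L) {
    if (length(bmodes) < 50L)
        stop("need at least 50 training frames")
    if (length(bmodes) != length(masks))
        stop("'bmodes' and 'masks' must have equal length")
    scales <- c(0L, 2L, 5L, 10L)
    dat <- withSeed(seed, lapply(seq_along(bmodes), function(i) {
        X <- segFeatures(bmodes[[i]], scales)
        y <- as.vector(asBits(masks[[i]]))
        pick <- sample.int(length(y), min(pixelsPerFrame, length(y)))
        list(X = X[pick, , drop = FALSE], y = y[pick])
    }))
    X <- do.call(rbind, lapply(dat, `[[`, "X"))
    y <- as.numeric(unlist(lapply(dat, `[[`, "y")))
    mu <- colMeans(X); sd <- pmax(apply(X, 2, stats::sd), 1e-8)
    Xs <- cbind(1, sweep(sweep(X, 2, mu), 2, sd, "/"))
    w <- numeric(ncol(Xs))
    for (it in seq_len(epochs)) {  # IRLS with mild ridge for stability
        eta <- drop(Xs %*% w)
        p <- 1 / (1 + exp(-eta))
        wt <- pmax(p * (1 - p), 1e-6)
        z <- eta + (y - p) / wt
        A <- crossprod(Xs * wt, Xs) + diag(1e-6, ncol(Xs))
        w <- drop(solve(A, crossprod(Xs * wt, z)))
    }
    structure(list(w = w, mu = mu, sd = sd, scales = scales),
              class = "toySegmenter")
}

#' Predict a lesion mask with the toy segmenter
#'
#' @param model a `toySegmenter` from [trainToySegmenter()].
#' @param bmode a B-mode panel raster.
#' @return A left-panel [LesionMask-class].
#' @export
predictMask <- function(model, bmode) {
    stopifnot(inherits(model, "toySegmenter"))
    X <- segFeatures(bmode, model$scales)
    Xs <- cbind(1, sweep(sweep(X, 2, model$mu), 2, model$sd, "/"))
    p <- 1 / (1 + exp(-drop(Xs %*% model$w)))
    bits <- matrix(p >= 0.5, nrow = dim(bmode)[1])
    if (any(bits)) {
        lab <- EBImage::bwlabel(EBImage::Image(t(bits) * 1))
        lab <- EBImage::imageData(EBImage::fillHull(lab))
        sizes <- tabulate(lab[lab > 0])
        bits <- t(lab == which.max(sizes))
    }
    lesionMask(bits, side = "left")
}

#' Patient-level train/test split
#'
#' Splits frames into training and test sets by patient id so that no
#' patient contributes to both sides.
#'
#' @param patientIds character or integer vector, one entry per frame.
#' @param trainFrac fraction of *patients* assigned to training
#'   (default 0.9).
#' @param seed RNG seed.
#' @return A list with logical vectors `train` and `test` over frames.
#' @export
splitByPatient <- function(patientIds, trainFrac = 0.9, seed = 1L) {
    ids <- unique(patientIds)
    nTrain <- max(1L, min(length(ids) - 1L,
                          round(trainFrac * length(ids))))
    trainIds <- withSeed(seed, sample(ids, nTrain))
    train <- patientIds %in% trainIds
    list(train = train, test = !train)
}
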