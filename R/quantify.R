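#' Quantification configuration
#'
#' Bundles the thresholds and colormap used when extracting the elasticity
#' index from a frame.
#'
#' @param sMin saturation floor for a pixel to count as colour overlay
#'   rather than grayscale underlay (default 0.15).
#' @param vMin value (brightness) floor for colour pixels (default 0.10).
#' @param solidTau B-mode luma floor, 0-255, below which a lesion pixel is
#'   considered anechoic/cystic and excluded from quantification
#'   (default 20); 0 disables the filter.
#' @param minColorFraction minimum fraction of solid lesion pixels that
#'   must pass the colour filter; frames below it are rejected as
#'   poor-quality rather than quantified (default 0.10).
#' @param sIndeterminate saturation floor for the mean colour itself; an
#'   achromatic mean has no meaningful hue and is refused (default 0.05).
#' @param colormap a [Colormap-class] or `NULL` for the canonical
#'   256-entry blue-to-red map.
#' @return A list of class `QuantConfig`.
#' @examples
#' cfg <- quantConfig(solidTau = 0)  # disable the solid-component filter
#' @export
quantConfig <- function(sMin = 0.15, vMin = 0.10, solidTau = 20,
                        minColorFraction = 0.10, sIndeterminate = 0.05,
                        colormap = NULL) {
    stopifnot(sMin >= 0, sMin <= 1, vMin >= 0, vMin <= 1,
              solidTau >= 0, solidTau <= 255,
              minColorFraction >= 0, minColorFraction <= 1)
    if (is.null(colormap)) colormap <- buildColormap()
    stopifnot(is(colormap, "Colormap"))
    structure(list(sMin = sMin, vMin = vMin, solidTau = solidTau,
                   minColorFraction = minColorFraction,
                   sIndeterminate = sIndeterminate, colormap = colormap),
              class = "QuantConfig")
}

#' Restrict a mask to the solid lesion component
#'
#' Elasticity is only meaningful over solid tissue: anechoic (cystic)
#' regions carry no strain signal.  A lesion pixel is kept when its B-mode
#' luma at the same panel-local coordinate is at least `tau`.
#'
#' @param bmode the B-mode panel raster (`height x width x 3`).
#' @param mask a [LesionMask-class] whose bits are panel-local to `bmode`.
#' @param tau luma threshold in \[0, 255\]; `tau <= 0` disables the filter.
#' @return A [LesionMask-class] (same side) with anechoic pixels removed.
#' @export
solidComponentFilter <- function(bmode, mask, tau = 20) {
    checkRaster(bmode, "bmode")
    bits <- maskBits(mask)
    if (!all(dim(bits) == dim(bmode)[1:2]))
        stop("mask dimensions do not match the B-mode panel")
    if (tau <= 0) return(mask)
    keep <- bits & (rasterLuma(bmode) >= tau)
    if (!any(keep))
        stop("degenerate lesion: no solid pixels remain after the ",
             "anechoic filter")
    new("LesionMask", bits = keep, side = panelSide(mask))
}

#' Select colour pixels inside the lesion
#'
#' Collects the elastogram pixels under the mask whose saturation and
#' value pass the configured floors, separating the colour overlay from
#' the grayscale B-mode underlay that shows through it.  When fewer than
#' `minColorFraction` of the supplied pixels are coloured the frame is
#' rejected as poor-quality.
#'
#' @param elasto the elastogram panel raster.
#' @param mask a [LesionMask-class] panel-local to `elasto` (normally
#'   already solid-filtered).
#' @param cfg a [quantConfig()] list.
#' @return A list with `pixels` (n x 3 RGB matrix of the retained
#'   pixels), `nGiven` (mask pixels supplied) and `nColor`.
#' @export
selectColorPixels <- function(elasto, mask, cfg = quantConfig()) {
    checkRaster(elasto, "elasto")
    bits <- maskBits(mask)
    if (!all(dim(bits) == dim(elasto)[1:2]))
        stop("mask dimensions do not match the elastogram panel")
    idx <- which(bits)
    if (!length(idx)) stop("degenerate lesion: empty mask")
    px <- cbind(elasto[, , 1][idx], elasto[, , 2][idx], elasto[, , 3][idx])
    colnames(px) <- c("r", "g", "b")
    hsv <- rgbToHsv(px)
    keep <- hsv[, 2] >= cfg$sMin & hsv[, 3] >= cfg$vMin
    nColor <- sum(keep)
    if (nColor / length(idx) < cfg$minColorFraction)
        stop(sprintf(
            "low colour coverage: %d of %d lesion pixels are coloured (fraction %.3f < %.3f)",
            nColor, length(idx), nColor / length(idx),
            cfg$minColorFraction))
    list(pixels = px[keep, , drop = FALSE], nGiven = length(idx),
         nColor = nColor)
}

#' Mean colour of a pixel sample
#'
#' Arithmetic per-channel mean, kept at full precision.
#'
#' @param pixels an n x 3 RGB matrix (or the list returned by
#'   [selectColorPixels()]).
#' @return Numeric vector (r, g, b).
#' @examples
#' meanRgb(rbind(c(255, 0, 0), c(0, 0, 255)))  # 127.5, 0, 127.5
#' @export
meanRgb <- function(pixels) {
    if (is.list(pixels) && !is.null(pixels$pixels)) pixels <- pixels$pixels
    if (!is.matrix(pixels) || ncol(pixels) != 3L || nrow(pixels) < 1L)
        stop("degenerate lesion: no pixels to average")
    m <- colMeans(pixels)
    names(m) <- c("r", "g", "b")
    m
}

#' Compute the elasticity index of one frame
#'
#' The full per-frame quantification pipeline: locate the marker line and
#' split the frame, transfer the B-mode lesion mask to the elastogram
#' panel, drop anechoic (cystic) pixels via the B-mode solid-component
#' filter, select the coloured overlay pixels, average them in RGB,
#' convert the mean to HSV, project it onto the colormap by minimum
#' distance, and rescale the matched index to the \[0, 1\] elasticity
#' scale.  Every intermediate quantity is retained in the result for
#' auditing.
#'
#' @param frame the dual-panel frame raster (`height x width x 3`, 0-255).
#' @param mask a left-panel [LesionMask-class] outlining the lesion in the
#'   B-mode panel.
#' @param cfg a [quantConfig()] list.
#' @param geom optional [SplitGeometry-class]; when `NULL` the marker line
#'   is auto-detected.
#' @return An [ElasticityResult-class] object.
#' @examples
#' ph <- makePhantom(eStar = 0.4, width = 240, height = 160, seed = 1,
#'                   hueNoiseSd = 0)
#' res <- computeEusEAi(ph$frame, ph$mask)
#' elasticity(res)
#' @export
computeEusEAi <- function(frame, mask, cfg = quantConfig(), geom = NULL) {
    checkRaster(frame, "frame")
    if (is.null(geom)) geom <- detectMarkerLine(frame)
    panels <- splitPanels(frame, geom)
    maskR <- mapMaskToElasto(mask, geom)
    nMask <- sum(maskBits(maskR))
    if (nMask < 1L) stop("degenerate lesion: empty mask")
    solid <- solidComponentFilter(panels$bmode, maskR, cfg$solidTau)
    nSolid <- sum(maskBits(solid))
    sample <- selectColorPixels(panels$elasto, solid, cfg)
    mRgb <- meanRgb(sample$pixels)
    mHsv <- rgbToHsv(mRgb)
    proj <- projectToColormap(mHsv, cfg$colormap, cfg$sIndeterminate)
    flags <- character()
    if (geom@fallback) flags <- c(flags, "fallback-split")
    new("ElasticityResult",
        eusEAi = indexToElasticity(proj$index, nEntries(cfg$colormap)),
        meanRgb = unname(mRgb), meanHsv = unname(mHsv),
        projIndex = proj$index, projDistance = proj$distance,
        projRgb = unname(as.numeric(proj$rgb0)),
        projHsv = unname(proj$hsv0),
        nMask = as.integer(nMask), nSolid = as.integer(nSolid),
        nColor = as.integer(sample$nColor), qcFlags = flags)
}
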