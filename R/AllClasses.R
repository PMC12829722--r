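#' @import methods
NULL

#' Elastography colormap
#'
#' Ordered lookup table of `N` RGB entries spanning the strain-elastography
#' colour scale from blue (index 0, stiff) to red (index `N - 1`, soft),
#' together with the HSV coordinates of every entry.  The inverse map --
#' position along the table, rescaled to \[0, 1\] -- defines the elasticity
#' index.
#'
#' @slot rgb integer matrix (`N` x 3, columns r/g/b) with channels in
#'   \[0, 255\].  Entries are 8-bit quantised so that a colour painted into a
#'   raster round-trips exactly.
#' @slot hsv numeric matrix (`N` x 3, columns h/s/v); hue in degrees
#'   \[0, 360), saturation and value in \[0, 1\].  Always derived from `rgb`.
#'
#' @seealso [buildColormap()], [projectToColormap()], [indexToElasticity()]
#' @export
setClass("Colormap", representation(rgb = "matrix", hsv = "matrix"))

setValidity("Colormap", function(object) {
    msg <- character()
    if (!is.numeric(object@rgb) || ncol(object@rgb) != 3L)
        msg <- c(msg, "'rgb' must be an N x 3 numeric matrix")
    if (nrow(object@rgb) < 2L)
        msg <- c(msg, "a colormap needs at least 2 entries")
    if (any(object@rgb < 0) || any(object@rgb > 255))
        msg <- c(msg, "RGB channels must lie in [0, 255]")
    if (!identical(dim(object@rgb), dim(object@hsv)))
        msg <- c(msg, "'hsv' must have the same dimensions as 'rgb'")
    if (length(msg)) msg else TRUE
})

#' Binary lesion mask
#'
#' A binary raster aligned to one panel of a dual-panel EUS-E frame.
#' Row/column indexing follows the raster convention used throughout the
#' package: rows are image rows (y, top to bottom), columns are image
#' columns (x, left to right), 1-based.
#'
#' @slot bits logical matrix (height x width); `TRUE` marks lesion pixels.
#' @slot side `"left"` (B-mode panel) or `"right"` (elastogram panel).
#'
#' @seealso [lesionMask()], [mapMaskToElasto()], [diceCoefficient()]
#' @export
setClass("LesionMask", representation(bits = "matrix", side = "character"))

setValidity("LesionMask", function(object) {
    msg <- character()
    if (!is.logical(object@bits))
        msg <- c(msg, "'bits' must be a logical matrix")
    if (nrow(object@bits) < 1L || ncol(object@bits) < 1L)
        msg <- c(msg, "mask must be at least 1 x 1")
    if (length(object@side) != 1L || !object@side %in% c("left", "right"))
        msg <- c(msg, "'side' must be \"left\" or \"right\"")
    if (length(msg)) msg else TRUE
})

#' Split geometry of a dual-panel frame
#'
#' Describes where a dual-panel EUS-E frame is divided: the left B-mode
#' panel spans columns `1 .. splitX - 1`, the marker band spans
#' `splitX .. splitX + markerWidth - 1`, and the right elastogram panel
#' spans the remainder.  Panel widths must agree within 2 px; larger
#' mismatches are rejected rather than silently rescaled.
#'
#' @slot splitX integer, 1-based column of the first marker-band pixel
#'   (equivalently, left-panel width + 1).
#' @slot markerWidth integer, marker-band width in pixels (0 allowed).
#' @slot width integer, total frame width the geometry refers to.
#' @slot fallback logical; `TRUE` when automatic detection found no marker
#'   and fell back to the frame midline.
#'
#' @seealso [detectMarkerLine()], [splitPanels()]
#' @export
setClass("SplitGeometry",
    representation(splitX = "integer", markerWidth = "integer",
                   width = "integer", fallback = "logical"))

setValidity("SplitGeometry", function(object) {
    msg <- character()
    sx <- object@splitX; mw <- object@markerWidth; w <- object@width
    if (mw < 0L) msg <- c(msg, "'markerWidth' must be >= 0")
    leftW <- sx - 1L
    rightW <- w - sx - mw + 1L
    if (leftW < 1L) msg <- c(msg, "left panel is empty")
    if (rightW < 1L) msg <- c(msg, "right panel is empty")
    if (leftW >= 1L && rightW >= 1L && abs(leftW - rightW) > 2L)
        msg <- c(msg, sprintf(
            "panel widths differ by %d px (max tolerated: 2)",
            abs(leftW - rightW)))
    if (length(msg)) msg else TRUE
})

#' Elasticity quantification result
#'
#' The elasticity index of one frame together with its full audit trail:
#' the mean colour of the selected lesion pixels, its HSV coordinates, the
#' colormap entry it projects onto, pixel counts at every filtering stage,
#' and QC flags.
#'
#' @slot eusEAi numeric in \[0, 1\]; the elasticity index (0 = stiffest /
#'   blue, 1 = softest / red).
#' @slot meanRgb numeric(3), full-precision per-channel mean of the
#'   selected colour pixels.
#' @slot meanHsv numeric(3), HSV coordinates (h degrees, s, v) of `meanRgb`.
#' @slot projIndex integer, 0-based colormap index of the nearest entry.
#' @slot projDistance numeric, HSV distance to that entry.
#' @slot projRgb numeric(3), RGB of the matched colormap entry.
#' @slot projHsv numeric(3), HSV of the matched colormap entry.
#' @slot nMask,nSolid,nColor integer pixel counts: mask total, after the
#'   solid-component filter, after the colour-pixel filter.
#' @slot qcFlags character vector of QC annotations (e.g.
#'   `"fallback-split"`).
#'
#' @seealso [computeEusEAi()]
#' @export
setClass("ElasticityResult",
    representation(eusEAi = "numeric", meanRgb = "numeric",
                   meanHsv = "numeric", projIndex = "integer",
                   projDistance = "numeric", projRgb = "numeric",
                   projHsv = "numeric", nMask = "integer",
                   nSolid = "integer", nColor = "integer",
                   qcFlags = "character"))

setValidity("ElasticityResult", function(object) {
    msg <- character()
    if (object@eusEAi < 0 || object@eusEAi > 1)
        msg <- c(msg, "'eusEAi' must lie in [0, 1]")
    if (object@nColor > object@nSolid || object@nSolid > object@nMask)
        msg <- c(msg, "counts must satisfy nColor <= nSolid <= nMask")
    if (length(msg)) msg else TRUE
})

#' ROC curve for a negatively oriented score
#'
#' Full ROC curve of a continuous score against a binary label, with the
#' convention that *lower* scores indicate the positive (high-risk) class:
#' a case is called positive when its score falls strictly below the
#' cutoff.  Candidate cutoffs are the midpoints between consecutive
#' distinct score values plus infinite sentinels, and the AUC is the
#' trapezoidal area over (1 - specificity, sensitivity).
#'
#' @slot cutoffs numeric vector of candidate cutoffs (increasing).
#' @slot sensitivity,specificity numeric vectors, one value per cutoff.
#' @slot auc numeric in \[0, 1\].
#'
#' @seealso [rocCurve()], [youdenCutoff()]
#' @export
setClass("RocCurve",
    representation(cutoffs = "numeric", sensitivity = "numeric",
                   specificity = "numeric", auc = "numeric"))

setValidity("RocCurve", function(object) {
    msg <- character()
    n <- length(object@cutoffs)
    if (length(object@sensitivity) != n || length(object@specificity) != n)
        msg <- c(msg, "cutoffs/sensitivity/specificity lengths differ")
    if (object@auc < 0 || object@auc > 1)
        msg <- c(msg, "'auc' must lie in [0, 1]")
    if (length(msg)) msg else TRUE
})
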