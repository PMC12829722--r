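#' Accessors for package classes
#'
#' Small accessor generics: `nEntries()` (number of colormap entries),
#' `cmapRgb()` / `cmapHsv()` (colormap lookup tables), `maskBits()` /
#' `panelSide()` (lesion-mask contents), `elasticity()` (the elasticity
#' index of a result), `qcFlags()` (QC annotations), `aucValue()` (area
#' under an ROC curve).
#'
#' @param x an object of the appropriate class.
#' @return The slot contents; see the class documentation.
#' @name accessors
#' @aliases nEntries cmapRgb cmapHsv maskBits panelSide elasticity qcFlags
#'   aucValue
NULL

#' @rdname accessors
#' @export
setGeneric("nEntries", function(x) standardGeneric("nEntries"))
#' @rdname accessors
#' @export
setGeneric("cmapRgb", function(x) standardGeneric("cmapRgb"))
#' @rdname accessors
#' @export
setGeneric("cmapHsv", function(x) standardGeneric("cmapHsv"))
#' @rdname accessors
#' @export
setGeneric("maskBits", function(x) standardGeneric("maskBits"))
#' @rdname accessors
#' @export
setGeneric("panelSide", function(x) standardGeneric("panelSide"))
#' @rdname accessors
#' @export
setGeneric("elasticity", function(x) standardGeneric("elasticity"))
#' @rdname accessors
#' @export
setGeneric("qcFlags", function(x) standardGeneric("qcFlags"))
#' @rdname accessors
#' @export
setGeneric("aucValue", function(x) standardGeneric("aucValue"))

#' @rdname accessors
setMethod("nEntries", "Colormap", function(x) nrow(x@rgb))
#' @rdname accessors
setMethod("cmapRgb", "Colormap", function(x) x@rgb)
#' @rdname accessors
setMethod("cmapHsv", "Colormap", function(x) x@hsv)
#' @rdname accessors
setMethod("maskBits", "LesionMask", function(x) x@bits)
#' @rdname accessors
setMethod("panelSide", "LesionMask", function(x) x@side)
#' @rdname accessors
setMethod("elasticity", "ElasticityResult", function(x) x@eusEAi)
#' @rdname accessors
setMethod("qcFlags", "ElasticityResult", function(x) x@qcFlags)
#' @rdname accessors
setMethod("aucValue", "RocCurve", function(x) x@auc)

setMethod("show", "Colormap", function(object) {
    n <- nrow(object@rgb)
    cat(sprintf("Colormap with %d entries\n", n))
    cat(sprintf("  entry 0:   rgb(%d, %d, %d)  hue %.1f\n",
        object@rgb[1, 1], object@rgb[1, 2], object@rgb[1, 3],
        object@hsv[1, 1]))
    cat(sprintf("  entry %d: rgb(%d, %d, %d)  hue %.1f\n", n - 1L,
        object@rgb[n, 1], object@rgb[n, 2], object@rgb[n, 3],
        object@hsv[n, 1]))
    invisible(NULL)
})

setMethod("show", "LesionMask", function(object) {
    cat(sprintf("LesionMask (%s panel): %d x %d, %d foreground px\n",
        object@side, nrow(object@bits), ncol(object@bits),
        sum(object@bits)))
    invisible(NULL)
})

setMethod("show", "SplitGeometry", function(object) {
    cat(sprintf(
        "SplitGeometry: width %d, splitX %d, marker %d px%s\n",
        object@width, object@splitX, object@markerWidth,
        if (object@fallback) " [midline fallback]" else ""))
    invisible(NULL)
})

setMethod("show", "ElasticityResult", function(object) {
    cat(sprintf("ElasticityResult: EUS-E-AI = %.4f\n", object@eusEAi))
    cat(sprintf("  mean rgb (%.1f, %.1f, %.1f) -> colormap index %d\n",
        object@meanRgb[1], object@meanRgb[2], object@meanRgb[3],
        object@projIndex))
    cat(sprintf("  pixels: mask %d, solid %d, colour %d\n",
        object@nMask, object@nSolid, object@nColor))
    if (length(object@qcFlags))
        cat("  QC flags:", paste(object@qcFlags, collapse = ", "), "\n")
    invisible(NULL)
})

setMethod("show", "RocCurve", function(object) {
    cat(sprintf("RocCurve: %d cutoffs, AUC = %.4f\n",
        length(object@cutoffs), object@auc))
    invisible(NULL)
})
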