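# Internal helpers shared across modules.

# Run `expr` under a temporary RNG state seeded with `seed`, restoring the
# caller's state afterwards.  `seed = NULL` leaves the RNG alone.
withSeed <- function(seed, expr) {
    if (is.null(seed))
        return(eval.parent(substitute(expr)))
    had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
    old <- if (had) get(".Random.seed", envir = globalenv())
    on.exit({
        if (had) assign(".Random.seed", old, envir = globalenv())
        else if (exists(".Random.seed", envir = globalenv(),
                        inherits = FALSE))
            rm(".Random.seed", envir = globalenv())
    })
    set.seed(seed)
    eval.parent(substitute(expr))
}

# Rec. 601 luma of a raster, as a height x width matrix on the 0-255 scale.
rasterLuma <- function(raster) {
    0.299 * raster[, , 1] + 0.587 * raster[, , 2] + 0.114 * raster[, , 3]
}

# Validate the package raster convention: numeric array [height, width, 3],
# channels in [0, 255].
checkRaster <- function(raster, what = "raster") {
    if (!is.array(raster) || length(dim(raster)) != 3L ||
        dim(raster)[3] != 3L)
        stop(sprintf("'%s' must be a height x width x 3 array", what))
    if (min(raster) < 0 || max(raster) > 255)
        stop(sprintf("'%s' channels must lie in [0, 255]", what))
    invisible(raster)
}

#' Construct a lesion mask
#'
#' @param bits logical matrix (height x width), `TRUE` on lesion pixels,
#'   or a numeric matrix that is coerced with `> 0.5`.
#' @param side which panel the mask is aligned to, `"left"` or `"right"`.
#' @return A [LesionMask-class] object.
#' @examples
#' m <- lesionMask(matrix(c(TRUE, FALSE, TRUE, TRUE), 2, 2))
#' sum(maskBits(m))
#' @export
lesionMask <- function(bits, side = "left") {
    if (is.numeric(bits)) bits <- bits > 0.5
    new("LesionMask", bits = bits, side = side)
}

# Coerce a LesionMask or logical matrix to a logical matrix.
asBits <- function(x, what = "mask") {
    if (is(x, "LesionMask")) return(x@bits)
    if (is.logical(x) && is.matrix(x)) return(x)
    if (is.numeric(x) && is.matrix(x)) return(x > 0.5)
    stop(sprintf("'%s' must be a LesionMask or a logical matrix", what))
}
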