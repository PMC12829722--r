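#' Load a dual-panel EUS-E frame
#'
#' Reads a PNG or JPEG raster into the package's array convention:
#' `height x width x 3`, 8-bit channels on the 0-255 scale, row 1 at the
#' top.  Grayscale inputs are promoted to RGB, alpha channels dropped, and
#' 16-bit images rescaled linearly to 0-255.
#'
#' @param path path to a PNG or JPEG file.
#' @return A numeric array (`height x width x 3`).
#' @export
loadFrame <- function(path) {
    if (!file.exists(path))
        stop(sprintf("cannot read frame: '%s' does not exist", path))
    img <- tryCatch(EBImage::readImage(path), error = function(e)
        stop(sprintf("failed to read '%s': %s", path, conditionMessage(e))))
    a <- EBImage::imageData(img)  # [x, y(, channel)], values in [0, 1]
    if (length(dim(a)) == 2L)
        a <- array(rep(a, 3L), dim = c(dim(a), 3L))
    if (dim(a)[3] > 3L)
        a <- a[, , 1:3, drop = FALSE]
    if (dim(a)[3] == 1L)
        a <- array(rep(a, 3L), dim = c(dim(a)[1:2], 3L))
    round(aperm(a, c(2L, 1L, 3L)) * 255)
}

#' Write a frame raster to disk
#'
#' @param raster a `height x width x 3` array on the 0-255 scale.
#' @param path output path; format from the extension (.png or .jpg).
#' @return `path`, invisibly.
#' @export
writeFrame <- function(raster, path) {
    checkRaster(raster)
    EBImage::writeImage(
        EBImage::Image(aperm(raster, c(2L, 1L, 3L)) / 255,
                       colormode = "Color"), path)
    invisible(path)
}

#' Locate the marker line separating the two panels
#'
#' Dual-panel EUS-E exports place a bright vertical marker band between
#' the B-mode panel (left) and the elastogram panel (right).  In `auto`
#' mode the central band of the frame (40-60 percent of its width) is
#' scanned for columns whose mean brightness stands out against the local
#' background; the contiguous run of such columns around the brightest one
#' is taken as the marker.  When no column exceeds `contrastFloor`, the
#' geometry falls back to the frame midline and is flagged.  `fixed` mode
#' trusts a caller-supplied split column.
#'
#' @param raster frame array (`height x width x 3`, 0-255).
#' @param mode `"auto"` or `"fixed"`.
#' @param x for `fixed` mode: 1-based column of the first marker pixel;
#'   must lie in the central 40-60 percent band.
#' @param markerWidth for `fixed` mode: marker-band width (default 0).
#' @param contrastFloor minimum brightness excess (luma units) over the
#'   central-band background for a column to count as marker (default 30).
#' @param band central search band as fractions of the width.
#' @return A [SplitGeometry-class] object.
#' @export
detectMarkerLine <- function(raster, mode = c("auto", "fixed"), x = NULL,
                             markerWidth = 0L, contrastFloor = 30,
                             band = c(0.4, 0.6)) {
    checkRaster(raster)
    mode <- match.arg(mode)
    w <- dim(raster)[2]
    if (w < 4L) stop("frame too narrow to split")
    lo <- max(2L, floor(band[1] * w))
    hi <- min(w - 1L, ceiling(band[2] * w))
    if (mode == "fixed") {
        if (is.null(x)) stop("fixed mode needs 'x'")
        if (x < lo || x > hi)
            stop(sprintf(
                "fixed split x=%d outside the central band [%d, %d]",
                x, lo, hi))
        return(new("SplitGeometry", splitX = as.integer(x),
                   markerWidth = as.integer(markerWidth),
                   width = as.integer(w), fallback = FALSE))
    }
    colMean <- colMeans(rasterLuma(raster))
    bandCols <- lo:hi
    bg <- stats::median(colMean[bandCols])
    isMarker <- colMean[bandCols] - bg >= contrastFloor
    if (!any(isMarker)) {
        sx <- as.integer(floor(w / 2) + 1L)  # left panel = first half
        return(new("SplitGeometry", splitX = sx, markerWidth = 0L,
                   width = as.integer(w), fallback = TRUE))
    }
    peak <- which.max(ifelse(isMarker, colMean[bandCols], -Inf))
    runs <- rle(isMarker)
    ends <- cumsum(runs$lengths)
    starts <- ends - runs$lengths + 1L
    k <- which(starts <= peak & ends >= peak)
    new("SplitGeometry",
        splitX = as.integer(bandCols[starts[k]]),
        markerWidth = as.integer(runs$lengths[k]),
        width = as.integer(w), fallback = FALSE)
}

#' Split a frame into B-mode and elastogram panels
#'
#' Crops the frame at the marker band.  The two panels must agree in width
#' within 2 px; a wider right panel is trimmed at its right edge and a
#' narrower one padded by replicating its last column, so both crops are
#' congruent.  Larger mismatches raise a geometry error rather than being
#' silently rescaled.
#'
#' @param raster frame array (`height x width x 3`).
#' @param geom a [SplitGeometry-class] for this frame.
#' @return A list with elements `bmode` and `elasto` (equal-size arrays)
#'   and `adjusted` (`TRUE` when the right panel was trimmed or padded).
#' @export
splitPanels <- function(raster, geom) {
    checkRaster(raster)
    w <- dim(raster)[2]
    if (geom@width != w)
        stop(sprintf("geometry is for width %d but frame has width %d",
                     geom@width, w))
    sx <- geom@splitX
    mw <- geom@markerWidth
    left <- raster[, seq_len(sx - 1L), , drop = FALSE]
    right <- raster[, seq.int(sx + mw, w), , drop = FALSE]
    lw <- dim(left)[2]; rw <- dim(right)[2]
    if (abs(lw - rw) > 2L)
        stop(sprintf("panel widths %d and %d differ by more than 2 px",
                     lw, rw))
    adjusted <- lw != rw
    if (rw > lw) {
        right <- right[, seq_len(lw), , drop = FALSE]
    } else if (rw < lw) {
        pad <- right[, rep(rw, lw - rw), , drop = FALSE]
        tmp <- array(0, dim = c(dim(right)[1], lw, 3L))
        tmp[, seq_len(rw), ] <- right
        tmp[, seq.int(rw + 1L, lw), ] <- pad
        right <- tmp
    }
    list(bmode = left, elasto = right, adjusted = adjusted)
}

#' Transfer a lesion mask from the B-mode panel to the elastogram panel
#'
#' The elastogram is an overlay on the same acquisition geometry as the
#' B-mode image, so after splitting, the two panels are congruent crops
#' and a mask transfers by pure horizontal translation: panel-local
#' coordinates are preserved, with no scaling or rotation.
#'
#' @param mask a left-panel [LesionMask-class].
#' @param geom the [SplitGeometry-class] the mask's frame was split with.
#' @return A right-panel [LesionMask-class] with identical bits.
#' @export
mapMaskToElasto <- function(mask, geom) {
    if (panelSide(mask) != "left")
        stop("'mask' must be aligned to the left (B-mode) panel")
    leftW <- geom@splitX - 1L
    if (ncol(maskBits(mask)) != leftW)
        stop(sprintf("mask width %d does not match left panel width %d",
                     ncol(maskBits(mask)), leftW))
    new("LesionMask", bits = maskBits(mask), side = "right")
}

#' Read or write a lesion mask as single-channel PNG
#'
#' Foreground is written as 255, background as 0; on reading, pixels above
#' half intensity are foreground.
#'
#' @param mask a [LesionMask-class].
#' @param path file path.
#' @param side panel side to assign on reading.
#' @return `readMaskPng` returns a [LesionMask-class]; `writeMaskPng`
#'   returns `path` invisibly.
#' @export
writeMaskPng <- function(mask, path) {
    EBImage::writeImage(EBImage::Image(t(maskBits(mask)) * 1), path)
    invisible(path)
}

#' @rdname writeMaskPng
#' @export
readMaskPng <- function(path, side = "left") {
    if (!file.exists(path))
        stop(sprintf("cannot read mask: '%s' does not exist", path))
    a <- EBImage::imageData(EBImage::readImage(path))
    if (length(dim(a)) == 3L) a <- a[, , 1]
    lesionMask(t(a) > 0.5, side = side)
}

#' Read or write a lesion mask as run-length JSON
#'
#' Plain-text mask interchange: `{"width": w, "height": h, "side": s,
#' "rows": {"<y>": [[start, len], ...]}}` with 1-based row and column
#' indices; rows without foreground are omitted.
#'
#' @param mask a [LesionMask-class].
#' @param path file path.
#' @return `readMaskRle` returns a [LesionMask-class]; `writeMaskRle`
#'   returns `path` invisibly.
#' @export
writeMaskRle <- function(mask, path) {
    bits <- maskBits(mask)
    rows <- list()
    for (y in seq_len(nrow(bits))) {
        r <- rle(bits[y, ])
        if (!any(r$values)) next
        ends <- cumsum(r$lengths)
        starts <- ends - r$lengths + 1L
        keep <- which(r$values)
        rows[[as.character(y)]] <- lapply(keep, function(k)
            c(starts[k], r$lengths[k]))
    }
    jsonlite::write_json(
        list(width = ncol(bits), height = nrow(bits),
             side = panelSide(mask), rows = rows),
        path, auto_unbox = TRUE)
    invisible(path)
}

#' @rdname writeMaskRle
#' @export
readMaskRle <- function(path) {
    obj <- jsonlite::read_json(path, simplifyVector = TRUE)
    bits <- matrix(FALSE, obj$height, obj$width)
    for (y in names(obj$rows)) {
        runs <- obj$rows[[y]]
        if (is.null(dim(runs))) runs <- matrix(runs, ncol = 2L)
        for (i in seq_len(nrow(runs)))
            bits[as.integer(y),
                 seq.int(runs[i, 1], length.out = runs[i, 2])] <- TRUE
    }
    lesionMask(bits, side = obj$side)
}
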