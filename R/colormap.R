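#' Build the canonical elastography colormap
#'
#' Constructs the blue-to-red colour scale used to quantify strain
#' elastography overlays: entry `i` (0-based) carries hue
#' `240 * (1 - i/(n - 1))` degrees at full saturation and value, so the
#' table sweeps linearly from pure blue (stiff, index 0) through green to
#' pure red (soft, index `n - 1`).  Entries are quantised to 8-bit RGB, so
#' a colour painted into an 8-bit raster and read back matches its table
#' entry exactly.
#'
#' @param nEntries number of entries (default 256, matching the 0-255
#'   colour scale of the elasticity index); must be >= 2.
#' @return A [Colormap-class] object.
#' @examples
#' cm <- buildColormap()
#' cmapRgb(cm)[1, ]    # pure blue
#' cmapRgb(cm)[256, ]  # pure red
#' @export
buildColormap <- function(nEntries = 256L) {
    nEntries <- as.integer(nEntries)
    if (is.na(nEntries) || nEntries < 2L)
        stop("'nEntries' must be an integer >= 2")
    hue <- 240 * (1 - (seq_len(nEntries) - 1) / (nEntries - 1))
    rgb <- t(grDevices::col2rgb(grDevices::hsv(hue / 360, 1, 1)))
    dimnames(rgb) <- list(NULL, c("r", "g", "b"))
    new("Colormap", rgb = rgb, hsv = rgbToHsv(rgb))
}

#' Convert RGB colours to HSV
#'
#' Standard hexcone conversion.  Hue is reported in degrees \[0, 360) and
#' stored as 0 for achromatic colours (s = 0), saturation and value in
#' \[0, 1\].
#'
#' @param rgb numeric vector of length 3 or an n x 3 matrix, channels on
#'   the 0-255 scale.
#' @return A vector of length 3 (named h, s, v) or an n x 3 matrix.
#' @examples
#' rgbToHsv(c(0, 0, 255))   # 240, 1, 1
#' rgbToHsv(c(128, 128, 128))
#' @export
rgbToHsv <- function(rgb) {
    vec <- is.null(dim(rgb))
    m <- if (vec) matrix(rgb, 1L) else as.matrix(rgb)
    if (ncol(m) != 3L) stop("'rgb' must have 3 channels")
    if (any(m < 0) || any(m > 255)) stop("RGB channels must lie in [0, 255]")
    hsv <- t(grDevices::rgb2hsv(t(m), maxColorValue = 255))
    hsv[, 1] <- (hsv[, 1] * 360) %% 360
    colnames(hsv) <- c("h", "s", "v")
    if (vec) hsv[1, ] else hsv
}

#' Convert HSV colours to 8-bit RGB
#'
#' Inverse hexcone conversion, quantised to the 0-255 channel scale.
#'
#' @param hsv numeric vector of length 3 (h degrees, s, v) or an n x 3
#'   matrix.
#' @return A vector of length 3 (named r, g, b) or an n x 3 matrix of
#'   integers in \[0, 255\].
#' @examples
#' hsvToRgb(c(240, 1, 1))  # 0, 0, 255
#' hsvToRgb(c(120, 1, 1))  # 0, 255, 0
#' @export
hsvToRgb <- function(hsv) {
    vec <- is.null(dim(hsv))
    m <- if (vec) matrix(hsv, 1L) else as.matrix(hsv)
    if (ncol(m) != 3L) stop("'hsv' must have 3 components")
    if (any(m[, 2] < 0) || any(m[, 2] > 1) || any(m[, 3] < 0) ||
        any(m[, 3] > 1))
        stop("saturation and value must lie in [0, 1]")
    rgb <- t(grDevices::col2rgb(
        grDevices::hsv((m[, 1] %% 360) / 360, m[, 2], m[, 3])))
    dimnames(rgb) <- list(NULL, c("r", "g", "b"))
    if (vec) rgb[1, ] else rgb
}

#' Project an HSV colour onto the colormap
#'
#' Finds the colormap entry closest to a colour in HSV space.  The squared
#' distance is `(dh/180)^2 + ds^2 + dv^2`, where `dh` is the circular hue
#' difference in degrees (in \[0, 180\]); dividing by 180 makes one unit of
#' hue span commensurate with the full saturation and value ranges.  Ties
#' resolve to the lower (stiffer) index.  Colours with saturation below
#' `sIndeterminate` carry no meaningful hue and are refused rather than
#' assigned a fabricated elasticity.
#'
#' @param hsv numeric vector (h degrees, s, v).
#' @param cmap a [Colormap-class]; default the canonical 256-entry map.
#' @param sIndeterminate saturation floor below which the projection is
#'   refused (default 0.05).
#' @return A list with elements `index` (0-based colormap index), `hsv0`
#'   and `rgb0` (the matched entry's coordinates) and `distance`.
#' @examples
#' projectToColormap(c(240, 1, 1))$index  # 0 (pure blue)
#' projectToColormap(c(0, 1, 1))$index    # 255 (pure red)
#' @export
projectToColormap <- function(hsv, cmap = buildColormap(),
                              sIndeterminate = 0.05) {
    if (length(hsv) != 3L) stop("'hsv' must have 3 components")
    if (hsv[2] < sIndeterminate)
        stop(sprintf(
            "indeterminate colour: saturation %.3f below floor %.3f, hue is meaningless",
            hsv[2], sIndeterminate))
    tab <- cmapHsv(cmap)
    dh <- abs(tab[, 1] - (hsv[1] %% 360))
    dh <- pmin(dh, 360 - dh)
    d2 <- (dh / 180)^2 + (tab[, 2] - hsv[2])^2 + (tab[, 3] - hsv[3])^2
    i <- which.min(d2)  # which.min returns the first minimum: lower index
    list(index = i - 1L, hsv0 = tab[i, ], rgb0 = cmapRgb(cmap)[i, ],
         distance = sqrt(d2[i]))
}

#' Convert a colormap index to an elasticity value
#'
#' Maps the 0-based position along the blue-to-red scale to the \[0, 1\]
#' elasticity index: `index / (nEntries - 1)`.  0 is stiffest (blue),
#' 1 softest (red); smaller values indicate stiffer tissue.
#'
#' @param index 0-based colormap index.
#' @param nEntries number of colormap entries (default 256).
#' @return Elasticity in \[0, 1\].
#' @examples
#' indexToElasticity(51, 256)  # 0.2
#' @export
indexToElasticity <- function(index, nEntries = 256L) {
    if (any(index < 0) || any(index > nEntries - 1L))
        stop(sprintf("'index' must lie in [0, %d]", nEntries - 1L))
    index / (nEntries - 1)
}

#' Read or write a colormap as CSV
#'
#' Plain-text interchange so alternative device colormaps can be dropped
#' in.  Columns: `index` (0-based), `r`, `g`, `b`.  On import the HSV table
#' is recomputed from the RGB entries; a warning is emitted when the
#' endpoints are not pure blue and pure red, since the elasticity scale
#' assumes that orientation.
#'
#' @param cmap a [Colormap-class] object.
#' @param path file path.
#' @return `readColormapCsv` returns a [Colormap-class];
#'   `writeColormapCsv` returns `path` invisibly.
#' @examples
#' p <- tempfile(fileext = ".csv")
#' writeColormapCsv(buildColormap(8), p)
#' nEntries(readColormapCsv(p))
#' @export
writeColormapCsv <- function(cmap, path) {
    rgb <- cmapRgb(cmap)
    utils::write.csv(
        data.frame(index = seq_len(nrow(rgb)) - 1L, r = rgb[, 1],
                   g = rgb[, 2], b = rgb[, 3]),
        path, row.names = FALSE)
    invisible(path)
}

#' @rdname writeColormapCsv
#' @export
readColormapCsv <- function(path) {
    df <- utils::read.csv(path)
    need <- c("index", "r", "g", "b")
    if (!all(need %in% names(df)))
        stop("colormap CSV needs columns index, r, g, b")
    df <- df[order(df$index), ]
    rgb <- as.matrix(df[, c("r", "g", "b")])
    dimnames(rgb) <- list(NULL, c("r", "g", "b"))
    cm <- new("Colormap", rgb = rgb, hsv = rgbToHsv(rgb))
    n <- nrow(rgb)
    if (any(rgb[1, ] != c(0, 0, 255)) || any(rgb[n, ] != c(255, 0, 0)))
        warning("colormap endpoints are not pure blue / pure red; ",
                "elasticity orientation may be wrong")
    cm
}
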