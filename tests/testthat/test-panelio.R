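test_that("frame I/O round-trips through PNG and promotes grayscale", {
    p <- withr::local_tempfile(fileext = ".png")
    ph <- smallPhantom(0.5, seed = 1)
    writeFrame(ph$frame, p)
    back <- loadFrame(p)
    expect_identical(dim(back), dim(ph$frame))
    expect_true(max(abs(back - ph$frame)) <= 1)
    # grayscale input comes back as a 3-channel raster
    g <- withr::local_tempfile(fileext = ".png")
    EBImage::writeImage(EBImage::Image(matrix(0.5, 20, 10)), g)
    gr <- loadFrame(g)
    expect_identical(dim(gr), c(10L, 20L, 3L))
    expect_identical(gr[, , 1], gr[, , 3])
    expect_error(loadFrame("no-such-file.png"), "does not exist")
})

test_that("marker detection recovers the generated split geometry", {
    for (s in 1:5) {
        ph <- smallPhantom(0.4, seed = s)
        g <- detectMarkerLine(ph$frame)
        expect_false(g@fallback)
        expect_true(abs(g@splitX - ph$truth$splitX) <= 1)
        expect_identical(g@markerWidth, ph$truth$markerWidth)
    }
})

test_that("marker detection falls back to the midline on markerless frames", {
    flat <- flatRaster(30, 60, c(90, 90, 90))
    g <- detectMarkerLine(flat)
    expect_true(g@fallback)
    expect_identical(g@splitX, 31L)
    fixed <- detectMarkerLine(flat, mode = "fixed", x = 29, markerWidth = 2)
    expect_identical(fixed@splitX, 29L)
    expect_error(detectMarkerLine(flat, mode = "fixed", x = 5),
                 "central band")
})

test_that("panel split crops congruent panels and tolerates 2 px mismatch", {
    fr <- flatRaster(30, 60, c(10, 20, 30))
    geom <- new("SplitGeometry", splitX = 29L, markerWidth = 4L,
                width = 60L, fallback = FALSE)
    p <- splitPanels(fr, geom)
    expect_identical(dim(p$bmode), c(30L, 28L, 3L))
    expect_identical(dim(p$elasto), c(30L, 28L, 3L))
    expect_false(p$adjusted)
    # odd width: right panel is 2 px narrower and gets edge-padded
    fr2 <- flatRaster(30, 61, c(10, 20, 30))
    geom2 <- new("SplitGeometry", splitX = 31L, markerWidth = 2L,
                 width = 61L, fallback = FALSE)
    p2 <- splitPanels(fr2, geom2)
    expect_identical(dim(p2$elasto)[2], 30L)
    expect_true(p2$adjusted)
    expect_identical(p2$elasto[, 30, ], p2$elasto[, 28, ])
    # empty or grossly unequal panels are geometry errors
    expect_error(new("SplitGeometry", splitX = 1L, markerWidth = 0L,
                     width = 60L, fallback = FALSE), "empty")
    expect_error(new("SplitGeometry", splitX = 10L, markerWidth = 0L,
                     width = 60L, fallback = FALSE), "differ")
})

test_that("splitting then reassembling reproduces the frame exactly", {
    ph <- smallPhantom(0.7, seed = 2)
    g <- detectMarkerLine(ph$frame)
    p <- splitPanels(ph$frame, g)
    rebuilt <- array(0, dim = dim(ph$frame))
    rebuilt[, seq_len(g@splitX - 1L), ] <- p$bmode
    rebuilt[, seq.int(g@splitX, g@splitX + g@markerWidth - 1L), ] <- 255
    rebuilt[, seq.int(g@splitX + g@markerWidth, g@width), ] <- p$elasto
    expect_identical(rebuilt, ph$frame)
})

test_that("mask transfer is an identity in panel-local coordinates", {
    geom <- new("SplitGeometry", splitX = 29L, markerWidth = 4L,
                width = 60L, fallback = FALSE)
    m <- rectMask(30, 28, 10:20, 5:15)
    mr <- mapMaskToElasto(m, geom)
    expect_identical(panelSide(mr), "right")
    expect_identical(maskBits(mr), maskBits(m))
    expect_identical(sum(maskBits(mr)), sum(maskBits(m)))
    expect_error(mapMaskToElasto(rectMask(30, 20, 1:5, 1:5), geom),
                 "width")
    expect_error(mapMaskToElasto(lesionMask(matrix(TRUE, 3, 3),
                                            side = "right"), geom),
                 "left")
})

test_that("phantom mask lands on the painted lesion after transfer", {
    ph <- smallPhantom(0.3, seed = 3, hueNoiseSd = 0)
    g <- detectMarkerLine(ph$frame)
    p <- splitPanels(ph$frame, g)
    mr <- mapMaskToElasto(ph$mask, g)
    # painted lesion pixels: hue of eStar = 0.3 -> not in the green
    # background band; recover them by colour
    painted <- rgbToHsv(cbind(as.vector(p$elasto[, , 1]),
                              as.vector(p$elasto[, , 2]),
                              as.vector(p$elasto[, , 3])))
    paintedBits <- matrix(abs(painted[, 1] - 240 * 0.7) < 1 &
                          painted[, 2] > 0.5, nrow = dim(p$elasto)[1])
    expect_equal(diceCoefficient(maskBits(mr), paintedBits), 1.0)
})

test_that("mask PNG and RLE JSON round-trip exactly", {
    m <- rectMask(25, 40, 3:12, 8:30)
    maskBitsOrig <- maskBits(m)
    p1 <- withr::local_tempfile(fileext = ".png")
    writeMaskPng(m, p1)
    expect_identical(maskBits(readMaskPng(p1)), maskBitsOrig)
    p2 <- withr::local_tempfile(fileext = ".json")
    # add a second run on some rows to exercise the encoder
    bits <- maskBitsOrig
    bits[5:8, 35:38] <- TRUE
    m2 <- lesionMask(bits, side = "right")
    writeMaskRle(m2, p2)
    back <- readMaskRle(p2)
    expect_identical(maskBits(back), bits)
    expect_identical(panelSide(back), "right")
})
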