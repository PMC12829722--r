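test_that("solid-component filter removes anechoic pixels by B-mode luma", {
    bmode <- flatRaster(20, 20, c(120, 120, 120))
    mask <- rectMask(20, 20, 6:15, 6:15)  # 100 px
    expect_identical(maskBits(solidComponentFilter(bmode, mask, 20)),
                     maskBits(mask))
    # black core over 30 of the 100 mask pixels
    dark <- bmode
    dark[6:8, 6:15, ] <- 0
    filtered <- solidComponentFilter(dark, mask, 20)
    expect_identical(sum(maskBits(filtered)), 70L)
    # tau = 0 disables the filter entirely
    expect_identical(maskBits(solidComponentFilter(dark, mask, 0)),
                     maskBits(mask))
    allDark <- flatRaster(20, 20, c(5, 5, 5))
    expect_error(solidComponentFilter(allDark, mask, 20), "degenerate")
})

test_that("colour-pixel selection separates overlay from grayscale underlay", {
    cfg <- quantConfig()
    sat <- flatRaster(10, 10, c(255, 0, 0))
    mask <- rectMask(10, 10, 1:10, 1:10)
    s <- selectColorPixels(sat, mask, cfg)
    expect_identical(s$nColor, s$nGiven)
    # half the lesion grayscale (s = 0) -> half retained
    mixed <- sat
    mixed[1:5, , ] <- 128
    s2 <- selectColorPixels(mixed, mask, cfg)
    expect_identical(s2$nColor, 50L)
    gray <- flatRaster(10, 10, c(128, 128, 128))
    expect_error(selectColorPixels(gray, mask, cfg), "colour coverage")
})

test_that("mean colour is the full-precision channel mean", {
    expect_equal(unname(meanRgb(rbind(c(255, 0, 0), c(0, 0, 255)))),
                 c(127.5, 0, 127.5))
    expect_equal(unname(meanRgb(matrix(rep(c(0, 255, 0), 100), ncol = 3,
                                       byrow = TRUE))),
                 c(0, 255, 0))
    expect_equal(unname(meanRgb(rbind(c(255, 0, 0), c(255, 0, 0),
                                      c(0, 0, 255)))),
                 c(170, 0, 85))
    expect_error(meanRgb(matrix(numeric(0), ncol = 3)), "degenerate")
})

test_that("uniformly painted lesions recover their colormap entry exactly", {
    for (k in c(0L, 1L, 51L, 128L, 254L, 255L)) {
        ph <- smallPhantom(k / 255, hueNoiseSd = 0, seed = 11)
        res <- computeEusEAi(ph$frame, ph$mask)
        expect_identical(res@projIndex, k)
        expect_equal(elasticity(res), k / 255)
        expect_equal(res@projDistance, 0)
    }
})

test_that("shifting lesion hues toward blue never increases elasticity", {
    cfg <- quantConfig()
    buildFrame <- function(hues) {
        fr <- flatRaster(20, 44, c(150, 150, 150))
        fr[, 21:24, ] <- 255  # marker
        rgb <- hsvToRgb(cbind(hues, 1, 1))
        for (ch in 1:3)
            fr[6:15, 29:38, ch] <- matrix(rgb[, ch], 10, 10)
        fr
    }
    mask <- rectMask(20, 20, 6:15, 5:14)
    set.seed(99)
    for (rep in 1:20) {
        h0 <- runif(1, 20, 160)
        hues <- runif(100, h0, h0 + 40)
        delta <- runif(1, 0, 35)
        e1 <- elasticity(computeEusEAi(buildFrame(hues), mask, cfg))
        e2 <- elasticity(computeEusEAi(
            buildFrame(pmin(hues + delta, 240)), mask, cfg))
        expect_lte(e2, e1)
    }
})

test_that("an achromatic mean colour is refused, not quantified", {
    # complementary colours average to gray: hue is meaningless
    fr <- flatRaster(20, 44, c(150, 150, 150))
    fr[, 21:24, ] <- 255
    fr[6:15, 29:38, 1] <- 255; fr[6:15, 29:38, 2:3] <- 0   # red
    fr[6:10, 29:38, 1] <- 0; fr[6:10, 29:38, 2:3] <- 255   # cyan
    mask <- rectMask(20, 20, 6:15, 5:14)
    expect_error(computeEusEAi(fr, mask), "indeterminate")
})

test_that("hue noise perturbs the estimate by at most the stated bound", {
    for (s in 1:10) {
        eStar <- runif(1, 0.05, 0.95)
        ph <- smallPhantom(eStar, hueNoiseSd = 5, seed = s)
        e <- elasticity(computeEusEAi(ph$frame, ph$mask))
        expect_lte(abs(e - eStar), 0.02)
    }
})

test_that("a cystic core is excluded and barely shifts the estimate", {
    cfg <- quantConfig()
    for (s in 1:5) {
        base <- smallPhantom(0.5, hueNoiseSd = 5, seed = s)
        cystic <- smallPhantom(0.5, hueNoiseSd = 5, seed = s,
                               cysticFraction = 0.3)
        e0 <- elasticity(computeEusEAi(base$frame, base$mask, cfg))
        r1 <- computeEusEAi(cystic$frame, cystic$mask, cfg)
        expect_lte(abs(elasticity(r1) - e0), 0.01)
        # the core is dropped by the solid filter
        expect_lt(r1@nSolid / r1@nMask, 0.8)
    }
})

test_that("the audit trail counts are consistent", {
    ph <- smallPhantom(0.4, seed = 5, cysticFraction = 0.2)
    r <- computeEusEAi(ph$frame, ph$mask)
    expect_true(r@nColor <= r@nSolid && r@nSolid <= r@nMask)
    expect_identical(r@nMask, sum(maskBits(ph$mask)))
    expect_equal(elasticity(r), r@projIndex / 255)
})
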