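test_that("GC anchors at zero on a perfect circle", {
    for (n in c(8, 100)) {
        th <- 2 * pi * (0:(n - 1)) / n
        ring <- Structure3D(cbind(3 * cos(th), 3 * sin(th), 1),
                            makeBinning(n))
        expect_lt(abs(globalCompactness(ring)), 1e-9)
    }
    # coincident points error
    expect_error(globalCompactness(Structure3D(matrix(1, 5, 3),
                                               makeBinning(5))),
                 "coincide")
})

test_that("LC anchors at zero on equally spaced collinear points", {
    n <- 40
    line <- Structure3D(cbind(seq_len(n) * 2, 5, -1),
                        makeBinning(n, circular = FALSE))
    lc <- localCompactness(line, 5 * 5000)
    interior <- 6:(n - 5)
    expect_lt(max(abs(lc[interior])), 1e-9)
    expect_error(localCompactness(line, 25 * 5000), "half")
})

test_that("GC and LC are invariant under rigid motions and scaling", {
    s <- randStructure(40, seed = 21)
    bn <- makeBinning(40)
    gc0 <- globalCompactness(Structure3D(s, bn))
    lc0 <- localCompactness(Structure3D(s, bn), 4 * 5000)
    for (k in 1:20) {
        sc <- exp(runif(1, -2, 2))
        st <- rigidTransform(s, seed = 100 + k, scale = sc)
        expect_lt(abs(globalCompactness(Structure3D(st, bn)) - gc0), 1e-9)
        expect_lt(max(abs(localCompactness(Structure3D(st, bn),
                                           4 * 5000) - lc0)), 1e-9)
    }
})

test_that("GC matches the brute-force evaluation on a folded ring", {
    n <- 8
    th <- 2 * pi * (0:(n - 1)) / n
    ring <- cbind(cos(th), sin(th), 0)
    folded <- ring
    folded[seq(1, n, 2), ] <- folded[seq(1, n, 2), ] * 0.4
    s <- Structure3D(folded, makeBinning(n))
    expect_equal(globalCompactness(s), gcOracle(folded), tolerance = 1e-10)
    expect_gt(globalCompactness(s), 0)
})

test_that("GC and LC equal naive evaluations on random structures", {
    for (seed in 1:4) {
        xyz <- randStructure(40, seed)
        s <- Structure3D(xyz, makeBinning(40))
        expect_equal(globalCompactness(s), gcOracle(xyz), tolerance = 1e-10)
        expect_equal(localCompactness(s, 6 * 5000), lcOracle(xyz, 6),
                     tolerance = 1e-10)
    }
    # linear binning windows truncate at the ends
    xyz <- randStructure(20, 99)
    sl <- Structure3D(xyz, makeBinning(20, circular = FALSE))
    expect_equal(localCompactness(sl, 3 * 5000),
                 lcOracle(xyz, 3, circular = FALSE), tolerance = 1e-10)
})

test_that("LC of a hairpin window matches the direct evaluation", {
    # polyline folded back on itself at 60 degrees
    k <- 10
    arm1 <- cbind(seq_len(k), 0, 0)
    dir2 <- c(cos(pi / 3), sin(pi / 3), 0)
    arm2 <- t(sapply(seq_len(k), function(i) arm1[k, ] + i * dir2))
    xyz <- rbind(arm1, arm2)
    s <- Structure3D(xyz, makeBinning(20, circular = FALSE))
    expect_equal(localCompactness(s, 4 * 5000),
                 lcOracle(xyz, 4, circular = FALSE), tolerance = 1e-10)
    lc <- localCompactness(s, 4 * 5000)
    # bins whose window spans the bend are more compact than the arms;
    # the apex itself scores 0 (every window point lies on a straight
    # ray from it, so model and line reference coincide)
    expect_gt(lc[k - 1], lc[5])
    expect_lt(abs(lc[k]), 1e-9)
})

test_that("flattening a circle into ellipses raises GC monotonically", {
    # bins equally spaced along the contour, as on a chromosome backbone
    ellipseArc <- function(n, b) {
        t <- seq(0, 2 * pi, length.out = 20001)
        x <- cos(t); y <- b * sin(t)
        cl <- c(0, cumsum(sqrt(diff(x)^2 + diff(y)^2)))
        tgt <- cl[length(cl)] * (0:(n - 1)) / n
        cbind(approx(cl, x, xout = tgt)$y, approx(cl, y, xout = tgt)$y, 0)
    }
    n <- 60
    gcs <- sapply(c(1, 0.8, 0.6, 0.4, 0.2), function(b) {
        s <- Structure3D(ellipseArc(n, b), makeBinning(n))
        globalCompactness(s)
    })
    expect_true(all(diff(gcs) > 0))
    expect_lt(abs(gcs[1]), 1e-9)
})

test_that("multiscale LC is consistent, ordered and circle-positive", {
    cfg <- syntheticConfig(nBins = 64)
    s <- genStructure(cfg)
    prof <- lcMultiscale(s, c(20 * 5000, 5 * 5000))
    expect_equal(lcScales(prof), c(25000, 100000))   # sorted ascending
    expect_equal(lcValues(prof)[, 1], localCompactness(s, 25000))
    # on a perfect circle the line reference is straight but the model
    # arcs away, so LC > 0, increasingly with scale
    expect_true(all(lcValues(prof) > 0))
    expect_true(all(lcValues(prof)[, 2] > lcValues(prof)[, 1]))
    expect_equal(lcValues(prof)[, 2], lcOracle(coords(s), 20),
                 tolerance = 1e-10)
    expect_equal(gcValue(prof), globalCompactness(s))
    expect_error(lcMultiscale(s, numeric(0)), "empty")
})

test_that("LC log ratios: identity, doubling, undefined entries", {
    cfg <- syntheticConfig(nBins = 48, foldRegions = list(
        list(start = 10, end = 25, amplitude = 2, period = 6)))
    s <- genStructure(cfg)
    p1 <- lcMultiscale(s, c(50000, 100000))
    expect_equal(lcLogRatio(p1, p1),
                 matrix(0, 48, 2), ignore_attr = TRUE)
    p2 <- new("CompactnessProfile", binning = binning(s), gc = gcValue(p1),
              lc = lcValues(p1) * 2, scales = lcScales(p1))
    expect_equal(lcLogRatio(p2, p1), matrix(1, 48, 2), ignore_attr = TRUE)
    # mixed signs are reported missing exactly where sign(a*b) <= 0
    la <- lcValues(p1); la[3, 1] <- -0.5
    pa <- new("CompactnessProfile", binning = binning(s), gc = 0,
              lc = la, scales = lcScales(p1))
    r <- lcLogRatio(pa, p1)
    expect_true(is.na(r[3, 1]))
    expect_false(anyNA(r[-3, ]))
    p3 <- lcMultiscale(s, 50000)
    expect_error(lcLogRatio(p1, p3), "scale mismatch")
})

test_that("a planted fold raises LC inside the folded region", {
    cfg <- syntheticConfig(nBins = 200, foldRegions = list(
        list(start = 60, end = 100, amplitude = 4, period = 8)))
    s <- genStructure(cfg)
    lc <- localCompactness(s, 20 * 5000)
    inside <- mean(lc[60:100])
    outside <- mean(lc[-(50:110)])
    expect_gt(inside, outside)
})
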