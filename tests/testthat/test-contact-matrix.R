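test_that("dense matrix reader handles plain, header and malformed tables", {
    b2 <- makeBinning(2)
    f <- withr::local_tempfile()
    writeLines(c("1 2", "2 1"), f)
    cm <- readContactMatrix(f, b2)
    expect_s4_class(cm, "ContactMatrix")
    expect_equal(contactValues(cm), matrix(c(1, 2, 2, 1), 2))

    # asymmetric input symmetrized with a warning
    writeLines(c("1 4", "2 1"), f)
    expect_warning(cm <- readContactMatrix(f, b2), "symmetrized")
    expect_equal(contactValues(cm), matrix(c(1, 3, 3, 1), 2))

    # non-square table
    writeLines(c("1 2", "2 1", "3 3"), f)
    expect_error(readContactMatrix(f, b2), "square")
    # negative entries
    writeLines(c("1 -2", "-2 1"), f)
    expect_error(readContactMatrix(f, b2), "negative")
    # size mismatch with the binning
    writeLines(c("1 2", "2 1"), f)
    expect_error(readContactMatrix(f, makeBinning(3)), "expects 3")

    # header row + coordinate column
    writeLines(c("bin\t0\t5000", "0\t1\t2", "5000\t2\t1"), f)
    expect_equal(contactValues(readContactMatrix(f, b2)),
                 matrix(c(1, 2, 2, 1), 2))
})

test_that("triplet reader densifies and mirrors", {
    b <- makeBinning(4)
    f <- withr::local_tempfile()
    writeLines(c("0\t1\t5", "2\t3\t7", "1\t1\t2"), f)
    cm <- readContactTriplets(f, b)
    v <- contactValues(cm)
    expect_equal(v[1, 2], 5); expect_equal(v[2, 1], 5)
    expect_equal(v[3, 4], 7); expect_equal(v[2, 2], 2)
    expect_equal(sum(v), 5 + 5 + 7 + 7 + 2)
    writeLines("5\t0\t1", f)
    expect_error(readContactTriplets(f, b), "out of range")
})

test_that("SCN normalizes a uniform matrix in one step", {
    cm <- makeCM(matrix(1, 2, 2))
    out <- scnNormalize(cm, minCoverageQuantile = 0)
    expect_equal(contactValues(out), matrix(1 / sqrt(2), 2, 2),
                 tolerance = 1e-12)
    expect_true(isNormalized(out))
})

test_that("SCN masks empty bins and keeps them zero and finite", {
    m <- matrix(runif(25, 1, 2), 5); m <- (m + t(m)) / 2
    m[3, ] <- 0; m[, 3] <- 0
    out <- scnNormalize(makeCM(m), minCoverageQuantile = 0)
    expect_true(3L %in% maskedBins(out))
    expect_equal(contactValues(out)[3, ], rep(0, 5))
    expect_true(all(is.finite(contactValues(out))))
})

test_that("SCN equals the step-by-step reference iteration", {
    m <- randSymMatrix(5, seed = 42)
    got <- contactValues(scnNormalize(makeCM(m), minCoverageQuantile = 0))
    expect_equal(got, scnOracle(m), tolerance = 1e-10)
})

test_that("SCN preserves symmetry/nonnegativity and equalizes row norms", {
    for (s in 1:5) {
        m <- randSymMatrix(20, seed = s)
        out <- contactValues(scnNormalize(makeCM(m),
                                          minCoverageQuantile = 0))
        expect_true(all(out >= 0))
        expect_lt(max(abs(out - t(out))), 1e-12)
        rn <- sqrt(rowSums(out^2))
        expect_lt(diff(range(rn)), 1e-6)
    }
    # non-convergence warns but returns
    m <- randSymMatrix(20, seed = 9)
    expect_warning(scnNormalize(makeCM(m), maxIter = 2,
                                minCoverageQuantile = 0), "converge")
})

test_that("distance decay: uniform, ring and diagonal cases", {
    expect_equal(distanceDecay(makeCM(matrix(3, 6, 6)))$meanFrequency,
                 rep(3, 4))
    m <- matrix(0, 4, 4)
    m[1, 2] <- m[2, 3] <- m[3, 4] <- m[4, 1] <- 2
    m <- m + t(m)    # ring of contacts at separation 1
    dec <- distanceDecay(makeCM(m))
    expect_equal(dec$meanFrequency[dec$separation == 1], 2)
    m2 <- diag(c(1, 2, 3, 4))
    expect_equal(distanceDecay(makeCM(m2))$meanFrequency[1], 2.5)
    # matches the double-loop oracle on random input
    m3 <- randSymMatrix(20, seed = 3)
    expect_equal(distanceDecay(makeCM(m3))$meanFrequency, decayOracle(m3),
                 tolerance = 1e-10)
})

test_that("log ratio maps: identity, doubling, pseudocount, antisymmetry", {
    a <- makeCM(randSymMatrix(6, seed = 1, lo = 1, hi = 2), normalized = TRUE)
    expect_equal(logRatioMap(a, a, pseudocount = 0),
                 matrix(0, 6, 6), ignore_attr = TRUE)
    b <- ContactMatrix(contactValues(a) * 2, binning(a), normalized = TRUE)
    expect_equal(logRatioMap(b, a, pseudocount = 0), matrix(1, 6, 6),
                 ignore_attr = TRUE)
    # (0, 3) with pc = 1 -> log2(1/4)
    z <- makeCM(matrix(0, 3, 3), normalized = TRUE)
    t3 <- makeCM(matrix(3, 3, 3), normalized = TRUE)
    expect_equal(logRatioMap(z, t3, pseudocount = 1)[1, 2], -2)
    # antisymmetry under swapping
    c2 <- makeCM(randSymMatrix(6, seed = 2, lo = 1, hi = 3),
                 normalized = TRUE)
    expect_equal(logRatioMap(a, c2), -logRatioMap(c2, a),
                 ignore_attr = TRUE)
    expect_error(logRatioMap(z, t3, pseudocount = 0), "pseudocount")
    expect_error(logRatioMap(a, makeCM(matrix(1, 3, 3), normalized = TRUE)),
                 "binning")
})

test_that("short-range frequency: uniform, flank average, mask", {
    u <- makeCM(matrix(4, 8, 8))
    f <- shortRangeFrequency(u, 2 * 5000)
    expect_equal(unname(f[, 2]), rep(4, 8))
    m <- matrix(0, 6, 6)
    m[3, 4] <- 4; m[4, 3] <- 4; m[3, 2] <- 2; m[2, 3] <- 2
    f2 <- shortRangeFrequency(makeCM(m), 5000)
    expect_equal(unname(f2[3, 2]), 3)          # (4 + 2) / 2
    mm <- ContactMatrix(matrix(1, 6, 6), makeBinning(6), mask = 2L)
    f3 <- shortRangeFrequency(mm, 5000)
    expect_equal(unname(f3[2, ]), c(0, 0))
    expect_error(shortRangeFrequency(u, 1e9), "genomeLength")
    # oracle equivalence
    m4 <- randSymMatrix(20, seed = 8)
    expect_equal(unname(shortRangeFrequency(makeCM(m4), 5 * 5000)),
                 shortFreqOracle(m4, 5), tolerance = 1e-10,
                 ignore_attr = TRUE)
})

test_that("short-range proportion: closed form, full window, oracle", {
    n <- 11; w <- 3
    u <- makeCM(matrix(2, n, n))
    expect_equal(shortRangeProportion(u, w * 5000),
                 rep(2 * w / (n - 1), n))
    expect_equal(shortRangeProportion(u, floor(n / 2) * 5000), rep(1, n))
    m <- randSymMatrix(8, seed = 5)
    expect_equal(shortRangeProportion(makeCM(m), 2 * 5000),
                 proportionOracle(m, 2), tolerance = 1e-12)
    # monotone in window for every bin
    m2 <- randSymMatrix(16, seed = 6)
    props <- sapply(1:8, function(w)
        shortRangeProportion(makeCM(m2), w * 5000))
    expect_true(all(diff(t(props)) >= -1e-12))
    # zero-total bin reported missing
    mz <- matrix(1, 5, 5); mz[2, ] <- 0; mz[, 2] <- 0
    expect_true(is.na(shortRangeProportion(makeCM(mz), 5000)[2]))
})
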