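test_that("XYZ and PDB-like structure readers round-trip", {
    b4 <- makeBinning(4)
    f <- withr::local_tempfile()
    writeLines(c("1 0 0 0", "2 1 0 0", "3 1 1 0", "4 0 1 0"), f)
    s <- readStructure(f, b4)
    expect_equal(coords(s)[2, ], c(1, 0, 0))
    # plain x y z, no index column
    writeLines(c("0 0 0", "1 0 0", "1 1 0", "0 1 0"), f)
    expect_equal(coords(readStructure(f, b4))[3, ], c(1, 1, 0))
    # count mismatch
    expect_error(readStructure(f, makeBinning(10)), "expects 10")

    # PDB-like CA trace
    pdb <- withr::local_tempfile(fileext = ".pdb")
    lines <- sapply(1:4, function(i) sprintf(
        "ATOM  %5d  CA  ALA A%4d    %8.3f%8.3f%8.3f  1.00  0.00           C",
        i, i, i * 1.5, 0, 0))
    writeLines(c(lines, "END"), pdb)
    sp <- readStructure(pdb, b4)
    expect_equal(coords(sp)[, 1], c(1.5, 3, 4.5, 6))

    # writer round-trip
    out <- withr::local_tempfile()
    writeStructureXyz(s, out)
    expect_equal(coords(readStructure(out, b4)), coords(s))
})

test_that("pairwise distance distribution matches geometry and oracle", {
    b2 <- makeBinning(2)
    two <- Structure3D(rbind(c(0, 0, 0), c(5, 0, 0)), b2)
    dd <- pairwiseDistanceDistribution(two, 5)
    expect_equal(sum(dd$counts), 1)
    expect_equal(dd$distances, 5)
    # square inscribed in the unit circle: chords sqrt(2) x4 and 2 x2
    th <- 2 * pi * (0:3) / 4
    sq <- Structure3D(cbind(cos(th), sin(th), 0), makeBinning(4))
    ds <- sort(pairwiseDistanceDistribution(sq, 3)$distances)
    expect_equal(ds, c(rep(sqrt(2), 4), 2, 2))
    # counts sum to n(n-1)/2 and match dist() on a random cloud
    r <- Structure3D(randStructure(30, 2), makeBinning(30))
    dr <- pairwiseDistanceDistribution(r, 12)
    expect_equal(sum(dr$counts), 30 * 29 / 2)
    expect_equal(sort(dr$distances),
                 sort(as.vector(dist(randStructure(30, 2)))))
})

test_that("macrodomain distance classes equal brute force", {
    bn <- makeBinning(9)
    xyz <- rbind(c(0, 0, 0), c(1, 0, 0), c(2, 0, 0),
                 c(0, 3, 0), c(1, 3, 0), c(2, 3, 0),
                 c(0, 0, 4), c(1, 0, 4), c(2, 0, 4))
    s <- Structure3D(xyz, bn)
    dom <- data.frame(name = c("A", "B", "C"),
                      start = c(1, 15001, 30001),
                      end = c(15000, 30000, 45000))
    md <- macrodomainDistances(s, dom)
    getm <- function(a, b)
        md$meanDistance[md$domainA == a & md$domainB == b]
    # brute force over the explicit members
    bf <- function(ia, ib) {
        acc <- c()
        for (i in ia) for (j in ib)
            acc <- c(acc, sqrt(sum((xyz[i, ] - xyz[j, ])^2)))
        mean(acc)
    }
    expect_equal(getm("A", "B"), bf(1:3, 4:6), tolerance = 1e-10)
    expect_equal(getm("A", "C"), bf(1:3, 7:9), tolerance = 1e-10)
    intra <- c(sqrt(sum((xyz[1, ] - xyz[2, ])^2)),
               sqrt(sum((xyz[1, ] - xyz[3, ])^2)),
               sqrt(sum((xyz[2, ] - xyz[3, ])^2)))
    expect_equal(getm("A", "A"), mean(intra), tolerance = 1e-10)

    # single-bin domains: inter-domain distance, intra missing
    bn2 <- makeBinning(2)
    s2 <- Structure3D(rbind(c(0, 0, 0), c(3, 0, 0)), bn2)
    dom2 <- data.frame(name = c("O", "T"), start = c(1, 5001),
                       end = c(5000, 10000))
    md2 <- macrodomainDistances(s2, dom2)
    expect_equal(md2$meanDistance[md2$domainA == "O" & md2$domainB == "T"], 3)
    expect_true(is.na(md2$meanDistance[md2$domainA == "O" &
                                       md2$domainB == "O"]))
    # empty domain errors
    dom3 <- data.frame(name = "far", start = 10 * 5000 + 1,
                       end = 11 * 5000)
    expect_error(macrodomainDistances(s, dom3), "no bins")
})

test_that("distance summaries are invariant under rigid motion", {
    s <- Structure3D(randStructure(25, 7), makeBinning(25))
    st <- Structure3D(rigidTransform(coords(s), seed = 8), makeBinning(25))
    d1 <- pairwiseDistanceDistribution(s, 10)
    d2 <- pairwiseDistanceDistribution(st, 10)
    expect_equal(sort(d1$distances), sort(d2$distances), tolerance = 1e-9)
})

test_that("embedding recovers an exact Euclidean configuration", {
    skip_if_not_installed("vegan")
    n <- 40
    th <- 2 * pi * (0:(n - 1)) / n
    ring <- cbind(cos(th), sin(th), 0)
    D <- as.matrix(dist(ring))
    M <- 1 / (D + diag(1e9, n))
    diag(M) <- max(M[upper.tri(M)])
    cm <- makeCM(M, normalized = TRUE)
    emb <- fallbackEmbedding(cm, alpha = 1, seed = 1)
    pr <- vegan::procrustes(ring, coords(emb), symmetric = FALSE)
    expect_lt(sqrt(mean(residuals(pr)^2)), 1e-6)
})

test_that("embedding round-trip preserves compactness approximately", {
    cfg <- syntheticConfig(nBins = 100, foldRegions = list(
        list(start = 20, end = 50, amplitude = 3, period = 8)))
    s0 <- genStructure(cfg)
    D <- as.matrix(dist(coords(s0)))
    M <- 1 / (D + diag(1e9, 100))
    diag(M) <- max(M[upper.tri(M)])
    emb <- fallbackEmbedding(makeCM(M, normalized = TRUE))
    expect_lt(abs(globalCompactness(emb) - globalCompactness(s0)), 0.2)
})

test_that("degenerate matrices cannot be embedded", {
    expect_error(fallbackEmbedding(makeCM(matrix(1, 10, 10),
                                          normalized = TRUE)),
                 "degenerate")
})

test_that("macrodomain BED example loads", {
    bed <- system.file("extdata", "macrodomains_example.bed",
                       package = "nucleoid3d")
    dom <- readMacrodomains(bed)
    expect_true(all(c("Ori", "Ter", "Left", "Right") %in% names(dom)))
    # non-overlapping
    expect_equal(sum(IRanges::width(IRanges::reduce(IRanges::ranges(dom)))),
                 sum(IRanges::width(IRanges::ranges(dom))))
})
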