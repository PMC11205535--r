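## Synthetic data with planted ground truth.
##
## Every generator is deterministic given its seed and mirrors one
## structural feature of real bacterial 3C data: power-law distance decay
## on a circular genome, planted CID blocks, Ter-specific long-range
## insulation, locally folded 3D regions, transcription coupled to
## near-diagonal contact frequency, and rod-shaped nucleoid images.

#' Configuration for the synthetic generators
#'
#' Defaults mirror the real study system: a 4.64 Mb circular genome at
#' 5 kb resolution (928 bins), a power-law contact decay with exponent 1,
#' and a base contact level of 100 counts at one-bin separation (so the
#' Poisson mode produces moderate, realistic counting noise).
#'
#' @param nBins number of bins (default 928).
#' @param binSize bin size in bp (default 5000).
#' @param decayExponent power-law decay exponent `gamma > 0` (default 1).
#' @param baseLevel expected contacts at one-bin separation (default 100).
#' @param domainBoundaries integer bin indices (1-based, sorted) where
#'   planted CIDs start; empty for no domains.
#' @param domainBoost within-domain contact multiplier `>= 1` (default 1).
#' @param terInterval `c(startBin, endBin)` of a Ter-like insulated
#'   interval, or `NULL`.
#' @param terInsulation factor (`>= 1`) dividing contacts between Ter and
#'   non-Ter bins beyond `terRangeBins` (default 1 = off).
#' @param terRangeBins separation (bins) beyond which Ter insulation
#'   applies (default 20 = 100 kb).
#' @param noise `"none"` or `"poisson"`.
#' @param foldRegions list of `list(start=, end=, amplitude=, period=)`
#'   bin intervals to fold in the synthetic structure (non-overlapping).
#' @param rho planted structure-expression correlation, `|rho| < 1`.
#' @param seed integer seed.
#' @return a validated config (list of class `SyntheticConfig`).
#' @export
syntheticConfig <- function(nBins = 928, binSize = 5000, decayExponent = 1,
                            baseLevel = 100, domainBoundaries = integer(0),
                            domainBoost = 1, terInterval = NULL,
                            terInsulation = 1, terRangeBins = 20,
                            noise = c("none", "poisson"),
                            foldRegions = list(), rho = 0, seed = 1L) {
    noise <- match.arg(noise)
    domainBoundaries <- as.integer(domainBoundaries)
    stopifnot(nBins >= 4, binSize > 0, decayExponent > 0, baseLevel > 0,
              domainBoost >= 1, terInsulation >= 1, terRangeBins >= 0,
              abs(rho) < 1)
    if (length(domainBoundaries)) {
        if (is.unsorted(domainBoundaries, strictly = TRUE))
            stop("domainBoundaries must be strictly increasing", call. = FALSE)
        if (any(domainBoundaries < 1L) || any(domainBoundaries > nBins))
            stop("domainBoundaries out of [1, nBins]", call. = FALSE)
    }
    if (!is.null(terInterval)) {
        stopifnot(length(terInterval) == 2, terInterval[1] <= terInterval[2],
                  terInterval[1] >= 1, terInterval[2] <= nBins)
    }
    for (fr in foldRegions) {
        stopifnot(!is.null(fr$start), !is.null(fr$end),
                  !is.null(fr$amplitude), fr$amplitude >= 0,
                  fr$start >= 1, fr$end <= nBins, fr$start <= fr$end)
    }
    if (length(foldRegions) > 1) {
        iv <- do.call(rbind, lapply(foldRegions, function(f)
            c(f$start, f$end)))
        iv <- iv[order(iv[, 1]), , drop = FALSE]
        if (any(iv[-1, 1] <= iv[-nrow(iv), 2]))
            stop("overlapping fold regions", call. = FALSE)
    }
    structure(list(nBins = as.integer(nBins), binSize = binSize,
                   decayExponent = decayExponent, baseLevel = baseLevel,
                   domainBoundaries = domainBoundaries,
                   domainBoost = domainBoost, terInterval = terInterval,
                   terInsulation = terInsulation,
                   terRangeBins = as.integer(terRangeBins), noise = noise,
                   foldRegions = foldRegions, rho = rho,
                   seed = as.integer(seed)),
              class = "SyntheticConfig")
}

# expected (noiseless) synthetic contact matrix
.expectedContacts <- function(cfg) {
    n <- cfg$nBins
    idx <- seq_len(n)
    cd <- circularBinDistance(matrix(idx, n, n),
                              matrix(idx, n, n, byrow = TRUE), n)
    E <- cfg$baseLevel * ifelse(cd == 0, 1, cd)^(-cfg$decayExponent)
    if (length(cfg$domainBoundaries) >= 1) {
        # domain of bin i: index of the last boundary at or before i,
        # wrapping so bins before the first boundary join the last domain
        dom <- findInterval(idx, cfg$domainBoundaries)
        dom[dom == 0L] <- length(cfg$domainBoundaries)
        same <- outer(dom, dom, "==")
        E[same] <- E[same] * cfg$domainBoost
    }
    if (!is.null(cfg$terInterval) && cfg$terInsulation > 1) {
        inTer <- idx >= cfg$terInterval[1] & idx <= cfg$terInterval[2]
        cross <- xor(matrix(inTer, n, n), matrix(inTer, n, n, byrow = TRUE))
        far <- cd > cfg$terRangeBins
        E[cross & far] <- E[cross & far] / cfg$terInsulation
    }
    E
}

#' Generate a synthetic contact matrix
#'
#' Noiseless expectation: `E[M_ij] = base * circdist(i,j)^(-gamma)` for
#' `i != j` (diagonal set to `base`), multiplied by `domainBoost` when `i`
#' and `j` lie in the same planted domain, and divided by `terInsulation`
#' when exactly one of them is in the Ter interval and their separation
#' exceeds `terRangeBins`.  With `noise = "poisson"` every unordered pair
#' is an independent Poisson draw with that expectation (then mirrored).
#'
#' @param cfg a [syntheticConfig()].
#' @return a raw [ContactMatrix]; the planted truth is in `cfg`.
#' @export
genContactMatrix <- function(cfg) {
    stopifnot(inherits(cfg, "SyntheticConfig"))
    E <- .expectedContacts(cfg)
    n <- cfg$nBins
    if (cfg$noise == "poisson") {
        set.seed(cfg$seed)
        up <- upper.tri(E, diag = TRUE)
        E[up] <- rpois(sum(up), E[up])
        E[lower.tri(E)] <- t(E)[lower.tri(E)]
    }
    ContactMatrix(E, GenomeBinning(n * cfg$binSize, cfg$binSize))
}

#' Generate a synthetic 3D structure
#'
#' A ring of `nBins` equally spaced points (the relaxed circular
#' chromosome) with optional planted folds: within each fold region the
#' radius is modulated by a sinusoid of the given amplitude and period
#' (with a smooth envelope so the backbone stays continuous), producing a
#' locally compacted zigzag.  The whole structure is rescaled so its
#' closed backbone contour keeps the unperturbed length.  With no folds
#' the output is a perfect circle (GC = 0).
#'
#' @param cfg a [syntheticConfig()]; `foldRegions` plants the folds.
#' @return a [Structure3D] labelled `"synthetic"`.
#' @export
genStructure <- function(cfg) {
    stopifnot(inherits(cfg, "SyntheticConfig"))
    n <- cfg$nBins
    R0 <- n / (2 * pi)          # unit backbone segment on the base ring
    theta <- 2 * pi * (seq_len(n) - 1) / n
    r <- rep(R0, n)
    for (fr in cfg$foldRegions) {
        k <- fr$start:fr$end
        m <- length(k)
        if (m < 3) next
        period <- if (is.null(fr$period)) 8 else fr$period
        t01 <- (seq_len(m) - 1) / (m - 1)
        env <- sin(pi * t01)
        r[k] <- r[k] + fr$amplitude * env * sin(2 * pi * (seq_len(m) - 1) /
                                                period)
    }
    xyz <- cbind(r * cos(theta), r * sin(theta), 0)
    L0 <- n * 2 * R0 * sin(pi / n)
    L1 <- sum(.segmentLengths(xyz, close = TRUE))
    xyz <- xyz * (L0 / L1)
    Structure3D(xyz, GenomeBinning(n * cfg$binSize, cfg$binSize),
                label = "synthetic")
}

#' Generate a transcription track with planted structure correlation
#'
#' The per-bin track is `rho * z + sqrt(1 - rho^2) * noise`, where `z` is
#' the Z-score of the matrix's near-diagonal contact frequency (10 kb
#' band) and the noise is standard normal, then shifted/scaled into a
#' plausible log2-expression range (mean 5, SD 2).  The empirical Pearson
#' correlation with the contact band is `rho` up to sampling error.
#'
#' @param M a [ContactMatrix].
#' @param rho planted correlation, `|rho| < 1`.
#' @param seed integer seed.
#' @return a [TranscriptionTrack] labelled `"synthetic"`.
#' @export
genTranscription <- function(M, rho, seed = 1L) {
    stopifnot(abs(rho) < 1)
    band <- diagBandFrequency(M, halfWidth = 2 * binSize(M))
    if (sd(band) == 0) {
        if (rho != 0)
            stop("contact matrix has no near-diagonal variation; ",
                 "cannot plant a correlation", call. = FALSE)
        z <- numeric(nBins(M))
    } else z <- zscoreTrack(band)
    set.seed(as.integer(seed))
    e <- rnorm(nBins(M))
    mix <- rho * z + sqrt(1 - rho^2) * e
    level <- 5 + 2 * mix
    new("TranscriptionTrack", binning = binning(M), level = level,
        zscore = zscoreTrack(level), source = "synthetic")
}

#' Generate a synthetic nucleoid field image
#'
#' Places `nCells` non-overlapping bright rods (rotated rectangles) on a
#' dark background and records each rod's true centre, length, width and
#' angle.  Dimensions are drawn from normal distributions truncated at 4
#' pixels; placement is rejection-sampled, erroring when the field cannot
#' host the requested number of cells.
#'
#' @param nCells number of rods.
#' @param lengthDist `c(mean, sd)` of rod length in pixels (default
#'   c(50, 5)).
#' @param widthDist `c(mean, sd)` of rod width in pixels (default c(20, 2)).
#' @param fieldSize `c(rows, cols)` of the image (default c(512, 512)).
#' @param seed integer seed.
#' @return a list with `image` (numeric matrix, background 0, rods 1) and
#'   `truth` (`data.frame`: `cell`, `cx`, `cy`, `length`, `width`,
#'   `angle`).
#' @export
genImages <- function(nCells, lengthDist = c(50, 5), widthDist = c(20, 2),
                      fieldSize = c(512, 512), seed = 1L) {
    stopifnot(nCells >= 0, lengthDist[1] > 0, widthDist[1] > 0)
    set.seed(as.integer(seed))
    img <- matrix(0, fieldSize[1], fieldSize[2])
    truth <- data.frame(cell = integer(0), cx = numeric(0), cy = numeric(0),
                        length = numeric(0), width = numeric(0),
                        angle = numeric(0))
    if (nCells == 0) return(list(image = img, truth = truth))
    placed <- matrix(numeric(0), ncol = 3)   # cx, cy, clearance radius
    tries <- 0L
    maxTries <- 500L * nCells
    for (cell in seq_len(nCells)) {
        repeat {
            tries <- tries + 1L
            if (tries > maxTries)
                stop("field too small to place all cells", call. = FALSE)
            len <- max(4, rnorm(1, lengthDist[1], lengthDist[2]))
            wid <- max(4, rnorm(1, widthDist[1], widthDist[2]))
            if (wid > len) { tmp <- len; len <- wid; wid <- tmp }
            ang <- runif(1, 0, pi)
            half <- len / 2 + 2
            if (fieldSize[1] <= 2 * half || fieldSize[2] <= 2 * half)
                stop("field too small to place all cells", call. = FALSE)
            cx <- runif(1, half, fieldSize[2] - half)
            cy <- runif(1, half, fieldSize[1] - half)
            if (nrow(placed)) {
                dd <- sqrt((placed[, 1] - cx)^2 + (placed[, 2] - cy)^2)
                if (any(dd < placed[, 3] + half)) next
            }
            break
        }
        placed <- rbind(placed, c(cx, cy, half))
        # rasterise: pixel lit when its centre falls inside the rod
        x0 <- max(1L, floor(cx - half)); x1 <- min(fieldSize[2], ceiling(cx + half))
        y0 <- max(1L, floor(cy - half)); y1 <- min(fieldSize[1], ceiling(cy + half))
        xs <- x0:x1; ys <- y0:y1
        dx <- outer(rep(1, length(ys)), xs - cx)
        dy <- outer(ys - cy, rep(1, length(xs)))
        lon <- dx * cos(ang) + dy * sin(ang)
        lat <- -dx * sin(ang) + dy * cos(ang)
        inside <- abs(lon) < len / 2 & abs(lat) < wid / 2
        img[ys, xs][inside] <- 1
        truth <- rbind(truth, data.frame(cell = cell, cx = cx, cy = cy,
                                         length = len, width = wid,
                                         angle = ang))
    }
    list(image = img, truth = truth)
}
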