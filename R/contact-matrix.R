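## Reading, balancing and summarising contact matrices.

#' Read a dense contact matrix from a whitespace/tab-delimited file
#'
#' Accepts a plain `n x n` numeric table, optionally preceded by a header
#' row and/or a leading column of bin start coordinates (both detected and
#' dropped).  Slightly asymmetric input is symmetrised as `(M + t(M))/2`
#' with a warning; this is the usual state of raw 3C matrices after
#' independent row-wise processing.
#'
#' @param path file path.
#' @param binning a [GenomeBinning]; the table must have one row per bin.
#' @return a raw [ContactMatrix].
#' @seealso [readContactTriplets()] for sparse triplet input.
#' @export
readContactMatrix <- function(path, binning) {
    first <- readLines(path, n = 1L)
    tokens <- strsplit(trimws(first), "[ \t,]+")[[1]]
    hasHeader <- any(is.na(suppressWarnings(as.numeric(tokens))))
    tab <- read.table(path, header = hasHeader, sep = "",
                      check.names = FALSE)
    m <- as.matrix(tab)
    if (!is.numeric(m)) {
        # a leading character column (row names of bin starts)
        if (ncol(m) >= 2 && all(!is.na(suppressWarnings(
                as.numeric(m[, -1]))))) {
            m <- matrix(as.numeric(m[, -1]), nrow = nrow(m))
        } else stop("non-numeric entries in contact matrix file", call. = FALSE)
    }
    if (ncol(m) == nrow(m) + 1L) {
        # leading coordinate column
        if (!is.unsorted(m[, 1])) m <- m[, -1, drop = FALSE]
    }
    if (nrow(m) != ncol(m))
        stop(sprintf("contact matrix must be square; got %d x %d",
                     nrow(m), ncol(m)), call. = FALSE)
    if (any(!is.finite(m)))
        stop("contact matrix contains non-finite values", call. = FALSE)
    if (any(m < 0))
        stop("contact matrix contains negative values", call. = FALSE)
    if (nrow(m) != binning@nBins)
        stop(sprintf("matrix has %d bins but binning expects %d",
                     nrow(m), binning@nBins), call. = FALSE)
    if (max(abs(m - t(m))) > 1e-9) {
        warning("asymmetric input symmetrized as (M + t(M))/2")
        m <- (m + t(m)) / 2
    }
    dimnames(m) <- NULL
    ContactMatrix(m, binning)
}

#' Read a sparse (triplet) contact matrix
#'
#' Cooler-style three-column input: `bin1 bin2 count`, one contact pair per
#' line, densified into a symmetric matrix.
#'
#' @param path file path to a 3-column table.
#' @param binning a [GenomeBinning].
#' @param zeroBased logical; whether bin indices in the file are 0-based
#'   (the cooler convention, default) or 1-based.
#' @return a raw [ContactMatrix].
#' @export
readContactTriplets <- function(path, binning, zeroBased = TRUE) {
    tab <- read.table(path, header = FALSE, sep = "")
    if (ncol(tab) < 3)
        stop("triplet file must have 3 columns: bin1 bin2 count", call. = FALSE)
    n <- binning@nBins
    i <- as.integer(tab[[1]]) + if (zeroBased) 1L else 0L
    j <- as.integer(tab[[2]]) + if (zeroBased) 1L else 0L
    x <- as.numeric(tab[[3]])
    if (any(i < 1L | i > n | j < 1L | j > n))
        stop("triplet bin index out of range", call. = FALSE)
    if (any(x < 0)) stop("negative contact counts", call. = FALSE)
    m <- matrix(0, n, n)
    m[cbind(i, j)] <- x
    m[cbind(j, i)] <- x
    ContactMatrix(m, binning)
}

#' SCN normalisation (sequential component normalisation)
#'
#' Iterative balancing of a raw contact matrix: each unmasked row is divided
#' by its Euclidean (L2) norm, then each column, until the largest relative
#' change of any entry falls below `tol`.  A final symmetrisation
#' `(M + t(M))/2` is applied.  Low-coverage bins (row sum below the
#' `minCoverageQuantile` quantile of row sums, or zero) are masked before
#' balancing and stay all-zero.
#'
#' @param M a raw [ContactMatrix].
#' @param tol convergence tolerance on the max relative entry change
#'   (default `1e-6`).
#' @param maxIter maximum number of row+column sweeps (default 200); hitting
#'   it raises a warning, not an error.
#' @param minCoverageQuantile quantile of row sums below which a bin is
#'   masked (default 0.01).
#' @return a normalised [ContactMatrix] with unmasked row L2 norms equal up
#'   to `tol`.
#' @examples
#' b <- GenomeBinning(10 * 5000, 5000)
#' M <- ContactMatrix(matrix(1, 10, 10), b)
#' scnNormalize(M)
#' @export
scnNormalize <- function(M, tol = 1e-6, maxIter = 200,
                         minCoverageQuantile = 0.01) {
    v <- contactValues(M)
    n <- nrow(v)
    rs <- rowSums(v)
    cut <- quantile(rs, minCoverageQuantile)
    mask <- sort(unique(c(maskedBins(M), which(rs < cut | rs == 0))))
    keep <- setdiff(seq_len(n), mask)
    if (!length(keep))
        stop("all bins masked; cannot normalize an empty matrix", call. = FALSE)
    v[mask, ] <- 0
    v[, mask] <- 0
    w <- v[keep, keep, drop = FALSE]
    converged <- FALSE
    for (it in seq_len(maxIter)) {
        rn <- sqrt(rowSums(w^2))
        rn[rn == 0] <- 1
        w <- w / rn
        cn <- sqrt(colSums(w^2))
        cn[cn == 0] <- 1
        w <- t.default(t.default(w) * (1 / cn))
        # every entry changed by the factor 1/(rn_i * cn_j), so the max
        # relative entry change is attained at the extremes of rn and cn
        f <- 1 / c(min(rn) * min(cn), min(rn) * max(cn),
                   max(rn) * min(cn), max(rn) * max(cn))
        if (max(abs(f - 1)) < tol) { converged <- TRUE; break }
    }
    if (!converged)
        warning(sprintf("SCN did not converge in %d iterations", maxIter))
    w <- (w + t(w)) / 2
    out <- matrix(0, n, n)
    out[keep, keep] <- w
    ContactMatrix(out, binning(M), mask = mask, normalized = TRUE)
}

#' Mean contact frequency by genomic separation (distance decay)
#'
#' For each circular bin separation `s = 0 .. floor(n/2)`, the mean over
#' unmasked bins `i` of `M[i, i + s]` (indices wrapping).  On a log-log
#' plot this is the classic contact-probability decay curve.
#'
#' @param M a [ContactMatrix].
#' @return a `data.frame` with columns `separation` (bins),
#'   `distance` (bp) and `meanFrequency`.
#' @export
distanceDecay <- function(M) {
    v <- contactValues(M)
    n <- nrow(v)
    keep <- setdiff(seq_len(n), maskedBins(M))
    if (!length(keep)) stop("all bins masked", call. = FALSE)
    smax <- floor(n / 2)
    mf <- vapply(0:smax, function(s) {
        j <- .wrap(keep + s, n)
        mean(v[cbind(keep, j)])
    }, numeric(1))
    data.frame(separation = 0:smax, distance = (0:smax) * binSize(M),
               meanFrequency = mf)
}

#' Log2 ratio map between two conditions
#'
#' Element-wise `log2((A + pc) / (B + pc))` between two normalised contact
#' matrices on the same binning, the standard display for condition
#' comparisons (red = enriched in `a`, blue = depleted).  The union of the
#' two masks is applied and masked entries are set to 0.
#'
#' @param a,b normalised [ContactMatrix] objects on the same binning.
#' @param pseudocount positive stabiliser added to both matrices; defaults
#'   to the smallest positive entry across the pair.  A zero pseudocount is
#'   only accepted when neither matrix has zero entries.
#' @return a plain symmetric `n x n` numeric matrix of log2 ratios, with
#'   attributes `pseudocount` and `mask`.
#' @export
logRatioMap <- function(a, b, pseudocount = NULL) {
    .checkSameBinning(a, b)
    va <- contactValues(a); vb <- contactValues(b)
    mask <- sort(union(maskedBins(a), maskedBins(b)))
    keep <- setdiff(seq_len(nrow(va)), mask)
    if (is.null(pseudocount)) {
        pos <- c(va[va > 0], vb[vb > 0])
        if (!length(pos)) stop("both matrices are all-zero", call. = FALSE)
        pseudocount <- min(pos)
    }
    if (pseudocount < 0) stop("pseudocount must be >= 0", call. = FALSE)
    if (pseudocount == 0 &&
        (any(va[keep, keep] == 0) || any(vb[keep, keep] == 0)))
        stop("zero entries present: pseudocount must be > 0", call. = FALSE)
    r <- matrix(0, nrow(va), ncol(va))
    r[keep, keep] <- log2((va[keep, keep] + pseudocount) /
                          (vb[keep, keep] + pseudocount))
    structure(r, pseudocount = pseudocount, mask = mask)
}

#' Short-range interaction frequency profile
#'
#' Average number of contacts between each target bin and its two flanks at
#' every separation `d` up to `maxDistance`:
#' `freq[i, d] = (M[i, i+d] + M[i, i-d]) / 2` (circular indices), with the
#' `d = 0` column holding the diagonal.  Rows of masked bins are zero.
#'
#' @param M a [ContactMatrix].
#' @param maxDistance window in base pairs (default 1 Mb); must not exceed
#'   half the genome length.
#' @return numeric `n x (maxd+1)` matrix, columns named by separation in
#'   bp, with attribute `window`.
#' @export
shortRangeFrequency <- function(M, maxDistance = 1e6) {
    if (maxDistance > genomeLength(M) / 2)
        stop("maxDistance must be <= genomeLength/2", call. = FALSE)
    v <- contactValues(M)
    n <- nrow(v)
    maxd <- as.integer(floor(maxDistance / binSize(M)))
    i <- seq_len(n)
    f <- vapply(0:maxd, function(d) {
        (v[cbind(i, .wrap(i + d, n))] + v[cbind(i, .wrap(i - d, n))]) / 2
    }, numeric(n))
    f <- matrix(f, nrow = n)
    colnames(f) <- (0:maxd) * binSize(M)
    structure(f, window = maxDistance)
}

#' Short-range interaction proportion per bin
#'
#' Fraction of each bin's total contacts that fall within `window` base
#' pairs of it: `sum over j with circdist(i,j) <= w of M[i,j]` divided by
#' the bin's total off-diagonal contacts.  Self-contacts are excluded from
#' both sums.  Bins with zero total (incl. masked bins) return `NA`.
#'
#' @param M a [ContactMatrix].
#' @param window window half-width in base pairs; must be
#'   `<= genomeLength/2`.
#' @return numeric vector of proportions in `[0, 1]` (NA where undefined).
#' @examples
#' b <- GenomeBinning(10 * 5000, 5000)
#' M <- ContactMatrix(matrix(1, 10, 10), b)
#' shortRangeProportion(M, 2 * 5000)   # uniform: 2w/(n-1)
#' @export
shortRangeProportion <- function(M, window) {
    if (window > genomeLength(M) / 2)
        stop("window must be <= genomeLength/2", call. = FALSE)
    v <- contactValues(M)
    n <- nrow(v)
    w <- as.integer(floor(window / binSize(M)))
    idx <- seq_len(n)
    cd <- circularBinDistance(matrix(idx, n, n), matrix(idx, n, n, byrow = TRUE),
                              n, isCircular(M))
    near <- cd <= w & cd > 0
    num <- rowSums(v * near)
    den <- rowSums(v) - diag(v)
    p <- ifelse(den > 0, num / den, NA_real_)
    p[maskedBins(M)] <- NA_real_
    p
}
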