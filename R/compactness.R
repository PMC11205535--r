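## Global and Local Compactness of 3D chromosome models.
##
## Both metrics compare the summed pairwise Euclidean distances D(i,j) of a
## model against the summed distances d(i,j) of an "unfolded" reference of
## identical backbone contour: a circle for the whole chromosome (GC), a
## straight line for a local window (LC).  GC = -log2(sum D / sum d); the
## metrics are dimensionless, invariant under rigid motion and uniform
## scaling, and anchored at 0 for a perfect circle / straight segment.

# consecutive backbone segment lengths of the (ordered) points, closing the
# ring when close = TRUE
.segmentLengths <- function(xyz, close = TRUE) {
    n <- nrow(xyz)
    nxt <- if (close) c(2:n, 1L) else 2:n
    cur <- if (close) 1:n else 1:(n - 1L)
    sqrt(rowSums((xyz[nxt, , drop = FALSE] - xyz[cur, , drop = FALSE])^2))
}

# Reference circle for GC: points placed on a circle so that consecutive
# chord lengths equal the backbone segment lengths (radius solved by
# root-finding on the inscribed-polygon closure condition).  Returns the
# angular positions and the radius.
.circleReference <- function(seg) {
    L <- sum(seg)
    if (L <= 0) stop("zero backbone contour: all points coincide",
                     call. = FALSE)
    seg <- seg[seg >= 0]
    rlo <- max(seg) / 2
    f <- function(R) sum(2 * asin(pmin(1, seg / (2 * R)))) - 2 * pi
    if (f(rlo * (1 + 1e-12)) < 0)
        stop("degenerate backbone: one segment spans half the contour",
             call. = FALSE)
    R <- uniroot(f, c(rlo * (1 + 1e-12), L), tol = 1e-13 * L,
                 maxiter = 1000)$root
    theta <- c(0, cumsum(2 * asin(pmin(1, seg / (2 * R)))))[seq_along(seg)]
    list(theta = theta, radius = R)
}

#' Global Compactness (GC) of a 3D chromosome model
#'
#' `GC = -log2( sum_{i != j} D(i,j) / sum_{i != j} d(i,j) )`, where `D` is
#' the Euclidean distance in the model and `d` the chord distance between
#' the same bins placed on a reference circle whose consecutive chord
#' lengths equal the model's backbone segment lengths (closing segment
#' included).  A perfectly circular model scores 0; the more the chromosome
#' is folded in on itself, the larger the GC.  Rigid motions and uniform
#' scaling leave GC unchanged.
#'
#' @param s a [Structure3D] with at least 3 present bins on a circular
#'   binning.
#' @return scalar GC value.
#' @examples
#' b <- GenomeBinning(100 * 5000, 5000)
#' th <- 2 * pi * (0:99) / 100
#' ring <- Structure3D(cbind(cos(th), sin(th), 0), b)
#' globalCompactness(ring)   # 0 up to numerical tolerance
#' @export
globalCompactness <- function(s) {
    pres <- .presentBins(s)
    if (length(pres) < 3) stop("need at least 3 points", call. = FALSE)
    xyz <- coords(s)[pres, , drop = FALSE]
    seg <- .segmentLengths(xyz, close = TRUE)
    ref <- .circleReference(seg)
    sumD <- sum(dist(xyz))
    dtheta <- abs(outer(ref$theta, ref$theta, "-"))
    chord <- 2 * ref$radius * sin(dtheta / 2)
    sumd <- sum(chord[upper.tri(chord)])
    -log2(sumD / sumd)
}

#' Local Compactness (LC) per bin
#'
#' For each bin `i`, the model distances `D(i,j)` to the bins `j` within
#' `thr` base pairs up- and downstream are compared with the distances
#' `d(i,j)` between the same bins laid out on a straight line whose
#' consecutive spacings equal the model's backbone segment lengths in that
#' window: `LC_i = -log2( sum_j D(i,j) / sum_j d(i,j) )`.  A straight,
#' evenly traversed window scores 0; local folding (hairpins, loops) makes
#' `D < d` and pushes LC up.  Windows wrap around a circular genome; on a
#' linear binning they are truncated at the ends.
#'
#' @param s a [Structure3D].
#' @param thr local-range threshold in base pairs; `thr/binSize` must be
#'   `>= 1` and `< nBins/2`.
#' @return numeric vector of per-bin LC values (NA for bins without
#'   coordinates).
#' @export
localCompactness <- function(s, thr) {
    bn <- binning(s)
    n <- bn@nBins
    t <- as.integer(floor(thr / bn@binSize))
    if (t < 1L) stop("thr must cover at least one bin", call. = FALSE)
    if (t >= n / 2) stop("thr must be < half the genome", call. = FALSE)
    xyz <- coords(s)
    present <- stats::complete.cases(xyz)
    lc <- rep(NA_real_, n)
    for (i in which(present)) {
        win <- if (bn@circular) .wrap((i - t):(i + t), n)
               else (max(1L, i - t)):(min(n, i + t))
        win <- win[present[win]]
        if (length(win) < 2) next
        pts <- xyz[win, , drop = FALSE]
        seg <- .segmentLengths(pts, close = FALSE)
        pos <- c(0, cumsum(seg))
        self <- which(win == i)
        D <- sqrt(rowSums((pts - matrix(xyz[i, ], nrow(pts), 3,
                                        byrow = TRUE))^2))
        d <- abs(pos - pos[self])
        sumd <- sum(d[-self])
        if (sumd <= 0) next
        lc[i] <- -log2(sum(D[-self]) / sumd)
    }
    lc
}

#' Multiscale Local Compactness profile
#'
#' LC computed at a series of genomic scales (thresholds), returned as a
#' bins-by-scales matrix ready for heat-map display, together with the
#' model's GC.
#'
#' @param s a [Structure3D].
#' @param scales vector of thresholds in base pairs (sorted ascending in
#'   the output regardless of input order).
#' @return a [CompactnessProfile].
#' @export
lcMultiscale <- function(s, scales) {
    if (!length(scales)) stop("empty scale list", call. = FALSE)
    scales <- sort(unique(as.numeric(scales)))
    lc <- vapply(scales, function(th) localCompactness(s, th),
                 numeric(nBins(s)))
    lc <- matrix(lc, nrow = nBins(s),
                 dimnames = list(NULL, format(scales, scientific = FALSE,
                                              trim = TRUE)))
    new("CompactnessProfile", binning = binning(s),
        gc = globalCompactness(s), lc = lc, scales = scales)
}

#' Log2 ratio of LC between two conditions
#'
#' Element-wise `log2(LC_a / LC_b)` across bins and scales, the display
#' used to compare local compaction between conditions.  Entries where
#' either LC is missing or non-positive are `NA` (the log ratio is
#' undefined there).
#'
#' @param a,b [CompactnessProfile] objects on the same binning and scales.
#' @return numeric bins-by-scales matrix.
#' @export
lcLogRatio <- function(a, b) {
    .checkSameBinning(a, b)
    if (length(lcScales(a)) != length(lcScales(b)) ||
        any(lcScales(a) != lcScales(b)))
        stop("scale mismatch between compactness profiles", call. = FALSE)
    la <- lcValues(a); lb <- lcValues(b)
    r <- suppressWarnings(log2(la / lb))
    r[!is.na(la) & !is.na(lb) & (la <= 0 | lb <= 0)] <- NA_real_
    r[is.na(la) | is.na(lb)] <- NA_real_
    r
}
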