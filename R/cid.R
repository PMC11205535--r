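## Directionality index and CID boundary calling.

#' Directionality index of every bin
#'
#' For each bin `i`, the upstream and downstream contact sums within a
#' genomic window of `w = window/binSize` bins are
#' `A = sum_d M[i, i-d]` and `B = sum_d M[i, i+d]` (`d = 1..w`, circular
#' indices), with expected value `E = (A+B)/2`.  The directionality index
#' is the signed chi-square-like statistic
#' `DI = sign(B - A) * ((A-E)^2/E + (B-E)^2/E)`,
#' zero when `A == B` or `E == 0`.  Positive DI marks a downstream
#' (rightward) contact bias, negative an upstream bias; domains start where
#' the DI flips from negative to positive.
#'
#' @param M a normalised [ContactMatrix].
#' @param window window size in base pairs (default 100 kb = 20 bins at
#'   5 kb); `window/binSize` must be `>= 1` and `< nBins/2`.
#' @return a [DIProfile].
#' @export
directionalityIndex <- function(M, window = 1e5) {
    v <- contactValues(M)
    n <- nrow(v)
    w <- as.integer(floor(window / binSize(M)))
    if (w < 1L) stop("window must cover at least one bin", call. = FALSE)
    if (w >= n / 2) stop("window must be < half the genome", call. = FALSE)
    i <- seq_len(n)
    A <- B <- numeric(n)
    for (d in seq_len(w)) {
        A <- A + v[cbind(i, .wrap(i - d, n))]
        B <- B + v[cbind(i, .wrap(i + d, n))]
    }
    E <- (A + B) / 2
    di <- numeric(n)
    ok <- E > 0 & A != B
    di[ok] <- sign(B[ok] - A[ok]) *
        ((A[ok] - E[ok])^2 / E[ok] + (B[ok] - E[ok])^2 / E[ok])
    new("DIProfile", binning = binning(M), di = di, upstream = A,
        downstream = B, window = as.numeric(window))
}

# maximal sign runs over the non-zero DI bins, scanned circularly.
# Returns a list of list(sign, bins) in circular order.
.signRuns <- function(di) {
    nz <- which(di != 0)
    if (!length(nz)) return(list())
    s <- sign(di[nz])
    # rotate so that position 1 starts a new run (if any change exists)
    chg <- which(s != s[c(length(s), seq_len(length(s) - 1L))])
    if (length(chg)) {
        rot <- chg[1L]
        ord <- c(rot:length(s), if (rot > 1L) 1:(rot - 1L))
        s <- s[ord]; nz <- nz[ord]
    }
    r <- rle(s)
    ends <- cumsum(r$lengths)
    starts <- c(1L, head(ends, -1L) + 1L)
    mapply(function(a, b, sg) list(sign = sg, bins = nz[a:b]),
           starts, ends, r$values, SIMPLIFY = FALSE)
}

#' Call CID boundaries from DI sign alternation
#'
#' Scans the DI profile circularly for alternations of sign.  Zero-DI bins
#' are skipped; maximal sign runs shorter than `minRun` non-zero bins are
#' ignored (suppressing single-bin flips) and their neighbours merged.  A
#' boundary — the start of a chromosome interaction domain — is placed at
#' the first bin of each remaining positive run that directly follows a
#' negative run.  On a circular genome the number of CIDs equals the number
#' of boundaries.
#'
#' @param di a [DIProfile].
#' @param minRun minimum run length in (non-zero) bins (default 3).
#' @param zeroTol DI values below `zeroTol * max(abs(di))` are treated as
#'   zero during run detection (default 0.02).  DI magnitudes this far
#'   below the strongest signal are indistinguishable from the balancing
#'   ripple and counting noise of the matrix, and letting them form sign
#'   runs would place boundaries inside essentially balanced regions.
#'   Set to 0 for the raw sign-alternation scan.
#' @param conditionLabel label stored in the result.
#' @return a [BoundarySet].
#' @export
callCidBoundaries <- function(di, minRun = 3, zeroTol = 0.02,
                              conditionLabel = "") {
    stopifnot(minRun >= 1)
    d <- diValues(di)
    if (any(d != 0)) d[abs(d) < zeroTol * max(abs(d))] <- 0
    runs <- .signRuns(d)
    runs <- Filter(function(r) length(r$bins) >= minRun, runs)
    if (length(runs) < 2)
        return(BoundarySet(integer(0), binning(di), conditionLabel))
    # merge adjacent same-sign runs left after dropping the short ones
    merged <- list(runs[[1]])
    for (r in runs[-1]) {
        last <- merged[[length(merged)]]
        if (r$sign == last$sign)
            merged[[length(merged)]]$bins <- c(last$bins, r$bins)
        else merged[[length(merged) + 1L]] <- r
    }
    if (length(merged) > 1 &&
        merged[[1]]$sign == merged[[length(merged)]]$sign) {
        merged[[1]]$bins <- c(merged[[length(merged)]]$bins, merged[[1]]$bins)
        merged[[length(merged)]] <- NULL
    }
    if (length(merged) < 2)
        return(BoundarySet(integer(0), binning(di), conditionLabel))
    signs <- vapply(merged, `[[`, numeric(1), "sign")
    k <- length(merged)
    prevSign <- signs[c(k, seq_len(k - 1L))]
    hit <- which(signs > 0 & prevSign < 0)
    b <- vapply(merged[hit], function(r) r$bins[1L], integer(1))
    BoundarySet(b, binning(di), conditionLabel)
}

#' Match CID boundaries between two conditions
#'
#' Greedy nearest matching of boundaries under circular bin distance
#' `<= toleranceBins`; closest pairs are matched first and each boundary is
#' used at most once.  Unmatched boundaries are condition-unique (the
#' "differential" boundaries whose genes are of interest downstream).
#'
#' @param a,b [BoundarySet] objects on the same binning.
#' @param toleranceBins maximum circular distance (bins) for a match
#'   (default 1).
#' @return a list with `matched` (two-column matrix of paired bin indices,
#'   columns `a` and `b`), `uniqueToA`, `uniqueToB` and `toleranceBins`.
#' @export
compareBoundaries <- function(a, b, toleranceBins = 1) {
    .checkSameBinning(a, b)
    n <- nBins(a)
    ba <- boundaries(a); bb <- boundaries(b)
    pairs <- expand.grid(ia = seq_along(ba), ib = seq_along(bb))
    if (nrow(pairs)) {
        pairs$d <- circularBinDistance(ba[pairs$ia], bb[pairs$ib], n,
                                       isCircular(a))
        pairs <- pairs[pairs$d <= toleranceBins, , drop = FALSE]
        pairs <- pairs[order(pairs$d, pairs$ia), , drop = FALSE]
    }
    usedA <- logical(length(ba)); usedB <- logical(length(bb))
    mA <- mB <- integer(0)
    for (r in seq_len(nrow(pairs))) {
        ia <- pairs$ia[r]; ib <- pairs$ib[r]
        if (!usedA[ia] && !usedB[ib]) {
            usedA[ia] <- usedB[ib] <- TRUE
            mA <- c(mA, ba[ia]); mB <- c(mB, bb[ib])
        }
    }
    list(matched = cbind(a = mA, b = mB),
         uniqueToA = ba[!usedA], uniqueToB = bb[!usedB],
         toleranceBins = toleranceBins)
}

#' Genes overlapping CID boundary bins
#'
#' Returns the identifiers of genes whose interval overlaps any boundary
#' bin's genomic span, strand-agnostically.  A gene ending exactly where a
#' boundary bin starts does not overlap it.
#'
#' @param bset a [BoundarySet].
#' @param annotation a `GRanges` (e.g. from [readGeneAnnotation()]) or a
#'   `data.frame` with columns `gene_id`, `start`, `end` (1-based closed
#'   coordinates).
#' @return character vector of gene identifiers.
#' @export
boundaryGenes <- function(bset, annotation) {
    bn <- binning(bset)
    if (is(annotation, "GRanges")) {
        ids <- if (!is.null(annotation$gene_id)) annotation$gene_id
               else if (!is.null(names(annotation))) names(annotation)
               else as.character(seq_along(annotation))
        gstart <- GenomicRanges::start(annotation)
        gend <- GenomicRanges::end(annotation)
    } else {
        ids <- as.character(annotation$gene_id)
        gstart <- annotation$start
        gend <- annotation$end
    }
    if (any(gend < gstart)) stop("gene end < start", call. = FALSE)
    if (any(gstart < 1) || any(gend > bn@genomeLength))
        stop("gene coordinates beyond genome length", call. = FALSE)
    if (!length(boundaries(bset))) return(character(0))
    bs <- bn@binSize
    binStart <- (boundaries(bset) - 1L) * bs + 1
    binEnd <- pmin(boundaries(bset) * bs, bn@genomeLength)
    genes <- IRanges::IRanges(start = gstart, end = gend)
    bins <- IRanges::IRanges(start = binStart, end = binEnd)
    hits <- IRanges::findOverlaps(genes, bins)
    unique(ids[S4Vectors::queryHits(hits)])
}

#' Read a gene annotation from GFF3
#'
#' Thin wrapper over `rtracklayer::import` keeping `gene` features (or all
#' features when none are typed `gene`) with a `gene_id` column.
#'
#' @param path GFF3 file path.
#' @return a `GRanges` with a `gene_id` metadata column.
#' @export
readGeneAnnotation <- function(path) {
    g <- rtracklayer::import(path, format = "gff3")
    if (any(g$type == "gene")) g <- g[g$type == "gene"]
    id <- if (!is.null(g$gene_id)) g$gene_id else if (!is.null(g$ID)) g$ID
          else if (!is.null(g$Name)) g$Name else as.character(seq_along(g))
    g$gene_id <- as.character(id)
    g
}

#' Export CID boundaries as BED
#'
#' One BED line per boundary bin (0-based half-open spans).
#'
#' @param bset a [BoundarySet].
#' @param path output file path.
#' @param chrom chromosome name to write (default "chr").
#' @return the path, invisibly.
#' @export
writeBoundariesBed <- function(bset, path, chrom = "chr") {
    bn <- binning(bset)
    b <- boundaries(bset)
    df <- data.frame(chrom = chrom,
                     start = (b - 1L) * bn@binSize,
                     end = pmin(b * bn@binSize, bn@genomeLength),
                     name = sprintf("CID_boundary_%d", seq_along(b)))
    write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
                col.names = FALSE)
    invisible(path)
}
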